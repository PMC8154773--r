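#' Reanalysis precision: RMS-SD
#'
#' Root-mean-square average over subjects of the per-subject standard
#' deviation of repeated analyses: `RMS-SD = sqrt(mean_i SD_i^2)` with
#' `SD_i` the sample (n-1 denominator) standard deviation of subject i's
#' replicates, in units of the measured variable.
#'
#' @param replicates data frame with columns `subject`, `value` and
#'   optionally further grouping columns (ignored here), or a numeric
#'   matrix with one row per subject.
#' @return RMS-SD (scalar).
#' @export
rms_sd <- function(replicates) {
  sds <- replicate_sds(replicates)
  sqrt(mean(sds^2))
}

#' Reanalysis precision: RMS-CV
#'
#' Root-mean-square average over subjects of the per-subject coefficient
#' of variation in percent: `CV_i = 100 * SD_i / mean_i`,
#' `RMS-CV = sqrt(mean_i CV_i^2)`.  Requires strictly positive subject
#' means.
#'
#' @inheritParams rms_sd
#' @return RMS-CV in percent (scalar).
#' @export
rms_cv <- function(replicates) {
  sds <- replicate_sds(replicates)
  means <- replicate_means(replicates)
  if (any(means <= 0))
    stop("RMS-CV requires strictly positive subject means")
  sqrt(mean((100 * sds / means)^2))
}

replicate_list <- function(replicates) {
  if (is.matrix(replicates)) {
    if (ncol(replicates) < 2L)
      stop("need at least 2 replicates per subject")
    return(split(replicates, row(replicates)))
  }
  if (!is.data.frame(replicates) ||
      !all(c("subject", "value") %in% names(replicates)))
    stop("`replicates` must be a matrix or a data frame with columns ",
         "`subject` and `value`")
  out <- split(replicates$value, as.character(replicates$subject))
  if (any(lengths(out) < 2L))
    stop("need at least 2 replicates per subject")
  if (length(unique(lengths(out))) > 1L)
    stop("all subjects must have the same replicate count")
  out
}

replicate_sds <- function(replicates)
  vapply(replicate_list(replicates), stats::sd, numeric(1))

replicate_means <- function(replicates)
  vapply(replicate_list(replicates), mean, numeric(1))

#' Precision table over parameters and groups
#'
#' Builds the standard reanalysis-precision summary: per parameter, the
#' grand mean, RMS-SD (units of the variable) and RMS-CV (%), overall
#' ("All") and stratified by group.
#'
#' @param replicates data frame with columns `subject`, `parameter`,
#'   `value`, and optionally `group`.
#' @return data frame with columns `group`, `parameter`, `mean`, `rms_sd`,
#'   `rms_cv`, `n_subjects`; the "All" rows come first.  Empty groups are
#'   dropped with a warning.
#' @export
precision_report <- function(replicates) {
  if (!all(c("subject", "parameter", "value") %in% names(replicates)))
    stop("`replicates` needs columns subject, parameter, value")
  if (is.null(replicates$group)) replicates$group <- "G1"
  groups <- unique(as.character(replicates$group))
  rows <- list()
  for (g in c("All", groups)) {
    sub <- if (g == "All") replicates
    else replicates[replicates$group == g, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning(sprintf("group '%s' is empty; omitted", g))
      next
    }
    for (p in unique(as.character(sub$parameter))) {
      ps <- sub[sub$parameter == p, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, parameter = p,
        mean = mean(replicate_means(ps[c("subject", "value")])),
        rms_sd = rms_sd(ps[c("subject", "value")]),
        rms_cv = rms_cv(ps[c("subject", "value")]),
        n_subjects = length(unique(ps$subject)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
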