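#' Pipeline configuration
#'
#' All stage parameters of the end-to-end segmentation/quantification
#' pipeline with their documented defaults.  The configuration serialises
#' round-trip stably to YAML; unknown keys are rejected.
#'
#' @param ... named overrides of the defaults, either top-level sections
#'   or `section = list(key = value)` partial overrides.
#' @return a nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    bias = list(order = 3L, k = 6L, tol = 1e-3, max_iter = 20L),
    fcm = list(k = 4L, m = 2, tol = 1e-4, max_iter = 200L),
    thigh = list(rind_voxels = 2L, close_radius = 2L),
    femur = list(expect = TRUE, min_voxels = 50L),
    envelope = list(g_stop = 0.2, curvature_weight = 1, smooth_every = 5L,
                    max_iter = 300L, conv_tol = 1e-4,
                    edge_quantile = 0.9, edge_value = 0.1),
    fascia = list(scales_mm = c(1.0, 1.5, 2.5), alpha = 0.5, beta = 0.5,
                  g_stop = 0.3),
    livewire = list(w_edge = 0.6, w_fascia = 0.4, window = 3L,
                    n_slices = 10L),
    histogram = list(bin_width = 10, smooth_window = 5L),
    trim = list(n = 3L),
    registration = list(bins = 32L, max_samples = 120000L, maxit = 400L))
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) &&
      is.list(over[[1L]])) over <- over[[1L]]
  cfg <- merge_config(defaults, over)
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(base, over) {
  if (length(over) == 0L) return(base)
  nm <- names(over)
  if (is.null(nm) || any(nm == ""))
    stop("configuration overrides must be named")
  for (k in nm) {
    if (!k %in% names(base))
      stop(sprintf("unknown configuration key '%s'", k))
    if (is.list(base[[k]]) && is.list(over[[k]]))
      base[[k]] <- merge_config(base[[k]], over[[k]])
    else base[[k]] <- over[[k]]
  }
  base
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return [pipeline_config()] for `read_config`; `path` invisibly for
#'   `write_config`.
#' @export
read_config <- function(path) pipeline_config(yaml::read_yaml(path))

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full segmentation and quantification pipeline
#'
#' Executes bias correction, fuzzy c-means clustering, thigh/femur
#' extraction, the muscle-envelope level set, fascia-lata plate filtering
#' and surface closure, optional scripted livewire refinement, and IMAT /
#' fat-fraction quantification.  Without an FF volume the pipeline stops
#' after the T1w quantities and marks the FF fields as absent.
#'
#' @param t1w T1w input: a [vol3d()] or a NIfTI path.
#' @param ff Dixon fat-fraction input: [vol3d()], NIfTI path, or `NULL`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every intermediate mask,
#'   the contours, the report and a run manifest are written there.
#' @param refinements optional list of scripted livewire edits, each a
#'   list with `slice` (0-based) and `seeds` (n-by-2 matrix); seeds are
#'   propagated `config$livewire$n_slices` slices forward and each
#'   resulting contour applied.
#' @return a list of class `pipeline_result`: `report` ([quant_report()]),
#'   masks (`thigh`, `femur`, `me`, `if_voi`), `labels`, `weights`,
#'   `contours`, `transform` (or `NULL`), `mt` (threshold object or
#'   `NULL`), `bias_model`, `degenerate_fl` flag.
#' @export
run_pipeline <- function(t1w, ff = NULL, config = pipeline_config(),
                         out_dir = NULL, refinements = NULL) {
  if (is.character(t1w)) t1w <- read_volume(t1w)
  if (is.character(ff)) ff <- read_volume(ff)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # rough foreground for the bias fit (the thigh proper is not known yet)
  fg <- stage("foreground", {
    thr <- 0.1 * stats::quantile(t1w$values, 0.99, names = FALSE)
    m <- t1w$values > thr
    m <- fill_holes_slices(close_slices(m, 2L))
    like_mask(largest_component_3d(m), t1w)
  })
  bc <- stage("bias", correct_bias(t1w, fg, order = config$bias$order,
                                   k = config$bias$k, tol = config$bias$tol,
                                   max_iter = config$bias$max_iter))
  mem <- stage("fcm", fcm(bc$volume, k = config$fcm$k, m = config$fcm$m,
                          tol = config$fcm$tol,
                          max_iter = config$fcm$max_iter))
  lab <- stage("harden", harden(mem))
  thigh <- stage("thigh", thigh_surface(lab, bc$volume,
                                        rind_voxels = config$thigh$rind_voxels,
                                        close_radius = config$thigh$close_radius))
  femur <- if (isTRUE(config$femur$expect))
    stage("femur", segment_femur(lab, thigh,
                                 min_voxels = config$femur$min_voxels))
  else NULL

  env_params <- level_set_params(g_stop = config$envelope$g_stop,
                                 curvature_weight = config$envelope$curvature_weight,
                                 smooth_every = config$envelope$smooth_every,
                                 max_iter = config$envelope$max_iter,
                                 conv_tol = config$envelope$conv_tol,
                                 edge_quantile = config$envelope$edge_quantile,
                                 edge_value = config$envelope$edge_value)
  me <- stage("envelope", muscle_envelope(mem, thigh, env_params))
  weights <- stage("fascia_weights",
                   fascia_weights(bc$volume, tissue_mask(lab, "fibrous"), me,
                                  scales_mm = config$fascia$scales_mm,
                                  alpha = config$fascia$alpha,
                                  beta = config$fascia$beta))
  fl_params <- level_set_params(g_stop = config$fascia$g_stop,
                                curvature_weight = config$envelope$curvature_weight,
                                smooth_every = config$envelope$smooth_every,
                                max_iter = config$envelope$max_iter,
                                conv_tol = config$envelope$conv_tol)
  fl <- stage("fl_surface",
              withCallingHandlers(
                fl_surface(me, weights, thigh, fl_params),
                warning = function(w) invokeRestart("muffleWarning")))
  if_voi <- fl$if_voi
  contours <- fl$contours

  if (!is.null(refinements)) {
    cost <- stage("refine", cost_map(bc$volume, weights,
                                     w_edge = config$livewire$w_edge,
                                     w_fascia = config$livewire$w_fascia))
    for (r in refinements) {
      ss <- seed_set(r$slice, r$seeds, closed = TRUE)
      sets <- c(list(ss),
                propagate_seeds(ss, cost,
                                n_slices = config$livewire$n_slices,
                                window = config$livewire$window,
                                mask = thigh))
      for (s in sets) {
        ct <- livewire_contour(cost, s)
        if_voi <- apply_refinement(if_voi, ct, s$slice)
        contours[[s$slice + 1L]] <- ct
      }
    }
    if_voi <- like_mask(if_voi$values | me$values, thigh)
  }

  trim_n <- config$trim$n
  if_trim <- stage("trim", trim_slices(if_voi, trim_n))
  me_trim <- trim_slices(me, trim_n)
  imat_fl <- stage("imat", imat_volume(lab, if_trim, femur))
  imat_me <- imat_volume(lab, me_trim, femur)
  analysis <- if_trim$values & (if (is.null(femur)) TRUE else !femur$values)
  volume_total <- sum(analysis) * voxel_volume_mm3(if_voi) / 1000
  d3 <- dim(if_voi$values)[3L]
  slices <- length(unique(which(analysis, arr.ind = TRUE)[, 3L]))

  transform <- NULL; mt <- NULL; ffmt <- NA_real_; thr <- NA_real_
  if (!is.null(ff)) {
    ff_mask <- stage("ff_mask", {
      m <- ff$values > 0.1 * stats::quantile(ff$values, 0.999, names = FALSE)
      m <- fill_holes_slices(close_slices(m, 2L))
      like_mask(largest_component_3d(m), ff)
    })
    transform <- stage("registration",
                       register_rigid(bc$volume, thigh, ff, ff_mask,
                                      bins = config$registration$bins,
                                      max_samples = config$registration$max_samples,
                                      maxit = config$registration$maxit))
    inv <- invert_rigid(transform)
    if_ff <- resample(if_trim, inv, target = like_mask(
      array(FALSE, dim(ff$values)), ff))
    fem_ff <- if (is.null(femur)) NULL else
      resample(femur, inv, target = like_mask(array(FALSE, dim(ff$values)),
                                              ff))
    voi_ff <- like_mask(if_ff$values &
                          (if (is.null(fem_ff)) TRUE else !fem_ff$values),
                        ff)
    mt <- stage("mt_threshold",
                mt_threshold(ff, voi_ff,
                             bin_width = config$histogram$bin_width,
                             smooth_window = config$histogram$smooth_window))
    thr <- mt$threshold
    mt_mask <- like_mask(voi_ff$values & ff$values < thr, ff)
    ffmt <- stage("ff_mt", ff_mt(ff, mt_mask))
  }

  report <- quant_report(volume_total_cm3 = volume_total,
                         imat_fl_cm3 = imat_fl, imat_me_cm3 = imat_me,
                         ff_mt_pct = ffmt, mt_threshold = thr,
                         slices_analyzed = slices)
  result <- structure(list(report = report, thigh = thigh, femur = femur,
                           me = me, if_voi = if_voi, labels = lab,
                           weights = weights, contours = contours,
                           transform = transform, mt = mt,
                           bias_model = bc$model,
                           degenerate_fl = fl$degenerate,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, bc$volume, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  if (x$degenerate_fl)
    cat("  NOTE: fascia surface degenerate (IF = ME)\n")
  invisible(x)
}

write_pipeline_outputs <- function(result, corrected, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(corrected, file.path(out_dir, "t1w_bc.nii.gz"))
  write_volume(result$thigh, file.path(out_dir, "thigh.nii.gz"))
  if (!is.null(result$femur))
    write_volume(result$femur, file.path(out_dir, "femur.nii.gz"))
  write_volume(result$me, file.path(out_dir, "me.nii.gz"))
  write_volume(result$if_voi, file.path(out_dir, "if_voi.nii.gz"))
  write_volume(result$weights, file.path(out_dir, "weights.nii.gz"))
  contours <- lapply(result$contours, function(ct)
    if (nrow(ct) > 0L) unname(as.matrix(ct)) else matrix(0, 0L, 2L))
  jsonlite::write_json(contours, file.path(out_dir, "fl_contours.json"),
                       matrix = "rowmajor")
  jsonlite::write_json(unclass(result$report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- list(
    config = unclass(result$config),
    checksums = list(
      me_voxels = sum(result$me$values),
      if_voxels = sum(result$if_voi$values),
      thigh_voxels = sum(result$thigh$values)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
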