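#' Synthetic thigh phantom specification
#'
#' Defines the geometry, tissue intensities and degradation model of a
#' synthetic mid-thigh MR phantom: a bright subcutaneous fat ring (SAT)
#' under a skin rind, a darker muscle ensemble carrying thin intramuscular
#' fat streaks, a thin dark fascia lata (FL) sheet separating SAT from the
#' perimuscular fat that lies between the muscle surface and the FL, a
#' femur (dark cortex, bright marrow), a saphenous-fascia decoy arc inside
#' the SAT, a smooth multiplicative bias field and additive Gaussian noise.
#' A paired fat-fraction (FF) volume is generated on its own coarser grid
#' under a known rigid offset; FF intensities use the scanner convention of
#' 0--1000 encoding 0.0--100.0 % fat.
#'
#' Cross-section outlines are star-convex perturbed circles (low-order
#' angular harmonics) and the FL centre drifts smoothly through the stack,
#' so the sheet is a genuinely 3D surface and the level-set stages are
#' exercised on non-trivial shapes.
#'
#' @param grid_shape integer length-3, voxels per axis of the T1w grid.
#' @param spacing_mm T1w voxel spacing (mm); default the 0.5 x 0.5 x 3.0 mm
#'   acquisition this phantom emulates.
#' @param thigh_radius_mm mean outer radius of the thigh cross-section.
#' @param fascia_thickness_mm thickness of the FL sheet (>= 1 in-plane voxel).
#' @param perimuscular_fat_fraction fraction of the intra-fascia
#'   cross-section area occupied by adipose tissue between the muscle
#'   surface and the FL, per slice; in [0, 1).
#' @param intramuscular_streak_count number of thin fat streaks inside the
#'   muscle ensemble.
#' @param streak_width_mm width of each streak.
#' @param femur_radius_mm outer radius of the femur (cortex included).
#' @param femur_cortex_mm cortical thickness.
#' @param femur_offset_mm in-plane offset of the femur centre from the
#'   thigh centre.
#' @param saphenous_decoy logical, add a fascia-like arc in the SAT.
#' @param decoy_angle_deg,decoy_span_deg position and angular span of the
#'   decoy arc.
#' @param skin_thickness_mm thickness of the skin rind.
#' @param fl_radius_frac FL radius as a fraction of the local thigh radius.
#' @param class_means named T1w mean intensities: `background`, `fibrous`,
#'   `muscle`, `AT`, `marrow`, `skin`; the first four must be strictly
#'   increasing (the intensity ordering the clustering stage relies on).
#' @param noise_sd additive Gaussian noise SD on the T1w intensities.
#' @param bias_coeffs named coefficients of the log-polynomial bias field
#'   (see [apply_bias()]); `NULL` disables the bias field.
#' @param ff_means named FF-map intensities (0--1000 scale) per class.
#' @param ff_noise_sd additive Gaussian noise SD on FF intensities.
#' @param ff_spacing_mm FF grid spacing; default 0.8 x 0.8 x 3.0 mm.
#' @param rigid_offset true [rigid3d()] mapping T1w world coordinates to FF
#'   world coordinates (centre taken at the T1w grid centre).
#' @param drift_amplitude_mm in-plane drift amplitude of the FL centre
#'   through the stack.
#' @param rng_seed integer seed controlling outline perturbation, streak
#'   placement and noise.
#' @return a validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(152L, 152L, 17L),
                         spacing_mm = c(0.5, 0.5, 3.0),
                         thigh_radius_mm = 32,
                         fascia_thickness_mm = 1.5,
                         perimuscular_fat_fraction = 0.25,
                         intramuscular_streak_count = 4L,
                         streak_width_mm = 1.2,
                         femur_radius_mm = 8,
                         femur_cortex_mm = 2,
                         femur_offset_mm = c(-5, -2.5),
                         saphenous_decoy = TRUE,
                         decoy_angle_deg = 200,
                         decoy_span_deg = 60,
                         skin_thickness_mm = 1.2,
                         fl_radius_frac = 0.72,
                         class_means = c(background = 10, fibrous = 160,
                                         muscle = 420, AT = 820,
                                         marrow = 800, skin = 700),
                         noise_sd = 15,
                         bias_coeffs = c(x = 0.06, y = -0.05, z = 0.03,
                                         xx = -0.04, yy = 0.03, xy = 0.02),
                         ff_means = c(background = 0, fibrous = 300,
                                      muscle = 65, AT = 850,
                                      marrow = 820, skin = 250),
                         ff_noise_sd = 20,
                         ff_spacing_mm = c(0.8, 0.8, 3.0),
                         rigid_offset = rigid3d(c(0, 0, 1.5), c(2, -1.5, 0)),
                         drift_amplitude_mm = 1.5,
                         rng_seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               spacing_mm = as.numeric(spacing_mm),
               thigh_radius_mm = thigh_radius_mm,
               fascia_thickness_mm = fascia_thickness_mm,
               perimuscular_fat_fraction = perimuscular_fat_fraction,
               intramuscular_streak_count = as.integer(intramuscular_streak_count),
               streak_width_mm = streak_width_mm,
               femur_radius_mm = femur_radius_mm,
               femur_cortex_mm = femur_cortex_mm,
               femur_offset_mm = as.numeric(femur_offset_mm),
               saphenous_decoy = isTRUE(saphenous_decoy),
               decoy_angle_deg = decoy_angle_deg,
               decoy_span_deg = decoy_span_deg,
               skin_thickness_mm = skin_thickness_mm,
               fl_radius_frac = fl_radius_frac,
               class_means = class_means,
               noise_sd = noise_sd,
               bias_coeffs = bias_coeffs,
               ff_means = ff_means,
               ff_noise_sd = ff_noise_sd,
               ff_spacing_mm = as.numeric(ff_spacing_mm),
               rigid_offset = rigid_offset,
               drift_amplitude_mm = drift_amplitude_mm,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 8L))
      stop("grid_shape must be 3 integers >= 8")
    if (any(spacing_mm <= 0) || any(ff_spacing_mm <= 0))
      stop("voxel spacing must be strictly positive")
    if (fascia_thickness_mm < max(spacing_mm[1:2]))
      stop("fascia_thickness_mm must be at least one in-plane voxel")
    if (perimuscular_fat_fraction < 0 || perimuscular_fat_fraction >= 1)
      stop("perimuscular_fat_fraction must lie in [0, 1)")
    cm <- class_means[c("background", "fibrous", "muscle", "AT")]
    if (anyNA(cm) || any(diff(cm) <= 0))
      stop("class_means must satisfy background < fibrous < muscle < AT")
    # the whole outline (harmonics can add ~10 %) must fit the grid
    half_extent <- min(grid_shape[1:2] * spacing_mm[1:2]) / 2
    if (thigh_radius_mm * 1.12 + 1 > half_extent)
      stop("thigh_radius_mm too large for the grid")
    # femur must sit strictly inside the smallest possible muscle outline
    r_me_min <- sqrt(1 - perimuscular_fat_fraction) * fl_radius_frac *
      thigh_radius_mm * 0.88
    if (sqrt(sum(femur_offset_mm^2)) + femur_radius_mm + 1 > r_me_min)
      stop("femur does not fit inside the muscle ensemble")
    if (noise_sd < 0 || ff_noise_sd < 0) stop("noise SDs must be >= 0")
  })
  invisible(spec)
}

# Tissue codes used by the phantom truth label volume.
PHANTOM_CLASSES <- c(background = 0L, skin = 1L, SAT = 2L, fascia = 3L,
                     decoy = 4L, perimuscular_AT = 5L, streak_AT = 6L,
                     muscle = 7L, femur_cortex = 8L, femur_marrow = 9L)

# Map tissue codes to the named intensity classes of class_means / ff_means.
class_to_intensity_group <- function(codes) {
  groups <- c("background", "skin", "AT", "fibrous", "fibrous",
              "AT", "AT", "muscle", "background", "marrow")
  groups[codes + 1L]
}

# Seeded nuisance parameters of one phantom's geometry.
phantom_geometry <- function(spec) {
  run_seeded(spec$rng_seed, {
    harmonics <- list(h = 2:4,
                      amp = stats::runif(3, 0.01, 0.04),
                      phase = stats::runif(3, 0, 2 * pi))
    drift_phase <- stats::runif(2, 0, 2 * pi)
    zmod_phase <- stats::runif(1, 0, 2 * pi)
    # streaks sit between muscle compartments: evenly spaced with a
    # random global rotation and a small per-streak jitter
    n_streaks <- spec$intramuscular_streak_count
    streak_angles <- if (n_streaks > 0L)
      2 * pi * seq_len(n_streaks) / n_streaks +
        stats::runif(1, 0, 2 * pi) +
        stats::runif(n_streaks, -0.12, 0.12)
    else numeric(0)
    list(harmonics = harmonics, drift_phase = drift_phase,
         zmod_phase = zmod_phase, streak_angles = streak_angles)
  })
}

# Evaluate the geometry at arbitrary world points (mm), vectorised.
# Returns integer tissue codes (PHANTOM_CLASSES).
classify_points <- function(spec, geom, xyz) {
  x <- xyz[, 1L]; y <- xyz[, 2L]; z <- xyz[, 3L]
  lz <- spec$grid_shape[3L] * spec$spacing_mm[3L]
  th <- atan2(y, x)
  shape <- rep(1, length(x))
  for (i in seq_along(geom$harmonics$h))
    shape <- shape + geom$harmonics$amp[i] *
      cos(geom$harmonics$h[i] * th + geom$harmonics$phase[i])
  zmod <- 1 + 0.02 * sin(2 * pi * z / lz + geom$zmod_phase)
  r_thigh <- spec$thigh_radius_mm * shape * zmod
  r <- sqrt(x^2 + y^2)

  # FL frame: centre drifts smoothly through the stack
  dx <- spec$drift_amplitude_mm * sin(2 * pi * z / lz + geom$drift_phase[1L])
  dy <- spec$drift_amplitude_mm * cos(2 * pi * z / lz + geom$drift_phase[2L])
  xf <- x - dx; yf <- y - dy
  thf <- atan2(yf, xf)
  shapef <- rep(1, length(x))
  for (i in seq_along(geom$harmonics$h))
    shapef <- shapef + geom$harmonics$amp[i] *
      cos(geom$harmonics$h[i] * thf + geom$harmonics$phase[i])
  r_fl <- spec$fl_radius_frac * spec$thigh_radius_mm * shapef * zmod
  rf <- sqrt(xf^2 + yf^2)
  half_t <- spec$fascia_thickness_mm / 2
  r_if <- r_fl - half_t
  r_me <- sqrt(1 - spec$perimuscular_fat_fraction) * r_if

  out <- rep.int(PHANTOM_CLASSES[["background"]], length(x))
  inside <- r < r_thigh
  skin <- inside & r >= r_thigh - spec$skin_thickness_mm
  fl <- inside & !skin & abs(rf - r_fl) <= half_t
  infl <- inside & !skin & rf < r_if
  sat <- inside & !skin & !fl & !infl

  out[sat] <- PHANTOM_CLASSES[["SAT"]]
  out[skin] <- PHANTOM_CLASSES[["skin"]]
  out[fl] <- PHANTOM_CLASSES[["fascia"]]

  if (spec$saphenous_decoy) {
    r_dec <- 0.5 * (spec$fl_radius_frac + 1) * spec$thigh_radius_mm *
      shape * zmod
    ang <- (th - spec$decoy_angle_deg * pi / 180 + pi) %% (2 * pi) - pi
    dec <- sat & abs(r - r_dec) <= half_t &
      abs(ang) <= spec$decoy_span_deg * pi / 360
    out[dec] <- PHANTOM_CLASSES[["decoy"]]
  }

  peri <- infl & rf >= r_me
  musc <- infl & rf < r_me
  out[peri] <- PHANTOM_CLASSES[["perimuscular_AT"]]
  out[musc] <- PHANTOM_CLASSES[["muscle"]]

  # femur (fixed in-plane position, straight bone)
  rho <- sqrt((x - spec$femur_offset_mm[1L])^2 +
                (y - spec$femur_offset_mm[2L])^2)
  cortex <- musc & rho <= spec$femur_radius_mm &
    rho > spec$femur_radius_mm - spec$femur_cortex_mm
  marrow <- musc & rho <= spec$femur_radius_mm - spec$femur_cortex_mm
  out[cortex] <- PHANTOM_CLASSES[["femur_cortex"]]
  out[marrow] <- PHANTOM_CLASSES[["femur_marrow"]]

  # intramuscular fat streaks: radial segments in the FL frame
  if (spec$intramuscular_streak_count > 0L) {
    r_me_bar <- sqrt(1 - spec$perimuscular_fat_fraction) *
      spec$fl_radius_frac * spec$thigh_radius_mm
    clearance <- 2 + spec$streak_width_mm / 2
    streak_ok <- musc & rho > spec$femur_radius_mm + 1 &
      rf < r_me - clearance
    for (a in geom$streak_angles) {
      u <- c(cos(a), sin(a))
      t0 <- 0.35 * r_me_bar; t1 <- 0.82 * r_me_bar
      proj <- xf * u[1L] + yf * u[2L]
      perp <- abs(xf * u[2L] - yf * u[1L])
      hit <- streak_ok & proj >= t0 & proj <= t1 &
        perp <= spec$streak_width_mm / 2
      out[hit] <- PHANTOM_CLASSES[["streak_AT"]]
    }
  }
  out
}

#' Generate a synthetic thigh phantom
#'
#' Builds the T1w volume (class means + Gaussian noise, multiplied by the
#' bias field), the paired FF volume on its own grid under the spec's rigid
#' offset, and exhaustive ground truth: one mask per tissue role plus the
#' true IMAT volumes and muscle fat fraction.  The truth masks are exact on
#' the T1w grid (no noise, no bias).
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `t1w` ([vol3d()]), `ff` ([vol3d()]), and
#'   `truth` (class `phantom_truth`): masks `thigh` (skin included), `skin`,
#'   `sat`, `fascia`, `decoy`, `if_region`, `me`, `perimuscular`, `streaks`,
#'   `femur`, `muscle`, the label volume `labels`, scalars `imat_fl_cm3`,
#'   `imat_me_cm3`, `ff_mt_pct`, and the true `rigid_offset`.
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)

  extent <- spec$grid_shape * spec$spacing_mm
  t1w_ref <- vol3d(array(0, spec$grid_shape), spec$spacing_mm, -extent / 2)
  centers <- all_voxel_centers(t1w_ref)
  codes <- classify_points(spec, geom, centers)
  groups <- class_to_intensity_group(codes)
  means <- spec$class_means[groups]

  labels <- array(codes, spec$grid_shape)
  cls <- PHANTOM_CLASSES
  msk <- function(which) like_mask(array(codes %in% cls[which],
                                         spec$grid_shape), t1w_ref)
  truth <- list(
    labels = like_volume(array(as.numeric(codes), spec$grid_shape), t1w_ref),
    thigh = msk(setdiff(names(cls), "background")),
    skin = msk("skin"),
    sat = msk(c("SAT", "decoy")),
    fascia = msk("fascia"),
    decoy = msk("decoy"),
    if_region = msk(c("perimuscular_AT", "streak_AT", "muscle",
                      "femur_cortex", "femur_marrow")),
    me = msk(c("streak_AT", "muscle", "femur_cortex", "femur_marrow")),
    perimuscular = msk("perimuscular_AT"),
    streaks = msk("streak_AT"),
    femur = msk(c("femur_cortex", "femur_marrow")),
    muscle = msk("muscle"))

  voxvol <- prod(spec$spacing_mm)
  truth$imat_fl_cm3 <- (sum(truth$perimuscular$values) +
                          sum(truth$streaks$values)) * voxvol / 1000
  truth$imat_me_cm3 <- sum(truth$streaks$values) * voxvol / 1000
  truth$ff_mt_pct <- unname(spec$ff_means[["muscle"]] / 10)
  truth$rigid_offset <- rigid3d(spec$rigid_offset$angles_deg,
                                spec$rigid_offset$translation_mm,
                                center = grid_center(t1w_ref))
  class(truth) <- "phantom_truth"

  t1w_vals <- run_seeded(spec$rng_seed + 1L,
                         means + stats::rnorm(length(means), 0, spec$noise_sd))
  t1w <- like_volume(array(t1w_vals, spec$grid_shape), t1w_ref)
  if (!is.null(spec$bias_coeffs))
    t1w <- apply_bias(t1w, spec$bias_coeffs, mask = truth$thigh)

  # FF volume: sample the anatomy at the pre-image of each FF voxel centre
  ff_shape <- c(pmax(8L, as.integer(ceiling(extent[1:2] /
                                              spec$ff_spacing_mm[1:2]))),
                spec$grid_shape[3L])
  ff_extent <- ff_shape * spec$ff_spacing_mm
  ff_ref <- vol3d(array(0, ff_shape), spec$ff_spacing_mm, -ff_extent / 2)
  inv <- invert_rigid(truth$rigid_offset)
  ff_pts <- transform_points(inv, all_voxel_centers(ff_ref))
  ff_codes <- classify_points(spec, geom, ff_pts)
  ff_mean <- spec$ff_means[class_to_intensity_group(ff_codes)]
  ff_vals <- run_seeded(spec$rng_seed + 2L,
                        ff_mean + stats::rnorm(length(ff_mean), 0,
                                               spec$ff_noise_sd))
  ff_vals <- pmin(1000, pmax(0, ff_vals))
  ff <- like_volume(array(ff_vals, ff_shape), ff_ref)

  list(t1w = t1w, ff = ff, truth = truth)
}

#' Apply a smooth multiplicative bias field
#'
#' The field is `exp(P(x))` with `P` a low-order polynomial in grid
#' coordinates normalised to [-1, 1] per axis, rescaled so its mean over
#' `mask` (or the whole grid) is exactly 1; the exponential form keeps the
#' field strictly positive, as a multiplicative MR bias field must be.
#'
#' @param volume a [vol3d()].
#' @param coeffs named numeric coefficients; recognised names are `x`, `y`,
#'   `z`, `xx`, `yy`, `zz`, `xy`, `xz`, `yz` (higher orders via
#'   [polynomial_basis()] powers are not needed for the phantom).
#' @param mask optional [mask3d()] over which the field is normalised to
#'   mean 1.
#' @return a list with `volume` (biased copy) when `return_field = FALSE`
#'   (default, returns just the volume) and the field itself via
#'   `attr(, "field")`.
#' @export
apply_bias <- function(volume, coeffs, mask = NULL) {
  field <- bias_field(volume, coeffs, mask)
  if (any(field$values <= 0)) stop("bias field must be strictly positive")
  out <- like_volume(volume$values * field$values, volume)
  attr(out, "field") <- field
  out
}

bias_field <- function(volume, coeffs, mask = NULL) {
  d <- dim(volume$values)
  nx <- norm_coord(d[1L]); ny <- norm_coord(d[2L]); nz <- norm_coord(d[3L])
  x <- array(rep(nx, times = d[2L] * d[3L]), d)
  y <- array(rep(rep(ny, each = d[1L]), d[3L]), d)
  z <- array(rep(nz, each = d[1L] * d[2L]), d)
  terms <- list(x = x, y = y, z = z, xx = x * x, yy = y * y, zz = z * z,
                xy = x * y, xz = x * z, yz = y * z)
  p <- array(0, d)
  for (nm in names(coeffs)) {
    if (!nm %in% names(terms))
      stop(sprintf("unknown bias coefficient '%s'", nm))
    p <- p + coeffs[[nm]] * terms[[nm]]
  }
  f <- exp(p)
  sel <- if (is.null(mask)) TRUE else mask$values
  f <- f / mean(f[sel])
  like_volume(f, volume)
}

norm_coord <- function(n) if (n == 1L) 0 else seq(-1, 1, length.out = n)

# Evaluate an expression with a private RNG stream, leaving the caller's
# .Random.seed untouched.
run_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a phantom to disk
#'
#' Writes `t1w.nii.gz`, `ff.nii.gz`, the truth label volume
#' (`truth_labels.nii.gz`, integer tissue codes), each truth mask as a
#' uint8 NIfTI, and the truth scalars as JSON.
#'
#' @param phantom result of [make_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$t1w, file.path(dir, "t1w.nii.gz"))
  write_volume(phantom$ff, file.path(dir, "ff.nii.gz"))
  write_volume(phantom$truth$labels, file.path(dir, "truth_labels.nii.gz"))
  for (nm in c("thigh", "skin", "sat", "fascia", "decoy", "if_region",
               "me", "perimuscular", "streaks", "femur", "muscle"))
    write_volume(phantom$truth[[nm]],
                 file.path(dir, sprintf("truth_%s.nii.gz", nm)))
  off <- phantom$truth$rigid_offset
  scalars <- list(imat_fl_cm3 = phantom$truth$imat_fl_cm3,
                  imat_me_cm3 = phantom$truth$imat_me_cm3,
                  ff_mt_pct = phantom$truth$ff_mt_pct,
                  rigid_offset = list(angles_deg = off$angles_deg,
                                      translation_mm = off$translation_mm,
                                      center_mm = off$center),
                  tissue_codes = as.list(PHANTOM_CLASSES))
  jsonlite::write_json(scalars, file.path(dir, "truth_scalars.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
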