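# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(builder), envir = .fixtures)
  get(name, envir = .fixtures)
}

dice <- function(a, b) {
  if (inherits(a, "mask3d")) a <- a$values
  if (inherits(b, "mask3d")) b <- b$values
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Reduced-field phantom used by the unit tests (smaller thigh, same voxel
# spacing and tissue model as the default).
small_spec <- function(...) {
  phantom_spec(grid_shape = c(96L, 96L, 12L),
               thigh_radius_mm = 20,
               femur_radius_mm = 5.5,
               femur_offset_mm = c(-3.2, -1.6),
               drift_amplitude_mm = 1.0,
               ...)
}

small_phantom <- function() fixture("small_phantom", make_phantom(small_spec()))

# Segmentation stages on the small phantom, shared across test files.
small_stages <- function() fixture("small_stages", {
  ph <- small_phantom()
  bc <- correct_bias(ph$t1w, ph$truth$thigh)
  mem <- fcm(bc$volume)
  lab <- harden(mem)
  thigh <- thigh_surface(lab, bc$volume)
  femur <- segment_femur(lab, thigh)
  me <- muscle_envelope(mem, thigh)
  weights <- fascia_weights(bc$volume, tissue_mask(lab, "fibrous"), me)
  fl <- fl_surface(me, weights, thigh)
  list(ph = ph, bc = bc, mem = mem, lab = lab, thigh = thigh,
       femur = femur, me = me, weights = weights, fl = fl)
})
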