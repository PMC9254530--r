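# Shared fixtures and independent oracles for the test suite.

# Tiny SUV volume from a vector of lesion values: the first length(suv)
# voxels of a zero grid carry the values, the mask marks exactly those.
toy_lesion <- function(suv, dims = NULL, spacing = c(4, 4, 4)) {
  n <- length(suv)
  if (is.null(dims)) dims <- c(max(n, 2), 2, 2)
  stopifnot(prod(dims) >= n)
  vals <- array(0, dim = dims)
  vals[seq_len(n)] <- suv
  msk <- array(FALSE, dim = dims)
  msk[seq_len(n)] <- TRUE
  list(volume = suv_volume(vals, spacing = spacing),
       mask = tumour_mask(msk, spacing = spacing))
}

# Brute-force AUC-CSH oracle: exact integral of the step function
# t -> #{suv >= t*ref}/n over t in [0,1], accumulated segment by segment
# over the sorted voxel values. Independent of compute_csh/auc_csh.
auc_csh_oracle <- function(suv, ref = max(suv)) {
  s <- sort(suv) / ref
  n <- length(s)
  s <- pmin(pmax(s, 0), 1)
  breaks <- c(0, s, 1)
  area <- 0
  for (i in seq_len(length(breaks) - 1)) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    if (hi > lo) {
      tm <- (lo + hi) / 2
      area <- area + (hi - lo) * sum(suv / ref >= tm) / n
    }
  }
  area
}

# Enumerate integer voxel offsets whose centre distance is <= r (mm);
# independent oracle for the SUVpeak sphere membership.
sphere_offsets_oracle <- function(r, spacing) {
  m <- floor(r / spacing)
  g <- expand.grid(i = -m[1]:m[1], j = -m[2]:m[2], k = -m[3]:m[3])
  keep <- (g$i * spacing[1])^2 + (g$j * spacing[2])^2 +
    (g$k * spacing[3])^2 <= r^2
  g[keep, , drop = FALSE]
}

# A default-geometry phantom, small enough for fast tests.
quick_phantom <- function(profile_kind, ..., spacing = 2, radius = 20,
                          shape = 27) {
  generate_phantom(phantom_spec(
    grid_shape = rep(shape, 3), voxel_spacing = rep(spacing, 3),
    tumour_radius = radius, profile_kind = profile_kind, ...))
}
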