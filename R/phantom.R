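#' Specification of a spherical digital PET phantom
#'
#' Defines a spherical lesion embedded in a uniform background, with one of
#' five radial SUV profiles chosen so that every downstream quantity
#' (SUVmean, MTV, TLG, AUC-CSH) has a closed form on the noise-free
#' continuous profile:
#'
#' * `homogeneous`: SUV = S everywhere in the lesion.
#' * `two_level`: an inner core at S occupying `high_volume_fraction` of the
#'   lesion volume, the remainder at `S * low_fraction`.
#' * `radial_linear`: SUV(r) = S (1 - r/R), peaked at the centre.
#' * `necrotic_core`: a hypometabolic core at `S * core_level_fraction`
#'   inside radius `core_radius_fraction * R`, viable rim at S.
#' * `uniform_histogram`: SUV(r) = S (1 - (r/R)^3), whose volume histogram
#'   is uniform on (0, S].
#'
#' @param grid_shape integer length-3, voxel counts per axis.
#' @param voxel_spacing numeric length-3, mm per axis.
#' @param tumour_centre voxel coordinates (0-based) of the lesion centre;
#'   default is the grid centre.
#' @param tumour_radius lesion radius R in mm.
#' @param profile_kind one of the five profiles above.
#' @param suv_max_true peak SUV S of the noise-free profile.
#' @param profile_params list of profile-specific scalars; defaults:
#'   `low_fraction = 0.5`, `high_volume_fraction = 0.5` (two_level),
#'   `core_radius_fraction = 0.5`, `core_level_fraction = 0.1`
#'   (necrotic_core).
#' @param noise_sd additive Gaussian SUV noise inside the lesion (the
#'   result is clipped at 0); the analytic truth is always noise-free.
#' @param background_suv SUV outside the lesion (default 0.5); must be
#'   below `suv_max_true`.
#' @param seed integer RNG seed; same seed gives a bit-identical phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(33, 33, 33),
                         voxel_spacing = c(4, 4, 4),
                         tumour_centre = NULL,
                         tumour_radius = 25,
                         profile_kind = c("homogeneous", "two_level",
                                          "radial_linear", "necrotic_core",
                                          "uniform_histogram"),
                         suv_max_true = 4,
                         profile_params = list(),
                         noise_sd = 0,
                         background_suv = 0.5,
                         seed = 1L) {
  profile_kind <- match.arg(profile_kind)
  grid_shape <- as.integer(grid_shape)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive voxel counts")
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop("voxel_spacing must be 3 positive sizes in mm")
  if (is.null(tumour_centre)) tumour_centre <- (grid_shape - 1) / 2
  if (tumour_radius <= 0) stop("tumour_radius must be > 0 mm")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (background_suv < 0) stop("background_suv must be >= 0")
  if (suv_max_true <= background_suv)
    stop("suv_max_true must exceed background_suv")
  defaults <- list(low_fraction = 0.5, high_volume_fraction = 0.5,
                   core_radius_fraction = 0.5, core_level_fraction = 0.1)
  pp <- utils::modifyList(defaults, profile_params)
  if (pp$low_fraction <= 0 || pp$low_fraction >= 1)
    stop("low_fraction must be in (0,1)")
  if (pp$high_volume_fraction <= 0 || pp$high_volume_fraction >= 1)
    stop("high_volume_fraction must be in (0,1)")
  if (pp$core_radius_fraction <= 0 || pp$core_radius_fraction >= 1)
    stop("core_radius_fraction must be in (0,1)")
  if (pp$core_level_fraction < 0 || pp$core_level_fraction >= 1)
    stop("core_level_fraction must be in [0,1)")
  # lesion must fit inside the grid (voxel-centre extent)
  centre_mm <- tumour_centre * voxel_spacing
  extent_mm <- (grid_shape - 1) * voxel_spacing
  if (any(centre_mm - tumour_radius < 0) ||
      any(centre_mm + tumour_radius > extent_mm))
    stop("tumour of radius ", tumour_radius,
         " mm extends outside the voxel grid; enlarge grid_shape or ",
         "reduce tumour_radius")
  structure(list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                 tumour_centre = as.numeric(tumour_centre),
                 tumour_radius = tumour_radius, profile_kind = profile_kind,
                 suv_max_true = suv_max_true, profile_params = pp,
                 noise_sd = noise_sd, background_suv = background_suv,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Noise-free continuous-profile truths. mean_frac is SUVmean/SUVmax, which
# equals the exact AUC-CSH through the cumulative-histogram identity.
phantom_analytic <- function(spec) {
  S <- spec$suv_max_true
  R <- spec$tumour_radius
  pp <- spec$profile_params
  a <- (3 * 1000 / (4 * pi))^(1 / 3)  # radius of the 1 cm^3 SUVpeak sphere, mm
  mean_frac <- switch(spec$profile_kind,
    homogeneous = 1,
    two_level = pp$high_volume_fraction +
      (1 - pp$high_volume_fraction) * pp$low_fraction,
    radial_linear = 0.25,  # 3 * integral_0^1 (1-u) u^2 du
    necrotic_core = {
      p <- pp$core_radius_fraction^3
      p * pp$core_level_fraction + (1 - p)
    },
    uniform_histogram = 0.5
  )
  # SUVpeak of the continuous profile: for centre-peaked radial profiles the
  # sphere average is maximised at the lesion centre; no closed form is
  # attempted for the rim-peaked necrotic profile.
  peak <- switch(spec$profile_kind,
    homogeneous = if (a <= R) S else NA_real_,
    two_level = {
      core_r <- pp$high_volume_fraction^(1 / 3) * R
      if (a <= core_r) S else NA_real_
    },
    radial_linear = if (a <= R) S * (1 - 0.75 * a / R) else NA_real_,
    necrotic_core = NA_real_,
    uniform_histogram = if (a <= R) S * (1 - a^3 / (2 * R^3)) else NA_real_
  )
  mtv_ml <- 4 / 3 * pi * R^3 / 1000
  list(suv_max = S, suv_mean = S * mean_frac, suv_peak = peak,
       mtv_ml = mtv_ml, tlg = mtv_ml * S * mean_frac,
       auc_csh = mean_frac)
}

# SUV of the noise-free profile at relative radius u = r/R in [0,1]
phantom_profile_value <- function(spec, u) {
  S <- spec$suv_max_true
  pp <- spec$profile_params
  switch(spec$profile_kind,
    homogeneous = rep(S, length(u)),
    two_level = ifelse(u <= pp$high_volume_fraction^(1 / 3),
                       S, S * pp$low_fraction),
    radial_linear = S * (1 - u),
    necrotic_core = ifelse(u <= pp$core_radius_fraction,
                           S * pp$core_level_fraction, S),
    uniform_histogram = S * (1 - u^3)
  )
}

#' Generate a digital PET phantom with analytically known heterogeneity
#'
#' Voxel membership is by voxel centre: a voxel belongs to the lesion when
#' its centre lies within `tumour_radius` of the lesion centre (no partial
#' volume). Lesion voxels get the noise-free profile value plus optional
#' Gaussian noise clipped at 0; all other voxels get `background_suv`
#' exactly. The returned `truth` holds the closed-form SUVmax/SUVmean/
#' SUVpeak/MTV/TLG and exact AUC-CSH of the continuous noise-free profile,
#' against which the voxel-level pipeline converges as spacing shrinks.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `pet_phantom` with elements `volume`
#'   ([suv_volume()]), `mask` ([tumour_mask()], label `total_lesion`),
#'   `truth` (closed-form profile values, see above) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_shape
  sp <- spec$voxel_spacing
  cx <- spec$tumour_centre * sp
  dx2 <- ((0:(g[1] - 1)) * sp[1] - cx[1])^2
  dy2 <- ((0:(g[2] - 1)) * sp[2] - cx[2])^2
  dz2 <- ((0:(g[3] - 1)) * sp[3] - cx[3])^2
  r <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
  inside <- r <= spec$tumour_radius
  vals <- array(spec$background_suv, dim = g)
  u <- pmin(r[inside] / spec$tumour_radius, 1)
  profile <- phantom_profile_value(spec, u)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    profile <- pmax(profile + stats::rnorm(length(profile), 0, spec$noise_sd), 0)
  }
  vals[inside] <- profile
  structure(list(
    volume = suv_volume(vals, spacing = sp),
    mask = tumour_mask(inside, spacing = sp, label = "total_lesion"),
    truth = phantom_analytic(spec),
    spec = spec
  ), class = "pet_phantom")
}

#' Write a phantom as paired NIfTI files plus a JSON truth sidecar
#'
#' @param phantom a `pet_phantom` from [generate_phantom()].
#' @param prefix path prefix; writes `<prefix>_suv.nii.gz`,
#'   `<prefix>_mask.nii.gz`, `<prefix>_truth.json`.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "pet_phantom"))
  paths <- c(volume = paste0(prefix, "_suv.nii.gz"),
             mask = paste0(prefix, "_mask.nii.gz"),
             truth = paste0(prefix, "_truth.json"))
  write_volume(phantom$volume, paths[["volume"]])
  write_volume(phantom$mask, paths[["mask"]])
  spec <- phantom$spec
  spec$profile_params <- as.list(spec$profile_params)
  jsonlite::write_json(list(spec = unclass(spec), truth = phantom$truth),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
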