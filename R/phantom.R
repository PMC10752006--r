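#' Published group means and standard deviations of optic-nerve metrics
#'
#' Group-level summaries (mean and SD per sham/TBI group and timepoint)
#' of the longitudinal in vivo study (days 1, 3, 7, 30; n = 5 mice = 10
#' eyes per group) and the day-3 ex vivo study (n = 6 mice per group)
#' that parameterize the synthetic phantoms and the worked percent-change
#' examples. Fractions are reported as printed, i.e. before the
#' renormalization applied by [tissue_preset()]; diffusivities in
#' um^2/ms, volumes in mm^3.
#'
#' @return data.frame with columns `mode` (invivo/exvivo), `day`,
#'   `group` (sham/TBI), `metric`, `mean`, `sd`.
#' @examples
#' gm <- study_group_means()
#' subset(gm, metric == "restricted_fraction" & day == 30)
#' @export
study_group_means <- function() {
  rec <- function(mode, day, group, vals) {
    data.frame(mode = mode, day = day, group = group,
               metric = vals$metric, mean = vals$mean, sd = vals$sd,
               row.names = NULL)
  }
  m <- function(...) {
    x <- matrix(c(...), ncol = 3, byrow = TRUE)
    list(metric = c("nonrestricted_fraction", "restricted_fraction",
                    "axon_volume", "dbsi_lambda_par", "dbsi_lambda_perp",
                    "dti_lambda_par", "dti_lambda_perp", "dti_fa", "dti_md",
                    "fiber_fraction", "nerve_volume")[x[, 1]],
         mean = x[, 2], sd = x[, 3])
  }
  tab <- rbind(
    rec("invivo", 1, "sham", m(1, 0.03, 0.043, 2, 0.03, 0.014, 3, 0.11, 0.009,
                               4, 1.89, 0.128, 5, 0.15, 0.038, 6, 1.72, 0.124,
                               7, 0.17, 0.046, 8, 0.88, 0.040, 9, 0.23, 0.012,
                               10, 0.81, 0.060, 11, 0.13, 0.011)),
    rec("invivo", 1, "TBI", m(1, 0.03, 0.029, 2, 0.12, 0.050, 3, 0.10, 0.009,
                              4, 1.47, 0.178, 5, 0.18, 0.029, 6, 1.19, 0.229,
                              7, 0.20, 0.025, 8, 0.81, 0.042, 9, 0.18, 0.027,
                              10, 0.76, 0.038, 11, 0.14, 0.011)),
    rec("invivo", 3, "sham", m(1, 0.05, 0.043, 2, 0.03, 0.018, 3, 0.10, 0.006,
                               4, 1.89, 0.092, 5, 0.17, 0.056, 6, 1.75, 0.058,
                               7, 0.20, 0.051, 8, 0.86, 0.039, 9, 0.24, 0.008,
                               10, 0.77, 0.031, 11, 0.13, 0.006)),
    rec("invivo", 3, "TBI", m(1, 0.05, 0.025, 2, 0.11, 0.046, 3, 0.11, 0.009,
                              4, 1.59, 0.163, 5, 0.22, 0.041, 6, 1.21, 0.220,
                              7, 0.26, 0.039, 8, 0.75, 0.059, 9, 0.19, 0.024,
                              10, 0.76, 0.024, 11, 0.15, 0.011)),
    rec("invivo", 7, "sham", m(1, 0.06, 0.035, 2, 0.04, 0.036, 3, 0.11, 0.009,
                               4, 1.84, 0.088, 5, 0.15, 0.039, 6, 1.68, 0.066,
                               7, 0.19, 0.040, 8, 0.87, 0.032, 9, 0.23, 0.009,
                               10, 0.76, 0.044, 11, 0.15, 0.011)),
    rec("invivo", 7, "TBI", m(1, 0.07, 0.054, 2, 0.12, 0.056, 3, 0.09, 0.014,
                              4, 1.55, 0.161, 5, 0.21, 0.044, 6, 1.20, 0.199,
                              7, 0.28, 0.046, 8, 0.71, 0.089, 9, 0.20, 0.019,
                              10, 0.72, 0.065, 11, 0.12, 0.017)),
    rec("invivo", 30, "sham", m(1, 0.06, 0.054, 2, 0.05, 0.014, 3, 0.11, 0.007,
                                4, 1.84, 0.210, 5, 0.14, 0.024, 6, 1.62, 0.183,
                                7, 0.20, 0.058, 8, 0.85, 0.062, 9, 0.22, 0.015,
                                10, 0.81, 0.082, 11, 0.14, 0.018)),
    rec("invivo", 30, "TBI", m(1, 0.10, 0.048, 2, 0.18, 0.069, 3, 0.08, 0.022,
                               4, 1.61, 0.211, 5, 0.23, 0.053, 6, 1.07, 0.184,
                               7, 0.34, 0.060, 8, 0.61, 0.117, 9, 0.19, 0.013,
                               10, 0.61, 0.107, 11, 0.12, 0.016)),
    rec("exvivo", 3, "sham", m(1, 0.06, 0.026, 2, 0.10, 0.042, 3, 0.07, 0.009,
                               4, 0.74, 0.090, 5, 0.06, 0.026, 6, 0.61, 0.090,
                               7, 0.08, 0.071, 8, 0.85, 0.071, 9, 0.09, 0.015,
                               10, 0.68, 0.050, 11, 0.10, 0.012)),
    rec("exvivo", 3, "TBI", m(1, 0.07, 0.058, 2, 0.19, 0.055, 3, 0.06, 0.015,
                              4, 0.53, 0.070, 5, 0.09, 0.017, 6, 0.42, 0.075,
                              7, 0.12, 0.036, 8, 0.68, 0.102, 9, 0.07, 0.013,
                              10, 0.62, 0.096, 11, 0.09, 0.018))
  )
  tab
}

#' Tissue composition preset for phantom generation
#'
#' A preset fixes the generative voxel composition of one group at one
#' timepoint. Printed fraction triplets (fiber, restricted,
#' non-restricted) do not sum exactly to 1 in the source summaries, so
#' they are renormalized here (the scaling factor is recorded). Ground
#' truth places the isotropic mass on two delta components at
#' `restricted_D` and `nonrestricted_D`.
#'
#' @param label preset name, e.g. `"invivo-sham-day30"`.
#' @param fiber_fraction,restricted_fraction,nonrestricted_fraction
#'   signal fractions (renormalized to sum to 1).
#' @param lambda_par,lambda_perp fiber diffusivities (um^2/ms).
#' @param restricted_D,nonrestricted_D isotropic delta-component
#'   diffusivities (um^2/ms); defaults 0.3 and 1.8.
#' @param nerve_volume whole-nerve volume (mm^3).
#' @param between_animal_cv coefficient of variation of animal-level
#'   parameter draws.
#' @return an object of class `tissue_preset`.
#' @export
tissue_preset <- function(label, fiber_fraction, restricted_fraction,
                          nonrestricted_fraction, lambda_par, lambda_perp,
                          restricted_D = 0.3, nonrestricted_D = 1.8,
                          nerve_volume = 0.14, between_animal_cv = 0.05) {
  total <- fiber_fraction + restricted_fraction + nonrestricted_fraction
  if (total <= 0) stop("fractions must have positive sum")
  if (lambda_par < 0 || lambda_perp < 0 || restricted_D < 0 ||
      nonrestricted_D < 0) stop("diffusivities must be non-negative")
  structure(list(label = label,
                 fiber_fraction = fiber_fraction / total,
                 restricted_fraction = restricted_fraction / total,
                 nonrestricted_fraction = nonrestricted_fraction / total,
                 renormalization = 1 / total,
                 lambda_par = lambda_par, lambda_perp = lambda_perp,
                 restricted_D = restricted_D,
                 nonrestricted_D = nonrestricted_D,
                 nerve_volume = nerve_volume,
                 between_animal_cv = between_animal_cv),
            class = "tissue_preset")
}

#' Preset for one study group and timepoint
#'
#' Builds a [tissue_preset()] from the published group means: fractions
#' renormalized to sum to 1, fiber diffusivities and nerve volume taken
#' directly, and the between-animal coefficient of variation derived
#' from the fiber-fraction SD with half of the printed variance
#' attributed to the animal level (`cv = (sd/mean)/sqrt(2)`); the other
#' half is left to measurement noise.
#'
#' @param mode `"invivo"` or `"exvivo"`.
#' @param day timepoint (1, 3, 7 or 30 in vivo; 3 ex vivo).
#' @param group `"sham"` or `"TBI"`.
#' @return a [tissue_preset()].
#' @examples
#' study_preset("invivo", 30, "sham")$fiber_fraction  # ~0.88
#' @export
study_preset <- function(mode = c("invivo", "exvivo"), day = 30,
                         group = c("sham", "TBI")) {
  mode <- match.arg(mode)
  group <- match.arg(group)
  gm <- study_group_means()
  gm <- gm[gm$mode == mode & gm$day == day & gm$group == group, ]
  if (nrow(gm) == 0L) stop("no group summary for ", mode, " day ", day)
  get <- function(metric) gm[gm$metric == metric, c("mean", "sd")]
  ff <- get("fiber_fraction")
  tissue_preset(label = paste0(mode, "-", group, "-day", day),
                fiber_fraction = ff$mean,
                restricted_fraction = get("restricted_fraction")$mean,
                nonrestricted_fraction = get("nonrestricted_fraction")$mean,
                lambda_par = get("dbsi_lambda_par")$mean,
                lambda_perp = get("dbsi_lambda_perp")$mean,
                nerve_volume = get("nerve_volume")$mean,
                between_animal_cv = (ff$sd / ff$mean) / sqrt(2))
}

# noise-free voxel model implied by a preset (two isotropic deltas)
.preset_model <- function(preset, orientation = c(0, 0, 1), s0 = 1) {
  D <- sort(c(preset$restricted_D, preset$nonrestricted_D))
  w <- c(preset$restricted_fraction,
         preset$nonrestricted_fraction)[order(c(preset$restricted_D,
                                                preset$nonrestricted_D))]
  voxel_model(
    fiber_component(preset$fiber_fraction, preset$lambda_par,
                    preset$lambda_perp, orientation),
    iso_spectrum(D, w), s0 = s0)
}

# Rician corruption of a noise-free magnitude signal
.rician <- function(signal, sigma) {
  n <- length(signal)
  sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

#' Simulate one voxel signal with Rician noise
#'
#' Evaluates the noise-free forward model for a preset (fiber along +z
#' unless overridden) and corrupts each measurement with Rician noise of
#' scale `s0 / snr`: the noisy magnitude is
#' `sqrt((S_k + e1)^2 + e2^2)` with independent Gaussian `e1`, `e2`.
#' `snr = Inf` returns the noise-free signal exactly. Deterministic
#' given `seed`.
#'
#' @param preset a [tissue_preset()].
#' @param scheme a [gradient_scheme()].
#' @param snr signal-to-noise ratio at b = 0 (`Inf` disables noise).
#' @param seed integer seed.
#' @param orientation fiber orientation (unit 3-vector).
#' @param s0 non-diffusion-weighted signal level.
#' @return numeric vector of K signals.
#' @export
simulate_voxel <- function(preset, scheme, snr = 30, seed = 1L,
                           orientation = c(0, 0, 1), s0 = 1) {
  if (!(snr > 0)) stop("snr must be positive")
  clean <- forward_signal(.preset_model(preset, orientation, s0), scheme)
  if (!is.finite(snr)) return(clean)
  with_seed(seed, .rician(clean, s0 / snr))
}

#' Specification of a synthetic sham/TBI cohort
#'
#' @param mode `"invivo"` (default days 1, 3, 7, 30) or `"exvivo"`
#'   (default day 3).
#' @param days timepoints to simulate.
#' @param n_per_group animals per group (each contributes both eyes).
#' @param snr b = 0 signal-to-noise ratio (`Inf` disables noise).
#' @param seed integer master seed; all cohort randomness flows from it.
#' @param voxel_dims voxel size in mm; the default reconstructed
#'   (zero-filled) grid is 0.0586 x 0.0586 mm in plane with a 1 mm
#'   slice. Larger voxels give proportionally smaller ROIs (useful for
#'   small worked examples).
#' @param scheme optional [gradient_scheme()]; defaults to
#'   `make_scheme(mode)`.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(mode = c("invivo", "exvivo"), days = NULL,
                        n_per_group = NULL, snr = 30, seed = 1L,
                        voxel_dims = c(0.0586, 0.0586, 1),
                        scheme = NULL) {
  mode <- match.arg(mode)
  if (is.null(days)) days <- if (mode == "invivo") c(1, 3, 7, 30) else 3
  if (is.null(n_per_group)) n_per_group <- if (mode == "invivo") 5L else 6L
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  if (!(snr > 0)) stop("snr must be positive")
  if (is.null(scheme)) scheme <- make_scheme(mode)
  structure(list(mode = mode, days = days, n_per_group = as.integer(n_per_group),
                 eyes = 2L, snr = snr, seed = as.integer(seed),
                 voxel_dims = voxel_dims, scheme = scheme),
            class = "cohort_spec")
}

# nerve cross-section: n voxels nearest the in-plane grid center
.nerve_roi <- function(n_vox) {
  side <- max(3L, ceiling(sqrt(n_vox)) + 2L)
  cx <- (side + 1) / 2
  ij <- expand.grid(i = seq_len(side), j = seq_len(side))
  d2 <- (ij$i - cx)^2 + (ij$j - cx)^2
  ord <- order(d2, ij$i, ij$j)          # deterministic tie-break
  sel <- ij[ord[seq_len(n_vox)], ]
  list(side = side, voxels = as.matrix(sel))
}

#' Simulate a synthetic sham/TBI optic-nerve cohort
#'
#' For each animal, eye and timepoint: draws animal-level tissue
#' parameters around the group preset (shared across that animal's eyes
#' and days to emulate within-mouse correlation), builds a single-slice
#' nerve cross-section whose voxel count matches the drawn nerve volume
#' at the spec's voxel size, simulates every voxel signal through the
#' forward model with Rician noise, and records the generative ground
#' truth. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements
#'   * `nerves`: list of per-nerve records (`animal`, `group`, `eye`,
#'     `day`, `dwi` 4-D array, `mask_metric`, `mask_whole`,
#'     `voxel_volume`),
#'   * `truth`: tidy data.frame (animal, group, eye, day, metric, value)
#'     of generator parameters including nerve and axon volume,
#'   * `scheme`, `voxel_volume`, `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  voxel_volume <- prod(spec$voxel_dims)
  scheme <- spec$scheme
  presets <- list()
  for (day in spec$days)
    for (grp in c("sham", "TBI"))
      presets[[paste(grp, day)]] <- study_preset(spec$mode, day, grp)
  min_vol <- min(vapply(presets, function(p) p$nerve_volume, 0))
  if (min_vol < voxel_volume)
    stop("nerve volume ", min_vol, " mm^3 is smaller than one voxel (",
         voxel_volume, " mm^3); override cohort voxel_dims")

  nerves <- list()
  truth <- list()
  with_seed(spec$seed, {
    for (grp in c("sham", "TBI")) {
      for (a in seq_len(spec$n_per_group)) {
        animal_id <- paste0(grp, "-", a)
        # one standardized draw per animal, reused at every timepoint so
        # the longitudinal records of an animal are correlated
        zs <- rnorm(16)
        for (day in spec$days) {
          preset <- presets[[paste(grp, day)]]
          pars <- local({
            k <- 0
            perturb <- function(x, cv, lo = 1e-3) {
              k <<- k + 1
              max(x * (1 + cv * zs[k]), lo)
            }
            cv <- preset$between_animal_cv
            ff <- perturb(preset$fiber_fraction, cv)
            rf <- perturb(preset$restricted_fraction, cv)
            nf <- perturb(preset$nonrestricted_fraction, cv)
            tot <- ff + rf + nf
            lpar <- perturb(preset$lambda_par, cv)
            lperp <- min(perturb(preset$lambda_perp, cv), lpar)
            nv <- perturb(preset$nerve_volume, cv, preset$nerve_volume / 10)
            list(fiber_fraction = ff / tot, restricted_fraction = rf / tot,
                 nonrestricted_fraction = nf / tot, lambda_par = lpar,
                 lambda_perp = lperp, nerve_volume = nv)
          })
          for (eye in c("L", "R")) {
            n_vox <- max(1L, round(pars$nerve_volume / voxel_volume))
            roi <- .nerve_roi(n_vox)
            side <- roi$side
            dwi <- array(0, c(side, side, 1L, scheme$K))
            mask_whole <- array(0L, c(side, side, 1L))
            animal_preset <- tissue_preset(
              label = paste0(preset$label, "-", animal_id, "-", eye),
              fiber_fraction = pars$fiber_fraction,
              restricted_fraction = pars$restricted_fraction,
              nonrestricted_fraction = pars$nonrestricted_fraction,
              lambda_par = pars$lambda_par, lambda_perp = pars$lambda_perp,
              restricted_D = preset$restricted_D,
              nonrestricted_D = preset$nonrestricted_D,
              nerve_volume = pars$nerve_volume)
            clean <- forward_signal(.preset_model(animal_preset), scheme)
            sigma <- if (is.finite(spec$snr)) 1 / spec$snr else 0
            for (v in seq_len(n_vox)) {
              i <- roi$voxels[v, 1]; j <- roi$voxels[v, 2]
              dwi[i, j, 1, ] <- if (sigma > 0) .rician(clean, sigma) else clean
              mask_whole[i, j, 1] <- 1L
            }
            n_metric <- max(1L, round(n_vox / 3))
            mask_metric <- array(0L, c(side, side, 1L))
            for (v in seq_len(n_metric))
              mask_metric[roi$voxels[v, 1], roi$voxels[v, 2], 1] <- 1L
            nerves[[length(nerves) + 1L]] <- list(
              animal = animal_id, group = grp, eye = eye, day = day,
              dwi = dwi, mask_metric = mask_metric, mask_whole = mask_whole,
              voxel_volume = voxel_volume)
            vals <- c(fiber_fraction = pars$fiber_fraction,
                      restricted_fraction = pars$restricted_fraction,
                      nonrestricted_fraction = pars$nonrestricted_fraction,
                      dbsi_lambda_par = pars$lambda_par,
                      dbsi_lambda_perp = pars$lambda_perp,
                      nerve_volume = n_vox * voxel_volume,
                      axon_volume = n_vox * voxel_volume * pars$fiber_fraction)
            truth[[length(truth) + 1L]] <- data.frame(
              animal = animal_id, group = grp, eye = eye, day = day,
              metric = names(vals), value = unname(vals), row.names = NULL)
          }
        }
      }
    }
  })
  list(nerves = nerves, truth = do.call(rbind, truth), scheme = scheme,
       voxel_volume = voxel_volume, spec = spec)
}
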