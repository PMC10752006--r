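#' Anisotropic fiber component
#'
#' The single axially-symmetric tensor term of the voxel model: a
#' signal-intensity fraction, axial and radial diffusivities
#' (um^2/ms) and a unit orientation vector. For a coherent tract the
#' radial diffusivity may not exceed the axial one.
#'
#' @param fraction signal-intensity fraction in \[0, 1\].
#' @param lambda_par axial diffusivity (um^2/ms), non-negative.
#' @param lambda_perp radial diffusivity (um^2/ms), `<= lambda_par`.
#' @param orientation unit 3-vector (norm within 1e-6 of 1).
#' @return an object of class `fiber_component`.
#' @export
fiber_component <- function(fraction, lambda_par, lambda_perp,
                            orientation = c(0, 0, 1)) {
  orientation <- as.numeric(orientation)
  if (length(orientation) != 3L || abs(sqrt(sum(orientation^2)) - 1) > 1e-6)
    stop("orientation must be a unit 3-vector")
  if (fraction < 0 || fraction > 1) stop("fiber fraction must lie in [0, 1]")
  if (lambda_par < 0 || lambda_perp < 0) stop("diffusivities must be non-negative")
  if (lambda_perp > lambda_par + 1e-12)
    stop("lambda_perp (", lambda_perp, ") exceeds lambda_par (", lambda_par, ")")
  structure(list(fraction = fraction, lambda_par = lambda_par,
                 lambda_perp = lambda_perp, orientation = orientation),
            class = "fiber_component")
}

#' Discretized isotropic diffusivity spectrum
#'
#' Non-negative weights on a strictly increasing grid of isotropic
#' diffusivities within limits \[a, b\] (um^2/ms). Weights are
#' signal-intensity fractions when the spectrum is part of a normalized
#' voxel model.
#'
#' @param diffusivities strictly increasing numeric grid (um^2/ms).
#' @param weights non-negative numeric weights, same length.
#' @param limits length-2 numeric `(a, b)`, `0 <= a < b`; defaults to
#'   `c(0, max(diffusivities, 3))`.
#' @return an object of class `iso_spectrum`.
#' @export
iso_spectrum <- function(diffusivities, weights,
                         limits = c(0, max(diffusivities, 3))) {
  diffusivities <- as.numeric(diffusivities)
  weights <- as.numeric(weights)
  if (length(diffusivities) != length(weights))
    stop("length mismatch: ", length(diffusivities), " diffusivities vs ",
         length(weights), " weights")
  if (any(diff(diffusivities) <= 0))
    stop("diffusivity grid must be strictly increasing")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  limits <- as.numeric(limits)
  if (length(limits) != 2L || limits[1] < 0 || limits[1] >= limits[2])
    stop("limits must satisfy 0 <= a < b")
  if (any(diffusivities < limits[1] - 1e-12) ||
      any(diffusivities > limits[2] + 1e-12))
    stop("all grid diffusivities must lie within limits [a, b]")
  structure(list(diffusivities = diffusivities, weights = weights,
                 limits = limits),
            class = "iso_spectrum")
}

#' Full voxel signal model
#'
#' Combines a fiber component, an isotropic spectrum and the
#' non-diffusion-weighted signal `s0`. The fiber fraction and spectrum
#' weights are signal-intensity fractions and must sum to 1.
#'
#' @param fiber a [fiber_component()].
#' @param spectrum an [iso_spectrum()].
#' @param s0 positive non-diffusion-weighted signal (arbitrary units).
#' @return an object of class `voxel_model`.
#' @export
voxel_model <- function(fiber, spectrum, s0 = 1) {
  stopifnot(inherits(fiber, "fiber_component"), inherits(spectrum, "iso_spectrum"))
  if (s0 <= 0) stop("s0 must be positive")
  total <- fiber$fraction + sum(spectrum$weights)
  if (abs(total - 1) > 1e-6)
    stop("fractions must sum to 1 (got ", format(total), ")")
  structure(list(fiber = fiber, spectrum = spectrum, s0 = s0),
            class = "voxel_model")
}

#' Restricted / non-restricted partition configuration
#'
#' ADC cut-offs (um^2/ms) splitting the isotropic spectrum: weights at
#' `ADC <= restricted_max` (inclusive, default 0.6) count as restricted
#' (putative cellularity); weights at
#' `restricted_max < ADC <= nonrestricted_max` count as non-restricted
#' (putative vasogenic edema / CSF). The non-restricted ceiling is
#' 3 um^2/ms for in vivo data and 2 um^2/ms for fixed ex vivo tissue.
#'
#' @param mode `"invivo"` or `"exvivo"`; sets the default ceiling.
#' @param restricted_max restricted cut-off (um^2/ms), default 0.6.
#' @param nonrestricted_max non-restricted ceiling; defaults by mode.
#' @return an object of class `partition_config`.
#' @export
partition_config <- function(mode = c("invivo", "exvivo"),
                             restricted_max = 0.6,
                             nonrestricted_max = NULL) {
  mode <- match.arg(mode)
  if (is.null(nonrestricted_max))
    nonrestricted_max <- if (mode == "invivo") 3 else 2
  if (!(restricted_max > 0) || !(restricted_max < nonrestricted_max))
    stop("need 0 < restricted_max < nonrestricted_max")
  structure(list(mode = mode, restricted_max = restricted_max,
                 nonrestricted_max = nonrestricted_max),
            class = "partition_config")
}

#' Evaluate the forward signal model
#'
#' Noise-free diffusion-weighted signal for each measurement k:
#' \deqn{S_k = S_0 [ f e^{-b_k \lambda_\perp}
#'   e^{-b_k (\lambda_\parallel - \lambda_\perp)\cos^2\Phi_k}
#'   + \sum_i w_i e^{-b_k D_i} ]}
#' where \eqn{\Phi_k} is the angle between the k-th gradient direction
#' and the fiber orientation. b-values are converted from s/mm^2 to
#' ms/um^2 internally so the exponents are dimensionless.
#'
#' @param model a [voxel_model()].
#' @param scheme a [gradient_scheme()].
#' @return numeric vector of K non-negative signals.
#' @examples
#' sch <- make_scheme("invivo")
#' m <- voxel_model(fiber_component(1, 1.89, 0.15), iso_spectrum(0.3, 0))
#' forward_signal(m, sch)[sch$b0]  # equals s0 at b = 0
#' @export
forward_signal <- function(model, scheme) {
  stopifnot(inherits(model, "voxel_model"), inherits(scheme, "dbsi_scheme"))
  b <- scheme$bvalues * 1e-3            # ms/um^2
  fib <- model$fiber
  cos_phi <- as.numeric(scheme$directions %*% fib$orientation)
  aniso <- fib$fraction *
    exp(-b * fib$lambda_perp) *
    exp(-b * (fib$lambda_par - fib$lambda_perp) * cos_phi^2)
  iso <- as.numeric(exp(-outer(b, model$spectrum$diffusivities)) %*%
                      model$spectrum$weights)
  model$s0 * (aniso + iso)
}

#' Partition an isotropic spectrum into restricted and non-restricted mass
#'
#' Sums spectrum weights below/above the restricted ADC cut-off. The
#' restricted boundary is inclusive (`D <= restricted_max`). Weights
#' above the non-restricted ceiling are excluded from both fractions and
#' returned separately.
#'
#' @param spectrum an [iso_spectrum()].
#' @param cfg a [partition_config()].
#' @return list with `restricted`, `nonrestricted` and `excluded`
#'   weight sums; the three always add up to the total spectrum weight.
#' @examples
#' sp <- iso_spectrum(c(0.2, 1.5), c(0.3, 0.7), limits = c(0, 3))
#' partition_spectrum(sp, partition_config("invivo"))
#' @export
partition_spectrum <- function(spectrum, cfg = partition_config("invivo")) {
  stopifnot(inherits(spectrum, "iso_spectrum"), inherits(cfg, "partition_config"))
  D <- spectrum$diffusivities
  w <- spectrum$weights
  restricted <- sum(w[D <= cfg$restricted_max])
  nonrestricted <- sum(w[D > cfg$restricted_max & D <= cfg$nonrestricted_max])
  excluded <- sum(w) - restricted - nonrestricted
  if (excluded > 1e-9)
    message("partition_spectrum: excluded weight ", format(excluded),
            " above ADC ", cfg$nonrestricted_max, " um^2/ms")
  list(restricted = restricted, nonrestricted = nonrestricted,
       excluded = excluded)
}
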