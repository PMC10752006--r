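#' Conventional single-tensor (DTI) fit
#'
#' Weighted log-linear least-squares estimate of the 3 x 3 symmetric
#' diffusion tensor and s0: a first ordinary LS pass on `log(S)` is
#' followed by one reweighted pass with weights equal to the squared
#' predicted signal (the standard variance-stabilizing weighting for
#' log-transformed Rician/Gaussian magnitude data). Scalar metrics use
#' the eigenvalues in descending order:
#' axial diffusivity = largest eigenvalue, radial = mean of the two
#' smaller ones, MD = trace/3 and
#' \deqn{FA = \sqrt{3/2 \cdot \sum_i(\lambda_i - MD)^2 / \sum_i \lambda_i^2}.}
#' Negative eigenvalues are not clipped; non-physical fits are flagged
#' via `valid = FALSE` so downstream ROI summaries can drop them.
#'
#' @param signal numeric vector of K signals (same order as `scheme`).
#' @param scheme a [gradient_scheme()] with at least 6 non-collinear
#'   weighted directions plus a b = 0 reference.
#' @return an object of class `dti_result`: `lambda_par`, `lambda_perp`,
#'   `fa`, `md` (um^2/ms), `eigenvalues`, `principal_direction`,
#'   `s0`, `tensor`, `valid`.
#' @examples
#' sch <- make_scheme("invivo")
#' m <- voxel_model(fiber_component(1, 1.89, 0.15), iso_spectrum(0.3, 0))
#' fit <- fit_dti(forward_signal(m, sch), sch)
#' c(fit$fa, fit$md)
#' @export
fit_dti <- function(signal, scheme) {
  stopifnot(inherits(scheme, "dbsi_scheme"))
  signal <- as.numeric(signal)
  if (length(signal) != scheme$K)
    stop("signal length ", length(signal), " does not match scheme length ",
         scheme$K)
  if (any(!is.finite(signal))) stop("signal contains non-finite values")
  valid <- all(signal > 0)
  floor_val <- 1e-6 * max(signal, 1e-300)
  s <- pmax(signal, floor_val)

  b <- scheme$bvalues * 1e-3
  g <- scheme$directions
  # design for log S = log s0 - b g' T g, tensor in (xx, yy, zz, xy, xz, yz)
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  if (qr(X)$rank < 7L)
    stop("rank-deficient DTI design: scheme with ", sum(!scheme$b0),
         " weighted directions does not span 6 independent tensor components")
  y <- log(s)
  beta <- qr.coef(qr(X), y)
  w <- exp(X %*% beta)^2            # squared predicted signal
  Xw <- X * sqrt(as.numeric(w))
  beta <- qr.coef(qr(Xw), y * sqrt(as.numeric(w)))

  tensor <- matrix(c(beta[2], beta[5], beta[6],
                     beta[5], beta[3], beta[7],
                     beta[6], beta[7], beta[4]), 3, 3)
  e <- eigen(tensor, symmetric = TRUE)   # eigenvalues in descending order
  lam <- e$values
  md <- mean(lam)
  denom <- sum(lam^2)
  fa <- if (denom > 0) sqrt(1.5 * sum((lam - md)^2) / denom) else 0
  v1 <- e$vectors[, 1]
  v1 <- v1 / sqrt(sum(v1^2))
  structure(list(lambda_par = lam[1],
                 lambda_perp = mean(lam[2:3]),
                 fa = fa, md = md,
                 eigenvalues = lam,
                 principal_direction = v1,
                 s0 = exp(beta[1]),
                 tensor = tensor,
                 valid = valid && all(lam > 0)),
            class = "dti_result")
}

#' @export
print.dti_result <- function(x, ...) {
  cat(sprintf("<dti_result> AD %.3f RD %.3f FA %.3f MD %.3f%s\n",
              x$lambda_par, x$lambda_perp, x$fa, x$md,
              if (x$valid) "" else " [flagged invalid]"))
  invisible(x)
}
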