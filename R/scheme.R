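#' Diffusion gradient scheme
#'
#' A gradient scheme pairs one diffusion-encoding direction with one
#' b-value per measurement. b-values are stored in s/mm^2 as printed on
#' scanner consoles; diffusivities elsewhere in the package are in
#' um^2/ms, so exponents use `b * 1e-3` internally. Entries with
#' b < 10 s/mm^2 are treated as non-diffusion-weighted (b = 0)
#' references, which tolerates real-world bval files.
#'
#' @param directions numeric K x 3 matrix of encoding directions; rows
#'   with b > 0 must be unit vectors (norm within 1e-6 of 1).
#' @param bvalues numeric vector of K non-negative b-values (s/mm^2).
#' @return an object of class `dbsi_scheme` with elements `directions`,
#'   `bvalues`, `b0` (logical reference-measurement flag) and `K`.
#' @examples
#' sch <- gradient_scheme(rbind(c(0, 0, 0), diag(3), -diag(3)),
#'                        c(0, rep(1000, 6)))
#' sch$K
#' @export
gradient_scheme <- function(directions, bvalues) {
  directions <- as.matrix(directions)
  bvalues <- as.numeric(bvalues)
  if (ncol(directions) != 3L)
    stop("directions must be a K x 3 matrix, got ", ncol(directions), " columns")
  K <- nrow(directions)
  if (length(bvalues) != K)
    stop("length mismatch: ", K, " directions vs ", length(bvalues), " b-values")
  if (K < 7L)
    stop("a scheme needs at least 7 measurements (6 weighted + 1 reference), got ", K)
  if (any(!is.finite(bvalues)) || any(bvalues < 0))
    stop("b-values must be finite and non-negative")
  b0 <- bvalues < 10
  if (!any(b0))
    stop("scheme has no b = 0 reference measurement (all b >= 10 s/mm^2)")
  nrm <- sqrt(rowSums(directions^2))
  bad <- !b0 & abs(nrm - 1) > 1e-6
  if (any(bad))
    stop("non-unit gradient direction(s) at weighted measurement(s): ",
         paste(which(bad), collapse = ", "))
  structure(list(directions = directions, bvalues = bvalues, b0 = b0, K = K),
            class = "dbsi_scheme")
}

#' @export
print.dbsi_scheme <- function(x, ...) {
  cat("<dbsi_scheme> ", x$K, " measurements (", sum(x$b0), " at b = 0), max b = ",
      max(x$bvalues), " s/mm^2\n", sep = "")
  invisible(x)
}

# electrostatic-repulsion layout of n points on the unit sphere treating
# each point and its antipode as one charge; deterministic given seed
.repulsion_directions <- function(n, seed, iters = 300L, step0 = 0.05) {
  with_seed(seed, {
    x <- matrix(rnorm(3 * n), n, 3)
  })
  x <- .normalize_rows(x)
  for (it in seq_len(iters)) {
    f <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- sweep(x[-i, , drop = FALSE], 2, x[i, ], function(a, b) b - a)
      d2 <- sweep(-x[-i, , drop = FALSE], 2, x[i, ], function(a, b) b - a)
      r1 <- pmax(sqrt(rowSums(d1^2)), 1e-3)
      r2 <- pmax(sqrt(rowSums(d2^2)), 1e-3)
      f[i, ] <- colSums(d1 / r1^3) + colSums(d2 / r2^3)
    }
    # tangential component only; largest move capped at the (annealed)
    # step so near-collisions cannot fling points across the sphere
    tang <- f - x * rowSums(f * x)
    step <- step0 * (1 - (it - 1) / iters)
    mx <- max(sqrt(rowSums(tang^2)))
    x <- .normalize_rows(x + (step / mx) * tang)
  }
  # canonical hemisphere (z >= 0) so layouts are reproducible to the byte
  flip <- x[, 3] < 0 | (x[, 3] == 0 & (x[, 2] < 0 | (x[, 2] == 0 & x[, 1] < 0)))
  x[flip, ] <- -x[flip, , drop = FALSE]
  x
}

#' Build an acquisition scheme for the in vivo or ex vivo protocol
#'
#' The in vivo protocol uses 25 measurements (1 reference at b = 0 plus
#' 24 diffusion-weighted directions, maximum b = 2,200 s/mm^2); the ex
#' vivo protocol uses 99 measurements (1 + 98, maximum b = 3,000
#' s/mm^2). Weighted directions are laid out approximately uniformly on
#' the hemisphere by electrostatic repulsion, and b-values cycle through
#' four levels (25/50/75/100% of the maximum) across directions so that
#' the scheme carries the b-value diversity the spectrum inversion
#' needs. The layout is deterministic given `seed`.
#'
#' @param mode `"invivo"` or `"exvivo"`.
#' @param seed integer seed controlling the direction layout.
#' @return a [gradient_scheme()].
#' @examples
#' sch <- make_scheme("invivo")
#' table(sch$bvalues)
#' @export
make_scheme <- function(mode = c("invivo", "exvivo"), seed = 20231213L) {
  mode <- match.arg(mode)
  n_weighted <- if (mode == "invivo") 24L else 98L
  bmax <- if (mode == "invivo") 2200 else 3000
  dirs <- .repulsion_directions(n_weighted, seed)
  levels <- c(0.25, 0.5, 0.75, 1) * bmax
  bvals <- levels[(seq_len(n_weighted) - 1L) %% 4L + 1L]
  gradient_scheme(rbind(c(0, 0, 0), dirs), c(0, bvals))
}
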