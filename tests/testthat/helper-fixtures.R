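# shared fixtures: tiny schemes, random rotations, quick model builders

# minimal 7-measurement scheme (1 reference + 6 weighted axes)
tiny_scheme <- function(b = 1000) {
  gradient_scheme(rbind(c(0, 0, 0), diag(3), -diag(3)), c(0, rep(b, 6)))
}

# seeded random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rotate_scheme <- function(scheme, R) {
  gradient_scheme(scheme$directions %*% t(R), scheme$bvalues)
}

# single-fiber voxel (no isotropic mass)
pure_fiber_model <- function(lpar = 1.89, lperp = 0.15,
                             orientation = c(0, 0, 1), s0 = 1) {
  voxel_model(fiber_component(1, lpar, lperp, orientation),
              iso_spectrum(0.3, 0), s0 = s0)
}

# two-delta mixture voxel
mixture_model <- function(f, r, nr, lpar, lperp, rD = 0.3, nrD = 1.8,
                          orientation = c(0, 0, 1), s0 = 1) {
  voxel_model(fiber_component(f, lpar, lperp, orientation),
              iso_spectrum(c(rD, nrD), c(r, nr)), s0 = s0)
}

# default in vivo scheme shared across tests (deterministic)
ivs <- make_scheme("invivo")
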