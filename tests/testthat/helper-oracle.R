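# Independent brute-force route to MAS sideband intensities: explicit
# rotation matrices at every time slice, trapezoidal phase integration,
# and a direct (non-FFT) discrete Fourier transform. Shares nothing with
# the package's analytic-harmonics + FFT implementation beyond the powder
# grid it is handed.
oracle_sidebands <- function(params, ctx, grid, max_order, nt = 2048L) {
  thm <- acos(1 / sqrt(3))
  dx <- (params$dxx - params$iso) * ctx$carrier_mhz
  dy <- (params$dyy - params$iso) * ctx$carrier_mhz
  dz <- (params$dzz - params$iso) * ctx$carrier_mhz
  D <- diag(c(dx, dy, dz))
  phi <- 2 * pi * (0:(nt - 1)) / nt
  u <- rbind(sin(thm) * cos(phi), -sin(thm) * sin(phi),
             rep(cos(thm), nt))
  orders <- -max_order:max_order
  E <- exp(-1i * outer(phi, orders))
  acc <- numeric(length(orders))
  for (o in seq_len(grid$n)) {
    b <- grid$beta[o]; gm <- grid$gamma[o]
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)),
                 3, 3, byrow = TRUE)
    Rz <- matrix(c(cos(gm), -sin(gm), 0, sin(gm), cos(gm), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    M <- Ry %*% Rz
    A <- M %*% D %*% t(M)
    nu <- colSums(u * (A %*% u))
    dpsi <- 2 * pi * nu / (ctx$mas_hz * nt)
    psi <- c(0, cumsum((dpsi[-1] + dpsi[-nt]) / 2))
    x <- exp(1i * psi)
    A_N <- colMeans(x * E)
    acc <- acc + grid$weights[o] * Re(A_N * Conj(A_N))
  }
  acc / sum(acc)
}

# Random CSA tensor with span and skew drawn uniformly; returns
# csa_parameters.
random_tensor <- function(span_range = c(20, 250), iso_range = c(0, 200)) {
  span <- stats::runif(1, span_range[1], span_range[2])
  skew <- stats::runif(1, -1, 1)
  iso <- stats::runif(1, iso_range[1], iso_range[2])
  derive_csa_parameters(components_from_csa(iso, span, skew))
}
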