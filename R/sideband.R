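#' MAS acquisition context
#'
#' Bundles the two frequencies every ppm/Hz conversion depends on: the
#' spectrometer carrier (13C Larmor) frequency and the magic-angle-spinning
#' rate. Keeping them in one object prevents silently mixing the carrier
#' used for acquisition (125.721 MHz here) with the one quoted for the
#' relaxation analysis (125.758 MHz); see [physical_constants()].
#'
#' @param carrier_mhz 13C carrier frequency in MHz (> 0).
#' @param mas_hz MAS rotor frequency in Hz (> 0). Slow-MAS sideband work on
#'   this instrument used 600 and 2000 Hz.
#' @return object of class `acquisition_context`.
#' @export
acquisition_context <- function(carrier_mhz = 125.721, mas_hz = 2000) {
  stopifnot(is.numeric(carrier_mhz), is.numeric(mas_hz))
  if (!is.finite(carrier_mhz) || carrier_mhz <= 0) {
    stop("carrier_mhz must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(mas_hz) || mas_hz <= 0) {
    stop("mas_hz must be a positive finite number", call. = FALSE)
  }
  structure(list(carrier_mhz = carrier_mhz, mas_hz = mas_hz),
            class = "acquisition_context")
}

#' Convert between ppm and Hz
#'
#' `ppm_to_hz()` multiplies by the carrier frequency in MHz (so 1 ppm at
#' 125.721 MHz is 125.721 Hz); `hz_to_ppm()` is its exact inverse.
#'
#' @param x numeric vector to convert.
#' @param ctx an [acquisition_context()].
#' @return converted numeric vector.
#' @export
ppm_to_hz <- function(x, ctx) {
  stopifnot(inherits(ctx, "acquisition_context"))
  x * ctx$carrier_mhz
}

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(x, ctx) {
  stopifnot(inherits(ctx, "acquisition_context"))
  x / ctx$carrier_mhz
}

#' Deterministic powder-orientation grid
#'
#' Unit-sphere sampling used for powder averaging. The default scheme is a
#' spherical Fibonacci (golden-spiral) lattice: deterministic, equal-weight,
#' and low-discrepancy, so repeated runs are bit-identical without any
#' seed. A seeded uniform random scheme is provided for cross-checks.
#'
#' Each point is stored as the polar pair (beta, gamma): beta is the angle
#' between the tensor z axis and the rotor axis, gamma the azimuth of the
#' rotor axis in the tensor frame. The third Euler angle (rotor phase) is
#' averaged analytically by the sideband simulator.
#'
#' @param n number of orientations (default 4181).
#' @param scheme "fibonacci" (default) or "random".
#' @param seed integer seed, used only by `scheme = "random"`.
#' @return object of class `orientation_grid` with fields `beta`, `gamma`,
#'   `weights` (summing to 1), `scheme`, `n`.
#' @export
orientation_grid <- function(n = 4181, scheme = c("fibonacci", "random"),
                             seed = 1L) {
  scheme <- match.arg(scheme)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (scheme == "fibonacci") {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n                      # uniform in cos(beta)
    phi <- 2 * pi * i * (sqrt(5) - 1) / 2   # golden-angle azimuth
    beta <- acos(z)
    gamma <- phi %% (2 * pi)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    z <- stats::runif(n, -1, 1)
    gamma <- stats::runif(n, 0, 2 * pi)
    beta <- acos(z)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  structure(
    list(beta = beta, gamma = gamma, weights = rep(1 / n, n),
         scheme = scheme, n = n),
    class = "orientation_grid"
  )
}

# Harmonic coefficients of the time-dependent MAS CSA frequency.
#
# For a crystallite whose rotor-axis direction in the tensor principal
# axis system is (beta, gamma), the instantaneous anisotropic frequency is
#   nu(t) = C1 cos(wr t) + S1 sin(wr t) + C2 cos(2 wr t) + S2 sin(2 wr t)
# (the constant term vanishes exactly at the magic angle). The
# coefficients follow from rotating the traceless PAS tensor
# diag(dx, dy, dz) into the rotor frame and projecting on the lab z axis
# tilted at the magic angle:
#   C1 = (2 sqrt 2 / 3) A13,  S1 = -(2 sqrt 2 / 3) A23,
#   C2 = (A11 - A22) / 3,     S2 = -(2 / 3) A12.
# All inputs/outputs in Hz. Vectorized over orientations.
mas_harmonics <- function(dx, dy, dz, beta, gamma) {
  cb <- cos(beta); sb <- sin(beta)
  cg <- cos(gamma); sg <- sin(gamma)
  A13 <- sb * cb * (dz - cg^2 * dx - sg^2 * dy)
  A23 <- sb * sg * cg * (dy - dx)
  A11 <- cb^2 * cg^2 * dx + cb^2 * sg^2 * dy + sb^2 * dz
  A22 <- sg^2 * dx + cg^2 * dy
  A12 <- cb * sg * cg * (dx - dy)
  list(
    C1 = 2 * sqrt(2) / 3 * A13,
    S1 = -2 * sqrt(2) / 3 * A23,
    C2 = (A11 - A22) / 3,
    S2 = -2 / 3 * A12
  )
}

#' Simulate a MAS spinning-sideband intensity pattern
#'
#' Computes the powder-averaged intensities of the spinning sidebands that
#' a CSA tensor produces under magic-angle spinning slower than the static
#' linewidth. For each crystallite orientation the anisotropic frequency
#' over one rotor period is a two-harmonic trigonometric polynomial whose
#' phase integral is known in closed form; the sideband amplitudes are its
#' Fourier coefficients \eqn{A_N} over the rotor period, and averaging the
#' rotor phase gives the N-th sideband intensity as the powder average of
#' \eqn{|A_N|^2}. Total intensity is conserved exactly (Parseval), so the
#' pattern sums to 1 by construction.
#'
#' @param params a `csa_parameters` object (see [derive_csa_parameters()]),
#'   a `principal_components` object, or a numeric vector of 3 components
#'   in ppm.
#' @param ctx an [acquisition_context()]; `mas_hz` sets the sideband
#'   spacing.
#' @param grid an [orientation_grid()] for the powder average.
#' @param max_order highest sideband order returned. Default
#'   `ceil(span_Hz / mas_hz) + 4`; an error is raised if the requested
#'   order window would truncate more than `1e-4` of the total intensity.
#' @param n_time time slices per rotor period for the Fourier transform
#'   (default 256, a power of two comfortably above twice the default
#'   `max_order`).
#' @return object of class `sideband_pattern`: list with integer `orders`
#'   (`-max_order:max_order`, 0 = centerband), `intensities` (nonnegative,
#'   summing to 1), `iso` (ppm), and `context`.
#' @examples
#' ctx <- acquisition_context(mas_hz = 2000)
#' p <- derive_csa_parameters(c(325.5, 165.8, 143.1), site = "C21")
#' sb <- simulate_sidebands(p, ctx)
#' sum(sb$intensities)
#' @export
simulate_sidebands <- function(params, ctx = acquisition_context(),
                               grid = orientation_grid(),
                               max_order = NULL, n_time = 256L) {
  stopifnot(inherits(ctx, "acquisition_context"),
            inherits(grid, "orientation_grid"))
  if (!inherits(params, "csa_parameters")) {
    params <- derive_csa_parameters(params)
  }
  n_time <- as.integer(n_time)
  if (n_time < 8L) stop("n_time must be >= 8", call. = FALSE)

  span_hz <- ppm_to_hz(params$span, ctx)
  if (is.null(max_order)) {
    max_order <- ceiling(span_hz / ctx$mas_hz) + 4L
  }
  max_order <- as.integer(max_order)
  if (max_order < 0L) stop("max_order must be >= 0", call. = FALSE)
  if (2L * max_order >= n_time) {
    stop("n_time must exceed twice max_order to resolve all sidebands",
         call. = FALSE)
  }

  orders <- seq.int(-max_order, max_order)
  if (params$span == 0) {
    intensities <- as.numeric(orders == 0L)
  } else {
    # traceless PAS components in Hz, Haeberlen labels (x, y, z)
    dx <- ppm_to_hz(params$dxx - params$iso, ctx)
    dy <- ppm_to_hz(params$dyy - params$iso, ctx)
    dz <- ppm_to_hz(params$dzz - params$iso, ctx)
    h <- mas_harmonics(dx, dy, dz, grid$beta, grid$gamma)
    phi <- 2 * pi * (seq_len(n_time) - 1) / n_time
    # closed-form phase integral of 2*pi*nu(t), in units of the rotor phase
    psi <- (outer(sin(phi), h$C1) + outer(1 - cos(phi), h$S1) +
              outer(sin(2 * phi) / 2, h$C2) +
              outer((1 - cos(2 * phi)) / 2, h$S2)) / ctx$mas_hz
    amp <- stats::mvfft(exp(1i * psi)) / n_time   # A_N per orientation
    inten_all <- Re(amp * Conj(amp)) %*% grid$weights  # powder average
    # fft index k (1-based) holds order N = k - 1 (mod n_time)
    idx <- ifelse(orders >= 0L, orders + 1L, n_time + orders + 1L)
    intensities <- as.numeric(inten_all[idx])
    leakage <- 1 - sum(intensities)
    if (leakage > 1e-4) {
      stop(sprintf(
        "max_order = %d truncates %.2e of the total sideband intensity; increase max_order",
        max_order, leakage), call. = FALSE)
    }
    intensities <- pmax(intensities, 0)
    intensities <- intensities / sum(intensities)
  }
  structure(
    list(orders = orders, intensities = intensities,
         iso = params$iso, context = ctx),
    class = "sideband_pattern"
  )
}

#' @export
print.sideband_pattern <- function(x, ...) {
  nz <- x$intensities > 1e-3
  cat(sprintf(
    "MAS sideband pattern: %d orders >0.1%% intensity, MAS %.0f Hz, iso %.1f ppm\n",
    sum(nz), x$context$mas_hz, x$iso))
  invisible(x)
}

#' Fit span and skew from measured sideband intensities
#'
#' Solves the inverse Herzfeld-Berger problem by nonlinear least squares:
#' finds the (span, skew) whose simulated sideband pattern best reproduces
#' the observed intensities. A coarse grid over span (bracketing the
#' observable comb width) and skew in \eqn{[-1, 1]} seeds a Nelder-Mead
#' refinement; the final parameters are re-simulated on a finer powder
#' grid. Because near-axial patterns constrain skew weakly and patterns
#' close to mirror-symmetric fit +skew and -skew almost equally, the fit
#' reports an `ambiguous` flag and the mirrored alternative whenever the
#' reflected solution's residual is within 10% of the best.
#'
#' @param obs a `sideband_pattern` (orders + normalized intensities); at
#'   least 3 orders must carry intensity above `min_intensity` or the
#'   problem is underdetermined and an error is raised.
#' @param ctx acquisition context; defaults to the one stored in `obs`.
#' @param min_intensity threshold defining an "informative" sideband
#'   (default 1e-3 of total).
#' @param grid_coarse small powder grid for the bracketing grid search.
#' @param grid_fit powder grid used during optimization (default 987
#'   orientations, enough for intensity accuracy well below typical noise).
#' @param grid_final powder grid for the refined final evaluation.
#' @param n_time time slices per rotor period (as in
#'   [simulate_sidebands()]).
#' @return list with `parameters` (a `csa_parameters` built from the
#'   fitted iso/span/skew), `span`, `skew`, `iso`, `residual` (sum of
#'   squared intensity differences), `ambiguous` (logical),
#'   `skew_poorly_constrained` (logical, centerband-dominated patterns),
#'   and `alternative` (mirrored solution or NULL).
#' @export
fit_tensor_from_sidebands <- function(obs, ctx = obs$context,
                                      min_intensity = 1e-3,
                                      grid_coarse = orientation_grid(233),
                                      grid_fit = orientation_grid(987),
                                      grid_final = orientation_grid(),
                                      n_time = 256L) {
  stopifnot(inherits(obs, "sideband_pattern"),
            inherits(ctx, "acquisition_context"))
  inten <- obs$intensities / sum(obs$intensities)
  orders <- obs$orders
  informative <- sum(inten > min_intensity)
  if (informative < 3L) {
    stop(paste0("underdetermined: only ", informative,
                " sideband order(s) carry intensity above the threshold; ",
                "need at least 3 to constrain span and skew"), call. = FALSE)
  }
  iso <- obs$iso
  max_ord <- max(abs(orders))

  loss <- function(span, skew, grid) {
    if (span <= 0 || abs(skew) > 1) return(Inf)
    sim <- try(simulate_sidebands(
      components_from_csa(iso, span, skew),
      ctx = ctx, grid = grid,
      max_order = max(max_ord,
                      ceiling(ppm_to_hz(span, ctx) / ctx$mas_hz) + 4L),
      n_time = max(n_time,
                   2L * (ceiling(ppm_to_hz(span, ctx) / ctx$mas_hz) + 8L))
    ), silent = TRUE)
    if (inherits(sim, "try-error")) return(Inf)
    sim_i <- sim$intensities[match(orders, sim$orders)]
    sim_i[is.na(sim_i)] <- 0
    sum((sim_i - inten)^2)
  }

  # coarse bracket: the observed comb width bounds the static span
  width_hz <- (max(abs(orders[inten > min_intensity])) + 1) * ctx$mas_hz
  width_ppm <- hz_to_ppm(width_hz, ctx)
  span_grid <- seq(0.35 * width_ppm, 1.4 * width_ppm, length.out = 10)
  skew_grid <- seq(-0.9, 0.9, by = 0.3)
  coarse <- expand.grid(span = span_grid, skew = skew_grid)
  coarse$loss <- mapply(function(s, k) loss(s, k, grid_coarse),
                        coarse$span, coarse$skew)
  best <- coarse[which.min(coarse$loss), ]

  refine <- stats::optim(
    par = c(best$span, best$skew),
    fn = function(p) loss(p[1], min(1, max(-1, p[2])), grid_fit),
    method = "Nelder-Mead",
    control = list(reltol = 1e-9, maxit = 200)
  )
  span_hat <- refine$par[1]
  skew_hat <- min(1, max(-1, refine$par[2]))
  resid <- loss(span_hat, skew_hat, grid_final)

  # mirrored-skew ambiguity check
  mirror <- stats::optim(
    par = c(span_hat, -skew_hat),
    fn = function(p) loss(p[1], min(1, max(-1, p[2])), grid_fit),
    method = "Nelder-Mead",
    control = list(reltol = 1e-9, maxit = 100)
  )
  resid_mirror <- loss(mirror$par[1], min(1, max(-1, mirror$par[2])),
                       grid_final)
  distinct <- abs(mirror$par[2] - skew_hat) > 0.05
  ambiguous <- distinct && resid_mirror <= max(resid, 1e-12) * 1.1

  centerband <- inten[match(0L, orders)]
  skew_flag <- isTRUE(centerband > 0.98)

  params <- derive_csa_parameters(
    components_from_csa(iso, span_hat, skew_hat), site = NA_character_)
  list(
    parameters = params,
    span = span_hat, skew = skew_hat, iso = iso,
    residual = resid,
    ambiguous = ambiguous,
    skew_poorly_constrained = skew_flag,
    alternative = if (ambiguous) {
      list(span = mirror$par[1],
           skew = min(1, max(-1, mirror$par[2])),
           residual = resid_mirror)
    } else NULL
  )
}

#' Read or write a sideband intensity table
#'
#' Delimited-text interchange for sideband patterns: two columns,
#' `order` (integer, 0 = centerband) and `intensity`.
#'
#' @param path file path.
#' @param iso centerband position in ppm attached to the pattern on read.
#' @param ctx acquisition context attached on read.
#' @param normalize renormalize intensities to sum 1 on read (default TRUE).
#' @return `read_sideband_table()` returns a `sideband_pattern`.
#' @export
read_sideband_table <- function(path, iso = 0,
                                ctx = acquisition_context(),
                                normalize = TRUE) {
  df <- utils::read.csv(path)
  if (!all(c("order", "intensity") %in% names(df))) {
    stop("sideband table must have columns `order` and `intensity`",
         call. = FALSE)
  }
  inten <- df$intensity
  if (any(inten < 0)) stop("negative sideband intensity", call. = FALSE)
  if (normalize) inten <- inten / sum(inten)
  structure(
    list(orders = as.integer(df$order), intensities = inten,
         iso = iso, context = ctx),
    class = "sideband_pattern"
  )
}

#' @rdname read_sideband_table
#' @param pattern a `sideband_pattern` to write.
#' @export
write_sideband_table <- function(pattern, path) {
  stopifnot(inherits(pattern, "sideband_pattern"))
  utils::write.csv(
    data.frame(order = pattern$orders, intensity = pattern$intensities),
    path, row.names = FALSE)
  invisible(path)
}
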