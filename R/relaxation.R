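# Model prefactors, isolated so an alternative reading of the relaxation
# equations is a one-line change. The Lorentzian spectral density used
# throughout is J(omega) = tau / (1 + omega^2 tau^2).
CSA_PREFACTOR <- 2 / 15
DD_PREFACTOR <- 1 / 10
MU0_OVER_4PI <- 1e-7  # T^2 m^3 / J

#' Physical constants for the relaxation model
#'
#' Field, gyromagnetic ratios and hbar used by the CSA and dipolar
#' relaxation rates. Gyromagnetic ratios are accepted in MHz/T (the
#' spectroscopist's linear-frequency convention) and converted internally
#' to rad s^-1 T^-1 (x 2 pi x 1e6). The 13C angular Larmor frequency
#' `omega_c` defaults to 2 pi times the carrier frequency quoted for the
#' relaxation analysis (125.758 MHz); note this differs slightly from the
#' acquisition carrier (125.721 MHz) and from gamma_c * B0 (125.717 MHz) -
#' the package carries each as stated and never silently reconciles them.
#'
#' @param B0 static field, tesla.
#' @param gamma_c_mhz 13C gyromagnetic ratio, MHz/T.
#' @param gamma_h_mhz 1H gyromagnetic ratio, MHz/T.
#' @param hbar reduced Planck constant, J s.
#' @param carrier_mhz 13C Larmor (linear) frequency used to form
#'   `omega_c`, MHz.
#' @return object of class `physical_constants` with the inputs plus
#'   `gamma_c`, `gamma_h` (rad s^-1 T^-1) and `omega_c` (rad/s).
#' @export
physical_constants <- function(B0 = 11.74, gamma_c_mhz = 10.7084,
                               gamma_h_mhz = 42.577, hbar = 1.054e-34,
                               carrier_mhz = 125.758) {
  vals <- c(B0, gamma_c_mhz, gamma_h_mhz, hbar, carrier_mhz)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all physical constants must be positive and finite", call. = FALSE)
  }
  structure(
    list(
      B0 = B0,
      gamma_c_mhz = gamma_c_mhz, gamma_h_mhz = gamma_h_mhz,
      gamma_c = 2 * pi * 1e6 * gamma_c_mhz,
      gamma_h = 2 * pi * 1e6 * gamma_h_mhz,
      hbar = hbar,
      carrier_mhz = carrier_mhz,
      omega_c = 2 * pi * 1e6 * carrier_mhz
    ),
    class = "physical_constants"
  )
}

#' Heteronuclear dipolar partner
#'
#' One C-X dipolar coupling partner for the relaxation model. Distances
#' are crystallographic and user-supplied; when none is available for a
#' directly bonded proton the nominal C-H bond length 1.09 Angstrom is the
#' conventional stand-in (set `nominal = TRUE` to record that).
#'
#' @param partner nucleus identity, e.g. "H", "F".
#' @param r_angstrom internuclear distance in Angstrom (> 0).
#' @param gamma_mhz partner gyromagnetic ratio in MHz/T; defaults by
#'   `partner`: H 42.577, F 40.078, C 10.7084.
#' @param nominal logical flag marking a nominal (non-crystallographic)
#'   distance.
#' @return object of class `dipolar_pair`.
#' @export
dipolar_pair <- function(partner = "H", r_angstrom = 1.09,
                         gamma_mhz = NULL, nominal = FALSE) {
  if (!is.finite(r_angstrom) || r_angstrom <= 0) {
    stop("r_angstrom must be > 0", call. = FALSE)
  }
  if (is.null(gamma_mhz)) {
    gamma_mhz <- switch(partner,
      H = 42.577, F = 40.078, C = 10.7084,
      stop(sprintf("no default gyromagnetic ratio for partner '%s'; supply gamma_mhz",
                   partner), call. = FALSE))
  }
  structure(
    list(partner = partner, r = r_angstrom * 1e-10,
         gamma = 2 * pi * 1e6 * gamma_mhz, nominal = nominal),
    class = "dipolar_pair"
  )
}

#' Combined CSA + heteronuclear dipolar relaxation model
#'
#' Assembles everything the spin-lattice relaxation rate of a 13C site
#' depends on: the CSA interaction strength
#' \eqn{S^2 = (\Delta\delta)^2 (1 + \eta^2/3)} (ppm^2), a list of
#' heteronuclear dipolar partners, the physical constants, and the
#' spectral-density mode for the dipolar term ("full" keeps the three
#' terms at \eqn{\omega_X-\omega_C, \omega_C, \omega_X+\omega_C};
#' "first_term_only" keeps only the difference-frequency term).
#'
#' @param anisotropy reduced anisotropy \eqn{\Delta\delta} in ppm
#'   (ignored if `s2_ppm2` given).
#' @param asymmetry asymmetry \eqn{\eta} (ignored if `s2_ppm2` given).
#' @param s2_ppm2 optionally, \eqn{S^2} directly in ppm^2.
#' @param pairs list of [dipolar_pair()] objects (possibly empty).
#' @param constants a [physical_constants()] object.
#' @param spectral_density "full" or "first_term_only".
#' @return object of class `relaxation_model`.
#' @export
relaxation_model <- function(anisotropy = 0, asymmetry = 0,
                             s2_ppm2 = NULL, pairs = list(),
                             constants = physical_constants(),
                             spectral_density = c("full", "first_term_only")) {
  spectral_density <- match.arg(spectral_density)
  stopifnot(inherits(constants, "physical_constants"))
  if (is.null(s2_ppm2)) {
    s2_ppm2 <- anisotropy^2 * (1 + asymmetry^2 / 3)
  }
  if (!is.finite(s2_ppm2) || s2_ppm2 < 0) {
    stop("S^2 must be finite and >= 0", call. = FALSE)
  }
  if (inherits(pairs, "dipolar_pair")) pairs <- list(pairs)
  if (!all(vapply(pairs, inherits, logical(1), "dipolar_pair"))) {
    stop("`pairs` must be a list of dipolar_pair objects", call. = FALSE)
  }
  structure(
    list(s2_ppm2 = s2_ppm2, pairs = pairs, constants = constants,
         spectral_density = spectral_density),
    class = "relaxation_model"
  )
}

lorentzian_j <- function(omega, tau) tau / (1 + (omega * tau)^2)

#' CSA contribution to the 13C spin-lattice relaxation rate
#'
#' \deqn{R_1^{CSA} = \frac{2}{15}\, \omega_C^2\, S^2\,
#'   \frac{\tau_2}{1 + \omega_C^2 \tau_2^2}}
#' with \eqn{S^2 = (\Delta\delta)^2(1+\eta^2/3)} converted from ppm^2 to a
#' dimensionless shielding variance (x 1e-12), and \eqn{\tau_2} the
#' rank-2 rotational correlation time; the molecular correlation time is
#' \eqn{\tau_c = 3\tau_2}.
#'
#' @param tau2 rank-2 correlation time in s (> 0, vectorized).
#' @param model a [relaxation_model()].
#' @return relaxation rate in 1/s.
#' @export
r1_csa <- function(tau2, model) {
  stopifnot(inherits(model, "relaxation_model"))
  if (any(!is.finite(tau2)) || any(tau2 <= 0)) {
    stop("tau2 must be positive and finite", call. = FALSE)
  }
  w <- model$constants$omega_c
  CSA_PREFACTOR * w^2 * model$s2_ppm2 * 1e-12 * lorentzian_j(w, tau2)
}

#' Heteronuclear dipolar contribution to the relaxation rate
#'
#' Standard heteronuclear dipole-dipole spin-lattice rate, summed over
#' partners X:
#' \deqn{R_1^{DD} = \sum_X \frac{d_X^2}{10}\,[J(\omega_X-\omega_C) +
#'   3J(\omega_C) + 6J(\omega_X+\omega_C)]}
#' with \eqn{d_X = (\mu_0/4\pi)\,\hbar\,\gamma_C\gamma_X / r_{CX}^3} and
#' \eqn{J(\omega) = \tau_c/(1+\omega^2\tau_c^2)}. In mode
#' `first_term_only` only the \eqn{J(\omega_X-\omega_C)} term is kept.
#'
#' @param tau_c molecular correlation time in s (> 0, vectorized).
#' @param model a [relaxation_model()]; an empty pair list gives 0.
#' @return relaxation rate in 1/s.
#' @export
r1_dipolar <- function(tau_c, model) {
  stopifnot(inherits(model, "relaxation_model"))
  if (any(!is.finite(tau_c)) || any(tau_c <= 0)) {
    stop("tau_c must be positive and finite", call. = FALSE)
  }
  if (length(model$pairs) == 0) return(rep(0, length(tau_c)))
  k <- model$constants
  wc <- k$gamma_c * k$B0
  total <- rep(0, length(tau_c))
  for (p in model$pairs) {
    wx <- p$gamma * k$B0
    d <- MU0_OVER_4PI * k$hbar * k$gamma_c * p$gamma / p$r^3
    jsum <- lorentzian_j(wx - wc, tau_c)
    if (model$spectral_density == "full") {
      jsum <- jsum + 3 * lorentzian_j(wc, tau_c) +
        6 * lorentzian_j(wx + wc, tau_c)
    }
    total <- total + DD_PREFACTOR * d^2 * jsum
  }
  total
}

#' Total spin-lattice relaxation rate as a function of tau_c
#'
#' \eqn{R_1(\tau_c) = R_1^{CSA}(\tau_c/3) + R_1^{DD}(\tau_c)}: the CSA
#' term is evaluated at the rank-2 correlation time \eqn{\tau_2 =
#' \tau_c/3}, the dipolar term at \eqn{\tau_c} itself.
#'
#' @inheritParams r1_dipolar
#' @return rate in 1/s.
#' @export
r1_total <- function(tau_c, model) {
  r1_csa(tau_c / 3, model) + r1_dipolar(tau_c, model)
}

#' Fit T1 from a Torchia-type magnetization decay curve
#'
#' Unweighted nonlinear least-squares fit of the mono-exponential decay
#' \eqn{M(t) = M_0 e^{-t/T_1}} (Levenberg-Marquardt), initialized from a
#' log-linear regression on the positive intensities. The fit is on raw
#' intensities rather than log-intensities because the log transform
#' biases the low-SNR tail.
#'
#' @param delays delay times in s (>= 0, strictly increasing, >= 4 points).
#' @param intensities measured magnetization, arbitrary units.
#' @return object of class `t1_estimate`: list with `t1` (s), `stderr`
#'   (s), `m0`, `rss`, `fitted`.
#' @examples
#' d <- c(1, 5, 10, 50, 100, 200, 400, 600)
#' fit_t1(d, exp(-d / 190))$t1
#' @export
fit_t1 <- function(delays, intensities) {
  if (length(delays) < 4L) stop("need at least 4 points", call. = FALSE)
  if (length(delays) != length(intensities)) {
    stop("delays and intensities must have equal length", call. = FALSE)
  }
  if (any(!is.finite(delays)) || any(!is.finite(intensities))) {
    stop("non-finite input", call. = FALSE)
  }
  if (any(diff(delays) <= 0)) {
    stop("delays must be strictly increasing", call. = FALSE)
  }
  # log-linear start values from the clearly positive points
  pos <- intensities > 0.05 * max(intensities)
  if (sum(pos) < 3L) stop("fit failure: intensities do not decay cleanly",
                          call. = FALSE)
  lf <- stats::lm(log(intensities[pos]) ~ delays[pos])
  slope <- stats::coef(lf)[2]
  if (!is.finite(slope) || slope >= 0) {
    stop("fit failure: data are not decaying (non-negative log-slope)",
         call. = FALSE)
  }
  start <- list(m0 = unname(exp(stats::coef(lf)[1])),
                t1 = unname(-1 / slope))
  df <- data.frame(t = delays, y = intensities)
  fit <- minpack.lm::nlsLM(
    y ~ m0 * exp(-t / t1), data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  est <- summary(fit)$coefficients
  t1 <- est["t1", "Estimate"]
  if (!is.finite(t1) || t1 <= 0) {
    stop("fit failure: best-fit T1 is not positive", call. = FALSE)
  }
  structure(
    list(
      t1 = t1,
      stderr = est["t1", "Std. Error"],
      m0 = est["m0", "Estimate"],
      rss = sum(stats::residuals(fit)^2),
      fitted = stats::fitted(fit)
    ),
    class = "t1_estimate"
  )
}

#' @export
print.t1_estimate <- function(x, ...) {
  cat(sprintf("T1 = %.4g +/- %.2g s (M0 = %.4g, rss = %.3g)\n",
              x$t1, x$stderr, x$m0, x$rss))
  invisible(x)
}

#' Invert the relaxation model for the molecular correlation time
#'
#' Solves \eqn{R_1(\tau_c) = 1/T_1} for \eqn{\tau_c}. The total rate is
#' single-peaked in \eqn{\tau_c}, so a measured rate below the model
#' maximum has two roots: a fast-motion root (\eqn{\tau_c} below the peak)
#' and a slow-motion root above it. The slow-motion root is reported as
#' `tau_c` (rigid crystalline solids live on that branch); the fast root
#' is returned alongside. If \eqn{1/T_1} exceeds the attainable maximum
#' the model is infeasible and an error reports the maximum rate.
#'
#' @param t1 measured spin-lattice relaxation time in s (> 0).
#' @param model a [relaxation_model()].
#' @param log10_range search window for log10(tau_c / s), default
#'   `c(-12, 0)`.
#' @return object of class `correlation_time_result`: list with `tau_c`
#'   (slow branch), `tau_c_fast`, `tau_peak` (rate-maximizing tau_c),
#'   `r1_target`, `r1_max`, `r1_csa_frac`, `r1_dd_frac` (contribution
#'   fractions at the slow root, summing to 1), `residual_rel`.
#' @export
invert_tau_c <- function(t1, model, log10_range = c(-12, 0)) {
  stopifnot(inherits(model, "relaxation_model"))
  if (!is.finite(t1) || t1 <= 0) stop("t1 must be > 0", call. = FALSE)
  target <- 1 / t1
  f <- function(lt) r1_total(10^lt, model) - target
  # locate the single interior rate maximum on the log axis
  pk <- stats::optimize(function(lt) r1_total(10^lt, model),
                        interval = log10_range, maximum = TRUE,
                        tol = 1e-10)
  r1_max <- pk$objective
  if (target > r1_max) {
    stop(sprintf(
      "infeasible T1: 1/T1 = %.4g /s exceeds the model's maximum achievable rate %.4g /s",
      target, r1_max), call. = FALSE)
  }
  root_on <- function(lo, hi) {
    stats::uniroot(f, lower = lo, upper = hi, tol = 1e-13)$root
  }
  slow <- 10^root_on(pk$maximum, log10_range[2])
  # in the fast-motion limit R1 is linear in tau_c, so the fast root can
  # sit below the nominal window; extend the bracket downward as needed
  lo <- log10_range[1]
  while (f(lo) > 0 && lo > -20) lo <- lo - 2
  fast <- if (f(lo) > 0) NA_real_ else 10^root_on(lo, pk$maximum)
  rc <- r1_csa(slow / 3, model)
  rd <- r1_dipolar(slow, model)
  structure(
    list(
      tau_c = slow,
      tau_c_fast = fast,
      tau_peak = 10^pk$maximum,
      r1_target = target,
      r1_max = r1_max,
      r1_csa_frac = rc / (rc + rd),
      r1_dd_frac = rd / (rc + rd),
      residual_rel = abs(r1_total(slow, model) - target) / target
    ),
    class = "correlation_time_result"
  )
}

#' @export
print.correlation_time_result <- function(x, ...) {
  cat(sprintf(
    "tau_c = %.3e s (slow branch; fast root %.3e s)\n  CSA fraction %.3f, dipolar fraction %.3f\n",
    x$tau_c, x$tau_c_fast, x$r1_csa_frac, x$r1_dd_frac))
  invisible(x)
}

#' Relative CSA and dipolar contributions to the relaxation rate
#'
#' @param result a `correlation_time_result` from [invert_tau_c()], or a
#'   `relaxation_model` together with `tau_c`.
#' @param tau_c correlation time at which to evaluate the split (required
#'   when `result` is a model).
#' @return named numeric vector `c(csa = ..., dipolar = ...)` summing to 1.
#' @export
contribution_report <- function(result, tau_c = NULL) {
  if (inherits(result, "correlation_time_result")) {
    return(c(csa = result$r1_csa_frac, dipolar = result$r1_dd_frac))
  }
  stopifnot(inherits(result, "relaxation_model"), !is.null(tau_c))
  rc <- r1_csa(tau_c / 3, result)
  rd <- r1_dipolar(tau_c, result)
  c(csa = rc / (rc + rd), dipolar = rd / (rc + rd))
}
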