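#' Order chemical shift tensor principal components by frequency
#'
#' Sorts three principal components of a chemical shift tensor into the
#' frequency-ordered (Herzfeld-Berger / IUPAC) convention
#' \eqn{\delta_{11} \ge \delta_{22} \ge \delta_{33}}.
#'
#' @param values numeric vector of length 3, principal components in ppm,
#'   in any order.
#' @param site optional site label carried through to the result.
#' @return an object of class `principal_components`: a named list with
#'   `d11`, `d22`, `d33` (ppm) and `site`.
#' @examples
#' order_components_frequency(c(143.1, 325.5, 165.8), site = "C21")
#' @export
order_components_frequency <- function(values, site = NA_character_) {
  if (!is.numeric(values) || length(values) != 3L) {
    stop("`values` must be a numeric vector of length 3", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("principal components must all be finite", call. = FALSE)
  }
  d <- sort(values, decreasing = TRUE)
  structure(
    list(site = site, d11 = d[1], d22 = d[2], d33 = d[3]),
    class = "principal_components"
  )
}

as_principal_components <- function(x, site = NA_character_) {
  if (inherits(x, "principal_components")) return(x)
  order_components_frequency(as.numeric(x), site = site)
}

#' @export
print.principal_components <- function(x, ...) {
  cat(sprintf(
    "Principal components%s: d11 = %.2f, d22 = %.2f, d33 = %.2f ppm\n",
    if (is.na(x$site)) "" else paste0(" [", x$site, "]"),
    x$d11, x$d22, x$d33
  ))
  invisible(x)
}

#' Relabel principal components in the Haeberlen convention
#'
#' Assigns \eqn{\delta_{zz}, \delta_{xx}, \delta_{yy}} so that
#' \eqn{|\delta_{zz}-\delta_{iso}| \ge |\delta_{xx}-\delta_{iso}| \ge
#' |\delta_{yy}-\delta_{iso}|}. This ordering gives the *signed* reduced
#' anisotropy: its sign tells on which side of the isotropic shift the
#' powder pattern extends farthest.
#'
#' An exact tie \eqn{|\delta_{11}-\delta_{iso}| = |\delta_{33}-\delta_{iso}|}
#' (isotropic shift coinciding with \eqn{\delta_{22}}) is broken toward
#' \eqn{\delta_{zz} = \delta_{33}}, i.e. the negative-anisotropy branch;
#' see the package vignette for the rationale.
#'
#' @param pc a `principal_components` object, or a numeric vector of length
#'   3 (any order).
#' @return a named list with `dzz`, `dxx`, `dyy` and `iso` (ppm).
#' @export
order_components_haeberlen <- function(pc) {
  pc <- as_principal_components(pc)
  iso <- (pc$d11 + pc$d22 + pc$d33) / 3
  # d22 is never the farthest component: |d22 - iso| <= max(|d11 - iso|, |d33 - iso|)
  if (abs(pc$d11 - iso) > abs(pc$d33 - iso)) {
    dzz <- pc$d11; rest <- c(pc$d22, pc$d33)
  } else {
    dzz <- pc$d33; rest <- c(pc$d11, pc$d22)
  }
  if (abs(rest[1] - iso) >= abs(rest[2] - iso)) {
    dxx <- rest[1]; dyy <- rest[2]
  } else {
    dxx <- rest[2]; dyy <- rest[1]
  }
  list(dzz = dzz, dxx = dxx, dyy = dyy, iso = iso)
}

#' Derive CSA parameters from principal components
#'
#' Computes every standard scalar descriptor of a chemical shift anisotropy
#' tensor from its three principal components:
#' \describe{
#'   \item{iso}{isotropic shift \eqn{(\delta_{11}+\delta_{22}+\delta_{33})/3}}
#'   \item{span}{\eqn{\Omega = \delta_{11}-\delta_{33} \ge 0}, static breadth}
#'   \item{skew}{\eqn{\kappa = 3(\delta_{22}-\delta_{iso})/\Omega \in [-1,1]}}
#'   \item{anisotropy}{reduced anisotropy
#'     \eqn{\Delta\delta = \delta_{zz}-(\delta_{xx}+\delta_{yy})/2} (signed,
#'     Haeberlen ordering)}
#'   \item{asymmetry}{\eqn{\eta = (\delta_{yy}-\delta_{xx})/(\delta_{zz}-\delta_{iso})
#'     \in [0,1]}; \eqn{\eta \le 0.3} means a nearly axially symmetric
#'     sideband pattern}
#' }
#' A fully degenerate (isotropic) tensor returns 0 for span, skew,
#' anisotropy and asymmetry so that pipelines stay total.
#'
#' @param pc a `principal_components` object or numeric vector of length 3
#'   (any order; ordering is internal).
#' @param site optional site label.
#' @return an object of class `csa_parameters`: named list with `site`,
#'   `d11`, `d22`, `d33`, `dzz`, `dxx`, `dyy`, `iso`, `span`, `skew`,
#'   `anisotropy`, `asymmetry`.
#' @examples
#' p <- derive_csa_parameters(c(309.1, 143.3, 61.9), site = "C5")
#' p$anisotropy # 206.5 ppm
#' @export
derive_csa_parameters <- function(pc, site = NA_character_) {
  pc <- as_principal_components(pc, site = site)
  if (!is.na(site)) pc$site <- site
  iso <- (pc$d11 + pc$d22 + pc$d33) / 3
  span <- pc$d11 - pc$d33
  if (span == 0) {
    hb <- list(dzz = iso, dxx = iso, dyy = iso)
    skew <- 0; anisotropy <- 0; asymmetry <- 0
  } else {
    hb <- order_components_haeberlen(pc)
    skew <- 3 * (pc$d22 - iso) / span
    anisotropy <- hb$dzz - (hb$dxx + hb$dyy) / 2
    asymmetry <- (hb$dyy - hb$dxx) / (hb$dzz - iso)
  }
  structure(
    list(
      site = pc$site,
      d11 = pc$d11, d22 = pc$d22, d33 = pc$d33,
      dzz = hb$dzz, dxx = hb$dxx, dyy = hb$dyy,
      iso = iso, span = span, skew = skew,
      anisotropy = anisotropy, asymmetry = asymmetry
    ),
    class = "csa_parameters"
  )
}

#' @export
print.csa_parameters <- function(x, ...) {
  cat(sprintf(
    paste0(
      "CSA parameters%s\n",
      "  components : %.2f / %.2f / %.2f ppm\n",
      "  iso %.2f  span %.2f  skew %.3f  anisotropy %.2f  asymmetry %.3f\n"
    ),
    if (is.na(x$site)) "" else paste0(" [", x$site, "]"),
    x$d11, x$d22, x$d33, x$iso, x$span, x$skew, x$anisotropy, x$asymmetry
  ))
  invisible(x)
}

#' Reconstruct principal components from (iso, span, skew)
#'
#' Inverse of the Herzfeld-Berger parameterization: given the isotropic
#' shift, span and skew, returns the frequency-ordered principal
#' components. Used to turn a sideband fit (which determines iso, span,
#' skew) back into a tensor.
#'
#' @param iso isotropic shift, ppm.
#' @param span span \eqn{\Omega \ge 0}, ppm.
#' @param skew skew \eqn{\kappa \in [-1, 1]}.
#' @param site optional site label.
#' @return a `principal_components` object.
#' @export
components_from_csa <- function(iso, span, skew, site = NA_character_) {
  stopifnot(is.finite(iso), is.finite(span), is.finite(skew))
  if (span < 0) stop("span must be >= 0", call. = FALSE)
  if (abs(skew) > 1 + 1e-12) stop("skew must lie in [-1, 1]", call. = FALSE)
  d22 <- iso + skew * span / 3
  d11 <- (3 * iso - d22 + span) / 2
  d33 <- d11 - span
  order_components_frequency(c(d11, d22, d33), site = site)
}

#' Magnetic anisotropy shift induced by a hydrogen bond
#'
#' Evaluates the point-susceptibility expression for the shift induced at a
#' nucleus by the anisotropic magnetic susceptibility of a nearby
#' hydrogen-bonded group,
#' \deqn{\delta_{anis} = \{\Delta\chi_{\parallel}(3\cos^2\theta_1 - 1) +
#'   \Delta\chi_{\perp}(3\cos^2\theta_2 - 1)\} / (3 R^3)}
#' where \eqn{\theta_1, \theta_2} are the angles subtended by the radius
#' vector with the x and z axes and R the distance to the perturbing group.
#'
#' @param dchi_par parallel susceptibility anisotropy (arbitrary units).
#' @param dchi_perp perpendicular susceptibility anisotropy.
#' @param theta1,theta2 angles in radians.
#' @param R distance (> 0), arbitrary length units.
#' @return the induced shift, units of `dchi / R^3`.
#' @examples
#' hbond_anisotropy(1, 0, theta1 = 0, theta2 = 0, R = 1) # 2/3
#' @export
hbond_anisotropy <- function(dchi_par, dchi_perp, theta1, theta2, R) {
  stopifnot(is.finite(dchi_par), is.finite(dchi_perp),
            is.finite(theta1), is.finite(theta2), is.finite(R))
  if (R <= 0) stop("R must be > 0", call. = FALSE)
  (dchi_par * (3 * cos(theta1)^2 - 1) +
     dchi_perp * (3 * cos(theta2)^2 - 1)) / (3 * R^3)
}

#' Compare computed CSA parameters to printed table values
#'
#' Field-by-field regression check of computed CSA parameters against a
#' published table row. Fields in ppm (`iso`, `span`, `anisotropy`) use
#' `tol_ppm`; dimensionless fields (`skew`, `asymmetry`) use `tol_dimless`.
#' The defaults accommodate one-decimal table rounding with mixed
#' round-half-up and truncation.
#'
#' @param computed a `csa_parameters` object (or list with the five fields).
#' @param printed named list/row with printed `iso`, `span`, `skew`,
#'   `anisotropy`, `asymmetry`.
#' @param tol_ppm absolute tolerance for ppm fields (default 0.15).
#' @param tol_dimless absolute tolerance for dimensionless fields
#'   (default 0.06).
#' @return data frame with columns `field`, `computed`, `printed`, `delta`,
#'   `tolerance`, `match`.
#' @export
compare_to_printed <- function(computed, printed,
                               tol_ppm = 0.15, tol_dimless = 0.06) {
  fields <- c("iso", "span", "skew", "anisotropy", "asymmetry")
  tol <- c(tol_ppm, tol_ppm, tol_dimless, tol_ppm, tol_dimless)
  comp <- vapply(fields, function(f) as.numeric(computed[[f]]), numeric(1))
  prnt <- vapply(fields, function(f) as.numeric(printed[[f]]), numeric(1))
  delta <- comp - prnt
  data.frame(
    field = fields,
    computed = comp,
    printed = prnt,
    delta = delta,
    tolerance = tol,
    match = abs(delta) <= tol,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
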