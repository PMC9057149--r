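#' Read a peak table
#'
#' Delimited text with columns `site,d11,d22,d33` (ppm). Malformed rows
#' raise a line-numbered error rather than propagating NAs.
#'
#' @param path file path.
#' @return data frame with columns `site`, `d11`, `d22`, `d33`.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "d11", "d22", "d33")
  if (!all(need %in% names(df))) {
    stop("peak table must have columns site,d11,d22,d33", call. = FALSE)
  }
  for (col in c("d11", "d22", "d33")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("peak table %s: non-numeric %s at data line %d",
                   path, col, bad[1]), call. = FALSE)
    }
    df[[col]] <- v
  }
  df[need]
}

#' Read a decay-curve table
#'
#' Delimited text with columns `site,delay_s,intensity`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_decay_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "delay_s", "intensity")
  if (!all(need %in% names(df))) {
    stop("decay table must have columns site,delay_s,intensity",
         call. = FALSE)
  }
  df[need]
}

#' Read a geometry (dipolar distance) table
#'
#' Delimited text with columns `site,partner,r_angstrom` listing the C-X
#' distances feeding the dipolar relaxation term.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_geometry_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "partner", "r_angstrom")
  if (!all(need %in% names(df))) {
    stop("geometry table must have columns site,partner,r_angstrom",
         call. = FALSE)
  }
  df[need]
}

#' Derive CSA parameters for every row of a peak table
#'
#' Applies [derive_csa_parameters()] site by site.
#'
#' @param peaks data frame with columns `site`, `d11`, `d22`, `d33`
#'   (components in any order within a row).
#' @return data frame with `site`, ordered components, `iso`, `span`,
#'   `skew`, `anisotropy`, `asymmetry`.
#' @examples
#' fx <- dexamethasone_sites()
#' head(derive_csa_table(fx))
#' @export
derive_csa_table <- function(peaks) {
  need <- c("site", "d11", "d22", "d33")
  if (!all(need %in% names(peaks))) {
    stop("peak table must have columns site,d11,d22,d33", call. = FALSE)
  }
  if (nrow(peaks) == 0L) {
    return(data.frame(site = character(), d11 = numeric(), d22 = numeric(),
                      d33 = numeric(), iso = numeric(), span = numeric(),
                      skew = numeric(), anisotropy = numeric(),
                      asymmetry = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    p <- derive_csa_parameters(
      c(peaks$d11[i], peaks$d22[i], peaks$d33[i]), site = peaks$site[i])
    data.frame(site = p$site, d11 = p$d11, d22 = p$d22, d33 = p$d33,
               iso = p$iso, span = p$span, skew = p$skew,
               anisotropy = p$anisotropy, asymmetry = p$asymmetry,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit T1 for every site of a decay table
#'
#' @param decays data frame with columns `site`, `delay_s`, `intensity`.
#' @return data frame with `site`, `t1_s`, `stderr_s`, `m0`, `rss`.
#' @export
fit_t1_table <- function(decays) {
  need <- c("site", "delay_s", "intensity")
  if (!all(need %in% names(decays))) {
    stop("decay table must have columns site,delay_s,intensity",
         call. = FALSE)
  }
  sites <- unique(decays$site)
  rows <- lapply(sites, function(s) {
    d <- decays[decays$site == s, ]
    d <- d[order(d$delay_s), ]
    f <- fit_t1(d$delay_s, d$intensity)
    data.frame(site = s, t1_s = f$t1, stderr_s = f$stderr, m0 = f$m0,
               rss = f$rss, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a site relaxation model from tensor parameters and geometry
#'
#' Convenience constructor for the per-site model used by
#' [invert_tau_c_table()]: \eqn{S^2} from the site's anisotropy and
#' asymmetry, dipolar partners from a geometry table if given, otherwise
#' nominal directly bonded protons by group type (methyl 3 H, methylene
#' 2 H, methine 1 H at 1.09 Angstrom; nonprotonated none).
#'
#' @param anisotropy,asymmetry tensor parameters (ppm, dimensionless).
#' @param group group type string, used only when `geometry` is NULL.
#' @param geometry optional data frame with `partner`, `r_angstrom` rows
#'   for this site.
#' @param constants a [physical_constants()].
#' @param spectral_density passed to [relaxation_model()].
#' @return a `relaxation_model`.
#' @export
site_relaxation_model <- function(anisotropy, asymmetry,
                                  group = "nonprotonated",
                                  geometry = NULL,
                                  constants = physical_constants(),
                                  spectral_density = "full") {
  pairs <- if (!is.null(geometry) && nrow(geometry) > 0) {
    lapply(seq_len(nrow(geometry)), function(i) {
      dipolar_pair(geometry$partner[i], geometry$r_angstrom[i])
    })
  } else {
    n_h <- switch(group,
                  methyl = 3L, methylene = 2L, methine = 1L,
                  nonprotonated = 0L,
                  stop(sprintf("unknown group type '%s'", group),
                       call. = FALSE))
    rep(list(dipolar_pair("H", 1.09, nominal = TRUE)), n_h)
  }
  relaxation_model(anisotropy = anisotropy, asymmetry = asymmetry,
                   pairs = pairs, constants = constants,
                   spectral_density = spectral_density)
}

#' Invert correlation times for a table of sites
#'
#' For each site, builds the combined CSA + dipolar model (see
#' [site_relaxation_model()]) and inverts the measured T1 for the
#' molecular correlation time on the slow-motion branch.
#'
#' @param t1_table data frame with `site`, `t1_s`.
#' @param tensors data frame with `site`, `anisotropy`, `asymmetry` (e.g.
#'   from [derive_csa_table()]) and optionally `group`.
#' @param geometry optional geometry table (`site`, `partner`,
#'   `r_angstrom`).
#' @param constants a [physical_constants()].
#' @param spectral_density "full" or "first_term_only".
#' @return data frame with `site`, `t1_s`, `tau_c_s` (slow branch),
#'   `tau_c_fast_s`, `branch`, `csa_frac`, `dd_frac`.
#' @export
invert_tau_c_table <- function(t1_table, tensors, geometry = NULL,
                               constants = physical_constants(),
                               spectral_density = "full") {
  stopifnot(all(c("site", "t1_s") %in% names(t1_table)),
            all(c("site", "anisotropy", "asymmetry") %in% names(tensors)))
  rows <- lapply(seq_len(nrow(t1_table)), function(i) {
    s <- t1_table$site[i]
    j <- match(s, tensors$site)
    if (is.na(j)) stop(sprintf("no tensor row for site '%s'", s),
                       call. = FALSE)
    geo <- if (!is.null(geometry)) geometry[geometry$site == s, ] else NULL
    if (!is.null(geo) && nrow(geo) == 0) geo <- NULL
    model <- site_relaxation_model(
      anisotropy = tensors$anisotropy[j],
      asymmetry = tensors$asymmetry[j],
      group = if ("group" %in% names(tensors)) tensors$group[j]
              else "nonprotonated",
      geometry = geo, constants = constants,
      spectral_density = spectral_density)
    res <- invert_tau_c(t1_table$t1_s[i], model)
    data.frame(site = s, t1_s = t1_table$t1_s[i],
               tau_c_s = res$tau_c, tau_c_fast_s = res$tau_c_fast,
               branch = "slow", csa_frac = res$r1_csa_frac,
               dd_frac = res$r1_dd_frac, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Regression report against the published dexamethasone CSA table
#'
#' Recomputes every derived CSA parameter from the published principal
#' components and compares cell by cell with the published values,
#' flagging the known printed inconsistencies (see
#' [table2_inconsistencies()]) instead of matching them. Deterministic:
#' identical reruns give identical reports.
#'
#' @param fixture fixture data frame, default [dexamethasone_sites()].
#' @param tol_ppm,tol_dimless tolerances passed to
#'   [compare_to_printed()].
#' @return list with `cells` (per-cell data frame: `site`, `field`,
#'   `computed`, `printed`, `delta`, `match`, `known_inconsistency`,
#'   `severity`) and `summary` (counts: `n_cells`, `n_derivable`,
#'   `n_pass`, `n_flagged`, `pass_rate` over derivable cells).
#' @export
table2_regression_report <- function(fixture = dexamethasone_sites(),
                                     tol_ppm = 0.15, tol_dimless = 0.06) {
  flags <- table2_inconsistencies()
  cells <- do.call(rbind, lapply(seq_len(nrow(fixture)), function(i) {
    row <- fixture[i, ]
    comp <- derive_csa_parameters(c(row$d11, row$d22, row$d33),
                                  site = row$site)
    cmp <- compare_to_printed(comp, row, tol_ppm = tol_ppm,
                              tol_dimless = tol_dimless)
    cmp$site <- row$site
    cmp
  }))
  idx <- match(paste(cells$site, cells$field),
               paste(flags$site, flags$field))
  cells$known_inconsistency <- !is.na(idx)
  cells$severity <- ifelse(is.na(idx), "", flags$severity[idx])
  cells <- cells[, c("site", "field", "computed", "printed", "delta",
                     "tolerance", "match", "known_inconsistency",
                     "severity")]
  derivable <- !cells$known_inconsistency
  summary <- list(
    n_cells = nrow(cells),
    n_derivable = sum(derivable),
    n_pass = sum(cells$match[derivable]),
    n_flagged = sum(!derivable),
    pass_rate = mean(cells$match[derivable])
  )
  list(cells = cells, summary = summary)
}
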