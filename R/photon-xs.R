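ELEMENT_Z <- c(H = 1, C = 6, N = 7, O = 8, Na = 11, Mg = 12, P = 15, S = 16,
               Cl = 17, K = 19, Ca = 20, Fe = 26, I = 53)
ELEMENT_A <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, Na = 22.990,
               Mg = 24.305, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
               Ca = 40.078, Fe = 55.845, I = 126.904)
MEC2 <- 0.510998950                 # electron rest energy, MeV
R_E <- 2.8179403262e-13             # classical electron radius, cm
N_AVOGADRO <- 6.02214076e23

#' Klein-Nishina total cross section per electron
#'
#' Closed-form free-electron incoherent cross section.
#'
#' @param E photon energy, MeV.
#' @return cross section in cm2 per electron.
#' @export
kn_total_cs <- function(E) {
  k <- E / MEC2
  t1 <- (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k)
  t2 <- log(1 + 2 * k) / (2 * k)
  t3 <- (1 + 3 * k) / (1 + 2 * k)^2
  2 * pi * R_E^2 * (t1 + t2 - t3)
}

#' Mean fraction of photon energy transferred in incoherent scatter
#'
#' `1 - <E'/E>` under the Klein-Nishina differential, by quadrature over
#' the scattered-fraction density; used to keep the packaged mass
#' energy-absorption coefficients exactly consistent with the analog
#' deposition model of the transport kernel.
#'
#' @param E photon energy (MeV), vectorized.
#' @return mean transferred fraction in `[0, 1)`.
#' @export
kn_mean_transfer_fraction <- function(E) {
  vapply(E, function(e) {
    k <- e / MEC2
    xmin <- 1 / (1 + 2 * k)
    f <- function(x) {
      cth <- 1 + 1 / k - 1 / (k * x)
      x + 1 / x - (1 - cth^2)
    }
    norm <- stats::integrate(f, xmin, 1, rel.tol = 1e-10)$value
    mean_x <- stats::integrate(function(x) x * f(x), xmin, 1,
                               rel.tol = 1e-10)$value / norm
    1 - mean_x
  }, numeric(1))
}

#' Synthetic elemental photon interaction tables
#'
#' Mass attenuation coefficients partitioned into photoelectric, incoherent
#' (Klein-Nishina free-electron) and pair-production channels, plus the mass
#' energy-absorption coefficient, for the 13 supported elements over
#' 0.001-20 MeV.  This is an analytic stand-in model, not evaluated nuclear
#' data: incoherent is exact Klein-Nishina; photoelectric uses a
#' `Z^4.5 / (A E^3)` parameterization calibrated to water at 0.01 MeV; pair
#' production uses a `Z^2/A` form calibrated to water at 10 MeV.  The
#' energy-absorption coefficient is built to be exactly consistent with the
#' kerma-approximation deposition rules of [run_transport()]
#' (full local absorption for photoelectric, Klein-Nishina mean transfer for
#' incoherent, `E - 1.022` for pair).
#'
#' @param energies energy grid in MeV (default: log grid, 15 points per
#'   decade, with the pair threshold inserted).
#' @return data.frame with columns `element`, `E`, `mu_pe`, `mu_incoh`,
#'   `mu_pair`, `mu_en`, all mass coefficients in cm2/g.
#' @export
elemental_photon_tables <- function(energies = default_energy_grid()) {
  stopifnot(all(energies > 0), !is.unsorted(energies))
  C_PE <- 7.68e-9
  C_PAIR <- 1.445e-3
  ftrans <- kn_mean_transfer_fraction(energies)
  sigma_kn <- kn_total_cs(energies)
  pair_shape <- ifelse(energies > 2 * MEC2,
                       (1 - 2 * MEC2 / energies)^3 *
                         log(energies / (2 * MEC2) + 1),
                       0)
  rows <- lapply(names(ELEMENT_Z), function(el) {
    Z <- ELEMENT_Z[[el]]; A <- ELEMENT_A[[el]]
    mu_pe <- C_PE * Z^4.5 / (A * energies^3)
    mu_incoh <- N_AVOGADRO * (Z / A) * sigma_kn
    mu_pair <- C_PAIR * (Z^2 / A) * pair_shape
    mu_en <- mu_pe + mu_incoh * ftrans +
      mu_pair * pmax(0, (energies - 2 * MEC2) / energies)
    data.frame(element = el, E = energies, mu_pe = mu_pe,
               mu_incoh = mu_incoh, mu_pair = mu_pair, mu_en = mu_en)
  })
  do.call(rbind, rows)
}

#' Default photon energy grid (MeV)
#'
#' Log-spaced, 15 points per decade over 0.001-20 MeV, with the pair
#' threshold (1.022 MeV) inserted.
#' @return numeric vector.
#' @export
default_energy_grid <- function() {
  g <- 10^seq(log10(0.001), log10(20), by = 1 / 15)
  sort(unique(c(g, 2 * MEC2, 20)))
}

#' Load the packaged elemental coefficient table
#'
#' Reads the shipped text fixture (identical to
#' [elemental_photon_tables()] on the default grid).
#' @return data.frame, see [elemental_photon_tables()].
#' @export
load_elemental_tables <- function() {
  read.delim(system.file("extdata", "mu_elemental_synthetic.tsv",
                         package = "phantomdose", mustWork = TRUE),
             comment.char = "#", stringsAsFactors = FALSE)
}

.xs_cache <- new.env(parent = emptyenv())

default_tables <- function() {
  if (is.null(.xs_cache$tables)) {
    .xs_cache$tables <- elemental_photon_tables()
  }
  .xs_cache$tables
}

loglog_interp <- function(x, y, xout) {
  # log-log where positive; linear across zeros (pair threshold)
  if (any(y <= 0)) {
    stats::approx(log(x), y, xout = log(xout), rule = 1)$y
  } else {
    exp(stats::approx(log(x), log(y), xout = log(xout), rule = 1)$y)
  }
}

#' Mixture mass energy-absorption coefficient
#'
#' Mass-fraction-weighted elemental coefficients with log-log interpolation
#' between grid energies.  No extrapolation: energies outside the packaged
#' 0.001-20 MeV grid are an error.
#'
#' @param material a material entry (list with `fractions` named over
#'   [PHANTOM_ELEMENTS]) or a named fraction vector.
#' @param E energies in MeV (vectorized).
#' @param tables elemental tables (default: packaged).
#' @param unit `"m2/kg"` (default, SI) or `"cm2/g"`.
#' @return numeric vector of coefficients.
#' @export
mixture_mu_en <- function(material, E, tables = NULL, unit = "m2/kg") {
  fr <- if (is.list(material)) material$fractions else material
  if (is.null(names(fr))) stop("fractions must be named by element")
  if (is.null(tables)) tables <- default_tables()
  unit <- match.arg(unit, c("m2/kg", "cm2/g"))
  rng <- range(tables$E)
  if (any(E < rng[1] | E > rng[2])) {
    stop("energy outside packaged table range ", rng[1], "-", rng[2],
         " MeV; extrapolation refused")
  }
  out <- numeric(length(E))
  for (el in names(fr)) {
    if (fr[[el]] == 0) next
    sub <- tables[tables$element == el, ]
    if (!nrow(sub)) stop("element ", el, " not covered by tables")
    out <- out + fr[[el]] * loglog_interp(sub$E, sub$mu_en, E)
  }
  if (unit == "m2/kg") out * 0.1 else out      # cm2/g -> m2/kg
}

#' Build per-material cross-section tables for transport
#'
#' Mixture mass coefficients (mass-fraction weighting of the elemental
#' channels) on the elemental energy grid, for every material in the
#' library.
#'
#' @param materials a [material_library()].
#' @param tables elemental tables (default: packaged analytic model).
#' @return object of class `cross_section_table`: `energies` (MeV),
#'   matrices `mu_pe`, `mu_incoh`, `mu_pair`, `mu_en`
#'   (materials x energies, cm2/g), `density` (g/cm3), `materials` names.
#' @export
build_cross_sections <- function(materials, tables = NULL) {
  stopifnot(inherits(materials, "material_library"))
  if (is.null(tables)) tables <- default_tables()
  eg <- sort(unique(tables$E))
  nm <- names(materials)
  mk <- function() matrix(0, length(nm), length(eg),
                          dimnames = list(nm, NULL))
  mu_pe <- mk(); mu_incoh <- mk(); mu_pair <- mk(); mu_en <- mk()
  by_el <- split(tables, tables$element)
  for (i in seq_along(nm)) {
    fr <- materials[[i]]$fractions
    for (el in names(fr)) {
      if (fr[[el]] == 0) next
      sub <- by_el[[el]]
      if (is.null(sub)) stop("element ", el, " not covered by tables")
      sub <- sub[order(sub$E), ]
      mu_pe[i, ] <- mu_pe[i, ] + fr[[el]] * sub$mu_pe
      mu_incoh[i, ] <- mu_incoh[i, ] + fr[[el]] * sub$mu_incoh
      mu_pair[i, ] <- mu_pair[i, ] + fr[[el]] * sub$mu_pair
      mu_en[i, ] <- mu_en[i, ] + fr[[el]] * sub$mu_en
    }
  }
  structure(list(energies = eg, mu_pe = mu_pe, mu_incoh = mu_incoh,
                 mu_pair = mu_pair, mu_en = mu_en,
                 density = vapply(materials, `[[`, numeric(1), "density"),
                 materials = nm),
            class = "cross_section_table")
}

#' Total mass attenuation coefficient of a material
#'
#' Sum of the photoelectric, incoherent and pair channels, log-log
#' interpolated (linear across the pair threshold).
#'
#' @param xs a [build_cross_sections()] table.
#' @param material material name.
#' @param E energies, MeV.
#' @param unit `"cm2/g"` (default) or `"1/cm"` (multiplied by density).
#' @return numeric vector.
#' @export
material_mu_total <- function(xs, material, E, unit = "cm2/g") {
  i <- match(material, xs$materials)
  if (is.na(i)) stop("unknown material ", material)
  tot <- loglog_interp(xs$energies, xs$mu_pe[i, ], E) +
    loglog_interp(xs$energies, xs$mu_incoh[i, ], E) +
    stats::approx(log(xs$energies), xs$mu_pair[i, ], xout = log(E),
                  rule = 1)$y
  unit <- match.arg(unit, c("cm2/g", "1/cm"))
  if (unit == "1/cm") tot * xs$density[i] else tot
}
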