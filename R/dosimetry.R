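#' Dose conversion constants
#'
#' @param c_J_per_MeV MeV-to-joule conversion (default the CODATA value
#'   1.602176634e-13 J/MeV).
#' @param high_energy_threshold MeV; at and above it the bone-component
#'   dose switches from the fluence-spectrum estimator to mass-proportional
#'   energy partition (default 1 MeV).
#' @return list of constants.
#' @export
dose_constants <- function(c_J_per_MeV = 1.602176634e-13,
                           high_energy_threshold = 1.0) {
  stopifnot(c_J_per_MeV > 0, high_energy_threshold > 0)
  list(c = c_J_per_MeV, threshold = high_energy_threshold)
}

#' Bone-component dose from a fluence spectrum (below-threshold route)
#'
#' Kerma-mode estimator for the dose to active marrow or endosteum inside a
#' homogenized bone region: the deposited energy is
#' `ED_a = M_a * sum_bins Phi_a(E) * (mu_en/rho)(E) * E`
#' (midpoint rule on the tally grid) and the absorbed dose
#' `D_a = ED_a * c / M_a`.  The mass cancels, as the closed form implies:
#' the dose depends only on the in-region fluence spectrum and the
#' component's own energy-absorption coefficient.
#'
#' @param spectrum numeric vector: fluence per energy bin, m^-2 (per unit
#'   incident fluence if a normalized coefficient is wanted).
#' @param bin_edges energy bin edges, MeV (length = bins + 1).
#' @param component_material material entry for the component (its
#'   `mu_en/rho` is evaluated at the bin midpoints).
#' @param mass_kg component mass `M_a` (kg), used only to report `ED`.
#' @param constants [dose_constants()].
#' @param tables elemental coefficient tables (default packaged).
#' @param bin_energies optional representative energy per bin; defaults to
#'   the log-midpoints.  Pass the tally's track-length-weighted bin
#'   energies (`tally$bin_energies`) to remove the midpoint bias for line
#'   spectra (a monoenergetic source sits at its bin's top edge, not its
#'   midpoint).
#' @return list with `dose_Gy` and `ED_MeV`.
#' @export
bone_component_dose_lowE <- function(spectrum, bin_edges, component_material,
                                     mass_kg, constants = dose_constants(),
                                     tables = NULL, bin_energies = NULL) {
  nb <- length(bin_edges) - 1L
  if (length(spectrum) != nb) {
    stop("spectrum has ", length(spectrum), " bins but edges imply ", nb)
  }
  mid <- bin_energies %||%
    sqrt(bin_edges[-1] * bin_edges[-(nb + 1L)])       # log-midpoint
  muen <- mixture_mu_en(component_material, mid, tables = tables,
                        unit = "m2/kg")
  ed_per_kg <- sum(spectrum * muen * mid)             # MeV / kg
  list(dose_Gy = ed_per_kg * constants$c,
       ED_MeV = ed_per_kg * mass_kg)
}

#' Bone-component dose by mass-proportional partition (threshold-and-above
#' route)
#'
#' Above the threshold the total energy deposited in a homogenized bone
#' region is divided among its components in proportion to their masses,
#' which makes the mass-specific dose identical for every component:
#' `D = ED_region * c / M_region`.
#'
#' @param ED_region_MeV total deposited energy in the region, MeV.
#' @param component_masses named numeric vector of component masses, kg
#'   (all > 0 in total).
#' @param constants [dose_constants()].
#' @return list with `dose_Gy` (scalar, same for every component) and
#'   `ED_MeV` (named per-component energy shares, summing to the input).
#' @export
bone_component_dose_highE <- function(ED_region_MeV, component_masses,
                                      constants = dose_constants()) {
  M <- sum(component_masses)
  if (M <= 0) stop("total component mass must be > 0")
  shares <- ED_region_MeV * component_masses / M
  list(dose_Gy = ED_region_MeV * constants$c / M,
       ED_MeV = shares)
}

#' Mass-weighted whole-body component dose
#'
#' `D = sum_a D_a M_a / sum_a M_a` over the anatomical bone regions with
#' nonzero component mass.
#'
#' @param doses named numeric vector of per-region doses (names = region
#'   names of the inventory).
#' @param inventory a [bone_inventory()].
#' @param component bone component name.
#' @return whole-body dose, same unit as `doses`.
#' @export
whole_body_component_dose <- function(doses, inventory, component) {
  if (!component %in% BONE_COMPONENTS) {
    stop("unknown bone component '", component, "'")
  }
  M <- setNames(inventory[[component]], inventory$region)
  M <- M[M > 0]
  missing <- setdiff(names(M), names(doses))
  if (length(missing)) {
    stop("missing dose for region(s) with nonzero ", component, " mass: ",
         paste(missing, collapse = ", "))
  }
  sum(doses[names(M)] * M) / sum(M)
}

#' Organ absorbed doses from a transport tally
#'
#' `D = E_dep * c / m`, normalized per unit incident fluence and reported
#' in pGy cm2.
#'
#' @param tally a `tally_result` from [run_transport()].
#' @param masses optional named vector (kg) overriding the voxel-derived
#'   region masses (names = region ids as character).
#' @param constants [dose_constants()].
#' @return data.frame: region id, name, mass (kg), `dose_pGycm2`, `fsd`.
#' @export
organ_absorbed_dose <- function(tally, masses = NULL,
                                constants = dose_constants()) {
  reg <- tally$regions
  m <- reg$mass
  if (!is.null(masses)) {
    i <- match(as.character(reg$id), names(masses))
    m <- ifelse(is.na(i), m, masses[i])
  }
  if (any(m <= 0)) stop("region mass must be > 0 for dose conversion")
  ed <- rowSums(tally$edep)                     # MeV over all batches
  # per history: ed / N; per unit fluence: * area; Gy: * c / m; pGy: 1e12
  dose <- ed / tally$histories_total * tally$area_cm2 * constants$c / m * 1e12
  unc <- estimate_uncertainty(tally$edep, threshold = Inf)
  data.frame(id = reg$id, name = reg$name, mass = m,
             dose_pGycm2 = dose, fsd = unc$fsd)
}

#' Equivalent dose for photon or electron irradiation
#'
#' Radiation weighting factor `w_R = 1` for both supported radiations, so
#' the equivalent dose is numerically the absorbed dose (pSv cm2 from
#' pGy cm2).
#'
#' @param dose absorbed dose (any consistent unit).
#' @param radiation `"photon"` or `"electron"`.
#' @return equivalent dose, numerically equal.
#' @export
equivalent_dose <- function(dose, radiation = c("photon", "electron")) {
  radiation <- match.arg(radiation)
  dose * 1.0
}

#' ICRP 103 tissue weighting configuration
#'
#' Packaged `w_T` values plus the arithmetic-mean remainder tissue and its
#' member list; the weights sum to 1.
#'
#' @param path optional override file (same layout as the packaged one).
#' @return list with `weights` (named numeric) and `remainder_tissues`
#'   (character).
#' @export
tissue_weighting <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "wt_icrp103.tsv",
                        package = "phantomdose", mustWork = TRUE)
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  w <- setNames(df$w_T[!is.na(df$w_T)], df$tissue[!is.na(df$w_T)])
  if (abs(sum(w) - 1) > 1e-6) {
    stop("tissue weights sum to ", sum(w), "; must be 1")
  }
  list(weights = w, remainder_tissues = df$tissue[is.na(df$w_T)])
}

#' Sex-averaged effective dose
#'
#' `E = sum_T w_T (H_T^male + H_T^female) / 2`.  The remainder equivalent
#' dose is the arithmetic mean over the configured remainder tissues,
#' computed per sex before sex-averaging.  Sex-specific tissues follow the
#' ICRP 103 convention: `gonads` is the testes dose in the male map and the
#' ovaries dose in the female map; the prostate/uterus pair enters the
#' remainder as `prostate_or_uterus`.
#'
#' @param male,female named numeric vectors of tissue equivalent doses
#'   (pSv cm2); names must cover every weighted tissue (and every remainder
#'   tissue present in the configuration that the phantom provides).
#' @param w a [tissue_weighting()] configuration.
#' @param strict_remainder if `TRUE`, all configured remainder tissues must
#'   be present; if `FALSE` (default) the remainder mean runs over the
#'   tissues available in both maps.
#' @return effective dose (pSv cm2).
#' @export
effective_dose <- function(male, female, w = tissue_weighting(),
                           strict_remainder = FALSE) {
  weighted <- setdiff(names(w$weights), "remainder")
  for (nm in list(male = male, female = female)) {
    miss <- setdiff(weighted, names(nm))
    if (length(miss)) {
      stop("missing weighted tissue(s): ", paste(miss, collapse = ", "))
    }
  }
  rem <- w$remainder_tissues
  if (strict_remainder) {
    miss <- setdiff(rem, intersect(names(male), names(female)))
    if (length(miss)) {
      stop("missing remainder tissue(s): ", paste(miss, collapse = ", "))
    }
  } else {
    rem <- intersect(rem, intersect(names(male), names(female)))
  }
  has_rem <- "remainder" %in% names(w$weights)
  if (has_rem && !length(rem)) {
    stop("no remainder tissues available in both dose maps")
  }
  h <- function(d) {
    if (has_rem) c(d[weighted], remainder = mean(d[rem])) else d[weighted]
  }
  hm <- h(male); hf <- h(female)
  sum(w$weights[names(hm)] * (hm + hf) / 2)
}
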