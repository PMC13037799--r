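#' AP parallel-beam specification
#'
#' Uniform parallel photon beam in anterior-to-posterior (AP) geometry:
#' photons travel along +y and the rectangular field covers the full x-z
#' cross-section of the phantom bounding box, so doses normalize per unit
#' incident fluence.
#'
#' @param energy photon energy, MeV (`0.01 <= E <= 20`).
#' @param histories number of source photons per batch, >= 1.
#' @param batches number of independent batches (>= 2 for uncertainty
#'   estimates; 10+ recommended).
#' @param seed integer RNG seed; batch `b` runs on stream `seed + b - 1`.
#' @return object of class `beam`.
#' @export
beam <- function(energy, histories, batches = 10L, seed = 1L) {
  if (energy < 0.01 || energy > 20) {
    stop("beam energy must lie in 0.01-20 MeV")
  }
  if (histories < 1) stop("histories must be >= 1")
  structure(list(geometry = "AP", energy = energy,
                 histories = as.integer(histories),
                 batches = as.integer(batches), seed = as.integer(seed)),
            class = "beam")
}

#' Fluence tally energy bins
#'
#' Logarithmic bins, 20 per decade, top edge exactly at the source energy.
#'
#' @param E0 source energy (MeV).
#' @param cutoff lower edge (MeV).
#' @return vector of bin edges, ascending.
#' @export
fluence_bins <- function(E0, cutoff = 0.001) {
  n <- max(1L, ceiling(20 * log10(E0 / cutoff)))
  exp(seq(log(cutoff), log(E0), length.out = n + 1L))
}

#' Analog Monte Carlo photon transport on a voxel phantom
#'
#' Woodcock delta-tracking with a global majorant; analog channel sampling
#' (photoelectric, Klein-Nishina incoherent, pair production); kerma
#' approximation: all charged-particle energy is deposited at the
#' interaction site, annihilation photons are re-emitted back-to-back.
#' Photons below the 1 keV cutoff deposit their residual energy locally.
#' Track-length fluence is accumulated per region and energy bin with the
#' delta-tracking collision estimator.  Results are reproducible bit-exactly
#' for a fixed beam seed.
#'
#' @param phantom a [voxel_phantom()].
#' @param catalog a [region_catalog()] mapping the raster ids to materials
#'   (id 0 is treated as air unless cataloged).
#' @param materials a [material_library()].
#' @param bm a [beam()].
#' @param xs optional [build_cross_sections()] table (built if omitted).
#' @param cutoff termination energy, MeV (default 0.001).
#' @return object of class `tally_result` with elements
#'   \describe{
#'     \item{regions}{data.frame: id, name, voxels, volume (cm3), mass (kg)}
#'     \item{edep}{matrix regions x batches, MeV deposited per batch}
#'     \item{fluence}{matrix regions x bins: track-length fluence per unit
#'       incident fluence (dimensionless, cm-2 per cm-2)}
#'     \item{bin_edges}{fluence bin edges, MeV}
#'     \item{beam, area_cm2, histories_total}{normalization data}
#'     \item{balance}{per-batch injected/deposited/escaped energy (MeV)}
#'     \item{uncollided_fraction}{primaries escaping with no real collision}
#'   }
#' @export
run_transport <- function(phantom, catalog, materials, bm, xs = NULL,
                          cutoff = 0.001) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(bm, "beam"))
  if (is.null(xs)) xs <- build_cross_sections(materials)
  ids_present <- sort(unique(as.vector(phantom$organ_ids)))
  if (!length(setdiff(ids_present, 0L))) stop("phantom raster is empty")
  # material per id: catalog entries; id 0 defaults to air if available
  id_max <- max(ids_present)
  id2mat <- rep(-1L, id_max + 1L)
  id2reg <- rep(-1L, id_max + 1L)
  tally_ids <- integer(0)
  for (id in ids_present) {
    mat <- if (id %in% catalog$region_id) {
      catalog_material(catalog, id)
    } else if (id == 0L && "air" %in% xs$materials) "air" else NULL
    if (is.null(mat)) {
      stop("raster id ", id, " has no catalog entry and no air default")
    }
    mi <- match(mat, xs$materials)
    if (is.na(mi)) stop("material '", mat, "' missing from cross sections")
    id2mat[id + 1L] <- mi - 1L
    if (id != 0L) {
      tally_ids <- c(tally_ids, id)
      id2reg[id + 1L] <- length(tally_ids) - 1L
    }
  }
  n_reg <- length(tally_ids)
  edges <- fluence_bins(bm$energy, cutoff)
  p_cm <- phantom$pitch / 10
  dims <- phantom$dims
  # mu in 1/cm = (mu/rho)[cm2/g] * rho[g/cm3]
  rho <- xs$density
  mu_pe <- xs$mu_pe * rho
  mu_inc <- xs$mu_incoh * rho
  mu_pair <- xs$mu_pair * rho

  nb <- length(edges) - 1L
  edep <- matrix(0, n_reg, bm$batches)
  fl <- matrix(0, n_reg, nb)
  flE <- matrix(0, n_reg, nb)
  balance <- data.frame(batch = seq_len(bm$batches), injected = 0,
                        deposited = 0, escaped = 0)
  n_unc <- 0
  for (b in seq_len(bm$batches)) {
    set.seed(bm$seed + b - 1L)
    res <- transport_kernel(phantom$organ_ids, as.integer(dims), p_cm,
                            phantom$origin, id2mat, id2reg, n_reg,
                            mu_pe, mu_inc, mu_pair, xs$energies,
                            bm$energy, bm$histories, edges, cutoff)
    edep[, b] <- res$edep
    fl <- fl + res$fluence_tracklength
    flE <- flE + res$fluence_tracklength_E
    balance$injected[b] <- res$injected
    balance$deposited[b] <- sum(res$edep) + res$edep_untallied
    balance$escaped[b] <- res$escaped
    n_unc <- n_unc + res$n_uncollided
  }
  area <- prod((dims * p_cm)[c(1, 3)])         # x-z field, cm2
  n_total <- bm$histories * bm$batches
  vol_voxel <- prod(p_cm)
  counts <- vapply(tally_ids, function(id) sum(phantom$organ_ids == id),
                   numeric(1))
  mass <- vapply(seq_along(tally_ids), function(i) {
    mat <- xs$materials[id2mat[tally_ids[i] + 1L] + 1L]
    counts[i] * vol_voxel * rho[[mat]] / 1000  # kg
  }, numeric(1))
  names_cat <- catalog$name[match(tally_ids, catalog$region_id)]
  regions <- data.frame(id = tally_ids, name = names_cat,
                        voxels = counts, volume = counts * vol_voxel,
                        mass = mass)
  # fluence per unit incident fluence: tracklength / V / (N / A)
  fl_norm <- fl / (regions$volume * (n_total / area))
  bin_E <- flE / fl                           # tracklength-weighted energy
  mid <- sqrt(edges[-1] * edges[-(nb + 1L)])
  bin_E[!is.finite(bin_E)] <- rep(mid, each = n_reg)[!is.finite(bin_E)]
  structure(list(regions = regions, edep = edep, fluence = fl_norm,
                 bin_energies = bin_E,
                 bin_edges = edges, beam = bm, area_cm2 = area,
                 histories_total = n_total, balance = balance,
                 uncollided_fraction = n_unc / n_total,
                 cutoff = cutoff),
            class = "tally_result")
}

#' @export
print.tally_result <- function(x, ...) {
  cat("<tally_result> E0 =", x$beam$energy, "MeV,", x$histories_total,
      "histories in", x$beam$batches, "batches\n")
  d <- organ_absorbed_dose(x)
  print(d)
  invisible(x)
}

#' Batch-based fractional standard deviations
#'
#' `fsd = (batch standard error) / (batch mean)` per region; regions above
#' `threshold` are flagged.
#'
#' @param tally a `tally_result`, or a numeric matrix regions x batches.
#' @param threshold flag level (default 0.01, the usual 1 % target).
#' @return data.frame with `mean`, `fsd`, `flagged`.
#' @export
estimate_uncertainty <- function(tally, threshold = 0.01) {
  m <- if (inherits(tally, "tally_result")) tally$edep else as.matrix(tally)
  nb <- ncol(m)
  if (nb < 2L) stop("need at least 2 batches to estimate uncertainty")
  if (nb < 10L) {
    warning("fewer than 10 batches; uncertainty estimates are coarse")
  }
  mu <- rowMeans(m)
  se <- apply(m, 1, sd) / sqrt(nb)
  fsd <- ifelse(mu > 0, se / mu, 0)
  out <- data.frame(mean = mu, fsd = fsd, flagged = fsd > threshold)
  if (inherits(tally, "tally_result")) {
    out <- cbind(tally$regions[, c("id", "name")], out)
  }
  out
}

#' Sample Klein-Nishina incoherent scattering
#'
#' Draws scattered-photon energies and polar scattering cosines from the
#' free-electron Klein-Nishina distribution (exact rejection sampling; the
#' same sampler the transport kernel uses).  Uses R's RNG, so
#' `set.seed()` gives reproducible streams.
#'
#' @param E incident photon energy, MeV (> 0).
#' @param n number of samples.
#' @return data.frame with `Eprime` (MeV) and `mu` (cos theta).
#' @export
kn_sample <- function(E, n = 1L) {
  stopifnot(E > 0, n >= 1)
  as.data.frame(kn_sample_cpp(E, as.integer(n)))
}
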