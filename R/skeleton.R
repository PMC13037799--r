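BONE_COMPONENTS <- c("active_marrow", "inactive_marrow", "hard_bone",
                     "endosteum")

#' Bone-region mass inventory
#'
#' Per-anatomical-region masses (kg) of active marrow, inactive marrow,
#' hard bone and endosteum over the 20 skeletal regions (Humeri upper half
#' ... Os hyoideum).  The packaged inventories `"jpm"` (male) and `"jpf"`
#' (female) are the printed tables of the adult Japanese polygon-mesh
#' phantoms.
#'
#' @param x `"jpm"`, `"jpf"`, or a data.frame with columns `region`,
#'   `active_marrow`, `inactive_marrow`, `hard_bone`, `endosteum`.
#' @return object of class `bone_inventory` (a validated data.frame).
#' @export
bone_inventory <- function(x = c("jpm", "jpf")) {
  if (is.character(x)) {
    x <- match.arg(x)
    df <- read.delim(system.file("extdata", paste0(x, "_bone.tsv"),
                                 package = "phantomdose", mustWork = TRUE),
                     comment.char = "#", stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x)
  }
  need <- c("region", BONE_COMPONENTS)
  if (!all(need %in% names(df))) {
    stop("bone inventory needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) != 20L) {
    stop("bone inventory must have exactly 20 anatomical regions, got ",
         nrow(df))
  }
  if (any(as.matrix(df[BONE_COMPONENTS]) < 0)) {
    stop("bone component masses must be >= 0")
  }
  structure(df, class = c("bone_inventory", "data.frame"))
}

#' Total skeletal mass of one bone component
#'
#' Sum of the component column over the 20 anatomical regions.
#'
#' @param inventory a [bone_inventory()] (or a zero-row data.frame with the
#'   component columns, which sums to 0).
#' @param component one of `active_marrow`, `inactive_marrow`, `hard_bone`,
#'   `endosteum`.
#' @return total mass, kg.
#' @export
aggregate_skeleton <- function(inventory, component) {
  if (!component %in% BONE_COMPONENTS) {
    stop("unknown bone component '", component, "'; expected one of: ",
         paste(BONE_COMPONENTS, collapse = ", "))
  }
  sum(inventory[[component]])
}

#' Mass ratio, reported at two decimals
#'
#' Ratio of a phantom mass to a population reference mass, with the
#' half-up rounding the printed parenthetical ratios use.
#'
#' @param mass kg.
#' @param reference kg, > 0.
#' @param digits decimals for the report (default 2).
#' @return list with `ratio` (exact) and `reported` (rounded half-up).
#' @export
mass_ratio <- function(mass, reference, digits = 2) {
  if (any(reference <= 0)) stop("reference mass must be > 0")
  r <- mass / reference
  # half-up (not banker's) rounding, matching the printed convention
  reported <- floor(r * 10^digits + 0.5) / 10^digits
  list(ratio = r, reported = reported)
}

#' Mass fraction of one component within a bone region
#'
#' @param inventory a [bone_inventory()].
#' @param region region name (as in the inventory).
#' @param component component name; a component absent from the inventory
#'   columns has fraction 0.
#' @return fraction of the region total.
#' @export
component_mass_fraction <- function(inventory, region, component) {
  i <- match(region, inventory$region)
  if (is.na(i)) stop("unknown bone region '", region, "'")
  tot <- sum(unlist(inventory[i, BONE_COMPONENTS]))
  if (tot == 0) stop("region '", region, "' has zero total mass")
  if (!component %in% BONE_COMPONENTS) return(0)
  inventory[[component]][i] / tot
}

#' Packaged bone-component compositions
#'
#' Elemental compositions and densities for hard bone, active marrow and
#' inactive marrow (reference-tissue values; see [default_materials()]).
#' Endosteum defaults to the active-marrow composition, since only its mass
#' is inventoried; override via the `endosteum` argument.
#'
#' @param endosteum optional material entry to use for endosteum.
#' @return named list of material entries (fractions + density), one per
#'   bone component.
#' @export
bone_component_compositions <- function(endosteum = NULL) {
  mats <- default_materials()
  list(active_marrow = mats$active_marrow,
       inactive_marrow = mats$inactive_marrow,
       hard_bone = mats$hard_bone,
       endosteum = endosteum %||% mats$active_marrow)
}

#' Homogenize a multi-component mixture
#'
#' Mass-weighted elemental fractions and harmonic-mean (volume-conserving)
#' density:
#' `w_e = sum(m_i w_ie) / sum(m_i)`, `rho = sum(m_i) / sum(m_i / rho_i)`.
#'
#' @param masses numeric vector of component masses (kg), >= 0, not all 0.
#' @param compositions list of material entries matching `masses`.
#' @return material entry (fractions, density) with extra field
#'   `component_fractions`.
#' @export
homogenize_region <- function(masses, compositions) {
  if (length(masses) != length(compositions)) {
    stop("masses and compositions must have the same length")
  }
  if (any(masses < 0) || sum(masses) <= 0) {
    stop("component masses must be >= 0 and not all zero")
  }
  frs <- lapply(compositions, function(m) {
    full <- setNames(numeric(length(PHANTOM_ELEMENTS)), PHANTOM_ELEMENTS)
    fr <- if (is.list(m)) m$fractions else m
    full[names(fr)] <- fr
    full
  })
  total <- sum(masses)
  w <- Reduce(`+`, Map(function(m, f) m * f, masses, frs)) / total
  rho <- total / sum(masses / vapply(compositions, `[[`, numeric(1),
                                     "density"))
  list(fractions = w, density = rho,
       component_fractions = masses / total)
}

#' Homogenized material for one inventoried bone region
#'
#' Convenience wrapper: pulls the four component masses of a region from a
#' [bone_inventory()] and mixes them with [homogenize_region()].
#'
#' @param inventory a [bone_inventory()].
#' @param region region name.
#' @param compositions output of [bone_component_compositions()].
#' @return material entry for the mixed bone region.
#' @export
homogenize_bone_region <- function(inventory, region,
                                   compositions = bone_component_compositions()) {
  i <- match(region, inventory$region)
  if (is.na(i)) stop("unknown bone region '", region, "'")
  m <- unlist(inventory[i, BONE_COMPONENTS])
  keep <- m > 0
  homogenize_region(m[keep], compositions[BONE_COMPONENTS][keep])
}
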