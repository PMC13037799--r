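#' Supported elements
#'
#' Elemental mass fractions in material definitions are restricted to this
#' 13-element set, which covers soft tissues, bone and contrast-relevant
#' iodine.
#' @export
PHANTOM_ELEMENTS <- c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl", "K",
                      "Ca", "Fe", "I")

#' Material library
#'
#' Maps a material id to elemental mass fractions over [PHANTOM_ELEMENTS]
#' and a density (g/cm3).  Fractions whose sum deviates from 1 by at most
#' 1e-4 are renormalized; larger deviations are rejected.
#'
#' @param materials named list; each entry a list with `fractions` (named
#'   numeric over a subset of [PHANTOM_ELEMENTS]) and `density` (g/cm3).
#' @return object of class `material_library`: named list of entries with
#'   full-length fraction vectors.
#' @export
material_library <- function(materials) {
  stopifnot(is.list(materials), length(names(materials)) == length(materials))
  out <- lapply(names(materials), function(id) {
    m <- materials[[id]]
    fr <- m$fractions
    if (is.null(names(fr))) stop("material '", id, "': fractions must be named")
    unknown <- setdiff(names(fr), PHANTOM_ELEMENTS)
    if (length(unknown)) {
      stop("material '", id, "': unsupported element(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(fr < 0)) stop("material '", id, "': negative mass fraction")
    if (is.null(m$density) || m$density <= 0) {
      stop("material '", id, "': density must be > 0")
    }
    s <- sum(fr)
    if (abs(s - 1) > 1e-4) {
      stop("material '", id, "': fractions sum to ", format(s),
           "; must be within 1e-4 of 1")
    }
    full <- setNames(numeric(length(PHANTOM_ELEMENTS)), PHANTOM_ELEMENTS)
    full[names(fr)] <- fr / s
    list(fractions = full, density = as.numeric(m$density))
  })
  names(out) <- names(materials)
  structure(out, class = "material_library")
}

#' @export
print.material_library <- function(x, ...) {
  cat("<material_library> ", length(x), " material(s)\n", sep = "")
  for (id in names(x)) {
    cat(sprintf("  %-16s rho = %.4g g/cm^3\n", id, x[[id]]$density))
  }
  invisible(x)
}

#' Read a material library from structured text
#'
#' The on-disk format is tab-separated with a header line: columns
#' `material`, `density`, then one column per element symbol.  Lines
#' starting with `#` are comments.
#'
#' @param path file path or connection.
#' @return a [material_library()].
#' @export
read_material_library <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("material", "density")
  if (!all(need %in% names(df))) {
    stop("material table must have columns 'material' and 'density'")
  }
  elems <- intersect(names(df), PHANTOM_ELEMENTS)
  mats <- lapply(seq_len(nrow(df)), function(i) {
    fr <- unlist(df[i, elems])
    fr <- fr[!is.na(fr)]
    list(fractions = fr, density = df$density[i])
  })
  names(mats) <- df$material
  material_library(mats)
}

#' Packaged default tissue material library
#'
#' Representative elemental compositions and densities for the tissues the
#' stylized phantoms use (water, air, generic soft tissue, skin, adipose,
#' breast, eye lens, hard bone, active and inactive marrow).  Values follow
#' the widely used reference-tissue compilations; they are packaged defaults
#' and fully overridable via [material_library()].
#'
#' @return a [material_library()].
#' @export
default_materials <- function() {
  read_material_library(system.file("extdata", "materials_default.tsv",
                                    package = "phantomdose", mustWork = TRUE))
}

#' Region catalog
#'
#' Maps region ids to names, material ids, optional target masses (kg) and
#' a component role.
#'
#' @param df data.frame with columns `region_id`, `name`, `material`,
#'   optionally `target_mass` (kg, NA allowed) and `role` (one of `organ`,
#'   `content`, `sensitive-layer`, `bone-region`).
#' @param materials a [material_library()] every `material` must exist in.
#' @return object of class `region_catalog` (a validated data.frame).
#' @export
region_catalog <- function(df, materials) {
  stopifnot(is.data.frame(df))
  need <- c("region_id", "name", "material")
  if (!all(need %in% names(df))) {
    stop("region catalog needs columns: ", paste(need, collapse = ", "))
  }
  if (!"target_mass" %in% names(df)) df$target_mass <- NA_real_
  if (!"role" %in% names(df)) df$role <- "organ"
  bad <- setdiff(df$material, names(materials))
  if (length(bad)) {
    stop("catalog references unknown material(s): ",
         paste(unique(bad), collapse = ", "))
  }
  if (any(!is.na(df$target_mass) & df$target_mass <= 0)) {
    stop("target_mass must be > 0 where present")
  }
  roles <- c("organ", "content", "sensitive-layer", "bone-region")
  if (any(!df$role %in% roles)) {
    stop("role must be one of: ", paste(roles, collapse = ", "))
  }
  if (anyDuplicated(df$region_id)) stop("duplicate region_id in catalog")
  df$region_id <- as.integer(df$region_id)
  structure(df, class = c("region_catalog", "data.frame"))
}

catalog_material <- function(catalog, region_id) {
  i <- match(as.integer(region_id), catalog$region_id)
  if (is.na(i)) stop("region ", region_id, " not in catalog")
  catalog$material[i]
}
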