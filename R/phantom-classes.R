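#' @useDynLib phantomdose, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd setNames
#' @importFrom utils read.delim write.table head tail
NULL

#' Region-tagged polygon surface phantom
#'
#' A `polygon_phantom` is a list of closed, region-tagged triangle surfaces,
#' the substrate for phantom construction and quality assurance.  Coordinates
#' are in centimetres.  Each region is a list with elements `region_id`
#' (integer), `name` (character), `vertices` (numeric n x 3 matrix) and
#' `faces` (integer m x 3 matrix of 1-based vertex indices).
#'
#' @param regions list of region lists as described above.
#' @param sex one of `"male"`, `"female"`, `"n/a"`.
#' @param source free-text provenance tag.
#' @return An object of class `polygon_phantom`.
#' @export
polygon_phantom <- function(regions, sex = "n/a", source = "") {
  stopifnot(is.list(regions))
  sex <- match.arg(sex, c("male", "female", "n/a"))
  ids <- vapply(regions, function(r) as.integer(r$region_id), integer(1))
  if (anyDuplicated(ids)) {
    stop("region_ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  regions <- lapply(regions, function(r) {
    v <- as.matrix(r$vertices)
    storage.mode(v) <- "double"
    f <- as.matrix(r$faces)
    storage.mode(f) <- "integer"
    if (ncol(v) != 3L) stop("vertices must be an n x 3 matrix")
    if (ncol(f) != 3L) stop("faces must be an m x 3 triangle matrix")
    if (!all(is.finite(v))) stop("non-finite vertex coordinate in region ",
                                 r$region_id)
    if (nrow(f) < 4L) stop("region ", r$region_id,
                           " has fewer than 4 faces; not a closed surface")
    if (any(f < 1L) || any(f > nrow(v))) {
      stop("face references missing vertex in region ", r$region_id)
    }
    list(region_id = as.integer(r$region_id),
         name = as.character(r$name %||% paste0("region_", r$region_id)),
         vertices = v, faces = f)
  })
  structure(list(regions = regions,
                 metadata = list(sex = sex, source = source)),
            class = "polygon_phantom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.polygon_phantom <- function(x, ...) {
  cat("<polygon_phantom> ", length(x$regions), " region(s), sex=",
      x$metadata$sex, "\n", sep = "")
  for (r in x$regions) {
    cat(sprintf("  [%d] %-24s %6d vertices %6d faces\n",
                r$region_id, r$name, nrow(r$vertices), nrow(r$faces)))
  }
  invisible(x)
}

region_ids <- function(phantom) {
  vapply(phantom$regions, `[[`, integer(1), "region_id")
}

get_region <- function(phantom, region_id) {
  i <- match(as.integer(region_id), region_ids(phantom))
  if (is.na(i)) stop("no region with id ", region_id)
  phantom$regions[[i]]
}

#' Tetrahedral mesh phantom
#'
#' Volume-element phantom: shared node coordinates (cm) plus 4-node elements
#' each carrying a region id.  On disk the TetGen ELE/NODE dialect is used
#' with 1-based indices; in memory indices are also 1-based (R convention).
#'
#' @param nodes numeric n x 3 matrix of coordinates (cm).
#' @param elements integer m x 4 matrix of node indices.
#' @param region_id integer vector of length m.
#' @return An object of class `tet_phantom`.  Zero-volume elements are kept
#'   but recorded in `attr(, "degenerate")` (volume below 1e-9 cm3).
#' @export
tet_phantom <- function(nodes, elements, region_id) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  elements <- as.matrix(elements); storage.mode(elements) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be n x 3")
  if (ncol(elements) != 4L) stop("elements must be m x 4")
  region_id <- as.integer(region_id)
  if (length(region_id) != nrow(elements)) {
    stop("region_id length must match element count")
  }
  if (any(elements < 1L) || any(elements > nrow(nodes))) {
    stop("element references node index out of range 1..", nrow(nodes))
  }
  vols <- tet_volumes(nodes, elements)
  # orientation normalization: report |V|; flag true degenerates
  degen <- which(abs(vols) < 1e-9)
  structure(list(nodes = nodes, elements = elements,
                 region_id = region_id, volumes = abs(vols)),
            degenerate = degen, class = "tet_phantom")
}

tet_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1], , drop = FALSE]
  b <- nodes[elements[, 2], , drop = FALSE]
  c_ <- nodes[elements[, 3], , drop = FALSE]
  d <- nodes[elements[, 4], , drop = FALSE]
  u <- b - a; v <- c_ - a; w <- d - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
   u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
   u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

#' @export
print.tet_phantom <- function(x, ...) {
  cat("<tet_phantom> ", nrow(x$nodes), " nodes, ", nrow(x$elements),
      " elements, ", length(unique(x$region_id)), " region(s)\n", sep = "")
  tab <- tapply(x$volumes, x$region_id, sum)
  for (id in names(tab)) {
    cat(sprintf("  region %s: %d elements, %.6g cm^3\n", id,
                sum(x$region_id == as.integer(id)), tab[[id]]))
  }
  invisible(x)
}

#' Total volume per region of a tetrahedral phantom
#'
#' Degenerate elements (below 1e-9 cm3) are excluded from the sums; they are
#' kept in the phantom and listed in `attr(phantom, "degenerate")` so mesher
#' defects stay visible.
#'
#' @param phantom a [tet_phantom()].
#' @return named numeric vector, cm3, names are region ids.
#' @export
tet_region_volumes <- function(phantom) {
  keep <- setdiff(seq_along(phantom$volumes), attr(phantom, "degenerate"))
  v <- tapply(phantom$volumes[keep], phantom$region_id[keep], sum)
  out <- as.numeric(v)
  names(out) <- names(v)
  out
}

#' Voxel raster phantom
#'
#' Organ-id raster on a regular grid.  `organ_ids` is an `nx x ny x nz`
#' integer array; id 0 is surrounding air.  `pitch` is the voxel pitch in
#' millimetres (the one place the package uses mm; everything else is cm).
#'
#' @param organ_ids 3-D integer array.
#' @param pitch numeric length-3, voxel pitch in mm
#'   (default `c(0.98, 0.98, 1.0)`).
#' @param origin numeric length-3, position (cm) of the low corner of voxel
#'   (1,1,1); defaults to the origin.
#' @return An object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(organ_ids, pitch = c(0.98, 0.98, 1.0),
                          origin = c(0, 0, 0)) {
  organ_ids <- as.array(organ_ids)
  if (length(dim(organ_ids)) != 3L) stop("organ_ids must be a 3-D array")
  storage.mode(organ_ids) <- "integer"
  pitch <- as.numeric(pitch)
  if (length(pitch) == 1L) pitch <- rep(pitch, 3)
  if (length(pitch) != 3L || any(pitch <= 0)) {
    stop("pitch must be 3 strictly positive values (mm)")
  }
  structure(list(dims = dim(organ_ids), pitch = pitch,
                 origin = as.numeric(origin), organ_ids = organ_ids),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat("<voxel_phantom> dims ", paste(x$dims, collapse = " x "),
      ", pitch ", paste(signif(x$pitch, 4), collapse = " x "), " mm\n",
      sep = "")
  tab <- table(x$organ_ids)
  vv <- prod(x$pitch / 10)                      # cm^3 per voxel
  for (id in names(tab)) {
    cat(sprintf("  id %s: %d voxels, %.6g cm^3\n", id, tab[[id]],
                tab[[id]] * vv))
  }
  invisible(x)
}

#' Voxel volume of one region
#'
#' Bookkeeping identity: `count(id) * dx * dy * dz`.
#'
#' @param phantom a [voxel_phantom()].
#' @param region_id integer id.
#' @return volume in cm3.
#' @export
voxel_region_volume <- function(phantom, region_id) {
  n <- sum(phantom$organ_ids == as.integer(region_id))
  n * prod(phantom$pitch / 10)
}
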