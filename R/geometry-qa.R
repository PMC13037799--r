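as_mesh <- function(region) {
  # accept either a bare mesh (vertices/faces) or a phantom region
  if (!is.list(region) || is.null(region$vertices) || is.null(region$faces)) {
    stop("expected a mesh with $vertices and $faces")
  }
  list(vertices = as.matrix(region$vertices),
       faces = matrix(as.integer(as.matrix(region$faces)), ncol = 3))
}

signed_mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Enclosed volume of a closed triangle surface
#'
#' Divergence-theorem signed tetrahedron sum.  The surface must be closed
#' (see [check_watertight()]); an inward-oriented surface yields the
#' absolute volume with attribute `inverted_orientation = TRUE`.
#'
#' @param region a mesh (`$vertices`, `$faces`) or phantom region.
#' @return volume in cm3 (attribute `inverted_orientation` logical).
#' @export
surface_volume <- function(region) {
  mesh <- as_mesh(region)
  qa <- check_watertight(mesh)
  if (!qa$closed) {
    stop("surface is not closed (", qa$boundary_edge_count,
         " boundary, ", qa$non_manifold_edge_count,
         " non-manifold edges); run check_watertight() for details")
  }
  v <- signed_mesh_volume(mesh)
  structure(abs(v), inverted_orientation = v < 0)
}

#' Convert region volume and density to mass
#'
#' @param volume cm3, > 0.
#' @param density g/cm3, > 0.
#' @return mass in kg.
#' @export
region_mass <- function(volume, density) {
  if (any(volume <= 0) || any(density <= 0)) {
    stop("volume and density must both be > 0")
  }
  volume * density / 1000
}

edge_table <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Watertightness report for one surface
#'
#' Boundary edges are edges used by exactly one face; non-manifold edges by
#' more than two.  A surface is closed iff both counts are zero.  The
#' orientation flag reports whether the signed volume is negative (inward
#' winding).
#'
#' @param region a mesh or phantom region.
#' @return list with `closed`, `boundary_edge_count`,
#'   `non_manifold_edge_count`, `inverted_orientation`.
#' @export
check_watertight <- function(region) {
  mesh <- as_mesh(region)
  tab <- edge_table(mesh$faces)
  boundary <- sum(tab == 1L)
  nonman <- sum(tab > 2L)
  list(closed = boundary == 0L && nonman == 0L,
       boundary_edge_count = as.integer(boundary),
       non_manifold_edge_count = as.integer(nonman),
       inverted_orientation = signed_mesh_volume(mesh) < 0)
}

#' Full QA report for a polygon phantom
#'
#' Per-region watertightness and (optionally) self-intersection counts.
#'
#' @param phantom a [polygon_phantom()].
#' @param self_intersections if `TRUE` (default) run the exact
#'   triangle-triangle overlap test per region.
#' @return data.frame, one row per region.
#' @export
qa_report <- function(phantom, self_intersections = TRUE) {
  rows <- lapply(phantom$regions, function(r) {
    w <- check_watertight(r)
    n_pairs <- if (self_intersections) {
      nrow(detect_self_intersections(r))
    } else NA_integer_
    data.frame(region_id = r$region_id, name = r$name,
               closed = w$closed,
               boundary_edge_count = w$boundary_edge_count,
               non_manifold_edge_count = w$non_manifold_edge_count,
               self_intersection_pair_count = n_pairs,
               inverted_orientation = w$inverted_orientation)
  })
  do.call(rbind, rows)
}

#' Detect self-intersecting triangle pairs
#'
#' Exact segment-against-triangle overlap test over bounding-box-filtered
#' candidate pairs; pairs sharing a vertex are excluded (mesh adjacency is
#' not an intersection).  Exactly coplanar overlaps are not reported; they
#' do not occur in the meshes this package generates.
#'
#' @param region a mesh or phantom region.
#' @return integer matrix with columns `tri1`, `tri2` (0 rows when clean).
#' @export
detect_self_intersections <- function(region) {
  mesh <- as_mesh(region)
  v <- mesh$vertices; f <- mesh$faces
  pairs <- tri_self_intersections(v, f)
  colnames(pairs) <- c("tri1", "tri2")
  pairs
}
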