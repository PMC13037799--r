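#' Angle-weighted vertex normals
#'
#' Per-vertex unit normals obtained by summing incident face normals
#' weighted by the face corner angle at the vertex; the standard choice for
#' offsetting because it is independent of triangulation density.
#'
#' @param mesh a mesh (`$vertices`, `$faces`), outward oriented.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- matrix(0, nrow(v), 3)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- function(p, q) {
    cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
          p[, 3] * q[, 1] - p[, 1] * q[, 3],
          p[, 1] * q[, 2] - p[, 2] * q[, 1])
  }
  fn <- cr(b - a, c_ - a)                      # area-weighted face normal
  fn <- fn / sqrt(rowSums(fn^2))
  ang <- function(p, q) {
    cosv <- rowSums(p * q) / sqrt(rowSums(p^2) * rowSums(q^2))
    acos(pmin(1, pmax(-1, cosv)))
  }
  w1 <- ang(b - a, c_ - a)
  w2 <- ang(c_ - b, a - b)
  w3 <- ang(a - c_, b - c_)
  for (k in 1:3) {
    w <- list(w1, w2, w3)[[k]]
    idx <- f[, k]
    for (d in 1:3) {
      add <- unname(tapply(fn[, d] * w, idx, sum)[
        as.character(seq_len(nrow(v)))])
      add[is.na(add)] <- 0
      n[, d] <- n[, d] + add
    }
  }
  n / sqrt(pmax(rowSums(n^2), .Machine$double.eps))
}

#' Offset a closed surface inward along vertex normals
#'
#' @param mesh outward-oriented closed mesh.
#' @param depth inward offset in cm.
#' @return mesh with the same connectivity, vertices moved inward.
#' @export
offset_surface <- function(mesh, depth) {
  n <- vertex_normals(mesh)
  mesh$vertices <- mesh$vertices - depth * n
  mesh
}

#' Extract a shell layer between two inward offsets
#'
#' Builds the radiosensitive-layer solid bounded by the inward offsets of a
#' closed surface at `depth_lo` and `depth_hi` below the outer surface
#' (e.g. the 50-100 um skin basal layer, or the full-thickness skin with
#' `depth_lo = 0`).  The result is a single watertight region whose boundary
#' has two components: the outer offset surface and the inner offset surface
#' with inverted winding, so its signed volume is the layer volume.
#'
#' @param region a closed, outward-oriented mesh or phantom region.
#' @param depth_lo,depth_hi depths below the surface in micrometres,
#'   `0 <= depth_lo < depth_hi`.
#' @param check if `TRUE`, verify the offsets did not self-intersect
#'   (exact test; quadratic, so off by default for large meshes).
#' @return a mesh for the layer solid, with attributes `outer_volume` and
#'   `inner_volume` (cm3).
#' @export
extract_shell_layer <- function(region, depth_lo, depth_hi, check = FALSE) {
  if (!(depth_lo >= 0 && depth_lo < depth_hi)) {
    stop("need 0 <= depth_lo < depth_hi (micrometres)")
  }
  mesh <- as_mesh(region)
  qa <- check_watertight(mesh)
  if (!qa$closed) stop("shell layer requires a closed surface")
  if (qa$inverted_orientation) {
    mesh <- flip_mesh(mesh)
  }
  lo_cm <- depth_lo * 1e-4
  hi_cm <- depth_hi * 1e-4
  outer <- if (lo_cm > 0) offset_surface(mesh, lo_cm) else mesh
  inner <- offset_surface(mesh, hi_cm)
  v_out <- signed_mesh_volume(outer)
  v_in <- signed_mesh_volume(inner)
  if (v_in <= 0 || v_out <= v_in) {
    stop("offset depth ", depth_hi, " um collapses the surface; ",
         "layer is thicker than the local feature size")
  }
  if (check) {
    layer_chk <- merge_meshes(outer, flip_mesh(inner))
    if (nrow(detect_self_intersections(layer_chk)) > 0) {
      stop("offsetting produced self-intersections beyond repair ",
           "tolerance; reduce depth or refine the mesh")
    }
  }
  layer <- merge_meshes(outer, flip_mesh(inner))
  structure(layer, outer_volume = v_out, inner_volume = v_in)
}

#' Uniformly scale a closed region to a target mass
#'
#' Scales about the region centroid with factor
#' `s = (target / current)^(1/3)` so the recomputed mass matches the target
#' to numerical precision.
#'
#' @param region a closed mesh or phantom region.
#' @param density g/cm3.
#' @param target_mass kg, > 0.
#' @return the scaled mesh, with attribute `scale_factor`.
#' @export
scale_to_target_mass <- function(region, density, target_mass) {
  if (target_mass <= 0) stop("target_mass must be > 0")
  mesh <- as_mesh(region)
  vol <- surface_volume(mesh)                  # errors if open
  cur <- region_mass(as.numeric(vol), density)
  s <- (target_mass / cur)^(1 / 3)
  ctr <- colMeans(mesh$vertices)
  mesh$vertices <- sweep(sweep(mesh$vertices, 2, ctr, `-`) * s, 2, ctr, `+`)
  structure(mesh, scale_factor = s)
}
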