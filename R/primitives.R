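#' Triangulated axis-aligned box surface
#'
#' @param lo,hi numeric length-3 corners (cm).
#' @return list with `vertices` (8 x 3) and `faces` (12 x 3), outward
#'   oriented.
#' @export
box_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  stopifnot(all(hi > lo))
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  dimnames(v) <- NULL
  # vertex order from expand.grid: x fastest, then y, then z
  # faces chosen outward-oriented (verified by signed volume > 0)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),    # z = lo
    c(5, 6, 8), c(5, 8, 7),    # z = hi
    c(1, 2, 6), c(1, 6, 5),    # y = lo
    c(3, 7, 8), c(3, 8, 4),    # y = hi
    c(1, 5, 7), c(1, 7, 3),    # x = lo
    c(2, 4, 8), c(2, 8, 6))    # x = hi
  list(vertices = v, faces = f)
}

#' Subdivided icosphere
#'
#' Deterministic geodesic sphere: a unit icosahedron subdivided `subdiv`
#' times with new vertices projected to the sphere, then scaled per axis
#' (an ellipsoid when `radii` differ) and translated.
#'
#' @param radii numeric length-1 or 3, semi-axes in cm.
#' @param center numeric length-3 (cm).
#' @param subdiv non-negative integer; faces = 20 * 4^subdiv.
#' @return list with `vertices` and `faces`, outward oriented.
#' @export
icosphere <- function(radii = 1, center = c(0, 0, 0), subdiv = 3) {
  if (length(radii) == 1L) radii <- rep(radii, 3)
  stopifnot(length(radii) == 3L, all(radii > 0), subdiv >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    e1 <- edge_key(f[, 1], f[, 2])
    e2 <- edge_key(f[, 2], f[, 3])
    e3 <- edge_key(f[, 3], f[, 1])
    keys <- unique(c(e1, e2, e3))
    mid_of <- setNames(seq_along(keys) + nrow(v), keys)
    pairs <- do.call(rbind, strsplit(keys, " "))
    a <- as.integer(pairs[, 1]); b <- as.integer(pairs[, 2])
    mids <- (v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m1 <- mid_of[e1]; m2 <- mid_of[e2]; m3 <- mid_of[e3]
    f <- rbind(cbind(f[, 1], m1, m3),
               cbind(f[, 2], m2, m1),
               cbind(f[, 3], m3, m2),
               cbind(m1, m2, m3))
  }
  v <- sweep(sweep(v, 2, radii, `*`), 2, center, `+`)
  dimnames(v) <- NULL; dimnames(f) <- NULL
  storage.mode(f) <- "integer"
  list(vertices = v, faces = f)
}

#' Flip the orientation of a triangle surface
#' @param mesh list with `vertices`, `faces`.
#' @return same mesh with reversed winding.
#' @export
flip_mesh <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Concatenate surfaces into one region mesh
#'
#' Used to build two-boundary solids (a shell bounded by an outer surface
#' and an inward-flipped inner surface).
#' @param ... meshes (lists with `vertices`, `faces`).
#' @return one combined mesh.
#' @export
merge_meshes <- function(...) {
  parts <- list(...)
  off <- 0L
  verts <- list(); faces <- list()
  for (p in parts) {
    verts[[length(verts) + 1L]] <- p$vertices
    faces[[length(faces) + 1L]] <- p$faces + off
    off <- off + nrow(p$vertices)
  }
  f <- do.call(rbind, faces)
  storage.mode(f) <- "integer"
  list(vertices = do.call(rbind, verts), faces = f)
}
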