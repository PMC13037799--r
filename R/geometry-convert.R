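#' Extract a region surface from a voxel phantom
#'
#' Emits the boundary faces between voxels of the region and everything
#' else, welded into a single closed triangle surface.  The enclosed volume
#' equals `count(id) * dx * dy * dz` exactly, so no voxel-shell tolerance is
#' consumed by the extraction itself.
#'
#' @param phantom a [voxel_phantom()].
#' @param region_id integer id present in the raster.
#' @return mesh (`$vertices` in cm, `$faces`), outward oriented.
#' @export
voxel_region_to_surface <- function(phantom, region_id) {
  mask <- phantom$organ_ids == as.integer(region_id)
  if (!any(mask)) stop("region id ", region_id, " not present in raster")
  d <- phantom$dims
  p <- phantom$pitch / 10                       # cm
  o <- phantom$origin
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask

  quads <- list()
  # for each axis, boundary faces where mask changes along that axis
  idx <- which(pad, arr.ind = TRUE)             # voxel cells (padded coords)
  for (axis in 1:3) {
    for (side in c(-1L, 1L)) {
      nb <- idx
      nb[, axis] <- nb[, axis] + side
      has_nb <- pad[nb]
      face_cells <- idx[!has_nb, , drop = FALSE]
      if (!nrow(face_cells)) next
      quads[[length(quads) + 1L]] <-
        cbind(face_cells, axis = axis, side = side)
    }
  }
  q <- do.call(rbind, quads)
  # build quad corner coordinates (integer lattice; padded offset -1)
  cell <- q[, 1:3, drop = FALSE] - 2L           # 0-based cell index
  axis <- q[, 4]; side <- q[, 5]
  n <- nrow(q)
  corners <- array(0L, c(n, 4, 3))
  for (r in seq_len(n)) {
    a <- axis[r]
    u <- (a %% 3L) + 1L
    v <- (u %% 3L) + 1L
    base <- cell[r, ]
    base[a] <- base[a] + (if (side[r] == 1L) 1L else 0L)
    c0 <- base; c1 <- base; c2 <- base; c3 <- base
    c1[u] <- c1[u] + 1L
    c2[u] <- c2[u] + 1L; c2[v] <- c2[v] + 1L
    c3[v] <- c3[v] + 1L
    if (side[r] == -1L) {                      # flip for outward orientation
      tmp <- c1; c1 <- c3; c3 <- tmp
    }
    corners[r, 1, ] <- c0; corners[r, 2, ] <- c1
    corners[r, 3, ] <- c2; corners[r, 4, ] <- c3
  }
  flat <- matrix(aperm(corners, c(2, 1, 3)), ncol = 3)   # 4n x 3 lattice pts
  key <- paste(flat[, 1], flat[, 2], flat[, 3])
  uk <- unique(key)
  vid <- match(key, uk)
  upts <- flat[!duplicated(key), , drop = FALSE]
  verts <- sweep(sweep(upts, 2, p, `*`), 2, o, `+`)
  i1 <- vid[seq(1, 4 * n, by = 4)]
  i2 <- vid[seq(2, 4 * n, by = 4)]
  i3 <- vid[seq(3, 4 * n, by = 4)]
  i4 <- vid[seq(4, 4 * n, by = 4)]
  faces <- rbind(cbind(i1, i2, i3), cbind(i1, i3, i4))
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  mesh <- list(vertices = verts, faces = faces)
  if (signed_mesh_volume(mesh) < 0) mesh <- flip_mesh(mesh)
  mesh
}

point_in_mesh <- function(mesh, pts) {
  # crossing parity along +z through a 1-voxel "grid": reuse the parity
  # classifier with a degenerate 1 x 1 x 1 grid per point (cheap for the
  # few containment queries nesting detection needs)
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    v <- mesh$vertices; f <- mesh$faces
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    c_ <- v[f[, 3], , drop = FALSE]
    # 2-D barycentric in xy, count plane crossings above the point
    d <- (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
      (c_[, 1] - a[, 1]) * (b[, 2] - a[, 2])
    px <- p[1] + 1.2345e-9; py <- p[2] + 2.3456e-9
    u <- ((px - a[, 1]) * (c_[, 2] - a[, 2]) -
            (c_[, 1] - a[, 1]) * (py - a[, 2])) / d
    v2 <- ((b[, 1] - a[, 1]) * (py - a[, 2]) -
             (px - a[, 1]) * (b[, 2] - a[, 2])) / d
    ok <- is.finite(u) & is.finite(v2) & u >= 0 & v2 >= 0 & (u + v2) <= 1
    if (!any(ok)) return(FALSE)
    z <- a[ok, 3] + u[ok] * (b[ok, 3] - a[ok, 3]) +
      v2[ok] * (c_[ok, 3] - a[ok, 3])
    sum(z > p[3]) %% 2L == 1L
  }, logical(1))
}

#' Voxelize a polygon or tetrahedral phantom
#'
#' Assigns each voxel the id of the region containing its center.  Where
#' regions nest, the innermost (smallest-volume containing) region wins, so
#' thin shells such as skin survive coarse rasterization.
#'
#' @param phantom a [polygon_phantom()] or [tet_phantom()].
#' @param pitch voxel pitch in mm (scalar or length 3).
#' @param margin empty border added around the bounding box, in voxels
#'   (default 0: the grid is the tight bounding box, so a pitch larger
#'   than the phantom degenerates to a single voxel).
#' @return a [voxel_phantom()] (id 0 = air/background).
#' @export
voxelize <- function(phantom, pitch, margin = 0L) {
  pitch <- as.numeric(pitch)
  if (length(pitch) == 1L) pitch <- rep(pitch, 3)
  if (any(pitch <= 0)) stop("pitch must be positive (mm)")
  p_cm <- pitch / 10
  if (inherits(phantom, "polygon_phantom")) {
    allv <- do.call(rbind, lapply(phantom$regions, `[[`, "vertices"))
  } else if (inherits(phantom, "tet_phantom")) {
    allv <- phantom$nodes
  } else stop("voxelize expects a polygon_phantom or tet_phantom")
  lo <- apply(allv, 2, min) - margin * p_cm
  hi <- apply(allv, 2, max) + margin * p_cm
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / p_cm)))
  origin <- lo
  arr <- array(0L, dims)

  if (inherits(phantom, "polygon_phantom")) {
    vols <- vapply(phantom$regions, function(r) {
      abs(signed_mesh_volume(as_mesh(r)))
    }, numeric(1))
    for (i in order(vols, decreasing = TRUE)) {
      r <- phantom$regions[[i]]
      inside <- voxelize_parity(r$vertices, r$faces, origin, p_cm, dims)
      arr[inside] <- r$region_id
    }
  } else {
    arr <- voxelize_tets(phantom, origin, p_cm, dims)
  }
  voxel_phantom(arr, pitch = pitch, origin = origin)
}

voxelize_tets <- function(phantom, origin, p_cm, dims) {
  arr <- array(0L, dims)
  nd <- phantom$nodes
  el <- phantom$elements
  centers <- lapply(1:3, function(d) origin[d] + (seq_len(dims[d]) - 0.5) *
                      p_cm[d])
  for (t in seq_len(nrow(el))) {
    vs <- nd[el[t, ], , drop = FALSE]
    lo <- pmax(ceiling((apply(vs, 2, min) - origin) / p_cm - 0.5), 1)
    hi <- pmin(floor((apply(vs, 2, max) - origin) / p_cm + 0.5), dims)
    if (any(lo > hi)) next
    gx <- centers[[1]][lo[1]:hi[1]]
    gy <- centers[[2]][lo[2]:hi[2]]
    gz <- centers[[3]][lo[3]:hi[3]]
    g <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    m <- cbind(vs[2, ] - vs[1, ], vs[3, ] - vs[1, ], vs[4, ] - vs[1, ])
    det_m <- det(m)
    if (abs(det_m) < 1e-14) next
    inv_m <- solve(m)
    bc <- sweep(g, 2, vs[1, ]) %*% t(inv_m)
    ok <- bc[, 1] >= 0 & bc[, 2] >= 0 & bc[, 3] >= 0 &
      (bc[, 1] + bc[, 2] + bc[, 3]) <= 1
    if (!any(ok)) next
    ig <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))[ok, , drop = FALSE]
    arr[ig] <- phantom$region_id[t]
  }
  arr
}

# --- tetrahedralization ----------------------------------------------------

fan_tetrahedralize <- function(mesh, apex = NULL) {
  if (is.null(apex)) apex <- colMeans(mesh$vertices)
  nv <- nrow(mesh$vertices)
  nodes <- rbind(mesh$vertices, apex)
  # swap two face vertices: an outward face plus an interior apex would
  # otherwise give a negatively oriented element
  elements <- cbind(mesh$faces[, c(2, 1, 3), drop = FALSE], nv + 1L)
  storage.mode(elements) <- "integer"
  list(nodes = nodes, elements = elements)
}

prism_tetrahedralize <- function(outer, inner) {
  # both meshes share the same face matrix (vertex correspondence);
  # each prism (outer tri, inner tri) is coned from its centroid over its
  # triangulated boundary; quads split by a min-vertex-id rule so that
  # neighbouring prisms tile the shell without gaps or overlaps
  stopifnot(identical(outer$faces, inner$faces))
  f <- outer$faces
  nv <- nrow(outer$vertices)
  nf <- nrow(f)
  nodes <- rbind(outer$vertices, inner$vertices)   # inner index = id + nv
  # prism centroids appended after
  cent <- matrix(0, nf, 3)
  for (d in 1:3) {
    cent[, d] <- (outer$vertices[f[, 1], d] + outer$vertices[f[, 2], d] +
                    outer$vertices[f[, 3], d] +
                    inner$vertices[f[, 1], d] + inner$vertices[f[, 2], d] +
                    inner$vertices[f[, 3], d]) / 6
  }
  nodes <- rbind(nodes, cent)
  tets <- vector("list", nf)
  for (t in seq_len(nf)) {
    i <- f[t, 1]; j <- f[t, 2]; k <- f[t, 3]
    ap <- 2L * nv + t                           # prism centroid node
    tri <- list(c(i, j, k))                     # outer cap (outward)
    tri[[2]] <- c(i + nv, k + nv, j + nv)       # inner cap (flipped)
    quad <- function(u, v) {
      # boundary quad over edge u->v: corners u, v, v+nv, u+nv
      if (u < v) {
        list(c(u, v, v + nv), c(u, v + nv, u + nv))
      } else {
        list(c(u, v, u + nv), c(v, v + nv, u + nv))
      }
    }
    tri <- c(tri, quad(i, j), quad(j, k), quad(k, i))
    tets[[t]] <- do.call(rbind, lapply(tri, function(tr) c(tr, ap)))
  }
  elements <- do.call(rbind, tets)
  storage.mode(elements) <- "integer"
  list(nodes = nodes, elements = elements)
}

#' Convert a polygon phantom to a tetrahedral phantom
#'
#' Regions must be closed and mutually non-intersecting (nesting allowed).
#' Leaf regions are fan-tetrahedralized about their centroid (they must be
#' star-shaped with respect to it); a region enclosing exactly one child
#' with identical mesh connectivity (offset or concentric copies, as all
#' generated phantoms provide) is decomposed into prisms between the two
#' surfaces.  Deeper constructions would need a constrained Delaunay
#' mesher, which this package deliberately does not bundle.
#'
#' @param phantom a [polygon_phantom()].
#' @param tol relative volume agreement required per region (default 0.005).
#' @return a [tet_phantom()].
#' @export
tetrahedralize <- function(phantom, tol = 0.005) {
  stopifnot(inherits(phantom, "polygon_phantom"))
  qa <- qa_report(phantom, self_intersections = FALSE)
  if (any(!qa$closed)) {
    stop("cannot tetrahedralize: open region(s): ",
         paste(qa$region_id[!qa$closed], collapse = ", "))
  }
  meshes <- lapply(phantom$regions, as_mesh)
  meshes <- lapply(meshes, function(m) {
    if (signed_mesh_volume(m) < 0) flip_mesh(m) else m
  })
  vols <- vapply(meshes, signed_mesh_volume, numeric(1))
  n <- length(meshes)
  # nesting: parent = smallest region containing this region's first vertex
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    probe <- meshes[[i]]$vertices[1, , drop = FALSE] * 0.999 +
      matrix(colMeans(meshes[[i]]$vertices), 1) * 0.001
    cand <- setdiff(which(vols > vols[i]), i)
    containing <- cand[vapply(cand, function(j) {
      point_in_mesh(meshes[[j]], probe)
    }, logical(1))]
    if (length(containing)) {
      parent[i] <- containing[which.min(vols[containing])]
    }
  }
  nodes_all <- list(); elem_all <- list(); reg_all <- list()
  offset <- 0L
  add <- function(tt, id) {
    nodes_all[[length(nodes_all) + 1L]] <<- tt$nodes
    elem_all[[length(elem_all) + 1L]] <<- tt$elements + offset
    reg_all[[length(reg_all) + 1L]] <<- rep(id, nrow(tt$elements))
    offset <<- offset + nrow(tt$nodes)
  }
  for (i in seq_len(n)) {
    id <- phantom$regions[[i]]$region_id
    children <- which(!is.na(parent) & parent == i)
    if (!length(children)) {
      tt <- fan_tetrahedralize(meshes[[i]])
      vt <- tet_volumes(tt$nodes, tt$elements)
      if (any(vt < -1e-12 * max(abs(vt)))) {
        stop("region ", id, " is not star-shaped about its centroid; ",
             "no bundled mesher can tetrahedralize it")
      }
      add(tt, id)
    } else if (length(children) == 1L &&
               identical(meshes[[i]]$faces, meshes[[children]]$faces)) {
      add(prism_tetrahedralize(meshes[[i]], meshes[[children]]), id)
    } else {
      stop("region ", id, " encloses ", length(children),
           " child region(s) without mesh correspondence; ",
           "tetrahedralization of this configuration is unsupported")
    }
  }
  ph <- tet_phantom(do.call(rbind, nodes_all), do.call(rbind, elem_all),
                    unlist(reg_all))
  # volume contract
  tv <- tet_region_volumes(ph)
  for (i in seq_len(n)) {
    id <- phantom$regions[[i]]$region_id
    children <- which(!is.na(parent) & parent == i)
    expect <- vols[i] - sum(vols[children])
    got <- tv[[as.character(id)]]
    if (abs(got - expect) > tol * expect) {
      stop("tet volume of region ", id, " off by ",
           signif(abs(got / expect - 1), 3), " relative (tol ", tol, ")")
    }
  }
  ph
}
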