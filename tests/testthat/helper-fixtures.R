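# shared in-code fixtures; everything is generated, nothing is stored

unit_cube_phantom <- function(id = 1L, name = "cube") {
  polygon_phantom(list(c(list(region_id = id, name = name), box_mesh())))
}

# cube with one quad side removed (both triangles of z = lo): 4-edge hole
holed_cube_mesh <- function() {
  m <- box_mesh()
  m$faces <- m$faces[-(1:2), , drop = FALSE]
  m
}

# two unit cubes welded across a shared face -> non-manifold edges
welded_cubes_mesh <- function() {
  a <- box_mesh(c(0, 0, 0), c(1, 1, 1))
  b <- box_mesh(c(1, 0, 0), c(2, 1, 1))
  m <- merge_meshes(a, b)
  # weld coincident vertices so the shared edges are truly shared
  key <- apply(round(m$vertices, 9), 1, paste, collapse = "/")
  uk <- unique(key)
  map <- match(key, uk)
  verts <- m$vertices[!duplicated(key), , drop = FALSE]
  faces <- matrix(map[m$faces], ncol = 3)
  storage.mode(faces) <- "integer"
  list(vertices = verts, faces = faces)
}

# two interpenetrating tetrahedra in one soup
crossed_tets_mesh <- function() {
  t1 <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                              c(0, 0, 1)),
             faces = rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  t2 <- t1
  t2$vertices <- sweep(t1$vertices, 2, c(0.15, 0.12, 0.1), `+`)
  merge_meshes(t1, t2)
}

water_slab <- function(t_cm, ny = NULL, lateral_cm = 4) {
  if (is.null(ny)) ny <- max(2L, ceiling(t_cm / 0.5))
  arr <- array(1L, c(4L, ny, 4L))
  voxel_phantom(arr, pitch = c(lateral_cm * 10 / 4, t_cm * 10 / ny,
                               lateral_cm * 10 / 4))
}

water_catalog <- function(mats = default_materials()) {
  region_catalog(data.frame(region_id = 1L, name = "slab",
                            material = "water"), mats)
}

# small deterministic test body: defaults everywhere the spec states them
# (skin thickness by sex, 50-100 um basal layer), ellipsoid scaled down so
# transport stays desk-sized
test_body <- function(...) {
  make_layered_body("male", semiaxes = c(4, 3, 5), subdiv = 3, ...)
}
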