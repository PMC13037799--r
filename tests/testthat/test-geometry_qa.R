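test_that("surface_volume: analytic solids, inversion flag, open error", {
  expect_equal(as.numeric(surface_volume(box_mesh())), 1, tolerance = 1e-12)
  s4 <- icosphere(1, subdiv = 4)
  expect_equal(as.numeric(surface_volume(s4)), 4 * pi / 3,
               tolerance = 0.005)
  # refinement converges monotonically from below
  v_by_level <- vapply(2:4, function(s) {
    as.numeric(surface_volume(icosphere(1, subdiv = s)))
  }, numeric(1))
  expect_true(all(diff(v_by_level) > 0))
  expect_true(all(v_by_level < 4 * pi / 3))

  inv <- flip_mesh(box_mesh())
  v <- surface_volume(inv)
  expect_equal(as.numeric(v), 1, tolerance = 1e-12)
  expect_true(attr(v, "inverted_orientation"))
  expect_error(surface_volume(holed_cube_mesh()), "not closed")
})

test_that("region_mass converts and validates", {
  expect_equal(region_mass(1, 1), 0.001)
  expect_equal(region_mass(15000 / 1.05, 1.05), 15)
  expect_error(region_mass(0, 1), "> 0")
  expect_error(region_mass(1, -2), "> 0")
})

test_that("watertightness detects constructed defects and passes clean meshes", {
  w <- check_watertight(box_mesh())
  expect_true(w$closed)
  expect_identical(w$boundary_edge_count, 0L)

  # cube missing one quad side: the hole loop has 4 boundary edges
  h <- check_watertight(holed_cube_mesh())
  expect_false(h$closed)
  expect_identical(h$boundary_edge_count, 4L)

  nm <- check_watertight(welded_cubes_mesh())
  expect_gt(nm$non_manifold_edge_count, 0L)
})

test_that("self-intersection detection", {
  expect_identical(nrow(detect_self_intersections(icosphere(1, subdiv = 3))),
                   0L)
  expect_gt(nrow(detect_self_intersections(crossed_tets_mesh())), 0L)
  # translated disjoint copies are clean
  a <- icosphere(1, subdiv = 2)
  b <- icosphere(1, center = c(3, 0, 0), subdiv = 2)
  expect_identical(nrow(detect_self_intersections(merge_meshes(a, b))), 0L)
})

test_that("scale_to_target_mass follows the cube-root law exactly", {
  sph <- icosphere(1, subdiv = 3)
  m0 <- region_mass(as.numeric(surface_volume(sph)), 1)
  sc <- scale_to_target_mass(sph, 1, 8 * m0)
  expect_equal(attr(sc, "scale_factor"), 2, tolerance = 1e-12)
  expect_equal(region_mass(as.numeric(surface_volume(sc)), 1), 8 * m0,
               tolerance = 1e-9)
  # identity
  sc1 <- scale_to_target_mass(sph, 1, m0)
  expect_equal(attr(sc1, "scale_factor"), 1, tolerance = 1e-12)
  expect_equal(sc1$vertices, sph$vertices, tolerance = 1e-12)
  expect_error(scale_to_target_mass(sph, 1, -1), "> 0")
  expect_error(scale_to_target_mass(holed_cube_mesh(), 1, 1), "not closed")
})

test_that("shell layers: analytic volume, nesting additivity, errors", {
  sph <- icosphere(10, subdiv = 3)
  lay <- extract_shell_layer(sph, 50, 100)
  expect_equal(as.numeric(surface_volume(lay)),
               (4 * pi / 3) * (9.995^3 - 9.990^3), tolerance = 0.02)
  expect_true(check_watertight(lay)$closed)

  # (d0,d1) + (d1,d2) == (d0,d2): shared middle surface makes it exact
  l1 <- extract_shell_layer(sph, 0, 50)
  l2 <- extract_shell_layer(sph, 50, 100)
  l12 <- extract_shell_layer(sph, 0, 100)
  expect_equal(as.numeric(surface_volume(l1)) +
                 as.numeric(surface_volume(l2)),
               as.numeric(surface_volume(l12)), tolerance = 1e-9)

  expect_error(extract_shell_layer(sph, 100, 100), "depth_lo < depth_hi")
  expect_error(extract_shell_layer(sph, 200, 100), "depth_lo < depth_hi")
  # collapsing offset: layer thicker than the sphere radius
  expect_error(extract_shell_layer(icosphere(0.1, subdiv = 2), 0, 2000),
               "collapses")
  # full-thickness male skin on the body fixture exists and is closed
  body <- test_body()
  skin <- body$regions[[2]]
  expect_true(check_watertight(skin)$closed)
})

test_that("voxel_region_to_surface volumes match the raster bookkeeping", {
  arr <- array(0L, c(3, 3, 3)); arr[2, 2, 2] <- 1L
  vp <- voxel_phantom(arr, pitch = c(1, 1, 1))
  m <- voxel_region_to_surface(vp, 1)
  expect_true(check_watertight(m)$closed)
  expect_equal(as.numeric(surface_volume(m)), 0.001, tolerance = 1e-12)

  arr2 <- array(0L, c(12, 12, 12)); arr2[2:11, 2:11, 2:11] <- 3L
  vp2 <- voxel_phantom(arr2, pitch = c(1, 1, 1))
  m2 <- voxel_region_to_surface(vp2, 3)
  expect_equal(as.numeric(surface_volume(m2)),
               1000 * 0.001, tolerance = 0.05)
  expect_error(voxel_region_to_surface(vp2, 99), "not present")
})

test_that("tetrahedralize: exact volumes, nesting, failure modes", {
  tp <- tetrahedralize(unit_cube_phantom())
  expect_equal(unname(tet_region_volumes(tp)), 1, tolerance = 0.005)

  outer <- icosphere(2, subdiv = 2)
  inner <- icosphere(1, subdiv = 2)
  ph <- polygon_phantom(list(
    c(list(region_id = 1L, name = "body"), outer),
    c(list(region_id = 2L, name = "content"), inner)))
  tp2 <- tetrahedralize(ph)
  tv <- tet_region_volumes(tp2)
  expect_equal(tv[["2"]], as.numeric(surface_volume(inner)),
               tolerance = 0.005)
  expect_equal(tv[["1"]],
               as.numeric(surface_volume(outer)) -
                 as.numeric(surface_volume(inner)), tolerance = 0.005)
  # content elements carry only the content id
  expect_setequal(unique(tp2$region_id), c(1L, 2L))

  open_ph <- polygon_phantom(list(c(list(region_id = 1L, name = "open"),
                                    holed_cube_mesh())))
  expect_error(tetrahedralize(open_ph), "open region")
})

test_that("voxelize: analytic volume, degenerate pitch, innermost wins", {
  sp <- polygon_phantom(list(c(list(region_id = 7L, name = "s"),
                               icosphere(5, subdiv = 3))))
  vp <- voxelize(sp, 1)
  expect_equal(voxel_region_volume(vp, 7), 4 * pi / 3 * 125,
               tolerance = 0.02)
  # voxelized volume converges to the mesh volume as pitch halves
  vmesh <- as.numeric(surface_volume(sp$regions[[1]]))
  errs <- vapply(c(4, 2, 1), function(p) {
    abs(voxel_region_volume(voxelize(sp, p), 7) / vmesh - 1)
  }, numeric(1))
  expect_true(errs[3] < errs[1])
  expect_lt(errs[3], 0.01)

  # pitch larger than the phantom: a handful of voxels survive
  vp_big <- voxelize(sp, 200)
  expect_lte(prod(vp_big$dims), 8)
  expect_error(voxelize(sp, -1), "positive")

  # thin skin survives coarse rasterization thanks to innermost-wins
  body <- test_body(bone = FALSE, breast = FALSE)
  vox <- voxelize(body, 2)
  expect_gt(sum(vox$organ_ids == SYNTH_IDS[["skin"]]), 0)
  expect_gt(sum(vox$organ_ids == SYNTH_IDS[["skin_sensitive"]]), 0)
})
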