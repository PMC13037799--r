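test_that("OBJ reader parses groups, resolves ids and fan-triangulates", {
  obj <- c("# fixture",
           "g skin_100",
           "v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
           "v 0 0 1", "v 1 0 1", "v 1 1 1", "v 0 1 1",
           "f 1 4 3 2", "f 5 6 7 8",     # quads: bottom and top
           "f 1 2 6 5", "f 2 3 7 6", "f 3 4 8 7", "f 4 1 5 8")
  ph <- read_obj_phantom(obj)
  expect_length(ph$regions, 1L)
  r <- ph$regions[[1]]
  expect_identical(r$region_id, 100L)
  expect_identical(nrow(r$vertices), 8L)
  expect_identical(nrow(r$faces), 12L)          # 6 quads -> 12 triangles
  # fan rule preserves vertex order: quad (1,4,3,2) -> (1,4,3), (1,3,2)
  expect_equal(r$faces[1, ], c(1L, 4L, 3L))
  expect_equal(r$faces[2, ], c(1L, 3L, 2L))
  expect_equal(as.numeric(surface_volume(r)), 1, tolerance = 1e-12)
  # explicit mapping wins over suffix parsing
  obj2 <- sub("g skin_100", "g outershell", obj)
  ph2 <- read_obj_phantom(obj2, group_to_region = c(outershell = 7L))
  expect_identical(ph2$regions[[1]]$region_id, 7L)
})

test_that("OBJ errors name the offending group / line", {
  obj <- c("g mystery", "v 0 0 0", "v 1 0 0", "v 0 1 0",
           "f 1 2 3", "f 1 2 3", "f 1 2 3", "f 1 2 3")
  expect_error(read_obj_phantom(obj), "mystery")
  bad <- c("g r_1", "v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 9")
  expect_error(read_obj_phantom(bad), "missing vertex")
})

test_that("OBJ write/read round-trips ids, counts and volumes", {
  eye <- make_stylized_eye("male", subdiv = 2)
  lines <- write_obj_phantom(eye)
  back <- read_obj_phantom(lines)
  expect_identical(vapply(back$regions, `[[`, integer(1), "region_id"),
                   vapply(eye$regions, `[[`, integer(1), "region_id"))
  for (i in seq_along(eye$regions)) {
    expect_identical(nrow(back$regions[[i]]$vertices),
                     nrow(eye$regions[[i]]$vertices))
    expect_identical(nrow(back$regions[[i]]$faces),
                     nrow(eye$regions[[i]]$faces))
    expect_equal(as.numeric(surface_volume(back$regions[[i]])),
                 as.numeric(surface_volume(eye$regions[[i]])),
                 tolerance = 1e-12)
  }
  expect_error(write_obj_phantom(
    structure(list(regions = list()), class = "polygon_phantom")),
    "no regions")
})

test_that("ELE/NODE round-trip and validation", {
  tmp_e <- withr::local_tempfile(fileext = ".ele")
  tmp_n <- withr::local_tempfile(fileext = ".node")
  tp <- tetrahedralize(unit_cube_phantom())
  write_tet_phantom(tp, tmp_e, tmp_n)
  back <- read_tet_phantom(tmp_e, tmp_n)
  expect_identical(table(back$region_id), table(tp$region_id))
  expect_equal(tet_region_volumes(back), tet_region_volumes(tp),
               tolerance = 1e-12)

  # single regular tetrahedron, edge 1 cm, region 5
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                 c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  writeLines(c("4 3 0 0",
               sprintf("%d %.17g %.17g %.17g", 1:4, nodes[, 1], nodes[, 2],
                       nodes[, 3])), tmp_n)
  writeLines(c("1 4 1", "1 1 2 3 4 5"), tmp_e)
  tp1 <- read_tet_phantom(tmp_e, tmp_n)
  expect_identical(tp1$region_id, 5L)
  expect_equal(tp1$volumes, sqrt(2) / 12, tolerance = 1e-12)

  # out-of-range node reference
  writeLines(c("1 4 1", "1 1 2 3 5 9"), tmp_e)
  expect_error(read_tet_phantom(tmp_e, tmp_n), "out of range")
  # header/record mismatch
  writeLines(c("2 4 1", "1 1 2 3 4 9"), tmp_e)
  expect_error(read_tet_phantom(tmp_e, tmp_n), "declares")
})

test_that("voxel ASCII reader enforces counts and keeps unknown ids", {
  tmp <- withr::local_tempfile(fileext = ".vox")
  writeLines("0 1 1 0", tmp)
  vp <- read_voxel_phantom(tmp, c(2, 2, 1), pitch = c(1, 1, 1))
  expect_identical(sum(vp$organ_ids == 1L), 2L)
  expect_equal(voxel_region_volume(vp, 1), 2 * 0.001)

  writeLines(paste(rep(0:2, 9), collapse = " "), tmp)   # 27 tokens
  expect_silent(read_voxel_phantom(tmp, c(3, 3, 3)))
  writeLines(paste(rep(0, 26), collapse = " "), tmp)
  expect_error(read_voxel_phantom(tmp, c(3, 3, 3)), "26")

  writeLines("0 1 1 9", tmp)
  catal <- water_catalog()
  expect_warning(read_voxel_phantom(tmp, c(2, 2, 1), catalog = catal), "9")

  # round trip preserves the raster and per-region volume exactly
  arr <- array(sample.int(3, 24, replace = TRUE) - 1L, c(2, 3, 4))
  vp2 <- voxel_phantom(arr, pitch = c(0.98, 0.98, 1))
  write_voxel_phantom(vp2, tmp)
  back <- read_voxel_phantom(tmp, c(2, 3, 4), pitch = c(0.98, 0.98, 1))
  expect_identical(back$organ_ids, vp2$organ_ids)
})

test_that("material library validates and renormalizes fractions", {
  ml <- material_library(list(
    water = list(fractions = c(H = 0.1119, O = 0.8881), density = 1)))
  expect_equal(sum(ml$water$fractions), 1, tolerance = 1e-12)
  expect_error(material_library(list(
    bad = list(fractions = c(H = 0.5, O = 0.4), density = 1))), "sum")
  ml2 <- material_library(list(
    near = list(fractions = c(H = 0.11195, O = 0.8881), density = 1)))
  expect_equal(sum(ml2$near$fractions), 1, tolerance = 1e-12)
  expect_error(material_library(list(
    neg = list(fractions = c(H = -0.1, O = 1.1), density = 1))), "negative")
  expect_error(material_library(list(
    nod = list(fractions = c(H = 0.1119, O = 0.8881), density = -1))),
    "density")
  # region catalog cross-checks materials
  expect_error(region_catalog(data.frame(region_id = 1, name = "x",
                                         material = "unobtainium"), ml),
               "unobtainium")
})
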