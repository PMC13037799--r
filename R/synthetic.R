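#' Region ids used by the stylized phantoms
#'
#' Fixed small integers so voxel rasters stay compact: 1 soft-tissue
#' interior, 2 all-skin shell, 3 skin sensitive sublayer, 4 breast-analog
#' sub-skin layer, 5 homogenized bone slab, 10 eyeball, 11 lens sensitive
#' (anterior), 12 lens insensitive (posterior).
#' @export
SYNTH_IDS <- c(interior = 1L, skin = 2L, skin_sensitive = 3L, breast = 4L,
               bone = 5L, eyeball = 10L, lens_sensitive = 11L,
               lens_insensitive = 12L)

#' Materials for the stylized phantoms
#'
#' The packaged tissue library plus a `bone_mix` entry: the whole-skeleton
#' homogenization of the packaged bone inventory for the requested sex.
#'
#' @param sex `"male"` or `"female"`.
#' @return a [material_library()].
#' @export
synth_materials <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  inv <- bone_inventory(if (sex == "male") "jpm" else "jpf")
  comp <- bone_component_compositions()
  masses <- vapply(BONE_COMPONENTS, function(cp) aggregate_skeleton(inv, cp),
                   numeric(1))
  mix <- homogenize_region(masses, comp[BONE_COMPONENTS])
  mats <- default_materials()
  entries <- lapply(names(mats), function(n) mats[[n]])
  names(entries) <- names(mats)
  entries$bone_mix <- list(fractions = mix$fractions, density = mix$density)
  material_library(entries)
}

#' Region catalog for the stylized body and eye
#'
#' @param sex `"male"` or `"female"`.
#' @return a [region_catalog()] against [synth_materials()].
#' @export
synth_catalog <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  mats <- synth_materials(sex)
  df <- data.frame(
    region_id = unname(SYNTH_IDS),
    name = names(SYNTH_IDS),
    material = c("soft_tissue", "skin", "skin", "breast", "bone_mix",
                 "eyeball", "eye_lens", "eye_lens"),
    role = c("organ", "organ", "sensitive-layer", "organ", "bone-region",
             "organ", "sensitive-layer", "organ"))
  region_catalog(df, mats)
}

#' Generate the stylized layered body
#'
#' A deterministic ellipsoidal body emulating the layered closed-surface
#' anatomy the polygon-mesh phantoms provide and voxel phantoms cannot: a
#' watertight all-skin shell of the sex-specific reference thickness, a
#' 50-100 um basal sensitive sublayer inside it, a soft-tissue interior, an
#' optional breast-analog sphere directly beneath the anterior skin, and an
#' optional homogenized bone slab.  The beam convention is AP along +y, so
#' "anterior" is the -y side.
#'
#' @param sex `"male"` (skin 1.28 mm) or `"female"` (skin 1.13 mm).
#' @param semiaxes ellipsoid semi-axes (x lateral, y AP, z vertical), cm.
#'   The default is a torso-scale body; tests use smaller bodies for speed.
#' @param skin_mm full skin thickness override, mm.
#' @param sensitive_um length-2 depth window of the basal layer, um.
#' @param breast include the breast-analog sub-skin layer (a shell of
#'   thickness `breast_mm` immediately beneath the skin, the tissue a
#'   resolution-limited voxel skin fails to cover).
#' @param breast_mm breast-analog layer thickness, mm.
#' @param bone include the bone slab.
#' @param subdiv icosphere subdivision of the body surface.
#' @return a [polygon_phantom()].
#' @export
make_layered_body <- function(sex = c("male", "female"),
                              semiaxes = c(17, 10, 30),
                              skin_mm = NULL,
                              sensitive_um = c(50, 100),
                              breast = TRUE, breast_mm = 5,
                              bone = TRUE, subdiv = 3) {
  sex <- match.arg(sex)
  if (is.null(skin_mm)) skin_mm <- if (sex == "male") 1.28 else 1.13
  skin_cm <- skin_mm / 10
  if (skin_cm >= min(semiaxes) / 20) {
    stop("skin thickness must stay below min(semiaxes)/20")
  }
  if (!(sensitive_um[1] >= 0 && sensitive_um[1] < sensitive_um[2] &&
        sensitive_um[2] * 1e-4 < skin_cm)) {
    stop("sensitive window must satisfy 0 <= lo < hi < skin thickness")
  }
  outer <- icosphere(semiaxes, subdiv = subdiv)
  skin_all <- extract_shell_layer(outer, 0, skin_mm * 1000)
  sens <- extract_shell_layer(outer, sensitive_um[1], sensitive_um[2])
  interior_depth <- skin_cm + if (breast) breast_mm / 10 else 0
  inner <- offset_surface(outer, interior_depth)

  regions <- list(
    list(region_id = SYNTH_IDS[["interior"]], name = "interior",
         vertices = inner$vertices, faces = inner$faces),
    list(region_id = SYNTH_IDS[["skin"]], name = "skin",
         vertices = skin_all$vertices, faces = skin_all$faces),
    list(region_id = SYNTH_IDS[["skin_sensitive"]], name = "skin_sensitive",
         vertices = sens$vertices, faces = sens$faces))
  if (breast) {
    sub <- extract_shell_layer(outer, skin_mm * 1000,
                               (skin_cm + breast_mm / 10) * 1e4)
    regions[[length(regions) + 1L]] <-
      list(region_id = SYNTH_IDS[["breast"]], name = "breast_analog",
           vertices = sub$vertices, faces = sub$faces)
  }
  if (bone) {
    half <- semiaxes * 0.15
    ctr <- c(0, 0.4 * semiaxes[2], 0)
    bx <- box_mesh(ctr - half, ctr + half)
    regions[[length(regions) + 1L]] <-
      list(region_id = SYNTH_IDS[["bone"]], name = "bone",
           vertices = bx$vertices, faces = bx$faces)
  }
  polygon_phantom(regions, sex = sex, source = "phantomdose stylized body")
}

half_spheroid_mesh <- function(center, semi, side = -1, nring = 12,
                               nseg = 24) {
  # closed half-spheroid: ellipsoid cap on the `side` of the y axis plus a
  # flat elliptical cap in the y = center[2] plane
  th <- seq(0, pi / 2, length.out = nring + 1L)      # polar from cap plane
  ph <- seq(0, 2 * pi, length.out = nseg + 1L)[-1]
  verts <- list(); nv <- 0L
  ring_idx <- list()
  for (i in seq_along(th)) {
    if (i == length(th)) {                          # pole
      verts[[i]] <- matrix(c(0, side * semi[2], 0), 1)
      ring_idx[[i]] <- nv + 1L
      nv <- nv + 1L
    } else {
      r <- cos(th[i]); y <- side * sin(th[i])
      verts[[i]] <- cbind(semi[1] * r * cos(ph), semi[2] * y,
                          semi[3] * r * sin(ph))
      ring_idx[[i]] <- nv + seq_len(nseg)
      nv <- nv + nseg
    }
  }
  # cap center vertex
  verts[[length(verts) + 1L]] <- matrix(c(0, 0, 0), 1)
  capc <- nv + 1L
  v <- do.call(rbind, verts)
  v <- sweep(v, 2, center, `+`)
  faces <- list()
  for (i in seq_len(length(th) - 1L)) {
    a <- ring_idx[[i]]
    b <- ring_idx[[i + 1L]]
    if (length(b) == 1L) {                          # triangles to pole
      faces[[i]] <- cbind(a, c(a[-1], a[1]), b)
    } else {
      a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
      faces[[i]] <- rbind(cbind(a, a2, b2), cbind(a, b2, b))
    }
  }
  # cap fan
  a <- ring_idx[[1]]
  faces[[length(faces) + 1L]] <- cbind(a, capc, c(a[-1], a[1]))
  f <- do.call(rbind, faces)
  storage.mode(f) <- "integer"
  mesh <- list(vertices = v, faces = f)
  if (signed_mesh_volume(mesh) < 0) mesh <- flip_mesh(mesh)
  mesh
}

#' Generate the stylized eye
#'
#' A spherical eyeball scaled so its mesh mass matches the sex-specific
#' target (15 g male / 12 g female), containing a lens modeled as an oblate
#' spheroid near the anterior pole, split at its equatorial plane into an
#' anterior sensitive and posterior insensitive half.  The two lens halves
#' are scaled jointly so the recomputed lens mass (sensitive + insensitive)
#' matches its target (0.4 g male / 0.3 g female).  Anterior is -y, matching
#' the AP beam convention.
#'
#' @param sex `"male"` or `"female"`.
#' @param eyeball_kg,lens_kg target masses (kg); defaults by sex.
#' @param subdiv eyeball icosphere subdivision.
#' @return a [polygon_phantom()] with regions eyeball (10),
#'   lens_sensitive (11), lens_insensitive (12).
#' @export
make_stylized_eye <- function(sex = c("male", "female"),
                              eyeball_kg = NULL, lens_kg = NULL,
                              subdiv = 3) {
  sex <- match.arg(sex)
  mats <- default_materials()
  if (is.null(eyeball_kg)) eyeball_kg <- if (sex == "male") 0.015 else 0.012
  if (is.null(lens_kg)) lens_kg <- if (sex == "male") 0.0004 else 0.0003
  rho_eye <- mats$eyeball$density
  rho_lens <- mats$eye_lens$density

  ball <- icosphere(1.5, subdiv = subdiv)
  ball <- scale_to_target_mass(ball, rho_eye, eyeball_kg)
  r_eye <- (3 * signed_mesh_volume(ball) / (4 * pi))^(1 / 3)

  # lens: oblate spheroid, thickness axis along y, anterior of center
  semi <- c(0.45, 0.20, 0.45)
  lens_center <- c(0, -r_eye + 0.30 + semi[2], 0)
  ant <- half_spheroid_mesh(lens_center, semi, side = -1)
  post <- half_spheroid_mesh(lens_center, semi, side = +1)
  v_tot <- signed_mesh_volume(ant) + signed_mesh_volume(post)
  s <- (lens_kg * 1000 / rho_lens / v_tot)^(1 / 3)
  rescale <- function(m) {
    m$vertices <- sweep(sweep(m$vertices, 2, lens_center, `-`) * s,
                        2, lens_center, `+`)
    m
  }
  ant <- rescale(ant); post <- rescale(post)
  regions <- list(
    list(region_id = SYNTH_IDS[["eyeball"]], name = "eyeball",
         vertices = ball$vertices, faces = ball$faces),
    list(region_id = SYNTH_IDS[["lens_sensitive"]], name = "lens_sensitive",
         vertices = ant$vertices, faces = ant$faces),
    list(region_id = SYNTH_IDS[["lens_insensitive"]],
         name = "lens_insensitive",
         vertices = post$vertices, faces = post$faces))
  polygon_phantom(regions, sex = sex, source = "phantomdose stylized eye")
}

#' Perforate the voxelized skin
#'
#' Emulates the resolution-limited voxel skin that cannot fully enclose the
#' body: a seeded-random fraction of skin voxels is reassigned to the
#' underlying tissue (the first non-skin, non-air id stepping inward, i.e.
#' along the dominant axis toward the raster centroid; falling back to the
#' interior id), so the tissue beneath is exposed at those positions.
#'
#' @param phantom a [voxel_phantom()] containing a skin region.
#' @param hole_fraction fraction of skin voxels to reassign, in `[0, 1)`.
#' @param seed integer seed (deterministic holes).
#' @param skin_ids raster ids treated as skin (default: all-skin and
#'   sensitive-layer ids of the stylized body).
#' @param fallback_id id used when no tissue lies behind (default interior).
#' @return the perforated [voxel_phantom()].
#' @export
make_perforated_voxel_skin <- function(phantom, hole_fraction, seed = 1L,
                                       skin_ids = c(SYNTH_IDS[["skin"]],
                                                    SYNTH_IDS[["skin_sensitive"]]),
                                       fallback_id = SYNTH_IDS[["interior"]]) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (!(hole_fraction >= 0 && hole_fraction < 1)) {
    stop("hole_fraction must be in [0, 1)")
  }
  arr <- phantom$organ_ids
  skin_vox <- which(arr %in% skin_ids)
  if (!length(skin_vox)) stop("phantom has no skin region to perforate")
  if (hole_fraction == 0) return(phantom)
  set.seed(seed)
  holes <- sample(skin_vox, round(hole_fraction * length(skin_vox)))
  d <- dim(arr)
  idx <- arrayInd(holes, d)
  ctr <- (d + 1) / 2
  for (r in seq_len(nrow(idx))) {
    pos <- idx[r, ]
    delta <- ctr - pos
    ax <- which.max(abs(delta))
    step <- sign(delta[ax])
    if (step == 0) step <- 1
    newid <- fallback_id
    p <- pos
    for (s in seq_len(60L)) {
      p[ax] <- p[ax] + step
      if (p[ax] < 1L || p[ax] > d[ax]) break
      v <- arr[p[1], p[2], p[3]]
      if (!v %in% skin_ids) {
        if (v != 0L) newid <- v
        break
      }
    }
    arr[idx[r, 1], idx[r, 2], idx[r, 3]] <- newid
  }
  voxel_phantom(arr, pitch = phantom$pitch, origin = phantom$origin)
}

#' Load a packaged data fixture
#'
#' @param name one of `jpm_masses`, `jpf_masses`, `jpm_bone`, `jpf_bone`,
#'   `reference_masses`, `wt_icrp103`.
#' @return a data.frame with the fixture, values exactly as printed.
#' @export
load_fixture <- function(name) {
  name <- match.arg(name, c("jpm_masses", "jpf_masses", "jpm_bone",
                            "jpf_bone", "reference_masses", "wt_icrp103"))
  rd <- function(f) {
    read.delim(system.file("extdata", f, package = "phantomdose",
                           mustWork = TRUE),
               comment.char = "#", stringsAsFactors = FALSE)
  }
  switch(name,
    jpm_masses = rd("jpm_masses.tsv"),
    jpf_masses = rd("jpf_masses.tsv"),
    jpm_bone = rd("jpm_bone.tsv"),
    jpf_bone = rd("jpf_bone.tsv"),
    wt_icrp103 = rd("wt_icrp103.tsv"),
    reference_masses = {
      m <- rd("jpm_masses.tsv")[, c("organ", "average")]
      f <- rd("jpf_masses.tsv")[, c("organ", "average")]
      names(m)[2] <- "male_average"
      names(f)[2] <- "female_average"
      merge(m, f, by = "organ", all = TRUE)
    })
}
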