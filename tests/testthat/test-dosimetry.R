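test_that("fluence-spectrum dose: closed form, zero fluence, mass cancellation", {
  cst <- dose_constants()
  # flat mu_en/rho of 0.003 m2/kg (0.03 cm2/g) via a custom one-element table
  tabs <- data.frame(element = "H", E = c(0.5, 2),
                     mu_pe = 0, mu_incoh = 0, mu_pair = 0,
                     mu_en = c(0.03, 0.03))
  edges <- c(0.999, 1.001)                     # single bin around 1 MeV
  res <- bone_component_dose_lowE(1, edges, c(H = 1), mass_kg = 0.5,
                                  tables = tabs, bin_energies = 1)
  expect_equal(res$dose_Gy, 1 * 0.003 * 1 * cst$c, tolerance = 1e-9)
  expect_equal(res$dose_Gy, 4.80653e-16, tolerance = 1e-4)

  expect_equal(bone_component_dose_lowE(0, edges, c(H = 1), 1,
                                        tables = tabs)$dose_Gy, 0)

  # the dose is independent of M_a (it cancels between Eq. 1 and Eq. 2)
  r1 <- bone_component_dose_lowE(2, edges, c(H = 1), 0.001, tables = tabs)
  r2 <- bone_component_dose_lowE(2, edges, c(H = 1), 10, tables = tabs)
  expect_equal(r1$dose_Gy, r2$dose_Gy)
  expect_equal(r2$ED_MeV / r1$ED_MeV, 10 / 0.001, tolerance = 1e-9)

  expect_error(bone_component_dose_lowE(c(1, 2), edges, c(H = 1), 1,
                                        tables = tabs), "bins")
})

test_that("multi-bin spectrum equals an independently coded quadrature", {
  set.seed(4)
  edges <- fluence_bins(1.0, cutoff = 0.01)
  nb <- length(edges) - 1
  spec <- runif(nb)
  mats <- default_materials()
  res <- bone_component_dose_lowE(spec, edges, mats$active_marrow, 1)
  # oracle: plain loop, same integrand, written independently
  mid <- sqrt(edges[-1] * edges[-(nb + 1)])
  acc <- 0
  for (b in seq_len(nb)) {
    acc <- acc + spec[b] *
      mixture_mu_en(mats$active_marrow, mid[b], unit = "m2/kg") * mid[b]
  }
  expect_equal(res$dose_Gy, acc * dose_constants()$c, tolerance = 1e-12)
})

test_that("high-energy partition: unit conversion, symmetry, conservation", {
  cst <- dose_constants()
  r <- bone_component_dose_highE(1, c(am = 1))
  expect_equal(r$dose_Gy, 1.602176634e-13, tolerance = 1e-12)

  r2 <- bone_component_dose_highE(10, c(a = 0.3, b = 0.3))
  expect_equal(unname(r2$ED_MeV["a"]), unname(r2$ED_MeV["b"]))
  set.seed(8)
  m <- runif(4)
  r3 <- bone_component_dose_highE(7.5, m)
  expect_equal(sum(r3$ED_MeV), 7.5, tolerance = 1e-12)
  # identical mass-specific dose for every component
  expect_equal(unname(r3$ED_MeV * cst$c / m), rep(r3$dose_Gy, 4),
               tolerance = 1e-12)
  expect_error(bone_component_dose_highE(1, c(0, 0)), "> 0")
})

test_that("whole-body mass weighting against a brute-force oracle", {
  inv <- bone_inventory("jpm")
  doses <- setNames(rep(3.5, 20), inv$region)
  expect_equal(whole_body_component_dose(doses, inv, "active_marrow"), 3.5)

  toy <- inv
  set.seed(12)
  d <- setNames(runif(20), inv$region)
  got <- whole_body_component_dose(d, inv, "endosteum")
  oracle <- 0; wsum <- 0
  for (i in seq_len(20)) {
    oracle <- oracle + d[[inv$region[i]]] * inv$endosteum[i]
    wsum <- wsum + inv$endosteum[i]
  }
  expect_equal(got, oracle / wsum, tolerance = 1e-12)
  expect_gte(got, min(d[inv$endosteum > 0]))
  expect_lte(got, max(d[inv$endosteum > 0]))

  expect_error(whole_body_component_dose(d[-1], inv, "active_marrow"),
               "missing dose")
})

test_that("two-region hand example", {
  inv <- bone_inventory("jpm")[1:20, ]
  # (D, M) = (1, 1) and (3, 1) -> 2, emulated through a synthetic inventory
  df <- data.frame(region = c("A", "B"),
                   active_marrow = c(1, 1), inactive_marrow = 0,
                   hard_bone = c(1, 1), endosteum = 0)
  df <- rbind(df, data.frame(region = letters[1:18], active_marrow = 0,
                             inactive_marrow = 0, hard_bone = 0.01,
                             endosteum = 0))
  inv2 <- bone_inventory(df)
  expect_equal(whole_body_component_dose(c(A = 1, B = 3), inv2,
                                         "active_marrow"), 2)
})

test_that("organ dose scaling and equivalent dose weights", {
  mats <- default_materials()
  vp <- water_slab(2)
  tal <- run_transport(vp, water_catalog(mats), mats,
                       beam(0.1, 2000, batches = 10, seed = 5))
  d <- organ_absorbed_dose(tal)
  expect_gt(d$dose_pGycm2, 0)
  # doubling the mass at fixed deposit halves the dose
  d2 <- organ_absorbed_dose(tal, masses = setNames(tal$regions$mass * 2,
                                                   as.character(tal$regions$id)))
  expect_equal(d2$dose_pGycm2, d$dose_pGycm2 / 2, tolerance = 1e-12)
  expect_error(organ_absorbed_dose(tal, masses = setNames(0, "1")), "> 0")

  expect_equal(equivalent_dose(5, "photon"), 5)
  expect_equal(equivalent_dose(5, "electron"), 5)
  expect_error(equivalent_dose(5, "neutron"), "arg")
})

test_that("effective dose: normalization, symmetry, toy weighting", {
  w <- tissue_weighting()
  expect_equal(sum(w$weights), 1, tolerance = 1e-6)
  tissues <- c(setdiff(names(w$weights), "remainder"), w$remainder_tissues)
  flat <- setNames(rep(4.2, length(tissues)), tissues)
  expect_equal(effective_dose(flat, flat, w), 4.2, tolerance = 1e-12)
  expect_equal(effective_dose(flat * 0 + 2, flat * 0, w), 1,
               tolerance = 1e-12)

  toy <- list(weights = c(a = 0.5, b = 0.3, c = 0.2),
              remainder_tissues = character(0))
  d <- c(a = 1, b = 2, c = 3)
  expect_equal(effective_dose(d, d, toy), 1.7, tolerance = 1e-12)
  # linearity and permutation invariance over equally weighted tissues
  toy2 <- list(weights = c(a = 0.5, b = 0.25, c = 0.25),
               remainder_tissues = character(0))
  expect_equal(effective_dose(c(a = 1, b = 5, c = 9), c(a = 1, b = 5, c = 9),
                              toy2),
               effective_dose(c(a = 1, b = 9, c = 5), c(a = 1, b = 9, c = 5),
                              toy2))
  expect_error(effective_dose(d[-1], d, toy), "missing weighted")
})
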