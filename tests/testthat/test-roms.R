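test_that("Kawakita-type force has the jamming boundary and printed form", {
  expect_equal(kawakita_force(0.33, a = 0.765, b = 61.39, rho_c = 0.33,
                              ref_geom), 0)
  # unit-checked arithmetic oracle: D mm, b 1/GPa -> kN
  F <- kawakita_force(0.85, a = 0.765, b = 61.39, rho_c = 0.33, ref_geom)
  oracle <- pi * 7.94^2 * (0.85 - 0.33) /
    (4 * 0.06139 * (0.85 * (0.765 - 1) + 0.33)) / 1000
  expect_equal(F, oracle, tolerance = 1e-12)
  expect_equal(F, 3.22, tolerance = 1e-3)

  # strictly increasing in density on the feasible interval
  rho <- seq(0.34, 1.3, length.out = 100)
  expect_true(all(diff(kawakita_force(rho, 0.765, 61.39, 0.33, ref_geom)) > 0))

  expect_error(kawakita_force(0.30, 0.765, 61.39, 0.33, ref_geom),
               class = "tabletrom_domain_error")
  expect_error(kawakita_force(1.5, 0.765, 61.39, 0.33, ref_geom),
               class = "tabletrom_domain_error")
})

test_that("elastic recovery interpolates between onset and full compaction", {
  expect_equal(elastic_recovery(0.334, 0.597, 0.334, 0.472), 0)
  expect_equal(elastic_recovery(1, 0.597, 0.334, 0.472), 0.597)
  expect_equal(elastic_recovery(0.85, 0.597, 0.334, 0.472),
               0.597 * ((0.85 - 0.334) / 0.666)^0.472, tolerance = 1e-12)
  expect_equal(elastic_recovery(0.85, 0.597, 0.334, 0.472), 0.529,
               tolerance = 1e-3)
  # below-onset convention: zero recovery, with a message
  expect_message(out <- elastic_recovery(0.2, 0.597, 0.334, 0.472))
  expect_equal(out, 0)
})

test_that("out-of-die density composes with recovery", {
  expect_equal(out_of_die_density(0.9, 0), 0.9)
  expect_equal(out_of_die_density(0.9, 0.1), 0.81)
  rho <- seq(0.4, 0.99, length.out = 30)
  eps <- elastic_recovery(rho, 0.597, 0.334, 0.472)
  expect_true(all(out_of_die_density(rho, eps) < rho))
  expect_error(out_of_die_density(0.9, 1), class = "tabletrom_domain_error")
})

test_that("Leuenberger strength rises from zero to the zero-porosity maximum", {
  expect_equal(leuenberger_strength(0.51, 5.90, 0.51), 0)
  expect_equal(leuenberger_strength(1, 5.90, 0.51), 5.90)
  expect_equal(leuenberger_strength(0.85, 5.90, 0.51),
               5.90 * (1 - (0.15 / 0.49) * exp(0.34)), tolerance = 1e-12)
  expect_equal(leuenberger_strength(0.85, 5.90, 0.51), 3.362,
               tolerance = 1e-3)
  expect_error(leuenberger_strength(0.4, 5.90, 0.51),
               class = "tabletrom_domain_error")
})

test_that("the packing surface collapses to p4 in the unimodal limits", {
  p <- reference_parameters()$weight
  X <- seq(0, 1, 0.1)
  expect_equal(packing_fraction(X, 0, p$p4, p$q1, p$q2), rep(p$p4, 11))
  expect_equal(packing_fraction(0, X, p$p4, p$q1, p$q2), rep(p$p4, 11))

  # arithmetic oracle at (0.3, 0.7)
  expect_equal(packing_fraction(0.3, 0.7, 0.367, -6.08, 7.33),
               0.367 * (7.33 * 0.3 + 1) /
                 (-6.08 * 0.3 * 0.7 + 7.33 * 0.3 + 1), tolerance = 1e-12)
  expect_equal(packing_fraction(0.3, 0.7, 0.367, -6.08, 7.33), 0.611,
               tolerance = 1e-3)

  # with the negative interaction coefficient, phi >= p4 on the unit square
  g <- expand.grid(X = seq(0, 1, 0.05), Y = seq(0, 1, 0.05))
  phi <- packing_fraction(g$X, g$Y, p$p4, p$q1, p$q2)
  expect_true(all(phi >= p$p4 - 1e-12))
})

test_that("tablet weight is the packing model times fill mass", {
  batch <- tibble::tibble(ribbon_density = 0.8, alpha = 1, lambda1 = 300,
                          k1 = 2, lambda2 = 900, k2 = 5)
  # alpha = 1: packing covariate X = 0, phi collapses to p4
  W <- tablet_weight(batch, p4 = 0.367, q1 = -6.08, q2 = 7.33,
                     geom = ref_geom, t_fill = 7.9957, rho_t = 1.558)
  expect_equal(W, 0.367 * 1.558 * 0.8 * volume_fill(ref_geom, 7.9957),
               tolerance = 1e-12)
  # linear in fill volume: pick the dosing position that doubles V_fill
  V1 <- volume_fill(ref_geom, 7.9957)
  t2 <- (2 * V1 - volume_cap(ref_geom) / 2) / (pi * 7.94^2 / 4)
  W2 <- tablet_weight(batch, 0.367, -6.08, 7.33, ref_geom,
                      t_fill = t2, rho_t = 1.558)
  expect_equal(W2 / W, 2, tolerance = 1e-9)
  # increasing in ribbon density
  batch2 <- dplyr::mutate(batch, ribbon_density = 0.9)
  expect_gt(tablet_weight(batch2, 0.367, -6.08, 7.33, ref_geom, 8, 1.558),
            tablet_weight(batch, 0.367, -6.08, 7.33, ref_geom, 8, 1.558))
})

test_that("the Brouwers reference packing behaves at its limits", {
  expect_equal(brouwers_packing(1, 0.5, phi_rp = 0.64, C = 0.2), 0.64)
  u <- seq(0.2, 1, 0.1)
  al <- seq(0, 1, 0.1)
  g <- expand.grid(u = u, a = al)
  expect_equal(brouwers_packing(g$u, g$a, 0.64, C = 0),
               rep(0.64, nrow(g)))
  phi <- brouwers_packing(g$u, g$a, 0.64, C = 0.25)
  expect_true(all(phi >= 0.64 - 1e-12))
})
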