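test_that("the granule-batch fixture matches the tabulated parameters", {
  b <- granule_batches()
  expect_equal(nrow(b), 6)
  expect_equal(b$ribbon_density,
               c(0.640, 0.613, 0.739, 0.708, 0.803, 0.770))
  expect_equal(b$alpha, c(0.54, 0.57, 0.46, 0.58, 0.44, 0.50))
  expect_equal(b$lambda1, c(524, 518, 541, 517, 546, 533))
  expect_equal(b$k2, c(5.32, 5.43, 4.98, 5.46, 4.89, 5.15))
  # batch (60 bar, 2 mm) and (90 bar, 2 mm) identification
  expect_equal(b$ribbon_density[b$roll_pressure_bar == 60 & b$roll_gap_mm == 2],
               0.739)
  expect_equal(b$ribbon_density[b$roll_pressure_bar == 90 & b$roll_gap_mm == 2],
               0.803)
  # means are recomputed from (lambda, k), printed values kept as metadata
  expect_equal(b$mu_gsd, b$alpha * b$mu1 + (1 - b$alpha) * b$mu2)
  expect_true(all(c("mu1_printed_um", "mu_gsd_printed_um") %in% names(b)))
})

test_that("setpoint windows and condition expansion give 24 conditions", {
  r <- press_setpoint_ranges()
  expect_equal(nrow(r), 6)
  expect_equal(unlist(r[r$batch == 1, -1], use.names = FALSE),
               c(7.0, 8.5, 2.5, 3.0))
  expect_equal(unlist(r[r$batch == 5, -1], use.names = FALSE),
               c(8.0, 9.0, 3.5, 4.0))

  cond <- campaign_conditions()
  expect_equal(nrow(cond), 24)
  expect_equal(sum(cond$batch == 3), 4)
  # thicknesses stay inside each batch's window
  joined <- dplyr::inner_join(cond, r, by = "batch")
  expect_true(all(joined$t_in_die >= joined$t_in_die_min &
                    joined$t_in_die <= joined$t_in_die_max))
  # four distinct target densities per batch
  chain <- predict_tablet_cqas(cond)
  spread <- tapply(chain$rho_in_die, chain$batch,
                   function(x) diff(range(x)))
  expect_true(all(spread > 0.1))
})

test_that("simulated campaigns are reproducible with calibrated weight noise", {
  cond <- campaign_conditions()
  c1 <- simulate_campaign(cond, tablets_per_condition = 100, seed = 5)
  c2 <- simulate_campaign(cond, tablets_per_condition = 100, seed = 5)
  expect_identical(c1, c2)
  c3 <- simulate_campaign(cond, tablets_per_condition = 100, seed = 6)
  expect_false(identical(c1$W_mg, c3$W_mg))

  expect_equal(nrow(c1), 2400)
  # per-condition weight RSD close to the 1.6% noise model
  rsd <- c1 |>
    dplyr::group_by(condition_id) |>
    dplyr::summarise(rsd = stats::sd(W_mg) / mean(W_mg))
  expect_true(all(rsd$rsd > 0.012 & rsd$rsd < 0.020))

  # zero noise everywhere reproduces the deterministic chain exactly
  c0 <- simulate_campaign(cond, tablets_per_condition = 2,
                          weight_rsd = 0, obs_rsd = 0, seed = 1)
  chain <- predict_tablet_cqas(cond)
  per <- c0[c0$tablet == 1, ]
  expect_equal(per$W_mg, chain$W_mg)
  expect_equal(per$F_punch_kN, chain$F_punch_kN)

  # provenance records the generator settings
  prov <- attr(c1, "provenance")
  expect_equal(prov$seed, 5)
  expect_equal(prov$weight_rsd, 0.016)
})

test_that("campaign files round-trip and reject malformed data", {
  cond <- campaign_conditions()
  camp <- simulate_campaign(cond, tablets_per_condition = 3, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_campaign(camp, tmp)
  back <- read_campaign(tmp)
  expect_equal(nrow(back), nrow(camp))
  expect_equal(back$W_mg, camp$W_mg, tolerance = 1e-12)

  bad <- camp
  bad$W_mg[4] <- -1
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, tmp2)
  expect_error(read_campaign(tmp2), regexp = "row\\(s\\) 4",
               class = "tabletrom_domain_error")

  expect_error(read_campaign(withr::local_tempfile()),
               class = "tabletrom_domain_error")
  expect_error(write_campaign(camp[, -6], tmp),
               class = "tabletrom_domain_error")
})

test_that("summaries derive densities and strength from raw measurements", {
  cond <- campaign_conditions()
  camp <- simulate_campaign(cond, tablets_per_condition = 50, seed = 8)
  s <- summarize_campaign(camp)
  expect_equal(nrow(s), 24)
  expect_equal(unique(s$n), 50)
  chain <- predict_tablet_cqas(cond)
  # condition means track the noise-free chain closely
  expect_lt(max(rel_err(s$W_mg, chain$W_mg)), 0.01)
  expect_lt(max(rel_err(s$rho_in_die, chain$rho_in_die)), 0.01)
  expect_lt(max(rel_err(s$F_punch_kN, chain$F_punch_kN)), 0.05)
  # back-computing strength from noisy hardness/thickness records carries a
  # small Jensen gap; hold it to 5% where the strength is appreciable and
  # 0.15 MPa everywhere
  big <- chain$sigma_t_mpa > 1
  expect_lt(max(rel_err(s$sigma_t_mpa[big], chain$sigma_t_mpa[big])), 0.05)
  expect_lt(max(abs(s$sigma_t_mpa - chain$sigma_t_mpa)), 0.15)
})

test_that("packing is maximal near a small-mode fraction of 0.7", {
  # sweep alpha at a fixed mode size ratio under the reference coefficients
  p <- reference_parameters()$weight
  alpha <- seq(0, 1, 0.01)
  ratio <- 0.3
  X <- (1 - alpha) * (1 - ratio^3)
  phi <- packing_fraction(X, alpha, p$p4, p$q1, p$q2)
  expect_gt(alpha[which.max(phi)], 0.6)
  expect_lt(alpha[which.max(phi)], 0.8)
})
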