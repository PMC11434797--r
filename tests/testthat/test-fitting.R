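test_that("AIC and R^2 follow their definitions", {
  expect_equal(aic_score(sse = 10, n = 10, np = 3), 6)  # ln(1) = 0
  expect_equal(aic_score(sse = 10 * exp(2), n = 10, np = 3), 26)
  expect_warning(val <- aic_score(0, 5, 2))
  expect_identical(val, -Inf)
  expect_error(aic_score(10, 0, 1), class = "tabletrom_domain_error")

  obs <- c(1, 2, 3, 4)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(rep(mean(obs), 4), obs), 0)
  expect_error(r_squared(1, 1), class = "tabletrom_domain_error")
  expect_error(r_squared(c(1, 2), c(3, 3)), class = "tabletrom_domain_error")
})

test_that("AIC ranking is invariant under uniform unit rescaling", {
  set.seed(7)
  for (case in 1:100) {
    k <- sample(3:8, 1)
    n <- sample(10:40, 1)
    sse <- runif(k, 0.01, 50)
    np <- sample(1:16, k, replace = TRUE)
    aic <- mapply(aic_score, sse, n, np)
    c2 <- runif(1, 1e-3, 1e3)^2
    aic_scaled <- mapply(aic_score, c2 * sse, n, np)
    expect_equal(order(aic), order(aic_scaled))
    # and the shift is the same for every model: n ln(c^2)
    expect_equal(aic_scaled - aic, rep(n * log(c2), k))
  }
})

test_that("the SSE objective is exact at the truth and rejects infeasibility", {
  truth <- noiseless_conditions()
  obj <- rom_objective(truth, "force", pair = c(7, 7))
  th_true <- c(18.50, 0.765, 27.69, 8.73, 0.33, 21.38, 10, 2.39, 61.39)
  expect_lt(obj$fn(th_true), 1e-12)

  # single-observation squared error
  one <- truth[1, ]
  one$F_punch_kN <- one$F_punch_kN + 2
  obj1 <- rom_objective(one, "force", pair = c(7, 7))
  expect_equal(obj1$fn(th_true), 4, tolerance = 1e-9)

  # uniform rescaling of observations and predictions scales SSE by c^2:
  # predictions are rescaled through b (force is proportional to 1/b)
  th_half_b <- th_true
  th_half_b[9] <- th_true[9] / 2 # doubles every predicted force
  doubled <- truth
  doubled$F_punch_kN <- 2 * doubled$F_punch_kN + 1 # offset to make SSE > 0
  obj2 <- rom_objective(doubled, "force", pair = c(7, 7))
  expect_equal(obj2$fn(th_half_b), nrow(truth) * 1^2, tolerance = 1e-9)

  # infeasible jamming density (rho_c above the data) is rejected as Inf
  th_bad <- th_true
  th_bad[5] <- 0.99 # corner rho_c close to 1
  th_bad[4] <- 90   # asymptote high too
  expect_identical(obj$fn(th_bad), Inf)

  # pairs outside the library are refused
  expect_error(rom_objective(truth, "force", pair = c(7, 3)),
               class = "tabletrom_domain_error")
})

test_that("fitting a constant-variant pair recovers constants exactly", {
  # campaign generated from a constant (9,9) force coupling
  p <- reference_parameters()
  p$force$a_surface <- list(variant = 9, p4 = 0.70)
  p$force$rho_c_surface <- list(variant = 9, p4 = 0.35)
  truth <- predict_tablet_cqas(campaign_conditions(params = p), params = p)
  ctl <- fit_control(pop_size = 40, generations = 30, n_starts = 10,
                     n_jitter = 5, n_cycles = 4, n_rounds = 1,
                     maxit_local = 500)
  fit <- fit_rom(truth, "force", pair = c(9, 9), control = ctl, seed = 5)
  expect_true(fit$feasible)
  expect_lt(fit$sse, 1e-8)
  expect_equal(fit$theta[["s1.p4"]], 0.70, tolerance = 1e-3)
  expect_equal(fit$theta[["s2.p4"]], 0.35, tolerance = 1e-3)
  expect_equal(fit$theta[["b"]], 61.39, tolerance = 1e-3)
  expect_equal(fit$np, 3L)

  # determinism: same seed, same data -> identical result
  fit2 <- fit_rom(truth, "force", pair = c(9, 9), control = ctl, seed = 5)
  expect_identical(fit$theta, fit2$theta)
  expect_identical(fit$sse, fit2$sse)
})

test_that("fit results store a self-consistent AIC and tidy/glance views", {
  truth <- noiseless_conditions()
  camp <- simulate_campaign(campaign_conditions(), tablets_per_condition = 10,
                            seed = 3)
  dat <- summarize_campaign(camp)
  ctl <- fit_control(pop_size = 30, generations = 20, n_starts = 8,
                     n_jitter = 4, n_cycles = 3, n_rounds = 1,
                     maxit_local = 300)
  fit <- fit_rom(dat, "weight", control = ctl, seed = 9)
  expect_true(fit$feasible)
  expect_equal(fit$aic, aic_score(fit$sse, fit$n, fit$np))
  expect_equal(fit$np, 3L)
  expect_gt(fit$r_squared, 0.9)

  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_equal(gl$sse, fit$sse)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("model selection ranks by AIC with documented tie-breaks", {
  # library of one: that pair ranks first trivially
  camp <- simulate_campaign(campaign_conditions(), tablets_per_condition = 10,
                            seed = 3)
  dat <- summarize_campaign(camp)
  ctl <- fit_control(pop_size = 30, generations = 20, n_starts = 8,
                     n_jitter = 4, n_cycles = 3, n_rounds = 1,
                     maxit_local = 300)
  lib1 <- model_library()[7, ]
  sel <- select_rom(dat, "force", library = lib1, control = ctl, seed = 2)
  expect_equal(nrow(sel), 1)
  expect_equal(c(sel$variant1, sel$variant2),
               c(lib1$variant1, lib1$variant2))

  # a small library containing the generating pair plus simpler and more
  # complex alternatives: the generating structure should win on AIC
  lib <- dplyr::filter(model_library(),
                       (variant1 == 7 & variant2 == 7) |
                         (variant1 == 8 & variant2 == 8) |
                         (variant1 == 9 & variant2 == 9) |
                         (variant1 == 4 & variant2 == 4))
  camp2 <- simulate_campaign(campaign_conditions(),
                             tablets_per_condition = 100, seed = 23)
  dat2 <- summarize_campaign(camp2)
  ctl2 <- fit_control(pop_size = 60, generations = 50, n_starts = 20,
                      n_jitter = 8, n_cycles = 6, n_rounds = 1,
                      maxit_local = 1000)
  sel2 <- select_rom(dat2, "force", library = lib, control = ctl2, seed = 4)
  expect_true(all(diff(sel2$aic) >= 0))
  top <- sel2[1, ]
  # the winner reproduces the generating surface values closely even if a
  # different structure edges out on AIC
  sv <- fitted_surface_values(top$fit[[1]])
  tv <- surface_values(reference_rom("force"), granule_batches())
  expect_lt(max(rel_err(sv$a, tv$a)), 0.05)

  rep5 <- report_ranking(sel2, top = 3)
  expect_equal(nrow(rep5), 3)
  expect_named(rep5, c("variant1", "variant2", "np", "sse", "r_squared",
                       "aic"))
})
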