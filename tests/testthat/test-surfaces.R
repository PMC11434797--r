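test_that("normalization maps bounds to 0 and infinity and is monotone", {
  expect_equal(normalize_variable(0.3, lb = 0.3, ub = 1, r = 7), 0)
  expect_equal(normalize_variable(0.65, lb = 0.3, ub = 1, r = 1), 1)
  # ribbon density of the densest reference batch under the force exponent
  expect_equal(normalize_variable(0.803, lb = 0.566, ub = 1, r = 10),
               ((0.803 - 0.566) / (1 - 0.803))^10, tolerance = 1e-12)
  expect_equal(normalize_variable(0.803, lb = 0.566, ub = 1, r = 10),
               6.36, tolerance = 3e-3)

  x <- seq(0.57, 0.99, length.out = 50)
  expect_true(all(diff(normalize_variable(x, 0.566, 1, r = 0.37)) > 0))

  # below-bound and above-bound violations signal distinct conditions
  expect_error(normalize_variable(0.5, 0.566, 1), class = "tabletrom_domain_error")
  err <- tryCatch(normalize_variable(1.0, 0.566, 1), error = identity)
  expect_s3_class(err, "tabletrom_overflow_error")
})

test_that("the nine constrained variants carry the printed parameter counts", {
  counts <- vapply(1:9, function(v) variant_spec(v)$n_parameters, integer(1))
  expect_equal(counts, c(9L, 7L, 7L, 5L, 7L, 5L, 5L, 3L, 1L))
  expect_equal(variant_spec(8)$zeroed, c("p2", "p3", "q2", "q3"))
  expect_true(variant_spec(8)$exponents_fixed)
  expect_false(variant_spec(7)$exponents_fixed)
  expect_equal(variant_spec(9)$n_free_coeffs, 1L)
  expect_error(variant_spec(10), class = "tabletrom_domain_error")

  # variants refuse nonzero masked coefficients
  expect_error(rational_surface(7, p2 = 1, p1 = 1, p4 = 1, q1 = 1),
               class = "tabletrom_domain_error")
})

test_that("surface evaluation honours corners and limit algebra", {
  s <- rational_surface(1, p1 = 15, p2 = 10, p3 = 5, p4 = 10,
                        q1 = 1, q2 = 2, q3 = 4)
  expect_equal(eval_surface(s, 0, 0), 10)        # p4
  expect_equal(eval_surface(s, Inf, Inf), 15)    # p1/q1
  expect_equal(eval_surface(s, 0, Inf), 5 / 4)   # p3/q3
  expect_equal(eval_surface(s, Inf, 0), 10 / 2)  # p2/q2
  expect_equal(eval_surface(s, 1, 1), 40 / 8)

  # boundary profiles agree with direct evaluation and corner values
  fX0 <- surface_limit(s, "X=0")
  expect_equal(fX0(2), (5 * 2 + 10) / (4 * 2 + 1))
  fXi <- surface_limit(s, "X=Inf")
  expect_equal(fXi(3), (15 * 3 + 10) / (1 * 3 + 2))
  expect_equal(fXi(0), 10 / 2)
  expect_equal(surface_limit(s, "Y=Inf")(0), 5 / 4)

  # a constant variant is constant on every edge, including both infinite
  s9 <- rational_surface(9, p4 = 0.334)
  for (edge in c("X=0", "X=Inf", "Y=0", "Y=Inf")) {
    expect_equal(surface_limit(s9, edge)(c(0, 1, 7)), rep(0.334, 3))
  }
  expect_equal(eval_surface(s9, Inf, Inf), 0.334)
})

test_that("zeroing coefficients commutes with evaluation (mask/eval)", {
  set.seed(101)
  X <- runif(20, 0, 5)
  Y <- runif(20, 0, 5)
  for (v in 2:9) {
    spec <- variant_spec(v)
    coefs <- setNames(runif(7, 0.1, 3), c("p1", "p2", "p3", "p4",
                                          "q1", "q2", "q3"))
    coefs[spec$zeroed] <- 0
    sv <- do.call(rational_surface, c(list(variant = v), as.list(coefs)))
    s1 <- do.call(rational_surface, c(list(variant = 1), as.list(coefs)))
    expect_equal(eval_surface(sv, X, Y), eval_surface(s1, X, Y))
  }
})

test_that("the model library holds exactly the 25 retained pairs", {
  lib <- model_library()
  expect_equal(nrow(lib), 25)
  expect_equal(nrow(dplyr::distinct(lib)), 25)
  expect_equal(9 * 9, 81) # full pair space for reference

  expected <- rbind(cbind(1:8, 1:8), cbind(1:8, 9), cbind(9, 1:9))
  expect_setequal(paste(lib$variant1, lib$variant2),
                  paste(expected[, 1], expected[, 2]))
  expect_true(tabletrom:::pair_in_library(7, 7))
  expect_false(tabletrom:::pair_in_library(7, 3))
  expect_true(tabletrom:::pair_in_library(9, 3))
})

test_that("pair parameter counts include shared exponents and constants", {
  expect_equal(n_parameters(7, 7, n_constants = 1), 9L)
  expect_equal(n_parameters(4, 9, n_constants = 1), 7L)
  expect_equal(n_parameters(1, 1, n_constants = 0), 16L)
  # exponents are fixed only when both members fix them
  expect_equal(n_parameters(2, 9, n_constants = 1), 9L)
  expect_equal(n_parameters(3, 9, n_constants = 1), 9L) # exponents stay free
  expect_equal(n_parameters(6, 9, n_constants = 1), 7L)
  expect_equal(n_parameters(9, 9, n_constants = 1), 3L)
  expect_error(n_parameters(0, 3), class = "tabletrom_domain_error")
})
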