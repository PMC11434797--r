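# Constrained estimation of coupled-model parameters and AIC-based model
# selection over the 25-pair rational-surface library.

#' Sum-of-squares fit metrics
#'
#' `aic_score()` computes the Akaike information criterion used for model
#' ranking, \eqn{AIC = n \ln(SSE/n) + 2 N_p}; because only differences
#' matter, rescaling all observations and predictions by a common factor
#' shifts every model's AIC equally and leaves the ranking unchanged.
#' `r_squared()` is the coefficient of determination about the observed
#' mean.
#'
#' @param sse Sum of squared errors (units of the attribute squared).
#' @param n Number of observations.
#' @param np Number of fitted parameters.
#'
#' @return A single number. `aic_score()` returns `-Inf` with a warning for
#'   a perfect fit (`sse = 0`).
#' @export
#'
#' @examples
#' aic_score(sse = 10 * exp(2) * 10 / 10, n = 10, np = 3)
aic_score <- function(sse, n, np) {
  if (n < 1) stop_domain("`n` must be at least 1.")
  if (sse < 0) stop_domain("`sse` must be non-negative.")
  if (sse == 0) {
    warn("Perfect fit (SSE = 0): AIC is -Inf.")
    return(-Inf)
  }
  n * log(sse / n) + 2 * np
}

#' @rdname aic_score
#' @param predicted,observed Numeric vectors of equal length (`n >= 2` for
#'   `r_squared()`).
#' @export
r_squared <- function(predicted, observed) {
  if (length(observed) < 2) stop_domain("Need at least two observations.")
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop_domain("Zero total variance: R^2 is undefined.")
  1 - sum((observed - predicted)^2) / tss
}

#' Constraint configuration for coupled-model fitting
#'
#' Box bounds, sign/order constraints and nonlinear feasibility settings
#' applied during estimation. Per attribute, the active constraints are:
#' force -- positive coefficients, exponents in (0, 10\], and the in-die
#' feasibility predicates \eqn{\rho_{in-die} > \rho_c} and
#' \eqn{\rho_{in-die}(a-1) + \rho_c > 0} at every observation; recovery --
#' order constraints \eqn{0 < p_i < q_i} (with \eqn{q_4 = 1}) so the
#' zero-porosity recovery stays in (0, 1), and an onset density in
#' `(rho_bar_c, 1)`; strength -- positive coefficients and
#' \eqn{\rho_{c,\sigma} > \rho_{c,\epsilon}}; weight -- `p4 > 0`, `q1 < 0`.
#'
#' @param rho_c_rib Critical ribbon density (ribbon normalization lower
#'   bound).
#' @param rho_bar_c Lower bound of the compaction critical relative
#'   density, applied to the force model's jamming-density surface and to
#'   the recovery onset density. Default 0.3, just below the
#'   direct-compression jamming density of this formulation (0.33); the
#'   granule jamming density is known to exceed the direct-compression one.
#' @param rho_c_eps_ref Recovery onset density used in the strength
#'   constraint `rho_c_sigma > rho_c_eps`.
#' @param coef_min,coef_max Box bounds for positive surface coefficients.
#' @param exp_min,exp_max Box bounds for normalization exponents.
#' @param b_range Box bounds for the Kawakita pressure parameter, 1/GPa.
#' @param n_range Box bounds for the recovery exponent.
#'
#' @return A list of class `rom_constraints`.
#' @export
rom_constraints <- function(rho_c_rib = 0.566, rho_bar_c = 0.3,
                            rho_c_eps_ref = 0.334,
                            coef_min = 1e-6, coef_max = 200,
                            exp_min = 0.05, exp_max = 10,
                            b_range = c(1, 200), n_range = c(0.05, 5)) {
  structure(
    list(rho_c_rib = rho_c_rib, rho_bar_c = rho_bar_c,
         rho_c_eps_ref = rho_c_eps_ref, coef_min = coef_min,
         coef_max = coef_max, exp_min = exp_min, exp_max = exp_max,
         b_range = b_range, n_range = n_range),
    class = "rom_constraints"
  )
}

#' Optimizer settings for coupled-model fitting
#'
#' The estimation runs in three stages: (1) a population-based global
#' search (real-coded genetic algorithm over the box, Latin-hypercube
#' initialised), (2) local constrained refinement of the stage-1 best
#' (Nelder-Mead then bounded Levenberg-Marquardt), and (3) multi-start
#' global polishing (bounded Levenberg-Marquardt from fresh Latin-hypercube
#' starts). Nonlinear data-dependent predicates are enforced by rejection:
#' the reported SSE of an infeasible point is infinite, while the search
#' itself uses a graded penalty so the stages remain informative.
#'
#' @param pop_size,generations Genetic-algorithm population and generation
#'   counts.
#' @param mutation_prob,mutation_sd Per-gene mutation probability and
#'   relative step (fraction of the box width).
#' @param n_elites Number of distinct genetic-algorithm elites carried into
#'   local refinement.
#' @param n_starts Multi-start count for stage 3.
#' @param n_jitter Restarts jittered around the incumbent best in stage 3.
#' @param n_cycles Maximum simplex/Levenberg-Marquardt alternations in the
#'   final valley-descent stage.
#' @param n_rounds Independent global-search rounds; later rounds restart
#'   the population stage to escape a poor basin and stop early once a
#'   round no longer improves the objective.
#' @param maxit_local Iteration cap for each local refinement.
#' @param ftol Relative function tolerance for local refinement.
#' @param penalty Penalty scale for constraint violations during search.
#'
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(pop_size = 120, generations = 120,
                        mutation_prob = 0.25, mutation_sd = 0.1,
                        n_elites = 6, n_starts = 50, n_jitter = 20,
                        n_cycles = 12, n_rounds = 2, maxit_local = 4000,
                        ftol = 1e-12, penalty = 1e6) {
  structure(
    list(pop_size = pop_size, generations = generations,
         mutation_prob = mutation_prob, mutation_sd = mutation_sd,
         n_elites = n_elites, n_starts = n_starts, n_jitter = n_jitter,
         n_cycles = n_cycles, n_rounds = n_rounds,
         maxit_local = maxit_local, ftol = ftol, penalty = penalty),
    class = "fit_control"
  )
}

# theta layout -----------------------------------------------------------

surface_coef_bounds <- function(cqa, which_surface, coef, cons) {
  lower <- cons$coef_min
  upper <- cons$coef_max
  if (cqa == "recovery") {
    if (which_surface == 1 && coef == "p4") upper <- 1 - 1e-6
    if (which_surface == 2 && coef == "p4") {
      lower <- cons$rho_bar_c
      upper <- 1 - 1e-6
    }
  }
  if (cqa == "force" && which_surface == 2 && coef == "p4") {
    lower <- cons$rho_bar_c
    upper <- 1 - 1e-6
  }
  c(lower, upper)
}

theta_spec <- function(cqa, variant1, variant2, cons) {
  if (cqa == "weight") {
    return(tibble::tibble(
      name = c("p4", "q1", "q2"),
      lower = c(0.05, -50, 0),
      upper = c(0.95, -1e-6, 50)
    ))
  }
  rows <- list()
  for (s in 1:2) {
    v <- if (s == 1) variant1 else variant2
    free <- setdiff(coef_names, variant_spec(v)$zeroed)
    for (cf in free) {
      b <- surface_coef_bounds(cqa, s, cf, cons)
      rows[[length(rows) + 1]] <- tibble::tibble(
        name = sprintf("s%d.%s", s, cf), lower = b[1], upper = b[2]
      )
    }
  }
  if (pair_exponents_free(variant1, variant2)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      name = c("rX", "rY"), lower = cons$exp_min, upper = cons$exp_max
    )
  }
  if (cqa == "force") {
    rows[[length(rows) + 1]] <- tibble::tibble(
      name = "b", lower = cons$b_range[1], upper = cons$b_range[2]
    )
  }
  if (cqa == "recovery") {
    rows[[length(rows) + 1]] <- tibble::tibble(
      name = "n", lower = cons$n_range[1], upper = cons$n_range[2]
    )
  }
  dplyr::bind_rows(rows)
}

theta_to_parts <- function(theta, cqa, variant1, variant2) {
  get <- function(nm, default = 0) {
    if (nm %in% names(theta)) unname(theta[[nm]]) else default
  }
  if (cqa == "weight") {
    return(list(p4 = get("p4"), q1 = get("q1"), q2 = get("q2")))
  }
  mk <- function(s, v) {
    args <- lapply(coef_names, function(cf) get(sprintf("s%d.%s", s, cf)))
    names(args) <- coef_names
    do.call(rational_surface, c(list(variant = v), args))
  }
  list(
    surface1 = mk(1, variant1), surface2 = mk(2, variant2),
    rX = get("rX", 1), rY = get("rY", 1),
    constant = switch(cqa, force = get("b", NA), recovery = get("n", NA),
                      NULL)
  )
}

# prediction with graded feasibility ------------------------------------

eval_surface_raw <- function(s, X, Y) {
  num <- s$p1 * X * Y + s$p2 * X + s$p3 * Y + s$p4
  den <- s$q1 * X * Y + s$q2 * X + s$q3 * Y + 1
  list(value = num / den, den = den)
}

# Returns list(pred, violation): violation == 0 iff all nonlinear
# feasibility predicates hold at every observation.
rom_predict_theta <- function(theta, cqa, variant1, variant2, data, cons) {
  viol <- 0
  hinge <- function(x) sum(pmax(x, 0))
  if (cqa == "weight") {
    p <- theta_to_parts(theta, cqa, variant1, variant2)
    den <- p$q1 * data$X_pack * data$Y_pack + p$q2 * data$X_pack + 1
    viol <- viol + hinge(1e-6 - den)
    pred <- p$p4 * (p$q2 * data$X_pack + 1) / den *
      data$rho_t * data$ribbon_density * data$V_fill
    return(list(pred = pred, violation = viol))
  }
  p <- theta_to_parts(theta, cqa, variant1, variant2)
  X <- data$x_base^p$rX
  Y <- data$y_base^p$rY
  e1 <- eval_surface_raw(p$surface1, X, Y)
  e2 <- eval_surface_raw(p$surface2, X, Y)
  viol <- viol + hinge(1e-6 - e1$den) + hinge(1e-6 - e2$den)
  if (cqa == "force") {
    a <- e1$value
    rho_c <- e2$value
    g1 <- data$rho_in_die - rho_c
    g2 <- data$rho_in_die * (a - 1) + rho_c
    viol <- viol + hinge(1e-6 - g1) + hinge(1e-6 - g2) +
      hinge(cons$rho_bar_c - rho_c)
    pred <- pi * data$D^2 * g1 / (4 * (p$constant / 1000) * g2) / 1000
    pred[g1 <= 0 | g2 <= 0] <- NA_real_
    return(list(pred = pred, violation = viol))
  }
  if (cqa == "recovery") {
    s1 <- p$surface1
    # order constraints 0 < p_i < q_i (q4 = 1) keep eps0 in (0, 1)
    viol <- viol + hinge(c(s1$p1 - s1$q1, s1$p2 - s1$q2, s1$p3 - s1$q3,
                           s1$p4 - 1))
    eps0 <- e1$value
    rho_ce <- e2$value
    viol <- viol + hinge(cons$rho_bar_c - rho_ce) + hinge(rho_ce - 1 + 1e-6)
    g <- data$rho_in_die - rho_ce
    viol <- viol + hinge(1e-6 - g)
    frac <- pmax(g, 0) / (1 - pmin(rho_ce, 1 - 1e-9))
    pred <- data$rho_in_die * (1 - eps0 * frac^p$constant)
    return(list(pred = pred, violation = viol))
  }
  # strength
  sigma0 <- e1$value
  rho_cs <- e2$value
  viol <- viol + hinge(cons$rho_c_eps_ref - rho_cs) +
    hinge(rho_cs - data$rho_tablet + 1e-6) + hinge(-sigma0)
  rc <- pmin(rho_cs, 1 - 1e-9)
  pred <- sigma0 * (1 - (1 - data$rho_tablet) / (1 - rc) *
                      exp(data$rho_tablet - rc))
  list(pred = pred, violation = viol)
}

observation_column <- c(weight = "W_mg", force = "F_punch_kN",
                        recovery = "rho_tablet", strength = "sigma_t_mpa")

prepare_fit_data <- function(data, cqa, cons, geom, rho_t, weight_params) {
  data <- add_gsd_means(tibble::as_tibble(data))
  obs_col <- observation_column[[cqa]]
  if (!obs_col %in% names(data)) {
    stop_domain(sprintf("Fitting `%s` needs column `%s`.", cqa, obs_col))
  }
  data$obs <- data[[obs_col]]
  data$D <- geom$D
  data$rho_t <- rho_t
  if (cqa == "weight") {
    data <- add_packing_covariates(data)
    data$V_fill <- volume_fill(geom, data$t_fill)
    return(data)
  }
  data$x_base <- (data$ribbon_density - cons$rho_c_rib) /
    (1 - data$ribbon_density)
  if (any(data$x_base <= 0)) {
    stop_domain("Ribbon densities must exceed the critical ribbon density.")
  }
  if (cqa == "strength") {
    if (!"phi" %in% names(data)) {
      data$phi <- batch_packing_fraction(data, weight_params)
    }
    data$y_base <- (data$phi - weight_params$phi_min) /
      (weight_params$phi_max - data$phi)
    data$y_base <- pmax(data$y_base, 0)
  } else {
    ub_um <- geom$D * 1000 / 6
    if (any(data$mu_gsd >= ub_um)) {
      stop_overflow("Mean granule size at or above D/6.")
    }
    data$y_base <- data$mu_gsd / (ub_um - data$mu_gsd)
  }
  data
}

#' Constrained fitting objective for a model pair
#'
#' Builds the sum-of-squared-errors objective used by [fit_rom()], exposed
#' for inspection and testing. `fn(theta)` enforces the nonlinear
#' feasibility predicates by rejection (infinite SSE); `fn_penalized(theta)`
#' is the graded-penalty version the optimizer stages minimise.
#'
#' @param data Condition-level fitting data (see [summarize_campaign()]).
#' @param cqa One of `"weight"`, `"force"`, `"recovery"`, `"strength"`.
#' @param pair Integer pair of surface variants (ignored for `"weight"`).
#' @param constraints A [rom_constraints()].
#' @param geom A [tool_geometry()].
#' @param rho_t True density, g/cc.
#' @param weight_params Packing-surface coefficients used to compute the
#'   strength covariate (default: reference values).
#' @param penalty Penalty scale for the graded objective.
#'
#' @return A list with `fn`, `fn_penalized`, `residuals(theta)`, the theta
#'   layout `spec` (name, lower, upper), and the prepared `data`.
#' @export
rom_objective <- function(data, cqa, pair = c(7, 7),
                          constraints = rom_constraints(),
                          geom = tool_geometry(), rho_t = 1.558,
                          weight_params = reference_parameters()$weight,
                          penalty = 1e6) {
  cqa <- match.arg(cqa, names(observation_column))
  v1 <- if (cqa == "weight") NA_integer_ else as.integer(pair[1])
  v2 <- if (cqa == "weight") NA_integer_ else as.integer(pair[2])
  if (cqa != "weight" && !pair_in_library(v1, v2)) {
    stop_domain(sprintf("Pair (%d, %d) is not in the model library.", v1, v2))
  }
  data <- prepare_fit_data(data, cqa, constraints, geom, rho_t, weight_params)
  spec <- theta_spec(cqa, v1, v2, constraints)
  n <- nrow(data)

  predict_theta <- function(theta) {
    theta <- setNames(as.numeric(theta), spec$name)
    rom_predict_theta(theta, cqa, v1, v2, data, constraints)
  }
  fn <- function(theta) {
    out <- predict_theta(theta)
    if (out$violation > 0 || any(!is.finite(out$pred))) return(Inf)
    sum((out$pred - data$obs)^2)
  }
  fn_penalized <- function(theta) {
    out <- predict_theta(theta)
    if (out$violation > 0 || any(!is.finite(out$pred))) {
      return(penalty * (1 + out$violation))
    }
    sum((out$pred - data$obs)^2)
  }
  residuals_fn <- function(theta) {
    out <- predict_theta(theta)
    if (out$violation > 0 || any(!is.finite(out$pred))) {
      return(rep(sqrt(penalty * (1 + out$violation) / n), n))
    }
    out$pred - data$obs
  }
  list(fn = fn, fn_penalized = fn_penalized, residuals = residuals_fn,
       predict = predict_theta, spec = spec, data = data,
       cqa = cqa, variant1 = v1, variant2 = v2)
}

# profile initialization -------------------------------------------------

# Two-step start for surface pairs without a shared scalar constant
# (tensile strength): first profile the two base-model parameters batch by
# batch (well-conditioned 2-parameter fits), then fit the surfaces and
# exponents to those per-batch targets. Returns candidate theta starts.
profile_init_strength <- function(obj, cons, control) {
  data <- obj$data
  key <- paste(signif(data$x_base, 12), signif(data$y_base, 12))
  groups <- split(seq_len(nrow(data)), key)
  targets <- purrr::map(groups, function(idx) {
    rho <- data$rho_tablet[idx]
    obs <- data$obs[idx]
    res <- function(p) {
      rc <- min(p[2], min(rho) - 1e-6)
      p[1] * (1 - (1 - rho) / (1 - rc) * exp(rho - rc)) - obs
    }
    best <- NULL
    for (start_rc in c(0.95, 0.8, 0.5) * min(rho)) {
      fit <- try(minpack.lm::nls.lm(
        par = c(max(obs) * 1.5, max(start_rc, cons$rho_c_eps_ref)),
        lower = c(1e-3, cons$rho_c_eps_ref),
        upper = c(1e3, min(rho) - 1e-6),
        fn = res,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
    if (is.null(best)) return(NULL)
    c(x = data$x_base[idx[1]], z = data$y_base[idx[1]],
      sigma0 = best$par[1], rho_cs = best$par[2])
  }) |> purrr::compact()
  if (length(targets) < 3) return(NULL)
  tg <- do.call(rbind, targets)
  spec <- obj$spec
  exps_free <- pair_exponents_free(obj$variant1, obj$variant2)
  r_grid <- if (exps_free) c(0.25, 0.5, 1, 2, 4, 8) else 1
  cands <- list()
  for (rX in r_grid) {
    for (rZ in r_grid) {
      c1 <- solve_surface_coefs(obj$variant1, tg[, "x"]^rX, tg[, "z"]^rZ,
                                tg[, "sigma0"])
      c2 <- solve_surface_coefs(obj$variant2, tg[, "x"]^rX, tg[, "z"]^rZ,
                                tg[, "rho_cs"])
      if (is.null(c1) || is.null(c2)) next
      for (a1 in c1) {
        for (a2 in c2) {
          theta <- numeric(nrow(spec))
          names(theta) <- spec$name
          for (nm in names(a1)) theta[paste0("s1.", nm)] <- a1[[nm]]
          for (nm in names(a2)) theta[paste0("s2.", nm)] <- a2[[nm]]
          if (exps_free) {
            theta["rX"] <- rX
            theta["rY"] <- rZ
          }
          theta <- pmin(pmax(theta, spec$lower), spec$upper)
          cands[[length(cands) + 1]] <-
            list(par = unname(theta), val = obj$fn_penalized(theta))
        }
      }
    }
  }
  if (!length(cands)) return(NULL)
  ord <- order(purrr::map_dbl(cands, "val"))
  purrr::map(cands[ord[seq_len(min(6, length(ord)))]], "par")
}

# Exact (or least-squares) coefficients of one surface variant through a
# set of (X, Z, target) points: the defining relation
#   p1 XZ + p2 X + p3 Z + p4 - t (q1 XZ + q2 X + q3 Z) = t
# is linear in the free coefficients, so the minimum-norm solution comes
# from an SVD; a one-dimensional null space is line-searched for the most
# interior (sign-feasible) exact solution.
solve_surface_coefs <- function(variant, X, Z, targets) {
  free <- setdiff(coef_names, variant_spec(variant)$zeroed)
  pcols <- list(p1 = X * Z, p2 = X, p3 = Z, p4 = rep(1, length(X)))
  qcols <- list(q1 = -targets * X * Z, q2 = -targets * X, q3 = -targets * Z)
  cols <- c(pcols[intersect(names(pcols), free)],
            qcols[intersect(names(qcols), free)])
  A <- do.call(cbind, cols)
  sv <- svd(A, nu = nrow(A), nv = ncol(A))
  tolr <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tolr)
  Ur <- sv$u[, seq_len(r), drop = FALSE]
  Vr <- sv$v[, seq_len(r), drop = FALSE]
  x0 <- drop(Vr %*% (drop(crossprod(Ur, targets)) / sv$d[seq_len(r)]))
  out <- list(setNames(x0, names(cols)))
  if (r < ncol(A)) {
    null_dir <- sv$v[, ncol(A), drop = TRUE]
    ts <- seq(-100, 100, length.out = 801)
    margins <- vapply(ts, function(t) min(x0 + t * null_dir), numeric(1))
    best_t <- ts[which.max(margins)]
    if (best_t != 0) {
      out[[2]] <- setNames(x0 + best_t * null_dir, names(cols))
    }
  }
  out
}

# optimizer stages -------------------------------------------------------

lhs_sample <- function(n, lower, upper) {
  d <- length(lower)
  u <- lhs::randomLHS(n, d)
  sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
}

ga_stage <- function(fn, lower, upper, control) {
  d <- length(lower)
  pop <- control$pop_size
  P <- lhs_sample(pop, lower, upper)
  f <- apply(P, 1, fn)
  width <- upper - lower
  for (gen in seq_len(control$generations)) {
    newP <- matrix(NA_real_, pop, d)
    best_idx <- which.min(f)
    newP[1, ] <- P[best_idx, ] # elitism
    for (i in 2:pop) {
      # tournament selection of two parents
      pick <- function() {
        cand <- sample.int(pop, 2)
        cand[which.min(f[cand])]
      }
      pa <- P[pick(), ]
      pb <- P[pick(), ]
      w <- runif(d)
      child <- w * pa + (1 - w) * pb
      mut <- runif(d) < control$mutation_prob
      child[mut] <- child[mut] +
        rnorm(sum(mut), 0, control$mutation_sd * width[mut])
      newP[i, ] <- pmin(pmax(child, lower), upper)
    }
    P <- newP
    f <- apply(P, 1, fn)
  }
  ord <- order(f)
  k <- min(length(ord), max(1, control$n_elites))
  list(par = P[ord[1], ], value = f[ord[1]],
       elites = P[ord[seq_len(k)], , drop = FALSE])
}

lm_polish <- function(start, residuals_fn, lower, upper, control) {
  fit <- try(
    minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = residuals_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = min(control$maxit_local, 1024L), ftol = control$ftol,
        ptol = control$ftol
      )
    ),
    silent = TRUE
  )
  if (inherits(fit, "try-error")) return(NULL)
  as.numeric(fit$par)
}

run_fit_stages <- function(obj, control, extra_starts = NULL) {
  lower <- obj$spec$lower
  upper <- obj$spec$upper
  width <- upper - lower
  best_par <- NULL
  best_val <- Inf
  consider <- function(par) {
    if (is.null(par)) return(invisible(NULL))
    par <- pmin(pmax(par, lower), upper)
    val <- obj$fn_penalized(par)
    if (val < best_val) {
      best_par <<- par
      best_val <<- val
    }
    invisible(NULL)
  }
  refine <- function(par) {
    par <- pmin(pmax(par, lower), upper)
    nm <- optim(par, function(p) {
      obj$fn_penalized(pmin(pmax(p, lower), upper))
    }, method = "Nelder-Mead",
    control = list(maxit = control$maxit_local, reltol = control$ftol))
    consider(nm$par)
    consider(lm_polish(pmin(pmax(nm$par, lower), upper),
                       obj$residuals, lower, upper, control))
    consider(lm_polish(par, obj$residuals, lower, upper, control))
  }
  descend <- function() {
    # valley descent: alternate simplex and Levenberg-Marquardt until the
    # objective stops improving (long curved valleys in over-parameterized
    # pairs defeat a single local pass)
    for (cycle in seq_len(control$n_cycles)) {
      prev <- best_val
      refine(best_par)
      if (best_val <= 0 ||
          prev - best_val < control$ftol * max(prev, 1e-30)) {
        break
      }
    }
  }
  for (round in seq_len(control$n_rounds)) {
    round_start <- best_val
    # stage 1: population-based global search
    s1 <- ga_stage(obj$fn_penalized, lower, upper, control)
    consider(s1$par)
    # stage 2: local constrained refinement of the stage-1 elites and any
    # structured initial guesses
    for (i in seq_len(nrow(s1$elites))) refine(s1$elites[i, ])
    if (round == 1) for (st in extra_starts %||% list()) refine(st)
    # stage 3: multi-start global polishing
    starts <- lhs_sample(control$n_starts, lower, upper)
    for (i in seq_len(nrow(starts))) {
      consider(lm_polish(starts[i, ], obj$residuals, lower, upper, control))
    }
    for (i in seq_len(control$n_jitter)) {
      jit <- best_par + rnorm(length(best_par), 0, 0.05 * width)
      consider(lm_polish(pmin(pmax(jit, lower), upper),
                         obj$residuals, lower, upper, control))
    }
    descend()
    if (best_val <= 0) break
    if (round > 1 &&
        round_start - best_val < 1e-3 * max(round_start, 1e-30)) {
      break
    }
  }
  setNames(best_par, obj$spec$name)
}

#' Fit a coupled model pair to campaign data
#'
#' Estimates the parameters of one model-library pair for a given quality
#' attribute by constrained nonlinear least squares, using the three-stage
#' search described in [fit_control()]. The fit is deterministic for a
#' given seed.
#'
#' @inheritParams rom_objective
#' @param control A [fit_control()].
#' @param seed Integer seed governing all optimizer randomness.
#'
#' @return An object of class `rom_fit`: estimated parameters (`theta`),
#'   `sse`, `np`, `aic`, `r_squared`, `feasible`, fitted values and the
#'   prepared data. Methods: [tidy()], [glance()], [autoplot()].
#' @export
#'
#' @examples
#' \donttest{
#' camp <- simulate_campaign(campaign_conditions(), tablets_per_condition = 20,
#'                           seed = 7)
#' cond <- summarize_campaign(camp)
#' fit <- fit_rom(cond, "weight", seed = 1)
#' glance(fit)
#' }
fit_rom <- function(data, cqa, pair = c(7, 7),
                    constraints = rom_constraints(),
                    control = fit_control(), geom = tool_geometry(),
                    rho_t = 1.558,
                    weight_params = reference_parameters()$weight,
                    seed = 1) {
  obj <- rom_objective(data, cqa, pair, constraints, geom, rho_t,
                       weight_params, penalty = control$penalty)
  theta <- withr::with_seed(seed, {
    extra <- if (obj$cqa == "strength") {
      profile_init_strength(obj, constraints, control)
    }
    run_fit_stages(obj, control, extra_starts = extra)
  })
  out <- obj$predict(theta)
  feasible <- out$violation == 0 && all(is.finite(out$pred))
  sse <- if (feasible) sum((out$pred - obj$data$obs)^2) else Inf
  n <- nrow(obj$data)
  np <- if (obj$cqa == "weight") 3L else {
    n_parameters(obj$variant1, obj$variant2,
                 n_constants = switch(obj$cqa, force = 1L, recovery = 1L, 0L))
  }
  aic <- if (feasible) {
    suppressWarnings(aic_score(sse, n, np))
  } else {
    Inf
  }
  structure(
    list(cqa = obj$cqa, variant1 = obj$variant1, variant2 = obj$variant2,
         theta = theta, np = np, n = n, sse = sse, aic = aic,
         r_squared = if (feasible) r_squared(out$pred, obj$data$obs) else NA_real_,
         feasible = feasible, fitted = out$pred, data = obj$data,
         constraints = constraints, control = control, seed = seed,
         geom = geom, rho_t = rho_t, weight_params = weight_params),
    class = "rom_fit"
  )
}

#' @export
print.rom_fit <- function(x, ...) {
  pair <- if (is.na(x$variant1)) "packing surface" else {
    sprintf("pair (%d, %d)", x$variant1, x$variant2)
  }
  cat(sprintf("<rom_fit> %s, %s\n", x$cqa, pair))
  cat(sprintf("  n = %d, Np = %d, SSE = %.4g, R^2 = %.4f, AIC = %.2f%s\n",
              x$n, x$np, x$sse, x$r_squared, x$aic,
              if (x$feasible) "" else " (infeasible)"))
  invisible(x)
}

#' @export
tidy.rom_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' @export
glance.rom_fit <- function(x, ...) {
  tibble::tibble(
    cqa = x$cqa, variant1 = x$variant1, variant2 = x$variant2,
    np = x$np, n = x$n, sse = x$sse, r.squared = x$r_squared,
    AIC = x$aic, feasible = x$feasible
  )
}

#' Surface values implied by a fitted model
#'
#' Evaluates a fitted pair's two surfaces at the covariates of the supplied
#' batches, returning the effective base-model parameters per batch --- the
#' quantity that is identifiable even when individual coefficients are not.
#'
#' @param fit A [fit_rom()] result for `"force"`, `"recovery"` or
#'   `"strength"`.
#' @param batches Granule batches (default [granule_batches()]).
#'
#' @return A tibble with the batch identifiers and the two coupled
#'   parameter values per batch.
#' @export
fitted_surface_values <- function(fit, batches = granule_batches()) {
  stopifnot(inherits(fit, "rom_fit"))
  if (fit$cqa == "weight") {
    stop_domain("The weight model has a single packing surface; see `tidy()`.")
  }
  parts <- theta_to_parts(fit$theta, fit$cqa, fit$variant1, fit$variant2)
  rom <- coupled_rom(
    fit$cqa, surface1 = parts$surface1, surface2 = parts$surface2,
    rX = parts$rX, rY = parts$rY,
    constant = if (fit$cqa %in% c("force", "recovery")) parts$constant else NULL,
    weight = if (fit$cqa == "strength") fit$weight_params else NULL,
    rho_c_rib = fit$constraints$rho_c_rib, geom = fit$geom, rho_t = fit$rho_t
  )
  surface_values(rom, batches)
}

#' Select the best model pair by AIC
#'
#' Fits every pair in the model library for one quality attribute and ranks
#' the results by ascending AIC (ties broken by smaller parameter count,
#' then lexicographic pair id). The model with the lowest AIC is the best.
#'
#' @inheritParams fit_rom
#' @param library Tibble of variant pairs (default the 25-pair
#'   [model_library()]).
#'
#' @return A tibble ranked by AIC with columns `variant1`, `variant2`,
#'   `np`, `sse`, `r_squared`, `aic`, `feasible`, and a list column `fit`
#'   of [fit_rom()] objects.
#' @export
select_rom <- function(data, cqa, library = model_library(),
                       constraints = rom_constraints(),
                       control = fit_control(), geom = tool_geometry(),
                       rho_t = 1.558,
                       weight_params = reference_parameters()$weight,
                       seed = 1) {
  if (cqa == "weight") {
    stop_domain("The weight model library has a single member; use `fit_rom()`.")
  }
  if (nrow(library) < 1) stop_domain("`library` must be nonempty.")
  fits <- purrr::map(seq_len(nrow(library)), function(i) {
    fit_rom(data, cqa, pair = c(library$variant1[i], library$variant2[i]),
            constraints = constraints, control = control, geom = geom,
            rho_t = rho_t, weight_params = weight_params, seed = seed + i)
  })
  tibble::tibble(
    variant1 = library$variant1, variant2 = library$variant2,
    np = purrr::map_int(fits, "np"),
    sse = purrr::map_dbl(fits, "sse"),
    r_squared = purrr::map_dbl(fits, "r_squared"),
    aic = purrr::map_dbl(fits, "aic"),
    feasible = purrr::map_lgl(fits, "feasible"),
    fit = fits
  ) |>
    dplyr::arrange(.data$aic, .data$np, .data$variant1, .data$variant2)
}

#' Ranked-model report
#'
#' Formats a [select_rom()] ranking as a compact top-`k` table (pair,
#' parameter count, SSE, R^2, AIC).
#'
#' @param results A [select_rom()] ranking.
#' @param top Number of rows to keep.
#'
#' @return A tibble with at most `top` rows, ascending AIC.
#' @export
report_ranking <- function(results, top = 5) {
  if (nrow(results) < 1) stop_domain("`results` must be nonempty.")
  results |>
    dplyr::arrange(.data$aic, .data$np, .data$variant1, .data$variant2) |>
    dplyr::select("variant1", "variant2", "np", "sse", "r_squared", "aic") |>
    head(top)
}
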