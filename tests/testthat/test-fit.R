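# Fitting-backend behavior on small generative datasets. The full-scale
# recovery study lives in test-acceptance.R; here the focus is on
# structure: identification constraints, prior behavior, hierarchical and
# time-varying modes, and posterior-summary plumbing.

small_recovery_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cv <- gen_covariates(n_players = 8, valid_per_round = 150,
                           environments = "concentrated", seed = 31)
      simd <- simulate_from_model(recovery_params(), cv, seed = 32)
      cache <<- fit_shmdm(simd, model = "fixed", draws = 400, seed = 33)
    }
    cache
  }
})

test_that("a small generative dataset is recovered with sane diagnostics", {
  fit <- suppressWarnings(small_recovery_fit())
  truth <- recovery_transition()
  truth <- truth[truth$environment == "concentrated", ]
  est <- fit$map$transition
  m <- merge(truth, est, by = c("incentive", "environment"),
             suffixes = c(".t", ".e"))
  expect_equal(nrow(m), 2L)
  # loose smoke bounds: this is ~600 steps per condition, so switching
  # coefficients carry substantial sampling noise; the calibrated
  # recovery claim lives in the full-scale study
  expect_lt(mean(abs(m$alpha.t - m$alpha.e)), 0.8)
  expect_lt(mean(abs(m$beta_V.t - m$beta_V.e)), 1.0)
  expect_lt(abs(fit$map$emission$S$dd_mu - (-1.5)), 0.15)
  # label-identification orderings hold in every retained draw
  expect_true(all(fit$draws[, "dd_mu[S]"] < fit$draws[, "dd_mu[I]"]))
  expect_true(all(fit$draws[, "vm_kappa[S]"] > fit$draws[, "vm_kappa[I]"]))
  expect_true(all(fit$draws[, "lb_mu[S]"] < fit$draws[, "lb_mu[I]"]))
  # diagnostics are reported for every parameter
  expect_equal(nrow(fit$diagnostics), ncol(fit$draws))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_gt(min(fit$diagnostics$ess), 100)
})

test_that("with no data the draws reproduce the prior", {
  ss0 <- data.frame(theta = numeric(0), V = integer(0), T = numeric(0),
                    segment = integer(0), t = numeric(0))
  expect_warning(fp <- fit_shmdm(ss0, model = "fixed", draws = 2000,
                                 seed = 41), "no valid segments")
  a <- fp$draws[, "alpha[individual:concentrated]"]
  ks <- suppressWarnings(ks.test(a, "pnorm", 0, 2.5))
  expect_lt(unname(ks$statistic), 0.06)
  bv <- fp$draws[, "beta_V[individual:concentrated]"]
  ks2 <- suppressWarnings(ks.test(bv, "pnorm", 0, 1))
  expect_lt(unname(ks2$statistic), 0.06)
})

test_that("hierarchical mode estimates per-unit offsets", {
  cv <- gen_covariates(n_players = 6, valid_per_round = 120,
                       environments = "concentrated", seed = 51)
  simd <- simulate_from_model(recovery_params(), cv, seed = 52)
  fit <- suppressWarnings(fit_shmdm(simd, model = "re", draws = 200,
                                    seed = 53))
  h <- fit$map$hierarchy
  expect_false(is.null(h))
  expect_equal(rownames(h$individual), as.character(1:6))
  expect_equal(colnames(h$individual),
               c("alpha", "beta_V", "beta_D", "beta_N", "beta_T"))
  expect_true(all(is.finite(h$individual)))
  expect_true(all(fit$draws[, "sd_ind_alpha"] > 0))
  # likelihood evaluates with the offsets in place
  expect_true(is.finite(forward_loglik(simd, fit$map)))
})

test_that("time-varying mode produces simplex minute profiles", {
  cv <- gen_covariates(n_players = 6, valid_per_round = 120,
                       environments = "concentrated", seed = 61)
  simd <- simulate_from_model(recovery_params(), cv, seed = 62)
  fit <- suppressWarnings(fit_shmdm(simd, model = "re-tv",
                                    tv_coefs = "alpha", draws = 200,
                                    seed = 63))
  tv <- fit$map$tv
  expect_equal(names(tv), "alpha")
  expect_equal(dim(tv$alpha$delta), c(2L, 12L))
  expect_equal(rowSums(tv$alpha$delta), c(1, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(tv$alpha$delta >= 0))
  # the resolved coefficient is monotone over minutes for each draw sign
  key <- fit$cond_keys[1]
  dl <- fit$draws[1, paste0("delta_alpha[", key, "].", 1:12)]
  expect_equal(sum(dl), 1, tolerance = 1e-9)
})

test_that("the switch surface is consistent with the transition matrix", {
  fit <- suppressWarnings(small_recovery_fit())
  grid1 <- data.frame(D = 0.3, N = 1, T = -0.2, minute = 4)
  surf <- switch_probability_surface(fit, "individual", "concentrated",
                                     newdata = grid1)
  expect_equal(length(surf), nrow(fit$draws))
  # check one draw by hand against the logistic rule
  k <- "individual:concentrated"
  d <- fit$draws[7, ]
  eta <- d[paste0("alpha[", k, "]")] + d[paste0("beta_V[", k, "]")] +
    d[paste0("beta_D[", k, "]")] * 0.3 + d[paste0("beta_N[", k, "]")] * 1 +
    d[paste0("beta_T[", k, "]")] * (-0.2)
  expect_equal(unname(surf[7]), unname(plogis(eta)), tolerance = 1e-12)
  # the MAP parameters reproduce the same value through transition_matrix
  M <- transition_matrix(fit$map, "individual", "concentrated", V = 1,
                         D = 0.3, N = 1, T = -0.2)
  expect_equal(M["I", "S"], mean(surf), tolerance = 0.05)
  # empirical-grid surface: probabilities in (0, 1) and draw-level spread
  s2 <- switch_probability_surface(fit, "group", "concentrated")
  expect_true(all(s2 > 0 & s2 < 1))
  expect_gt(sd(s2), 0)
  expect_error(switch_probability_surface(fit, "group", "distributed"),
               "unknown condition")
})

test_that("a condition with larger true alpha has a larger baseline", {
  tr <- recovery_transition()
  tr <- tr[tr$environment == "concentrated", ]
  # individual incentives have the larger switching intercept by design
  cv <- gen_covariates(n_players = 10, valid_per_round = 250,
                       environments = "concentrated", seed = 71)
  simd <- simulate_from_model(shmdm_params(recovery_emission(), tr), cv,
                              seed = 72)
  fit <- suppressWarnings(fit_shmdm(simd, model = "fixed", draws = 400,
                                    seed = 73))
  s_ind <- switch_probability_surface(fit, "individual", "concentrated")
  s_grp <- switch_probability_surface(fit, "group", "concentrated")
  ct <- contrast(s_ind, s_grp, direction = "greater")
  expect_gt(ct$mean, 0)
  expect_gt(ct$er$value, 1)
})

test_that("contrasts summarize draw vectors with HPDI and evidence ratio", {
  set.seed(81)
  x <- rnorm(5000, 0.3, 0.1)
  ct <- contrast(x)
  expect_equal(ct$mean, 0.3, tolerance = 0.01)
  expect_true(ct$hpdi[1] < 0.3 && 0.3 < ct$hpdi[2])
  expect_true(ct$er$capped)  # all draws essentially positive
  y <- rnorm(5000, 0.3, 0.1)
  ct2 <- contrast(x, y)
  expect_equal(ct2$mean, 0, tolerance = 0.01)
  expect_lt(abs(log(ct2$er$value)), log(1.3))
  expect_error(contrast(rnorm(10)), "at least 100")
  expect_output(print(ct), "ER")
})
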