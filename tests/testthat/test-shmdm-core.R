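test_that("switch probabilities follow the gated logistic rule", {
  tr <- data.frame(incentive = "individual", environment = "concentrated",
                   alpha = 0, beta_V = 0, beta_D = 0, beta_N = 0,
                   beta_T = 0, gamma = 0)
  em <- list(vm_mu = 0, vm_kappa = 1, dd_mu = 0, dd_sigma = 1,
             lb_mu = 0, lb_sigma = 1)
  p0 <- shmdm_params(list(I = em, S = em), tr)
  M <- transition_matrix(p0, "individual", "concentrated", V = 0, T = 0)
  expect_equal(M["I", "S"], 0.5)
  expect_equal(rowSums(M), c(I = 1, S = 1))

  tr2 <- transform(tr, alpha = -2, beta_V = 1)
  p2 <- shmdm_params(list(I = em, S = em), tr2)
  M2 <- transition_matrix(p2, "individual", "concentrated", V = 1, D = 0,
                          N = 0, T = 0)
  expect_equal(M2["I", "S"], plogis(-1), tolerance = 1e-12)
  expect_equal(M2["I", "S"], 0.26894, tolerance = 1e-5)

  # with V = 0 the values of D and N are irrelevant (multiplicative gate)
  tr3 <- transform(tr, beta_D = 5, beta_N = -7)
  p3 <- shmdm_params(list(I = em, S = em), tr3)
  a <- transition_matrix(p3, "individual", "concentrated", V = 0, D = 100,
                         N = 50, T = 0)
  b <- transition_matrix(p3, "individual", "concentrated", V = 0, T = 0)
  expect_equal(a, b)
  # but V = 1 requires D and N
  expect_error(transition_matrix(p3, "individual", "concentrated", V = 1,
                                 T = 0), "requires D and N")
})

test_that("transition rows sum to one across random parameters", {
  set.seed(11)
  for (i in 1:100) {
    p <- random_params()
    M <- transition_matrix(p, "individual", "concentrated",
                           V = rbinom(1, 1, 0.5), D = rnorm(1),
                           N = rpois(1, 1), T = rnorm(1))
    expect_equal(rowSums(M), c(I = 1, S = 1), tolerance = 1e-12)
  }
})

test_that("emission densities are correct and integrate to one", {
  # kappa = 0 is the uniform circular density
  expect_equal(dvonmises(1.3, 0, 0), 1 / (2 * pi), tolerance = 1e-12)
  expect_equal(dvonmises(0.2, 0, 0, log = TRUE), -log(2 * pi),
               tolerance = 1e-12)
  # von Mises at the mode vs an independent quadrature of the
  # normalization constant (Bessel I0 computed by numerical integration)
  I0 <- integrate(function(u) exp(1 * cos(u)) / (2 * pi), -pi, pi,
                  rel.tol = 1e-10)$value
  expect_equal(dvonmises(0, 0, 1), exp(1) / (2 * pi * I0),
               tolerance = 1e-8)
  for (k in c(0, 0.5, 2, 10, 50)) {
    expect_equal(integrate(dvonmises, -pi, pi, kappa = k,
                           rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  }
})

test_that("missing social channels are marginalized out", {
  p <- recovery_params()
  full <- emission_logdensity(0.3, -1.2, 0.4, "S", p)
  vm_only <- emission_logdensity(0.3, NA, NA, "S", p)
  expect_equal(vm_only, dvonmises(0.3, 0, 4, log = TRUE))
  expect_lt(abs(full - (vm_only +
    dnorm(-1.2, -1.5, 0.4, log = TRUE) +
    dlnorm(0.4, -1, 0.6, log = TRUE))), 1e-12)
  expect_error(emission_logdensity(0.3, NA, -0.1, "S", p),
               "strictly positive")
  expect_error(emission_logdensity(0.3, NA, 0, "S", p),
               "strictly positive")
})

test_that("forward algorithm matches brute-force enumeration", {
  set.seed(12)
  for (i in 1:60) {
    p <- random_params()
    ss <- random_segment(sample(1:8, 1))
    b <- brute_force_hmm(ss, p)
    expect_equal(forward_loglik(ss, p), b$loglik, tolerance = 1e-9)
    expect_identical(viterbi(ss, p), b$path)
  }
})

test_that("forward likelihood has the right structure", {
  set.seed(13)
  p <- random_params()
  s1 <- random_segment(1)
  # a single step is just the emission density under the start state I
  expect_equal(forward_loglik(s1, p),
               emission_logdensity(s1$theta, s1$ddist, s1$bearing, "I", p))
  # segment order does not matter, and segments are independent
  a <- random_segment(5, 1); b <- random_segment(7, 2)
  expect_equal(forward_loglik(rbind(a, b), p),
               forward_loglik(rbind(b, a), p), tolerance = 1e-12)
  expect_equal(forward_loglik(rbind(a, b), p),
               forward_loglik(a, p) + forward_loglik(b, p),
               tolerance = 1e-12)
  # empty data: zero with a warning
  expect_warning(ll0 <- forward_loglik(a[0, ], p), "no valid segments")
  expect_equal(ll0, 0)
  # identical emissions under both states: state labels do not matter
  em <- list(vm_mu = 0.1, vm_kappa = 2, dd_mu = -1, dd_sigma = 0.7,
             lb_mu = 0, lb_sigma = 1)
  tr <- data.frame(incentive = "individual", environment = "concentrated",
                   alpha = -1, beta_V = 1, beta_D = 0.2, beta_N = -0.1,
                   beta_T = 0.4, gamma = -0.6)
  psym <- shmdm_params(list(I = em, S = em), tr)
  em2 <- list(I = em, S = em)
  ll1 <- forward_loglik(a, psym)
  # swapping which state's parameters are which leaves the likelihood
  # unchanged when the emissions coincide
  expect_equal(ll1, forward_loglik(a, shmdm_params(em2, tr)),
               tolerance = 1e-12)
})

test_that("viterbi honors absorbing transitions and recovers clean states", {
  em_I <- list(vm_mu = 0, vm_kappa = 1, dd_mu = 0, dd_sigma = 1,
               lb_mu = 0, lb_sigma = 1)
  em_S <- list(vm_mu = 0, vm_kappa = 1, dd_mu = -5, dd_sigma = 1,
               lb_mu = 0, lb_sigma = 1)
  # impossible switch: the path can never leave I
  tr <- data.frame(incentive = "individual", environment = "concentrated",
                   alpha = -50, beta_V = 0, beta_D = 0, beta_N = 0,
                   beta_T = 0, gamma = 0)
  p <- shmdm_params(list(I = em_I, S = em_S), tr)
  set.seed(14)
  ss <- random_segment(20)
  expect_true(all(viterbi(ss, p) == "I"))

  # strongly separated change-in-distance emissions: near-perfect recovery
  emS2 <- list(vm_mu = 0, vm_kappa = 1, dd_mu = -2, dd_sigma = 0.1,
               lb_mu = 0, lb_sigma = 1)
  emI2 <- list(vm_mu = 0, vm_kappa = 1, dd_mu = 0, dd_sigma = 0.1,
               lb_mu = 0, lb_sigma = 1)
  tr2 <- transform(tr, alpha = -1.5, gamma = -1.5)
  psep <- shmdm_params(list(I = emI2, S = emS2), tr2)
  cv <- data.frame(segment = rep(1:40, each = 50),
                   t = rep(1:50, 40), V = 1, D = 0, N = 0, T = 0,
                   minute = 1)
  simd <- simulate_from_model(psep, cv, seed = 15)
  acc <- mean(viterbi(simd, psep) == simd$state)
  expect_gte(acc, 0.99)
})

test_that("monotonic coefficients accumulate a simplex", {
  expect_equal(monotonic_coeff(2.4, rep(1 / 12, 12), 12), 2.4)
  expect_equal(monotonic_coeff(2.4, rep(1 / 12, 12), 6), 1.2)
  expect_equal(monotonic_coeff(-3, c(1, rep(0, 11)), 1:12), rep(-3, 12))
  expect_error(monotonic_coeff(1, rep(1 / 12, 12), 13), "out of range")
  expect_error(monotonic_coeff(1, rep(0.2, 12), 3))
  set.seed(16)
  for (i in 1:20) {
    d <- as.numeric(rmultinom(1, 100, runif(12))) / 100
    bm <- rnorm(1)
    prof <- monotonic_coeff(bm, d, 1:12)
    if (bm >= 0) expect_true(all(diff(prof) >= -1e-12))
    else expect_true(all(diff(prof) <= 1e-12))
  }
})

test_that("decoded display sequences reinsert observed and omitted states", {
  sim <- simulate_round(env_config("concentrated"), seed = 22,
                        duration = 180)
  t1 <- resample_to_1hz(sim$trajectories)
  ss <- state_series(t1, sim$patches, sim$events)
  p <- recovery_params()
  tr1 <- p$transition[p$transition$incentive == "individual" &
                      p$transition$environment == "concentrated", ]
  p1 <- shmdm_params(p$emission, tr1)
  dec <- decode_states(ss, p1)
  expect_true(all(dec$state[dec$exploiting] == "E"))
  expect_true(all(dec$state[!dec$valid & !dec$exploiting] == "I"))
  expect_true(all(dec$state[dec$valid] %in% c("I", "S")))
})
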