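# Shared fixtures for the recovery studies: ground-truth parameters and a
# covariate-series generator emulating the experiment's structure (two
# incentive groups between players, two environments within player,
# validity-masked segments, visibility with one-second persistence).

recovery_emission <- function() {
  list(
    I = list(vm_mu = 0, vm_kappa = 0.7, dd_mu = -0.5, dd_sigma = 1.0,
             lb_mu = 0.5, lb_sigma = 0.8),
    S = list(vm_mu = 0, vm_kappa = 4.0, dd_mu = -1.5, dd_sigma = 0.4,
             lb_mu = -1.0, lb_sigma = 0.6)
  )
}

recovery_transition <- function() {
  data.frame(
    incentive = rep(c("group", "individual"), each = 2),
    environment = rep(c("concentrated", "distributed"), 2),
    alpha = c(-2.2, -2.6, -1.8, -2.4),
    beta_V = c(1.2, 1.5, 1.8, 1.4),
    beta_D = -0.6, beta_N = -0.4, beta_T = 0.3, gamma = -1.5
  )
}

recovery_params <- function() {
  shmdm_params(recovery_emission(), recovery_transition())
}

# Covariate series: per player and environment, segments of geometric
# length separated by omission gaps; V follows a persistent binary chain;
# N is drawn with the observed co-exploiter shares (one exploiter 83%,
# two 14%, three 3%).
gen_covariates <- function(n_players = 40, valid_per_round = 300,
                           environments = c("concentrated", "distributed"),
                           seed = 1) {
  set.seed(seed)
  rows <- list()
  seg <- 0L
  for (p in seq_len(n_players)) {
    inc <- if (p <= n_players / 2) "group" else "individual"
    for (env in environments) {
      t_cur <- 1
      nv <- 0
      while (nv < valid_per_round) {
        len <- min(5 + stats::rgeom(1, 1 / 35), valid_per_round - nv + 5)
        seg <- seg + 1L
        V <- integer(len)
        V[1] <- stats::rbinom(1, 1, 0.5)
        for (i in seq_len(len - 1)) {
          V[i + 1] <- if (stats::runif(1) < 0.8) V[i] else 1L - V[i]
        }
        t_cur <- t_cur + sample(5:30, 1)
        rows[[length(rows) + 1]] <- data.frame(
          player_id = p, group_id = ceiling(p / 4), segment = seg,
          t = t_cur + seq_len(len) - 1, V = V,
          D = ifelse(V == 1, stats::rnorm(len), NA),
          N = ifelse(V == 1,
                     sample(0:2, len, TRUE, prob = c(.83, .14, .03)), NA),
          T = stats::rnorm(len),
          minute = pmin(floor((t_cur + seq_len(len) - 1) / 60) + 1, 12),
          incentive = inc, environment = env)
        t_cur <- t_cur + len
        nv <- nv + len
      }
    }
  }
  do.call(rbind, rows)
}

# Synthetic group series with an AR(1)-smooth predictor and a collective
# outcome optionally driven by the predictor at a short and a long lag.
gen_group_series <- function(n_groups = 4, len = 720, b_short = 0,
                             b_long = 0, lag_short = 5, lag_long = 60,
                             seed = 1) {
  set.seed(seed)
  out <- list()
  for (g in seq_len(n_groups)) {
    x <- as.numeric(stats::arima.sim(list(ar = 0.9), len, sd = 1))
    x <- (x - mean(x)) / stats::sd(x)
    xs <- c(rep(0, lag_short), x[seq_len(len - lag_short)])
    xl <- c(rep(0, lag_long), x[seq_len(len - lag_long)])
    p <- stats::plogis(-1 + b_short * xs + b_long * xl)
    out[[g]] <- data.frame(group_id = g, round_id = 1, t = 0:(len - 1),
                           group_size = 4,
                           n_exploiting = stats::rbinom(len, 4, p),
                           dist_mean = x * 3 + 20, vis_edges = 6)
  }
  do.call(rbind, out)
}

# Brute-force path enumeration oracle for a single segment: the marginal
# log likelihood (sum over all state paths) and the maximum-probability
# path, with ties broken towards state I like the recursion under test.
brute_force_hmm <- function(ss, params) {
  len <- nrow(ss)
  inc <- if ("incentive" %in% names(ss)) ss$incentive[1] else "individual"
  env <- if ("environment" %in% names(ss)) ss$environment[1] else
    "concentrated"
  states <- c("I", "S")
  em <- function(i, s) {
    emission_logdensity(ss$theta[i], ss$ddist[i], ss$bearing[i], s, params)
  }
  tm <- function(i) {
    transition_matrix(params, inc, env, V = ss$V[i], D = ss$D[i],
                      N = ss$N[i], T = ss$T[i], minute = ss$minute[i])
  }
  paths <- if (len > 1) {
    as.matrix(expand.grid(rep(list(1:2), len - 1)))
  } else {
    matrix(integer(0), 1, 0)
  }
  tot <- -Inf
  best <- -Inf
  bestpath <- rep(1L, len)
  for (r in seq_len(nrow(paths))) {
    path <- c(1L, paths[r, ])
    lp <- em(1, "I")
    for (i in seq_len(len)[-1]) {
      M <- tm(i)
      lp <- lp + log(M[path[i - 1], path[i]]) + em(i, states[path[i]])
    }
    tot <- socialhmm:::lse2(tot, lp)
    if (lp > best + 1e-12 ||
        (abs(lp - best) <= 1e-12 && path_precedes(path, bestpath))) {
      best <- lp
      bestpath <- path
    }
  }
  list(loglik = tot, path = states[bestpath])
}

# tie order: prefer the path that is lexicographically more "I" from the
# end, matching the Viterbi backtracking tie-break
path_precedes <- function(a, b) {
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  FALSE
}

# random single-segment observation set for the oracle comparisons
random_segment <- function(len, seg_id = 1L) {
  V <- stats::rbinom(len, 1, 0.6)
  data.frame(
    segment = seg_id, t = seq_len(len), V = V,
    D = ifelse(V == 1, stats::rnorm(len), NA),
    N = ifelse(V == 1, stats::rpois(len, 1), NA),
    T = stats::rnorm(len),
    minute = sample(1:12, len, replace = TRUE),
    theta = stats::runif(len, -pi, pi),
    ddist = ifelse(V == 1, stats::rnorm(len), NA),
    bearing = ifelse(V == 1, stats::rlnorm(len), NA),
    incentive = "individual", environment = "concentrated"
  )
}

random_params <- function() {
  tr <- data.frame(incentive = "individual", environment = "concentrated",
                   alpha = stats::rnorm(1, -1, 1),
                   beta_V = stats::rnorm(1), beta_D = stats::rnorm(1),
                   beta_N = stats::rnorm(1), beta_T = stats::rnorm(1),
                   gamma = stats::rnorm(1))
  em <- function() {
    list(vm_mu = stats::runif(1, -1, 1), vm_kappa = stats::runif(1, 0, 3),
         dd_mu = stats::rnorm(1), dd_sigma = stats::runif(1, 0.2, 2),
         lb_mu = stats::rnorm(1), lb_sigma = stats::runif(1, 0.2, 1.5))
  }
  shmdm_params(list(I = em(), S = em()), tr)
}
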