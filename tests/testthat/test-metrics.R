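# hand-built toy round: player 2 digs at a patch; player 1 watches, walks
# over and joins; player 3 faces away and never sees anyone
toy_round <- function() {
  secs <- 0:29
  patches <- data.frame(patch_id = 1L, x = 50, y = 50, radius = 3,
                        coins = 10L, coins_init = 16L, t_created = 0,
                        t_depleted = NA_real_, group_id = 1L, round_id = 1L)
  # player 2 exploiting at the patch the whole time
  p2 <- data.frame(group_id = 1, round_id = 1, player_id = 2, t = secs,
                   x = 50, y = 50, heading = 0, exploiting = TRUE)
  # player 1 starts 30 m east facing the patch, walks in from t = 10
  x1 <- c(rep(80, 10), seq(80, 53, length.out = 15), rep(51, 5))
  p1 <- data.frame(group_id = 1, round_id = 1, player_id = 1, t = secs,
                   x = x1, y = 50, heading = pi, exploiting = secs >= 25)
  # player 3 nearby but facing away from everyone
  p3 <- data.frame(group_id = 1, round_id = 1, player_id = 3, t = secs,
                   x = 20, y = 20, heading = -3 * pi / 4,
                   exploiting = FALSE)
  traj <- rbind(p1, p2, p3)
  events <- data.frame(group_id = 1, round_id = 1, t = c(0.5, 25.2),
                       event = "patch_joined", player_id = c(2L, 1L),
                       patch_id = 1L, x = c(50, 51), y = 50)
  list(traj = traj, events = events, patches = patches)
}

test_that("scrounging episodes follow the observe-then-join rule", {
  tt <- toy_round()
  led <- scrounging_ledger(tt$traj, tt$events, tt$patches)
  ep <- led$episodes
  # player 1 observed the digger (from t = 0, facing the patch) and joined
  e1 <- ep[ep$player_id == 1, ]
  expect_equal(nrow(e1), 1L)
  expect_true(e1$joined)
  expect_lt(e1$first_seen, 25)
  # player 3 never sees any digger: no episode
  expect_equal(sum(ep$player_id == 3), 0L)
  # player 2 discovered the patch without observing anyone there first
  expect_equal(sum(ep$player_id == 2), 0L)
  expect_error(scrounging_ledger(tt$traj,
                                 transform(tt$events, patch_id = 99L),
                                 tt$patches), "unknown patch")
})

test_that("scrounging rates are ratios with missing-not-zero semantics", {
  ep <- data.frame(group_id = 1, round_id = 1,
                   player_id = c(1, 1, 1, 2, 2),
                   patch_id = 1:5, first_seen = 1:5,
                   joined = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  led <- list(episodes = ep)
  expect_equal(scrounging_rate(led), 0.8)
  byp <- scrounging_rate(led, "player")
  expect_equal(byp$rate[byp$player_id == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(byp$rate[byp$player_id == 2], 1)
  expect_true(is.na(scrounging_rate(list(episodes = ep[0, ]))))
})

test_that("a generative join probability is recovered empirically", {
  set.seed(91)
  n <- 1000
  ep <- data.frame(group_id = 1, round_id = 1, player_id = 1,
                   patch_id = seq_len(n), first_seen = seq_len(n),
                   joined = runif(n) < 0.5)
  r <- scrounging_rate(list(episodes = ep))
  ci <- qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(r, ci[1]); expect_lte(r, ci[2])
})

test_that("metrics episodes equal the simulator's ground-truth ledger", {
  sim <- simulate_round(env_config("distributed"), seed = 92,
                        duration = 420)
  t1 <- resample_to_1hz(sim$trajectories)
  led <- scrounging_ledger(t1, sim$events, sim$patches)
  a <- led$episodes[order(led$episodes$player_id, led$episodes$patch_id),
                    c("player_id", "patch_id", "first_seen", "joined")]
  b <- sim$scrounge_truth[order(sim$scrounge_truth$player_id,
                                sim$scrounge_truth$patch_id),
                          c("player_id", "patch_id", "first_seen", "joined")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  expect_true(all(led$summary$n_joined <= led$summary$n_observed))
})

test_that("patch discovery accounting: one discoverer per extracted patch", {
  sim <- simulate_round(env_config("concentrated"), seed = 93,
                        duration = 420)
  t1 <- resample_to_1hz(sim$trajectories)
  sm <- spatial_social_summaries(t1, sim$events)
  ev <- sim$events
  joins <- ev[ev$event == "patch_joined", ]
  extracted <- unique(ev$patch_id[ev$event == "coin_extracted"])
  # discoveries + joins >= 1 exactly for patches that were ever extracted
  expect_setequal(unique(joins$patch_id), extracted)
  expect_equal(sum(sm$patches_discovered), length(unique(joins$patch_id)))
  expect_equal(sum(sm$patches_discovered) + sum(sm$patches_joined),
               nrow(joins))
})

test_that("spatial summaries on stationary toy configurations", {
  secs <- 0:9
  mk <- function(pid, x, y, h) data.frame(group_id = 1, round_id = 1,
    player_id = pid, t = secs, x = x, y = y, heading = h,
    exploiting = FALSE)
  traj <- rbind(mk(1, 0, 0, 0), mk(2, 10, 0, pi))
  ev <- data.frame(group_id = numeric(0), round_id = numeric(0),
                   t = numeric(0), event = character(0),
                   player_id = integer(0), patch_id = integer(0),
                   x = numeric(0), y = numeric(0))
  sm <- spatial_social_summaries(traj, ev)
  expect_equal(sm$mean_dist, c(10, 10))
  expect_equal(sm$mean_in_fov, c(1, 1))  # facing each other
  solo <- spatial_social_summaries(mk(1, 5, 5, 0), ev)
  expect_true(is.na(solo$mean_dist))
  expect_equal(solo$patches_discovered, 0L)
})

test_that("trajectory descriptors behave on canonical shapes", {
  # straight line
  line <- data.frame(x = 0:50, y = 0, heading = 0)
  td <- trajectory_descriptors(line)
  expect_equal(td$straightness, 1)
  expect_equal(td$dispersion, 0)
  # closed loop
  ang <- seq(0, 2 * pi, length.out = 101)
  loop <- data.frame(x = cos(ang), y = sin(ang),
                     heading = wrap_angle(ang + pi / 2))
  tl <- trajectory_descriptors(loop)
  expect_lt(tl$straightness, 0.01)
  # constant-rate turning is perfectly regular: zero circular dispersion
  expect_equal(tl$dispersion, 0, tolerance = 1e-6)
  # erratic headings disperse widely
  set.seed(96)
  erratic <- data.frame(x = cumsum(rnorm(200)), y = cumsum(rnorm(200)),
                        heading = runif(200, -pi, pi))
  expect_gt(trajectory_descriptors(erratic)$dispersion, 1)
  expect_warning(trajectory_descriptors(data.frame(x = c(1, 1),
                                                   y = c(2, 2),
                                                   heading = c(0, 0))),
                 "zero path")
  # random walks straighten out less the longer they run
  set.seed(94)
  avg_straight <- function(len) {
    mean(replicate(30, {
      h <- cumsum(rvonmises(len, 0, 2))
      trajectory_descriptors(data.frame(x = cumsum(cos(h)),
                                        y = cumsum(sin(h)),
                                        heading = h))$straightness
    }))
  }
  expect_gt(avg_straight(20), avg_straight(400))
})

test_that("time-course fit recovers flat and monotone regimes", {
  set.seed(95)
  df <- data.frame(exploiting = rbinom(20 * 720, 1, 0.3) > 0,
                   minute = rep(rep(1:12, each = 60), 20))
  tc <- exploitation_timecourse(df, draws = 500, seed = 1)
  expect_true(tc$converged)
  cur <- colMeans(timecourse_curve(tc))
  expect_true(all(abs(cur - 0.3) < 0.05))
  # a draw with beta_max = 0 gives an exactly flat curve
  tc0 <- tc
  tc0$draws[, "beta_max[individual:concentrated]"] <- 0
  expect_true(all(apply(timecourse_curve(tc0), 1,
                        function(r) diff(range(r))) < 1e-12))
  # monotone-increasing truth: recovered cumulative steps increase
  minute <- rep(rep(1:12, each = 60), 20)
  p <- plogis(-1.5 + 0.15 * minute)
  df2 <- data.frame(exploiting = rbinom(length(minute), 1, p) > 0,
                    minute = minute)
  tc2 <- exploitation_timecourse(df2, draws = 500, seed = 2)
  cur2 <- colMeans(timecourse_curve(tc2))
  expect_true(all(diff(cur2) > -1e-9))
  expect_gt(cur2[12] - cur2[1], 0.2)
})
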