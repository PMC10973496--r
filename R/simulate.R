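# Agent-based simulation of the collective foraging experiment: avatars
# with a limited field of view alternate between individual exploration
# (correlated random walk), social relocation (straight pursuit of a
# visible exploiting group member) and exploitation (immobile extraction
# at one coin per two seconds, shared depletion, patch respawn). The
# one-second discretization of the movement policy is exactly the
# generative process of the hidden Markov model, so latent-state and
# parameter recovery are well-posed.

#' Movement and decision policy of a simulated avatar
#'
#' The switching rule mirrors the model's transition structure: while
#' exploring, the per-second probability of switching to social relocation
#' is `logit^-1(alpha + beta_V + beta_D * D + beta_N * N + beta_T * T)`
#' whenever at least one exploiting player is visible (`D` the raw
#' distance in meters to the closest visible exploiting player, `N` the
#' number of other players at that player's patch, `T` the time since the
#' focal's last coin in minutes). Relocation requires a visible target, so
#' the social state can only occur while some group member is exploiting.
#' A relocating avatar abandons pursuit with probability `revert_prob` per
#' second, or when the target stops exploiting.
#'
#' @param speed_max maximum speed in m/s (avatars always move at full
#'   speed while exploring or relocating).
#' @param fov_deg horizontal field of view in degrees.
#' @param turn_kappa von Mises concentration of the per-second heading
#'   change while exploring (larger = straighter search).
#' @param turn_rate_max maximum turn rate in rad/s.
#' @param pursuit_kappa von Mises concentration of the per-second aiming
#'   error while relocating (humans track targets imperfectly; a perfectly
#'   deterministic pursuit would put all relative bearings at exactly
#'   zero, outside the support of the log-normal bearing law).
#' @param alpha,beta_V,beta_D,beta_N,beta_T switch-rule coefficients on
#'   the logit scale (see Details for the cue scales).
#' @param revert_prob per-second probability of abandoning relocation.
#' @return object of class `agent_policy`.
#' @export
agent_policy <- function(speed_max = 2, fov_deg = 108, turn_kappa = 2,
                         turn_rate_max = pi / 2, pursuit_kappa = 100,
                         alpha = -3, beta_V = 1.5, beta_D = -0.05,
                         beta_N = -0.3, beta_T = 0.2,
                         revert_prob = 0.15) {
  stopifnot(speed_max > 0, fov_deg > 0, fov_deg <= 360,
            turn_kappa >= 0, turn_rate_max > 0,
            revert_prob >= 0, revert_prob <= 1)
  structure(list(speed_max = speed_max, fov_deg = fov_deg,
                 turn_kappa = turn_kappa, turn_rate_max = turn_rate_max,
                 pursuit_kappa = pursuit_kappa,
                 alpha = alpha, beta_V = beta_V, beta_D = beta_D,
                 beta_N = beta_N, beta_T = beta_T,
                 revert_prob = revert_prob),
            class = "agent_policy")
}

#' Simulate one round of collective foraging
#'
#' Runs the agent-based model for `duration` seconds at `tick_hz` ticks
#' per second and returns raw trajectories, the event log, the patch
#' table, per-second ground-truth latent states, the per-second social
#' covariates the avatars actually acted on, and a ground-truth scrounging
#' ledger. With the same seed, configuration and policies the output is
#' bit-identical.
#'
#' @param config an [env_config()].
#' @param policies a single [agent_policy()] (recycled) or a list, one per
#'   agent.
#' @param n_agents number of avatars (used when `policies` is a single
#'   policy).
#' @param duration round length in seconds.
#' @param tick_hz simulation tick rate (Hz).
#' @param seed optional integer seed.
#' @param group_id,round_id identifiers attached to all outputs.
#' @param incentive `"individual"` or `"group"` (annotation only; payoffs
#'   are not simulated).
#' @return object of class `forage_sim`: a list with `trajectories` (raw,
#'   one row per tick per agent), `events`, `patches`, `truth` (per-second
#'   latent state in I/S/E), `covariates` (per-second V/D_raw/N/T_raw and
#'   validity), `scrounge_truth`, `config`, `policies`, `seed`.
#' @export
simulate_round <- function(config, policies = agent_policy(), n_agents = 4,
                           duration = 720, tick_hz = 25, seed = NULL,
                           group_id = 1L, round_id = 1L,
                           incentive = c("individual", "group")) {
  stopifnot(inherits(config, "env_config"), duration > 0, tick_hz > 0)
  incentive <- match.arg(incentive)
  if (inherits(policies, "agent_policy")) {
    policies <- rep(list(policies), n_agents)
  }
  n <- length(policies)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / tick_hz
  side <- config$arena_side
  n_ticks <- as.integer(round(duration * tick_hz))

  # agent state
  px <- stats::runif(n, 0.05 * side, 0.95 * side)
  py <- stats::runif(n, 0.05 * side, 0.95 * side)
  hd <- wrap_angle(stats::runif(n, -pi, pi))
  mode <- rep("I", n)
  target <- rep(NA_integer_, n)
  cur_patch <- rep(NA_integer_, n)
  timer <- rep(0, n)
  coins <- rep(0L, n)
  last_coin <- rep(0, n)
  turn_sec <- rep(0, n)
  aim_err <- rep(0, n)

  patches <- make_environment(config, avoid = cbind(px, py))

  # policy coefficient matrices for vectorized lookups
  pol <- function(f) vapply(policies, `[[`, 0, f)
  p_speed <- pol("speed_max"); p_fov <- pol("fov_deg")
  p_kap <- pol("turn_kappa"); p_trm <- pol("turn_rate_max")
  p_pk <- pol("pursuit_kappa")
  p_a <- pol("alpha"); p_bV <- pol("beta_V"); p_bD <- pol("beta_D")
  p_bN <- pol("beta_N"); p_bT <- pol("beta_T"); p_rev <- pol("revert_prob")

  # storage
  tr_x <- matrix(NA_real_, n_ticks, n); tr_y <- tr_x; tr_h <- tr_x
  tr_e <- matrix(FALSE, n_ticks, n); tr_c <- matrix(0L, n_ticks, n)
  n_sec <- as.integer(duration)
  truth <- matrix(NA_character_, n_sec, n)
  cov_V <- matrix(NA_integer_, n_sec, n); cov_D <- matrix(NA_real_, n_sec, n)
  cov_N <- matrix(NA_integer_, n_sec, n); cov_T <- matrix(NA_real_, n_sec, n)
  cov_valid <- matrix(FALSE, n_sec, n)
  ev <- list(t = numeric(0), event = character(0), player_id = integer(0),
             patch_id = integer(0), x = numeric(0), y = numeric(0))
  add_event <- function(t, type, player = NA_integer_, patch = NA_integer_,
                        x = NA_real_, y = NA_real_) {
    ev$t <<- c(ev$t, t); ev$event <<- c(ev$event, type)
    ev$player_id <<- c(ev$player_id, player)
    ev$patch_id <<- c(ev$patch_id, patch)
    ev$x <<- c(ev$x, x); ev$y <<- c(ev$y, y)
  }
  for (p in seq_len(nrow(patches))) {
    add_event(0, "patch_created", patch = patches$patch_id[p],
              x = patches$x[p], y = patches$y[p])
  }
  # scrounging ground truth: first time each focal saw an exploiting
  # member at each patch, and whether the focal later joined that patch
  sc_first <- new.env(parent = emptyenv())
  sc_join <- new.env(parent = emptyenv())

  prev_x <- px; prev_y <- py

  for (k in seq_len(n_ticks) - 1L) {
    t <- k * dt
    # record raw tick
    tr_x[k + 1, ] <- px; tr_y[k + 1, ] <- py; tr_h[k + 1, ] <- hd
    tr_e[k + 1, ] <- mode == "E"; tr_c[k + 1, ] <- coins

    if (k %% tick_hz == 0L) {
      s <- as.integer(k %/% tick_hz)  # integer second, 0-based
      expl <- mode == "E"
      for (a in seq_len(n)) {
        if (expl[a]) next
        oth <- setdiff(seq_len(n), a)
        sc <- social_channels(
          focal = list(x = px[a], y = py[a], heading = hd[a],
                       x_prev = prev_x[a], y_prev = prev_y[a]),
          others = data.frame(x = px[oth], y = py[oth],
                              x_prev = prev_x[oth], y_prev = prev_y[oth],
                              exploiting = expl[oth],
                              patch_id = cur_patch[oth]),
          fov_deg = p_fov[a])
        T_raw <- t - last_coin[a]
        cov_V[s + 1, a] <- sc$V; cov_D[s + 1, a] <- sc$D_raw
        cov_N[s + 1, a] <- sc$N; cov_T[s + 1, a] <- T_raw
        cov_valid[s + 1, a] <- any(expl[oth]) && s > 0
        # ledger: patches at which the focal currently sees an exploiter
        vis_expl <- integer(0)
        for (b in oth[expl[oth]]) {
          if (fov_visible(c(px[a], py[a]), hd[a], c(px[b], py[b]),
                          p_fov[a])) {
            vis_expl <- c(vis_expl, b)
          }
        }
        for (p_seen in unique(cur_patch[vis_expl])) {
          key <- paste(a, p_seen, sep = ".")
          if (is.null(sc_first[[key]])) sc_first[[key]] <- t
        }
        if (mode[a] == "S") {
          if (mode[target[a]] != "E" || stats::runif(1) < p_rev[a]) {
            mode[a] <- "I"; target[a] <- NA_integer_
          }
        }
        if (mode[a] == "I" && sc$V == 1L) {
          eta <- p_a[a] + p_bV[a] + p_bD[a] * sc$D_raw +
            p_bN[a] * sc$N + p_bT[a] * (T_raw / 60)
          if (stats::runif(1) < stats::plogis(eta)) {
            d2 <- (px[vis_expl] - px[a])^2 + (py[vis_expl] - py[a])^2
            mode[a] <- "S"
            target[a] <- vis_expl[which.min(d2)]
          }
        }
        if (mode[a] == "I") {
          turn_sec[a] <- rvonmises(1, 0, p_kap[a])
        } else if (mode[a] == "S") {
          aim_err[a] <- rvonmises(1, 0, p_pk[a])
        }
      }
      truth[s + 1, ] <- mode
      prev_x <- px; prev_y <- py
    }

    # movement over (t, t + dt]
    mv <- mode != "E"
    if (any(mv)) {
      for (a in which(mv)) {
        if (mode[a] == "I") {
          dh <- turn_sec[a] * dt
        } else {
          desired <- atan2(py[target[a]] - py[a], px[target[a]] - px[a]) +
            aim_err[a]
          dh <- wrap_angle(desired - hd[a])
        }
        cap <- p_trm[a] * dt
        hd[a] <- wrap_angle(hd[a] + max(-cap, min(cap, dh)))
        step <- p_speed[a] * dt
        nx <- px[a] + cos(hd[a]) * step
        ny <- py[a] + sin(hd[a]) * step
        if (nx < 0 || nx > side) {
          hd[a] <- wrap_angle(pi - hd[a])
          nx <- px[a] + cos(hd[a]) * step
          ny <- py[a] + sin(hd[a]) * step
        }
        if (ny < 0 || ny > side) {
          hd[a] <- wrap_angle(-hd[a])
          nx <- px[a] + cos(hd[a]) * step
          ny <- py[a] + sin(hd[a]) * step
        }
        px[a] <- min(max(nx, 0), side)
        py[a] <- min(max(ny, 0), side)
      }
    }

    t_now <- (k + 1) * dt
    # extraction first, patch encounter second: an avatar that joins a
    # patch during this tick starts its two-second extraction clock at
    # the moment of contact, so its m-th coin falls exactly 2 m seconds
    # after joining
    for (a in which(mode == "E")) {
      timer[a] <- timer[a] + dt
      if (timer[a] >= 2 - 1e-9) {
        timer[a] <- timer[a] - 2
        p <- which(patches$patch_id == cur_patch[a])
        if (patches$coins[p] > 0) {
          patches$coins[p] <- patches$coins[p] - 1L
          coins[a] <- coins[a] + 1L
          last_coin[a] <- t_now
          add_event(t_now, "coin_extracted", player = a,
                    patch = patches$patch_id[p], x = px[a], y = py[a])
          if (patches$coins[p] == 0L) {
            patches$t_depleted[p] <- t_now
            add_event(t_now, "patch_depleted", patch = patches$patch_id[p],
                      x = patches$x[p], y = patches$y[p])
            out <- which(!is.na(cur_patch) & cur_patch == patches$patch_id[p])
            mode[out] <- "I"; cur_patch[out] <- NA_integer_
            timer[out] <- 0
            newp <- respawn_patch(patches, config, avoid = cbind(px, py),
                                  t_created = t_now)
            patches <- rbind(patches, newp)
            add_event(t_now, "patch_created", patch = newp$patch_id,
                      x = newp$x, y = newp$y)
          }
        }
      }
    }

    # patch encounter: moving avatars that touch an active patch start
    # extracting there (discovery or join)
    act <- which(is.na(patches$t_depleted))
    for (a in which(mode != "E")) {
      if (!length(act)) break
      d2 <- (patches$x[act] - px[a])^2 + (patches$y[act] - py[a])^2
      hit <- act[d2 <= patches$radius[act]^2]
      if (length(hit)) {
        p <- hit[1]
        mode[a] <- "E"; cur_patch[a] <- patches$patch_id[p]
        timer[a] <- 0; target[a] <- NA_integer_
        add_event(t_now, "patch_joined", player = a,
                  patch = patches$patch_id[p], x = px[a], y = py[a])
        key <- paste(a, patches$patch_id[p], sep = ".")
        if (!is.null(sc_first[[key]])) sc_join[[key]] <- TRUE
      }
    }
  }

  environment_mode <- config$mode
  ticks <- (seq_len(n_ticks) - 1L) * dt
  traj <- data.frame(
    group_id = group_id, round_id = round_id,
    player_id = rep(seq_len(n), each = n_ticks),
    t = rep(ticks, n),
    x = as.vector(tr_x), y = as.vector(tr_y),
    heading = as.vector(tr_h), exploiting = as.vector(tr_e),
    coins_cum = as.vector(tr_c),
    incentive = incentive, environment = environment_mode
  )
  secs <- 0:(n_sec - 1)
  truth_df <- data.frame(
    group_id = group_id, round_id = round_id,
    player_id = rep(seq_len(n), each = n_sec), t = rep(secs, n),
    state = as.vector(truth)
  )
  cov_df <- data.frame(
    group_id = group_id, round_id = round_id,
    player_id = rep(seq_len(n), each = n_sec), t = rep(secs, n),
    V = as.vector(cov_V), D_raw = as.vector(cov_D),
    N = as.vector(cov_N), T_raw = as.vector(cov_T),
    valid = as.vector(cov_valid)
  )
  events <- data.frame(group_id = group_id, round_id = round_id,
                       t = ev$t, event = ev$event, player_id = ev$player_id,
                       patch_id = ev$patch_id, x = ev$x, y = ev$y)
  patches$group_id <- group_id; patches$round_id <- round_id
  keys <- ls(sc_first)
  sc_df <- if (length(keys)) {
    parts <- strsplit(keys, ".", fixed = TRUE)
    data.frame(
      group_id = group_id, round_id = round_id,
      player_id = as.integer(vapply(parts, `[`, "", 1)),
      patch_id = as.integer(vapply(parts, `[`, "", 2)),
      first_seen = vapply(keys, function(k) sc_first[[k]], 0),
      joined = vapply(keys, function(k) isTRUE(sc_join[[k]]), TRUE)
    )
  } else {
    data.frame(group_id = integer(0), round_id = integer(0),
               player_id = integer(0), patch_id = integer(0),
               first_seen = numeric(0), joined = logical(0))
  }
  rownames(sc_df) <- NULL
  structure(list(trajectories = traj, events = events, patches = patches,
                 truth = truth_df, covariates = cov_df,
                 scrounge_truth = sc_df, config = config,
                 policies = policies, seed = seed, tick_hz = tick_hz,
                 duration = duration, incentive = incentive),
            class = "forage_sim")
}

#' @export
print.forage_sim <- function(x, ...) {
  cat(sprintf(
    "<forage_sim> %d agents, %g s at %g Hz, %s environment (%s incentives)\n",
    length(x$policies), x$duration, x$tick_hz, x$config$mode, x$incentive))
  cat(sprintf("  coins extracted: %d; patches spawned: %d; events: %d\n",
              sum(x$events$event == "coin_extracted"), nrow(x$patches),
              nrow(x$events)))
  invisible(x)
}

#' Write simulation output as delimited text files
#'
#' @param sim a [simulate_round()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly. Writes `trajectories.csv`, `events.csv`,
#'   `patches.csv`, `truth.csv`, `covariates.csv` and `config.dcf`.
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "forage_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(sim$trajectories, file.path(dir, "trajectories.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$patches, file.path(dir, "patches.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(sim$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  cfg <- sim$config
  write.dcf(data.frame(mode = cfg$mode, arena_side = cfg$arena_side,
                       n_patches = cfg$n_patches,
                       coins_per_patch = cfg$coins_per_patch,
                       patch_radius = cfg$patch_radius,
                       tick_hz = sim$tick_hz, duration = sim$duration,
                       incentive = sim$incentive,
                       seed = if (is.null(sim$seed)) NA else sim$seed),
            file.path(dir, "config.dcf"))
  invisible(dir)
}
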