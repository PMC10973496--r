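# Behavioral outcome measures: scrounging opportunities and joins,
# exploitation time-courses with monotonic minute effects, spatial and
# visual summaries, and simple trajectory descriptors.

#' Scrounging ledger: observed and joined patch episodes
#'
#' One scrounging opportunity is one (focal player, patch lifetime) pair
#' at which the focal observed at least one exploiting group member while
#' not exploiting themselves. The opportunity counts as joined when the
#' focal started extracting at that patch after first observing an
#' exploiter there (and necessarily before the patch was depleted, since
#' extraction events only occur during a patch's lifetime).
#'
#' @param traj 1 Hz trajectory table (see [resample_to_1hz()]).
#' @param events event table with `patch_joined` rows.
#' @param patches patch table.
#' @param fov_deg horizontal field of view in degrees.
#' @return list with `episodes` (one row per opportunity: `group_id`,
#'   `round_id`, `player_id`, `patch_id`, `first_seen`, `joined`) and
#'   `summary` (per player-round `n_observed`, `n_joined`).
#' @export
scrounging_ledger <- function(traj, events, patches, fov_deg = 108) {
  if (nrow(events) && any(!events$patch_id[events$event == "patch_joined"]
                          %in% patches$patch_id)) {
    stop("events reference unknown patch ids")
  }
  rounds <- split(traj, list(traj$group_id, traj$round_id), drop = TRUE)
  eps <- list()
  for (rd in rounds) {
    g <- rd$group_id[1]; rnd <- rd$round_id[1]
    pt <- patches
    if (all(c("group_id", "round_id") %in% names(patches))) {
      pt <- patches[patches$group_id == g & patches$round_id == rnd, ,
                    drop = FALSE]
    }
    ev <- events[events$group_id == g & events$round_id == rnd, ,
                 drop = FALSE]
    players <- sort(unique(rd$player_id))
    secs <- sort(unique(rd$t))
    get_mat <- function(col) {
      m <- matrix(NA_real_, length(secs), length(players))
      m[cbind(match(rd$t, secs), match(rd$player_id, players))] <-
        as.numeric(rd[[col]])
      m
    }
    X <- get_mat("x"); Y <- get_mat("y"); H <- get_mat("heading")
    E <- get_mat("exploiting") > 0
    P <- matrix(NA_integer_, length(secs), length(players))
    for (si in seq_along(secs)) {
      for (pj in which(E[si, ])) {
        P[si, pj] <- patch_at(X[si, pj], Y[si, pj], secs[si], pt)
      }
    }
    first_seen <- list()
    for (pj in seq_along(players)) {
      for (si in seq_along(secs)) {
        if (E[si, pj]) next
        for (oj in which(E[si, ])) {
          if (oj == pj || is.na(P[si, oj])) next
          if (fov_visible(c(X[si, pj], Y[si, pj]), H[si, pj],
                          c(X[si, oj], Y[si, oj]), fov_deg)) {
            key <- paste(players[pj], P[si, oj], sep = ".")
            if (is.null(first_seen[[key]])) first_seen[[key]] <- secs[si]
          }
        }
      }
    }
    jn <- ev[ev$event == "patch_joined", , drop = FALSE]
    for (key in names(first_seen)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      pid <- as.integer(parts[1]); pat <- as.integer(parts[2])
      fs <- first_seen[[key]]
      joined <- any(jn$player_id == pid & jn$patch_id == pat & jn$t > fs)
      eps[[length(eps) + 1]] <- data.frame(
        group_id = g, round_id = rnd, player_id = pid, patch_id = pat,
        first_seen = fs, joined = joined)
    }
  }
  episodes <- if (length(eps)) do.call(rbind, eps) else {
    data.frame(group_id = integer(0), round_id = integer(0),
               player_id = integer(0), patch_id = integer(0),
               first_seen = numeric(0), joined = logical(0))
  }
  agg <- stats::aggregate(cbind(n_observed = rep(1, nrow(episodes)),
                                n_joined = as.integer(episodes$joined)) ~
                            group_id + round_id + player_id,
                          data = episodes, FUN = sum)
  list(episodes = episodes,
       summary = if (nrow(episodes)) agg else
         data.frame(group_id = integer(0), round_id = integer(0),
                    player_id = integer(0), n_observed = integer(0),
                    n_joined = integer(0)))
}

#' Empirical scrounging rate
#'
#' Conditional probability of joining a patch at which at least one
#' exploiting group member was observed. Players (or pools) without any
#' observed episode get `NA`, not zero.
#'
#' @param ledger result of [scrounging_ledger()].
#' @param pooling `"overall"`, `"player"` or `"round"`.
#' @return for `"overall"` a single proportion; otherwise a data.frame
#'   with `n_observed`, `n_joined` and `rate`.
#' @export
scrounging_rate <- function(ledger, pooling = c("overall", "player",
                                                "round")) {
  pooling <- match.arg(pooling)
  ep <- ledger$episodes
  if (pooling == "overall") {
    if (nrow(ep) == 0) return(NA_real_)
    return(mean(ep$joined))
  }
  by <- if (pooling == "player") {
    list(group_id = ep$group_id, round_id = ep$round_id,
         player_id = ep$player_id)
  } else {
    list(group_id = ep$group_id, round_id = ep$round_id)
  }
  agg <- stats::aggregate(ep$joined, by = by,
                          FUN = function(j) c(sum(length(j)), sum(j)))
  out <- do.call(data.frame, agg)
  names(out)[(ncol(out) - 1):ncol(out)] <- c("n_observed", "n_joined")
  out$rate <- ifelse(out$n_observed > 0, out$n_joined / out$n_observed,
                     NA_real_)
  out
}

#' Exploitation time-course with a monotonic minute effect
#'
#' Fits, per incentive x environment condition, a Bernoulli model of the
#' per-second probability that a player is currently exploiting:
#' `P(E) = logit^-1(alpha + beta_max * sum(delta[1:minute]))` with `delta`
#' a 12-simplex, so the curve is monotone in the minute without a
#' prescribed functional form. Fitted by the same penalized-likelihood /
#' Laplace backend as the main model, on counts aggregated by condition
#' and minute.
#'
#' @param df data.frame with columns `exploiting` (logical), `minute`
#'   (1-12) and optionally `incentive`, `environment`.
#' @param draws number of Laplace draws.
#' @param seed optional seed.
#' @param control passed to the optimizer.
#' @return object of class `timecourse_fit` with `draws`, `cond_keys`,
#'   `converged` and the aggregated counts.
#' @export
exploitation_timecourse <- function(df, draws = 1000, seed = NULL,
                                    control = list()) {
  stopifnot(all(c("exploiting", "minute") %in% names(df)))
  if (!"incentive" %in% names(df)) {
    df$incentive <- "individual"; df$environment <- "concentrated"
  }
  key <- cond_key(df$incentive, df$environment)
  minute <- pmin(pmax(as.integer(df$minute), 1L), 12L)
  tab_n <- table(key, minute)
  tab_k <- table(key[df$exploiting], factor(minute[df$exploiting],
                                            levels = colnames(tab_n)))
  cond_keys <- rownames(tab_n)
  n_c <- length(cond_keys)
  kmat <- matrix(0, n_c, 12, dimnames = list(cond_keys, NULL))
  nmat <- kmat
  nmat[, as.integer(colnames(tab_n))] <- tab_n
  if (nrow(tab_k)) kmat[rownames(tab_k), as.integer(colnames(tab_k))] <- tab_k
  # parameters: per condition alpha, beta_max, 11 raw simplex values
  p_per <- 13L
  negpost <- function(theta) {
    v <- 0
    for (ci in seq_len(n_c)) {
      th <- theta[(ci - 1) * p_per + 1:p_per]
      a <- th[1]; bm <- th[2]; dl <- softmax_delta(th[3:13])
      p <- stats::plogis(a + bm * cumsum(dl))
      v <- v - sum(stats::dbinom(kmat[ci, ], nmat[ci, ], p, log = TRUE))
      v <- v + neg_lp_gauss(a, 0, 2.5) + neg_lp_gauss(bm, 0, 1) +
        neg_lp_gauss(th[3:13], 0, 1)
    }
    if (!is.finite(v)) 1e10 else v
  }
  theta0 <- rep(0, n_c * p_per)
  theta0[seq(1, n_c * p_per, p_per)] <- logit(pmin(pmax(
    rowSums(kmat) / pmax(rowSums(nmat), 1), 0.01), 0.99))
  lm <- laplace_machine(negpost, theta0, n_draws = draws,
                        control = control, seed = seed)
  cols <- list()
  for (ci in seq_len(n_c)) {
    i0 <- (ci - 1) * p_per
    a <- lm$draws[, i0 + 1]; bm <- lm$draws[, i0 + 2]
    dl <- t(apply(lm$draws[, i0 + 3:13, drop = FALSE], 1, softmax_delta))
    colnames(dl) <- paste0("delta[", cond_keys[ci], "].", 1:12)
    cols[[ci]] <- cbind(stats::setNames(data.frame(a, bm),
                                        paste0(c("alpha[", "beta_max["),
                                               cond_keys[ci], "]")), dl)
  }
  dmat <- as.matrix(do.call(cbind, cols))
  converged <- lm$convergence == 0 && lm$hessian_ok
  if (!converged) warning("time-course fit flagged as not converged")
  structure(list(draws = dmat, cond_keys = cond_keys, counts_k = kmat,
                 counts_n = nmat, converged = converged),
            class = "timecourse_fit")
}

#' Per-minute exploitation-probability curve from a time-course fit
#'
#' @param fit a [exploitation_timecourse()] result.
#' @param incentive,environment condition labels.
#' @return matrix of draws (rows) by minute (12 columns) of P(E).
#' @export
timecourse_curve <- function(fit, incentive = "individual",
                             environment = "concentrated") {
  key <- cond_key(incentive, environment)
  stopifnot(key %in% fit$cond_keys)
  a <- fit$draws[, paste0("alpha[", key, "]")]
  bm <- fit$draws[, paste0("beta_max[", key, "]")]
  dl <- fit$draws[, paste0("delta[", key, "].", 1:12), drop = FALSE]
  cum <- t(apply(dl, 1, cumsum))
  stats::plogis(a + bm * cum)
}

#' Spatial and visual social summaries per player-round
#'
#' Mean distance to the other players and mean number of players in the
#' field of view, both computed over the focal player's non-exploiting
#' seconds, plus patch discovery and joining counts (the first extractor
#' at a patch is its discoverer; later extractors joined it).
#'
#' @param traj 1 Hz trajectory table.
#' @param events event table with `patch_joined` rows.
#' @param fov_deg horizontal field of view in degrees.
#' @return data.frame, one row per player-round.
#' @export
spatial_social_summaries <- function(traj, events, fov_deg = 108) {
  rounds <- split(traj, list(traj$group_id, traj$round_id), drop = TRUE)
  out <- list()
  for (rd in rounds) {
    g <- rd$group_id[1]; rnd <- rd$round_id[1]
    ev <- events[events$group_id == g & events$round_id == rnd &
                 events$event == "patch_joined", , drop = FALSE]
    ev <- ev[order(ev$t), , drop = FALSE]
    firsts <- ev[!duplicated(ev$patch_id), , drop = FALSE]
    players <- sort(unique(rd$player_id))
    secs <- sort(unique(rd$t))
    get_mat <- function(col) {
      m <- matrix(NA_real_, length(secs), length(players))
      m[cbind(match(rd$t, secs), match(rd$player_id, players))] <-
        as.numeric(rd[[col]])
      m
    }
    X <- get_mat("x"); Y <- get_mat("y"); H <- get_mat("heading")
    E <- get_mat("exploiting") > 0
    for (pj in seq_along(players)) {
      pid <- players[pj]
      use <- which(!E[, pj])
      dists <- fovn <- rep(NA_real_, length(use))
      if (length(players) > 1) {
        for (k in seq_along(use)) {
          si <- use[k]
          oth <- setdiff(seq_along(players), pj)
          dd <- sqrt((X[si, oth] - X[si, pj])^2 + (Y[si, oth] - Y[si, pj])^2)
          dists[k] <- mean(dd)
          fovn[k] <- sum(vapply(oth, function(oj) {
            fov_visible(c(X[si, pj], Y[si, pj]), H[si, pj],
                        c(X[si, oj], Y[si, oj]), fov_deg)
          }, TRUE))
        }
      }
      out[[length(out) + 1]] <- data.frame(
        group_id = g, round_id = rnd, player_id = pid,
        mean_dist = if (length(players) > 1) mean(dists) else NA_real_,
        mean_in_fov = if (length(players) > 1) mean(fovn) else NA_real_,
        patches_discovered = sum(firsts$player_id == pid),
        patches_joined = sum(ev$player_id == pid) -
          sum(firsts$player_id == pid)
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trajectory straightness and turning-angle dispersion
#'
#' Straightness is net displacement over path length (1 for a straight
#' line, 0 for a closed loop); dispersion is the circular standard
#' deviation of the turning angles.
#'
#' @param track data.frame for one player-round with `x`, `y`, `heading`
#'   ordered in time (1 Hz).
#' @return list with `straightness` and `dispersion`.
#' @export
trajectory_descriptors <- function(track) {
  stopifnot(nrow(track) >= 2)
  dx <- diff(track$x); dy <- diff(track$y)
  path <- sum(sqrt(dx^2 + dy^2))
  net <- sqrt((track$x[nrow(track)] - track$x[1])^2 +
              (track$y[nrow(track)] - track$y[1])^2)
  straight <- if (path == 0) {
    warning("zero path length: straightness undefined")
    NA_real_
  } else {
    min(net / path, 1)
  }
  th <- turning_angle(track$heading[-nrow(track)], track$heading[-1])
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  disp <- sqrt(pmax(-2 * log(R), 0))
  list(straightness = straight, dispersion = disp)
}
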