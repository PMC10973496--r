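# Feature construction: from raw trajectories to the per-second
# state-dependent variables, state predictors and validity-masked segments
# consumed by the hidden Markov model.

#' Field-of-view visibility
#'
#' An observer at `pos_a` heading `heading_a` sees a target at `pos_b` iff
#' the absolute wrapped angle between the heading and the vector to the
#' target is at most half the horizontal field of view. There is no
#' distance cutoff: the arena is small and walled. Visibility is not
#' symmetric since it depends on each player's own heading.
#'
#' @param pos_a observer position, numeric length-2 (m).
#' @param heading_a observer heading (radians, 0 along +x).
#' @param pos_b target position, numeric length-2 (m).
#' @param fov_deg full horizontal field-of-view width in degrees.
#' @return logical.
#' @examples
#' fov_visible(c(0, 0), 0, c(10, 0))    # dead ahead
#' fov_visible(c(0, 0), 0, c(0, 10), 108) # 90 deg off: not visible
#' @export
fov_visible <- function(pos_a, heading_a, pos_b, fov_deg = 108) {
  if (all(pos_a == pos_b)) stop("coincident positions: bearing undefined")
  ang <- atan2(pos_b[2] - pos_a[2], pos_b[1] - pos_a[1])
  abs(wrap_angle(ang - heading_a)) <= (fov_deg * pi / 180) / 2
}

#' Turning angle between successive headings
#'
#' @param heading_prev,heading_curr headings in radians.
#' @return wrapped difference in (-pi, pi].
#' @examples
#' turning_angle(3.0, -3.0) # +0.2832, wraps through pi
#' @export
turning_angle <- function(heading_prev, heading_curr) {
  stopifnot(all(is.finite(heading_prev)), all(is.finite(heading_curr)))
  wrap_angle(heading_curr - heading_prev)
}

#' Social observation channels for one focal player at one second
#'
#' Computes, over the set of exploiting players currently inside the focal
#' player's field of view: the smallest change in distance since the
#' previous second (`ddist`, m), the smallest absolute relative bearing
#' (`bearing`, rad, floored at 1e-6 since the downstream log-normal law has
#' strictly positive support), the visibility indicator `V`, the raw
#' distance to the closest visible exploiting player (`D_raw`, m) and the
#' number of other players extracting at that closest player's patch (`N`,
#' with `N = 0` meaning a single exploiter). All channels except `V` are
#' `NA` when no exploiting player is visible.
#'
#' @param focal list with `x`, `y`, `heading`, `x_prev`, `y_prev`.
#' @param others data.frame with one row per other player: `x`, `y`,
#'   `x_prev`, `y_prev`, `exploiting` (logical), `patch_id` (integer, NA
#'   when not exploiting).
#' @param fov_deg horizontal field-of-view width in degrees.
#' @return list with `V`, `ddist`, `bearing`, `D_raw`, `N`.
#' @export
social_channels <- function(focal, others, fov_deg = 108) {
  expl <- which(others$exploiting)
  vis <- logical(length(expl))
  for (k in seq_along(expl)) {
    vis[k] <- fov_visible(c(focal$x, focal$y), focal$heading,
                          c(others$x[expl[k]], others$y[expl[k]]), fov_deg)
  }
  idx <- expl[vis]
  if (length(idx) == 0) {
    return(list(V = 0L, ddist = NA_real_, bearing = NA_real_,
                D_raw = NA_real_, N = NA_integer_))
  }
  dx <- others$x[idx] - focal$x
  dy <- others$y[idx] - focal$y
  dist_t <- sqrt(dx^2 + dy^2)
  dist_prev <- sqrt((others$x_prev[idx] - focal$x_prev)^2 +
                    (others$y_prev[idx] - focal$y_prev)^2)
  bearings <- abs(wrap_angle(atan2(dy, dx) - focal$heading))
  closest <- idx[which.min(dist_t)]
  closest_patch <- others$patch_id[closest]
  n_at_patch <- if (is.na(closest_patch)) 1L else {
    sum(others$exploiting & !is.na(others$patch_id) &
        others$patch_id == closest_patch)
  }
  list(V = 1L,
       ddist = min(dist_t - dist_prev),
       bearing = max(min(bearings), 1e-6),
       D_raw = min(dist_t),
       N = as.integer(n_at_patch - 1L))
}

#' Z-standardize a series
#'
#' Centers and scales by the sample standard deviation (denominator
#' `n - 1`, the usual z-scoring convention), ignoring missing values.
#' Errors on zero variance.
#'
#' @param x numeric vector (NAs allowed and preserved).
#' @return standardized vector with mean 0 and sd 1 over the non-missing
#'   entries.
#' @examples
#' standardize(c(0, 2)) # -0.707..., +0.707...
#' @export
standardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need at least 2 defined values to standardize")
  m <- mean(x[ok])
  s <- stats::sd(x[ok])
  if (s == 0) stop("zero variance: cannot standardize")
  (x - m) / s
}

#' Decompose a validity mask into contiguous segments
#'
#' Maximal runs of valid seconds become half-open `[start, end)` segments
#' (0-based on the mask positions). The latent chain restarts in the
#' individual-exploration state at the first step of every segment.
#'
#' @param valid logical vector, one entry per second.
#' @return data.frame with columns `start`, `end` (half-open, 0-based) and
#'   `length`; zero rows when nothing is valid.
#' @examples
#' build_segments(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
#' @export
build_segments <- function(valid) {
  stopifnot(is.logical(valid), !anyNA(valid))
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Time since the focal player's last coin extraction
#'
#' @param extraction_times sorted numeric vector of the focal player's coin
#'   extraction times (s).
#' @param t query time(s) (s).
#' @param t0 round start (s); before any extraction the clock runs from
#'   `t0`.
#' @return `t - `(most recent extraction at or before `t`), in seconds.
#' @examples
#' time_since_success(100, 130) # 30
#' time_since_success(numeric(0), 0) # 0
#' @export
time_since_success <- function(extraction_times, t, t0 = 0) {
  extraction_times <- sort(extraction_times)
  idx <- findInterval(t, extraction_times)
  last <- ifelse(idx == 0, t0, extraction_times[pmax(idx, 1)])
  t - last
}

#' Resample a raw trajectory table to 1 Hz
#'
#' Sample-and-hold: for every integer second (per player) the tick nearest
#' the second boundary is retained with all its columns, including the
#' exploiting flag at that tick.
#'
#' @param raw trajectory data.frame with at least `player_id` and `t`
#'   columns, strictly time-ordered within player.
#' @return data.frame with one row per player per integer second, `t`
#'   replaced by the integer second.
#' @export
resample_to_1hz <- function(raw) {
  stopifnot(all(c("player_id", "t") %in% names(raw)))
  out <- lapply(split(raw, raw$player_id), function(d) {
    d <- d[order(d$t), , drop = FALSE]
    if (nrow(d) > 1) {
      gaps <- diff(d$t)
      bad <- which(gaps > 1 + 1e-9)
      if (length(bad)) {
        stop(sprintf("gap of %.2f s in raw input at t = %.2f (player %s)",
                     gaps[bad[1]], d$t[bad[1]], d$player_id[1]))
      }
    }
    secs <- seq(ceiling(min(d$t) - 1e-9), floor(max(d$t) + 1e-9))
    idx <- vapply(secs, function(s) which.min(abs(d$t - s)), 0L)
    r <- d[idx, , drop = FALSE]
    r$t <- as.numeric(secs)
    r
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# patch occupied by an exploiting player at time t: the unique active patch
# whose disc contains the position (patches never overlap)
patch_at <- function(x, y, t, patches) {
  active <- which(patches$t_created <= t + 1e-9 &
                  (is.na(patches$t_depleted) | patches$t_depleted > t - 1e-9))
  if (!length(active)) return(NA_integer_)
  d2 <- (patches$x[active] - x)^2 + (patches$y[active] - y)^2
  hit <- active[d2 <= patches$radius[active]^2 + 1e-9]
  if (!length(hit)) return(NA_integer_)
  hit[1]
}

#' Build the per-second state series for the hidden Markov model
#'
#' Transforms 1 Hz trajectories of one or more group-rounds into the
#' observation channels (turning angle, smallest change in distance to
#' visible exploiting players, smallest relative bearing) and state
#' predictors (visibility `V`, z-scored distance `D`, co-exploiter count
#' `N`, z-scored time since success `T`) of the model, together with the
#' validity mask and segment structure. A second is valid only when the
#' focal player is not exploiting, at least one other group member is
#' exploiting, and a previous second exists (the first second of a round
#' has no turning angle). `D` is standardized over the valid seconds where
#' it is defined (V = 1); `T` over all valid seconds; both pooled across
#' the supplied data.
#'
#' @param traj 1 Hz trajectory data.frame with columns `group_id`,
#'   `round_id`, `player_id`, `t`, `x`, `y`, `heading`, `exploiting`, and
#'   optionally `incentive` and `environment`.
#' @param patches patch table (see [make_environment()]) with matching
#'   `group_id`/`round_id` columns when several rounds are supplied.
#' @param events event table containing `coin_extracted` rows (used for
#'   the time-since-success clock); may be NULL, in which case `T` runs
#'   from the round start.
#' @param fov_deg horizontal field of view in degrees.
#' @return data.frame of class `state_series`, one row per player-second,
#'   with columns `group_id`, `round_id`, `player_id`, `t`, `minute`,
#'   `theta`, `ddist`, `bearing`, `V`, `D_raw`, `D`, `N`, `T_raw`, `T`,
#'   `exploiting`, `valid`, `segment` (global segment id, NA when
#'   invalid), plus `incentive`/`environment` if present in `traj`.
#' @export
state_series <- function(traj, patches, events = NULL, fov_deg = 108) {
  need <- c("group_id", "round_id", "player_id", "t", "x", "y",
            "heading", "exploiting")
  stopifnot(all(need %in% names(traj)))
  has_cond <- all(c("incentive", "environment") %in% names(traj))
  multi_patch <- all(c("group_id", "round_id") %in% names(patches))
  rounds <- split(traj, list(traj$group_id, traj$round_id), drop = TRUE)
  rows <- list()
  for (rd in rounds) {
    g <- rd$group_id[1]; rnd <- rd$round_id[1]
    pt <- if (multi_patch) {
      patches[patches$group_id == g & patches$round_id == rnd, , drop = FALSE]
    } else patches
    ev <- events
    if (!is.null(ev) && all(c("group_id", "round_id") %in% names(ev))) {
      ev <- ev[ev$group_id == g & ev$round_id == rnd, , drop = FALSE]
    }
    players <- sort(unique(rd$player_id))
    secs <- sort(unique(rd$t))
    t0 <- secs[1]
    # snapshot matrices [second, player]
    get_mat <- function(col) {
      m <- matrix(NA_real_, length(secs), length(players))
      i <- match(rd$t, secs); j <- match(rd$player_id, players)
      m[cbind(i, j)] <- as.numeric(rd[[col]])
      m
    }
    X <- get_mat("x"); Y <- get_mat("y"); H <- get_mat("heading")
    E <- get_mat("exploiting") > 0
    # patch id of each exploiting player at each second
    P <- matrix(NA_integer_, length(secs), length(players))
    for (si in seq_along(secs)) {
      for (pj in which(E[si, ])) {
        P[si, pj] <- patch_at(X[si, pj], Y[si, pj], secs[si], pt)
      }
    }
    for (pj in seq_along(players)) {
      pid <- players[pj]
      ex_times <- numeric(0)
      if (!is.null(ev)) {
        ex_times <- ev$t[ev$event == "coin_extracted" & ev$player_id == pid]
      }
      n <- length(secs)
      theta <- ddist <- bearing <- D_raw <- rep(NA_real_, n)
      V <- integer(n); N <- rep(NA_integer_, n)
      for (si in 2:n) {
        theta[si] <- turning_angle(H[si - 1, pj], H[si, pj])
        oth <- setdiff(seq_along(players), pj)
        sc <- social_channels(
          focal = list(x = X[si, pj], y = Y[si, pj], heading = H[si, pj],
                       x_prev = X[si - 1, pj], y_prev = Y[si - 1, pj]),
          others = data.frame(x = X[si, oth], y = Y[si, oth],
                              x_prev = X[si - 1, oth], y_prev = Y[si - 1, oth],
                              exploiting = E[si, oth],
                              patch_id = P[si, oth]),
          fov_deg = fov_deg)
        V[si] <- sc$V; ddist[si] <- sc$ddist; bearing[si] <- sc$bearing
        D_raw[si] <- sc$D_raw; N[si] <- sc$N
      }
      any_other <- rowSums(E[, -pj, drop = FALSE]) > 0
      valid <- !E[, pj] & any_other
      valid[1] <- FALSE
      out <- data.frame(
        group_id = g, round_id = rnd, player_id = pid, t = secs,
        minute = pmin(pmax(floor((secs - t0) / 60) + 1, 1), 12),
        theta = theta, ddist = ddist, bearing = bearing,
        V = V, D_raw = D_raw, N = N,
        T_raw = time_since_success(ex_times, secs, t0),
        exploiting = E[, pj], valid = valid
      )
      if (has_cond) {
        out$incentive <- rd$incentive[match(pid, rd$player_id)]
        out$environment <- rd$environment[match(pid, rd$player_id)]
      }
      rows[[length(rows) + 1]] <- out
    }
  }
  ss <- do.call(rbind, rows)
  rownames(ss) <- NULL
  # pooled standardization: D over valid V=1 steps, T over valid steps
  ss$D <- NA_real_
  dmask <- ss$valid & ss$V == 1
  if (sum(dmask) >= 2) {
    sd_fit <- standardize(ss$D_raw[dmask])
    ss$D[dmask] <- sd_fit
  }
  ss$T <- NA_real_
  if (sum(ss$valid) >= 2) {
    ss$T[ss$valid] <- standardize(ss$T_raw[ss$valid])
  }
  # global segment ids over player-rounds
  ss$segment <- NA_integer_
  seg_counter <- 0L
  key <- interaction(ss$group_id, ss$round_id, ss$player_id, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    segs <- build_segments(ss$valid[idx])
    if (nrow(segs)) {
      for (si in seq_len(nrow(segs))) {
        seg_counter <- seg_counter + 1L
        ss$segment[idx[(segs$start[si] + 1):(segs$end[si])]] <- seg_counter
      }
    }
  }
  class(ss) <- c("state_series", "data.frame")
  ss
}
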