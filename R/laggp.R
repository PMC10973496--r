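# Time-lagged Gaussian-process regression: how a group's spatial or
# visual organization at time t - tau predicts collective foraging
# success (number of players exploiting) at time t, across a grid of
# lags. The per-lag regression weight is an average effect plus a
# lag-specific offset with a squared-exponential (RBF) prior across lags,
# so nearby lags shrink towards each other while the lag profile remains
# free in shape.

#' Squared-exponential covariance between two lags
#'
#' `eta * exp(-rho * (tau_y - tau_x)^2 / tau_max^2)`: maximum covariance
#' `eta`, decaying at rate `rho` with the squared lag distance relative
#' to the largest lag. Depends only on `|tau_y - tau_x|` (stationary,
#' symmetric).
#'
#' @param tau_x,tau_y lags (s); vectorized.
#' @param eta maximum covariance, `eta >= 0`.
#' @param rho decay rate, `rho >= 0`.
#' @param tau_max largest lag (s), `> 0`.
#' @return covariance value(s).
#' @examples
#' rbf_cov(10, 10, eta = 2, rho = 1, tau_max = 180) # eta
#' @export
rbf_cov <- function(tau_x, tau_y, eta, rho, tau_max) {
  stopifnot(eta >= 0, rho >= 0)
  if (tau_max <= 0) stop("tau_max must be > 0")
  eta * exp(-rho * (tau_y - tau_x)^2 / tau_max^2)
}

rbf_gram <- function(lags, eta, rho, tau_max, jitter = 1e-8) {
  K <- outer(lags, lags, rbf_cov, eta = eta, rho = rho, tau_max = tau_max)
  K + diag(jitter * max(eta, 1), length(lags))
}

#' Lag grid: every second up to half a minute, 5-second steps up to
#' three minutes
#'
#' @param fine_max largest 1-second lag (default 30 s).
#' @param coarse_step coarse step (default 5 s).
#' @param tau_max largest lag (default 180 s).
#' @return sorted vector of distinct lags in seconds.
#' @examples
#' length(lag_grid()) # 60 distinct lags
#' @export
lag_grid <- function(fine_max = 30, coarse_step = 5, tau_max = 180) {
  sort(unique(c(seq_len(fine_max), seq(coarse_step, tau_max, coarse_step))))
}

#' Per-second group series
#'
#' Collapses a 1 Hz trajectory table to one row per group-round-second:
#' the number of players currently exploiting, the mean pairwise distance
#' among players, and the number of directed visibility edges (player a
#' sees player b; exploiting players see no one, so for 4 players the
#' count ranges from 0 to 12).
#'
#' @param traj 1 Hz trajectory table.
#' @param fov_deg horizontal field of view in degrees.
#' @return data.frame with `group_id`, `round_id`, `t`, `group_size`,
#'   `n_exploiting`, `dist_mean`, `vis_edges` (plus condition columns if
#'   present in `traj`).
#' @export
group_series <- function(traj, fov_deg = 108) {
  has_cond <- all(c("incentive", "environment") %in% names(traj))
  rounds <- split(traj, list(traj$group_id, traj$round_id), drop = TRUE)
  out <- list()
  for (rd in rounds) {
    players <- sort(unique(rd$player_id))
    np <- length(players)
    secs <- sort(unique(rd$t))
    get_mat <- function(col) {
      m <- matrix(NA_real_, length(secs), np)
      m[cbind(match(rd$t, secs), match(rd$player_id, players))] <-
        as.numeric(rd[[col]])
      m
    }
    X <- get_mat("x"); Y <- get_mat("y"); H <- get_mat("heading")
    E <- get_mat("exploiting") > 0
    dist_mean <- vis <- numeric(length(secs))
    for (si in seq_along(secs)) {
      if (np > 1) {
        dm <- stats::dist(cbind(X[si, ], Y[si, ]))
        dist_mean[si] <- mean(dm)
        v <- 0L
        for (a in seq_len(np)) {
          if (E[si, a]) next
          for (b in seq_len(np)[-a]) {
            if (fov_visible(c(X[si, a], Y[si, a]), H[si, a],
                            c(X[si, b], Y[si, b]), fov_deg)) v <- v + 1L
          }
        }
        vis[si] <- v
      } else {
        dist_mean[si] <- NA_real_
      }
    }
    r <- data.frame(group_id = rd$group_id[1], round_id = rd$round_id[1],
                    t = secs, group_size = np,
                    n_exploiting = rowSums(E), dist_mean = dist_mean,
                    vis_edges = vis)
    if (has_cond) {
      r$incentive <- rd$incentive[1]; r$environment <- rd$environment[1]
    }
    out[[length(out) + 1]] <- r
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the lagged design for the GP regression
#'
#' For each usable second t (those at least `max(lags)` after the start
#' of the series) and each lag tau, pairs the collective outcome at t
#' (players exploiting out of group size) with the z-scored predictor at
#' t - tau. The predictor is standardized within condition when condition
#' columns are present, otherwise pooled.
#'
#' @param gs a [group_series()] result.
#' @param predictor `"distance"` (mean pairwise distance) or
#'   `"visibility"` (directed visibility edges).
#' @param lags vector of lags in seconds (see [lag_grid()]).
#' @return data.frame with columns `group_id`, `round_id`, `t`, `lag`,
#'   `x`, `y`, `size` (plus condition columns when present).
#' @export
build_lag_design <- function(gs, predictor = c("distance", "visibility"),
                             lags = lag_grid()) {
  predictor <- match.arg(predictor)
  col <- if (predictor == "distance") "dist_mean" else "vis_edges"
  has_cond <- all(c("incentive", "environment") %in% names(gs))
  gs$x_raw <- gs[[col]]
  if (has_cond) {
    for (k in unique(cond_key(gs$incentive, gs$environment))) {
      sel <- cond_key(gs$incentive, gs$environment) == k
      gs$x_raw[sel] <- standardize(gs$x_raw[sel])
    }
  } else {
    gs$x_raw <- standardize(gs$x_raw)
  }
  max_lag <- max(lags)
  rounds <- split(gs, list(gs$group_id, gs$round_id), drop = TRUE)
  out <- list()
  for (rd in rounds) {
    rd <- rd[order(rd$t), , drop = FALSE]
    n <- nrow(rd)
    if (n <= max_lag) {
      stop("series of length ", n, " shorter than max lag ", max_lag)
    }
    use <- (max_lag + 1):n
    for (lg in lags) {
      r <- data.frame(group_id = rd$group_id[1], round_id = rd$round_id[1],
                      t = rd$t[use], lag = lg,
                      x = rd$x_raw[use - lg],
                      y = rd$n_exploiting[use],
                      size = rd$group_size[use])
      if (has_cond) {
        r$incentive <- rd$incentive[1]; r$environment <- rd$environment[1]
      }
      out[[length(out) + 1]] <- r
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the time-lagged Gaussian-process binomial regression
#'
#' Per condition, a distributed-lag binomial model: the collective
#' outcome at each second enters the likelihood once, with a linear
#' predictor summing all lagged predictor values,
#' `y_t ~ Binomial(size, logit^-1(a + sum_tau (bbar + d[tau]) *
#' x_{t-tau}))`. The lag-specific offsets `d` have a zero-mean
#' multivariate Gaussian prior with squared-exponential covariance across
#' lags whose amplitude `eta` and decay `rho` are estimated, so the
#' per-lag regression weights `bbar + d[tau]` form a smooth curve over
#' lags. Fitted by penalized maximum likelihood with Laplace draws.
#'
#' @param design a [build_lag_design()] result.
#' @param draws number of Laplace draws.
#' @param seed optional seed.
#' @param control passed to the optimizer.
#' @return object of class `laggp_fit`: per condition a list with
#'   `draws` (columns `a`, `bbar`, `eta`, `rho`, `d.<lag>`), `effects`
#'   (data.frame `lag`, `mean`, `lower`, `upper` of `bbar + d`),
#'   `converged`.
#' @export
fit_laggp <- function(design, draws = 1000, seed = NULL, control = list()) {
  has_cond <- all(c("incentive", "environment") %in% names(design))
  keys <- if (has_cond) {
    sort(unique(cond_key(design$incentive, design$environment)))
  } else "all"
  lags <- sort(unique(design$lag))
  L <- length(lags)
  tau_max <- max(lags)
  fits <- list()
  for (k in keys) {
    d <- if (has_cond) {
      design[cond_key(design$incentive, design$environment) == k, ,
             drop = FALSE]
    } else design
    # pivot to one row per observed second, one column per lag
    obs_key <- interaction(d$group_id, d$round_id, d$t, drop = TRUE)
    obs <- !duplicated(obs_key)
    oi <- match(obs_key, obs_key[obs])
    y <- d$y[obs]; size <- d$size[obs]
    X <- matrix(NA_real_, sum(obs), L)
    X[cbind(oi, match(d$lag, lags))] <- d$x
    if (anyNA(X)) stop("design is not complete over the lag grid")
    # non-centered parameterization: d = sqrt(eta) * chol(C(rho))' z with
    # z ~ N(0, I), so draws of d propagate amplitude and length-scale
    # uncertainty instead of collapsing with the mode of eta
    d_from <- function(theta) {
      eta <- exp(theta[3]); rho <- exp(theta[4])
      z <- theta[4 + seq_len(L)]
      Rc <- chol(rbf_gram(lags, 1, rho, tau_max))
      sqrt(eta) * drop(crossprod(Rc, z))
    }
    negpost <- function(theta) {
      v <- tryCatch({
        a <- theta[1]; bbar <- theta[2]
        dv <- d_from(theta)
        p <- stats::plogis(a + drop(X %*% (bbar + dv)))
        ll <- sum(stats::dbinom(y, size, p, log = TRUE))
        pen <- neg_lp_gauss(a, 0, 2.5) + neg_lp_gauss(bbar, 0, 0.5) +
          neg_lp_gauss(theta[3], log(0.2), 1) +
          neg_lp_gauss(theta[4], log(5), 1.5) +
          neg_lp_gauss(theta[4 + seq_len(L)], 0, 1)
        -ll + pen
      }, error = function(e) NA_real_)
      if (!is.finite(v)) 1e10 else v
    }
    theta0 <- c(logit(pmin(pmax(mean(y / size), 0.01), 0.99)), 0,
                log(0.2), log(5), rep(0, L))
    lm <- laplace_machine(negpost, theta0, n_draws = draws,
                          control = control, seed = seed)
    dmat <- t(apply(lm$draws, 1, d_from))
    dm <- cbind(lm$draws[, 1:4], dmat)
    colnames(dm) <- c("a", "bbar", "log_eta", "log_rho",
                      paste0("d.", lags))
    eff_draws <- dm[, "bbar"] + dm[, paste0("d.", lags), drop = FALSE]
    effects <- data.frame(
      lag = lags,
      mean = colMeans(eff_draws),
      lower = apply(eff_draws, 2, function(z) hpdi(z)["lower"]),
      upper = apply(eff_draws, 2, function(z) hpdi(z)["upper"])
    )
    rownames(effects) <- NULL
    converged <- lm$convergence == 0 && lm$hessian_ok
    if (!converged) warning("lag-GP fit for ", k,
                            " flagged as not converged")
    out <- cbind(dm[, c("a", "bbar")], eta = exp(dm[, "log_eta"]),
                 rho = exp(dm[, "log_rho"]),
                 dm[, paste0("d.", lags), drop = FALSE])
    fits[[k]] <- list(draws = out, effects = effects,
                      converged = converged, map = lm$par)
  }
  structure(list(conditions = fits, lags = lags, tau_max = tau_max),
            class = "laggp_fit")
}

#' @export
print.laggp_fit <- function(x, ...) {
  cat(sprintf("<laggp_fit> %d lags (max %g s), %d condition(s)\n",
              length(x$lags), x$tau_max, length(x$conditions)))
  for (k in names(x$conditions)) {
    e <- x$conditions[[k]]$effects
    cat(sprintf("  %s: effect at lag %g = %.3f [%.3f, %.3f]\n", k,
                e$lag[1], e$mean[1], e$lower[1], e$upper[1]))
  }
  invisible(x)
}
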