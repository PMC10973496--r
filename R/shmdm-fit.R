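# Fitting the social hidden Markov decision model by penalized maximum
# likelihood with Laplace-approximation draws. The model is optimized in
# an unconstrained parameterization that enforces the label-identification
# ordering by construction: the social-relocation state S has the smaller
# change-in-distance mean (approach), the larger turning-angle
# concentration (directed movement) and the smaller log-normal bearing
# median (orientation towards the target) in every retained draw.

EM_LABELS <- c("vm_mu_I", "vm_mu_S", "log_kappa_I", "log_dkappa",
               "dd_mu_I", "log_dd_gap", "log_dd_sigma_I", "log_dd_sigma_S",
               "lb_mu_I", "log_lb_gap", "log_lb_sigma_I", "log_lb_sigma_S")

#' Prior (penalty) configuration for the model fit
#'
#' Weakly informative Gaussian penalties in the unconstrained space, plus
#' the informative structure baked into the parameterization itself (the
#' state-ordering constraints on the emission parameters).
#'
#' @param alpha_sd,beta_sd,gamma_sd prior standard deviations of the
#'   switching intercepts (`alpha`, `gamma`) and slopes on the logit
#'   scale.
#' @param delta_sd prior sd of the raw (softmax) monotonic-simplex
#'   parameters.
#' @param em_mu,em_sd length-12 prior means and sds of the unconstrained
#'   emission parameters (see `socialhmm:::EM_LABELS` for their order).
#' @param lsd_mu,lsd_sd prior on the log random-effect scales.
#' @return list of class `shmdm_prior`.
#' @export
shmdm_prior <- function(alpha_sd = 2.5, beta_sd = 1, gamma_sd = 2.5,
                        delta_sd = 1,
                        em_mu = c(0, 0, 0, 0, 0, 0, -0.5, -0.5,
                                  0, 0, -0.5, -0.5),
                        em_sd = rep(1, 12),
                        lsd_mu = log(0.3), lsd_sd = 0.5) {
  structure(list(alpha_sd = alpha_sd, beta_sd = beta_sd,
                 gamma_sd = gamma_sd, delta_sd = delta_sd,
                 em_mu = em_mu, em_sd = em_sd,
                 lsd_mu = lsd_mu, lsd_sd = lsd_sd),
            class = "shmdm_prior")
}

# ---- parameter map -------------------------------------------------------

build_map <- function(cfg, prior) {
  idx <- list(); mu <- numeric(0); sd <- numeric(0); nms <- character(0)
  pos <- 0L
  push <- function(block, labels, m, s) {
    n <- length(labels)
    idx[[block]] <<- pos + seq_len(n)
    pos <<- pos + n
    mu <<- c(mu, rep_len(m, n)); sd <<- c(sd, rep_len(s, n))
    nms <<- c(nms, labels)
  }
  push("em", EM_LABELS, prior$em_mu, prior$em_sd)
  n_c <- length(cfg$cond_keys)
  for (cf in STATE_COEFS) {
    s_cf <- if (cf == "alpha") prior$alpha_sd else prior$beta_sd
    if (cfg$tv[cf]) {
      push(paste0("bmax_", cf), paste0("bmax_", cf, "[", cfg$cond_keys, "]"),
           0, s_cf)
      push(paste0("draw_", cf),
           paste0("draw_", cf, "[", rep(cfg$cond_keys, each = 11), "].",
                  rep(2:12, n_c)),
           0, prior$delta_sd)
    } else {
      push(paste0("b_", cf), paste0(cf, "[", cfg$cond_keys, "]"), 0, s_cf)
    }
  }
  push("gamma", paste0("gamma[", cfg$cond_keys, "]"), 0, prior$gamma_sd)
  if (cfg$re) {
    push("lsd_ind", paste0("lsd_ind_", STATE_COEFS), prior$lsd_mu,
         prior$lsd_sd)
    push("z_ind", paste0("z_ind[", rep(cfg$players, each = 5), ",",
                         rep(STATE_COEFS, length(cfg$players)), "]"), 0, 1)
    push("lsd_grp", paste0("lsd_grp_", STATE_COEFS), prior$lsd_mu,
         prior$lsd_sd)
    push("z_grp", paste0("z_grp[", rep(cfg$groups, each = 5), ",",
                         rep(STATE_COEFS, length(cfg$groups)), "]"), 0, 1)
  }
  list(idx = idx, mu = mu, sd = sd, names = nms, n = pos)
}

softmax_delta <- function(raw11) {
  e <- exp(c(0, raw11) - max(0, raw11))
  e / sum(e)
}

# unconstrained vector -> structured parameter pieces
unpack_shmdm <- function(theta, map, cfg) {
  g <- function(b) theta[map$idx[[b]]]
  e <- g("em")
  kI <- exp(e[3]); kS <- kI + exp(e[4])
  em <- list(
    I = list(vm_mu = wrap_angle(e[1]), vm_kappa = kI, dd_mu = e[5],
             dd_sigma = exp(e[7]), lb_mu = e[9], lb_sigma = exp(e[11])),
    S = list(vm_mu = wrap_angle(e[2]), vm_kappa = kS,
             dd_mu = e[5] - exp(e[6]), dd_sigma = exp(e[8]),
             lb_mu = e[9] - exp(e[10]), lb_sigma = exp(e[12]))
  )
  n_c <- length(cfg$cond_keys)
  B <- matrix(0, n_c, 5, dimnames = list(cfg$cond_keys, STATE_COEFS))
  bmax <- list(); cumdelta <- list()
  for (cf in STATE_COEFS) {
    if (cfg$tv[cf]) {
      bmax[[cf]] <- g(paste0("bmax_", cf))
      raw <- matrix(g(paste0("draw_", cf)), nrow = n_c, byrow = TRUE)
      dl <- t(apply(raw, 1, softmax_delta))
      cumdelta[[cf]] <- t(apply(dl, 1, cumsum))
      attr(cumdelta[[cf]], "delta") <- dl
    } else {
      B[, cf] <- g(paste0("b_", cf))
    }
  }
  gamma <- g("gamma")
  ind_off <- grp_off <- NULL
  sd_ind <- sd_grp <- NULL
  if (cfg$re) {
    sd_ind <- exp(g("lsd_ind"))
    z <- matrix(g("z_ind"), ncol = 5, byrow = TRUE)
    ind_off <- sweep(z, 2, sd_ind, `*`)
    rownames(ind_off) <- cfg$players; colnames(ind_off) <- STATE_COEFS
    sd_grp <- exp(g("lsd_grp"))
    zg <- matrix(g("z_grp"), ncol = 5, byrow = TRUE)
    grp_off <- sweep(zg, 2, sd_grp, `*`)
    rownames(grp_off) <- cfg$groups; colnames(grp_off) <- STATE_COEFS
  }
  list(em = em, B = B, bmax = bmax, cumdelta = cumdelta, gamma = gamma,
       ind_off = ind_off, grp_off = grp_off, sd_ind = sd_ind,
       sd_grp = sd_grp)
}

# structured pieces -> user-facing shmdm_params
up_to_params <- function(up, cfg) {
  parts <- strsplit(cfg$cond_keys, ":", fixed = TRUE)
  tr <- data.frame(
    incentive = vapply(parts, `[`, "", 1),
    environment = vapply(parts, `[`, "", 2)
  )
  for (cf in STATE_COEFS) tr[[cf]] <- up$B[, cf]
  tr$gamma <- up$gamma
  tv <- NULL
  if (any(cfg$tv)) {
    tv <- list()
    for (cf in STATE_COEFS[cfg$tv]) {
      dl <- attr(up$cumdelta[[cf]], "delta")
      rownames(dl) <- cfg$cond_keys
      bm <- up$bmax[[cf]]; names(bm) <- cfg$cond_keys
      tv[[cf]] <- list(beta_max = bm, delta = dl)
      # static column carries the minute-1 value for completeness
      tr[[cf]] <- bm * up$cumdelta[[cf]][, 1]
    }
  }
  hier <- NULL
  if (!is.null(up$ind_off)) {
    hier <- list(individual = up$ind_off, group = up$grp_off,
                 sd_individual = up$sd_ind, sd_group = up$sd_grp)
  }
  shmdm_params(up$em, tr, tv = tv, hierarchy = hier)
}

#' Fit the social hidden Markov decision model
#'
#' Penalized maximum likelihood (the forward-algorithm likelihood plus
#' weakly informative Gaussian penalties in an unconstrained, ordering-
#' enforcing parameterization), with draws from the Laplace approximation
#' at the mode standing in for posterior draws. Three model structures
#' are available: condition-level coefficients only (`"fixed"`),
#' additional per-individual and per-group offsets on the five switching
#' coefficients (`"re"`), and monotonic time-varying coefficients with
#' offsets on the average effects (`"re-tv"`).
#'
#' @param ss a [state_series()] (or the output of
#'   [simulate_from_model()] with its covariate columns).
#' @param model `"fixed"`, `"re"` or `"re-tv"`.
#' @param tv_coefs coefficients that vary by minute in `"re-tv"` mode.
#' @param draws number of Laplace draws to retain.
#' @param prior an [shmdm_prior()].
#' @param seed optional integer seed (used for the draws).
#' @param control passed to [stats::optim()] (`maxit`, `reltol`).
#' @return object of class `shmdm_fit`: list with `map` (an
#'   [shmdm_params()] at the mode), `draws` (matrix of constrained
#'   parameter draws), `diagnostics` (per-parameter split-chain
#'   convergence statistic and effective sample size), `converged`,
#'   `loglik`, `model`, `cond_keys`, `n_steps`, and the V = 1 covariate
#'   grids per condition used by [switch_probability_surface()].
#' @export
fit_shmdm <- function(ss, model = c("fixed", "re", "re-tv"),
                      tv_coefs = STATE_COEFS, draws = 1000,
                      prior = shmdm_prior(), seed = NULL,
                      control = list()) {
  model <- match.arg(model)
  pp <- prep_steps(ss)
  if (is.null(pp)) {
    warning("no valid segments: returning the prior (empty-likelihood fit)")
  }
  steps <- if (!is.null(pp)) pp$steps else NULL
  cond_keys <- if (!is.null(steps)) {
    sort(unique(cond_key(steps$incentive, steps$environment)))
  } else if (all(c("incentive", "environment") %in% names(ss)) &&
             nrow(ss) > 0) {
    sort(unique(cond_key(ss$incentive, ss$environment)))
  } else {
    cond_key("individual", "concentrated")
  }
  re <- model %in% c("re", "re-tv")
  tv <- stats::setNames(rep(model == "re-tv", 5), STATE_COEFS)
  if (model == "re-tv") tv[!(STATE_COEFS %in% tv_coefs)] <- FALSE
  players <- groups <- character(0)
  if (re && !is.null(steps)) {
    players <- as.character(sort(unique(steps$player_id)))
    groups <- as.character(sort(unique(steps$group_id %||%
                                       rep(1, nrow(steps)))))
    if (!"group_id" %in% names(steps)) pp$steps$group_id <- 1
  }
  cfg <- list(cond_keys = cond_keys, tv = tv, re = re,
              players = players, groups = groups)
  map <- build_map(cfg, prior)

  # data-driven starting values: the likelihood is multimodal (e.g. a
  # mode that splits the approach cluster in two), so the emissions are
  # initialized from a rough deterministic split of the complete-case
  # steps — small-bearing, strongly-approaching steps proxy the social
  # relocation state — which starts the optimizer in the right basin
  theta0 <- map$mu
  names(theta0) <- map$names
  if (!is.null(steps)) {
    theta0[map$idx$em] <- init_emissions(steps)
    for (cf in STATE_COEFS) {
      if (!cfg$tv[cf] && cf == "alpha") theta0[map$idx$b_alpha] <- -2
    }
    theta0[map$idx$gamma] <- -1
  }

  negpost <- make_negpost(pp, map, cfg, prior)
  lm <- laplace_machine(negpost, theta0, n_draws = draws,
                        control = control, seed = seed)
  up <- unpack_shmdm(lm$par, map, cfg)
  map_params <- up_to_params(up, cfg)
  ll <- if (!is.null(pp)) .forward_pp(pp, map_params) else 0

  cdraws <- transform_draws(lm$draws, map, cfg)
  diag_df <- data.frame(
    parameter = colnames(cdraws),
    rhat = apply(cdraws, 2, rhat_split),
    ess = apply(cdraws, 2, ess_basic)
  )
  converged <- lm$convergence == 0 && lm$hessian_ok &&
    all(diag_df$rhat <= 1.01, na.rm = TRUE)
  if (!converged) {
    warning("fit flagged as not converged (optimizer code ",
            lm$convergence, ", hessian_ok = ", lm$hessian_ok, ")")
  }
  grids <- list()
  if (!is.null(steps)) {
    for (k in cond_keys) {
      sel <- steps$V == 1 & cond_key(steps$incentive, steps$environment) == k
      grids[[k]] <- steps[sel, c("D0", "N0", "T", "minute"), drop = FALSE]
    }
  }
  structure(list(map = map_params, draws = cdraws, diagnostics = diag_df,
                 converged = converged, loglik = ll, model = model,
                 cond_keys = cond_keys, cfg = cfg, parmap = map,
                 theta_hat = lm$par, n_steps = if (is.null(pp)) 0 else
                   nrow(pp$steps),
                 n_segments = if (is.null(pp)) 0 else pp$n_seg,
                 grids = grids, seed = seed),
            class = "shmdm_fit")
}

# moment-based starting values for the unconstrained emission block
init_emissions <- function(steps) {
  # von Mises concentration from the mean resultant length (Fisher)
  kap_hat <- function(x) {
    R <- sqrt(mean(cos(x))^2 + mean(sin(x))^2)
    max(R * (2 - R^2) / max(1 - R^2, 1e-6), 0.1)
  }
  sel <- which(!is.na(steps$ddist) & !is.na(steps$bearing))
  fallback <- c(0, 0, 0, 0, 0, log(0.5), 0, -0.5, 0, log(0.5), 0, 0)
  if (length(sel) < 50) return(fallback)
  dd <- steps$ddist[sel]; lb <- log(steps$bearing[sel])
  th <- steps$theta[sel]
  sprox <- dd <= stats::quantile(dd, 0.3) & lb <= stats::quantile(lb, 0.3)
  if (sum(sprox) < 10 || sum(!sprox) < 10) return(fallback)
  kI <- kap_hat(th[!sprox])
  kS <- max(kap_hat(th[sprox]), kI * 1.5)
  ddI <- mean(dd[!sprox]); ddS <- min(mean(dd[sprox]), ddI - 0.1)
  sdI <- max(stats::sd(dd[!sprox]), 0.05)
  sdS <- max(stats::sd(dd[sprox]), 0.05)
  lbI <- mean(lb[!sprox]); lbS <- min(mean(lb[sprox]), lbI - 0.1)
  lsI <- max(stats::sd(lb[!sprox]), 0.1)
  lsS <- max(stats::sd(lb[sprox]), 0.1)
  c(0, 0, log(kI), log(max(kS - kI, 0.1)),
    ddI, log(ddI - ddS), log(sdI), log(sdS),
    lbI, log(lbI - lbS), log(lsI), log(lsS))
}

# negative penalized log-likelihood with precomputed step indices
make_negpost <- function(pp, map, cfg, prior) {
  if (!is.null(pp)) {
    st <- pp$steps
    cond_idx <- match(cond_key(st$incentive, st$environment), cfg$cond_keys)
    minute <- pmin(pmax(as.integer(st$minute), 1L), 12L)
    V <- st$V; D0 <- st$D0; N0 <- st$N0; Tz <- st$T
    th <- st$theta; dd <- st$ddist; bb <- st$bearing
    dd_ok <- !is.na(dd); bb_ok <- !is.na(bb)
    ddv <- dd[dd_ok]; bbv <- log(bb[bb_ok])
    ind_idx <- if (cfg$re) match(as.character(st$player_id), cfg$players)
    grp_idx <- if (cfg$re) match(as.character(st$group_id), cfg$groups)
  }
  function(theta) {
    v <- tryCatch({
      pen <- neg_lp_gauss(theta, map$mu, map$sd)
      if (is.null(pp)) return(pen)
      up <- unpack_shmdm(theta, map, cfg)
      cf_step <- matrix(0, length(cond_idx), 5)
      for (j in seq_along(STATE_COEFS)) {
        cf <- STATE_COEFS[j]
        base <- if (cfg$tv[cf]) {
          up$bmax[[cf]][cond_idx] * up$cumdelta[[cf]][cbind(cond_idx, minute)]
        } else {
          up$B[cond_idx, j]
        }
        if (cfg$re) {
          base <- base + up$ind_off[cbind(ind_idx, j)] +
            up$grp_off[cbind(grp_idx, j)]
        }
        cf_step[, j] <- base
      }
      eta <- cf_step[, 1] + cf_step[, 2] * V + cf_step[, 3] * V * D0 +
        cf_step[, 4] * V * N0 + cf_step[, 5] * Tz
      eta_si <- up$gamma[cond_idx]
      L1 <- dvonmises(th, up$em$I$vm_mu, up$em$I$vm_kappa, log = TRUE)
      L2 <- dvonmises(th, up$em$S$vm_mu, up$em$S$vm_kappa, log = TRUE)
      L1[dd_ok] <- L1[dd_ok] +
        stats::dnorm(ddv, up$em$I$dd_mu, up$em$I$dd_sigma, log = TRUE)
      L2[dd_ok] <- L2[dd_ok] +
        stats::dnorm(ddv, up$em$S$dd_mu, up$em$S$dd_sigma, log = TRUE)
      L1[bb_ok] <- L1[bb_ok] +
        stats::dnorm(bbv, up$em$I$lb_mu, up$em$I$lb_sigma, log = TRUE) - bbv
      L2[bb_ok] <- L2[bb_ok] +
        stats::dnorm(bbv, up$em$S$lb_mu, up$em$S$lb_sigma, log = TRUE) - bbv
      q <- list(L = cbind(L1, L2),
                lp_is = stats::plogis(eta, log.p = TRUE),
                lp_not_is = stats::plogis(-eta, log.p = TRUE),
                lp_si = stats::plogis(eta_si, log.p = TRUE),
                lp_not_si = stats::plogis(-eta_si, log.p = TRUE))
      -.forward_rec(pp, q) + pen
    }, error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
}

# unconstrained Laplace draws -> constrained, user-facing draw matrix
transform_draws <- function(draws_u, map, cfg) {
  n <- nrow(draws_u)
  g <- function(b) draws_u[, map$idx[[b]], drop = FALSE]
  e <- g("em")
  kI <- exp(e[, 3]); kS <- kI + exp(e[, 4])
  out <- cbind(
    "vm_mu[I]" = wrap_angle(e[, 1]), "vm_mu[S]" = wrap_angle(e[, 2]),
    "vm_kappa[I]" = kI, "vm_kappa[S]" = kS,
    "dd_mu[I]" = e[, 5], "dd_mu[S]" = e[, 5] - exp(e[, 6]),
    "dd_sigma[I]" = exp(e[, 7]), "dd_sigma[S]" = exp(e[, 8]),
    "lb_mu[I]" = e[, 9], "lb_mu[S]" = e[, 9] - exp(e[, 10]),
    "lb_sigma[I]" = exp(e[, 11]), "lb_sigma[S]" = exp(e[, 12])
  )
  for (cf in STATE_COEFS) {
    if (cfg$tv[cf]) {
      bm <- g(paste0("bmax_", cf))
      colnames(bm) <- paste0("beta_max_", cf, "[", cfg$cond_keys, "]")
      out <- cbind(out, bm)
      raw <- g(paste0("draw_", cf))
      for (ci in seq_along(cfg$cond_keys)) {
        rsub <- raw[, (ci - 1) * 11 + 1:11, drop = FALSE]
        dl <- t(apply(rsub, 1, softmax_delta))
        colnames(dl) <- paste0("delta_", cf, "[", cfg$cond_keys[ci], "].",
                               1:12)
        out <- cbind(out, dl)
      }
    } else {
      b <- g(paste0("b_", cf))
      colnames(b) <- paste0(cf, "[", cfg$cond_keys, "]")
      out <- cbind(out, b)
    }
  }
  gm <- g("gamma")
  colnames(gm) <- paste0("gamma[", cfg$cond_keys, "]")
  out <- cbind(out, gm)
  if (cfg$re) {
    si <- exp(g("lsd_ind")); sg <- exp(g("lsd_grp"))
    colnames(si) <- paste0("sd_ind_", STATE_COEFS)
    colnames(sg) <- paste0("sd_grp_", STATE_COEFS)
    out <- cbind(out, si, sg)
  }
  out
}

#' @export
print.shmdm_fit <- function(x, ...) {
  cat(sprintf("<shmdm_fit> model '%s', %d steps in %d segments, %d conditions\n",
              x$model, x$n_steps, x$n_segments, length(x$cond_keys)))
  cat(sprintf("  log-likelihood at mode: %.2f; converged: %s\n",
              x$loglik, x$converged))
  cat(sprintf("  max split-Rhat: %.3f; min ESS: %.0f (on %d draws)\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE), nrow(x$draws)))
  invisible(x)
}

# per-draw switching coefficient for one condition at given minutes
draw_coef <- function(fit, cf, key, minutes) {
  d <- fit$draws
  if (fit$cfg$tv[cf]) {
    bm <- d[, paste0("beta_max_", cf, "[", key, "]")]
    dl <- d[, paste0("delta_", cf, "[", key, "].", 1:12), drop = FALSE]
    cum <- t(apply(dl, 1, cumsum))
    cum[, minutes, drop = FALSE] * bm  # n_draws x n_minutes
  } else {
    matrix(d[, paste0(cf, "[", key, "]")], nrow(d), length(minutes))
  }
}

#' Posterior switch-probability surface for one condition
#'
#' Evaluates, for every retained draw, the probability of switching from
#' individual exploration to social relocation averaged over a covariate
#' grid — by default the condition's empirical distribution of covariates
#' over the seconds when at least one exploiting player was visible
#' (V = 1). The result is the draw-level distribution of the baseline
#' switching probability used for condition contrasts.
#'
#' @param fit an [fit_shmdm()] result.
#' @param incentive,environment condition labels.
#' @param newdata optional grid: data.frame with columns `D`, `N`, `T`,
#'   `minute` (V = 1 is implied).
#' @return numeric vector with one averaged probability per draw.
#' @export
switch_probability_surface <- function(fit, incentive, environment,
                                       newdata = NULL) {
  stopifnot(inherits(fit, "shmdm_fit"))
  key <- cond_key(incentive, environment)
  if (!key %in% fit$cond_keys) stop("unknown condition: ", key)
  grid <- newdata
  if (is.null(grid)) {
    grid <- fit$grids[[key]]
    if (is.null(grid) || nrow(grid) == 0) stop("no V = 1 grid available")
    names(grid)[names(grid) == "D0"] <- "D"
    names(grid)[names(grid) == "N0"] <- "N"
  }
  stopifnot(nrow(grid) > 0,
            all(c("D", "N", "T", "minute") %in% names(grid)))
  minutes <- pmin(pmax(as.integer(grid$minute), 1L), 12L)
  n_draws <- nrow(fit$draws)
  acc <- numeric(n_draws)
  # coefficient draws at each distinct minute, then average over the grid
  um <- sort(unique(minutes))
  co <- lapply(STATE_COEFS, function(cf) draw_coef(fit, cf, key, um))
  names(co) <- STATE_COEFS
  mi <- match(minutes, um)
  for (d in seq_len(n_draws)) {
    eta <- co$alpha[d, mi] + co$beta_V[d, mi] +
      co$beta_D[d, mi] * grid$D + co$beta_N[d, mi] * grid$N +
      co$beta_T[d, mi] * grid$T
    acc[d] <- mean(stats::plogis(eta))
  }
  acc
}

#' Posterior contrast summary
#'
#' Mean, 90% highest-density interval and evidence ratio of a draw vector
#' (or of the difference of two draw vectors).
#'
#' @param x numeric draw vector.
#' @param y optional second draw vector; the contrast is `x - y`.
#' @param direction direction of the evidence ratio.
#' @param prob HPDI mass.
#' @return list of class `shmdm_contrast` with `mean`, `hpdi`, `er`.
#' @export
contrast <- function(x, y = NULL, direction = c("greater", "less"),
                     prob = 0.9) {
  direction <- match.arg(direction)
  if (!is.null(y)) {
    stopifnot(length(x) == length(y))
    x <- x - y
  }
  if (length(x) < 100) stop("need at least 100 draws")
  structure(list(mean = mean(x), hpdi = hpdi(x, prob),
                 er = evidence_ratio(x, direction), prob = prob,
                 direction = direction),
            class = "shmdm_contrast")
}

#' @export
print.shmdm_contrast <- function(x, ...) {
  cat(sprintf("%.3f [%.3f, %.3f], ER (%s) = %s\n", x$mean,
              x$hpdi[1], x$hpdi[2], x$direction, x$er$label))
  invisible(x)
}
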