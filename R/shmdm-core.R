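# Core of the social hidden Markov decision model: a two-state HMM over
# "individual exploration" (I) and "social relocation" (S) with von Mises
# turning-angle, normal change-in-distance and log-normal bearing
# emissions, and a covariate-dependent switching probability
#   P(I -> S at t) = logit^-1(alpha + bV*V_t + bD*V_t*D_t + bN*V_t*N_t + bT*T_t)
# per incentive x environment condition. D and N are gated by V so that
# distance and co-exploiter effects only act when an exploiting player is
# actually visible. The reverse switch S -> I is a condition-specific
# intercept gamma. Exploitation is observed and masked out; the latent
# chain restarts in I at the start of every valid segment.

STATE_COEFS <- c("alpha", "beta_V", "beta_D", "beta_N", "beta_T")

#' Construct model parameters
#'
#' @param emission list with elements `I` and `S`, each a list with
#'   `vm_mu`, `vm_kappa` (von Mises turning angle), `dd_mu`, `dd_sigma`
#'   (normal change in distance, m), `lb_mu`, `lb_sigma` (log-normal
#'   relative bearing).
#' @param transition data.frame with columns `incentive`, `environment`,
#'   `alpha`, `beta_V`, `beta_D`, `beta_N`, `beta_T`, `gamma` (one row per
#'   condition).
#' @param tv optional time-varying structure: named list (names among
#'   `alpha`, `beta_V`, `beta_D`, `beta_N`, `beta_T`), each element a list
#'   with `beta_max` (named vector, one entry per condition key
#'   `"incentive:environment"`) and `delta` (matrix, one row per condition
#'   key, each row a length-12 simplex). When a coefficient has a
#'   time-varying entry it replaces the static column.
#' @param hierarchy optional list with matrices `individual` and/or
#'   `group`: per-unit additive offsets on the five transition
#'   coefficients (columns `alpha`..`beta_T`, rownames = unit ids).
#' @return object of class `shmdm_params`.
#' @export
shmdm_params <- function(emission, transition, tv = NULL, hierarchy = NULL) {
  for (s in c("I", "S")) {
    e <- emission[[s]]
    stopifnot(!is.null(e), e$vm_kappa >= 0, e$dd_sigma > 0, e$lb_sigma > 0)
  }
  stopifnot(is.data.frame(transition),
            all(c("incentive", "environment", STATE_COEFS, "gamma") %in%
                names(transition)))
  if (!is.null(tv)) {
    stopifnot(all(names(tv) %in% STATE_COEFS))
    for (cf in names(tv)) {
      d <- tv[[cf]]$delta
      stopifnot(is.matrix(d), all(d >= 0),
                all(abs(rowSums(d) - 1) < 1e-8))
    }
  }
  structure(list(emission = emission, transition = transition, tv = tv,
                 hierarchy = hierarchy),
            class = "shmdm_params")
}

cond_key <- function(incentive, environment) {
  paste(incentive, environment, sep = ":")
}

#' Monotonic (ordered-categorical) coefficient at a given minute
#'
#' The effect at minute `minute` is the total effect `beta_max` times the
#' cumulative sum of the simplex `delta` up to that minute:
#' `beta_max * sum(delta[1:minute])`. With a uniform simplex the profile
#' is linear in the minute; at the final minute the full `beta_max` is
#' returned because the simplex sums to one.
#'
#' @param beta_max total effect on the logit scale.
#' @param delta non-negative simplex (sums to 1), one entry per minute.
#' @param minute integer (vector) in `1:length(delta)`.
#' @return coefficient value(s).
#' @examples
#' monotonic_coeff(2, rep(1 / 12, 12), 6) # half the total effect
#' @export
monotonic_coeff <- function(beta_max, delta, minute) {
  stopifnot(all(delta >= 0), abs(sum(delta) - 1) < 1e-8)
  if (any(minute < 1 | minute > length(delta))) {
    stop("minute out of range 1..", length(delta))
  }
  beta_max * cumsum(delta)[minute]
}

# resolve the five transition coefficients for a vector of steps
resolve_coefs <- function(params, key, minute, player = NULL, group = NULL) {
  tr <- params$transition
  rows <- match(key, cond_key(tr$incentive, tr$environment))
  if (anyNA(rows)) stop("condition not present in transition table")
  out <- sapply(STATE_COEFS, function(cf) tr[[cf]][rows])
  if (!is.matrix(out)) out <- matrix(out, nrow = length(rows),
                                     dimnames = list(NULL, STATE_COEFS))
  if (!is.null(params$tv)) {
    for (cf in names(params$tv)) {
      bm <- params$tv[[cf]]$beta_max
      dl <- params$tv[[cf]]$delta
      krow <- match(key, rownames(dl))
      if (anyNA(krow)) stop("condition not present in tv delta matrix")
      cum <- t(apply(dl, 1, cumsum))
      out[, cf] <- bm[key] * cum[cbind(krow, minute)]
    }
  }
  h <- params$hierarchy
  if (!is.null(h)) {
    if (!is.null(h$individual) && !is.null(player)) {
      ri <- match(as.character(player), rownames(h$individual))
      add <- h$individual[ri, STATE_COEFS, drop = FALSE]
      add[is.na(add)] <- 0
      out <- out + add
    }
    if (!is.null(h$group) && !is.null(group)) {
      rg <- match(as.character(group), rownames(h$group))
      add <- h$group[rg, STATE_COEFS, drop = FALSE]
      add[is.na(add)] <- 0
      out <- out + add
    }
  }
  out
}

# logit of P(I -> S) for vectors of covariates (D, N already gated: the
# caller passes 0 where V = 0)
eta_switch <- function(coefs, V, D, N, T) {
  coefs[, "alpha"] + coefs[, "beta_V"] * V + coefs[, "beta_D"] * V * D +
    coefs[, "beta_N"] * V * N + coefs[, "beta_T"] * T
}

#' Transition matrix at one time step
#'
#' Row-stochastic 2x2 matrix over the latent states (I, S). The switch
#' probability I to S follows the logistic rule in the package overview;
#' S to I is the inverse logit of the condition's `gamma`.
#'
#' @param params an [shmdm_params()].
#' @param incentive,environment condition labels matching the transition
#'   table.
#' @param V visibility indicator (0/1).
#' @param D z-scored distance to the closest visible exploiting player
#'   (required when `V = 1`).
#' @param N number of other players at the closest visible patch
#'   (required when `V = 1`).
#' @param T z-scored time since the focal's last success.
#' @param minute minute of the round (1-12), needed when `params`
#'   contains time-varying coefficients.
#' @param player,group optional unit ids for hierarchical offsets.
#' @return 2x2 matrix with rownames/colnames `c("I", "S")`.
#' @examples
#' tr <- data.frame(incentive = "individual", environment = "concentrated",
#'                  alpha = -2, beta_V = 1, beta_D = 0, beta_N = 0,
#'                  beta_T = 0, gamma = 0)
#' em <- list(vm_mu = 0, vm_kappa = 1, dd_mu = 0, dd_sigma = 1,
#'            lb_mu = 0, lb_sigma = 1)
#' p <- shmdm_params(list(I = em, S = em), tr)
#' transition_matrix(p, "individual", "concentrated", V = 1, D = 0, N = 0,
#'                   T = 0)["I", "S"] # logit^-1(-1)
#' @export
transition_matrix <- function(params, incentive, environment, V, D = NULL,
                              N = NULL, T = 0, minute = 1,
                              player = NULL, group = NULL) {
  stopifnot(inherits(params, "shmdm_params"), V %in% c(0, 1))
  if (V == 1 && (is.null(D) || is.null(N) || is.na(D) || is.na(N))) {
    stop("V = 1 requires D and N")
  }
  if (V == 0) { D <- 0; N <- 0 }
  key <- cond_key(incentive, environment)
  coefs <- resolve_coefs(params, key, minute, player, group)
  p_is <- inv_logit(eta_switch(coefs, V, D, N, T))
  tr <- params$transition
  row <- match(key, cond_key(tr$incentive, tr$environment))
  p_si <- inv_logit(tr$gamma[row])
  m <- matrix(c(1 - p_is, p_is, p_si, 1 - p_si), 2, 2, byrow = TRUE,
              dimnames = list(c("I", "S"), c("I", "S")))
  m
}

#' State-dependent log density of one observation
#'
#' Sum of the log densities of the channels present: von Mises for the
#' turning angle, normal for the change in distance, log-normal for the
#' relative bearing. Missing social channels (no exploiting player
#' visible) contribute zero — marginalization, not imputation.
#'
#' @param theta turning angle (radians; must be present).
#' @param ddist change in distance (m) or `NA`.
#' @param bearing relative bearing (rad, > 0) or `NA`.
#' @param state `"I"` or `"S"`.
#' @param params an [shmdm_params()] (its `emission` element is used).
#' @return log density (vectorized over the inputs).
#' @export
emission_logdensity <- function(theta, ddist, bearing, state, params) {
  e <- params$emission[[state]]
  if (is.null(e)) stop("unknown state: ", state)
  if (any(!is.na(bearing) & bearing <= 0)) {
    stop("bearing must be strictly positive where present")
  }
  ld <- dvonmises(theta, e$vm_mu, e$vm_kappa, log = TRUE)
  dd <- ifelse(is.na(ddist), 0,
               stats::dnorm(ddist, e$dd_mu, e$dd_sigma, log = TRUE))
  bb <- ifelse(is.na(bearing), 0,
               stats::dlnorm(bearing, e$lb_mu, e$lb_sigma, log = TRUE))
  ld + dd + bb
}

# ---- internal: prepared step table ---------------------------------------

# Extract the valid, segment-ordered steps from a state_series-like
# data.frame and precompute the index structure used by the vectorized
# forward/Viterbi recursions.
prep_steps <- function(ss, params = NULL) {
  stopifnot(all(c("theta", "V", "T", "segment") %in% names(ss)))
  steps <- ss[!is.na(ss$segment), , drop = FALSE]
  if (nrow(steps) == 0) return(NULL)
  ord <- order(steps$segment, steps$t %||% seq_len(nrow(steps)))
  steps <- steps[ord, , drop = FALSE]
  if (!"incentive" %in% names(steps)) {
    if (!is.null(params) && nrow(params$transition) != 1) {
      stop("data lack condition labels but the transition table has ",
           nrow(params$transition), " rows")
    }
    steps$incentive <- if (is.null(params)) "individual" else
      params$transition$incentive[1]
    steps$environment <- if (is.null(params)) "concentrated" else
      params$transition$environment[1]
  }
  if (!"minute" %in% names(steps)) steps$minute <- 1L
  if (!"ddist" %in% names(steps)) steps$ddist <- NA_real_
  if (!"bearing" %in% names(steps)) steps$bearing <- NA_real_
  steps$D0 <- ifelse(steps$V == 1, steps$D, 0)
  steps$N0 <- ifelse(steps$V == 1, as.numeric(steps$N), 0)
  if (any(steps$V == 1 & (is.na(steps$D0) | is.na(steps$N0)))) {
    stop("V = 1 steps with missing D or N")
  }
  seg_ids <- unique(steps$segment)
  seg_idx <- match(steps$segment, seg_ids)
  pos <- sequence(rle(seg_idx)$lengths)
  maxlen <- max(pos)
  rows_by_pos <- split(seq_len(nrow(steps)), pos)
  seg_by_pos <- split(seg_idx, pos)
  list(steps = steps, seg_idx = seg_idx, pos = pos, n_seg = length(seg_ids),
       maxlen = maxlen, rows_by_pos = rows_by_pos, seg_by_pos = seg_by_pos,
       seg_ids = seg_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-step transition log-probabilities and emission log-densities
step_quantities <- function(pp, params) {
  steps <- pp$steps
  key <- cond_key(steps$incentive, steps$environment)
  coefs <- resolve_coefs(params, key, steps$minute,
                         player = steps$player_id %||% NULL,
                         group = steps$group_id %||% NULL)
  eta <- eta_switch(coefs, steps$V, steps$D0, steps$N0, steps$T)
  tr <- params$transition
  grow <- match(key, cond_key(tr$incentive, tr$environment))
  eta_si <- tr$gamma[grow]
  L <- cbind(
    emission_logdensity(steps$theta, steps$ddist, steps$bearing, "I", params),
    emission_logdensity(steps$theta, steps$ddist, steps$bearing, "S", params)
  )
  list(
    L = L,
    lp_is = stats::plogis(eta, log.p = TRUE),
    lp_not_is = stats::plogis(-eta, log.p = TRUE),
    lp_si = stats::plogis(eta_si, log.p = TRUE),
    lp_not_si = stats::plogis(-eta_si, log.p = TRUE)
  )
}

#' Forward-algorithm log marginal likelihood
#'
#' Sums, over all latent-state paths, the joint density of the observed
#' channels, recursively in log space. Every segment starts in the
#' individual-exploration state with probability one. Segments are
#' independent, so the result does not depend on their order.
#'
#' @param ss a [state_series()] (or compatible data.frame with columns
#'   `theta`, `ddist`, `bearing`, `V`, `D`, `N`, `T`, `minute`,
#'   `segment`, and `incentive`/`environment` when the transition table
#'   has several conditions).
#' @param params an [shmdm_params()].
#' @return scalar log likelihood; `0` with a warning when there are no
#'   valid segments.
#' @export
forward_loglik <- function(ss, params) {
  pp <- prep_steps(ss, params)
  if (is.null(pp)) {
    warning("no valid segments: log likelihood is 0")
    return(0)
  }
  .forward_pp(pp, params)
}

# recursion on a prepared step table (shared with the fitting backend)
.forward_pp <- function(pp, params) {
  .forward_rec(pp, step_quantities(pp, params))
}

.forward_rec <- function(pp, q) {
  alpha_I <- rep(-Inf, pp$n_seg); alpha_S <- rep(-Inf, pp$n_seg)
  r1 <- pp$rows_by_pos[[1]]; s1 <- pp$seg_by_pos[[1]]
  alpha_I[s1] <- q$L[r1, 1]
  for (p in seq_len(pp$maxlen)[-1]) {
    rows <- pp$rows_by_pos[[p]]
    sg <- pp$seg_by_pos[[p]]
    aI <- alpha_I[sg]; aS <- alpha_S[sg]
    newI <- lse2(aI + q$lp_not_is[rows], aS + q$lp_si[rows]) + q$L[rows, 1]
    newS <- lse2(aI + q$lp_is[rows], aS + q$lp_not_si[rows]) + q$L[rows, 2]
    alpha_I[sg] <- newI; alpha_S[sg] <- newS
  }
  sum(lse2(alpha_I, alpha_S))
}

#' Viterbi decoding of the most likely latent-state path
#'
#' Dynamic-programming maximization of the joint probability of states and
#' observations, per segment, with each segment constrained to start in
#' the individual-exploration state. Ties are broken deterministically in
#' favor of state I.
#'
#' @inheritParams forward_loglik
#' @return character vector of states (`"I"`/`"S"`), one per valid step,
#'   in the row order of the valid steps of `ss` (sorted by segment and
#'   time).
#' @export
viterbi <- function(ss, params) {
  pp <- prep_steps(ss, params)
  if (is.null(pp)) {
    warning("no valid segments: empty path")
    return(character(0))
  }
  q <- step_quantities(pp, params)
  n_seg <- pp$n_seg; maxlen <- pp$maxlen
  dI <- rep(-Inf, n_seg); dS <- rep(-Inf, n_seg)
  bpI <- matrix(NA, maxlen, n_seg); bpS <- matrix(NA, maxlen, n_seg)
  r1 <- pp$rows_by_pos[[1]]; s1 <- pp$seg_by_pos[[1]]
  dI[s1] <- q$L[r1, 1]
  for (p in seq_len(maxlen)[-1]) {
    rows <- pp$rows_by_pos[[p]]
    sg <- pp$seg_by_pos[[p]]
    aI <- dI[sg]; aS <- dS[sg]
    toI_fromI <- aI + q$lp_not_is[rows]; toI_fromS <- aS + q$lp_si[rows]
    chooseI <- toI_fromI >= toI_fromS       # tie -> I
    dI[sg] <- pmax(toI_fromI, toI_fromS) + q$L[rows, 1]
    bpI[p, sg] <- chooseI
    toS_fromI <- aI + q$lp_is[rows]; toS_fromS <- aS + q$lp_not_si[rows]
    chooseI_S <- toS_fromI >= toS_fromS
    dS[sg] <- pmax(toS_fromI, toS_fromS) + q$L[rows, 2]
    bpS[p, sg] <- chooseI_S
  }
  path <- character(nrow(pp$steps))
  seg_len <- tabulate(pp$seg_idx, nbins = n_seg)
  for (sg in seq_len(n_seg)) {
    len <- seg_len[sg]
    states <- integer(len)
    states[len] <- if (dI[sg] >= dS[sg]) 1L else 2L  # tie -> I
    if (len > 1) {
      for (p in len:2) {
        fromI <- if (states[p] == 1L) bpI[p, sg] else bpS[p, sg]
        states[p - 1] <- if (isTRUE(fromI)) 1L else 2L
      }
    }
    path[pp$seg_idx == sg] <- c("I", "S")[states]
  }
  path
}

#' Decode a full per-second state sequence for display
#'
#' Runs [viterbi()] on the valid segments and re-inserts the observed
#' exploitation state and the omitted gaps: seconds where the focal player
#' was exploiting are labeled `"E"`; invalid non-exploiting seconds are
#' labeled `"I"` (the state a player is reset to after every omission).
#'
#' @param ss a [state_series()].
#' @param params an [shmdm_params()] or an [fit_shmdm()] result (its MAP
#'   parameters are used).
#' @return `ss` with an added `state` column.
#' @export
decode_states <- function(ss, params) {
  if (inherits(params, "shmdm_fit")) params <- params$map
  path <- viterbi(ss, params)
  steps <- which(!is.na(ss$segment))
  ord <- order(ss$segment[steps], ss$t[steps])
  ss$state <- ifelse(ss$exploiting %||% FALSE, "E", "I")
  ss$state[steps[ord]] <- path
  ss
}

#' Simulate observations from the generative model
#'
#' Exact generative twin of the fitted model: latent states follow the
#' covariate-dependent switching chain (restarting in I at every segment
#' start), and the observation channels are drawn from the state's von
#' Mises / normal / log-normal laws. Social channels are emitted as
#' missing whenever no exploiting player is visible (`V = 0`).
#'
#' @param params an [shmdm_params()].
#' @param covariates data.frame with columns `segment`, `V`, `D`, `N`,
#'   `T`, and optionally `t`, `minute`, `incentive`, `environment`,
#'   `player_id`, `group_id`. `D`/`N` may be `NA` where `V = 0`.
#' @param seed optional integer seed.
#' @return `covariates` augmented with `state`, `theta`, `ddist`,
#'   `bearing`.
#' @export
simulate_from_model <- function(params, covariates, seed = NULL) {
  stopifnot(inherits(params, "shmdm_params"))
  if (!is.null(seed)) set.seed(seed)
  cv <- covariates
  if (!"minute" %in% names(cv)) cv$minute <- 1L
  if (!"t" %in% names(cv)) cv$t <- seq_len(nrow(cv))
  if (!"incentive" %in% names(cv)) {
    stopifnot(nrow(params$transition) == 1)
    cv$incentive <- params$transition$incentive[1]
    cv$environment <- params$transition$environment[1]
  }
  stopifnot(all(is.finite(cv$T)), all(cv$V %in% c(0, 1)))
  if (any(cv$V == 1 & (is.na(cv$D) | is.na(cv$N)))) {
    stop("V = 1 steps require finite D and N")
  }
  ord <- order(cv$segment, cv$t)
  cv <- cv[ord, , drop = FALSE]
  key <- cond_key(cv$incentive, cv$environment)
  coefs <- resolve_coefs(params, key, cv$minute,
                         player = cv$player_id %||% NULL,
                         group = cv$group_id %||% NULL)
  D0 <- ifelse(cv$V == 1, cv$D, 0)
  N0 <- ifelse(cv$V == 1, as.numeric(cv$N), 0)
  p_is <- inv_logit(eta_switch(coefs, cv$V, D0, N0, cv$T))
  tr <- params$transition
  p_si <- inv_logit(tr$gamma[match(key, cond_key(tr$incentive,
                                                 tr$environment))])
  n <- nrow(cv)
  state <- integer(n)
  new_seg <- c(TRUE, cv$segment[-1] != cv$segment[-n])
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    if (new_seg[i]) {
      state[i] <- 1L
    } else if (state[i - 1] == 1L) {
      state[i] <- if (u[i] < p_is[i]) 2L else 1L
    } else {
      state[i] <- if (u[i] < p_si[i]) 1L else 2L
    }
  }
  lab <- c("I", "S")[state]
  theta <- numeric(n); dd <- rep(NA_real_, n); bb <- rep(NA_real_, n)
  for (s in 1:2) {
    e <- params$emission[[c("I", "S")[s]]]
    idx <- which(state == s)
    if (!length(idx)) next
    theta[idx] <- rvonmises(length(idx), e$vm_mu, e$vm_kappa)
    vis <- idx[cv$V[idx] == 1]
    dd[vis] <- stats::rnorm(length(vis), e$dd_mu, e$dd_sigma)
    bb[vis] <- stats::rlnorm(length(vis), e$lb_mu, e$lb_sigma)
  }
  cv$state <- lab
  cv$theta <- theta
  cv$ddist <- dd
  cv$bearing <- bb
  cv
}
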