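# Penalized-maximum-likelihood backend: optimize a negative log posterior
# in an unconstrained parameterization and draw from the Gaussian
# (Laplace) approximation at the mode. All model fits in the package run
# through this machine.

laplace_machine <- function(negloglik, theta0, n_draws = 1000,
                            control = list(), seed = NULL) {
  ctrl <- utils::modifyList(list(maxit = 1000, reltol = 1e-8), control)
  opt <- stats::optim(theta0, negloglik, method = "BFGS", control = ctrl)
  H <- stats::optimHess(opt$par, negloglik)
  H <- (H + t(H)) / 2
  p <- length(theta0)
  ridge <- 0
  R <- NULL
  base <- max(abs(diag(H)), 1)
  for (k in 0:10) {
    Hk <- H + diag(ridge, p)
    R <- tryCatch(chol(Hk), error = function(e) NULL)
    if (!is.null(R)) break
    ridge <- if (ridge == 0) 1e-8 * base else ridge * 10
  }
  hessian_ok <- !is.null(R) && ridge <= 1e-4 * base
  if (is.null(R)) {
    # last resort: independent draws at curvature floor
    R <- diag(sqrt(base), p)
    hessian_ok <- FALSE
  }
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n_draws * p), p, n_draws)
  draws <- t(opt$par + backsolve(R, z))
  list(par = opt$par, draws = draws, value = opt$value,
       convergence = opt$convergence, hessian_ok = hessian_ok,
       ridge = ridge)
}

# shared Gaussian penalty helper: -sum log N(x | mu, sd)
neg_lp_gauss <- function(x, mu, sd) {
  -sum(stats::dnorm(x, mu, sd, log = TRUE))
}
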