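# Small numerical helpers shared across the package.

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi))
#' @export
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # %% maps onto [-pi, pi); move the -pi atom to +pi so the range is (-pi, pi]
  w[w == -pi & is.finite(w)] <- pi
  w
}

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

# elementwise log(exp(a) + exp(b)) that survives -Inf on either side
lse2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' von Mises density
#'
#' Density of the von Mises distribution on the circle, the standard
#' emission law for turning angles in movement HMMs. At `kappa = 0` it
#' reduces to the uniform circular density `1 / (2 * pi)`.
#'
#' @param x numeric vector of angles (radians).
#' @param mu mean direction (radians).
#' @param kappa concentration, `kappa >= 0`.
#' @param log logical; return log density?
#' @return numeric vector of (log) densities.
#' @examples
#' dvonmises(0.3, mu = 0, kappa = 0) # 1 / (2 * pi)
#' @export
dvonmises <- function(x, mu = 0, kappa = 1, log = FALSE) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  # exponentially scaled Bessel keeps this finite for large kappa
  ld <- kappa * (cos(x - mu) - 1) - log(2 * pi) -
    base::log(besselI(kappa, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, `kappa >= 0`.
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-10) {
    return(wrap_angle(stats::runif(n, -pi, pi)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      take <- min(length(th), n - got)
      out[(got + 1):(got + take)] <- th[seq_len(take)]
      got <- got + take
    }
  }
  wrap_angle(out + mu)
}

#' Highest posterior density interval
#'
#' Narrowest interval containing a given fraction of a set of draws.
#'
#' @param x numeric vector of draws.
#' @param prob mass to cover (default 0.9).
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' set.seed(1)
#' hpdi(runif(1e4)) # close to width 0.9
#' @export
hpdi <- function(x, prob = 0.9) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2) stop("need at least 2 finite draws")
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Evidence ratio for a directed effect
#'
#' Posterior odds that an effect lies in the stated direction, the
#' one-sided Bayes-factor analogue used to summarize directed contrasts.
#' When fewer than 1/101 of the draws oppose the direction the ratio is
#' reported as capped (displayed `"> 100"`); with zero opposing draws the
#' numeric value is bounded by the number of draws rather than infinity.
#'
#' @param x numeric vector of draws.
#' @param direction `"greater"` or `"less"` (than `null`).
#' @param null null value, default 0.
#' @return list with `value` (numeric odds, possibly the draw-count bound),
#'   `capped` (logical) and `label` (display string).
#' @export
evidence_ratio <- function(x, direction = c("greater", "less"), null = 0) {
  direction <- match.arg(direction)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 1) stop("no finite draws")
  n_for <- if (direction == "greater") sum(x > null) else sum(x < null)
  n_against <- n - n_for
  if (n_against == 0) {
    return(list(value = n, capped = TRUE, label = paste0("> ", n)))
  }
  er <- n_for / n_against
  capped <- n_against < n / 101
  list(value = er, capped = capped,
       label = if (capped) "> 100" else formatC(er, digits = 3, format = "fg"))
}

# split-chain Gelman-Rubin statistic on a single vector of draws
rhat_split <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  ch <- list(x[seq_len(half)], x[(n - half + 1):n])
  means <- vapply(ch, mean, 0)
  vars <- vapply(ch, stats::var, 0)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# crude effective sample size from the empirical autocorrelation function
ess_basic <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) {
    if (r < 0.05) break
    s <- s + r
  }
  max(1, n / (1 + 2 * s))
}
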