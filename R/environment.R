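# Resource environments: square arena with non-overlapping circular patches.

#' Resource environment configuration
#'
#' Describes a square foraging arena with non-overlapping circular resource
#' patches. Two named presets reproduce the experimental conditions: a
#' `"concentrated"` environment of 5 patches holding 48 coins each and a
#' `"distributed"` environment of 15 patches holding 16 coins each, both in
#' a 90 m x 90 m arena with patch radius 3 m.
#'
#' @param mode `"concentrated"`, `"distributed"` or `"custom"`.
#' @param arena_side side length of the square arena in meters.
#' @param n_patches number of patches (required for `"custom"`).
#' @param coins_per_patch coins initially in each patch (required for
#'   `"custom"`).
#' @param patch_radius patch radius in meters.
#' @return an object of class `env_config`.
#' @examples
#' env_config("concentrated")
#' @export
env_config <- function(mode = c("concentrated", "distributed", "custom"),
                       arena_side = 90, n_patches = NULL,
                       coins_per_patch = NULL, patch_radius = 3) {
  mode <- match.arg(mode)
  if (mode == "concentrated") {
    n_patches <- 5L; coins_per_patch <- 48L
  } else if (mode == "distributed") {
    n_patches <- 15L; coins_per_patch <- 16L
  } else {
    if (is.null(n_patches) || is.null(coins_per_patch))
      stop("custom mode requires n_patches and coins_per_patch")
  }
  stopifnot(arena_side > 0, n_patches >= 0, patch_radius > 0)
  if (n_patches > 0) stopifnot(coins_per_patch >= 1)
  structure(list(mode = mode, arena_side = arena_side,
                 n_patches = as.integer(n_patches),
                 coins_per_patch = as.integer(coins_per_patch),
                 patch_radius = patch_radius),
            class = "env_config")
}

#' @export
print.env_config <- function(x, ...) {
  cat(sprintf("<env_config> %s: %d patches x %d coins, radius %g m, arena %g m\n",
              x$mode, x$n_patches, x$coins_per_patch, x$patch_radius,
              x$arena_side))
  invisible(x)
}

# Rejection-sample one patch center: fully inside the arena, >= 2r from
# every existing center (non-overlap) and >= r from every avoid point.
place_patch_center <- function(existing_xy, config, avoid_xy = NULL,
                               max_tries = 10000L) {
  r <- config$patch_radius
  side <- config$arena_side
  if (side < 2 * r) stop("arena too small for a single patch")
  for (i in seq_len(max_tries)) {
    cx <- stats::runif(1, r, side - r)
    cy <- stats::runif(1, r, side - r)
    ok <- TRUE
    if (!is.null(existing_xy) && nrow(existing_xy) > 0) {
      d2 <- (existing_xy[, 1] - cx)^2 + (existing_xy[, 2] - cy)^2
      if (any(d2 < (2 * r)^2)) ok <- FALSE
    }
    if (ok && !is.null(avoid_xy) && nrow(avoid_xy) > 0) {
      d2 <- (avoid_xy[, 1] - cx)^2 + (avoid_xy[, 2] - cy)^2
      if (any(d2 < r^2)) ok <- FALSE
    }
    if (ok) return(c(cx, cy))
  }
  stop(sprintf("could not place a non-overlapping patch within %d tries",
               max_tries))
}

#' Generate the initial patch layout
#'
#' Places `n_patches` non-overlapping circular patches uniformly at random,
#' each fully inside the arena and (optionally) away from a set of avoided
#' points such as initial avatar positions.
#'
#' @param config an [env_config()].
#' @param seed optional integer seed.
#' @param avoid optional two-column matrix of points (e.g. avatar
#'   positions) that no patch may cover.
#' @param max_tries rejection-sampling budget per patch.
#' @return data.frame with one row per patch: `patch_id`, `x`, `y`,
#'   `radius`, `coins`, `coins_init`, `t_created`, `t_depleted` (NA while
#'   active).
#' @examples
#' p <- make_environment(env_config("concentrated"), seed = 1)
#' nrow(p) # 5
#' @export
make_environment <- function(config, seed = NULL, avoid = NULL,
                             max_tries = 10000L) {
  stopifnot(inherits(config, "env_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_patches
  xy <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    xy <- rbind(xy, place_patch_center(xy, config, avoid, max_tries))
  }
  data.frame(
    patch_id = seq_len(n),
    x = if (n) xy[, 1] else numeric(0),
    y = if (n) xy[, 2] else numeric(0),
    radius = rep(config$patch_radius, n),
    coins = rep(config$coins_per_patch, n),
    coins_init = rep(config$coins_per_patch, n),
    t_created = rep(0, n),
    t_depleted = rep(NA_real_, n)
  )
}

#' Respawn a depleted patch
#'
#' When a patch is depleted a replacement holding the full coin count is
#' generated at a random location that overlaps neither the surviving
#' patches nor any current avatar position, keeping the number of active
#' patches constant through the round.
#'
#' @param patches patch table as returned by [make_environment()]; rows
#'   with `is.na(t_depleted)` are treated as active.
#' @param config an [env_config()].
#' @param avoid optional two-column matrix of avatar positions.
#' @param t_created creation time stamp for the new patch.
#' @param max_tries rejection-sampling budget.
#' @return one-row data.frame for the new patch (with the next `patch_id`).
#' @export
respawn_patch <- function(patches, config, avoid = NULL, t_created = 0,
                          max_tries = 10000L) {
  stopifnot(inherits(config, "env_config"))
  active <- patches[is.na(patches$t_depleted), , drop = FALSE]
  ctr <- place_patch_center(cbind(active$x, active$y), config, avoid,
                            max_tries)
  data.frame(
    patch_id = if (nrow(patches)) max(patches$patch_id) + 1L else 1L,
    x = ctr[1], y = ctr[2], radius = config$patch_radius,
    coins = config$coins_per_patch, coins_init = config$coins_per_patch,
    t_created = t_created, t_depleted = NA_real_
  )
}
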