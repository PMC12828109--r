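## Monte-Carlo calibration of the overshoot corrections.  The statistic,
## viewed at patient-entry updates with complete follow-up, is a random walk
## with increments log(delta_star) + (1 - delta_star) * X where X is the
## rescaled lifetime: X ~ Exp(1) under the null, X ~ Exp(delta_star) under the
## alternative.  The walk drifts downward under the null and upward under the
## alternative (for every delta_star != 1).  gamma0 is the Laplace transform
## E exp(-R) of the excess R over the lower boundary under the null walk;
## gamma1 the same for the upper boundary under the alternative walk.

# run a seed-local expression without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Simulate the overshoot correction factor for one hypothesis
#'
#' Runs `n_reps` independent copies of the SPRT random walk with increments
#' `log(delta_star) + (1 - delta_star) * X` until first passage: under the
#' alternative (`X ~ Exp(delta_star)`, positive drift) across `+level`, under
#' the null (`X ~ Exp(1)`, negative drift) across `-level`.  The excess
#' `R >= 0` beyond the boundary at crossing is recorded and the Monte-Carlo
#' estimate of the Laplace transform `gamma = E[exp(-R)]` returned.  Because
#' the excess distribution converges as the level grows, the estimate is
#' insensitive to `level` once `level` is of order 10.
#'
#' @param delta_star Effective hazard ratio (> 0, != 1).
#' @param hypothesis `"null"` (estimates `gamma0`) or `"alternative"`
#'   (`gamma1`).
#' @param level Boundary height for the first-passage simulation; default 15.
#' @param n_reps Number of walk replications (>= 1).
#' @param seed RNG seed (required: calibration results must be reproducible).
#' @param block Number of walk steps generated per vectorised batch.
#' @return An object of class `serm_gamma_estimate`: a list with `delta_star`,
#'   `hypothesis`, `gamma_hat`, `mc_se`, `n_reps`, `level`, `seed`.
#' @examples
#' simulate_gamma(0.734, "null", n_reps = 1e4, seed = 1)
#' @export
simulate_gamma <- function(delta_star, hypothesis = c("null", "alternative"),
                           level = 15, n_reps = 1e5, seed, block = 64L) {
  hypothesis <- match.arg(hypothesis)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!is.numeric(n_reps) || n_reps < 1)
    stop("`n_reps` must be >= 1", call. = FALSE)
  if (!is.numeric(delta_star) || delta_star <= 0 || delta_star == 1)
    stop("`delta_star` must be positive and != 1", call. = FALSE)
  if (level <= 0) stop("`level` must be positive", call. = FALSE)
  n_reps <- as.integer(n_reps)
  up <- hypothesis == "alternative"
  rate <- if (up) delta_star else 1
  drift <- log(delta_star) + (1 - delta_star) / rate
  if ((up && drift <= 0) || (!up && drift >= 0))
    stop("walk drift has the wrong sign for the chosen hypothesis",
         call. = FALSE)
  block <- as.integer(block)

  excess <- .with_seed(seed, {
    walk <- numeric(n_reps)
    exc <- rep(NA_real_, n_reps)
    active <- seq_len(n_reps)
    while (length(active)) {
      na <- length(active)
      incr <- log(delta_star) + (1 - delta_star) * stats::rexp(block * na, rate)
      csum <- cumsum(incr)
      m <- matrix(csum, nrow = block)
      # column-wise cumulative sums via the global cumsum minus column offsets
      offset <- c(0, csum[block * seq_len(na - 1)])
      path <- sweep(m, 2L, offset) + rep(walk[active], each = block)
      hit <- if (up) path > level else path < -level
      crossed <- colSums(hit) > 0L
      if (any(crossed)) {
        cols <- which(crossed)
        first_row <- apply(hit[, cols, drop = FALSE], 2L, which.max)
        val <- path[cbind(first_row, cols)]
        exc[active[cols]] <- if (up) val - level else -level - val
      }
      keep <- which(!crossed)
      walk[active[keep]] <- path[block, keep]
      active <- active[keep]
    }
    exc
  })

  g <- exp(-excess)
  structure(
    list(delta_star = delta_star, hypothesis = hypothesis,
         gamma_hat = mean(g), mc_se = stats::sd(g) / sqrt(n_reps),
         n_reps = n_reps, level = level, seed = seed),
    class = "serm_gamma_estimate")
}

#' @export
print.serm_gamma_estimate <- function(x, ...) {
  cat(sprintf(
    "gamma%s(delta* = %.4g) = %.4f (MC se %.5f; %d reps at level %.3g)\n",
    if (x$hypothesis == "null") "0" else "1",
    x$delta_star, x$gamma_hat, x$mc_se, x$n_reps, x$level))
  invisible(x)
}

#' Calibrate both correction factors on a grid of effective ratios
#'
#' Runs [simulate_gamma()] for the null and alternative walks at each value of
#' `delta_star_grid`, with deterministic per-point seeds derived from `seed`.
#'
#' @param delta_star_grid Numeric vector of effective ratios.
#' @inheritParams simulate_gamma
#' @return A data frame with columns `delta_star`, `gamma0_hat`, `gamma0_se`,
#'   `gamma1_hat`, `gamma1_se`.
#' @export
calibrate_gamma <- function(delta_star_grid, n_reps = 1e5, seed, level = 15) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  rows <- lapply(seq_along(delta_star_grid), function(i) {
    ds <- delta_star_grid[i]
    g0 <- simulate_gamma(ds, "null", level, n_reps,
                         seed = .child_seed(seed, 2L * i - 1L))
    g1 <- simulate_gamma(ds, "alternative", level, n_reps,
                         seed = .child_seed(seed, 2L * i))
    data.frame(delta_star = ds,
               gamma0_hat = g0$gamma_hat, gamma0_se = g0$mc_se,
               gamma1_hat = g1$gamma_hat, gamma1_se = g1$mc_se)
  })
  do.call(rbind, rows)
}

#' Fit the sine approximation to calibrated gamma values
#'
#' Least-squares fit of `gamma = a1 * sin(a2 * delta_star) + a3` to a grid of
#' (delta_star, gamma) pairs, initialised from the packaged coefficient table
#' for the range containing the grid.
#'
#' @param delta_star Numeric vector of effective ratios (>= 10 points, all
#'   inside one fitted range).
#' @param gamma Matching vector of gamma estimates.
#' @param hypothesis `"null"` or `"alternative"`: selects the coefficient row
#'   used as the starting value.
#' @return An object of class `serm_gamma_fit`: list with `coefficients`
#'   (named a1, a2, a3), `residuals`, `rss`, and the `nls` fit.
#' @export
fit_trig <- function(delta_star, gamma,
                     hypothesis = c("null", "alternative")) {
  hypothesis <- match.arg(hypothesis)
  if (length(delta_star) != length(gamma))
    stop("`delta_star` and `gamma` must have equal length", call. = FALSE)
  if (length(delta_star) < 10L)
    stop("need at least 10 grid points for a stable 3-parameter fit",
         call. = FALSE)
  lo <- min(delta_star); hi <- max(delta_star)
  tab <- .gamma_coef[.gamma_coef$hypothesis == hypothesis, ]
  row <- tab[lo >= tab$range_low & hi <= tab$range_high, ]
  if (nrow(row) != 1L)
    stop("grid must lie inside a single fitted range ([0.2, 0.8] or [1.2, 2.0])",
         call. = FALSE)
  dat <- data.frame(x = delta_star, y = gamma)
  start <- list(a1 = row$a1, a2 = row$a2, a3 = row$a3)
  fit <- tryCatch(
    # scaleOffset makes the convergence test robust to (near-)zero residuals
    stats::nls(y ~ a1 * sin(a2 * x) + a3, data = dat, start = start,
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) {
      r0 <- dat$y - (start$a1 * sin(start$a2 * dat$x) + start$a3)
      stop(sprintf(
        "sine fit did not converge (%s); RSS at initialisation = %.4g",
        conditionMessage(e), sum(r0^2)), call. = FALSE)
    })
  co <- stats::coef(fit)
  structure(list(coefficients = co, residuals = stats::resid(fit),
                 rss = sum(stats::resid(fit)^2), fit = fit,
                 hypothesis = hypothesis),
            class = "serm_gamma_fit")
}

#' @export
print.serm_gamma_fit <- function(x, ...) {
  cat(sprintf(
    "sine fit (%s): gamma = %.4f * sin(%.4f * delta*) + %.4f  (RSS %.3g)\n",
    x$hypothesis, x$coefficients[["a1"]], x$coefficients[["a2"]],
    x$coefficients[["a3"]], x$rss))
  invisible(x)
}
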