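# Simulation-based sample-size determination: how many devices are needed
# to estimate the median discard time of a Weibull distribution to within a
# stated precision with stated confidence.

#' Weibull scale from the distribution mean
#'
#' `scale = mean / gamma(1 + 1/shape)`.
#'
#' @param mean Distribution mean in days.
#' @param shape Weibull shape (> 0).
#' @return Scale in days.
#' @examples
#' weibull_scale_from_mean(180, 3)  # ~201.6
#' @export
weibull_scale_from_mean <- function(mean, shape) {
  stopifnot(mean > 0, shape > 0)
  mean / gamma(1 + 1 / shape)
}

# Sample median: mean of the two central order statistics for even n.
sample_median <- function(x) stats::median.default(x)

#' Simulated coverage of the sample median over a sample-size grid
#'
#' For each candidate sample size n, draws `reps` datasets of size n from a
#' Weibull with the given mean and shape and records the fraction whose
#' sample median falls within `tol` days (closed interval) of the true
#' median `scale * log(2)^(1/shape)`. The chosen sample size is the
#' smallest grid n whose coverage reaches `conf`. Each (grid point) uses a
#' counter-derived seed so reruns are reproducible and memory stays O(n).
#'
#' @param mean Planning mean of the discard-time distribution, days.
#' @param shape Planning Weibull shape.
#' @param tol Half-width of the precision target, days.
#' @param conf Required coverage (e.g. 0.95).
#' @param n_grid Candidate sample sizes (default 100 to 1,000 in steps of 10).
#' @param reps Simulated datasets per grid point.
#' @param seed Integer seed.
#' @return An object of class `sample_size_result`: `n_grid`, `coverage`,
#'   `chosen_n` (NA if the target is never reached on the grid, with
#'   `attained = FALSE`), `true_median`, `reps`, `seed`.
#' @examples
#' \donttest{
#' res <- median_precision_sim(180, 3, tol = 7, reps = 2000,
#'                             n_grid = seq(400, 700, 50), seed = 1)
#' res$chosen_n
#' }
#' @export
median_precision_sim <- function(mean, shape, tol = 7, conf = 0.95,
                                 n_grid = seq(100L, 1000L, by = 10L),
                                 reps = 10000L, seed = 1L) {
  stopifnot(tol > 0, conf > 0, conf < 1, reps >= 1, all(n_grid >= 1))
  scale <- weibull_scale_from_mean(mean, shape)
  true_med <- scale * log(2)^(1 / shape)
  lo <- true_med - tol
  hi <- true_med + tol
  coverage <- vapply(seq_along(n_grid), function(i) {
    n <- n_grid[i]
    with_seed(stream_seed(seed, i), {
      k1 <- (n + 1L) %/% 2L
      k2 <- n %/% 2L + 1L
      hits <- 0L
      for (r in seq_len(reps)) {
        x <- stats::rweibull(n, shape = shape, scale = scale)
        s <- sort.int(x, partial = c(k1, k2))
        med <- (s[k1] + s[k2]) / 2
        if (med >= lo && med <= hi) hits <- hits + 1L
      }
      hits / reps
    })
  }, numeric(1))
  ok <- which(coverage >= conf)
  structure(list(n_grid = as.integer(n_grid), coverage = coverage,
                 chosen_n = if (length(ok)) as.integer(n_grid[ok[1L]]) else NA_integer_,
                 attained = length(ok) > 0, conf = conf, tol = tol,
                 true_median = true_med, mean = mean, shape = shape,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("<sample_size_result> Weibull(mean %.4g, shape %.4g), median %.4g days\n",
              x$mean, x$shape, x$true_median))
  if (x$attained) {
    cat(sprintf("  smallest n with >=%.0f%% of %d medians within +/-%g days: %d\n",
                100 * x$conf, x$reps, x$tol, x$chosen_n))
  } else {
    cat(sprintf("  coverage target %.0f%% not reached on the grid (max %.3f)\n",
                100 * x$conf, max(x$coverage)))
  }
  invisible(x)
}

#' @export
plot.sample_size_result <- function(x, ...) {
  graphics::plot(x$n_grid, x$coverage, type = "b", xlab = "sample size",
                 ylab = sprintf("P(|median - %.3g| <= %g)", x$true_median,
                                x$tol), ...)
  graphics::abline(h = x$conf, lty = 2)
  if (x$attained) graphics::abline(v = x$chosen_n, lty = 3)
  invisible(x)
}

#' Closed-form approximation to the required sample size
#'
#' Large-sample approximation from the asymptotic normality of the sample
#' median: `n = (z / (2 f(m) tol))^2` with `f` the Weibull density at its
#' median `m`. An internal cross-check for [median_precision_sim()].
#'
#' @inheritParams median_precision_sim
#' @return Approximate required n (not rounded).
#' @export
analytic_median_sample_size <- function(mean, shape, tol = 7, conf = 0.95) {
  scale <- weibull_scale_from_mean(mean, shape)
  m <- scale * log(2)^(1 / shape)
  fm <- stats::dweibull(m, shape = shape, scale = scale)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  (z / (2 * fm * tol))^2
}
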