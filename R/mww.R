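# Sampled one-sided Mann-Whitney-Wilcoxon testing.
#
# All pattern statements are backed by a one-sided MWW rank test between two
# pixel samples; the direction is fixed in advance by the observed mean
# difference of the compared areas. Because compared areas differ in size,
# the larger sample is first subsampled uniformly without replacement down to
# the size of the smaller one.

#' Test configuration
#'
#' @param alpha significance level for pattern tests (default 0.001).
#' @param rng_seed base integer seed; every randomised step derives its own
#'   stream from it via [stream_seed()], so results are independent of
#'   iteration order.
#' @param n_rule subsampling rule: `"subsample_larger"` (default; the smaller
#'   sample is used whole, the larger is subsampled to its size) or
#'   `"subsample_both"` (both subsampled to the minimum size).
#' @param alpha_metadata reporting threshold for metadata comparisons
#'   (default 1e-4).
#' @param exact_limit combined sample size at or below which the exact MWW
#'   null distribution is used when there are no ties (default 12).
#' @return object of class `test_config`.
#' @export
test_config <- function(alpha = 0.001, rng_seed = 1L,
                        n_rule = c("subsample_larger", "subsample_both"),
                        alpha_metadata = 1e-4, exact_limit = 12L) {
  n_rule <- match.arg(n_rule)
  abort_if(!(alpha > 0 && alpha < 1), "alpha must be in (0, 1)")
  structure(list(alpha = alpha, rng_seed = as.integer(rng_seed),
                 n_rule = n_rule, alpha_metadata = alpha_metadata,
                 exact_limit = as.integer(exact_limit)),
            class = "test_config")
}

#' Draw size-matched test samples from two pixel samples
#'
#' Implements the sampling scheme used before every rank test: with
#' `n = min(|a|, |b|)`, the smaller sample is returned whole and the larger
#' one is subsampled uniformly without replacement to `n` (rule
#' `"subsample_larger"`); under `"subsample_both"` both are subsampled to
#' `n`. The draw is reproducible from `seed`.
#'
#' @param sample_a,sample_b [pixel_sample()] objects (both non-empty).
#' @param seed integer seed for this draw (typically a [stream_seed()]).
#' @param n_rule see [test_config()].
#' @return list with numeric vectors `x` (from `sample_a`) and `y` (from
#'   `sample_b`), both of length `n`.
#' @export
draw_test_samples <- function(sample_a, sample_b, seed,
                              n_rule = c("subsample_larger", "subsample_both")) {
  n_rule <- match.arg(n_rule)
  abort_if(length(sample_a$values) == 0L, "empty pixel sample: %s", sample_a$source)
  abort_if(length(sample_b$values) == 0L, "empty pixel sample: %s", sample_b$source)
  a <- sample_a$values
  b <- sample_b$values
  n <- min(length(a), length(b))
  with_seed(seed, {
    if (n_rule == "subsample_both") {
      x <- if (length(a) > n) a[sample.int(length(a), n)] else a
      y <- if (length(b) > n) b[sample.int(length(b), n)] else b
    } else {
      x <- if (length(a) > n) a[sample.int(length(a), n)] else a
      y <- if (length(b) > n) b[sample.int(length(b), n)] else b
    }
    list(x = x, y = y)
  })
}

#' One-sided Mann-Whitney-Wilcoxon test
#'
#' Computes the U statistic of `x` versus `y` (ties counted 1/2) and its
#' one-sided p-value for the stated direction. For tie-free data with
#' combined size at most `exact_limit` the exact null distribution of U is
#' used ([stats::pwilcox]); otherwise the normal approximation with tie and
#' continuity correction. Degenerate input in which every value across both
#' samples is identical returns `p = 0.5` with `direction = "tie"` (fixed
#' convention), never an error.
#'
#' @param x,y numeric vectors (length >= 1).
#' @param direction `"x_greater"` to test whether `x` is stochastically
#'   greater than `y`, `"y_greater"` for the reverse.
#' @param exact_limit see [test_config()].
#' @return object of class `mww_test`: `p_value`, `direction`
#'   (`"first_greater"`, `"second_greater"` or `"tie"`, from the observed
#'   mean difference), `n_used = min(length(x), length(y))`, `mean_diff =
#'   mean(x) - mean(y)`, `u` and `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mww_one_sided(c(1, 2), c(3, 4), "y_greater")$p_value  # 1/6, exact
mww_one_sided <- function(x, y, direction = c("x_greater", "y_greater"),
                          exact_limit = 12L) {
  direction <- match.arg(direction)
  abort_if(length(x) < 1L || length(y) < 1L, "both samples must be non-empty")
  m <- as.numeric(length(x))   # doubles: m * n overflows integer range
  n <- as.numeric(length(y))
  md <- mean(x) - mean(y)
  obs_dir <- if (md > 0) "first_greater" else if (md < 0) "second_greater" else "tie"

  # U for "x greater": pairs with x_i > y_j, ties 1/2, via midranks
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  u <- if (direction == "x_greater") u_x else m * n - u_x

  ties <- as.numeric(table(c(x, y)))
  has_ties <- any(ties > 1)
  N <- m + n

  if (all(c(x, y) == c(x, y)[1])) {
    return(structure(list(p_value = 0.5, direction = "tie", n_used = as.integer(min(m, n)),
                          mean_diff = 0, u = u, method = "degenerate"),
                     class = "mww_test"))
  }

  if (!has_ties && N <= exact_limit) {
    # exact upper tail: P(U >= u)
    p <- pwilcox(u - 1, m, n, lower.tail = FALSE)
    method <- "exact"
  } else {
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (u - m * n / 2 - 0.5) / sqrt(sigma2)
    p <- pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  structure(list(p_value = min(max(p, 0), 1), direction = obs_dir,
                 n_used = as.integer(min(m, n)), mean_diff = md, u = u, method = method),
            class = "mww_test")
}

#' @export
print.mww_test <- function(x, ...) {
  cat(sprintf("<mww_test> p = %.4g (%s), n_used = %d, mean diff = %.3f degC (%s)\n",
              x$p_value, x$method, x$n_used, x$mean_diff, x$direction))
  invisible(x)
}

# Subsample two pixel samples (seeded stream) then run the one-sided test in
# the given direction. Shared by the global, local, per-ROI and compliance
# paths.
sampled_mww <- function(sample_a, sample_b, direction, config, ...) {
  seed <- stream_seed(config$rng_seed, ...)
  dr <- draw_test_samples(sample_a, sample_b, seed, n_rule = config$n_rule)
  mww_one_sided(dr$x, dr$y, direction, exact_limit = config$exact_limit)
}
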