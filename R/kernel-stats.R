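#' Slope index of a kernel or pulse response
#'
#' Summarises the temporal shape of a differential kernel (behavioural) or
#' differential pulse response (neural) as the slope of the ordinary
#' least-squares line of its values against time. A slope of 0 indicates a
#' temporally flat difference between contexts, a positive slope a rising
#' difference, and a negative slope a converging (decreasing) difference.
#'
#' @param values Numeric series (kernel or response values).
#' @param times Numeric time points in seconds, same length as `values`.
#' @return An object of class `slope_fit` with elements `slope` (value units
#'   per second), `intercept` and `r_squared`.
#' @examples
#' slope_index(c(0.1, 0.2, 0.3), c(0, 0.5, 1))
#' @export
slope_index <- function(values, times) {
  if (length(values) != length(times)) {
    abort("`values` and `times` must have the same length.")
  }
  if (length(values) < 2L) abort("Need at least 2 points for a slope.")
  if (isTRUE(all.equal(var(times), 0)) || var(times) == 0) {
    abort("All `times` are equal; slope is undefined.")
  }
  tm <- mean(times)
  vm <- mean(values)
  sxx <- sum((times - tm)^2)
  slope <- sum((times - tm) * (values - vm)) / sxx
  intercept <- vm - slope * tm
  ss_tot <- sum((values - vm)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum((values - intercept - slope * times)^2) / ss_tot
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "Slope fit: slope = %.4g /s, intercept = %.4g, R^2 = %.3f\n",
    x$slope, x$intercept, x$r_squared
  ))
  invisible(x)
}

#' @export
tidy.slope_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept)
  )
}

#' Bootstrap standard error of a trial-level statistic
#'
#' Resamples rows of `trials` with replacement and reports the standard
#' deviation of `statistic` across resamples. A resample on which the
#' statistic fails (error) is redrawn; the number of redraws is reported.
#'
#' @param trials A data frame of trials (one row per trial).
#' @param statistic A function taking a data frame and returning a numeric
#'   scalar or vector of fixed length.
#' @param n_boot Number of bootstrap iterations (default 100).
#' @param seed Optional integer seed.
#' @return A list with `se` (elementwise standard error), `replicates`
#'   (matrix, iterations in rows) and `n_redrawn`.
#' @export
bootstrap_se <- function(trials, statistic, n_boot = 100, seed = NULL) {
  stopifnot(is.data.frame(trials), n_boot >= 1)
  n <- nrow(trials)
  with_seed(seed, {
    reps <- vector("list", n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        out <- tryCatch(statistic(trials[idx, , drop = FALSE]), error = function(e) NULL)
        if (!is.null(out)) break
        redrawn <- redrawn + 1L
        if (redrawn > 50L * n_boot) abort("Statistic failed on too many bootstrap resamples.")
      }
      reps[[b]] <- as.numeric(out)
    }
    mat <- do.call(rbind, reps)
    list(
      se = apply(mat, 2, sd),
      replicates = mat,
      n_redrawn = redrawn
    )
  })
}

#' Pearson correlation with a permutation p-value
#'
#' Computes the Pearson correlation between `x` and `y` and a two-sided
#' permutation p-value obtained by shuffling `y`, with add-one smoothing
#' `(count + 1) / (n_permutations + 1)`.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return A list with `r` and `p_value`.
#' @export
correlation_with_permutation <- function(x, y, n_permutations = 1000, seed = NULL) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("Need at least 3 observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in `x` or `y`.")
  if (n_permutations < 1L) abort("`n_permutations` must be at least 1.")
  r_obs <- cor(x, y)
  with_seed(seed, {
    r_null <- replicate(n_permutations, cor(x, sample(y)))
    p <- (sum(abs(r_null) >= abs(r_obs)) + 1) / (n_permutations + 1)
    list(r = r_obs, p_value = p)
  })
}
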