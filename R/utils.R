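#' @importFrom rlang %||% abort warn .data
#' @importFrom stats plogis qlogis rbinom rpois runif rnorm coef glm sd
#'   binomial optim cor approx var quantile
#' @importFrom Rcpp evalCpp
#' @useDynLib pulsedyn, .registration = TRUE
NULL

# Run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards so seeded helpers do not perturb each other.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) abort("Cannot normalise a zero vector.")
  v / n
}

# Centers of `n_bins` equal half-open bins [t, t + width) spanning
# [0, duration).
bin_centers <- function(duration, n_bins) {
  width <- duration / n_bins
  (seq_len(n_bins) - 0.5) * width
}
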