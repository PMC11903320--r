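#' Fit a four-parameter psychometric function
#'
#' Fits the probability of a rightward choice as a function of evidence
#' strength with the four-parameter logistic
#' \deqn{y(x) = y_0 + a / (1 + e^{-(x - x_0)/b})}
#' by binomial maximum likelihood (default) or by nonlinear least squares on
#' the per-strength choice fractions. The lower asymptote `y0` and the
#' range `a` are constrained so the curve stays in \[0, 1\].
#'
#' @param trials A trials tibble with a `choice` column (`"R"`/`"L"`).
#' @param feature Which evidence strength to use: `"loc"` (#right - #left)
#'   or `"frq"` (#high - #low).
#' @param method `"ml"` (binomial maximum likelihood) or `"ls"`
#'   (least squares on choice fractions).
#' @return A `psychometric_fit` with elements `y0`, `a`, `x0`, `b`,
#'   `log_lik`, `status` (`"ok"` or `"degenerate"`) and `data` (per-strength
#'   choice fractions).
#' @export
fit_psychometric <- function(trials, feature = c("loc", "frq"),
                             method = c("ml", "ls")) {
  feature <- match.arg(feature)
  method <- match.arg(method)
  if (!"loc_strength" %in% names(trials)) trials <- evidence_strengths(trials)
  x <- if (feature == "loc") trials$loc_strength else trials$frq_strength
  y <- as.integer(trials$choice == "R")
  if (length(unique(x)) < 2L) abort("Need at least 2 distinct strength values.")

  agg <- dplyr::tibble(x = x, y = y) |>
    dplyr::summarise(n = dplyr::n(), frac_right = mean(.data$y), .by = "x") |>
    dplyr::arrange(.data$x)

  status <- "ok"
  if (length(unique(y)) == 1L) {
    warn("All choices identical; psychometric fit is degenerate.")
    status <- "degenerate"
    y0 <- mean(y)
    fit <- list(y0 = y0, a = 0, x0 = 0, b = 1)
    ll <- 0
  } else {
    # (u0, u1) parametrise the asymptotes through a logistic map so the
    # fitted curve is always within [0, 1]; b > 0 via log-scale.
    curve_fun <- function(par, x) {
      y0 <- plogis(par[1]); y1 <- plogis(par[2])
      y0 + (y1 - y0) / (1 + exp(-(x - par[3]) / exp(par[4])))
    }
    obj_ml <- function(par) {
      p <- pmin(pmax(curve_fun(par, x), 1e-9), 1 - 1e-9)
      -sum(y * log(p) + (1 - y) * log(1 - p))
    }
    obj_ls <- function(par) {
      sum(agg$n * (agg$frac_right - curve_fun(par, agg$x))^2)
    }
    start <- c(qlogis(0.05), qlogis(0.95), 0, log(max(sd(x) / 2, 0.5)))
    opt <- optim(start, if (method == "ml") obj_ml else obj_ls,
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
    opt <- optim(opt$par, if (method == "ml") obj_ml else obj_ls,
                 method = "BFGS", control = list(maxit = 500))
    y0 <- plogis(opt$par[1])
    y1 <- plogis(opt$par[2])
    fit <- list(y0 = y0, a = y1 - y0, x0 = opt$par[3], b = exp(opt$par[4]))
    ll <- -obj_ml(opt$par)
  }
  structure(
    c(fit, list(log_lik = ll, status = status, method = method,
                feature = feature, data = agg)),
    class = "psychometric_fit"
  )
}

#' Predict from a psychometric fit
#' @param object A `psychometric_fit`.
#' @param newdata Numeric vector of strengths (defaults to fitted range).
#' @param ... Unused.
#' @export
predict.psychometric_fit <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$data$x
  object$y0 + object$a / (1 + exp(-(x - object$x0) / object$b))
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Psychometric fit (%s, %s): y0 = %.3f, a = %.3f, x0 = %.3f, b = %.3f [%s]\n",
    x$feature, x$method, x$y0, x$a, x$x0, x$b, x$status
  ))
  invisible(x)
}

#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("y0", "a", "x0", "b"),
    estimate = c(x$y0, x$a, x$x0, x$b)
  )
}

# Per-context logistic regression of choice on the two signed evidence
# strengths; ridge fallback (small penalty) under separation.
context_logistic <- function(x_loc, x_frq, y) {
  flagged <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x_loc + x_frq, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (flagged) {
    X <- cbind(x_loc, x_frq)
    gf <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                         lambda = 1e-4, standardize = FALSE)
    co <- as.numeric(coef(gf))
    list(beta = co[1], w_loc = co[2], w_frq = co[3], penalized = TRUE)
  } else {
    co <- coef(fit)
    list(beta = unname(co[1]), w_loc = unname(co[2]), w_frq = unname(co[3]),
         penalized = FALSE)
  }
}

#' Feature selection index
#'
#' Quantifies context use from choices: in each context, choices are fit by
#' a logistic regression on the signed location and frequency evidence
#' strengths. The relative weight of the relevant feature is computed per
#' context (relevant weight over the sum of both weights) and the feature
#' selection index (FSI) is the average of the two relative weights: 1 for
#' perfect context use, 0.5 for context-blind behaviour.
#'
#' @param trials A trials tibble containing both contexts with choices.
#' @param strengths `"generative"` (rate differences from `p_right`/`p_high`;
#'   used when available) or `"realized"` (pulse count differences).
#' @return An `fsi_fit` with per-context raw weights and biases, relative
#'   weights, `fsi`, the strength definition used, and a `penalized` flag.
#' @export
feature_selection_index <- function(trials, strengths = c("generative", "realized")) {
  strengths <- match.arg(strengths)
  if (length(unique(trials$context)) < 2L) {
    abort("Both contexts must be present to compute the FSI.")
  }
  if (strengths == "generative") {
    s_loc <- trials$total_rate * (2 * trials$p_right - 1)
    s_frq <- trials$total_rate * (2 * trials$p_high - 1)
  } else {
    if (!"loc_strength" %in% names(trials)) trials <- evidence_strengths(trials)
    s_loc <- trials$loc_strength
    s_frq <- trials$frq_strength
  }
  y <- as.integer(trials$choice == "R")
  in_loc <- trials$context == "LOC"
  f_loc <- context_logistic(s_loc[in_loc], s_frq[in_loc], y[in_loc])
  f_frq <- context_logistic(s_loc[!in_loc], s_frq[!in_loc], y[!in_loc])
  rw_loc <- f_loc$w_loc / (f_loc$w_loc + f_loc$w_frq)
  rw_frq <- f_frq$w_frq / (f_frq$w_loc + f_frq$w_frq)
  structure(
    list(
      w_loc_in_locctx = f_loc$w_loc, w_frq_in_locctx = f_loc$w_frq,
      w_loc_in_frqctx = f_frq$w_loc, w_frq_in_frqctx = f_frq$w_frq,
      beta_locctx = f_loc$beta, beta_frqctx = f_frq$beta,
      relative_weight_location = rw_loc,
      relative_weight_frequency = rw_frq,
      fsi = (rw_loc + rw_frq) / 2,
      strengths = strengths,
      penalized = f_loc$penalized || f_frq$penalized
    ),
    class = "fsi_fit"
  )
}

#' @export
print.fsi_fit <- function(x, ...) {
  cat(sprintf(
    "FSI = %.3f (rel. weight location %.3f, rel. weight frequency %.3f)%s\n",
    x$fsi, x$relative_weight_location, x$relative_weight_frequency,
    if (x$penalized) " [ridge fallback]" else ""
  ))
  invisible(x)
}

#' @export
glance.fsi_fit <- function(x, ...) {
  tibble::tibble(
    fsi = x$fsi,
    relative_weight_location = x$relative_weight_location,
    relative_weight_frequency = x$relative_weight_frequency,
    penalized = x$penalized
  )
}

#' Filter sessions by performance
#'
#' Retains sessions whose accuracy, feature selection index and trial count
#' all reach their thresholds, and reports per-session exclusion reasons.
#'
#' @param trials A trials tibble covering one or more sessions
#'   (`session_id` column).
#' @param min_accuracy Minimum fraction correct (default 0.70).
#' @param min_fsi Minimum feature selection index (default 0.7). Sessions
#'   with a single context get `NA` FSI and fail this criterion.
#' @param min_trials Minimum number of trials (default 100).
#' @return A list with `trials` (retained rows) and `report` (one row per
#'   session: metrics, `retained`, `reasons`).
#' @export
session_filter <- function(trials, min_accuracy = 0.70, min_fsi = 0.7,
                           min_trials = 100) {
  report <- trials |>
    dplyr::group_by(.data$session_id) |>
    dplyr::group_modify(function(d, key) {
      fsi <- tryCatch(feature_selection_index(d)$fsi, error = function(e) NA_real_)
      tibble::tibble(
        n_trials = nrow(d),
        accuracy = mean(d$correct),
        fsi = fsi
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      retained = .data$accuracy >= min_accuracy &
        !is.na(.data$fsi) & .data$fsi >= min_fsi &
        .data$n_trials >= min_trials,
      reasons = purrr::pmap_chr(
        list(.data$accuracy, .data$fsi, .data$n_trials),
        function(acc, fsi, nt) {
          r <- c(
            if (acc < min_accuracy) "low_accuracy",
            if (is.na(fsi) || fsi < min_fsi) "low_fsi",
            if (nt < min_trials) "too_few_trials"
          )
          if (length(r) == 0) "" else paste(r, collapse = ";")
        }
      )
    )
  keep <- report$session_id[report$retained]
  list(trials = dplyr::filter(trials, .data$session_id %in% keep),
       report = report)
}

#' Fit time-binned behavioural kernels
#'
#' Logistic regression of choice on the time-binned log-ratio evidence of
#' both features (26 location + 26 frequency regressors by default) plus a
#' bias, with a ridge penalty whose strength is selected by k-fold
#' cross-validated predictive likelihood. The bias is never penalised.
#'
#' @param trials A trials tibble from a single context, with choices.
#' @param n_bins Number of stimulus time bins (default 26).
#' @param pseudo_count Pseudo-count for the log-ratio evidence (default 1).
#' @param ridge_grid Decreasing grid of ridge strengths; defaults to 30
#'   log-spaced values between 1e2 and 1e-4 (on the glmnet lambda scale).
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param pulse_window Optional `c(start, end)` in seconds: only bins whose
#'   centers fall inside are used as regressors (e.g. the second half of the
#'   stimulus in split-mode analyses).
#' @param seed Optional integer seed (fold assignment).
#' @return A `behavioral_kernel_fit` with `w_loc`, `w_frq` (per-bin
#'   weights), `beta`, `times` (bin centers), `ridge_strength`, `cv_score`
#'   (mean held-out log-likelihood per trial) and `context`.
#' @export
fit_behavioral_kernels <- function(trials, n_bins = 26, pseudo_count = 1,
                                   ridge_grid = NULL, cv_folds = 5,
                                   pulse_window = NULL, seed = NULL) {
  ctx <- unique(trials$context)
  if (length(ctx) != 1L) {
    abort("`trials` must come from a single context; fit each context separately.")
  }
  design <- kernel_design(trials, n_bins, pseudo_count)
  keep <- seq_len(n_bins)
  if (!is.null(pulse_window)) {
    keep <- which(design$times >= pulse_window[1] & design$times < pulse_window[2])
    if (length(keep) == 0) abort("`pulse_window` contains no bins.")
  }
  X <- cbind(design$loc[, keep, drop = FALSE], design$frq[, keep, drop = FALSE])
  y <- as.integer(trials$choice == "R")
  ridge_grid <- ridge_grid %||% 10^seq(2, -4, length.out = 30)
  ridge_grid <- sort(ridge_grid, decreasing = TRUE)
  foldid <- with_seed(seed, sample(rep_len(seq_len(cv_folds), nrow(X))))
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = ridge_grid, foldid = foldid,
                          standardize = FALSE, type.measure = "deviance")
  co <- as.numeric(coef(cv, s = "lambda.min"))
  nb <- length(keep)
  w_loc <- rep(NA_real_, n_bins); w_frq <- rep(NA_real_, n_bins)
  w_loc[keep] <- co[1 + seq_len(nb)]
  w_frq[keep] <- co[1 + nb + seq_len(nb)]
  structure(
    list(
      w_loc = w_loc, w_frq = w_frq, beta = co[1],
      times = design$times, bins_used = keep,
      ridge_strength = cv$lambda.min,
      cv_score = -cv$cvm[cv$lambda == cv$lambda.min] / 2,
      context = ctx, n_trials = nrow(X)
    ),
    class = "behavioral_kernel_fit"
  )
}

#' @export
print.behavioral_kernel_fit <- function(x, ...) {
  cat(sprintf(
    "Behavioural kernel fit (%s context, %d trials, %d bins): ridge = %.3g\n",
    x$context, x$n_trials, length(x$bins_used), x$ridge_strength
  ))
  invisible(x)
}

#' @export
tidy.behavioral_kernel_fit <- function(x, ...) {
  tibble::tibble(
    time = rep(x$times, 2),
    feature = rep(c("loc", "frq"), each = length(x$times)),
    weight = c(x$w_loc, x$w_frq),
    context = x$context
  )
}

#' Differential behavioural kernel
#'
#' Per-bin difference between a feature's kernel fitted in its relevant
#' context and in its irrelevant context, with the slope index of the
#' difference attached. For location: LOC-context weights minus FRQ-context
#' weights; for frequency: FRQ-context minus LOC-context.
#'
#' @param fit_rel Kernel fit from the feature's relevant context.
#' @param fit_irr Kernel fit from the feature's irrelevant context.
#' @param feature `"loc"` or `"frq"`.
#' @param slope_window Optional `c(start, end)` in seconds: the slope index
#'   is computed over bins whose centers fall inside this window (e.g. the
#'   second half of the stimulus in split-mode analyses), while the kernel
#'   itself keeps all fitted bins.
#' @return A `differential_kernel` with `values`, `times`, `slope_index`
#'   (a [slope_index()] fit) and `feature`.
#' @export
differential_behavioral_kernel <- function(fit_rel, fit_irr,
                                           feature = c("loc", "frq"),
                                           slope_window = NULL) {
  feature <- match.arg(feature)
  if (!identical(fit_rel$times, fit_irr$times) ||
      !identical(fit_rel$bins_used, fit_irr$bins_used)) {
    abort("Kernel fits have mismatched bin configurations.")
  }
  w_rel <- if (feature == "loc") fit_rel$w_loc else fit_rel$w_frq
  w_irr <- if (feature == "loc") fit_irr$w_loc else fit_irr$w_frq
  keep <- fit_rel$bins_used
  values <- (w_rel - w_irr)[keep]
  times <- fit_rel$times[keep]
  in_win <- if (is.null(slope_window)) rep(TRUE, length(times)) else {
    times >= slope_window[1] & times < slope_window[2]
  }
  if (sum(in_win) < 2) abort("`slope_window` contains fewer than 2 bins.")
  structure(
    list(
      feature = feature, values = values, times = times,
      slope_index = slope_index(values[in_win], times[in_win]),
      slope_window = slope_window, se = NULL
    ),
    class = "differential_kernel"
  )
}

#' @export
print.differential_kernel <- function(x, ...) {
  cat(sprintf(
    "Differential behavioural kernel (%s): slope index = %.4g /s\n",
    x$feature, x$slope_index$slope
  ))
  invisible(x)
}
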