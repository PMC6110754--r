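# Protein half-life estimation from cycloheximide chase series:
# log-linear fits of the exponential decay N(t) = N0 * exp(-lambda * t),
# t_1/2 = ln(2) / lambda, and replicate-level comparison between
# constructs.

#' Fit exponential decay to one chase series
#'
#' Ordinary least squares of ln(intensity) on time. lambda is the
#' negated slope and the half-life is ln(2)/lambda. A non-decaying
#' series (slope >= 0) is flagged and returns NA for lambda and the
#' half-life. The log-linear fit is deterministic, closed-form, and
#' exact on noiseless data; a nonlinear least-squares refinement on the
#' raw scale is available via `nonlinear = TRUE`.
#'
#' @param time Timepoints in minutes (at least 3 distinct values), or a
#'   data frame with columns `time_min` and `intensity`.
#' @param intensity Positive intensities (loading-control-normalized
#'   densitometry), omitted when `time` is a data frame.
#' @param nonlinear Refine by `nls` on the raw scale, started from the
#'   log-linear estimates.
#' @return An object of class `"decay_fit"`: list with `n0`, `lambda`
#'   (per minute), `t_half` (minutes), `r_squared` (of the log-linear
#'   fit) and `decaying`.
#' @export
fit_decay <- function(time, intensity = NULL, nonlinear = FALSE) {
  if (is.data.frame(time)) {
    intensity <- time$intensity
    time <- time$time_min
  }
  if (length(time) != length(intensity) || length(time) < 3L)
    stop("need at least 3 paired (time, intensity) points", call. = FALSE)
  if (length(unique(time)) < 3L)
    stop("need at least 3 distinct timepoints", call. = FALSE)
  if (any(!is.finite(intensity) | intensity <= 0))
    stop("intensities must be strictly positive", call. = FALSE)

  fit <- stats::lm(log(intensity) ~ time)
  slope <- unname(stats::coef(fit)[2])
  n0 <- exp(unname(stats::coef(fit)[1]))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (slope >= 0) {
    warning("series does not decay; lambda undefined", call. = FALSE)
    return(structure(list(n0 = n0, lambda = NA_real_, t_half = NA_real_,
                          r_squared = r2, decaying = FALSE),
                     class = "decay_fit"))
  }
  lambda <- -slope
  if (nonlinear) {
    nl <- try(stats::nls(intensity ~ a * exp(-l * time),
                         start = list(a = n0, l = lambda)), silent = TRUE)
    if (!inherits(nl, "try-error")) {
      n0 <- unname(stats::coef(nl)["a"])
      lambda <- unname(stats::coef(nl)["l"])
    }
  }
  structure(list(n0 = n0, lambda = lambda, t_half = log(2) / lambda,
                 r_squared = r2, decaying = TRUE),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$decaying)
    cat(sprintf(
      "Exponential decay fit: N0 = %.3g, lambda = %.4g/min, t1/2 = %.3g min (R^2 = %.3f)\n",
      x$n0, x$lambda, x$t_half, x$r_squared))
  else
    cat("Series does not decay (slope >= 0); no half-life estimated\n")
  invisible(x)
}

#' Fit decay per construct and replicate of a chase table
#'
#' @param chase Data frame with columns `construct`, `replicate`,
#'   `time_min`, `intensity` (as written by [simulate_chase()]).
#' @param nonlinear Passed to [fit_decay()].
#' @return Data frame with one row per construct x replicate: `n0`,
#'   `lambda`, `t_half`, `r_squared`.
#' @export
fit_chase <- function(chase, nonlinear = FALSE) {
  req <- c("construct", "replicate", "time_min", "intensity")
  if (!all(req %in% names(chase)))
    stop("chase table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  keys <- unique(chase[, c("construct", "replicate")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- chase[chase$construct == keys$construct[i] &
                   chase$replicate == keys$replicate[i], , drop = FALSE]
    f <- fit_decay(sub$time_min, sub$intensity, nonlinear = nonlinear)
    data.frame(construct = keys$construct[i],
               replicate = keys$replicate[i], n0 = f$n0,
               lambda = f$lambda, t_half = f$t_half,
               r_squared = f$r_squared, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare replicate half-lives between two constructs
#'
#' Two-tailed t-test on replicate half-lives (Welch by default; set
#' `var_equal = TRUE` for the pooled-variance Student form), with
#' per-construct mean and standard deviation.
#'
#' @param t_half_a,t_half_b Numeric vectors of replicate half-lives
#'   (>= 2 each).
#' @param var_equal Assume equal variances (default FALSE = Welch).
#' @return List with `p_value`, `mean_a`, `sd_a`, `mean_b`, `sd_b`.
#' @export
compare_halflives <- function(t_half_a, t_half_b, var_equal = FALSE) {
  if (length(t_half_a) < 2L || length(t_half_b) < 2L)
    stop("need at least 2 replicates per construct", call. = FALSE)
  p <- if (stats::sd(t_half_a) == 0 && stats::sd(t_half_b) == 0) {
    if (mean(t_half_a) == mean(t_half_b)) 1 else 0
  } else {
    stats::t.test(t_half_a, t_half_b, var.equal = var_equal)$p.value
  }
  list(p_value = p,
       mean_a = mean(t_half_a), sd_a = stats::sd(t_half_a),
       mean_b = mean(t_half_b), sd_b = stats::sd(t_half_b))
}
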