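#' Statistical inefficiency of a time series
#'
#' `g = 1 + 2 sum_{t>=1} (1 - t/N) rho(t)`, with the empirical
#' autocorrelation sum truncated at the first non-positive value
#' (initial-positive-sequence convention) and g floored at 1. For an AR(1)
#' process with coefficient phi the long-series limit is
#' `(1 + phi)/(1 - phi)`. Thinning a series by `ceiling(g)` yields
#' approximately independent samples; `g * dt` is the correlation time in
#' physical units.
#'
#' @param x numeric series of length >= 4
#' @return statistical inefficiency g (dimensionless, >= 1); for a constant
#'   series g = 1 with a warning (autocorrelation undefined)
#' @export
statistical_inefficiency <- function(x) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 4L) stop("series too short (need length >= 4)")
  if (var(x) == 0) {
    warning("constant series: autocorrelation undefined, returning g = 1")
    return(1)
  }
  lag_max <- min(N - 1L, 256L)
  repeat {
    rho <- as.numeric(acf(x, lag.max = lag_max, plot = FALSE,
                          demean = TRUE)$acf)[-1L]
    cut <- which(rho <= 0)
    if (length(cut) > 0L || lag_max >= N - 1L) break
    lag_max <- min(N - 1L, lag_max * 4L)
  }
  L <- if (length(cut)) cut[1L] - 1L else length(rho)
  if (L == 0L) return(1)
  t <- seq_len(L)
  max(1, 1 + 2 * sum((1 - t / N) * rho[t]))
}

#' Time-resolved binding free-energy estimates
#'
#' Runs the full reconstruct -> project -> reference -> standard-state
#' pipeline on the hills deposited up to each evaluation time (the bias grid
#' is accumulated incrementally, which gives results identical to a fresh
#' reconstruction at each time). The resulting dG_meta(t) series is the
#' input of [final_estimate()].
#'
#' Evaluation times at which a stage fails (typically because the site or
#' the reference range is still unsampled early in the run) are returned as
#' `NA` with a single collective warning by default; `strict = TRUE` turns
#' the first failure into an error carrying the failing time.
#'
#' @param hills a [hills_record()] spanning at least two evaluation strides
#' @param cfg a [binding_config()]
#' @param grid a [fes_grid()]
#' @param eval_stride spacing of evaluation times (ps)
#' @param t_end last evaluation time (ps); defaults to the last deposition
#'   time, but may extend beyond it (the series is then constant there)
#' @param estimator optional function(fes) -> numeric replacing the default
#'   standard-state estimator; e.g. a basin free-energy difference
#'   `function(fes) pmf_delta_f(project_pmf(fes), divider)`
#' @param cutoff Gaussian cutoff passed to the reconstruction
#' @param strict error (rather than NA) on a failing evaluation time
#' @return an object of class `dg_series`: list with `times`, `dg` and the
#'   configuration used
#' @export
dg_meta_timeseries <- function(hills, cfg = binding_config(), grid = fes_grid(),
                               eval_stride, estimator = NULL, cutoff = 6,
                               strict = FALSE, t_end = NULL) {
  stopifnot(inherits(hills, "hills_record"))
  if (length(hills$times) == 0L) stop("empty hills record")
  .check_hills_in_grid(hills, grid)
  t_max <- if (is.null(t_end)) max(hills$times) else t_end
  if (eval_stride <= 0) stop("eval_stride must be positive")
  if (t_max < 2 * eval_stride)
    stop("hills span less than two evaluation strides (", t_max, " ps)")
  eval_times <- seq(eval_stride, t_max, by = eval_stride)
  if (is.null(estimator))
    estimator <- function(fes)
      delta_g_meta(set_reference_level(project_pmf(fes, cfg$T), cfg$ref_range),
                   cfg)
  V <- matrix(0, length(grid$z), length(grid$c))
  prev <- -Inf
  dg <- rep(NA_real_, length(eval_times))
  failed <- character(0)
  for (k in seq_along(eval_times)) {
    tt <- eval_times[k]
    idx <- which(hills$times > prev & hills$times <= tt)
    V <- .accumulate_bias(V, grid, hills, idx, cutoff)
    prev <- tt
    fes <- try(.fes_from_bias(V, grid, hills$gamma, cfg$T, c(0, tt)),
               silent = TRUE)
    val <- if (inherits(fes, "try-error")) fes else
      try(as.numeric(estimator(fes)), silent = TRUE)
    if (inherits(val, "try-error")) {
      msg <- conditionMessage(attr(val, "condition"))
      if (strict)
        stop(sprintf("evaluation failed at t = %g ps: %s", tt, msg),
             call. = FALSE)
      failed <- c(failed, sprintf("t = %g ps (%s)", tt, msg))
    } else dg[k] <- val
  }
  if (length(failed))
    warning(sprintf("%d evaluation time(s) failed and were set to NA; first: %s",
                    length(failed), failed[1]))
  structure(list(times = eval_times, dg = dg, eval_stride = eval_stride),
            class = "dg_series")
}

#' @export
print.dg_series <- function(x, ...) {
  ok <- !is.na(x$dg)
  cat(sprintf("dG(t) series: %d evaluations every %g ps, %d valid\n",
              length(x$times), x$eval_stride, sum(ok)))
  if (any(ok))
    cat(sprintf("  last value %.3f kcal/mol at t = %g ps\n",
                x$dg[max(which(ok))], x$times[max(which(ok))]))
  invisible(x)
}

#' Final estimate and error from a convergence series
#'
#' Averages the free-energy series over the last window of length `window`
#' and reports the statistical uncertainty as the maximum of two numbers:
#' the fluctuation (standard deviation) of the estimates inside that window,
#' and the absolute difference between the means of the two last consecutive
#' blocks of length `window` (which accounts for residual drift). The series
#' must cover at least two windows. The fluctuation is an SD, not a standard
#' error of the mean; `fluctuation = "sem"` switches to the SEM reading.
#'
#' @param series a `dg_series` from [dg_meta_timeseries()], or a list with
#'   `times` and `dg`
#' @param window averaging window length (same time units as the series)
#' @param fluctuation `"sd"` (default) or `"sem"`
#' @return list with `mean`, `error`, `sd_window`, `block_diff`, `window`,
#'   `n_window`
#' @export
final_estimate <- function(series, window, fluctuation = c("sd", "sem")) {
  fluctuation <- match.arg(fluctuation)
  t <- series$times; y <- series$dg
  stopifnot(length(t) == length(y))
  t_end <- t[length(t)]
  span <- t_end - t[1]
  if (span < 2 * window - 1e-9)
    stop("series spans ", format(span), " which is less than two windows")
  last <- t > t_end - window + 1e-9
  prev <- t > t_end - 2 * window + 1e-9 & !last
  if (sum(last) < 2 || sum(prev) < 2)
    stop("too few evaluations per block; decrease the evaluation stride")
  if (anyNA(y[last | prev]))
    stop("NA estimates inside the averaging blocks")
  m_last <- mean(y[last]); m_prev <- mean(y[prev])
  s <- sd(y[last])
  if (fluctuation == "sem") s <- s / sqrt(sum(last))
  list(mean = m_last,
       error = max(s, abs(m_prev - m_last)),
       sd_window = s,
       block_diff = abs(m_prev - m_last),
       window = window,
       n_window = sum(last))
}
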