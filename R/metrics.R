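#' Prediction table for error metrics
#'
#' Per-system calculated and experimental binding free energies with a host
#' group label, the input of the SAMPL error metrics. System ids must be
#' unique.
#'
#' @param system character system identifiers
#' @param host character host group labels (e.g. "OAH", "OAMe")
#' @param dg_calc calculated binding free energies (kcal/mol)
#' @param dg_exp experimental binding free energies (kcal/mol)
#' @param dg_err optional per-system statistical errors (kcal/mol)
#' @return a data frame of class `prediction_table`
#' @export
prediction_table <- function(system, host, dg_calc, dg_exp, dg_err = NA_real_) {
  system <- as.character(system); host <- as.character(host)
  if (anyDuplicated(system)) stop("duplicated system ids")
  n <- length(system)
  if (length(host) != n || length(dg_calc) != n || length(dg_exp) != n)
    stop("all columns must have the same length")
  out <- data.frame(system = system, host = host,
                    dg_calc = as.numeric(dg_calc),
                    dg_err = rep_len(as.numeric(dg_err), n),
                    dg_exp = as.numeric(dg_exp),
                    stringsAsFactors = FALSE)
  class(out) <- c("prediction_table", class(out))
  out
}

.group_rows <- function(table, group) {
  stopifnot(inherits(table, "prediction_table"))
  if (identical(group, "combined")) return(seq_len(nrow(table)))
  rows <- which(table$host == group)
  if (length(rows) == 0L) stop("empty or unknown group: ", group)
  rows
}

#' Average signed error
#'
#' `AvErr = mean(dg_calc - dg_exp)` over a host group (or `"combined"` for
#' all systems). Negative values mean over-binding predictions.
#'
#' @param table a [prediction_table()]
#' @param group host label or `"combined"`
#' @return AvErr (kcal/mol)
#' @export
av_err <- function(table, group = "combined") {
  r <- .group_rows(table, group)
  mean(table$dg_calc[r] - table$dg_exp[r])
}

#' Mean absolute deviation
#'
#' `MAD = mean(|dg_calc - dg_exp|)` over a group.
#'
#' @inheritParams av_err
#' @return MAD (kcal/mol)
#' @export
mad_err <- function(table, group = "combined") {
  r <- .group_rows(table, group)
  mean(abs(table$dg_calc[r] - table$dg_exp[r]))
}

#' Mean absolute deviation after translation
#'
#' `MADTr = mean(|(dg_calc - dg_exp) - AvErr|)`: the MAD after subtracting
#' the group's average signed error, i.e. an accuracy metric for *relative*
#' binding free energies, exactly invariant under adding any constant to the
#' predictions. For the combined group the combined AvErr is subtracted
#' (not the per-host ones).
#'
#' @inheritParams av_err
#' @return MADTr (kcal/mol)
#' @export
mad_tr <- function(table, group = "combined") {
  r <- .group_rows(table, group)
  e <- table$dg_calc[r] - table$dg_exp[r]
  mean(abs(e - mean(e)))
}

#' Squared Pearson correlation between calculation and experiment
#'
#' @inheritParams av_err
#' @return R squared (dimensionless); errors on groups of fewer than 3
#'   systems or with a constant column
#' @export
r_squared <- function(table, group = "combined") {
  r <- .group_rows(table, group)
  if (length(r) < 3L) stop("R^2 needs a group of at least 3 systems")
  if (var(table$dg_calc[r]) == 0 || var(table$dg_exp[r]) == 0)
    stop("R^2 undefined for a constant column")
  cor(table$dg_calc[r], table$dg_exp[r])^2
}

#' MADTr of the equal-affinity dummy predictor
#'
#' The MADTr obtained by a predictor that assigns every system the same
#' binding free energy reduces to the mean absolute deviation of the
#' experimental values from their group mean; submissions should beat this
#' number to demonstrate any resolution of relative affinities.
#'
#' @inheritParams av_err
#' @return dummy MADTr (kcal/mol)
#' @export
dummy_madtr <- function(table, group = "combined") {
  r <- .group_rows(table, group)
  e <- table$dg_exp[r]
  mean(abs(e - mean(e)))
}

#' All error metrics for all groups
#'
#' Convenience wrapper computing MAD, MADTr, AvErr and R squared for each
#' host group and the combined set.
#'
#' @param table a [prediction_table()]
#' @return a data frame with columns `group`, `MAD`, `MADTr`, `AvErr`, `R2`
#' @export
metric_table <- function(table) {
  groups <- c(sort(unique(table$host)), "combined")
  do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g,
               MAD = mad_err(table, g),
               MADTr = mad_tr(table, g),
               AvErr = av_err(table, g),
               R2 = r_squared(table, g),
               stringsAsFactors = FALSE)
  }))
}

#' Monte-Carlo uncertainty of the set metrics
#'
#' Resamples the calculated free energies from normal distributions centered
#' on `dg_calc` with the per-system errors as standard deviations and
#' reports, per metric and group, the standard deviation (and mean) over the
#' perturbed tables. This measures how stable the set metrics are given the
#' per-system statistical errors.
#'
#' @param table a [prediction_table()] with `dg_err` present for all rows
#' @param n_rep number of perturbed tables
#' @param seed optional integer seed (caller's RNG state restored)
#' @return a data frame with `group`, `metric`, `mean`, `sd`
#' @export
metric_uncertainty <- function(table, n_rep = 1000, seed = NULL) {
  stopifnot(inherits(table, "prediction_table"))
  if (anyNA(table$dg_err))
    stop("per-system errors are required for metric_uncertainty()")
  groups <- c(sort(unique(table$host)), "combined")
  metrics <- c("MAD", "MADTr", "AvErr", "R2")
  draws <- .with_seed(seed, {
    vapply(seq_len(n_rep), function(b) {
      pert <- table
      pert$dg_calc <- rnorm(nrow(table), table$dg_calc, table$dg_err)
      unlist(lapply(groups, function(g)
        c(mad_err(pert, g), mad_tr(pert, g), av_err(pert, g),
          r_squared(pert, g))))
    }, numeric(4L * length(groups)))
  })
  out <- expand.grid(metric = metrics, group = groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean <- apply(draws, 1, mean)
  out$sd <- apply(draws, 1, sd)
  out[, c("group", "metric", "mean", "sd")]
}

#' Packaged SAMPL5 octa-acid prediction sets
#'
#' Loads the packaged table of calculated and experimental binding free
#' energies for the twelve SAMPL5 octa-acid host-guest systems (hosts OAH
#' and OAMe, guests G1-G6) as a [prediction_table()]. Three prediction sets
#' are available: the refined GAFF and OPLS results (full-length runs with
#' the rigorous water-restraint correction) and the originally submitted
#' GAFF set (shorter runs with an empirical offset; no per-system errors).
#' The OAH-Gu2 complex is a reference compound used only to calibrate the
#' empirical offset and is excluded from all metric groups unless
#' `include_reference = TRUE`.
#'
#' @param set which prediction set to load
#' @param include_reference include the OAH-Gu2 reference row
#' @return a [prediction_table()]
#' @export
sampl5_predictions <- function(set = c("gaff_refined", "opls_refined",
                                       "gaff_submitted"),
                               include_reference = FALSE) {
  set <- match.arg(set)
  path <- system.file("extdata", "sampl5_octa_acid.csv", package = "funmetad",
                      mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  raw <- raw[raw$set == set, ]
  if (!include_reference) raw <- raw[raw$system != "OAH-Gu2", ]
  prediction_table(raw$system, raw$host, raw$dg_calc, raw$dg_exp, raw$dg_err)
}
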