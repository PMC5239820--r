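#' Write a hills record to a PLUMED-1.x-style text file
#'
#' Whitespace-separated columns `time center1 center2 sigma1 sigma2 height
#' biasfactor`; lines starting with `#` are comments. Numbers are written
#' with enough digits (`%.17g`) that [read_hills()] recovers the record
#' exactly and a write-read-write cycle is a fixed point.
#'
#' @param hills a [hills_record()]
#' @param path output file
#' @param meta optional named character vector written as comment header
#' @return `path`, invisibly
#' @export
write_hills <- function(hills, path, meta = NULL) {
  stopifnot(inherits(hills, "hills_record"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  writeLines("#! FIELDS time cv1 cv2 sigma1 sigma2 height biasfactor", con)
  n <- length(hills$times)
  if (n > 0) {
    rows <- sprintf("%.17g %.17g %.17g %.17g %.17g %.17g %.17g",
                    hills$times, hills$centers[, 1], hills$centers[, 2],
                    hills$widths[, 1], hills$widths[, 2], hills$heights,
                    rep(hills$gamma, n))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a hills record from a PLUMED-1.x-style text file
#'
#' @param path input file (see [write_hills()] for the format)
#' @return a [hills_record()]
#' @export
read_hills <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(data_idx) == 0L) stop("no hills in ", path, " (only comments)")
  fields <- lapply(data_idx, function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) != 7L || anyNA(vals))
      stop(sprintf("malformed hills line %d in %s: '%s'", i, path, lines[i]))
    vals
  })
  m <- do.call(rbind, fields)
  if (any(m[, 4] <= 0) || any(m[, 5] <= 0))
    stop("invalid hills file: non-positive Gaussian widths")
  gamma <- unique(m[, 7])
  if (length(gamma) != 1L)
    stop("invalid hills file: bias factor column is not constant")
  if (gamma <= 0) gamma <- Inf  # standard-metadynamics convention
  hills_record(m[, 1], m[, 2:3], m[, 4:5], m[, 6], gamma = gamma)
}

#' Write a collective-variable time series to a COLVAR-style text file
#'
#' Whitespace-separated columns declared in a `#! FIELDS` header; additional
#' `#` comment lines carry metadata (model, seed). Trajectories from the 2D
#' toy write `time cv1 cv2`; solvent-trap trajectories write
#' `time cv1 S restraint_energy`; restraint series write
#' `time restraint_energy` (plus `S` when available).
#'
#' @param x an `fmd_trajectory` or `restraint_series`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_colvar <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "fmd_trajectory")) {
    writeLines(sprintf("# model: %s", x$model), con)
    writeLines(sprintf("# seed: %s", format(x$seed)), con)
    if (!is.null(x$S)) {
      writeLines("#! FIELDS time cv1 S restraint_energy", con)
      writeLines(sprintf("%.17g %.17g %.17g %.17g",
                         x$times, x$cv1, x$S, x$V_S), con)
    } else {
      writeLines("#! FIELDS time cv1 cv2", con)
      writeLines(sprintf("%.17g %.17g %.17g", x$times, x$cv1, x$cv2), con)
    }
  } else if (inherits(x, "restraint_series")) {
    if (!is.null(x$seed)) writeLines(sprintf("# seed: %s", format(x$seed)), con)
    if (!is.null(x$S)) {
      writeLines("#! FIELDS time S restraint_energy", con)
      writeLines(sprintf("%.17g %.17g %.17g", x$times, x$S, x$V_S), con)
    } else {
      writeLines("#! FIELDS time restraint_energy", con)
      writeLines(sprintf("%.17g %.17g", x$times, x$V_S), con)
    }
  } else stop("cannot write object of class ", class(x)[1], " as COLVAR")
  invisible(path)
}

#' Read a COLVAR-style text file
#'
#' Columns are mapped by the `#! FIELDS` header names; without a header the
#' columns are assumed to be `time cv1 [cv2]`. Returns an `fmd_trajectory`
#' when a `cv1` column is present, otherwise a [restraint_series()]. The
#' time column must be uniform.
#'
#' @param path input file
#' @return an `fmd_trajectory` or `restraint_series`
#' @export
read_colvar <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  fline <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(data_idx) == 0L) stop("no data in ", path)
  cols <- if (length(fline))
    strsplit(trimws(sub("^#!\\s*FIELDS\\s+", "", fline[1])), "\\s+")[[1]]
  else NULL
  rows <- lapply(data_idx, function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(vals))
      stop(sprintf("malformed COLVAR line %d in %s", i, path))
    vals
  })
  ncol <- unique(lengths(rows))
  if (length(ncol) != 1L) stop("inconsistent column counts in ", path)
  m <- do.call(rbind, rows)
  if (is.null(cols)) cols <- c("time", "cv1", "cv2")[seq_len(ncol)]
  if (length(cols) != ncol)
    stop("FIELDS header declares ", length(cols), " columns but data has ", ncol)
  colnames(m) <- cols
  if (!"time" %in% cols) stop("no time column in ", path)
  t <- m[, "time"]
  dts <- diff(t)
  if (length(dts) && any(abs(dts - dts[1]) > 1e-9 * max(abs(dts[1]), 1)))
    stop("non-uniform time column in ", path)
  seed <- sub("^#\\s*seed:\\s*", "", grep("^#\\s*seed:", lines, value = TRUE)[1])
  if ("cv1" %in% cols) {
    traj <- structure(list(times = t, cv1 = m[, "cv1"],
                           cv2 = if ("cv2" %in% cols) m[, "cv2"] else NULL,
                           S = if ("S" %in% cols) m[, "S"] else NULL,
                           V_S = if ("restraint_energy" %in% cols)
                             m[, "restraint_energy"] else NULL,
                           seed = if (is.na(seed)) NULL else seed,
                           dt_out = if (length(dts)) dts[1] else NA_real_,
                           model = "colvar"),
                      class = "fmd_trajectory")
    return(traj)
  }
  if (!"restraint_energy" %in% cols)
    stop("COLVAR file ", path, " has neither cv1 nor restraint_energy columns")
  out <- restraint_series(t, m[, "restraint_energy"])
  if ("S" %in% cols) out$S <- m[, "S"]
  out
}

#' Read a restraint-energy series for FEP
#'
#' Like [read_colvar()] but guarantees a [restraint_series()]; errors at
#' read time when the file carries no restraint-energy column so that a
#' downstream FEP stage never starts on unusable input.
#'
#' @param path input file
#' @return a [restraint_series()]
#' @export
read_restraint_series <- function(path) {
  x <- read_colvar(path)
  if (inherits(x, "restraint_series")) return(x)
  if (is.null(x$V_S))
    stop("COLVAR file ", path,
         " has no restraint_energy column; cannot run FEP on it")
  out <- restraint_series(x$times, x$V_S)
  out$S <- x$S
  out
}

#' Write a PMF table
#'
#' Two-column text `z w` with a `#` metadata header (gnuplot-compatible),
#' recording the temperature and whether the profile has been referenced to
#' the unbound plateau.
#'
#' @param pmf a `pmf`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# T: %.17g", pmf$T), con)
  writeLines(sprintf("# referenced: %s",
                     if (isTRUE(attr(pmf, "referenced"))) "yes" else "no"), con)
  rr <- attr(pmf, "ref_range")
  if (!is.null(rr))
    writeLines(sprintf("# ref_range: %.17g %.17g", rr[1], rr[2]), con)
  writeLines("#! FIELDS z w", con)
  writeLines(sprintf("%.17g %.17g", pmf$z, pmf$w), con)
  invisible(path)
}

#' Read a PMF table written by [write_pmf()]
#'
#' @param path input file
#' @return a `pmf`
#' @export
read_pmf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(data_idx) == 0L) stop("no data in ", path)
  m <- do.call(rbind, lapply(data_idx, function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(vals) != 2L || anyNA(vals))
      stop(sprintf("malformed PMF line %d in %s", i, path))
    vals
  }))
  Tline <- grep("^#\\s*T:", lines, value = TRUE)
  T <- if (length(Tline)) as.numeric(sub("^#\\s*T:\\s*", "", Tline[1])) else 298
  refd <- any(grepl("^#\\s*referenced:\\s*yes", lines))
  pmf_profile(m[, 1], m[, 2], T = T, referenced = refd)
}

#' Default run configuration
#'
#' A nested list aggregating every tunable of the workflow - funnel
#' geometry, coordination restraint, well-tempered deposition, binding
#' conventions, toy-engine settings and analysis settings - with each
#' default equal to the constant used throughout the package's host-guest
#' protocol where one exists.
#'
#' @return a named nested list (class `run_config`)
#' @export
default_run_config <- function() {
  structure(list(
    geometry = unclass(funnel_geometry()),
    restraint = unclass(coordination_restraint()),
    wt = unclass(wt_params()),
    binding = unclass(binding_config()),
    engine = list(preset = "double_well", nsteps = 1e6, dt = 0.002, seed = 1,
                  out_stride = 100),
    analysis = list(grid_nz = 200, grid_nc = 100, grid_z = c(0, 2),
                    grid_c = c(-1, 1), window = 500, eval_stride = 25)),
    class = "run_config")
}

#' Read and write run configurations (YAML)
#'
#' Configurations round-trip bit-identically: `write_run_config()` followed
#' by `read_run_config()` reproduces the same values. Fields missing from
#' the file fall back to [default_run_config()].
#'
#' @param path configuration file
#' @return the configuration list (class `run_config`)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (sec in names(user)) {
    if (!sec %in% names(cfg)) stop("unknown configuration section: ", sec)
    for (k in names(user[[sec]])) {
      if (!k %in% names(cfg[[sec]]))
        stop("unknown configuration key: ", sec, "$", k)
      cfg[[sec]][[k]] <- user[[sec]][[k]]
    }
  }
  cfg
}

#' @rdname read_run_config
#' @param cfg a configuration list
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 17)
  invisible(path)
}
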