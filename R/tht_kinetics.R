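# Thioflavin T (ThT) fibrillization-kinetics analysis. ThT fluorescence
# increases on binding amyloid, so a plate-reader time course traces
# aggregation as a sigmoid. Each background-subtracted well is fit with the
# Gompertz function
#
#   y(t) = A * exp(-exp(-(t - t_i) / B))
#
# by Levenberg-Marquardt nonlinear least squares: A is the amplitude (RFU),
# t_i the inflection time (h), and B a time constant whose reciprocal
# k_app = 1/B is the apparent elongation rate (1/h). The half-maximal time
# is t_half = t_i - B * ln(ln 2), and the aggregation propensity is
# 1 / t_half. Wells with low raw signal or poor fits (bubble artifacts)
# are discarded by the QC filter.

#' Construct a ThT fluorescence time course
#'
#' @param well_id well identifier (e.g. "A1").
#' @param time time points in hours, strictly increasing, >= 6 points
#'   (background subtraction needs 5, the fit needs more).
#' @param rfu relative fluorescence units, same length as `time`.
#' @param condition condition label (e.g. construct name).
#' @param background_subtracted has the baseline already been removed?
#' @param raw_max maximum of the raw (pre-subtraction) RFU values, kept for
#'   QC; defaults to `max(rfu)` for raw curves.
#' @return an object of class `tht_curve`.
#' @export
tht_curve <- function(well_id, time, rfu, condition = "unknown",
                      background_subtracted = FALSE, raw_max = NULL) {
  time <- as.numeric(time); rfu <- as.numeric(rfu)
  if (length(time) != length(rfu))
    stop("tht_curve: time and rfu lengths differ in well ", well_id)
  if (length(time) < 6L)
    stop("tht_curve: need >= 6 points in well ", well_id)
  if (any(diff(time) <= 0))
    stop("tht_curve: time must be strictly increasing in well ", well_id)
  if (anyNA(rfu))
    warning("tht_curve: well ", well_id, " has missing values; ",
            "gaps are not interpolated")
  if (is.null(raw_max)) raw_max <- if (background_subtracted) NA_real_
                                   else max(rfu, na.rm = TRUE)
  structure(list(well_id = well_id, condition = condition, time = time,
                 rfu = rfu, background_subtracted = background_subtracted,
                 raw_max = raw_max),
            class = "tht_curve")
}

#' @export
print.tht_curve <- function(x, ...) {
  cat(sprintf(
    "<tht_curve> well %s (%s): %d points over %.2f h%s\n",
    x$well_id, x$condition, length(x$time), diff(range(x$time)),
    if (x$background_subtracted) ", background-subtracted" else ""))
  invisible(x)
}

#' Load a plate-reader export
#'
#' Reads a delimited text export of ThT time courses. Wide layout: one time
#' column (named `time`, case-insensitive) and one column per well. Long
#' layout: columns `well`, `time`, `rfu`. Times are normalised to hours on
#' load.
#'
#' @param path CSV/TSV file (delimiter sniffed from the header line).
#' @param layout `"wide"` or `"long"`.
#' @param time_unit `"h"` or `"min"`; minutes are converted to hours.
#' @param conditions optional named character vector mapping well ids to
#'   condition labels.
#' @return list of [tht_curve] objects, named by well.
#' @export
load_plate <- function(path, layout = c("wide", "long"),
                       time_unit = c("h", "min"), conditions = NULL) {
  layout <- match.arg(layout)
  time_unit <- match.arg(time_unit)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  to_h <- if (time_unit == "min") 1 / 60 else 1
  cond_of <- function(w) {
    if (!is.null(conditions) && w %in% names(conditions)) conditions[[w]]
    else "unknown"
  }
  if (layout == "wide") {
    tcol <- which(tolower(names(df)) == "time")
    if (length(tcol) != 1L)
      stop("load_plate: wide layout needs exactly one 'time' column")
    wells <- names(df)[-tcol]
    if (anyDuplicated(wells))
      stop("load_plate: duplicated well id: ",
           wells[duplicated(wells)][1])
    tt <- df[[tcol]] * to_h
    curves <- lapply(wells, function(w)
      tht_curve(w, tt, df[[w]], cond_of(w)))
  } else {
    need <- c("well", "time", "rfu")
    if (!all(need %in% tolower(names(df))))
      stop("load_plate: long layout needs columns well, time, rfu")
    names(df) <- tolower(names(df))
    curves <- lapply(split(df, df$well), function(d)
      tht_curve(d$well[1], d$time * to_h, d$rfu, cond_of(d$well[1])))
    wells <- vapply(curves, function(cv) cv$well_id, character(1))
  }
  names(curves) <- wells
  curves
}

#' Subtract the pre-aggregation background
#'
#' Averages the first five raw readings of the well and subtracts that
#' baseline from every point. Refuses to run twice on the same curve. The
#' raw maximum is retained for the QC low-signal rule.
#'
#' @param curve a [tht_curve] with >= 5 points, not yet subtracted.
#' @return the background-subtracted [tht_curve].
#' @export
subtract_background <- function(curve) {
  stopifnot(inherits(curve, "tht_curve"))
  if (curve$background_subtracted)
    stop("subtract_background: curve ", curve$well_id,
         " is already background-subtracted")
  if (length(curve$rfu) < 5L)
    stop("subtract_background: need >= 5 points")
  bg <- mean(curve$rfu[1:5])
  tht_curve(curve$well_id, curve$time, curve$rfu - bg, curve$condition,
            background_subtracted = TRUE,
            raw_max = max(curve$rfu, na.rm = TRUE))
}

#' Fit the Gompertz growth function to a ThT curve
#'
#' Minimises the sum of squared residuals of
#' `y(t) = A * exp(-exp(-(t - t_i)/B))` over `(A, t_i, B)` by
#' Levenberg-Marquardt least squares. Starting values: `A0 = max(rfu)`,
#' `t_i0` = time of the steepest observed increase, `B0` = time range / 10.
#' Non-convergence is reported via `converged = FALSE`, never silently.
#'
#' @param curve a background-subtracted [tht_curve].
#' @return an object of class `gompertz_fit`: list with `A`, `t_i`, `B`,
#'   `k_app` (= 1/B), `t_half` (= t_i - B ln ln 2), `mse` (residual sum of
#'   squares / n), `converged`, `well_id`, `condition`, `n`, and the data.
#' @export
fit_gompertz <- function(curve) {
  stopifnot(inherits(curve, "tht_curve"))
  if (!curve$background_subtracted)
    stop("fit_gompertz: subtract the background first (well ",
         curve$well_id, ")")
  ok <- !is.na(curve$rfu)
  tt <- curve$time[ok]; yy <- curve$rfu[ok]
  if (length(yy) < 4L)
    stop("fit_gompertz: fewer points than parameters in well ",
         curve$well_id)
  if (all(abs(yy) < .Machine$double.eps^0.5))
    stop("fit_gompertz: all-zero curve in well ", curve$well_id)
  slopes <- diff(yy) / diff(tt)
  start <- list(A = max(yy), t_i = tt[which.max(slopes)],
                B = diff(range(tt)) / 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ A * exp(-exp(-(tt - t_i) / B)), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(A = NA_real_, t_i = NA_real_, B = NA_real_,
                k_app = NA_real_, t_half = NA_real_, mse = NA_real_,
                converged = FALSE, diagnostics = conditionMessage(fit))
  } else {
    cf <- stats::coef(fit)
    conv <- isTRUE(fit$convInfo$isConv)
    mse <- sum(stats::resid(fit)^2) / length(yy)
    out <- list(A = unname(cf["A"]), t_i = unname(cf["t_i"]),
                B = unname(cf["B"]), k_app = 1 / unname(cf["B"]),
                t_half = unname(cf["t_i"]) - unname(cf["B"]) * log(log(2)),
                mse = mse, converged = conv, diagnostics = NULL)
  }
  out$well_id <- curve$well_id
  out$condition <- curve$condition
  out$n <- length(yy)
  out$curve <- curve
  class(out) <- "gompertz_fit"
  out
}

#' @export
print.gompertz_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "<gompertz_fit> well %s: A=%.3g RFU, t_i=%.3g h, B=%.3g h (k_app=%.3g /h, t_half=%.3g h), mse=%.3g\n",
      x$well_id, x$A, x$t_i, x$B, x$k_app, x$t_half, x$mse))
  else cat(sprintf("<gompertz_fit> well %s: NOT converged (%s)\n",
                   x$well_id, x$diagnostics))
  invisible(x)
}

#' Quality-control filter for fitted ThT curves
#'
#' A well is discarded when its maximum raw RFU is below `min_raw_rfu`
#' (reason `low_signal`) or when its fit MSE exceeds one standard deviation
#' of the per-curve maximum ThT signals within its condition group (reason
#' `high_mse`); both reasons are recorded when both hold. Either defect
#' alone discards: failed wells show bubble-like artifacts, and a
#' high-signal bubble curve must not survive on signal alone. With a
#' single curve in a group the sd is undefined and the MSE rule is skipped
#' with a warning.
#'
#' @param fits list of [fit_gompertz] results (curves are carried inside).
#' @param min_raw_rfu low-signal cutoff on the maximum raw RFU (default 50).
#' @param mse_sd_factor multiplier on the group sd used as the MSE cutoff
#'   (default 1).
#' @return an object of class `qc_report`: data frame with columns `well`,
#'   `condition`, `max_raw_rfu`, `mse`, `verdict` (`"keep"`/`"discard"`),
#'   `reasons`; attributes record the thresholds used.
#' @export
qc_filter <- function(fits, min_raw_rfu = 50, mse_sd_factor = 1) {
  stopifnot(length(fits) > 0L)
  df <- data.frame(
    well = vapply(fits, function(f) f$well_id, character(1)),
    condition = vapply(fits, function(f) f$condition, character(1)),
    max_raw_rfu = vapply(fits, function(f) f$curve$raw_max, numeric(1)),
    mse = vapply(fits, function(f) f$mse, numeric(1)),
    stringsAsFactors = FALSE)
  mse_cut <- rep(NA_real_, nrow(df))
  for (g in unique(df$condition)) {
    i <- which(df$condition == g)
    if (length(i) < 2L) {
      warning("qc_filter: single curve in condition '", g,
              "'; MSE criterion skipped")
      next
    }
    mse_cut[i] <- mse_sd_factor * stats::sd(df$max_raw_rfu[i])
  }
  low <- !is.na(df$max_raw_rfu) & df$max_raw_rfu < min_raw_rfu
  high <- !is.na(mse_cut) & !is.na(df$mse) & df$mse > mse_cut
  bad_fit <- vapply(fits, function(f) !isTRUE(f$converged), logical(1))
  high <- high | bad_fit
  df$mse_cutoff <- mse_cut
  df$verdict <- ifelse(low | high, "discard", "keep")
  df$reasons <- mapply(function(l, h)
    paste(c(if (l) "low_signal", if (h) "high_mse"), collapse = ","),
    low, high)
  rownames(df) <- NULL
  structure(df, min_raw_rfu = min_raw_rfu, mse_sd_factor = mse_sd_factor,
            class = c("qc_report", "data.frame"))
}

#' Aggregation propensity (inverse half-time)
#'
#' The propensity is `1 / t_half`. In analytic mode (default) the half-time
#' comes from the fit: `t_half = t_i - B * ln(ln 2)`. In interpolation mode
#' it is the linearly interpolated time at which the observed
#' background-subtracted curve first crosses half its maximum.
#'
#' @param x a `gompertz_fit` (analytic mode) or a background-subtracted
#'   [tht_curve] (interpolation mode).
#' @param mode `"analytic"` or `"interpolate"`.
#' @return propensity in 1/h, with the half-time as attribute `t_half`.
#' @export
aggregation_propensity <- function(x, mode = c("analytic", "interpolate")) {
  mode <- match.arg(mode)
  if (mode == "analytic") {
    stopifnot(inherits(x, "gompertz_fit"))
    if (!isTRUE(x$converged))
      stop("aggregation_propensity: fit did not converge")
    t_half <- x$t_half
  } else {
    curve <- if (inherits(x, "gompertz_fit")) x$curve else x
    stopifnot(inherits(curve, "tht_curve"))
    if (!curve$background_subtracted)
      stop("aggregation_propensity: curve must be background-subtracted")
    yy <- curve$rfu; tt <- curve$time
    half <- max(yy, na.rm = TRUE) / 2
    above <- which(yy >= half)
    if (length(above) == 0L)
      stop("aggregation_propensity: curve never reaches half-maximum")
    j <- above[1]
    if (j == 1L) t_half <- tt[1]
    else t_half <- tt[j - 1] + (half - yy[j - 1]) *
        (tt[j] - tt[j - 1]) / (yy[j] - yy[j - 1])
  }
  if (is.na(t_half) || t_half <= 0)
    stop("aggregation_propensity: non-positive half-time (unphysical)")
  structure(1 / t_half, t_half = t_half)
}

#' Simulate ThT curves from Gompertz parameters
#'
#' Generates replicate wells with
#' `rfu = baseline + A * exp(-exp(-(t - t_i)/B)) + N(0, noise_sd)`,
#' sampled every `dt` hours. The default sampling emulates a plate read
#' every 5 minutes for 24 hours (289 points). Each replicate uses a
#' distinct sub-seed derived from `seed`, so the whole set is reproducible.
#'
#' @param A,t_i,B Gompertz parameters (RFU, h, h), all > 0.
#' @param noise_sd Gaussian noise sd in RFU (default 0).
#' @param baseline additive baseline RFU (default 0).
#' @param n_points number of time points (default 289).
#' @param dt sampling interval in hours (default 5/60).
#' @param n_replicates number of wells (default 1).
#' @param seed base RNG seed.
#' @param condition condition label for the wells.
#' @return list of [tht_curve] objects (raw, not background-subtracted).
#' @export
simulate_tht <- function(A, t_i, B, noise_sd = 0, baseline = 0,
                         n_points = 289, dt = 5 / 60, n_replicates = 1,
                         seed = 1L, condition = "sim") {
  stopifnot(A > 0, B > 0, n_points >= 6, dt > 0, n_replicates >= 1)
  tt <- (seq_len(n_points) - 1) * dt
  mu <- baseline + A * exp(-exp(-(tt - t_i) / B))
  lapply(seq_len(n_replicates), function(r) {
    eps <- if (noise_sd > 0)
      with_seed((as.integer(seed) + r - 1L) %% .Machine$integer.max,
                stats::rnorm(n_points, 0, noise_sd))
    else 0
    tht_curve(sprintf("sim%02d", r), tt, mu + eps, condition)
  })
}

#' Tabulate per-well fits with QC verdicts
#'
#' @param fits list of `gompertz_fit` objects.
#' @param qc optional [qc_filter] report; verdicts are joined by well.
#' @return data frame with columns `well`, `condition`, `A`, `t_i`, `B`,
#'   `k_app`, `t_half`, `mse`, `converged`, `verdict`.
#' @export
fit_table <- function(fits, qc = NULL) {
  df <- data.frame(
    well = vapply(fits, function(f) f$well_id, character(1)),
    condition = vapply(fits, function(f) f$condition, character(1)),
    A = vapply(fits, function(f) f$A, numeric(1)),
    t_i = vapply(fits, function(f) f$t_i, numeric(1)),
    B = vapply(fits, function(f) f$B, numeric(1)),
    k_app = vapply(fits, function(f) f$k_app, numeric(1)),
    t_half = vapply(fits, function(f) f$t_half, numeric(1)),
    mse = vapply(fits, function(f) f$mse, numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    stringsAsFactors = FALSE)
  df$verdict <- if (is.null(qc)) NA_character_
                else qc$verdict[match(df$well, qc$well)]
  df
}

#' Per-condition summary of accepted fits
#'
#' Mean and sd of `k_app` and of the aggregation propensity across the
#' accepted wells of each condition. Inferential group statistics are out
#' of scope; export the table to a statistics package for those.
#'
#' @param fits list of `gompertz_fit` objects.
#' @param qc optional [qc_filter] report; discarded wells are excluded.
#' @return data frame keyed by condition.
#' @export
condition_summary <- function(fits, qc = NULL) {
  tab <- fit_table(fits, qc)
  if (!is.null(qc)) tab <- tab[tab$verdict == "keep", , drop = FALSE]
  if (nrow(tab) == 0L) {
    warning("condition_summary: no accepted wells")
    return(data.frame(condition = character(), n = integer(),
                      k_app_mean = numeric(), k_app_sd = numeric(),
                      propensity_mean = numeric(),
                      propensity_sd = numeric(), t_half_mean = numeric()))
  }
  tab$propensity <- 1 / tab$t_half
  agg <- lapply(split(tab, tab$condition), function(d) {
    data.frame(condition = d$condition[1], n = nrow(d),
               k_app_mean = mean(d$k_app), k_app_sd = stats::sd(d$k_app),
               propensity_mean = mean(d$propensity),
               propensity_sd = stats::sd(d$propensity),
               t_half_mean = mean(d$t_half))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Overlay plot of observed curves and fitted Gompertz models
#'
#' @param fits list of `gompertz_fit` objects.
#' @param out_path output path; `.png` and `.svg` siblings are written.
#' @return files written, invisibly.
#' @export
plot_fits <- function(fits, out_path) {
  obs <- do.call(rbind, lapply(fits, function(f)
    data.frame(well = f$well_id, time = f$curve$time, rfu = f$curve$rfu)))
  pred <- do.call(rbind, lapply(fits, function(f) {
    if (!isTRUE(f$converged)) return(NULL)
    tt <- seq(min(f$curve$time), max(f$curve$time), length.out = 200)
    data.frame(well = f$well_id, time = tt,
               rfu = f$A * exp(-exp(-(tt - f$t_i) / f$B)))
  }))
  p <- ggplot2::ggplot(obs, ggplot2::aes(time, rfu)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(data = pred, colour = "firebrick") +
    ggplot2::facet_wrap(~well, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "ThT fluorescence (RFU)") +
    ggplot2::theme_minimal()
  base <- tools::file_path_sans_ext(out_path)
  files <- paste0(base, c(".png", ".svg"))
  ggplot2::ggsave(files[1], p, width = 8, height = 5, dpi = 150)
  ggplot2::ggsave(files[2], p, width = 8, height = 5,
                  device = grDevices::svg)
  invisible(files)
}
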