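# FAP retention indices for a linear temperature-programmed method, their
# inversion, relative retention times, and retention-time-locking calibration.

#' FAP retention index of a retention time
#'
#' Linear temperature-programmed retention index against the FAP ladder:
#' for a compound eluting at `t` between the pyrrolidides with `n` and
#' `N = n + 1` carbon atoms,
#' `RI = 100 * (n + (t - t(n)) / (t(N) - t(n)))`.
#' The index equals 100 x carbon number at every anchor. Values are returned
#' at full precision; reported indices are rounded to whole numbers with
#' [ri_report()], matching the stability of the scale (run-to-run
#' fluctuations are on the order of one index unit, so the first decimal is
#' not meaningful).
#'
#' @param t retention time(s), minutes (or any monotone retention proxy, as
#'   long as the anchors are on the same scale).
#' @param anchors a [fap_anchor_set()].
#' @return numeric vector of class `ri_fap` with attribute `brackets`
#'   (two-column matrix of bracketing carbon numbers).
#' @export
#' @examples
#' a <- fap_anchor_set(c("23" = 30.000, "24" = 32.972))
#' compute_ri_fap(31.486, a) # 2350
compute_ri_fap <- function(t, anchors) {
  stopifnot(inherits(anchors, "fap_anchor_set"))
  a <- as.numeric(anchors)
  carbons <- as.integer(names(anchors))
  k <- length(a)
  if (any(t < a[1] - 1e-12 | t > a[k] + 1e-12)) {
    out <- t[t < a[1] - 1e-12 | t > a[k] + 1e-12]
    hint <- if (any(out > a[k])) {
      paste0("; a compound beyond ", carbons[k],
             ":0-P requires extending the ladder (e.g. include 26:0-P)")
    } else ""
    stop(sprintf(
      "retention time(s) %s outside the anchor ladder [%.3f, %.3f] min%s",
      paste(sprintf("%.3f", out), collapse = ", "), a[1], a[k], hint),
      call. = FALSE)
  }
  i <- findInterval(t, a)
  i[i >= k] <- k - 1L # t at the last anchor: use the top bracket
  if (any(carbons[i + 1L] != carbons[i] + 1L)) {
    bad <- unique(paste0(carbons[i], "-", carbons[i + 1L])[
      carbons[i + 1L] != carbons[i] + 1L])
    stop("anchor ladder has a gap spanning t (missing carbon between ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  ri <- 100 * (carbons[i] + (t - a[i]) / (a[i + 1L] - a[i]))
  structure(ri, brackets = cbind(n = carbons[i], N = carbons[i + 1L]),
            class = "ri_fap")
}

#' Report retention indices as whole numbers
#'
#' @param ri numeric RI values (e.g. from [compute_ri_fap()]).
#' @return integer-valued numeric, rounded half-up.
#' @export
ri_report <- function(ri) round_half_up(as.numeric(ri), 0)

#' @export
print.ri_fap <- function(x, ...) {
  b <- attr(x, "brackets")
  cat("<ri_fap>", paste(sprintf("%d (C%d-C%d)", ri_report(x), b[, 1], b[, 2]),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Invert a FAP retention index to a retention time
#'
#' Exact algebraic inverse of [compute_ri_fap()] on the same anchor ladder:
#' `t = t(n) + (RI/100 - n) * (t(N) - t(n))`.
#'
#' @param ri retention index value(s).
#' @param anchors a [fap_anchor_set()].
#' @return retention time(s), minutes.
#' @export
invert_ri_fap <- function(ri, anchors) {
  stopifnot(inherits(anchors, "fap_anchor_set"))
  ri <- as.numeric(ri)
  a <- as.numeric(anchors)
  carbons <- as.integer(names(anchors))
  k <- length(a)
  if (any(ri < 100 * carbons[1] - 1e-9 | ri > 100 * carbons[k] + 1e-9)) {
    stop(sprintf("RI outside the anchor ladder [%d, %d]",
                 100 * carbons[1], 100 * carbons[k]), call. = FALSE)
  }
  i <- findInterval(ri / 100, carbons)
  i[i >= k] <- k - 1L
  if (any(carbons[i + 1L] != carbons[i] + 1L)) {
    stop("anchor ladder has a gap spanning the requested RI", call. = FALSE)
  }
  a[i] + (ri / 100 - carbons[i]) * (a[i + 1L] - a[i])
}

#' Relative retention time
#'
#' Retention time relative to an internal standard (conventionally
#' 5alpha-cholestane).
#'
#' @param t retention time(s), minutes.
#' @param t_reference internal-standard retention time, minutes (> 0).
#' @return unitless ratio(s).
#' @export
compute_rrt <- function(t, t_reference) {
  if (!is.numeric(t_reference) || length(t_reference) != 1 ||
      t_reference <= 0) {
    stop("t_reference must be a single positive retention time",
         call. = FALSE)
  }
  t / t_reference
}

#' Fit a five-point retention-time-locking calibration
#'
#' The lock compound (24:0-P) is measured at the nominal inlet pressure and
#' at -20%, -10%, +10% and +20% of it; a quadratic `rt(p)` is fitted by
#' least squares. The quadratic form approximates the underlying holdup-time
#' physics (`rt ~ a + b/p`) over the calibrated +-20% envelope; the
#' approximation error is absorbed by the verification step of
#' [solve_lock_pressure()].
#'
#' @param points data.frame with columns `pressure` (relative units,
#'   nominal = 1) and `rt` (minutes); exactly 5 rows.
#' @param lock_target target retention time of the lock compound, minutes
#'   (default 32.972, the 24:0-P lock point).
#' @param pressure_grid expected relative pressures.
#' @param grid_tol tolerance for checking the pressure grid.
#' @return object of class `rtl_calibration`: coefficients, fitted model,
#'   residuals, `lock_target`, pressure and rt ranges, `degenerate` flag,
#'   `monotone` flag.
#' @export
fit_rtl_calibration <- function(points, lock_target = 32.972,
                                pressure_grid = c(0.8, 0.9, 1.0, 1.1, 1.2),
                                grid_tol = 0.02) {
  stopifnot(is.data.frame(points), all(c("pressure", "rt") %in% names(points)))
  if (nrow(points) != 5) {
    stop("retention time locking requires exactly 5 calibration points, got ",
         nrow(points), call. = FALSE)
  }
  if (anyDuplicated(points$pressure)) {
    stop("calibration pressures must be distinct", call. = FALSE)
  }
  p <- sort(points$pressure)
  if (any(abs(p - sort(pressure_grid)) > grid_tol)) {
    stop("calibration pressures must be the nominal pressure and -20%, ",
         "-10%, +10%, +20% deviations", call. = FALSE)
  }
  fit <- stats::lm(rt ~ pressure + I(pressure^2), data = points)
  degenerate <- stats::sd(points$rt) < 1e-9
  monotone <- all(diff(points$rt[order(points$pressure)]) < 0) ||
    all(diff(points$rt[order(points$pressure)]) > 0)
  structure(
    list(points = points[order(points$pressure), ],
         coef = stats::coef(fit), fit = fit,
         residuals = stats::resid(fit),
         lock_target = lock_target,
         pressure_range = range(points$pressure),
         rt_range = range(points$rt),
         degenerate = degenerate, monotone = monotone),
    class = "rtl_calibration"
  )
}

#' @export
print.rtl_calibration <- function(x, ...) {
  cat(sprintf(
    "<rtl_calibration> lock target %.3f min; rt range %.3f-%.3f min%s%s\n",
    x$lock_target, x$rt_range[1], x$rt_range[2],
    if (x$degenerate) " [degenerate]" else "",
    if (!x$monotone) " [non-monotone]" else ""))
  invisible(x)
}

.rtl_predict <- function(cal, p) {
  unname(cal$coef[1] + cal$coef[2] * p + cal$coef[3] * p^2)
}

#' Solve for the locking pressure
#'
#' Finds the inlet pressure at which the fitted calibration predicts the
#' lock compound at its target time, within the calibrated pressure
#' interval. When a measurement function is supplied (a verification run,
#' standard practice after relocking), the solution is refined by up to
#' `max_refine` local-slope corrections using the confirmatory
#' measurement(s), which removes the quadratic-approximation residual.
#'
#' @param cal an [fit_rtl_calibration()] result.
#' @param measure optional function `p -> rt` performing a verification run
#'   at pressure `p`.
#' @param max_refine maximum verification corrections (default 4).
#' @param tol stop refining when |rt - target| < `tol` minutes.
#' @return locking pressure (relative units), with attribute `verified_rt`
#'   when a measurement function was used.
#' @export
solve_lock_pressure <- function(cal, measure = NULL, max_refine = 4,
                                tol = 5e-4) {
  stopifnot(inherits(cal, "rtl_calibration"))
  if (cal$degenerate) {
    stop("degenerate calibration: retention time does not respond to ",
         "pressure", call. = FALSE)
  }
  tgt <- cal$lock_target
  if (tgt < cal$rt_range[1] || tgt > cal$rt_range[2]) {
    stop(sprintf(
      paste0("lock target %.3f min outside the calibrated range ",
             "[%.3f, %.3f] min; the column state has drifted beyond the ",
             "+-20%% pressure envelope (avoid column-length changes > 1 m) ",
             "- recalibrate"),
      tgt, cal$rt_range[1], cal$rt_range[2]), call. = FALSE)
  }
  f <- function(p) .rtl_predict(cal, p) - tgt
  lo <- cal$pressure_range[1]; hi <- cal$pressure_range[2]
  p <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  if (!is.null(measure)) {
    # verification runs: first correction uses the calibration slope, later
    # ones the secant through the two most recent measurements
    slope <- cal$coef[2] + 2 * cal$coef[3] * p
    p_prev <- NA_real_; obs_prev <- NA_real_
    for (k in seq_len(max_refine)) {
      obs <- measure(p)
      if (abs(obs - tgt) < tol) {
        return(structure(p, verified_rt = obs))
      }
      if (!is.na(p_prev) && abs(obs - obs_prev) > 1e-12) {
        slope <- (obs - obs_prev) / (p - p_prev)
      }
      p_prev <- p; obs_prev <- obs
      p <- p + (tgt - obs) / slope
    }
    return(structure(p, verified_rt = measure(p)))
  }
  p
}

#' Read a five-point RTL calibration file
#'
#' TSV with columns `pressure_rel, rt_min`.
#'
#' @param path file path.
#' @param lock_target lock target, minutes.
#' @return an `rtl_calibration`.
#' @export
read_rtl_calibration <- function(path, lock_target = 32.972) {
  tab <- utils::read.delim(path)
  if (!all(c("pressure_rel", "rt_min") %in% names(tab))) {
    stop("calibration file needs columns pressure_rel, rt_min", call. = FALSE)
  }
  fit_rtl_calibration(data.frame(pressure = tab$pressure_rel,
                                 rt = tab$rt_min),
                      lock_target = lock_target)
}
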