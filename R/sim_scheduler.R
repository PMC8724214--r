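# SIM acquisition schedules: the two initial 20-molecular-ion methods and
# the merged four-window method under an ion budget.

.new_window <- function(start, end, unit, indep, dep) {
  structure(list(start = start, end = end, unit = unit,
                 retention_independent_ions = sort(unname(indep)),
                 retention_dependent_ions = dep),
            class = "sim_time_window")
}

.window_ions <- function(w) {
  sort(unique(c(w$retention_independent_ions,
                unlist(w$retention_dependent_ions, use.names = FALSE))))
}

#' All distinct ions of a SIM method
#'
#' @param method a `sim_method`.
#' @return sorted numeric vector of all m/z monitored anywhere.
#' @export
sim_method_ions <- function(method) {
  sort(unique(unlist(lapply(method$windows, .window_ions))))
}

#' Ions of one window of a SIM method
#'
#' @param method a `sim_method`.
#' @param i window index.
#' @return sorted numeric m/z vector.
#' @export
sim_window_ions <- function(method, i) .window_ions(method$windows[[i]])

.new_method <- function(name, windows, budget) {
  structure(list(name = name, windows = windows, budget = budget),
            class = "sim_method")
}

#' @export
print.sim_method <- function(x, ...) {
  cat(sprintf("<sim_method> %s: %d window(s), budget %d\n", x$name,
              length(x$windows), x$budget))
  for (i in seq_along(x$windows)) {
    w <- x$windows[[i]]
    cat(sprintf("  [%d] %s-%s %s: %d ions (%d groups)\n", i,
                format(w$start), format(w$end), w$unit,
                length(.window_ions(w)), length(w$retention_dependent_ions)))
  }
  invisible(x)
}

# molecular-ion grid rows for a set of carbon numbers, as named list
.grid_row <- function(cn, dbs = 3:0) {
  g <- molecular_ion_grid()
  sort(unname(g[as.character(cn), as.character(dbs)]))
}

#' Build the two initial SIM methods
#'
#' The starting point of method development: every sample is measured by
#' two complementary runs covering the full 5 x 4 molecular-ion grid.
#' Method 1 monitors the C28 and C29 molecular ions (8 ions) together with
#' the nine retention-independent fragment ions throughout the run.
#' Method 2 covers C27, C30 and C31 in three time windows: C27 ions only in
#' the early part of the run (sterol-TMS retention increases with carbon
#' number, so C27/C31 cannot overlap), C31 thereafter; the pentacyclic
#' fragment pair 189/218 replaces the FAP ion 126 in the middle window where
#' the triterpenols elute (and where only three C31 ions leave room).
#'
#' @param library a `reference_library` (defines which groups exist; the
#'   published grid is monitored in full for discovery).
#' @param budget maximum simultaneous SIM ions (default 17; 15-18 can be
#'   measured without loss of quality).
#' @param minutes window boundaries in minutes (start, C27/C31 switch,
#'   mid-window end, run end).
#' @return list of two `sim_method` objects.
#' @export
build_initial_methods <- function(library = builtin_library(), budget = 17,
                                  minutes = c(20, 29.6, 32.5, 41.8)) {
  frag <- retention_independent_ions()
  m1 <- .new_method("SIM 1", list(
    .new_window(minutes[1], minutes[4], "min", frag,
                list(C28 = .grid_row(28), C29 = .grid_row(29)))), budget)
  frag_mid <- c(retention_independent_ions(include_fap = FALSE,
                                           include_pentacyclic = TRUE),
                "fap1" = 113.0)
  m2 <- .new_method("SIM 2", list(
    .new_window(minutes[1], minutes[2], "min", frag,
                list(C27 = .grid_row(27), C30 = .grid_row(30))),
    .new_window(minutes[2], minutes[3], "min", frag_mid,
                list(C30 = .grid_row(30), C31 = .grid_row(31, dbs = 2:0))),
    .new_window(minutes[3], minutes[4], "min", frag,
                list(C30 = .grid_row(30), C31 = .grid_row(31)))), budget)
  list(m1, m2)
}

# carbon-group elution spans (RI) of the analytes of a library; pentacyclic
# triterpenols form their own group contributing the 189/218 fragment pair
.group_spans <- function(lib) {
  e <- library_analytes(lib)
  groups <- list()
  for (cn in sort(unique(e$cn))) {
    sub <- e[e$cn == cn, ]
    groups[[paste0("C", cn)]] <- list(
      cn = cn, min_ri = min(sub$ri_fap), max_ri = max(sub$ri_fap),
      dbs_present = sort(unique(sub$db)), pentacyclic = FALSE)
  }
  pent <- e[e$class == "pentacyclic", ]
  if (nrow(pent)) {
    groups[["Amyrins"]] <- list(
      cn = NA_integer_, min_ri = min(pent$ri_fap), max_ri = max(pent$ri_fap),
      dbs_present = integer(), pentacyclic = TRUE)
  }
  groups
}

#' Build the merged time-window SIM method
#'
#' Merges the two initial methods into one acquisition by partitioning the
#' retention-index range into windows snapped to multiples of `snap`,
#' covering the elution span of every carbon group. Each window carries the
#' retention-independent fragment ions plus the molecular-ion grids of the
#' carbon groups whose span (extended by `margin` index units) intersects
#' it. Where the ion budget binds, ions are released in documented order:
#' first the FAP ion 126.0 (113.0 alone anchors the ladder and is never
#' dropped), then the grids of groups that only partially overlap the
#' window are restricted to the (cn, db) combinations detected anywhere in
#' the library - starting with the group with fewest compounds in the
#' window - then, if necessary, to the combinations present in the window
#' itself. This is the substitution that places a lone heavy molecular ion
#' (e.g. m/z 512.5) into a window in place of grid ions of undetected
#' compositions (e.g. m/z 496.4).
#'
#' @param library a `reference_library`.
#' @param budget maximum simultaneous ions per window (default 17).
#' @param snap window-boundary snap, RI units (default 100).
#' @param margin boundary safety margin, RI units (default 2): a compound
#'   this close to a boundary is also covered by the neighbouring window.
#' @return a `sim_method` with RI-bounded windows.
#' @export
build_time_windows <- function(library = builtin_library(), budget = 17,
                               snap = 100, margin = 2) {
  e <- library_analytes(library)
  if (nrow(e) == 0) stop("empty library", call. = FALSE)
  groups <- .group_spans(library)
  lo <- floor(min(e$ri_fap) / snap) * snap
  hi <- ceiling(max(e$ri_fap) / snap) * snap
  if (hi <= lo) hi <- lo + snap
  starts <- seq(lo, hi - snap, by = snap)
  frag_all <- retention_independent_ions()
  windows <- lapply(starts, function(s) {
    w_lo <- s; w_hi <- s + snap
    in_win <- function(g) g$min_ri - margin < w_hi && g$max_ri + margin >= w_lo
    act <- Filter(in_win, groups)
    if (!length(act)) return(NULL)
    dep <- list()
    indep <- frag_all
    for (nm in names(act)) {
      g <- act[[nm]]
      if (g$pentacyclic) {
        dep[[nm]] <- unname(retention_independent_ions(
          include_fap = FALSE, include_pentacyclic = TRUE)[c("penta189",
                                                             "penta218")])
      } else {
        dep[[nm]] <- .grid_row(g$cn)
      }
    }
    count <- function() length(unique(c(unname(indep),
                                        unlist(dep, use.names = FALSE))))
    if (count() > budget) {
      indep <- indep[names(indep) != "fap2"] # release 126.0 first
      # groups only partially inside the window, fewest in-window compounds
      # first; restrict their grid to (cn,db) detected anywhere
      partial <- names(act)[vapply(names(act), function(nm) {
        g <- act[[nm]]
        !g$pentacyclic && (g$min_ri < w_lo || g$max_ri >= w_hi)
      }, logical(1))]
      n_in <- vapply(partial, function(nm) {
        g <- act[[nm]]
        sum(e$cn == g$cn & e$ri_fap >= w_lo & e$ri_fap < w_hi)
      }, numeric(1))
      for (nm in partial[order(n_in)]) {
        if (count() <= budget) break
        dep[[nm]] <- .grid_row(act[[nm]]$cn,
                               dbs = act[[nm]]$dbs_present)
      }
      for (nm in partial[order(n_in)]) {
        if (count() <= budget) break
        g <- act[[nm]]
        dbs_here <- sort(unique(e$db[e$cn == g$cn & e$ri_fap + margin >= w_lo &
                                       e$ri_fap - margin < w_hi]))
        dep[[nm]] <- .grid_row(g$cn, dbs = dbs_here)
      }
      if (count() > budget) {
        stop(sprintf(
          "ion budget %d infeasible in window %g-%g even after substitution (%d ions)",
          budget, w_lo, w_hi, count()), call. = FALSE)
      }
    }
    .new_window(w_lo, w_hi, "RI", indep, dep)
  })
  windows <- Filter(Negate(is.null), windows)
  m <- .new_method("merged time-window method", windows, budget)
  attr(m, "note") <- paste(
    "window fragment lists are inherited across windows unless the budget",
    "forces a release; inheritance for sparsely printed windows is an",
    "explicit builder choice")
  m
}

#' Validate a SIM schedule against a library
#'
#' Per compound: is its molecular ion monitored in the window containing its
#' retention index, and is the [M-15]+/[M-14]+ isotope check observable
#' there (i.e. is an ion at M+ - 14 monitored)? Per window: ion count
#' against the budget.
#'
#' @param method a `sim_method` with RI windows.
#' @param library a `reference_library`.
#' @return list with `compounds` (data.frame: name, ri, mplus, window,
#'   mplus_monitored, isotope_observable) and `windows` (data.frame: index,
#'   start, end, n_ions, within_budget), plus `all_covered` flag.
#' @export
validate_schedule <- function(method, library = builtin_library()) {
  e <- library_analytes(library)
  win_of <- function(ri) {
    for (i in seq_along(method$windows)) {
      w <- method$windows[[i]]
      if (ri >= w$start && ri < w$end) return(i)
    }
    if (length(method$windows) &&
        ri == method$windows[[length(method$windows)]]$end) {
      return(length(method$windows))
    }
    NA_integer_
  }
  comp <- do.call(rbind, lapply(seq_len(nrow(e)), function(k) {
    en <- e[k, ]
    mplus <- library$ion_sets[[en$name]]$molecular_ion
    wi <- win_of(en$ri_fap)
    ions <- if (is.na(wi)) numeric() else .window_ions(method$windows[[wi]])
    data.frame(name = en$name, ri = en$ri_fap, mplus = mplus, window = wi,
               mplus_monitored = any(abs(ions - mplus) <= 0.3),
               isotope_observable = any(abs(ions - (mplus - 14)) <= 0.3))
  }))
  wins <- do.call(rbind, lapply(seq_along(method$windows), function(i) {
    w <- method$windows[[i]]
    n <- length(.window_ions(w))
    data.frame(index = i, start = w$start, end = w$end, n_ions = n,
               within_budget = n <= method$budget)
  }))
  list(compounds = comp, windows = wins,
       all_covered = all(comp$mplus_monitored))
}

#' Export a SIM schedule as TSV
#'
#' Long format: window, start, end, ion, group (`indep` for
#' retention-independent ions). With `anchors`, RI boundaries are also
#' projected to minutes via [invert_ri_fap()].
#'
#' @param method a `sim_method`.
#' @param path output path.
#' @param anchors optional [fap_anchor_set()] for minute projection.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(method, path, anchors = NULL) {
  rows <- do.call(rbind, lapply(seq_along(method$windows), function(i) {
    w <- method$windows[[i]]
    grp <- c(list(indep = w$retention_independent_ions),
             w$retention_dependent_ions)
    do.call(rbind, lapply(names(grp), function(nm) {
      if (!length(grp[[nm]])) return(NULL)
      data.frame(window = i, start = w$start, end = w$end, unit = w$unit,
                 start_min = if (!is.null(anchors) && w$unit == "RI")
                   invert_ri_fap(w$start, anchors) else NA_real_,
                 end_min = if (!is.null(anchors) && w$unit == "RI")
                   invert_ri_fap(w$end, anchors) else NA_real_,
                 ion = grp[[nm]], group = nm)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
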