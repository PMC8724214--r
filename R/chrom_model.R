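# Data model and I/O for GC/MS runs represented as peak tables with per-ion
# apex intensities; FAP anchor extraction and anchor QC.

.mz_tol <- 0.3 # unit-resolution quadrupole: 1-decimal m/z matched +-0.3 u

#' Construct a chromatogram from peak and ion tables
#'
#' A chromatogram is a set of detected peaks, each with an apex retention
#' time (minutes), a total area, a height and per-ion apex intensities.
#' Peaks are sorted by apex time; ties are broken by descending area, then
#' ascending lowest m/z, so ordering is total and deterministic.
#'
#' @param run_id run identifier.
#' @param peaks data.frame with columns `peak_id, apex_rt, area, height`
#'   (optional `asymmetry`).
#' @param ions data.frame with columns `peak_id, mz, intensity`.
#' @param mode `"full_scan"` or `"sim"`.
#' @param monitored_ions numeric m/z set (required for sim mode).
#' @return object of class `chromatogram`.
#' @export
chromatogram <- function(run_id, peaks, ions, mode = c("full_scan", "sim"),
                         monitored_ions = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("peak_id", "apex_rt", "area", "height") %in% names(peaks)),
            all(c("peak_id", "mz", "intensity") %in% names(ions)))
  if (any(peaks$apex_rt <= 0)) stop("apex_rt must be > 0", call. = FALSE)
  if (any(peaks$area < 0)) stop("areas must be >= 0", call. = FALSE)
  if (any(ions$intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (!all(peaks$peak_id %in% ions$peak_id)) {
    stop("every peak needs at least one ion intensity", call. = FALSE)
  }
  if (!"asymmetry" %in% names(peaks)) peaks$asymmetry <- NA_real_
  ions$mz <- round_half_up(ions$mz, 1)
  if (mode == "sim") {
    if (is.null(monitored_ions)) {
      stop("sim mode requires monitored_ions", call. = FALSE)
    }
    stray <- !vapply(ions$mz, function(m) {
      any(abs(m - monitored_ions) <= .mz_tol)
    }, logical(1))
    if (any(stray)) {
      stop("sim-mode chromatogram contains unmonitored ions: ",
           paste(unique(ions$mz[stray]), collapse = ", "), call. = FALSE)
    }
  }
  # deterministic total order: rt, then area desc, then lowest m/z asc
  lowmz <- vapply(peaks$peak_id, function(id) {
    min(ions$mz[ions$peak_id == id])
  }, numeric(1))
  o <- order(peaks$apex_rt, -peaks$area, lowmz)
  peaks <- peaks[o, , drop = FALSE]
  rownames(peaks) <- NULL
  ions <- ions[order(match(ions$peak_id, peaks$peak_id), ions$mz), ,
               drop = FALSE]
  rownames(ions) <- NULL
  structure(list(run_id = run_id, peaks = peaks, ions = ions, mode = mode,
                 monitored_ions = monitored_ions),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> run '%s': %d peaks (%s mode), rt %.2f-%.2f min\n",
              x$run_id, nrow(x$peaks), x$mode,
              min(x$peaks$apex_rt), max(x$peaks$apex_rt)))
  invisible(x)
}

#' Ion intensities of one peak
#'
#' @param chrom a `chromatogram`.
#' @param peak_id peak identifier.
#' @return named numeric vector (names = m/z at 1 decimal).
#' @export
peak_ions <- function(chrom, peak_id) {
  sub <- chrom$ions[chrom$ions$peak_id == peak_id, , drop = FALSE]
  stats::setNames(sub$intensity, sprintf("%.1f", sub$mz))
}

.ion_at <- function(ints, mz, tol = .mz_tol) {
  mzv <- as.numeric(names(ints))
  hit <- abs(mzv - mz) <= tol
  if (!any(hit)) 0 else sum(ints[hit])
}

#' Read a peak table
#'
#' The documented flat schema is one row per (peak, ion): columns
#' `run_id, rt_min, mz, intensity, area, peak_id` (optional `asymmetry`,
#' `height`); rows sharing `peak_id` form one peak, `area` is the per-ion
#' area and peak area is their sum. Unparseable rows (non-numeric rt/mz/
#' intensity) are dropped with a warning.
#'
#' @param path file path.
#' @param dialect list with `sep` (default tab) and `dec`.
#' @return a [chromatogram()].
#' @export
read_peak_table <- function(path, dialect = list(sep = "\t", dec = ".")) {
  if (!file.exists(path)) stop("peak table not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = dialect$sep %||% "\t",
                           dec = dialect$dec %||% ".", header = TRUE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty peak table: ", path, call. = FALSE)
  need <- c("run_id", "rt_min", "mz", "intensity", "area", "peak_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("peak table missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("rt_min", "mz", "intensity", "area")) {
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  bad <- !stats::complete.cases(tab[c("rt_min", "mz", "intensity", "area")])
  if (any(bad)) {
    warning(sum(bad), " unparseable row(s) dropped from ", path)
    tab <- tab[!bad, , drop = FALSE]
  }
  if (nrow(tab) == 0) stop("no parseable rows in ", path, call. = FALSE)
  sp <- split(tab, tab$peak_id)
  peaks <- do.call(rbind, lapply(sp, function(g) {
    data.frame(peak_id = g$peak_id[1],
               apex_rt = g$rt_min[which.max(g$intensity)],
               area = sum(g$area),
               height = if ("height" %in% names(g)) max(g$height) else
                 sum(g$intensity),
               asymmetry = if ("asymmetry" %in% names(g)) g$asymmetry[1] else
                 NA_real_,
               stringsAsFactors = FALSE)
  }))
  ions <- tab[c("peak_id", "mz", "intensity")]
  chromatogram(run_id = tab$run_id[1], peaks = peaks, ions = ions)
}

#' Write a chromatogram as a flat peak table
#'
#' Inverse of [read_peak_table()]: one row per (peak, ion); per-ion areas are
#' the peak area split proportionally to ion intensity so that a read/write
#' round trip is row-equivalent.
#'
#' @param chrom a `chromatogram`.
#' @param path output path.
#' @param dialect list with `sep`.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(chrom, path, dialect = list(sep = "\t")) {
  stopifnot(inherits(chrom, "chromatogram"))
  rows <- do.call(rbind, lapply(seq_len(nrow(chrom$peaks)), function(i) {
    p <- chrom$peaks[i, ]
    ions <- chrom$ions[chrom$ions$peak_id == p$peak_id, , drop = FALSE]
    share <- ions$intensity / sum(ions$intensity)
    data.frame(run_id = chrom$run_id, rt_min = p$apex_rt, mz = ions$mz,
               intensity = ions$intensity, area = p$area * share,
               peak_id = p$peak_id, asymmetry = p$asymmetry, height = p$height,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = dialect$sep %||% "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' FAP anchor set
#'
#' Retention-time ladder of the fatty acid pyrrolidide internal standards:
#' one apex time per carbon number, strictly increasing.
#'
#' @param rt named numeric vector, names = carbon numbers (18-26).
#' @param locked logical: acquired under retention time locking?
#' @return object of class `fap_anchor_set`.
#' @export
fap_anchor_set <- function(rt, locked = FALSE) {
  carbons <- as.integer(names(rt))
  if (anyNA(carbons)) stop("anchor names must be carbon numbers",
                           call. = FALSE)
  o <- order(carbons)
  rt <- rt[o]; carbons <- carbons[o]
  if (length(rt) < 2) stop("need at least two anchors", call. = FALSE)
  if (any(diff(rt) <= 0)) {
    stop("anchor retention times must increase strictly with carbon number",
         call. = FALSE)
  }
  structure(as.numeric(rt), names = carbons, locked = locked,
            class = "fap_anchor_set")
}

#' @export
print.fap_anchor_set <- function(x, ...) {
  cat(sprintf("<fap_anchor_set> %d anchors (C%s-C%s)%s\n", length(x),
              names(x)[1], names(x)[length(x)],
              if (isTRUE(attr(x, "locked"))) ", locked" else ""))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Extract FAP anchors from a chromatogram
#'
#' FAP spectra are dominated by m/z 113 and m/z 126 irrespective of chain
#' length; a peak is FAP-flagged when m/z 113.0 is its most intense ion and
#' the two FAP ions together carry at least `fap_share` of its summed
#' intensity. Flagged peaks are assigned to the expected carbon numbers in
#' elution order.
#'
#' @param chrom a `chromatogram`.
#' @param expected_carbons integer carbon numbers expected in the ladder
#'   (default 18:25, the final FAP mix; 26:0 produces a small peak and is
#'   kept out of the routine mix).
#' @param fap_share minimum joint share of m/z 113+126 (default 0.8).
#' @param locked mark the resulting anchor set as locked.
#' @return a [fap_anchor_set()].
#' @export
extract_fap_anchors <- function(chrom, expected_carbons = 18:25,
                                fap_share = 0.8, locked = FALSE) {
  stopifnot(inherits(chrom, "chromatogram"))
  expected_carbons <- sort(as.integer(expected_carbons))
  flagged <- vapply(chrom$peaks$peak_id, function(id) {
    ints <- peak_ions(chrom, id)
    i113 <- .ion_at(ints, 113.0)
    i126 <- .ion_at(ints, 126.0)
    i113 > 0 && i113 >= max(ints) - 1e-12 &&
      (i113 + i126) >= fap_share * sum(ints)
  }, logical(1))
  hits <- chrom$peaks[flagged, , drop = FALSE]
  if (nrow(hits) < length(expected_carbons)) {
    missing_c <- expected_carbons[seq.int(nrow(hits) + 1,
                                          length(expected_carbons))]
    stop("missing FAP anchor(s): found ", nrow(hits), " FAP peaks for ",
         length(expected_carbons), " expected carbons; missing carbon(s) ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  if (nrow(hits) > length(expected_carbons)) {
    stop("found ", nrow(hits), " FAP-flagged peaks for ",
         length(expected_carbons), " expected carbons; ",
         "adjust expected_carbons or fap_share", call. = FALSE)
  }
  rt <- sort(hits$apex_rt)
  fap_anchor_set(stats::setNames(rt, expected_carbons), locked = locked)
}

#' Anchor quality-control report
#'
#' Per-anchor pass/fail on peak-shape (asymmetry factor at 10% height,
#' b/a convention) and minimum height; routine inspection of the FAP ladder
#' guards the retention-index scale.
#'
#' @param chrom a `chromatogram`.
#' @param anchors a [fap_anchor_set()] extracted from `chrom`.
#' @param tailing_limit maximum acceptable asymmetry factor (default 1.5).
#' @param min_height minimum acceptable apex height (default 0).
#' @return data.frame with one row per anchor (`carbon, rt, asymmetry,
#'   height, shape_ok, height_ok, pass`) and attribute `overall` (logical).
#' @export
anchor_quality_report <- function(chrom, anchors, tailing_limit = 1.5,
                                  min_height = 0) {
  if (length(anchors) == 0) {
    rep <- data.frame(carbon = integer(), rt = numeric(),
                      asymmetry = numeric(), height = numeric(),
                      shape_ok = logical(), height_ok = logical(),
                      pass = logical())
    attr(rep, "overall") <- TRUE
    return(rep)
  }
  rows <- lapply(seq_along(anchors), function(i) {
    rt <- as.numeric(anchors[i])
    j <- which.min(abs(chrom$peaks$apex_rt - rt))
    p <- chrom$peaks[j, ]
    asym <- if (is.na(p$asymmetry)) 1 else p$asymmetry
    data.frame(carbon = as.integer(names(anchors)[i]), rt = rt,
               asymmetry = asym, height = p$height,
               shape_ok = asym <= tailing_limit,
               height_ok = p$height >= min_height)
  })
  rep <- do.call(rbind, rows)
  rep$pass <- rep$shape_ok & rep$height_ok
  attr(rep, "overall") <- all(rep$pass)
  rep
}
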