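# Semi-quantitative composition: percentage contribution of each annotated
# compound to the summed sterol/triterpenol TIC of a run.

#' TIC percentage composition
#'
#' Per run, each annotated compound's percentage of the summed sterol TIC
#' area. Internal-standard and FAP peaks never enter the annotation table,
#' so the denominator is the sum over annotated sterols/triterpenols;
#' co-eluting compounds carry the areas apportioned during annotation, which
#' conserve the shared peak area. Equal response factors are assumed: the
#' values rank the relevance of the compounds in the SIM chromatogram and
#' are not a quantitative composition.
#'
#' @param annotations an `annotation_table` (possibly several runs
#'   row-bound).
#' @param chrom optional chromatogram (unused for peak-table annotations;
#'   accepted for interface symmetry).
#' @return object of class `composition_table`: data.frame `compound` x one
#'   column per run (percent, full precision), attribute `totals`.
#' @export
tic_percentages <- function(annotations, chrom = NULL) {
  a <- as.data.frame(annotations)
  a <- a[!is.na(a$compound) & a$area > 0, , drop = FALSE]
  if (nrow(a) == 0) {
    stop("undefined composition: no annotated compounds with positive area",
         call. = FALSE)
  }
  runs <- unique(a$run_id)
  compounds <- unique(a$compound)
  out <- data.frame(compound = compounds, stringsAsFactors = FALSE)
  totals <- stats::setNames(numeric(length(runs)), runs)
  for (r in runs) {
    sub <- a[a$run_id == r, ]
    tot <- sum(sub$area)
    if (tot <= 0) {
      stop("undefined composition: zero total sterol area in run ", r,
           call. = FALSE)
    }
    totals[[r]] <- tot
    pct <- 100 * vapply(compounds, function(nm) {
      sum(sub$area[sub$compound == nm])
    }, numeric(1)) / tot
    out[[r]] <- pct
  }
  structure(out, totals = totals,
            class = c("composition_table", class(out)))
}

#' Flag trace entries of a composition table
#'
#' Formats a composition table for display: values below `floor` percent are
#' reported as `"tr"`, zeros (compound absent from the run) as empty
#' strings; remaining values follow the table granularity (one decimal at
#' or above 1%, one to two significant digits below). Stored values keep
#' full precision; this function only affects the printed representation.
#'
#' @param table a [tic_percentages()] result.
#' @param floor trace threshold, percent (default 0.02, the smallest
#'   printed composition value).
#' @return data.frame of character columns with `"tr"` marks.
#' @export
trace_flagging <- function(table, floor = 0.02) {
  stopifnot(floor >= 0)
  out <- data.frame(compound = table$compound, stringsAsFactors = FALSE)
  for (r in setdiff(names(table), "compound")) {
    v <- table[[r]]
    out[[r]] <- vapply(v, function(x) {
      if (is.na(x) || x == 0) ""
      else if (x < floor) "tr"
      else if (x >= 1) sprintf("%.1f", x)
      else format(signif(x, if (x >= 0.095) 2 else 1), scientific = FALSE)
    }, character(1))
  }
  out
}

#' @export
print.composition_table <- function(x, ...) {
  cat("<composition_table>\n")
  print(trace_flagging(x), row.names = FALSE)
  invisible(x)
}

#' Write a composition table
#'
#' Wide TSV (compounds x runs), display-formatted with trace flags.
#'
#' @param table a `composition_table`.
#' @param path output path.
#' @param floor trace threshold for display.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(table, path, floor = 0.02) {
  utils::write.table(trace_flagging(table, floor), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
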