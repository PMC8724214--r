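# Reference library of sterols/triterpenols: descriptors, retention indices,
# assignment metadata and computed ion sets.

.lib_entry <- function(name, cn, db, positions, rings, class, rrt, ri,
                       mplus_print, base_print, level,
                       standard = FALSE, tentative = FALSE, role = "analyte",
                       note = "") {
  data.frame(name = name, cn = as.integer(cn), db = as.integer(db),
             positions = positions, rings = rings, class = class,
             rrt = rrt, ri_fap = ri, mplus_print = mplus_print,
             base_print = base_print, level = as.integer(level),
             standard = standard, tentative = tentative, role = role,
             note = note, stringsAsFactors = FALSE)
}

# The 30 detected sterols/triterpenols plus the 5alpha-cholestane internal
# standard. Delta-position strings: "24(24^1)" = methylene at C-24,
# "24(25)" = Delta24(25). Ring strings: "3r9,10" cyclopropane (cycloartane),
# "6r17,18"/"5r17,18" pentacyclic E-ring. Unknowns carry NA positions.
.builtin_entries <- function() {
  e <- rbind(
    .lib_entry("5a-Cholestane", 27, 0, "", "", "internal_standard",
               1.00, 1868, 372, 217, 1, standard = TRUE,
               role = "internal_standard"),
    .lib_entry("Cholesterol", 27, 1, "5", "", "desmethyl_sterol",
               1.29, 2129, 458, 129, 1, standard = TRUE),
    .lib_entry("Brassicasterol", 28, 2, "5;22", "", "desmethyl_sterol",
               1.34, 2169, 470, 129, 2),
    .lib_entry("24-Methylenecholesterol", 28, 2, "5;24(24^1)", "",
               "desmethyl_sterol", 1.39, 2217, 470, 129, 2),
    .lib_entry("Campesterol", 28, 1, "5", "", "desmethyl_sterol",
               1.40, 2225, 472, 129, 1, standard = TRUE),
    .lib_entry("Unknown 1", 29, 2, NA, "", "unknown", 1.41, 2230, 484, 129, 4),
    .lib_entry("Campestanol", 28, 0, "", "", "stanol", 1.41, 2235, 474, 215, 2),
    .lib_entry("D8-Campesterol", 28, 1, "8", "", "desmethyl_sterol",
               1.42, 2247, 472, 472, 3, tentative = TRUE,
               note = "most likely proposed structure"),
    .lib_entry("Stigmasterol", 29, 2, "5;22", "", "desmethyl_sterol",
               1.42, 2247, 484, 129, 1, standard = TRUE),
    .lib_entry("Unknown 3", 29, 1, NA, "", "unknown", 1.45, 2274, 486, 129, 4),
    .lib_entry("Unknown 4", 28, 2, NA, "", "unknown", 1.45, 2274, 470, 129, 4),
    .lib_entry("D7-Campesterol", 28, 1, "7", "", "desmethyl_sterol",
               1.45, 2284, 472, 255, 2),
    .lib_entry("Clerosterol", 29, 2, "5;25", "", "desmethyl_sterol",
               1.46, 2291, 484, 129, 2),
    .lib_entry("Lanosterol", 30, 2, "8;24", "", "4_4_dimethyl",
               1.48, 2306, 498, 129, 2),
    .lib_entry("b-Sitosterol", 29, 1, "5", "", "desmethyl_sterol",
               1.48, 2306, 486, 129, 1, standard = TRUE),
    .lib_entry("Sitostanol", 29, 0, "", "", "stanol", 1.49, 2319, 488, 215, 2),
    .lib_entry("D5-Avenasterol", 29, 2, "5;24(24^1)", "", "desmethyl_sterol",
               1.49, 2320, 484, 129, 2),
    .lib_entry("b-Amyrin", 30, 2, "12", "6r17,18", "pentacyclic",
               1.50, 2327, 498, 218, 2),
    .lib_entry("D8-Sitosterol", 29, 1, "8", "", "desmethyl_sterol",
               1.50, 2329, 486, 486, 3, tentative = TRUE,
               note = "most likely proposed structure"),
    .lib_entry("Butyrospermol", 30, 2, "7;24", "", "4_4_dimethyl",
               1.51, 2336, 498, 129, 3, tentative = TRUE),
    .lib_entry("Stigmasta-5,24(25)-dienol", 29, 2, "5;24(25)", "",
               "desmethyl_sterol", 1.51, 2342, 484, 129, 2),
    .lib_entry("Unknown 7", 31, 2, NA, "", "unknown", 1.53, 2354, 512, 129, 4),
    .lib_entry("Gramisterol", 29, 2, "7;24(24^1)", "", "4_methyl",
               1.53, 2354, 484, 129, 2),
    .lib_entry("D7-Sitosterol", 29, 1, "7", "", "desmethyl_sterol",
               1.54, 2364, 486, 255, 2),
    .lib_entry("a-Amyrin", 30, 2, "12", "6r17,18", "pentacyclic",
               1.54, 2365, 498, 218, 2),
    .lib_entry("Cycloartenol", 30, 2, "24", "3r9,10", "4_4_dimethyl",
               1.54, 2371, 498, 129, 2),
    .lib_entry("Lupeol", 30, 2, "20", "5r17,18", "pentacyclic",
               1.54, 2371, 498, 189, 2),
    .lib_entry("D7-Avenasterol", 29, 2, "7;24(24^1)", "", "desmethyl_sterol",
               1.55, 2378, 484, 253, 2),
    .lib_entry("24-Methylenecycloartanol", 31, 2, "24(24^1)", "3r9,10",
               "4_4_dimethyl", 1.60, 2423, 512, 129, 2),
    .lib_entry("Unknown 8", 30, 1, NA, "", "unknown", 1.63, 2442, 500, 500, 4),
    .lib_entry("Citrostadienol", 30, 2, "7;24", "", "4_methyl",
               1.64, 2457, 498, 129, 2)
  )
  rownames(e) <- NULL
  e
}

.descriptor_from_row <- function(r) {
  pos_chr <- as.character(r$positions)
  rng_chr <- as.character(r$rings)
  pos <- if (is.na(pos_chr) || pos_chr == "") character() else
    strsplit(pos_chr, ";", fixed = TRUE)[[1]]
  rng <- if (is.na(rng_chr) || rng_chr == "") character() else
    strsplit(rng_chr, ";", fixed = TRUE)[[1]]
  sterol_descriptor(r$name, r$cn, r$db, pos, rng, r$class)
}

# base-peak overrides where the printed base peak differs from the rule
# table (e.g. Delta7-avenasterol base at 253 rather than 255); keyed by name
.base_overrides <- c("D7-Avenasterol" = 253.2,
                     "Unknown 1" = 129.1, "Unknown 3" = 129.1,
                     "Unknown 4" = 129.1, "Unknown 7" = 129.1)

.ion_set_for_row <- function(r, mplus_override = NULL) {
  d <- .descriptor_from_row(r)
  is <- diagnostic_fragments(d, mplus_override = mplus_override)
  bo <- .base_overrides[r$name]
  if (!is.na(bo)) is$expected_base_peak <- unname(bo)
  is
}

.make_library <- function(entries, source = "builtin") {
  ov <- if ("mplus_override" %in% names(entries)) entries$mplus_override else
    rep(NA_real_, nrow(entries))
  ion_sets <- lapply(seq_len(nrow(entries)), function(i) {
    .ion_set_for_row(entries[i, , drop = FALSE], mplus_override = ov[i])
  })
  names(ion_sets) <- entries$name
  structure(list(entries = entries, ion_sets = ion_sets, source = source),
            class = "reference_library")
}

#' Built-in sterol/triterpenol reference library
#'
#' The 30 sterols and triterpene alcohols characterized in the four
#' reference vegetable oils (rapeseed, hemp, corn, sunflower), plus the
#' 5alpha-cholestane internal standard. Each entry carries the relative
#' retention time (RRT, vs 5alpha-cholestane), FAP retention index, carbon
#' number, double-bond count and Delta positions, compound class, printed
#' molecular ion and base peak, assignment level (1 standard available,
#' 2 major sterol verified by GC/MS data, 3 tentative, 4 unknown) and a
#' computed ion set. Delta-position labels for the two compounds printed
#' with ambiguous "5. 22"-style separators are carried in corrected
#' "5;22" form.
#'
#' @return object of class `reference_library`.
#' @export
#' @examples
#' lib <- builtin_library()
#' nrow(lib$entries) # 31 = 30 analytes + internal standard
builtin_library <- function() {
  .make_library(.builtin_entries())
}

#' Analyte rows of a reference library
#'
#' @param lib a `reference_library`.
#' @return entries data.frame without internal-standard rows.
#' @export
library_analytes <- function(lib) {
  stopifnot(inherits(lib, "reference_library"))
  lib$entries[lib$entries$role == "analyte", , drop = FALSE]
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("<reference_library> %d entries (%d analytes), source: %s\n",
              nrow(x$entries), nrow(library_analytes(x)), x$source))
  invisible(x)
}

#' Read a compound library from a TSV file
#'
#' Expected columns: `name, cn, db, positions, rings, class, ri_fap, level,
#' mplus_override`; optional `rrt, standard, tentative, role, base_print,
#' mplus_print, note`. Positions and rings are `;`-separated Delta/ring
#' labels. For entries without ring annotations the printed molecular ion
#' (when given) is checked against [tms_molecular_mz()]; a mismatch beyond
#' 0.5 u is a consistency error.
#'
#' @param path TSV file path.
#' @return a `reference_library`.
#' @export
build_compound_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    warning("empty library file: ", path)
    return(.make_library(.builtin_entries()[0, , drop = FALSE],
                         source = path))
  }
  need <- c("name", "cn", "db", "positions", "rings", "class", "ri_fap",
            "level")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("library file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"mplus_override" %in% names(tab)) tab$mplus_override <- NA_real_
  if (!"rrt" %in% names(tab)) tab$rrt <- NA_real_
  if (!"standard" %in% names(tab)) tab$standard <- tab$level == 1
  if (!"tentative" %in% names(tab)) tab$tentative <- tab$level == 3
  if (!"role" %in% names(tab)) tab$role <- "analyte"
  if (!"mplus_print" %in% names(tab)) tab$mplus_print <- NA_real_
  if (!"base_print" %in% names(tab)) tab$base_print <- NA_real_
  if (!"note" %in% names(tab)) tab$note <- ""
  # consistency: printed M+ vs computed TMS mass (non-ring-annotated rows)
  plain <- (is.na(tab$rings) | tab$rings == "") & !is.na(tab$mplus_print) &
    tab$class %in% c("desmethyl_sterol", "4_methyl", "stanol", "unknown")
  if (any(plain)) {
    calc <- tms_molecular_mz(tab$cn[plain], tab$db[plain])
    bad <- abs(calc - tab$mplus_print[plain]) > 0.5
    if (any(bad)) {
      stop("library M+ inconsistent with TMS mass for: ",
           paste(tab$name[plain][bad], collapse = ", "), call. = FALSE)
    }
  }
  .make_library(tab, source = path)
}

#' Write a compound library to TSV
#'
#' @param lib a `reference_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_compound_library <- function(lib, path) {
  stopifnot(inherits(lib, "reference_library"))
  utils::write.table(lib$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
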