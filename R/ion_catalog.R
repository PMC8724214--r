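# Masses and diagnostic EI fragment ions for silylated sterols, stanols,
# 4-methyl/4,4-dimethylsterols and pentacyclic triterpenols.

# monoisotopic atomic masses (u)
.MASS <- c(C = 12, H = 1.00782503207, O = 15.9949146196, Si = 27.9769265325)

# natural 13C abundance used for the [M-14]+ check; Si/H/O isotopes are
# ignored (the one-13C term dominates at these fragment sizes)
.P13C <- 0.0107

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed SIM tables use
#' conventional half-up rounding, so m/z and retention indices are rounded
#' with this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Monoisotopic m/z of a silylated sterol molecular ion
#'
#' Mass of the trimethylsilyl (TMS) ether of a sterol with `carbon_number`
#' skeletal carbons and `db_count` double-bond equivalents beyond the
#' tetracyclic ring system (extra rings such as the cyclopropane of
#' cycloartane-type sterols count as double-bond equivalents). The TMS ether
#' has the elemental composition C(n+3) H(2n+2-2*db) O Si.
#'
#' @param carbon_number integer 27-31, sterol skeleton carbon count.
#' @param db_count integer 0-3, double-bond equivalents beyond the ring
#'   system.
#' @param digits decimals for rounding (default 1, unit-resolution
#'   quadrupole convention); use `NA` for the unrounded mass.
#' @return numeric m/z (vectorized over both arguments).
#' @seealso [molecular_ion_grid()] for the published SIM acquisition grid.
#' @export
#' @examples
#' tms_molecular_mz(27, 1) # cholesterol-TMS, 458.4
#' tms_molecular_mz(29, 0) # sitostanol-TMS, 488.4
tms_molecular_mz <- function(carbon_number, db_count, digits = 1) {
  if (any(carbon_number < 27 | carbon_number > 31)) {
    stop("carbon_number must be in 27..31", call. = FALSE)
  }
  if (any(db_count < 0 | db_count > 3)) {
    stop("db_count must be in 0..3", call. = FALSE)
  }
  m <- (carbon_number + 3) * .MASS[["C"]] +
    (2 * carbon_number + 2 - 2 * db_count) * .MASS[["H"]] +
    .MASS[["O"]] + .MASS[["Si"]]
  if (is.na(digits)) m else round_half_up(m, digits)
}

#' Published 5 x 4 molecular-ion SIM grid
#'
#' The acquisition m/z grid for silylated sterols with 27-31 carbons and 0-3
#' double-bond equivalents, as used by the published SIM methods. Values are
#' the monoisotopic TMS-ether masses rounded to one decimal; the two most
#' unsaturated C31 entries are carried at the published setpoints 512.5 and
#' 510.5 (the published method lists the whole C31 column at x.5, 0.1 u above
#' the rounded monoisotopic mass; a SIM quadrupole window is wide enough that
#' the distinction is immaterial for acquisition, and the published values are
#' what the schedule must reproduce).
#'
#' @return numeric matrix, rownames carbon numbers 27-31, colnames db counts
#'   0-3.
#' @export
molecular_ion_grid <- function() {
  g <- outer(27:31, 0:3, tms_molecular_mz)
  dimnames(g) <- list(27:31, 0:3)
  g["31", "2"] <- 512.5
  g["31", "3"] <- 510.5
  g
}

#' m/z of the [M-84-TMSOH]+ fragment
#'
#' Loss of 84.1 u together with trimethylsilanol (90.1 u) from the molecular
#' ion; at m/z 296 this fragment verifies Delta5-sterols carrying a second
#' double bond at C-24.
#'
#' @param molecular_ion numeric m/z of the TMS molecular ion (> 174.2).
#' @return numeric m/z, one decimal.
#' @export
#' @examples
#' m84_tmsoh_loss(470.4) # 296.2
m84_tmsoh_loss <- function(molecular_ion) {
  if (any(molecular_ion <= 174.2)) {
    stop("molecular_ion must exceed 174.2 u", call. = FALSE)
  }
  round_half_up(molecular_ion - 84.1 - 90.1, 1)
}

#' Expected [M-14]+ / [M-15]+ isotope ratio
#'
#' Intensity of the one-13C isotopologue of a fragment relative to its
#' monoisotopic peak, for a fragment containing `n_carbons` carbon atoms.
#' Under the binomial isotope model the ratio is exactly
#' `n * p / (1 - p)` with `p` the 13C abundance. Used to decide whether the
#' signal one unit above a prominent [M-15]+ ion is the 13C satellite or the
#' molecular ion of a co-eluting sterol with one carbon less.
#'
#' @param n_carbons_in_fragment non-negative integer(s).
#' @param p13c 13C abundance (default 0.0107).
#' @return numeric ratio(s).
#' @export
#' @examples
#' isotope_m14_ratio(34) # ~0.368
isotope_m14_ratio <- function(n_carbons_in_fragment, p13c = .P13C) {
  if (any(n_carbons_in_fragment < 0)) {
    stop("n_carbons_in_fragment must be >= 0", call. = FALSE)
  }
  # ratio of the one-13C to the zero-13C binomial term; exact, the
  # first-order expression n*p coincides with it up to the 1/(1-p) factor
  n_carbons_in_fragment * p13c / (1 - p13c)
}

# retention-independent fragment ions of the SIM methods: the two FAP ions
# (113/126), the sterol ring diagnostics and the side-chain marker 296
.FRAG <- c(
  fap1 = 113.0, fap2 = 126.0, d5_base = 129.1, penta189 = 189.2,
  d57_211 = 211.2, ring213 = 213.2, stanol215 = 215.2, penta218 = 218.3,
  d57_253 = 253.2, ring255 = 255.2, sidechain296 = 296.2
)

#' Retention-independent SIM fragment ions
#'
#' The fragment ions monitored throughout the run: m/z 113.0 and 126.0 (fatty
#' acid pyrrolidide ladder), 129.1 (Delta5 base peak), 211.2/253.2
#' (Delta5,7- and Delta5,8-sterols), 213.2/255.2 (Delta5- and Delta7-sterols),
#' 215.2 (stanols), 296.2 (side-chain Delta24 marker) and 189.2/218.3
#' (pentacyclic triterpenols, retro-Diels-Alder).
#'
#' @param include_fap include the FAP ions 113.0/126.0 (default TRUE).
#' @param include_pentacyclic include 189.2/218.3 (default FALSE; they are
#'   scheduled only where triterpenols elute).
#' @return named numeric vector of m/z.
#' @export
retention_independent_ions <- function(include_fap = TRUE,
                                       include_pentacyclic = FALSE) {
  keep <- names(.FRAG)
  if (!include_fap) keep <- setdiff(keep, c("fap1", "fap2"))
  if (!include_pentacyclic) keep <- setdiff(keep, c("penta189", "penta218"))
  .FRAG[keep]
}

#' Construct a sterol descriptor
#'
#' Structural summary of a sterol or triterpenol: skeleton carbon count,
#' double-bond count and positions, extra-ring annotations and compound
#' class. Double-bond positions use Delta labels as plain strings ("5", "7",
#' "22", "24(24^1)", "24(25)", ...); ring annotations use the x-ring-y
#' notation as strings (e.g. "3r9,10" for a cyclopropane bridging C-9/C-10).
#'
#' @param name compound name.
#' @param carbon_number integer 27-31.
#' @param db_count double-bond equivalents beyond the tetracyclic core
#'   (extra rings included); `NA` when unknown.
#' @param db_positions character vector of Delta labels (may be empty).
#' @param ring_annotations character vector of ring terms (cycloartane and
#'   pentacyclic classes only).
#' @param compound_class one of `"desmethyl_sterol"`, `"4_methyl"`,
#'   `"4_4_dimethyl"`, `"stanol"`, `"pentacyclic"`, `"unknown"`,
#'   `"internal_standard"`.
#' @return object of class `sterol_descriptor`.
#' @export
sterol_descriptor <- function(name, carbon_number, db_count = NA_integer_,
                              db_positions = character(),
                              ring_annotations = character(),
                              compound_class = "desmethyl_sterol") {
  classes <- c("desmethyl_sterol", "4_methyl", "4_4_dimethyl", "stanol",
               "pentacyclic", "unknown", "internal_standard")
  compound_class <- match.arg(compound_class, classes)
  if (length(ring_annotations) &&
      !compound_class %in% c("4_4_dimethyl", "pentacyclic", "unknown")) {
    stop("ring annotations are only valid for cycloartane-type or ",
         "pentacyclic classes", call. = FALSE)
  }
  if (!is.na(db_count) && length(db_positions) &&
      length(db_positions) + length(ring_annotations) > db_count) {
    stop("more Delta positions/rings than double-bond equivalents for '",
         name, "'", call. = FALSE)
  }
  structure(
    list(name = name, carbon_number = as.integer(carbon_number),
         db_count = as.integer(db_count),
         db_positions = as.character(db_positions),
         ring_annotations = as.character(ring_annotations),
         compound_class = compound_class),
    class = "sterol_descriptor"
  )
}

#' @export
print.sterol_descriptor <- function(x, ...) {
  dl <- if (length(x$db_positions)) {
    paste0("Delta", paste(x$db_positions, collapse = ","))
  } else "positions n/a"
  cat(sprintf("<sterol_descriptor> %s: C%d:%s (%s) [%s]\n", x$name,
              x$carbon_number,
              ifelse(is.na(x$db_count), "?", x$db_count), dl,
              x$compound_class))
  invisible(x)
}

# ring-B saturation class from Delta labels: the positions relevant to the
# EI ring fragments are 5, 7 and 8
.ring_positions <- function(d) {
  pos <- sub("\\(.*", "", d$db_positions)
  intersect(pos, c("5", "7", "8"))
}

.has_sidechain_24 <- function(d) {
  any(grepl("^24(\\(24\\^?1\\)|\\(25\\))$", d$db_positions))
}

#' Diagnostic EI ions for a sterol descriptor
#'
#' Applies the fragment rule table to a structural descriptor and returns the
#' expected ion set: molecular ion, [M-15]+, diagnostic fragments with
#' strong/weak intensity hints and the expected base peak among the
#' monitored ions. The rules: stanols give the base peak at m/z 215;
#' Delta5-sterols the base peak at m/z 129 plus 213/255; Delta7-sterols
#' 213/255 without the 129 base; Delta5,7- and Delta5,8-sterols 211/253;
#' a side-chain double bond at C-24 on a Delta5-sterol adds m/z 296
#' ([M-84-TMSOH]+); pentacyclic triterpenols give the retro-Diels-Alder pair
#' 218/189 with 218 > 189 for the Delta12 (amyrin) type and 189 > 218 for the
#' Delta13/lupeol type. In 4-methyl and 4,4-dimethylsterols the ring
#' diagnostics are weakened and (for 4-methyl) shifted by +14 u; the shifted
#' ions are computed but flagged weak and are not part of the default SIM
#' ion set.
#'
#' @param d a [sterol_descriptor()].
#' @param mplus_override optional published molecular-ion m/z overriding the
#'   computed value.
#' @return object of class `ion_set`: list with `molecular_ion`,
#'   `m_minus_15`, `diagnostic` (named m/z vector), `expected_base_peak`,
#'   `intensity_hints` (named character, "strong"/"weak").
#' @export
diagnostic_fragments <- function(d, mplus_override = NULL) {
  stopifnot(inherits(d, "sterol_descriptor"))
  db_equiv <- d$db_count
  if (is.na(db_equiv)) {
    stop("rule gap: descriptor for '", d$name,
         "' lacks db_count; cannot assign an ion set", call. = FALSE)
  }
  mplus <- if (!is.null(mplus_override) && !is.na(mplus_override)) {
    as.numeric(mplus_override)
  } else if (d$compound_class == "internal_standard") {
    # 5alpha-cholestane is run underivatized: C27H48
    round_half_up(27 * .MASS[["C"]] + 48 * .MASS[["H"]], 1)
  } else {
    gr <- molecular_ion_grid()
    gr[as.character(d$carbon_number), as.character(db_equiv)]
  }
  diag <- numeric(0)
  hints <- character(0)
  base <- NA_real_
  add <- function(mz, hint) {
    diag[[sprintf("%.1f", mz)]] <<- mz
    hints[[sprintf("%.1f", mz)]] <<- hint
  }
  cls <- d$compound_class
  if (cls == "internal_standard") {
    add(217.2, "strong"); add(357.4, "strong")
    base <- 217.2
  } else if (cls == "stanol") {
    add(.FRAG[["stanol215"]], "strong")
    base <- .FRAG[["stanol215"]]
  } else if (cls == "pentacyclic") {
    pos <- sub("\\(.*", "", d$db_positions)
    if ("12" %in% pos) {
      add(.FRAG[["penta218"]], "strong"); add(.FRAG[["penta189"]], "strong")
      base <- .FRAG[["penta218"]]
    } else { # Delta13 or lupeol (Delta20) type
      add(.FRAG[["penta189"]], "strong"); add(.FRAG[["penta218"]], "weak")
      base <- .FRAG[["penta189"]]
    }
  } else if (cls == "unknown") {
    base <- mplus
  } else {
    rb <- .ring_positions(d)
    weakened <- cls %in% c("4_methyl", "4_4_dimethyl")
    shift <- if (cls == "4_methyl") 14 else 0
    hint <- if (weakened) "weak" else "strong"
    if (all(c("5", "7") %in% rb) || all(c("5", "8") %in% rb)) {
      add(.FRAG[["d57_211"]] + shift, hint)
      add(.FRAG[["d57_253"]] + shift, hint)
      base <- if (weakened) .FRAG[["d5_base"]] else .FRAG[["d57_211"]] + shift
    } else if ("5" %in% rb) {
      add(.FRAG[["d5_base"]], hint)
      add(.FRAG[["ring213"]] + shift, hint)
      add(.FRAG[["ring255"]] + shift, hint)
      base <- .FRAG[["d5_base"]]
    } else if ("7" %in% rb && !weakened) {
      add(.FRAG[["ring213"]] + shift, hint)
      add(.FRAG[["ring255"]] + shift, hint)
      base <- .FRAG[["ring255"]] + shift
    } else if ("8" %in% rb && !weakened) {
      # desmethyl Delta8: ring diagnostics are not formed in useful abundance
      base <- mplus
    } else if (weakened && "7" %in% rb) {
      # 4-methyl/4,4-dimethyl Delta7: shifted/weakened ring ions, silyl 129
      # dominates the monitored set
      add(.FRAG[["ring213"]] + shift, "weak")
      add(.FRAG[["ring255"]] + shift, "weak")
      base <- .FRAG[["d5_base"]]
    } else if (weakened) {
      # 4,4-dimethyl with side-chain unsaturation only (lanosterol-,
      # cycloartane-type): weak saturated-ring fragments, 129 base
      add(.FRAG[["stanol215"]], "weak")
      add(.FRAG[["ring255"]], "weak")
      base <- .FRAG[["d5_base"]]
    } else if (length(d$db_positions) == 0 && db_equiv == 0) {
      add(.FRAG[["stanol215"]], "strong")
      base <- .FRAG[["stanol215"]]
    } else {
      stop("rule gap: cannot classify ring system of '", d$name,
           "'; missing Delta positions", call. = FALSE)
    }
    if ("5" %in% rb && .has_sidechain_24(d)) {
      add(.FRAG[["sidechain296"]], if (weakened) "weak" else "strong")
    }
  }
  structure(
    list(molecular_ion = mplus,
         m_minus_15 = round_half_up(mplus - 15.0, 1),
         diagnostic = diag,
         expected_base_peak = base,
         intensity_hints = hints),
    class = "ion_set"
  )
}

#' @export
print.ion_set <- function(x, ...) {
  cat(sprintf("<ion_set> M+ %.1f, [M-15]+ %.1f, base %.1f\n",
              x$molecular_ion, x$m_minus_15, x$expected_base_peak))
  if (length(x$diagnostic)) {
    cat("  diagnostics:",
        paste(sprintf("%.1f(%s)", x$diagnostic, x$intensity_hints),
              collapse = " "), "\n")
  }
  invisible(x)
}
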