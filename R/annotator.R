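# Rule-based peak identification: class inference from diagnostic ions,
# retention-index library matching, the [M-14]+ isotope interference check
# and 4-level assignment.

#' Annotation configuration
#'
#' Tunable thresholds of the rule engine. `ri_tol` defaults to 2.5 index
#' units (run-to-run fluctuations are generally < 1 unit and stay below
#' ~2.1 even for co-eluting peaks). `mplus_floor` and `diag_floor` are
#' relative to the peak's most intense monitored ion; the molecular-ion
#' floor is 0.5% so that minor sterols resolved underneath a dominant
#' co-eluting peak (e.g. lanosterol under beta-sitosterol, at a few percent
#' of its intensity) are not discarded. `major_share` (percent of summed
#' sterol TIC) separates "major" level-2 sterols from tentative trace
#' assignments; assignments down to ~0.1% shares are verifiable in SIM.
#' `isotope_tol` is the relative tolerance of the [M-14]+/[M-15]+ check.
#'
#' @param ri_tol retention-index matching tolerance, index units.
#' @param mplus_floor molecular-ion candidate floor, fraction of top ion.
#' @param diag_floor diagnostic-ion presence floor, fraction of top ion.
#' @param isotope_tol relative tolerance of the isotope-ratio check.
#' @param major_share minimum TIC share (percent) for level 2.
#' @param istd_mz molecular ion of the internal standard (5alpha-cholestane).
#' @param istd_ri expected retention index of the internal standard.
#' @param mz_tol m/z matching tolerance, u.
#' @return list of class `annotation_config`.
#' @export
annotation_config <- function(ri_tol = 2.5, mplus_floor = 0.005,
                              diag_floor = 0.005, isotope_tol = 0.30,
                              major_share = 0.1, istd_mz = 372.4,
                              istd_ri = 1868, mz_tol = 0.3) {
  stopifnot(ri_tol > 0, mplus_floor >= 0, diag_floor >= 0, isotope_tol > 0)
  structure(list(ri_tol = ri_tol, mplus_floor = mplus_floor,
                 diag_floor = diag_floor, isotope_tol = isotope_tol,
                 major_share = major_share, istd_mz = istd_mz,
                 istd_ri = istd_ri, mz_tol = mz_tol),
            class = "annotation_config")
}

# (cn, db) lookup for an observed m/z against the published grid
.grid_lookup <- function(mz, tol = 0.3) {
  g <- molecular_ion_grid()
  hit <- which(abs(g - mz) <= tol, arr.ind = TRUE)
  if (nrow(hit) == 0) return(NULL)
  list(cn = as.integer(rownames(g)[hit[1, 1]]),
       db = as.integer(colnames(g)[hit[1, 2]]),
       grid_mz = g[hit[1, 1], hit[1, 2]])
}

#' Isotope interference check for a molecular-ion candidate
#'
#' Compares the observed intensity one mass unit above the [M-15]+ ion
#' (nominally [M-14]+) with the binomial expectation for the one-13C
#' satellite of the methyl-loss fragment. Agreement means the signal is the
#' isotope satellite; a significant excess flags a genuine co-eluting sterol
#' with one carbon atom less, whose molecular ion is isobaric with [M-14]+.
#'
#' @param ints named ion-intensity vector (names = m/z).
#' @param mplus molecular-ion m/z of the candidate.
#' @param cn carbon number of the candidate (fragment carbons = cn + 2:
#'   the TMS ether has cn + 3 carbons, minus the lost methyl).
#' @param config an [annotation_config()].
#' @return list with `status` ("pass", "fail" or "inconclusive"),
#'   `observed` and `expected` ratios.
#' @export
isotope_interference_check <- function(ints, mplus, cn,
                                       config = annotation_config()) {
  i15 <- .ion_at(ints, mplus - 15.0, config$mz_tol)
  i14 <- .ion_at(ints, mplus - 14.0, config$mz_tol)
  expected <- isotope_m14_ratio(cn + 2L)
  if (i15 <= 0 || i14 <= 0) {
    return(list(status = "inconclusive", observed = NA_real_,
                expected = expected))
  }
  observed <- i14 / i15
  ok <- abs(observed - expected) <= config$isotope_tol * expected
  list(status = if (ok) "pass" else "fail", observed = observed,
       expected = expected)
}

#' Classify a peak from its ions
#'
#' Infers carbon number and double-bond count from molecular-ion grid
#' matches and a ring/side-chain class from the diagnostic-ion pattern.
#' Rule precedence for the ring system: base peak at m/z 215 - stanol;
#' m/z 211 + 253 - Delta5,7/Delta5,8; base peak at m/z 129 - Delta5;
#' m/z 213 + 255 without the 129 base - Delta7; m/z 296 adds a side-chain
#' Delta24 label. A pentacyclic hypothesis is raised independently whenever
#' the retro-Diels-Alder pair 189/218 is present (Delta12/amyrin type when
#' I(218) > I(189), Delta13/lupeol type otherwise), so one chromatographic
#' peak can carry both a tetracyclic and a pentacyclic hypothesis (e.g.
#' co-eluting cycloartenol and lupeol). Molecular-ion candidates whose
#' intensity is explained as the 13C satellite of a heavier candidate's
#' [M-15]+ ion are removed ([M-14]+ logic).
#'
#' @param chrom a [chromatogram()].
#' @param peak_id peak to classify.
#' @param config an [annotation_config()].
#' @return list of hypothesis lists (`mplus, cn, db, ring_class,
#'   sidechain24, pentacyclic, penta_type, evidence`), possibly empty;
#'   attribute `ambiguities` records conflicting rule firings.
#' @export
classify_peak <- function(chrom, peak_id, config = annotation_config()) {
  ints <- peak_ions(chrom, peak_id)
  top <- max(ints)
  tol <- config$mz_tol
  i_of <- function(mz) .ion_at(ints, mz, tol)
  base_mz <- as.numeric(names(ints)[which.max(ints)])

  # molecular-ion candidates from the published grid
  cand <- list()
  for (k in seq_along(ints)) {
    mz <- as.numeric(names(ints)[k])
    if (ints[k] < config$mplus_floor * top) next
    hit <- .grid_lookup(mz, tol)
    if (is.null(hit)) next
    key <- sprintf("%.1f", hit$grid_mz)
    if (is.null(cand[[key]]) || cand[[key]]$intensity < ints[k]) {
      cand[[key]] <- c(hit, list(intensity = unname(ints[k]), obs_mz = mz))
    }
  }
  # drop candidates explained as [M-15]+1 satellites of a heavier candidate
  if (length(cand) > 1) {
    mzs <- vapply(cand, function(x) x$grid_mz, numeric(1))
    keep <- rep(TRUE, length(cand))
    for (k in seq_along(cand)) {
      heavier <- which(abs(mzs - (mzs[k] + 14.0)) <= 0.2)
      if (!length(heavier)) next
      chk <- isotope_interference_check(ints, mzs[heavier[1]],
                                        cand[[heavier[1]]]$cn, config)
      if (identical(chk$status, "pass")) keep[k] <- FALSE
    }
    cand <- cand[keep]
  }
  if (!length(cand)) {
    return(structure(list(), ambiguities = character()))
  }

  # shared ring/side-chain context
  ambig <- character()
  has <- function(mz) i_of(mz) >= config$diag_floor * top
  ring <- if (abs(base_mz - 215.2) <= tol) {
    "stanol"
  } else if (has(211.2) && has(253.2)) {
    "d5_7"
  } else if (abs(base_mz - 129.1) <= tol) {
    "d5"
  } else if (has(213.2) && has(255.2)) {
    "d7"
  } else {
    "none"
  }
  if (ring == "stanol" && (has(213.2) || i_of(129.1) >= 0.5 * top)) {
    ambig <- c(ambig, "stanol base with unsaturated-ring fragments present")
  }
  sidechain24 <- has(296.2)
  penta <- has(189.2) || has(218.3)
  penta_type <- if (penta) {
    if (i_of(218.3) > i_of(189.2)) "d12" else "d13_or_lupeol"
  } else NA_character_

  hyp <- list()
  for (k in seq_along(cand)) {
    cc <- cand[[k]]
    ev <- c(sprintf("M+ %.1f (C%d:%d)", cc$grid_mz, cc$cn, cc$db),
            if (ring != "none") paste0("ring:", ring),
            if (sidechain24) "sidechain Delta24 (296)")
    hyp[[length(hyp) + 1L]] <- list(
      mplus = cc$grid_mz, cn = cc$cn, db = cc$db, intensity = cc$intensity,
      ring_class = ring, sidechain24 = sidechain24,
      pentacyclic = FALSE, penta_type = NA_character_, evidence = ev)
    if (penta) {
      # weak molecular ions are typical for pentacyclic triterpenols, so
      # the pentacyclic reading is carried as a separate hypothesis
      hyp[[length(hyp) + 1L]] <- list(
        mplus = cc$grid_mz, cn = cc$cn, db = cc$db, intensity = cc$intensity,
        ring_class = "pentacyclic", sidechain24 = FALSE,
        pentacyclic = TRUE, penta_type = penta_type,
        evidence = c(ev[1], sprintf("retro-Diels-Alder 189/218 (%s type)",
                                    penta_type)))
    }
  }
  structure(hyp, ambiguities = ambig)
}

# hard class-compatibility: stanol and pentacyclic signatures are binding;
# Delta-position readings are soft (they are weakened or hindered in
# 4-methyl/4,4-dimethylsterols) and only affect ranking
.class_compatible <- function(hyp, entry) {
  if (entry$class == "internal_standard") return(FALSE)
  if (entry$class == "unknown") return(!hyp$pentacyclic)
  if (hyp$pentacyclic) return(entry$class == "pentacyclic")
  if (entry$class == "pentacyclic") return(FALSE)
  if (hyp$ring_class == "stanol" && !entry$class %in% c("stanol")) {
    # a 215 base peak is binding unless the entry's ring system is fully
    # saturated anyway (cycloartane-type without ring-B DBs)
    pos <- entry$positions
    if (is.na(pos) || !grepl("(^|;)(5|7|8)", pos)) return(TRUE)
    return(FALSE)
  }
  TRUE
}

.class_specificity <- function(hyp, entry) {
  score <- 0
  pos <- if (is.na(entry$positions)) "" else entry$positions
  if (hyp$pentacyclic) {
    score <- score + 2
    d12 <- grepl("(^|;)12(;|$)", pos)
    if ((hyp$penta_type == "d12") == d12) score <- score + 2
  } else {
    ring_pos <- c(d5 = "5", d7 = "7", d5_7 = "5;7", stanol = "")
    if (hyp$ring_class %in% names(ring_pos)) {
      expect <- ring_pos[[hyp$ring_class]]
      if (hyp$ring_class == "stanol" && entry$class == "stanol") {
        score <- score + 2
      } else if (nzchar(expect) &&
                 grepl(paste0("(^|;)", sub(";", ".*;", expect)), pos)) {
        score <- score + 1
      }
    }
    if (hyp$sidechain24 && grepl("24\\(", pos)) score <- score + 1
  }
  score
}

#' Match a classified peak against a reference library
#'
#' Candidates are library entries within `tol_ri` index units whose carbon
#' number and double-bond count equal the hypothesis and whose class does
#' not contradict it (stanol and pentacyclic ion signatures are binding;
#' Delta-position readings only rank). Ties are broken by class specificity,
#' then by smaller |Delta RI|.
#'
#' @param ri retention index of the peak (numeric).
#' @param cls one classification hypothesis (element of [classify_peak()]
#'   output).
#' @param lib a `reference_library`.
#' @param tol_ri matching tolerance, index units (default 2.5).
#' @return data.frame of ranked candidates (`name, ri_fap, delta_ri, level,
#'   standard, tentative, class, specificity`), best first; zero rows when
#'   nothing matches.
#' @export
match_library <- function(ri, cls, lib, tol_ri = 2.5) {
  stopifnot(tol_ri > 0)
  e <- library_analytes(lib)
  ri <- as.numeric(ri)
  rows <- lapply(seq_len(nrow(e)), function(i) {
    en <- e[i, ]
    d <- abs(en$ri_fap - ri)
    if (d > tol_ri) return(NULL)
    if (!is.na(cls$cn) && (en$cn != cls$cn || en$db != cls$db)) return(NULL)
    if (!.class_compatible(cls, en)) return(NULL)
    data.frame(name = en$name, ri_fap = en$ri_fap, delta_ri = en$ri_fap - ri,
               level = en$level, standard = en$standard,
               tentative = en$tentative, class = en$class,
               specificity = .class_specificity(cls, en))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(name = character(), ri_fap = numeric(),
                      delta_ri = numeric(), level = integer(),
                      standard = logical(), tentative = logical(),
                      class = character(), specificity = numeric()))
  }
  out[order(-out$specificity, abs(out$delta_ri)), , drop = FALSE]
}

#' Assign the identification level
#'
#' Level 1: the top candidate has an authentic reference standard and the
#' diagnostic evidence is complete and uncontradicted. Level 2: major
#' sterol (TIC share at or above `major_share`) with complete diagnostics
#' matching a literature entry. Level 3: retention index and molecular ion
#' match a library entry but the diagnostics are incomplete, or the entry
#' itself is a tentative literature structure. Level 4: unknown (molecular
#' ion only, or no library match).
#'
#' @param candidates ranked candidate data.frame from [match_library()].
#' @param evidence_complete logical: all expected diagnostic ions of the top
#'   candidate observed, none contradicted.
#' @param share TIC share of the compound in the run, percent.
#' @param config an [annotation_config()].
#' @return integer level 1-4.
#' @export
assign_level <- function(candidates, evidence_complete, share,
                         config = annotation_config()) {
  if (nrow(candidates) == 0) return(4L)
  top <- candidates[1, ]
  if (top$class == "unknown") return(4L)
  if (top$standard && evidence_complete) return(1L)
  if (top$tentative) return(3L)
  if (evidence_complete && !is.na(share) && share >= config$major_share) {
    return(2L)
  }
  3L
}

# are all expected diagnostics of a library entry present in the peak?
.evidence_complete <- function(ints, entry_ion_set, config) {
  diag <- entry_ion_set$diagnostic
  if (!length(diag)) return(FALSE) # nothing verifiable beyond M+
  top <- max(ints)
  all(vapply(diag, function(mz) {
    .ion_at(ints, mz, config$mz_tol) >= config$diag_floor * top
  }, logical(1)))
}

#' Annotate a full run
#'
#' Pipeline composition: FAP peaks are flagged and form (or confirm) the
#' anchor ladder; the internal standard is located; every remaining peak is
#' indexed on the ladder, classified, matched against the library, isotope-
#' checked and levelled. Peaks carrying several molecular-ion candidates
#' (or both a tetracyclic and a pentacyclic signature) yield several
#' annotations; their shared area is apportioned by least-squares
#' deconvolution of the observed ions against the candidates' expected
#' spectra, conserving the total peak area.
#'
#' @param chrom a [chromatogram()].
#' @param anchors a [fap_anchor_set()], or NULL to extract from `chrom`.
#' @param lib a `reference_library` (default [builtin_library()]).
#' @param config an [annotation_config()].
#' @param anchor_carbons expected FAP carbons when extracting anchors.
#' @return data.frame of class `annotation_table`: one row per annotation
#'   (`run_id, peak_id, rt, rrt, ri, ri_exact, compound, cn, db, class,
#'   level, evidence, interference, delta_ri, area`), with attributes
#'   `anchors`, `istd_rt` and `ambiguities`.
#' @export
annotate_run <- function(chrom, anchors = NULL, lib = builtin_library(),
                         config = annotation_config(),
                         anchor_carbons = 18:25) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (nrow(chrom$peaks) == 0) {
    return(.empty_annotation_table())
  }
  if (is.null(anchors)) {
    anchors <- extract_fap_anchors(chrom, expected_carbons = anchor_carbons)
  }
  anchor_rts <- as.numeric(anchors)
  # internal standard: peak with the expected molecular ion near its RI
  istd_rt <- NA_real_
  for (i in seq_len(nrow(chrom$peaks))) {
    p <- chrom$peaks[i, ]
    ints <- peak_ions(chrom, p$peak_id)
    if (.ion_at(ints, config$istd_mz, config$mz_tol) >= 0.3 * max(ints)) {
      ri_p <- tryCatch(as.numeric(compute_ri_fap(p$apex_rt, anchors)),
                       error = function(e) NA_real_)
      if (!is.na(ri_p) && abs(ri_p - config$istd_ri) <= 10 * config$ri_tol) {
        istd_rt <- p$apex_rt
        break
      }
    }
  }
  rows <- list()
  ambig_all <- character()
  for (i in seq_len(nrow(chrom$peaks))) {
    p <- chrom$peaks[i, ]
    ints <- peak_ions(chrom, p$peak_id)
    i113 <- .ion_at(ints, 113.0, config$mz_tol)
    is_fap <- i113 > 0 && i113 >= max(ints) - 1e-12 &&
      (i113 + .ion_at(ints, 126.0, config$mz_tol)) >= 0.8 * sum(ints)
    if (is_fap || any(abs(p$apex_rt - anchor_rts) < 1e-9)) next # FAP anchor
    if (!is.na(istd_rt) && p$apex_rt == istd_rt) next # internal standard
    ri_exact <- tryCatch(as.numeric(compute_ri_fap(p$apex_rt, anchors)),
                         error = function(e) NA_real_)
    if (is.na(ri_exact)) next
    hyps <- classify_peak(chrom, p$peak_id, config)
    ambig_all <- c(ambig_all, attr(hyps, "ambiguities"))
    if (!length(hyps)) {
      rows[[length(rows) + 1L]] <- .annotation_row(
        chrom, p, istd_rt, ri_exact, compound = NA_character_,
        cn = NA_integer_, db = NA_integer_, class = "unassigned",
        level = 4L, evidence = "no molecular-ion candidate",
        interference = "inconclusive", delta_ri = NA_real_, area = p$area)
      next
    }
    matched <- list()
    for (h in hyps) {
      cands <- match_library(ri_exact, h, lib, tol_ri = config$ri_tol)
      if (nrow(cands) == 0) next
      nm <- cands$name[1]
      if (nm %in% names(matched)) next # one annotation per compound
      chk <- isotope_interference_check(ints, h$mplus, h$cn, config)
      matched[[nm]] <- list(hyp = h, cands = cands, check = chk)
    }
    if (!length(matched)) {
      h <- hyps[[1]]
      rows[[length(rows) + 1L]] <- .annotation_row(
        chrom, p, istd_rt, ri_exact, compound = NA_character_,
        cn = h$cn, db = h$db, class = "unmatched", level = 4L,
        evidence = paste(h$evidence, collapse = "; "),
        interference = "inconclusive", delta_ri = NA_real_, area = p$area)
      next
    }
    areas <- .apportion_peak_area(ints, p$area, names(matched), lib)
    for (nm in names(matched)) {
      m <- matched[[nm]]
      entry <- lib$entries[lib$entries$name == nm, ]
      evc <- .evidence_complete(ints, lib$ion_sets[[nm]], config)
      rows[[length(rows) + 1L]] <- .annotation_row(
        chrom, p, istd_rt, ri_exact, compound = nm, cn = entry$cn,
        db = entry$db, class = entry$class, level = NA_integer_,
        evidence = paste(m$hyp$evidence, collapse = "; "),
        interference = m$check$status,
        delta_ri = m$cands$delta_ri[1], area = areas[[nm]],
        evidence_complete = evc, candidates = m$cands)
    }
  }
  if (!length(rows)) return(.empty_annotation_table())
  tab <- do.call(rbind, lapply(rows, `[[`, "row"))
  # levels need TIC shares: percent of summed annotated sterol area
  total <- sum(tab$area[!is.na(tab$compound)])
  for (j in seq_len(nrow(tab))) {
    meta <- rows[[j]]
    if (is.na(tab$compound[j])) next
    share <- if (total > 0) 100 * tab$area[j] / total else NA_real_
    tab$level[j] <- assign_level(meta$candidates, meta$evidence_complete,
                                 share, config)
  }
  rownames(tab) <- NULL
  structure(tab, anchors = anchors, istd_rt = istd_rt,
            ambiguities = unique(ambig_all),
            class = c("annotation_table", class(tab)))
}

.annotation_row <- function(chrom, p, istd_rt, ri_exact, compound, cn, db,
                            class, level, evidence, interference, delta_ri,
                            area, evidence_complete = FALSE,
                            candidates = NULL) {
  row <- data.frame(
    run_id = chrom$run_id, peak_id = p$peak_id, rt = p$apex_rt,
    rrt = if (is.na(istd_rt)) NA_real_ else p$apex_rt / istd_rt,
    ri = ri_report(ri_exact), ri_exact = ri_exact,
    compound = compound, cn = cn, db = db, class = class, level = level,
    evidence = evidence, interference = interference, delta_ri = delta_ri,
    area = area, stringsAsFactors = FALSE)
  list(row = row, evidence_complete = evidence_complete,
       candidates = candidates %||% data.frame(name = character()))
}

.empty_annotation_table <- function() {
  tab <- data.frame(
    run_id = character(), peak_id = character(), rt = numeric(),
    rrt = numeric(), ri = numeric(), ri_exact = numeric(),
    compound = character(), cn = integer(), db = integer(),
    class = character(), level = integer(), evidence = character(),
    interference = character(), delta_ri = numeric(), area = numeric(),
    stringsAsFactors = FALSE)
  structure(tab, class = c("annotation_table", class(tab)))
}

# least-squares deconvolution of a co-eluting peak's area over the matched
# compounds' expected spectra; conserves total area exactly
.apportion_peak_area <- function(ints, area, compounds, lib) {
  if (length(compounds) == 1) {
    return(stats::setNames(list(area), compounds))
  }
  mzs <- as.numeric(names(ints))
  S <- vapply(compounds, function(nm) {
    spec <- .expected_spectrum(lib, nm)
    smz <- as.numeric(names(spec))
    vapply(mzs, function(m) {
      hit <- abs(smz - m) <= 0.3
      if (any(hit)) sum(spec[hit]) else 0
    }, numeric(1))
  }, numeric(length(mzs)))
  w <- tryCatch({
    fit <- stats::lsfit(S, as.numeric(ints), intercept = FALSE)
    pmax(fit$coefficients, 0)
  }, error = function(e) rep(1, length(compounds)))
  if (sum(w) <= 0) w <- rep(1, length(compounds))
  stats::setNames(as.list(area * w / sum(w)), compounds)
}

#' Write an annotation report
#'
#' TSV mirroring the reference-table layout (name, RRT, RI, cn:DB, class,
#' level, evidence, area).
#'
#' @param annotations an `annotation_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_report <- function(annotations, path) {
  utils::write.table(as.data.frame(annotations), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
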