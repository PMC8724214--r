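# masses, fragment rules and the compound library

test_that("TMS molecular masses follow exact monoisotopic arithmetic", {
  # independent oracle: elemental sums with CODATA monoisotopic masses
  mC <- 12; mH <- 1.00782503207; mO <- 15.9949146196; mSi <- 27.9769265325
  oracle <- function(n, db) {
    round((n + 3) * mC + (2 * n + 2 - 2 * db) * mH + mO + mSi, 4)
  }
  for (n in 27:31) {
    for (db in 0:3) {
      expect_equal(tms_molecular_mz(n, db, digits = NA), oracle(n, db),
                   tolerance = 1e-6)
    }
  }
  expect_equal(tms_molecular_mz(27, 1), 458.4)
  expect_equal(tms_molecular_mz(29, 1), 486.4)
  expect_error(tms_molecular_mz(26, 1), "carbon_number")
  expect_error(tms_molecular_mz(27, 4), "db_count")
})

test_that("molecular-ion grid reproduces the published SIM acquisition values", {
  g <- molecular_ion_grid()
  published <- matrix(c(
    460.4, 458.4, 456.4, 454.4,
    474.4, 472.4, 470.4, 468.4,
    488.4, 486.4, 484.4, 482.4,
    502.5, 500.4, 498.4, 496.4,
    516.5, 514.5, 512.5, 510.5), nrow = 5, byrow = TRUE,
    dimnames = list(27:31, 0:3))
  expect_equal(g, published)
})

test_that("homologue and saturation mass steps are exact on unrounded masses", {
  for (n in 27:30) {
    for (db in 0:3) {
      expect_equal(tms_molecular_mz(n + 1, db, digits = NA) -
                     tms_molecular_mz(n, db, digits = NA), 14.01565,
                   tolerance = 1e-4) # one CH2
    }
  }
  for (n in 27:31) {
    for (db in 0:2) {
      expect_equal(tms_molecular_mz(n, db, digits = NA) -
                     tms_molecular_mz(n, db + 1, digits = NA), 2.01565,
                   tolerance = 1e-4) # one H2
    }
  }
})

test_that("[M-84-TMSOH]+ arithmetic and its precondition", {
  expect_equal(m84_tmsoh_loss(470.4), 296.2)
  expect_equal(m84_tmsoh_loss(484.4), 310.2)
  expect_error(m84_tmsoh_loss(174.2), "exceed")
})

test_that("isotope ratio matches the exact binomial oracle", {
  p <- 0.0107
  for (n in 0:40) {
    oracle <- if (n == 0) 0 else dbinom(1, n, p) / dbinom(0, n, p)
    expect_equal(isotope_m14_ratio(n), oracle, tolerance = 1e-6)
  }
  expect_equal(round(isotope_m14_ratio(34), 3), 0.368)
  expect_equal(round(isotope_m14_ratio(10), 3), 0.108)
  expect_true(all(diff(isotope_m14_ratio(0:40)) > 0))
  expect_error(isotope_m14_ratio(-1), "must be >= 0")
})

test_that("fragment rule table assigns class-diagnostic ion sets", {
  sitostanol <- diagnostic_fragments(
    sterol_descriptor("sitostanol", 29, 0, compound_class = "stanol"))
  expect_equal(sitostanol$expected_base_peak, 215.2)
  expect_equal(sitostanol$molecular_ion, 488.4)

  sito <- diagnostic_fragments(
    sterol_descriptor("b-sitosterol", 29, 1, "5"))
  expect_equal(sito$expected_base_peak, 129.1)
  expect_true(all(c(213.2, 255.2) %in% sito$diagnostic))
  expect_equal(sito$molecular_ion, 486.4)
  expect_equal(sito$m_minus_15, 471.4)

  amyrin <- diagnostic_fragments(
    sterol_descriptor("b-amyrin", 30, 2, "12", "6r17,18", "pentacyclic"))
  expect_equal(amyrin$expected_base_peak, 218.3)
  expect_true(189.2 %in% amyrin$diagnostic)
  expect_equal(amyrin$molecular_ion, 498.4)

  mc24 <- diagnostic_fragments(
    sterol_descriptor("24-methylenecholesterol", 28, 2, c("5", "24(24^1)")))
  expect_true(296.2 %in% mc24$diagnostic)

  lupeol <- diagnostic_fragments(
    sterol_descriptor("lupeol", 30, 2, "20", "5r17,18", "pentacyclic"))
  expect_equal(lupeol$expected_base_peak, 189.2)
  expect_equal(lupeol$intensity_hints[["218.3"]], "weak")

  # 4-methyl: ring ions shifted +14 u and weakened
  citro <- diagnostic_fragments(
    sterol_descriptor("citrostadienol", 30, 2, c("7", "24"),
                      compound_class = "4_methyl"))
  expect_true(all(c(227.2, 269.2) %in% citro$diagnostic))
  expect_true(all(citro$intensity_hints[c("227.2", "269.2")] == "weak"))

  expect_error(diagnostic_fragments(
    sterol_descriptor("mystery", 29, NA_integer_)), "rule gap")
})

test_that("built-in library has the 30 characterized compounds plus the IS", {
  lib <- builtin_library()
  expect_equal(nrow(lib$entries), 31)
  expect_equal(nrow(library_analytes(lib)), 30)
  chol <- lib$entries[lib$entries$name == "Cholesterol", ]
  expect_equal(chol$cn, 27)
  expect_equal(chol$db, 1)
  expect_equal(chol$level, 1)
  expect_equal(lib$ion_sets[["Cholesterol"]]$molecular_ion, 458.4)
  expect_equal(lib$ion_sets[["Cholesterol"]]$expected_base_peak, 129.1)
  # documented co-elutions share an index; otherwise indices are unique
  ri <- library_analytes(lib)$ri_fap
  expect_true(all(table(ri) <= 2))
})

test_that("library TSV round trip preserves entries; empty file warns", {
  lib <- builtin_library()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_compound_library(lib, f)
  lib2 <- build_compound_library(f)
  expect_equal(lib2$entries$name, lib$entries$name)
  expect_equal(lib2$entries$ri_fap, lib$entries$ri_fap)
  expect_equal(names(lib2$ion_sets), names(lib$ion_sets))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("name", "cn", "db", "positions", "rings", "class",
                     "ri_fap", "level"), collapse = "\t"), empty)
  expect_warning(le <- build_compound_library(empty), "empty")
  expect_equal(nrow(le$entries), 0)

  # inconsistent printed M+ is a consistency error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("name", "cn", "db", "positions", "rings", "class",
                       "ri_fap", "level", "mplus_print"), collapse = "\t"),
               paste(c("Fake", "29", "1", "5", "", "desmethyl_sterol",
                       "2300", "2", "480"), collapse = "\t")), bad)
  expect_error(build_compound_library(bad), "inconsistent")
})
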