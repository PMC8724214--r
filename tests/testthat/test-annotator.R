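# rule engine, library matching, isotope check and level assignment

test_that("classification reads carbon number, saturation and ring class", {
  ch <- tiny_chromatogram()
  h1 <- classify_peak(ch, "S1") # Delta5 C29:1 with 129 base, 213/255
  expect_length(h1, 1)
  expect_equal(h1[[1]]$cn, 29)
  expect_equal(h1[[1]]$db, 1)
  expect_equal(h1[[1]]$ring_class, "d5")
  h2 <- classify_peak(ch, "S2") # stanol: base 215
  expect_equal(h2[[1]]$ring_class, "stanol")
  expect_equal(h2[[1]]$mplus, 488.4)
})

test_that("pentacyclic and side-chain signatures raise the right hypotheses", {
  peaks <- data.frame(peak_id = c("A", "B"), apex_rt = c(31.0, 28.5),
                      area = c(10, 10), height = c(100, 100))
  ions <- rbind(
    # amyrin-type: weak M+ 498, 218 > 189
    data.frame(peak_id = "A", mz = c(218.3, 189.2, 498.4),
               intensity = c(1000, 600, 80)),
    # Delta5 C28:2 with the 296 side-chain marker
    data.frame(peak_id = "B", mz = c(129.1, 213.2, 255.2, 296.2, 470.4),
               intensity = c(1000, 400, 450, 300, 600)))
  ch <- chromatogram("t", peaks, ions)
  ha <- classify_peak(ch, "A")
  penta <- Filter(function(h) h$pentacyclic, ha)
  expect_length(penta, 1)
  expect_equal(penta[[1]]$penta_type, "d12")
  hb <- classify_peak(ch, "B")
  expect_equal(hb[[1]]$cn, 28)
  expect_equal(hb[[1]]$db, 2)
  expect_true(hb[[1]]$sidechain24)
})

test_that("isotope satellites are not mistaken for molecular ions", {
  # a C31:2 sterol whose [M-15]+ satellite lands on the C30:2 grid value
  m15 <- 497.4
  sat <- 2500 * isotope_m14_ratio(33)
  peaks <- data.frame(peak_id = "P", apex_rt = 35.0, area = 10, height = 100)
  ions <- data.frame(peak_id = "P",
                     mz = c(129.1, 512.5, m15, m15 + 1),
                     intensity = c(10000, 6000, 2500, sat))
  ch <- chromatogram("t", peaks, ions)
  hyp <- classify_peak(ch, "P")
  expect_equal(vapply(hyp, `[[`, numeric(1), "mplus"), 512.5)

  # spiking a genuine co-eluting C30:2 on top of the satellite is flagged
  ions2 <- ions
  ions2$intensity[4] <- sat + 1500
  ch2 <- chromatogram("t", peaks, ions2)
  hyp2 <- classify_peak(ch2, "P")
  expect_true(498.4 %in% vapply(hyp2, `[[`, numeric(1), "mplus"))
  chk <- isotope_interference_check(peak_ions(ch2, "P"), 512.5, 31)
  expect_equal(chk$status, "fail")
  chk0 <- isotope_interference_check(peak_ions(ch, "P"), 512.5, 31)
  expect_equal(chk0$status, "pass")
  # no [M-15]+ at all: inconclusive
  chk_na <- isotope_interference_check(c("486.4" = 100), 486.4, 29)
  expect_equal(chk_na$status, "inconclusive")
})

test_that("library matching ranks by class compatibility then index distance", {
  lib <- builtin_library()
  d5 <- list(mplus = 486.4, cn = 29, db = 1, ring_class = "d5",
             sidechain24 = FALSE, pentacyclic = FALSE,
             penta_type = NA_character_)
  m <- match_library(2306, d5, lib)
  expect_equal(m$name[1], "b-Sitosterol") # lanosterol 2306 is C30:2
  expect_false("Lanosterol" %in% m$name)

  # cycloartenol vs lupeol at a shared index: the ions decide
  lup <- list(mplus = 498.4, cn = 30, db = 2, ring_class = "pentacyclic",
              sidechain24 = FALSE, pentacyclic = TRUE,
              penta_type = "d13_or_lupeol")
  expect_equal(match_library(2371, lup, lib)$name[1], "Lupeol")
  cyc <- list(mplus = 498.4, cn = 30, db = 2, ring_class = "d5",
              sidechain24 = FALSE, pentacyclic = FALSE,
              penta_type = NA_character_)
  mc <- match_library(2371, cyc, lib)
  expect_equal(mc$name[1], "Cycloartenol")
  expect_false("Lupeol" %in% mc$name)

  expect_equal(nrow(match_library(1500, d5, lib)), 0)
})

test_that("levels follow standards, evidence, abundance and library status", {
  lib <- builtin_library()
  std <- match_library(2225, list(mplus = 472.4, cn = 28, db = 1,
                                  ring_class = "d5", sidechain24 = FALSE,
                                  pentacyclic = FALSE,
                                  penta_type = NA_character_), lib)
  expect_equal(std$name[1], "Campesterol")
  expect_equal(assign_level(std, evidence_complete = TRUE, share = 13.3), 1L)

  tent <- match_library(2247, list(mplus = 472.4, cn = 28, db = 1,
                                   ring_class = "d5", sidechain24 = FALSE,
                                   pentacyclic = FALSE,
                                   penta_type = NA_character_), lib)
  expect_equal(tent$name[1], "D8-Campesterol")
  expect_equal(assign_level(tent, evidence_complete = FALSE, share = 0.1), 3L)

  unk <- match_library(2274, list(mplus = 486.4, cn = 29, db = 1,
                                  ring_class = "d5", sidechain24 = FALSE,
                                  pentacyclic = FALSE,
                                  penta_type = NA_character_), lib)
  expect_equal(unk$name[1], "Unknown 3")
  expect_equal(assign_level(unk, evidence_complete = FALSE, share = 0.2), 4L)

  major <- match_library(2319, list(mplus = 488.4, cn = 29, db = 0,
                                    ring_class = "stanol",
                                    sidechain24 = FALSE, pentacyclic = FALSE,
                                    penta_type = NA_character_), lib)
  expect_equal(major$name[1], "Sitostanol")
  expect_equal(assign_level(major, evidence_complete = TRUE, share = 7.2), 2L)
  expect_equal(assign_level(major, evidence_complete = TRUE, share = 0.01), 3L)
  expect_equal(assign_level(major[0, ], TRUE, 50), 4L)
})

test_that("noise-free synthetic oils are recovered completely and exactly", {
  runs <- oil_runs()
  lib <- builtin_library()
  anns <- lapply(runs, function(r) annotate_run(r$chromatogram, lib = lib))
  for (oil in names(runs)) {
    truth <- runs[[oil]]$truth
    ann <- anns[[oil]]
    expect_setequal(ann$compound[!is.na(ann$compound)], truth$compound)
    dri <- ann$ri_exact - truth$true_ri[match(ann$compound, truth$compound)]
    expect_equal(max(abs(dri)), 0, tolerance = 1e-9)
    # class identity
    expect_identical(
      ann$class[order(ann$compound)],
      truth$true_class[match(sort(ann$compound), truth$compound)])
    # no spurious annotations
    expect_false(any(ann$class %in% c("unassigned", "unmatched")))
  }
  # 30 distinct identities across the four oils
  all30 <- unique(unlist(lapply(anns, function(a) a$compound)))
  expect_length(setdiff(all30, NA), 30)
  # per-compound best level equals the library assignment level
  ann_all <- do.call(rbind, anns)
  lev <- tapply(ann_all$level, ann_all$compound, min)
  libl <- stats::setNames(library_analytes(lib)$level,
                          library_analytes(lib)$name)
  expect_equal(as.integer(lev[names(libl)]), unname(libl))
})

test_that("small index drift does not break identity recovery", {
  run <- generate_run(builtin_profiles()$corn, noise = 0, seed = 13,
                      drift = drift_model("uniform_multiplicative", 0.02))
  ann <- annotate_run(run$chromatogram)
  expect_setequal(ann$compound[!is.na(ann$compound)], run$truth$compound)
})

test_that("specific oils carry their marker sterols", {
  runs <- oil_runs()
  sun <- annotate_run(runs$sunflower$chromatogram)
  expect_true("D7-Sitosterol" %in% sun$compound)
  expect_false("Brassicasterol" %in% sun$compound)
  rap <- annotate_run(runs$rapeseed$chromatogram)
  expect_true("Brassicasterol" %in% rap$compound)
})

test_that("an empty chromatogram yields an empty annotation table", {
  expect_equal(nrow(annotate_run(structure(
    list(run_id = "e", peaks = data.frame(), ions = data.frame(),
         mode = "full_scan", monitored_ions = NULL),
    class = "chromatogram"))), 0)
})
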