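# SIM schedule construction and validation

test_that("initial method 1 monitors exactly 17 ions: C28+C29 grids + fragments", {
  ms <- build_initial_methods()
  m1 <- ms[[1]]
  ions <- sim_method_ions(m1)
  expect_length(ions, 17)
  expect_true(all(c(468.4, 470.4, 472.4, 474.4, 482.4, 484.4, 486.4,
                    488.4) %in% ions))
  expect_true(all(c(113.0, 126.0, 129.1, 211.2, 213.2, 215.2, 253.2,
                    255.2, 296.2) %in% ions))
})

test_that("initial method 2 splits C27 from C31 and never exceeds the budget", {
  m2 <- build_initial_methods()[[2]]
  expect_length(m2$windows, 3)
  c27 <- c(454.4, 456.4, 458.4, 460.4)
  expect_true(all(c27 %in% sim_window_ions(m2, 1)))
  expect_false(any(c27 %in% sim_window_ions(m2, 2)))
  expect_false(any(c27 %in% sim_window_ions(m2, 3)))
  expect_true(all(c(189.2, 218.3) %in% sim_window_ions(m2, 2)))
  expect_true(510.5 %in% sim_window_ions(m2, 3))
  expect_false(510.5 %in% sim_window_ions(m2, 2))
  for (i in 1:3) expect_lte(length(sim_window_ions(m2, i)), 18)
})

test_that("merged method has four snapped windows covering the library", {
  m <- build_time_windows(builtin_library(), budget = 18)
  expect_length(m$windows, 4)
  expect_equal(vapply(m$windows, `[[`, numeric(1), "start"),
               c(2100, 2200, 2300, 2400))
  expect_equal(vapply(m$windows, `[[`, numeric(1), "end"),
               c(2200, 2300, 2400, 2500))
  v <- validate_schedule(m, builtin_library())
  expect_true(v$all_covered)
  expect_true(all(v$windows$within_budget))
})

test_that("window 3 substitutes the lone C31 ion for undetected compositions", {
  m <- build_time_windows(builtin_library(), budget = 18)
  w3 <- sim_window_ions(m, 3)
  expect_true(512.5 %in% w3)
  expect_false(496.4 %in% w3)
  expect_false(502.5 %in% w3)
  expect_true(all(c(189.2, 218.3) %in% w3)) # amyrins elute here
  expect_true(all(c(482.4, 484.4, 486.4, 488.4) %in% w3)) # full C29 grid
  expect_true(113.0 %in% w3)
  expect_false(126.0 %in% w3) # released first under the budget
})

test_that("every scheduled ion traces to the library or the fragment set", {
  lib <- builtin_library()
  m <- build_time_windows(lib)
  frag <- c(113.0, 126.0, 129.1, 189.2, 211.2, 213.2, 215.2, 218.3, 253.2,
            255.2, 296.2)
  grid <- as.numeric(molecular_ion_grid())
  expect_true(all(sim_method_ions(m) %in% c(frag, grid)))
})

test_that("rebuilding from the same library is a fixed point", {
  lib <- builtin_library()
  m1 <- build_time_windows(lib)
  m2 <- build_time_windows(lib)
  expect_identical(lapply(seq_along(m1$windows),
                          function(i) sim_window_ions(m1, i)),
                   lapply(seq_along(m2$windows),
                          function(i) sim_window_ions(m2, i)))
})

test_that("a single-compound library yields one window with M+ and fragments", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_compound_library(builtin_library(), f)
  tab <- utils::read.delim(f)
  utils::write.table(tab[tab$name %in% c("5a-Cholestane", "b-Sitosterol"), ],
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  lib1 <- build_compound_library(f)
  m <- build_time_windows(lib1)
  expect_length(m$windows, 1)
  ions <- sim_window_ions(m, 1)
  expect_true(486.4 %in% ions)
  expect_true(all(c(113.0, 129.1) %in% ions))
})

test_that("a schedule missing a molecular ion fails exactly that compound", {
  lib <- builtin_library()
  m <- build_time_windows(lib, budget = 18)
  # strip 512.5 from window 3: the C31 compound eluting there loses coverage
  m$windows[[3]]$retention_dependent_ions$C31 <- numeric(0)
  v <- validate_schedule(m, lib)
  failed <- v$compounds$name[!v$compounds$mplus_monitored]
  expect_equal(failed, "Unknown 7")
})

test_that("isotope-check observability is reported per compound", {
  lib <- builtin_library()
  m <- build_time_windows(lib, budget = 18)
  v <- validate_schedule(m, lib)
  # 24-methylenecycloartanol: [M-14]+ at 498 is monitored in its window
  mca <- v$compounds[v$compounds$name == "24-Methylenecycloartanol", ]
  expect_true(mca$isotope_observable)
})

test_that("an infeasible budget names the offending window", {
  expect_error(build_time_windows(builtin_library(), budget = 10),
               "budget 10 infeasible")
})

test_that("schedules export to the documented TSV layout", {
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- build_time_windows(builtin_library())
  write_schedule(m, f, anchors = nominal_fap_ladder())
  tab <- utils::read.delim(f)
  expect_true(all(c("window", "start", "end", "ion", "group",
                    "start_min") %in% names(tab)))
  expect_equal(sort(unique(tab$window)), 1:4)
  expect_true(all(diff(tab$start_min[match(1:4, tab$window)]) > 0))
})
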