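# shared fixtures, built in code at test time

# minimal hand-built chromatogram: 3 FAP anchors, the internal standard and
# two sterol peaks (a Delta5 C29:1 and a stanol C29:0)
tiny_chromatogram <- function() {
  peaks <- data.frame(
    peak_id = c("F21", "F22", "IS", "S1", "S2", "F23"),
    apex_rt = c(26.462, 28.982, 21.001, 30.0, 30.3, 30.872),
    area = c(200, 200, 500, 1000, 300, 200),
    height = c(2000, 2000, 5000, 10000, 3000, 2000))
  ions <- rbind(
    data.frame(peak_id = "F21", mz = c(113.0, 126.0), intensity = c(2000, 1100)),
    data.frame(peak_id = "F22", mz = c(113.0, 126.0), intensity = c(2000, 1100)),
    data.frame(peak_id = "F23", mz = c(113.0, 126.0), intensity = c(2000, 1100)),
    data.frame(peak_id = "IS", mz = c(217.2, 357.4, 372.4),
               intensity = c(5000, 3000, 3500)),
    data.frame(peak_id = "S1", mz = c(129.1, 213.2, 255.2, 486.4, 471.4, 472.4),
               intensity = c(10000, 4000, 4500, 6000, 2500,
                             2500 * isotope_m14_ratio(31))),
    data.frame(peak_id = "S2", mz = c(215.2, 488.4, 473.4, 474.4),
               intensity = c(3000, 1650, 750, 750 * isotope_m14_ratio(31))))
  chromatogram("tiny", peaks, ions)
}

# noise-free synthetic runs for the four oils, generated once per test file
oil_runs <- local({
  cache <- NULL
  function(seed = 11) {
    if (is.null(cache)) {
      cache <<- lapply(builtin_profiles(), generate_run, noise = 0,
                       seed = seed)
    }
    cache
  }
})

expect_peak_table_equivalent <- function(path_a, path_b) {
  a <- utils::read.delim(path_a)
  b <- utils::read.delim(path_b)
  key <- function(x) x[order(x$peak_id, x$mz), c("rt_min", "mz", "intensity",
                                                 "area", "peak_id")]
  expect_equal(key(a), key(b), tolerance = 1e-9, ignore_attr = TRUE)
}
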