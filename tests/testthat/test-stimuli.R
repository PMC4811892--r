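test_that("cross-splicing is sample-exact concatenation", {
  a <- synthesize_token(500, boundary_ms = 200, seed = 1)
  b <- synthesize_token(600, boundary_ms = 300, seed = 2)
  out <- cross_splice(a, b, snap_to_zero = FALSE)
  i1 <- round(200 * a$audio$rate / 1000)
  i2 <- round(300 * b$audio$rate / 1000)
  expect_identical(length(out), as.integer(i1 + (length(b$audio) - i2)))
  expect_identical(out$samples[seq_len(i1)], a$audio$samples[seq_len(i1)])
  expect_identical(out$samples[-seq_len(i1)],
                   b$audio$samples[seq(i2 + 1, length(b$audio))])

  b_other <- synthesize_token(600, boundary_ms = 300, rate = 44100, seed = 2)
  expect_error(cross_splice(a, b_other), "rates")
})

test_that("condition assembly realizes the durational manipulation", {
  pair <- generate_stimulus_inventory(seed = 5)$pairs[1, ]
  ns_match <- build_condition_stimulus(pair, "target_matching", "NS")
  ns_mis <- build_condition_stimulus(pair, "target_mismatching", "NS")
  # mismatching cue = the longer monosyllabic first part, so the assembled
  # sentence is longer by the pair's duration difference (up to the
  # zero-crossing snap, bounded by one f0 period)
  d_ms <- (length(ns_mis$audio) - length(ns_match$audio)) /
    ns_match$audio$rate * 1000
  expect_lt(abs(d_ms - pair$duration_difference_ms), 1000 / 150)

  ds_match <- build_condition_stimulus(pair, "target_matching", "DS")
  expect_identical(length(ds_match$audio), length(ns_match$audio))
  ds_mis <- build_condition_stimulus(pair, "target_mismatching", "DS")
  expect_identical(length(ds_mis$audio), length(ns_mis$audio))
})

test_that("synthetic tokens are deterministic with the requested structure", {
  tk <- synthesize_token(300, f0 = 150, rate = 44100, seed = 9)
  expect_identical(length(tk$audio), 13230L)
  tk2 <- synthesize_token(300, f0 = 150, rate = 44100, seed = 9)
  expect_identical(tk$audio$samples, tk2$audio$samples)
  expect_true(tk$boundary_ms > 0 && tk$boundary_ms < 300)

  spec <- abs(stats::fft(tk$audio$samples))[seq_len(6615)]
  freqs <- (seq_len(6615) - 1) * 44100 / 13230
  peak <- freqs[which.max(spec)]
  expect_lt(abs(peak - 150), 44100 / 13230 + 1)  # within one FFT bin
})

test_that("the inventory reproduces the materials' counts and durations", {
  inv <- generate_stimulus_inventory(seed = 3)
  expect_equal(nrow(inv$pairs), 26)
  expect_equal(nrow(inv$fillers), 40)
  expect_equal(sum(inv$fillers$syllabic == "polysyllabic"), 7)
  expect_equal(sum(inv$fillers$syllabic == "monosyllabic"), 33)
  expect_equal(as.integer(table(inv$fillers$embedding)[c("none", "initial", "final")]),
               c(20L, 10L, 10L))
  expect_true(all(inv$pairs$duration_difference_ms >= 20 &
                  inv$pairs$duration_difference_ms <= 120))
  expect_true(all(inv$pairs$syllable_duration_mono_ms >
                  inv$pairs$syllable_duration_poly_ms))
  expect_error(
    generate_stimulus_inventory(filler_counts = c(poly = 10, mono = 33,
                                                  none = 20, initial = 10,
                                                  final = 10)),
    "partition")

  diffs <- unlist(lapply(1:300, function(s)
    generate_stimulus_inventory(seed = s)$pairs$duration_difference_ms))
  expect_equal(mean(diffs), 65, tolerance = 1 / 65)  # Monte-Carlo error ~0.25 ms
})

test_that("inventory manifest writes as TSV", {
  inv <- generate_stimulus_inventory(seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_inventory_tsv(inv, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 26)
  expect_equal(back$duration_difference_ms, inv$pairs$duration_difference_ms)
  unlink(path)
})
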