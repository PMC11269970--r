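test_that("event snippets have the requested length and unit RMS", {
  x <- generate_bs_event(0.025, seed = 1)
  expect_length(x, 400L)
  x <- generate_bs_event(0.223, seed = 2)
  expect_length(x, 3568L)
  expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-6)
  # long events are burst trains but still one waveform of full length
  x <- generate_bs_event(2.5, seed = 3)
  expect_length(x, 40000L)
  expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-6)
})

test_that("out-of-bounds event durations are rejected", {
  expect_error(generate_bs_event(0.010), "outside bounds")
  expect_error(generate_bs_event(7.5), "outside bounds")
})

test_that("generated recordings hit the target sparsity and guidelines", {
  spec <- corpus_spec(recording_duration = 1800, seed = 3)
  set.seed(spec$seed)
  r <- generate_recording(spec)
  confirmed <- r$events[!r$events$tentative, , drop = FALSE]
  ratio <- sum(confirmed$offset - confirmed$onset) / r$recording$n_samples
  expect_gt(ratio, 0.0089 * 0.8)
  expect_lt(ratio, 0.0089 * 1.2)
  durs <- (r$events$offset - r$events$onset) / 16000
  expect_true(all(durs >= 0.018))
  if (nrow(r$events) > 1) {
    gaps <- r$events$onset[-1] - r$events$offset[-nrow(r$events)]
    expect_true(all(gaps >= 0.1 * 16000))
  }
})

test_that("sample median duration tracks the configured log-normal median", {
  spec <- corpus_spec(seed = 4)
  set.seed(4)
  durs <- bowelspot:::draw_durations(500, spec)
  expect_gt(stats::median(durs), 0.223 * 0.85)
  expect_lt(stats::median(durs), 0.223 * 1.15)
})

test_that("zero target ratio gives pure noise", {
  spec <- corpus_spec(recording_duration = 30, target_bs_ratio = 0, seed = 5)
  set.seed(5)
  r <- generate_recording(spec)
  expect_equal(nrow(r$events), 0L)
  expect_length(r$recording$samples, 30 * 16000)
})

test_that("infeasible sparsity targets are rejected", {
  spec <- corpus_spec(recording_duration = 60, target_bs_ratio = 0.98,
                      seed = 6)
  # constructor bound first
  expect_error(corpus_spec(target_bs_ratio = 1.2), "target_bs_ratio")
  set.seed(6)
  expect_error(generate_recording(spec), "infeasible")
})

test_that("guideline-violating corpus specs are rejected", {
  expect_error(corpus_spec(duration_bounds = c(0.010, 6.29)), "0.018")
  expect_error(corpus_spec(min_gap = 0.05), "min_gap")
})

test_that("write_corpus emits one WAV and TSV per channel plus a manifest", {
  dir <- withr::local_tempdir()
  spec <- corpus_spec(n_participants = 3, channels_per_participant = 2,
                      recording_duration = 12, target_bs_ratio = 0.02,
                      seed = 7)
  manifest <- write_corpus(spec, dir)
  expect_equal(nrow(manifest), 6L)
  expect_length(list.files(dir, pattern = "\\.wav$"), 6L)
  expect_length(list.files(dir, pattern = "\\.tsv$"), 6L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  m2 <- read_manifest(dir)
  expect_equal(m2$participant_id, manifest$participant_id)
  expect_true(all(file.exists(m2$wav_path)))
})

test_that("an empty corpus yields an empty manifest and no WAVs", {
  dir <- withr::local_tempdir()
  spec <- corpus_spec(n_participants = 0, recording_duration = 10, seed = 8)
  manifest <- write_corpus(spec, dir)
  expect_equal(nrow(manifest), 0L)
  expect_length(list.files(dir, pattern = "\\.wav$"), 0L)
})

test_that("label round trip through disk preserves boundaries to <= 1 sample", {
  dir <- withr::local_tempdir()
  spec <- corpus_spec(n_participants = 1, recording_duration = 60,
                      target_bs_ratio = 0.02, seed = 9)
  write_corpus(spec, dir)
  m <- read_manifest(dir)
  set.seed(spec$seed)
  ref <- generate_recording(spec, "P01", "CH1")
  back <- read_labels(m$label_path[1])
  expect_equal(nrow(back), nrow(ref$events))
  expect_true(all(abs(back$onset - ref$events$onset) <= 1))
  expect_true(all(abs(back$offset - ref$events$offset) <= 1))
  expect_equal(back$tentative, ref$events$tentative)
})

test_that("the corpus is bit-identical under a fixed spec and seed", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  spec <- corpus_spec(n_participants = 2, recording_duration = 8,
                      target_bs_ratio = 0.02, seed = 10)
  write_corpus(spec, dir1)
  write_corpus(spec, dir2)
  for (f in list.files(dir1, pattern = "\\.(wav|tsv)$")) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e7),
                     readBin(file.path(dir2, f), "raw", 1e7))
  }
})

test_that("per-event SNR scaling is visible in the waveform", {
  spec <- corpus_spec(n_participants = 1, recording_duration = 120,
                      target_bs_ratio = 0.03, snr_range = c(10, 10 + 1e-9),
                      tentative_snr_floor = -100, seed = 12)
  set.seed(12)
  r <- generate_recording(spec)
  segs <- segment_audio(r$recording)
  snrs <- vapply(segs, function(s) segment_snr(s, r$events), numeric(1))
  snrs <- snrs[!is.na(snrs)]
  # measured in-event power includes the background under the event:
  # expected 10*log10(1 + 10^(10/10)) = 10.41 dB
  expect_equal(stats::median(snrs), 10.41, tolerance = 0.15)
})
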