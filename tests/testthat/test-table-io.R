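toy_rows <- function() {
  data.frame(rt_sec = c(100, 100, 100, 240.5, 240.5),
             mz = c(85, 100, 200, 90, 150),
             S1 = c(10, 100, 50, 80, 20),
             S2 = c(12, 110, 55, 70, 22))
}

test_that("peak CSV reading round-trips and reports parse errors with locations", {
  rows <- toy_rows()
  f <- tempfile(fileext = ".csv")
  write_peak_csv(rows, f)
  expect_equal(read_peak_csv(f), rows)
  # non-numeric cell errors name the row and column
  bad <- rows
  bad$S1 <- as.character(bad$S1)
  bad$S1[2] <- "NA"
  fb <- tempfile(fileext = ".csv")
  utils::write.csv(bad, fb, row.names = FALSE, quote = FALSE)
  expect_error(read_peak_csv(fb), "row 2.*S1")
  # unknown header lists the expected dialect
  fh <- tempfile(fileext = ".csv")
  writeLines(c("time,mass,s1", "1,85,3"), fh)
  expect_error(read_peak_csv(fh), "rt_sec,mz")
  # the column-mapping option adapts foreign headers
  mapped <- read_peak_csv(fh, col_map = c(rt_sec = "time", mz = "mass"))
  expect_equal(mapped$rt_sec, 1)
  expect_error(read_peak_csv(tempfile()), "not found")
})

test_that("signals group into peaks by RT with reconstructed spectra and base-peak heights", {
  tab <- group_signals_into_peaks(toy_rows(), rt_tolerance = 1.5)
  expect_length(tab$peaks, 2L)
  p1 <- tab$peaks[[1]]
  expect_equal(sum(p1$spectrum$intensities > 0), 3L)   # masses 85, 100, 200
  expect_equal(p1$spectrum$intensities[100 - 85 + 1], 100)  # base peak
  expect_equal(p1$heights, c(100, 110))  # base-peak m/z intensities per sample
  expect_equal(p1$rt, 100)
  # two signal groups 10 s apart with tolerance 1 s stay distinct peaks
  rows2 <- data.frame(rt_sec = c(50, 60), mz = c(100, 100),
                      S1 = c(5, 5), S2 = c(5, 5))
  expect_length(group_signals_into_peaks(rows2, rt_tolerance = 1)$peaks, 2L)
  # duplicate m/z within a cluster keeps the more intense signal and warns
  rows3 <- data.frame(rt_sec = c(100, 100.2), mz = c(100, 100),
                      S1 = c(10, 90), S2 = c(10, 90))
  expect_warning(tab3 <- group_signals_into_peaks(rows3, rt_tolerance = 1.5),
                 "duplicate m/z")
  expect_equal(tab3$peaks[[1]]$heights, c(90, 90))
  # out-of-range masses are dropped with a warning
  rows4 <- data.frame(rt_sec = 100, mz = 600, S1 = 5, S2 = 5)
  expect_warning(tab4 <- group_signals_into_peaks(rows4), "outside")
  expect_length(tab4$peaks, 0L)
})

test_that("peaks reconstructed from known spectra match their generators", {
  tpl <- make_default_templates(1)
  batch <- make_synthetic_batch(tpl, library_size = 12, n_samples = 4,
                                drift = c(1, 0), seed = 71)
  tab <- group_signals_into_peaks(batch$signal_rows)
  expect_length(tab$peaks, 12L)
  w <- spectrum_weighting()
  docs <- vapply(seq_len(12), function(i) {
    pearson_doc(weight_spectrum(tab$peaks[[i]]$spectrum, w),
                weight_spectrum(batch$library[[i]]$spectrum, w))
  }, numeric(1))
  expect_true(all(docs > 0.99))
})

test_that("the organized matrix covers every peak with no missing cells", {
  tab <- group_signals_into_peaks(toy_rows())
  reports <- data.frame(
    peak_id = vapply(tab$peaks, function(p) p$peak_id, character(1)),
    rt_sec = vapply(tab$peaks, function(p) p$rt, numeric(1)),
    status = c("identified", "unknown"),
    label = c("glucose", "unknown"), score = c(0.99, 0))
  f <- tempfile(fileext = ".csv")
  write_organized_matrix(reports, tab, f)
  out <- utils::read.csv(f)
  expect_equal(nrow(out), 2L)
  expect_equal(ncol(out), 7L)  # 5 report columns + 2 samples
  expect_false(anyNA(out))
  expect_false(any(out == ""))
  # heights survive the round trip
  expect_equal(out$S1, c(100, 80))
  expect_equal(out$S2, c(110, 70))
  # report/peak count mismatch errors
  expect_error(write_organized_matrix(reports[1, ], tab, f), "2 peaks")
  # empty inputs give a header-only file
  empty <- peak_table("S1", list())
  write_organized_matrix(reports[0, ], empty, f)
  expect_equal(nrow(utils::read.csv(f)), 0L)
})

test_that("random synthetic batches always produce complete matrices", {
  tpl <- make_default_templates(1)
  for (seed in 1:10) {
    batch <- make_synthetic_batch(tpl, library_size = 5, n_samples = 3,
                                  drift = c(1, 0), n_noise_peaks = 1,
                                  seed = 100 + seed)
    tab <- group_signals_into_peaks(batch$signal_rows)
    ids <- identify_all(tab, batch$library, c_sec = 2)
    reports <- data.frame(
      peak_id = ids$peak_id,
      rt_sec = vapply(tab$peaks, function(p) p$rt, numeric(1)),
      status = ifelse(ids$status == "identified", "identified", "unknown"),
      label = ifelse(is.na(ids$match_name), "unknown", ids$match_name),
      score = ifelse(is.na(ids$doc), 0, ids$doc))
    f <- tempfile(fileext = ".csv")
    write_organized_matrix(reports, tab, f)
    out <- utils::read.csv(f)
    expect_equal(nrow(out), length(tab$peaks))
    expect_false(anyNA(out))
  }
})
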