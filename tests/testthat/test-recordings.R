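test_that("recordings round-trip through CSV + sidecar losslessly", {
  set.seed(1)
  n <- 50
  rec <- pen_recording(t = cumsum(runif(n, 0.005, 0.012)),
                       x = rnorm(n, 100, 30), y = rnorm(n, 200, 30),
                       pressure = runif(n, 0.2, 4.0),
                       participant_id = "P9", shape = "square",
                       group = "CM", meta = list(age = 70, seed = 5L))
  path <- file.path(tempdir(), "rec.csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$samples, rec$samples, tolerance = 1e-9)
  expect_identical(back$participant_id, "P9")
  expect_identical(back$shape, "square")
  expect_identical(back$group, "CM")
  expect_equal(back$meta$age, 70)

  # unlabeled recording: sidecar omits the group field entirely
  rec2 <- pen_recording((0:3) / 120, 0:3, rep(0, 4), rep(1, 4),
                        "P1", "spiral")
  write_recording(rec2, path)
  meta <- jsonlite::read_json(sub("\\.csv$", ".meta.json", path))
  expect_false("group" %in% names(meta))
  expect_null(read_recording(path)$group)
})

test_that("reading rejects malformed recordings with a located diagnostic", {
  dir <- tempdir()
  w <- function(txt, name) {
    p <- file.path(dir, name)
    writeLines(txt, p)
    p
  }
  expect_error(read_recording(w("t,x,y\n0,0,0\n1,1,1", "m1.csv")),
               "missing column")
  expect_error(
    read_recording(w("t,x,y,pressure\n0,0,0,1\n0,1,1,1", "m2.csv")),
    "not strictly increasing at row 2")
  expect_error(
    read_recording(
      w("t,x,y,pressure\n0,0,0,1\n0.01,1,1,4.2", "m3.csv")),
    "row 2.*4\\.2")
  expect_error(read_recording(w("t,x,y,pressure\n0,0,0,1", "m4.csv")),
               "at least 2 samples")
  # the device boundary value itself is legal
  p <- w("t,x,y,pressure\n0,0,0,1\n0.01,1,1,4.166667", "m5.csv")
  expect_equal(max(read_recording(p)$samples$pressure), 4.166667)
  expect_error(read_recording(file.path(dir, "nope.csv")), "no such")
})

test_that("validation reports gaps, duplicates and range violations", {
  ok <- uniform_rec(rep(1, 30))
  expect_true(validate_recording(ok)$ok)
  expect_false(validate_recording(ok)$multi_stroke)

  gap <- pen_recording(c((0:9) / 120, 0.5 + (0:9) / 120),
                       1:20, rep(0, 20), rep(1, 20), "G", "spiral")
  v <- validate_recording(gap)
  expect_true(v$multi_stroke)
  expect_match(v$violations, "gap", all = FALSE)

  # bare list bypasses the constructor so broken series can be examined
  dup <- list(samples = data.frame(t = c(0, 1, 1, 2) / 120, x = 1:4,
                                   y = 1:4, pressure = rep(1, 4)),
              nominal_rate = 120)
  v2 <- validate_recording(dup)
  expect_false(v2$ok)
  expect_match(v2$violations, "strictly increasing", all = FALSE)

  out <- list(samples = data.frame(t = (0:2) / 120, x = 1:3, y = 1:3,
                                   pressure = c(1, 9, 1)),
              nominal_rate = 120)
  expect_match(validate_recording(out)$violations, "pressure out of range",
               all = FALSE)
})

test_that("keep_longest_stroke retains the longest contiguous segment", {
  gap <- pen_recording(c((0:4) / 120, 0.5 + (0:14) / 120),
                       1:20, rep(0, 20), rep(1, 20), "G", "spiral")
  kept <- keep_longest_stroke(gap)
  expect_equal(nrow(kept$samples), 15)
  expect_false(validate_recording(kept)$multi_stroke)
})

test_that("cohorts enforce uniqueness and JOA range, and round-trip", {
  co <- simulate_cohort(n_noncm = 3, n_cm = 2, seed = 11)
  expect_equal(length(co$recordings), 15)  # one per participant per shape
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, dir)
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(manifest), 15)
  back <- read_cohort(dir)
  expect_equal(length(back$recordings), 15)
  expect_equal(back$recordings[[1]]$samples, co$recordings[[1]]$samples,
               tolerance = 1e-9)
  expect_equal(back$participants$joa_score, co$participants$joa_score)

  r <- co$recordings[[1]]
  expect_error(cmscreen:::new_cohort(list(r, r), NULL), "duplicate")
  bad <- co$participants
  bad$joa_score[bad$group == "CM"][1] <- 19
  expect_error(cmscreen:::new_cohort(co$recordings, bad), "JOA")
})
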