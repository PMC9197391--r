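# Domain types, windowing, QC and on-disk round trips.

test_that("trace invariants are enforced", {
  expect_error(trace(numeric(0), 0.1), "non-empty")
  expect_error(trace(c(1, NA, 3), 0.1), "non-finite")
  expect_error(trace(c(1, 2), 0), "dt")
  tr <- trace(rep(-70, 1000), 0.1)
  expect_equal(trace_duration(tr), 100)
  # 10-minute segment at 10 kHz: duration arithmetic
  long <- trace(numeric(6e6) - 73, 0.1)
  expect_identical(trace_duration(long), 600000)
})

test_that("extract_window obeys the half-open convention and composes", {
  tr <- trace(seq_len(1000), 0.1, t0 = 0)
  expect_equal(extract_window(tr, 0, 100)$samples, tr$samples)   # identity
  one <- extract_window(tr, 0, 0.1)                              # [0, dt)
  expect_equal(length(one$samples), 1L)
  expect_equal(one$samples, 1)
  # composition equals intersected window
  a <- extract_window(extract_window(tr, 10, 80), 20, 50)
  b <- extract_window(tr, 20, 50)
  expect_equal(a, b)
  # 3 min of a 10 min trace at 10 kHz -> exactly 1.8e6 samples
  long <- trace(numeric(6e6), 0.1)
  expect_identical(length(extract_window(long, 0, 180000)$samples), 1800000L)
  expect_error(extract_window(tr, -1, 50), "out of range")
  expect_error(extract_window(tr, 50, 150), "out of range")
})

test_that("sweep and recording validation", {
  v <- trace(rep(-70, 100), 0.1, "voltage")
  i <- trace(numeric(100), 0.1, "current")
  expect_error(sweep(v, i, "bogus"), "protocol_tag")
  expect_error(sweep(v, trace(numeric(50), 0.1, "current"), "iv_step"),
               "length")
  expect_error(sweep(v, trace(numeric(100), 0.2, "current"), "iv_step"),
               "dt")
  sw <- sweep(v, i, "spontaneous")
  expect_error(recording("c", "current_clamp", "before", list()), "sweep")
  expect_error(recording("c", "current_clamp", "nope", list(sw)))
  # voltage-clamp recordings must carry current-signal sweeps
  expect_error(recording("c", "voltage_clamp", "before", list(sw)),
               "current")
  rec <- recording("c", "current_clamp", "before", list(sw))
  expect_s3_class(rec, "ephys_recording")
  expect_equal(recording_dt(rec), 0.1)
})

test_that("qc_recording follows the strict-inequality thresholds", {
  mk <- function(leak, seal) {
    r <- tiny_recording()
    r$leak_pA <- leak; r$seal_Gohm <- seal
    r
  }
  expect_true(qc_recording(mk(10, 2))$pass)
  q <- qc_recording(mk(26, 2))
  expect_false(q$pass)
  expect_identical(q$reasons, "leak")
  # boundary values pass: criteria are "> 25" and "< 1"
  expect_true(qc_recording(mk(25, 2))$pass)
  expect_true(qc_recording(mk(10, 1))$pass)
  expect_false(qc_recording(mk(10, 0.9))$pass)
  # absent metadata: pass with reason
  qna <- qc_recording(mk(NA, NA))
  expect_true(qna$pass)
  expect_identical(qna$reasons, "not_measured")
  expect_error(qc_recording(mk(10, -1)), "negative seal")
})

test_that("qc_recording is monotone in the leak threshold", {
  r <- tiny_recording(); r$leak_pA <- 30; r$seal_Gohm <- 2
  passes <- vapply(c(20, 25, 29, 30, 40), function(lm)
    qc_recording(r, leak_max = lm)$pass, logical(1))
  expect_false(any(diff(passes) < 0))   # raising leak_max never flips pass->fail
})

test_that("recording IO round-trips exactly", {
  rec <- tiny_recording()
  d <- withr::local_tempdir()
  p1 <- file.path(d, "rec1")
  write_recording(rec, p1)
  back <- read_recording(p1)
  expect_equal(back, rec, tolerance = 1e-12)
  # write -> read -> write is byte-identical
  p2 <- file.path(d, "rec2")
  write_recording(back, p2)
  for (f in dir(p1)) {
    expect_identical(unname(tools::md5sum(file.path(p1, f))),
                     unname(tools::md5sum(file.path(p2, f))))
  }
})

test_that("recording IO reports format and data errors", {
  d <- withr::local_tempdir()
  expect_error(read_recording(file.path(d, "nothing")), "sidecar")
  rec <- tiny_recording()
  p <- file.path(d, "rec")
  write_recording(rec, p)
  # dt mismatch: resample one sweep's time column
  f <- file.path(p, "sweep_001.csv")
  tab <- data.table::fread(f)
  tab[[1]] <- tab[[1]] * 2
  data.table::fwrite(tab, f)
  expect_error(read_recording(p), "consistency")
  # non-finite sample
  write_recording(rec, p, overwrite = TRUE)
  tab <- data.table::fread(f)
  tab[[2]][5] <- NA
  data.table::fwrite(tab, f)
  expect_error(read_recording(p), "non-finite")
})

test_that("pair recordings round-trip", {
  pre <- tiny_recording(seed = 1)
  post <- tiny_recording(seed = 2)
  post$cell_id <- "cell2"
  pair <- pair_recording(pre, post, pair_id = "p1")
  d <- withr::local_tempdir()
  write_pair_recording(pair, file.path(d, "p1"))
  back <- read_pair_recording(file.path(d, "p1"))
  expect_equal(back, pair, tolerance = 1e-12)
})
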