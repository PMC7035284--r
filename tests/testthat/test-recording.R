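test_that("recording construction enforces the sample invariants", {
  # tilt angle out of [0, 180]
  expect_error(
    stroke_rec(x = 1:3, y = 0, azimuth = 200),
    class = "handscale_validation_error")
  # non-monotone time within a stroke
  expect_error(
    recording(tibble::tibble(stroke_id = 1L, t = c(0.1, 0.05, 0.2),
                             x = 1:3, y = 0, pressure = 1, azimuth = 60,
                             altitude = 40),
              age = 8, gender = "F"),
    class = "handscale_validation_error")
  # negative pressure
  expect_error(
    stroke_rec(x = 1:3, y = 0, pressure = -1),
    class = "handscale_validation_error")
  # overlapping stroke time ranges
  expect_error(
    strokes_rec(list(stroke_tbl(5, t0 = 0), stroke_tbl(5, t0 = 0.02))),
    class = "handscale_validation_error")
  # empty
  expect_error(
    recording(tibble::tibble(stroke_id = integer(), t = numeric(),
                             x = numeric(), y = numeric(),
                             pressure = numeric(), azimuth = numeric(),
                             altitude = numeric()),
              age = 8, gender = "F"),
    class = "handscale_validation_error")
})

test_that("degenerate one-sample strokes are dropped with a warning", {
  samples <- dplyr::bind_rows(
    tibble::tibble(stroke_id = 1L, t = 0.01, x = 0, y = 0, pressure = 1,
                   azimuth = 60, altitude = 40),
    dplyr::mutate(stroke_tbl(5, t0 = 0.1), stroke_id = 2L))
  expect_warning(rec <- recording(samples, age = 8, gender = "F"),
                 "degenerate")
  expect_equal(n_strokes(rec), 1L)
  expect_equal(nrow(rec), 5L)
})

test_that("concat_samples preserves count and order and indexes strokes", {
  rec <- strokes_rec(list(stroke_tbl(3, t0 = 0), stroke_tbl(4, t0 = 0.5)))
  cs <- concat_samples(rec)
  expect_equal(nrow(cs), 7L)
  expect_false(is.unsorted(cs$t))
  idx <- attr(cs, "stroke_index")
  expect_equal(idx$start, c(1L, 4L))
  expect_equal(idx$end, c(3L, 7L))
  # single stroke: identity
  rec1 <- stroke_rec(x = 1:5, y = 0)
  expect_equal(nrow(concat_samples(rec1)), 5L)
  # random recordings conserve counts
  for (s in 1:5) {
    rec <- random_recording(s, n_strokes = 4)
    expect_equal(nrow(concat_samples(rec)), nrow(rec))
  }
})

test_that("line segmentation groups strokes by vertical position", {
  # two lines at median y 100 and 400, stroke height ~40
  wob <- seq(-20, 20, length.out = 10)
  mk <- function(y0, t0) {
    s <- stroke_tbl(10, t0 = t0)
    s$y <- y0 + wob
    s
  }
  rec <- strokes_rec(list(mk(100, 0), mk(400, 0.5), mk(100, 1.0),
                          mk(400, 1.5)))
  seg <- segment_lines(rec)
  lines <- unique(seg[, c("stroke_id", "line_id")])
  expect_equal(lines$line_id, c(1L, 2L, 1L, 2L))

  # all strokes at the same y: one line
  rec1 <- strokes_rec(list(mk(100, 0), mk(100, 0.5)))
  expect_true(all(segment_lines(rec1)$line_id == 1L))

  # idempotent, and explicit labels win
  seg2 <- segment_lines(seg)
  expect_identical(seg2$line_id, seg$line_id)
  pre <- rec
  pre$line_id <- rep(7L, nrow(pre))
  expect_identical(segment_lines(pre)$line_id, rep(7L, nrow(pre)))
})

test_that("line labels are invariant to stroke order up to renumbering", {
  wob <- seq(-15, 15, length.out = 8)
  mk <- function(y0, t0) {
    s <- stroke_tbl(8, t0 = t0)
    s$y <- y0 + wob
    s
  }
  a <- segment_lines(strokes_rec(list(mk(100, 0), mk(300, 1), mk(500, 2))))
  b <- segment_lines(strokes_rec(list(mk(500, 0), mk(100, 1), mk(300, 2))))
  # same grouping by construction: line of y=100 < line of y=300 < y=500
  la <- unique(a[, c("stroke_id", "line_id")])$line_id
  lb <- unique(b[, c("stroke_id", "line_id")])$line_id
  expect_equal(la, c(1L, 2L, 3L))
  expect_equal(lb, c(3L, 1L, 2L))
})

test_that("recordings round-trip through CSV and JSON files", {
  for (s in 1:5) {
    rec <- random_recording(s)
    for (dialect in c("csv", "json")) {
      path <- tempfile(fileext = paste0(".", dialect))
      write_recording(rec, path, dialect = dialect)
      back <- read_recording(path)
      for (col in c("stroke_id", "t", "x", "y", "pressure", "azimuth",
                    "altitude")) {
        expect_equal(back[[col]], rec[[col]], tolerance = 0,
                     info = paste(dialect, col))
      }
      expect_equal(rec_meta(back)[c("age", "gender", "laterality",
                                    "sampling_rate_hz")],
                   rec_meta(rec)[c("age", "gender", "laterality",
                                   "sampling_rate_hz")])
      unlink(path)
    }
  }
})

test_that("recording readers report precise parse and validation errors", {
  # malformed row names its line number
  path <- tempfile(fileext = ".csv")
  writeLines(c("# age=8", "# gender=F",
               "stroke_id,t,x,y,pressure,azimuth,altitude",
               "1,0.01,0,0,1,60,40", "1,0.02,1,0,1,60"), path)
  expect_error(read_recording(path), "line 5", class = "handscale_parse_error")
  # azimuth out of range is a validation error
  writeLines(c("# age=8", "# gender=F",
               "stroke_id,t,x,y,pressure,azimuth,altitude",
               "1,0.01,0,0,1,200,40", "1,0.02,1,0,1,200,40"), path)
  expect_error(read_recording(path), class = "handscale_validation_error")
  # minimal well-formed file: one stroke, three samples
  writeLines(c("# age=8", "# gender=M",
               "stroke_id,t,x,y,pressure,azimuth,altitude",
               "1,0.01,0,0,1,60,40", "1,0.02,1,0,1,60,40",
               "1,0.03,2,0,1,60,40"), path)
  rec <- read_recording(path)
  expect_equal(n_strokes(rec), 1L)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec_meta(rec)$gender, "M")
  # missing file is an I/O error
  expect_error(read_recording(tempfile()), class = "handscale_io_error")
  unlink(path)
})

test_that("metadata can come from a JSON sidecar", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("stroke_id,t,x,y,pressure,azimuth,altitude",
               "1,0.01,0,0,1,60,40", "1,0.02,1,0,1,60,40"), path)
  jsonlite::write_json(
    list(child_id = "c1", age = 9.5, gender = "F", laterality = "left",
         sampling_rate_hz = 60),
    paste0(path, ".meta.json"), auto_unbox = TRUE)
  rec <- read_recording(path)
  expect_equal(rec_meta(rec)$age, 9.5)
  expect_equal(rec_meta(rec)$laterality, "left")
  expect_equal(rec_meta(rec)$child_id, "c1")
  unlink(c(path, paste0(path, ".meta.json")))
})
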