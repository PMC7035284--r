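test_that("the catalogue has the canonical partition", {
  cat_tbl <- feature_catalogue()
  expect_equal(nrow(cat_tbl), 62L)
  expect_equal(sort(cat_tbl$feature_id), c(1:36, 38:63))
  counts <- table(cat_tbl$category)
  expect_equal(counts[["static"]], 12L)
  expect_equal(counts[["kinematic"]], 11L)
  expect_equal(counts[["pressure"]], 13L)
  expect_equal(counts[["tilt"]], 26L)
})

feat <- function(fv, id) fv$value[fv$feature_id == id]

test_that("straight constant-speed traces zero out straightness and velocity spread", {
  rec <- stroke_rec(x = seq(0, 599), y = 50)   # 600 evenly spaced points
  fv <- extract_features(rec)
  expect_equal(feat(fv, 1), 0)                  # barycenters share y
  expect_equal(feat(fv, 15), 0, tolerance = 1e-9)
  expect_equal(feat(fv, 16), 0, tolerance = 1e-9)
  expect_equal(feat(fv, 26), 0)                 # constant pressure
  expect_equal(feat(fv, 27), 0)
  expect_equal(feat(fv, 28), 0)
  expect_equal(feat(fv, 29), 0)
  expect_equal(feat(fv, 31), 0)
  expect_equal(feat(fv, 40), 0)                 # constant tilt
  expect_equal(feat(fv, 43), 0)
  expect_equal(feat(fv, 52), 0)
  expect_equal(feat(fv, 53), 0)
})

test_that("convex hull area and grid density match hand-computed fixtures", {
  # dense cover of the 3-4-5 triangle: hull area = 6
  pts <- expand.grid(x = seq(0, 4, by = 0.25), y = seq(0, 3, by = 0.25))
  pts <- pts[pts$y <= 3 - 0.75 * pts$x + 1e-9, ]
  rec <- stroke_rec(x = pts$x, y = 1)  # y replaced next
  rec$y <- pts$y
  fv <- static_features(rec)$values
  expect_equal(fv$value[fv$feature_id == 7], 6.0, tolerance = 1e-9)

  # 7 points in one 20-px cell, 3 in another: mean count 5
  xs <- c(seq(0, 15, length.out = 7), c(25, 28, 31))
  rec2 <- stroke_rec(x = xs, y = 5)
  fv2 <- static_features(rec2)$values
  expect_equal(fv2$value[fv2$feature_id == 4], 5.0)
})

test_that("pen-lift features follow the stroke geometry", {
  # two 1-second strokes separated by a 1-second gap: in-air ratio 1/3
  s1 <- stroke_tbl(61, t0 = 0, dt = 1 / 60)       # spans 1 s
  s2 <- stroke_tbl(61, t0 = 1 + 1 / 60, dt = 1 / 60, x0 = 100)
  s2$t <- seq(2 + 1 / 60, by = 1 / 60, length.out = 61)
  rec <- strokes_rec(list(s1, s2))
  fv <- kinematic_features(rec)$values
  expect_equal(fv$value[fv$feature_id == 23], 1 / 3, tolerance = 1e-9)
  # single stroke: ratio 0 and stroke distance 0
  rec1 <- stroke_rec(x = 1:30, y = 0)
  fv1 <- extract_features(rec1)
  expect_equal(feat(fv1, 23), 0)
  expect_equal(feat(fv1, 3), 0)
  # space between strokes: last sample of stroke 1 to first of stroke 2
  d <- sqrt((s2$x[1] - s1$x[61])^2 + (s2$y[1] - s1$y[61])^2)
  fvs <- static_features(rec)$values
  expect_equal(fvs$value[fvs$feature_id == 3], d, tolerance = 1e-9)
})

test_that("velocity peaks per second match a brute-force count on the fixture", {
  # triangular-wave speed with 4 extrema over a 2-second stroke
  v <- c(10, 20, 30, 20, 10, 20, 30, 20, 10, 20, 30)
  dt <- 2 / length(v)
  x <- cumsum(c(0, v * dt))
  tt <- dt * seq_along(x)
  rec <- stroke_rec(x = x, y = 0, t = tt)
  fv <- kinematic_features(rec)$values
  # independent oracle: direct convolution with the window, loop count
  w <- exp(-0.5 * abs(c(-1, 0, 1) / 2)^(2 * 0.5)); w <- w / sum(w)
  vp <- c(v[2], v, v[length(v) - 1])
  sm <- vapply(seq_along(v), function(i) sum(w * vp[i:(i + 2)]), numeric(1))
  peaks <- 0
  d <- diff(sm); d <- d[d != 0]
  for (i in seq_len(length(d) - 1)) {
    if (sign(d[i]) != sign(d[i + 1])) peaks <- peaks + 1
  }
  expect_equal(peaks, 4)
  dur <- max(tt) - min(tt)
  expect_equal(fv$value[fv$feature_id == 17], peaks / dur)
  expect_equal(fv$value[fv$feature_id == 17], 2.0, tolerance = 1e-9)
})

test_that("pressure rate features have their closed forms on ramps and zigzags", {
  # linear ramp a + b*t: mean rate |b|, rate slope 0
  b <- 0.4
  s <- stroke_tbl(60, dt = 1 / 60)
  s$pressure <- 0.5 + b * s$t
  rec <- strokes_rec(list(s))
  fv <- pressure_features(rec)$values
  expect_equal(fv$value[fv$feature_id == 27], b, tolerance = 1e-9)
  expect_equal(fv$value[fv$feature_id == 28], b, tolerance = 1e-9)
  expect_equal(fv$value[fv$feature_id == 29], 0, tolerance = 1e-9)
  expect_equal(fv$value[fv$feature_id == 30], 0, tolerance = 1e-9)

  # alternating pressure: 6 inversions over 2 seconds -> 3 per second
  p <- rep_len(c(1, 2), 8)
  tt <- seq(0, 2, length.out = 8)
  s2 <- stroke_tbl(8)
  s2$t <- tt; s2$pressure <- p
  rec2 <- strokes_rec(list(s2))
  fv2 <- pressure_features(rec2)$values
  expect_equal(fv2$value[fv2$feature_id == 31], 3.0)
})

test_that("tilt features mirror the pressure machinery per channel", {
  b <- 2
  s <- stroke_tbl(60, dt = 1 / 60)
  s$azimuth <- 30 + b * s$t
  rec <- strokes_rec(list(s))
  fv <- tilt_features(rec)$values
  expect_equal(fv$value[fv$feature_id == 44], b, tolerance = 1e-9)
  expect_equal(fv$value[fv$feature_id == 50], 0, tolerance = 1e-9)

  # swapping the azimuth and altitude series swaps the two feature blocks
  rec_sw <- rec
  az <- rec_sw$azimuth
  rec_sw$azimuth <- rec_sw$altitude
  rec_sw$altitude <- az
  a <- tilt_features(rec)$values
  bsw <- tilt_features(rec_sw)$values
  block_az <- c(38:40, 44:46, 50, 52, 54:58)
  block_al <- c(41:43, 47:49, 51, 53, 59:63)
  expect_equal(a$value[match(block_az, a$feature_id)],
               bsw$value[match(block_al, bsw$feature_id)])
  expect_equal(a$flag[match(block_az, a$feature_id)],
               bsw$flag[match(block_al, bsw$feature_id)])
})

test_that("extract_features returns the exact catalogue with honest flags", {
  rec <- simulate_recording(age = 9, gender = "M", seed = 11,
                            duration_s = 115)
  ex <- extract_cohort(list(rec, simulate_recording(8, "F", seed = 12,
                                                    duration_s = 115)))
  vals <- as.numeric(unlist(ex$cohort[1, grep("^f_", names(ex$cohort))]))
  expect_length(vals, 62L)
  expect_true(all(is.finite(vals)))

  # a 10-sample recording still yields scalar features, flags the rest
  tiny <- stroke_rec(x = cumsum(runif(10, 0.5, 1.5)), y = 0)
  fv <- extract_features(tiny)
  expect_true(all(fv$flag[fv$feature_id %in% c(8:12, 18:22, 32:36)] ==
                    "insufficient_data"))
  expect_true(all(is.finite(fv$value[fv$feature_id %in% c(13, 14, 15, 23,
                                                          24, 25, 26)])))
  # category filter returns exactly the pressure block
  pv <- extract_features(tiny, categories = "pressure")
  expect_equal(sort(pv$feature_id), 24:36)
})

test_that("all features are translation invariant", {
  rec <- simulate_recording(age = 8, gender = "F", seed = 3,
                            duration_s = 115)
  fv <- extract_features(rec)
  ref <- attr(fv, "spectra")   # compare both writers against the same refs
  fv <- extract_features(rec, ref_spectra = ref)
  shifted <- rec
  shifted$x <- shifted$x + 137
  shifted$y <- shifted$y + 519
  fv2 <- extract_features(shifted, ref_spectra = ref)
  expect_equal(fv2$value, fv$value, tolerance = 1e-8)
})

test_that("time-unit covariance scales velocity and per-second features exactly", {
  rec <- stroke_rec(x = cumsum(runif(200, 0.5, 2)), y = 0,
                    pressure = runif(200, 0.5, 1.5))
  ms <- rec
  ms$t <- ms$t * 1000
  f1 <- extract_features(rec)
  f2 <- extract_features(ms)
  for (id in c(13, 14, 15)) {            # velocity rescales by the unit
    expect_equal(feat(f2, id), feat(f1, id) / 1000, tolerance = 1e-9)
  }
  for (id in c(17, 27, 28, 31)) {        # rates and per-second counts too
    expect_equal(feat(f2, id), feat(f1, id) / 1000, tolerance = 1e-9)
  }
  expect_equal(feat(f2, 23), feat(f1, 23))   # ratios are dimensionless
})
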