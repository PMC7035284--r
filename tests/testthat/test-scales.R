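test_that("fit_scale recovers planted populations and matches an eigen oracle", {
  fids <- c(13:17, 24:28)   # kinematic + pressure block
  cohort <- gaussian_cohort(200, 50, fids, shift_ids = 13:17, shift = 6,
                            seed = 42)
  norms <- identity_norms(fids)
  sc <- fit_scale(cohort, norms, "total", seed = 11)
  ev <- evaluate_clustering(sc)
  expect_gte(ev$sensitivity, 0.95)
  expect_gte(ev$specificity, 0.95)

  # axes orthonormal
  gram <- t(sc$axes) %*% sc$axes
  expect_equal(gram, diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  # variance fractions non-increasing, in [0, 1], summing <= 1
  evf <- sc$explained_variance_fractions
  expect_true(all(diff(evf) <= 1e-12))
  expect_true(all(evf >= 0 & evf <= 1))
  expect_lte(sum(evf), 1 + 1e-9)
  expect_gt(sc$d_ref, 0)
})

test_that("PCA axes match a brute-force eigendecomposition on a toy table", {
  fids <- c(1, 13, 24, 38, 39)
  cohort <- gaussian_cohort(60, 0, fids, seed = 9)
  # plant correlation so the axes are distinct
  cohort$f_13 <- cohort$f_1 * 0.8 + cohort$f_13 * 0.6
  norms <- identity_norms(fids)
  sc <- fit_scale(cohort, norms, "total", seed = 2)

  # oracle: eigendecomposition of the covariance of the standardized input
  x <- as.matrix(cohort[paste0("f_", fids)])
  xs <- sweep(sweep(x, 2, colMeans(x)), 2, apply(x, 2, sd), `/`)
  eig <- eigen(stats::cov(xs), symmetric = TRUE)
  evf_oracle <- eig$values / sum(eig$values)
  expect_equal(sc$explained_variance_fractions, evf_oracle[1:3],
               tolerance = 1e-6)
  for (a in 1:3) {   # loadings equal up to sign
    expect_equal(abs(sc$axes[, a]), abs(eig$vectors[, a]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("degenerate cohorts are refused", {
  fids <- 13:17
  cohort <- gaussian_cohort(60, 0, fids, seed = 1)
  for (f in paste0("f_", fids)) cohort[[f]] <- 1.0   # identical children
  expect_error(fit_scale(cohort, identity_norms(fids), "total"),
               class = "handscale_degenerate")
  # too few features in a category
  small <- gaussian_cohort(60, 0, c(13, 14), seed = 2)
  expect_error(fit_scale(small, identity_norms(c(13, 14)), "total"),
               class = "handscale_validation_error")
  # too few school children
  few <- gaussian_cohort(5, 40, fids, seed = 3)
  expect_error(fit_scale(few, identity_norms(fids), "total"),
               class = "handscale_validation_error")
})

test_that("projection is linear in the standardized deviations", {
  fids <- c(13, 14, 15, 16)
  sc <- onehot_scale(fids)
  norms <- identity_norms(fids)
  # child exactly at every norm projects to the origin
  at_norm <- tibble::tibble(feature_id = fids, value = 0)
  expect_equal(project(at_norm, 8, "F", sc, norms), c(0, 0, 0))
  # one active feature at +2 SD on a one-hot axis
  dev2 <- tibble::tibble(feature_id = fids, value = c(2, 0, 0, 0))
  expect_equal(project(dev2, 8, "F", sc, norms), c(2, 0, 0))
  # Bessel: projection norm never exceeds the standardized-input norm
  for (s in 1:10) {
    v <- withr::with_seed(s, rnorm(4))
    p <- project(tibble::tibble(feature_id = fids, value = v), 8, "F",
                 sc, norms)
    expect_lte(sqrt(sum(p^2)), sqrt(sum(v^2)) + 1e-12)
  }
  # missing features are reported by id
  expect_error(
    project(tibble::tibble(feature_id = fids, value = c(1, NA, 0, 0)),
            8, "F", sc, norms),
    "14", class = "handscale_validation_error")
})

test_that("the centroid-distance score has its closed forms", {
  fids <- c(13, 14, 15, 16)
  sc <- onehot_scale(fids, d_ref = 2)
  norms <- identity_norms(fids)
  at_centroid <- tibble::tibble(feature_id = fids, value = 0)
  expect_equal(global_score(at_centroid, 8, "F", sc, norms), 1.0)
  # at exactly d_ref: score exp(-1)
  at_dref <- tibble::tibble(feature_id = fids, value = c(2, 0, 0, 0))
  expect_equal(global_score(at_dref, 8, "F", sc, norms), exp(-1))
  # moving radially outward never increases the score
  for (s in 1:5) {
    dir <- withr::with_seed(s, rnorm(3))
    dir <- dir / sqrt(sum(dir^2))
    scores <- vapply(seq(0.2, 5, by = 0.4), function(r) {
      v <- c(r * dir, 0)
      global_score(tibble::tibble(feature_id = fids, value = v), 8, "F",
                   sc, norms)
    }, numeric(1))
    expect_true(all(diff(scores) < 0))
  }
})

test_that("threshold ranks hit the exact reference fractions", {
  scores <- withr::with_seed(1, runif(1000))
  th <- threshold_from_quantiles(scores)
  expect_equal(sum(scores <= th[["vs"]]), 20L)
  expect_equal(sum(scores <= th[["s"]]), 86L)
  expect_equal(sum(scores <= th[["m"]]), 150L)
  expect_equal(sum(scores <= th[["l"]]), 250L)
  expect_true(all(diff(th) > 0))

  # 1..100: the very-severe threshold is the 2nd smallest value
  th2 <- threshold_from_quantiles(as.numeric(1:100))
  expect_equal(th2[["vs"]], 2)

  # duplicate-heavy input: realized fractions can only exceed nominal
  dup <- rep(seq(0.1, 1, by = 0.1), each = 10)
  th3 <- tryCatch(threshold_from_quantiles(dup), condition = function(c) NULL)
  if (!is.null(th3)) {
    realized <- vapply(th3, function(t) mean(dup <= t), numeric(1))
    expect_true(all(realized >= c(0.02, 0.086, 0.15, 0.25)))
  }

  expect_error(threshold_from_quantiles(scores, c(vs = 0.2, s = 0.1,
                                                  m = 0.3, l = 0.4)),
               class = "handscale_validation_error")
  expect_error(threshold_from_quantiles(runif(10)),
               class = "handscale_validation_error")
})

test_that("categorize partitions (0, 1] into the five ordered severities", {
  th <- c(vs = 0.1, s = 0.2, m = 0.3, l = 0.4)
  expect_equal(categorize(0.05, th), "very_severe")
  expect_equal(categorize(1.0, th), "typical")
  grid <- seq(0.01, 1, by = 0.01)
  cats <- categorize(grid, th)
  expect_setequal(unique(cats), c("very_severe", "severe", "moderate",
                                  "light", "typical"))
  # ordered: severity only relaxes as the score grows
  lev <- c("very_severe", "severe", "moderate", "light", "typical")
  expect_true(all(diff(match(cats, lev)) >= 0))
})

test_that("axis importance sums to one per axis and spots one-hot loadings", {
  fids <- c(13, 24, 38, 1)   # one feature per category
  sc <- onehot_scale(fids)
  imp <- axis_importance(sc)
  shares <- imp$category_shares
  for (a in 1:3) {
    expect_equal(sum(shares$share[shares$axis == a]), 1, tolerance = 1e-9)
  }
  # axis 1 loads only f_13 (kinematic): share 1
  expect_equal(shares$share[shares$axis == 1 & shares$category ==
                              "kinematic"], 1)
  # equal |loading| on one feature per category: shares 0.25 each
  sc$axes <- matrix(0.5, 4, 3)
  imp2 <- axis_importance(sc)
  expect_true(all(abs(imp2$category_shares$share - 0.25) < 1e-12))
})

test_that("profiles combine global, category and feature scores coherently", {
  cats <- c("total", "static", "kinematic", "pressure", "tilt")
  fids <- list(total = c(1, 13, 24, 38), static = c(1, 2, 4, 6),
               kinematic = 13:16, pressure = 24:27, tilt = 38:41)
  scales <- setNames(lapply(cats, function(ct)
    onehot_scale(fids[[ct]], category = ct)), cats)
  all_ids <- sort(unique(unlist(fids)))
  norms <- identity_norms(all_ids)

  at_norm <- tibble::tibble(feature_id = all_ids, value = 0)
  p <- profile(at_norm, 8, "F", scales, norms, child_id = "kid1")
  expect_equal(p$global_score, 1.0)
  expect_true(all(unlist(p$category_scores) == 1.0))
  expect_equal(p$severity, "typical")
  expect_true(all(p$feature_scores$score == 1.0))

  # deviant only in pressure: pressure sub-score drops the most
  dev <- at_norm
  dev$value[dev$feature_id %in% 24:27] <- 3
  p2 <- profile(dev, 8, "F", scales, norms, child_id = "kid2")
  expect_lt(p2$category_scores$pressure,
            min(p2$category_scores$static, p2$category_scores$kinematic,
                p2$category_scores$tilt))
  expect_lt(p2$global_score, 1.0)

  # JSON round trip
  path <- tempfile(fileext = ".json")
  write_profile(p2, path)
  back <- read_profile(path)
  expect_equal(back$global_score, p2$global_score, tolerance = 1e-12)
  expect_equal(back$severity, p2$severity)
  expect_equal(unlist(back$category_scores), unlist(p2$category_scores),
               tolerance = 1e-12)
  unlink(path)

  # missing scale errors
  expect_error(profile(at_norm, 8, "F", scales[-1], norms),
               class = "handscale_validation_error")
})

test_that("cluster evaluation reproduces the printed contingency arithmetic", {
  # perfect separation
  ev <- evaluate_clustering(rep(c("atypical", "typical"), c(10, 20)),
                            rep(c("dysgraphic", "school"), c(10, 20)))
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 1.0)
  # 58 dysgraphic children, 5 in the wrong cluster: sensitivity 53/58
  assign58 <- rep(c("atypical", "typical"), c(53, 5))
  ev2 <- evaluate_clustering(c(assign58, rep("typical", 100)),
                             c(rep("dysgraphic", 58), rep("school", 100)))
  expect_equal(ev2$sensitivity, 53 / 58, tolerance = 1e-12)
  expect_equal(round(ev2$sensitivity, 2), 0.91)
  # random balanced assignment: both near 0.5
  n <- 4000
  lab <- rep(c("dysgraphic", "school"), each = n / 2)
  asg <- withr::with_seed(7, sample(c("typical", "atypical"), n,
                                    replace = TRUE))
  ev3 <- evaluate_clustering(asg, lab)
  expect_lt(abs(ev3$sensitivity - 0.5), 0.05)
  expect_lt(abs(ev3$specificity - 0.5), 0.05)
  # one label absent
  expect_error(evaluate_clustering(rep("typical", 5), rep("school", 5)),
               class = "handscale_validation_error")
})

test_that("a deviation planted in one category separates best on that sub-scale", {
  all_ids <- feature_catalogue()$feature_id
  cohort <- gaussian_cohort(150, 40, all_ids,
                            shift_ids = feature_catalogue("kinematic")$feature_id,
                            shift = 5, seed = 21)
  norms <- identity_norms(all_ids)
  scs <- fit_scales(cohort, norms, seed = 5)
  sens <- vapply(c("kinematic", "pressure", "tilt", "static"), function(ct)
    evaluate_clustering(scs[[ct]])$sensitivity, numeric(1))
  expect_gte(sens[["kinematic"]], 0.9)
  expect_true(all(sens[["kinematic"]] >= sens))
})

test_that("scale models survive a JSON round trip", {
  fids <- c(13:17, 24:28)
  cohort <- gaussian_cohort(100, 30, fids, shift_ids = 13:17, shift = 6,
                            seed = 8)
  sc <- fit_scale(cohort, identity_norms(fids), "total", seed = 3)
  path <- tempfile(fileext = ".json")
  write_scale_model(sc, path)
  back <- read_scale_model(path)
  expect_equal(back$axes, unname(sc$axes), tolerance = 1e-12)
  expect_equal(back$centroid_typical, unname(sc$centroid_typical),
               tolerance = 1e-12)
  expect_equal(back$d_ref, sc$d_ref, tolerance = 1e-12)
  expect_equal(back$thresholds, sc$thresholds, tolerance = 1e-12)
  # scoring with the reloaded model is identical
  norms <- identity_norms(fids)
  s1 <- score_cohort(cohort, sc, norms)
  s2 <- score_cohort(cohort, back, norms)
  expect_equal(s2$score, s1$score, tolerance = 1e-12)
  unlink(path)
})
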