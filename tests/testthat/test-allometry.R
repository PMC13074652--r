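make_segment_record <- function(basal = 20, main = 20, left = 20, right = 20,
                                main_len = 10, left_len = 0, right_len = 0) {
  data.frame(
    year = 2021L, season = "spring", cultivar = "c", treatment = "CT",
    dat = 100L, pruning = 0L, plant_height = 100,
    basal_stem_diam = basal, main_stem_diam = main,
    left_stem_diam = left, right_stem_diam = right,
    main_stem_len = main_len, left_stem_len = left_len, right_stem_len = right_len,
    shoot_fw = 1, fruit_fw = 0, is_synthetic = FALSE, source_group = "",
    stringsAsFactors = FALSE
  )
}

test_that("cylinder and cone volumes match hand arithmetic", {
  # single 10 cm segment of diameter 2 cm (20 mm): V = pi r^2 L = 10 pi
  rec <- make_segment_record()
  expect_equal(plant_volume(rec, "cylinder"), 10 * pi, tolerance = 1e-12)
  # equal radii: truncated cone degenerates to the cylinder
  expect_equal(plant_volume(rec, "truncated_cone"), 10 * pi, tolerance = 1e-12)
  # r1 = 0.6, r2 = 0.4, L = 30 -> (pi 30 / 3)(0.36 + 0.24 + 0.16) = 7.6 pi
  rec2 <- make_segment_record(basal = 12, main = 8, main_len = 30)
  expect_equal(plant_volume(rec2, "truncated_cone"), 7.6 * pi, tolerance = 1e-12)
  # stick is the summed segment lengths; height mode uses plant height
  rec3 <- make_segment_record(main_len = 10, left_len = 20, right_len = 30)
  expect_equal(plant_volume(rec3, "stick"), 60)
  expect_equal(plant_volume(rec3, "stick", stick_mode = "height"), 100)
})

test_that("cone reduces to cylinder for equal radii and grows with length", {
  set.seed(41)
  for (i in 1:1000) {
    d <- runif(1, 2, 40)
    L <- runif(3, 0, 200)
    rec <- make_segment_record(basal = d, main = d, left = d, right = d,
                               main_len = L[1], left_len = L[2], right_len = L[3])
    expect_equal(plant_volume(rec, "truncated_cone"), plant_volume(rec, "cylinder"),
                 tolerance = 1e-9)
  }
  # monotone in each segment length
  set.seed(42)
  for (i in 1:50) {
    d <- runif(4, 2, 40)
    L <- runif(3, 0, 200)
    rec <- make_segment_record(d[1], d[2], d[3], d[4], L[1], L[2], L[3])
    rec_up <- make_segment_record(d[1], d[2], d[3], d[4], L[1] + 5, L[2], L[3])
    for (g in c("stick", "cylinder", "truncated_cone")) {
      expect_gte(plant_volume(rec_up, g), plant_volume(rec, g))
    }
  }
})

test_that("volume validation rejects impossible measurements", {
  rec <- make_segment_record(main = -1)
  expect_error(plant_volume(rec, "cylinder"), "positive")
  rec2 <- make_segment_record(main_len = -5)
  expect_error(plant_volume(rec2, "stick"), "non-negative")
})

test_that("the linear fit is exact on exact lines", {
  f <- fit_allometric(c(1, 2), c(3, 5), "linear")
  expect_equal(unname(f$coef), c(2, 1), tolerance = 1e-12)
  # constant FW
  f2 <- fit_allometric(1:10, rep(7, 10), "linear")
  expect_equal(unname(f2$coef["alpha"]), 0, tolerance = 1e-12)
  expect_equal(unname(f2$coef["beta"]), 7, tolerance = 1e-12)
  # 50 noiseless points
  V <- seq(0, 10, length.out = 50)
  f3 <- fit_allometric(V, 2.5 * V + 10, "linear")
  expect_equal(unname(f3$coef), c(2.5, 10), tolerance = 1e-9)
  expect_error(fit_allometric(rep(1, 5), 1:5, "linear"), "degenerate")
})

test_that("noiseless sigmoid data is recovered to near machine precision", {
  V <- seq(0, 400, length.out = 60)
  truth <- c(L = 2000, k = 0.05, V0 = 150)
  FW <- truth["L"] / (1 + exp(-truth["k"] * (V - truth["V0"])))
  f <- fit_allometric(V, FW, "sigmoid")
  expect_false(f$fallback_used)
  expect_lt(max(abs(f$coef - truth) / truth), 1e-6)
  # inflection identity: prediction at V0 is L/2
  expect_equal(predict(f, f$coef[["V0"]]), f$coef[["L"]] / 2, tolerance = 1e-9)
})

test_that("sigmoid recovery under 5% noise has median relative error below 5%", {
  V <- seq(5, 400, length.out = 100)
  truth <- c(L = 2000, k = 0.05, V0 = 150)
  mu <- truth["L"] / (1 + exp(-truth["k"] * (V - truth["V0"])))
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    FW <- mu * exp(rnorm(100, 0, sqrt(log(1 + 0.05^2))))
    f <- fit_allometric(V, FW, "sigmoid")
    max(abs(f$coef[names(truth)] - truth) / truth)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("sigmoid predictions stay in (0, L) and are symmetric about the inflection", {
  V <- seq(0, 400, length.out = 60)
  FW <- 1500 / (1 + exp(-0.03 * (V - 180)))
  f <- fit_allometric(V, FW, "sigmoid")
  grid <- seq(-500, 900, length.out = 201)
  p <- predict(f, grid)
  expect_true(all(p > 0 & p < f$coef[["L"]]))
  d <- seq(0, 300, length.out = 31)
  expect_equal(
    predict(f, f$coef[["V0"]] + d) + predict(f, f$coef[["V0"]] - d),
    rep(f$coef[["L"]], length(d)), tolerance = 1e-8
  )
})

test_that("an unstable sigmoid fit falls back to the linear model", {
  set.seed(3)
  V <- 1:50
  FW <- pmax(100 - 1.5 * V + rnorm(50), 1) # monotonically decreasing
  f <- fit_allometric(V, FW, "sigmoid")
  expect_true(f$fallback_used)
  expect_equal(f$form, "linear")
  expect_error(fit_allometric(1:3, c(1, 2, 3), "sigmoid"), "4 points")
})

test_that("cross-validated allometry ranks stick above cylinder for shoot FW", {
  recs <- pf_default_records()
  plan <- make_fold_plan(recs, seed = 31)
  tab <- evaluate_allometric(recs, plan, targets = "shoot_fw")
  sm <- summarize_metrics(tab)
  stick <- sm$r2_mean[sm$geometry == "stick" & sm$form == "sigmoid"]
  cyl <- sm$r2_mean[sm$geometry == "cylinder" & sm$form == "sigmoid"]
  expect_gt(stick, cyl)
  # perfect and mean predictors pin down the metric definitions
  y <- recs$shoot_fw
  expect_equal(r2(y, y), 1)
  expect_equal(rmse(y, y), 0)
  expect_equal(r2(y, rep(mean(y), length(y))), 0, tolerance = 1e-12)
})
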