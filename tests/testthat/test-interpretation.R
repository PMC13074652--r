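test_that("sampled Shapley values recover the closed form for an additive model", {
  set.seed(3)
  f <- function(X) 2 * X[, 1] + 3 * X[, 2] + 0 * X[, 3]
  bg <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, paste0("x", 1:3)))
  xe <- matrix(c(1.5, -0.5, 2), 1, 3, dimnames = list(NULL, paste0("x", 1:3)))
  s <- shapley_attribution(f, xe, bg, n_permutations = 2000, seed = 4)
  expected <- c(2 * (1.5 - mean(bg[, 1])), 3 * (-0.5 - mean(bg[, 2])), 0)
  expect_equal(unname(s$attributions[1, ]), expected, tolerance = 0.02)
  # dummy feature gets zero attribution
  expect_equal(unname(s$attributions[1, 3]), 0, tolerance = 1e-10)
})

test_that("Shapley efficiency holds exactly for exhaustive and sampled estimators", {
  set.seed(5)
  f <- function(X) X[, 1] * X[, 2] + exp(X[, 3] / 4) - 0.5 * X[, 4]
  bg <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  xe <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("x", 1:4)))
  ex <- shapley_attribution(f, xe, bg, exact = TRUE)
  expect_equal(ex$baseline + rowSums(ex$attributions), unname(f(xe)), tolerance = 1e-10)
  sm <- shapley_attribution(f, xe, bg, n_permutations = 25, seed = 6)
  # the telescoping permutation form is exactly efficient too
  expect_equal(sm$baseline + rowSums(sm$attributions), unname(f(xe)), tolerance = 1e-10)
  # and within 2% of the prediction scale at 200 permutations by spec of the estimator
  sm200 <- shapley_attribution(f, xe, bg, n_permutations = 200, seed = 6)
  expect_lt(
    max(abs(sm200$baseline + rowSums(sm200$attributions) - f(xe))),
    0.02 * max(abs(f(xe)))
  )
})

test_that("sampled estimates converge to the exhaustive oracle", {
  set.seed(7)
  f <- function(X) X[, 1]^2 + X[, 1] * X[, 2] - X[, 3]
  bg <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, paste0("x", 1:3)))
  xe <- matrix(c(1, -1, 0.5), 1, 3, dimnames = list(NULL, paste0("x", 1:3)))
  oracle <- shapley_attribution(f, xe, bg, exact = TRUE)
  est <- shapley_attribution(f, xe, bg, n_permutations = 2000, seed = 8)
  expect_equal(est$attributions, oracle$attributions, tolerance = 0.05)
  # symmetry: identical columns receive equal attributions
  g <- function(X) X[, 1] + X[, 2]
  xs <- matrix(c(1, 1, 0), 1, 3, dimnames = list(NULL, paste0("x", 1:3)))
  bgs <- cbind(x1 = rnorm(50), x2 = 0, x3 = rnorm(50))
  bgs[, 2] <- bgs[, 1]
  ss <- shapley_attribution(g, xs, bgs, n_permutations = 500, seed = 9)
  expect_equal(unname(ss$attributions[1, "x1"]), unname(ss$attributions[1, "x2"]),
               tolerance = 0.05)
  expect_error(shapley_attribution(g, xs, bgs, n_permutations = 0), "n_permutations")
  expect_error(shapley_attribution(g, xs, bgs[0, , drop = FALSE]), "non-empty")
})

test_that("identical observation and background give zero attributions", {
  f <- function(X) X[, 1] - 2 * X[, 2]
  x <- matrix(c(1, 2), 1, 2, dimnames = list(NULL, c("x1", "x2")))
  s <- shapley_attribution(f, x, x, n_permutations = 10, seed = 1)
  expect_equal(unname(s$attributions[1, ]), c(0, 0))
})

test_that("removing a duplicated or constant group leaves R^2 unchanged", {
  # a generator where fruit FW is a pure DAT curve: basic group carries no
  # information beyond what structure already encodes
  recs <- generate_dataset(sim_config(design = pf_small_design(), seed = 16))
  plan <- make_fold_plan(recs, k = 5, repeats = 1, seed = 3)
  # management variables are nearly constant here: ablating them is ~ a no-op
  row <- ablate_group(recs, "management", "fruit_fw", plan,
                      models = c("gbm_leaf", "ensemble"), seed = 4)
  expect_lt(abs(row$delta_r2), 0.02)
  expect_error(ablate_group(recs, "bogus", "fruit_fw", plan), "unknown feature group")
})

test_that("the importance report combines both analyses and flags missing attributions", {
  abl <- data.frame(
    group = c("basic", "structural", "temporal", "management"),
    target = "fruit_fw", r2_full = 0.9,
    r2_reduced = c(0.88, 0.85, 0.60, 0.89),
    delta_r2 = c(0.02, 0.05, 0.30, 0.01)
  )
  rep0 <- importance_report(abl)
  expect_false(rep0$has_attribution)
  expect_null(rep0$shap_ranking)

  f <- function(X) X[, 1]
  bg <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("dat", "pruning")))
  s <- shapley_attribution(f, bg[1:3, ], bg, n_permutations = 20, seed = 2)
  rep1 <- importance_report(abl, list(fruit_fw = s))
  expect_true(rep1$has_attribution)
  expect_equal(names(rep1$shap_ranking$fruit_fw)[1], "dat")
  expect_setequal(unique(rep1$beeswarm$fruit_fw$feature), c("dat", "pruning"))
})

test_that("one-hot treatment attributions collapse into a single factor", {
  set.seed(10)
  cols <- c("dat", paste0("treatment_", c("CT", "RB", "FR")))
  bg <- cbind(rnorm(30), diag(3)[sample(1:3, 30, TRUE), ])
  colnames(bg) <- cols
  f <- function(X) X[, 1] + X[, 2] - X[, 4]
  s <- shapley_attribution(f, bg[1:2, ], bg, n_permutations = 50, seed = 11)
  summ <- shap_summary(s)
  expect_true("treatment" %in% names(summ))
  expect_false(any(grepl("treatment_", names(summ))))
})
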