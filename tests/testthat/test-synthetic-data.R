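test_that("the experimental design table matches the printed study design", {
  d <- design_from_table1()
  expect_equal(sum(d$n), 303)
  expect_equal(nrow(d), 36)
  expect_equal(d$n[d$year == 2020 & d$season == "spring" & d$treatment == "CT" & d$dat == 133], 20)
  expect_equal(d$n[d$year == 2021 & d$season == "winter" & d$treatment == "FR" & d$dat == 150], 36)
  # one plant slot per design row unit
  expect_true(all(d$n >= 1))
})

test_that("generator output matches the design exactly and has valid records", {
  recs <- pf_default_records()
  expect_equal(nrow(recs), 303)
  expect_silent(validate_records(recs))
  expect_false(any(recs$is_synthetic))
  # group keys of every record appear in the design
  d <- design_from_table1()
  got <- table(paste(recs$season, recs$treatment, recs$dat))
  want <- tapply(d$n, paste(d$season, d$treatment, d$dat), sum)
  expect_equal(as.vector(got[names(want)]), as.vector(want))
})

test_that("generation is deterministic given the seed", {
  a <- generate_dataset(sim_config(seed = 7))
  b <- generate_dataset(sim_config(seed = 7))
  expect_identical(a, b)
  c <- generate_dataset(sim_config(seed = 8))
  expect_false(identical(a, c))
})

test_that("noise-free traits hit the logistic midpoint identity", {
  cfg <- pf_clean_config()
  cfg$design <- data.frame(
    year = 2021L, season = "spring", cultivar = "Mavera", treatment = "CT",
    dat = 75L, n = 1L, stringsAsFactors = FALSE # DAT at the trait midpoint
  )
  rec <- generate_dataset(cfg)
  for (tr in c("basal_stem_diam", "main_stem_len", "left_stem_len")) {
    expect_equal(rec[[tr]], cfg$traits[[tr]]$asym / 2, tolerance = 1e-12)
  }
})

test_that("noise-free shoot FW is an exact sigmoid of stick volume", {
  recs <- generate_dataset(pf_clean_config())
  v <- plant_volume(recs, "stick")
  sl <- pf_clean_config()$shoot_link
  expect_equal(recs$shoot_fw, sl$L / (1 + exp(-sl$k * (v - sl$V0))), tolerance = 1e-12)
})

test_that("fruit FW is cumulative: zero before onset, non-decreasing in DAT", {
  cfg <- pf_clean_config()
  cfg$design <- data.frame(
    year = 2021L, season = "spring", cultivar = "Mavera", treatment = "CT",
    dat = seq(10L, 160L, by = 10L), n = 1L, stringsAsFactors = FALSE
  )
  rec <- generate_dataset(cfg)
  expect_true(all(rec$fruit_fw[rec$dat < cfg$fruit_link$onset] == 0))
  expect_true(all(diff(rec$fruit_fw[order(rec$dat)]) >= 0))
})

test_that("the generated correlations favor structure for shoot and time for fruit", {
  recs <- pf_default_records()
  stick <- recs$main_stem_len + recs$left_stem_len + recs$right_stem_len
  expect_gt(cor(recs$shoot_fw, stick), cor(recs$shoot_fw, recs$dat))
  trait_cors <- vapply(
    c("plant_height", "basal_stem_diam", "main_stem_diam", "left_stem_diam",
      "right_stem_diam", "main_stem_len", "left_stem_len", "right_stem_len"),
    function(f) cor(recs$fruit_fw, recs[[f]]), numeric(1)
  )
  expect_true(all(cor(recs$fruit_fw, recs$dat) > trait_cors))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(cv_traits = -1), "cv_traits")
  expect_error(sim_config(pruning_prob = 2), "pruning_prob")
  d <- design_from_table1()
  d$n[1] <- 0L
  expect_error(sim_config(design = d), "design")
})

test_that("CSV round trip is lossless and schema violations are named", {
  recs <- pf_default_records()
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(recs, path)
  back <- read_records(path)
  expect_equal(back, recs)

  # missing column
  broken <- recs
  broken$dat <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(broken, path2, row.names = FALSE)
  expect_error(read_records(path2), "dat")

  # unknown treatment level lists the allowed set
  bad <- recs
  bad$treatment[1] <- "XX"
  expect_error(validate_records(bad), "CT, RB, FR")

  # unknown column rejected
  extra <- recs
  extra$bogus <- 1
  expect_error(validate_records(extra), "bogus")
})
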