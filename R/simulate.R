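#' Configuration for the synthetic plant-record generator
#'
#' Builds the parameter set driving [generate_dataset()]. The defaults encode
#' the generative assumptions of the package's synthetic stand-in for the
#' greenhouse measurements: per-trait logistic growth in days after
#' transplanting (DAT), a sigmoid allometric link from summed stem length
#' ("stick volume") to shoot fresh weight, a DAT-dominated cumulative
#' logistic for harvested fruit fresh weight with a small structural
#' modulation, small multiplicative management effects, and multiplicative
#' lognormal noise.
#'
#' @param design data.frame of design rows (`year`, `season`, `cultivar`,
#'   `treatment`, `dat`, `n`); defaults to [design_from_table1()].
#' @param traits named list of logistic growth parameters per trait, each a
#'   list with `asym` (asymptote, trait units), `rate` (1/day) and `mid`
#'   (DAT at half asymptote). Diameters are in mm, segment lengths in cm.
#' @param canopy_offset cm added on top of the stem segments to form plant
#'   height.
#' @param shoot_link sigmoid link from stick volume V (cm) to shoot FW (g):
#'   list with `L` (asymptotic FW, g), `k` (per cm), `V0` (inflection, cm).
#' @param fruit_link cumulative fruit FW curve in DAT: list with `L` (g),
#'   `k` (per day), `mid` (DAT), `onset` (first fruiting DAT; fruit FW is 0
#'   before it).
#' @param struct_weight weight of the structural modulation of fruit FW
#'   (relative stick-volume deviation from its DAT expectation).
#' @param treatment_effects named list per treatment of multiplicative
#'   effects on `shoot` and `fruit`.
#' @param pruning_prob probability that a plant's main stem was pruned.
#' @param pruning_effect multiplicative effect of pruning on shoot FW.
#' @param cv_traits coefficient of variation of the lognormal trait noise.
#' @param cv_targets coefficient of variation of the lognormal target noise.
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(design = design_from_table1(),
                       traits = list(
                         basal_stem_diam = list(asym = 22, rate = 0.03, mid = 75),
                         main_stem_diam  = list(asym = 18, rate = 0.03, mid = 75),
                         left_stem_diam  = list(asym = 14, rate = 0.03, mid = 75),
                         right_stem_diam = list(asym = 14, rate = 0.03, mid = 75),
                         main_stem_len   = list(asym = 80, rate = 0.03, mid = 75),
                         left_stem_len   = list(asym = 120, rate = 0.03, mid = 75),
                         right_stem_len  = list(asym = 120, rate = 0.03, mid = 75)
                       ),
                       canopy_offset = 15,
                       shoot_link = list(L = 2000, k = 0.02, V0 = 150),
                       fruit_link = list(L = 3000, k = 0.06, mid = 120, onset = 45),
                       struct_weight = 0.3,
                       treatment_effects = list(
                         CT = list(shoot = 1.00, fruit = 1.00),
                         RB = list(shoot = 1.02, fruit = 1.03),
                         FR = list(shoot = 1.03, fruit = 1.05)
                       ),
                       pruning_prob = 0.3,
                       pruning_effect = 0.97,
                       cv_traits = 0.08,
                       cv_targets = 0.12,
                       seed = 42L) {
  cfg <- list(
    design = design, traits = traits, canopy_offset = canopy_offset,
    shoot_link = shoot_link, fruit_link = fruit_link,
    struct_weight = struct_weight, treatment_effects = treatment_effects,
    pruning_prob = pruning_prob, pruning_effect = pruning_effect,
    cv_traits = cv_traits, cv_targets = cv_targets, seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  d <- cfg$design
  if (!is.data.frame(d) || !all(c("year", "season", "cultivar", "treatment", "dat", "n") %in% names(d))) {
    stop_config("design", "must be a data.frame with year, season, cultivar, treatment, dat, n")
  }
  if (any(d$n < 1)) stop_config("design", "every design row needs n >= 1")
  if (!all(d$season %in% SEASON_LEVELS)) stop_config("design", "season must be one of spring, winter")
  if (!all(d$treatment %in% TREATMENT_LEVELS)) {
    stop_config("design", sprintf("treatment must be one of %s", paste(TREATMENT_LEVELS, collapse = ", ")))
  }
  if (any(d$dat < 0)) stop_config("design", "dat must be >= 0")
  needed <- setdiff(TRAIT_COLUMNS, "plant_height")
  missing <- setdiff(needed, names(cfg$traits))
  if (length(missing)) stop_config("traits", paste("missing trait parameters for", paste(missing, collapse = ", ")))
  for (tr in needed) {
    p <- cfg$traits[[tr]]
    if (!all(c("asym", "rate", "mid") %in% names(p)) || p$asym <= 0 || p$rate <= 0) {
      stop_config("traits", sprintf("trait '%s' needs positive asym and rate plus mid", tr))
    }
  }
  for (f in c("cv_traits", "cv_targets")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0) stop_config(f, "must be a finite value >= 0")
  }
  if (!all(c("L", "k", "V0") %in% names(cfg$shoot_link)) || cfg$shoot_link$L <= 0 || cfg$shoot_link$k <= 0) {
    stop_config("shoot_link", "needs L > 0, k > 0, V0")
  }
  if (!all(c("L", "k", "mid", "onset") %in% names(cfg$fruit_link)) || cfg$fruit_link$L <= 0 || cfg$fruit_link$k <= 0) {
    stop_config("fruit_link", "needs L > 0, k > 0, mid, onset")
  }
  missing_tr <- setdiff(unique(d$treatment), names(cfg$treatment_effects))
  if (length(missing_tr)) stop_config("treatment_effects", paste("missing treatments:", paste(missing_tr, collapse = ", ")))
  for (tr in names(cfg$treatment_effects)) {
    e <- cfg$treatment_effects[[tr]]
    if (!all(is.finite(c(e$shoot, e$fruit)))) stop_config("treatment_effects", "effect sizes must be finite")
  }
  if (cfg$pruning_prob < 0 || cfg$pruning_prob > 1) stop_config("pruning_prob", "must be in [0, 1]")
  if (!is.finite(cfg$seed)) stop_config("seed", "must be a finite integer")
  invisible(cfg)
}

logistic_curve <- function(dat, asym, rate, mid) asym / (1 + exp(-rate * (dat - mid)))

# Multiplicative lognormal noise with mean 1 and coefficient of variation cv.
lognorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# Noiseless expected stick volume (summed segment lengths) at a given DAT.
expected_stick_volume <- function(cfg, dat) {
  lens <- c("main_stem_len", "left_stem_len", "right_stem_len")
  Reduce(`+`, lapply(lens, function(tr) {
    p <- cfg$traits[[tr]]
    logistic_curve(dat, p$asym, p$rate, p$mid)
  }))
}

fruit_base_curve <- function(cfg, dat) {
  fl <- cfg$fruit_link
  raw <- fl$L / (1 + exp(-fl$k * (dat - fl$mid)))
  at_onset <- fl$L / (1 + exp(-fl$k * (fl$onset - fl$mid)))
  pmax(0, ifelse(dat < fl$onset, 0, raw - at_onset))
}

#' Generate a synthetic plant-record table
#'
#' Draws one record per design-row slot. Morphological traits follow
#' per-trait logistic curves in DAT with multiplicative lognormal noise;
#' plant height is the main segment plus the taller lateral segment plus a
#' canopy offset; shoot FW is a logistic-sigmoid function of the realized
#' stick volume; cumulative fruit FW is a DAT-dominated logistic modulated by
#' the plant's relative structural deviation and small treatment/pruning
#' effects. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a data.frame of plant records (columns in the documented CSV
#'   order, `is_synthetic = FALSE` throughout).
#' @export
#' @examples
#' recs <- generate_dataset(sim_config(seed = 1))
#' nrow(recs) # 303
generate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  d <- config$design
  with_seed(config$seed, {
    n_total <- sum(d$n)
    idx <- rep(seq_len(nrow(d)), d$n)
    rec <- data.frame(
      year = d$year[idx], season = d$season[idx], cultivar = d$cultivar[idx],
      treatment = d$treatment[idx], dat = d$dat[idx],
      stringsAsFactors = FALSE
    )
    rec$pruning <- stats::rbinom(n_total, 1L, config$pruning_prob)

    for (tr in setdiff(TRAIT_COLUMNS, "plant_height")) {
      p <- config$traits[[tr]]
      mu <- logistic_curve(rec$dat, p$asym, p$rate, p$mid)
      rec[[tr]] <- mu * lognorm_noise(n_total, config$cv_traits)
    }
    rec$plant_height <- (rec$main_stem_len + pmax(rec$left_stem_len, rec$right_stem_len) +
      config$canopy_offset) * lognorm_noise(n_total, config$cv_traits)

    stick_v <- rec$main_stem_len + rec$left_stem_len + rec$right_stem_len
    sl <- config$shoot_link
    shoot_mu <- sl$L / (1 + exp(-sl$k * (stick_v - sl$V0)))
    tr_shoot <- vapply(rec$treatment, function(t) config$treatment_effects[[t]]$shoot, numeric(1))
    shoot_mu <- shoot_mu * tr_shoot * ifelse(rec$pruning == 1L, config$pruning_effect, 1)
    rec$shoot_fw <- shoot_mu * lognorm_noise(n_total, config$cv_targets)

    v_exp <- expected_stick_volume(config, rec$dat)
    vol_dev <- ifelse(v_exp > 0, stick_v / v_exp - 1, 0)
    fruit_mu <- fruit_base_curve(config, rec$dat)
    tr_fruit <- vapply(rec$treatment, function(t) config$treatment_effects[[t]]$fruit, numeric(1))
    fruit_mu <- fruit_mu * pmax(0, 1 + config$struct_weight * vol_dev) * tr_fruit
    rec$fruit_fw <- pmax(0, fruit_mu * lognorm_noise(n_total, config$cv_targets))

    rec$is_synthetic <- FALSE
    rec$source_group <- ""
    rec <- rec[, RECORD_COLUMNS]
    rownames(rec) <- NULL
    rec
  })
}
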