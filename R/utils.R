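#' @keywords internal
"_PACKAGE"

# Season / treatment levels used throughout the package.
SEASON_LEVELS <- c("spring", "winter")
TREATMENT_LEVELS <- c("CT", "RB", "FR")

# Column order of a plant-record table (CSV header order).
RECORD_COLUMNS <- c(
  "year", "season", "cultivar", "treatment", "dat", "pruning",
  "plant_height", "basal_stem_diam", "main_stem_diam", "left_stem_diam",
  "right_stem_diam", "main_stem_len", "left_stem_len", "right_stem_len",
  "shoot_fw", "fruit_fw", "is_synthetic", "source_group"
)

# The eight morphological trait columns (continuous inputs).
TRAIT_COLUMNS <- c(
  "plant_height", "basal_stem_diam", "main_stem_diam", "left_stem_diam",
  "right_stem_diam", "main_stem_len", "left_stem_len", "right_stem_len"
)

TARGET_COLUMNS <- c("shoot_fw", "fruit_fw")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-group seed from a master seed and a group key
#'
#' A polynomial rolling hash of the key string is folded into the master seed
#' modulo 2^31 - 1, so per-group random streams are independent of the order
#' in which groups are processed.
#'
#' @param seed integer master seed.
#' @param key character group key (e.g. `"spring|CT|133"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
group_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(key) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(as.character(key))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

# Run code with a temporary RNG state seeded at `seed`; restores the caller's
# RNG stream afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Group key string for augmentation groups: season|treatment|dat.
record_group_key <- function(records) {
  paste(records$season, records$treatment, records$dat, sep = "|")
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}
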