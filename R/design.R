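#' Experimental design of the greenhouse study
#'
#' Returns the sampling design of the five-season greenhouse experiment:
#' one row per combination of year, season, cultivar, interlighting treatment
#' (CT = none, RB = red-blue, FR = red-blue + far-red) and days after
#' transplanting (DAT), with the number of destructively sampled plants.
#' The design totals 303 plants over 36 rows.
#'
#' @return a data.frame with columns `year`, `season`, `cultivar`,
#'   `treatment`, `dat`, `n`.
#' @export
#' @examples
#' d <- design_from_table1()
#' sum(d$n) # 303
design_from_table1 <- function() {
  row <- function(year, season, cultivar, treatment, dat, n) {
    data.frame(
      year = year, season = season, cultivar = cultivar,
      treatment = treatment, dat = dat, n = n,
      stringsAsFactors = FALSE
    )
  }
  d <- rbind(
    row(2020L, "spring", "Scirocco", "CT", c(30L, 56L, 84L, 113L, 133L), c(3L, 3L, 3L, 4L, 20L)),
    row(2020L, "spring", "Scirocco", "RB", c(84L, 133L), c(3L, 12L)),
    row(2020L, "spring", "Scirocco", "FR", c(84L, 133L), c(3L, 12L)),
    row(2020L, "winter", "Mavera/Florate", "CT", c(50L, 80L, 108L, 153L), c(6L, 6L, 3L, 15L)),
    row(2020L, "winter", "Mavera/Florate", "RB", c(108L, 153L), c(3L, 13L)),
    row(2020L, "winter", "Mavera/Florate", "FR", c(108L, 153L), c(3L, 12L)),
    row(2021L, "spring", "Mavera/Florate", "CT", c(40L, 60L, 80L, 100L, 120L), c(5L, 5L, 5L, 5L, 10L)),
    row(2021L, "spring", "Mavera/Florate", "RB", c(40L, 60L, 80L, 100L, 120L), c(5L, 5L, 5L, 5L, 10L)),
    row(2021L, "spring", "Mavera/Florate", "FR", c(40L, 60L, 80L, 100L, 120L), c(9L, 10L, 10L, 10L, 20L)),
    row(2021L, "winter", "Mavera", "CT", 150L, 9L),
    row(2021L, "winter", "Mavera", "RB", 150L, 9L),
    row(2021L, "winter", "Mavera", "FR", 150L, 36L),
    row(2022L, "spring", "Mavera", "CT", 61L, 6L)
  )
  rownames(d) <- NULL
  d
}
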