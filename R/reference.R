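#' Published New Zealand case-study estimates
#'
#' Headline estimates from the published NZ application of the method, for
#' use as *inputs* to arithmetic checks (revealed TFEe, TFEe-adjusted
#' expenditure change, HALY-gain reduction). These are transcribed published
#' numbers, not outputs of this package: reproducing them from scratch
#' requires national survey, price-database and burden-of-disease inputs
#' that are out of scope here.
#'
#' Columns: `policy`; `fpi_pct` (% change in the food price index);
#' `conventional_exp_pct` and `tfee_exp_pct` (% change in total food
#' expenditure without / with TFEe adjustment); `conventional_haly` and
#' `tfee_haly` (HALYs gained over the population lifetime, 0% discount).
#'
#' @return data.frame, one row per policy.
#' @export
nz_case_studies <- function() {
  data.frame(
    policy = c("safa_tax", "sugar_tax", "fv_subsidy"),
    fpi_pct = c(3.91, 1.88, -3.27),
    conventional_exp_pct = c(-1.92, -1.04, 0.72),
    tfee_exp_pct = c(2.93, 1.41, -2.45),
    conventional_haly = c(3343000, 2504000, 415000),
    tfee_haly = c(1805000, 1671000, 953000),
    stringsAsFactors = FALSE
  )
}
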