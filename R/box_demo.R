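# A stylized three-food world (fruit, vegetables, cereal) demonstrating why
# a conditional PE matrix cannot be transplanted between settings without
# rescaling. The published demonstration prints its input tables only as
# images; the systems below are a SYNTHETIC RECONSTRUCTION solved to satisfy
# every figure the accompanying prose does print:
#   * a 1% fruit price rise moves fruit -1%, vegetables +0.3%, cereal -0.05%
#     (the fruit column of the PE matrix);
#   * a 20% fruit subsidy leaves total expenditure in the original setting
#     exactly unchanged and raises total energy by 0.51%;
#   * transplanting the same matrix and subsidy to a second setting (same
#     prices, different consumption) changes total expenditure and raises
#     total energy by 2.38%.
# The vegetable and cereal price columns are never exercised by a fruit-only
# price change; they are filled with arbitrary negative-diagonal values.

#' Three-food transferability demonstration (synthetic reconstruction)
#'
#' Returns the two consumption settings, the shared PE matrix and the 20%
#' fruit subsidy of the classic conditional-PE transferability
#' demonstration. Running the subsidy conventionally leaves expenditure
#' unchanged and raises energy by 0.51% in `setting_a`, but by 2.38% (with
#' an expenditure shift) in the transplanted `setting_b`.
#'
#' @return list with `setting_a`, `setting_b` ([food_system()]s sharing
#'   prices and energy densities), `pe` (a [pe_matrix()]), `policy` (the
#'   20% fruit subsidy).
#' @examples
#' d <- box_demo_systems()
#' r <- run_policy_scenario(d$setting_a, d$policy, d$pe, mode = "conventional")
#' subset(r$summaries, measure == "energy_kj")$pct_change # 0.51
#' @export
box_demo_systems <- function() {
  mk <- function(q) food_system(
    c("fruit", "vegetables", "cereal"),
    price = c(0.50, 0.20, 1.00),
    quantity = q,
    energy = c(200, 160, 780))
  eps <- rbind(fruit      = c(-1.00, 0.20, -0.05),
               vegetables = c(0.30, -0.90, 0.10),
               cereal     = c(-0.05, 0.10, -0.70))
  colnames(eps) <- rownames(eps)
  list(setting_a = mk(c(50, 400, 580)),
       setting_b = mk(c(300, 200, 733)),
       pe = pe_matrix(eps),
       policy = policy_spec("20% fruit subsidy",
                            ad_valorem = c(fruit = -0.20)))
}
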