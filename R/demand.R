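# Two-step post-policy quantity estimation.
#
# Step 1 propagates price changes through the conditional PE matrix and
# rescales so total food expenditure is unchanged (the 'conditional'
# assumption). Step 2 moves total expenditure by %dFPI * TFEe and allocates
# the change across foods with their expenditure elasticities, with a final
# scalar so the target is hit exactly.
#
# Units: prices per 100 g, quantities g/day, expenditure = sum(q/100 * p).
# Percent-change quantities are fractions internally; fields suffixed _pct
# are percentages for presentation.

#' Total daily food expenditure
#'
#' @param q quantities, g/day.
#' @param p prices, currency per 100 g.
#' @return scalar expenditure, currency/day: `sum(q / 100 * p)`.
#' @examples
#' total_expenditure(c(100, 200), c(1, 0.5)) # 2
#' @export
total_expenditure <- function(q, p) {
  if (length(q) != length(p)) stop("q and p must have equal length")
  if (any(p <= 0)) stop("prices must be > 0")
  if (any(q < 0)) stop("quantities must be >= 0")
  sum(q / 100 * p)
}

#' Post-policy prices
#'
#' Applies a policy's specific nutrient taxes (currency per 100 g nutrient,
#' added in proportion to nutrient content) and ad valorem changes
#' (multiplicative) to baseline prices. Pass-through is 100% and producer
#' prices are fixed.
#'
#' @param fs a [food_system()].
#' @param policy a [policy_spec()].
#' @return numeric vector of post-policy prices per 100 g, named by food_id.
#' @examples
#' fs <- food_system("butter", price = 2, quantity = 10, energy = 3000,
#'                   nutrients = data.frame(safa = 50))
#' apply_policy(fs, policy_spec("SAFA tax", nutrient_taxes = c(safa = 2))) # 3
#' @export
apply_policy <- function(fs, policy) {
  stopifnot(inherits(fs, "food_system"), inherits(policy, "policy_spec"))
  p_a <- fs$price
  for (nm in names(policy$nutrient_taxes)) {
    if (!nm %in% nutrient_names(fs))
      stop("policy taxes unknown nutrient: ", nm)
    # content is g nutrient per 100 g food; tax is per 100 g nutrient, so the
    # surcharge per 100 g food is rate * content / 100
    p_a <- p_a + policy$nutrient_taxes[[nm]] * fs[[nm]] / 100
  }
  av <- policy$ad_valorem
  if (length(av) == 1L && is.null(names(av))) {
    p_a <- p_a * (1 + av)
  } else if (length(av)) {
    unknown <- setdiff(names(av), fs$food_id)
    if (length(unknown))
      stop("policy names unknown food_id: ", paste(unknown, collapse = ", "))
    idx <- match(names(av), fs$food_id)
    p_a[idx] <- p_a[idx] * (1 + av)
  }
  if (any(p_a <= 0)) stop("policy drives a price non-positive")
  stats::setNames(p_a, fs$food_id)
}

#' Percent change in the food price index
#'
#' Laspeyres-type, base-quantity-weighted:
#' `100 * (sum(q_B p_A) / sum(q_B p_B) - 1)`.
#'
#' @param fs a [food_system()].
#' @param p_a post-policy prices per 100 g.
#' @return percent change in the FPI (scalar, percentage points).
#' @export
fpi_percent_change <- function(fs, p_a) {
  stopifnot(inherits(fs, "food_system"))
  if (any(p_a <= 0)) stop("post-policy prices must be > 0")
  x_b <- total_expenditure(fs$quantity, fs$price)
  if (x_b <= 0) stop("zero baseline expenditure: FPI undefined")
  100 * (total_expenditure(fs$quantity, p_a) / x_b - 1)
}

#' Step 1: conditional application of the PE matrix with expenditure rescale
#'
#' Computes the raw elasticity response `dq_pe[i] = sum_j dp[j] * eps[i, j]`
#' (fractions), the implied expenditure `x_pe = sum((1 + dq_pe) q_B p_A)`,
#' and the rescaled response `dq_pes = (x_B / x_pe) (1 + dq_pe) - 1`, which
#' guarantees `sum((1 + dq_pes) q_B p_A) == x_B` (no change in total food
#' expenditure, as a conditional matrix assumes).
#'
#' Quantities driven below zero by extreme elasticities are clamped to zero
#' with a warning before rescaling.
#'
#' @param fs a [food_system()].
#' @param p_a post-policy prices per 100 g.
#' @param pe a [pe_matrix()] indexed like `fs`.
#' @return list with fractions `dq_pe`, `dq_pes`, expenditure `x_pe`, and
#'   `clamped` (logical vector).
#' @export
conditional_step <- function(fs, p_a, pe) {
  stopifnot(inherits(fs, "food_system"), inherits(pe, "pe_matrix"))
  n <- nrow(fs)
  if (!identical(dim(pe$eps), c(n, n)))
    stop("PE matrix dimension does not match the food system")
  dp <- p_a / fs$price - 1
  dq_pe <- as.vector(pe$eps %*% dp)
  rel <- 1 + dq_pe
  clamped <- rel < 0
  if (any(clamped)) {
    warning(sprintf("%d food(s) driven below zero consumption; clamped: %s",
                    sum(clamped),
                    paste(fs$food_id[clamped], collapse = ", ")))
    rel[clamped] <- 0
  }
  x_b <- total_expenditure(fs$quantity, fs$price)
  x_pe <- total_expenditure(rel * fs$quantity, p_a)
  if (x_pe <= 0)
    stop("implied post-elasticity expenditure is non-positive; cannot rescale")
  dq_pes <- (x_b / x_pe) * rel - 1
  list(dq_pe = stats::setNames(dq_pe, fs$food_id),
       dq_pes = stats::setNames(dq_pes, fs$food_id),
       x_pe = x_pe, clamped = clamped)
}

#' Step 2: expenditure-elasticity allocation under a TFEe target
#'
#' Sets the target expenditure change `dX = fpi * tfee * x_B` (fpi as a
#' fraction), forms preliminary per-food changes
#' `dq_ee[i] = fpi * tfee * eta[i] * (1 + dq_pes[i]) * q_B[i]`, rescales them
#' by `dX / sum(dq_ee * p_A)` so the target is hit exactly, and assembles
#' final quantities `q_A = scalar * dq_ee + dq_pes * q_B + q_B`.
#'
#' @param fs a [food_system()].
#' @param p_a post-policy prices.
#' @param step1 output of [conditional_step()].
#' @param ee an [ee_vector()] (or plain numeric) of expenditure elasticities.
#' @param tfee scalar total food expenditure elasticity (normally in [0, 1]).
#' @return a `scenario_result` (see [run_policy_scenario()]).
#' @export
expenditure_step <- function(fs, p_a, step1, ee, tfee) {
  stopifnot(inherits(fs, "food_system"))
  n <- nrow(fs)
  eta <- as.numeric(ee)
  if (length(eta) != n) stop("expenditure-elasticity vector length mismatch")
  if (!is.finite(tfee)) stop("tfee must be finite")
  x_b <- total_expenditure(fs$quantity, fs$price)
  fpi <- fpi_percent_change(fs, p_a) / 100
  delta_x <- fpi * tfee * x_b
  dq_pes <- step1$dq_pes
  q_pes <- (1 + dq_pes) * fs$quantity
  dq_ee <- (fpi * tfee * eta) * q_pes          # preliminary g/day changes
  dx_ee <- sum(dq_ee / 100 * p_a)
  if (delta_x == 0) {
    scal <- 0                                  # null target: nothing to allocate
  } else if (dx_ee == 0) {
    stop("degenerate expenditure-elasticity vector: cannot allocate a nonzero ",
         "expenditure change")
  } else {
    scal <- delta_x / dx_ee
  }
  q_a <- scal * dq_ee + dq_pes * fs$quantity + fs$quantity
  if (any(q_a < 0)) {
    warning(sprintf("%d post-policy quantities negative; clamped to zero: %s",
                    sum(q_a < 0),
                    paste(fs$food_id[q_a < 0], collapse = ", ")))
    q_a[q_a < 0] <- 0
  }
  new_scenario_result(fs, p_a, q_a, dq_pes, mode = "tfee_adjusted",
                      delta_x = delta_x, tfee = tfee)
}

# assemble a scenario_result; x_a recomputed from (q_a, p_a) per Eq 12
new_scenario_result <- function(fs, p_a, q_a, dq_pes, mode, delta_x, tfee = NA_real_) {
  x_b <- total_expenditure(fs$quantity, fs$price)
  x_a <- total_expenditure(q_a, p_a)
  structure(list(
    food_id = fs$food_id,
    q_b = stats::setNames(fs$quantity, fs$food_id),
    q_a = stats::setNames(q_a, fs$food_id),
    p_b = stats::setNames(fs$price, fs$food_id),
    p_a = stats::setNames(p_a, fs$food_id),
    x_b = x_b, x_a = x_a, delta_x = delta_x,
    fpi_pct = fpi_percent_change(fs, p_a),
    dq_pes = dq_pes,
    tfee = tfee, mode = mode,
    summaries = diet_summary(fs, q_a)
  ), class = "scenario_result")
}

#' Diet summaries before and after a quantity change
#'
#' Totals of grams/day, energy kJ/day and each nutrient g/day, pre and post.
#'
#' @param fs a [food_system()].
#' @param q_a post-policy quantities g/day.
#' @return data.frame with columns `measure`, `pre`, `post`, `pct_change`.
#' @export
diet_summary <- function(fs, q_a) {
  stopifnot(inherits(fs, "food_system"), length(q_a) == nrow(fs))
  tot <- function(q, dens) sum(q * dens / 100)
  measures <- c("grams", "energy_kj", nutrient_names(fs))
  pre <- c(sum(fs$quantity), tot(fs$quantity, fs$energy),
           vapply(nutrient_names(fs), function(nm) tot(fs$quantity, fs[[nm]]),
                  numeric(1)))
  post <- c(sum(q_a), tot(q_a, fs$energy),
            vapply(nutrient_names(fs), function(nm) tot(q_a, fs[[nm]]),
                   numeric(1)))
  data.frame(measure = measures, pre = unname(pre), post = unname(post),
             pct_change = unname(ifelse(pre == 0, NA_real_,
                                        100 * (post / pre - 1))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run a full policy scenario
#'
#' `mode = "tfee_adjusted"` runs Step 1 (conditional application with the
#' expenditure-preserving rescale) then Step 2 (TFEe/EE allocation).
#' `mode = "conventional"` applies the PE matrix raw -- no rescale, no TFEe --
#' which is what produces the implausible total-expenditure shifts the TFEe
#' adjustment exists to repair.
#'
#' @param fs a [food_system()].
#' @param policy a [policy_spec()].
#' @param pe a [pe_matrix()].
#' @param ee an [ee_vector()] (required for `tfee_adjusted`).
#' @param tfee scalar TFEe (required for `tfee_adjusted`).
#' @param mode `"tfee_adjusted"` or `"conventional"`.
#' @return A `scenario_result`: list with pre/post quantities and prices,
#'   expenditures `x_b`/`x_a`, target `delta_x`, `fpi_pct` (percent), Step-1
#'   fractions `dq_pes`, `mode` and a `summaries` data.frame.
#' @examples
#' fs <- food_system(c("a", "b"), price = c(1, 1), quantity = c(100, 100),
#'                   energy = c(500, 1500))
#' pe <- pe_matrix(diag(c(-1, -1)), food_id = fs$food_id)
#' res <- run_policy_scenario(fs, policy_spec("tax", ad_valorem = c(a = 0.1)),
#'                            pe, ee = c(1, 1), tfee = 0.75)
#' res$x_a / res$x_b
#' @export
run_policy_scenario <- function(fs, policy, pe, ee = NULL, tfee = NULL,
                                mode = c("tfee_adjusted", "conventional")) {
  mode <- match.arg(mode)
  p_a <- apply_policy(fs, policy)
  if (mode == "conventional") {
    dp <- p_a / fs$price - 1
    dq_pe <- as.vector(pe$eps %*% dp)
    q_a <- pmax(0, (1 + dq_pe)) * fs$quantity
    if (any(1 + dq_pe < 0))
      warning("conventional mode clamped negative quantities to zero")
    return(new_scenario_result(fs, p_a, q_a,
                               dq_pes = stats::setNames(dq_pe, fs$food_id),
                               mode = "conventional", delta_x = NA_real_))
  }
  if (is.null(ee) || is.null(tfee))
    stop("tfee_adjusted mode requires ee and tfee")
  s1 <- conditional_step(fs, p_a, pe)
  expenditure_step(fs, p_a, s1, ee, tfee)
}

#' Revealed total food expenditure elasticity
#'
#' The TFEe a model run implies post hoc: the ratio of the % change in total
#' food expenditure to the % change in the food price index. A conventional
#' (unadjusted) run typically reveals an implausible value (e.g. negative
#' for a tax); a `tfee_adjusted` run returns its input TFEe exactly.
#'
#' @param result a `scenario_result`, or a numeric % expenditure change.
#' @param fpi_pct % FPI change (only when `result` is numeric).
#' @return dimensionless revealed TFEe.
#' @examples
#' revealed_tfee(-1.92, 3.91) # -0.49: tax raises prices yet spending falls
#' @export
revealed_tfee <- function(result, fpi_pct = NULL) {
  if (is.numeric(result)) {
    if (is.null(fpi_pct)) stop("supply fpi_pct with a numeric expenditure change")
    exp_pct <- result
  } else {
    stopifnot(inherits(result, "scenario_result"))
    exp_pct <- 100 * (result$x_a / result$x_b - 1)
    fpi_pct <- result$fpi_pct
  }
  if (fpi_pct == 0) stop("FPI change is zero: revealed TFEe undefined")
  exp_pct / fpi_pct
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> mode=%s, %d foods\n", x$mode,
              length(x$food_id)))
  cat(sprintf("  FPI change: %+.2f%%   expenditure: %.4f -> %.4f (%+.2f%%)\n",
              x$fpi_pct, x$x_b, x$x_a, 100 * (x$x_a / x$x_b - 1)))
  if (x$fpi_pct != 0)
    cat(sprintf("  revealed TFEe: %.3f\n", revealed_tfee(x)))
  print(x$summaries, ...)
  invisible(x)
}
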