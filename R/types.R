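#' Construct a food system
#'
#' A food system is the state a price policy perturbs: for each food, its
#' baseline consumption, price, energy density and nutrient composition.
#' Beverages are carried in the same quantity column with ml treated as g.
#'
#' @param food_id character vector of unique food labels.
#' @param price numeric, price in currency units per 100 g. Must be > 0.
#' @param quantity numeric, baseline consumption in g/person/day. Must be >= 0.
#' @param energy numeric, energy density in kJ per 100 g. Must be >= 0.
#' @param nutrients optional data.frame (one row per food) of nutrient
#'   content in g per 100 g; each value must lie in [0, 100].
#' @param group_id character vector linking each food to an elasticity food
#'   group. Defaults to `food_id` (each food its own group).
#'
#' @return An object of class `food_system`: a data.frame with columns
#'   `food_id`, `group_id`, `price`, `quantity`, `energy` and one column per
#'   nutrient, plus attribute `nutrients` naming the nutrient columns.
#' @examples
#' fs <- food_system(c("bread", "butter"), price = c(0.35, 0.80),
#'                   quantity = c(120, 15), energy = c(1000, 3000),
#'                   nutrients = data.frame(safa = c(0.6, 52), sugar = c(3, 0.6)))
#' expenditure_shares(fs)
#' @export
food_system <- function(food_id, price, quantity, energy = 0,
                        nutrients = NULL, group_id = food_id) {
  food_id <- as.character(food_id)
  n <- length(food_id)
  if (n == 0L) stop("food system must contain at least one food")
  if (anyDuplicated(food_id)) stop("duplicate food_id: ",
                                   paste(unique(food_id[duplicated(food_id)]), collapse = ", "))
  price <- rep_len(as.numeric(price), n)
  quantity <- rep_len(as.numeric(quantity), n)
  energy <- rep_len(as.numeric(energy), n)
  group_id <- rep_len(as.character(group_id), n)
  if (any(!is.finite(price)) || any(price <= 0))
    stop("all prices must be finite and > 0")
  if (any(!is.finite(quantity)) || any(quantity < 0))
    stop("all quantities must be finite and >= 0")
  if (any(!is.finite(energy)) || any(energy < 0))
    stop("all energy densities must be finite and >= 0")
  df <- data.frame(food_id = food_id, group_id = group_id, price = price,
                   quantity = quantity, energy = energy,
                   stringsAsFactors = FALSE)
  nutr_names <- character(0)
  if (!is.null(nutrients)) {
    nutrients <- as.data.frame(nutrients)
    if (nrow(nutrients) != n) stop("nutrients must have one row per food")
    bad <- vapply(nutrients, function(x) any(!is.finite(x) | x < 0 | x > 100),
                  logical(1))
    if (any(bad))
      stop("nutrient content out of [0, 100] g/100 g: ",
           paste(names(nutrients)[bad], collapse = ", "))
    nutr_names <- names(nutrients)
    df <- cbind(df, nutrients)
  }
  structure(df, nutrients = nutr_names,
            class = c("food_system", "data.frame"))
}

#' @export
print.food_system <- function(x, ...) {
  cat(sprintf("<food_system> %d foods, %d groups, baseline expenditure %.4f/day\n",
              nrow(x), length(unique(x$group_id)),
              total_expenditure(x$quantity, x$price)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Expenditure shares of a food system
#'
#' Budget share w_i = q_i p_i / sum(q p); shares sum to 1.
#'
#' @param fs a [food_system()].
#' @return numeric vector of shares, named by food_id.
#' @export
expenditure_shares <- function(fs) {
  stopifnot(inherits(fs, "food_system"))
  e <- fs$quantity / 100 * fs$price
  tot <- sum(e)
  if (tot <= 0) stop("zero baseline expenditure: shares undefined")
  stats::setNames(e / tot, fs$food_id)
}

#' Nutrient columns of a food system
#' @param fs a [food_system()].
#' @return character vector of nutrient column names (possibly empty).
#' @export
nutrient_names <- function(fs) attr(fs, "nutrients")

#' Construct a price-elasticity matrix
#'
#' Entry `eps[i, j]` is the Marshallian conditional elasticity: the % change
#' in quantity of food i per 1% change in the price of food j. Own-price
#' elasticities (the diagonal) are normally negative; positive diagonals
#' trigger a warning (or an error with `own_positive = "error"`).
#'
#' @param eps square numeric matrix of elasticities.
#' @param sd optional square matrix of standard deviations (same dim, >= 0).
#' @param food_id labels for rows/columns; defaults to existing dimnames.
#' @param own_positive `"warn"` (default) or `"error"` for positive own-PEs.
#' @return An object of class `pe_matrix`: list with elements `eps`, `sd`.
#' @export
pe_matrix <- function(eps, sd = NULL, food_id = rownames(eps),
                      own_positive = c("warn", "error")) {
  own_positive <- match.arg(own_positive)
  eps <- as.matrix(eps)
  if (nrow(eps) != ncol(eps)) stop("elasticity matrix must be square")
  if (any(!is.finite(eps))) stop("elasticity matrix must be finite")
  if (is.null(food_id)) food_id <- paste0("food", seq_len(nrow(eps)))
  food_id <- as.character(food_id)
  if (length(food_id) != nrow(eps)) stop("food_id length mismatch")
  dimnames(eps) <- list(food_id, food_id)
  d <- diag(eps)
  if (any(d > 0)) {
    msg <- paste0("positive own-price elasticity for: ",
                  paste(food_id[d > 0], collapse = ", "))
    if (own_positive == "error") stop(msg) else warning(msg)
  }
  if (!is.null(sd)) {
    sd <- as.matrix(sd)
    if (!identical(dim(sd), dim(eps))) stop("sd matrix dimension mismatch")
    if (any(!is.finite(sd)) || any(sd < 0)) stop("sd entries must be >= 0")
    dimnames(sd) <- dimnames(eps)
  }
  structure(list(eps = eps, sd = sd), class = "pe_matrix")
}

#' @export
print.pe_matrix <- function(x, ...) {
  cat(sprintf("<pe_matrix> %d x %d, own-PE range [%.3f, %.3f]%s\n",
              nrow(x$eps), ncol(x$eps), min(diag(x$eps)), max(diag(x$eps)),
              if (is.null(x$sd)) "" else ", with SDs"))
  print(x$eps, ...)
  invisible(x)
}

#' @export
dim.pe_matrix <- function(x) dim(x$eps)

#' Construct a price-policy specification
#'
#' A policy combines specific (per-nutrient) taxes and ad valorem price
#' changes. A nutrient tax is levied per 100 g of the nutrient and passed
#' through 100% to the shelf price in proportion to nutrient content; an ad
#' valorem entry of -0.20 is a 20% subsidy.
#'
#' @param name policy label.
#' @param nutrient_taxes named numeric: tax in currency per 100 g of nutrient.
#' @param ad_valorem named numeric: proportional price change per food_id
#'   (fraction; must be > -1), or a single unnamed value applied to all foods.
#' @return An object of class `policy_spec`.
#' @examples
#' policy_spec("SAFA tax", nutrient_taxes = c(safa = 2))
#' policy_spec("F&V subsidy", ad_valorem = c(fruit = -0.2, veg = -0.2))
#' @export
policy_spec <- function(name = "policy", nutrient_taxes = numeric(0),
                        ad_valorem = numeric(0)) {
  nutrient_taxes <- unlist(nutrient_taxes)
  ad_valorem <- unlist(ad_valorem)
  if (length(nutrient_taxes) && is.null(names(nutrient_taxes)))
    stop("nutrient_taxes must be named by nutrient")
  if (length(ad_valorem) > 1L && is.null(names(ad_valorem)))
    stop("ad_valorem must be named by food_id (or a single global value)")
  if (any(ad_valorem <= -1))
    stop("ad valorem change must be > -1 (price cannot reach zero)")
  structure(list(name = name,
                 nutrient_taxes = nutrient_taxes,
                 ad_valorem = ad_valorem),
            class = "policy_spec")
}

#' @export
print.policy_spec <- function(x, ...) {
  cat(sprintf("<policy_spec> %s\n", x$name))
  if (length(x$nutrient_taxes))
    cat("  nutrient taxes (per 100 g nutrient):",
        paste(sprintf("%s=%.3g", names(x$nutrient_taxes), x$nutrient_taxes),
              collapse = ", "), "\n")
  if (length(x$ad_valorem))
    cat("  ad valorem:",
        if (is.null(names(x$ad_valorem)))
          sprintf("%+.1f%% (all foods)", 100 * x$ad_valorem)
        else paste(sprintf("%s=%+.1f%%", names(x$ad_valorem),
                           100 * x$ad_valorem), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a food-group expenditure-elasticity vector
#'
#' eta_i is the % change in consumption of food i per 1% change in total
#' food expenditure. When `normalized = TRUE` the vector is checked against
#' Engel aggregation: the expenditure-share-weighted mean must equal 1.
#'
#' @param eta numeric vector of expenditure elasticities.
#' @param food_id optional labels.
#' @param normalized if TRUE, `weights` must be supplied and
#'   `sum(weights * eta)` must equal 1 within `tol`.
#' @param weights expenditure shares used for the Engel check.
#' @param tol tolerance for the Engel check.
#' @return An object of class `ee_vector` (numeric with attributes).
#' @export
ee_vector <- function(eta, food_id = names(eta), normalized = FALSE,
                      weights = NULL, tol = 1e-6) {
  eta <- as.numeric(eta)
  if (any(!is.finite(eta))) stop("expenditure elasticities must be finite")
  if (normalized) {
    if (is.null(weights)) stop("normalized = TRUE requires weights")
    if (abs(sum(weights * eta) - 1) > tol)
      stop(sprintf("Engel aggregation violated: sum(w * eta) = %.8f != 1",
                   sum(weights * eta)))
  }
  structure(eta, names = food_id, normalized = normalized,
            class = "ee_vector")
}
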