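# CSV/YAML/JSON interchange. All files are UTF-8, comma-delimited, '.'
# decimal. Readers validate; writers round-trip losslessly at full float
# precision (15 significant digits). Percent quantities are serialized as
# percentages with a units note; internal computation uses fractions.

#' Read / write a food-system table
#'
#' CSV columns: `food_id`, `group_id`, `price_per_100g`, `grams_per_day`,
#' `kj_per_100g`, then one column per nutrient (g per 100 g).
#'
#' @param path file path.
#' @return a [food_system()].
#' @export
read_food_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("food_id", "group_id", "price_per_100g", "grams_per_day",
           "kj_per_100g")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("food table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$food_id))
    stop("duplicate food_id in ", path, " at row(s): ",
         paste(which(duplicated(df$food_id)), collapse = ", "))
  bad <- which(!is.finite(df$price_per_100g) | df$price_per_100g <= 0)
  if (length(bad))
    stop("non-positive price in ", path, " at row(s): ",
         paste(bad, collapse = ", "))
  nutr <- setdiff(names(df), req)
  food_system(df$food_id, price = df$price_per_100g,
              quantity = df$grams_per_day, energy = df$kj_per_100g,
              nutrients = if (length(nutr)) df[nutr] else NULL,
              group_id = df$group_id)
}

#' @rdname read_food_table
#' @param fs a [food_system()].
#' @export
write_food_table <- function(fs, path) {
  stopifnot(inherits(fs, "food_system"))
  df <- data.frame(food_id = fs$food_id, group_id = fs$group_id,
                   price_per_100g = fs$price, grams_per_day = fs$quantity,
                   kj_per_100g = fs$energy, stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (nm in nutrient_names(fs)) df[[nm]] <- fs[[nm]]
  write_csv_full(df, path)
  invisible(path)
}

# full-precision CSV writer
write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15,
                                                scientific = FALSE,
                                                trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Read / write a PE matrix
#'
#' Square CSV with a leading `food_id` column and one column per food.
#'
#' @param path file path.
#' @param sd_path optional path of a like-shaped SD matrix.
#' @return a [pe_matrix()].
#' @export
read_pe_matrix <- function(path, sd_path = NULL) {
  read_square <- function(p) {
    df <- utils::read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
    ids <- df[[1]]
    m <- as.matrix(df[-1])
    if (!identical(colnames(m), as.character(ids)))
      stop("PE matrix ", p, " header does not match its food_id column")
    dimnames(m) <- list(ids, ids)
    m
  }
  if (!file.exists(path)) stop("file not found: ", path)
  eps <- read_square(path)
  sd <- if (!is.null(sd_path)) read_square(sd_path)
  pe_matrix(eps, sd = sd)
}

#' @rdname read_pe_matrix
#' @param pe a [pe_matrix()].
#' @export
write_pe_matrix <- function(pe, path, sd_path = NULL) {
  stopifnot(inherits(pe, "pe_matrix"))
  dump <- function(m, p) {
    df <- data.frame(food_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_csv_full(df, p)
  }
  dump(pe$eps, path)
  if (!is.null(sd_path)) {
    if (is.null(pe$sd)) stop("matrix carries no SDs")
    dump(pe$sd, sd_path)
  }
  invisible(path)
}

#' Read / write an expenditure-elasticity vector
#'
#' Two-column CSV: `food_id`, `ee`.
#'
#' @param path file path.
#' @return an [ee_vector()] (not Engel-checked; check on use).
#' @export
read_ee_vector <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("food_id", "ee") %in% names(df)))
    stop("EE file needs columns food_id, ee")
  ee_vector(df$ee, food_id = df$food_id)
}

#' @rdname read_ee_vector
#' @param ee an [ee_vector()] or named numeric.
#' @export
write_ee_vector <- function(ee, path) {
  write_csv_full(data.frame(food_id = names(ee), ee = as.numeric(ee),
                            stringsAsFactors = FALSE), path)
  invisible(path)
}

#' Read a disaggregation scheme
#'
#' CSV columns: `group_id`, `sub_food_id`, `within_group_share`.
#'
#' @param path file path.
#' @param s,sd_s strengthening scalar and SD (scheme files carry shares only).
#' @return a [disagg_scheme()].
#' @export
read_disagg_scheme <- function(path, s = 0.025, sd_s = 0.0125) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("group_id", "sub_food_id", "within_group_share")
  if (!all(req %in% names(df)))
    stop("scheme file needs columns ", paste(req, collapse = ", "))
  disagg_scheme(df$group_id, df$sub_food_id, df$within_group_share,
                s = s, sd_s = sd_s)
}

#' @rdname read_disagg_scheme
#' @param scheme a [disagg_scheme()].
#' @export
write_disagg_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "disagg_scheme"))
  df <- scheme$table
  names(df)[names(df) == "share"] <- "within_group_share"
  write_csv_full(df, path)
  invisible(path)
}

#' Read a policy from YAML
#'
#' Mapping with optional keys `name`, `nutrient_taxes` (map nutrient ->
#' currency per 100 g nutrient) and `ad_valorem` (map food_id -> fractional
#' price change).
#'
#' @param path YAML file path.
#' @return a [policy_spec()].
#' @export
read_policy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  policy_spec(name = if (is.null(y$name)) basename(path) else y$name,
              nutrient_taxes = unlist(y$nutrient_taxes),
              ad_valorem = unlist(y$ad_valorem))
}

#' Write a scenario result as JSON
#'
#' Serializes every `scenario_result` field, percent quantities as
#' percentages (with a `units` block), plus a provenance block (package
#' version, timestamp optional, seed, config hash if supplied).
#'
#' @param result a `scenario_result`.
#' @param path output path.
#' @param seed,config_hash optional provenance entries.
#' @return `path`, invisibly.
#' @export
write_scenario_json <- function(result, path, seed = NULL,
                                config_hash = NULL) {
  stopifnot(inherits(result, "scenario_result"))
  payload <- list(
    mode = result$mode,
    tfee = result$tfee,
    food_id = result$food_id,
    q_b = unname(result$q_b), q_a = unname(result$q_a),
    p_b = unname(result$p_b), p_a = unname(result$p_a),
    x_b = result$x_b, x_a = result$x_a, delta_x = result$delta_x,
    fpi_pct = result$fpi_pct,
    expenditure_pct = 100 * (result$x_a / result$x_b - 1),
    pct_dq_pes = 100 * unname(result$dq_pes),
    summaries = result$summaries,
    units = list(q = "g/day", p = "currency per 100 g",
                 x = "currency/day", fpi_pct = "%", pct_dq_pes = "%"),
    provenance = list(package = "elastax",
                      version = as.character(utils::packageVersion("elastax")),
                      seed = if (is.null(seed)) NA else as.numeric(seed),
                      config_hash = if (is.null(config_hash)) NA
                                    else config_hash)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
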