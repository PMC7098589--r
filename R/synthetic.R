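# Synthetic food systems, elasticity matrices, expenditure-elasticity
# vectors, disaggregation schemes and health inputs with the statistical
# structure the method assumes, so every stage is testable without any
# external dataset. The generated tables mirror the structure of a national
# food-system input bundle: per-food prices, consumption, energy and
# nutrient composition; a square conditional PE matrix satisfying Cournot
# aggregation; Engel-normalized expenditure elasticities.

#' Synthetic-data configuration
#'
#' Defaults emulate the aggregate food system the method was designed
#' around: 23 food groups (one food per group unless
#' `subfoods_per_group > 1`; 23 x 15 = 345 for the fine fixture), prices of
#' a few currency units per 100 g, consumption up to a few hundred g/day,
#' own-PEs in [-1.5, -0.2].
#'
#' @param n_groups number of aggregate food groups.
#' @param subfoods_per_group sub-foods per group.
#' @param price_range currency per 100 g, `c(min, max)`.
#' @param quantity_range g/person/day, `c(min, max)`.
#' @param energy_range kJ per 100 g, `c(min, max)` (floored so energy is at
#'   least 17 kJ/g of sugar + 37 kJ/g of fat content).
#' @param own_pe_range own-price elasticity range, strictly negative.
#' @param cross_scale scale of raw cross-elasticity draws before the
#'   adding-up adjustment.
#' @param nutrient_max named vector of maximum nutrient content g/100 g.
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_groups = 23, subfoods_per_group = 1,
                             price_range = c(0.2, 3),
                             quantity_range = c(5, 300),
                             energy_range = c(80, 2200),
                             own_pe_range = c(-1.5, -0.2),
                             cross_scale = 0.08,
                             nutrient_max = c(safa = 40, sugar = 60),
                             seed = 1L) {
  stopifnot(n_groups >= 1, subfoods_per_group >= 1,
            diff(price_range) >= 0, price_range[1] > 0,
            diff(quantity_range) >= 0, quantity_range[1] >= 0,
            diff(own_pe_range) >= 0, own_pe_range[2] < 0,
            cross_scale >= 0)
  structure(list(n_groups = n_groups,
                 subfoods_per_group = subfoods_per_group,
                 price_range = price_range, quantity_range = quantity_range,
                 energy_range = energy_range, own_pe_range = own_pe_range,
                 cross_scale = cross_scale, nutrient_max = nutrient_max,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

runif_in <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate a synthetic food system
#'
#' @param cfg a [synthetic_config()].
#' @return a [food_system()] with `n_groups * subfoods_per_group` foods;
#'   energy densities respect the macronutrient plausibility floor.
#' @export
make_food_system <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_groups * cfg$subfoods_per_group
  group <- rep(sprintf("group%02d", seq_len(cfg$n_groups)),
               each = cfg$subfoods_per_group)
  id <- if (cfg$subfoods_per_group == 1L) group
        else paste0(group, letters[rep(seq_len(cfg$subfoods_per_group),
                                       cfg$n_groups)])
  # right-skewed content: most foods carry little of a given nutrient, a
  # few are concentrated sources (as in real composition tables)
  nutr <- as.data.frame(lapply(cfg$nutrient_max,
                               function(mx) mx * stats::rbeta(n, 1, 4)))
  energy <- runif_in(n, cfg$energy_range)
  floor_kj <- 17 * (if ("sugar" %in% names(nutr)) nutr$sugar else 0) +
              37 * (if ("safa" %in% names(nutr)) nutr$safa else 0)
  food_system(id,
              price = runif_in(n, cfg$price_range),
              quantity = runif_in(n, cfg$quantity_range),
              energy = pmax(energy, floor_kj),
              nutrients = if (ncol(nutr)) nutr else NULL,
              group_id = group)
}

#' Generate a Cournot-consistent synthetic PE matrix
#'
#' Negative own-PEs on the diagonal; off-diagonal entries drawn then
#' column-adjusted (proportionally to expenditure shares) so every
#' budget-share-weighted column sum satisfies Cournot aggregation,
#' `sum_i w_i eps[i, j] = -w_j`, within 1e-9. SDs are set proportional to
#' entry magnitude.
#'
#' @param w expenditure shares (sum to 1), e.g. from [expenditure_shares()].
#' @param cfg a [synthetic_config()].
#' @param sd_frac SD as a fraction of `|eps|` (plus a small floor).
#' @return a [pe_matrix()] with SDs.
#' @export
make_pe_matrix <- function(w, cfg, sd_frac = 0.25) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- length(w)
  if (abs(sum(w) - 1) > 1e-8) stop("shares must sum to 1")
  set.seed(cfg$seed + 1L)
  if (n == 1L) {
    eps <- matrix(-w, 1, 1)          # forced by the adding-up constraint
  } else {
    eps <- matrix(stats::rnorm(n * n, 0, cfg$cross_scale), n)
    diag(eps) <- runif_in(n, cfg$own_pe_range)
    for (j in seq_len(n)) {
      # spread each column's Cournot deficit uniformly over its
      # off-diagonal entries: a bounded, share-free correction that keeps
      # cross-elasticities at realistic magnitudes even for tiny shares
      others <- setdiff(seq_len(n), j)
      deficit <- -w[j] - sum(w * eps[, j])
      eps[others, j] <- eps[others, j] + deficit / sum(w[others])
    }
  }
  sd <- sd_frac * abs(eps) + 0.005
  pe_matrix(eps, sd = sd, food_id = names(w))
}

#' Generate an Engel-normalized expenditure-elasticity vector
#'
#' Raw elasticities drawn in [0.3, 1.8] then scaled so the share-weighted
#' mean is exactly 1 (Engel aggregation).
#'
#' @param w expenditure shares.
#' @param cfg a [synthetic_config()].
#' @return an [ee_vector()] flagged normalized.
#' @export
make_ee_vector <- function(w, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 2L)
  eta <- stats::runif(length(w), 0.3, 1.8)
  eta <- eta / sum(w * eta)
  ee_vector(eta, food_id = names(w), normalized = TRUE, weights = w)
}

#' Generate a disaggregation scheme
#'
#' Within-group shares drawn from a symmetric Dirichlet (Gamma normalization).
#'
#' @param cfg a [synthetic_config()] (uses `n_groups`, `subfoods_per_group`).
#' @param s,sd_s strengthening scalar and its SD.
#' @return a [disagg_scheme()].
#' @export
make_disagg_scheme <- function(cfg, s = 0.025, sd_s = 0.0125) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 3L)
  k <- cfg$subfoods_per_group
  groups <- sprintf("group%02d", seq_len(cfg$n_groups))
  share <- unlist(lapply(groups, function(g) {
    x <- stats::rgamma(k, shape = 2)
    x / sum(x)
  }))
  disagg_scheme(group_id = rep(groups, each = k),
                sub_food_id = paste0(rep(groups, each = k),
                                     letters[rep(seq_len(k), cfg$n_groups)]),
                share = share, s = s, sd_s = sd_s)
}

#' Generate synthetic health-model inputs
#'
#' A small population (ages 20/40/60, both sexes) with age-increasing
#' all-cause mortality, constant morbidity, and a few chronic diseases with
#' rates in plausible annual ranges.
#'
#' @param cfg a [synthetic_config()].
#' @param n_diseases number of parallel diseases (2 to 4 typical).
#' @param discount_rate annual HALY discount rate.
#' @return list with `pop` (a [population_lifetable()]) and `diseases`
#'   (list of [disease_spec()]).
#' @export
make_health_inputs <- function(cfg, n_diseases = 3, discount_rate = 0) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 4L)
  ages <- c(20, 40, 60)
  cohorts <- expand.grid(age = ages, sex = c("male", "female"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cohorts$count <- round(stats::runif(nrow(cohorts), 500, 1500))
  band <- c(0, 20, 40, 60, 80, 100)
  mort <- expand.grid(age = band, sex = c("male", "female"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mort$rate <- pmin(0.5, 0.001 * exp(0.055 * mort$age) *
                      ifelse(mort$sex == "male", 1.2, 1.0))
  pyld <- mort
  pyld$rate <- pmin(0.3, 0.02 + 0.001 * pyld$age)
  pop <- population_lifetable(cohorts, mortality = mort, pyld = pyld,
                              discount_rate = discount_rate)
  diseases <- lapply(seq_len(n_diseases), function(k) {
    disease_spec(
      name = sprintf("disease%d", k),
      incidence = stats::runif(1, 0.001, 0.01),
      case_fatality = stats::runif(1, 0.01, 0.1),
      remission = stats::runif(1, 0, 0.05),
      disability_weight = stats::runif(1, 0.05, 0.3),
      lag_years = sample(c(0, 10, 20), 1),
      initial_prevalence = stats::runif(1, 0, 0.05))
  })
  list(pop = pop, diseases = diseases)
}
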