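# Monte-Carlo propagation of the three uncertain inputs -- TFEe (Beta),
# the disaggregation scalar (truncated Normal) and the PE-matrix entries
# (Normal, own-PEs capped at 0) -- plus the matching univariate sensitivity
# design (all parameters central except one, set to its 2.5th / 97.5th
# percentile). A single master seed spawns per-iteration substreams so any
# iteration is reproducible in isolation.

#' Uncertainty specification
#'
#' @param tfee a [tfee_spec()] (default Beta(6, 2)).
#' @param scalar_mean,scalar_sd Normal parameters of the disaggregation
#'   scalar, truncated at 0 when sampled (defaults 0.025 and 0.0125).
#' @param pe optional [pe_matrix()] carrying SDs to perturb.
#' @param n_iter Monte-Carlo iterations (default 2000).
#' @param seed master seed.
#' @return object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(tfee = tfee_spec(), scalar_mean = 0.025,
                             scalar_sd = 0.0125, pe = NULL,
                             n_iter = 2000, seed = 1L) {
  stopifnot(inherits(tfee, "tfee_spec"))
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (scalar_sd < 0) stop("scalar_sd must be >= 0")
  if (!is.null(pe)) stopifnot(inherits(pe, "pe_matrix"))
  structure(list(tfee = tfee, scalar_mean = scalar_mean,
                 scalar_sd = scalar_sd, pe = pe,
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "uncertainty_spec")
}

#' Central (expected-value) parameter set of an uncertainty specification
#'
#' @param spec an [uncertainty_spec()].
#' @return list with `tfee`, `scalar`, `pe` at their central values.
#' @export
central_parameters <- function(spec) {
  stopifnot(inherits(spec, "uncertainty_spec"))
  list(tfee = spec$tfee$central, scalar = spec$scalar_mean, pe = spec$pe)
}

#' Draw one parameter set
#'
#' TFEe from its Beta (or fixed) specification; the disaggregation scalar
#' from a Normal truncated at 0 (rejection sampling); each PE entry from a
#' Normal centred on its estimate with the supplied SD, own-PE draws capped
#' at 0 so they can never turn positive. Sampled PE matrices are not
#' re-projected onto the adding-up constraint; use [cournot_residuals()] to
#' diagnose the violation magnitude.
#'
#' @param spec an [uncertainty_spec()].
#' @return list with `tfee`, `scalar`, `pe` (a [pe_matrix()] or NULL).
#' @export
sample_parameters <- function(spec) {
  stopifnot(inherits(spec, "uncertainty_spec"))
  tfee <- sample_tfee(spec$tfee, 1)
  scalar <- stats::rnorm(1, spec$scalar_mean, spec$scalar_sd)
  while (scalar < 0) scalar <- stats::rnorm(1, spec$scalar_mean, spec$scalar_sd)
  pe <- spec$pe
  if (!is.null(pe) && !is.null(pe$sd)) {
    eps <- pe$eps + pe$sd * matrix(stats::rnorm(length(pe$eps)),
                                   nrow(pe$eps))
    diag(eps) <- pmin(diag(eps), 0)
    pe <- pe_matrix(eps, sd = pe$sd, food_id = rownames(pe$eps))
  }
  list(tfee = tfee, scalar = scalar, pe = pe)
}

# independent, reproducible substream seeds from the master seed
iteration_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Monte-Carlo uncertainty propagation
#'
#' Runs `scenario_fn(params)` for `n_iter` independent parameter draws and
#' summarises each named output with its mean and empirical 2.5th / 97.5th
#' percentiles. Iteration k uses its own substream seed, so results are
#' bit-reproducible for a fixed master seed and recoverable in isolation.
#' Failing iterations are recorded and excluded, not fatal.
#'
#' @param scenario_fn function taking the list from [sample_parameters()]
#'   and returning a named numeric vector of outputs.
#' @param spec an [uncertainty_spec()].
#' @return list: `summary` data.frame (output, mean, p2.5, p97.5),
#'   `draws` data.frame (one row per successful iteration: iter, tfee,
#'   scalar, outputs), `n_failed`, `failures` (messages).
#' @export
monte_carlo <- function(scenario_fn, spec) {
  stopifnot(inherits(spec, "uncertainty_spec"))
  seeds <- iteration_seeds(spec$seed, spec$n_iter)
  rows <- vector("list", spec$n_iter)
  failures <- character(0)
  for (k in seq_len(spec$n_iter)) {
    set.seed(seeds[k])
    params <- sample_parameters(spec)
    out <- tryCatch(scenario_fn(params), error = function(e) e)
    if (inherits(out, "error")) {
      failures <- c(failures, sprintf("iter %d: %s", k, conditionMessage(out)))
      next
    }
    rows[[k]] <- c(iter = k, tfee = params$tfee, scalar = params$scalar, out)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("every Monte-Carlo iteration failed")
  draws <- as.data.frame(do.call(rbind, rows))
  outs <- setdiff(names(draws), c("iter", "tfee", "scalar"))
  summ <- data.frame(
    output = outs,
    mean = vapply(outs, function(o) mean(draws[[o]]), numeric(1)),
    p2.5 = vapply(outs, function(o)
      unname(stats::quantile(draws[[o]], 0.025, type = 7)), numeric(1)),
    p97.5 = vapply(outs, function(o)
      unname(stats::quantile(draws[[o]], 0.975, type = 7)), numeric(1)),
    row.names = NULL)
  if (length(failures))
    warning(sprintf("%d of %d iterations failed and were excluded",
                    length(failures), spec$n_iter))
  list(summary = summ, draws = draws, n_failed = length(failures),
       failures = failures)
}

#' Univariate sensitivity analysis
#'
#' Two deterministic runs with one parameter at its 2.5th and 97.5th
#' percentile and everything else central, plus the all-central run. For
#' the default distributions the percentile values are 0.42 / 0.96 (TFEe,
#' Beta(6, 2)) and 0.0005 / 0.0495 (disaggregation scalar, Normal
#' 0.025 +/- 1.96 x 0.0125, floored at 0).
#'
#' @param scenario_fn as in [monte_carlo()].
#' @param spec an [uncertainty_spec()].
#' @param param `"tfee"` or `"disaggregation_scalar"`.
#' @return data.frame with rows `low`, `central`, `high`: the parameter
#'   value used and every scenario output.
#' @export
univariate_sensitivity <- function(scenario_fn, spec,
                                   param = c("tfee", "disaggregation_scalar")) {
  param <- match.arg(param)
  central <- central_parameters(spec)
  vals <- if (param == "tfee") {
    if (!is.null(spec$tfee$fixed)) rep(spec$tfee$fixed, 2)
    else stats::qbeta(c(0.025, 0.975), spec$tfee$alpha, spec$tfee$beta)
  } else {
    pmax(0, normal_ci(spec$scalar_mean, spec$scalar_sd))
  }
  run_at <- function(v) {
    p <- central
    if (param == "tfee") p$tfee <- v else p$scalar <- v
    scenario_fn(p)
  }
  out <- rbind(low = run_at(vals[1]),
               central = scenario_fn(central),
               high = run_at(vals[2]))
  data.frame(run = rownames(out),
             value = c(vals[1], unlist(central[if (param == "tfee") "tfee"
                                               else "scalar"]), vals[2]),
             out, row.names = NULL)
}
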