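# The total food expenditure elasticity (TFEe): % change in total food
# spending per 1% change in the food price index. Economic theory bounds it
# in [0, 1]; its uncertainty is represented by a Beta distribution,
# Beta(6, 2) by default (mean 0.75, 95% interval roughly 0.42 to 0.96).

#' Summary statistics of a Beta-distributed TFEe
#'
#' @param alpha,beta Beta shape parameters (defaults 6 and 2).
#' @return list with `mean`, `median`, `mode`, `p2.5`, `p97.5`. The mode is
#'   `NA` (with a warning) unless both shapes exceed 1.
#' @examples
#' tfee_beta_stats(6, 2) # mean 0.75, median 0.77, mode 0.83
#' @export
tfee_beta_stats <- function(alpha = 6, beta = 2) {
  if (alpha <= 0 || beta <= 0) stop("Beta shapes must be > 0")
  mode <- if (alpha > 1 && beta > 1) (alpha - 1) / (alpha + beta - 2) else {
    warning("Beta mode undefined for shape <= 1")
    NA_real_
  }
  q <- stats::qbeta(c(0.025, 0.5, 0.975), alpha, beta)
  list(mean = alpha / (alpha + beta), median = q[2], mode = mode,
       p2.5 = q[1], p97.5 = q[3])
}

#' Convert an all-food own-price elasticity to a TFEe
#'
#' An unconditional own-PE for "all food combined" of e implies that a 1%
#' rise in the food price index changes quantity by e% and hence spending by
#' (1 + e)%: TFEe = 1 + e.
#'
#' @param own_pe all-food own-price elasticity.
#' @return TFEe (dimensionless).
#' @examples
#' own_pe_to_tfee(-0.168) # 0.832
#' @export
own_pe_to_tfee <- function(own_pe) 1 + own_pe

#' Normal-theory confidence interval
#'
#' `mean +/- z * se` with `z = qnorm(1 - (1 - level) / 2)` (1.959964 at 95%).
#'
#' @param mean point estimate.
#' @param se standard error (>= 0).
#' @param level confidence level in (0, 1).
#' @return numeric vector `c(low, high)`.
#' @examples
#' normal_ci(0.832, 0.1952) # 0.45 to 1.21
#' @export
normal_ci <- function(mean, se, level = 0.95) {
  if (se < 0) stop("se must be >= 0")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = mean - z * se, high = mean + z * se)
}

#' TFEe specification
#'
#' Either a fixed value or a Beta uncertainty distribution, as configured in
#' scenario files (`tfee: {alpha: 6, beta: 2}` or `tfee: {fixed: 0.75}`).
#'
#' @param alpha,beta Beta shapes (ignored when `fixed` is given).
#' @param fixed optional fixed TFEe value.
#' @return object of class `tfee_spec` with a `central` value (Beta mean or
#'   the fixed value).
#' @export
tfee_spec <- function(alpha = 6, beta = 2, fixed = NULL) {
  if (!is.null(fixed)) {
    if (!is.finite(fixed)) stop("fixed TFEe must be finite")
    return(structure(list(fixed = fixed, central = fixed),
                     class = "tfee_spec"))
  }
  if (alpha <= 0 || beta <= 0) stop("Beta shapes must be > 0")
  structure(list(alpha = alpha, beta = beta,
                 central = alpha / (alpha + beta)),
            class = "tfee_spec")
}

#' Draw TFEe values from a specification
#'
#' @param spec a [tfee_spec()].
#' @param n number of draws.
#' @return numeric vector of length n.
#' @export
sample_tfee <- function(spec, n = 1) {
  stopifnot(inherits(spec, "tfee_spec"))
  if (!is.null(spec$fixed)) rep(spec$fixed, n)
  else stats::rbeta(n, spec$alpha, spec$beta)
}
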