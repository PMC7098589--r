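# Disaggregating an aggregate PE matrix (e.g. 23 food groups) to a finer
# food list (e.g. 345 foods). Sub-foods within a group are assumed
# substitutes, so each sub-food's own-PE strengthens (|own| grows) relative
# to the group's, by a scalar s per sub-food; the freed-up response is
# returned as positive within-group cross-PEs allocated in proportion to
# expenditure shares. Between-group cross-PEs are replicated uniformly.
#
# Exact conservation laws, by construction:
#   * diagonal blocks: every row sums to the aggregate own-PE (a uniform 1%
#     price rise across the whole group reproduces the aggregate response);
#   * off-diagonal blocks: any share-weighted re-aggregation reproduces the
#     aggregate cross-PE (entries are constant).

#' Disaggregation scheme
#'
#' Maps each aggregate food group to its sub-foods with within-group
#' expenditure shares, plus the own-PE strengthening scalar.
#'
#' @param group_id character, aggregate group of each sub-food.
#' @param sub_food_id character, unique sub-food labels.
#' @param share within-group expenditure share of each sub-food; shares must
#'   sum to 1 within each group (tolerance 1e-9).
#' @param s own-PE strengthening per additional sub-food, as a fraction
#'   (default 0.025, i.e. 2.5% per sub-food).
#' @param sd_s standard deviation of `s` for Monte-Carlo draws (default 0.0125).
#' @return object of class `disagg_scheme`.
#' @export
disagg_scheme <- function(group_id, sub_food_id, share,
                          s = 0.025, sd_s = 0.0125) {
  group_id <- as.character(group_id)
  sub_food_id <- as.character(sub_food_id)
  share <- as.numeric(share)
  stopifnot(length(group_id) == length(sub_food_id),
            length(share) == length(sub_food_id))
  if (anyDuplicated(sub_food_id)) stop("duplicate sub_food_id")
  if (any(share < 0)) stop("negative within-group share")
  if (s < 0) stop("strengthening scalar s must be >= 0")
  bad <- vapply(split(share, group_id),
                function(x) abs(sum(x) - 1) > 1e-9, logical(1))
  if (any(bad))
    stop("within-group shares do not sum to 1 for group(s): ",
         paste(names(bad)[bad], collapse = ", "))
  structure(list(table = data.frame(group_id = group_id,
                                    sub_food_id = sub_food_id,
                                    share = share,
                                    stringsAsFactors = FALSE),
                 s = s, sd_s = sd_s),
            class = "disagg_scheme")
}

#' @export
print.disagg_scheme <- function(x, ...) {
  cat(sprintf("<disagg_scheme> %d groups -> %d sub-foods, s = %.4g (sd %.4g)\n",
              length(unique(x$table$group_id)), nrow(x$table), x$s, x$sd_s))
  invisible(x)
}

#' Disaggregate one group's own-PE into a within-group block
#'
#' With k sub-foods and scalar s, each sub-food own-PE is
#' `own_sub = own_agg * (1 + k s)` (multiplicative, the default) or
#' `own_sub = own_agg - k s` (additive). The strengthening increment
#' `inc_i = |own_sub_i| - |own_agg|` is redistributed as positive
#' within-group cross-PEs `eps[i, j] = share[j] / (1 - share[i]) * inc_i`,
#' so that each row sums exactly to `own_agg`.
#'
#' @param own_pe aggregate own-price elasticity (<= 0).
#' @param shares within-group expenditure shares (sum to 1).
#' @param s strengthening scalar per sub-food (fraction).
#' @param method `"multiplicative"` or `"additive"` increment.
#' @return k x k numeric matrix (diagonal block of the fine matrix).
#' @examples
#' # five foods, shares 20/40/20/10/10%, s = 2.5%: own-PEs all -1.125 and
#' # cross-PEs onto food 1 of 0.0625, 0.03125, 0.015625, 0.015625
#' disaggregate_group(-1, c(.2, .4, .2, .1, .1), 0.025)[1, ]
#' @export
disaggregate_group <- function(own_pe, shares, s = 0.025,
                               method = c("multiplicative", "additive")) {
  method <- match.arg(method)
  if (own_pe > 0) stop("aggregate own-PE must be <= 0")
  k <- length(shares)
  if (k == 0L) stop("empty group")
  if (abs(sum(shares) - 1) > 1e-9) stop("shares must sum to 1")
  if (k == 1L) return(matrix(own_pe, 1, 1))
  own_sub <- if (method == "multiplicative") own_pe * (1 + k * s)
             else own_pe - k * s
  inc <- abs(own_sub) - abs(own_pe)    # same for every sub-food
  block <- outer(1 / (1 - shares), shares) * inc
  diag(block) <- own_sub
  block
}

#' Disaggregate a between-group cross-PE block
#'
#' Uniform replication: every sub-pair receives the aggregate cross-PE, so
#' any expenditure-weighted re-aggregation of the block reproduces it.
#'
#' @param cross_pe aggregate cross elasticity (group A quantity response to
#'   group B price).
#' @param n_row,n_col numbers of sub-foods in the row (quantity) and column
#'   (price) groups.
#' @return `n_row` x `n_col` matrix.
#' @export
disaggregate_cross_block <- function(cross_pe, n_row, n_col) {
  if (n_row < 1L || n_col < 1L) stop("empty group in cross block")
  matrix(cross_pe, n_row, n_col)
}

#' Disaggregate a full aggregate PE matrix
#'
#' Assembles the fine matrix from [disaggregate_group()] diagonal blocks and
#' [disaggregate_cross_block()] off-diagonal blocks, ordered as in the
#' scheme table.
#'
#' @param pe_agg a [pe_matrix()] whose food_ids are the scheme's group_ids.
#' @param scheme a [disagg_scheme()] covering every aggregate group.
#' @param s optional override of the scheme's strengthening scalar.
#' @param method passed to [disaggregate_group()].
#' @return a [pe_matrix()] over the sub-foods.
#' @export
disaggregate_matrix <- function(pe_agg, scheme, s = NULL,
                                method = c("multiplicative", "additive")) {
  stopifnot(inherits(pe_agg, "pe_matrix"), inherits(scheme, "disagg_scheme"))
  method <- match.arg(method)
  if (is.null(s)) s <- scheme$s
  groups <- rownames(pe_agg$eps)
  missing <- setdiff(groups, scheme$table$group_id)
  if (length(missing))
    stop("scheme missing group(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(scheme$table$group_id, groups)
  if (length(extra))
    stop("scheme has group(s) absent from the matrix: ",
         paste(extra, collapse = ", "))
  idx <- split(seq_len(nrow(scheme$table)), scheme$table$group_id)[groups]
  n_fine <- nrow(scheme$table)
  fine <- matrix(0, n_fine, n_fine)
  pos <- lapply(idx, function(i) i)  # row/col positions per group
  for (gi in seq_along(groups)) {
    ri <- pos[[gi]]
    for (gj in seq_along(groups)) {
      cj <- pos[[gj]]
      fine[ri, cj] <- if (gi == gj)
        disaggregate_group(pe_agg$eps[gi, gi],
                           scheme$table$share[ri], s, method)
      else
        disaggregate_cross_block(pe_agg$eps[gi, gj], length(ri), length(cj))
    }
  }
  ids <- scheme$table$sub_food_id
  pe_matrix(fine, food_id = ids)
}

#' Adding-up diagnostics for a disaggregated matrix
#'
#' Checks the conservation laws the disaggregation is built to satisfy.
#' For each diagonal (within-group) block, the residual is the maximum
#' absolute difference between a sub-food row sum and the aggregate own-PE
#' (a uniform 1% within-group price change must reproduce the aggregate
#' response). For each off-diagonal block, the residual is the difference
#' between the share-weighted re-aggregated block and the aggregate
#' cross-PE.
#'
#' @param pe_fine fine [pe_matrix()] from [disaggregate_matrix()].
#' @param pe_agg the aggregate [pe_matrix()].
#' @param scheme the [disagg_scheme()] used.
#' @return data.frame with columns `row_group`, `col_group`, `residual`.
#' @export
check_adding_up <- function(pe_fine, pe_agg, scheme) {
  stopifnot(inherits(pe_fine, "pe_matrix"), inherits(pe_agg, "pe_matrix"),
            inherits(scheme, "disagg_scheme"))
  groups <- rownames(pe_agg$eps)
  idx <- split(seq_len(nrow(scheme$table)), scheme$table$group_id)[groups]
  out <- expand.grid(row_group = groups, col_group = groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$residual <- NA_real_
  for (r in seq_len(nrow(out))) {
    ri <- idx[[out$row_group[r]]]
    cj <- idx[[out$col_group[r]]]
    blk <- pe_fine$eps[ri, cj, drop = FALSE]
    agg <- pe_agg$eps[out$row_group[r], out$col_group[r]]
    out$residual[r] <- if (out$row_group[r] == out$col_group[r]) {
      max(abs(rowSums(blk) - agg))
    } else {
      wr <- scheme$table$share[ri]
      wc <- scheme$table$share[cj]
      abs(sum(wr * (blk %*% wc)) - agg)
    }
  }
  out
}

#' Cournot-aggregation residuals of a PE matrix
#'
#' For a complete demand system, budget-share-weighted column sums satisfy
#' `sum_i w_i eps[i, j] = -w_j` (Cournot aggregation). Returns the per-column
#' residual `sum_i w_i eps[i, j] + w_j`; zero means the constraint holds.
#'
#' @param pe a [pe_matrix()].
#' @param w expenditure shares (sum to 1).
#' @return named numeric vector of residuals, one per price column.
#' @export
cournot_residuals <- function(pe, w) {
  stopifnot(inherits(pe, "pe_matrix"))
  if (abs(sum(w) - 1) > 1e-8) stop("shares must sum to 1")
  if (length(w) != nrow(pe$eps)) stop("share vector length mismatch")
  stats::setNames(as.vector(w %*% pe$eps) + w, colnames(pe$eps))
}
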