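# Independent, spreadsheet-style oracles and small fixture builders.
# The oracles deliberately use plain element-by-element loops and never call
# the package's vectorised implementations.

# full two-step recomputation (conditional application + rescale, then
# expenditure-elasticity allocation with the closing scalar)
oracle_two_step <- function(q_b, p_b, p_a, eps, eta, tfee) {
  n <- length(q_b)
  x_b <- 0
  for (i in 1:n) x_b <- x_b + q_b[i] / 100 * p_b[i]
  dq_pe <- numeric(n)
  for (i in 1:n)
    for (j in 1:n)
      dq_pe[i] <- dq_pe[i] + (p_a[j] / p_b[j] - 1) * eps[i, j]
  x_pe <- 0
  for (i in 1:n) x_pe <- x_pe + (1 + dq_pe[i]) * q_b[i] / 100 * p_a[i]
  dq_pes <- numeric(n)
  for (i in 1:n) dq_pes[i] <- x_b / x_pe * (1 + dq_pe[i]) - 1
  fpi <- 0
  for (i in 1:n) fpi <- fpi + q_b[i] / 100 * p_a[i]
  fpi <- fpi / x_b - 1
  d_x <- fpi * tfee * x_b
  dq_ee <- numeric(n)
  for (i in 1:n) dq_ee[i] <- fpi * tfee * eta[i] * (1 + dq_pes[i]) * q_b[i]
  dx_ee <- 0
  for (i in 1:n) dx_ee <- dx_ee + dq_ee[i] / 100 * p_a[i]
  scal <- if (d_x == 0) 0 else d_x / dx_ee
  q_a <- numeric(n)
  for (i in 1:n) q_a[i] <- scal * dq_ee[i] + dq_pes[i] * q_b[i] + q_b[i]
  x_a <- 0
  for (i in 1:n) x_a <- x_a + q_a[i] / 100 * p_a[i]
  list(q_a = q_a, x_a = x_a, x_b = x_b, d_x = d_x, fpi = fpi,
       dq_pes = dq_pes)
}

# cycle-by-cycle single-disease lifetable recomputation with scalar
# arithmetic (constant rates, one cohort per call)
oracle_lifetable_cohort <- function(count, mort, pyld, inc, cfr, rem, dw,
                                    pif, lag, horizon, disc_rate = 0,
                                    prev0 = 0) {
  l_b <- l_i <- count
  pv_b <- pv_i <- prev0
  h_b <- h_i <- 0
  for (t in 0:(horizon - 1)) {
    inc_i <- if (t >= lag) inc * (1 - pif) else inc
    m_b <- mort
    m_i <- mort + cfr * (pv_i - pv_b)
    mb_b <- pyld
    mb_i <- pyld + dw * (pv_i - pv_b)
    w <- (1 / (1 + disc_rate))^t
    h_b <- h_b + w * l_b * (1 - m_b / 2) * (1 - mb_b)
    h_i <- h_i + w * l_i * (1 - m_i / 2) * (1 - mb_i)
    l_b <- l_b * (1 - m_b)
    l_i <- l_i * (1 - m_i)
    pv_b <- pv_b + inc * (1 - pv_b) - (cfr + rem) * pv_b
    pv_i <- pv_i + inc_i * (1 - pv_i) - (cfr + rem) * pv_i
  }
  c(bau = h_b, int = h_i, gain = h_i - h_b)
}

# random scenario bundle: Cournot-consistent system + Engel-normalized EEs
# + a random mixed policy
random_bundle <- function(seed, n_groups = 6) {
  cfg <- synthetic_config(n_groups = n_groups, seed = seed)
  fs <- make_food_system(cfg)
  w <- expenditure_shares(fs)
  list(fs = fs, w = w,
       pe = make_pe_matrix(w, cfg),
       ee = make_ee_vector(w, cfg),
       cfg = cfg)
}

random_policy <- function(fs, seed) {
  set.seed(seed)
  kind <- seed %% 3
  if (kind == 0) {
    policy_spec("rand safa tax",
                nutrient_taxes = c(safa = stats::runif(1, 0.5, 3)))
  } else if (kind == 1) {
    policy_spec("rand sugar tax",
                nutrient_taxes = c(sugar = stats::runif(1, 0.1, 1)))
  } else {
    k <- sample(nrow(fs), max(1, nrow(fs) %/% 3))
    policy_spec("rand subsidy",
                ad_valorem = stats::setNames(stats::runif(length(k), -0.3, -0.05),
                                             fs$food_id[k]))
  }
}
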