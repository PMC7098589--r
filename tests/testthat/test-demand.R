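test_that("total_expenditure applies the per-100g convention", {
  expect_equal(total_expenditure(c(100, 200), c(1.00, 0.50)), 2.00)
  expect_equal(total_expenditure(c(0, 0), c(1, 2)), 0)
  expect_equal(total_expenditure(300, 2.00), 6.00)
  expect_error(total_expenditure(c(1, 2), 1), "equal length")
  expect_error(total_expenditure(100, -1), "> 0")
})

test_that("apply_policy composes nutrient taxes and ad valorem changes", {
  fs <- food_system(c("butter", "apple"), price = c(2.00, 1.00),
                    quantity = c(20, 100), energy = c(3000, 250),
                    nutrients = data.frame(safa = c(50, 0), sugar = c(1, 10)))
  # 50 g SAFA / 100 g at $2 per 100 g SAFA adds $1 per 100 g food
  p <- apply_policy(fs, policy_spec(nutrient_taxes = c(safa = 2)))
  expect_equal(unname(p), c(3.00, 1.00))
  # empty policy is the identity
  expect_equal(unname(apply_policy(fs, policy_spec())), fs$price)
  # 20% subsidy multiplies after the specific tax
  p2 <- apply_policy(fs, policy_spec(ad_valorem = c(apple = -0.2)))
  expect_equal(unname(p2), c(2.00, 0.80))
  both <- apply_policy(fs, policy_spec(nutrient_taxes = c(safa = 2),
                                       ad_valorem = c(butter = -0.5)))
  expect_equal(unname(both), c(1.50, 1.00))
  expect_error(apply_policy(fs, policy_spec(nutrient_taxes = c(sodium = 1))),
               "unknown nutrient")
  expect_error(policy_spec(ad_valorem = c(apple = -1)), "> -1")
})

test_that("fpi_percent_change is Laspeyres with base quantities", {
  fs <- food_system(c("a", "b"), price = c(1, 2), quantity = c(200, 100),
                    energy = 0)
  expect_equal(fpi_percent_change(fs, fs$price), 0)
  # equal expenditures, one price +10% -> +5%
  expect_equal(fpi_percent_change(fs, c(1.1, 2)), 5)
  expect_equal(fpi_percent_change(fs, fs$price * 1.2), 20)
})

test_that("conditional_step matches the two-food worked example", {
  fs <- food_system(c("a", "b"), price = c(1, 1), quantity = c(100, 100),
                    energy = 0)
  pe <- pe_matrix(diag(c(-1, -1)))
  p_a <- c(1.1, 1)  # +10% tax on food a
  s1 <- conditional_step(fs, p_a, pe)
  expect_equal(unname(s1$dq_pe), c(-0.1, 0))
  expect_equal(s1$x_pe, 1.99)
  expect_equal(unname(s1$dq_pes), c(2 / 1.99 * 0.9 - 1, 2 / 1.99 - 1))
  # guarantee: post-price expenditure back to baseline
  expect_equal(total_expenditure((1 + s1$dq_pes) * fs$quantity, p_a), 2.00,
               tolerance = 1e-12)
  # no price change -> identically zero
  s0 <- conditional_step(fs, fs$price, pe)
  expect_equal(unname(s0$dq_pes), c(0, 0))
})

test_that("extreme elasticities clamp at zero consumption with a warning", {
  fs <- food_system(c("a", "b"), price = c(1, 1), quantity = c(100, 100),
                    energy = 0)
  pe <- pe_matrix(rbind(c(-8, 0), c(0, -1)))
  expect_warning(s1 <- conditional_step(fs, c(1.5, 1), pe), "clamped")
  expect_true(all(1 + s1$dq_pes >= 0))
  expect_equal(total_expenditure((1 + s1$dq_pes) * fs$quantity, c(1.5, 1)),
               2, tolerance = 1e-12)
})

test_that("expenditure_step hits the TFEe expenditure target exactly", {
  b <- random_bundle(7)
  pol <- policy_spec("10% tax", ad_valorem = 0.10)
  p_a <- apply_policy(b$fs, pol)
  s1 <- conditional_step(b$fs, p_a, b$pe)
  res <- expenditure_step(b$fs, p_a, s1, b$ee, tfee = 0.75)
  fpi <- fpi_percent_change(b$fs, p_a) / 100
  expect_equal(res$x_a, res$x_b * (1 + fpi * 0.75), tolerance = 1e-12)
  expect_equal(res$x_a, total_expenditure(res$q_a, res$p_a))
  # tfee = 0 forces X_A = X_B
  res0 <- expenditure_step(b$fs, p_a, s1, b$ee, tfee = 0)
  expect_equal(res0$x_a, res0$x_b, tolerance = 1e-12)
  # uniform eta = 1, FPI +4%: X_A = 1.03 X_B
  fs <- food_system(c("a", "b"), price = c(1, 1), quantity = c(100, 100),
                    energy = 0)
  pe <- pe_matrix(diag(c(-1, -1)))
  pol4 <- policy_spec(ad_valorem = 0.04)
  pa4 <- apply_policy(fs, pol4)
  r4 <- expenditure_step(fs, pa4, conditional_step(fs, pa4, pe),
                         ee = c(1, 1), tfee = 0.75)
  expect_equal(r4$x_a, 1.03 * r4$x_b, tolerance = 1e-12)
})

test_that("null policy is the identity in both modes", {
  b <- random_bundle(11)
  for (mode in c("conventional", "tfee_adjusted")) {
    res <- run_policy_scenario(b$fs, policy_spec(), b$pe, b$ee, 0.75,
                               mode = mode)
    expect_equal(unname(res$q_a), b$fs$quantity)
    expect_equal(res$x_a, res$x_b)
    expect_true(all(abs(res$summaries$pct_change) < 1e-12))
  }
})

test_that("revealed TFEe reproduces the published diagnostic arithmetic", {
  expect_equal(round(revealed_tfee(-1.92, 3.91), 2), -0.49)
  expect_equal(round(revealed_tfee(0.72, -3.27), 2), -0.22)
  expect_error(revealed_tfee(1, 0), "zero")
})

test_that("revealed TFEe is a fixed point of the adjusted model", {
  for (seed in c(3, 17, 29)) {
    b <- random_bundle(seed)
    pol <- random_policy(b$fs, seed)
    for (t in c(0.2, 0.75, 1)) {
      res <- run_policy_scenario(b$fs, pol, b$pe, b$ee, t)
      expect_equal(revealed_tfee(res), t, tolerance = 1e-9)
    }
  }
})

test_that("step conservation laws hold on random systems and policies", {
  for (seed in 1:25) {
    b <- random_bundle(seed, n_groups = 5 + seed %% 4)
    pol <- random_policy(b$fs, seed)
    p_a <- apply_policy(b$fs, pol)
    # clamping at zero consumption may fire in extreme draws; conservation
    # must survive it
    s1 <- suppressWarnings(conditional_step(b$fs, p_a, b$pe))
    x_b <- total_expenditure(b$fs$quantity, b$fs$price)
    expect_equal(total_expenditure((1 + s1$dq_pes) * b$fs$quantity, p_a),
                 x_b, tolerance = 1e-9)
    res <- suppressWarnings(run_policy_scenario(b$fs, pol, b$pe, b$ee, 0.6))
    expect_equal(res$x_a, x_b * (1 + res$fpi_pct / 100 * 0.6),
                 tolerance = 1e-9)
  }
})

test_that("quantities are non-decreasing in TFEe under a pure tax", {
  b <- random_bundle(5)
  expect_true(all(as.numeric(b$ee) > 0))
  pol <- policy_spec("uniform tax", ad_valorem = 0.08)  # FPI > 0
  grid <- seq(0, 1, by = 0.25)
  qs <- sapply(grid, function(t)
    run_policy_scenario(b$fs, pol, b$pe, b$ee, t)$q_a)
  expect_true(all(diff(t(qs)) >= -1e-12))
})

test_that("two-step output matches the brute-force oracle on tiny systems", {
  n_valid <- 0
  for (seed in 1:50) {
    n <- 2 + seed %% 3  # 2 to 4 foods
    b <- random_bundle(seed + 100, n_groups = n)
    pol <- random_policy(b$fs, seed + 100)
    p_a <- apply_policy(b$fs, pol)
    dp <- unname(p_a / b$fs$price - 1)
    if (any(1 + as.vector(b$pe$eps %*% dp) < 0)) next  # outside Eq domain
    n_valid <- n_valid + 1
    res <- run_policy_scenario(b$fs, pol, b$pe, b$ee, 0.75)
    ora <- oracle_two_step(b$fs$quantity, b$fs$price, unname(res$p_a),
                           b$pe$eps, as.numeric(b$ee), 0.75)
    expect_equal(unname(res$q_a), ora$q_a, tolerance = 1e-12)
    expect_equal(res$x_a, ora$x_a, tolerance = 1e-12)
    expect_equal(unname(res$dq_pes), ora$dq_pes, tolerance = 1e-12)
  }
  expect_gte(n_valid, 45)
})

test_that("conventional mode skips both rescaling steps", {
  d <- box_demo_systems()
  res <- run_policy_scenario(d$setting_b, d$policy, d$pe,
                             mode = "conventional")
  # raw Eq-2 application: q_a = (1 + eps %*% dp) * q_b
  dp <- unname(res$p_a / d$setting_b$price - 1)
  expect_equal(unname(res$q_a),
               as.vector((1 + d$pe$eps %*% dp)) * d$setting_b$quantity)
  # and expenditure is NOT conserved in the transplanted setting
  expect_gt(abs(res$x_a - res$x_b), 1e-6)
})
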