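test_that("steady-state fold is the product of mechanism factors", {
  p <- expression_params(k_m = 10, k_p = 10, d_m = 6, d_p = 1)
  expect_equal(steady_state_fold(p, knockdown_config()), 1)
  expect_equal(steady_state_fold(p, knockdown_config(crispri_block = 68 / 69)),
               69)
  expect_equal(steady_state_fold(p, knockdown_config(srna_extra_decay = 9 * 6)),
               10)
  expect_equal(steady_state_fold(p, knockdown_config(protease_extra_decay = 4)),
               5)
  # multiplicativity across mechanisms
  kA <- knockdown_config(crispri_block = 0.9)
  kB <- knockdown_config(srna_extra_decay = 12)
  kAB <- knockdown_config(crispri_block = 0.9, srna_extra_decay = 12)
  expect_equal(steady_state_fold(p, kAB),
               steady_state_fold(p, kA) * steady_state_fold(p, kB))
})

test_that("calibration inverts the closed form for each mechanism", {
  p <- expression_params()
  for (mech in c("crispri", "srna", "protease")) {
    k <- calibrate_knockdown(42, mech, p)
    expect_equal(steady_state_fold(p, k), 42, tolerance = 1e-12)
  }
  expect_error(knockdown_config(crispri_block = 1), "\\[0, 1\\)")
})

test_that("the ODE trajectory reaches the closed-form fold", {
  p <- expression_params()
  for (mech in c("crispri", "srna", "protease")) {
    k <- calibrate_knockdown(20, mech, p, induction_time = 1)
    tc <- simulate_knockdown(p, k, horizon = 30, dt = 0.005)
    expect_equal(tail(tc$values, 1), 1 / 20, tolerance = 1e-6)
    # flat at 1 before induction, monotone non-increasing after
    pre <- tc$values[tc$times <= k$induction_time]
    expect_true(all(abs(pre - 1) < 1e-9))
    post <- tc$values[tc$times >= k$induction_time]
    expect_true(all(diff(post) <= 1e-12))
  }
  # mechanisms off: flat at 1 throughout
  flat <- simulate_knockdown(p, knockdown_config(), horizon = 10)
  expect_true(all(abs(flat$values - 1) < 1e-9))
})

test_that("protein removal outpaces transcript run-out at equal fold", {
  # eigenvalue oracle: after induction the protein relaxes through modes
  # exp(-d_m_eff t) and exp(-d_p_eff t); proteolysis acts on the protein
  # directly, so at equal final folds its 50%-reduction time is earlier
  # whenever protease_extra_decay > d_m
  p <- expression_params(k_m = 10, k_p = 10, d_m = 2, d_p = 0.5)
  fold <- 8
  k_cr <- calibrate_knockdown(fold, "crispri", p, induction_time = 1)
  k_pr <- calibrate_knockdown(fold, "protease", p, induction_time = 1)
  expect_gt(k_pr$protease_extra_decay, p$d_m)
  t50 <- function(k) {
    tc <- simulate_knockdown(p, k, horizon = 40, dt = 0.002)
    crossing_time(tc, 0.5, "down")
  }
  expect_lt(t50(k_pr), t50(k_cr))
})

test_that("adding proteolysis to CRISPRi never slows the knockdown", {
  p <- expression_params()
  k_cr <- calibrate_knockdown(69, "crispri", p, induction_time = 2)
  k_both <- knockdown_config(crispri_block = k_cr$crispri_block,
                             protease_extra_decay = 3, induction_time = 2)
  tc_cr <- simulate_knockdown(p, k_cr, horizon = 20, dt = 0.005)
  tc_both <- simulate_knockdown(p, k_both, horizon = 20, dt = 0.005)
  expect_true(all(tc_both$values <= tc_cr$values + 1e-9))
})

test_that("fold estimation from populations recovers the median ratio", {
  pre <- generate_population(median = 1000, cv = 0.4, n_cells = 1e4,
                             seed = 21)
  same <- generate_population(median = 1000, cv = 0.4, n_cells = 1e4,
                              seed = 22)
  est1 <- estimate_fold(pre, same, seed = 5)
  expect_equal(est1$fold, 1, tolerance = 0.05)
  expect_true(est1$ci[1] <= 1 && 1 <= est1$ci[2])

  post <- generate_population(median = 1000 / 69, cv = 0.4, n_cells = 1e4,
                              seed = 23)
  est69 <- estimate_fold(pre, post, seed = 5)
  expect_equal(est69$fold, 69, tolerance = 0.05)

  zeros <- estimate_fold(pre, rep(0, 100), seed = 5)
  expect_true(zeros$infinite)
  expect_equal(zeros$fold, Inf)
  expect_error(estimate_fold(pre[1:10], post), ">= 50")
})

test_that("knockdown guards catch unresolvable configurations", {
  p <- expression_params()
  k <- calibrate_knockdown(10, "srna", p)
  expect_error(simulate_knockdown(p, k, horizon = 10, dt = 0.5),
               "timescale")
  expect_error(simulate_knockdown(p, knockdown_config(induction_time = 20),
                                  horizon = 10), "horizon")
})

test_that("knockdown scenarios load from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    params = list(k_m = 5, k_p = 2, d_m = 3, d_p = 0.8),
    mechanisms = list(crispri_block = 0.9, induction_time = 1),
    horizon = 12), path)
  sc <- read_knockdown_scenario(path)
  expect_equal(sc$params$k_m, 5)
  expect_equal(sc$config$crispri_block, 0.9)
  expect_equal(sc$horizon, 12)
  expect_equal(steady_state_fold(sc$params, sc$config), 10)
})
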