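# outcomes_accounting: discounting, cost and QALY accrual, summaries

test_that("discount factors follow 1/(1+r)^t", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(10, 0.03), 0.744093914897, tolerance = 1e-10)
  expect_equal(discount_factor(c(1, 7, 30), 0), rep(1, 3))
  expect_error(discount_factor(5, -0.01), ">= 0")
})

test_that("a zero-risk cohort accrues no costs", {
  p <- accounting_params()
  tr <- run_cohort(strategy_natural_history("MSH2"), p, zero_onset_pair())
  expect_equal(accumulate_costs(tr, p), 0)
  expect_equal(summarize_trace(tr, p)$total_incidence, 0)
  expect_equal(summarize_trace(tr, p)$total_mortality, 0)
})

test_that("one scheduled surgery discounts from the model start", {
  # deathless, risk-free world: hyst-BSO at 40 costs 8922 at t = 15
  p <- accounting_params()
  tr <- run_cohort(strategy(40, 40, Inf, gene = "MSH2"), p,
                   zero_onset_pair())
  expect_equal(accumulate_costs(tr, p), 5726.69229467, tolerance = 1e-8)
  # the 2-stage approach adds the oophorectomy at t = 25
  tr2 <- run_cohort(strategy(40, 50, Inf, gene = "MSH2"), p,
                    zero_onset_pair())
  expect_equal(accumulate_costs(tr2, p),
               8922 * 1.03^-15 + 6155 * 1.03^-25, tolerance = 1e-8)
})

test_that("surveillance billing separates the first encounter", {
  p <- accounting_params()
  p <- param_set(p, "ec_screen_spec", 1)
  p <- param_set(p, "oc_screen_spec", 1)  # no false positives
  tr <- run_cohort(strategy(surveillance_start = 30, gene = "MSH2"), p,
                   zero_onset_pair())
  # screens at ages 30..74: one initial encounter, 44 subsequent
  expected <- 1920 * 1.03^-5 + 1376 * sum(1.03^-(6:49))
  expect_equal(accumulate_costs(tr, p), expected, tolerance = 1e-8)
})

test_that("perfect utilities without discounting reproduce life-years", {
  p <- accounting_params(life_table = constant_life_table(0.01))
  for (nm in c("util_healthy_start", "util_healthy_end"))
    p <- param_set(p, nm, 1)
  tr <- run_cohort(strategy_natural_history("MSH2"), p, zero_onset_pair())
  ly <- summarize_trace(tr, p)$life_years
  q_trap <- accumulate_qalys(tr, p, rate = 0, accrual = "trapezoid")
  expect_equal(q_trap, ly, tolerance = 1e-12)
  # cycle-end accrual is the conservative variant
  q_end <- accumulate_qalys(tr, p, rate = 0)
  expect_lt(q_end, q_trap)
  expect_lt(q_trap - q_end, 1)  # within one cycle's utility
})

test_that("QALYs never exceed life-years", {
  for (gene in c("MLH1", "PMS2")) {
    res <- evaluate_strategies(base_params(gene), onset = base_onset(gene))
    expect_true(all(res$qalys <= res$life_years))
    expect_true(all(res$ec_incidence >= res$ec_mortality))
    expect_true(all(res$oc_incidence >= res$oc_mortality))
    expect_equal(res$total_incidence, res$ec_incidence + res$oc_incidence)
  }
})

test_that("removing discounting weakly increases costs and QALYs", {
  p <- base_params("MSH2")
  on <- base_onset("MSH2")
  for (s in list(strategy(40, 40, 30, gene = "MSH2"),
                 strategy_natural_history("MSH2"))) {
    tr <- run_cohort(s, p, on)
    expect_gte(accumulate_costs(tr, p, rate = 0), accumulate_costs(tr, p))
    expect_gte(accumulate_qalys(tr, p, rate = 0), accumulate_qalys(tr, p))
  }
})

test_that("costs are linear in each unit cost", {
  p <- base_params("MSH2")
  on <- base_onset("MSH2")
  tr <- run_cohort(strategy(40, 40, 30, gene = "MSH2"), p, on)
  for (nm in c("cost_hysterectomy", "cost_oc_terminal",
               "cost_surveillance_subsequent", "cost_ec_continuing")) {
    base <- param_get(p, nm)
    f0 <- accumulate_costs(tr, p)
    f1 <- accumulate_costs(tr, param_set(p, nm, base + 100))
    f2 <- accumulate_costs(tr, param_set(p, nm, base + 200))
    expect_equal(f2 - f1, f1 - f0, tolerance = 1e-8)
    expect_gte(f1, f0)
  }
})

test_that("surgical complications carry the blended utility decrement", {
  # deathless world, one operation: the QALY difference between a 3%
  # complication rate and none is 0.03 * (-0.0425 + 0.025) * disc(15)
  p0 <- accounting_params()
  p3 <- param_set(p0, "complication_prob", 0.03)
  s <- strategy(40, 40, Inf, gene = "MSH2")
  q0 <- accumulate_qalys(run_cohort(s, p0, zero_onset_pair()), p0)
  q3 <- accumulate_qalys(run_cohort(s, p3, zero_onset_pair()), p3)
  expect_equal(q3 - q0, 0.03 * (-0.0425 + 0.025) * 1.03^-15,
               tolerance = 1e-10)
})

test_that("early surgical menopause applies its utility until age 50", {
  # deathless, risk-free world with flat healthy utility: BSO at 40 scales
  # the nine cycle-end rows at ages 41..49 by 0.90
  p <- accounting_params()
  for (nm in c("util_healthy_start", "util_healthy_end"))
    p <- param_set(p, nm, 1)
  p <- param_set(p, "disutil_surgery", 0)
  tr <- run_cohort(strategy(40, 40, Inf, gene = "MSH2"), p,
                   zero_onset_pair())
  expect_equal(accumulate_qalys(tr, p, rate = 0), 50 - 9 * 0.10,
               tolerance = 1e-10)
  # the 2-stage approach retains full utility (hyst-BS multiplier is 1.00)
  p2 <- param_set(p, "cost_oophorectomy", 6155)  # unchanged; clarity only
  tr2 <- run_cohort(strategy(40, 50, Inf, gene = "MSH2"), p2,
                    zero_onset_pair())
  expect_equal(accumulate_qalys(tr2, p2, rate = 0), 50, tolerance = 1e-10)
})
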