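# cohort_engine: strategy grid, screening algebra, transition rows, traces

test_that("the default strategy grid holds the twelve published arms", {
  for (gene in c("MLH1", "PMS2")) {
    ss <- enumerate_strategies(gene)
    expect_length(ss, 12)
    labels <- vapply(ss, `[[`, character(1), "label")
    expect_true("2-stage approach" %in% labels)
    expect_true("Natural history" %in% labels)
    expect_true("Hyst-BSO: 35, survey: 30" %in% labels)
    expect_false("Hyst-BSO: 35, survey: 35" %in% labels)  # incoherent
    for (s in ss) {
      fin <- Filter(is.finite, c(s$hyst_age, s$ooph_age,
                                 s$surveillance_start))
      if (length(fin)) expect_true(min(fin) >= 30)
    }
  }
  expect_error(strategy(hyst_age = 28), "before age 30")
  expect_error(strategy(hyst_age = 40, ooph_age = 35), ">= hyst_age")
  expect_error(strategy(hyst_age = 40, surveillance_start = 45),
               "incoherent")
})

test_that("a JSON grid file overrides the default strategies", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    list(hyst_age = 40, ooph_age = 50, surveillance_start = "never",
         label = "staged"),
    list(hyst_age = "never", surveillance_start = 30)
  ), auto_unbox = TRUE), f)
  ss <- enumerate_strategies("MLH1", grid_path = f)
  expect_length(ss, 2)
  expect_equal(ss[[1]]$label, "staged")
  expect_equal(ss[[1]]$ooph_age, 50)
  expect_equal(ss[[2]]$label, "Surveillance: 30")
})

test_that("screening algebra multiplies risks by test characteristics", {
  r <- screen_cycle_probabilities(0.01, 0, ec_sens = 0.91, ec_spec = 0.98,
                                  oc_sens = 0.60, oc_spec = 0.962)
  expect_equal(r$TP_EC, 0.0091)
  expect_equal(r$FN_EC, 0.0009)
  expect_equal(r$FP_any, 0.99 * 0.05724, tolerance = 1e-12)
  # cancer-free false-positive rate is the complement of joint specificity
  r2 <- screen_cycle_probabilities(0, 0, 0.91, 0.98, 0.60, 0.962)
  expect_equal(r2$FP_any, 0.05724, tolerance = 1e-12)
  # perfect sensitivity leaves no false negatives
  r3 <- screen_cycle_probabilities(0.3, 0.2, 1, 0.98, 1, 0.962)
  expect_equal(r3$FN_EC, 0)
  expect_equal(r3$FN_OC, 0)
  # outputs are a partition of unity
  expect_equal(r$TP_EC + r$FN_EC + r$TP_OC + r$FN_OC + r$FP_any + r$TN, 1)
  expect_error(screen_cycle_probabilities(1.2, 0, 0.9, 0.9, 0.9, 0.9),
               "probabilities")
})

test_that("relative survival converts to annual death probabilities", {
  expect_equal(annual_cancer_death_prob(0.168), 0.300058318754,
               tolerance = 1e-10)
  expect_equal(annual_cancer_death_prob(0.924), 0.015684340766,
               tolerance = 1e-10)
  expect_equal(annual_cancer_death_prob(1), 0)
  expect_error(annual_cancer_death_prob(0), "\\(0, 1\\]")
})

test_that("every transition row is stochastic for every state and age", {
  p <- base_params("MSH2")
  on <- base_onset("MSH2")
  strategies <- list(strategy_natural_history("MSH2"),
                     strategy(40, 40, 30, gene = "MSH2"),
                     strategy(40, 50, Inf, gene = "MSH2"),
                     strategy(surveillance_start = 30, gene = "MSH2"))
  for (s in strategies) {
    for (age in c(25, 30, 39, 40, 49, 50, 60, 74)) {
      for (st in model_states()) {
        row <- build_transition(age, st, p, s, on)
        expect_equal(sum(row), 1, tolerance = 1e-12)
        expect_true(all(row >= 0))
      }
    }
  }
  # death states are absorbing
  row <- build_transition(50, "death_EC", p,
                          strategy_natural_history("MSH2"), on)
  expect_equal(unname(row["death_EC"]), 1)
})

test_that("post-surgical states carry no residual cancer risk", {
  p <- base_params("MLH1")
  on <- base_onset("MLH1")
  s <- strategy(40, 50, Inf, gene = "MLH1")
  row <- build_transition(45, "post_hystBSO_early", p, s, on)
  expect_equal(sum(row[c("EC_local", "EC_regional", "EC_distant",
                         "OC_local", "OC_regional", "OC_distant")]), 0)
  # ovaries retained in the 2-stage interval: OC risk persists at the
  # calibrated rate times the salpingectomy risk ratio (1.0 base)
  row2 <- build_transition(45, "post_hystBS", p, s, on)
  oc_mass <- sum(row2[c("OC_local", "OC_regional", "OC_distant")])
  po <- on$oc$p[on$oc$age == 45]
  expect_equal(oc_mass, (1 - p$life_table$qx[p$life_table$age == 45]) * po,
               tolerance = 1e-12)
  expect_equal(sum(row2[c("EC_local", "EC_regional", "EC_distant")]), 0)
})

test_that("the cohort trace matches the transition-matrix product", {
  # oracle equivalence: the flow-based loop must reproduce iterated
  # multiplication of the build_transition rows
  p <- base_params("MSH2")
  on <- base_onset("MSH2")
  for (s in list(strategy(40, 40, 30, gene = "MSH2"),
                 strategy(40, 50, Inf, gene = "MSH2"))) {
    tr <- run_cohort(s, p, on)
    occ <- c(1, rep(0, 15))
    for (i in seq(25, 74)) {
      M <- t(vapply(model_states(), function(st)
        build_transition(i, st, p, s, on), numeric(16)))
      occ <- as.numeric(occ %*% M)
      expect_equal(unname(tr$occupancy[i - 23, ]), occ, tolerance = 1e-12)
    }
  }
})

test_that("cohort mass is conserved at every cycle", {
  for (gene in c("MSH2", "PMS2")) {
    p <- base_params(gene)
    on <- base_onset(gene)
    for (s in enumerate_strategies(gene)) {
      tr <- run_cohort(s, p, on)
      expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
      expect_true(all(tr$occupancy >= -1e-15))
    }
  }
})

test_that("a three-state toy chain matches its geometric closed form", {
  q <- 0.01
  p <- load_parameters(gene = "MSH2", life_table = constant_life_table(q))
  tr <- run_cohort(strategy_natural_history("MSH2"), p, zero_onset_pair())
  t <- 0:50
  expect_equal(unname(tr$occupancy[, "healthy"]), (1 - q)^t,
               tolerance = 1e-10)
  expect_equal(unname(tr$occupancy[, "death_other"]), 1 - (1 - q)^t,
               tolerance = 1e-10)
  expect_equal(sum(tr$flows$new_ec) + sum(tr$flows$new_oc), 0)
})

test_that("perfect screening leaves the undetected states empty", {
  p <- base_params("MSH2")
  p <- param_set(p, "ec_screen_sens", 1)
  p <- param_set(p, "oc_screen_sens", 1)
  tr <- run_cohort(strategy(surveillance_start = 30, gene = "MSH2"), p,
                   base_onset("MSH2"))
  expect_equal(sum(tr$occupancy[, c("undetected_EC", "undetected_OC")]), 0)
})

test_that("undetected cancers are diagnosed exactly one cycle later", {
  p <- base_params("MSH2")
  on <- base_onset("MSH2")
  tr <- run_cohort(strategy(surveillance_start = 30, gene = "MSH2"), p, on)
  occ <- tr$occupancy
  u <- occ[, "undetected_EC"] + occ[, "undetected_OC"]
  # occupancy present while screening detects imperfectly, but each row's
  # undetected mass equals that cycle's false negatives only (no carryover):
  # diagnosing (1 - qx) of the prior row and never re-entering
  expect_true(any(u > 0))
  qx <- lt_qx(p$life_table, 25:74)
  fn_dx <- u[1:50] * (1 - qx)  # diagnosed from undetected at each cycle
  new_dx <- tr$flows$new_ec + tr$flows$new_oc
  expect_true(all(new_dx[u[1:50] > 0] >= fn_dx[u[1:50] > 0] - 1e-15))
})

test_that("earlier hyst-BSO weakly reduces total cancer incidence", {
  for (gene in c("MSH2", "PMS2")) {
    p <- base_params(gene)
    on <- base_onset(gene)
    inc <- vapply(c(35, 40, 50), function(h) {
      tr <- run_cohort(strategy(h, h, Inf, gene = gene), p, on)
      sum(tr$flows$new_ec) + sum(tr$flows$new_oc)
    }, numeric(1))
    expect_true(all(diff(inc) >= -1e-12))
  }
})

test_that("one diagnosed cancer precludes the other", {
  # mutual exclusivity: total diagnoses cannot exceed the cohort, and the
  # stage-state inflow comes only from healthy/undetected/post-BS pools
  p <- base_params("MSH2")
  tr <- run_cohort(strategy_natural_history("MSH2"), p, base_onset("MSH2"))
  expect_lt(sum(tr$flows$new_ec) + sum(tr$flows$new_oc), 1)
})
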