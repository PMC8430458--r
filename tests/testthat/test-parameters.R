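# parameters_and_fixtures: life-table fixture, loading, validation,
# perturbation

test_that("fixture life table evaluates the Gompertz-Makeham form", {
  lt <- make_fixture_life_table()
  expect_equal(lt$qx[lt$age == 50], 0.00300289825182, tolerance = 1e-10)
  expect_equal(lt$qx[lt$age == 25], 0.000406398085441, tolerance = 1e-10)
  # strictly increasing and bounded
  expect_true(all(diff(lt$qx) > 0))
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  expect_true(all(25:75 %in% lt$age))
  expect_error(make_fixture_life_table(B = 0), "B must be")
  expect_error(make_fixture_life_table(C = -1), "C must be")
  expect_error(make_fixture_life_table(A = -0.1), "A must be")
})

test_that("life tables round-trip through the two-column text format", {
  lt <- make_fixture_life_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_life_table(lt, f)
  lt2 <- read_life_table(f)
  expect_equal(lt2$age, lt$age)
  expect_equal(lt2$qx, lt$qx, tolerance = 1e-12)
  expect_error(read_life_table(file.path(tempdir(), "nope.tsv")),
               "not found")
  # coverage check
  expect_error(validate_life_table(data.frame(age = 40:80, qx = 0.01)),
               "cover ages 25 through 75")
  expect_error(validate_life_table(data.frame(age = 25:80, qx = 1.5)),
               "\\[0, 1\\]")
})

test_that("bundled parameters load with published base-case values", {
  p2 <- base_params("MSH2")
  expect_equal(param_get(p2, "oc_cum_risk_MSH2"), 0.174)
  expect_equal(param_get(base_params("PMS2"), "ec_cum_risk_PMS2"), 0.118)
  expect_equal(param_get(p2, "surgical_mortality"), 0.0017)
  expect_equal(param_get(p2, "cost_hysterectomy"), 8922)
  expect_equal(param_get(p2, "discount_rate"), 0.03)
  expect_error(load_parameters(gene = "BRCA1"))
  expect_error(param_get(p2, "no_such_parameter"), "unknown parameter")
})

test_that("validation rejects malformed parameter tables", {
  p <- base_params("MSH2")
  tbl <- p$table
  # stage distribution not summing to one
  tbl$value[tbl$name == "ec_stage_noint_local"] <- 0.83
  expect_error(build_parameters(tbl, "MSH2", p$life_table, p$anchors),
               "does not sum to 1")
  # missing parameter
  tbl2 <- p$table[p$table$name != "wtp", ]
  expect_error(build_parameters(tbl2, "MSH2", p$life_table, p$anchors),
               "missing parameters")
  # probability out of range
  expect_error(param_set(p, "ec_screen_sens", 1.2), "out of \\[0,1\\]")
  expect_error(param_set(p, "rr_oophorectomy_mortality", 0.5), ">= 1")
})

test_that("parameter tables round-trip through write/load", {
  p <- base_params("MSH6")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_parameters(p, f)
  p2 <- load_parameters(f, gene = "MSH6")
  expect_equal(p2$values, p$values, tolerance = 1e-12)
  expect_equal(p2$anchors, p$anchors)
})

test_that("perturbation applies the conventional rules and clamps", {
  p <- base_params("MSH2")
  q <- perturb_parameters(p, prob_factor = 1.1, cost_factor = 1.2,
                          utility_shift = 0.10)
  expect_equal(param_get(q, "surgical_mortality"), 0.00187, tolerance = 1e-12)
  expect_equal(param_get(q, "cost_hysterectomy"), 10706.4, tolerance = 1e-9)
  # utility 0.90 + 0.10 hits the ceiling at 1
  expect_equal(param_get(q, "util_hystbso_premenopausal"), 1.0)
  # stage triplets renormalized back to 1
  s <- sum(vapply(paste0("oc_stage_noint_", c("local", "regional", "distant")),
                  function(nm) param_get(q, nm), numeric(1)))
  expect_equal(s, 1, tolerance = 1e-12)
  # random rule reproducible under seed, and always valid
  r1 <- perturb_parameters(p, seed = 42)
  r2 <- perturb_parameters(p, seed = 42)
  expect_equal(r1$values, r2$values)
  expect_silent(validate_parameters(r1))
})

test_that("risk anchors rescale with the lifetime-risk parameter", {
  p <- base_params("MSH2")
  a0 <- risk_anchors(p, "OC")
  expect_equal(a0$ci[nrow(a0)], 0.174)
  p2 <- param_set(p, "oc_cum_risk_MSH2", 0.30)
  a2 <- risk_anchors(p2, "OC")
  expect_equal(a2$ci[nrow(a2)], 0.30, tolerance = 1e-12)
  # shape preserved: proportional-hazards relation between curves
  k <- log1p(-0.30) / log1p(-0.174)
  expect_equal(a2$ci, 1 - (1 - a0$ci)^k, tolerance = 1e-12)
  expect_true(!is.unsorted(a2$ci))
})
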