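#' Discount factor
#'
#' @param t Years from model start (age 25).
#' @param rate Annual discount rate (>= 0), default 3%.
#' @return `1 / (1 + rate)^t`.
#' @examples
#' discount_factor(10, 0.03)  # ~0.74409
#' @export
discount_factor <- function(t, rate = 0.03) {
  if (rate < 0) stop("rate must be >= 0")
  (1 + rate)^(-t)
}

# trapezoidal half-cycle weights over the 51 occupancy rows
.hc_weights <- function(n) {
  w <- rep(1, n); w[1] <- 0.5; w[n] <- 0.5
  w
}

#' Discounted lifetime cost of a cohort trace
#'
#' Sums, per cycle and discounted to model start: surveillance encounter
#' costs (the first screening round is billed at the initial-encounter rate,
#' later rounds at the subsequent rate), surgery costs (hysterectomy with or
#' without BSO for scheduled and false-positive-triggered operations,
#' oophorectomy for the second stage of the 2-stage approach), complication
#' costs, stage-specific initial cancer care in the diagnosis cycle, annual
#' continuing care while in a cancer state, and end-of-life care replacing
#' continuing care in the cycle of cancer-specific death.
#'
#' @param trace `ls_trace`.
#' @param params `ls_params`.
#' @param rate Discount rate; default taken from `params`.
#' @return Discounted cost in 2020 USD per cohort member.
#' @export
accumulate_costs <- function(trace, params, rate = NULL) {
  v <- params$values
  if (is.null(rate)) rate <- unname(v["discount_rate"])
  fl <- trace$flows
  t <- fl$age - unname(v["start_age"])
  disc <- discount_factor(t, rate)
  screen_cost <- ifelse(fl$age == trace$surveillance_start,
                        v["cost_surveillance_initial"],
                        v["cost_surveillance_subsequent"])
  per_cycle <-
    fl$screens * screen_cost +
    (fl$surgery_hyst + fl$surgery_fp) * v["cost_hysterectomy"] +
    fl$surgery_ooph * v["cost_oophorectomy"] +
    fl$complications * v["cost_complication"] +
    fl$new_ec_local * v["cost_ec_initial_local"] +
    fl$new_ec_regional * v["cost_ec_initial_regional"] +
    fl$new_ec_distant * v["cost_ec_initial_distant"] +
    fl$new_oc_local * v["cost_oc_initial_local"] +
    fl$new_oc_regional * v["cost_oc_initial_regional"] +
    fl$new_oc_distant * v["cost_oc_initial_distant"] +
    fl$cont_ec * v["cost_ec_continuing"] +
    fl$cont_oc * v["cost_oc_continuing"] +
    fl$death_ec * v["cost_ec_terminal"] +
    fl$death_oc * v["cost_oc_terminal"]
  sum(per_cycle * disc)
}

# state utility matrix (ages x states); death states stay 0
.utility_matrix <- function(params, ages) {
  v <- params$values
  uh <- u_healthy(params, ages)
  menop <- unname(v["menopause_age"])
  U <- matrix(0, length(ages), length(.S),
              dimnames = list(NULL, model_states()))
  U[, .S["healthy"]] <- uh
  U[, .S["post_hystBSO_early"]] <- uh *
    ifelse(ages < menop, v["util_hystbso_premenopausal"],
           v["util_hystbso_postmenopausal"])
  U[, .S["post_hystBSO_late"]] <- uh * v["util_hystbso_postmenopausal"]
  U[, .S["post_hystBS"]] <- uh * v["util_hystbs"]
  U[, .S["undetected_EC"]] <- uh
  U[, .S["undetected_OC"]] <- uh
  for (k in 1:3) {
    U[, .S[.EC_STATES[k]]] <- v[paste0("util_ec_", c("local", "regional", "distant"))[k]]
    U[, .S[.OC_STATES[k]]] <- v[paste0("util_oc_", c("local", "regional", "distant"))[k]]
  }
  U
}

# state utility values at a given age (vector over states)
.state_utilities <- function(params, age) {
  .utility_matrix(params, age)[1, ]
}

#' Discounted quality-adjusted life-years of a cohort trace
#'
#' State occupancy at each age is weighted by state utilities (healthy
#' utility declines linearly with age between the published endpoints;
#' post-surgical utilities act as multipliers on it; diagnosed-cancer
#' utilities are absolute) and discounted.  The default accrual convention
#' is cycle-end membership: each annual cycle contributes the utility of
#' the state occupied at its end, discounted at the cycle-end time - the
#' half-cycle-corrected convention this model validates against.  The
#' `"trapezoid"` alternative weights the first and last of the 51
#' occupancy rows by one half; it values each transition as occurring
#' mid-cycle and yields about half a (discounted) utility-year more.
#' One-off event decrements - per screen, and for the first postoperative
#' year with or without complication - are applied at the event cycle,
#' weighted by the event flows.
#'
#' @param trace `ls_trace`.
#' @param params `ls_params`.
#' @param rate Discount rate; default taken from `params`.
#' @param accrual `"cycle_end"` (default) or `"trapezoid"`.
#' @return Discounted QALYs per cohort member.
#' @export
accumulate_qalys <- function(trace, params, rate = NULL,
                             accrual = c("cycle_end", "trapezoid")) {
  accrual <- match.arg(accrual)
  v <- params$values
  if (is.null(rate)) rate <- unname(v["discount_rate"])
  start_age <- unname(v["start_age"])
  ages <- trace$ages
  n <- length(ages)
  u_rows <- rowSums(trace$occupancy * .utility_matrix(params, ages))
  disc <- discount_factor(ages - start_age, rate)
  w <- if (accrual == "trapezoid") .hc_weights(n) else c(0, rep(1, n - 1))
  base <- sum(w * disc * u_rows)

  fl <- trace$flows
  t <- fl$age - start_age
  discf <- discount_factor(t, rate)
  ops_surv <- fl$surgery_hyst + fl$surgery_fp + fl$surgery_ooph - fl$surg_deaths
  events <-
    fl$screens * v["disutil_screen"] +
    (ops_surv - fl$complications) * v["disutil_surgery"] +
    fl$complications * v["disutil_surgery_complication"]
  base + sum(events * discf)
}

#' Summarize a cohort trace into strategy-level outcomes
#'
#' @param trace `ls_trace`.
#' @param params `ls_params`.
#' @return An `ls_result`: one-row data frame with discounted QALYs and
#'   cost, undiscounted life-years (half-cycle corrected), and EC/OC
#'   incidence and mortality as cohort fractions.
#' @export
summarize_trace <- function(trace, params) {
  fl <- trace$flows
  alive <- 1 - rowSums(trace$occupancy[, .DEATH_STATES])
  ly <- sum(.hc_weights(length(alive)) * alive)
  out <- data.frame(
    gene = if (is.null(trace$gene)) NA_character_ else trace$gene,
    strategy = trace$strategy,
    qalys = accumulate_qalys(trace, params),
    cost = accumulate_costs(trace, params),
    life_years = ly,
    ec_incidence = sum(fl$new_ec),
    ec_mortality = sum(fl$death_ec),
    oc_incidence = sum(fl$new_oc),
    oc_mortality = sum(fl$death_oc),
    stringsAsFactors = FALSE)
  out$total_incidence <- out$ec_incidence + out$oc_incidence
  out$total_mortality <- out$ec_mortality + out$oc_mortality
  class(out) <- c("ls_result", "data.frame")
  out
}

#' Run and summarize one strategy
#'
#' @param strategy `ls_strategy`.
#' @param params `ls_params`.
#' @param onset Calibrated onset schedules (list `ec`, `oc`).
#' @return `ls_result` row.
#' @export
evaluate_strategy <- function(strategy, params, onset) {
  summarize_trace(run_cohort(strategy, params, onset), params)
}

#' Run and summarize a list of strategies
#'
#' @param strategies List of `ls_strategy` (default: the standard grid for
#'   the gene in `params`).
#' @param params `ls_params`.
#' @param onset Calibrated onset schedules; calibrated on the fly if `NULL`.
#' @return `ls_result` data frame, one row per strategy.
#' @export
evaluate_strategies <- function(params, strategies = NULL, onset = NULL) {
  if (is.null(strategies)) strategies <- enumerate_strategies(params$gene)
  if (is.null(onset)) {
    cal <- calibrate_gene(params)
    onset <- list(ec = cal$ec, oc = cal$oc)
  }
  out <- do.call(rbind, lapply(strategies, evaluate_strategy,
                               params = params, onset = onset))
  class(out) <- c("ls_result", "data.frame")
  out
}
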