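#' Annual cancer-specific death probability from 5-year relative survival
#'
#' Converts a stage-specific 5-year relative survival `RS` into the constant
#' annual probability of cancer-specific death `1 - RS^(1/5)`, applied each
#' cycle in addition to all-cause mortality.
#'
#' @param rs 5-year relative survival, in (0, 1].
#' @return Annual cancer-death probability.
#' @examples
#' annual_cancer_death_prob(0.168)  # 0.300 for distant endometrial cancer
#' @export
annual_cancer_death_prob <- function(rs) {
  if (any(rs <= 0 | rs > 1)) stop("relative survival must be in (0, 1]")
  1 - rs^(1 / 5)
}

#' Screening outcome probabilities for one cycle
#'
#' Splits the annual cancer risks of a screened, currently cancer-free woman
#' into true-positive/false-negative fractions per site and the
#' false-positive fraction among the cancer-free remainder (one minus the
#' product of the two test specificities, since both screens are performed).
#'
#' @param ec_risk,oc_risk Annual onset probabilities this cycle.
#' @param ec_sens,ec_spec,oc_sens,oc_spec Test characteristics.
#' @return Named list: `TP_EC`, `FN_EC`, `TP_OC`, `FN_OC`, `FP_any`, `TN`.
#' @examples
#' screen_cycle_probabilities(0.01, 0, ec_sens = 0.91, ec_spec = 0.98,
#'                            oc_sens = 0.60, oc_spec = 0.962)
#' @export
screen_cycle_probabilities <- function(ec_risk, oc_risk,
                                       ec_sens, ec_spec, oc_sens, oc_spec) {
  probs <- c(ec_risk, oc_risk, ec_sens, ec_spec, oc_sens, oc_spec)
  if (any(probs < 0 | probs > 1)) stop("inputs must be probabilities")
  if (ec_risk + oc_risk > 1) stop("combined annual risk exceeds 1")
  fp <- (1 - ec_risk - oc_risk) * (1 - ec_spec * oc_spec)
  list(TP_EC = ec_risk * ec_sens, FN_EC = ec_risk * (1 - ec_sens),
       TP_OC = oc_risk * oc_sens, FN_OC = oc_risk * (1 - oc_sens),
       FP_any = fp,
       TN = (1 - ec_risk - oc_risk) - fp)
}

# Precompute everything the cycle loop needs for one strategy x parameter set
.cycle_inputs <- function(strategy, params, onset) {
  ages <- 25:74
  v <- params$values
  pe <- onset$ec$p[match(ages, onset$ec$age)]
  po <- onset$oc$p[match(ages, onset$oc$age)]
  if (anyNA(pe) || anyNA(po)) stop("onset schedules must cover ages 25-74")
  hyst <- strategy$hyst_age; ooph <- strategy$ooph_age
  surv0 <- strategy$surveillance_start
  list(
    ages = ages,
    qx = lt_qx(params$life_table, ages),
    pe = pe, po = po,
    screen = is.finite(surv0) & ages >= surv0 & ages < hyst,
    surv_start_age = surv0,
    hyst_now = is.finite(hyst) & ages == hyst,
    bso_with_hyst = is.finite(ooph) && is.finite(hyst) && ooph == hyst,
    ooph2_now = if (is.finite(ooph) && is.finite(hyst) && ooph > hyst)
      ages == ooph else rep(FALSE, length(ages)),
    menop = unname(v["menopause_age"]),
    mort = unname(v["surgical_mortality"]),
    comp = unname(v["complication_prob"]),
    rr_salp = unname(v["rr_salpingectomy_oc"]),
    rr_ooph = unname(v["rr_oophorectomy_mortality"]),
    ec_sens = unname(v["ec_screen_sens"]), ec_spec = unname(v["ec_screen_spec"]),
    oc_sens = unname(v["oc_screen_sens"]), oc_spec = unname(v["oc_screen_spec"]),
    split_ec_surv = unname(v[paste0("ec_stage_surv_", c("local", "regional", "distant"))]),
    split_ec_noint = unname(v[paste0("ec_stage_noint_", c("local", "regional", "distant"))]),
    split_oc_surv = unname(v[paste0("oc_stage_surv_", c("local", "regional", "distant"))]),
    split_oc_noint = unname(v[paste0("oc_stage_noint_", c("local", "regional", "distant"))]),
    pc_ec = annual_cancer_death_prob(
      unname(v[paste0("ec_surv5_", c("local", "regional", "distant"))])),
    pc_oc = annual_cancer_death_prob(
      unname(v[paste0("oc_surv5_", c("local", "regional", "distant"))]))
  )
}

#' One transition row of the cohort model
#'
#' Probability row over all model states for a woman in `state` at the start
#' of the annual cycle beginning at `age`, under the fixed within-cycle
#' event order: all-cause death, scheduled surgery, cancer onset, detection
#' (symptomatic or screen-based), stage-specific cancer death for prevalent
#' cancers.
#'
#' @param age Integer age in 25..74 (cycle start).
#' @param state State label (see [model_states()]).
#' @param params `ls_params`.
#' @param strategy `ls_strategy`.
#' @param onset List with `ec` and `oc` onset schedules (`ls_onset`).
#' @return Named numeric vector over states summing to one.
#' @export
build_transition <- function(age, state, params, strategy, onset) {
  pre <- .cycle_inputs(strategy, params, onset)
  i <- match(age, pre$ages)
  if (is.na(i)) stop("age must be one of 25..74")
  if (!state %in% model_states()) stop("unknown state: ", state)
  M <- .cycle_matrix(i, pre)
  stats::setNames(M[.S[[state]], ], model_states())
}

# Full one-cycle transition matrix (rows: from-state).  Used by
# build_transition and as the oracle cross-check for the flow-based loop.
.cycle_matrix <- function(i, pre) {
  n <- length(.S)
  M <- matrix(0, n, n)
  qx <- pre$qx[i]; pe <- pre$pe[i]; po <- pre$po[i]
  a <- pre$ages[i]
  bso_dest <- if (a < pre$menop) .S["post_hystBSO_early"] else .S["post_hystBSO_late"]

  # healthy
  r <- numeric(n); s <- 1 - qx
  r[.S["death_other"]] <- qx
  if (pre$hyst_now[i]) {
    sd <- s * pre$mort
    r[.S["death_surgical"]] <- sd
    dest <- if (pre$bso_with_hyst) bso_dest else .S["post_hystBS"]
    r[dest] <- s - sd
  } else if (pre$screen[i]) {
    r[.S["undetected_EC"]] <- s * pe * (1 - pre$ec_sens)
    r[.S["undetected_OC"]] <- s * po * (1 - pre$oc_sens)
    r[.S[.EC_STATES]] <- r[.S[.EC_STATES]] + s * pe * pre$ec_sens * pre$split_ec_surv
    r[.S[.OC_STATES]] <- r[.S[.OC_STATES]] + s * po * pre$oc_sens * pre$split_oc_surv
    pfree <- 1 - pe - po
    fp <- pfree * (1 - pre$ec_spec * pre$oc_spec)
    sd <- s * fp * pre$mort
    r[.S["death_surgical"]] <- sd
    r[bso_dest] <- r[bso_dest] + s * fp - sd
    r[.S["healthy"]] <- s * (pfree - fp)
  } else {
    r[.S[.EC_STATES]] <- s * pe * pre$split_ec_noint
    r[.S[.OC_STATES]] <- s * po * pre$split_oc_noint
    r[.S["healthy"]] <- s * (1 - pe - po)
  }
  M[.S["healthy"], ] <- r

  # post hyst-BSO, early (surgical menopause): elevated all-cause mortality
  r <- numeric(n); q <- min(1, qx * pre$rr_ooph)
  r[.S["death_other"]] <- q
  r[.S["post_hystBSO_early"]] <- 1 - q
  M[.S["post_hystBSO_early"], ] <- r

  r <- numeric(n)
  r[.S["death_other"]] <- qx
  r[.S["post_hystBSO_late"]] <- 1 - qx
  M[.S["post_hystBSO_late"], ] <- r

  # post hyst-BS, ovaries retained: OC risk persists (times salpingectomy RR)
  r <- numeric(n); s <- 1 - qx
  r[.S["death_other"]] <- qx
  if (pre$ooph2_now[i]) {
    sd <- s * pre$mort
    r[.S["death_surgical"]] <- sd
    r[bso_dest] <- s - sd
  } else {
    poB <- po * pre$rr_salp
    r[.S[.OC_STATES]] <- s * poB * pre$split_oc_noint
    r[.S["post_hystBS"]] <- s * (1 - poB)
  }
  M[.S["post_hystBS"], ] <- r

  # undetected cancers: diagnosed next cycle (missed-screen stage
  # distribution = no-intervention) unless death intervenes
  r <- numeric(n)
  r[.S["death_other"]] <- qx
  r[.S[.EC_STATES]] <- (1 - qx) * pre$split_ec_noint
  M[.S["undetected_EC"], ] <- r
  r <- numeric(n)
  r[.S["death_other"]] <- qx
  r[.S[.OC_STATES]] <- (1 - qx) * pre$split_oc_noint
  M[.S["undetected_OC"], ] <- r

  # diagnosed cancer states: all-cause then stage-specific cancer death
  for (k in 1:3) {
    r <- numeric(n)
    r[.S["death_other"]] <- qx
    r[.S["death_EC"]] <- (1 - qx) * pre$pc_ec[k]
    r[.S[.EC_STATES[k]]] <- (1 - qx) * (1 - pre$pc_ec[k])
    M[.S[.EC_STATES[k]], ] <- r
    r <- numeric(n)
    r[.S["death_other"]] <- qx
    r[.S["death_OC"]] <- (1 - qx) * pre$pc_oc[k]
    r[.S[.OC_STATES[k]]] <- (1 - qx) * (1 - pre$pc_oc[k])
    M[.S[.OC_STATES[k]], ] <- r
  }

  for (d in .DEATH_STATES) M[.S[d], .S[d]] <- 1
  M
}

#' Run the annual-cycle cohort trace for one strategy
#'
#' Deterministically propagates a unit cohort from age 25 to 75 and records
#' state occupancy at every age together with the per-cycle event flows
#' needed for costing and outcome accounting (screens, surgeries,
#' complications, surgical deaths, new stage-specific diagnoses, cancer
#' deaths, continuing-care occupancy).
#'
#' @param strategy `ls_strategy`.
#' @param params `ls_params`.
#' @param onset List with calibrated `ec` and `oc` onset schedules.
#' @return An `ls_trace`: list with `occupancy` (51 x 16 matrix, rows ages
#'   25..75) and `flows` (data frame, one row per cycle age 25..74).
#' @export
run_cohort <- function(strategy, params, onset) {
  pre <- .cycle_inputs(strategy, params, onset)
  n_cyc <- length(pre$ages)
  ns <- length(.S)
  occ <- matrix(0, n_cyc + 1, ns, dimnames = list(NULL, model_states()))
  occ[1, .S["healthy"]] <- 1

  z <- numeric(n_cyc)
  screens_v <- z; s_hyst <- z; s_ooph <- z; s_fp <- z
  comps <- z; s_dead <- z
  ne_l <- z; ne_r <- z; ne_d <- z; no_l <- z; no_r <- z; no_d <- z
  d_ec <- z; d_oc <- z; c_ec <- z; c_oc <- z

  iS <- .S  # local copies for speed
  i_h <- iS[["healthy"]]; i_be <- iS[["post_hystBSO_early"]]
  i_bl <- iS[["post_hystBSO_late"]]; i_bs <- iS[["post_hystBS"]]
  i_ue <- iS[["undetected_EC"]]; i_uo <- iS[["undetected_OC"]]
  i_ec <- unname(iS[.EC_STATES]); i_oc <- unname(iS[.OC_STATES])
  i_dec <- iS[["death_EC"]]; i_doc <- iS[["death_OC"]]
  i_dot <- iS[["death_other"]]; i_dsu <- iS[["death_surgical"]]

  for (i in seq_len(n_cyc)) {
    cur <- occ[i, ]
    nxt <- numeric(ns)
    qx <- pre$qx[i]; pe <- pre$pe[i]; po <- pre$po[i]
    a <- pre$ages[i]
    bso_dest <- if (a < pre$menop) i_be else i_bl

    new_ec <- numeric(3); new_oc <- numeric(3)

    # --- healthy ---
    H <- cur[i_h]
    if (H > 0) {
      nxt[i_dot] <- nxt[i_dot] + H * qx
      s <- H * (1 - qx)
      if (pre$hyst_now[i]) {
        sd <- s * pre$mort
        nxt[i_dsu] <- nxt[i_dsu] + sd
        dest <- if (pre$bso_with_hyst) bso_dest else i_bs
        nxt[dest] <- nxt[dest] + s - sd
        s_hyst[i] <- s_hyst[i] + s
        s_dead[i] <- s_dead[i] + sd
        comps[i] <- comps[i] + (s - sd) * pre$comp
      } else if (pre$screen[i]) {
        screens_v[i] <- screens_v[i] + s
        tp_e <- pe * pre$ec_sens; fn_e <- pe - tp_e
        tp_o <- po * pre$oc_sens; fn_o <- po - tp_o
        nxt[i_ue] <- nxt[i_ue] + s * fn_e
        nxt[i_uo] <- nxt[i_uo] + s * fn_o
        new_ec <- new_ec + s * tp_e * pre$split_ec_surv
        new_oc <- new_oc + s * tp_o * pre$split_oc_surv
        pfree <- 1 - pe - po
        fp <- pfree * (1 - pre$ec_spec * pre$oc_spec)
        fps <- s * fp
        sd <- fps * pre$mort
        nxt[i_dsu] <- nxt[i_dsu] + sd
        nxt[bso_dest] <- nxt[bso_dest] + fps - sd
        s_fp[i] <- s_fp[i] + fps
        s_dead[i] <- s_dead[i] + sd
        comps[i] <- comps[i] + (fps - sd) * pre$comp
        nxt[i_h] <- nxt[i_h] + s * (pfree - fp)
      } else {
        new_ec <- new_ec + s * pe * pre$split_ec_noint
        new_oc <- new_oc + s * po * pre$split_oc_noint
        nxt[i_h] <- nxt[i_h] + s * (1 - pe - po)
      }
    }

    # --- post hyst-BSO states ---
    Be <- cur[i_be]
    if (Be > 0) {
      q <- min(1, qx * pre$rr_ooph)
      nxt[i_dot] <- nxt[i_dot] + Be * q
      nxt[i_be] <- nxt[i_be] + Be * (1 - q)
    }
    Bl <- cur[i_bl]
    if (Bl > 0) {
      nxt[i_dot] <- nxt[i_dot] + Bl * qx
      nxt[i_bl] <- nxt[i_bl] + Bl * (1 - qx)
    }

    # --- post hyst-BS (ovaries retained) ---
    B <- cur[i_bs]
    if (B > 0) {
      nxt[i_dot] <- nxt[i_dot] + B * qx
      sB <- B * (1 - qx)
      if (pre$ooph2_now[i]) {
        sd <- sB * pre$mort
        nxt[i_dsu] <- nxt[i_dsu] + sd
        nxt[bso_dest] <- nxt[bso_dest] + sB - sd
        s_ooph[i] <- s_ooph[i] + sB
        s_dead[i] <- s_dead[i] + sd
        comps[i] <- comps[i] + (sB - sd) * pre$comp
      } else {
        poB <- po * pre$rr_salp
        new_oc <- new_oc + sB * poB * pre$split_oc_noint
        nxt[i_bs] <- nxt[i_bs] + sB * (1 - poB)
      }
    }

    # --- undetected cancers: diagnosed this cycle unless death intervenes ---
    uE <- cur[i_ue]
    if (uE > 0) {
      nxt[i_dot] <- nxt[i_dot] + uE * qx
      new_ec <- new_ec + uE * (1 - qx) * pre$split_ec_noint
    }
    uO <- cur[i_uo]
    if (uO > 0) {
      nxt[i_dot] <- nxt[i_dot] + uO * qx
      new_oc <- new_oc + uO * (1 - qx) * pre$split_oc_noint
    }

    # --- prevalent cancers ---
    E3 <- cur[i_ec]
    if (any(E3 > 0)) {
      cd <- E3 * (1 - qx) * pre$pc_ec
      nxt[i_dot] <- nxt[i_dot] + sum(E3) * qx
      nxt[i_dec] <- nxt[i_dec] + sum(cd)
      nxt[i_ec] <- nxt[i_ec] + E3 * (1 - qx) - cd
      d_ec[i] <- d_ec[i] + sum(cd)
      c_ec[i] <- c_ec[i] + sum(E3 - cd)
    }
    O3 <- cur[i_oc]
    if (any(O3 > 0)) {
      cd <- O3 * (1 - qx) * pre$pc_oc
      nxt[i_dot] <- nxt[i_dot] + sum(O3) * qx
      nxt[i_doc] <- nxt[i_doc] + sum(cd)
      nxt[i_oc] <- nxt[i_oc] + O3 * (1 - qx) - cd
      d_oc[i] <- d_oc[i] + sum(cd)
      c_oc[i] <- c_oc[i] + sum(O3 - cd)
    }

    # new diagnoses enter their stage states
    nxt[i_ec] <- nxt[i_ec] + new_ec
    nxt[i_oc] <- nxt[i_oc] + new_oc
    ne_l[i] <- new_ec[1]; ne_r[i] <- new_ec[2]; ne_d[i] <- new_ec[3]
    no_l[i] <- new_oc[1]; no_r[i] <- new_oc[2]; no_d[i] <- new_oc[3]

    # deaths are absorbing
    nxt[i_dec] <- nxt[i_dec] + cur[i_dec]
    nxt[i_doc] <- nxt[i_doc] + cur[i_doc]
    nxt[i_dot] <- nxt[i_dot] + cur[i_dot]
    nxt[i_dsu] <- nxt[i_dsu] + cur[i_dsu]

    occ[i + 1, ] <- nxt
  }

  fl <- data.frame(age = pre$ages, screens = screens_v,
                   surgery_hyst = s_hyst, surgery_ooph = s_ooph,
                   surgery_fp = s_fp,
                   complications = comps, surg_deaths = s_dead,
                   new_ec_local = ne_l, new_ec_regional = ne_r,
                   new_ec_distant = ne_d,
                   new_oc_local = no_l, new_oc_regional = no_r,
                   new_oc_distant = no_d,
                   death_ec = d_ec, death_oc = d_oc,
                   cont_ec = c_ec, cont_oc = c_oc)
  fl$new_ec <- fl$new_ec_local + fl$new_ec_regional + fl$new_ec_distant
  fl$new_oc <- fl$new_oc_local + fl$new_oc_regional + fl$new_oc_distant

  structure(list(occupancy = occ, flows = fl, ages = 25:75,
                 strategy = strategy$label, gene = params$gene,
                 surveillance_start = strategy$surveillance_start),
            class = "ls_trace")
}

#' @export
print.ls_trace <- function(x, ...) {
  alive <- 1 - rowSums(x$occupancy[, .DEATH_STATES])
  cat("Cohort trace:", x$strategy,
      if (!is.null(x$gene)) paste0("(", x$gene, ")"), "\n")
  cat("  survival to 75:", round(alive[length(alive)], 4),
      "| EC incidence:", round(sum(x$flows$new_ec), 4),
      "| OC incidence:", round(sum(x$flows$new_oc), 4), "\n")
  invisible(x)
}

#' Export a cohort trace to TSV files
#' @param trace `ls_trace`.
#' @param occupancy_path,flows_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_trace <- function(trace, occupancy_path = NULL, flows_path = NULL) {
  if (!is.null(occupancy_path)) {
    df <- data.frame(age = trace$ages, trace$occupancy, check.names = FALSE)
    utils::write.table(df, occupancy_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(flows_path))
    utils::write.table(trace$flows, flows_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(c(occupancy_path, flows_path))
}
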