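#' Health states of the cohort model
#'
#' The model tracks a closed cohort of women from age 25 to 75 through an
#' annual-cycle Markov process.  States cover the intact (pre-surgical)
#' condition, the two post-surgical conditions (hysterectomy with bilateral
#' salpingo-oophorectomy, and hysterectomy with bilateral salpingectomy with
#' ovaries retained), transient undetected-cancer states used for
#' false-negative screens, stage-specific diagnosed cancer states, and four
#' absorbing death states.  Post-BSO occupancy is split by whether the
#' ovaries were removed before the natural menopause age (50), because the
#' early-menopause utility decrement and the optional all-cause mortality
#' multiplier apply only to that subgroup.
#'
#' @return Character vector of state labels, in canonical column order.
#' @export
model_states <- function() {
  c("healthy",
    "post_hystBSO_early", "post_hystBSO_late", "post_hystBS",
    "undetected_EC", "undetected_OC",
    "EC_local", "EC_regional", "EC_distant",
    "OC_local", "OC_regional", "OC_distant",
    "death_EC", "death_OC", "death_other", "death_surgical")
}

# state index shorthand used throughout the engine
.S <- local({
  s <- c("healthy",
         "post_hystBSO_early", "post_hystBSO_late", "post_hystBS",
         "undetected_EC", "undetected_OC",
         "EC_local", "EC_regional", "EC_distant",
         "OC_local", "OC_regional", "OC_distant",
         "death_EC", "death_OC", "death_other", "death_surgical")
  stats::setNames(seq_along(s), s)
})

.DEATH_STATES <- c("death_EC", "death_OC", "death_other", "death_surgical")
.EC_STATES <- c("EC_local", "EC_regional", "EC_distant")
.OC_STATES <- c("OC_local", "OC_regional", "OC_distant")
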