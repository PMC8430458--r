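#' Seed an annual onset schedule from cumulative-incidence anchors
#'
#' Converts a piecewise cumulative-incidence curve into piecewise-constant
#' conditional annual onset probabilities: on an interval from age `a0`
#' (cumulative incidence `c0`) to `a1` (`c1`),
#' \deqn{p = 1 - \left(\frac{1 - c_1}{1 - c_0}\right)^{1/(a_1 - a_0)}.}
#' This is exact in the absence of competing risks and is the starting point
#' for calibration against the full natural-history model.
#'
#' @param anchors Data frame with columns `age` and `ci` (non-decreasing,
#'   `ci < 1`), sorted by age.  Onset is zero before the first anchor age.
#' @param site `"EC"` or `"OC"` (metadata only).
#' @param ages Ages the schedule must cover (default 25-74, the cycle start
#'   ages of the model).
#' @return An `ls_onset` object: data frame with columns `age` and `p`.
#' @examples
#' s <- seed_from_cumulative(data.frame(age = c(30, 75), ci = c(0, 0.118)))
#' s$p[s$age == 50]  # ~0.002786
#' @export
seed_from_cumulative <- function(anchors, site = "EC", ages = 25:74) {
  stopifnot(is.data.frame(anchors), all(c("age", "ci") %in% names(anchors)))
  anchors <- anchors[order(anchors$age), ]
  if (any(anchors$ci >= 1)) stop("cumulative incidence must be < 1")
  if (any(anchors$ci < 0)) stop("cumulative incidence must be >= 0")
  if (is.unsorted(anchors$ci)) stop("cumulative incidence must be non-decreasing")
  if (nrow(anchors) < 2) stop("need at least two anchors")
  p <- numeric(length(ages))
  for (j in seq_len(nrow(anchors) - 1)) {
    a0 <- anchors$age[j];  a1 <- anchors$age[j + 1]
    c0 <- anchors$ci[j];   c1 <- anchors$ci[j + 1]
    if (a1 <= a0) stop("anchor ages must be strictly increasing")
    pj <- 1 - ((1 - c1) / (1 - c0))^(1 / (a1 - a0))
    p[ages >= a0 & ages < a1] <- pj
  }
  out <- data.frame(age = ages, p = p)
  attr(out, "site") <- site
  class(out) <- c("ls_onset", "data.frame")
  out
}

# zero onset schedule
.zero_onset <- function(site, ages = 25:74) {
  out <- data.frame(age = ages, p = numeric(length(ages)))
  attr(out, "site") <- site
  class(out) <- c("ls_onset", "data.frame")
  out
}

# modeled cumulative diagnosed incidence at given ages, from a natural
# history trace
.modeled_ci <- function(trace, site, at_ages) {
  fl <- trace$flows
  new_col <- if (site == "EC") "new_ec" else "new_oc"
  cum <- cumsum(fl[[new_col]])
  # flows at cycle age a are diagnoses between a and a+1 -> counted before
  # any anchor age strictly greater than a
  vapply(at_ages, function(a) {
    i <- which(fl$age < a)
    if (length(i)) cum[max(i)] else 0
  }, numeric(1))
}

#' Calibrate an onset schedule to cumulative-incidence targets
#'
#' Runs the natural-history cohort (competing all-cause mortality and the
#' other cancer included) and multiplicatively rescales the onset
#' probabilities on each inter-anchor interval until the modeled cumulative
#' diagnosed incidence matches every anchor to within `tol` (absolute).
#' Replaces the visual-fit calibration of the original analysis with a
#' deterministic fixed-point iteration.
#'
#' @param params `ls_params` for the gene being calibrated.
#' @param site `"EC"` or `"OC"`.
#' @param other Onset schedule of the other site held fixed during
#'   calibration (default: its closed-form seed).
#' @param anchors Optional anchor data frame (`age`, `ci`); default
#'   `risk_anchors(params, site)`.
#' @param tol Absolute convergence tolerance on each anchor (default 1e-4).
#' @param max_iter Iteration cap (default 200).
#' @return List with elements `schedule` (`ls_onset`) and `report`
#'   (`ls_calibration_report`: per-anchor target/modeled/error, iterations,
#'   converged flag).  Non-convergence raises an error carrying the report.
#' @export
calibrate_onset <- function(params, site, other = NULL, anchors = NULL,
                            tol = 1e-4, max_iter = 200) {
  site <- match.arg(site, c("EC", "OC"))
  if (tol <= 0) stop("tol must be > 0")
  if (is.null(anchors)) anchors <- risk_anchors(params, site)
  names(anchors)[names(anchors) == "cum_inc"] <- "ci"
  other_site <- setdiff(c("EC", "OC"), site)
  if (is.null(other))
    other <- seed_from_cumulative(risk_anchors(params, other_site),
                                  site = other_site)
  sched <- seed_from_cumulative(anchors, site = site)
  nh <- strategy_natural_history(params$gene)
  iters <- 0L
  modeled <- NULL
  repeat {
    onset <- if (site == "EC") list(ec = sched, oc = other)
             else list(ec = other, oc = sched)
    trace <- run_cohort(nh, params, onset)
    modeled <- .modeled_ci(trace, site, anchors$age)
    err <- abs(modeled - anchors$ci)
    if (all(err <= tol) || iters >= max_iter) break
    iters <- iters + 1L
    # per-interval multiplicative rescale by the ratio of target to modeled
    # incidence gained across the interval
    for (j in seq_len(nrow(anchors) - 1)) {
      tgt_gain <- anchors$ci[j + 1] - anchors$ci[j]
      mod_gain <- modeled[j + 1] - modeled[j]
      sel <- sched$age >= anchors$age[j] & sched$age < anchors$age[j + 1]
      if (tgt_gain <= 0) {
        sched$p[sel] <- 0
      } else if (mod_gain > 0) {
        sched$p[sel] <- pmin(0.99, sched$p[sel] * tgt_gain / mod_gain)
      } else {
        # modeled gain vanished (e.g. all-zero seed); reseed the interval
        sched$p[sel] <- 1 - (1 - tgt_gain)^(1 /
          (anchors$age[j + 1] - anchors$age[j]))
      }
    }
  }
  report <- structure(
    list(site = site, gene = params$gene,
         anchors = data.frame(age = anchors$age, target = anchors$ci,
                              modeled = modeled,
                              abs_error = abs(modeled - anchors$ci)),
         iterations = iters, tol = tol,
         converged = all(abs(modeled - anchors$ci) <= tol)),
    class = "ls_calibration_report")
  if (!report$converged) {
    cond <- simpleError(paste0("calibration for ", site, " (", params$gene,
                               ") did not converge in ", max_iter,
                               " iterations"))
    cond$report <- report
    stop(cond)
  }
  list(schedule = sched, report = report)
}

#' @export
print.ls_calibration_report <- function(x, ...) {
  cat("Calibration report:", x$gene, x$site, "-",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations (tol", x$tol, ")\n")
  print(x$anchors, row.names = FALSE)
  invisible(x)
}

#' Calibrate both cancer sites jointly for one gene
#'
#' Alternates site-wise calibration (each against the other's current
#' schedule) until both sites' anchors are met simultaneously, respecting
#' the competing structure in which a first cancer removes the risk of the
#' second.
#'
#' @param params `ls_params` object.
#' @param tol Absolute tolerance per anchor.
#' @param max_iter Per-site iteration cap.
#' @param max_rounds Alternation cap.
#' @return List with `ec`, `oc` (`ls_onset` schedules) and `reports`.
#' @export
calibrate_gene <- function(params, tol = 1e-4, max_iter = 200,
                           max_rounds = 10) {
  ec <- seed_from_cumulative(risk_anchors(params, "EC"), "EC")
  oc <- seed_from_cumulative(risk_anchors(params, "OC"), "OC")
  reports <- NULL
  for (r in seq_len(max_rounds)) {
    fit_ec <- calibrate_onset(params, "EC", other = oc, tol = tol,
                              max_iter = max_iter)
    ec <- fit_ec$schedule
    fit_oc <- calibrate_onset(params, "OC", other = ec, tol = tol,
                              max_iter = max_iter)
    oc <- fit_oc$schedule
    reports <- list(ec = fit_ec$report, oc = fit_oc$report)
    # verify the EC fit still holds against the updated OC schedule
    nh <- strategy_natural_history(params$gene)
    trace <- run_cohort(nh, params, list(ec = ec, oc = oc))
    a_ec <- risk_anchors(params, "EC")
    err <- abs(.modeled_ci(trace, "EC", a_ec$age) - a_ec$ci)
    if (all(err <= tol)) break
  }
  list(ec = ec, oc = oc, reports = reports)
}

#' Fast proportional rescale of a calibrated schedule to a new lifetime risk
#'
#' One-pass analytic adjustment used inside the probabilistic sensitivity
#' analysis: annual survival probabilities are raised to the power
#' `log(1 - target_new) / log(1 - target_old)`, which reproduces the new
#' cumulative incidence exactly in the absence of competing risks and to
#' first order within the full model.
#'
#' @param schedule Calibrated `ls_onset` schedule.
#' @param old_risk,new_risk Old and new cumulative risks (fractions < 1).
#' @return Rescaled `ls_onset`.
#' @export
rescale_onset <- function(schedule, old_risk, new_risk) {
  if (new_risk >= 1 || old_risk >= 1) stop("risks must be < 1")
  if (old_risk <= 0) {
    if (new_risk > 0)
      stop("cannot rescale an all-zero schedule to a positive risk")
    return(schedule)
  }
  k <- log1p(-new_risk) / log1p(-old_risk)
  schedule$p <- 1 - (1 - schedule$p)^k
  schedule
}
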