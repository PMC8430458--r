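#' Fit a sampling distribution to a base value and plausible range
#'
#' Published ranges are interpreted as 95% intervals: the distribution is
#' fitted by method of moments with mean equal to the base value and
#' SD = (high - low) / (2 * 1.96).  Probabilities use beta, costs gamma and
#' utilities normal distributions; when the implied beta is infeasible (the
#' variance reaches the Bernoulli bound, or the mean sits on 0/1) the
#' conventional fallback is a normal with SD equal to 10% of the base
#' value.  A degenerate range gives a point mass.
#'
#' @param base Base-case value.
#' @param low,high Plausible range, `low <= base` is not required (some
#'   published ranges are asymmetric or exclude the base); only
#'   `low <= high` is.
#' @param family `"beta"`, `"gamma"`, `"normal"` or `"none"`.
#' @return An `ls_dist` list: `family`, `mean`, `sd` and family-specific
#'   hyper-parameters.
#' @examples
#' fit_distribution(0.90, 0.77, 0.95, "normal")$sd  # ~0.0459
#' @export
fit_distribution <- function(base, low, high, family) {
  family <- match.arg(family, c("beta", "gamma", "normal", "none"))
  if (is.na(low) || is.na(high) || family == "none")
    return(structure(list(family = "point", mean = base, sd = 0,
                          value = base), class = "ls_dist"))
  if (low > high) stop("low must be <= high")
  s <- (high - low) / (2 * 1.96)
  if (s == 0)
    return(structure(list(family = "point", mean = base, sd = 0,
                          value = base), class = "ls_dist"))
  v <- s^2
  if (family == "beta") {
    feasible <- base > 0 && base < 1 && v < base * (1 - base)
    if (!feasible) {
      # normal fallback with SD = 10% of base, the convention for
      # probabilities whose range does not admit a beta
      return(structure(list(family = "normal", mean = base,
                            sd = 0.10 * base), class = "ls_dist"))
    }
    nu <- base * (1 - base) / v - 1
    return(structure(list(family = "beta", mean = base, sd = s,
                          shape1 = base * nu, shape2 = (1 - base) * nu),
                     class = "ls_dist"))
  }
  if (family == "gamma") {
    if (base <= 0)
      return(structure(list(family = "point", mean = base, sd = 0,
                            value = base), class = "ls_dist"))
    return(structure(list(family = "gamma", mean = base, sd = s,
                          shape = base^2 / v, rate = base / v),
                     class = "ls_dist"))
  }
  structure(list(family = "normal", mean = base, sd = s), class = "ls_dist")
}

#' Draw samples from a fitted `ls_dist`
#' @param d `ls_dist` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(d, n) {
  switch(d$family,
         point = rep(d$value, n),
         beta = stats::rbeta(n, d$shape1, d$shape2),
         gamma = stats::rgamma(n, shape = d$shape, rate = d$rate),
         normal = stats::rnorm(n, d$mean, d$sd),
         stop("unknown family ", d$family))
}

# resolve user-facing parameter aliases to table names
.resolve_param_name <- function(params, name) {
  if (name %in% c("ec_cum_risk", "oc_cum_risk"))
    return(paste0(name, "_", params$gene))
  name
}

# does changing this parameter require recalibrating onset schedules?
.affects_onset <- function(name) grepl("_cum_risk_", name)

# closure evaluating the full strategy set at one value of one parameter
.make_evaluator <- function(params, name, strategies, onset, wtp) {
  force(onset)
  function(value) {
    p2 <- param_set(params, name, value)
    onset2 <- if (.affects_onset(name)) {
      cal <- calibrate_gene(p2)
      list(ec = cal$ec, oc = cal$oc)
    } else onset
    res <- evaluate_strategies(p2, strategies, onset2)
    build_frontier(res, wtp = wtp)
  }
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full strategy comparison at each grid value of one parameter
#' (all other inputs at base case) and reports per-strategy outcomes,
#' dominance status and the optimal strategy at the willingness-to-pay
#' threshold.  Changing a lifetime-risk parameter triggers full
#' recalibration of the onset schedules.
#'
#' @param params `ls_params`.
#' @param name Parameter name; aliases `"ec_cum_risk"` / `"oc_cum_risk"`
#'   (expanded with the gene) and `"util_posthyst"` (utility after
#'   hysterectomy, setting the post-hysterectomy and postmenopausal-BSO
#'   utilities together) are accepted.
#' @param low,high Grid end points (`low < high`).
#' @param n_grid Number of grid values (default 10).
#' @param strategies Strategy list (default: standard grid for the gene).
#' @param onset Base-case onset schedules (calibrated on the fly if `NULL`).
#' @param wtp Willingness-to-pay; default from `params`.
#' @return `ls_oneway` data frame (long format: one row per grid value x
#'   strategy) with attributes `optimal` (per grid value) and `evaluator`
#'   (used by [find_threshold()] for bisection refinement).
#' @export
one_way <- function(params, name, low, high, n_grid = 10,
                    strategies = NULL, onset = NULL, wtp = NULL) {
  name <- .resolve_param_name(params, name)
  if (!(name %in% names(params$values) || name == "util_posthyst"))
    stop("unknown parameter: ", name)
  if (low >= high) stop("low must be < high")
  if (is.null(wtp)) wtp <- param_get(params, "wtp")
  if (is.null(strategies)) strategies <- enumerate_strategies(params$gene)
  if (is.null(onset) && !.affects_onset(name)) {
    cal <- calibrate_gene(params)
    onset <- list(ec = cal$ec, oc = cal$oc)
  }
  evalr <- .make_evaluator(params, name, strategies, onset, wtp)
  grid <- seq(low, high, length.out = n_grid)
  rows <- list(); optimal <- character(n_grid)
  for (g in seq_along(grid)) {
    cea <- evalr(grid[g])
    optimal[g] <- attr(cea, "optimal")
    df <- as.data.frame(cea)
    df$value <- grid[g]
    df$optimal_strategy <- optimal[g]
    rows[[g]] <- df[, c("value", "strategy", "qalys", "cost", "status",
                        "icer", "optimal_strategy")]
  }
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- name
  attr(out, "grid") <- grid
  attr(out, "optimal") <- optimal
  attr(out, "evaluator") <- evalr
  class(out) <- c("ls_oneway", "data.frame")
  out
}

#' Locate strategy-switch thresholds from a one-way analysis
#'
#' Scans the one-way grid for changes in the optimal strategy and refines
#' each switch point by bisection (re-running the model) down to the stated
#' resolution.
#'
#' @param ow `ls_oneway` result.
#' @param resolution Absolute bracket width at which bisection stops
#'   (default 0.005 in parameter units).
#' @return `ls_threshold` data frame: one row per switch with the bracketing
#'   values (`lower`, `upper`), the midpoint estimate `switch`, and the
#'   optimal strategies `below` and `above`.  Zero rows when the optimum
#'   never changes.
#' @export
find_threshold <- function(ow, resolution = 0.005) {
  grid <- attr(ow, "grid"); optimal <- attr(ow, "optimal")
  if (length(grid) < 2) stop("need a grid of at least 2 points")
  evalr <- attr(ow, "evaluator")
  out <- list()
  for (g in seq_len(length(grid) - 1)) {
    if (optimal[g] == optimal[g + 1]) next
    lo <- grid[g]; hi <- grid[g + 1]
    lab_lo <- optimal[g]; lab_hi <- optimal[g + 1]
    while (hi - lo > resolution && !is.null(evalr)) {
      mid <- (lo + hi) / 2
      lab <- attr(evalr(mid), "optimal")
      if (lab == lab_lo) lo <- mid
      else { hi <- mid; lab_hi <- lab }
    }
    out[[length(out) + 1]] <-
      data.frame(parameter = attr(ow, "parameter"),
                 lower = lo, upper = hi, switch = (lo + hi) / 2,
                 below = lab_lo, above = lab_hi,
                 stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(parameter = character(), lower = numeric(),
               upper = numeric(), switch = numeric(),
               below = character(), above = character(),
               stringsAsFactors = FALSE)
  class(res) <- c("ls_threshold", "data.frame")
  res
}
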