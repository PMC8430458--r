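#' Build a probabilistic-sensitivity-analysis specification
#'
#' Collects every parameter with a sampling distribution in the parameter
#' table (beta for probabilities, gamma for costs, normal for utilities and
#' the published-range normals), restricted to the lifetime risks of the
#' gene under analysis, and fits hyper-parameters with
#' [fit_distribution()].
#'
#' @param params `ls_params`.
#' @param n Number of PSA draws (default 10000).
#' @param seed Integer seed.
#' @return `ls_psa_spec`: list with `table` (name, family, base, low, high),
#'   `fits`, `n`, `seed`.
#' @export
psa_spec <- function(params, n = 10000, seed = 1) {
  tbl <- params$table
  keep <- tbl$distribution != "none"
  risk <- grepl("_cum_risk_", tbl$name)
  keep <- keep & (!risk | grepl(paste0("_", params$gene, "$"), tbl$name))
  tbl <- tbl[keep, ]
  fits <- lapply(seq_len(nrow(tbl)), function(i)
    fit_distribution(tbl$value[i], tbl$low[i], tbl$high[i],
                     tbl$distribution[i]))
  names(fits) <- tbl$name
  structure(list(table = tbl, fits = fits, n = n, seed = seed),
            class = "ls_psa_spec")
}

# clamp a sampled vector to the legal domain of its parameter
.clamp_draws <- function(x, name, units) {
  if (grepl("_cum_risk_", name)) return(pmin(0.99, pmax(0, x)))
  if (units %in% c("probability", "fraction")) return(pmin(1, pmax(0, x)))
  if (units == "risk ratio") return(pmin(1, pmax(0, x)))
  if (units == "2020 USD") return(pmax(0, x))
  if (units == "utility") return(pmin(1, pmax(0, x)))
  if (units == "utility decrement") return(pmin(0, pmax(-1, x)))
  x
}

# renormalize the five stage triplets inside a values vector
.renorm_stage_values <- function(v) {
  for (g in c("ec_stage_noint", "ec_stage_surv",
              "oc_stage_noint", "oc_stage_surv", "oc_stage_rrs")) {
    nm <- paste0(g, "_", c("local", "regional", "distant"))
    s <- pmax(0, v[nm]); tot <- sum(s)
    v[nm] <- if (tot > 0) s / tot else c(1, 0, 0)
  }
  v
}

#' Probabilistic sensitivity analysis with acceptability curves
#'
#' Draws all sampled parameters simultaneously, rescales the calibrated
#' onset schedules to each draw's lifetime risks (one-pass proportional
#' hazard rescale), re-runs every strategy, and records the optimal
#' strategy at each willingness-to-pay grid point.  Reproducible under the
#' specification seed.
#'
#' @param params `ls_params`.
#' @param spec `ls_psa_spec`; default `psa_spec(params)`.
#' @param strategies Strategy list (default: standard grid).
#' @param onset Base-case calibrated schedules (calibrated if `NULL`).
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @return `ls_psa`: list with `ceac` (data frame, one row per WTP x
#'   strategy with the fraction of draws in which it is optimal),
#'   `optimal_fraction` (named fractions at the base-case WTP), `n`, `seed`.
#' @export
run_psa <- function(params, spec = NULL, strategies = NULL, onset = NULL,
                    wtp_grid = seq(0, 2e5, by = 2e4)) {
  if (is.null(spec)) spec <- psa_spec(params)
  if (spec$n < 1) stop("need at least one draw")
  if (is.null(strategies)) strategies <- enumerate_strategies(params$gene)
  if (is.null(onset)) {
    cal <- calibrate_gene(params)
    onset <- list(ec = cal$ec, oc = cal$oc)
  }
  base_wtp <- param_get(params, "wtp")
  wtp_grid <- sort(unique(c(wtp_grid, base_wtp)))
  labels <- vapply(strategies, `[[`, character(1), "label")

  set.seed(spec$seed)
  n <- spec$n
  draws <- matrix(NA_real_, n, nrow(spec$table),
                  dimnames = list(NULL, spec$table$name))
  for (j in seq_len(nrow(spec$table))) {
    nm <- spec$table$name[j]
    draws[, j] <- .clamp_draws(sample_dist(spec$fits[[nm]], n), nm,
                               spec$table$units[j])
  }

  ec_name <- paste0("ec_cum_risk_", params$gene)
  oc_name <- paste0("oc_cum_risk_", params$gene)
  r_ec0 <- param_get(params, ec_name)
  r_oc0 <- param_get(params, oc_name)

  opt_idx <- matrix(0L, n, length(wtp_grid))
  for (i in seq_len(n)) {
    p_i <- params
    p_i$values[colnames(draws)] <- draws[i, ]
    p_i$values <- .renorm_stage_values(p_i$values)
    onset_i <- onset
    if (ec_name %in% colnames(draws))
      onset_i$ec <- rescale_onset(onset$ec, r_ec0, p_i$values[[ec_name]])
    if (oc_name %in% colnames(draws))
      onset_i$oc <- rescale_onset(onset$oc, r_oc0, p_i$values[[oc_name]])
    # frontier needs only cost and QALYs; skip the full summary for speed
    qalys <- numeric(length(strategies)); cost <- numeric(length(strategies))
    for (k in seq_along(strategies)) {
      tr <- run_cohort(strategies[[k]], p_i, onset_i)
      qalys[k] <- accumulate_qalys(tr, p_i)
      cost[k] <- accumulate_costs(tr, p_i)
    }
    res <- data.frame(strategy = labels, cost = cost, qalys = qalys,
                      stringsAsFactors = FALSE)
    cea <- build_frontier(res, wtp = base_wtp)
    for (w in seq_along(wtp_grid))
      opt_idx[i, w] <- match(optimal_at_wtp(cea, wtp_grid[w]), labels)
  }

  frac <- function(w) {
    tab <- tabulate(opt_idx[, w], nbins = length(labels)) / n
    stats::setNames(tab, labels)
  }
  ceac <- do.call(rbind, lapply(seq_along(wtp_grid), function(w) {
    data.frame(wtp = wtp_grid[w], strategy = labels,
               fraction = unname(frac(w)), stringsAsFactors = FALSE)
  }))
  w0 <- match(base_wtp, wtp_grid)
  structure(list(ceac = ceac, optimal_fraction = frac(w0),
                 wtp = base_wtp, n = n, seed = spec$seed,
                 strategies = labels),
            class = "ls_psa")
}

#' @export
print.ls_psa <- function(x, ...) {
  cat("PSA:", x$n, "draws (seed", x$seed, ")\n")
  cat("Optimal-strategy fractions at WTP", x$wtp, ":\n")
  f <- sort(x$optimal_fraction[x$optimal_fraction > 0], decreasing = TRUE)
  for (nm in names(f)) cat(sprintf("  %-28s %6.1f%%\n", nm, 100 * f[nm]))
  invisible(x)
}

#' Write a cost-effectiveness acceptability curve to CSV
#' @param psa `ls_psa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ceac <- function(psa, path) {
  wide <- stats::reshape(psa$ceac, idvar = "wtp", timevar = "strategy",
                         direction = "wide")
  names(wide) <- sub("^fraction\\.", "", names(wide))
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
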