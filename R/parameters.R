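#' @importFrom stats setNames approx qnorm rbeta rgamma rnorm runif
#' @importFrom utils read.table write.table modifyList
NULL

.GENES <- c("MLH1", "MSH2", "MSH6", "PMS2")

# parameter names that must be present exactly once in a parameter table
.required_parameter_names <- function() {
  c("surgical_mortality", "complication_prob",
    "oc_screen_sens", "oc_screen_spec", "ec_screen_sens", "ec_screen_spec",
    "rr_salpingectomy_oc", "rr_oophorectomy_mortality",
    paste0("ec_cum_risk_", .GENES), paste0("oc_cum_risk_", .GENES),
    paste0("ec_stage_noint_", c("local", "regional", "distant")),
    paste0("ec_stage_surv_", c("local", "regional", "distant")),
    paste0("ec_surv5_", c("local", "regional", "distant")),
    paste0("oc_stage_noint_", c("local", "regional", "distant")),
    paste0("oc_stage_surv_", c("local", "regional", "distant")),
    paste0("oc_stage_rrs_", c("local", "regional", "distant")),
    paste0("oc_surv5_", c("local", "regional", "distant")),
    "util_healthy_start", "util_healthy_end",
    "util_hystbso_premenopausal", "util_hystbso_postmenopausal", "util_hystbs",
    paste0("util_ec_", c("local", "regional", "distant")),
    paste0("util_oc_", c("local", "regional", "distant")),
    "disutil_surgery", "disutil_surgery_complication", "disutil_screen",
    "cost_surveillance_initial", "cost_surveillance_subsequent",
    "cost_hysterectomy", "cost_oophorectomy", "cost_complication",
    paste0("cost_ec_initial_", c("local", "regional", "distant")),
    "cost_ec_continuing", "cost_ec_terminal",
    paste0("cost_oc_initial_", c("local", "regional", "distant")),
    "cost_oc_continuing", "cost_oc_terminal",
    "discount_rate", "wtp",
    "start_age", "end_age", "min_intervention_age", "menopause_age")
}

#' Path to a bundled data file
#' @param file File name under the package `extdata` directory.
#' @return Absolute path.
#' @export
lynchcea_extdata <- function(file) {
  p <- system.file("extdata", file, package = "lynchcea")
  if (!nzchar(p)) stop("bundled file not found: ", file)
  p
}

#' Load and validate the full model parameter set for one gene
#'
#' Reads a flat TSV of model inputs (columns `name`, `value`, `low`, `high`,
#' `distribution`, `units`, `source`), attaches a life table and the
#' age-shape anchors of cumulative cancer incidence, and validates every
#' invariant (probabilities in range, stage distributions summing to one,
#' non-negative costs, utilities in \[0,1\], age ordering).
#'
#' @param path Parameter TSV; `NULL` for the bundled base-case table.
#' @param gene One of `"MLH1"`, `"MSH2"`, `"MSH6"`, `"PMS2"`.
#' @param life_table An `ls_life_table`, a path to a two-column age/qx text
#'   file, or `NULL` for the parametric fixture table.
#' @param anchors Data frame with columns `gene`, `site`, `age`, `cum_inc`
#'   giving the cumulative-incidence anchors used for calibration, a path to
#'   such a TSV, or `NULL` for the bundled synthetic reconstruction.
#' @return An object of class `ls_params`.
#' @examples
#' p <- load_parameters(gene = "MSH2")
#' param_get(p, "oc_cum_risk_MSH2")  # 0.174
#' @export
load_parameters <- function(path = NULL, gene, life_table = NULL,
                            anchors = NULL) {
  if (is.null(path)) path <- lynchcea_extdata("default_parameters.tsv")
  if (!file.exists(path)) stop("parameter file not found: ", path)
  tbl <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (is.null(life_table)) {
    life_table <- make_fixture_life_table()
  } else if (is.character(life_table)) {
    life_table <- read_life_table(life_table)
  } else {
    life_table <- validate_life_table(life_table)
  }
  if (is.null(anchors)) anchors <- lynchcea_extdata("risk_anchors_synthetic.tsv")
  if (is.character(anchors)) {
    anchors <- utils::read.table(anchors, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE, comment.char = "#")
  }
  build_parameters(tbl, gene = gene, life_table = life_table,
                   anchors = anchors)
}

#' Assemble a validated parameter object from its components
#'
#' @param table Parameter data frame (`name`, `value`, `low`, `high`,
#'   `distribution`, `units`, `source`).
#' @param gene MMR gene symbol.
#' @param life_table Validated life table.
#' @param anchors Anchor data frame (all genes; the relevant rows are kept).
#' @return `ls_params` object.
#' @export
build_parameters <- function(table, gene, life_table, anchors) {
  gene <- match.arg(gene, .GENES)
  need <- c("name", "value", "low", "high", "distribution", "units")
  if (!all(need %in% names(table)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  if (!"source" %in% names(table)) table$source <- ""
  req <- .required_parameter_names()
  dup <- table$name[duplicated(table$name)]
  if (length(dup)) stop("duplicated parameters: ", paste(dup, collapse = ", "))
  missing <- setdiff(req, table$name)
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  v <- stats::setNames(as.numeric(table$value), table$name)

  if ("gene" %in% names(anchors))
    anchors <- anchors[anchors$gene == gene, ]
  anchors <- anchors[, c("site", "age", "cum_inc")]
  if (!nrow(anchors)) stop("no risk anchors for gene ", gene)
  anchors <- anchors[order(anchors$site, anchors$age), ]

  p <- structure(list(gene = gene, table = table, values = v,
                      life_table = life_table, anchors = anchors),
                 class = "ls_params")
  validate_parameters(p, check_anchor_base = TRUE)
}

#' Validate an `ls_params` object
#'
#' @param p `ls_params` object.
#' @param check_anchor_base Also require the stored final anchors to equal
#'   the lifetime-risk parameters (true at construction; after
#'   [param_set()] of a `*_cum_risk_*` value the stored anchors deliberately
#'   stay at base and [risk_anchors()] rescales them on access).
#' @return `p`, invisibly valid (errors otherwise).
#' @export
validate_parameters <- function(p, check_anchor_base = FALSE) {
  v <- p$values
  chk01 <- function(nm, open0 = FALSE) {
    x <- v[nm]
    bad <- !is.finite(x) | x < 0 | x > 1 | (open0 & x == 0)
    if (any(bad)) stop("parameter out of [0,1]: ",
                       paste(nm[bad], collapse = ", "))
  }
  chk01(c("surgical_mortality", "complication_prob",
          "oc_screen_sens", "oc_screen_spec",
          "ec_screen_sens", "ec_screen_spec"))
  chk01(grep("^(ec|oc)_cum_risk_", names(v), value = TRUE))
  chk01(grep("_surv5_", names(v), value = TRUE), open0 = TRUE)
  chk01(grep("^util_", names(v), value = TRUE))
  stage_groups <- c("ec_stage_noint", "ec_stage_surv",
                    "oc_stage_noint", "oc_stage_surv", "oc_stage_rrs")
  for (g in stage_groups) {
    s <- v[paste0(g, "_", c("local", "regional", "distant"))]
    chk01(names(s))
    if (abs(sum(s) - 1) > 1e-9)
      stop("stage distribution ", g, " does not sum to 1 (", sum(s), ")")
  }
  costs <- v[grep("^cost_", names(v))]
  if (any(costs < 0)) stop("negative cost parameter")
  dec <- v[grep("^disutil_", names(v))]
  if (any(dec > 0)) stop("utility decrements must be <= 0")
  if (v["discount_rate"] < 0) stop("discount_rate must be >= 0")
  if (!(v["start_age"] < v["min_intervention_age"] &&
        v["min_intervention_age"] < v["end_age"]))
    stop("need start_age < min_intervention_age < end_age")
  if (v["rr_oophorectomy_mortality"] < 1)
    stop("rr_oophorectomy_mortality must be >= 1")
  for (site in unique(p$anchors$site)) {
    a <- p$anchors[p$anchors$site == site, ]
    if (is.unsorted(a$cum_inc)) stop("anchors for ", site, " not non-decreasing")
    if (any(a$cum_inc < 0 | a$cum_inc >= 1)) stop("anchor CI outside [0, 1)")
    if (check_anchor_base) {
      tgt <- v[paste0(tolower(site), "_cum_risk_", p$gene)]
      if (abs(a$cum_inc[nrow(a)] - tgt) > 1e-9)
        stop("final ", site, " anchor must equal the gene cumulative risk")
    }
  }
  invisible(p)
}

#' @export
print.ls_params <- function(x, ...) {
  cat("Lynch-syndrome model parameters for", x$gene, "\n")
  cat("  EC cumulative risk to 75:",
      param_get(x, paste0("ec_cum_risk_", x$gene)), "\n")
  cat("  OC cumulative risk to 75:",
      param_get(x, paste0("oc_cum_risk_", x$gene)), "\n")
  cat("  ", nrow(x$table), "parameters; life table ages",
      min(x$life_table$age), "-", max(x$life_table$age), "\n")
  invisible(x)
}

#' Get a parameter value by name
#' @param p `ls_params` object.
#' @param name Parameter name (row of the parameter table).
#' @return Numeric scalar.
#' @export
param_get <- function(p, name) {
  if (!name %in% names(p$values)) stop("unknown parameter: ", name)
  unname(p$values[name])
}

#' Set a parameter value by name
#'
#' Returns a modified copy; the stored cumulative-incidence anchors are kept
#' as-is (accessors rescale them to the current age-75 risk, so changing a
#' `*_cum_risk_*` value rescales the whole age curve on a proportional-hazard
#' basis).
#'
#' @param p `ls_params` object.
#' @param name Parameter name. The alias `"util_posthyst"` sets
#'   `util_hystbs` and `util_hystbso_postmenopausal` together (they share one
#'   published estimate).
#' @param value New numeric value.
#' @param validate Re-run the full validation (default TRUE).
#' @return Modified `ls_params`.
#' @export
param_set <- function(p, name, value, validate = TRUE) {
  if (identical(name, "util_posthyst")) {
    p <- param_set(p, "util_hystbs", value, validate = FALSE)
    p <- param_set(p, "util_hystbso_postmenopausal", value,
                   validate = validate)
    return(p)
  }
  if (!name %in% names(p$values)) stop("unknown parameter: ", name)
  p$values[name] <- value
  p$table$value[p$table$name == name] <- value
  if (validate) validate_parameters(p)
  p
}

#' Cumulative-incidence anchors for one cancer site, rescaled to the current
#' lifetime-risk parameter
#'
#' The stored anchor curve fixes the age shape; its level follows the current
#' `ec_cum_risk_*` / `oc_cum_risk_*` value by raising each anchor's survival
#' to the power `log(1 - risk) / log(1 - base_risk)` (a proportional-hazards
#' rescale that preserves monotonicity and the \[0,1) range).
#'
#' @param p `ls_params` object.
#' @param site `"EC"` or `"OC"`.
#' @return Data frame with columns `age`, `ci`.
#' @export
risk_anchors <- function(p, site) {
  site <- match.arg(site, c("EC", "OC"))
  a <- p$anchors[p$anchors$site == site, ]
  base <- a$cum_inc[nrow(a)]
  cur <- param_get(p, paste0(tolower(site), "_cum_risk_", p$gene))
  ci <- a$cum_inc
  if (base > 0 && abs(cur - base) > 1e-12) {
    k <- log1p(-cur) / log1p(-base)
    ci <- 1 - (1 - ci)^k
  } else if (base == 0) {
    ci <- rep(0, length(ci))
    ci[length(ci)] <- cur
  }
  data.frame(age = a$age, ci = ci)
}

# age-adjusted healthy utility (linear between the published endpoints)
u_healthy <- function(p, ages) {
  a0 <- param_get(p, "start_age"); a1 <- param_get(p, "end_age")
  u0 <- param_get(p, "util_healthy_start")
  u1 <- param_get(p, "util_healthy_end")
  u0 + (u1 - u0) * (pmin(pmax(ages, a0), a1) - a0) / (a1 - a0)
}

#' Write a parameter table to TSV (round-trips with `load_parameters`)
#' @param p `ls_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  utils::write.table(p$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Perturb a parameter set for test scenarios
#'
#' Applies the conventional perturbation rules: a multiplicative factor on
#' probability-type inputs (default range +/-10%), a multiplicative factor
#' on costs (+/-20%) and an additive shift on utilities (+/-0.10), either
#' deterministically (scalar factors) or drawn uniformly per parameter under
#' a seed.  Results are clamped to legal domains (probabilities and
#' utilities to \[0,1\], costs to non-negative, decrements to \[-1,0\]).
#'
#' @param p `ls_params` object.
#' @param prob_factor Scalar multiplier for probabilities/fractions, or
#'   `NULL` to draw from `U(0.9, 1.1)` per parameter.
#' @param cost_factor Scalar multiplier for costs, or `NULL` for
#'   `U(0.8, 1.2)`.
#' @param utility_shift Scalar additive shift for utilities, or `NULL` for
#'   `U(-0.1, 0.1)`.
#' @param seed Integer seed used when any rule is drawn randomly.
#' @return Perturbed `ls_params` (stage distributions renormalized).
#' @export
perturb_parameters <- function(p, prob_factor = NULL, cost_factor = NULL,
                               utility_shift = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tbl <- p$table
  is_prob <- tbl$units %in% c("probability", "fraction") |
    tbl$name == "rr_salpingectomy_oc"
  is_cost <- tbl$units == "2020 USD"
  is_util <- tbl$units == "utility"
  is_dec <- tbl$units == "utility decrement"
  n <- nrow(tbl)
  pf <- if (is.null(prob_factor)) stats::runif(n, 0.9, 1.1) else rep(prob_factor, n)
  cf <- if (is.null(cost_factor)) stats::runif(n, 0.8, 1.2) else rep(cost_factor, n)
  us <- if (is.null(utility_shift)) stats::runif(n, -0.1, 0.1) else rep(utility_shift, n)
  val <- tbl$value
  val[is_prob] <- pmin(1, pmax(0, val[is_prob] * pf[is_prob]))
  val[is_cost] <- pmax(0, val[is_cost] * cf[is_cost])
  val[is_util] <- pmin(1, pmax(0, val[is_util] + us[is_util]))
  val[is_dec] <- pmin(0, pmax(-1, val[is_dec] * pf[is_dec]))
  tbl$value <- val
  tbl <- .renormalize_stages(tbl)
  build_parameters(tbl, gene = p$gene, life_table = p$life_table,
                   anchors = .rebase_anchor_table(p, tbl))
}

# rescale stage triplets so they sum to one again after perturbation/sampling
.renormalize_stages <- function(tbl) {
  for (g in c("ec_stage_noint", "ec_stage_surv",
              "oc_stage_noint", "oc_stage_surv", "oc_stage_rrs")) {
    nm <- paste0(g, "_", c("local", "regional", "distant"))
    i <- match(nm, tbl$name)
    s <- pmax(0, tbl$value[i])
    tot <- sum(s)
    tbl$value[i] <- if (tot > 0) s / tot else c(1, 0, 0)
  }
  tbl
}

# rebuild an anchor table whose final anchors match (possibly new) lifetime
# risks in `tbl`, preserving the stored age shape
.rebase_anchor_table <- function(p, tbl) {
  out <- do.call(rbind, lapply(c("EC", "OC"), function(site) {
    a <- p$anchors[p$anchors$site == site, ]
    base <- a$cum_inc[nrow(a)]
    cur <- tbl$value[tbl$name == paste0(tolower(site), "_cum_risk_", p$gene)]
    ci <- a$cum_inc
    if (base > 0) {
      k <- log1p(-min(cur, 0.999)) / log1p(-base)
      ci <- 1 - (1 - ci)^k
    } else {
      ci <- c(rep(0, length(ci) - 1), cur)
    }
    data.frame(gene = p$gene, site = site, age = a$age, cum_inc = ci)
  }))
  rownames(out) <- NULL
  out
}
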