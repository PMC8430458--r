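#' Assemble a run configuration
#'
#' @param path Optional JSON file whose fields override the defaults below.
#' @param ... Named overrides applied after the file.
#' @return `ls_config` list: `genes`, `parameter_path`, `life_table` (path
#'   or `NULL` for the parametric fixture), `grid_path`, `wtp`,
#'   `discount_rate`, `psa_n`, `seed`, `out_dir`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(genes = .GENES, parameter_path = NULL, life_table = NULL,
              grid_path = NULL, wtp = NULL, discount_rate = NULL,
              psa_n = 10000, seed = 1, out_dir = ".")
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- utils::modifyList(cfg, jsonlite::fromJSON(path,
                                                     simplifyVector = TRUE))
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  bad <- setdiff(cfg$genes, .GENES)
  if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "ls_config")
}

.load_config_params <- function(cfg, gene) {
  p <- load_parameters(cfg$parameter_path, gene = gene,
                       life_table = cfg$life_table)
  if (!is.null(cfg$wtp)) p <- param_set(p, "wtp", cfg$wtp)
  if (!is.null(cfg$discount_rate))
    p <- param_set(p, "discount_rate", cfg$discount_rate)
  p
}

# header lines embedded in every report file for reproducibility
.report_header <- function(cfg, extra = character()) {
  c(paste0("# lynchcea ", as.character(utils::packageVersion("lynchcea"))),
    paste0("# seed: ", cfg$seed),
    extra)
}

#' Base-case analysis for one gene
#'
#' Calibrates the gene's onset schedules, runs every strategy and builds
#' the cost-effectiveness frontier.
#'
#' @param gene MMR gene symbol.
#' @param params Optional pre-built `ls_params`.
#' @param strategies Optional strategy list.
#' @return List with `results` (`ls_result`), `cea` (`ls_cea`) and
#'   `calibration` reports.
#' @export
basecase_gene <- function(gene, params = NULL, strategies = NULL) {
  if (is.null(params)) params <- load_parameters(gene = gene)
  if (is.null(strategies)) strategies <- enumerate_strategies(gene)
  cal <- calibrate_gene(params)
  res <- evaluate_strategies(params, strategies,
                             onset = list(ec = cal$ec, oc = cal$oc))
  cea <- build_frontier(res, wtp = param_get(params, "wtp"))
  list(results = res, cea = cea, calibration = cal$reports)
}

#' Write base-case outcome tables for every configured gene
#'
#' One TSV per gene, mirroring the primary/secondary outcome table layout:
#' per strategy, QALYs, life-years, EC and OC incidence and mortality (as
#' percentages), discounted cost, dominance status, ICER and an optimal
#' flag.
#'
#' @param config `ls_config` (or path to a JSON config).
#' @return Named character vector of files written, invisibly; the per-gene
#'   result objects as the `"results"` attribute.
#' @export
cmd_basecase <- function(config = run_config()) {
  if (is.character(config)) config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0); all_res <- list()
  for (gene in config$genes) {
    p <- .load_config_params(config, gene)
    strategies <- enumerate_strategies(gene, config$grid_path)
    if (!length(strategies)) stop("empty strategy grid")
    bc <- basecase_gene(gene, params = p, strategies = strategies)
    tab <- as.data.frame(bc$cea)
    out <- data.frame(
      strategy = tab$strategy,
      qalys = round(tab$qalys, 2),
      life_years = round(tab$life_years, 2),
      ec_incidence_pct = round(100 * tab$ec_incidence, 2),
      ec_mortality_pct = round(100 * tab$ec_mortality, 2),
      oc_incidence_pct = round(100 * tab$oc_incidence, 2),
      oc_mortality_pct = round(100 * tab$oc_mortality, 2),
      cost = round(tab$cost),
      status = tab$status,
      icer = round(tab$icer),
      optimal = tab$optimal)
    f <- file.path(config$out_dir, paste0("basecase_", gene, ".tsv"))
    writeLines(.report_header(config, paste0("# gene: ", gene)), f)
    suppressWarnings(utils::write.table(out, f, sep = "\t",
                                        row.names = FALSE, quote = FALSE,
                                        append = TRUE))
    files[gene] <- f
    all_res[[gene]] <- bc
  }
  attr(files, "results") <- all_res
  invisible(files)
}

#' Run a sensitivity analysis and write its report files
#'
#' @param config `ls_config` (or path to JSON config).
#' @param mode `"oneway"`, `"threshold"` or `"psa"`.
#' @param gene Gene to analyze (default: first configured gene).
#' @param parameter Parameter name for `oneway`/`threshold` modes.
#' @param low,high Grid range for `oneway`/`threshold`.
#' @param n_grid Grid size (default 10).
#' @return Path(s) of the files written, invisibly, with the result object
#'   as the `"result"` attribute.
#' @export
cmd_sensitivity <- function(config = run_config(),
                            mode = c("oneway", "threshold", "psa"),
                            gene = NULL, parameter = NULL,
                            low = NULL, high = NULL, n_grid = 10) {
  if (is.character(config)) config <- run_config(config)
  mode <- match.arg(mode)
  if (is.null(gene)) gene <- config$genes[1]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- .load_config_params(config, gene)
  strategies <- enumerate_strategies(gene, config$grid_path)
  if (mode == "psa") {
    spec <- psa_spec(p, n = config$psa_n, seed = config$seed)
    t0 <- Sys.time()
    psa <- run_psa(p, spec, strategies = strategies)
    dt <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
    f <- file.path(config$out_dir, paste0("ceac_", gene, ".csv"))
    writeLines(c(.report_header(config,
                                c(paste0("# gene: ", gene),
                                  paste0("# n: ", config$psa_n),
                                  paste0("# runtime_s: ", dt)))), f)
    wide <- stats::reshape(psa$ceac, idvar = "wtp", timevar = "strategy",
                           direction = "wide")
    names(wide) <- sub("^fraction\\.", "", names(wide))
    suppressWarnings(utils::write.table(wide, f, sep = ",",
                                        row.names = FALSE, append = TRUE))
    attr(f, "result") <- psa
    return(invisible(f))
  }
  if (is.null(parameter) || is.null(low) || is.null(high))
    stop(mode, " mode needs `parameter`, `low` and `high`")
  ow <- one_way(p, parameter, low, high, n_grid = n_grid,
                strategies = strategies)
  if (mode == "oneway") {
    f <- file.path(config$out_dir,
                   paste0("oneway_", gene, "_", parameter, ".tsv"))
    writeLines(.report_header(config, paste0("# gene: ", gene)), f)
    suppressWarnings(utils::write.table(as.data.frame(ow), f, sep = "\t",
                                        row.names = FALSE, quote = FALSE,
                                        append = TRUE))
    attr(f, "result") <- ow
    return(invisible(f))
  }
  th <- find_threshold(ow)
  f <- file.path(config$out_dir,
                 paste0("threshold_", gene, "_", parameter, ".tsv"))
  writeLines(.report_header(config, paste0("# gene: ", gene)), f)
  suppressWarnings(utils::write.table(as.data.frame(th), f, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  attr(f, "result") <- th
  invisible(f)
}

#' Command-line entry point
#'
#' Subcommands: `basecase`, `oneway`, `threshold`, `psa`.  Example:
#' `Rscript -e 'lynchcea::cli_main()' basecase --gene MSH2 --out results/`
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   trailing arguments of the Rscript call).
#' @return Exit status 0, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop("usage: <basecase|oneway|threshold|psa> [--gene G] [--config F] ",
         "[--parameter P --low X --high Y] [--n N] [--seed S] [--wtp W] ",
         "[--discount D] [--life-table F] [--out DIR]")
  cmd <- args[1]; rest <- args[-1]
  getopt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i)) rest[i[1] + 1] else default
  }
  cfg <- run_config(getopt("--config"))
  gene <- getopt("--gene")
  if (!is.null(gene)) cfg$genes <- gene
  cfg$out_dir <- getopt("--out", cfg$out_dir)
  cfg$seed <- as.integer(getopt("--seed", cfg$seed))
  cfg$psa_n <- as.integer(getopt("--n", cfg$psa_n))
  if (!is.null(getopt("--wtp"))) cfg$wtp <- as.numeric(getopt("--wtp"))
  if (!is.null(getopt("--discount")))
    cfg$discount_rate <- as.numeric(getopt("--discount"))
  lt <- getopt("--life-table")
  if (!is.null(lt)) cfg$life_table <- lt
  switch(cmd,
         basecase = cmd_basecase(cfg),
         oneway = ,
         threshold = cmd_sensitivity(cfg, mode = cmd, gene = cfg$genes[1],
                                     parameter = getopt("--parameter"),
                                     low = as.numeric(getopt("--low")),
                                     high = as.numeric(getopt("--high")),
                                     n_grid = as.integer(getopt("--grid", 10))),
         psa = cmd_sensitivity(cfg, mode = "psa", gene = cfg$genes[1]),
         stop("unknown subcommand: ", cmd))
  invisible(0)
}
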