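#' Cost-effectiveness frontier with dominance and ICERs
#'
#' Orders strategies by discounted cost, removes strictly dominated options
#' (at least as costly and no more effective than another), then iteratively
#' removes extendedly dominated options (whose ICER against the next cheaper
#' frontier strategy exceeds that of a more effective strategy), and
#' computes ICERs along the surviving efficiency frontier.  Cost ties are
#' broken in favor of higher QALYs, then stable input order.
#'
#' @param results `ls_result` data frame (one gene; columns `strategy`,
#'   `cost`, `qalys`).
#' @param wtp Willingness-to-pay threshold used to flag the optimal
#'   strategy; default from the attached results or 100000.
#' @return An `ls_cea` data frame sorted by cost with columns `status`
#'   (`"frontier"`, `"dominated"`, `"extendedly_dominated"`), `icer` (NA off
#'   the frontier and for the cheapest frontier strategy) and `optimal`
#'   (logical), plus attribute `optimal` (the label).
#' @export
build_frontier <- function(results, wtp = 100000) {
  df <- as.data.frame(results)
  stopifnot(all(c("strategy", "cost", "qalys") %in% names(df)))
  if (anyDuplicated(df$strategy)) stop("duplicate strategy labels")
  if (!nrow(df)) stop("no strategies to compare")
  df <- df[order(df$cost, -df$qalys), ]
  n <- nrow(df)
  status <- rep("frontier", n)

  # strict dominance: an option is dominated if some other option has
  # cost <= and qalys >= with at least one strict inequality
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$qalys[j] >= df$qalys[i] &&
          (df$cost[j] < df$cost[i] || df$qalys[j] > df$qalys[i])) {
        status[i] <- "dominated"
        break
      }
    }
  }

  # extended dominance: ICERs along the remaining frontier must be
  # non-decreasing in cost; offenders are removed iteratively
  repeat {
    idx <- which(status == "frontier")
    if (length(idx) < 3) break
    icers <- diff(df$cost[idx]) / diff(df$qalys[idx])
    bad <- which(diff(icers) < 0)
    if (!length(bad)) break
    status[idx[bad[1] + 1]] <- "extendedly_dominated"
  }

  df$status <- status
  df$icer <- NA_real_
  idx <- which(status == "frontier")
  if (length(idx) > 1)
    df$icer[idx[-1]] <- diff(df$cost[idx]) / diff(df$qalys[idx])
  opt <- optimal_at_wtp(df, wtp)
  df$optimal <- df$strategy == opt
  attr(df, "optimal") <- opt
  attr(df, "wtp") <- wtp
  class(df) <- c("ls_cea", "data.frame")
  df
}

#' Optimal strategy at a willingness-to-pay threshold
#'
#' Returns the most effective frontier strategy whose ICER does not exceed
#' `wtp`; the cheapest frontier strategy qualifies unconditionally.
#'
#' @param cea `ls_cea` frontier (or any data frame with `strategy`, `cost`,
#'   `qalys`, `status`, `icer`).
#' @param wtp Willingness-to-pay in USD per QALY.
#' @return Strategy label.
#' @export
optimal_at_wtp <- function(cea, wtp) {
  f <- cea[cea$status == "frontier", ]
  if (!nrow(f)) stop("empty frontier")
  f <- f[order(f$cost), ]
  ok <- which(is.na(f$icer) | f$icer <= wtp)
  # frontier ICERs are non-decreasing, so admissible strategies form a
  # prefix; take the most effective one
  f$strategy[max(ok)]
}

#' @export
print.ls_cea <- function(x, ...) {
  cols <- intersect(c("strategy", "qalys", "cost", "status", "icer",
                      "optimal"), names(x))
  print(as.data.frame(x)[, cols], row.names = FALSE, digits = 6)
  cat("Optimal at WTP", attr(x, "wtp"), ":", attr(x, "optimal"), "\n")
  invisible(x)
}

#' Export a frontier table to TSV
#' @param cea `ls_cea`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cea <- function(cea, path) {
  utils::write.table(as.data.frame(cea), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
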