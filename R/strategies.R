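#' Define a prevention strategy
#'
#' A strategy is defined by the age of hysterectomy (with bilateral
#' salpingectomy; ovaries are removed in the same operation when
#' `ooph_age == hyst_age`), the age of oophorectomy, and the age at which
#' annual surveillance starts.  `Inf` means never.  Surveillance runs
#' annually from its start age until the first positive result or
#' risk-reducing surgery.
#'
#' @param hyst_age Age of hysterectomy + bilateral salpingectomy (`Inf` =
#'   never).
#' @param ooph_age Age of bilateral oophorectomy (`Inf` = never; must be
#'   `>= hyst_age` - ovaries are not removed while the uterus is retained in
#'   any modeled strategy).
#' @param surveillance_start Age annual EC + OC surveillance begins (`Inf` =
#'   none).  Must be below `hyst_age`.
#' @param gene Optional gene tag.
#' @param label Display label; a conventional one is built if omitted.
#' @param min_age Earliest permissible intervention age (default 30).
#' @return An `ls_strategy` object.
#' @export
strategy <- function(hyst_age = Inf, ooph_age = hyst_age,
                     surveillance_start = Inf, gene = NULL, label = NULL,
                     min_age = 30) {
  ages <- c(hyst_age, ooph_age, surveillance_start)
  if (any(is.finite(ages) & ages < min_age))
    stop("no intervention may be scheduled before age ", min_age)
  if (is.finite(ooph_age) && !is.finite(hyst_age))
    stop("oophorectomy without hysterectomy is not a modeled strategy")
  if (is.finite(ooph_age) && ooph_age < hyst_age)
    stop("ooph_age must be >= hyst_age")
  if (is.finite(surveillance_start) && surveillance_start >= hyst_age)
    stop("surveillance starting at or after surgery is incoherent")
  if (is.null(label)) {
    label <-
      if (!is.finite(hyst_age) && !is.finite(surveillance_start))
        "Natural history"
      else if (!is.finite(hyst_age))
        paste0("Surveillance: ", surveillance_start)
      else if (is.finite(ooph_age) && ooph_age > hyst_age)
        "2-stage approach"
      else {
        base <- paste0("Hyst-BSO: ", hyst_age)
        if (is.finite(surveillance_start))
          paste0(base, ", survey: ", surveillance_start) else base
      }
  }
  structure(list(label = label, gene = gene, hyst_age = hyst_age,
                 ooph_age = ooph_age,
                 surveillance_start = surveillance_start),
            class = "ls_strategy")
}

#' @export
print.ls_strategy <- function(x, ...) {
  cat("Strategy:", x$label,
      if (!is.null(x$gene)) paste0("(", x$gene, ")"), "\n")
  invisible(x)
}

#' Natural-history (no intervention) strategy
#' @param gene Optional gene tag.
#' @return `ls_strategy`.
#' @export
strategy_natural_history <- function(gene = NULL) {
  strategy(gene = gene)
}

#' Enumerate the default strategy grid for a gene
#'
#' The default grid holds twelve arms: hysterectomy-BSO at 35, 40 or 50
#' years crossed with surveillance starting at 30, 35 or never (combinations
#' where surveillance would start at or after surgery are dropped),
#' surveillance alone from 30 or 35, the 2-stage approach (hysterectomy with
#' bilateral salpingectomy at 40 and oophorectomy at 50, no surveillance),
#' and natural history.  A JSON grid file (array of objects with fields
#' `hyst_age`, `ooph_age`, `surveillance_start`, optional `label`; `null` or
#' `"never"` for never) overrides the default.
#'
#' @param gene MMR gene symbol.
#' @param grid_path Optional JSON strategy-grid file.
#' @return List of `ls_strategy` objects.
#' @export
enumerate_strategies <- function(gene, grid_path = NULL) {
  gene <- match.arg(gene, .GENES)
  if (!is.null(grid_path)) {
    raw <- jsonlite::fromJSON(grid_path, simplifyVector = FALSE)
    if (!length(raw)) stop("strategy grid is empty")
    return(lapply(raw, function(r) {
      num <- function(x, default = Inf) {
        if (is.null(x) || identical(x, "never")) default else as.numeric(x)
      }
      strategy(hyst_age = num(r$hyst_age),
               ooph_age = num(r$ooph_age, default = num(r$hyst_age)),
               surveillance_start = num(r$surveillance_start),
               gene = gene, label = r$label)
    }))
  }
  out <- list()
  for (h in c(35, 40, 50)) {
    for (s in c(30, 35, Inf)) {
      if (is.finite(s) && s >= h) next
      out <- c(out, list(strategy(h, h, s, gene = gene)))
    }
  }
  out <- c(out,
           list(strategy(surveillance_start = 30, gene = gene),
                strategy(surveillance_start = 35, gene = gene),
                strategy(40, 50, Inf, gene = gene),
                strategy_natural_history(gene)))
  out
}
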