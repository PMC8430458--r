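#' Gompertz-Makeham fixture life table
#'
#' Builds a parametric annual life table for the female cohort, used as a
#' download-free stand-in for a national (CDC-style) women's life table.
#' The annual probability of all-cause death is
#' \deqn{q_x(a) = \min(1,\; A + B e^{C a})}
#' with defaults chosen to approximate contemporary US female mortality
#' (about 4e-4 at age 25, 3e-3 at 50, 2.2e-2 at 75).
#'
#' @param A Makeham (age-independent) hazard component, >= 0.
#' @param B Gompertz scale, > 0.
#' @param C Gompertz log-slope per year of age, > 0.
#' @param ages Integer ages covered; must include 25..75.
#' @return A `data.frame` with columns `age` and `qx`, classed
#'   `"ls_life_table"`.
#' @examples
#' lt <- make_fixture_life_table()
#' lt$qx[lt$age == 50]  # ~0.0030
#' @export
make_fixture_life_table <- function(A = 0, B = 5.5e-5, C = 0.08,
                                    ages = 25:110) {
  if (!is.numeric(A) || A < 0) stop("A must be >= 0")
  if (!is.numeric(B) || B <= 0) stop("B must be > 0")
  if (!is.numeric(C) || C <= 0) stop("C must be > 0")
  ages <- as.integer(ages)
  qx <- pmin(1, A + B * exp(C * ages))
  lt <- data.frame(age = ages, qx = qx)
  validate_life_table(lt)
}

#' Read a life table from a two-column text file
#'
#' Accepts the simple interchange format `age<TAB>qx` (header optional,
#' column names `age` and `qx` if present), so a real national life table
#' can be swapped in for the parametric fixture.
#'
#' @param path Path to a whitespace/tab-delimited text file.
#' @return A validated `ls_life_table` data frame.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path)
  first <- readLines(path, n = 1L)
  header <- grepl("age", first, ignore.case = TRUE)
  lt <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  names(lt)[1:2] <- c("age", "qx")
  validate_life_table(lt[, c("age", "qx")])
}

#' Validate a life table
#'
#' Checks the invariants required by the cohort engine: integer ages with
#' full coverage of the modeled range 25-75, and death probabilities in
#' \[0, 1\].
#'
#' @param lt Data frame with columns `age`, `qx`.
#' @return The life table, classed `"ls_life_table"`, ordered by age.
#' @export
validate_life_table <- function(lt) {
  stopifnot(is.data.frame(lt), all(c("age", "qx") %in% names(lt)))
  lt <- lt[order(lt$age), c("age", "qx")]
  if (anyDuplicated(lt$age)) stop("duplicate ages in life table")
  if (any(!is.finite(lt$qx)) || any(lt$qx < 0) || any(lt$qx > 1))
    stop("life table qx values must lie in [0, 1]")
  covered <- 25:75
  if (!all(covered %in% lt$age))
    stop("life table must cover ages 25 through 75")
  class(lt) <- c("ls_life_table", "data.frame")
  rownames(lt) <- NULL
  lt
}

# annual death probability lookup for a vector of ages
lt_qx <- function(lt, ages) {
  idx <- match(ages, lt$age)
  if (anyNA(idx)) stop("ages outside life table range: ",
                       paste(ages[is.na(idx)], collapse = ", "))
  lt$qx[idx]
}

#' Write a life table (or onset schedule) to the two-column text format
#'
#' @param x Data frame whose first two columns are age and a per-age value.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
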