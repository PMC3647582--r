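#' Construct a 2x2 exposure-by-status contingency table
#'
#' The canonical unit of the package: counts of carrier/non-carrier subjects
#' among cases and controls. Cell layout follows the epidemiological
#' convention
#' \preformatted{
#'                 exposed  unexposed
#'   cases            a         b
#'   controls         c         d
#' }
#'
#' @param a exposed (carrier) cases.
#' @param b unexposed cases.
#' @param c exposed controls.
#' @param d unexposed controls.
#' @return An object of class \code{"contingency_table"}: a named list with
#'   integer fields \code{a}, \code{b}, \code{c}, \code{d}.
#' @examples
#' contingency_table(3, 7, 8, 2)
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (length(cells) != 4L || anyNA(cells) || !is.numeric(cells))
    stop("all four cells must be supplied as numbers", call. = FALSE)
  if (any(cells < 0))
    stop("cell counts must be non-negative", call. = FALSE)
  if (any(abs(cells - round(cells)) > 1e-8))
    stop("cell counts must be integers", call. = FALSE)
  cells <- as.list(as.integer(round(cells)))
  names(cells) <- c("a", "b", "c", "d")
  structure(cells, class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- as.matrix(x)
  cat("2x2 contingency table (rows: case/control, cols: exposed/unexposed)\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_table <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), nrow = 2L,
         dimnames = list(c("case", "control"), c("exposed", "unexposed")))
}

as_table2x2 <- function(x) {
  if (inherits(x, "contingency_table")) return(x)
  if (is.matrix(x) && all(dim(x) == 2L))
    return(contingency_table(x[1, 1], x[1, 2], x[2, 1], x[2, 2]))
  if (is.numeric(x) && length(x) == 4L)
    return(contingency_table(x[1], x[2], x[3], x[4]))
  stop("cannot interpret input as a 2x2 table", call. = FALSE)
}

#' Cross-product odds ratio of a 2x2 table
#'
#' Returns \eqn{(a d)/(b c)}. With a zero cell the cross-product is reported
#' as a sentinel rather than silently corrected: \code{Inf} when only the
#' denominator product vanishes, \code{NaN} when both products vanish. An
#' explicit Haldane-Anscombe continuity correction (+0.5 to every cell) is
#' available but off by default, so that estimates and sentinels are never
#' mixed unknowingly.
#'
#' @param table a \code{\link{contingency_table}} (or 2x2 matrix / length-4
#'   vector in a, b, c, d order).
#' @param continuity add 0.5 to every cell before forming the ratio.
#' @return A single numeric odds ratio; possibly \code{Inf} or \code{NaN}.
#' @examples
#' odds_ratio(contingency_table(2, 18, 34, 6))   # 0.0196
#' odds_ratio(contingency_table(5, 0, 3, 4))     # Inf
#' @export
odds_ratio <- function(table, continuity = FALSE) {
  t <- as_table2x2(table)
  cells <- as.numeric(c(t$a, t$b, t$c, t$d))  # avoid integer overflow
  if (isTRUE(continuity)) cells <- cells + 0.5
  num <- cells[1] * cells[4]
  den <- cells[2] * cells[3]
  if (den == 0) {
    if (num == 0) return(NaN)
    return(Inf)
  }
  num / den
}

#' Wald confidence interval for the log odds ratio
#'
#' @param table a \code{\link{contingency_table}}.
#' @param conf_level confidence level, default 0.95.
#' @return Named numeric vector \code{c(lower, or, upper)}; degenerate
#'   tables (a zero cell) yield \code{NA} bounds.
#' @export
odds_ratio_ci <- function(table, conf_level = 0.95) {
  t <- as_table2x2(table)
  or <- odds_ratio(t)
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0) || !is.finite(or))
    return(c(lower = NA_real_, or = or, upper = NA_real_))
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(lower = exp(log(or) - z * se), or = or, upper = exp(log(or) + z * se))
}

## Relative slack used to group point probabilities that are equal up to
## floating-point noise when accumulating the two-sided tail.
TWO_SIDED_TIE_TOL <- 1e-7

## log(sum(exp(lx))) without overflow; -Inf for an empty selection.
logsumexp <- function(lx) {
  if (length(lx) == 0L) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

## P-values over the full hypergeometric support of a margin.
##
## lp: log point probabilities over the support (in support order).
## Returns, for every support point, the Fisher p-value of the table having
## that count in cell `a`, under the requested alternative. The two-sided
## rule is "sum of point probabilities <= observed", with relative tie
## slack TWO_SIDED_TIE_TOL. Shared by fisher_exact() and the power engine
## so both use one rejection convention.
hyper_pvalues <- function(lp, alternative) {
  m <- max(lp)
  p <- exp(lp - m)                       # relative scale, sums to exp(-m)
  scale <- exp(m)
  switch(alternative,
    less = pmin(cumsum(p) * scale, 1),
    greater = pmin(rev(cumsum(rev(p))) * scale, 1),
    two.sided = {
      sp <- sort(p)
      cs <- cumsum(sp)
      pmin(cs[findInterval(p * (1 + TWO_SIDED_TIE_TOL), sp)] * scale, 1)
    },
    stop("unknown alternative: ", alternative, call. = FALSE))
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test of independence based on the hypergeometric
#' distribution with all margins fixed at their observed values. Point
#' probabilities are evaluated in log space; tails are accumulated with
#' log-sum-exp, so the test is stable up to totals of order 1e4. The
#' two-sided p-value sums the probabilities of every table in the support
#' whose point probability does not exceed that of the observed table
#' (with a small relative slack for floating-point ties) -- the dominant
#' convention, and the one used by the power engine's rejection rule.
#'
#' @param table a \code{\link{contingency_table}}.
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}; directions refer to cell \code{a} (exposed cases)
#'   given the margins.
#' @return A single p-value in [0, 1]. A table with an empty row or column
#'   carries no information against independence: p = 1 with a warning.
#' @examples
#' fisher_exact(contingency_table(3, 7, 8, 2), "less")       # 0.0349
#' fisher_exact(contingency_table(3, 7, 8, 2), "two.sided")  # 0.0698
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "less", "greater")) {
  t <- as_table2x2(table)
  alternative <- match.arg(alternative)
  n_case <- t$a + t$b
  n_ctrl <- t$c + t$d
  n_exp <- t$a + t$c
  n_unexp <- t$b + t$d
  if (n_case == 0L || n_ctrl == 0L || n_exp == 0L || n_unexp == 0L) {
    warning("degenerate margins (empty row or column); returning p = 1")
    return(1)
  }
  s <- n_exp                                  # exposed-column total
  supp <- max(0L, s - n_ctrl):min(s, n_case)  # support of cell a
  lp <- stats::dhyper(supp, n_case, n_ctrl, s, log = TRUE)
  pv <- hyper_pvalues(lp, alternative)
  unname(pv[match(t$a, supp)])
}

#' Read 2x2 tables from a TSV file
#'
#' One scenario per row, header columns \code{exposed_cases},
#' \code{unexposed_cases}, \code{exposed_controls},
#' \code{unexposed_controls}.
#'
#' @param path file path.
#' @return A list of \code{\link{contingency_table}} objects, named by a
#'   \code{label} column when present.
#' @export
read_tables_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("exposed_cases", "unexposed_cases",
            "exposed_controls", "unexposed_controls")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    contingency_table(df$exposed_cases[i], df$unexposed_cases[i],
                      df$exposed_controls[i], df$unexposed_controls[i]))
  if ("label" %in% names(df)) names(out) <- df$label
  out
}

#' Write 2x2 tables to a TSV file
#'
#' @param tables a list of \code{\link{contingency_table}} objects (names,
#'   if any, become a \code{label} column).
#' @param path file path.
#' @return Invisibly, the data frame written.
#' @export
write_tables_tsv <- function(tables, path) {
  if (inherits(tables, "contingency_table")) tables <- list(tables)
  df <- data.frame(
    exposed_cases = vapply(tables, `[[`, integer(1), "a"),
    unexposed_cases = vapply(tables, `[[`, integer(1), "b"),
    exposed_controls = vapply(tables, `[[`, integer(1), "c"),
    unexposed_controls = vapply(tables, `[[`, integer(1), "d"))
  if (!is.null(names(tables)) && any(nzchar(names(tables))))
    df <- cbind(label = names(tables), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
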