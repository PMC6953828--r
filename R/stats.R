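#' Reconstruct a 2x2 agreement table from its marginals
#'
#' Given the total, each rater's positive count and the both-positive count,
#' the four cells are forced by arithmetic: `a = both`, `b = r1 - both`,
#' `c = r2 - both`, `d = n - a - b - c`.
#'
#' @param n total number of rated items (>= 1)
#' @param r1_pos items rated positive by rater 1
#' @param r2_pos items rated positive by rater 2
#' @param both_pos items rated positive by both
#' @return object of class `two_by_two`: integers `a`, `b`, `c`, `d`, `n`
#' @export
table_from_marginals <- function(n, r1_pos, r2_pos, both_pos) {
  if (both_pos > min(r1_pos, r2_pos))
    stop("infeasible marginals: both_pos exceeds a rater's positive count")
  if (both_pos < 0 || r1_pos < 0 || r2_pos < 0)
    stop("infeasible marginals: negative count")
  if (r1_pos + r2_pos - both_pos > n)
    stop("infeasible marginals: union of positives exceeds n")
  two_by_two(both_pos, r1_pos - both_pos, r2_pos - both_pos,
             n - r1_pos - r2_pos + both_pos)
}

#' 2x2 agreement table
#'
#' @param a both-positive count
#' @param b rater1-positive / rater2-negative
#' @param c rater1-negative / rater2-positive
#' @param d both-negative
#' @return object of class `two_by_two`
#' @export
two_by_two <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  n <- sum(v)
  if (n < 1) stop("table must contain at least one observation")
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), n = as.integer(n)), class = "two_by_two")
}

#' Cohen's kappa with large-sample test under independence
#'
#' Chance-corrected agreement for two raters on a binary label. The standard
#' error is the large-sample SE of kappa under the independence null
#' (Fleiss), `z = kappa / se0`, with a two-sided normal p-value -- the
#' convention that reproduces textbook SPSS output for 2x2 tables.
#'
#' @param table a `two_by_two`
#' @return object of class `kappa_result`: `kappa`, `p_observed`,
#'   `p_expected`, `se0`, `z`, `p_value`, `band` (interpretation label)
#' @export
cohen_kappa <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  n <- table$n
  a <- table$a / n; b <- table$b / n; c <- table$c / n; d <- table$d / n
  p1r <- a + b; p2r <- c + d   # rater 1 margins (pos, neg)
  p1c <- a + c; p2c <- b + d   # rater 2 margins
  po <- a + d
  pe <- p1r * p1c + p2r * p2c
  if (1 - pe == 0) stop("degenerate marginals: expected agreement is 1")
  kap <- (po - pe) / (1 - pe)
  sum_term <- p1r * p1c * (p1r + p1c) + p2r * p2c * (p2r + p2c)
  se0 <- sqrt((pe + pe^2 - sum_term) / n) / (1 - pe)
  z <- kap / se0
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(kappa = kap, p_observed = po, p_expected = pe,
                 se0 = se0, z = z, p_value = p,
                 band = interpret_kappa(kap)), class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s), z = %.2f, p = %.3f\n",
              x$kappa, x$band, x$z, x$p_value))
  invisible(x)
}

#' Interpretation band of a kappa value
#'
#' Bands: kappa < 0.2 no agreement; 0.2-0.4 minimal; 0.4-0.6 weak; 0.6-0.8
#' strong; 0.8-0.9 very strong; 0.9-1.0 almost perfect (lower bound
#' inclusive). Negative values map to "no agreement".
#'
#' @param kappa value in `[-1, 1]`
#' @return character band label
#' @export
interpret_kappa <- function(kappa) {
  if (is.na(kappa) || kappa < -1 || kappa > 1) stop("kappa must be in [-1, 1]")
  if (kappa < 0.2) "no agreement"
  else if (kappa < 0.4) "minimal agreement"
  else if (kappa < 0.6) "weak agreement"
  else if (kappa < 0.8) "strong agreement"
  else if (kappa < 0.9) "very strong agreement"
  else "almost perfect agreement"
}

#' Diagnostic accuracy metrics from a 2x2 table (rater 2 = truth)
#'
#' Sensitivity `a/(a+c)`, specificity `d/(b+d)`, PPV `a/(a+b)`,
#' NPV `d/(c+d)`. Zero denominators yield NA with the metric listed in
#' `undefined` rather than a silent 0.
#'
#' @param table a `two_by_two` with rater 1 = classifier, rater 2 = reference
#' @return object of class `diagnostic_metrics`: `sensitivity`,
#'   `specificity`, `ppv`, `npv` (proportions), `undefined` (character)
#' @export
diagnostic_metrics <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(sensitivity = safe(table$a, table$a + table$c),
              specificity = safe(table$d, table$b + table$d),
              ppv = safe(table$a, table$a + table$b),
              npv = safe(table$d, table$c + table$d))
  out$undefined <- names(out)[vapply(out, is.na, logical(1))]
  structure(out, class = "diagnostic_metrics")
}

#' Integer percentage, rounding half away from zero
#'
#' The rounding convention of clinical tables (22/53 -> 42%).
#'
#' @param count numerator (0 <= count <= total)
#' @param total denominator (>= 1)
#' @return integer percent
#' @export
percent_of <- function(count, total) {
  if (total < 1) stop("total must be at least 1")
  if (count < 0 || count > total) stop("count must be in [0, total]")
  as.integer(floor(100 * count / total + 0.5))
}
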