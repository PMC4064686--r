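#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided D = sup |ECDF_x - ECDF_y| with the asymptotic p-value, as used to
#' compare cumulative apical-area and cycle-length distributions.
#'
#' @param x,y numeric samples (each of size >= 2)
#' @return list (test, statistic, p_value)
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per sample")
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(test = "Kolmogorov-Smirnov two-sample", statistic = unname(res$statistic),
       p_value = res$p.value)
}

#' G test of independence on a 2x2 (or r x c) contingency table
#'
#' G = 2 * sum O * ln(O/E), with expectations from the row/column margins,
#' referred to the chi-square distribution with (r-1)(c-1) degrees of freedom.
#' Zero cells contribute 0 to the sum; zero margins are rejected.
#'
#' @param table integer matrix of counts
#' @return list (test, statistic, df, p_value)
#' @export
g_test <- function(table) {
  stopifnot(is.matrix(table), all(table >= 0), sum(table) > 0)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  terms <- ifelse(table > 0, table * log(table / E), 0)
  G <- 2 * sum(terms)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(test = "G test of independence", statistic = G, df = df,
       p_value = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Two-sample t test (Student pooled-variance or Welch)
#'
#' @param x,y numeric samples (each of size >= 2)
#' @param mode "student" (pooled variance, the classical two-tailed Student
#'   test) or "welch"
#' @return list (test, statistic, df, p_value). When both samples have zero
#'   variance: equal means give statistic 0 / p 1, unequal means give an
#'   infinite statistic / p 0 (the degenerate limit).
#' @export
t_test_two_sample <- function(x, y, mode = c("student", "welch")) {
  mode <- match.arg(mode)
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per sample")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(test = "Student t (degenerate)", statistic = 0,
                  df = length(x) + length(y) - 2, p_value = 1))
    return(list(test = "Student t (degenerate)", statistic = Inf,
                df = length(x) + length(y) - 2, p_value = 0))
  }
  res <- stats::t.test(x, y, var.equal = (mode == "student"))
  list(test = if (mode == "student") "Student two-sample t" else "Welch t",
       statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}
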