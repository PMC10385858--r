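#' Pearson correlation with its Student t statistic
#'
#' Product-moment correlation of two vectors with
#' \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}}, df = n - 2, and a two-sided
#' p-value. Degenerate perfect correlation (|r| = 1, as arises on analytic
#' fixtures) is reported with the sentinels t = +/-Inf, p = 0 rather than an
#' error. Incomplete pairs are dropped.
#'
#' @param x,y Numeric vectors of equal length; at least 4 complete pairs,
#'   neither constant.
#' @return An object of class \code{"cor_test_result"}: list with \code{r},
#'   \code{n}, \code{t}, \code{df} (= n - 2), \code{p}.
#' @examples
#' # the classic printed pair: r = 0.61 over 59 codons gives t = 5.81
#' r <- 0.61; n <- 59
#' r * sqrt(n - 2) / sqrt(1 - r^2)
#' @export
pearson_with_t <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  if (abs(r) >= 1 - 1e-12) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(r = r, n = n, t = t, df = df, p = p),
            class = "cor_test_result")
}

#' @export
print.cor_test_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), t = %.3f on %d df, p = %.3g\n",
              x$r, x$n, x$t, x$df, x$p))
  invisible(x)
}

#' Hotelling's test for two dependent correlations sharing a variable
#'
#' Tests whether the correlation of variable 1 with variable 2 differs from
#' the correlation of variable 1 with variable 3, given the correlation
#' between 2 and 3 (all measured on the same n observations) - e.g. whether
#' a virus's codon usage correlates more strongly with one host cell type
#' than with another. The 1940 Hotelling statistic is
#' \deqn{t = (r_{12} - r_{13}) \sqrt{(n-3)(1+r_{23})} /
#'   \sqrt{2 (1 - r_{12}^2 - r_{13}^2 - r_{23}^2 + 2 r_{12} r_{13} r_{23})},}
#' with df = n - 3 and a two-sided p-value. Williams' modification is
#' available via \code{method = "williams"}. The statistic is zero when
#' r12 = r13 and exactly antisymmetric under swapping r12 and r13.
#'
#' @param r12,r13,r23 Correlations in (-1, 1); the implied 3x3 correlation
#'   matrix must be positive definite.
#' @param n Number of observations, at least 4.
#' @param method \code{"hotelling"} (1940, default) or \code{"williams"}.
#' @return An object of class \code{"hotelling_result"}: list with
#'   \code{r12}, \code{r13}, \code{r23}, \code{n}, \code{t}, \code{df}
#'   (= n - 3), \code{p}, \code{method}.
#' @references Hotelling, H. (1940) The selection of variates for use in
#'   prediction. Ann. Math. Statist. 11, 271-283.
#' @export
hotelling_dependent_t <- function(r12, r13, r23, n,
                                  method = c("hotelling", "williams")) {
  method <- match.arg(method)
  n <- as.integer(n)
  if (n <= 3L) stop("need n >= 4", call. = FALSE)
  if (any(abs(c(r12, r13, r23)) >= 1)) {
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR <= 0) {
    stop("correlation triple is not positive definite", call. = FALSE)
  }
  df <- n - 3L
  if (method == "hotelling") {
    t <- (r12 - r13) * sqrt(df * (1 + r23)) / sqrt(2 * detR)
  } else {
    rbar <- (r12 + r13) / 2
    t <- (r12 - r13) *
      sqrt((n - 1) * (1 + r23) /
             (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3))
  }
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(r12 = r12, r13 = r13, r23 = r23, n = n, t = t, df = df,
                 p = p, method = method),
            class = "hotelling_result")
}

#' @export
print.hotelling_result <- function(x, ...) {
  cat(sprintf(
    "%s test of dependent correlations: r12 = %.3f vs r13 = %.3f (r23 = %.3f, n = %d)\n",
    if (x$method == "hotelling") "Hotelling" else "Williams",
    x$r12, x$r13, x$r23, x$n))
  cat(sprintf("  t = %.3f on %d df, p = %.3g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Pearson chi-square on the table \code{rbind(c(a, b), c(c, d))}, by default
#' without Yates continuity correction (with counts in the thousands the
#' correction is negligible; a flag enables it). df = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts; all margins must be
#'   positive.
#' @param correct Apply Yates continuity correction (default \code{FALSE}).
#' @return An object of class \code{"chisq_result"}: list with \code{chi2},
#'   \code{df}, \code{p}, \code{table}, \code{expected}.
#' @export
chisq_2x2 <- function(a, b, c, d, correct = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || anyNA(cells)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  tab <- matrix(as.numeric(cells), nrow = 2L, byrow = TRUE,
                dimnames = list(group = c("A", "B"),
                                outcome = c("yes", "no")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in 2x2 table", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(list(chi2 = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value, table = tab, expected = res$expected,
                 correct = correct),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Chi-square (2x2%s): chi2 = %.3f on %d df, p = %.3g\n",
              if (x$correct) ", Yates-corrected" else "", x$chi2, x$df, x$p))
  invisible(x)
}

#' Two-sample Student t test for group means
#'
#' Pooled-variance Student t by default (the convention for comparing group
#' mean A+T3 contents); Welch via \code{pooled = FALSE}.
#'
#' @param group_a,group_b Numeric vectors, each of length at least 2.
#' @param pooled Use the pooled-variance statistic (default \code{TRUE}).
#' @return An object of class \code{"two_sample_t"}: list with \code{t},
#'   \code{df}, \code{p}, \code{mean_a}, \code{mean_b}, \code{pooled}.
#' @export
two_sample_t <- function(group_a, group_b, pooled = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(group_a) + stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(structure(list(t = 0, df = length(group_a) + length(group_b) - 2L,
                            p = 1, mean_a = mean(group_a),
                            mean_b = mean(group_b), pooled = pooled),
                       class = "two_sample_t"))
    }
    stop("zero pooled variance", call. = FALSE)
  }
  res <- stats::t.test(group_a, group_b, var.equal = pooled)
  structure(list(t = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value, mean_a = mean(group_a),
                 mean_b = mean(group_b), pooled = pooled),
            class = "two_sample_t")
}

#' @export
print.two_sample_t <- function(x, ...) {
  cat(sprintf(
    "%s two-sample t: mean %.3f vs %.3f, t = %.3f on %s df, p = %.3g\n",
    if (x$pooled) "Pooled" else "Welch", x$mean_a, x$mean_b, x$t,
    format(x$df, digits = 4), x$p))
  invisible(x)
}

#' Chi-square comparison of one amino acid's content between two groups
#'
#' Builds the 2x2 table (count of one amino acid vs all other degenerate-
#' family amino acids) x (group A vs group B) and applies
#' \code{\link{chisq_2x2}}. By default each group is pooled by summing the
#' raw codon counts over its member taxa ("overall content"); with
#' \code{pooling = "mean"} the group's mean per-taxon percentages are scaled
#' back to the pooled total instead (a mean-of-taxa reading of group
#' content).
#'
#' @param group_a,group_b Lists of \code{"codon_counts"} objects (or single
#'   objects).
#' @param amino_acid One-letter code of a degenerate-family amino acid.
#' @param pooling \code{"sum"} (default) or \code{"mean"}.
#' @param correct Passed to \code{\link{chisq_2x2}}.
#' @return The \code{"chisq_result"}, with the amino acid recorded in
#'   \code{amino_acid}.
#' @export
aa_content_chisq <- function(group_a, group_b, amino_acid,
                             pooling = c("sum", "mean"), correct = FALSE) {
  pooling <- match.arg(pooling)
  code <- genetic_code()
  if (!amino_acid %in% code$degenerate_aa) {
    stop("'", amino_acid, "' is not one of the 18 degenerate-family ",
         "amino acids", call. = FALSE)
  }
  as_list <- function(g) if (inherits(g, "codon_counts")) list(g) else g
  cells <- function(g) {
    g <- as_list(g)
    profs <- lapply(g, amino_acid_composition)
    total <- sum(vapply(profs, function(p) p$total_aa, numeric(1)))
    n_aa <- if (pooling == "sum") {
      sum(vapply(profs, function(p) p$counts[[amino_acid]], numeric(1)))
    } else {
      round(mean(vapply(profs, function(p) p$pct[[amino_acid]], numeric(1))) /
              100 * total)
    }
    c(n_aa, total - n_aa)
  }
  ca <- cells(group_a); cb <- cells(group_b)
  out <- chisq_2x2(ca[1L], ca[2L], cb[1L], cb[2L], correct = correct)
  out$amino_acid <- amino_acid
  out
}
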