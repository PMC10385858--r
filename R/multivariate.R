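#' Principal component analysis of a usage matrix
#'
#' Covariance (or correlation) PCA of a taxa-by-codons usage matrix, or of
#' its transpose when codons are to be treated as the observations
#' (orientation is an explicit argument, never inferred from the shape).
#' Default preprocessing is column-centred and unscaled: RSCU values and
#' percentages already share a common scale, so covariance PCA is the
#' documented default; both flags are exposed because variance fractions are
#' preprocessing-sensitive.
#'
#' @param x Numeric matrix (observations in rows). \code{NA} entries are not
#'   accepted here: apply the pairwise-exclusion policy (or drop columns)
#'   first.
#' @param center,scale. Passed to \code{stats::prcomp}.
#' @param transpose If \code{TRUE}, analyse \code{t(x)} (e.g. codons as
#'   observations across taxa).
#' @return An object of class \code{"usage_pca"}: list with \code{scores}
#'   (observations x components), \code{loadings}, \code{sdev},
#'   \code{variance_fraction} (non-increasing, summing to 1),
#'   \code{center}, \code{scale}, \code{orientation_anchor} (per-component
#'   sign-rule descriptions, filled by \code{\link{orient_component}}).
#' @export
usage_pca <- function(x, center = TRUE, scale. = FALSE, transpose = FALSE) {
  x <- as.matrix(x)
  if (transpose) x <- t(x)
  if (anyNA(x)) {
    stop("usage matrix contains NA; apply pairwise exclusion or drop ",
         "undefined columns before PCA", call. = FALSE)
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  if (nrow(unique(x)) < 2L) {
    stop("degenerate matrix: fewer than 2 distinct rows", call. = FALSE)
  }
  if (scale. && any(apply(x, 2L, stats::sd) == 0)) {
    stop("constant column: cannot scale", call. = FALSE)
  }
  p <- stats::prcomp(x, center = center, scale. = scale.)
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(scores = p$x, loadings = p$rotation, sdev = p$sdev,
         variance_fraction = vf, center = p$center, scale = p$scale,
         orientation_anchor = stats::setNames(
           rep(NA_character_, ncol(p$x)), colnames(p$x))),
    class = "usage_pca"
  )
}

#' @export
print.usage_pca <- function(x, ...) {
  k <- min(5L, length(x$variance_fraction))
  cat("PCA of usage matrix:", nrow(x$scores), "observations,",
      nrow(x$loadings), "features\n")
  cat("  variance fractions:",
      paste0(colnames(x$scores)[seq_len(k)], "=",
             sprintf("%.1f%%", 100 * x$variance_fraction[seq_len(k)]),
             collapse = " "), "\n")
  anch <- x$orientation_anchor[!is.na(x$orientation_anchor)]
  if (length(anch)) {
    cat("  sign anchors:",
        paste(names(anch), anch, sep = " ~ ", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Fix the sign of a principal component against an external covariate
#'
#' The sign of a principal component is arbitrary; this anchors it
#' deterministically: the component's scores and loadings are negated if and
#' only if their correlation with the anchor covariate is negative, so that
#' the component increases with the anchor (e.g. PC1 increasing with
#' third-position A+T content). Idempotent.
#'
#' @param result A \code{"usage_pca"} object.
#' @param component Component index (default 1).
#' @param anchor Numeric covariate, one value per observation, non-constant.
#' @param label Description of the anchor stored in the result.
#' @return The \code{"usage_pca"} object, possibly with the component
#'   negated.
#' @export
orient_component <- function(result, component = 1L, anchor,
                             label = deparse(substitute(anchor))) {
  stopifnot(inherits(result, "usage_pca"))
  component <- as.integer(component)
  if (length(anchor) != nrow(result$scores)) {
    stop("anchor must have one value per observation", call. = FALSE)
  }
  if (stats::sd(anchor) == 0) {
    stop("zero-variance anchor cannot fix a sign", call. = FALSE)
  }
  r <- stats::cor(result$scores[, component], anchor)
  if (r < 0) {
    result$scores[, component] <- -result$scores[, component]
    result$loadings[, component] <- -result$loadings[, component]
  }
  result$orientation_anchor[component] <- label
  result
}

#' Correlation screen of features against a component score
#'
#' Pearson correlation of each feature (column) with a per-observation score
#' vector, with the associated Student statistic
#' \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}} and two-sided p-value. Features
#' whose |t| strictly exceeds the cutoff are partitioned by the sign of r
#' into a positive and a negative set. Flagged-undefined entries (NA) are
#' excluded pairwise, so n can differ between features. The default cutoff
#' 4.84 is taken as a given constant (a conventional p = 1e-5 threshold for
#' panels of this size); it is not re-derived from a p-value.
#'
#' @param x Numeric matrix, observations in rows; may contain NA.
#' @param scores Numeric vector aligned with the rows of \code{x}.
#' @param t_cutoff Positive cutoff on |t| (default 4.84).
#' @return An object of class \code{"codon_screen"}: list with \code{table}
#'   (data.frame: feature, n, r, t, p, set in {"+", "-", "ns"}),
#'   \code{positive_set}, \code{negative_set}, \code{t_cutoff}.
#' @export
screen_features <- function(x, scores, t_cutoff = 4.84) {
  x <- as.matrix(x)
  if (length(scores) != nrow(x)) {
    stop("'scores' must align with the rows of 'x'", call. = FALSE)
  }
  feats <- colnames(x)
  if (is.null(feats)) feats <- paste0("V", seq_len(ncol(x)))
  rows <- lapply(seq_len(ncol(x)), function(j) {
    ok <- stats::complete.cases(x[, j], scores)
    n <- sum(ok)
    if (n < 4L) {
      stop("feature '", feats[j], "': fewer than 4 complete pairs",
           call. = FALSE)
    }
    ct <- pearson_with_t(x[ok, j], scores[ok])
    data.frame(feature = feats[j], n = n, r = ct$r, t = ct$t, p = ct$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$set <- ifelse(abs(tab$t) > t_cutoff, ifelse(tab$r > 0, "+", "-"), "ns")
  structure(
    list(table = tab,
         positive_set = tab$feature[tab$set == "+"],
         negative_set = tab$feature[tab$set == "-"],
         t_cutoff = t_cutoff),
    class = "codon_screen"
  )
}

#' @export
print.codon_screen <- function(x, ...) {
  cat("Correlation screen at |t| >", x$t_cutoff, "\n")
  cat("  positive set (", length(x$positive_set), "): ",
      paste(x$positive_set, collapse = " "), "\n", sep = "")
  cat("  negative set (", length(x$negative_set), "): ",
      paste(x$negative_set, collapse = " "), "\n", sep = "")
  invisible(x)
}
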