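#' Relative synonymous codon usage (RSCU)
#'
#' For each synonymous codon c of an amino acid a with degeneracy D and family
#' count N_a > 0,
#' \deqn{RSCU(c) = (N_c / N_a) \times D,}
#' where N_c is the absolute count of the codon and N_a the count of the
#' amino acid over all its synonyms. Under equal use of all synonyms every
#' codon has RSCU 1; exclusive use of one synonym gives RSCU D for it and 0
#' for the rest. Families with N_a = 0 are flagged in
#' \code{undefined_families} and their codons carry the sentinel value 0;
#' downstream correlation code excludes such entries pairwise rather than
#' treating the sentinel as an observed zero.
#'
#' @param counts A \code{"codon_counts"} object.
#' @return An object of class \code{"rscu_profile"}: list with \code{values}
#'   (named numeric over the 59 synonymous codons, alphabetical),
#'   \code{undefined_families}, \code{family_totals} (N_a per degenerate
#'   amino acid), \code{source_id}.
#' @examples
#' arg <- codon_counts(c(AGA = 30, AGG = 15, CGT = 5, CGC = 5, CGA = 3, CGG = 2))
#' rscu(arg)$values[["AGA"]]  # (30/60) * 6 = 3
#' @export
rscu <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  code <- genetic_code()
  values <- stats::setNames(numeric(59L), code$synonymous_codons)
  totals <- stats::setNames(numeric(length(code$degenerate_aa)),
                            code$degenerate_aa)
  undefined <- character(0)
  for (a in code$degenerate_aa) {
    syn <- code$synonym_families[[a]]
    n_a <- sum(counts$counts[syn])
    totals[a] <- n_a
    if (n_a == 0) {
      undefined <- c(undefined, a)
      values[syn] <- 0
    } else {
      values[syn] <- counts$counts[syn] / n_a * length(syn)
    }
  }
  structure(
    list(values = values, undefined_families = undefined,
         family_totals = totals, source_id = counts$source_id),
    class = "rscu_profile"
  )
}

#' @export
print.rscu_profile <- function(x, ...) {
  cat("RSCU profile",
      if (!is.na(x$source_id)) paste0("[", x$source_id, "]"), "\n")
  cat("  total synonymous occurrences:", sum(x$family_totals), "\n")
  if (length(x$undefined_families)) {
    cat("  undefined families (no observations):",
        paste(x$undefined_families, collapse = ", "), "\n")
  }
  print(round(x$values, 3))
  invisible(x)
}

#' Assemble an RSCU matrix from per-taxon profiles
#'
#' @param profiles A (named) list of \code{"rscu_profile"} objects.
#' @param undefined How to represent codons of unobserved families:
#'   \code{"NA"} (default; enables pairwise exclusion downstream) or
#'   \code{"zero"} (the stored sentinel).
#' @return Numeric matrix, taxa in rows, the 59 codons (alphabetical) in
#'   columns.
#' @export
rscu_matrix <- function(profiles, undefined = c("NA", "zero")) {
  undefined <- match.arg(undefined)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "rscu_profile")))
  code <- genetic_code()
  m <- t(vapply(profiles, function(p) {
    v <- p$values
    if (undefined == "NA" && length(p$undefined_families)) {
      bad <- unlist(code$synonym_families[p$undefined_families],
                    use.names = FALSE)
      v[bad] <- NA_real_
    }
    v
  }, numeric(59L)))
  if (is.null(rownames(m))) {
    rownames(m) <- vapply(profiles, function(p) p$source_id, character(1))
  }
  m
}

#' Wright's effective number of codons (Nc)
#'
#' Estimates the effective number of codons from codon counts. Per amino-acid
#' family a with n_a >= 2 observations and synonym frequencies p_i, the
#' bias-corrected homozygosity is
#' \deqn{\hat F_a = (n_a \sum_i \hat p_i^2 - 1) / (n_a - 1).}
#' Families with n_a < 2 or \eqn{\hat F_a = 0} are excluded. The class means
#' F2, F3, F4, F6 average \eqn{\hat F} over families of equal degeneracy
#' (six-fold families Leu, Ser, Arg are kept whole, not split 4+2, preserving
#' the 2 + 9 + 1 + 5 + 3 = 20 class structure), and
#' \deqn{Nc = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6.}
#' If the single three-fold family (Ile) is unobserved, F3 is imputed as
#' (F2 + F4)/2. The finite-sample estimator can slightly exceed 61 (uniform
#' usage of all 59 synonyms gives a raw value of about 61.04), so the
#' returned \code{nc} is capped into the statistic's theoretical range
#' [20, 61]; the uncapped value is kept in \code{nc_raw}. Nc is 20 when a
#' single codon is used per amino acid (maximal bias) and 61 when all
#' synonyms are used equally (no bias).
#'
#' @param counts A \code{"codon_counts"} object. Every represented degeneracy
#'   class except the three-fold one must have at least one family with
#'   n >= 2.
#' @return An object of class \code{"enc_value"}: list with \code{nc}
#'   (capped), \code{nc_raw}, \code{f_bars} (named over classes "2", "3",
#'   "4", "6"), \code{families_used}, \code{imputed_f3} (logical).
#' @references Wright, F. (1990) The 'effective number of codons' used in a
#'   gene. Gene 87, 23-29.
#' @export
effective_number_of_codons <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  code <- genetic_code()
  f_hat <- stats::setNames(rep(NA_real_, length(code$degenerate_aa)),
                           code$degenerate_aa)
  for (a in code$degenerate_aa) {
    syn <- code$synonym_families[[a]]
    n_a <- sum(counts$counts[syn])
    if (n_a >= 2) {
      p <- counts$counts[syn] / n_a
      f <- (n_a * sum(p^2) - 1) / (n_a - 1)
      if (f > 0) f_hat[a] <- f
    }
  }
  deg <- code$degeneracy[code$degenerate_aa]
  classes <- c("2", "3", "4", "6")
  f_bars <- stats::setNames(vapply(classes, function(k) {
    mean(f_hat[deg == as.integer(k)], na.rm = TRUE)
  }, numeric(1)), classes)
  imputed <- FALSE
  if (is.nan(f_bars[["3"]])) {
    if (!is.nan(f_bars[["2"]]) && !is.nan(f_bars[["4"]])) {
      f_bars[["3"]] <- (f_bars[["2"]] + f_bars[["4"]]) / 2
      imputed <- TRUE
    }
  }
  if (any(is.nan(f_bars))) {
    stop("Nc undefined: no computable homozygosity for degeneracy class(es) ",
         paste(classes[is.nan(f_bars)], collapse = ", "), call. = FALSE)
  }
  nc_raw <- 2 + 9 / f_bars[["2"]] + 1 / f_bars[["3"]] +
    5 / f_bars[["4"]] + 3 / f_bars[["6"]]
  structure(
    list(nc = min(max(nc_raw, 20), 61), nc_raw = nc_raw, f_bars = f_bars,
         families_used = sum(!is.na(f_hat)), imputed_f3 = imputed,
         source_id = counts$source_id),
    class = "enc_value"
  )
}

#' @export
print.enc_value <- function(x, ...) {
  cat("Effective number of codons (Nc):", format(x$nc, digits = 4),
      if (x$nc != x$nc_raw) paste0("(raw ", format(x$nc_raw, digits = 4), ", capped)"),
      "\n")
  cat("  class mean homozygosities:",
      paste(names(x$f_bars), round(x$f_bars, 4), sep = "=", collapse = " "),
      "\n  families used:", x$families_used,
      if (x$imputed_f3) "(F3 imputed)", "\n")
  invisible(x)
}

#' Amino acid composition over the 18 degenerate families
#'
#' Percent content of the 18 amino acids encoded by the 59 synonymous codons.
#' Met and Trp occurrences are excluded from numerator and denominator (the
#' 18-amino-acid convention), so an 18-dimensional profile is never silently
#' comparable with a 20-dimensional one.
#'
#' @param counts A \code{"codon_counts"} object with at least one synonymous
#'   codon observed.
#' @return An object of class \code{"aa_profile"}: list with \code{pct}
#'   (named over the 18 amino acids, alphabetical, summing to 100),
#'   \code{counts} (raw N_a, for contingency tests), \code{total_aa}.
#' @export
amino_acid_composition <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  code <- genetic_code()
  n_a <- vapply(code$degenerate_aa, function(a) {
    sum(counts$counts[code$synonym_families[[a]]])
  }, numeric(1))
  total <- sum(n_a)
  if (total == 0) {
    stop("amino acid composition undefined: no synonymous codon observed ",
         "(Met/Trp are excluded)", call. = FALSE)
  }
  structure(
    list(pct = 100 * n_a / total, counts = n_a, total_aa = total,
         source_id = counts$source_id),
    class = "aa_profile"
  )
}

#' @export
print.aa_profile <- function(x, ...) {
  cat("Amino acid composition (18 degenerate families,",
      x$total_aa, "residues)\n")
  print(round(x$pct, 2))
  invisible(x)
}

#' Assemble an amino-acid composition matrix from per-taxon profiles
#'
#' @param profiles A (named) list of \code{"aa_profile"} objects.
#' @return Numeric matrix, taxa in rows, the 18 amino acids in columns.
#' @export
aa_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "aa_profile")))
  m <- t(vapply(profiles, function(p) p$pct, numeric(18L)))
  if (is.null(rownames(m))) {
    rownames(m) <- vapply(profiles, function(p) p$source_id, character(1))
  }
  m
}
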