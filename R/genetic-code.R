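#' The standard genetic code and its synonym structure
#'
#' Returns the bookkeeping tables used throughout the package: the standard
#' genetic code (translation table 1), its synonym families, and the per-family
#' degeneracy. Only the standard code is supported: the analyses this package
#' implements concern primate retro-/lentiviral coding regions, which use it.
#'
#' The "59 synonymous codons" are the 61 sense codons minus ATG (Met) and TGG
#' (Trp), the two codons whose amino acids admit no synonymous alternative.
#' Exactly 18 amino acids have degeneracy D >= 2, and their family sizes sum
#' to 59.
#'
#' @return A list with components:
#'   \item{codon_to_aa}{named character: all 64 codons to one-letter amino
#'     acid codes, stop codons mapped to \code{"*"}.}
#'   \item{sense_codons}{the 61 sense codons, alphabetical.}
#'   \item{stop_codons}{TAA, TAG, TGA.}
#'   \item{synonymous_codons}{the 59 synonymous codons, alphabetical.}
#'   \item{synonym_families}{named list: amino acid to its codons
#'     (alphabetical within family), all 20 amino acids.}
#'   \item{degeneracy}{named integer: amino acid to family size D.}
#'   \item{degenerate_aa}{the 18 amino acids with D >= 2, alphabetical.}
#' @examples
#' code <- genetic_code()
#' length(code$synonymous_codons)  # 59
#' code$degeneracy[["R"]]          # 6 (Arg)
#' @export
genetic_code <- function() {
  if (!is.null(.codontrend_cache$code)) {
    return(.codontrend_cache$code)
  }
  aa <- Biostrings::GENETIC_CODE
  codons <- sort(names(aa))
  aa <- aa[codons]
  stop_codons <- codons[aa == "*"]
  sense <- codons[aa != "*"]
  families <- split(sense, aa[sense])
  degeneracy <- vapply(families, length, integer(1))
  degenerate_aa <- names(degeneracy)[degeneracy >= 2L]
  synonymous <- sort(unlist(families[degenerate_aa], use.names = FALSE))
  code <- list(
    codon_to_aa = aa,
    sense_codons = sense,
    stop_codons = stop_codons,
    synonymous_codons = synonymous,
    synonym_families = families,
    degeneracy = degeneracy,
    degenerate_aa = degenerate_aa
  )
  .codontrend_cache$code <- code
  code
}

.codontrend_cache <- new.env(parent = emptyenv())

#' Codons excluded from first-position composition analysis
#'
#' A substitution at the first codon position is usually non-synonymous, but
#' not always: the six-fold families of Arg and Leu each contain codon pairs
#' that differ only at position one (AGA/CGA, AGG/CGG for Arg; TTA/CTA,
#' TTG/CTG for Leu). First-position composition is therefore computed after
#' excluding these eight codons, so that the retained positions are strictly
#' non-synonymous.
#'
#' @return Character vector of the eight excluded codons, alphabetical.
#' @export
first_position_exclusions <- function() {
  c("AGA", "AGG", "CGA", "CGG", "CTA", "CTG", "TTA", "TTG")
}

#' Count codons of an in-frame coding sequence
#'
#' Reads a coding sequence triplet by triplet and tallies the 61 sense codons.
#' Triplets containing any non-ACGT symbol (ambiguity codes) are skipped whole
#' and counted in \code{n_skipped_ambiguous}; stop codons are tallied
#' separately in \code{n_stop_codons} and never enter the sense-codon counts.
#'
#' @param sequence A single character string (or anything coercible by
#'   \code{as.character}, e.g. a \code{DNAString}). Case-insensitive; RNA
#'   \code{U} is normalised to \code{T}. Length must be divisible by 3.
#' @param policy Stop-handling policy. Under \code{"strict"} (default) a stop
#'   triplet anywhere but the final position is an error (an internal stop in
#'   a coding region indicates a frame problem); a single terminal stop is
#'   accepted and tallied. Under \code{"lenient"} all stop triplets are
#'   tallied without error.
#' @param id Optional source label stored in the result.
#' @return An object of class \code{"codon_counts"}: a list with
#'   \code{counts} (named integer over the 61 sense codons),
#'   \code{n_skipped_ambiguous}, \code{n_stop_codons}, \code{source_id}.
#' @examples
#' count_codons("ATGGCTGCA")
#' count_codons("atggcttaa")$n_stop_codons  # 1 terminal stop
#' @export
count_codons <- function(sequence, policy = c("strict", "lenient"), id = NULL) {
  policy <- match.arg(policy)
  code <- genetic_code()
  s <- toupper(as.character(sequence))
  if (length(s) != 1L) {
    stop("'sequence' must be a single string", call. = FALSE)
  }
  s <- chartr("U", "T", s)
  n <- nchar(s)
  if (n %% 3L != 0L) {
    stop("frame error: sequence length ", n, " is not divisible by 3",
         call. = FALSE)
  }
  counts <- stats::setNames(integer(61L), code$sense_codons)
  n_amb <- 0L
  n_stop <- 0L
  if (n > 0L) {
    n_trip <- n %/% 3L
    trip <- substring(s, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
    clean <- !grepl("[^ACGT]", trip)
    n_amb <- sum(!clean)
    is_stop <- clean & trip %in% code$stop_codons
    n_stop <- sum(is_stop)
    if (policy == "strict" && any(is_stop & seq_len(n_trip) != n_trip)) {
      stop("internal stop codon at triplet ",
           paste(which(is_stop & seq_len(n_trip) != n_trip), collapse = ", "),
           if (!is.null(id)) paste0(" in '", id, "'"),
           call. = FALSE)
    }
    keep <- trip[clean & !is_stop]
    if (length(keep)) {
      tab <- table(keep)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
  }
  new_codon_counts(counts, n_amb, n_stop,
                   if (is.null(id)) NA_character_ else as.character(id))
}

new_codon_counts <- function(counts, n_skipped_ambiguous, n_stop_codons,
                             source_id = NA_character_) {
  structure(
    list(counts = counts,
         n_skipped_ambiguous = as.integer(n_skipped_ambiguous),
         n_stop_codons = as.integer(n_stop_codons),
         source_id = source_id),
    class = "codon_counts"
  )
}

#' Build codon counts directly from a named count vector
#'
#' Convenience constructor for analytic inputs (worked examples, host tables):
#' takes a named vector of sense-codon counts, fills the remaining codons with
#' zero.
#'
#' @param x Named non-negative integer vector; names must be sense codons.
#' @param id Optional source label.
#' @return A \code{"codon_counts"} object.
#' @export
codon_counts <- function(x, id = NULL) {
  code <- genetic_code()
  if (is.null(names(x)) || anyNA(names(x))) {
    stop("'x' must be a named vector of codon counts", call. = FALSE)
  }
  names(x) <- chartr("U", "T", toupper(names(x)))
  bad <- setdiff(names(x), code$sense_codons)
  if (length(bad)) {
    stop("not sense codons: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop("duplicated codon names", call. = FALSE)
  }
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  counts <- stats::setNames(integer(61L), code$sense_codons)
  counts[names(x)] <- as.integer(round(x))
  new_codon_counts(counts, 0L, 0L,
                   if (is.null(id)) NA_character_ else as.character(id))
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("Codon counts",
      if (!is.na(x$source_id)) paste0("[", x$source_id, "]"), "\n")
  cat("  sense codons:", sum(x$counts),
      "| stop codons:", x$n_stop_codons,
      "| ambiguous triplets skipped:", x$n_skipped_ambiguous, "\n")
  top <- sort(x$counts[x$counts > 0], decreasing = TRUE)
  if (length(top)) {
    show <- utils::head(top, 8L)
    cat("  most frequent:",
        paste(names(show), show, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
`+.codon_counts` <- function(e1, e2) {
  stopifnot(inherits(e1, "codon_counts"), inherits(e2, "codon_counts"))
  ids <- c(e1$source_id, e2$source_id)
  ids <- ids[!is.na(ids)]
  new_codon_counts(e1$counts + e2$counts,
                   e1$n_skipped_ambiguous + e2$n_skipped_ambiguous,
                   e1$n_stop_codons + e2$n_stop_codons,
                   if (length(ids)) paste(ids, collapse = "+") else NA_character_)
}

#' Pool codon counts over several sources
#'
#' @param x A list of \code{"codon_counts"} objects.
#' @param id Optional label for the pooled result.
#' @return A single \code{"codon_counts"} object with summed counts.
#' @export
pool_counts <- function(x, id = NULL) {
  stopifnot(length(x) >= 1L, all(vapply(x, inherits, TRUE, "codon_counts")))
  out <- Reduce(`+`, x)
  if (!is.null(id)) out$source_id <- as.character(id)
  out
}

#' Position-specific nucleotide composition of counted codons
#'
#' Computes the percent frequency of A, T, G, C (plus A+T and G+C) at one
#' codon position, occurrence-weighted over a stated inclusion set of codons:
#' each counted codon occurrence contributes its base at that position. The
#' inclusion rule makes the denominator explicit:
#' \describe{
#'   \item{\code{"third-synonymous"}}{the 59 synonymous codons; the standard
#'     choice for third-position (A+T3 / GC3) composition.}
#'   \item{\code{"first-nonsynonymous"}}{the 59 synonymous codons minus the
#'     eight Arg/Leu codons of \code{\link{first_position_exclusions}}, so
#'     that every retained first position is strictly non-synonymous.}
#'   \item{\code{"second-all-synonymous"}}{the 59 synonymous codons (every
#'     second-position substitution is non-synonymous, so no exclusion is
#'     needed).}
#'   \item{\code{"custom"}}{the codon set passed in \code{codons}.}
#' }
#'
#' @param counts A \code{"codon_counts"} object.
#' @param position Codon position, 1, 2 or 3.
#' @param rule Inclusion rule, see Details.
#' @param codons Codon set for \code{rule = "custom"}.
#' @return An object of class \code{"composition_profile"}: list with
#'   \code{position}, \code{pct} (named over A, T, G, C, A+T, G+C, summing to
#'   100), \code{included_codons}, \code{n_occurrences}.
#' @examples
#' x <- codon_counts(c(GCA = 10))
#' positional_composition(x, 3)$pct[["A+T"]]  # 100
#' @export
positional_composition <- function(counts, position,
                                   rule = c("third-synonymous",
                                            "first-nonsynonymous",
                                            "second-all-synonymous",
                                            "custom"),
                                   codons = NULL) {
  stopifnot(inherits(counts, "codon_counts"))
  position <- as.integer(position)
  if (!position %in% 1:3) stop("'position' must be 1, 2 or 3", call. = FALSE)
  if (missing(rule)) {
    rule <- switch(position, "first-nonsynonymous", "second-all-synonymous",
                   "third-synonymous")
  }
  rule <- match.arg(rule)
  code <- genetic_code()
  included <- switch(
    rule,
    "third-synonymous" = code$synonymous_codons,
    "second-all-synonymous" = code$synonymous_codons,
    "first-nonsynonymous" = setdiff(code$synonymous_codons,
                                    first_position_exclusions()),
    "custom" = {
      if (is.null(codons)) {
        stop("rule = \"custom\" needs a 'codons' set", call. = FALSE)
      }
      codons <- chartr("U", "T", toupper(codons))
      bad <- setdiff(codons, code$sense_codons)
      if (length(bad)) {
        stop("not sense codons: ", paste(bad, collapse = ", "), call. = FALSE)
      }
      unique(codons)
    }
  )
  n <- counts$counts[included]
  total <- sum(n)
  if (total == 0) {
    stop("composition undefined: no included codon observed under rule '",
         rule, "'", call. = FALSE)
  }
  base_at_pos <- substr(included, position, position)
  pct <- vapply(c("A", "T", "G", "C"),
                function(b) 100 * sum(n[base_at_pos == b]) / total,
                numeric(1))
  pct <- c(pct, "A+T" = unname(pct["A"] + pct["T"]),
           "G+C" = unname(pct["G"] + pct["C"]))
  structure(
    list(position = position, rule = rule, pct = pct,
         included_codons = included, n_occurrences = total),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("Nucleotide composition at codon position", x$position,
      paste0("(rule: ", x$rule, ", ", x$n_occurrences, " occurrences)"), "\n")
  print(round(x$pct, 2))
  invisible(x)
}
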