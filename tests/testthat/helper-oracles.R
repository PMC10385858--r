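# Independent oracles and fixture builders, derived directly from the
# Biostrings code table so they share nothing with the package internals
# beyond the genetic code itself.

oracle_families <- function() {
  aa <- Biostrings::GENETIC_CODE
  sense <- names(aa)[aa != "*"]
  fam <- split(sense, aa[sense])
  fam[vapply(fam, length, integer(1)) >= 2L]
}

# Wright's Nc evaluated family by family from first principles.
oracle_nc <- function(counts_vec) {
  fam <- oracle_families()
  f_by_class <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (syn in fam) {
    n <- sum(counts_vec[syn])
    if (n < 2) next
    p <- counts_vec[syn] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) next
    k <- as.character(length(syn))
    f_by_class[[k]] <- c(f_by_class[[k]], f)
  }
  fbar <- vapply(f_by_class, function(v) mean(v), numeric(1))
  if (is.nan(fbar[["3"]])) fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] + 3 / fbar[["6"]]
}

# Random plausible codon counts over all 61 sense codons.
random_counts_vec <- function(seed, lambda = 40) {
  set.seed(seed)
  aa <- Biostrings::GENETIC_CODE
  sense <- sort(names(aa)[aa != "*"])
  stats::setNames(stats::rpois(length(sense), lambda) + 1L, sense)
}

# Equal counts for every synonym within each family (uniform usage).
uniform_synonym_counts <- function(per_codon = 100L) {
  fam <- oracle_families()
  syn <- sort(unlist(fam, use.names = FALSE))
  codon_counts(stats::setNames(rep(per_codon, length(syn)), syn))
}

# Exactly one synonym used per family.
one_codon_per_family_counts <- function(per_family = 100L, pick = 1L) {
  fam <- oracle_families()
  chosen <- vapply(fam, function(s) s[[min(pick, length(s))]], character(1))
  codon_counts(stats::setNames(rep(per_family, length(chosen)), chosen))
}

# A pair of vectors of length n with an exactly prescribed Pearson r.
vectors_with_r <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- scale(stats::rnorm(n))[, 1L]
  e <- stats::rnorm(n)
  e <- scale(stats::residuals(stats::lm(e ~ x)))[, 1L]
  y <- r * x + sqrt(1 - r^2) * e
  list(x = x, y = y)
}

# Small gradient panel spec for pipeline tests (kept fast).
small_gradient_spec <- function(seed = 1, at3 = c(0.55, 0.62, 0.70),
                                n_taxa = 4L, codons = 1200L) {
  panel_spec(
    data.frame(label = paste0("g", seq_along(at3)), n_taxa = n_taxa,
               target_AT3 = at3, stringsAsFactors = FALSE),
    codons_per_taxon = codons, seed = seed)
}
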