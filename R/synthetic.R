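#' Per-codon sampling weights for a target third-position A+T content
#'
#' Inverse model for the gradient the panel generator emulates. Within every
#' amino-acid family the probability mass placed on A/T-ending synonyms is
#' set to the target (spread uniformly within the A/T-ending and the
#' G/C-ending synonyms respectively), so the expected occurrence-weighted
#' A+T3 of a sampled sequence equals the target exactly, whatever the amino
#' acid distribution. Across families, amino acid frequencies follow a base
#' distribution, optionally multiplied by per-amino-acid shift weights and
#' renormalised.
#'
#' @param target_AT3 Target third-position A+T fraction in [0, 1] (note:
#'   fraction, not percent), or \code{NULL} for uniform synonym usage within
#'   every family (the no-bias null, expected RSCU 1 for every codon).
#' @param aa_shift Optional named numeric: multiplicative weights on amino
#'   acid frequencies (e.g. \code{c(I = 2)} doubles the Ile share before
#'   renormalisation).
#' @param aa_base Base amino-acid distribution: \code{"uniform"} over the 18
#'   degenerate families, or \code{"lentivirus"}, an Ile/Ser-rich,
#'   Tyr/Leu-adjusted preset whose Ile/Ser/Tyr/Leu shares match typical
#'   primate-lentivirus coding regions (6.7/4.4/3.7/8.6% of the 18-family
#'   total).
#' @return Named numeric vector of sampling probabilities over the 59
#'   synonymous codons (alphabetical), summing to 1, with the attained
#'   expected A+T3 in \code{attr(, "expected_AT3")}.
#' @export
codon_weights_for <- function(target_AT3, aa_shift = NULL,
                              aa_base = c("uniform", "lentivirus")) {
  aa_base <- match.arg(aa_base)
  uniform_synonyms <- is.null(target_AT3) ||
    (length(target_AT3) == 1L && is.na(target_AT3))
  if (!uniform_synonyms &&
      (!is.numeric(target_AT3) || length(target_AT3) != 1L ||
       target_AT3 < 0 || target_AT3 > 1)) {
    stop("'target_AT3' must be a fraction in [0, 1] or NULL", call. = FALSE)
  }
  code <- genetic_code()
  aa <- code$degenerate_aa
  base <- if (aa_base == "uniform") {
    stats::setNames(rep(1 / 18, 18L), aa)
  } else {
    w <- stats::setNames(rep((100 - 6.7 - 4.4 - 3.7 - 8.6) / 14, 18L), aa)
    w[c("I", "S", "Y", "L")] <- c(6.7, 4.4, 3.7, 8.6)
    w / sum(w)
  }
  if (!is.null(aa_shift)) {
    bad <- setdiff(names(aa_shift), aa)
    if (length(bad)) {
      stop("aa_shift names not degenerate-family amino acids: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    base[names(aa_shift)] <- base[names(aa_shift)] * aa_shift
    base <- base / sum(base)
  }
  at_codons <- .at_ending_codons()
  weights <- stats::setNames(numeric(59L), code$synonymous_codons)
  attained <- 0
  for (a in aa) {
    syn <- code$synonym_families[[a]]
    is_at <- syn %in% at_codons
    k_at <- sum(is_at); k_gc <- sum(!is_at)
    share <- if (uniform_synonyms) k_at / length(syn)
             else if (k_at == 0L) 0 else if (k_gc == 0L) 1 else target_AT3
    weights[syn[is_at]] <- base[[a]] * share / max(k_at, 1L)
    weights[syn[!is_at]] <- base[[a]] * (1 - share) / max(k_gc, 1L)
    attained <- attained + base[[a]] * share
  }
  if (!uniform_synonyms && abs(attained - target_AT3) > 0.005) {
    stop("target A+T3 of ", target_AT3, " is unattainable with these ",
         "families (closest expected value ", round(attained, 4), ")",
         call. = FALSE)
  }
  structure(weights, expected_AT3 = attained)
}

#' Specify a synthetic virus panel
#'
#' Defines the groups of a synthetic coding-sequence panel following a
#' gradient in third-position A+T content, the statistical structure the
#' trend analysis assumes. Codons are later sampled i.i.d. per taxon from
#' the group's weights.
#'
#' @param groups A data.frame with columns \code{label}, \code{n_taxa}
#'   (>= 1) and \code{target_AT3} (fractions strictly inside (0, 1)), and
#'   optionally a list-column \code{aa_shift} of named shift vectors (or
#'   NULL entries).
#' @param codons_per_taxon Codons sampled per taxon; at least 500 for stable
#'   RSCU estimates (default 8000, the scale of a full non-overlapping
#'   lentiviral coding complement).
#' @param seed Integer seed; the generated panel is a pure function of the
#'   spec, seed included.
#' @param aa_base Base amino-acid distribution, see
#'   \code{\link{codon_weights_for}}.
#' @return An object of class \code{"panel_spec"}.
#' @export
panel_spec <- function(groups, codons_per_taxon = 8000L, seed = 1L,
                       aa_base = c("uniform", "lentivirus")) {
  aa_base <- match.arg(aa_base)
  stopifnot(is.data.frame(groups),
            all(c("label", "n_taxa", "target_AT3") %in% names(groups)))
  if (any(groups$n_taxa < 1L)) stop("n_taxa must be >= 1", call. = FALSE)
  ok <- is.na(groups$target_AT3) |
    (groups$target_AT3 > 0 & groups$target_AT3 < 1)
  if (!all(ok)) {
    stop("target_AT3 must lie strictly inside (0, 1), or be NA for ",
         "uniform synonym usage", call. = FALSE)
  }
  if (anyDuplicated(groups$label)) {
    stop("duplicated group labels", call. = FALSE)
  }
  if (codons_per_taxon < 500L) {
    stop("codons_per_taxon must be >= 500 for stable RSCU", call. = FALSE)
  }
  if (!"aa_shift" %in% names(groups)) {
    groups$aa_shift <- rep(list(NULL), nrow(groups))
  }
  structure(
    list(groups = groups, codons_per_taxon = as.integer(codons_per_taxon),
         seed = as.integer(seed), aa_base = aa_base),
    class = "panel_spec"
  )
}

#' The default gradient panel specification
#'
#' Eight groups following the primate-lentivirus gradient in third-position
#' A+T content, from 65.4% (the SIV-in-Old-World-monkey end) to 70.4% (the
#' pandemic HIV-1 group M end), evenly spaced; 54 taxa of 8000 codons each.
#'
#' @param seed Integer seed.
#' @param codons_per_taxon Codons per taxon (default 8000).
#' @param aa_gradient If \code{TRUE}, add a correlated amino-acid drift along
#'   the gradient (Ile and Ser enriched, Tyr and Leu depleted, linearly up to
#'   +/-20% at the gradient's top end), emulating the composition trend that
#'   accompanies the codon-usage trend.
#' @return A \code{"panel_spec"}.
#' @export
lentivirus_panel_spec <- function(seed = 1L, codons_per_taxon = 8000L,
                                  aa_gradient = FALSE) {
  labels <- c("SIV-monkey", "HIV-2", "SIV-gor", "SIV-cpz",
              "HIV-1-P", "HIV-1-O", "HIV-1-N", "HIV-1-M")
  n_taxa <- c(7L, 7L, 7L, 7L, 7L, 7L, 6L, 6L)
  at3 <- seq(0.654, 0.704, length.out = 8L)
  groups <- data.frame(label = labels, n_taxa = n_taxa, target_AT3 = at3,
                       stringsAsFactors = FALSE)
  groups$aa_shift <- lapply(seq_len(8L), function(i) {
    if (!aa_gradient) return(NULL)
    f <- (i - 1) / 7 * 0.2
    c(I = 1 + f, S = 1 + f, Y = 1 - f, L = 1 - f)
  })
  panel_spec(groups, codons_per_taxon = codons_per_taxon, seed = seed,
             aa_base = "lentivirus")
}

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic coding-sequence panel
#'
#' For each taxon, codons are sampled i.i.d. from its group's weights (no
#' positional autocorrelation and no RNA-structure constraints: the analyses
#' under test consume codon counts only), a terminal stop (TAA) is appended,
#' and a manifest row covering the whole sequence is emitted. Output is a
#' pure function of the spec; the same spec yields byte-identical files.
#'
#' @param spec A \code{"panel_spec"}.
#' @param fasta,manifest Optional output paths; when given, the FASTA and
#'   manifest TSV are written (they satisfy the input contracts of
#'   \code{\link{read_fasta}} and \code{\link{read_region_manifest}}, so
#'   generated fixtures exercise the real readers).
#' @return Invisibly, a list with \code{sequences} (a named
#'   \code{DNAStringSet}), \code{manifest} (parsed form, as returned by
#'   \code{\link{read_region_manifest}}), and \code{spec}.
#' @export
generate_panel <- function(spec, fasta = NULL, manifest = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  code <- genetic_code()
  out <- .with_seed(spec$seed, {
    seqs <- character(0)
    ids <- character(0)
    grp <- character(0)
    for (i in seq_len(nrow(spec$groups))) {
      g <- spec$groups[i, ]
      tgt <- if (is.na(g$target_AT3)) NULL else g$target_AT3
      w <- codon_weights_for(tgt, aa_shift = spec$groups$aa_shift[[i]],
                             aa_base = spec$aa_base)
      for (k in seq_len(g$n_taxa)) {
        cods <- sample(names(w), spec$codons_per_taxon, replace = TRUE,
                       prob = w)
        seqs <- c(seqs, paste0(paste(cods, collapse = ""), "TAA"))
        ids <- c(ids, sprintf("%s_%02d", g$label, k))
        grp <- c(grp, g$label)
      }
    }
    list(seqs = seqs, ids = ids, grp = grp)
  })
  sequences <- Biostrings::DNAStringSet(stats::setNames(out$seqs, out$ids))
  man <- data.frame(record_id = out$ids, group = out$grp,
                    stringsAsFactors = FALSE)
  man$intervals <- lapply(nchar(out$seqs), function(L) {
    .parse_spans(paste0("1-", L))
  })
  man$exclusions <- rep(list(.parse_spans("")), nrow(man))
  man$genes <- rep(list(NULL), nrow(man))
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(sequences, fasta)
  }
  if (!is.null(manifest)) {
    raw <- data.frame(record_id = man$record_id, group = man$group,
                      intervals = vapply(man$intervals, .format_spans, ""),
                      exclusions = "", stringsAsFactors = FALSE)
    utils::write.table(raw, manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(sequences = sequences, manifest = man, spec = spec))
}

#' Generate a synthetic host codon-usage table
#'
#' Draws a large multinomial codon sample whose expected occurrence-weighted
#' A/T-ending share equals the target fraction, and returns it as a host
#' usage table (counts plus derived RSCU). Labelled synthetic: it emulates
#' the shape of transcriptome-derived cell-type usage tables (e.g. a
#' monocyte-like table at 53.4% A/T-ending codons, lymphocyte-like tables at
#' 45.2%/46.7%) without any external data.
#'
#' @param at_ending_fraction Target A/T-ending fraction in (0, 1).
#' @param cell_type Label for the table.
#' @param n_codons Codon occurrences to sample (default 1e6; the attained
#'   share is then within about 0.1 percentage points of the target).
#' @param seed Integer seed; same arguments, same table.
#' @param aa_base Base amino-acid distribution, see
#'   \code{\link{codon_weights_for}}.
#' @return A \code{"host_usage"} object with counts.
#' @export
generate_host_table <- function(at_ending_fraction,
                                cell_type = "synthetic-host",
                                n_codons = 1e6, seed = 1L,
                                aa_base = c("uniform", "lentivirus")) {
  aa_base <- match.arg(aa_base)
  if (at_ending_fraction <= 0 || at_ending_fraction >= 1) {
    stop("'at_ending_fraction' must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  w <- codon_weights_for(at_ending_fraction, aa_base = aa_base)
  cnt <- .with_seed(seed, {
    as.vector(stats::rmultinom(1L, size = n_codons, prob = w))
  })
  counts <- stats::setNames(cnt, names(w))
  cc <- codon_counts(counts, id = cell_type)
  new_host_usage(cell_type, rscu(cc)$values, counts = counts,
                 source = "synthetic")
}
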