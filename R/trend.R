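#' Fit the codon-usage trend analysis to a panel of coding regions
#'
#' The package's central fitting function. Given a panel of viral genomes and
#' a region manifest, it runs the full compositional trend analysis:
#' \enumerate{
#'   \item extracts and validates each taxon's non-overlapping coding region
#'     (\code{\link{extract_regions}});
#'   \item computes per-taxon RSCU (\code{\link{rscu}}), Wright's Nc
#'     (\code{\link{effective_number_of_codons}}), and nucleotide composition
#'     at the three codon positions (third-synonymous, first-nonsynonymous
#'     and second-all-synonymous inclusion rules);
#'   \item runs covariance PCA of the taxa-by-59-codon RSCU matrix, anchors
#'     the sign of PC1 to increase with third-position A+T content, and
#'     screens every codon's RSCU against the PC1 score at the |t| cutoff;
#'   \item correlates PC1 with the per-taxon percent content of A, T, G, C,
#'     A+T and G+C at each codon position (the position-wise correlation
#'     table);
#'   \item runs the analogous PCA of the 18-amino-acid composition matrix
#'     (PC1 anchored to Ile content) with its screen;
#'   \item when the manifest defines two or more groups, summarises A+T3 per
#'     group (both mean-of-taxa and pooled-count variants), compares the two
#'     contrast groups with the pooled two-sample t, and compares their
#'     Ile/Ser/Tyr/Leu content with the 2x2 chi-square on pooled counts;
#'   \item when host cell-type usage tables are supplied, correlates each
#'     taxon's RSCU with each table (Pearson, pairwise exclusion of
#'     unobserved families) and compares every pair of host tables per taxon
#'     with the Hotelling dependent-correlation test.
#' }
#'
#' @param sequences A FASTA path, a \code{DNAStringSet}, or a named character
#'   vector of genome sequences.
#' @param manifest A manifest TSV path or a data.frame as returned by
#'   \code{\link{read_region_manifest}} (a raw data.frame with
#'   \code{"start-end"} interval strings is also accepted).
#' @param host_tables A \code{"host_usage"} object or list of them.
#' @param center,scale. PCA preprocessing flags (default: centred,
#'   unscaled covariance PCA).
#' @param t_cutoff Screen cutoff on |t| (default 4.84).
#' @param contrast Two group labels to compare in the group-level tests;
#'   default: the first and last group in manifest order (for a gradient
#'   panel, the two gradient extremes).
#' @param chisq_aa Amino acids for the group chi-square comparisons
#'   (default Ile, Ser, Tyr, Leu).
#' @return An object of class \code{"codon_trend"}; see
#'   \code{\link{summary.codon_trend}}, \code{\link{plot.codon_trend}},
#'   \code{\link{write_report_bundle}}.
#' @examples
#' panel <- generate_panel(lentivirus_panel_spec(seed = 42,
#'                                               codons_per_taxon = 600))
#' fit <- codon_trend(panel$sequences, panel$manifest)
#' fit
#' @export
codon_trend <- function(sequences, manifest, host_tables = list(),
                        center = TRUE, scale. = FALSE, t_cutoff = 4.84,
                        contrast = NULL, chisq_aa = c("I", "S", "Y", "L")) {
  cl <- match.call()
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  seqs <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
  man <- .normalise_manifest(manifest)
  missing_ids <- setdiff(man$record_id, names(seqs))
  if (length(missing_ids)) {
    stop("manifest records absent from sequences: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  n_taxa <- nrow(man)
  regions <- lapply(seq_len(n_taxa), function(i) {
    extract_regions(seqs[[man$record_id[i]]], man$intervals[[i]],
                    exclusions = man$exclusions[[i]],
                    genes = man$genes[[i]], id = man$record_id[i])
  })
  counts <- lapply(regions, function(r) r$counts)
  names(counts) <- man$record_id

  profiles <- lapply(counts, rscu)
  X <- rscu_matrix(profiles, undefined = "NA")
  rownames(X) <- man$record_id
  enc <- vapply(counts, function(cc) effective_number_of_codons(cc)$nc,
                numeric(1))
  comp <- lapply(1:3, function(pos) {
    t(vapply(counts, function(cc) positional_composition(cc, pos)$pct,
             numeric(6L)))
  })
  names(comp) <- c("pos1", "pos2", "pos3")
  at3 <- comp$pos3[, "A+T"]

  X_pca <- X
  if (anyNA(X_pca)) {
    bad <- colnames(X_pca)[colSums(is.na(X_pca)) > 0]
    message("dropping ", length(bad),
            " codon column(s) with undefined RSCU from PCA: ",
            paste(bad, collapse = ", "))
    X_pca <- X_pca[, setdiff(colnames(X_pca), bad), drop = FALSE]
  }
  pca <- usage_pca(X_pca, center = center, scale. = scale.)
  pca <- orient_component(pca, 1L, at3, label = "third-position A+T content")
  pc1 <- pca$scores[, 1L]
  screen <- screen_features(X, pc1, t_cutoff = t_cutoff)

  table1 <- .position_correlations(comp, pc1, t_cutoff)

  A <- aa_matrix(lapply(counts, amino_acid_composition))
  rownames(A) <- man$record_id
  aa_pca <- usage_pca(A, center = center, scale. = scale.)
  aa_pca <- orient_component(aa_pca, 1L, A[, "I"], label = "Ile content")
  aa_screen <- screen_features(A, aa_pca$scores[, 1L], t_cutoff = t_cutoff)

  groups <- factor(man$group, levels = unique(man$group))
  group_summary <- NULL; at3_test <- NULL; aa_tests <- NULL
  if (nlevels(groups) >= 2L) {
    group_summary <- .group_summary(groups, at3, pc1, counts)
    if (is.null(contrast)) {
      contrast <- levels(groups)[c(1L, nlevels(groups))]
    }
    if (!all(contrast %in% levels(groups))) {
      stop("contrast groups not in manifest: ",
           paste(setdiff(contrast, levels(groups)), collapse = ", "),
           call. = FALSE)
    }
    a <- at3[groups == contrast[1L]]; b <- at3[groups == contrast[2L]]
    if (length(a) >= 2L && length(b) >= 2L) {
      at3_test <- two_sample_t(a, b)
    } else {
      message("contrast group with fewer than 2 taxa: A+T3 t test skipped")
    }
    aa_tests <- lapply(chisq_aa, function(aa) {
      aa_content_chisq(counts[groups == contrast[1L]],
                       counts[groups == contrast[2L]], aa)
    })
    names(aa_tests) <- chisq_aa
  } else {
    message("single-group manifest: group comparison stages skipped")
  }

  host <- NULL
  if (inherits(host_tables, "host_usage")) host_tables <- list(host_tables)
  if (length(host_tables)) {
    host <- .host_correlations(X, host_tables, groups)
  }

  structure(
    list(counts = counts, rscu = X, enc = enc, composition = comp,
         at3 = at3, pca = pca, screen = screen, table1 = table1,
         aa = list(matrix = A, pca = aa_pca, screen = aa_screen),
         groups = groups, group_summary = group_summary,
         contrast = contrast, at3_test = at3_test, aa_chisq = aa_tests,
         host = host,
         params = list(center = center, scale. = scale.,
                       t_cutoff = t_cutoff),
         call = cl),
    class = "codon_trend"
  )
}

.normalise_manifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L) {
    return(read_region_manifest(manifest))
  }
  stopifnot(is.data.frame(manifest))
  man <- manifest
  if (!is.list(man$intervals)) {
    man$intervals <- lapply(man$intervals, .parse_spans)
  }
  if (is.null(man$exclusions)) {
    man$exclusions <- rep(list(.parse_spans("")), nrow(man))
  } else if (!is.list(man$exclusions)) {
    man$exclusions <- lapply(man$exclusions, .parse_spans)
  }
  if (is.null(man$genes)) {
    man$genes <- rep(list(NULL), nrow(man))
  } else if (!is.list(man$genes)) {
    man$genes <- lapply(man$genes, function(g) {
      if (is.na(g) || !nzchar(g)) NULL else strsplit(g, ";", fixed = TRUE)[[1L]]
    })
  }
  man
}

.position_correlations <- function(comp, pc1, t_cutoff) {
  bases <- c("A", "T", "G", "C", "A+T", "G+C")
  r <- t_stat <- matrix(NA_real_, nrow = 3L, ncol = 6L,
                        dimnames = list(paste0("pos", 1:3), bases))
  for (i in 1:3) {
    for (b in bases) {
      v <- comp[[i]][, b]
      if (stats::sd(v) == 0) next
      ct <- pearson_with_t(pc1, v)
      r[i, b] <- ct$r
      t_stat[i, b] <- ct$t
    }
  }
  list(r = r, t = t_stat, significant = abs(t_stat) > t_cutoff,
       t_cutoff = t_cutoff)
}

.group_summary <- function(groups, at3, pc1, counts) {
  lv <- levels(groups)
  data.frame(
    group = lv,
    n = as.integer(table(groups)[lv]),
    at3_mean = vapply(lv, function(g) mean(at3[groups == g]), numeric(1)),
    at3_sd = vapply(lv, function(g) stats::sd(at3[groups == g]), numeric(1)),
    at3_pooled = vapply(lv, function(g) {
      at_ending_fraction(pool_counts(counts[groups == g]))
    }, numeric(1)),
    pc1_mean = vapply(lv, function(g) mean(pc1[groups == g]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

.host_correlations <- function(X, host_tables, groups) {
  labels <- vapply(host_tables, function(h) h$cell_type, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicated host table labels", call. = FALSE)
  }
  names(host_tables) <- labels
  taxa <- rownames(X)
  r <- n_used <- matrix(NA_real_, nrow = nrow(X), ncol = length(labels),
                        dimnames = list(taxa, labels))
  for (j in seq_along(host_tables)) {
    h <- host_tables[[j]]$rscu[colnames(X)]
    for (i in seq_len(nrow(X))) {
      ct <- pearson_with_t(X[i, ], h)
      r[i, j] <- ct$r
      n_used[i, j] <- ct$n
    }
  }
  hotelling <- NULL
  if (length(labels) >= 2L) {
    pairs <- utils::combn(labels, 2L, simplify = FALSE)
    rows <- list()
    for (pr in pairs) {
      h1 <- host_tables[[pr[1L]]]$rscu[colnames(X)]
      h2 <- host_tables[[pr[2L]]]$rscu[colnames(X)]
      for (i in seq_len(nrow(X))) {
        ok <- stats::complete.cases(X[i, ], h1, h2)
        ht <- hotelling_dependent_t(
          r12 = stats::cor(X[i, ok], h1[ok]),
          r13 = stats::cor(X[i, ok], h2[ok]),
          r23 = stats::cor(h1[ok], h2[ok]),
          n = sum(ok))
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = taxa[i], host_a = pr[1L], host_b = pr[2L],
          r_a = ht$r12, r_b = ht$r13, r_ab = ht$r23, n = ht$n,
          t = ht$t, df = ht$df, p = ht$p, stringsAsFactors = FALSE)
      }
    }
    hotelling <- do.call(rbind, rows)
  }
  mean_by_group <- NULL
  if (nlevels(groups) >= 1L) {
    mean_by_group <- do.call(rbind, lapply(levels(groups), function(g) {
      data.frame(group = g, cell_type = labels,
                 r_mean = colMeans(r[groups == g, , drop = FALSE]),
                 r_sd = apply(r[groups == g, , drop = FALSE], 2L, stats::sd),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }
  list(tables = host_tables, r = r, n = n_used,
       best = labels[max.col(r)], hotelling = hotelling,
       mean_by_group = mean_by_group)
}

#' @export
print.codon_trend <- function(x, ...) {
  cat("Codon-usage trend analysis\n")
  cat("  taxa:", nrow(x$rscu), "| groups:", nlevels(x$groups), "\n")
  cat(sprintf("  RSCU PCA: PC1 %.1f%%, PC2 %.1f%% of variance (PC1 anchored to A+T3)\n",
              100 * x$pca$variance_fraction[1L],
              100 * x$pca$variance_fraction[2L]))
  cat(sprintf("  codon screen at |t| > %.2f: %d positive, %d negative\n",
              x$params$t_cutoff, length(x$screen$positive_set),
              length(x$screen$negative_set)))
  cat(sprintf("  A+T3 range: %.1f%% to %.1f%% | Nc range: %.1f to %.1f\n",
              min(x$at3), max(x$at3), min(x$enc), max(x$enc)))
  if (!is.null(x$host)) {
    best <- table(x$host$best)
    cat("  best-correlated host table per taxon:",
        paste(names(best), best, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Summarise a codon-usage trend analysis
#'
#' @param object A \code{"codon_trend"} fit.
#' @param ... Unused.
#' @return An object of class \code{"summary.codon_trend"} collecting the
#'   variance fractions, the position-wise PC1 correlation table, the group
#'   summary, the contrast tests and the host correlation summary.
#' @method summary codon_trend
#' @export
summary.codon_trend <- function(object, ...) {
  structure(
    list(n_taxa = nrow(object$rscu), groups = object$groups,
         variance_fraction = object$pca$variance_fraction,
         aa_variance_fraction = object$aa$pca$variance_fraction,
         table1 = object$table1, screen = object$screen,
         aa_screen = object$aa$screen,
         group_summary = object$group_summary, contrast = object$contrast,
         at3_test = object$at3_test, aa_chisq = object$aa_chisq,
         host = object$host, params = object$params),
    class = "summary.codon_trend"
  )
}

#' @export
print.summary.codon_trend <- function(x, ...) {
  cat("Codon-usage trend analysis:", x$n_taxa, "taxa,",
      nlevels(x$groups), "group(s)\n\n")
  cat(sprintf("RSCU PCA: PC1 %.1f%%, PC2 %.1f%% (together %.1f%%)\n",
              100 * x$variance_fraction[1L], 100 * x$variance_fraction[2L],
              100 * sum(x$variance_fraction[1:2])))
  cat(sprintf("Amino-acid PCA: PC1 %.1f%%, PC2 %.1f%%\n\n",
              100 * x$aa_variance_fraction[1L],
              100 * x$aa_variance_fraction[2L]))
  cat("PC1 vs percent base content by codon position (r):\n")
  print(round(x$table1$r, 2))
  cat("\nCodon screen: ", length(x$screen$positive_set), " positive / ",
      length(x$screen$negative_set), " negative at |t| > ",
      x$params$t_cutoff, "\n", sep = "")
  if (!is.null(x$group_summary)) {
    cat("\nGroup summary (A+T3 %, mean-of-taxa and pooled):\n")
    print(cbind(x$group_summary[, c("group", "n")],
                round(x$group_summary[, c("at3_mean", "at3_sd",
                                          "at3_pooled", "pc1_mean")], 3)))
    if (!is.null(x$at3_test)) {
      cat(sprintf("\nA+T3 contrast %s vs %s: t = %.2f, p = %.3g\n",
                  x$contrast[1L], x$contrast[2L], x$at3_test$t,
                  x$at3_test$p))
    }
    if (!is.null(x$aa_chisq)) {
      cat("Amino-acid content chi-square (contrast groups, pooled counts):\n")
      for (aa in names(x$aa_chisq)) {
        cat(sprintf("  %s: chi2 = %.2f, p = %.3g\n", aa,
                    x$aa_chisq[[aa]]$chi2, x$aa_chisq[[aa]]$p))
      }
    }
  }
  if (!is.null(x$host)) {
    cat("\nMean correlation with host tables (all taxa):\n")
    m <- colMeans(x$host$r); s <- apply(x$host$r, 2L, stats::sd)
    for (h in names(m)) {
      cat(sprintf("  %s: r = %.3f (sd %.3f)\n", h, m[h], s[h]))
    }
  }
  invisible(x)
}

#' Plot a codon-usage trend analysis
#'
#' @param x A \code{"codon_trend"} fit.
#' @param which \code{"scores"} (PC1 vs PC2, coloured by group) or
#'   \code{"at3"} (PC1 vs third-position A+T content, the trend view).
#' @param ... Passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @method plot codon_trend
#' @export
plot.codon_trend <- function(x, which = c("scores", "at3"), ...) {
  which <- match.arg(which)
  col <- as.integer(x$groups)
  if (which == "scores") {
    graphics::plot(x$pca$scores[, 1L], x$pca$scores[, 2L], col = col,
                   pch = 19,
                   xlab = sprintf("PC1 (%.1f%%)",
                                  100 * x$pca$variance_fraction[1L]),
                   ylab = sprintf("PC2 (%.1f%%)",
                                  100 * x$pca$variance_fraction[2L]), ...)
  } else {
    graphics::plot(x$pca$scores[, 1L], x$at3, col = col, pch = 19,
                   xlab = "PC1 score", ylab = "A+T3 (%)", ...)
  }
  graphics::legend("topleft", legend = levels(x$groups), bty = "n",
                   col = seq_len(nlevels(x$groups)), pch = 19, cex = 0.8)
  invisible(x)
}

#' @method coef codon_trend
#' @export
coef.codon_trend <- function(object, ...) {
  object$pca$loadings
}

#' Per-taxon PC scores of a trend analysis
#'
#' @param x A \code{"codon_trend"} fit.
#' @param space \code{"rscu"} (default) or \code{"aa"}.
#' @return Matrix of scores, taxa in rows.
#' @export
trend_scores <- function(x, space = c("rscu", "aa")) {
  stopifnot(inherits(x, "codon_trend"))
  space <- match.arg(space)
  if (space == "rscu") x$pca$scores else x$aa$pca$scores
}

#' Simulate panels resembling a fitted trend
#'
#' Draws synthetic panels whose groups sit at the fitted pooled A+T3 values,
#' with the fitted group sizes and the mean observed codon count per taxon -
#' a parametric-bootstrap style generator for the fitted gradient.
#'
#' @param object A \code{"codon_trend"} fit with at least 2 groups.
#' @param nsim Number of panels.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of \code{nsim} generated panels (see
#'   \code{\link{generate_panel}}).
#' @method simulate codon_trend
#' @export
simulate.codon_trend <- function(object, nsim = 1L, seed = 1L, ...) {
  if (is.null(object$group_summary)) {
    stop("simulate needs a fitted group structure (>= 2 groups)",
         call. = FALSE)
  }
  gs <- object$group_summary
  codons <- max(500L, round(mean(vapply(
    object$counts, function(cc) sum(cc$counts), numeric(1)))))
  lapply(seq_len(nsim), function(k) {
    spec <- panel_spec(
      data.frame(label = gs$group, n_taxa = gs$n,
                 target_AT3 = gs$at3_pooled / 100,
                 stringsAsFactors = FALSE),
      codons_per_taxon = codons, seed = seed + k - 1L)
    generate_panel(spec)
  })
}
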