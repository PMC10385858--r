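#' Per-gene correlation of viral codon usage with host usage tables
#'
#' For each taxon, computes the RSCU of each individually tagged gene and of
#' the accessory/regulatory genes pooled together, and correlates each with
#' every host cell-type usage table. Pooling is concatenation-then-RSCU: the
#' member genes' codon counts are summed before the RSCU is computed (never a
#' mean of per-gene RSCU vectors, which weights genes equally regardless of
#' length).
#'
#' @param sequences A FASTA path, \code{DNAStringSet}, or named character
#'   vector.
#' @param manifest A manifest (path or data.frame) whose every entry tags its
#'   intervals with gene names; an untagged entry is an error.
#' @param host_tables A \code{"host_usage"} object or list of them.
#' @param accessory Gene names pooled into the \code{"accessory"} entry
#'   (default tat, rev, vif, vpr, nef); genes not listed here are reported
#'   individually.
#' @return A data.frame with one row per taxon x gene x host table:
#'   \code{record_id}, \code{group}, \code{gene}, \code{cell_type},
#'   \code{n} (codons used), \code{r}, \code{t}, \code{p}.
#' @export
gene_host_correlations <- function(sequences, manifest, host_tables,
                                   accessory = c("tat", "rev", "vif",
                                                 "vpr", "nef")) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  seqs <- stats::setNames(as.character(sequences), names(sequences))
  man <- .normalise_manifest(manifest)
  untagged <- vapply(man$genes, is.null, logical(1))
  if (any(untagged)) {
    stop("gene tag absent for record(s): ",
         paste(man$record_id[untagged], collapse = ", "), call. = FALSE)
  }
  if (inherits(host_tables, "host_usage")) host_tables <- list(host_tables)
  labels <- vapply(host_tables, function(h) h$cell_type, character(1))
  names(host_tables) <- labels

  rows <- list()
  for (i in seq_len(nrow(man))) {
    reg <- extract_regions(seqs[[man$record_id[i]]], man$intervals[[i]],
                           exclusions = man$exclusions[[i]],
                           genes = man$genes[[i]], id = man$record_id[i])
    pc <- reg$piece_counts
    gene_counts <- list()
    for (g in setdiff(names(pc), accessory)) {
      gene_counts[[g]] <- pc[[g]]
    }
    acc <- intersect(names(pc), accessory)
    if (length(acc)) {
      gene_counts[["accessory"]] <- pool_counts(pc[acc])
    }
    for (g in names(gene_counts)) {
      prof <- rscu(gene_counts[[g]])
      v <- rscu_matrix(list(prof), undefined = "NA")[1L, ]
      for (h in labels) {
        ct <- pearson_with_t(v, host_tables[[h]]$rscu[names(v)])
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = man$record_id[i], group = man$group[i], gene = g,
          cell_type = h, n = ct$n, r = ct$r, t = ct$t, p = ct$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
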