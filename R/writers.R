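.config_hash <- function(s) {
  # deterministic 31-bit polynomial fingerprint of the config string
  h <- 17
  for (b in utf8ToInt(s)) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

.bundle_header <- function(fit) {
  p <- fit$params
  desc <- sprintf("center=%s scale=%s t_cutoff=%g contrast=%s",
                  p$center, p$scale., p$t_cutoff,
                  paste(fit$contrast, collapse = "/"))
  sprintf("# codontrend %s | %s | config=%s",
          as.character(utils::packageVersion("codontrend")), desc,
          .config_hash(desc))
}

.write_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the full report bundle of a trend analysis
#'
#' Emits the analysis as a directory of TSV tables (taxa sorted in manifest
#' order, codons alphabetical), each carrying a header comment with the
#' package version and a hash of the configuration. Rewriting the same fit
#' reproduces the files byte for byte.
#'
#' Files: \code{rscu.tsv}, \code{enc.tsv}, \code{composition.tsv},
#' \code{scores.tsv}, \code{loadings.tsv}, \code{variance.tsv},
#' \code{screen.tsv}, \code{position_correlations.tsv},
#' \code{aa_composition.tsv}, \code{aa_scores.tsv}, and - where the fit
#' contains them - \code{group_summary.tsv}, \code{group_tests.tsv},
#' \code{host_correlations.tsv}, \code{hotelling.tsv}.
#'
#' @param fit A \code{"codon_trend"} object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report_bundle <- function(fit, dir) {
  stopifnot(inherits(fit, "codon_trend"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- .bundle_header(fit)
  fmt <- function(x) sprintf("%.10g", x)
  taxa <- rownames(fit$rscu)

  rs <- data.frame(record_id = taxa, group = as.character(fit$groups),
                   stringsAsFactors = FALSE)
  rs <- cbind(rs, as.data.frame(apply(fit$rscu, 2L, fmt)))
  .write_tsv(rs, file.path(dir, "rscu.tsv"), hdr)

  .write_tsv(data.frame(record_id = taxa, group = as.character(fit$groups),
                        nc = fmt(fit$enc), at3 = fmt(fit$at3)),
             file.path(dir, "enc.tsv"), hdr)

  comp <- do.call(rbind, lapply(names(fit$composition), function(pos) {
    m <- fit$composition[[pos]]
    data.frame(record_id = taxa, position = pos,
               as.data.frame(apply(m, 2L, fmt), check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  .write_tsv(comp, file.path(dir, "composition.tsv"), hdr)

  k <- min(5L, ncol(fit$pca$scores))
  sc <- data.frame(record_id = taxa, group = as.character(fit$groups),
                   stringsAsFactors = FALSE)
  sc <- cbind(sc, as.data.frame(apply(fit$pca$scores[, 1:k, drop = FALSE],
                                      2L, fmt)))
  .write_tsv(sc, file.path(dir, "scores.tsv"), hdr)

  ld <- data.frame(codon = rownames(fit$pca$loadings),
                   stringsAsFactors = FALSE)
  ld <- cbind(ld, as.data.frame(apply(fit$pca$loadings[, 1:k, drop = FALSE],
                                      2L, fmt)))
  .write_tsv(ld, file.path(dir, "loadings.tsv"), hdr)

  .write_tsv(data.frame(component = colnames(fit$pca$scores),
                        variance_fraction = fmt(fit$pca$variance_fraction)),
             file.path(dir, "variance.tsv"), hdr)

  scr <- fit$screen$table
  scr[c("r", "t", "p")] <- lapply(scr[c("r", "t", "p")], fmt)
  .write_tsv(scr, file.path(dir, "screen.tsv"), hdr)

  tb <- fit$table1$r
  .write_tsv(data.frame(position = rownames(tb),
                        as.data.frame(apply(tb, 2L, fmt),
                                      check.names = FALSE),
                        check.names = FALSE),
             file.path(dir, "position_correlations.tsv"), hdr)

  aam <- data.frame(record_id = taxa, group = as.character(fit$groups),
                    stringsAsFactors = FALSE)
  aam <- cbind(aam, as.data.frame(apply(fit$aa$matrix, 2L, fmt)))
  .write_tsv(aam, file.path(dir, "aa_composition.tsv"), hdr)

  ka <- min(5L, ncol(fit$aa$pca$scores))
  aas <- data.frame(record_id = taxa, group = as.character(fit$groups),
                    stringsAsFactors = FALSE)
  aas <- cbind(aas, as.data.frame(apply(
    fit$aa$pca$scores[, 1:ka, drop = FALSE], 2L, fmt)))
  .write_tsv(aas, file.path(dir, "aa_scores.tsv"), hdr)

  if (!is.null(fit$group_summary)) {
    gs <- fit$group_summary
    gs[-(1:2)] <- lapply(gs[-(1:2)], fmt)
    .write_tsv(gs, file.path(dir, "group_summary.tsv"), hdr)

    tests <- data.frame(comparison = character(0), statistic = character(0),
                        value = character(0), df = character(0),
                        p = character(0), stringsAsFactors = FALSE)
    if (!is.null(fit$at3_test)) {
      tests <- rbind(tests, data.frame(
        comparison = paste0("AT3:", paste(fit$contrast, collapse = "-vs-")),
        statistic = "t", value = fmt(fit$at3_test$t),
        df = fmt(fit$at3_test$df), p = fmt(fit$at3_test$p),
        stringsAsFactors = FALSE))
    }
    for (aa in names(fit$aa_chisq)) {
      tests <- rbind(tests, data.frame(
        comparison = paste0(aa, ":", paste(fit$contrast, collapse = "-vs-")),
        statistic = "chi2", value = fmt(fit$aa_chisq[[aa]]$chi2),
        df = fmt(fit$aa_chisq[[aa]]$df), p = fmt(fit$aa_chisq[[aa]]$p),
        stringsAsFactors = FALSE))
    }
    .write_tsv(tests, file.path(dir, "group_tests.tsv"), hdr)
  }

  if (!is.null(fit$host)) {
    hc <- data.frame(record_id = rep(taxa, ncol(fit$host$r)),
                     group = rep(as.character(fit$groups), ncol(fit$host$r)),
                     cell_type = rep(colnames(fit$host$r),
                                     each = nrow(fit$host$r)),
                     r = fmt(as.vector(fit$host$r)),
                     n = as.vector(fit$host$n), stringsAsFactors = FALSE)
    .write_tsv(hc, file.path(dir, "host_correlations.tsv"), hdr)
    if (!is.null(fit$host$hotelling)) {
      ho <- fit$host$hotelling
      num <- c("r_a", "r_b", "r_ab", "t", "p")
      ho[num] <- lapply(ho[num], fmt)
      .write_tsv(ho, file.path(dir, "hotelling.tsv"), hdr)
    }
  }
  invisible(dir)
}

#' Re-read a table written by \code{write_report_bundle}
#'
#' @param path Path to one of the bundle's TSV files.
#' @return A data.frame (the header comment is skipped).
#' @export
read_report_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
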