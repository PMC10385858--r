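make_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panel <- generate_panel(small_gradient_spec(seed = 17, codons = 1500L))
      hosts <- list(generate_host_table(0.534, "monocyte", seed = 1),
                    generate_host_table(0.452, "B-lymphocyte", seed = 2),
                    generate_host_table(0.467, "T-lymphocyte", seed = 3))
      cache <<- list(panel = panel, hosts = hosts,
                     fit = codon_trend(panel$sequences, panel$manifest,
                                       host_tables = hosts))
    }
    cache
  }
})

test_that("the fitted trend object is coherent end to end", {
  ctx <- make_fit()
  fit <- ctx$fit
  expect_s3_class(fit, "codon_trend")
  expect_identical(nrow(fit$rscu), 12L)
  expect_identical(colnames(fit$rscu), genetic_code()$synonymous_codons)
  expect_true(all(fit$enc >= 20 & fit$enc <= 61))

  # PC1 is anchored: it must increase with A+T3
  r <- cor(trend_scores(fit)[, 1L], fit$at3)
  expect_gt(r, 0.9)
  # and the third-position row of the position-wise correlation table
  # reflects the same trend
  expect_gt(fit$table1$r["pos3", "A+T"], 0.9)
  expect_equal(fit$table1$r["pos3", "A+T"], -fit$table1$r["pos3", "G+C"],
               tolerance = 1e-9)

  # group bookkeeping
  gs <- fit$group_summary
  expect_identical(gs$group, c("g1", "g2", "g3"))
  expect_identical(sum(gs$n), 12L)
  expect_true(all(diff(gs$at3_mean) > 0))  # strong designed gradient
  expect_identical(fit$contrast, c("g1", "g3"))
  direct <- two_sample_t(fit$at3[fit$groups == "g1"],
                         fit$at3[fit$groups == "g3"])
  expect_equal(fit$at3_test$t, direct$t, tolerance = 1e-12)
  expect_named(fit$aa_chisq, c("I", "S", "Y", "L"))

  # host stage: every taxon correlates best with the closest A/T share
  expect_true(all(fit$host$best == "monocyte"))
  expect_identical(dim(fit$host$r), c(12L, 3L))
  ho <- fit$host$hotelling
  expect_identical(nrow(ho), 12L * 3L)  # 3 host pairs per taxon
  expect_true(all(ho$df == ho$n - 3L))
})

test_that("fitting is deterministic for a fixed panel", {
  ctx <- make_fit()
  fit2 <- codon_trend(ctx$panel$sequences, ctx$panel$manifest,
                      host_tables = ctx$hosts)
  expect_equal(trend_scores(fit2), trend_scores(ctx$fit), tolerance = 0)
  expect_identical(fit2$screen$table, ctx$fit$screen$table)
})

test_that("coef, scores and summary expose the fit", {
  fit <- make_fit()$fit
  expect_identical(coef(fit), fit$pca$loadings)
  expect_identical(trend_scores(fit, "aa"), fit$aa$pca$scores)
  s <- summary(fit)
  expect_s3_class(s, "summary.codon_trend")
  out <- capture.output(print(s))
  expect_true(any(grepl("Group summary", out)))
  expect_true(any(grepl("monocyte", out)))
  out2 <- capture.output(print(fit))
  expect_true(any(grepl("Codon-usage trend analysis", out2)))
})

test_that("plot and simulate methods run on a fitted object", {
  fit <- make_fit()$fit
  png_path <- tempfile(fileext = ".png")
  grDevices::png(png_path)
  expect_silent(plot(fit))
  expect_silent(plot(fit, which = "at3"))
  grDevices::dev.off()
  expect_true(file.exists(png_path))

  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2L)
  expect_identical(nrow(sims[[1]]$manifest), 12L)
  expect_false(identical(as.character(sims[[1]]$sequences),
                         as.character(sims[[2]]$sequences)))
})

test_that("a single-group manifest skips the comparison stages", {
  spec <- panel_spec(data.frame(label = "only", n_taxa = 4L,
                                target_AT3 = 0.65),
                     codons_per_taxon = 900L, seed = 2)
  panel <- generate_panel(spec)
  expect_message(fit <- codon_trend(panel$sequences, panel$manifest),
                 "single-group")
  expect_null(fit$group_summary)
  expect_null(fit$at3_test)
  expect_null(fit$aa_chisq)
})

test_that("the report bundle is complete, re-readable and byte-stable", {
  ctx <- make_fit()
  d1 <- tempfile(); d2 <- tempfile()
  write_report_bundle(ctx$fit, d1)
  write_report_bundle(ctx$fit, d2)
  files <- c("rscu.tsv", "enc.tsv", "composition.tsv", "scores.tsv",
             "loadings.tsv", "variance.tsv", "screen.tsv",
             "position_correlations.tsv", "aa_composition.tsv",
             "aa_scores.tsv", "group_summary.tsv", "group_tests.tsv",
             "host_correlations.tsv", "hotelling.tsv")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  rs <- read_report_table(file.path(d1, "rscu.tsv"))
  expect_identical(nrow(rs), 12L)
  expect_identical(ncol(rs), 61L)  # id + group + 59 codons
  sc <- read_report_table(file.path(d1, "scores.tsv"))
  expect_equal(sc$PC1, unname(trend_scores(ctx$fit)[, 1L]),
               tolerance = 1e-9)
  vr <- read_report_table(file.path(d1, "variance.tsv"))
  expect_equal(sum(vr$variance_fraction), 1, tolerance = 1e-8)
  # every file carries the version/config header
  for (f in files) {
    expect_match(readLines(file.path(d1, f), n = 1L), "^# codontrend ")
  }
})

test_that("gene-level correlations pool accessory genes by concatenation", {
  set.seed(51)
  w <- codon_weights_for(0.68)
  seq_of <- function(n) paste0(paste(sample(names(w), n, replace = TRUE,
                                            prob = w), collapse = ""), "TAA")
  gag <- seq_of(500); tat <- seq_of(200); rev <- seq_of(150)
  genome <- paste0(gag, tat, rev)
  L <- nchar(c(gag, tat, rev))
  b <- cumsum(c(0, L[-3]))
  man <- data.frame(
    record_id = "vir1", group = "g",
    intervals = paste(sprintf("%d-%d", b + 1, b + L), collapse = ";"),
    genes = "gag;tat;rev", stringsAsFactors = FALSE)
  host <- generate_host_table(0.534, "monocyte", seed = 6)
  res <- gene_host_correlations(c(vir1 = genome), man, host)
  expect_setequal(res$gene, c("gag", "accessory"))

  # oracle: concatenate tat+rev, then RSCU, then correlate
  pooled <- pool_counts(list(count_codons(tat), count_codons(rev)))
  v <- rscu_matrix(list(rscu(pooled)))[1L, ]
  r_ref <- pearson_with_t(v, host$rscu[names(v)])$r
  expect_equal(res$r[res$gene == "accessory"], r_ref, tolerance = 1e-12)

  # single-gene manifest: report contains exactly that gene
  man1 <- data.frame(record_id = "vir1", group = "g",
                     intervals = sprintf("1-%d", L[1]), genes = "gag",
                     stringsAsFactors = FALSE)
  res1 <- gene_host_correlations(c(vir1 = genome), man1, host)
  expect_identical(res1$gene, "gag")

  # untagged manifest is an error
  man0 <- man; man0$genes <- NULL
  expect_error(gene_host_correlations(c(vir1 = genome), man0, host),
               "gene tag absent")
})

test_that("genes drawn from one codon distribution correlate alike", {
  set.seed(52)
  w <- codon_weights_for(0.65)
  piece <- function(n) paste(sample(names(w), n, replace = TRUE, prob = w),
                             collapse = "")
  g1 <- piece(3000); g2 <- piece(3000)
  genome <- paste0(g1, g2)
  man <- data.frame(record_id = "v", group = "g",
                    intervals = sprintf("1-%d;%d-%d", 9000, 9001, 18000),
                    genes = "gag;pol", stringsAsFactors = FALSE)
  host <- generate_host_table(0.534, "monocyte", seed = 7)
  res <- gene_host_correlations(c(v = genome), man, host)
  expect_lt(abs(diff(res$r)), 0.15)  # equal within multinomial noise
})
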