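test_that("codon weights hit the target A+T3 analytically", {
  for (target in c(0.3, 0.534, 0.654, 0.704, 0.9)) {
    w <- codon_weights_for(target)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    at <- substr(names(w), 3, 3) %in% c("A", "T")
    expect_equal(sum(w[at]), target, tolerance = 1e-12)
    expect_equal(attr(w, "expected_AT3"), target, tolerance = 1e-12)
  }
  # boundary: all mass on A/T-ending synonyms
  w1 <- codon_weights_for(1)
  expect_equal(sum(w1[substr(names(w1), 3, 3) %in% c("G", "C")]), 0)
  expect_error(codon_weights_for(1.5), "fraction")
})

test_that("empirical A+T3 of a large sample matches the target", {
  w <- codon_weights_for(0.654)
  set.seed(41)
  cnt <- as.vector(rmultinom(1, 1e6, w))
  cc <- codon_counts(stats::setNames(cnt, names(w)))
  expect_equal(at_ending_fraction(cc) / 100, 0.654, tolerance = 0.005)
})

test_that("amino-acid shifts scale family mass multiplicatively", {
  w0 <- codon_weights_for(0.6)
  w2 <- codon_weights_for(0.6, aa_shift = c(I = 2))
  fam <- genetic_code()$synonym_families
  mass <- function(w, a) sum(w[fam[[a]]])
  # pre-normalisation the Ile share doubles, so the Ile:Ala mass ratio does
  expect_equal(mass(w2, "I") / mass(w2, "A"),
               2 * mass(w0, "I") / mass(w0, "A"), tolerance = 1e-12)
  expect_error(codon_weights_for(0.6, aa_shift = c(M = 2)), "aa_shift")
})

test_that("the lentivirus amino-acid preset enriches Ile over uniform", {
  wu <- codon_weights_for(0.6, aa_base = "uniform")
  wl <- codon_weights_for(0.6, aa_base = "lentivirus")
  fam <- genetic_code()$synonym_families
  expect_gt(sum(wl[fam[["I"]]]), sum(wu[fam[["I"]]]))
  expect_lt(sum(wl[fam[["Y"]]]), sum(wu[fam[["Y"]]]))
})

test_that("panel generation is a pure function of its spec", {
  spec <- small_gradient_spec(seed = 7, codons = 600L)
  f1 <- tempfile(); m1 <- tempfile(); f2 <- tempfile(); m2 <- tempfile()
  generate_panel(spec, fasta = f1, manifest = m1)
  generate_panel(spec, fasta = f2, manifest = m2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(m1), readLines(m2))
  # a different seed changes the sequences
  f3 <- tempfile()
  generate_panel(small_gradient_spec(seed = 8, codons = 600L), fasta = f3)
  expect_false(identical(readLines(f1), readLines(f3)))
  # generation does not disturb the session RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); generate_panel(spec); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("panel sequences carry the designed group structure", {
  spec <- small_gradient_spec(seed = 3, at3 = c(0.55, 0.70), n_taxa = 3L,
                              codons = 2000L)
  panel <- generate_panel(spec)
  man <- panel$manifest
  expect_identical(nrow(man), 6L)
  at3 <- vapply(seq_len(nrow(man)), function(i) {
    cc <- extract_regions(as.character(panel$sequences[[i]]),
                          man$intervals[[i]])$counts
    at_ending_fraction(cc) / 100
  }, numeric(1))
  expect_equal(mean(at3[man$group == "g1"]), 0.55, tolerance = 0.02)
  expect_equal(mean(at3[man$group == "g2"]), 0.70, tolerance = 0.02)
  # terminal stop present on every sequence, stripped by extraction
  expect_true(all(vapply(as.character(panel$sequences), function(s) {
    substr(s, nchar(s) - 2, nchar(s)) == "TAA"
  }, logical(1))))
})

test_that("uniform synonym usage yields RSCU near 1 for every codon", {
  spec <- panel_spec(data.frame(label = "null", n_taxa = 6L,
                                target_AT3 = NA, stringsAsFactors = FALSE),
                     codons_per_taxon = 4000L, seed = 5)
  panel <- generate_panel(spec)
  profs <- lapply(seq_len(6L), function(i) {
    rscu(extract_regions(as.character(panel$sequences[[i]]),
                         panel$manifest$intervals[[i]])$counts)
  })
  m <- rscu_matrix(profs)
  # multinomial noise around 1: the mean over taxa stays within 3 sd
  expect_true(all(abs(colMeans(m) - 1) < 0.25))
  expect_equal(mean(colMeans(m)), 1, tolerance = 0.01)
})

test_that("synthetic host tables are deterministic and hit their share", {
  h1 <- generate_host_table(0.534, "monocyte", seed = 2, n_codons = 2e5)
  h2 <- generate_host_table(0.534, "monocyte", seed = 2, n_codons = 2e5)
  expect_identical(h1$rscu, h2$rscu)
  expect_equal(at_ending_fraction(h1) / 100, 0.534, tolerance = 0.005)
  expect_error(generate_host_table(1.2), "inside")
})

test_that("host tables order correlations by A/T-share proximity", {
  # a lentivirus-like taxon at A+T3 = 0.70 should correlate positively with
  # a monocyte-like table (0.534) and less with a B-cell-like one (0.452)
  set.seed(43)
  w <- codon_weights_for(0.70)
  cc <- codon_counts(stats::setNames(as.vector(rmultinom(1, 20000, w)),
                                     names(w)))
  v <- rscu(cc)$values
  mono <- generate_host_table(0.534, "mono", seed = 11)
  bcell <- generate_host_table(0.452, "b", seed = 12)
  r_mono <- pearson_with_t(v, mono$rscu[names(v)])$r
  r_b <- pearson_with_t(v, bcell$rscu[names(v)])$r
  expect_gt(r_mono, 0)
  expect_gt(r_mono, r_b)
})

test_that("a strong gradient is recovered in rank order", {
  # recovery property at a clearly separated gradient: group ordering along
  # PC1 reproduces the generating order in every seed
  for (seed in 1:5) {
    spec <- small_gradient_spec(seed = seed, at3 = c(0.55, 0.62, 0.70),
                                n_taxa = 4L, codons = 1200L)
    panel <- generate_panel(spec)
    fit <- codon_trend(panel$sequences, panel$manifest)
    gm <- fit$group_summary$pc1_mean
    expect_identical(order(gm), 1:3)
  }
})

test_that("panel_spec validates its invariants", {
  g <- data.frame(label = "a", n_taxa = 2L, target_AT3 = 0.6)
  expect_error(panel_spec(g, codons_per_taxon = 100L), ">= 500")
  expect_error(panel_spec(transform(g, n_taxa = 0L)), ">= 1")
  expect_error(panel_spec(transform(g, target_AT3 = 1.0)), "inside")
  expect_error(panel_spec(rbind(g, g)), "duplicated")
})
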