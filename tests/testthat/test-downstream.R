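test_that("Bonferroni thresholds reproduce the two-level correction", {
  expect_equal(bonferroni_thresholds(0.05, 1)$threshold, 0.05)
  t1 <- bonferroni_thresholds(0.05, 40749)
  expect_equal(t1$display, 1.23e-6)
  t2 <- bonferroni_thresholds(0.05, 41086, n_traits = 4671)
  expect_equal(t2$threshold, 0.05 / 41086 / 4671, tolerance = 1e-15)
  expect_equal(t2$threshold, 2.605e-10, tolerance = 1e-3)
  # strictly decreasing in both counts
  expect_lt(bonferroni_thresholds(0.05, 100)$threshold,
            bonferroni_thresholds(0.05, 99)$threshold)
  expect_lt(bonferroni_thresholds(0.05, 100, 10)$threshold,
            bonferroni_thresholds(0.05, 100, 9)$threshold)
  expect_error(bonferroni_thresholds(0.05, 0))
})

test_that("GReX-trait association behaves under null and planted signal", {
  set.seed(61)
  n <- 400
  grex <- matrix(rnorm(n * 60), n, dimnames = list(NULL,
                                                   sprintf("t%02d", 1:60)))
  # null: roughly uniform p-values
  y0 <- rnorm(n)
  a0 <- associate_grex_with_trait(grex, y0)
  expect_lt(abs(mean(a0$p < 0.05) - 0.05), 0.1)
  expect_gt(stats::ks.test(a0$p, "punif")$p.value, 0.001)
  # planted signal: the causal transcript has the smallest p
  y1 <- grex[, 7] + rnorm(n, 0, 0.5)
  a1 <- associate_grex_with_trait(grex, y1)
  expect_equal(which.min(a1$p), 7L)
  # binary phenotype switches to logistic
  yb <- rbinom(n, 1, plogis(grex[, 3]))
  ab <- associate_grex_with_trait(grex, yb)
  expect_equal(which.min(ab$p), 3L)
  # constant GReX skipped with flag
  grex2 <- cbind(grex, const = 1)
  a2 <- associate_grex_with_trait(grex2, y0)
  expect_true(a2$skipped[a2$transcript_id == "const"])
  expect_true(is.na(a2$p[a2$transcript_id == "const"]))
})

test_that("GWAS locus classification partitions loci by hit support", {
  loci <- data.frame(locus_id = sprintf("L%02d", 1:10), chrom = "chr1",
                     start = seq(0, 9e5, 1e5), end = seq(1e5, 1e6, 1e5),
                     mhc = c(rep(FALSE, 9), TRUE))
  # planted assignment: eRNA hits in loci 1-3, gene hits in loci 3-6
  erna <- data.frame(chrom = "chr1", start = c(1e4, 1.2e5, 2.5e5),
                     end = c(1.1e4, 1.3e5, 2.6e5))
  gene <- data.frame(chrom = "chr1",
                     start = c(2.1e5, 3.5e5, 4.5e5, 5.5e5),
                     end = c(2.2e5, 3.6e5, 4.6e5, 5.6e5))
  lab <- classify_gwas_loci(loci, erna, gene)
  expect_equal(nrow(lab), 9)  # MHC locus excluded
  counts <- table(factor(lab$label, c("eRNA-only", "gene-only", "both",
                                      "neither")))
  expect_equal(unname(counts["eRNA-only"]), 2L)  # L1, L2
  expect_equal(unname(counts["gene-only"]), 3L)  # L4, L5, L6
  expect_equal(unname(counts["both"]), 1L)       # L3
  expect_equal(unname(counts["neither"]), 3L)
  expect_equal(sum(counts), 9L)
  # empty hit tables: everything neither
  lab0 <- classify_gwas_loci(loci, erna[0, ], gene[0, ])
  expect_true(all(lab0$label == "neither"))
  # single eRNA hit -> eRNA-only
  lab1 <- classify_gwas_loci(loci[1, ], erna[1, ], gene[0, ],
                             exclude_mhc = FALSE)
  expect_equal(lab1$label, "eRNA-only")
})

test_that("causal tallies reproduce printed fraction arithmetic", {
  t1 <- tally_causal_fraction(392, c(rep(TRUE, 222), rep(FALSE, 170)))
  expect_equal(t1$display_pct, 56.63)
  t2 <- tally_causal_fraction(109, c(rep(TRUE, 14), rep(FALSE, 95)))
  expect_equal(t2$display_pct, 12.84)
  t0 <- tally_causal_fraction(50, rep(FALSE, 50))
  expect_equal(t0$fraction_pct, 0)
  # unique transcript counting from a data.frame input
  assoc <- data.frame(transcript_id = c("a", "a", "b", "c"))
  t3 <- tally_causal_fraction(assoc, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(t3$n_unique_transcripts, 2L)
})

test_that("causal-contact intersection matches a brute-force join", {
  pairs <- data.frame(
    upstream_id = c("e1", "e2", "e3", "g9", "e1"),
    downstream_id = c("g1", "g2", "e4", "e5", "g1"),
    stringsAsFactors = FALSE)
  ce <- c("e1", "e2", "e5", "e6")
  cg <- c("g1", "g3", "g9")
  out <- intersect_causal_contacts(ce, cg, pairs)
  # e1~g1 (twice, deduplicated) and g9~e5
  expect_equal(out$n_pairs, 2)
  expect_setequal(out$contact_free_ernas, c("e2", "e6"))
  expect_setequal(out$contact_free_genes, "g3")
  # disjoint sets with no pairs: all contact-free
  none <- intersect_causal_contacts(c("a"), c("b"), pairs[0, ])
  expect_equal(none$n_pairs, 0)
  expect_equal(none$contact_free_ernas, "a")
  # single joined pair
  one <- intersect_causal_contacts("e1", "g1", pairs)
  expect_equal(one$n_pairs, 1)
  # brute-force oracle on a random 20-transcript instance
  set.seed(5)
  tp <- data.frame(upstream_id = sample(sprintf("t%02d", 1:20), 40,
                                        replace = TRUE),
                   downstream_id = sample(sprintf("t%02d", 1:20), 40,
                                          replace = TRUE))
  ce2 <- sprintf("t%02d", 1:6)
  cg2 <- sprintf("t%02d", 15:20)
  got <- intersect_causal_contacts(ce2, cg2, tp)
  want <- unique(do.call(rbind, lapply(seq_len(nrow(tp)), function(i) {
    u <- tp$upstream_id[i]; d <- tp$downstream_id[i]
    if (u %in% ce2 && d %in% cg2) data.frame(erna = u, gene = d)
    else if (u %in% cg2 && d %in% ce2) data.frame(erna = d, gene = u)
    else NULL
  })))
  expect_equal(got$n_pairs, if (is.null(want)) 0 else nrow(want))
})

test_that("peak overlap fractions count regions with half-open semantics", {
  regions <- data.frame(chrom = "chr1", start = (0:33) * 1000,
                        end = (0:33) * 1000 + 500)
  # peaks overlapping exactly the first 12 regions
  peaks <- data.frame(chrom = "chr1", start = (0:11) * 1000 + 499,
                      end = (0:11) * 1000 + 600)
  out <- peak_overlap_fractions(regions, list(atac = peaks))
  expect_equal(out$per_mark$n_overlapping, 12)
  expect_equal(round(out$per_mark$fraction * 100, 2), 35.29)
  # full coverage and empty set
  all_cov <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  out2 <- peak_overlap_fractions(regions, list(a = all_cov,
                                               b = peaks[0, ]))
  expect_equal(out2$per_mark$fraction, c(1, 0))
  expect_equal(out2$any_of$fraction, 1)
  # composite any-of combines marks
  out3 <- peak_overlap_fractions(regions,
                                 list(a = peaks,
                                      b = data.frame(chrom = "chr1",
                                                     start = 20000,
                                                     end = 20100)))
  expect_equal(out3$any_of$n_overlapping, 13)
})

test_that("eQTL set comparison computes Jaccard and nearest-TSS distances", {
  mk_set <- function(ids) data.frame(variant_id = ids,
                                     significant = TRUE,
                                     stringsAsFactors = FALSE)
  vt <- data.frame(id = letters[1:10], chrom = "chr1",
                   pos = c(100, 900, 2500, 5000, 7000, 10000, 12000,
                           20000, 30000, 40000))
  tss <- data.frame(chrom = "chr1", pos = c(1000, 11000, 29000))
  idn <- eqtl_set_comparison(mk_set(c("a", "b", "c")),
                             mk_set(c("b", "c", "d")), vt, tss)
  expect_equal(idn$jaccard, 0.5)
  same <- eqtl_set_comparison(mk_set(c("a", "b")), mk_set(c("a", "b")),
                              vt, tss)
  expect_equal(same$jaccard, 1)
  # nearest-TSS distances equal a brute-force all-pairs minimum
  ids <- letters[1:10]
  cmp <- eqtl_set_comparison(mk_set(ids[1:5]), mk_set(ids[6:10]), vt, tss)
  brute <- vapply(vt$pos, function(p) min(abs(tss$pos - p)), numeric(1))
  expect_equal(cmp$distances$erna, brute[1:5])
  expect_equal(cmp$distances$gene, brute[6:10])
  expect_equal(cmp$median_distance_erna, median(brute[1:5]))
  expect_true(is.finite(cmp$mannwhitney_p))
  # Jaccard symmetry
  ab <- eqtl_set_comparison(mk_set(c("a", "b", "c")), mk_set(c("c", "d")),
                            vt, tss)
  ba <- eqtl_set_comparison(mk_set(c("c", "d")), mk_set(c("a", "b", "c")),
                            vt, tss)
  expect_equal(ab$jaccard, ba$jaccard)
})

test_that("colocalization tallies respect the inclusive threshold and identities", {
  rec <- data.frame(
    signal_id = c("s1", "s1", "s2", "s3", "s3", "s4"),
    tissue = c("blood", "brain", "blood", "blood", "brain", "blood"),
    eqtl_class = c("eRNA", "canonical", "eRNA", "canonical", "eRNA",
                   "canonical"),
    pp = c(0.9, 0.8, 0.7, 0.2, 0.65, 0.71),
    stringsAsFactors = FALSE)
  out <- coloc_tally(rec)
  # s1 both; s2 eRNA only (pp exactly 0.7 colocalizes); s3 neither;
  # s4 gene only
  expect_equal(out$erna_any, 2)
  expect_equal(out$gene_any, 2)
  expect_equal(out$both, 1)
  expect_equal(out$either, 3)
  expect_equal(out$exclusive_erna, 1)
  # identities hold
  expect_equal(out$either, out$erna_any + out$gene_any - out$both)
  expect_equal(out$exclusive_erna + out$exclusive_gene + out$both,
               out$either)
  # all-zero posterior: all counts zero
  zero <- coloc_tally(transform(rec, pp = 0))
  expect_equal(zero$either, 0)
  # count-level accounting of the printed totals
  s <- coloc_summary(26926, 29669, 8111)
  expect_equal(s$exclusive_erna, 18815)
  expect_equal(s$either, 48484)
  expect_equal(round(s$percent_increase), 63)
})

test_that("transcript length classification uses a strict cutoff", {
  ann <- toy_annotations()
  out <- classify_transcript_lengths(ann, cutoff_bp = 2000)
  expect_equal(out$n_short, 2)  # the two eRNAs (600, 500 bp)
  expect_equal(out$n_long, 2)
  expect_equal(out$pct_short, 50)
  # boundary: lengths equal to the cutoff count as long
  annb <- data.frame(id = "t", class = "eRNA", chrom = "c", start = 0,
                     end = 2000, strand = "+", tss = 0)
  expect_equal(classify_transcript_lengths(annb, 2000)$n_short, 0)
  # strict inequality on a tiny example
  ann3 <- data.frame(id = c("a", "b", "c"), class = "eRNA", chrom = "c",
                     start = 0, end = c(1, 2, 3), strand = "+", tss = 0)
  expect_equal(classify_transcript_lengths(ann3, 2)$n_short, 1)
})
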