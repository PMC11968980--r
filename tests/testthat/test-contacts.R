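test_that("contact matrices canonicalize, round-trip and densify", {
  bins <- data.frame(chrom = "chrS", start = c(0, 1e4, 2e4),
                     end = c(1e4, 2e4, 3e4), bin_id = 0:2)
  # swapped-bin pixel stored once in canonical order
  cm <- contact_matrix(data.frame(bin1_id = 2L, bin2_id = 0L, value = 4),
                       bins, 1e4)
  expect_equal(cm$pixels$bin1_id, 0L)
  expect_equal(cm$pixels$bin2_id, 2L)
  # dense 3x3 symmetric toy: 6 canonical pixels incl. diagonal
  m <- matrix(c(1, 2, 3, 2, 4, 5, 3, 5, 6), 3)
  cm3 <- dense_to_contact_matrix(m, 1e4)
  expect_equal(nrow(cm3$pixels), 6)
  expect_equal(contact_matrix_dense(cm3), m)
  # round trip through cooler-dump and BEDPE text
  dir <- withr::local_tempdir()
  write_contacts_cooler(cm3, file.path(dir, "b.tsv"), file.path(dir, "p.tsv"))
  back <- load_contacts(file.path(dir, "p.tsv"), "cooler",
                        bins_path = file.path(dir, "b.tsv"))
  expect_equal(back$pixels, cm3$pixels)
  write_contacts_bedpe(cm3, file.path(dir, "c.bedpe"))
  back2 <- load_contacts(file.path(dir, "c.bedpe"), "bedpe",
                         resolution = 1e4)
  expect_equal(back2$pixels, cm3$pixels)
  # misaligned BEDPE anchors are rejected with the row named
  writeLines("chrS\t5\t10005\tchrS\t10000\t20000\t1",
             file.path(dir, "bad.bedpe"))
  expect_error(load_contacts(file.path(dir, "bad.bedpe"), "bedpe",
                             resolution = 1e4), "row 1")
})

test_that("ICE balancing equalizes row sums and matches a Sinkhorn oracle", {
  m <- random_dense_contacts(20, seed = 7)
  cm <- dense_to_contact_matrix(m, 1e4)
  ice <- ice_normalize(cm, max_iter = 500L, tol = 1e-12)
  d <- contact_matrix_dense(ice)
  rs <- rowSums(d)
  expect_lt(sd(rs) / mean(rs), 1e-6)
  # independent Sinkhorn oracle agrees up to global scale
  oracle <- sinkhorn_balance(m)
  ratio <- d / oracle
  off <- ratio[upper.tri(ratio)]
  expect_lt(max(off) / min(off) - 1, 1e-5)
  # mean contact preserved
  expect_equal(mean(ice$pixels$value), mean(cm$pixels$value),
               tolerance = 1e-12)
  # idempotence: rerunning ICE changes nothing
  ice2 <- ice_normalize(ice, tol = 1e-10)
  expect_equal(ice2$pixels$value, ice$pixels$value, tolerance = 1e-8)
  # already balanced: a constant symmetric matrix is a fixed point
  flat <- matrix(1, 5, 5)
  icef <- ice_normalize(dense_to_contact_matrix(flat, 1e4))
  expect_equal(contact_matrix_dense(icef), flat, tolerance = 1e-10)
  # 2x2 off-diagonal matrix balances to equal row sums
  two <- ice_normalize(dense_to_contact_matrix(matrix(c(0, 4, 4, 0), 2),
                                               1e4))
  rs2 <- rowSums(contact_matrix_dense(two))
  expect_equal(rs2[1], rs2[2], tolerance = 1e-9)
})

test_that("bin-transcript overlap uses half-open 1 bp semantics", {
  bins <- data.frame(chrom = "chrS", start = c(0, 1e4, 2e4, 3e4),
                     end = c(1e4, 2e4, 3e4, 4e4), bin_id = 0:3)
  cm <- contact_matrix(data.frame(bin1_id = 0L, bin2_id = 1L, value = 1),
                       bins, 1e4)
  ann <- toy_annotations()
  ann <- rbind(ann,
               data.frame(id = c("edge_in", "edge_out", "span3"),
                          class = "eRNA", chrom = "chrS",
                          start = c(19999, 20000, 5000),
                          end = c(21000, 21000, 32000),
                          strand = "+", tss = c(19999, 20000, 5000)))
  class(ann) <- c("transcript_annotation", "data.frame")
  # toy gene_y extends past the 4-bin extent and is clipped
  bm <- suppressWarnings(overlap_bins_with_transcripts(cm, ann))
  # 1 bp overlap into bin [10000,20000) counts; half-open start at 20000
  # does not
  expect_true("edge_in" %in% bm[[2]])
  expect_false("edge_out" %in% bm[[2]])
  # transcript spanning three bins appears in all of them
  expect_true(all(vapply(bm[1:3], function(s) "span3" %in% s, logical(1))))
  # annotation beyond chromosome extent is clipped with a warning
  ann_far <- ann[1, ]
  ann_far$end <- 1e6
  expect_warning(overlap_bins_with_transcripts(cm, ann_far), "clipping")
})

test_that("pair assembly filters classes and matches brute-force enumeration", {
  # hand-built: two eRNAs in bin 0, one gene in bin 2, one gene in bin 3
  bins <- data.frame(chrom = "chrS", start = (0:3) * 1e4,
                     end = (1:4) * 1e4, bin_id = 0:3)
  ann <- data.frame(id = c("e1", "e2", "g1", "g2"),
                    class = c("eRNA", "eRNA", "canonical", "canonical"),
                    chrom = "chrS",
                    start = c(100, 5000, 21000, 31000),
                    end = c(700, 5600, 25000, 39000),
                    strand = "+", stringsAsFactors = FALSE)
  ann$tss <- ann$start
  class(ann) <- c("transcript_annotation", "data.frame")
  px <- data.frame(bin1_id = c(0L, 2L, 0L), bin2_id = c(2L, 3L, 0L),
                   value = c(2, 5, 9))
  cm <- contact_matrix(px, bins, 1e4, normalized = TRUE)
  bm <- overlap_bins_with_transcripts(cm, ann)
  gm <- c(e1 = 0.1, e2 = -0.2, g1 = 0.5, g2 = 1)
  pd <- build_pair_dataset(cm, bm, ann, gm, min_contact = 1)
  # two eRNAs x one gene -> 2 enhancer-gene records; gene-gene pixel
  # contributes none; diagonal pixel excluded
  expect_equal(nrow(pd), 2)
  expect_true(all(pd$pair_class == "enhancer-gene"))
  expect_equal(sort(pd$upstream_id), c("e1", "e2"))
  expect_equal(unique(pd$distance_bp), 2e4)
  expect_equal(unique(pd$log1p_distance), log1p(2e4))
  # unnormalized matrix refused
  raw <- contact_matrix(px, bins, 1e4, normalized = FALSE)
  expect_error(build_pair_dataset(raw, bm, ann, gm), "normalized")

  # randomized instances against the brute-force oracle
  for (seed in 1:3) {
    cfg <- sim_config(n_samples = 20, n_ernas = 30, n_genes = 15,
                      genome_length = 3e5, contact_noise_sd = 1,
                      seed = seed)
    annr <- simulate_annotations(cfg)
    gmr <- stats::setNames(rnorm(nrow(annr)), annr$id)
    # drop some transcripts from the GReX map (non-imputable members)
    gmr <- gmr[-seq(1, length(gmr), by = 7)]
    sim <- simulate_contact_matrix(annr, stats::setNames(rnorm(nrow(annr)),
                                                         annr$id), cfg)
    bmr <- overlap_bins_with_transcripts(sim$contacts, annr)
    got <- build_pair_dataset(sim$contacts, bmr, annr, gmr,
                              min_contact = 1)
    want <- brute_force_pairs(sim$contacts, bmr, annr, gmr,
                              min_contact = 1)
    expect_equal(nrow(got), length(want))
    key <- paste(got$upstream_id, got$downstream_id)
    expect_setequal(key, names(want))
    expect_equal(got$contact,
                 unname(vapply(want[key], `[[`, numeric(1), "contact")))
    # class partition
    expect_equal(sum(table(got$pair_class)), nrow(got))
  }
})

test_that("train/test split sizes follow the floor rule", {
  d <- data.frame(x = seq_len(10))
  sp <- split_train_test(d, fraction = 0.9999, seed = 1)
  expect_equal(nrow(sp$train), 9)  # floor(9.999)
  expect_equal(nrow(sp$test), 1)
  expect_length(intersect(sp$train$x, sp$test$x), 0)
  expect_error(split_train_test(d, fraction = 1), "fraction")
  # seeded split is reproducible
  d2 <- data.frame(x = seq_len(1000))
  a <- split_train_test(d2, 0.8, seed = 5)
  b <- split_train_test(d2, 0.8, seed = 5)
  expect_identical(a$train$x, b$train$x)
})

test_that("strand signal aggregation sums coverage then log1p-transforms", {
  ann <- toy_annotations()
  # zero signal -> all log1p(0) = 0
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0))
  expect_true(all(aggregate_strand_signal(empty, empty, ann) == 0))
  # uniform signal 1.0 over the 600 bp transcript eRNA_a => log1p(600)
  plus <- data.frame(chrom = "chrS", start = 0, end = 5e4, value = 1)
  out <- aggregate_strand_signal(plus, empty, ann)
  expect_equal(unname(out["eRNA_a"]), log1p(600))
  # additivity: split intervals equal one covering interval
  split_bg <- data.frame(chrom = "chrS",
                         start = c(0, 1200, 30000),
                         end = c(1200, 30000, 5e4),
                         value = 1)
  out2 <- aggregate_strand_signal(split_bg, empty, ann)
  expect_equal(out2, out)
  # both strands combine before the transform
  both <- aggregate_strand_signal(plus, plus, ann)
  expect_equal(unname(both["eRNA_a"]), log1p(1200))
  # negative signal rejected
  neg <- data.frame(chrom = "chrS", start = 0, end = 10, value = -1)
  expect_error(aggregate_strand_signal(neg, empty, ann), "negative")
})
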