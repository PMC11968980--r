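#' Bonferroni significance thresholds
#'
#' threshold = alpha / n_tests, further divided by n_traits when a
#' phenome-wide correction across traits applies. The full-precision value
#' is returned together with a 3-significant-digit display string.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests (e.g. transcript-tissue pairs).
#' @param n_traits optional number of traits for the two-level correction.
#' @return a `threshold_spec`: list with alpha, n_tests, n_traits,
#'   threshold, display.
#' @export
bonferroni_thresholds <- function(alpha = 0.05, n_tests, n_traits = NULL) {
  stopifnot(alpha > 0, n_tests >= 1)
  thr <- alpha / n_tests
  if (!is.null(n_traits)) {
    stopifnot(n_traits >= 1)
    thr <- thr / n_traits
  }
  structure(list(alpha = alpha, n_tests = n_tests, n_traits = n_traits,
                 threshold = thr, display = signif(thr, 3)),
            class = "threshold_spec")
}

#' Individual-level GReX-trait association scan
#'
#' Per-transcript regression of the phenotype on imputed GReX with
#' covariates: linear for quantitative phenotypes, logistic for binary.
#' Transcripts with constant GReX are skipped with a flag.
#'
#' @param grex samples x transcripts matrix of imputed GReX.
#' @param phenotype numeric (quantitative) or 0/1 (binary) vector.
#' @param covariates optional samples x k covariate matrix.
#' @param family "auto" detects binary phenotypes; or "gaussian"/"binomial".
#' @return data.frame with transcript_id, beta, z, p, skipped.
#' @export
associate_grex_with_trait <- function(grex, phenotype, covariates = NULL,
                                      family = c("auto", "gaussian",
                                                 "binomial")) {
  family <- match.arg(family)
  stopifnot(nrow(grex) == length(phenotype))
  if (family == "auto")
    family <- if (all(phenotype %in% c(0, 1))) "binomial" else "gaussian"
  ids <- colnames(grex)
  if (is.null(ids)) ids <- sprintf("t%04d", seq_len(ncol(grex)))
  out <- data.frame(transcript_id = ids, beta = NA_real_, z = NA_real_,
                    p = NA_real_, skipped = FALSE, stringsAsFactors = FALSE)
  base <- if (is.null(covariates)) NULL else as.matrix(covariates)
  for (k in seq_len(ncol(grex))) {
    g <- grex[, k]
    if (stats::sd(g) == 0) { out$skipped[k] <- TRUE; next }
    X <- if (is.null(base)) data.frame(g = g) else data.frame(g = g, base)
    fit <- stats::glm(phenotype ~ ., data = X,
                      family = if (family == "binomial")
                        stats::binomial() else stats::gaussian())
    cf <- summary(fit)$coefficients
    out$beta[k] <- cf["g", 1]
    out$z[k] <- cf["g", 3]
    out$p[k] <- if (family == "binomial") cf["g", 4] else
      2 * stats::pnorm(abs(cf["g", 3]), lower.tail = FALSE)
  }
  out
}

#' Classify GWAS loci by eRNA / canonical gene support
#'
#' A TWAS hit is assigned to a locus when its transcript interval
#' intersects the locus interval (at least 1 bp, half-open semantics).
#' Each locus is labeled eRNA-only, gene-only, both, or neither according
#' to the presence of significant eRNA and canonical-gene hits in any
#' tissue; MHC-flagged loci are excluded when requested.
#'
#' @param loci data.frame with locus_id, chrom, start, end and optional
#'   logical mhc column.
#' @param erna_hits,gene_hits data.frames of significant hits with chrom,
#'   start, end (transcript intervals).
#' @param exclude_mhc drop MHC-flagged loci before labeling.
#' @return data.frame with locus_id and label; label counts partition the
#'   retained loci.
#' @export
classify_gwas_loci <- function(loci, erna_hits, gene_hits,
                               exclude_mhc = TRUE) {
  if (exclude_mhc && "mhc" %in% names(loci))
    loci <- loci[!loci$mhc, , drop = FALSE]
  hit_any <- function(hits) {
    if (is.null(hits) || nrow(hits) == 0) return(rep(FALSE, nrow(loci)))
    res <- rep(FALSE, nrow(loci))
    for (ch in unique(loci$chrom)) {
      li <- which(loci$chrom == ch)
      hi <- which(hits$chrom == ch)
      if (length(li) == 0 || length(hi) == 0) next
      q <- IRanges::IRanges(loci$start[li] + 1L, loci$end[li])
      s <- IRanges::IRanges(hits$start[hi] + 1L, hits$end[hi])
      ov <- IRanges::countOverlaps(q, s, minoverlap = 1L)
      res[li] <- ov > 0
    }
    res
  }
  e <- hit_any(erna_hits)
  g <- hit_any(gene_hits)
  label <- ifelse(e & g, "both",
                  ifelse(e, "eRNA-only", ifelse(g, "gene-only", "neither")))
  data.frame(locus_id = loci$locus_id, label = label,
             stringsAsFactors = FALSE)
}

#' Tally the fraction of associations with causal (MR) support
#'
#' @param associations data.frame of significant associations with a
#'   transcript_id column (or a plain count of associations).
#' @param mr_pass logical vector aligned to the associations.
#' @return list with n_total, n_causal, fraction_pct (raw), display_pct
#'   (2 decimals, round-half-even), n_unique_transcripts.
#' @export
tally_causal_fraction <- function(associations, mr_pass) {
  if (is.data.frame(associations)) {
    n <- nrow(associations)
    ids <- associations$transcript_id
  } else {
    n <- as.integer(associations)
    ids <- NULL
  }
  stopifnot(length(mr_pass) == n)
  n_causal <- sum(mr_pass)
  frac <- if (n == 0) 0 else n_causal / n * 100
  list(n_total = n, n_causal = n_causal,
       fraction_pct = frac,
       display_pct = round(frac, 2),
       n_unique_transcripts = if (is.null(ids)) NA_integer_ else
         length(unique(ids[mr_pass])))
}

#' Intersect causal eRNAs and causal genes through contact pairs
#'
#' Partitions MR-causal transcripts by whether any contact-pair row joins
#' a causal eRNA with a causal canonical gene.
#'
#' @param causal_ernas,causal_genes character vectors of transcript ids.
#' @param pairs a `pair_dataset`.
#' @return list with in_contact_pairs (data.frame of unique joined pairs),
#'   n_pairs, contact_free_ernas, contact_free_genes.
#' @export
intersect_causal_contacts <- function(causal_ernas, causal_genes, pairs) {
  joined <- pairs[(pairs$upstream_id %in% causal_ernas &
                     pairs$downstream_id %in% causal_genes) |
                    (pairs$upstream_id %in% causal_genes &
                       pairs$downstream_id %in% causal_ernas), ,
                  drop = FALSE]
  key <- unique(data.frame(
    erna = ifelse(joined$upstream_id %in% causal_ernas,
                  joined$upstream_id, joined$downstream_id),
    gene = ifelse(joined$upstream_id %in% causal_genes,
                  joined$upstream_id, joined$downstream_id),
    stringsAsFactors = FALSE))
  in_contact_e <- unique(key$erna)
  in_contact_g <- unique(key$gene)
  list(in_contact_pairs = key,
       n_pairs = nrow(key),
       contact_free_ernas = setdiff(causal_ernas, in_contact_e),
       contact_free_genes = setdiff(causal_genes, in_contact_g))
}

#' Fraction of regions overlapping epigenomic peaks
#'
#' For each named peak set, counts regions overlapping at least one peak
#' (>= 1 bp, half-open semantics) and reports the fraction, plus a
#' composite any-of-marks fraction.
#'
#' @param regions data.frame with chrom, start, end (0-based half-open).
#' @param peak_sets named list of data.frames with chrom, start, end.
#' @return list with per_mark (data.frame: mark, n_overlapping, fraction)
#'   and any_of (n_overlapping, fraction).
#' @export
peak_overlap_fractions <- function(regions, peak_sets) {
  n <- nrow(regions)
  overlap_vec <- function(peaks) {
    if (is.null(peaks) || nrow(peaks) == 0) return(rep(FALSE, n))
    res <- rep(FALSE, n)
    for (ch in unique(regions$chrom)) {
      ri <- which(regions$chrom == ch)
      pi <- which(peaks$chrom == ch)
      if (length(ri) == 0 || length(pi) == 0) next
      q <- IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri])
      s <- IRanges::IRanges(peaks$start[pi] + 1L, peaks$end[pi])
      res[ri] <- IRanges::countOverlaps(q, s, minoverlap = 1L) > 0
    }
    res
  }
  marks <- lapply(peak_sets, overlap_vec)
  per_mark <- data.frame(mark = names(peak_sets),
                         n_overlapping = vapply(marks, sum, numeric(1)),
                         fraction = vapply(marks, mean, numeric(1)),
                         stringsAsFactors = FALSE, row.names = NULL)
  any_of <- Reduce(`|`, marks, rep(FALSE, n))
  list(per_mark = per_mark,
       any_of = list(n_overlapping = sum(any_of), fraction = mean(any_of)))
}

#' Compare eRNA and canonical gene eQTL sets
#'
#' Jaccard index over variant-id sets, per-class distances to the nearest
#' TSS (absolute bp, same chromosome), class-wise median distances, and a
#' two-sided Mann-Whitney U test of the distance distributions.
#'
#' @param erna_eqtls,gene_eqtls `eqtl_set` data.frames (or any with
#'   variant_id and significant columns; only significant rows are used
#'   when the column is present).
#' @param variant_table data.frame with id, chrom, pos for every variant.
#' @param tss_table data.frame with chrom, pos of transcription start sites.
#' @return an `eqtl_comparison` list: jaccard, median_distance_erna,
#'   median_distance_gene, mannwhitney_p, distances (per class).
#' @export
eqtl_set_comparison <- function(erna_eqtls, gene_eqtls, variant_table,
                                tss_table) {
  sig_ids <- function(x) {
    if ("significant" %in% names(x)) x <- x[x$significant, , drop = FALSE]
    unique(x$variant_id)
  }
  a <- sig_ids(erna_eqtls)
  b <- sig_ids(gene_eqtls)
  uni <- union(a, b)
  jac <- if (length(uni) == 0) NA_real_ else
    length(intersect(a, b)) / length(uni)
  nearest <- function(ids) {
    vt <- variant_table[match(ids, variant_table$id), , drop = FALSE]
    vapply(seq_len(nrow(vt)), function(k) {
      tpos <- tss_table$pos[tss_table$chrom == vt$chrom[k]]
      if (length(tpos) == 0) return(NA_real_)
      min(abs(tpos - vt$pos[k]))
    }, numeric(1))
  }
  d_a <- nearest(a)
  d_b <- nearest(b)
  mw <- if (length(d_a) >= 1 && length(d_b) >= 1)
    stats::wilcox.test(d_a, d_b, exact = FALSE)$p.value else NA_real_
  structure(list(jaccard = jac,
                 median_distance_erna = stats::median(d_a, na.rm = TRUE),
                 median_distance_gene = stats::median(d_b, na.rm = TRUE),
                 mannwhitney_p = mw,
                 distances = list(erna = d_a, gene = d_b)),
            class = "eqtl_comparison")
}

#' Tally colocalization of GWAS signals with eQTL classes
#'
#' A signal colocalizes with an eQTL class when its posterior probability
#' reaches the threshold (inclusive) in at least one tissue. Summary
#' counts follow the accounting identities either = eRNA-any + gene-any -
#' both and exclusive-eRNA + exclusive-gene + both = either; the percent
#' increase is exclusive-eRNA / gene-any x 100.
#'
#' @param records data.frame with signal_id, tissue, eqtl_class
#'   ("eRNA"/"canonical") and pp (posterior probability in \[0, 1\]).
#' @param pp_threshold inclusive colocalization threshold (default 0.7).
#' @return list with per_signal flags and the summary counts: erna_any,
#'   gene_any, both, either, exclusive_erna, exclusive_gene,
#'   percent_increase.
#' @export
coloc_tally <- function(records, pp_threshold = 0.7) {
  stopifnot(all(records$pp >= 0 & records$pp <= 1))
  hit <- records$pp >= pp_threshold
  sig <- unique(records$signal_id)
  e_hit <- unique(records$signal_id[hit & records$eqtl_class == "eRNA"])
  g_hit <- unique(records$signal_id[hit & records$eqtl_class == "canonical"])
  per_signal <- data.frame(signal_id = sig,
                           erna = sig %in% e_hit,
                           gene = sig %in% g_hit,
                           stringsAsFactors = FALSE)
  coloc_summary(length(e_hit), length(g_hit),
                length(intersect(e_hit, g_hit)), per_signal = per_signal)
}

#' Colocalization summary from class counts
#'
#' The same accounting as [coloc_tally()], starting from the three counts.
#'
#' @param erna_any signals colocalizing with an eRNA eQTL in any tissue.
#' @param gene_any signals colocalizing with a canonical-gene eQTL.
#' @param both signals colocalizing with both classes.
#' @param per_signal optional per-signal flag table to attach.
#' @return list of counts and percent_increase (raw percent).
#' @export
coloc_summary <- function(erna_any, gene_any, both, per_signal = NULL) {
  stopifnot(both <= erna_any, both <= gene_any)
  either <- erna_any + gene_any - both
  excl_e <- erna_any - both
  excl_g <- gene_any - both
  list(per_signal = per_signal,
       erna_any = erna_any, gene_any = gene_any, both = both,
       either = either,
       exclusive_erna = excl_e, exclusive_gene = excl_g,
       percent_increase = if (gene_any == 0) NA_real_ else
         excl_e / gene_any * 100)
}

#' Classify transcripts by length cutoff
#'
#' Counts transcripts strictly below the cutoff versus at/above it; the
#' short class matches the profile of 2D enhancer RNAs (short, unspliced).
#'
#' @param annotations a `transcript_annotation` data.frame (lengths are
#'   end - start).
#' @param cutoff_bp length cutoff (default 2000).
#' @return list with n_short, n_long, pct_short, pct_long (raw), display
#'   percentages (2 decimals, round-half-even), median_length.
#' @export
classify_transcript_lengths <- function(annotations, cutoff_bp = 2000) {
  stopifnot(nrow(annotations) >= 1)
  len <- annotations$end - annotations$start
  n_short <- sum(len < cutoff_bp)
  n_long <- sum(len >= cutoff_bp)
  pct_short <- n_short / length(len) * 100
  list(n_short = n_short, n_long = n_long,
       pct_short = pct_short, pct_long = 100 - pct_short,
       display_pct_short = round(pct_short, 2),
       display_pct_long = round(100 - pct_short, 2),
       median_length = stats::median(len))
}
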