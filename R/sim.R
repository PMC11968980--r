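#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cohort: genotypes, transcript
#' annotations (enhancer RNAs vs canonical genes), cis-genetic expression
#' architecture, and the binned contact matrix with its planted
#' GReX-dependent link. Defaults emulate the regulatory architecture the
#' pipeline assumes: eRNAs are short (median ~550 bp, >90% under 2 kb) with
#' more, smaller-effect cis SNPs than canonical genes (2:1 SNP ratio), and
#' contact frequency decays with genomic distance on top of a smooth
#' non-linear dependence on pairwise mean GReX.
#'
#' @param n_samples number of diploid individuals.
#' @param n_variants_per_window biallelic variants per 100 kb of genome.
#' @param maf_range minor allele frequency range, within (0, 0.5].
#' @param n_ernas,n_genes number of eRNA / canonical gene transcripts.
#' @param genome_length simulated chromosome length in bp.
#' @param bin_resolution contact matrix bin size in bp (default 10 kb).
#' @param heritability_range range of per-transcript cis heritabilities in
#'   \[0, 1\]; each transcript's h2 is drawn uniformly from it.
#' @param erna_snps_per_transcript_mean,gene_snps_per_transcript_mean mean
#'   number of causal cis SNPs per transcript (Poisson, at least 1).
#' @param cis_window_bp half-width of the simulated cis window around the TSS
#'   from which causal SNPs are drawn.
#' @param contact_noise_sd standard deviation of the additive contact noise
#'   (truncated so contacts stay nonnegative).
#' @param distance_decay_rate exponential decay rate of contact with distance,
#'   per bp.
#' @param distance_decay_scale multiplier of the decay term; set to 0 to
#'   isolate the planted GReX link.
#' @param planted_link_strength multiplier of the planted non-linear link
#'   between pairwise GReX and contact frequency; 0 plants no link.
#' @param link_family one of "saturating_product" (default; tanh(u) tanh(v)),
#'   "bilinear" (u v) or "radial_bump" (exp(-(u^2+v^2)/2)).
#' @param chrom chromosome name used throughout the fixture set.
#' @param seed integer seed; every simulation draw derives from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 500,
                       n_variants_per_window = 30,
                       maf_range = c(0.05, 0.5),
                       n_ernas = 60,
                       n_genes = 40,
                       genome_length = 2e6,
                       bin_resolution = 1e4,
                       heritability_range = c(0.05, 0.6),
                       erna_snps_per_transcript_mean = 8,
                       gene_snps_per_transcript_mean = 4,
                       cis_window_bp = 1e5,
                       contact_noise_sd = 0.5,
                       distance_decay_rate = 1e-5,
                       distance_decay_scale = 3,
                       planted_link_strength = 1,
                       link_family = c("saturating_product", "bilinear",
                                       "radial_bump"),
                       chrom = "chrS",
                       seed = 1L) {
  link_family <- match.arg(link_family)
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants_per_window = as.integer(n_variants_per_window),
              maf_range = as.numeric(maf_range),
              n_ernas = as.integer(n_ernas),
              n_genes = as.integer(n_genes),
              genome_length = as.numeric(genome_length),
              bin_resolution = as.numeric(bin_resolution),
              heritability_range = as.numeric(heritability_range),
              erna_snps_per_transcript_mean = as.numeric(erna_snps_per_transcript_mean),
              gene_snps_per_transcript_mean = as.numeric(gene_snps_per_transcript_mean),
              cis_window_bp = as.numeric(cis_window_bp),
              contact_noise_sd = as.numeric(contact_noise_sd),
              distance_decay_rate = as.numeric(distance_decay_rate),
              distance_decay_scale = as.numeric(distance_decay_scale),
              planted_link_strength = as.numeric(planted_link_strength),
              link_family = link_family,
              chrom = as.character(chrom),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$maf_range) == 2, length(cfg$heritability_range) == 2)
  if (cfg$n_samples < 1L)
    stop("n_samples must be positive", call. = FALSE)
  if (cfg$n_variants_per_window < 1L)
    stop("n_variants_per_window must be positive", call. = FALSE)
  if (cfg$n_ernas < 1L || cfg$n_genes < 0L)
    stop("transcript counts must be positive", call. = FALSE)
  if (any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5) ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must be an increasing pair within (0, 0.5]",
         call. = FALSE)
  if (any(cfg$heritability_range < 0) || any(cfg$heritability_range > 1) ||
      cfg$heritability_range[1] > cfg$heritability_range[2])
    stop("heritability_range must be an increasing pair within [0, 1]",
         call. = FALSE)
  if (cfg$contact_noise_sd < 0)
    stop("contact_noise_sd must be nonnegative", call. = FALSE)
  if (cfg$distance_decay_rate <= 0)
    stop("distance_decay_rate must be positive", call. = FALSE)
  if (cfg$genome_length < cfg$bin_resolution)
    stop("genome_length must cover at least one bin", call. = FALSE)
  invisible(cfg)
}

#' Planted link functions
#'
#' Smooth non-linear functions of the mean GReX of the two bins of a contact
#' pair, used to plant a known dependence of contact frequency on expression.
#' The saturating product is the default family: it is bounded, smooth, and
#' orthogonal to linear trends when the GReX inputs are symmetric about zero,
#' so a plain linear regression on the features recovers essentially nothing.
#'
#' @param family link family name (see [sim_config()]).
#' @return a vectorized function f(u, v).
#' @export
planted_link_function <- function(family = c("saturating_product", "bilinear",
                                             "radial_bump")) {
  family <- match.arg(family)
  switch(family,
         saturating_product = function(u, v) tanh(u) * tanh(v),
         bilinear = function(u, v) u * v,
         radial_bump = function(u, v) exp(-(u^2 + v^2) / 2))
}

#' Simulate a genotype dosage matrix
#'
#' Draws independent biallelic variants with MAF uniform over
#' `config$maf_range` and dosages Binomial(2, maf) per individual.
#'
#' @param config a [sim_config()].
#' @return a `genotype_matrix`: list with `dosage` (samples x variants,
#'   entries 0/1/2) and `variants` (data.frame chrom/pos/id/maf, 1-based pos).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_var <- max(1L, as.integer(ceiling(config$genome_length / 1e5) *
                                config$n_variants_per_window))
  pos <- sort(sample.int(config$genome_length, n_var, replace = FALSE))
  maf <- stats::runif(n_var, config$maf_range[1], config$maf_range[2])
  dosage <- vapply(seq_len(n_var),
                   function(j) stats::rbinom(config$n_samples, 2L, maf[j]),
                   integer(config$n_samples))
  dosage <- matrix(dosage, nrow = config$n_samples)
  ids <- sprintf("snp_%05d", seq_len(n_var))
  colnames(dosage) <- ids
  rownames(dosage) <- sprintf("sample_%04d", seq_len(config$n_samples))
  genotype_matrix(dosage,
                  data.frame(chrom = config$chrom, pos = pos, id = ids,
                             maf = maf, stringsAsFactors = FALSE))
}

#' Construct a genotype matrix container
#'
#' @param dosage samples x variants numeric matrix with values in \[0, 2\];
#'   missing entries are mean-imputed per variant.
#' @param variants data.frame with columns chrom, pos (1-based), id, maf.
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), ncol(dosage) == nrow(variants))
  if (anyNA(dosage)) {
    for (j in which(colSums(is.na(dosage)) > 0)) {
      m <- mean(dosage[, j], na.rm = TRUE)
      dosage[is.na(dosage[, j]), j] <- m
    }
  }
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' Simulate transcript annotations
#'
#' Places eRNA and canonical gene transcripts on the synthetic chromosome in
#' 0-based half-open coordinates. eRNA lengths are log-normal with median
#' 550 bp and ~94% below 2 kb, matching the short, unspliced profile of 2D
#' enhancer RNAs; canonical genes are log-normal around 20 kb. Strands are
#' assigned at random and the TSS is the strand-aware 5' end.
#'
#' @param config a [sim_config()].
#' @return a data.frame of class `transcript_annotation` with columns
#'   id, class ("eRNA"/"canonical"), chrom, start, end, strand, tss.
#' @export
simulate_annotations <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_ernas + config$n_genes
  erna_len <- pmax(50, round(stats::rlnorm(config$n_ernas,
                                           meanlog = log(550), sdlog = 0.8)))
  gene_len <- pmax(200, round(stats::rlnorm(config$n_genes,
                                            meanlog = log(2e4), sdlog = 0.8)))
  len <- c(erna_len, gene_len)
  len <- pmin(len, config$genome_length - 1)
  if (max(len) >= config$genome_length)
    stop("genome_length cannot accommodate the requested transcripts",
         call. = FALSE)
  start <- vapply(len, function(l)
    sample.int(config$genome_length - l, 1L) - 1L, numeric(1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ann <- data.frame(
    id = c(sprintf("eRNA_%04d", seq_len(config$n_ernas)),
           sprintf("gene_%04d", seq_len(config$n_genes))),
    class = rep(c("eRNA", "canonical"), c(config$n_ernas, config$n_genes)),
    chrom = config$chrom,
    start = start,
    end = start + len,
    strand = strand,
    stringsAsFactors = FALSE)
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  class(ann) <- c("transcript_annotation", "data.frame")
  ann
}

#' Simulate expression with a known cis-genetic architecture
#'
#' For each transcript, draws a sparse causal SNP set within the cis window
#' around the TSS (eRNAs receive more, smaller-effect SNPs than genes),
#' forms the genetic value G beta, and adds Gaussian noise scaled so the
#' realized variance ratio var(G beta) / var(expression) equals the sampled
#' heritability. Optional age/sex-like covariates with known coefficients
#' are appended so covariate residualization is verifiable downstream.
#'
#' @param genotypes a `genotype_matrix`.
#' @param annotations a `transcript_annotation` data.frame.
#' @param config a [sim_config()].
#' @param add_covariates add age/sex analogues with known coefficients.
#' @return list with `expression` (an `expression_matrix`: values samples x
#'   transcripts plus covariates) and `truth` (per-transcript effect vectors,
#'   heritabilities, genetic values, covariate coefficients).
#' @export
simulate_expression <- function(genotypes, annotations, config,
                                add_covariates = FALSE) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  G <- genotypes$dosage
  n <- nrow(G)
  vt <- genotypes$variants
  nt <- nrow(annotations)
  h2 <- stats::runif(nt, config$heritability_range[1],
                     config$heritability_range[2])
  values <- matrix(0, n, nt, dimnames = list(rownames(G), annotations$id))
  effects <- vector("list", nt)
  names(effects) <- annotations$id
  genetic <- matrix(0, n, nt, dimnames = dimnames(values))
  flagged <- character(0)
  for (k in seq_len(nt)) {
    tss <- annotations$tss[k]
    cis <- which(vt$chrom == annotations$chrom[k] &
                   vt$pos >= tss - config$cis_window_bp &
                   vt$pos <= tss + config$cis_window_bp)
    if (length(cis) == 0L) {
      flagged <- c(flagged, annotations$id[k])
      values[, k] <- stats::rnorm(n)
      effects[[k]] <- numeric(0)
      next
    }
    is_erna <- annotations$class[k] == "eRNA"
    mu <- if (is_erna) config$erna_snps_per_transcript_mean else
      config$gene_snps_per_transcript_mean
    n_causal <- min(length(cis), 1L + stats::rpois(1L, max(mu - 1, 0)))
    causal <- sample(cis, n_causal)
    eff_sd <- if (is_erna) 0.15 else 0.4
    beta <- stats::rnorm(n_causal, 0, eff_sd)
    g <- as.vector(G[, causal, drop = FALSE] %*% beta)
    vg <- stats::var(g)
    if (h2[k] == 0 || vg == 0) {
      beta <- rep(0, n_causal)
      g <- rep(0, n)
      e <- stats::rnorm(n)
    } else {
      # noise scaled to the realized genetic variance so the sample
      # variance ratio matches the target heritability
      e <- stats::rnorm(n)
      e <- (e - mean(e)) / stats::sd(e) * sqrt(vg * (1 - h2[k]) / h2[k])
    }
    values[, k] <- g + e
    genetic[, k] <- g
    effects[[k]] <- stats::setNames(beta, vt$id[causal])
  }
  covariates <- NULL
  cov_coef <- NULL
  if (add_covariates) {
    covariates <- cbind(age = stats::rnorm(n, 50, 15),
                        sex = stats::rbinom(n, 1L, 0.5))
    rownames(covariates) <- rownames(G)
    cov_coef <- matrix(stats::rnorm(2L * nt, 0, 0.02), 2L, nt,
                       dimnames = list(c("age", "sex"), annotations$id))
    values <- values + covariates %*% cov_coef
  }
  expr <- expression_matrix(values, covariates)
  truth <- list(effects = effects, heritability = stats::setNames(h2, annotations$id),
                genetic_values = genetic, covariate_coefficients = cov_coef,
                untrainable = flagged)
  list(expression = expr, truth = truth)
}

#' Construct an expression matrix container
#'
#' @param values samples x transcripts numeric matrix.
#' @param covariates optional samples x k covariate matrix (aligned rows).
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, covariates = NULL) {
  stopifnot(is.matrix(values))
  if (!is.null(covariates))
    stopifnot(nrow(covariates) == nrow(values))
  structure(list(values = values, covariates = covariates),
            class = "expression_matrix")
}

#' Simulate a binned contact matrix with a planted GReX link
#'
#' Builds a symmetric nonnegative contact matrix over genome bins at the
#' configured resolution. The expected contact for bin pair (i, j) is
#' `decay_scale * exp(-decay_rate * d) + link_strength * f(g_i, g_j)` where
#' d is the bin-start distance in bp, g_i is the mean GReX of transcripts
#' overlapping bin i, and f is the planted link function; truncated-at-zero
#' Gaussian noise is added on top. Bins without overlapping transcripts
#' contribute no link term. The noiseless surface is returned as truth.
#'
#' @param annotations a `transcript_annotation` data.frame.
#' @param grex_means named per-transcript mean GReX vector covering all
#'   annotated transcripts.
#' @param config a [sim_config()].
#' @return list with `contacts` (a `contact_matrix`, see
#'   [contact_matrix()]) and `truth` (noiseless pixel values, link family
#'   and strength, per-bin mean GReX).
#' @export
simulate_contact_matrix <- function(annotations, grex_means, config) {
  validate_sim_config(config)
  missing_t <- setdiff(annotations$id, names(grex_means))
  if (length(missing_t) > 0)
    stop("grex_means missing transcripts: ",
         paste(utils::head(missing_t, 3), collapse = ", "), call. = FALSE)
  set.seed(config$seed + 3L)
  res <- config$bin_resolution
  if (config$genome_length %% res != 0)
    warning("bin_resolution does not divide genome_length; ",
            "last partial bin retained")
  n_bins <- as.integer(ceiling(config$genome_length / res))
  bins <- data.frame(chrom = config$chrom,
                     start = (seq_len(n_bins) - 1) * res,
                     end = pmin(seq_len(n_bins) * res, config$genome_length),
                     bin_id = seq_len(n_bins) - 1L)
  bin_map <- overlap_bins_with_annotations(bins, annotations)
  g_bin <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    ids <- bin_map[[b]]
    if (length(ids) > 0) g_bin[b] <- mean(grex_means[ids])
  }
  f <- planted_link_function(config$link_family)
  idx <- which(upper.tri(matrix(0, n_bins, n_bins), diag = TRUE),
               arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d <- (j - i) * res
  decay <- config$distance_decay_scale * exp(-config$distance_decay_rate * d)
  link <- ifelse(is.na(g_bin[i]) | is.na(g_bin[j]), 0,
                 config$planted_link_strength * f(g_bin[i], g_bin[j]))
  noiseless <- pmax(decay + link, 0)
  eps <- if (config$contact_noise_sd > 0)
    stats::rnorm(length(noiseless), 0, config$contact_noise_sd) else 0
  value <- pmax(noiseless + eps, 0)
  pixels <- data.frame(bin1_id = i - 1L, bin2_id = j - 1L, value = value)
  pixels <- pixels[pixels$value > 0, ]
  cm <- contact_matrix(pixels, bins, resolution = res, normalized = TRUE)
  truth <- list(noiseless = data.frame(bin1_id = i - 1L, bin2_id = j - 1L,
                                       value = noiseless),
                link_family = config$link_family,
                link_strength = config$planted_link_strength,
                bin_grex = g_bin)
  list(contacts = cm, truth = truth)
}

# bin -> transcript id map on 0-based half-open intervals (>=1 bp overlap)
overlap_bins_with_annotations <- function(bins, annotations) {
  out <- vector("list", nrow(bins))
  if (nrow(annotations) == 0) return(out)
  by_chrom <- split(seq_len(nrow(annotations)), annotations$chrom)
  for (ch in names(by_chrom)) {
    bsel <- which(bins$chrom == ch)
    if (length(bsel) == 0) next
    ai <- by_chrom[[ch]]
    q <- IRanges::IRanges(start = bins$start[bsel] + 1L, end = bins$end[bsel])
    s <- IRanges::IRanges(start = annotations$start[ai] + 1L,
                          end = annotations$end[ai])
    hits <- IRanges::findOverlaps(q, s, minoverlap = 1L)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (k in seq_along(qh)) {
      b <- bsel[qh[k]]
      out[[b]] <- c(out[[b]], annotations$id[ai[sh[k]]])
    }
  }
  out
}

#' Simulate a ready-made contact pair dataset
#'
#' Convenience generator for benchmarking the contact-frequency models in
#' isolation: draws standard-normal GReX features for upstream and
#' downstream transcripts, applies the planted link plus Gaussian noise,
#' and packages the rows as a pair dataset. The noiseless R-squared ceiling
#' Var(f) / Var(f + noise) attainable by any regression on the two GReX
#' features is returned alongside.
#'
#' @param n_pairs number of contact pairs.
#' @param link_strength multiplier of the planted link.
#' @param link_family link family (see [sim_config()]).
#' @param noise_sd contact noise standard deviation.
#' @param baseline additive constant keeping contacts positive.
#' @param seed integer seed.
#' @return list with `pairs` (a `pair_dataset`), `ceiling` (noiseless
#'   R-squared ceiling estimated on the drawn sample) and `truth`
#'   (noiseless contact values).
#' @export
simulate_pair_dataset <- function(n_pairs = 20000, link_strength = 3,
                                  link_family = "saturating_product",
                                  noise_sd = 1, baseline = 5, seed = 1L) {
  set.seed(seed)
  f <- planted_link_function(link_family)
  g_up <- stats::rnorm(n_pairs)
  g_down <- stats::rnorm(n_pairs)
  signal <- baseline + link_strength * f(g_up, g_down)
  eps <- stats::rnorm(n_pairs, 0, noise_sd)
  y <- pmax(signal + eps, 1e-3)
  dist_bp <- sample(seq(1e4, 2e6, by = 1e4), n_pairs, replace = TRUE)
  cls <- sample(c("enhancer-gene", "gene-enhancer", "enhancer-enhancer"),
                n_pairs, replace = TRUE, prob = c(0.47, 0.5, 0.03))
  pairs <- data.frame(
    upstream_id = sprintf("up_%06d", seq_len(n_pairs)),
    downstream_id = sprintf("dn_%06d", seq_len(n_pairs)),
    pair_class = cls,
    grex_up = g_up, grex_down = g_down,
    distance_bp = dist_bp, log1p_distance = log1p(dist_bp),
    contact = y, stringsAsFactors = FALSE)
  class(pairs) <- c("pair_dataset", "data.frame")
  attr(pairs, "provenance") <- list(tissue = "synthetic",
                                    link_family = link_family)
  ceiling_r2 <- stats::var(signal) / stats::var(y)
  list(pairs = pairs, ceiling = ceiling_r2, truth = signal)
}

#' Write the synthetic fixture set to plain-text files
#'
#' Writes BED for annotations, a dosage matrix TSV plus variant table,
#' an expression TSV, the contact matrix in both cooler-dump style
#' (bin + pixel tables) and BEDPE, and optional strand bedGraphs.
#' All files round-trip through the package readers.
#'
#' @param dir output directory (created if needed).
#' @param annotations,genotypes,expression,contacts components to write;
#'   any may be NULL to skip.
#' @return invisibly, the named vector of written paths.
#' @export
write_fixtures <- function(dir, annotations = NULL, genotypes = NULL,
                           expression = NULL, contacts = NULL) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  paths <- character(0)
  if (!is.null(annotations)) {
    p <- file.path(dir, "annotations.bed")
    write_annotation_bed(annotations, p)
    paths["annotations"] <- p
  }
  if (!is.null(genotypes)) {
    pd <- file.path(dir, "dosage.tsv")
    pv <- file.path(dir, "variants.tsv")
    data.table::fwrite(data.table::as.data.table(genotypes$dosage,
                                                 keep.rownames = "sample"),
                       pd, sep = "\t")
    data.table::fwrite(genotypes$variants, pv, sep = "\t")
    paths["dosage"] <- pd; paths["variants"] <- pv
  }
  if (!is.null(expression)) {
    pe <- file.path(dir, "expression.tsv")
    data.table::fwrite(data.table::as.data.table(expression$values,
                                                 keep.rownames = "sample"),
                       pe, sep = "\t")
    paths["expression"] <- pe
  }
  if (!is.null(contacts)) {
    pb <- file.path(dir, "bins.tsv")
    pp <- file.path(dir, "pixels.tsv")
    write_contacts_cooler(contacts, bins_path = pb, pixels_path = pp)
    pe2 <- file.path(dir, "contacts.bedpe")
    write_contacts_bedpe(contacts, pe2)
    paths["bins"] <- pb; paths["pixels"] <- pp; paths["bedpe"] <- pe2
  }
  invisible(paths)
}

#' Write transcript annotations as BED
#'
#' Six-column BED (0-based half-open), with the transcript class in the
#' score slot's place left at 0 and carried in the name as `id|class`.
#' @param annotations a `transcript_annotation` data.frame.
#' @param path output file.
#' @export
write_annotation_bed <- function(annotations, path) {
  bed <- data.frame(chrom = annotations$chrom,
                    start = as.integer(annotations$start),
                    end = as.integer(annotations$end),
                    name = if (nrow(annotations)) paste(annotations$id,
                                                        annotations$class,
                                                        sep = "|")
                           else character(0),
                    score = integer(nrow(annotations)),
                    strand = annotations$strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read transcript annotations from BED
#'
#' Inverse of [write_annotation_bed()]; also accepts plain 6-column BED in
#' which case every transcript is classed "canonical".
#' @param path BED file.
#' @return a `transcript_annotation` data.frame.
#' @export
read_annotation_bed <- function(path) {
  bed <- if (file.size(path) == 0) data.frame() else
    data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (nrow(bed) == 0) {
    ann <- data.frame(id = character(0), class = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      tss = numeric(0), stringsAsFactors = FALSE)
    class(ann) <- c("transcript_annotation", "data.frame")
    return(ann)
  }
  nm <- strsplit(as.character(bed[[4]]), "|", fixed = TRUE)
  id <- vapply(nm, `[`, character(1), 1L)
  cls <- vapply(nm, function(x) if (length(x) > 1) x[2] else "canonical",
                character(1))
  strand <- if (ncol(bed) >= 6) as.character(bed[[6]]) else "+"
  ann <- data.frame(id = id, class = cls, chrom = as.character(bed[[1]]),
                    start = bed[[2]], end = bed[[3]], strand = strand,
                    stringsAsFactors = FALSE)
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  class(ann) <- c("transcript_annotation", "data.frame")
  ann
}
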