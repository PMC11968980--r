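#' Residualize expression on covariates
#'
#' Per-transcript ordinary least squares of expression on the covariate
#' matrix (an intercept is always included); returns the residuals.
#' Collinear covariate columns are dropped with a warning. Residuals are
#' orthogonal to every retained covariate column.
#'
#' @param expr an `expression_matrix` or plain samples x transcripts matrix.
#' @param covariates samples x k numeric covariate matrix; NULL or
#'   zero-column input mean-centers each transcript.
#' @return an `expression_matrix` of residuals (covariates slot cleared).
#' @export
residualize_expression <- function(expr, covariates = NULL) {
  values <- if (inherits(expr, "expression_matrix")) expr$values else expr
  if (is.null(covariates) && inherits(expr, "expression_matrix"))
    covariates <- expr$covariates
  n <- nrow(values)
  X <- cbind(intercept = rep(1, n), covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]
    warning("dropping ", length(drop_cols),
            " collinear covariate column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  resid <- values - X %*% qr.coef(qrX, values)
  dimnames(resid) <- dimnames(values)
  expression_matrix(resid, covariates = NULL)
}

#' Train an elastic-net cis model of transcript expression
#'
#' Regresses residualized expression on cis dosages (variants within
#' `window_bp` of the TSS) with an elastic net at mixing parameter 0.5 and
#' the penalty chosen by inner cross-validation. Cross-validated
#' performance uses nested CV: out-of-fold predictions from `cv_folds`
#' outer folds (each refitting the penalty on its training part) are
#' correlated with the observed expression; `cv_r2` is the squared Pearson
#' correlation and `cv_pvalue` the one-sided (positive association)
#' correlation test p-value. A transcript is imputable when cv_r2 > 0 and
#' cv_pvalue < 0.05. Transcripts with an empty cis window are returned
#' untrainable (and count against the imputable denominator downstream).
#'
#' @param genos a `genotype_matrix`.
#' @param expr an `expression_matrix` of residualized expression.
#' @param annotation one row of a `transcript_annotation` data.frame.
#' @param window_bp cis half-window around the TSS (default 1 Mb).
#' @param cv_folds outer CV folds for performance estimation.
#' @param seed integer seed controlling the fold assignment.
#' @return a `grex_model`: list with transcript_id, weights (named, only
#'   nonzero), cv_r2, cv_pvalue, n_snps, imputable, trainable.
#' @export
train_cis_elastic_net <- function(genos, expr, annotation,
                                  window_bp = 1e6, cv_folds = 5L,
                                  seed = 1L) {
  tid <- annotation$id
  y <- expr$values[, tid]
  vt <- genos$variants
  cis <- which(vt$chrom == annotation$chrom &
                 vt$pos >= annotation$tss - window_bp &
                 vt$pos <= annotation$tss + window_bp)
  if (length(cis) == 0L) {
    return(structure(list(transcript_id = tid, weights = numeric(0),
                          cv_r2 = NA_real_, cv_pvalue = NA_real_,
                          n_snps = 0L, imputable = FALSE, trainable = FALSE),
                     class = "grex_model"))
  }
  X <- genos$dosage[, cis, drop = FALSE]
  n <- length(y)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(cv_folds), n))
  oof <- rep(NA_real_, n)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    oof[!tr] <- tryCatch({
      fit <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr], alpha = 0.5,
                               nfolds = 5L, standardize = TRUE)
      as.vector(stats::predict(fit, X[!tr, , drop = FALSE],
                               s = "lambda.min"))
    }, error = function(e) rep(mean(y[tr]), sum(!tr)))
  }
  if (stats::sd(oof) == 0) {
    cv_r2 <- 0; cv_p <- 1
  } else {
    ct <- stats::cor.test(oof, y, alternative = "greater")
    cv_r2 <- unname(ct$estimate)^2
    cv_p <- ct$p.value
  }
  final <- tryCatch(
    glmnet::cv.glmnet(X, y, alpha = 0.5, nfolds = 5L, standardize = TRUE),
    error = function(e) NULL)
  w <- if (is.null(final)) numeric(0) else {
    cf <- as.vector(stats::coef(final, s = "lambda.min"))[-1]
    stats::setNames(cf, colnames(X))[cf != 0]
  }
  structure(list(transcript_id = tid, weights = w,
                 cv_r2 = cv_r2, cv_pvalue = cv_p,
                 n_snps = length(w),
                 imputable = is.finite(cv_r2) && cv_r2 > 0 && cv_p < 0.05,
                 trainable = TRUE),
            class = "grex_model")
}

#' Train cis models for a set of transcripts
#'
#' @param genos a `genotype_matrix`.
#' @param expr residualized `expression_matrix`.
#' @param annotations `transcript_annotation` data.frame.
#' @param window_bp,cv_folds,seed passed to [train_cis_elastic_net()].
#' @return named list of `grex_model` objects.
#' @export
train_grex_models <- function(genos, expr, annotations, window_bp = 1e6,
                              cv_folds = 5L, seed = 1L) {
  models <- lapply(seq_len(nrow(annotations)), function(k)
    train_cis_elastic_net(genos, expr, annotations[k, , drop = FALSE],
                          window_bp = window_bp, cv_folds = cv_folds,
                          seed = seed + k))
  stats::setNames(models, annotations$id)
}

#' Impute GReX from a trained model
#'
#' Genetically regulated expression is the dosage-weighted sum of the
#' model's SNP weights. Model SNPs absent from the cohort contribute zero
#' with a warning.
#'
#' @param model a `grex_model`.
#' @param genos a `genotype_matrix` for the target cohort.
#' @return list with `grex` (per-sample vector) and `mean` (the cohort mean,
#'   the feature used by the contact models).
#' @export
impute_grex <- function(model, genos) {
  n <- nrow(genos$dosage)
  if (length(model$weights) == 0L)
    return(list(grex = stats::setNames(rep(0, n), rownames(genos$dosage)),
                mean = 0))
  present <- names(model$weights) %in% colnames(genos$dosage)
  if (!all(present))
    warning(sum(!present), " model SNP(s) missing from cohort; contributing 0")
  w <- model$weights[present]
  g <- if (length(w) == 0L) rep(0, n) else
    as.vector(genos$dosage[, names(w), drop = FALSE] %*% w)
  names(g) <- rownames(genos$dosage)
  list(grex = g, mean = mean(g))
}

#' Impute cohort-mean GReX for a model set
#'
#' @param models named list of `grex_model`s.
#' @param genos target cohort `genotype_matrix`.
#' @param imputable_only keep only imputable models (default TRUE).
#' @return named numeric vector of cohort-mean GReX per transcript.
#' @export
impute_grex_means <- function(models, genos, imputable_only = TRUE) {
  if (imputable_only)
    models <- Filter(function(m) isTRUE(m$imputable), models)
  vapply(models, function(m) impute_grex(m, genos)$mean, numeric(1))
}

#' Map cis-eQTLs by per-variant linear regression
#'
#' For each transcript and each variant within the cis window, fits the
#' simple additive linear model expression ~ dosage and records slope,
#' t-statistic and p-value (via the correlation-to-t identity
#' t = r sqrt(n-2) / sqrt(1-r^2)). Benjamini-Hochberg FDR is computed
#' across all cis tests in the run; pairs with FDR below the threshold are
#' flagged significant. Zero-variance variants are skipped.
#'
#' @param genos a `genotype_matrix`.
#' @param expr residualized `expression_matrix`.
#' @param annotations `transcript_annotation` data.frame.
#' @param window_bp cis half-window around the TSS.
#' @param fdr_threshold BH FDR cutoff for the significant set.
#' @return an `eqtl_set`: data.frame with transcript_id, variant_id, beta,
#'   t, p, fdr, significant.
#' @export
map_cis_eqtls <- function(genos, expr, annotations, window_bp = 1e6,
                          fdr_threshold = 0.1) {
  vt <- genos$variants
  n <- nrow(genos$dosage)
  res <- vector("list", nrow(annotations))
  for (k in seq_len(nrow(annotations))) {
    tid <- annotations$id[k]
    cis <- which(vt$chrom == annotations$chrom[k] &
                   vt$pos >= annotations$tss[k] - window_bp &
                   vt$pos <= annotations$tss[k] + window_bp)
    if (length(cis) == 0L) next
    X <- genos$dosage[, cis, drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    ok <- sds > 0
    if (!any(ok)) next
    X <- X[, ok, drop = FALSE]
    y <- expr$values[, tid]
    r <- as.vector(stats::cor(X, y))
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    beta <- r * stats::sd(y) / sds[ok]
    res[[k]] <- data.frame(transcript_id = tid,
                           variant_id = colnames(X),
                           beta = unname(beta), t = tstat, p = p,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(transcript_id = character(0), variant_id = character(0),
                      beta = numeric(0), t = numeric(0), p = numeric(0),
                      fdr = numeric(0), significant = logical(0))
  } else {
    out$fdr <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$fdr < fdr_threshold
    rownames(out) <- NULL
  }
  class(out) <- c("eqtl_set", "data.frame")
  out
}

#' Summarize a set of trained GReX models
#'
#' Reports the proportion of imputable transcripts (untrainable transcripts
#' count in the denominator), mean cross-validated R-squared among imputable
#' models, mean MAF of model SNPs, and mean SNPs per transcript. With a
#' second model set, compares SNPs/transcript between the sets with a
#' two-sided Mann-Whitney U test.
#'
#' @param models named list of `grex_model`s.
#' @param genos the training `genotype_matrix` (for SNP MAF lookup).
#' @param other optional second model set to compare against.
#' @return list with proportion_imputable, mean_cv_r2, mean_maf,
#'   mean_snps_per_transcript, and (when `other` given) the comparison's
#'   mean_snps_other and mannwhitney_p.
#' @export
summarize_model_set <- function(models, genos, other = NULL) {
  stopifnot(length(models) >= 1)
  imputable <- vapply(models, function(m) isTRUE(m$imputable), logical(1))
  snps <- vapply(models, function(m) m$n_snps, numeric(1))
  all_snp_ids <- unlist(lapply(models, function(m) names(m$weights)))
  maf <- genos$variants$maf[match(all_snp_ids, genos$variants$id)]
  out <- list(
    n_models = length(models),
    proportion_imputable = mean(imputable),
    mean_cv_r2 = if (any(imputable))
      mean(vapply(models[imputable], `[[`, numeric(1), "cv_r2")) else NA_real_,
    mean_maf = if (length(maf)) mean(maf, na.rm = TRUE) else NA_real_,
    mean_snps_per_transcript = mean(snps))
  if (!is.null(other)) {
    snps2 <- vapply(other, function(m) m$n_snps, numeric(1))
    out$mean_snps_other <- mean(snps2)
    out$mannwhitney_p <- stats::wilcox.test(snps, snps2, exact = FALSE)$p.value
  }
  out
}
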