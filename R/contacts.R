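#' Construct a binned contact matrix
#'
#' Canonical sparse symmetric representation of a binned Hi-C matrix:
#' pixels are stored once in upper-triangle order (bin1_id <= bin2_id) over
#' a bin table tiling each chromosome at a fixed resolution.
#'
#' @param pixels data.frame with columns bin1_id, bin2_id, value (0-based
#'   bin ids, nonnegative values); rows with swapped ids are canonicalized
#'   and duplicate pixels summed.
#' @param bins data.frame with columns chrom, start, end, bin_id (0-based
#'   half-open coordinates, 0-based ids).
#' @param resolution bin size in bp.
#' @param normalized whether the values are already balanced (ICE) rather
#'   than raw counts.
#' @return a `contact_matrix` object.
#' @export
contact_matrix <- function(pixels, bins, resolution,
                           normalized = FALSE) {
  stopifnot(all(c("bin1_id", "bin2_id", "value") %in% names(pixels)),
            all(c("chrom", "start", "end", "bin_id") %in% names(bins)))
  if (any(pixels$value < 0))
    stop("contact values must be nonnegative", call. = FALSE)
  swap <- pixels$bin1_id > pixels$bin2_id
  if (any(swap)) {
    tmp <- pixels$bin1_id[swap]
    pixels$bin1_id[swap] <- pixels$bin2_id[swap]
    pixels$bin2_id[swap] <- tmp
  }
  px <- data.table::as.data.table(pixels[c("bin1_id", "bin2_id", "value")])
  px <- px[, list(value = sum(value)), by = c("bin1_id", "bin2_id")]
  data.table::setorderv(px, c("bin1_id", "bin2_id"))
  structure(list(pixels = as.data.frame(px),
                 bins = as.data.frame(bins),
                 resolution = resolution,
                 normalized = isTRUE(normalized)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins @ %g bp, %d pixels (%s)\n",
              nrow(x$bins), x$resolution, nrow(x$pixels),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Load a contact matrix from text
#'
#' Reads one of three text dialects into the canonical sparse symmetric
#' representation:
#' \describe{
#'   \item{cooler-dump}{two files: a bin table (chrom, start, end, bin_id)
#'     and a pixel table (bin1_id, bin2_id, count).}
#'   \item{BEDPE}{chrom1, start1, end1, chrom2, start2, end2, value; the bin
#'     table is constructed from the coordinates at `resolution`.}
#'   \item{dense}{a square TSV matrix; bins tile a single chromosome.}
#' }
#'
#' @param path pixel/BEDPE/dense file path.
#' @param dialect one of "cooler", "bedpe", "dense".
#' @param bins_path bin table path (cooler dialect).
#' @param resolution bin size in bp (required for bedpe/dense).
#' @param chrom chromosome name for the dense dialect.
#' @param normalized whether the stored values are already balanced.
#' @return a `contact_matrix`.
#' @export
load_contacts <- function(path, dialect = c("cooler", "bedpe", "dense"),
                          bins_path = NULL, resolution = NULL,
                          chrom = "chrS", normalized = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "cooler") {
    if (is.null(bins_path))
      stop("cooler dialect needs bins_path", call. = FALSE)
    bins <- data.table::fread(bins_path, data.table = FALSE)
    names(bins) <- c("chrom", "start", "end", "bin_id")[seq_len(ncol(bins))]
    px <- data.table::fread(path, data.table = FALSE)
    names(px) <- c("bin1_id", "bin2_id", "value")[seq_len(ncol(px))]
    res <- if (is.null(resolution)) max(bins$end - bins$start) else resolution
    return(contact_matrix(px, bins, res, normalized = normalized))
  }
  if (dialect == "bedpe") {
    if (is.null(resolution))
      stop("bedpe dialect needs resolution", call. = FALSE)
    bp <- data.table::fread(path, data.table = FALSE)
    names(bp)[1:7] <- c("chrom1", "start1", "end1", "chrom2", "start2",
                        "end2", "value")
    if (any(bp$start1 %% resolution != 0) || any(bp$start2 %% resolution != 0)) {
      bad <- which(bp$start1 %% resolution != 0 | bp$start2 %% resolution != 0)[1]
      stop("BEDPE anchors not aligned to resolution at row ", bad,
           call. = FALSE)
    }
    chroms <- sort(unique(c(bp$chrom1, bp$chrom2)))
    ends <- vapply(chroms, function(ch)
      max(bp$end1[bp$chrom1 == ch], bp$end2[bp$chrom2 == ch]), numeric(1))
    bins <- do.call(rbind, lapply(seq_along(chroms), function(k) {
      nb <- ceiling(ends[k] / resolution)
      data.frame(chrom = chroms[k], start = (seq_len(nb) - 1) * resolution,
                 end = seq_len(nb) * resolution)
    }))
    bins$bin_id <- seq_len(nrow(bins)) - 1L
    key <- paste(bins$chrom, bins$start)
    b1 <- bins$bin_id[match(paste(bp$chrom1, bp$start1), key)]
    b2 <- bins$bin_id[match(paste(bp$chrom2, bp$start2), key)]
    px <- data.frame(bin1_id = b1, bin2_id = b2, value = bp$value)
    return(contact_matrix(px, bins, resolution, normalized = normalized))
  }
  m <- as.matrix(data.table::fread(path, data.table = FALSE, header = FALSE))
  dense_to_contact_matrix(m, resolution = resolution, chrom = chrom,
                          normalized = normalized)
}

#' Convert a dense symmetric matrix to a contact matrix
#'
#' @param m square symmetric numeric matrix.
#' @param resolution bin size in bp.
#' @param chrom chromosome name for the constructed bin table.
#' @param normalized whether values are balanced.
#' @return a `contact_matrix` with pixels for every nonzero upper-triangle
#'   entry (diagonal included).
#' @export
dense_to_contact_matrix <- function(m, resolution = 1e4, chrom = "chrS",
                                    normalized = FALSE) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8 * (1 + max(abs(m))))
    stop("dense matrix is not symmetric", call. = FALSE)
  n <- nrow(m)
  bins <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * resolution,
                     end = seq_len(n) * resolution,
                     bin_id = seq_len(n) - 1L)
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  px <- data.frame(bin1_id = idx[, 1] - 1L, bin2_id = idx[, 2] - 1L,
                   value = m[idx])
  contact_matrix(px, bins, resolution, normalized = normalized)
}

#' Expand a contact matrix to dense form
#'
#' @param m a `contact_matrix`.
#' @return a symmetric numeric matrix, one row/column per bin.
#' @export
contact_matrix_dense <- function(m) {
  n <- nrow(m$bins)
  out <- matrix(0, n, n)
  i <- m$pixels$bin1_id + 1L
  j <- m$pixels$bin2_id + 1L
  out[cbind(i, j)] <- m$pixels$value
  out[cbind(j, i)] <- m$pixels$value
  out
}

#' Write a contact matrix in cooler-dump style
#'
#' Two tab-separated files: a bin table (chrom, start, end, bin_id) and a
#' pixel table (bin1_id, bin2_id, value).
#' @param m a `contact_matrix`.
#' @param bins_path,pixels_path output paths.
#' @export
write_contacts_cooler <- function(m, bins_path, pixels_path) {
  data.table::fwrite(m$bins, bins_path, sep = "\t")
  data.table::fwrite(m$pixels, pixels_path, sep = "\t")
  invisible(c(bins = bins_path, pixels = pixels_path))
}

#' Write a contact matrix as BEDPE
#'
#' @param m a `contact_matrix`.
#' @param path output path.
#' @export
write_contacts_bedpe <- function(m, path) {
  b <- m$bins
  i <- match(m$pixels$bin1_id, b$bin_id)
  j <- match(m$pixels$bin2_id, b$bin_id)
  bedpe <- data.frame(chrom1 = b$chrom[i], start1 = b$start[i],
                      end1 = b$end[i], chrom2 = b$chrom[j],
                      start2 = b$start[j], end2 = b$end[j],
                      value = m$pixels$value)
  data.table::fwrite(bedpe, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' ICE matrix balancing
#'
#' Iterative correction of a raw contact matrix: per-bin biases are
#' estimated from the (masked) marginal sums and divided out repeatedly
#' until all unmasked row sums agree within tolerance, equalizing bin
#' coverage. Bins with zero coverage are masked and left untouched. The
#' total contact mass is preserved up to a single global rescale so the
#' mean pixel value is unchanged.
#'
#' @param m a raw `contact_matrix`.
#' @param max_iter maximum number of correction sweeps.
#' @param tol convergence tolerance on the coefficient of variation of the
#'   unmasked row sums.
#' @return the balanced `contact_matrix` (normalized flag set), with the
#'   per-bin bias vector in attribute "bias".
#' @export
ice_normalize <- function(m, max_iter = 200L, tol = 1e-8) {
  stopifnot(inherits(m, "contact_matrix"))
  px <- m$pixels
  n <- nrow(m$bins)
  i <- px$bin1_id + 1L
  j <- px$bin2_id + 1L
  v <- px$value
  marg0 <- rowsums_sym(i, j, v, n)
  masked <- marg0 == 0
  bias <- rep(1, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    marg <- rowsums_sym(i, j, v, n)
    mu <- mean(marg[!masked])
    cv <- stats::sd(marg[!masked]) / mu
    if (!is.finite(cv) || cv < tol) { converged <- TRUE; break }
    b <- marg / mu
    b[masked | b == 0] <- 1
    v <- v / (b[i] * b[j])
    bias <- bias * b
  }
  if (!converged) {
    marg <- rowsums_sym(i, j, v, n)
    cv <- stats::sd(marg[!masked]) / mean(marg[!masked])
    if (!is.finite(cv) || cv >= tol)
      stop(sprintf("ICE did not converge in %d iterations (row-sum CV %.3g)",
                   max_iter, cv), call. = FALSE)
  }
  # preserve the mean pixel value
  v <- v * sum(px$value) / sum(v)
  out <- m
  out$pixels$value <- v
  out$normalized <- TRUE
  attr(out, "bias") <- bias
  out
}

# symmetric marginals of upper-triangle pixels; diagonal counted once
rowsums_sym <- function(i, j, v, n) {
  s <- numeric(n)
  agg1 <- rowsum(v, i)
  s[as.integer(rownames(agg1))] <- agg1[, 1]
  off <- i != j
  if (any(off)) {
    agg2 <- rowsum(v[off], j[off])
    idx <- as.integer(rownames(agg2))
    s[idx] <- s[idx] + agg2[, 1]
  }
  s
}

#' Map contact bins to overlapping transcripts
#'
#' Interval intersection with at least 1 bp of overlap on 0-based half-open
#' coordinates (bedtools semantics); strand is ignored. Annotations
#' extending beyond the last bin are clipped with a warning.
#'
#' @param m a `contact_matrix`.
#' @param annotations a `transcript_annotation` data.frame.
#' @return a list mapping each bin (by position in the bin table) to the
#'   character vector of overlapping transcript ids.
#' @export
overlap_bins_with_transcripts <- function(m, annotations) {
  ann <- annotations
  for (ch in unique(ann$chrom)) {
    ext <- max(m$bins$end[m$bins$chrom == ch], 0)
    over <- ann$chrom == ch & ann$end > ext
    if (any(over)) {
      warning("clipping ", sum(over), " annotation(s) beyond chromosome extent")
      ann$end[over] <- ext
    }
  }
  ann <- ann[ann$end > ann$start, , drop = FALSE]
  overlap_bins_with_annotations(m$bins, ann)
}

#' Assemble the pair-level contact training set
#'
#' For every off-diagonal pixel with contact at or above `min_contact`,
#' emits one record per transcript pair (one transcript from each bin)
#' whose classes are {eRNA, eRNA} or {eRNA, canonical}; gene-gene pairs are
#' skipped. The member in the leftmost bin is the upstream transcript;
#' the pair class is "enhancer-gene", "gene-enhancer" or
#' "enhancer-enhancer" according to member classes and order. Distance is
#' the downstream minus upstream bin start, with log1p recorded alongside.
#' Pairs lacking a GReX value for either member are dropped, and the same
#' transcript pair seen through several pixels collapses to its maximum
#' contact value.
#'
#' @param m a normalized `contact_matrix`.
#' @param bin_map output of [overlap_bins_with_transcripts()].
#' @param annotations the `transcript_annotation` data.frame.
#' @param grex_means named per-transcript mean GReX values; transcripts
#'   absent from it are treated as non-imputable and excluded.
#' @param min_contact minimum normalized contact to retain a pixel.
#' @return a `pair_dataset` data.frame with columns upstream_id,
#'   downstream_id, pair_class, grex_up, grex_down, distance_bp,
#'   log1p_distance, contact.
#' @export
build_pair_dataset <- function(m, bin_map, annotations, grex_means,
                               min_contact = 1.0) {
  if (!m$normalized)
    stop("contact matrix must be ICE-normalized before pair assembly",
         call. = FALSE)
  cls <- stats::setNames(annotations$class, annotations$id)
  keep <- m$pixels$value >= min_contact & m$pixels$bin1_id != m$pixels$bin2_id
  px <- m$pixels[keep, , drop = FALSE]
  start_of <- stats::setNames(m$bins$start, m$bins$bin_id)
  chrom_of <- stats::setNames(m$bins$chrom, m$bins$bin_id)
  rows <- vector("list", nrow(px))
  for (r in seq_len(nrow(px))) {
    b1 <- px$bin1_id[r]; b2 <- px$bin2_id[r]
    if (chrom_of[as.character(b1)] != chrom_of[as.character(b2)]) next
    t1 <- bin_map[[match(b1, m$bins$bin_id)]]
    t2 <- bin_map[[match(b2, m$bins$bin_id)]]
    if (length(t1) == 0 || length(t2) == 0) next
    grid <- expand.grid(up = t1, down = t2, stringsAsFactors = FALSE)
    c_up <- cls[grid$up]; c_down <- cls[grid$down]
    ok <- (c_up == "eRNA" | c_down == "eRNA") &
      grid$up %in% names(grex_means) & grid$down %in% names(grex_means) &
      grid$up != grid$down
    if (!any(ok)) next
    grid <- grid[ok, , drop = FALSE]
    c_up <- c_up[ok]; c_down <- c_down[ok]
    pair_class <- ifelse(c_up == "eRNA" & c_down == "eRNA",
                         "enhancer-enhancer",
                         ifelse(c_up == "eRNA", "enhancer-gene",
                                "gene-enhancer"))
    d <- start_of[as.character(b2)] - start_of[as.character(b1)]
    rows[[r]] <- data.frame(upstream_id = grid$up,
                            downstream_id = grid$down,
                            pair_class = pair_class,
                            grex_up = unname(grex_means[grid$up]),
                            grex_down = unname(grex_means[grid$down]),
                            distance_bp = unname(d),
                            contact = px$value[r],
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(upstream_id = character(0), downstream_id = character(0),
                      pair_class = character(0), grex_up = numeric(0),
                      grex_down = numeric(0), distance_bp = numeric(0),
                      log1p_distance = numeric(0), contact = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("pair_dataset", "data.frame")
    return(out)
  }
  dt <- data.table::rbindlist(rows)
  dt <- dt[, list(pair_class = pair_class[1],
                  grex_up = grex_up[1], grex_down = grex_down[1],
                  distance_bp = min(distance_bp),
                  contact = max(contact)),
           by = c("upstream_id", "downstream_id")]
  dt$log1p_distance <- log1p(dt$distance_bp)
  out <- as.data.frame(dt[, c("upstream_id", "downstream_id", "pair_class",
                              "grex_up", "grex_down", "distance_bp",
                              "log1p_distance", "contact"), with = FALSE])
  class(out) <- c("pair_dataset", "data.frame")
  attr(out, "provenance") <- list(resolution = m$resolution,
                                  min_contact = min_contact)
  out
}

#' Random train/test split of a pair dataset
#'
#' Uniform split without replacement: the training set receives
#' `floor(fraction * n)` rows and the test set the remainder (so
#' 95,701 rows at 0.8 give 76,560 / 19,141 and 85,630 give 68,504 / 17,126).
#'
#' @param pairs a `pair_dataset` (or any data.frame).
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
split_train_test <- function(pairs, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  n <- nrow(pairs)
  n_train <- floor(fraction * n)
  set.seed(seed)
  idx <- sample.int(n, n_train)
  list(train = pairs[idx, , drop = FALSE],
       test = pairs[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Aggregate stranded run-on signal over transcripts
#'
#' Combines plus- and minus-strand bedGraph coverage: for each transcript,
#' sums signal x overlapped-bp across both strands over the transcript
#' interval, then applies log1p. This is the nuclear run-on expression
#' proxy used in place of imputed GReX for cell lines without genotypes.
#'
#' @param plus,minus data.frames with columns chrom, start, end, value
#'   (0-based half-open; non-overlapping intervals per strand).
#' @param annotations a `transcript_annotation` data.frame.
#' @return named numeric vector of log1p totals, one per transcript.
#' @export
aggregate_strand_signal <- function(plus, minus, annotations) {
  for (bg in list(plus, minus))
    if (nrow(bg) > 0 && any(bg$value < 0))
      stop("negative signal values in bedGraph", call. = FALSE)
  totals <- stats::setNames(numeric(nrow(annotations)), annotations$id)
  for (bg in list(plus, minus)) {
    if (nrow(bg) == 0) next
    for (ch in unique(annotations$chrom)) {
      ai <- which(annotations$chrom == ch)
      bi <- which(bg$chrom == ch)
      if (length(ai) == 0 || length(bi) == 0) next
      q <- IRanges::IRanges(annotations$start[ai] + 1L, annotations$end[ai])
      s <- IRanges::IRanges(bg$start[bi] + 1L, bg$end[bi])
      hits <- IRanges::findOverlaps(q, s)
      if (length(hits) == 0) next
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
      contrib <- ov * bg$value[bi][sh]
      agg <- rowsum(contrib, qh)
      totals[ai[as.integer(rownames(agg))]] <-
        totals[ai[as.integer(rownames(agg))]] + agg[, 1]
    }
  }
  log1p(totals)
}

#' Read a bedGraph file
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open).
#' @return data.frame with those four columns.
#' @export
read_bedgraph <- function(path) {
  bg <- data.table::fread(path, header = FALSE, data.table = FALSE)
  names(bg)[1:4] <- c("chrom", "start", "end", "value")
  bg
}

#' Write a bedGraph file
#' @param bg data.frame with chrom, start, end, value.
#' @param path output path.
#' @export
write_bedgraph <- function(bg, path) {
  data.table::fwrite(bg[c("chrom", "start", "end", "value")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}
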