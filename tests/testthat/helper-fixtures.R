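# Small programmatic fixtures shared across test files.

# tiny annotation table in 0-based half-open coordinates
toy_annotations <- function() {
  ann <- data.frame(
    id = c("eRNA_a", "eRNA_b", "gene_x", "gene_y"),
    class = c("eRNA", "eRNA", "canonical", "canonical"),
    chrom = "chrS",
    start = c(1000, 12000, 21000, 35000),
    end = c(1600, 12500, 30000, 45000),
    strand = c("+", "-", "+", "-"),
    stringsAsFactors = FALSE)
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  class(ann) <- c("transcript_annotation", "data.frame")
  ann
}

# dense symmetric random contact matrix with strictly positive entries
random_dense_contacts <- function(n = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, 0.5, 3), n)
  m + t(m)
}

# independent symmetric Sinkhorn balancing oracle on a dense matrix:
# divide both sides by the square root of the normalized row sums until
# all row sums agree; a pure diagonal scaling D m D, rescaled to the
# input mean.
sinkhorn_balance <- function(m, iter = 10000, tol = 1e-13) {
  x <- m
  for (k in seq_len(iter)) {
    rs <- rowSums(x)
    if (stats::sd(rs) / mean(rs) < tol) break
    s <- sqrt(rs / mean(rs))
    x <- x / outer(s, s)
  }
  x * sum(m) / sum(x)
}

# brute-force enumeration oracle for pair-dataset construction
brute_force_pairs <- function(m, bin_map, annotations, grex_means,
                              min_contact = 1.0) {
  cls <- stats::setNames(annotations$class, annotations$id)
  start_of <- stats::setNames(m$bins$start, m$bins$bin_id)
  recs <- list()
  for (r in seq_len(nrow(m$pixels))) {
    b1 <- m$pixels$bin1_id[r]; b2 <- m$pixels$bin2_id[r]
    v <- m$pixels$value[r]
    if (v < min_contact || b1 == b2) next
    for (tu in bin_map[[match(b1, m$bins$bin_id)]])
      for (td in bin_map[[match(b2, m$bins$bin_id)]]) {
        if (tu == td) next
        cu <- cls[tu]; cd <- cls[td]
        if (cu != "eRNA" && cd != "eRNA") next
        if (!(tu %in% names(grex_means)) || !(td %in% names(grex_means)))
          next
        key <- paste(tu, td)
        d <- start_of[as.character(b2)] - start_of[as.character(b1)]
        if (is.null(recs[[key]])) {
          recs[[key]] <- list(up = tu, down = td, contact = v, d = d)
        } else {
          recs[[key]]$contact <- max(recs[[key]]$contact, v)
          recs[[key]]$d <- min(recs[[key]]$d, d)
        }
      }
  }
  recs
}

# a hand-built linear contact_nn computing f(u, v) = a*u + b*v + c,
# used as a transparent model for attribution oracles
linear_contact_nn <- function(a, b, c = 0) {
  arch <- nn_architecture(n_inputs = 2L, hidden_layers = 1L,
                          hidden_neurons = 2L, activation = "linear",
                          hidden_init = "zeros", output_init = "zeros")
  params <- list(W = list(diag(2), matrix(c(a, b), 2, 1)),
                 b = list(c(0, 0), c))
  structure(list(params = params, architecture = arch,
                 config = train_config("sgd", 0.1, 1L, 10L),
                 center = c(0, 0), scale = c(1, 1),
                 loss_trace = numeric(0)),
            class = "contact_nn")
}
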