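#' Relative-error statistics for contact predictions
#'
#' Per-pair relative error E = |predicted - observed| / observed, defined
#' only for positive observed contact (guaranteed upstream by the
#' minimum-contact filter). Reports the median (standard mid-interpolation)
#' and the best- and worst-predicted pairs.
#'
#' @param pairs data.frame with upstream_id, downstream_id.
#' @param observed,predicted aligned numeric vectors.
#' @return list with `errors`, `median_error`, `best`, `worst` (each a
#'   one-row data.frame with ids, observed, predicted, error).
#' @export
relative_error_stats <- function(pairs, observed, predicted) {
  stopifnot(nrow(pairs) == length(observed),
            length(observed) == length(predicted),
            length(observed) >= 1)
  if (any(observed <= 0)) {
    bad <- which(observed <= 0)
    stop("nonpositive observed contact for pair(s): ",
         paste(utils::head(paste(pairs$upstream_id[bad],
                                 pairs$downstream_id[bad], sep = "~"), 3),
               collapse = ", "), call. = FALSE)
  }
  E <- abs(predicted - observed) / observed
  pick <- function(i) data.frame(upstream_id = pairs$upstream_id[i],
                                 downstream_id = pairs$downstream_id[i],
                                 observed = observed[i],
                                 predicted = predicted[i],
                                 error = E[i], stringsAsFactors = FALSE)
  list(errors = E,
       median_error = stats::median(E),
       best = pick(which.min(E)),
       worst = pick(which.max(E)))
}

#' Exact two-feature Shapley attribution
#'
#' For a model with exactly two input features, Shapley values are exact
#' from the four coalition evaluations against a background point b:
#' phi1 = 1/2 \[(f(x1, b2) - f(b1, b2)) + (f(x1, x2) - f(b1, x2))\], and
#' symmetrically for phi2. Local accuracy phi1 + phi2 =
#' f(x1, x2) - f(b1, b2) is asserted per instance. Relative contributions
#' are mean |phi_i| / sum_j mean |phi_j| x 100 and always sum to 100.
#'
#' @param model a `contact_nn`, any object with a predict method over a
#'   pair dataset, or a plain function f(u, v) of the two features.
#' @param data a `pair_dataset` of instances to explain.
#' @param background length-2 reference point (grex_up, grex_down);
#'   defaults to the column means of `data`.
#' @return list with `phi` (n x 2 matrix), `mean_abs_phi`,
#'   `contribution_pct` (named, sums to 100).
#' @export
shap_two_feature <- function(model, data, background = NULL) {
  if (!is.function(model) && !is.null(model$architecture) &&
      model$architecture$n_inputs != 2L)
    stop("exact two-feature attribution requires a 2-input model",
         call. = FALSE)
  if (is.null(background))
    background <- c(mean(data$grex_up), mean(data$grex_down))
  stopifnot(length(background) == 2)
  eval_at <- if (is.function(model)) model else function(u, v) {
    nd <- data.frame(grex_up = u, grex_down = v)
    predict(model, nd)
  }
  n <- nrow(data)
  x1 <- data$grex_up; x2 <- data$grex_down
  b1 <- rep(background[1], n); b2 <- rep(background[2], n)
  f_bb <- eval_at(b1, b2)
  f_xb <- eval_at(x1, b2)
  f_bx <- eval_at(b1, x2)
  f_xx <- eval_at(x1, x2)
  phi1 <- 0.5 * ((f_xb - f_bb) + (f_xx - f_bx))
  phi2 <- 0.5 * ((f_bx - f_bb) + (f_xx - f_xb))
  if (max(abs(phi1 + phi2 - (f_xx - f_bb))) > 1e-9 * (1 + max(abs(f_xx))))
    stop("local accuracy violated; model predictions are not deterministic",
         call. = FALSE)
  mean_abs <- c(upstream = mean(abs(phi1)), downstream = mean(abs(phi2)))
  pct <- mean_abs / sum(mean_abs) * 100
  list(phi = cbind(upstream = phi1, downstream = phi2),
       mean_abs_phi = mean_abs,
       contribution_pct = pct)
}

#' Cross-tissue transfer evaluation
#'
#' Applies a trained model, with its stored training-tissue feature
#' scaling, to a foreign pair dataset and returns the R-squared of the
#' predictions against the foreign observed contacts.
#'
#' @param model a `contact_nn`.
#' @param foreign a `pair_dataset` with the same feature schema.
#' @return R-squared on the foreign data.
#' @export
cross_tissue_transfer <- function(model, foreign) {
  needed <- c("grex_up", "grex_down",
              if (model$architecture$n_inputs == 3L) "log1p_distance")
  if (!all(needed %in% names(foreign)))
    stop("foreign dataset lacks feature columns: ",
         paste(setdiff(needed, names(foreign)), collapse = ", "),
         call. = FALSE)
  evaluate_r2(foreign$contact, predict(model, foreign))
}

#' Correlation of genomic distance with predicted and observed contact
#'
#' Pearson correlation of log1p genomic distance with the predicted and
#' with the observed contact frequency. A degenerate input (zero variance
#' on either side) reports a correlation of 0 with a flag instead of NaN.
#'
#' @param distances log1p distances (or raw distances; used as given).
#' @param observed,predicted aligned contact vectors.
#' @return list with r_pred, r_obs, degenerate_pred, degenerate_obs.
#' @export
distance_contact_correlation <- function(distances, observed, predicted) {
  stopifnot(length(distances) == length(observed),
            length(observed) == length(predicted))
  if (length(distances) < 3)
    stop("need at least three pairs", call. = FALSE)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      return(list(r = 0, degenerate = TRUE))
    list(r = stats::cor(a, b), degenerate = FALSE)
  }
  co <- safe_cor(distances, observed)
  cp <- safe_cor(distances, predicted)
  list(r_pred = cp$r, r_obs = co$r,
       degenerate_pred = cp$degenerate, degenerate_obs = co$degenerate)
}
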