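#' Log10-scale RMSE and Pearson correlation between paired abundances
#'
#' Both metrics act on `log10`-transformed abundances with non-positive pairs
#' excluded pairwise (sequencing zeros carry no log-scale information).
#'
#' @param pred,obs Paired abundance vectors.
#' @return `rmse_log10()` returns a single non-negative number (`NA` if no
#'   positive pair survives); `pearson_log10()` returns a tibble with
#'   columns `r`, `p_value`, `n` (`NA` row when fewer than 3 pairs survive).
#' @export
rmse_log10 <- function(pred, obs) {
  keep <- pred > 0 & obs > 0 & !is.na(pred) & !is.na(obs)
  if (!any(keep)) return(NA_real_)
  sqrt(mean((log10(pred[keep]) - log10(obs[keep]))^2))
}

#' @rdname rmse_log10
#' @export
pearson_log10 <- function(pred, obs) {
  keep <- pred > 0 & obs > 0 & !is.na(pred) & !is.na(obs)
  if (sum(keep) < 3) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = sum(keep)))
  }
  ht <- cor.test(log10(pred[keep]), log10(obs[keep]), method = "pearson")
  tibble::tibble(r = unname(ht$estimate), p_value = ht$p.value, n = sum(keep))
}

#' Replicate-to-replicate variability at one passage
#'
#' Mean over all unordered replicate pairs of the log10-scale RMSE between
#' the two replicates' abundance vectors. This is the irreducible noise floor
#' against which model RMSE is judged.
#'
#' @param reps Strain x replicate abundance matrix (>= 2 columns).
#' @return Mean pairwise log10 RMSE.
#' @export
replicate_rmse <- function(reps) {
  reps <- as.matrix(reps)
  if (ncol(reps) < 2) stop("need at least 2 replicates", call. = FALSE)
  pairs <- utils::combn(ncol(reps), 2)
  mean(apply(pairs, 2, function(p) rmse_log10(reps[, p[1]], reps[, p[2]])))
}

#' Cumulative RMSE over abundance-thresholded strain subsets
#'
#' For each threshold, computes the log10 RMSE restricted to strains whose
#' observed abundance exceeds the threshold; low-abundance strains dominate
#' the error, so the curve falls as the threshold rises. Subsets with fewer
#' than 2 strains are omitted.
#'
#' @param pred,obs Paired abundance vectors (observed values define the
#'   subsets).
#' @param thresholds Abundance thresholds, typically evenly spaced on the
#'   log10 scale.
#' @return Tibble with columns `threshold`, `n`, `rmse`.
#' @export
cumulative_rmse <- function(pred, obs, thresholds) {
  rows <- lapply(thresholds, function(t) {
    keep <- obs > t
    if (sum(keep) < 2) return(NULL)
    tibble::tibble(threshold = t, n = sum(keep),
                   rmse = rmse_log10(pred[keep], obs[keep]))
  })
  dplyr::bind_rows(rows)
}

#' Non-interacting monoculture null model
#'
#' Predicts each strain's abundance as the biomass it would reach growing
#' alone on the fitted medium: the sum of the concentrations of every
#' resource it consumes, `N[a] = sum_i R[i] * [C[a, i] > 0]`.
#'
#' @param R Named resource concentration vector.
#' @param C Consumption matrix (strains x resources).
#' @param normalize If `TRUE`, rescale to relative abundances; default
#'   `FALSE`.
#' @return Named per-strain abundance vector.
#' @export
monoculture_null <- function(R, C, normalize = FALSE) {
  out <- as.vector((C > 0) %*% as.numeric(R))
  names(out) <- rownames(C)
  if (normalize && sum(out) > 0) out <- out / sum(out)
  out
}

#' Growth-ratio metrics against the static passage-2 null
#'
#' The passage-2 null model predicts no dynamics between passages 2 and 3
#' (growth ratio 1 for every strain, hence zero covariance with anything).
#' This report compares the model's predicted growth ratios
#' (`pred3 / obs2`) with the observed ratios (`obs3 / obs2`) by log10-scale
#' Pearson correlation and RMSE, alongside the null's RMSE.
#'
#' @param obs2,obs3 Observed abundance vectors at passages 2 and 3.
#' @param pred3 Model-predicted abundance vector at passage 3.
#' @param pred2 Optional model-predicted abundances at passage 2 to use as
#'   the denominator of the predicted ratio; default `obs2`.
#' @return Tibble with columns `r`, `p_value`, `n`, `rmse_model`,
#'   `rmse_null`.
#' @export
passage2_null_metrics <- function(obs2, obs3, pred3, pred2 = NULL) {
  if (is.null(pred2)) pred2 <- obs2
  keep <- obs2 > 0 & obs3 > 0 & pred3 > 0 & pred2 > 0
  ratio_obs <- obs3[keep] / obs2[keep]
  ratio_pred <- pred3[keep] / pred2[keep]
  ct <- pearson_log10(ratio_pred, ratio_obs)
  tibble::tibble(
    r = ct$r, p_value = ct$p_value, n = ct$n,
    rmse_model = rmse_log10(ratio_pred, ratio_obs),
    rmse_null = rmse_log10(rep(1, sum(keep)), ratio_obs)
  )
}

#' Shuffle a consumption matrix for null-model controls
#'
#' Permutes the entries of the consumption matrix while preserving either
#' nothing but the entry multiset (`complete`), the row sums
#' (`row_preserve`: entries permuted within each strain), or the column sums
#' (`col_preserve`: entries permuted within each resource).
#'
#' @param C Consumption matrix.
#' @param mode One of `"complete"`, `"row_preserve"`, `"col_preserve"`.
#' @param seed Integer RNG seed.
#' @return Shuffled matrix with the same dimnames.
#' @export
shuffle_consumption <- function(C, mode = c("complete", "row_preserve",
                                            "col_preserve"), seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  out <- C
  if (mode == "complete") {
    out[] <- sample(as.vector(C))
  } else if (mode == "row_preserve") {
    for (i in seq_len(nrow(C))) out[i, ] <- sample(C[i, ])
  } else {
    for (j in seq_len(ncol(C))) out[, j] <- sample(C[, j])
  }
  out
}

#' Per-passage evaluation report for model predictions
#'
#' Compares a predicted trajectory with an observed replicate-resolved
#' abundance table passage by passage: log10 Pearson correlation, log10
#' RMSE against the geometric-mean observation, replicate-to-replicate RMSE,
#' and the adjusted RMSE (model RMSE minus replicate RMSE — the part of the
#' error not explained by replicate noise).
#'
#' @param trajectory A `crm_trajectory` from [simulate_passages()].
#' @param abundance Long observed table (`strain`, `passage`, `replicate`,
#'   `abundance`).
#' @param passages Passages to evaluate; default all shared non-inoculum
#'   passages.
#' @return A `crm_eval` tibble with one row per passage: `passage`, `r`,
#'   `p_value`, `n`, `rmse`, `replicate_rmse`, `adjusted_rmse`.
#' @export
evaluate_predictions <- function(trajectory, abundance, passages = NULL) {
  if (is.null(passages)) {
    passages <- intersect(unique(trajectory$passage),
                          unique(abundance$passage))
    passages <- setdiff(passages, 0)
  }
  rows <- lapply(passages, function(k) {
    pred <- trajectory_state(trajectory, k)
    obs_mat <- abundance_matrix(abundance, k, strains = names(pred))
    obs_geo <- apply(obs_mat, 1, function(x) {
      x <- x[x > 0]
      if (length(x) == 0) 0 else 10^mean(log10(x))
    })
    ct <- pearson_log10(pred, obs_geo)
    rr <- if (ncol(obs_mat) >= 2) replicate_rmse(obs_mat) else NA_real_
    rm <- rmse_log10(pred, obs_geo)
    tibble::tibble(passage = k, r = ct$r, p_value = ct$p_value, n = ct$n,
                   rmse = rm, replicate_rmse = rr, adjusted_rmse = rm - rr)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("crm_eval", class(out))
  out
}
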