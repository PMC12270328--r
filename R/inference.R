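#' Assemble the linear system for resource-concentration inference
#'
#' Given observed abundances at two consecutive passages, the one-passage
#' mass-conservation balance is linear in the resource concentrations `R`:
#' for each strain `a` and replicate `r`,
#' `N_next[a, r] - N_prev[a, r] / D = sum_i R[i] * m[i] * share[a, i]`,
#' where `share[a, i] = C[a, i] * W[a] / sum_g C[g, i] * W[g]` is the sharing
#' fraction built from the observed time-weighted average abundances `W`
#' ([weighted_avg_abundance()]), and `m[i] = 1 + sum_g P[g, i] * N_next[g]`
#' is the cross-feeding multiplier. Each replicate contributes its own block
#' of rows, with `W` and `m` computed from that replicate's own abundances.
#'
#' @param N_prev,N_next Observed abundances at passages `k - 1` and `k`:
#'   strain x replicate matrices (or vectors for a single replicate), rows in
#'   the strain order of `fluxes`.
#' @param fluxes A [flux_set()].
#' @param P Per-biomass production matrix (strains x resources); defaults to
#'   zeros (no cross-feeding).
#' @param f Time fraction; default 0.9.
#' @param D Dilution factor; default 15000.
#' @return An `nnls_system`: list with design matrix `A`
#'   (`n_S * n_reps` x `n_R`, non-negative), target `b`, a `rows` tibble
#'   (`strain`, `replicate`, `all_zero`), and `resources`.
#' @export
build_nnls_system <- function(N_prev, N_next, fluxes, P = NULL, f = 0.9,
                              D = 15000) {
  stopifnot(inherits(fluxes, "flux_set"))
  N_prev <- as.matrix(N_prev)
  N_next <- as.matrix(N_next)
  if (!all(dim(N_prev) == dim(N_next))) {
    stop("N_prev and N_next must have matching shapes", call. = FALSE)
  }
  C <- fluxes$C
  if (nrow(N_prev) != nrow(C)) stop("row count must match n_S", call. = FALSE)
  if (any(N_prev < 0) || any(N_next < 0)) stop("abundances must be >= 0", call. = FALSE)
  if (is.null(P)) P <- matrix(0, nrow(C), ncol(C))
  n_rep <- ncol(N_prev)
  blocks <- lapply(seq_len(n_rep), function(r) {
    W <- weighted_avg_abundance(N_prev[, r], N_next[, r], f)
    denom <- as.vector(crossprod(C, W))
    mult <- 1 + as.vector(crossprod(P, N_next[, r]))
    share <- C * W  # c_ai * W_a
    share <- sweep(share, 2, ifelse(denom > 0, denom, Inf), "/")
    A <- sweep(share, 2, mult, "*")
    b <- N_next[, r] - N_prev[, r] / D
    list(A = A, b = b)
  })
  A <- do.call(rbind, lapply(blocks, `[[`, "A"))
  b <- unlist(lapply(blocks, `[[`, "b"), use.names = FALSE)
  rows <- tibble::tibble(
    strain = rep(fluxes$strains, times = n_rep),
    replicate = rep(seq_len(n_rep), each = length(fluxes$strains)),
    all_zero = rowSums(A) == 0
  )
  structure(list(A = unname(A), b = b, rows = rows,
                 resources = fluxes$resources),
            class = "nnls_system")
}

#' Solve a resource-inference system by non-negative least squares
#'
#' Minimizes `||A R - b||_2` subject to `R >= 0` (Lawson-Hanson active-set
#' algorithm via [pracma::lsqnonneg()]). Fitted concentrations below
#' `zero_tol` are reported as exact zeros.
#'
#' @param system An `nnls_system` from [build_nnls_system()].
#' @param zero_tol Cutoff below which a fitted concentration is treated as
#'   zero; default `1e-8`.
#' @return Named non-negative resource vector with attribute `residual`
#'   (`||A R - b||_2`).
#' @export
solve_nnls <- function(system, zero_tol = 1e-8) {
  stopifnot(inherits(system, "nnls_system"))
  if (nrow(system$A) == 0) stop("empty system", call. = FALSE)
  fit <- pracma::lsqnonneg(system$A, system$b)
  R <- fit$x
  R[R < zero_tol] <- 0
  structure(setNames(R, system$resources),
            residual = sqrt(sum((system$A %*% R - system$b)^2)))
}

#' Jointly infer resource concentrations and monoculture biomasses
#'
#' The per-biomass production fluxes needed in the design matrix are
#' `P = P_total / N_alone`, but the monoculture biomasses `N_alone` are
#' themselves determined by the resource concentrations through mass
#' conservation, `N_alone[g] = sum_i R[i] * [C[g, i] > 0]` (Iverson bracket:
#' a strain growing alone takes all of every resource it consumes). The two
#' are solved jointly by fixed-point iteration: initialize
#' `N_alone = 1 / n_S`, then alternate (NNLS for `R`) and (mass-conservation
#' update of `N_alone`) for up to `n_outer` rounds, exiting early once
#' `N_alone` is stationary. With no production fluxes the loop converges in
#' one round since `R` does not depend on `N_alone`.
#'
#' @param abundance Either a long tibble with columns `strain`, `passage`,
#'   `replicate`, `abundance` (see [read_abundance_table()]), or a list with
#'   strain x replicate matrices `N_prev` and `N_next`.
#' @param fluxes A [flux_set()].
#' @param f Time fraction; default 0.9.
#' @param D Dilution factor; default 15000.
#' @param passages Length-2 vector of consecutive passage indices to fit on
#'   when `abundance` is a long table; default `c(1, 2)` (the most dynamic
#'   pair after the inoculum).
#' @param n_outer Maximum outer iterations; default 100.
#' @param outer_tol Early-exit tolerance on the max relative change of
#'   `N_alone`; default `1e-12`.
#' @param zero_tol Passed to [solve_nnls()].
#' @return A `crm_fit`: list with `R`, `N_alone`, the final `nnls_system`,
#'   `residual`, `f`, `D`, `n_outer_used`, and `delta_n_alone` (max relative
#'   change at exit).
#' @export
infer_resources <- function(abundance, fluxes, f = 0.9, D = 15000,
                            passages = c(1, 2), n_outer = 100,
                            outer_tol = 1e-12, zero_tol = 1e-8) {
  stopifnot(inherits(fluxes, "flux_set"))
  if (is.data.frame(abundance)) {
    N_prev <- abundance_matrix(abundance, passages[1], strains = fluxes$strains)
    N_next <- abundance_matrix(abundance, passages[2], strains = fluxes$strains)
  } else {
    N_prev <- as.matrix(abundance$N_prev)
    N_next <- as.matrix(abundance$N_next)
  }
  if (n_outer < 1) stop("n_outer must be >= 1", call. = FALSE)
  n_S <- length(fluxes$strains)
  consumes <- fluxes$C > 0
  N_alone <- rep(1 / n_S, n_S)
  R <- NULL
  system <- NULL
  delta <- Inf
  used <- 0
  for (it in seq_len(n_outer)) {
    used <- it
    P <- fluxes$P_total / N_alone
    system <- build_nnls_system(N_prev, N_next, fluxes, P = P, f = f, D = D)
    R <- solve_nnls(system, zero_tol = zero_tol)
    N_new <- as.vector(consumes %*% R)
    if (any(N_new <= 0)) {
      warning("strain(s) consuming no non-zero-R resource; N_alone floored at 1e-12",
              call. = FALSE)
      N_new <- pmax(N_new, 1e-12)
    }
    delta <- max(abs(N_new - N_alone) / pmax(abs(N_alone), 1e-300))
    N_alone <- N_new
    if (delta < outer_tol) break
  }
  structure(
    list(R = R, N_alone = setNames(N_alone, fluxes$strains), system = system,
         residual = attr(R, "residual"), f = f, D = D, n_outer_used = used,
         delta_n_alone = delta),
    class = "crm_fit"
  )
}

#' @export
print.crm_fit <- function(x, ...) {
  cat("<crm_fit> ", sum(x$R > 0), "/", length(x$R),
      " resources with non-zero fitted concentration\n", sep = "")
  cat("  residual ||A R - b|| = ", signif(x$residual, 4),
      "; outer iterations = ", x$n_outer_used,
      " (max rel. change of N_alone = ", signif(x$delta_n_alone, 3), ")\n",
      sep = "")
  invisible(x)
}

#' Convert a fitted model into full simulation parameters
#'
#' @param fit A `crm_fit` from [infer_resources()].
#' @param fluxes The [flux_set()] used in the fit.
#' @return A [model_params()] with the fitted `R`, the fitted `N_alone`, and
#'   `P = P_total / N_alone`.
#' @export
params_from_fit <- function(fit, fluxes) {
  stopifnot(inherits(fit, "crm_fit"), inherits(fluxes, "flux_set"))
  model_params(R = fit$R, f = fit$f, D = fit$D,
               P = fluxes$P_total / fit$N_alone, N_alone = fit$N_alone)
}

#' Estimate the time fraction by grid search
#'
#' For each candidate `f`, the model is refitted on the training passage pair
#' ([infer_resources()]), then used to predict abundances from the averaged
#' inoculum out to the target passage; the score is the Pearson correlation
#' between `log10` predicted and `log10` observed abundances (observations
#' combined across replicates by geometric mean on the log10 scale; strains
#' with zero predicted or observed abundance are excluded pairwise). The `f`
#' with the highest score wins; ties break toward the larger `f`.
#'
#' @param abundance Long abundance tibble (`strain`, `passage`, `replicate`,
#'   `abundance`) covering the inoculum, training and target passages.
#' @param fluxes A [flux_set()].
#' @param D Dilution factor; default 15000.
#' @param f_grid Candidate time fractions; default `seq(0.3, 1, by = 0.05)`.
#' @param train_passages Passage pair used for fitting; default `c(1, 2)`.
#' @param target_passage Passage scored for validation; default 3.
#' @param inoculum_passage Passage index holding the inoculum; default 0.
#' @param n_iter Fixed-point sweeps per predicted passage; default 2000
#'   (successive substitution slows as `f` approaches 1, and every grid point
#'   must be scored on a fully converged prediction).
#' @param ... Passed to [infer_resources()].
#' @return A `crm_fscan`: list with `f_best`, the score tibble `scores`
#'   (`f`, `score`), and `fit_best` (the refit at `f_best`).
#' @export
estimate_time_fraction <- function(abundance, fluxes, D = 15000,
                                   f_grid = seq(0.3, 1, by = 0.05),
                                   train_passages = c(1, 2),
                                   target_passage = 3,
                                   inoculum_passage = 0, n_iter = 2000, ...) {
  if (length(f_grid) < 1 || any(f_grid < 0) || any(f_grid > 1)) {
    stop("f_grid must be a non-empty vector within [0, 1]", call. = FALSE)
  }
  inoc <- abundance_matrix(abundance, inoculum_passage, strains = fluxes$strains)
  N0 <- rowMeans(inoc)
  obs <- abundance_matrix(abundance, target_passage, strains = fluxes$strains)
  obs_geo <- apply(obs, 1, function(x) {
    x <- x[x > 0]
    if (length(x) == 0) 0 else 10^mean(log10(x))
  })
  n_steps <- target_passage - inoculum_passage
  scores <- vapply(f_grid, function(f) {
    fit <- infer_resources(abundance, fluxes, f = f, D = D,
                           passages = train_passages, ...)
    params <- params_from_fit(fit, fluxes)
    pred <- N0
    for (k in seq_len(n_steps)) {
      pred <- passage_update(pred, params, fluxes, n_iter = n_iter)
    }
    keep <- pred > 0 & obs_geo > 0
    if (sum(keep) < 3) return(-Inf)
    r <- suppressWarnings(cor(log10(pred[keep]), log10(obs_geo[keep])))
    if (is.na(r)) -Inf else r
  }, numeric(1))
  ord <- order(f_grid)
  f_grid <- f_grid[ord]
  scores <- scores[ord]
  best_idx <- max(which(scores == max(scores)))  # ties -> larger f
  f_best <- f_grid[best_idx]
  structure(
    list(f_best = f_best,
         scores = tibble::tibble(f = f_grid, score = scores),
         fit_best = infer_resources(abundance, fluxes, f = f_best, D = D,
                                    passages = train_passages, ...)),
    class = "crm_fscan"
  )
}

#' @export
print.crm_fscan <- function(x, ...) {
  cat("<crm_fscan> best f = ", x$f_best, " (score = ",
      signif(max(x$scores$score), 4), ") over ", nrow(x$scores),
      " grid points\n", sep = "")
  invisible(x)
}
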