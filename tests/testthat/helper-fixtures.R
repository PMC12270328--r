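# Shared fixtures and the independent fixed-point oracle.

# tiny deterministic flux set used across files
tiny_fluxes <- function() {
  C <- matrix(c(0.8, 0.1,
                0.2, 0.9), nrow = 2, byrow = FALSE,
              dimnames = list(c("sA", "sB"), c("m1", "m2")))
  P <- matrix(c(0, 0,
                0.3, 0), nrow = 2, byrow = FALSE,
              dimnames = list(c("sA", "sB"), c("m1", "m2")))
  flux_set(C, P)
}

random_instance <- function(seed, n_S = NULL, n_R = NULL, with_production = FALSE,
                            f = NULL, D = 15000) {
  set.seed(seed)
  if (is.null(n_S)) n_S <- sample(2:10, 1)
  if (is.null(n_R)) n_R <- sample(2:10, 1)
  if (is.null(f)) f <- runif(1, 0.3, 0.95)
  fx <- generate_fluxes(n_S, n_R, consumer_density = 0.5,
                        producer_density = if (with_production) 0.2 else 0)
  R <- runif(n_R, 0.05, 1)
  params <- derive_params(fx, R, f = f, D = D)
  N_prev <- runif(n_S, 1e-4, 0.1)
  list(fluxes = fx, params = params, N_prev = N_prev)
}

# Independent oracle: solve the one-passage balance as a nonlinear root
# problem with a general-purpose solver, writing the equations out in plain
# scalar form (no shared code with passage_update).
oracle_passage <- function(N_prev, params, fluxes) {
  C <- fluxes$C
  P <- params$P
  if (is.null(P)) P <- matrix(0, nrow(C), ncol(C))
  R <- params$R
  f <- params$f
  D <- params$D
  n_S <- nrow(C)
  n_R <- ncol(C)
  balance <- function(N) {
    W <- numeric(n_S)
    for (a in seq_len(n_S)) {
      W[a] <- if (N_prev[a] > 0 && N[a] > 0) N_prev[a]^(1 - f) * N[a]^f else 0
    }
    out <- numeric(n_S)
    for (a in seq_len(n_S)) {
      growth <- 0
      for (i in seq_len(n_R)) {
        den <- 0
        for (g in seq_len(n_S)) den <- den + C[g, i] * W[g]
        if (den > 0) {
          prod_mult <- 1
          for (g in seq_len(n_S)) prod_mult <- prod_mult + P[g, i] * N[g]
          growth <- growth + R[i] * prod_mult * C[a, i] * W[a] / den
        }
      }
      out[a] <- N[a] - N_prev[a] / D - growth
    }
    out
  }
  # independent general-purpose solver: Levenberg-Marquardt (minpack.lm) on
  # the balance residuals in log-abundance space (positivity-preserving),
  # multi-started from a crude equal-split share guess, the previous state,
  # and jittered restarts; accept only a residual at root tolerance
  C_mat <- C
  share_guess <- as.vector(((C_mat > 0) /
                              pmax(colSums(C_mat > 0), 1)[col(C_mat)]) %*% R)
  log_balance <- function(z) balance(exp(z))
  starts <- list(log(pmax(share_guess, 1e-8)), log(pmax(N_prev, 1e-12)),
                 rep(log(sum(R) / n_S), n_S))
  for (j in 1:10) {
    starts[[length(starts) + 1]] <- log(pmax(share_guess, 1e-8)) +
      rnorm(n_S, 0, j / 3)  # progressively wider restarts
  }
  best <- NULL
  for (z0 in starts) {
    lm <- suppressWarnings(minpack.lm::nls.lm(
      par = z0, fn = log_balance,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15)))
    res <- max(abs(log_balance(lm$par)))
    if (is.null(best) || res < best$res) best <- list(x = exp(lm$par), res = res)
    if (res < 1e-10) break
  }
  if (best$res > 1e-9) stop("oracle root-finder failed to converge")
  best$x
}

expect_no_zero <- function(x) expect_true(all(x > 0))
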