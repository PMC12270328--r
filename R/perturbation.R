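#' Leave-one-out strain-removal experiment
#'
#' Removes each strain in turn from the inoculum, recomputes the community
#' steady state, and records the change in `log10` steady-state abundance of
#' every other strain. Entry `[s, t]` of the result is
#' `log10 N_t(without s) - log10 N_t(unperturbed)`; the diagonal is `NA`.
#' Abundances are floored at `floor` before taking logs so that extinctions
#' yield large finite deltas; if the unperturbed steady state already has
#' strains at the floor a warning is emitted. Removing a strain absent from
#' the inoculum changes nothing, giving an all-zero row.
#'
#' @param inoculum Named non-negative inoculum vector (strain order of
#'   `fluxes`).
#' @param params A [model_params()].
#' @param fluxes A [flux_set()].
#' @param floor Log-abundance floor; default `1e-15`.
#' @param mode,tol Steady-state convention passed to [steady_state()];
#'   defaults `"passage3"` (the community reaches steady state by the third
#'   passage under strong dilution, and strains being excluded decline
#'   geometrically forever, so a log-change convergence loop would chase them
#'   to underflow) and `1e-8`.
#' @param ... Passed to [steady_state()].
#' @return A `crm_loo`: list with `delta` (removed-strain x strain matrix),
#'   `unperturbed` (steady-state vector) and `floor`.
#' @export
leave_one_out <- function(inoculum, params, fluxes, floor = 1e-15,
                          mode = "passage3", tol = 1e-8, ...) {
  stopifnot(inherits(params, "model_params"), inherits(fluxes, "flux_set"))
  n_S <- length(fluxes$strains)
  if (length(inoculum) != n_S) stop("inoculum length must match n_S", call. = FALSE)
  base <- steady_state(inoculum, params, fluxes, mode = mode, tol = tol, ...)
  if (any(base[inoculum > 0] <= floor)) {
    warning("strain(s) extinct (<= floor) in the unperturbed steady state; ",
            "deltas computed on floored values", call. = FALSE)
  }
  log_base <- log10(pmax(base, floor))
  delta <- matrix(NA_real_, n_S, n_S,
                  dimnames = list(removed = fluxes$strains,
                                  strain = fluxes$strains))
  for (s in seq_len(n_S)) {
    if (inoculum[s] == 0) {
      delta[s, ] <- 0
      delta[s, s] <- NA_real_
      next
    }
    N0 <- inoculum
    N0[s] <- 0
    pert <- steady_state(N0, params, fluxes, mode = mode, tol = tol, ...)
    d <- log10(pmax(pert, floor)) - log_base
    d[s] <- NA_real_
    delta[s, ] <- d
  }
  structure(list(delta = delta, unperturbed = base, floor = floor),
            class = "crm_loo")
}

#' @export
print.crm_loo <- function(x, ...) {
  cat("<crm_loo> ", nrow(x$delta), " leave-one-out removals; max |delta log10| = ",
      signif(max(abs(x$delta), na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Build the strain-strain interaction network from leave-one-out deltas
#'
#' Keeps an edge from removed strain `s` to perturbed strain `t` whenever
#' `|delta[s, t]|` exceeds `log10(fold_threshold)`. The edge is competitive
#' when the target's abundance increased upon removal (`delta > 0`) and
#' cooperative when it decreased; the weight is `|delta|`. Node attributes
#' aggregate weighted in/out degrees per interaction sign.
#'
#' @param loo A `crm_loo` from [leave_one_out()], or a bare delta matrix
#'   (removed x strain, `NA` diagonal).
#' @param fold_threshold Minimum fold change to call an interaction; default
#'   10.
#' @return A `crm_network`: list with tibbles `edges` (`source`, `target`,
#'   `sign`, `weight`) and `nodes` (per-sign weighted in/out degrees), plus
#'   `fold_threshold`.
#' @export
build_interaction_network <- function(loo, fold_threshold = 10) {
  if (fold_threshold <= 1) stop("fold_threshold must be > 1", call. = FALSE)
  delta <- if (inherits(loo, "crm_loo")) loo$delta else as.matrix(loo)
  cut <- log10(fold_threshold)
  idx <- which(!is.na(delta) & abs(delta) > cut, arr.ind = TRUE)
  edges <- tibble::tibble(
    source = rownames(delta)[idx[, 1]],
    target = colnames(delta)[idx[, 2]],
    sign = ifelse(delta[idx] > 0, "competitive", "cooperative"),
    weight = abs(delta[idx])
  ) |> dplyr::arrange(.data$source, .data$target)
  strains <- colnames(delta)
  deg <- function(tbl, key, sgn) {
    out <- setNames(numeric(length(strains)), strains)
    sub <- tbl[tbl$sign == sgn, ]
    agg <- tapply(sub$weight, sub[[key]], sum)
    out[names(agg)] <- agg
    unname(out)
  }
  nodes <- tibble::tibble(
    strain = strains,
    in_competitive = deg(edges, "target", "competitive"),
    in_cooperative = deg(edges, "target", "cooperative"),
    out_competitive = deg(edges, "source", "competitive"),
    out_cooperative = deg(edges, "source", "cooperative")
  )
  structure(list(edges = edges, nodes = nodes, fold_threshold = fold_threshold),
            class = "crm_network")
}

#' @export
print.crm_network <- function(x, ...) {
  cat("<crm_network> ", nrow(x$edges), " edges (",
      sum(x$edges$sign == "competitive"), " competitive, ",
      sum(x$edges$sign == "cooperative"), " cooperative) at fold threshold ",
      x$fold_threshold, "\n", sep = "")
  invisible(x)
}

#' Convert an interaction network to an igraph object
#'
#' @param network A `crm_network`.
#' @return An [igraph][igraph::graph_from_data_frame] directed graph with
#'   edge attributes `sign` and `weight`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "crm_network"))
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$nodes)
}

#' Resource-overlap competition score for an ordered strain pair
#'
#' Fraction of the resources consumed by the perturbed strain (among
#' resources present in the medium) that the removed strain also consumes.
#' 1 means complete dietary overlap, 0 disjoint diets. Undefined (`NA`) when
#' the perturbed strain consumes no present resource.
#'
#' @param removed,perturbed Strain identifiers (names or indices into the
#'   rows of `B`).
#' @param B Binary consumption matrix (strains x resources).
#' @param nonzero_R Logical mask of resources present in the medium
#'   (`R > 0`); default all `TRUE`.
#' @return A fraction in `[0, 1]`, or `NA`.
#' @export
competition_score <- function(removed, perturbed, B,
                              nonzero_R = rep(TRUE, ncol(B))) {
  cons_p <- B[perturbed, ] > 0 & nonzero_R
  if (!any(cons_p)) return(NA_real_)
  sum(cons_p & B[removed, ] > 0) / sum(cons_p)
}

#' Cross-feeding score for an ordered strain pair
#'
#' Fraction of the resources consumed by the perturbed strain that are
#' produced (`P_total > 0`) by the removed strain. 1 means the removed strain
#' produces everything the perturbed strain eats.
#'
#' @inheritParams competition_score
#' @param P_bin Binary production matrix (strains x resources,
#'   `P_total > 0`).
#' @param nonzero_R Optional mask restricting the consumed set to resources
#'   present in the medium; default no restriction.
#' @return A fraction in `[0, 1]`, or `NA` when the perturbed strain
#'   consumes nothing.
#' @export
crossfeeding_score <- function(removed, perturbed, B, P_bin,
                               nonzero_R = rep(TRUE, ncol(B))) {
  cons_p <- B[perturbed, ] > 0 & nonzero_R
  if (!any(cons_p)) return(NA_real_)
  sum(cons_p & P_bin[removed, ] > 0) / sum(cons_p)
}

#' Score every ordered strain pair and mark interaction edges
#'
#' Convenience table for comparing edge scores with background scores:
#' computes the competition and cross-feeding scores for all ordered pairs
#' (removed, perturbed) and joins the interaction sign from a network (pairs
#' without an edge get sign `"none"`).
#'
#' @param network A `crm_network`.
#' @param fluxes A [flux_set()].
#' @param threshold Binarization threshold applied to the consumption matrix;
#'   default 0.3.
#' @param nonzero_R Logical mask of present resources; default all `TRUE`.
#' @return Tibble with columns `removed`, `perturbed`, `sign`, `competition`,
#'   `crossfeeding`.
#' @export
pair_scores <- function(network, fluxes, threshold = 0.3,
                        nonzero_R = rep(TRUE, length(fluxes$resources))) {
  B <- (fluxes$C >= threshold) * 1
  P_bin <- (fluxes$P_total > 0) * 1
  strains <- fluxes$strains
  grid <- expand.grid(removed = strains, perturbed = strains,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$removed != grid$perturbed, ]
  out <- tibble::tibble(
    removed = grid$removed,
    perturbed = grid$perturbed,
    competition = mapply(competition_score, grid$removed, grid$perturbed,
                         MoreArgs = list(B = B, nonzero_R = nonzero_R)),
    crossfeeding = mapply(crossfeeding_score, grid$removed, grid$perturbed,
                          MoreArgs = list(B = B, P_bin = P_bin,
                                          nonzero_R = nonzero_R))
  )
  key <- paste(network$edges$source, network$edges$target, sep = "\r")
  sign <- setNames(network$edges$sign, key)
  out$sign <- dplyr::coalesce(sign[paste(out$removed, out$perturbed, sep = "\r")],
                              "none")
  out[, c("removed", "perturbed", "sign", "competition", "crossfeeding")]
}

#' Mann-Whitney comparison of edge scores against background scores
#'
#' Two-sided Mann-Whitney U test of whether the scores attached to one group
#' of strain pairs (e.g. cooperative edges) differ from a background group
#' (e.g. non-interacting plus competitive pairs). An exact p-value is used
#' for small tie-free samples (both groups < 20), otherwise the normal
#' approximation with tie correction.
#'
#' @param edge_scores,background_scores Numeric score vectors (NAs dropped).
#' @return Tibble with columns `U` (statistic for `edge_scores`),
#'   `p_value`, `n_edge`, `n_background`, and the two group means.
#' @export
score_group_test <- function(edge_scores, background_scores) {
  x <- edge_scores[!is.na(edge_scores)]
  y <- background_scores[!is.na(background_scores)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both score groups must be non-empty", call. = FALSE)
  }
  exact <- length(x) < 20 && length(y) < 20 && !any(duplicated(c(x, y)))
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = FALSE)
  )
  tibble::tibble(
    U = unname(ht$statistic), p_value = ht$p.value,
    n_edge = length(x), n_background = length(y),
    mean_edge = mean(x), mean_background = mean(y)
  )
}

#' Response of the community to amplifying a single resource
#'
#' Multiplies the concentration of one resource by `factor`, recomputes the
#' steady state from the inoculum, and returns the per-strain change in
#' `log10` steady-state abundance relative to the unperturbed community.
#'
#' @inheritParams leave_one_out
#' @param resource Resource identifier (name or column index).
#' @param factor Amplification factor (> 0); default 100. `factor = 1` gives
#'   zero change everywhere.
#' @param unperturbed Optional precomputed unperturbed steady state (to avoid
#'   recomputation inside screens).
#' @return Named per-strain vector of `delta log10` abundances.
#' @export
perturb_resource <- function(params, fluxes, inoculum, resource, factor = 100,
                             floor = 1e-15, mode = "passage3", tol = 1e-8,
                             unperturbed = NULL, ...) {
  if (factor <= 0) stop("factor must be > 0", call. = FALSE)
  if (is.null(unperturbed)) {
    unperturbed <- steady_state(inoculum, params, fluxes, mode = mode,
                                tol = tol, ...)
  }
  params2 <- params
  params2$R[resource] <- params2$R[resource] * factor
  pert <- steady_state(inoculum, params2, fluxes, mode = mode, tol = tol, ...)
  setNames(log10(pmax(as.numeric(pert), floor)) -
             log10(pmax(as.numeric(unperturbed), floor)), fluxes$strains)
}

#' Single-resource amplification screen
#'
#' Runs [perturb_resource()] for every resource present in the medium
#' (`R > 0` by default) and assembles the strain x resource matrix of
#' `delta log10` steady-state responses. A strain is flagged non-responsive
#' when fewer than `min_responses` resources move it by at least
#' `response_threshold` on the log10 scale (10-fold by default, matching the
#' interaction-network edge threshold).
#'
#' @inheritParams perturb_resource
#' @param resources Resources to screen; default all with `R > 0`.
#' @param response_threshold `|delta log10|` needed to count as a response;
#'   default 1.
#' @param min_responses Minimum number of moving resources for a strain to
#'   count as responsive; default 3.
#' @return A `crm_perturb`: list with `delta` (strain x resource matrix),
#'   `responsive` (named logical), `factor`, `response_threshold`,
#'   `min_responses`.
#' @export
perturbation_matrix <- function(params, fluxes, inoculum, factor = 100,
                                resources = NULL, response_threshold = 1,
                                min_responses = 3, floor = 1e-15,
                                mode = "passage3", tol = 1e-8, ...) {
  if (is.null(resources)) resources <- fluxes$resources[params$R > 0]
  base <- steady_state(inoculum, params, fluxes, mode = mode, tol = tol, ...)
  cols <- lapply(resources, function(i) {
    perturb_resource(params, fluxes, inoculum, i, factor = factor,
                     floor = floor, mode = mode, tol = tol,
                     unperturbed = base, ...)
  })
  delta <- do.call(cbind, cols)
  colnames(delta) <- resources
  rownames(delta) <- fluxes$strains
  responsive <- rowSums(abs(delta) >= response_threshold) >= min_responses
  structure(
    list(delta = delta, responsive = responsive, factor = factor,
         response_threshold = response_threshold,
         min_responses = min_responses, unperturbed = base),
    class = "crm_perturb"
  )
}

#' @export
print.crm_perturb <- function(x, ...) {
  cat("<crm_perturb> ", nrow(x$delta), " strains x ", ncol(x$delta),
      " amplified resources (factor ", x$factor, ")\n  responsive strains: ",
      sum(x$responsive), "/", length(x$responsive), "\n", sep = "")
  invisible(x)
}
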