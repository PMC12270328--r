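#' Consumption flux from before/after metabolite concentrations
#'
#' The consumption flux of a strain for a metabolite is one minus the ratio
#' of the metabolite's concentration after and before monoculture batch
#' growth, clipped into `[0, 1 - 1e-9]`. The cap just below 1 keeps the
#' log-domain cluster aggregation ([aggregate_cluster_fluxes()]) finite for
#' fully consumed metabolites.
#'
#' @param before,after Concentrations before (`> 0`) and after (`>= 0`) batch
#'   growth (vectorized).
#' @return Consumed fraction in `[0, 1 - 1e-9]`.
#' @export
consumption_flux <- function(before, after) {
  if (any(before <= 0)) stop("'before' concentrations must be > 0", call. = FALSE)
  if (any(after < 0)) stop("'after' concentrations must be >= 0", call. = FALSE)
  pmin(pmax(1 - after / before, 0), 1 - 1e-9)
}

#' Total production flux from before/after metabolite concentrations
#'
#' Fold-excess of a metabolite produced during monoculture batch growth:
#' `after / before - 1`, floored at 0 (net consumption is recorded as zero
#' production).
#'
#' @inheritParams consumption_flux
#' @return Fold-excess `>= 0`.
#' @export
production_flux_total <- function(before, after) {
  if (any(before <= 0)) stop("'before' concentrations must be > 0", call. = FALSE)
  if (any(after < 0)) stop("'after' concentrations must be >= 0", call. = FALSE)
  pmax(after / before - 1, 0)
}

#' Binarize consumption fluxes and partition metabolites
#'
#' Thresholds the consumption matrix into a binary consumer/non-consumer
#' matrix `B = [C >= threshold]` and partitions metabolites by consumer
#' count: metabolites consumed by more than `min_consumers` strains are
#' candidates for clustering, those consumed by at least one but at most
#' `min_consumers` strains become singleton clusters, and metabolites
#' consumed by nobody are dropped.
#'
#' @param C Consumption matrix (strains x resources) with dimnames.
#' @param threshold Binarization threshold in `(0, 1)`; default 0.3.
#' @param min_consumers Consumer-count cutoff separating clusterable from
#'   singleton metabolites; default 5.
#' @return List with the binary matrix `B` and character vectors
#'   `clusterable`, `singleton`, `dropped`.
#' @export
binarize_and_partition <- function(C, threshold = 0.3, min_consumers = 5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)", call. = FALSE)
  B <- (C >= threshold) * 1
  n_cons <- colSums(B)
  list(
    B = B,
    clusterable = colnames(C)[n_cons > min_consumers],
    singleton = colnames(C)[n_cons >= 1 & n_cons <= min_consumers],
    dropped = colnames(C)[n_cons == 0]
  )
}

#' Select the binarization threshold by degree-abundance correlation
#'
#' Scores each candidate threshold by the Spearman rank correlation between
#' each strain's degree in the binarized consumption matrix (number of
#' metabolites it consumes above threshold) and its steady-state abundance,
#' and returns the threshold with the highest correlation (ties broken toward
#' the smallest threshold). A threshold whose degree vector is constant gives
#' an undefined correlation and is scored `-Inf`.
#'
#' @param C Consumption matrix (strains x resources).
#' @param steady_abundances Positive per-strain steady-state abundances in
#'   the same strain order as `rownames(C)`.
#' @param thresholds Numeric vector of candidate thresholds.
#' @return The selected threshold, with the score table in attribute
#'   `scores` (tibble with columns `threshold`, `rho`).
#' @export
select_threshold <- function(C, steady_abundances, thresholds) {
  if (length(thresholds) < 1) stop("need at least one candidate threshold", call. = FALSE)
  if (any(steady_abundances <= 0)) {
    stop("steady_abundances must be > 0 for rank correlation", call. = FALSE)
  }
  thresholds <- sort(thresholds)
  rho <- vapply(thresholds, function(t) {
    deg <- rowSums(C >= t)
    if (length(unique(deg)) < 2) return(-Inf)
    suppressWarnings(cor(deg, steady_abundances, method = "spearman"))
  }, numeric(1))
  rho[is.na(rho)] <- -Inf
  best <- thresholds[which.max(rho)]
  structure(best, scores = tibble::tibble(threshold = thresholds, rho = rho))
}

#' Cluster metabolites by binarized consumption profiles
#'
#' Runs hierarchical agglomerative clustering (Euclidean distance, Ward
#' linkage) on the columns of the binary consumption matrix restricted to the
#' clusterable metabolites, cuts the tree into `n_clusters` groups, and
#' appends the singleton metabolites as their own clusters.
#'
#' @param partition Output of [binarize_and_partition()].
#' @param n_clusters Number of non-singleton clusters to cut; default 10.
#' @return A `cluster_map`: tibble with columns `metabolite`, `cluster`
#'   (label), `kind` (`"non-singleton"` or `"singleton"`), plus attribute
#'   `dropped` (metabolites consumed by nobody).
#' @export
cluster_metabolites <- function(partition, n_clusters = 10) {
  clusterable <- partition$clusterable
  if (length(clusterable) == 0) {
    assign_tbl <- tibble::tibble(metabolite = character(), cluster = character(),
                                 kind = character())
  } else {
    if (n_clusters < 1 || n_clusters > length(clusterable)) {
      stop("n_clusters must be between 1 and the number of clusterable metabolites",
           call. = FALSE)
    }
    Bc <- partition$B[, clusterable, drop = FALSE]
    hc <- hclust(dist(t(Bc), method = "euclidean"), method = "ward.D2")
    grp <- cutree(hc, k = n_clusters)
    assign_tbl <- tibble::tibble(
      metabolite = clusterable,
      cluster = sprintf("cluster_%02d", grp),
      kind = "non-singleton"
    )
  }
  singles <- tibble::tibble(
    metabolite = partition$singleton,
    cluster = partition$singleton,
    kind = "singleton"
  )
  out <- dplyr::bind_rows(assign_tbl, singles)
  structure(out, dropped = partition$dropped,
            class = c("cluster_map", class(out)))
}

#' Aggregate member fluxes of one metabolite cluster
#'
#' Per-strain geometric-mean aggregation in the log domain: consumption
#' fluxes are combined as `c = 1 - exp(mean(log(1 - c_j)))` (the geometric
#' mean of the surviving fractions, transformed back) and total production
#' fluxes as `p = exp(mean(log(1 + p_j))) - 1`. A singleton cluster returns
#' its metabolite's fluxes unchanged.
#'
#' @param C_sub,P_sub Strain x member-metabolite submatrices of consumption
#'   and total production fluxes for one cluster.
#' @return List with per-strain vectors `c` and `p`.
#' @export
aggregate_cluster_fluxes <- function(C_sub, P_sub) {
  C_sub <- as.matrix(C_sub)
  P_sub <- as.matrix(P_sub)
  if (ncol(C_sub) == 0) stop("cluster must be non-empty", call. = FALSE)
  if (any(C_sub >= 1)) stop("consumption fluxes must be < 1 (apply the 1 - 1e-9 cap)",
                            call. = FALSE)
  list(
    c = 1 - exp(rowMeans(log(1 - C_sub))),
    p = exp(rowMeans(log(1 + P_sub))) - 1
  )
}

#' Coarse-grain a flux set into metabolite clusters
#'
#' End-to-end coarse-graining: binarize the consumption matrix, partition
#' metabolites, cluster the clusterable ones ([cluster_metabolites()]), and
#' aggregate member fluxes per cluster ([aggregate_cluster_fluxes()]).
#' Cluster columns are ordered non-singleton clusters first (by label), then
#' singletons in input order.
#'
#' @param fluxes A [flux_set()] at individual-metabolite resolution.
#' @param threshold Binarization threshold; default 0.3.
#' @param min_consumers Consumer-count cutoff; default 5.
#' @param n_clusters Number of non-singleton clusters; default 10.
#' @return List with elements `fluxes` (cluster-level [flux_set()]) and
#'   `map` (the `cluster_map`).
#' @export
coarse_grain <- function(fluxes, threshold = 0.3, min_consumers = 5,
                         n_clusters = 10) {
  stopifnot(inherits(fluxes, "flux_set"))
  part <- binarize_and_partition(fluxes$C, threshold, min_consumers)
  map <- cluster_metabolites(part, n_clusters = n_clusters)
  cl_order <- c(
    sort(unique(map$cluster[map$kind == "non-singleton"])),
    map$cluster[map$kind == "singleton"]
  )
  C_capped <- pmin(fluxes$C, 1 - 1e-9)  # keep log(1 - c) finite
  agg <- lapply(cl_order, function(cl) {
    members <- map$metabolite[map$cluster == cl]
    aggregate_cluster_fluxes(
      C_capped[, members, drop = FALSE],
      fluxes$P_total[, members, drop = FALSE]
    )
  })
  C_new <- do.call(cbind, lapply(agg, `[[`, "c"))
  P_new <- do.call(cbind, lapply(agg, `[[`, "p"))
  colnames(C_new) <- colnames(P_new) <- cl_order
  rownames(C_new) <- rownames(P_new) <- fluxes$strains
  list(
    fluxes = flux_set(C_new, P_new),
    map = map
  )
}
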