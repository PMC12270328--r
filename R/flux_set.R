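#' Bundle consumption and production flux matrices for a community
#'
#' A `flux_set` holds the two strain-by-resource matrices that parameterize a
#' community: the consumption fluxes `C` (fraction of each resource consumed
#' per unit biomass during monoculture batch growth, in `[0, 1]`) and the
#' total production fluxes `P_total` (fold-excess of each resource produced in
#' monoculture, `>= 0`). Row names are strain labels, column names resource
#' (metabolite or metabolite-cluster) labels.
#'
#' @param C Numeric matrix (strains x resources) of consumption fluxes in
#'   `[0, 1]`. Must carry row and column names unless `strains`/`resources`
#'   are given.
#' @param P_total Numeric matrix of the same shape with total production
#'   fluxes (fold-excess, `>= 0`). Defaults to all zeros (no cross-feeding).
#' @param strains,resources Optional character vectors of labels overriding
#'   the dimnames of `C`.
#' @return An object of class `flux_set`: a list with elements `C`,
#'   `P_total`, `strains`, `resources`.
#' @examples
#' C <- matrix(c(0.8, 0.1, 0.2, 0.9), 2, 2,
#'             dimnames = list(c("sA", "sB"), c("m1", "m2")))
#' flux_set(C)
#' @export
flux_set <- function(C, P_total = NULL, strains = NULL, resources = NULL) {
  C <- as.matrix(C)
  if (is.null(strains)) strains <- rownames(C)
  if (is.null(resources)) resources <- colnames(C)
  if (is.null(strains)) strains <- paste0("strain_", seq_len(nrow(C)))
  if (is.null(resources)) resources <- paste0("resource_", seq_len(ncol(C)))
  if (anyDuplicated(strains)) stop("strain labels must be unique", call. = FALSE)
  if (anyDuplicated(resources)) stop("resource labels must be unique", call. = FALSE)
  if (length(strains) != nrow(C) || length(resources) != ncol(C)) {
    stop("label lengths inconsistent with matrix shape", call. = FALSE)
  }
  if (!is.numeric(C) || anyNA(C)) stop("C must be numeric without NA", call. = FALSE)
  if (any(C < 0) || any(C > 1)) stop("consumption fluxes must lie in [0, 1]", call. = FALSE)
  if (is.null(P_total)) {
    P_total <- matrix(0, nrow(C), ncol(C))
  }
  P_total <- as.matrix(P_total)
  if (!all(dim(P_total) == dim(C))) {
    stop("P_total must have the same shape as C", call. = FALSE)
  }
  if (!is.numeric(P_total) || anyNA(P_total) || any(P_total < 0)) {
    stop("production fluxes must be numeric and >= 0", call. = FALSE)
  }
  dimnames(C) <- dimnames(P_total) <- list(strains, resources)
  structure(
    list(C = C, P_total = P_total, strains = strains, resources = resources),
    class = "flux_set"
  )
}

#' @export
print.flux_set <- function(x, ...) {
  cat("<flux_set> ", length(x$strains), " strains x ", length(x$resources),
      " resources\n", sep = "")
  cat("  consumption: ", sum(x$C > 0), " non-zero entries (density ",
      signif(mean(x$C > 0), 3), ")\n", sep = "")
  cat("  production:  ", sum(x$P_total > 0), " non-zero entries\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.flux_set <- function(x, ...) {
  tibble::tibble(
    strain = rep(x$strains, times = length(x$resources)),
    resource = rep(x$resources, each = length(x$strains)),
    consumption = as.vector(x$C),
    production_total = as.vector(x$P_total)
  )
}

#' Model parameters for the serial-dilution consumer-resource model
#'
#' Collects the environment-side parameters of the model: the medium resource
#' concentration vector `R` (in normalized biomass units), the time fraction
#' `f` weighting the geometric mean of start- and end-of-cycle abundances, the
#' dilution factor `D`, the per-biomass production matrix `P`, and the
#' monoculture biomasses `N_alone` used to normalize production fluxes.
#'
#' `f` is the single exponent that absorbs resource depletion timing: `f`
#' close to 1 means resources deplete late in the growth cycle, so the
#' end-of-cycle abundance dominates the resource-sharing weights.
#'
#' @param R Named (by resource) non-negative numeric vector of resource
#'   concentrations in biomass units.
#' @param f Time fraction in `[0, 1]`; default 0.9.
#' @param D Dilution factor (> 1); default 15000.
#' @param P Optional per-biomass production matrix (strains x resources,
#'   `>= 0`). Defaults to all zeros.
#' @param N_alone Optional positive vector of monoculture biomasses, one per
#'   strain (only required when `P` is derived from total production fluxes).
#' @return An object of class `model_params`.
#' @seealso [derive_params()] to construct parameters from a [flux_set()] and
#'   a resource vector using the mass-conservation estimate of `N_alone`.
#' @export
model_params <- function(R, f = 0.9, D = 15000, P = NULL, N_alone = NULL) {
  R <- as.numeric(R) |> setNames(names(R))
  if (anyNA(R) || any(R < 0)) stop("R must be >= 0", call. = FALSE)
  if (length(f) != 1 || f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  if (length(D) != 1 || D <= 1) stop("D must be > 1", call. = FALSE)
  if (!is.null(P)) {
    P <- as.matrix(P)
    if (ncol(P) != length(R)) stop("P column count must match length(R)", call. = FALSE)
    if (any(P < 0)) stop("P must be >= 0", call. = FALSE)
  }
  if (!is.null(N_alone) && any(N_alone <= 0)) {
    stop("N_alone must be > 0", call. = FALSE)
  }
  structure(
    list(R = R, f = f, D = D, P = P, N_alone = N_alone),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> n_R = ", length(x$R), ", f = ", x$f, ", D = ", x$D,
      "\n  total resource supply: ", signif(sum(x$R), 4),
      if (is.null(x$P) || all(x$P == 0)) "\n  no cross-feeding" else
        "\n  with cross-feeding", "\n", sep = "")
  invisible(x)
}

#' Derive model parameters from fluxes and a resource vector
#'
#' Computes the monoculture biomass of each strain by mass conservation,
#' `N_alone[g] = sum_i R[i] * [C[g, i] > 0]` (a strain growing alone consumes
#' every resource it can reach in full), and normalizes the total production
#' fluxes to per-biomass fluxes `P = P_total / N_alone` row-wise. Strains
#' consuming no non-zero resource get `N_alone` floored at `floor` with a
#' warning.
#'
#' @param fluxes A [flux_set()].
#' @inheritParams model_params
#' @param floor Positive floor for `N_alone` of strains that consume nothing
#'   in the medium; default `1e-12`.
#' @return A [model_params()] object.
#' @export
derive_params <- function(fluxes, R, f = 0.9, D = 15000, floor = 1e-12) {
  stopifnot(inherits(fluxes, "flux_set"))
  if (length(R) != length(fluxes$resources)) {
    stop("length(R) must match the number of resources", call. = FALSE)
  }
  R <- setNames(as.numeric(R), fluxes$resources)
  N_alone <- monoculture_null(R, fluxes$C)
  if (any(N_alone <= 0)) {
    warning("some strains consume no non-zero resource; N_alone floored at ",
            floor, call. = FALSE)
    N_alone <- pmax(N_alone, floor)
  }
  P <- fluxes$P_total / N_alone
  model_params(R = R, f = f, D = D, P = P, N_alone = N_alone)
}
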