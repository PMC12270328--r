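#' Generate a random sparse flux set for a synthetic community
#'
#' Draws a strain x resource consumption matrix in which each entry is
#' non-zero with probability `consumer_density`, with magnitudes uniform on
#' `(0.3, 1)` so that binarization at the default 0.3 threshold keeps every
#' realized consumer, and a sparse non-negative total production matrix with
#' log-normal magnitudes centred on a 1% fold-excess: byproduct excesses are
#' small relative to bolus concentrations in rich media, which also keeps the
#' linear cross-feeding feedback subcritical (below unit gain) even under
#' strong single-resource amplification, so perturbation experiments retain a
#' finite steady state. Draws in which some strain consumes nothing or some
#' resource has no consumer are rejected and redrawn (such communities are
#' not viable under the model); after `max_tries` rejections an error is
#' raised.
#'
#' @param n_strains,n_resources Community dimensions.
#' @param consumer_density Probability that a strain consumes a given
#'   resource; default 0.3.
#' @param producer_density Probability that a strain produces a given
#'   resource; default 0.1.
#' @param seed Optional integer seed.
#' @param max_tries Rejection-sampling cap; default 100.
#' @return A [flux_set()].
#' @export
generate_fluxes <- function(n_strains, n_resources, consumer_density = 0.3,
                            producer_density = 0.1, seed = NULL,
                            max_tries = 100) {
  if (consumer_density <= 0 || consumer_density > 1 ||
      producer_density < 0 || producer_density > 1) {
    stop("densities must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  strains <- sprintf("strain_%02d", seq_len(n_strains))
  resources <- sprintf("res_%02d", seq_len(n_resources))
  for (try in seq_len(max_tries)) {
    mask <- matrix(runif(n_strains * n_resources) < consumer_density,
                   n_strains, n_resources)
    if (any(rowSums(mask) == 0) || any(colSums(mask) == 0)) next
    C <- matrix(0, n_strains, n_resources)
    C[mask] <- runif(sum(mask), 0.3, 1)
    P <- matrix(0, n_strains, n_resources)
    pmask <- matrix(runif(n_strains * n_resources) < producer_density,
                    n_strains, n_resources)
    P[pmask] <- rlnorm(sum(pmask), meanlog = log(0.01), sdlog = 0.5)
    return(flux_set(C, P, strains = strains, resources = resources))
  }
  stop("could not generate a fully covered flux set in ", max_tries,
       " tries; increase consumer_density", call. = FALSE)
}

#' Define a synthetic serial-dilution study
#'
#' Bundles everything needed to simulate a synthetic serial-dilution
#' experiment whose statistical structure matches what the inference
#' assumes: a true flux set, a true resource vector, the experimental
#' protocol (dilution factor, passage count, replicate count) and a
#' multiplicative log-normal replicate-noise level. The true monoculture
#' biomasses follow from mass conservation
#' (`N_alone = sum of consumed R`), so the per-biomass production fluxes are
#' internally consistent with the true `R`.
#'
#' @param n_strains,n_resources Community dimensions; defaults 30 and 20
#'   (keeps 3 replicates comfortably overdetermined for the NNLS fit).
#' @param f True time fraction; default 0.9.
#' @param D Dilution factor; default 15000.
#' @param sigma Replicate noise standard deviation on the log10 scale;
#'   default 0.3 (comparable to biological replicate scatter in rich-medium
#'   serial-dilution data); 0 gives identical replicates.
#' @param n_replicates Biological replicates; default 3.
#' @param n_passages Passages to simulate; default 3.
#' @param consumer_density,producer_density Passed to [generate_fluxes()].
#' @param seed Integer seed; default 1.
#' @return A `crm_scenario`: list with `fluxes`, `params` (true
#'   [model_params()]), `R` (true vector), `inoculum`, `sigma`,
#'   `n_replicates`, `n_passages`, `seed`.
#' @export
synthetic_scenario <- function(n_strains = 30, n_resources = 20, f = 0.9,
                               D = 15000, sigma = 0.3, n_replicates = 3,
                               n_passages = 3, consumer_density = 0.3,
                               producer_density = 0.1, seed = 1) {
  set.seed(seed)
  fluxes <- generate_fluxes(n_strains, n_resources,
                            consumer_density = consumer_density,
                            producer_density = producer_density)
  R <- setNames(runif(n_resources, 0.05, 1), fluxes$resources)
  params <- derive_params(fluxes, R, f = f, D = D)
  inoculum <- runif(n_strains, 0.2, 1)
  inoculum <- setNames(inoculum / sum(inoculum), fluxes$strains)
  structure(
    list(fluxes = fluxes, params = params, R = R, inoculum = inoculum,
         sigma = sigma, n_replicates = n_replicates,
         n_passages = n_passages, seed = seed),
    class = "crm_scenario"
  )
}

#' @export
print.crm_scenario <- function(x, ...) {
  cat("<crm_scenario> ", length(x$fluxes$strains), " strains x ",
      length(x$fluxes$resources), " resources; f = ", x$params$f,
      ", D = ", x$params$D, ", sigma = ", x$sigma, ", ",
      x$n_replicates, " replicates, ", x$n_passages, " passages (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Simulate the observed abundance table of a synthetic study
#'
#' Runs the exact forward dynamics ([simulate_passages()]) once, then applies
#' independent multiplicative log-normal replicate noise
#' (`N_obs = N * 10^rnorm(0, sigma)`) to every passage of each replicate.
#' With `sigma = 0` all replicates equal the exact trajectory. When
#' `normalize = TRUE`, each replicate at each passage is rescaled to relative
#' abundances summing to 1 (the standard treatment for sequencing-derived
#' compositional data); the default keeps the model's absolute
#' (yield-rescaled) biomass units so that inferred concentrations are
#' directly comparable to the scenario's truth.
#'
#' @param scenario A `crm_scenario` from [synthetic_scenario()].
#' @param normalize Renormalize each replicate to relative abundance;
#'   default `FALSE`.
#' @param n_iter Fixed-point sweeps per passage; default 200 (tight forward
#'   trajectories so the noiseless data sit exactly on the model).
#' @param seed Optional seed for the noise draws; defaults to
#'   `scenario$seed + 1`.
#' @return List with `abundance` (long tibble: `strain`, `passage`,
#'   `replicate`, `abundance`) and `trajectory` (the exact noiseless
#'   `crm_trajectory`).
#' @export
simulate_experiment <- function(scenario, normalize = FALSE, n_iter = 200,
                                seed = NULL) {
  stopifnot(inherits(scenario, "crm_scenario"))
  if (is.null(seed)) seed <- scenario$seed + 1
  traj <- simulate_passages(scenario$inoculum, scenario$params,
                            scenario$fluxes, n_passages = scenario$n_passages,
                            n_iter = n_iter)
  set.seed(seed)
  reps <- lapply(seq_len(scenario$n_replicates), function(r) {
    x <- traj
    if (scenario$sigma > 0) {
      noise <- 10^rnorm(nrow(x), 0, scenario$sigma)
      x$abundance <- x$abundance * noise
      if (normalize) {
        x <- x |>
          dplyr::group_by(.data$passage) |>
          dplyr::mutate(abundance = .data$abundance / sum(.data$abundance)) |>
          dplyr::ungroup()
      }
    }
    x$replicate <- r
    x
  })
  abundance <- dplyr::bind_rows(reps)[, c("strain", "passage", "replicate",
                                          "abundance")]
  list(abundance = tibble::as_tibble(abundance), trajectory = traj)
}

#' Reshape a long abundance table into a strain x replicate matrix
#'
#' @param abundance Long tibble with columns `strain`, `passage`,
#'   `replicate`, `abundance`.
#' @param passage Passage to extract.
#' @param strains Optional strain order for the rows; default the order of
#'   first appearance.
#' @return Strain x replicate numeric matrix.
#' @export
abundance_matrix <- function(abundance, passage, strains = NULL) {
  x <- abundance[abundance$passage == passage, ]
  if (nrow(x) == 0) stop("passage ", passage, " not present in the table",
                         call. = FALSE)
  if (is.null(strains)) strains <- unique(x$strain)
  reps <- sort(unique(x$replicate))
  out <- matrix(NA_real_, length(strains), length(reps),
                dimnames = list(strains, paste0("rep_", reps)))
  for (j in seq_along(reps)) {
    sub <- x[x$replicate == reps[j], ]
    idx <- match(strains, sub$strain)
    if (anyNA(idx)) stop("replicate ", reps[j], " is missing strain(s): ",
                         paste(strains[is.na(idx)], collapse = ", "),
                         call. = FALSE)
    out[, j] <- sub$abundance[idx]
  }
  out
}
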