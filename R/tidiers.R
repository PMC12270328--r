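# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a fitted resource-concentration model
#'
#' @param x A `crm_fit` from [infer_resources()].
#' @param ... Unused.
#' @return Tibble with columns `resource`, `R`, `nonzero`.
#' @exportS3Method generics::tidy crm_fit
tidy.crm_fit <- function(x, ...) {
  tibble::tibble(resource = names(x$R), R = as.numeric(x$R),
                 nonzero = x$R > 0)
}

#' @rdname tidy.crm_fit
#' @return `glance()` returns a one-row tibble with `n_resources`,
#'   `n_nonzero`, `residual`, `n_outer_used`, `delta_n_alone`, `f`, `D`.
#' @exportS3Method generics::glance crm_fit
glance.crm_fit <- function(x, ...) {
  tibble::tibble(
    n_resources = length(x$R), n_nonzero = sum(x$R > 0),
    residual = x$residual, n_outer_used = x$n_outer_used,
    delta_n_alone = x$delta_n_alone, f = x$f, D = x$D
  )
}

#' Tidy leave-one-out deltas into long format
#'
#' @param x A `crm_loo` from [leave_one_out()].
#' @param ... Unused.
#' @return Tibble with columns `removed`, `strain`, `delta_log10` (diagonal
#'   rows dropped).
#' @exportS3Method generics::tidy crm_loo
tidy.crm_loo <- function(x, ...) {
  out <- tibble::tibble(
    removed = rep(rownames(x$delta), times = ncol(x$delta)),
    strain = rep(colnames(x$delta), each = nrow(x$delta)),
    delta_log10 = as.vector(x$delta)
  )
  out[!is.na(out$delta_log10), ]
}

#' Tidy an interaction network into its edge list
#'
#' @param x A `crm_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy crm_network
tidy.crm_network <- function(x, ...) x$edges

#' @rdname tidy.crm_network
#' @exportS3Method generics::glance crm_network
glance.crm_network <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x$edges),
    n_competitive = sum(x$edges$sign == "competitive"),
    n_cooperative = sum(x$edges$sign == "cooperative"),
    n_sources = length(unique(x$edges$source)),
    n_targets = length(unique(x$edges$target)),
    fold_threshold = x$fold_threshold
  )
}

#' Tidy a single-resource perturbation screen
#'
#' @param x A `crm_perturb` from [perturbation_matrix()].
#' @param ... Unused.
#' @return Tibble with columns `strain`, `resource`, `delta_log10`,
#'   `responsive`.
#' @exportS3Method generics::tidy crm_perturb
tidy.crm_perturb <- function(x, ...) {
  tibble::tibble(
    strain = rep(rownames(x$delta), times = ncol(x$delta)),
    resource = rep(colnames(x$delta), each = nrow(x$delta)),
    delta_log10 = as.vector(x$delta),
    responsive = rep(unname(x$responsive), times = ncol(x$delta))
  )
}

#' Tidy greedy-equalization run profiles
#'
#' @param x A `crm_greedy` from [greedy_equalize()].
#' @param ... Unused.
#' @return Tibble of accepted moves with columns `run`, `step`, `resource`,
#'   `direction`, `objective`.
#' @exportS3Method generics::tidy crm_greedy
tidy.crm_greedy <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$runs), function(r) {
    dplyr::mutate(x$runs[[r]], run = r, .before = 1)
  }))
}

#' @rdname tidy.crm_greedy
#' @exportS3Method generics::glance crm_greedy
glance.crm_greedy <- function(x, ...) {
  tibble::tibble(
    n_runs = length(x$runs),
    objective_initial = x$objective_initial,
    objective_final_mean = mean(x$objective_final),
    objective_final_best = min(x$objective_final),
    n_steps_mean = mean(vapply(x$runs, nrow, integer(1))),
    any_truncated = any(vapply(x$runs, attr, logical(1), "truncated"))
  )
}

#' Tidy a time-fraction grid scan
#'
#' @param x A `crm_fscan` from [estimate_time_fraction()].
#' @param ... Unused.
#' @exportS3Method generics::tidy crm_fscan
tidy.crm_fscan <- function(x, ...) x$scores

#' Plot a simulated serial-dilution trajectory
#'
#' Strain abundances (log10) across passages, one line per strain.
#'
#' @param object A `crm_trajectory` from [simulate_passages()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot crm_trajectory
autoplot.crm_trajectory <- function(object, ...) {
  dat <- object[object$abundance > 0, ]
  ggplot2::ggplot(dat, ggplot2::aes(.data$passage, .data$abundance,
                                    group = .data$strain,
                                    colour = .data$strain)) +
    ggplot2::geom_line(alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_point(size = 1, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "passage", y = "abundance (biomass units)") +
    ggplot2::theme_minimal()
}

#' Plot a time-fraction scan
#'
#' @param object A `crm_fscan`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot crm_fscan
autoplot.crm_fscan <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(.data$f, .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$f_best, linetype = 2) +
    ggplot2::labs(x = "time fraction f",
                  y = "Pearson r (log10 predicted vs observed)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a single-resource perturbation screen
#'
#' @param object A `crm_perturb`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot crm_perturb
autoplot.crm_perturb <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$resource, .data$strain,
                               fill = .data$delta_log10)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = expression(Delta ~ log[10] ~ N)) +
    ggplot2::labs(x = "amplified resource", y = "strain") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Objective traces of the greedy equalization runs
#'
#' @param object A `crm_greedy`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot crm_greedy
autoplot.crm_greedy <- function(object, ...) {
  steps <- tidy(object)
  start <- tibble::tibble(run = seq_along(object$runs), step = 0,
                          objective = object$objective_initial)
  dat <- dplyr::bind_rows(start, steps[, c("run", "step", "objective")])
  ggplot2::ggplot(dat, ggplot2::aes(.data$step, .data$objective,
                                    group = .data$run,
                                    colour = factor(.data$run))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "accepted move", y = "log10-RMSD from equal abundance",
                  colour = "run") +
    ggplot2::theme_minimal()
}
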