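test_that("removing a fully decoupled strain leaves the rest untouched", {
  # strain c consumes its own private resource and produces nothing
  C <- rbind(a = c(0.8, 0.4, 0), b = c(0.5, 0.6, 0), c = c(0, 0, 0.9))
  colnames(C) <- c("m1", "m2", "m3")
  fl <- flux_set(C)
  pp <- derive_params(fl, c(1, 0.5, 0.8), f = 0.9, D = 15000)
  loo <- leave_one_out(c(0.1, 0.1, 0.1), pp, fl)
  expect_true(all(abs(loo$delta["c", c("a", "b")]) < 1e-10))
  expect_true(all(abs(loo$delta[c("a", "b"), "c"]) < 1e-10))
  expect_true(is.na(loo$delta["a", "a"]))
})

test_that("removing one of two identical competitors doubles the survivor's share", {
  C <- matrix(c(1, 1), 2, 1, dimnames = list(c("a", "b"), "m"))
  fl <- flux_set(C)
  pp <- derive_params(fl, 1, f = 0.9, D = 1e6)  # D >> 1: carry-over negligible
  loo <- leave_one_out(c(0.01, 0.01), pp, fl,
                       mode = "converge", tol = 1e-10, max_passages = 50)
  expect_equal(loo$delta["a", "b"], log10(2), tolerance = 1e-6)
})

test_that("removing an absent strain changes nothing", {
  inst <- random_instance(17, n_S = 5, n_R = 8)
  N0 <- inst$N_prev
  N0[3] <- 0
  loo <- leave_one_out(N0, inst$params, inst$fluxes)
  expect_true(all(loo$delta[3, -3] == 0))
})

test_that("network edges follow the fold-change threshold and sign convention", {
  delta <- matrix(c(NA, 1.5, -0.5,
                    0.2, NA, -2.0,
                    0.0, 0.9, NA), 3, 3, byrow = TRUE,
                  dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  net <- build_interaction_network(delta, fold_threshold = 10)
  expect_equal(nrow(net$edges), 2)
  e1 <- net$edges[net$edges$source == "s1", ]
  expect_equal(e1$sign, "competitive")
  expect_equal(e1$weight, 1.5)
  e2 <- net$edges[net$edges$source == "s2", ]
  expect_equal(e2$sign, "cooperative")
  expect_equal(e2$weight, 2.0)
  expect_equal(net$nodes$in_cooperative[net$nodes$strain == "s3"], 2.0)
  expect_equal(net$nodes$out_competitive[net$nodes$strain == "s1"], 1.5)
  g <- as_igraph(net)
  expect_equal(igraph::ecount(g), 2)
})

test_that("competition and cross-feeding scores count shared metabolites", {
  B <- rbind(removed = c(1, 1, 0, 0, 0), perturbed = c(1, 1, 1, 1, 0))
  expect_equal(competition_score("removed", "perturbed", B), 0.5)
  expect_equal(competition_score("perturbed", "perturbed", B), 1)
  B2 <- rbind(r = c(1, 0), p = c(0, 1))
  expect_equal(competition_score("r", "p", B2), 0)
  P_bin <- rbind(r = c(0, 1, 0, 1, 1), p = c(0, 0, 0, 0, 0))
  Bc <- rbind(r = c(0, 0, 0, 0, 0), p = c(1, 1, 1, 1, 0))
  expect_equal(crossfeeding_score("r", "p", Bc, P_bin), 0.5)
  expect_equal(crossfeeding_score("r", "p", Bc, P_bin * 0), 0)
  # empty denominator is undefined
  expect_true(is.na(competition_score("r", "p", Bc * 0)))
})

test_that("the Mann-Whitney comparison matches exact enumeration", {
  res <- score_group_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)  # 2 / choose(6, 3)
  same <- score_group_test(c(0.2, 0.4, 0.6, 0.8), c(0.2, 0.4, 0.6, 0.8))
  expect_gt(same$p_value, 0.95)
  expect_error(score_group_test(numeric(0), 1:3), "non-empty")
})

test_that("resource amplification scales a lone consumer linearly", {
  fl <- flux_set(matrix(1, 1, 1, dimnames = list("s", "m")))
  pp <- derive_params(fl, 1, f = 0.9, D = 1e6)
  d <- perturb_resource(pp, fl, 0.01, "m", factor = 100,
                        mode = "converge", tol = 1e-10, max_passages = 50)
  expect_equal(unname(d), 2, tolerance = 1e-6)
  expect_equal(unname(perturb_resource(pp, fl, 0.01, "m", factor = 1)), 0)
})

test_that("the amplification screen covers present resources and flags responders", {
  sc <- synthetic_scenario(n_strains = 10, n_resources = 15, sigma = 0,
                           producer_density = 0.1, seed = 41)
  pm <- perturbation_matrix(sc$params, sc$fluxes, sc$inoculum, factor = 100)
  expect_equal(ncol(pm$delta), sum(sc$params$R > 0))
  expect_true(all(is.finite(pm$delta)))
  pm1 <- perturbation_matrix(sc$params, sc$fluxes, sc$inoculum, factor = 1)
  expect_true(all(pm1$delta == 0))
  expect_true(all(!pm1$responsive))
  td <- tidy(pm)
  expect_named(td, c("strain", "resource", "delta_log10", "responsive"))
  expect_s3_class(autoplot(pm), "ggplot")
})

test_that("the equalization objective measures log-distance from uniformity", {
  expect_equal(equalization_objective(c(0.2, 0.2)), 0)
  expect_equal(equalization_objective(rep(3, 7)), 0)
  expected <- sqrt((log10(1 / 50.5)^2 + log10(100 / 50.5)^2) / 2)
  expect_equal(equalization_objective(c(1, 100)), expected, tolerance = 1e-12)
})

test_that("greedy equalization is monotone, floored at the base medium, and reproducible", {
  sc <- synthetic_scenario(n_strains = 10, n_resources = 15, sigma = 0,
                           producer_density = 0.1, seed = 43)
  gr <- greedy_equalize(sc$params, sc$fluxes, sc$inoculum, max_steps = 40,
                        n_runs = 2, seed = 5)
  for (run in gr$runs) {
    if (nrow(run) > 1) expect_true(all(diff(run$objective) < 0))
    if (nrow(run) > 0) expect_true(all(run$objective < gr$objective_initial))
  }
  expect_true(all(gr$R_final >= gr$R_base - 1e-15))
  gr2 <- greedy_equalize(sc$params, sc$fluxes, sc$inoculum, max_steps = 40,
                         n_runs = 2, seed = 5)
  expect_identical(gr$R_final, gr2$R_final)
  expect_identical(tidy(gr), tidy(gr2))
  expect_s3_class(autoplot(gr), "ggplot")
})

test_that("an already uniform community is a greedy local optimum", {
  # identical strains sharing one resource equally are perfectly uniform
  C <- matrix(c(1, 1), 2, 1, dimnames = list(c("a", "b"), "m"))
  fl <- flux_set(C)
  pp <- derive_params(fl, 1, f = 0.9, D = 15000)
  gr <- greedy_equalize(pp, fl, c(0.01, 0.01), max_steps = 10, n_runs = 1,
                        seed = 1)
  expect_equal(nrow(gr$runs[[1]]), 0)
  expect_equal(gr$objective_initial, 0, tolerance = 1e-10)
})
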