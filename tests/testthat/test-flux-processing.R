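test_that("fluxes derived from before/after concentrations follow the ratio rules", {
  expect_equal(consumption_flux(10, 10), 0)
  expect_equal(consumption_flux(10, 5), 0.5)
  expect_equal(consumption_flux(10, 0), 1 - 1e-9)   # complete consumption capped
  expect_equal(consumption_flux(10, 20), 0)          # net production clips
  expect_error(consumption_flux(0, 5), "before")
  expect_equal(production_flux_total(10, 10), 0)
  expect_equal(production_flux_total(10, 30), 2)
  expect_equal(production_flux_total(10, 5), 0)      # net consumption clips
  expect_error(production_flux_total(-1, 5), "before")
})

test_that("binarization partitions metabolites by consumer count", {
  # 8 strains; col1: 6 consumers -> clusterable; col2: 1 -> singleton;
  # col3: none -> dropped; col4: exactly 5 -> singleton (needs > 5)
  C <- cbind(c(0.31, 0.29, 0.9, 0.5, 0.4, 0.35, 0.6, 0.1),
             c(0.8, rep(0.1, 7)),
             rep(0.05, 8),
             c(rep(0.5, 5), rep(0.2, 3)))
  dimnames(C) <- list(paste0("s", 1:8), c("mA", "mB", "mC", "mD"))
  part <- binarize_and_partition(C, threshold = 0.3, min_consumers = 5)
  expect_equal(part$clusterable, "mA")
  expect_setequal(part$singleton, c("mB", "mD"))
  expect_equal(part$dropped, "mC")
  expect_true(all(part$B %in% c(0, 1)))
})

test_that("threshold selection maximizes the degree-abundance rank correlation", {
  expect_equal(as.numeric(select_threshold(matrix(runif(20), 4, 5),
                                           runif(4, 0.1, 1), 0.4)), 0.4)
  # construct data where abundance is exactly proportional to degree at t* = 0.5
  set.seed(8)
  C <- matrix(runif(30 * 40), 30, 40)
  deg <- rowSums(C >= 0.5)
  abund <- 2 * deg + 1  # monotone in degree, same tie pattern -> rho = 1
  got <- select_threshold(C, abund, c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(as.numeric(got), 0.5)
  scores <- attr(got, "scores")
  expect_equal(scores$rho[scores$threshold == 0.5], 1, tolerance = 1e-12)
})

test_that("clustering separates identical binary profiles and appends singletons", {
  B <- cbind(g1a = c(1, 1, 1, 1, 1, 1, 0, 0), g1b = c(1, 1, 1, 1, 1, 1, 0, 0),
             g2a = c(0, 0, 1, 1, 1, 1, 1, 1), g2b = c(0, 0, 1, 1, 1, 1, 1, 1))
  part <- list(B = B, clusterable = colnames(B), singleton = "lonely",
               dropped = character())
  map <- cluster_metabolites(part, n_clusters = 2)
  grp <- setNames(map$cluster, map$metabolite)
  expect_equal(grp[["g1a"]], grp[["g1b"]])
  expect_equal(grp[["g2a"]], grp[["g2b"]])
  expect_false(grp[["g1a"]] == grp[["g2a"]])
  expect_equal(map$kind[map$metabolite == "lonely"], "singleton")
  # n_clusters = number of metabolites -> every metabolite its own cluster
  map2 <- cluster_metabolites(part, n_clusters = 4)
  expect_equal(length(unique(map2$cluster[map2$kind == "non-singleton"])), 4)
})

test_that("cluster flux aggregation matches its closed forms", {
  # two metabolites with c = (0, 0.75): 1 - exp(-(0 + log 4)/2) = 0.5
  agg <- aggregate_cluster_fluxes(matrix(c(0, 0.75), 1, 2),
                                  matrix(c(0, 0), 1, 2))
  expect_equal(agg$c, 0.5, tolerance = 1e-12)
  # equal members are a fixed point of the aggregation
  agg2 <- aggregate_cluster_fluxes(matrix(0.5, 3, 2), matrix(2, 3, 2))
  expect_equal(agg2$c, rep(0.5, 3))
  expect_equal(agg2$p, rep(2, 3))
  # singleton cluster is the identity
  agg3 <- aggregate_cluster_fluxes(matrix(0.37, 1, 1), matrix(1.4, 1, 1))
  expect_equal(agg3$c, 0.37, tolerance = 1e-12)
  expect_equal(agg3$p, 1.4, tolerance = 1e-12)
})

test_that("aggregated fluxes are bounded by their member ranges", {
  set.seed(4)
  for (rep in 1:20) {
    C_sub <- matrix(runif(12, 0, 0.99), 3, 4)
    P_sub <- matrix(rlnorm(12, -1, 1), 3, 4)
    agg <- aggregate_cluster_fluxes(C_sub, P_sub)
    expect_true(all(agg$c >= apply(C_sub, 1, min) - 1e-12))
    expect_true(all(agg$c <= apply(C_sub, 1, max) + 1e-12))
    expect_true(all(agg$c >= 0 & agg$c < 1))
    expect_true(all(agg$p >= 0))
  }
})

test_that("coarse-graining is invariant to metabolite input order", {
  set.seed(5)
  fx <- generate_fluxes(12, 15, consumer_density = 0.6, producer_density = 0.2)
  cg1 <- coarse_grain(fx, n_clusters = 3)
  perm <- sample(15)
  fx2 <- flux_set(fx$C[, perm], fx$P_total[, perm],
                  resources = fx$resources[perm])
  cg2 <- coarse_grain(fx2, n_clusters = 3)
  # same partition of metabolites into groups, whatever the labels
  part1 <- split(cg1$map$metabolite, cg1$map$cluster)
  part2 <- split(cg2$map$metabolite, cg2$map$cluster)
  canon <- function(p) sort(vapply(p, function(m) paste(sort(m), collapse = "|"),
                                   character(1)))
  expect_equal(unname(canon(part1)), unname(canon(part2)))
})

test_that("coarse-graining a full flux set keeps shapes and units coherent", {
  set.seed(6)
  fx <- generate_fluxes(12, 20, consumer_density = 0.5, producer_density = 0.2)
  cg <- coarse_grain(fx, threshold = 0.3, min_consumers = 5, n_clusters = 2)
  expect_s3_class(cg$fluxes, "flux_set")
  n_clusters_total <- length(unique(cg$map$cluster))
  expect_equal(length(cg$fluxes$resources), n_clusters_total)
  expect_true(all(cg$fluxes$C >= 0 & cg$fluxes$C < 1))
  expect_true(all(cg$fluxes$P_total >= 0))
  expect_setequal(c(cg$map$metabolite, attr(cg$map, "dropped")), fx$resources)
})
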