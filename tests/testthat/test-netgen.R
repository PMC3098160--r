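test_that("source topology generation is deterministic, connected and signed", {
  net1 <- generate_source_topology(100, avg_degree = 2, activation_fraction = 0.6, seed = 1)
  net2 <- generate_source_topology(100, avg_degree = 2, activation_fraction = 0.6, seed = 1)
  expect_identical(net1$edges, net2$edges)
  expect_equal(net1$n, 100)
  # ~ n * avg_degree edges for a preferential-attachment growth
  expect_gt(nrow(net1$edges), 150)
  expect_lt(nrow(net1$edges), 250)
  expect_true(all(net1$edges$sign %in% c(-1L, 1L)))
  expect_false(any(net1$edges$regulator == net1$edges$target))
  # weak connectivity: growth from any seed must be able to exhaust the graph
  full <- extract_subnetwork(net1, 100, seed = 5)
  expect_setequal(full$gene_names, net1$gene_names)

  net3 <- generate_source_topology(100, 2, seed = 2)
  expect_false(identical(net1$edges, net3$edges))
})

test_that("degenerate and forced-parameter topologies behave as documented", {
  tiny <- generate_source_topology(2, avg_degree = 1, seed = 3)
  expect_equal(tiny$n, 2)
  expect_gte(nrow(tiny$edges), 1)
  all_act <- generate_source_topology(60, 2, activation_fraction = 1, seed = 4)
  expect_true(all(all_act$edges$sign == 1L))
  all_rep <- generate_source_topology(60, 2, activation_fraction = 0, seed = 4)
  expect_true(all(all_rep$edges$sign == -1L))
  expect_error(generate_source_topology(10, avg_degree = 10, seed = 1), "avg_degree")
  expect_error(generate_source_topology(1, 1, seed = 1), "n_genes")
})

test_that("subnetwork extraction grows an induced, connected subgraph", {
  src <- generate_source_topology(80, 2, seed = 7)
  sub <- extract_subnetwork(src, 12, seed = 9)
  expect_equal(sub$n, 12)
  expect_true(all(sub$gene_names %in% src$gene_names))
  # induced: every source edge between selected genes is present
  induced <- src$edges[src$edges$regulator %in% sub$gene_names &
    src$edges$target %in% sub$gene_names, ]
  expect_equal(nrow(sub$edges), nrow(induced))
  # weakly connected (grown one neighbour at a time)
  for (s in 1:5) {
    g <- extract_subnetwork(src, 8, seed = s)
    adj <- adjacency_matrix(g) != 0
    reach <- (adj | t(adj))
    comp <- Reduce(`%*%`, rep(list(reach + diag(8)), 7)) > 0
    expect_true(all(comp[1, ]), info = sprintf("seed %d", s))
  }
  expect_error(extract_subnetwork(src, 81, seed = 1), "size")
})

test_that("growth replay with the same seed reproduces the selected gene set", {
  src <- generate_source_topology(40, 2, seed = 3)
  sub <- extract_subnetwork(src, 6, seed = 17)
  # independent replay of the documented procedure: start from a random
  # gene, repeatedly add a uniformly chosen undirected neighbour
  ri <- match(src$edges$regulator, src$gene_names)
  ti <- match(src$edges$target, src$gene_names)
  nbr <- lapply(seq_len(src$n), function(v) {
    unique(c(ti[ri == v], ri[ti == v]))
  })
  sel <- withr::with_seed(17L, {
    sel <- sample.int(src$n, 1)
    while (length(sel) < 6) {
      frontier <- sort(setdiff(unique(unlist(nbr[sel])), sel))
      sel <- c(sel, frontier[sample.int(length(frontier), 1)])
    }
    sel
  })
  expect_setequal(sub$gene_names, src$gene_names[sel])
})

test_that("edge cases of extraction: full size and single gene", {
  src <- generate_source_topology(30, 2, seed = 2)
  expect_setequal(extract_subnetwork(src, 30, seed = 1)$gene_names, src$gene_names)
  single <- extract_subnetwork(src, 1, seed = 1)
  expect_equal(single$n, 1)
  expect_equal(nrow(single$edges), 0)
})

test_that("sampled kinetic models admit a steady state meeting the tolerance", {
  net <- fixture_chain_network()
  for (mode in c("hill", "linear")) {
    model <- sample_kinetics(net, mode, seed = 5)
    x <- model$wt_steady
    dx <- goalnet:::kinetic_rhs(model)(0, x, NULL)[[1]]
    expect_lt(max(abs(dx)), 1e-6 * max(abs(x)))
    expect_true(all(x >= 0))
  }
})

test_that("a decoupled linear model settles at basal/decay exactly", {
  net <- grn_network(paste0("G", 1:3), tibble::tibble(
    regulator = character(0), target = character(0), sign = integer(0)
  ))
  model <- sample_kinetics(net, "linear", seed = 8)
  tc <- simulate_timecourse(model, NULL, noise_level = 0, replicates = 1,
                            seed = 1, normalize = FALSE)
  expected <- model$basal / model$decay
  for (k in seq_len(26)) {
    expect_equal(unname(tc$values[, k, 1]), unname(expected), tolerance = 1e-5)
  }
})

test_that("the sampling grid matches the reference protocol", {
  net <- fixture_chain_network()
  model <- sample_kinetics(net, "hill", seed = 5)
  tc <- simulate_timecourse(model, NULL, seed = 1)
  expect_equal(length(tc$times), 26)
  expect_equal(tc$times, seq(0, 200, by = 8))
  expect_equal(dim(tc$values)[3], 3)
})

test_that("replicate noise is calibrated to the requested level", {
  net <- fixture_chain_network()
  model <- sample_kinetics(net, "hill", seed = 5)
  pert <- sample_perturbation(model, seed = 2)
  tc <- simulate_timecourse(model, pert, replicates = 400, noise_level = 0.05, seed = 3)
  m <- apply(tc$values, c(1, 2), mean)
  s <- apply(tc$values, c(1, 2), sd)
  cv <- s[m > 0.05] / m[m > 0.05] # stay clear of the zero-truncation region
  expect_lt(abs(mean(cv) - 0.05) / 0.05, 0.1) # within 10% relative

  zero <- simulate_timecourse(model, pert, noise_level = 0, seed = 4)
  expect_equal(zero$values[, , 1], zero$values[, , 2])
})

test_that("knockouts clamp the deleted gene and respect coverage", {
  net <- fixture_chain_network()
  model <- sample_kinetics(net, "hill", seed = 5)
  panel <- simulate_knockout_compendium(model, "steady", seed = 6)
  expect_equal(length(panel$mutant_ids), 5)
  for (k in seq_along(panel$mutant_ids)) {
    g <- match(panel$mutant_ids[k], panel$gene_names)
    expect_equal(panel$mutant_values[g, k], 0)
  }
  half <- simulate_knockout_compendium(model, "steady", coverage = 0.5, seed = 6)
  expect_equal(length(half$mutant_ids), round(0.5 * 5))

  tcp <- simulate_knockout_compendium(model, "timecourse", seed = 6)
  expect_true(tcp$time_resolved)
  expect_equal(dim(tcp$mutant_values), c(5, 26, 5))
  for (k in seq_along(tcp$mutant_ids)) {
    g <- match(tcp$mutant_ids[k], tcp$gene_names)
    expect_true(all(tcp$mutant_values[g, , k] == 0))
  }
})

test_that("deleting a gene without outgoing edges leaves the rest at wild type", {
  # G5 regulates nothing in the chain fixture
  net <- fixture_chain_network()
  model <- sample_kinetics(net, "hill", seed = 11)
  panel <- simulate_knockout_compendium(model, "steady", noise_level = 0, seed = 2,
                                        normalize = FALSE)
  k <- match("G5", panel$mutant_ids)
  others <- setdiff(seq_len(5), 5)
  expect_equal(panel$mutant_values[others, k], model$wt_steady[others],
               tolerance = 1e-4)
})

test_that("simulation outputs are bit-identical under a fixed seed", {
  net <- fixture_chain_network()
  model <- sample_kinetics(net, "hill", seed = 5)
  pert <- sample_perturbation(model, seed = 2)
  a <- simulate_timecourse(model, pert, seed = 9)
  b <- simulate_timecourse(model, pert, seed = 9)
  expect_identical(a$values, b$values)
  pa <- simulate_knockout_compendium(model, "steady", seed = 9)
  pb <- simulate_knockout_compendium(model, "steady", seed = 9)
  expect_identical(pa$mutant_values, pb$mutant_values)
})
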