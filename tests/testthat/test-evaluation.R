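# Independent oracles used by several blocks ---------------------------------

# undirected AUC by explicit threshold sweep and trapezoid over (FPR, TPR)
oracle_auc_undirected <- function(w, truth) {
  a <- adjacency_matrix(truth)
  n <- nrow(a)
  scores <- labels <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      scores <- c(scores, max(abs(w[i, j]), abs(w[j, i])))
      labels <- c(labels, a[i, j] != 0 || a[j, i] != 0)
    }
  }
  taus <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- fpr <- numeric(0)
  for (tau in taus) {
    pred <- scores >= tau
    tpr <- c(tpr, sum(pred & labels) / sum(labels))
    fpr <- c(fpr, sum(pred & !labels) / sum(!labels))
  }
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# directed-signed AUC by direct enumeration of the definition
oracle_auc_directed <- function(w, truth) {
  a <- adjacency_matrix(truth)
  n <- nrow(a)
  off <- which(diag(n) == 0)
  n_pos <- sum(a[off] != 0)
  n_neg <- sum(a[off] == 0)
  taus <- sort(unique(abs(w[off])[abs(w[off]) > 0]), decreasing = TRUE)
  tnr <- 1
  tpr <- 0
  for (tau in taus) {
    tp <- tn <- 0
    for (k in off) {
      pred <- abs(w[k]) >= tau && w[k] != 0
      if (pred && a[k] != 0 && sign(w[k]) == a[k]) tp <- tp + 1
      if (!pred && a[k] == 0) tn <- tn + 1
    }
    tpr <- c(tpr, tp / n_pos)
    tnr <- c(tnr, tn / n_neg)
  }
  tpr <- c(tpr, sum(a[off] != 0 & sign(w[off]) == a[off]) / n_pos)
  tnr <- c(tnr, 0)
  # integrate along the sweep: tnr is non-increasing by construction
  sum(-diff(tnr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

random_instance <- function(n, seed, p_edge = 0.25, act = 0.6) {
  withr::with_seed(seed, {
    a <- matrix(0L, n, n)
    off <- which(diag(n) == 0)
    pick <- off[runif(length(off)) < p_edge]
    if (length(pick) == 0) pick <- off[1]
    if (length(pick) == length(off)) pick <- pick[-1]
    a[pick] <- ifelse(runif(length(pick)) < act, 1L, -1L)
    a[1, 2] <- a[2, 1] <- 0L # guarantee an unlinked unordered pair
    w <- matrix(rnorm(n * n), n, n)
    w[sample(length(w), n)] <- 0 # exercise zero-score ties
  })
  genes <- paste0("G", seq_len(n))
  idx <- which(a != 0, arr.ind = TRUE)
  net <- grn_network(genes, tibble::tibble(
    regulator = genes[idx[, 2]], target = genes[idx[, 1]], sign = a[idx]
  ))
  list(w = w, net = net)
}

test_that("undirected AUC handles perfect, uninformative and degenerate input", {
  net <- fixture_chain_network()
  a <- adjacency_matrix(net)
  perfect <- a * 2.5 # any positive scale of the truth separates perfectly
  expect_equal(auc_undirected(perfect, net), 1)
  flat <- matrix(1, 5, 5)
  expect_equal(auc_undirected(flat, net), 0.5) # all tied -> chance
  none <- grn_network(paste0("G", 1:3), tibble::tibble(
    regulator = character(0), target = character(0), sign = integer(0)
  ))
  expect_error(auc_undirected(matrix(1, 3, 3), none), "degenerate")
})

test_that("undirected AUC agrees with the threshold-sweep oracle", {
  for (seed in 1:20) {
    inst <- random_instance(n = 4 + seed %% 5, seed = seed)
    expect_equal(
      auc_undirected(inst$w, inst$net),
      oracle_auc_undirected(inst$w, inst$net),
      tolerance = 1e-12, info = sprintf("seed %d", seed)
    )
  }
})

test_that("undirected AUC matches the Mann-Whitney closed form on tie-free instances", {
  inst <- random_instance(n = 6, seed = 101)
  w <- inst$w
  w[w == 0] <- 0.123 # remove planted zeros so all pair scores are distinct
  a <- adjacency_matrix(inst$net)
  iu <- which(upper.tri(a))
  s <- pmax(abs(w)[iu], abs(t(w))[iu])
  lab <- (a[iu] != 0) | (t(a)[iu] != 0)
  # closed form: count of positive-negative pairs won
  wins <- 0
  for (p in s[lab]) wins <- wins + sum(p > s[!lab]) + 0.5 * sum(p == s[!lab])
  expect_equal(auc_undirected(w, inst$net), wins / (sum(lab) * sum(!lab)))
})

test_that("directed-signed AUC rewards exact sign recovery and punishes flips", {
  net <- fixture_chain_network()
  a <- adjacency_matrix(net)
  expect_equal(auc_directed_signed(a * 1.0, net), 1)
  expect_equal(auc_directed_signed(-a, net), 0) # all signs flipped
})

test_that("directed-signed AUC agrees with the enumeration oracle", {
  for (seed in 1:20) {
    inst <- random_instance(n = 4 + seed %% 4, seed = 1000 + seed)
    expect_equal(
      auc_directed_signed(inst$w, inst$net),
      oracle_auc_directed(inst$w, inst$net),
      tolerance = 1e-12, info = sprintf("seed %d", seed)
    )
  }
})

test_that("random scores sit at the chance level of each metric", {
  # undirected chance is 0.5; directed-signed chance is ~0.25 because a
  # random prediction must match direction and sign together
  net <- random_instance(n = 8, seed = 5)$net
  withr::with_seed(42, {
    u <- replicate(200, auc_undirected(matrix(rnorm(64), 8), net))
    d <- replicate(200, auc_directed_signed(matrix(rnorm(64), 8), net))
  })
  expect_lt(abs(mean(u) - 0.5), 0.05)
  expect_lt(abs(mean(d) - 0.25), 0.05)
  expect_true(all(u >= 0 & u <= 1))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("diagonal entries never influence the metrics", {
  inst <- random_instance(n = 6, seed = 77)
  w2 <- inst$w
  diag(w2) <- 1e6
  expect_equal(auc_undirected(inst$w, inst$net), auc_undirected(w2, inst$net))
  expect_equal(auc_directed_signed(inst$w, inst$net), auc_directed_signed(w2, inst$net))
})

test_that("thresholding keeps the largest weights and hits connectivity targets", {
  set.seed(3)
  w <- matrix(rnorm(100), 10)
  diag(w) <- 0
  nz <- sum(w != 0) - 0 # all off-diagonal nonzero here
  all_net <- threshold_network(w, n_edges = 90)
  expect_equal(nrow(all_net$edges), 90)
  empty <- threshold_network(w, n_edges = 0)
  expect_equal(nrow(empty$edges), 0)
  top5 <- threshold_network(w, n_edges = 5)
  expect_equal(nrow(top5$edges), 5)
  kept <- sort(abs(w[diag(10) == 0]), decreasing = TRUE)[1:5]
  got <- abs(w[cbind(
    match(top5$edges$target, top5$gene_names),
    match(top5$edges$regulator, top5$gene_names)
  )])
  expect_setequal(round(got, 12), round(kept, 12))
  expect_true(all(top5$edges$sign == sign(w[cbind(
    match(top5$edges$target, top5$gene_names),
    match(top5$edges$regulator, top5$gene_names)
  )])))
})

test_that("connectivity-target thresholding matches a brute-force scan", {
  set.seed(9)
  w <- matrix(rnorm(100), 10)
  diag(w) <- 0
  net8 <- threshold_network(w, n_connected_genes = 8)
  genes_in <- unique(c(net8$edges$regulator, net8$edges$target))
  expect_gte(length(genes_in), 8)
  # oracle: scan all candidate thresholds from above, first to reach 8 genes
  mags <- sort(unique(abs(w[diag(10) == 0])), decreasing = TRUE)
  for (thr in mags) {
    sel <- which(abs(w) >= thr & diag(10) == 0)
    genes <- unique(c((sel - 1) %% 10 + 1, (sel - 1) %/% 10 + 1))
    if (length(genes) >= 8) break
  }
  expect_equal(length(genes_in), length(genes))
  expect_equal(nrow(net8$edges), length(sel))
  expect_error(threshold_network(matrix(0, 3, 3), n_edges = 1), "nonzero")
})

test_that("rank-sum comparison reproduces exact references", {
  same <- compare_auc_distributions(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(same$p_value, 1)
  sep <- compare_auc_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p_value, 0.1) # exact two-sided: 2/20
  expect_equal(sep$method, "exact")
  big <- compare_auc_distributions(rnorm(30), rnorm(30))
  expect_equal(big$method, "normal approximation")
  expect_error(compare_auc_distributions(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("rank-sum test has power against a one-sd shift", {
  withr::with_seed(7, {
    rej <- replicate(200, {
      a <- rnorm(10)
      b <- rnorm(10, mean = 1)
      compare_auc_distributions(a, b)$p_value < 0.05
    })
  })
  expect_gt(mean(rej), 0.5)
})

test_that("benchmark bookkeeping: rows, determinism, tidy output", {
  src <- generate_source_topology(30, 2, seed = 4)
  cfg <- benchmark_config(
    sizes = 8, n_networks = 2, procedures = "SOO", seed = 5, source = src
  )
  res <- run_benchmark(cfg)
  expect_s3_class(res, "grn_benchmark")
  expect_equal(nrow(res), 4) # 2 networks x 1 procedure x 2 modes
  expect_setequal(unique(res$mode), c("undirected", "directed_signed"))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  res2 <- run_benchmark(cfg)
  expect_identical(as.data.frame(res), as.data.frame(res2))
  sm <- summary(res)
  expect_s3_class(sm, "tbl_df")
  expect_equal(nrow(sm), 2)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
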