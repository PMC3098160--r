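# Report every failure rather than stopping at testthat's default cap: the
# benchmark-comparison block intentionally asserts many published reference
# values and some stay red by design.
options(testthat.progress.max_fails = 1000)

# Shared fixtures, built in code. Everything is tiny and seeded.

# A small signed network given explicitly (chain with one branch and a repressor)
fixture_chain_network <- function() {
  grn_network(
    gene_names = paste0("G", 1:5),
    edges = tibble::tibble(
      regulator = c("G1", "G2", "G3", "G2"),
      target = c("G2", "G3", "G4", "G5"),
      sign = c(1L, 1L, -1L, 1L)
    )
  )
}

# An interpolated series built directly from closed forms (bypasses the
# simulator): values and analytic derivatives on a dense grid
fixture_series <- function(values, derivatives, t_max = 1) {
  n_pts <- ncol(values)
  grn_interp(
    values, derivatives, seq(0, t_max, length.out = n_pts),
    rep(2L, nrow(values)), sprintf("G%d", seq_len(nrow(values)))
  )
}

# A well-conditioned synthetic regression instance: smooth random profiles
# and derivatives generated exactly by a known linear model
fixture_linear_instance <- function(n = 6, n_pts = 60, seed = 1, noise = 0) {
  withr::with_seed(seed, {
    tt <- seq(0, 1, length.out = n_pts)
    X <- t(sapply(seq_len(n), function(i) {
      a <- rnorm(3)
      a[1] * sin(2 * pi * i * tt / 3) + a[2] * cos(2 * pi * tt * (i + 1) / 4) + a[3]
    }))
    W <- matrix(rnorm(n * n, sd = 0.5), n, n)
    b <- rnorm(n)
    D <- W %*% X + b + matrix(rnorm(n * n_pts, sd = noise), n, n_pts)
  })
  list(series = fixture_series(X, D), w = W, b = b)
}

# Small steady-state knockout panel with known entries
fixture_ko_panel <- function() {
  genes <- paste0("G", 1:4)
  mut <- matrix(
    c(0, 1, 4, 2,
      2, 0, 1, 2,
      2, 2, 0, 2),
    nrow = 4, byrow = FALSE,
    dimnames = list(genes, genes[1:3])
  )
  grn_ko_panel(mut, genes[1:3], wildtype = c(2, 2, 2, 2), gene_names = genes)
}
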