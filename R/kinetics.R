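#' Sample a kinetic model for a signed network
#'
#' Attaches data-generating dynamics to a topology. Two modes:
#'
#' * `hill` (default): production of gene `i` is its basal rate multiplied by
#'   one saturating factor per incoming edge,
#'   \deqn{dx_i/dt = m_i \prod_{j \to i} f_{ij}(x_j) - \delta_i x_i,}
#'   with \eqn{f = (1 + s H)/(1 + s)} for activators and
#'   \eqn{f = (1 + s(1-H))/(1+s)} for repressors, where
#'   \eqn{H = (x/K)^h / (1 + (x/K)^h)} is a Hill term, `s` the edge strength
#'   (maximal fold effect `1+s`), `h` the Hill coefficient and `K` the
#'   half-saturation constant, set to the regulator's decoupled steady level
#'   `m_j/delta_j` so each edge is responsive around the operating point.
#'   This mimics the saturating multiplicative kinetics of in-silico
#'   benchmark generators and guarantees bounded, non-negative dynamics.
#' * `linear`: \eqn{dx_i/dt = b_i + \sum_j a_{ij} x_j - \delta_i x_i} with
#'   \eqn{a_{ij} = sign \times strength} rescaled for stability. Used for
#'   closed-form checks: here the generating interaction matrix seen by the
#'   inference model is exactly `a - diag(decay)`.
#'
#' @param network a [grn_network()].
#' @param mode `"hill"` or `"linear"`.
#' @param seed integer seed for parameter sampling.
#' @param basal_range,decay_range,strength_range,hill_range uniform sampling
#'   ranges for basal production rates (expression/time), first-order decay
#'   rates (1/time), edge strengths (dimensionless) and Hill coefficients.
#' @param half_sat_spread half-saturation constants are drawn per edge as
#'   the regulator's decoupled level times `2^U`, `U ~ Uniform(-spread,
#'   spread)` (log2 units). The spread emulates the heterogeneous binding
#'   affinities of in-silico benchmark kinetics: edges whose Hill term is
#'   saturated (or starved) at the operating point are effectively weak.
#' @return a `grn_kinetics` object.
#' @export
sample_kinetics <- function(network, mode = c("hill", "linear"), seed = 1,
                            basal_range = c(0.5, 1.5),
                            decay_range = c(0.02, 0.1),
                            strength_range = c(1, 5),
                            hill_range = c(1, 3),
                            half_sat_spread = 2) {
  stopifnot(inherits(network, "grn_network"))
  mode <- match.arg(mode)
  n <- network$n
  ne <- nrow(network$edges)
  withr::with_seed(as.integer(seed), {
    basal <- runif_range(n, basal_range)
    decay <- runif_range(n, decay_range)
    strength <- runif_range(ne, strength_range)
    hill <- runif_range(ne, hill_range)
    kspread <- 2^runif(ne, -half_sat_spread, half_sat_spread)
  })
  if (any(decay <= 0)) stop_bad("decay rates must be positive")
  if (mode == "hill" && any(hill < 1)) stop_bad("hill coefficients must be >= 1")
  names(basal) <- names(decay) <- network$gene_names
  ri <- match(network$edges$regulator, network$gene_names)
  ti <- match(network$edges$target, network$gene_names)
  edges <- tibble::tibble(
    regulator = network$edges$regulator,
    target = network$edges$target,
    sign = network$edges$sign,
    strength = strength,
    hill = hill,
    half_sat = basal[ri] / decay[ri] * kspread
  )
  model <- structure(
    list(
      network = network, mode = mode,
      basal = basal, decay = decay, edges = edges,
      reg_index = ri, tgt_index = ti
    ),
    class = "grn_kinetics"
  )
  if (mode == "linear") {
    a <- matrix(0, n, n, dimnames = list(network$gene_names, network$gene_names))
    a[cbind(ti, ri)] <- network$edges$sign * strength
    # rescale interactions until a - diag(decay) is strictly diagonally
    # dominant (Gershgorin): every clamped subsystem is then stable too,
    # so a finite non-negative steady state exists from any start
    rs <- max(rowSums(abs(a)))
    if (rs > 0) a <- a * (0.8 * min(decay) / rs)
    model$a_matrix <- a
  }
  # fail fast on models without a computable wild-type steady state
  model$wt_steady <- steady_state(model)
  model
}

#' @export
print.grn_kinetics <- function(x, ...) {
  cat(sprintf(
    "<grn_kinetics> %s mode, %d genes, %d regulatory edges\n",
    x$mode, x$network$n, nrow(x$edges)
  ))
  invisible(x)
}

# Right-hand side of the kinetic ODE. `pert` multiplies basal rates,
# `knockout` (gene index vector) clamps production and state of deleted genes.
kinetic_rhs <- function(model, pert = NULL, knockout = NULL) {
  n <- model$network$n
  pert <- pert %||% rep(1, n)
  basal <- model$basal * pert
  decay <- model$decay
  if (model$mode == "linear") {
    a <- model$a_matrix
    rhs <- function(t, x, parms) {
      x <- pmax(x, 0)
      if (length(knockout)) x[knockout] <- 0
      dx <- basal + drop(a %*% x) - decay * x
      # projection at the non-negativity boundary: a gene held at zero by
      # net repression must not integrate to negative expression
      dx[x <= 0 & dx < 0] <- 0
      if (length(knockout)) dx[knockout] <- 0
      list(dx)
    }
    return(rhs)
  }
  ri <- model$reg_index
  ti <- model$tgt_index
  s <- model$edges$strength
  h <- model$edges$hill
  k0 <- model$edges$half_sat
  act <- model$edges$sign > 0
  function(t, x, parms) {
    x <- pmax(x, 0)
    if (length(knockout)) x[knockout] <- 0
    prod <- basal
    if (length(ri)) {
      hterm <- (x[ri] / k0)^h
      hterm <- hterm / (1 + hterm)
      f <- ifelse(act, (1 + s * hterm) / (1 + s), (1 + s * (1 - hterm)) / (1 + s))
      for (e in seq_along(ri)) prod[ti[e]] <- prod[ti[e]] * f[e]
    }
    dx <- prod - decay * x
    dx[x <= 0 & dx < 0] <- 0
    if (length(knockout)) dx[knockout] <- 0
    list(dx)
  }
}

#' Numerically computed steady state of a kinetic model
#'
#' Integrates the ODE system from `x0` (default: the decoupled levels
#' `basal/decay`) in blocks until `max |dx/dt| < tol * max |x|`.
#'
#' @param model a `grn_kinetics`.
#' @param pert optional per-gene multiplicative factors on basal rates.
#' @param knockout optional gene names/indices whose production and state are
#'   clamped to zero (hard deletion).
#' @param x0 optional start state.
#' @param tol relative convergence tolerance on the derivative.
#' @param max_time integration horizon before declaring non-convergence.
#' @return named numeric vector of steady expression levels.
#' @export
steady_state <- function(model, pert = NULL, knockout = NULL, x0 = NULL,
                         tol = 1e-6, max_time = 2e4) {
  stopifnot(inherits(model, "grn_kinetics"))
  n <- model$network$n
  knockout <- resolve_genes(model$network, knockout)
  x <- x0 %||% (model$basal / model$decay)
  if (length(knockout)) x[knockout] <- 0
  rhs <- kinetic_rhs(model, pert, knockout)
  block <- max(200, 10 / min(model$decay))
  t_done <- 0
  repeat {
    sol <- deSolve::lsoda(y = x, times = c(0, block), func = rhs, parms = NULL,
                          rtol = 1e-9, atol = 1e-10)
    x <- sol[nrow(sol), -1]
    t_done <- t_done + block
    dx <- rhs(0, x, NULL)[[1]]
    if (max(abs(dx)) < tol * max(max(abs(x)), 1e-12)) break
    if (t_done >= max_time) {
      stop_bad(
        "steady state not reached for %d-gene %s model within t = %g (max |dx/dt| = %.3g)",
        n, model$mode, max_time, max(abs(dx))
      )
    }
  }
  stats::setNames(pmax(as.numeric(x), 0), model$network$gene_names)
}

resolve_genes <- function(network, genes) {
  if (is.null(genes) || length(genes) == 0) return(integer(0))
  if (is.character(genes)) {
    idx <- match(genes, network$gene_names)
    if (anyNA(idx)) stop_bad("unknown gene: %s", genes[is.na(idx)][1])
    idx
  } else {
    as.integer(genes)
  }
}

#' Sample a perturbation of basal production rates
#'
#' The wild-type "stimulus" experiment is emulated by shifting basal
#' production rates of a random subset of genes at t = 0. The default
#' perturbs every gene by +/-50% (factor 0.5 or 1.5, sign chosen at random).
#'
#' @param model a `grn_kinetics`.
#' @param frac_change magnitude of the relative change (0.5 = +/-50%).
#' @param genes which genes to perturb (`"all"` or names/indices).
#' @param seed integer seed.
#' @return numeric vector of per-gene multiplicative factors on basal rates.
#' @export
sample_perturbation <- function(model, frac_change = 0.5, genes = "all", seed = 1) {
  stopifnot(inherits(model, "grn_kinetics"))
  n <- model$network$n
  idx <- if (identical(genes, "all")) seq_len(n) else resolve_genes(model$network, genes)
  pert <- rep(1, n)
  withr::with_seed(as.integer(seed), {
    pert[idx] <- 1 + frac_change * sign(runif(length(idx)) - 0.5)
  })
  stats::setNames(pert, model$network$gene_names)
}

#' Simulate a replicated expression time course
#'
#' Integrates the model from the unperturbed wild-type steady state with the
#' perturbation applied at t = 0 and, in the default `"pulse"` protocol,
#' removed at `t_max / 2` (the standard in-silico benchmark time-series
#' design: the first half of the window shows the response to the
#' perturbation, the second half the relaxation back to the wild type).
#' The trajectory is sampled on an equally spaced grid, normalized to a
#' maximum of 1 (expression units are relative, as in benchmark suites),
#' and independent multiplicative Gaussian noise (sd = `noise_level` x
#' signal, truncated at zero) is added to each replicate.
#'
#' @param model a `grn_kinetics`.
#' @param perturbation per-gene multiplicative factors on basal rates (see
#'   [sample_perturbation()]); `NULL` for none.
#' @param n_timepoints number of samples (default 26).
#' @param t_max end of the sampling window (default 200 time units).
#' @param replicates number of noisy replicates (default 3).
#' @param noise_level relative noise standard deviation (default 0.05).
#' @param seed integer seed for the noise.
#' @param protocol `"pulse"` (perturbation removed at `t_max/2`) or
#'   `"step"` (perturbation held for the whole window).
#' @param normalize divide by the maximum of the noiseless trajectory so
#'   expression lies in \[0, 1\]? Default `TRUE`.
#' @return a [grn_timecourse()].
#' @export
simulate_timecourse <- function(model, perturbation = NULL, n_timepoints = 26,
                                t_max = 200, replicates = 3,
                                noise_level = 0.05, seed = 1,
                                protocol = c("pulse", "step"),
                                normalize = TRUE) {
  stopifnot(inherits(model, "grn_kinetics"))
  protocol <- match.arg(protocol)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 2)
  replicates <- check_count(replicates, "replicates", min = 1)
  check_number(noise_level, "noise_level", min = 0)
  check_number(t_max, "t_max", min = 0)
  times <- seq(0, t_max, length.out = n_timepoints)
  x0 <- model$wt_steady
  if (protocol == "step" || is.null(perturbation)) {
    rhs <- kinetic_rhs(model, perturbation)
    sol <- deSolve::lsoda(y = x0, times = times, func = rhs, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    if (nrow(sol) < n_timepoints || any(!is.finite(sol[, -1]))) {
      stop_bad("ODE integration diverged for %d-gene %s model", model$network$n, model$mode)
    }
    clean <- t(unname(sol[, -1, drop = FALSE])) # genes x time
  } else {
    t_half <- t_max / 2
    t1 <- times[times <= t_half]
    t2 <- times[times > t_half]
    s1 <- deSolve::lsoda(y = x0, times = unique(c(t1, t_half)),
                         func = kinetic_rhs(model, perturbation), parms = NULL,
                         rtol = 1e-8, atol = 1e-10)
    if (any(!is.finite(s1[, -1]))) {
      stop_bad("ODE integration diverged for %d-gene %s model", model$network$n, model$mode)
    }
    x_half <- s1[nrow(s1), -1]
    s2 <- deSolve::lsoda(y = x_half, times = c(t_half, t2),
                         func = kinetic_rhs(model, NULL), parms = NULL,
                         rtol = 1e-8, atol = 1e-10)
    if (nrow(s2) < length(t2) + 1 || any(!is.finite(s2[, -1]))) {
      stop_bad("ODE integration diverged for %d-gene %s model", model$network$n, model$mode)
    }
    clean <- cbind(
      t(unname(s1[seq_along(t1), -1, drop = FALSE])),
      t(unname(s2[-1, -1, drop = FALSE]))
    )
  }
  if (normalize) clean <- clean / max(clean)
  n <- model$network$n
  values <- array(NA_real_, c(n, n_timepoints, replicates))
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(replicates)) {
      eps <- matrix(rnorm(n * n_timepoints, sd = noise_level), n, n_timepoints)
      values[, , r] <- pmax(clean * (1 + eps), 0)
    }
  })
  grn_timecourse(values, times, model$network$gene_names)
}

#' Simulate a gene-knockout compendium
#'
#' Deletes each (covered) gene in turn — production forced to zero and the
#' state clamped at zero — starting from the wild-type steady state, and
#' records either the new post-deletion steady state (`mode = "steady"`) or
#' the transient response on an equally spaced grid (`mode = "timecourse"`).
#' Multiplicative Gaussian noise is applied as in [simulate_timecourse()].
#'
#' @param model a `grn_kinetics`.
#' @param mode `"steady"` or `"timecourse"`.
#' @param coverage fraction of genes with a knockout column, in (0, 1]. When
#'   below 1 a seeded random subset of genes is retained.
#' @param noise_level relative noise standard deviation.
#' @param seed integer seed (subset selection and noise).
#' @param n_timepoints,t_max sampling grid for `mode = "timecourse"`.
#' @param normalize divide the whole panel (mutants and wild type, one
#'   shared constant) by the maximum noiseless value, as in
#'   [simulate_timecourse()]? Ratios are unaffected. Default `TRUE`.
#' @return a [grn_ko_panel()]. The wild-type reference is the (noisy)
#'   unperturbed steady state, or its constant extension over the grid for
#'   time-resolved panels.
#' @export
simulate_knockout_compendium <- function(model, mode = c("steady", "timecourse"),
                                         coverage = 1.0, noise_level = 0.05,
                                         seed = 1, n_timepoints = 26, t_max = 200,
                                         normalize = TRUE) {
  stopifnot(inherits(model, "grn_kinetics"))
  mode <- match.arg(mode)
  check_number(coverage, "coverage", min = 0, max = 1)
  if (coverage <= 0) stop_bad("coverage must be in (0, 1]")
  n <- model$network$n
  genes <- model$network$gene_names
  n_mut <- max(1L, round(coverage * n))
  wt <- model$wt_steady

  withr::with_seed(derive_seed(seed, 1), {
    mutants <- sort(sample.int(n, n_mut))
  })

  if (mode == "steady") {
    clean <- matrix(NA_real_, n, n_mut, dimnames = list(genes, genes[mutants]))
    for (m in seq_len(n_mut)) {
      clean[, m] <- steady_state(model, knockout = mutants[m], x0 = wt)
    }
    wt_ref <- wt
  } else {
    times <- seq(0, t_max, length.out = n_timepoints)
    clean <- array(NA_real_, c(n, n_timepoints, n_mut),
                   dimnames = list(genes, NULL, genes[mutants]))
    for (m in seq_len(n_mut)) {
      ko <- mutants[m]
      x0 <- wt
      x0[ko] <- 0
      rhs <- kinetic_rhs(model, knockout = ko)
      sol <- deSolve::lsoda(y = x0, times = times, func = rhs, parms = NULL,
                            rtol = 1e-8, atol = 1e-10)
      if (nrow(sol) < n_timepoints) {
        stop_bad("knockout simulation diverged for gene %s", genes[ko])
      }
      clean[, , m] <- t(unname(sol[, -1, drop = FALSE]))
    }
    wt_ref <- matrix(wt, n, n_timepoints, dimnames = list(genes, NULL))
  }

  if (normalize) {
    norm_const <- max(clean, wt_ref)
    clean <- clean / norm_const
    wt_ref <- wt_ref / norm_const
  }
  withr::with_seed(derive_seed(seed, 2), {
    noisy <- pmax(clean * (1 + array(rnorm(length(clean), sd = noise_level), dim(clean))), 0)
    wt_noisy <- pmax(wt_ref * (1 + rnorm(length(wt_ref), sd = noise_level)), 0)
    if (is.matrix(wt_ref)) dim(wt_noisy) <- dim(wt_ref)
  })
  # the deleted gene is clamped exactly, noise does not resurrect it
  if (mode == "steady") {
    noisy[cbind(mutants, seq_len(n_mut))] <- 0
  } else {
    for (m in seq_len(n_mut)) noisy[mutants[m], , m] <- 0
  }

  grn_ko_panel(
    mutant_values = noisy,
    mutant_ids = genes[mutants],
    wildtype = wt_noisy,
    gene_names = genes,
    times = if (mode == "timecourse") seq(0, t_max, length.out = n_timepoints) else NULL,
    t_p = if (mode == "steady") "steady" else NULL,
    coverage = n_mut / n
  )
}
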