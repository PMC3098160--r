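#' Fitted gene regulatory matrices
#'
#' A `grn_fit` holds the estimated interaction matrix `w` (entry `w[i, j]` =
#' effect of gene `j` on gene `i`, 1/time), the perturbation vector `b`
#' (expression/time), and fit metadata.
#'
#' @param w numeric N x N matrix.
#' @param b numeric length-N vector.
#' @param role one of `"soo"`, `"moo"`, `"ratio_fit"`, `"correlation_fit"`,
#'   `"ensemble"`, `"score"`.
#' @param gene_names character identifiers.
#' @param sqe attained squared error, if known.
#' @param gamma attained goal-attainment scalar, if any.
#' @param attainment per-term attainment tibble, if any.
#' @param provenance free-form list (objective labels, seeds).
#' @return object of class `grn_fit`.
#' @export
grn_fit <- function(w, b, role, gene_names = NULL, sqe = NA_real_,
                    gamma = NA_real_, attainment = NULL, provenance = list()) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w), length(b) == nrow(w))
  if (any(!is.finite(w)) || any(!is.finite(b))) stop_bad("non-finite fitted parameters")
  gene_names <- gene_names %||% rownames(w) %||% sprintf("G%03d", seq_len(nrow(w)))
  dimnames(w) <- list(gene_names, gene_names)
  names(b) <- gene_names
  structure(
    list(
      w = w, b = b, role = role, gene_names = gene_names,
      sqe = sqe, gamma = gamma, attainment = attainment, provenance = provenance
    ),
    class = "grn_fit"
  )
}

#' @export
print.grn_fit <- function(x, ...) {
  cat(sprintf(
    "<grn_fit> role %s, %d genes; E^SQE = %s%s\n",
    x$role, nrow(x$w),
    if (is.na(x$sqe)) "?" else format(x$sqe, digits = 5),
    if (is.na(x$gamma)) "" else sprintf(", gamma = %.4g", x$gamma)
  ))
  invisible(x)
}

#' @describeIn grn_fit ranked edge list of a fit: one row per off-diagonal
#'   entry with columns `regulator`, `target`, `weight`, `sign`, sorted by
#'   decreasing `abs(weight)`.
#' @param x a `grn_fit`.
#' @param ... unused.
#' @export
tidy.grn_fit <- function(x, ...) {
  n <- nrow(x$w)
  idx <- which(diag(n) == 0, arr.ind = TRUE)
  out <- tibble::tibble(
    regulator = x$gene_names[idx[, 2]],
    target = x$gene_names[idx[, 1]],
    weight = x$w[idx],
    sign = as.integer(sign(x$w[idx]))
  )
  dplyr::arrange(out, dplyr::desc(abs(.data$weight)))
}

#' @describeIn grn_fit one-row fit summary (`role`, `n_genes`, `sqe`,
#'   `gamma`, `n_terms`).
#' @export
glance.grn_fit <- function(x, ...) {
  tibble::tibble(
    role = x$role, n_genes = nrow(x$w), sqe = x$sqe, gamma = x$gamma,
    n_terms = if (is.null(x$attainment)) 0L else nrow(x$attainment)
  )
}

# coerce a fit or plain matrix to the (w, b) pair used by the metrics
as_wb <- function(w, b = NULL) {
  if (inherits(w, "grn_fit")) return(list(w = w$w, b = w$b))
  stopifnot(is.matrix(w))
  list(w = w, b = b %||% rep(0, nrow(w)))
}

#' Squared error of the linear ODE model
#'
#' The model squared error
#' \deqn{E^{SQE} = \sum_i \sum_t \big(\dot x_i(t) - \sum_j w_{ij} x_j(t) - b_i\big)^2}
#' evaluated on the dense interpolated series and its analytic derivatives.
#'
#' @param w a [grn_fit()] or plain N x N matrix.
#' @param data a [grn_interp()].
#' @param b perturbation vector when `w` is a plain matrix.
#' @return non-negative scalar.
#' @export
sqe <- function(w, data, b = NULL) {
  stopifnot(inherits(data, "grn_interp"))
  wb <- as_wb(w, b)
  if (nrow(wb$w) != nrow(data$values)) stop_bad("fit and data have different gene counts")
  if (any(!is.finite(data$values)) || any(!is.finite(data$derivatives))) {
    stop_bad("non-finite data")
  }
  r <- data$derivatives - wb$w %*% data$values - wb$b
  sum(r * r)
}

#' Euclidean distance between a fit and an objective matrix
#'
#' \deqn{E^{object} = \sqrt{\sum_{(i,j) \in mask} (w_{ij} - O_{ij})^2}}
#'
#' @param w a [grn_fit()] or plain matrix.
#' @param term a [grn_objective()].
#' @return non-negative scalar; 0 with a warning if the mask is empty.
#' @export
objective_distance <- function(w, term) {
  stopifnot(inherits(term, "grn_objective"))
  wb <- as_wb(w)
  if (!all(dim(wb$w) == dim(term$O))) stop_bad("fit and objective shapes differ")
  if (!any(term$mask)) {
    warning("objective mask is empty; distance is 0")
    return(0)
  }
  sqrt(sum((wb$w[term$mask] - term$O[term$mask])^2))
}

# Exact minimum of E^SQE (and a minimizing w, b) by orthogonal projection.
# The design A = [X; 1] is shared across genes, so one decomposition serves
# all rows. Rank deficiency (polynomial-interpolated series span few
# dimensions) is handled by SVD truncation: the returned solution is the
# minimum-norm least-squares solution.
sqe_minimum <- function(data) {
  X <- data$values
  D <- data$derivatives
  n <- nrow(X)
  A <- t(rbind(X, 1)) # timepoints x (n + 1)
  sv <- svd(A)
  keep <- sv$d > max(sv$d) * 1e-10
  U <- sv$u[, keep, drop = FALSE]
  coef_t <- sv$v[, keep, drop = FALSE] %*% (diag(1 / sv$d[keep], sum(keep)) %*% (t(U) %*% t(D)))
  resid <- t(D) - A %*% coef_t
  list(
    value = sum(resid^2),
    w = t(coef_t[seq_len(n), , drop = FALSE]),
    b = as.numeric(coef_t[n + 1, ])
  )
}

#' Single-objective least-squares fit (SOO)
#'
#' Minimizes the model squared error [sqe()] over `(w, b)`, starting from a
#' seeded random matrix with entries uniform on (-0.1, 0.1). The problem is
#' linear least squares — each gene's row of `(w, b)` enters a quadratic
#' with the shared design `[x; 1]` — so the minimization runs per gene by
#' preconditioned conjugate-gradient iterations on the normal equations
#' (the inner workhorse of trust-region least-squares solvers), terminated
#' when the squared error improves by less than `tolerance` relative. The
#' attained squared error matches the closed-form solution; when the
#' interpolated series spans fewer dimensions than there are genes the
#' minimizer is not unique and the returned `w` retains the (small,
#' random) null-space components of its initialization, as any
#' gradient-descent family does on rank-deficient quadratics.
#'
#' @param data a [grn_interp()].
#' @param tolerance relative convergence tolerance (default 1e-6).
#' @param init_seed seed of the random initial matrix.
#' @param max_iter iteration cap per gene.
#' @return a [grn_fit()] with role `"soo"`.
#' @export
soo_fit <- function(data, tolerance = 1e-6, init_seed = 1, max_iter = 2000) {
  stopifnot(inherits(data, "grn_interp"))
  check_number(tolerance, "tolerance", min = 0)
  X <- data$values
  D <- data$derivatives
  n <- nrow(X)
  A <- t(rbind(X, 1)) # timepoints x (n + 1), shared design
  withr::with_seed(as.integer(init_seed), {
    B0 <- matrix(runif(n * (n + 1), -0.1, 0.1), n + 1, n)
  })
  # one preconditioner serves every gene: Cholesky factor of the (ridge-
  # stabilized) Gram matrix of the shared design
  G <- crossprod(A)
  lam <- 1e-10 * mean(diag(G)) + 1e-300
  R <- chol(G + diag(lam, ncol(G)))
  B <- matrix(NA_real_, n + 1, n)
  total <- 0
  for (g in seq_len(n)) {
    cg <- cg_least_squares(A, D[g, ], B0[, g], R, tol = tolerance, max_iter = max_iter)
    B[, g] <- cg$beta
    total <- total + cg$value
  }
  grn_fit(
    w = t(B[seq_len(n), , drop = FALSE]), b = B[n + 1, ],
    role = "soo", gene_names = data$gene_names, sqe = total,
    provenance = list(init_seed = init_seed, tolerance = tolerance)
  )
}

# Preconditioned conjugate gradients on the normal equations
# A'A beta = A'y from a given start. `R` is an upper-triangular Cholesky
# factor preconditioning the system (M = R'R ~ A'A), so convergence takes a
# handful of iterations at any conditioning; the random start's components
# outside the data span are untouched, as in any gradient-family solver.
cg_least_squares <- function(A, y, beta0, R, tol = 1e-6, max_iter = 2000) {
  beta <- beta0
  r <- y - drop(A %*% beta)
  g <- drop(crossprod(A, r)) # negative gradient / 2
  z <- backsolve(R, forwardsolve(t(R), g))
  p <- z
  gz <- sum(g * z)
  f_prev <- sum(r * r)
  for (it in seq_len(max_iter)) {
    if (abs(gz) < 1e-30) break
    Ap <- drop(A %*% p)
    app <- sum(Ap * Ap)
    if (app <= 0) break
    alpha <- gz / app
    beta <- beta + alpha * p
    r <- r - alpha * Ap
    g <- drop(crossprod(A, r))
    z <- backsolve(R, forwardsolve(t(R), g))
    gz_new <- sum(g * z)
    f <- sum(r * r)
    if (abs(f_prev - f) < tol * max(f, 1e-12) && it > 3) {
      gz <- gz_new
      break
    }
    p <- z + (gz_new / gz) * p
    gz <- gz_new
    f_prev <- f
  }
  list(beta = beta, value = sum(r * r))
}

#' Multi-objective goal-attainment fit (MOO)
#'
#' Estimates `(w, b)` by the goal attainment method: minimize the scalar
#' \eqn{\gamma} over \eqn{(w, b, \gamma)} subject to
#' \eqn{F_k - \theta_k \gamma \le J_k} for every objective, where
#' \eqn{F_1 = E^{SQE}} and the remaining \eqn{F_k} are Euclidean distances
#' [objective_distance()] to the supplied objective matrices. A weight
#' \eqn{\theta_k = 0} makes goal `k` a hard constraint.
#'
#' The squared-error term always carries `J = 0, theta = 0` (a hard goal).
#' Taken literally that constraint is infeasible whenever the data are
#' noisy, so it is implemented in two stages: the minimal squared error
#' `SQE_min` is computed first (exactly, by projection — the same value an
#' SOO run attains), and the hard constraint becomes
#' `E^SQE <= SQE_min * (1 + sqe_slack)`. The constrained problem is then
#' solved by an augmented-Lagrangian scheme with analytic gradients and
#' seeded random initialization (entries uniform on (-0.1, 0.1)). The
#' problem is convex, so independent restarts reach the same optimum to
#' solver tolerance.
#'
#' Two solvers are available. The `"exact"` solver applies when every
#' data-derived term is soft (`theta > 0`), which covers all standard
#' procedures: the optimum then minimizes the (weight-equalized) objective
#' distances subject to the squared-error cap, a convex problem solved to
#' machine precision by per-gene ridge systems with a bisection on the
#' constraint multiplier (and, for two terms, on the equalizing weight).
#' Because the problem is convex with a unique masked-entry optimum, the
#' random initialization only seeds the entries the problem leaves free
#' (the diagonal and any coordinate outside both the data span and the
#' masks) — independent restarts agree to solver precision. The `"alm"`
#' solver (augmented Lagrangian with analytic gradients) handles the
#' general case including hard data-derived goals.
#'
#' @param data a [grn_interp()].
#' @param terms a [grn_objective()] or list of them (scale first, see
#'   [scale_objective()]). Empty list falls back to [soo_fit()].
#' @param sqe_slack relative slack on the squared-error hard goal
#'   (default 0.05).
#' @param tolerance convergence tolerance (default 1e-6).
#' @param init_seed seed of the random initial matrix.
#' @param solver `"auto"` (exact where applicable, else ALM), `"exact"`,
#'   or `"alm"`.
#' @param max_outer augmented-Lagrangian outer iteration cap.
#' @param inner_maxit quasi-Newton iteration cap per outer step.
#' @return a [grn_fit()] with role `"moo"`, attained `gamma`, per-term
#'   attainment table, and the attained `E^SQE`.
#' @export
moo_fit <- function(data, terms, sqe_slack = 0.05, tolerance = 1e-6,
                    init_seed = 1, solver = c("auto", "exact", "alm"),
                    max_outer = 30, inner_maxit = 400) {
  stopifnot(inherits(data, "grn_interp"))
  solver <- match.arg(solver)
  if (inherits(terms, "grn_objective")) terms <- list(terms)
  if (length(terms) == 0) {
    fit <- soo_fit(data, tolerance = tolerance, init_seed = init_seed)
    fit$role <- "moo"
    return(fit)
  }
  stopifnot(all(vapply(terms, inherits, logical(1), "grn_objective")))
  all_soft <- all(vapply(terms, `[[`, numeric(1), "weight") > 0)
  if (solver == "exact" && !all_soft) {
    stop_bad("the exact solver requires every data term to be soft (theta > 0)")
  }
  if (solver == "auto") solver <- if (all_soft && length(terms) <= 2) "exact" else "alm"
  if (solver == "exact") {
    return(moo_fit_exact(data, terms, sqe_slack, tolerance, init_seed))
  }
  X <- data$values
  D <- data$derivatives
  n <- nrow(X)
  if (any(vapply(terms, function(tm) nrow(tm$O), integer(1)) != n)) {
    stop_bad("objective dimensions do not match the data")
  }
  Xt <- t(X)
  base <- sqe_minimum(data)
  sqe_cap <- base$value * (1 + sqe_slack) + 1e-12
  # normalize the squared-error constraint by the empty-model error so the
  # augmented Lagrangian stays well scaled even when the interpolated data
  # satisfy the linear model exactly (SQE_min ~ 0)
  e_empty <- sum((D - rowMeans(D))^2)
  sqe_scale <- max(sqe_cap, e_empty, 1e-10)

  thetas <- vapply(terms, `[[`, numeric(1), "weight")
  goals <- vapply(terms, `[[`, numeric(1), "goal")
  soft <- which(thetas > 0)
  hard <- which(thetas == 0)
  masks <- lapply(terms, `[[`, "mask")
  Os <- lapply(terms, `[[`, "O")
  m <- length(terms)

  npar <- n * n + n
  withr::with_seed(as.integer(init_seed), {
    z0 <- runif(npar, -0.1, 0.1)
  })

  term_vals <- function(W) {
    vapply(seq_len(m), function(k) {
      sqrt(sum((W[masks[[k]]] - Os[[k]][masks[[k]]])^2))
    }, numeric(1))
  }
  gamma0 <- if (length(soft)) {
    W0 <- matrix(z0[seq_len(n * n)], n, n)
    fv <- term_vals(W0)
    max((fv[soft] - goals[soft]) / thetas[soft]) + 1
  } else {
    0
  }
  z0 <- c(z0, gamma0)

  # augmented Lagrangian for: min gamma  s.t.
  #   E^SQE / sqe_scale - cap_ratio <= 0        (hard, normalized)
  #   F_k - theta_k gamma - J_k <= 0            (per objective term)
  cap_ratio <- sqe_cap / sqe_scale
  lam_sqe <- 0
  lam <- rep(0, m)
  rho <- 10
  prev_viol <- Inf
  z <- z0
  has_gamma <- length(soft) > 0

  pack_eval <- function(z, want_grad = FALSE) {
    W <- matrix(z[seq_len(n * n)], n, n)
    b <- z[n * n + seq_len(n)]
    gamma <- z[npar + 1]
    r <- D - W %*% X - b
    e_sqe <- sum(r * r)
    fv <- term_vals(W)
    g_sqe <- e_sqe / sqe_scale - cap_ratio
    g_terms <- fv - thetas * gamma - goals
    out <- list(e_sqe = e_sqe, fv = fv, g_sqe = g_sqe, g_terms = g_terms)
    if (want_grad) {
      out$r <- r
      out$W <- W
    }
    out
  }

  obj_fn <- function(z) {
    ev <- pack_eval(z)
    gamma <- z[npar + 1]
    pen <- max(0, lam_sqe + rho * ev$g_sqe)^2 - lam_sqe^2
    for (k in seq_len(m)) {
      pen <- pen + max(0, lam[k] + rho * ev$g_terms[k])^2 - lam[k]^2
    }
    (if (has_gamma) gamma else 0) + pen / (2 * rho)
  }
  obj_gr <- function(z) {
    ev <- pack_eval(z, want_grad = TRUE)
    gamma <- z[npar + 1]
    gW <- matrix(0, n, n)
    gb <- rep(0, n)
    ggamma <- if (has_gamma) 1 else 0
    mult_sqe <- max(0, lam_sqe + rho * ev$g_sqe)
    if (mult_sqe > 0) {
      gW <- gW + mult_sqe * (-2 * (ev$r %*% Xt)) / sqe_scale
      gb <- gb + mult_sqe * (-2 * rowSums(ev$r)) / sqe_scale
    }
    for (k in seq_len(m)) {
      mult <- max(0, lam[k] + rho * ev$g_terms[k])
      if (mult > 0) {
        fk <- max(ev$fv[k], 1e-12)
        dk <- matrix(0, n, n)
        dk[masks[[k]]] <- (ev$W[masks[[k]]] - Os[[k]][masks[[k]]]) / fk
        gW <- gW + mult * dk
        ggamma <- ggamma - mult * thetas[k]
      }
    }
    c(as.numeric(gW), gb, ggamma)
  }

  feas_tol <- max(tolerance, 1e-8)
  gamma_prev <- Inf
  for (outer in seq_len(max_outer)) {
    opt <- optim(z, obj_fn, obj_gr, method = "L-BFGS-B",
                 control = list(maxit = inner_maxit, factr = 1e3))
    z <- opt$par
    ev <- pack_eval(z)
    viol <- max(0, ev$g_sqe, if (m > 0) ev$g_terms else NULL)
    lam_sqe <- max(0, lam_sqe + rho * ev$g_sqe)
    lam <- pmax(0, lam + rho * ev$g_terms)
    gamma_now <- z[npar + 1]
    if (viol < feas_tol && outer >= 4 &&
        abs(gamma_now - gamma_prev) < 1e-4 * (1 + abs(gamma_now))) {
      break
    }
    if (viol > 0.25 * prev_viol) rho <- rho * 5
    prev_viol <- viol
    gamma_prev <- gamma_now
  }
  ev <- pack_eval(z)
  hard_viol <- ev$g_terms[hard]
  if (length(hard_viol) && any(hard_viol > 1e-3 * (1 + abs(goals[hard])))) {
    bad <- hard[which(hard_viol > 1e-3 * (1 + abs(goals[hard])))]
    stop_bad(
      "infeasible hard goals: %s (violation %s)",
      paste(vapply(terms[bad], `[[`, character(1), "label"), collapse = ", "),
      paste(signif(hard_viol[hard_viol > 1e-3], 3), collapse = ", ")
    )
  }

  W <- matrix(z[seq_len(n * n)], n, n)
  b <- z[n * n + seq_len(n)]
  gamma <- z[npar + 1]
  labels <- vapply(terms, `[[`, character(1), "label")
  attainment <- tibble::tibble(
    label = c("SQE", labels),
    F = c(ev$e_sqe, ev$fv),
    goal = c(0, goals),
    theta = c(0, thetas),
    slack = c(ev$e_sqe - sqe_cap, ev$fv - goals)
  )
  role <- "moo"
  if (length(labels) == 1 && labels %in% c("Tr", "Sr")) role <- "ratio_fit"
  if (length(labels) == 1 && labels %in% c("Tc", "Sc")) role <- "correlation_fit"
  grn_fit(
    w = W, b = b, role = role, gene_names = data$gene_names,
    sqe = ev$e_sqe, gamma = if (has_gamma) gamma else NA_real_,
    attainment = attainment,
    provenance = list(labels = labels, init_seed = init_seed,
                      sqe_slack = sqe_slack, sqe_min = base$value,
                      solver = "alm")
  )
}

# Exact goal-attainment solver for soft distance terms under the
# squared-error cap. Minimizes max_k (F_k - J_k)/theta_k over (w, b) s.t.
# E^SQE <= SQE_min (1 + slack), by bisection on the constraint multiplier
# mu (per-gene ridge systems share the design Gram matrix) and, for two
# terms, an outer bisection on the weight that equalizes the attainments.
moo_fit_exact <- function(data, terms, sqe_slack, tolerance, init_seed) {
  X <- data$values
  D <- data$derivatives
  n <- nrow(X)
  if (any(vapply(terms, function(tm) nrow(tm$O), integer(1)) != n)) {
    stop_bad("objective dimensions do not match the data")
  }
  A <- t(rbind(X, 1))
  # truncated SVD of the shared design: the constraint acts on the leading
  # singular directions; discarded directions are data-null and fall to the
  # objective/initialization pull (Woodbury keeps every mu well conditioned)
  sv <- svd(A)
  keep <- sv$d > max(sv$d) * 1e-8
  Ur <- sv$u[, keep, drop = FALSE]
  Vr <- sv$v[, keep, drop = FALSE]
  sr <- sv$d[keep]
  UD <- crossprod(Ur, t(D)) # r x n, column g = U' d_g
  dd <- colSums(t(D)^2)
  base <- sqe_minimum(data)
  sqe_cap <- base$value * (1 + sqe_slack) + 1e-9
  thetas <- vapply(terms, `[[`, numeric(1), "weight")
  goals <- vapply(terms, `[[`, numeric(1), "goal")
  m <- length(terms)
  withr::with_seed(as.integer(init_seed), {
    Binit <- matrix(runif(n * (n + 1), -0.1, 0.1), n + 1, n)
  })
  eps_reg <- 1e-6 # pins directions the problem leaves free to the init

  solve_weights <- function(alpha) {
    # alpha: per-term weights of the combined quadratic surrogate
    q <- matrix(0, n, n) # per-gene diagonal penalty on w entries
    lin <- matrix(0, n, n) # per-gene linear target contribution
    for (k in seq_len(m)) {
      mk <- terms[[k]]$mask
      q <- q + alpha[k] * mk
      lin <- lin + alpha[k] * (terms[[k]]$O * mk)
    }
    ridge_beta <- function(mu) {
      # solve (diag(P) + mu * Vr diag(sr^2) Vr') beta = c0 + mu * Vr (sr U'd)
      # per gene via the Woodbury identity, algebraically rearranged so mu
      # only enters through 1/(mu sr^2): stable from mu = 0 to mu -> Inf
      B <- matrix(0, n + 1, n)
      r <- length(sr)
      for (g in seq_len(n)) {
        dinv <- 1 / (c(q[g, ], 0) + eps_reg)
        c0 <- c(lin[g, ], 0) + eps_reg * Binit[, g]
        y0 <- dinv * c0
        if (mu > 0) {
          VtD <- Vr * dinv # (n+1) x r, rows scaled by 1/diag
          core <- diag(1 / (mu * sr^2), r) + crossprod(Vr, VtD)
          y0 <- y0 - VtD %*% solve(core, crossprod(Vr, y0) - UD[, g] / sr)
        }
        B[, g] <- y0
      }
      B
    }
    e_of <- function(B) {
      s_proj <- sr * crossprod(Vr, B) # r x n: singular-space image of each fit
      sum(s_proj^2) - 2 * sum(s_proj * UD) + sum(dd)
    }
    # feasible for large mu; check whether the unconstrained optimum already is
    B0 <- ridge_beta(0)
    if (e_of(B0) <= sqe_cap) {
      B <- B0
    } else {
      lo <- -10; hi <- 14
      while (e_of(ridge_beta(10^hi)) > sqe_cap) hi <- hi + 2
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (e_of(ridge_beta(10^mid)) > sqe_cap) lo <- mid else hi <- mid
      }
      B <- ridge_beta(10^hi)
    }
    W <- t(B[seq_len(n), , drop = FALSE])
    b <- B[n + 1, ]
    fv <- vapply(seq_len(m), function(k) {
      mk <- terms[[k]]$mask
      sqrt(sum((W[mk] - terms[[k]]$O[mk])^2))
    }, numeric(1))
    list(W = W, b = b, fv = fv, e = e_of(B))
  }

  if (m == 1) {
    sol <- solve_weights(1)
  } else {
    att <- function(sol) (sol$fv - goals) / thetas
    s1 <- solve_weights(c(1, 0)) # corner: optimize term 1 alone
    s2 <- solve_weights(c(0, 1))
    if (att(s1)[1] >= att(s1)[2]) {
      sol <- s1 # term 1 dominates everywhere on the frontier
    } else if (att(s2)[2] >= att(s2)[1]) {
      sol <- s2
    } else {
      lo <- 0; hi <- 1 # weight on term 1; equalize attainments
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        sm <- solve_weights(c(mid, 1 - mid))
        if (att(sm)[1] > att(sm)[2]) lo <- mid else hi <- mid
      }
      sol <- solve_weights(c((lo + hi) / 2, 1 - (lo + hi) / 2))
    }
  }

  gamma <- max((sol$fv - goals) / thetas)
  labels <- vapply(terms, `[[`, character(1), "label")
  attainment <- tibble::tibble(
    label = c("SQE", labels),
    F = c(sol$e, sol$fv),
    goal = c(0, goals),
    theta = c(0, thetas),
    slack = c(sol$e - sqe_cap, sol$fv - goals)
  )
  role <- "moo"
  if (length(labels) == 1 && labels %in% c("Tr", "Sr")) role <- "ratio_fit"
  if (length(labels) == 1 && labels %in% c("Tc", "Sc")) role <- "correlation_fit"
  grn_fit(
    w = sol$W, b = sol$b, role = role, gene_names = data$gene_names,
    sqe = sol$e, gamma = gamma, attainment = attainment,
    provenance = list(labels = labels, init_seed = init_seed,
                      sqe_slack = sqe_slack, sqe_min = base$value,
                      solver = "exact")
  )
}

#' Combine two fits into an ensemble
#'
#' Elementwise combination taking interaction magnitudes from the ratio fit
#' and signs from the correlation fit:
#' `|w_a| = |w_r|`, `sign(w_a) = sign(w_c)`. Entries where the sign donor is
#' exactly zero keep a positive sign (documented tie rule); entries where
#' the magnitude donor is zero stay zero. The perturbation vector is taken
#' from the magnitude fit.
#'
#' @param w_r magnitude donor (usually a ratio-objective fit).
#' @param w_c sign donor (usually a correlation-objective fit).
#' @return a [grn_fit()] with role `"ensemble"`.
#' @export
ensemble_combine <- function(w_r, w_c) {
  stopifnot(inherits(w_r, "grn_fit"), inherits(w_c, "grn_fit"))
  if (!all(dim(w_r$w) == dim(w_c$w))) stop_bad("fits have different shapes")
  s <- sign(w_c$w)
  s[s == 0] <- 1
  grn_fit(
    w = abs(w_r$w) * s, b = w_r$b, role = "ensemble",
    gene_names = w_r$gene_names,
    provenance = list(magnitude_from = w_r$role, sign_from = w_c$role)
  )
}
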