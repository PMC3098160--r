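#' Objective matrices for goal-attainment inference
#'
#' A `grn_objective` packages an N x N evidence matrix `O` — entry `O[i, j]`
#' is independent evidence that gene `j` regulates gene `i` — together with
#' the boolean mask of entries that participate in the distance to the
#' fitted interaction matrix, the goal `J`, the weight `theta` of the goal
#' attainment formulation and a label.
#'
#' @param O numeric N x N matrix.
#' @param mask logical N x N matrix; masked-out entries contribute nothing
#'   to the objective distance. Defaults to all off-diagonal entries.
#' @param goal non-negative goal `J` (default 0).
#' @param weight non-negative weight `theta`; 0 makes the goal hard.
#' @param label one of `"DSp"`, `"Tr"`, `"Sr"`, `"Tc"`, `"Sc"`, `"custom"`.
#' @return object of class `grn_objective`.
#' @export
grn_objective <- function(O, mask = NULL, goal = 0, weight = 1, label = "custom") {
  stopifnot(is.matrix(O), nrow(O) == ncol(O))
  mask <- mask %||% (diag(nrow(O)) == 0)
  stopifnot(is.logical(mask), all(dim(mask) == dim(O)))
  if (any(!is.finite(O[mask]))) stop_bad("objective has non-finite masked entries")
  check_number(goal, "goal", min = 0)
  check_number(weight, "weight", min = 0)
  O[!mask] <- 0
  structure(
    list(O = O, mask = mask, goal = goal, weight = weight, label = label),
    class = "grn_objective"
  )
}

#' @export
print.grn_objective <- function(x, ...) {
  cat(sprintf(
    "<grn_objective> %s: %d x %d, %d masked-in entries, J = %g, theta = %g\n",
    x$label, nrow(x$O), ncol(x$O), sum(x$mask), x$goal, x$weight
  ))
  invisible(x)
}

#' Time-delayed Spearman rank-correlation objective (DSp)
#'
#' For every ordered gene pair (i, j) the profile of gene `i` is shifted
#' forward along the time axis by each delay d = 0..`max_delay` grid steps
#' and the Spearman rank correlation with gene `j`'s profile is computed on
#' the overlapping window. The coefficient of largest magnitude becomes
#' `d_src[i, j]` and its delay `dt[i, j]` (smallest delay wins ties). The
#' objective matrix keeps `d_src` only where `dt >= t_o`, so that only
#' pairs where the putative regulator `j` clearly precedes its target `i`
#' contribute; everything else, including the diagonal, is set to 0.
#'
#' @param series a [grn_interp()] (dense interpolated series).
#' @param max_delay maximum delay in grid steps (< half the grid length).
#' @param t_o minimum delay, in grid steps, for a pair to be retained.
#' @param goal,weight goal and weight of the resulting objective term.
#' @return list with elements `d_src` (max delayed correlations), `dt`
#'   (best delays, grid steps), `t_o`, and `objective` (a [grn_objective()]
#'   labelled `"DSp"`).
#' @export
delayed_spearman_objective <- function(series, max_delay = 20, t_o = 1,
                                       goal = 0, weight = 1) {
  stopifnot(inherits(series, "grn_interp"))
  n_t <- ncol(series$values)
  max_delay <- check_count(max_delay, "max_delay", min = 0)
  t_o <- check_count(t_o, "t_o", min = 0)
  if (max_delay >= n_t / 2) stop_bad("max_delay must be below half the grid length")
  if (t_o > max_delay) stop_bad("t_o (%d) cannot exceed max_delay (%d)", t_o, max_delay)
  x <- series$values
  n <- nrow(x)
  best <- matrix(0, n, n)
  best_dt <- matrix(0L, n, n)
  for (d in 0:max_delay) {
    lead <- x[, (1 + d):n_t, drop = FALSE] # gene i, shifted forward
    lag <- x[, 1:(n_t - d), drop = FALSE] # gene j
    cc <- suppressWarnings(cor(t(rank_rows(lead)), t(rank_rows(lag))))
    cc[!is.finite(cc)] <- 0 # constant profiles carry no rank information
    upd <- abs(cc) > abs(best) + 1e-15
    best[upd] <- cc[upd]
    best_dt[upd] <- d
  }
  diag(best) <- 0
  diag(best_dt) <- 0L
  O <- best
  O[best_dt < t_o] <- 0
  diag(O) <- 0
  mask <- diag(n) == 0
  dimnames(O) <- dimnames(best) <- dimnames(best_dt) <- list(series$gene_names, series$gene_names)
  list(
    d_src = best, dt = best_dt, t_o = t_o,
    objective = grn_objective(O, mask, goal = goal, weight = weight, label = "DSp")
  )
}

rank_rows <- function(m) {
  t(apply(m, 1, rank))
}

#' Select the knockout readout time t_p
#'
#' Heuristic readout time for time-resolved knockout panels: for each gene,
#' find the time at which its wild-type response has the largest absolute
#' derivative; `t_p` is the panel time index where the largest number of
#' genes attain that maximum (earliest index on ties).
#'
#' @param ko_panel a time-resolved [grn_ko_panel()] (supplies the candidate
#'   time grid).
#' @param wt_series the wild-type response as a [grn_interp()].
#' @return integer time index into `ko_panel$times` (1-based).
#' @export
select_tp <- function(ko_panel, wt_series) {
  stopifnot(inherits(ko_panel, "grn_ko_panel"), inherits(wt_series, "grn_interp"))
  if (!ko_panel$time_resolved) stop_bad("select_tp needs a time-resolved panel")
  if (length(ko_panel$times) < 3) stop_bad("need at least 3 timepoints")
  dmat <- abs(wt_series$derivatives)
  if (max(dmat) < 1e-12) {
    warning("all profiles are constant; falling back to the midpoint index")
    return(as.integer(ceiling(length(ko_panel$times) / 2)))
  }
  t_at_max <- wt_series$times[apply(dmat, 1, which.max)]
  idx <- vapply(t_at_max, function(t0) which.min(abs(ko_panel$times - t0)), integer(1))
  counts <- tabulate(idx, nbins = length(ko_panel$times))
  as.integer(which.max(counts)) # which.max returns the earliest tie
}

# expression of all genes across mutants at the requested readout
panel_readout <- function(ko_panel, at, tp = NULL) {
  if (at == "steady") {
    if (ko_panel$time_resolved) stop_bad("steady readout requested on a time-resolved panel")
    list(mut = ko_panel$mutant_values, wt = ko_panel$wildtype)
  } else {
    if (!ko_panel$time_resolved) stop_bad("t_p readout requested on a steady-state panel")
    tp <- tp %||% ko_panel$t_p
    if (is.null(tp)) stop_bad("no t_p available: pass `tp` or run select_tp() first")
    tp <- check_count(tp, "tp", min = 1)
    if (tp > length(ko_panel$times)) stop_bad("tp index %d out of range", tp)
    wt <- ko_panel$wildtype
    mv <- ko_panel$mutant_values[, tp, , drop = FALSE]
    dim(mv) <- dim(ko_panel$mutant_values)[c(1, 3)]
    dimnames(mv) <- list(ko_panel$gene_names, ko_panel$mutant_ids)
    list(mut = mv, wt = if (is.matrix(wt)) wt[, tp] else wt)
  }
}

#' Knockout ratio objective (Tr / Sr)
#'
#' Computes, for every gene `i` and mutant `j`, the ratio
#' `r_ij = x_i(KO j) / x_i(WT)` at the requested readout (time index `t_p`
#' for time-resolved panels, steady state otherwise), and turns it into an
#' objective matrix. Conventions:
#'
#' * `"negated_log"` (default): `O_ij = -log2(r_ij)`, so that loss of an
#'   activator (target drops, r < 1) gives a positive entry — signs aligned
#'   with the regulatory sign of the ODE interaction matrix.
#' * `"log"`: `O_ij = +log2(r_ij)`. Same magnitudes, opposite signs; the
#'   orientation whose directed-signed behaviour matches historical
#'   ratio-based objectives (see the methods vignette).
#' * `"raw"`: the untransformed ratio.
#'
#' Columns of genes without a knockout and each mutant's own row are masked.
#'
#' @param ko_panel a [grn_ko_panel()].
#' @param at `"tp"` or `"steady"`.
#' @param sign_convention `"negated_log"`, `"log"` or `"raw"`.
#' @param tp readout index for `at = "tp"` (defaults to `ko_panel$t_p`).
#' @param floor_eps values below this are floored before forming ratios.
#' @param goal,weight goal and weight of the objective term.
#' @return a [grn_objective()] labelled `"Tr"` or `"Sr"`.
#' @export
ratio_objective <- function(ko_panel, at = c("steady", "tp"),
                            sign_convention = c("negated_log", "log", "raw"),
                            tp = NULL, floor_eps = 1e-6, goal = 0, weight = 1) {
  stopifnot(inherits(ko_panel, "grn_ko_panel"))
  at <- match.arg(at)
  sign_convention <- match.arg(sign_convention)
  rd <- panel_readout(ko_panel, at, tp)
  mut <- as.matrix(rd$mut)
  wt <- as.numeric(rd$wt)
  n <- length(ko_panel$gene_names)
  cols <- match(ko_panel$mutant_ids, ko_panel$gene_names)
  # the deleted gene's own row is always ~0 and masked out below; only warn
  # when flooring touches entries that actually enter the objective
  informative <- matrix(TRUE, n, ncol(mut))
  informative[cbind(cols, seq_along(cols))] <- FALSE
  if (any(wt <= floor_eps) || any(mut[informative] < floor_eps)) {
    warning("expression values at/below floor_eps were floored before forming ratios")
  }
  wt <- pmax(wt, floor_eps)
  mut <- pmax(mut, floor_eps)
  r <- mut / wt # recycles wt down columns

  O <- matrix(0, n, n, dimnames = list(ko_panel$gene_names, ko_panel$gene_names))
  mask <- matrix(FALSE, n, n)
  vals <- switch(sign_convention,
    negated_log = -log2(r),
    log = log2(r),
    raw = r
  )
  O[, cols] <- vals
  mask[, cols] <- TRUE
  diag(mask) <- FALSE # a mutant carries no evidence about its own regulation
  diag(O) <- 0
  O[!mask] <- 0
  grn_objective(O, mask, goal = goal, weight = weight,
                label = if (at == "steady") "Sr" else "Tr")
}

#' Knockout cross-mutant correlation objective (Tc / Sc)
#'
#' Correlates the expression vectors of every gene pair across all available
#' mutant conditions at the requested readout. The resulting matrix is
#' symmetric with zero diagonal; genes whose own knockout is missing still
#' receive entries because the correlation runs across the available
#' mutant columns.
#'
#' @inheritParams ratio_objective
#' @param method `"pearson"` (default, continuous expression) or
#'   `"spearman"`.
#' @return a [grn_objective()] labelled `"Tc"` or `"Sc"`.
#' @export
correlation_objective <- function(ko_panel, at = c("steady", "tp"),
                                  method = c("pearson", "spearman"),
                                  tp = NULL, goal = 0, weight = 1) {
  stopifnot(inherits(ko_panel, "grn_ko_panel"))
  at <- match.arg(at)
  method <- match.arg(method)
  rd <- panel_readout(ko_panel, at, tp)
  mut <- as.matrix(rd$mut)
  if (ncol(mut) < 3) stop_bad("need at least 3 mutant columns, got %d", ncol(mut))
  O <- suppressWarnings(cor(t(mut), method = method))
  O[!is.finite(O)] <- 0 # constant genes carry no correlation signal
  diag(O) <- 0
  n <- length(ko_panel$gene_names)
  dimnames(O) <- list(ko_panel$gene_names, ko_panel$gene_names)
  grn_objective(O, diag(n) == 0, goal = goal, weight = weight,
                label = if (at == "steady") "Sc" else "Tc")
}

#' Rescale an objective matrix
#'
#' Brings an objective onto a scale commensurate with the fitted
#' interaction weights before entering the goal-attainment distance.
#'
#' * `"unit_max"` (default): divide masked entries by `max(abs(O))`,
#'   preserving signs and zeros.
#' * `"zscore"`: standardize masked entries to mean 0, sd 1.
#' * `"none"`: identity.
#'
#' An all-zero objective is returned unchanged.
#'
#' @param term a [grn_objective()].
#' @param strategy scaling strategy.
#' @return a rescaled [grn_objective()].
#' @export
scale_objective <- function(term, strategy = c("unit_max", "zscore", "none")) {
  stopifnot(inherits(term, "grn_objective"))
  strategy <- match.arg(strategy)
  if (strategy == "none") return(term)
  v <- term$O[term$mask]
  if (length(v) == 0 || max(abs(v)) == 0) return(term)
  if (strategy == "unit_max") {
    term$O[term$mask] <- v / max(abs(v))
  } else {
    term$O[term$mask] <- (v - mean(v)) / sd(v)
  }
  term
}
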