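#' Undirected ROC AUC of an inferred network
#'
#' Scores every unordered gene pair by `max(|w_ij|, |w_ji|)` (a pair is
#' detected if either direction carries weight), labels it positive when the
#' true network links the pair in either direction, and computes the area
#' under the ROC curve by the rank (Mann-Whitney) formula with ties
#' averaged. Diagonal entries are excluded.
#'
#' @param w a [grn_fit()] or plain N x N score matrix.
#' @param truth a [grn_network()] with at least one edge and one non-edge.
#' @return AUC in \[0, 1\].
#' @export
auc_undirected <- function(w, truth) {
  stopifnot(inherits(truth, "grn_network"))
  wb <- as_wb(w)
  n <- truth$n
  if (nrow(wb$w) != n) stop_bad("fit and truth have different gene counts")
  a <- adjacency_matrix(truth)
  iu <- which(upper.tri(a))
  scores <- pmax(abs(wb$w)[iu], abs(t(wb$w))[iu])
  labels <- (a[iu] != 0) | (t(a)[iu] != 0)
  rank_auc(scores, labels)
}

rank_auc <- function(scores, labels) {
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop_bad("degenerate truth: need at least one linked and one unlinked pair")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Directed-signed AUC (TNR versus TPR)
#'
#' Evaluates how well an inferred weight matrix recovers edges with the
#' correct target, regulator *and* sign. Thresholds tau sweep the sorted
#' nonzero `|w_ij|` values over ordered pairs (i != j). At each tau the
#' predicted network is `{j -> i : |w_ij| >= tau}` with sign `sign(w_ij)`;
#' a true positive is a predicted edge present in the true network with
#' matching direction and sign, and a true negative is an ordered non-edge
#' of the truth that is not predicted. The AUC is the trapezoid area under
#' the TPR-versus-TNR curve, with the empty-prediction endpoint
#' (TNR = 1, TPR = 0) and the full-inclusion endpoint (TNR = 0, TPR = share
#' of true edges whose sign matches) appended. Because a predicted edge with
#' the wrong sign counts against both rates, sign-discordant predictors
#' score below 0.5 (a random dense predictor sits near 0.25, and a
#' perfectly sign-flipped one at 0).
#'
#' @inheritParams auc_undirected
#' @return AUC in \[0, 1\].
#' @export
auc_directed_signed <- function(w, truth) {
  stopifnot(inherits(truth, "grn_network"))
  wb <- as_wb(w)
  n <- truth$n
  if (nrow(wb$w) != n) stop_bad("fit and truth have different gene counts")
  a <- adjacency_matrix(truth)
  off <- which(diag(n) == 0)
  sc <- abs(wb$w)[off]
  sg <- sign(wb$w)[off]
  tr <- a[off]
  n_pos <- sum(tr != 0)
  n_neg <- sum(tr == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_bad("degenerate truth: need at least one edge and one non-edge")
  }
  ord <- order(sc, decreasing = TRUE)
  sc <- sc[ord]
  hit <- (tr[ord] != 0) & (sg[ord] == tr[ord]) # correct direction and sign
  neg <- tr[ord] == 0
  # walk thresholds down the distinct nonzero scores
  nz <- sc > 0
  tp_cum <- cumsum(hit & nz)
  fpneg_cum <- cumsum(neg & nz) # true non-edges predicted so far
  keep <- which(nz & !duplicated(sc, fromLast = TRUE)) # last index per distinct score
  tpr <- tp_cum[keep] / n_pos
  tnr <- (n_neg - fpneg_cum[keep]) / n_neg
  tpr_full <- sum((tr != 0) & (sg == tr)) / n_pos
  tnr_c <- c(1, tnr, 0)
  tpr_c <- c(0, tpr, tpr_full)
  # integrate TPR over TNR along the sweep: TNR is non-increasing and TPR
  # non-decreasing, so tied-TNR points contribute zero-width segments
  sum(-diff(tnr_c) * (head(tpr_c, -1) + tail(tpr_c, -1)) / 2)
}

#' Threshold a weight matrix into a sparse signed network
#'
#' Keeps the largest-magnitude off-diagonal weights. With `n_edges` exactly
#' that many edges are retained (ties broken deterministically by row-major
#' position). With `n_connected_genes` the threshold is lowered through the
#' sorted weights until the number of non-isolated genes first reaches the
#' target.
#'
#' @param w a [grn_fit()] or plain matrix.
#' @param n_edges number of edges to keep.
#' @param n_connected_genes alternatively, target number of connected genes.
#' @return a [grn_network()] with signs from `sign(w_ij)`.
#' @export
threshold_network <- function(w, n_edges = NULL, n_connected_genes = NULL) {
  wb <- as_wb(w)
  n <- nrow(wb$w)
  genes <- rownames(wb$w) %||% sprintf("G%03d", seq_len(n))
  off <- which(diag(n) == 0)
  mag <- abs(wb$w)[off]
  nz <- off[mag > 0]
  ordv <- nz[order(-abs(wb$w)[nz])]
  if (!is.null(n_edges)) {
    n_edges <- check_count(n_edges, "n_edges", min = 0)
    if (n_edges > length(ordv)) {
      stop_bad("cannot keep %d edges: only %d nonzero weights", n_edges, length(ordv))
    }
    sel <- ordv[seq_len(n_edges)]
  } else if (!is.null(n_connected_genes)) {
    n_connected_genes <- check_count(n_connected_genes, "n_connected_genes", min = 0)
    sel <- integer(0)
    connected <- 0L
    k <- 0L
    while (connected < n_connected_genes) {
      if (k == length(ordv)) {
        stop_bad("cannot connect %d genes: only %d reachable with nonzero weights",
                 n_connected_genes, connected)
      }
      k <- k + 1L
      thr <- abs(wb$w)[ordv[k]]
      sel <- ordv[abs(wb$w)[ordv] >= thr]
      connected <- length(unique(c((sel - 1) %% n + 1, (sel - 1) %/% n + 1)))
    }
  } else {
    stop_bad("supply either n_edges or n_connected_genes")
  }
  i <- (sel - 1) %% n + 1 # row = target
  j <- (sel - 1) %/% n + 1 # col = regulator
  grn_network(genes, tibble::tibble(
    regulator = genes[j], target = genes[i],
    sign = as.integer(sign(wb$w[sel]))
  ))
}

#' Compare two AUC distributions by the Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum comparison of AUC batches,
#' exact when both groups have at most 10 values (and no ties), normal
#' approximation otherwise.
#'
#' @param a,b numeric vectors of AUC values (each length >= 3).
#' @return one-row tibble with `statistic`, `p_value`, `method`.
#' @export
compare_auc_distributions <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) stop_bad("each AUC batch needs >= 3 values")
  exact <- length(a) <= 10 && length(b) <= 10 && !any(duplicated(c(a, b)))
  ht <- stats::wilcox.test(a, b, exact = exact, correct = !exact)
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = if (exact) "exact" else "normal approximation"
  )
}
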