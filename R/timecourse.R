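#' Expression time courses
#'
#' A `grn_timecourse` holds expression trajectories as a genes x timepoints
#' x replicates array together with the time grid.
#'
#' @param values numeric array genes x timepoints x replicates (a matrix is
#'   treated as a single replicate).
#' @param times strictly increasing numeric time grid.
#' @param gene_names character gene identifiers.
#' @return object of class `grn_timecourse`.
#' @export
grn_timecourse <- function(values, times, gene_names) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (length(dim(values)) != 3) stop_bad("values must be genes x time x replicates")
  if (dim(values)[1] != length(gene_names)) stop_bad("gene_names length does not match values")
  if (dim(values)[2] != length(times)) stop_bad("times length does not match values")
  if (any(diff(times) <= 0)) stop_bad("times must be strictly increasing")
  if (any(!is.finite(values))) stop_bad("non-finite expression values")
  dimnames(values) <- list(gene_names, NULL, NULL)
  structure(
    list(values = values, times = as.numeric(times), gene_names = as.character(gene_names)),
    class = "grn_timecourse"
  )
}

#' @export
print.grn_timecourse <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<grn_timecourse> %d genes x %d timepoints x %d replicate(s), t in [%g, %g]\n",
    d[1], d[2], d[3], min(x$times), max(x$times)
  ))
  invisible(x)
}

#' @describeIn grn_timecourse long tibble (gene, time, replicate, value).
#' @param x a `grn_timecourse`.
#' @param ... unused.
#' @export
as_tibble.grn_timecourse <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    gene = rep(x$gene_names, times = d[2] * d[3]),
    time = rep(rep(x$times, each = d[1]), times = d[3]),
    replicate = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.numeric(x$values)
  )
}

#' Average replicates of a time course
#'
#' Pointwise arithmetic mean across the replicate axis; the time grid is
#' unchanged. Downstream interpolation expects a single averaged replicate.
#'
#' @param tc a [grn_timecourse()].
#' @return a [grn_timecourse()] with one replicate.
#' @export
average_replicates <- function(tc) {
  stopifnot(inherits(tc, "grn_timecourse"))
  avg <- apply(tc$values, c(1, 2), mean)
  grn_timecourse(avg, tc$times, tc$gene_names)
}

#' Gene-knockout expression panels
#'
#' A `grn_ko_panel` holds mutant expression profiles, one column (or slab)
#' per deleted gene, plus the wild-type reference. Steady-state panels store
#' a genes x mutants matrix; time-resolved panels a genes x timepoints x
#' mutants array with a `times` grid.
#'
#' @param mutant_values matrix (steady) or 3-d array (time-resolved).
#' @param mutant_ids gene deleted in each column, unique.
#' @param wildtype wild-type reference: vector (steady) or genes x time matrix.
#' @param gene_names full gene universe of the panel rows.
#' @param times time grid for time-resolved panels, else `NULL`.
#' @param t_p readout time index, `"steady"`, or `NULL` if not yet selected.
#' @param coverage fraction of genes with a knockout column.
#' @return object of class `grn_ko_panel`.
#' @export
grn_ko_panel <- function(mutant_values, mutant_ids, wildtype, gene_names,
                         times = NULL, t_p = NULL, coverage = NULL) {
  gene_names <- as.character(gene_names)
  mutant_ids <- as.character(mutant_ids)
  if (anyDuplicated(mutant_ids)) stop_bad("each gene may be deleted at most once")
  if (!all(mutant_ids %in% gene_names)) stop_bad("mutant_ids must be listed genes")
  time_resolved <- length(dim(mutant_values)) == 3
  nm <- if (time_resolved) dim(mutant_values)[3] else ncol(mutant_values)
  if (nm != length(mutant_ids)) stop_bad("mutant_ids length does not match columns")
  if (dim(mutant_values)[1] != length(gene_names)) stop_bad("row count does not match gene_names")
  if (time_resolved && is.null(times)) stop_bad("time-resolved panel needs a `times` grid")
  coverage <- coverage %||% (length(mutant_ids) / length(gene_names))
  if (coverage <= 0 || coverage > 1) stop_bad("coverage must be in (0, 1]")
  structure(
    list(
      mutant_values = mutant_values, mutant_ids = mutant_ids,
      wildtype = wildtype, gene_names = gene_names,
      times = times, t_p = t_p, coverage = coverage,
      time_resolved = time_resolved
    ),
    class = "grn_ko_panel"
  )
}

#' @export
print.grn_ko_panel <- function(x, ...) {
  cat(sprintf(
    "<grn_ko_panel> %d genes, %d mutants (coverage %.0f%%), %s\n",
    length(x$gene_names), length(x$mutant_ids), 100 * x$coverage,
    if (x$time_resolved) sprintf("time-resolved (%d timepoints)", length(x$times)) else "steady state"
  ))
  invisible(x)
}
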