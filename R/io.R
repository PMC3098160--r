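# Plain-text serialization. One dialect throughout: TSV with genes as rows,
# a header row of time/condition labels, and a `gene` first column. Values
# round-trip at 12 significant digits. Sidecar JSON files carry metadata
# (seed, grid, configuration hash) so any artifact can be regenerated.

fmt_num <- function(x) {
  formatC(x, digits = 12, format = "g")
}

write_matrix_tsv <- function(m, path, col_labels, first = "gene") {
  header <- paste(c(first, col_labels), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop_bad("%s: expected a header row and at least one gene row", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    stop_bad("%s: ragged row at line %d (%d fields, %d expected)", path, bad, nf[bad], nf[1])
  }
  header <- parts[[1]][-1]
  genes <- vapply(parts[-1], `[[`, character(1), 1)
  if (anyDuplicated(genes)) {
    stop_bad("%s: duplicate gene name '%s'", path, genes[duplicated(genes)][1])
  }
  vals <- suppressWarnings(
    do.call(rbind, lapply(parts[-1], function(p) as.numeric(p[-1])))
  )
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop_bad("%s: non-numeric cell at line %d", path, bad + 1)
  }
  dimnames(vals) <- list(genes, header)
  vals
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  meta$package_version <- as.character(utils::packageVersion("goalnet"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write expression time courses as TSV
#'
#' `write_timecourse_tsv()` writes one file per replicate, suffixed
#' `_rep1`, `_rep2`, ... before the extension, with genes as rows and the
#' time grid as header labels, plus a JSON sidecar with the grid and
#' replicate count. `read_timecourse_tsv()` reassembles the replicates.
#'
#' @param tc a [grn_timecourse()].
#' @param path base file path (e.g. `"run/timecourse.tsv"`).
#' @param meta optional extra metadata stored in the sidecar (e.g. seed).
#' @return the base path, invisibly; the reader returns a
#'   [grn_timecourse()].
#' @export
write_timecourse_tsv <- function(tc, path, meta = list()) {
  stopifnot(inherits(tc, "grn_timecourse"))
  d <- dim(tc$values)
  for (r in seq_len(d[3])) {
    m <- tc$values[, , r, drop = FALSE]
    dim(m) <- d[1:2]
    rownames(m) <- tc$gene_names
    write_matrix_tsv(m, rep_path(path, r), fmt_num(tc$times))
  }
  write_sidecar(path, c(list(kind = "timecourse", times = tc$times, replicates = d[3]), meta))
  invisible(path)
}

rep_path <- function(path, r) {
  sub("(\\.[^.]*)$|$", sprintf("_rep%d\\1", r), path)
}

#' @rdname write_timecourse_tsv
#' @export
read_timecourse_tsv <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  reps <- lapply(seq_len(meta$replicates), function(r) read_matrix_tsv(rep_path(path, r)))
  vals <- array(unlist(reps), c(dim(reps[[1]]), length(reps)))
  grn_timecourse(vals, meta$times, rownames(reps[[1]]))
}

#' Read and write a generic expression matrix TSV
#'
#' Genes as rows, one header row of column labels. Round-trips numeric
#' content at 12 significant digits. The reader reports ragged rows,
#' duplicate gene names and non-numeric cells with their line number.
#'
#' @param m numeric matrix with rownames (genes).
#' @param path file path.
#' @return `read_expression_tsv()` returns the named matrix.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  write_matrix_tsv(m, path, colnames(m) %||% sprintf("c%d", seq_len(ncol(m))))
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  read_matrix_tsv(path)
}

#' Read and write knockout panels as TSV
#'
#' Steady-state panels are a single matrix (columns = deleted genes, plus a
#' `WT` wild-type column); time-resolved panels store one file per mutant
#' (suffix `_koGENE`) plus `_wt`. A JSON sidecar records the layout.
#'
#' @param panel a [grn_ko_panel()].
#' @param path base file path.
#' @param meta optional extra sidecar metadata.
#' @return base path invisibly; the reader returns a [grn_ko_panel()].
#' @export
write_ko_panel_tsv <- function(panel, path, meta = list()) {
  stopifnot(inherits(panel, "grn_ko_panel"))
  if (!panel$time_resolved) {
    m <- cbind(panel$mutant_values, WT = panel$wildtype)
    rownames(m) <- panel$gene_names
    write_matrix_tsv(m, path, c(panel$mutant_ids, "WT"))
  } else {
    for (k in seq_along(panel$mutant_ids)) {
      m <- panel$mutant_values[, , k]
      rownames(m) <- panel$gene_names
      write_matrix_tsv(m, ko_path(path, panel$mutant_ids[k]), fmt_num(panel$times))
    }
    wt <- panel$wildtype
    rownames(wt) <- panel$gene_names
    write_matrix_tsv(wt, ko_path(path, "wt"), fmt_num(panel$times))
  }
  write_sidecar(path, c(list(
    kind = "ko_panel", time_resolved = panel$time_resolved,
    mutant_ids = panel$mutant_ids, times = panel$times,
    t_p = panel$t_p, coverage = panel$coverage
  ), meta))
  invisible(path)
}

ko_path <- function(path, tag) suffix_path(path, paste0("ko", tag))

suffix_path <- function(path, tag) {
  sub("(\\.[^.]*)$|$", sprintf("_%s\\1", tag), path)
}

#' @rdname write_ko_panel_tsv
#' @export
read_ko_panel_tsv <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (!isTRUE(meta$time_resolved)) {
    m <- read_matrix_tsv(path)
    wt <- m[, ncol(m)]
    mut <- m[, -ncol(m), drop = FALSE]
    grn_ko_panel(mut, meta$mutant_ids, wt, rownames(m),
                 t_p = meta$t_p, coverage = meta$coverage)
  } else {
    mats <- lapply(meta$mutant_ids, function(id) read_matrix_tsv(ko_path(path, id)))
    wt <- read_matrix_tsv(ko_path(path, "wt"))
    vals <- array(unlist(mats), c(dim(mats[[1]]), length(mats)))
    dimnames(vals) <- list(rownames(mats[[1]]), NULL, meta$mutant_ids)
    grn_ko_panel(vals, meta$mutant_ids, wt, rownames(mats[[1]]),
                 times = meta$times, t_p = meta$t_p, coverage = meta$coverage)
  }
}

#' Read and write objective terms
#'
#' The matrix goes to TSV; mask, goal, weight and label go to the JSON
#' sidecar.
#'
#' @param term a [grn_objective()].
#' @param path file path.
#' @return base path invisibly; the reader returns a [grn_objective()].
#' @export
write_objective_tsv <- function(term, path) {
  stopifnot(inherits(term, "grn_objective"))
  m <- term$O
  if (is.null(rownames(m))) dimnames(m) <- list(sprintf("G%03d", seq_len(nrow(m))), NULL)
  write_matrix_tsv(m, path, rownames(m))
  write_sidecar(path, list(
    kind = "objective", label = term$label, goal = term$goal,
    weight = term$weight,
    mask = apply(term$mask, 1, function(r) paste0(ifelse(r, "T", "F"), collapse = ""))
  ))
  invisible(path)
}

#' @rdname write_objective_tsv
#' @export
read_objective_tsv <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  O <- read_matrix_tsv(path)
  # mask rows are serialized as strings of T/F characters
  mask <- matrix(unlist(strsplit(meta$mask, "")) == "T", nrow(O), ncol(O), byrow = TRUE)
  grn_objective(O, mask, goal = meta$goal, weight = meta$weight, label = meta$label)
}

#' Read and write fitted weight matrices
#'
#' The interaction matrix `w` goes to one TSV (genes x genes), the
#' perturbation vector `b` to a second with suffix `_b`, and role/metadata
#' to the JSON sidecar. A ranked edge list is available via
#' [tidy.grn_fit()].
#'
#' @param fit a [grn_fit()].
#' @param path file path of the `w` matrix.
#' @return base path invisibly; the reader returns a [grn_fit()].
#' @export
write_fit_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "grn_fit"))
  write_matrix_tsv(fit$w, path, fit$gene_names)
  bmat <- matrix(fit$b, ncol = 1, dimnames = list(fit$gene_names, "b"))
  write_matrix_tsv(bmat, suffix_path(path, "b"), "b")
  write_sidecar(path, list(
    kind = "fit", role = fit$role, sqe = fit$sqe, gamma = fit$gamma,
    provenance = fit$provenance
  ))
  invisible(path)
}

#' @rdname write_fit_tsv
#' @export
read_fit_tsv <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  w <- read_matrix_tsv(path)
  b <- read_matrix_tsv(suffix_path(path, "b"))[, 1]
  grn_fit(w, b, role = meta$role, gene_names = rownames(w),
          sqe = meta$sqe %||% NA_real_, gamma = meta$gamma %||% NA_real_,
          provenance = as.list(meta$provenance %||% list()))
}
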