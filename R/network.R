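#' Signed directed gene networks
#'
#' A `grn_network` stores a signed directed topology over a set of genes:
#' the ground truth of a benchmark or a thresholded inferred network. Edges
#' are kept as a tibble with columns `regulator`, `target` and
#' `sign` (+1 activation, -1 repression).
#'
#' @param gene_names character vector of gene identifiers (unique).
#' @param edges tibble/data.frame with columns `regulator`, `target`, `sign`.
#' @param allow_self_loops keep self edges? Ground-truth generators never
#'   emit them; defaults to `FALSE` which drops any present.
#' @return An object of class `grn_network` with fields `gene_names`,
#'   `edges` and `n`.
#' @export
grn_network <- function(gene_names, edges, allow_self_loops = FALSE) {
  gene_names <- as.character(gene_names)
  if (anyDuplicated(gene_names)) stop_bad("duplicate gene names in network")
  edges <- tibble::as_tibble(edges)
  required <- c("regulator", "target", "sign")
  if (!all(required %in% names(edges))) {
    stop_bad("edges need columns: %s", paste(required, collapse = ", "))
  }
  edges <- edges[required]
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  bad <- setdiff(unique(c(edges$regulator, edges$target)), gene_names)
  if (length(bad) > 0) {
    stop_bad("edge endpoints not in gene_names: %s", paste(head(bad, 5), collapse = ", "))
  }
  if (!all(edges$sign %in% c(-1L, 1L))) {
    stop_bad("edge signs must be +1 or -1")
  }
  if (!allow_self_loops) {
    edges <- edges[edges$regulator != edges$target, , drop = FALSE]
  }
  edges <- dplyr::distinct(edges, .data$regulator, .data$target, .keep_all = TRUE)
  structure(
    list(gene_names = gene_names, edges = edges, n = length(gene_names)),
    class = "grn_network"
  )
}

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf(
    "<grn_network> %d genes, %d edges (%d activating, %d repressing)\n",
    x$n, nrow(x$edges), sum(x$edges$sign == 1), sum(x$edges$sign == -1)
  ))
  invisible(x)
}

#' @describeIn grn_network edge table of a network as a tibble.
#' @param x a `grn_network`.
#' @param ... unused.
#' @export
as_tibble.grn_network <- function(x, ...) x$edges

#' Signed adjacency matrix of a network
#'
#' Returns the N x N signed adjacency in the orientation used by the ODE
#' model: entry `(i, j)` is the sign of the edge from regulator `j` to
#' target `i` (rows index targets, columns regulators), 0 if absent.
#'
#' @param network a `grn_network`.
#' @return integer matrix with `dimnames = list(target, regulator)`.
#' @export
adjacency_matrix <- function(network) {
  stopifnot(inherits(network, "grn_network"))
  n <- network$n
  a <- matrix(0L, n, n, dimnames = list(network$gene_names, network$gene_names))
  if (nrow(network$edges) > 0) {
    a[cbind(
      match(network$edges$target, network$gene_names),
      match(network$edges$regulator, network$gene_names)
    )] <- network$edges$sign
  }
  a
}

#' Generate a scale-free signed source topology
#'
#' Builds a weakly connected signed directed network with heavy-tailed
#' out-degree by preferential attachment: each newly added gene is regulated
#' by existing genes chosen proportionally to their connectivity, so early
#' genes become regulatory hubs. This plays the role of the large curated
#' source network (e.g. a transcriptional network of a model bacterium) from
#' which benchmark subnetworks are extracted.
#'
#' @param n_genes number of genes (>= 2).
#' @param avg_degree target average number of regulators per gene (>= 1 and
#'   < `n_genes`). May be fractional.
#' @param activation_fraction probability that an edge is activating (+1).
#' @param seed integer seed; output is deterministic given the seed.
#' @return a [grn_network()].
#' @examples
#' net <- generate_source_topology(50, avg_degree = 2, seed = 1)
#' net
#' @export
generate_source_topology <- function(n_genes, avg_degree = 2,
                                     activation_fraction = 0.6, seed = 1) {
  n_genes <- check_count(n_genes, "n_genes", min = 2)
  check_number(avg_degree, "avg_degree", min = 1)
  if (avg_degree >= n_genes) {
    stop_bad("avg_degree (%s) must be smaller than n_genes (%d)", avg_degree, n_genes)
  }
  check_number(activation_fraction, "activation_fraction", min = 0, max = 1)
  gene_names <- sprintf("G%0*d", max(3L, nchar(n_genes)), seq_len(n_genes))

  withr::with_seed(as.integer(seed), {
    base <- floor(avg_degree)
    extra <- rbinom(n_genes, 1, avg_degree - base)
    out_seq <- pmin(base + extra, seq_len(n_genes) - 1L)
    out_seq[-1] <- pmax(out_seq[-1], 1L) # keep the growth connected
    out_seq[1] <- 0L
    g <- igraph::sample_pa(n_genes, power = 1, out.seq = out_seq, directed = TRUE)
    el <- igraph::as_edgelist(g, names = FALSE)
    # sample_pa points each new node at established nodes; the established
    # (preferentially attached) node acts as the regulator, so hubs acquire
    # heavy-tailed out-degree.
    edges <- tibble::tibble(
      regulator = gene_names[el[, 2]],
      target = gene_names[el[, 1]],
      sign = ifelse(runif(nrow(el)) < activation_fraction, 1L, -1L)
    )
  })
  grn_network(gene_names, edges)
}

#' Extract a subnetwork by random neighbour growth
#'
#' Grows a node set from a randomly selected seed gene by repeatedly adding
#' a uniformly chosen neighbouring gene (ignoring edge direction) until the
#' requested size is reached, then returns the induced subgraph. This is how
#' in-silico benchmark suites carve biologically plausible modules out of a
#' large source network.
#'
#' @param source a weakly connected [grn_network()].
#' @param size number of genes to extract (1..`source$n`).
#' @param seed integer seed controlling the growth.
#' @return a [grn_network()] on the grown gene set (order of `gene_names`
#'   follows the source network).
#' @export
extract_subnetwork <- function(source, size, seed = 1) {
  stopifnot(inherits(source, "grn_network"))
  size <- check_count(size, "size", min = 1)
  if (size > source$n) {
    stop_bad("requested size %d exceeds source network size %d", size, source$n)
  }
  nbrs <- neighbour_sets(source)
  withr::with_seed(as.integer(seed), {
    sel <- sample.int(source$n, 1)
    while (length(sel) < size) {
      # sorted frontier: the growth is fully defined by seed and topology
      frontier <- sort(setdiff(unique(unlist(nbrs[sel], use.names = FALSE)), sel))
      if (length(frontier) == 0) {
        stop_bad("source network is not weakly connected: growth stalled at %d genes", length(sel))
      }
      sel <- c(sel, frontier[sample.int(length(frontier), 1)])
    }
  })
  keep <- source$gene_names[sort(sel)]
  edges <- source$edges[source$edges$regulator %in% keep &
    source$edges$target %in% keep, , drop = FALSE]
  grn_network(keep, edges)
}

# Undirected neighbour index sets, by gene index.
neighbour_sets <- function(network) {
  n <- network$n
  ri <- match(network$edges$regulator, network$gene_names)
  ti <- match(network$edges$target, network$gene_names)
  nbrs <- vector("list", n)
  for (k in seq_len(n)) nbrs[[k]] <- integer(0)
  for (e in seq_along(ri)) {
    nbrs[[ri[e]]] <- c(nbrs[[ri[e]]], ti[e])
    nbrs[[ti[e]]] <- c(nbrs[[ti[e]]], ri[e])
  }
  lapply(nbrs, unique)
}

#' Read or write a signed edge list
#'
#' The plain-text dialect is a 3-column TSV `regulator  target  sign` with
#' signs written as `+`, `-`, `+1` or `-1`. The SIF dialect
#' `regulator  relation  target` with relation `activates`/`represses` is
#' also accepted on read (detected from the middle column).
#'
#' @param path file path.
#' @param gene_names optional explicit gene universe; defaults to the genes
#'   seen in the file.
#' @return `read_edge_list()` returns a [grn_network()];
#'   `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path, gene_names = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3)) {
    stop_bad("edge list %s: line %d has %d fields (3 expected)", path, which(nf != 3)[1], nf[nf != 3][1])
  }
  m <- do.call(rbind, parts)
  mid <- trimws(m[, 2])
  if (any(mid %in% c("activates", "represses"))) { # SIF dialect
    regulator <- trimws(m[, 1])
    target <- trimws(m[, 3])
    sign <- ifelse(mid == "activates", 1L, ifelse(mid == "represses", -1L, NA_integer_))
    if (anyNA(sign)) stop_bad("edge list %s: unknown relation '%s'", path, mid[is.na(sign)][1])
  } else {
    regulator <- trimws(m[, 1])
    target <- mid
    sraw <- trimws(m[, 3])
    sign <- ifelse(sraw %in% c("+", "+1", "1"), 1L, ifelse(sraw %in% c("-", "-1"), -1L, NA_integer_))
    if (anyNA(sign)) stop_bad("edge list %s: unknown sign '%s'", path, sraw[is.na(sign)][1])
  }
  genes <- gene_names %||% sort(unique(c(regulator, target)))
  grn_network(genes, tibble::tibble(regulator = regulator, target = target, sign = sign))
}

#' @rdname read_edge_list
#' @param network a [grn_network()] to serialize.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "grn_network"))
  lines <- sprintf(
    "%s\t%s\t%+d", network$edges$regulator, network$edges$target, network$edges$sign
  )
  writeLines(lines, path)
  invisible(path)
}
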