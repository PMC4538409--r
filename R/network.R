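#' Construct a protein-protein interaction network
#'
#' A `ppi_network` is an undirected weighted graph stored as a sorted node
#' vector plus a canonical edge table (each unordered pair appears once, with
#' `from` lexicographically before `to`). Self-loops are dropped with a
#' warning; duplicate edges (including reversed duplicates) are merged keeping
#' the maximum weight.
#'
#' @param edges data.frame with columns `from`, `to` and optionally `weight`
#'   (default 1). Weights must be nonnegative; a weight of 0 is treated as
#'   edge absence during normalization.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers to include.
#' @return object of class `ppi_network` with elements `nodes` (sorted
#'   character vector) and `edges` (data.frame `from`, `to`, `weight`).
#' @export
ppi_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(edges)))
      stop("edges must have columns 'from' and 'to'")
    if (is.null(edges$weight)) edges$weight <- 1
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$weight <- as.numeric(edges$weight)
    if (anyNA(edges$weight) || any(!is.finite(edges$weight)))
      stop("edge weights must be finite numbers")
    if (any(edges$weight < 0))
      stop("edge weights must be nonnegative")
    loops <- edges$from == edges$to
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped")
      nodes <- c(nodes, edges$from[loops])   # keep the node, drop the loop
      edges <- edges[!loops, , drop = FALSE]
    }
    if (nrow(edges)) {
      swap <- edges$from > edges$to
      tmp <- edges$from[swap]
      edges$from[swap] <- edges$to[swap]
      edges$to[swap] <- tmp
      key <- paste(edges$from, edges$to, sep = "\t")
      if (anyDuplicated(key)) {
        w <- tapply(edges$weight, key, max)
        parts <- strsplit(names(w), "\t", fixed = TRUE)
        edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                            to = vapply(parts, `[`, "", 2L),
                            weight = as.numeric(w),
                            stringsAsFactors = FALSE)
      }
      o <- order(edges$from, edges$to, method = "radix")
      edges <- edges[o, , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  all_nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)),
                    method = "radix")
  structure(list(nodes = all_nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("PPI network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Number of nodes in a network
#' @param net a [ppi_network]
#' @return integer node count
#' @export
n_nodes <- function(net) length(net$nodes)

#' Number of edges in a network
#' @param net a [ppi_network]
#' @return integer edge count
#' @export
n_edges <- function(net) nrow(net$edges)

edge_keys <- function(edges) paste(edges$from, edges$to, sep = "\t")

#' Read an edge list from a TSV file
#'
#' One edge per line with 2 or 3 whitespace/tab-separated columns
#' (`protein_a`, `protein_b`, optional nonnegative `weight`). Lines starting
#' with `#` are treated as comments/headers and skipped. Reversed duplicates
#' are merged (maximum weight kept) and self-loops dropped with a warning.
#'
#' @param path file path.
#' @param has_weights logical; `NA` (default) auto-detects from the column
#'   count, `TRUE` requires 3 columns, `FALSE` ignores any third column.
#' @return a [ppi_network]
#' @export
read_edge_list <- function(path, has_weights = NA) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx))
    return(ppi_network())
  parts <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(parts)
  bad <- which(nf != 2L & nf != 3L)
  if (length(bad))
    stop("malformed edge line ", idx[bad[1L]], " in '", path,
         "': expected 2 or 3 columns, got ", nf[bad[1L]])
  if (isTRUE(has_weights) && any(nf != 3L))
    stop("has_weights = TRUE but line ", idx[which(nf != 3L)[1L]],
         " has no weight column")
  from <- vapply(parts, `[`, "", 1L)
  to <- vapply(parts, `[`, "", 2L)
  if (isFALSE(has_weights)) {
    weight <- rep(1, length(from))
  } else {
    weight <- vapply(parts, function(p)
      if (length(p) == 3L) suppressWarnings(as.numeric(p[3L])) else 1,
      numeric(1))
  }
  if (anyNA(weight)) {
    j <- which(is.na(weight))[1L]
    stop("non-numeric weight on line ", idx[j], " in '", path, "'")
  }
  if (any(weight < 0)) {
    j <- which(weight < 0)[1L]
    stop("negative weight on line ", idx[j], " in '", path, "'")
  }
  ppi_network(data.frame(from = from, to = to, weight = weight,
                         stringsAsFactors = FALSE))
}

#' Write a network as a 3-column TSV edge list
#'
#' Output round-trips through [read_edge_list()]: a `#`-prefixed header line
#' followed by `from TAB to TAB weight`, weights serialized with 15
#' significant digits.
#'
#' @param net a [ppi_network]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_weighted_edges <- function(net, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#from\tto\tweight", con)
  if (nrow(net$edges))
    writeLines(paste(net$edges$from, net$edges$to,
                     formatC(net$edges$weight, digits = 15, format = "g"),
                     sep = "\t"), con)
  invisible(path)
}

#' Sparse weighted adjacency matrix of a network
#'
#' @param net a [ppi_network]
#' @return symmetric sparse `Matrix` indexed by the network's sorted node
#'   order
#' @export
adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  i <- match(net$edges$from, net$nodes)
  j <- match(net$edges$to, net$nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                       x = rep(net$edges$weight, 2L),
                       dims = c(n, n), dimnames = list(net$nodes, net$nodes))
}

#' Degree-normalized adjacency matrix
#'
#' Computes `W'[v,u] = w(v,u) / sqrt(d(v) d(u))` where `d(x)` is the weighted
#' degree, i.e. the symmetric normalization `D^{-1/2} W D^{-1/2}`. Rows and
#' columns of isolated (zero-degree) nodes are all zero; the spectral radius
#' of the result is at most 1, which guarantees convergence of the
#' propagation iteration for any smoothing weight below 1.
#'
#' @param net a [ppi_network]
#' @return symmetric sparse `Matrix` with entries in `[0, 1]`, same node
#'   order as `net$nodes`
#' @export
normalize_adjacency <- function(net) {
  W <- adjacency_matrix(net)
  d <- Matrix::rowSums(W)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  D <- Matrix::Diagonal(x = inv_sqrt)
  Wn <- D %*% W %*% D
  dimnames(Wn) <- list(net$nodes, net$nodes)
  Wn
}
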