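#' Random walk with restart proximity to a seed set
#'
#' Iterates `p <- (1 - r) * M p + r * p0` where `M` is the column-stochastic
#' transition matrix built from the (reliability-weighted) edge weights —
#' dangling nodes receive a self-loop so columns stay stochastic — and `p0`
#' is uniform over the seeds present in the network. This is the standard
#' PageRank-with-personalization walk: the stationary vector measures each
#' protein's network proximity to the known disease genes.
#'
#' @param net a [ppi_network], typically reliability-weighted
#' @param seeds character vector of seed gene/protein ids; seeds absent from
#'   the network are dropped with a warning
#' @param r restart probability in `(0, 1]` (default 0.75)
#' @param tol L1 convergence threshold (default 1e-6)
#' @param max_iter iteration cap (default 1000)
#' @return named numeric probability vector over `net$nodes` (sums to 1),
#'   with attributes `r`, `iterations`, `converged`, `seeds`
#' @export
rwr <- function(net, seeds, r = 0.75, tol = 1e-6, max_iter = 1000L) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1)
    stop("restart probability r must lie in (0, 1]")
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, net$nodes)
  if (length(missing)) {
    warning(length(missing), " seed(s) absent from network dropped: ",
            paste(utils::head(missing, 5L), collapse = ", "))
    seeds <- setdiff(seeds, missing)
  }
  if (!length(seeds)) stop("no usable seeds in the network")
  n <- length(net$nodes)
  W <- adjacency_matrix(net)
  d <- Matrix::colSums(W)
  dangling <- which(d == 0)
  if (length(dangling)) {
    W <- W + Matrix::sparseMatrix(i = dangling, j = dangling,
                                  x = rep(1, length(dangling)),
                                  dims = c(n, n))
    d <- Matrix::colSums(W)
  }
  M <- W %*% Matrix::Diagonal(x = 1 / d)   # columns sum to 1
  p0 <- numeric(n)
  p0[match(seeds, net$nodes)] <- 1 / length(seeds)
  p <- p0
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    p_new <- as.numeric((1 - r) * (M %*% p)) + r * p0
    iterations <- iterations + 1L
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) { converged <- TRUE; break }
  }
  names(p) <- net$nodes
  attr(p, "r") <- r
  attr(p, "iterations") <- iterations
  attr(p, "converged") <- converged
  attr(p, "seeds") <- seeds
  p
}

#' Rank nodes by proximity score
#'
#' @param pro named proximity vector from [rwr()]
#' @return character vector of node ids sorted by score descending, ties
#'   broken lexicographically
#' @export
rank_by_proximity <- function(pro) {
  ids <- names(pro)
  ids[order(-as.numeric(pro), ids, method = "radix")]
}

#' Write a proximity vector as a sorted 2-column TSV
#' @param pro named proximity vector from [rwr()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_proximity <- function(pro, path) {
  ord <- rank_by_proximity(pro)
  writeLines(c("#protein\tscore",
               paste(ord, formatC(as.numeric(pro[ord]), digits = 15,
                                  format = "g"), sep = "\t")), path)
  invisible(path)
}
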