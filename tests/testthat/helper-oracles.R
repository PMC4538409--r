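# Independent oracles and small fixture builders shared across test files.
# These deliberately avoid the package's own code paths (dense base-R linear
# algebra, exhaustive enumeration) so that agreement is evidence, not
# tautology.

# Erdos-Renyi style random network with optional random weights
rand_network <- function(n, p = 0.15, seed = 1, weighted = FALSE) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  w <- if (weighted) runif(sum(keep), 0.1, 2) else rep(1, sum(keep))
  ppi_network(data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                         weight = w, stringsAsFactors = FALSE),
              nodes = ids)
}

path_network <- function(n) {
  ids <- sprintf("p%02d", seq_len(n))
  ppi_network(data.frame(from = ids[-n], to = ids[-1]))
}

# dense adjacency straight from the edge table
dense_adjacency <- function(net) {
  n <- length(net$nodes)
  W <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$from[i]; b <- net$edges$to[i]
    W[a, b] <- W[a, b] + net$edges$weight[i]
    W[b, a] <- W[b, a] + net$edges$weight[i]
  }
  W
}

# RWR stationary vector by direct dense linear solve
rwr_direct <- function(net, seeds, r) {
  W <- dense_adjacency(net)
  d <- colSums(W)
  for (j in which(d == 0)) W[j, j] <- 1
  d <- colSums(W)
  M <- sweep(W, 2, d, "/")
  n <- nrow(W)
  p0 <- numeric(n); names(p0) <- net$nodes
  p0[seeds] <- 1 / length(seeds)
  drop(solve(diag(n) - (1 - r) * M, r * p0))
}

# propagation fixed point by direct dense linear solve
propagate_direct <- function(Wn, b, alpha) {
  Wd <- as.matrix(Wn)
  unname(drop(solve(diag(nrow(Wd)) - alpha * Wd, (1 - alpha) * b)))
}

# -log hypergeometric tail by exhaustive enumeration of all placements of
# the second neighbor set among the N proteins
sw_enum <- function(k, nv, nu, N) {
  if (k <= 0) return(0)
  placements <- combn(N, nu)
  overlap <- colSums(placements <= nv)  # treat nodes 1..nv as N(v)
  -log(mean(overlap >= k))
}

# neighbor sets computed independently from the edge table
neighbors_of <- function(net, v) {
  e <- net$edges[net$edges$weight > 0, , drop = FALSE]
  unique(c(e$to[e$from == v], e$from[e$to == v]))
}

sw_enum_net <- function(net, v, u) {
  nv <- neighbors_of(net, v)
  nu <- neighbors_of(net, u)
  N <- length(net$nodes)
  # relabel so N(v) occupies slots 1..|N(v)|; overlap count is all that
  # matters, so only sizes and the shared count enter
  k <- length(intersect(nv, nu))
  if (k == 0) return(0)
  placements <- combn(N, length(nu))
  # draws hitting the first |N(v)| slots are "shared"
  -log(mean(colSums(placements <= length(nv)) >= k))
}

spectral_radius <- function(A, iters = 500) {
  x <- rep(1, nrow(A))
  for (i in seq_len(iters)) {
    y <- as.numeric(A %*% x)
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) return(0)
    x <- y / nrm
  }
  sum(x * as.numeric(A %*% x))
}

# AUC of scores against 0/1 labels via the package's ROC sweep
score_auc <- function(scores, labels) {
  ids <- sprintf("g%05d", seq_along(scores))
  ord <- ids[order(-scores, ids, method = "radix")]
  roc_points(ord, ids[labels == 1], ids[labels == 0])$auc
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

tiny_bundle <- function(seed = 7) {
  generate_prosim_data(synth_config(n_nodes = 120L, module_size = 12L,
                                    n_seed_genes = 6L, n_samples = 40L,
                                    negative_size = 60L, seed = seed))
}
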