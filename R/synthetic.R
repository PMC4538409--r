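#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the statistical structure the prioritization
#' method assumes: a scale-free interaction backbone with a planted dense
#' disease module, factor-model coexpression inside the module,
#' localization-compatibility bias of true interactions, a block-structured
#' disease similarity matrix whose related/unrelated levels sit in the
#' informative (>= 0.6) and uninformative (<= 0.3) similarity bands, and a
#' negative interaction set disjoint from the true edges.
#'
#' @param n_nodes network size (default 500)
#' @param pa_m edges added per node during preferential attachment
#' @param pa_power preferential-attachment exponent (1 = linear)
#' @param module_size planted disease-module size (default 25)
#' @param module_density target within-module edge density in `(0, 1]`
#' @param n_samples expression sample count
#' @param loading within-module latent-factor loading; the expected
#'   within-module Pearson correlation is `loading^2 / (loading^2 +
#'   noise_sd^2)`
#' @param noise_sd per-gene expression noise standard deviation
#' @param n_diseases number of diseases (1 query + decoys, default 5)
#' @param n_related number of diseases phenotypically related to the query
#' @param n_seed_genes associated genes per disease (default 10)
#' @param sim_related similarity of related disease pairs (informative
#'   band, default 0.7)
#' @param sim_unrelated similarity of unrelated pairs (uninformative band,
#'   default 0.2)
#' @param negative_size number of negative (non-interacting) pairs
#' @param compat_bias probability of rejecting a localization-compatible
#'   pair when sampling negatives (drives the compatibility contrast
#'   between true and false interactions)
#' @param seed RNG seed; recorded in the output manifest
#' @return list of class `synth_config`
#' @export
synth_config <- function(n_nodes = 500L, pa_m = 2L, pa_power = 1,
                         module_size = 25L, module_density = 0.3,
                         n_samples = 100L, loading = 1, noise_sd = 1,
                         n_diseases = 5L, n_related = 2L,
                         n_seed_genes = 10L, sim_related = 0.7,
                         sim_unrelated = 0.2, negative_size = 250L,
                         compat_bias = 0.8, seed = 1L) {
  cfg <- list(n_nodes = as.integer(n_nodes), pa_m = as.integer(pa_m),
              pa_power = pa_power, module_size = as.integer(module_size),
              module_density = module_density,
              n_samples = as.integer(n_samples), loading = loading,
              noise_sd = noise_sd, n_diseases = as.integer(n_diseases),
              n_related = as.integer(n_related),
              n_seed_genes = as.integer(n_seed_genes),
              sim_related = sim_related, sim_unrelated = sim_unrelated,
              negative_size = as.integer(negative_size),
              compat_bias = compat_bias, seed = as.integer(seed))
  if (cfg$module_size >= cfg$n_nodes)
    stop("module_size must be smaller than n_nodes")
  if (cfg$module_density <= 0 || cfg$module_density > 1)
    stop("module_density must lie in (0, 1]")
  if (cfg$n_related >= cfg$n_diseases)
    stop("need at least one unrelated decoy disease")
  if (cfg$n_seed_genes > cfg$module_size)
    stop("n_seed_genes cannot exceed module_size")
  structure(cfg, class = "synth_config")
}

synth_node_names <- function(n) {
  sprintf("P%0*d", max(4L, nchar(n)), seq_len(n))
}

#' Generate a scale-free network with a planted disease module
#'
#' Grows a preferential-attachment backbone, then densifies a randomly
#' chosen module of `module_size` nodes up to the configured internal edge
#' density. Deterministic given `cfg$seed`.
#'
#' @param cfg a [synth_config()]
#' @return list with `network` (a [ppi_network], unit weights) and `truth`
#'   (planted module membership, node names, query disease id, config)
#' @export
generate_network <- function(cfg) {
  set.seed(cfg$seed)
  nodes <- synth_node_names(cfg$n_nodes)
  g <- igraph::sample_pa(cfg$n_nodes, power = cfg$pa_power, m = cfg$pa_m,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(from = nodes[el[, 1L]], to = nodes[el[, 2L]],
                      weight = 1, stringsAsFactors = FALSE)
  module <- sort(sample(nodes, cfg$module_size), method = "radix")
  pairs <- t(utils::combn(module, 2L))
  n_target <- ceiling(cfg$module_density * nrow(pairs))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\t")
  have <- key(edges$from, edges$to)
  pair_keys <- key(pairs[, 1L], pairs[, 2L])
  present <- pair_keys %in% have
  n_extra <- n_target - sum(present)
  if (n_extra > nrow(pairs) - sum(present))
    stop("infeasible module density")
  if (n_extra > 0) {
    add <- sample(which(!present), n_extra)
    edges <- rbind(edges,
                   data.frame(from = pairs[add, 1L], to = pairs[add, 2L],
                              weight = 1, stringsAsFactors = FALSE))
  }
  net <- ppi_network(edges)
  truth <- list(module = module, nodes = net$nodes,
                query_disease = "D1", config = cfg,
                true_edge_keys = edge_keys(net$edges))
  list(network = net, truth = truth)
}

#' Generate a factor-model expression matrix
#'
#' Module genes load on one shared latent factor
#' (`loading * latent + noise`), so their pairwise population correlation is
#' `loading^2 / (loading^2 + noise_sd^2)` in expectation; background genes
#' are independent noise.
#'
#' @param cfg a [synth_config()]
#' @param truth truth record from [generate_network()]
#' @return numeric matrix, `n_nodes` x `n_samples`, gene ids as rownames
#' @export
generate_expression <- function(cfg, truth) {
  set.seed(cfg$seed + 1L)
  nodes <- truth$nodes
  m <- cfg$n_samples
  latent <- stats::rnorm(m)
  E <- matrix(stats::rnorm(length(nodes) * m), nrow = length(nodes),
              dimnames = list(nodes, sprintf("S%03d", seq_len(m))))
  in_mod <- nodes %in% truth$module
  E[in_mod, ] <- cfg$loading * matrix(latent, nrow = sum(in_mod), ncol = m,
                                      byrow = TRUE) +
    matrix(stats::rnorm(sum(in_mod) * m, sd = cfg$noise_sd),
           nrow = sum(in_mod))
  E
}

## compatible compartment pairs used by the generator (self-pairs implicit)
synth_compat_pairs <- function() {
  data.frame(
    a = c("cytoplasm", "cytoplasm", "cytoplasm", "cytoplasm",
          "cytoplasm", "endoplasmic reticulum", "Golgi apparatus",
          "endoplasmic reticulum", "extracell"),
    b = c("nucleus", "plasma membrane", "cytoskeleton", "mitochondria",
          "endoplasmic reticulum", "Golgi apparatus", "lysosome",
          "microsome", "plasma membrane"),
    stringsAsFactors = FALSE)
}

#' Generate localization assignments and a negative interaction set
#'
#' Module proteins are biased toward a compatible compartment pair
#' (nucleus/cytoplasm); background proteins draw uniformly from the
#' 12-site vocabulary. Negative pairs are sampled from non-edges with a
#' bias against localization-compatible pairs (a compatible candidate is
#' rejected with probability `compat_bias`), and never coincide with a true
#' edge.
#'
#' @param cfg a [synth_config()]
#' @param truth truth record from [generate_network()]
#' @return list with `localization` (a [localization_table]) and
#'   `negatives` (a [ppi_network] of negative pairs, unit weights)
#' @export
generate_localization_and_negatome <- function(cfg, truth) {
  set.seed(cfg$seed + 2L)
  nodes <- truth$nodes
  home <- c("nucleus", "cytoplasm")
  sites <- lapply(nodes, function(v)
    if (v %in% truth$module) sample(home, 1L)
    else sample(LOCALIZATION_SITES, 1L))
  names(sites) <- nodes
  locs <- localization_table(sites, synth_compat_pairs())
  true_keys <- truth$true_edge_keys
  neg_from <- character(0)
  neg_to <- character(0)
  got <- character(0)
  attempts <- 0L
  max_attempts <- 200L * cfg$negative_size
  while (length(got) < cfg$negative_size && attempts < max_attempts) {
    attempts <- attempts + 1L
    pair <- sample(nodes, 2L)
    k <- paste(min(pair), max(pair), sep = "\t")
    if (k %in% true_keys || k %in% got) next
    compat <- suppressMessages(localization_compat(locs, pair[1L], pair[2L]))
    if (compat == 1L && stats::runif(1) < cfg$compat_bias) next
    got <- c(got, k)
    neg_from <- c(neg_from, min(pair))
    neg_to <- c(neg_to, max(pair))
  }
  if (length(got) < cfg$negative_size)
    stop("could not sample the requested number of negative pairs")
  negatives <- ppi_network(data.frame(from = neg_from, to = neg_to,
                                      weight = 1, stringsAsFactors = FALSE))
  list(localization = locs, negatives = negatives)
}

#' Generate a block disease-similarity matrix and association map
#'
#' One query disease (`D1`) plus decoys: `n_related` diseases sit in the
#' informative similarity band with the query (and with each other), all
#' remaining pairs in the uninformative band. The query's and the related
#' diseases' genes are drawn from the planted module; unrelated diseases
#' get background genes.
#'
#' @param cfg a [synth_config()]
#' @param truth truth record from [generate_network()]
#' @return list with `similarity` (matrix, diagonal 1) and `associations`
#'   (data.frame `disease`, `gene`)
#' @export
generate_disease_data <- function(cfg, truth) {
  set.seed(cfg$seed + 3L)
  diseases <- paste0("D", seq_len(cfg$n_diseases))
  related <- diseases[seq_len(cfg$n_related) + 1L]
  S <- matrix(cfg$sim_unrelated, cfg$n_diseases, cfg$n_diseases,
              dimnames = list(diseases, diseases))
  block <- c("D1", related)
  S[block, block] <- cfg$sim_related
  diag(S) <- 1
  background <- setdiff(truth$nodes, truth$module)
  assoc_list <- lapply(diseases, function(dz) {
    genes <- if (dz == "D1" || dz %in% related)
      sample(truth$module, cfg$n_seed_genes)
    else
      sample(background, cfg$n_seed_genes)
    data.frame(disease = dz, gene = genes, stringsAsFactors = FALSE)
  })
  list(similarity = S, associations = do.call(rbind, assoc_list))
}

#' Generate the complete synthetic input bundle
#'
#' @param cfg a [synth_config()]
#' @return list with `network`, `expression`, `localization`, `negatives`,
#'   `similarity`, `associations`, `truth`, `config`
#' @export
generate_prosim_data <- function(cfg = synth_config()) {
  gn <- generate_network(cfg)
  expr <- generate_expression(cfg, gn$truth)
  ln <- generate_localization_and_negatome(cfg, gn$truth)
  dd <- generate_disease_data(cfg, gn$truth)
  list(network = gn$network, expression = expr,
       localization = ln$localization, negatives = ln$negatives,
       similarity = dd$similarity, associations = dd$associations,
       truth = gn$truth, config = cfg)
}

#' Write a synthetic bundle to TSV files plus a truth manifest
#'
#' Emits every input in the format the package's readers consume, a
#' ready-to-run pipeline config file, and a plain-text manifest recording
#' the seed and planted-module membership.
#'
#' @param bundle result of [generate_prosim_data()]
#' @param dir output directory (created if absent)
#' @return named list of written file paths (invisibly)
#' @export
write_prosim_data <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_weighted_edges(bundle$network, p("network.tsv"))
  write_weighted_edges(bundle$negatives, p("negatives.tsv"))
  E <- bundle$expression
  utils::write.table(data.frame(gene = rownames(E), E, check.names = FALSE),
                     p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(vapply(names(bundle$localization$sites), function(v)
    paste0(v, "\t", paste(bundle$localization$sites[[v]], collapse = ";")),
    character(1)), p("localization.tsv"))
  cp <- synth_compat_pairs()
  writeLines(paste(cp$a, cp$b, sep = "\t"), p("compatibility.tsv"))
  S <- bundle$similarity
  utils::write.table(data.frame(disease = rownames(S), S,
                                check.names = FALSE),
                     p("similarity.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(paste(bundle$associations$disease, bundle$associations$gene,
                   sep = "\t"), p("associations.tsv"))
  writeLines(c(paste0("network = ", p("network.tsv")),
               paste0("negatives = ", p("negatives.tsv")),
               paste0("expression = ", p("expression.tsv")),
               paste0("localization = ", p("localization.tsv")),
               paste0("compatibility = ", p("compatibility.tsv")),
               paste0("similarity = ", p("similarity.tsv")),
               paste0("associations = ", p("associations.tsv")),
               paste0("disease = ", bundle$truth$query_disease)),
             p("config.txt"))
  writeLines(c(paste0("seed=", bundle$config$seed),
               paste0("n_nodes=", bundle$config$n_nodes),
               paste0("module_size=", bundle$config$module_size),
               paste0("query_disease=", bundle$truth$query_disease),
               paste0("module=", paste(bundle$truth$module, collapse = ","))),
             p("manifest.txt"))
  invisible(list(network = p("network.tsv"), negatives = p("negatives.tsv"),
                 expression = p("expression.tsv"),
                 localization = p("localization.tsv"),
                 compatibility = p("compatibility.tsv"),
                 similarity = p("similarity.tsv"),
                 associations = p("associations.tsv"),
                 config = p("config.txt"), manifest = p("manifest.txt")))
}

#' Generate labeled feature data from a planted logistic model
#'
#' Draws feature triples matching the semantics of the real features —
#' `C` uniform on `[0, 3]` (a -log tail probability, unbounded below only
#' by 0), `rho` uniform on `[-1, 1]`, `loc` Bernoulli(1/2) — and labels
#' from a Bernoulli with success probability `plogis(beta0 + beta . x)`;
#' the generating model is the ground truth for coefficient-recovery tests
#' of the reliability module.
#'
#' @param n number of examples
#' @param beta length-4 coefficient vector (intercept first)
#' @param seed RNG seed
#' @return list with `features` (data.frame `C`, `rho`, `loc`) and `labels`
#'   (0/1 vector)
#' @export
generate_logistic_data <- function(n, beta = c(0, 3, 2, -1), seed = 1L) {
  set.seed(seed)
  X <- cbind(C = stats::runif(n, 0, 3), rho = stats::runif(n, -1, 1),
             loc = stats::rbinom(n, 1L, 0.5))
  p <- stats::plogis(beta[1L] + drop(X %*% beta[-1L]))
  list(features = as.data.frame(X), labels = stats::rbinom(n, 1L, p))
}
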