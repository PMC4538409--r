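#' Parameters of the score-propagation iteration
#'
#' @param alpha smoothing weight in `(0, 1)`: the share of a node's score
#'   drawn from its neighbors versus its own prior-plus-proximity signal.
#'   Default 0.9, the value at which prioritization performance peaked.
#' @param max_iter iteration cap `T` (default 100)
#' @param tol L1 convergence threshold (default 1e-6)
#' @return list of class `propagation_params`
#' @export
propagation_params <- function(alpha = 0.9, max_iter = 100L, tol = 1e-6) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  structure(list(alpha = alpha, max_iter = as.integer(max_iter), tol = tol),
            class = "propagation_params")
}

#' Propagate prior and proximity scores over the network
#'
#' Computes the relevance score `F` as the fixed point of
#' `F_t = alpha * W' F_{t-1} + (1 - alpha) * (Y + Pro)` starting from
#' `F_0 = Y + Pro`, where `W'` is the degree-normalized adjacency. Because
#' the spectral radius of `W'` is at most 1 and `alpha < 1`, the iteration
#' is a contraction and converges to
#' `(1 - alpha) (I - alpha W')^{-1} (Y + Pro)`; iteration stops when the L1
#' change drops below `tol` or after `max_iter` steps.
#'
#' @param Wn normalized adjacency from [normalize_adjacency()]
#' @param Y prior vector from [build_prior()] (use zeros to ablate)
#' @param Pro proximity vector from [rwr()] (use zeros to ablate)
#' @param params a [propagation_params()] list
#' @return named numeric score vector `F` with attributes `iterations` and
#'   `converged`
#' @export
propagate <- function(Wn, Y, Pro, params = propagation_params()) {
  n <- nrow(Wn)
  if (length(Y) != n || length(Pro) != n)
    stop("Y, Pro and W' must share the network's node order (dimension mismatch)")
  nodes <- rownames(Wn)
  if (!is.null(names(Y)) && !identical(names(Y), nodes))
    Y <- Y[nodes]
  if (!is.null(names(Pro)) && !identical(names(Pro), nodes))
    Pro <- Pro[nodes]
  b <- as.numeric(Y) + as.numeric(Pro)
  if (any(!is.finite(b))) stop("non-finite prior or proximity values")
  alpha <- params$alpha
  f <- b
  iterations <- 0L
  converged <- FALSE
  while (iterations < params$max_iter) {
    f_new <- alpha * as.numeric(Wn %*% f) + (1 - alpha) * b
    iterations <- iterations + 1L
    delta <- sum(abs(f_new - f))
    f <- f_new
    if (delta < params$tol) { converged <- TRUE; break }
  }
  names(f) <- nodes
  attr(f, "iterations") <- iterations
  attr(f, "converged") <- converged
  f
}

#' Rank candidate genes by relevance score
#'
#' Seeds are excluded from the candidate set; remaining nodes are sorted by
#' score descending with lexicographic tie-breaking, and assigned ranks
#' `1..n`.
#'
#' @param scores named score vector (from [propagate()] or [rwr()])
#' @param seeds character vector of seed ids to exclude
#' @return data.frame with columns `rank`, `protein`, `score`
#' @export
rank_candidates <- function(scores, seeds = character()) {
  ids <- setdiff(names(scores), seeds)
  s <- as.numeric(scores[ids])
  o <- order(-s, ids, method = "radix")
  data.frame(rank = seq_along(ids), protein = ids[o], score = s[o],
             stringsAsFactors = FALSE)
}

#' Score one disease on a weighted network
#'
#' Runs the scoring stage shared by the full method and its ablations:
#' extracts the seed set from the association map, computes RWR proximity
#' and the similarity prior, and blends them by propagation. Method
#' `"prosim"` propagates `Y + Pro`; `"rwr"` ranks by raw proximity (the
#' plain random-walk comparator); `"prior"` propagates the similarity prior
#' alone (the label-propagation comparator without proximity).
#'
#' @param net a reliability-weighted [ppi_network]
#' @param S disease similarity matrix
#' @param assoc association data.frame (`disease`, `gene`)
#' @param disease query disease id
#' @param method `"prosim"`, `"rwr"` or `"prior"`
#' @param restart RWR restart probability
#' @param params a [propagation_params()] list
#' @param Wn optional precomputed [normalize_adjacency()] result for `net`
#' @return list with `ranking` (data.frame `rank`, `protein`, `F`, `Y`,
#'   `Pro`), `scores`, `Y`, `Pro`, `seeds`, `method`
#' @export
score_disease <- function(net, S, assoc, disease,
                          method = c("prosim", "rwr", "prior"),
                          restart = 0.75, params = propagation_params(),
                          Wn = NULL) {
  method <- match.arg(method)
  seeds <- unique(assoc$gene[assoc$disease == disease])
  seeds <- intersect(seeds, net$nodes)
  if (!length(seeds))
    stop("no seed genes of disease '", disease, "' present in the network")
  zero <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  Pro <- zero
  Y <- zero
  if (method %in% c("prosim", "rwr"))
    Pro <- rwr(net, seeds, r = restart)
  if (method %in% c("prosim", "prior"))
    Y <- build_prior(S, disease, assoc, net)
  if (method == "rwr") {
    f <- Pro
  } else {
    if (is.null(Wn)) Wn <- normalize_adjacency(net)
    f <- propagate(Wn, Y, Pro, params)
  }
  ranking <- rank_candidates(f, seeds)
  ranking$F <- ranking$score
  ranking$Y <- as.numeric(Y[ranking$protein])
  ranking$Pro <- as.numeric(Pro[ranking$protein])
  ranking$score <- NULL
  list(ranking = ranking, scores = f, Y = Y, Pro = Pro, seeds = seeds,
       method = method)
}

#' Run the full prioritization pipeline from a configuration
#'
#' Reads every input, computes edge features on the positive and negative
#' networks (each using its own topology), trains the reliability model,
#' re-weights the positive network, and scores the query disease. The
#' configuration is either a named list or the path of a flat `key = value`
#' text file with keys: `network`, `negatives`, `expression`,
#' `localization`, `compatibility`, `similarity`, `associations`, `disease`
#' and optionally `alpha` (0.9), `restart` (0.75), `tol` (1e-6), `max_iter`
#' (100), `folds` (10), `train_seed` (1), `ridge` (0), `method`
#' (`"prosim"`), `top_k` (100).
#'
#' @param config named list or path to a key-value config file
#' @return list with `ranking`, `scores`, `Y`, `Pro`, `seeds`, `model`,
#'   `network` (the weighted network) and a `provenance` record (parameters,
#'   input file checksums)
#' @export
prosim_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  getopt <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  required <- c("network", "negatives", "similarity", "associations",
                "disease")
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop("config missing required key(s): ", paste(miss, collapse = ", "))

  net <- read_edge_list(config$network)
  neg <- read_edge_list(config$negatives)
  expr <- if (!is.null(config$expression)) read_expression(config$expression)
  locs <- if (!is.null(config$localization))
    read_localization(config$localization, config$compatibility)
  S <- read_similarity_matrix(config$similarity)
  assoc <- read_associations(config$associations)

  pos_feat <- build_edge_features(net, expr, locs)
  neg_feat <- build_edge_features(neg, expr, locs)
  model <- train_reliability(pos_feat, neg_feat,
                             folds = as.integer(getopt("folds", 10L)),
                             seed = as.integer(getopt("train_seed", 1L)),
                             ridge = as.numeric(getopt("ridge", 0)))
  wnet <- weight_network(net, model, pos_feat)

  params <- propagation_params(alpha = as.numeric(getopt("alpha", 0.9)),
                               max_iter = as.integer(getopt("max_iter", 100L)),
                               tol = as.numeric(getopt("tol", 1e-6)))
  res <- score_disease(wnet, S, assoc, config$disease,
                       method = getopt("method", "prosim"),
                       restart = as.numeric(getopt("restart", 0.75)),
                       params = params)
  top_k <- as.integer(getopt("top_k", 100L))
  paths <- unlist(config[intersect(names(config),
                                   c("network", "negatives", "expression",
                                     "localization", "compatibility",
                                     "similarity", "associations"))])
  res$model <- model
  res$network <- wnet
  res$provenance <- list(
    disease = config$disease, method = res$method,
    alpha = params$alpha, restart = as.numeric(getopt("restart", 0.75)),
    tol = params$tol, max_iter = params$max_iter, top_k = top_k,
    train_seed = as.integer(getopt("train_seed", 1L)),
    seeds = res$seeds,
    checksums = as.list(tools::md5sum(paths)))
  res
}

read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  if (any(lengths(kv) != 2L)) stop("config lines must be 'key = value'")
  vals <- trimws(vapply(kv, `[`, "", 2L))
  stats::setNames(as.list(vals), trimws(vapply(kv, `[`, "", 1L)))
}

#' Write a ranking table as TSV
#'
#' Columns: rank, protein, F, Y, Pro — the final relevance score and the two
#' signals that produced it.
#'
#' @param ranking data.frame from [score_disease()]'s `ranking`
#' @param path output path
#' @param top_k optionally truncate to the first `top_k` rows
#' @return `path`, invisibly
#' @export
write_ranking <- function(ranking, path, top_k = NULL) {
  if (!is.null(top_k)) ranking <- utils::head(ranking, top_k)
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  writeLines(c("#rank\tprotein\tF\tY\tPro",
               paste(ranking$rank, ranking$protein, fmt(ranking$F),
                     fmt(ranking$Y), fmt(ranking$Pro), sep = "\t")), path)
  invisible(path)
}
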