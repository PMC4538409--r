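#' Mean enrichment of leave-one-out ranks
#'
#' `enrichment = 50 / rank`, averaged over trials; a gene recovered at rank
#' 50 scores 1, at rank 1 scores 50. Higher is better.
#'
#' @param ranks vector of positive integer ranks
#' @return mean enrichment
#' @export
mean_enrichment <- function(ranks) {
  if (!length(ranks)) stop("no ranks supplied")
  if (any(!is.finite(ranks)) || any(ranks < 1))
    stop("ranks must be integers >= 1")
  mean(50 / ranks)
}

#' Leave-one-out cross validation of disease-gene recovery
#'
#' For each known disease gene `g` of the query disease, removes `g` from
#' the seed set *and* from the disease's association map (so neither the
#' restart vector nor the similarity prior can see it), reruns the scoring
#' stage on the weighted network, and records the rank at which `g`
#' reappears among the candidates. The hit fraction is the share of trials
#' whose rank is at most `k`.
#'
#' @param net reliability-weighted [ppi_network]
#' @param S disease similarity matrix
#' @param assoc association data.frame (`disease`, `gene`)
#' @param disease query disease id
#' @param k rank threshold for a hit (default 100)
#' @param method scoring method passed to [score_disease()]
#' @param restart RWR restart probability
#' @param params a [propagation_params()] list
#' @param scorer optional replacement scoring function
#'   `function(net, S, assoc, disease)` returning a ranking data.frame with
#'   a `protein` column (used for protocol tests); when supplied it fully
#'   replaces [score_disease()]
#' @param interval_size optional artificial-interval size: instead of
#'   ranking `g` against all candidates, rank it against `interval_size - 1`
#'   random genes not associated with the disease (seeded)
#' @param seed seed for the interval sampling
#' @return list with `trials` (data.frame `gene`, `rank`), `hit_fraction`,
#'   `mean_enrichment`, `k`, `n_candidates`
#' @export
loocv <- function(net, S, assoc, disease, k = 100L,
                  method = c("prosim", "rwr", "prior"), restart = 0.75,
                  params = propagation_params(), scorer = NULL,
                  interval_size = NULL, seed = 1L) {
  if (is.null(scorer)) method <- match.arg(method)
  seeds <- intersect(unique(assoc$gene[assoc$disease == disease]), net$nodes)
  if (length(seeds) < 2L)
    stop("need at least 2 usable seed genes for leave-one-out trials")
  Wn <- if (is.null(scorer) && method != "rwr") normalize_adjacency(net)
  ranks <- integer(length(seeds))
  for (i in seq_along(seeds)) {
    g <- seeds[i]
    assoc2 <- assoc[!(assoc$disease == disease & assoc$gene == g), ,
                    drop = FALSE]
    ranking <- if (is.null(scorer)) {
      score_disease(net, S, assoc2, disease, method = method,
                    restart = restart, params = params, Wn = Wn)$ranking
    } else {
      scorer(net, S, assoc2, disease)
    }
    r <- match(g, ranking$protein)
    if (is.na(r)) stop("held-out gene '", g, "' missing from ranking")
    if (!is.null(interval_size)) {
      pool <- setdiff(ranking$protein,
                      unique(assoc$gene[assoc$disease == disease]))
      set.seed(seed + i)
      controls <- sample(pool, min(interval_size - 1L, length(pool)))
      r <- 1L + sum(match(controls, ranking$protein) < r)
    }
    ranks[i] <- r
  }
  list(trials = data.frame(gene = seeds, rank = ranks,
                           stringsAsFactors = FALSE),
       hit_fraction = mean(ranks <= k),
       mean_enrichment = mean_enrichment(ranks),
       k = as.integer(k),
       n_candidates = length(net$nodes) - length(seeds) + 1L)
}

#' ROC curve and AUC for a ranked gene list
#'
#' Sweeps the rank threshold `t = 0..n`: sensitivity is the fraction of true
#' disease genes ranked at or above `t`, specificity the fraction of
#' non-related genes ranked below `t`. The curve runs from (0, 0) to (1, 1)
#' in (1 - specificity, sensitivity) coordinates and the AUC is computed by
#' the trapezoid rule.
#'
#' @param ranked ordered character vector of gene ids (best first), or a
#'   ranking data.frame with a `protein` column
#' @param positives,negatives disjoint, non-empty subsets of `ranked`
#' @return list with `points` (data.frame `threshold`, `sensitivity`,
#'   `fpr`) and `auc`
#' @export
roc_points <- function(ranked, positives, negatives) {
  if (is.data.frame(ranked)) ranked <- ranked$protein
  positives <- unique(positives)
  negatives <- unique(negatives)
  if (!length(positives) || !length(negatives))
    stop("positives and negatives must both be non-empty")
  if (length(intersect(positives, negatives)))
    stop("positives and negatives must be disjoint")
  if (!all(positives %in% ranked) || !all(negatives %in% ranked))
    stop("positives and negatives must be subsets of the ranked list")
  n <- length(ranked)
  cum_pos <- cumsum(ranked %in% positives)
  cum_neg <- cumsum(ranked %in% negatives)
  sens <- c(0, cum_pos / length(positives))
  fpr <- c(0, cum_neg / length(negatives))   # 1 - specificity
  auc <- sum(diff(fpr) * (utils::head(sens, -1L) + utils::tail(sens, -1L)) / 2)
  list(points = data.frame(threshold = 0:n, sensitivity = sens, fpr = fpr),
       auc = auc)
}

#' Tenfold edge-removal cross validation
#'
#' Randomly partitions the network's edges into `folds` equal parts
#' (seeded); for each fold, removes that tenth of the edges, reruns the
#' leave-one-out protocol on the reduced network, and records the per-fold
#' hit fraction. Node set (and hence the candidate set) is unchanged.
#'
#' @inheritParams loocv
#' @param folds number of edge folds (default 10)
#' @param seed partition seed
#' @return list with `fold_results` (data.frame `fold`, `hit_fraction`,
#'   `mean_enrichment`), `partition` (fold id per edge of `net`), and
#'   `mean_hit_fraction`
#' @export
tenfold_edge_cv <- function(net, S, assoc, disease, folds = 10L, seed = 1L,
                            k = 100L, method = "prosim", restart = 0.75,
                            params = propagation_params()) {
  ne <- n_edges(net)
  if (ne < folds) stop("need at least `folds` edges")
  set.seed(seed)
  partition <- sample(rep_len(seq_len(folds), ne))
  hf <- numeric(folds)
  me <- numeric(folds)
  for (f in seq_len(folds)) {
    sub <- ppi_network(net$edges[partition != f, , drop = FALSE],
                       nodes = net$nodes)
    res <- loocv(sub, S, assoc, disease, k = k, method = method,
                 restart = restart, params = params)
    hf[f] <- res$hit_fraction
    me[f] <- res$mean_enrichment
  }
  list(fold_results = data.frame(fold = seq_len(folds), hit_fraction = hf,
                                 mean_enrichment = me),
       partition = partition,
       mean_hit_fraction = mean(hf))
}

#' Side-by-side comparison of scoring methods under identical LOOCV
#'
#' @inheritParams loocv
#' @param methods methods to compare (default: the full method, the plain
#'   random-walk baseline, and the prior-only propagation baseline)
#' @return data.frame with one row per method: `method`, `hit_fraction`,
#'   `mean_enrichment`, `n_trials`
#' @export
compare_methods <- function(net, S, assoc, disease,
                            methods = c("prosim", "rwr", "prior"),
                            k = 100L, restart = 0.75,
                            params = propagation_params()) {
  rows <- lapply(methods, function(m) {
    res <- loocv(net, S, assoc, disease, k = k, method = m,
                 restart = restart, params = params)
    data.frame(method = m, hit_fraction = res$hit_fraction,
               mean_enrichment = res$mean_enrichment,
               n_trials = nrow(res$trials), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full pipeline on one synthetic benchmark instance
#'
#' Generates a synthetic input bundle, computes edge features on the
#' positive and negative networks, trains the reliability model, re-weights
#' the positive network, and evaluates the requested scoring methods by
#' leave-one-out cross validation on the planted query disease.
#'
#' @param cfg a [synth_config()] list
#' @param methods scoring methods to evaluate
#' @param k LOOCV rank threshold
#' @param restart RWR restart probability
#' @param params a [propagation_params()] list
#' @param ridge ridge penalty for reliability training (clean synthetic
#'   features can be linearly separable)
#' @return list with `results` (data.frame as from [compare_methods()]),
#'   `loocv` (per-method LOOCV details), `model`, `network` (weighted),
#'   `bundle`
#' @export
prosim_benchmark <- function(cfg = synth_config(),
                             methods = c("prosim", "rwr", "prior"),
                             k = 100L, restart = 0.75,
                             params = propagation_params(), ridge = 0) {
  bundle <- generate_prosim_data(cfg)
  pos_feat <- build_edge_features(bundle$network, bundle$expression,
                                  bundle$localization)
  neg_feat <- build_edge_features(bundle$negatives, bundle$expression,
                                  bundle$localization)
  model <- train_reliability(pos_feat, neg_feat, seed = cfg$seed,
                             ridge = ridge)
  wnet <- weight_network(bundle$network, model, pos_feat)
  q <- bundle$truth$query_disease
  details <- lapply(methods, function(m)
    loocv(wnet, bundle$similarity, bundle$associations, q, k = k,
          method = m, restart = restart, params = params))
  names(details) <- methods
  results <- do.call(rbind, lapply(methods, function(m)
    data.frame(method = m, hit_fraction = details[[m]]$hit_fraction,
               mean_enrichment = details[[m]]$mean_enrichment,
               n_trials = nrow(details[[m]]$trials),
               stringsAsFactors = FALSE)))
  list(results = results, loocv = details, model = model, network = wnet,
       bundle = bundle)
}
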