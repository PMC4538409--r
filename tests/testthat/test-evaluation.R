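test_that("mean enrichment follows 50/rank and is monotone in every rank", {
  expect_equal(mean_enrichment(50), 1.0)
  expect_equal(mean_enrichment(1), 50.0)
  expect_equal(mean_enrichment(c(10, 25, 50)), 8 / 3)
  expect_error(mean_enrichment(c(1, 0)), "ranks")
  expect_error(mean_enrichment(numeric(0)), "no ranks")
  set.seed(1)
  ranks <- sample(1:500, 20)
  base <- mean_enrichment(ranks)
  for (i in c(1, 10, 20)) {
    worse <- ranks; worse[i] <- worse[i] + 1
    expect_lt(mean_enrichment(worse), base)
  }
})

test_that("ROC endpoints, perfect and reversed rankings behave as expected", {
  ranked <- sprintf("g%02d", 1:20)
  pos <- ranked[1:5]; neg <- ranked[16:20]
  r <- roc_points(ranked, pos, neg)
  expect_equal(r$auc, 1.0)
  expect_equal(r$points$sensitivity[1], 0)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(tail(r$points$sensitivity, 1), 1)
  expect_equal(tail(r$points$fpr, 1), 1)
  expect_equal(roc_points(rev(ranked), pos, neg)$auc, 0.0)
  expect_error(roc_points(ranked, character(0), neg), "non-empty")
  expect_error(roc_points(ranked, pos, pos), "disjoint")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(8)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  a1 <- score_auc(scores, labels)
  a2 <- score_auc(exp(3 * scores) + 5, labels)
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  ours <- score_auc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("random rankings give chance-level AUC on average", {
  set.seed(5)
  ids <- sprintf("g%03d", 1:50)
  pos <- ids[1:20]; neg <- ids[21:50]
  aucs <- replicate(400, roc_points(sample(ids), pos, neg)$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("LOOCV with a perfect oracle scorer recovers every held-out gene", {
  b <- tiny_bundle(seed = 2)
  q <- b$truth$query_disease
  # scorer that always places the missing disease gene first
  all_assoc <- b$associations
  oracle <- function(net, S, assoc, disease) {
    full <- unique(all_assoc$gene[all_assoc$disease == disease])
    now <- unique(assoc$gene[assoc$disease == disease])
    held <- setdiff(full, now)
    rest <- sort(setdiff(net$nodes, c(held, now)), method = "radix")
    data.frame(rank = seq_along(c(held, rest)), protein = c(held, rest),
               stringsAsFactors = FALSE)
  }
  res <- loocv(b$network, b$similarity, b$associations, q, k = 100,
               scorer = oracle)
  expect_equal(res$hit_fraction, 1.0)
  expect_equal(res$trials$rank, rep(1L, nrow(res$trials)))
  expect_equal(res$mean_enrichment, 50)
})

test_that("LOOCV with a fixed lexicographic scorer matches direct enumeration", {
  b <- tiny_bundle(seed = 2)
  q <- b$truth$query_disease
  lexi <- function(net, S, assoc, disease) {
    seeds <- unique(assoc$gene[assoc$disease == disease])
    cand <- sort(setdiff(net$nodes, seeds), method = "radix")
    data.frame(rank = seq_along(cand), protein = cand,
               stringsAsFactors = FALSE)
  }
  k <- 30
  res <- loocv(b$network, b$similarity, b$associations, q, k = k,
               scorer = lexi)
  seeds <- intersect(unique(b$associations$gene[b$associations$disease == q]),
                     b$network$nodes)
  expected_hits <- vapply(seeds, function(g) {
    cand <- sort(setdiff(b$network$nodes, setdiff(seeds, g)),
                 method = "radix")
    match(g, cand) <= k
  }, logical(1))
  expect_equal(res$hit_fraction, mean(expected_hits))
})

test_that("the held-out gene never leaks into the scorer's inputs", {
  b <- tiny_bundle(seed = 4)
  q <- b$truth$query_disease
  seeds_full <- intersect(
    unique(b$associations$gene[b$associations$disease == q]),
    b$network$nodes)
  seen <- new.env()
  seen$ok <- TRUE
  probe <- function(net, S, assoc, disease) {
    now <- unique(assoc$gene[assoc$disease == disease])
    held <- setdiff(seeds_full, now)
    # exactly one gene hidden, and it must be absent from the disease's map
    if (length(held) != 1L || held %in% now) seen$ok <- FALSE
    if (any(assoc$disease == disease & assoc$gene == held)) seen$ok <- FALSE
    cand <- sort(setdiff(net$nodes, now), method = "radix")
    data.frame(rank = seq_along(cand), protein = cand,
               stringsAsFactors = FALSE)
  }
  loocv(b$network, b$similarity, b$associations, q, scorer = probe)
  expect_true(seen$ok)
})

test_that("LOOCV requires at least two usable seeds and supports interval mode", {
  b <- tiny_bundle(seed = 4)
  assoc1 <- data.frame(disease = "D1", gene = b$truth$module[1])
  expect_error(loocv(b$network, b$similarity, assoc1, "D1"),
               "at least 2")
  res <- loocv(b$network, b$similarity, b$associations, "D1",
               k = 50, method = "rwr", interval_size = 100, seed = 3)
  expect_true(all(res$trials$rank >= 1 & res$trials$rank <= 100))
})

test_that("edge folds partition the edges and reruns are deterministic", {
  b <- tiny_bundle(seed = 6)
  q <- b$truth$query_disease
  cv1 <- tenfold_edge_cv(b$network, b$similarity, b$associations, q,
                         folds = 5, seed = 11, method = "rwr")
  cv2 <- tenfold_edge_cv(b$network, b$similarity, b$associations, q,
                         folds = 5, seed = 11, method = "rwr")
  expect_equal(length(cv1$partition), n_edges(b$network))
  expect_equal(sort(unique(cv1$partition)), 1:5)
  expect_equal(as.numeric(table(cv1$partition)),
               rep(n_edges(b$network) / 5, 5), tolerance = 1)
  expect_identical(cv1$partition, cv2$partition)
  expect_identical(cv1$fold_results, cv2$fold_results)
  expect_true(all(cv1$fold_results$hit_fraction >= 0 &
                    cv1$fold_results$hit_fraction <= 1))
})

test_that("removing a tenth of the edges perturbs the hit fraction only mildly", {
  b <- tiny_bundle(seed = 6)
  q <- b$truth$query_disease
  full <- loocv(b$network, b$similarity, b$associations, q, method = "rwr")
  cv <- tenfold_edge_cv(b$network, b$similarity, b$associations, q,
                        folds = 10, seed = 1, method = "rwr")
  expect_lt(abs(cv$mean_hit_fraction - full$hit_fraction), 0.15)
})

test_that("method comparison reports one row per method, identical for identical scorers", {
  b <- tiny_bundle(seed = 8)
  q <- b$truth$query_disease
  tab <- compare_methods(b$network, b$similarity, b$associations, q,
                         methods = c("rwr", "rwr", "prosim"))
  expect_equal(nrow(tab), 3L)
  expect_equal(names(tab), c("method", "hit_fraction", "mean_enrichment",
                             "n_trials"))
  expect_equal(tab$hit_fraction[1], tab$hit_fraction[2])
  expect_equal(tab$mean_enrichment[1], tab$mean_enrichment[2])
})
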