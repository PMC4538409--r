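small_cfg <- function(seed = 1, ...) {
  synth_config(n_nodes = 100L, module_size = 10L, n_seed_genes = 5L,
               n_samples = 30L, negative_size = 40L, seed = seed, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(synth_config(n_nodes = 20, module_size = 30), "module_size")
  expect_error(synth_config(module_density = 0), "density")
  expect_error(synth_config(n_diseases = 3, n_related = 3), "decoy")
  expect_error(synth_config(module_size = 10, n_seed_genes = 11),
               "n_seed_genes")
})

test_that("network generation is deterministic and densifies the module", {
  cfg <- small_cfg(seed = 21)
  g1 <- generate_network(cfg)
  g2 <- generate_network(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_weighted_edges(g1$network, f1)
  write_weighted_edges(g2$network, f2)
  expect_identical(readLines(f1), readLines(f2))
  # internal module density meets the configured level
  mod <- g1$truth$module
  e <- g1$network$edges
  internal <- sum(e$from %in% mod & e$to %in% mod)
  expect_gte(internal, ceiling(cfg$module_density * choose(length(mod), 2)))
})

test_that("degree distribution is heavier-tailed than an equal-size random graph", {
  max_pa <- numeric(20)
  max_er <- numeric(20)
  for (s in 1:20) {
    g <- generate_network(small_cfg(seed = s))$network
    deg <- table(c(g$edges$from, g$edges$to))
    max_pa[s] <- max(deg)
    set.seed(1000 + s)
    er <- igraph::sample_gnm(length(g$nodes), n_edges(g))
    max_er[s] <- max(igraph::degree(er))
  }
  expect_gt(mean(max_pa), mean(max_er))
})

test_that("expression matrix matches the factor-model correlation closed form", {
  cfg <- synth_config(n_nodes = 150L, module_size = 20L, n_samples = 200L,
                      loading = 1, noise_sd = 1, seed = 31)
  gn <- generate_network(cfg)
  E <- generate_expression(cfg, gn$truth)
  expect_equal(dim(E), c(cfg$n_nodes, cfg$n_samples))
  mod <- gn$truth$module
  pairs <- t(combn(mod, 2))
  within <- vapply(seq_len(nrow(pairs)), function(i)
    pearson_cc(E[pairs[i, 1], ], E[pairs[i, 2], ]), numeric(1))
  expected <- cfg$loading^2 / (cfg$loading^2 + cfg$noise_sd^2)
  expect_lt(abs(mean(within) - expected), 0.05)
  # background genes are uncorrelated on average
  bg <- setdiff(gn$truth$nodes, mod)[1:20]
  bg_pairs <- t(combn(bg, 2))
  bg_cor <- vapply(seq_len(nrow(bg_pairs)), function(i)
    pearson_cc(E[bg_pairs[i, 1], ], E[bg_pairs[i, 2], ]), numeric(1))
  expect_lt(abs(mean(bg_cor)), 0.05)
})

test_that("negatome avoids true edges and is compatibility-biased", {
  cfg <- small_cfg(seed = 41)
  gn <- generate_network(cfg)
  ln1 <- generate_localization_and_negatome(cfg, gn$truth)
  ln2 <- generate_localization_and_negatome(cfg, gn$truth)
  expect_identical(ln1$negatives$edges, ln2$negatives$edges)
  expect_equal(n_edges(ln1$negatives), cfg$negative_size)
  neg_keys <- prosim:::edge_keys(ln1$negatives$edges)
  expect_length(intersect(neg_keys, gn$truth$true_edge_keys), 0)
  compat_rate <- function(net, locs) {
    mean(vapply(seq_len(n_edges(net)), function(i)
      suppressMessages(localization_compat(locs, net$edges$from[i],
                                           net$edges$to[i])), integer(1)))
  }
  expect_gt(compat_rate(gn$network, ln1$localization),
            compat_rate(ln1$negatives, ln1$localization))
})

test_that("disease similarity blocks sit in the informative and uninformative bands", {
  cfg <- small_cfg(seed = 51)
  gn <- generate_network(cfg)
  dd <- generate_disease_data(cfg, gn$truth)
  S <- dd$similarity
  expect_equal(S, t(S))
  expect_equal(as.numeric(diag(S)), rep(1, nrow(S)))
  related <- paste0("D", 1 + seq_len(cfg$n_related))
  expect_true(all(S["D1", related] >= 0.6))
  others <- setdiff(rownames(S), c("D1", related))
  expect_true(all(S["D1", others] <= 0.3))
  # every disease has associated genes present in the network
  counts <- table(dd$associations$disease)
  expect_true(all(counts >= 1))
  expect_true(all(dd$associations$gene %in% gn$truth$nodes))
  # related diseases draw genes from the planted module
  rel_genes <- dd$associations$gene[dd$associations$disease %in% related]
  expect_true(all(rel_genes %in% gn$truth$module))
})

test_that("written bundles round-trip through the package readers", {
  bundle <- generate_prosim_data(small_cfg(seed = 61))
  dir <- tempfile("roundtrip")
  paths <- write_prosim_data(bundle, dir)
  net <- read_edge_list(paths$network)
  expect_equal(net$edges, bundle$network$edges)
  neg <- read_edge_list(paths$negatives)
  expect_equal(neg$edges, bundle$negatives$edges)
  E <- read_expression(paths$expression)
  expect_equal(E, bundle$expression, tolerance = 1e-6)
  locs <- read_localization(paths$localization, paths$compatibility)
  expect_equal(locs$sites, bundle$localization$sites)
  expect_setequal(locs$compat, bundle$localization$compat)
  S <- read_similarity_matrix(paths$similarity)
  expect_equal(S, bundle$similarity)
  assoc <- read_associations(paths$associations)
  expect_equal(assoc, bundle$associations)
})
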