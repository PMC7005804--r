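edges_df <- function(a, b, score = 0.9, coex = 0.5) {
  ppi_edge_table(data.frame(gene_a = a, gene_b = b,
                            combined_score = score, coexpression = coex))
}

test_that("graph building filters by score and iterates the degree filter", {
  et <- edges_df(c("A", "B", "C"), c("B", "C", "D"),
                 score = c(0.9, 0.3, 0.8))
  g0 <- build_graph(et, score_threshold = 0)
  expect_equal(igraph::ecount(g0), 3L)
  g4 <- build_graph(et, score_threshold = 0.4)
  expect_equal(igraph::ecount(g4), 2L)

  # path graph has no node of degree >= 3
  path <- edges_df(c("A", "B", "C"), c("B", "C", "D"))
  expect_warning(gp <- build_graph(path, 0, min_degree = 3), "empty")
  expect_equal(igraph::vcount(gp), 0L)

  # iterative filter equals a brute-force fixed point on random graphs
  set.seed(6)
  for (rep in 1:5) {
    n <- 30
    pairs <- t(utils::combn(n, 2))
    pick <- pairs[stats::runif(nrow(pairs)) < 0.08, , drop = FALSE]
    if (!nrow(pick)) next
    et <- edges_df(sprintf("n%02d", pick[, 1]), sprintf("n%02d", pick[, 2]))
    g <- suppressWarnings(build_graph(et, 0, min_degree = 2))
    # brute force: repeatedly drop low-degree nodes from the edge list
    nodes <- unique(c(et$gene_a, et$gene_b))
    el <- et
    repeat {
      deg <- table(factor(c(el$gene_a, el$gene_b), levels = nodes))
      bad <- names(deg)[deg < 2]
      if (!length(bad)) break
      nodes <- setdiff(nodes, bad)
      el <- el[el$gene_a %in% nodes & el$gene_b %in% nodes, ]
    }
    expect_setequal(igraph::V(g)$name[igraph::degree(g) > 0],
                    nodes[nodes %in% c(el$gene_a, el$gene_b)])
  }
})

test_that("centralities match closed forms on star and triangle", {
  star <- edges_df(rep("hub", 5), paste0("leaf", 1:5))
  ct <- centralities(build_graph(star, 0))
  hub <- ct[ct$gene == "hub", ]
  expect_equal(hub$degree, 5)
  expect_equal(hub$betweenness, 10)  # (n-1)(n-2)/2 with n = 6
  expect_equal(hub$clustering_coefficient, 0)
  expect_equal(hub$stress, 10)
  expect_equal(hub$closeness, 1 / 5)
  leaf <- ct[ct$gene == "leaf1", ]
  expect_equal(leaf$betweenness, 0)
  expect_equal(leaf$avg_shortest_path, (1 + 4 * 2) / 5)

  tri <- edges_df(c("A", "B", "C"), c("B", "C", "A"))
  ct <- centralities(build_graph(tri, 0))
  expect_equal(ct$clustering_coefficient, rep(1, 3))
  expect_equal(ct$betweenness, rep(0, 3))
})

test_that("centralities equal the brute-force all-pairs oracle", {
  set.seed(13)
  for (rep in 1:4) {
    n <- 12
    adj <- matrix(0L, n, n)
    pairs <- t(utils::combn(n, 2))
    on <- pairs[stats::runif(nrow(pairs)) < 0.25, , drop = FALSE]
    adj[on] <- 1L
    adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- sprintf("v%02d", 1:n)
    ct <- centralities(g)
    oracle <- oracle_centralities(adj)
    for (col in names(oracle)) {
      expect_equal(ct[[col]], oracle[[col]], tolerance = 1e-10,
                   info = paste(col, "rep", rep))
    }
  }
})

test_that("k-means hub clustering is stable on separable blobs", {
  set.seed(20)
  feats <- rbind(
    matrix(stats::rnorm(30 * 4, 0, 0.2), 30, 4),
    matrix(stats::rnorm(30 * 4, 5, 0.2), 30, 4))
  colnames(feats) <- c("betweenness", "degree", "closeness",
                       "clustering_coefficient")
  ct <- data.frame(gene = sprintf("g%02d", 1:60), feats)
  hc <- kmeans_hub_clusters(ct, k = 2, seed = 3L, n_boot = 50)
  expect_true(all(hc$jaccard_mean >= 0.95))
  expect_true(all(hc$stable))
  expect_gt(hc$pillai, 0.9)
  expect_lt(hc$manova_p, 1e-6)
  expect_lte(hc$pillai, min(2 - 1, 4) + 1e-9)

  # identical rows: degenerate, warned
  ct2 <- data.frame(gene = c("a", "b", "c"),
                    betweenness = 1, degree = 1, closeness = 1,
                    clustering_coefficient = 1)
  expect_warning(hd <- kmeans_hub_clusters(ct2, k = 2, n_boot = 5),
                 "degenerate")
  expect_true(all(is.na(hd$jaccard_mean)))

  expect_error(kmeans_hub_clusters(ct2, k = 5), "exceeds")
})

test_that("MANOVA p-values are uniform under label permutation", {
  set.seed(33)
  p <- vapply(seq_len(400), function(i) {
    x <- matrix(stats::rnorm(40 * 3), 40, 3)
    lab <- factor(sample(rep(1:3, length.out = 40)))
    summary(stats::manova(x ~ lab), test = "Pillai")$stats[1, "Pr(>F)"]
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("hypergeometric enrichment matches enumeration and handles edges", {
  db <- structure(list(P1 = list(description = "d", genes = c("A", "B", "C")),
                       P2 = list(description = "d", genes = c("D", "E"))),
                  class = "pathway_db")
  bg <- LETTERS[1:10]
  # disjoint set and pathway: overlap 0, p = 1
  res <- hypergeom_enrichment(c("D", "E"), db, bg, min_genes = 0)
  expect_equal(res$p[res$pathway_id == "P1"], 1)
  expect_equal(res$n_genes_in_set[res$pathway_id == "P2"], 2L)

  # gene_set = pathway = background: overlap maximal, p = 1
  res2 <- hypergeom_enrichment(c("A", "B", "C"), db["P1"], c("A", "B", "C"),
                               min_genes = 0)
  expect_equal(res2$n_genes_in_set, 3L)
  expect_equal(res2$p, 1)

  # exhaustive enumeration oracle: P(X >= q) by summing the pmf
  set.seed(2)
  for (rep in 1:10) {
    N <- 20; K <- sample(3:10, 1); n <- sample(3:10, 1)
    bg <- sprintf("g%02d", 1:N)
    pw <- sample(bg, K)
    gs <- sample(bg, n)
    q <- length(intersect(gs, pw))
    db <- structure(list(PX = list(description = "", genes = pw)),
                    class = "pathway_db")
    got <- hypergeom_enrichment(gs, db, bg, min_genes = 0)$p
    oracle <- sum(vapply(q:min(K, n), function(x) {
      choose(K, x) * choose(N - K, n - x) / choose(N, n)
    }, 0))
    expect_equal(got, oracle, tolerance = 1e-12)
  }

  expect_error(hypergeom_enrichment("A", db, character()), "background")
})

test_that("ward clustering recovers planted correlation blocks", {
  set.seed(17)
  n_ind <- 12
  block <- function(k, center) {
    base <- stats::rnorm(n_ind)
    sapply(seq_len(k), function(i) base + stats::rnorm(n_ind, 0, 0.1))
  }
  m <- cbind(block(5), block(5), block(5))
  colnames(m) <- sprintf("g%02d", 1:15)
  wc <- ward_signal_clusters(m, n_clusters = 3, n_boot = 30, seed = 2L)
  truth <- rep(1:3, each = 5)
  # exact block recovery up to label permutation
  expect_equal(length(unique(paste(wc$labels, truth))), 3L)
  expect_true(all(wc$support > 0.8))

  # constant column dropped with warning
  m2 <- cbind(m, gZZ = rep(1, n_ind))
  expect_warning(ward_signal_clusters(m2, 3, n_boot = 0), "constant")

  # 1 - corr dissimilarities: perfectly correlated 0, anti-correlated 2
  x <- stats::rnorm(10)
  cr <- stats::cor(cbind(x, x, -x))
  expect_equal((1 - cr)[1, 2], 0)
  expect_equal((1 - cr)[1, 3], 2)
})

test_that("cluster-to-network mapping scores preservation against a null", {
  # a clique maps entirely into the main component
  cl_genes <- sprintf("c%d", 1:5)
  pairs <- t(utils::combn(5, 2))
  clique <- edges_df(cl_genes[pairs[, 1]], cl_genes[pairs[, 2]],
                     score = 0.9)
  # isolated genes have no edges at all
  lonely <- sprintf("iso%d", 1:5)
  noise_a <- sprintf("x%02d", 1:30)
  noise_b <- sprintf("x%02d", c(2:30, 1))
  et <- ppi_edge_table(rbind(as.data.frame(clique),
                             data.frame(gene_a = noise_a, gene_b = noise_b,
                                        combined_score = 0.75,
                                        coexpression = 0.5)))
  clusters <- list(hub = cl_genes, iso = lonely)
  universe <- c(cl_genes, lonely, noise_a)
  mp <- map_clusters_to_network(clusters, et, score_threshold = 0.7,
                                min_degree = 3, n_random = 300,
                                seed = 5L, universe = universe)
  expect_equal(mp$preserved_fraction[mp$cluster == "hub"], 1)
  expect_equal(mp$preserved_fraction[mp$cluster == "iso"], 0)
  # planted hub cluster is non-random
  expect_lt(mp$empirical_p[mp$cluster == "hub"], 0.05)

  expect_error(map_clusters_to_network(list(a = LETTERS[1:5]), et,
                                       universe = c("A", "B")),
               "larger than")
})

test_that("preservation fractions are invariant to node relabeling", {
  set.seed(30)
  genes <- sprintf("g%02d", 1:20)
  pairs <- t(utils::combn(20, 2))
  on <- pairs[stats::runif(nrow(pairs)) < 0.2, , drop = FALSE]
  et <- edges_df(genes[on[, 1]], genes[on[, 2]])
  cl <- list(a = genes[1:8])
  m1 <- map_clusters_to_network(cl, et, 0.5, 2, n_random = 10, seed = 1L,
                                universe = genes)
  relabel <- stats::setNames(sprintf("H%02d", 20:1), genes)
  et2 <- ppi_edge_table(data.frame(gene_a = unname(relabel[et$gene_a]),
                                   gene_b = unname(relabel[et$gene_b]),
                                   combined_score = et$combined_score,
                                   coexpression = et$coexpression))
  m2 <- map_clusters_to_network(list(a = unname(relabel[cl$a])), et2,
                                0.5, 2, n_random = 10, seed = 1L,
                                universe = unname(relabel[genes]))
  expect_equal(m1$preserved_fraction, m2$preserved_fraction)
})
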