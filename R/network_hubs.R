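# PPI network construction, node centralities, K-means hub clustering with
# bootstrap Jaccard stability and MANOVA validation, hypergeometric pathway
# enrichment, Ward clustering of methylation signal, and mapping of gene
# clusters back onto the network with a random-subset null.

#' Build a PPI graph from an edge table
#'
#' Drops edges below the combined-score threshold, then (optionally)
#' removes low-degree nodes iteratively until every remaining node has at
#' least `min_degree` interactions.
#'
#' @param edge_table A `ppi_edge_table`.
#' @param score_threshold Minimum combined score (e.g. 0.4 medium, 0.7
#'   high confidence).
#' @param min_degree Iterative minimum-degree filter (0 disables).
#' @return An `igraph` undirected graph with `combined_score` and
#'   `coexpression` edge attributes.
#' @export
build_graph <- function(edge_table, score_threshold = 0.4, min_degree = 0) {
  keep <- edge_table$combined_score >= score_threshold
  et <- edge_table[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(et, directed = FALSE)
  repeat {
    low <- igraph::V(g)[igraph::degree(g) < min_degree]
    if (!length(low) || min_degree <= 0) break
    g <- igraph::delete_vertices(g, low)
  }
  if (igraph::vcount(g) == 0) {
    warning("graph is empty after score/degree filtering")
  }
  g
}

# BFS shortest-path distance and path-count matrices for one connected
# component (small-graph exact computation; used for stress/radiality).
shortest_path_counts <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(igraph::adjacent_vertices(g, seq_len(n)), as.integer)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[s, w])) {
            if (!(w %in% nxt)) nxt <- c(nxt, w)
            dist[s, w] <- d
          }
          if (dist[s, w] == d) sigma[s, w] <- sigma[s, w] + sigma[s, v]
        }
      }
      frontier <- nxt
    }
  }
  list(dist = dist, sigma = sigma)
}

#' Node centralities of a PPI graph
#'
#' Standard unweighted definitions: degree; betweenness as shortest-path
#' pair fractions (raw, unnormalized counts by default); closeness as the
#' reciprocal of the sum of distances within the node's connected
#' component; local clustering coefficient; average shortest path length to
#' reachable nodes; stress as the raw number of shortest paths passing
#' through the node; radiality as
#' `sum_u (diameter + 1 - d(v, u)) / (n - 1)` within the component.
#' Singleton components get 0 for all path-based metrics.
#'
#' @param graph An `igraph` graph.
#' @param normalized_betweenness Use the normalized betweenness variant?
#'   Default `FALSE` (raw counts).
#' @return `data.frame` of class `centrality_table`, one row per node.
#' @export
centralities <- function(graph, normalized_betweenness = FALSE) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(graph)))
  out <- data.frame(
    gene = nodes,
    degree = as.numeric(igraph::degree(graph)),
    betweenness = as.numeric(igraph::betweenness(
      graph, directed = FALSE, normalized = normalized_betweenness)),
    closeness = 0, clustering_coefficient = 0, avg_shortest_path = 0,
    stress = 0, radiality = 0,
    stringsAsFactors = FALSE
  )
  cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  out$clustering_coefficient <- as.numeric(cc)

  comp <- igraph::components(graph)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(graph, members)
    sp <- shortest_path_counts(sub)
    d <- sp$dist
    sg <- sp$sigma
    n <- length(members)
    diam <- max(d)
    for (vi in seq_len(n)) {
      row <- members[vi]
      dv <- d[vi, -vi]
      out$closeness[row] <- 1 / sum(dv)
      out$avg_shortest_path[row] <- mean(dv)
      out$radiality[row] <- sum(diam + 1 - dv) / (n - 1)
      # stress: shortest paths through v (v interior), unordered pairs
      stress <- 0
      for (s in seq_len(n)) {
        if (s == vi) next
        for (t in seq_len(n)) {
          if (t <= s || t == vi) next
          if (d[s, vi] + d[vi, t] == d[s, t]) {
            stress <- stress + sg[s, vi] * sg[vi, t]
          }
        }
      }
      out$stress[row] <- stress
    }
  }
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

# Jaccard similarity between two index sets
jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' K-means hub clustering with bootstrap stability and MANOVA validation
#'
#' Clusters nodes on z-scored centrality features with K-means (50 random
#' restarts). Stability: nodes are resampled with replacement `n_boot`
#' times, the resample is reclustered, each original cluster is matched to
#' the bootstrap cluster of maximum Jaccard similarity, and the mean
#' Jaccard per original cluster is reported; clusters with mean Jaccard
#' >= 0.75 are flagged stable. Cluster separation is validated with a
#' MANOVA Pillai trace over the features plus pairwise F tests.
#'
#' @param centrality_table A `centrality_table` (or data.frame with a
#'   `gene` column and the feature columns).
#' @param k Number of clusters (default 3).
#' @param features Feature columns used for clustering.
#' @param seed Integer seed for K-means restarts and the bootstrap.
#' @param n_boot Number of bootstrap resamples.
#' @param stable_threshold Mean-Jaccard stability threshold (default 0.75).
#' @return A list of class `hub_clustering`: `k`, `labels` (named),
#'   `jaccard_mean`, `stable`, `pillai`, `manova_p`, `pairwise_f`.
#' @export
kmeans_hub_clusters <- function(centrality_table, k = 3,
                                features = c("betweenness", "degree",
                                             "closeness",
                                             "clustering_coefficient"),
                                seed = 1L, n_boot = 100,
                                stable_threshold = 0.75) {
  x <- as.matrix(centrality_table[features])
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of nodes")
  x <- scale(x)
  x[!is.finite(x)] <- 0  # constant features carry no information
  if (nrow(unique(x)) < k) {
    warning("fewer distinct feature rows than clusters; ",
            "degenerate clustering, stability undefined")
    labels <- stats::setNames(rep(1L, n), centrality_table$gene)
    return(structure(list(k = k, labels = labels,
                          jaccard_mean = rep(NA_real_, k),
                          stable = rep(NA, k), pillai = NA_real_,
                          manova_p = NA_real_, pairwise_f = NULL),
                     class = "hub_clustering"))
  }
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 50, iter.max = 100)
  labels <- stats::setNames(km$cluster, centrality_table$gene)

  orig <- split(seq_len(n), km$cluster)
  jacc <- matrix(NA_real_, n_boot, k)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    ux <- x[idx, , drop = FALSE]
    kb <- tryCatch(
      stats::kmeans(ux, centers = k, nstart = 10, iter.max = 100),
      error = function(e) NULL)
    if (is.null(kb)) next
    boot_sets <- split(unique(idx),
                       kb$cluster[match(unique(idx), idx)])
    present <- unique(idx)
    for (ci in seq_len(k)) {
      oc <- intersect(orig[[ci]], present)
      if (!length(oc)) next
      jacc[b, ci] <- max(vapply(boot_sets, jaccard, 0, a = oc))
    }
  }
  jaccard_mean <- colMeans(jacc, na.rm = TRUE)

  fit <- stats::manova(x ~ factor(km$cluster))
  sm <- summary(fit, test = "Pillai")$stats
  pairs <- utils::combn(k, 2)
  pairwise <- apply(pairs, 2, function(pr) {
    sel <- km$cluster %in% pr
    f2 <- stats::manova(x[sel, , drop = FALSE] ~
                          factor(km$cluster[sel]))
    s2 <- summary(f2, test = "Pillai")$stats
    c(cluster_a = pr[1], cluster_b = pr[2],
      f = s2[1, "approx F"], p = s2[1, "Pr(>F)"])
  })
  structure(list(k = k, labels = labels, jaccard_mean = jaccard_mean,
                 stable = jaccard_mean >= stable_threshold,
                 pillai = sm[1, "Pillai"], manova_p = sm[1, "Pr(>F)"],
                 pairwise_f = as.data.frame(t(pairwise))),
            class = "hub_clustering")
}

#' @export
print.hub_clustering <- function(x, ...) {
  cat(sprintf("<hub_clustering> k=%d, mean Jaccard: %s, Pillai %.3f (p %.3g)\n",
              x$k, paste(sprintf("%.2f", x$jaccard_mean), collapse = ", "),
              x$pillai, x$manova_p))
  invisible(x)
}

#' Hypergeometric pathway over-representation test
#'
#' One-sided hypergeometric tail probability of observing at least the
#' seen overlap between the gene set and each pathway, within the stated
#' background universe; BH-adjusted across pathways. Pathways overlapping
#' the gene set in fewer than `min_genes` genes are excluded from the
#' report.
#'
#' @param gene_set Character vector (subset of `background`).
#' @param pathway_db A `pathway_db`.
#' @param background Background gene universe.
#' @param min_genes Minimum overlap to report (default 2).
#' @return `data.frame` with `pathway_id`, `n_genes_in_set`, `p`, `fdr_p`.
#' @export
hypergeom_enrichment <- function(gene_set, pathway_db, background,
                                 min_genes = 2) {
  if (!length(background)) stop("empty background universe")
  gene_set <- intersect(unique(gene_set), background)
  res <- lapply(names(pathway_db), function(id) {
    pw <- intersect(pathway_db[[id]]$genes, background)
    q <- length(intersect(gene_set, pw))
    p <- stats::phyper(q - 1, length(pw), length(background) - length(pw),
                       length(gene_set), lower.tail = FALSE)
    data.frame(pathway_id = id, n_genes_in_set = q, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_p <- stats::p.adjust(out$p, method = "BH")
  out <- out[out$n_genes_in_set >= min_genes, , drop = FALSE]
  out <- out[order(out$fdr_p, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ward clustering of methylation signal across individuals
#'
#' Genes are clustered on the dissimilarity `1 - cor(x, y)` of their
#' methylation signal profiles through individuals (Pearson), using Ward's
#' minimum-variance agglomeration, and the tree is cut at `n_clusters`.
#' Cluster support is estimated by resampling individuals with
#' replacement: for each original cluster the maximum Jaccard similarity
#' to any cluster of the resampled tree is averaged over `n_boot`
#' resamples (ordinary bootstrap probabilities, not multiscale-bootstrap
#' AU p-values).
#'
#' @param gene_by_individual_signal Numeric matrix, individuals x genes
#'   (e.g. from [signal_density_matrix()]).
#' @param n_clusters Number of clusters to cut.
#' @param n_boot Bootstrap resamples (0 skips support estimation).
#' @param seed Integer seed.
#' @return A list with `labels` (named per gene), `support` (per
#'   cluster), `hclust` (the tree).
#' @export
ward_signal_clusters <- function(gene_by_individual_signal, n_clusters,
                                 n_boot = 100, seed = 1L) {
  m <- gene_by_individual_signal
  stopifnot(nrow(m) >= 3, ncol(m) >= 3)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant-signal gene(s)")
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) < 3) stop("fewer than 3 genes with non-constant signal")
  tree_labels <- function(mat) {
    cr <- suppressWarnings(stats::cor(mat))
    cr[!is.finite(cr)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cr), method = "ward.D2")
    list(hc = hc, labels = stats::cutree(hc, n_clusters))
  }
  base <- tree_labels(m)
  orig <- split(colnames(m), base$labels)
  support <- rep(NA_real_, n_clusters)
  if (n_boot > 0) {
    set.seed(seed)
    jacc <- matrix(NA_real_, n_boot, n_clusters)
    for (b in seq_len(n_boot)) {
      mb <- m[sample.int(nrow(m), replace = TRUE), , drop = FALSE]
      lb <- tryCatch(tree_labels(mb)$labels, error = function(e) NULL)
      if (is.null(lb)) next
      boot_sets <- split(names(lb), lb)
      for (ci in seq_len(n_clusters)) {
        jacc[b, ci] <- max(vapply(boot_sets, jaccard, 0, a = orig[[ci]]))
      }
    }
    support <- colMeans(jacc, na.rm = TRUE)
  }
  list(labels = base$labels, support = support, hclust = base$hc)
}

#' Map gene clusters onto a PPI network with a random-subset null
#'
#' For each cluster, a PPI network is built on the cluster's genes
#' (combined score >= `score_threshold`, iterative minimum-degree filter)
#' and the preserved information is measured as the fraction of cluster
#' genes integrating the main (largest) connected component. The null
#' distribution repeats the measurement on `n_random` uniform same-size
#' gene subsets of the sampling universe; the empirical p is the fraction
#' of null subsets achieving a preservation fraction at least as large.
#'
#' @param clusters Named list of gene character vectors.
#' @param edge_table A `ppi_edge_table`.
#' @param score_threshold Combined-score threshold (default 0.7).
#' @param min_degree Iterative minimum-degree filter (default 3).
#' @param n_random Null subsets per cluster (default 1000).
#' @param seed Integer seed.
#' @param universe Sampling universe for the null; defaults to the union
#'   of all cluster genes.
#' @return `data.frame` with per-cluster `size`, `preserved_fraction`,
#'   `empirical_p`; null fractions in attribute `"null"`.
#' @export
map_clusters_to_network <- function(clusters, edge_table,
                                    score_threshold = 0.7, min_degree = 3,
                                    n_random = 1000, seed = 1L,
                                    universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(clusters))
  preserved <- function(genes) {
    et <- edge_table[edge_table$gene_a %in% genes &
                       edge_table$gene_b %in% genes, , drop = FALSE]
    if (!nrow(et)) return(0)
    g <- suppressWarnings(build_graph(et, score_threshold, min_degree))
    if (igraph::vcount(g) == 0) return(0)
    comp <- igraph::components(g)
    main <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
    length(intersect(main, genes)) / length(genes)
  }
  set.seed(seed)
  rows <- lapply(names(clusters), function(nm) {
    genes <- clusters[[nm]]
    if (length(genes) > length(universe)) {
      stop("cluster ", nm, " larger than the sampling universe")
    }
    obs <- preserved(genes)
    null <- vapply(seq_len(n_random), function(i) {
      preserved(sample(universe, length(genes)))
    }, 0)
    structure(data.frame(cluster = nm, size = length(genes),
                         preserved_fraction = obs,
                         empirical_p = mean(null >= obs),
                         stringsAsFactors = FALSE),
              null = null)
  })
  out <- do.call(rbind, rows)
  attr(out, "null") <- lapply(rows, attr, "null")
  rownames(out) <- NULL
  out
}
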