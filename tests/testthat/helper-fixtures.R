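# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures.

# minimal hand-built methylome sample
tiny_sample <- function(id = "s1", group = "control",
                        pos = c(10L, 20L, 30L),
                        n_meth = c(2L, 5L, 0L),
                        n_total = c(10L, 10L, 10L)) {
  methylome_sample(id, group,
                   data.frame(chrom = "chr1", pos = pos, strand = "+",
                              context = "CpG", n_meth = n_meth,
                              n_total = n_total))
}

# small simulated world shared across divergence/region tests (cached)
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 60, n_enhancers = 10,
                        sites_per_region = 40, n_signal_genes = 12,
                        n_signal_enhancers = 3, n_pathways = 20,
                        n_signal_pathways = 6, seed = 42L)
      cache <<- list(config = cfg, data = simulate_dataset(cfg))
    }
    cache
  }
})

small_dmps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- small_world()$data
      groups <- vapply(ds$samples, function(s) s$group, "")
      cache <<- call_dmps(ds$samples[groups != "reference"],
                          ds$samples[groups == "reference"])
    }
    cache
  }
})

# independent all-pairs shortest-path oracle (Floyd-Warshall distances,
# DP path counts) used against centralities()
oracle_centralities <- function(adj_matrix) {
  n <- nrow(adj_matrix)
  d <- matrix(Inf, n, n)
  d[adj_matrix == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  # shortest-path counts by DP over increasing distance
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    reach <- which(is.finite(d[s, ]))
    for (t in reach[order(d[s, reach])]) {
      if (t == s) next
      preds <- which(adj_matrix[, t] == 1 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  betw <- stress <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (!is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t] && sigma[s, t] > 0) {
          paths_through <- sigma[s, v] * sigma[v, t]
          stress[v] <- stress[v] + paths_through
          betw[v] <- betw[v] + paths_through / sigma[s, t]
        }
      }
    }
  }
  closeness <- radiality <- avg_sp <- numeric(n)
  comp_of <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (is.na(comp_of[v])) {
      cid <- cid + 1
      comp_of[is.finite(d[v, ])] <- cid
    }
  }
  for (v in seq_len(n)) {
    members <- setdiff(which(comp_of == comp_of[v]), v)
    if (!length(members)) next
    dv <- d[v, members]
    diam <- max(d[comp_of == comp_of[v], comp_of == comp_of[v]])
    closeness[v] <- 1 / sum(dv)
    avg_sp[v] <- mean(dv)
    radiality[v] <- sum(diam + 1 - dv) / length(members)
  }
  cc <- vapply(seq_len(n), function(v) {
    nb <- which(adj_matrix[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj_matrix[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, 0)
  data.frame(degree = rowSums(adj_matrix), betweenness = betw,
             closeness = closeness, clustering_coefficient = cc,
             avg_shortest_path = avg_sp, stress = stress,
             radiality = radiality)
}

# definition-level Kendall's W oracle (independent of kendall_w)
oracle_kendall_w <- function(ratings) {
  ranks <- apply(ratings, 2, rank)
  n <- nrow(ranks)
  m <- ncol(ranks)
  r_i <- rowSums(ranks)
  s <- sum((r_i - m * (n + 1) / 2)^2)
  tie <- sum(vapply(seq_len(m), function(j) {
    tt <- table(ranks[, j])
    sum(tt^3 - tt)
  }, 0))
  12 * s / (m^2 * (n^3 - n) - m * tie)
}
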