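make_regions <- function(n = 5, width = 100L, chrom = "chr1") {
  region_set(data.frame(chrom = chrom,
                        start = (seq_len(n) - 1L) * 2L * width,
                        end = (seq_len(n) - 1L) * 2L * width + width,
                        name = sprintf("r%02d", seq_len(n))))
}

# wrap a hand-built DMP table into the dmp_set contract
fake_dmp_set <- function(sites, individuals) {
  structure(list(sites = sites, individuals = individuals,
                 divergences = sites, cutoff = 0, youden_j = 1,
                 alpha = 0.05),
            class = "dmp_set")
}

test_that("DMP counting respects the half-open region convention", {
  regions <- make_regions(2)
  ind <- data.frame(sample_id = "s1", group = "control")
  sites <- data.frame(chrom = "chr1", pos = c(0L, 99L, 100L, 200L),
                      sample_id = "s1", group = "control",
                      stringsAsFactors = FALSE)
  rcm <- count_dmps_per_region(fake_dmp_set(sites, ind), regions)
  # pos = start counted; pos = end (100) not; 200 = start of r02 counted
  expect_equal(unname(rcm$counts[, "s1"]), c(2L, 1L))
})

test_that("region counts equal a brute-force interval scan", {
  set.seed(4)
  regions <- make_regions(50)
  ids <- sprintf("s%d", 1:4)
  ind <- data.frame(sample_id = ids,
                    group = rep(c("control", "treatment"), each = 2))
  sites <- data.frame(chrom = "chr1",
                      pos = sample.int(10000, 600, replace = TRUE) - 1L,
                      sample_id = sample(ids, 600, replace = TRUE),
                      group = "control", stringsAsFactors = FALSE)
  rcm <- count_dmps_per_region(fake_dmp_set(sites, ind), regions)
  for (i in seq_len(nrow(regions))) {
    for (id in ids) {
      brute <- sum(sites$sample_id == id & sites$pos >= regions$start[i] &
                     sites$pos < regions$end[i])
      expect_identical(rcm$counts[i, id], as.integer(brute))
    }
  }
})

test_that("identical group counts give log2fc 0 and no DM call", {
  counts <- matrix(rep(c(10L, 12L, 9L, 11L, 10L, 12L, 9L), each = 3),
                   nrow = 3, byrow = FALSE,
                   dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:7)))
  groups <- rep(c("control", "treatment"), c(4, 3))
  # make treatment columns copies of control means: identical profiles
  counts[, 5:7] <- counts[, 1:3]
  res <- glm_count_test(counts, family = "poisson", min_count = 0,
                        groups = groups,
                        lengths = stats::setNames(rep(1000, 3),
                                                  rownames(counts)))
  expect_true(all(abs(res$log2fc_dmp) < 0.2))
  expect_true(all(res$p_lrt > 0.3))
  expect_false(any(res$is_dm))
})

test_that("min-count filter keeps regions where one full group passes", {
  counts <- rbind(r1 = c(10, 10, 10, 10, 2, 2, 2),   # controls pass
                  r2 = c(2, 2, 2, 2, 10, 10, 10),    # treatments pass
                  r3 = c(2, 2, 2, 10, 10, 10, 2))    # neither group complete
  colnames(counts) <- sprintf("s%d", 1:7)
  groups <- rep(c("control", "treatment"), c(4, 3))
  res <- glm_count_test(counts, family = "poisson", min_count = 8,
                        groups = groups,
                        lengths = stats::setNames(rep(1000, 3),
                                                  rownames(counts)))
  expect_setequal(res$name, c("r1", "r2"))
})

test_that("families agree on log2fc and BH adjustment is monotone", {
  set.seed(14)
  counts <- matrix(rnbinom(50 * 7, size = 10, mu = 15), 50, 7,
                   dimnames = list(sprintf("r%02d", 1:50),
                                   sprintf("s%d", 1:7)))
  groups <- rep(c("control", "treatment"), c(4, 3))
  lens <- stats::setNames(rep(1500, 50), rownames(counts))
  nb <- glm_count_test(counts, family = "negbinom", min_count = 0,
                       groups = groups, lengths = lens)
  po <- glm_count_test(counts, family = "poisson", min_count = 0,
                       groups = groups, lengths = lens)
  expect_equal(nb$log2fc_dmp, po$log2fc_dmp, tolerance = 1e-6)

  ord <- order(nb$p_lrt)
  expect_true(all(diff(nb$p_adj[ord]) >= -1e-12))
})

test_that("planted signal regions are recovered and nulls are not flagged", {
  w <- small_world()
  dmps <- small_dmps()
  regions <- w$data$regions
  genes <- regions[regions$kind == "gene", ]
  class(genes) <- class(regions)
  rcm <- count_dmps_per_region(dmps, genes)
  res <- glm_count_test(rcm)
  truth <- w$data$truth
  sig <- truth$name[truth$signal & truth$kind == "gene"]
  flagged <- res$name[res$is_dm]
  expect_gte(mean(sig %in% flagged), 0.8)
  if (length(flagged)) {
    expect_lte(mean(!flagged %in% sig), 0.10)
  }
})

test_that("enhancer spanning takes the envelope across tissues", {
  iv <- data.frame(name = c("e1", "e1", "e2"), chrom = "chr1",
                   start = c(100L, 150L, 500L), end = c(200L, 400L, 600L))
  sp <- span_enhancers(iv)
  expect_equal(sp$start[sp$name == "e1"], 100L)
  expect_equal(sp$end[sp$name == "e1"], 400L)
  # single tissue: unchanged
  expect_equal(sp$start[sp$name == "e2"], 500L)
  expect_error(span_enhancers(iv[0, ]), "no intervals")

  # brute-force envelope on 100 simulated enhancers
  set.seed(8)
  ids <- sprintf("e%03d", 1:100)
  sim <- do.call(rbind, lapply(ids, function(id) {
    k <- sample(1:5, 1)
    st <- sample.int(1e6, k)
    data.frame(name = id, chrom = "chr2", start = st,
               end = st + sample.int(5000, k))
  }))
  sp <- span_enhancers(sim)
  for (id in sample(ids, 20)) {
    g <- sim[sim$name == id, ]
    expect_equal(sp$start[sp$name == id], min(g$start))
    expect_equal(sp$end[sp$name == id], max(g$end))
  }
})

test_that("overlap filter applies the >= 500 bp rule exactly", {
  a <- region_set(data.frame(chrom = "chr1", start = 0L, end = 600L,
                             name = "a1"))
  b1 <- region_set(data.frame(chrom = "chr1", start = 100L, end = 700L,
                              name = "b1"))
  b2 <- region_set(data.frame(chrom = "chr1", start = 101L, end = 700L,
                              name = "b2"))
  expect_equal(nrow(overlap_filter(a, b1, 500)), 1L)  # overlap exactly 500
  expect_equal(nrow(overlap_filter(a, b2, 500)), 0L)  # 499

  # quadratic brute force on random 200-region fixtures
  set.seed(10)
  ra <- region_set(data.frame(chrom = "chr3",
                              start = st <- sample.int(5e4, 200),
                              end = st + sample.int(2000, 200),
                              name = sprintf("a%03d", 1:200)))
  rb <- region_set(data.frame(chrom = "chr3",
                              start = st2 <- sample.int(5e4, 200),
                              end = st2 + sample.int(2000, 200),
                              name = sprintf("b%03d", 1:200)))
  got <- overlap_filter(ra, rb, 500)
  brute <- list()
  for (i in 1:200) {
    for (j in 1:200) {
      ov <- min(ra$end[i], rb$end[j]) - max(ra$start[i], rb$start[j])
      if (ov >= 500) brute[[length(brute) + 1]] <-
          paste(ra$name[i], rb$name[j], ov)
    }
  }
  expect_setequal(paste(got$name_a, got$name_b, got$overlap_bp),
                  unlist(brute))
})

test_that("region densities follow the per-kb definition", {
  regions <- region_set(data.frame(chrom = "chr1", start = 0L, end = 2000L,
                                   name = "g1"))
  div <- data.frame(chrom = "chr1", pos = c(10L, 20L, 10L, 20L),
                    sample_id = c("c1", "c1", "t1", "t1"),
                    group = rep(c("control", "treatment"), each = 2),
                    hd = c(1, 3, 2, 2), p_sample = c(0.5, 0.5, 0.1, 0.3),
                    tv = 0, tvb = 0, stringsAsFactors = FALSE)
  d <- region_density(div, regions, metric = "hd")
  expect_equal(d$density_control, (1 + 3) / 2000 * 1000)  # 2 per kb
  expect_equal(d$density_treatment, 2)
  expect_equal(d$delta_density, 0)

  # identical groups: delta 0; independent per-site loop oracle
  w <- small_world()
  dmps <- small_dmps()
  genes <- w$data$regions[w$data$regions$kind == "gene", ][1:10, ]
  class(genes) <- c("region_set", "data.frame")
  d <- region_density(dmps$divergences, genes, metric = "hd")
  dv <- dmps$divergences
  for (i in seq_len(nrow(genes))) {
    for (g in c("control", "treatment")) {
      rows <- dv$group == g & dv$chrom == genes$chrom[i] &
        dv$pos >= genes$start[i] & dv$pos < genes$end[i]
      ids <- unique(dv$sample_id[dv$group == g])
      per_ind <- vapply(ids, function(id) {
        sum(abs(dv$hd[rows & dv$sample_id == id]))
      }, 0)
      oracle <- mean(per_ind / (genes$end[i] - genes$start[i]) * 1000)
      expect_equal(d[[paste0("density_", g)]][i], oracle)
    }
  }
})

test_that("filter chain order does not change the DM set", {
  w <- small_world()
  dmps <- small_dmps()
  genes <- w$data$regions[w$data$regions$kind == "gene", ]
  class(genes) <- c("region_set", "data.frame")
  rcm <- count_dmps_per_region(dmps, genes)
  res <- glm_count_test(rcm, family = "poisson")
  # reapply the alpha and lfc filters in the opposite order by hand
  manual <- res$name[abs(res$log2fc_dmp) > 1 & !is.na(res$p_adj) &
                       res$p_adj <= 0.05]
  expect_setequal(res$name[res$is_dm], manual)
})
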