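test_that("reference pooling sums counts and equals the weighted mean level", {
  r1 <- tiny_sample("r1", "reference", n_meth = c(3L, 1L, 2L),
                    n_total = c(10L, 5L, 8L))
  r2 <- tiny_sample("r2", "reference", n_meth = c(5L, 0L, 4L),
                    n_total = c(10L, 6L, 9L))
  pooled <- pool_reference(list(r1, r2))
  expect_equal(pooled$n_meth[pooled$pos == 10], 8L)
  expect_equal(pooled$n_total[pooled$pos == 10], 20L)

  # site present in only one reference keeps that reference's counts
  r3 <- tiny_sample("r3", "reference", pos = c(10L, 99L),
                    n_meth = c(1L, 7L), n_total = c(4L, 9L))
  pooled <- pool_reference(list(r1, r3))
  expect_equal(pooled$n_meth[pooled$pos == 99], 7L)

  # algebraic identity: pooled level is the coverage-weighted mean
  set.seed(2)
  refs <- lapply(1:4, function(i) {
    nt <- sample(5:40, 30, replace = TRUE)
    tiny_sample(paste0("r", i), "reference", pos = seq_len(30) * 7L,
                n_meth = rbinom(30, nt, 0.3), n_total = nt)
  })
  pooled <- pool_reference(refs)
  nm <- rowSums(sapply(refs, function(s) s$sites$n_meth))
  nt <- rowSums(sapply(refs, function(s) s$sites$n_total))
  expect_equal(pooled$n_meth / pooled$n_total, unname(nm / nt))
})

test_that("site divergence statistics match their definitions", {
  s <- tiny_sample("a", "control", pos = c(1L, 2L, 3L),
                   n_meth = c(5L, 10L, 0L), n_total = c(10L, 10L, 10L))
  ref <- data.frame(chrom = "chr1", pos = c(1L, 2L, 3L), strand = "+",
                    n_meth = c(5L, 0L, 10L), n_total = c(10L, 10L, 10L))
  d <- site_divergence(s, ref, weighted = FALSE)

  # identical proportions: tv = 0, hd = 0, fisher p = 1
  expect_equal(d$tv[1], 0)
  expect_equal(d$hd[1], 0)
  expect_equal(d$fisher_p[1], 1)
  # maximal divergence of the squared-Hellinger form
  expect_equal(d$hd[2], 2)
  expect_equal(d$hd[3], 2)
  expect_equal(d$tv[3], -1)

  # Bayesian correction shrinks levels toward the prior mean
  expect_equal(d$tvb[2], 10.5 / 11 - 0.5 / 11)

  # coverage weight w = 2 n_s n_r / (n_s + n_r)
  dw <- site_divergence(s, ref, weighted = TRUE)
  expect_equal(dw$hd, d$hd * 2 * 10 * 10 / 20)
})

test_that("vectorized Fisher p equals fisher.test on random tables", {
  set.seed(7)
  for (i in 1:50) {
    nt1 <- sample(1:60, 1)
    nt2 <- sample(1:120, 1)
    a <- rbinom(1, nt1, runif(1))
    c <- rbinom(1, nt2, runif(1))
    mine <- methnet:::fisher_p_2x2(a, nt1 - a, c, nt2 - c)
    ref <- stats::fisher.test(matrix(c(a, nt1 - a, c, nt2 - c), 2,
                                     byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("youden cutoff maximizes J over observed thresholds", {
  yc <- youden_cutoff(c(0.1, 0.2), c(0.8, 0.9))
  expect_equal(yc$j, 1)
  expect_equal(yc$cutoff, 0.8)  # smallest qualifying observed threshold

  # identical class distributions give J = 0
  yc0 <- youden_cutoff(c(1, 2, 3), c(1, 2, 3))
  expect_equal(yc0$j, 0)

  expect_warning(youden_cutoff(c(1, 1), c(1, 1)), "identical")

  # brute-force oracle over all observed thresholds
  set.seed(3)
  for (rep in 1:5) {
    neg <- rgamma(100, 1.2)
    pos <- rgamma(100, 2.5)
    yc <- youden_cutoff(neg, pos)
    thr <- sort(unique(c(neg, pos)))
    j_all <- vapply(thr, function(t) {
      sum(pos >= t) / length(pos) + sum(neg < t) / length(neg) - 1
    }, 0)
    expect_equal(yc$j, max(j_all))
    expect_equal(yc$cutoff, thr[which.max(j_all)])
  }
})

test_that("planted signal genes accumulate patient DMPs", {
  w <- small_world()
  dmps <- small_dmps()
  truth <- w$data$truth
  sig <- truth$name[truth$signal & truth$kind == "gene"]
  regions <- w$data$regions

  pat <- dmps$sites[dmps$sites$group == "treatment", ]
  per_gene_ind <- table(
    factor(regions$name[findInterval(pat$pos, regions$start)],
           levels = regions$name),
    pat$sample_id)
  # at least 8 DMPs in every patient for >= 80% of planted genes
  ok <- rowSums(per_gene_ind[sig, ] >= 8) == ncol(per_gene_ind)
  expect_gte(mean(ok), 0.8)

  # control individuals also carry DMPs (natural variability)
  expect_gt(sum(dmps$sites$group == "control"), 0)
})

test_that("null world yields comparable DMP densities in signal and null genes", {
  cfg <- sim_config(n_genes = 40, n_enhancers = 0, sites_per_region = 40,
                    n_signal_genes = 8, n_signal_enhancers = 0,
                    delta = 0, seed = 55L)
  meth <- simulate_methylomes(cfg)
  groups <- vapply(meth$samples, function(s) s$group, "")
  dmps <- call_dmps(meth$samples[groups != "reference"],
                    meth$samples[groups == "reference"])
  truth <- meth$truth
  sig <- truth$name[truth$signal]
  counts <- count_dmps_per_region(dmps, meth$regions)
  per_kb <- rowSums(counts$counts) / (counts$lengths / 1000)
  ratio <- mean(per_kb[sig]) / mean(per_kb[setdiff(names(per_kb), sig)])
  expect_gte(ratio, 0.5)
  expect_lte(ratio, 2)
})

test_that("raising alpha never decreases the DMP count", {
  w <- small_world()$data
  groups <- vapply(w$samples, function(s) s$group, "")
  cmp <- w$samples[groups != "reference"]
  ref <- w$samples[groups == "reference"]
  alphas <- c(0.01, 0.05, 0.2)
  counts <- vapply(alphas, function(a) {
    nrow(call_dmps(cmp, ref, alpha = a)$sites)
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("hd is symmetric in sample and reference (unweighted)", {
  set.seed(9)
  nt <- sample(5:30, 20, replace = TRUE)
  s <- tiny_sample("a", "control", pos = seq_len(20) * 3L,
                   n_meth = rbinom(20, nt, 0.4), n_total = nt)
  nt2 <- sample(5:30, 20, replace = TRUE)
  r <- data.frame(chrom = "chr1", pos = seq_len(20) * 3L, strand = "+",
                  n_meth = rbinom(20, nt2, 0.6), n_total = nt2)
  fwd <- site_divergence(s, r, weighted = FALSE)
  s2 <- methylome_sample("b", "control",
                         data.frame(chrom = "chr1", pos = seq_len(20) * 3L,
                                    strand = "+", context = "CpG",
                                    n_meth = r$n_meth, n_total = r$n_total))
  r2 <- s$sites[c("chrom", "pos", "strand", "n_meth", "n_total")]
  rev <- site_divergence(s2, r2, weighted = FALSE)
  expect_equal(fwd$hd, rev$hd)
  expect_equal(fwd$hd == 0, fwd$p_sample == fwd$p_ref)
})
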