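# Per-cytosine divergence statistics versus a pooled reference group and
# signal-detection DMP classification. A site is a DMP for a given
# individual when it passes a BH-adjusted Fisher exact test AND its
# Hellinger divergence exceeds a Youden-index ROC cutoff estimated from the
# control-vs-treatment divergence distributions.

#' Pool reference samples into per-site counts
#'
#' Methylated and total read counts are summed across reference individuals
#' at each (chrom, pos, strand) site. The pooled methylation level is the
#' coverage-weighted mean of the individual levels.
#'
#' @param reference_samples Non-empty list of `methylome_sample` objects.
#' @return `data.frame` with `chrom`, `pos`, `strand`, `n_meth`, `n_total`.
#' @export
pool_reference <- function(reference_samples) {
  if (inherits(reference_samples, "methylome_sample")) {
    reference_samples <- list(reference_samples)
  }
  if (!length(reference_samples)) stop("empty reference set")
  all_sites <- do.call(rbind, lapply(reference_samples, function(s) {
    stopifnot(inherits(s, "methylome_sample"))
    s$sites[c("chrom", "pos", "strand", "n_meth", "n_total")]
  }))
  key <- paste(all_sites$chrom, all_sites$pos, all_sites$strand, sep = "\r")
  n_meth <- rowsum(all_sites$n_meth, key)
  n_total <- rowsum(all_sites$n_total, key)
  parts <- strsplit(rownames(n_meth), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    pos = as.integer(vapply(parts, `[[`, "", 2L)),
    strand = vapply(parts, `[[`, "", 3L),
    n_meth = as.integer(n_meth[, 1]),
    n_total = as.integer(n_total[, 1]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Vectorized two-sided Fisher exact p for 2x2 tables
# [[a, b], [c, d]] = [(meth, unmeth) sample; (meth, unmeth) reference].
# Sums hypergeometric point probabilities <= that of the observed table
# (with the standard relative tolerance), matching stats::fisher.test.
fisher_p_2x2 <- function(a, b, c, d) {
  mapply(function(a, b, c, d) {
    m <- a + c
    n <- b + d
    k <- a + b
    x <- max(0L, k - n):min(k, m)
    probs <- stats::dhyper(x, m, n, k)
    p0 <- stats::dhyper(a, m, n, k)
    min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
  }, a, b, c, d)
}

#' Per-site divergence of a sample versus pooled reference counts
#'
#' For each site present in both the sample and the reference:
#' methylation levels `p = n_meth / n_total`; signed total variation
#' `tv = p_sample - p_ref`; Bayesian-corrected `tvb` computed from
#' posterior-mean levels `(n_meth + a) / (n_total + a + b)` under a
#' Beta(a, b) prior; squared Hellinger divergence
#' `hd = (sqrt(p_s) - sqrt(p_r))^2 + (sqrt(1-p_s) - sqrt(1-p_r))^2`,
#' optionally multiplied by the coverage weight
#' `w = 2 n_s n_r / (n_s + n_r)` (default on); and a two-sided Fisher
#' exact p-value on the 2x2 (meth, unmeth) x (sample, reference) table.
#'
#' @param sample A `methylome_sample` (or its `sites` data.frame).
#' @param ref Pooled reference counts from [pool_reference()].
#' @param prior Length-2 Beta prior (a, b); default Jeffreys (0.5, 0.5).
#' @param weighted Multiply `hd` by the coverage weight? Default `TRUE`.
#' @return `data.frame` with one row per shared site: `chrom`, `pos`,
#'   `strand`, `sample_id`, `group`, `p_sample`, `p_ref`, `tv`, `tvb`,
#'   `hd`, `fisher_p`.
#' @export
site_divergence <- function(sample, ref, prior = c(0.5, 0.5),
                            weighted = TRUE) {
  if (inherits(sample, "methylome_sample")) {
    sites <- sample$sites
    sample_id <- sample$sample_id
    group <- sample$group
  } else {
    sites <- sample
    sample_id <- NA_character_
    group <- NA_character_
  }
  if (any(sites$n_total < 1) || any(ref$n_total < 1)) {
    stop("zero total reads encountered")
  }
  key_s <- paste(sites$chrom, sites$pos, sites$strand, sep = "\r")
  key_r <- paste(ref$chrom, ref$pos, ref$strand, sep = "\r")
  idx <- match(key_s, key_r)
  keep <- !is.na(idx)
  s <- sites[keep, , drop = FALSE]
  r <- ref[idx[keep], , drop = FALSE]

  p_s <- s$n_meth / s$n_total
  p_r <- r$n_meth / r$n_total
  a <- prior[1]
  b <- prior[2]
  pt_s <- (s$n_meth + a) / (s$n_total + a + b)
  pt_r <- (r$n_meth + a) / (r$n_total + a + b)
  hd <- (sqrt(p_s) - sqrt(p_r))^2 + (sqrt(1 - p_s) - sqrt(1 - p_r))^2
  if (weighted) {
    hd <- hd * 2 * s$n_total * r$n_total / (s$n_total + r$n_total)
  }
  out <- data.frame(
    chrom = s$chrom, pos = s$pos, strand = s$strand,
    sample_id = sample_id, group = group,
    p_sample = p_s, p_ref = p_r,
    tv = p_s - p_r, tvb = pt_s - pt_r, hd = hd,
    fisher_p = fisher_p_2x2(s$n_meth, s$n_total - s$n_meth,
                            r$n_meth, r$n_total - r$n_meth),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Youden-index optimal cutoff on observed thresholds
#'
#' Scans all observed score values as candidate cutoffs (score >= cutoff
#' classified positive) and returns the cutoff maximizing
#' J = sensitivity + specificity - 1. Ties are broken by the smallest
#' qualifying cutoff.
#'
#' @param negative_scores,positive_scores Non-empty numeric vectors of
#'   scores for the negative (control) and positive (treatment) class.
#' @return A list with `cutoff` and `j`.
#' @export
youden_cutoff <- function(negative_scores, positive_scores) {
  neg <- negative_scores[is.finite(negative_scores)]
  pos <- positive_scores[is.finite(positive_scores)]
  if (!length(neg) || !length(pos)) stop("both score sets must be non-empty")
  thresholds <- sort(unique(c(neg, pos)))
  if (length(thresholds) == 1L) {
    warning("all scores identical; J = 0")
    return(list(cutoff = thresholds, j = 0))
  }
  sens <- vapply(thresholds, function(t) mean(pos >= t), 0)
  spec <- vapply(thresholds, function(t) mean(neg < t), 0)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]
  list(cutoff = thresholds[best], j = j[best])
}

#' Call differentially methylated positions (DMPs)
#'
#' Runs the full signal-detection DMP classification:
#' (i) per-site divergences for every control and treatment individual
#' against the pooled reference; (ii) candidate sites are those with
#' BH-adjusted Fisher p <= alpha; (iii) the Hellinger-divergence cutoff is
#' the Youden-index maximizer with control candidates as the negative class
#' and treatment candidates as the positive class; (iv) DMPs are candidate
#' sites with divergence >= cutoff, retained per individual with
#' direction = sign of the methylation-level change.
#'
#' @param samples List of control and treatment `methylome_sample`s.
#' @param reference List of reference `methylome_sample`s, or the
#'   pre-pooled count table from [pool_reference()].
#' @param alpha Significance level applied to BH-adjusted Fisher p-values.
#' @param adjust Multiple-testing adjustment method (see
#'   [stats::p.adjust()]).
#' @param prior,weighted Passed to [site_divergence()].
#' @return A list of class `dmp_set` with elements `sites` (DMPs, one row
#'   per site x individual, with `direction`), `cutoff`, `youden_j`,
#'   `alpha`, `divergences` (all sites), `individuals`.
#' @export
call_dmps <- function(samples, reference, alpha = 0.05, adjust = "BH",
                      prior = c(0.5, 0.5), weighted = TRUE) {
  groups <- vapply(samples, function(s) s$group, "")
  if (!any(groups == "control") || !any(groups == "treatment")) {
    stop("samples must include at least one control and one treatment")
  }
  ref <- if (is.data.frame(reference)) reference else
    pool_reference(reference)
  div <- do.call(rbind, lapply(samples, site_divergence, ref = ref,
                               prior = prior, weighted = weighted))
  div$p_adj <- stats::p.adjust(div$fisher_p, method = adjust)
  cand <- div[div$p_adj <= alpha, , drop = FALSE]
  individuals <- data.frame(
    sample_id = vapply(samples, function(s) s$sample_id, ""),
    group = groups, stringsAsFactors = FALSE)
  if (!nrow(cand)) {
    warning("no candidate sites survive the Fisher filter")
    return(structure(list(sites = cand[0, ], cutoff = NA_real_,
                          youden_j = NA_real_, alpha = alpha,
                          divergences = div, individuals = individuals),
                     class = "dmp_set"))
  }
  neg <- cand$hd[cand$group == "control"]
  pos <- cand$hd[cand$group == "treatment"]
  if (length(neg) && length(pos)) {
    yc <- youden_cutoff(neg, pos)
  } else {
    # degenerate candidate sets: fall back to the smallest candidate hd
    yc <- list(cutoff = min(cand$hd), j = NA_real_)
  }
  dmps <- cand[cand$hd >= yc$cutoff, , drop = FALSE]
  dmps$direction <- ifelse(dmps$tv >= 0, "hyper", "hypo")
  rownames(dmps) <- NULL
  structure(list(sites = dmps, cutoff = yc$cutoff, youden_j = yc$j,
                 alpha = alpha, divergences = div,
                 individuals = individuals),
            class = "dmp_set")
}

#' @export
print.dmp_set <- function(x, ...) {
  cat(sprintf(paste0("<dmp_set> %d DMPs across %d individuals ",
                     "(cutoff %.4g, J %.3f, alpha %g)\n"),
              nrow(x$sites), nrow(x$individuals), x$cutoff, x$youden_j,
              x$alpha))
  invisible(x)
}

#' Group-mean methylation level difference per site
#'
#' For each site, the mean over a group's individuals of the sample
#' methylation level minus the pooled reference level; the usual input for
#' WIG track export.
#'
#' @param divergences Combined [site_divergence()] rows (e.g.
#'   `dmp_set$divergences`).
#' @param group `"control"` or `"treatment"`.
#' @return `data.frame` with `chrom`, `pos`, `value`.
#' @export
group_level_diff <- function(divergences, group) {
  d <- divergences[divergences$group == group, , drop = FALSE]
  if (!nrow(d)) stop("no divergences for group ", group)
  key <- paste(d$chrom, d$pos, sep = "\r")
  means <- tapply(d$tv, key, mean)
  first <- !duplicated(key)
  out <- data.frame(chrom = d$chrom[first], pos = d$pos[first],
                    value = as.numeric(means[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
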