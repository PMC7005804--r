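# Pathway-score construction (number of enriched genes times a discretized
# significance level) and concordance statistics between the DMG- and
# DEG-derived pathway enrichments: Lin's concordance correlation
# coefficient with bootstrap CI, Kendall's coefficient of concordance with
# a permutation test, OLS agreement regression, Bland-Altman limits, and
# the enriched-pathway overlap fraction.

#' Discretized significance level (sig) of an enriched pathway
#'
#' Maps an enrichment FDR p-value to the integer scale used by the pathway
#' score: pathways not enriched in a gene set get 0; enriched pathways get
#' 3 for p <= 1e-6, 2 for p in (1e-6, 1e-5], 1 for p in (1e-5, 1e-4].
#' Enriched pathways with p in (1e-4, 4e-4) -- considered by the FDR <
#' 4e-4 screen but above the top of the scale -- receive 1 when
#' `extended = TRUE` (default) and 0 otherwise. p >= 4e-4 is never scored.
#'
#' @param fdr_p FDR p-value(s) in \[0, 1\].
#' @param enriched Logical: is the pathway enriched in this gene set?
#' @param extended Score the (1e-4, 4e-4) band as 1?
#' @return Integer vector in \{0, 1, 2, 3\}.
#' @export
sig_value <- function(fdr_p, enriched = TRUE, extended = TRUE) {
  n <- max(length(fdr_p), length(enriched))
  fdr_p <- rep_len(fdr_p, n)
  enriched <- rep_len(enriched, n)
  if (any(enriched & (is.na(fdr_p) | fdr_p < 0 | fdr_p > 1))) {
    stop("enriched pathway with FDR p outside [0, 1]")
  }
  out <- integer(n)
  e <- which(enriched)
  p <- fdr_p[e]
  out[e] <- ifelse(p <= 1e-6, 3L,
            ifelse(p <= 1e-5, 2L,
            ifelse(p <= 1e-4, 1L,
            ifelse(p < 4e-4 & extended, 1L, 0L))))
  out
}

#' Pathway scores for two enrichment result lists
#'
#' Builds, over the union of pathways passing the FDR screen in at least
#' one list, the per-set pathway score `P = n_genes_in_pathway x sig`.
#' A pathway absent from (or unenriched in) one list gets `n_genes = 0`,
#' `sig = 0` and hence `P = 0` in that set.
#'
#' @param enrich_dmg,enrich_deg `data.frame`s as returned by
#'   [hypergeom_enrichment()] (columns `pathway_id`, `n_genes_in_set`,
#'   `fdr_p`).
#' @param fdr_threshold Screening threshold (default 4e-4).
#' @param extended Passed to [sig_value()].
#' @return `data.frame` of class `pathway_score_pair`: per pathway
#'   `n_genes_dmg`, `n_genes_deg`, `fdr_dmg`, `fdr_deg`, `sig_dmg`,
#'   `sig_deg`, `p_dmg`, `p_deg`.
#' @export
pathway_scores <- function(enrich_dmg, enrich_deg, fdr_threshold = 4e-4,
                           extended = TRUE) {
  screen <- function(e) e[e$fdr_p < fdr_threshold, , drop = FALSE]
  a <- screen(enrich_dmg)
  b <- screen(enrich_deg)
  ids <- union(a$pathway_id, b$pathway_id)
  pull <- function(e, ids, col, default) {
    v <- e[[col]][match(ids, e$pathway_id)]
    v[is.na(v)] <- default
    v
  }
  n_dmg <- pull(a, ids, "n_genes_in_set", 0L)
  n_deg <- pull(b, ids, "n_genes_in_set", 0L)
  f_dmg <- pull(a, ids, "fdr_p", NA_real_)
  f_deg <- pull(b, ids, "fdr_p", NA_real_)
  sig_dmg <- ifelse(is.na(f_dmg), 0L,
                    sig_value(ifelse(is.na(f_dmg), 1, f_dmg),
                              enriched = !is.na(f_dmg),
                              extended = extended))
  sig_deg <- ifelse(is.na(f_deg), 0L,
                    sig_value(ifelse(is.na(f_deg), 1, f_deg),
                              enriched = !is.na(f_deg),
                              extended = extended))
  out <- data.frame(pathway_id = ids,
                    n_genes_dmg = n_dmg, n_genes_deg = n_deg,
                    fdr_dmg = f_dmg, fdr_deg = f_deg,
                    sig_dmg = sig_dmg, sig_deg = sig_deg,
                    p_dmg = n_dmg * sig_dmg, p_deg = n_deg * sig_deg,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pathway_score_pair", "data.frame")
  out
}

#' Lin's concordance correlation coefficient with bootstrap CI
#'
#' Point estimate
#' `rho_cc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`
#' (sample moments, n - 1 denominators) with a nonparametric bootstrap
#' percentile 95% confidence interval.
#'
#' @param x,y Paired numeric vectors (length >= 3).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @return A list with `ccc`, `ci_lo`, `ci_hi`.
#' @export
lin_ccc <- function(x, y, n_boot = 2000, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  point <- function(x, y) {
    2 * stats::cov(x, y) /
      (stats::var(x) + stats::var(y) + (mean(x) - mean(y))^2)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero variance in both vectors; CCC undefined")
  }
  ccc <- point(x, y)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(length(x), replace = TRUE)
    if (stats::var(x[idx]) == 0 && stats::var(y[idx]) == 0) return(NA_real_)
    point(x[idx], y[idx])
  }, 0)
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(ccc = ccc, ci_lo = ci[1], ci_hi = ci[2])
}

# Kendall's W from an items x raters rank-ready matrix, with tie correction
kendall_w_stat <- function(ratings) {
  n <- nrow(ratings)
  m <- ncol(ratings)
  ranks <- apply(ratings, 2, rank)
  tie_term <- sum(apply(ranks, 2, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  r_sum <- rowSums(ranks)
  s <- sum((r_sum - mean(r_sum))^2)
  denom <- m^2 * (n^3 - n) - m * tie_term
  if (denom <= 0) stop("all ratings tied; W undefined")
  12 * s / denom
}

#' Kendall's coefficient of concordance with a permutation test
#'
#' `W = 12 S / (m^2 (n^3 - n) - m T)` over `n` items rated by `m` raters,
#' with `S` the sum of squared deviations of item rank sums and `T` the
#' tie correction. The p-value permutes each rater's ranks independently
#' `n_perm` times.
#'
#' @param rating_matrix Numeric matrix, items x raters (m >= 2 columns).
#' @param n_perm Permutations (default 999).
#' @param seed Integer seed.
#' @return A list with `w` and `p`.
#' @export
kendall_w <- function(rating_matrix, n_perm = 999, seed = 1L) {
  ratings <- as.matrix(rating_matrix)
  stopifnot(ncol(ratings) >= 2, nrow(ratings) >= 3)
  w <- kendall_w_stat(ratings)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    perm <- apply(ratings, 2, sample)
    if (kendall_w_stat(perm) >= w) exceed <- exceed + 1L
  }
  list(w = w, p = (exceed + 1) / (n_perm + 1))
}

#' Bland-Altman agreement summary
#'
#' Per-item means and differences of two paired measurements, with
#' agreement limits at `mean(diff) +/- 2 sd(diff)` (n - 1 denominator) and
#' the fraction of points within the limits.
#'
#' @param x,y Paired numeric vectors (length >= 3).
#' @return A list with `points` (`data.frame` of `mean`, `diff`),
#'   `mean_diff`, `lower`, `upper`, `fraction_within`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  d <- x - y
  md <- mean(d)
  s <- stats::sd(d)
  lower <- md - 2 * s
  upper <- md + 2 * s
  list(points = data.frame(mean = (x + y) / 2, diff = d),
       mean_diff = md, lower = lower, upper = upper,
       fraction_within = mean(d >= lower & d <= upper))
}

#' Overlap fraction of two enriched-pathway id sets
#'
#' Jaccard fraction `|A intersect B| / |A union B|`, optionally after
#' filtering each set to pathways with at least `min_genes` genes.
#'
#' @param enriched_ids_a,enriched_ids_b Character vectors of pathway ids,
#'   or `data.frame`s with `pathway_id` and `n_genes_in_set`.
#' @param min_genes Minimum gene count filter applied to `data.frame`
#'   inputs (default 7).
#' @return The overlap fraction in \[0, 1\].
#' @export
overlap_fraction <- function(enriched_ids_a, enriched_ids_b,
                             min_genes = 7) {
  ids <- function(x) {
    if (is.data.frame(x)) {
      x$pathway_id[x$n_genes_in_set >= min_genes]
    } else unique(x)
  }
  a <- ids(enriched_ids_a)
  b <- ids(enriched_ids_b)
  if (!length(a) && !length(b)) stop("both pathway sets are empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Full concordance report between two pathway enrichments
#'
#' Convenience wrapper producing every concordance statistic from a
#' [pathway_scores()] table: Lin's CCC with bootstrap CI, Kendall's W with
#' permutation p, the OLS agreement regression of `p_deg` on `p_dmg`
#' restricted to pathways with both scores positive, Bland-Altman limits,
#' and the overlap fraction of the two enriched sets.
#'
#' @param scores A `pathway_score_pair`.
#' @param n_boot,n_perm,seed Resampling controls.
#' @return A list of class `concordance_report`.
#' @export
concordance_report <- function(scores, n_boot = 2000, n_perm = 999,
                               seed = 1L) {
  stopifnot(inherits(scores, "pathway_score_pair"))
  ccc <- lin_ccc(scores$p_dmg, scores$p_deg, n_boot = n_boot, seed = seed)
  kw <- kendall_w(cbind(scores$p_dmg, scores$p_deg), n_perm = n_perm,
                  seed = seed)
  both <- scores$p_dmg > 0 & scores$p_deg > 0
  fit <- if (sum(both) >= 3) {
    stats::coef(stats::lm(p_deg ~ p_dmg, data = scores[both, ]))
  } else c(`(Intercept)` = NA_real_, p_dmg = NA_real_)
  ba <- bland_altman(scores$p_dmg, scores$p_deg)
  ovl <- overlap_fraction(scores$pathway_id[scores$p_dmg > 0],
                          scores$pathway_id[scores$p_deg > 0])
  structure(list(ccc = ccc$ccc, ccc_ci = c(ccc$ci_lo, ccc$ci_hi),
                 kendall_w = kw$w, kendall_p = kw$p,
                 slope = unname(fit[2]), intercept = unname(fit[1]),
                 bland_altman = ba, overlap_fraction = ovl),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(paste0("<concordance_report> CCC %.3f [%.3f, %.3f], ",
                     "W %.3f (p %.3g), slope %.3f, overlap %.2f\n"),
              x$ccc, x$ccc_ci[1], x$ccc_ci[2], x$kendall_w, x$kendall_p,
              x$slope, x$overlap_fraction))
  invisible(x)
}
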