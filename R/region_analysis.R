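# GLM group comparison of DMP counts on genomic regions (DMGs on
# gene bodies, DMERs on enhancers), per-kb density metrics, enhancer
# spanning across tissues, and minimum-overlap filters.

# 0-based half-open regions -> 1-based closed IRanges
regions_to_iranges <- function(regions) {
  IRanges::IRanges(start = regions$start + 1L, end = regions$end)
}

#' Count DMPs per region per individual
#'
#' Counts, for each region and individual, the DMPs (both directions
#' pooled) whose position falls inside `[start, end)`.
#'
#' @param dmp_set A `dmp_set` from [call_dmps()].
#' @param regions A `region_set`.
#' @return A list of class `region_count_matrix` with `counts`
#'   (regions x individuals matrix), `lengths` (bp), `groups` (per
#'   individual), `regions`.
#' @export
count_dmps_per_region <- function(dmp_set, regions) {
  stopifnot(inherits(dmp_set, "dmp_set"), inherits(regions, "region_set"))
  ids <- dmp_set$individuals$sample_id
  counts <- matrix(0L, nrow(regions), length(ids),
                   dimnames = list(regions$name, ids))
  sites <- dmp_set$sites
  for (chrom in unique(regions$chrom)) {
    rsel <- regions$chrom == chrom
    ir_regions <- regions_to_iranges(regions[rsel, , drop = FALSE])
    for (j in seq_along(ids)) {
      s <- sites[sites$sample_id == ids[j] & sites$chrom == chrom, ,
                 drop = FALSE]
      if (!nrow(s)) next
      ir_sites <- IRanges::IRanges(start = s$pos + 1L, width = 1L)
      counts[rsel, j] <- IRanges::countOverlaps(ir_regions, ir_sites)
    }
  }
  structure(list(counts = counts,
                 lengths = stats::setNames(regions$end - regions$start,
                                           regions$name),
                 groups = stats::setNames(dmp_set$individuals$group, ids),
                 regions = regions),
            class = "region_count_matrix")
}

# Method-of-moments NB size estimate, used as glm.nb fallback
mom_theta <- function(y) {
  m <- mean(y)
  v <- stats::var(y)
  if (!is.finite(v) || v <= m) return(1e6)  # near-Poisson
  max(m^2 / (v - m), 1e-3)
}

#' GLM group test of region DMP counts
#'
#' Regions passing the minimum-count filter (every individual of at least
#' one group has `>= min_count` DMPs) are tested with
#' `count ~ group + offset(log(length / 1000))` under the chosen family
#' (log link); the p-value is a likelihood-ratio test of the group term,
#' BH-adjusted across tested regions. A region is differentially
#' methylated (`is_dm`) when `p_adj <= alpha` and `|log2fc| > lfc_cut`.
#' `log2fc` is the log2 ratio of group mean counts with a 0.5 pseudo-count;
#' `density_variation` is the group mean difference of DMPs per kb.
#'
#' @param rcm A `region_count_matrix`, or a plain counts matrix (then
#'   `groups` and `lengths` must be given).
#' @param family `"negbinom"` (default), `"poisson"` or `"quasipoisson"`.
#' @param min_count Minimum DMP count per individual (default 8).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param lfc_cut |log2 fold change| cutoff (default 1).
#' @param groups,lengths Used when `rcm` is a plain matrix.
#' @return `data.frame` of class `region_test_result`: one row per tested
#'   region with `log2fc_dmp`, `p_lrt`, `p_adj`, `is_dm`,
#'   `density_variation`, `converged`.
#' @export
glm_count_test <- function(rcm, family = c("negbinom", "poisson",
                                           "quasipoisson"),
                           min_count = 8, alpha = 0.05, lfc_cut = 1,
                           groups = NULL, lengths = NULL) {
  family <- match.arg(family)
  if (inherits(rcm, "region_count_matrix")) {
    counts <- rcm$counts
    groups <- rcm$groups
    lengths <- rcm$lengths
  } else {
    counts <- rcm
    stopifnot(!is.null(groups), !is.null(lengths))
  }
  groups <- factor(groups, levels = c("control", "treatment"))
  stopifnot(ncol(counts) == length(groups))
  if (any(table(groups) < 2)) stop("need >= 2 individuals per group")

  ctl <- groups == "control"
  trt <- groups == "treatment"
  keep <- apply(counts, 1, function(y) {
    all(y[ctl] >= min_count) || all(y[trt] >= min_count)
  })
  tested <- which(keep)
  len_kb <- lengths[rownames(counts)] / 1000

  res <- lapply(tested, function(i) {
    y <- counts[i, ]
    off <- rep(log(len_kb[i]), length(y))
    p <- NA_real_
    converged <- TRUE
    if (family == "poisson") {
      full <- stats::glm(y ~ groups + offset(off), family = stats::poisson())
      null <- stats::glm(y ~ 1 + offset(off), family = stats::poisson())
      p <- stats::pchisq(null$deviance - full$deviance, df = 1,
                         lower.tail = FALSE)
      converged <- full$converged && null$converged
    } else if (family == "quasipoisson") {
      full <- stats::glm(y ~ groups + offset(off),
                         family = stats::quasipoisson())
      an <- stats::anova(full, test = "F")
      p <- an[["Pr(>F)"]][2]
      converged <- full$converged
    } else {
      # dispersion estimated under the null model (intercept + offset):
      # estimating theta under the alternative makes the chi-square LRT
      # badly anticonservative at n ~ 7 (type-I ~0.13 at nominal 0.05)
      theta <- tryCatch({
        fit <- suppressWarnings(
          MASS::glm.nb(y ~ 1 + offset(off),
                       control = stats::glm.control(maxit = 50)))
        fit$theta
      }, error = function(e) mom_theta(y))
      fam <- MASS::negative.binomial(theta)
      full <- tryCatch(
        suppressWarnings(stats::glm(y ~ groups + offset(off), family = fam)),
        error = function(e) NULL)
      null <- tryCatch(
        suppressWarnings(stats::glm(y ~ 1 + offset(off), family = fam)),
        error = function(e) NULL)
      if (is.null(full) || is.null(null)) {
        converged <- FALSE
      } else {
        p <- stats::pchisq(null$deviance - full$deviance, df = 1,
                           lower.tail = FALSE)
        converged <- full$converged && null$converged
      }
    }
    m_c <- mean(y[ctl])
    m_t <- mean(y[trt])
    data.frame(
      name = rownames(counts)[i],
      log2fc_dmp = log2((m_t + 0.5) / (m_c + 0.5)),
      p_lrt = p,
      density_variation = abs(m_t - m_c) / len_kb[i],
      converged = converged,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(name = character(), log2fc_dmp = numeric(),
                      p_lrt = numeric(), density_variation = numeric(),
                      converged = logical())
  }
  out$p_adj <- NA_real_
  ok <- out$converged & is.finite(out$p_lrt)
  out$p_adj[ok] <- stats::p.adjust(out$p_lrt[ok], method = "BH")
  out$is_dm <- !is.na(out$p_adj) & out$p_adj <= alpha &
    abs(out$log2fc_dmp) > lfc_cut
  rownames(out) <- NULL
  class(out) <- c("region_test_result", "data.frame")
  out
}

#' Span enhancers across tissue-specific intervals
#'
#' For each enhancer id, returns the maximum region
#' `[min(start), max(end))` spanning all reported per-tissue intervals.
#'
#' @param per_tissue_intervals `data.frame` with columns `name` (enhancer
#'   id), `chrom`, `start`, `end`.
#' @return A `region_set` of kind `"enhancer"`, one row per enhancer.
#' @export
span_enhancers <- function(per_tissue_intervals) {
  x <- per_tissue_intervals
  if (!nrow(x)) stop("no intervals to span")
  stopifnot(all(c("name", "chrom", "start", "end") %in% names(x)))
  sp <- lapply(split(x, x$name), function(g) {
    if (length(unique(g$chrom)) != 1) {
      stop("enhancer ", g$name[1], " spans multiple chromosomes")
    }
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               name = g$name[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, sp)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  region_set(out, kind = "enhancer")
}

#' Minimum-overlap filter between two region sets
#'
#' Returns all pairs (a, b) whose intervals intersect by at least
#' `min_overlap_bp` base pairs.
#'
#' @param set_a,set_b `region_set`s.
#' @param min_overlap_bp Minimum intersection length (default 500).
#' @return `data.frame` with `name_a`, `name_b`, `overlap_bp`.
#' @export
overlap_filter <- function(set_a, set_b, min_overlap_bp = 500) {
  out <- list()
  for (chrom in intersect(unique(set_a$chrom), unique(set_b$chrom))) {
    a <- set_a[set_a$chrom == chrom, , drop = FALSE]
    b <- set_b[set_b$chrom == chrom, , drop = FALSE]
    hits <- IRanges::findOverlaps(regions_to_iranges(a),
                                  regions_to_iranges(b),
                                  minoverlap = min_overlap_bp)
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
    out[[chrom]] <- data.frame(name_a = a$name[qi], name_b = b$name[si],
                               overlap_bp = ov, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(name_a = character(), name_b = character(),
                      overlap_bp = integer())
  }
  rownames(res) <- NULL
  res
}

#' Per-kb signal density of a metric over regions, by group
#'
#' The density of a variable X over a region is the sum of X at the
#' region's sites divided by the region length and multiplied by 1000.
#' The group density is the mean over the group's individuals; the
#' between-group difference is reported as an absolute value.
#'
#' @param divergences Combined per-individual [site_divergence()] rows
#'   (with `group` filled), e.g. `dmp_set$divergences` or `dmp_set$sites`.
#' @param regions A `region_set`.
#' @param metric One of `"p"` (sample methylation level), `"tv"`, `"tvb"`,
#'   `"hd"`; the absolute value of the metric is summed.
#' @return `data.frame` with one row per region: `density_control`,
#'   `density_treatment`, `delta_density`.
#' @export
region_density <- function(divergences, regions,
                           metric = c("hd", "p", "tv", "tvb")) {
  metric <- match.arg(metric)
  col <- switch(metric, p = "p_sample", tv = "tv", tvb = "tvb", hd = "hd")
  d <- divergences
  val <- abs(d[[col]])
  lens <- stats::setNames(regions$end - regions$start, regions$name)
  dens <- matrix(0, nrow(regions), 2,
                 dimnames = list(regions$name, c("control", "treatment")))
  for (g in c("control", "treatment")) {
    dg <- d[d$group == g, , drop = FALSE]
    vg <- val[d$group == g]
    ids <- unique(dg$sample_id)
    if (!length(ids)) next
    per_ind <- matrix(0, nrow(regions), length(ids),
                      dimnames = list(regions$name, ids))
    for (chrom in unique(regions$chrom)) {
      rsel <- regions$chrom == chrom
      ir_regions <- regions_to_iranges(regions[rsel, , drop = FALSE])
      csel <- dg$chrom == chrom
      for (id in ids) {
        sel <- csel & dg$sample_id == id
        if (!any(sel)) next
        ir_sites <- IRanges::IRanges(start = dg$pos[sel] + 1L, width = 1L)
        hits <- IRanges::findOverlaps(ir_regions, ir_sites)
        sums <- rowsum(vg[sel][S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
        rows <- which(rsel)[as.integer(rownames(sums))]
        per_ind[rows, id] <- sums[, 1]
      }
    }
    dens[, g] <- rowMeans(per_ind / lens[rownames(per_ind)] * 1000)
  }
  data.frame(name = regions$name,
             density_control = dens[, "control"],
             density_treatment = dens[, "treatment"],
             delta_density = abs(dens[, "control"] - dens[, "treatment"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Individuals-by-regions signal density matrix
#'
#' Builds the matrix used by the PCA scoring and the Ward signal
#' clustering: rows are individuals (control and treatment), columns are
#' regions, cells are the per-kb density of the chosen metric over the
#' individual's DMPs in the region.
#'
#' @param dmp_set A `dmp_set`.
#' @param regions A `region_set`.
#' @param metric As in [region_density()].
#' @param sites Which site rows to aggregate: `"dmps"` (default; the
#'   classified DMPs) or `"all"` (every site).
#' @return Numeric matrix individuals x regions, with a `groups` attribute.
#' @export
signal_density_matrix <- function(dmp_set, regions,
                                  metric = c("hd", "p", "tv", "tvb"),
                                  sites = c("dmps", "all")) {
  metric <- match.arg(metric)
  sites <- match.arg(sites)
  col <- switch(metric, p = "p_sample", tv = "tv", tvb = "tvb", hd = "hd")
  d <- if (sites == "dmps") dmp_set$sites else dmp_set$divergences
  ids <- dmp_set$individuals$sample_id
  lens <- stats::setNames(regions$end - regions$start, regions$name)
  m <- matrix(0, length(ids), nrow(regions),
              dimnames = list(ids, regions$name))
  for (chrom in unique(regions$chrom)) {
    rsel <- regions$chrom == chrom
    ir_regions <- regions_to_iranges(regions[rsel, , drop = FALSE])
    csel <- d$chrom == chrom
    for (id in ids) {
      sel <- csel & d$sample_id == id
      if (!any(sel)) next
      ir_sites <- IRanges::IRanges(start = d$pos[sel] + 1L, width = 1L)
      hits <- IRanges::findOverlaps(ir_regions, ir_sites)
      sums <- rowsum(abs(d[[col]][sel])[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
      cols <- which(rsel)[as.integer(rownames(sums))]
      m[id, cols] <- sums[, 1]
    }
  }
  m <- sweep(m, 2, lens[colnames(m)] / 1000, "/")
  attr(m, "groups") <- stats::setNames(dmp_set$individuals$group, ids)
  m
}
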