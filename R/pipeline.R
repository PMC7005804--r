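# End-to-end orchestration: simulate -> dmp -> dmg/dmer -> network ->
# concordance -> dependence -> pcscore, with one config, one seed, and a
# machine-readable manifest per run. Stage outputs are pure functions of
# (inputs, parameters, seed); re-running with an identical config
# reproduces identical files.

#' Pipeline configuration
#'
#' Aggregates all stage thresholds with defaults equal to the analysis's
#' stated operating point: Fisher/GLM alpha 0.05, minimum 8 DMPs per
#' individual, |log2FC| > 1, enrichment FDR screen 4e-4, >= 500 bp
#' DMER/gene overlap, PPI score thresholds 0.4 (build) and 0.7 (cluster
#' mapping) with minimum degree 3, k = 3 hub clusters.
#'
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @param alpha Significance level for the DMP Fisher filter and the
#'   region GLM.
#' @param min_count Minimum DMP count per individual for region testing.
#' @param lfc_cut Region |log2FC| cutoff.
#' @param glm_family Count-model family for the region tests.
#' @param enrich_fdr FDR screen for scored pathways.
#' @param min_overlap_bp DMER-gene overlap threshold.
#' @param score_build,score_map PPI combined-score thresholds.
#' @param map_min_degree Minimum degree in cluster-to-network mapping.
#' @param k Hub cluster count.
#' @param n_boot,n_perm,n_random Resampling sizes.
#' @param seed Integer master seed (also overrides `sim$seed`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), alpha = 0.05,
                            min_count = 8, lfc_cut = 1,
                            glm_family = "negbinom",
                            enrich_fdr = 4e-4, min_overlap_bp = 500,
                            score_build = 0.4, score_map = 0.7,
                            map_min_degree = 3, k = 3,
                            n_boot = 100, n_perm = 999, n_random = 200,
                            seed = 101L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  cfg$sim$seed <- cfg$seed
  class(cfg) <- "pipeline_config"
  cfg
}

write_manifest <- function(dir, stage, params, files) {
  files <- files[file.exists(files)]
  cks <- tools::md5sum(files)
  names(cks) <- basename(files)
  manifest <- list(stage = stage, params = params,
                   checksums = as.list(cks))
  jsonlite::write_json(manifest,
                       file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full pipeline on a synthetic dataset
#'
#' Executes every stage in dependency order, writing each stage's outputs
#' and a manifest (parameters plus md5 checksums) under `out_dir`. When
#' `with_expression = FALSE` the concordance and dependence stages are
#' skipped with explicit messages.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param with_expression Couple in the expression table? Default `TRUE`.
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_all <- function(config = pipeline_config(), out_dir,
                    with_expression = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)

  # -- simulate -------------------------------------------------------
  ds <- simulate_dataset(config$sim)
  res$dataset <- ds
  for (s in ds$samples) {
    write_methylation_table(s, file.path(out_dir,
                                         paste0("meth_", s$sample_id,
                                                ".tsv")))
  }
  write_bed(ds$regions, file.path(out_dir, "regions.bed"))
  write_gmt(ds$pathways, file.path(out_dir, "pathways.gmt"))
  write_ppi_table(ds$ppi, file.path(out_dir, "ppi.tsv"))
  utils::write.csv(ds$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(ds$expression),
                   file.path(out_dir, "expression.csv"), row.names = FALSE)
  message(sprintf("[simulate] %d samples, %d regions, %d PPI edges",
                  length(ds$samples), nrow(ds$regions), nrow(ds$ppi)))
  write_manifest(out_dir, "simulate", list(seed = config$seed),
                 list.files(out_dir, full.names = TRUE))

  # -- dmp ------------------------------------------------------------
  groups <- vapply(ds$samples, function(s) s$group, "")
  ref <- ds$samples[groups == "reference"]
  cmp <- ds$samples[groups != "reference"]
  dmps <- call_dmps(cmp, ref, alpha = config$alpha)
  res$dmps <- dmps
  utils::write.table(dmps$sites, file.path(out_dir, "dmps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in c("control", "treatment")) {
    track <- group_level_diff(dmps$divergences, g)
    write_wig(paste0("mean_level_diff_", g), track,
              file.path(out_dir, paste0("diff_", g, ".wig")))
  }
  message(sprintf("[dmp] %d sites -> %d candidates -> %d DMPs (cutoff %.3g)",
                  nrow(dmps$divergences),
                  sum(dmps$divergences$p_adj <= config$alpha),
                  nrow(dmps$sites), dmps$cutoff))
  write_manifest(out_dir, "dmp",
                 list(alpha = config$alpha, cutoff = dmps$cutoff),
                 file.path(out_dir, c("dmps.tsv", "diff_control.wig",
                                      "diff_treatment.wig")))

  # -- dmg / dmer -----------------------------------------------------
  region_stage <- function(kind, label) {
    regs <- ds$regions[ds$regions$kind == kind, , drop = FALSE]
    class(regs) <- class(ds$regions)
    rcm <- count_dmps_per_region(dmps, regs)
    tst <- glm_count_test(rcm, family = config$glm_family,
                          min_count = config$min_count,
                          alpha = config$alpha, lfc_cut = config$lfc_cut)
    utils::write.csv(tst, file.path(out_dir, paste0(label, ".csv")),
                     row.names = FALSE)
    dm <- regs[regs$name %in% tst$name[tst$is_dm], , drop = FALSE]
    class(dm) <- class(regs)
    if (nrow(dm)) write_bed(dm, file.path(out_dir, paste0(label, ".bed")))
    message(sprintf("[%s] %d regions -> %d tested -> %d differentially methylated",
                    label, nrow(regs), nrow(tst), sum(tst$is_dm)))
    list(regions = regs, counts = rcm, test = tst, dm = dm)
  }
  dmg <- region_stage("gene", "dmg")
  dmer <- region_stage("enhancer", "dmer")
  res$dmg <- dmg
  res$dmer <- dmer

  deg_genes <- ds$expression$gene[ds$expression$deg_flag]
  dmg_genes <- dmg$test$name[dmg$test$is_dm]
  deg_dmg <- intersect(deg_genes, dmg_genes)
  if (nrow(dmer$dm) && length(deg_dmg)) {
    dd_regions <- ds$regions[ds$regions$name %in% deg_dmg, , drop = FALSE]
    class(dd_regions) <- class(ds$regions)
    ovl <- overlap_filter(dmer$dm, dd_regions,
                          min_overlap_bp = config$min_overlap_bp)
    utils::write.csv(ovl, file.path(out_dir, "dmer_degdmg_overlap.csv"),
                     row.names = FALSE)
    res$dmer_overlap <- ovl
  }
  write_manifest(out_dir, "regions",
                 list(family = config$glm_family,
                      min_count = config$min_count),
                 file.path(out_dir, c("dmg.csv", "dmer.csv")))

  # -- network --------------------------------------------------------
  g <- build_graph(ds$ppi, score_threshold = config$score_build)
  ct <- centralities(g)
  utils::write.csv(ct, file.path(out_dir, "centralities.csv"),
                   row.names = FALSE)
  hc <- kmeans_hub_clusters(ct, k = config$k, seed = config$seed,
                            n_boot = config$n_boot)
  utils::write.csv(data.frame(gene = names(hc$labels),
                              cluster = hc$labels),
                   file.path(out_dir, "hub_clusters.csv"),
                   row.names = FALSE)
  background <- sprintf("gene_%03d", seq_len(config$sim$n_genes))
  enr_dmg <- hypergeom_enrichment(dmg_genes, ds$pathways, background)
  utils::write.csv(enr_dmg, file.path(out_dir, "enrichment_dmg.csv"),
                   row.names = FALSE)
  res$network <- list(graph = g, centralities = ct, clusters = hc,
                      enrich_dmg = enr_dmg)
  message(sprintf("[network] %d nodes, %d edges; hub cluster Jaccard %s",
                  igraph::vcount(g), igraph::ecount(g),
                  paste(sprintf("%.2f", hc$jaccard_mean), collapse = "/")))
  write_manifest(out_dir, "network",
                 list(score = config$score_build, k = config$k),
                 file.path(out_dir, c("centralities.csv",
                                      "hub_clusters.csv",
                                      "enrichment_dmg.csv")))

  if (!with_expression) {
    message("[concordance] skipped: no expression input")
    message("[dependence] skipped: no expression input")
  } else {
    # -- concordance --------------------------------------------------
    enr_deg <- hypergeom_enrichment(deg_genes, ds$pathways, background)
    utils::write.csv(enr_deg, file.path(out_dir, "enrichment_deg.csv"),
                     row.names = FALSE)
    sc <- pathway_scores(enr_dmg, enr_deg,
                         fdr_threshold = config$enrich_fdr)
    res$scores <- sc
    if (nrow(sc) >= 3 && (any(sc$p_dmg > 0) || any(sc$p_deg > 0))) {
      rep <- concordance_report(sc, n_boot = config$n_boot,
                                n_perm = config$n_perm,
                                seed = config$seed)
      res$concordance <- rep
      jsonlite::write_json(
        list(ccc = rep$ccc, ccc_ci = rep$ccc_ci, kendall_w = rep$kendall_w,
             kendall_p = rep$kendall_p, slope = rep$slope,
             overlap_fraction = rep$overlap_fraction),
        file.path(out_dir, "concordance.json"), auto_unbox = TRUE,
        digits = NA)
      message(sprintf("[concordance] %d scored pathways, CCC %.2f, W %.2f",
                      nrow(sc), rep$ccc, rep$kendall_w))
    } else {
      message("[concordance] skipped: too few scored pathways")
    }

    # -- dependence ---------------------------------------------------
    gene_regs <- ds$regions[ds$regions$kind == "gene", , drop = FALSE]
    class(gene_regs) <- class(ds$regions)
    merged_genes <- if (length(deg_dmg) >= 10) deg_dmg else dmg_genes
    if (length(merged_genes) >= 10) {
      sel <- gene_regs[gene_regs$name %in% merged_genes, , drop = FALSE]
      class(sel) <- class(gene_regs)
      dep <- lapply(c(p = "p", tv = "tv", tvb = "tvb", hd = "hd"),
                    function(metric) {
        dens <- region_density(dmps$divergences, sel, metric = metric)
        lfc <- abs(ds$expression$log2fc[match(dens$name,
                                              ds$expression$gene)])
        dependence_analysis(dens$delta_density, lfc)
      })
      res$dependence <- dep
      jsonlite::write_json(
        lapply(dep, function(d) list(rho = d$spearman$rho,
                                     rho_p = d$spearman$p,
                                     theta = d$fgm$theta,
                                     tau_implied = d$fgm$tau_implied)),
        file.path(out_dir, "dependence.json"), auto_unbox = TRUE,
        digits = NA)
      message(sprintf("[dependence] %d genes; FGM theta (hd) %.2f",
                      length(merged_genes), dep$hd$fgm$theta))
    } else {
      message("[dependence] skipped: fewer than 10 usable genes")
    }
  }

  # -- pcscore --------------------------------------------------------
  score_genes <- if (with_expression && length(deg_dmg) >= 3) deg_dmg
                 else dmg_genes
  if (length(score_genes) >= 3) {
    sel <- ds$regions[ds$regions$name %in% score_genes, , drop = FALSE]
    class(sel) <- class(ds$regions)
    sm <- signal_density_matrix(dmps, sel, metric = "hd")
    pca <- pca_signal(sm)
    keep <- retain_components(pca$eigenvalues)
    dens <- region_density(dmps$divergences, sel, metric = "hd")
    pcs <- gene_pc_scores(pca$loadings[, 1],
                          stats::setNames(dens$delta_density, dens$name))
    utils::write.csv(pcs, file.path(out_dir, "pc_scores.csv"),
                     row.names = FALSE)
    res$pc_scores <- pcs
    message(sprintf("[pcscore] %d genes; PC1 carries %.1f%% of variance",
                    ncol(sm), 100 * pca$variance_fraction[1]))
  } else {
    message("[pcscore] skipped: fewer than 3 scored genes")
  }

  write_manifest(out_dir, "run",
                 list(seed = config$seed),
                 list.files(out_dir, full.names = TRUE,
                            pattern = "\\.(csv|tsv|bed|gmt|wig|json)$"))
  invisible(res)
}
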