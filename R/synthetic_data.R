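# Seeded synthetic-data generator. The generator is first-class, tested
# code: it emulates the statistical structure the downstream analysis
# assumes (Beta-distributed baseline methylation with natural
# inter-individual variability plus rare individual epimutations, planted
# hyper/hypomethylation in designated regions, negative-binomial read
# coverage, expression changes coupled to methylation density through an
# FGM copula, a toy pathway database, and a scale-free PPI graph with
# designated hubs) so every stage has a ground-truth fixture.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with defaults matching
#' the study design the pipeline targets: 4 reference, 4 control and 3
#' patient methylomes, Beta(2, 8) baseline methylation, negative-binomial
#' read coverage with mean 30, planted hypermethylation shifts of +0.4 in a
#' fifth of the genes (with a minority of hypomethylated regions), and an
#' FGM copula coupling (theta = 0.9) between methylation density and
#' expression change.
#'
#' @param n_reference,n_control,n_patient Individuals per group (>= 2 for
#'   reference/control; patients >= 1).
#' @param n_genes,n_enhancers Number of gene-body / enhancer regions.
#' @param sites_per_region Cytosine sites per region.
#' @param site_spacing Base pairs between consecutive sites; region length
#'   is `sites_per_region * site_spacing`.
#' @param baseline_beta Length-2 shape parameters (a, b) of the Beta
#'   baseline methylation level shared across individuals.
#' @param coverage_nb Length-2 `(mean, dispersion)` of the negative-binomial
#'   read coverage; `dispersion` is the NB size parameter. Coverage is
#'   `rnbinom + 1` so every site has at least one read.
#' @param n_signal_genes Genes carrying planted differential methylation.
#' @param n_signal_enhancers Enhancers carrying planted signal.
#' @param delta Methylation-probability shift planted in patient samples
#'   inside signal regions (in (0, 1]).
#' @param hypo_fraction Fraction of signal regions planted as
#'   hypomethylated (shift -delta) rather than hypermethylated.
#' @param epsilon_sd SD of the per-individual, per-site Gaussian wobble on
#'   the baseline level (natural variability).
#' @param epimutation_rate Per-site, per-individual probability of a rare
#'   large individual shift (natural epimutation), applied in every group.
#' @param epimutation_shift Length-2 range of the absolute epimutation
#'   shift, signed at random.
#' @param copula_theta FGM dependence parameter in \[-1, 1\] coupling
#'   methylation density rank to |log2FC| rank.
#' @param ppi_m Edges added per step of preferential attachment.
#' @param ppi_power Preferential-attachment exponent.
#' @param n_hubs Designated hub count; hub identities are forced onto the
#'   top-degree nodes of the generated graph.
#' @param n_pathways,n_signal_pathways Total and hub-neighborhood pathway
#'   counts in the toy pathway database.
#' @param pathway_size Length-2 range of pathway sizes.
#' @param seed Integer seed driving all stochastic operations.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_reference = 4, n_control = 4, n_patient = 3,
                       n_genes = 200, n_enhancers = 50,
                       sites_per_region = 50, site_spacing = 50,
                       baseline_beta = c(2, 8),
                       coverage_nb = c(mean = 30, dispersion = 10),
                       n_signal_genes = 40, n_signal_enhancers = 10,
                       delta = 0.4, hypo_fraction = 0.2,
                       epsilon_sd = 0.03,
                       epimutation_rate = 0.01,
                       epimutation_shift = c(0.3, 0.5),
                       copula_theta = 0.9,
                       ppi_m = 2, ppi_power = 1, n_hubs = 8,
                       n_pathways = 40, n_signal_pathways = 10,
                       pathway_size = c(10, 30),
                       seed = 101L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_reference >= 1, cfg$n_control >= 1, cfg$n_patient >= 1,
            cfg$n_genes >= 1, cfg$sites_per_region >= 1,
            cfg$delta >= 0, cfg$delta <= 1,
            abs(cfg$copula_theta) <= 1,
            cfg$n_signal_genes <= cfg$n_genes,
            cfg$n_signal_enhancers <= cfg$n_enhancers,
            cfg$n_hubs <= cfg$n_genes)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# Region layout on a single synthetic chromosome: genes first, then
# enhancers, each `sites_per_region * site_spacing` wide with a one-region
# gap between neighbours.
sim_region_layout <- function(config) {
  width <- config$sites_per_region * config$site_spacing
  n <- config$n_genes + config$n_enhancers
  starts <- (seq_len(n) - 1L) * 2L * width
  kind <- rep(c("gene", "enhancer"), c(config$n_genes, config$n_enhancers))
  name <- c(sprintf("gene_%03d", seq_len(config$n_genes)),
            sprintf("enh_%03d", seq_len(config$n_enhancers)))
  region_set(data.frame(chrom = "chrS", start = starts,
                        end = starts + width, name = name,
                        strand = "+", kind = kind))
}

# Planted-signal assignment: which regions carry signal and in which
# direction. Deterministic given the config seed.
sim_truth <- function(config) {
  regions <- sim_region_layout(config)
  set.seed(config$seed)
  sig_genes <- sample(regions$name[regions$kind == "gene"],
                      config$n_signal_genes)
  sig_enh <- if (config$n_enhancers > 0) {
    sample(regions$name[regions$kind == "enhancer"],
           config$n_signal_enhancers)
  } else character()
  signal <- regions$name %in% c(sig_genes, sig_enh)
  n_sig <- sum(signal)
  dir <- rep("none", nrow(regions))
  hypo <- rep(FALSE, n_sig)
  if (n_sig > 0) {
    n_hypo <- round(config$hypo_fraction * n_sig)
    hypo[sample.int(n_sig, n_hypo)] <- TRUE
  }
  dir[signal] <- ifelse(hypo, "hypo", "hyper")
  data.frame(name = regions$name, kind = regions$kind, signal = signal,
             direction = dir,
             delta = ifelse(signal, config$delta, 0) *
               ifelse(dir == "hypo", -1, 1),
             stringsAsFactors = FALSE)
}

#' Simulate methylome samples with planted differential methylation
#'
#' Per site i a latent baseline level p_i ~ Beta(a, b) is shared across all
#' individuals. Each individual's methylated reads are
#' Binomial(n_total, p_i + eps) with a small Gaussian eps (natural
#' variability) plus rare large individual shifts (epimutations) in every
#' group. Patient samples get an additional +/- delta shift at sites inside
#' signal regions. All probabilities are truncated to \[0, 1\]; coverage is
#' NB(mean, dispersion) + 1.
#'
#' @param config A [sim_config()].
#' @return A list with `samples` (list of `methylome_sample`), `regions`
#'   (a `region_set` of genes and enhancers), `truth` (per-region planted
#'   signal table) and `latent` (per-region true mean patient-control level
#'   difference density used to couple expression).
#' @export
simulate_methylomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  regions <- sim_region_layout(config)
  truth <- sim_truth(config)
  set.seed(config$seed + 1L)

  width <- config$sites_per_region * config$site_spacing
  site_pos <- unlist(lapply(seq_len(nrow(regions)), function(i) {
    regions$start[i] + (seq_len(config$sites_per_region) - 1L) *
      config$site_spacing
  }))
  n_sites <- length(site_pos)
  site_region <- rep(regions$name, each = config$sites_per_region)
  site_delta <- rep(truth$delta, each = config$sites_per_region)

  p0 <- stats::rbeta(n_sites, config$baseline_beta[1], config$baseline_beta[2])

  groups <- rep(c("reference", "control", "treatment"),
                c(config$n_reference, config$n_control, config$n_patient))
  ids <- c(sprintf("ref_%d", seq_len(config$n_reference)),
           sprintf("ctl_%d", seq_len(config$n_control)),
           sprintf("pat_%d", seq_len(config$n_patient)))

  mean_p <- matrix(0, n_sites, 2,
                   dimnames = list(NULL, c("control", "treatment")))
  samples <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    eps <- stats::rnorm(n_sites, 0, config$epsilon_sd)
    epi <- stats::runif(n_sites) < config$epimutation_rate
    if (any(epi)) {
      shift <- stats::runif(sum(epi), config$epimutation_shift[1],
                            config$epimutation_shift[2]) *
        sample(c(-1, 1), sum(epi), replace = TRUE)
      eps[epi] <- eps[epi] + shift
    }
    p <- p0 + eps
    if (groups[j] == "treatment") p <- p + site_delta
    p <- pmin(pmax(p, 0), 1)
    n_total <- stats::rnbinom(n_sites, size = config$coverage_nb[[2]],
                              mu = config$coverage_nb[[1]]) + 1L
    n_meth <- stats::rbinom(n_sites, n_total, p)
    if (groups[j] %in% c("control", "treatment")) {
      g <- if (groups[j] == "control") "control" else "treatment"
      mean_p[, g] <- mean_p[, g] + p
    }
    samples[[j]] <- methylome_sample(
      ids[j], groups[j],
      data.frame(chrom = "chrS", pos = site_pos, strand = "+",
                 context = "CpG", n_meth = n_meth, n_total = n_total,
                 stringsAsFactors = FALSE))
  }
  mean_p[, "control"] <- mean_p[, "control"] / config$n_control
  mean_p[, "treatment"] <- mean_p[, "treatment"] / config$n_patient

  dp <- abs(mean_p[, "treatment"] - mean_p[, "control"])
  latent <- vapply(split(dp, site_region), sum, 0)[regions$name] /
    width * 1000
  list(samples = samples, regions = regions, truth = truth,
       latent = data.frame(name = regions$name, kind = regions$kind,
                           density = unname(latent),
                           stringsAsFactors = FALSE))
}

#' Sample from the Farlie-Gumbel-Morgenstern copula
#'
#' Conditional-inverse sampling: U ~ Uniform(0,1) and V solves
#' `F(v | u) = v + theta (1 - 2u) v (1 - v) = w` for W ~ Uniform(0,1); the
#' conditional quantile has a closed form (root of a quadratic).
#'
#' @param n Sample size.
#' @param theta FGM parameter in \[-1, 1\].
#' @return An `n x 2` matrix of (u, v) pairs with uniform marginals and
#'   Kendall tau `2 theta / 9`.
#' @export
rfgm <- function(n, theta) {
  stopifnot(abs(theta) <= 1)
  u <- stats::runif(n)
  w <- stats::runif(n)
  a <- theta * (1 - 2 * u)
  v <- ifelse(abs(a) < 1e-12, w,
              (1 + a - sqrt((1 + a)^2 - 4 * a * w)) / (2 * a))
  cbind(u = u, v = pmin(pmax(v, 0), 1))
}

#' Simulate a differential-expression table coupled to methylation density
#'
#' Per-gene |log2FC| is drawn so that the ranks of (methylation density,
#' |log2FC|) follow an FGM copula with the configured theta; fold-change
#' magnitudes are Gamma(2, scale = 0.8)-distributed. Genes are flagged as
#' differentially expressed with probability increasing in the copula rank
#' of their methylation density for planted signal genes, and at a low base
#' rate otherwise; p-values are drawn consistently with the flag.
#'
#' @param config A [sim_config()].
#' @param methylation_density_per_gene Named numeric vector of per-gene
#'   methylation change density (any monotone proxy works; only ranks are
#'   used).
#' @return An `expression_table` with a `true_deg` attribute.
#' @export
simulate_expression <- function(config, methylation_density_per_gene) {
  stopifnot(inherits(config, "sim_config"))
  d <- methylation_density_per_gene
  stopifnot(!is.null(names(d)), length(d) >= 4)
  set.seed(config$seed + 2L)
  n <- length(d)
  u <- rank(d, ties.method = "average") / (n + 1)
  # FGM conditional sample of the |log2FC| rank given the density rank
  w <- stats::runif(n)
  a <- config$copula_theta * (1 - 2 * u)
  v <- ifelse(abs(a) < 1e-12, w,
              (1 + a - sqrt((1 + a)^2 - 4 * a * w)) / (2 * a))
  abs_lfc <- stats::qgamma(pmin(pmax(v, 1e-9), 1 - 1e-9),
                           shape = 2, scale = 0.8)
  sign <- sample(c(-1, 1), n, replace = TRUE)
  truth <- sim_truth(config)
  sig <- names(d) %in% truth$name[truth$signal & truth$kind == "gene"]
  p_deg <- ifelse(sig, stats::plogis(-0.5 + 4 * (u - 0.5)), 0.05)
  deg <- stats::runif(n) < p_deg
  p_value <- ifelse(deg, 10^stats::runif(n, -8, log10(0.04)),
                    stats::runif(n, 0.06, 1))
  tab <- expression_table(data.frame(
    gene = names(d), log2fc = sign * abs_lfc, p_value = p_value,
    deg_flag = deg, stringsAsFactors = FALSE))
  attr(tab, "true_deg") <- names(d)[deg]
  tab
}

#' Simulate a toy pathway database and a scale-free PPI graph
#'
#' The graph is grown by preferential attachment over the configured gene
#' universe; designated hub identities are assigned to the top-degree
#' vertices so hubs land in the top degree decile by construction. Edges
#' incident to hubs receive high combined scores (>= 0.7) so hub
#' neighbourhoods survive stringent score filtering. Signal pathways are
#' hub neighbourhoods; null pathways are uniform random gene sets.
#'
#' @param config A [sim_config()].
#' @return A list with `pathways` (a `pathway_db`), `ppi` (a
#'   `ppi_edge_table`) and `hubs` (designated hub gene names).
#' @export
simulate_pathways_and_ppi <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  genes <- sprintf("gene_%03d", seq_len(config$n_genes))
  truth <- sim_truth(config)
  sig_genes <- truth$name[truth$signal & truth$kind == "gene"]
  hubs <- sig_genes[seq_len(min(config$n_hubs, length(sig_genes)))]

  g <- igraph::sample_pa(config$n_genes, power = config$ppi_power,
                         m = config$ppi_m, directed = FALSE)
  deg_order <- order(igraph::degree(g), decreasing = TRUE)
  labels <- character(config$n_genes)
  labels[deg_order[seq_along(hubs)]] <- hubs
  labels[labels == ""] <- sample(setdiff(genes, hubs))
  igraph::V(g)$name <- labels

  el <- igraph::as_edgelist(g)
  hub_edge <- el[, 1] %in% hubs | el[, 2] %in% hubs
  score <- stats::runif(nrow(el), 0.40, 0.999)
  score[hub_edge] <- stats::runif(sum(hub_edge), 0.70, 0.999)
  ppi <- ppi_edge_table(data.frame(
    gene_a = el[, 1], gene_b = el[, 2],
    combined_score = round(score, 3),
    coexpression = round(stats::runif(nrow(el), 0.042, 0.938), 3),
    stringsAsFactors = FALSE))

  sizes <- sample(seq(config$pathway_size[1], config$pathway_size[2]),
                  config$n_pathways, replace = TRUE)
  db <- vector("list", config$n_pathways)
  names(db) <- sprintf("path_%02d", seq_len(config$n_pathways))
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  names(adj) <- labels
  for (i in seq_len(config$n_pathways)) {
    if (i <= config$n_signal_pathways) {
      # signal pathways mix the hub's PPI neighbourhood with planted
      # signal genes (two thirds of the membership), mirroring pathways
      # jointly targeted by methylation and expression changes
      hub <- hubs[(i - 1L) %% length(hubs) + 1L]
      nb <- igraph::V(g)$name[as.integer(adj[[hub]])]
      nb <- nb[seq_len(min(length(nb), max(1, sizes[i] %/% 3)))]
      core <- unique(c(hub, nb))
      n_sig <- min(length(setdiff(sig_genes, core)),
                   max(0, ceiling(2 * sizes[i] / 3) - length(core) +
                         length(intersect(core, sig_genes))))
      core <- unique(c(core, sample(setdiff(sig_genes, core), n_sig)))
      extra <- setdiff(genes, core)
      members <- c(core, sample(extra, min(length(extra),
                                           max(0, sizes[i] - length(core)))))
      desc <- sprintf("signal pathway around %s", hub)
    } else {
      members <- sample(genes, min(sizes[i], length(genes)))
      desc <- "null pathway"
    }
    db[[i]] <- list(description = desc, genes = unique(members))
  }
  class(db) <- "pathway_db"
  list(pathways = db, ppi = ppi, hubs = hubs)
}

#' Simulate a complete synthetic dataset
#'
#' Runs all three generators with one config/seed and couples the
#' expression table to the generator's latent per-gene methylation change
#' density.
#'
#' @param config A [sim_config()].
#' @return A list with `samples`, `regions`, `truth`, `latent`,
#'   `expression`, `pathways`, `ppi`, `hubs`.
#' @export
simulate_dataset <- function(config) {
  meth <- simulate_methylomes(config)
  gene_density <- with(meth$latent[meth$latent$kind == "gene", ],
                       stats::setNames(density, name))
  expr <- simulate_expression(config, gene_density)
  net <- simulate_pathways_and_ppi(config)
  c(meth, list(expression = expr, pathways = net$pathways, ppi = net$ppi,
               hubs = net$hubs))
}
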