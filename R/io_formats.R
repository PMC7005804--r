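# Readers/writers for the external formats the pipeline touches.
# All coordinates are 0-based half-open internally; WIG output is 1-based
# per the WIG standard.

GROUP_LEVELS <- c("reference", "control", "treatment")

#' Construct a methylome sample
#'
#' A methylome sample holds per-cytosine methylated/total read counts for one
#' individual, together with a group label. Sites are kept sorted by
#' (chrom, pos) and must be unique on (chrom, pos, strand).
#'
#' @param sample_id Character scalar identifying the individual.
#' @param group One of `"reference"`, `"control"`, `"treatment"`.
#' @param sites `data.frame` with columns `chrom`, `pos` (0-based integer),
#'   `strand` (`"+"`, `"-"` or `"."`), `context` (e.g. `"CpG"`), `n_meth`,
#'   `n_total`.
#' @return An object of class `methylome_sample`.
#' @export
methylome_sample <- function(sample_id, group, sites) {
  group <- match.arg(group, GROUP_LEVELS)
  stopifnot(is.data.frame(sites))
  required <- c("chrom", "pos", "strand", "context", "n_meth", "n_total")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols)) {
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  sites <- sites[required]
  sites$chrom <- as.character(sites$chrom)
  sites$strand <- as.character(sites$strand)
  sites$context <- as.character(sites$context)
  sites$pos <- as.integer(sites$pos)
  sites$n_meth <- as.integer(sites$n_meth)
  sites$n_total <- as.integer(sites$n_total)
  if (any(sites$pos < 0)) stop("site positions must be >= 0")
  if (any(sites$n_total < 1)) stop("n_total must be >= 1 at every site")
  if (any(sites$n_meth < 0)) stop("n_meth must be >= 0")
  if (any(sites$n_meth > sites$n_total)) {
    bad <- which(sites$n_meth > sites$n_total)[1]
    stop(sprintf("n_meth > n_total at site %s:%d", sites$chrom[bad],
                 sites$pos[bad]))
  }
  if (!all(sites$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  key <- paste(sites$chrom, sites$pos, sites$strand)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, strand) sites")
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sample_id = as.character(sample_id), group = group,
                 sites = sites),
            class = "methylome_sample")
}

#' @export
print.methylome_sample <- function(x, ...) {
  cat(sprintf("<methylome_sample> %s [%s], %d sites on %d chrom(s)\n",
              x$sample_id, x$group, nrow(x$sites),
              length(unique(x$sites$chrom))))
  invisible(x)
}

#' Read a methylation count table
#'
#' Expects a TSV with header columns `chrom`, `pos`, `strand`, `context`,
#' `n_meth`, `n_total`. Positions are 0-based unless the file starts with a
#' pragma line `## coordinates=1-based`, in which case they are shifted down
#' by one on input.
#'
#' @param path File path.
#' @param sample_id,group Passed to [methylome_sample()].
#' @return A `methylome_sample`.
#' @export
read_methylation_table <- function(path, sample_id, group) {
  first <- readLines(path, n = 1L)
  one_based <- grepl("^##\\s*coordinates\\s*=\\s*1-based", first)
  skip <- if (startsWith(first, "##")) 1L else 0L
  tab <- utils::read.delim(path, skip = skip, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "strand", "context", "n_meth", "n_total")
  if (!all(required %in% names(tab))) {
    stop("methylation table must have header columns: ",
         paste(required, collapse = ", "))
  }
  for (col in c("pos", "n_meth", "n_total")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    if (anyNA(v)) {
      stop(sprintf("malformed value in column '%s' at line %d of %s",
                   col, which(is.na(v))[1] + 1L + skip, path))
    }
    tab[[col]] <- v
  }
  if (any(tab$n_meth > tab$n_total)) {
    bad <- which(tab$n_meth > tab$n_total)[1]
    stop(sprintf("n_meth > n_total at line %d of %s", bad + 1L + skip, path))
  }
  if (one_based) tab$pos <- tab$pos - 1L
  methylome_sample(sample_id, group, tab)
}

#' Write a methylation count table
#'
#' Inverse of [read_methylation_table()]; always writes 0-based positions.
#'
#' @param sample A `methylome_sample`.
#' @param path Output path.
#' @export
write_methylation_table <- function(sample, path) {
  stopifnot(inherits(sample, "methylome_sample"))
  utils::write.table(sample$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a region set
#'
#' @param regions `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), and optionally `name`, `strand`, `kind`.
#' @param kind Default kind (`"gene"`, `"enhancer"` or `"other"`) for rows
#'   without one.
#' @return `data.frame` of class `region_set`.
#' @export
region_set <- function(regions, kind = "other") {
  stopifnot(is.data.frame(regions))
  kind <- match.arg(kind, c("gene", "enhancer", "other"))
  if (!all(c("chrom", "start", "end") %in% names(regions))) {
    stop("regions need columns chrom, start, end")
  }
  regions$chrom <- as.character(regions$chrom)
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (is.null(regions$name)) {
    regions$name <- sprintf("region_%d", seq_len(nrow(regions)))
  }
  if (is.null(regions$strand)) regions$strand <- "."
  if (is.null(regions$kind)) regions$kind <- kind
  if (any(regions$start >= regions$end)) {
    bad <- which(regions$start >= regions$end)[1]
    stop(sprintf("start >= end for region %s", regions$name[bad]))
  }
  for (k in unique(regions$kind)) {
    nm <- regions$name[regions$kind == k]
    if (anyDuplicated(nm)) stop("region names must be unique within kind ", k)
  }
  regions <- regions[c("chrom", "start", "end", "name", "strand", "kind")]
  rownames(regions) <- NULL
  class(regions) <- c("region_set", "data.frame")
  regions
}

#' Read a BED file into a region set
#'
#' BED3+ with 0-based half-open coordinates preserved verbatim. The name
#' column is used when present; otherwise regions are auto-named
#' `region_<i>`.
#'
#' @param path BED file path.
#' @param kind Region kind recorded for all rows.
#' @return A `region_set`.
#' @export
read_bed <- function(path, kind = "other") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3)) stop("BED line with fewer than 3 fields at line ",
                        which(nf < 3)[1])
  tab <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(tab$start) || anyNA(tab$end)) stop("non-integer BED coordinates")
  tab$name <- ifelse(nf >= 4, vapply(fields, function(f)
    if (length(f) >= 4) f[[4]] else NA_character_, ""), NA_character_)
  auto <- is.na(tab$name) | tab$name == "."
  tab$name[auto] <- sprintf("region_%d", which(auto))
  tab$strand <- vapply(fields, function(f)
    if (length(f) >= 6 && f[[6]] %in% c("+", "-")) f[[6]] else ".", "")
  region_set(tab, kind = kind)
}

#' Write a region set as BED
#'
#' @param regions A `region_set`.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  out <- data.frame(regions$chrom, regions$start, regions$end, regions$name,
                    0L, regions$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT pathway database
#'
#' Tab-separated lines: pathway id, description, then member genes.
#' Duplicate genes within a line are deduplicated.
#'
#' @param path GMT file path.
#' @return A named list of class `pathway_db`; each element has `description`
#'   and `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) stop("GMT line with fewer than 3 fields at line ",
                        which(nf < 3)[1])
  db <- lapply(fields, function(f) {
    list(description = f[[2]], genes = unique(f[-(1:2)]))
  })
  names(db) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(db))) stop("duplicate pathway ids in GMT")
  structure(db, class = "pathway_db")
}

#' Write a pathway database as GMT
#'
#' @param db A `pathway_db` (named list with `description` and `genes`).
#' @param path Output path.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db), function(id) {
    paste(c(id, db[[id]]$description, db[[id]]$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-protein interaction edge table
#'
#' TSV with header `gene_a`, `gene_b`, `combined_score`, `coexpression`.
#' Scores outside \[0, 1\] and self-loops are rejected. Duplicate unordered
#' pairs are collapsed keeping the row with maximum `combined_score`.
#'
#' @param path File path.
#' @return `data.frame` of class `ppi_edge_table`.
#' @export
read_ppi_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_a", "gene_b", "combined_score", "coexpression")
  if (!all(required %in% names(tab))) {
    stop("PPI table must have columns: ", paste(required, collapse = ", "))
  }
  ppi_edge_table(tab[required])
}

#' Construct/validate a PPI edge table
#'
#' @param tab `data.frame` with columns `gene_a`, `gene_b`,
#'   `combined_score`, `coexpression`.
#' @return Validated, deduplicated `ppi_edge_table`.
#' @export
ppi_edge_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  tab$gene_a <- as.character(tab$gene_a)
  tab$gene_b <- as.character(tab$gene_b)
  tab$combined_score <- as.numeric(tab$combined_score)
  tab$coexpression <- as.numeric(tab$coexpression)
  if (any(tab$gene_a == tab$gene_b)) {
    stop("self-loop edge: ", tab$gene_a[tab$gene_a == tab$gene_b][1])
  }
  for (col in c("combined_score", "coexpression")) {
    v <- tab[[col]]
    if (anyNA(v) || any(v < 0 | v > 1)) {
      stop(col, " outside [0, 1]")
    }
  }
  a <- pmin(tab$gene_a, tab$gene_b)
  b <- pmax(tab$gene_a, tab$gene_b)
  tab$gene_a <- a
  tab$gene_b <- b
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -tab$combined_score)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(key[ord]), , drop = FALSE]
  tab <- tab[order(tab$gene_a, tab$gene_b), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("ppi_edge_table", "data.frame")
  tab
}

#' Write a PPI edge table
#'
#' @param tab A `ppi_edge_table`.
#' @param path Output path.
#' @export
write_ppi_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' CSV/TSV (sniffed by extension; `.csv` means comma) with columns `gene`,
#' `log2fc`, `p_value` and optionally `deg_flag`.
#'
#' @param path File path.
#' @param deg_alpha Used to derive `deg_flag` when the column is absent.
#' @return `data.frame` of class `expression_table`, one row per gene.
#' @export
read_expression_table <- function(path, deg_alpha = 0.05) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("gene", "log2fc", "p_value") %in% names(tab))) {
    stop("expression table needs columns gene, log2fc, p_value")
  }
  expression_table(tab, deg_alpha = deg_alpha)
}

#' Construct/validate an expression table
#' @param tab `data.frame` with `gene`, `log2fc`, `p_value`, optional
#'   `deg_flag`.
#' @param deg_alpha p-value threshold for `deg_flag` when absent.
#' @export
expression_table <- function(tab, deg_alpha = 0.05) {
  tab$gene <- as.character(tab$gene)
  tab$log2fc <- as.numeric(tab$log2fc)
  tab$p_value <- as.numeric(tab$p_value)
  if (anyDuplicated(tab$gene)) stop("one row per gene required")
  if (any(tab$p_value < 0 | tab$p_value > 1, na.rm = TRUE)) {
    stop("p_value outside [0, 1]")
  }
  if (is.null(tab$deg_flag)) tab$deg_flag <- tab$p_value <= deg_alpha
  tab$deg_flag <- as.logical(tab$deg_flag)
  tab <- tab[c("gene", "log2fc", "p_value", "deg_flag")]
  rownames(tab) <- NULL
  class(tab) <- c("expression_table", "data.frame")
  tab
}

#' Write per-site values as a variableStep WIG track
#'
#' Internal 0-based positions are written 1-based per the WIG standard.
#'
#' @param track_name Track name placed in the `track` line.
#' @param per_site_values `data.frame` with columns `chrom`, `pos` (0-based)
#'   and `value`.
#' @param path Output path.
#' @export
write_wig <- function(track_name, per_site_values, path) {
  stopifnot(all(c("chrom", "pos", "value") %in% names(per_site_values)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s\"", track_name), con)
  v <- per_site_values[order(per_site_values$chrom, per_site_values$pos), ,
                       drop = FALSE]
  for (chrom in unique(v$chrom)) {
    block <- v[v$chrom == chrom, , drop = FALSE]
    writeLines(sprintf("variableStep chrom=%s", chrom), con)
    writeLines(sprintf("%d\t%.6g", block$pos + 1L, block$value), con)
  }
  invisible(path)
}

#' Read a variableStep WIG track written by [write_wig()]
#'
#' Positions are converted back to the internal 0-based convention.
#'
#' @param path WIG file path.
#' @return `data.frame` with `chrom`, `pos`, `value`.
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^track", lines)]
  chrom <- NA_character_
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "variableStep")) {
      chrom <- sub(".*chrom=(\\S+).*", "\\1", ln)
    } else if (nzchar(ln)) {
      f <- strsplit(ln, "\t| +")[[1]]
      out[[i]] <- data.frame(chrom = chrom,
                             pos = as.integer(f[1]) - 1L,
                             value = as.numeric(f[2]),
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) {
    res <- data.frame(chrom = character(), pos = integer(),
                      value = numeric())
  }
  rownames(res) <- NULL
  res
}
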