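#' Expression matrices with sample metadata
#'
#' Container for a gene x sample expression matrix (TPM or RPKM) with a
#' metadata tibble describing each sample (`sample`, `tissue`, `species`,
#' `region_class` in `neocortex` / `non_neocortex` / `non_brain`).
#'
#' @param values numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns (colnames = sample ids); non-negative.
#' @param samples sample-metadata tibble covering every column.
#' @param unit `"TPM"` or `"RPKM"`.
#' @return an `expr_matrix` object.
#' @export
expr_matrix <- function(values, samples, unit = c("TPM", "RPKM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) abort("negative expression values")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("values must carry gene rownames and sample colnames")
  }
  samples <- as_tibble(samples)
  need <- c("sample", "tissue", "species", "region_class")
  missing <- setdiff(need, names(samples))
  if (length(missing) > 0) {
    abort(paste0("sample metadata missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  uncovered <- setdiff(colnames(values), samples$sample)
  if (length(uncovered) > 0) {
    abort(paste0("sample(s) without metadata: ",
                 paste(uncovered, collapse = ", ")))
  }
  if (any(is.na(samples$region_class)) ||
      !all(samples$region_class %in% c("neocortex", "non_neocortex",
                                       "non_brain"))) {
    abort("region_class must be neocortex/non_neocortex/non_brain")
  }
  samples <- samples[match(colnames(values), samples$sample), ]
  structure(list(values = values, samples = samples, unit = unit),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples [", x$unit, "]\n", sep = "")
  invisible(x)
}

#' Read an expression matrix and its sample metadata
#'
#' @param values_path TSV, first column gene symbol, remaining columns one
#'   per sample.
#' @param meta_path sample-metadata TSV (`sample`, `tissue`, `species`,
#'   `region_class`).
#' @param unit `"TPM"` or `"RPKM"`.
#' @return an [expr_matrix()].
#' @export
read_expression <- function(values_path, meta_path, unit = "TPM") {
  df <- readr::read_tsv(values_path, col_types = readr::cols(),
                        progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  meta <- read_table(meta_path, "sample_meta")
  expr_matrix(m, meta, unit)
}

#' @rdname read_expression
#' @param em an `expr_matrix`.
#' @param values_path,meta_path output paths.
#' @export
write_expression <- function(em, values_path, meta_path) {
  df <- as_tibble(em$values, rownames = "gene")
  readr::write_tsv(df, values_path, progress = FALSE)
  write_table(em$samples, meta_path, "sample_meta")
  invisible(values_path)
}

#' Cerebral-cortex enrichment over a tissue panel
#'
#' For each gene, the enrichment ratio is its cerebral-cortex expression
#' divided by its mean expression over all tissues of the panel (the mean
#' includes the cortex itself). `ratio > 1` flags enrichment, `ratio > 2`
#' strong enrichment. Strongly enriched genes are typed:
#' `CORTEX_RELATIVE` when the gene is weakly expressed overall (its row
#' maximum is below the median per-gene maximum of the panel),
#' `CORTEX_DOMINANT` when the cortex is the gene's maximum, otherwise
#' `BROAD`; genes that are not strongly enriched are `BROAD`, and genes
#' with zero mean are `UNDETERMINED`.
#'
#' @param em an [expr_matrix()] of human tissues (one column per tissue).
#' @param cortex_tissue tissue label of the cerebral-cortex column
#'   (default `"cerebral cortex"`).
#' @param strong_threshold strong-enrichment ratio cutoff (default 2).
#' @return a tibble sorted by descending ratio: `gene_symbol`,
#'   `cortex_value`, `tissue_mean`, `ratio`, `enriched`,
#'   `strongly_enriched`, `pattern`.
#' @export
cortex_enrichment <- function(em, cortex_tissue = "cerebral cortex",
                              strong_threshold = 2) {
  stopifnot(inherits(em, "expr_matrix"))
  if (ncol(em$values) < 2) abort("need at least 2 tissues")
  cortex_cols <- which(em$samples$tissue == cortex_tissue)
  if (length(cortex_cols) == 0) {
    abort(paste0("configuration error: no sample with tissue '",
                 cortex_tissue, "'"))
  }
  cortex_value <- rowMeans(em$values[, cortex_cols, drop = FALSE])
  tissue_mean <- rowMeans(em$values)
  ratio <- ifelse(tissue_mean > 0, cortex_value / tissue_mean, NA_real_)
  row_max <- apply(em$values, 1, max)
  med_max <- median(row_max)
  strong <- !is.na(ratio) & ratio > strong_threshold
  pattern <- case_when(
    tissue_mean == 0 ~ "UNDETERMINED",
    strong & row_max < med_max ~ "CORTEX_RELATIVE",
    strong & cortex_value >= row_max ~ "CORTEX_DOMINANT",
    TRUE ~ "BROAD")
  tibble(gene_symbol = rownames(em$values),
         cortex_value = unname(cortex_value),
         tissue_mean = unname(tissue_mean),
         ratio = unname(ratio),
         enriched = !is.na(ratio) & ratio > 1,
         strongly_enriched = strong,
         pattern = pattern) %>%
    arrange(dplyr::desc(.data$ratio))
}

#' Variant-isoform expression relative to the principal isoform
#'
#' @param variant_tpm,principal_tpm numeric vectors of isoform expression.
#' @return percent of principal, `100 * variant / principal`; `NA` with a
#'   warning where the principal isoform is unexpressed.
#' @export
#' @examples
#' isoform_relative_expression(2.1, 10)  # 21
isoform_relative_expression <- function(variant_tpm, principal_tpm) {
  undefined <- principal_tpm == 0
  if (any(undefined)) {
    warn(paste0(sum(undefined), " isoform pair(s) with unexpressed ",
                "principal isoform: relative expression undefined"))
  }
  ifelse(undefined, NA_real_, 100 * variant_tpm / principal_tpm)
}

#' Cross-species neocortex fold change
#'
#' Per-gene fold change of mean expression over the focal species'
#' neocortex samples against the mean over all other species' neocortex
#' samples (pooled equally).
#'
#' @param em an [expr_matrix()] with species and region-class metadata.
#' @param focal_species species in the numerator (default `"human"`).
#' @return tibble (`gene_symbol`, `focal_mean`, `other_mean`,
#'   `fold_change`, `zero_denominator`).
#' @export
cross_species_neocortex_fc <- function(em, focal_species = "human") {
  stopifnot(inherits(em, "expr_matrix"))
  if (any(is.na(em$samples$region_class)) ||
      any(is.na(em$samples$species))) {
    abort("species/region_class metadata incomplete")
  }
  neo <- em$samples$region_class == "neocortex"
  foc <- neo & em$samples$species == focal_species
  oth <- neo & em$samples$species != focal_species
  if (!any(foc)) abort(paste0("no neocortex sample for ", focal_species))
  if (!any(oth)) abort("no non-focal neocortex sample")
  focal_mean <- rowMeans(em$values[, foc, drop = FALSE])
  other_mean <- rowMeans(em$values[, oth, drop = FALSE])
  tibble(gene_symbol = rownames(em$values),
         focal_mean = unname(focal_mean),
         other_mean = unname(other_mean),
         fold_change = ifelse(other_mean > 0, focal_mean / other_mean,
                              NA_real_),
         zero_denominator = other_mean == 0)
}

#' Hierarchical clustering of expression samples
#'
#' Samples are clustered on correlation distance (1 - Pearson, computed
#' across genes) with average linkage. Expression values are
#' `log2(x + 1)`-transformed first (the standard preprocessing before
#' correlating expression profiles; Pearson on raw TPM/RPKM is dominated
#' by the few highest-expressed genes) — set `log_transform = FALSE` to
#' correlate raw values. Columns are ordered by sample label before
#' clustering so the result is independent of input column order;
#' zero-variance genes are dropped with a warning. The clade report states,
#' per species, whether its neocortex samples form a monophyletic clade in
#' the dendrogram, and, per non-neocortex tissue, whether that tissue's
#' samples group together across species.
#'
#' @param em an [expr_matrix()] with >= 3 samples.
#' @param log_transform correlate `log2(x + 1)` values (default) instead
#'   of raw values.
#' @return a list: `hclust`, `phylo` (ape tree), `clade_report` (tibble
#'   `group`, `kind`, `n_tips`, `monophyletic`), `dropped_genes`,
#'   `degenerate` (all pairwise distances zero).
#' @export
cluster_samples <- function(em, log_transform = TRUE) {
  stopifnot(inherits(em, "expr_matrix"))
  if (ncol(em$values) < 3) abort("need at least 3 samples")
  ord <- order(em$samples$sample)
  vals <- em$values[, ord, drop = FALSE]
  if (log_transform) vals <- log2(vals + 1)
  meta <- em$samples[ord, ]
  v <- apply(vals, 1, stats::var)
  if (all(v == 0)) {
    # all samples identical: keep a zero distance matrix, flag degenerate
    d <- matrix(0, ncol(vals), ncol(vals),
                dimnames = list(colnames(vals), colnames(vals)))
  } else {
    if (any(v == 0)) {
      warn(paste0("dropping ", sum(v == 0),
                  " zero-variance gene(s) before clustering"))
      vals <- vals[v > 0, , drop = FALSE]
    }
    if (nrow(vals) < 2) abort("fewer than 2 genes after variance filter")
    d <- 1 - cor(vals, method = "pearson")
  }
  degenerate <- all(abs(d) < 1e-12)
  hc <- hclust(as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  report <- clade_report(phy, meta, degenerate)
  list(hclust = hc, phylo = phy, clade_report = report,
       dropped_genes = rownames(em$values)[v == 0],
       degenerate = degenerate)
}

clade_report <- function(phy, meta, degenerate) {
  rows <- list()
  for (sp in unique(meta$species)) {
    tips <- meta$sample[meta$species == sp &
                          meta$region_class == "neocortex"]
    if (length(tips) >= 2) {
      rows[[length(rows) + 1]] <- tibble(
        group = sp, kind = "species_neocortex", n_tips = length(tips),
        monophyletic = if (degenerate) NA else
          ape::is.monophyletic(phy, tips))
    }
  }
  non_neo <- meta[meta$region_class == "non_neocortex", ]
  for (tis in unique(non_neo$tissue)) {
    tips <- non_neo$sample[non_neo$tissue == tis]
    if (length(tips) >= 2) {
      rows[[length(rows) + 1]] <- tibble(
        group = tis, kind = "tissue_across_species",
        n_tips = length(tips),
        monophyletic = if (degenerate) NA else
          ape::is.monophyletic(phy, tips))
    }
  }
  bind_rows(rows)
}

#' Species-clade purity of neocortex samples
#'
#' Clusters the neocortex samples alone, cuts the tree into one cluster
#' per species, and scores the agreement of the partition with the species
#' labels by the adjusted Rand index (1 = perfect species clades).
#'
#' @param em an [expr_matrix()].
#' @return adjusted Rand index in \eqn{[-1, 1]}.
#' @export
neocortex_clade_purity <- function(em) {
  neo <- em$samples$region_class == "neocortex"
  sub <- expr_matrix(em$values[, neo, drop = FALSE], em$samples[neo, ],
                     em$unit)
  cl <- cluster_samples(sub)
  k <- n_distinct(sub$samples$species)
  part <- cutree(cl$hclust, k = k)
  labels <- sub$samples$species[match(names(part), sub$samples$sample)]
  mclust::adjustedRandIndex(part, labels)
}
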