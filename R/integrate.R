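#' Read a differential-expression table
#'
#' Expected columns: `gene_id`, `padj` (adjusted p-value of the selection
#' contrast), then one log2 fold-change column per condition. The table is
#' consumed as produced by an external differential-expression tool; no DE
#' calling happens here.
#'
#' @param path CSV/TSV path (delimiter autodetected).
#' @return An object of class `"differential_table"`: list with `values`
#'   (genes x conditions log2 FC), `gene_ids`, `padj`.
#' @export
read_differential_table <- function(path) {
  d <- .read_delim_auto(path)
  need <- c("gene_id", "padj")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("differential table missing columns: ", paste(miss, collapse = ", "))
  differential_table(
    as.matrix(d[, setdiff(names(d), need), drop = FALSE]) |>
      `rownames<-`(as.character(d$gene_id)),
    padj = d$padj)
}

#' Construct a differential-expression table
#'
#' @param values Genes x conditions log2 fold-change matrix with rownames
#'   (gene ids) and colnames (condition ids).
#' @param padj Per-gene adjusted p-value in `[0, 1]` for the selection
#'   contrast.
#' @return A `"differential_table"`.
#' @export
differential_table <- function(values, padj) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            length(padj) == nrow(values))
  storage.mode(values) <- "double"
  if (any(padj < 0 | padj > 1, na.rm = TRUE))
    stop("padj values must lie in [0, 1]")
  structure(list(values = values, gene_ids = rownames(values),
                 padj = as.numeric(padj)),
            class = "differential_table")
}

#' Select differentially expressed genes
#'
#' Genes with `|log2 FC| > fc_cutoff` in the selection-contrast column and
#' adjusted p below `fdr_cutoff`. The fold-change criterion is two-sided
#' (absolute value): strong down-regulation selects a gene just as strong
#' up-regulation does.
#'
#' @param dt A `"differential_table"`.
#' @param contrast Condition id of the selection contrast (default: first
#'   column).
#' @param fc_cutoff Absolute log2 fold-change cutoff (default 1).
#' @param fdr_cutoff Adjusted-p cutoff (default 0.1).
#' @return Character vector of selected gene ids.
#' @export
select_de_genes <- function(dt, contrast = NULL, fc_cutoff = 1,
                            fdr_cutoff = 0.1) {
  stopifnot(inherits(dt, "differential_table"), nrow(dt$values) > 0)
  if (is.null(contrast)) contrast <- colnames(dt$values)[1]
  if (!contrast %in% colnames(dt$values))
    stop("unknown contrast condition: ", contrast)
  sel <- abs(dt$values[, contrast]) > fc_cutoff &
    !is.na(dt$padj) & dt$padj < fdr_cutoff
  dt$gene_ids[sel]
}

#' Gene-by-lipid correlation matrix
#'
#' Pearson correlation of every (gene, lipid) pair of log2 fold-change
#' vectors across the shared, identically ordered conditions. Conditions are
#' matched by exact id; control lipid conditions are excluded. Zero-variance
#' gene rows are excluded with a warning.
#'
#' @param genes A `"differential_table"` (optionally pre-filtered to a gene
#'   subset via `gene_ids`).
#' @param lipids An `"fc_matrix"` of lipid fold-changes.
#' @param gene_ids Optional subset of genes to correlate.
#' @return An object of class `"gene_lipid_corr"`: list with `values`
#'   (genes x lipids correlations), `n_conditions`, `gene_ids`,
#'   `lipid_ids`, and `clusters` (`NULL` until assigned).
#' @export
gene_lipid_correlation <- function(genes, lipids, gene_ids = NULL) {
  stopifnot(inherits(genes, "differential_table"),
            inherits(lipids, "fc_matrix"))
  lcond <- lipids$conditions$condition_id[!lipids$conditions$is_control]
  shared <- intersect(colnames(genes$values), lcond)
  if (length(shared) < 3)
    stop("need at least 3 shared conditions; have ", length(shared))
  gm <- genes$values[, shared, drop = FALSE]
  if (!is.null(gene_ids)) {
    miss <- setdiff(gene_ids, rownames(gm))
    if (length(miss))
      stop("gene id(s) not in table: ",
           paste(utils::head(miss, 5), collapse = ", "))
    gm <- gm[gene_ids, , drop = FALSE]
  }
  v <- apply(gm, 1, stats::var)
  if (any(v == 0)) {
    warning("excluding zero-variance gene(s): ",
            paste(utils::head(rownames(gm)[v == 0], 5), collapse = ", "))
    gm <- gm[v > 0, , drop = FALSE]
  }
  lm_ <- lipids$values[, shared, drop = FALSE]
  vals <- stats::cor(t(gm), t(lm_))
  structure(list(values = vals, n_conditions = length(shared),
                 gene_ids = rownames(vals), lipid_ids = colnames(vals),
                 clusters = NULL),
            class = "gene_lipid_corr")
}

#' Cluster genes by their lipid-correlation profiles
#'
#' Delegates to [cluster_profiles()] on the genes x lipids correlation rows:
#' genes correlating with similar lipids land in the same cluster. The
#' published analysis used k = 11 for its differentially expressed genes.
#'
#' @param glc A `"gene_lipid_corr"`.
#' @param k Number of gene clusters (default 11).
#' @param ... Passed to [cluster_profiles()] (`metric`, `linkage`).
#' @return The `"gene_lipid_corr"` with `clusters` set to the
#'   `"group_assignment"`.
#' @export
cluster_genes_by_lipid_profile <- function(glc, k = 11, ...) {
  stopifnot(inherits(glc, "gene_lipid_corr"), k <= length(glc$gene_ids))
  glc$clusters <- cluster_profiles(glc$values, k = k, ...)
  glc
}

#' Per-cluster gene-set enrichment
#'
#' Tests each gene cluster for enrichment of a gene set via
#' [set_enrichment()]. Universe defaults to all clustered genes; an
#' explicit universe (e.g. the whole transcriptome) may be supplied instead,
#' in which case every cluster must be contained in it.
#'
#' @param glc A clustered `"gene_lipid_corr"`.
#' @param gene_set Character vector of set members.
#' @param universe Optional universe; default all clustered genes.
#' @return Data frame with `cluster`, `n_genes` and [set_enrichment()]
#'   columns, one row per cluster.
#' @export
cluster_set_enrichment <- function(glc, gene_set, universe = NULL) {
  stopifnot(inherits(glc, "gene_lipid_corr"))
  if (is.null(glc$clusters))
    stop("genes are not clustered; call cluster_genes_by_lipid_profile first")
  groups <- glc$clusters
  if (is.null(universe)) universe <- groups$feature_ids
  res <- lapply(seq_len(groups$k), function(g) {
    members <- groups$feature_ids[groups$labels == g]
    cbind(cluster = g, n_genes = length(members),
          set_enrichment(members, gene_set, universe))
  })
  do.call(rbind, res)
}

#' Per-lipid phenotype correlation
#'
#' Pearson correlation of each lipid's log2 fold-change vector with a
#' phenotype vector (e.g. percent S-phase cells) across shared conditions.
#' The result is a named vector suitable for [overlay_values()].
#'
#' @param lipids An `"fc_matrix"`.
#' @param pheno Named numeric vector, names = condition ids.
#' @param use Condition subset, as in [pairwise_correlation()].
#' @return Named numeric vector of correlations per lipid.
#' @export
phenotype_correlation <- function(lipids, pheno, use = c("treated", "all")) {
  stopifnot(inherits(lipids, "fc_matrix"), !is.null(names(pheno)))
  use <- match.arg(use)
  conds <- lipids$conditions$condition_id
  if (use == "treated") conds <- conds[!lipids$conditions$is_control]
  shared <- intersect(conds, names(pheno))
  if (length(shared) < 3)
    stop("need at least 3 shared conditions; have ", length(shared))
  drop(stats::cor(t(lipids$values[, shared, drop = FALSE]), pheno[shared]))
}

#' Read a phenotype vector
#'
#' Two-column CSV/TSV: `condition_id`, `value`.
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_phenotype <- function(path) {
  d <- .read_delim_auto(path)
  if (!all(c("condition_id", "value") %in% names(d)))
    stop("phenotype table needs columns condition_id, value")
  stats::setNames(as.numeric(d$value), as.character(d$condition_id))
}
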