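#' Cluster fold-change profiles into k groups
#'
#' Agglomerative hierarchical clustering of the rows of a fold-change
#' matrix, with the tree cut to exactly `k` groups. Groups are renumbered by
#' dendrogram leaf order: the group containing the first leaf is group 1,
#' the next newly encountered group is 2, and so on, giving stable
#' reportable indices. The partition is deterministic given the input matrix
#' and parameters, and invariant to row permutation up to label renaming.
#'
#' @param fc An `"fc_matrix"` (or bare numeric matrix with rownames).
#' @param k Number of groups (>= 1, <= number of rows).
#' @param metric `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson r between rows).
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"average"`.
#' @return An object of class `"group_assignment"`: list with
#'   `feature_ids`, `labels` (named integer vector in 1..k), `k`,
#'   `leaf_order` (feature ids in dendrogram order) and `tree` (the
#'   `hclust` object, `NULL` when `k` equals the row count of 1).
#' @export
cluster_profiles <- function(fc, k, metric = c("euclidean", "correlation"),
                             linkage = "average") {
  x <- if (inherits(fc, "fc_matrix")) fc$values else fc
  stopifnot(is.matrix(x), !is.null(rownames(x)), k >= 1, nrow(x) >= k)
  metric <- match.arg(metric)
  if (metric == "correlation") {
    v <- apply(x, 1, stats::var)
    if (any(v == 0))
      stop("zero-variance row(s) under correlation metric: ",
           paste(rownames(x)[v == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(t(x)))
  } else {
    d <- stats::dist(x, method = "euclidean")
  }
  tree <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(tree, k = k)
  leaf_order <- rownames(x)[tree$order]
  # renumber so first-encountered leaf group becomes 1, etc.
  seen <- unique(raw[leaf_order])
  labels <- match(raw, seen)
  names(labels) <- rownames(x)
  structure(list(feature_ids = rownames(x), labels = labels, k = k,
                 leaf_order = leaf_order, tree = tree),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("group_assignment: %d features in %d groups (sizes: %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Named lipid category predicates
#'
#' Predicates over parsed lipid annotations used for group enrichment:
#' `"saturated"` (SFA), `"unsaturated"` (MUFA or PUFA), any saturation
#' category (`"SFA"`, `"MUFA"`, `"PUFA"`), or any lipid class token (e.g.
#' `"TG"`).
#'
#' @param species A `"lipid_species"` data frame.
#' @param predicate Predicate name.
#' @return Logical vector over species.
#' @export
lipid_category <- function(species, predicate) {
  stopifnot(is.data.frame(species))
  switch(predicate,
    saturated = species$saturation == "SFA",
    unsaturated = species$saturation %in% c("MUFA", "PUFA"),
    if (predicate %in% c("SFA", "MUFA", "PUFA"))
      species$saturation == predicate
    else if (predicate %in% lipid_classes())
      species$lipid_class == predicate
    else stop("unknown lipid category predicate: ", predicate)
  )
}

#' Per-group category enrichment
#'
#' Tests each group of a partition for enrichment of a lipid category, with
#' the universe being all clustered lipids. One row per group; the 2x2
#' margins of each row sum to the universe counts.
#'
#' @param groups A `"group_assignment"` over lipid features.
#' @param species A `"lipid_species"` data frame aligned with
#'   `groups$feature_ids` (matched by `name`).
#' @param predicate Category predicate name (see [lipid_category()]).
#' @return Data frame with `group`, `n_lipids` and the [set_enrichment()]
#'   columns.
#' @export
group_category_enrichment <- function(groups, species, predicate) {
  stopifnot(inherits(groups, "group_assignment"))
  idx <- match(groups$feature_ids, species$name)
  if (anyNA(idx))
    stop("species annotation missing for: ",
         paste(utils::head(groups$feature_ids[is.na(idx)], 5), collapse = ", "))
  species <- species[idx, ]
  in_cat <- species$name[lipid_category(species, predicate)]
  universe <- groups$feature_ids
  res <- lapply(seq_len(groups$k), function(g) {
    members <- groups$feature_ids[groups$labels == g]
    cbind(group = g, n_lipids = length(members),
          set_enrichment(members, in_cat, universe))
  })
  do.call(rbind, res)
}

#' Cumulative fold-change across ordered conditions
#'
#' Running sum of log2 fold-changes across conditions in the given order,
#' per feature — the quantity displayed as cumulative fold-change bars after
#' acute inhibition time courses.
#'
#' @param fc An `"fc_matrix"`.
#' @param condition_order Character vector of condition ids (all must
#'   exist).
#' @return Numeric matrix, features x ordered conditions, of running sums.
#' @export
cumulative_fc_profile <- function(fc, condition_order) {
  stopifnot(inherits(fc, "fc_matrix"))
  missing <- setdiff(condition_order, colnames(fc$values))
  if (length(missing))
    stop("unknown condition(s): ", paste(missing, collapse = ", "))
  x <- fc$values[, condition_order, drop = FALSE]
  if (ncol(x) == 1) return(x)
  out <- t(apply(x, 1, cumsum))
  dimnames(out) <- dimnames(x)
  out
}
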