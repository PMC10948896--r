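#' Pairwise lipid correlations across conditions
#'
#' Pearson (or Spearman) correlation of every pair of features' log2
#' fold-change vectors across conditions. Control conditions (identically
#' zero by construction) are excluded by default so that only perturbation
#' responses drive coregulation. Zero-variance rows are excluded with a
#' warning — their correlation is undefined.
#'
#' @param fc An `"fc_matrix"`.
#' @param use `"treated"` (default; drops control conditions) or `"all"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `"correlation_matrix"`: list with
#'   `values` (symmetric, unit diagonal), `n_obs` (conditions used) and
#'   `feature_ids`.
#' @export
pairwise_correlation <- function(fc, use = c("treated", "all"),
                                 method = c("pearson", "spearman")) {
  stopifnot(inherits(fc, "fc_matrix"))
  use <- match.arg(use)
  method <- match.arg(method)
  keep <- if (use == "treated") !fc$conditions$is_control
          else rep(TRUE, ncol(fc$values))
  x <- fc$values[, keep, drop = FALSE]
  if (ncol(x) < 3)
    stop("need at least 3 conditions to correlate; have ", ncol(x))
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warning("excluding zero-variance feature(s): ",
            paste(utils::head(rownames(x)[v == 0], 5), collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  cm <- stats::cor(t(x), method = method)
  diag(cm) <- 1
  structure(list(values = cm, n_obs = ncol(x), feature_ids = rownames(x)),
            class = "correlation_matrix")
}

#' Build a thresholded coregulation network
#'
#' Undirected graph whose nodes are lipid species and whose edges connect
#' pairs with correlation at or above the threshold (inclusive; the
#' published cut is r >= 0.76). Negative correlations never form edges, but
#' the full correlation matrix remains available upstream for querying
#' anti-correlated pairs. Nodes carry class, chain length (carbons),
#' double-bond and saturation annotations; chain length is the conventional
#' node-size proxy.
#'
#' @param cm A `"correlation_matrix"`.
#' @param threshold Edge threshold in (-1, 1]; default 0.76.
#' @param annot Optional `"lipid_species"` data frame covering all features.
#' @return An object of class `"coreg_network"`: list with `graph` (an
#'   [igraph][igraph::igraph-package] object with edge attribute `r`) and
#'   `threshold`.
#' @export
build_network <- function(cm, threshold = 0.76, annot = NULL) {
  stopifnot(inherits(cm, "correlation_matrix"),
            threshold > -1, threshold <= 1)
  ids <- cm$feature_ids
  if (!is.null(annot)) {
    idx <- match(ids, annot$name)
    if (anyNA(idx))
      stop("annotation missing for feature(s): ",
           paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
    annot <- annot[idx, ]
  }
  r <- cm$values
  ut <- which(upper.tri(r) & r >= threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (!is.null(annot)) {
    g <- igraph::set_vertex_attr(g, "lipid_class", value = annot$lipid_class)
    g <- igraph::set_vertex_attr(g, "carbons", value = annot$carbons)
    g <- igraph::set_vertex_attr(g, "double_bonds", value = annot$double_bonds)
    g <- igraph::set_vertex_attr(g, "saturation", value = annot$saturation)
  }
  if (nrow(ut)) {
    g <- igraph::add_edges(g, t(ut))
    g <- igraph::set_edge_attr(g, "r", value = r[ut])
  }
  structure(list(graph = g, threshold = threshold), class = "coreg_network")
}

#' @export
print.coreg_network <- function(x, ...) {
  cat(sprintf("coreg_network: %d nodes, %d edges at r >= %g\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold))
  invisible(x)
}

#' Leave-one-out robustness of network edges
#'
#' For every edge, finds the condition that contributed most to the
#' correlation — the condition whose single removal most decreases r —
#' recomputes r without it, and flags the edge as retained when the reduced
#' r still clears the network threshold. Edges supported by only 3
#' conditions cannot be evaluated (removal leaves 2 points, where r is
#' degenerate) and are flagged `"insufficient"`.
#'
#' @param fc The `"fc_matrix"` the network was built from.
#' @param net A `"coreg_network"` built from `fc` at its stated threshold.
#' @param use Condition subset, as in [pairwise_correlation()].
#' @return A list of class `"robustness_report"`: `edges` (data frame with
#'   `from`, `to`, `original_r`, `most_influential_condition`,
#'   `r_without_it`, `retained`, `status`) and `fraction_retained` (over
#'   evaluable edges).
#' @export
edge_robustness <- function(fc, net, use = c("treated", "all")) {
  stopifnot(inherits(fc, "fc_matrix"), inherits(net, "coreg_network"))
  use <- match.arg(use)
  keep <- if (use == "treated") !fc$conditions$is_control
          else rep(TRUE, ncol(fc$values))
  x <- fc$values[, keep, drop = FALSE]
  el <- igraph::as_edgelist(net$graph)
  if (!nrow(el)) {
    return(structure(list(edges = data.frame(), fraction_retained = NA_real_),
                     class = "robustness_report"))
  }
  res <- lapply(seq_len(nrow(el)), function(i) {
    xi <- x[el[i, 1], ]; xj <- x[el[i, 2], ]
    r0 <- stats::cor(xi, xj)
    if (length(xi) <= 3) {
      return(data.frame(from = el[i, 1], to = el[i, 2], original_r = r0,
                        most_influential_condition = NA_character_,
                        r_without_it = NA_real_, retained = NA,
                        status = "insufficient"))
    }
    loo <- vapply(seq_along(xi),
                  function(c) stats::cor(xi[-c], xj[-c]), numeric(1))
    worst <- which.min(loo)
    data.frame(from = el[i, 1], to = el[i, 2], original_r = r0,
               most_influential_condition = colnames(x)[worst],
               r_without_it = loo[worst],
               retained = loo[worst] >= net$threshold, status = "ok")
  })
  edges <- do.call(rbind, res)
  structure(list(edges = edges,
                 fraction_retained = mean(edges$retained, na.rm = TRUE)),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("robustness_report: %d edges, %.1f%% retained after leave-one-out\n",
              nrow(x$edges), 100 * x$fraction_retained))
  invisible(x)
}

#' Overlay per-lipid values on network nodes
#'
#' Attaches a named numeric map (e.g. per-lipid phenotype correlations) as a
#' node attribute. Lipids absent from the map are marked `NA` explicitly —
#' never defaulted to 0 — so "missing" and "uncorrelated" stay
#' distinguishable. Successive overlays under different labels coexist.
#'
#' @param net A `"coreg_network"`.
#' @param values Named numeric vector keyed by lipid name.
#' @param label Attribute name for the overlay.
#' @return The network with the overlay attribute added.
#' @export
overlay_values <- function(net, values, label) {
  stopifnot(inherits(net, "coreg_network"), !is.null(names(values)),
            is.character(label), nzchar(label))
  ids <- igraph::V(net$graph)$name
  net$graph <- igraph::set_vertex_attr(net$graph, label,
                                       value = unname(values[ids]))
  net
}

#' Deterministic force-directed layout
#'
#' Fruchterman-Reingold coordinates computed under a fixed RNG seed, stored
#' as `x`/`y` node attributes so they survive export. Identical seeds give
#' identical coordinates.
#'
#' @param net A `"coreg_network"`.
#' @param seed Integer seed.
#' @return The network with `x` and `y` vertex attributes.
#' @export
layout_network <- function(net, seed = 1L) {
  stopifnot(inherits(net, "coreg_network"))
  # components are laid out separately and merged without bounding-box
  # overlap when the graph is disconnected
  coords <- withr_seed(seed, {
    if (igraph::is_connected(net$graph) || igraph::vcount(net$graph) == 0)
      igraph::layout_with_fr(net$graph)
    else
      igraph::layout_components(net$graph, layout = igraph::layout_with_fr)
  })
  net$graph <- igraph::set_vertex_attr(net$graph, "x", value = coords[, 1])
  net$graph <- igraph::set_vertex_attr(net$graph, "y", value = coords[, 2])
  net
}

# run expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Export a network as GraphML / edge list
#'
#' GraphML carries all node attributes (class, carbons, saturation,
#' overlays, layout coordinates) and the edge attribute `r`. The edge list
#' is a plain TSV (`from`, `to`, `r`).
#'
#' @param net A `"coreg_network"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "coreg_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "coreg_network"))
  el <- igraph::as_edgelist(net$graph)
  df <- data.frame(from = el[, 1], to = el[, 2],
                   r = if (igraph::ecount(net$graph))
                     igraph::E(net$graph)$r else numeric(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
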