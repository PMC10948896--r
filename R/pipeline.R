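#' Write / read simulated traces as CSV
#'
#' Long format: `cell_id`, `frame`, `cdk`, `degron`, `mitosis` (0/1 event
#' marker at that frame).
#'
#' @param traces A `"trace_set"`.
#' @param path File path.
#' @param treatment_frame,interval_min Metadata needed to reconstruct the
#'   set on read.
#' @return `path` (write) or a `"trace_set"` (read).
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  n <- nrow(traces$cdk); f <- ncol(traces$cdk)
  mit <- matrix(0L, n, f)
  for (i in seq_len(n)) mit[i, traces$mitosis[[i]]] <- 1L
  df <- data.frame(cell_id = rep(seq_len(n), each = f),
                   frame = rep(seq_len(f), n),
                   cdk = as.vector(t(traces$cdk)),
                   degron = as.vector(t(traces$degron)),
                   mitosis = as.vector(t(mit)))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path, treatment_frame, interval_min = 12) {
  d <- .read_delim_auto(path)
  cells <- sort(unique(d$cell_id))
  frames <- sort(unique(d$frame))
  d <- d[order(d$cell_id, d$frame), ]
  n <- length(cells); f <- length(frames)
  cdk <- matrix(d$cdk, n, f, byrow = TRUE)
  degron <- matrix(d$degron, n, f, byrow = TRUE)
  mit <- matrix(d$mitosis, n, f, byrow = TRUE)
  mitosis <- lapply(seq_len(n), function(i) which(mit[i, ] == 1))
  trace_set(cdk, degron, interval_min, treatment_frame, mitosis)
}

#' Generate every simulated input for a full pipeline run
#'
#' Writes, under `out_dir`: the lipidome abundance table and design
#' (`lipidome.tsv`, `design.tsv`), a differential-expression table
#' (`de_table.tsv`), gene sets (`gene_sets.gmt`), a phenotype vector
#' (`phenotype.tsv`), four channel TIFFs plus per-cell image ground truth
#' (`img_*.tif`, `images_truth.csv`), traces (`traces.csv`,
#' `traces_truth.csv`) and a `manifest.json` recording all parameters.
#' Ground-truth files (`*_truth*`, `truth_*`) suffice to compute every
#' recovery metric without re-deriving hidden state.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; sub-generators derive fixed offsets
#'   from it.
#' @param preset Parameter preset; `"paper-like"` (the defaults of the
#'   individual generators) or `"small"` (reduced sizes for quick runs).
#' @return Invisibly, a list with the simulation objects (`lipidome`,
#'   `transcriptome`, `phenotype`, `images`, `traces`) and `paths`.
#' @export
simulate_all <- function(out_dir, seed = 1L,
                         preset = c("paper-like", "small")) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- if (preset == "paper-like")
    list(n_lipids = 120, n_conditions = 12, n_genes = 300, n_cells_img = 40,
         img_size = 512, n_traces = 500)
  else
    list(n_lipids = 40, n_conditions = 8, n_genes = 60, n_cells_img = 12,
         img_size = 256, n_traces = 60)

  lip <- simulate_lipidome(n_lipids = p$n_lipids,
                           n_conditions = p$n_conditions, seed = seed)
  trx <- simulate_transcriptome(lip$truth, n_genes = p$n_genes,
                                seed = seed + 1L)
  pheno <- simulate_phenotype(lip$truth, seed = seed + 2L)
  img <- simulate_images(n_cells = p$n_cells_img, size = p$img_size,
                         seed = seed + 3L)
  trc <- simulate_traces(n_cells = p$n_traces, seed = seed + 4L)

  paths <- list(
    lipidome = file.path(out_dir, "lipidome.tsv"),
    design = file.path(out_dir, "design.tsv"),
    de_table = file.path(out_dir, "de_table.tsv"),
    gmt = file.path(out_dir, "gene_sets.gmt"),
    phenotype = file.path(out_dir, "phenotype.tsv"),
    images_truth = file.path(out_dir, "images_truth.csv"),
    traces = file.path(out_dir, "traces.csv"),
    traces_truth = file.path(out_dir, "traces_truth.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  for (ch in names(img$channels))
    paths[[paste0("img_", ch)]] <- file.path(out_dir,
                                             sprintf("img_%s.tif", ch))

  write_lipidome_table(lip$matrix, paths$lipidome)
  utils::write.table(lip$matrix$design, paths$design, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  de <- data.frame(gene_id = trx$table$gene_ids, padj = trx$table$padj,
                   trx$table$values, check.names = FALSE)
  utils::write.table(de, paths$de_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(trx$gene_sets, paths$gmt)
  utils::write.table(data.frame(condition_id = names(pheno), value = pheno),
                     paths$phenotype, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (ch in names(img$channels))
    write_image_tiff(pmin(img$channels[[ch]], 65535),
                     paths[[paste0("img_", ch)]])
  utils::write.table(img$truth, paths$images_truth, sep = ",", quote = FALSE,
                     row.names = FALSE)
  write_traces_csv(trc$traces, paths$traces)
  utils::write.table(trc$truth, paths$traces_truth, sep = ",", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(seed = seed, preset = preset, params = p),
                       paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(lipidome = lip, transcriptome = trx, phenotype = pheno,
                 images = img, traces = trc, paths = paths))
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Simulates all inputs under a seed ([simulate_all()]) and runs every
#' stage: preprocessing to log2 fold-changes, the thresholded coregulation
#' network (with layout, phenotype overlay, GraphML/edge-list export and
#' leave-one-out robustness), fold-change group clustering with saturation
#' enrichment, gene-lipid correlation with gene clustering and set
#' enrichment, image quantification with phase gating, and trace outcome
#' calling. All outputs are plain text; a run is a pure function of the
#' seed, so two runs with the same seed produce byte-identical files.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param threshold Network edge threshold (default 0.76).
#' @param k_lipid_groups,k_gene_clusters Cluster counts (defaults 4, 11).
#' @param preset Passed to [simulate_all()].
#' @return Invisibly, a list of the main result objects and output paths.
#' @export
run_pipeline <- function(out_dir, seed = 1L, threshold = 0.76,
                         k_lipid_groups = 4, k_gene_clusters = 11,
                         preset = c("paper-like", "small")) {
  preset <- match.arg(preset)
  sim <- simulate_all(out_dir, seed = seed, preset = preset)

  m <- read_lipidome_table(sim$paths$lipidome, sim$paths$design)
  fc <- preprocess_lipidome(m)
  fc_path <- file.path(out_dir, "fc.tsv")
  write_fc_table(fc, fc_path)

  cm <- pairwise_correlation(fc)
  net <- build_network(cm, threshold = threshold, annot = m$species)
  pheno <- read_phenotype(sim$paths$phenotype)
  net <- overlay_values(net, phenotype_correlation(fc, pheno),
                        "phenotype_r")
  net <- layout_network(net, seed = seed)
  graphml_path <- file.path(out_dir, "network.graphml")
  write_network_graphml(net, graphml_path)
  write_edge_list(net, file.path(out_dir, "edges.tsv"))
  rob <- edge_robustness(fc, net)
  utils::write.table(rob$edges, file.path(out_dir, "robustness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  groups <- cluster_profiles(fc, k = k_lipid_groups)
  grp_path <- file.path(out_dir, "lipid_groups.tsv")
  utils::write.table(
    data.frame(feature_id = groups$feature_ids, group = groups$labels),
    grp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- group_category_enrichment(groups, m$species, "saturated")
  utils::write.table(enr, file.path(out_dir, "group_enrichment.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)

  dt <- read_differential_table(sim$paths$de_table)
  glc <- gene_lipid_correlation(dt, fc)
  glc <- cluster_genes_by_lipid_profile(glc, k = k_gene_clusters)
  sets <- read_gmt(sim$paths$gmt)
  cse <- cluster_set_enrichment(glc, sets[[1]])
  utils::write.table(
    data.frame(gene_id = glc$clusters$feature_ids,
               cluster = glc$clusters$labels),
    file.path(out_dir, "gene_clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(cse, file.path(out_dir, "cluster_enrichment.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)

  channels <- lapply(stats::setNames(nm = c("dna", "reporter", "edu",
                                            "marker")),
                     function(ch) read_image_tiff(
                       sim$paths[[paste0("img_", ch)]]))
  labels <- segment_nuclei(channels$dna)
  cells <- measure_cells(labels, channels)
  utils::write.table(cells, file.path(out_dir, "cells.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  gates <- gate_fixed(cells)
  utils::write.table(as.data.frame(gates$summary),
                     file.path(out_dir, "gate_summary.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)

  traces <- read_traces_csv(sim$paths$traces, treatment_frame = 21)
  outc <- call_trace_outcomes(traces, bin = c(0.4, 0.6))
  utils::write.table(
    data.frame(n_selected = outc$n_selected,
               frac_cdk_rise = outc$frac_cdk_rise,
               frac_degron_rise = outc$frac_degron_rise,
               frac_mitosis = outc$frac_mitosis),
    file.path(out_dir, "trace_outcomes.csv"), sep = ",", quote = FALSE,
    row.names = FALSE)

  invisible(list(sim = sim, fc = fc, network = net, robustness = rob,
                 groups = groups, group_enrichment = enr, gene_lipid = glc,
                 cluster_enrichment = cse, cells = cells, gates = gates,
                 trace_outcomes = outc,
                 paths = list(fc = fc_path, graphml = graphml_path,
                              out_dir = out_dir)))
}
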