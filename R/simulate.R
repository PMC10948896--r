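#' Simulate a lipidome with planted circular coregulation
#'
#' Generates a replicate-level abundance table whose lipids respond to
#' perturbation conditions through a circular latent model: lipid `l` sits
#' at angle `theta_l`, condition `c` at phase `phi_c`, and the log2 response
#' is `amplitude * cos(phi_c - theta_l)` plus log-normal replicate noise.
#' Over phases spread uniformly on the circle the correlation between two
#' lipids converges to `cos(theta_i - theta_j)`; with the default evenly
#' spaced phase grid the zero-noise sample correlation equals it exactly, so
#' the planted adjacency (pairs with `cos` difference at or above the edge
#' threshold) is the analytically known ground truth of the coregulation
#' network.
#'
#' Angles are assigned by lipid class: precursor classes (FA, PA, LPA, LPC,
#' LPE, MG, DG, So) occupy one half of the circle and complex classes (PE,
#' PC, TG, SM, PI, PS, Cer, ChE) the opposite half, with double-bond counts
#' drawn from sector-dependent distributions, so class and saturation
#' enrichment analyses have planted signal.
#'
#' @param n_lipids Number of species (default 120).
#' @param n_conditions Number of treated conditions (default 12; >= 3).
#' @param n_replicates Biological replicates per condition (default 4).
#' @param amplitude Response amplitude on the log2 scale (default 1).
#' @param sigma Replicate noise SD on the log2 scale (default 0.2).
#' @param phases `"grid"` (evenly spaced, default) or `"uniform"` (random,
#'   mimicking irregular inhibitor/timepoint designs).
#' @param edge_threshold Threshold defining the planted adjacency (default
#'   0.76).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline abundance
#'   parameters (defaults `log(1e5)` and 1).
#' @param seed Integer seed; the generator is a pure function of its
#'   parameters and seed.
#' @return List with `matrix` (a `"lipidome_matrix"` including matched
#'   DMSO controls per timepoint) and `truth`: `theta` (named), `phi`
#'   (named, treated conditions), `adjacency` (logical lipid x lipid),
#'   `species`, `edge_threshold`.
#' @export
simulate_lipidome <- function(n_lipids = 120, n_conditions = 12,
                              n_replicates = 4, amplitude = 1, sigma = 0.2,
                              phases = c("grid", "uniform"),
                              edge_threshold = 0.76,
                              baseline_meanlog = log(1e5),
                              baseline_sdlog = 1, seed = 1L) {
  if (n_conditions < 3) stop("need at least 3 conditions")
  phases <- match.arg(phases)
  set.seed(seed)
  theta <- 2 * pi * (seq_len(n_lipids) - 1) / n_lipids
  species <- .simulate_species(theta)
  names(theta) <- species$name
  phi <- if (phases == "grid") 2 * pi * (seq_len(n_conditions) - 1) / n_conditions
         else stats::runif(n_conditions, 0, 2 * pi)

  treatments <- c("C75", "GSKi", "Cerulenin")
  timepoints <- c(3, 6)
  trt <- rep(treatments, length.out = n_conditions)
  tp <- rep(timepoints, each = ceiling(n_conditions / length(timepoints)),
            length.out = n_conditions)
  cond_ids <- sprintf("%s_%gh_%02d", trt, tp, seq_len(n_conditions))
  names(phi) <- cond_ids
  ctrl_ids <- sprintf("DMSO_%gh", timepoints)

  design <- rbind(
    do.call(rbind, lapply(seq_len(n_conditions), function(i)
      data.frame(condition_id = cond_ids[i], treatment = trt[i],
                 dose = "30 uM", timepoint_h = tp[i],
                 sample_id = sprintf("%s_r%d", cond_ids[i],
                                     seq_len(n_replicates)),
                 control_condition_id = sprintf("DMSO_%gh", tp[i])))),
    do.call(rbind, lapply(seq_along(timepoints), function(i)
      data.frame(condition_id = ctrl_ids[i], treatment = "DMSO",
                 dose = "0", timepoint_h = timepoints[i],
                 sample_id = sprintf("%s_r%d", ctrl_ids[i],
                                     seq_len(n_replicates)),
                 control_condition_id = ctrl_ids[i]))))

  baseline <- stats::rlnorm(n_lipids, baseline_meanlog, baseline_sdlog)
  response <- outer(theta, phi, function(th, ph) amplitude * cos(ph - th))
  vals <- matrix(NA_real_, n_lipids, nrow(design),
                 dimnames = list(species$name, design$sample_id))
  for (s in seq_len(nrow(design))) {
    cid <- design$condition_id[s]
    resp <- if (cid %in% cond_ids) response[, cid] else 0
    vals[, s] <- baseline * 2^(resp + stats::rnorm(n_lipids, 0, sigma))
  }
  adjacency <- outer(theta, theta,
                     function(a, b) cos(a - b)) >= edge_threshold
  diag(adjacency) <- FALSE
  list(matrix = lipidome_matrix(vals, design, species = species),
       truth = list(theta = theta, phi = phi, adjacency = adjacency,
                    species = species, edge_threshold = edge_threshold))
}

.precursor_classes <- c("FA", "PA", "LPA", "LPC", "LPE", "MG", "DG", "So")
.complex_classes <- c("PE", "PC", "TG", "SM", "PI", "PS", "Cer", "ChE")

.class_carbons <- list(
  FA = seq(14, 22, 2), PA = seq(30, 40, 2), LPA = seq(16, 22, 2),
  LPC = seq(16, 22, 2), LPE = seq(16, 22, 2), MG = seq(14, 22, 2),
  DG = seq(30, 40, 2), So = seq(16, 20, 2), PE = seq(32, 42, 2),
  PC = seq(32, 42, 2), TG = seq(44, 58, 2), SM = seq(32, 42, 2),
  PI = seq(32, 42, 2), PS = seq(32, 42, 2), Cer = seq(32, 42, 2),
  ChE = seq(16, 22, 2))

# species annotations for lipids at the given angles; precursor sector is
# [0, pi), complex sector the rest; double bonds skew lower in the
# precursor sector
.simulate_species <- function(theta) {
  n <- length(theta)
  precursor <- theta < pi
  cls <- character(n)
  cls[precursor] <- rep(.precursor_classes, length.out = sum(precursor))
  cls[!precursor] <- rep(.complex_classes, length.out = sum(!precursor))
  seen <- character(0)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    carb <- sample(.class_carbons[[cls[i]]], 1)
    db <- if (precursor[i]) sample(0:3, 1, prob = c(0.45, 0.3, 0.15, 0.1))
          else sample(0:6, 1, prob = c(0.2, 0.2, 0.15, 0.15, 0.1, 0.1, 0.1))
    suffix <- if (cls[i] %in% c("PE", "PC") && stats::runif(1) < 0.15 && db > 0)
      "p" else ""
    nm <- sprintf("%s(%d:%d%s)", cls[i], carb, db, suffix)
    while (nm %in% seen) {
      carb <- carb + 2
      nm <- sprintf("%s(%d:%d%s)", cls[i], carb, db, suffix)
    }
    seen <- c(seen, nm)
    rows[[i]] <- nm
  }
  parse_lipid_name(unlist(rows))
}

#' Simulate lipid fold-change time courses with planted groups
#'
#' Four temporal archetypes (sustained rise, sustained fall, transient rise,
#' transient fall) with Gaussian noise on the log2 scale, each instantiated
#' by `n_per_group` lipids. Group 1 is planted all-saturated (0 double
#' bonds) and each other group contains exactly one saturated species, so
#' saturation enrichment has known ground truth.
#'
#' @param n_per_group Lipids per archetype (default 10).
#' @param sigma Noise SD on the log2 scale (default 0.25).
#' @param n_timepoints Number of timepoints (default 6).
#' @param seed Integer seed.
#' @return List with `fc` (an `"fc_matrix"`, conditions `t1..tN`), `truth`
#'   (integer archetype label per lipid) and `species`.
#' @export
simulate_timecourse_lipids <- function(n_per_group = 10, sigma = 0.25,
                                       n_timepoints = 6, seed = 1L) {
  stopifnot(n_per_group >= 1, n_timepoints >= 3)
  set.seed(seed)
  tt <- seq(0, 1, length.out = n_timepoints)
  archetypes <- rbind(
    rise = 2.5 * tt,
    fall = -2.5 * tt,
    transient_up = 2.5 * sin(pi * tt),
    transient_down = -2.5 * sin(pi * tt))
  labels <- rep(1:4, each = n_per_group)
  # group 1 all-saturated; one saturated species seeded into each other group
  db <- ifelse(labels == 1, 0L, 1L + (seq_along(labels) %% 4L))
  first_of <- match(2:4, labels)
  db[first_of] <- 0L
  cls <- rep(c("TG", "PC", "PE", "DG", "FA"), length.out = length(labels))
  carb <- vapply(seq_along(labels), function(i)
    .class_carbons[[cls[i]]][1] + 2 * ((i - 1) %/% 5), numeric(1))
  nms <- sprintf("%s(%d:%d)", cls, carb, db)
  stopifnot(!anyDuplicated(nms))
  vals <- archetypes[labels, ] +
    matrix(stats::rnorm(length(labels) * n_timepoints, 0, sigma),
           length(labels))
  dimnames(vals) <- list(nms, paste0("t", seq_len(n_timepoints)))
  conds <- data.frame(condition_id = colnames(vals),
                      timepoint_h = 3 * seq_len(n_timepoints),
                      is_control = FALSE)
  species <- parse_lipid_name(nms)
  list(fc = fc_matrix(vals, conds, features = species),
       truth = stats::setNames(labels, nms), species = species)
}

#' Simulate a transcriptome coupled to the lipid circle
#'
#' Genes carry coupling angles `psi` grouped into angular modules on the
#' same circle as the lipids, so the expected gene-lipid correlation is
#' `cos(psi_g - theta_l)`. One module is designated stress-responsive; a
#' planted annotation set contains part of that module, a few scattered
#' background genes, and identifiers outside the differential table (as a
#' cross-species annotation set would), so null clusters are neither
#' enriched nor conspicuously depleted. Adjusted p-values are Beta(0.1, 5)
#' for responsive genes and Uniform(0, 1) otherwise — only thresholding
#' behavior matters.
#'
#' @param lipid_truth The `truth` element of [simulate_lipidome()] (condition
#'   phases must match).
#' @param n_genes Number of genes (default 300).
#' @param n_modules Number of angular modules including the stress module
#'   (default 10).
#' @param amplitude Response amplitude (default 1).
#' @param sigma Per-condition noise SD (default 0.3).
#' @param n_set_in_module Planted-set members inside the stress module
#'   (default 15).
#' @param n_set_background Planted-set members scattered over other modules
#'   (default 3).
#' @param n_set_external Set members outside the differential table
#'   (default 42).
#' @param seed Integer seed.
#' @return List with `table` (a `"differential_table"` over the treated
#'   conditions), `gene_sets` (named list, GMT-ready), and `truth` (`psi`,
#'   `module` per gene, `stress_module` index, `responsive` logical).
#' @export
simulate_transcriptome <- function(lipid_truth, n_genes = 300,
                                   n_modules = 10, amplitude = 1,
                                   sigma = 0.3, n_set_in_module = 15,
                                   n_set_background = 3,
                                   n_set_external = 42, seed = 1L) {
  stopifnot(is.list(lipid_truth), !is.null(lipid_truth$phi))
  set.seed(seed)
  phi <- lipid_truth$phi
  centers <- 2 * pi * (seq_len(n_modules) - 1) / n_modules
  module <- rep(seq_len(n_modules), length.out = n_genes)
  module <- sort(module)
  psi <- centers[module] + stats::runif(n_genes, -0.1, 0.1)
  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  names(psi) <- gene_ids
  stress_module <- 1L
  responsive <- module == stress_module
  vals <- outer(psi, phi, function(ps, ph) amplitude * cos(ph - ps)) +
    matrix(stats::rnorm(n_genes * length(phi), 0, sigma), n_genes)
  dimnames(vals) <- list(gene_ids, names(phi))
  padj <- ifelse(responsive, stats::rbeta(n_genes, 0.1, 5),
                 stats::runif(n_genes))
  n_set_in_module <- min(n_set_in_module, sum(responsive))
  n_set_background <- min(n_set_background, sum(!responsive))
  in_module <- sample(gene_ids[responsive], n_set_in_module)
  background <- sample(gene_ids[!responsive], n_set_background)
  external <- sprintf("EXT%04d", seq_len(n_set_external))
  gene_sets <- list(stress_response = c(in_module, background, external))
  list(table = differential_table(vals, padj), gene_sets = gene_sets,
       truth = list(psi = psi, module = stats::setNames(module, gene_ids),
                    stress_module = stress_module, responsive = responsive,
                    set_members = gene_sets$stress_response))
}

#' Simulate a phenotype driven by one lipid module
#'
#' Per-condition phenotype (scaled to 0-100, e.g. percent S-phase cells) as
#' an affine function of `cos(phi_c - pro_angle)` plus noise: lipids near
#' `pro_angle` correlate positively with the phenotype, opposite lipids
#' negatively. Control conditions sit at the midpoint.
#'
#' @param lipid_truth The `truth` element of [simulate_lipidome()].
#' @param pro_angle Angle of the pro-phenotype lipid module (default 0).
#' @param noise Additive noise SD in phenotype units (default 3).
#' @param seed Integer seed.
#' @return Named numeric vector over treated conditions.
#' @export
simulate_phenotype <- function(lipid_truth, pro_angle = 0, noise = 3,
                               seed = 1L) {
  set.seed(seed)
  phi <- lipid_truth$phi
  p <- 50 + 35 * cos(phi - pro_angle) + stats::rnorm(length(phi), 0, noise)
  pmin(pmax(p, 0), 100)
}

#' Simulate a fixed-cell population for gating
#'
#' Per-cell records with programmed cell-cycle composition: DNA content
#' around 1 (G0/1), spread between 1 and 2 (S) or around 2 (G2) units, and
#' EdU intensity high only in S cells. Class counts are exact
#' (`round(fraction * n)`), so the programmed fractions are a property of
#' the emitted population.
#'
#' @param n Number of cells (default 5000).
#' @param frac_s,frac_g2 S and G2 fractions (defaults 0.25, 0.2); the rest
#'   is G0/1.
#' @param seed Integer seed.
#' @return List with `records` (a `"cell_records"` data frame with
#'   `dna_content`, `nuc_edu`) and `truth` (phase factor).
#' @export
simulate_cell_records <- function(n = 5000, frac_s = 0.25, frac_g2 = 0.2,
                                  seed = 1L) {
  stopifnot(frac_s >= 0, frac_g2 >= 0, frac_s + frac_g2 <= 1)
  set.seed(seed)
  n_s <- round(frac_s * n); n_g2 <- round(frac_g2 * n)
  phase <- sample(rep(c("S", "G2", "G0/1"), c(n_s, n_g2, n - n_s - n_g2)))
  dna <- ifelse(phase == "G0/1", stats::rnorm(n, 1, 0.05),
         ifelse(phase == "G2", stats::rnorm(n, 2, 0.1),
                stats::runif(n, 1.1, 1.9)))
  edu <- ifelse(phase == "S", stats::rlnorm(n, log(500), 0.3),
                stats::rlnorm(n, log(30), 0.3))
  records <- data.frame(cell_id = seq_len(n), dna_content = dna * 1e4,
                        nuc_edu = edu)
  class(records) <- c("cell_records", "data.frame")
  list(records = records, truth = factor(phase, c("G0/1", "S", "G2")))
}

#' Simulate multichannel microscopy images with known ground truth
#'
#' Lays non-overlapping nuclei on a jittered grid with margins wide enough
#' that every cell's cytoplasmic sampling ring is uncontested, then renders
#' four channels: DNA (total intensity equal to the programmed DNA
#' content), CDK reporter (nuclear disk at a base intensity, cytoplasm at
#' base times the programmed ratio), EdU (high in programmed S cells) and a
#' generic marker. Gaussian noise is added to every channel.
#'
#' @param n_cells Number of cells (default 40).
#' @param size Canvas side in pixels (default 512).
#' @param radius_range Nucleus radius range in pixels (default `c(8, 12)`).
#' @param ratio_range True CDK-activity ratio range (default `c(0.3, 2.2)`).
#' @param frac_s Fraction of EdU-positive (S) cells, exact count (default
#'   0.25).
#' @param noise_sd Gaussian noise SD in intensity units (default 3).
#' @param cfg An `"imaging_config"`; ring geometry sets the exclusion
#'   margin.
#' @param seed Integer seed; identical seeds give identical images.
#' @return List with `channels` (named list of matrices: `dna`, `reporter`,
#'   `edu`, `marker`) and `truth` (data frame: `cell_id`, `centroid_x`,
#'   `centroid_y`, `radius`, `cdk_true`, `dna_true`, `s_phase`).
#' @export
simulate_images <- function(n_cells = 40, size = 512,
                            radius_range = c(8, 12),
                            ratio_range = c(0.3, 2.2), frac_s = 0.25,
                            noise_sd = 3, cfg = imaging_config(),
                            seed = 1L) {
  set.seed(seed)
  px <- .ring_px(cfg)
  r_max <- radius_range[2]
  cyto_r <- r_max + px["outer"] + 2
  pitch <- 2 * cyto_r + 2 * px["outer"] + 4
  per_side <- floor((size - 2 * cyto_r) / pitch)
  if (per_side^2 < n_cells)
    stop(sprintf("cannot pack %d cells of effective radius %d on a %dx%d canvas",
                 n_cells, cyto_r, size, size))
  centers <- expand.grid(
    x = cyto_r + pitch * (seq_len(per_side) - 0.5),
    y = cyto_r + pitch * (seq_len(per_side) - 0.5))
  centers <- centers[sample(nrow(centers), n_cells), ]
  jit <- (pitch - 2 * cyto_r - 2 * px["outer"]) / 2
  centers$x <- round(centers$x + stats::runif(n_cells, -jit, jit))
  centers$y <- round(centers$y + stats::runif(n_cells, -jit, jit))

  radius <- round(stats::runif(n_cells, radius_range[1], radius_range[2]))
  ratio <- stats::runif(n_cells, ratio_range[1], ratio_range[2])
  dna_units <- sample(rep(c(1, 2), length.out = n_cells)) +
    stats::rnorm(n_cells, 0, 0.03)
  n_s <- round(frac_s * n_cells)
  s_phase <- sample(rep(c(TRUE, FALSE), c(n_s, n_cells - n_s)))
  nuc_base <- 300

  blank <- function() matrix(0, size, size)
  dna <- blank(); reporter <- blank(); edu <- blank(); marker <- blank()
  row_i <- row(blank()); col_j <- col(blank())
  dna_true <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    d2 <- (row_i - centers$x[i])^2 + (col_j - centers$y[i])^2
    nuc <- d2 <= radius[i]^2
    cyto <- d2 <= cyto_r^2 & !nuc
    area <- sum(nuc)
    dna_val <- dna_units[i] * 2e4 / area
    dna[nuc] <- dna_val
    dna_true[i] <- dna_val * area
    reporter[nuc] <- nuc_base
    reporter[cyto] <- nuc_base * ratio[i]
    edu[nuc] <- if (s_phase[i]) 500 else 30
    marker[nuc] <- if (stats::runif(1) < 0.5) 400 else 100
  }
  addnoise <- function(img)
    pmax(img + matrix(stats::rnorm(size^2, 0, noise_sd), size), 0)
  list(channels = list(dna = addnoise(dna), reporter = addnoise(reporter),
                       edu = addnoise(edu), marker = addnoise(marker)),
       truth = data.frame(cell_id = seq_len(n_cells),
                          centroid_x = centers$x, centroid_y = centers$y,
                          radius = radius, cdk_true = ratio,
                          dna_true = dna_true, s_phase = s_phase))
}

#' Simulate CDK-activity / degron reporter traces
#'
#' Emits linked per-cell time series with programmed outcomes. Archetypes:
#' G1 cells ramp through the 0.4-0.6 activity window at the treatment
#' frame, after which programmed S-entry cells keep rising across 1.0 while
#' their degron reporter ramps past 100, and non-entry cells decay;
#' quiescent cells plateau near 0.2; G2 cells plateau at 1.4-1.6 and
#' programmed mitotic cells undergo an annotated mitosis (activity reset)
#' after treatment. Outcome counts are exact (`round(fraction * n)`), and a
#' programmed S-entry trace always crosses 1.0.
#'
#' @param n_cells Number of traces (default 500).
#' @param n_frames Frames per trace (default 80).
#' @param treatment_frame Treatment frame index (default 21).
#' @param interval_min Sampling interval in minutes (default 12).
#' @param frac_s_entry Programmed S-entry fraction among G1 cells (default
#'   0.3).
#' @param frac_mitosis Programmed mitosis fraction among G2 cells (default
#'   0.8).
#' @param frac_defect Programmed mitotic-defect fraction among mitotic
#'   cells (default 0).
#' @param mix Named proportions of archetypes `g1`, `quiescent`, `g2`
#'   (default all G1).
#' @param noise_cdk,noise_degron Additive noise SDs (defaults 0.02, 3).
#' @param seed Integer seed.
#' @return List with `traces` (a `"trace_set"`) and `truth` (data frame:
#'   `cell_id`, `archetype`, `s_entry`, `mitosis`, `defect`).
#' @export
simulate_traces <- function(n_cells = 500, n_frames = 80,
                            treatment_frame = 21, interval_min = 12,
                            frac_s_entry = 0.3, frac_mitosis = 0.8,
                            frac_defect = 0,
                            mix = c(g1 = 1, quiescent = 0, g2 = 0),
                            noise_cdk = 0.02, noise_degron = 3, seed = 1L) {
  stopifnot(all(c(frac_s_entry, frac_mitosis, frac_defect) >= 0),
            all(c(frac_s_entry, frac_mitosis, frac_defect) <= 1),
            treatment_frame >= 2, treatment_frame < n_frames)
  set.seed(seed)
  mix <- mix / sum(mix)
  counts <- round(n_cells * mix)
  counts[1] <- n_cells - sum(counts[-1])
  archetype <- sample(rep(names(mix), counts))
  tpost <- n_frames - treatment_frame

  cdk <- matrix(NA_real_, n_cells, n_frames)
  degron <- matrix(20, n_cells, n_frames)
  mitosis <- rep(list(integer(0)), n_cells)
  g1_idx <- which(archetype == "g1")
  n_entry <- round(frac_s_entry * length(g1_idx))
  s_entry <- logical(n_cells)
  s_entry[sample(g1_idx, n_entry)] <- TRUE
  g2_idx <- which(archetype == "g2")
  n_mit <- round(frac_mitosis * length(g2_idx))
  mitotic <- logical(n_cells)
  if (length(g2_idx)) mitotic[sample(g2_idx, n_mit)] <- TRUE
  defect <- logical(n_cells)
  mit_cells <- which(mitotic)
  if (length(mit_cells) && frac_defect > 0)
    defect[sample(mit_cells, round(frac_defect * length(mit_cells)))] <- TRUE

  frames <- seq_len(n_frames)
  for (i in seq_len(n_cells)) {
    if (archetype[i] == "quiescent") {
      cdk[i, ] <- 0.2
    } else if (archetype[i] == "g2") {
      base <- stats::runif(1, 1.4, 1.6)
      cdk[i, ] <- base
      if (mitotic[i]) {
        tm <- sample(seq(treatment_frame + 2L, n_frames - 1L), 1)
        cdk[i, tm:n_frames] <- 0.3
        mitosis[[i]] <- tm
      }
    } else {
      b <- stats::runif(1, 0.42, 0.58)
      pre <- pmax(b - 0.01 * (treatment_frame - frames), 0.2)
      if (s_entry[i]) {
        slope <- stats::runif(1, 0.015, 0.03)
        post <- pmin(b + slope * (frames - treatment_frame), 1.6)
        # degron ramps once activity commits (crossing ~0.9)
        t_s <- treatment_frame + ceiling((0.9 - b) / slope)
        deg <- pmin(20 + 8 * pmax(frames - t_s, 0), 350)
        degron[i, ] <- deg
      } else {
        post <- pmax(b - 0.004 * (frames - treatment_frame), 0.15)
      }
      cdk[i, ] <- ifelse(frames <= treatment_frame, pre, post)
    }
  }
  cdk <- cdk + matrix(stats::rnorm(n_cells * n_frames, 0, noise_cdk), n_cells)
  degron <- degron +
    matrix(stats::rnorm(n_cells * n_frames, 0, noise_degron), n_cells)
  list(traces = trace_set(cdk, degron, interval_min, treatment_frame,
                          mitosis, defect),
       truth = data.frame(cell_id = seq_len(n_cells), archetype = archetype,
                          s_entry = s_entry, mitosis = mitotic,
                          defect = defect))
}
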