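#' Gating configuration
#'
#' Windows and thresholds for cell-cycle phase gating of fixed-cell records
#' and for live-trace outcome calling. DNA windows are expressed in
#' G1-peak-normalized units (the G1 mode is scaled to 1 internally before
#' gating). `edu_threshold = NULL` requests an automatic Otsu threshold on
#' log intensities. Trace bins select cells by CDK activity at the
#' treatment frame: 0.4-0.6 captures G0/G1 cells, 1.0-1.2 S-phase cells,
#' 1.4-1.6 G2 cells. A cell counts as committing to the cycle when its
#' post-treatment CDK activity exceeds `cdk_rise` (1.0) and as starting S
#' phase when its degron reporter exceeds `degron_rise` (100 a.u.).
#'
#' @param g1_window,g2_window DNA-content windows (normalized units).
#' @param edu_threshold EdU intensity threshold, or `NULL` for automatic.
#' @param marker_thresholds Named numeric vector of per-marker thresholds.
#' @param cdk_rise,degron_rise Post-treatment rise thresholds for traces.
#' @return A list of class `"gating_config"`.
#' @export
gating_config <- function(g1_window = c(0.75, 1.25), g2_window = c(1.5, 2.5),
                          edu_threshold = NULL, marker_thresholds = NULL,
                          cdk_rise = 1.0, degron_rise = 100) {
  stopifnot(length(g1_window) == 2, g1_window[1] < g1_window[2],
            length(g2_window) == 2, g2_window[1] < g2_window[2],
            is.finite(cdk_rise), is.finite(degron_rise))
  structure(list(g1_window = g1_window, g2_window = g2_window,
                 edu_threshold = edu_threshold,
                 marker_thresholds = marker_thresholds,
                 cdk_rise = cdk_rise, degron_rise = degron_rise),
            class = "gating_config")
}

# 1-D Otsu threshold on a numeric vector (histogram with nbins bins)
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (rng[2] <= rng[1]) return(rng[1])
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = nbins + 1),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# mode of the G1 peak: leftmost density maximum at >= 25% of the global max
.g1_mode <- function(dna) {
  d <- stats::density(dna, n = 512)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  if (!length(peaks)) return(d$x[which.max(d$y)])
  prominent <- peaks[d$y[peaks] >= 0.25 * max(d$y)]
  d$x[min(prominent)]
}

#' Gate fixed-cell records into cell-cycle phases
#'
#' DNA content is first normalized so the G1 peak mode equals 1 (leftmost
#' prominent mode of its density). Cells with EdU signal above threshold are
#' S phase regardless of DNA content; remaining cells fall into G0/1 or G2
#' by their DNA window, and anything else is unclassified. Marker-positive
#' percentages are reported for each configured marker threshold.
#'
#' @param records A `"cell_records"` data frame (needs `dna_content`; EdU is
#'   read from `nuc_edu` or an `edu` column; markers from `nuc_<marker>`
#'   columns).
#' @param cfg A `"gating_config"`.
#' @return A list of class `"gating_result"`: `phase` (factor per cell:
#'   `G0/1`, `S`, `G2`, `unclassified`), `dna_norm`, `edu_threshold`,
#'   `summary` (percentages per phase and per marker), `n`.
#' @export
gate_fixed <- function(records, cfg = gating_config()) {
  if (!nrow(records)) stop("no cell records to gate")
  stopifnot("dna_content" %in% names(records))
  edu_col <- intersect(c("nuc_edu", "edu"), names(records))[1]
  if (is.na(edu_col)) stop("records carry no EdU measurement")
  dna <- records$dna_content
  dna_norm <- dna / .g1_mode(dna)
  edu <- records[[edu_col]]
  thr <- cfg$edu_threshold
  if (is.null(thr)) thr <- exp(otsu_threshold(log(pmax(edu, 1e-9))))
  phase <- rep("unclassified", nrow(records))
  phase[edu > thr] <- "S"
  low <- edu <= thr
  phase[low & dna_norm >= cfg$g1_window[1] & dna_norm <= cfg$g1_window[2]] <- "G0/1"
  phase[low & dna_norm >= cfg$g2_window[1] & dna_norm <= cfg$g2_window[2]] <- "G2"
  phase <- factor(phase, levels = c("G0/1", "S", "G2", "unclassified"))
  summary <- as.list(100 * prop.table(table(phase)))
  names(summary) <- paste0("pct_", c("g01", "s", "g2", "unclassified"))
  for (m in names(cfg$marker_thresholds)) {
    col <- paste0("nuc_", m)
    if (col %in% names(records))
      summary[[paste0("pct_", m, "_positive")]] <-
        100 * mean(records[[col]] > cfg$marker_thresholds[[m]])
  }
  structure(list(phase = phase, dna_norm = dna_norm, edu_threshold = thr,
                 summary = summary, n = nrow(records)),
            class = "gating_result")
}

#' Construct a trace set
#'
#' Per-cell time series sampled at a fixed interval: CDK-activity and degron
#' reporter levels, annotated mitosis frames, and the frame at which
#' treatment was applied. Cells are consumed already linked (tracked).
#'
#' @param cdk,degron Cells x frames numeric matrices (equal shape).
#' @param interval_min Sampling interval in minutes (default 12).
#' @param treatment_frame Frame index of treatment (1-based, strictly inside
#'   the series so post-treatment frames exist).
#' @param mitosis List (per cell) of integer frame indices of mitosis
#'   events; `NULL` for none.
#' @param defect Optional logical per-cell mitotic-defect flag, passed
#'   through to summaries (defect subtyping is not algorithmized).
#' @return A list of class `"trace_set"`.
#' @export
trace_set <- function(cdk, degron, interval_min = 12, treatment_frame,
                      mitosis = NULL, defect = NULL) {
  stopifnot(is.matrix(cdk), identical(dim(cdk), dim(degron)),
            treatment_frame >= 1, treatment_frame < ncol(cdk))
  if (is.null(mitosis)) mitosis <- rep(list(integer(0)), nrow(cdk))
  stopifnot(length(mitosis) == nrow(cdk))
  structure(list(cdk = cdk, degron = degron, interval_min = interval_min,
                 treatment_frame = as.integer(treatment_frame),
                 mitosis = mitosis, defect = defect),
            class = "trace_set")
}

#' Call outcomes for traces binned by activity at treatment
#'
#' Selects cells whose CDK activity at the treatment frame lies within
#' `bin`, then reports: the fraction whose post-treatment CDK activity
#' rises above `cdk_rise` (cycle commitment), the fraction whose
#' post-treatment degron level rises above `degron_rise` (S-phase start),
#' and the fraction with at least one annotated mitosis event after
#' treatment.
#'
#' @param traces A `"trace_set"`.
#' @param cfg A `"gating_config"` (rise thresholds).
#' @param bin Length-2 numeric activity window, e.g. `c(0.4, 0.6)`.
#' @return A list of class `"trace_outcomes"`: `n_selected`, `bin`,
#'   `frac_cdk_rise`, `frac_degron_rise`, `frac_mitosis`, plus
#'   `frac_defect` when defect flags are present, and the per-cell logical
#'   vectors (`cdk_positive`, `degron_positive`, `mitotic`) with `selected`
#'   indices.
#' @export
call_trace_outcomes <- function(traces, cfg = gating_config(), bin) {
  stopifnot(inherits(traces, "trace_set"), length(bin) == 2, bin[1] < bin[2])
  at_treat <- traces$cdk[, traces$treatment_frame]
  selected <- which(at_treat >= bin[1] & at_treat <= bin[2])
  if (!length(selected))
    stop(sprintf("no cells in activity bin [%g, %g] at treatment (n = 0 of %d)",
                 bin[1], bin[2], nrow(traces$cdk)))
  post <- seq(traces$treatment_frame + 1L, ncol(traces$cdk))
  cdk_pos <- apply(traces$cdk[selected, post, drop = FALSE], 1, max) >
    cfg$cdk_rise
  deg_pos <- apply(traces$degron[selected, post, drop = FALSE], 1, max) >
    cfg$degron_rise
  mit <- vapply(traces$mitosis[selected],
                function(f) any(f > traces$treatment_frame), logical(1))
  out <- list(n_selected = length(selected), bin = bin,
              frac_cdk_rise = mean(cdk_pos), frac_degron_rise = mean(deg_pos),
              frac_mitosis = mean(mit), selected = selected,
              cdk_positive = cdk_pos, degron_positive = deg_pos,
              mitotic = mit)
  if (!is.null(traces$defect))
    out$frac_defect <- mean(traces$defect[selected] & mit)
  structure(out, class = "trace_outcomes")
}

#' @export
print.trace_outcomes <- function(x, ...) {
  cat(sprintf(
    "trace_outcomes: n = %d in bin [%g, %g]; CDK rise %.1f%%, degron rise %.1f%%, mitosis %.1f%%\n",
    x$n_selected, x$bin[1], x$bin[2], 100 * x$frac_cdk_rise,
    100 * x$frac_degron_rise, 100 * x$frac_mitosis))
  invisible(x)
}
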