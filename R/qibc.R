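#' Imaging configuration
#'
#' Geometry and thresholds for the fixed- and live-cell quantification
#' pipeline. The cytoplasmic sampling ring spans `ring_inner` to
#' `ring_outer` micrometers outward from the nuclear boundary (defaults
#' 0.65 and 3.25 um). `pixel_size` converts those radii to pixels (rounded
#' half-up); the default 0.65 um/px corresponds to a 6.5 um camera pixel at
#' 10x magnification and should be overridden to match the instrument.
#'
#' @param pixel_size Micrometers per pixel (> 0).
#' @param ring_inner,ring_outer Ring radii in micrometers,
#'   `ring_outer > ring_inner > 0`.
#' @param background_percentile Percentile (0-100) of the corrected image
#'   used as the global background scalar.
#' @param min_area,max_area Nucleus area bounds in pixels.
#' @return A list of class `"imaging_config"`.
#' @export
imaging_config <- function(pixel_size = 0.65, ring_inner = 0.65,
                           ring_outer = 3.25, background_percentile = 1,
                           min_area = 20, max_area = 5000) {
  stopifnot(pixel_size > 0, ring_inner > 0, ring_outer > ring_inner,
            background_percentile >= 0, background_percentile <= 100,
            min_area >= 1, max_area > min_area)
  structure(list(pixel_size = pixel_size, ring_inner = ring_inner,
                 ring_outer = ring_outer,
                 background_percentile = background_percentile,
                 min_area = min_area, max_area = max_area),
            class = "imaging_config")
}

# ring radii in integer pixels (rounded half-up)
.ring_px <- function(cfg) {
  c(inner = floor(cfg$ring_inner / cfg$pixel_size + 0.5),
    outer = floor(cfg$ring_outer / cfg$pixel_size + 0.5))
}

#' Illumination and background correction
#'
#' Divides the raw image by its (mean-normalized) illumination profile, then
#' subtracts a global background scalar — the configured low percentile of
#' the corrected image — clipping at zero.
#'
#' @param raw Numeric matrix (one channel).
#' @param illumination_profile Optional strictly positive matrix of the same
#'   shape; `NULL` skips flat-fielding.
#' @param cfg An `"imaging_config"`.
#' @return Corrected matrix, same shape, non-negative.
#' @export
correct_image <- function(raw, illumination_profile = NULL,
                          cfg = imaging_config()) {
  stopifnot(is.matrix(raw))
  img <- raw
  if (!is.null(illumination_profile)) {
    if (!identical(dim(illumination_profile), dim(raw)))
      stop("illumination profile shape does not match image")
    if (any(illumination_profile <= 0))
      stop("illumination profile must be strictly positive")
    img <- img / (illumination_profile / mean(illumination_profile))
  }
  bg <- stats::quantile(img, cfg$background_percentile / 100, names = FALSE)
  pmax(img - bg, 0)
}

#' Segment nuclei from a DNA-channel image
#'
#' Global Otsu threshold on log-transformed intensities (log compression
#' keeps the split at the background/foreground boundary even when nuclear
#' intensities span the 2x range between G1 and G2 DNA content),
#' connected-component labelling, then an area filter. Labels are
#' renumbered 1..N in raster order. An empty mask (no nuclei) is valid.
#'
#' @param dna_image Corrected DNA-channel matrix (non-negative).
#' @param cfg An `"imaging_config"` (area bounds).
#' @return Integer label matrix, 0 = background.
#' @export
segment_nuclei <- function(dna_image, cfg = imaging_config()) {
  stopifnot(is.matrix(dna_image))
  lg <- log1p(pmax(dna_image, 0))
  rng <- range(lg)
  if (rng[2] <= rng[1]) return(matrix(0L, nrow(dna_image), ncol(dna_image)))
  scaled <- (lg - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  mask <- EBImage::bwlabel(scaled > thr)
  labels <- matrix(as.integer(EBImage::imageData(mask)),
                   nrow(dna_image), ncol(dna_image))
  areas <- tabulate(labels)
  keep <- which(areas >= cfg$min_area & areas <= cfg$max_area)
  relab <- integer(max(labels, 1L))
  relab[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0] <- relab[labels[labels > 0]]
  out
}

#' Per-cell measurements with neighbor-exclusive ring sampling
#'
#' For each labelled nucleus: median nuclear intensity per channel, median
#' intensity over a cytoplasmic ring, total DNA-channel intensity
#' (`dna_content`), and the CDK-activity ratio (ring median / nuclear median
#' of the reporter channel). The ring is the set of pixels whose distance
#' from the cell's nuclear boundary lies within the configured radii,
#' excluding pixels inside any nucleus and pixels within `ring_outer` of a
#' different nucleus — so no ring pixel can carry a neighboring cell's
#' cytoplasm. Cells whose ring is empty (crowding) are flagged
#' (`ring_ok = FALSE`) with `NA` ratios and should be excluded from ratio
#' statistics.
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param channels Named list of channel matrices aligned with `labels`;
#'   must include `dna`; `reporter` enables `cdk_activity`.
#' @param cfg An `"imaging_config"`.
#' @return Data frame of class `"cell_records"`: `cell_id`, `centroid_x`,
#'   `centroid_y` (pixel coordinates, row/col), `nucleus_area`,
#'   `dna_content`, `cdk_activity`, `ring_ok`, plus `nuc_<channel>` and
#'   `ring_<channel>` medians.
#' @export
measure_cells <- function(labels, channels, cfg = imaging_config()) {
  stopifnot(is.matrix(labels), is.list(channels), "dna" %in% names(channels))
  for (ch in channels) stopifnot(identical(dim(ch), dim(labels)))
  n <- max(labels)
  if (n == 0) {
    return(structure(data.frame(), class = c("cell_records", "data.frame")))
  }
  rings <- compute_rings(labels, cfg)
  rows <- lapply(seq_len(n), function(i) {
    sel <- labels == i
    idx <- which(sel, arr.ind = TRUE)
    ring <- rings[[i]]
    ring_ok <- any(ring)
    nuc_med <- vapply(channels, function(ch) stats::median(ch[sel]),
                      numeric(1))
    ring_med <- vapply(channels, function(ch)
      if (ring_ok) stats::median(ch[ring]) else NA_real_, numeric(1))
    cdk <- if ("reporter" %in% names(channels) && ring_ok &&
               nuc_med[["reporter"]] > 0)
      ring_med[["reporter"]] / nuc_med[["reporter"]] else NA_real_
    out <- data.frame(cell_id = i, centroid_x = mean(idx[, 1]),
                      centroid_y = mean(idx[, 2]), nucleus_area = sum(sel),
                      dna_content = sum(channels$dna[sel]),
                      cdk_activity = cdk, ring_ok = ring_ok)
    for (nm in names(channels)) {
      out[[paste0("nuc_", nm)]] <- nuc_med[[nm]]
      out[[paste0("ring_", nm)]] <- ring_med[[nm]]
    }
    out
  })
  structure(do.call(rbind, rows), class = c("cell_records", "data.frame"))
}

#' Neighbor-exclusive cytoplasmic ring masks
#'
#' The ring of cell `i` is the set of pixels whose Euclidean distance from
#' the cell's nuclear boundary lies within the configured radii, excluding
#' pixels inside any nucleus and pixels within `ring_outer` of a different
#' nucleus (contested pixels). By construction no ring pixel belongs to any
#' nucleus or to two cells' rings.
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param cfg An `"imaging_config"`.
#' @return List of logical masks, one per cell label.
#' @export
compute_rings <- function(labels, cfg = imaging_config()) {
  stopifnot(is.matrix(labels))
  n <- max(labels)
  if (n == 0) return(list())
  px <- .ring_px(cfg)
  any_nuc <- labels > 0
  # distance from every pixel to the nearest pixel of each nucleus
  dists <- lapply(seq_len(n), function(i) .distance_to_mask(labels == i))
  # pixels within ring_outer of >= 2 nuclei are contested and dropped
  within_outer <- Reduce(`+`, lapply(dists, function(d) d <= px["outer"]))
  lapply(seq_len(n), function(i) {
    d <- dists[[i]]
    d >= px["inner"] & d <= px["outer"] & !any_nuc & within_outer == 1
  })
}

# Euclidean distance of every pixel to the nearest TRUE pixel of a mask.
# EBImage::distmap measures foreground-to-background distance, so the mask
# is inverted: distance of non-mask pixels to the mask; mask pixels get 0.
.distance_to_mask <- function(mask) {
  d <- EBImage::distmap(EBImage::Image(!mask), metric = "euclidean")
  matrix(as.numeric(EBImage::imageData(d)), nrow(mask), ncol(mask))
}

#' Nuclear puncta count per cell
#'
#' Number of foreground pixels — pixels exceeding the threshold on a
#' background-subtracted channel — within each nucleus label.
#'
#' @param channel Background-subtracted channel matrix.
#' @param labels Label matrix from [segment_nuclei()].
#' @param threshold Foreground threshold.
#' @return Integer vector of counts, one per cell label.
#' @export
puncta_count <- function(channel, labels, threshold) {
  stopifnot(identical(dim(channel), dim(labels)))
  n <- max(labels)
  if (n == 0) return(integer(0))
  fg <- channel > threshold & labels > 0
  counts <- tabulate(labels[fg], nbins = n)
  as.integer(counts)
}

#' Read / write single-channel 16-bit TIFF
#'
#' Intensities are stored as 16-bit grayscale; values are scaled by
#' `2^16 - 1` on write and restored on read.
#'
#' @param path File path.
#' @param img Numeric matrix with values in `[0, 65535]`.
#' @return A numeric matrix (read) or `path` invisibly (write).
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  img * 65535
}

#' @rdname read_image_tiff
#' @export
write_image_tiff <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0), all(img <= 65535))
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
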