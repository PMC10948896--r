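#' Normalize each sample by its total lipid signal
#'
#' Divides every sample column by its sum so each column sums to 1.
#' Relative proportions within a column are preserved; the operation is
#' idempotent. The normalization target (1) is arbitrary: any constant
#' cancels in downstream fold-change ratios.
#'
#' @param m A `"lipidome_matrix"`.
#' @return A `"lipidome_matrix"` with unit column sums.
#' @export
normalize_total_signal <- function(m) {
  stopifnot(inherits(m, "lipidome_matrix"))
  sums <- colSums(m$values)
  if (any(sums <= 0))
    stop("sample(s) with non-positive total signal: ",
         paste(colnames(m$values)[sums <= 0], collapse = ", "))
  m$values <- sweep(m$values, 2, sums, "/")
  m
}

#' Average replicates within each condition
#'
#' Arithmetic mean of the replicate sample columns of each condition, on the
#' (typically normalized) abundance scale.
#'
#' @param m A `"lipidome_matrix"`.
#' @return An object of class `"condition_matrix"`: list with `values`
#'   (species x conditions), `species`, and `conditions` (one row per
#'   condition, see [design_conditions()]).
#' @export
average_replicates <- function(m) {
  stopifnot(inherits(m, "lipidome_matrix"))
  conds <- design_conditions(m$design)
  vals <- vapply(conds$condition_id, function(cid) {
    cols <- .condition_samples(m$design, cid)
    rowMeans(m$values[, cols, drop = FALSE])
  }, numeric(nrow(m$values)))
  dimnames(vals) <- list(rownames(m$values), conds$condition_id)
  structure(list(values = vals, species = m$species, conditions = conds),
            class = "condition_matrix")
}

#' Log2 fold-change against time-matched vehicle controls
#'
#' For every condition, computes per species `log2(value / control value)`
#' where the control is the condition's matched vehicle at the same
#' timepoint. Control conditions yield identically zero columns. Zero
#' condition-means are replaced, with a warning, by half the smallest
#' positive mean of that species across conditions so all fold-changes stay
#' finite; a species that is zero everywhere cannot be rescued and raises an
#' error.
#'
#' @param cm A `"condition_matrix"` from [average_replicates()].
#' @return An object of class `"fc_matrix"`: list with `values` (features x
#'   conditions log2 fold-change), `conditions` (with `is_control` flags),
#'   and `features`.
#' @export
log2_fold_change <- function(cm) {
  stopifnot(inherits(cm, "condition_matrix"))
  vals <- cm$values
  if (any(vals == 0)) {
    repl <- apply(vals, 1, function(r) {
      pos <- r[r > 0]
      if (!length(pos)) NA_real_ else min(pos) / 2
    })
    dead <- rownames(vals)[is.na(repl) & rowSums(vals == 0) > 0]
    if (length(dead))
      stop("species with all-zero abundance: ", paste(dead, collapse = ", "))
    nz <- sum(vals == 0)
    vals[vals == 0] <- repl[row(vals)[vals == 0]]
    warning(sprintf(
      "%d zero condition-mean(s) imputed as half the species' minimum positive value", nz))
  }
  conds <- cm$conditions
  ctrl_idx <- match(conds$control_condition_id, conds$condition_id)
  if (anyNA(ctrl_idx))
    stop("condition(s) without a matched control: ",
         paste(conds$condition_id[is.na(ctrl_idx)], collapse = ", "))
  fc <- log2(vals / vals[, ctrl_idx, drop = FALSE])
  fc[, conds$is_control] <- 0  # exact zeros for self-referential controls
  structure(list(values = fc, conditions = conds, features = cm$species),
            class = "fc_matrix")
}

#' Full preprocessing: normalize, average, fold-change
#'
#' Convenience composition of [normalize_total_signal()],
#' [average_replicates()] and [log2_fold_change()], the stated order of the
#' pipeline: normalization per replicate, replicate averaging, then log2
#' transform against the time-matched control.
#'
#' @param m A `"lipidome_matrix"`.
#' @return An `"fc_matrix"`.
#' @export
preprocess_lipidome <- function(m) {
  log2_fold_change(average_replicates(normalize_total_signal(m)))
}

#' Construct a fold-change matrix from components
#'
#' For callers that already hold a features-by-conditions log2 fold-change
#' table (e.g. a differential-expression table restricted to shared
#' conditions).
#'
#' @param values Numeric matrix with rownames (features) and colnames
#'   (condition ids).
#' @param conditions Optional condition metadata (`condition_id`,
#'   `timepoint_h`, `is_control`); minimal metadata is synthesized when
#'   omitted, treating all conditions as treated.
#' @param features Optional feature annotation data frame.
#' @return An `"fc_matrix"`.
#' @export
fc_matrix <- function(values, conditions = NULL, features = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)), all(is.finite(values)))
  if (is.null(conditions))
    conditions <- data.frame(condition_id = colnames(values),
                             timepoint_h = NA_real_, is_control = FALSE,
                             stringsAsFactors = FALSE)
  stopifnot(identical(conditions$condition_id, colnames(values)))
  structure(list(values = values, conditions = conditions,
                 features = features),
            class = "fc_matrix")
}

#' Write / read a fold-change matrix as TSV
#'
#' @param fc An `"fc_matrix"`.
#' @param path File path.
#' @return `path` (write) or an `"fc_matrix"` (read; condition metadata is
#'   reconstructed minimally with all-zero columns flagged as controls).
#' @export
write_fc_table <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  .write_feature_table(fc$values, "feature_id", path)
}

#' @rdname write_fc_table
#' @export
read_fc_table <- function(path) {
  d <- .read_delim_auto(path)
  vals <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(d[[1]])
  conds <- data.frame(condition_id = colnames(vals), timepoint_h = NA_real_,
                      is_control = apply(vals == 0, 2, all),
                      stringsAsFactors = FALSE)
  fc_matrix(vals, conds)
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("fc_matrix: %d features x %d conditions (%d control)\n",
              nrow(x$values), ncol(x$values), sum(x$conditions$is_control)))
  invisible(x)
}
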