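#' Read a condition design table
#'
#' The design table lists one row per sample with columns `condition_id`,
#' `treatment`, `dose`, `timepoint_h`, `sample_id` and
#' `control_condition_id`. Control (vehicle) conditions reference themselves
#' in `control_condition_id`. Comma or tab delimiting is autodetected from
#' the first line.
#'
#' @param path Path to a CSV/TSV design file.
#' @return A validated `data.frame` of class `"condition_design"`.
#' @seealso [validate_design()]
#' @export
read_design <- function(path) {
  d <- .read_delim_auto(path)
  validate_design(d)
}

#' Validate a condition design
#'
#' Checks the structural invariants of a design: required columns present,
#' sample identifiers unique, every condition's control resolvable, and every
#' non-control condition matched to a control at the same timepoint.
#'
#' @param design A data frame with design columns (see [read_design()]).
#' @return The design, classed `"condition_design"`, invisibly unchanged.
#' @export
validate_design <- function(design) {
  need <- c("condition_id", "treatment", "dose", "timepoint_h", "sample_id",
            "control_condition_id")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  design$timepoint_h <- as.numeric(design$timepoint_h)
  conds <- unique(design[, c("condition_id", "timepoint_h",
                             "control_condition_id")])
  if (anyDuplicated(conds$condition_id))
    stop("condition_id with inconsistent metadata across samples")
  unknown <- setdiff(conds$control_condition_id, conds$condition_id)
  if (length(unknown))
    stop("control_condition_id not present in design: ",
         paste(unknown, collapse = ", "))
  tp <- stats::setNames(conds$timepoint_h, conds$condition_id)
  bad <- conds$condition_id[tp[conds$control_condition_id] != conds$timepoint_h]
  if (length(bad))
    stop("condition and its control differ in timepoint: ",
         paste(bad, collapse = ", "))
  class(design) <- c("condition_design", "data.frame")
  design
}

#' Condition-level view of a design
#'
#' @param design A `"condition_design"` data frame.
#' @return One row per condition with `condition_id`, `treatment`, `dose`,
#'   `timepoint_h`, `control_condition_id` and `is_control` (a condition is a
#'   control when it is its own control).
#' @export
design_conditions <- function(design) {
  cols <- c("condition_id", "treatment", "dose", "timepoint_h",
            "control_condition_id")
  out <- unique(design[, cols])
  rownames(out) <- NULL
  out$is_control <- out$condition_id == out$control_condition_id
  out
}

# samples belonging to a condition, in design order
.condition_samples <- function(design, condition_id) {
  design$sample_id[design$condition_id == condition_id]
}

# delimiter autodetection: tab wins if present in the header line
.read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", fileEncoding = "UTF-8")
}
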