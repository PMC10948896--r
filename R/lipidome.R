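#' Construct a lipidome abundance matrix
#'
#' Bundles a species-by-sample abundance matrix with parsed species
#' annotations and the experimental design. All values must be finite and
#' non-negative, and every sample column must belong to exactly one condition
#' in the design.
#'
#' @param values Numeric matrix, species in rows (rownames = species names),
#'   samples in columns (colnames = sample ids).
#' @param design A `"condition_design"` data frame covering all samples.
#' @param species Optional pre-parsed `"lipid_species"` annotation; parsed
#'   from rownames when omitted.
#' @return An object of class `"lipidome_matrix"`: a list with elements
#'   `values`, `species`, `design`.
#' @export
lipidome_matrix <- function(values, design, species = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate species names: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundances must be finite and non-negative")
  design <- validate_design(design)
  tbl_only <- setdiff(colnames(values), design$sample_id)
  des_only <- setdiff(design$sample_id, colnames(values))
  if (length(tbl_only) || length(des_only))
    stop("sample reconciliation failed; in table but not design: [",
         paste(tbl_only, collapse = ", "), "]; in design but not table: [",
         paste(des_only, collapse = ", "), "]")
  if (is.null(species)) species <- parse_lipid_name(rownames(values))
  stopifnot(identical(species$name, rownames(values)))
  structure(list(values = values, species = species, design = design),
            class = "lipidome_matrix")
}

#' Read a lipidome table with its design
#'
#' The abundance table is delimited text (comma or tab autodetected) with
#' species names in the first column and sample identifiers in the header
#' row. Every sample must be reconcilable against the design and every
#' species name must parse; row and column order are preserved.
#'
#' @param table_path Path to the species-by-sample abundance table.
#' @param design_path Path to the design table (see [read_design()]).
#' @return A `"lipidome_matrix"`.
#' @export
read_lipidome_table <- function(table_path, design_path) {
  d <- .read_delim_auto(table_path)
  if (ncol(d) < 2) stop("abundance table needs a species column and samples")
  vals <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(d[[1]])
  lipidome_matrix(vals, read_design(design_path))
}

#' Write a lipidome table
#'
#' Writes the abundance matrix as TSV (species column first). Writing then
#' re-reading a matrix reproduces identical values; re-writing a file read by
#' [read_lipidome_table()] from a canonical TSV is byte-identical.
#'
#' @param m A `"lipidome_matrix"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lipidome_table <- function(m, path) {
  stopifnot(inherits(m, "lipidome_matrix"))
  .write_feature_table(m$values, "species", path)
}

#' Reconciliation report for a table/design pair
#'
#' Compares the samples of an abundance table against a design without
#' constructing the matrix, reporting mismatches in both directions and
#' species names that fail to parse.
#'
#' @param table_path,design_path Paths as in [read_lipidome_table()].
#' @return A list with elements `ok`, `in_table_only`, `in_design_only`,
#'   `bad_species` (named character of parse failures), `n_species`,
#'   `n_samples`.
#' @export
validate_input <- function(table_path, design_path) {
  d <- .read_delim_auto(table_path)
  design <- read_design(design_path)
  samples <- colnames(d)[-1]
  sp <- as.character(d[[1]])
  bad <- character(0)
  for (nm in sp) {
    err <- tryCatch({parse_lipid_name(nm); NULL}, error = conditionMessage)
    if (!is.null(err)) bad[nm] <- err
  }
  in_table_only <- setdiff(samples, design$sample_id)
  in_design_only <- setdiff(design$sample_id, samples)
  list(ok = !length(in_table_only) && !length(in_design_only) && !length(bad),
       in_table_only = in_table_only, in_design_only = in_design_only,
       bad_species = bad, n_species = length(sp), n_samples = length(samples))
}

#' @export
print.lipidome_matrix <- function(x, ...) {
  cat(sprintf("lipidome_matrix: %d species x %d samples, %d conditions\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$design$condition_id))))
  invisible(x)
}

# shared TSV writer for feature-by-column tables (deterministic bytes)
.write_feature_table <- function(values, id_col, path) {
  df <- data.frame(rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
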