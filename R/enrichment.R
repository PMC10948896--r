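#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the hypergeometric null with both margins
#' fixed, using the probability method: the sum of probabilities of all
#' tables (with the observed margins) whose point probability does not
#' exceed that of the observed table. This is the definition used by the
#' common `fishertest`-style implementations; it is stated explicitly
#' because two-sided Fisher tests have competing definitions.
#'
#' Point probabilities are compared on exact integer numerators
#' (`choose` products) whenever the total count allows them to be
#' represented exactly in a double, making tie handling exact; larger tables
#' fall back to log-space hypergeometric densities with a relative tie
#' tolerance of 1e-7.
#'
#' @param a,b,c,d Non-negative integer cell counts, laid out as rows
#'   `(a, b)` / `(c, d)`.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_two_sided(4, 0, 1, 5)  # 10/210
#' @export
fisher_two_sided <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  if (sum(cnt) == 0) stop("empty 2x2 table")
  m <- a + b          # row-1 margin
  n <- c + d          # row-2 margin
  k <- a + c          # column-1 margin
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- seq(lo, hi)
  total <- choose(m + n, k)
  if (is.finite(total) && total < 2^53) {
    # exact integer numerators: choose(m, x) * choose(n, k - x)
    num <- choose(m, x) * choose(n, k - x)
    sum(num[num <= num[x == a]]) / total
  } else {
    ld <- stats::dhyper(x, m, n, k, log = TRUE)
    obs <- ld[x == a]
    sum(exp(ld[ld <= obs + log(1 + 1e-7)]))
  }
}

#' Category enrichment of a subset within a universe
#'
#' Builds the 2x2 table (subset-and-category, subset-not-category,
#' outside-and-category, outside-not-category) over the universe and returns
#' the fold enrichment together with the two-sided Fisher p-value. Fold
#' enrichment is the category's fraction in the subset divided by its
#' fraction in the universe, and is reported whether or not p is
#' significant. When the category does not intersect the universe the fold
#' is undefined (`NA`) and p is reported as 1.
#'
#' @param subset Character vector of features, a subset of `universe`.
#' @param category Character vector defining the category; only its
#'   intersection with the universe enters the margins.
#' @param universe Character vector of all features under consideration.
#' @return A one-row `data.frame` with columns `subset_size`,
#'   `universe_size`, `category_in_subset`, `category_in_universe`,
#'   `fold_enrichment`, `p_two_sided`.
#' @export
set_enrichment <- function(subset, category, universe) {
  universe <- unique(universe)
  subset <- unique(subset)
  category <- unique(category)
  if (!length(subset)) stop("empty subset")
  if (!length(universe)) stop("empty universe")
  if (length(setdiff(subset, universe)))
    stop("subset contains features outside the universe: ",
         paste(utils::head(setdiff(subset, universe), 5), collapse = ", "))
  cat_u <- intersect(category, universe)
  ns <- length(subset); nu <- length(universe)
  a <- length(intersect(subset, cat_u))        # subset & category
  b <- ns - a                                  # subset, not category
  cc <- length(cat_u) - a                      # outside, category
  dd <- (nu - ns) - cc                         # outside, not category
  if (!length(cat_u)) {
    fold <- NA_real_; p <- 1
  } else {
    fold <- (a / ns) / (length(cat_u) / nu)
    p <- fisher_two_sided(a, b, cc, dd)
  }
  data.frame(subset_size = ns, universe_size = nu, category_in_subset = a,
             category_in_universe = length(cat_u), fold_enrichment = fold,
             p_two_sided = p)
}

#' Read gene sets in GMT format
#'
#' GMT is tab-separated: set name, description, then member identifiers.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (members per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1))
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, mem, desc)
    paste(c(nm, desc, mem), collapse = "\t"),
    names(sets), sets, description)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Benjamini-Hochberg adjustment helper
#'
#' Thin wrapper over [stats::p.adjust()] for callers that want
#' FDR-adjusted enrichment p-values; the enrichment functions themselves
#' return raw p-values.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
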