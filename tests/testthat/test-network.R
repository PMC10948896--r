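fc_from <- function(vals) {
  if (is.null(colnames(vals))) colnames(vals) <- paste0("c", seq_len(ncol(vals)))
  fc_matrix(vals)
}

test_that("pairwise correlation reproduces textbook cases", {
  vals <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(1, 3, 2, 4))
  cm <- pairwise_correlation(fc_from(vals))
  expect_equal(cm$values["a", "b"], 1)
  expect_equal(cm$values["a", "c"], 0.8)
  vals2 <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), d = c(2, 1, 3))
  cm2 <- pairwise_correlation(fc_from(vals2))
  expect_equal(cm2$values["a", "b"], -1)
  expect_true(isSymmetric(cm$values))
  expect_true(all(diag(cm$values) == 1))
  expect_true(all(cm$values >= -1 & cm$values <= 1))
})

test_that("pairwise correlation matches the naive covariance oracle", {
  set.seed(11)
  m <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(sprintf("L%02d", 1:50), sprintf("c%d", 1:8)))
  cm <- pairwise_correlation(fc_from(m))
  expect_lt(max(abs(cm$values - corr_matrix_oracle(m))), 1e-12)
})

test_that("too few conditions and zero-variance rows are handled", {
  vals <- rbind(a = c(1, 2), b = c(2, 1))
  expect_error(pairwise_correlation(fc_from(vals)), "at least 3")
  vals2 <- rbind(a = c(1, 2, 3), flat = c(5, 5, 5))
  expect_warning(cm <- pairwise_correlation(fc_from(vals2)), "flat")
  expect_false("flat" %in% cm$feature_ids)
})

test_that("edge threshold is inclusive and monotone", {
  ids <- c("A", "B", "C")
  r <- matrix(1, 3, 3, dimnames = list(ids, ids))
  r["A", "B"] <- r["B", "A"] <- 0.76
  r["A", "C"] <- r["C", "A"] <- 0.759
  r["B", "C"] <- r["C", "B"] <- 0.9
  cm <- structure(list(values = r, n_obs = 12, feature_ids = ids),
                  class = "correlation_matrix")
  net <- build_network(cm, threshold = 0.76)
  el <- igraph::as_edgelist(net$graph)
  pairs <- apply(el, 1, paste, collapse = "-")
  expect_true("A-B" %in% pairs)    # exactly at threshold: edge present
  expect_false("A-C" %in% pairs)   # 0.759: absent
  expect_true("B-C" %in% pairs)
  # no self loops from the unit diagonal
  expect_equal(sum(igraph::which_loop(net$graph)), 0)
  # edge count equals upper-triangle threshold count
  expect_equal(igraph::ecount(net$graph),
               sum(r[upper.tri(r)] >= 0.76))
  # raising the threshold never adds edges
  set.seed(2)
  m <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("L%02d", 1:20), sprintf("c%d", 1:6)))
  cmr <- pairwise_correlation(fc_from(m))
  counts <- vapply(c(0, 0.3, 0.6, 0.76, 0.9),
                   function(th) igraph::ecount(build_network(cmr, th)$graph),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("node annotations are carried and mismatches rejected", {
  sim <- simulate_lipidome(n_lipids = 20, n_conditions = 6, seed = 4)
  fc <- preprocess_lipidome(sim$matrix)
  cm <- pairwise_correlation(fc)
  net <- build_network(cm, 0.76, annot = sim$matrix$species)
  expect_equal(igraph::V(net$graph)$carbons,
               sim$matrix$species$carbons[match(cm$feature_ids,
                                                sim$matrix$species$name)])
  bad <- sim$matrix$species[1:5, ]
  expect_error(build_network(cm, 0.76, annot = bad), "annotation missing")
})

test_that("leave-one-out flags edges held up by a single condition", {
  vals <- rbind(a = c(0.1, -0.1, 0, 10), b = c(-0.1, 0.1, 0, 10))
  fc <- fc_from(vals)
  cm <- pairwise_correlation(fc)
  expect_gt(cm$values["a", "b"], 0.9)
  net <- build_network(cm, 0.76)
  rob <- edge_robustness(fc, net)
  expect_equal(rob$edges$most_influential_condition, "c4")
  expect_equal(rob$edges$r_without_it, -1, tolerance = 1e-12)
  expect_false(rob$edges$retained)
  expect_equal(rob$fraction_retained, 0)
})

test_that("edges with only three supporting conditions are 'insufficient'", {
  vals <- rbind(a = c(1, 2, 3), b = c(1.1, 2, 3.2))
  fc <- fc_from(vals)
  net <- build_network(pairwise_correlation(fc), 0.76)
  rob <- edge_robustness(fc, net)
  expect_equal(rob$edges$status, "insufficient")
  expect_true(is.na(rob$edges$retained))
})

test_that("overlays attach values, mark missing lipids, and coexist", {
  sim <- simulate_lipidome(n_lipids = 10, n_conditions = 6, seed = 6)
  fc <- preprocess_lipidome(sim$matrix)
  net <- build_network(pairwise_correlation(fc), 0.76)
  ids <- igraph::V(net$graph)$name
  ov <- setNames(-0.88, ids[1])
  net <- overlay_values(net, ov, "phenotype_r")
  vals <- igraph::vertex_attr(net$graph, "phenotype_r")
  expect_equal(vals[1], -0.88)
  expect_true(all(is.na(vals[-1])))  # missing marked, never defaulted to 0
  net <- overlay_values(net, setNames(0.5, ids[2]), "gene_r")
  expect_equal(igraph::vertex_attr(net$graph, "phenotype_r")[1], -0.88)
  expect_equal(igraph::vertex_attr(net$graph, "gene_r")[2], 0.5)
})

test_that("layout is deterministic by seed and separates components", {
  ids <- sprintf("L%02d", 1:10)
  r <- diag(10); dimnames(r) <- list(ids, ids)
  r[1:5, 1:5] <- 0.9; r[6:10, 6:10] <- 0.9; diag(r) <- 1
  cm <- structure(list(values = r, n_obs = 8, feature_ids = ids),
                  class = "correlation_matrix")
  net <- build_network(cm, 0.76)
  n1 <- layout_network(net, seed = 5)
  n2 <- layout_network(net, seed = 5)
  expect_identical(igraph::V(n1$graph)$x, igraph::V(n2$graph)$x)
  expect_identical(igraph::V(n1$graph)$y, igraph::V(n2$graph)$y)
  # disconnected components: bounding boxes do not overlap
  comp <- igraph::components(n1$graph)$membership
  x <- igraph::V(n1$graph)$x; y <- igraph::V(n1$graph)$y
  b1 <- c(range(x[comp == 1]), range(y[comp == 1]))
  b2 <- c(range(x[comp == 2]), range(y[comp == 2]))
  separated <- b1[2] < b2[1] || b2[2] < b1[1] || b1[4] < b2[3] || b2[4] < b1[3]
  expect_true(separated)
})

test_that("GraphML and edge-list exports round trip through igraph", {
  sim <- simulate_lipidome(n_lipids = 15, n_conditions = 6, seed = 10)
  fc <- preprocess_lipidome(sim$matrix)
  net <- build_network(pairwise_correlation(fc), 0.5,
                       annot = sim$matrix$species)
  net <- layout_network(net, seed = 1)
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(net$graph))
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
  expect_true(all(c("lipid_class", "carbons", "x", "y") %in%
                    igraph::vertex_attr_names(g2)))
  el <- tempfile(fileext = ".tsv")
  write_edge_list(net, el)
  df <- read.delim(el)
  expect_equal(nrow(df), igraph::ecount(net$graph))
  expect_true(all(df$r >= 0.5))
})
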