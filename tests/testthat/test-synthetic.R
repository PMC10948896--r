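test_that("generators are pure functions of parameters and seed", {
  a <- simulate_lipidome(n_lipids = 20, n_conditions = 4, seed = 9)
  b <- simulate_lipidome(n_lipids = 20, n_conditions = 4, seed = 9)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$theta, b$truth$theta)
  t1 <- simulate_transcriptome(a$truth, n_genes = 30, seed = 3)
  t2 <- simulate_transcriptome(b$truth, n_genes = 30, seed = 3)
  expect_identical(t1$table$values, t2$table$values)
  i1 <- simulate_images(n_cells = 5, size = 256, seed = 4)
  i2 <- simulate_images(n_cells = 5, size = 256, seed = 4)
  expect_identical(i1$channels$dna, i2$channels$dna)
  expect_identical(i1$truth, i2$truth)
  tr1 <- simulate_traces(n_cells = 15, seed = 5)
  tr2 <- simulate_traces(n_cells = 15, seed = 5)
  expect_identical(tr1$traces$cdk, tr2$traces$cdk)
})

test_that("planted lipid correlations follow the circular law", {
  # zero noise, equal baselines: equal angles correlate at exactly 1,
  # opposite angles at exactly -1
  sim <- simulate_lipidome(n_lipids = 8, n_conditions = 8, sigma = 0,
                           baseline_sdlog = 0, seed = 2)
  fc <- preprocess_lipidome(sim$matrix)
  cm <- pairwise_correlation(fc)
  th <- sim$truth$theta
  opposite <- abs(abs(outer(th, th, `-`)) - pi) < 1e-9
  expect_lt(max(abs(cm$values[opposite] + 1)), 1e-9)
  expected <- outer(th, th, function(a, b) cos(a - b))
  expect_lt(max(abs(cm$values - expected)), 1e-6)
  # 90-degree pairs decorrelate under many uniformly random phases
  # (sample r has sd ~ 1/sqrt(n_conditions) around cos(90 deg) = 0)
  simu <- simulate_lipidome(n_lipids = 8, n_conditions = 2000, sigma = 0,
                            baseline_sdlog = 0, phases = "uniform", seed = 3)
  cmu <- pairwise_correlation(preprocess_lipidome(simu$matrix))
  orth <- which(abs(abs(outer(simu$truth$theta, simu$truth$theta, `-`)) -
                      pi / 2) < 1e-9)
  expect_lt(max(abs(cmu$values[orth])), 0.05)
})

test_that("planted adjacency equals its defining formula", {
  sim <- simulate_lipidome(n_lipids = 30, n_conditions = 6, seed = 7)
  th <- sim$truth$theta
  recomputed <- outer(th, th, function(a, b) cos(a - b)) >= 0.76
  diag(recomputed) <- FALSE
  expect_identical(unname(sim$truth$adjacency), unname(recomputed))
  expect_error(simulate_lipidome(n_conditions = 2), "at least 3")
})

test_that("species annotations are split into angular class sectors", {
  sim <- simulate_lipidome(seed = 13)
  sp <- sim$truth$species
  pre <- sim$truth$theta < pi
  expect_true(all(sp$lipid_class[pre] %in%
                    c("FA", "PA", "LPA", "LPC", "LPE", "MG", "DG", "So")))
  expect_true(all(sp$lipid_class[!pre] %in%
                    c("PE", "PC", "TG", "SM", "PI", "PS", "Cer", "ChE")))
})

test_that("transcriptome couples genes to the lipid circle with a planted set", {
  sim <- simulate_lipidome(n_conditions = 12, sigma = 0, baseline_sdlog = 0,
                           seed = 5)
  trx <- simulate_transcriptome(sim$truth, sigma = 0, seed = 6)
  fc <- preprocess_lipidome(sim$matrix)
  glc <- gene_lipid_correlation(trx$table, fc)
  expected <- outer(trx$truth$psi, sim$truth$theta, function(p, t) cos(p - t))
  expect_lt(max(abs(glc$values -
                      expected[rownames(glc$values), colnames(glc$values)])),
            1e-6)
  # the planted annotation set is concentrated in the stress module
  in_table <- intersect(trx$truth$set_members, trx$table$gene_ids)
  stress <- names(trx$truth$module)[trx$truth$module ==
                                      trx$truth$stress_module]
  expect_gte(length(intersect(in_table, stress)), 15)
  # responsive genes carry small adjusted p-values more often
  expect_lt(median(trx$table$padj[trx$truth$responsive]),
            median(trx$table$padj[!trx$truth$responsive]))
})

test_that("phenotype correlates by angle with sign structure", {
  sim <- simulate_lipidome(n_conditions = 12, sigma = 0, baseline_sdlog = 0,
                           seed = 8)
  ph <- simulate_phenotype(sim$truth, pro_angle = 0, noise = 0, seed = 9)
  fc <- preprocess_lipidome(sim$matrix)
  r <- phenotype_correlation(fc, ph)
  at_pro <- names(which(abs(sim$truth$theta) < 1e-9))
  at_anti <- names(which(abs(sim$truth$theta - pi) < 1e-9))
  expect_equal(unname(r[at_pro]), rep(1, length(at_pro)), tolerance = 1e-6)
  expect_equal(unname(r[at_anti]), rep(-1, length(at_anti)),
               tolerance = 1e-6)
  expect_true(all(ph >= 0 & ph <= 100))
})

test_that("image truth has one row per cell and packing fails loudly", {
  img <- simulate_images(n_cells = 5, size = 256, seed = 1)
  expect_equal(nrow(img$truth), 5)
  expect_true(all(vapply(img$channels, function(ch) all(ch >= 0),
                         logical(1))))
  expect_error(simulate_images(n_cells = 500, size = 256), "cannot pack")
})

test_that("programmed trace outcomes are consistent with the trajectories", {
  # S-entry fraction 0: nothing crosses 1.0 after treatment
  t0 <- simulate_traces(n_cells = 40, frac_s_entry = 0, noise_cdk = 0,
                        noise_degron = 0, seed = 2)
  post <- seq(t0$traces$treatment_frame + 1, ncol(t0$traces$cdk))
  expect_true(all(apply(t0$traces$cdk[, post], 1, max) < 1))
  # S-entry fraction 1, zero noise: every trace crosses
  t1 <- simulate_traces(n_cells = 40, frac_s_entry = 1, noise_cdk = 0,
                        noise_degron = 0, seed = 2)
  expect_true(all(apply(t1$traces$cdk[, post], 1, max) > 1))
  expect_true(all(apply(t1$traces$degron[, post], 1, max) > 100))
  # programmed labels match emitted trajectories
  tm <- simulate_traces(n_cells = 60, frac_s_entry = 0.5, noise_cdk = 0,
                        noise_degron = 0, seed = 3)
  crossed <- apply(tm$traces$cdk[, post], 1, max) > 1
  expect_identical(unname(crossed), tm$truth$s_entry)
  expect_equal(mean(crossed), 0.5)
})

test_that("cell-record composition is exact by construction", {
  pop <- simulate_cell_records(n = 400, frac_s = 0.25, frac_g2 = 0.2,
                               seed = 4)
  expect_equal(unname(table(pop$truth)["S"]), 100)
  expect_equal(unname(table(pop$truth)["G2"]), 80)
})

test_that("simulate_all writes a complete, reproducible input bundle", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_all(d1, seed = 3, preset = "small")
  simulate_all(d2, seed = 3, preset = "small")
  files <- list.files(d1)
  expect_true(all(c("lipidome.tsv", "design.tsv", "de_table.tsv",
                    "gene_sets.gmt", "phenotype.tsv", "traces.csv",
                    "manifest.json", "img_dna.tif") %in% files))
  expect_identical(unname(tools::md5sum(file.path(d1, files))),
                   unname(tools::md5sum(file.path(d2, files))))
  unlink(c(d1, d2), recursive = TRUE)
})
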