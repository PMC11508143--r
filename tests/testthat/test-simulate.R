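test_that("the generator reproduces the 2 x 6 x 3 study design deterministically", {
  sim1 <- simulate_experiment(sim_config(seed = 1))
  sim2 <- simulate_experiment(sim_config(seed = 1))
  expect_identical(sim1$counts, sim2$counts)
  expect_identical(sim1$truth$latent, sim2$truth$latent)
  expect_identical(sim1$sheet, sim2$sheet)

  sheet <- sim1$sheet
  expect_equal(nrow(sheet), 36L)
  expect_setequal(unique(sheet$condition), c("control", "salt"))
  expect_equal(sort(unique(sheet$time_h)), c(0, 3, 6, 12, 24, 48))
  expect_equal(max(sheet$replicate), 3L)
  expect_equal(anyDuplicated(sheet[, c("condition", "time_h", "replicate")]), 0L)
  expect_identical(colnames(sim1$counts), sheet$sample_id)
  expect_true(all(sim1$counts >= 0))
  expect_true(all(sim1$counts == round(sim1$counts)))

  sim3 <- simulate_experiment(sim_config(seed = 2))
  expect_false(identical(sim1$counts, sim3$counts))
})

test_that("written simulation files are read back by the pipeline I/O layer", {
  sim <- simulate_experiment(small_sim_config(seed = 5))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_identical(read_counts(paths[["counts"]]), sim$counts)
  sheet <- read_sample_sheet(paths[["sheet"]], counts = sim$counts)
  expect_equal(sheet, sim$sheet)
  cfg_json <- jsonlite::read_json(paths[["config"]])
  expect_equal(cfg_json$seed, 5)
})

test_that("in the noiseless unit-loading limit module genes are perfectly correlated", {
  cfg <- sim_config(noise_sd = 0, activity_sd = 0,
                    loading_mean = 1, loading_sd = 1e-9,
                    neg_loading_prob = 0, seed = 4)
  sim <- simulate_experiment(cfg)
  lat <- sim$truth$latent
  genes <- sim$truth$genes
  for (m in c("sim1", "sim5")) {
    members <- genes$gene_id[genes$module == m]
    r <- cor(t(lat[members[1:10], ]))
    expect_equal(abs(r), matrix(1, 10, 10), ignore_attr = TRUE,
                 tolerance = 1e-6)
  }
})

test_that("planted structure shows up in transformed counts", {
  sim <- simulate_experiment(sim_config(seed = 6))
  x <- vst_transform(sim$counts)
  genes <- sim$truth$genes
  m1 <- genes$gene_id[genes$module == "sim1"][1:30]
  m2 <- genes$gene_id[genes$module == "sim2"][1:30]
  r <- cor(t(x[c(m1, m2), ]))
  within <- c(r[1:30, 1:30][upper.tri(diag(30))],
              r[31:60, 31:60][upper.tri(diag(30))])
  between <- r[1:30, 31:60]
  expect_gt(mean(abs(within)), mean(abs(between)))

  # planted hubs carry the top loadings of their stress module
  stress <- genes[genes$module == "sim5" | genes$module == "sim6", ]
  expect_true(all(abs(stress$loading[stress$is_hub]) >
                  max(abs(stress$loading[!stress$is_hub]))))

  # constitutive activity profiles are orthogonal to every other module's
  # profile across design cells (the two stress modules share their
  # salt-time trend by design and separate only through their opposite
  # condition offsets)
  act <- sim$truth$activity
  flat <- apply(act, 1, c)                      # cells x modules
  gram <- crossprod(flat)
  for (i in 1:4) for (j in seq_len(6)[-i])
    expect_equal(gram[i, j], 0, tolerance = 1e-10)
  r56 <- cor(scale(flat[, 5], scale = FALSE), scale(flat[, 6], scale = FALSE))
  expect_lt(abs(r56), 0.5)

  # stress modules are silent under control
  ctrl <- act[, "control", ]
  expect_true(all(ctrl[c(5, 6), ] == 0))
  expect_true(all(rowSums(abs(ctrl[1:4, ])) > 0))
})

test_that("recovery evaluation scores partitions and hub sets correctly", {
  sim <- simulate_experiment(small_sim_config(seed = 8))
  genes <- sim$truth$genes
  truth_modules <- setNames(genes$module, genes$gene_id)

  perfect <- evaluate_recovery(sim$truth, truth_modules,
                               keys = data.frame(gene_id =
                                 genes$gene_id[genes$is_hub]))
  expect_equal(perfect$ari, 1)
  expect_equal(perfect$hub_recall, 1)
  expect_equal(perfect$hub_precision, 1)

  # shuffled labels have ARI near zero
  set.seed(9)
  aris <- replicate(20, {
    shuffled <- setNames(sample(genes$module), genes$gene_id)
    evaluate_recovery(sim$truth, shuffled, NULL)$ari
  })
  expect_lt(max(abs(aris)), 0.05)

  empty <- evaluate_recovery(sim$truth, truth_modules,
                             keys = data.frame(gene_id = character()))
  expect_equal(empty$hub_recall, 0)
  expect_true(is.na(empty$hub_precision))

  excl <- evaluate_recovery(sim$truth, truth_modules, NULL,
                            include_background = FALSE)
  expect_equal(excl$n_genes_compared, sum(genes$module != "background"))
})

test_that("generator configuration errors name the offending field", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(n_genes = 100, n_modules = 6, genes_per_module = 80,
                          seed = 1), "exceeds n_genes")
  expect_error(sim_config(stress_modules = 9, seed = 1), "stress_modules")
  expect_error(sim_config(n_hubs = 200, seed = 1), "n_hubs")
  expect_error(sim_config(member_qmax = 1.2, seed = 1), "member_qmax")
  expect_error(sim_config(hub_loading = c(2, 1), seed = 1), "hub_loading")
})
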