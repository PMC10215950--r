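small_scenario <- function(seed = 17, n = 150) {
  gess_like_scenario(n_snps = 10, n = n, seed = seed)
}

test_that("leave-k-out draws are sized, seeded and uniform", {
  sets <- leave_k_out(267, 1, replicates = 100, master_seed = 9)
  expect_length(sets, 100)
  expect_true(all(lengths(sets) == 266))

  expect_identical(leave_k_out(10, 0, 5, 1), rep(list(1:10), 5))
  expect_error(leave_k_out(10, 10, 5, 1), "k must satisfy")
  expect_identical(leave_k_out(50, 5, 20, 3), leave_k_out(50, 5, 20, 3))
  expect_false(identical(leave_k_out(50, 5, 20, 3), leave_k_out(50, 5, 20, 4)))

  # exclusion frequency ~ k/n for every index
  reps <- leave_k_out(10, 3, replicates = 3000, master_seed = 2)
  excl <- 1 - tabulate(unlist(reps), 10) / 3000
  expect_true(all(abs(excl - 0.3) < 4 * sqrt(0.3 * 0.7 / 3000)))
})

test_that("replicate seeds are distinct across the (k, replicate) grid", {
  grid <- expand.grid(k = c(1, 2, 3, 5, 10, 20, 30, 50), r = 1:100)
  seeds <- mapply(causalstab:::derive_seed, 1L, grid$k, grid$r)
  expect_equal(anyDuplicated(seeds), 0)
})

test_that("resampling plans validate their grid", {
  expect_error(resampling_plan(k_grid = integer()), "must not be empty")
  expect_error(resampling_plan(k_grid = c(5, 3)), "strictly increasing")
  expect_error(resampling_plan(replicates = 0), "positive")
  p <- resampling_plan()
  expect_equal(p$k_grid, c(1L, 2L, 3L, 5L, 10L, 20L, 30L, 50L))
  expect_equal(p$replicates, 100L)
})

test_that("k = 0 degenerates to perfect self-agreement in all pillars", {
  ds <- simulate_dataset(small_scenario())
  snp <- drop_outcome(ds)
  plan <- resampling_plan(k_grid = 0L, replicates = 3, master_seed = 5)

  p1 <- run_pillar_one(snp, plan)
  expect_equal(p1$summary$pct_common_undirected, 100)
  expect_equal(p1$summary$pct_common_directed, 100)
  expect_equal(p1$summary$mean_shd, 0)

  p2 <- run_pillar_two(snp, snp, plan)
  expect_equal(p2$baseline$shd, 0)
  expect_equal(p2$summary$ratio_common_undirected, 1)
  expect_equal(p2$summary$ratio_common_directed, 1)
  expect_equal(p2$summary$mean_shd, 0)

  p3 <- run_pillar_three(ds, plan = plan)
  expect_true(all(p3$summary$inclusion_initial == 100))
  nmb <- length(p3$reference_mb)
  expect_equal(unname(p3$summary$exact_counts_pct[nmb + 1, ]), 100)
  expect_equal(unname(p3$summary$mean_extra), 0)
})

test_that("pillar-one replicates satisfy the directed-fate partition", {
  ds <- drop_outcome(simulate_dataset(small_scenario(23)))
  plan <- resampling_plan(k_grid = c(1L, 5L), replicates = 4, master_seed = 3)
  p1 <- run_pillar_one(ds, plan)
  expect_equal(nrow(p1$long), 8)  # |k_grid| * replicates
  ndir <- edge_counts(p1$reference)[["directed"]]
  with(p1$long, expect_true(all(
    common_directed + directed_to_undirected + directed_reversed +
      directed_vanished == ndir)))
})

test_that("pillar two requires matching variables and reports baselines", {
  ds <- simulate_dataset(small_scenario(29, n = 160))
  parts <- split_by_outcome(ds)
  other <- genotype_dataset(parts$zero_part$values[, 1:5])
  expect_error(run_pillar_two(parts$zero_part, other), "same variables")

  plan <- resampling_plan(k_grid = c(1L, 3L), replicates = 4, master_seed = 1)
  p2 <- run_pillar_two(parts$zero_part, parts$positive_part, plan)
  expect_equal(nrow(p2$long), 8)
  expect_true(all(c("common_undirected", "common_directed", "shd") %in%
                    names(p2$baseline)))
  expect_true(all(p2$summary$mean_shd >= 0))
})

test_that("pillar-three exact-count buckets always sum to one hundred", {
  ds <- simulate_dataset(small_scenario(31, n = 200))
  plan <- resampling_plan(k_grid = c(1L, 5L), replicates = 5, master_seed = 2)
  p3 <- run_pillar_three(ds, plan = plan)
  sums <- colSums(p3$summary$exact_counts_pct)
  expect_equal(unname(sums), rep(100, length(p3$summary$k)), tolerance = 1e-9)
  expect_true(all(p3$inclusion >= 0 & p3$inclusion <= 100))
  expect_equal(nrow(p3$long), 10)
  expect_error(run_pillar_three(drop_outcome(ds)), "target")
})

test_that("wide tables carry one column per k plus the metric labels", {
  ds <- simulate_dataset(small_scenario(37))
  snp <- drop_outcome(ds)
  plan <- resampling_plan(k_grid = c(1L, 2L, 5L), replicates = 3,
                          master_seed = 8)
  p1 <- run_pillar_one(snp, plan)
  w1 <- format_pillar_one(p1)
  expect_equal(names(w1), c("metric", "k=1", "k=2", "k=5"))
  expect_equal(nrow(w1), 10)

  p3 <- run_pillar_three(ds, plan = plan)
  w3 <- format_pillar_three(p3)
  expect_equal(ncol(w3), 4)

  dir <- withr::local_tempdir()
  out <- file.path(dir, "run1")
  summarize_tables(out, pillar1 = p1, pillar3 = p3,
                   config = list(master_seed = 8))
  expect_true(all(file.exists(file.path(out,
    c("pillar1_wide.csv", "pillar1_long.csv", "pillar3_wide.csv",
      "manifest.yaml", "pillar1_reference.graph")))))
  expect_error(summarize_tables(out, pillar1 = p1), "exists")
  expect_error(summarize_tables(file.path(dir, "x")), "at least one pillar")
})
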