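test_that("importance ranking is seeded-deterministic and finds separators", {
  withr::with_seed(11, {
    n <- 200
    bm <- tibble::tibble(
      sample_id = paste0("s", seq_len(n)),
      sep = c(runif(n / 2, 0, 0.4), runif(n / 2, 0.6, 1)),
      noise1 = runif(n), noise2 = runif(n), noise3 = runif(n)
    )
  })
  labels <- tibble::tibble(sample_id = bm$sample_id,
                           class = rep(c("a", "b"), each = 100))
  params <- rf_params(ntree = 500, seed = 7)
  imp <- oob_permutation_importance(bm, labels, params = params)
  expect_identical(imp$probe_id[1], "sep")
  # pure-noise features sit within sampling noise of zero
  expect_true(all(abs(imp$importance[imp$probe_id != "sep"]) < 0.02))
  imp2 <- oob_permutation_importance(bm, labels, params = params)
  expect_identical(imp, imp2)
})

test_that("forward selection keeps a strictly decreasing OOB trace", {
  sim <- small_sim()
  cand <- candidate_probes(diff_methylation(sim$beta, sim$labels))
  params <- rf_params(ntree = 150, seed = 3)
  ranking <- oob_permutation_importance(sim$beta, sim$labels, cand, params)
  sel <- oob_forward_selection(sim$beta, sim$labels, ranking, params)
  expect_true(all(diff(sel$oob_trace) < 0) || length(sel$oob_trace) == 1)
  expect_identical(sel$kept[1], ranking$probe_id[1])
  expect_true(all(sel$kept %in% ranking$probe_id))
  expect_equal(sum(sel$evaluated$accepted), length(sel$kept))

  # a single-entry ranking keeps exactly that feature
  solo <- oob_forward_selection(sim$beta, sim$labels, ranking$probe_id[1],
                                params)
  expect_identical(solo$kept, ranking$probe_id[1])

  # a larger acceptance tolerance can only shrink the kept set
  strict <- oob_forward_selection(sim$beta, sim$labels, ranking, params,
                                  min_improve = 0.05)
  expect_lte(length(strict$kept), length(sel$kept))
  if (length(strict$oob_trace) > 1) {
    expect_true(all(diff(strict$oob_trace) < -0.05))
  }
})

test_that("a duplicate of a kept feature cannot beat a zero-error baseline", {
  withr::with_seed(31, {
    n <- 60
    sep <- c(runif(n / 2, 0, 0.35), runif(n / 2, 0.65, 1))
    bm <- tibble::tibble(sample_id = paste0("s", seq_len(n)),
                         orig = sep, dup = sep, noise = runif(n))
  })
  labels <- tibble::tibble(sample_id = bm$sample_id,
                           class = rep(c("a", "b"), each = 30))
  sel <- oob_forward_selection(bm, labels, c("orig", "dup", "noise"),
                               rf_params(ntree = 200, seed = 2),
                               min_improve = 0.001)
  expect_false("dup" %in% sel$kept)
})

test_that("multi-run selection respects union bounds and panel structure", {
  sim <- small_sim()
  sel <- suppressWarnings(run_panel_selection(
    sim$beta, sim$labels, params = rf_params(ntree = 100, seed = 5),
    n_runs = 3, per_run_top = 10, final_k = 10
  ))
  expect_gte(length(sel$union), 10)
  expect_lte(length(sel$union), 30)
  expect_true(all(sel$panel %in% sel$union))
  expect_length(sel$panel, 10)
  for (r in sel$runs) {
    expect_length(r$top, 10)
    tr <- r$selection$oob_trace
    expect_true(length(tr) == 1 || all(diff(tr) < 0))
  }
  td <- tidy(sel)
  expect_equal(sum(td$in_final), 10)
  expect_equal(nrow(td), length(sel$union))
})

test_that("per-run 'kept' mode restricts contributions to the kept sets", {
  sim <- small_sim()
  sel <- suppressWarnings(run_panel_selection(
    sim$beta, sim$labels, params = rf_params(ntree = 80, seed = 9),
    n_runs = 2, per_run_top = 10, final_k = 5, per_run_source = "kept"
  ))
  for (r in sel$runs) {
    expect_true(all(r$top %in% r$selection$kept))
  }
})

test_that("panel-size sweep is deterministic and skips oversized k", {
  sim <- small_sim()
  split <- stratified_split(sim$labels, 0.6, seed = 2)
  train <- sim$beta[sim$beta$sample_id %in% split$train, ]
  valid <- sim$beta[sim$beta$sample_id %in% split$valid, ]
  ranking <- candidate_probes(diff_methylation(train, sim$labels))
  expect_warning(
    sw <- sweep_panel_size(train, valid, sim$labels, ranking,
                           ks = c(5, length(ranking), 10000),
                           algorithm = "rf", params = rf_params(ntree = 100)),
    "skipping"
  )
  expect_equal(sw$k, c(5, length(ranking)))

  # k = all features is the same model as the explicit full list
  full <- sweep_panel_size(train, valid, sim$labels, ranking,
                           ks = length(ranking),
                           algorithm = "rf", params = rf_params(ntree = 100))
  expect_equal(sw$accuracy[2], full$accuracy[1])

  again <- suppressWarnings(sweep_panel_size(
    train, valid, sim$labels, ranking, ks = c(5, length(ranking), 10000),
    algorithm = "rf", params = rf_params(ntree = 100)
  ))
  expect_equal(sw$accuracy, again$accuracy)

  # train/validation overlap is rejected
  expect_error(sweep_panel_size(train, train, sim$labels, ranking, ks = 5),
               "share samples")
})
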