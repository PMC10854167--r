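test_that("single-probe ANOVA and Tukey match independent references", {
  # textbook-style instance against brute-force sums of squares
  v <- c(0.1, 0.2, 0.15, 0.3, 0.35, 0.4, 0.7, 0.8, 0.75)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- one_way_anova(v, g)
  or <- oracle_anova(v, g)
  expect_equal(res$statistic, or$f, tolerance = 1e-8)
  expect_equal(res$p_value, or$p, tolerance = 1e-8)

  # Tukey against both stats::TukeyHSD and the integration oracle
  tk <- tukey_hsd(v, g)
  ref <- TukeyHSD(aov(v ~ factor(g)))$`factor(g)`
  expect_equal(tk$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)
  for (i in seq_len(nrow(tk))) {
    expect_lt(abs(tk$p_adj[i] - oracle_tukey_p(tk$q[i], k = 3, df = 6)),
              1e-6)
  }
})

test_that("k = 2 reduces to the pooled t-test (and F to t squared)", {
  withr::with_seed(5, {
    v <- runif(11)
    g <- rep(c("x", "y"), c(5, 6))
  })
  tt <- t.test(v[g == "x"], v[g == "y"], var.equal = TRUE)
  an <- one_way_anova(v, g)
  expect_equal(an$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p_value, tt$p.value, tolerance = 1e-10)
  tk <- tukey_hsd(v, g)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-8)
  expect_equal(tk$q, abs(unname(tt$statistic)) * sqrt(2), tolerance = 1e-10)
})

test_that("degenerate probes are handled: constants fail, separation saturates", {
  bm <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    const = rep(0.5, 6),
    sep = c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9),
    equalmeans = c(0.2, 0.4, 0.3, 0.2, 0.4, 0.3)
  )
  labels <- tibble::tibble(sample_id = bm$sample_id,
                           class = rep(c("a", "b"), each = 3))
  res <- diff_methylation(bm, labels, filter_config(delta = 0.2, alpha = 0.01))
  expect_true(is.na(res$statistic[res$probe_id == "const"]))
  expect_false(res$pass[res$probe_id == "const"])
  expect_equal(res$statistic[res$probe_id == "sep"], Inf)
  expect_equal(res$p_value[res$probe_id == "sep"], 0)
  expect_true(res$pass[res$probe_id == "sep"])
  # equal group means: adjusted p ~ 1
  pairs <- attr(res, "pairs")
  expect_gt(pairs$p_adj[pairs$probe_id == "equalmeans"], 0.95)
})

test_that("vectorised filter agrees with the single-probe functions", {
  sim <- small_sim()
  bm <- sim$beta[, 1:41]
  res <- diff_methylation(bm, sim$labels)
  g <- sim$labels$class
  for (probe in names(bm)[c(2, 12, 25, 41)]) {
    single <- one_way_anova(bm[[probe]], g)
    expect_equal(res$statistic[res$probe_id == probe], single$statistic,
                 tolerance = 1e-10)
    expect_equal(res$p_value[res$probe_id == probe], single$p_value,
                 tolerance = 1e-10)
    tk <- tukey_hsd(bm[[probe]], g)
    pr <- attr(res, "pairs")
    pr <- pr[pr$probe_id == probe, ]
    expect_equal(pr$p_adj, tk$p_adj, tolerance = 1e-10)
    expect_equal(pr$delta, tk$delta, tolerance = 1e-12)
  }
})

test_that("planted shifts pass and sub-threshold shifts fail the filter", {
  cfg <- sim_config(n_classes = 3, samples_per_class = 40, n_probes = 60,
                    informative_per_class = 6, effect_delta = 0.4, seed = 21)
  sim <- simulate_methylation(cfg)
  res <- diff_methylation(sim$beta, sim$labels)
  planted <- unlist(sim$truth$planted)
  expect_true(all(res$pass[res$probe_id %in% planted]))

  weak <- simulate_methylation(sim_config(
    n_classes = 3, samples_per_class = 40, n_probes = 60,
    informative_per_class = 6, effect_delta = 0.1, seed = 22
  ))
  wres <- diff_methylation(weak$beta, weak$labels,
                           filter_config(delta = 0.2, alpha = 0.01))
  wplanted <- unlist(weak$truth$planted)
  expect_true(all(wres$max_abs_delta[wres$probe_id %in% wplanted] < 0.2))
  expect_false(any(wres$pass[wres$probe_id %in% wplanted]))
})

test_that("one_vs_all candidates are a subset of any_pair candidates", {
  sim <- small_sim()
  bm <- sim$beta[, 1:101]
  ova <- candidate_probes(diff_methylation(bm, sim$labels,
                                           filter_config(criterion = "one_vs_all")))
  anp <- candidate_probes(diff_methylation(bm, sim$labels,
                                           filter_config(criterion = "any_pair")))
  expect_true(all(ova %in% anp))
})

test_that("F and delta-beta are invariant under adding a constant", {
  sim <- small_sim()
  v <- pmin(sim$beta[[2]], 0.9)
  g <- sim$labels$class
  a1 <- one_way_anova(v, g)
  a2 <- one_way_anova(v + 0.05, g)
  expect_equal(a1$statistic, a2$statistic, tolerance = 1e-9)
  t1 <- tukey_hsd(v, g)
  t2 <- tukey_hsd(v + 0.05, g)
  expect_equal(t1$delta, t2$delta, tolerance = 1e-12)
})

test_that("probes with missing values use per-probe complete cases", {
  sim <- small_sim()
  bm <- sim$beta[, 1:11]
  bm[[2]][c(1, 5, 20)] <- NA
  res <- diff_methylation(bm, sim$labels)
  v <- bm[[2]]
  g <- sim$labels$class
  single <- one_way_anova(v[!is.na(v)], g[!is.na(v)])
  expect_equal(res$statistic[res$probe_id == names(bm)[2]],
               single$statistic, tolerance = 1e-10)
  # a probe losing a whole class is unevaluable and never passes
  bm[[3]][sim$labels$class == "C01"] <- NA
  res2 <- diff_methylation(bm, sim$labels)
  expect_false(res2$evaluable[res2$probe_id == names(bm)[3]])
  expect_false(res2$pass[res2$probe_id == names(bm)[3]])
})
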