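train_small <- function(algorithm, seed = 1, ...) {
  sim <- small_sim()
  panel <- candidate_probes(diff_methylation(sim$beta, sim$labels))
  train_classifier(sim$beta[, c("sample_id", panel)], sim$labels,
                   algorithm = algorithm,
                   cfg = en_config(seed = seed, ...),
                   params = rf_params(ntree = 100, seed = seed))
}

test_that("lasso is the alpha_mix = 1 special case of the elastic net", {
  m_lasso <- train_small("lasso")
  m_en1 <- train_small("en", alpha_mix = 1)
  expect_equal(m_lasso$fitted$coefficients, m_en1$fitted$coefficients)
  expect_equal(m_lasso$fitted$intercepts, m_en1$fitted$intercepts)
  expect_equal(m_lasso$fitted$lambda, m_en1$fitted$lambda)
})

test_that("probabilities are normalised and argmax rules are deterministic", {
  sim <- small_sim()
  for (alg in c("en", "rf")) {
    model <- train_small(alg)
    pred <- predict(model, sim$beta[1:10, c("sample_id", model$probes)])
    probs <- as.matrix(pred[, grep("^prob_", names(pred))])
    expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
    expect_true(all(probs >= 0))
    expect_identical(
      pred$predicted_class,
      model$classes[max.col(probs, ties.method = "first")]
    )
  }
})

test_that("an all-zero coefficient model yields uniform probabilities and a flagged tie", {
  model <- train_small("en")
  model$fitted$coefficients[] <- 0
  model$fitted$intercepts[] <- 0
  sim <- small_sim()
  pred <- predict(model, sim$beta[1:3, c("sample_id", model$probes)])
  probs <- as.matrix(pred[, grep("^prob_", names(pred))])
  expect_true(all(abs(probs - 1 / 3) < 1e-12))
  expect_true(all(pred$tie))
  expect_true(all(pred$predicted_class == model$classes[1]))
  expect_true(all(pred$margin == 0))
})

test_that("two separated classes on one probe are learned perfectly", {
  withr::with_seed(13, {
    n <- 40
    bm <- tibble::tibble(sample_id = paste0("s", seq_len(n)),
                         marker = c(runif(n / 2, 0, 0.3),
                                    runif(n / 2, 0.7, 1)))
  })
  labels <- tibble::tibble(sample_id = bm$sample_id,
                           class = rep(c("left", "right"), each = n / 2))
  hold_in <- c(seq_len(15), 21:35)
  model <- train_classifier(bm[hold_in, ], labels,
                            algorithm = "en", cfg = en_config(seed = 3))
  pred <- predict(model, bm[-hold_in, ])
  truth <- labels$class[match(pred$sample_id, labels$sample_id)]
  expect_equal(mean(pred$predicted_class == truth), 1)
})

test_that("prediction demands a harmonized probe set and complete values", {
  sim <- small_sim()
  model <- train_small("en")
  expect_error(predict(model, sim$beta[1:2, 1:10]), "harmonize_to_panel")
  bm <- sim$beta[1:2, c("sample_id", model$probes)]
  bm[[2]][1] <- NA
  expect_error(predict(model, bm), "missing values")
})

test_that("model save/load round trip preserves predictions bitwise", {
  sim <- small_sim()
  newdata <- sim$beta[1:8, ]
  for (alg in c("en", "rf")) {
    model <- train_small(alg, seed = 6)
    path <- withr::local_tempfile(fileext = ".json")
    save_model(model, path)
    back <- load_model(path)
    nd <- newdata[, c("sample_id", model$probes)]
    expect_identical(predict(model, nd), predict(back, nd))
  }
})

test_that("model files are refused when truncated, unversioned, or too new", {
  model <- train_small("en")
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)

  txt <- readLines(path, warn = FALSE)
  writeLines(substr(paste(txt, collapse = ""), 1, 200), path)
  expect_error(load_model(path), "cannot parse")

  save_model(model, path)
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = FALSE)
  obj$version <- NULL
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  expect_error(load_model(path), "no format version")

  obj$version <- "99.0"
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  expect_error(load_model(path), "newer than supported")
})

test_that("seeded retraining reproduces the model file byte for byte", {
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_model(train_small("en", seed = 17), p1)
  save_model(train_small("en", seed = 17), p2)
  expect_identical(readLines(p1, warn = FALSE), readLines(p2, warn = FALSE))
})

test_that("the number of active coefficients shrinks along the lambda path", {
  sim <- small_sim()
  panel <- candidate_probes(diff_methylation(sim$beta, sim$labels))
  grid <- exp(seq(log(0.2), log(0.0005), length.out = 25))
  nz <- vapply(grid, function(l) {
    m <- train_classifier(sim$beta[, c("sample_id", panel)], sim$labels,
                          "en", en_config(lambda = l, seed = 1))
    sum(m$fitted$coefficients != 0)
  }, numeric(1))
  expect_true(all(diff(nz) >= 0))  # nonzeros non-increasing in lambda
})

test_that("tidy and glance expose the fitted model structure", {
  m <- train_small("en")
  td <- tidy(m)
  expect_true(all(c("class", "term", "estimate") %in% names(td)))
  expect_true(all(td$estimate != 0))
  gl <- glance(m)
  expect_equal(gl$algorithm, "en")
  expect_equal(gl$n_classes, 3)

  mrf <- train_small("rf")
  expect_true("importance" %in% names(tidy(mrf)))
  expect_false(is.na(glance(mrf)$oob_error))
})
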