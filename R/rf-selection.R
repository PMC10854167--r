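#' Random-forest parameters
#'
#' Defaults follow common practice for methylation classifiers: 500 trees,
#' terminal node size 1 (fully grown trees), and `mtry = floor(sqrt(p))`
#' recomputed whenever the feature count `p` changes during selection.
#'
#' @param ntree Number of trees (>= 1).
#' @param node_size Minimum terminal node size.
#' @param mtry Features tried per split; `NULL` (default) means
#'   `floor(sqrt(p))`, clamped to \[1, p\].
#' @param seed Integer seed; the forest is bit-reproducible given the seed.
#' @return An `rf_params` list.
#' @export
rf_params <- function(ntree = 500, node_size = 1, mtry = NULL, seed = 1) {
  stopifnot(ntree >= 1, node_size >= 1)
  structure(list(ntree = as.integer(ntree), node_size = as.integer(node_size),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 seed = as.integer(seed)),
            class = "rf_params")
}

resolve_mtry <- function(params, p) {
  m <- if (is.null(params$mtry)) floor(sqrt(p)) else params$mtry
  max(1L, min(as.integer(m), p))
}

# Fit the internal random forest on a numeric matrix. Used by both the
# selection stage and the "rf" classifier algorithm.
fit_random_forest <- function(X, y, params = rf_params(), importance = FALSE,
                              seed = NULL) {
  stopifnot(is.matrix(X), is.factor(y), nrow(X) == length(y))
  if (anyNA(X)) {
    stop("random forest input contains missing values; harmonize/impute first",
         call. = FALSE)
  }
  if (any(table(y) < 1) || nlevels(y) < 2) {
    stop("need at least 2 classes with samples", call. = FALSE)
  }
  fit <- cpp_rf_fit(X, as.integer(y) - 1L, nlevels(y), params$ntree,
                    resolve_mtry(params, ncol(X)), params$node_size,
                    if (is.null(seed)) params$seed else as.integer(seed),
                    importance)
  list(trees = fit$trees, classes = levels(y), features = colnames(X),
       ntree = params$ntree, oob_error = fit$oob_error,
       oob_votes = fit$oob_votes,
       importance = stats::setNames(fit$importance, colnames(X)))
}

rf_vote_fractions <- function(forest, X) {
  X <- X[, forest$features, drop = FALSE]
  votes <- cpp_rf_votes(forest$trees, X, length(forest$classes))
  colnames(votes) <- forest$classes
  rownames(votes) <- rownames(X)
  votes / length(forest$trees)
}

#' OOB permutation importance ranking
#'
#' Fits a random forest and ranks features by mean decrease in accuracy:
#' for each feature, the mean over trees of the rise in that tree's
#' out-of-bag error after permuting the feature's values among the tree's
#' OOB samples. Features a tree never splits on contribute exactly zero for
#' that tree. Ties are broken deterministically (score descending, then
#' probe id ascending).
#'
#' @param beta A beta tibble.
#' @param labels Labels tibble.
#' @param features Probe ids to rank; `NULL` means all probes of `beta`.
#' @param params [rf_params()].
#' @return An `importance_ranking` tibble: `probe_id`, `importance`, sorted;
#'   OOB error of the fitted forest in the `"oob_error"` attribute.
#' @export
oob_permutation_importance <- function(beta, labels, features = NULL,
                                       params = rf_params()) {
  X <- beta_to_matrix(beta)
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(X))
    if (length(missing) > 0) {
      stop("features not in beta matrix: ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
    }
    X <- X[, features, drop = FALSE]
  }
  y <- align_labels(beta, labels)
  fit <- fit_random_forest(X, y, params, importance = TRUE)
  ord <- order(-fit$importance, colnames(X))
  res <- tibble::tibble(probe_id = colnames(X)[ord],
                        importance = unname(fit$importance[ord]))
  attr(res, "oob_error") <- fit$oob_error
  class(res) <- c("importance_ranking", class(res))
  res
}

#' OOB-error-guided forward feature inclusion
#'
#' Walks a ranked candidate list in order of descending importance, starting
#' from the top-ranked feature, and accepts each candidate only if retraining
#' the forest on the enlarged set lowers the OOB error by more than
#' `min_improve`. `min_improve = 0` is the literal strict-decrease rule; a
#' small positive tolerance damps acceptance of candidates whose apparent
#' improvement is OOB noise.
#'
#' @param beta A beta tibble.
#' @param labels Labels tibble.
#' @param ranking An `importance_ranking` tibble or character vector of probe
#'   ids in rank order.
#' @param params [rf_params()]. Each retrain uses seed `params$seed + step`.
#' @param min_improve Minimum OOB-error decrease to accept a candidate.
#' @return A `selection_run` list: `kept` (inclusion order), `oob_trace`
#'   (OOB error after each acceptance, strictly decreasing), `evaluated`
#'   (per-candidate tibble), `seed`.
#' @export
oob_forward_selection <- function(beta, labels, ranking,
                                  params = rf_params(), min_improve = 0) {
  probes <- if (is.data.frame(ranking)) ranking$probe_id else ranking
  if (length(probes) == 0) stop("empty ranking", call. = FALSE)
  X <- beta_to_matrix(beta)[, probes, drop = FALSE]
  y <- align_labels(beta, labels)

  kept <- probes[1]
  fit <- fit_random_forest(X[, kept, drop = FALSE], y, params,
                           seed = params$seed)
  current <- fit$oob_error
  trace <- current
  evaluated <- list(tibble::tibble(probe_id = kept, oob_error = current,
                                   accepted = TRUE))
  for (step in seq_along(probes)[-1]) {
    cand <- probes[step]
    trial <- c(kept, cand)
    fit <- fit_random_forest(X[, trial, drop = FALSE], y, params,
                             seed = params$seed + step)
    accept <- fit$oob_error < current - min_improve
    evaluated[[step]] <- tibble::tibble(probe_id = cand,
                                        oob_error = fit$oob_error,
                                        accepted = accept)
    if (accept) {
      kept <- trial
      current <- fit$oob_error
      trace <- c(trace, current)
    }
  }
  structure(list(kept = kept, oob_trace = trace,
                 evaluated = dplyr::bind_rows(evaluated),
                 seed = params$seed, min_improve = min_improve),
            class = "selection_run")
}

#' Two-step multi-run panel selection
#'
#' The full feature-selection procedure: (1) the candidate filter
#' ([select_candidate_cpgs()]) reduces the probe set to differentially
#' methylated CpGs; (2) for each of `n_runs` runs (differing only in RF
#' seed), a forest on the candidates yields a permutation-importance
#' ranking, forward inclusion guided by OOB error records a kept set, and
#' the run contributes its top `per_run_top` probes; (3) the per-run top
#' sets are unioned, a forest is retrained on the union, and the final
#' panel is the top `final_k` probes of the re-ranked union.
#'
#' `per_run_source` chooses where a run's top probes come from:
#' `"ranking"` (default) takes them from the run's full candidate importance
#' ranking, so each run contributes exactly `per_run_top` probes whenever
#' enough candidates exist; `"kept"` takes them from a re-ranking of the
#' run's forward-selected kept set (padded with the whole kept set when it
#' is smaller). The default matches the observed arithmetic of multi-run
#' unions, where each run contributes a full top list; see the package
#' vignette for the reasoning.
#'
#' @param beta Training beta tibble.
#' @param labels Labels tibble.
#' @param filter A [filter_config()].
#' @param params [rf_params()]; run `r` uses seed `params$seed + r`.
#' @param n_runs Number of selection runs.
#' @param per_run_top Probes contributed per run.
#' @param final_k Size of the final panel.
#' @param per_run_source `"ranking"` or `"kept"` (see above).
#' @param min_improve Forward-selection acceptance tolerance.
#' @return A `panel_selection` object: `panel` (ordered final probe list),
#'   `final_importance` (re-ranked union), `union`, `runs` (per-run
#'   rankings, kept sets and OOB traces), `candidates`, `diff_result`,
#'   and the configuration used.
#' @export
run_panel_selection <- function(beta, labels, filter = filter_config(),
                                params = rf_params(), n_runs = 5,
                                per_run_top = 200, final_k = 200,
                                per_run_source = c("ranking", "kept"),
                                min_improve = 0) {
  per_run_source <- match.arg(per_run_source)
  diff_res <- select_candidate_cpgs(beta, labels, filter)
  candidates <- candidate_probes(diff_res)
  if (length(candidates) == 0) {
    stop("no candidate probes available for selection", call. = FALSE)
  }
  if (length(candidates) < final_k) {
    warning(sprintf("only %d candidates for a %d-probe panel; proceeding",
                    length(candidates), final_k), call. = FALSE)
  }

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_params <- params
    run_params$seed <- params$seed + r
    ranking <- oob_permutation_importance(beta, labels, candidates, run_params)
    sel <- oob_forward_selection(beta, labels, ranking, run_params,
                                 min_improve)
    top <- if (per_run_source == "ranking") {
      head(ranking$probe_id, per_run_top)
    } else {
      kept_rank <- oob_permutation_importance(beta, labels, sel$kept,
                                              run_params)
      head(kept_rank$probe_id, per_run_top)
    }
    runs[[r]] <- list(seed = run_params$seed, ranking = ranking,
                      selection = sel, top = top)
  }

  union_probes <- sort(unique(unlist(lapply(runs, `[[`, "top"))))
  final_importance <- oob_permutation_importance(beta, labels, union_probes,
                                                 params)
  if (length(union_probes) < final_k) {
    warning(sprintf("union has %d probes (< final_k = %d); panel is the union",
                    length(union_probes), final_k), call. = FALSE)
  }
  panel <- head(final_importance$probe_id, final_k)

  structure(list(panel = panel, final_importance = final_importance,
                 union = union_probes, runs = runs, candidates = candidates,
                 diff_result = diff_res,
                 config = list(filter = filter, params = params,
                               n_runs = n_runs, per_run_top = per_run_top,
                               final_k = final_k,
                               per_run_source = per_run_source,
                               min_improve = min_improve)),
            class = "panel_selection")
}

#' @export
print.panel_selection <- function(x, ...) {
  cat(sprintf(
    "Panel selection: %d candidates -> %d runs -> union %d -> panel %d\n",
    length(x$candidates), length(x$runs), length(x$union), length(x$panel)
  ))
  invisible(x)
}

#' @method tidy panel_selection
#' @export
tidy.panel_selection <- function(x, ...) {
  in_run <- sapply(x$runs, function(r) x$final_importance$probe_id %in% r$top)
  colnames(in_run) <- paste0("run", seq_along(x$runs))
  dplyr::bind_cols(
    x$final_importance,
    tibble::as_tibble(in_run),
    tibble::tibble(in_final = x$final_importance$probe_id %in% x$panel)
  )
}

#' @method glance panel_selection
#' @export
glance.panel_selection <- function(x, ...) {
  tibble::tibble(n_candidates = length(x$candidates),
                 n_runs = length(x$runs),
                 n_union = length(x$union),
                 n_panel = length(x$panel))
}

#' Validation accuracy as a function of panel size
#'
#' Trains a classifier on the top `k` probes of a ranking for each `k` and
#' reports accuracy on a disjoint validation set — the sweep used to choose
#' the deployed panel size. `k` larger than the available ranking is skipped
#' with a warning.
#'
#' @param train_beta,valid_beta Disjoint beta tibbles.
#' @param labels Labels covering both sets.
#' @param ranking A `panel_selection` (its re-ranked union is used), an
#'   `importance_ranking`, or a character vector in rank order.
#' @param ks Panel sizes to evaluate.
#' @param algorithm Classifier algorithm, see [train_classifier()].
#' @param cfg Classifier configuration ([en_config()]).
#' @param params [rf_params()] when `algorithm = "rf"`.
#' @return A `panel_sweep` tibble: `k`, `n_features`, `accuracy`.
#' @export
sweep_panel_size <- function(train_beta, valid_beta, labels, ranking,
                             ks = c(50, 100, 150, 200, 250, 300),
                             algorithm = "en", cfg = en_config(),
                             params = rf_params()) {
  probes <- if (inherits(ranking, "panel_selection")) {
    ranking$final_importance$probe_id
  } else if (is.data.frame(ranking)) {
    ranking$probe_id
  } else ranking
  overlap <- intersect(train_beta$sample_id, valid_beta$sample_id)
  if (length(overlap) > 0) {
    stop("train and validation sets share samples", call. = FALSE)
  }
  skipped <- ks[ks > length(probes)]
  if (length(skipped) > 0) {
    warning("skipping k > available features: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  ks <- ks[ks <= length(probes)]
  rows <- lapply(ks, function(k) {
    panel <- head(probes, k)
    model <- train_classifier(train_beta[, c("sample_id", panel)], labels,
                              algorithm = algorithm, cfg = cfg,
                              params = params)
    hv <- harmonize_to_panel(valid_beta, panel, impute = "training_mean",
                             impute_values = model$impute_means)
    pred <- predict(model, hv)
    truth <- labels$class[match(pred$sample_id, labels$sample_id)]
    tibble::tibble(k = k, n_features = length(panel),
                   accuracy = mean(pred$predicted_class == truth))
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("panel_sweep", class(res))
  res
}
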