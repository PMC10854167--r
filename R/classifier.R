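MODEL_FORMAT_VERSION <- "1.0"

#' Elastic-net classifier configuration
#'
#' Multinomial logistic regression with an elastic-net penalty. `alpha_mix`
#' is the L1/L2 mixing parameter (1 = lasso, 0 = ridge); the default 0.5 is
#' the conventional midpoint. The penalty strength `lambda` is chosen by
#' cross-validated multinomial deviance on the training set unless given
#' explicitly. Features are standardised internally for the penalised fit;
#' coefficients are reported on the original beta scale.
#'
#' @param alpha_mix Elastic-net mixing parameter in \[0, 1\].
#' @param cv_folds Cross-validation folds for lambda selection (>= 2);
#'   reduced with a warning when the smallest class has fewer samples.
#' @param standardize Standardise features inside the fit.
#' @param lambda Optional fixed penalty; `NULL` selects by CV.
#' @param seed Integer seed controlling the CV fold assignment.
#' @return An `en_config` list.
#' @export
en_config <- function(alpha_mix = 0.5, cv_folds = 5, standardize = TRUE,
                      lambda = NULL, seed = 1) {
  stopifnot(alpha_mix >= 0, alpha_mix <= 1, cv_folds >= 2)
  structure(list(alpha_mix = alpha_mix, cv_folds = as.integer(cv_folds),
                 standardize = isTRUE(standardize), lambda = lambda,
                 seed = as.integer(seed)),
            class = "en_config")
}

# stratified, seeded fold assignment so every fold sees every class
make_foldid <- function(y, nfolds, seed) {
  withr::local_seed(seed)
  foldid <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  foldid
}

#' Train a tissue-of-origin classifier on a probe panel
#'
#' Fits one of three multiclass models on a harmonized beta matrix:
#' `"en"` / `"lasso"` (multinomial logistic regression with elastic-net /
#' L1 penalty, via glmnet; lasso is the `alpha_mix = 1` special case) or
#' `"rf"` (the package's random forest). Per-probe training means are
#' computed and stored so new samples from sparser platforms can be
#' harmonized with [harmonize_to_panel()] before prediction.
#'
#' @param beta Training beta tibble, restricted to the panel probes, with no
#'   missing values.
#' @param labels Labels tibble covering the training samples.
#' @param algorithm `"en"`, `"lasso"` or `"rf"`.
#' @param cfg [en_config()] for the penalised fits.
#' @param params [rf_params()] for the forest.
#' @return A `meth_classifier` object.
#' @export
train_classifier <- function(beta, labels, algorithm = c("en", "lasso", "rf"),
                             cfg = en_config(), params = rf_params()) {
  algorithm <- match.arg(algorithm)
  validate_beta(beta)
  X <- beta_to_matrix(beta)
  if (anyNA(X)) {
    stop("training matrix has missing values; run harmonize_to_panel() first",
         call. = FALSE)
  }
  y <- align_labels(beta, labels)
  if (nlevels(y) < 2) stop("need at least 2 classes to train", call. = FALSE)
  impute_means <- colMeans(X)

  if (algorithm %in% c("en", "lasso")) {
    alpha <- if (algorithm == "lasso") 1 else cfg$alpha_mix
    Xfit <- X
    if (ncol(Xfit) == 1) {
      # glmnet needs >= 2 columns; a zero-variance pad gets coefficient 0
      Xfit <- cbind(Xfit, `.pad.` = 0)
    }
    nfolds <- cfg$cv_folds
    min_class <- min(table(y))
    if (min_class < nfolds) {
      nfolds <- max(2L, as.integer(min_class))
      warning(sprintf("smallest class has %d samples; reducing cv folds to %d",
                      min_class, nfolds), call. = FALSE)
    }
    if (is.null(cfg$lambda)) {
      foldid <- make_foldid(y, nfolds, cfg$seed)
      cv <- glmnet::cv.glmnet(Xfit, y, family = "multinomial", alpha = alpha,
                              foldid = foldid, type.measure = "deviance",
                              standardize = cfg$standardize)
      lambda <- cv$lambda.min
      fit <- cv$glmnet.fit
    } else {
      lambda <- cfg$lambda
      fit <- glmnet::glmnet(Xfit, y, family = "multinomial", alpha = alpha,
                            standardize = cfg$standardize)
    }
    co <- stats::coef(fit, s = lambda)
    intercepts <- vapply(co, function(m) m[1, 1], numeric(1))
    coefs <- vapply(co, function(m) as.numeric(m[-1, 1]),
                    numeric(ncol(Xfit)))
    rownames(coefs) <- colnames(Xfit)
    coefs <- coefs[colnames(X), , drop = FALSE]
    fitted <- list(intercepts = intercepts, coefficients = coefs,
                   lambda = lambda, alpha_mix = alpha)
  } else {
    fitted <- fit_random_forest(X, y, params, importance = TRUE)
  }

  structure(list(
    version = MODEL_FORMAT_VERSION,
    algorithm = algorithm,
    classes = levels(y),
    probes = colnames(X),
    impute_means = impute_means,
    fitted = fitted,
    meta = list(
      n_train = nrow(X),
      config = if (algorithm == "rf") unclass(params) else unclass(cfg),
      note = if (algorithm != "rf") {
        "elastic-net mixing and lambda rule are package defaults (CV deviance)"
      } else NULL
    )
  ), class = "meth_classifier")
}

#' @export
print.meth_classifier <- function(x, ...) {
  cat(sprintf("<meth_classifier> %s: %d classes, %d probes\n",
              x$algorithm, length(x$classes), length(x$probes)))
  invisible(x)
}

softmax_rows <- function(eta) {
  m <- apply(eta, 1, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

#' Predict tissue of origin for new samples
#'
#' Produces per-class probabilities and the argmax call for each sample.
#' Probabilities are softmax-normalised linear predictors for the penalised
#' models and tree-vote fractions for the forest; they sum to 1 per sample.
#' The predicted class is the one with the highest probability; an exact
#' tie goes to the lexicographically first class and is flagged.
#'
#' @param object A `meth_classifier`.
#' @param beta A beta tibble whose probes exactly match the model's panel
#'   (use [harmonize_to_panel()] with the model's `impute_means` otherwise).
#' @param ... Unused.
#' @return A tibble: `sample_id`, `predicted_class`, `margin` (top minus
#'   runner-up probability), `tie`, and one `prob_<class>` column per class.
#' @export
predict.meth_classifier <- function(object, beta, ...) {
  validate_beta(beta)
  if (!setequal(probe_ids(beta), object$probes)) {
    stop("probe set does not match the model's panel; ",
         "run harmonize_to_panel(beta, model$probes, impute_values = ",
         "model$impute_means) first", call. = FALSE)
  }
  X <- beta_to_matrix(beta)[, object$probes, drop = FALSE]
  if (anyNA(X)) {
    stop("missing values in input; run harmonize_to_panel() first",
         call. = FALSE)
  }
  if (object$algorithm %in% c("en", "lasso")) {
    eta <- X %*% object$fitted$coefficients
    eta <- sweep(eta, 2, object$fitted$intercepts, `+`)
    probs <- softmax_rows(eta)
  } else {
    probs <- rf_vote_fractions(object$fitted, X)
  }
  colnames(probs) <- object$classes

  top <- apply(probs, 1, function(p) {
    best <- which(p == max(p))[1]   # lexicographic tie-break: classes sorted
    sorted <- sort(p, decreasing = TRUE)
    c(best, sorted[1] - ifelse(length(sorted) > 1, sorted[2], 0),
      sum(p == max(p)) > 1)
  })
  res <- tibble::tibble(
    sample_id = rownames(X),
    predicted_class = object$classes[top[1, ]],
    margin = top[2, ],
    tie = as.logical(top[3, ])
  )
  probs_tbl <- tibble::as_tibble(probs, .name_repair = "minimal")
  names(probs_tbl) <- paste0("prob_", object$classes)
  dplyr::bind_cols(res, probs_tbl)
}

#' Save / load a fitted classifier
#'
#' Models are stored as a single self-contained JSON file: a metadata block
#' (format version, algorithm, classes, probes, seeds) plus the parameter
#' arrays (coefficients or forest). Numbers are written at full precision so
#' a round trip reproduces predictions bitwise. Loading refuses files with a
#' newer major format version or missing version field.
#'
#' @param model A `meth_classifier`.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the `meth_classifier`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "meth_classifier"))
  payload <- unclass(model)
  if (model$algorithm %in% c("en", "lasso")) {
    # per-class coefficient vectors; row order is the probe order
    payload$fitted$coefficients <-
      as.list(as.data.frame(payload$fitted$coefficients))
  } else {
    payload$fitted$oob_votes <- NULL  # bulky and not needed for prediction
  }
  # I(17) significant digits: doubles survive the round trip bitwise
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop("model file does not exist: '", path, "'", call. = FALSE)
  }
  obj <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE),
                                     simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE),
                  error = function(e) {
                    stop("cannot parse model file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(obj$version)) {
    stop("model file has no format version field", call. = FALSE)
  }
  major <- as.integer(strsplit(as.character(obj$version), "[.]")[[1]][1])
  have <- as.integer(strsplit(MODEL_FORMAT_VERSION, "[.]")[[1]][1])
  if (is.na(major) || major > have) {
    stop(sprintf("model format version %s is newer than supported (%s)",
                 obj$version, MODEL_FORMAT_VERSION), call. = FALSE)
  }
  obj$impute_means <- stats::setNames(as.numeric(obj$impute_means),
                                      obj$probes)
  if (obj$algorithm %in% c("en", "lasso")) {
    cm <- do.call(cbind, lapply(obj$fitted$coefficients, as.numeric))
    rownames(cm) <- obj$probes
    colnames(cm) <- obj$classes
    obj$fitted$coefficients <- cm
    obj$fitted$intercepts <- stats::setNames(
      as.numeric(obj$fitted$intercepts), obj$classes)
  } else {
    obj$fitted$trees <- lapply(obj$fitted$trees, function(t) {
      list(feature = as.integer(t$feature),
           threshold = as.numeric(t$threshold),
           left = as.integer(t$left), right = as.integer(t$right),
           pred = as.integer(t$pred))
    })
    obj$fitted$importance <- stats::setNames(
      as.numeric(obj$fitted$importance), obj$fitted$features)
  }
  structure(obj, class = "meth_classifier")
}

#' @method tidy meth_classifier
#' @export
tidy.meth_classifier <- function(x, ...) {
  if (x$algorithm %in% c("en", "lasso")) {
    cm <- x$fitted$coefficients
    tibble::tibble(
      class = rep(colnames(cm), each = nrow(cm)),
      term = rep(rownames(cm), times = ncol(cm)),
      estimate = c(cm)
    ) |> dplyr::filter(.data$estimate != 0)
  } else {
    imp <- x$fitted$importance
    tibble::tibble(term = names(imp), importance = unname(imp)) |>
      dplyr::arrange(dplyr::desc(.data$importance), .data$term)
  }
}

#' @method glance meth_classifier
#' @export
glance.meth_classifier <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    n_classes = length(x$classes),
    n_probes = length(x$probes),
    n_train = x$meta$n_train,
    lambda = if (x$algorithm == "rf") NA_real_ else x$fitted$lambda,
    alpha_mix = if (x$algorithm == "rf") NA_real_ else x$fitted$alpha_mix,
    oob_error = if (x$algorithm == "rf") x$fitted$oob_error else NA_real_
  )
}
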