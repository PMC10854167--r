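#' Configuration for the differential-methylation candidate filter
#'
#' The filter keeps CpGs that are differentially methylated in at least one
#' class: per-CpG one-way ANOVA across classes followed by Tukey's honest
#' significant difference post hoc test, with both a significance threshold
#' and a minimum absolute group-mean beta difference (delta-beta).
#'
#' @param delta Minimum absolute group-mean beta difference (default 0.2).
#' @param alpha Significance level for both the ANOVA and the Tukey-adjusted
#'   pairwise p-values (default 0.01). Thresholds are per-probe; no
#'   across-probe multiplicity correction is applied.
#' @param criterion `"one_vs_all"` (default): a probe passes when some class
#'   separates from *every* other class at both thresholds. `"any_pair"`:
#'   one qualifying pair suffices (sensitivity analysis).
#' @return A `filter_config` list.
#' @export
filter_config <- function(delta = 0.2, alpha = 0.01,
                          criterion = c("one_vs_all", "any_pair")) {
  criterion <- match.arg(criterion)
  stopifnot(delta > 0, delta < 1, alpha > 0, alpha < 1)
  structure(list(delta = delta, alpha = alpha, criterion = criterion),
            class = "filter_config")
}

#' One-way ANOVA for a single CpG
#'
#' Classic fixed-effects one-way ANOVA of beta values across classes:
#' F = between-group mean square / within-group mean square on (k-1, N-k)
#' degrees of freedom. Missing values are dropped. With zero within- and
#' between-group variance (all values identical) the statistic is undefined
#' and reported as `NA`; perfect separation gives `F = Inf`, `p = 0`.
#'
#' @param values Numeric vector of beta values for one probe.
#' @param groups Class membership, same length as `values`.
#' @return One-row tibble: `statistic`, `p_value`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]
  g <- factor(groups[keep])
  if (nlevels(g) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(table(g) < 2)) {
    stop("every class needs >= 2 non-missing values", call. = FALSE)
  }
  n_g <- tapply(values, g, length)
  m_g <- tapply(values, g, mean)
  N <- length(values)
  k <- nlevels(g)
  ssb <- sum(n_g * (m_g - mean(values))^2)
  ssw <- sum((values - m_g[g])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  f <- if (msw == 0 && msb == 0) NA_real_ else msb / msw
  p <- if (is.na(f)) NA_real_ else pf(f, k - 1, N - k, lower.tail = FALSE)
  tibble::tibble(statistic = f, p_value = p,
                 df_between = k - 1, df_within = N - k)
}

#' Tukey HSD post hoc test for a single CpG
#'
#' All-pairs comparisons of class mean beta values using the studentized
#' range distribution with the pooled within-group variance and the
#' Tukey-Kramer standard error for unequal class sizes:
#' `q = |mean_a - mean_b| / sqrt(msw/2 * (1/n_a + 1/n_b))`, with adjusted
#' p-value from the range distribution with k groups and N-k df. With two
#' groups this reduces to the pooled-variance two-sample t-test
#' (`q = |t| * sqrt(2)`).
#'
#' @inheritParams one_way_anova
#' @return A tibble with one row per class pair: `class_a`, `class_b`,
#'   `delta` (mean_a - mean_b), `q`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]
  g <- factor(groups[keep])
  if (nlevels(g) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(table(g) < 2)) {
    stop("every class needs >= 2 non-missing values", call. = FALSE)
  }
  n_g <- tapply(values, g, length)
  m_g <- tapply(values, g, mean)
  k <- nlevels(g)
  N <- length(values)
  msw <- sum((values - m_g[g])^2) / (N - k)
  pairs <- utils::combn(levels(g), 2)
  delta <- m_g[pairs[1, ]] - m_g[pairs[2, ]]
  se <- sqrt(msw / 2 * (1 / n_g[pairs[1, ]] + 1 / n_g[pairs[2, ]]))
  q <- abs(delta) / se
  p_adj <- ifelse(is.nan(q), 1,
                  ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE))
  tibble::tibble(class_a = pairs[1, ], class_b = pairs[2, ],
                 delta = as.numeric(delta), q = as.numeric(q),
                 p_adj = as.numeric(p_adj))
}

#' Differential methylation across all probes of a beta matrix
#'
#' Vectorised per-probe one-way ANOVA and Tukey HSD over every CpG of a
#' beta matrix, applying the candidate filter of `cfg`. Missingness is
#' handled per probe by complete-case analysis; a probe where any class
#' retains fewer than 2 samples is flagged unevaluable and cannot pass.
#'
#' @param beta A beta tibble.
#' @param labels Labels tibble (`sample_id`, `class`) covering the samples.
#' @param cfg A [filter_config()].
#' @return A `diff_meth` tibble with one row per probe: `probe_id`,
#'   `statistic`, `p_value`, `qualifying_class` (under `one_vs_all`),
#'   `min_pair_p`, `max_abs_delta`, `evaluable`, `pass`. The per-pair table
#'   (`probe_id`, `class_a`, `class_b`, `delta`, `p_adj`) is in the
#'   `"pairs"` attribute; the candidate probe list in `"candidates"`.
#' @export
diff_methylation <- function(beta, labels, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  X <- beta_to_matrix(beta)
  g <- align_labels(beta, labels)
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 classes", call. = FALSE)

  obs <- !is.na(X)
  X0 <- ifelse(obs, X, 0)
  n_g <- rowsum(obs + 0, g)             # k x p counts
  s_g <- rowsum(X0, g)
  ss_g <- rowsum(X0^2, g)
  m_g <- s_g / n_g                      # NaN where a class has no data
  evaluable <- colSums(n_g >= 2) == k
  N <- colSums(n_g)
  grand <- colSums(s_g) / N
  ssw <- pmax(colSums(ss_g - n_g * ifelse(n_g > 0, m_g, 0)^2, na.rm = TRUE), 0)
  ssb <- pmax(colSums(n_g * sweep(ifelse(n_g > 0, m_g, 0), 2, grand)^2,
                      na.rm = TRUE), 0)
  df2 <- N - k
  msw <- ssw / df2
  msb <- ssb / (k - 1)
  f <- ifelse(msw == 0 & msb == 0, NA_real_, msb / msw)   # Inf when msw=0
  p <- ifelse(is.na(f), NA_real_, pf(f, k - 1, df2, lower.tail = FALSE))
  f[!evaluable] <- NA_real_
  p[!evaluable] <- NA_real_

  cl <- levels(g)
  pair_idx <- utils::combn(k, 2)
  n_pairs <- ncol(pair_idx)
  p_probes <- ncol(X)
  # per-pair matrices over probes
  delta_m <- matrix(NA_real_, n_pairs, p_probes)
  padj_m <- matrix(NA_real_, n_pairs, p_probes)
  for (j in seq_len(n_pairs)) {
    a <- pair_idx[1, j]; b <- pair_idx[2, j]
    d <- m_g[a, ] - m_g[b, ]
    se <- sqrt(msw / 2 * (1 / n_g[a, ] + 1 / n_g[b, ]))
    q <- abs(d) / se
    pa <- ifelse(is.nan(q) | is.na(q), 1,
                 ptukey(q, nmeans = k, df = df2, lower.tail = FALSE))
    delta_m[j, ] <- d
    padj_m[j, ] <- pa
  }

  alpha <- cfg$alpha; delta_thr <- cfg$delta
  pair_ok <- padj_m < alpha & abs(delta_m) > delta_thr
  pair_ok[is.na(pair_ok)] <- FALSE

  # per-class all-pairs condition: class c vs every other class
  class_ok <- matrix(TRUE, k, p_probes)
  for (j in seq_len(n_pairs)) {
    a <- pair_idx[1, j]; b <- pair_idx[2, j]
    class_ok[a, ] <- class_ok[a, ] & pair_ok[j, ]
    class_ok[b, ] <- class_ok[b, ] & pair_ok[j, ]
  }
  anova_ok <- !is.na(p) & p < alpha & evaluable
  qualifying <- apply(class_ok, 2, function(z) {
    w <- which(z)
    if (length(w) == 0) NA_character_ else cl[w[1]]
  })
  pass <- if (cfg$criterion == "one_vs_all") {
    anova_ok & colSums(class_ok) > 0
  } else {
    anova_ok & colSums(pair_ok) > 0
  }
  qualifying[!pass] <- NA_character_

  res <- tibble::tibble(
    probe_id = colnames(X),
    statistic = unname(f), p_value = unname(p),
    qualifying_class = unname(qualifying),
    min_pair_p = apply(padj_m, 2, min),
    max_abs_delta = apply(abs(delta_m), 2, max),
    evaluable = unname(evaluable), pass = unname(pass)
  )
  pairs_tbl <- tibble::tibble(
    probe_id = rep(colnames(X), each = n_pairs),
    class_a = rep(cl[pair_idx[1, ]], times = p_probes),
    class_b = rep(cl[pair_idx[2, ]], times = p_probes),
    delta = c(delta_m), p_adj = c(padj_m)
  )
  attr(res, "pairs") <- pairs_tbl
  attr(res, "candidates") <- res$probe_id[res$pass]
  attr(res, "config") <- cfg
  class(res) <- c("diff_meth", class(res))
  res
}

#' Select candidate CpGs for panel construction
#'
#' Thin wrapper over [diff_methylation()] that warns when no probe passes
#' the filter (downstream stages handle the empty candidate set).
#'
#' @inheritParams diff_methylation
#' @return The `diff_meth` tibble; candidate probe ids are in the
#'   `"candidates"` attribute and via [candidate_probes()].
#' @export
select_candidate_cpgs <- function(beta, labels, cfg = filter_config()) {
  res <- diff_methylation(beta, labels, cfg)
  if (length(attr(res, "candidates")) == 0) {
    warning("no probe passed the candidate filter", call. = FALSE)
  }
  res
}

#' @rdname select_candidate_cpgs
#' @param result A `diff_meth` result.
#' @export
candidate_probes <- function(result) {
  attr(result, "candidates")
}
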