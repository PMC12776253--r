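#' One-way ANOVA by explicit sums of squares
#'
#' Classical fixed-effects one-way analysis of variance:
#' `F = MS_between / MS_within`, with the p-value from the upper tail of
#' the F distribution on (k - 1, N - k) degrees of freedom.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @return A list with `F`, `df1`, `df2`, `p`, `ms_within`, `grand_mean`,
#'   `means`, `ns`, and `degenerate` (`TRUE` when the within-group variance
#'   is zero but group means differ, in which case `p = 0`).
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))$F # 3
#' @export
anova_oneway <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort("Need >= 2 groups with >= 2 values each.")
  }
  ns <- lengths(groups)
  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  msb <- ssb / df1
  msw <- ssw / df2
  if (msw == 0 && msb == 0) {
    abort("All values identical: the feature has zero variance.")
  }
  degenerate <- msw == 0
  f <- if (degenerate) Inf else msb / msw
  p <- if (degenerate) 0 else pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, df1 = df1, df2 = df2, p = p, ms_within = msw,
       grand_mean = grand, means = means, ns = ns, degenerate = degenerate)
}

#' Tukey (Tukey-Kramer) pairwise comparisons
#'
#' For every pair of groups computes the mean difference, the studentized
#' range statistic
#' `q = |mean_i - mean_j| / sqrt(MS_within / 2 * (1/n_i + 1/n_j))`
#' and the family-wise adjusted p-value from the studentized range
#' distribution with `k` groups and the ANOVA within-group degrees of
#' freedom. Unbalanced groups use the Tukey-Kramer standard error.
#'
#' @param groups List of >= 2 numeric vectors (named names are kept).
#' @return Tibble with `group_i`, `group_j`, `difference`
#'   (`mean_j - mean_i`), `q`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  a <- anova_oneway(groups)
  k <- length(groups)
  nms <- names(groups) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(c_) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    diff <- a$means[j] - a$means[i]
    se <- sqrt(a$ms_within / 2 * (1 / a$ns[i] + 1 / a$ns[j]))
    q <- if (se == 0) ifelse(diff == 0, 0, Inf) else abs(diff) / se
    p <- if (is.infinite(q)) 0 else ptukey(q, nmeans = k, df = a$df2,
                                           lower.tail = FALSE)
    tibble::tibble(group_i = nms[i], group_j = nms[j],
                   difference = unname(diff), q = unname(q),
                   p_adj = unname(p))
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the
#' input. Thin, validated wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Differential abundance across differentiation days
#'
#' Per-feature one-way ANOVA over the day groups (on log2 values by
#' default), Benjamini-Hochberg adjustment across features, then Tukey
#' pairwise comparisons within each feature. Pairwise p-values of the
#' ANOVA-significant features are pooled and BH-adjusted across that pool.
#' A feature is called significant when its ANOVA `padj < alpha` and at
#' least one Tukey pair has `padj < alpha`. Features with fewer than
#' `min_per_group` observed replicates in any day, or zero variance, are
#' skipped and reported.
#'
#' @param matrix An [abundance_matrix()] at protein or site-normalized
#'   level.
#' @param design A [study_design()] (or any tibble with `sample`, `day`).
#' @param alpha Significance threshold applied to both adjusted levels
#'   (default 0.05).
#' @param log2_transform Analyse `log2(value)` (default `TRUE`).
#' @param pair_adjust `"bh"` (default) to BH-adjust pooled Tukey p-values
#'   across significant features, `"none"` to use Tukey's family-wise
#'   p-values directly.
#' @param min_per_group Minimum observed replicates per day (default 2).
#' @return A tibble of class `kme_diff`: per feature the day means (log2
#'   scale when transformed), `F`, `p`, `padj`, per pair (`2v0`, `6v0`,
#'   `6v2`) the difference, Tukey p, pair padj and `log2fc_*`, and
#'   `significant`. Skipped features are in `attr(, "skip_report")`.
#' @export
differential_features <- function(matrix, design, alpha = 0.05,
                                  log2_transform = TRUE,
                                  pair_adjust = c("bh", "none"),
                                  min_per_group = 2) {
  pair_adjust <- match.arg(pair_adjust)
  sc <- sample_cols(matrix)
  if (!all(design$sample %in% sc)) {
    abort("Design samples missing from the abundance matrix.")
  }
  pair_names <- c("2v0", "6v0", "6v2")
  pair_idx <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))

  x <- as.matrix(matrix[design$sample])
  if (log2_transform) {
    if (any(x <= 0, na.rm = TRUE)) {
      abort("Non-positive values cannot be log2-transformed; add a pseudocount.")
    }
    x <- log2(x)
  }
  day_cols <- lapply(c(0L, 2L, 6L), function(d) which(design$day == d))
  # per-day observation counts, means and within-group sums of squares,
  # vectorized across features
  ns <- sapply(day_cols, function(cc) rowSums(!is.na(x[, cc, drop = FALSE])))
  ns <- base::matrix(ns, ncol = 3)
  sums <- sapply(day_cols, function(cc) rowSums(x[, cc, drop = FALSE], na.rm = TRUE))
  sums <- base::matrix(sums, ncol = 3)
  means <- sums / ns
  sqsum <- sapply(day_cols, function(cc) rowSums(x[, cc, drop = FALSE]^2, na.rm = TRUE))
  sqsum <- base::matrix(sqsum, ncol = 3)
  ssw_g <- sqsum - ns * means^2
  ssw <- pmax(rowSums(ssw_g), 0)
  N <- rowSums(ns)
  grand <- rowSums(sums) / N
  ssb <- rowSums(ns * (means - grand)^2)
  df2 <- N - 3L
  msw <- ssw / df2
  msb <- ssb / 2

  too_few <- apply(ns < min_per_group, 1, any)
  zero_var <- !too_few & (msw + msb) <= 1e-300
  degenerate <- !too_few & !zero_var & msw <= .Machine$double.eps * pmax(msb, 1)
  ok <- !too_few & !zero_var

  skipped <- tibble::tibble(
    feature_id = c(matrix$feature_id[too_few], matrix$feature_id[zero_var]),
    reason = c(rep("insufficient_replicates", sum(too_few)),
               rep("zero_variance", sum(zero_var)))
  )

  f <- ifelse(degenerate, Inf, msb / msw)
  p <- ifelse(degenerate, 0, pf(f, 2, df2, lower.tail = FALSE))
  out <- tibble::tibble(
    feature_id = matrix$feature_id,
    accession = if ("accession" %in% names(matrix)) matrix$accession else matrix$feature_id,
    mean_d0 = means[, 1], mean_d2 = means[, 2], mean_d6 = means[, 3],
    F = f, df1 = 2L, df2 = as.integer(df2), p = p, degenerate = degenerate
  )
  for (pi in seq_along(pair_names)) {
    ij <- pair_idx[[pi]]
    diffp <- means[, ij[2]] - means[, ij[1]]
    se <- sqrt(msw / 2 * (1 / ns[, ij[1]] + 1 / ns[, ij[2]]))
    q <- ifelse(se == 0, ifelse(diffp == 0, 0, Inf), abs(diffp) / se)
    pp <- ifelse(is.infinite(q), 0, ptukey(q, nmeans = 3, df = df2,
                                           lower.tail = FALSE))
    out[[paste0("diff_", pair_names[pi])]] <- diffp
    out[[paste0("p_", pair_names[pi])]] <- pp
    out[[paste0("log2fc_", pair_names[pi])]] <-
      if (log2_transform) diffp else log2(means[, ij[2]] / means[, ij[1]])
  }
  out <- out[ok, , drop = FALSE]
  if (nrow(out) > 0) {
    out$padj <- bh_adjust(out$p)
    sig_anova <- out$padj < alpha
    pair_p_cols <- paste0("p_", pair_names)
    pair_padj <- matrix(NA_real_, nrow(out), 3,
                        dimnames = list(NULL, paste0("padj_", pair_names)))
    if (any(sig_anova)) {
      pooled <- as.matrix(out[sig_anova, pair_p_cols])
      adj <- if (pair_adjust == "bh") bh_adjust(as.vector(pooled)) else as.vector(pooled)
      pair_padj[sig_anova, ] <- matrix(adj, ncol = 3)
    }
    out <- dplyr::bind_cols(out, tibble::as_tibble(pair_padj))
    out$significant <- sig_anova &
      rowSums(pair_padj < alpha, na.rm = TRUE) > 0
  } else {
    out <- tibble::tibble(feature_id = character(), significant = logical())
  }
  attr(out, "skip_report") <- skipped
  attr(out, "alpha") <- alpha
  class(out) <- unique(c("kme_diff", class(out)))
  out
}

#' Pairwise replicate correlation
#'
#' Pearson correlation between all sample pairs on (log2) abundances,
#' pairwise-complete; pairs with fewer than 3 complete observations get a
#' missing `r`.
#'
#' @param matrix An [abundance_matrix()].
#' @param log2_transform Correlate `log2(value)` (default `TRUE`).
#' @return Tibble `sample_i`, `sample_j`, `r`, `n` covering all ordered
#'   pairs including the diagonal (`r = 1`).
#' @export
replicate_correlation <- function(matrix, log2_transform = TRUE) {
  sc <- sample_cols(matrix)
  if (length(sc) < 2) abort("Need >= 2 samples.")
  x <- as.matrix(matrix[sc])
  if (log2_transform) x <- log2(x)
  grid <- expand.grid(i = seq_along(sc), j = seq_along(sc))
  purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    i <- grid$i[g]; j <- grid$j[g]
    ok <- stats::complete.cases(x[, c(i, j)])
    n <- sum(ok)
    r <- if (n < 3) NA_real_ else cor(x[ok, i], x[ok, j])
    tibble::tibble(sample_i = sc[i], sample_j = sc[j], r = r, n = n)
  })
}

#' Principal component analysis of samples
#'
#' Features with any missing value are dropped (PCA only), each remaining
#' feature is z-scored across samples, and the sample-by-feature matrix is
#' column-centered and decomposed by SVD. Component signs are fixed by
#' forcing each component's largest-magnitude feature loading positive.
#'
#' @param matrix An [abundance_matrix()].
#' @param log2_transform Use `log2(value)` (default `TRUE`).
#' @param n_components Number of components to keep (default 2).
#' @return A list of class `kme_pca`: `scores` (tibble `sample`,
#'   `PC1`..), `explained_variance` (fractions, non-increasing),
#'   `n_features`.
#' @export
pca_samples <- function(matrix, log2_transform = TRUE, n_components = 2) {
  sc <- sample_cols(matrix)
  if (length(sc) < 2) abort("Need >= 2 samples for PCA.")
  x <- as.matrix(matrix[sc])
  complete <- stats::complete.cases(x)
  x <- x[complete, , drop = FALSE]
  if (log2_transform) x <- log2(x)
  sds <- apply(x, 1, sd)
  x <- x[sds > 0, , drop = FALSE]
  z <- t(scale(t(x)))           # z-score each feature across samples
  m <- t(z)                     # samples x features
  m <- scale(m, center = TRUE, scale = FALSE)
  dec <- svd(m)
  keep <- seq_len(min(n_components, length(dec$d)))
  # sign convention: largest-|loading| positive per component
  for (c_ in keep) {
    v <- dec$v[, c_]
    if (v[which.max(abs(v))] < 0) {
      dec$v[, c_] <- -v
      dec$u[, c_] <- -dec$u[, c_]
    }
  }
  scores <- sweep(dec$u[, keep, drop = FALSE], 2, dec$d[keep], `*`)
  colnames(scores) <- paste0("PC", keep)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample = sc),
                              tibble::as_tibble(scores)),
    explained_variance = (dec$d^2 / sum(dec$d^2)),
    n_features = nrow(x)
  ), class = "kme_pca")
}
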