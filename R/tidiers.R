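#' Tidy a differential-methylation result
#'
#' One row per feature and pairwise comparison, volcano-ready
#' (`log2fc`, `neg_log10_padj`).
#'
#' @param x A `kme_diff` tibble from [differential_features()].
#' @param ... Unused.
#' @return Tibble `feature_id`, `accession`, `contrast`, `log2fc`,
#'   `p_pair`, `padj_pair`, `padj_anova`, `neg_log10_padj`, `significant`.
#' @export
tidy.kme_diff <- function(x, ...) {
  pairs <- c("2v0", "6v0", "6v2")
  purrr::map_dfr(pairs, function(pr) {
    tibble::tibble(
      feature_id = x$feature_id,
      accession = x$accession,
      contrast = paste0("day", sub("v", "_vs_day", pr)),
      log2fc = x[[paste0("log2fc_", pr)]],
      p_pair = x[[paste0("p_", pr)]],
      padj_pair = x[[paste0("padj_", pr)]],
      padj_anova = x$padj,
      neg_log10_padj = -log10(pmax(x$padj, .Machine$double.xmin)),
      significant = x$significant
    )
  })
}

#' Summarise a differential-methylation result
#'
#' @param x A `kme_diff` tibble.
#' @param ... Unused.
#' @return One-row tibble: features tested/skipped, significant count,
#'   alpha.
#' @export
glance.kme_diff <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_skipped = nrow(attr(x, "skip_report") %||% tibble::tibble()),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha") %||% NA_real_
  )
}

#' Tidy sample PCA scores
#'
#' @param x A `kme_pca` object from [pca_samples()].
#' @param ... Unused.
#' @return The score tibble with one row per sample.
#' @export
tidy.kme_pca <- function(x, ...) x$scores

#' Summarise a sample PCA
#'
#' @param x A `kme_pca` object.
#' @param ... Unused.
#' @return One-row tibble with explained-variance fractions of the first
#'   two components and the feature count.
#' @export
glance.kme_pca <- function(x, ...) {
  tibble::tibble(
    pc1_var = x$explained_variance[1],
    pc2_var = x$explained_variance[2] %||% NA_real_,
    n_features = x$n_features
  )
}

#' Tidy a module assignment
#'
#' @param x A `kme_modules` object from [coexpression_modules()].
#' @param ... Unused.
#' @return Tibble `feature_id`, `module`.
#' @export
tidy.kme_modules <- function(x, ...) x$assignment

#' Summarise detected modules
#'
#' @param x A `kme_modules` object.
#' @param ... Unused.
#' @return One row per non-grey module with size, archetype and eigengene
#'   variance explained, plus the grey (unassigned) count as attribute-free
#'   columns `n_grey` repeated.
#' @export
glance.kme_modules <- function(x, ...) {
  n_grey <- sum(x$assignment$module == "grey")
  if (nrow(x$eigengenes) == 0) {
    return(tibble::tibble(module = character(), n_members = integer(),
                          archetype = character(), var_explained = double(),
                          n_grey = integer()))
  }
  dplyr::bind_cols(
    x$eigengenes[c("module", "n_members", "archetype", "var_explained")],
    tibble::tibble(n_grey = n_grey)
  )
}
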