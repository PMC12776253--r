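# Canonical module color sequence (size rank order), as used by weighted
# co-expression analysis tooling; "grey" is reserved for unassigned features.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue"
)

#' Co-expression network configuration
#'
#' Defaults follow the study's two analysis levels: soft-threshold power 30
#' and minimum module size 30 at the protein level; power 18 and minimum
#' size 10 for protein-normalized Kme peptides. Clustering is
#' average-linkage on topological-overlap dissimilarity with a static tree
#' cut.
#'
#' @param level `"protein"` or `"kme"`.
#' @param power Soft-threshold power (>= 1).
#' @param min_size Minimum module size (>= 2).
#' @param cut_height Static tree-cut height on `1 - TOM` (default 0.99).
#' @param merge_height Eigengene-correlation merge threshold; `NULL`
#'   (default) disables module merging.
#' @return List of class `network_config`.
#' @export
network_config <- function(level = c("protein", "kme"), power = NULL,
                           min_size = NULL, cut_height = 0.99,
                           merge_height = NULL) {
  level <- match.arg(level)
  power <- power %||% if (level == "protein") 30 else 18
  min_size <- min_size %||% if (level == "protein") 30 else 10
  if (power < 1) abort("`power` must be >= 1.")
  if (min_size < 2) abort("`min_size` must be >= 2.")
  structure(list(level = level, power = power, min_size = min_size,
                 cut_height = cut_height, merge_height = merge_height),
            class = "network_config")
}

#' Signed adjacency matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^power`: perfectly correlated features get
#' adjacency 1, anti-correlated features are suppressed toward 0 rather
#' than treated as connected.
#'
#' @param x Feature-by-sample numeric matrix (complete, each feature with
#'   nonzero variance) or an [abundance_matrix()] (log2-transformed
#'   internally).
#' @param power Soft-threshold power.
#' @param log2_transform For abundance matrices, correlate log2 values.
#' @return Symmetric adjacency matrix with unit diagonal, values in [0,1].
#' @export
signed_adjacency <- function(x, power, log2_transform = TRUE) {
  if (inherits(x, "kme_abun")) {
    m <- as.matrix(x[sample_cols(x)])
    rownames(m) <- x$feature_id
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (log2_transform) m <- log2(m)
    x <- m
  }
  if (ncol(x) < 4) abort("Need >= 4 samples to build a network.")
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    abort(sprintf("Zero-variance feature(s): %s",
                  paste(head(rownames(x)[sds == 0], 3), collapse = ", ")))
  }
  r <- cor(t(x))
  a <- ((1 + r) / 2)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' the sum over `u != i, j` and connectivity `k_i = sum_{u != i} a_iu`;
#' `TOM_ii = 1`. Two features overlap when they share neighbours even if
#' their direct adjacency is modest.
#'
#' @param adjacency Symmetric adjacency with unit diagonal.
#' @return The TOM matrix (symmetric, unit diagonal).
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    abort("`adjacency` must be symmetric.")
  }
  a <- adjacency
  n <- nrow(a)
  k <- rowSums(a) - 1
  shared <- a %*% a - 2 * a        # sum_{u != i,j} a_iu a_uj (diag(a) = 1)
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  (tom + t(tom)) / 2
}

#' Assign features to modules by clustering TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a fixed
#' height; clusters smaller than the minimum module size become `"grey"`,
#' and surviving clusters are labelled in decreasing size order with the
#' canonical color sequence (largest = `"turquoise"`).
#'
#' @param dissimilarity Square dissimilarity matrix (`1 - TOM`), with
#'   feature ids as rownames.
#' @param config A [network_config()].
#' @return Tibble `feature_id`, `module`.
#' @export
detect_modules <- function(dissimilarity, config) {
  ids <- rownames(dissimilarity) %||% as.character(seq_len(nrow(dissimilarity)))
  hc <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  cl <- stats::cutree(hc, h = config$cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= config$min_size]
  if (length(big) == 0) {
    warn("All features unassigned (grey): no cluster reached the minimum size.")
  }
  # decreasing size, ties broken by first appearance for determinism
  ord <- big[order(-sizes[big], match(big, names(sizes)))]
  labels <- stats::setNames(rep("grey", length(sizes)), names(sizes))
  labels[ord] <- MODULE_COLORS[seq_along(ord)]
  tibble::tibble(feature_id = ids, module = unname(labels[as.character(cl)]))
}

#' Module eigengene
#'
#' First right-singular vector of the member-wise z-scored feature-by-sample
#' matrix (the module's first principal component across samples), unit
#' norm, sign-oriented so that it correlates positively with the mean
#' member profile.
#'
#' @param x Members-by-samples numeric matrix (>= 2 members).
#' @return List: `profile` (named numeric, unit norm), `var_explained`.
#' @export
module_eigengene <- function(x) {
  if (nrow(x) < 2) abort("An eigengene needs >= 2 members.")
  z <- t(scale(t(x)))
  if (any(!is.finite(z))) {
    # all-identical member profiles: z-scored common profile, unit norm
    z <- z[is.finite(rowSums(z)), , drop = FALSE]
    if (nrow(z) == 0) {
      common <- colMeans(x) - mean(colMeans(x))
      if (all(common == 0)) common <- rep(1, ncol(x))
      prof <- common / sqrt(sum(common^2))
      return(list(profile = stats::setNames(prof, colnames(x)), var_explained = 1))
    }
  }
  dec <- svd(z)
  prof <- dec$v[, 1]
  mean_prof <- colMeans(z)
  if (sum(prof * mean_prof) < 0) prof <- -prof
  list(profile = stats::setNames(prof, colnames(x)),
       var_explained = dec$d[1]^2 / sum(dec$d^2))
}

classify_archetype <- function(day_means) {
  m0 <- day_means[["0"]]; m2 <- day_means[["2"]]; m6 <- day_means[["6"]]
  if (m0 > m2 && m2 > m6) "decreasing"
  else if (m2 > m0 && m2 > m6) "transient_up"
  else if (m6 > m2 && m2 > m0) "increasing"
  else "other"
}

#' Detect co-expression modules from an abundance matrix
#'
#' The full network chain: complete features on log2 abundances, signed
#' adjacency at the configured power, topological overlap, average-linkage
#' clustering with a static cut, size filtering and color labelling, then a
#' module eigengene and a day-profile archetype (decreasing / transient_up /
#' increasing / other) per module.
#'
#' @param matrix An [abundance_matrix()].
#' @param design A [study_design()] (for eigengene day means).
#' @param config A [network_config()].
#' @param log2_transform Use log2 abundances (default `TRUE`).
#' @return Object of class `kme_modules`: list with `assignment`
#'   (tibble `feature_id`, `module`), `eigengenes` (tibble `module`,
#'   `archetype`, `var_explained`, one column per sample), `config`.
#' @export
coexpression_modules <- function(matrix, design, config, log2_transform = TRUE) {
  assert_design(design)
  m <- as.matrix(matrix[sample_cols(matrix)])
  rownames(m) <- matrix$feature_id
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (log2_transform) m <- log2(m)
  m <- m[apply(m, 1, sd) > 0, , drop = FALSE]
  adj <- signed_adjacency(m, power = config$power)
  tom <- topological_overlap(adj)
  assignment <- detect_modules(1 - tom, config)
  eig <- purrr::map_dfr(setdiff(unique(assignment$module), "grey"), function(mod) {
    members <- assignment$feature_id[assignment$module == mod]
    eg <- module_eigengene(m[members, , drop = FALSE])
    prof <- eg$profile[design$sample]
    day_means <- tapply(prof, design$day, mean)
    dplyr::bind_cols(
      tibble::tibble(module = mod, n_members = length(members),
                     archetype = classify_archetype(day_means),
                     var_explained = eg$var_explained),
      tibble::as_tibble(as.list(prof))
    )
  })
  if (nrow(eig) > 0) {
    # size order, ties by canonical color rank (turquoise first)
    eig <- eig[order(-eig$n_members, match(eig$module, MODULE_COLORS)), ,
               drop = FALSE]
  }
  structure(list(assignment = assignment, eigengenes = eig,
                 design = design, config = config),
            class = "kme_modules")
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set's overlap with a module
#' within a stated universe, Benjamini-Hochberg-adjusted across sets.
#'
#' @param members Character vector of module member identifiers (must be a
#'   subset of `universe`).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param universe Character vector of all testable identifiers.
#' @return Tibble `set`, `set_size` (within universe), `overlap`, `p`,
#'   `padj`, sorted by `p`.
#' @export
ora <- function(members, gene_sets, universe) {
  if (length(universe) == 0) abort("`universe` is empty.")
  if (length(gene_sets) == 0) abort("`gene_sets` is empty.")
  universe <- unique(universe)
  members <- unique(members)
  if (!all(members %in% universe)) {
    abort("All module members must be in the universe.")
  }
  out <- purrr::imap_dfr(gene_sets, function(set, nm) {
    set_u <- intersect(unique(set), universe)
    ov <- length(intersect(members, set_u))
    p <- phyper(ov - 1, length(set_u), length(universe) - length(set_u),
                length(members), lower.tail = FALSE)
    tibble::tibble(set = nm, set_size = length(set_u), overlap = ov, p = p)
  })
  out$padj <- bh_adjust(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}
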