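# An abundance matrix is a tibble: `feature_id`, optional `accession`, then
# one numeric column per design sample. Attributes track its processing
# level ("protein", "kme_peptide", "kme_site_normalized") and whether a
# pseudocount has been applied, so the normalization chain can enforce its
# ordering contract.

ID_COLS <- c("feature_id", "accession")

#' Processing level of an abundance matrix
#'
#' @param matrix An [abundance_matrix()].
#' @return `"protein"`, `"kme_peptide"` or `"kme_site_normalized"`.
#' @export
abundance_level <- function(matrix) attr(matrix, "level") %||% NA_character_

#' Construct an abundance matrix
#'
#' @param df Tibble with `feature_id`, optional `accession`, and numeric
#'   sample columns.
#' @param level One of `"protein"`, `"kme_peptide"`,
#'   `"kme_site_normalized"`.
#' @return The tibble with level metadata attached.
#' @export
abundance_matrix <- function(df, level = c("protein", "kme_peptide",
                                           "kme_site_normalized")) {
  level <- match.arg(level)
  if (!"feature_id" %in% names(df)) abort("`df` needs a `feature_id` column.")
  vals <- df[setdiff(names(df), ID_COLS)]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("All sample columns must be numeric.")
  }
  if (any(unlist(vals) < 0, na.rm = TRUE)) {
    abort("Abundances must be non-negative.")
  }
  structure(df, level = level,
            pseudocount = attr(df, "pseudocount"),
            class = unique(c("kme_abun", class(df))))
}

sample_cols <- function(matrix) setdiff(names(matrix), ID_COLS)

#' Convert quantification records to an abundance matrix
#'
#' @param records Peptide or protein records from [read_quant_tables()].
#' @param design The plex [study_design()].
#' @param level Matrix level; `feature_id` is the accession at protein
#'   level and the peptide id otherwise.
#' @return An [abundance_matrix()].
#' @export
as_abundance_matrix <- function(records, design,
                                level = c("protein", "kme_peptide")) {
  level <- match.arg(level)
  assert_design(design)
  samples <- design$sample
  if (!all(samples %in% names(records))) {
    abort("Records lack the design's sample columns; read them with the design.")
  }
  id <- if (level == "protein") records$accession else records$peptide_id
  df <- tibble::tibble(feature_id = id)
  if (level != "protein" && "accession" %in% names(records)) {
    df$accession <- records$accession
  }
  abundance_matrix(dplyr::bind_cols(df, records[samples]), level)
}

#' Filter protein records by identification quality
#'
#' Keeps proteins identified at high FDR confidence with two or more unique
#' peptides. The removed rows and reasons are attached as the
#' `"drop_report"` attribute (retrieve with [drop_report()]).
#'
#' @param records Protein quantification records.
#' @return The kept records.
#' @export
filter_proteins <- function(records) {
  keep <- records$confidence == "high" & records$n_unique_peptides >= 2
  dropped <- records[!keep, , drop = FALSE]
  reason <- ifelse(dropped$confidence != "high", "confidence_not_high",
                   "fewer_than_2_unique_peptides")
  out <- records[keep, , drop = FALSE]
  attr(out, "drop_report") <- tibble::tibble(
    feature_id = dropped$accession, reason = reason
  )
  out
}

#' Filter methylated-peptide records by site localization
#'
#' Operates on peptides carrying at least one lysine-methyl modification:
#' keeps those with a localization score >= `min_score` and an unambiguous
#' site assignment. Peptides without any methyl modification belong to the
#' protein-evidence stream and are rejected here. Methyl peptides with a
#' missing localization score are removed and counted in the drop report.
#'
#' @param records Peptide records with `n_methyl`, `loc_score`, `ambiguous`.
#' @param min_score Localization-score threshold (default 0.9).
#' @return Kept records, with a `"drop_report"` attribute.
#' @export
filter_kme_peptides <- function(records, min_score = 0.9) {
  if (any(records$n_methyl == 0)) {
    abort("`records` must contain only methylated peptides; route unmodified peptides to the protein stream.")
  }
  score_missing <- is.na(records$loc_score)
  keep <- !score_missing & records$loc_score >= min_score & !records$ambiguous
  dropped <- records[!keep, , drop = FALSE]
  reason <- dplyr::case_when(
    is.na(dropped$loc_score) ~ "missing_localization_score",
    dropped$loc_score < min_score ~ "localization_below_threshold",
    TRUE ~ "ambiguous_site"
  )
  out <- records[keep, , drop = FALSE]
  attr(out, "drop_report") <- tibble::tibble(
    feature_id = dropped$peptide_id, reason = reason
  )
  out
}

#' Retrieve the drop report of a filtering or normalization step
#'
#' @param x Object returned by a kmeflow filter/normalize step.
#' @return Tibble of dropped feature ids and reasons (possibly empty).
#' @export
drop_report <- function(x) {
  attr(x, "drop_report") %||%
    tibble::tibble(feature_id = character(), reason = character())
}

#' Normalize to total peptide amount (no scaling)
#'
#' Equalizes channel loading: each sample column is multiplied by
#' `mean(column sums) / (its column sum)`, so all column sums become equal
#' while the overall scale is preserved. Missing values are ignored in the
#' sums and stay missing.
#'
#' @param matrix An [abundance_matrix()].
#' @return The normalized matrix (same level).
#' @export
total_peptide_normalize <- function(matrix) {
  sc <- sample_cols(matrix)
  sums <- vapply(matrix[sc], function(col) sum(col, na.rm = TRUE), numeric(1))
  n_obs <- vapply(matrix[sc], function(col) sum(!is.na(col)), numeric(1))
  if (any(n_obs == 0)) {
    abort(sprintf("Sample column(s) %s are entirely missing.",
                  paste(sc[n_obs == 0], collapse = ", ")))
  }
  if (any(sums == 0)) {
    abort(sprintf("Sample column(s) %s have zero total abundance.",
                  paste(sc[sums == 0], collapse = ", ")))
  }
  factors <- mean(sums) / sums
  out <- matrix
  out[sc] <- purrr::map2(matrix[sc], factors, `*`)
  attr(out, "normalized") <- TRUE
  out
}

#' Add a pseudocount to normalized abundances
#'
#' Adds a small constant to every observed abundance to keep downstream
#' ratios finite. Missing values stay missing. Applying it twice is a
#' guarded error (the level metadata tracks it).
#'
#' @param matrix An [abundance_matrix()].
#' @param pseudocount Non-negative constant (default 0.1).
#' @return The shifted matrix.
#' @export
add_pseudocount <- function(matrix, pseudocount = 0.1) {
  if (pseudocount < 0) abort("`pseudocount` must be >= 0.")
  if (!is.null(attr(matrix, "pseudocount"))) {
    abort("A pseudocount has already been added to this matrix.")
  }
  sc <- sample_cols(matrix)
  out <- matrix
  out[sc] <- lapply(matrix[sc], function(col) col + pseudocount)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Normalize Kme peptide abundances to parent-protein abundances
#'
#' The core of the stoichiometry readout: for every methylated-peptide
#' feature and every sample, divides the peptide's (channel-normalized,
#' pseudocounted) abundance by the parent protein's abundance in the same
#' biological replicate. Protein-level changes across differentiation cancel
#' in this ratio, isolating changes in methylation stoichiometry. Features
#' whose parent protein is absent from the protein matrix (e.g. filtered
#' out) are dropped and reported; a missing protein value yields a missing
#' ratio for that sample only.
#'
#' @param kme_matrix Peptide-level [abundance_matrix()] restricted to
#'   methylated peptides; must carry an `accession` column.
#' @param protein_matrix Protein-level [abundance_matrix()].
#' @param require_pseudocount Check both inputs were pseudocounted
#'   (default `TRUE`; set `FALSE` to ratio raw normalized abundances).
#' @return An [abundance_matrix()] at level `"kme_site_normalized"`, with a
#'   `"drop_report"` attribute for features lacking protein evidence.
#' @export
normalize_kme_to_protein <- function(kme_matrix, protein_matrix,
                                     require_pseudocount = TRUE) {
  if (!"accession" %in% names(kme_matrix)) {
    abort("`kme_matrix` needs an `accession` column to map to proteins.")
  }
  if (require_pseudocount &&
      (is.null(attr(kme_matrix, "pseudocount")) ||
       is.null(attr(protein_matrix, "pseudocount")))) {
    abort("Both matrices must be pseudocounted first (or set `require_pseudocount = FALSE`).")
  }
  sc <- sample_cols(kme_matrix)
  if (!identical(sort(sc), sort(sample_cols(protein_matrix)))) {
    abort("Peptide and protein matrices must share the same sample columns.")
  }
  have <- kme_matrix$accession %in% protein_matrix$feature_id
  dropped <- kme_matrix$feature_id[!have]
  kept <- kme_matrix[have, , drop = FALSE]
  idx <- match(kept$accession, protein_matrix$feature_id)
  out <- kept
  for (s in sc) out[[s]] <- kept[[s]] / protein_matrix[[s]][idx]
  out <- structure(out, level = "kme_site_normalized", pseudocount = NULL)
  attr(out, "drop_report") <- tibble::tibble(
    feature_id = dropped, reason = "protein_not_quantified"
  )
  class(out) <- unique(c("kme_abun", class(out)))
  out
}
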