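# Readers for search-engine-export-like quantification tables and flat
# annotation tables. All tab-separated with a header row. Channel columns are
# matched to the design by channel label; a column-mapping list decouples the
# package's canonical column names from whatever dialect the export used.

default_peptide_columns <- function() {
  list(sequence = "sequence", modifications = "modifications",
       accession = "accession", loc_score = "loc_score",
       ambiguous = "ambiguous")
}

default_protein_columns <- function() {
  list(accession = "accession", confidence = "confidence",
       n_unique_peptides = "n_unique_peptides")
}

#' Parse a modification string
#'
#' The modification mini-grammar is `"<residue><pos>(<kind>)"`, tokens
#' separated by `";"`, e.g. `"K4(me3);K9(me1)"`. Positions are 1-based within
#' the peptide. Kinds `me1`, `me2`, `me3` denote lysine methylation and must
#' sit on a K; any other kind is carried through as `"other"`.
#'
#' @param x Character vector of modification strings (`""`/`NA` = none).
#' @param sequence Optional matching character vector of peptide sequences;
#'   when given, positions are range- and residue-checked.
#' @return A list of tibbles with columns `position`, `kind`, `raw_kind`.
#' @export
parse_modifications <- function(x, sequence = NULL) {
  purrr::imap(x, function(s, i) {
    empty <- tibble::tibble(position = integer(), kind = character(),
                            raw_kind = character())
    if (is.na(s) || !nzchar(trimws(s))) return(empty)
    tokens <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(tokens)]
    m <- regmatches(tokens, regexec("^([A-Za-z])([0-9]+)\\(([^)]+)\\)$", tokens))
    bad <- tokens[vapply(m, length, integer(1)) == 0]
    if (length(bad) > 0) {
      abort(sprintf("Unparseable modification token '%s' (row %s).", bad[1], i))
    }
    residue <- vapply(m, `[`, character(1), 2)
    position <- as.integer(vapply(m, `[`, character(1), 3))
    raw_kind <- vapply(m, `[`, character(1), 4)
    kind <- ifelse(raw_kind %in% METHYL_STATES, raw_kind, "other")
    if (!is.null(sequence)) {
      seq_i <- sequence[[i]]
      if (any(position > nchar(seq_i)) || any(position < 1)) {
        abort(sprintf(
          "Modification position out of range for peptide '%s' (row %s).",
          seq_i, i
        ))
      }
      res_at <- substring(seq_i, position, position)
      if (any(kind %in% METHYL_STATES & res_at != "K")) {
        abort(sprintf(
          "Methyl modification on non-K residue in peptide '%s' (row %s).",
          seq_i, i
        ))
      }
    }
    tibble::tibble(position = position, kind = kind, raw_kind = raw_kind)
  })
}

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) abort(sprintf("%s table '%s' does not exist.", what, path))
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = c("", "NA"), progress = FALSE)
}

resolve_channels <- function(df, design, path) {
  missing_ch <- setdiff(design$channel, names(df))
  if (length(missing_ch) > 0) {
    abort(sprintf(
      "Channel column(s) %s from the design are absent from '%s'.",
      paste(missing_ch, collapse = ", "), path
    ))
  }
  ab <- df[design$channel]
  ab[] <- lapply(ab, function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (any(!is.na(col) & is.na(v))) {
      abort(sprintf("Non-numeric abundance value in '%s'.", path))
    }
    if (any(v < 0, na.rm = TRUE)) {
      abort(sprintf("Negative abundance value in '%s'.", path))
    }
    v
  })
  names(ab) <- design$sample
  tibble::as_tibble(ab)
}

#' Read peptide and protein quantification tables for one plex
#'
#' Reads the modified-peptide and protein tab-separated quantification
#' exports of one TMT plex and resolves their channel columns against the
#' plex design. Empty abundance cells become missing values (`NA`), never
#' zeros.
#'
#' @param peptide_path,protein_path Paths to the two TSV tables.
#' @param design A [study_design()] for this plex.
#' @param peptide_columns,protein_columns Named lists mapping canonical
#'   column names to the header names used in the files (the escape hatch
#'   for export-dialect drift). Defaults expect the canonical names.
#' @return A list with elements `peptides` and `proteins`. `peptides` has
#'   columns `plex_id`, `peptide_id`, `sequence`, `modifications` (list
#'   column, see [parse_modifications()]), `accession`, `loc_score`,
#'   `ambiguous`, `n_methyl` plus one numeric column per design sample.
#'   `proteins` has `plex_id`, `accession`, `confidence`,
#'   `n_unique_peptides` plus the sample columns.
#' @export
read_quant_tables <- function(peptide_path, protein_path, design,
                              peptide_columns = default_peptide_columns(),
                              protein_columns = default_protein_columns()) {
  assert_design(design)
  pep_raw <- read_tsv_checked(peptide_path, "Peptide")
  prot_raw <- read_tsv_checked(protein_path, "Protein")
  pc <- utils::modifyList(default_peptide_columns(), peptide_columns)
  qc <- utils::modifyList(default_protein_columns(), protein_columns)

  need <- unlist(pc)
  if (!all(need %in% names(pep_raw))) {
    abort(sprintf("Peptide table lacks column(s): %s",
                  paste(setdiff(need, names(pep_raw)), collapse = ", ")))
  }
  sequence <- toupper(pep_raw[[pc$sequence]])
  purrr::walk2(sequence, seq_along(sequence),
               function(s, i) check_canonical(s, paste0("peptide row ", i)))
  mods <- parse_modifications(pep_raw[[pc$modifications]], sequence)
  n_mods <- vapply(mods, nrow, integer(1))
  if (any(n_mods > 5)) {
    abort("More than 5 modifications on a peptide (search constraint).")
  }
  peptides <- tibble::tibble(
    plex_id = design$plex_id[1],
    peptide_id = sprintf("%s_pep%05d", design$plex_id[1], seq_along(sequence)),
    sequence = sequence,
    modifications = mods,
    accession = pep_raw[[pc$accession]],
    loc_score = suppressWarnings(as.numeric(pep_raw[[pc$loc_score]])),
    ambiguous = tolower(pep_raw[[pc$ambiguous]]) %in% c("true", "1", "yes"),
    n_methyl = vapply(mods, function(m) sum(m$kind %in% METHYL_STATES), integer(1))
  )
  peptides <- dplyr::bind_cols(peptides, resolve_channels(pep_raw, design, peptide_path))

  needp <- unlist(qc)
  if (!all(needp %in% names(prot_raw))) {
    abort(sprintf("Protein table lacks column(s): %s",
                  paste(setdiff(needp, names(prot_raw)), collapse = ", ")))
  }
  conf <- tolower(prot_raw[[qc$confidence]])
  if (!all(conf %in% c("high", "medium", "low"))) {
    abort("Protein confidence must be one of high/medium/low.")
  }
  proteins <- tibble::tibble(
    plex_id = design$plex_id[1],
    accession = prot_raw[[qc$accession]],
    confidence = conf,
    n_unique_peptides = as.integer(prot_raw[[qc$n_unique_peptides]])
  )
  proteins <- dplyr::bind_cols(proteins, resolve_channels(prot_raw, design, protein_path))
  list(peptides = peptides, proteins = proteins)
}

#' Read a GMT gene-set file
#'
#' One set per tab-separated line: name, description, then members.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (set name -> members).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file '%s' does not exist.", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  bad <- which(vapply(sets, length, integer(1)) < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", bad[1]))
  }
  stats::setNames(
    lapply(sets, function(s) unique(s[-(1:2)])),
    vapply(sets, `[`, character(1), 1)
  )
}

#' Read a known-methylation-site table
#'
#' Flat tab-separated table in the style of a PhosphoSitePlus export:
#' columns `accession`, `position`, `kind`.
#'
#' @param path Path to the TSV (a header row is expected).
#' @return Tibble with columns `accession`, `position` (integer >= 1),
#'   `kind`.
#' @export
read_site_table <- function(path) {
  df <- read_tsv_checked(path, "Known-site")
  need <- c("accession", "position", "kind")
  if (!all(need %in% names(df))) {
    abort(sprintf("Site table must have columns: %s", paste(need, collapse = ", ")))
  }
  pos <- suppressWarnings(as.integer(df$position))
  if (any(is.na(pos)) || any(pos < 1)) {
    abort("Site positions must be integers >= 1.")
  }
  tibble::tibble(accession = df$accession, position = pos, kind = df$kind)
}

#' Read a residue-level clinical-variant table
#'
#' Flat tab-separated, ClinVar-style: columns `accession`, `position`,
#' `ref_residue`, `variant`, `condition`, `significance`.
#'
#' @param path Path to the TSV (a header row is expected).
#' @return Tibble with typed columns; positions are integers >= 1.
#' @export
read_variant_table <- function(path) {
  df <- read_tsv_checked(path, "Variant")
  need <- c("accession", "position", "ref_residue", "variant",
            "condition", "significance")
  if (!all(need %in% names(df))) {
    abort(sprintf("Variant table must have columns: %s", paste(need, collapse = ", ")))
  }
  pos <- suppressWarnings(as.integer(df$position))
  if (any(is.na(pos)) || any(pos < 1)) {
    abort("Variant positions must be integers >= 1.")
  }
  tibble::tibble(
    accession = df$accession, position = pos, ref_residue = df$ref_residue,
    variant = df$variant, condition = df$condition,
    significance = df$significance
  )
}
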