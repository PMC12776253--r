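#' Read a protein FASTA database
#'
#' Parses a protein FASTA file into a tibble of protein entries. UniProt-style
#' headers (`>sp|ACC|NAME description`) are recognised and the accession is
#' taken as the middle token; otherwise the first whitespace-delimited token
#' of the header is the accession.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#'
#' @return A tibble with columns `accession`, `sequence`, `description`.
#'   Sequences are validated against the 20-letter canonical amino-acid
#'   alphabet; any other character is an error naming the record and residue.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P62158|CALM Calmodulin", "MADQLTEEQK"), fa)
#' read_protein_fasta(fa)
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file '%s' does not exist.", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) abort(sprintf("FASTA file '%s' contains no records.", path))
  headers <- names(set)
  first_token <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  accession <- vapply(first_token, function(tok) {
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 3) parts[2] else tok
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(accession)) {
    dup <- unique(accession[duplicated(accession)])
    abort(sprintf("Duplicate accession(s) in FASTA: %s", paste(dup, collapse = ", ")))
  }
  sequence <- toupper(as.character(set))
  purrr::walk2(sequence, accession, function(s, a) {
    if (nchar(s) == 0) abort(sprintf("Record '%s' has an empty sequence.", a))
    check_canonical(s, a)
  })
  tibble::tibble(accession = accession, sequence = unname(sequence),
                 description = description)
}

#' Write a protein tibble to FASTA
#'
#' @param proteins Tibble with `accession`, `sequence` and optionally
#'   `description` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  desc <- proteins$description %||% rep("", nrow(proteins))
  hdr <- ifelse(nzchar(desc), paste(proteins$accession, desc), proteins$accession)
  lines <- as.vector(rbind(paste0(">", hdr), proteins$sequence))
  writeLines(lines, path)
  invisible(path)
}
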