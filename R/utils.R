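# Canonical amino-acid alphabet used throughout (20 proteinogenic residues).
AA_CANONICAL <- c(
  "A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

METHYL_STATES <- c("me1", "me2", "me3")

check_canonical <- function(sequence, id = "<sequence>") {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_CANONICAL)
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-canonical residue(s) %s in record '%s'.",
      paste0("'", bad, "'", collapse = ", "), id
    ))
  }
  invisible(sequence)
}

# Sample-column labels resolved from a design: d<day>_r<replicate>.
sample_label <- function(day, replicate) sprintf("d%d_r%d", day, replicate)

#' @noRd
assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s.", name, format(min)))
  }
  invisible(x)
}
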