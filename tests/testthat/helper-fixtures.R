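# Small builders shared across tests.

tiny_design <- function(plex = "plexA", protease = "trypsin_lysc") {
  study_design(plex, protease)
}

# abundance matrix with explicit values: rows = features, cols follow design
tiny_matrix <- function(values, design, ids = NULL, accession = NULL,
                        level = "protein") {
  values <- base::matrix(values, ncol = 12)
  ids <- ids %||% paste0("f", seq_len(nrow(values)))
  df <- tibble::tibble(feature_id = ids)
  if (!is.null(accession)) df$accession <- accession
  colnames(values) <- design$sample
  abundance_matrix(dplyr::bind_cols(df, tibble::as_tibble(values)), level)
}

# peptide quant TSV + protein quant TSV on disk for the reader tests
write_mini_tables <- function(dir, design,
                              pep_rows = NULL, prot_rows = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- design$channel
  pep_header <- c("sequence", "modifications", "accession", "loc_score",
                  "ambiguous", channels)
  pep_default <- c("MAKAAAR", "K3(me3)", "P1", "0.95", "false",
                   as.character(seq(100, 1200, by = 100)))
  pep_rows <- pep_rows %||% list(pep_default)
  pep_path <- file.path(dir, "peptides.tsv")
  writeLines(c(paste(pep_header, collapse = "\t"),
               vapply(pep_rows, paste, character(1), collapse = "\t")),
             pep_path)
  prot_header <- c("accession", "confidence", "n_unique_peptides", channels)
  prot_default <- c("P1", "high", "4", as.character(seq(1000, 12000, by = 1000)))
  prot_rows <- prot_rows %||% list(prot_default)
  prot_path <- file.path(dir, "proteins.tsv")
  writeLines(c(paste(prot_header, collapse = "\t"),
               vapply(prot_rows, paste, character(1), collapse = "\t")),
             prot_path)
  list(peptides = pep_path, proteins = prot_path)
}

# features-by-12-samples matrix with three planted archetype blocks
block_profile_matrix <- function(sizes = c(40, 35, 30), design = tiny_design(),
                                 within_cor = 0.9, seed = 1) {
  profs <- list(decreasing = c(1, 0, -1), transient_up = c(-0.5, 1, -0.5),
                increasing = c(-1, 0, 1))
  day_col <- match(design$day, c(0, 2, 6))
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    rows <- list(); truth <- character(0)
    for (b in seq_along(sizes)) {
      prof <- profs[[b]][day_col]
      v_sig <- stats::var(prof) * 11 / 12
      sd_noise <- sqrt(v_sig * (1 - within_cor) / within_cor)
      block <- t(replicate(sizes[b], prof + rnorm(12, 0, sd_noise)))
      rows[[b]] <- block
      truth <- c(truth, rep(names(profs)[b], sizes[b]))
    }
    x <- do.call(rbind, rows)
    rownames(x) <- sprintf("f%03d", seq_len(nrow(x)))
    list(x = x, truth = truth)
  })
}

rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  agree <- sum(choose(tab, 2))
  a_pairs <- sum_comb(rowSums(tab))
  b_pairs <- sum_comb(colSums(tab))
  total <- choose(n, 2)
  (total + 2 * agree - a_pairs - b_pairs) / total
}
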