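#' Map methylated peptides to protein-coordinate Kme sites
#'
#' Locates each peptide as an exact substring of its master protein and
#' converts each lysine-methyl modification to a 1-based protein coordinate
#' (`match start + position in peptide - 1`). Coordinates are on the FASTA
#' sequence including the initiator methionine. Peptides that match the
#' protein at no offset or at more than one offset are excluded from
#' site-level output and listed in the `"mapping_report"` attribute; a
#' mapped methyl landing on a non-K residue is an error.
#'
#' @param peptides Peptide records ([read_quant_tables()] output), ideally
#'   localization-filtered; only rows with `n_methyl >= 1` yield sites.
#' @param proteins Tibble `accession`, `sequence` ([read_protein_fasta()]).
#' @param protease Optional protease label recorded with each site.
#' @return Tibble of sites: `accession`, `position`, `kind`, `plex_id`,
#'   `peptide_id`, `protease`, `window` (the 7-mer context).
#' @export
map_peptide_to_sites <- function(peptides, proteins, protease = NA_character_) {
  res <- list(); report <- list()
  for (r in seq_len(nrow(peptides))) {
    mods <- peptides$modifications[[r]]
    me <- mods[mods$kind %in% METHYL_STATES, , drop = FALSE]
    if (nrow(me) == 0) next
    acc <- peptides$accession[r]
    prot <- proteins$sequence[proteins$accession == acc]
    pid <- peptides$peptide_id[r]
    if (length(prot) == 0) {
      report[[length(report) + 1]] <- tibble::tibble(
        peptide_id = pid, reason = "accession_not_in_fasta")
      next
    }
    hits <- gregexpr(peptides$sequence[r], prot, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    if (length(hits) == 0) {
      report[[length(report) + 1]] <- tibble::tibble(
        peptide_id = pid, reason = "no_match_in_protein")
      next
    }
    if (length(hits) > 1) {
      report[[length(report) + 1]] <- tibble::tibble(
        peptide_id = pid, reason = "ambiguous_mapping")
      next
    }
    pos <- hits[1] + me$position - 1L
    residue <- substring(prot, pos, pos)
    if (any(residue != "K")) {
      abort(sprintf("Mapped methyl site not on K (peptide '%s', protein '%s').",
                    pid, acc))
    }
    res[[length(res) + 1]] <- tibble::tibble(
      accession = acc, position = as.integer(pos), kind = me$kind,
      plex_id = peptides$plex_id[r], peptide_id = pid, protease = protease,
      window = vapply(pos, function(p) window7(prot, p), character(1))
    )
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(accession = character(), position = integer(),
                          kind = character(), plex_id = character(),
                          peptide_id = character(), protease = character(),
                          window = character())
  }
  attr(out, "mapping_report") <- if (length(report) > 0) {
    dplyr::bind_rows(report)
  } else {
    tibble::tibble(peptide_id = character(), reason = character())
  }
  out
}

#' Aggregate mapped sites across protease experiments
#'
#' Site identity is the triple (accession, position, methyl state); the
#' same lysine observed with different methyl states is two sites. Returns
#' the unique site set with its supporting evidence and the
#' digestion-strategy overlap summary at site and protein level.
#'
#' @param sites Mapped sites from [map_peptide_to_sites()] (rows from any
#'   number of plexes bound together, `protease` filled in).
#' @return List with `sites` (tibble: identity, `detected_in`
#'   (`;`-separated proteases), `n_proteases`, `n_supporting_peptides`,
#'   `window`) and `summary` (tibble of site- and protein-level counts:
#'   unique to each protease, shared, union).
#' @export
aggregate_sites <- function(sites) {
  proteases <- sort(unique(sites$protease))
  uniq <- sites |>
    dplyr::group_by(.data$accession, .data$position, .data$kind) |>
    dplyr::summarise(
      detected_in = paste(sort(unique(.data$protease)), collapse = ";"),
      n_proteases = dplyr::n_distinct(.data$protease),
      n_supporting_peptides = dplyr::n_distinct(.data$peptide_id),
      window = .data$window[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$accession, .data$position, .data$kind)
  count_level <- function(keys_by_protease) {
    all_keys <- unique(unlist(keys_by_protease))
    in_each <- lapply(keys_by_protease, unique)
    n_in <- vapply(all_keys, function(k) {
      sum(vapply(in_each, function(s) k %in% s, logical(1)))
    }, numeric(1))
    c(vapply(seq_along(in_each), function(i) {
      sum(vapply(all_keys, function(k) {
        k %in% in_each[[i]] && n_in[[k]] == 1
      }, logical(1)))
    }, numeric(1)), shared = sum(n_in > 1), union = length(all_keys))
  }
  site_keys <- split(paste(sites$accession, sites$position, sites$kind),
                     sites$protease)[proteases]
  prot_keys <- split(sites$accession, sites$protease)[proteases]
  mk_summary <- function(level, counts) {
    tibble::tibble(
      level = level,
      measure = c(paste0("unique_to_", proteases), "shared", "union"),
      n = unname(counts)
    )
  }
  summary <- dplyr::bind_rows(
    mk_summary("site", count_level(site_keys)),
    mk_summary("protein", count_level(prot_keys))
  )
  list(sites = uniq, summary = summary)
}

#' 7-mer sequence window around a residue
#'
#' Residues `position - 3` to `position + 3`, with `'-'` padding beyond the
#' protein termini.
#'
#' @param sequence Protein sequence.
#' @param position 1-based residue position.
#' @return A 7-character string with the residue of interest at its center.
#' @examples
#' window7("MKAAAAA", 2) # "--MKAAA"
#' @export
window7 <- function(sequence, position) {
  n <- nchar(sequence)
  if (position < 1 || position > n) abort("`position` out of range.")
  idx <- (position - 3):(position + 3)
  chars <- ifelse(idx < 1 | idx > n, "-",
                  substring(sequence, pmax(idx, 1), pmax(idx, 1)))
  paste(chars, collapse = "")
}

#' K/R density of site windows or peptide sequences
#'
#' For 7-mer windows, counts the K/R residues other than the central
#' methylated K; for peptide sequences, counts all K/R residues. Returns
#' the histogram over counts with fractions summing to 1.
#'
#' @param x Character vector of 7-mer windows or peptide sequences.
#' @param mode `"window"` (exclude the central K) or `"peptide"` (total).
#' @return Tibble `n_kr`, `count`, `fraction`.
#' @export
kr_density <- function(x, mode = c("window", "peptide")) {
  mode <- match.arg(mode)
  if (length(x) == 0) abort("`x` is empty.")
  count_kr <- function(s) sum(strsplit(s, "")[[1]] %in% c("K", "R"))
  n <- vapply(x, count_kr, numeric(1), USE.NAMES = FALSE)
  if (mode == "window") {
    centers <- substring(x, 4, 4)
    if (any(centers != "K")) abort("Window centers must be 'K'.")
    n <- n - 1
  }
  tab <- table(factor(n, levels = 0:max(n)))
  tibble::tibble(
    n_kr = as.integer(names(tab)),
    count = as.integer(tab),
    fraction = as.integer(tab) / length(x)
  )
}

#' Positional residue frequencies of site windows
#'
#' Per flanking position (-3..+3, center excluded) the frequency of each
#' amino acid across windows, computed over non-padding entries only; each
#' position's frequencies sum to 1.
#'
#' @param windows Character vector of 7-mer windows.
#' @return Tibble `position` (-3..3 without 0), `residue`, `count`,
#'   `frequency`.
#' @export
motif_matrix <- function(windows) {
  if (length(windows) == 0) abort("`windows` is empty.")
  offsets <- setdiff(-3:3, 0)
  purrr::map_dfr(offsets, function(off) {
    chars <- substring(windows, off + 4, off + 4)
    chars <- chars[chars != "-"]
    tab <- table(factor(chars, levels = AA_CANONICAL))
    tab <- tab[tab > 0]
    tibble::tibble(position = off, residue = names(tab),
                   count = as.integer(tab),
                   frequency = as.integer(tab) / length(chars))
  })
}

#' Flag novel sites against a known-site table
#'
#' A site is novel when its (accession, position) — or, in state-aware
#' mode, (accession, position, methyl state) — is absent from the known
#' table. A protein is novel when the known table reports no methylation
#' site on it at all.
#'
#' @param sites Aggregated site tibble (`accession`, `position`, `kind`).
#' @param known Known-site tibble ([read_site_table()]).
#' @param state_aware Match the methyl state too (default `FALSE`).
#' @return `sites` with logical columns `novel_site` and `novel_protein`.
#' @export
annotate_novelty <- function(sites, known, state_aware = FALSE) {
  key <- if (state_aware) {
    paste(sites$accession, sites$position, sites$kind)
  } else {
    paste(sites$accession, sites$position)
  }
  known_key <- if (state_aware) {
    paste(known$accession, known$position, known$kind)
  } else {
    paste(known$accession, known$position)
  }
  sites$novel_site <- !key %in% known_key
  sites$novel_protein <- !sites$accession %in% known$accession
  sites
}

#' Join sites with residue-level clinical variants
#'
#' Left join of detected sites with a variant table on (accession,
#' position). Variants whose reference residue is not K are still joined
#' but flagged, since the coordinate systems may disagree by the initiator
#' methionine.
#'
#' @param sites Aggregated site tibble.
#' @param variants Variant tibble ([read_variant_table()]).
#' @return One row per site x matching variant (sites without variants keep
#'   `NA` variant fields), with `ref_mismatch` flagging non-K reference
#'   residues.
#' @export
annotate_variants <- function(sites, variants) {
  out <- dplyr::left_join(
    sites,
    variants[c("accession", "position", "ref_residue", "variant",
               "condition", "significance")],
    by = c("accession", "position"),
    relationship = "many-to-many"
  )
  out$ref_mismatch <- !is.na(out$ref_residue) & out$ref_residue != "K"
  if (any(out$ref_mismatch)) {
    warn(sprintf("%d variant join(s) have a non-K reference residue.",
                 sum(out$ref_mismatch)))
  }
  out
}
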