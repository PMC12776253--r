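#' Read a study-design table
#'
#' TSV with columns `plex_id`, `protease`, `channel`, `day`, `replicate`
#' (the format [write_simulated_study()] emits); one [study_design()] is
#' built per plex.
#'
#' @param path Path to the design TSV.
#' @return Named list of `kme_design` tibbles (names = proteases).
#' @export
read_design_table <- function(path) {
  df <- read_tsv_checked(path, "Design")
  need <- c("plex_id", "protease", "channel", "day", "replicate")
  if (!all(need %in% names(df))) {
    abort(sprintf("Design table must have columns: %s", paste(need, collapse = ", ")))
  }
  out <- lapply(split(df, df$plex_id), function(d) {
    study_design(d$plex_id[1], d$protease[1], channels = d$channel,
                 days = as.integer(d$day), replicates = as.integer(d$replicate))
  })
  stats::setNames(out, vapply(out, function(d) d$protease[1], character(1)))
}

# Per-plex quantification chain: filter, build matrices, channel-normalize,
# pseudocount, protein-normalize the Kme peptides.
process_plex <- function(peptides, proteins, design, pseudocount = 0.1,
                         min_loc_score = 0.9) {
  prot_kept <- filter_proteins(proteins)
  prot_mat <- as_abundance_matrix(prot_kept, design, "protein") |>
    total_peptide_normalize() |>
    add_pseudocount(pseudocount)
  # channel-loading factors are computed over the whole peptide export
  # (unmodified peptides dominate the totals), then the methylated subset
  # is carried forward
  pep_all <- as_abundance_matrix(peptides, design, "kme_peptide") |>
    total_peptide_normalize()
  kme <- peptides[peptides$n_methyl >= 1, , drop = FALSE]
  kme_kept <- filter_kme_peptides(kme, min_score = min_loc_score)
  kme_mat <- pep_all[pep_all$feature_id %in% kme_kept$peptide_id, , drop = FALSE] |>
    add_pseudocount(pseudocount)
  kme_norm <- normalize_kme_to_protein(kme_mat, prot_mat)
  list(
    design = design,
    proteins_kept = prot_kept, peptides_kept = kme_kept,
    protein_matrix = prot_mat, kme_matrix = kme_norm,
    counts = tibble::tibble(
      stage = c("proteins_in", "proteins_kept", "kme_peptides_in",
                "kme_peptides_kept", "kme_features_normalized"),
      n = c(nrow(proteins), nrow(prot_kept), nrow(kme), nrow(kme_kept),
            nrow(kme_norm))
    ),
    drop_reports = list(
      proteins = drop_report(prot_kept),
      kme_peptides = drop_report(kme_kept),
      kme_normalization = drop_report(kme_norm)
    )
  )
}

#' Run the full lysine-methylome analysis pipeline
#'
#' Orchestrates every stage over a two-protease study: read (or accept
#' in-memory simulated) quantification tables, filter proteins and
#' methylated peptides, channel-normalize, pseudocount, protein-normalize
#' Kme peptide abundances, call differential features at both levels,
#' build co-expression modules, map peptides to unique Kme sites,
#' aggregate across proteases and annotate. Every stage records its
#' input/output feature counts.
#'
#' @param input_dir Directory holding `proteins.fasta`, `design.tsv` and
#'   per-plex `peptides_<protease>.tsv` / `proteins_<protease>.tsv`
#'   (as written by [write_simulated_study()]). Ignored when `study` is
#'   given.
#' @param study Optional in-memory [simulate_study()] result.
#' @param alpha Significance level for both adjusted-p thresholds.
#' @param pseudocount Pseudocount added to normalized abundances
#'   (default 0.1).
#' @param min_loc_score Localization-score threshold (default 0.9).
#' @param known,variants,gene_sets Optional annotation tables
#'   ([read_site_table()], [read_variant_table()], [read_gmt()]).
#' @param run_modules Build co-expression modules (default `TRUE`).
#' @param protein_network,kme_network [network_config()]s for the two
#'   levels.
#' @param out_dir Optional directory: results are written with
#'   [write_results()].
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return List of class `kme_pipeline`: `plex` (per-protease processed
#'   chains), `diff` (per level/protease `kme_diff` tibbles), `modules`,
#'   `sites` (aggregated unique sites with annotations), `site_summary`,
#'   `qc`, `report`.
#' @export
run_pipeline <- function(input_dir = NULL, study = NULL, alpha = 0.05,
                         pseudocount = 0.1, min_loc_score = 0.9,
                         known = NULL, variants = NULL, gene_sets = NULL,
                         run_modules = TRUE,
                         protein_network = network_config("protein"),
                         kme_network = network_config("kme"),
                         out_dir = NULL, seed = NA_integer_) {
  if (is.null(study) && is.null(input_dir)) {
    abort("Provide `input_dir` or `study`.")
  }
  if (!is.null(study)) {
    proteins_fa <- study$truth$proteins[c("accession", "sequence", "description")]
    designs <- study$designs
    plex_in <- lapply(study$plex, function(p) p[c("peptides", "proteins")])
  } else {
    proteins_fa <- read_protein_fasta(file.path(input_dir, "proteins.fasta"))
    designs <- read_design_table(file.path(input_dir, "design.tsv"))
    plex_in <- lapply(names(designs), function(nm) {
      read_quant_tables(
        file.path(input_dir, paste0("peptides_", nm, ".tsv")),
        file.path(input_dir, paste0("proteins_", nm, ".tsv")),
        designs[[nm]]
      )
    })
    names(plex_in) <- names(designs)
  }

  plex <- purrr::imap(plex_in, function(p, nm) {
    process_plex(p$peptides, p$proteins, designs[[nm]],
                 pseudocount = pseudocount, min_loc_score = min_loc_score)
  })

  diff <- list()
  for (nm in names(plex)) {
    diff[[paste0("protein_", nm)]] <-
      differential_features(plex[[nm]]$protein_matrix, designs[[nm]], alpha = alpha)
    diff[[paste0("kme_", nm)]] <-
      differential_features(plex[[nm]]$kme_matrix, designs[[nm]], alpha = alpha)
  }

  qc <- lapply(plex, function(p) {
    list(replicate_correlation = replicate_correlation(p$protein_matrix),
         pca = pca_samples(p$protein_matrix))
  })

  modules <- NULL
  if (run_modules) {
    ref <- names(plex)[1]
    modules <- list(
      protein = coexpression_modules(plex[[ref]]$protein_matrix, designs[[ref]],
                                     protein_network)
    )
    kme_diff_ref <- diff[[paste0("kme_", ref)]]
    sig_ids <- kme_diff_ref$feature_id[kme_diff_ref$significant]
    kme_mat <- plex[[ref]]$kme_matrix
    use <- if (length(sig_ids) >= 3 * kme_network$min_size) {
      kme_mat[kme_mat$feature_id %in% sig_ids, , drop = FALSE]
    } else kme_mat
    modules$kme <- coexpression_modules(use, designs[[ref]], kme_network)
    if (!is.null(gene_sets)) {
      assign_p <- modules$protein$assignment
      universe <- assign_p$feature_id
      modules$ora <- purrr::map_dfr(
        setdiff(unique(assign_p$module), "grey"),
        function(mod) {
          res <- ora(assign_p$feature_id[assign_p$module == mod],
                     gene_sets, universe)
          dplyr::bind_cols(tibble::tibble(module = mod), res)
        })
    }
  }

  mapped <- purrr::imap_dfr(plex, function(p, nm) {
    map_peptide_to_sites(p$peptides_kept, proteins_fa, protease = nm)
  })
  sites <- NULL; site_summary <- NULL
  if (nrow(mapped) > 0) {
    agg <- aggregate_sites(mapped)
    sites <- agg$sites
    site_summary <- agg$summary
    # merge differential status: a site is differential if any supporting
    # peptide feature is significant in any plex
    sig_map <- purrr::imap_dfr(plex, function(p, nm) {
      d <- diff[[paste0("kme_", nm)]]
      mapped_nm <- mapped[mapped$protease == nm, ]
      idx <- match(mapped_nm$peptide_id, d$feature_id)
      tibble::tibble(accession = mapped_nm$accession,
                     position = mapped_nm$position, kind = mapped_nm$kind,
                     quantified = !is.na(idx),
                     significant = !is.na(idx) & d$significant[idx])
    })
    sig_site <- sig_map |>
      dplyr::group_by(.data$accession, .data$position, .data$kind) |>
      dplyr::summarise(quantified = any(.data$quantified),
                       differential = any(.data$significant), .groups = "drop")
    sites <- dplyr::left_join(sites, sig_site,
                              by = c("accession", "position", "kind"))
    if (!is.null(known)) sites <- annotate_novelty(sites, known)
    if (!is.null(variants)) sites <- annotate_variants(sites, variants)
  }

  result <- structure(list(
    designs = designs, plex = plex, diff = diff, qc = qc, modules = modules,
    sites = sites, site_summary = site_summary, alpha = alpha, seed = seed
  ), class = "kme_pipeline")
  result$report <- pipeline_report(result)

  if (!is.null(out_dir)) {
    tabs <- list()
    for (nm in names(diff)) tabs[[paste0("diff_", nm)]] <- diff[[nm]]
    if (!is.null(sites)) {
      tabs$sites <- sites
      tabs$site_summary <- site_summary
    }
    if (!is.null(modules)) {
      tabs$modules_protein <- modules$protein$assignment
      tabs$modules_kme <- modules$kme$assignment
      tabs$eigengenes_protein <- modules$protein$eigengenes
      tabs$eigengenes_kme <- modules$kme$eigengenes
    }
    for (nm in names(qc)) {
      tabs[[paste0("replicate_correlation_", nm)]] <- qc[[nm]]$replicate_correlation
    }
    write_results(tabs, out_dir, seed = seed,
                  config = list(alpha = alpha, pseudocount = pseudocount,
                                min_loc_score = min_loc_score))
  }
  result
}

#' Summarise a pipeline run
#'
#' Headline tallies of a [run_pipeline()] result: per-plex stage counts,
#' detected/quantified/differential site counts, protease overlap, module
#' sizes with archetypes, novelty fraction and variant hits. The counts
#' reconcile exactly with the per-stage logs.
#'
#' @param result A `kme_pipeline` object.
#' @return List of class `kme_report` with `counts` (named numbers) and
#'   `tables`; `format()`/`print()` give the plain-text rendering, and the
#'   object serialises to JSON with [jsonlite::toJSON()].
#' @export
pipeline_report <- function(result) {
  counts <- list()
  for (nm in names(result$plex)) {
    st <- result$plex[[nm]]$counts
    for (i in seq_len(nrow(st))) {
      counts[[paste0(nm, "_", st$stage[i])]] <- st$n[i]
    }
  }
  for (nm in names(result$diff)) {
    counts[[paste0("n_significant_", nm)]] <- sum(result$diff[[nm]]$significant)
  }
  if (!is.null(result$sites)) {
    counts$n_unique_sites <- nrow(result$sites)
    counts$n_unique_proteins <- length(unique(result$sites$accession))
    counts$n_quantified_sites <- sum(result$sites$quantified, na.rm = TRUE)
    counts$n_differential_sites <- sum(result$sites$differential, na.rm = TRUE)
    if ("novel_site" %in% names(result$sites)) {
      counts$fraction_novel_sites <- mean(result$sites$novel_site)
    }
    if ("variant" %in% names(result$sites)) {
      counts$n_variant_hits <- sum(!is.na(result$sites$variant))
    }
  }
  if (!is.null(result$modules)) {
    counts$n_protein_modules <-
      sum(unique(result$modules$protein$assignment$module) != "grey")
    counts$n_kme_modules <-
      sum(unique(result$modules$kme$assignment$module) != "grey")
  }
  tables <- list(site_summary = result$site_summary)
  if (!is.null(result$modules)) {
    pick <- function(eg) {
      if (nrow(eg) == 0) eg else eg[, c("module", "n_members", "archetype")]
    }
    tables$protein_modules <- pick(result$modules$protein$eigengenes)
    tables$kme_modules <- pick(result$modules$kme$eigengenes)
  }
  structure(list(counts = counts, tables = tables), class = "kme_report")
}

#' @export
format.kme_report <- function(x, ...) {
  lines <- c("kmeflow pipeline report", "-----------------------")
  lines <- c(lines, vapply(names(x$counts), function(nm) {
    sprintf("%-45s %s", nm, format(x$counts[[nm]], digits = 4))
  }, character(1)))
  lines
}

#' @export
print.kme_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Score recovery of planted differential sites
#'
#' Compares a pipeline run on a simulated study against the generator's
#' ground truth: a planted site is recovered when any of its supporting
#' peptide features is called significant in any protease arm.
#'
#' @param result A [run_pipeline()] result run on `study`.
#' @param study The [simulate_study()] object.
#' @return List: `sensitivity` (recovered / planted differential), `fdr`
#'   (false discoveries among called sites), `n_called`, `n_true`,
#'   `fraction_significant` (all tested Kme features with `padj < alpha`),
#'   `per_site` tibble.
#' @export
evaluate_recovery <- function(result, study) {
  truth_sites <- study$truth$sites
  called <- list()
  for (nm in names(study$plex)) {
    d <- result$diff[[paste0("kme_", nm)]]
    if (is.null(d) || nrow(d) == 0) next
    peps <- result$plex[[nm]]$peptides_kept
    obs <- study$plex[[nm]]$observed_sites
    key_pep <- paste(peps$accession, peps$sequence, peps$mod_string)
    key_obs <- paste(obs$accession, obs$sequence, obs$modstring)
    idx <- match(key_obs, key_pep)
    ok <- !is.na(idx)
    pid <- peps$peptide_id[idx[ok]]
    didx <- match(pid, d$feature_id)
    called[[nm]] <- tibble::tibble(
      site_id = obs$site_id[ok],
      tested = !is.na(didx),
      significant = !is.na(didx) & d$significant[didx],
      diff_applied = obs$diff_applied[ok]
    )
  }
  per_site <- dplyr::bind_rows(called) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(tested = any(.data$tested),
                     called = any(.data$significant),
                     evidence_differential = any(.data$diff_applied),
                     .groups = "drop")
  per_site <- dplyr::left_join(
    truth_sites[c("site_id", "differential")], per_site, by = "site_id")
  per_site$tested[is.na(per_site$tested)] <- FALSE
  per_site$called[is.na(per_site$called)] <- FALSE
  per_site$evidence_differential[is.na(per_site$evidence_differential)] <- FALSE
  n_true <- sum(per_site$differential)
  n_called <- sum(per_site$called)
  tp <- sum(per_site$called & per_site$differential)
  # a called site whose quantified peptide carried a planted effect from a
  # co-resident site is not a false discovery of the statistics
  fp <- sum(per_site$called & !per_site$differential &
              !per_site$evidence_differential)
  all_d <- dplyr::bind_rows(result$diff[paste0("kme_", names(study$plex))])
  list(
    sensitivity = if (n_true > 0) tp / n_true else NA_real_,
    fdr = if (n_called > 0) fp / n_called else 0,
    n_called = n_called, n_true = n_true,
    fraction_significant = mean(all_d$padj < result$alpha),
    per_site = per_site
  )
}
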