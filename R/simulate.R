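# Ground-truth synthetic study generator. It emulates the study design the
# analysis assumes: two 12-plex TMT experiments (trypsin/lys-C and
# chymotrypsin), three differentiation days (0/2/6) with four biological
# replicates each, stage-structured protein profiles, planted differential
# methylation-stoichiometry effects, lognormal replicate noise, channel
# loading variation, a localization-score mixture with ambiguous decoys,
# and missingness.

# Approximate human proteome residue composition (relative frequencies).
AA_FREQ_HUMAN <- c(
  A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, E = 7.1, Q = 4.8, G = 6.6,
  H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7, P = 6.3, S = 8.3,
  T = 5.3, W = 1.2, Y = 2.7, V = 6.0
)

# Evaluate `code` under `seed` without disturbing the session's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Synthetic-study configuration
#'
#' Defaults encode the study conditions the generator emulates: 500 Kme
#' sites over 250 proteins, 15% of sites carrying a planted differential
#' stoichiometry effect of 1 log2 unit at day 6, 10% lognormal replicate
#' CV, 5% channel-loading spread, four archetype classes of protein
#' day-profiles, a high-beta localization-score distribution for true sites
#' against a low-beta ambiguous decoy class, and 2% random missingness.
#'
#' @param n_proteins Number of proteins.
#' @param protein_length Length range (uniform integer draw).
#' @param frac_methylated Fraction of proteins eligible to carry Kme sites.
#' @param n_sites Total planted Kme sites.
#' @param methyl_state_probs Named probabilities over me1/me2/me3.
#' @param archetype_probs Named probabilities over
#'   decreasing/transient_up/increasing/flat.
#' @param archetype_profiles Named list of day-mean log2 offsets (days
#'   0/2/6) per archetype.
#' @param base_log2_mean,base_log2_sd Protein baseline log2 abundance.
#' @param diff_fraction Fraction of sites with a planted effect.
#' @param effect_log2fc Planted |log2 fold change| at day 6.
#' @param noise_cv Lognormal replicate noise CV.
#' @param loading_cv Channel loading-factor CV.
#' @param missing_rate Per-cell missingness probability.
#' @param stoichiometry_range Uniform range of site stoichiometry (fraction
#'   of parent protein).
#' @param loc_score_true,loc_score_decoy Beta(shape1, shape2) parameters of
#'   the localization-score mixture.
#' @param decoy_fraction Fraction of peptide rows that are decoys.
#' @param ambiguous_true,ambiguous_decoy Probability of the ambiguous flag.
#' @param trypsin_invisible_fraction Fraction of sites planted in a
#'   K/R-sparse, aromatic-flanked context invisible to trypsin/lys-C.
#' @param n_bulk_peptides Unmodified peptides emitted per protein; the
#'   peptide export is dominated by the unmethylated complement, which is
#'   what total-peptide channel normalization is computed over.
#' @param max_missed Missed-cleavage cap used when choosing observed
#'   peptides.
#' @param filter_exercise_fraction Fraction of unmethylated proteins
#'   emitted at medium confidence or with one unique peptide (to exercise
#'   the protein filter).
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 250,
                       protein_length = c(200L, 600L),
                       frac_methylated = 0.8,
                       n_sites = 500,
                       methyl_state_probs = c(me1 = 0.4, me2 = 0.25, me3 = 0.35),
                       archetype_probs = c(decreasing = 0.35, transient_up = 0.15,
                                           increasing = 0.35, flat = 0.15),
                       archetype_profiles = list(
                         decreasing = c(1, 0, -1),
                         transient_up = c(-0.5, 1, -0.5),
                         increasing = c(-1, 0, 1),
                         flat = c(0, 0, 0)
                       ),
                       base_log2_mean = 16.5, base_log2_sd = 1.5,
                       diff_fraction = 0.15,
                       effect_log2fc = 1.0,
                       noise_cv = 0.10,
                       loading_cv = 0.05,
                       missing_rate = 0.02,
                       stoichiometry_range = c(0.02, 0.2),
                       loc_score_true = c(50, 0.7),
                       loc_score_decoy = c(2, 2),
                       decoy_fraction = 0.10,
                       ambiguous_true = 0.02,
                       ambiguous_decoy = 0.7,
                       trypsin_invisible_fraction = 0,
                       max_missed = 5,
                       filter_exercise_fraction = 0.05,
                       n_bulk_peptides = 5,
                       seed = 1L) {
  probs <- c(methyl_state_probs, archetype_probs, diff_fraction, missing_rate,
             decoy_fraction, ambiguous_true, ambiguous_decoy,
             trypsin_invisible_fraction, frac_methylated,
             filter_exercise_fraction)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  assert_scalar_number(seed, "seed")
  cfg <- as.list(environment())
  cfg$probs <- NULL
  structure(cfg, class = "sim_config")
}

random_sequence <- function(n, alphabet = names(AA_FREQ_HUMAN),
                            weights = AA_FREQ_HUMAN) {
  paste(sample(alphabet, n, replace = TRUE, prob = weights), collapse = "")
}

# Residues allowed in a trypsin-invisible context block: no K/R (tryptic
# cuts), no F/W/Y/L (chymotryptic cuts), no P (cleavage blocking).
INVISIBLE_FILLER <- setdiff(names(AA_FREQ_HUMAN),
                            c("K", "R", "F", "W", "Y", "L", "P"))

# Overwrite a 61-residue block centered on `center`: filler everywhere, K at
# the center, F at center-5 and center+4, so chymotrypsin yields a 9-mer
# containing the K while the shortest tryptic peptide spanning it has >= 61
# residues.
plant_invisible_context <- function(sequence, center) {
  n <- nchar(sequence)
  stopifnot(center - 30 >= 1, center + 30 <= n)
  block <- sample(INVISIBLE_FILLER, 61, replace = TRUE,
                  prob = AA_FREQ_HUMAN[INVISIBLE_FILLER])
  block[31] <- "K"
  block[31 - 5] <- "F"
  block[31 + 4] <- "F"
  paste0(substring(sequence, 1, center - 31),
         paste(block, collapse = ""),
         substring(sequence, center + 31, n))
}

#' Simulate a ground-truth proteome
#'
#' Generates random protein sequences over a human-like residue
#' composition, assigns each protein an abundance archetype and baseline,
#' and plants lysine-methylation sites — optionally placing a configured
#' fraction in K/R-sparse, aromatic-flanked contexts that trypsin/lys-C
#' digestion cannot render detectable.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_truth`: `proteins` (tibble `accession`,
#'   `sequence`, `description`, `archetype`, `base_log2`,
#'   `filter_exercise`), `sites` (tibble `site_id`, `accession`,
#'   `position`, `kind`, `stoichiometry`, `differential`, `effect_d0/2/6`,
#'   `trypsin_invisible`), `config`.
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_proteins
    lens <- sample(seq(config$protein_length[1], config$protein_length[2]),
                   n, replace = TRUE)
    seqs <- vapply(lens, random_sequence, character(1))
    acc <- sprintf("SYN%04d", seq_len(n))
    archetype <- sample(names(config$archetype_probs), n, replace = TRUE,
                        prob = config$archetype_probs)
    base <- rnorm(n, config$base_log2_mean, config$base_log2_sd)

    methylated <- sort(sample(n, round(config$frac_methylated * n)))
    n_inv <- round(config$trypsin_invisible_fraction * config$n_sites)

    # invisible sites: one engineered context per site, planted mid-protein
    inv_sites <- list()
    if (n_inv > 0) {
      used <- stats::setNames(vector("list", n), acc)
      for (i in seq_len(n_inv)) {
        # hosts drawn among methylated proteins that can still fit a block:
        # centers at least 61 residues from both termini and 70 from any
        # previously planted block on the same protein
        placed <- FALSE
        for (p in sample(methylated, length(methylated))) {
          if (lens[p] < 124) next
          cand <- seq(62, lens[p] - 62)
          prior <- used[[acc[p]]]
          if (!is.null(prior)) {
            cand <- cand[vapply(cand, function(x) all(abs(x - prior) > 70),
                                logical(1))]
          }
          if (length(cand) == 0) next
          center <- cand[sample.int(length(cand), 1)]
          used[[acc[p]]] <- c(used[[acc[p]]], center)
          seqs[p] <- plant_invisible_context(seqs[p], center)
          inv_sites[[i]] <- tibble::tibble(accession = acc[p], position = center,
                                           trypsin_invisible = TRUE)
          placed <- TRUE
          break
        }
        if (!placed) {
          abort("Cannot place all trypsin-invisible contexts; proteins too short.")
        }
      }
    }
    inv_sites <- dplyr::bind_rows(inv_sites)

    # ordinary sites on remaining K residues of methylated proteins
    n_ord <- config$n_sites - n_inv
    k_pool <- purrr::map_dfr(methylated, function(p) {
      kpos <- which(strsplit(seqs[p], "")[[1]] == "K")
      if (nrow(inv_sites) > 0) {
        taken <- inv_sites$position[inv_sites$accession == acc[p]]
        # keep ordinary sites out of engineered blocks
        kpos <- kpos[!vapply(kpos, function(x) any(abs(x - taken) <= 31), logical(1))]
      }
      tibble::tibble(accession = acc[p], position = kpos)
    })
    if (nrow(k_pool) < n_ord) {
      abort("Site count exceeds available K residues; lower `n_sites`.")
    }
    ord <- k_pool[sample(nrow(k_pool), n_ord), ]
    ord$trypsin_invisible <- FALSE
    sites <- dplyr::bind_rows(inv_sites, ord)
    sites <- sites[order(sites$accession, sites$position), ]
    sites$site_id <- sprintf("site%04d", seq_len(nrow(sites)))
    sites$kind <- sample(names(config$methyl_state_probs), nrow(sites),
                         replace = TRUE, prob = config$methyl_state_probs)
    sites$stoichiometry <- runif(nrow(sites), config$stoichiometry_range[1],
                                 config$stoichiometry_range[2])
    sites$differential <- seq_len(nrow(sites)) %in%
      sample(nrow(sites), round(config$diff_fraction * nrow(sites)))
    sgn <- sample(c(-1, 1), nrow(sites), replace = TRUE)
    sites$effect_d0 <- 0
    sites$effect_d2 <- 0
    sites$effect_d6 <- ifelse(sites$differential, sgn * config$effect_log2fc, 0)

    filter_ex <- rep(FALSE, n)
    unmeth <- setdiff(seq_len(n), methylated)
    if (length(unmeth) > 0 && config$filter_exercise_fraction > 0) {
      n_ex <- round(config$filter_exercise_fraction * length(unmeth))
      filter_ex[sample(unmeth, n_ex)] <- TRUE
    }
    proteins <- tibble::tibble(
      accession = acc, sequence = seqs,
      description = sprintf("synthetic protein %d (%s)", seq_len(n), archetype),
      archetype = archetype, base_log2 = base, filter_exercise = filter_ex
    )
    structure(list(proteins = proteins,
                   sites = sites[c("site_id", "accession", "position", "kind",
                                   "stoichiometry", "differential", "effect_d0",
                                   "effect_d2", "effect_d6", "trypsin_invisible")],
                   config = config),
              class = "sim_truth")
  })
}

ab_tibble <- function(mat, samples) {
  colnames(mat) <- samples
  tibble::as_tibble(mat)
}

lognoise <- function(n, cv) {
  if (cv == 0) return(rep(0, n))
  sdlog2 <- sqrt(log(1 + cv^2)) / log(2)
  rnorm(n, 0, sdlog2)
}

#' Simulate quantification tables for one plex
#'
#' Produces the protein and modified-peptide quantification tables one
#' protease experiment would export. Protein channel abundances follow
#' `2^(baseline + archetype day offset + replicate noise) * loading`;
#' each Kme site's observed peptide is chosen by methylation-aware
#' [digest()] under the plex's protease (fewest missed cleavages, then
#' shortest, among peptides passing [detectable()]), and its abundance is
#' the parent protein's signal times the site stoichiometry times
#' `2^(planted effect at that day)`, with independent measurement noise.
#' Localization scores and ambiguous flags are drawn from the true/decoy
#' mixture; decoy rows carry deliberately mislocalized methyls. Cells go
#' missing at the configured rate.
#'
#' @param truth A [simulate_proteome()] result.
#' @param design A [study_design()] (12 channels, 3 days x 4 replicates).
#' @param plex_seed Seed offset for this plex (so the two protease plexes
#'   differ); defaults derive from the design's protease.
#' @return List: `peptides` and `proteins` in the shape
#'   [read_quant_tables()] returns, plus `observed_sites` (tibble
#'   `site_id`, `peptide_id`, `detectable`).
#' @export
simulate_quant <- function(truth, design, plex_seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  assert_design(design)
  config <- truth$config
  plex_seed <- plex_seed %||%
    (config$seed + 1000L + match(design$protease[1],
                                 c("trypsin_lysc", "chymotrypsin")))
  rule <- protease_rule(design$protease[1])
  dconf <- detect_config()
  with_seed(plex_seed, {
    samples <- design$sample
    days <- design$day
    nprot <- nrow(truth$proteins)
    loading <- 2^lognoise(12, config$loading_cv)

    day_col <- match(as.character(days), c("0", "2", "6"))
    profiles <- do.call(rbind, config$archetype_profiles[truth$proteins$archetype])
    signal_log2 <- truth$proteins$base_log2 + profiles[, day_col, drop = FALSE]

    # unmodified bulk peptides, generated first: they dominate the peptide
    # export, and the protein table is their roll-up (summed peptide
    # abundances), as consensus workflows compute it
    bulk <- NULL; bulk_ab <- NULL
    if (config$n_bulk_peptides > 0) {
      bulk <- purrr::map_dfr(seq_len(nprot), function(p) {
        prot <- truth$proteins[p, ]
        peps <- digest(prot, rule, max_missed = 0, label = "tmt")
        cand <- peps[detectable(nchar(peps$sequence), peps$mass, dconf) &
                       peps$n_methyl == 0, , drop = FALSE]
        if (nrow(cand) == 0) return(NULL)
        take <- sample.int(nrow(cand), min(config$n_bulk_peptides, nrow(cand)))
        tibble::tibble(sequence = cand$sequence[take], accession = prot$accession,
                       protein_idx = p)
      })
      nb <- nrow(bulk)
      if (nb > 0) {
        bulk_ab <- 2^(signal_log2[bulk$protein_idx, , drop = FALSE] +
                        matrix(lognoise(nb * 12, config$noise_cv), nb, 12)) *
          runif(nb, 0.05, 0.3) * matrix(loading, nb, 12, byrow = TRUE)
      }
    }
    if (!is.null(bulk_ab)) {
      rolled <- rowsum(bulk_ab, group = bulk$protein_idx)
      prot_ab <- matrix(NA_real_, nprot, 12)
      prot_ab[as.integer(rownames(rolled)), ] <- rolled
      orphan <- which(is.na(prot_ab[, 1]))
      if (length(orphan) > 0) {
        prot_ab[orphan, ] <- 2^(signal_log2[orphan, , drop = FALSE] +
                                  matrix(lognoise(length(orphan) * 12,
                                                  config$noise_cv),
                                         length(orphan), 12)) *
          matrix(loading, length(orphan), 12, byrow = TRUE)
      }
    } else {
      prot_ab <- 2^(signal_log2 +
                      matrix(lognoise(nprot * 12, config$noise_cv), nprot, 12)) *
        matrix(loading, nprot, 12, byrow = TRUE)
    }
    conf <- rep("high", nprot)
    n_unique <- 2L + stats::rpois(nprot, 4)
    ex <- truth$proteins$filter_exercise
    if (any(ex)) {
      half <- runif(sum(ex)) < 0.5
      conf[ex][half] <- "medium"
      n_unique[ex][!half] <- 1L
    }
    prot_tab <- dplyr::bind_cols(
      tibble::tibble(plex_id = design$plex_id[1],
                     accession = truth$proteins$accession,
                     confidence = conf, n_unique_peptides = n_unique),
      ab_tibble(prot_ab, samples)
    )

    # choose the observed peptide per site via methyl-aware digestion
    digest_cache <- new.env(parent = emptyenv())
    site_rows <- purrr::map_dfr(seq_len(nrow(truth$sites)), function(si) {
      s <- truth$sites[si, ]
      if (is.null(digest_cache[[s$accession]])) {
        prot <- truth$proteins[truth$proteins$accession == s$accession, ]
        mods <- truth$sites[truth$sites$accession == s$accession,
                            c("position", "kind")]
        peps <- digest(prot, rule, max_missed = config$max_missed,
                       site_mods = mods, label = "tmt")
        peps$det <- detectable(nchar(peps$sequence), peps$mass, dconf)
        digest_cache[[s$accession]] <- peps
      }
      peps <- digest_cache[[s$accession]]
      cover <- peps[peps$start <= s$position & peps$end >= s$position &
                      peps$det, , drop = FALSE]
      if (nrow(cover) == 0) {
        return(tibble::tibble(site_id = s$site_id, detectable = FALSE,
                              sequence = NA_character_, start = NA_integer_,
                              modstring = NA_character_))
      }
      cover <- cover[order(cover$missed_cleavages, nchar(cover$sequence)), ]
      best <- cover[1, ]
      carried <- best$modifications[[1]]
      carried <- carried[carried$kind %in% METHYL_STATES, ]
      modstring <- paste(sprintf("K%d(%s)", carried$position - best$start + 1L,
                                 carried$kind), collapse = ";")
      tibble::tibble(site_id = s$site_id, detectable = TRUE,
                     sequence = best$sequence, start = best$start,
                     modstring = modstring)
    })

    observed <- dplyr::bind_cols(truth$sites, site_rows[c("detectable", "sequence",
                                                          "start", "modstring")])
    observed <- observed[observed$detectable, , drop = FALSE]
    # One row per distinct observed peptide: a peptide spanning several
    # sites supports all of them and its abundance carries the largest
    # planted effect among them (the peptide is the quantifiable unit; co-
    # resident sites are not separable, as with adjacent methylated K's).
    pep_key <- paste(observed$accession, observed$sequence, observed$modstring)
    o_ord <- order(match(pep_key, unique(pep_key)), -abs(observed$effect_d6))
    observed <- observed[o_ord, , drop = FALSE]
    pep_key <- pep_key[o_ord]
    grp <- match(pep_key, unique(pep_key))
    first <- !duplicated(grp)
    obs1 <- observed[first, , drop = FALSE]
    observed$applied_effect_d6 <- obs1$effect_d6[grp]
    observed$diff_applied <- observed$applied_effect_d6 != 0

    n_true <- nrow(obs1)
    pep_rows <- list()
    if (n_true > 0) {
      pidx <- match(obs1$accession, truth$proteins$accession)
      pep_noise <- matrix(lognoise(n_true * 12, config$noise_cv), n_true, 12)
      effects <- cbind(obs1$effect_d0, obs1$effect_d2, obs1$effect_d6)[, day_col,
                                                                      drop = FALSE]
      pep_ab <- 2^(signal_log2[pidx, , drop = FALSE] + effects + pep_noise) *
        obs1$stoichiometry *
        matrix(loading, n_true, 12, byrow = TRUE)
      pep_rows[["true"]] <- dplyr::bind_cols(
        tibble::tibble(
          sequence = obs1$sequence, mod_string = obs1$modstring,
          accession = obs1$accession,
          loc_score = rbeta(n_true, config$loc_score_true[1],
                            config$loc_score_true[2]),
          ambiguous = runif(n_true) < config$ambiguous_true,
          origin = "true"
        ),
        ab_tibble(pep_ab, samples)
      )
    }

    if (!is.null(bulk_ab)) {
      pep_rows[["bulk"]] <- dplyr::bind_cols(
        tibble::tibble(sequence = bulk$sequence, mod_string = "",
                       accession = bulk$accession,
                       loc_score = NA_real_, ambiguous = FALSE,
                       origin = "bulk"),
        ab_tibble(bulk_ab, samples)
      )
    }

    # ambiguous decoy rows: peptides with a deliberately mislocalized methyl
    n_decoy <- if (config$decoy_fraction > 0 && n_true > 0) {
      round(n_true * config$decoy_fraction / (1 - config$decoy_fraction))
    } else 0
    if (n_decoy > 0) {
      hosts <- sample(seq_len(nprot), n_decoy, replace = TRUE)
      decoys <- purrr::map_dfr(hosts, function(p) {
        prot <- truth$proteins[p, ]
        peps <- digest(prot, rule, max_missed = 2, label = "tmt")
        with_k <- peps[grepl("K", peps$sequence) &
                         detectable(nchar(peps$sequence), peps$mass, dconf), ]
        if (nrow(with_k) == 0) return(NULL)
        pep <- with_k[sample.int(nrow(with_k), 1), ]
        kpos <- which(strsplit(pep$sequence, "")[[1]] == "K")
        tibble::tibble(
          sequence = pep$sequence,
          mod_string = sprintf("K%d(%s)", kpos[sample.int(length(kpos), 1)],
                               METHYL_STATES[sample.int(3, 1)]),
          accession = prot$accession
        )
      })
      if (nrow(decoys) > 0) {
        nd <- nrow(decoys)
        didx <- match(decoys$accession, truth$proteins$accession)
        d_ab <- 2^(signal_log2[didx, , drop = FALSE] +
                     matrix(lognoise(nd * 12, config$noise_cv), nd, 12)) *
          runif(nd, 0.005, 0.05) * matrix(loading, nd, 12, byrow = TRUE)
        pep_rows[["decoy"]] <- dplyr::bind_cols(
          decoys,
          tibble::tibble(
            loc_score = rbeta(nd, config$loc_score_decoy[1],
                              config$loc_score_decoy[2]),
            ambiguous = runif(nd) < config$ambiguous_decoy,
            origin = "decoy"
          ),
          ab_tibble(d_ab, samples)
        )
      }
    }
    peptides <- dplyr::bind_rows(pep_rows)
    if (nrow(peptides) > 0 && config$missing_rate > 0) {
      for (s in samples) {
        peptides[[s]][runif(nrow(peptides)) < config$missing_rate] <- NA_real_
      }
      for (s in samples) {
        prot_tab[[s]][runif(nrow(prot_tab)) < config$missing_rate] <- NA_real_
      }
    }
    if (nrow(peptides) > 0) {
      peptides <- dplyr::bind_cols(
        tibble::tibble(plex_id = design$plex_id[1],
                       peptide_id = sprintf("%s_pep%05d", design$plex_id[1],
                                            seq_len(nrow(peptides)))),
        peptides
      )
      peptides$modifications <-
        parse_modifications(peptides$mod_string, peptides$sequence)
      peptides$n_methyl <- vapply(peptides$modifications,
                                  function(m) sum(m$kind %in% METHYL_STATES),
                                  integer(1))
    }
    obs_map <- observed[c("site_id", "accession", "sequence", "modstring",
                          "applied_effect_d6", "diff_applied")]
    list(peptides = peptides, proteins = prot_tab, observed_sites = obs_map,
         design = design)
  })
}

#' Simulate the complete two-protease study
#'
#' @param config A [sim_config()].
#' @param designs Named list of the two plex designs
#'   (default [default_study_designs()]).
#' @return List of class `sim_study`: `truth`, `plex` (named list of
#'   [simulate_quant()] outputs), `designs`, `config`.
#' @export
simulate_study <- function(config = sim_config(),
                           designs = default_study_designs()) {
  truth <- simulate_proteome(config)
  plex <- lapply(designs, function(d) simulate_quant(truth, d))
  structure(list(truth = truth, plex = plex, designs = designs,
                 config = config),
            class = "sim_study")
}

#' Write a simulated study in the package's input formats
#'
#' Emits exactly what the readers consume: a protein FASTA, one peptide and
#' one protein TSV per plex (channel columns named by channel label), a
#' design TSV, and a JSON manifest recording the seed and configuration
#' hash. Numeric values are written at 6 significant digits, so
#' regeneration from the same seed is byte-identical.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, "proteins.fasta")
  write_protein_fasta(study$truth$proteins, files)
  for (nm in names(study$plex)) {
    pl <- study$plex[[nm]]
    design <- pl$design
    pep <- pl$peptides
    pep_out <- tibble::tibble(
      sequence = pep$sequence, modifications = pep$mod_string,
      accession = pep$accession,
      loc_score = format_num6(pep$loc_score),
      ambiguous = ifelse(pep$ambiguous, "true", "false")
    )
    for (i in seq_len(12)) {
      pep_out[[design$channel[i]]] <- format_num6(pep[[design$sample[i]]])
    }
    pep_out[pep_out == "NA"] <- ""
    f1 <- file.path(dir, paste0("peptides_", nm, ".tsv"))
    readr::write_tsv(pep_out, f1, progress = FALSE)
    prot <- pl$proteins
    prot_out <- tibble::tibble(
      accession = prot$accession, confidence = prot$confidence,
      n_unique_peptides = prot$n_unique_peptides
    )
    for (i in seq_len(12)) {
      prot_out[[design$channel[i]]] <- format_num6(prot[[design$sample[i]]])
    }
    prot_out[prot_out == "NA"] <- ""
    f2 <- file.path(dir, paste0("proteins_", nm, ".tsv"))
    readr::write_tsv(prot_out, f2, progress = FALSE)
    files <- c(files, f1, f2)
  }
  dtab <- dplyr::bind_rows(lapply(study$designs, function(d) {
    d[c("plex_id", "protease", "channel", "day", "replicate")]
  }))
  fdes <- file.path(dir, "design.tsv")
  readr::write_tsv(dtab, fdes, progress = FALSE)
  manifest <- list(seed = study$config$seed,
                   config_hash = rlang::hash(unclass(study$config)),
                   generator = "kmeflow simulate_study")
  fman <- file.path(dir, "sim_manifest.json")
  jsonlite::write_json(manifest, fman, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, fdes, fman))
}

#' Configuration of the packaged mini-study fixture
#'
#' A deterministic small study (50 proteins, 30 Kme sites, both proteases,
#' 20% trypsin-invisible contexts) used by the end-to-end tests and the
#' documentation; regenerating it from its seed is byte-identical to the
#' copy under `inst/extdata/fixture`.
#'
#' @return A [sim_config()].
#' @export
fixture_config <- function() {
  sim_config(n_proteins = 50, protein_length = c(180L, 400L), n_sites = 30,
             trypsin_invisible_fraction = 0.2, decoy_fraction = 0.15,
             seed = 420L)
}

#' Generate (or locate) the packaged mini-study
#'
#' @param dir Directory to generate into; `NULL` returns the installed
#'   fixture directory.
#' @return Path to the fixture directory.
#' @export
fixture_small <- function(dir = NULL) {
  if (is.null(dir)) {
    return(system.file("extdata", "fixture", package = "kmeflow"))
  }
  study <- simulate_study(fixture_config())
  write_simulated_study(study, dir)
  dir
}
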