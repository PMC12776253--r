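# Monoisotopic residue masses (Da) for the 20 canonical amino acids.
AA_MONO_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)
MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276
MASS_METHYL <- 14.015650
MASS_TMTPRO <- 304.207146

#' Protease cleavage rules
#'
#' Returns the cleavage specificity used by [digest()]. The trypsin/lys-C
#' mixture cleaves after K always (lys-C cuts K-P) and after R unless the
#' next residue is proline. Chymotrypsin cleaves after F/W/Y/L (or F/W/Y
#' only with `chymo_low_specificity = FALSE`), never before proline.
#' Methylated lysine blocks cleavage for every methyl state by default,
#' reflecting the steric hindrance a methylated epsilon-amine presents to
#' trypsin/lys-C; this is configurable per state.
#'
#' @param name `"trypsin_lysc"` or `"chymotrypsin"`.
#' @param methyl_blocks Named logical vector over `me1`, `me2`, `me3`:
#'   whether that methyl state suppresses cleavage after the K.
#' @param chymo_low_specificity Include L in the chymotrypsin cut set
#'   (default `TRUE`, the common search-engine dialect).
#' @return A list of class `protease_rule` with elements `name`,
#'   `cleave_after`, `proline_blocked` (subset of `cleave_after` whose cut
#'   is suppressed by a following P) and `methyl_blocks`.
#' @export
protease_rule <- function(name = c("trypsin_lysc", "chymotrypsin"),
                          methyl_blocks = c(me1 = TRUE, me2 = TRUE, me3 = TRUE),
                          chymo_low_specificity = TRUE) {
  name <- match.arg(name)
  stopifnot(all(METHYL_STATES %in% names(methyl_blocks)))
  rule <- switch(name,
    trypsin_lysc = list(
      cleave_after = c("K", "R"),
      proline_blocked = "R"
    ),
    chymotrypsin = list(
      cleave_after = if (chymo_low_specificity) c("F", "W", "Y", "L") else c("F", "W", "Y"),
      proline_blocked = if (chymo_low_specificity) c("F", "W", "Y", "L") else c("F", "W", "Y")
    )
  )
  structure(
    c(list(name = name), rule,
      list(methyl_blocks = methyl_blocks[METHYL_STATES])),
    class = "protease_rule"
  )
}

# Positions (1-based, < protein length) after which the protease cuts.
cleavage_sites <- function(sequence, rule, site_mods = NULL) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2) return(integer(0))
  i <- seq_len(n - 1)
  cut <- chars[i] %in% rule$cleave_after &
    !(chars[i] %in% rule$proline_blocked & chars[i + 1] == "P")
  if (!is.null(site_mods) && nrow(site_mods) > 0) {
    blocked_states <- names(rule$methyl_blocks)[rule$methyl_blocks]
    blocked_pos <- site_mods$position[site_mods$kind %in% blocked_states]
    cut[i %in% blocked_pos] <- FALSE
  }
  which(cut)
}

#' Methylation-aware in silico digestion
#'
#' Digests one protein with a protease rule, allowing up to `max_missed`
#' missed cleavages. A lysine carrying a methyl state that the rule blocks
#' is removed from the cleavage-site set entirely — peptides span it and it
#' does not count toward the missed-cleavage tally.
#'
#' @param protein One-row tibble (or list) with `accession` and `sequence`.
#' @param rule A [protease_rule()].
#' @param max_missed Maximum missed cleavages (default 5, the search
#'   setting).
#' @param site_mods Tibble of methyl placements on this protein:
#'   columns `position` (1-based protein coordinate, must be K for me*)
#'   and `kind` (`me1`/`me2`/`me3`).
#' @param label Label policy for peptide mass: `"none"` or `"tmt"`
#'   (isobaric tag on the N-terminus and every unmethylated K).
#' @return Tibble of digest peptides: `accession`, `start`, `end`,
#'   `sequence`, `missed_cleavages`, `n_methyl`, `modifications` (list
#'   column of carried protein-coordinate mods), `mass` (monoisotopic Da,
#'   methyl and label included).
#' @examples
#' p <- tibble::tibble(accession = "P1", sequence = "MKRPAK")
#' digest(p, protease_rule("trypsin_lysc"), max_missed = 0)
#' @export
digest <- function(protein, rule, max_missed = 5, site_mods = NULL,
                   label = c("none", "tmt")) {
  label <- match.arg(label)
  accession <- protein$accession[[1]]
  sequence <- protein$sequence[[1]]
  check_canonical(sequence, accession)
  n <- nchar(sequence)
  if (is.null(site_mods)) {
    site_mods <- tibble::tibble(position = integer(), kind = character())
  }
  if (nrow(site_mods) > 0) {
    if (any(site_mods$position < 1 | site_mods$position > n)) {
      abort(sprintf("Modification position out of range for '%s'.", accession))
    }
    res <- substring(sequence, site_mods$position, site_mods$position)
    if (any(site_mods$kind %in% METHYL_STATES & res != "K")) {
      abort(sprintf("Methyl modification on non-K residue in '%s'.", accession))
    }
  }
  cuts <- cleavage_sites(sequence, rule, site_mods)
  bounds <- c(0L, cuts, n)
  nb <- length(bounds)
  # enumerate all boundary pairs (i, j) with j - i - 1 <= max_missed
  i_idx <- rep.int(seq_len(nb - 1L),
                   pmin(nb - seq_len(nb - 1L), max_missed + 1L))
  j_idx <- unlist(lapply(seq_len(nb - 1L), function(i) {
    seq(i + 1L, min(nb, i + 1L + max_missed))
  }), use.names = FALSE)
  starts <- bounds[i_idx] + 1L
  ends <- bounds[j_idx]
  missed <- j_idx - i_idx - 1L
  pep_seq <- substring(sequence, starts, ends)

  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  # cumulative residue masses / K counts / methyl units for O(1) peptide sums
  cum_mass <- cumsum(AA_MONO_MASS[chars])
  cum_k <- cumsum(chars == "K")
  units <- numeric(n); meth_k <- numeric(n)
  if (nrow(site_mods) > 0) {
    me <- site_mods[site_mods$kind %in% METHYL_STATES, , drop = FALSE]
    units[me$position] <- match(me$kind, METHYL_STATES)
    meth_k[me$position] <- 1
  }
  cum_units <- cumsum(units)
  cum_meth <- cumsum(meth_k)
  seg <- function(cum) {
    cum0 <- c(0, cum)
    unname(cum0[ends + 1L] - cum0[starts])
  }
  mass <- seg(cum_mass) + MASS_WATER + seg(cum_units) * MASS_METHYL
  n_me <- as.integer(seg(cum_meth))
  if (label == "tmt") {
    unlabelled_k <- seg(cum_k) - n_me
    mass <- mass + MASS_TMTPRO * (1 + unlabelled_k)
  }
  empty_mods <- site_mods[0, , drop = FALSE]
  mods <- rep(list(empty_mods), length(starts))
  if (nrow(site_mods) > 0) {
    hit <- lapply(seq_len(nrow(site_mods)), function(s) {
      which(starts <= site_mods$position[s] & ends >= site_mods$position[s])
    })
    touched <- unique(unlist(hit))
    per_pep <- lapply(touched, function(k) integer(0))
    names(per_pep) <- as.character(touched)
    for (s in seq_along(hit)) {
      for (k in hit[[s]]) {
        per_pep[[as.character(k)]] <- c(per_pep[[as.character(k)]], s)
      }
    }
    for (k in touched) {
      mods[[k]] <- site_mods[per_pep[[as.character(k)]], , drop = FALSE]
    }
  }
  tibble::new_tibble(list(
    accession = rep(accession, length(starts)), start = starts, end = ends,
    sequence = pep_seq, missed_cleavages = missed, n_methyl = n_me,
    modifications = mods, mass = unname(mass)
  ), nrow = length(starts))
}

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus water, plus 14.015650 Da per
#' methyl unit (me1 = 1, me2 = 2, me3 = 3). Under the `"tmt"` label policy
#' the isobaric tag mass is added once for the N-terminus and once per K
#' residue that carries no methyl (the label reaction is blocked on a
#' methylated epsilon-amine).
#'
#' @param sequence Peptide sequence (canonical residues).
#' @param modifications Tibble with `position` (1-based in the peptide) and
#'   `kind` (`me1`/`me2`/`me3`; other kinds are mass-ignored here).
#' @param label `"none"` or `"tmt"`.
#' @param tag_mass Isobaric tag mass in Da (default TMTpro, 304.207146).
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mass("G") # 75.032029
#' @export
peptide_mass <- function(sequence, modifications = NULL,
                         label = c("none", "tmt"), tag_mass = MASS_TMTPRO) {
  label <- match.arg(label)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (any(!chars %in% names(AA_MONO_MASS))) {
    abort(sprintf("Unknown residue in peptide '%s'.", sequence))
  }
  mass <- sum(AA_MONO_MASS[chars]) + MASS_WATER
  methyl_pos <- integer(0)
  if (!is.null(modifications) && nrow(modifications) > 0) {
    me <- modifications[modifications$kind %in% METHYL_STATES, , drop = FALSE]
    units <- match(me$kind, METHYL_STATES) # me1->1, me2->2, me3->3
    mass <- mass + sum(units) * MASS_METHYL
    methyl_pos <- me$position
  }
  if (label == "tmt") {
    k_pos <- which(chars == "K")
    n_labelled_k <- sum(!k_pos %in% methyl_pos)
    mass <- mass + tag_mass * (1 + n_labelled_k)
  }
  mass
}

#' Mass-to-charge ratio
#'
#' @param mass Monoisotopic mass (Da).
#' @param charge Positive integer charge.
#' @return `(mass + charge * 1.007276) / charge`.
#' @export
mz <- function(mass, charge) {
  if (any(charge <= 0)) abort("`charge` must be >= 1.")
  (mass + charge * MASS_PROTON) / charge
}

#' Detectability window configuration
#'
#' Length and survey-scan bounds a peptide must satisfy to be considered
#' detectable: length within `[min_len, max_len]` and at least one charge in
#' `charges` placing its m/z within `[mz_min, mz_max]`. The m/z window and
#' charge range follow the instrument settings (survey 400-1600 m/z,
#' fragmentation charges 2-7); the length bounds are package defaults.
#'
#' @param min_len,max_len Peptide length bounds (default 6 and 50).
#' @param mz_min,mz_max Survey m/z window (default 400 and 1600).
#' @param charges Candidate charge states (default 2:7).
#' @return A list of class `detect_config`.
#' @export
detect_config <- function(min_len = 6, max_len = 50,
                          mz_min = 400, mz_max = 1600, charges = 2:7) {
  structure(list(min_len = min_len, max_len = max_len,
                 mz_min = mz_min, mz_max = mz_max, charges = charges),
            class = "detect_config")
}

#' Is a digest peptide detectable?
#'
#' Pure predicate over peptide length and mass under a [detect_config()].
#' Vectorised over `length` and `mass`.
#'
#' @param length Peptide length(s) in residues.
#' @param mass Monoisotopic mass(es), Da (label mass included if relevant).
#' @param config A [detect_config()].
#' @return Logical vector.
#' @export
detectable <- function(length, mass, config = detect_config()) {
  len_ok <- length >= config$min_len & length <= config$max_len
  mz_ok <- vapply(mass, function(m) {
    any(mz(m, config$charges) >= config$mz_min &
          mz(m, config$charges) <= config$mz_max)
  }, logical(1))
  len_ok & mz_ok
}

#' Per-site detectability across digestion strategies
#'
#' For each methylation site and each protease, digests the parent protein
#' (with all of that protein's methyl sites planted, blocking cleavage) and
#' reports the best digest peptide containing the site that passes
#' [detectable()] — "best" meaning fewest missed cleavages, then shortest.
#' A site with no passing peptide for a protease is reported
#' `detectable = FALSE` for that arm.
#'
#' @param proteins Tibble with `accession`, `sequence`.
#' @param sites Tibble with `accession`, `position`, `kind`.
#' @param rules List of [protease_rule()]s (default both study proteases).
#' @param max_missed Maximum missed cleavages (default 5).
#' @param config A [detect_config()].
#' @param label Label policy for mass (default `"tmt"`).
#' @return Tibble: one row per site x protease with `accession`, `position`,
#'   `kind`, `protease`, `detectable`, and the best peptide's `sequence`,
#'   `start`, `end`, `missed_cleavages`, `mass`, `best_charge`, `best_mz`
#'   (`NA` when none).
#' @export
site_detectability_matrix <- function(proteins, sites,
                                      rules = list(protease_rule("trypsin_lysc"),
                                                   protease_rule("chymotrypsin")),
                                      max_missed = 5,
                                      config = detect_config(),
                                      label = "tmt") {
  empty <- tibble::tibble(
    accession = character(), position = integer(), kind = character(),
    protease = character(), detectable = logical(), sequence = character(),
    start = integer(), end = integer(), missed_cleavages = integer(),
    mass = double(), best_charge = integer(), best_mz = double()
  )
  if (nrow(sites) == 0) return(empty)
  res <- list()
  for (acc in unique(sites$accession)) {
    prot <- proteins[proteins$accession == acc, , drop = FALSE]
    if (nrow(prot) == 0) abort(sprintf("Site accession '%s' not in proteins.", acc))
    acc_sites <- sites[sites$accession == acc, , drop = FALSE]
    resi <- substring(prot$sequence[1], acc_sites$position, acc_sites$position)
    if (any(resi != "K")) abort(sprintf("Site not on K in '%s'.", acc))
    for (rule in rules) {
      peps <- digest(prot, rule, max_missed = max_missed,
                     site_mods = acc_sites[c("position", "kind")], label = label)
      peps$det <- detectable(nchar(peps$sequence), peps$mass, config)
      for (si in seq_len(nrow(acc_sites))) {
        pos <- acc_sites$position[si]
        cover <- peps[peps$start <= pos & peps$end >= pos & peps$det, , drop = FALSE]
        if (nrow(cover) > 0) {
          cover <- cover[order(cover$missed_cleavages, nchar(cover$sequence)), ]
          best <- cover[1, ]
          mzs <- mz(best$mass, config$charges)
          ok <- which(mzs >= config$mz_min & mzs <= config$mz_max)
          res[[length(res) + 1]] <- tibble::tibble(
            accession = acc, position = pos, kind = acc_sites$kind[si],
            protease = rule$name, detectable = TRUE,
            sequence = best$sequence, start = best$start, end = best$end,
            missed_cleavages = best$missed_cleavages, mass = best$mass,
            best_charge = as.integer(config$charges[ok[1]]),
            best_mz = mzs[ok[1]]
          )
        } else {
          res[[length(res) + 1]] <- tibble::tibble(
            accession = acc, position = pos, kind = acc_sites$kind[si],
            protease = rule$name, detectable = FALSE,
            sequence = NA_character_, start = NA_integer_, end = NA_integer_,
            missed_cleavages = NA_integer_, mass = NA_real_,
            best_charge = NA_integer_, best_mz = NA_real_
          )
        }
      }
    }
  }
  dplyr::bind_rows(res)
}
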