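mk_peptides <- function(seqs, mods, accs, ids = NULL) {
  ids <- ids %||% sprintf("pep%02d", seq_along(seqs))
  tibble::tibble(
    plex_id = "p", peptide_id = ids, sequence = seqs,
    modifications = parse_modifications(mods, seqs),
    accession = accs,
    n_methyl = vapply(parse_modifications(mods, seqs),
                      function(m) sum(m$kind %in% c("me1", "me2", "me3")),
                      integer(1))
  )
}

test_that("peptides map to protein site coordinates by exact matching", {
  proteins <- tibble::tibble(accession = "P1", sequence = "MAAAKAAAR")
  peps <- mk_peptides("AAKAAAR", "K3(me3)", "P1")
  sites <- map_peptide_to_sites(peps, proteins, protease = "trypsin_lysc")
  expect_equal(sites$position, 5L) # match at offset 3, mod at peptide pos 3
  expect_equal(sites$kind, "me3")
  expect_equal(sites$window, substr("MAAAKAAAR", 2, 8))
  # ambiguous placement in a repeat-containing protein is excluded
  prot_rep <- tibble::tibble(accession = "P2", sequence = "GGKAGGKAGG")
  peps2 <- mk_peptides("GKA", "K2(me1)", "P2")
  s2 <- map_peptide_to_sites(peps2, prot_rep)
  expect_equal(nrow(s2), 0)
  expect_equal(attr(s2, "mapping_report")$reason, "ambiguous_mapping")
  # no match is reported, not silently dropped
  peps3 <- mk_peptides("WWWKWWW", "K4(me1)", "P1")
  s3 <- map_peptide_to_sites(peps3, proteins)
  expect_equal(attr(s3, "mapping_report")$reason, "no_match_in_protein")
})

test_that("site aggregation counts protease overlap with set arithmetic", {
  sites <- tibble::tibble(
    accession = c("A", "A", "B", "B", "A"),
    position = c(5L, 9L, 3L, 3L, 5L),
    kind = c("me1", "me2", "me3", "me3", "me1"),
    plex_id = "x", peptide_id = paste0("q", 1:5),
    protease = c("trypsin_lysc", "trypsin_lysc", "trypsin_lysc",
                 "chymotrypsin", "chymotrypsin"),
    window = "AAAKAAA"
  )
  agg <- aggregate_sites(sites)
  s <- agg$summary
  pick <- function(lvl, ms) s$n[s$level == lvl & s$measure == ms]
  expect_equal(pick("site", "unique_to_trypsin_lysc"), 1) # A:9
  expect_equal(pick("site", "unique_to_chymotrypsin"), 0)
  expect_equal(pick("site", "shared"), 2)                 # A:5, B:3
  expect_equal(pick("site", "union"), 3)
  expect_equal(pick("site", "unique_to_trypsin_lysc") +
                 pick("site", "unique_to_chymotrypsin") +
                 pick("site", "shared"), pick("site", "union"))
  # same residue with different methyl states is two sites
  two_states <- dplyr::mutate(sites[c(1, 2), ], position = 5L,
                              kind = c("me1", "me3"))
  expect_equal(nrow(aggregate_sites(two_states)$sites), 2)
  # one protease only: shared 0
  solo <- aggregate_sites(sites[sites$protease == "trypsin_lysc", ])
  expect_equal(solo$summary$n[solo$summary$level == "site" &
                                solo$summary$measure == "shared"], 0)
})

test_that("7-mer windows pad past the termini and center on K", {
  expect_equal(window7("MKAAAAA", 2), "--MKAAA")
  expect_equal(window7("AAAKAAA", 4), "AAAKAAA")
  expect_equal(window7("AAAAAK", 6), "AAAK---")
  expect_equal(substr(window7("AAAKAAA", 4), 4, 4), "K")
  expect_error(window7("AAA", 9), "out of range")
})

test_that("K/R density counts windows and peptides differently", {
  d <- kr_density(c("AAAKAAA", "RKAKAKR"))
  expect_equal(d$n_kr, 0:4)
  expect_equal(d$fraction[d$n_kr == 0], 0.5)
  expect_equal(d$fraction[d$n_kr == 4], 0.5)
  expect_equal(sum(d$fraction), 1, tolerance = 1e-12)
  p <- kr_density("AKRGGK", mode = "peptide")
  expect_equal(p$n_kr[p$count == 1], 3L)
  expect_error(kr_density(character(0)), "empty")
  expect_error(kr_density("AAAWAAA"), "center")
})

test_that("motif matrix uses non-padding entries and sums to one", {
  mm <- motif_matrix(c("AAAKAAA", "AAAKAAA"))
  expect_true(all(mm$frequency == 1))
  expect_setequal(mm$position, setdiff(-3:3, 0))
  mm2 <- motif_matrix(c("--MKAAA", "AAMKAAA"))
  m3 <- mm2[mm2$position == -3, ]
  expect_equal(m3$residue, "A")       # padding excluded from the denominator
  expect_equal(m3$frequency, 1)
  sums <- tapply(mm2$frequency, mm2$position, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("novelty annotation supports state-agnostic and state-aware joins", {
  sites <- tibble::tibble(accession = c("P1", "P1", "P2"),
                          position = c(10L, 20L, 5L),
                          kind = c("me3", "me1", "me2"))
  known <- tibble::tibble(accession = "P1", position = 10L, kind = "me1")
  ann <- annotate_novelty(sites, known)
  expect_equal(ann$novel_site, c(FALSE, TRUE, TRUE))
  expect_equal(ann$novel_protein, c(FALSE, FALSE, TRUE))
  aware <- annotate_novelty(sites, known, state_aware = TRUE)
  expect_true(aware$novel_site[1]) # known me1, detected me3
  none <- annotate_novelty(sites, known[0, ])
  expect_true(all(none$novel_site))
})

test_that("variant joins are left joins with reference-residue checks", {
  sites <- tibble::tibble(accession = c("P1", "P2"), position = c(55L, 9L),
                          kind = c("me3", "me1"))
  variants <- tibble::tibble(
    accession = c("P1", "P1", "P3"), position = c(55L, 99L, 1L),
    ref_residue = c("K", "K", "R"), variant = c("p.Lys55Arg", "x", "y"),
    condition = "NDD", significance = "VUS"
  )
  j <- annotate_variants(sites, variants)
  expect_equal(nrow(j), 2)                       # left join on sites
  expect_equal(j$variant[j$accession == "P1"], "p.Lys55Arg")
  expect_true(is.na(j$variant[j$accession == "P2"]))
  bad <- dplyr::mutate(variants[1, ], ref_residue = "R")
  expect_warning(j2 <- annotate_variants(sites, bad), "non-K")
  expect_true(j2$ref_mismatch[1])
})

test_that("sites planted by the generator round-trip through digestion and mapping", {
  cfg <- sim_config(n_proteins = 25, n_sites = 20, decoy_fraction = 0,
                    ambiguous_true = 0, missing_rate = 0,
                    loc_score_true = c(200, 0.1), seed = 31)
  study <- simulate_study(cfg)
  proteins <- study$truth$proteins
  recovered <- list()
  for (nm in names(study$plex)) {
    peps <- study$plex[[nm]]$peptides
    peps <- peps[peps$n_methyl > 0, ]
    recovered[[nm]] <- map_peptide_to_sites(peps, proteins, protease = nm)
  }
  rec <- dplyr::bind_rows(recovered)
  key_rec <- unique(paste(rec$accession, rec$position, rec$kind))
  key_truth <- paste(study$truth$sites$accession, study$truth$sites$position,
                     study$truth$sites$kind)
  # every unambiguous mapped site is a planted site
  expect_true(all(key_rec %in% key_truth))
  # and planted sites observed in either arm are recovered exactly
  obs_keys <- unique(unlist(lapply(names(study$plex), function(nm) {
    obs <- study$plex[[nm]]$observed_sites
    tr <- study$truth$sites
    paste(tr$accession, tr$position, tr$kind)[match(obs$site_id, tr$site_id)]
  })))
  expect_gt(mean(obs_keys %in% key_rec), 0.9)
})
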