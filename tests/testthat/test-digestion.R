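trypsin <- protease_rule("trypsin_lysc")
chymo <- protease_rule("chymotrypsin")

test_that("digestion follows the combined trypsin/lys-C rule", {
  p <- tibble::tibble(accession = "P1", sequence = "MKRPAK")
  d <- digest(p, trypsin, max_missed = 0)
  # cleave after K2; R3 blocked by following P; K6 is the C-terminus
  expect_setequal(d$sequence, c("MK", "RPAK"))
  # lys-C cleaves K even before proline
  d2 <- digest(tibble::tibble(accession = "P2", sequence = "AKPAR"), trypsin, 0)
  expect_setequal(d2$sequence, c("AK", "PAR"))
})

test_that("methylated lysine blocks cleavage without counting as missed", {
  p <- tibble::tibble(accession = "P1", sequence = "AAKGGRAA")
  d <- digest(p, trypsin, max_missed = 0,
              site_mods = tibble::tibble(position = 3L, kind = "me3"))
  expect_setequal(d$sequence, c("AAKGGR", "AA"))
  expect_true(all(d$missed_cleavages == 0))
  expect_equal(d$n_methyl[d$sequence == "AAKGGR"], 1L)
  # per-state configurability: me1 cleavable when unblocked
  rule_me1_cuts <- protease_rule("trypsin_lysc",
                                 methyl_blocks = c(me1 = FALSE, me2 = TRUE,
                                                   me3 = TRUE))
  d3 <- digest(p, rule_me1_cuts, 0,
               site_mods = tibble::tibble(position = 3L, kind = "me1"))
  expect_setequal(d3$sequence, c("AAK", "GGR", "AA"))
})

test_that("missed cleavages enumerate all rule-consistent peptides", {
  p <- tibble::tibble(accession = "P1", sequence = "AKGKGA")
  d <- digest(p, trypsin, max_missed = 1)
  expect_setequal(d$sequence, c("AK", "GK", "GA", "AKGK", "GKGA"))
  expect_equal(sort(unique(d$missed_cleavages)), c(0L, 1L))
})

test_that("digest errors on invalid methyl placements", {
  p <- tibble::tibble(accession = "P1", sequence = "AAKGGRAA")
  expect_error(digest(p, trypsin, 0,
                      site_mods = tibble::tibble(position = 4L, kind = "me1")),
               "non-K")
  expect_error(digest(p, trypsin, 0,
                      site_mods = tibble::tibble(position = 99L, kind = "me1")),
               "out of range")
})

test_that("digest matches the brute-force enumeration oracle", {
  set.seed(202)
  for (i in 1:60) {
    seqn <- random_protein(sample(8:60, 1))
    kpos <- which(strsplit(seqn, "")[[1]] == "K")
    np <- if (length(kpos) > 0) sample(0:min(3, length(kpos)), 1) else 0
    sm <- if (np > 0) {
      tibble::tibble(position = sort(kpos[sample.int(length(kpos), np)]),
                     kind = sample(c("me1", "me2", "me3"), np, replace = TRUE))
    } else NULL
    for (rule in list(trypsin, chymo)) {
      mm <- sample(0:5, 1)
      d <- digest(tibble::tibble(accession = "X", sequence = seqn), rule, mm,
                  site_mods = sm)
      o <- oracle_digest(seqn, rule, mm, sm)
      expect_setequal(paste(d$start, d$end, d$missed_cleavages),
                      paste(o$start, o$end, o$missed))
    }
  }
})

test_that("digest coverage, monotonicity and methyl-terminus invariants hold", {
  set.seed(7)
  for (i in 1:20) {
    seqn <- random_protein(sample(20:60, 1))
    kpos <- which(strsplit(seqn, "")[[1]] == "K")
    sm <- if (length(kpos) > 0) {
      tibble::tibble(position = kpos[1], kind = "me2")
    } else NULL
    p <- tibble::tibble(accession = "X", sequence = seqn)
    d0 <- digest(p, trypsin, 0, site_mods = sm)
    # zero-missed peptides tile the protein exactly
    tile <- d0[d0$missed_cleavages == 0, ]
    expect_equal(paste(tile$sequence[order(tile$start)], collapse = ""), seqn)
    # peptide set grows monotonically with the missed-cleavage budget
    d1 <- digest(p, trypsin, 1, site_mods = sm)
    expect_true(all(paste(d0$start, d0$end) %in% paste(d1$start, d1$end)))
    # no peptide C-terminus at a methylated K except the protein terminus
    if (!is.null(sm)) {
      dd <- digest(p, trypsin, 3, site_mods = sm)
      internal_ends <- dd$end[dd$end < nchar(seqn)]
      expect_false(sm$position %in% internal_ends)
    }
  }
})

test_that("peptide mass follows monoisotopic arithmetic", {
  expect_equal(peptide_mass("G"), 75.032028, tolerance = 1e-5)
  base <- peptide_mass("AAKGGR")
  me1 <- peptide_mass("AAKGGR", tibble::tibble(position = 3L, kind = "me1"))
  me3 <- peptide_mass("AAKGGR", tibble::tibble(position = 3L, kind = "me3"))
  expect_equal(me1 - base, 14.015650)
  expect_equal(me3 - base, 3 * 14.015650)
  expect_error(peptide_mass("AXZ"), "Unknown residue")
})

test_that("isobaric label policy tags the N-terminus and unmethylated K only", {
  tag <- 304.207146
  plain <- peptide_mass("AAKGGK")
  labelled <- peptide_mass("AAKGGK", label = "tmt")
  expect_equal(labelled - plain, 3 * tag) # N-term + two K
  half <- peptide_mass("AAKGGK", tibble::tibble(position = 3L, kind = "me2"),
                       label = "tmt")
  expect_equal(half - plain, 2 * tag + 2 * 14.015650) # methylated K unlabeled
})

test_that("m/z arithmetic and monotonicity", {
  expect_equal(mz(1000, 2), 501.007276)
  expect_equal(mz(1000, 1), 1001.007276)
  zs <- 1:7
  expect_true(all(diff(mz(1234.5, zs)) < 0))
  expect_error(mz(1000, 0), "charge")
})

test_that("detectability window combines length and m/z rules", {
  cfg <- detect_config()
  expect_true(detectable(7, 1600, cfg))      # z = 2 puts m/z near 801
  expect_false(detectable(3, 400, cfg))      # below the length floor
  expect_false(detectable(80, 5000, cfg))    # above the length ceiling
  expect_false(detectable(40, 12000, cfg))   # no z in 2..7 reaches <= 1600
  expect_true(detectable(40, 12000, detect_config(charges = 2:12)))
})

test_that("site detectability captures the trypsin-invisible scenario", {
  filler <- paste(rep("A", 28), collapse = "")
  seqn <- paste0(filler, "F", "AGSA", "K", "STV", "F", filler)
  pos <- nchar(filler) + 6L
  proteins <- tibble::tibble(accession = "NVA", sequence = seqn)
  sites <- tibble::tibble(accession = "NVA", position = pos, kind = "me3")
  m <- site_detectability_matrix(proteins, sites)
  tryp <- m[m$protease == "trypsin_lysc", ]
  chy <- m[m$protease == "chymotrypsin", ]
  expect_false(tryp$detectable) # no K/R nearby: covering peptides too long
  expect_true(chy$detectable)   # aromatic-flanked 9-mer passes the window
  expect_equal(chy$sequence, "AGSAKSTVF")
  # empty site list -> empty table
  empty <- site_detectability_matrix(proteins, sites[0, ])
  expect_equal(nrow(empty), 0)
  expect_error(site_detectability_matrix(
    proteins, tibble::tibble(accession = "NVA", position = 2L, kind = "me1")),
    "not on K")
})
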