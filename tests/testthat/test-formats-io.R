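test_that("FASTA reading parses plain and UniProt headers", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MKAAR",
               ">sp|P62158|CALM_HUMAN Calmodulin", "MADQLTEEQK"), fa)
  prot <- read_protein_fasta(fa)
  expect_equal(prot$accession, c("P1", "P62158"))
  expect_equal(prot$sequence[1], "MKAAR")
  expect_equal(prot$description[2], "Calmodulin")
})

test_that("FASTA reader rejects bad input with informative errors", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MKBAR"), fa)
  expect_error(read_protein_fasta(fa), "B.*P1|P1.*B")
  writeLines(c(">P1", "MKA", ">P1", "MKA"), fa)
  expect_error(read_protein_fasta(fa), "Duplicate")
  writeLines(character(0), fa)
  expect_error(read_protein_fasta(fa))
  expect_error(read_protein_fasta(file.path(tempdir(), "nope.fasta")), "exist")
})

test_that("modification mini-grammar parses and validates", {
  m <- parse_modifications("K4(me3)", "AAAKAAA")[[1]]
  expect_equal(m$position, 4L)
  expect_equal(m$kind, "me3")
  m2 <- parse_modifications("K1(me1);K5(me2)", "KAAAK")[[1]]
  expect_equal(nrow(m2), 2)
  expect_equal(parse_modifications("M1(oxidation)", "MAAA")[[1]]$kind, "other")
  expect_equal(nrow(parse_modifications("", "AAA")[[1]]), 0)
  expect_equal(nrow(parse_modifications(NA_character_, "AAA")[[1]]), 0)
  expect_error(parse_modifications("K9(me1)", "AAAKAAA"), "out of range")
  expect_no_error(parse_modifications("K2(me1)", "AKAA")) # K at 2: fine
  expect_error(parse_modifications("K3(me1)", "AAGK"), "non-K")
  expect_error(parse_modifications("K4me3", "AAAKAAA"), "Unparseable")
})

test_that("quant tables resolve channels by design and keep missing distinct from zero", {
  design <- tiny_design()
  dir <- withr::local_tempdir()
  pep <- c("MAKAAAR", "K3(me3)", "P1", "0.95", "false",
           c("", as.character(2:12)))
  paths <- write_mini_tables(dir, design, pep_rows = list(pep))
  out <- read_quant_tables(paths$peptides, paths$proteins, design)
  expect_equal(nrow(out$peptides), 1)
  expect_true(is.na(out$peptides[[design$sample[1]]]))
  expect_false(any(out$peptides[[design$sample[1]]] %in% 0))
  expect_equal(out$peptides$n_methyl, 1L)
  expect_equal(out$peptides$modifications[[1]]$position, 3L)
  expect_equal(out$proteins$confidence, "high")
  expect_equal(out$proteins[[design$sample[12]]], 12000)
})

test_that("quant readers reject malformed tables", {
  design <- tiny_design()
  dir <- withr::local_tempdir()
  # missing channel column
  paths <- write_mini_tables(dir, design)
  bad_design <- study_design("plexA", "trypsin_lysc",
                             channels = paste0("ch", 1:12))
  expect_error(read_quant_tables(paths$peptides, paths$proteins, bad_design),
               "absent")
  # negative abundance
  pep <- c("MAKAAAR", "K3(me3)", "P1", "0.95", "false",
           c("-5", as.character(2:12)))
  paths2 <- write_mini_tables(file.path(dir, "b"), design, pep_rows = list(pep))
  expect_error(read_quant_tables(paths2$peptides, paths2$proteins, design),
               "Negative")
  # more than 5 modifications
  pep3 <- c("KAKAKAKAKAKA", paste(sprintf("K%d(me1)", seq(1, 11, 2)), collapse = ";"),
            "P1", "0.95", "false", as.character(1:12))
  paths3 <- write_mini_tables(file.path(dir, "c"), design, pep_rows = list(pep3))
  expect_error(read_quant_tables(paths3$peptides, paths3$proteins, design),
               "5 modifications")
})

test_that("column mapping decouples canonical names from export headers", {
  design <- tiny_design()
  dir <- withr::local_tempdir()
  header <- c("Annotated Sequence", "Modifications", "Master Protein",
              "ptmRS", "Ambig", design$channel)
  row <- c("MAKAAAR", "K3(me2)", "P1", "0.99", "true", as.character(1:12))
  pep_path <- file.path(dir, "pep.tsv")
  writeLines(c(paste(header, collapse = "\t"), paste(row, collapse = "\t")),
             pep_path)
  paths <- write_mini_tables(dir, design)
  out <- read_quant_tables(
    pep_path, paths$proteins, design,
    peptide_columns = list(sequence = "Annotated Sequence",
                           modifications = "Modifications",
                           accession = "Master Protein",
                           loc_score = "ptmRS", ambiguous = "Ambig")
  )
  expect_equal(out$peptides$loc_score, 0.99)
  expect_true(out$peptides$ambiguous)
})

test_that("annotation flat files parse into typed tables", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("S1\tdesc\tA\tB", "S2\tdesc\tB\tC\tD"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets$S1, c("A", "B"))
  expect_equal(length(sets$S2), 3)
  writeLines("S1\tdesc", gmt)
  expect_error(read_gmt(gmt), "fewer than 3")

  st <- file.path(dir, "sites.tsv")
  writeLines(c("accession\tposition\tkind", "P1\t116\tme3"), st)
  known <- read_site_table(st)
  expect_equal(known$position, 116L)
  writeLines(c("accession\tposition\tkind", "P1\tx\tme3"), st)
  expect_error(read_site_table(st), "integers")

  vt <- file.path(dir, "variants.tsv")
  writeLines(c(paste("accession", "position", "ref_residue", "variant",
                     "condition", "significance", sep = "\t"),
               "P1\t55\tK\tp.Lys55Arg\tNDD\tVUS"), vt)
  v <- read_variant_table(vt)
  expect_equal(v$variant, "p.Lys55Arg")
  expect_equal(v$position, 55L)
})

test_that("result writing is deterministic and round-trips values", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  tab <- tibble::tibble(
    feature_id = c("b", "a", "c"),
    value = c(1.23456789, NA, 3.14159265e-4),
    label = c("x", "y", "z")
  )
  write_results(list(res = tab), dir1, seed = 7, config = list(a = 1))
  write_results(list(res = tab), dir2, seed = 7, config = list(a = 1))
  expect_identical(readLines(file.path(dir1, "res.tsv")),
                   readLines(file.path(dir2, "res.tsv")))
  back <- readr::read_tsv(file.path(dir1, "res.tsv"),
                          show_col_types = FALSE)
  expect_equal(back$feature_id, c("a", "b", "c")) # sorted by first column
  expect_equal(sum(is.na(back$value)), 1)         # missing preserved, not 0
  expect_equal(back$value[2], signif(1.23456789, 6))
  manifest <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  expect_equal(manifest$seed, 7)
  expect_true(nzchar(manifest$config_hash))
  # empty result: header-only file, no error
  write_results(list(empty = tab[0, ]), dir1)
  expect_equal(length(readLines(file.path(dir1, "empty.tsv"))), 1)
})
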