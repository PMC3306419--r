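test_that("RGD and furin scanners match sliding-window brute force", {
  hits <- scan_rgd("AARGDNPA")
  expect_equal(hits$start, 2L)
  expect_equal(hits$end, 5L)
  f <- scan_furin("ARSKRG")
  expect_equal(f$start, 1L)
  expect_equal(f$end, 5L)
  # near-miss tetrapeptides reported in degraded fibrillin-3 termini
  expect_equal(nrow(scan_furin("RVWR")), 0L)
  expect_equal(nrow(scan_furin("SVRR")), 0L)
  expect_equal(nrow(scan_furin("RPPR")), 0L)
  # exhaustive 4-mers over {R, K, A}
  grid <- expand.grid(rep(list(c("R", "K", "A")), 4), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    s <- paste(unlist(grid[i, ]), collapse = "")
    expect_equal(nrow(scan_furin(s)), length(bf_furin(s)), info = s)
  }
  # scanner completeness on random strings
  set.seed(12)
  for (i in 1:40) {
    s <- random_aa(60)
    expect_equal(scan_rgd(s)$start, bf_rgd(s))
    expect_equal(scan_furin(s)$start, bf_furin(s))
  }
})

test_that("overlapping furin matches are all reported unless disabled", {
  s <- "RRRRR"
  expect_equal(scan_furin(s)$start, c(0L, 1L))
  expect_equal(scan_furin(s, overlapping = FALSE)$start, 0L)
  expect_equal(scan_furin("RRKRKR")$start, bf_furin("RRKRKR"))
})

test_that("hits are localized to their containing domains", {
  fam <- tiny_family()
  id <- fam$records$id[fam$records$isoform == "FBN2"][1]
  rec <- fam$records[fam$records$id == id, ]
  map <- fam$truth_maps[[id]]
  hits <- scan_rgd(rec, map)
  expect_equal(hits$domain, c("TB3", "TB4"))
  expect_equal(unique(hits$note), "between Cys1 and Cys2")
  # localization soundness: the named segment really contains the hit
  for (i in seq_len(nrow(hits))) {
    seg <- dplyr::filter(map, domain_id == hits$domain[i])
    expect_true(seg$start <= hits$start[i] && hits$end[i] <= seg$end)
  }
  # the edited lineage has no TB3 hit
  id1 <- fam$records$id[fam$records$isoform == "FBN1"][1]
  h1 <- scan_rgd(fam$records[fam$records$id == id1, ], fam$truth_maps[[id1]])
  expect_false("TB3" %in% h1$domain)
  # furin restriction to terminal domains
  fur <- scan_furin(rec, map, restrict_to_terminals = TRUE)
  expect_setequal(fur$domain, c("NTERM", "CTERM"))
})

test_that("terminal cysteine counts are 4 and 2, with missing reported as NA", {
  g <- generate_architecture(fibrillin1_profile(), seed = 2)
  tc <- terminal_cysteine_count(g$record, g$map)
  expect_equal(tc$n_term, 4L)
  expect_equal(tc$c_term, 2L)
  noct <- dplyr::filter(g$map, klass != "CTERM")
  tc2 <- terminal_cysteine_count(g$record, noct)
  expect_equal(tc2$n_term, 4L)
  expect_true(is.na(tc2$c_term))
})

test_that("homologous alignment columns report per-record variants", {
  msa <- as_protein_msa(c(a = "AARGDNPA", b = "AAKGDNPA", c = "AARGDNPA"))
  rep <- homologous_column_residues(msa, "a", 2L, 5L)
  expect_equal(rep$residues, c("RGD", "KGD", "RGD"))
  # identity alignment returns the reference substring
  expect_equal(rep$residues[rep$record == "a"], "RGD")
  # gap-aware extraction
  msa2 <- as_protein_msa(c(a = "AARGDNPA", b = "AAR-DNPA"))
  rep2 <- homologous_column_residues(msa2, "a", 2L, 5L)
  expect_equal(rep2$residues[rep2$record == "b"], "R-D")
  expect_error(homologous_column_residues(msa2, "zz", 0L, 2L), "not in")
  expect_error(homologous_column_residues(msa2, "a", 5L, 12L), "outside")
})

test_that("motif writers emit TSV and BED", {
  g <- generate_architecture(fibrillin2_profile(), seed = 3)
  hits <- scan_rgd(g$record, g$map)
  tsv <- tempfile(); bed <- tempfile()
  write_motif_tsv(hits, tsv)
  write_motif_bed(hits, bed)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 2L)
  bedl <- strsplit(readLines(bed)[1], "\t")[[1]]
  expect_equal(bedl[4], "RGD:TB3")
})
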