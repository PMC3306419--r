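test_that("calcium-binding consensus matching agrees with a brute-force
          enumerator over random windows", {
  hit <- match_cb_consensus("DIDECDAAAAYGSW")
  expect_equal(hit$start, 0L)
  expect_equal(hit$m, 1L)
  expect_equal(hit$n, 4L)
  # leading residue outside D/N breaks the strict match but not the relaxed
  expect_null(match_cb_consensus("GIDECDAAAAYGSW"))
  relaxed <- match_cb_consensus("GIDECDAAAAYGSW", strict = FALSE)
  expect_equal(relaxed$first_residue, "G")
  expect_error(match_cb_consensus("DID3C"), "non-amino-acid")
  set.seed(31)
  for (i in 1:60) {
    w <- random_aa(30)
    for (strict in c(TRUE, FALSE)) {
      mine <- match_cb_consensus(w, strict = strict)
      ref <- bf_cb_match(w, strict = strict)
      if (is.null(ref)) {
        expect_null(mine)
      } else {
        expect_equal(mine$start, unname(ref$start))
        expect_equal(mine$m, unname(ref$m))
        expect_equal(mine$n, unname(ref$n))
      }
    }
  }
})

test_that("segment classification follows the cysteine-signature rules", {
  seg_from <- function(klass) {
    tpl <- fibevo:::default_template(klass)
    r <- fibevo:::realize_template_checked(
      tpl, fibevo:::residue_weights(NULL), fibevo:::residue_weights(NULL),
      context = list(leading = FALSE, trailing = FALSE)
    )
    paste(r$chars, collapse = "")
  }
  set.seed(5)
  expect_equal(classify_segment(seg_from("TB"))$klass, "TB")
  expect_equal(classify_segment(seg_from("HYBRID8"))$klass, "HYBRID8")
  h9 <- classify_segment(seg_from("HYBRID9"))
  expect_equal(h9$klass, "HYBRID9")
  expect_match(h9$note, "extra Cys after Cys2")
  h10 <- classify_segment(seg_from("HYBRID10"))
  expect_equal(h10$klass, "HYBRID10")
  expect_match(h10$note, "Cys4a/Cys6a")
  cb <- seg_from("cbEGF")
  expect_equal(classify_segment(cb)$klass, "cbEGF")
  # mutating the leading consensus Asp turns cbEGF into cbEGF-like
  cbl <- cb
  substr(cbl, 4, 4) <- "A"
  cls <- classify_segment(cbl)
  expect_equal(cls$klass, "cbEGF_like")
  # unknown patterns are flagged, not errors
  bad <- classify_segment("ACACACACACACACACA")
  expect_equal(bad$klass, "UNKNOWN")
  expect_match(bad$note, "cysteine")
  expect_error(classify_segment(seg_from("TB"), cys_count = 6), "expected")
})

test_that("find_domains tiles the sequence and handles degenerate input", {
  set.seed(2)
  rec <- paste(sample(setdiff(AA20, "C"), 50, replace = TRUE), collapse = "")
  map <- find_domains(rec)
  expect_equal(nrow(map), 1L)
  expect_equal(map$klass, "GAP")
  expect_equal(map$end - map$start, 50L)
  expect_error(find_domains(""), "length")
  for (prof in list(fibrillin1_profile(), fibrillin3_profile(),
                    ancestral_profile(arthropod = TRUE))) {
    g <- generate_architecture(prof, seed = 19)
    m <- find_domains(g$record)
    expect_equal(sum(m$end - m$start), nchar(g$record$sequence))
    expect_true(all(diff(m$start) > 0))
    # every emitted segment's cysteine count matches its class
    seg <- dplyr::filter(m, !klass %in% c("GAP", "UNIQUE"))
    expect_equal(seg$ncys,
                 unname(fibevo:::DOMAIN_CYS_COUNT[seg$klass]))
  }
})

test_that("find_domains is a pure function of sequence and config", {
  g <- generate_architecture(fibrillin1_profile(), seed = 8)
  m1 <- find_domains(g$record)
  m2 <- find_domains(g$record)
  expect_identical(m1, m2)
})

test_that("a fibrillin-1-like record yields exactly seven TB domains", {
  g <- generate_architecture(fibrillin1_profile(), seed = 23)
  map <- find_domains(g$record)
  expect_equal(sum(map$klass == "TB"), 7L)
  expect_equal(sum(map$klass %in% c("HYBRID8", "HYBRID9")), 2L)
})

test_that("unique-region location follows the TB1 rule", {
  g <- generate_architecture(fibrillin1_profile(), seed = 4)
  map <- find_domains(g$record)
  seg <- locate_unique_region(map)
  tb1 <- which(map$klass == "TB")[1]
  expect_equal(seg$start, map$end[tb1])
  expect_equal(seg$klass, "UNIQUE")
  # threshold behaviour
  expect_null(suppressMessages(locate_unique_region(map, min_len = 1000L)))
  # invertebrate-like record: cbEGF-like occupies the position
  anc <- generate_architecture(ancestral_profile(), seed = 4)
  amap <- find_domains(anc$record)
  expect_null(suppressMessages(locate_unique_region(amap)))
  after <- amap$klass[which(amap$klass == "TB")[1] + 1:2]
  expect_equal(after, c("cbEGF_like", "cbEGF"))
  # no TB domain at all
  nomap <- find_domains("ACDDCAADDCAACDDCAADDCAAGG")
  expect_null(suppressMessages(locate_unique_region(nomap)))
})

test_that("annotation writers emit half-open TSV and GFF3", {
  g <- generate_architecture(fibrillin1_profile(), seed = 3)
  tsv <- tempfile(fileext = ".tsv")
  gff <- tempfile(fileext = ".gff3")
  write_annotation_tsv(g$map, tsv)
  write_annotation_gff3(g$map, gff)
  tab <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(tab), sum(g$map$klass != "GAP"))
  expect_equal(tab$start[1], 0L)
  lines <- readLines(gff)
  expect_equal(lines[1], "##gff-version 3")
  first <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(first[4]), 1L)  # GFF3 is 1-based closed
})
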