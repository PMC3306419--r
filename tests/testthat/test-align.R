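test_that("pairwise alignment is optimal against exhaustive enumeration", {
  params <- align_params()
  S <- fibevo:::substitution_matrix(params)
  self <- pairwise_align("ACDE", "ACDE", params)
  expect_equal(self$score, sum(diag(S[c("A", "C", "D", "E"),
                                      c("A", "C", "D", "E")])))
  expect_false(grepl("-", self$a_gapped))
  set.seed(3)
  for (i in 1:25) {
    a <- random_aa(sample(2:6, 1))
    b <- random_aa(sample(2:6, 1))
    got <- pairwise_align(a, b, params)
    ref <- bf_align_score(a, b, S, params$gap_open, params$gap_extend)
    expect_equal(got$score, ref, info = paste(a, b))
    # symmetry
    expect_equal(got$score, pairwise_align(b, a, params)$score)
    # gapped outputs degap to the inputs
    expect_equal(fibevo:::ungap(got$a_gapped), a)
    expect_equal(fibevo:::ungap(got$b_gapped), b)
  }
  expect_error(pairwise_align("", "ACD"), "non-empty")
})

test_that("progressive alignment satisfies the msa invariants", {
  fam <- tiny_family()
  msa <- progressive_msa(fam$records[1:3, ])
  expect_s3_class(msa, "protein_msa")
  expect_equal(length(unique(nchar(msa$seqs))), 1L)
  # ungap round trip
  for (id in msa$ids) {
    expect_equal(fibevo:::ungap(msa$seqs[[id]]),
                 fam$records$sequence[fam$records$id == id])
  }
  # identical records align without gap columns
  same <- tibble::tibble(id = c("x", "y", "z"),
                         sequence = rep(fam$records$sequence[1], 3))
  m2 <- progressive_msa(same)
  expect_false(any(grepl("-", m2$seqs, fixed = TRUE)))
  # two records reduce to pairwise_align
  two <- progressive_msa(fam$records[1:2, ])
  pw <- pairwise_align(fam$records$sequence[1], fam$records$sequence[2])
  expect_equal(unname(two$seqs), c(pw$a_gapped, pw$b_gapped))
  expect_error(progressive_msa(tibble::tibble(id = c("a", "a"),
                                              sequence = c("AC", "AD"))),
               "duplicate")
})

test_that("low-divergence families recover the ground-truth columns", {
  fam <- tiny_family()   # no indels: every truth column is the residue index
  msa <- progressive_msa(fam$records)
  expect_equal(msa$width, nchar(fam$records$sequence[1]))
  expect_false(any(grepl("-", msa$seqs, fixed = TRUE)))
})

test_that("gap-only column stripping is idempotent", {
  msa <- as_protein_msa(c(a = "AC-D", b = "AG-D"))
  s1 <- strip_gap_only_columns(msa)
  expect_equal(s1$width, 3L)
  expect_identical(strip_gap_only_columns(s1), s1)
  msa2 <- as_protein_msa(c(a = "ACD", b = "AGD"))
  expect_identical(strip_gap_only_columns(msa2)$seqs, msa2$seqs)
  set.seed(8)
  for (i in 1:10) {
    w <- sample(5:12, 1)
    rows <- vapply(1:3, function(j) {
      paste(sample(c(AA20, "-"), w, replace = TRUE), collapse = "")
    }, character(1))
    m <- as_protein_msa(setNames(rows, c("a", "b", "c")))
    once <- strip_gap_only_columns(m)
    expect_identical(strip_gap_only_columns(once)$seqs, once$seqs)
  }
})

test_that("domain slices span the reference coordinates", {
  fc <- family_concat()
  ref_map <- fc$ref_map
  tb4 <- dplyr::filter(ref_map, domain_id == "TB4")
  sl <- extract_domain_alignment(fc$msa, ref_map, "TB4")
  expect_equal(sl$width, tb4$end - tb4$start)
  expect_error(extract_domain_alignment(fc$msa, ref_map, "TB99"), "absent")
  # all-gap record is dropped under the gap threshold
  rows <- c(fc$msa$seqs[1:3], gappy = paste(rep("-", fc$msa$width),
                                            collapse = ""))
  m <- as_protein_msa(rows)
  sl2 <- suppressMessages(
    extract_domain_alignment(m, ref_map, "TB4", drop_gapped = TRUE)
  )
  expect_false("gappy" %in% sl2$ids)
  expect_equal(attr(sl2, "dropped"), "gappy")
})

test_that("concatenation sums widths and drops unshared records loudly", {
  fc <- family_concat()
  tb <- fc$ref_map$domain_id[fc$ref_map$klass == "TB"]
  slices <- lapply(tb, function(d) extract_domain_alignment(fc$msa, fc$ref_map, d))
  cc <- concatenate_alignments(slices)
  expect_equal(cc$width, sum(vapply(slices, function(s) s$width, numeric(1))))
  expect_identical(concatenate_alignments(slices[1])$seqs, slices[[1]]$seqs)
  # a record missing from one slice is dropped with a warning
  short <- slices
  short[[2]] <- as_protein_msa(short[[2]]$seqs[-1])
  expect_warning(cc2 <- concatenate_alignments(short), "dropped")
  expect_false(slices[[1]]$ids[1] %in% cc2$ids)
})

test_that("aligned FASTA round-trips through the readers", {
  fc <- family_concat()
  path <- tempfile(fileext = ".fasta")
  write_msa_fasta(fc$concat, path)
  back <- read_msa_fasta(path)
  expect_equal(back$seqs, fc$concat$seqs)
})
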