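test_that("residue frequencies match direct counts", {
  t1 <- residue_frequency("PPPP")
  expect_equal(t1$pct[t1$residue == "P"], 100)
  t2 <- residue_frequency("GGGGGPPPNN")
  expect_equal(t2$pct[t2$residue == "G"], 50)
  expect_equal(t2$pct[t2$residue == "P"], 30)
  expect_equal(t2$pct[t2$residue == "N"], 20)
  expect_error(residue_frequency(""), "non-empty")
  # independent tally on a random 200-mer
  set.seed(7)
  r <- random_aa(200)
  tab <- residue_frequency(r)
  counts <- table(factor(strsplit(r, "")[[1]], levels = sort(AA20)))
  expect_equal(tab$pct, as.numeric(100 * counts / 200))
  expect_equal(sum(tab$pct), 100, tolerance = 1e-9)
})

test_that("unknown characters count under X and leave the 100% base", {
  tab <- residue_frequency("PPPPZZ")
  expect_equal(tab$pct[tab$residue == "P"], 100)
  expect_equal(tab$count[tab$residue == "X"], 2L)
})

test_that("residue ranking handles exact ties", {
  mk <- function(vals) tibble::tibble(residue = names(vals), pct = vals)
  r1 <- rank_residues(mk(c(G = 50, P = 30, N = 20)))
  expect_equal(r1$most_common, "G")
  expect_equal(r1$second_most_common, "P")
  r2 <- rank_residues(mk(c(G = 40, L = 16, P = 16)))
  expect_equal(r2$second_most_common, "L & P")
  # tie at rank 1: joined pair, rank 2 moves to next distinct frequency
  r3 <- rank_residues(mk(c(G = 40, P = 40, L = 10)))
  expect_equal(r3$most_common, "G & P")
  expect_equal(r3$second_most_common, "L")
  # 20-way tie
  r4 <- rank_residues(mk(setNames(rep(5, 20), sort(AA20))))
  expect_equal(r4$most_common, paste(sort(AA20), collapse = " & "))
  expect_true(is.na(r4$second_most_common))
  # permutation invariance over equal-frequency residues
  v <- c(A = 30, G = 30, P = 25, L = 15)
  expect_equal(rank_residues(mk(v)), rank_residues(mk(rev(v))))
})

test_that("group summaries average per-sequence percentages", {
  g1 <- group_summary(tibble::tibble(group = "g", region = "GGP"))
  expect_equal(g1$most_pct, 200 / 3, tolerance = 1e-9)
  expect_equal(g1$gly_pro_ratio, 2)
  g2 <- group_summary(tibble::tibble(group = "g", region = c("GGGG", "PPPP")))
  tab <- g2$table[[1]]
  expect_equal(tab$pct[tab$residue == "G"], 50)
  expect_equal(tab$pct[tab$residue == "P"], 50)
  # summary of identical regions equals the single-region table
  g3 <- group_summary(tibble::tibble(group = "g", region = c("GGPL", "GGPL")))
  g4 <- group_summary(tibble::tibble(group = "g", region = "GGPL"))
  expect_equal(g3$table[[1]], g4$table[[1]])
  expect_equal(g3$most_common, g4$most_common)
  # zero proline flags an infinite ratio
  g5 <- group_summary(tibble::tibble(group = "g", region = "GGGG"))
  expect_true(is.infinite(g5$gly_pro_ratio))
  expect_error(group_summary(tibble::tibble(group = character(),
                                            region = character())),
               "no regions")
})

test_that("pooled mode pools residue counts", {
  g <- group_summary(tibble::tibble(group = "g", region = c("GGGG", "PP")),
                     pooled = TRUE)
  tab <- g$table[[1]]
  expect_equal(tab$pct[tab$residue == "G"], 100 * 4 / 6)
})
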