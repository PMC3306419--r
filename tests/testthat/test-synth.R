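test_that("domain templates enforce their cysteine grammar", {
  expect_error(domain_template("EGF", c(2, 3, 1, 4, 1, 2)), "7 gap lengths")
  tpl <- domain_template("EGF", c(2, 3, 1, 4, 1, 2, 2))
  expect_equal(length(fibevo:::template_cys_offsets(tpl)), 6L)
  expect_error(domain_template("TB", c(-1, rep(2, 8))), ">= 0")
  expect_error(domain_template("XXX", 1:3), "unknown domain class")
  expect_error(
    architecture_profile(list(domain_template("CTERM", c(8, 2, 16)),
                              domain_template("EGF", c(2, 3, 1, 4, 1, 2, 2))),
                         isoform = "x"),
    "CTERM"
  )
})

test_that("a single-EGF profile places exactly six templated cysteines", {
  prof <- architecture_profile(
    list(domain_template("EGF", c(2, 3, 1, 4, 1, 2, 2))), isoform = "mini"
  )
  g <- generate_architecture(prof, seed = 1)
  chars <- strsplit(g$record$sequence, "")[[1]]
  expect_equal(which(chars == "C") - 1L,
               fibevo:::template_cys_offsets(prof$templates[[1]]))
  expect_equal(nchar(g$record$sequence), 21L)
})

test_that("payload motifs land strictly between the flanking cysteines", {
  g <- generate_architecture(fibrillin2_profile(), seed = 9)
  hits <- scan_rgd(g$record, g$map)
  expect_equal(hits$domain, c("TB3", "TB4"))
  for (i in seq_len(nrow(hits))) {
    seg <- dplyr::filter(g$map, domain_id == hits$domain[i])
    cys <- seg$cys[[1]]
    expect_gt(hits$start[i], cys[1])
    expect_lt(hits$end[i] - 1L, cys[2])
  }
})

test_that("generation is seed-deterministic", {
  a <- generate_architecture(fibrillin1_profile(), seed = 77)
  b <- generate_architecture(fibrillin1_profile(), seed = 77)
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$map, b$map)
  c <- generate_architecture(fibrillin1_profile(), seed = 78)
  expect_false(identical(a$record$sequence, c$record$sequence))
})

test_that("zero-length branches and no edits reproduce the root at every tip", {
  g <- generate_architecture(fibrillin1_profile(), seed = 5, id = "root")
  nwk <- "((a:0,b:0)x:0,(c:0,d:0)y:0)r;"
  fam <- evolve_family(g, script = event_script(nwk), seed = 2)
  expect_true(all(fam$records$sequence == g$record$sequence))
})

test_that("family evolution is byte-identical under a fixed seed", {
  f1 <- simulate_fibrillin_family(seed = 13, n_species = 2)
  f2 <- simulate_fibrillin_family(seed = 13, n_species = 2)
  expect_identical(f1$records, f2$records)
  expect_identical(lapply(f1$truth_maps, as.data.frame),
                   lapply(f2$truth_maps, as.data.frame))
})

test_that("scripted RGD edits appear only on the targeted lineage", {
  fam <- tiny_family()
  for (id in fam$records$id) {
    rec <- fam$records[fam$records$id == id, ]
    hits <- scan_rgd(rec, fam$truth_maps[[id]])
    iso <- rec$isoform
    if (iso %in% c("FBN", "FBN2")) {
      expect_setequal(hits$domain, c("TB3", "TB4"))
    } else {
      # fibrillin-1 lost the TB3 site (RGE), fibrillin-3 degraded it (RAD)
      expect_equal(hits$domain, "TB4")
    }
  }
  ed <- fam$events[fam$events$type == "motif_sub", ]
  expect_setequal(ed$node, c("anc_FBN1", "anc_FBN3"))
})

test_that("edits referencing absent domains or payloads are configuration
          errors", {
  g <- generate_architecture(fibrillin1_profile(), seed = 6)
  nwk <- "((a:0.01,b:0.01)x:0.01,(c:0.01,d:0.01)y:0.01)r;"
  bad1 <- event_script(nwk, edits = tibble::tibble(
    node = "a", type = "motif_sub", domain = "TB9", from = "RGD", to = "RGE"
  ))
  expect_error(evolve_family(g, script = bad1, seed = 1), "missing domain")
  bad2 <- event_script(nwk, edits = tibble::tibble(
    node = "a", type = "motif_sub", domain = "TB2", from = "RGD", to = "RGE"
  ))
  expect_error(evolve_family(g, script = bad2, seed = 1), "no RGD payload")
  expect_error(event_script(nwk, duplications = "nope"), "not in tree")
})

test_that("cysteine counts per domain are conserved without scripted edits", {
  g <- generate_architecture(fibrillin1_profile(), seed = 30, id = "root")
  nwk <- "((a:0.15,b:0.15)x:0.15,(c:0.15,d:0.15)y:0.15)r;"
  fam <- evolve_family(g, script = event_script(nwk), seed = 3)
  for (id in fam$records$id) {
    m <- fam$truth_maps[[id]]
    chars <- strsplit(fam$records$sequence[fam$records$id == id], "")[[1]]
    for (i in seq_len(nrow(m))) {
      n_obs <- sum(chars[seq(m$start[i] + 1L, m$end[i])] == "C")
      expect_equal(n_obs, m$ncys[i])
    }
  }
})

test_that("branch substitution rates match the model expectation", {
  g <- generate_architecture(fibrillin1_profile(), seed = 50, id = "root")
  model <- jtt_model()
  t <- 0.05
  # two nested duplications, six tips
  nwk <- sprintf(
    "((a:%g,b:%g)d1:%g,((c:%g,d:%g)d2:%g,(e:%g,f:%g)x:%g)y:%g)r;",
    t, t, t, t, t, t, t, t, t, t
  )
  fam <- evolve_family(g, script = event_script(nwk, duplications = c("d1", "d2")),
                       model = model, seed = 8)
  root_chars <- strsplit(g$record$sequence, "")[[1]]
  prot <- fibevo:::protected_positions(
    root_chars, g$map, fibevo:::rescan_payloads(root_chars, g$map)
  )
  free <- setdiff(seq_along(root_chars), prot + 1L)
  P <- transition_matrix(model, t)
  # compare a tip two branches from the root against the doubled expectation
  tip <- strsplit(fam$records$sequence[fam$records$id == "a"], "")[[1]]
  P2 <- transition_matrix(model, 2 * t)
  states <- match(root_chars[free], fibevo:::AA_ALPHABET)
  expected <- mean(1 - diag(P2)[states])
  observed <- mean(tip[free] != root_chars[free])
  se <- sqrt(expected * (1 - expected) / length(free))
  expect_lt(abs(observed - expected), 3 * se + 0.01)
})

test_that("the unique-region swap exchanges architectures in both directions", {
  g <- generate_architecture(fibrillin1_profile(), seed = 61, id = "root")
  nwk <- "((a:0.01,b:0.01)x:0.01,(c:0.01,d:0.01)y:0.01)r;"
  sc <- event_script(nwk, edits = tibble::tibble(
    node = "a", type = "unique_swap", domain = "UNIQUE",
    from = NA_character_, to = NA_character_
  ))
  fam <- evolve_family(g, script = sc, seed = 4)
  ma <- fam$truth_maps[["a"]]
  expect_false("UNIQUE" %in% ma$klass)
  tb1 <- which(ma$klass == "TB")[1]
  expect_equal(ma$klass[tb1 + 1:2], c("cbEGF_like", "cbEGF"))
  # the swapped record still scans exactly
  rec <- fam$records[fam$records$id == "a", ]
  sc2 <- find_domains(rec)
  expect_equal(sc2$klass, ma$klass)
  expect_equal(sc2$start, ma$start)
  # untouched sibling keeps the unique region
  expect_true("UNIQUE" %in% fam$truth_maps[["b"]]$klass)
})

test_that("family writers produce FASTA, TSV, and Newick artifacts", {
  fam <- tiny_family()
  dir <- tempfile()
  write_family(fam, dir)
  expect_setequal(list.files(dir),
                  c("records.fasta", "truth_maps.tsv", "truth_tree.nwk",
                    "events.tsv"))
  back <- read_fasta(file.path(dir, "records.fasta"))
  expect_equal(back$id, fam$records$id)
  expect_equal(back$sequence, fam$records$sequence)
  tr <- ape::read.tree(file.path(dir, "truth_tree.nwk"))
  expect_setequal(tr$tip.label, fam$records$id)
})
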