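test_that("ML pairwise distances match a fine grid search and behave
          monotonically", {
  m <- jtt_model()
  a <- random_aa(120)
  expect_lt(ml_pairwise_distance(a, a, m)$distance, 1e-3)
  set.seed(21)
  for (i in 1:5) {
    x <- random_aa(150)
    y <- strsplit(x, "")[[1]]
    flip <- sample(150, 30)
    y[flip] <- vapply(y[flip], function(r) sample(setdiff(AA20, r), 1), "")
    y <- paste(y, collapse = "")
    got <- ml_pairwise_distance(x, y, m)
    # independent grid-search oracle at 1e-4 resolution
    sa <- match(strsplit(x, "")[[1]], AA20)
    sb <- match(strsplit(y, "")[[1]], AA20)
    obj <- function(t) {
      P <- transition_matrix(m, t)
      sum(log(m$pi[sa] * P[cbind(sa, sb)]))
    }
    grid <- seq(1e-4, 2, by = 1e-4)
    ref <- grid[which.max(vapply(grid, obj, numeric(1)))]
    expect_lt(abs(got$distance - ref), 2e-4)
    expect_false(got$saturated)
  }
  # monotonicity: more differing sites, larger distance
  x <- random_aa(200)
  prev <- 0
  chars <- strsplit(x, "")[[1]]
  set.seed(4)
  flip_order <- sample(200)
  for (k in c(20, 60, 100)) {
    y <- chars
    idx <- flip_order[1:k]
    y[idx] <- vapply(chars[idx], function(r) sample(setdiff(AA20, r), 1), "")
    d <- ml_pairwise_distance(x, paste(y, collapse = ""), m)$distance
    expect_gte(d, prev)
    prev <- d
  }
  # gap handling: pairwise deletion, missing flag with no shared columns
  g <- ml_pairwise_distance("AC--", "--CD", m)
  expect_true(is.na(g$distance))
  expect_equal(g$shared, 0L)
})

test_that("neighbor joining solves the 3-taxon closed form and recovers
          additive trees exactly", {
  D3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(D3)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  pl <- path_length_matrix(tr)[letters[1:3], letters[1:3]]
  expect_equal(unname(pl), unname(D3), tolerance = 1e-12)
  # additive matrices from random trees, n <= 8
  set.seed(9)
  for (n in c(4, 5, 8)) {
    for (rep in 1:5) {
      true <- ape::rtree(n, br = function(k) runif(k, 0.2, 1))
      true <- ape::unroot(true)
      D <- path_length_matrix(true)
      got <- neighbor_joining(D)
      expect_equal(path_length_matrix(got)[rownames(D), colnames(D)], D,
                   tolerance = 1e-10)
      expect_equal(sort(names(fibevo:::tree_splits(got))),
                   sort(names(fibevo:::tree_splits(true))))
    }
  }
  expect_error(neighbor_joining(D3[1:2, 1:2]), ">= 3")
  D3na <- D3; D3na[1, 2] <- D3na[2, 1] <- NA
  expect_error(neighbor_joining(D3na), "incomplete")
})

test_that("pruning likelihood equals exhaustive state enumeration", {
  m <- jtt_model()
  mI <- jtt_model(p_inv = 0.3)
  set.seed(14)
  phy <- ape::read.tree(text = "((a:0.2,b:0.15):0.1,(c:0.3,d:0.05):0.2);")
  seqs <- setNames(vapply(1:4, function(i) random_aa(3), ""), letters[1:4])
  seqs["b"] <- seqs["a"]   # include a constant-ish pattern
  msa <- as_protein_msa(seqs)
  for (model in list(m, mI)) {
    mine <- log_likelihood(phy, msa, model)
    ref <- bf_tree_loglik(phy, as.list(seqs), model)
    if (model$p_inv > 0) {
      # add the invariant mixture to the enumeration oracle per site
      sites <- vapply(1:3, function(s) {
        one <- lapply(seqs, function(x) substr(x, s, s))
        lv <- bf_tree_loglik(phy, one, jtt_model())
        con <- length(unique(unlist(one))) == 1L
        pc <- if (con) model$pi[match(one[[1]], AA20)] else 0
        log(model$p_inv * pc + (1 - model$p_inv) * exp(lv))
      }, numeric(1))
      ref <- sum(sites)
    }
    expect_lt(abs(as.numeric(mine) - ref), 1e-10)
  }
})

test_that("likelihood is invariant under rerooting (pulley principle)", {
  fc <- family_concat()
  m <- jtt_model(p_inv = 0.1, alpha = 1)
  small <- as_protein_msa(fc$concat$seqs[1:6])
  D <- protein_distance_matrix(small)
  tr <- neighbor_joining(D)
  l0 <- as.numeric(log_likelihood(tr, small, m))
  for (og in list(small$ids[1], small$ids[2:3])) {
    rr <- tryCatch(reroot_at_clade(tr, og), error = function(e) NULL)
    if (is.null(rr)) next
    l1 <- as.numeric(log_likelihood(rr, small, m))
    expect_lt(abs(l0 - l1), 1e-8)
  }
})

test_that("the cached edge objective agrees with the full likelihood", {
  fc <- family_concat()
  m <- jtt_model(alpha = 0.8, p_inv = 0.1)
  small <- as_protein_msa(fc$concat$seqs[1:5])
  D <- protein_distance_matrix(small)
  phy <- fibevo:::as_postorder(neighbor_joining(D))
  pd <- fibevo:::prep_patterns(small, phy$tip.label)
  full <- fibevo:::tree_ll(phy, pd, m)
  fl <- fibevo:::edge_flows(phy, pd, m)
  pc <- fibevo:::pconst_of(pd$conststate, m)
  for (e in seq_len(nrow(phy$edge))) {
    at_t <- fibevo:::cpp_edge_loglik(
      fl$Z, fl$ls, e - 1L, ncol(pd$states), m$n_categories, pd$weights,
      m$eig$lambda, m$rates, m$cat_weights, m$p_inv, pc,
      phy$edge.length[e]
    )
    expect_lt(abs(at_t - full), 1e-8)
  }
})

test_that("bootstrap replicates are seeded and multinomial", {
  msa <- as_protein_msa(c(a = "A", b = "C"))
  rep1 <- bootstrap_replicates(msa, 1, seed = 1)
  expect_identical(rep1[[1]]$seqs, msa$seqs)
  fc <- family_concat()
  r1 <- bootstrap_replicates(fc$concat, 3, seed = 5)
  r2 <- bootstrap_replicates(fc$concat, 3, seed = 5)
  r3 <- bootstrap_replicates(fc$concat, 3, seed = 6)
  expect_identical(r1[[2]]$seqs, r2[[2]]$seqs)
  expect_false(identical(r1[[1]]$seqs, r3[[1]]$seqs))
  # column multiplicities: each column expected once per replicate
  B <- 2000
  idx <- fibevo:::bootstrap_indices(10, B, seed = 2)
  counts <- tabulate(idx, nbins = 10)
  expect_true(all(abs(counts / B - 1) < 3 * sqrt(0.9 / B)))
})

test_that("majority consensus counts bipartitions correctly", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  cons <- majority_consensus(list(t1, t1, t1))
  expect_equal(sort(names(fibevo:::tree_splits(cons))),
               sort(names(fibevo:::tree_splits(t1))))
  expect_true(all(fibevo:::tree_splits(cons) == 100))
  # 50/50 conflict collapses to a star
  ta <- ape::read.tree(text = "((a,b),(c,d));")
  tb <- ape::read.tree(text = "((a,c),(b,d));")
  star <- majority_consensus(list(ta, tb))
  expect_equal(length(fibevo:::tree_splits(star)), 0L)
  # supports equal brute-force counting (ape::prop.part as oracle)
  set.seed(33)
  trees <- lapply(1:20, function(i) ape::rtree(6, tip.label = letters[1:6]))
  cons2 <- majority_consensus(trees)
  pp <- ape::prop.part(trees)
  labels <- attr(pp, "labels")
  sp <- fibevo:::tree_splits(cons2)
  sides <- attr(sp, "sides")
  for (key in names(sp)) {
    side <- sides[[key]]
    hit <- which(vapply(pp, function(p) {
      s1 <- sort(labels[p])
      identical(s1, side) || identical(sort(setdiff(labels, s1)), side)
    }, logical(1)))
    expect_equal(unname(sp[key]), 100 * attr(pp, "number")[hit[1]] / 20)
  }
  expect_error(majority_consensus(list(ta, ape::rtree(3))), "identical tip")
  expect_error(majority_consensus(list(ta, tb), threshold = 0.3), ">= 0.5")
})

test_that("clade support returns NA for absent partitions and errors on
          unknown taxa", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  cons <- majority_consensus(list(t1, t1))
  expect_equal(clade_support(cons, c("a", "b")), 100)
  expect_equal(clade_support(cons, c("c", "d", "e")), 100)
  expect_true(is.na(clade_support(cons, c("a", "c"))))
  expect_error(clade_support(cons, c("a", "zz")), "unknown")
})

test_that("rerooting preserves the bipartition set and supports", {
  fc <- family_concat()
  bs <- nj_bootstrap(fc$concat, B = 25, seed = 3)
  cons <- bs$consensus
  fbn <- grep("_FBN$", cons$tip.label, value = TRUE)
  rr <- reroot_at_clade(cons, fbn)
  expect_true(ape::is.rooted(rr))
  expect_equal(sort(names(fibevo:::tree_splits(rr))),
               sort(names(fibevo:::tree_splits(cons))))
  sp0 <- fibevo:::tree_splits(cons)
  sp1 <- fibevo:::tree_splits(rr)
  expect_equal(unname(sp1[names(sp0)]), unname(as.numeric(sp0)))
  # reroot on a single tip makes it the outgroup
  one <- reroot_at_clade(bs$tree, cons$tip.label[1])
  expect_true(ape::is.rooted(one))
  # rerooting twice on different clades keeps the unrooted topology
  two <- reroot_at_clade(one, fbn)
  expect_equal(sort(names(fibevo:::tree_splits(two))),
               sort(names(fibevo:::tree_splits(bs$tree))))
  mixed <- c(grep("_FBN$", cons$tip.label, value = TRUE)[1],
             grep("FBN3", cons$tip.label, value = TRUE)[1])
  expect_error(reroot_at_clade(cons, mixed), "not a bipartition")
})

test_that("NNI search recovers the 4-taxon topology from wrong starts", {
  m <- jtt_model()
  g <- generate_architecture(
    architecture_profile(replicate(12, fibevo:::default_template("EGF"),
                                   simplify = FALSE), isoform = "toy"),
    seed = 3, id = "root"
  )
  truth <- "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);"
  fam <- evolve_family(g, script = event_script(truth), seed = 10)
  msa <- as_protein_msa(setNames(fam$records$sequence, fam$records$id))
  # exhaustive 3-topology oracle
  tops <- c("((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);",
            "((A:0.1,C:0.1):0.1,(B:0.1,D:0.1):0.1);",
            "((A:0.1,D:0.1):0.1,(B:0.1,C:0.1):0.1);")
  lls <- vapply(tops, function(t) {
    optimize_branch_lengths(ape::read.tree(text = t), msa, m)$loglik
  }, numeric(1))
  expect_equal(which.max(lls), 1L, ignore_attr = TRUE)
  truth_key <- names(fibevo:::tree_splits(ape::read.tree(text = tops[1])))
  for (wrong in tops[2:3]) {
    fit <- nni_search(ape::read.tree(text = wrong), msa, m)
    expect_equal(names(fibevo:::tree_splits(fit$tree)), truth_key)
    # log-likelihood is non-decreasing across accepted moves
    expect_true(all(diff(fit$trace$loglik) > 0))
    expect_lt(abs(fit$loglik - max(lls)), 0.5)
  }
  # starting at the truth, no move is accepted
  fit0 <- nni_search(ape::read.tree(text = tops[1]), msa, m)
  expect_equal(nrow(fit0$trace), 1L)
})

test_that("AIC ranking normalises weights and prefers rate heterogeneity
          when it is simulated", {
  fc <- family_concat()
  small <- as_protein_msa(fc$concat$seqs[1:6])
  tr <- neighbor_joining(protein_distance_matrix(small))
  aic <- aic_select(small, tr, models = c("JTT", "JTT+G"))
  expect_equal(sum(aic$weight, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_true(all(aic$AIC == 2 * aic$k - 2 * aic$loglik))
  # duplicated single candidate: dAIC = 0, weight 1
  dup <- aic_select(small, tr, models = c("JTT", "JTT"))
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$delta_AIC, 0)
  expect_equal(dup$weight, 1)
  expect_error(aic_select(small, tr, models = "WAG"), "unknown")
})

test_that("strong rate heterogeneity favours a gamma model", {
  # simulate with per-site rates drawn from a gamma(0.3) mixture
  g <- generate_architecture(
    architecture_profile(replicate(18, fibevo:::default_template("cbEGF"),
                                   simplify = FALSE), isoform = "toy"),
    seed = 8, id = "root"
  )
  m <- jtt_model()
  rates <- fibevo:::discrete_gamma_rates(0.3, 4)
  set.seed(77)
  nwk <- "((a:0.4,b:0.4):0.2,(c:0.4,d:0.4):0.2);"
  # evolve each category block separately by scaling branch lengths
  chars <- strsplit(g$record$sequence, "")[[1]]
  n <- length(chars)
  cat_of <- sample(1:4, n, replace = TRUE)
  tips <- NULL
  for (k in 1:4) {
    nwk_k <- gsub("0.4", format(0.4 * rates[k]), gsub("0.2", format(0.2 * rates[k]), nwk))
    famk <- evolve_family(g, script = event_script(nwk_k), seed = 100 + k)
    mk <- do.call(rbind, strsplit(famk$records$sequence, ""))
    rownames(mk) <- famk$records$id
    if (is.null(tips)) tips <- mk
    tips[, cat_of == k] <- mk[, cat_of == k]
  }
  msa <- as_protein_msa(setNames(apply(tips, 1, paste, collapse = ""),
                                 rownames(tips)))
  tr <- neighbor_joining(protein_distance_matrix(msa))
  aic <- aic_select(msa, tr, models = c("JTT", "JTT+G", "JTT+I+G"))
  best <- aic$model[which.min(aic$AIC)]
  expect_true(grepl("G", best))
})
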