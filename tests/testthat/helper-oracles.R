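# independent brute-force oracles used across the suite

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_aa <- function(n, exclude = character()) {
  paste(sample(setdiff(AA20, exclude), n, replace = TRUE), collapse = "")
}

# exhaustive global affine-gap alignment score by enumeration over all
# alignments (gap of length L costs open + ext * L); strings <= 6
bf_align_score <- function(a, b, S, open, ext) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(ac) && j > length(bc)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ac) && j <= length(bc)) {
      rec(i + 1, j + 1, score + S[ac[i], bc[j]], 0L)
    }
    if (i <= length(ac)) {
      pen <- if (state == 1L) ext else open + ext
      rec(i + 1, j, score - pen, 1L)
    }
    if (j <= length(bc)) {
      pen <- if (state == 2L) ext else open + ext
      rec(i, j + 1, score - pen, 2L)
    }
  }
  rec(1L, 1L, 0, 0L)
  best
}

# regex-based calcium-binding consensus enumerator (leftmost, shortest m
# then n), strict or relaxed first position
bf_cb_match <- function(window, m_bounds = c(0, 4), n_bounds = c(2, 12),
                        strict = TRUE) {
  hits <- list()
  for (m in m_bounds[1]:m_bounds[2]) {
    for (n in n_bounds[1]:n_bounds[2]) {
      head <- if (strict) "[DN]" else "."
      pat <- sprintf("%s.[DN][EQ].{%d}[DN].{%d}[YF]", head, m, n)
      g <- gregexpr(pat, window)[[1]]
      if (g[1] != -1) {
        for (p in as.integer(g)) {
          hits <- c(hits, list(c(start = p - 1L, m = m, n = n)))
        }
      }
    }
  }
  if (!length(hits)) return(NULL)
  h <- do.call(rbind, hits)
  h <- h[order(h[, "start"], h[, "m"], h[, "n"]), , drop = FALSE]
  as.list(h[1, ])
}

# sliding-window motif scans
bf_rgd <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 3) return(integer())
  i <- seq_len(n - 2)
  which(chars[i] == "R" & chars[i + 1] == "G" & chars[i + 2] == "D") - 1L
}

bf_furin <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 4) return(integer())
  i <- seq_len(n - 3)
  which(chars[i] == "R" & chars[i + 2] %in% c("K", "R") &
          chars[i + 3] == "R") - 1L
}

# path-length (patristic) distances of a phylo tree
path_length_matrix <- function(phy) {
  D <- ape::dist.nodes(phy)[seq_along(phy$tip.label), seq_along(phy$tip.label)]
  dimnames(D) <- list(phy$tip.label, phy$tip.label)
  D
}

# brute-force pruning oracle: sum over all internal-node state assignments
bf_tree_loglik <- function(phy, seqs, model) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  states <- lapply(seqs[phy$tip.label], function(s) {
    match(strsplit(s, "")[[1]], AA20)
  })
  nsite <- length(states[[1]])
  Pm <- lapply(seq_len(nrow(phy$edge)), function(e) {
    transition_matrix(model, phy$edge.length[e])
  })
  root <- phy$edge[nrow(phy$edge), 1]
  internals <- sort(unique(phy$edge[phy$edge[, 1] > ntip, 1]))
  internals <- sort(unique(phy$edge[, 1]))
  total <- 0
  for (site in seq_len(nsite)) {
    grid <- expand.grid(rep(list(1:20), length(internals)))
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(node) {
        if (node <= ntip) states[[node]][site]
        else grid[g, match(node, internals)]
      }
      p <- model$pi[assign_state(root)]
      for (e in seq_len(nrow(phy$edge))) {
        u <- assign_state(phy$edge[e, 1])
        v <- assign_state(phy$edge[e, 2])
        p <- p * Pm[[e]][u, v]
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# small simulated family shared across tests (cached per session)
tiny_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_fibrillin_family(seed = 42, n_species = 2,
                                          branch_length = 0.08)
    }
    cache
  }
})

family_concat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fam <- tiny_family()
      msa <- progressive_msa(fam$records)
      ref_map <- fam$truth_maps[[fam$records$id[1]]]
      tb <- ref_map$domain_id[ref_map$klass == "TB"]
      slices <- lapply(tb, function(d) extract_domain_alignment(msa, ref_map, d))
      cache <<- list(family = fam, msa = msa, ref_map = ref_map,
                     concat = concatenate_alignments(slices))
    }
    cache
  }
})
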