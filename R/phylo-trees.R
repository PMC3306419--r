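# Bipartition bookkeeping: majority-rule consensus with supports, clade
# support lookup, and rerooting that preserves per-bipartition supports.

# reorder to postorder regardless of a (possibly stale) "order" attribute
as_postorder <- function(phy) {
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "postorder")
}

# canonical key of a bipartition: the side not containing the reference tip
# (the lexicographically smallest label), sorted and collapsed
split_key <- function(side, all_tips) {
  ref <- min(all_tips)
  if (ref %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = "\r")
}

# non-trivial bipartitions of a tree: named numeric (support or NA), names
# are canonical keys; attribute "sides" holds the tip sets
tree_splits <- function(phy, use_labels = TRUE) {
  ntip <- length(phy$tip.label)
  phy <- as_postorder(phy)
  below <- vector("list", ntip + phy$Nnode)
  for (tip in seq_len(ntip)) below[[tip]] <- phy$tip.label[tip]
  for (e in seq_len(nrow(phy$edge))) {
    u <- phy$edge[e, 1]; v <- phy$edge[e, 2]
    below[[u]] <- c(below[[u]], below[[v]])
  }
  keys <- character(); supports <- numeric(); sides <- list()
  root <- phy$edge[nrow(phy$edge), 1]
  for (e in seq_len(nrow(phy$edge))) {
    v <- phy$edge[e, 2]
    if (v <= ntip) next
    size <- length(below[[v]])
    if (size < 2L || size > ntip - 2L) next
    key <- split_key(below[[v]], phy$tip.label)
    if (key %in% keys) next
    keys <- c(keys, key)
    sides <- c(sides, list(sort(below[[v]])))
    sup <- NA_real_
    if (use_labels && !is.null(phy$node.label)) {
      lab <- phy$node.label[v - ntip]
      if (!is.null(lab) && !is.na(lab) && nzchar(lab)) {
        sup <- suppressWarnings(as.numeric(lab))
      }
    }
    supports <- c(supports, sup)
  }
  names(supports) <- keys
  attr(supports, "sides") <- setNames(sides, keys)
  supports
}

#' Majority-rule consensus with bootstrap supports
#'
#' Keeps the bipartitions present in strictly more than `threshold` of the
#' trees; the support of each retained bipartition is the percentage of
#' trees containing it. Bipartitions above a 0.5 threshold are mutually
#' compatible, so the consensus is well defined.
#'
#' @param trees list of trees (`ape::phylo`) on an identical tip set
#' @param threshold retention threshold as a fraction (>= 0.5)
#' @return an `ape::phylo` cladogram whose internal node labels carry the
#'   support percentages
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) abort("no trees given")
  if (threshold < 0.5) abort("threshold must be >= 0.5")
  tips <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), tips)) {
      abort("all trees must share an identical tip set")
    }
  }
  counts <- new.env(parent = emptyenv())
  sides <- new.env(parent = emptyenv())
  for (tr in trees) {
    sp <- tree_splits(tr, use_labels = FALSE)
    for (key in names(sp)) {
      counts[[key]] <- (counts[[key]] %||% 0) + 1
      if (is.null(sides[[key]])) {
        sides[[key]] <- attr(sp, "sides")[[key]]
      }
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], numeric(1))
  keep <- keys[freq / length(trees) > threshold]
  support <- 100 * freq[keep] / length(trees)
  clusters <- lapply(keep, function(k) sides[[k]])
  build_consensus_tree(tips, clusters, support)
}

# assemble a (possibly multifurcating) tree from compatible clusters; the
# clusters all exclude the reference tip, so they nest or are disjoint
build_consensus_tree <- function(tips, clusters, support) {
  ord <- order(lengths(clusters))
  clusters <- clusters[ord]
  support <- support[ord]
  k <- length(clusters)
  parent_cluster <- function(members) {
    for (j in seq_len(k)) {
      if (length(clusters[[j]]) > length(members) &&
          all(members %in% clusters[[j]])) {
        return(j)
      }
    }
    0L
  }
  cl_parent <- vapply(seq_len(k), function(i) parent_cluster(clusters[[i]]),
                      integer(1))
  tip_parent <- vapply(tips, function(tp) {
    for (j in seq_len(k)) if (tp %in% clusters[[j]]) return(j)
    0L
  }, integer(1))
  lab <- function(s) formatC(s, format = "fg", digits = 7)
  render <- function(node) {
    child_tips <- tips[tip_parent == node]
    child_cls <- which(cl_parent == node)
    parts <- c(child_tips, vapply(child_cls, render, character(1)))
    if (node == 0L) {
      paste0("(", paste(parts, collapse = ","), ");")
    } else {
      paste0("(", paste(parts, collapse = ","), ")", lab(support[node]))
    }
  }
  ape::read.tree(text = render(0L))
}

#' Bootstrap column resampling of an alignment
#'
#' Each replicate samples alignment columns with replacement to the
#' original length; seeded and reproducible.
#'
#' @param msa a `protein_msa`
#' @param B number of replicates (>= 1)
#' @param seed integer seed
#' @return list of `B` `protein_msa` objects
#' @export
bootstrap_replicates <- function(msa, B, seed = 1L) {
  msa <- as_protein_msa(msa)
  if (B < 1L) abort("B must be >= 1")
  idx <- bootstrap_indices(msa$width, B, seed)
  m <- msa_matrix(msa)
  lapply(seq_len(B), function(b) {
    new_protein_msa(msa$ids, apply(m[, idx[, b], drop = FALSE], 1, paste,
                                   collapse = ""))
  })
}

# column index draws shared by the tree pipelines (width x B)
bootstrap_indices <- function(width, B, seed) {
  with_local_seed(seed, {
    matrix(sample.int(width, width * B, replace = TRUE), nrow = width)
  })
}

#' Support of a two-set partition in a consensus tree
#'
#' @param consensus tree with support values as internal node labels
#' @param taxa tip labels of one side of the partition
#' @return the support percentage, or `NA` when the consensus does not
#'   contain the bipartition
#' @export
clade_support <- function(consensus, taxa) {
  tips <- consensus$tip.label
  bad <- setdiff(taxa, tips)
  if (length(bad)) {
    abort(paste0("unknown taxa: ", paste(bad, collapse = ", ")))
  }
  sp <- tree_splits(consensus)
  key <- split_key(taxa, tips)
  if (!key %in% names(sp)) return(NA_real_)
  unname(sp[key])
}

#' Reroot a tree at the edge subtending a clade
#'
#' The root is placed on the edge whose bipartition separates `clade` from
#' the rest; supports are preserved on the same bipartitions.
#'
#' @param tree an `ape::phylo`
#' @param clade tip labels of the clade (may be a single tip)
#' @return a rooted `ape::phylo`
#' @export
reroot_at_clade <- function(tree, clade) {
  tips <- tree$tip.label
  bad <- setdiff(clade, tips)
  if (length(bad)) {
    abort(paste0("unknown taxa: ", paste(bad, collapse = ", ")))
  }
  old <- tree_splits(tree)
  if (length(clade) > 1L && length(clade) < length(tips) - 1L) {
    key <- split_key(clade, tips)
    if (!key %in% names(old)) {
      abort("the given tip set is not a bipartition of the tree")
    }
  }
  rooted <- ape::root(tree, outgroup = clade, resolve.root = TRUE)
  # reattach supports by bipartition
  ntip <- length(tips)
  new_sp <- tree_splits(rooted, use_labels = FALSE)
  sides <- attr(new_sp, "sides")
  if (!is.null(tree$node.label) || any(!is.na(old))) {
    labs <- rep("", rooted$Nnode)
    post <- as_postorder(rooted)
    below <- vector("list", ntip + rooted$Nnode)
    for (tip in seq_len(ntip)) below[[tip]] <- rooted$tip.label[tip]
    for (e in seq_len(nrow(post$edge))) {
      below[[post$edge[e, 1]]] <- c(below[[post$edge[e, 1]]],
                                    below[[post$edge[e, 2]]])
    }
    for (v in (ntip + 1L):(ntip + rooted$Nnode)) {
      size <- length(below[[v]])
      if (size < 2L || size > ntip - 2L) next
      key <- split_key(below[[v]], tips)
      if (key %in% names(old) && !is.na(old[key])) {
        labs[v - ntip] <- formatC(unname(old[key]), format = "fg",
                                  digits = 7)
      }
    }
    rooted$node.label <- labs
  }
  rooted
}
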