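# Seeded bootstrap tree pipelines: distance-based (ML distances + NJ) and
# maximum-likelihood (NJ start + NNI per replicate), with majority-rule
# consensus supports.

#' Distance-based bootstrap consensus tree
#'
#' For each replicate, alignment columns are resampled with replacement,
#' ML (plain JTT) pairwise distances are recomputed and a neighbor-joining
#' tree is built; the majority-rule consensus carries the bootstrap
#' supports.
#'
#' @param msa a `protein_msa`
#' @param model substitution model for the distances
#' @param B bootstrap replicates
#' @param seed integer seed
#' @param threshold consensus threshold
#' @param return_trees also return the replicate trees
#' @return list with `consensus` (supports as node labels), `tree` (NJ tree
#'   on the original alignment) and optionally `trees`
#' @export
nj_bootstrap <- function(msa, model = jtt_model(), B = 100L, seed = 1L,
                         threshold = 0.5, return_trees = FALSE) {
  msa <- as_protein_msa(msa)
  idx <- bootstrap_indices(msa$width, B, seed)
  trees <- lapply(seq_len(B), function(b) {
    w <- tabulate(idx[, b], nbins = msa$width)
    D <- protein_distance_matrix(msa, model, weights = w)
    neighbor_joining(D)
  })
  main <- neighbor_joining(protein_distance_matrix(msa, model))
  out <- list(consensus = majority_consensus(trees, threshold), tree = main)
  if (return_trees) out$trees <- trees
  out
}

#' Maximum-likelihood bootstrap consensus tree
#'
#' Per replicate: column resampling, NJ starting tree on plain-JTT
#' distances of the replicate, branch-length optimisation and NNI search
#' under the given model; majority-rule consensus of the replicate ML
#' trees.
#'
#' @inheritParams nj_bootstrap
#' @param model likelihood model (e.g. `jtt_model(p_inv = ..., alpha = ...)`)
#' @param max_rounds NNI rounds per replicate
#' @return list with `consensus`, `fit` (the `ml_fit` on the original
#'   alignment) and optionally `trees`
#' @export
ml_bootstrap <- function(msa, model = jtt_model(), B = 100L, seed = 1L,
                         threshold = 0.5, max_rounds = 5L,
                         return_trees = FALSE) {
  msa <- as_protein_msa(msa)
  idx <- bootstrap_indices(msa$width, B, seed)
  dist_model <- jtt_model()
  base <- prep_patterns(msa, msa$ids)
  key <- apply(msa_state_matrix(msa), 2, paste, collapse = ",")
  pat_index <- match(key, apply(base$states, 2, paste, collapse = ","))
  trees <- lapply(seq_len(B), function(b) {
    w <- tabulate(idx[, b], nbins = msa$width)
    D <- protein_distance_matrix(msa, dist_model, weights = w)
    start <- neighbor_joining(D)
    patw <- as.numeric(tapply(w, factor(pat_index, seq_len(ncol(base$states))),
                              sum))
    patw[is.na(patw)] <- 0
    keep <- patw > 0
    pd <- list(states = base$states[, keep, drop = FALSE],
               weights = patw[keep],
               conststate = base$conststate[keep], n_sites = sum(w))
    fit <- nni_search(start, msa, model, max_rounds = max_rounds,
                      sweeps = 3L, patterns = pd)
    fit$tree
  })
  fit <- ml_tree(msa, model, max_rounds = max_rounds)
  out <- list(consensus = majority_consensus(trees, threshold), fit = fit)
  if (return_trees) out$trees <- trees
  out
}

#' Bootstrap-support comparison table across analyses
#'
#' One row per named split, one column per analysis; cells are
#' [clade_support()] values (`NA` when the analysis lacks the split or its
#' taxa). A final list element reports the number of sequences per
#' analysis.
#'
#' @param consensus_trees named list of consensus trees (with supports)
#' @param splits named list of tip-label vectors (one side of each
#'   partition)
#' @return a tibble of class `support_comparison`; attribute
#'   `"n_sequences"` holds the per-analysis record counts
#' @export
support_comparison <- function(consensus_trees, splits) {
  analyses <- names(consensus_trees)
  rows <- purrr::imap(splits, function(taxa, split_name) {
    vals <- purrr::map_dbl(consensus_trees, function(tr) {
      present <- taxa[taxa %in% tr$tip.label]
      if (length(present) < 2L ||
          length(present) > length(tr$tip.label) - 2L) {
        return(NA_real_)
      }
      if (!all(taxa %in% tr$tip.label)) {
        # analyses on reduced record sets are compared on the induced split
        taxa <- present
      }
      clade_support(tr, taxa)
    })
    tibble(split = split_name, !!!setNames(as.list(vals), analyses))
  })
  out <- bind_rows(rows)
  attr(out, "n_sequences") <- purrr::map_int(consensus_trees,
                                             ~ length(.x$tip.label))
  class(out) <- c("support_comparison", class(out))
  out
}

#' Write a support-comparison table (with its per-analysis sequence counts)
#'
#' @param comparison a [support_comparison()] result
#' @param path output file
#' @export
write_support_tsv <- function(comparison, path) {
  n <- attr(comparison, "n_sequences")
  bottom <- tibble(split = "n_sequences",
                   !!!setNames(as.list(as.numeric(n)), names(n)))
  readr::write_tsv(bind_rows(as_tibble(comparison), bottom), path)
  invisible(path)
}
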