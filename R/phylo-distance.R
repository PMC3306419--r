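# Maximum-likelihood pairwise distances under the JTT model (Protdist-like,
# pairwise deletion of gap columns) and the distance-matrix container.

# integer state matrix (0..19, -1 for gap) for the given records of an msa
msa_state_matrix <- function(msa, ids = NULL) {
  msa <- as_protein_msa(msa)
  ids <- ids %||% msa$ids
  m <- do.call(rbind, lapply(msa$seqs[ids], function(s) {
    st <- aa_states(s)
    st[is.na(st)] <- -1L
    st
  }))
  rownames(m) <- ids
  m
}

#' Maximum-likelihood distance between two aligned sequences
#'
#' Maximises the likelihood `sum_i log(pi_{a_i} P_{a_i b_i}(t))` over the
#' branch length `t`, using pairwise deletion of gap columns. The
#' optimisation is bracketed on `[1e-6, 20]` with tolerance `1e-6`; a pair
#' whose optimum sits at the top of the bracket is flagged saturated.
#'
#' @param a,b equal-length aligned sequences (gaps as `-`)
#' @param model an [jtt_model()] (rate heterogeneity is not used for
#'   distances)
#' @param bracket optimisation bracket
#' @param tol optimisation tolerance
#' @return list with `distance`, `loglik`, `saturated`, `shared` (number of
#'   shared non-gap columns); `distance` is `NA` with `shared = 0` when the
#'   pair shares no columns
#' @export
ml_pairwise_distance <- function(a, b, model = jtt_model(),
                                 bracket = c(1e-6, 20), tol = 1e-6) {
  if (nchar(a) != nchar(b)) abort("aligned sequences must have equal length")
  sa <- aa_states(a); sb <- aa_states(b)
  ok <- !is.na(sa) & !is.na(sb)
  if (!any(ok)) {
    return(list(distance = NA_real_, loglik = NA_real_, saturated = FALSE,
                shared = 0L))
  }
  key <- sa[ok] * 20L + sb[ok]
  tab <- table(key)
  cells <- cbind(as.integer(names(tab)) %/% 20L,
                 as.integer(names(tab)) %% 20L)
  res <- cpp_mldist(cells, as.numeric(tab), model$pi, model$eig$V,
                    model$eig$lambda, model$eig$Vinv,
                    bracket[1], bracket[2], tol)
  res$shared <- sum(ok)
  res
}

#' All pairwise ML distances of an alignment
#'
#' @param msa a `protein_msa`
#' @param model an [jtt_model()]
#' @param deletion `"pairwise"` (Protdist-like, default) or `"complete"`
#'   (drop every column containing a gap first)
#' @param weights optional non-negative column weights (bootstrap
#'   reweighting)
#' @inheritParams ml_pairwise_distance
#' @return a symmetric matrix of class `aa_dist_matrix` with attributes
#'   `saturated` (logical matrix) and `shared` (shared-column counts)
#' @export
protein_distance_matrix <- function(msa, model = jtt_model(),
                                    deletion = c("pairwise", "complete"),
                                    weights = NULL,
                                    bracket = c(1e-6, 20), tol = 1e-6) {
  msa <- as_protein_msa(msa)
  deletion <- match.arg(deletion)
  st <- msa_state_matrix(msa)
  w <- weights %||% rep(1, ncol(st))
  if (length(w) != ncol(st)) abort("weights must match alignment width")
  if (deletion == "complete") {
    w[colSums(st < 0L) > 0L] <- 0
  }
  res <- cpp_mldist_matrix(st, as.numeric(w), model$pi, model$eig$V,
                           model$eig$lambda, model$eig$Vinv,
                           bracket[1], bracket[2], tol)
  D <- res$d
  dimnames(D) <- list(msa$ids, msa$ids)
  structure(D, saturated = res$saturated, shared = res$shared,
            class = c("aa_dist_matrix", "matrix", "array"))
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param D matrix with taxon dimnames
#' @param path output file
#' @export
write_phylip_dist <- function(D, path) {
  n <- nrow(D)
  lines <- c(
    sprintf("%5d", n),
    vapply(seq_len(n), function(i) {
      paste0(formatC(rownames(D)[i], width = -10),
             paste(sprintf("%9.6f", D[i, ]), collapse = " "))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
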