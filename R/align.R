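# Pairwise and progressive multiple alignment, column hygiene, and
# domain-wise slicing / concatenation of alignments.
#
# The aligner is a guide-tree progressive method: global affine-gap
# (Gotoh) pairwise and profile-profile alignment under BLOSUM62 (gap open
# 11, extend 1), with the guide tree from average-linkage clustering
# (UPGMA) of pairwise-identity distances. An externally produced aligned
# FASTA can be ingested instead for exact-replication workflows.

#' Alignment parameters
#'
#' @param matrix substitution matrix name (a matrix object shipped with
#'   Biostrings, e.g. `"BLOSUM62"`)
#' @param gap_open,gap_extend affine gap penalties (> 0); a gap of length L
#'   costs `gap_open + gap_extend * L`
#' @return a list of class `align_params`
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (gap_open <= 0 || gap_extend <= 0) abort("gap penalties must be > 0")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "align_params")
}

substitution_matrix <- function(params) {
  e <- new.env()
  utils::data(list = params$matrix, package = "Biostrings", envir = e)
  m <- get(params$matrix, envir = e)
  m[AA_ALPHABET, AA_ALPHABET]
}

# ------------------------------------------------------------------------
# msa container

new_protein_msa <- function(ids, seqs) {
  widths <- unique(nchar(seqs))
  if (length(widths) != 1L) abort("aligned sequences must have equal length")
  structure(list(ids = ids, seqs = setNames(seqs, ids), width = widths),
            class = "protein_msa")
}

#' Multiple-alignment container
#'
#' @param x named character vector of gapped sequences, a tibble with `id`
#'   and `sequence`/`aligned` columns, or a `Biostrings::AAMultipleAlignment`
#' @return a `protein_msa`
#' @export
as_protein_msa <- function(x) {
  if (inherits(x, "protein_msa")) return(x)
  if (inherits(x, "AAMultipleAlignment")) {
    s <- as.character(x)
    return(new_protein_msa(names(s), unname(s)))
  }
  if (is.data.frame(x)) {
    col <- if ("aligned" %in% names(x)) "aligned" else "sequence"
    return(new_protein_msa(x$id, x[[col]]))
  }
  if (is.character(x) && !is.null(names(x))) {
    return(new_protein_msa(names(x), unname(x)))
  }
  abort("cannot interpret input as a protein alignment")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat("Protein alignment:", length(x$ids), "records x", x$width, "columns\n")
  invisible(x)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unname(msa$seqs), ""))
}

# 1-based alignment column of each ungapped residue of a record
msa_colmap <- function(msa, id) {
  chars <- strsplit(msa$seqs[[id]], "")[[1]]
  which(chars != "-")
}

ungap <- function(s) gsub("-", "", s, fixed = TRUE)

#' @rdname fasta-io
#' @param msa a `protein_msa`
#' @export
write_msa_fasta <- function(msa, path) {
  x <- Biostrings::AAStringSet(msa$seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname fasta-io
#' @export
read_msa_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  new_protein_msa(names(x), as.character(x))
}

# ------------------------------------------------------------------------

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment; ties in the traceback resolve
#' deterministically as match/mismatch, then gap-in-`b`, then gap-in-`a`.
#'
#' @param a,b amino-acid strings
#' @param params an [align_params()]
#' @return list with `a_gapped`, `b_gapped`, `score`
#' @export
pairwise_align <- function(a, b, params = align_params()) {
  check_aa_string(a, "a")
  check_aa_string(b, "b")
  S <- substitution_matrix(params)
  res <- cpp_nw_pair(aa_states(a), aa_states(b), S,
                     params$gap_open, params$gap_extend)
  achars <- strsplit(a, "")[[1]]
  bchars <- strsplit(b, "")[[1]]
  gapchar <- function(chars, idx) {
    out <- rep("-", length(idx))
    out[idx >= 0] <- chars[idx[idx >= 0] + 1L]
    paste(out, collapse = "")
  }
  list(a_gapped = gapchar(achars, res$a_idx),
       b_gapped = gapchar(bchars, res$b_idx),
       score = res$score)
}

profile_of <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(m)
  p <- matrix(0, 20, L)
  for (i in seq_len(20)) p[i, ] <- colSums(m == AA_ALPHABET[i])
  p / nrow(m)
}

merge_profiles <- function(a_rows, b_rows, S, params) {
  res <- cpp_nw_profile(profile_of(a_rows), profile_of(b_rows), S,
                        params$gap_open, params$gap_extend)
  expand <- function(rows, idx) {
    vapply(rows, function(r) {
      chars <- strsplit(r, "")[[1]]
      out <- rep("-", length(idx))
      out[idx >= 0] <- chars[idx[idx >= 0] + 1L]
      paste(out, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  c(expand(a_rows, res$a_idx), expand(b_rows, res$b_idx))
}

#' Progressive multiple sequence alignment
#'
#' Guide tree from average-linkage (UPGMA) clustering of pairwise-identity
#' distances; profiles merged in guide-tree order. Two records reduce to
#' [pairwise_align()].
#'
#' @param records tibble with `id` and `sequence` columns, or a named
#'   character vector
#' @param params an [align_params()]
#' @return a `protein_msa` with records in input order
#' @export
progressive_msa <- function(records, params = align_params()) {
  if (is.character(records)) {
    records <- tibble(id = names(records), sequence = unname(records))
  }
  if (nrow(records) < 2L) abort("progressive_msa needs >= 2 records")
  if (anyDuplicated(records$id)) abort("duplicate record identifiers")
  n <- nrow(records)
  S <- substitution_matrix(params)
  if (n == 2L) {
    pw <- pairwise_align(records$sequence[1], records$sequence[2], params)
    return(new_protein_msa(records$id, c(pw$a_gapped, pw$b_gapped)))
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pw <- pairwise_align(records$sequence[i], records$sequence[j], params)
      ac <- strsplit(pw$a_gapped, "")[[1]]
      bc <- strsplit(pw$b_gapped, "")[[1]]
      ident <- sum(ac == bc & ac != "-") / length(ac)
      D[i, j] <- D[j, i] <- 1 - ident
    }
  }
  hc <- hclust(as.dist(D), method = "average")
  nodes <- vector("list", n - 1L)
  leaf <- function(i) list(ids = records$id[i], rows = records$sequence[i])
  for (k in seq_len(n - 1L)) {
    pick <- function(m) if (m < 0) leaf(-m) else nodes[[m]]
    a <- pick(hc$merge[k, 1])
    b <- pick(hc$merge[k, 2])
    rows <- merge_profiles(a$rows, b$rows, S, params)
    nodes[[k]] <- list(ids = c(a$ids, b$ids), rows = rows)
  }
  final <- nodes[[n - 1L]]
  ord <- match(records$id, final$ids)
  new_protein_msa(records$id, final$rows[ord])
}

#' Remove alignment columns consisting only of gaps
#'
#' Idempotent; record order preserved.
#'
#' @param msa a `protein_msa`
#' @return a `protein_msa`
#' @export
strip_gap_only_columns <- function(msa) {
  msa <- as_protein_msa(msa)
  m <- msa_matrix(msa)
  keep <- colSums(m != "-") > 0L
  new_protein_msa(msa$ids, apply(m[, keep, drop = FALSE], 1, paste,
                                 collapse = ""))
}

#' Extract the alignment slice of a reference domain
#'
#' Takes the alignment columns spanned by a domain of the reference
#' record's map. With `drop_gapped`, records whose slice is more than
#' `gap_threshold` gaps are excluded (mirroring the exclusion of gapped or
#' missense regions from per-domain analyses).
#'
#' @param msa a `protein_msa`
#' @param ref_map `domain_map` of a record present in the alignment
#' @param domain domain identifier on the reference, e.g. `"TB4"`
#' @param drop_gapped drop heavily gapped records
#' @param gap_threshold gap fraction above which a record is dropped
#' @return a `protein_msa`; dropped record ids in attribute `"dropped"`
#' @export
extract_domain_alignment <- function(msa, ref_map, domain,
                                     drop_gapped = FALSE,
                                     gap_threshold = 0.5) {
  msa <- as_protein_msa(msa)
  ref_id <- attr(ref_map, "record") %||% ref_map$record[1]
  if (!ref_id %in% msa$ids) abort("reference record is not in the alignment")
  seg <- filter(ref_map, .data$domain_id == !!domain)
  if (!nrow(seg)) abort(paste0("domain ", domain, " absent from reference map"))
  cmap <- msa_colmap(msa, ref_id)
  cols <- seq(cmap[seg$start + 1L], cmap[seg$end])
  m <- msa_matrix(msa)[, cols, drop = FALSE]
  rows <- apply(m, 1, paste, collapse = "")
  out <- new_protein_msa(msa$ids, rows)
  dropped <- character()
  if (drop_gapped) {
    gapfrac <- rowMeans(m == "-")
    keep <- gapfrac <= gap_threshold
    dropped <- msa$ids[!keep]
    if (length(dropped)) {
      inform(paste0("dropping gapped records from ", domain, " slice: ",
                    paste(dropped, collapse = ", ")))
    }
    out <- new_protein_msa(msa$ids[keep], rows[keep])
  }
  attr(out, "dropped") <- dropped
  out
}

#' Concatenate alignment slices over a shared record set
#'
#' Records missing from some slices are dropped with a warning; the
#' remaining rows are concatenated in the record order of the first slice.
#'
#' @param slices list of `protein_msa` objects
#' @return a `protein_msa` of width `sum(widths)`
#' @export
concatenate_alignments <- function(slices) {
  if (!length(slices)) abort("no slices to concatenate")
  slices <- purrr::map(slices, as_protein_msa)
  common <- Reduce(intersect, purrr::map(slices, "ids"))
  if (!length(common)) abort("slices share no records")
  all_ids <- unique(unlist(purrr::map(slices, "ids")))
  lost <- setdiff(all_ids, common)
  if (length(lost)) {
    warn(paste0("records missing from some slices were dropped: ",
                paste(lost, collapse = ", ")))
  }
  ord <- intersect(slices[[1]]$ids, common)
  rows <- vapply(ord, function(id) {
    paste(vapply(slices, function(s) s$seqs[[id]], character(1)),
          collapse = "")
  }, character(1))
  new_protein_msa(ord, unname(rows))
}
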