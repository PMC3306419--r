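# RGD integrin-binding sites, furin-cleavage consensus sites, terminal
# cysteines, and alignment-based residue variants at homologous positions.

localize_hit <- function(map, start, end) {
  if (is.null(map)) return(list(domain = NA_character_, note = ""))
  seg <- filter(map, .data$klass != "GAP",
                .data$start <= !!start, !!end <= .data$end)
  if (!nrow(seg)) return(list(domain = "outside", note = ""))
  seg <- seg[1, ]
  cys <- seg$cys[[1]]
  note <- ""
  if (length(cys) &&
      seg$klass %in% c("TB", "HYBRID8", "HYBRID9", "HYBRID10", "EGF",
                       "cbEGF", "cbEGF_like")) {
    k <- sum(cys < start)
    note <- if (k == 0L) "before Cys1"
            else if (k == length(cys)) paste0("after Cys", k)
            else paste0("between Cys", k, " and Cys", k + 1L)
  }
  list(domain = seg$domain_id, note = note)
}

motif_hit_tibble <- function(id, kind, starts, width, map) {
  if (!length(starts)) {
    return(tibble(record = character(), kind = character(),
                  start = integer(), end = integer(),
                  domain = character(), note = character()))
  }
  loc <- purrr::map(starts, ~ localize_hit(map, .x, .x + width))
  tibble(
    record = id, kind = kind, start = as.integer(starts),
    end = as.integer(starts + width),
    domain = purrr::map_chr(loc, "domain"),
    note = purrr::map_chr(loc, "note")
  )
}

#' Scan a record for RGD integrin-binding sites
#'
#' Reports every occurrence of the exact tripeptide RGD (0-based half-open
#' coordinates). With a domain map, each hit is localized to its containing
#' domain and positioned relative to the flanking cysteines (the vertebrate
#' TB4 site sits between Cys1 and Cys2).
#'
#' @param record record tibble (one row) or sequence string
#' @param map optional `domain_map` for localization
#' @return tibble with columns `record`, `kind`, `start`, `end`, `domain`,
#'   `note`
#' @export
scan_rgd <- function(record, map = NULL) {
  record <- as_protein_record(record)
  seq <- record$sequence[[1]]
  motif_hit_tibble(record$id[[1]], "RGD", find_exact(seq, "RGD"), 3L, map)
}

#' Scan a record for furin-cleavage consensus sites
#'
#' Matches the tribasic proprotein-convertase consensus Arg-x-(Lys/Arg)-Arg.
#' Overlapping matches are all reported by default.
#'
#' @inheritParams scan_rgd
#' @param restrict_to_terminals keep only hits inside the N-/C-terminal
#'   domains (requires `map`)
#' @param overlapping report self-overlapping matches (default) or greedy
#'   non-overlapping ones
#' @return tibble as in [scan_rgd()] with `kind = "FURIN"`
#' @export
scan_furin <- function(record, map = NULL, restrict_to_terminals = FALSE,
                       overlapping = TRUE) {
  record <- as_protein_record(record)
  seq <- record$sequence[[1]]
  starts <- find_furin(seq)
  if (!overlapping && length(starts) > 1L) {
    keep <- starts[1]
    for (s in starts[-1]) {
      if (s >= keep[length(keep)] + 4L) keep <- c(keep, s)
    }
    starts <- keep
  }
  hits <- motif_hit_tibble(record$id[[1]], "FURIN", starts, 4L, map)
  if (restrict_to_terminals) {
    if (is.null(map)) abort("restrict_to_terminals requires a domain map")
    hits <- filter(hits, .data$domain %in% c("NTERM", "CTERM"))
  }
  hits
}

#' Count cysteines in the terminal domains
#'
#' The fibrillin N-terminal domain carries four and the C-terminal domain
#' two cysteines; an absent terminal segment is reported as missing (`NA`),
#' not zero.
#'
#' @inheritParams scan_rgd
#' @param map a `domain_map`
#' @return list with integer (or `NA`) elements `n_term` and `c_term`
#' @export
terminal_cysteine_count <- function(record, map) {
  record <- as_protein_record(record)
  count_in <- function(klass) {
    seg <- filter(map, .data$klass == !!klass)
    if (!nrow(seg)) return(NA_integer_)
    sum(purrr::map_int(seg$cys, length))
  }
  list(n_term = count_in("NTERM"), c_term = count_in("CTERM"))
}

#' Residues of all aligned records at a reference window
#'
#' Maps reference residue coordinates to alignment columns and returns each
#' record's residues at those columns (gaps as `-`). This is how RGD-anchor
#' variants (RGE, KGD, RAD, ...) are read off the alignment rather than
#' searched for.
#'
#' @param msa a `protein_msa`
#' @param ref_id reference record identifier
#' @param ref_start,ref_end 0-based half-open window on the reference's
#'   ungapped sequence
#' @return tibble with `record` and `residues`; attribute `"columns"` holds
#'   the 0-based alignment columns used
#' @export
homologous_column_residues <- function(msa, ref_id, ref_start, ref_end) {
  stopifnot(inherits(msa, "protein_msa"))
  if (!ref_id %in% msa$ids) abort(paste0(ref_id, " is not in the alignment"))
  cmap <- msa_colmap(msa, ref_id)           # 1-based columns per residue
  if (ref_start < 0L || ref_end > length(cmap) || ref_start >= ref_end) {
    abort("reference window outside the ungapped reference sequence")
  }
  cols <- cmap[(ref_start + 1L):ref_end]
  res <- vapply(msa$seqs, function(s) {
    paste(strsplit(s, "")[[1]][cols], collapse = "")
  }, character(1))
  out <- tibble(record = msa$ids, residues = unname(res[msa$ids]))
  attr(out, "columns") <- cols - 1L
  out
}

#' Write motif hits
#'
#' Tab-separated `(record, kind, start, end, domain, note)`, or BED
#' (0-based half-open, name = `kind:domain`).
#'
#' @param hits tibble of motif hits
#' @param path output file
#' @name motif-io
#' @export
write_motif_tsv <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}

#' @rdname motif-io
#' @export
write_motif_bed <- function(hits, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", hits$record, hits$start, hits$end,
                   paste0(hits$kind, ":", hits$domain))
  writeLines(lines, path)
  invisible(path)
}
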