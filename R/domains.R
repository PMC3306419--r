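# Domain annotation from cysteine signatures.
#
# Fibrillin domains are defined entirely by their cysteine content: 6-Cys
# EGF-family domains (calcium-binding when the N-terminal consensus
# (D/N)-x-(D/N)-(E/Q)-x{m}-(D/N)-x{n}-(Y/F) is present), 8-Cys TB domains
# with the triple Cys-Cys-Cys, 8/9/10-Cys hybrid domains with the tandem
# Cys-Cys, 4-Cys N- and 2-Cys C-terminal domains, and the cysteine-free
# unique region after TB1. Segmentation is anchored on cysteines: candidate
# boundaries are midpoints of long cysteine-free runs.

#' Domain-scan configuration
#'
#' @param gap_split cysteine-free run length above which two cysteines are
#'   assigned to different domains
#' @param boundary_flank residues kept on each side of a domain's outermost
#'   cysteines when the inter-domain run is too long to split at a midpoint
#' @param linker_max maximum inter-domain run split at its midpoint; longer
#'   runs become uncovered gaps (or the unique region)
#' @param unique_min_len minimum length of the cysteine-free region after the
#'   first TB domain to be annotated as the unique region
#' @param cb_m,cb_n bounds `c(min, max)` for the two variable spacers of the
#'   calcium-binding consensus
#' @param terminal_max maximum leading/trailing overhang attached to the
#'   first/last domain (longer overhangs stay uncovered)
#' @return a list of class `domain_scan_config`
#' @export
domain_scan_config <- function(gap_split = 12L, boundary_flank = 7L,
                               linker_max = 20L, unique_min_len = 30L,
                               cb_m = c(0L, 4L), cb_n = c(2L, 12L),
                               terminal_max = 40L) {
  structure(
    list(gap_split = gap_split, boundary_flank = boundary_flank,
         linker_max = linker_max, unique_min_len = unique_min_len,
         cb_m = cb_m, cb_n = cb_n, terminal_max = terminal_max),
    class = "domain_scan_config"
  )
}

#' Match the calcium-binding consensus in a sequence window
#'
#' Finds the leftmost (then shortest-spacer) occurrence of
#' `(D/N)-x-(D/N)-(E/Q)-x{m}-(D/N)-x{n}-(Y/F)` with the spacer lengths `m`,
#' `n` within the configured bounds. In relaxed mode the identity of the
#' first residue is not enforced, which is how calcium-binding-EGF-like
#' domains (consensus intact except for the leading Asp/Asn) are detected.
#'
#' @param window uppercase amino-acid string
#' @param m_bounds,n_bounds inclusive bounds for the variable spacers
#' @param strict require the leading residue to be D or N
#' @return a list with `start`, `end` (0-based half-open, within the
#'   window), `m`, `n` and `first_residue`, or `NULL` when no match exists
#' @export
match_cb_consensus <- function(window, m_bounds = c(0L, 4L),
                               n_bounds = c(2L, 12L), strict = TRUE) {
  check_aa_string(window, "window")
  chars <- strsplit(window, "")[[1]]
  len <- length(chars)
  dn <- chars %in% c("D", "N")
  eq <- chars %in% c("E", "Q")
  yf <- chars %in% c("Y", "F")
  for (p in seq_len(len)) {                      # 1-based candidate start
    if (p + 3L > len) break
    if (strict && !dn[p]) next
    if (!dn[p + 2L] || !eq[p + 3L]) next
    for (m in m_bounds[1]:m_bounds[2]) {
      pd <- p + 4L + m
      if (pd > len) break
      if (!dn[pd]) next
      for (n in n_bounds[1]:n_bounds[2]) {
        py <- pd + n + 1L
        if (py > len) break
        if (yf[py]) {
          return(list(start = p - 1L, end = py, m = m, n = n,
                      first_residue = chars[p]))
        }
      }
    }
  }
  NULL
}

# helpers over cysteine gap structure -------------------------------------

cys_gaps <- function(cys) diff(cys) - 1L  # residues between consecutive Cys

has_triple <- function(gaps) {
  any(gaps == 0L & dplyr::lead(gaps, default = 1L) == 0L)
}

tandem_positions <- function(gaps) which(gaps == 0L)  # pair (i, i+1)

#' Classify a candidate domain segment
#'
#' Applies the cysteine-signature rules: the 8-cysteine TB domain carries
#' the triple Cys-Cys-Cys (Cys3-5); hybrid domains carry the tandem Cys-Cys
#' (positions 4-5, shifted to 5-6 by the extra cysteine of hybrid 1, and
#' extended by Cys4a/Cys6a in the 10-cysteine arthropod variant); 6-cysteine
#' domains split into cbEGF / cbEGF-like / EGF by the calcium-binding
#' consensus in the N-terminal window. Unrecognisable patterns yield class
#' `UNKNOWN` with a diagnostic note, never an error.
#'
#' @param segment amino-acid string of the candidate segment
#' @param cys_count expected cysteine count (checked against the sequence
#'   when given)
#' @param context list with logical `leading` / `trailing` flags used for
#'   the 4- and 2-cysteine terminal domains
#' @param config a [domain_scan_config()]
#' @return list with `klass`, `cb_status`, `note`
#' @export
classify_segment <- function(segment, cys_count = NULL, context = NULL,
                             config = domain_scan_config()) {
  check_aa_string(segment, "segment")
  chars <- strsplit(segment, "")[[1]]
  cys <- which(chars == "C")
  n <- length(cys)
  if (!is.null(cys_count) && cys_count != n) {
    abort(paste0("segment has ", n, " cysteines, expected ", cys_count))
  }
  leading <- isTRUE(context$leading)
  trailing <- isTRUE(context$trailing)
  gaps <- cys_gaps(cys)
  unknown <- function(note) list(klass = "UNKNOWN", cb_status = "not_applicable",
                                 note = note)
  if (n == 6L) {
    window <- substr(segment, 1L, max(cys[2] - 1L, 1L))
    hit <- match_cb_consensus(window, config$cb_m, config$cb_n, strict = TRUE)
    if (!is.null(hit)) {
      return(list(klass = "cbEGF", cb_status = "calcium_binding", note = ""))
    }
    relaxed <- match_cb_consensus(window, config$cb_m, config$cb_n,
                                  strict = FALSE)
    if (!is.null(relaxed)) {
      return(list(
        klass = "cbEGF_like", cb_status = "cb_like",
        note = paste0("consensus first residue ", relaxed$first_residue,
                      ", not D/N")
      ))
    }
    return(list(klass = "EGF", cb_status = "non_cb", note = ""))
  }
  if (n == 8L) {
    if (has_triple(gaps)) {
      return(list(klass = "TB", cb_status = "not_applicable", note = ""))
    }
    td <- tandem_positions(gaps)
    if (length(td) && 4L %in% td) {
      return(list(klass = "HYBRID8", cb_status = "not_applicable",
                  note = "tandem Cys-Cys at 4-5"))
    }
    return(unknown("8 cysteines without triple or 4-5 tandem"))
  }
  if (n == 9L) {
    td <- tandem_positions(gaps)
    if (!has_triple(gaps) && length(td) == 1L && td == 5L) {
      return(list(klass = "HYBRID9", cb_status = "not_applicable",
                  note = "extra Cys after Cys2"))
    }
    return(unknown("9 cysteines without the hybrid-1 signature"))
  }
  if (n == 10L) {
    td <- tandem_positions(gaps)
    # triple occupies gap indices (i, i+1); a separate tandem must remain
    triple_at <- which(gaps == 0L & dplyr::lead(gaps, default = 1L) == 0L)
    if (length(triple_at)) {
      sep <- setdiff(td, c(triple_at, triple_at + 1L))
      if (length(sep)) {
        canonical <- 4L %in% triple_at && 8L %in% sep
        return(list(
          klass = "HYBRID10", cb_status = "not_applicable",
          note = if (canonical) "Cys4a/Cys6a present"
                 else "triple and tandem at non-canonical positions"
        ))
      }
    }
    return(unknown("10 cysteines without triple plus tandem"))
  }
  if (n == 4L && leading) {
    return(list(klass = "NTERM", cb_status = "not_applicable", note = ""))
  }
  if (n == 2L && trailing) {
    return(list(klass = "CTERM", cb_status = "not_applicable", note = ""))
  }
  unknown(paste0(n, " cysteines match no domain class"))
}

# ------------------------------------------------------------------------

as_protein_record <- function(record, id = "seq") {
  if (is.character(record) && length(record) == 1L) {
    return(tibble(id = id, sequence = record))
  }
  if (is.data.frame(record)) {
    if (!all(c("id", "sequence") %in% names(record))) {
      abort("protein records need `id` and `sequence` columns")
    }
    return(record)
  }
  abort("record must be a sequence string or a data frame of records")
}

new_domain_map <- function(df, seq_length, record) {
  df <- as_tibble(df)
  structure(
    df,
    seq_length = seq_length,
    record = record,
    class = c("domain_map", class(df))
  )
}

#' Annotate the domain architecture of a fibrillin-like protein
#'
#' Greedy left-to-right segmentation at cysteine-cluster boundaries:
#' cysteines separated by more than `gap_split` non-cysteine residues open a
#' new candidate domain; runs up to `linker_max` between two domains are
#' split at their midpoint, longer runs become uncovered gaps. The
#' cysteine-free gap immediately after the first TB domain is promoted to
#' the unique region when it is at least `unique_min_len` residues long. The
#' leading 4-cysteine and trailing 2-cysteine clusters become the N- and
#' C-terminal domains.
#'
#' @param record a data frame with `id` and `sequence` columns (one row), or
#'   a plain sequence string
#' @param config a [domain_scan_config()]
#' @return a tibble of class `domain_map` with one row per segment or gap:
#'   `record`, `domain_id` (e.g. `"TB4"`), `klass`, `ordinal`, `start`,
#'   `end` (0-based half-open), `ncys`, `cys` (list of absolute cysteine
#'   positions), `cb_status`, `note`. Rows with `klass == "GAP"` are
#'   uncovered gaps; segments and gaps tile the sequence.
#' @examples
#' rec <- generate_architecture(fibrillin1_profile(), seed = 1)
#' find_domains(rec$record)
#' @export
find_domains <- function(record, config = domain_scan_config()) {
  record <- as_protein_record(record)
  seq <- record$sequence[[1]]
  id <- record$id[[1]]
  if (!nzchar(seq)) abort("sequence must have length >= 1")
  check_aa_string(seq, "sequence")
  chars <- strsplit(seq, "")[[1]]
  len <- length(chars)
  cys <- which(chars == "C") - 1L               # 0-based
  gap_row <- function(start, end) {
    tibble(record = id, domain_id = NA_character_, klass = "GAP",
           ordinal = NA_integer_, start = start, end = end, ncys = 0L,
           cys = list(integer()), cb_status = "not_applicable", note = "")
  }
  if (!length(cys)) {
    return(new_domain_map(gap_row(0L, len), len, id))
  }
  # cluster cysteines
  splits <- which(diff(cys) - 1L > config$gap_split)
  cluster_id <- cumsum(c(1L, seq_along(cys)[-1] %in% (splits + 1L)))
  clusters <- split(cys, cluster_id)
  k <- length(clusters)
  firsts <- vapply(clusters, function(x) x[1], integer(1))
  lasts <- vapply(clusters, function(x) x[length(x)], integer(1))
  # segment boundaries between consecutive clusters
  seg_start <- integer(k)
  seg_end <- integer(k)
  gaps <- list()
  seg_start[1] <- if (firsts[1] <= config$terminal_max) 0L
                  else firsts[1] - config$boundary_flank
  if (seg_start[1] > 0L) gaps <- c(gaps, list(c(0L, seg_start[1])))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      d <- firsts[i + 1L] - lasts[i] - 1L
      if (d <= config$linker_max) {
        seg_end[i] <- lasts[i] + 1L + d %/% 2L
        seg_start[i + 1L] <- seg_end[i]
      } else {
        seg_end[i] <- lasts[i] + 1L + config$boundary_flank
        seg_start[i + 1L] <- firsts[i + 1L] - config$boundary_flank
        gaps <- c(gaps, list(c(seg_end[i], seg_start[i + 1L])))
      }
    }
  }
  trail <- len - lasts[k] - 1L
  seg_end[k] <- if (trail <= config$terminal_max) len
                else lasts[k] + 1L + config$boundary_flank
  if (seg_end[k] < len) gaps <- c(gaps, list(c(seg_end[k], len)))

  segs <- purrr::map(seq_len(k), function(i) {
    sub <- substr(seq, seg_start[i] + 1L, seg_end[i])
    cls <- classify_segment(
      sub,
      context = list(leading = i == 1L, trailing = i == k),
      config = config
    )
    tibble(record = id, domain_id = NA_character_, klass = cls$klass,
           ordinal = NA_integer_, start = seg_start[i], end = seg_end[i],
           ncys = length(clusters[[i]]), cys = list(clusters[[i]]),
           cb_status = cls$cb_status, note = cls$note)
  })
  map <- bind_rows(c(segs, purrr::map(gaps, ~ gap_row(.x[1], .x[2]))))
  map <- arrange(map, .data$start)
  # promote the cysteine-free run after TB1 to the unique region
  tb_rows <- which(map$klass == "TB")
  if (length(tb_rows)) {
    after <- tb_rows[1] + 1L
    if (after <= nrow(map) && map$klass[after] == "GAP" &&
        (map$end[after] - map$start[after]) >= config$unique_min_len) {
      map$klass[after] <- "UNIQUE"
      map$note[after] <- "cysteine-free region after TB1"
    }
  }
  # within-class ordinals and domain ids
  map <- map |>
    group_by(.data$klass) |>
    mutate(ordinal = dplyr::if_else(.data$klass %in% c("GAP"),
                                    NA_integer_, as.integer(row_number()))) |>
    ungroup() |>
    mutate(domain_id = dplyr::if_else(
      is.na(.data$ordinal), NA_character_,
      dplyr::if_else(.data$klass %in% c("NTERM", "CTERM", "UNIQUE"),
                     .data$klass, paste0(.data$klass, .data$ordinal))
    ))
  new_domain_map(map, len, id)
}

#' Locate the unique region of an annotated record
#'
#' Returns the cysteine-free segment immediately following the first TB
#' domain when it is at least `min_len` residues long; `NULL` otherwise
#' (including when a cbEGF-like domain occupies that position, as in
#' single-fibrillin invertebrates, or when the map has no TB domain).
#'
#' @param map a `domain_map` from [find_domains()]
#' @param record the corresponding protein record (unused, kept for
#'   interface symmetry; the map carries the coordinates)
#' @param min_len minimum length in residues (default 30)
#' @return a one-row tibble (the segment) or `NULL` with a `"reason"`
#'   attribute
#' @export
locate_unique_region <- function(map, record = NULL, min_len = 30L) {
  stopifnot(inherits(map, "domain_map"))
  tb_rows <- which(map$klass == "TB")
  none <- function(reason) {
    inform(paste0("no unique region: ", reason),
           class = "fibevo_no_unique_region")
    invisible(NULL)
  }
  if (!length(tb_rows)) return(none("map has no TB domain"))
  after <- tb_rows[1] + 1L
  if (after > nrow(map)) return(none("nothing follows TB1"))
  row <- map[after, ]
  if (!row$klass %in% c("UNIQUE", "GAP")) {
    return(none(paste0("position after TB1 occupied by ", row$klass)))
  }
  if ((row$end - row$start) < min_len) {
    return(none("region after TB1 shorter than min_len"))
  }
  row
}

#' @export
print.domain_map <- function(x, ...) {
  cat("Domain map for", attr(x, "record"), "(", attr(x, "seq_length"),
      "residues )\n")
  NextMethod()
}

# ------------------------------------------------------------------------
# annotation writers (0-based half-open TSV; GFF3 uses its native 1-based
# closed convention)

#' Write domain annotations
#'
#' @param map a `domain_map` (or row-bound tibble of several)
#' @param path output file
#' @name annotation-io
#' @export
write_annotation_tsv <- function(map, path) {
  out <- map |>
    filter(.data$klass != "GAP") |>
    select("record", "klass", "start", "end", "cb_status", "note")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname annotation-io
#' @export
write_annotation_gff3 <- function(map, path) {
  seg <- filter(map, .data$klass != "GAP")
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\tfibevo\t%s\t%d\t%d\t.\t.\t.\tID=%s;cb_status=%s",
      seg$record, seg$klass, seg$start + 1L, seg$end,
      paste0(seg$record, ":", seg$domain_id), seg$cb_status
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Architecture summary counts of an annotated fibrillin record
#'
#' The headline counts used to recognise a fibrillin: number of TB domains,
#' cysteines per TB domain, cysteine count of the first hybrid domain,
#' terminal-domain cysteines and number of RGD sites.
#'
#' @param record record tibble (one row) or sequence string
#' @param map optional `domain_map` (computed when missing)
#' @return one-row tibble with `n_tb`, `tb_cys` (unique cysteine count per
#'   TB domain), `hybrid1_cys`, `n_term_cys`, `c_term_cys`, `n_rgd`
#' @export
fibrillin_architecture_summary <- function(record, map = NULL) {
  record <- as_protein_record(record)
  map <- map %||% find_domains(record)
  tb <- filter(map, .data$klass == "TB")
  hyb <- filter(map, .data$klass %in% c("HYBRID8", "HYBRID9", "HYBRID10"))
  tc <- terminal_cysteine_count(record, map)
  n_rgd <- nrow(scan_rgd(record, map))
  tibble(
    record = record$id[[1]],
    n_tb = nrow(tb),
    tb_cys = if (nrow(tb)) unique(tb$ncys)[1] else NA_integer_,
    hybrid1_cys = if (nrow(hyb)) hyb$ncys[1] else NA_integer_,
    n_term_cys = tc$n_term,
    c_term_cys = tc$c_term,
    n_rgd = n_rgd
  )
}
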