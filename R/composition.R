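# Amino-acid composition of unique regions: per-residue percentages,
# most/second-most common residues with exact-frequency ties, and group
# summaries with the glycine:proline ratio.

#' Per-residue composition of a sequence region
#'
#' Percentages are taken over the 20 standard residues; other characters
#' are counted under `X` and excluded from the 100% base.
#'
#' @param region non-empty amino-acid string
#' @return tibble with `residue`, `count`, `pct` (one row per standard
#'   residue, plus an `X` row when non-standard characters occur)
#' @export
residue_frequency <- function(region) {
  if (!is.character(region) || length(region) != 1L || !nzchar(region)) {
    abort("region must be a non-empty string")
  }
  chars <- strsplit(toupper(region), "")[[1]]
  std <- chars %in% AA_ALPHABET
  counts <- table(factor(chars[std], levels = sort(AA_ALPHABET)))
  base <- sum(counts)
  out <- tibble(
    residue = names(counts),
    count = as.integer(counts),
    pct = if (base > 0) 100 * as.integer(counts) / base else 0
  )
  if (any(!std)) {
    out <- bind_rows(out, tibble(residue = "X", count = sum(!std), pct = NA_real_))
  }
  out
}

#' Most and second-most common residues of a composition table
#'
#' Exact frequency ties are reported as a joined pair (`"L & P"`); a tie at
#' rank 1 makes rank 2 the next distinct frequency. Residues with zero
#' frequency are never ranked.
#'
#' @param table a composition tibble from [residue_frequency()] (or any
#'   tibble with `residue` and `pct`)
#' @return list with `most_common`, `second_most_common` (strings, possibly
#'   `"A & B"`; `NA` when fewer than two distinct frequencies exist) and the
#'   corresponding `most_pct`, `second_pct`
#' @export
rank_residues <- function(table) {
  tab <- filter(table, .data$residue %in% AA_ALPHABET,
                !is.na(.data$pct), .data$pct > 0)
  if (!nrow(tab)) abort("composition table has no ranked residues")
  lvls <- sort(unique(tab$pct), decreasing = TRUE)
  join <- function(p) {
    paste(sort(tab$residue[tab$pct == p]), collapse = " & ")
  }
  list(
    most_common = join(lvls[1]),
    second_most_common = if (length(lvls) >= 2L) join(lvls[2]) else NA_character_,
    most_pct = lvls[1],
    second_pct = if (length(lvls) >= 2L) lvls[2] else NA_real_
  )
}

#' Composition summary of grouped unique regions
#'
#' Group percentages are unweighted means over member sequences (each
#' sequence contributes its own percentage), mirroring how isoform groups
#' are summarised; pooled residue counting is available as an alternative.
#' The glycine:proline ratio is the mean of per-sequence ratios; a sequence
#' without proline makes the group ratio infinite.
#'
#' @param regions tibble with columns `group` and `region` (one row per
#'   sequence)
#' @param pooled pool residue counts across the group instead of averaging
#'   per-sequence percentages
#' @return tibble of class `composition_summary`: `group`, `n`,
#'   `most_common`, `most_pct`, `second_most_common`, `second_pct`,
#'   `gly_pro_ratio`, and `table` (list column of per-residue mean
#'   percentages)
#' @export
group_summary <- function(regions, pooled = FALSE) {
  regions <- as_tibble(regions)
  if (!all(c("group", "region") %in% names(regions))) {
    abort("regions needs columns `group` and `region`")
  }
  if (!nrow(regions)) abort("no regions given")
  groups <- split(regions, factor(regions$group, unique(regions$group)))
  rows <- purrr::imap(groups, function(g, label) {
    if (!nrow(g)) abort(paste0("group ", label, " has no sequences"))
    tabs <- purrr::map(g$region, residue_frequency)
    per_seq <- purrr::map(tabs, function(t) {
      filter(t, .data$residue %in% AA_ALPHABET)$pct
    })
    mean_pct <- Reduce(`+`, per_seq) / length(per_seq)
    if (pooled) {
      counts <- Reduce(`+`, purrr::map(tabs, function(t) {
        filter(t, .data$residue %in% AA_ALPHABET)$count
      }))
      mean_pct <- 100 * counts / sum(counts)
    }
    tab <- tibble(residue = sort(AA_ALPHABET), pct = mean_pct)
    rk <- rank_residues(tab)
    gi <- which(tab$residue == "G")
    ratios <- purrr::map_dbl(per_seq, function(p) {
      names(p) <- sort(AA_ALPHABET)
      if (p[["P"]] == 0) Inf else p[["G"]] / p[["P"]]
    })
    tibble(
      group = label, n = nrow(g),
      most_common = rk$most_common, most_pct = rk$most_pct,
      second_most_common = rk$second_most_common, second_pct = rk$second_pct,
      gly_pro_ratio = mean(ratios),
      table = list(tab)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("composition_summary", class(out))
  out
}

#' Unique regions of a set of annotated records, grouped by isoform
#'
#' @param records record tibble (`id`, `sequence`, optionally `isoform`)
#' @param maps named list of `domain_map`s (one per record id); computed
#'   with [find_domains()] when missing
#' @param min_len minimum unique-region length
#' @return tibble with `id`, `group`, `region` suitable for
#'   [group_summary()] (records without a unique region are dropped)
#' @export
unique_regions <- function(records, maps = NULL, min_len = 30L) {
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    map <- if (!is.null(maps)) maps[[rec$id]] else find_domains(rec)
    seg <- locate_unique_region(map, min_len = min_len)
    if (is.null(seg)) return(NULL)
    tibble(
      id = rec$id,
      group = if ("isoform" %in% names(rec)) rec$isoform else "all",
      region = substr(rec$sequence, seg$start + 1L, seg$end)
    )
  })
  bind_rows(rows)
}

#' Write a composition summary as TSV
#'
#' Columns mirror the standard unique-region composition table layout:
#' group, most common (with percentage), second most common, member count.
#' Percentages are rounded to the nearest integer at this presentation
#' layer only.
#'
#' @param summary a [group_summary()] result
#' @param path output file
#' @export
write_composition_tsv <- function(summary, path) {
  out <- tibble(
    group = summary$group,
    most_common = sprintf("%s (%d/%.0f%%)", summary$most_common, summary$n,
                          summary$most_pct),
    second_most_common = ifelse(
      is.na(summary$second_most_common), "",
      sprintf("%s (%d/%.0f%%)", summary$second_most_common, summary$n,
              summary$second_pct)
    ),
    n = summary$n
  )
  readr::write_tsv(out, path)
  invisible(path)
}
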