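# Fibrillin-family simulator: realizes architecture profiles into sequences
# with exact ground-truth domain maps, then evolves them along a locus tree
# with gene duplications, site-wise substitution under the JTT model and
# scripted motif events.
#
# Class-defining features (cysteines, motif payloads, calcium-binding
# consensus anchors) are protected from substitution, substitutions are
# conditioned against creating new cysteines, and rare substitutions that
# would create a spurious RGD/furin/consensus signature are reverted -
# purifying selection against confounding signatures, which keeps the
# domain grammar of every simulated record scannable exactly.

NON_CYS <- setdiff(AA_ALPHABET, "C")

# sampling distribution over the 19 non-cysteine residues
residue_weights <- function(weights = NULL) {
  w <- setNames(rep(0, length(NON_CYS)), NON_CYS)
  if (is.null(weights)) {
    w[] <- 1 / length(NON_CYS)
    return(w)
  }
  if (is.null(names(weights)) || any(!names(weights) %in% NON_CYS)) {
    abort("unique-region weights must be named with non-Cys residues")
  }
  if (sum(weights) > 1 + 1e-9) abort("residue weights must sum to <= 1")
  w[names(weights)] <- weights
  rest <- setdiff(NON_CYS, names(weights))
  w[rest] <- (1 - sum(weights)) / length(rest)
  w
}

sample_residues <- function(n, w) {
  if (n == 0L) return(character())
  sample(names(w), n, replace = TRUE, prob = w)
}

# positions of the fixed calcium-binding consensus anchors, relative to the
# first cysteine c1 (0-based): D(c1-4) x D(c1-2) E(c1-1) [C] D(c1+1) x4 Y(c1+6)
cb_anchor_offsets <- function(c1) c(c1 - 4L, c1 - 2L, c1 - 1L, c1 + 1L, c1 + 6L)
cb_anchor_residues <- function(like = FALSE) {
  c(if (like) "G" else "D", "D", "E", "D", "Y")
}

realize_template <- function(tpl, base_w, unique_w) {
  len <- template_length(tpl)
  cys <- template_cys_offsets(tpl)
  w <- if (tpl$klass == "UNIQUE") unique_w else base_w
  chars <- sample_residues(len, w)
  if (length(cys)) chars[cys + 1L] <- "C"
  fixed <- cys
  if (tpl$klass %in% c("cbEGF", "cbEGF_like")) {
    anchors <- cb_anchor_offsets(cys[1])
    chars[anchors + 1L] <- cb_anchor_residues(tpl$klass == "cbEGF_like")
    fixed <- c(fixed, anchors)
  }
  payloads <- purrr::map(tpl$motif_payloads, function(p) {
    start <- if (p$after_cys == 0L) p$offset
             else cys[p$after_cys] + 1L + p$offset
    motif <- strsplit(p$motif, "")[[1]]
    end <- start + length(motif)
    limit <- if (p$after_cys < length(cys)) cys[p$after_cys + 1L] else len
    if (end > limit) {
      abort(paste0("payload ", p$motif, " does not fit in ", tpl$klass,
                   " template"))
    }
    chars[(start + 1L):end] <<- motif
    tibble(motif = p$motif, start = start, end = end)
  })
  payloads <- if (length(payloads)) bind_rows(payloads) else
    tibble(motif = character(), start = integer(), end = integer())
  fixed <- sort(unique(c(fixed, unlist(purrr::map2(
    payloads$start, payloads$end, ~ seq(.x, .y - 1L)
  )))))
  list(chars = chars, cys = cys, fixed = fixed, payloads = payloads)
}

# resample the free residues of a realized domain until the classifier
# reproduces the template class (prevents chance calcium-binding consensus
# or broken signatures)
realize_template_checked <- function(tpl, base_w, unique_w, context,
                                     config = domain_scan_config()) {
  for (try in 1:100) {
    r <- realize_template(tpl, base_w, unique_w)
    if (tpl$klass == "UNIQUE") return(r)
    cls <- classify_segment(paste(r$chars, collapse = ""), context = context,
                            config = config)
    if (cls$klass == tpl$klass) return(r)
  }
  abort(paste0("failed to realize a ", tpl$klass,
               " domain matching its own class"))
}

# motif positions that are allowed: payloads plus any furin inside terminals
spurious_motifs <- function(chars, map, payloads) {
  seq <- paste(chars, collapse = "")
  bad <- list()
  rgd <- find_exact(seq, "RGD")
  for (s in rgd) {
    if (!any(payloads$motif == "RGD" & payloads$start == s)) {
      bad <- c(bad, list(c(s, s + 3L)))
    }
  }
  terminals <- filter(map, .data$klass %in% c("NTERM", "CTERM"))
  fur <- find_furin(seq)
  for (s in fur) {
    inside <- any(s >= terminals$start & (s + 4L) <= terminals$end)
    if (!inside) bad <- c(bad, list(c(s, s + 4L)))
  }
  bad
}

# 0-based match starts
find_exact <- function(seq, motif) {
  hits <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits) - 1L
}

find_furin <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 4L) return(integer())
  i <- seq_len(n - 3L)
  which(chars[i] == "R" & chars[i + 2L] %in% c("K", "R") &
          chars[i + 3L] == "R") - 1L
}

#' Generate a fibrillin-like record from an architecture profile
#'
#' Realizes every domain template in order: cysteines at the templated
#' offsets, motif payloads in place, calcium-binding consensus anchors in
#' cbEGF templates (cbEGF-like templates carry the same anchors with a
#' leading residue outside D/N). Free residues are sampled from the
#' profile's composition weights (uniform over the 19 non-Cys residues
#' outside the unique region). The returned map is the exact ground truth;
#' the same seed gives identical output.
#'
#' @param profile an [architecture_profile()]
#' @param seed integer seed
#' @param id record identifier (defaults to the profile's isoform label)
#' @param species species label stored with the record
#' @return a list with `record` (tibble: `id`, `species`, `isoform`,
#'   `sequence`), `map` (the ground-truth `domain_map`) and `payloads`
#'   (motif payload coordinates)
#' @export
generate_architecture <- function(profile, seed, id = NULL,
                                  species = "synthetic") {
  if (!inherits(profile, "architecture_profile")) {
    abort("profile must be an architecture_profile")
  }
  id <- id %||% profile$isoform
  with_local_seed(seed, {
    base_w <- residue_weights(NULL)
    unique_w <- residue_weights(profile$unique_weights)
    n <- length(profile$templates)
    parts <- vector("list", n)
    for (i in seq_len(n)) {
      tpl <- profile$templates[[i]]
      parts[[i]] <- realize_template_checked(
        tpl, base_w, unique_w,
        context = list(leading = i == 1L, trailing = i == n)
      )
    }
    lens <- vapply(parts, function(p) length(p$chars), integer(1))
    starts <- cumsum(c(0L, lens[-n]))
    chars <- unlist(purrr::map(parts, "chars"))
    map <- build_truth_map(profile, parts, starts, id)
    payloads <- payload_table(profile, parts, starts, map)
    # purge motif signatures arising by chance (incl. junction-spanning)
    for (iter in 1:100) {
      bad <- spurious_motifs(chars, map, payloads)
      if (!length(bad)) break
      fixed <- fixed_positions(parts, starts)
      for (b in bad) {
        idx <- setdiff(seq(b[1], b[2] - 1L), fixed)
        if (!length(idx)) next
        in_unique <- map$klass == "UNIQUE" &
          map$start <= idx[1] & idx[1] < map$end
        w <- if (any(in_unique)) unique_w else base_w
        chars[idx + 1L] <- sample_residues(length(idx), w)
      }
    }
    record <- tibble(id = id, species = species, isoform = profile$isoform,
                     sequence = paste(chars, collapse = ""))
    list(record = record, map = map, payloads = payloads)
  })
}

fixed_positions <- function(parts, starts) {
  sort(unique(unlist(purrr::map2(parts, starts, ~ .x$fixed + .y))))
}

payload_table <- function(profile, parts, starts, map) {
  rows <- purrr::pmap(
    list(parts, starts, seq_along(parts)),
    function(p, s, i) {
      if (!nrow(p$payloads)) return(NULL)
      mutate(p$payloads, start = .data$start + s, end = .data$end + s,
             template = i)
    }
  )
  out <- bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(motif = character(), start = integer(), end = integer(),
                  domain_id = character()))
  }
  seg <- filter(map, .data$klass != "GAP")
  out$domain_id <- purrr::map_chr(out$start, function(s) {
    hit <- which(seg$start <= s & s < seg$end)
    if (length(hit)) seg$domain_id[hit[1]] else "outside"
  })
  select(out, "motif", "start", "end", "domain_id")
}

build_truth_map <- function(profile, parts, starts, id) {
  n <- length(parts)
  rows <- purrr::pmap(
    list(profile$templates, parts, starts, seq_len(n)),
    function(tpl, p, s, i) {
      len <- length(p$chars)
      if (tpl$klass == "UNIQUE") {
        return(tibble(
          record = id, domain_id = "UNIQUE", klass = "UNIQUE",
          ordinal = 1L, start = s, end = s + len, ncys = 0L,
          cys = list(integer()), cb_status = "not_applicable",
          note = "cysteine-free region after TB1"
        ))
      }
      cls <- classify_segment(paste(p$chars, collapse = ""),
                              context = list(leading = i == 1L,
                                             trailing = i == n))
      tibble(record = id, domain_id = NA_character_, klass = cls$klass,
             ordinal = NA_integer_, start = s, end = s + len,
             ncys = length(p$cys), cys = list(p$cys + s),
             cb_status = cls$cb_status, note = cls$note)
    }
  )
  map <- bind_rows(rows) |>
    group_by(.data$klass) |>
    mutate(ordinal = as.integer(row_number())) |>
    ungroup() |>
    mutate(domain_id = dplyr::if_else(
      .data$klass %in% c("NTERM", "CTERM", "UNIQUE"),
      .data$klass, paste0(.data$klass, .data$ordinal)
    ))
  total <- sum(vapply(parts, function(p) length(p$chars), integer(1)))
  new_domain_map(map, total, id)
}

# ------------------------------------------------------------------------
# event scripts and family evolution

#' Event script for family evolution
#'
#' @param tree an `ape::phylo` (or Newick string) with branch lengths in
#'   expected substitutions per site and named internal nodes; tips are the
#'   final locus identifiers
#' @param duplications names of internal nodes that represent gene
#'   duplications (metadata recorded in the event log)
#' @param edits tibble of scripted branch edits applied on the branch above
#'   the named node: columns `node`, `type` (`"motif_sub"` or
#'   `"unique_swap"`), `domain`, `from`, `to`
#' @return an object of class `event_script`
#' @export
event_script <- function(tree, duplications = character(), edits = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) abort("tree must be a phylo or Newick string")
  if (is.null(tree$edge.length)) abort("script tree needs branch lengths")
  if (any(tree$edge.length < 0)) abort("branch lengths must be >= 0")
  if (length(tree$tip.label) < 2L) abort("script tree needs >= 2 tips")
  known <- c(tree$tip.label, tree$node.label)
  bad <- setdiff(duplications, known)
  if (length(bad)) {
    abort(paste0("duplication node(s) not in tree: ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(edits)) {
    edits <- as_tibble(edits)
    need <- c("node", "type", "domain")
    if (!all(need %in% names(edits))) {
      abort("edits need columns node, type, domain")
    }
    bad <- setdiff(edits$node, known)
    if (length(bad)) {
      abort(paste0("edit node(s) not in tree: ", paste(bad, collapse = ", ")))
    }
  }
  structure(list(tree = tree, duplications = duplications, edits = edits),
            class = "event_script")
}

# protected positions (0-based) derived from a state's map and payloads
protected_positions <- function(chars, map, payloads) {
  prot <- which(chars == "C") - 1L
  cb <- filter(map, .data$klass %in% c("cbEGF", "cbEGF_like"))
  if (nrow(cb)) {
    anchors <- unlist(purrr::map(cb$cys, function(cys) {
      cb_anchor_offsets(cys[1])
    }))
    prot <- c(prot, anchors)
  }
  if (nrow(payloads)) {
    prot <- c(prot, unlist(purrr::map2(payloads$start, payloads$end,
                                       ~ seq(.x, .y - 1L))))
  }
  sort(unique(prot))
}

mutate_branch <- function(chars, t, model, protected) {
  if (t == 0) return(chars)
  P <- transition_matrix(model, t)
  states <- match(chars, AA_ALPHABET)
  free <- setdiff(seq_along(chars), protected + 1L)
  ci <- match("C", AA_ALPHABET)
  for (a in unique(states[free])) {
    idx <- free[states[free] == a]
    p <- P[a, ]
    if (a != ci) p[ci] <- 0
    p <- p / sum(p)
    chars[idx] <- sample(AA_ALPHABET, length(idx), replace = TRUE, prob = p)
  }
  chars
}

# revert child-side changes that create spurious signatures or flip a class
fix_signatures <- function(chars, parent, map, payloads) {
  for (iter in 1:20) {
    dirty <- FALSE
    bad <- spurious_motifs(chars, map, payloads)
    for (b in bad) {
      idx <- seq(b[1] + 1L, b[2])
      changed <- idx[chars[idx] != parent[idx]]
      if (length(changed)) {
        chars[changed] <- parent[changed]
        dirty <- TRUE
      }
    }
    egf <- filter(map, .data$klass %in% c("EGF", "cbEGF", "cbEGF_like"))
    for (i in seq_len(nrow(egf))) {
      idx <- seq(egf$start[i] + 1L, egf$end[i])
      cls <- classify_segment(paste(chars[idx], collapse = ""))
      if (cls$klass != egf$klass[i]) {
        changed <- idx[chars[idx] != parent[idx]]
        chars[changed] <- parent[changed]
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  chars
}

apply_edit <- function(state, edit, base_w) {
  if (edit$type == "motif_sub") {
    seg <- filter(state$map, .data$domain_id == edit$domain)
    if (!nrow(seg)) {
      abort(paste0("scripted edit names missing domain ", edit$domain))
    }
    hit <- filter(state$payloads, .data$domain_id == edit$domain,
                  .data$motif == edit$from)
    if (!nrow(hit)) {
      abort(paste0("no ", edit$from, " payload in ", edit$domain))
    }
    if (hit$start[1] < seg$start || hit$end[1] > seg$end) {
      abort("scripted edit coordinates fall outside the named domain")
    }
    if (nchar(edit$from) != nchar(edit$to)) {
      abort("motif_sub edits must preserve length")
    }
    idx <- seq(hit$start[1] + 1L, hit$end[1])
    state$chars[idx] <- strsplit(edit$to, "")[[1]]
    state$payloads$motif[state$payloads$domain_id == edit$domain &
                           state$payloads$start == hit$start[1]] <- edit$to
    return(state)
  }
  if (edit$type == "unique_swap") {
    return(apply_unique_swap(state, base_w))
  }
  abort(paste0("unknown edit type ", edit$type))
}

# swap the unique region (+ following EGF) for a cbEGF-like + cbEGF pair,
# or back; rebuilds coordinates downstream of the splice
apply_unique_swap <- function(state, base_w) {
  map <- state$map
  urow <- which(map$klass == "UNIQUE")
  if (length(urow)) {
    rows <- c(urow, urow + 1L)
    if (rows[2] > nrow(map) || map$klass[rows[2]] != "EGF") {
      abort("unique_swap expects the unique region followed by an EGF domain")
    }
    new_tpls <- list(default_template("cbEGF_like"), default_template("cbEGF"))
  } else {
    crow <- which(map$klass == "cbEGF_like")
    if (!length(crow)) {
      abort("unique_swap: map has neither a unique region nor a cbEGF-like")
    }
    rows <- c(crow[1], crow[1] + 1L)
    if (rows[2] > nrow(map) || map$klass[rows[2]] != "cbEGF") {
      abort("unique_swap expects cbEGF-like followed by cbEGF")
    }
    new_tpls <- list(default_template("UNIQUE"), default_template("EGF"))
  }
  at <- map$start[rows[1]]
  old_end <- map$end[rows[2]]
  n <- nrow(map)
  parts <- purrr::map(seq_along(new_tpls), function(i) {
    realize_template_checked(
      new_tpls[[i]], base_w, residue_weights(NULL),
      context = list(leading = FALSE, trailing = FALSE)
    )
  })
  new_chars <- unlist(purrr::map(parts, "chars"))
  delta <- (at + length(new_chars)) - old_end
  chars <- c(
    state$chars[seq_len(at)],
    new_chars,
    if (old_end < length(state$chars))
      state$chars[(old_end + 1L):length(state$chars)]
  )
  lens <- vapply(parts, function(p) length(p$chars), integer(1))
  starts <- at + cumsum(c(0L, lens[-length(lens)]))
  new_rows <- purrr::pmap(
    list(new_tpls, parts, starts),
    function(tpl, p, s) {
      if (tpl$klass == "UNIQUE") {
        tibble(record = map$record[1], domain_id = "UNIQUE", klass = "UNIQUE",
               ordinal = 1L, start = s, end = s + length(p$chars), ncys = 0L,
               cys = list(integer()), cb_status = "not_applicable",
               note = "cysteine-free region after TB1")
      } else {
        cls <- classify_segment(paste(p$chars, collapse = ""))
        tibble(record = map$record[1], domain_id = NA_character_,
               klass = cls$klass, ordinal = NA_integer_, start = s,
               end = s + length(p$chars), ncys = length(p$cys),
               cys = list(p$cys + s), cb_status = cls$cb_status,
               note = cls$note)
      }
    }
  )
  after <- map[setdiff(seq_len(n), seq_len(rows[2])), ] |>
    filter(.data$start >= old_end) |>
    mutate(start = .data$start + delta, end = .data$end + delta,
           cys = purrr::map(.data$cys, ~ .x + delta))
  before <- map[seq_len(rows[1] - 1L), ]
  map2 <- bind_rows(before, bind_rows(new_rows), after) |>
    group_by(.data$klass) |>
    mutate(ordinal = dplyr::if_else(.data$klass == "GAP", NA_integer_,
                                    as.integer(row_number()))) |>
    ungroup() |>
    mutate(domain_id = dplyr::if_else(
      is.na(.data$ordinal), NA_character_,
      dplyr::if_else(.data$klass %in% c("NTERM", "CTERM", "UNIQUE"),
                     .data$klass, paste0(.data$klass, .data$ordinal))
    ))
  payloads <- state$payloads |>
    filter(.data$start < at | .data$start >= old_end) |>
    mutate(shift = dplyr::if_else(.data$start >= old_end, delta, 0L),
           start = .data$start + .data$shift,
           end = .data$end + .data$shift) |>
    select(-"shift")
  state$chars <- chars
  state$map <- new_domain_map(map2, length(chars), map$record[1])
  state$payloads <- payloads
  state
}

#' Evolve a fibrillin family along a duplication tree
#'
#' Evolves the root record tip-ward along the script's tree: sites mutate
#' under the substitution model (cysteines, motif payloads and consensus
#' anchors are protected; substitutions never create new cysteines, and the
#' rare draws that would create a spurious RGD/furin/consensus signature
#' are reverted), duplication nodes start two independently evolving loci,
#' and scripted edits are applied after the branch substitution so they are
#' always observable at descendant tips.
#'
#' @param root record tibble (or the list returned by
#'   [generate_architecture()])
#' @param root_map ground-truth `domain_map` of the root (taken from `root`
#'   when it is a `generate_architecture()` result)
#' @param script an [event_script()]
#' @param model an [jtt_model()]
#' @param seed integer seed
#' @return an object of class `simulated_family`: `records` (one per tip
#'   locus), `truth_tree`, `truth_maps`, `events`, `model`
#' @examples
#' fam <- simulate_fibrillin_family(seed = 1, branch_length = 0.05)
#' fam$records$id
#' @export
evolve_family <- function(root, root_map = NULL, script, model = jtt_model(),
                          seed = 1L) {
  if (is.list(root) && !is.data.frame(root) && !is.null(root$record)) {
    root_map <- root$map
    root_payloads <- root$payloads
    root <- root$record
  } else {
    root_payloads <- NULL
  }
  if (is.null(root_map)) abort("root_map is required")
  if (!inherits(script, "event_script")) abort("script must be an event_script")
  seq_len_root <- nchar(root$sequence[[1]])
  if (sum(root_map$end - root_map$start) != seq_len_root) {
    abort("root_map does not tile the root sequence")
  }
  tree <- script$tree
  with_local_seed(seed, {
    chars <- strsplit(root$sequence[[1]], "")[[1]]
    if (is.null(root_payloads)) {
      root_payloads <- rescan_payloads(chars, root_map)
    }
    base_w <- residue_weights(NULL)
    ntip <- length(tree$tip.label)
    nnode_total <- ntip + tree$Nnode
    states <- vector("list", nnode_total)
    root_node <- ntip + 1L
    states[[root_node]] <- list(chars = chars, map = root_map,
                                payloads = root_payloads)
    events <- list()
    nl <- tree$node.label
    node_name <- function(v) {
      if (v <= ntip) return(tree$tip.label[v])
      if (!is.null(nl) && length(nl) >= v - ntip && nzchar(nl[v - ntip])) {
        nl[v - ntip]
      } else {
        paste0("node", v)
      }
    }
    for (dup in script$duplications) {
      events <- c(events, list(tibble(node = dup, type = "duplication",
                                      detail = "two child loci")))
    }
    ro <- ape::reorder.phylo(tree, "cladewise")
    edge_order <- ro$edge
    el <- ro$edge.length
    for (e in seq_len(nrow(edge_order))) {
      u <- edge_order[e, 1]; v <- edge_order[e, 2]
      st <- states[[u]]
      prot <- protected_positions(st$chars, st$map, st$payloads)
      child <- st
      child$chars <- mutate_branch(st$chars, el[e], model, prot)
      child$chars <- fix_signatures(child$chars, st$chars, st$map, st$payloads)
      vn <- node_name(v)
      if (!is.null(script$edits)) {
        todo <- filter(script$edits, .data$node == vn)
        for (i in seq_len(nrow(todo))) {
          child <- apply_edit(child, as.list(todo[i, ]), base_w)
          events <- c(events, list(tibble(
            node = vn, type = todo$type[i],
            detail = paste0(todo$domain[i], ": ",
                            todo$from[i] %||% "", " -> ", todo$to[i] %||% "")
          )))
        }
      }
      states[[v]] <- child
    }
    records <- purrr::map(seq_len(ntip), function(tip) {
      tibble(id = tree$tip.label[tip],
             species = sub("_[^_]*$", "", tree$tip.label[tip]),
             isoform = sub("^.*_", "", tree$tip.label[tip]),
             sequence = paste(states[[tip]]$chars, collapse = ""))
    }) |> bind_rows()
    truth_maps <- purrr::map(seq_len(ntip), function(tip) {
      m <- states[[tip]]$map
      m$record <- tree$tip.label[tip]
      attr(m, "record") <- tree$tip.label[tip]
      m
    })
    names(truth_maps) <- tree$tip.label
    structure(
      list(records = records, truth_tree = tree, truth_maps = truth_maps,
           events = bind_rows(events), model = model,
           duplications = script$duplications),
      class = "simulated_family"
    )
  })
}

# recover payload coordinates from a clean (simulator-grade) sequence
rescan_payloads <- function(chars, map) {
  seq <- paste(chars, collapse = "")
  seg <- filter(map, .data$klass != "GAP")
  locate <- function(starts, width, motif) {
    purrr::map(starts, function(s) {
      hit <- which(seg$start <= s & s < seg$end)
      tibble(motif = motif, start = s, end = s + width,
             domain_id = if (length(hit)) seg$domain_id[hit[1]] else "outside")
    })
  }
  bind_rows(c(locate(find_exact(seq, "RGD"), 3L, "RGD"),
              locate(find_furin(seq), 4L, "FURIN")))
}

#' @export
print.simulated_family <- function(x, ...) {
  cat("Simulated fibrillin family:", nrow(x$records), "tip loci,",
      length(x$duplications), "duplication(s)\n")
  invisible(x)
}

# ------------------------------------------------------------------------
# default study family: a single-fibrillin clade plus the two nested
# duplications giving the fibrillin-1 / -2 / -3 clades

# balanced subtree over tip labels; returns Newick without the top branch
balanced_clade <- function(labels, bl) {
  if (length(labels) == 1L) return(labels)
  half <- ceiling(length(labels) / 2)
  paste0("(", balanced_clade(labels[seq_len(half)], bl), ":", bl, ",",
         balanced_clade(labels[-seq_len(half)], bl), ":", bl, ")")
}

#' Truth tree and event script of the default simulated family
#'
#' The locus tree has four clades: a single-fibrillin clade (pre-duplication
#' lineage) and the fibrillin-1, -2 and -3 clades produced by two nested
#' duplications (`dup1`, then `dup2` on the fibrillin-2/3 lineage), each
#' clade containing `n_species` species. All branches have the same length.
#'
#' @param n_species species per clade (default 3, i.e. 12 tip loci)
#' @param branch_length branch length in substitutions/site (default 0.1)
#' @return an [event_script()]; the default edits remove the TB3 RGD site on
#'   the fibrillin-1 stem (RGD to RGE) and degrade it on the fibrillin-3
#'   stem (RGD to RAD)
#' @export
fibrillin_event_script <- function(n_species = 3L, branch_length = 0.1) {
  if (n_species < 2L) abort("n_species must be >= 2")
  bl <- branch_length
  clade <- function(iso) {
    labs <- paste0("sp", seq_len(n_species), "_", iso)
    paste0(balanced_clade(labs, bl), "anc_", iso)
  }
  nwk <- paste0(
    "(", clade("FBN"), ":", bl, ",((", clade("FBN2"), ":", bl, ",",
    clade("FBN3"), ":", bl, ")dup2:", bl, ",", clade("FBN1"), ":", bl,
    ")dup1:", bl, ")root;"
  )
  edits <- tibble(
    node = c("anc_FBN1", "anc_FBN3"),
    type = "motif_sub", domain = "TB3",
    from = "RGD", to = c("RGE", "RAD")
  )
  event_script(ape::read.tree(text = nwk),
               duplications = c("dup1", "dup2"), edits = edits)
}

#' Simulate the default fibrillin family
#'
#' Generates the ancestral chordate-like architecture (vertebrate backbone
#' with RGD sites in TB3 and TB4) and evolves it along
#' [fibrillin_event_script()]'s tree.
#'
#' @inheritParams fibrillin_event_script
#' @param seed integer seed
#' @param model substitution model used for simulation (default plain JTT)
#' @param script optional [event_script()] overriding the default
#' @return a `simulated_family`
#' @export
simulate_fibrillin_family <- function(seed, n_species = 3L,
                                      branch_length = 0.1,
                                      model = jtt_model(), script = NULL) {
  script <- script %||% fibrillin_event_script(n_species, branch_length)
  root_profile <- architecture_profile(
    fibrillin_backbone(vertebrate_post_tb1, rgd_tb3 = TRUE, rgd_tb4 = TRUE),
    isoform = "FBNanc", unique_weights = c(G = 0.30, P = 0.30)
  )
  root <- generate_architecture(root_profile, seed = seed, id = "root")
  evolve_family(root, script = script, model = model, seed = seed + 1L)
}

#' Bipartitions of the two duplication events
#'
#' @param family a `simulated_family` from [simulate_fibrillin_family()]
#' @return named list of tip-label vectors: `dup1` (all fibrillin-1/2/3
#'   loci versus the single-fibrillin clade) and `dup2` (the fibrillin-2/3
#'   loci versus the rest)
#' @export
duplication_splits <- function(family) {
  ids <- family$records$id
  iso <- family$records$isoform
  list(
    dup1 = ids[iso %in% c("FBN1", "FBN2", "FBN3")],
    dup2 = ids[iso %in% c("FBN2", "FBN3")]
  )
}

# ------------------------------------------------------------------------
# writers

#' Write a simulated family to disk
#'
#' FASTA records, ground-truth maps as TSV (0-based half-open), the truth
#' tree as Newick and the event log as TSV.
#'
#' @param family a `simulated_family`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_family <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(family$records, file.path(dir, "records.fasta"))
  maps <- bind_rows(family$truth_maps)
  write_annotation_tsv(maps, file.path(dir, "truth_maps.tsv"))
  ape::write.tree(family$truth_tree, file.path(dir, "truth_tree.nwk"))
  readr::write_tsv(family$events, file.path(dir, "events.tsv"))
  invisible(dir)
}

#' Read and write protein FASTA
#'
#' @param records tibble with `id` and `sequence`
#' @param path file path
#' @name fasta-io
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname fasta-io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  tibble(id = names(x), sequence = unname(as.character(x)))
}
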