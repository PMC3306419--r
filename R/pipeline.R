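# Full-analysis orchestration: annotate -> motif/composition reports ->
# alignment -> per-TB-domain, concatenated-TB and complete-sequence trees
# -> bootstrap supports for named splits -> report bundle.

#' Pipeline run configuration
#'
#' Defaults mirror the study design: 1000 bootstrap replicates, 0.5
#' consensus threshold, JTT+I+Gamma (4 categories) for likelihood, plain
#' JTT for distances, NNI search, gap-only column stripping, 50% gap
#' exclusion for per-domain slices.
#'
#' @param fasta input FASTA path (mutually exclusive with passing records
#'   to [run_pipeline()] directly)
#' @param msa_fasta optional pre-computed aligned FASTA to ingest instead
#'   of running the internal aligner
#' @param outgroup identifiers used as outgroup/reroot target (may be
#'   empty)
#' @param reference record id whose domain map anchors the slices (default:
#'   first record)
#' @param per_domain,concatenated,complete,run_ml analysis toggles
#' @param motifs,composition report toggles
#' @param B bootstrap replicate count (>= 1)
#' @param seed integer seed (required whenever a stochastic stage runs)
#' @param consensus_threshold majority-rule threshold
#' @param gap_exclusion slice gap fraction above which a record is dropped
#' @param unique_min_len minimum unique-region length
#' @param p_inv,alpha,n_categories likelihood model settings (`NULL` alpha
#'   disables gamma)
#' @param estimate_rates estimate `alpha`/`p_inv` on the concatenated
#'   alignment before the likelihood analyses
#' @return a list of class `run_config`
#' @export
fibevo_config <- function(fasta = NULL, msa_fasta = NULL,
                          outgroup = character(), reference = NULL,
                          per_domain = TRUE, concatenated = TRUE,
                          complete = TRUE, run_ml = TRUE, motifs = TRUE,
                          composition = TRUE, B = 1000L, seed = 1L,
                          consensus_threshold = 0.5, gap_exclusion = 0.5,
                          unique_min_len = 30L, p_inv = 0.05, alpha = 1,
                          n_categories = 4L, estimate_rates = FALSE) {
  if (B < 1L) abort("B must be >= 1")
  if (is.null(seed)) abort("a seed is required for the stochastic stages")
  structure(
    list(fasta = fasta, msa_fasta = msa_fasta, outgroup = outgroup,
         reference = reference, per_domain = per_domain,
         concatenated = concatenated, complete = complete, run_ml = run_ml,
         motifs = motifs, composition = composition, B = as.integer(B),
         seed = as.integer(seed),
         consensus_threshold = consensus_threshold,
         gap_exclusion = gap_exclusion,
         unique_min_len = as.integer(unique_min_len), p_inv = p_inv,
         alpha = alpha, n_categories = as.integer(n_categories),
         estimate_rates = estimate_rates),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with `fibevo_config()` fields
#' @return a `run_config`
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(fibevo_config, vals)
}

config_fingerprint <- function(config) {
  vals <- config[order(names(config))]
  paste(
    vapply(names(vals), function(n) {
      paste0(n, "=", paste(format(vals[[n]]), collapse = ","))
    }, character(1)),
    collapse = "; "
  )
}

#' Run the full comparative pipeline
#'
#' Annotates every record, reports motifs and unique-region composition,
#' aligns the records (or ingests a provided alignment), builds the
#' per-TB-domain distance trees, the concatenated-TB tree and the
#' complete-sequence tree (distance-based, plus maximum likelihood for the
#' concatenated and complete analyses), and collects bootstrap supports
#' for the named splits. Fully seed-deterministic.
#'
#' @param config a [fibevo_config()]
#' @param records optional record tibble (`id`, `sequence`, ...) used
#'   instead of `config$fasta` (e.g. a `simulated_family$records`)
#' @param splits named list of tip sets whose supports are tabulated
#'   (defaults to no support table)
#' @param out_dir optional output directory for the report artifacts
#' @return a list of class `report_bundle`: `annotations`, `motif_hits`,
#'   `composition`, `msa`, `trees` (named list of consensus trees),
#'   `supports`, `log`, `fingerprint`
#' @export
run_pipeline <- function(config, records = NULL, splits = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  note("fibevo pipeline; fingerprint: ", config_fingerprint(config))

  if (is.null(records)) {
    if (is.null(config$fasta)) abort("no input records or FASTA given")
    records <- read_fasta(config$fasta)
  }
  if (!"isoform" %in% names(records)) {
    records$isoform <- sub("^.*_", "", records$id)
  }

  # annotation ------------------------------------------------------------
  maps <- list()
  kept <- character()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    m <- tryCatch(find_domains(rec), error = function(e) e)
    if (inherits(m, "error")) {
      note("record ", rec$id, " excluded: annotation failed (",
           conditionMessage(m), ")")
      next
    }
    if (any(m$klass == "UNKNOWN")) {
      note("record ", rec$id, " carries UNKNOWN segments")
    }
    maps[[rec$id]] <- m
    kept <- c(kept, rec$id)
  }
  records <- records[records$id %in% kept, ]
  annotations <- bind_rows(maps)

  # motifs and composition ------------------------------------------------
  motif_hits <- NULL
  if (config$motifs) {
    motif_hits <- bind_rows(lapply(kept, function(id) {
      rec <- records[records$id == id, ]
      bind_rows(scan_rgd(rec, maps[[id]]), scan_furin(rec, maps[[id]]))
    }))
  }
  composition <- NULL
  if (config$composition) {
    regions <- unique_regions(records, maps, config$unique_min_len)
    if (nrow(regions)) composition <- group_summary(regions)
    else note("no unique regions found; composition report empty")
  }

  # alignment -------------------------------------------------------------
  trees <- list()
  supports <- NULL
  msa <- NULL
  run_trees <- config$per_domain || config$concatenated || config$complete
  if (run_trees && nrow(records) < 4L) {
    abort("tree stages need at least 4 records")
  }
  if (run_trees) {
    msa <- if (!is.null(config$msa_fasta)) {
      note("ingesting external alignment: ", config$msa_fasta)
      read_msa_fasta(config$msa_fasta)
    } else {
      progressive_msa(records)
    }
    msa <- strip_gap_only_columns(msa)
    ref_id <- config$reference %||% records$id[1]
    ref_map <- maps[[ref_id]]
    dist_model <- jtt_model()
    ml_model <- jtt_model(p_inv = config$p_inv, alpha = config$alpha,
                          n_categories = config$n_categories)

    tb_ids <- ref_map$domain_id[ref_map$klass == "TB"]
    slices <- NULL
    if (config$per_domain || config$concatenated) {
      slices <- lapply(tb_ids, function(d) {
        extract_domain_alignment(msa, ref_map, d, drop_gapped = TRUE,
                                 gap_threshold = config$gap_exclusion)
      })
      names(slices) <- tb_ids
    }
    if (config$per_domain) {
      for (d in tb_ids) {
        if (length(slices[[d]]$ids) < 4L) {
          note("slice ", d, " has fewer than 4 records; skipped")
          next
        }
        bs <- nj_bootstrap(slices[[d]], dist_model, config$B,
                           seed = config$seed + match(d, tb_ids),
                           threshold = config$consensus_threshold)
        trees[[d]] <- bs$consensus
      }
    }
    if (config$concatenated) {
      concat <- concatenate_alignments(unname(slices))
      concat <- strip_gap_only_columns(concat)
      if (config$estimate_rates && config$run_ml) {
        start <- neighbor_joining(protein_distance_matrix(concat, dist_model))
        fitp <- fit_rate_parameters(start, concat,
                                    gamma = !is.null(config$alpha),
                                    inv = config$p_inv > 0,
                                    n_categories = config$n_categories)
        ml_model <- fitp$model
        note("estimated rates on concatenated alignment: alpha = ",
             format(fitp$alpha), ", p_inv = ", format(fitp$p_inv))
      }
      bs <- nj_bootstrap(concat, dist_model, config$B,
                         seed = config$seed + 101L,
                         threshold = config$consensus_threshold)
      trees[["concatenated_db"]] <- bs$consensus
      if (config$run_ml) {
        mb <- ml_bootstrap(concat, ml_model, config$B,
                           seed = config$seed + 102L,
                           threshold = config$consensus_threshold)
        trees[["concatenated_ml"]] <- mb$consensus
      }
    }
    if (config$complete) {
      bs <- nj_bootstrap(msa, dist_model, config$B, seed = config$seed + 103L,
                         threshold = config$consensus_threshold)
      trees[["complete_db"]] <- bs$consensus
      if (config$run_ml) {
        mb <- ml_bootstrap(msa, ml_model, config$B,
                           seed = config$seed + 104L,
                           threshold = config$consensus_threshold)
        trees[["complete_ml"]] <- mb$consensus
      }
    }
    if (length(config$outgroup)) {
      trees <- lapply(trees, function(tr) {
        og <- intersect(config$outgroup, tr$tip.label)
        if (length(og)) reroot_at_clade(tr, og) else tr
      })
    }
    if (!is.null(splits) && length(trees)) {
      supports <- support_comparison(trees, splits)
    }
  }

  bundle <- structure(
    list(annotations = annotations, motif_hits = motif_hits,
         composition = composition, msa = msa, trees = trees,
         supports = supports, records = records, log = log,
         fingerprint = config_fingerprint(config)),
    class = "report_bundle"
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("fibevo report bundle:", nrow(x$records), "records;",
      length(x$trees), "tree analyses\n")
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' GFF3 + TSV annotations, TSV motif/composition/support tables, Newick
#' trees and the run log.
#'
#' @param bundle a `report_bundle`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation_tsv(bundle$annotations, file.path(dir, "domains.tsv"))
  write_annotation_gff3(bundle$annotations, file.path(dir, "domains.gff3"))
  if (!is.null(bundle$motif_hits)) {
    write_motif_tsv(bundle$motif_hits, file.path(dir, "motifs.tsv"))
  }
  if (!is.null(bundle$composition)) {
    write_composition_tsv(bundle$composition, file.path(dir, "composition.tsv"))
  }
  if (!is.null(bundle$msa)) {
    write_msa_fasta(bundle$msa, file.path(dir, "alignment.fasta"))
  }
  for (nm in names(bundle$trees)) {
    ape::write.tree(bundle$trees[[nm]], file.path(dir, paste0(nm, ".nwk")))
  }
  if (!is.null(bundle$supports)) {
    write_support_tsv(bundle$supports, file.path(dir, "supports.tsv"))
  }
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}
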