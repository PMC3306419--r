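# Domain grammar for the fibrillin-family simulator.
#
# Every fibrillin domain class is defined by its cysteine count and the runs
# of non-cysteine residues between them (plus leading/trailing flanks):
#   EGF / cbEGF / cbEGF_like : 6 Cys
#   TB                       : 8 Cys with the triple Cys-Cys-Cys (Cys3-5)
#   HYBRID8                  : 8 Cys with the tandem Cys-Cys at 4-5
#   HYBRID9                  : 9 Cys, extra cysteine after Cys2
#   HYBRID10                 : 10 Cys, Cys4a/Cys6a as in arthropod hybrid 2
#   NTERM / CTERM            : 4 / 2 Cys terminal domains with furin sites
#   UNIQUE                   : cysteine-free region after TB1

DOMAIN_CYS_COUNT <- c(
  EGF = 6L, cbEGF = 6L, cbEGF_like = 6L, TB = 8L, HYBRID8 = 8L,
  HYBRID9 = 9L, HYBRID10 = 10L, UNIQUE = 0L, NTERM = 4L, CTERM = 2L
)

# disulfide connectivity is annotation metadata only, never computed
DOMAIN_DISULFIDES <- c(
  EGF = "1-3, 2-4, 5-6", cbEGF = "1-3, 2-4, 5-6", cbEGF_like = "1-3, 2-4, 5-6",
  TB = "1-3, 2-6, 4-7, 5-8", HYBRID8 = "1-3, 2-5, 4-6, 7-8",
  HYBRID9 = "1-3, 2-5, 4-6, 7-8 (+1 unpaired)", HYBRID10 = "unknown",
  UNIQUE = "", NTERM = "unknown", CTERM = "unknown"
)

#' Domain template
#'
#' A template fixes a domain class, the inter-cysteine gap lengths (with
#' leading and trailing flanks) and optional fixed motif payloads placed at
#' an offset after a given cysteine (`after_cys = 0` counts from the domain
#' start).
#'
#' @param klass domain class label (EGF, cbEGF, cbEGF_like, TB, HYBRID8,
#'   HYBRID9, HYBRID10, UNIQUE, NTERM or CTERM)
#' @param cys_spacing integer vector `c(pre, gap12, ..., post)`; its length
#'   must be the class's cysteine count plus one (for `UNIQUE`, a single
#'   total length)
#' @param motif_payloads list of `list(motif=, after_cys=, offset=)`
#' @return an object of class `domain_template`
#' @export
domain_template <- function(klass, cys_spacing, motif_payloads = list()) {
  if (!klass %in% names(DOMAIN_CYS_COUNT)) {
    abort(paste0("unknown domain class: ", klass))
  }
  ncys <- DOMAIN_CYS_COUNT[[klass]]
  cys_spacing <- as.integer(cys_spacing)
  if (any(cys_spacing < 0)) abort("cys_spacing gaps must be >= 0")
  expected <- if (ncys == 0L) 1L else ncys + 1L
  if (length(cys_spacing) != expected) {
    abort(paste0(
      klass, " template needs ", expected, " gap lengths (",
      ncys, " cysteines), got ", length(cys_spacing)
    ))
  }
  structure(
    list(klass = klass, cys_spacing = cys_spacing,
         motif_payloads = motif_payloads,
         disulfides = DOMAIN_DISULFIDES[[klass]]),
    class = "domain_template"
  )
}

template_length <- function(tpl) {
  sum(tpl$cys_spacing) + DOMAIN_CYS_COUNT[[tpl$klass]]
}

# cysteine offsets (0-based) within a realized template
template_cys_offsets <- function(tpl) {
  ncys <- DOMAIN_CYS_COUNT[[tpl$klass]]
  if (ncys == 0L) return(integer())
  cumsum(tpl$cys_spacing[seq_len(ncys)] + 1L) - 1L
}

# interior flank shared by all default templates; boundaries between default
# domains therefore sit at the midpoint of a 2 * flank cysteine-free run
SYNTH_FLANK <- 7L

default_template <- function(klass, payloads = list()) {
  f <- SYNTH_FLANK
  spacing <- switch(klass,
    EGF        = c(f, 6, 4, 6, 3, 8, f),
    cbEGF      = c(f, 10, 4, 6, 3, 8, f),
    cbEGF_like = c(f, 10, 4, 6, 3, 8, f),
    TB         = c(f, 10, 8, 0, 0, 9, 8, 7, f),
    HYBRID8    = c(f, 9, 8, 7, 0, 9, 8, 6, f),
    HYBRID9    = c(f, 9, 4, 4, 7, 0, 9, 8, 6, f),
    HYBRID10   = c(f, 9, 8, 7, 0, 0, 9, 6, 0, 8, f),
    UNIQUE     = 58L,
    NTERM      = c(14, 6, 10, 6, f),
    CTERM      = c(8, 2, 16),
    abort(paste0("no default template for class ", klass))
  )
  domain_template(klass, spacing, payloads)
}

furin_payload <- function(offset, after_cys = 0L, motif = "RSKR") {
  list(motif = motif, after_cys = after_cys, offset = offset)
}

rgd_payload <- function(offset = 3L) {
  list(motif = "RGD", after_cys = 1L, offset = offset)
}

#' Architecture profile
#'
#' An ordered list of [domain_template()]s plus the isoform label and the
#' residue sampling weights of the unique region.
#'
#' @param templates list of `domain_template`s; `NTERM` first and `CTERM`
#'   last when present, at most one `UNIQUE`
#' @param isoform isoform label (e.g. `"FBN1"`)
#' @param unique_weights named numeric sampling weights for unique-region
#'   residues; unnamed mass is spread uniformly over the remaining non-Cys
#'   residues
#' @return an object of class `architecture_profile`
#' @export
architecture_profile <- function(templates, isoform,
                                 unique_weights = NULL) {
  if (!length(templates) ||
      !all(vapply(templates, inherits, logical(1), "domain_template"))) {
    abort("templates must be a non-empty list of domain_template objects")
  }
  klasses <- vapply(templates, function(t) t$klass, character(1))
  if (sum(klasses == "UNIQUE") > 1L) abort("at most one UNIQUE template")
  if ("NTERM" %in% klasses && klasses[1] != "NTERM") {
    abort("NTERM template must come first")
  }
  if ("CTERM" %in% klasses && klasses[length(klasses)] != "CTERM") {
    abort("CTERM template must come last")
  }
  structure(
    list(templates = templates, isoform = isoform,
         unique_weights = unique_weights),
    class = "architecture_profile"
  )
}

#' @export
print.architecture_profile <- function(x, ...) {
  klasses <- vapply(x$templates, function(t) t$klass, character(1))
  cat("Architecture profile:", x$isoform, "(", length(klasses), "domains )\n")
  cat(" ", paste(klasses, collapse = " - "), "\n")
  invisible(x)
}

# shared core: hybrid1 / cbEGF / TB backbone with per-isoform choices in the
# post-TB1 position (unique region vs cbEGF-like + cbEGF) and RGD payloads
fibrillin_backbone <- function(post_tb1, rgd_tb3, rgd_tb4,
                               hybrid2_klass = "HYBRID8") {
  tb_payload <- function(k) {
    if ((k == 3L && rgd_tb3) || (k == 4L && rgd_tb4)) list(rgd_payload())
    else list()
  }
  tbs <- lapply(1:7, function(k) default_template("TB", tb_payload(k)))
  c(
    list(
      default_template("NTERM", list(furin_payload(offset = 2L))),
      default_template("EGF"), default_template("EGF"),
      default_template("EGF"),
      default_template("HYBRID9"),
      default_template("cbEGF"),
      tbs[[1]]
    ),
    post_tb1,
    list(
      default_template("cbEGF"), default_template("cbEGF"),
      tbs[[2]],
      default_template("cbEGF"),
      tbs[[3]],
      default_template("cbEGF"),
      default_template(hybrid2_klass),
      default_template("cbEGF"),
      tbs[[4]],
      default_template("cbEGF"),
      tbs[[5]],
      default_template("cbEGF"),
      tbs[[6]],
      default_template("cbEGF"),
      tbs[[7]],
      default_template("cbEGF"),
      default_template("CTERM", list(furin_payload(offset = 4L,
                                                   after_cys = 2L)))
    )
  )
}

vertebrate_post_tb1 <- list(
  default_template("UNIQUE"), default_template("EGF")
)
ancestral_post_tb1 <- list(
  default_template("cbEGF_like"), default_template("cbEGF")
)

# unique-region composition weights follow the per-isoform enrichments of the
# three vertebrate paralogues (proline-rich, glycine-rich, mixed)
UNIQUE_WEIGHTS <- list(
  FBN1 = c(P = 0.40, V = 0.14),
  FBN2 = c(G = 0.38, P = 0.12),
  FBN3 = c(G = 0.24, P = 0.18, L = 0.16),
  FBN23 = c(G = 0.46, N = 0.16)
)

#' Built-in fibrillin-like architecture profiles
#'
#' `fibrillin1_profile()`, `fibrillin2_profile()` and `fibrillin3_profile()`
#' carry the vertebrate architecture (unique region after TB1, furin sites
#' in both terminal domains, RGD in TB4 and - for fibrillin-2 - also TB3).
#' `ancestral_profile()` is the single-fibrillin architecture in which the
#' unique region is replaced by a cbEGF-like domain followed by a true cbEGF
#' domain; `arthropod` swaps the second hybrid domain for the 10-cysteine
#' variant.
#'
#' @param arthropod use the 10-cysteine hybrid 2 domain (ancestral profile)
#' @param rgd include the chordate RGD sites in TB3/TB4 (ancestral profile)
#' @return an [architecture_profile()]
#' @export
fibrillin1_profile <- function() {
  architecture_profile(
    fibrillin_backbone(vertebrate_post_tb1, rgd_tb3 = FALSE, rgd_tb4 = TRUE),
    isoform = "FBN1", unique_weights = UNIQUE_WEIGHTS$FBN1
  )
}

#' @rdname fibrillin1_profile
#' @export
fibrillin2_profile <- function() {
  architecture_profile(
    fibrillin_backbone(vertebrate_post_tb1, rgd_tb3 = TRUE, rgd_tb4 = TRUE),
    isoform = "FBN2", unique_weights = UNIQUE_WEIGHTS$FBN2
  )
}

#' @rdname fibrillin1_profile
#' @export
fibrillin3_profile <- function() {
  architecture_profile(
    fibrillin_backbone(vertebrate_post_tb1, rgd_tb3 = FALSE, rgd_tb4 = TRUE),
    isoform = "FBN3", unique_weights = UNIQUE_WEIGHTS$FBN3
  )
}

#' @rdname fibrillin1_profile
#' @export
ancestral_profile <- function(arthropod = FALSE, rgd = TRUE) {
  architecture_profile(
    fibrillin_backbone(
      ancestral_post_tb1, rgd_tb3 = rgd, rgd_tb4 = rgd,
      hybrid2_klass = if (arthropod) "HYBRID10" else "HYBRID8"
    ),
    isoform = "FBN", unique_weights = NULL
  )
}
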