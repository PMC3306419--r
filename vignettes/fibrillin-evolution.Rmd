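---
title: "Methods: simulating and analysing fibrillin family evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing fibrillin family evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibevo)
```

## The scientific problem

Fibrillins are very large, cysteine-rich extracellular matrix glycoproteins
that form the core of microfibrils. Vertebrates carry up to three
paralogues (fibrillin-1, -2, -3) produced by two nested gene duplications
from a single ancestral gene that is still found in invertebrates and
jawless fish. The evidence for that history is phylogenetic: trees built
from the seven TB domains (individually and concatenated) and from the
complete sequences consistently separate a fibrillin-1 clade from a
fibrillin-2/3 clade, and fibrillin-2 from fibrillin-3, with high bootstrap
support. Alongside the trees, a set of short functional signatures tracks
the history: the RGD integrin-binding tripeptide in TB4 (and TB3 in some
lineages), furin-cleavage sites (Arg-x-(Lys/Arg)-Arg) in both terminal
domains, the four N-terminal and two C-terminal cysteines, and the
cysteine-free "unique region" after TB1 whose amino-acid composition
(proline-rich, glycine-rich, or mixed) distinguishes the paralogues.

`fibevo` implements that comparative analysis as a reusable pipeline:
domain annotation from cysteine signatures, motif scans, unique-region
composition statistics, and distance-based plus maximum-likelihood
phylogenetics with bootstrap supports — together with a fibrillin-family
simulator that provides exact ground truth for every stage.

## Domain annotation

Fibrillin domains are defined entirely by cysteine content, which is what
the scanner exploits:

* 6 cysteines: EGF family. The domain is calcium-binding (cbEGF) when its
  N-terminal window carries the consensus
  (D/N)-x-(D/N)-(E/Q)-x(m)-(D/N)-x(n)-(Y/F); it is cbEGF-like when the
  consensus is intact except for the first residue (not Asp/Asn), the
  annotation given to the domain replacing the unique region in
  single-fibrillin invertebrates; otherwise it is a plain EGF domain.
* 8 cysteines with the adjacent triple Cys-Cys-Cys (Cys3-5): TB domain.
* 8 cysteines with the tandem Cys-Cys at positions 4-5 and no triple:
  hybrid domain. An extra cysteine after Cys2 gives the 9-cysteine hybrid 1
  signature; the arthropod hybrid 2 carries two extra cysteines (Cys4a
  extends the tandem into a triple; Cys6a precedes the penultimate
  cysteine) for 10 in total.
* 4 (leading) and 2 (trailing) cysteines: the N- and C-terminal domains.
* A cysteine-free run of at least `unique_min_len` residues (default 30)
  directly after TB1: the unique region.

Segmentation is anchored on cysteines. Cysteines separated by more than
`gap_split` (default 12) non-cysteine residues belong to different
domains; inter-domain runs up to `linker_max` (default 20) are split at
their midpoint, and longer runs become uncovered gaps (or the unique
region). The defaults are calibrated to the simulator's domain templates —
real inter-cysteine spacings vary more than the published consensus
descriptions pin down, so all of these knobs are exposed in
`domain_scan_config()`. The consensus spacer bounds default to m in [0, 4]
and n in [2, 12]; hydroxylation of the consensus aspartate is not
observable in sequence and is ignored. Disulfide connectivity (e.g. the TB
1-3, 2-6, 4-7, 5-8 pattern) is carried as per-class annotation metadata
only and never inferred. All coordinates in machine outputs are 0-based
half-open; the GFF3 writer uses that format's native 1-based closed
convention.

```{r annotate}
g <- generate_architecture(fibrillin1_profile(), seed = 1)
find_domains(g$record)
```

## The simulator

The generator realizes an architecture profile (an ordered list of domain
templates) into a sequence with an exact ground-truth map. Built-in
profiles follow the shared fibrillin backbone — N-terminal domain, three
EGF domains, the 9-cysteine hybrid 1, cbEGF, TB1, then the isoform-specific
post-TB1 position, followed by the alternating cbEGF/TB region including
hybrid 2 and the C-terminal domain (seven TB domains in total, roughly
1.4 kres per record; real fibrillins are about twice as long because they
carry longer cbEGF tandem arrays, which add phylogenetic signal but no new
domain classes). Vertebrate-like profiles place the unique region plus
EGF4 after TB1; the ancestral profile places a cbEGF-like plus cbEGF pair
there instead, and optionally the 10-cysteine arthropod hybrid 2.

Free residues are sampled uniformly over the 19 non-cysteine residues;
unique regions use isoform-specific weights (fibrillin-1-like P = 0.40,
V = 0.14; fibrillin-2-like G = 0.38, P = 0.12; fibrillin-3-like G = 0.24,
P = 0.18, L = 0.16; ray-finned-fish fibrillin-2/3 G = 0.46, N = 0.16),
matching the reported enrichments of the paralogues. The calcium-binding
consensus is instantiated as D-x-D-E-x(1)-D-x(4)-Y (the shortest
realization of the variable-length consensus), with the third flank
residue ahead of Cys1 as its first position; cbEGF-like templates replace
the leading D with G.

`evolve_family()` evolves the root record along a locus tree under the
same JTT model used for inference. Three realism compromises are made
deliberately, and stated here because they define what passing tests do
and do not show about real data:

* **Protected features.** Cysteines, motif payloads and the consensus
  anchor residues never substitute, substitutions are conditioned against
  creating new cysteines, and the rare draw that would create a spurious
  RGD / furin / calcium-binding signature is reverted. This models strong
  purifying selection on the class-defining residues; it also makes the
  scanner's recovery of the truth map exact, which is what the round-trip
  tests assert. Real sequences violate this occasionally (lineage-specific
  cysteine gains/losses, incidental RGDs), so perfect recovery on
  simulations does not promise perfect recovery on database sequences.
* **No indel process.** Length changes happen only through scripted edits
  (e.g. the unique-region to cbEGF-like swap), so alignment columns are
  homologous by construction at the default settings. The aligner is still
  exercised end to end, but its gap placement is only lightly stressed.
* **Uniform rates by default.** The default simulation uses plain JTT
  (no rate heterogeneity), and the simulation-analog tests therefore infer
  under plain JTT as well — a model-consistent comparison. The pipeline
  default for real data remains JTT+I+Gamma with four discrete categories.

The default study family has four clades of `n_species = 3` species each —
a single-fibrillin clade plus the fibrillin-1, -2 and -3 clades produced by
the two nested duplications (`dup1`, `dup2`) — for 12 tip loci, with every
branch at 0.1 substitutions/site. The divergence between paralogues is not
quantified in the literature at the level needed here, so 0.1 per branch
is the package's choice of a clearly-resolvable yet non-trivial signal.
Scripted edits on the default tree remove the TB3 RGD on the fibrillin-1
stem (RGD to RGE, the state seen in monotreme/marsupial fibrillin-1) and
degrade it on the fibrillin-3 stem (RGD to RAD). Edits are applied after
the branch substitution so they are always observable at descendant tips.

## Alignment

The aligner is a guide-tree progressive method: global affine-gap (Gotoh)
pairwise and profile-profile alignment under BLOSUM62 with gap open 11 and
extend 1 (a gap of length L costs open + ext * L), the guide tree from
average-linkage (UPGMA) clustering of pairwise-identity distances, and
deterministic traceback (match/mismatch preferred, then gap in the second
sequence, then the first). It deliberately does not reproduce ClustalX
bit-exactly — downstream trees depend on the alignment only through
homologous columns — and an externally produced aligned FASTA can be
ingested instead for exact-replication workflows. Gap-only columns are
stripped. Per-domain slices take the alignment columns spanned by the
reference record's domain; records whose slice is more than 50% gaps
(configurable) are excluded, mirroring the exclusion of gapped or missense
regions from per-domain analyses, and records missing from some slices are
dropped from the concatenation with a logged warning.

## Phylogenetics

The substitution model embeds the published Jones-Taylor-Thornton
exchangeabilities and frequencies, scaled to one expected substitution per
site per unit branch length, with optional invariant sites and
discrete-gamma rate heterogeneity (category means, four categories; the
more common convention than category medians). Transition matrices come
from the cached spectral decomposition of the reversible rate matrix.

* **Distances** are maximum-likelihood pairwise estimates under plain JTT
  (Protdist-like), with pairwise deletion of gap columns (complete
  deletion available), Brent's method on [1e-6, 20] with tolerance 1e-6,
  and saturation flagged at the bracket top. Gamma rates are not used for
  distances by default.
* **Neighbor joining** uses the standard Q-criterion with deterministic
  lowest-index tie-breaking; negative branch-length estimates are clamped
  to zero and noted.
* **Likelihood** is Felsenstein pruning over compressed site patterns with
  per-pattern scaling; gaps are missing data (all-ones tip vectors). The
  invariant-site mixture is p_inv * pi(residue) for constant patterns
  (columns whose non-gap residues are all identical) plus
  (1 - p_inv) * the discrete-gamma average. Branch lengths are optimised
  per branch by Brent's method on cached conditional-likelihood "flows";
  a sweep is accepted only if the full log-likelihood improves.
* **NNI search** screens every nearest-neighbor interchange exactly at the
  current branch lengths in one pass (a candidate swap costs three extra
  matrix-vector products), refines candidates within a 5 log-unit window
  by branch re-optimisation, and accepts improvements above 1e-8
  log-units. This makes a full ML bootstrap replicate cheap while keeping
  the hill-climbing contract: the log-likelihood never decreases across
  accepted moves.
* **Bootstrap and consensus**: columns resampled with replacement to the
  original length, seeded; majority-rule consensus retains bipartitions in
  strictly more than the threshold (default 0.5) of replicate trees, which
  guarantees mutual compatibility; supports are percentages of replicate
  trees containing the bipartition. Consensus trees can be re-rooted at
  the edge subtending a named clade (e.g. the single-fibrillin clade, or a
  designated outgroup record) with supports preserved per bipartition.
* **Model ranking** by AIC = 2k - 2 lnL with k counting branch lengths
  plus one parameter each for alpha and p_inv; alpha and p_inv are
  estimated by coordinate golden-section (alpha on a log scale over
  [0.05, 10], p_inv over [0, 0.8]). Identical candidate specifications
  are deduplicated before ranking, so a duplicated single candidate
  reports delta-AIC = 0.00 with weight 1.00 — the output format of a
  decisive model test.

```{r pipeline, eval = FALSE}
fam <- simulate_fibrillin_family(seed = 1)
cfg <- fibevo_config(B = 100, seed = 1, p_inv = 0, alpha = NULL)
bundle <- run_pipeline(cfg, records = fam$records,
                       splits = duplication_splits(fam))
bundle$supports
```

## Problem sizes and reproducibility

The default simulated family (12 tips, about 1.4 kres per record, seven
64-residue TB domains giving a 448-column concatenation) is sized so that
a full analysis — annotation, alignment, seven per-domain distance
bootstraps, concatenated and complete-sequence distance and likelihood
bootstraps at B = 100 — completes in well under a minute, and the
package's 20-replicate support study runs in a few minutes; B defaults to
1000 in `fibevo_config()` for real analyses. Every stochastic stage takes
an explicit seed and is byte-reproducible; the run log records a
fingerprint of the configuration.

## Known limitations

* The domain grammar covers fibrillin-like architectures; LTBP-specific
  features (e.g. the two-residue insertion between Cys6 and Cys7 of the
  TGF-beta-binding TB domain) are not modelled, although LTBP-like records
  can be carried through the pipeline as outgroup sequences.
* The scanner assumes signal peptides were removed upstream; it does not
  predict them.
* The simulator has no background indel process and protects
  class-defining residues, so it cannot generate the partially degraded,
  mispredicted database entries that required manual curation in real
  fibrillin surveys; annotation failure modes on such records are
  exercised only through the pipeline's exclusion logic.
* Consensus trees are cladograms (supports without branch lengths);
  divergence-time estimation and richer tree searches (SPR, partitioned
  models) are out of scope.
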