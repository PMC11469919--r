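---
title: "Mining bacterial proteomes for fused diterpene cyclase/synthases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining bacterial proteomes for fused diterpene cyclase/synthases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcsminer)
```

# The screen

A bifunctional diterpene cyclase/synthase (DCS) is a single protein fusing a
Class II diterpene cyclase (DTC; γβ didomain, DxDD catalytic acid) to a
Class I terpene synthase (TS; α domain, DDxxD and NSE metal-binding
motifs) in γβα order. `dcsminer` detects such fusions by *dataset
intersection*: every protein with α-domain evidence enters a TS dataset,
every protein with didomain evidence (and not flagged as a squalene–hopene
cyclase, SHC) enters a DTC dataset, and the overlap — with the didomain
strictly N-terminal to the α domain — is the candidate pool. The screen is
deliberately architecture-first: motif status refines a candidate's
predicted activity but never rescues or removes one.

Two evidence providers feed the same downstream code path:

* **external**: HMMER3 per-domain tables (`domtblout`) from profile
  searches run elsewhere. Envelope coordinates are used because they bound
  the domain region conservatively, which is what the fusion-order test
  needs; alignment coordinates can truncate a weak domain edge. Per-domain
  independent e-values (not full-sequence e-values) are filtered because the
  order test is a per-domain question. The shorthand "e−3" style cutoff
  notation is read as 1×10⁻³.
* **internal**: a position-probability profile scan built from the three
  packaged templates. This is a desk-scale heuristic scanner, not a
  profile-HMM implementation: each profile column assigns the template
  residue probability 1.05/2 and every other residue 0.05/2 (pseudocount
  1/20), scored as log₂(p/(1/20)); windows slide at stride 1 and windows
  scoring at least the class threshold merge like external sub-hits.

# Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha_evalue_cutoff` | 1e-3 | per-domain i-e-value | the α-profile search cutoff of the published screen |
| `gb_evalue_cutoff` | 1e-3 | per-domain i-e-value | the γβ HMM step has no published cutoff; set equal to the α cutoff (the published 1e-4 figure is the downstream blastp filter, retained as metadata) |
| `merge_gap` | 30 | residues | one domain often surfaces as split sub-hits; 30 aa tolerates such splits without bridging genuinely separate domains (α and γβ domains are ≥ 300 aa apart in scale) |
| `internal_score_threshold` | 60% of profile self-score | half-bits | calibrated so random sequences score far below threshold (a random residue scores −0.78 expected per column vs +3.39 for a template match; at 300–500 columns the threshold sits ~50 standard deviations above the random mean) while instances at ≥ 0.7 template identity still clear it |
| `class1_spacing` | [80, 220] | residues between DDxxD and NSE starts | the source material never states a spacing; this window brackets typical Class I TS architecture and the packaged template's 140. Configurable because real α domains vary |
| `min_total_length` | 0 | residues | no length gate by default; the published screen applies none |

Didomain evidence additionally requires *both* flavors of SHC-domain
profile (C-terminal PF13243-type and N-terminal PF13249-type) on the same
protein before a γβ hit is emitted, spanning their combined extent — a
didomain is two domains, and one-sided evidence is how SHC fragments and
spurious hits enter.

Motif semantics: `x` matches the unknown residue `X`; exact positions do
not. When canonical and aberrant Class I motifs co-occur with valid
spacing, canonical wins (the active configuration takes precedence).
Multiple α or γβ hits on one protein: the order test uses the most
N-terminal didomain hit and the most C-terminal α hit — the conservative
reading of "γβ before α".

# The synthetic proteome

`generateProteome()` plants six classes from three fixed packaged
templates: intact fusions (γβ template + random linker + α template),
aberrant fusions (DDxxD → DDxxx(D/E), NSE → NGxxSxxxE), α-only TSs,
γβ-only DTCs, SHC-like decoys (an independent random basis sharing only
DxDD), and uniform-random background. Planted motif spans are
mutation-locked, so truth labels stay valid under diversification; all
other positions mutate independently with probability 1 − `template_identity`
(default 0.9). The default composition — 5 intact + 2 aberrant fusions, 10
TSs, 10 DTCs, 3 decoys, 20 background, 50 proteins — is the desk-scale
study condition used throughout the test suite.

The template coordinates are chosen so that an identity-1 fusion with a
10-residue linker reproduces the numbering conventions of the
characterized cyanobacterial CPS–KS: dyad His 187 (LHS context) and
Asn 253 (PNV) in the γ domain, DxDD in the second (β) half of the
didomain, DDxxD at 610, NSE at 750, and the key isoleucines at 726
(bacterial-type position, one helical turn before) and 730 (plant-type,
PIx context). The annotated reference used by `locateSites()` is exactly
this synthetic construct (shipped as
`inst/extdata/csedcs_like_synthetic.fasta` with a sidecar TSV); it is a
synthetic stand-in built in code, not a deposited sequence.

One construction choice is deliberately hierarchical: the α domains of
*intact* fusions descend from a single proteome-level ancestor (itself a
template instance drawn at `template_identity`), while aberrant fusions,
TSs and all didomain parts draw straight from the templates. Independent
identically-distributed divergence from one template carries no
phylogenetic signal — every instance is equidistant from every other in
expectation, and no clade structure can be asserted of such data. The
shared ancestor gives the intact fusions' α domains common derived states,
so the NJ tree of all α parts recovers them as a clade while the γβ tree
of the same fusions shows no clustering — the asymmetry the screen's
phylogenetic stage is designed to expose. At `template_identity = 1` the
ancestor equals the template and fusions are exact concatenations.

What the generator does **not** emulate: indel evolution (domains never
shift register), compositional bias (background is uniform over the 20
residues), domain truncation, and realistic sequence divergence along a
tree. Passing tests therefore demonstrate the interval, motif, order and
dataset logic — not profile-search power on remote homologs. Real
proteomes should be screened with external HMMER evidence.

# Alignment and trees

The aligner is global Needleman–Wunsch with affine gaps (a gap of length L
costs `gap_open + gap_extend·L`, end gaps included) over the packaged
BLOSUM62, defaults 10/0.5 on the half-bit scale. Traceback ties resolve
deterministically: substitution over gap-in-first over gap-in-second. The
progressive MSA generalizes the same dynamic program to frequency-profile
columns (`C = PᵀAS PB`), merging groups in the order of a guide tree built
by neighbor joining on 3-mer cosine distances. It is a stand-in for
external multiple aligners at desk scale, not an emulation of them.

Distances are Poisson-corrected (`d = −ln(1−p)`, p over pairwise-complete
columns). Pairwise deletion — rather than dropping every gapped column
globally — keeps short toy alignments informative; a pair with no
comparable columns is an error, not a silent zero. Saturated pairs cap at
d = 5. Neighbor joining minimizes the standard Q criterion; ties pick the
lexicographically smallest cluster-label pair (a cluster is labeled by its
smallest leaf), so runs are reproducible across platforms, and negative
branch estimates clamp to zero. Distance-based NJ replaces
maximum-likelihood inference deliberately: the claims the package asserts
are topology-level (monophyly, bipartition support), and NJ is exact on
additive matrices, which makes it independently testable by path-sum
inversion. Bootstrap supports resample alignment columns with replacement
and count bipartition recovery; replicates in which some pair loses all
comparable columns support no bipartition.

Newick serialization carries branch lengths to 6 significant digits;
round-trips are lossless for lengths at that precision.

# Product-outcome rules

`predictProduct()` is an annotation lookup faithful to characterized
outcomes in the CPS–KS (*ent*-kaurene) lineage, not a mechanistic model:
wild type with intact Class I → *ent*-kaurene; Class I knockout (first D
of DDxxD → A) → *ent*-CPP; dyad His→A → *ent*-13-*epi*-manoyl oxide;
dyad Asn→A → the same with residual *ent*-kaurene; dyad substitution plus
knockout → *ent*-LPP; Thr at the bacterial-type key position →
*ent*-pimara-8(14),15-diene; Thr at the plant-type Ile →
8α-hydroxy-*ent*-pimar-15-ene with residual *ent*-kaurene. Rule conditions
are mutually exclusive by construction (verified by enumeration over the
mutation-state space); inputs outside the table — including enzymes from
other product lineages, whose outcomes are annotations on records rather
than transferable rules — return `"none"` with a `no_rule` flag. The table
anchors on alignment-transferred positions, so it applies to homologs, but
only within the lineage it was derived for.

# Degenerate inputs and numerical conventions

All coordinates are 1-based inclusive. Empty FASTA files parse to empty
sets; an all-zero synthetic spec yields empty outputs; a proteome with no
detectable domains produces a report of `NONE` calls, not an error.
Sequences shorter than a profile scan to no hits. Explicit split
boundaries are validated against `[didomain end − 20, α start − 1]` to
guard nonsense constructs. The screen is deterministic end to end given
its inputs; repeated runs emit byte-identical artifacts.

# Problem sizes

The shipped tests and the acceptance script run entirely at desk scale:
50-protein proteomes, 1000-sequence scanner calibrations and motif-oracle
sweeps, 100-tree NJ inversion batches, 100-replicate bootstraps, and
alignments of ≤ 20 sequences of ≤ 900 residues. These sizes exercise every
code path of the screen; scaling to thousands of proteomes is a matter of
supplying external HMMER evidence per proteome file.

# Known limitations

* The internal scanner detects instances of the packaged templates; it has
  no power on remote homologs and is not a substitute for profile-HMM
  searches on real data.
* The SHC relatedness filter defaults to 3-mer cosine distance, which
  separates template-derived instances cleanly but is cruder than the
  alignment-based comparison it stands in for; `closerToGroup()` accepts a
  custom distance function.
* Class I spacing, the didomain e-value cutoff and the 60% scanner
  threshold are package choices where the source workflow is silent; all
  three are configurable.
* Product rules cover one lineage; everything else is reported, not
  predicted.
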