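---
title: "Methods: signature proteins, conserved indels and their phylogenomic mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature proteins, conserved indels and their phylogenomic mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cladesig)
```

# Scope

`cladesig` implements a comparative-genomics protocol for circumscribing
bacterial clades in molecular terms: calling clade-specific signature
proteins (CSPs) from homology hit tables, detecting conserved signature
indels (CSIs) in protein alignments, mapping family origins onto a rooted
tree by Dollo parsimony, and building the reference tree itself as a
neighbour-joining supermatrix analysis. The motivating system is the
cyanobacteria and their principal clades (the deep-branching Clade A, a
broad Clade B containing the NOC subclade of *Nostocales*, *Oscillatoriales*
and *Chroococcales*, the marine picocyanobacterial Clade C, and the
high-light-adapted low-B/A *Prochlorococcus* ecotype), but nothing in the
code is taxon-specific: clades are named taxon sets, and specificity targets
are set-algebra expressions over them.

Out of scope by design: running a homology-search engine (hits enter as
12/13-column tabular files), building alignments (MSAs are consumed), and
maximum-likelihood tree inference (the ML branch of the original protocol is
replaced by accepting a reference topology as input; the NJ branch is fully
implemented).

# The CSP decision procedure

For a query protein of length $L_q$ and a target clade expression resolved
to a taxon set $T$, the per-query hit list (E-value ascending, bitscore
descending, subject id — a total order, so the "last in-clade hit" is well
defined) is evaluated as:

1. **Presence.** A taxon $t \in T$ possesses the protein when it has a hit
   with $E \le$ `e_presence` whose subject length lies within
   `length_ratio_bounds` $\times L_q$ (when the subject length is known —
   from the 13th column or a length file; otherwise the check is skipped).
   The query's own taxon counts as present: its self-hit is removed on
   ingestion, and a genome trivially contains its own query.
2. **ORFan exclusion.** Fewer than `min_members` possessing taxa means the
   protein is effectively private to one genome and is excluded rather than
   reported.
3. **Foreign evidence.** Hits to taxa outside $T$ are split into whitelisted
   (group tags intersecting `exception_groups`, default the plastid-bearing
   eukaryotes) and ordinary foreign hits.
4. **Specificity.** The protein stays specific when no ordinary foreign hit
   reaches `e_sig`. The ratio of the first foreign E-value to the last
   in-clade presence E-value (the "large increase in E values") is recorded
   as `gap_ratio` on every decision, with a note when it falls below
   `gap_factor`; under the rule as specified the ratio is corroborating
   evidence rather than an independent rejection criterion.
5. **Exceptions.** Significant foreign hits confined to at most
   `max_isolated_foreign` distinct taxa — or to whitelisted taxa only —
   downgrade the call to `retained_with_exception` with the taxa on record.
   More foreign taxa reject it.
6. **Completeness.** Full coverage of $T$ is `specific_core`; 1 to
   `max_missing` absentees is `specific_partial` (the published tables'
   asterisk tier, "missing in 1–2 isolated species/strains"); more is
   rejection.

`call_genome()` evaluates an ordered target list most-specific-first
(smallest resolved set, ties by listed order) and assigns each query to the
first target with a positive verdict, mirroring the convention that each
protein is reported under exactly one table.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `e_sig` | `1e-4` | E-value | the published ceiling above which foreign similarity is attributed to chance |
| `e_presence` | `1e-6` | E-value | "high-scoring homolog" is unquantified in the source protocol; chosen stricter than `e_sig`, configurable |
| `gap_factor` | `1e3` | ratio | operationalizes the unquantified "large increase in E values"; the motivating examples jump by many orders of magnitude |
| `length_ratio_bounds` | (0.7, 1.3) | fraction of $L_q$ | significant hits "very similar in length" to the query; hard presence filter by default, `length_check = "warn"` relaxes it |
| `min_members` | 2 | taxa | a protein in one taxon is an ORFan |
| `max_missing` | 2 | taxa | the asterisk tier covers 1–2 missing members |
| `max_isolated_foreign` | 1 | taxa | "an isolated species from some other groups" |
| `e_floor` | `1e-180` | E-value | used only inside ratio computations so `E = 0` never divides by zero; stored E-values are never mutated |

Open points in the source protocol, resolved here and configurable: the
length check is applied *inside* the presence step (order unstated in the
original); in-clade "significant" uses `e_presence`, not `e_sig`; an
isolated-foreign significant hit yields a retained-with-exception call (the
protocol retains such proteins "noted appropriately") rather than a clean
specific or an outright rejection.

# The CSI scanner

A candidate CSI is a maximal run of alignment columns in which at least
$1-\tau$ of the clade members hold residues while at least $1-\tau$ of all
other sequences are gapped (pattern A), or the reverse (pattern B). Both
flanks of `flank_width` columns must be gap-free in every sequence (the
flanks anchor the homology of the region) and conserved: each flank column's
majority-residue fraction must reach `flank_min_identity`. Outgroup state
polarizes the call — gapped outgroup under pattern A is an insertion in the
clade; residue-holding outgroup under pattern B is a deletion in the clade;
anything else leaves polarity `NA`. Lengths are residue counts on the
residue-holding side (clade members for insertions, everyone else for
deletions), reported as a (min, max) range across carriers; coordinates are
0-based half-open throughout.

The original criteria live in prior work and are not restated in the source;
the defaults here ($F = 5$, $c = 0.6$, gap-free flanks, $\tau = 0$,
`min_length` 1) are this package's explicit operationalization and are not
claimed to match that prior dialect. Two consequences worth knowing:

* at $\tau = 0$ every clade member must hold residues in every region
  column, so an indel whose carriers disagree (e.g. a 4–5 residue insert
  with one internally gapped carrier) is only recoverable as a single region
  with $\tau \ge 1/k$ for $k$ carriers — the pipeline default is
  $\tau = 0.05$ for this reason, while the strict $\tau = 0$ default is kept
  for clean planted indels;
* the dash-notation rendering (`render_indel()`) is an output convention
  only; inputs must be full-letter FASTA.

# Dollo mapping

Presence/absence rows (from CSP presence sets, or from hits at
`e_presence`) are explained by a single gain at the MRCA of the present
taxa followed by losses. Losses are attributed to the roots of the maximal
absent subtrees under the gain node; this is the minimum number of loss
events for a single-origin model, which the test suite verifies against
exhaustive enumeration over all candidate loss sets on trees of up to 8
leaves. Families whose loss count exceeds `lgt_ratio` times their presence
count are flagged as lateral-transfer candidates — a diagnostic only, since
the mapper is strictly parsimony-on-presence and deliberately encodes no
auxiliary (e.g. indel) evidence for preferring deeper origins.

# The supermatrix NJ stage

* **Concatenation** appends per-gene alignments in list order, recording
  half-open column intervals; `pad` fills taxa absent from a gene with gaps,
  `strict` refuses.
* **Block filtering** reconstructs the published description of the
  Gblocks 0.91b defaults for $n$ sequences: conserved positions need the
  modal residue in more than $n/2$ sequences, highly conserved in at least
  $0.85 n$; nonconserved stretches longer than 8 are removed; blocks are
  trimmed to highly conserved ends and dropped below 10 columns; the
  allowed-gap mode is `half` (gap fraction at most 0.5), the one
  non-default setting of the original protocol. Exact dialect fidelity to
  the binary is not claimed; all five knobs are exposed. The filter is
  idempotent, and the supermatrix site count of the original study is not a
  reproduction target (it depends on the exact aligner/filter binaries and
  2009 sequence set).
* **Kimura protein distance**: $p$ is the fraction of differing sites among
  pairwise-complete sites (complete deletion available), and
  $d = -\ln(1 - p - 0.2\,p^2)$. The correction diverges at
  $p \ge (\sqrt{1.8}-1)/0.4 \approx 0.854$; such pairs raise an error
  rather than being capped, because silent capping distorts the distance
  matrix that NJ consumes.
* **Neighbour joining** is the standard Q-criterion agglomeration with
  deterministic tie-breaking (smallest current index pair; the merged node
  takes the smaller vacated slot). Negative branch lengths are clamped to
  zero with a warning. Consistency on additive matrices is tested against
  the generating topologies and against an independent NJ implementation.
* **Bootstrap** resamples columns to full length, recomputes distances and
  the tree, and reports per-bipartition support percentages mapped onto the
  original tree (not a consensus), matching the numbers-at-nodes convention.
  The function default is the publication-grade 1000 replicates; the
  pipeline config default is 100 to keep a full desk-scale run in minutes.
* **Outgroup rooting** places the root at the midpoint of the edge
  separating the outgroup clan; an outgroup that is not a clan is an error,
  never silently forced.

# The synthetic world

The generator's defaults state the benchmark conditions: 46 taxa (an
outgroup pair plus 44 ingroup taxa arranged in the reference clade
hierarchy), 40 universal housekeeping families, 10 families at each of 11
targets (the named clades plus the compound targets `Cyano-CladeA`,
`CladeB+Elongatus`, `CladeC-LowBA`), 20 ORFans, four planted indels of
lengths 6, 2, 1 (a deletion) and 4–5 residues with frozen 5-column flanks,
300-residue roots, and decoy rate 0. Branch lengths are chosen so that
within-ingroup identities stay high (presence calling is noise-free by
construction: with the E-model defaults, $a + b \cdot s - 3\sigma \gg 4$ for
any within-family identity $s \ge 0.3$) while outgroup–ingroup paths
(~1.2–1.4 substitutions/site) stay inside the Kimura domain.

Design choices, stated once:

* **Substitution model.** Sites substitute independently along a branch of
  length $t$ with probability $1-e^{-t}$; the replacement letter is uniform
  over all 20 amino acids. The uniform-over-20 choice (rather than over the
  19 non-identical letters) makes a substitution event silent with
  probability 1/20, so identity saturates at 1/20 and path identity has the
  exact closed form $e^{-T} + (1-e^{-T})/20$ — the property the generator's
  statistical tests check. No exchangeability matrix, no rate variation, no
  model-generated indels: realism beyond what the downstream rules consume
  is a non-goal.
* **E-value model.** Phenomenological, not Karlin–Altschul:
  $E = 10^{-(a + b s + \varepsilon)}$ with $a=5$, $b=100$,
  $\varepsilon \sim N(0, \sigma^2)$ truncated at $3\sigma$ ($\sigma = 2$),
  clipped to $[10^{-180}, 1]$. It only needs to induce the orderings and
  thresholds the CSP rules consume. Decoys are log-uniform on
  $[10^{-4}, 10]$, i.e. at or above the significance ceiling, emulating the
  chance-similarity background.
* **Planted indels** freeze their flanking columns to one conserved motif
  across all members, guaranteeing the flank checks pass by construction;
  the insert segment itself is identical across carriers (a conserved
  indel, not a hypervariable loop).
* **Queries** are the complete proteomes of six tip genomes, one per major
  clade, mirroring the original six-genome search design; a planted family
  is "recovered" when any of its queried members is called for its target.
* All randomness flows from the single scenario seed through R's global
  generator; the emitted bundle is byte-deterministic in the configuration.

What a green test does **not** establish: robustness to alignment error
(true alignments are emitted site-correspondence-perfect), to systematic
E-value miscalibration, to lateral transfer (not simulated), or to
rate-heterogeneous sequence evolution. The synthetic world demonstrates
that the decision rules, scanner, mapper and tree stage implement their
definitions exactly and recover planted structure with no noise and with
threshold-respecting decoy noise — not that the thresholds are optimal for
real genomes.

# Numerical and degenerate-input conventions

E-values of exactly 0 are preserved and floored only inside ratios
(`e_floor`). Hit ordering ties break by bitscore then subject id. Newick
input without branch lengths gets zeros (topology-only reference trees are
legitimate). Empty filtered alignments and empty call sets are warnings or
empty results, not errors; an all-absent presence row, an unrooted tree
where a rooted one is required, a non-clan outgroup, and a
Kimura-domain violation are errors. Bootstrap supports attach to
bipartition keys (the side not containing the alphabetically first taxon),
making support lookup stable under re-rooting.

# Known limitations

* The CSP gap-ratio criterion is recorded but, per the rule as specified,
  cannot by itself reject a call whose foreign hits are all above `e_sig`.
* The scanner reports polarity `NA` whenever the designated outgroup is
  internally inconsistent over the region, rather than voting.
* The ML branch of the original tree protocol (quartet puzzling, WAG+F+Γ)
  is intentionally absent; reference topologies from external ML tools are
  consumed as Newick.
* `emit_hit_table()` enumerates non-homologous pairs when the decoy rate is
  positive, which is quadratic in sequence count and guarded accordingly;
  decoy noise is meant for desk-scale experiments.
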