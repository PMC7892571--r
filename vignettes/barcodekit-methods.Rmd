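---
title: "Methods: codon-aware primer design and barcode-gap delimitation"
author: "barcodekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-aware primer design and barcode-gap delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodekit)
```

This vignette documents the models and algorithmic choices behind
`barcodekit`: what is computed, under which assumptions, which knobs
matter, and where the design was genuinely open and a choice had to be
made.

## Genetic codes and codon-level invariance

A genetic code is stored as a complete 64-entry codon → amino-acid map
(stop = `*`), addressable NCBI-style by table id. Two codes are built in:
the standard code (table 1) and the ascidian mitochondrial code, for which
we adopt NCBI translation table 13. The published facts about the ascidian
code that this package's design logic rests on — AGR encodes Gly alongside
GGN, ATA encodes Met, TGA encodes Trp — are exactly the table-13
assignments; the full 64-entry ascidian table is not spelled out anywhere
we could verify entry by entry, so table 13 is an assumption, flagged
here. Users can supply any other code as a 64-line plain-text file
(`read_genetic_code()`).

The primer-design core is `guaranteed_positions()`. For an amino-acid set
$A$ and code $c$, let $C = c^{-1}(A)$ be all codons encoding members of
$A$. For each codon position $p \in \{1,2,3\}$ the allowed set is
$U_p = \{\,x_p : x \in C\,\}$, and $p$ is *invariant* iff $|U_p| = 1$. A
primer base placed on an invariant position pairs perfectly with every
template whose translated residue stays within $A$ — regardless of
synonymous change. Two consequences drive everything else:

* Asp and Glu are jointly encoded by GAN, so $U_1 = \{G\}$,
  $U_2 = \{A\}$: a 3′ end on positions 1–2 of a conserved acidic residue
  is safe even under D↔E replacement.
* Under table 13, Gly has $U_1 = \{A, G\}$ (AGR ∪ GGN): position 1 of a
  conserved Gly is *not* safe, although under the standard code it is.
  This is the failure mode flagged as "MP" in primer screens: a mismatch
  at the 3′-penultimate position.

Translation is total on codon strings: codons containing `-` or `N`
translate to `X`, stops to `*`, so downstream amino-acid profiles never
drop sequences. `U` is normalised to `T` and lowercase to uppercase on
every input path.

## Alignment profiles

Coordinates are 1-based and inclusive everywhere except BED-like exports
(0-based half-open), matching the conventions of the surrounding
literature and of genome browsers respectively.

Per column, the information content is $R_i = \log_2 s - H_i$ with
$H_i = -\sum_b f_b \log_2 f_b$ over the observed unambiguous symbols
($s = 4$ for nucleotides, $20$ for amino acids). No small-sample
correction is applied by default — logo tools differ here, and the
uncorrected value is the one whose closed forms are easily checked
(all-identical column: $R = 2$ bits for nt; 50/50 column: $R = 1$) — but
`correct = TRUE` applies the usual $\frac{s-1}{2 n \ln 2}$ correction.

Two rules are deliberate choices the data sources leave open:

* **Ambiguity symbols never count toward variability.** A column is
  variable iff at least two *distinct unambiguous* symbols occur; gaps and
  IUPAC/`X` codes are ignored. This is conservative: an `N` can never
  create a variable site.
* **Haplotypes are exact full-length matches** after case/U→T
  normalisation; sequences of different lengths are distinct haplotypes.
  Any looser rule (substring containment, N-tolerant matching) changes
  haplotype counts in ways that are hard to reason about.

The strict consensus (threshold 1.0) emits `N`/`X` exactly where a column
is variable; for nucleotide alignments an IUPAC mode emits the union of
observed bases instead, which is the degenerate consensus a primer
designer wants.

## Primer matching and the 3′ clamp

A template base matches a primer symbol iff the base lies in the symbol's
IUPAC expansion. `N` in the template always counts as a mismatch — the
conservative reading, since an undetermined base cannot be promised to
pair. Default mapping options are a maximum of 6 mismatches per window and
a clamp of 2: no mismatch at 3′ offsets 0 or 1 ("within 2 bp of the 3′
end"). Ties between equal-mismatch windows are broken leftmost-first.
Reverse primers are matched against the reverse complement and reported in
forward-strand coordinates, so a reverse primer's 3′ end is the *left*
edge of its footprint.

`mp_scan()` and `screen_panel()` deliberately relax the clamp to 0 when
looking for each template's best site: the point of a screen is to
*observe* clamp violations (the MP flag at offset 1), not to hide them.
Templates where no window reaches half the primer length in matches are
reported as "no site found" rather than given a meaningless best score.

Melting temperatures for degenerate primers are reported as a range over
the least- and most-stable unambiguous expansions, using the unified
nearest-neighbour parameter set (SantaLucia 1998) at 50 mM monovalent salt
and 500 nM oligo. Published primer tables rarely state their Tm method, so
these values are for relative comparison, not cross-tool equality.

## Genetic-code aware design

`design_primer()` builds a primer from an alignment window in two steps.

1. **3′ anchor.** The candidate 3′ end starts at the window edge. For each
   of the `clamp_len` (default 2) terminal positions, the covering codon's
   observed amino-acid set is collected across sequences and
   `guaranteed_positions()` is consulted; every clamp position must be
   invariant-by-code. A failing candidate is shifted upstream one base at
   a time, up to one full codon, before the window is rejected with an
   error that lists every rejected position and why (e.g. "codon position
   1 of conserved {G} admits {A,G}"). One codon is the natural search
   radius: after three shifts the clamp faces the same codon-position
   pattern again, so further shifting only repeats the same verdicts one
   codon earlier — a genuinely hopeless window should fail loudly instead.
2. **Body.** Remaining columns follow `degenerate_consensus()`: invariant
   columns contribute their base; variable columns contribute the IUPAC
   union while the running product of expansion sizes stays within
   `max_total_degeneracy` (default 32, a typical synthesis-friendly
   budget), otherwise the major base if its frequency reaches
   `major_base_threshold` (default 0.5), otherwise the union anyway with
   a warning — a primer that silently drops observed variation would be
   worse than a noisy one.

For reverse primers the same logic runs on the reverse complement; the 3′
anchor then sits at the window *start* in forward coordinates and
"upstream" means towards larger forward coordinates.

`derive_from_anchor()` is the complementary operation for re-targeting an
existing primer: positions where the consensus base set is contained in
the anchor's expansion are kept, mismatched positions adopt the (possibly
degenerate) consensus symbol, boundaries unchanged. A warning fires when
more than half the positions change — at that point the "derived" primer
is mostly a new primer.

## Distances

`pair_distance()` removes columns where either sequence carries a gap or
any ambiguity symbol (pairwise deletion — the common barcoding choice, and
the one that wastes the least signal on ragged alignment ends), then
computes the mismatch proportion $p$, transition proportion $P$ and
transversion proportion $Q$, with $d$ given by the p-distance, JC69
$-\tfrac34\ln(1-\tfrac{4p}{3})$, or K80
$-\tfrac12\ln(1-2P-Q)-\tfrac14\ln(1-2Q)$.

Saturation (JC69 $p \ge 3/4$; K80 log arguments $\le 0$) yields `d = NA`
with a `saturated` flag rather than an exception: a matrix with one
saturated pair is still useful for inspection. The *partitioner* refuses
saturated matrices loudly, because a threshold inferred from a distance
distribution with missing entries is not meaningful.

## Barcode-gap partitioning

The partitioner is an independent implementation in the spirit of
automatic barcode-gap discovery; it promises concordance on well-separated
data, not numeric equality with any particular server. All steps are fixed
and documented:

1. Priors $P$ form a geometric grid of `steps` values from `pmin` to
   `pmax` (defaults 0.001–0.1, 10 steps) — geometric because the plausible
   range spans two orders of magnitude.
2. The $m$ off-diagonal distances are sorted ascending; consecutive
   differences $g_k = d_{(k+1)} - d_{(k)}$.
3. The local width $w_k$ is the mean of $g$ over a window of
   $\max(2, \lceil m/\texttt{nb\_bins} \rceil)$ consecutive ranks centred
   on $k$ (default `nb_bins` 20). The window never shrinks to a single
   rank: with $w_k = g_k$ the relative-width test $g_k > X w_k$ could not
   pass for any $X \ge 1$, making small matrices silently undelimitable.
4. The barcode gap is the smallest $k$ whose *upper* edge reaches the
   prior ($d_{(k+1)} \ge P$) with $w_k > 0$ and $g_k > X w_k$ (default
   $X = 1.5$; 1.0–1.1 are useful fallbacks on weakly structured data).
   Anchoring the prior to the gap's upper rather than lower edge is a
   deliberate choice: the prior is an assumed ceiling on intraspecific
   divergence, and the gap separating "intraspecific-like" from
   "interspecific-like" distances must still be found when every
   intraspecific distance lies *below* the prior — exactly the common
   case. With the lower-edge rule the search would start inside the
   interspecific block and either find nothing or split it arbitrarily.
   A consequence worth knowing: initial partitions are typically stable
   across the upper part of the prior grid.
5. The threshold is the mid-gap $T = d_{(k)} + g_k/2$; the initial
   partition is the single-linkage components of pairs with $d < T$.
   Single linkage is not one clustering choice among many here: "pairs
   closer than $T$ are conspecific" is transitive closure, which *is*
   single linkage.
6. The recursive partition reapplies steps 2–5 within each group (of at
   least 3 members) on its submatrix, repeatedly, until no group splits.
   Recursive partitions therefore always refine initial ones. They differ
   from initial ones exactly when between-group heterogeneity masks a
   subgroup's internal gap in the global distance distribution — and, by
   step 4, only at priors below the masked gap's upper edge, so recursive
   and initial partitions coincide at the top of the prior grid.
7. If no gap is found at a prior, the initial partition is the single
   all-inclusive group, flagged `no_gap` — this is an observable outcome,
   not an error; all-equal distance matrices produce it at every prior.

Partitions are invariant to input row order up to OTU relabelling; labels
are contiguous integers by first appearance.

`compare_partitions()` reports exact identity, matched/split/merged group
counts, and the adjusted Rand index (via `mclust::adjustedRandIndex`,
cross-checked in the tests against explicit pair counting).

## The simulator

`simulate()` generates the study conditions the rest of the package is
validated against: $k$ species of $n$ individuals over $c$ codons. A
random sense-codon ancestor is drawn; each species founder mutates from it
at per-site rate `inter_sub_rate`, each individual from its founder at
`intra_sub_rate`. Given a substitution event, a transition is chosen with
probability $\kappa/(\kappa+1)$ ($\kappa$ = `ti_tv_ratio`, default 4, a
typical mitochondrial protein-coding value), the two transversions
equiprobably. Codons listed in the conserved profile only ever exchange
synonymously (uniform redraw within `codons_for()` of their amino acid),
so conserved anchors are exact by construction. The defaults —
`intra_sub_rate = 0.005`, `inter_sub_rate = 0.15` — put intraspecific
pairwise distances around 0.01 and interspecific ones around 0.25–0.3, a
well-separated barcode-gap regime.

What the simulator does *not* emulate, and what passing tests therefore do
not show about real data: rate heterogeneity across sites, indels (and
hence alignment error), codon-usage bias, saturation at deep divergences,
and non-tree-like population structure. Sites are i.i.d. and the "species
tree" is a star of stars. The simulator's job is to exercise every
downstream contract exactly — conserved codons exactly conserved, planted
partitions exactly known — not to be a coalescent simulator. The seed is
part of the configuration and the output is byte-deterministic given it.

Validation problem sizes: primer-matching oracles run on 1,000 random
primer/template pairs (degeneracy ≤ 64, 45-nt templates); codon-invariance
enumeration covers every 1–3-element amino-acid set under both built-in
codes; cluster recovery sweeps $k \in \{2,3,5\}$ species ×
$\{3,5\}$ individuals × 200 codons × 10 seeds, asserting ARI = 1 at every
grid prior inside the planted gap.

## Degenerate inputs and edge cases

* Empty alignments, duplicate ids, ragged lengths, invalid characters:
  errors naming the offender.
* A primer longer than its template: empty match table plus a warning
  (not an error — panels legitimately mix fragment lengths).
* Zero comparable sites after pairwise deletion: an error naming the pair.
* Fewer than 3 sequences: the partitioner refuses; 1–2-member groups are
  never recursed into.
* Windows that would place a primer over a gap column: design refuses;
  degenerating a gap is not meaningful.
* `plant_primer_site()` refuses footprints that could contradict a
  conserved codon under *any* expansion, keeping the simulator's
  guarantees intact.

## Known limitations

* Table 13 as "the" ascidian mitochondrial code is an assumption (see
  above); any divergence would affect which positions are declared
  invariant, not the machinery.
* The gap detector's windowed relative-width rule is one reasonable
  formalisation; on weakly separated data it can disagree with other
  implementations — lower `x` (1.0–1.1) is the practical fallback, and
  `no_gap` outcomes should be taken seriously rather than retried away.
* Tm ranges use one parameter set and ignore dangling ends, mismatch
  thermodynamics, and divalent cations.
* The region-comparison pipeline assumes both windows come from one
  alignment with shared ids; it does not align anything itself (alignments
  are consumed, not produced).
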