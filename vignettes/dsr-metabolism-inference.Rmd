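---
title: "Inferring the direction of dissimilatory sulfur metabolism from gene complements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the direction of dissimilatory sulfur metabolism from gene complements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsrscreen)
```

## The model

The dissimilatory sulfate-reduction (Dsr) pathway — Sat activating sulfate
to APS, AprAB reducing APS to sulfite, DsrAB/DsrC reducing sulfite to
sulfide, with QmoAB(C) and DsrMK(JOP) shuttling reducing equivalents — is
shared between sulfate/sulfite reducers (SRM) and the many sulfur oxidizers
(SOM) that run it in reverse. Because the *dsrAB* genes are both the
functional core and a phylogenetic marker, a genome's *direction* of sulfur
metabolism is inferred here from three interlocking signals:

* the **DsrAB type** (reductive bacterial, reductive archaeal, oxidative
  bacterial), obtained by nearest-reference classification;
* the presence of **DsrD**, the allosteric DsrAB activator that tracks
  reductive metabolism, and of **DsrL**, an NAD(P)-dependent oxidoreductase
  whose subclusters split by polarity (1A/1B/2A/2B with oxidative context,
  2C with reductive context);
* the **DsrEFH** sulfur-donor complex, typical of SOM but demonstrably
  encoded by some reductive genomes, hence treated as *supporting evidence
  only* — the package guarantees (and tests exhaustively) that toggling
  DsrEFH never changes a direction call.

The locus-level decision table, in fixed precedence:

| rule | condition | call |
|------|-----------|------|
| R1 | type = reductive archaeal | REDUCTIVE |
| R2 | type = oxidative bacterial | OXIDATIVE |
| R3 | type = reductive bacterial, *dsrD* anywhere in genome | REDUCTIVE |
| R4 | reductive bacterial, no *dsrD*, DsrL 1A/1B/2A/2B present | OXIDATIVE, `conflict = TRUE` |
| R5 | reductive bacterial, no *dsrD*, no *dsrL*, early-diverging | REDUCTIVE |
| R6 | anything else (incl. untyped or fragmented dsrAB) | UNCERTAIN |

R3 deliberately accepts *dsrD* anywhere in the genome, not only co-localized
with the locus: in real dual-locus genomes the *dsrD* gene can sit on a
separate contig or operon from the rest of the Dsr genes while the organism
is still read as reduction-capable. Co-localization (same contig, gene
indices within `coloc_window_genes` = 10 — wide enough to span a gene
"a few genes downstream" of the locus with margin) only *strengthens the
evidence trail*, never flips a call. R4 returns OXIDATIVE with an explicit
conflict flag rather than UNCERTAIN: the configuration is interpretable
(the DsrL polarity wins over the missing activator) but the tension is kept
auditable. A genome with at least one REDUCTIVE and one OXIDATIVE locus is
SWITCHABLE — inferred able to reverse its sulfur metabolism by
differentially deploying its DsrAB(D/L) sets. All calls are about *genetic
potential*; the package makes no claim about realized physiology.

Pathway completeness is orthogonal to direction: FULL_SULFATE_PATHWAY
requires sat, aprA, aprB, qmoA, qmoB, dsrA, dsrB, dsrC, dsrM, dsrK (qmoC
and dsrJ/O/P being optional subunits of their complexes); SULFITE_ONLY
requires the dsr core with the *entire* sulfate-activation branch absent —
the configuration of gut-dwelling sulfite reducers that draw sulfite from
organosulfonates. Organosulfonate-lyase genes are not part of the rule set;
they would refine SULFITE_ONLY interpretation but are outside the screened
family inventory.

## Detection and typing without profile HMMs

Published screens of this kind use protein hidden Markov models whose score
cut-offs are not printed and whose model files are external artifacts.
Detection is therefore re-specified as reference-seeded local alignment,
which is fully reproducible from shipped inputs: a query is scored by
Smith–Waterman (BLOSUM62; a gap of length L costs `gap_open + L *
gap_extend` = 11 + L) against every family seed, normalized by the seed's
self-score, and accepted at `detect_frac = 0.3` with margin
`detect_margin = 0.05` over the runner-up family. The two thresholds are
*calibrated on the synthetic benchmark* — the suite verifies that
composition-preserving shuffled decoys stay below 0.3 while members mutated
at 15% stay above with sensitivity ≥ 0.95 — and are therefore documented as
non-equivalent to any published HMM cut-off. Near-ties between dsrA and
dsrB specifically yield `UNASSIGNED_DSR` (fragmented MAG subunits); a
genome whose only dsrAB signal is unassigned is called UNCERTAIN and
flagged in the warnings table.

Typing replaces phylogenetic placement with k-nearest typed references
(`typing_k = 5`) under the same normalized score: deterministic, order
invariant, and oracle-checkable, at the price of ignoring tree topology —
for queries within the calibrated divergence envelope (≤ 15% mutation
against references ≥ 40% apart between types) the label recovery is exact,
which is what the tests assert; no claim is made for deeply divergent
queries, which surface as low support or UNCERTAIN. Support is the agreeing
fraction of the k votes; no strict majority means UNCERTAIN. The
early-diverging flag is inherited when at least half of the neighborhood
carries it, and an LGT *candidate* is flagged (never asserted) when the
genome's phylum differs from the nearest reference's phylum at support
≥ 0.5, after GTDB sublineage merging.

The alignment-column **indel filter** keeps a column iff its gap fraction is
at most `indel_filter_max_gap_frac` (0.5), the usual pre-filter before
distance computation on a DsrAB alignment.

## Primer evaluation

Matching is indel-free IUPAC set intersection. An ambiguity code on the
*target* side matches whenever the expansion sets intersect — so a target N
always matches, which inflates coverage on N-rich sequences; the
`target_ambiguity_is_mismatch` flag flips this to conservative counting.
The whole sequence is scanned (database sequences have heterogeneous
starts; primer anchor coordinates are reporting metadata only), forward
primers on the given strand and reverse primers against the reverse
complement with positions mapped back. A degenerate *mix* covers a sequence
if any variant binds within the budget (logical OR, matching the wet-lab
mixture). Clade coverage passes at fraction **≥ 0.75** (inclusive) with
**≤ 1 mismatch**; lineage gene presence displays at fraction **> 0.30**
(strict). The two inequalities differ on purpose — they are encoded
verbatim from the respective display rules, and the boundary cases (0.75
passes, 0.30 does not) are pinned by acceptance tests. The mismatch budget
is applied per primer, not per pair; `find_amplicons` takes its own budget
argument so a per-pair policy can be composed by the caller.

## What the generator emulates — and what it does not

The synthetic world is: random protein ancestors per family; type groups
radiated at `between_type_divergence = 0.45` expected pairwise divergence;
`n_seeds = 5` seeds per group at `within_family_divergence = 0.15`; genome
genes emitted at `query_mutation_rate = 0.10`; uniform amino-acid
background; shuffled decoys; nucleotide backbones with primer sites
implanted at exact mismatch counts. Twelve archetypes mirror recurring
real-genome configurations: canonical reducer and oxidizer, dual-*dsrAB*
switchers (separate-contig and same-contig variants), sulfite-only gut
organism, the no-*dsrD*-but-DsrL-1 conflict case, early-diverging archaeon
and bacterium, and an all-decoy negative.

Deliberate simplifications: substitution-only evolution (no indels, no rate
heterogeneity, no site-specific conservation), uniform residue background,
and type groups that are equidistant star radiations rather than trees. A
green test therefore establishes that the *algorithms implement their
contracts* — exact oracle agreement, exact truth recovery inside the
calibrated divergence envelope, correct threshold semantics — not that the
thresholds transfer to real proteomes, where detection cut-offs should be
re-examined against a curated reference set. Two generator parameters were
fixed by design rather than by any source: `n_seeds = 5`, so a type group
can fill the default typing neighborhood (a self-query must be able to
reach support 1.0 at k = 5), and sequence lengths of 180–260 residues,
short enough to keep the full suite fast while long enough that shuffled
decoys and true members separate by two orders of magnitude in normalized
score.

## Numerical and engineering choices

* **Scoring backend.** Smith–Waterman is delegated to
  `Biostrings::pairwiseAlignment`; an independent full-DP oracle in the
  test suite checks exact score agreement on a thousand random pairs, so
  the gap-cost convention is pinned by test, not by documentation.
* **Phylum merging.** `normalize_phylum` strips trailing `_<CAPITALS>`
  tokens to exhaustion. Stripping only one token would satisfy the
  sublineage examples but violate idempotence on pathological inputs;
  idempotence is the stronger invariant and the two rules agree on all real
  GTDB names.
* **Determinism.** One RNG stream per generator run; every pipeline output
  is a plain TSV with a fixed column order and a config-hash comment header
  (no timestamps), so reruns are byte-identical — asserted by test.
* **Ties.** Nearest-neighbor candidates order by (score, reference id);
  binding-site ties break to the smallest input-strand position; vote ties
  yield UNCERTAIN.
* **Degenerate inputs.** Empty proteomes error unless `lenient`; empty
  clades, ragged alignments, mixed-orientation mixes, and
  sequence-shorter-than-primer are classed errors
  (`dsr_empty_clade_error`, `dsr_alignment_error`, …) that tests dispatch
  on by class.

## Limitations

Typing is nearest-reference, not phylogenetic placement: no branch
supports, no detection of novel deep lineages. Detection thresholds are
benchmark-calibrated, not transferable constants. The LGT flag is a
discordance marker, not an evolutionary claim. Catalogue summaries
(`count_catalogue`) define their own input schema; users holding a
published supplementary genome table must map its columns onto
`genome_id / domain / taxonomy / genome_type / completeness /
contamination / dsrab_type`.
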