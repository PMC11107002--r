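---
title: "Designing species-diagnostic multiplex PCR assays with ampliplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing species-diagnostic multiplex PCR assays with ampliplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliplex)
```

## The problem

Many groups of morphologically plastic organisms — oysters of the genus
*Saccostrea* are the motivating case — contain sympatric species that cannot
be told apart by eye. Barcoding every specimen by Sanger sequencing of the
mitochondrial COI gene is accurate but expensive, and COI amplification and
sequencing is notoriously unreliable in bivalves. A cheaper route is a
**multiplex PCR assay**: one primer pair per species, all run in a single
reaction, with each pair amplifying only its target species and producing a
product of a distinctive length. A plain agarose gel then identifies the
species of every sample from its band size alone.

Designing such an assay is a constrained search problem:

1. each primer must anneal to *every* individual of its target species
   (avoid intraspecific polymorphism),
2. each pair must amplify *no other* species in the panel (exploit
   interspecific differences, especially near the primer 3' end),
3. the product sizes of all pairs must be far enough apart to be readable as
   separate gel bands, and
4. all primers must co-exist in one reaction (similar melting temperatures,
   no strong primer–primer interactions).

ampliplex implements this search, plus the downstream machinery: in-silico
PCR to predict what a panel amplifies, gel band-pattern simulation, and a
rule-based species caller that turns observed band sizes into identifications.

## Species profiles and discriminative positions

All design happens on one shared master alignment of barcode sequences with
species labels. For each species, `build_profile()` computes:

* a **consensus**: per-column majority base over non-gap residues; ties
  become the IUPAC code of the tied set (`A`/`T` tie → `W`), so
  within-species variation is carried forward rather than hidden behind an
  arbitrary base; all-gap columns become `N`;
* the **polymorphic columns**: every column where two or more distinct
  concrete bases occur among the members (an ambiguity code counts as all
  its bases). Primer windows must not touch these columns, so every
  conspecific individual matches its primers exactly;
* a **degenerate consensus**: the per-column IUPAC union of every observed
  base — the "any individual of this species" view used for specificity
  screening (below).

A column *discriminates* two species when their consensus bases are
**disjoint as IUPAC sets** — they share no concrete base. An ambiguous
consensus that overlaps the other species' base is deliberately *not*
counted: a primer ending on such a column might still anneal to some
non-target individuals. Gap and `N` columns never count.
`count_discriminative_positions()` applies this definition to any column
interval, and `discrimination_table()` tabulates counts for every
(primer region, target, non-target) combination; a `worst_case` mode
instead takes the minimum over the non-target's individual sequences.
Disjointness of sets is symmetric, so the count is symmetric in its two
species, and enlarging a region can only increase it.

## Melting temperature

Candidates are scored with a nearest-neighbor duplex model: unified
dinucleotide \(\Delta H\)/\(\Delta S\) stacks with terminal A·T / G·C
initiation corrections,

\[
T_m = \frac{1000\,\Delta H}{\Delta S + 0.368\,(N-1)\ln[\mathrm{Mon}^+]
      + R \ln(C_T/4)} - 273.15 ,
\]

with the divalent cations of a PCR buffer folded into a monovalent
equivalent \(\mathrm{Mon} = \mathrm{Na} + 120\sqrt{\mathrm{Mg} -
\mathrm{dNTP}}\) (all mM). The chemistry defaults — 50 mM monovalent,
1.5 mM Mg²⁺, 0.6 mM dNTP, 50 nM total oligo — follow the Primer3 defaults,
so the conventional 57–62 °C design window behaves as practitioners expect;
with monovalent salt alone the same window would demand implausibly GC-rich
primers. The test suite pins `melting_temperature()` against an independent
published nearest-neighbor implementation to 0.01 °C at identical chemistry.

Only unambiguous A/C/G/T windows ever reach the Tm computation; windows
containing ambiguity codes or gaps are rejected earlier.

## Candidate enumeration and pairing

`enumerate_candidates()` slides every window of length 18–23 bp along the
species consensus, both strands, and keeps windows that

* contain no gap, no ambiguity code and no polymorphic column,
* fall inside the GC bounds (30–70 %, optimum 50 %) and Tm bounds
  (57–62 °C, optimum 59 °C).

Each survivor is annotated with its discriminative-position counts against
every other species, over the whole window and inside the 3'-terminal
window (4 bp by default) — on the correct end for its strand. Candidates
are ranked by a score that weighs closeness to the length/Tm/GC optima and
the minimum discrimination equally (1:1; there is no principled weighting
to inherit, so the simplest one is used and documented).

`enumerate_pairs()` combines forward candidates with downstream reverse
candidates of the same species. The **product size is measured on the
gap-stripped consensus** from the forward footprint start to the reverse
footprint end, inclusive of both footprints — the length a gel band runs
at. Two admissibility rules apply per non-target species:

* each primer carries at least `min_discrimination` (default 1)
  discriminative positions, and
* at least one primer of the pair has a discriminative position inside its
  3'-terminal window **against the degenerate consensus** of that species.

The second rule is exactly the condition under which the annealing model
(below) forbids the pair from amplifying *any* observed haplotype of that
species. Requiring a 3'-window difference of every primer individually
turns out to be counterproductive: such windows cluster in one divergent
region of the barcode, leaving no convergent forward/reverse geometry, while
specificity only needs one blocked primer per pair. Using the degenerate
rather than the majority consensus matters too: a rare non-target allele
can erase the single blocking mismatch, which is precisely the mechanism by
which nominally species-specific primers occasionally amplify close
relatives in the laboratory.

Pairs are deduplicated to at most one per 10 bp product-size bin (keeping
the best-scoring), so the panel search sees size diversity rather than many
near-identical products.

## The annealing mismatch model and in-silico PCR

A primer anneals to a template site when, under IUPAC-aware matching
(positions match when base sets intersect),

* total mismatches ≤ 2, and
* mismatches in the 3'-terminal 4 bases = 0.

These defaults are conservative and configurable (`mismatch_model()`). The
model is purely sequence-based: it does not capture the
annealing-temperature dependence of specificity, which in practice can both
create and remove faint non-target bands. Positive cross-amplification
predictions therefore carry a "verify empirically" note.

`find_binding_sites()` scans both strands of a template exhaustively;
`predict_amplicons()` turns every convergent (plus-strand forward,
minus-strand reverse) site combination with an in-range product length into
a predicted amplicon; `simulate_multiplex()` unions amplicon lengths over a
panel to produce per-sample band patterns (presence/absence only — no
intensity model). The scanner is validated against an independent quadratic
re-scan on hundreds of random templates.

## Panel search

`select_panel()` performs a deterministic branch-and-bound over one
candidate pair per species. A feasible panel must satisfy

* pairwise product-size differences ≥ 55 bp — the readability limit for
  neighbouring bands on a standard agarose gel, applied to **all** panel
  members (the conservative reading when co-occurrence is unknown),
* no predicted cross-amplification among the panel's species (screened
  against degenerate consensuses),
* a melting-temperature spread ≤ 5 °C across all primers, and
* at most `max_plex` pairs (default 4; larger multiplexes commonly fail in
  practice even when the in-silico constraints hold, because reaction
  chemistry degrades with primer count).

Among feasible panels the search maximises first the minimum pairwise
spacing, then the minimum discrimination, with a deterministic
lexicographic tie-break, so identical inputs always yield byte-identical
reports (`format_panel_report()`). When the full species set is infeasible
— or simply larger than `max_plex` — the result is not an error but a
structured report of **all maximal feasible subsets**; split assays used
sequentially are a perfectly serviceable outcome, and
`end_to_end_benchmark()` applies them that way (samples one assay leaves
unidentified are re-run with the next).

`cross_dimer_screen()` additionally flags primer pairs whose 3'-terminal
k-mer (k ≥ 5) can anneal within the other primer — extendable 3' dimers
being a plausible mechanism of multiplex failure. The screen is advisory
and never blocks a panel, because the evidence linking predicted dimers to
failed multiplexes is weak.

## Calling species from band patterns

`call_species()` matches observed band sizes to the panel's expected
product sizes within ± 10 bp (agarose sizing precision; configurable).

* Bands **larger than the panel's largest expected size plus the
  tolerance** are ignored as non-specific amplification — they cannot
  collide with any diagnostic product. This generalises the common
  observation of a large extra band accompanying a correct diagnostic band.
* No matched band → `unidentified`; one matched species → that species.
* Several matched species are resolved by **priority rules, which are data,
  not code**: an ordered table of band-pattern → call entries
  (`default_priority_rules()`, shipped as a TSV). The default rule encodes
  the interpretation that a lane showing both the lineage B and lineage G
  product sizes is lineage G, because lineage B primers can cross-amplify
  lineage G DNA at multiplex annealing temperatures while the reverse does
  not occur. Other clades can ship their own rules file.
* Matched sets covered by no rule return `ambiguous`, with all matches
  listed in the rationale. In-range bands matching nothing are recorded in
  the rationale but do not overturn a unique expected-size match.

Every band set maps to exactly one call, and the call is invariant under
adding any band above the ignore threshold. `render_lanes()` draws a
deterministic text gel with a 100 bp ladder, merging bands closer than the
spacing limit and annotating them as unresolvable.

## The synthetic clade generator

`generate_clade()` provides the controlled substrate for testing the whole
pipeline without any downloads: one random ancestral sequence; a **star
phylogeny** in which each species consensus is derived by independent
per-site substitutions at the interspecific rate; individuals derived from
their species consensus at the polymorphism rate; substitutions uniform
over the three alternative bases. Defaults — 5 species, 600 bp, divergence
0.05/site/branch, polymorphism 0.003/site/individual, 20 individuals per
species — mirror the design setting the toolkit targets: a handful of
confusable congeners whose public barcode records are mostly under 600 bp,
with ~20 reference specimens per species. Under this model two species
consensuses differ per site with probability \(2d(1-d) + \tfrac{2}{3}d^2\)
(both branches mutating the same site coincide with probability 1/3), and
the generator is tested against that closed form.

`generate_cohort()` draws a sample set by multinomial species proportions,
picks a random conspecific individual as each sample's template, and marks
a configurable fraction (default 10 %) as dropouts with empty templates —
emulating failed extractions or PCR inhibitors.

What the generator deliberately does **not** emulate: real COI base
composition and codon structure, transition/transversion bias, realistic
coalescent genealogies, sequencing error, PCR stochasticity beyond
dropout, or band intensities. Passing end-to-end tests on synthetic clades
therefore demonstrates the internal consistency of the design–amplify–call
chain under its own assumptions, not performance on real *Saccostrea* data;
empirical validation of any designed panel remains necessary.

Everything is a pure function of its integer seed, so all simulation-based
tests and the acceptance script are exactly reproducible.

## Problem sizes used in the test suite

The shipped tests exercise: oracle-equivalence of the binding-site scanner
on 200 random templates up to 1 kb; independent constraint-checking of
designed panels on 50 synthetic clades at default settings; perfect
end-to-end identification over 20 cohort seeds; the divergence closed form
over 50 clades; and feasibility monotonicity over a divergence grid with 15
seeds per level. These sizes give stable statistics for each property while
keeping the default suite quick enough to run routinely.

## Known limitations

* Annealing-temperature effects on specificity are not modelled; the
  empirical optimisation they sometimes require has no in-silico
  counterpart here.
* No hairpin/secondary-structure free-energy computation and no degenerate
  primer or probe design.
* The input alignment is taken as given; the package computes no alignment
  (any standard aligner's output works).
* Band calling is presence/absence; faint-band evidence is not usable.
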