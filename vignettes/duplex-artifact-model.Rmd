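---
title: "Duplex consensus error correction and the single-strand artifact model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex consensus error correction and the single-strand artifact model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexsim)
library(data.table)
```

## The problem

Duplex consensus sequencing calls a base only where read families derived
from *both* strands of one original DNA molecule agree. Because polymerase
and sequencing errors, and almost all DNA damage, affect a single strand,
this suppresses the error rate to roughly the product of the two per-strand
family error rates — low enough to measure mutation frequencies around
10⁻⁷ per base pair.

One error class survives: damage sitting in a **single-stranded (SS)
region** of the sheared fragment. Sonication leaves 5′ and 3′ overhangs at
fragment ends, and possibly nicks and gaps inside the duplex. During
library preparation, end repair fills 5′ overhangs and gaps using the
(possibly damaged) SS stretch as template and chews back 3′ overhangs.
A miscoding lesion on a filled-in template — 8-oxoguanine pairing with
adenine (G>T), 2-aminoimidazolone (G>C), deaminated cytosine (C>T) — is
thereby copied into *both* strands before any PCR happens. The resulting
substitution is strand-concordant and indistinguishable from a true
mutation to any duplex caller.

This package implements both halves of the problem: a consensus caller
that groups read pairs without molecular barcodes, and a mechanistic
simulator that generates fragments with SS regions, damages them, digests
them with single-strand-specific nuclease (SSN) models, end-repairs them
and sequences them — with full truth tables — so the artifact mechanism,
the read-clipping countermeasure, and nuclease-based removal can be
studied quantitatively without any real sequencing data.

## The consensus model

Aligned read pairs are grouped by their exact fragment interval
`(chrom, start, end)` — the *same-position group* (SP-G) — and split into
the two orientation families (R1-forward vs R1-reverse), which correspond
to the two template strands of the original molecule. Per family and
position, a base is called when at least a fraction θ of covering reads
agree; the duplex consensus (dsDCS) emits a base only where both family
calls agree, `N` elsewhere, with positions flagged as resolved, strand
conflict, or insufficient.

Choices the method itself does not pin down, and the defaults used here:

* **Minimum family size — 1 per orientation.** Presence of both read
  directions is the method's only hard requirement; deeper families are
  welcome but not required. Configurable.
* **Agreement threshold — unanimity for families of ≤ 2 pairs, θ = 0.8
  above.** Small families cannot out-vote an error, so they must be
  unanimous; at 3+ members 0.8 tolerates a single dissenting read in
  families of five or more. A fraction exactly equal to θ is accepted;
  when two bases tie at the maximum the position is ambiguous and (for any
  θ > 0.5) becomes `N`.
* **No re-mapping of consensus reads.** dsDCS records keep their SP-G
  coordinates, which are exact for simulated data; `export_dcs_fastq()`
  exists for users who want to re-align externally.
* **Substitutions only.** Positions under indels are projected as `N`
  (insertions dropped, deletions masked) and never counted.

## Counting frames

Strand-resolved (12-type) spectra need a convention for which strand a
substitution is reported on. Two frames are implemented:

* `frame = "reference"`: classes follow the reference plus strand.
* `frame = "fragment"` (default): classes follow the orientation in which
  each base was *sequenced*. Positions nearer the left fragment end are
  read by the forward mate and keep reference orientation; positions
  nearer the right end are read by the reverse mate and are complemented
  (a tie at the exact midpoint sides with the forward read).

The fragment frame is the one in which the SS artifact shows its
signature. End-repair damage lands near fragment ends: on the plus strand
at left ends (reference G>T) and on the minus strand at right ends
(reference C>A). In reference frame these cancel into symmetry; in the
sequenced-read frame both appear as G>T, which is exactly the G>T ≫ C>A
and G>C ≫ C>G excess that motivates the whole exercise. The 6-type pooled
spectrum is identical in either frame, which the test suite asserts.

Frequencies divide substitution counts by the total non-`N` consensus
bases whose (frame) reference base matches the class, scaled to 10⁶;
classes with zero denominator are reported missing, not zero.

## The simulator

`shear_fragments()` draws fragment lengths from a truncated normal
(default mean 350 bp, SD 50 bp — a typical sonication peak) placed
uniformly on the genome. Each end is independently blunt, 5′ or 3′
overhanging (default ⅓ each); overhang lengths are zero-truncated
geometric with mean 8 bp. The geometric default reflects that overhang
lengths of sonicated DNA are poorly characterized and apparently
heavy-tailed — long enough that clipping 20 terminal bases does not remove
every artifact, which matches the observed residual. Nicks and gaps occur
in the double-stranded core as Poisson processes (defaults 5×10⁻⁴ and
2×10⁻⁴ per bp; gaps are a hypothesis about sonicated DNA rather than an
established fact, so their rate is a dial that can be set to zero).

`apply_ss_damage()` places lesions only at eligible bases inside SS
regions: overhangs (the protruding strand), gap intervals (the intact
opposite strand, i.e. the fill-in template), and a frayed window of the
strand opposite each nick (half-width 2 bp). Default per-base
probabilities: 8-oxoG 0.02 and Iz 0.005 per SS guanine — chosen so an
undamaged-looking library still shows a clear artifact signal at desk
scale — plus strand-discordant damage at 10⁻⁴ per ds base. The
manifestation map (oxoG→T, Iz→C, deamC→T on the damaged strand) is fixed
at damage time; the spectrum module chooses the reporting frame later.

`digest_nuclease()` models three enzyme archetypes with saturating
activities `p(units) = p_max (1 − e^{−units/k})`: an S1-like
endonuclease (overhangs, gaps, and nicks), a mung-bean-like endonuclease
(same but with much weaker nick activity, `p_max = 0.25`, large `k`), and
a RecJf-like 5′→3′ exonuclease (5′ overhangs only). Cleavage at a gap or
nick splits the molecule (lineage tracked via dotted suffixes); products
below 50 bp are not emitted. Random draws are pre-laid-out per substrate,
so runs at different units under one seed share common random numbers and
surviving-lesion counts are provably monotone in dose. Endonuclease
cutting carries an optional terminal-base preference (default favoring G
4:1 for the S1 model, G/C 2.5:1 for the MBN model, none for RecJf) that
reproduces the first-cycle composition bias of treated libraries.

`end_repair()` chews 3′ overhangs (their lesions vanish with the removed
strand), fills 5′ overhangs and gaps over their templates, and reseals
nicks after resynthesis of the frayed window; surviving SS lesions become
concordant duplex substitutions, ds damage stays discordant. The
nick-adjacent rule deserves a note: treating the region around a nick as
pseudo-double-stranded material whose strand is replaced 5′→3′ during end
repair is what makes differential *nick* activity matter — it is the
mechanistic reading under which an S1-like enzyme outperforms an MBN-like
one specifically on G>T errors.

`sample_and_sequence()` samples molecules without replacement
(proportional to the ligated amount via `molecules_per_unit`), gives both
strands of each molecule a zero-truncated-geometric number of PCR
duplicates (mean 3; the duplicate law is not known, a geometric is the
simplest overdispersed choice), plants early-PCR errors once per strand
family (10⁻³ per base; shared by all duplicates, which is what makes them
survivable by strand consensus and catchable only by the duplex step) and
independent sequencing errors per read base (10⁻³, matching the constant
Q30 qualities written to FASTQ; quality-aware consensus is out of scope).
Output is paired FASTQ, a truth-aligned SAM (no aligner involved), and
truth tables of molecules and planted substitutions.

## What the simulation does and does not show

The generator reproduces the *mechanism*: coordinate-based family
grouping, strand-asymmetric artifact fixation, dose-dependent digestion,
dilution-dependent coordinate collisions. It does not model real base
quality, GC-dependent coverage bias, chimeras, alignment ambiguity, or
enzyme biochemistry (units are probability dials, not enzyme units), and
its genome is i.i.d. rather than a real bacterial sequence. Passing the
property suite therefore validates the pipeline's logic and the
mechanism's arithmetic, not instrument-level realism.

## Statistics

Group comparisons run per mutation class on per-replicate frequencies:
two-sided equal-variance Student's *t* (Welch by flag), or Dunnett's
many-to-one test for several treatments against one control, computed
from the equicorrelated multivariate-*t* distribution of max |t|
(correlation `sqrt(n_i n_j / ((n_i+n0)(n_j+n0)))`, df = N − k − 1) via
`mvtnorm`. With one treatment group it reduces exactly to the *t* test,
which is asserted in the tests together with a Monte-Carlo max-|t| oracle
and a cross-check against `multcomp`. Fold changes use a frequency
pseudocount ε = 0.001 per 10⁶ bp so zero-frequency classes stay finite;
the choice of ε only matters for classes within ~ε of zero.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; SAM output is 1-based.
* Consensus ties exactly at threshold are accepted; tied top bases → `N`.
* Clipping masks `k` bases at *each* fragment end as `N` (2k ≥ length
  blanks the pair), shrinking numerator and denominator together.
* Coverage mean/SD/CV are per-position over the whole genome; the
  50,000-section histogram is descriptive, and a per-bin variant of the
  statistics is available by flag since published summaries do not state
  which basis they used. The covered rate counts all genomic positions.
* Empty inputs: an all-zero denominator raises an explicit error rather
  than emitting a 0-frequency table; empty coverage reports CV as missing.
* Misassignment: the closed-form expectation throws k molecules into the
  coordinate cells of the length model (Poisson occupancy per length
  class) and reports the expected multi-molecule fraction of occupied
  cells, alongside the classical 1 − exp(−k(k−1)/2N) any-collision form
  with N the effective coordinate count 1/Σp².

## Scale of the shipped experiments

The property tests and the acceptance script run at desk scale, chosen to
make every asserted effect at least ~3 counting-noise standard deviations
wide: a 100 kb genome with 10⁴ fragments for the mechanism and nuclease
experiments, 4×10⁴ molecules for the duplex-suppression measurement, up to
6.2×10⁵ molecules (coordinates only) for the collision curve, and 3×10⁴ bp
at matched depth for the coverage-robustness comparison. All stages derive
their seeds from one global seed.

## A worked mini-run

```{r worked, eval = FALSE}
g <- make_genome(50000, 0.52, seed = 1)
fr <- shear_fragments(g, 3000, nick_rate = 5e-4, gap_rate = 2e-4, seed = 2)
fr <- apply_ss_damage(fr, damage_params(), seed = 3)
sim <- sample_and_sequence(end_repair(fr),
                           library_params(n_molecules = 2500, seed = 4))
dcs <- call_duplex_consensus(sim$pairs)
frequencies(count_substitutions(dcs, g, frame = "fragment"))$freq12
```

The G>T and G>C rows dominate their C>A / C>G counterparts; repeating
with `digest_nuclease(fr, nuclease_model("s1"), units = 100, ...)`
before `end_repair()` collapses the excess.

## Known limitations

* SP-G grouping requires exact coordinate equality; soft-clipped or
  ragged alignments of real data would fragment families (real pipelines
  sometimes tolerate ±1 bp).
* The fragment-frame assignment splits read orientation at the fragment
  midpoint, which is exact for terminal artifacts but approximate for
  mid-fragment positions of heavily overlapping pairs.
* PCR errors are modeled as first-cycle only; late-cycle errors (which
  duplex calling also removes) are folded into the sequencing error rate.
* `run_experiment()` compares each treated cell against the untreated
  cell of the same ligated amount; other contrasts are available by
  calling `compare_groups()` directly.
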