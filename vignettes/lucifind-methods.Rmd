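---
title: "Methods: homology screening, isotope-label detection and COI delimitation in lucifind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology screening, isotope-label detection and COI delimitation in lucifind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lucifind)
```

## What the package computes

`lucifind` implements the computational side of a question in copepod
bioluminescence: does a *Metridia* copepod transcribe luciferases (and
perhaps photoproteins or luciferin-synthesis enzymes), and does it make its
own coelenterazine luciferin rather than eating it? The pipeline has five
analysis stages plus a synthetic-data module:

1. **ORF prediction** from assembled transcripts (six-frame, structural);
2. a **homology screen** of predicted peptides against small curated local
   databases, validated by a **reciprocal bitscore comparison** against a
   large curated reference database;
3. a **C-terminal FYY motif scan** of mature predicted proteins, the
   putative coelenterazine-precursor signature;
4. **exact-mass detection** of ¹³C-labelled coelenterazine-pathway ions in
   centroided LC-MS peak lists via extracted ion chromatograms (EICs);
5. **COI barcode distance analysis** with threshold-based species
   delimitation and a neighbor-joining tree.

## ORF prediction

ORF calling is purely structural: both strands × three frames are
translated under the standard genetic code, and within each frame a
*complete* ORF runs from the first ATG of a stop-delimited segment to that
stop. Segments that touch a frame end without the corresponding start or
stop are classed `five_prime_partial`, `three_prime_partial` or `internal`,
mirroring the completeness vocabulary of transcriptome ORF callers. No
coding-likelihood (Markov) score is computed: the only retention criterion
is a minimum peptide length, default **5 aa** — deliberately permissive so
that short luciferin-precursor peptides are not discarded. "Mature"
downstream always means `complete` (start **and** stop codon present).

Conventions worth stating explicitly, since they are where off-by-one bugs
live: coordinates are 0-based half-open nucleotide offsets *on the reported
strand* (minus-strand ORFs are indexed on the reverse complement), the stop
codon is included in the span, and codons containing `N` translate to `X`.
`X` scores the substitution-matrix minimum against every residue, so
ambiguous sequence can never create a hit. All ORFs are reported per
transcript; when a per-cluster representative is wanted,
`longest_per_cluster()` keeps the longest peptide per read-cluster label
with deterministic tie-breaks (lexicographically smallest transcript id,
then smallest start). We predict all ORFs per transcript rather than a
single best one, since several database matches can legitimately come from
one transcript.

## Local alignment and its statistics

The screen's alignment engine is an exact Smith–Waterman with affine gaps
(Gotoh's three-state recursion, implemented in C++), not a heuristic
seeded search: at the database sizes this pipeline targets (tens to
hundreds of curated proteins) exhaustive optimal alignment is affordable
and removes seeding artefacts. A gap of length $L$ costs
$G_\mathrm{open} + L \cdot G_\mathrm{extend}$. The traceback is
deterministic (diagonal preferred over up over left on ties) so results are
byte-reproducible.

Raw scores $S$ are converted to bitscores with the Karlin–Altschul
parameters $\lambda$ and $K$:

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad
  E = m \, n \, 2^{-S'},$$

with $m$ the query length and $n$ the total residue count of the searched
database. Defaults are the conventional gapped-BLOSUM62 values: gap open
11, extend 1, $\lambda = 0.267$, $K = 0.041$. We apply no effective-length
(edge) correction and no composition-based adjustment, so E-values track
but do not exactly reproduce those of production BLAST; published E-values
should be treated as consistency references. Bitscores are unaffected by
this choice, which matters because the screen's decision rule compares
bitscores precisely *because* they are insensitive to database size.

## The reciprocal screen

For each ORF × local database, the best local hit must pass the E-value
cutoff (default $10^{-5}$); only the top hit is kept, with ties broken by
lower E-value then lexicographic accession. Passing candidates are
re-queried against the reference database and **retained iff the local
bitscore is equal to or higher than the best reference bitscore** — equal
counts as retained. Two readings of the comparison were open; we resolved
them as follows. The comparison uses the *single best* reference hit (the
standard reciprocal-best-hit reading), and **no E-value cutoff is applied
on the reference side**: a weak reference hit should still be allowed to
outscore a weak local hit (both choices are configurable). Rejected
candidates are kept in the output with their winning reference accession,
because the negative results — photoprotein candidates that really are
calmodulins, luciferin candidates that really are other oxidoreductases —
are part of the scientific story.

## The FYY motif scan

Coelenterazine is plausibly a cyclized Phe–Tyr–Tyr tripeptide, so complete
predicted proteins whose final three residues before the stop are exactly
`F`,`Y`,`Y` are flagged as putative precursor/synthesis candidates.
Matching is literal and case-insensitive with no substitutions tolerated;
partial ORFs are never candidates (an absent stop codon makes the
"C-terminus" unknowable). A mature ORF is defined by its start and stop
codon only; no untranslated flanks are required. Candidates are
cross-referenced against the screen output so a report can say whether
they match known oxidoreductases or nothing at all.

## Exact-mass isotope-label detection

Label arithmetic is done from a fixed constant table (monoisotopic masses:
C = 12 exactly, H = 1.00782503, N = 14.0030740, O = 15.9949146,
¹³C = 13.0033548) with the **proton** mass 1.00727646 Da for the
[M+H]⁺ adduct — using the hydrogen-atom mass instead would miss the
published 4-decimal ion centers, since the electron mass matters at this
precision. Coelenteramine is C₁₇H₁₅N₃O and coelenterazine C₂₆H₂₁N₃O₃ in
the built-in compound table; each ¹³C label shifts the ion by exactly
1.0033548 Th regardless of position. For C₁₇H₁₅N₃O this gives the ¹³C₈ and
¹³C₉ [M+H]⁺ centers 286.1556 and 287.1590.

EIC extraction sums, per scan, the intensities of peaks within a **closed**
±10 ppm window of the target m/z (a 10.0-ppm peak is in; the closed
boundary carries a 10⁻⁹-ppm absolute slack purely so floating-point
rounding of the ratio can never drop an exactly-boundary peak). Detection
takes the EIC apex, computes the mass error at the apex as the
intensity-weighted mean observed m/z inside the window versus the
theoretical value (reported to 1 decimal place, as conventional), and
compares the apex retention time against an authentic standard within a
configurable tolerance (default 0.2 min). An all-zero EIC yields an
explicit "not detected" report — the machinery must be able to state
absence, e.g. for intact coelenterazine. Peak areas are trapezoidal over
the EIC; integration bounds are the whole chromatogram, a choice that only
matters for reporting since no quantification is attempted.

## COI distances and delimitation

Distances are **uncorrected p-distances** — the barcoding convention, and
the natural reading of divergences quoted as plain percentages — with
**pairwise deletion**: a site enters a pair's comparison only if both
characters are in {A,C,G,T}. Whether published ranges used pairwise or
complete deletion is typically unstated; pairwise is the default here and
complete deletion is available as a flag (`deletion = "complete"`).
Delimitation joins every pair at distance ≤ cutoff (default **3%**, the
customary crustacean COI species threshold) and takes connected components
— single-linkage semantics with a closed boundary. `group_range()` reports
the min–max cross-group distance in the form interspecies divergence is
conventionally quoted.

The `nj_tree()` function wraps standard neighbor joining (via `ape`) with
negative branch lengths clamped to zero. It is an auxiliary, desk-scale
visualization of clade structure: it is *not* a maximum-likelihood
phylogeny, performs no model selection and no bootstrap, and makes no
claim to replace one. NJ does recover any additive metric's topology and
branch lengths exactly, which is what the test suite exercises.
`flag_misidentified()` operationalizes "this GenBank record nests in the
wrong species" as: a sequence whose nearest label by mean distance differs
from its own label is flagged.

## The synthetic-data generators

The generators exist so every stage is testable, with known ground truth,
without any download. They emulate the *structure* of the real inputs, not
their full biology:

* **Transcriptomes** (`gen_transcriptome()`): each planted transcript
  embeds a mutated copy of a named source protein at a controlled identity
  — substitution positions drawn without replacement, replacements uniform
  over the 19 alternative residues, so the realized identity is the closest
  achievable to the target (±0.5 residue). Mature plants are flanked by an
  ATG and a stop plus start-codon-free UTRs (20–60 nt), so the planted ORF
  is exactly the first-ATG ORF of its segment; immature plants omit the
  stop. The first and last residues are left unmutated (`protect_ends`) so
  that a local re-alignment of the recovered ORF against its source spans
  the full protein instead of trimming mismatched termini — without this,
  round-trip identity estimates are biased upward by end-clipping. Decoys
  are i.i.d. uniform nucleotides (default 300–600 nt): at test-scale
  database sizes the probability of a decoy ORF reaching the E ≤ 10⁻⁵
  needed for retention is negligible. No read-level error, expression
  levels, chimerism or codon-usage bias is simulated.
* **Peak lists** (`gen_peaklist()`): planted ions trace a Gaussian
  chromatographic profile (default sd 0.2 min on a 0.05-min scan grid, a
  typical LC peak shape; the true shape is irrelevant to apex/area
  testing), with each observed m/z displaced uniformly within ±`ppm_jitter`
  of the planted value. Noise peaks are scattered uniformly but never
  within 3 × jitter of a planted m/z, so recovery-vs-noise tests are
  well-posed by construction. No isotope envelopes, detector saturation or
  intensity noise are simulated.
* **COI alignments** (`gen_coi_alignment()`): species ancestors diverge
  from a common root at *disjoint dedicated* sites (so the planted
  between-species p-distance is tight), individuals add uniform
  within-species substitutions on top; `between_div` is interpreted as the
  total individual-to-individual cross-species divergence, hence the split
  contributes `between_div − within_div`. This is a p-distance-controlled
  toy genealogy, not a coalescent; defaults (within 1%, between 13%,
  600 nt) sit inside the 10–15% range typical of congeneric copepod COI
  comparisons and the ~650-nt barcode region.

Because the generators control exactly the properties the stages measure,
passing round-trip tests demonstrates correctness of the *computations*,
not robustness to real-data pathologies (assembly artefacts, frameshifts,
co-eluting isobars, alignment error).

## Reproducibility and test scale

Every generator takes an explicit seed and restores the caller's RNG
state; identical seeds give byte-identical files. The pipeline driver
writes a manifest of MD5 checksums and treats run directories as
write-once. The test suite checks the alignment engine against an
independently written pure-R affine-gap DP (500 random pairs up to 30 aa,
plus a cross-check against `Biostrings::pairwiseAlignment`), ORF calling
against a brute-force enumerator (200 random transcripts up to 1 kb),
screen retention on 20 seeded fixture instances, NJ on 50 random additive
trees, and delimitation on planted partitions — sizes chosen so the whole
suite runs in well under a minute on one core while still giving the
property tests real coverage.

## Known limitations

* E-values are uncorrected (`m·n·2^(−S′)`); use bitscores for decisions.
* The alignment engine is exhaustive: fine for curated databases, wrong
  tool for proteome-scale searches.
* ORF calling has no coding-potential model; at `min_len = 5` it
  deliberately reports enormous numbers of spurious short ORFs and relies
  on the downstream screens for specificity.
* The ¹³C label count is capped by the carbon count but label *position*
  is ignored (it cannot affect integer-labelled monoisotopic masses).
* `nj_tree()` is distance-based only; branch support is out of scope.
* The supplied compound table covers the coelenterazine pathway only;
  other compounds can be passed as raw formulas.
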