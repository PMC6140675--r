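# lucifind

Tools for characterising the molecular basis of copepod bioluminescence
from assembled transcriptomes, LC-MS peak lists and COI barcode
alignments.

Bioluminescent *Metridia* copepods oxidise the luciferin coelenterazine
with secreted luciferases. Establishing how a species makes light involves
three computational questions this package answers:

1. **Which predicted proteins are luciferases (or photoproteins, or
   luciferin-synthesis enzymes)?** Open reading frames are predicted from
   transcripts (six-frame, minimum 5 aa so short precursor peptides
   survive) and screened against small curated local databases by optimal
   local alignment; candidates are validated by a *reciprocal bitscore
   comparison* against a large curated reference database. With raw
   Smith–Waterman score *S* and Karlin–Altschul parameters λ, K,

   &nbsp;&nbsp;&nbsp;&nbsp;S′ = (λS − ln K)/ln 2, &nbsp; E = m·n·2^(−S′),

   and a candidate is retained iff its local-database bitscore is **equal
   or higher** than the best reference bitscore (bitscores, unlike
   E-values, are comparable across databases of different sizes).
   Complete ("mature") ORFs are additionally scanned for a C-terminal
   **Phe-Tyr-Tyr (FYY)** motif, the putative coelenterazine-precursor
   signature.

2. **Does the animal synthesise its own coelenterazine?** After feeding
   ¹³C-labelled phenylalanine/tyrosine, labelled coelenteramine (the
   coelenterazine degradation product, C₁₇H₁₅N₃O) is sought in centroided
   Q-TOF peak lists by exact mass: each ¹³C shifts the [M+H]⁺ ion by
   1.0033548 Th, extracted ion chromatograms use a closed ±10 ppm window,
   and a detection reports apex retention time, mass error in ppm and
   whether the apex co-elutes with an authentic standard.

3. **Is the population one species or several?** COI barcode alignments
   are reduced to uncorrected p-distances (pairwise deletion), species are
   delimited as single-linkage clusters at the customary ~3% crustacean
   cutoff, cross-group divergence ranges are reported, and a
   neighbor-joining tree gives a quick distance-based view of clade
   structure.

A seeded synthetic-data module (`gen_transcriptome()`, `gen_peaklist()`,
`gen_coi_alignment()`) generates all of these inputs with known ground
truth, so the whole pipeline is testable offline.

## Worked example

```r
library(lucifind)

## -- isotope-label detection -------------------------------------------
labeled_mz("C17H15N3O", 8)   # 13C8-coelenteramine [M+H]+
#> [1] 286.1556

planted <- data.frame(mz = c(labeled_mz("C17H15N3O", 8),
                             labeled_mz("C17H15N3O", 9)),
                      rt_min = 14.4, intensity = c(1e5, 2e4))
sim <- gen_peaklist(planted, ppm_jitter = 2, noise_peaks = 50, seed = 42)
detect_labeled_ion(sim$peaklist, "C17H15N3O", 8, standard_rt = 14.4,
                   rt_tol = 0.2, compound = "coelenteramine")
#> 13C8-coelenteramine [M+H]+ m/z 286.1556: apex 14.40 min,
#>   observed m/z 286.1562 (1.9 ppm error), retention time matches standard
detect_labeled_ion(sim$peaklist, "C26H21N3O3", 0, compound = "coelenterazine")
#> coelenterazine [M+H]+ m/z 424.1656: not detected

## -- homology screen on a synthetic transcriptome ----------------------
luc <- random_proteins(2, seed = 8, len_range = c(120L, 150L), prefix = "LUC")
tx  <- gen_transcriptome(list(
         plant_spec(names(luc)[1], luc[[1]], 0.97, cluster = "c1"),
         plant_spec(names(luc)[2], luc[[2]], 0.62, cluster = "c2")),
       n_decoys = 10, seed = 7)
orfs <- find_orfs_all(tx$transcripts, min_len = 5)   # 140 ORFs
res  <- reciprocal_screen(orfs, list(luciferase = luc),
                          random_proteins(8, seed = 9, prefix = "SP"))
report_table(res, setNames(rep("Metridia sp.", 2), names(luc)))
#>          taxon accession pct_identity match_length  evalue bitscore
#> 1 Metridia sp.  LUC00001         97.1          139 2.2e-89    309.7
#> 2 Metridia sp.  LUC00002         62.3          130 7.8e-44    158.3

## -- COI species delimitation ------------------------------------------
coi <- gen_coi_alignment(c(4, 4), within_div = 0.01, between_div = 0.13,
                         length = 600, seed = 11)
m <- distance_matrix(coi$alignment)
threshold_clusters(m, cutoff = 0.03)
#> [[1]] "sp1_01" "sp1_02" "sp1_03" "sp1_04"
#> [[2]] "sp2_01" "sp2_02" "sp2_03" "sp2_04"
group_range(m, paste0("sp1_0", 1:4), paste0("sp2_0", 1:4))
#>   between-species COI distance: 12.7-13.0%
```

The two planted homologs come back at their planted identities (97% and
62%) with only the planted accessions retained; the two simulated species
separate cleanly at the 3% cutoff with a 12.7–13.0% divergence range
bracketing the planted 13%.

A thin command-line front end over the same functions lives at
`inst/scripts/lucifind.R`
(`simulate | orfs | screen | fyy | isoms | coi | run`), e.g.

```sh
Rscript inst/scripts/lucifind.R simulate --seed 4 --out-dir sim
Rscript inst/scripts/lucifind.R coi --alignment sim/coi.fasta --cutoff 0.03
```

For the full model description — scoring statistics, screen decision
rules, EIC conventions, distance conventions, what the synthetic
generators do and do not emulate — see
`vignettes/lucifind-methods.Rmd`.

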