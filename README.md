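# ipQC

Quality control, curation and candidate prioritization for MHC class I
immunopeptidomics, in R.

Immunopeptidomics identifies the peptides presented by MHC class I
molecules on a cell surface (the *immunopeptidome*) by immunoaffinity
purification and LC-MS/MS. Before any of those peptides can be trusted —
let alone nominated as a tumor-antigen vaccine candidate — the dataset has
to pass a QC battery: does the length distribution peak at 9 residues, are
the peptides predicted binders of the sample's own MHC haplotype, do
replicates overlap sensibly, and are proteolytic degradation products
("ladder" peptides) contaminating the runs? ipQC is written for
computational immunologists and proteomics bioinformaticians who need
those checks, the contaminant filter, and the downstream candidate
selection as reproducible, scriptable functions.

## What it computes

* **Ingestion** — search-engine peptide exports (TSV/CSV, PEAKS-style
  modification annotations stripped), FASTA proteomes, haplotype tables,
  reference ligand lists; allele-name normalization across dialects
  (`HLA-A*02:01` → `A02:01`, `H-2Kd` → `H2-Kd`).
* **Binding surrogate** — per-allele position-specific scoring matrices
  with log-odds entries `log(((c + κb)/(N + κ))/b)`, Monte-Carlo rank
  calibration (`rank = 100 · #{background ≥ score}/n`), SB/WB/nB classes
  at the standard 0.5%/2% rank thresholds, and a monotone surrogate
  affinity `50000^(1−s)` nM; external predictor output plugs in as a
  table.
* **Per-run QC** — length distributions, binder fractions (best-allele
  rank < 2) for 8–13mers and 9mers, allele-specificity deconvolution,
  UpSet-style exclusive replicate overlaps, motif summaries with
  per-position information content.
* **Contaminant filter** — the protein coverage ratio
  `r(P) = (1/L(P)) · Σ L(p)`, a cutoff calibrated as the mean 95th
  percentile over clean reference runs, and conservative curation
  (a peptide is removed only when *all* its source proteins are flagged).
* **Cohort comparison** — Szymkiewicz–Simpson overlap matrices (40%
  display cap, raw values retained), deterministic hierarchical
  clustering, one-hot haplotype encoding with the shared-allele rule and
  motif-group–conditional two-digit aggregation, known-ligand annotation.
* **Proteome scan** — all 9mer windows of the eluted proteins, predicted
  across the haplotype, compared against observation; abundance
  association statistics (Mann–Whitney, Spearman).
* **Candidate selection** — affinity < 50 nM, log fold change > 2, found
  in ≥ 3 replicates, 9mers preferred, deterministic ranking, poly-lysine
  export for capsid loading.
* **Synthetic data** — motif-consistent runs, proteomes, contaminant
  ladders and expression tables with full ground truth; this is how the
  package tests itself.

## Worked example

A complete synthetic study: generate a run, QC it, and query predictions.

```r
library(ipQC)

cfg       <- syntheticConfig(seed = 1)          # 2000 peptides, 2 alleles
proteome  <- generateProteome(cfg)
predictor <- trainSyntheticPredictor(cfg, nBackground = 20000, seed = 1)
run <- generateRun(cfg, proteome, sampleId = "MESO", replicateId = "r1",
                   seed = 2)$run
run
#> SampleRun MESO:r1 (cell_line)
#>   2000 unique peptides; haplotype: A02:01, B07:02

ld <- lengthDistribution(run)
round(c(ld$fraction8to13, ld$fraction9Of8to13), 1)
#> [1] 100.0  43.3        # % of peptides in 8-13; % of those that are 9mers

round(c(binderFraction(run, predictor, "all_8_13"),
        binderFraction(run, predictor, "only_9")), 1)
#> [1] 78.3 90.3           # % predicted binders (best-allele rank < 2)

deconvoluteSpecificity(run, predictor)$composition
#>   allele  SB WB
#> 1 A02:01 351 33
#> 2 B07:02 361 37

predictBinding(predictor, c("LLDVSMFGV", "APRLLDTYF", "GQDNTWMHS"))$best
#>     peptide allele  rank affinityNM class
#> 1 LLDVSMFGV A02:01  0.45   1.049894    SB
#> 2 APRLLDTYF B07:02  0.00   1.000000    SB
#> 3 GQDNTWMHS B07:02 11.69   3.542498    nB
```

The first two peptides carry the planted A02:01 (L-x7-V) and B07:02
(P/R-x-F) anchor motifs and come out as strong binders of the right
allele; the third is a random sequence. The 9mer binder fraction (90.3%)
exceeds the 8–13mer fraction (78.3%) because random "noise" peptides in
the generator — like real non-ligand contaminants — do not share the 9mer
length peak.

Contaminant filtering on the same design:

```r
clean  <- lapply(1:3, function(i)
  generateRun(cfg, proteome, replicateId = paste0("c", i), seed = 10 + i)$run)
cutoff <- coverageCutoff(calibrateCutoff(clean, proteome))
inj    <- injectContaminantLadder(run, proteome, "SYNP0001",
                                  nFragments = 20, fragmentLength = 9)
res    <- flagAndClean(inj$run, proteome, cutoff)
subset(res$report, flagged)[, c("accession", "proteinLength", "nPeptides", "ratio")]
```

The injected 20-fragment ladder drives `SYNP0001` well above the
clean-run-derived cutoff and its peptides are removed (`res$removed`
lists them). By construction of the 95th-percentile rule, about 5% of
ordinary proteins also sit above the cutoff in any run — the flag report
records every one, with its ratio, for inspection.

A thin command-line front end with subcommands `synth`, `qc`, `clean`,
`predict`, `compare`, `scan` and `select` ships in
`inst/scripts/ipqc` (run it with `Rscript`).

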