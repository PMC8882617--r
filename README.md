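# kernelreg

Analysis stack for F1-hybrid/parent seed-development transcriptomes, for
researchers studying heterosis in maize (or any diploid hybrid system) who
have gene-level FPKM matrices, allele-specific SNP read counts and kernel
phenotypes. It answers three questions:

1. **How is a hybrid gene expressed relative to its parents?** Each gene's
   F1 replicates are tested against per-replicate mid-parent values (MPV,
   `(P1 + P2)/2`) with a two-tailed homoscedastic t-test; genes with
   p ≥ 0.05 are *additive*, the rest are *over-dominant* (F1 mean above
   both parents), *under-dominant* (below both) or *dominant* (between).
2. **Does regulatory divergence act in cis or in trans?** For each SNP,
   three tests at α = 0.05 — hybrid allelic imbalance (H set, chi-square
   vs 1:1), parental imbalance (P set, chi-square vs 1:1 across the two
   parental libraries) and hybrid-vs-parent ratio difference (T set,
   t-test on per-replicate log2 ratios) — drive a seven-way assignment:
   cis-only, trans-only, cis+trans, cis×trans, compensatory, conserved,
   ambiguous. Genes take the modal SNP pattern at a ≥ 60% majority. Sites
   must be co-detected in DNA evidence, homozygous-divergent in parents,
   heterozygous in every hybrid replicate, and covered by ≥ 20 reads.
3. **Which co-expressed modules track kernel traits, and through which
   hubs?** Unsigned weighted networks (`a_ij = |cor|^β`, β = 9),
   topological-overlap clustering (min module size 50, eigengene merge cut
   0.15), module-eigengene/trait Pearson correlation (significant at
   p < 0.05), top-30 intramodular-connectivity hubs, and an edge list at
   TOM weight ≥ 0.20.

A synthetic-data generator plants known regulatory categories, inheritance
modes and module structure, so the whole stack is validated by recovery of
planted truth. See `vignettes/methods.Rmd` for the models, assumptions and
design decisions.

## Worked example

The `analysis/` scripts run the three arms on simulated data with planted
truth, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_inheritance.R
Rscript analysis/04_regulatory_divergence.R
Rscript analysis/05_coexpression.R
```

Output of the regulatory-divergence step (seed 2026, 100 genes per
category, depth 200, 3 replicates):

```
Gene-level pattern fractions:
      pattern count   fraction
     cis-only    96 0.16000000
   trans-only    96 0.16000000
    cis+trans   105 0.17500000
    cis×trans   107 0.17833333
 compensatory    98 0.16333333
    conserved    88 0.14666667
    ambiguous    10 0.01666667
   unassigned     0 0.00000000
Recovery of planted categories:
    cis-only    cis+trans    cis×trans compensatory    conserved   trans-only
        0.96         1.00         1.00         0.97         0.88         0.95
```

Reading this: with 2-log2-unit effects at depth 200, 96% of planted
cis-only genes are called cis-only; conserved genes top out near
(1 − 0.05)³ ≈ 0.86 because each of the three α = 0.05 tests can fire
falsely. The co-expression step recovers all 5 planted modules, all 50
planted hubs, and pairs each module with the kernel trait its factor
drives (|r| > 0.99):

```
 module trait         r      p_value
     M5   FKW 0.9919436 3.080645e-21
     M1   DKW 0.9936474 2.274912e-22
     M2   TKL 0.9963302 5.505890e-25
     M4   TKW 0.9957245 2.947322e-24
```

Programmatic use mirrors the scripts:

```r
library(kernelreg)
cfg  <- simulation_config(seed = 1)
sim  <- simulate_regulatory_counts(cfg)
res  <- run_ase_pipeline(sim$counts)
head(res$gene_calls)
```

`run_all(default_run_config(seed = 1), "out/")` executes all three arms and
writes every stage table plus a `summary.json` stamped with the seed and a
config fingerprint; reruns at the same seed are byte-identical.

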