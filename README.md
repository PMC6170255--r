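# kinsel — selectivity scoring for kinase inhibitor screens

Small-molecule kinase inhibitors are notoriously promiscuous: because kinase
ATP pockets are structurally similar, almost every inhibitor also hits
"off-target" kinases. Large kinome profiling screens quantify this as a
compound × kinase matrix of percent-inhibition values, but turning such a
matrix into "which compound should I use against kinase X?" needs a
selectivity metric that respects both *how many* off-targets a compound hits
and *how hard* it hits them.

`kinsel` is an R package (library + command-line tool) for researchers in
cell biology, chemical biology, and pharmacology who work with single-dose
kinome screen exports. It reads wide-format CSV/TSV inhibition matrices,
standardizes kinase names, scores and ranks every compound for a chosen set
of up to ten target kinases, reports significant off-targets, and renders
the classic black–yellow–red inhibition heatmap.

## The score

For one compound with target-set inhibitions *I<sub>t</sub>* and measured
off-target inhibitions *I<sub>1</sub> … I<sub>M</sub>* (all in percent,
missing cells excluded, never imputed):

- **Inhibition score** *G* = the target's percent inhibition, or the
  geometric mean over the chosen targets (a zero annihilates it);
- **Broad penalty** *P<sub>b</sub>* = (1/M) Σ<sub>j</sub> *I<sub>j</sub>* —
  catches the compound that weakly inhibits nearly the whole panel;
- **Near penalty** *P<sub>n</sub>* = (1/M) Σ<sub>j</sub>
  *I<sub>j</sub>*² / (*I<sub>j</sub>* + *G*) — catches the compound with a
  few off-targets at a magnitude comparable to (or beyond) the target; the
  weight *I<sub>j</sub>*/(*I<sub>j</sub>* + *G*) is continuous and
  threshold-free;
- **Selectivity score** *S* = *G* − *P<sub>b</sub>* − *P<sub>n</sub>*, in
  percent units, at most 100 (reached only by a perfectly selective, fully
  inhibiting compound).

A *significant off-target* is any kinase inhibited at least half as much as
the target (boundary included). Comparison metrics — the Gini coefficient of
the inhibition profile and the hard-threshold S(x) score — are provided for
side-by-side columns.

## Worked example

```r
library(kinsel)

# a 51-kinase panel with the three canonical archetypes
m <- generate_matrix(synthetic_spec(), "TARGET1")
rank_compounds(m, "TARGET1")
#>       compound_id inhibition_score penalty_broad penalty_near selectivity_score
#> 1 clean_selective               90           2.0   0.04347826          87.95652
#> 2        pan_weak               90          10.0   1.00000000          79.00000
#> 3      few_strong               90          10.8   4.53913043          74.66087
#>   n_targets_measured n_offtargets_measured defined n_significant_offtargets
#> 1                  1                    50    TRUE                        0
#> 2                  1                    50    TRUE                        0
#> 3                  1                    50    TRUE                        5
```

All three archetypes inhibit the target equally (90%). The clean compound
(off-targets at 2%) wins. The pan-weak compound (everything at 10%) loses 10
points of broad penalty but only 1 point of near penalty. The few-strong
compound (five off-targets at the target's own 90%) pays both penalties and
ranks last — those five kinases are exactly its significant off-targets. A
hard-threshold metric like S(50) sees no difference at all between the clean
and pan-weak profiles.

From the shell (the same functions behind a thin script):

```sh
Rscript inst/cli/kinsel simulate --seed 1 --out screen.csv
Rscript inst/cli/kinsel score --matrix screen.csv --targets TARGET1 \
    --with-alt-metrics --out-dir results/
Rscript inst/cli/kinsel heatmap --matrix screen.csv --targets TARGET1 \
    --page-size 10 --format png --out-dir results/
```

`score` writes `ranked_table.csv` and `off_targets.csv`; `heatmap` writes
the image plus an exact CSV twin of the displayed submatrix. After
installation the script is at `system.file("cli", "kinsel", package = "kinsel")`.

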