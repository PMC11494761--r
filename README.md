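# cardiorelevance

Variant prioritization for inherited cardiopathies (cardiomyopathies,
channelopathies, genetic aortic diseases). The package is aimed at
bioinformaticians who need a deterministic, auditable answer to the
question *"which of this patient's variants plausibly matter for a
cardiopathy panel, and why?"* — and at methodologists who want to
evaluate such rule sets against clinical classifications.

## What it does

Given a VCF, transcript models and a disorder gene panel, the pipeline

1. **annotates** each variant–transcript pair with a Sequence Ontology
   consequence, its impact class (HIGH/MODERATE/LOW/MODIFIER), the
   amino-acid change, and loss-of-function (LOF) / nonsense-mediated
   decay (NMD) predictions — using either the built-in codon-local
   annotator or pre-computed SnpEff-style `ANN` INFO fields;
2. **filters** to variants on panel genes;
3. **classifies relevance**: a variant is relevant iff it satisfies any
   of

   | criterion | condition |
   |---|---|
   | `HIGH_IMPACT` | impact(consequence) = HIGH |
   | `DISRUPTIVE_PROTEIN_CHANGE` | disruptive inframe insertion/deletion |
   | `LOF_OR_NMD` | PTC in the first 95 % of the protein, splice-site or start loss (LOF); PTC ≥ 50 nt upstream of the last exon–exon junction (NMD) |
   | `CRITICAL_AA_CHANGE` | missense changing **both** the Kyte–Doolittle hydropathy class and the polarity class of the residue |

4. **contextualizes** relevant variants in a five-dimension knowledge
   graph (gene → protein → complexes → cellular components → cell →
   tissue → organ → system; and protein → processes → pathways with
   participation roles);
5. **aggregates and exports** counts by chromosome, gene, impact and
   effect, plus per-variant detail records, as TSV/JSON with a checksum
   manifest.

A concordance module scores relevant/irrelevant calls against
ClinVar-style labels: with positive class "relevant ∧
pathogenic-group", it reports sensitivity = tp/(tp+fn), specificity =
tn/(tn+fp), accuracy = (tp+tn)/n.

## Worked example

```r
library(cardiorelevance)

# a deterministic toy set: 4 genes (TTN, MYH7 on panel), 20 variants
ts  <- toy_discovery_set(11, vcf_path = "toy.vcf")
res <- run_discovery("toy.vcf", ts$genes, packaged_graph("cardiomyopathy"),
                     discovery_options(ts$panel), ref = ts$ref)
#> 12 variant(s) outside panel 'custom' removed
res
#> <discovery_result> 8 variant(s) retained, 3 relevant

res$relevant[, c("gene", "consequence", "impact", "criteria")]
#>   gene                 consequence   impact                  criteria
#> 1  TTN                 stop_gained     HIGH    HIGH_IMPACT,LOF_OR_NMD
#> 2  TTN        splice_donor_variant     HIGH    HIGH_IMPACT,LOF_OR_NMD
#> 6 MYH7 disruptive_inframe_deletion MODERATE DISRUPTIVE_PROTEIN_CHANGE
```

Twelve of the twenty variants fall outside the panel; of the eight
retained, exactly three satisfy a relevance rule — the TTN stop gained
is flagged HIGH impact *and* LOF+NMD (it truncates early and sits far
upstream of the last junction), and the MYH7 inframe deletion is
relevant only because it straddles a codon boundary.

Structural context for a relevant TTN variant, most specific first:

```r
structural_context(packaged_graph("cardiomyopathy"), "TTN")
#>                      id              kind                 label
#> 1            myofibrils CellularComponent            Myofibrils
#> 2            sarcoplasm CellularComponent            Sarcoplasm
#> 3         cardiomyocyte              Cell         Cardiomyocyte
#> 4             fascicles            Tissue             Fascicles
#> 5            myocardium            Tissue            Myocardium
#> 6                 heart             Organ                 Heart
#> 7 cardiovascular_system            System Cardiovascular system
```

Concordance arithmetic on a known confusion matrix:

```r
cm <- confusion_matrix(tp = 1057, fp = 36, tn = 2630, fn = 186)
unlist(metrics(cm))
#> sensitivity specificity    accuracy
#>       85.04       98.65       94.32
```

All metrics are percentages rounded to two decimals; they are computed
from the matrix, never restated.

## Command line

A thin CLI wraps the same functions:

```sh
inst/cli/cardiorelevance discover --vcf patient.vcf \
    --panel cardiomyopathy --gene-models models.json --ref ref.fa \
    --graph graph.json --out results/
inst/cli/cardiorelevance concordance --calls summary.tsv --labels clinvar.vcf --out metrics.json
inst/cli/cardiorelevance synth cohort --seed 7 --out synth/
inst/cli/cardiorelevance aa-matrix          # 20x20 criticality matrix as TSV
inst/cli/cardiorelevance graph validate --graph inst/extdata/kg/cardiomyopathy.json
```

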