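---
title: "Methods: variant relevance discovery for inherited cardiopathies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant relevance discovery for inherited cardiopathies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiorelevance)
```

## Overview

Inherited cardiopathies — cardiomyopathies, channelopathies and genetic
aortic diseases — have strong genetic components, and sequencing a patient
yields thousands of DNA variants of which only a handful plausibly matter.
`cardiorelevance` implements a deterministic prioritization pipeline for
this setting: variants from a VCF are annotated against transcript models
of disorder gene panels, classified as *relevant* or not by a fixed
four-criterion rule set, and the relevant ones are situated in a curated
knowledge graph that connects genes to proteins, heart anatomy and cardiac
pathways. A concordance module scores the relevant/irrelevant calls
against ClinVar-style clinical classifications.

This vignette records the model, its tunable parameters, the numerical
choices made where the design was genuinely open, and what the synthetic
test data does and does not demonstrate.

## The relevance rule set

A variant is **relevant** when its representative annotation satisfies at
least one of:

1. **HIGH impact** — the predicted consequence belongs to the HIGH
   severity class (stop gained, stop lost, start lost, frameshift,
   splice acceptor/donor), following the SnpEff-style four-level impact
   vocabulary (HIGH / MODERATE / LOW / MODIFIER).
2. **Disruptive protein change** — a disruptive inframe insertion or
   deletion, i.e. an inframe indel that does not respect codon
   boundaries and therefore rewrites residues beyond the pure
   insertion/deletion.
3. **LOF or NMD** — predicted loss-of-function or nonsense-mediated
   decay (below).
4. **Critical amino-acid change** — a missense substitution that changes
   *both* the hydropathy class and the polarity class of the residue.

The decision carries the satisfied criteria, so downstream consumers can
see *why* a variant was kept. Relevance is the plain disjunction: the
rule engine is monotone (adding a LOF flag can never revoke relevance),
and the test suite checks the full truth table.

Two open points were settled as follows. The source rule list states the
"disruptive change in the protein sequence" clause twice; it is
implemented once (duplication carries no extra semantics). And criteria
are evaluated on the representative annotation — canonical transcript
preferred, then highest severity, then smallest transcript id — mirroring
annotation restricted to canonical transcripts; a switch
(`any_transcript = TRUE`) widens evaluation to every transcript.

## The built-in annotator

The annotator is codon-local: for an SNV it projects the genomic position
onto the spliced CDS, mutates the single affected codon and compares the
two residues; indels are classified by frame (`indel length mod 3`) and
codon alignment. This keeps the call path independent of the brute-force
verification oracle (`retranslation_annotation()`), which instead rebuilds
the *entire* mutated CDS base-by-base and re-translates it. The two paths
are compared on every generated variant — consequence term, amino-acid
change, LOF and NMD flags — in both the unit tests and the acceptance
script.

Supported consequence terms and their impact classes follow the
conventional annotation vocabulary; a few decisions deserve a note:

* **Start-codon SNVs.** A change that turns ATG into one of the
  alternative initiation codons CTG/GTG/TTG is called
  `initiator_codon_variant` (MODERATE); any other start-codon
  disruption is `start_lost` (HIGH). The distinction matters because
  different annotation engines disagree on exactly these sites, and the
  two calls land on opposite sides of the relevance rule.
* **Splice geometry.** Splice acceptor/donor sites are the 2 intronic nt
  at each intron end; the splice region covers intronic distances 3–8 nt
  and the 3 exonic nt flanking internal junctions (checked for
  non-coding exonic bases; a coding consequence takes precedence on CDS
  bases). All constants sit in `ann_options()`.
* **Upstream/downstream window** is 5 kb; variants farther from every
  transcript are `intergenic_variant`.
* **Normalization.** Variants are trimmed (shared prefix/suffix) and
  pure indels are left-aligned against the reference before annotation.
  Multi-allelic records are split into one variant per alternate allele.
  The original VCF representation is retained for reporting and keying.
* **`N` handling.** Codons containing `N` translate to `X`; `X` never
  satisfies the critical-change criterion (the property table rejects
  non-standard residues, and the rule engine guards the lookup).

### LOF and NMD

Loss-of-function is predicted for splice acceptor/donor and start-loss
variants unconditionally, and for premature termination codons (stop
gained, frameshift) whose residue index falls within the first 95 % of
the protein — truncations of only the final 5 % are assumed tolerated.
Nonsense-mediated decay uses the classic 50-nt rule: a PTC triggers NMD
when the transcript has at least two exons and the PTC lies at least
50 nt upstream of the last exon–exon junction in spliced coordinates.
Both thresholds (`lof_fraction = 0.95`, `nmd_distance = 50`) are exposed
in `ann_options()`; the defaults mirror the published defaults of
mainstream annotation engines. For frameshifts the PTC position is
approximated by the first changed residue, a deliberate simplification
shared by the implementation and the oracle. By construction
`nmd == TRUE` implies `lof == TRUE`.

### The ANN-field adapter

Pipelines that already carry SnpEff-style annotations can skip the
built-in annotator: `parse_ann_field()` reads the pipe-separated ANN
entries (most severe term kept when several are ampersand-joined, HGVS.p
parsed into residues) and the companion `LOF=`/`NMD=` INFO keys. The
fixture writer `format_ann_field()` is its inverse on the retained
fields, which the tests exploit to show the two annotation sources give
identical relevance calls on the same variants.

## Amino-acid property tables

The critical-change criterion needs a hydropathy and a polarity
classification, and the choice of scheme was open. The packaged tables
(in `inst/extdata/aa_properties.tsv`, swappable) use:

* **Hydropathy** — the sign of the Kyte–Doolittle score: hydrophobic =
  {A, C, F, I, L, M, V}, hydrophilic otherwise. The table stores the
  numeric scores and the loader enforces the sign/class consistency.
* **Polarity** — the four textbook side-chain classes: nonpolar
  {A, V, L, I, P, F, M, W, G, C}, polar uncharged {S, T, Y, N, Q},
  positive {K, R, H}, negative {D, E}. Any class change counts.

The resulting 20×20 predicate is symmetric and reflexively false, and the
tests recompute the whole matrix from the raw class columns.

## The knowledge graph

Context is served from a typed property graph over five dimensions —
location (System/Organ/Tissue/Cell/CellularComponent), entity
(complexes, proteins, ions, molecules, families), structural
(chromosomes and genes), pathway (pathways and processes), and variation
(attached per run, never persisted). Edge kinds carry an endpoint
legality table; `kg_validate()` checks legality, acyclicity of the four
hierarchy relations, that every acting entity participates in a process
with an explicit role (input/output/regulator), and that every protein
has a coding gene.

Three curated fixtures ship with the package, one per disorder group,
containing only content stated in the domain narrative they were curated
from: the heart location hierarchy (heart, chambers, wall layers,
fascicles, cardiomyocytes, sarcolemma/sarcoplasm, sarcoplasmic reticulum,
myofibrils), the sarcomere proteins of the 13 cardiomyopathy panel genes
with their chromosome placements, the phase-0/phase-3 action-potential
pathway with the Na+/Ca2+/K+ channel proteins, and the elastic-lamella
entity complex (elastin, fibrillin-1 and its interactors) for the aortic
group. The fixtures are deliberately small (≤ 52 nodes) so that the
traversal tests can compare against exhaustive path enumeration. They
reproduce the documented example subgraphs, not the full production
database, so per-dimension counts are asserted against the package's own
manifest rather than any external total.

`structural_context()` walks gene → protein(s) → component-of closure →
located-in anchors → part-of ancestors, returning locations ordered
most-specific-first (BFS level order, ties by node id).
`functional_context()` returns (pathway, process, role) triples via the
takes-part-in edges and the decomposes-into ancestry. The graph store is
an in-process structure with JSON and GraphML serialization; a database
service is out of scope because the method, not the deployment, is the
subject here.

## The discovery pipeline

`run_discovery()` composes parse → annotate → panel-filter → assess →
contextualize → aggregate, with errors tagged by stage. Panel filtering
keeps variants with at least one annotation on a panel gene (filtering
after annotation — the result set is the same either way, and it lets
one annotation pass serve several panels). Aggregates count variants by
chromosome, gene, impact and effect, one vote per variant keyed on the
representative annotation, so each map sums to the retained-variant
count — an invariant the tests assert. Quality and genotype columns pass
through verbatim. The pipeline is pure given inputs and options;
re-exports are checksum-identical because the provenance timestamp is
kept out of every hashed payload.

## Concordance evaluation

Clinical labels are mapped from CLNSIG strings (composites like
`Benign/Likely_benign` fold into the likely tier of their group;
conflicting and uncertain records map to their own labels). Eligibility
keeps only benign-group and pathogenic-group variants whose condition
matches a phenotype filter (case-insensitive substring, default
{cardiomyopathy, long qt, marfan}). The confusion matrix orientation
takes "relevant ∧ pathogenic-group" as true positive — the only
orientation consistent with the published specificity figure
(2630/2666 = 98.65 %). Metrics are percentages rounded to two decimals;
zero denominators yield `NA`.

One documented discrepancy: from the published concordance marginals
(1,057 of 1,093 relevant calls concordant; 2,630 of 2,816 irrelevant
calls concordant) the computed sensitivity is 1057/1243 = **85.04 %**,
while the source narrative prints 85.5 %. The two cannot both follow
from the same matrix; this package reports only values it computes, so
85.04 % is what `metrics()` returns and what the acceptance script
writes. Accuracy (94.32 %), specificity (98.65 %) and the discordant
total (222) are reproduced exactly.

A full ClinVar re-evaluation needs an external download and is subject
to release drift, so it is not part of the test suite; the harness reads
any ClinVar-style VCF (CLNSIG/CLNDN) or a 3-column TSV if a user wants
to run it locally.

## Synthetic data: what it emulates and what it does not

The generators build, for a fixed seed, a single-contig locus of
non-overlapping multi-exon genes (alternating strands, CDS a multiple of
3 starting ATG and ending with a stop, introns of 60–120 nt, 12 kb
intergenic gaps so window-based calls are unambiguous), then draw
variants that *provably* realize a requested consequence mix — every
candidate is verified against the re-translation oracle before being
written, and unsatisfiable requests error after bounded retries. Default
sizes (2–4 genes, 2–5 exons, CDS 150–360 nt) keep exhaustive per-base
oracles affordable while covering splicing, strand and frame edge cases.

The labeled cohort emulates, at desk scale, an evaluation against
clinically classified variants: each of 500 variants gets a
pathogenic-group or benign-group label (balanced in expectation), and a
pathogenic-labeled variant draws its site from the HIGH/LOF consequence
pool with probability 0.8 (the enrichment), otherwise from the
synonymous/intronic pool; benign-labeled variants always draw benign
sites. The pool choice is fixed before site sampling, so the pipeline's
expected sensitivity equals the enrichment exactly and the acceptance
check can use a closed-form binomial band (observed sensitivity within
three standard errors of 80 %). Specificity is 100 % by construction —
the benign pool contains no relevant consequences.

What passing these tests shows: the annotation arithmetic, rule engine,
traversals and evaluation harness are internally consistent and agree
with independent brute-force recomputation. What it does not show:
performance on real genomes — the synthetic loci have no repetitive
sequence, no overlapping genes, no population allele-frequency structure,
no multi-nucleotide phased codon effects, and labels generated from
consequence classes are a far cleaner signal than curated clinical
assertions.

All generators run under a private Mersenne–Twister stream seeded once
per call, leaving the caller's RNG state untouched; seeds are recorded in
generated VCF headers.

## Known limitations

* The annotator covers the consequence inventory listed above; it does
  not model regulatory or protein-domain annotations, structural
  variants, or codon-merged MNVs beyond simple same-length
  substitutions.
* Left-alignment of indels inside repeats can move a variant across an
  exon–intron boundary, in which case the call follows the normalized
  representation.
* Canonical-transcript selection (explicit flag, then longest CDS, then
  smallest id) is a documented stand-in for engine-specific canonical
  sets, which vary by version.
* The knowledge-graph fixtures are illustrative subgraphs; structural
  and functional context on real panels would require instantiating the
  graph from current database releases.
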