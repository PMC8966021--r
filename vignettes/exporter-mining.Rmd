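---
title: "Mining exporters and designing tunable plug-and-play exporter cassettes"
author: "TuppeMiner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining exporters and designing TuPPE cassettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TuppeMiner)
```

# The problem

Industrial *Streptomyces* strains often accumulate their secondary
metabolite — here, macrolide biopesticides such as milbemycins — faster
than they can export it. Many biosynthetic gene clusters carry no
exporter at all, yet the genome encodes hundreds of transporters of
unknown function. Two practical questions follow:

1. **Which of the genome's many transporters actually move the product?**
   Exporters that matter tend to be transcribed in step with production:
   their time-course expression tracks the titer curve.
2. **How strongly, and when, should a chosen exporter be expressed?**
   Constitutive overexpression of membrane proteins burdens growing
   cells; what is wanted is a *temporal* promoter — quiet during
   logarithmic growth, strong during the production stage — combined
   with an adjustable ribosome binding site (RBS).

TuppeMiner implements this workflow as four testable analysis stages,
plus a synthetic-data generator that plants known signal so every stage
can be validated without any external download.

# Stage 1: the expression–titer screen

For each gene the screen computes, over the production-stage window
(default days 3–8 of a 0.75/2/3/4/6/8-day sampling grid):

* $r^2$, the squared Pearson correlation between the gene's FPKM series
  and the titer series;
* the least-squares slope of FPKM against titer **after min–max scaling
  both series to $[0,1]$**;
* the FPKM at the final timepoint and its $\log_{10}$.

Candidates must exceed all three thresholds strictly — conventionally
$r^2 > 0.995$, slope $> 0.05$, $\log_{10}\mathrm{FPKM} > 1$ — and, when
an annotation is available, carry a defined product string (a small
editable lexicon rejects "hypothetical protein" and friends).

Two quantities here required a design decision:

* **The slope.** A slope threshold of 0.05 is only meaningful if the
  slope is scale-free: a raw FPKM-per-(mg/l) slope would depend on the
  magnitude of each gene's expression. We therefore min–max-scale both
  axes before regression, which makes the threshold comparable across
  genes; the raw-slope mode remains available
  (`slopeMode = "raw"`).
* **Zero variance.** A constant gene has an undefined correlation; we
  define $r^2 = 0$, slope $= 0$ so that filters behave deterministically
  rather than propagating `NaN`.

A mutant-versus-parent comparison (`lateStageUpregulation()`) reports
$\log_2((\mathrm{FPKM}_\mathrm{mut}+1)/(\mathrm{FPKM}_\mathrm{par}+1))$
per late-stage day (pseudocount 1 guards zeros) and flags genes whose
*minimum* late-stage fold change clears the threshold — consistent
upregulation, not a single spike.

# Stage 2: transporter triage

Putative efflux proteins are classified by an ordered, first-match-wins
rule list, with every fired rule recorded in an `evidence` field so each
call is auditable:

1. a substrate-class keyword lexicon applied to the annotation product
   string (drug-multi, drug-specific, dye, sterol, toxin); the lexicon
   ships as an editable text resource because annotation vocabularies
   differ between genomes;
2. family assignment with structural corroboration: **ABC** requires a
   Walker A motif (`[AG]-x(4)-G-K-[ST]`) in the protein or an adjacent
   gene; **MFS** requires 10–14 predicted transmembrane helices; RND,
   DMT, AbgT, NbcE, I-PPI and SanA are keyword-only.

Transmembrane helices are predicted with a Kyte–Doolittle sliding-window
scan (window 19, mean hydropathy cutoff 1.6 — the classic
membrane-protein setting), calling maximal runs of windows above the
cutoff and merging overlaps. This is a deliberate, deterministic,
network-free approximation of HMM-based topology predictors: it is
accurate on the cleanly hydrophobic stretches the generator plants and
adequate for coarse triage, but it is *not* a topology model (no
inside/outside orientation, no signal-peptide discrimination).

Bacterial ABC exporters are typically dimers of half-transporters, one
transmembrane domain (TMD) fused to one nucleotide-binding domain (NBD),
and genomes frequently split the two across neighbouring genes.
`assembleAbcSystems()` therefore groups contiguous ABC-family genes
(gene-order gap ≤ 2 by default — the workflow reasons in locus-tag
neighbourhoods, not base pairs) into systems and, when a system lacks a
TMD or NBD member, searches the non-ABC genes within the same window for
a protein with ≥ 4 predicted helices (respectively a Walker A motif),
recruiting the nearest hit and labelling the system
`tmd_completed_from_neighborhood` / `nbd_completed_from_neighborhood`;
otherwise the system is `incomplete`. The triage report's summary
statistic, `familyFraction()`, gives the fraction of drug-efflux
proteins covered by the named families.

# Stage 3: phylogenetic diversification

Candidates from one clade tend to share substrate preferences; picking
one representative per branch diversifies what goes into the strain.
The stage expects a *pre-aligned* protein FASTA (multiple-sequence
alignment construction is out of scope; any standard aligner's output
works) and computes:

* **Poisson-corrected distances.** After removing every column with a
  gap or missing residue in any sequence (complete deletion), the
  proportion of differing sites $p$ per pair is corrected for multiple
  hits: $d = -\ln(1-p)$. Pairs with $p \ge 1$ (saturation) are an error,
  not an imputation.
* **Neighbor joining** per Saitou & Nei: join the pair minimising
  $Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$, standard
  limb-length formulas. Negative limb lengths are clamped to zero (the
  display convention of common tree software) with the total deficit
  recorded on the tree. Ties in $Q$ are broken by the lexicographically
  smallest label pair, which makes the output independent of taxon input
  order. On an additive matrix the tree reproduces the input distances
  exactly; the test suite verifies this to $10^{-9}$ and cross-checks
  topologies against an independent NJ implementation and, for 4-taxon
  cases, against brute-force least-squares over all three unrooted
  topologies.
* **Bootstrap supports**: alignment columns resampled with replacement
  (1000 replicates is the publication convention; the pipeline default
  is smaller for speed), NJ rebuilt per replicate, support = percentage
  of retained replicates containing each original internal split.
  Replicates that saturate are dropped and counted; losing more than 10%
  is an error.
* **Representative picking.** "Different branches" is formalised as:
  remove internal edges in order of decreasing length (ties by smallest
  split) until the requested number of leaf groups exists — continuing
  with pendant edges if the internal edges run out, so requesting one
  group per leaf is well defined — then take each group's anchor taxon
  if one was supplied, else its medoid under tree path distance. The
  original analysis picked branches by eye; this rule is a deterministic,
  documented stand-in.

# Stage 4: TuPPE cassette design

Temporal promoters are mined from the same time-course transcriptome:

1. every gene's profile is reduced to $|\log_2$ fold change$|$ relative
   to the first timepoint (pseudocount 1);
2. the production curve's own fold-change profile is clustered *with*
   the genes — correlation distance ($1-r$ between magnitude profiles),
   average linkage, dendrogram cut at height 0.25 by default (i.e.
   within-cluster shape correlation ≈ 0.75; shape, not magnitude, is
   what matters, hence correlation distance rather than Euclidean);
3. candidates must share the production profile's cluster **and** pass a
   temporal gate: mean FPKM over logarithmic-phase days (≤ day 2) at or
   below the all-gene median, and a late/early FPKM ratio of at least 4.
   The gate encodes "low strength while growing, strongly up during
   production"; the clustering criterion alone would also admit strong
   constitutive-then-stronger genes.

From the candidates, `selectStrengthGradient()` picks promoters spanning
the strength range: strength is the donor gene's final-day FPKM (the
full profile is available, but a single documented convention keeps the
gradient reproducible), and the picks are the candidates nearest the $n$
evenly spaced quantiles of the strength distribution, min and max
included. With $n=1$ the rule yields the median — a deliberate
consequence of the quantile formalisation, documented rather than
special-cased.

Promoter sequences are the 500 bp immediately upstream of the donor
gene's start (GFF3 1-based inclusive coordinates; reverse-strand genes
take the reverse complement downstream of the gene end; truncation at a
contig edge warns). The window abuts the start codon, so the donor's
own RBS rides along; the native-RBS cassette variant therefore simply
uses an empty RBS part.

A cassette is `GAATTC` (EcoRI) + promoter + RBS + `ACTAGT` (SpeI) +
exporter CDS + `TCTAGA` (XbaI). Parts containing any of the three
recognition sites are rejected with the offending offset (the sites must
stay unique for part swapping), the assembled cassette is re-scanned so
junction-spanning sites are caught too, and multi-gene ABC exporters are
cloned as one genomic block with native intergenic spacing preserved.
`enumerateLibrary()` builds the full promoter × RBS × exporter product —
5 promoters × 5 RBS variants is the canonical 25-cassette library — and
reports failed combinations instead of dropping them.

# The synthetic-data generator

The generator emulates the structure of a fermentation time-course
study: an FPKM matrix over days 0.75, 2, 3, 4, 6 and 8, a logistic
production curve plateauing near day 8, and a single-contig genome with
planted transporter architecture. Its defaults are the study conditions
used throughout the tests: 1000 genes with 10 planted titer-correlated
profiles for the screen; 5 complete, 3 neighbourhood-completable and 3
incomplete ABC systems, 10 MFS proteins and 50 decoys for the triage.

Design choices worth knowing:

* **Noise** is multiplicative log-normal per FPKM cell (expression noise
  is scale-dependent), log-sd `noiseSd`, default 0.1.
* **Backgrounds are smooth temporal programs**, not white noise: each
  unplanted gene follows one of five archetypes (flat 30%, growth-phase
  decline 30%, early transient peak 15%, late exponential rise 15%, late
  decline 10%) with random parameters. The decline-heavy mix reflects
  stationary-phase biology, where growth-associated transcription shuts
  down and a smaller set is induced. This matters statistically: with
  only four production-stage timepoints, the sample correlation of an
  i.i.d.-noise profile against anything is nearly uniform on $[-1,1]$,
  so white-noise backgrounds would routinely produce perfect-looking
  correlations; smooth archetypes have bounded, noise-free correlation
  with a saturating titer curve (the worst case, a linear drift, reaches
  $r^2 \approx 0.82$).
* **Planted membrane stretches** are 21 residues over {I,L,V,F,M,A},
  comfortably inside Kyte–Doolittle detection range; non-membrane
  segments use a hydrophilic alphabet that excludes G and K, so neither
  a spurious transmembrane window nor an accidental Walker A motif can
  arise. Planted NBDs embed a canonical `GPSGSGKST` P-loop.
* **Genome layout**: genes are non-overlapping with ≥ 600 bp intergenic
  gaps (so 500-bp promoter extraction is exercised in full), the first
  gene starts at base 201 (so truncation is exercised too), and the
  contig is scrubbed of EcoRI/SpeI/XbaI sites so extracted parts are
  cassette-ready. Planted blocks are insulated by two decoy genes so
  neighbourhood completion finds exactly its intended partner.
* **Seeding**: one master seed; each stage derives its own stream
  deterministically, so a genome can be regenerated without replaying
  the expression simulation. All outputs are byte-identical for a fixed
  configuration.

What the generator does **not** emulate: read-level sequencing (FPKM
values are drawn directly, with no length or depth model), codon-level
DNA evolution (protein genes are placed on random scrubbed DNA),
regulatory correlation between neighbouring genes, or any particular
quantification pipeline's normalisation. Passing tests therefore
demonstrate the correctness of the algorithms under the stated noise
model, not screen performance on any specific real dataset.

# Sensitivity limits of the screen

One property of the screen deserves emphasis. With i.i.d. multiplicative
log-normal noise of log-sd $s$ on a nonnegative profile, the population
$r^2$ between the noisy profile and the titer is bounded by

$$ r^2 \;\le\; \frac{\mathrm{var}(x)}{\mathrm{var}(x) + s^2\,E[x^2]}
   \;<\; \frac{1}{1+s^2}, $$

which is 0.990 for $s = 0.1$ — *below* the conventional 0.995 screen
threshold. At 10% expression noise, a strict $r^2 > 0.995$ filter
therefore cannot retain most truly correlated genes (measured
sensitivity is around 10% under the default conditions), while it keeps
false positives rare (well under one per 1000 genes screened). The
screen is a high-precision, low-recall instrument by construction; at
zero noise it recovers the planted set exactly, and the acceptance
script reports the measured sensitivity at both noise levels rather than
hiding the trade-off.

# Numerical conventions, in one place

* Strict inequalities at all screen thresholds.
* Zero-variance series: $r^2 = 0$, slope 0; zero-variance fold-change
  profiles cluster as "unrelated" (correlation 0).
* Pseudocount 1 in every fold-change and ratio (FPKM can be 0).
* NJ ties broken lexicographically; negative limb lengths clamped at 0
  with the deficit recorded; 2-taxon trees are a path of total length
  $d_{12}$.
* Bootstrap replicates that saturate are dropped and counted, never
  imputed; > 10% loss is an error.
* Promoter/exporter coordinates follow GFF3 1-based inclusive
  conventions throughout.

# Problem sizes used by the test suite

The suite validates the screen on 1000-gene matrices over 20 seeds, NJ
on 50 random additive matrices of 4–8 taxa, topology recovery from
simulated 2000-site alignments over 20 seeds, bootstrap behaviour at
200 replicates on 6-taxon alignments, and the full pipeline on the
default ~80-gene synthetic genome — sizes chosen so the whole suite
runs in well under a minute while every code path is exercised.

# Known limitations

* The hydropathy scan under-calls marginally hydrophobic or
  re-entrant helices compared to HMM predictors; on real proteomes the
  ABC/MFS corroboration rules inherit this.
* Family calls depend on annotation vocabulary; the shipped lexicons are
  starting points, not references, and real-genome counts will differ
  with the annotation source.
* The clustering cut height (0.25) and temporal-gate defaults were
  chosen once as reasonable shape-matching settings; the cluster-count
  of "satisfactory" promoters in any real genome is sensitive to them.
* Bootstrap support is attached to the input NJ topology only; no
  consensus tree is built.
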