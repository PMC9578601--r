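---
title: "Methods: locus-resolved HML-2 expression from multimapping reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus-resolved HML-2 expression from multimapping reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(provex)
```

# The problem

The human genome carries ~90 "2-LTR" HERV-K (HML-2) proviruses plus
hundreds of solo LTRs. The youngest of them are nearly identical in
sequence, so short RNA-seq reads from one provirus align almost as
well to several others: any locus-resolved expression analysis stands
or falls with how those multimapping reads are reassigned. Downstream
of quantification, the questions are the ones a provirus catalogue
raises naturally: which loci are transcribed in which tissues and at
what level; whether expression tracks provirus age (the earliest
shared ancestor, ESA, of the orthologous insertion); whether donor
covariates (sex, age, death rapidity / Hardy score) move it; which
viral ORFs are still intact; how the LTR sequence subtypes (LTR5A,
LTR5B, LTR5HS) relate in phylogeny and in transcription-factor binding
repertoire; and whether each expressed provirus is driven by its own
5' LTR promoter or transcribed by read-through from an outside
element.

`provex` implements this entire chain at desk scale. Cohort-scale
human tissue RNA-seq is access-controlled, so the package pairs every
analysis stage with a synthetic-data generator that reproduces the
*structural* features that make the problem hard — families of
near-identical proviral loci, LTR subtypes, type 1/2 proviruses, solo
LTRs, controlled ORF lesions, tissue- and covariate-structured
expression, LTR-driven versus read-through transcript units — with
exact ground truth for every read and every planted mutation.

# The provirus template

All loci derive from one deterministic ~9.5 kb 2-LTR template
(`hml2_template()`). Coordinates are 1-based inclusive throughout:
968-nt LTRs at 1–968 and 8505–9472, and the viral genes at their
reference positions — *gag* 1112–3112, *pro* 2938–3918, *pol*
3915–6749, *env* 6451–8550, with the spliced accessory genes *rec*
(6451–6711 + 8411–8467) and *np9* (6451–6494 + 8411–8591). Note the
gene and LTR coordinate systems overlap at the 3' end (env and np9 run
into the 3' LTR interval); the template keeps both as printed, which
is possible because the 3' LTR is a byte copy of the 5' LTR and the
sequence sampler avoids TA/TG dinucleotides in coding spans, so no
reading frame anywhere in the gene region contains a stop codon. That
gives a clean invariant: the lesion-free template classifies all six
genes intact, and ORF truth in any simulated provirus is controlled
entirely by the planted lesion list.

The type 1 provirus class carries the diagnostic 292-nt deletion at
the pol–env border. Its default placement (template nt 6690–6981) was
chosen so that the deletion (a) frameshifts *env* (292 is not a
multiple of 3), (b) truncates *rec* part 1 by 22 nt (frameshift),
(c) leaves both *np9* parts untouched, and (d) removes only an
in-frame 60-nt tail (2.1%) of *pol* — reproducing the biological
definition of type 1 (no *env*/*rec*, *np9* instead) without forcing
*pol* broken.

# What the generator emulates

`build_genome()` plants each provirus as template + three layers of
variation:

* **Subtype edits.** The template LTR is the LTR5HS baseline; LTR5A
  and LTR5B substitute 30 diagnostic positions and carry their own
  motif words (below). Edits are applied identically to both LTRs.
* **Divergence.** Each provirus receives random substitutions at rate
  `divergence / 2` (default 1%), so two same-template proviruses
  differ by ~2% — the regime in which 75-nt reads multimap.
  Substitutions inside gene spans are resampled if they would create a
  TA/TG dinucleotide, keeping ORF truth lesion-controlled.
  Substitutions falling in the 5' LTR are mirrored into the 3' LTR,
  then each LTR receives small independent private substitutions
  (default 0.2%). This mirrors the empirical structure of real
  provirus LTR pairs: the two LTRs of one insertion are far closer to
  each other than to any other LTR, so they sit as sister taxa on the
  NJ tree — a property the test suite asserts on every seeded genome.
* **Lesions.** Explicit, exactly-placed mutations
  (substitution/insertion/deletion/duplication) in template
  coordinates; `make_type1()` adds the 292-nt deletion.

Transcript units follow the annotation: an LTR-driven unit runs from
the U3–R border of the driving LTR (its own 5' LTR, or an annotated
upstream solo LTR) to the R–U5 border of the 3' LTR; a read-through
unit starts a configurable window (default 1.5 kb) upstream of the
provirus and runs through it; host genes are their own units. Within
the 968-nt LTR the U3/R/U5 partition is fixed at 1–780 / 781–870 /
871–968. Read counts per unit are multinomial with weights abundance ×
unit length; read starts are uniform within the unit, except that
LTR-driven units place a fraction of starts (default 15%) within 50 nt
of the U3–R border — the generator's model of the transcription-start
pile-up visible in read alignments, which is the observable signature
the mechanism classifier keys on.

Candidate alignments are produced by exact scan of the planted
homologous copies (including the 5'↔3' LTR cross-homology and solo
LTRs): every genomic location matching the read within the mismatch
budget (default 3 of 75 nt) becomes a SAM record with alignment score
`AS = -6 × mismatches`; the true source is always the single primary
record, and a hidden truth table accompanies every SAM. Defaults the
study design does not pin down are held fixed at field-typical values:
75-nt single-end reads and a 0.1% per-base substitution error rate.

What the generator deliberately does **not** emulate: spliced host
isoforms, paired-end fragments, base-quality strings, stranded
protocols (the classifier assumes unstranded data and takes direction
from the annotation), insertional polymorphism between donors, and the
real nucleotide composition of HML-2 (the template is synthetic).
Passing tests therefore demonstrate that the algorithms are correct on
data with the stated structure — not that a particular biological
conclusion holds in any real cohort.

# Read reassignment model

Each read *i* has candidate loci *j* with weights
$q_{ij} = \exp(AS_{ij}/T)$, normalised within the read, and the locus
proportions $\pi_j$ are mixture weights. EM alternates

$$r_{ij} = \frac{\pi_j q_{ij}}{\sum_k \pi_k q_{ik}}, \qquad
  \pi_j \leftarrow \frac{\sum_i r_{ij} + \alpha}{n + K\alpha},$$

with $\alpha$ a Dirichlet-style `prior_weight` (default 0 = maximum
likelihood), until $\max_j |\Delta\pi_j| <$ `tol` ($10^{-6}$) or 1000
iterations. Fractional counts are $\sum_i r_{ij}$; they are conserved
exactly ($\sum_j = n$), and the observed-data log-likelihood is
non-decreasing (both asserted in tests). On instances small enough to
enumerate, the converged $\pi$ matches a dense grid search over the
simplex at $10^{-3}$ resolution.

The softmax temperature sets how strongly a mismatch discounts a
candidate. The default is $T = 1$, i.e. weights $e^{AS}$: with the
simulator's score scale one mismatch multiplies the weight by
$e^{-6} \approx 0.25\%$, close to the generative substitution model at
sub-percent error rates. This is the scale at which abundance recovery
on the 5-locus benchmark is accurate; flatter settings (e.g. $T = 6$)
leak mass toward the degenerate attractor and underestimate rare loci.
Ties in any argmax reporting break by lexicographic locus id, so runs
are deterministic.

TPM is computed per sample as $10^6 \cdot (c_j/\ell_j) / \sum_k
(c_k/\ell_k)$. Whether the denominator runs over all annotated
features or only proviral loci is a study-level choice the upstream
tooling leaves open; both are provided (`tpm_universe = "all"`,
default, or `"hml2"`).

**Expression calling** uses the tissue-mean TPM with a closed
threshold (mean ≥ 1 TPM). The source analyses apply the ≥ 1 TPM rule
both per sample and per tissue without distinguishing; the tissue-mean
reading reproduces the per-tissue expressed sets and is the single
rule used everywhere here (prominently: a tissue mean of exactly 1.0
is expressed; 0.99 is not).

# Profiling choices

* **Patterns.** "Expressed in almost all tissues" is quantified as
  ≥ 90% of tissues (`ubiquitous_frac`, configurable — no exact
  fraction is published); a locus whose expressing tissues all share
  one tissue type is `type_restricted`; anything else with expression
  is `mixed`; no expression is `silent`.
* **ESA breakdown.** Group expression per tissue is the mean over
  samples of the summed member TPM; the published group-size
  normalisation divides by the member count before converting to a
  percentage share (shares sum to 100 within a tissue; an all-zero
  tissue reports NA). Pairwise group differences use Tukey's HSD on
  per-provirus within-tissue mean TPM.
* **Covariates.** The source pipeline fit limma/voom models; here the
  comparisons are transparent classical tests on `log2(TPM + 1)`:
  Welch's t for two groups, one-way ANOVA followed by Tukey's HSD for
  more, Benjamini–Hochberg adjustment within each tissue × covariate
  family (the original's correction is unstated; BH within family is
  this package's choice). This substitution is deliberate: the tests
  are dependency-light and their error calibration is verified by
  simulation (type-I error within [0.03, 0.07] at α = 0.05; power
  above 95% for a 2-sd shift at n = 50/50). α defaults to 0.05 — the
  published figure legend's "p < 0.5" is read as a typo for 0.05. Age
  bins follow the published grouping 20–35 / 35–51 / 52–70, with the
  boundary assignment age ≤ 35 → youngest bin (the text's "36 to 51"
  reading).

# ORF annotation

Each provirus is aligned globally to the reference (banded
Needleman–Wunsch with affine gaps, match +2 / mismatch −3 / gap open 5
/ gap extend 2; the band is the length difference plus 400 columns,
and scores are cross-checked against `Biostrings::pairwiseAlignment`
in the test suite). Tie-breaking is deterministic, with indels placed
as left-anchored runs. Reference gene intervals are projected through
the alignment; spliced genes concatenate their parts 5'→3'; an
interval wholly deleted in the provirus is reported `absent` rather
than an error.

A projected segment is **intact** when, in the reading frame anchored
at the reference interval start, it has no premature stop codon, no
frameshifting indel (length mod 3 ≠ 0), no missing spliced part, and
no in-frame indel longer than 5% of the segment (`in_frame_tol`; the
treatment of small in-frame indels is not published, so they are
reported as lesions but tolerated below that fraction). The −1
frameshift between gag/pro/pol is handled purely at the coordinate
level — the printed intervals already encode the overlaps. Two rules
act above the single-gene level: *pro* is only intact with an intact
*gag* upstream, *pol* with intact *gag* and *pro* (GagProPol
polyprotein context), and type 1 proviruses report *env*/*rec* as not
expressible and evaluate *np9* instead. Pfam-domain retention is *not*
re-implemented; the default intactness criterion is purely
lesion-based, and an external domain-scan report can tighten it
downstream.

# LTR phylogeny and motif clustering

5' and 3' LTRs are the projections of reference 1–968 and 8505–9472; a
provirus lacking its 5' LTR contributes a single 3' record flagged
`*`, and solo LTRs enter directly. For distance work each LTR is
aligned to the 968-nt reference LTR and projected onto the reference
columns (a reference-anchored alignment matrix; insertions relative to
the reference are dropped). p-distance is the proportion of differing
sites with pairwise gap deletion; the neighbor-joining tree (Saitou &
Nei, via `ape::nj`) gets 500 bootstrap replicates by resampling
alignment columns, with clade support reported as the plain resample
proportion. Negative NJ branch lengths are clamped to zero and
counted.

Motif scanning is FIMO-style with an exact null: log-odds scores
(pseudocount 0.01 of the background) are discretised to a $10^{-3}$-bit
grid and the score distribution under a 0-order background is computed
exactly by dynamic programming, so every reported p-value equals the
brute-force enumeration over all words (verified to $10^{-6}$ for the
bundled motifs). Matches use p ≤ $10^{-4}$ on both strands; the
background defaults to the letter frequencies of the scanned LTR set
(the original tool's background setting is unstated — both the
strands and background choices are documented defaults, not published
facts). The binary LTR × motif presence matrix (one match anywhere in
the LTR counts) is clustered with Ward linkage (`ward.D2`) on
Euclidean distances, 1000 column bootstraps, support again as plain
resample proportion — the multiscale "approximately unbiased"
correction of pvclust is deliberately out of scope. Rows are sorted
lexicographically before clustering, so results are order-invariant.
A clade's *defining motifs* are those present in all of its members
and absent from every member of its sibling.

The bundled toy motif set (11 PWMs, MEME minimal format under
`inst/extdata/motifs/`) matches the words the generator plants: three
10-mers per subtype in shared U3 position slots plus two 8-mers common
to all subtypes. The 10-mer length is deliberate: at p ≤ $10^{-4}$ a
match tolerates one substitution, so ~1% divergence rarely erases a
planted site, and simulated LTRs cluster by subtype in both the
sequence tree and the motif matrix.

# Mechanism classification

The manual, viewer-based classification of the source study is
operationalised with two ratios over primary-alignment profiles
(locus ± 2 kb):

* **start enrichment** — read starts within ±50 nt of a candidate TSS
  (the U3–R border of the provirus's own 5' LTR, or of an annotated
  solo LTR up to 2 kb upstream) over the expectation under uniform
  starts across the covered span;
* **upstream continuity** — mean depth in the 500 nt upstream flank
  over mean internal depth.

A locus is `ltr_driven` when enrichment ≥ 5 at a candidate TSS with
continuity ≤ 0.2 upstream of the driving element (attribution goes to
that element, so a provirus driven by an upstream solo LTR is
LTR-driven with the solo as driver); `read_through` when continuity ≥
0.8; `indeterminate` between; `silent` below the expression threshold.
Every threshold is a configuration knob; the defaults were chosen for
separability on the generator (LTR-driven units score enrichment ≈ 13
and continuity ≈ 0 at default settings; read-through units enrichment
≈ 1 and continuity ≈ 1), not taken from any published rule — none is
published. The neighbour-gene analysis replaces network construction
with the direct quantity of interest: Pearson correlation of
`log2(TPM+1)` between each provirus and every host gene within 10 kb,
BH-adjusted, with intronic containment flagged by interval
arithmetic.

# Numerical and reproducibility choices

EM: tol $10^{-6}$ on $\max|\Delta\pi|$, 1000 iterations, uniform
initialisation. Alignment: band = length difference + 400 (an error is
raised if the optimum would leave the band). PWM DP: $10^{-3}$-bit
bins; p-values are exact for the discretised score, and scanning uses
the same discretisation, so threshold decisions are self-consistent.
NJ: negative branch lengths clamped to 0. Degenerate inputs follow a
"warn and carry NA" policy where a result is representable (all-zero
TPM column, empty ESA group, zero-variance covariate group, constant
correlation vector) and reject with a named offender where it is not
(overlapping loci, lesion outside the template, SAM without header or
AS tag, NA distances, constant motif matrix). Every stochastic
operation takes an explicit seed; a fixed seed gives bit-identical
FASTA/SAM/TSV outputs and identical bootstrap supports, which the test
suite asserts.

The test and demonstration problem sizes are the package's own
defaults chosen to exercise the regime of interest at interactive
speed: 5 near-identical loci × 50,000 reads × 10 seeds for quantifier
recovery; ≤ 3 loci × ≤ 20 reads against a $10^{-3}$ simplex grid for
the EM oracle; 100 random additive matrices (6–12 taxa) and 20 seeded
genomes for the phylogeny; 100 randomized lesion fixtures for the ORF
classifier; 1000 null and 200 shifted replicates for covariate
calibration; 20 fixtures at 10,000 reads per unit for the mechanism
classifier. The bundled demonstration cohort is 6 donors × 3 tissues ×
20,000 reads.

# Known limitations

* The EM operates on per-read candidate sets with a single background
  category; it does not model fragment-length or positional bias, and
  reads crossing an insertion or a unit junction fall back to their
  source candidate only.
* ORF intactness without the Pfam-retention criterion is a weaker
  notion than the original's; a provirus called intact here could
  still have lost a required domain through substitutions.
* The reference-anchored LTR alignment discards insertions relative to
  the reference; a subtype defined by an insertion would be invisible
  to the distance (none of the modelled subtypes is).
* Mechanism thresholds are calibrated on the generator's idealised
  coverage; real libraries with 3' bias, splicing into the provirus,
  or low depth would need the knobs revisited, and `indeterminate` is
  the expected honest output there.
* The compositional closure of TPM induces negative correlations
  between unrelated highly expressed features; the neighbour-gene
  correlation is therefore most interpretable for positive, shared-
  driver signals.
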