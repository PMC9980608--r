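---
title: "Methods: multiomic integration analysis of the gut virome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiomic integration analysis of the gut virome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design decisions behind
`mviomics`. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The analysis model

The unit of analysis is the **viral contig (VC)**: a dereplicated viral
genome or genome fragment observed across up to three sequencing datasets of
the same samples — whole metagenome (MG), VLP-enriched metavirome (MV) and
metatranscriptome (MT) — at up to three gut sites per participant (proximal
colon, distal colon, stool; MT only for the colonic sites).

**Containment dereplication.** Contigs are clustered greedily: sorted by
length descending (ties by id), each contig joins the first existing
cluster, in founding order, whose representative contains it at ≥ 95%
identity across ≥ 90% of its own length, else founds a cluster. The
published procedure names a tool but not its algorithm; alignment-based
containment is the defensible reading of "95% identity across 90% of the
length of the smaller contig", and the greedy order makes the result
deterministic. Verification uses an exact-substring fast path and otherwise
local alignment (match 1, mismatch −2, gap open 4, extend 1; identity =
matches / aligned columns, coverage = aligned query span / query length). A
sampled 21-mer containment prescreen (at most 200 k-mers per contig,
candidate threshold 10% of sampled k-mers found in the target) skips pairs
that cannot reach 95%·90%: at 95% identity the expected per-21-mer survival
is 0.95^21 ≈ 0.34, comfortably above the 0.10 threshold, while unrelated
sequences share essentially no 21-mers.

**Source and integration classes.** A VC's *source* is "both" iff its
cluster contains members assembled from both MG and MV. A VC is
*integration-capable* (IC) on either of two kinds of evidence: a
metagenome-derived member flagged as pruned from a longer contig with host
flanks (the pruning itself is upstream; the flag and the donor contig id are
inputs), or a metavirome-derived member contained within a non-viral contig
at the clustering thresholds. Everything else is *non-integrated* (NI) —
deliberately not "virulent": NI only means integration was not observed.
A VC may link to several host contigs and one host may carry several VCs.
Prophage spans in host contigs are masked to N, overlapping spans merged
first; the metadata keeps an `effective_length` (unmasked positions).

**Abundance.** `x_i = reads_i / length_i` (reads per bp) and
`NRA_i = x_i / Σ_j x_j`. Two conventions matter and are fixed here:

* *Filter first.* MG and MV cells with breadth of coverage < 75% are zeroed
  **before** normalization (MT is exempt). Filtering and normalizing do not
  commute; a regression test asserts the orders differ on a crafted fixture.
* *Normalization universe.* The denominator runs over **all** contigs mapped
  in that dataset, viral and non-viral alike — which is why viral contigs
  can be a large share of the metavirome but a small share of the metagenome
  and metatranscriptome. Masked hosts contribute their unmasked
  (`effective_length`) positions, since reads cannot map onto N-runs.

**Transcription.** A complete/high-quality VC is *transcriptionally active*
(TA) in an MT sample when its NRA is at least `ta_threshold = 1e-6`
(0.0001%). The published description uses both "greater than" and "minimum
of"; the package fixes `>=` and exposes `strict = TRUE` for the other
reading — boundary ties are measure-zero in continuous data but the contract
must be explicit. Genes on TA VCs with more than one MT count (per sample;
whether the published rule pooled sites is unstated, so the per-sample
reading is used and recorded in the output) are *transcribed*; genes on
non-TA VCs are *not evaluated*, a third state distinct from *not
transcribed*. Transcription ratios (MT NRA / MG NRA) are computed per
(participant, site) and never pooled across participants, because NRA
denominators differ per sample; zero-MG cells yield undefined ratios that
are counted but excluded from means.

**Lysogeny statistics.** Integrase detection is a case-insensitive substring
match of "integrase" in the annotation term name (the published census
aggregated four distinct terms across two databases; a fixed term list can
be supplied instead). For each gene family present in ≥ 10% of
complete/high-quality Caudovirales VCs: sensitivity = IC VCs carrying it /
all IC VCs, specificity = 1 − the NI analogue, and the integration
likelihood ratio LR = sensitivity / (1 − specificity). The LR uses raw
presence counts; the per-kb ORF frequencies are reported alongside but do
not enter the LR — the published formula is stated on sensitivity and
specificity while length normalization is described for the frequency
display. Both views are emitted so either reading is reproducible. Families
absent from every NI VC get LR = ∞, ranked first and resolved among
themselves by sensitivity.

**Ecology.** Rarefaction is a single seeded draw without replacement
(replicate rarefaction is not part of the published procedure); rarefied
column sums equal the depth exactly. Chao1 is the classic
`S0 + a1²/(2·a2)`; when `a2 = 0` the formula is undefined and the standard
bias-corrected fallback `S0 + a1(a1−1)/2` is used. Shannon is natural-log.
"Population variance" is nowhere defined in the source material; it is
implemented as the variance of the per-sample NRA vector over detected VCs
(an evenness proxy consistent with its pairing alongside Shannon) and no
equivalence with published values is asserted. Bray-Curtis dissimilarities
feed intra- vs inter-individual and colon-vs-stool contrasts
(two-sided Wilcoxon rank-sum, normal approximation with tie correction — the
published test; no multiple-testing correction, matching the raw p-values
reported there) and classical MDS (`cmdscale`) for principal coordinates;
whether the published ordination transformed the dissimilarity is unstated,
so plain classical MDS is used. Matched phage–host Spearman correlations are
compared against a seeded null of random re-pairings.

**Depth saturation.** The published analysis re-assembles reads at each
subsampled depth; assembly is out of scope, so saturation is reframed as
*detection*: reads are allocated multinomially to known genomes by
abundance × length, per-bp depth `d` gives breadth `1 − exp(−d)`
(Lander–Waterman), and a genome is detected at breadth ≥ 0.75. Subsamples
are nested (incremental multinomial draws), so detection is monotone in
depth for a fixed seed. Knee locations and the diminishing-returns shape are
preserved; the published absolute yields (VCs per million) are
assembly-dependent and **not** claimed. Yields are reported per million
*read pairs* and labelled as such (the published phrasing mixes "per million
bases" with read-count depths).

## The synthetic community

The generator states one world and the tests measure recovery in it.

* **Design**: 3 participants × {PC, DC, STL}, MG and MV everywhere, MT at
  the colonic sites with one failed library (the third participant's distal
  colon), mirroring the reference study design, including its inflammation
  grades (PC/DC = 2,2; 0,1; 0,2; stool ungraded).
* **Catalog**: 350 free phages + 150 prophages (50% of them "active", i.e.
  also released as particles) over 50 host contigs — ~500 VCs. Free phages
  are 85% Caudovirales-like (log-normal lengths, median 25 kb, sdlog 0.35)
  and 15% Microviridae-like (median 5 kb, sdlog 0.12); prophages are always
  Caudovirales-like and are embedded verbatim in their host with 2–4 kb
  random flanks per side.
* **Dataset states**: free phages assemble only in MV; prophages assemble in
  MG as pruned VCs; active prophages additionally in MV. This is what makes
  source labels and IC/NI recoverable exactly at saturating depth.
* **Abundance**: log-normal with a global (sd 0.75), per-participant
  (sd 1.5) and per-sample (sd 0.75) component, giving intra-participant
  correlation ≈ 0.83 vs inter-participant ≈ 0.17 — sites within a person
  resemble each other more than people resemble each other. Active-prophage
  particle abundance is coupled to the host at `mv_coupling = 0.7` (induction
  bursts decouple particles from host abundance, keeping MV semi-independent
  of MG), flank-linked pairs therefore correlate tighter than WIsH-style
  assigned pairs (`assigned_coupling = 0.5`), and MT abundance tracks MG with
  sd-0.5 noise, reproducing the published correlation ordering
  (MT–MG > MV–MT > MG–MV; flank pairs > assigned pairs).
* **Mass shares**: per sample, the viral/non-viral abundance split is
  rescaled to the dataset's stated viral NRA share — 75.1% (MV), 4.85% (MG),
  1.9% (MT), the study's reported fractions — before multinomial read
  allocation, so per-sample totals conserve the library size exactly.
* **Library sizes**: 2M read pairs for MG and MV, 20M for MT. The reference
  depths are ~75M/211M/119M; MG and MV scale down 40–100× without harming
  label recovery, but MT must stay within ~6× because only 1.9% of MT mass
  is viral and the "> 1 counts" transcribed-gene rule needs per-gene
  coverage.
* **Genes**: one record per kb slot at ~1 gene/2 kb, drawn from a small
  vocabulary (integrase, repressor cI, major capsid, terminase, packaging
  protein 1, ParB-like nuclease, unannotated filler). Integrase is planted
  on 69.6% of prophages and 49.8% of free Caudovirales — the proportions the
  source survey observed — so the planted integration LR is ≈ 1.4, the
  "weak predictor" regime. Transcription probabilities are per family
  (integrase 0.84, repressor 0.82, structural genes 0.5–0.6) with a +0.25
  bonus for packaging protein 1 on prophages; non-transcribed genes on TA
  VCs leak a single stray count with probability 0.1 to exercise the "> 1"
  boundary.
* **Contamination**: host-read fractions by inflammation grade
  {0: 0.02, 1: 0.037, 2: 0.70} (the study reports > 69.8% at Mayo grade 2
  and ≤ 3.7% below) are removed from the MG library before mapping; cpn60-
  style marker reads are drawn at 172 per million (MG) vs 1 per million
  (MV), the study's mean 172-fold VLP-enrichment effect.
* **Breadth model**: `1 − exp(−c · depth)` with `c = 1` per the standard
  Poisson-coverage argument; reads are 150 bp.
* **Composition**: nucleotide composition is uniform i.i.d. Real genomes are
  skewed, but containment at 95% identity is composition-insensitive, and
  uniform composition keeps the exhaustive alignment oracle honest (random
  pairs share no 21-mers).

**What a green test does not establish.** The generator has no sequencing
error, no chimeras, no strain microdiversity (contigs recur verbatim, so
clustering recovery is exact by construction — the mutated-sequence
behaviour is tested separately on fixtures), no assembly fragmentation, no
compositional bias of amplification, and quality tiers are sampled labels
rather than derived from completeness. Recovery rates here are therefore
upper bounds on real-data performance; what the tests do establish is that
the statistics are implemented correctly and that the stated signal
structure is recovered at the stated depths.

## Numerical and interface conventions

* Coordinates are 1-based inclusive in all files (GFF3 convention), 0-based
  half-open internally; the conversion lives in one place
  (`to_zero_based()` / `to_one_based()`).
* TSV dialect: tab-separated, UTF-8, `#` comments; reals written with 15
  significant digits so round trips agree to at least 12.
* A failed library is an absent sample-sheet row and an absent matrix
  column, never a zero-filled column; `validate_bundle()` reports a missing
  MT dataset as a warning (transcription disabled), not an error.
* All stochastic operations take an explicit seed; the generator's seeded
  runs are byte-reproducible (asserted on FASTA output).
* Wilcoxon tests use `exact = FALSE, correct = TRUE` uniformly.
* `matchPattern` caps patterns at 20 kb, so exact containment of longer
  queries falls back to a plain fixed-string search.

## Scaling choices in the test suite

Monte-Carlo module examples stated at 50 seeds run at 10 seeds (correlation
ordering, transcription-bonus contrast, yield-decay) to keep the default
suite under a minute apart from the acceptance file; the acceptance
criteria themselves (host-pair ordering and intra/inter Bray-Curtis, 50
seeds; yield decay, 20 seeds) run at full count. The transcription-bonus
contrast uses a dedicated scenario (`ta_fraction = 1`, 1000 VCs) because the
planted +0.25 family effect lives in per-family gene counts: at the default
scale the contrast is dominated by TA-calling sparsity rather than the
quantity under test.

## Known limitations

* Identity is computed from a single local alignment; a containment split
  across several alignment blocks (large indels) may be under-covered and
  missed. Real dereplication tools aggregate HSPs.
* The IC/NI dichotomy inherits the published caveat: NI means "integration
  not observed", and flank detection depends on upstream assembly quality.
* The integration LR computed from the published IC/NI integrase counts
  (71/102, 148/297) is 1.397; the source survey prints 1.31, which those
  counts cannot produce (possibly a length-normalized variant). Both the
  counts and the formula are exposed; neither value is asserted as the
  other.
* The published VC-source bookkeeping is internally inconsistent (text says
  330 "both"/342 metagenome-only; the table's totals and a later percentage
  imply the reverse; table body rows do not sum to the printed totals). The
  accounting helper reports sums as given and does not adjudicate.
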