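---
title: "Methods: miRNA discovery and phosphate-response analysis in phosmiR"
author: "phosmiR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery and phosphate-response analysis in phosmiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phosmiR implements a complete small-RNA analysis for a two-tissue,
two-condition plant study: leaf and root libraries under phosphate-replete
(+Pi, libraries HPL/HPR) and phosphate-depleted (−Pi, LPL/LPR) growth. This
vignette records the models, conventions and design choices behind each
stage, and what the synthetic-data tests do and do not demonstrate.

## Read preparation

Reads are screened for quality (no `N`, mean Phred ≥ 20 by default; the
original base-caller's quality rule is proprietary, so a simple mean-quality
rule stands in), the 3′ adapter is located by exact match of its first 8
bases anywhere in the read, and the insert upstream of the match is kept if
its length lies in [18, 31] nt. Discards are counted by reason (low quality,
no adapter, adapter-only, too short, too long) and the accounting identity
`total = clean + sum(discards)` is enforced by test. Exact prefix matching
is deterministic and sufficient for adapter-bearing synthetic reads;
mismatch-tolerant trimming is deliberately out of scope. All sequence
handling is in the DNA alphabet; `U` is accepted on input and mapped to `T`.

Reported percentages are rounded half away from zero to two decimals
(`round_half_up()`), matching the convention of published library tables; a
zero denominator yields `NA`, never 0. First-nucleotide bias is computed
over unique tags by default with a count-weighted option, since the original
report does not say which was used.

## Mapping and origin categories

Mapping is perfect-match only, on both strands, with every locus retained
(multimapping tags are not discarded; expression counts a read once per tag,
not once per locus). Matching delegates to Biostrings `PDict`/`matchPDict`;
a property test checks exact agreement with a naive all-positions scan on
genomes up to ~10 kb per chromosome.

A tag's category is the highest-precedence annotation feature overlapped by
any of its loci: known miRNA > rRNA > tRNA > snRNA > snoRNA > exon >
intron > unannotated. This precedence is our resolution of the sequential
remove-structural-RNA-then-exons wording of the original workflow; database
(Rfam) matching is replaced by coordinate overlap with annotation features
of the corresponding types, since no external database is bundled.
Coordinates are 1-based inclusive throughout the user-facing tables.

## Discovery: fold, excise, refold, filter

For every candidate tag locus three windows are proposed (upstream-anchored,
downstream-anchored, centred; flank 200 nt, clipped at chromosome ends) and
folded with RNAfold. The miRNA\* is inferred from the dot-bracket structure
as the pairing partner of the mature with the canonical 2-nt 3′ overhang;
matures that span the terminal loop are rejected. Because a 200-nt window
usually folds with extra stems contributed by flanking sequence, criteria
are **not** evaluated on the window: the precursor (duplex span plus a 10-nt
pad) is excised and refolded, mirroring the fold-again-and-inspect step of
the original pipeline. MFE, MFEI, and the single-stem test all refer to the
refolded precursor.

The seven criteria and their exact semantics:

| # | rule | default | semantics |
|---|------|---------|-----------|
| 1 | abundance | ≥ 100 TPM in any library | inclusive ("at least") |
| 2 | both arms | star tag detected | see below |
| 3 | mature length | 20–24 nt | inclusive window |
| 4 | precursor MFE | < −37 kcal/mol | strict |
| 5 | MFEI | > 0.85 | strict |
| 6 | hairpin | single-stem structure | no multiloop after removing unpaired positions |
| 7 | classifier hook | pass | user-pluggable function |

plus duplex constraints applied when candidates are formed: matched pairs
within the mature strictly greater than 16, and |len(mature) − len(star)| ≤
4 nt.

Two genuinely open readings are exposed as configuration rather than
guessed. First, the published arm-ratio rule ("5p/3p or 3p/5p higher than
0.9") is literally satisfied whenever both arms are detected, because
max(a/b, b/a) ≥ 1; the default (`arm_ratio_mode = "detect"`) implements that
literal reading, and `"min_over_max"` implements the balance test
min(a,b)/max(a,b) > 0.9 for users who want one. Second, the energy threshold
is printed in kJ/mol in places, but plant-miRNA MFEI practice and the
folding engine both use kcal/mol; the threshold is applied as −37 on the
engine's kcal/mol output and is configurable. The mature window is likewise
configurable to 20–23 nt, the stricter length statement that appears
alongside the 20–24 criterion. The single-stem test accepts internal loops
and bulges (one hairpin loop) and rejects any branching.

Overlapping windows yielding the same mature collapse to the best-MFEI
candidate; distinct loci of the same mature are kept as separate records
(miRNA families occupy multiple loci). MFEI uses |MFE| so the "> 0.85"
direction is meaningful; it is recomputable from the stored MFE, length and
GC% to 1e−9 by test, and an independent formula evaluation agrees to 1e−12.

Conservation classing: an exact same-species catalog match is *known*;
otherwise a family is assigned on an equal-length match with ≤ 3
substitutions (no indels) to any family member, *conserved* if the family
occurs outside the legumes, *less-conserved* if legume-only, *novel* if no
family. The bundled reference catalog is a constructed, clearly-labelled
synthetic stand-in whose family-by-species memberships follow the published
homology table; a real miRBase extract can be supplied instead.

## Expression and response

TPM = count / clean reads × 10⁶. Zeros are reported as 0.01 — a display
pseudocount applied on the TPM scale (not to raw counts), which is what
makes the published fold-change extremes reproducible from the printed
tables. Response per tissue is log₂(−Pi/+Pi) on reported TPM with strict
thresholds: induced iff > 1, repressed iff < −1 (the repression rule is the
symmetric completion of the published induction rule; only the induction
threshold is stated explicitly there). Tissue specificity requires a true
zero (a printed 0.01) in one tissue and detection in the other, per
condition. Counts sitting at the log₂fc = 1 boundary are sensitive to the
rounding of printed TPMs, so the test suite asserts the boundary-insensitive
quantities (the maxima, partitions, and set algebra) and treats induced
counts as soft.

## Degradome targets

Degradome reads pass the same trimming, keep 20–21-nt tags, drop polyN tags
(any single base > 70%), and are normalised to RP10M of clean reads. The
complementarity score follows the plant target-prediction convention —
mismatch 1, G:U wobble 0.5, gap 2, all doubled at miRNA positions 2–13 — as
the published score cap of 7 names no scheme; this choice is recorded as an
assumption and every penalty is configurable. Alignments are gap-free by
default (published target tables show gap-free sites); a single-gap option
exists. A degradome hit needs score ≤ 7 (inclusive), perfect Watson–Crick
pairing at miRNA positions 10 and 11 (G:U counts as a violation; a lenient
option admits it), and a degradome tag whose 5′ end equals the transcript
base pairing miRNA nt 10 — for a gap-free site, `site_end − 9`, with no ±1
slop by default. Peak-dominance site categories (CleaveLand-style 0–4) are
not implemented; the RP10M at the site is reported instead. Cleavage
positions are located against the transcript model as 5′UTR (before CDS
start), CDS (inclusive bounds), or 3′UTR.

Target mimics are sites that pair well on both flanks around a 2–4-nt
insertion bulge in the target strand between the partners of miRNA
positions k and k+1 (k ∈ 9–11), the configuration that sequesters a miRNA
without being sliced. One subtlety found during testing: a perfectly
complementary (cleavable) site also admits nearby bulged alignments of
modest score, so mimic detection excludes any span that contains a
cleavable gap-free site — there the bulge is not what blocks cleavage. The
mimic detector is verified against a brute-force enumeration of all bulged
alignments.

## Promoters

The promoter of a precursor is the 2000-base region 5′ of it on its own
strand (clipped and flagged if the chromosome ends first). Motifs are IUPAC
patterns scanned on both strands (sense-only is available per motif) with
all overlapping hits reported. The offset convention — nowhere defined in
the original — is the distance from the hit's 3′-most promoter base to the
precursor 5′ end, 1 = adjacent, applied identically when planting and when
scanning; palindromic patterns (e.g. the P1BS consensus GNATATNC) match both
strands over the same span and are reported once per strand. The default
motif table (P1BS GNATATNC, W-box TTGACY, TATA-box TATAWAW, an Inr-like TSS
proxy TTCANTYY, PHO CACGTG, PHO-like CACGTC, NIT2 TATCTA, TC TTCTTCTC) is a
set of implementer-chosen stand-ins: the element classes are the published
ones, but their consensi live in cited references, so the table is entirely
config-driven and TSS "prediction" is motif scanning, not a trained
promoter model. Positional summaries use half-open proximal [0, 1000) and
distal [1000, 2000] bins.

## The synthetic-data generator

The generator emulates the study design, not the sequencing chemistry.
Hairpins are built constructively: a near-perfect stem (12-nt GC-rich
extensions on both sides of the mature — GC-rich so the excised precursor
stays well below the −37 kcal/mol criterion even for AT-rich matures — and
two designed mismatches opposite interior mature positions so the stem is
not a perfect inverted repeat), an 8–40-nt low-pairing loop, and a designed
star derived from the designed structure with the same 2-nt-overhang rule
the discovery stage uses. Such precursors
satisfy the duplex and energy criteria by construction, which the suite
verifies by folding every planted precursor.

Counts are negative-binomial around depth × TPM/10⁶ with library-level
depth scaling (dispersion 0.05 by default, reducing to Poisson at 0; no
noise model is published for these libraries, NB is the standard choice for
tag counts). A designed TPM of zero emits exactly zero reads. Star tags are
emitted at 10% of mature abundance — enough for arm detection without
dominating libraries. Background fills each library to its depth: 60%
decoy-locus fragments (tandem-repeat rRNA/tRNA-like loci and random exonic
regions, so the category table is exercised), the rest random inserts, plus
small fractions of too-short, adapter-free and N-containing reads so every
cleaning counter is hit. Quality strings are constant Q40; base-call error
models are out of scope.

The default expression design cycles twelve archetypes: constitutive (high
and mid), leaf-/root-specific with true zeros, leaf-/root-/both-induced,
leaf-/root-repressed, a low-abundance unchanged profile, a leaf-specific
induced profile, and a root-specific −Pi-only profile. Designed fold
changes are ≥ 4-fold and responsive baselines ≥ 300 TPM: at the desk-scale
depths used in the tests (5 × 10⁴–2 × 10⁵ reads per library) Poisson noise
on a 100-TPM profile is large, and a scientist calibrating a recoverable
desk-scale simulation sets effects that clear the thresholds with margin.
Intended response classes are derived by applying the classifier to the
designed TPM matrix itself, so truth and pipeline semantics cannot drift
apart.

Degradome tags of 20–21 nt start exactly at each planted cleavage position
(site_end − 9); background tags are uniform over transcripts; one
non-coding transcript carries a 3-nt-bulge mimic site for the first planted
miRNA. Promoters are rejection-sampled to be motif-free (hit spans are
resampled until a full scan is clean), then planted with elements whose
pools differ by response class (induced genes P1BS-rich, repressed genes
PHO/NIT2-leaning), at recorded offsets and strands.

What passing these tests shows: the pipeline's rules are implemented
exactly (thresholds, coordinates, conventions), and in the noiseless limit
(dispersion 0, zero background) every planted object is recovered with
precision 1. What they do not show: performance on real libraries with
sequencing error, RNA modification artefacts, repetitive genomes, isomiR
heterogeneity, or hairpins near the criteria boundaries — the published
genome-scale discovery counts are not reproducible at desk scale and are
not asserted anywhere.

## Numerical and reproducibility choices

Percentages round half away from zero (two decimals for library tables, one
for site-region shares). Thresshold comparisons are strict or inclusive
exactly as tabulated above; ties are never broken stochastically —
candidate deduplication orders by single-stem first, then MFEI. All
randomness flows from a single integer seed through fixed per-stage offsets
(kept below 2³¹), making genomes, FASTQ files and all report tables
byte-identical across reruns; the run manifest records a hash of the
scientific configuration (output paths excluded). Published count tables
bundled as fixtures are transcribed as printed, with one systematic
exception: where a printed numerator/denominator pair is inconsistent with
its own column's clean-read total (two root-library mapping entries appear
swapped in the original), the pair is assigned to the library whose clean
total matches the denominator, so every recomputed percentage reproduces a
printed one. One typeset artefact (a TPM printed with an internal space) is
transcribed as the single number its fold change corroborates.

Problem sizes in the test suite are chosen for depth of coverage per unit
time: genomes of 20–40 kb with 4–8 planted hairpins and 4 × (3–5) × 10⁴
reads per run, five independent seeds for the recovery properties, and
brute-force oracles on inputs small enough to enumerate (≤ 10 kb scans,
1–2-edit scoring neighbourhoods, ≤ 500-nt promoters).

## Known limitations

Exact-match mapping only (no mismatch tolerance); no statistical testing of
differential expression (the design has no replicates); conservation
classing depends entirely on the supplied reference catalog; criterion 7 is
a hook, not a classifier; degradome site categories by peak dominance are
not implemented; the CLI's per-stage subcommands run through the integrated
pipeline rather than as isolated stage invocations.
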