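---
title: "Methods: array-CGH CNV calling and breakpoint mechanism classification"
author: "cghcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: array-CGH CNV calling and breakpoint mechanism classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghcnv)
```

`cghcnv` implements a complete comparative genomic hybridization (CGH)
workflow for surveying copy number variation (CNV) among inbred genotypes of
a species with a large, repeat-rich genome (the motivating system is barley,
whose early assemblies were collections of short whole-genome shotgun
contigs). The package covers array design, two-channel signal processing,
mixture-model CNV calling, genome-wide landscape summaries, sequence-level
confirmation of calls through orthologous alignment, and classification of
the double-strand-break (DSB) repair mechanisms that generated the
underlying insertions/deletions. Because real hybridization data and
multi-gigabase assemblies are outside desk scale, the package ships a
first-class synthetic-data generator whose outputs exercise every stage; this
vignette explains the models behind each stage, the defaults, and what the
synthetic tests do and do not demonstrate about real data.

## The unit of detection: 10-probe contig fragments

Low-copy regions of the genome are tiled with variable-length
oligonucleotides (56-100-mers) generated at a 10 bp step. Probes whose
average genome-wide 15-mer frequency exceeds 25 are removed as repetitive,
and probes with any secondary genomic alignment of at least 30 matched bases
(either strand) are removed as non-unique. From the survivors, greedy
left-to-right assembly collects sets of 10 probes clustered in 200 bp
windows ("contig fragments"), with consecutive windows separated by at least
500 bp. The fragment, not the probe, is the unit of CNV detection: testing
10 overlapping probes as a group suppresses the influence of small sequence
polymorphisms on individual probes.

Two design choices are not dictated by the procedure above and are therefore
explicit package decisions:

* **Per-start probe length.** The smallest length on the grid
  {56, 66, ..., 96, 100} whose GC-based melting proxy
  $T_m = 64.9 + 41\,(n_{GC} - 16.4)/L$ reaches `tm_target` is chosen,
  falling back to the longest grid length that fits. The default
  `tm_target = 74.5` gives a median probe length near 76 bp on a 45% GC
  genome, the length regime typical of long-oligo CGH arrays. This rule is a
  stand-in for an unpublished vendor procedure and is fully configurable.
* **k-mer strand policy.** The 15-mer table pools a word with its reverse
  complement (hybridization is double-stranded); a forward-only table is
  available via `strand = "forward"`.
* **Uniqueness detection.** A qualifying secondary alignment is anchored by
  an exact seed of `min_match` (30) bases; gapped extension beyond the seed
  cannot change the keep/eliminate decision under this scheme, so `max_gaps`
  is interface-compatible but inert. On small genomes the decisions coincide
  with an exhaustive scan over all $\ge 30$ bp substrings, which is how the
  tests check them.

## Signal model and normalization

The simulator draws a per-probe brightness $B_i$ (log2-normal, default mean
$2^{10}$, sd 1 in log2), scales the sample channel by the expected dosage
ratio, and adds three noise components chosen to exercise a
variance-stabilizing normalization: Gaussian noise on the log2 ratio
(`sigma_log2`, default 0.2), per-probe per-channel multiplicative noise
(log2 sd 0.1) and an exponential additive background (mean 100, i.e. about
10% of the median signal).

The expected probe ratio is $\log_2((c + \varepsilon)/(1 + \varepsilon))$
where $c$ is the relative copy number of the probe target and
$\varepsilon = 0.01$ is a pseudo-copy that bounds the ratio for absent
sequence — arrays report background, not $-\infty$. A probe whose target is
interrupted by a breakpoint retains only its longest contiguous matching
stretch $m$; its signal fraction is $\max(0, (m - m_0)/(L - m_0))$ with
$m_0 = 0.75\,L$. The thresholded form matters: under a model linear in
$m/L$, probes that span a mid-fragment insertion are bounded below by half
signal ($m \ge L/2$), the unaffected probes of the fragment stay at 0, and
the fragment mean can never cross the $-0.9$ calling threshold — yet
insertions observed between real genotypes do produce DownCNV/PAV calls.
Requiring three quarters of the probe to form a contiguous duplex before any
signal accumulates reproduces that artifact: a 22 bp insertion in the middle
of a fragment drives the fragment mean below $-0.9$ with zero noise.
Query-side insertions of at most `loopout_max = 21` bp are treated as
tolerated hybridization loop-outs and do not interrupt the duplex; the 22 bp
boundary mirrors the smallest insertions observed to cause such artifacts.

Normalization applies, per array and per channel, a generalized-log
transform $g(x) = \log_2(x + \sqrt{x^2 + a^2})$ with offset $a$ set to the
5th percentile of that channel (a robust proxy for additive background), and
then re-anchors the ratios so their median equals the median raw
$\log_2(\text{sample}/\text{reference})$ ratio. The per-channel offset makes
noise-free proportional channels map to a constant, exact log2 ratio; the
re-anchoring removes the additive constant introduced by the transform
without erasing genuine global dosage, and leaves the null mode at 0
whenever most probes are unchanged — which stabilizes the mixture
initialization downstream. The transform is monotone in each channel and
exactly invariant to rescaling both channels. The contract verified by the
tests is variance flatness (null-probe ratio spread varies less than 2-fold
across intensity deciles) rather than any particular calibration; one
consequence worth knowing is mild ratio compression at low intensities, so
single-copy gains (+1 expected) sit close to the 0.9 threshold and are
called with reduced sensitivity. Replicate arrays are averaged per probe
first, then the 10 probe values are averaged per fragment.

## CNV calling

Per genotype, fragment signals are modeled as a two-component Gaussian
mixture — a null component near 0 and a two-sided variant component —
fitted by expectation maximization with deterministic initialization (null
at median/MAD; variant at the mean of values beyond 0.9 absolute, inflated
variance; convergence at log-likelihood gain below $10^{-8}$, at most 500
iterations, variances floored at $10^{-4}$ to prevent collapse). The variant
component is identified after fitting as the component whose mean lies
farther from 0, ties broken by larger variance. A fragment is called when
its posterior probability of the variant component exceeds 0.95 **and** its
absolute log2 ratio exceeds 0.9 (a near two-fold change); the sign gives
UpCNV versus DownCNV/PAV. The array cannot distinguish a strong copy loss
from complete absence, hence the joint Down/PAV class. Whether the original
analysis fitted one mixture per genotype or globally is not documented;
per-genotype fitting matches the "tested genotype vs reference" framing and
is the default here.

Maximal runs of same-class calls on consecutive fragments of one contig are
merged into events (singletons allowed), and call sets from independent
replicates or array layouts are compared as the fraction of one set's
(fragment, class) pairs present in the other. On independent-noise synthetic
replicates of one truth this concordance exceeds 0.90, the property-level
analogue of the two-layout validation.

## Landscape statistics

The fragment-by-genotype call matrix feeds: the sharing spectrum (singleton
fraction), per-chromosome variant proportions with a one-vs-rest two-sample
t-test over 1.5 Mbp window proportions (the published chromosome tests do
not state their sampling unit; windows are this package's choice, and exact
published p-values are consequently not reproduction targets), signed
wild-minus-cultivated window differences, and Spearman correlation between
cM/Mb and CNV proportion in 10 Mb bins pooled across chromosomes, with
cM interpolated linearly at bin edges. Fragments enter windows by their
start coordinate (half-open windows, no double counting). Exon overlap is
any $\ge$1 bp intersection with annotated intervals.

## Sequence-level confirmation and indel extraction

For contigs where a called fragment is flanked on both sides by uncalled
fragments (anchoring the alignment), orthologous query contigs are found by
best local alignment at >95% identity — identity computed over aligned
columns only, so that the very indel under study does not disqualify its own
ortholog — chained along the reference and concatenated into supercontigs
with 50 `N` spacers (N scores as a strong mismatch, so alignments never
cross a spacer). The reference and supercontig are aligned with
Smith-Waterman under affine gaps (defaults match +1, mismatch -1, gap open
10, extension 0.5 per position; the original Water parameters are
unpublished and these are configurable). Every gap run becomes an indel
record with 60 bp flanks; a deletion-side and insertion-side run separated
by fewer than 5 aligned columns merge into one replacement record, the form
SDSA fillers take. Indels inside repeat or microhomology tracts are
normalized to their leftmost equivalent placement so signature detection is
deterministic (this is why round-trip position recovery is guaranteed only
to $\pm 2$ bp). One caveat of the +1/-1 scoring: a short filler flanked by
similar-sized deleted sequence can be absorbed as a low-identity mismatch
block instead of an explicit gap pair; a mismatch-averse scoring such as
+5/-4 keeps such replacements explicit.

Fragment coverage in the query (aligned bases / fragment length) is binned
as 0 / 0-24 / 25-49 / 50-74 / 75-99 / 100; the interior bin edges are a
convention of this package (the published table does not define them). A
fully covered fragment at $\ge$95% identity with no indel over 1 bp is
flagged as a false-positive call.

## Mechanism classification and the randomization null

Each indel record is classified by fixed precedence:

1. **template slippage** — 1-6 bp and the complete indel sequence repeated
   perfectly in the immediately adjacent flank;
2. **SDSA** — a replacement whose query-only segment is at least
   `min_filler = 5` bp and aligns to at most `max_identity = 60`% of its
   bases against the local reference context (both free parameters; the
   source analysis does not quantify "cannot be aligned");
3. **SSA** — breakpoint microhomology of 2-40 bp: the longest motif
   bordering the breakpoint and repeated at the other end inside the
   deleted sequence, taken as the maximum over both junctions (which side
   the original analysis scored is unclear; the maximum is the conservative
   symmetric choice);
4. **unknown** otherwise.

The precedence runs from the most specific signature (a full-length perfect
adjacent copy) to the weakest (residual homology); the four classes are
disjoint by construction. Classification is a pure function of the record.

Chance expectations come from placing the observed indel sizes at uniform
random positions in the same genome and scoring microhomology classes
{0, 1-2, >2 bp} per simulation; on equal-base-frequency sequence the
analytic chance of >2 bp homology at either junction is
$1 - (1 - 4^{-3})^2 \approx 0.031$, which the null reproduces. Enrichment
uses add-one Monte-Carlo p-values, $(1 + \#\{\text{sims at least as
extreme}\})/(1 + n_{sim})$, upper-tailed for >2 bp and lower-tailed for the
other classes.

## The synthetic generator as the study's stand-in

`spike_variants()` implants signatures into a copy of the reference (the
signatures are ancestral features, so reference and derived genome must
share them) and verifies each realized variant by re-running the detectors
at the truth coordinates, resampling on failure; "none" variants have their
junction bases adjusted so no signature remains. This rejection sampling
makes signature classes exclusive by construction, so classifier
proportion-recovery tests are exact up to multinomial noise — which is
precisely what they are meant to measure. What the generator does **not**
emulate: SNP-level divergence between genotypes (probe mismatch attenuation
is unmodeled; the panel is inbred and homozygous, as in barley),
transposon-scale nested repeats, assembly errors, and spatial array
artifacts (a published same-probes/different-layout comparison showed
spatial bias to be negligible, so it is deliberately out of scope). Passing
tests therefore demonstrate correctness of the procedures under the stated
noise model, not field performance on real hybridizations.

Default study conditions follow the motivating survey: panels split into
wild and cultivated groups with a configurable singleton fraction (default
0.391) and a wild-to-cultivated rate multiplier (default 1.5); the mechanism
panel uses 299 deletions mixed at proportions 0.411 / 0.127 / 0.157 / 0.304
(SSA / SDSA / slippage / none) with sizes 20-200 bp for SSA, 30-200 bp
deleted plus 10-60 bp filler for SDSA, 1-6 bp for slippage and 7-200 bp for
signature-free deletions. Note that with shared variants the realized
per-genotype wild/cultivated count ratio is attenuated below the configured
multiplier (shared variants hit both groups); the multiplier is recovered
exactly only in the all-singleton limit.

## Problem sizes and reproducibility

The packaged tests and the acceptance script run on genomes of 0.1-0.6 Mb
with a few hundred contig fragments, 299-indel mechanism panels and 10,000
null simulations — sizes chosen so that every stage, including the
quadratic alignments, completes in seconds to about a minute while keeping
all estimated proportions within tight multinomial error of their targets.
All randomness flows from one integer seed through `derive_seed()`, which
hashes a stage label into an independent, reproducible stream per stage;
re-running any stage with the same configuration reproduces its outputs
checksum-identically (see `run_pipeline()`'s manifest).
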