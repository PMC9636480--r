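---
title: "From DamID reads to reproducible binding peaks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From DamID reads to reproducible binding peaks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The assay and its resolution unit

DamID profiles protein–DNA interaction by fusing the *E. coli* Dam
methylase to a chromatin protein (or, in NanoDam, to an anti-GFP nanobody
that recruits it to any GFP-tagged protein). Dam methylates adenines in
GATC motifs near binding sites; DpnI then cuts only methylated GATCs, so
the sequenced library consists of genomic fragments released between
pairs of methylated GATC sites. The analysis therefore does not operate
on base pairs but on **GATC fragments** — the intervals between
consecutive GATC motifs — which in *Drosophila* lie a median of roughly
190 bp apart. Everything downstream (signal tracks, peaks, QC) lives on
this fragment tiling.

`build_fragment_map()` places each internal fragment boundary at
`motif_start + 2`, the blunt DpnI cut between GA and TC. The convention
is not dictated by the file formats (any fixed offset would tile the
genome); we chose the enzymatic cut point because it makes the simulator
and the map agree exactly: a molecule released between two methylated
motifs is precisely one or more map fragments. Internally all coordinates
are 0-based half-open; GFF output is 1-based inclusive, and
bedgraph/BED/broadPeak outputs are 0-based half-open, following each
format's standard.

# The signal model

For a Dam-fusion sample $e$ and a Dam-only control $c$, reads are
extended to 300 bp in their strand direction and each read's unit weight
is distributed over the fragments it overlaps, proportional to overlap
length. The proportional rule was chosen over "full count to every
overlapped fragment" because it yields an exact conservation law — total
fragment weight equals the aligned read count — which the test suite
asserts to numerical precision ("all-overlap" counting remains available
via `count_fragments(mode = "all")`).

The binding track is the per-fragment log ratio

$$r_i \;=\; \log_2 \frac{e_i^{\mathrm{RPM}} + \psi}{c_i^{\mathrm{RPM}} + \psi},$$

with both libraries scaled to reads per million and a symmetric
pseudocount $\psi$ (default 0.5 RPM). The upstream Perl implementation of
this normalization applies a kernel-density read-count correction whose
details are not part of this package's contract; we deliberately use the
fully specified RPM-plus-pseudocount form instead. It is antisymmetric
(swapping experiment and control negates the track exactly), well defined
at zero counts, and has one tunable parameter. Larger $\psi$ shrinks
ratios of low-coverage fragments toward zero; 0.5 RPM corresponds to half
a read in a one-million-read library, a conventional weakly-informative
choice.

Tracks from all pairwise comparisons are quantile normalized (rank $r$
receives the mean of the $r$-th order statistics across tracks; ties
receive the mean of the reference values of their tied ranks, the
standard convention, computed via limma) and averaged. Dam-only samples
additionally yield **accessibility tracks** in the CATaDa sense: their
raw RPM signal, not compared to any control, quantile normalized across
the Dam-only replicates and averaged.

# The comparison design

With $m$ fusion and $n$ Dam-only replicates the pipeline runs all
$m \times n$ pairwise comparisons, named `<exp>_vs_<ctrl>`, rather than
pooling replicates. Averaging the $m\,n$ ratio tracks and demanding
reproducibility of peaks across the pairs uses replicate information
without assuming balanced designs. For negative controls the same grid
machinery runs Dam-only against Dam-only with self-pairs excluded
($n(n-1)$ comparisons), which is also how the `*_DamOnly_peaks` outputs
are produced.

# Broad peak calling

DamID signal is not point-like, so the caller only has a broad mode. Per
pairwise comparison it tests each fragment's experimental weight $w_i$
against a local Poisson background:

$$\lambda_i \;=\; s \cdot \ell_i \cdot \max\left\{d_i^{\mathrm{frag}},\,
d_i^{1\mathrm{kb}},\, d_i^{5\mathrm{kb}},\, d_i^{10\mathrm{kb}},\,
d^{\mathrm{genome}}\right\},
\qquad p_i = P\!\left(X \ge \mathrm{round}(w_i)\right),\; X \sim
\mathrm{Pois}(\lambda_i),$$

where $\ell_i$ is the fragment length, the $d$ terms are control read
densities over the fragment itself, windows centered on it, and the
genome-wide mean (the floor that guards against empty control regions).
Taking the maximum makes the test conservative in regions where the
control fluctuates.

The scale factor $s$ maps control depth onto experimental depth. Its
default is the **median per-fragment ratio** $\mathrm{median}_i\,(w_i /
c_i)$ over fragments with control coverage, not the total-library ratio.
The reason is composition: in a successful experiment a substantial share
of the fusion library sits in peaks, so the total-read ratio
overestimates the experiment's *background* depth in one direction and
underestimates it in the other; the median ratio tracks the background
compartment robustly (the same idea as median-of-ratios size factors in
RNA-seq, and the problem the kernel-density correction of the original
pipeline addresses). `peak_call_params(scaling = "library_size")`
restores the naive behaviour.

Fragment p-values are converted to q-values by Benjamini–Hochberg.
Fragments with $q \le$ 0.05 seed peaks; maximal runs of consecutive
fragments with $q \le$ 0.1 containing at least one seed are emitted as
broad peaks, so sub-threshold fragments can link two seeds into one
region. A peak records the $-\log_{10}$ of its best fragment p- and
q-value, the mean log ratio as `signalValue`, and a display score
$\min(1000, 10\,q_{\mathrm{peak}})$.

# Consensus and reproducibility

Peaks from all pairwise comparisons are thresholded at each value of a
41-entry $-\log_{10}(\mathrm{FDR})$ ladder, pooled, sorted and merged
(≥ 1 bp overlap) into one consensus set per threshold. The ladder is
anchored at 0–5 in steps of 1 and 10–100 in steps of 10 and rises to
2000; the interior values between 100 and 2000 are a round-number
progression (125, 150, 175, 200, 250…500 by 50, 600…2000 by 100) chosen
to complete the 41 entries, and the whole list is user-overridable
(`consensus_config()`).

The reproducible set at a threshold keeps the consensus peaks that
overlap a thresholded peak in at least 50% of the per-pair files; "at
least" is inclusive, so presence in exactly half the comparisons
suffices. Reproducibility is evaluated per threshold (on the thresholded
per-pair sets) rather than once on the raw peak files; both readings of
the upstream description are defensible, and the per-threshold one keeps
the `.reproPeak` outputs consistent with their `.mergePeak` companions at
every stringency.

# Quality analyses

Four library-level diagnostics are implemented:

1. **Genome-wide correlation.** Reads extended to 150 bp are counted in
   500 bp bins and Pearson correlations computed between all samples, on
   raw binned counts (a log-transform can be applied by the caller).
   Libraries are kept when the *median* of their correlations to
   same-type libraries is ≥ 0.9, and pairwise-ratio tracks when it is
   ≥ 0.8; both bounds are inclusive. The aggregation rule (median of
   off-diagonal correlations) is this package's choice — the
   recommendation the thresholds come from shows full matrices but no
   aggregation — and it is robust to a single bad partner.
2. **Complexity curves.** The expected number of distinct reads at
   subsampled depth $n$ is computed exactly as
   $\sum_u \left(1 - \binom{N-c_u}{n}\big/\binom{N}{n}\right)$ over
   duplicate classes (identical alignment coordinates) of multiplicity
   $c_u$. The closed form was preferred over random subsampling so the
   curves, and their tests, are deterministic.
3. **Fingerprint curves.** Bins ranked by count; the cumulative read
   fraction against bin-rank fraction. Fusion libraries, whose reads
   concentrate in bound regions, bow further toward the lower-right than
   Dam-only libraries.
4. **Enrichment profiles.** The averaged binding track is sampled at
   evenly spaced offsets within ±1 kb of each reproducible-peak center
   and averaged across peaks; fusion comparisons should peak at offset 0
   while Dam-only negative controls stay close to flat. A slight central
   bump in the negative control is expected — it reflects stochastic
   methylation of open chromatin.

A pooling calculator implements the pre-sequencing molarity and volume
formulas (molarity $= (1500/\text{fragment size}) \times$ concentration;
per-library volume $= (\text{target}/\text{molarity}) \times
(\text{final volume}/n)$; water $=$ final volume $-$ sum of volumes) and
checks feasibility and mass balance.

# The simulator

`simulate_experiment()` generates a complete toy experiment with known
ground truth. What it emulates:

* a genome with GATC motifs planted at geometric start-to-start spacings
  (mean 190 bp by default, matching the *Drosophila* motif density) and
  GATC-free filler between them, so the planted positions are exactly
  the map's motifs;
* per genome copy, independent methylation of each GATC: probability 0.8
  at sites flanking one of the 40 planted binding fragments (fusion
  samples only) and 0.05 elsewhere — the open-chromatin background that
  Dam-only samples consist of entirely;
* fragment release only between *consecutive* methylated sites (an
  isolated methylated site releases nothing), mirroring the DpnI
  double-cut requirement;
* sonication to a normal length around 300 bp (sd 15%, truncated below
  at the read length), a single 50 nt read from a random molecule end on
  the corresponding strand, geometric PCR duplication with mean 1.5
  (duplicates are exact copies, so complexity curves have signal), and
  the DamID PCR primer plus index-adaptor read-through on the sequence
  itself when `include_adaptors` is on.

`n_molecules` counts released library molecules (pre-PCR): genome copies
are drawn until that many molecules have accumulated. The default of
50,000 molecules per sample on a single 200 kb chromosome gives
per-fragment background weights of a few dozen reads — deep enough for
the Poisson machinery to behave as it would genome-wide, small enough
that the full six-sample pipeline runs in well under a minute. These
defaults are the package's reference study conditions; the parameter
recovery and QC-separation tests in `tests/testthat/test-acceptance.R`
run against them unchanged, with seed 1 and sample $i$ seeded at
`seed + i`.

What the simulator does **not** model: sequencing errors and quality
variation (qualities are constant), mappability and repeats (the toy
aligner requires a unique exact match), GC bias, chromatin-state
structure in the background beyond a uniform open-chromatin rate,
barcode demultiplexing (barcodes only appear in read IDs), and
paired-end reads. Passing the recovery tests therefore demonstrates that
the statistical machinery is correctly calibrated for the assay's
fragment-release logic, not that real libraries are free of these
additional artifacts.

## Evaluation conventions

On the default simulation, recovery is scored at the reproducible set
with $-\log_{10}(\mathrm{FDR}) = 10$: *recall* is the fraction of the 40
planted fragments overlapped by a reproducible peak, and *precision* is
the fraction of reproducible peaks lying within 300 bp — the
fragment-count extension — of a planted fragment. The tolerance exists
because molecules released at a planted fragment's borders legitimately
deposit extended-read weight on the flanking fragments, so peaks may
extend one fragment beyond the planted interval; a stricter 0 bp
tolerance penalizes the workflow's own extension step rather than the
caller.

# Numerical and degenerate-input conventions

* Poisson p-values are computed on `round(weight)` (fractional weights
  arise from proportional assignment) and clamped into $(0, 1]$; a zero
  weight always gives $p = 1$.
* Quantile normalization of a single track returns it unchanged.
* A chromosome without any GATC motif is a single fragment; reads
  extending past chromosome ends are clipped; an extension shorter than
  the read keeps the read's own length.
* Trimming iterates to a fixed point, so it is idempotent by
  construction; a single matching pass is not, because removing an
  adaptor can expose a new spurious minimum-overlap match at the fresh
  end. Matching allows a 10% per-overlap mismatch rate with minimum
  overlap 3 (conventional trimmer defaults; the tools this replaces do
  not publish a different contract), both configurable.
* Zero-variance tracks make Pearson correlations undefined; they are
  reported as `NA` and flagged rather than silently dropped.
* All simulation entry points take explicit seeds and restore the
  caller's RNG state; identical configurations reproduce outputs byte
  for byte, which the pipeline test asserts via checksums.

# Known limitations

The aligner is an exact-match toy intended for simulated data — real
libraries should be mapped externally and ingested as SAM text. The
local-lambda caller assumes Poisson counts; overdispersion between
biological replicates is handled only indirectly, through the
reproducibility filter across pairwise comparisons. Background windows
(1/5/10 kb) and the q cut-offs (0.05 seed, 0.1 link) are exposed but
have been validated only on the simulator's conditions. The per-bp
cumulative arrays used for window densities are economical at toy-genome
scale but would need chunking for gigabase genomes.
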