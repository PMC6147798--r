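---
title: "snmcpipe: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{snmcpipe: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements:
what each stage models, which parameters matter and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and where the design was genuinely open.

## The measurement model

Bisulfite treatment converts unmethylated cytosine to uracil (read as
T) while methylated cytosine is protected. A sequencing read over a
known cytosine position therefore carries one binary basecall:
C = methylated, T = unmethylated (on the opposite strand frame, G vs
A). Every quantity in the package is a ratio of such basecalls,

$$ m = \frac{\sum \mathrm{mc}}{\sum \mathrm{cov}}, $$

pooled over whatever set of cytosines is of interest: a single site
(allc record), all CG- or CH-context sites of a cell (global mCG/mCH),
a gene body, or a 100 kb genomic bin. Cytosine context is collapsed to
two classes: CG (the canonical methylation context) and CH (H ∈
{A, C, T}; gene-body CH methylation anticorrelates with expression and
is the cell-type signature used for clustering and annotation in
neurons). A site whose trinucleotide context contains an N, or runs
off the contig end, is uncallable and excluded everywhere.

With conversion rate $c < 1$, a set of cytosines with true methylation
level $m$ reads at the apparent level $m + (1-m)(1-c)$. Reported
levels are raw (uncorrected), matching common practice; the inversion
is available as `correct_conversion()`. The conversion rate itself is
estimated from the unmethylated lambda spike-in, where every retained
C basecall is a conversion failure: `rate = 1 − Σmc/Σcov` over lambda
cytosines, with the pass threshold at 0.99.

## What the simulator emulates

`simulate_genome()` draws i.i.d. sequence at a background GC fraction
(default 0.42, mammalian-like), rewrites CGI intervals at elevated GC
with explicitly planted CG dinucleotides (measured CGI CG density is
then several-fold above background), and carries gene-body intervals
with marker flags. A 10 kb synthetic contig named `lambda` stands in
for the unmethylated spike-in — it is a stand-in, not the phage
sequence.

`simulate_methylome()` assigns every callable cytosine in every cell
an independent Bernoulli state at the level implied by its context
class, region and the cell's type: CG sites at `mcg` (with a CGI
override, default hypomethylated at 0.10), CH sites at
`mch × gene multiplier`. The bundled model has three cortical-flavoured
types (`L23`, `L4`, `Inh`) at global mCH 0.030/0.035/0.045 and marker
multipliers arranged so that the L2/3-like type is low at Cux1/Satb2
and high at Rorb — the pattern the annotation rule looks for.

`simulate_library()` emits paired reads with the artifact chemistry:

* **strands and frames.** Both genomic strands are sampled with equal
  probability; conversion is applied once per molecule so overlapping
  mates agree. R1 begins with the cell's 8-nt in-line barcode followed
  by converted sequence carrying the C→T signature of the sampled
  strand; R2 is the reverse-complement mate and therefore carries the
  G→A signature. Which physical mate carries which frame differs
  between published protocols; the package fixes this convention once
  and the aligner, caller and diagnostics are all written against it.
  One consequence worth knowing: the "expected ~1% C" composition
  regime of converted reads applies to the C→T frame (R1 here), while
  R2 reads C where the molecule has G (≈ half the GC fraction); the
  contamination diagnostics below use the frame-appropriate baseline.
* **Adaptase tail.** R2 starts with a low-complexity tail whose length
  is geometric with mean `tail_mean` (default 8 bp), truncated and
  renormalised at `tail_max` (default 50 bp). The geometric family is
  a maximum-entropy choice: only the mean and maximum of the real tail
  distribution are characterised. The tail alphabet on the tailed
  strand defaults to two letters (A/C, appearing as G/T at R2 starts);
  the two nucleotides the real enzyme uses are not published, so the
  alphabet is configurable. Setting it to the uniform four-letter
  alphabet emulates dNTP-carryover contamination: high-complexity
  tails that defeat fixed-length trimming and put C bases at R2
  starts.
* **Adapter dimers** (default 6% of pairs) carry no genomic insert —
  the read is adapter sequence after the barcode/tail. They model the
  primer-derived artifact class directly; primer chemistry is not
  simulated mechanistically.
* **PCR duplicates** (default 10%) copy a previous molecule —
  identical coordinates and conversion outcomes, fresh sequencing
  errors — so clonal collapse and complexity extrapolation have
  realistic substrate.
* **Lambda spike-in** (default 1% of genomic molecules) is drawn fully
  unmethylated.
* **Errors** are uniform substitutions at `seq_error_rate` (default
  1e-3) applied after conversion; no indels, and quality scores are a
  constant, so the aligner is ungapped and quality-blind by design.
* **CGI bias** (`cgi_bias`, default 1 = none) oversamples fragment
  starts near CGIs to emulate the CGI enrichment of PBAT libraries for
  uniformity comparisons.

What it does **not** emulate, hence what passing tests do not show
about real data: indels and structural variation, sequence-dependent
error and coverage biases, chimeric reads, index hopping, real
adapter/primer thermodynamics, and real genome composition (repeats,
true CGI structure). Results on this simulator validate the
*algorithms*, not performance on any particular organism's data.

## Preprocessing

Demultiplexing assigns a pair to the unique barcode within
`max_mismatch` (default 1) of the R1 prefix. The default set of eight
8-nt barcodes has pairwise Hamming distance ≥ 3, so the invariant
`distance > 2 × max_mismatch` makes ties impossible; violating sets
are rejected at load. With 768 dual-index pool labels the default
configuration multiplexes 6,144 cells.

Tail detection (the paper trail for trimming gives only fixed 16 bp
end trims) is a greedy scan of the R2 prefix over the expected
two-letter alphabet: in-alphabet bases extend the tail; an
out-of-alphabet base is absorbed only while the cumulative in-alphabet
fraction stays ≥ 0.9 **and** the next five bases are all in-alphabet —
clear evidence the tail continues — otherwise the scan stops and the
tail is trimmed back to the last in-alphabet position, capped at
`tail_max`. The five-base lookahead matters: converted genomic
sequence is ~30% G/T in the R2 frame, so a permissive cumulative-0.9
rule alone absorbs genomic runs at the junction and biases detected
lengths upward by close to a base pair; requiring a five-base run
(chance ~0.2% in genomic sequence) keeps the false extension near the
irreducible junction ambiguity (~0.4 bp, from genomic G/T bases
immediately after the true tail) while still absorbing isolated
sequencing errors inside genuine long tails. Detected mean tail length
is therefore expected to sit a few tenths of a base pair above the
generator mean; the recovery tolerance used in the tests (±0.5 bp)
accounts for this.

A pair whose R1 insert after adapter removal is shorter than
`min_insert` (default 30 bp — the artifact class is quantified but not
given a cutoff anywhere, so the cutoff is explicit and configurable)
is classified `dimer_or_short`; fixed trims are applied afterwards, so
classification is independent of trim settings.

## Alignment

The aligner is deliberately minimal — a desk-scale stand-in for the
production bisulfite mappers, sufficient for genomes of a few hundred
kb: exact k-mer seeds (k = 16, 2-bit packed) over the two converted
reference frames (genome C→T and G→A), ungapped extension over the
full read, mismatch fraction ≤ 0.1, best locus reported with
`score = matches − mismatches` and
`mapq = min(60, 2 × (best − second_best))`, ties at mapq 0. The MAPQ
formula is this package's own; only the downstream `MAPQ > 10` filter
semantics (strict inequality) follow the protocol's analysis.
Clonal reads — same cell, contig, start and frame — collapse to the
highest-scoring representative, with ties broken deterministically by
read id. On small genomes the aligner is tested for exact agreement
with an exhaustive scan over every position and frame.

## Library QC

Library complexity uses the Good–Toulmin estimator on the duplication
histogram $n_j$ (positions seen exactly $j$ times): the expected
number of new distinct positions at fold $t$ is
$\Delta(t) = \sum_j (-1)^{j+1} (t-1)^j n_j$. The raw series diverges
for $t > 2$; beyond that the sum is evaluated through its Euler
transformation ($\sum_k (-1)^k \Delta^k b_0 / 2^{k+1}$ over the
zero-padded term sequence, truncated when terms stop contributing at
relative 1e-12), the classical smoothing for this estimator — a
deliberate, documented stand-in for the rational-function acceleration
used by production tools. Conventions mirror the standard
extrapolation setup: bound 5e9, step grid 1e7, and a reference depth
of 50 million read pairs for the QC table's coverage-at-depth field.
Two honesty caps apply: predictions are bounded by genome size when
known, and targets beyond `max_fold` (default 100×) are truncated to
it and flagged `capped` — an alternating-series extrapolation carries
no information thousands of folds out, and desk-scale libraries hit
the reference depth only through this cap. Fraction-of-genome is
`distinct positions × read length / genome size` (capped at 1), an
approximation that ignores read overlap. Validation is against the
analytic Poisson expectation $G(1 - e^{-2\lambda})$ at fold 2, within
5%.

Coverage uniformity reports mean ± SD of per-CG-site depth over
covered sites (depth ≥ 1 — "covered" needs a definition and this is
it), the CV of read-base counts in 1 kb and 10 kb bins (ragged
terminal bins dropped), and CGI enrichment as mean per-base coverage
inside CGIs over the genome-wide mean. Group comparisons use Welch's
t-test (the pooled-variance alternative is defensible too; unequal
variances are the safer default for per-library QC metrics), with the
degenerate all-constant case returning p = 1 by convention.

## Clustering and annotation

Per-cell CH basecalls are aggregated into non-overlapping 100 kb bins
anchored at multiples of the bin size (0-based, half-open; terminal
partial bins included). The breadth filter keeps a bin only if
strictly more than `min_cell_fraction` (0.975) of cells have strictly
more than `min_basecalls` (100) total basecalls in it — both
inequalities strict, and the filter is idempotent. Bin ratios are
divided by each cell's global mCH, which removes per-cell global scale
(scaling a cell's methylome and its global level together leaves the
normalised matrix unchanged — a tested invariance) so clustering
reflects regional differences. Zero-coverage entries in kept bins are
rare at this filter stringency; they are imputed with the bin's
across-cell mean normalised ratio to avoid biasing the PCA. Columns
are centred but not scaled (bins share units, and scaling would
inflate low-coverage noise); the top `min(n_pcs, rank)` components
(default request 150) feed Ward-linkage (`ward.D2`) hierarchical
clustering on Euclidean distances. `k` is user-supplied or chosen at
the largest gap between successive merge heights. Cluster identity is
robust to the number of components on well-separated data — a tested
property, not an assumption.

Annotation evaluates pooled gene-body mCH per cluster and applies
rules of the form "low at Cux1 and Satb2, high at Rorb", with
low/high meaning strictly below/above the across-cluster median of
that gene (no published numeric cutoff exists; the median rule is
scale-free and never fires when all clusters are identical). Exactly
one satisfying cluster gets the label; several are all reported and
flagged ambiguous; ties at the median satisfy nothing.

Cross-dataset comparison pools `mc`/`cov` per interval (1 kb bins or
DMR-like intervals supplied as BED — DMR discovery is out of scope)
and reports Pearson correlation over intervals covered in both
datasets, refusing fewer than 3 shared intervals.

## Reproducibility and problem sizes

Every stochastic function takes a seed; the pipeline fans per-stage
seeds out of one global seed by stable string hashing, and a rerun
with the same configuration is bit-identical through alignment and
deterministic thereafter (manifest records version, seeds and a
parameter digest). The bundled study conditions — a 610 kb genome,
three cell types, a few hundred read pairs per cell, 10,000 pairs for
tail-recovery measurements — were chosen as the smallest sizes at
which every binomial recovery check has comfortable statistical power;
they complete in seconds to a couple of minutes on one core.

## Known limitations

* Ungapped alignment and no indel simulation — consistent with each
  other, unrealistic for real data.
* The Good–Toulmin/Euler extrapolator is honest only to modest folds;
  the `max_fold` cap makes extreme extrapolations explicit rather than
  silently unstable.
* CH sub-contexts (CHG/CHH) are not distinguished; analysis is CG/CH
  only.
* The mate/frame convention is fixed by the package (see above);
  tools with the opposite convention need their mates swapped at
  import.
* Per-cell conversion estimates are coarse at desk-scale lambda
  coverage; pooled estimation (`per_cell = FALSE`) is the stable
  option on small simulations.
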