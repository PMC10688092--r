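---
title: "Allele-specific copy number from well-barcoded linked reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific copy number from well-barcoded linked reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

wellcnv calls allele-specific somatic copy number alterations (CNAs) from
picogram quantities of tumour DNA sequenced on a well-barcoded linked-read
platform. This vignette is the package's account of its science: the data
model, the de-noising constructions, the segmentation and fitting
machinery, the simulator behind the test suite, and the numerical choices
where the design was genuinely open.

## The platform and the mono-allelic property

Large input DNA fragments (on the order of 100 kb) are distributed across
the wells of one or more 384-well plates, then amplified, fragmented and
sequenced; the well of origin of every short read is preserved in its read
group. With tens of picograms of input spread over hundreds of wells, a
given genomic locus is covered by at most one input fragment in the vast
majority of wells. We call this the *mono-allelic property*: all reads in
one well at one locus derive from a single parental allele. Both de-noising
constructions below rest on it.

The expected fraction of bi-allelic wells is a binomial calculation
(`predict_biallelic_fraction()`): with `c = input_pg / 6.6` genome copies
per parental allele (6.6 pg per diploid genome, roughly 6 pg per cell),
each copy landing uniformly in one of `W` wells, a specific allele reaches
a well with probability `q = 1 - (1 - 1/W)^c`, and the bi-allelic fraction
among covered wells is `q^2 / (1 - (1 - 1/W)^(2c))`. At 240 pg over 384
wells this is about 4.7%; spreading the same input over three plates lowers
it. The simulator reproduces this fraction from first principles (fragment
collisions), which the test suite checks.

## De-noised read depth ratio (RDR)

Per-fragment amplification depth is wildly non-uniform, so raw short-read
depth is a poor copy-number signal at this input scale. Instead, the
original fragments are reconstructed in silico (`reconstruct_rlfs()`):
within each well and chromosome, read pairs are chained while the gap to
the previous read is strictly less than 100 kb (`next start - previous
end`), and each reconstructed large fragment (RLF) spans from its first
read's start to its last read's end. Counting RLF depth rather than read
depth collapses the amplification noise to (approximately) Poisson fragment
sampling.

The RDR per non-overlapping 1 Mb window is `r = 100 * mean RLF depth /
germline reads`, with windows lacking germline coverage masked. GC content
and mappability are removed by an ordinary least squares fit `r ~ gc +
mappability` applied multiplicatively (`corrected = r * mean(fitted) /
fitted`, then recentred to preserve the genome-wide mean exactly). The
multiplicative form keeps depth non-negative; sex chromosomes are excluded
from the fit and from the genome-wide mean `r_bar` by default.

## De-noised B-allele frequency (BAF)

Heterozygous SNPs are retained when the germline shows at least 20 reads
and an allele fraction between 25% and 75% (inclusive). Per retained SNP
and well, the genotype entry is `+1` if the well's reads support only the
alternative allele, `-1` if only the reference, `0` if uncovered. Wells
showing *both* alleles contradict the mono-allelic assumption — they mark
fragment collisions — and are zeroed rather than majority-voted.

SNPs are partitioned into haplotype blocks: contiguous runs with inter-SNP
gaps of at most 500 kb; runs of more than 100 SNPs subdivided into
near-equal contiguous chunks (the equal-chunk rule is our choice; only
"subdivided" is prescribed); chunks split into connected components of the
graph joining SNPs that share a covering well (non-connectivity is exactly
the condition under which a block cannot be jointly phased); singletons
dropped. Within a block the SNP-SNP similarity matrix is

    M_ij = sum_k G_ik G_jk / sum_l |G_il| |G_jl|,

which under the exact mono-allelic property equals the rank-1 outer product
`h h'` of the haplotype sign vector. `h` is estimated as the sign of the
first singular vector of `M` (no centering; ties between singular values
broken by first occurrence; `sgn(0)` mapped to `+1`; global sign fixed by
`h_1 = +1`). Pairs with no co-covering well get `M_ij = 0`: they carry no
phasing signal.

The de-noised BAF is then computed per haplotype group from *counts of
wells*, not reads: `b = (wells supporting alt) / (wells covering)`, summed
over the group's SNPs, placed at the group's median SNP coordinate and
weighted by group size. Well counts are insensitive to per-fragment
amplification depth, which is where the short-read BAF noise comes from;
the test suite verifies that both the RLF-based RDR and the well-count BAF
have strictly higher signal-to-noise ratios than their read-based
counterparts on simulated data with per-fragment amplification noise.

## Segmentation

BAF values are mirrored (`b_mirr = 0.5 - |0.5 - b|`) and RDR values
normalised (`r_norm = r / (4 r_bar)`) so the two tracks live on comparable
scales. Each chromosome arm is segmented separately — no segment can span a
centromere — by minimising

    L(x) = sum_s sum_{i in s} w_i (x_i - xbar_s)^2 + lambda |S|,

with `lambda = 0.1`, weights equal to haplotype-group size for BAF and 1
for RDR (renormalised to mean 1 per arm so the penalty is comparable across
arms), and a minimum genomic span of 5 Mb per segment (arms shorter than
5 Mb are emitted whole). The printed form of the loss multiplies `x_i` by
`w_i` inside the square; we read it as standard weighted least squares
`w_i (x_i - xbar_s)^2` with weighted segment means, because the literal
reading is inconsistent with a weighted mean for non-unit weights. The
literal form is retained behind `segment_loss(literal_weights = TRUE)`.

Minimisation is a restarted stochastic greedy search (`greedy_segment()`,
compiled): each restart starts from the single-segment solution and
proposes random moves — add a breakpoint at a random admissible position,
remove a random breakpoint, shift one by a data point — accepting only
strict improvements and stopping after 100 consecutive rejections; the best
of 10,000 restarts (configurable; the tests use 200) is kept. The move set
and stopping rule are this package's definition — only "stochastic greedy
search" is prescribed. An exact dynamic-programming minimiser
(`dp_segment()`, O(n^2)) provides the independent optimum on small arms;
the suite requires the greedy search to attain it in at least 99 of 100
random arms of up to 20 points.

The BAF track is segmented first (it is cleaner), its breakpoints are
snapped to window boundaries and frozen, and the RDR pass may only add
breakpoints. The 5 Mb minimum binds in both passes.

## Purity, ploidy, and copy-number states

For purity `phi`, tumour ploidy `psi`, and a segment with major/minor
copies `{n_A, n_B}`, assuming diploid non-cancer cells:

    r_hat = r_bar * (phi*(n_A+n_B) + 2*(1-phi)) / (phi*psi + 2*(1-phi))
    b_hat = (phi*n_B + (1-phi)) / (phi*(n_A+n_B) + 2*(1-phi))

Per segment, `MSE_s = MSE_s^(r) + MSE_s^(b)` where each term is the mean
squared deviation of the segment's points from the state's expectation,
normalised by a genome-wide per-track noise estimate (pooled within-segment
variance, `sum SSE / (N - S)`, floored at 1e-6). The genome MSE is the
genomic-length-weighted mean of segment MSEs. States are enumerated up to
the largest total copy number consistent with the highest observed segment
mean (hard cap 30). Segments without BAF data, and the state `{0,0}` at
`phi = 1` whose BAF is undefined, are scored on the RDR term alone.

**Mirrored-BAF fold correction.** Mirroring folds the noise distribution at
0.5, so a balanced segment's mirrored mean sits below 0.5 by about
`sqrt(2/pi) * sigma_b`. Comparing the folded data mean against an unfolded
expectation systematically penalises exactly the true state, and on
simulated data lets degenerate low-purity solutions (whose state continuum
can match any mean) win. The MSE therefore evaluates the *folded-normal
mean* of `b_hat` under the estimated BAF noise; away from 0.5 this is
numerically identical to `b_hat`. The closed-form estimators exposed as
`expected_baf()` are untouched.

**Solution selection.** The purity/ploidy grid (`phi` 0.05–1.00 by 0.01,
`psi` 1.0–8.0 by 0.05; no grid is prescribed) often contains aliased
optima: a whole-genome doubling fits the data exactly as well as the true
karyotype, and at low purity an over-rich state set can mimic almost
anything. Following the lowest-ploidy-pronounced-minimum idea, we identify
local minima of the MSE surface (strictly below all eight neighbours;
ploidy-grid-boundary cells excluded, since a minimum cannot be verified
there), require a minimal relative prominence along the ploidy axis (1e-4,
which discards flat-ridge artifacts of the low-purity mimicry while keeping
genuinely shallow minima), and among minima within `kappa = 1.2` of the
global minimum return the lowest-ploidy one. If nothing qualifies, the
global minimum is returned. Identifiability fundamentally requires allelic
asymmetry: a genome with LOH pins the purity (only `phi` near the truth can
produce mirrored BAF near its observed floor), whereas a genome whose only
states are `{1,1}` and `{2,1}` is genuinely ambiguous and no selection rule
can rescue it.

**Sub-clonal states.** Given `(phi, psi)`, segments are first fitted with
clonal states; the genomic-length mode of that solution is the modal state
`{m_A, m_B}`. The state set is then expanded by clonalities `chi` in
{0.5, ..., 0.9}: a fraction `chi` of tumour cells carries the CNA and the
remainder sits at the modal state, giving the mixture forms of `r_hat` and
`b_hat` (which reduce exactly to the clonal forms at `chi = 1`, asserted
numerically over random states). A constant penalty `pi = 1` is added to
every sub-clonal MSE to prevent over-fitting. Ties prefer lower total copy,
then clonality, then higher minor copy.

## The simulator

Two levels. The **well-level simulator** (`simulate_well_data()`) emulates
the platform end to end: `round(input_pg / 6.6)` cells split into tumour
(fraction `phi`) and diploid normal; per cell, chromosome and haplotype,
each region is chopped into fragments with log-normal lengths (mean 100 kb)
in proportion to its copy number; fragments land in uniform random wells;
per-fragment amplification depth is log-normal with mean 1 (only
"non-uniform amplification" is prescribed; log-normal is our choice); read
pairs are placed uniformly within fragments at a Poisson rate proportional
to amplification; SNP allele observations follow the covering fragment's
haplotype, with read counts again Poisson in the fragment's amplification;
germline window depths are Poisson around a constant. Defaults are the
platform's stated conditions: 384 wells per plate, 240 pg of input
(about 40 cells at 6 pg each), 100 kb fragments. Everything is
deterministic given the config seed.

What it does *not* emulate: base-level sequencing error, mappability and
GC structure along a real reference (covariates default flat, so the
correction step is exercised by constructed-bias tests instead), reference
bias at SNPs, structural rearrangement breakpoints below window size, and
fragments spanning CNA boundaries (fragments are chopped within
constant-copy regions). Passing tests therefore demonstrate correctness of
the method's logic under its own assumptions, not performance on real
sequencing artifacts.

The **track-level simulator** (`simulate_cn_tracks()`) draws the de-noised
window RDR and BAF points directly around their model expectations with
Gaussian noise — the appropriate scale for segmentation and fitting
experiments on 3,000 Mb genomes where well-level simulation buys nothing.
Baseline noise (`sigma_r = 0.16` on a corrected-RDR level of 2, i.e. 8% a
window; `sigma_b = 0.02` per BAF point) reflects clean, bulk-like de-noised
tracks; the sub-clonal spike-in experiments use `sigma_r = 0.3`,
`sigma_b = 0.05`, the noisier microscopic-sample regime the spike-in
protocol was designed for. The exactness tests run baseline noise and two
inflated levels (3x, 6x) and require accuracy to degrade monotonically.

## Sub-clonal spike-in

Per-state means and variances of both tracks are estimated from a fully
clonal solution (`state_stats()`). A random eligible segment is overwritten
with draws from

    r ~ chi * N(mean_CNA, var_CNA) + (1 - chi) * N(mean_modal, var_modal)

read literally as a sum of two scaled independent normals (normal with mean
`chi*m1 + (1-chi)*m2` and variance `chi^2*v1 + (1-chi)^2*v2`); a
two-component mixture distribution is available behind
`method = "mixture"` — it has the same mean but a larger spread, and the
difference is immaterial at segment-mean level. BAF is spiked with the same
construction on the mirrored scale using per-state BAF statistics (no BAF
spike-in form is prescribed; this is an extension). Spiked segments are
chosen uniformly among eligible segments, and sensitivity at clonality
`chi` is the fraction of spikes re-fitted to the spiked state with
`chi < 1`. On the calibrated background the sensitivity curve is highest
around `chi = 0.5` and collapses toward `chi = 0.9`, where nearly-clonal
CNAs are (correctly) absorbed into clonal states. One caveat discovered
during design: states whose `chi = 0.5` mixture mean coincides with another
integer state's expectation (e.g. a `{3,1}` spike averaging to total 3,
the expectation of clonal `{2,1}`) are intrinsically hard at exactly half
clonality — the RDR is blind to the alias and only the BAF separates them —
so the spike experiment's background uses non-aliasing states.

## Benchmarking layer

Events are called from a profile as: amplification, total copy at least
twice the length-weighted median total; deletion, total 0; LOH, `n_B = 0`
with `n_A > 0` (a deletion is never LOH). Sensitivity is agreeing bases
over truth bases; the quantity reported as `specificity_paper` is agreeing
bases over called bases — a precision, named as the field's convention
prints it; `F1` combines the two, with undefined ratios reported `NA` and
`F1 = 0`. Exact-match fraction, ploidy error, and SNR ((difference of
`{1,1}` and `{1,0}` means)^2 over average within-truth-segment variance,
zero-noise capped at 1e12) complete the layer. Multi-caller consensus takes
per-base lower medians of majors and minors and flags callers whose
rounded ploidy loses the popular vote; re-running a dissenting caller at a
forced ploidy is out of scope.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| fragment chain gap | 100,000 | bp | fragments are ~100 kb; a larger gap cannot be intra-fragment |
| RDR window | 1,000,000 | bp | depth resolution at picogram input |
| SNP depth / AF filter | 20; 0.25–0.75 | reads; fraction | confident germline heterozygosity |
| block gap / size | 500,000; 100 | bp; SNPs | phasable block extent |
| lambda | 0.1 | loss units | segment penalty; detectability scales with points per CNA |
| min segment span | 5,000,000 | bp | CNAs of interest are multi-megabase |
| restarts | 10,000 | – | global-minimum assurance; 200 suffices at test scale |
| phi grid | 0.05–1.00 / 0.01 | – | full purity range |
| psi grid | 1.0–8.0 / 0.05 | – | up to octoploid |
| kappa | 1.2 | – | pronounced-minimum slack |
| prominence | 1e-4 | relative MSE | flat-ridge rejection |
| chi grid | 0.5–0.9 / 0.1, 1 | – | sub-clonal clonalities |
| pi | 1 | MSE units | sub-clonal penalty |
| state cap | 30 | copies | hard bound on enumeration |

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open internally (1-based VCF in, BED out).
Noise estimates are floored at 1e-6. `sgn(0)` in the singular vector maps
to +1. Segment-state ties break deterministically (parsimony, clonality,
minor copy). Greedy moves accept only improvements beyond 1e-12 so plateaus
terminate. Empty inputs return empty tables, not errors; an all-masked RDR
or an empty purity grid is fatal. Discordant read pairs spanning more than
100 kb are split into their mates, since one input fragment cannot explain
them. Zero germline depth masks a window everywhere downstream.

## Test problem sizes

The suite and the acceptance script size their simulations to the method,
not the platform: well-level runs use a 140 Mb two-chromosome genome at
240 pg input and 10 kb SNP spacing (about 250,000 read pairs); track-level
runs use a 470 Mb three-chromosome genome at 1 Mb windows; segmentation
oracles use arms of up to 20 points where exhaustive optimisation is
available; spike-in experiments run 200 spikes per clonality.

## Known limitations

Purity/ploidy identifiability requires allelic asymmetry in the genome
(see above); samples that are purely `{1,1}`/`{2,1}` mixtures admit aliased
solutions. The BAF fold correction uses the pooled noise estimate, which
mixes folded and unfolded segments and slightly under-corrects when most of
the genome is balanced. Only one sub-clone per segment is modelled, against
the clonal modal state. The `specificity_paper` metric is a precision, not
a true specificity. The simulator's realism limits are listed above.
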