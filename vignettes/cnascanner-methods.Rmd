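---
title: "Methods: allele-specific CNA calling in single cells"
author: "cnascanner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific CNA calling in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its statistical machinery:
the models, the tunable parameters with their defaults and the reasons
behind them, what the synthetic-diploid simulator does and does not
emulate, and the numerical choices that matter in corner cases.

## Signals and notation

For each cell and genomic bin the package works with the read-depth
ratio (RDR) $x_i = a_i / b_i$, where $a_i$ is the observed read count
and $b_i$ the expected count from a per-cell GC model, and with the
phased B-allele frequency (pBAF), the fraction of haplotype-B reads
among all reads at phased germline heterozygous SNPs (gHETs) aggregated
over the bin. Aggregation over the bin is what makes the pBAF usable at
all in single cells: per-site allele counts are noisy and allelically
biased, but with phase information the per-site depths pool into a
binomial-like count with thousands of trials per 100 kb bin.

## Allelic dropout and the minimum bin size

Allelic dropout (ADO) — failed amplification of one allele — depresses
read depth and pushes the local BAF toward 0 or 1, mimicking a one-copy
loss. The length scale of dropout is a property of the amplification
chemistry (kilobases for PTA, ~100 kb for MDA), so the package fits it
per dataset: site BAF is binarized (0 iff $|BAF - 0.5| < 0.2$) and a
two-state hidden Markov model (states "ADO" and "non-ADO") is trained
by Baum-Welch with random restarts; Viterbi decoding turns maximal ADO
runs into events, and the 95th percentile of the event-length
distribution (value at index $\lceil 0.95 n \rceil$ of the sorted
sample — stated explicitly because conventions differ) is the smallest
permissible bin size, optionally snapped upward to a user ladder.

**Emission model.** The default emission family is Bernoulli: each
state is a coin with its own probability of emitting 1. A Gaussian
kernel per state is also provided, but on 0/1 data its maximum
likelihood is degenerate — the density concentrates on the two atoms,
the posteriors harden, and the fitted transition matrix collapses onto
the transition frequencies of the *observed* sequence rather than the
hidden chain. Under the Bernoulli family the transition matrix of a
simulated two-state chain is recovered to within a few hundredths at
$n = 10^4$, which is the property the bin-size rule relies on.
Defaults: uniform initial distribution, 10 random restarts, absolute
log-likelihood tolerance $10^{-4}$, at most 100 iterations. Training
cells should be low-aneuploidy cells; the HMM assumes CNAs are rare
relative to dropout in the training genome.

## GC normalisation

Expected counts come from a robust loess (locally quadratic, symmetric
family, span 0.75) of observed bin count against GC fraction, rescaled
so the fitted relative depth averages exactly 1 over the training bins;
$b_i$ is the cell mean count times that relative depth. Bins with less
than half their span uniquely mappable are masked. The model is fit per
cell, on all bins: with a genome-scale bin set, CNA bins are a minority
at every GC value and the robust fit ignores them. On toy genomes
(tens of megabases) a multi-megabase event *can* occupy a whole GC
stratum and be partially absorbed into the curve — worth knowing when
constructing small examples; the package's reference simulations use a
150 Mb genome where this does not occur. A hook accepts externally
produced expected-count tracks in place of the built-in model.

## Joint segmentation

Segmentation maximises parsimony under the simplified multi-sample BIC
(see the README for the formula): starting from singleton bins, the
adjacent pair whose merge most lowers the BIC is merged (leftmost on
ties, so output is deterministic) until no merge lowers it, separately
per chromosome. The implementation keeps per-segment sufficient
statistics ($\sum a$, $\sum b$ per cell) and updates only the two
neighbouring merge candidates after each merge, so a 30,000-bin genome
stays comfortably tractable. Total reads $N_k$ count *observed* reads
only, following the single-sample definition. Cells are treated as
independent; BAF never enters the segmentation criterion.

**Choosing $\lambda$.** The criterion's tuning parameter trades
sensitivity to short private events against over-segmentation of
amplification waviness, and its useful range depends on the number of
cells sharing breakpoints and their depth. `joint_segment()` defaults
to $\lambda = 1$ (the natural unpenalised-BIC scale); the pipeline
default is $\lambda = 12$, calibrated once on the simulator's reference
condition (pairs of 30×-equivalent cells on 100 kb bins, PTA-like
noise) by scanning $\lambda \in \{5, 8, 10, 12, 15, 25\}$ at several
seeds and choosing the centre of the plateau on which 1–5 Mb losses,
500 kb gains and >2 Mb copy-neutral LOH are all recovered. Users
running many cells jointly at different depths should expect to
re-tune.

## Per-segment BAF and the LOH test

Copy-neutral LOH leaves read depth untouched, so it must be read off
the BAF. Two obstacles: dropout artifacts also push BAF to 0/1, and a
balanced segment's pBAF is not exactly 0.5 bin by bin (allelic
amplification bias). The refinement runs per cell and segment:

1. **BAF changepoint split.** Depth-derived segment boundaries carry no
   information about LOH edges, so each segment is first recursively
   split at the cut maximising the two-mean deviance of its per-bin
   folded BAF whenever the deviance (scaled by the cell's per-bin BAF
   variance) exceeds 30. An LOH edge shifts the folded BAF by ~0.5,
   i.e. tens of standard deviations per bin, and is always found;
   amplification noise (~1 sd per bin) never reaches the threshold.
   The depth-based joint segmentation itself remains RDR-only — the
   split is a per-cell refinement between segmentation and calling.
2. **LOH test.** The haplotype-specific shift divides the B-haplotype
   count by the bin's GC-expected relative depth and recomputes pBAF.
   In a balanced segment GC affects both haplotypes, so the unshifted
   pBAF is tight around 0.5 while the shifted one spreads with GC; in
   an LOH segment ($count_B \approx 0$) the shift does nothing. A
   two-sample Kolmogorov-Smirnov test compares $|pBAF - 0.5|$ before
   and after: indistinguishable distributions ($p \ge \alpha$, default
   0.05) indicate LOH, guarded by a homozygosity condition (median
   $|pBAF - 0.5| > 0.4$) so that flat balanced segments — where the GC
   signal is too weak for the test — are never labelled LOH. Segments
   with fewer than 10 informative bins skip the test (low-confidence,
   non-LOH assumed). On balanced simulated segments the false-LOH rate
   is effectively zero, well inside $\alpha + 0.02$.
3. **Peak calling.** The per-bin pBAF distribution is peak-called by
   Gaussian kernel density (Silverman bandwidth computed on the
   original sample; the data are reflected at 0 and 1 only to remove
   boundary bias), peaks within 0.1 of 0 or 1 are discarded as dropout
   artifacts, and the highest-density survivor — folded to
   $\min(p, 1-p)$ — is the segment BAF (median folded pBAF if nothing
   survives; 0 for LOH segments). Peak calling runs on the *unfolded*
   values deliberately: folding first biases the mode of balanced
   segments below 0.5, because the fold is a max-type statistic.
   Numerical guards: bandwidth from the original sample only, peaks
   below $10^{-3}$ of the maximum density ignored (floating-point
   ripples in zero-density regions are not peaks), segments with fewer
   than 3 informative bins use the median directly.

The 1/3-vs-2/3 ambiguity of a single-copy gain (which allele the BAF is
measured against) collapses under the minor-allele convention; the
copy-number likelihood only needs $\min(a,b)/(a+b)$.

## Scale factor and allelic copy numbers

Bins with $0.45 < pBAF < 0.55$ (exclusive) are taken as allelically
balanced; a Gaussian mixture over their RDR values (1 to $t$
components, selected by BIC via `mclust`) keeps only the largest
cluster, and the candidate scale factors are
$\Gamma = \{\, 2\theta / \overline{x}_S : \theta = 1, \dots, t \,\}$
with $\overline{x}_S$ the mean RDR of that cluster. Default $t = 2$
(up to two whole-genome duplications); if fewer than 30 balanced bins
exist the band widens once to (0.4, 0.6) with a warning.

For each candidate $\gamma$, each segment takes the state
$(a, b), a \ge b \ge 0, a + b \le 8$ maximising a Gaussian
log-likelihood of its observed (RDR, folded BAF) around
$((a+b)/\gamma,\; b/(a+b))$; LOH segments are restricted to $b = 0$.
Variance model: the per-segment RDR sd is the balanced-bin RDR sd
scaled by $\sqrt{\mathrm{ESS}/n_{bins}}$, where the effective-sample
-size factor $(1+\rho_1)/(1-\rho_1)$ is estimated from the lag-1
autocorrelation of balanced-bin RDR (amplification waviness is
autocorrelated, so $1/\sqrt{n}$ alone is overconfident); the BAF sd
uses the same inflation on the cell's per-bin folded-BAF sd, with a
binomial-sampling lower bound $\sqrt{0.25/\text{depth}}$. Floors: 0.02
(RDR) and 0.01 (BAF). A parsimony log-prior of 2 per unit of
$|a-\theta| + |b-\theta|$ keeps focal artifacts from drifting into
exotic states without real evidence.

**Selecting $\theta$.** Model selection for the scale factor uses
$-2\sum \log L + \theta \log S$ over segments with at least 10 bins,
and a larger $\theta$ is accepted only when it beats the smaller one by
a decisive margin (200 BIC units). Both guards address the same
failure: focal amplification artifacts (partial dropout) produce small
segments with extreme BAF that a doubled state space fits spuriously
well, while genuine whole-genome duplication leaves megabases of
segments at half-integer relative depth worth thousands of BIC units.
The flip side, a documented limitation, is that a truly tetraploid cell
whose genome is *perfectly* balanced is indistinguishable from diploid
by relative signals alone and is resolved to $\theta = 1$ by parsimony
— the same identifiability limit any relative-depth method has; such a
cell is called (2,2) genome-wide when the caller is run with
$\Theta = \{2\}$.

Adjacent same-state segments merge into call intervals; states other
than the balanced baseline $(\theta, \theta)$ are reported as CNAs.

## The synthetic-diploid simulator

The simulator emulates — at binned-depth and per-site allele-count
resolution — a diploid chromosome assembled from two independently
amplified haploid sources, so CNAs can be spiked into one haplotype
without disturbing the other's signal structure. Defaults define the
package's reference condition and were chosen once:

| parameter | default | rationale |
|---|---|---|
| genome | one 150 Mb chromosome | chromosome-scale, desk-size |
| bin size | 100 kb | reference analysis resolution |
| depth | 15× per haplotype (30× total), 150 bp reads | high-coverage scWGS |
| amplification field | Gamma, CV 0.1, 300 kb correlation | PTA-like waviness |
| ADO | log-normal(log 2000, 0.8), 5 events/Mb/haplotype | PTA-like kb-scale dropout |
| gHETs | 5 per 10 kb, uniform within window | realistic SNP density |
| phase switches | Binomial(0.01) per site, depths swapped | reference-panel phasing error |
| depth noise | Poisson on bins and sites | sequencing sampling |
| CNA sizes | 13 geometric steps, 200 kb – 5 Mb | sub-Mb to multi-Mb range |

Spike semantics: a `1|0` loss zeroes haplotype B in the interval (with
binomial thinning of partially covered bins); `2|1` and `3|1` gains add
one or two independently amplified replicates of B; `2|0` copy-neutral
LOH leaves depth untouched and reassigns B's allele identity to A at
the gHETs (total allele depth conserved exactly). Each mutated cell
carries one event; every condition also emits an unmutated control
cell. The experiment driver's default condition spikes 100 events of
one type and size.

**What the simulator does not emulate:** real read alignment and
mappability structure, GC bias beyond a smooth composition wave,
chimeric amplification artifacts, cell-to-cell clonal structure
(every simulated CNA is private), and locus-specific dropout hotspots.
Passing the packaged benchmarks therefore demonstrates correctness of
the statistical machinery under a realistic noise model, not
performance on any particular real dataset.

## Benchmark harness and problem sizes

The benchmark driver analyses each mutated cell jointly with its
condition's control cell, mirroring per-individual analysis: synthetic
diploids are assembled from their own haploid donors, so cells from
different conditions share no clonal breakpoints and pooling them into
one joint segmentation would be scientifically wrong (and would also
scale the breakpoint penalty with cohort size against private events).
Packaged experiment sizes — 20 cells for 1–5 Mb losses, 40 for 500 kb
gains, 20 for 2.5/5 Mb copy-neutral LOH, ~1,500 bins per cell — were
chosen to give stable rates while keeping a full run in minutes on one
CPU. Copy-neutral LOH evaluation considers calls larger than 2 Mb,
the scale at which that variant class is reliably separable from
dropout artifacts. Matching uses 50% reciprocal overlap per cell and
type.

## Other numerical conventions

- SNP positions are 1-based; bins and BED-style outputs are 0-based
  half-open; round-trips preserve coordinates exactly.
- $0 \log 0 = 0$ throughout the BIC likelihood terms.
- Multi-allelic SNPs are dropped at ingestion; unphased heterozygous
  records are dropped and counted.
- VAF bounds for gHETs are exclusive, default (0.1, 0.9).
- All randomness is seeded explicitly; functions restore the caller's
  RNG state, and two runs of the pipeline with the same inputs and
  configuration are byte-identical.
- Precision with zero calls is 1 by convention ("no false positives"),
  with NA selectable.
- Stage caching across runs is not implemented; determinism makes
  re-execution equivalent.
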