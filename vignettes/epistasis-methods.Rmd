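---
title: "Decomposing complete genotype-phenotype landscapes into epistatic interactions"
author: "epicube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing complete genotype-phenotype landscapes into epistatic interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicube)
```

## The problem

When a protein separates two phenotypically distinct variants by $N$
substitutions, the $2^N$ combinations of those substitutions form a binary
hypercube of genotypes, each with a quantitative phenotype $y(g)$ (here:
fluorescence brightness of variants linking a blue and a red parent of a
sea-anemone fluorescent protein). The phenotype of a combination is rarely
the sum of its parts: mutational effects depend on the genetic background
(epistasis), potentially up to the $N$-th order. `epicube` implements the
complete analysis chain for such landscapes: decomposition into interaction
terms of all orders, significance calling under propagated measurement
noise, sparse recovery of the interaction spectrum from subsampled
phenotypes, estimation of low-order interactions from thresholded sequence
alignments, trajectory and connectivity analysis of the functional
genotype network, and preprocessing of the FACS-seq barcode counts that
such experiments produce.

## Conventions

Genotypes are indexed by the integer whose bit $k$ (least-significant bit
first) carries the allele at position $k+1$; allele 0 is the first
("blue") parent, allele 1 the second ("red"), so the parents are index 0
and $2^N - 1$. Phenotype and spectrum vectors are stored in ascending
index ("binary") order. The source does not pin this orientation; it is a
package convention, and every sign-sensitive test fixes it explicitly.
The order of an interaction term is the popcount of its index.

## The two epistasis transforms

Epistasis is a linear change of representation,
$\bar\omega = \Omega \, \bar y$, between the $2^N$ phenotypes and $2^N$
interaction terms. Two operator forms are supported, built from $2\times2$
block recursions with $V_0 = H_0 = X_0 = 1$ (the recursion step appends
each new position as the most-significant bit):

$$
V_{n+1} = \begin{pmatrix} \tfrac12 V_n & 0 \\ 0 & -V_n \end{pmatrix},
\quad
H_{n+1} = \begin{pmatrix} H_n & H_n \\ H_n & -H_n \end{pmatrix},
\quad
X_{n+1} = \begin{pmatrix} X_n & 0 \\ X_n & X_n \end{pmatrix}.
$$

* **Background-averaged**: $\Omega = V H$, a weighted Walsh–Hadamard
  transform. Each order-$o$ term is the average, over all $2^{N-o}$
  backgrounds, of the corresponding nested difference of phenotypes; the
  order-0 term is the mean phenotype.
* **Single-reference**: $\Omega = V X^{T} H$, which reduces to the boolean
  finite-difference (Möbius) transform: a local Taylor-like expansion
  around one reference genotype, whose order-0 term is the reference
  phenotype. Non-zero references are handled by XOR relabeling
  (`rereference()`) rather than by rebuilding the operator — one operator,
  one testable permutation.

`build_operator()` materialises the dense matrices (validation, small
$N$); `epistasis_transform()` evaluates both forms with $O(N 2^N)$
butterfly passes and is the production path. The inverses are analytic:
$\Omega^{-1} = H V^{-1} / 2^N$ for the averaged form and the subset-sum
(zeta) transform for the single-reference form — no numerical inversion
anywhere. The dense and butterfly routes agree to $10^{-10}$ relative
error in the tests, and the butterfly transform of an $N = 12$ landscape
runs in well under a second.

Because the columns of $\Omega^{-1}$ (averaged form) are mutually
orthogonal, each term $i$ owns an exact, additive share
$c_i = \omega_i^2\,2^{N - 2\,\mathrm{order}(i)}$ of the reconstruction
SSE. `rank_terms()` orders terms by $c_i$; the $R^2$ of reconstructing
from the top $k$ terms is then provably non-decreasing in $k$. The
source material ranks terms "by degree of contribution" without defining
the metric; this orthogonal decomposition is exact for nested
reconstructions, though it need not replicate the original figure's exact
ordering. Ties (rare in real data) break by ascending order then index.

Goodness of fit is $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ (negative when a
reconstruction is worse than the mean) and goodness of prediction
$\mathrm{GoP} = 1/(1 + \mathrm{SSE}/\mathrm{SST}) \in (0, 1]$.

```{r transform-demo}
sim <- simulate_sparse_landscape(synthetic_spec(6, 8, seed = 1))
spec <- epistasis_transform(sim$landscape)
top <- rank_terms(spec)[1:8]
goodness_of_fit(sim$landscape, reconstruct(spec, keep = c(0, top)))
```

## Significance of interaction terms

Per-variant measurement SDs propagate linearly:
$\mathrm{sd}(\omega_i) = \bigl(\sum_j \Omega_{ij}^2 \sigma_j^2\bigr)^{1/2}$.
Both forms admit closed forms (averaged rows have constant magnitude
$(1/2)^{N-o}$, giving the homoscedastic law
$\sigma\,2^{o - N/2}$; single-reference rows are $\pm 1$ on subsets), so
no operator is materialised. Terms are tested with two-sided normal-theory
p-values at a raw threshold $P < 0.01$ by default — deliberately with no
multiple-testing correction, which mirrors the published procedure;
Benjamini–Hochberg is available but off by default. The order-0 term is
never tested (it is the mean or reference, not an interaction), and a term
with zero propagated SD but nonzero value is flagged trivially
significant. The exact published error model lives in supplementary
material that is not reproduced here; linear propagation with normal
theory is the documented stand-in, and its calibration is itself tested:
over 200 null landscapes the selected fraction matches the nominal 0.01
within three binomial standard deviations, and planted terms at
$|\omega|/\mathrm{sd} = 5$ are recovered at $\ge 99\%$ power.

## Sparse recovery from subsampled phenotypes

Interaction spectra of real proteins are sparse, so the spectrum can be
estimated from a random subsample of phenotypes by basis-pursuit
denoising: minimise $\lVert\omega\rVert_1$ subject to
$\lVert A\omega - y_{\mathrm{obs}}\rVert_2 \le \varepsilon$, where $A$
holds the sampled rows of $\Omega^{-1}$. Implementation choices that
matter:

* The order-0 column of $A$ is constant; its coefficient is the mean
  phenotype, not an interaction, and is fitted as an unpenalised
  intercept. Penalising it distorts the entire regularisation path when
  phenotypes have a non-zero baseline.
* Interaction columns are normalised to unit norm before the L1 step
  (raw norms scale as $2^{-o}$ and would bias selection by order), then
  the scaling is undone. The raw-basis mode is available
  (`normalize_columns = FALSE`) because whether the original analysis
  normalised is not stated.
* The L1 problem is solved on the lasso path (`glmnet`), taking the
  most-penalised solution whose residual meets $\varepsilon$ — the
  path-equivalence of the lasso and the $\varepsilon$-constrained
  basis-pursuit formulations. With per-variant noise SD $s$ known,
  $\varepsilon = s\sqrt{m}$ is the natural bound; without it, the penalty
  is chosen by 5-fold cross-validation on the held-in samples.
* The selected support is debiased by a least-squares refit (relaxed
  lasso), optionally followed by backward elimination of support terms
  with refit $|t| <$ `t_prune` — the guard against the small spurious
  coefficients the lasso keeps near its residual bound. A fully
  determined noiseless system bypasses the solver and returns the exact
  transform.

In the reference recovery regime ($N = 10$, 20 planted fixed-magnitude
terms over orders 1–5, signal-to-noise 20, 15% sampling), median support
precision and recall reach at least 0.9 and median held-out GoP at least
0.95 over 20 seeded designs. Support metrics are assessed on
fixed-magnitude spectra because recovering terms whose magnitude tends to
zero is ill-posed by definition; prediction (GoP) metrics do not depend on
that choice.

## Epistasis from alignment statistics

Selecting the genotypes with $y >$ threshold (strict, matching the
published $y > 0.73$ criterion) yields a "functional alignment" over a
two-letter alphabet, encoded $+1$ for allele 0 and $-1$ for allele 1.
With $\varphi_i$ the column means and $\varphi_{ij}$ the pair expectations
over the $n_{\mathrm{func}}$ functional rows,

$$
\omega_i^{\mathrm{aln}} = \varphi_i \frac{2\,N^{\mathrm{func}}_{\mathrm{tot}}}{N_{\mathrm{tot}}},
\qquad
\omega_{ij}^{\mathrm{aln}} = \varphi_{ij} \frac{4\,N^{\mathrm{func}}_{\mathrm{tot}}}{N_{\mathrm{tot}}}.
$$

With the $-1$ encoding on allele 1, the raw character-basis coefficients
differ from the $V$-weighted transform terms by $(-1)^{\mathrm{order}}$;
the estimators apply that factor by default (`adjust_sign = TRUE`) so that
— exactly, not asymptotically — they equal the order-1 and order-2
background-averaged terms of the selection indicator
$F(g) = \mathbf{1}\{y(g) > \mathrm{threshold}\}$. That identity is the
module's central test, and the raw values remain available because the
original figure's axis convention is not printed. Subsampling rows scales
$N_{\mathrm{tot}}$ to preserve the functional fraction, which keeps the
estimators unbiased while their SD shrinks as $\sim 1/\sqrt{n}$.

## Functional trajectories and connectivity

Genotypes above threshold, linked by single mutations, form the
functional network. The $(i,j)$ element of the $m$-th power of its
adjacency matrix counts functional $m$-step trajectories; the package
propagates an indicator vector $m$ times through the edge set instead of
powering an $8192^2$ matrix. Counts are kept in double precision, which
is exact for integers below $2^{53}$ — far above the $13! \approx 6.2
\times 10^9$ direct-path scale of a full 13-cube (verified against the
closed form). Trajectories of length $m$ are walks (revisits allowed),
exactly as the matrix-power definition implies; for antipodal endpoints
with $m = N$ they coincide with direct paths. `step_connectivity()`
reports, per mutational layer $k$, the fraction of all
$\binom{N}{k}$ genotypes (functional or not — the denominator choice is
an interpretation, flagged as such) lying on at least one functional
direct path, computed by two directional dynamic-programming passes and
verified against exhaustive path enumeration for $N \le 6$.
`classify_pairwise()` types each $2\times2$ sub-square as no, magnitude,
sign, or reciprocal-sign epistasis with a $10^{-9}$ comparison tolerance;
because the published severity statistic's aggregation is not stated,
both per-background fractions and the per-pair modal class are reported.

## FACS-seq preprocessing

Barcode counts become phenotypes through the published chain:

1. **Pooled enrichment** $E_a = \sum_k N^{\mathrm{out}}_{a,k} / \sum_k
   N^{\mathrm{in}}_{a,k}$ over uniqueness barcodes. The printed formula is
   typographically ambiguous (sum of ratios vs ratio of sums); the pooled
   ratio is the default because the Z-score model treats $E_a$ as a common
   rate applied to each barcode's input, and the sum-of-ratios reading is
   available behind a flag.
2. **Outlier rejection**: per barcode
   $Z = (N^{\mathrm{out}} - E_a N^{\mathrm{in}}) /
   (E_a N^{\mathrm{in}})^{1/\beta}$ with $\beta = 1/0.35$; reject outside
   the asymmetric window $(-c_2, c_1) = (-15, 35)$, recompute, repeat for
   three rounds. The printed description of the boundaries is circular;
   the window-on-$Z$ reading is the implemented interpretation. Within a
   round the upper bound is applied before the lower with enrichments
   recomputed in between — a gross over-counting outlier inflates $E_a$,
   and judging the remaining barcodes against the corrupted rate would
   cascade into wholesale rejection — and a group's last barcode is never
   rejected.
3. **Channel normalisation** to the parental brightness ratio
   $(25.0{\times}10^3 / 32.4{\times}10^3) \times 0.222$; note the rounded
   printed factors multiply to 0.171, one unit in the last digit from the
   printed 0.172. Rescaling is one positive factor, so within-channel
   ranks never change.
4. **Quadratic combination**
   $x_a = \sqrt{E_{a,\mathrm{blue}}^2 + E_{a,\mathrm{red}}^2}$.
5. **Linearisation**: the exponent $\alpha$ of $y = x^\alpha$ minimises
   $\lVert f(x) - \Omega^{-1} S\, \Omega f(x)\rVert^2 / \mathrm{var}(f(x))$
   with $S$ the order-$\le 2$ selector (golden-section search on
   $[0.05, 2]$, tolerance $10^{-4}$); global assay nonlinearities curve
   every variant alike, whereas true epistasis is variant-specific.
6. **Detection-floor pseudocounts**: deterministic clamping at the floor
   (default: the 95th percentile of the null-class values) — the exact
   published pseudocount scheme is not printed, and a deterministic clamp
   keeps runs reproducible.

No attempt is made to anchor the absolute phenotype scale to specific
published values (0.73/0.85): the printed constants do not determine the
anchoring, so the scale is relative to the parental calibration. The
segment-barcode parity check (three bases plus their sum modulo four)
uses the alphabetical base map A=0, C=1, G=2, T=3 — the map itself is not
printed and is configurable; parity detects every single-base error.

## The synthetic-data generators

Three generators provide ground truth for every stage; their defaults are
the study conditions, chosen once:

* `simulate_sparse_landscape()`: $K$ distinct nonzero terms drawn with
  order probabilities following a discretised unimodal curve peaking at
  order 3–4 (the shape of empirically observed interaction spectra,
  without copying any published counts), magnitudes fixed, normal, or
  Laplace, inverted to phenotypes with additive Gaussian noise. The
  noiseless transform of the output is the planted spectrum exactly.
* `simulate_counts_experiment()`: 20 uniqueness barcodes per allele,
  $10^6$ input reads per channel, a top-1% sorter gate over per-cell
  log-normal fluorescence (sdlog 0.5), Poisson output counts, and planted
  outlier barcodes whose expected output is multiplied by 100 — planted
  only in an allele's active channel, where reads exist to corrupt. The
  blue/red channel split keys on a designated chromophore bit plus
  optional co-required bits; this mixing rule is a fixture convention,
  not a biological claim. The end-to-end check runs brightnesses spanning
  [0.3, 1] — the gated assay's informative range — with the parents at
  the bright end as the calibration anchors of their channels, as in the
  real system; outside that range a top-percentile gate simply yields no
  output reads, which is the real assay's detection floor, not a failure
  of the chain.
* `simulate_two_parent_landscape()`: both antipodal parents functional,
  interior genotypes pruned with probability $\propto$ ruggedness
  $\times$ a mid-cube-peaked layer weight, producing the dumbbell shapes
  relevant to connectivity analysis; an optional guard keeps one direct
  path alive.

What these generators do *not* emulate: chromophore photochemistry and
maturation kinetics, sequencing error beyond Poisson counting noise,
read-level artefacts (the package starts from error-corrected counts),
and any fitting of generator parameters to the deposited reads. Passing
tests therefore demonstrate the correctness and calibration of the
analysis chain under its own assumptions, not the reproduction of the
original experiment's headline numbers, which require the deposited raw
data.

## Numerical choices and problem sizes

All operator weights are dyadic rationals, exact in binary floating
point; transforms round-trip to $\sim 10^{-15}$. The test-suite and
acceptance workloads use $N = 5$–10 for simulation studies (200 null
landscapes for type-I calibration, 20 seeded designs for recovery and
topology sweeps, 10 for exponent recovery) and $N = 13$ only for the
closed-form checks (space size, path count) — sizes at which every
property is verifiable against brute-force oracles in seconds while
exercising the same code paths as a full 13-position analysis.

## Known limitations

Only biallelic positions are supported (no multi-allelic sites, indels,
or full amino-acid alphabets); alignment-based estimation stops at order
2 (orders $\ge 3$ are not defined by the published formulas); walk counts
above $2^{53}$ would lose exactness (unreachable at supported sizes);
and the preprocessing chain's absolute scale is relative to the parental
calibration rather than anchored to any published phenotype value.
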