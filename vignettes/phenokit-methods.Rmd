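---
title: "phenokit: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenokit: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific and numerical decisions behind
`phenokit`: what each stage assumes, which tunable parameters matter and
why their defaults are what they are, what the synthetic-data world does
and does not emulate, and where the package's guarantees end. It states
no empirical result that the test suite does not itself compute.

# Plant imaging

## Segmentation

Side-view scenes are assumed to show green vegetation on a roughly
uniform, non-green background (an imaging cabinet, not a field). The
foreground score is the excess-green index ExG = 2G − R − B, which is
insensitive to achromatic brightness changes; it is quantized to 256
bins and thresholded by Otsu's criterion (a fixed ExG threshold is
available for cabinets with known illumination). Connected components
smaller than `min_object_px` (default 64 px) are discarded as debris.
Holes inside retained components are deliberately kept open: the
projected area *A* is the count of plant pixels, not of the filled
silhouette. A scene with no greenness contrast at all is an error ("no
plant found") rather than an empty mask, since every downstream
descriptor needs a nonempty foreground.

One practical bin-boundary rule is worth recording: Otsu returns a bin
index, so the comparison is made on the *quantized* values. Comparing
raw continuous intensities against a bin index silently shifts the
class boundary by up to one bin width (this was a real bug caught by the
renderer's exact truth).

## The 33-feature catalogue

Each view yields projected area + 25 morphological + 7 texture
descriptors. The catalogue is a frozen, versioned contract
(`feature_catalogue()`); the identities of the morphological and texture
sets are this package's own documented choice of standard shape and
Haralick-style statistics, anchored by the traits the domain names
explicitly (plant height, plant width, plant compactness).

Conventions that define the numbers:

* Pixels are unit squares; row 0 is the image top. The *corner-point
  convex hull* of a w×h rectangle has continuous area exactly w·h.
* **Compactness** = A / (number of pixel centres inside-or-on the convex
  hull of the pixel centres). This is the rasterized-hull ratio: it
  equals 1 exactly iff the mask equals its own rasterized hull, which
  holds for every digitally convex region — rectangles and rasterized
  discs alike. It measures how densely the shoot fills its outline
  (more upright, more compact plants score higher).
* **Solidity** = A / continuous corner-hull area. On smooth shapes it
  sits slightly below compactness (a disc of radius 50 px scores
  ≈ 0.98) because the corner hull bulges half a pixel beyond the
  region. Keeping both exposes the rasterization convention instead of
  hiding it.
* **Perimeter** uses the 4-direction Crofton configuration-weight
  estimator, accurate to well under 1% on discs (r = 50 gives 315.26 vs
  2π·50 = 314.16); a naive edge-count perimeter would bias circularity
  4πA/P² down to ≈ 0.6 on a perfect disc.
* Axis lengths, orientation and eccentricity come from second central
  moments of the pixel centres (major = 4√λ₁, as in standard
  regionprops); the skeleton is Zhang–Suen thinning, with length summed
  over 4-adjacent (1) and diagonal (√2) skeleton pairs and branch
  points defined as skeleton pixels with ≥ 3 skeleton neighbours.
* Texture is computed on the channel-mean grey image, quantized to
  `levels` = 32 grey levels *within the mask*, with symmetric,
  normalized co-occurrence matrices at distance 1 averaged over the four
  directions (offsets configurable). A constant region therefore gives
  contrast = 0, entropy = 0, energy = 1 exactly.

Views are aggregated per plant by the arithmetic mean (max available);
the facility protocol that motivates this takes 12 rotated side views,
and the mean is the natural estimator of a rotation-averaged descriptor.

# Grain scoring

The scorer mirrors a two-conveyor design: software receives one image of
all spikelets and one of the filled spikelets (the unfilled ones having
been blown away by hardware), plus the weighed filled-grain mass. The
package never classifies filled vs unfilled photometrically.

Segmentation is Otsu on a bright-on-dark scene with a debris filter
(`min_area_px`, default 40). A scene whose grey dynamic range is below
`min_contrast` (default 50 of 255) is declared empty rather than
letting Otsu split background noise into spurious "grains". Components
larger than `split_factor` (default 1.6) times the median accepted area
are re-split by a watershed on the Euclidean distance transform, seeded
at distance maxima merged within ~0.9·√(median area/π); the line-scan
feeder spaces grains, so splitting is best-effort and is validated at a
10% touching-pair rate.

Grain length/width are the sides of the minimum-area rotated bounding
rectangle. The extent along each rectangle axis is the pixel-centre
projection span **plus half the observed lattice gap at each extreme,
capped at half a pixel**. Rationale: for grid-aligned sides the gap is
exactly one pixel, recovering the exact w and h of rectangles; for
oblique sides the staircase extremes already hug the continuous
boundary, and adding a full pixel (the naive convention) inflates the
short side of a 24-px-wide grain by 3–5% depending on angle. The
gap-corrected span keeps rotation bias ≤ 2% on a 60×24 px ellipse, which
is the scale of real rice grains at ~0.1 mm/px. This convention is the
package's own; it is exact on rectangles and is frozen by tests.

Yield arithmetic: fertility = filled/total (flagged undefined at
total = 0), yield per plant = filled mass, thousand-grain weight =
1000·mass/filled (flagged undefined at filled = 0); the identity
TGW·filled/1000 = mass is exact by construction.

# Trait prediction models

The feature grouping defines four candidate families: A, AM, AT, ATM
(area alone, plus one morphological, one texture, or one of each).
All-subsets search enumerates every candidate in a family — the pools
are small by design, so enumeration is exact, not heuristic.

Scoring and selection:

* **PRESS** is the primary ranking criterion because the models are
  built to *predict* destructive measurements; it is computed from
  leverages, Σ(eᵢ/(1−hᵢᵢ))², which equals the explicit leave-one-out
  refit sum algebraically (asserted to 1e-8 relative on random problems).
  A leverage of 1 (exactly interpolated point) is an error, not a
  silent Inf.
* **AIC** uses the Gaussian profile-likelihood convention
  n·ln(RSS/n) + 2(p+2), counting slopes, intercept and error variance;
  only differences matter and the constant is documented.
* "Noticeably better" is quantified: a larger family replaces the
  incumbent only with ≥ 5% relative PRESS reduction **and** ≥ 0.01
  adjusted-R² gain, following the partial order A ≺ {AM, AT} ≺ ATM with
  ties favouring the smaller family. The margins are configurable; the
  defaults are chosen so that, at n = 200 and signal R² ≈ 0.9, the
  generating family is recovered in ≥ 90% of simulations (this is a
  tested property, not an assumption).
* Responses are modelled on the identity scale; trait values must be
  positive because MAPE divides by the truth.

Evaluation is a seeded 50/50 train/test split (floor on odd n) with
test R² (allowed negative out of sample) and MAPE, plus k-fold
cross-validation (default k = 10) with pooled out-of-fold predictions —
at k = n and an intercept-only model the pooled SSE reproduces PRESS
exactly, which the tests assert.

# Mixed-model association chain

The scan follows the classic exact-LMM factorization. With kinship K
eigendecomposed once (K = U S Uᵀ), the model
y = μ + xβ + g + ε, g ~ N(0, σg²K), ε ~ N(0, σe²I)
becomes weighted least squares in the rotated coordinates with weights
1/(sᵢ + δ), δ = σe²/σg². δ is estimated by maximum likelihood under the
no-SNP null on a 100-point log₁₀ grid over [−5, 5] plus Brent
refinement, and held fixed per SNP (the EMMAX-style approximation);
`per_snp_delta` re-optimizes per SNP exactly. ML (not REML) is used
throughout so the likelihood-ratio statistic 2(ℓ₁ − ℓ₀) ~ χ²₁ is valid;
under fixed δ it reduces to n·ln(RSS₀/RSS₁) in the weighted space.
Missing dosages are mean-imputed in the design column only; monomorphic
SNPs report `p = NA`.

Supporting pieces:

* **Kinship** is the identity-genotype proportion over an evenly spaced
  SNP subset with a seeded random phase (emulating "evenly distributed
  random SNPs"). Identity proportions need not be PSD once pairwise
  denominators differ, so the matrix is repaired by eigenvalue clipping
  at 0 and rescaling to unit diagonal; the raw matrix is retained and
  the repair warns.
* **Effective marker number** N is a block-wise eigenvalue estimator:
  per chromosome, consecutive blocks of ≤ 200 SNPs contribute
  Σ I(λ≥1) + (λ − ⌊λ⌋) over the eigenvalues of the block correlation
  matrix. Exactly orthogonal SNPs give N = m; k identical columns give
  1. This is a documented stand-in for an external tool whose internals
  are not public; the 1/N (suggestive) and 0.05/N (significant)
  threshold logic on top of it is exact, with significant = α·suggestive
  by construction.
* **LD r²** uses haplotype frequencies, treating homozygous calls of an
  inbred panel as observed haplotypes and excluding heterozygous or
  missing calls pairwise; on fully homozygous data it equals the squared
  Pearson correlation of dosages (tested algebraically). **Clumping** is
  greedy: smallest-p unassigned SNP leads, passing SNPs within ±250 kb
  and r² > 0.25 join, repeat. The optional **peak filter** (off by
  default) keeps loci with ≥ 2 supporting SNPs below 100× the lead
  threshold inside the window — a configurable proxy for "clear
  peak-like signal", which no main text defines precisely.
* **Phenotype cleaning** is a single-pass mean ± 3 SD rule with the
  dropped accessions recorded; SD = 0 returns the input unchanged.

# The synthetic world

Every test input is generated in code from a seed; generators are pure
functions of (parameters, seed) and record their truth at draw time
(masks at rendering, never re-segmented).

* **Plants**: a 3-px stem plus arcing leaf strokes in green hues with
  mild jitter on a near-white background. This exercises the
  segmentation and descriptor contracts (exact area/height truth,
  overlap accounting); it does not emulate panicles, pots, soil, wind
  or specular highlights.
* **Grains**: rejection-sampled rotated ellipses (semi-axes 26–34 ×
  10–13 px by default, grain-like at 0.1 mm/px), bright on dark, with a
  stated fraction placed as edge-adjacent touching pairs; isolated
  grains keep a 1-px clearance ring, so non-touching scenes are exactly
  countable. No husk texture, no overlapping (stacked) grains.
* **Genotypes**: inbred (dosages {0,2}; optional het_rate), ancestral
  allele frequencies U(0.05, 0.5), subpopulation frequencies by the
  Balding–Nichols Beta construction at the stated Fst, and a first-order
  copying chain giving adjacent-SNP correlation ≈ ld_rho (restarted at
  chromosome boundaries; verified: mean adjacent r = 0.898 at target
  0.9). The structured-null world used in the acceptance tests is
  n = 400, m = 5000, 2 subpopulations, Fst 0.1, polygenic h² = 0.4 and
  **ld_rho = 0.9 at 1 kb spacing**. The LD level is the one genuinely
  open parameter: cultivated-rice panels show LD decaying over ~100 kb,
  so adjacent resequencing SNPs are strongly correlated, and it is
  exactly this blockiness that makes an uncorrected scan inflate
  (λ_GC ≈ 1.35 here) while the kinship-corrected scan stays calibrated;
  with independent SNPs the uncorrected scan barely inflates and the
  correction would be demonstrated against a strawman.
* **Phenotypes**: y = causal + polygenic + noise with the components
  rescaled to the stated sample-variance fractions (total variance 1);
  the polygenic term is built from genome-wide small effects on the
  same SNPs, so kinship estimated from those SNPs is internally
  consistent. The realized per-SNP effect after scaling is recorded as
  the β truth that effect-recovery tests compare against.

What a green test establishes: the operators implement their stated
mathematics on well-posed inputs at the stated tolerances. What it does
not establish: robustness to field imagery, lighting drift, occlusion
by pots, awned or touching-and-overlapping grains, genotyping error, or
panels whose structure is not two clean subpopulations.

# Numerical choices and degenerate inputs

* Ties in the all-subsets ranking break by AIC, then lexicographic
  predictor names; selection ties keep the smaller family (AM before AT
  on exact ties).
* RSS = 0 maps AIC to a −Inf sentinel with a perfect-fit flag; constant
  responses give r² = 0 with a warning; rank-deficient designs are
  errors.
* Single-pixel masks are flagged degenerate with ratio conventions
  (compactness 1, axes 1); regions under 4 px refuse shape metrics.
* Type-I error at α = 1e-3 is a small-count binomial: the calibration
  test pools four seeded replicates (20,000 tests) so the stated band
  [5e-4, 2e-3] is checked on a stable estimate, and λ_GC bands on the
  replicate mean.
* All seeds are 32-bit integers; every public generator and stage takes
  one explicitly, and the pipeline's provenance file echoes the config
  and its hash beside every output bundle.

# Known limitations

* PNG/TIFF are not decodable with the available toolchain; images move
  through lossless ASCII PNM instead, with external conversion.
* The effective-marker estimator shares the spirit, not the
  implementation, of the published black-box tool; published threshold
  pairs from real panels are not reproducible without the panel.
* The watershed splitter handles pairs (and the tested 10% touching
  rate) well; clusters of 3+ mutually touching grains may undercount.
* `per_snp_delta` is a per-SNP optimization loop and is meant for
  refinement on candidate regions, not million-SNP scans.
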