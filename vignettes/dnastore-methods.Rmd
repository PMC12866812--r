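---
title: "Constrained DNA codecs and physics-based randomness assessment"
author: "dnastore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained DNA codecs and physics-based randomness assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnastore)
```

# The problem

Synthetic DNA is an attractive archival medium, but raw binary-to-base
mappings produce sequences that are hostile to synthesis and sequencing:
long homopolymer runs, skewed GC content and repetitive motifs cause
dropouts, uneven amplification and base-calling errors. The package
implements a family of *randomized design rules* that encode arbitrary
binary payloads under run-length constraints, together with three
physics-based models that *quantify* how random an encoded sequence
actually is. The models matter because "looks random" is not a design
criterion; a velocity fitted from a trajectory, a spin-coupling estimate,
or a logic-scan RMS is.

# The codec family

A rule `R_N-B#` is parameterised by the maximum homopolymer run length
`N` (unbounded, 2 or 1) and the numerical base `B` of the digit string.
Encoding proceeds in two stages:

1. **Radix conversion.** The payload bits are read as one big integer,
   most significant bit first, after prepending a guard 1-bit, and written
   in base B (`bitsToDigits()`). The guard preserves leading zeros and
   pins the digit count to the bit length: a 16384-bit payload always
   yields 4097 base-16 digits, 8193 base-4 digits, 4571 base-12 digits,
   5169 base-9 digits, 10338 base-3 digits.
2. **Context-dependent emission.** Starting from an arbitrary initiator
   unit (`AT` for dimer rules, `A` for monomer rules), each digit selects
   one encoding unit from the bijection attached to the current *context*,
   the last emitted base. The allowed unit sets enforce the run limit
   structurally: B16 uses all 16 dimers, B12 the 12 heterodimers (runs can
   only reach length 2 at unit junctions), B9 the 9 heterodimers that do
   not start with the context base (no run can exceed 1), B4 all 4
   monomers, B3 the 3 monomers differing from the context.

With a 57-nt payload per strand, encoded sequences are split into
106-nt strands (20-nt forward primer, 8-nt index, payload, 21-nt reverse
primer) by `assembleStrands()`. The index region is the 16-bit big-endian
chunk ordinal passed through the positional 2-bit map; the layout itself
fixes no index encoding, so this is the package's own (documented)
convention.

## Why the shipped digit-to-unit bijections are scrambled

For the power-of-two radices, base conversion is mere bit regrouping: a
base-16 digit is a nibble, a base-4 digit a bit pair. If digits were
assigned to units in lexicographic order, a constant bit region would map
to a repeated unit (`1111...` to `TT TT ...`), and the "randomized" rule
would inherit all of the payload's structure — indistinguishable from
simple mapping. The shipped tables therefore use fixed scrambled
bijections, drawn once at random within each rule's allowed-unit
constraints and frozen in the source. The `RInf-B4` table additionally
honours the five published example assignments (after `A`: digit 3 to
`C`; after `C`: 1 to `G`, 2 to `C`; after `G`: 3 to `T`; after `T`: 0 to
`G`) and fills the remaining cells so constant-digit runs trace cycles
over the bases (digit 0: `A`-`G`-`C`, digit 3: `A`-`C`-`T`, digit 1 the
full 4-cycle `A`-`T`-`C`-`G`); this reproduces the characteristic
rotational signature of base-4 encodings on constant bit regions. Digit 2
maps every context to itself — some residue of payload structure is
unavoidable for an unconstrained 4-unit rule, and alternating-bit regions
are the rarest pattern in bilevel images. Users needing agreement with an
externally published table can load it bit-exactly through
`buildRuleTable(rows = ...)` or `readRuleTableJSON()`.

```{r}
buildRuleTable("RInf-B4")
```

For genuinely non-power-of-two radices (9, 12, 3) the carry propagation
of the base conversion already mixes payload structure thoroughly; the
scrambled tables there are a uniformity choice, not a necessity.

# Translational trajectory model

Each base is a unit step in the plane — `A = (L, 0)`, `C = (0, L)`,
`G = (-L, 0)`, `T = (0, -L)` — so a sequence is a lattice trajectory
(`trajectory2D()`). Homopolymer runs become ballistic flights; a
well-mixed sequence performs a random walk. `msdCurve()` slides 20-nt
displacement windows along the trajectory with 1-nt stride (19-nt
overlap) and averages the squared displacement from each window's own
origin; 8000 windows are used by default, so an 8020-nt sequence is fully
consumed. When one extra window would fit, the first 8000 are taken —
window bookkeeping is deliberately deterministic. The short-lag curve is
fitted (`fitTranslational()`) to

$$\langle (\Delta r)^2 \rangle = 4D\,\Delta n + V^2\,\Delta n^2,$$

with both coefficients constrained non-negative (non-negative least
squares via `pracma::lsqnonneg`), so `V = sqrt(quad)` is always real.
Ordinary least squares with clipping is available as `method = "ls"`;
on noisy near-degenerate curves NNLS is the safer default because the
unconstrained quadratic coefficient can go slightly negative. Fitted
units: V in L/nt, D in L²/nt. The closed forms pin the estimator:
a pure homopolymer gives MSD = Δn² and (V, D) = (1, 0); an ideal
diffusive curve MSD = Δn gives (0, 0.25).

# Rotational trajectory model

The four bases sit in antipodal pairs on the eight vertices of a cube:

| base | vertices |
|------|----------------------|
| A | (+1,+1,+1), (−1,−1,−1) |
| C | (−1,+1,+1), (+1,−1,−1) |
| G | (+1,−1,+1), (−1,+1,−1) |
| T | (+1,+1,−1), (−1,−1,+1) |

This is the unique antipodal labeling up to rotation: every vertex's
three edge-neighbours carry the three other bases, so each non-repeated
base has exactly one reachable vertex. The particle starts at the first
base's vertex in the upper plane; a repeated base leaves it stationary
(homopolymers freeze rotation), any other base moves it along one edge,
producing a signed angular displacement of ±π/2 about exactly two axes
(the angle between before/after positions projected on the plane
perpendicular to each axis). Axis naming is conventional: a 4-periodic
repeat such as `ATGC...` circulates around one face and accumulates angle
monotonically about that face's normal (the Y axis under this labeling);
which axis a given repeat excites may be a permutation of other published
conventions, but all scalar summaries are rotation-invariant.
`msadCurves()` applies the same window scheme to the cumulative angles —
an n-nt sequence provides n−1 angular steps, so 8020 nt again gives
exactly 8000 windows — and `fitRotational()` fits per axis

$$\langle (\Delta\theta)^2 \rangle = 2D_R\,\Delta n + \omega^2\,\Delta n^2,$$

reporting per-axis components and Euclidean magnitudes
ω = (ω_X² + ω_Y² + ω_Z²)^½, D_R likewise.

The model is a deterministic sequence-to-trajectory map: there is no
thermal noise, no physical time, and units are lattice units per nt.

# Inverse-Ising factors

`toSpinMatrix()` converts a sequence to bits via the positional 2-bit
map, fills a 128 × 128 lattice row-major from the first 16384 bits
(an 8196-nt sequence yields 16392 bits; the trailing 8 are dropped), and
maps 1-bits to spin +1. `spinSums()` collects
$\sum_i \sigma_i$, the pair sum over unordered 4-connected
nearest-neighbour pairs, and the counts $N_T = NM$,
$N_n = (N-1)M + (M-1)N$, $N_t = 12(N-1)(M-1) - 4$. `isingParams()` then
computes, with $c = \sum \sigma_i\sigma_j / N_n$ the mean neighbour
correlation:

* **polarization factor** $\gamma = \sum_i \sigma_i / N_T$ — the exact
  magnetisation per node, in [−1, 1];
* **interaction factor**
  $\lambda = (c - \gamma^2) / (1 - \gamma^2)^2$ — the mean-field coupling
  estimate: the connected neighbour correlation normalised by the squared
  single-site variance. It is ≈ −1 for a checkerboard, 0 for an
  uncorrelated lattice, and grows without bound for clustered lattices;
* **bias factor**
  $h = \mathrm{atanh}(\gamma) - \bar z \lambda \gamma$, with
  $\bar z = 2N_n/N_T$ the mean coordination number — the mean-field local
  field consistent with the observed magnetisation and coupling, an
  increasing function of γ.

On the 2 × 2 configuration `[1,0;0,0]` these give γ = −0.5,
λ = −4/9 ≈ −0.444 (the denominator $(1-\gamma^2)^2 = 9/16$) and
h = −0.9938; the two lattice-dependent factors are pinned as regression
fixtures in the test suite. Comparative figures use |λ|, which is
insensitive to the sign convention of the coupling. On a fully polarised
lattice the coupling is undefined (`NaN`) and h is ±∞. A different
closed form can be injected through the `formula` argument without
touching the rest of the pipeline. $N_t$ is carried as printed-formula
bookkeeping and does not enter the default estimators.

# Logic-scan statistics

`logicStats()` scans the measurable region of an n × m binary matrix:
each horizontal 3-bit input `(r, c..c+2)` is paired with the output bit
below its centre, `(r+1, c+1)` — the geometry that makes the measurable
count come out to (n−1)(m−2), and the natural reading for matrices
generated by 3-input/1-output rules. Per input, α = N₀/(N₀+N₁) and
β = (N₀+N₁)/Σ(N₀+N₁); a perfectly random matrix has α = 0.5 (two
equiprobable outputs) and β = 0.125 (eight equiprobable inputs).
The RMS summaries are deviations *about those expectations*, since
"lower RMS = more random" is only coherent for a deviation measure;
inputs that never occur are excluded from RMS(α) (α undefined) but
included in RMS(β) (β = 0 is defined). The literal uncentred
$\sqrt{\mathrm{mean}(\alpha^2)}$ variant is available via
`centered = FALSE`. A matrix actually generated by a 3-input rule has
deterministic outputs, so every observed α is 0 or 1 and RMS(α) is
exactly 0.5 — the scan detects cellular-automaton structure at the
maximum of its scale.

# Synthetic fixtures

`ecaMatrix()` generates the binary test images: elementary cellular
automata in the Wolfram numbering with circular boundary (the boundary
condition is the package's choice; published pattern images do not state
one), first row either uniform random under the caller's seed or a single
centred 1. Rule 204 is the identity, rules 0/255 are constants, rule 182
produces the structured triangular patterns used as a worst case for
simple mapping. These fixtures emulate the *structured* end of real
payloads (large constant regions, self-similar texture). They do not
emulate photographic halftones, dithering, or compressed bitstreams —
passing the ordering tests on ECA fixtures shows the models separate
structured from randomized encodings, not that any particular real image
would produce the same numeric values.

# Problem sizes and determinism

The package's own reference analyses use 128 × 128-bit payloads
(16384 bits), 20-nt windows with 1-nt stride and 8000 windows, and a
128 × 128 spin lattice; the test suite exercises the full pipeline at
these sizes and the statistical concentration checks at 512 × 512.
Every pipeline stage is deterministic given the payload and settings;
randomness enters only through payload/first-row generation, which always
draws from R's RNG stream so a single `set.seed()` call fixes an entire
analysis.

# Known limitations

* The encoded-length overhead of the run-length-limited rules
  (~26% for R0-B9 versus simple mapping) is inherent to the radix
  reduction, not an implementation cost.
* `sequenceIdentity()` is positional by design (fixed strand layout);
  indels shift the frame and are counted as mismatches from the shift
  onward. Use an aligner upstream if indels matter.
* The identity metric is reported as the match percentage
  100 × matches / reference length. A literal reading of
  errors/length × 100 is an *error* rate; the match convention is used so
  that "95–98% identity" describes mostly-correct reads.
* Decoding is strict: a single corrupted unit aborts with a position
  rather than error-correcting. Error-correcting codes are out of scope.
* λ and h are mean-field estimators, not maximum-likelihood inverse-Ising
  solutions; they are comparative randomness scores, not fitted couplings
  of a generative model.
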