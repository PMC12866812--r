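# dnastore

Constrained DNA sequence codecs and physics-based randomness assessment
for DNA data storage.

DNA data storage needs sequences that synthesizers and sequencers can
handle: no long homopolymer runs, balanced GC content, no large repeated
motifs. `dnastore` is for people designing or evaluating binary-to-DNA
encodings. It provides

* the **R_N-B# codec family** — binary payloads are guarded with a
  leading 1-bit, converted to a base-B digit string as one big integer,
  and emitted as context-dependent monomer/dimer encoding units whose
  allowed sets structurally cap homopolymer runs at N nt
  (`RInf-B16`, `RInf-B4`, `R1-B12`, `R0-B9`, `R0-B3`, plus the positional
  2-bit `simple` mapping), with exact lossless decoding;
* **sequencing-ready strand assembly** — 106-nt strands with the fixed
  20-nt/8-nt-index/57-nt-payload/21-nt layout, plus a positional
  sequence-identity metric for reads;
* three **physics-based randomness models** applied to encoded sequences:
  * *translational active-particle trajectories*: bases are unit steps in
    the plane; sliding 20-nt windows give an MSD curve fitted to
    ⟨(Δr)²⟩ = 4D·Δn + V²·Δn², so velocity V exposes homopolymer bias and
    D quantifies diffusion;
  * *rotational trajectories*: bases sit antipodally on a cube's
    vertices; edge moves give per-axis MSAD curves fitted to
    ⟨(Δθ)²⟩ = 2D_R·Δn + ω²·Δn², with ω detecting periodic repeats;
  * *inverse-Ising factors* of the spin lattice built from the sequence:
    polarization γ = Σσᵢ/N_T, mean-field coupling
    λ = (c − γ²)/(1 − γ²)² and field h = atanh(γ) − z̄λγ;
  * a *3-input/1-output logic scan* with per-input zero-output ratios α,
    occurrence fractions β, and RMS deviations from the ideal 0.5/0.125;
* an **elementary-cellular-automaton fixture generator** (`ecaMatrix`)
  and PBM/PNG bitmap handling for test payloads.

## Worked example

Generate a structured 128 × 128 test image with logic rule 182, encode it
three ways, and score the encodings:

```r
library(dnastore)
set.seed(0)
img <- ecaMatrix(182, 128, 128)
report <- assessAll(img, schemes = c("simple", "RInf-B16", "R0-B9"))
report[, c("scheme", "length_nt", "density_bits_nt", "gc_ratio",
           "longest_homopolymer", "V", "D", "gamma", "lambda", "rms_alpha")]
#>     scheme length_nt density_bits_nt gc_ratio longest_homopolymer      V     D
#> 1   simple      8192            2.00    0.495                  13 0.3614 0.317
#> 2 RInf-B16      8196            2.00    0.478                  13 0.0888 0.232
#> 3    R0-B9     10340            1.58    0.504                   1 0.0000 0.137
#>     gamma   lambda rms_alpha
#> 1 0.47705 -0.39989    0.5000
#> 2 0.15173  0.04168    0.0881
#> 3 0.00464  0.00742    0.0124
```

Read the rows bottom-up: the run-length-limited `R0-B9` rule pays ~26%
sequence length (1.58 vs 2 bits/nt) and in exchange caps homopolymers at
1 nt, balances GC at 0.504, drives the trajectory velocity V to zero
(no ballistic bias), and leaves near-zero polarization and coupling in
the spin lattice. Simple mapping keeps maximum density but inherits every
pathology of the image: a 13-nt homopolymer, V = 0.36, strong spin
clustering (λ = −0.40), and a logic-scan RMS(α) pinned at 0.5 — the scan
recognises that the matrix is literally generated by a 3-input rule.

Encoding, strand assembly and decoding are exact inverses:

```r
seq <- encodeSequence(flattenBits(img), "R0-B9")   # 10340 nt
strands <- assembleStrands(as.character(seq), prefix = "R0-B9")
strands[1:2]
#> DNAStringSet object of length 2:
#>     width seq                                               names
#> [1]   106 ACACGACGCTCTTCCGATCTAAA...AGAGATCGGAAGAGCACACGTCT R0-B9_0
#> [2]   106 ACACGACGCTCTTCCGATCTAAA...CGAGATCGGAAGAGCACACGTCT R0-B9_1
identical(reshapeBits(decodeSequence(seq, "R0-B9"), 128, 128), img)
#> [1] TRUE
```

A thin command-line front end over the same functions ships in
`inst/cli/dnastore.R` (`encode`, `decode`, `strands`, `identity`,
`fixture`, `stats`, `assess`, `report`).

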