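# dualelastica

Grayscale image denoising, inpainting, and two-phase Chan–Vese
segmentation with an **Euler's elastica** regularizer, solved by a
primal–dual projection scheme — plus the dual total-variation baseline it
generalizes, synthetic phantoms, and PSNR/Dice evaluation. Intended for
image-analysis work (e.g. denoising and organ/lesion segmentation of CT
slices) where plain TV regularization leaves staircase artifacts or clips
smooth boundaries and corners.

## The method

TV restoration penalizes the length of level lines,
`γ ∫ |∇u|`. Euler's elastica also penalizes their bending:

    ∫ (a + b·κ(u)²) |∇u| dx,    κ(u) = ∇·(∇u/|∇u|),

which suppresses staircasing and preserves smooth boundaries, at the price
of a non-convex fourth-order term. Instead of the usual
augmented-Lagrangian splitting (eight auxiliary variables), the solvers
here use a saddle-point form with a single dual vector field `p`
constrained by a pointwise, curvature-dependent radius:

    min_u max_{|p| ≤ g}  η/2 ∫ (f−u)² + γ ∫ (∇·p) u,    g = a + b·κ(u)².

Each iteration is two elementary steps: the closed-form update
`u = f + γ∇·p` on known pixels (an explicit step where the inpainting mask
is 0), and one dual ascent `p ← p + t∇u` followed by the radial projection
onto `|p| ≤ g`. With `b = 0` this is exactly the dual (projection) TV
algorithm, available as `tv_restore()` — the test suite asserts
bit-identical iterates. Segmentation replaces the fidelity by the
Chan–Vese region field `Q = α₁(c₁−f)² − α₂(c₂−f)²` acting on a relaxed
indicator `u ∈ [0,1]`.

See the methods vignette (`vignettes/dual-elastica-methods.Rmd`) for the
discretization, parameter meanings, and design decisions.

## Worked example

```r
library(dualelastica)

# noisy clipped-triangle phantom, sigma = 15 on the [0, 255] scale
ph  <- make_phantom("triangle", size = c(128, 128))
f   <- add_gaussian_noise(ph$clean, sigma = 15, seed = 7)
res <- denoise(f)                       # (a, b, gamma, t) = (3, 1, 1, 0.0125)

res$trace$iterations                    # 92
res$stop_reason                         # "tolerance"
psnr(f, ph$clean)                       # 24.53 dB  (input)
psnr(res$u, ph$clean)                   # 31.58 dB  (restored)

# two-phase segmentation of a noisy scene
ph2  <- make_phantom("two_phase", size = c(128, 128))
fs   <- add_gaussian_noise(ph2$clean, sigma = 10, seed = 5)
sres <- segment(fs)                     # (a, b, gamma, t) = (0.001, 5, 2, 0.0125)

sres$state$c1; sres$state$c2            # 199.67, 50.01  (true: 200, 50)
dice(sres$mask, ph2$mask)               # 1
```

The denoiser raises PSNR by ~7 dB and stops via the relative-energy
criterion (tolerance 0.001) well inside its 500-iteration cap; the
segmenter recovers the two region means to a fraction of a gray level and
the foreground mask exactly on this phantom.

The same solvers are scriptable from a shell:

```sh
exec/dualelastica make-fixture --output /tmp/fix --kind disk --noise-sigma 10
exec/dualelastica denoise --input /tmp/fix.png --output /tmp/out.png
exec/dualelastica evaluate --result /tmp/out.png --reference /tmp/fix_clean.png
```

Subcommands: `denoise`, `inpaint` (needs `--mask`, 0 = damaged), `segment`
(`--init circle:CX,CY,R`), `make-fixture`, `evaluate`. Every run writes a
per-iteration energy trace CSV and the effective configuration next to its
output.

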