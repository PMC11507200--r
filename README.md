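# histoscar

Color-based detection, isolation and quantification of myocardial infarct
in stained histological sections.

## The problem

After an experimental myocardial infarction (cryoinjury or
ischemia/reperfusion in mouse), the standard readout is the infarct size
measured on stained serial sections. Infarcted and viable myocardium take
different colors under the common stains, but the measurement is usually
done by hand-tracing the scar, which is slow and operator-dependent.
`histoscar` implements a per-pixel RGB rule for each of four staining
techniques, plus the surrounding workflow: splitting multi-section slide
scans, cleaning up binary masks, converting pixel counts into physical
areas and serial-section volumes, and quantifying diffuse fibrosis. It is
aimed at labs that scan stained sections and want a scriptable,
reproducible alternative to manual tracing.

## The classification rules

All rules operate on raw 8-bit R, G, B values inside a tissue mask
(non-near-white pixels), with thresholds pre-set per stain and adjustable
by the user:

- **MTS** (Masson's trichrome; scar blue, muscle red): infarct iff
  `R ≤ r_limit` and `B/R ≥ br_ratio_min` (R = 0 counts as infinitely
  blue). Defaults `r_limit = 150`, `br_ratio_min = 1.2`.
- **TTC** (viable tissue deep red, infarct off-white): infarct iff the
  sample standard deviation of the three channel values is `≤ std_max`
  (default 20) — the off-white infarct has nearly equal channels.
- **PSR** (picrosirius red; collagen saturated red, normal pale): with
  `mean_GB = (G + B)/2`, infarct iff `R − mean_GB ≥ thd` (default 40).
- **H&E**: a two-step transform reveals the infarct's elevated green —
  step 1 zeroes R where `R > r_limit` (default 200); step 2 keeps only
  green where green dominates. The binary mask then keeps only large,
  dense green components (morphological closing + a minimum-area floor),
  rejecting the sparse green speckle of normal tissue.

Quantities derived from the masks: relative infarct size
`100 · ΣP_s / ΣP_t` (%), physical area `Px² · ΣP` (mm²), and
serial-section volumes `V_si = A_si·h1`, `V_rsi = A_si·h2` summed over
sections, where `h1` is the stained-section thickness and `h2` the
removed-tissue thickness between sections.

## Worked example

Everything is testable without data: the package ships a synthetic
generator that paints sections in each stain's characteristic palette with
exact ground-truth masks.

```r
library(histoscar)

fx <- make_section("mts", seed = 42)        # synthetic MTS section, noise sd 8
a  <- analyze_section(fx$image, "mts", pixel_size = 5)
a
#> Stained-section infarct analysis (MTS)
#>   tissue pixels:  21887
#>   infarct pixels: 3893
#>   relative infarct size: 17.8%
#>   infarct area: 0.097 mm^2, section area: 0.547 mm^2 (Px = 5 um)
```

The generator painted 3893 of 21887 tissue pixels as infarct (17.79 %), so
the analysis recovered the ground-truth fraction to within 0.01 points
despite the pixel noise. Diffuse fibrosis on an MTS section uses the same
color rule without minimum-component filtering:

```r
r <- fibrosis_pct(make_section("mts", diffuse_frac = 0.097, seed = 42)$image)
r
#> Diffuse fibrosis: 9.7% of the tissue section (2123 / 21888 pixels)
```

Serial-section volume from per-heart totals (one 1 mm slab at Px = 1 µm
carrying 11.15·10⁶ infarct and 134.37·10⁶ tissue pixels, i.e. volumes of
11.15 and 134.37 mm³):

```r
m <- section_measurement(11.15e6, 134.37e6, pixel_size = 1)
stack_volumes(volume_stack(list(m), h1 = 1000, h2 = 0))
#> Serial-section volume summary (1 sections, h1 = 1000 um, h2 = 0 um, gaps: per-section)
#>   infarct volume V_Ts: 11.15 mm^3
#>   tissue  volume V_Tt: 134.37 mm^3
#>   relative infarct volume: 8.3%
```

The same operations are available from a shell via the installed
`exec/histoscar` script (`split`, `analyze`, `volume`, `fibrosis`,
`make-fixture` subcommands); every analysis writes a RunRecord JSON with
the command line, thresholds, input hashes and pixel counts, so any result
can be re-derived exactly.

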