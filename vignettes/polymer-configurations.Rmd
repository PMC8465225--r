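---
title: "Modeling small-polyelectrolyte configurations in crowded fluids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling small-polyelectrolyte configurations in crowded fluids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyfluid)
```

## The model

Short polyelectrolytes — the motivating case is an ssDNA homopolymer of
thymines ("pT", tens of nucleotides) — live in fluids crowded by much larger
non-ionic polymers such as PEG. Their size and shape are set by the
competition of two effective forces: a short-range *stretching* force $F_1$
(electrostatic repulsion between the charged backbone monomers, plus steric
and exclusion effects), and a medium/long-range *compressing* force $F_2$
(entropic: depletion, packing and osmotic pressure from the crowders).
`polyfluid` implements the desk-scale machinery of this picture: scaling
laws, an effective potential, idealized coordinate-level configurations, the
wormlike-chain model, and conversions among the three standard size
measurements ($R_g$, $R_h$, $R_{e\text{-}e}$).

## Salt-dependent scaling law

The dilute radius of gyration follows $R_g = A_0(s)\,N^{\nu(s)}$, with both
the effective monomer length $A_0$ (Å) and the stiffness exponent $\nu$
interpolated linearly in $y = \log_{10}(s/1\,\mathrm{mM})$:

$$A_0 = \tfrac{11}{4} + \tfrac{y}{4}, \qquad \nu = 0.794 - 0.0674\,y .$$

The mM convention for $y$ is the only one that reproduces the reference
parameter grid ($y = 0$ at 1 mM, $y = 3$ at 1 M). Salt screens the backbone
charges, so $\nu$ falls from 0.794 (stiff, nearly rod-like) at 1 mM toward
0.52 at 10 M. Outside the calibrated window the interpolation is still
evaluated but clamped to the physical extremes $[1/3, 1]$ (globule to rigid
rope), with a warning. Because measured $A_0$ values scatter strongly with
$s$, all scaling-law radii default to monomer-length units ($A_0$ normalized
to 1, `normalized = TRUE`); the Å-scale prefactor is available behind the
flag.

Crowding enters as a multiplicative deformation factor $F(s, N, P)$ with the
boundary condition $F \equiv 1$ at crowding percentage $P = 0$. No
functional form is imposed — the literature gives none — so `rg_scaling()`
accepts a caller-supplied constant or function, plus the convenience choice
`deformation_from_potential(m, n)` which compresses the dilute radius by the
potential's compression factor ($F = 1/\beta$ for any $P > 0$), the natural
reading of $\beta$ as the crowding-induced size change.

```{r scaling}
rg_scaling(125, N = 40)                      # dilute, monomer lengths
rg_scaling(125, N = 40, P = 20,
           F = deformation_from_potential(12, 6))
fit_scaling(seq(20, 60, 10), seq(20, 60, 10)^0.653)$nu_hat
```

## The effective potential

The $F_1$/$F_2$ competition is encoded in a generalized Lennard-Jones
potential on the chain size $r$,

$$V(r) = a\,\varepsilon\!\left[\left(\frac{\sigma}{r}\right)^{m}
  - \left(\frac{\sigma}{r}\right)^{n}\right], \qquad m > n > 0,$$

where $\sigma$ is the compressed chain size ($R_{e\text{-}e}$ under
crowding), the minimum $r_m = \beta\sigma$ is the uncrowded size, and
$\beta = (m/n)^{1/(m-n)} > 1$ is the compression factor. The exponents are
accepted as positive reals; nothing pins them to the classic 12-6, which the
command-line interface uses only as an illustrative default.

**Normalization.** We use the standard depth normalization of the
generalized (Mie) potential, $a = \frac{m}{m-n}\beta^{n}$, so that
$V(\sigma) = 0$ and $V(r_m) = -\varepsilon$ for *every* admissible $(m, n)$:
$\varepsilon$ is always the well depth. The power-of-$\beta$ prefactors
($a = \beta^m$, $b = \beta^{m-n}$) sometimes quoted for this potential
coincide with the depth normalization exactly on the $m = 2n$ family
(including 12-6, where $a = 4$, $b = 2$), but away from it they make the
well depth $(m/n - 1)\varepsilon$, contradicting the definition of
$\varepsilon$; the package therefore treats them as an algebraic identity
between the two written forms (covered by a property test), not as the
normalization.

The force decomposition reports $F_1 = -a\varepsilon m\sigma^m/r^{m+1}$
(negative = repulsive/stretching) and $F_2 = +a\varepsilon n\sigma^n/r^{n+1}$
(positive = attractive/compressing); their sum vanishes at $r_m$, is
negative (net expansion) below it and positive (net compression) above it.
For a chain envelope shaped as a prolate spheroid with long semi-axis $d$
and short semi-axes $c$, force balance requires
$F_1/F_2 = 1 - 2d/\sqrt{d^2 + c^2}$ — the scale-invariant reading of the
relation, which reproduces the two anchors $-0.41$ (sphere, $c = d$) and
$-0.79$ ($c = d/2$) for any absolute size. The non-invariant variant
$1 - 2d/(d^2+c^2)$, which yields those anchors only at unit axes, is kept
behind `literal = TRUE` for auditability.

```{r potential}
p <- potential_params(m = 12, n = 6)
c(a = p$a, b = p$b, r_m = p$r_m, V_min = lj_potential(p, p$r_m))
ellipsoid_force_ratio(1, 1)
```

## Idealized configurations

Five coordinate-level generators cover the ladder of symmetry and
dimensionality loss, from fully 3D to 1D. Unless stated otherwise, monomers
are unit-radius hard spheres (diameter 2) and the generated centers never
overlap.

* **Straight rope (`straight_rope`)** — $N$ touching beads on a line;
  $R_g = \sqrt{(N^2-1)/3}$. The diameter-2 spacing is what reproduces the
  reference column (11.53 at $N = 20$).
* **Ring (`ring`)** — equally spaced centers on a circle of radius
  $R = N/(2\pi)$, so $R_g = R$ exactly. At that radius the beads are
  unit-*diameter* (`r_mono = 0.5`): the reference table mixes unit
  conventions across columns, and $N/(2\pi)$ is the one its ring column
  encodes. The unit-radius reading ($R = N/\pi$) sits behind
  `convention = "perimeter"`. On a closed ring neighbors sit on a chord,
  ~0.4% closer than touching at $N = 20$ — the polygon-vs-arc effect.
* **Dense sphere (`dense_sphere`)** — concentric shells at radii
  $0, 2, 4, \dots$ with capacities $1, 7, 19, 37, \dots$ (centered-hexagonal
  numbers $3k(k-1)+1$; their cumulative sum is exactly $k^3$, consistent
  with the volume bound $R^3/r^3$). The outermost shell is partially filled
  with the remainder. The nominal $R_g$ uses the shell radii (distances to
  the sphere center); for XYZ export each shell's beads are placed
  quasi-uniformly (icosahedral directions for ≤ 12 beads, a Fibonacci
  lattice otherwise), which keeps hard-sphere separation at every $N$ and
  moves the coordinate centroid only slightly off the center.
* **Sparse sphere (`sparse_sphere`)** — the same occupancy with all radii
  dilated so the envelope grows from the compact estimate $R = N^{1/3}$ to
  $R + r$: one explicit construction for an intrinsically under-specified
  shape ("degrees of sparsity" are a family, not a point). Its $R_g$ is
  treated as approximate.
* **Parabola (`parabola`)** — equal arc-length steps along $y = x^2$,
  mirror-symmetric about the axis, arc positions inverted through the
  closed-form arc length $s(x) = x\sqrt{1+4x^2}/2 + \sinh^{-1}(2x)/4$. The
  default step is **one unit** of arc (unit-length monomers,
  `r_mono = 0.5`): the reference construction is explicit that its parabola
  is built from unit-length monomers, and only the unit step reproduces its
  $N = 20$ value (3.45 vs 3.5 printed; a diameter-2 step gives 6.2). The
  diameter-2 step remains available via `step = 2`. Because the reference
  truncation rule is internally inconsistent, parabola values at larger $N$
  are treated as approximate.
* **Self-avoiding walk (`saw_walk`)** — the realistic configuration: an
  off-lattice pearl-necklace chain, bond length one diameter, uniformly
  random directions, rejection of any placement within one diameter of a
  non-bonded bead, per-step retries with whole-walk restarts (dead ends are
  rare off-lattice at these lengths). A seed makes walks bit-reproducible.

```{r configs}
vapply(list(dense_sphere(40), sparse_sphere(40), parabola(40),
            straight_rope(40), ring(40)),
       function(cfg) round(cfg$rg, 2), numeric(1))
```

The size ordering DS < Pa < SS < SR holds for the smaller chains
($N \le 30$); by $N = 40$ the parabola construction outgrows the sparse
sphere — as indeed it already does in the reference table's own printed
$N = 50$ row — so tests assert the full chain only where it actually holds.

## Wormlike chain and measurement conversions

The Benoit–Doty wormlike-chain expression gives $R_g$ for contour length
$l = N$ (unit effective monomer length) and persistence length $L_p$:

$$R_g^2 = \frac{l L_p}{3} - L_p^2 + \frac{2L_p^3}{l}
        - \frac{2L_p^4}{l^2}\left(1 - e^{-l/L_p}\right),$$

monotone in $L_p$, with the coil limit $R_g \to \sqrt{l/3}$ at $L_p = 1$ and
the stiff limit $R_g \to 0.263\,l \approx l/4$ at $L_p = l$.

Conversions: the default hydrodynamic-radius rule is
$R_h = \sqrt{5R_g/3}$ — dimensionally inconsistent, but it is demonstrably
the rule that generated the reference measurement grids, so it is the
default and is recorded in `measure_set()$convention`; the dimensionally
sane linear reading $R_h = \tfrac{3}{5}R_g$ sits behind
`convention = "linear"`. Then $R_{e\text{-}e} = 3.1 R_h$. For a compact
sphere of $N$ unit beads, $R = N^{1/3}$, $R_{e\text{-}e} \approx 2R$, and
$R_{e\text{-}e} = 2\sqrt{5/6}\,R_g \approx 1.8 R_g$. The shape factor
$\alpha = R_g/R_{e\text{-}e}$ is $1/\sqrt{6} \approx 0.408$ for ideal
chains and $\approx 0.55$ for compact spheres. `classify_regime()` maps an
exponent to the nearest of the named anchors (sphere 1/3, theta 0.5, SAW
0.588, good solvent 0.6, rope 1); the anchors are physical, the midpoint
boundaries (ties to the stiffer side) are an implementation convention.

## Reference grids and the known-discrepancy ledger

`build_table(1..5)` regenerates the five reference grids from the model
alone, and each is shipped with a cell-by-cell fixture
(`table_fixture()`) classifying every printed value exactly once:

* `verified` — the recomputation reproduces the printed value within the
  table tolerance (one last-digit unit, 0.001, for the 3-decimal parameter
  grid; 0.05 for the 1-decimal grids; 0.1 for the chained measurement grids,
  whose conversions amplify intermediate rounding);
* `paper-drift` — the printed value disagrees with the very formula it is
  attributed to (e.g. whole scaling rows computed with an exponent other
  than the printed one, and the $R_h$/$R_{e\text{-}e}$ rows chained from
  those drifted radii);
* `typo-suspect` — isolated values inconsistent with their own row or
  column (e.g. a wormlike cell smaller than its softer neighbor, or the
  dense-sphere cells that follow the alternative volume-ratio shell
  capacities instead of the $1, 7, 19, 37$ sequence used everywhere else).

Only `verified` cells are asserted; the others are reported, never tested,
so the disagreement stays visible without failing the suite
(`verify_tables()`, `compare_to_fixture()`, `report_to_json()`).

## Numerical and design choices

* Parabola arc inversion uses `uniroot` at tolerance $10^{-12}$ on the
  closed-form arc length; no numeric integration.
* The SAW overlap test allows a $10^{-9}$ relative slack on the hard-sphere
  distance so that exact touching survives floating point; bond directions
  use the standard uniform-sphere construction ($z \sim U(-1,1)$, uniform
  azimuth).
* Ensemble sizes: the packaged checks fit the SAW exponent over
  $N \in \{10, 20, 40, 80\}$ with 2000 walks each under a fixed seed —
  enough for the log–log slope to sit well within $0.59 \pm 0.03$ — and the
  scaling-law fit recovery uses 1000 replicates at 1% multiplicative noise,
  where the theoretical slope standard error ($\approx 0.012$) keeps the
  mean absolute error under 0.02.
* `fit_scaling()` is ordinary least squares on
  $\log R_g = \log A_0 + \nu \log N$; it refuses degenerate designs (fewer
  than two distinct $N$).
* Degenerate inputs are rejected rather than coerced: non-positive salt,
  $N < 1$, $L_p > l$, non-positive separations, $m \le n$.

## What the idealized constructions do and do not show

The generators emulate the *idealized* limits of chain geometry — exact
lines, circles, filled shells, noiseless parabolas — plus one stochastic
but still athermal chain (the SAW). They carry no solvent, no explicit
charges, no Boltzmann sampling of the effective potential, and no kinetic
trapping; temperature never enters an implemented equation. Passing tests
therefore demonstrate internal consistency of the model's closed forms and
constructions, not agreement with scattering or FRET measurements on real
ssDNA. The deformation factor $F(s,N,P)$ is an interface with a boundary
condition, not a fitted crowding law; any quantitative use under $P > 0$
requires the caller to supply one.
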