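---
title: "Methods: clustering, structure and association dynamics under periodic boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering, structure and association dynamics under periodic boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oilcluster)
```

`oilcluster` post-processes molecular dynamics trajectories of small
hydrophobic solutes (terpenoid essential-oil ingredients such as carvacrol or
thymol) mixed with hyperbranched polymer carriers in water. The questions it
answers are of the form: do the solutes coalesce into one droplet or stay
dispersed, where do the carriers sit relative to the droplet, how fast do
molecules move and rearrange, and how long do polymer-solute hydrogen bonds
persist. All methods work in nm/ps units on orthorhombic periodic boxes.

## Conventions and minimum-image geometry

Every analysis reduces molecules to their centers of mass (COM) first.
Positions are *wrapped* into `[0, L)`; displacements between frames use the
minimum-image convention. Two operations deserve care:

* **Molecule reassembly.** A molecule split across a boundary is made whole by
  chaining: the first atom anchors, each subsequent atom is placed at its
  minimum image relative to the previously placed atom (GRO files store
  molecule atoms contiguously, so no bond graph is needed). The COM is then
  computed from the reassembled coordinates and wrapped back.
* **Unwrapping.** For transport quantities the wrapped COM series is unwrapped
  frame-to-frame by adding the minimum-image displacement. This assumes no
  molecule moves further than `L/2` between saved frames; the package does not
  attempt heuristic repair when that is violated.

```{r pbc}
min_image_vector(c(3.9, 0.1, 0.0), c(0.1, 3.9, 2.0), box = 4)
```

## Cluster analysis: DBSCAN on a torus

Aggregation is quantified with DBSCAN over molecular COMs using periodic
(torus) distances. The defaults are `eps = 0.65` nm — a close-contact COM
separation for terpenoid-sized molecules — and `min_samples = 2`, which makes
every non-noise point a core point. With `min_samples = 2` DBSCAN reduces
exactly to the connected components of the eps-neighborhood graph, which
removes the classic border-point order ambiguity and matches the
"freely floating vs clustered" dichotomy: a molecule is clustered if and only
if it has at least one neighbor within `eps`.

`cluster_time_series()` reports, per frame, the number of clusters, the number
of clustered molecules, the largest cluster size and the mean neighbor count.
`swarm_radius_of_gyration()` gives the spatial extent of a molecular swarm; its
center is found by circular statistics (each axis mapped to an angle
`2*pi*x/L`, mean direction inverted back), the standard translation-invariant
centroid on a torus.

```{r clusters}
pl <- gen_planted_clusters(3, c(8, 5, 7), spread = 0.12, box_l = 10, seed = 1)
table(dbscan_pbc(pl$points, 10, eps = 0.65))
```

## Pair structure: g(r) with a long-range extension

`rdf_com()` bins minimum-image COM distances and normalizes by ideal-gas shell
occupancy. Standard g(r) stops at `L/2`, where spherical shells leave the
minimum-image cell. In extended mode the per-bin normalization volume beyond
`L/2` is estimated once per box shape by Monte-Carlo sampling of the
minimum-image distance distribution of uniform points (fixed internal seed, so
results are reproducible), which carries g(r) out to `sqrt(3) L/2` without
error-prone closed-form sphere-cube intersections. `coordination_number()`
integrates `rho * g(r)` shells to a cutoff; `first_shell_boundary()` locates
the minimum after the first peak on a lightly smoothed curve.

A geometric aside used for surface-population arguments: the area of the
portion of a probe sphere of radius `x` centered on a cluster-surface molecule
that lies *outside* a cluster of radius `R` is `cap_area(x, R)`. It vanishes at
`x = 2R` and peaks at `x = 4R/3`:

```{r cap}
cap_argmax(1)
cap_area(4 / 3, 1)
```

## Transport and rearrangement: MSD and van Hove functions

`msd()` is a multi-origin mean square displacement on *unwrapped* COMs;
`fit_diffusion()` fits the Einstein relation `MSD = 6 D t` over a lag window
(default 10-50% of the maximum lag, avoiding short-time noise and poor
long-lag statistics) and flags non-linearity.

The self van Hove function `van_hove_self()` histograms single-molecule
displacement magnitudes at selected lags (normalized `4 pi r^2 G_s`; for a
Brownian walker its mode sits at `2 sqrt(D t)`). The distinct part
`van_hove_distinct()` uses wrapped minimum-image distances between *different*
molecules, so at lag 0 it reproduces g(r) exactly; `peak_decay()` tracks the
decay of its first-shell peak, a fingerprint of how fast the local cage
rearranges.

```{r msd}
b <- gen_brownian(200, d = 1, dt = 0.01, steps = 500, seed = 11)
fit <- fit_diffusion(msd(b$unwrapped, origin_stride = 5L))
fit$d
```

## Hydrogen bonding

`detect_hbonds()` applies the conventional geometric criterion
(donor-acceptor distance below 0.35 nm and hydrogen-donor-acceptor angle below
30 degrees) using donor/acceptor/hydrogen designations from the species map,
classifying bonds as polymer-compound, polymer-polymer, compound-compound or
to water. `hbond_acf()` computes the intermittent autocorrelation
`C(t) = <h(t0 + t) h(t0)> / <h(t0)^2>` of bond indicator series (so
`C(0) = 1`), and `integrate_acf()` reports the integrated timescale `tau`,
truncating where `C` drops below a small cutoff and flagging window-limited
plateaus. For a two-state Markov bond with rates `k_on`, `k_off` the ACF is
exactly `p + (1 - p) exp(-(k_on + k_off) t)`, which the synthetic generator
exposes as a ground truth:

```{r hbonds}
mb <- gen_markov_bonds(0.02, 0.05, dt = 1, steps = 5000L, n_chains = 50L,
                       seed = 5)
acf <- hbond_acf(mb$h, max_lag = 100L, dt = 1)
max(abs(acf$c - mb$acf_exact(acf$lag_times)))
```

## Synthetic trajectories with known ground truth

Because every estimator above is statistical, the package ships seeded
generators whose answers are known in closed form: an ideal gas (g(r) = 1), a
Brownian ensemble with prescribed `D` (wrapped and unwrapped twins), planted
clusters with guaranteed labels, Markov bond chains, and an overdamped
aggregation model of solutes plus carriers. The aggregation model uses
smoothed square-well attractions and, optionally, a screened (Yukawa-type)
carrier-carrier repulsion; its two presets contrast a neutral carrier
(`"hpg_like"`: one dominant droplet with carriers enriched toward its surface)
against a charged-carrier emulation (`"hbpei_like"`: the repulsion between
carrier-cored micelles blocks coalescence, leaving several small clusters).

```{r presets, eval = FALSE}
tr <- gen_aggregation(aggregation_preset("hpg_like", seed = 1))
cs <- com_series(discard_frames(tr, 0.75), "oil")
cluster_time_series(cs, eps = 0.65)$summary
```

## Composition bookkeeping

`load_composition()` returns the packaged simulated-system compositions;
`count_atoms()` and `molar_ratios()` reproduce their per-species and total
atom counts and mixing ratios:

```{r comp}
ca <- count_atoms(load_composition(label = "car"))
ca$per_species[["carvacrol"]]
ca$total
```
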