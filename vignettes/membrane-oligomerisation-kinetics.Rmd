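---
title: "Methods: membrane receptor oligomerisation kinetics with memrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane receptor oligomerisation kinetics with memrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(memrate)
library(dplyr)
```

## The scientific problem

Docosahexaenoic acid (DHA, C22:6n3) is the dominant omega-3 fatty acid of
neuronal membranes, and its level drops in several neuropsychiatric
conditions. Because DHA chains are extremely flexible, membranes rich in
DHA-carrying phospholipids (SDPC, SDPE) are more fluid, and transmembrane
proteins — here the adenosine A2A and dopamine D2 receptors, which form
functionally important heteromers — diffuse and rotate faster in them. The
package quantifies how membrane DHA content changes the *kinetics* of
receptor oligomerisation: how quickly receptors find each other and
consolidate contacts, how DHA lipids solvate receptors, how saturated and
unsaturated lipids demix, and whether the *steady-state* amount of
oligomer (measured by BRET titrations in cells) changes at all.

`memrate` packages the complete quantitative pipeline around that
question:

1. a seeded 2D Brownian-dynamics generator of membrane trajectories with
   known ground truth (`sim_config()`, `simulate_membrane()`, presets);
2. trajectory containers with periodic geometry and plain-text I/O;
3. contact/oligomer analyses (`contact_matrix()`,
   `contacts_per_protomer()`, `oligomer_clusters()`,
   `compare_aggregation()`);
4. lipid-environment analyses (`rdf2d()`, `shell_report()`,
   `mixing_contact_fraction()`, `bound_fraction()`);
5. diffusion estimation (`msd()`, `fit_diffusion()`, `rotational_acf()`);
6. composition accounting (`tail_census()`, `dha_tail_fraction()`);
7. BRET saturation-curve analysis (`fit_saturation()`, `select_model()`,
   `compare_conditions()`).

## The synthetic membrane generator

Coarse-grained molecular-dynamics trajectories of this system are not
publicly deposited and regenerating them needs cluster-scale computing.
The generator therefore *emulates the statistical structure* of such
membranes — it is a first-class, tested model, not a mock. Each particle
(receptor or lipid) moves by overdamped Langevin dynamics in a periodic
box:

$$\mathbf{x}_{t+\Delta t} = \mathbf{x}_t
  + \frac{D}{k_BT}\,\mathbf{F}\,\Delta t
  + \sqrt{2D\,\Delta t}\;\boldsymbol{\xi}, \qquad
  \boldsymbol{\xi}\sim\mathcal{N}(0, I_2),$$

with $k_BT \equiv 1$, lengths in nm and time in µs (so diffusion is in
nm²/µs; numerically equal to $10^{-8}$ cm²/s). Receptor orientations
follow $\theta_{t+\Delta t} = \theta_t + \sqrt{2D_r\Delta t}\,\xi$. Pairs
interact through a quadratic soft core inside the contact distance
$r_0 = R_i + R_j$ plus, where declared, a Gaussian attraction
$-\varepsilon\exp(-(r-r_0)^2/2\sigma^2)$ truncated at $r_0 + 3\sigma$.
This potential was chosen for continuity and cheap analytic forces; it
makes no attempt to reproduce a coarse-grained force field, only the
emergent observables the analyses consume.

Ground truth (every $D$, $D_r$, the interaction table and seed) is
returned beside each trajectory, so every estimator in the package can be
validated by parameter recovery.

### Study-condition presets

`sim_preset()` encodes the membrane conditions as published measurements:

* receptor translational $D$: 0.48 / 0.46 nm²/µs (A2A / D2) in the
  DHA-rich "healthy" membrane, 0.18 / 0.22 in the DHA-poor "diseased"
  one; rotational rates are scaled like the translational ones (a package
  convention — the rotational magnitudes themselves are not tabulated);
* crowded-membrane lipid $D$ per species (1.3–3.4 nm²/µs; ternary mixture
  8.1–12.4 nm²/µs);
* lipid counts apportioned from the matching composition preset
  (largest-remainder method), 33% cholesterol in healthy/diseased, 20% in
  the ternary mixture;
* a receptor–receptor attraction (ε = 3 kT, σ = 0.8 nm, well at 3.6 nm)
  so contacts consolidate once receptors meet, and an SDPC/SDPE–receptor
  attraction (ε = 2 kT, σ = 0.5 nm) that builds the preferential DHA
  solvation shell.

Default problem sizes are deliberately desk-scale and are stated here as
the package's own choices: 18 receptors plus 150 lipid particles in a
40 × 40 nm box (a sparse stand-in, not bilayer density), Δt = 2 × 10⁻⁴ µs,
20 000 steps saved every 100 (4 µs raw, i.e. 16 µs at the standard 4-fold
effective-time conversion of coarse models). The presets are calibrated
to reproduce *orderings* (healthy aggregates faster than diseased), never
magnitudes of the published contact counts; no association/dissociation
rate constants are published that would pin magnitudes down.

```{r ordering, eval = FALSE}
h <- simulate_membrane(sim_preset("healthy"), seed = 1)$trajectory
d <- simulate_membrane(sim_preset("diseased"), seed = 1001)$trajectory
contacts_per_protomer(h)$summary$mean_contacts # > diseased value
```

### What the generator does and does not emulate

It reproduces: species-specific lateral diffusion at the published scale,
short-range receptor association, preferential DHA solvation, partial
saturated/unsaturated demixing (via `demix_preset()`), and hyperbolic
BRET titrations with linear bystander controls. It does **not** model
protein internal structure or shape, bilayer leaflets, membrane
undulations, hydrodynamic coupling, or chemically detailed lipids.
Passing tests therefore certify the *estimators and analysis code* on
data with known truth; they do not re-derive the published
molecular-dynamics observations from physics.

## Contact and oligomer analysis

Two receptors are in contact when their lateral minimum-image
centre-of-mass distance is **strictly** below 4.2 nm; ties are
non-contacts. Distances are lateral (in-plane) throughout: the membrane
analyses that define shells and radial distributions are stated in the
membrane plane, and coarse receptor models are of near-equal height, so
a 3D criterion would differ only marginally. Because the criterion is
distance-only, lipid-mediated closeness counts as contact. Contacts are
counted instantaneously per frame; stability is captured by restricting
to a late analysis window (default: the final third of the trajectory,
generalising "the last 20 µs of 60 µs") rather than by a persistence
filter, which is available in `pair_distance_series()` but off by
default. Oligomers are connected components of the contact graph
(igraph), monomers included.

Errors: SEM over replicas when at least 3 replicate runs are supplied,
otherwise a 5-block block average. `compare_aggregation()` reports the
relative difference of condition means and a replicate-level Welch test —
the replicate, not the frame, is the statistical unit.

`effective_time()` multiplies raw times by 4 and flags the axis; it is
applied at reporting only, never to stored trajectories.

## Lipid environment

`rdf2d()` uses the standard two-dimensional ideal-gas normalisation
(annulus counts over $2\pi r\,\Delta r\,\rho\,n_{\mathrm{ref}}
n_{\mathrm{frames}}$), so g → 1 for uniform mixing and curves are
comparable across species; bin width defaults to 0.05 nm. Shell
detection uses the all-lipid curve (per-species curves are noisy for
sparse species): outer radius = first local minimum after the global
peak (undetectable when max g < 1.1), core radius = half-rise point
(g > 0.5), width = outer − core.

Contact cutoffs are centre-centre translations of bead-scale values:
receptor–lipid 2.8 nm (receptor radius 1.8 + lipid radius 0.4 + 0.6 nm
gap) and lipid–lipid 1.1 nm. Both are exposed as arguments; the exact
bead-level values used on real coarse-grained systems are a
supplementary-protocol detail that is not published, so these defaults
are package conventions. The demixing order parameter
(`mixing_contact_fraction()`) is the fraction of lipid–lipid contact
pairs that join the saturated and unsaturated classes; it is reported
next to the random-mixing expectation $2x(1-x)$ and drops below it under
phase separation.

## Diffusion estimation

`msd()` averages squared lateral displacements over all time origins and
selected particles (input must be unwrapped; box-scale jumps are
detected and refused). `fit_diffusion()` fits $\mathrm{MSD} = 4D\Delta + b$
by weighted least squares with a free intercept — the intercept absorbs
short-time artefacts — over lags in 10–50% of the maximum by default
(the exact published fit protocol lives in unavailable supplementary
material; this window is the package's documented convention, and any
window can be passed). Negative slopes report D = 0 with a warning.
Rotational rates come from $C(\Delta)=\langle\cos\Delta\theta\rangle$,
which for a planar rotor is exactly $e^{-D_r\Delta}$; the log-linear fit
is restricted to $C \ge 0.3$ to avoid log-noise. Unit conversions are
exact: 1 nm²/µs = 10⁻⁸ cm²/s.

Estimator validation: free-walk recovery is unbiased (checked at the
published coefficient scales 0.48, 1.3 and 12.4 nm²/µs); the
acceptance-level check uses 200 walks × 100 seeds per coefficient so the
seed-level SEM of a 2-SEM equivalence band is itself stable.

## Composition accounting

Compositions hold phospholipid percentages (of phospholipids) plus a
cholesterol fraction (of all lipids). Tail bookkeeping is per 100
phospholipids against a nominal 200 tails, the accounting that
reproduces the published fatty-acid rows that are convention-robust:
DHA = 10.5% exact (reported 11%) in the healthy model, 3% in the
diseased one, 31.25% (~31%) in the ternary mixture, and C16:0 = 39/51%.
Two conventions are worth stating. First, sphingomyelin is booked as one
C16:0 acyl chain plus the sphingosine backbone as one saturated C18
chain; the published C18:0/C18:1 rows are not reproducible under any
single stated convention, so only the robust rows are relied upon.
Second, the diseased phospholipid column totals 101; the constructor
warns beyond ±0.5 and keeps the nominal-200 basis, which is the only
choice that reproduces the printed C16:0 row. Reported percentages use
half-away-from-zero rounding (hence 10.5 → 11). `particle_counts()`
apportions simulator particles by largest remainder with a
deterministic name-order tie-break, so counts always sum exactly.

## BRET analysis

The BRET ratio is $1000\,(F - F_{bg})/(L - L_{bg})$ in mBU. Saturation
curves are fitted as $\mathrm{BRET} = \mathrm{BRET_{max}}\,x/
(\mathrm{BRET_{50}} + x)$ by multistart Levenberg–Marquardt with
positivity bounds; the abscissa is the acceptor expression level
(acceptor/donor normalisation is the adopted, configurable convention —
the published figures do not state it). Specific versus bystander
transfer is decided by an extra-sum-of-squares F test against the
1-parameter line through the origin at α = 0.05: the published argument
is visual (saturating versus quasi-linear), but software needs a formal
rule. Conditions are compared by a paired two-sided t test across
independent experiments. Fits are unweighted by default (1/y optional);
the 1 and 10-minute reads of a plate are kept as separate measurements.
The titration generator mirrors the laboratory design: 8 acceptor
levels in triplicate, multiplicative noise, hyperbolic or linear truth.
Under the null (both conditions from the same generator) the paired
test's type-I error is nominal — the test suite checks 4–6% at α = 0.05
over 1000 seeds.

## Numerical choices and degenerate inputs

* Minimum-image components lie in (−L/2, L/2]; periodic COMs use the
  circular-mean construction, which matches the recentred naive mean for
  clusters smaller than half the box.
* Strict inequalities at every contact cutoff; `contact_matrix()`
  refuses cutoffs ≥ half the box edge (ambiguous under periodicity).
* The integrator refuses timesteps with $\sqrt{2D\Delta t} \ge \sigma/5$
  for the narrowest declared well and suggests a usable Δt. At very high
  D the soft core itself produces collision kicks that bias MSDs upward;
  free-walk benchmarking therefore switches the core off (`k_rep = 0`).
* Largest-remainder ties break by species name; identical `(config,
  seed)` pairs are bit-identical; frames with no lipid–lipid contacts
  flag the mixing fraction as undefined rather than inventing a value.
* `fit_saturation()` falls back to the linear model when no multistart
  converges (typical for genuinely linear data) and flags it.

## Known limitations

* The generator's receptors are featureless discs: no interfaces, no
  orientation-dependent binding, so homo- versus heteromer preferences
  beyond composition stoichiometry are outside its reach.
* Contact magnitudes from presets are not comparable to published
  contact counts; only condition orderings are meaningful.
* Oligomers in the generator rarely dissociate on test timescales, as in
  the source simulations — equilibrium constants are not estimable.
* XTC input is unsupported (no installed reader); the native text format
  and PDB+DCD cover interchange.
* Single-run error bars (block SEM with 5 blocks) are approximate when
  the correlation time approaches a block length.
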