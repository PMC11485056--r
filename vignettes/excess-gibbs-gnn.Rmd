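---
title: "Thermodynamically consistent activity-coefficient prediction with excess-Gibbs graph neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamically consistent activity-coefficient prediction with excess-Gibbs graph neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gegnn)
```

## The modelling problem

Activity coefficients $\gamma_i$ quantify how far a liquid mixture departs
from ideal (Raoult) behaviour; they are the central quantity in vapor–liquid
equilibrium and separation-process design. Machine-learned predictors that
map two molecular structures and a composition directly to
$(\ln\gamma_1, \ln\gamma_2)$ can be accurate at their training compositions
yet *thermodynamically inconsistent*: their two outputs, viewed as functions
of the mole fraction $x_1$, need not satisfy the isothermal–isobaric
Gibbs–Duhem relation for a binary mixture,

$$ x_1 \frac{d\ln\gamma_1}{dx_1} + x_2 \frac{d\ln\gamma_2}{dx_1} = 0,
\qquad x_2 = 1 - x_1 . $$

Inconsistent predictions produce physically impossible VLE curves.

This package takes the fundamental-property route: the network predicts a
single scalar, the dimensionless molar excess Gibbs free energy
$g \equiv g^E\!/RT$, and the activity coefficients are *derived* from it by
the exact differential relations

$$ \ln\gamma_1 = g + (1 - x_1)\, g', \qquad
   \ln\gamma_2 = g - x_1\, g', \qquad g' = \frac{dg}{dx_1}, $$

which invert the defining identity $g = x_1\ln\gamma_1 + x_2\ln\gamma_2$
together with $\ln\gamma_1 - \ln\gamma_2 = g'$. Any twice-differentiable
$g(x_1)$ then satisfies the Gibbs–Duhem relation *identically*: both
composition derivatives are proportional to $g''$ with prefactors
$x_1(1-x_1)$ and $-(1-x_1)x_1$, which cancel exactly. Consistency is a
property of the architecture, not of the training data, the weights, or a
penalty term — the package's consistency tests pass for untrained models.
Labels supervise the *derived* $\ln\gamma_i$, so training is end-to-end
through the differentiation.

Temperature is fixed at 298.15 K throughout and recorded for provenance
only; $R$ and $T$ are constants folded into the dimensionless target.

## Architecture

1. **Molecular encoder.** Each SMILES is parsed (via OpenBabel through
   ChemmineR/ChemmineOB) into a heavy-atom graph with a fixed featurisation:
   one-hot element over {C,N,O,F,P,S,Cl,Br,I,other}, one-hot degree 0–4,
   formal charge, aromaticity flag, one-hot implicit-H count 0–4
   (22 atom features); one-hot kekulised bond order plus aromatic- and
   ring-membership flags (5 bond features). Two graph-convolution layers
   (self, neighbour-sum and incident-bond-feature channels) followed by sum
   pooling give a molecular fingerprint.
2. **Mixture interaction.** The two fingerprints become the nodes of a
   two-node mixture graph with one undirected edge and self-loops; one
   further convolution exchanges information between the components,
   giving updated fingerprints. Self-loops are the minimal way to retain
   each component's own identity while mixing in its partner; the
   mixture-graph layer uses no edge features.
3. **Composition and pooling.** Each updated fingerprint is concatenated
   with *its own* mole fraction ($x_1$ and $1-x_1$; $x_1$ is the single
   free composition variable everywhere), passed through a shared
   single-layer perceptron, and **mean-pooled** over the two components.
   Mean pooling over the per-component multiset — rather than concatenation
   — makes the mixture fingerprint invariant under the simultaneous swap
   (component 1 ↔ component 2, $x_1 \leftrightarrow 1-x_1$), so relabeling
   the components never changes predictions (verified to machine precision
   in the tests).
4. **Output MLP.** Two hidden layers map the mixture fingerprint to the
   scalar $g$. Composition enters *after* the graph convolutions; the
   alternative of injecting it before the mixture convolution would force
   differentiation through the graph-convolution stack at higher cost and
   (in our and others' experience) lower accuracy, and is not implemented.

All activations from the SLP onward are **softplus** (SiLU is also
accepted). The configuration constructor rejects non-smooth activations
such as ReLU: the head needs $g''$ for consistency audits, and a kink in
the activation produces kinked activity-coefficient curves and is known to
stall training of this model family.

### Differentiation strategy

$g'$ and $g''$ are computed by forward-mode automatic differentiation:
because composition enters only at the SLP, the value, first- and
second-derivative channels are propagated analytically from that point
through the MLP (dual numbers of order two). Training gradients with
respect to the parameters are reverse-mode over the *dual* computation
graph — the loss depends on both $g$ and $g'$, so the reverse pass carries
adjoints for both channels, which brings in the activation's second
derivative. The implementation is plain dense linear algebra; gradient
correctness is verified against finite differences in the test suite
(agreement ~1e-10). Finite differences appear only as test oracles, never
in the prediction path.

### Baselines

Two direct predictors share the *identical* encoder, SLP, MLP and readout
parameter shapes (so comparisons isolate the consistency mechanism); they
skip the mean pooling and read out each component's stream separately,
giving permutation-*equivariant* $(\ln\gamma_1, \ln\gamma_2)$:

* **direct** — trained on the prediction loss only;
* **gdi** — additionally penalised by $\lambda \times$ the mean squared
  Gibbs–Duhem residual, evaluated at the labeled interior compositions and
  at 5 uniformly random interior compositions per mixture per epoch
  (re-drawn each epoch from the master seed). The residual needs
  $d\ln\gamma_i/dx_1$, supplied by the same dual-channel machinery.

The qualitative ordering GD-RMSE(direct) > GD-RMSE(gdi) > GD-RMSE(ge)
is asserted in the acceptance tests.

## Synthetic data generator

The generator emulates the *shape* of composition-resolved activity
coefficient datasets computed by continuum-solvation models: a compound
library, sampled unordered pairs, and a fixed composition grid
$\{0, 0.1, 0.3, 0.5, 0.7, 0.9, 1\}$ whose end points are infinite-dilution
records (at $x_1 = 0$ the label carries $\ln\gamma_1^\infty$ and the pure
component's $\ln\gamma_2 = 0$ is included as a supervised point). Labels
come from classical excess-Gibbs models — two-parameter Margules, van Laar,
NRTL — whose closed forms satisfy the Gibbs–Duhem relation analytically and
double as independent oracles for the differentiation head (the closed-form
$\ln\gamma_i$ and the symbolically derived $dg/dx_1$ are separate code
paths, cross-checked to 1e-10).

Model parameters are a smooth deterministic function of two graph-derived
descriptors (a polarity proxy: heteroatom fraction plus normalised
H-bond donor/acceptor counts; and a size proxy: heavy-atom count/10):
with $\Delta p$ the polarity difference and $s$ the relative size contrast,
$S = 3\Delta p^2 (1 + s/2)$, $D = 0.6\,\Delta p\, S$, $A_{12} = S + D$,
$A_{21} = S - D$ (NRTL: $\tau_{ij} = A_{ij}$, $\alpha = 0.3$). This makes
the label-generating map learnable from the graphs, gives ideal behaviour
for polarity-matched pairs, spans $\ln\gamma^\infty$ up to ≈ 6 for
water/alkane-like contrasts (realistic for strongly non-ideal aqueous
systems), and swaps $A_{12} \leftrightarrow A_{21}$ exactly under component
relabeling. Optional zero-mean Gaussian parameter noise (off by default) is
drawn once per *unordered* pair so the swap symmetry survives.

Default scale: 50 compounds, 400 mixtures, 7-point grid (2,800 records) —
large enough for the network to learn the descriptor→parameter map, small
enough to train in minutes on one CPU.

What the generator does *not* emulate: real quantum-chemistry label noise
and outliers, temperature dependence, associating-system curve shapes
outside the three closed-form families, and intramolecular subtleties the
descriptors ignore. Passing tests therefore demonstrate the architecture's
consistency and learnability properties, not accuracy on experimental or
COSMO-RS data; an adapter (`read_mixture_csv()`) accepts external data in
the same schema.

## Split protocols

* `comp_inter` (interpolation): each mixture's five interior compositions
  are dealt one-per-fold by a seeded permutation, so every fold withholds
  one random interior composition from every mixture and no mixture ever
  loses all its points. Because every mixture contributes one test point
  per fold, polarity combinations are exactly balanced across folds.
  Boundary (infinite-dilution) records always stay in training.
* `comp_extra` (composition extrapolation): a stated set — e.g. {0.5},
  {0.3, 0.7}, {0.1, 0.9}, {0, 1} — is withheld across *all* mixtures; one
  split per exclusion set, no folding.
* `mixt_extra` (unseen pairs): whole mixtures are held out, stratified
  over unordered pairs of polarity tertile bins (round-robin within
  stratum after a seeded shuffle, so per-fold stratum counts differ by at
  most 1); the molecules themselves still occur in training in other
  combinations. Mixture identity is the unordered pair of canonical
  SMILES, so input order never leaks across splits.

Splits are verified post-hoc against their defining invariants and can be
serialised to a manifest CSV.

## Metrics

Accuracy (RMSE, MAE, $R^2$) is pooled over both components' $\ln\gamma$ at
all test points; $R^2$ uses a single pooled label variance (a documented
choice — per-mixture averaging would weight short curves up). Consistency
is GD-RMSE: the root mean square Gibbs–Duhem residual pooled over all
(mixture, composition) evaluation pairs, audited at *interior* compositions
only — at the boundary the residual is not part of any reported grid, and
the derived infinite-dilution values come from evaluating the same smooth
formulas at $x_1 \in \{0, 1\}$. The external audit grid is every multiple
of 0.05 inside (0,1) not on the data grid — 14 points for the default
grid. The error histogram reports the fraction of absolute errors below
0.05 and an outlier threshold defined as the smallest of the top
1 % largest errors (`ceiling(0.01 n)` order statistic).

## Training configuration and numerical choices

* Optimiser: Adam on a flat parameter vector; default step size 3e-3 with
  cosine decay to zero over the training budget, batch = 5 mixtures
  (every labeled composition of a mixture is processed in one forward
  pass). Defaults were chosen on the default synthetic task, where they
  reach training MSE ≈ 4e-4 and held-out RMSE ≈ 0.016 in 100 epochs
  (~3–4 minutes on one CPU); a constant step size is available.
* Width: hidden dimension 64 everywhere. At this problem scale a width-128
  variant trains markedly more slowly per step and reaches clearly worse
  optima within the same epoch budget, so 64 is the package default.
* Initialisation: Glorot-scaled normal draws under the configuration seed;
  every stochastic step (weights, shuffling, augmentation, split and
  dataset sampling) derives its own sub-seed from a master seed, making
  dataset generation, splitting and training bit-for-bit reproducible.
* Degenerate inputs: van Laar with both parameters 0 is defined as ideal;
  NRTL with $\alpha = 0$ is allowed but degenerate (both Boltzmann factors
  collapse to 1). Mole fractions outside $[0,1]$ raise domain errors;
  Gibbs–Duhem audits refuse non-interior points.
* Checkpoints are R serialisations of configuration plus weights and
  round-trip exactly.

## Vapor–liquid equilibrium

`vle_curve()` applies modified Raoult's law
$P = x_1\gamma_1 P^{sat}_1 + x_2\gamma_2 P^{sat}_2$,
$y_1 = x_1\gamma_1 P^{sat}_1 / P$, with Antoine saturation pressures
$\log_{10} P^{sat} = A - B/(T + C)$ (coefficients bundled for the example
compounds in the NIST-webbook log10/bar/K convention, sources cited in the
fixtures file). At the pure limits the pure component's $\gamma$ is set to
exactly 1 — its thermodynamic definition — so endpoint pressures equal the
pure-component values even though the network does not enforce
$\gamma_i(x_i{=}1) = 1$; this is a documented divergence between raw model
output and the VLE boundary convention. A $y_1 = x_1$ crossing in the
interior sets an azeotrope flag.

## Known limitations

* Binary mixtures only; no multicomponent Gibbs–Duhem relations, no
  pressure or temperature consistency, no temperature dependence.
* Nothing constrains $\ln\gamma_i = 0$ at $x_i = 1$ architecturally; in
  composition-extrapolation settings the derived curves can bend sharply
  near unseen boundary regions.
* The featurisation is a deliberately minimal standard set (no
  stereochemistry, conformers, charges beyond neutral organics).
* Accuracy statements in this package are about the synthetic task; real
  datasets require retraining and their own validation.
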