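---
title: "Evidence-weighted extraction of active metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-weighted extraction of active metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(initgem)
```

## The problem

A genome-scale metabolic model (GEM) catalogues every reaction an
organism's genome can support, with gene-protein-reaction (GPR) rules
linking reactions to the genes encoding their enzymes. Any single cell
type expresses only part of that catalogue. Given per-tissue evidence —
antibody-staining categories for proteins, expression signals for
transcripts, and detected-metabolite lists — `initgem` carves out of a
generic template the subnetwork that is best supported by the evidence
while remaining functional: every included reaction can carry flux, and
every metabolite known to be present can be synthesised.

## The extraction program

Let $S$ be the stoichiometric matrix over internal metabolites, $v$ the
flux vector, $y_i \in \{0,1\}$ inclusion of reaction $i$, and
$x_j \in \{0,1\}$ a production indicator for metabolite $j$. The mixed
integer program is

$$\max \; \sum_i w_i\, y_i + \delta \sum_j x_j$$

subject to

* relaxed steady state: $S v = b$, $b \ge 0$ — metabolites may
  accumulate (or, equivalently, be secreted), never be consumed in net.
  This keeps pathways to "dead-end" products, which a strict steady
  state would delete;
* flux coupling: $\varepsilon\, y_i \le |v_i| \le M y_i$. For
  reversible reactions a direction binary selects the sign, so an
  included reversible reaction must carry a nonzero *net* flux and
  cannot fake activity by internal cancellation;
* production semantics: $\varepsilon_b x_j \le b_j \le M x_j$, and
  additionally the non-exchange part of metabolite $j$'s net production
  must reach $\varepsilon_b$ when $x_j = 1$. The second condition makes
  rewards and presence forcing mean *synthesis*: merely importing a
  metabolite through an exchange earns nothing and satisfies nothing;
* metabolome forcing: $x_j = 1$ for every metabolite detected in the
  tissue;
* exchange reactions are always permitted and carry no weight.

The production reward is a per-metabolite bonus $\delta$ rather than a
linear reward in $b_j$: a linear reward would push fluxes to the $M$
bound and make the objective depend on $M$.

### Evidence weights

Staining categories map to weights $20 / 15 / 10 / {-8}$ for
high/medium/low/absent. When a gene only has an expression signal $s$
in the target tissue, the weight is
$\mathrm{scale} \cdot \log_b\!\big((s + c)/(\bar s + c)\big)$ with
$\bar s$ the gene's mean signal over all tissues: positive above the
tissue average, negative below, zero at it. The published rendering of
this formula is not machine-readable in our source text; only its sign
and ratio structure are fixed. We use base 2 and scale 10 so that a
2-fold elevation scores like a "low" staining call, and isolate both
constants in `weight_config()`. The pseudocount $c$ (default: half the
smallest positive signal, or 1 for integer signals) guards zero
signals.

A reaction scores the **maximum** over the genes in its GPR — the rule
is deliberately blind to AND/OR structure, as stated for the original
method. Reactions with no gene, or no scored gene, get $-2$: enough to
exclude them unless they are needed for connectivity. Staining evidence
wins over expression for the same gene (the antibody atlas is the
method's primary evidence source). When a reaction is kept, its GPR is
pruned to the genes with positive scores, possibly becoming empty.

### Numerical choices

$\varepsilon = \varepsilon_b = 1$, $M = 1000$, $\delta = 0.1$, relative
MIP gap $10^{-6}$ (all in `init_config()`). $\delta$ is far below the
smallest evidence-weight magnitude (2), so production rewards only
break ties and never override evidence. Feasibility certificates are
recomputed in R for every solve: $S v = b$ to $10^{-6}$, coupling of
$y$, $v$, $b$, $x$, and the objective identity; a violation is an
error, not a warning. Degeneracy is real — ties between equal-weight
subnetworks are broken by the solver — so cross-implementation tests
compare objectives, not reaction sets, except on fixtures built to have
unique optima.

Linear and integer programs are solved with HiGHS through SciPy in a
bundled Python helper; a persistent worker process answers batched
requests over FIFOs, with a one-shot subprocess fallback. This replaces
the commercial solver used in the original work; the enumeration oracle
(below) guards the encoding regardless of backend.

### The enumeration oracle

`brute_force_oracle()` enumerates every inclusion subset (up to a cap,
default 12 non-exchange reactions), checks each with an independently
written fixed-subset subproblem — inclusion frozen into variable
bounds, only direction and production binaries free — and prunes
subsets whose weight sum plus the maximal production reward cannot beat
the incumbent. Because minimum-flux constraints on reversible reactions
and the "zero or at least $\varepsilon_b$" accumulation rule are
disjunctive, the per-subset check is itself a (tiny) MILP rather than
an LP; the oracle's independence lies in the exhaustive enumeration and
the separate encoding. Solver and oracle agree to $10^{-6}$ on hundreds
of randomized instances in the acceptance suite.

## Template preprocessing

`build_template()` applies, in order: (1) removal of reactions touching
blacklisted generic metabolites and of elementally unbalanced reactions
(hydrogen imbalance is tolerated — protonation states are unreliable
and proton exchange is treated as free; reactions with formula-less
metabolites are *uncheckable*, not unbalanced); (2) removal of
reactions with unknown directionality; (3) dead-end removal: a
reaction survives if, in some allowed direction, all its substrates are
producible, where producibility is the closure of "importable or
producible by a supported reaction" — accumulating products do not
block a reaction, consistent with the extraction's relaxed steady
state; (4) flux-consistency pruning under the *strict* steady state
with all exchanges open, by per-reaction flux maximisation
($\tau = 10^{-4}$ against LP tolerances of about $10^{-7}$ separates
numerical zero from real flux). Stages 3–4 are iterated to a joint
fixed point, since a flux-inconsistency removal can create new dead
ends; the original description does not specify looping. `leak_test()`
closes all uptakes and maximises each metabolite's net production;
anything above tolerance indicates a mass/energy-creating cycle.
Unbalanced reactions are removed, not auto-fixed; curated replacements
can be supplied as a model file, mirroring the manual curation step of
the original database build.

## What the synthetic generator emulates

`generate_network()` grows a bipartite metabolite–reaction graph from a
set of exchanged seed metabolites, so every reaction's substrates are
producible by construction; secretion outlets are added until the
network — and the planted active subnetwork on its own — passes the
flux-consistency check. Coefficients are drawn from $\{1, 2\}$ (85/15),
keeping balance checks meaningful without formula bookkeeping and
keeping flux demands far from the $M$ bound. Defaults (40 metabolites,
50 reactions, 30% reversible, 15% seed exchanges, half the reactions
planted, 5% label noise, lognormal expression with $\sigma = 0.5$ over
8 tissues) are the stated world of the test-suite; one gene per
reaction keeps planted-recovery truth unambiguous, with GPR complexity
available as an opt-in axis. Evidence simulation labels planted genes
with a configurable staining mixture and others absent, flips labels at
the noise rate, and gives planted genes a 4-fold elevated expression
mean in the target tissue.

What the generator does *not* emulate: realistic pathway topologies,
compartment structure beyond the cytosol, currency-metabolite hubs,
correlated antibody errors, or probe-level expression noise. A green
planted-recovery test therefore establishes that the optimisation
recovers a known truth under the stated noise model — not that real
tissue networks would be equally recoverable.

## Comparative statistics

Presence/absence of genes or reactions across extracted networks forms
a binary matrix. Group enrichment is the one-sided hypergeometric upper
tail $P(X \ge k_a)$ for a feature present in $k_a$ of $n_a$ group-a
networks among $k_a + k_b$ presences overall, reported with the
original fixed cutoff $10^{-4}$ and, additionally, Benjamini–Hochberg
q-values (clearly labelled; the original analysis used the raw cutoff).
The null universe for enrichment is exposed as a parameter rather than
hard-coded. Reporter Metabolite scores aggregate per-gene p-values onto
each metabolite's neighbour genes (genes of reactions producing *or*
consuming it — the cited aggregation method is direction-agnostic):
$Z = \sum_g \Phi^{-1}(1 - p_g) / \sqrt{k}$, corrected by the mean and
standard deviation of random size-$k$ gene sets; if all p-values are
identical the null is degenerate and the corrected score is defined as
0. Networks are clustered by average linkage on the Jaccard distance
between gene profiles (the source text names no metric; Jaccard matches
"similarity in terms of shared genes"), with clade support from an
ordinary feature-resampling bootstrap — the multiscale variant used in
the original study is a substantial separate method and is deliberately
not reimplemented; support values are therefore plain bootstrap
proportions, not approximately-unbiased p-values.

## Sensitivity harness and its calibrated floor

`weight_sensitivity()` rescales the four staining weights by
$1 \pm 0.2$ (full factorial grid by default) and reports the Jaccard
similarity of each perturbed reaction set to the unperturbed one. On
the two calibration fixtures (50-reaction networks, 10% label noise,
seeds 42/43) every one of the 16 grid points returned similarity 1.0.
The acceptance floor is set one tie-flip below at 0.9 — a single
marginal reaction flipping on a network of this size costs about 0.03
— to absorb solver tie-breaking differences across platforms; it was
fixed before the acceptance test was first run against it and is far
above the regime that would contradict the robustness claim being
checked.

## Known limitations

* Alternative optima are reported as the solver finds them; no
  enumeration of the optimal face.
* The exchangeable-metabolite set for flux-consistency testing is taken
  from the input model's exchange reactions; an external
  exchangeable-set definition is not consulted.
* Directionality conflicts between source databases are out of scope; a
  single input model is assumed.
* Expression weighting constants (base, scale) are conventions, not
  published values; see above.
* The bootstrap support is ordinary, not multiscale.
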