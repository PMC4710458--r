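---
title: "Modelling reference fish assemblages for stream bioassessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reference fish assemblages for stream bioassessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Stream bioassessment under the reference-condition approach compares the
biota observed at a test site against the biota *predicted* for an
environmentally similar but minimally disturbed site. The quality of
that comparison rests entirely on the species distribution models that
supply the predictions. `refstream` implements and compares the three
modelling strategies in routine use for this task, applied to binary
site-by-species data for stream fish:

1. **Predict then assemble** (`ens_sdm()`): each species is modelled
   separately, by an ensemble of candidate models drawn from five
   learner families (logistic GLM, random forest, boosted trees, a
   feed-forward neural network, and adaptive regression splines).
2. **Predict and assemble together** (`mars_sdm()`, `mann_sdm()`): one
   multi-response model predicts every species at once, either through
   a shared adaptive-splines basis or a shared hidden layer, so that
   rare species can borrow strength from the community signal.
3. **Assemble then predict** (`rivpacs_sdm()`): the classic
   RIVPACS-style community-classification model — cluster the
   reference-site biota, learn the cluster from the environment, and
   predict each species as its membership-weighted average group
   frequency.

Each fitted model predicts a site-by-species matrix of occurrence
probabilities; sites are then scored with the taxonomic completeness
index O/E (at a probability cut-off, default 0.5) and the Bray–Curtis
dissimilarity between observed occurrences and raw probabilities.

## The models

### Single-species ensemble

For each species, each learner family is fit on ten random 80/20
split-validation repeats; each candidate is scored on its holdout by
the true skill statistic, TSS = sensitivity + specificity − 1, at the
binarization threshold that maximizes TSS over the candidate's observed
predicted values. (A fixed 0.5 threshold is available via
`ens_config(tss_threshold = "fixed")`; the optimized default avoids
systematically penalizing low-prevalence species.) Candidates with
TSS > 0.8 are retained; if none qualify the rule falls back to
TSS > 0.7, and failing that the single best candidate is kept, flagged
`best-available`. The ensemble prediction is the unweighted arithmetic
mean of the retained members' probabilities, each member predicting
with its split-trained fit — members are never refit on the full data.
Candidate splits are stratified by presence/absence so that a species
occurring at 3 of 103 sites still places presences on both sides of
every split; without stratification a fifth of the repeats for such a
species would have no presence to validate against.

### Multi-response adaptive splines

The forward pass grows paired hinge functions `max(0, ±(x − knot))`,
choosing each split point to minimize the squared error summed over
*all* species responses, so every species shares one basis; first-order
interactions are allowed (`max_degree = 2`) and candidate knots are
quantiles of each predictor. The backward pass prunes by generalized
cross-validation with a cost-per-basis penalty (default 2, selectable
over {0.5, 1, 1.5, 2, 2.5} by cross-validated mean species AUC with
`select_penalty = TRUE`). Because the model fits `S` coefficient sets
to `S` response columns on a shared basis, the GCV is computed on the
stacked regression: `N = sites x species` cells, with effective
parameters `S·M + penalty·(M − 1)` for `M` basis functions — the knot
cost is paid once, the coefficients once per species. With a single
response this reduces exactly to the textbook
`M + penalty·(M − 1)` count (which is what the ensemble's
adaptive-splines member uses). A per-row GCV would prune any
25-species model to a near-intercept, because binary responses leave a
large irreducible Bernoulli residual that no basis can remove. After
pruning, each species gets a logistic-regression refit on the retained
basis, so predictions are genuine probabilities; a constant species
keeps an intercept-only mapping equal to its prevalence.

### Multi-response neural network

A single-hidden-layer network with logistic output units (one per
species) and squared-weight decay on all weights, fit via `nnet`.
Predictors are standardized internally, making predictions invariant
to affine rescaling of the inputs. The structure — hidden-node count
and decay — is chosen by the highest mean cross-validated species AUC
over a grid; the default grid is {0, 1, 3, 5, 7, 10} hidden nodes
(0 = a direct input-output logistic layer, realized with skip
connections) by decays {0.001, 0.003, 0.01, 0.03, 0.1}. The full 0–20
node range is accepted; the coarse default keeps the search affordable
without changing what it can find in these small-n settings. Because
the objective is non-convex, the final model is the best of 10 random
initializations by mean species AUC.

### RIVPACS community classification

Sørensen dissimilarity `1 − 2a/(2a + b + c)` is computed between all
reference-site pairs (two empty sites are assigned d = 0 by convention
and logged, so sites emptied by filtering remain clusterable — vegan's
`vegdist` returns NaN there, which is why the matrix is built
in-package and cross-checked against vegan on non-degenerate data).
Sites are clustered by flexible-beta agglomeration under the
Lance–Williams update with β = −0.6. Two variants are provided:
the default size-weighted coefficients
`alpha_i = (1 − β)·n_i/(n_i + n_j)` ("flexible UPGMA") and the
size-unweighted `alpha_i = (1 − β)/2`. Both satisfy
`alpha_i + alpha_j + β = 1`, which guarantees monotone merge heights;
with β = −0.6 the scheme is space-dilating, so heights may exceed the
[0, 1] input range — that is expected, not an error. Ties are broken
towards the lowest cluster-index pair, making the tree deterministic.
The tree is cut into a configured number of groups (default 6, the
kind of choice practitioners make by inspecting the dendrogram;
`silhouette_widths()` reports a descriptive aid but never decides).
Groups smaller than `min_group_size` are merged into the nearest group
by average cophenetic dissimilarity, with a log note. Group membership
of new sites is predicted either by linear discriminant analysis with
backward stepwise elimination, or by a random forest. Classical DFA
has no canonical AIC, so the stepwise criterion is defined on the
multinomial assignment likelihood of the posterior probabilities with
`(G − 1)(p + 1)` parameters; priors are proportional to group sizes.
Species probabilities are the membership-weighted group frequencies
`p_s(x) = Σ_g P(g|x)·f_{s,g}`, which are therefore always bounded by
the extreme group frequencies — the structural reason these models are
conservative about which taxa can ever exceed a 0.5 threshold
(`predictable_taxa()` counts them).

## Indices and evaluation

`oe_index()` defines E as the sum of probabilities above the threshold
and O as the count of *those same taxa* that were observed (the
standard RIVPACS-family convention; taxa predicted below threshold
never enter either term). A site where no probability clears the
threshold has an undefined O/E; it is flagged and excluded from
summaries rather than scored. `bray_curtis()` uses all species with
raw probabilities — "threshold 0" is read as "no taxa excluded,
probabilities not binarized". Assemblage summaries report accuracy
(mean O/E), precision (SD and the 90th-minus-10th percentile
bandwidth; percentiles use R's default type-7 linear interpolation,
recorded here because the bandwidth depends on the convention), fit
(squared Pearson correlation of O and E) and bias (least-squares
regression of O *on* E — "O vs E" is read with O as the response).
Species-level metrics are rank-based AUC (ties half-credit),
sensitivity, specificity, CCR and Cohen's kappa at the threshold;
metrics undefined for single-class species are NA and excluded from
cross-species averages, mirroring the evaluation of species absent
from an external dataset. Strategies are compared by one-way ANOVA
with Tukey HSD letters; the replication unit is whatever vector you
pass (`compare_strategies()` is agnostic) — species for species-level
metrics, sites for assemblage-level ones.

Variable importance follows each strategy's own literature:
permutation (ensemble), deviance loss on basis removal (MARS),
connection weights (MANN), F-to-remove from the partial Wilks' lambda
(DFA), Gini impurity decrease (random forest). Scores become
within-strategy ranks; `aggregate_ranks()` averages ranks over the
strategies that retained a variable, leaving unretained variables
absent rather than penalized.

## What the synthetic generator emulates — and what it does not

`synthetic_benchmark()` produces the dataset suite the evaluation
design needs, at the reference shapes: 128 sites split 80/20 into 103
training and 25 spatial-holdout sites, 79 sites resampled under a
seasonal niche shift, 23 sites revisited ~15 times (~331 site-occasion
rows, with a few visits dropped as in real monitoring programs), and
33 sites observed under a different protocol with imperfect detection
(default 20% missed presences, 2% spurious ones). Environments are
linear combinations of two latent axes — the dominant one playing the
elevation-like upland–lowland gradient — plus noise, with one variable
pair deliberately collinear (|r| > 0.8) so the screen always has work.
The default species pool has 25 species whose target prevalences are
the spectrum of a subtropical coastal stream-fish assemblage, spanning
3–95% with seven species under 10%; `max_prob` of each niche is
calibrated by quadrature so realized prevalences match the targets,
and the sum of prevalences (6.52) fixes the expected per-site richness
at ~6.5. High-prevalence species get monotone logistic responses,
the rest unimodal Gaussian niches spread along the gradient, central
optima going to the more prevalent species.

What the generator does **not** emulate: residual co-occurrence (cells
are independent Bernoulli given the environment, so richness varies
less between sites than in field data — an optional shared site effect
`site_effect_sd` reintroduces some of it, off by default); dispersal
barriers and river-network topology; detection error in the training
data; and abundance. Passing tests therefore demonstrate that the
algorithms are implemented correctly and recover known structure under
the stated conditions — not that any strategy will rank the same way
on a particular field dataset.

## Numerical choices and degenerate inputs

* Binary matrices reject any cell outside {0, 1} with the offending
  row and column named; duplicate site ids are structural errors.
* The collinearity screen iterates on the worst pair; the default
  victim is the member with the larger mean absolute correlation with
  all other variables (a deterministic stand-in for the expert
  judgement the screen would otherwise need), overridable with
  `priority_order`. Zero-variance columns are dropped with a note.
* `split_sites()` gives the training side `ceiling(fraction·n)` sites
  — an 80% split of 128 sites is 103/25 — and repeated-visit rows
  always travel with their site.
* One global seed fans out deterministically to every stage; identical
  config + seed reproduces byte-identical CSV outputs.
* Learner failures inside the ensemble are flagged and excluded, never
  silently imputed; a species with a single class refuses to fit.
* Test and example problem sizes (hundreds of sites, 4–25 species) are
  the package's choices for demonstrating each property at comfortable
  statistical resolution.

## Known limitations

* The discriminant path assumes roughly continuous, non-degenerate
  predictors within groups; heavily categorical predictors belong with
  the random-forest classifier.
* The stepwise AIC is greedy backward only, as in standard practice;
  it will not revisit a dropped variable.
* O/E bandwidth depends on the percentile convention (type 7 here);
  compare bandwidths across packages only under the same convention.
* The MARS forward pass caps candidate knots at per-variable quantiles
  (`max_knots`), trading a little knot resolution for speed.
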