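---
title: "Methods: semantic networks, distributional scoring, and the SemExp model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic networks, distributional scoring, and the SemExp model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`semexplore` analyses word association data collected under instructed search
strategies. Participants see target words and produce free associations under
three instructions: respond with an *ordinary* association (OR), a *random*
one (RA), or a *creative* one balancing the two (CR). The package quantifies
how the three strategies reorganise semantic memory search along three
complementary routes — network topology, distributional semantics, and a
one-parameter reinforcement-learning model of response generation — and ships
a synthetic-data generator with known ground truth so the full pipeline can be
exercised and tested without access to restricted child data.

## The analysis pipeline

### Preprocessing

`clean_responses()` lowercases responses, strips characters other than
letters and hyphens (multi-word answers become hyphenated compounds), drops
stop-words and empty strings, applies an optional user-supplied
singularisation/correction map, and removes any response equal to or
containing its target word (substring match on lowercased forms — the match
granularity is our choice; the coarser rule errs on the side of exclusion).
*Idiosyncratic* responses are defined as response strings produced by exactly
one participant within a condition; their removal is a flag, on for network
construction (a response given by a single participant carries no overlap
signal) and off for the distributional and SemExp analyses, whose vocabulary
is all unique sample responses. `fluency()` counts responses per participant
and condition; `first_two_subset()` keeps the first two responses per
participant-target cell as a fluency-controlled replica of every analysis.

### Semantic networks

For each condition, `build_count_matrix()` arranges the data as a
responses-by-targets matrix whose cells count the *distinct participants*
giving that response to that target. `cosine_network()` links two targets by
the cosine similarity of their count columns: overlap in who-said-what binds
targets together. All-zero columns (a target with no surviving responses)
get similarity 0 with a warning rather than NaN.

`tmfg_filter()` sparsifies the dense similarity matrix to a Triangulated
Maximally Filtered Graph: seed with the 4-clique of maximal total weight,
then repeatedly insert the outside vertex with the highest summed similarity
to an existing triangular face, splitting that face in three. The result has
exactly `3n - 6` edges and is planar by construction; the face list is kept
as a certificate that `is_planar_triangulation()` verifies through Euler's
formula (`2n - 4` triangular faces, every edge on exactly two faces). Ties
are broken by lowest node index so the filter is reproducible. Because
insertion compares sums of three weights, adding a constant to all
similarities leaves the edge set unchanged.

`topology()` computes, on the binarised filtered graph: the global
clustering coefficient CC (transitivity, 3 x triangles / connected triples),
the average shortest path length ASPL, the modularity Q of the partition
found by igraph's greedy modularity maximisation, and small-worldness
`S = (CC / CC_rand) / (ASPL / ASPL_rand)` against means over `n_random = 100`
connected Erdős–Rényi graphs with matched nodes and edges (the count is our
choice; 100 replicates put the Monte-Carlo error of S well below the
between-condition differences of interest). Quantifiers are computed
unweighted by default — the networks under study are displayed and compared
as unweighted graphs — with a `weighted` flag switching ASPL (distances
`1/w`) and Q to weighted variants. Whether modularity should be weighted or
binary is genuinely open; both are exposed.

Robustness is assessed two ways: `lono_topology()` deletes one node at a
time from the filtered graph *without* re-running the filter (drop-node
semantics; if deletion disconnects the graph the largest component is used
and flagged), while `loso_topology()` removes one participant and re-runs
the entire pipeline — count matrix, cosine, TMFG, quantifiers. The two
procedures deliberately differ in what they hold fixed.

### Percolation

`percolation_curve()` attacks the *unfiltered* weighted network: at each
threshold, edges with weight strictly below it are removed (edges equal to
the threshold survive) and the size of the largest connected component
(LCCS) is recorded. The threshold grid is the ascending set of unique edge
weights, where the LCCS can change; the process stops once the LCCS falls
below three nodes. The percolation integral `phi` summarises robustness as
the area under the LCCS curve, computed as the left Riemann sum
`sum_i LCCS(th_i) (th_{i+1} - th_i)` over the steps before termination. A
note on this convention: between unique weights the LCCS is right-continuous
in the threshold, so the left sum upper-bounds the pointwise-exact area and
a fine-grid evaluation converges to the exact area; the discrepancy is
bounded by the largest step width times the total LCCS drop, and the test
suite asserts exactly that bound. The alternative reading of the integral —
the sum of LCCS values weighted by their threshold — is available as
`phi(net, method = "weighted")`.

Because higher fluency mechanically inflates association overlap,
`normalize_fluency()` first divides each condition's weights by the ratio of
its mean fluency to the lowest-fluency (CR) condition; with mean fluencies
172.52 / 130.96 / 78.45 this yields factors 2.20 (RA) and 1.67 (OR).
Dividing the higher-fluency conditions (rather than multiplying the
reference) is our reading of an under-specified normalisation; it preserves
the CR scale.

`percolation_significance()` provides four stability analyses: LONO and LOSO
as above; link shuffling (LS), which swaps the weights of random edge pairs
— ten passes over the edge set per iteration, so a 114-edge TMFG receives
~1,140 swaps — preserving the weight multiset while destroying its
placement; and a noise analysis adding Gaussian perturbations with a
standard deviation drawn uniformly from `[1e-4, 1e-3]` per iteration, with
weights clipped at zero. LS is meaningful on either the filtered or the
unfiltered graph; the swap-count convention of ten passes per link matches
the filtered edge count, so LS defaults to whatever network it is handed and
the caller chooses.

### Distributional semantics

Word meanings come from word2vec-format embedding tables
(`read_word2vec()`/`write_word2vec()`), several of which are combined by
`average_embeddings()`: each word's vector is the element-wise mean over the
models that contain it, and words missing from all models are excluded with
a report. The semantic distance between two words is one minus their cosine
similarity, in `[0, 2]`. Each target and response is assigned to the
category word minimising this distance (ties go to the lowest index, with a
warning), and the category-switching indicator is 1 when target and response
map to different categories. `participant_summaries()` averages distance and
switching per participant and condition — the units on which all inference
runs. `model_space_correlation()` checks that the per-model distance
structures correlate strongly enough to justify averaging.

### The SemExp model

The Semantic Explorer model treats response generation as softmax action
selection over a semantic value function. `build_value_matrix()` derives
nonnegative values from the consensus embedding as the *inverse* of the
semantic distance — by default the reciprocal `1 / max(sd, 1e-6)` (the
epsilon floor guards the degenerate zero-distance case), with the bounded
alternative `2 - sd` selectable. Both satisfy the nonnegativity requirement;
the reciprocal is the more literal reading of "inverse" and is the default.

Given a target's value row `x`, the policy is
`P(word i) = exp(beta x_i) / sum_j exp(beta x_j)`, computed with
max-subtraction. The inverse temperature `beta` is the model's single free
parameter: `beta < 1` means exploratory, near-uniform sampling; large `beta`
exploits the highest-value words. `beta = 0` is exactly uniform.

Fitting stacks all responses of one participant-condition cell and minimises
the summed negative log-likelihood by plain gradient descent with the
analytic gradient (the NLL is convex in `beta`): learning rate 0.01,
convergence declared when the NLL change stays below `1e-7` for 20
consecutive iterations, at most 10,000 iterations, 10 restarts initialised
uniformly in `[0.5, 5]`, best restart reported. `beta` is unconstrained
during descent — negative excursions are allowed and reported, since
sub-unity values are meaningful. The NLL is summed, not averaged, over a
cell's responses. `grid_landscape()` evaluates the NLL on a 50-point linear
grid over `[0.1, 5]` for loss-landscape inspection.

`model_selection()` compares three nested accounts per cell: a null model
(uniform over the `k` vocabulary words, NLL `n log k`), the parameter-free
WordEmb model — our reading of "the first component only" is each value row
normalised to sum to one, used directly as the choice distribution — and the
fitted SemExp model. Because `beta = 0` reproduces the uniform null exactly,
the fitted NLL is bounded by the null NLL in every cell; WordEmb, by
contrast, is *not* nested in the softmax family, so on model-generated data
the ordering SemExp <= WordEmb <= null holds in the group mean and in almost
every cell, but isolated low-beta cells can favour WordEmb by chance. The
suite asserts the ordering at that group level.

`parameter_recovery()` simulates the recovery experiment: one true `beta`
per participant-condition cell drawn uniformly from `[0.1, 4]`, response
counts at the condition's mean fluency, i.i.d. draws from the policy, a
refit of every cell, and the Pearson correlation between true and fitted
values. At the study's sample sizes this correlation is ~0.99 on the default
synthetic spaces.

### Inference

`paired_perm_ttest()` uses the parametric paired t statistic as the observed
value and a sign-flipping null (10,000 iterations by default) with the
add-one rule, so `p >= 1/(n_iter + 1)`; zero-variance difference vectors
return `p = 1` with a warning rather than an undefined statistic. Effect
sizes are paired Cohen's d (mean over SD of differences) with noncentral-t
confidence intervals; the analytic interval was chosen over a bootstrap for
determinism. Three pairwise condition contrasts are Bonferroni-corrected to
`alpha = 0.05 / 3 ~ 0.017`. Rater agreement uses the two-way fixed-effects
consistency ICC for the average of k raters, ICC(3,k), computed from
closed-form balanced ANOVA mean squares (items can number in the thousands);
the single-measures ICC(3,1) sits behind a flag. The average-measures
variant reflects that analyses consume rater means.

## The synthetic generator

`synth_config()` fixes the study conditions: 56 participants, 40 targets in
10 categories, 300-dimensional embeddings from 3 model spaces, a ~3,300-word
response pool, condition inverse temperatures `OR 2.47, CR 2.34, RA 0.76`,
condition mean fluencies `OR 130.96, CR 78.45, RA 172.52`, and 8 raters.

`make_embedding_spaces()` places all words in one latent space — Gaussian
category centroids with members scattered around them
(`within_category_sd = 0.7`, giving clear but overlapping categories) — and
derives each model space as an independent random rotation plus additive
noise (`cross_model_noise = 0.35`, calibrated once so that per-model
distance structures correlate at r ~ 0.9, comfortably above the 0.83
consistency bound the real models exhibit). The shared latent space is a
deliberate idealisation: real corpora-trained models are not geometrically
aligned, but element-wise averaging is only meaningful if the spaces are,
so the generator makes the operation well-defined by construction.

`simulate_responses()` draws per-target response counts as Poisson with mean
`fluency_mean / 40` — the simplest count model consistent with the condition
totals, since only totals are specified; how responses spread over targets
within the one-minute window is unknown — and samples responses from the
SemExp policy at the condition's beta, without replacement within a
participant-target pair (people rarely repeat themselves). Parameter
recovery instead samples with replacement, i.e. faithfully from the model
being fitted. A configurable 2% of dirty rows (uppercase, punctuation,
target-containing, stop-word, and nonword responses) is injected to exercise
every preprocessing rule.

`simulate_ratings()` scores unique target-response pairs of one target per
category on three 5-point scales whose latent values are deterministic
transforms of semantic distance — novelty `1 + 2 sd` (increasing),
appropriateness `5 - 2 sd` (decreasing), creativity `5 - 4 |sd - 1|` (peaked
at intermediate distance) — plus a rater-specific leniency and per-rating
Gaussian noise, discretised to 1..5. The noise defaults
(0.35 / 0.25 / 2.5) were calibrated once so the resulting ICCs land near the
agreement levels observed in comparable rating studies (~0.93 / 0.96 / 0.61);
the variance-components prediction
`ICC(3,k) = v / (v + (sigma^2 + 1/12) / k)` (the `1/12` being discretisation
variance) is the oracle the tests check against at moderate noise, where
clipping at the scale ends is negligible.

**What the generator does not emulate.** Tokens are synthetic letter strings
with no lexical realism; category structure is isotropic Gaussian rather
than the anisotropic topology of real lexical semantics; response counts are
Poisson rather than bursty; and the three "models" share a latent geometry
by construction. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that its qualitative contrasts (fluency ordering
RA > OR > CR, distance ordering OR < CR < RA, beta ordering OR > CR > RA,
percolation robustness CR > OR > RA) follow from the configured conditions —
not that any particular numeric value would replicate on real child data.

## Numerical choices and degenerate inputs

* Probabilities of observed choices are clamped at `1e-12` in the NLL, with
  a warning, so a single impossible response cannot produce an infinite
  loss.
* The softmax is always computed with max-subtraction; at extreme beta the
  without-replacement sampler falls back to sequential renormalised draws
  when all but a few probabilities underflow.
* All-equal edge weights give a single-step percolation curve with
  `phi = 0` under the left-sum convention (one step of zero width), with a
  message.
* The garbled noise-range specification for the percolation noise analysis
  is read as sigma in `[1e-4, 1e-3]`.
* Every stochastic routine takes an explicit seed; `run_all()` derives all
  stage seeds from one master seed, and two runs with the same
  configuration are bit-identical.

## Problem sizes used by the test suite

The unit tests run the full pipeline on a scaled-down study (8 participants,
50-dimensional embeddings, 300-word vocabulary) chosen so that every
qualitative property of the full configuration — orderings, recovery,
network sizes — already holds; the parameter-recovery acceptance check runs
at the full 56 x 3 scale. The group beta-ordering checks use 12 or more
participants: the OR-CR contrast is only 0.13 in beta units, and with fewer
participants its sampling error approaches the contrast itself.

## Limitations

The package implements edge-threshold (bond) percolation only, not node
removal; TMFG is the stated greedy heuristic, not an exact maximal-planar
optimisation; no lemmatiser or dictionary validation backs the cleaning
rules beyond the alphabetic-character test; and t-SNE projections of the
embedding spaces are left to the user's preferred visualisation tooling.
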