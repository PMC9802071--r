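# semexplore

Semantic networks and reinforcement-learning models of word association
search.

`semexplore` is an R package for analysing word association task (WAT) data
collected under instructed search strategies. In the paradigm it supports,
participants produce free associations to target words under three
instructions — an *ordinary* association (OR), a *random* one (RA), or a
*creative* one balancing appropriateness and novelty (CR) — and the package
quantifies how each strategy reorganises semantic search. It is aimed at
researchers in creativity, semantic cognition, and computational modelling
of memory search.

Three complementary analysis routes are implemented end to end, together
with the statistics used to compare conditions and a synthetic-data
generator with known ground truth (useful because raw child data in this
area are typically access-restricted):

* **Semantic networks.** Per condition, a response-by-target count matrix
  (cells = number of participants giving response *n* to target *m*) is
  turned into a weighted network whose links are cosine similarities between
  target columns, sparsified with the Triangulated Maximally Filtered Graph
  (TMFG, `3n - 6` edges, planar by construction), and summarised by the
  clustering coefficient CC, average shortest path length ASPL, modularity
  Q, and small-worldness `S = (CC/CC_rand)/(ASPL/ASPL_rand)` against matched
  Erdős–Rényi baselines, with leave-one-node-out and leave-one-subject-out
  resampling.
* **Percolation.** Unfiltered networks, fluency-normalised, are attacked by
  removing edges below a rising threshold; the robustness integral φ is the
  area under the largest-connected-component curve. Link-shuffling and
  noise perturbations probe the stability of φ.
* **The SemExp model.** Response generation is modelled as softmax action
  selection over a semantic value matrix built from word embeddings:
  `P(response i | target) = exp(β x_i) / Σ_j exp(β x_j)`, with a single
  inverse temperature β per participant and condition (β < 1 exploratory,
  β > 1 exploitative), fitted by gradient descent on the negative
  log-likelihood and compared against uniform-null and parameter-free
  WordEmb baselines. Word-level scores — semantic distance
  `1 - cos(x, y)` and a nearest-category switching indicator — feed the
  distributional analysis.

Inference throughout uses paired two-tailed sign-flip permutation t tests
(10,000 iterations, Bonferroni-corrected α = 0.017 for three contrasts),
paired Cohen's d with noncentral-t confidence intervals, and two-way
fixed-effects ICC(3,k) for rater agreement.

See the methods vignette (`vignettes/semexplore-methods.Rmd`) for the full
model descriptions, parameter defaults, and design decisions.

## Worked example

The pipeline runs end to end on synthetic data with a single call. Here a
reduced study (12 participants instead of 56, and light resampling
settings) keeps the runtime around two minutes:

```r
library(semexplore)

cfg <- run_config(
  synth_cfg   = synth_config(n_participants = 12L, seed = 7L),
  n_random    = 50L,   # ER baselines for small-worldness
  perc_n_iter = 20L,   # link-shuffling / noise iterations
  stat_n_iter = 2000L, # permutation iterations
  semexp_ctrl = semexp_control(n_restarts = 3L),
  seed = 7L)
run <- run_all(cfg)
print(run)
```

```
Word association pipeline run
  responses: 4674 cleaned rows, 12 participants
  fluency means: OR 135.5, CR 81.6, RA 172.4
  topology:
 condition        cc     aspl         q        s provenance
        OR 0.4666667 2.706410 0.5113496 2.660344       full
        CR 0.3474664 2.117949 0.4355571 2.531174       full
        RA 0.4546685 2.823077 0.4702986 2.484830       full
  percolation phi: OR 2.357, CR 5.374, RA 1.672
  mean fitted beta: CR 2.27, OR 2.45, RA 0.76
  rater ICC: appropriateness 0.96, creativity 0.55, novelty 0.94
```

Reading the output: response fluency is highest under the random
instruction and lowest under the creative one (RA > OR > CR); the creative
condition's network survives percolation longest (φ: CR > OR > RA),
the hallmark of a flexible-but-organised semantic structure; and the fitted
inverse temperatures recover the generating exploration levels — near 0.76
for RA (exploratory, β < 1) and above 2 for OR and CR (exploitative), with
OR > CR. Per-contrast permutation tests accompany every summary, e.g. for
semantic distance:

```r
print(run$distsem$sd_tests, row.names = FALSE, digits = 3)
#>  comparison      t      p       d    d_lo   d_hi alpha_corrected
#>    CR vs OR   2.78 0.0135   0.803   0.134   1.44          0.0167
#>    OR vs RA -59.83 0.0010 -17.272 -24.119 -10.15          0.0167
#>    CR vs RA -41.96 0.0015 -12.112 -16.930  -7.10          0.0167
```

(At small sample sizes a few targets may end up with no shared responses
after idiosyncratic-response removal; the pipeline warns and assigns those
columns zero similarity.)

`write_report(run, "out/")` serialises the tables as CSV, the networks as
GraphML, and a seed manifest as JSON.

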