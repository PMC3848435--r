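---
title: "Word-composition models behind afclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Word-composition models behind afclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(afclust)
```

## The problem

High-throughput sequencing runs produce tens of millions of short reads
(30–500 bp). When a sample is too large to assemble in one piece, one wants
to split the reads into groups that are likely to come from the same genes
or organisms and assemble each group separately. At that scale alignment is
off the table, so the only usable signal is sequence *composition*: each
read is summarized by the counts of the $4^n$ possible words (n-mers) it
contains, and reads are clustered in that $4^n$-dimensional space.
Centroid-based clustering is the natural choice because it is linear in the
number of reads, unlike hierarchical ($O(N^2)$) or density-based methods.

`afclust` implements this program end to end: word counting, eight centroid
engines, bootstrap consensus, evaluation against known read origins, and a
read simulator to exercise all of it.

## The multinomial model and KL divergence

The generative model treats the words of a read as independent draws from a
pool with frequencies $q_i$, $i = 1, \dots, 4^n$. For a read with counts
$c_i$ and total word count $L = \sum_i c_i$, Stirling's approximation turns
the multinomial log-probability into

$$\log P(\mathbf{c} \mid \mathbf{q}) \approx -L\, D_{KL}(\mathbf{p}
\,\|\, \mathbf{q}), \qquad p_i = c_i / L,$$

with $D_{KL}(\mathbf{p}\|\mathbf{q}) = \sum_i p_i \log(p_i/q_i)$ in natural
logarithms. KL divergence is therefore not a heuristic distance here but the
exact (length-scaled) negative log-likelihood, which is what licenses the EM
machinery:

* **Hard EM** (`method = "em"`) alternates assigning each read to the
  centroid minimizing $L_a D_{KL}(\mathbf{p}^a \| \mathbf{q}^\alpha)$ with
  recomputing each centroid as its members' pooled word counts, plus a
  pseudocount, renormalized. The distortion
  $D = \sum_a L_a D_{KL}(\mathbf{p}^a\|\mathbf{q}^{z_a})$ never increases,
  so the iteration terminates (at unchanged assignments).
* **Soft EM** (`method = "soft_em"`) keeps a membership probability
  $Z_{a\alpha} \propto P(\mathbf{p}^a \mid \mathbf{q}^\alpha)$ (equal
  cluster priors) and updates centroids from membership-weighted pooled
  counts. The weights $\exp(-L_a D_{KL})$ underflow for realistic $L$, so
  the E-step is computed in the log domain with max-subtraction.

The factor $L_a$ matters: a long read's composition estimate is more
reliable, and the likelihood automatically weighs it more. Engines that
operate on per-read normalized vectors (`l2`, `d2`) deliberately discard
this weighting and treat short and long reads alike.

### What is, and is not, monotone in soft EM

For hard EM the distortion decreases at every step and the package asserts
this in its tests. For soft EM the quantity with the guarantee is the
*marginal* log-likelihood $\sum_a \log \frac{1}{K} \sum_\alpha
P(\mathbf{p}^a\mid\mathbf{q}^\alpha)$, stored per iteration as
`log_likelihood_trace`. The *expected complete-data* log-likelihood
$-\sum_{a\alpha} Z_{a\alpha} L_a D_{KL}(\mathbf{p}^a\|\mathbf{q}^\alpha)$
(stored in `trace` and reported as `expected_log_likelihood`) is **not**
monotone: the E-step maximizes the free energy — this expectation *plus*
the membership entropy — so whenever an E-step spreads memberships, the
expectation itself can dip while the free energy still rises. On simulated
read sets the dips are real but small (typically $10^{-4}$–$10^{-3}$ of the
objective, observed in roughly 40% of random instances). An independent
straight-loop EM reproduces the same dips exactly, and the marginal
likelihood of the same runs is monotone to $10^{-9}$, which is how we
distinguish a property of the algorithm from a bug in the implementation.
Convergence is therefore declared on memberships
($\max |\Delta Z| <$ `tol`), not on either likelihood.

## The other dissimilarities

* **L2** — Euclidean distance between per-read simplex frequencies; the
  centroid update is the member mean.
* **k-means** — L2 after dividing every frequency coordinate by its
  across-dataset standard deviation (whitening), computed once on the
  input. Centroids are reported de-whitened. Zero-variance coordinates are
  left unscaled.
* **d2** — $1 - \cos\theta$ between word-count vectors normalized to unit
  Euclidean norm. The minimizing centroid is the renormalized vector sum of
  member unit vectors, so the update is exact and the iteration converges.
* **d2\*** — both the read's counts and the cluster's pooled counts are
  standardized against the cluster's zero-order Markov expectation
  ($\tilde{x}_i = (x_i - Q_i S)/\sqrt{Q_i S}$ with
  $Q_w = \prod_{\text{bases } b \in w} f_b$ from the pooled
  single-nucleotide frequencies of the cluster), and compared by
  $\tfrac12(1 - \cos)$, which stays in $[0,1]$ although standardized
  entries may be negative.
* **chi-squared** — the Pearson statistic
  $\sum_i (c_i - Q_i L)^2 / (Q_i L)$ of read counts against the same
  cluster-level expectation.
* **symmetrized KL** — $\sum_i (p_i - q_i)\log(p_i/q_i)$, identically
  $D_{KL}(p\|q) + D_{KL}(q\|p)$.

The last three have no known convergence proof, and d2\* genuinely cycles:
the package ships a six-read configuration on which the d2\* assignment map
provably oscillates with period 2 (found by exhaustive search over initial
assignments). Such runs stop at `max_iter` with `converged = FALSE` and a
warning; this mirrors the observation that d2\* clustering occasionally
fails to converge in practice.

## Numerical and design choices

* **Word indexing** is lexicographic over `A < C < G < T` everywhere,
  including serialized centroids; counting is delegated to
  `Biostrings::oligonucleotideFrequency`, whose conventions match
  (windows containing non-ACGT characters are skipped, deterministically).
* **Pseudocount** (default 1) is added to pooled centroid counts so
  centroid frequencies are strictly positive and KL stays finite; per-read
  vectors are left raw, since $0 \log 0 = 0$ makes read-side zeros
  harmless. The one exception is the symmetrized-KL engine, where a
  read-side zero against a positive centroid frequency makes the distance
  infinite; that engine therefore pseudocounts the read frequencies too.
* **Initialization** assigns reads to clusters uniformly at random
  (seeded) and takes one update step — this always produces valid simplex
  centroids, unlike picking random points.
* **Ties** in any argmin/argmax go to the lowest cluster index, making
  runs bit-reproducible given a seed.
* **Empty clusters** (possible after any assignment step) are by default
  reseeded with the read farthest from its current centroid, with a
  message; `empty_cluster = "fail"` reproduces the strict behaviour where
  the run is abandoned instead.
* **Restarts** rerun the whole fit with seeds `seed`, `seed + 1`, … and
  keep the minimal-distortion (or maximal-likelihood) run. Restarts matter
  more than they may appear: single-restart EM occasionally lands in a
  visibly worse local optimum, which is also why the package's own trend
  experiments (below) use 3 restarts.
* **L2 normalization** of per-read vectors is on the simplex by default
  (`l2_scheme = "unit_norm"` switches to the d2-style convention); with
  word frequencies the two differ only by a per-read scale.
* Reads whose total word count is zero (e.g. all-N) are dropped with a
  warning before clustering, as their composition is undefined.

## Consensus clustering

`consensus_cluster()` repeats a hard clustering `runs` times on random
subsamples (default fraction 0.8, chosen as a conventional bootstrap
compromise; the method itself prescribes none) and summarizes co-clustering
as $D_{ij} = 1 - \#\text{together}/\#\text{co-sampled}$, followed by an
average-linkage tree cut into $K$ groups. Pairs never co-sampled get
$D_{ij} = 1$ with a warning — the conservative resolution of a case the
formula leaves undefined; the alternative (adding runs until coverage) has
unbounded runtime and was rejected.

## Evaluation

With known read origins, `recall_rate()` reports, per gene, the largest
fraction of its reads landing in one cluster — the quantity that predicts
how little a pre-assembly split will fragment that gene's contig. For soft
fits, thresholding memberships at $\varepsilon$ yields overlapping cluster
sets; `roc_curve()` sweeps $\varepsilon$ over all distinct membership
values (an exact sweep, affordable because the grid is at most $N K$
values), recomputing at each threshold which cluster "correctly" captures
the gene (ties to the lowest index), and closes the curve with its limits
$(1,1)$ at $\varepsilon \to 0$ and $(0,0)$ at $\varepsilon \to 1$. Because
clusters overlap, a read can be a true and a false positive simultaneously
— this is deliberately *not* a classical ROC, and the trapezoid AUC is
reported on the curve as defined.

## The read simulator, and what it does not emulate

`generate_sources()` draws each source i.i.d. from its own base
composition; `simulate_reads()` picks a source proportional to its length,
a uniform start, optionally a random strand, and applies substitution-only
errors (each hit base replaced by a uniformly chosen different base). The
defaults are chosen once as study conditions: source lengths 500–10000 bp
(typical mRNA span), GC contents evenly spaced on [0.35, 0.65] unless given
explicitly, reads from both strands. Simulating from zero-order models
means every read *exactly* satisfies the compositional assumption of the
clustering model. Real transcripts do not: composition drifts along a
genome, and viral composition mimics the host. Passing tests on this
simulator therefore validate the machinery — estimators, updates,
monotonicity, bookkeeping — and the qualitative trends (recall grows with
read length, falls with error rate and with the number of clusters), not
absolute recall values on real data, which are set by how compositionally
distinct real sources are.

Problem sizes in the test suite were likewise chosen as desk-scale study
conditions: trend experiments use 2 fixed sources at GC 47%/53% (close
enough that the length effect is far from its ceiling), 500 reads per
replicate, 10 replicates per condition, with read draws paired across error
rates through a shared seed (common random numbers); the recovery
experiment uses the classic well-separated setting, GC 30%/70% with 1000
reads of 200 bp; exhaustive-enumeration cross-checks run at $N = 8$ reads
where all $2^8$ assignments can be scored.

## Worked example

```{r example}
sources <- generate_sources(2, c(500, 1500), gc = c(0.35, 0.65), seed = 1)
reads <- simulate_reads(sources, num_reads = 300, read_length = 100,
                        error_rate = 0.01, seed = 2)
fit <- af_cluster(reads, k = 2, method = "em", n = 2, seed = 3, restarts = 3)
glance(fit)
recall_rate(fit, reads)
```

```{r soft}
soft <- af_cluster(reads, k = 2, method = "soft_em", n = 2, seed = 3)
roc <- roc_curve(soft, reads, "source_1")
glance(roc)
```

```{r plot, fig.width = 5, fig.height = 4}
autoplot(roc)
```

## Known limitations

* Word sizes are capped at $n \le 8$; beyond $n = 3$ short reads give
  sparse counts and the multinomial approximation degrades (the model
  wants $L \gg 4^n$).
* Consensus clustering is $O(N^2)$ in memory and is meant for thousands,
  not millions, of reads.
* The d2\*, chi-squared and symmetrized-KL engines can fail to converge by
  design of the underlying iteration; they report it rather than hide it.
* No indel or quality-score model in the simulator; substitutions only.
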