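# phenomi

Quantifying, in bits, how much information about a dynamic cellular
phenotype is carried by mRNA abundance measured in the same cell.

## The problem

Multimodal single-cell experiments can pair transcript counts for a gene
panel with a live-cell recording of a dynamic phenotype — for example the
cytoplasmic Ca²⁺ response of each cell to an ATP stimulus, imaged for
hundreds of timepoints before the same cells are fixed and their
transcripts counted. Correlation coefficients between single genes and
single trace features barely scratch such data: the dependence is
nonlinear, distributed over gene combinations, and partly redundant.
`phenomi` measures it directly with information theory:

* **Mutual information (MI)** between arbitrary feature blocks — single
  genes, gene pairs, gene sets, principal components — and the full trace
  block, estimated with a neural lower bound (the Donsker–Varadhan
  representation of the KL divergence between the paired distribution and
  the product of its marginals), trained by Adam with a
  moving-average-corrected gradient:

  $$I(G;Ca) \ge \mathbb{E}_{\mathbb{P}}[T_\theta] - \log \mathbb{E}_{\mathbb{Q}}[e^{T_\theta}]$$

  Each estimate gets a training-curve bias-correction fit
  $I_{obs}(t) = I_{true}(1-a e^{-bt}) + ct$, a half-sample jackknife in
  $1/n$, and technical replicates with convergence screening.
* **Spectral entropy** of the trace ensemble,
  $H = -\sum_{f=1}^{f_s/2} P(f)\log_2 P(f)$, and **Gaussian differential
  entropy** of PCA-transformed expression,
  $\frac n2 \log_2(2\pi e) + \frac12 \log_2 \det \Sigma_{PC}$.
* The **synergy–redundancy index** of gene pairs conditioned on the
  phenotype, $SRI(G_i,G_j\mid Ca) = I(\{G_i,G_j\};Ca) - I(G_i;Ca) -
  I(G_j;Ca)$ (negative = redundant, positive = synergistic), with
  annotation-level summaries.
* **Nonredundant information** $NRI(k) = E[I_k]\,n/k$ and **redundancy
  explained** $RE(k) = 1 - \frac{NRI(k)-I(G;Ca)}{NRI(1)-I(G;Ca)}$ over
  gene-set size, fed by random-set sampling.
* **Greedy set searches** (most- and least-informative-first) bracketing
  the information content of gene sets of every size.
* A **synthetic-data generator** producing paired count/trace datasets
  from a latent cell state with known coupling, planted redundancy and
  planted (XOR-style) synergy, plus multivariate Gaussian suites with
  closed-form MI for calibration.

Who it is for: anyone with row-aligned cells × features matrices from two
modalities who wants dependence quantified in bits rather than assumed
linear — and tested estimators to do it with.

## Worked example

Simulate a paired dataset whose first two genes redundantly encode the
latent state that drives trace amplitude, estimate per-gene MI and the
SRI of the redundant pair:

```r
library(phenomi)

L <- matrix(0, 6, 3); L[1, 1] <- L[2, 1] <- 0.8; L[3, 2] <- 0.5
spec <- paired_sim_spec(n_cells = 4000, n_genes = 6, n_timepoints = 100,
                        gene_loading = L, seed = 1)
ds <- preprocess(sample_paired_dataset(spec))

cfg <- mine_config(n_iterations = 2500, batch_size = 256,
                   n_replicates = 3, n_jackknife = 0, seed = 7)

sri <- sri_pair(ds, 1, 2, cfg)
round(c(sri = sri$sri, pair = sri$pair_mi, g1 = sri$mi_i, g2 = sri$mi_j), 3)
#>    sri   pair     g1     g2
#> -0.305  0.391  0.360  0.336
```

gene01 and gene02 each carry ~0.35 bits about the traces on their own,
but jointly only ~0.39 bits — far less than the 0.70-bit sum of their
individual contributions — so the pair's SRI is strongly negative
(−0.31 bits): the two genes report the same latent state. They are
redundant, exactly as planted. The trace side of the same dataset:

```r
spectral_entropy(periodogram(ds$traces))
#> [1] 4.096
```

about 4.1 bits of spectral entropy in the simulated oscillations — the
ceiling any expression block could explain. `run_full_analysis()` chains
all stages (entropy curves, per-gene MI, SRI matrix, set searches,
redundancy curve, PC–MI curve) and writes provenance-stamped tables.

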