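# genHawkes

Multivariate Hawkes process models for the joint occurrences of
transcriptional regulatory elements (TREs) along the genome.

## The problem

ChIP-seq/ChIP-chip experiments locate the enriched regions where
transcription factors and other regulators bind. Reducing each enriched
region to its midpoint turns the data for K regulators into a marked
point process along every chromosome. The scientific questions are then:
does the occurrence of one TRE change the local rate of occurrence of
another, at which distances, and is an observed pairwise association
direct or merely mediated by the other TREs in the model? Pairwise
co-occurrence counts and genomic binning cannot answer the last
question; a joint intensity model can.

## The model

For mark k in window i (a chromosome or an ENCODE-style region), the
conditional intensity is log-linear in covariates and in the history of
all marks:

    log λ_k^(i)(t) = (α^(i)k)' X_i(t) + Σ_m Σ_{t_j^m < t} h^{mk}(t − t_j^m)

* `X_i(t)` holds a constant (so the first α coefficient is the log
  baseline intensity, optionally per window) and 0/1 indicator tracks of
  non-point-like covariates such as histone modifications; `γ_j^k =
  exp(α_j^k)` is the fold-change of the baseline when covariate j is
  present.
* Each transfer function `h^{mk}(s) = (β^{mk})' B(s)` is a cubic spline
  on 8 simple equidistant knots spanning −400 to 1000 bp, so
  `g_{m,k}(s) = exp(h^{mk}(s))` is the multiplicative effect of an
  upstream mark-m point at distance s: excitation where g > 1,
  inhibition where g < 1, and dependence capped at 1000 bp.
* `g_{m,k} ≡ 1` (i.e. `β^{mk} = 0`) is exactly local independence of
  mark k from mark m given the remaining marks. It is tested by a
  likelihood-ratio statistic `Q = 2(l1 − l0)` referred to χ²(4), with
  Holm correction across all K² ordered pairs.
* The log-likelihood `Σ_j log λ(t_j) − ∫ λ(s) ds` is discretized on a
  sparse design (midpoint quadrature at resolution r, plus one
  zero-weight row per event) and is concave; fitting uses damped Newton
  steps with the analytic gradient and Hessian, and the parameter
  covariance is the inverse negative Hessian at the optimum.
* TREs are grouped by Ward clustering of the interaction weights
  `H^{mk} = ∫ |h^{mk}|`, and the generative model is simulated exactly
  by Ogata thinning with a linear cap on the intensity for large
  predictors (which prevents explosion).

## Worked example

Simulate two marks where A excites B with a 3-fold peak near 200 bp,
then fit and test:

```r
library(genHawkes)

sim <- make_synthetic_dataset("one_pair_excitation", seed = 11)
sim$dataset
#> MarkedPointDataset: 10 window(s), 2 mark(s)
#>   total length: 5e+06 bp
#>   points per mark: A=493, B=542

tab <- test_all_pairs(sim$dataset, r = 10)
tab[, c("m", "k", "Q", "p_raw", "holm_reject")]
#>   m k         Q        p_raw holm_reject
#> 1 A A  4.348618 3.608766e-01       FALSE
#> 2 B A  3.942025 4.139087e-01       FALSE
#> 3 A B 62.066878 1.066479e-12        TRUE
#> 4 B B  2.031709 7.299266e-01       FALSE

fit <- attr(tab, "fit")
band <- g_confidence_band(fit, "A", "B", lags = c(100, 200, 300))
round(band, 3)
#>   lag estimate lower upper
#> 1 100    2.861 1.990 4.112
#> 2 200    3.175 2.152 4.685
#> 3 300    3.162 2.300 4.348
```

The planted A→B dependence is the only Holm-rejected pair, and the
fitted g-function's pointwise 95% band covers the true 3-fold peak at
lag 200. `cluster_tres(interaction_matrix(fit))` groups marks by these
interaction strengths, and `cmd_fit`/`cmd_test`/`cmd_cluster`/
`cmd_simulate` (or the wrapper script `inst/cli/genhawkes.R`) run the
same steps from BED-like files and a JSON/YAML config.

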