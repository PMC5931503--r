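# vulturediet

Dual-method diet analysis for scavenging raptors: a Bayesian stable-isotope
mixing model and a rule-based prey-remains analysis, plus the statistics to
ask whether the two methods agree.

## Who this is for

Trophic ecologists quantifying how much of a raptor population's diet comes
from each of several food sources — here the five-category scheme used for
Egyptian vultures in landfill-dense landscapes: **landfill, livestock, wild
herbivores, carnivores, birds**. The package covers the full workflow:

1. **Isotope prep** — convert ratios to δ notation, average sibling
   feathers into one observation per nest-year, aggregate multi-prey source
   categories (equal-weight mixture variance).
2. **Mixing model** — per nest-year, estimate diet proportions
   *p* from feather (δ¹³C, δ¹⁵N) under

   x_j ~ N( Σ_k p_k (μ_kj + μ_TEF,j),  Σ_k p_k² (σ_kj² + σ_TEF,j²) + σ_j² ),

   with p = softmax(f), f_k ~ N(0,1), half-Cauchy(0,1) residual SDs, and an
   adaptive Metropolis sampler (compiled core; 4 chains × 10000 steps
   default; split-R̂ and ESS reported).
3. **Conventional analysis** — classify remains by the field's origin rules
   (butchery marks ⇒ landfill; white rabbit hair ⇒ domestic; black
   pig-family hair ⇒ wild boar; …), count by MNI / skeletal-fragment rules,
   and compute per-nest-year proportions.
4. **Agreement** — per category: weighted Cohen's kappa on consumption
   ranks, intraclass correlation, a posterior-resampling difference test
   (P(SIA draw − conventional < 0) per nest, median across nests), and mean
   differences ± SE.
5. **Synthetic data** — a generator with known ground truth (Dirichlet
   diets, Gaussian sources/TEF/noise, multinomial remains with optional
   detectability bias) so every stage is testable end to end.

See `vignettes/vulturediet-methods.Rmd` for the model, assumptions, and
design choices.

## Worked example

```r
library(vulturediet)
st   <- simulate_study(simulation_config(seed = 7))   # known ground truth
cons <- average_siblings(st$consumers)
spec <- mixing_model_spec(st$sources, st$tef, cons,
                          n_iter = 2000, n_burnin = 500, seed = 7)
post <- sample_posterior(spec)
fs   <- summarize_posterior(post)
population_diet_summary(fs)
```

```
           source mean_pct   sd_pct
1        landfill 20.29913 4.384235
2       livestock 19.33741 3.512644
3 wild_herbivores 20.54641 5.825356
4      carnivores 19.39551 4.867760
5           birds 20.42154 1.813457
```

Population-level SIA diet composition: mean ± SD (percent) across the 35
simulated nest-years of each source's posterior-mean contribution. Under
the default uniform-Dirichlet truths all five hover near 20%.

```r
props <- diet_proportions(count_items(st$remains))
compare_methods(post, fs, props, seed = 7)
```

```
Method-agreement report (SIA vs conventional), per category:
        category  kappa  kappa_p    icc  icc_p median_p_below_0 mean_diff se_diff  n
        landfill 0.5258 0.000203 0.3911 0.0497            0.471  -0.01201  0.0262 24
       livestock 0.1054 0.415328 0.0174 0.9312            0.548   0.03111  0.0235 24
 wild_herbivores 0.4113 0.005776 0.4108 0.0384            0.506   0.00469  0.0258 24
      carnivores 0.3288 0.021258 0.2122 0.3013            0.599  -0.03254  0.0345 24
           birds 0.0842 0.438578 0.0782 0.7049            0.509   0.00876  0.0291 24
```

With unbiased detection the difference-test medians sit near 0.5 (methods
agree); inflate `detectability_bias` for livestock in the generator and the
livestock median moves to an extreme, reproducing the signature of
bone-persistence bias in conventional diet analysis.

## Command line

```sh
Rscript inst/scripts/vulturediet.R simulate --outdir data/ --seed 7
Rscript inst/scripts/vulturediet.R run --consumers data/consumers.csv \
    --sources data/sources.csv --tef data/tef.csv --remains data/remains.csv \
    --outdir out/ --seed 7
```

`run` writes every stage's CSV (fit summary, population summaries,
counts/proportions, agreement tables) plus a JSON manifest with settings,
seed and convergence flags.

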