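# predinfo

Why do languages express meanings with systematic, word-like, hierarchically
nested codes instead of arbitrary holistic ones?  One information-theoretic
answer: natural codes keep the **predictive information** (excess entropy) of
the speech stream low — the amount of information a predictor must carry
about the past to predict the future.  `predinfo` implements that framework
for discrete meaning→form codes, for researchers in computational
linguistics, cognitive science and emergent communication who want to score
and compare codes, run the supporting simulation experiments, and test
attested lexicons/paradigms/phrase tables against counterfactual baselines.

## The quantity at the core

A code `L : M → Σ*` plus a source distribution `p_M` induces a stationary
symbol process: meanings are sampled i.i.d., mapped to strings, and the
strings are concatenated with a delimiter `# ∉ Σ` between them.  The package
computes, exactly:

* the n-gram conditional entropies `h_n = H[X_t | X_{t−n+1..t−1}]`,
* the entropy rate `h = lim h_n`, and
* the predictive information
  `E = I[X_past : X_future] = Σ_{n≥1} (h_n − h)`  (bits).

Because the delimiter statistically severs forms, `h_n = h` exactly for all
`n ≥ L_max + 2`, so `E` is a finite sum computed in closed form (C++ core) —
no Monte-Carlo anywhere in the headline quantities.  An independent
cut-construction oracle (`excess_entropy_cut()`) recomputes `E` from the
definition `I[past : future]` and is required to agree to 1e-9.

On top of the core sit:

* **sources** — weighted-coin products, correlated mixtures, Zipfian,
  hierarchically coupled, and empirical (count-table) sources;
* **codes** — systematic (homomorphic) code builders, random bijections and
  full bijection enumeration, position scrambles, meaning permutations,
  manner-preserving phoneme scrambles, and scorers for systematicity,
  contiguity and well-nestedness;
* **experiments** — five deterministic drivers showing that E-minimization
  selects systematic, natural, local and well-nested codes;
* **corpus pipeline** — attested-vs-counterfactual analyses for morphology,
  adjective–noun pairs, phonotactics, noun-phrase word order and semantic
  norms, with permutation p-values; CoNLL-U extraction; TSV/JSON I/O;
* **synthetic data** — seeded generators emulating the corpus inputs, so
  everything is testable offline.

## Worked example

```r
library(predinfo)

src <- product_bernoulli_source(epsilon = 0.05)    # three weighted coins
digits <- c(`0` = "0", `1` = "1")
sys <- systematic_code(src, list(M1 = digits, M2 = digits, M3 = digits))
hol <- random_bijection_code(src, sys$form, seed = 42)

predictive_information(form_process(sys))
#> <pi_result: E = 2.000000 bits, h = 0.640506 bits/symbol, N = 5>
predictive_info(hol)
#> [1] 2.08496
```

The systematic code needs 2 bits of memory across time (that is the cost of
knowing your position between delimiters); the holistic bijection pays ~0.08
bits more because its letters carry information about each other.  Over all
40,320 bijections (`run_bijection_enumeration()`), the minimum E is attained
*only* by fully systematic codes.

The corpus-style analyses compare attested forms against counterfactuals:

```r
mt <- morphology_test(gen_paradigm(), n_samples = 1000, seed = 1)
mt
#> <baseline_ensemble: E_attested = 2.5420 bits (letter level), 1000 samples/baseline>
#>   length_matched     p = 0.0000
#>   nonlocal           p = 0.0000
#>   unnatural          p = 0.0000

phonotactics_test(gen_lexicon(), seed = 1)
#> # A tibble: 1 × 3
#>   E_attested E_scrambled delta
#>        <dbl>       <dbl> <dbl>
#> 1       3.71        4.73  1.01
```

The synthetic agglutinative paradigm has lower E than every sample of all
three baseline ensembles (p = 0 at 1,000 samples); scrambling the lexicon's
phonemes while preserving manner of articulation raises E by ~1 bit.
`autoplot()` methods display the `h_n` convergence, baseline densities and
ranked-code scatters; `tidy()`/`glance()` return the underlying tibbles.

A thin CLI wrapping these functions ships at
`inst/scripts/predinfo-cli.R` (subcommands `compute-e`, `simulate`,
`analyze`, `extract`, `synth`).

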