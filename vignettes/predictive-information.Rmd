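---
title: "Predictive information of meaning-form codes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive information of meaning-form codes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A *code* (or language) is a deterministic map `L` from a finite set of
meanings to strings over a finite alphabet.  Meanings carry a probability
distribution, the *source*.  Sampling meanings i.i.d., translating them to
strings and concatenating the strings in both directions with a reserved
delimiter `#` between them defines a stationary symbol process.  The
complexity measure of interest is the **predictive information** (excess
entropy) of that process,

  E = I[past : future],

the mutual information between everything before a time point and everything
from it onward.  E is low exactly when the next symbol is predictable from a
*short* local context: it measures how much memory any predictor must carry
across time, not how random the process is.

E is computed through the n-gram entropies.  Let `h_n` be the conditional
entropy of one symbol given the `n - 1` preceding symbols.  `h_n` decreases
in `n` to the entropy rate `h`, and

  E = sum over n >= 1 of (h_n - h).

Because the delimiter statistically severs consecutive forms (meanings are
i.i.d.), a conditioning window that reaches back to the previous delimiter
extracts everything the past can offer.  The package exploits this: window
statistics treat each form as padded with delimiters on both sides, so
`h_n = h` exactly for all `n >= L_max + 2` (`L_max` = longest form).  The sum
above is therefore a *finite* sum up to `L_max + 1`, computed exactly — no
sampling, no truncation error.  The implementation additionally verifies
`h_{L_max+2} = h_{L_max+3}` to 1e-12 at every call.

One subtlety is worth recording.  Under the padding convention the
conditional entropy `h_n` is *not* the difference of two window-table
entropies collected the same way: the conditioning contexts of the windows
ending at each symbol of `s#` are the length `n - 1` windows ending one
position earlier, *including* the all-delimiter context before the form's
first symbol.  `conditional_entropy()` and the C++ core both use this
joint-minus-context form; the window tables themselves are exposed by
`ngram_distribution()`, whose n-table marginalizes (over its oldest symbol)
onto the (n-1)-table.

### Two independent routes to E

`predictive_information()` computes E by the finite h-series sum, in C++.
`excess_entropy_cut()` re-derives E independently in R from the definition:
draw a form `s` and a cut point `k` with the length-reweighted distribution;
the prefix `s[1..k]` is a sufficient statistic of the infinite past and the
suffix-plus-delimiter determines the future, so E is the mutual information
between prefix and suffix classes.  The test suite and the acceptance script
require the two routes to agree to 1e-9 on hundreds of random instances;
the routes share no code.

## Parameters that matter

* **Logarithms** are base 2 throughout; all quantities are in bits.
* **Tolerances**: 1e-12 for distribution validity and convergence checks,
  1e-9 for the dual-route equality; probabilities below 1e-15 are treated as
  zero.  Entropy accumulation uses extended (long double) precision so the
  1e-12 convergence check is meaningful even with 10^5-window tables.
* **Non-injective codes** are allowed in the core: meanings sharing a form
  are aggregated.  Analyses that need unambiguity (the meaning-permutation
  baselines) check injectivity and refuse otherwise.
* **Word-level analyses** reuse the same machinery with whole words as
  atomic symbols and the phrase boundary as delimiter
  (`form_process(..., mode = "word")`).

## The simulation experiments

1. `run_coinflip_comparison()` — three independent weighted coins
   (Bernoulli 2/3, 2/3 + eps, 2/3 + 2 eps, eps = 0.05); the one-digit-per-coin
   systematic code against seeded random bijections onto the length-3 binary
   strings.
2. `run_bijection_enumeration()` — all 40,320 bijections, each scored for E
   and for the number of coins expressed systematically.  A coin counts as
   systematic when some string position is a bijective function of that coin
   alone, positions claimed at most once; this makes the fully systematic
   codes score 3 and fully holistic ones 0 and is computable by brute force.
3. `run_mixture_sweep()` — the source interpolates toward a perfectly tied
   (M2, M3) pair.  The candidate codes keep total length 3.  Because every
   bijection of two bits onto two bits is affine, a literally "holistic"
   two-symbol block does not exist; the partial-holistic candidates use
   XOR blocks — natural: (M2 xor M3, M3); unnatural: (M1, M1 xor M2) — so
   that at full correlation the natural block collapses to one informative
   symbol.  These choices were fixed once, after verifying that the
   qualitative claims (systematic optimal at independence, natural optimal
   at high correlation, natural never worse than unnatural) hold on the
   whole grid.
4. `run_locality_permutations()` — Zipf(1) source over 100 two-digit
   meanings, each digit coded by a distinct random word in {0,1}^4; E for
   all 40,320 position permutations, flagged for whether both words stay
   contiguous.
5. `run_hierarchy_permutations()` — the six-variable hierarchical source
   (couplings alpha = 0.01, beta = 0.20, gamma = 0.99; every q is Zipfian
   over the lexicographically ordered product of its outcome sets, the
   reading we adopt since only the one-dimensional case is pinned down);
   E for all 720 orders of a one-symbol-per-variable code, flagged for
   well-nestedness under the tree ((M1, M2), M3), ((M4, M5), M6).

## Counterfactual baselines and p-values

The corpus analyses compare attested forms against ensembles of
counterfactuals:

* **non-local**: one random position permutation per form length per
  sample, shared by all forms of that length — a deterministic scrambling
  function, covering variable-length codes (a single truncated permutation
  would make identical forms scramble differently);
* **unnatural**: the form-meaning assignment permuted;
* **length-matched unnatural**: permuted within classes of equal length.

The permutation p-value is the fraction of samples with lower E than the
attested forms.  Strictly lower samples count, and exact ties (within
1e-12 — e.g. the identity permutation, or a full reversal, which E cannot
distinguish) also count toward the numerator: the conservative direction.

Add-1/2 smoothing of paradigm counts applies over the listed cells.  A cell
absent from the table has no form and cannot enter the process, so the
package expects the paradigm table to enumerate the full feature
cross-product (zero counts allowed) and warns otherwise.

The adjective-noun analysis treats the space between the two words as an
ordinary symbol that participates in the non-local permutation; nothing in
the scrambling construction motivates exempting it.

## What the synthetic generators emulate — and what they do not

The generators produce inputs with the *statistical premises* of the
empirical analyses, so the whole pipeline is testable offline:

* `gen_paradigm()` — concatenative suffixal morphology (stem dummy `X`,
  one injective suffix per feature; 2 x 2 x 4 x 2 cells) with near-independent
  Zipf-flavoured feature marginals; a fusional control fuses each cell into
  an arbitrary suffix.
* `gen_lexicon()` — CV-syllable words whose vowel is coupled to the
  preceding consonant with probability `strictness` (default 0.9): a local
  phonotactic co-occurrence restriction.  The manner-preserving scramble
  relocates these dependencies to longer ranges, raising E.
* `gen_phrase_table()` — Zipf-distributed noun lemmas with determiner /
  numeral / adjective slots; determiner-noun coupling strongest (0.9) so
  the minimizing order puts D adjacent to the noun.  Lemmas are random CV
  strings, not opaque identifiers: the letter-level adjective-noun analysis
  needs within-word letter structure for attested concatenation to be local,
  exactly as in real lexicons.
* `gen_semantic_norms()` — binary content features driven by a latent
  two-class mixture (mutually informative), an independent number feature,
  and verb-object pairs whose latent classes agree only weakly across
  words.  The word-frequency Zipf exponent defaults to 0.5: with exponent 1
  the weighted plug-in MI has an effective sample size of a few dozen
  regardless of vocabulary size, and estimator noise can swamp the
  number-feature contrast the generator is supposed to exhibit.

What passing these tests shows is that the *pipeline* recovers the stated
structure when it is present, with correct baselines and p-values.  It does
not show anything about real languages: the generators have none of the
morphophonology, syncretism, frequency dynamics or annotation noise of real
corpora, and the published cross-linguistic numbers depend on external
datasets (phonemic vocabulary lists, treebanks, sensorimotor norms,
typological counts) that are not redistributed here.  The analysis
functions accept such files in the documented TSV/CoNLL-U schemas.

## Problem sizes and determinism

Exactness makes the heavy experiments enumerable: the two 40,320-code
sweeps and the 720-order sweep run in seconds to a couple of minutes
through the C++ core (dense window tables when the coded window space is
small, hashed otherwise).  The shipped checks run the baseline ensembles at
1,000 samples per baseline — the full 10,000 of the empirical studies is a
single argument away — and use the generator defaults above.  Every
stochastic step is seeded; experiments are bit-for-bit reproducible, and
scrambles derive per-word seeds from (global seed, word identity) so
identical words scramble identically.

## Known limitations

* E is symmetric under time reversal, so order analyses cannot distinguish
  an order from its mirror image; outputs flag reversal pairs.
* The regression in `word_order_analysis()` uses ordinary least squares of
  log genus count on E and must drop orders with zero typological count.
* Divergent long-range predictive information over connected text, latent
  (causal-state) constructions and continuous sources are out of scope; the
  construction here deliberately treats single utterances as statistically
  independent.
* For degenerate inputs: one-form paradigms are refused; constant norm
  features binarize to all-zero with a warning; zero-probability meanings
  are dropped (provably without effect on any output).
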