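# Seeded generators for paradigm, lexicon, phrase and semantic-norm inputs
# with the statistical structure the analyses presuppose: concatenative
# suffixal morphology, local phonotactic co-occurrence constraints,
# slot-value dependencies in noun phrases, and correlated content features
# with a near-independent number feature.  Pure functions of their arguments
# (bit-identical re-runs for a fixed seed).

#' Generate a synthetic noun paradigm table
#'
#' Agglutinative mode: every cell's form is the stem dummy `X` followed by
#' one suffix per feature in a fixed order, with injective value-to-suffix
#' maps per feature (unmarked values take an empty suffix).  Fusional mode
#' (control): each cell gets a single fused random suffix, so there is no
#' shared sub-structure across cells.  Cell counts follow a product of
#' independent Zipf-flavoured marginals over the features, scaled to
#' `n_tokens` observations.
#'
#' @param mode `"agglutinative"` or `"fusional"`.
#' @param n_tokens Total token mass distributed over the cells.
#' @param seed Integer seed (used by the fusional suffix draw).
#' @return A paradigm tibble: `number`, `case`, `possessor`, `definiteness`,
#'   `form`, `count`; one row per cell of the full cross-product.
#' @export
gen_paradigm <- function(mode = c("agglutinative", "fusional"),
                         n_tokens = 5000, seed = 1) {
  mode <- match.arg(mode)
  suffixes <- list(
    number = c(sg = "", pl = "ek"),
    possessor = c(none = "", p1 = "im"),
    case = c(nom = "", acc = "et", dat = "nek", ine = "ben"),
    definiteness = c(ind = "", def = "sa")
  )
  cells <- tidyr::expand_grid(
    number = names(suffixes$number),
    possessor = names(suffixes$possessor),
    case = names(suffixes$case),
    definiteness = names(suffixes$definiteness)
  )
  marg <- list(number = c(2 / 3, 1 / 3), possessor = c(0.8, 0.2),
               case = zipf_probs(4), definiteness = c(0.7, 0.3))
  p <- marg$number[match(cells$number, names(suffixes$number))] *
    marg$possessor[match(cells$possessor, names(suffixes$possessor))] *
    marg$case[match(cells$case, names(suffixes$case))] *
    marg$definiteness[match(cells$definiteness, names(suffixes$definiteness))]
  cells$count <- round(n_tokens * p)
  if (mode == "agglutinative") {
    cells <- systematic_code(cells, suffixes,
                             order = c("number", "possessor", "case", "definiteness"))
    cells$form <- paste0("X", cells$form)
  } else {
    letters_pool <- c("a", "e", "i", "o", "u", "k", "n", "t", "s", "m", "b")
    cells$form <- with_seed(seed, {
      repeat {
        suf <- vapply(seq_len(nrow(cells)), function(i) {
          paste(sample(letters_pool, sample(2:4, 1), replace = TRUE), collapse = "")
        }, character(1))
        if (!anyDuplicated(suf)) break
      }
      paste0("X", suf)
    })
  }
  stopifnot(!anyDuplicated(cells$form))
  cells[c("number", "possessor", "case", "definiteness", "form", "count")]
}

#' Generate a synthetic phonemic lexicon with local phonotactic constraints
#'
#' Words are built from consonant-vowel syllables (consonants are stops,
#' vowels are vowels, so the manner skeleton is `C V C V ...`).  The local
#' constraint couples each vowel to the consonant that precedes it: with
#' probability `strictness` the vowel is the consonant's preferred vowel,
#' otherwise uniform.  At `strictness = 0` sampling is unconstrained.
#'
#' @param n_words Number of word types to attempt (duplicates are dropped).
#' @param strictness Constraint strength in `[0, 1]`.
#' @param syllables Vector of admissible syllable counts per word.
#' @param seed Integer seed.
#' @return A lexicon tibble: `word`, `phonemes`, `manner`, `frequency`
#'   (Zipfian over types).
#' @export
gen_lexicon <- function(n_words = 200, strictness = 0.9, syllables = 2:3,
                        seed = 1) {
  stopifnot(strictness >= 0, strictness <= 1)
  consonants <- c("p", "t", "k", "b", "d", "g")
  vowels <- c("a", "e", "i", "o", "u")
  preferred <- c(p = "a", t = "e", k = "i", b = "o", d = "u", g = "a")
  words <- with_seed(seed, {
    purrr::map_chr(seq_len(n_words), function(i) {
      ns <- sample(syllables, 1)
      ph <- character(0)
      for (s in seq_len(ns)) {
        c1 <- sample(consonants, 1)
        v1 <- if (runif(1) < strictness) preferred[[c1]] else sample(vowels, 1)
        ph <- c(ph, c1, v1)
      }
      paste(ph, collapse = " ")
    })
  })
  keep <- !duplicated(words)
  words <- words[keep]
  manner <- vapply(strsplit(words, " ", fixed = TRUE), function(ph) {
    paste(ifelse(ph %in% consonants, "stop", "vowel"), collapse = " ")
  }, character(1))
  tibble::tibble(
    word = gsub(" ", "", words, fixed = TRUE),
    phonemes = words,
    manner = manner,
    frequency = zipf_probs(length(words))
  )
}

#' Generate a synthetic noun-phrase count table
#'
#' Noun lemmas are Zipf-distributed; a determiner, numeral and adjective are
#' present with the given probabilities.  Each noun has a preferred
#' determiner and a preferred adjective; with probability `coupling_det`
#' (resp. `coupling_adj`) the preferred value is used, otherwise a uniform
#' draw.  Numerals are uniform (no coupling).  With all couplings and
#' presence probabilities fixed, the table is a deterministic function of
#' the seed.
#'
#' @param n_nouns,n_dets,n_adjs,n_nums Vocabulary sizes per slot.
#' @param p_det,p_num,p_adj Slot presence probabilities.
#' @param coupling_det,coupling_adj Preferred-value probabilities in `[0, 1]`.
#' @param n_phrases Number of phrase tokens sampled before tallying.
#' @param seed Integer seed.
#' @return A phrase tibble: `determiner`, `numeral`, `adjective`, `noun`
#'   (`NA` = slot absent), `count`.
#' @export
gen_phrase_table <- function(n_nouns = 20, n_dets = 3, n_adjs = 8, n_nums = 4,
                             p_det = 0.7, p_num = 0.1, p_adj = 0.35,
                             coupling_det = 0.9, coupling_adj = 0.4,
                             n_phrases = 2000, seed = 1) {
  # lemmas are pronounceable CV strings so that letter-level analyses of the
  # derived tables (e.g. adjective-noun pairs) see within-word structure
  vocab <- with_seed(derive_seed(seed, "lemmas"), {
    cv_word <- function(n_syll) {
      paste(vapply(seq_len(n_syll), function(i) {
        paste0(sample(c("p", "t", "k", "b", "d", "g", "m", "n", "s", "l"), 1),
               sample(c("a", "e", "i", "o", "u"), 1))
      }, character(1)), collapse = "")
    }
    seen <- character(0)
    draw <- function(k, syll_min, syll_max) {
      out <- character(0)
      while (length(out) < k) {
        w <- cv_word(sample(syll_min:syll_max, 1))
        if (!w %in% seen) {
          seen <<- c(seen, w)
          out <- c(out, w)
        }
      }
      out
    }
    list(nouns = draw(n_nouns, 2, 3), dets = draw(n_dets, 1, 1),
         adjs = draw(n_adjs, 2, 3), nums = draw(n_nums, 2, 2))
  })
  nouns <- vocab$nouns
  dets <- vocab$dets
  adjs <- vocab$adjs
  nums <- vocab$nums
  pref_det <- dets[(seq_len(n_nouns) - 1L) %% n_dets + 1L]
  pref_adj <- adjs[(seq_len(n_nouns) - 1L) %% n_adjs + 1L]
  draws <- with_seed(seed, {
    ni <- sample.int(n_nouns, n_phrases, replace = TRUE, prob = zipf_probs(n_nouns))
    tibble::tibble(
      determiner = ifelse(runif(n_phrases) < p_det,
                          ifelse(runif(n_phrases) < coupling_det,
                                 pref_det[ni], sample(dets, n_phrases, replace = TRUE)),
                          NA_character_),
      numeral = ifelse(runif(n_phrases) < p_num,
                       sample(nums, n_phrases, replace = TRUE), NA_character_),
      adjective = ifelse(runif(n_phrases) < p_adj,
                         ifelse(runif(n_phrases) < coupling_adj,
                                pref_adj[ni], sample(adjs, n_phrases, replace = TRUE)),
                         NA_character_),
      noun = nouns[ni]
    )
  })
  dplyr::count(draws, .data$determiner, .data$numeral, .data$adjective,
               .data$noun, name = "count")
}

#' Synthetic adjective-noun pair table
#'
#' The adjective-bearing rows of [gen_phrase_table()], tallied as
#' (adjective, noun) pairs.  The adjective-noun coupling of the phrase
#' generator provides the selectional dependence between the two lemmas.
#'
#' @inheritParams gen_phrase_table
#' @param ... Passed on to [gen_phrase_table()].
#' @return A pair tibble: `adjective`, `noun`, `count`.
#' @export
gen_adjnoun_pairs <- function(seed = 1, ...) {
  ph <- gen_phrase_table(seed = seed, ...)
  withadj <- ph[!is.na(ph$adjective), ]
  dplyr::count(withadj, .data$adjective, .data$noun, wt = .data$count,
               name = "count")
}

#' Packaged noun-phrase fixture rows
#'
#' The four example phrase-count rows shipped with the package
#' (`die/Hand 234`, `ein/alt/Kind 4`, `drei/Buch 2`,
#' `ein/einzigartig/Parfümeur 1`), as a phrase table.
#'
#' @return A four-row phrase tibble.
#' @export
example_phrase_table <- function() {
  read_phrases_tsv(system.file("extdata", "example_noun_phrases.tsv",
                               package = "predinfo", mustWork = TRUE))
}

#' Generate synthetic binary semantic norms with an independent number feature
#'
#' Content features are driven by a latent two-class mixture: within a
#' class, each feature is 1 with probability `0.5 + coupling/2` (class A) or
#' `0.5 - coupling/2` (class B), which makes content features mutually
#' informative; the `number` feature is an independent Bernoulli, mirroring
#' numerosity being uncorrelated with sensorimotor content.  Optionally
#' generates a verb-object pair table in which the two words' latent classes
#' agree with probability `0.5 + across_coupling/2`, so within-word feature
#' MI exceeds across-word MI.
#'
#' @param n_words Number of words (split evenly into verbs and objects when
#'   pairs are generated).
#' @param n_features Number of content features.
#' @param coupling Content-feature class separation in `[0, 1]`.
#' @param p_number Success probability of the independent number feature.
#' @param freq_exponent Zipf exponent of the word-frequency distribution.
#'   The default 0.5 keeps the frequency weighting skewed while leaving a
#'   large effective sample size, so weighted plug-in MI estimates are
#'   stable at the default lexicon size.
#' @param pairs Whether to generate the verb-object pair table.
#' @param across_coupling Class agreement strength across the two words of a
#'   pair, in `[0, 1]`.
#' @param n_pairs Number of pair tokens sampled before tallying.
#' @param seed Integer seed.
#' @return A list with `norms` (tibble: `word`, binary feature columns
#'   `f1..fk`, `number`, `frequency`) and, when `pairs = TRUE`, `pairs`
#'   (tibble: `verb`, `object`, `count`).
#' @export
gen_semantic_norms <- function(n_words = 300, n_features = 8, coupling = 0.7,
                               p_number = 0.3, pairs = TRUE,
                               across_coupling = 0.25, n_pairs = 1200,
                               freq_exponent = 0.5, seed = 1) {
  stopifnot(n_features >= 2, coupling >= 0, coupling <= 1)
  with_seed(seed, {
    words <- sprintf("w%03d", seq_len(n_words))
    class <- sample(c(0L, 1L), n_words, replace = TRUE)
    p_hi <- 0.5 + coupling / 2
    p_lo <- 0.5 - coupling / 2
    feats <- lapply(seq_len(n_features), function(f) {
      rbinom(n_words, 1, ifelse(class == 1L, p_hi, p_lo))
    })
    norms <- tibble::as_tibble(stats::setNames(feats, paste0("f", seq_len(n_features))))
    norms <- dplyr::bind_cols(tibble::tibble(word = words), norms)
    norms$number <- rbinom(n_words, 1, p_number)
    norms$frequency <- zipf_probs(n_words, freq_exponent)
    out <- list(norms = norms)
    if (pairs) {
      half <- n_words %/% 2
      verbs <- words[seq_len(half)]
      objects <- words[(half + 1):n_words]
      vi <- sample.int(length(verbs), n_pairs, replace = TRUE,
                       prob = zipf_probs(length(verbs), freq_exponent))
      agree <- runif(n_pairs) < 0.5 + across_coupling / 2
      oi <- vapply(seq_len(n_pairs), function(i) {
        vc <- class[vi[i]]
        pool_match <- which(class[(half + 1):n_words] == vc)
        pool_other <- which(class[(half + 1):n_words] != vc)
        pool <- if (agree[i] && length(pool_match)) pool_match
                else if (length(pool_other)) pool_other else pool_match
        pool[sample.int(length(pool), 1)]
      }, integer(1))
      out$pairs <- dplyr::count(
        tibble::tibble(verb = verbs[vi], object = objects[oi]),
        .data$verb, .data$object, name = "count"
      )
    }
    out
  })
}
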