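# Attested-versus-counterfactual analyses: morphological paradigms,
# adjective-noun pairs, phonotactics, noun-phrase word order, and semantic
# feature correlations, with permutation baselines and permutation p-values.

new_baseline_ensemble <- function(E_attested, samples, n_samples, level) {
  # a baseline sample counts toward p when its E is lower than the attested
  # E; exact ties (within 1e-12, e.g. the identity or reversal permutation)
  # also count, which is the conservative direction
  p <- dplyr::summarise(dplyr::group_by(samples, .data$baseline),
                        p_lower = mean(.data$E < E_attested + 1e-12),
                        .groups = "drop")
  structure(list(E_attested = E_attested, samples = samples, p = p,
                 n_samples = n_samples, level = level),
            class = "baseline_ensemble")
}

#' @export
print.baseline_ensemble <- function(x, ...) {
  cat(sprintf("<baseline_ensemble: E_attested = %.4f bits (%s level), %d samples/baseline>\n",
              x$E_attested, x$level, x$n_samples))
  for (i in seq_len(nrow(x$p))) {
    cat(sprintf("  %-18s p = %.4f\n", x$p$baseline[i], x$p$p_lower[i]))
  }
  invisible(x)
}

#' @rdname morphology_test
#' @param x A `baseline_ensemble`.
#' @param ... Unused.
#' @export
tidy.baseline_ensemble <- function(x, ...) x$samples

#' @rdname morphology_test
#' @export
glance.baseline_ensemble <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$p, names_from = "baseline",
                             values_from = "p_lower", names_prefix = "p_")
  dplyr::bind_cols(tibble::tibble(E_attested = x$E_attested,
                                  n_samples = x$n_samples), wide)
}

# shared permutation-baseline machinery over a code given as (forms, prob)
baseline_sweep <- function(forms, prob, n_samples, seed,
                           baselines = c("nonlocal", "unnatural", "length_matched")) {
  symbols <- sort(unique(unlist(strsplit(forms, "", fixed = TRUE))))
  if ("#" %in% symbols) abort("forms must not contain '#'",
                              class = "predinfo_reserved_symbol")
  tokens <- forms_to_int(forms, symbols)
  base <- length(symbols) + 1L
  lens <- nchar(forms)
  n <- length(forms)
  with_seed(seed, {
    out <- list()
    if ("unnatural" %in% baselines) {
      assign <- t(replicate(n_samples, sample.int(n)))
      out$unnatural <- pi_assign_sweep_cpp(tokens, prob, assign, base)
    }
    if ("length_matched" %in% baselines) {
      classes <- split(seq_len(n), lens)
      assign <- t(replicate(n_samples, {
        a <- integer(n)
        for (idx in classes) a[idx] <- idx[sample.int(length(idx))]
        a
      }))
      out$length_matched <- pi_assign_sweep_cpp(tokens, prob, assign, base)
    }
    if ("nonlocal" %in% baselines) {
      out$nonlocal <- vapply(seq_len(n_samples), function(s) {
        perms <- random_length_permutations(lens)
        scrambled <- lapply(tokens, function(t) t[perms[[as.character(length(t))]]])
        pi_e_cpp(scrambled, prob, base)$E
      }, numeric(1))
    }
    dplyr::bind_rows(purrr::imap(out, function(e, nm) {
      tibble::tibble(baseline = nm, sample = seq_along(e), E = e)
    }))
  })
}

#' Morphological paradigm versus counterfactual baselines
#'
#' Computes letter-level predictive information of a paradigm (source
#' probabilities proportional to smoothed cell counts) and compares it with
#' three counterfactual ensembles: a non-local baseline (a random position
#' permutation per form length, shared by all forms of that length), an
#' unnatural baseline (the form-meaning assignment permuted), and a
#' length-matched unnatural baseline (assignment permuted within classes of
#' equal form length).  The permutation p-value per baseline is the fraction
#' of samples with lower E than the attested forms.
#'
#' @param paradigm Data frame: one column per grammatical feature, plus
#'   `form` (strings; stem dummies such as `X` count as single letters) and
#'   `count` (non-negative).  Feature tuples must be unique and the table
#'   should list every cell of the paradigm (zero counts allowed), since the
#'   add-1/2 smoothing assigns mass to every listed cell.
#' @param n_samples Baseline samples per ensemble.
#' @param seed Integer seed.
#' @param smoothing Additive smoothing for the cell counts (default 1/2).
#' @return A `baseline_ensemble`.
#' @export
morphology_test <- function(paradigm, n_samples = 10000, seed = 1,
                            smoothing = 0.5) {
  stopifnot(is.data.frame(paradigm), all(c("form", "count") %in% names(paradigm)))
  if (length(unique(paradigm$form)) < 2) {
    abort("paradigm must contain at least two distinct forms",
          class = "predinfo_domain_error")
  }
  feats <- setdiff(names(paradigm), c("form", "count"))
  if (anyDuplicated(paradigm[feats])) abort("feature tuples must be unique")
  n_cells <- prod(vapply(paradigm[feats], function(v) length(unique(v)), numeric(1)))
  if (nrow(paradigm) < n_cells) {
    warn("paradigm does not list every cell of the feature cross-product; smoothing covers listed cells only")
  }
  if (anyDuplicated(paradigm$form)) {
    abort("paradigm forms must be distinct (injective code) for the permutation baselines",
          class = "predinfo_ambiguity_error")
  }
  w <- paradigm$count + smoothing
  prob <- w / sum(w)
  e_att <- predictive_info(tibble::tibble(form = paradigm$form, prob = prob))
  samples <- baseline_sweep(paradigm$form, prob, n_samples, seed)
  new_baseline_ensemble(e_att, samples, n_samples, "letter")
}

#' Adjective-noun pairs versus counterfactual baselines
#'
#' The meaning is the (adjective, noun) lemma pair; the form is the
#' adjective and noun in attested order with a single space between them,
#' analysed at the character level (the space is an ordinary symbol and
#' participates in the non-local permutation).  Source probabilities are
#' proportional to pair frequencies.  Baselines: unnatural (form-meaning
#' assignment permuted) and non-local (per-length position permutation).
#'
#' @param pairs Data frame with columns `adjective`, `noun`, `count`.
#' @inheritParams morphology_test
#' @return A `baseline_ensemble`.
#' @export
adjnoun_test <- function(pairs, n_samples = 10000, seed = 1) {
  stopifnot(is.data.frame(pairs),
            all(c("adjective", "noun", "count") %in% names(pairs)))
  if (nrow(pairs) < 2) {
    abort("need at least two pairs", class = "predinfo_domain_error")
  }
  forms <- paste(pairs$adjective, pairs$noun)
  if (anyDuplicated(forms)) {
    pairs <- dplyr::summarise(dplyr::group_by(pairs, .data$adjective, .data$noun),
                              count = sum(.data$count), .groups = "drop")
    forms <- paste(pairs$adjective, pairs$noun)
  }
  prob <- pairs$count / sum(pairs$count)
  e_att <- predictive_info(tibble::tibble(form = forms, prob = prob))
  samples <- baseline_sweep(forms, prob, n_samples, seed,
                            baselines = c("nonlocal", "unnatural"))
  new_baseline_ensemble(e_att, samples, n_samples, "letter")
}

#' Attested versus manner-preserving scrambled lexicon
#'
#' Computes phoneme-level predictive information of a lexicon under a
#' uniform distribution over word types, for the attested forms and for the
#' deterministic manner-preserving scramble of every form.
#'
#' @param lexicon Data frame with columns `word`, `phonemes`
#'   (space-separated phoneme tokens), `manner` (space-separated manner
#'   classes, same length) and optionally `frequency` (unused: the source is
#'   uniform over types).
#' @param seed Integer seed for the deterministic scramble.
#' @return A one-row tibble with `E_attested`, `E_scrambled` and `delta`.
#' @export
phonotactics_test <- function(lexicon, seed = 1) {
  stopifnot(is.data.frame(lexicon),
            all(c("word", "phonemes", "manner") %in% names(lexicon)))
  if (nrow(lexicon) == 0) {
    abort("lexicon is empty", class = "predinfo_domain_error")
  }
  lexicon <- lexicon[!duplicated(lexicon$phonemes), ]
  phon <- strsplit(lexicon$phonemes, "\\s+")
  mann <- strsplit(lexicon$manner, "\\s+")
  if (any(lengths(phon) != lengths(mann))) {
    abort("phonemes and manner classes must align per word",
          class = "predinfo_mapping_error")
  }
  uni <- rep(1 / nrow(lexicon), nrow(lexicon))
  e_att <- predictive_info(tibble::tibble(form = phon, prob = uni), mode = "word")
  scrambled <- purrr::map2(phon, mann, function(p, m) {
    manner_preserving_scramble(p, m, seed = seed)
  })
  e_scr <- predictive_info(tibble::tibble(form = scrambled, prob = uni),
                           mode = "word")
  tibble::tibble(E_attested = e_att, E_scrambled = e_scr,
                 delta = e_scr - e_att)
}

np_slots <- c(D = "determiner", N = "numeral", A = "adjective", n = "noun")

order_label <- function(perm) paste(names(np_slots)[perm], collapse = "-")

#' Word-level predictive information of all noun-phrase slot orders
#'
#' Realizes every attested noun phrase in each of the 24 orders of the slots
#' Determiner-Numeral-Adjective-noun (absent slots are skipped) and computes
#' predictive information at the word level, treating each lemma as one
#' atomic symbol.  E is identical for an order and its reversal, which the
#' output flags.  If a typology table is supplied, the driver fits an
#' ordinary least-squares regression of log genus count on E and reports the
#' Pearson correlation; orders with zero genus count are excluded from the
#' regression.
#'
#' @param phrases Data frame with columns `determiner`, `numeral`,
#'   `adjective`, `noun` (`NA` for absent slots; noun always present) and
#'   `count`.
#' @param typology Optional data frame with columns `order` (labels such as
#'   `"D-N-A-n"`) and `genus_count`.
#' @return A tibble with `order`, `E` and `reversal_of`; when `typology` is
#'   given, also `genus_count`, plus a `summary` attribute with `pearson_r`,
#'   `slope` and `n_orders_used`, and the `lm` fit in attribute `fit`.
#' @export
word_order_analysis <- function(phrases, typology = NULL) {
  stopifnot(is.data.frame(phrases),
            all(c(unname(np_slots), "count") %in% names(phrases)))
  if (nrow(phrases) == 0) {
    abort("phrase table is empty", class = "predinfo_domain_error")
  }
  if (anyNA(phrases$noun)) abort("the noun slot must always be present")
  prob <- phrases$count / sum(phrases$count)
  slot_values <- lapply(unname(np_slots), function(s) as.character(phrases[[s]]))
  perms <- perm_matrix(4L)
  orders <- vapply(seq_len(nrow(perms)), function(r) order_label(perms[r, ]),
                   character(1))
  e <- vapply(seq_len(nrow(perms)), function(r) {
    p <- perms[r, ]
    toks <- lapply(seq_len(nrow(phrases)), function(i) {
      vals <- vapply(p, function(s) slot_values[[s]][i], character(1))
      vals[!is.na(vals)]
    })
    predictive_info(tibble::tibble(form = toks, prob = prob), mode = "word")
  }, numeric(1))
  rev_label <- vapply(seq_len(nrow(perms)), function(r) {
    order_label(rev(perms[r, ]))
  }, character(1))
  out <- tibble::tibble(order = orders, E = e, reversal_of = rev_label)
  summary <- list(max_reversal_gap = max(abs(out$E - out$E[match(rev_label, orders)])))
  fit <- NULL
  if (!is.null(typology)) {
    stopifnot(all(c("order", "genus_count") %in% names(typology)))
    if (!all(typology$order %in% orders)) {
      abort("typology orders do not match the D-N-A-n slot labels",
            class = "predinfo_key_error")
    }
    out <- dplyr::left_join(out, typology, by = "order")
    used <- out[!is.na(out$genus_count) & out$genus_count > 0, ]
    fit <- stats::lm(log(genus_count) ~ E, data = used)
    summary$pearson_r <- stats::cor(used$E, log(used$genus_count))
    summary$slope <- unname(stats::coef(fit)[["E"]])
    summary$n_orders_used <- nrow(used)
  }
  out <- experiment_result(out, summary)
  attr(out, "fit") <- fit
  out
}

#' Binarize real-valued semantic norms
#'
#' Recodes each feature as 1 where the value strictly exceeds the unweighted
#' mean of that feature across all words, 0 otherwise.  A constant feature
#' becomes all-zero with a warning.
#'
#' @param norms Data frame with a `word` column and numeric feature columns.
#' @param exclude Columns to leave untouched (default `word`, `frequency`).
#' @return The data frame with feature columns binarized to 0/1 integers.
#' @export
binarize_norms <- function(norms, exclude = c("word", "frequency")) {
  stopifnot(is.data.frame(norms), nrow(norms) >= 2)
  feats <- setdiff(names(norms), exclude)
  for (f in feats) {
    v <- norms[[f]]
    if (!is.numeric(v)) next
    if (max(v) == min(v)) {
      warn(sprintf("feature '%s' is constant; binarized to all 0", f))
    }
    norms[[f]] <- as.integer(v > mean(v))
  }
  norms
}

mi_pair <- function(x, y, w) {
  hx <- weighted_entropy(as.numeric(tapply(w, x, sum)))
  hy <- weighted_entropy(as.numeric(tapply(w, y, sum)))
  hxy <- weighted_entropy(as.numeric(tapply(w, paste(x, y, sep = "\r"), sum)))
  max(hx + hy - hxy, 0)
}

#' Pairwise mutual information of binary semantic features
#'
#' `I[f_i : f_j]` in bits for every feature pair under the word-frequency
#' distribution; the diagonal holds the feature entropies `H[f_i]`.
#'
#' @param norms Binarized norm table (see [binarize_norms()]) with a `word`
#'   column, binary feature columns, and optionally `frequency`.
#' @param features Feature columns (default: all binary columns).
#' @return A symmetric matrix of bits with feature dimnames.
#' @export
pairwise_feature_mi <- function(norms, features = NULL) {
  stopifnot(is.data.frame(norms))
  features <- features %||%
    names(norms)[vapply(norms, function(v) {
      is.numeric(v) && all(v %in% c(0, 1))
    }, logical(1))]
  w <- if ("frequency" %in% names(norms)) norms$frequency else rep(1, nrow(norms))
  if (any(w < 0)) abort("frequencies must be non-negative")
  w <- w / sum(w)
  k <- length(features)
  out <- matrix(0, k, k, dimnames = list(features, features))
  for (i in seq_len(k)) {
    out[i, i] <- weighted_entropy(as.numeric(tapply(w, norms[[features[i]]], sum)))
    for (j in seq_len(k)) {
      if (j > i) {
        out[i, j] <- out[j, i] <- mi_pair(norms[[features[i]]], norms[[features[j]]], w)
      }
    }
  }
  out
}

#' Within-word and across-word feature mutual information for verb-object pairs
#'
#' Under the verb-object pair distribution, computes the pairwise MI of one
#' word's features with itself (within-verb and within-object matrices) and
#' the MI between verb feature i and object feature j (across matrix, not
#' symmetric).
#'
#' @param norms Binarized norm table with `word` and binary feature columns.
#' @param pairs Data frame with columns `verb`, `object`, `count`; both words
#'   must appear in `norms`.
#' @param features Feature columns (default: all binary columns of `norms`).
#' @return A list of class `cross_word_mi` with `within_verb`,
#'   `within_object`, `across`, `mean_within`, `mean_across` (off-diagonal
#'   means; `across` uses all cells).
#' @export
cross_word_feature_mi <- function(norms, pairs, features = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("verb", "object", "count") %in% names(pairs)))
  if (nrow(pairs) == 0) {
    abort("pair table is empty", class = "predinfo_domain_error")
  }
  features <- features %||%
    names(norms)[vapply(norms, function(v) {
      is.numeric(v) && all(v %in% c(0, 1))
    }, logical(1))]
  iv <- match(pairs$verb, norms$word)
  io <- match(pairs$object, norms$word)
  if (anyNA(iv) || anyNA(io)) abort("all pair words must appear in the norm table")
  w <- pairs$count / sum(pairs$count)
  k <- length(features)
  vf <- lapply(features, function(f) norms[[f]][iv])
  of <- lapply(features, function(f) norms[[f]][io])
  within <- function(fs) {
    m <- matrix(0, k, k, dimnames = list(features, features))
    for (i in seq_len(k)) {
      m[i, i] <- weighted_entropy(as.numeric(tapply(w, fs[[i]], sum)))
      for (j in seq_len(k)) if (j > i) {
        m[i, j] <- m[j, i] <- mi_pair(fs[[i]], fs[[j]], w)
      }
    }
    m
  }
  wv <- within(vf)
  wo <- within(of)
  across <- matrix(0, k, k, dimnames = list(features, features))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      across[i, j] <- mi_pair(vf[[i]], of[[j]], w)
    }
  }
  off <- function(m) m[row(m) != col(m)]
  structure(list(within_verb = wv, within_object = wo, across = across,
                 mean_within = mean(c(off(wv), off(wo))),
                 mean_across = mean(across)),
            class = "cross_word_mi")
}

#' @export
print.cross_word_mi <- function(x, ...) {
  cat(sprintf("<cross_word_mi: mean within = %.4f bits, mean across = %.4f bits>\n",
              x$mean_within, x$mean_across))
  invisible(x)
}
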