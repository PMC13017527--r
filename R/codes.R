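# Code builders (systematic / holistic), counterfactual baseline generators,
# and scorers for systematicity, contiguity and well-nestedness.

#' Systematic (homomorphic) code over a factored source
#'
#' Builds the form of each meaning as the concatenation of per-feature
#' subforms: `L(m) = f_1(m_1) f_2(m_2) ...` in the given feature order.  This
#' is the operational sense of systematicity: the form of a composite meaning
#' is the combination of the forms of its parts.
#'
#' @param data A source tibble with one column per feature variable (plus,
#'   optionally, `prob`).
#' @param subforms Named list: for each feature, a named character vector
#'   mapping feature values to sub-strings.  Each map must be injective.
#' @param order Feature order of concatenation (default: order of `subforms`).
#' @return `data` with a `form` column appended.
#' @examples
#' src <- product_bernoulli_source()
#' digits <- c(`0` = "0", `1` = "1")
#' systematic_code(src, list(M1 = digits, M2 = digits, M3 = digits))
#' @export
systematic_code <- function(data, subforms, order = names(subforms)) {
  stopifnot(is.data.frame(data), all(order %in% names(data)),
            all(order %in% names(subforms)))
  for (f in order) {
    m <- subforms[[f]]
    if (anyDuplicated(m)) {
      abort(sprintf("subform map for '%s' is not injective", f),
            class = "predinfo_ambiguity_error")
    }
    vals <- unique(as.character(data[[f]]))
    if (!all(vals %in% names(m))) {
      abort(sprintf("subform map for '%s' does not cover all values", f))
    }
  }
  parts <- lapply(order, function(f) unname(subforms[[f]][as.character(data[[f]])]))
  data$form <- do.call(paste0, parts)
  data
}

#' Holistic code: a seeded uniformly random bijection onto a form inventory
#'
#' @param data Source tibble (one row per meaning).
#' @param forms Character vector of distinct forms, one per meaning.
#' @param seed Integer seed.
#' @return `data` with a `form` column appended.
#' @export
random_bijection_code <- function(data, forms, seed = 1) {
  stopifnot(is.data.frame(data))
  if (length(forms) != nrow(data)) {
    abort("need exactly one form per meaning", class = "predinfo_arity_error")
  }
  if (anyDuplicated(forms)) abort("forms must be distinct")
  data$form <- with_seed(seed, sample(forms))
  data
}

#' Enumerate all bijective codes between meanings and forms
#'
#' Yields every one of the `n!` bijections exactly once, as an enumeration
#' object; realize individual codes with [code_at()].  Refuses `n > 10`.
#'
#' @param meanings Data frame of meanings (one per row) or a vector.
#' @param forms Character vector of distinct forms, same length.
#' @return An object of class `code_enumeration` with an `n! x n` assignment
#'   matrix (`$assign`): row `r`, column `m` gives the index of the form
#'   assigned to meaning `m` in the `r`-th bijection.
#' @export
enumerate_bijections <- function(meanings, forms) {
  n <- if (is.data.frame(meanings)) nrow(meanings) else length(meanings)
  if (n != length(forms)) {
    abort("meanings and forms must have equal size", class = "predinfo_arity_error")
  }
  if (n > 10) {
    abort("refusing to enumerate more than 10! bijections",
          class = "predinfo_domain_error")
  }
  structure(list(meanings = meanings, forms = forms, assign = perm_matrix(n)),
            class = "code_enumeration")
}

#' @export
print.code_enumeration <- function(x, ...) {
  cat(sprintf("<code_enumeration: %d bijections over %d meanings>\n",
              nrow(x$assign), ncol(x$assign)))
  invisible(x)
}

#' @rdname enumerate_bijections
#' @param enum A `code_enumeration`.
#' @param i Index of the bijection to realize.
#' @export
code_at <- function(enum, i) {
  stopifnot(inherits(enum, "code_enumeration"))
  m <- enum$meanings
  if (!is.data.frame(m)) m <- tibble::tibble(meaning = m)
  m$form <- enum$forms[enum$assign[i, ]]
  m
}

#' Scramble a code by per-length position permutations
#'
#' Applies, uniformly to every form of length `L`, the permutation registered
#' for `L`: output position `j` takes the input symbol at position `perm[j]`.
#' This realizes counterfactual "non-local" string combination functions.
#'
#' @param data Code tibble with a `form` column.
#' @param perm Either a single integer permutation (applied to the one form
#'   length it matches) or a named list of permutations keyed by form length.
#' @param form Name of the form column.
#' @return `data` with the `form` column rewritten.
#' @export
apply_position_permutation <- function(data, perm, form = "form") {
  stopifnot(is.data.frame(data), form %in% names(data))
  forms <- data[[form]]
  lens <- nchar(forms)
  if (!is.list(perm)) perm <- stats::setNames(list(perm), length(perm))
  for (l in unique(lens)) {
    key <- as.character(l)
    p <- perm[[key]]
    if (is.null(p)) {
      abort(sprintf("no permutation supplied for form length %d", l),
            class = "predinfo_domain_error")
    }
    stopifnot(length(p) == l, all(sort(p) == seq_len(l)))
    idx <- which(lens == l)
    chars <- strsplit(forms[idx], "", fixed = TRUE)
    forms[idx] <- vapply(chars, function(ch) paste(ch[p], collapse = ""),
                         character(1))
  }
  data[[form]] <- forms
  data
}

# draw one random permutation per form length, shared across all forms of
# that length (the deterministic non-local baseline for variable-length codes)
random_length_permutations <- function(lens) {
  lens <- sort(unique(lens))
  stats::setNames(lapply(lens, sample.int), as.character(lens))
}

#' Permute the assignment of forms to meanings
#'
#' The "unnatural" baseline: `L'(m) = L(pi(m))` for a uniformly random
#' bijection `pi` over meanings.  The multiset of forms (hence the letter
#' statistics of the lexicon) is preserved; only the form-meaning relation
#' changes, which matters because meanings carry unequal probability.
#'
#' @inheritParams apply_position_permutation
#' @param seed Integer seed.
#' @return `data` with the `form` column permuted.
#' @export
permute_meanings <- function(data, seed = 1, form = "form") {
  stopifnot(is.data.frame(data), form %in% names(data))
  if (anyDuplicated(data[[form]])) {
    abort("code must be injective to permute meanings", class = "predinfo_ambiguity_error")
  }
  data[[form]] <- with_seed(seed, sample(data[[form]]))
  data
}

#' @describeIn permute_meanings Random form-meaning permutation restricted to
#'   classes of equal form length, so every meaning keeps a form of its
#'   attested length.
#' @export
permute_meanings_length_matched <- function(data, seed = 1, form = "form") {
  stopifnot(is.data.frame(data), form %in% names(data))
  if (anyDuplicated(data[[form]])) {
    abort("code must be injective to permute meanings", class = "predinfo_ambiguity_error")
  }
  forms <- data[[form]]
  lens <- nchar(forms)
  data[[form]] <- with_seed(seed, {
    out <- forms
    for (l in unique(lens)) {
      idx <- which(lens == l)
      out[idx] <- forms[idx][sample.int(length(idx))]
    }
    out
  })
  data
}

#' Deterministic manner-preserving phoneme scramble
#'
#' Scrambles the phonemes of a word while preserving each position's manner
#' of articulation: positions are grouped by manner class and a random
#' permutation is applied within every class group.  The permutation is
#' derived deterministically from `(seed, word identity)`, so identical words
#' scramble identically anywhere in a lexicon and reruns are reproducible.
#'
#' @param phonemes Character vector of phoneme tokens for one word.
#' @param classes Character vector of manner classes, same length.
#' @param seed Integer global seed.
#' @param word Word identity used (with `seed`) to derive the permutation;
#'   defaults to the concatenated phonemes.
#' @return Scrambled phoneme vector with the same manner-class skeleton.
#' @export
manner_preserving_scramble <- function(phonemes, classes, seed = 1,
                                       word = paste(phonemes, collapse = "")) {
  if (length(phonemes) != length(classes) || anyNA(classes)) {
    abort("every phoneme needs a manner class", class = "predinfo_mapping_error")
  }
  out <- phonemes
  with_seed(derive_seed(seed, word), {
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      if (length(idx) > 1) out[idx] <- phonemes[idx][sample.int(length(idx))]
    }
  })
  out
}

#' Number of features expressed systematically by a fixed-length code
#'
#' Counts the feature variables `M_i` for which some string position `j`
#' carries `M_i` systematically: the symbol at `j` is a bijective function of
#' `M_i` alone (constant in all other variables), with each position claimed
#' by at most one feature.  A fully systematic code over `k` features scores
#' `k`; a fully holistic one scores 0.
#'
#' @param data Code tibble: feature columns plus a `form` column of strings
#'   whose common length equals the number of features.
#' @param features Character vector of feature column names (default: all
#'   columns except `form` and `prob`).
#' @param form Name of the form column.
#' @return Integer count of systematically expressed features.
#' @export
count_systematic_features <- function(data, features = NULL, form = "form") {
  stopifnot(is.data.frame(data), form %in% names(data))
  features <- features %||% setdiff(names(data), c(form, "prob"))
  forms <- data[[form]]
  L <- unique(nchar(forms))
  if (length(L) != 1 || L != length(features)) {
    abort("code must be fixed-length with length equal to the number of features",
          class = "predinfo_domain_error")
  }
  sym <- do.call(rbind, strsplit(forms, "", fixed = TRUE))
  k <- length(features)
  compat <- matrix(FALSE, k, L)
  for (i in seq_len(k)) {
    mi <- as.character(data[[features[i]]])
    for (j in seq_len(L)) {
      per_value <- tapply(sym[, j], mi, function(s) {
        u <- unique(s)
        if (length(u) == 1) u else NA_character_
      })
      ok <- !anyNA(per_value) && !anyDuplicated(per_value)
      compat[i, j] <- isTRUE(ok)
    }
  }
  max_bipartite_matching(compat)
}

# maximum matching of a small k x L boolean compatibility matrix
max_bipartite_matching <- function(compat) {
  k <- nrow(compat)
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (k - i + 1L) <= best) return()
    if (i > k) {
      best <<- max(best, count)
      return()
    }
    for (j in which(compat[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1L, used, count + 1L)
      used[j] <- FALSE
    }
    recurse(i + 1L, used, count)
  }
  recurse(1L, rep(FALSE, ncol(compat)), 0L)
  best
}

#' Is every block contiguous under a position permutation?
#'
#' With the convention of [apply_position_permutation()] (output position `j`
#' takes input position `perm[j]`), a block of input positions stays
#' contiguous iff its image is an unbroken interval of output positions.
#'
#' @param perm Integer permutation of positions.
#' @param blocks List of integer vectors: the input positions of each block
#'   ("word"); blocks must be disjoint and cover all positions.
#' @return `TRUE` iff the image of every block is a contiguous interval.
#' @export
blocks_contiguous <- function(perm, blocks) {
  stopifnot(all(sort(unlist(blocks)) == seq_along(perm)))
  all(vapply(blocks, function(b) {
    img <- which(perm %in% b)
    max(img) - min(img) + 1L == length(img)
  }, logical(1)))
}

#' Is a position permutation well nested with respect to a tree?
#'
#' A code is well nested when the positions of every node (grouping) of the
#' constituency tree map to a contiguous interval of output positions.
#'
#' @param perm Integer permutation of positions.
#' @param tree List of integer vectors, one per tree node (internal nodes
#'   suffice; leaves and the root are trivially contiguous).
#' @return `TRUE` iff every node's position set is contiguous under `perm`.
#' @export
is_well_nested <- function(perm, tree) {
  all(vapply(tree, function(node) {
    img <- which(perm %in% node)
    max(img) - min(img) + 1L == length(img)
  }, logical(1)))
}
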