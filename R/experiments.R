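# Deterministic, seeded drivers for the five simulation experiments: each
# returns a tidy table of codes with E values and structural scores, plus a
# `summary` attribute holding the machine-checkable conclusions.

all_binary_strings <- function(len) {
  g <- do.call(tidyr::expand_grid,
               stats::setNames(rep(list(0:1), len), paste0("b", seq_len(len))))
  do.call(paste0, g)
}

forms_to_int <- function(forms, symbols) {
  lapply(strsplit(forms, "", fixed = TRUE), function(ch) match(ch, symbols))
}

forms_to_matrix <- function(forms, symbols) {
  t(vapply(strsplit(forms, "", fixed = TRUE),
           function(ch) match(ch, symbols), integer(nchar(forms[1]))))
}

experiment_result <- function(tbl, summary, ...) {
  attr(tbl, "summary") <- summary
  extras <- list(...)
  for (nm in names(extras)) attr(tbl, nm) <- extras[[nm]]
  tbl
}

#' Checked conclusions of an experiment driver
#'
#' @param x A table returned by one of the `run_*` drivers.
#' @return Named list of claim checks (logicals and margins).
#' @export
experiment_summary <- function(x) attr(x, "summary")

#' Systematic versus holistic codes for three weighted coin flips
#'
#' Builds the product-Bernoulli source, the identity systematic code (one
#' digit per coin) and `n_holistic` seeded random bijections onto the
#' length-3 binary strings, and computes E for each.
#'
#' @param epsilon Source skew increment.
#' @param seed Integer seed for the holistic draws.
#' @param n_holistic Number of holistic bijections to draw.
#' @return A tibble with columns `language`, `draw`, `E`, `systematicity`.
#'   The `summary` attribute reports the fraction of non-systematic holistic
#'   draws with `E > E_systematic`.
#' @export
run_coinflip_comparison <- function(epsilon = 0.05, seed = 1, n_holistic = 20) {
  src <- product_bernoulli_source(epsilon)
  digits <- c(`0` = "0", `1` = "1")
  sys <- systematic_code(src, list(M1 = digits, M2 = digits, M3 = digits))
  e_sys <- predictive_info(sys)
  forms <- all_binary_strings(3)
  draws <- purrr::map(seq_len(n_holistic), function(d) {
    code <- random_bijection_code(src, forms, seed = derive_seed(seed, paste0("holistic", d)))
    tibble::tibble(language = "holistic", draw = d,
                   E = predictive_info(code),
                   systematicity = count_systematic_features(code, c("M1", "M2", "M3")))
  })
  out <- dplyr::bind_rows(
    tibble::tibble(language = "systematic", draw = 0L, E = e_sys,
                   systematicity = count_systematic_features(sys, c("M1", "M2", "M3"))),
    dplyr::bind_rows(draws)
  )
  hol <- out[out$language == "holistic" & out$systematicity < 3, ]
  experiment_result(out, list(
    E_systematic = e_sys,
    n_holistic_compared = nrow(hol),
    frac_systematic_wins = mean(e_sys < hol$E)
  ))
}

#' Predictive information of all bijections onto length-3 binary strings
#'
#' Enumerates all `8! = 40320` bijective codes from the eight three-coin
#' meanings to the length-3 binary strings, computing E and the systematicity
#' score (number of coins expressed systematically) for each.
#'
#' @param epsilon Source skew increment.
#' @return A tibble with columns `code_id`, `E`, `systematicity` and a
#'   list-column `assign` (form index per meaning), sorted by `(E, code_id)`.
#'   Attributes: `forms`, `prob` for recomputation; `summary` holds the
#'   minimum-E systematicity check.
#' @export
run_bijection_enumeration <- function(epsilon = 0.05) {
  src <- product_bernoulli_source(epsilon)
  forms <- all_binary_strings(3)
  enum <- enumerate_bijections(src, forms)
  assign <- enum$assign
  symbols <- c("0", "1")
  e <- pi_assign_sweep_cpp(forms_to_int(forms, symbols), src$prob, assign, 3L)

  # systematicity, specialised to binary features and binary digits: the
  # symbol at position j is a bijective function of M_i alone iff the digit
  # column equals M_i or its complement across all meanings
  digits <- forms_to_matrix(forms, symbols) - 1L
  m <- as.matrix(src[, c("M1", "M2", "M3")])
  scores <- vapply(seq_len(nrow(assign)), function(r) {
    b <- digits[assign[r, ], , drop = FALSE]
    compat <- matrix(FALSE, 3L, 3L)
    for (i in 1:3) {
      for (j in 1:3) {
        compat[i, j] <- all(b[, j] == m[, i]) || all(b[, j] == 1L - m[, i])
      }
    }
    max_bipartite_matching(compat)
  }, integer(1))

  out <- tibble::tibble(code_id = seq_len(nrow(assign)), E = e,
                        systematicity = scores,
                        assign = lapply(seq_len(nrow(assign)),
                                        function(r) assign[r, ]))
  out <- dplyr::arrange(out, .data$E, .data$code_id)
  e_min <- min(out$E)
  at_min <- out$systematicity[out$E <= e_min + 1e-12]
  experiment_result(out, list(
    n_codes = nrow(out),
    min_E = e_min,
    all_min_fully_systematic = all(at_min == 3L),
    exists_worse_nonsystematic = any(out$systematicity < 3L & out$E > e_min + 1e-12)
  ), forms = forms, prob = src$prob)
}

mixture_candidates <- function(src) {
  x12 <- (src$M1 + src$M2) %% 2
  x23 <- (src$M2 + src$M3) %% 2
  list(
    systematic = paste0(src$M1, src$M2, src$M3),
    natural = paste0(src$M1, x23, src$M3),
    unnatural = paste0(src$M1, x12, src$M3),
    nonlocal = paste0(src$M2, src$M1, src$M3)
  )
}

#' Candidate codes under increasing correlation between M2 and M3
#'
#' Sweeps the mixture source over a grid of `alpha` and computes E for four
#' candidate codes: fully systematic; "natural" partial-holistic (the tied
#' pair `(M2, M3)` expressed jointly as a two-symbol block); "unnatural"
#' partial-holistic (the independent pair `(M1, M2)` expressed jointly); and
#' a non-local systematic code in which `M1`'s letter separates the letters
#' of `M2` and `M3`.  Block codings keep total form length 3 for
#' comparability.
#'
#' @param alphas Grid of mixture weights in `[0, 1]`.
#' @param epsilon Source skew increment.
#' @return A tibble with columns `alpha`, `mi` (`I[M2:M3]` in bits),
#'   `language`, `E`.
#' @export
run_mixture_sweep <- function(alphas = seq(0, 1, by = 0.1), epsilon = 0.05) {
  rows <- purrr::map(alphas, function(a) {
    src <- correlated_mixture_source(a, epsilon)
    mi <- mutual_information(src, "M2", "M3")
    cands <- mixture_candidates(src)
    purrr::imap(cands, function(forms, lang) {
      d <- src
      d$form <- forms
      tibble::tibble(alpha = a, mi = mi, language = lang,
                     E = predictive_info(d))
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  wide <- tidyr::pivot_wider(out, names_from = "language", values_from = "E")
  a_lo <- wide[wide$alpha == min(alphas), ]
  a_hi <- wide[wide$alpha == max(alphas), ]
  experiment_result(out, list(
    mi_strictly_increasing = all(diff(wide$mi[order(wide$alpha)]) > 0),
    systematic_argmin_at_low = a_lo$systematic <=
      min(a_lo$natural, a_lo$unnatural, a_lo$nonlocal) + 1e-12,
    natural_best_at_high = a_hi$natural < a_hi$systematic &&
      a_hi$natural < a_hi$unnatural,
    natural_never_worse_than_unnatural = all(wide$natural <= wide$unnatural + 1e-12)
  ))
}

#' Scrambled variants of a two-word systematic code for a Zipfian source
#'
#' A Zipf-distributed source over 100 two-digit meanings is coded by two
#' length-4 binary "words", one per digit (each digit value mapped to a
#' distinct random string in `{0,1}^4`).  E is computed for all 40320
#' permutations of the eight string positions; each permutation is flagged
#' for whether both words stay contiguous.
#'
#' @param seed Seed for drawing the digit words.
#' @param perms Optional integer matrix of position permutations (default:
#'   all `8!`).
#' @return A tibble with `perm_id`, list-column `perm`, `E`, `contiguous`,
#'   sorted by `(E, perm_id)`; attributes `forms`, `prob` for recomputation.
#' @export
run_locality_permutations <- function(seed = 1, perms = NULL) {
  src <- zipfian_source(100)
  d1 <- src$i %/% 10L
  d2 <- src$i %% 10L
  pool <- all_binary_strings(4)
  words <- with_seed(seed, list(w1 = sample(pool, 10), w2 = sample(pool, 10)))
  forms <- paste0(words$w1[d1 + 1L], words$w2[d2 + 1L])
  symbols <- c("0", "1")
  if (is.null(perms)) perms <- perm_matrix(8L)
  e <- pi_perm_sweep_cpp(forms_to_matrix(forms, symbols), src$prob, perms, 3L)
  blocks <- list(1:4, 5:8)
  contig <- vapply(seq_len(nrow(perms)), function(r) {
    blocks_contiguous(perms[r, ], blocks)
  }, logical(1))
  out <- tibble::tibble(perm_id = seq_len(nrow(perms)),
                        perm = lapply(seq_len(nrow(perms)), function(r) perms[r, ]),
                        E = e, contiguous = contig)
  out <- dplyr::arrange(out, .data$E, .data$perm_id)
  experiment_result(out, list(
    argmin_contiguous = out$contiguous[1],
    mean_E_contiguous = mean(out$E[out$contiguous]),
    mean_E_noncontiguous = mean(out$E[!out$contiguous]),
    noncontiguous_sometimes_better =
      min(out$E[!out$contiguous]) < max(out$E[out$contiguous])
  ), forms = forms, prob = src$prob)
}

#' All orderings of a systematic code for the hierarchical source
#'
#' The six-variable hierarchical source is coded systematically with one
#' five-letter symbol per variable; E is computed for all 720 orderings of
#' the six positions, and each ordering is flagged for well-nestedness with
#' respect to the coupling tree `((M1, M2), M3)` and `((M4, M5), M6)`.
#'
#' @param alpha,beta,gamma Coupling constants of [hierarchical_source()].
#' @return A tibble with `perm_id`, list-column `perm`, `E`, `well_nested`,
#'   sorted by `(E, perm_id)`; attributes `forms`, `prob`.
#' @export
run_hierarchy_permutations <- function(alpha = 0.01, beta = 0.20, gamma = 0.99) {
  src <- hierarchical_source(alpha, beta, gamma)
  letters5 <- c("a", "b", "c", "d", "e")
  vars <- paste0("M", 1:6)
  forms_mat <- as.matrix(src[, vars]) + 1L
  storage.mode(forms_mat) <- "integer"
  forms <- apply(forms_mat, 1, function(r) paste(letters5[r], collapse = ""))
  perms <- perm_matrix(6L)
  e <- pi_perm_sweep_cpp(forms_mat, src$prob, perms, 6L)
  tree <- list(c(1L, 2L), 1:3, c(4L, 5L), 4:6)
  nested <- vapply(seq_len(nrow(perms)), function(r) {
    is_well_nested(perms[r, ], tree)
  }, logical(1))
  out <- tibble::tibble(perm_id = seq_len(nrow(perms)),
                        perm = lapply(seq_len(nrow(perms)), function(r) perms[r, ]),
                        E = e, well_nested = nested)
  out <- dplyr::arrange(out, .data$E, .data$perm_id)
  rev_e <- out$E[match(
    vapply(out$perm, function(p) paste(rev(p), collapse = "-"), character(1)),
    vapply(out$perm, function(p) paste(p, collapse = "-"), character(1))
  )]
  experiment_result(out, list(
    argmin_well_nested = out$well_nested[1],
    mean_E_well_nested = mean(out$E[out$well_nested]),
    mean_E_other = mean(out$E[!out$well_nested]),
    max_reversal_gap = max(abs(out$E - rev_e))
  ), forms = forms, prob = src$prob)
}

#' Write an experiment table and its claim summary to disk
#'
#' Emits the ranked table as TSV (list-columns collapsed to dashed strings)
#' and the `summary` attribute as JSON.
#'
#' @param x A driver result.
#' @param tsv,json Output paths.
#' @return `x`, invisibly.
#' @export
write_experiment <- function(x, tsv, json) {
  flat <- x
  for (nm in names(flat)) {
    if (is.list(flat[[nm]])) {
      flat[[nm]] <- vapply(flat[[nm]], paste, character(1), collapse = "-")
    }
  }
  readr::write_tsv(flat, tsv)
  jsonlite::write_json(experiment_summary(x), json, auto_unbox = TRUE, digits = NA)
  invisible(x)
}
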