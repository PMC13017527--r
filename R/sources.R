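# Source distributions over meanings used by the simulation experiments and
# the empirical (count-table) analyses.  A source is a tibble with one column
# per feature variable plus a `prob` column summing to 1.

zipf_probs <- function(n, exponent = 1) {
  p <- (seq_len(n))^(-exponent)
  p / sum(p)
}

#' Product-of-Bernoullis source over three binary features
#'
#' Three independent weighted coin flips `M1 ~ Bernoulli(2/3)`,
#' `M2 ~ Bernoulli(2/3 + epsilon)`, `M3 ~ Bernoulli(2/3 + 2 epsilon)`.
#'
#' @param epsilon Skew increment; all three success probabilities must lie in
#'   `[0, 1]`.
#' @return A tibble with columns `M1`, `M2`, `M3` (0/1) and `prob`.
#' @export
product_bernoulli_source <- function(epsilon = 0.05) {
  ps <- 2 / 3 + c(0, 1, 2) * epsilon
  if (any(ps < 0 | ps > 1)) {
    abort("Bernoulli parameters must lie in [0, 1]", class = "predinfo_domain_error")
  }
  out <- tidyr::expand_grid(M1 = 0:1, M2 = 0:1, M3 = 0:1)
  out$prob <- ifelse(out$M1 == 1, ps[1], 1 - ps[1]) *
    ifelse(out$M2 == 1, ps[2], 1 - ps[2]) *
    ifelse(out$M3 == 1, ps[3], 1 - ps[3])
  out
}

#' Mixture source with tunable correlation between M2 and M3
#'
#' Starts from the independent three-coin source and mixes the `(M2, M3)`
#' block with a perfectly tied pair:
#' `p_a(ijk) = p(M1=i) * [(1-a) p(M2=j) p(M3=k) + (a/2) delta_jk]`.
#' The mixture weight `alpha` moves `I[M2:M3]` from 0 (at `alpha = 0`) up to
#' at most 1 bit (at `alpha = 1`); `M1` stays independent throughout.
#'
#' @param alpha Mixture weight in `[0, 1]`.
#' @inheritParams product_bernoulli_source
#' @return A tibble with columns `M1`, `M2`, `M3`, `prob`.
#' @export
correlated_mixture_source <- function(alpha, epsilon = 0.05) {
  if (alpha < 0 || alpha > 1) {
    abort("alpha must lie in [0, 1]", class = "predinfo_domain_error")
  }
  ps <- 2 / 3 + c(0, 1, 2) * epsilon
  if (any(ps < 0 | ps > 1)) {
    abort("Bernoulli parameters must lie in [0, 1]", class = "predinfo_domain_error")
  }
  bern <- function(v, p) ifelse(v == 1, p, 1 - p)
  out <- tidyr::expand_grid(M1 = 0:1, M2 = 0:1, M3 = 0:1)
  out$prob <- bern(out$M1, ps[1]) *
    ((1 - alpha) * bern(out$M2, ps[2]) * bern(out$M3, ps[3]) +
       (alpha / 2) * as.numeric(out$M2 == out$M3))
  out
}

#' Zipfian source over n atomic meanings
#'
#' `p(m_i)` proportional to `(i + 1)^(-exponent)` for `i = 0 .. n-1`.
#'
#' @param n Number of meanings (>= 1).
#' @param exponent Zipf exponent (default 1).
#' @return A tibble with columns `i` (0-based rank), `meaning` and `prob`,
#'   strictly decreasing in `i`.
#' @export
zipfian_source <- function(n, exponent = 1) {
  if (!is.numeric(n) || n < 1) {
    abort("n must be >= 1", class = "predinfo_domain_error")
  }
  n <- as.integer(n)
  tibble::tibble(
    i = 0:(n - 1L),
    meaning = sprintf("m%d", 0:(n - 1L)),
    prob = zipf_probs(n, exponent)
  )
}

#' Hierarchically coupled source over six five-valued features
#'
#' A mixture distribution over `5^6 = 15625` meanings
#' `(M1, ..., M6)`, each variable over five outcomes, in which `(M1, M2)` and
#' `(M4, M5)` are highly internally correlated, weakly coupled to `M3` and
#' `M6` respectively, and the two triples are very weakly coupled to each
#' other:
#' \deqn{p = \alpha q_{123456} + (1-\alpha)
#'   [\beta q_{123} + (1-\beta)(\gamma q_{12} + (1-\gamma) q_1 q_2) q_3]
#'   [\beta q_{456} + (1-\beta)(\gamma q_{45} + (1-\gamma) q_4 q_5) q_6]}
#' Every `q` over a group of variables is a Zipfian distribution over the
#' lexicographically ordered product of its outcome sets.
#'
#' @param alpha,beta,gamma Coupling constants in `[0, 1]`; the defaults give
#'   the correlation structure used by [run_hierarchy_permutations()].
#' @return A tibble with columns `M1 .. M6` (values 0..4) and `prob`.
#' @export
hierarchical_source <- function(alpha = 0.01, beta = 0.20, gamma = 0.99) {
  for (v in c(alpha, beta, gamma)) {
    if (v < 0 || v > 1) {
      abort("coupling constants must lie in [0, 1]", class = "predinfo_domain_error")
    }
  }
  g <- tidyr::expand_grid(M1 = 0:4, M2 = 0:4, M3 = 0:4,
                          M4 = 0:4, M5 = 0:4, M6 = 0:4)
  qz <- function(idx, k) zipf_probs(5^k)[idx + 1L]
  lex <- function(...) {
    vars <- list(...)
    idx <- 0
    for (v in vars) idx <- idx * 5 + v
    idx
  }
  q1 <- function(v) qz(v, 1)
  left <- beta * qz(lex(g$M1, g$M2, g$M3), 3) +
    (1 - beta) * (gamma * qz(lex(g$M1, g$M2), 2) +
                    (1 - gamma) * q1(g$M1) * q1(g$M2)) * q1(g$M3)
  right <- beta * qz(lex(g$M4, g$M5, g$M6), 3) +
    (1 - beta) * (gamma * qz(lex(g$M4, g$M5), 2) +
                    (1 - gamma) * q1(g$M4) * q1(g$M5)) * q1(g$M6)
  g$prob <- alpha * qz(lex(g$M1, g$M2, g$M3, g$M4, g$M5, g$M6), 6) +
    (1 - alpha) * left * right
  g
}

#' Empirical source from a count table
#'
#' With `smoothing > 0`, add-`smoothing` smoothing over the full
#' cross-product of the attested values of every feature variable (unseen
#' cells get mass); with `smoothing = 0`, probabilities proportional to the
#' counts over observed tuples only (zero-count rows are dropped), as used
#' for phrase tables.
#'
#' @param counts A data frame with one column per feature variable and a
#'   `count` column of non-negative counts.
#' @param smoothing Additive smoothing constant (default 1/2).
#' @param count Name of the count column.
#' @return A tibble with the feature columns and `prob`.
#' @export
empirical_source <- function(counts, smoothing = 0.5, count = "count") {
  stopifnot(is.data.frame(counts), count %in% names(counts))
  cnt <- counts[[count]]
  if (any(cnt < 0)) abort("counts must be non-negative")
  feats <- setdiff(names(counts), count)
  if (smoothing > 0) {
    full <- counts[c(feats, count)]
    full <- tidyr::complete(full, !!!rlang::syms(feats),
                            fill = stats::setNames(list(0), count))
    w <- full[[count]] + smoothing
    out <- full[feats]
    out$prob <- w / sum(w)
  } else {
    if (sum(cnt) == 0) {
      abort("all counts are zero and smoothing is 0: empty source",
            class = "predinfo_empty_source")
    }
    keep <- cnt > 0
    out <- counts[keep, feats, drop = FALSE]
    out$prob <- cnt[keep] / sum(cnt[keep])
  }
  tibble::as_tibble(out)
}
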