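#' Build the stationary form process induced by a weighted set of forms
#'
#' A code together with a source induces a stationary symbol process: meanings
#' are sampled i.i.d., translated to strings, and the strings are concatenated
#' in both directions with a reserved delimiter `#` between them.  All
#' information-theoretic quantities of the package ([predictive_information()],
#' [entropy_rate()], [conditional_entropy()]) are computed exactly from this
#' object.  Meanings that share a form are aggregated (their probabilities
#' summed), so non-injective codes are allowed here; analyses that require an
#' unambiguous code check injectivity themselves.
#'
#' @param data A data frame with one row per meaning (or per form).
#' @param form Name of the column holding forms.  In `"letter"` mode a form is
#'   a string, split into single characters; in `"word"` mode it is a string of
#'   whitespace-separated tokens treated as atomic symbols.  A list column of
#'   character vectors is used as tokens directly.
#' @param prob Name of the probability column; `NULL` for a uniform
#'   distribution over rows.
#' @param mode `"letter"` or `"word"`.
#' @param delimiter Reserved boundary symbol, must not occur in any form.
#' @return An object of class `form_process`.
#' @examples
#' fp <- form_process(tibble::tibble(form = c("0", "1"), prob = c(0.5, 0.5)))
#' predictive_information(fp)$E # 1 bit
#' @export
form_process <- function(data, form = "form", prob = "prob",
                         mode = c("letter", "word"), delimiter = "#") {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(data), form %in% names(data))
  forms <- data[[form]]
  if (is.null(prob) || !prob %in% names(data)) {
    p <- rep(1 / nrow(data), nrow(data))
  } else {
    p <- data[[prob]]
  }
  check_distribution(p, what = "form distribution")

  tokens <- tokenize_forms(forms, mode)
  if (any(vapply(tokens, function(t) delimiter %in% t, logical(1)))) {
    abort(sprintf("forms must not contain the reserved delimiter '%s'", delimiter),
          class = "predinfo_reserved_symbol")
  }

  # drop zero-probability meanings, aggregate duplicate forms
  keep <- p > 1e-15
  tokens <- tokens[keep]
  p <- p[keep]
  key <- vapply(tokens, paste, character(1), collapse = "\r")
  agg <- rowsum(p, key, reorder = FALSE)
  first <- !duplicated(key)
  tokens <- tokens[first]
  p <- as.numeric(agg[match(key[first], rownames(agg)), 1])

  symbols <- sort(unique(unlist(tokens)))
  coded <- lapply(tokens, function(t) match(t, symbols))

  structure(
    list(tokens = coded, symbols = symbols, prob = p,
         L_max = max(lengths(coded)), mode = mode, delimiter = delimiter),
    class = "form_process"
  )
}

tokenize_forms <- function(forms, mode) {
  if (is.list(forms)) return(lapply(forms, as.character))
  if (mode == "letter") strsplit(forms, "", fixed = TRUE)
  else strsplit(trimws(forms), "\\s+")
}

#' @export
print.form_process <- function(x, ...) {
  cat(sprintf("<form_process: %d forms, %d symbols + '%s', L_max = %d, %s level>\n",
              length(x$tokens), length(x$symbols), x$delimiter, x$L_max, x$mode))
  invisible(x)
}

# render coded tokens back to display strings
render_window <- function(ints, process) {
  syms <- character(length(ints))
  syms[ints == 0L] <- process$delimiter
  syms[ints > 0L] <- process$symbols[ints[ints > 0L]]
  paste(syms, collapse = if (process$mode == "word") " " else "")
}

#' n-gram window distribution of a form process
#'
#' Distribution over windows of `n` consecutive symbols of the stationary
#' process.  Each form `s` contributes `|s| + 1` windows, one ending at every
#' symbol of `s#`, left-padded with delimiters where the window extends past
#' the start of the form; window weights are proportional to `prob(s)` with
#' normalizer `Z = sum(prob(s) * (|s| + 1))`.
#'
#' @param process A [form_process()].
#' @param n Window length (>= 1).
#' @return A tibble with columns `window` and `prob`, summing to 1.
#' @export
ngram_distribution <- function(process, n) {
  stopifnot(inherits(process, "form_process"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("n must be a positive integer", class = "predinfo_domain_error")
  }
  ngram_table(process, as.integer(n), context = FALSE)
}

# window distribution; with context = TRUE, the conditioning contexts instead:
# windows of length n ending one position earlier (including the
# all-delimiter context preceding the form's first symbol)
ngram_table <- function(process, n, context = FALSE) {
  if (n == 0) return(tibble::tibble(window = "", prob = 1))
  lens <- lengths(process$tokens)
  z <- sum(process$prob * (lens + 1))
  rows <- purrr::map2(process$tokens, process$prob, function(s, p) {
    len <- length(s)
    padded <- c(rep(0L, n + 1L), s, 0L)
    ends <- if (context) seq_len(len + 1L) - 1L else seq_len(len + 1L)
    wins <- vapply(ends, function(j) {
      render_window(padded[(j + 2L):(j + n + 1L)], process)
    }, character(1))
    tibble::tibble(window = wins, prob = p / z)
  })
  dplyr::summarise(dplyr::group_by(dplyr::bind_rows(rows), .data$window),
                   prob = sum(.data$prob), .groups = "drop")
}

#' Conditional n-gram entropy h_n
#'
#' The average entropy in bits of one symbol given a window of `n - 1`
#' preceding symbols: the entropy of the joint n-window table minus the
#' entropy of its conditioning-context table (the length `n - 1` windows
#' ending one position earlier, including the all-delimiter context before a
#' form's first symbol).  `h_1` is the marginal symbol entropy.  Computed
#' from the exact window distributions of the process.
#'
#' @inheritParams ngram_distribution
#' @return `h_n` in bits per symbol.
#' @export
conditional_entropy <- function(process, n) {
  stopifnot(inherits(process, "form_process"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("n must be a positive integer", class = "predinfo_domain_error")
  }
  n <- as.integer(n)
  joint <- shannon_entropy(ngram_distribution(process, n)$prob)
  context <- shannon_entropy(ngram_table(process, n - 1L, context = TRUE)$prob)
  joint - context
}

pi_result_cpp <- function(process) {
  pi_e_cpp(process$tokens, process$prob, length(process$symbols) + 1L)
}

#' Entropy rate of a form process
#'
#' The asymptotic per-symbol entropy `h`.  Because the delimiter statistically
#' severs consecutive forms, `h_n` is exactly constant for all
#' `n >= L_max + 2` (the conditioning window always reaches back to the
#' previous delimiter); the implementation verifies
#' `h_{L_max+2} = h_{L_max+3}` to 1e-12 and returns that common value.
#'
#' @inheritParams ngram_distribution
#' @return `h` in bits per symbol.
#' @export
entropy_rate <- function(process) {
  stopifnot(inherits(process, "form_process"))
  pi_result_cpp(process)$h
}

#' Predictive information (excess entropy) of a form process
#'
#' The mutual information between the infinite past and the infinite future
#' of the stationary symbol process, computed through the convergence of the
#' n-gram entropies: `E = sum_{n>=1} (h_n - h)`.  The sum is truncated
#' exactly at `n = L_max + 1` because `h_n = h` for all `n >= L_max + 2`
#' under the delimiter-padding construction (verified internally).
#'
#' @inheritParams ngram_distribution
#' @return An object of class `pi_result` with fields `E` (bits), `h`
#'   (bits/symbol), `h_series` (`h_1 .. h_N`) and `N = L_max + 2`.
#' @seealso [excess_entropy_cut()] for an independent computation of the same
#'   quantity through the past/future cut construction.
#' @export
predictive_information <- function(process) {
  stopifnot(inherits(process, "form_process"))
  res <- pi_result_cpp(process)
  n_keep <- res$L_max + 2L
  structure(
    list(E = res$E, h = res$h, h_series = res$h_series[seq_len(n_keep)],
         N = n_keep),
    class = "pi_result"
  )
}

#' @export
print.pi_result <- function(x, ...) {
  cat(sprintf("<pi_result: E = %.6f bits, h = %.6f bits/symbol, N = %d>\n",
              x$E, x$h, x$N))
  invisible(x)
}

#' @rdname predictive_information
#' @param x A `pi_result`.
#' @param ... Unused.
#' @export
tidy.pi_result <- function(x, ...) {
  tibble::tibble(n = seq_along(x$h_series), h_n = x$h_series,
                 excess = x$h_series - x$h)
}

#' @rdname predictive_information
#' @export
glance.pi_result <- function(x, ...) {
  tibble::tibble(E = x$E, h = x$h, N = x$N)
}

#' Predictive information of a tidy form table
#'
#' Convenience wrapper: builds the [form_process()] and returns `E` in bits.
#'
#' @inheritParams form_process
#' @return Predictive information in bits.
#' @export
predictive_info <- function(data, form = "form", prob = "prob",
                            mode = c("letter", "word")) {
  predictive_information(form_process(data, form, prob, mode))$E
}

#' Cut-construction oracle for excess entropy
#'
#' Independent re-derivation of predictive information as
#' `I[past : future]`: a pair (form `s`, cut point `k` in `0..|s|`) is drawn
#' with weight `prob(s)/Z`; the past class is the prefix `s[1..k]` and the
#' future class is the suffix `s[(k+1)..|s|]` followed by the delimiter.
#' Under the padding construction the within-form prefix is a sufficient
#' statistic of the infinite past, so this mutual information equals the
#' summed-h_n value of [predictive_information()] (to 1e-9).  Implemented in
#' plain R, separately from the n-gram machinery, so the two routes check
#' each other.
#'
#' @inheritParams ngram_distribution
#' @return Excess entropy in bits.
#' @export
excess_entropy_cut <- function(process) {
  stopifnot(inherits(process, "form_process"))
  lens <- lengths(process$tokens)
  z <- sum(process$prob * (lens + 1))
  pieces <- purrr::map2(process$tokens, process$prob, function(s, p) {
    len <- length(s)
    list(
      past = vapply(0:len, function(k) {
        paste(c("<", s[seq_len(k)]), collapse = ",")
      }, character(1)),
      fut = vapply(0:len, function(k) {
        paste(c(s[seq_len(len - k) + k], 0L), collapse = ",")
      }, character(1)),
      w = rep(p / z, len + 1L)
    )
  })
  past <- unlist(lapply(pieces, `[[`, "past"), use.names = FALSE)
  fut <- unlist(lapply(pieces, `[[`, "fut"), use.names = FALSE)
  w <- unlist(lapply(pieces, `[[`, "w"), use.names = FALSE)
  h_past <- weighted_entropy(as.numeric(tapply(w, past, sum)))
  h_fut <- weighted_entropy(as.numeric(tapply(w, fut, sum)))
  h_joint <- weighted_entropy(as.numeric(tapply(w, paste(past, fut, sep = "|"), sum)))
  max(h_past + h_fut - h_joint, 0)
}

#' Sample a symbol stream from a form process
#'
#' Draws forms i.i.d. from the form distribution and joins them with single
#' delimiters.  Used for Monte-Carlo validation of the analytic computations;
#' all headline quantities are exact and do not rely on sampling.
#'
#' @inheritParams ngram_distribution
#' @param length Number of symbols to return (>= 1).
#' @param seed Integer seed.
#' @return Character vector of `length` symbols (including delimiters).
#' @export
sample_stream <- function(process, length, seed = 1) {
  stopifnot(inherits(process, "form_process"), length >= 1)
  rendered <- lapply(process$tokens, function(s) process$symbols[s])
  mean_len <- sum(process$prob * (lengths(rendered) + 1))
  out <- with_seed(seed, {
    n_draw <- ceiling(length / mean_len) + 10L
    draws <- sample.int(length(rendered), n_draw, replace = TRUE,
                        prob = process$prob)
    stream <- unlist(lapply(draws, function(i) c(rendered[[i]], process$delimiter)))
    while (base::length(stream) < length) {
      extra <- sample.int(base::length(rendered), 50L, replace = TRUE,
                          prob = process$prob)
      stream <- c(stream,
                  unlist(lapply(extra, function(i) c(rendered[[i]], process$delimiter))))
    }
    stream
  })
  out[seq_len(length)]
}
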