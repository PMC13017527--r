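# internal helpers: seeded RNG scoping, validation, permutation enumeration

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit seed derived from a base seed and a string key, so that
# e.g. identical words scramble identically across a lexicon.
derive_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (cp in utf8ToInt(as.character(key))) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

check_distribution <- function(p, tol = 1e-12, what = "distribution") {
  if (!is.numeric(p) || length(p) == 0) {
    abort(sprintf("%s must be a non-empty numeric vector", what),
          class = "predinfo_invalid_distribution")
  }
  if (any(!is.finite(p)) || any(p < -tol)) {
    abort(sprintf("%s has negative or non-finite probabilities", what),
          class = "predinfo_invalid_distribution")
  }
  if (abs(sum(p) - 1) > max(tol, 1e-12 * length(p))) {
    abort(sprintf("%s does not sum to 1 (sum = %.15g)", what, sum(p)),
          class = "predinfo_invalid_distribution")
  }
  invisible(p)
}

# All permutations of 1..n as an (n!) x n integer matrix, lexicographic order.
perm_matrix <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    block <- cbind(first, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  storage.mode(out) <- "integer"
  out
}

# length of a form: characters in letter mode, tokens in word mode
form_lengths <- function(forms) {
  if (is.list(forms)) lengths(forms) else nchar(forms)
}
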