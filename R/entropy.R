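#' Shannon entropy of a discrete distribution
#'
#' Entropy in base-2 bits, with the convention that \eqn{0 \log 0 = 0}.
#'
#' @param p Numeric vector of probabilities (non-negative, summing to 1
#'   within `tol`).
#' @param tol Tolerance for the validity check of `p`.
#' @return Entropy in bits (a single number).
#' @examples
#' shannon_entropy(c(0.5, 0.5)) # 1 bit
#' shannon_entropy(1)           # 0 bits
#' @export
shannon_entropy <- function(p, tol = 1e-12) {
  check_distribution(p, tol)
  p <- p[p > 1e-15]
  -sum(p * log2(p))
}

#' Mutual information between two groups of columns of a joint table
#'
#' Computes \eqn{I[X:Y] = H[X] + H[Y] - H[X,Y]} in bits from a tidy joint
#' probability table: one row per outcome, outcome variables in columns, and
#' a probability column.  Values within `-1e-12` of zero are clipped to 0.
#'
#' @param data A data frame holding the joint distribution.
#' @param x,y Character vectors naming the columns that make up the two
#'   variables (each may be a group of columns, treated jointly).
#' @param prob Name of the probability column (default `"prob"`).
#' @return Mutual information in bits.
#' @examples
#' joint <- tidyr::expand_grid(a = 0:1, b = 0:1)
#' joint$prob <- 0.25
#' mutual_information(joint, "a", "b") # 0: independent fair coins
#' @export
mutual_information <- function(data, x, y, prob = "prob") {
  stopifnot(is.data.frame(data), all(c(x, y, prob) %in% names(data)))
  p <- data[[prob]]
  check_distribution(p, what = "joint distribution")
  key <- function(cols) {
    do.call(paste, c(unname(as.list(data[cols])), sep = "\r"))
  }
  hx <- shannon_entropy(as.numeric(tapply(p, key(x), sum)))
  hy <- shannon_entropy(as.numeric(tapply(p, key(y), sum)))
  hxy <- shannon_entropy(as.numeric(tapply(p, key(c(x, y)), sum)))
  mi <- hx + hy - hxy
  if (mi < -1e-12) {
    abort(sprintf("mutual information came out negative (%.3g)", mi))
  }
  max(mi, 0)
}

# entropy of a possibly unnormalized weight vector after normalization
weighted_entropy <- function(w) {
  shannon_entropy(w / sum(w))
}
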