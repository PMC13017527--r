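test_that("n-gram window distributions match hand enumerations", {
  fp <- form_process(tibble::tibble(form = "a", prob = 1))
  n1 <- ngram_distribution(fp, 1)
  expect_setequal(n1$window, c("a", "#"))
  expect_equal(sort(n1$prob), c(0.5, 0.5))
  n2 <- ngram_distribution(fp, 2)
  expect_setequal(n2$window, c("#a", "a#"))
  expect_equal(n2$prob, c(0.5, 0.5))

  fp2 <- form_process(tibble::tibble(form = c("0", "1"), prob = c(0.5, 0.5)))
  n1b <- ngram_distribution(fp2, 1)
  expect_equal(stats::setNames(n1b$prob, n1b$window)[c("#", "0", "1")],
               c(`#` = 0.5, `0` = 0.25, `1` = 0.25))
  expect_error(ngram_distribution(fp2, 0), class = "predinfo_domain_error")
})

test_that("suffix-marginalizing the n-table reproduces the (n-1)-table", {
  for (seed in c(3, 17)) {
    fp <- form_process(random_form_table(seed))
    for (n in 2:3) {
      tab_n <- ngram_distribution(fp, n)
      tab_n$suffix <- substring(tab_n$window, 2)
      marg <- tapply(tab_n$prob, tab_n$suffix, sum)
      tab_m <- ngram_distribution(fp, n - 1)
      expect_equal(sort(as.numeric(marg[tab_m$window])), sort(tab_m$prob),
                   tolerance = 1e-12)
    }
  }
})

test_that("conditional n-gram entropies match hand-derived values", {
  fp2 <- form_process(tibble::tibble(form = c("0", "1"), prob = c(0.5, 0.5)))
  expect_equal(conditional_entropy(fp2, 1), 1.5, tolerance = 1e-12)
  expect_equal(conditional_entropy(fp2, 2), 0.5, tolerance = 1e-12)
  expect_gte(conditional_entropy(fp2, 1), conditional_entropy(fp2, 2))
})

test_that("entropy rate matches enumeration and equals the converged h_n", {
  expect_equal(entropy_rate(form_process(tibble::tibble(form = "a", prob = 1))), 0)
  expect_equal(entropy_rate(form_process(tibble::tibble(form = c("0", "1"),
                                                        prob = c(0.5, 0.5)))),
               0.5, tolerance = 1e-12)
  expect_equal(entropy_rate(form_process(cube_table())), 0.75, tolerance = 1e-12)
})

test_that("predictive information matches the h_n summation on micro-cases", {
  r1 <- predictive_information(form_process(tibble::tibble(form = "a", prob = 1)))
  expect_equal(r1$E, 1, tolerance = 1e-12)
  expect_equal(r1$h_series[r1$N], r1$h, tolerance = 1e-12)
  r2 <- predictive_information(form_process(tibble::tibble(form = c("0", "1"),
                                                           prob = c(0.5, 0.5))))
  expect_equal(r2$E, 1, tolerance = 1e-12)
  expect_equal(r2$h_series[1:2], c(1.5, 0.5), tolerance = 1e-12)
})

test_that("C++ h_series agrees with the R window-table route", {
  for (seed in c(5, 23)) {
    fp <- form_process(random_form_table(seed))
    r <- predictive_information(fp)
    for (n in seq_len(min(4, r$N))) {
      expect_equal(r$h_series[n], conditional_entropy(fp, n), tolerance = 1e-10)
    }
  }
})

test_that("uniform source over the binary cube gives one E for any bijection", {
  d <- cube_table()
  e0 <- predictive_info(d)
  for (seed in 1:5) {
    d2 <- d
    d2$form <- predinfo:::with_seed(seed, sample(d$form))
    expect_equal(predictive_info(d2), e0, tolerance = 1e-12)
  }
})

test_that("Eq.-4 route equals the cut-construction oracle on random instances", {
  for (seed in 1:40) {
    fp <- form_process(random_form_table(seed))
    expect_lt(abs(predictive_information(fp)$E - excess_entropy_cut(fp)), 1e-9)
  }
})

test_that("h_series is non-increasing and E is non-negative", {
  for (seed in 41:60) {
    r <- predictive_information(form_process(random_form_table(seed)))
    expect_gte(r$E, 0)
    expect_true(all(diff(r$h_series) <= 1e-12))
  }
})

test_that("E is invariant under symbol relabeling and time reversal", {
  for (seed in 61:70) {
    d <- random_form_table(seed)
    e0 <- predictive_info(d)
    chars <- strsplit(d$form, "", fixed = TRUE)
    syms <- sort(unique(unlist(chars)))
    relab <- stats::setNames(rev(syms), syms)
    d_rel <- d
    d_rel$form <- vapply(chars, function(ch) paste(relab[ch], collapse = ""),
                         character(1))
    expect_equal(predictive_info(d_rel), e0, tolerance = 1e-12)
    d_rev <- d
    d_rev$form <- vapply(chars, function(ch) paste(rev(ch), collapse = ""),
                         character(1))
    expect_equal(predictive_info(d_rev), e0, tolerance = 1e-12)
  }
})

test_that("meanings sharing a form are aggregated; the delimiter is reserved", {
  agg <- form_process(tibble::tibble(form = c("a", "a"), prob = c(0.3, 0.7)))
  expect_length(agg$tokens, 1)
  expect_equal(agg$prob, 1)
  expect_error(form_process(tibble::tibble(form = "a#b", prob = 1)),
               class = "predinfo_reserved_symbol")
})

test_that("word-level mode treats whitespace-separated tokens as symbols", {
  d <- tibble::tibble(form = c("the cat", "the dog"), prob = c(0.5, 0.5))
  fp <- form_process(d, mode = "word")
  expect_equal(fp$L_max, 2)
  expect_setequal(fp$symbols, c("the", "cat", "dog"))
  # structurally identical to a letter-level code with one letter per word
  e_letters <- predictive_info(tibble::tibble(form = c("tc", "td"),
                                              prob = c(0.5, 0.5)))
  expect_equal(predictive_info(d, mode = "word"), e_letters, tolerance = 1e-12)
})

test_that("sampled streams reproduce the analytic statistics", {
  fp <- form_process(tibble::tibble(form = "a", prob = 1))
  expect_equal(paste(sample_stream(fp, 10, seed = 1), collapse = ""),
               "a#a#a#a#a#")
  d <- tibble::tibble(form = c("ab", "b", "aab"), prob = c(0.5, 0.3, 0.2))
  fp2 <- form_process(d)
  s <- sample_stream(fp2, 2e4, seed = 2)
  expect_identical(s, sample_stream(fp2, 2e4, seed = 2))
  # form frequencies: i.i.d. draws, 3 standard errors
  complete <- strsplit(paste(s, collapse = ""), "#", fixed = TRUE)[[1]]
  complete <- complete[complete != ""]
  n <- length(complete)
  for (i in seq_len(nrow(d))) {
    phat <- mean(complete == d$form[i])
    se <- sqrt(d$prob[i] * (1 - d$prob[i]) / n)
    expect_lt(abs(phat - d$prob[i]), 3 * se + 1e-3)
  }
  # plug-in unigram distribution close to the analytic stationary one
  tab1 <- ngram_distribution(fp2, 1)
  emp <- table(s) / length(s)
  for (i in seq_len(nrow(tab1))) {
    expect_lt(abs(emp[[tab1$window[i]]] - tab1$prob[i]), 0.01)
  }
})

test_that("tidy, glance and autoplot work on pi_result", {
  r <- predictive_information(form_process(cube_table()))
  td <- tidy(r)
  expect_named(td, c("n", "h_n", "excess"))
  expect_equal(nrow(td), r$N)
  gl <- glance(r)
  expect_equal(gl$E, r$E)
  expect_s3_class(autoplot(r), "ggplot")
})
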