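digits01 <- c(`0` = "0", `1` = "1")

test_that("systematic codes concatenate per-feature subforms", {
  src <- product_bernoulli_source()
  code <- systematic_code(src, list(M1 = digits01, M2 = digits01, M3 = digits01))
  expect_equal(code$form[code$M1 == 1 & code$M2 == 0 & code$M3 == 1], "101")
  expect_false(anyDuplicated(code$form) > 0)
  bad <- list(M1 = c(`0` = "x", `1` = "x"), M2 = digits01, M3 = digits01)
  expect_error(systematic_code(src, bad), class = "predinfo_ambiguity_error")
})

test_that("random bijection codes are seeded, injective and size-checked", {
  src <- product_bernoulli_source()
  forms <- sprintf("f%d", 1:8)
  c1 <- random_bijection_code(src, forms, seed = 9)
  c2 <- random_bijection_code(src, forms, seed = 9)
  expect_identical(c1$form, c2$form)
  expect_false(anyDuplicated(c1$form) > 0)
  expect_error(random_bijection_code(src, forms[1:3]), class = "predinfo_arity_error")
  one <- random_bijection_code(tibble::tibble(m = "a"), "f")
  expect_equal(one$form, "f")
})

test_that("bijection enumeration yields every bijection exactly once", {
  e2 <- enumerate_bijections(c("m1", "m2"), c("x", "y"))
  expect_equal(nrow(e2$assign), 2)
  e3 <- enumerate_bijections(c("a", "b", "c"), c("x", "y", "z"))
  expect_equal(nrow(e3$assign), 6)
  expect_equal(nrow(unique(as.data.frame(e3$assign))), 6)
  e8 <- enumerate_bijections(sprintf("m%d", 1:8), sprintf("f%d", 1:8))
  expect_equal(nrow(e8$assign), 40320)
  expect_error(enumerate_bijections(1:11, sprintf("f%d", 1:11)),
               class = "predinfo_domain_error")
  code <- code_at(e3, 4)
  expect_false(anyDuplicated(code$form) > 0)
})

test_that("position permutations scramble forms as specified", {
  d <- tibble::tibble(form = "aaaabbbb")
  ident <- apply_position_permutation(d, 1:8)
  expect_equal(ident$form, "aaaabbbb")
  # an interleaving that mixes the two words' symbols
  mixed <- apply_position_permutation(d, c(5L, 1L, 2L, 3L, 6L, 7L, 4L, 8L))
  expect_equal(mixed$form, "baaabbab")
  # applying a permutation and then its inverse restores the code
  p <- c(3L, 1L, 4L, 2L)
  d2 <- tibble::tibble(form = c("abcd", "dcba", "aabb"))
  there <- apply_position_permutation(d2, p)
  back <- apply_position_permutation(there, order(p))
  expect_equal(back$form, d2$form)
  expect_error(apply_position_permutation(d2, 1:3), class = "predinfo_domain_error")
})

test_that("meaning permutations preserve the forms but can change E", {
  d <- tibble::tibble(form = c("aa", "ab", "ba", "bb"),
                      prob = c(0.6, 0.2, 0.15, 0.05))
  shuffled <- permute_meanings(d, seed = 1)  # a non-identity draw
  expect_setequal(shuffled$form, d$form)
  # generic source weights: E of the source-weighted process changes
  expect_false(isTRUE(all.equal(predictive_info(shuffled), predictive_info(d))))
  expect_error(permute_meanings(tibble::tibble(form = c("a", "a"))),
               class = "predinfo_ambiguity_error")
  single <- permute_meanings(tibble::tibble(form = "zz"), seed = 1)
  expect_equal(single$form, "zz")
})

test_that("length-matched permutation preserves each meaning's form length", {
  d <- tibble::tibble(form = c("a", "b", "cc", "dd", "eee"))
  out <- permute_meanings_length_matched(d, seed = 5)
  expect_equal(nchar(out$form), nchar(d$form))
  expect_setequal(out$form, d$form)
  distinct_lens <- tibble::tibble(form = c("a", "bb", "ccc"))
  expect_equal(permute_meanings_length_matched(distinct_lens, seed = 2)$form,
               distinct_lens$form)
})

test_that("manner-preserving scramble keeps the class skeleton and is deterministic", {
  ph <- c("f", "a", "s", "t", "e", "d")
  cl <- c("fric", "vowel", "fric", "stop", "vowel", "stop")
  s1 <- manner_preserving_scramble(ph, cl, seed = 4)
  expect_identical(manner_preserving_scramble(ph, cl, seed = 4), s1)
  expect_setequal(s1, ph)
  # skeleton unchanged
  cls_of <- stats::setNames(cl, ph)
  expect_equal(unname(cls_of[s1]), cl)
  # a word whose positions all have distinct classes cannot move
  expect_equal(manner_preserving_scramble(c("p", "a", "s"),
                                          c("stop", "vowel", "fric"), seed = 1),
               c("p", "a", "s"))
  # the swapped-within-every-class variant is reachable under some seed
  reached <- vapply(1:200, function(s) {
    paste(manner_preserving_scramble(ph, cl, seed = s), collapse = "")
  }, character(1))
  expect_true("sefdat" %in% reached)
  expect_error(manner_preserving_scramble(ph, cl[-1]),
               class = "predinfo_mapping_error")
})

test_that("systematicity counting follows the position-function definition", {
  src <- product_bernoulli_source()
  ident <- systematic_code(src, list(M1 = digits01, M2 = digits01, M3 = digits01))
  expect_equal(count_systematic_features(ident, c("M1", "M2", "M3")), 3)
  # flipping one position's symbols is still a bijective per-position map
  flipped <- src
  flipped$form <- paste0(src$M1, 1 - src$M2, src$M3)
  expect_equal(count_systematic_features(flipped, c("M1", "M2", "M3")), 3)
  # position 1 = M1 xor M2 depends on two features, so only M2 (position 2)
  # and M3 (position 3) are expressed systematically
  xor1 <- src
  xor1$form <- paste0((src$M1 + src$M2) %% 2, src$M2, src$M3)
  expect_equal(count_systematic_features(xor1, c("M1", "M2", "M3")), 2)
  expect_error(count_systematic_features(tibble::tibble(M1 = 0:1, form = c("aa", "bb")),
                                         "M1"),
               class = "predinfo_domain_error")
})

test_that("block contiguity and well-nestedness are checked per grouping", {
  blocks <- list(1:4, 5:8)
  expect_true(blocks_contiguous(1:8, blocks))
  expect_true(blocks_contiguous(c(5:8, 1:4), blocks))  # words swapped whole
  expect_false(blocks_contiguous(c(1, 5, 2, 6, 3, 7, 4, 8), blocks))

  tree <- list(c(1L, 2L), 1:3, c(4L, 5L), 4:6)
  expect_true(is_well_nested(1:6, tree))
  expect_false(is_well_nested(c(1L, 4L, 2L, 5L, 3L, 6L), tree))
  # exhaustive count over all 720 orders: per triple the pair must stay
  # adjacent inside a contiguous triple (2! x 2 = 4 ways), and the triples
  # can come in either order: 2 x 4 x 4 = 32
  pm <- predinfo:::perm_matrix(6)
  n_nested <- sum(vapply(seq_len(720), function(r) is_well_nested(pm[r, ], tree),
                         logical(1)))
  expect_equal(n_nested, 32)
})
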