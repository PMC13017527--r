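# Minimal CoNLL-U reader and the count-table extraction rules used by the
# corpus analyses (noun feature tuples, adjacent amod pairs, noun phrases,
# verb-object pairs).

parse_conllu <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, encoding = "UTF-8")
  } else if (length(x) == 1 && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
  sentences <- list()
  tok <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^\\s*$", line)) {
      if (length(tok)) sentences[[length(sentences) + 1L]] <- dplyr::bind_rows(tok)
      tok <- list()
      next
    }
    if (startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 10) {
      abort(sprintf("malformed CoNLL-U line %d: expected 10 tab-separated fields, got %d",
                    ln, length(fields)),
            class = "predinfo_parse_error")
    }
    id <- fields[1]
    if (grepl("-", id, fixed = TRUE) || grepl(".", id, fixed = TRUE)) next
    tok[[length(tok) + 1L]] <- tibble::tibble(
      id = as.integer(id), form = fields[2], lemma = fields[3],
      upos = fields[4], feats = fields[6],
      head = suppressWarnings(as.integer(fields[7])), deprel = fields[8]
    )
  }
  if (length(tok)) sentences[[length(sentences) + 1L]] <- dplyr::bind_rows(tok)
  sentences
}

feat_value <- function(feats, key) {
  vapply(feats, function(f) {
    if (is.na(f) || f == "_") return("None")
    kv <- strsplit(strsplit(f, "|", fixed = TRUE)[[1]], "=", fixed = TRUE)
    for (p in kv) if (p[1] == key) return(p[2])
    "None"
  }, character(1), USE.NAMES = FALSE)
}

#' Extract analysis count tables from a CoNLL-U treebank
#'
#' Supported modes:
#' * `"nouns"`: grammatical feature tuples (number, case, possessor,
#'   definiteness) of every `NOUN` token, as a count table for the
#'   morphology source.
#' * `"amod_pairs"`: adjective-noun pairs, defined as a `NOUN` head modified
#'   by an *adjacent* `ADJ` dependent with relation `amod`; wordforms.
#' * `"noun_phrases"`: per `NOUN` head lemma, the head lemmas of its `amod`
#'   (`ADJ`), `nummod` (`NUM`) and `det` (`DET`) dependents (adjacency not
#'   required); when several adjectives modify one noun, one is chosen at
#'   random (seeded) and the others discarded.
#' * `"verb_objects"`: `VERB` head with an `obj` dependent of
#'   part-of-speech `NOUN`; wordforms.
#'
#' @param x Path to a CoNLL-U file, a single string of CoNLL-U text, or a
#'   character vector of lines.
#' @param mode One of `"nouns"`, `"amod_pairs"`, `"noun_phrases"`,
#'   `"verb_objects"`.
#' @param seed Seed for the random adjective choice in `"noun_phrases"`.
#' @return A count tibble in the schema of the corresponding analysis.
#' @export
extract_from_conllu <- function(x, mode = c("nouns", "amod_pairs",
                                            "noun_phrases", "verb_objects"),
                                seed = 1) {
  mode <- match.arg(mode)
  sents <- parse_conllu(x)
  rows <- with_seed(seed, purrr::map(sents, function(s) {
    switch(mode,
      nouns = {
        nn <- s[s$upos == "NOUN", ]
        if (nrow(nn) == 0) return(NULL)
        tibble::tibble(number = feat_value(nn$feats, "Number"),
                       case = feat_value(nn$feats, "Case"),
                       possessor = feat_value(nn$feats, "Number[psor]"),
                       definiteness = feat_value(nn$feats, "Definite"))
      },
      amod_pairs = {
        dep <- s[s$deprel == "amod" & s$upos == "ADJ", ]
        if (nrow(dep) == 0) return(NULL)
        keep <- purrr::map(seq_len(nrow(dep)), function(i) {
          h <- s[s$id == dep$head[i], ]
          if (nrow(h) == 1 && h$upos == "NOUN" && abs(h$id - dep$id[i]) == 1L) {
            tibble::tibble(adjective = dep$form[i], noun = h$form)
          }
        })
        dplyr::bind_rows(keep)
      },
      noun_phrases = {
        heads <- s[s$upos == "NOUN", ]
        if (nrow(heads) == 0) return(NULL)
        dplyr::bind_rows(purrr::map(seq_len(nrow(heads)), function(i) {
          h <- heads[i, ]
          deps <- s[!is.na(s$head) & s$head == h$id, ]
          adj <- deps$lemma[deps$deprel == "amod" & deps$upos == "ADJ"]
          num <- deps$lemma[deps$deprel == "nummod" & deps$upos == "NUM"]
          det <- deps$lemma[deps$deprel == "det" & deps$upos == "DET"]
          if (length(adj) > 1) adj <- sample(adj, 1)
          tibble::tibble(determiner = if (length(det)) det[1] else NA_character_,
                         numeral = if (length(num)) num[1] else NA_character_,
                         adjective = if (length(adj)) adj[1] else NA_character_,
                         noun = h$lemma)
        }))
      },
      verb_objects = {
        dep <- s[s$deprel == "obj" & s$upos == "NOUN", ]
        if (nrow(dep) == 0) return(NULL)
        dplyr::bind_rows(purrr::map(seq_len(nrow(dep)), function(i) {
          h <- s[s$id == dep$head[i], ]
          if (nrow(h) == 1 && h$upos == "VERB") {
            tibble::tibble(verb = h$form, object = dep$form[i])
          }
        }))
      }
    )
  }))
  all <- dplyr::bind_rows(rows)
  if (nrow(all) == 0) return(dplyr::mutate(all, count = integer(0)))
  dplyr::count(all, dplyr::across(dplyr::everything()), name = "count")
}
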