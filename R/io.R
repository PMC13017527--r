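# Plain-text interchange: UTF-8 tab-delimited tables with '#' comments, a
# simple code format (meaning_id / probability / form), and JSON results.

read_predinfo_tsv <- function(path, col_types) {
  readr::read_tsv(path, comment = "#", col_types = col_types, progress = FALSE)
}

#' Read and write the package's TSV schemas
#'
#' * Code: `meaning_id`, `probability`, `form` (a whitespace-free symbol
#'   string, or whitespace-separated tokens in word-level mode); the
#'   delimiter `#` is reserved.
#' * Paradigm: one column per grammatical feature, then `form`, `count`.
#' * Lexicon: `word`, `phonemes` (space-separated), `manner`
#'   (space-separated classes), `frequency`.
#' * Phrases: `determiner`, `numeral`, `adjective`, `noun`, `count` (empty
#'   slot = missing value).
#'
#' @param path File path.
#' @return A tibble in the respective schema.
#' @name predinfo_io
NULL

#' @rdname predinfo_io
#' @export
read_code_tsv <- function(path) {
  read_predinfo_tsv(path, readr::cols(meaning_id = readr::col_character(),
                                      probability = readr::col_double(),
                                      form = readr::col_character()))
}

#' @rdname predinfo_io
#' @export
read_paradigm_tsv <- function(path) {
  out <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character(),
                                                 count = readr::col_double()))
  stopifnot(all(c("form", "count") %in% names(out)))
  out
}

#' @rdname predinfo_io
#' @export
read_lexicon_tsv <- function(path) {
  read_predinfo_tsv(path, readr::cols(word = readr::col_character(),
                                      phonemes = readr::col_character(),
                                      manner = readr::col_character(),
                                      frequency = readr::col_double()))
}

#' @rdname predinfo_io
#' @export
read_phrases_tsv <- function(path) {
  read_predinfo_tsv(path, readr::cols(determiner = readr::col_character(),
                                      numeral = readr::col_character(),
                                      adjective = readr::col_character(),
                                      noun = readr::col_character(),
                                      count = readr::col_double()))
}

#' @rdname predinfo_io
#' @param x Table to write.
#' @export
write_predinfo_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' Write a predictive-information result as JSON
#'
#' Emits `{E, h, h_series, N}` with full double precision.
#'
#' @param x A `pi_result` from [predictive_information()].
#' @param path Output path.
#' @export
write_e_result_json <- function(x, path) {
  stopifnot(inherits(x, "pi_result"))
  jsonlite::write_json(list(E = x$E, h = x$h, h_series = x$h_series, N = x$N),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' Build a form table from a code TSV
#'
#' @param code Tibble from [read_code_tsv()].
#' @param mode `"letter"` or `"word"`.
#' @return A [form_process()].
#' @export
process_from_code <- function(code, mode = c("letter", "word")) {
  form_process(code, form = "form", prob = "probability", mode = mode)
}
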