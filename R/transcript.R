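#' Construct a Transcript
#'
#' @param words data.frame with columns `surface`, `lemma`, `onset`, `offset`,
#'   `align_id` and optionally `word_class` (classified from `surface` via
#'   [classifyWord()] when absent).
#' @param role `"source"` or `"target"`.
#' @param direction `"L1toL2"` or `"L2toL1"` (L1 = Russian, L2 = English).
#' @param language `"EN"` or `"RU"`.
#' @return A validated [Transcript-class] object.
#' @export
Transcript <- function(words, role, direction, language) {
  words <- as.data.frame(words)
  if (is.null(words$word_class))
    words$word_class <- vapply(words$surface, classifyWord, "", language = language)
  if (is.null(words$align_id)) words$align_id <- NA_integer_
  words$align_id <- as.integer(words$align_id)
  rownames(words) <- NULL
  new("Transcript", role = role, direction = direction,
      language = language, words = words)
}

.norm_token <- function(surface) {
  # lowercase and strip non-letter edge characters before classification
  # and frequency lookup (keeps word-internal hyphens)
  s <- tolower(surface)
  gsub("^[^\\p{L}]+|[^\\p{L}]+$", "", s, perl = TRUE)
}

.fw_cache <- new.env(parent = emptyenv())

#' Function-word list for a language
#'
#' The shipped lists implement the closed classes excluded from
#' content-word load counting: for English, articles, prepositions,
#' auxiliary verbs and the conjunction "and"; for Russian, prepositions and
#' the conjunction "и".  A user file (one lowercase token per line,
#' `#` comments) can replace the shipped list.
#'
#' @param language `"EN"` or `"RU"`.
#' @param path optional path to an override list.
#' @return character vector of function words.
#' @export
functionWords <- function(language = c("EN", "RU"), path = NULL) {
  language <- match.arg(language)
  if (is.null(path)) {
    key <- language
    if (!is.null(.fw_cache[[key]])) return(.fw_cache[[key]])
    path <- system.file("extdata",
                        sprintf("function_words_%s.txt", tolower(language)),
                        package = "decalage")
  } else key <- NULL
  stopifnot(nzchar(path), file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- trimws(lines[!startsWith(lines, "#") & nzchar(trimws(lines))])
  if (!is.null(key)) .fw_cache[[key]] <- words
  words
}

#' Classify a word as content or function
#'
#' A token is a function word iff its normalized form (lowercased,
#' non-letter edge characters stripped) appears in the language's
#' function-word list; every other token — including hyphenated compounds
#' and numerals — is treated as a content word.
#'
#' @param surface the word as transcribed.
#' @param language `"EN"` or `"RU"`.
#' @param wordlist optional character vector overriding the shipped list.
#' @return `"content"` or `"function"`.
#' @examples
#' classifyWord("and", "EN")   # "function"
#' classifyWord("peace", "EN") # "content"
#' @export
classifyWord <- function(surface, language = c("EN", "RU"), wordlist = NULL) {
  language <- match.arg(language)
  stopifnot(is.character(surface), length(surface) == 1L, nzchar(surface))
  if (is.null(wordlist)) wordlist <- functionWords(language)
  if (.norm_token(surface) %in% wordlist) "function" else "content"
}

#' Count syllables in a word
#'
#' Russian: the number of Cyrillic vowel letters
#' (а е ё и о у ы э ю я),
#' which equals the syllable count exactly.  English: the number of maximal
#' vowel-letter groups (a e i o u y), minus one for a terminal silent "e"
#' when the count stays >= 1.  The result is floored at 1 so every word
#' occupies at least one syllable.  The English rule is a heuristic and can
#' be swapped via `counter`.
#'
#' @param surface the word.
#' @param language `"EN"` or `"RU"`.
#' @param counter optional function(surface) -> integer replacing the
#'   English heuristic (e.g. a pronunciation-dictionary lookup).
#' @return integer >= 1.
#' @examples
#' countSyllables("peace", "EN")                 # 1
#' countSyllables("мир", "RU")    # 1
#' @export
countSyllables <- function(surface, language = c("EN", "RU"), counter = NULL) {
  language <- match.arg(language)
  s <- .norm_token(surface)
  if (!grepl("\\p{L}", s, perl = TRUE))
    stop("countSyllables: no letters in ", sQuote(surface))
  if (!is.null(counter)) return(max(1L, as.integer(counter(s))))
  if (language == "RU") {
    n <- lengths(regmatches(s, gregexpr("[аеёиоуыэюя]", s)))
  } else {
    groups <- lengths(regmatches(s, gregexpr("[aeiouy]+", s)))
    n <- groups
    if (groups >= 2L && grepl("e$", s) && !grepl("[aeiouy]e$", s)) n <- groups - 1L
  }
  max(1L, as.integer(n))
}

#' Construct a FrequencyTable
#'
#' @param entries named numeric vector of absolute lemma frequencies (>= 1);
#'   names are lemmas.
#' @return A validated [FrequencyTable-class].
#' @export
FrequencyTable <- function(entries) {
  entries <- unlist(entries)
  storage.mode(entries) <- "double"
  new("FrequencyTable", entries = entries,
      Fmin = min(entries), Fmax = max(entries))
}

#' Min-max normalized log frequency
#'
#' Maps an absolute corpus frequency `f` to
#' \deqn{\hat f = \frac{\log f - \log F_{min}}{\log F_{max} - \log F_{min}}}
#' so the least frequent word in the corpus maps to 0 and the most frequent
#' to 1.  Frequencies outside the table range are clamped into \[0, 1\].
#'
#' @param f absolute frequency (>= 1), vectorized.
#' @param table a [FrequencyTable-class].
#' @return normalized frequency in \[0, 1\].
#' @export
normalizedLogFrequency <- function(f, table) {
  stopifnot(is(table, "FrequencyTable"), all(f >= 1))
  if (table@Fmin >= table@Fmax)
    stop("degenerate frequency table: Fmin must be < Fmax")
  v <- (log(f) - log(table@Fmin)) / (log(table@Fmax) - log(table@Fmin))
  pmin(1, pmax(0, v))
}

#' Look up a lemma's normalized log frequency
#'
#' Out-of-vocabulary lemmas are assigned `Fmin` (maximum unfamiliarity on
#' the normalized scale) with a warning.
#'
#' @param lemma character vector of lemmas (already normalized/lowercased).
#' @param table a [FrequencyTable-class].
#' @param warn warn about out-of-vocabulary lemmas (default TRUE).
#' @return normalized frequency in \[0, 1\] per lemma.
#' @export
lemmaWeight <- function(lemma, table, warn = TRUE) {
  f <- table@entries[lemma]
  oov <- is.na(f)
  if (any(oov)) {
    if (warn)
      warning(sum(oov), " out-of-vocabulary lemma(s) assigned Fmin, e.g. ",
              paste(utils::head(unique(lemma[oov]), 3), collapse = ", "))
    f[oov] <- table@Fmin
  }
  normalizedLogFrequency(unname(f), table)
}

# ---- TSV I/O ----------------------------------------------------------------

.TRANSCRIPT_COLS <- c("role", "index", "surface", "lemma", "language",
                      "onset_s", "offset_s", "align_id")

#' Read a time-coded transcript TSV
#'
#' Expected UTF-8 tab-separated columns: `role`, `index`, `surface`,
#' `lemma`, `language`, `onset_s`, `offset_s`, `align_id` (empty `align_id`
#' allowed for target-only fillers).  Rows must satisfy `offset_s >
#' onset_s` and be sorted by onset; violations are reported with their line
#' number.
#'
#' @param path file path.
#' @param direction `"L1toL2"` or `"L2toL1"`.
#' @return A [Transcript-class].
#' @export
readTranscript <- function(path, direction = c("L1toL2", "L2toL1")) {
  direction <- match.arg(direction)
  stopifnot(file.exists(path))
  d <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                         fileEncoding = "UTF-8",
                         colClasses = "character", blank.lines.skip = FALSE)
  if (!all(.TRANSCRIPT_COLS %in% names(d)))
    stop("transcript TSV must have columns: ",
         paste(.TRANSCRIPT_COLS, collapse = ", "))
  on_n <- suppressWarnings(as.numeric(d$onset_s))
  off_n <- suppressWarnings(as.numeric(d$offset_s))
  bad <- which(is.na(on_n) | is.na(off_n) | !nzchar(d$surface))
  if (length(bad))
    stop("malformed transcript row at line ", bad[1L] + 1L,
         " of ", basename(path))
  bad <- which(off_n <= on_n)
  if (length(bad))
    stop("offset_s <= onset_s at line ", bad[1L] + 1L, " of ", basename(path))
  if (is.unsorted(on_n))
    stop("transcript rows not sorted by onset in ", basename(path))
  role <- unique(d$role)
  lang <- unique(d$language)
  if (length(role) != 1L || length(lang) != 1L)
    stop("transcript must have a single role and language")
  align <- suppressWarnings(as.integer(d$align_id))
  words <- data.frame(surface = d$surface, lemma = d$lemma,
                      onset = on_n, offset = off_n, align_id = align,
                      stringsAsFactors = FALSE)
  Transcript(words, role = role, direction = direction, language = lang)
}

#' Write a transcript TSV
#'
#' @param x a [Transcript-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTranscript <- function(x, path) {
  w <- x@words
  d <- data.frame(role = x@role, index = seq_len(nrow(w)),
                  surface = w$surface, lemma = w$lemma, language = x@language,
                  onset_s = sprintf("%.4f", w$onset),
                  offset_s = sprintf("%.4f", w$offset),
                  align_id = ifelse(is.na(w$align_id), "", w$align_id))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a lemma frequency TSV
#'
#' Columns: `lemma`, `abs_freq`.  `Fmin`/`Fmax` are computed from the table
#' on load.
#'
#' @param path file path.
#' @return [FrequencyTable-class] (reader); `path` invisibly (writer).
#' @export
readFrequencyTable <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                         fileEncoding = "UTF-8")
  stopifnot(all(c("lemma", "abs_freq") %in% names(d)))
  FrequencyTable(stats::setNames(as.numeric(d$abs_freq), d$lemma))
}

#' @rdname readFrequencyTable
#' @param x a [FrequencyTable-class].
#' @export
writeFrequencyTable <- function(x, path) {
  d <- data.frame(lemma = names(x@entries), abs_freq = unname(x@entries))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
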