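#' Tokenise and normalise raw text
#'
#' Applies the package's seven-step preprocessing pipeline, in order:
#' (i) replacement of non-alphanumeric characters by spaces,
#' (ii) tokenisation by whitespace, (iii) stop-word removal (bundled frozen
#' English list, compared case-insensitively), (iv) lower-casing, (v) removal
#' of tokens shorter than three characters, (vi) removal of pure-integer
#' tokens, and (vii) stemming with the package's Porter-style stemmer (see
#' [stem_porter()]).
#'
#' The output is idempotent: `preprocess(paste(preprocess(x), collapse = " "))`
#' returns the same token stream.
#'
#' @param text A character vector; elements are concatenated with spaces.
#' @return A character vector of stemmed lowercase tokens (possibly empty).
#' @examples
#' preprocess("disambiguated disambiguations disambiguating")
#' @export
preprocess <- function(text) {
  if (length(text) == 0) return(character())
  text <- paste(text[!is.na(text)], collapse = " ")
  if (!nzchar(text)) return(character())
  # (i) non-alphanumeric -> space, (ii) split on whitespace
  toks <- str_split(str_squish(str_replace_all(text, "[^[:alnum:]]+", " ")), " ")[[1]]
  toks <- toks[nzchar(toks)]
  # (iii) stop words, case-insensitive
  toks <- toks[!(str_to_lower(toks) %in% genelit_stopwords())]
  # (iv) lower case
  toks <- str_to_lower(toks)
  # (v) short tokens, (vi) integer tokens
  toks <- toks[nchar(toks) >= 3L & !grepl("^[0-9]+$", toks)]
  # (vii) stemming; the length/integer/stop-word filters are re-applied to the
  # stems (a stem can drop under three characters) so the stream is idempotent
  toks <- vapply(toks, stem_porter, character(1), USE.NAMES = FALSE)
  toks[nchar(toks) >= 3L & !grepl("^[0-9]+$", toks) &
         !(toks %in% genelit_stopwords())]
}

# Bundled frozen English stop-word list; cached per session.
genelit_stopwords <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "stopwords_english.txt", package = "genelit")
      cache <<- readLines(path, encoding = "UTF-8", warn = FALSE)
    }
    cache
  }
})

#' Porter-style English stemmer
#'
#' A suffix-stripping stemmer in the Porter family. It follows the classic
#' measure-based steps (plural/participle removal, `-ational` to `-ate`,
#' derivational suffix stripping, final `-e` removal), with one deliberate
#' dialect choice: step 4 does not delete a final `-ate`, so the
#' `-ate`/`-ated`/`-ating`/`-ation` family collapses consistently to a stem
#' ending in `at` (e.g. all of "disambiguated", "disambiguations",
#' "disambiguating" map to `"disambiguat"`).
#'
#' @param word A single lowercase word.
#' @return The stemmed word.
#' @examples
#' stem_porter("disambiguations")
#' @export
stem_porter <- function(word) {
  w <- str_to_lower(word)
  if (nchar(w) <= 2) return(w)

  is_cons <- function(chs) {
    # y is a consonant at the start or after a vowel
    n <- length(chs)
    out <- logical(n)
    for (i in seq_len(n)) {
      ch <- chs[i]
      if (ch %in% c("a", "e", "i", "o", "u")) {
        out[i] <- FALSE
      } else if (ch == "y") {
        out[i] <- if (i == 1) TRUE else !out[i - 1]
      } else {
        out[i] <- TRUE
      }
    }
    out
  }
  measure <- function(stem) {
    if (!nzchar(stem)) return(0L)
    cons <- is_cons(strsplit(stem, "")[[1]])
    runs <- rle(cons)$values
    sum(seq_along(runs) > 1 & runs)  # count V->C transitions
  }
  has_vowel <- function(stem) {
    if (!nzchar(stem)) return(FALSE)
    any(!is_cons(strsplit(stem, "")[[1]]))
  }
  ends_double_cons <- function(stem) {
    n <- nchar(stem)
    if (n < 2) return(FALSE)
    a <- substr(stem, n - 1, n - 1); b <- substr(stem, n, n)
    a == b && all(is_cons(strsplit(stem, "")[[1]])[c(n - 1, n)])
  }
  ends_cvc <- function(stem) {
    n <- nchar(stem)
    if (n < 3) return(FALSE)
    cons <- is_cons(strsplit(stem, "")[[1]])
    lastch <- substr(stem, n, n)
    cons[n - 2] && !cons[n - 1] && cons[n] && !(lastch %in% c("w", "x", "y"))
  }
  ends_with <- function(w, suf) {
    nchar(w) > nchar(suf) && substr(w, nchar(w) - nchar(suf) + 1, nchar(w)) == suf
  }
  chop <- function(w, suf) substr(w, 1, nchar(w) - nchar(suf))

  # step 1a
  if (ends_with(w, "sses")) w <- paste0(chop(w, "sses"), "ss")
  else if (ends_with(w, "ies")) w <- paste0(chop(w, "ies"), "i")
  else if (ends_with(w, "ss")) w <- w
  else if (ends_with(w, "s")) w <- chop(w, "s")

  # step 1b
  if (ends_with(w, "eed")) {
    if (measure(chop(w, "eed")) > 0) w <- chop(w, "d")
  } else {
    removed <- FALSE
    if (ends_with(w, "ed") && has_vowel(chop(w, "ed"))) {
      w <- chop(w, "ed"); removed <- TRUE
    } else if (ends_with(w, "ing") && has_vowel(chop(w, "ing"))) {
      w <- chop(w, "ing"); removed <- TRUE
    }
    if (removed) {
      if (ends_with(w, "at") || ends_with(w, "bl") || ends_with(w, "iz")) {
        w <- paste0(w, "e")
      } else if (ends_double_cons(w) &&
                 !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
        w <- substr(w, 1, nchar(w) - 1)
      } else if (measure(w) == 1 && ends_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c
  if (ends_with(w, "y") && has_vowel(chop(w, "y"))) {
    w <- paste0(chop(w, "y"), "i")
  }

  # step 2 (m > 0)
  step2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
             izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
             ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
             alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
             aliti = "al", iviti = "ive", biliti = "ble")
  for (suf in names(step2)) {
    if (ends_with(w, suf)) {
      if (measure(chop(w, suf)) > 0) w <- paste0(chop(w, suf), step2[[suf]])
      break
    }
  }

  # step 3 (m > 0)
  step3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
             ical = "ic", ful = "", ness = "")
  for (suf in names(step3)) {
    if (ends_with(w, suf)) {
      if (measure(chop(w, suf)) > 0) w <- paste0(chop(w, suf), step3[[suf]])
      break
    }
  }

  # step 4 (m > 1); the '-ate' suffix is deliberately absent (see Details)
  step4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
             "ment", "ent", "ion", "ou", "ism", "iti", "ous", "ive", "ize")
  for (suf in step4) {
    if (ends_with(w, suf)) {
      stem <- chop(w, suf)
      ok <- measure(stem) > 1
      if (suf == "ion") {
        ok <- ok && substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (ends_with(w, "e")) {
    stem <- chop(w, "e")
    m <- measure(stem)
    if (m > 1 || (m == 1 && !ends_cvc(stem))) w <- stem
  }
  # step 5b
  if (measure(w) > 1 && ends_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    w <- substr(w, 1, nchar(w) - 1)
  }
  w
}
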