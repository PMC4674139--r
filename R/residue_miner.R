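## Amino-acid vocabularies used by the mention grammar.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
.AA_FULL <- c("Alanine", "Arginine", "Asparagine", "Aspartate",
              "Aspartic acid", "Cysteine", "Glutamine", "Glutamate",
              "Glutamic acid", "Glycine", "Histidine", "Isoleucine",
              "Leucine", "Lysine", "Methionine", "Phenylalanine",
              "Proline", "Serine", "Threonine", "Tryptophan", "Tyrosine",
              "Valine")
.AA_FULL_TO3 <- c(Alanine = "ALA", Arginine = "ARG", Asparagine = "ASN",
                  Aspartate = "ASP", `Aspartic acid` = "ASP",
                  Cysteine = "CYS", Glutamine = "GLN", Glutamate = "GLU",
                  `Glutamic acid` = "GLU", Glycine = "GLY",
                  Histidine = "HIS", Isoleucine = "ILE", Leucine = "LEU",
                  Lysine = "LYS", Methionine = "MET",
                  Phenylalanine = "PHE", Proline = "PRO", Serine = "SER",
                  Threonine = "THR", Tryptophan = "TRP", Tyrosine = "TYR",
                  Valine = "VAL")
names(.AA1) <- .AA3

#' The 20 standard amino acids
#'
#' Lookup vectors used by the mention grammar: `aa_three()` returns the
#' canonical upper-case three-letter codes, `aa_one()` the one-letter codes
#' named by their three-letter counterparts.
#' @return Character vector.
#' @export
aa_three <- function() .AA3

#' @rdname aa_three
#' @export
aa_one <- function() .AA1

# Case styles admitted by the grammar: Title, lower, UPPER for the
# three-letter codes; Title and lower for the full names. No other mixed
# casing matches.
.case_styles3 <- function() {
  title <- paste0(substring(.AA3, 1, 1), tolower(substring(.AA3, 2)))
  c(title, tolower(.AA3), .AA3)
}
.case_styles_full <- function() {
  c(.AA_FULL, tolower(.AA_FULL))
}

.NUM <- "[1-9][0-9]*"   # no leading zero

.alt <- function(x) paste0("(?:", paste(x, collapse = "|"), ")")

# separators between residue name and number: nothing, one space, hyphen
# (ASCII or en dash); the parenthesized form "Name(123)" is a separate
# branch with no interior spaces.
.SEP <- "(?:|[ ]|-|–)"

.mention_patterns <- function() {
  aa3 <- .alt(.case_styles3())
  full <- .alt(gsub(" ", "[ ]", .case_styles_full()))
  aa1 <- .alt(.AA1)
  list(
    `three-letter` = paste0("\\b(", aa3, ")(?:", .SEP, "(", .NUM, ")\\b|",
                            "\\((", .NUM, ")\\))"),
    `full-word` = paste0("\\b(", full, ")(?:", .SEP, "(", .NUM, ")\\b|",
                         "\\((", .NUM, ")\\))"),
    `one-letter-mutation` = paste0("\\b(", aa1, ")(", .NUM, ")(", aa1, ")\\b"),
    `three-letter-mutation` = paste0("\\b(", aa3, ")-?(", .NUM, ")(", aa3,
                                     ")\\b")
  )
}

#' Detect a mutagenesis context in abstract text
#'
#' One-letter and three-letter mutation shorthands (such as "S4A") are
#' too ambiguous to mine everywhere; they are only searched for when the
#' abstract signals a mutagenesis study through one of the keywords
#' "mutation", "mutagenesis", "mutagen", "mutant", "substitution"
#' (case-insensitive, whole-word, plurals accepted).
#'
#' @param text Character vector of abstract text.
#' @return Logical vector, `TRUE` where a keyword occurs.
#' @export
detect_mutagenesis_context <- function(text) {
  grepl("\\b(?:mutation|mutagenesis|mutagen|mutant|substitution)s?\\b",
        text, ignore.case = TRUE, perl = TRUE)
}

.canon_aa <- function(token) {
  up <- toupper(token)
  if (up %in% .AA3) return(up)
  # full name (possibly two words); normalize case to the canonical form
  key <- paste0(toupper(substring(token, 1, 1)), tolower(substring(token, 2)))
  key <- sub("acid$", "acid", key)
  if (key %in% names(.AA_FULL_TO3)) return(unname(.AA_FULL_TO3[key]))
  NA_character_
}

.match_all <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(NULL)
  starts <- attr(m, "capture.start")
  lens <- attr(m, "capture.length")
  lapply(seq_along(m), function(i) {
    caps <- vapply(seq_len(ncol(starts)), function(j) {
      if (starts[i, j] > 0L)
        substring(text, starts[i, j], starts[i, j] + lens[i, j] - 1L)
      else NA_character_
    }, "")
    caps[!is.na(caps) & nzchar(caps)]
  })
}

#' Extract residue mentions from text
#'
#' Applies the mention grammar: a residue is a three-letter code or full
#' amino-acid name followed by its sequence number with no space, one
#' space, a hyphen, or with the number parenthesized (`Ser4`, `Ser 4`,
#' `Ser-4`, `Ser(4)`); three case styles are admitted for codes (Title,
#' lower, UPPER) and two for full names. Numbers never carry a leading
#' zero. When `mutagenesis` is `TRUE`, mutation shorthands are also
#' matched: one-letter `X4Y` and three-letter `Ser4Ala` / `Ser-4Ala`; a
#' mutation emits *both* the original and the substituted residue at that
#' position. Matches are required to sit on word boundaries so that
#' substrings of longer identifiers never fire. Duplicates within one text
#' are collapsed by (residue, number).
#'
#' @param text One abstract's text.
#' @param mutagenesis Logical; search mutation shorthands too. Defaults to
#'   [detect_mutagenesis_context()] of the text.
#' @return Data frame with columns `aa` (canonical three-letter code),
#'   `number` (integer) and `pattern_kind`.
#' @export
extract_mentions <- function(text, mutagenesis = detect_mutagenesis_context(text)) {
  stopifnot(length(text) == 1L)
  pats <- .mention_patterns()
  out <- list()
  add <- function(aa, num, kind) {
    out[[length(out) + 1L]] <<- data.frame(
      aa = aa, number = as.integer(num), pattern_kind = kind,
      stringsAsFactors = FALSE)
  }
  for (kind in c("three-letter", "full-word")) {
    for (caps in .match_all(text, pats[[kind]]) %||% list()) {
      aa <- .canon_aa(caps[[1L]])
      if (!is.na(aa)) add(aa, caps[[2L]], kind)
    }
  }
  if (isTRUE(mutagenesis)) {
    for (caps in .match_all(text, pats[["one-letter-mutation"]]) %||% list()) {
      from <- names(.AA1)[match(caps[[1L]], .AA1)]
      to <- names(.AA1)[match(caps[[3L]], .AA1)]
      add(from, caps[[2L]], "one-letter-mutation")
      add(to, caps[[2L]], "one-letter-mutation")
    }
    for (caps in .match_all(text, pats[["three-letter-mutation"]]) %||% list()) {
      from <- .canon_aa(caps[[1L]])
      to <- .canon_aa(caps[[3L]])
      if (!is.na(from) && !is.na(to)) {
        add(from, caps[[2L]], "three-letter-mutation")
        add(to, caps[[2L]], "three-letter-mutation")
      }
    }
  }
  if (!length(out))
    return(data.frame(aa = character(), number = integer(),
                      pattern_kind = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[c("aa", "number")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract residue mentions from a whole corpus
#'
#' Runs [detect_mutagenesis_context()] and [extract_mentions()] on every
#' record and annotates each mention with its source PMID and retrieval
#' tags.
#'
#' @param corpus A corpus data frame from [read_corpus()].
#' @return Data frame with columns `pmid`, `aa`, `number`, `pattern_kind`,
#'   `from_and` (logical: abstract retrieved by the AND-query).
#' @export
mine_corpus <- function(corpus) {
  muta <- detect_mutagenesis_context(corpus$text)
  from_and <- retrieved_by_and(corpus)
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    m <- extract_mentions(corpus$text[i], mutagenesis = muta[i])
    if (!nrow(m)) return(NULL)
    cbind(pmid = corpus$pmid[i], m, from_and = from_and[i],
          stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(pmid = character(), aa = character(),
                      number = integer(), pattern_kind = character(),
                      from_and = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
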