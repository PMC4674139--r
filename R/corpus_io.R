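#' Read an abstract corpus
#'
#' Two on-disk formats are supported. The canonical fixture format is a
#' JSON array of records with fields `pmid`, `title`, `abstract`,
#' `pub_date` (ISO `YYYY-MM-DD`, optional) and `retrieved_by` (array of
#' tags among `"AND"`, `"OR-1"`, `"OR-2"`). MEDLINE/PubMed XML
#' (`PubmedArticleSet`) is supported read-only; records read from XML get
#' an empty `retrieved_by` and must be tagged by the caller.
#'
#' @param path Path to a `.json` fixture or a MEDLINE `.xml` file.
#' @param format `"json"` or `"medline"`; guessed from the file extension
#'   by default.
#' @return A corpus: a data frame with columns `pmid` (character), `title`,
#'   `body`, `text` (title and body concatenated for text operations),
#'   `pub_date` (`Date`, `NA` when unknown) and `retrieved_by`
#'   (list-column of character tags).
#' @export
read_corpus <- function(path, format = c("auto", "json", "medline")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xml$", path, ignore.case = TRUE)) "medline" else "json"
  switch(format,
         json = .read_corpus_json(path),
         medline = .read_corpus_medline(path))
}

.empty_corpus <- function() {
  d <- data.frame(pmid = character(), title = character(), body = character(),
                  text = character(), pub_date = as.Date(character()),
                  stringsAsFactors = FALSE)
  d$retrieved_by <- list()
  d
}

.as_corpus <- function(pmid, title, body, pub_date, retrieved_by) {
  d <- data.frame(pmid = as.character(pmid), title = title, body = body,
                  text = paste(title, body),
                  pub_date = pub_date, stringsAsFactors = FALSE)
  d$retrieved_by <- retrieved_by
  if (anyDuplicated(d$pmid))
    stop("duplicate pmid in corpus: ", d$pmid[duplicated(d$pmid)][1L])
  rownames(d) <- NULL
  d
}

.read_corpus_json <- function(path) {
  recs <- tryCatch(jsonlite::read_json(path),
                   error = function(e) stop("malformed corpus JSON in '", path,
                                            "': ", conditionMessage(e)))
  if (!length(recs)) return(.empty_corpus())
  get1 <- function(r, f, default = "") {
    v <- r[[f]]
    if (is.null(v)) default else as.character(v)
  }
  pmids <- vapply(seq_along(recs), function(i) {
    p <- recs[[i]]$pmid
    if (is.null(p)) stop("malformed corpus record ", i, ": missing pmid")
    as.character(p)
  }, "")
  dates <- as.Date(vapply(recs, get1, "", f = "pub_date", default = NA_character_))
  .as_corpus(
    pmid = pmids,
    title = vapply(recs, get1, "", f = "title"),
    body = vapply(recs, get1, "", f = "abstract"),
    pub_date = dates,
    retrieved_by = lapply(recs, function(r)
      as.character(unlist(r$retrieved_by)))
  )
}

.read_corpus_medline <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed MEDLINE XML in '", path,
                                           "': ", conditionMessage(e)))
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  if (!length(arts)) return(.empty_corpus())
  one <- function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid))
      stop("malformed MEDLINE record: missing PMID")
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abst <- paste(xml2::xml_text(
      xml2::xml_find_all(a, ".//Abstract/AbstractText")), collapse = " ")
    dt <- xml2::xml_find_first(a, ".//Article//PubDate")
    date <- NA_character_
    if (!inherits(dt, "xml_missing")) {
      y <- xml2::xml_text(xml2::xml_find_first(dt, "./Year"))
      m <- xml2::xml_text(xml2::xml_find_first(dt, "./Month"))
      d <- xml2::xml_text(xml2::xml_find_first(dt, "./Day"))
      if (!is.na(y)) {
        if (is.na(m)) m <- "1"
        if (is.na(d)) d <- "1"
        if (m %in% month.abb) m <- match(m, month.abb)
        date <- sprintf("%s-%02d-%02d", y, as.integer(m), as.integer(d))
      }
    }
    list(pmid = pmid, title = if (is.na(title)) "" else title,
         body = abst, date = date)
  }
  parsed <- lapply(arts, one)
  .as_corpus(
    pmid = vapply(parsed, `[[`, "", "pmid"),
    title = vapply(parsed, `[[`, "", "title"),
    body = vapply(parsed, `[[`, "", "body"),
    pub_date = as.Date(vapply(parsed, `[[`, "", "date")),
    retrieved_by = rep(list(character()), length(parsed))
  )
}

#' Filter a corpus by PMID exclusion list, date window and size cap
#'
#' Order-preserving and idempotent. The direct citation describing the
#' target structure is excluded through `exclude_pmids` to emulate the
#' blind-prediction scenario; a "prior publications only" analysis passes
#' the citation date minus one day as the window end. Records with an
#' unknown date fail any active window (conservative).
#'
#' @param corpus A corpus data frame from [read_corpus()].
#' @param exclude_pmids Character vector of PMIDs to drop.
#' @param date_window `NULL`, or a length-2 vector coercible to `Date`
#'   (`c(start, end)`); either bound may be `NA` for one-sided windows.
#' @param cap Maximum number of records retained (first `cap` kept).
#' @return The filtered corpus, tags untouched.
#' @export
filter_corpus <- function(corpus, exclude_pmids = NULL, date_window = NULL,
                          cap = Inf) {
  keep <- rep(TRUE, nrow(corpus))
  if (length(exclude_pmids))
    keep <- keep & !(corpus$pmid %in% as.character(exclude_pmids))
  if (!is.null(date_window)) {
    dw <- as.Date(date_window)
    stopifnot(length(dw) == 2L)
    ok <- !is.na(corpus$pub_date)
    if (!is.na(dw[1L])) ok <- ok & corpus$pub_date >= dw[1L]
    if (!is.na(dw[2L])) ok <- ok & corpus$pub_date <= dw[2L]
    keep <- keep & ok
  }
  out <- corpus[keep, , drop = FALSE]
  if (is.finite(cap) && nrow(out) > cap) out <- out[seq_len(cap), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fetch abstracts for a query (live-retrieval adapter)
#'
#' Optional adapter around an E-utilities-style search service. The two
#' halves of an OR-query are submitted separately so each abstract is
#' tagged with the interactor(s) it mentions; an abstract returned by both
#' halves carries both tags. Abstracts retrieved by the AND-query are a
#' subset of those retrieved by the OR-query, so AND-retrieval tags are
#' added onto the OR-side records when both queries are fetched together.
#'
#' No transport ships with the package: tests and offline use must inject
#' one, and calling the adapter without a transport is an explicit error,
#' never a silently empty corpus.
#'
#' @param query A `tm_query` (typically the `and_query` or `or_query` of
#'   [assemble_pair_queries()]).
#' @param date_window Passed to [filter_corpus()].
#' @param cap Maximum number of records per submitted query.
#' @param transport A function `function(query_string)` returning a corpus
#'   data frame (as from [read_corpus()]); its `retrieved_by` column is
#'   overwritten by this adapter.
#' @param mode `"and"` or `"or"`: how to tag results. In `"or"` mode the
#'   query must be a decomposable OR-pair.
#' @return A corpus data frame with `retrieved_by` tags filled in.
#' @export
fetch_pubmed <- function(query, date_window = NULL, cap = 100000,
                         transport = NULL, mode = c("or", "and")) {
  mode <- match.arg(mode)
  if (is.null(transport))
    stop("offline: no retrieval transport configured; ",
         "supply `transport` or work from a corpus file")
  stopifnot(inherits(query, "tm_query"))
  tag_fetch <- function(q, tag) {
    res <- transport(query_string(q))
    res <- filter_corpus(res, date_window = date_window, cap = cap)
    res$retrieved_by <- rep(list(tag), nrow(res))
    res
  }
  if (mode == "and") return(tag_fetch(query, "AND"))
  halves <- decompose_or_query(query)
  r1 <- tag_fetch(halves[[1L]], "OR-1")
  r2 <- tag_fetch(halves[[2L]], "OR-2")
  merge_corpora(list(r1, r2))
}

#' Merge corpora, unioning retrieval tags of duplicate PMIDs
#' @param corpora List of corpus data frames.
#' @return One corpus; first occurrence of each PMID kept, tags unioned.
#' @export
merge_corpora <- function(corpora) {
  all <- do.call(rbind, corpora)
  if (!nrow(all)) return(.empty_corpus())
  first <- !duplicated(all$pmid)
  out <- all[first, , drop = FALSE]
  out$retrieved_by <- lapply(out$pmid, function(p)
    sort(unique(unlist(all$retrieved_by[all$pmid == p]))))
  rownames(out) <- NULL
  out
}

#' Was a record retrieved by the AND-query / only by the OR-query?
#' @param corpus A corpus data frame.
#' @return Logical vector.
#' @export
retrieved_by_and <- function(corpus) {
  vapply(corpus$retrieved_by, function(t) "AND" %in% t, TRUE)
}

#' @rdname retrieved_by_and
#' @export
retrieved_by_or_only <- function(corpus) {
  vapply(corpus$retrieved_by,
         function(t) length(t) > 0 && !("AND" %in% t), TRUE)
}
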