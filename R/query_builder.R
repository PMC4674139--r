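#' Protein name metadata for query construction
#'
#' Bundles all literature-query-relevant names of one interactor: the
#' free-text name attached to the structure entry, the curated recommended
#' name, short and alternative names, and the names of proteolytically
#' cleaved chains (when the mature protein is cut into several named
#' components). Gene names, organism names, E.C. numbers and CD-antigen
#' tags are deliberately not part of this record.
#'
#' @param pdb_name Free-text protein name from the structure entry.
#' @param recommended Curated recommended protein name. Required.
#' @param short_names Character vector of short names (may be empty).
#'   Short names under 3 characters are retained here but never reach a
#'   query.
#' @param alternative_names Character vector of alternative names.
#' @param cleaved_chain_names Character vector of named cleaved-chain
#'   components, if the protein is processed into several chains.
#' @param is_generic_word Logical; `TRUE` when the protein name collides
#'   with a generic English word (e.g. "act"), in which case queries are
#'   AND-restricted by controlled-vocabulary terms.
#'
#' @return An object of class `protein_names`.
#' @export
protein_names <- function(pdb_name, recommended, short_names = character(),
                          alternative_names = character(),
                          cleaved_chain_names = character(),
                          is_generic_word = FALSE) {
  if (missing(recommended) || is.null(recommended) || !nzchar(trimws(recommended)))
    stop("malformed metadata: a recommended name is required")
  trim <- function(x) {
    x <- sub("\\s+$", "", as.character(x))
    x[nzchar(x)]
  }
  out <- list(
    pdb_name = sub("\\s+$", "", as.character(pdb_name)),
    recommended = sub("\\s+$", "", as.character(recommended)),
    short_names = trim(short_names),
    alternative_names = trim(alternative_names),
    cleaved_chain_names = trim(cleaved_chain_names),
    is_generic_word = isTRUE(is_generic_word)
  )
  class(out) <- "protein_names"
  out
}

#' Read protein name metadata from a JSON file
#'
#' One record per interactor with fields `pdb_name`, `recommended`,
#' `short_names`, `alternative_names`, `cleaved_chain_names`,
#' `is_generic_word` (all but the first two optional).
#'
#' @param path Path to a JSON file holding one record or an array of records.
#' @return A list of `protein_names` objects.
#' @export
read_protein_names <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(raw$recommended)) raw <- list(raw)   # single record
  lapply(raw, function(r) {
    protein_names(
      pdb_name = r$pdb_name %||% "",
      recommended = r$recommended,
      short_names = unlist(r$short_names) %||% character(),
      alternative_names = unlist(r$alternative_names) %||% character(),
      cleaved_chain_names = unlist(r$cleaved_chain_names) %||% character(),
      is_generic_word = isTRUE(unlist(r$is_generic_word))
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Percent-encode everything outside the RFC 3986 unreserved set, leaving
# already-valid %XX escapes untouched (so encoding is idempotent).
.url_encode <- function(x) {
  n <- nchar(x)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- substr(x, i, i)
    if (ch == "%" && i + 2L <= n &&
        grepl("^[0-9A-Fa-f]{2}$", substr(x, i + 1L, i + 2L))) {
      out <- c(out, substr(x, i, i + 2L))
      i <- i + 3L
    } else {
      if (grepl("^[A-Za-z0-9._~-]$", ch)) out <- c(out, ch)
      else out <- c(out, paste0("%", toupper(as.character(charToRaw(ch)))))
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

#' Normalize a protein name into query-term variants
#'
#' A name is trimmed of trailing spaces and URL-encoded (space becomes
#' `%20`; the RFC 3986 reserved set is percent-encoded). For every hyphen
#' the full set of combinations is generated in which each hyphen is kept,
#' removed, or replaced by an (encoded) space, and the variants are
#' deduplicated. Names shorter than 3 characters are unusable and yield an
#' empty vector.
#'
#' @param name Free-text protein name.
#' @return Character vector of URL-encoded query-term variants (possibly
#'   empty). The attribute `needs_keyword` is `TRUE` for exactly-3-character
#'   names, which are AND-combined with the keyword "protein" when a query
#'   is assembled.
#' @examples
#' normalize_name("IL-15R-alpha")
#' normalize_name("ab")         # too short: empty
#' @export
normalize_name <- function(name) {
  stopifnot(length(name) == 1L)
  name <- sub("\\s+$", "", as.character(name))
  if (nchar(name) < 3L) {
    return(structure(character(), needs_keyword = FALSE))
  }
  hyph <- gregexpr("-", name, fixed = TRUE)[[1L]]
  variants <- name
  if (hyph[1L] != -1L) {
    reps <- c("-", "", " ")
    grid <- expand.grid(rep(list(reps), length(hyph)), stringsAsFactors = FALSE)
    parts <- strsplit(name, "-", fixed = TRUE)[[1L]]
    # a trailing hyphen leaves an implicit empty last part
    if (substring(name, nchar(name)) == "-") parts <- c(parts, "")
    variants <- apply(grid, 1L, function(seps) {
      out <- parts[1L]
      for (i in seq_along(seps)) out <- paste0(out, seps[i], parts[i + 1L])
      out
    })
  }
  variants <- unique(sub("\\s+$", "", variants))
  variants <- variants[nchar(variants) >= 3L]
  enc <- unique(vapply(variants, .url_encode, "", USE.NAMES = FALSE))
  structure(enc, needs_keyword = nchar(name) == 3L)
}

.norm_for_match <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Resolve which names of a cleaved protein enter the query
#'
#' Curated entries for proteolytically processed proteins list the mature
#' cleaved chains separately. Which names join the query depends on how
#' the structure entry's own name relates to them; "exact match" means
#' Levenshtein distance 0 after case-folding and whitespace collapsing.
#'
#' * The structure name equals the recommended name: the structure holds
#'   the whole protein, so the recommended name plus all cleaved-chain
#'   names are used.
#' * The structure name equals exactly one cleaved-chain name: the
#'   recommended name plus that single chain name.
#' * No exact match: the recommended name plus the structure name itself.
#'
#' @param pdb_name Free-text name from the structure entry; defaults to the
#'   one stored in `name_set`.
#' @param name_set A [protein_names()] object.
#' @return Character vector of names to include in the query.
#' @export
resolve_cleaved_names <- function(name_set, pdb_name = name_set$pdb_name) {
  if (is.null(name_set$recommended) || !nzchar(name_set$recommended))
    stop("malformed metadata: missing recommended name")
  rec <- name_set$recommended
  chains <- name_set$cleaved_chain_names
  pn <- .norm_for_match(pdb_name)
  if (utils::adist(pn, .norm_for_match(rec)) == 0L)
    return(unique(c(rec, chains)))
  if (length(chains)) {
    hit <- which(utils::adist(pn, vapply(chains, .norm_for_match, "")) == 0L)
    if (length(hit) == 1L) return(unique(c(rec, chains[hit])))
    if (length(hit) > 1L) return(unique(c(rec, chains[hit[1L]])))
  }
  unique(c(rec, pdb_name))
}

## ---- boolean query tree ----------------------------------------------------

.query_node <- function(op, term = NULL, children = list(), provenance = integer()) {
  structure(list(op = op, term = term, children = children,
                 provenance = as.integer(provenance)),
            class = "tm_query")
}

#' Build a literal query term
#' @param term URL-encoded term.
#' @param provenance Integer id(s) of the interactor(s) the term covers.
#' @return A `tm_query` leaf node.
#' @export
query_term <- function(term, provenance = integer()) {
  stopifnot(is.character(term), length(term) == 1L, nzchar(term))
  .query_node("TERM", term = term, provenance = provenance)
}

#' Combine queries with a boolean operator
#' @param queries List of `tm_query` nodes (or a single node).
#' @param op `"AND"` or `"OR"`.
#' @return A `tm_query` node whose provenance is the union of its children's.
#' @export
combine_queries <- function(queries, op = c("OR", "AND")) {
  op <- match.arg(op)
  if (inherits(queries, "tm_query")) queries <- list(queries)
  stopifnot(length(queries) >= 1L,
            all(vapply(queries, inherits, TRUE, "tm_query")))
  if (length(queries) == 1L) return(queries[[1L]])
  prov <- sort(unique(unlist(lapply(queries, `[[`, "provenance"))))
  .query_node(op, children = queries, provenance = prov)
}

#' Serialize a query to the E-utilities boolean dialect
#'
#' Terms are joined by `" AND "` / `" OR "` and boolean nodes are
#' parenthesized; leaves stay URL-encoded.
#'
#' @param q A `tm_query`.
#' @return A single string.
#' @export
query_string <- function(q) {
  stopifnot(inherits(q, "tm_query"))
  if (q$op == "TERM") return(q$term)
  inner <- vapply(q$children, query_string, "")
  paste0("(", paste(inner, collapse = paste0(" ", q$op, " ")), ")")
}

#' @export
print.tm_query <- function(x, ...) {
  cat("<tm_query> ", query_string(x), "\n", sep = "")
  if (length(x$provenance))
    cat("  provenance: interactor(s) ",
        paste(x$provenance, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Collect the literal terms of a query
#' @param q A `tm_query`.
#' @return Character vector of all leaf terms.
#' @export
query_terms <- function(q) {
  if (q$op == "TERM") return(q$term)
  unlist(lapply(q$children, query_terms))
}

#' Assemble the disjunctive query for one interactor
#'
#' All usable names of the interactor (resolved recommended/cleaved-chain
#' names, short names of at least 3 characters, and alternative names) are
#' normalized and OR-combined. Variants of exactly-3-character names are
#' each AND-restricted by the keyword "protein" to cut noise. When the
#' protein name is a generic English word, the whole name disjunction is
#' AND-combined with a disjunction of controlled-vocabulary (MeSH) terms.
#'
#' @param name_set A [protein_names()] object.
#' @param mesh_terms Optional character vector of controlled-vocabulary
#'   terms; used only when `name_set$is_generic_word` is `TRUE`.
#' @param provenance Integer id of this interactor (tags every leaf).
#' @return A `tm_query`.
#' @export
build_protein_query <- function(name_set, mesh_terms = NULL, provenance = 1L) {
  stopifnot(inherits(name_set, "protein_names"))
  names_all <- unique(c(resolve_cleaved_names(name_set),
                        name_set$short_names, name_set$alternative_names))
  leaves <- list()
  for (nm in names_all) {
    v <- normalize_name(nm)
    if (!length(v)) next
    kw <- isTRUE(attr(v, "needs_keyword"))
    for (term in v) {
      leaf <- query_term(term, provenance)
      if (kw)
        leaf <- combine_queries(list(leaf, query_term("protein", provenance)),
                                op = "AND")
      leaves <- c(leaves, list(leaf))
    }
  }
  if (!length(leaves))
    stop("no usable names for interactor: all names empty or shorter than 3 characters")
  q <- combine_queries(leaves, op = "OR")
  if (isTRUE(name_set$is_generic_word) && length(mesh_terms)) {
    mesh <- combine_queries(lapply(mesh_terms, function(m)
      query_term(.url_encode(m), provenance)), op = "OR")
    q <- combine_queries(list(q, mesh), op = "AND")
  }
  q
}

#' Assemble the AND- and OR-queries for a protein pair
#'
#' The AND-query requires both interactors in an abstract; the OR-query
#' accepts either. The two halves of the OR-query keep their interactor
#' provenance so that retrieval can submit them separately and record which
#' interactor an abstract mentions.
#'
#' @param q1,q2 Per-interactor `tm_query` objects (for a multimeric
#'   interactor, pass the OR-combination of its monomer queries built with
#'   [combine_queries()]).
#' @return A list with elements `and_query` and `or_query`.
#' @export
assemble_pair_queries <- function(q1, q2) {
  stopifnot(inherits(q1, "tm_query"), inherits(q2, "tm_query"))
  list(and_query = .query_node("AND", children = list(q1, q2),
                               provenance = union(q1$provenance, q2$provenance)),
       or_query = .query_node("OR", children = list(q1, q2),
                              provenance = union(q1$provenance, q2$provenance)))
}

#' Split an OR-query back into its per-interactor halves
#' @param or_query An OR `tm_query` built by [assemble_pair_queries()].
#' @return List of the two sub-queries, in original order.
#' @export
decompose_or_query <- function(or_query) {
  stopifnot(inherits(or_query, "tm_query"), or_query$op == "OR",
            length(or_query$children) == 2L)
  or_query$children
}
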