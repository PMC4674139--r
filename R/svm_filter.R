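## Bag-of-words relevance filtering of abstracts: labeling from residue
## counts, tokenization + suffix stripping, frequency-contrast feature
## selection, margin SVM classification, and confusion-matrix metrics.

#' Label an abstract from its interface / non-interface residue counts
#'
#' An abstract is a positive (interaction-relevant) training example when
#' its identified residues are predominantly at the interface:
#' `n_int - n_non > threshold`, or `n_non == 0` with at least one
#' interface residue. It is negative in the mirrored cases, and otherwise
#' unused. The three classes are exhaustive and mutually exclusive;
#' abstracts with no identified residues at all are unused.
#'
#' @param n_int,n_non Non-negative counts of interface and non-interface
#'   identified residues in the abstract (vectorized).
#' @param threshold Count-difference threshold (strict).
#' @return Character vector in `{"positive", "negative", "unused"}`.
#' @export
label_abstract <- function(n_int, n_non, threshold = 4) {
  stopifnot(all(n_int >= 0), all(n_non >= 0))
  pos <- (n_int - n_non > threshold) | (n_non == 0 & n_int > 0)
  neg <- (n_non - n_int > threshold) | (n_non > 0 & n_int == 0)
  out <- rep("unused", length(pos))
  out[pos] <- "positive"
  out[neg] <- "negative"
  out
}

## ---- Porter stemmer --------------------------------------------------------

.is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.is_cons(chars, i - 1L))
  }
  TRUE
}

.porter_measure <- function(stem) {
  chars <- strsplit(stem, "")[[1L]]
  if (!length(chars)) return(0L)
  types <- vapply(seq_along(chars), function(i) .is_cons(chars, i), TRUE)
  runs <- rle(types)$values
  if (runs[1L]) runs <- runs[-1L]   # drop leading consonant run
  # remaining runs alternate V, C, V, ...; m = number of VC pairs
  sum(runs)
}

.has_vowel <- function(stem) {
  chars <- strsplit(stem, "")[[1L]]
  any(!vapply(seq_along(chars), function(i) .is_cons(chars, i), TRUE))
}

.ends_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  chars <- strsplit(word, "")[[1L]]
  chars[n] == chars[n - 1L] && .is_cons(chars, n)
}

.ends_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chars <- strsplit(word, "")[[1L]]
  .is_cons(chars, n - 2L) && !.is_cons(chars, n - 1L) &&
    .is_cons(chars, n) && !(chars[n] %in% c("w", "x", "y"))
}

.chop <- function(word, k) substring(word, 1L, nchar(word) - k)

#' Porter suffix-stripping stemmer
#'
#' The classic five-step suffix-stripping algorithm reducing inflected
#' English words to a common root form (e.g. "binding", "binds" to
#' "bind"; "interactions" to "interact"). Words of up to 2 characters
#' and tokens containing non-letters are returned unchanged.
#'
#' @param words Character vector of lower-case words.
#' @return Character vector of stems.
#' @export
porter_stem <- function(words) {
  vapply(words, .porter_stem1, "", USE.NAMES = FALSE)
}

.porter_stem1 <- function(word) {
  if (nchar(word) <= 2L || grepl("[^a-z]", word)) return(word)
  w <- word

  # step 1a
  if (grepl("sses$", w)) w <- .chop(w, 2L)
  else if (grepl("ies$", w)) w <- .chop(w, 2L)
  else if (grepl("ss$", w)) w <- w
  else if (grepl("s$", w)) w <- .chop(w, 1L)

  # step 1b
  step1b_fixup <- FALSE
  if (grepl("eed$", w)) {
    if (.porter_measure(.chop(w, 3L)) > 0L) w <- .chop(w, 1L)
  } else if (grepl("ed$", w) && .has_vowel(.chop(w, 2L))) {
    w <- .chop(w, 2L); step1b_fixup <- TRUE
  } else if (grepl("ing$", w) && .has_vowel(.chop(w, 3L))) {
    w <- .chop(w, 3L); step1b_fixup <- TRUE
  }
  if (step1b_fixup) {
    if (grepl("(at|bl|iz)$", w)) w <- paste0(w, "e")
    else if (.ends_double_cons(w) && !grepl("[lsz]$", w)) w <- .chop(w, 1L)
    else if (.porter_measure(w) == 1L && .ends_cvc(w)) w <- paste0(w, "e")
  }

  # step 1c
  if (grepl("y$", w) && .has_vowel(.chop(w, 1L))) w <- paste0(.chop(w, 1L), "i")

  # steps 2-4: longest matching suffix; rule applies only if the measure
  # condition holds on the remaining stem (otherwise nothing happens)
  apply_rules <- function(w, rules, cond) {
    sufs <- names(rules)
    hit <- sufs[vapply(sufs, function(s) grepl(paste0(s, "$"), w), TRUE)]
    if (!length(hit)) return(w)
    s <- hit[which.max(nchar(hit))]
    stem <- .chop(w, nchar(s))
    if (cond(stem, s)) paste0(stem, rules[[s]]) else w
  }
  rules2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
              izer = "ize", abli = "able", alli = "al", entli = "ent",
              eli = "e", ousli = "ous", ization = "ize", ation = "ate",
              ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
              ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble")
  w <- apply_rules(w, as.list(rules2),
                   function(stem, s) .porter_measure(stem) > 0L)
  rules3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
              ical = "ic", ful = "", ness = "")
  w <- apply_rules(w, as.list(rules3),
                   function(stem, s) .porter_measure(stem) > 0L)
  rules4 <- c(ement = "", ance = "", ence = "", able = "", ible = "",
              ment = "", ion = "", ant = "", ent = "", ism = "", ate = "",
              iti = "", ous = "", ive = "", ize = "", al = "", er = "",
              ic = "", ou = "")
  w <- apply_rules(w, as.list(rules4), function(stem, s) {
    if (.porter_measure(stem) <= 1L) return(FALSE)
    if (s == "ion") return(grepl("[st]$", stem))
    TRUE
  })

  # step 5a
  if (grepl("e$", w)) {
    stem <- .chop(w, 1L)
    m <- .porter_measure(stem)
    if (m > 1L || (m == 1L && !.ends_cvc(stem))) w <- stem
  }
  # step 5b
  if (.porter_measure(w) > 1L && .ends_double_cons(w) && grepl("l$", w))
    w <- .chop(w, 1L)
  w
}

## ---- tokenization ----------------------------------------------------------

#' Default English stop-word list
#'
#' A compact list of function words purged before stemming; seeded with
#' the canonical examples ("and", "as", "because", "the") and extensible
#' by the caller.
#' @return Character vector.
#' @export
default_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "because", "been", "but",
    "by", "for", "from", "had", "has", "have", "here", "how", "if", "in",
    "into", "is", "it", "its", "no", "not", "of", "on", "or", "our",
    "such", "than", "that", "the", "their", "then", "there", "these",
    "they", "this", "to", "was", "we", "were", "which", "while", "will",
    "with")
}

#' Default stem-collapsing exception map
#'
#' Plain suffix stripping leaves spelling families of one concept on
#' different roots (e.g. "include"/"inclusion", or the mutation family
#' "mutant"/"mutagenesis"/"mutation"). The exception map collapses any
#' stem matching a prefix onto a single root; it ships with the
#' `inclu-` and `muta-` families and is user-extensible.
#'
#' @return Named character vector: names are the collapsed roots, values
#'   are regular expressions matched against stems.
#' @export
default_stem_exceptions <- function() {
  c(inclu = "^inclu", muta = "^muta")
}

#' Tokenize text into a bag of stems
#'
#' Lower-cases, tokenizes, removes stop words and caller-supplied extra
#' stop terms (specific protein and amino-acid names, which are part of
#' the retrieval queries and would leak label information), Porter-stems
#' the remaining words, and collapses spelling families through the
#' exception map.
#'
#' @param text Character scalar.
#' @param stopwords Stop-word list.
#' @param extra_stop Additional stop terms (matched on the lower-cased
#'   token, before stemming).
#' @param exceptions Stem exception map, see [default_stem_exceptions()].
#' @return Character vector of stems, one entry per surviving token
#'   (a multiset: duplicates preserved).
#' @export
tokenize_stem <- function(text, stopwords = default_stopwords(),
                          extra_stop = character(),
                          exceptions = default_stem_exceptions()) {
  toks <- regmatches(text, gregexpr("[a-z][a-z0-9+]*", tolower(text)))[[1L]]
  drop <- c(stopwords, tolower(extra_stop))
  toks <- toks[!(toks %in% drop)]
  if (!length(toks)) return(character())
  stems <- porter_stem(toks)
  for (root in names(exceptions)) {
    stems[grepl(exceptions[[root]], stems)] <- root
  }
  stems
}

## ---- feature sets ----------------------------------------------------------

#' Normalized per-class stem frequencies
#'
#' For class `k` with `L_k` training abstracts,
#' `f_k(m) = (1/L_k) * sum_i J_i(m)` where `J_i(m)` counts the
#' occurrences of stem `m` in abstract `i`.
#'
#' @param stem_lists List of character vectors, one bag of stems per
#'   training abstract of the class.
#' @param universe Optional character vector fixing the stem universe
#'   (stems absent from the class get frequency 0).
#' @return Named numeric vector of normalized counts.
#' @export
feature_counts <- function(stem_lists, universe = NULL) {
  if (!length(stem_lists)) stop("empty class: no training abstracts")
  tab <- table(unlist(stem_lists))
  f <- as.numeric(tab) / length(stem_lists)
  names(f) <- names(tab)
  if (!is.null(universe)) {
    out <- stats::setNames(numeric(length(universe)), universe)
    common <- intersect(universe, names(f))
    out[common] <- f[common]
    f <- out
  }
  f
}

#' Select discriminative stems into a feature set
#'
#' Stems with both a frequency contrast `|f_pos - f_neg| > diff_min` and
#' total signal `f_pos + f_neg > sum_min` are retained and sorted by the
#' normalized contrast `delta = (f_pos - f_neg) / (f_pos + f_neg)`,
#' descending. Truncating the sorted set to the stems of largest
#' `|delta|` yields the automated feature-set family.
#'
#' @param f_pos,f_neg Named frequency vectors over the same stem universe
#'   (names are aligned by stem, not by position).
#' @param diff_min,sum_min Selection thresholds (strict).
#' @return A `feature_set`: data frame with columns `stem`, `f_pos`,
#'   `f_neg`, `delta`, sorted by `delta` descending.
#' @export
select_features <- function(f_pos, f_neg, diff_min = 0.02, sum_min = 0.2) {
  universe <- sort(union(names(f_pos), names(f_neg)))
  fp <- stats::setNames(numeric(length(universe)), universe)
  fn <- fp
  fp[names(f_pos)] <- f_pos
  fn[names(f_neg)] <- f_neg
  keep <- abs(fp - fn) > diff_min & (fp + fn) > sum_min
  d <- (fp - fn) / (fp + fn)
  out <- data.frame(stem = universe[keep], f_pos = unname(fp[keep]),
                    f_neg = unname(fn[keep]), delta = unname(d[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$delta, out$stem), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_set", "data.frame")
  out
}

#' Truncate a feature set to its strongest members
#' @param fs A `feature_set`.
#' @param n Number of stems to keep (largest `|delta|`), order preserved.
#' @return A `feature_set`.
#' @export
truncate_features <- function(fs, n) {
  if (n >= nrow(fs)) return(fs)
  keep <- rank(-abs(fs$delta), ties.method = "first") <= n
  out <- fs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_set", "data.frame")
  out
}

#' Read / write feature sets as plain text
#'
#' One stem per line, optionally followed by whitespace and a `delta`
#' column.
#' @param path File path.
#' @return `read_feature_set`: a `feature_set` data frame (frequencies
#'   `NA` when only stems are stored).
#' @export
read_feature_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  out <- data.frame(
    stem = vapply(parts, `[[`, "", 1L),
    f_pos = NA_real_, f_neg = NA_real_,
    delta = vapply(parts, function(p)
      if (length(p) > 1L) as.numeric(p[2L]) else NA_real_, 0),
    stringsAsFactors = FALSE)
  class(out) <- c("feature_set", "data.frame")
  out
}

#' @rdname read_feature_set
#' @param fs A `feature_set`.
#' @export
write_feature_set <- function(fs, path) {
  lines <- if (all(is.na(fs$delta))) fs$stem
  else sprintf("%s\t%.6f", fs$stem, fs$delta)
  writeLines(lines, path)
  invisible(path)
}

#' Bundled feature sets
#'
#' Returns one of the feature-set word lists shipped with the package:
#' the manually curated sets (`"MF60"` down to `"MF10"`) and the
#' automated full set (`"AF143"`, stems in decreasing-`delta` order).
#'
#' @param name Set name, e.g. `"MF50"` or `"AF143"`.
#' @return A `feature_set`.
#' @export
bundled_feature_set <- function(name) {
  path <- system.file("extdata", "feature_sets",
                      paste0(tolower(name), ".txt"), package = "dockmine")
  if (!nzchar(path)) stop("unknown bundled feature set: ", name)
  read_feature_set(path)
}

#' Feature vectors for a corpus
#'
#' Token-wise counting: entry `(i, m)` is `J_i(m)`, the number of times
#' stem `m` occurs in abstract `i`.
#'
#' @param stem_lists List of per-abstract stem bags (from
#'   [tokenize_stem()]).
#' @param fs A `feature_set`.
#' @return Numeric matrix, abstracts in rows, stems in columns.
#' @export
featurize <- function(stem_lists, fs) {
  m <- vapply(stem_lists, function(st)
    as.numeric(table(factor(st, levels = fs$stem))),
    numeric(nrow(fs)))
  m <- t(matrix(m, nrow = nrow(fs)))
  colnames(m) <- fs$stem
  m
}

## ---- train / validate ------------------------------------------------------

#' Split labeled abstracts into training and validation sets
#'
#' Per-class random split: `floor(train_frac * n)` of each class go to
#' training, the remainder to validation. Deterministic under `seed`.
#'
#' @param labels Character vector of `"positive"` / `"negative"` labels.
#' @param train_frac Training fraction.
#' @param seed Integer RNG seed.
#' @return List with integer index vectors `train` and `validation`.
#' @export
split_train_validation <- function(labels, train_frac = 0.8, seed = 1) {
  stopifnot(all(labels %in% c("positive", "negative")))
  train <- integer()
  set.seed(seed)
  for (cls in c("positive", "negative")) {
    ix <- which(labels == cls)
    if (!length(ix)) stop("no abstracts in class ", cls)
    n_tr <- floor(train_frac * length(ix))
    train <- c(train, sort(sample(ix, n_tr)))
  }
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(labels), train))
}

#' Train the abstract-relevance margin classifier
#'
#' A support vector machine on raw stem-count feature vectors. Kernels:
#' `"linear"`, `"polynomial"` (`(alpha * <x, y> + c0)^degree`; the linear
#' kernel is the degree-1 case) and `"rbf"`
#' (`exp(-gamma * |x - y|^2)`). Feature vectors are used unscaled.
#'
#' @param x Feature matrix from [featurize()].
#' @param labels `"positive"` / `"negative"` per row of `x`.
#' @param kernel Kernel name.
#' @param degree Polynomial degree.
#' @param gamma RBF width (also the polynomial `alpha`; default 1).
#' @param coef0 Polynomial additive constant (default 0).
#' @param cost Soft-margin cost.
#' @return An object of class `abstract_svm`.
#' @export
train_abstract_svm <- function(x, labels,
                               kernel = c("linear", "polynomial", "rbf"),
                               degree = 1, gamma = 1, coef0 = 0, cost = 1) {
  kernel <- match.arg(kernel)
  if (length(unique(labels)) < 2L)
    stop("degenerate training set: a single class")
  y <- factor(labels, levels = c("negative", "positive"))
  ek <- switch(kernel, linear = "linear", polynomial = "polynomial",
               rbf = "radial")
  fit <- e1071::svm(x, y, type = "C-classification", kernel = ek,
                    degree = degree, gamma = gamma, coef0 = coef0,
                    cost = cost, scale = FALSE)
  # orient decision values so positive score = positive class
  dv <- attr(stats::predict(fit, x[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- grepl("^negative/", colnames(dv)[1L])
  structure(list(fit = fit, flip = flip, features = colnames(x),
                 kernel = kernel),
            class = "abstract_svm")
}

#' Signed relevance scores
#' @param model An `abstract_svm`.
#' @param x Feature matrix on the model's feature set.
#' @return Numeric vector: positive scores mean relevance.
#' @export
svm_score <- function(model, x) {
  stopifnot(identical(colnames(x), model$features))
  dv <- attr(stats::predict(model$fit, x, decision.values = TRUE),
             "decision.values")
  s <- as.numeric(dv[, 1L])
  if (model$flip) -s else s
}

#' Classify abstracts with an optional unclassified margin
#'
#' The sign of the score decides the class; scores within `margin` of
#' zero are too uncertain and are left `"unclassified"` (and excluded
#' from metric evaluation).
#'
#' @param model An `abstract_svm`.
#' @param x Feature matrix.
#' @param margin Half-width of the unclassified score band.
#' @return Character vector in
#'   `{"positive", "negative", "unclassified"}`.
#' @export
classify_abstracts <- function(model, x, margin = 0.05) {
  stopifnot(margin >= 0)
  s <- svm_score(model, x)
  out <- ifelse(s > 0, "positive", "negative")
  out[abs(s) < margin] <- "unclassified"
  out
}

## ---- metrics ---------------------------------------------------------------

#' Confusion matrix of a validation run
#'
#' Unclassified abstracts are excluded.
#'
#' @param predicted,truth Character vectors (`"positive"` / `"negative"`;
#'   `predicted` may contain `"unclassified"`).
#' @return A list with counts `tp`, `fp`, `tn`, `fn` (class
#'   `confusion_matrix`).
#' @export
confusion_matrix <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  keep <- predicted != "unclassified"
  p <- predicted[keep]; t <- truth[keep]
  structure(list(tp = sum(p == "positive" & t == "positive"),
                 fp = sum(p == "positive" & t == "negative"),
                 tn = sum(p == "negative" & t == "negative"),
                 fn = sum(p == "negative" & t == "positive")),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Precision `P = TP/(TP+FP)`, recall `R = TP/(TP+FN)`, accuracy
#' `A = (TP+TN)/total`, and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Metrics with a zero denominator are undefined and reported as `NA`,
#' never silently as zero.
#'
#' @param cm A `confusion_matrix` (or a list with `tp`, `fp`, `tn`,
#'   `fn`).
#' @return Named numeric vector `c(precision, recall, accuracy, mcc)`
#'   (proportions, not percentages).
#' @export
svm_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  den_mcc <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  c(precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    accuracy = safe_div(tp + tn, tp + fp + tn + fn),
    mcc = if (den_mcc > 0) (tp * tn - fp * fn) / den_mcc else NA_real_)
}
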