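## Synthetic corpora and toy complexes with recorded ground truth, so the
## whole pipeline is testable without any network or external data.

.POS_WORDS <- c("binding", "binds", "bound", "interaction", "interactions",
                "interacts", "interface", "complex", "complexes", "contact",
                "contacts", "conserved", "conformation", "conformational",
                "recognition", "induced", "allosteric", "domain", "domains",
                "affinity", "association", "associates", "specific",
                "specificity", "stability", "stabilized", "surface",
                "substrate", "receptor", "signaling", "target", "catalytic",
                "linkage", "proximal", "attached")
.NEG_WORDS <- c("polymorphism", "polymorphisms", "antibody", "antibodies",
                "patients", "disease", "diseases", "gene", "genes",
                "expression", "expressed", "phenotype", "phenotypes",
                "promoter", "transcription", "membrane", "resistance",
                "levels", "detected", "detection", "assay", "cells",
                "clinical", "population", "diagnosis", "serum", "tissue",
                "therapy", "treatment", "filament", "light")
.NEUTRAL_WORDS <- c("study", "results", "data", "observed", "analysis",
                    "role", "effect", "region", "method", "reported",
                    "experiments", "measurements")

#' Render a residue mention in a chosen surface form
#'
#' Produces the textual form of a residue mention in one of the styles
#' the mention grammar recognizes, for planting into synthetic abstracts.
#'
#' @param aa Canonical three-letter code.
#' @param number Residue number.
#' @param style One of `"nospace"`, `"space"`, `"hyphen"`, `"paren"`,
#'   `"full-nospace"`, `"full-space"`, `"full-hyphen"`, `"full-paren"`,
#'   `"mut1"` (one-letter mutation `S4A`), `"mut3"` (`Ser4Ala`),
#'   `"mut3-hyphen"` (`Ser-4Ala`).
#' @param case `"title"`, `"lower"` or `"upper"` (full names support
#'   title and lower only; mutation one-letter forms ignore it).
#' @param to_aa Substituted residue (three-letter code) for mutation
#'   styles.
#' @return Character scalar.
#' @export
render_mention <- function(aa, number, style = "space", case = "title",
                           to_aa = NULL) {
  aa <- toupper(aa)
  stopifnot(aa %in% .AA3)
  cased3 <- function(a) switch(case,
    title = paste0(substring(a, 1, 1), tolower(substring(a, 2))),
    lower = tolower(a),
    upper = a,
    stop("unknown case style: ", case))
  full_of <- function(a) {
    full <- names(.AA_FULL_TO3)[match(a, .AA_FULL_TO3)]
    if (case == "lower") tolower(full) else full
  }
  if (style %in% c("mut1", "mut3", "mut3-hyphen")) {
    stopifnot(!is.null(to_aa))
    to_aa <- toupper(to_aa)
    return(switch(style,
      mut1 = paste0(.AA1[aa], number, .AA1[to_aa]),
      mut3 = paste0(cased3(aa), number, cased3(to_aa)),
      `mut3-hyphen` = paste0(cased3(aa), "-", number, cased3(to_aa))))
  }
  tok <- if (startsWith(style, "full")) full_of(aa) else cased3(aa)
  switch(sub("^full-", "", style),
         nospace = paste0(tok, number),
         space = paste(tok, number),
         hyphen = paste0(tok, "-", number),
         paren = paste0(tok, "(", number, ")"),
         stop("unknown mention style: ", style))
}

.sample_sentence <- function(vocab, n_words) {
  paste0(paste(sample(vocab, n_words, replace = TRUE), collapse = " "), ".")
}

#' Generate a synthetic abstract corpus with planted residue mentions
#'
#' Each row of `mentions` plants one residue mention in the abstract it
#' names; an abstract may carry several. Mutation-style mentions also get
#' a mutagenesis keyword sentence unless `mutagenesis` is `FALSE` for
#' that row (a deliberate no-context plant for testing the contrast).
#' Abstract bodies are filler sentences drawn from a neutral vocabulary.
#' Deterministic under `seed`.
#'
#' @param n_abstracts Number of abstracts.
#' @param mentions Data frame with columns `abstract` (1-based index),
#'   `aa`, `number`, `style`, `case`, `to_aa` (NA unless a mutation
#'   style) and `mutagenesis` (logical: include a keyword sentence).
#' @param retrieved_by Tag set given to every record (list or single
#'   tag).
#' @param seed Integer seed.
#' @return List with `corpus` (a corpus data frame) and `truth`: the
#'   expected extraction result (`pmid`, `aa`, `number`), mutation plants
#'   expanded to both residues and only when their context allows it.
#' @export
generate_mention_corpus <- function(n_abstracts, mentions, seed = 1,
                                    retrieved_by = "AND") {
  set.seed(seed)
  if (!is.list(retrieved_by)) retrieved_by <- list(retrieved_by)
  bodies <- character(n_abstracts)
  truth <- list()
  for (i in seq_len(n_abstracts)) {
    sents <- c(.sample_sentence(.NEUTRAL_WORDS, 8L))
    rows <- mentions[mentions$abstract == i, , drop = FALSE]
    muta_ctx <- any(rows$mutagenesis %in% TRUE)
    for (r in seq_len(nrow(rows))) {
      m <- rows[r, ]
      form <- render_mention(m$aa, m$number, m$style, m$case,
                             to_aa = if (is.na(m$to_aa)) NULL else m$to_aa)
      sents <- c(sents, paste0("The residue ", form, " was examined."))
      is_mut <- m$style %in% c("mut1", "mut3", "mut3-hyphen")
      if (!is_mut || isTRUE(muta_ctx)) {
        truth[[length(truth) + 1L]] <- data.frame(
          pmid = as.character(1000L + i), aa = toupper(m$aa),
          number = as.integer(m$number), stringsAsFactors = FALSE)
        if (is_mut)
          truth[[length(truth) + 1L]] <- data.frame(
            pmid = as.character(1000L + i), aa = toupper(m$to_aa),
            number = as.integer(m$number), stringsAsFactors = FALSE)
      }
    }
    if (isTRUE(muta_ctx))
      sents <- c(sents, "Site-directed mutagenesis was performed.")
    bodies[i] <- paste(sents, collapse = " ")
  }
  corpus <- .as_corpus(pmid = as.character(1000L + seq_len(n_abstracts)),
                       title = sprintf("Synthetic abstract %d",
                                       seq_len(n_abstracts)),
                       body = bodies,
                       pub_date = as.Date("2000-01-01") +
                         seq_len(n_abstracts),
                       retrieved_by = rep(retrieved_by, n_abstracts))
  truth <- if (length(truth)) unique(do.call(rbind, truth))
           else data.frame(pmid = character(), aa = character(),
                           number = integer(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(corpus = corpus, truth = truth)
}

#' Generate a two-class corpus with class-specific vocabulary profiles
#'
#' Emulates the class structure the relevance classifier is trained on:
#' interaction-relevant abstracts draw their tokens mostly from an
#' interaction vocabulary (word forms whose stems carry positive
#' frequency contrast), irrelevant abstracts from a clinical/genetics
#' vocabulary, with `separation` in `[0, 1]` controlling the mixture
#' (1 = fully separated profiles, 0 = indistinguishable). Deterministic
#' under `seed`.
#'
#' @param n_pos,n_neg Abstracts per class.
#' @param words_per_abstract Tokens drawn per abstract.
#' @param separation Profile separation.
#' @param seed Integer seed.
#' @return List with `corpus` and `labels`
#'   (`"positive"` / `"negative"` per record).
#' @export
generate_svm_corpus <- function(n_pos = 50, n_neg = 50,
                                words_per_abstract = 60, separation = 1,
                                seed = 1) {
  stopifnot(separation >= 0, separation <= 1)
  set.seed(seed)
  p_own <- (1 + separation) / 2
  one <- function(own, other) {
    n_own <- stats::rbinom(1L, words_per_abstract, p_own)
    words <- c(sample(own, n_own, replace = TRUE),
               sample(other, words_per_abstract - n_own, replace = TRUE),
               sample(.NEUTRAL_WORDS, 6L, replace = TRUE))
    paste0(paste(sample(words), collapse = " "), ".")
  }
  bodies <- c(vapply(seq_len(n_pos), function(i)
    one(.POS_WORDS, .NEG_WORDS), ""),
    vapply(seq_len(n_neg), function(i) one(.NEG_WORDS, .POS_WORDS), ""))
  labels <- c(rep("positive", n_pos), rep("negative", n_neg))
  n <- n_pos + n_neg
  corpus <- .as_corpus(pmid = as.character(2000L + seq_len(n)),
                       title = sprintf("Synthetic abstract %d", seq_len(n)),
                       body = bodies,
                       pub_date = as.Date("2001-01-01") + seq_len(n),
                       retrieved_by = rep(list("AND"), n))
  list(corpus = corpus, labels = labels)
}

## ---- toy complexes ---------------------------------------------------------

.random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

.small_rotation <- function(max_angle = 0.15) {
  axis <- stats::rnorm(3L)
  axis <- axis / sqrt(sum(axis^2))
  th <- stats::runif(1L, 0, max_angle)
  K <- matrix(c(0, -axis[3L], axis[2L], axis[3L], 0, -axis[1L],
                -axis[2L], axis[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.toy_chain <- function(chain, resids, x0 = 0, y = 0, flip = 1) {
  # backbone template per residue; CB points along +y (or -y when
  # flipped), so facing chains touch through their CB atoms
  tmpl <- list(
    N = c(-1.2, 0.5, 0.0), CA = c(0.0, 0.0, 0.0), C = c(1.2, -0.5, 0.0),
    O = c(1.4, -1.6, 0.3), CB = c(0.0, 1.2, 1.0))
  rows <- list()
  for (i in seq_along(resids)) {
    cx <- x0 + 3.8 * i
    wig <- 0.3 * sin(1.7 * i)   # keep the CA trace off a common plane
    for (a in names(tmpl)) {
      off <- tmpl[[a]]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = i, insert = "", resid = resids[i],
        elety = a, elesy = substring(a, 1L, 1L),
        x = cx + off[1L], y = y + flip * off[2L], z = off[3L] + wig,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a toy two-chain complex with a known interface
#'
#' Two synthetic extended chains (receptor chain `A`, smaller ligand
#' chain `B`) face each other through a designed contact patch: patch
#' residue pairs sit exactly opposite at a closest heavy-atom distance of
#' 5.5 Angstrom (inside the 6 Angstrom interface cutoff) while every
#' non-patch pair is beyond it, so the interface truth is exact by
#' construction. Residue names are drawn from the 19 standard types with
#' a side-chain atom (no glycine). Also produced: rigidly perturbed
#' copies of both chains standing in for unbound structures, and a pose
#' list with one near-native pose (the transform returning the unbound
#' ligand to its bound position) followed by far-away decoys. No claim
#' of physical realism is made.
#'
#' @param n_receptor,n_ligand Residues per chain.
#' @param patch_start Index of the first patch residue (on both chains).
#' @param patch_length Number of contact residue pairs.
#' @param n_decoys Number of decoy poses.
#' @param perturb Magnitude of the unbound rigid perturbation is fixed;
#'   set `perturb = FALSE` to make unbound structures identical to the
#'   bound chains.
#' @param seed Integer seed.
#' @return List with `bound` (`dock_structure`), `receptor_chains`,
#'   `ligand_chains`, `receptor_unbound`, `ligand_unbound`,
#'   `interface_truth` (list of residue tables `side1`, `side2`),
#'   `poses` (pose data frame, scan order; column `match`),
#'   `near_native_match` (its `match` id).
#' @export
generate_complex <- function(n_receptor = 30, n_ligand = 20,
                             patch_start = 5, patch_length = 6,
                             n_decoys = 20, perturb = TRUE, seed = 1) {
  stopifnot(patch_start + patch_length - 1 <= min(n_receptor, n_ligand))
  set.seed(seed)
  aa_pool <- setdiff(.AA3, "GLY")
  res_a <- sample(aa_pool, n_receptor, replace = TRUE)
  res_b <- sample(aa_pool, n_ligand, replace = TRUE)
  # facing chains: A's CB points +y from y=0, B's CB points -y from
  # y=7.9, giving an aligned CB-CB gap of 5.5 A; off-patch B residues
  # are displaced to y=30 (> 20 A from anything in A)
  a_atoms <- .toy_chain("A", res_a, x0 = 0, y = 0, flip = 1)
  b_atoms <- .toy_chain("B", res_b, x0 = 0, y = 7.9, flip = -1)
  patch <- seq(patch_start, patch_start + patch_length - 1L)
  far <- !(b_atoms$resno %in% patch)
  b_atoms$y[far] <- b_atoms$y[far] + 30
  bound <- structure_from_atoms(rbind(a_atoms, b_atoms))
  truth <- list(
    side1 = data.frame(chain = "A", resno = patch, insert = "",
                       resid = res_a[patch], stringsAsFactors = FALSE),
    side2 = data.frame(chain = "B", resno = patch, insert = "",
                       resid = res_b[patch], stringsAsFactors = FALSE))
  split_side <- function(st, ch)
    structure_from_atoms(st$atoms[st$atoms$chain %in% ch, , drop = FALSE])
  perturb_structure <- function(st, jitter = 0.05, rigid = TRUE) {
    Rp <- if (rigid) .small_rotation() else diag(3L)
    tp <- if (rigid) stats::rnorm(3L, sd = 4) else c(0, 0, 0)
    xyz <- as.matrix(st$atoms[, c("x", "y", "z")])
    new <- xyz %*% t(Rp)
    new <- sweep(new, 2L, tp, "+") +
      matrix(stats::rnorm(length(xyz), sd = jitter), ncol = 3L)
    out <- st
    out$atoms$x <- new[, 1L]; out$atoms$y <- new[, 2L]
    out$atoms$z <- new[, 3L]
    list(structure = out, R = Rp, t = tp)
  }
  rec_b <- split_side(bound, "A")
  lig_b <- split_side(bound, "B")
  if (isTRUE(perturb)) {
    # the unbound receptor stays in the bound frame (poses and i-RMSD
    # references are expressed in it); its unbound character is the
    # coordinate jitter emulating a conformational difference
    rec_u <- perturb_structure(rec_b, rigid = FALSE)$structure
    pl <- perturb_structure(lig_b)
    lig_u <- pl$structure
    # near-native pose: undo the ligand perturbation
    Rn <- t(pl$R)
    tn <- -as.numeric(t(pl$R) %*% pl$t)
  } else {
    rec_u <- rec_b
    lig_u <- lig_b
    Rn <- diag(3L)
    tn <- c(0, 0, 0)
  }
  pose_row <- function(id, R, t) {
    data.frame(match = id, r11 = R[1, 1], r12 = R[1, 2], r13 = R[1, 3],
               r21 = R[2, 1], r22 = R[2, 2], r23 = R[2, 3],
               r31 = R[3, 1], r32 = R[3, 2], r33 = R[3, 3],
               tx = t[1L], ty = t[2L], tz = t[3L])
  }
  # decoys: the bound ligand placement, rotated about the ligand's own
  # centroid and shifted far enough that no decoy can touch the receptor
  # whatever the direction relative to the elongated chains
  cen <- colMeans(as.matrix(lig_b$atoms[, c("x", "y", "z")]))
  decoys <- lapply(seq_len(n_decoys), function(i) {
    dirv <- stats::rnorm(3L)
    dirv <- dirv / sqrt(sum(dirv^2))
    shift <- dirv * stats::runif(1L, 150, 250)
    Rr <- .random_rotation()
    Rd <- Rr %*% Rn
    td <- as.numeric(Rr %*% (tn - cen)) + cen + shift
    pose_row(i + 1L, Rd, td)
  })
  poses <- do.call(rbind, c(list(pose_row(1L, Rn, tn)), decoys))
  # near-native buried mid-list: decoys keep scan ranks 1..n, the
  # near-native is appended last so rescoring has to promote it
  poses <- poses[c(seq_len(nrow(poses))[-1L], 1L), , drop = FALSE]
  poses$match <- seq_len(nrow(poses))
  rownames(poses) <- NULL
  list(bound = bound, receptor_chains = "A", ligand_chains = "B",
       receptor_unbound = rec_u, ligand_unbound = lig_u,
       interface_truth = truth, poses = poses,
       near_native_match = nrow(poses))
}

#' Write a structure as a PDB-format file
#' @param structure A `dock_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   insert = ifelse(nzchar(at$insert), at$insert, ""),
                   elety = at$elety, elesy = at$elesy,
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}

#' Write a corpus in the fixture JSON format
#' @param corpus A corpus data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_json <- function(corpus, path) {
  recs <- lapply(seq_len(nrow(corpus)), function(i) {
    r <- list(pmid = corpus$pmid[i], title = corpus$title[i],
              abstract = corpus$body[i],
              retrieved_by = as.list(corpus$retrieved_by[[i]]))
    if (!is.na(corpus$pub_date[i]))
      r$pub_date <- format(corpus$pub_date[i], "%Y-%m-%d")
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
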