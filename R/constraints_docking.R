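## Turning identified residues into ranked docking constraints and
## rescoring rigid-body docking matches with them.

#' Confidence score of a mined residue
#'
#' Each distinct abstract mentioning the residue contributes weight 2
#' when it was retrieved by the AND-query and 1 when retrieved by the
#' OR-query only; the sum is capped at 10 to balance low- against
#' high-confidence constraints and to damp over-represented residues.
#'
#' @param n_and Number of distinct AND-retrieved abstracts mentioning the
#'   residue.
#' @param n_or_only Number of distinct abstracts retrieved by the
#'   OR-query only.
#' @param cap Upper limit of the confidence.
#' @return Numeric confidence in `[1, cap]` (vectorized).
#' @export
residue_confidence <- function(n_and, n_or_only = 0, cap = 10) {
  stopifnot(all(n_and >= 0), all(n_or_only >= 0),
            all(n_and + n_or_only >= 1))
  pmin(cap, 2 * n_and + n_or_only)
}

#' Rank identified residues into docking constraints
#'
#' Residues are scored with [residue_confidence()] and the top `k` per
#' interactor are kept. When more residues than fit share the cutoff
#' confidence, residues whose score contains more AND-retrieved
#' contributions are preferred; remaining ties are broken by seeded
#' random removal.
#'
#' @param identified Identified-residue table (from
#'   [identify_residues()]): columns `side`, `chain`, `resno`, `insert`,
#'   `aa`, `n_abstracts_and`, `n_abstracts_or_only`.
#' @param k Constraints kept per interactor.
#' @param seed Integer seed for the random tie-break.
#' @param cap Confidence cap.
#' @return Constraint table: the selected rows with a `confidence`
#'   column, sorted by side then confidence descending.
#' @export
select_constraints <- function(identified, k = 5, seed = 1, cap = 10) {
  if (!nrow(identified)) {
    identified$confidence <- numeric()
    return(identified)
  }
  identified$confidence <- residue_confidence(identified$n_abstracts_and,
                                              identified$n_abstracts_or_only,
                                              cap = cap)
  set.seed(seed)
  out <- lapply(split(identified, identified$side), function(d) {
    jitter <- stats::runif(nrow(d))
    ord <- order(-d$confidence, -d$n_abstracts_and, jitter)
    d <- d[ord, , drop = FALSE]
    d[seq_len(min(k, nrow(d))), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Reference constraints from the bound interface
#'
#' For validation against ground truth: all (side-1, side-2) pairs of
#' crystallographic interface residues are sorted ascending by their
#' C-alpha distance, exactly tied distances broken lexicographically by
#' (chain, residue number) of both members, and the top `n_pairs` pairs
#' returned with the maximal confidence. When the interface yields fewer
#' pairs, all are returned with a warning.
#'
#' @param complex A `dock_structure` of the bound complex.
#' @param side1,side2 Chain-id vectors of the two interactors.
#' @param n_pairs Number of pairs to return.
#' @param cutoff Interface heavy-atom cutoff (Angstrom).
#' @param confidence Confidence assigned to every reference residue.
#' @return Data frame of pairs: `chain1`, `resno1`, `insert1`, `aa1`,
#'   `chain2`, `resno2`, `insert2`, `aa2`, `ca_dist`, `confidence`.
#' @export
reference_constraints <- function(complex, side1, side2, n_pairs = 3,
                                  cutoff = 6, confidence = 10) {
  iface <- compute_interface(complex, side1, side2, cutoff = cutoff)
  if (!nrow(iface$side1) || !nrow(iface$side2))
    stop("empty interface: no reference constraints available")
  ca <- complex$atoms[trimws(complex$atoms$elety) == "CA", , drop = FALSE]
  ca_of <- function(df) {
    key <- paste(df$chain, df$resno, df$insert)
    m <- match(key, paste(ca$chain, ca$resno, ca$insert))
    cbind(df, cax = ca$x[m], cay = ca$y[m], caz = ca$z[m])
  }
  r1 <- ca_of(iface$side1)
  r2 <- ca_of(iface$side2)
  r1 <- r1[!is.na(r1$cax), , drop = FALSE]
  r2 <- r2[!is.na(r2$cax), , drop = FALSE]
  g <- expand.grid(i = seq_len(nrow(r1)), j = seq_len(nrow(r2)))
  d <- sqrt((r1$cax[g$i] - r2$cax[g$j])^2 + (r1$cay[g$i] - r2$cay[g$j])^2 +
              (r1$caz[g$i] - r2$caz[g$j])^2)
  ord <- order(round(d, 6), r1$chain[g$i], r1$resno[g$i], r2$chain[g$j],
               r2$resno[g$j])
  g <- g[ord, , drop = FALSE]
  d <- d[ord]
  if (nrow(g) < n_pairs)
    warning("interface yields only ", nrow(g), " residue pair(s); ",
            "returning all of them")
  take <- seq_len(min(n_pairs, nrow(g)))
  out <- data.frame(
    chain1 = r1$chain[g$i[take]], resno1 = r1$resno[g$i[take]],
    insert1 = r1$insert[g$i[take]], aa1 = r1$resid[g$i[take]],
    chain2 = r2$chain[g$j[take]], resno2 = r2$resno[g$j[take]],
    insert2 = r2$insert[g$j[take]], aa2 = r2$resid[g$j[take]],
    ca_dist = d[take], confidence = confidence,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## ---- poses -----------------------------------------------------------------

#' Apply a rigid pose to a structure
#'
#' A pose is a rigid transform `x' = R x + t` stored as a named list or
#' one-row data frame with rotation entries `r11 ... r33` (row-major) and
#' translation `tx`, `ty`, `tz`.
#'
#' @param structure A `dock_structure` (the unbound ligand).
#' @param pose Pose row.
#' @return The transformed `dock_structure`.
#' @export
apply_pose <- function(structure, pose) {
  R <- matrix(as.numeric(pose[c("r11", "r12", "r13", "r21", "r22", "r23",
                                "r31", "r32", "r33")]),
              3L, 3L, byrow = TRUE)
  t <- as.numeric(pose[c("tx", "ty", "tz")])
  if (anyNA(R) || anyNA(t)) stop("malformed pose: missing transform entries")
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  new <- xyz %*% t(R)
  new <- sweep(new, 2L, t, "+")
  out <- structure
  out$atoms$x <- new[, 1L]
  out$atoms$y <- new[, 2L]
  out$atoms$z <- new[, 3L]
  out
}

#' Identity pose
#' @return One-row pose data frame leaving coordinates unchanged.
#' @export
identity_pose <- function() {
  data.frame(r11 = 1, r12 = 0, r13 = 0, r21 = 0, r22 = 1, r23 = 0,
             r31 = 0, r32 = 0, r33 = 1, tx = 0, ty = 0, tz = 0)
}

#' Read / write a docking-match pose list
#'
#' Tab-separated, one rigid transform per match: columns `match`,
#' `r11 ... r33` (row-major rotation), `tx`, `ty`, `tz`, in scan order.
#'
#' @param path File path.
#' @return `read_poses`: data frame of poses in scan order.
#' @export
read_poses <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_poses
#' @param poses Pose data frame.
#' @export
write_poses <- function(poses, path) {
  utils::write.table(poses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rescore docking matches by constraint support
#'
#' For every match the unbound ligand is posed and the model interface is
#' determined with the same heavy-atom cutoff used for real interfaces.
#' The match score is the summed confidence of all constraint residues
#' lying at that model interface; matches are re-sorted by score,
#' descending, with the original scan order preserved among equal scores
#' (stable sort). Without constraints all scores are zero and scan order
#' is preserved. The multiset of matches is never changed, only their
#' order.
#'
#' @param matches Pose data frame (scan order; column `match` plus the
#'   transform columns of [read_poses()]).
#' @param constraints Constraint table from [select_constraints()]
#'   (columns `side`, `chain`, `resno`, `insert`, `confidence`; side 1 =
#'   receptor, side 2 = ligand). May be empty or `NULL`.
#' @param receptor,ligand Unbound `dock_structure`s; the receptor stays
#'   fixed, poses move the ligand.
#' @param cutoff Model-interface heavy-atom cutoff (Angstrom).
#' @return `matches` re-sorted, with a `tm_score` column appended.
#' @export
rescore <- function(matches, constraints, receptor, ligand, cutoff = 6) {
  n <- nrow(matches)
  if (is.null(constraints) || !nrow(constraints)) {
    matches$tm_score <- 0
    return(matches)
  }
  need <- c("r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32", "r33",
            "tx", "ty", "tz")
  scores <- numeric(n)
  rec_key <- .residue_key(receptor$atoms)
  lig_key_orig <- .residue_key(ligand$atoms)
  rx <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  c1 <- constraints[constraints$side == 1L, , drop = FALSE]
  c2 <- constraints[constraints$side == 2L, , drop = FALSE]
  k1 <- paste(c1$chain, c1$resno, c1$insert, sep = "|")
  k2 <- paste(c2$chain, c2$resno, c2$insert, sep = "|")
  for (i in seq_len(n)) {
    pose <- matches[i, need]
    if (anyNA(suppressWarnings(as.numeric(pose))))
      stop("malformed pose in match ",
           if ("match" %in% names(matches)) matches$match[i] else i)
    posed <- apply_pose(ligand, matches[i, ])
    lx <- as.matrix(posed$atoms[, c("x", "y", "z")])
    d2 <- outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * tcrossprod(rx, lx)
    contact <- d2 <= cutoff^2 + 1e-9
    rec_iface <- unique(rec_key[apply(contact, 1L, any)])
    lig_iface <- unique(lig_key_orig[apply(contact, 2L, any)])
    scores[i] <- sum(c1$confidence[k1 %in% rec_iface]) +
      sum(c2$confidence[k2 %in% lig_iface])
  }
  ord <- order(-scores)   # order() is stable: scan order kept among ties
  out <- matches[ord, , drop = FALSE]
  out$tm_score <- scores[ord]
  rownames(out) <- NULL
  out
}

## ---- i-RMSD and success ----------------------------------------------------

.ca_coords <- function(structure, keys = NULL) {
  at <- structure$atoms
  ca <- at[trimws(at$elety) == "CA", , drop = FALSE]
  if (!is.null(keys)) {
    m <- match(keys, paste(ca$chain, ca$resno, ca$insert, sep = "|"))
    ca <- ca[m[!is.na(m)], , drop = FALSE]
  }
  as.matrix(ca[, c("x", "y", "z")])
}

#' Ligand interface RMSD of a docking match
#'
#' The quality measure of a pose: the reference position of the unbound
#' ligand is obtained by least-squares superposition of its C-alpha trace
#' onto the bound ligand within the co-crystallized complex; the i-RMSD
#' is then the C-alpha RMSD over the ligand's *interface* residues
#' (defined on the bound reference with the heavy-atom cutoff) between
#' the posed unbound ligand and that reference. The ligand is the
#' smaller protein of the pair. Residues present in the bound but absent
#' from the unbound ligand are skipped; the number of matched interface
#' residues is attached as attribute `n_matched`.
#'
#' @param pose Pose row (applied to `unbound_ligand`), or `NULL` if
#'   `unbound_ligand` is already posed.
#' @param bound A `dock_structure` of the co-crystallized complex.
#' @param receptor_chains,ligand_chains Chain ids of the two interactors
#'   within `bound`.
#' @param unbound_ligand Unbound ligand `dock_structure`; residue
#'   numbering must correspond to the bound ligand (same `resno` means
#'   same residue).
#' @param cutoff Interface heavy-atom cutoff on the bound reference.
#' @return i-RMSD in Angstrom (attribute `n_matched`).
#' @export
irmsd <- function(pose, bound, receptor_chains, ligand_chains,
                  unbound_ligand, cutoff = 6) {
  iface <- compute_interface(bound, receptor_chains, ligand_chains,
                             cutoff = cutoff)$side2
  if (!nrow(iface)) stop("bound reference has no ligand interface residues")
  # superimpose the unbound ligand onto the bound ligand (all shared CAs)
  bound_lig <- bound$atoms[bound$atoms$chain %in% ligand_chains, ,
                           drop = FALSE]
  bl_ca <- bound_lig[trimws(bound_lig$elety) == "CA", , drop = FALSE]
  ul_ca <- unbound_ligand$atoms[
    trimws(unbound_ligand$atoms$elety) == "CA", , drop = FALSE]
  shared <- intersect(paste(bl_ca$resno, bl_ca$insert),
                      paste(ul_ca$resno, ul_ca$insert))
  if (length(shared) < 3L)
    stop("fewer than 3 shared ligand C-alpha atoms for superposition")
  bsel <- match(shared, paste(bl_ca$resno, bl_ca$insert))
  usel <- match(shared, paste(ul_ca$resno, ul_ca$insert))
  bxyz <- as.numeric(t(as.matrix(bl_ca[bsel, c("x", "y", "z")])))
  uxyz_all <- as.numeric(t(as.matrix(ul_ca[, c("x", "y", "z")])))
  usel_inds <- as.vector(vapply(usel, function(i) (3L * (i - 1L) + 1L):(3L * i),
                                integer(3)))
  fitted <- bio3d::fit.xyz(fixed = bxyz, mobile = uxyz_all,
                           fixed.inds = seq_along(bxyz),
                           mobile.inds = usel_inds)
  ref_ca <- matrix(as.numeric(fitted), ncol = 3L, byrow = TRUE)
  # docked coordinates of the same CA atoms
  docked <- if (is.null(pose)) unbound_ligand
            else apply_pose(unbound_ligand, pose)
  dl_ca <- docked$atoms[trimws(docked$atoms$elety) == "CA", , drop = FALSE]
  # interface residues (bound numbering) present in the unbound ligand
  iface_keys <- paste(iface$resno, iface$insert)
  sel <- which(paste(ul_ca$resno, ul_ca$insert) %in% iface_keys)
  if (!length(sel))
    stop("no interface residues matched between bound and unbound ligand")
  dif <- as.matrix(dl_ca[sel, c("x", "y", "z")]) - ref_ca[sel, , drop = FALSE]
  out <- sqrt(mean(rowSums(dif^2)))
  attr(out, "n_matched") <- length(sel)
  out
}

#' Docking success rate over a set of complexes
#'
#' Strict criterion: at least one match with i-RMSD <= 5 Angstrom among
#' the top 10 re-ranked predictions. Relaxed: i-RMSD <= 8 Angstrom among
#' the top 100. Both thresholds are inclusive.
#'
#' @param results Data frame with columns `complex`, `rank` (position
#'   after rescoring, 1-based) and `irmsd`.
#' @param criterion `"strict"` or `"relaxed"`.
#' @return Percentage of complexes satisfying the criterion.
#' @export
success_rate <- function(results, criterion = c("strict", "relaxed")) {
  criterion <- match.arg(criterion)
  top <- if (criterion == "strict") 10 else 100
  thr <- if (criterion == "strict") 5 else 8
  ok <- vapply(split(results, results$complex), function(d)
    any(d$rank <= top & d$irmsd <= thr, na.rm = TRUE), TRUE)
  100 * mean(ok)
}
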