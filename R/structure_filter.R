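## Structures are held as a plain atom table: one row per heavy atom with
## chain, residue number (+ insertion code), residue name and coordinates.

.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
          H = 1.20)
.VDW_DEFAULT <- 1.70

# Theoretical maximum accessible surface areas (A^2) per residue type
# (Tien et al. 2013), used for the relative-exposure threshold.
.MAX_ASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0,
              CYS = 167.0, GLN = 225.0, GLU = 223.0, GLY = 104.0,
              HIS = 224.0, ILE = 197.0, LEU = 201.0, LYS = 236.0,
              MET = 224.0, PHE = 240.0, PRO = 159.0, SER = 155.0,
              THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

#' Build a structure from an atom table
#'
#' @param atoms Data frame with columns `chain`, `resno` (integer),
#'   `insert` (character, `""` when blank), `resid` (three-letter code),
#'   `elety` (atom name), `elesy` (element symbol) and `x`, `y`, `z` in
#'   Angstrom. Only heavy atoms should be present.
#' @return An object of class `dock_structure`.
#' @export
structure_from_atoms <- function(atoms) {
  need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  atoms$resno <- as.integer(atoms$resno)
  atoms$insert[is.na(atoms$insert)] <- ""
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "dock_structure")
}

#' Read a PDB-format structure
#'
#' Keeps `ATOM` records of the first model only; hydrogens, waters and
#' heteroatoms are dropped, and of alternate-location conformers the
#' highest-occupancy one is kept. Chain, residue number and insertion code
#' are honored.
#'
#' @param path Path to a PDB file.
#' @return A `dock_structure`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  elesy <- toupper(trimws(at$elesy))
  guess <- toupper(substring(trimws(at$elety), 1L, 1L))
  elesy[is.na(elesy) | !nzchar(elesy)] <- guess[is.na(elesy) | !nzchar(elesy)]
  at$elesy <- elesy
  at <- at[elesy != "H" & !grepl("^[0-9]*H", trimws(at$elety)), , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  if (any(nzchar(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    ord <- order(key, -at$o)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
             drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  structure_from_atoms(at[, c("chain", "resno", "insert", "resid",
                              "elety", "elesy", "x", "y", "z")])
}

#' @export
print.dock_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("<dock_structure> ", nrow(x$atoms), " heavy atoms, ",
      nrow(rt), " residues, chains: ",
      paste(unique(rt$chain), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Residue table of a structure
#' @param structure A `dock_structure`.
#' @param chains Optional chain subset.
#' @return Data frame with one row per residue (`chain`, `resno`,
#'   `insert`, `resid`), in file order.
#' @export
residue_table <- function(structure, chains = NULL) {
  at <- structure$atoms
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  key <- paste(at$chain, at$resno, at$insert)
  at <- at[!duplicated(key), c("chain", "resno", "insert", "resid")]
  rownames(at) <- NULL
  at
}

.residue_key <- function(df) paste(df$chain, df$resno, df$insert, sep = "|")

# quasi-uniform points on the unit sphere (golden-spiral lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue solvent-accessible surface area
#'
#' Rolling-probe SASA by sphere sampling (Shrake-Rupley): every heavy atom
#' is inflated by the probe radius and covered with a quasi-uniform point
#' lattice; points falling inside any neighboring inflated atom are
#' occluded, and the accessible fraction times the sphere area gives the
#' atomic SASA. Atomic areas are summed per residue and divided by the
#' residue type's theoretical maximum area to give relative exposure.
#'
#' @param structure A `dock_structure`.
#' @param chains Optional chain subset: SASA is then computed on those
#'   chains in isolation (the rest of the structure removed).
#' @param probe Probe radius in Angstrom.
#' @param n_points Sample points per atom.
#' @return Residue table with columns `area` (A^2) and `rel_exposure`.
#' @export
compute_sasa <- function(structure, chains = NULL, probe = 1.4,
                         n_points = 960) {
  at <- structure$atoms
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (!nrow(at)) stop("no atoms in selection")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  radii <- .VDW[at$elesy]
  radii[is.na(radii)] <- .VDW_DEFAULT
  radii <- unname(radii) + probe
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  # neighbor lists from the full squared-distance matrix
  sq <- rowSums(xyz^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    thr <- (radii[i] + radii)^2
    nb <- which(d2[i, ] < thr)
    nb <- nb[nb != i]
    p <- pts * radii[i]
    p <- sweep(p, 2L, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj >= radii[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * radii[i]^2 * sum(acc) / n_points
  }
  key <- paste(at$chain, at$resno, at$insert)
  res_area <- tapply(area, key, sum)
  rt <- residue_table(structure, chains)
  rt$area <- as.numeric(res_area[paste(rt$chain, rt$resno, rt$insert)])
  unknown <- !(rt$resid %in% names(.MAX_ASA))
  if (any(unknown))
    stop("no reference maximal area for residue type(s): ",
         paste(unique(rt$resid[unknown]), collapse = ", "))
  rt$rel_exposure <- rt$area / .MAX_ASA[rt$resid]
  rownames(rt) <- NULL
  rt
}

#' Surface residues of a structure
#'
#' Residues with at least `exposure_threshold` of their maximal solvent
#' accessible area exposed (default 25%).
#'
#' @inheritParams compute_sasa
#' @param exposure_threshold Relative-exposure cutoff.
#' @return Residue table of surface residues (with `area`,
#'   `rel_exposure`).
#' @export
compute_surface <- function(structure, chains = NULL,
                            exposure_threshold = 0.25, probe = 1.4,
                            n_points = 960) {
  sasa <- compute_sasa(structure, chains = chains, probe = probe,
                       n_points = n_points)
  out <- sasa[sasa$rel_exposure >= exposure_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interface residues of a two-sided complex
#'
#' A residue of one interactor is at the interface iff any of its heavy
#' atoms lies within `cutoff` (inclusive) of any heavy atom of the other
#' interactor.
#'
#' @param complex A `dock_structure` holding both interactors.
#' @param side1,side2 Character vectors of chain ids designating the two
#'   interactors.
#' @param cutoff Heavy-atom distance cutoff in Angstrom.
#' @return List with residue tables `side1` and `side2`.
#' @export
compute_interface <- function(complex, side1, side2, cutoff = 6) {
  at <- complex$atoms
  a1 <- at[at$chain %in% side1, , drop = FALSE]
  a2 <- at[at$chain %in% side2, , drop = FALSE]
  if (!nrow(a1) || !nrow(a2)) stop("empty interactor in interface computation")
  x1 <- as.matrix(a1[, c("x", "y", "z")])
  x2 <- as.matrix(a2[, c("x", "y", "z")])
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  hit1 <- apply(d2 <= cutoff^2 + 1e-9, 1L, any)
  hit2 <- apply(d2 <= cutoff^2 + 1e-9, 2L, any)
  pick <- function(a, hit) {
    k <- paste(a$chain, a$resno, a$insert)
    contact <- unique(k[hit])
    rt <- a[!duplicated(k), c("chain", "resno", "insert", "resid")]
    out <- rt[paste(rt$chain, rt$resno, rt$insert) %in% contact, ,
              drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(side1 = pick(a1, hit1), side2 = pick(a2, hit2))
}

#' One-letter sequence of a structure chain
#' @param structure A `dock_structure`.
#' @param chain Chain id.
#' @return Character scalar (one-letter codes, `X` for unknowns).
#' @export
chain_sequence <- function(structure, chain) {
  rt <- residue_table(structure, chains = chain)
  paste(bio3d::aa321(rt$resid), collapse = "")
}

.aa_identity_matrix <- function() {
  letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V", "X")
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 2
  m["X", ] <- 0; m[, "X"] <- 0
  m
}

#' Map reference-sequence positions onto structure residue numbers
#'
#' Mined residue numbers follow the database (reference) sequence, which
#' often differs from the numbering of the deposited structure. A global
#' alignment of the reference sequence against the chain's sequence maps
#' every aligned position to the corresponding structure residue number;
#' positions aligned to gaps stay unmapped.
#'
#' @param reference_sequence One-letter reference sequence (character
#'   scalar).
#' @param structure A `dock_structure`.
#' @param chain Chain id to map onto.
#' @param min_identity Refuse to map when percent identity (over the
#'   shorter sequence) falls below this floor.
#' @return Data frame with columns `ref_pos`, `chain`, `resno`, `insert`.
#' @export
map_numbering <- function(reference_sequence, structure, chain,
                          min_identity = 90) {
  stopifnot(nzchar(reference_sequence))
  sseq <- chain_sequence(structure, chain)
  stopifnot(nzchar(sseq))
  pa <- Biostrings::pairwiseAlignment(
    reference_sequence, sseq, type = "global",
    substitutionMatrix = .aa_identity_matrix(),
    gapOpening = 4, gapExtension = 1)
  ident <- Biostrings::pid(pa, type = "PID3")
  if (ident < min_identity)
    stop(sprintf(paste0("refusing to map numbering: alignment identity ",
                        "%.1f%% below the %.0f%% floor"), ident, min_identity))
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  rt <- residue_table(structure, chains = chain)
  rp <- 0L; sp <- 0L
  rows <- vector("list", length(ap))
  for (k in seq_along(ap)) {
    if (ap[k] != "-") rp <- rp + 1L
    if (as_[k] != "-") sp <- sp + 1L
    if (ap[k] != "-" && as_[k] != "-")
      rows[[k]] <- data.frame(ref_pos = rp, chain = chain,
                              resno = rt$resno[sp], insert = rt$insert[sp],
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Match mined residue mentions to surface residues of a complex
#'
#' A mention survives iff both its residue name and its (optionally
#' remapped) number match a *surface* residue of the structure. With the
#' AND retrieval mode the check runs against both interactors; with the
#' OR mode only against the interactor the abstract mentions, to limit
#' accidental name/number coincidences. Mentions carrying a plain integer
#' match only residues with a blank insertion code. Surviving residues are
#' annotated with the interface truth and with per-retrieval-source
#' abstract counts, which feed the confidence ranking.
#'
#' @param mentions Mention table from [mine_corpus()] (columns `pmid`,
#'   `aa`, `number`, `from_and`).
#' @param complex A `dock_structure` of the bound complex.
#' @param sides List of two chain-id vectors designating the interactors.
#' @param mode `"and"` (check both interactors) or `"or"` (check only
#'   `mentioned_side`).
#' @param mentioned_side Integer 1 or 2: the interactor the abstracts
#'   mention (required in `"or"` mode).
#' @param surface Optional list of two precomputed surface residue tables
#'   (from [compute_surface()], one per interactor); computed on the
#'   isolated interactors when omitted.
#' @param interface Optional precomputed [compute_interface()] result.
#' @param mapping Optional list of two numbering maps (from
#'   [map_numbering()], per interactor; `NULL` entries mean raw structure
#'   numbering).
#' @return Data frame of identified residues: `side`, `chain`, `resno`,
#'   `insert`, `aa`, `is_interface`, `n_abstracts_and`,
#'   `n_abstracts_or_only`.
#' @export
identify_residues <- function(mentions, complex, sides,
                              mode = c("and", "or"), mentioned_side = NULL,
                              surface = NULL, interface = NULL,
                              mapping = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.list(sides), length(sides) == 2L)
  if (mode == "or" && is.null(mentioned_side))
    stop("OR mode requires `mentioned_side`")
  if (is.null(surface))
    surface <- lapply(sides, function(ch) compute_surface(complex, chains = ch))
  if (is.null(interface))
    interface <- compute_interface(complex, sides[[1L]], sides[[2L]])
  iface_keys <- c(.residue_key(interface$side1), .residue_key(interface$side2))
  check_sides <- if (mode == "and") 1:2 else as.integer(mentioned_side)
  hits <- list()
  for (s in check_sides) {
    surf <- surface[[s]]
    map <- if (!is.null(mapping)) mapping[[s]] else NULL
    for (i in seq_len(nrow(mentions))) {
      num <- mentions$number[i]
      ins <- ""
      if (!is.null(map)) {
        mrow <- map[map$ref_pos == num, , drop = FALSE]
        if (!nrow(mrow)) next
        num <- mrow$resno[1L]
        ins <- mrow$insert[1L]
      }
      m <- surf[surf$resno == num & surf$insert == ins &
                  surf$resid == mentions$aa[i], , drop = FALSE]
      if (!nrow(m)) next
      hits[[length(hits) + 1L]] <- data.frame(
        side = s, chain = m$chain[1L], resno = m$resno[1L],
        insert = m$insert[1L], aa = m$resid[1L],
        pmid = mentions$pmid[i], from_and = isTRUE(mentions$from_and[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(side = integer(), chain = character(),
                      resno = integer(), insert = character(),
                      aa = character(), is_interface = logical(),
                      n_abstracts_and = integer(),
                      n_abstracts_or_only = integer(),
                      stringsAsFactors = FALSE))
  h <- do.call(rbind, hits)
  h <- h[!duplicated(h[c("side", "chain", "resno", "insert", "pmid")]), ,
         drop = FALSE]
  key <- paste(h$side, h$chain, h$resno, h$insert, sep = "|")
  agg <- lapply(split(seq_len(nrow(h)), key), function(ix) {
    r <- h[ix[1L], ]
    data.frame(side = r$side, chain = r$chain, resno = r$resno,
               insert = r$insert, aa = r$aa,
               is_interface = paste(r$chain, r$resno, r$insert,
                                    sep = "|") %in% iface_keys,
               n_abstracts_and = sum(h$from_and[ix]),
               n_abstracts_or_only = sum(!h$from_and[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$side, out$chain, out$resno, out$insert), , drop = FALSE]
  rownames(out) <- NULL
  out
}
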