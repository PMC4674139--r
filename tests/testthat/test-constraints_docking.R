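test_that("residue confidence weights retrieval source and caps at 10", {
  expect_equal(residue_confidence(2, 1), 5)     # 2+2+1
  expect_equal(residue_confidence(12, 0), 10)   # capped
  expect_equal(residue_confidence(0, 1), 1)     # minimal case
  expect_equal(residue_confidence(5, 0), 10)
  expect_equal(residue_confidence(4, 1), 9)
  expect_error(residue_confidence(0, 0))
})

idres_row <- function(side, resno, n_and, n_or) {
  data.frame(side = side, chain = ifelse(side == 1, "A", "B"),
             resno = resno, insert = "", aa = "ALA",
             is_interface = TRUE, n_abstracts_and = n_and,
             n_abstracts_or_only = n_or, stringsAsFactors = FALSE)
}

test_that("constraint selection keeps top-k and prefers AND contributions among ties", {
  # scores 10,9,8,7,6,6,6 with differing AND counts among the 6-ties
  d <- rbind(idres_row(1, 1, 5, 0),   # 10
             idres_row(1, 2, 4, 1),   # 9
             idres_row(1, 3, 4, 0),   # 8
             idres_row(1, 4, 3, 1),   # 7
             idres_row(1, 5, 2, 2),   # 6, AND=2
             idres_row(1, 6, 1, 4),   # 6, AND=1
             idres_row(1, 7, 0, 6))   # 6, AND=0
  sel <- select_constraints(d, k = 5, seed = 1)
  expect_equal(nrow(sel), 5L)
  expect_equal(sel$confidence, c(10, 9, 8, 7, 6))
  expect_equal(sel$resno[5], 5)   # the AND-2 residue wins the cut

  # fewer residues than k: all kept
  few <- d[1:3, ]
  expect_equal(nrow(select_constraints(few, k = 5, seed = 1)), 3L)
})

test_that("fully symmetric ties break randomly but deterministically per seed", {
  d <- do.call(rbind, lapply(1:6, function(i) idres_row(1, i, 1, 1)))
  s1 <- select_constraints(d, k = 5, seed = 7)$resno
  s2 <- select_constraints(d, k = 5, seed = 7)$resno
  expect_identical(s1, s2)
  picks <- vapply(1:30, function(s)
    paste(sort(select_constraints(d, k = 5, seed = s)$resno),
          collapse = ","), "")
  expect_gt(length(unique(picks)), 1L)   # selection varies across seeds
})

test_that("selection is per interactor", {
  d <- rbind(do.call(rbind, lapply(1:7, function(i) idres_row(1, i, 2, 0))),
             do.call(rbind, lapply(1:7, function(i) idres_row(2, i, 2, 0))))
  sel <- select_constraints(d, k = 5, seed = 2)
  expect_equal(as.vector(table(sel$side)), c(5L, 5L))
})

test_that("reference constraints are the closest interface residue pairs", {
  fx <- generate_complex(n_receptor = 16, n_ligand = 12, patch_start = 4,
                         patch_length = 5, seed = 14)
  rc <- reference_constraints(fx$bound, "A", "B", n_pairs = 3)
  expect_equal(nrow(rc), 3L)
  expect_true(all(rc$confidence == 10))
  expect_true(all(diff(rc$ca_dist) >= 0))

  # all-pairs oracle over the interface CA distances
  ifc <- compute_interface(fx$bound, "A", "B")
  ca <- fx$bound$atoms[trimws(fx$bound$atoms$elety) == "CA", ]
  ca_xyz <- function(df) {
    m <- match(residue_keys(df), residue_keys(ca))
    as.matrix(ca[m, c("x", "y", "z")])
  }
  x1 <- ca_xyz(ifc$side1); x2 <- ca_xyz(ifc$side2)
  dmin <- Inf
  for (i in seq_len(nrow(x1))) for (j in seq_len(nrow(x2)))
    dmin <- min(dmin, sqrt(sum((x1[i, ] - x2[j, ])^2)))
  expect_equal(rc$ca_dist[1], dmin)

  # fewer interface pairs than requested: all returned with a warning
  expect_warning(rc2 <- reference_constraints(two_atom_complex(5), "A", "B",
                                              n_pairs = 3),
                 "pair")
  expect_equal(nrow(rc2), 1L)
})

test_that("tied reference distances keep a stable lexicographic order", {
  # two exactly mirrored contact pairs
  st <- structure_from_atoms(rbind(
    atoms_df("A", 1L, "ALA", "CA", 0, 0, 0),
    atoms_df("A", 2L, "ALA", "CA", 10, 0, 0),
    atoms_df("B", 1L, "GLY", "CA", 0, 5, 0),
    atoms_df("B", 2L, "GLY", "CA", 10, 5, 0)))
  rc <- reference_constraints(st, "A", "B", n_pairs = 2)
  expect_equal(rc$ca_dist, c(5, 5))
  expect_equal(rc$resno1, c(1L, 2L))   # sorted by (chain, residue number)
})

test_that("rescoring promotes the pose supported by true-interface constraints", {
  fx <- generate_complex(seed = 5)
  ifc <- fx$interface_truth
  idres <- rbind(
    do.call(rbind, lapply(seq_len(nrow(ifc$side1)), function(i)
      idres_row(1, ifc$side1$resno[i], 5, 0))),
    do.call(rbind, lapply(seq_len(nrow(ifc$side2)), function(i)
      idres_row(2, ifc$side2$resno[i], 5, 0))))
  cons <- select_constraints(idres, k = 5, seed = 1)
  rs <- rescore(fx$poses, cons, fx$receptor_unbound, fx$ligand_unbound)
  expect_equal(rs$match[1], fx$near_native_match)
  expect_gt(rs$tm_score[1], max(rs$tm_score[-1]))
  # only the order changes, never the multiset of matches
  expect_setequal(rs$match, fx$poses$match)
})

test_that("without constraints the scan order is preserved with zero scores", {
  fx <- generate_complex(n_decoys = 6, seed = 11)
  rs <- rescore(fx$poses, NULL, fx$receptor_unbound, fx$ligand_unbound)
  expect_identical(rs$match, fx$poses$match)
  expect_true(all(rs$tm_score == 0))
  # ties keep scan order (stable sort): constraints hitting nothing
  ghost <- idres_row(1, 999, 1, 0)
  rs2 <- rescore(fx$poses, select_constraints(ghost, seed = 1),
                 fx$receptor_unbound, fx$ligand_unbound)
  expect_identical(rs2$match, fx$poses$match)
})

test_that("raising a constraint's confidence never demotes a match containing it", {
  fx <- generate_complex(n_decoys = 10, seed = 23)
  ifc <- fx$interface_truth
  base <- rbind(idres_row(1, ifc$side1$resno[1], 1, 0),
                idres_row(2, ifc$side2$resno[1], 1, 0))
  rank_of <- function(cons) {
    rs <- rescore(fx$poses, cons, fx$receptor_unbound, fx$ligand_unbound)
    which(rs$match == fx$near_native_match)
  }
  r_lo <- rank_of(select_constraints(base, seed = 1))
  boosted <- base
  boosted$n_abstracts_and <- 5
  r_hi <- rank_of(select_constraints(boosted, seed = 1))
  expect_lte(r_hi, r_lo)
})

test_that("a malformed pose is an error naming the match", {
  fx <- generate_complex(n_decoys = 2, seed = 3)
  poses <- fx$poses
  poses$r11[2] <- NA
  cons <- select_constraints(idres_row(1, fx$interface_truth$side1$resno[1],
                                       1, 0), seed = 1)
  expect_error(rescore(poses, cons, fx$receptor_unbound, fx$ligand_unbound),
               "malformed pose")
})

test_that("i-RMSD is zero at the reference pose and tracks rigid translations", {
  fx <- generate_complex(perturb = FALSE, seed = 6)
  p0 <- identity_pose()
  r0 <- irmsd(p0, fx$bound, "A", "B", fx$ligand_unbound)
  expect_equal(as.numeric(r0), 0, tolerance = 1e-6)

  p3 <- identity_pose()
  p3$tx <- 3
  r3 <- irmsd(p3, fx$bound, "A", "B", fx$ligand_unbound)
  expect_equal(as.numeric(r3), 3, tolerance = 1e-6)
})

test_that("i-RMSD equals the direct coordinate-wise oracle on random poses", {
  fx <- generate_complex(perturb = FALSE, seed = 26)
  ifc_keys <- residue_keys(fx$interface_truth$side2)
  lig_ca <- fx$ligand_unbound$atoms[
    trimws(fx$ligand_unbound$atoms$elety) == "CA", ]
  sel <- residue_keys(lig_ca) %in% ifc_keys
  set.seed(77)
  for (i in 1:5) {
    ang <- runif(1, 0, 0.3)
    R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    pose <- identity_pose()
    pose[c("r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32",
           "r33")] <- as.numeric(t(R))
    pose[c("tx", "ty", "tz")] <- rnorm(3, sd = 4)
    got <- irmsd(pose, fx$bound, "A", "B", fx$ligand_unbound)
    posed <- apply_pose(fx$ligand_unbound, pose)
    posed_ca <- posed$atoms[trimws(posed$atoms$elety) == "CA", ]
    want <- oracle_rmsd(as.matrix(posed_ca[sel, c("x", "y", "z")]),
                        as.matrix(lig_ca[sel, c("x", "y", "z")]))
    expect_equal(as.numeric(got), want, tolerance = 1e-6)
  }
})

test_that("success criteria are inclusive and rate matches the planted fraction", {
  res <- rbind(
    data.frame(complex = "c1", rank = 10, irmsd = 4.9),   # strict success
    data.frame(complex = "c2", rank = 1, irmsd = 8.2),    # fails both
    data.frame(complex = "c3", rank = 100, irmsd = 8.0),  # relaxed only
    data.frame(complex = "c4", rank = 11, irmsd = 3.0))   # relaxed only
  expect_equal(success_rate(res, "strict"), 25)
  expect_equal(success_rate(res, "relaxed"), 75)

  # synthetic cohort with a planted success fraction
  set.seed(55)
  cohort <- do.call(rbind, lapply(1:40, function(i) {
    success <- i <= 16
    data.frame(complex = paste0("x", i), rank = 1:10,
               irmsd = if (success) c(runif(9, 10, 40), 4)
                       else runif(10, 10, 40))
  }))
  expect_equal(success_rate(cohort, "strict"), 40)
})

test_that("pose lists round-trip through the tabular format", {
  fx <- generate_complex(n_decoys = 3, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_poses(fx$poses, path)
  back <- read_poses(path)
  expect_equal(back, fx$poses, tolerance = 1e-9)
})
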