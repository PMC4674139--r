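test_that("an isolated tripeptide is entirely surface", {
  tri <- structure_from_atoms(rbind(
    atoms_df("A", 1L, "GLY", "CA", 0.0, 0, 0),
    atoms_df("A", 2L, "GLY", "CA", 3.8, 0, 0),
    atoms_df("A", 3L, "GLY", "CA", 7.6, 0, 0)))
  surf <- compute_surface(tri)
  expect_equal(nrow(surf), 3L)
  expect_true(all(surf$rel_exposure > 0.25))
})

test_that("a residue enclosed by a dense neighbor shell is buried", {
  # central CA surrounded by a shell of atoms on a sphere of radius 4 A
  n <- 200
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  shell <- atoms_df("A", rep(2L, n), "ALA", "C",
                    4 * sin(phi) * cos(th), 4 * sin(phi) * sin(th),
                    4 * cos(phi))
  center <- atoms_df("A", 1L, "GLY", "CA", 0, 0, 0)
  st <- structure_from_atoms(rbind(center, shell))
  sasa <- compute_sasa(st)
  expect_equal(sasa$area[sasa$resno == 1L], 0, tolerance = 1e-9)
  expect_false(1L %in% compute_surface(st)$resno)
})

test_that("spiral-lattice SASA agrees with an independent grid quadrature", {
  fx <- generate_complex(n_receptor = 25, n_ligand = 15, seed = 9)
  mine <- compute_sasa(fx$bound, chains = "A")
  orac <- oracle_sasa(fx$bound, chains = "A")
  rel_err <- abs(mine$area - orac$area) / pmax(orac$area, 1)
  expect_lt(max(rel_err), 0.05)   # per-residue areas within 5%
  # the surface set at the 25% threshold differs by at most 1 residue
  surf_mine <- residue_keys(mine[mine$rel_exposure >= 0.25, ])
  orac$rel <- orac$area / c(ALA = 129, ARG = 274, ASN = 195, ASP = 193,
                            CYS = 167, GLN = 225, GLU = 223, GLY = 104,
                            HIS = 224, ILE = 197, LEU = 201, LYS = 236,
                            MET = 224, PHE = 240, PRO = 159, SER = 155,
                            THR = 172, TRP = 285, TYR = 263,
                            VAL = 174)[orac$resid]
  surf_orac <- residue_keys(orac[orac$rel >= 0.25, ])
  expect_lte(length(union(setdiff(surf_mine, surf_orac),
                          setdiff(surf_orac, surf_mine))), 1L)
})

test_that("unknown residue types are an error naming the residue", {
  st <- structure_from_atoms(atoms_df("A", 1L, "XYZ", "CA", 0, 0, 0))
  expect_error(compute_sasa(st), "XYZ")
})

test_that("the interface cutoff is inclusive at 6 Angstrom", {
  near <- compute_interface(two_atom_complex(5.9), "A", "B")
  expect_equal(nrow(near$side1), 1L)
  expect_equal(nrow(near$side2), 1L)
  at <- compute_interface(two_atom_complex(6.0), "A", "B")
  expect_equal(nrow(at$side1), 1L)
  far <- compute_interface(two_atom_complex(6.1), "A", "B")
  expect_equal(nrow(far$side1), 0L)
  expect_equal(nrow(far$side2), 0L)
  expect_error(compute_interface(two_atom_complex(5), "A", "C"), "empty")
})

test_that("interface matches the all-pairs oracle and is symmetric", {
  fx <- generate_complex(n_receptor = 20, n_ligand = 14, patch_start = 3,
                         patch_length = 5, seed = 21)
  mine <- compute_interface(fx$bound, "A", "B")
  orac <- oracle_interface(fx$bound, "A", "B")
  expect_setequal(residue_keys(mine$side1), orac$side1)
  expect_setequal(residue_keys(mine$side2), orac$side2)
  swapped <- compute_interface(fx$bound, "B", "A")
  expect_identical(mine$side1, swapped$side2)
  expect_identical(mine$side2, swapped$side1)
  # the designed contact patch is exactly what is flagged
  expect_setequal(residue_keys(mine$side1),
                  residue_keys(fx$interface_truth$side1))
  expect_setequal(residue_keys(mine$side2),
                  residue_keys(fx$interface_truth$side2))
})

test_that("surface and interface sets are computed independently", {
  # a buried-by-construction residue can still be at the interface: the
  # two sets must not be coupled through shared state
  fx <- generate_complex(seed = 2)
  surf <- compute_surface(fx$bound, chains = "A")
  ifc <- compute_interface(fx$bound, "A", "B")
  expect_false(identical(residue_keys(surf), residue_keys(ifc$side1)))
})

test_that("numbering maps handle offsets, extensions and refuse unrelated sequences", {
  fx <- generate_complex(n_receptor = 20, n_ligand = 12, seed = 4)
  st <- fx$bound
  seqA <- chain_sequence(st, "A")

  # identical sequence, structure numbered from its own resno values
  mp <- map_numbering(seqA, st, "A")
  expect_equal(mp$ref_pos, 1:20)
  expect_equal(mp$resno, residue_table(st, "A")$resno)

  # a 5-residue N-terminal extension shifts the mapping
  ext <- paste0("MMMMM", seqA)
  mp2 <- map_numbering(ext, st, "A")
  expect_equal(mp2$resno[mp2$ref_pos == 6], residue_table(st, "A")$resno[1])
  expect_false(1 %in% mp2$ref_pos)

  # unrelated sequence refused
  expect_error(map_numbering(strrep("W", 20), st, "A"), "identity")
})

test_that("mention identification enforces surface, name and mode rules", {
  fx <- generate_complex(n_receptor = 15, n_ligand = 10, patch_start = 3,
                         patch_length = 4, seed = 12)
  rtA <- residue_table(fx$bound, "A")
  surf <- list(compute_surface(fx$bound, chains = "A"),
               compute_surface(fx$bound, chains = "B"))
  ifc <- compute_interface(fx$bound, "A", "B")

  target <- rtA[3, ]   # an interface residue of side 1
  mentions <- data.frame(pmid = "1", aa = target$resid,
                         number = target$resno, from_and = FALSE)
  idr <- identify_residues(mentions, fx$bound, list("A", "B"), mode = "or",
                           mentioned_side = 1, surface = surf,
                           interface = ifc)
  expect_equal(nrow(idr), 1L)
  expect_true(idr$is_interface)
  expect_equal(idr$n_abstracts_or_only, 1L)

  # name mismatch drops the mention
  wrong_aa <- setdiff(aa_three(), target$resid)[1L]
  m2 <- data.frame(pmid = "1", aa = wrong_aa, number = target$resno,
                   from_and = FALSE)
  expect_equal(nrow(identify_residues(m2, fx$bound, list("A", "B"),
                                      mode = "or", mentioned_side = 1,
                                      surface = surf, interface = ifc)), 0L)

  # buried residues never identify: restrict the surface set artificially
  surf_none <- list(surf[[1L]][0, ], surf[[2L]][0, ])
  expect_equal(nrow(identify_residues(mentions, fx$bound, list("A", "B"),
                                      mode = "or", mentioned_side = 1,
                                      surface = surf_none,
                                      interface = ifc)), 0L)

  # AND mode checks both interactors; OR mode only the mentioned one
  rtB <- residue_table(fx$bound, "B")
  bt <- rtB[5, ]
  m3 <- data.frame(pmid = "2", aa = bt$resid, number = bt$resno,
                   from_and = TRUE)
  both <- identify_residues(m3, fx$bound, list("A", "B"), mode = "and",
                            surface = surf, interface = ifc)
  expect_true(any(both$side == 2))
  or_side1 <- identify_residues(m3, fx$bound, list("A", "B"), mode = "or",
                                mentioned_side = 1, surface = surf,
                                interface = ifc)
  expect_true(all(or_side1$side == 1))
})

test_that("abstract counts aggregate by retrieval source over distinct abstracts", {
  fx <- generate_complex(n_receptor = 10, n_ligand = 8, patch_start = 2,
                         patch_length = 4, seed = 6)
  rtA <- residue_table(fx$bound, "A")
  t1 <- rtA[2, ]
  mentions <- data.frame(pmid = c("1", "2", "3", "3"),
                         aa = t1$resid, number = t1$resno,
                         from_and = c(TRUE, TRUE, FALSE, FALSE))
  idr <- identify_residues(mentions, fx$bound, list("A", "B"), mode = "or",
                           mentioned_side = 1)
  expect_equal(idr$n_abstracts_and, 2L)
  expect_equal(idr$n_abstracts_or_only, 1L)   # pmid 3 counted once
})

test_that("PDB files round-trip through the reader", {
  fx <- generate_complex(n_receptor = 8, n_ligand = 6, patch_start = 2,
                         patch_length = 3, seed = 8)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(fx$bound, path)
  st <- read_structure(path)
  expect_equal(nrow(st$atoms), nrow(fx$bound$atoms))
  expect_identical(residue_table(st), residue_table(fx$bound))
  expect_equal(st$atoms$x, fx$bound$atoms$x, tolerance = 1e-3)
})
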