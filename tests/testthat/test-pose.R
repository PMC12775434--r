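# Superposition, ligand RMSD, contacts, displacements, polar contacts.

rigid_move <- function(model, deg, axis, trans) {
  R <- screenfunnel:::rotation_matrix(axis, deg)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, -trans)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

test_that("superposition recovers rigid motions exactly", {
  tc <- make_toy_complex(n_pocket_atoms = 25, planted_contacts = 6,
                         seed = 31)
  sp0 <- superpose(tc$reference, tc$reference)
  expect_equal(sp0$ca_rmsd, 0, tolerance = 1e-9)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)

  moved <- rigid_move(tc$reference, 90, c(0, 0, 1), c(10, 0, 0))
  sp <- superpose(moved, tc$reference)
  expect_lt(sp$ca_rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-6)
  expect_equal(sp$n_pairs, 25)
  # the transform is applied to the ligand too
  expect_lt(ligand_rmsd(sp$model, tc$reference, symmetry_aware = FALSE),
            1e-9)
  expect_error(superpose(tc$reference, tc$reference, selection = 1:2),
               "at least 3")
})

test_that("pose metrics are invariant under a common rigid transform", {
  tc <- make_toy_complex(n_pocket_atoms = 25, planted_contacts = 6,
                         rotation_deg = 25, translation_ang = 1.5,
                         seed = 32)
  r0 <- ligand_rmsd(tc$perturbed, tc$reference, symmetry_aware = FALSE)
  lc0 <- contact_recovery(contact_set(tc$perturbed, 4),
                          contact_set(tc$reference, 4))
  ref2 <- rigid_move(tc$reference, 40, c(1, 1, 0), c(-3, 5, 2))
  per2 <- rigid_move(tc$perturbed, 40, c(1, 1, 0), c(-3, 5, 2))
  expect_equal(ligand_rmsd(per2, ref2, symmetry_aware = FALSE), r0,
               tolerance = 1e-9)
  expect_equal(contact_recovery(contact_set(per2, 4),
                                contact_set(ref2, 4)), lc0)
})

test_that("a pure translation gives exactly its RMSD", {
  tc <- make_toy_complex(translation_ang = 3.0, rotation_deg = 0,
                         seed = 33)
  expect_equal(ligand_rmsd(tc$perturbed, tc$reference,
                           symmetry_aware = FALSE), 3.0,
               tolerance = 1e-9)
  expect_equal(tc$truth$ligand_rmsd, 3.0, tolerance = 1e-9)
})

test_that("symmetry-aware RMSD equals the automorphism-enumeration oracle", {
  # para-disubstituted ring: hexagon of C with two O at opposite vertices
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  subst <- rbind(2.8 * c(cos(ang[1]), sin(ang[1]), 0),
                 2.8 * c(cos(ang[4]), sin(ang[4]), 0))
  B <- rbind(ring, subst)
  elements <- c(rep("C", 6), "O", "O")
  bonds <- rbind(cbind(1:6, c(2:6, 1)), c(1, 7), c(4, 8))
  # flip 180 degrees about the para axis, plus a small offset
  axis <- c(cos(ang[1]), sin(ang[1]), 0)
  R <- screenfunnel:::rotation_matrix(axis, 180)
  A <- B %*% t(R) + matrix(c(0.3, 0.1, -0.2), 8, 3, byrow = TRUE)
  dfA <- data.frame(element = elements, x = A[, 1], y = A[, 2], z = A[, 3])
  dfB <- data.frame(element = elements, x = B[, 1], y = B[, 2], z = B[, 3])
  naive <- ligand_rmsd(dfA, dfB, symmetry_aware = FALSE)
  sym <- ligand_rmsd(dfA, dfB, symmetry_aware = TRUE, bonds = bonds)
  expect_lt(sym, naive)
  expect_equal(sym, oracle_sym_rmsd(A, B, elements, bonds),
               tolerance = 1e-9)

  # asymmetric molecule: symmetry correction changes nothing
  set.seed(1)
  chain <- data.frame(element = c("C", "N", "O", "S"),
                      x = c(0, 1.4, 2.8, 4.2), y = 0, z = 0)
  chain2 <- chain; chain2$x <- chain2$x + 0.5
  cb <- cbind(1:3, 2:4)
  expect_equal(ligand_rmsd(chain2, chain, symmetry_aware = TRUE,
                           bonds = cb),
               ligand_rmsd(chain2, chain, symmetry_aware = FALSE))
})

test_that("contact sets honour the cutoff and match the all-pairs oracle", {
  # single receptor atom just inside / outside the 4 A shell
  mk <- function(d) {
    atoms <- data.frame(chain = "A", resno = c(1L, 900L),
                        resname = c("POC", "LIG"),
                        atom = c("CA", "C1"), element = "C",
                        x = c(d, 0), y = 0, z = 0,
                        ligand = c(FALSE, TRUE))
    structure_model(atoms)
  }
  expect_equal(nrow(contact_set(mk(3.9), 4.0)), 1)
  expect_equal(nrow(contact_set(mk(4.1), 4.0)), 0)

  for (seed in c(41, 42)) {
    tc <- make_toy_complex(n_pocket_atoms = 30, planted_contacts = 7,
                           seed = seed)
    cs <- contact_set(tc$reference, 4)
    expect_equal(nrow(cs), 7)
    expect_identical(sort(screenfunnel:::contact_keys(cs)),
                     oracle_contacts(tc$reference, 4))
  }
  expect_error(contact_set(structure_model(
    data.frame(chain = "A", resno = 1L, resname = "ALA", atom = "CA",
               element = "C", x = 0, y = 0, z = 0, ligand = FALSE)), 4),
    "no ligand")
})

test_that("contact recovery behaves as a percentage of reference contacts", {
  tc <- make_toy_complex(seed = 43)
  cs <- contact_set(tc$reference, 4)
  expect_equal(contact_recovery(cs, cs), 100)
  other <- cs; other$resno <- other$resno + 1000L
  expect_equal(contact_recovery(other, cs), 0)
  expect_error(contact_recovery(cs, cs[0, ]), "empty")
  # symmetric variant is a Jaccard percentage
  half <- cs[1:3, ]; attr(half, "cutoff") <- 4
  expect_equal(contact_recovery(half, cs, symmetric = TRUE),
               100 * 3 / nrow(cs))
})

test_that("residue displacements are zero for identical structures and
          exact for a planted shift", {
  tc <- make_toy_complex(n_pocket_atoms = 10, planted_contacts = 3,
                         seed = 44)
  ref <- tc$reference
  d0 <- residue_displacement(ref, ref, c("x1", "x5"))
  expect_equal(unname(d0), c(0, 0))
  moved <- ref
  i <- which(!moved$atoms$ligand & moved$atoms$resno == 5)
  moved$atoms$x[i] <- moved$atoms$x[i] + 2.0
  d <- residue_displacement(moved, ref, c("x1", "x5"))
  expect_equal(unname(d), c(0, 2.0))
  expect_error(residue_displacement(moved, ref, "9x99"), "not present")
})

test_that("planted polar contacts are found exactly", {
  # three N/O receptor atoms inside 3.5 A of ligand polar atoms, one
  # beyond the cutoff, plus apolar carbons nearby
  lig <- data.frame(chain = "A", resno = 900L, resname = "LIG",
                    atom = c("N1", "O1", "C1"),
                    element = c("N", "O", "C"),
                    x = c(0, 3, 6), y = 0, z = 0, ligand = TRUE)
  rec <- data.frame(chain = "A",
                    resno = c(10L, 11L, 12L, 13L, 14L),
                    resname = "ALA",
                    atom = c("OD1", "NE2", "OG", "OD2", "CB"),
                    element = c("O", "N", "O", "O", "C"),
                    x = c(0, 3, 3, 0, 0.5),
                    y = c(2.9, 3.1, -3.0, 5.0, 1.0),
                    z = 0, ligand = FALSE)
  model <- structure_model(rbind(rec, lig))
  pc <- polar_contacts(model, dist_cutoff = 3.5)
  expect_equal(nrow(pc), 3)
  expect_setequal(pc$rec_resno, c(10L, 11L, 12L))
  expect_true(all(pc$distance <= 3.5))

  # with an explicit donor hydrogen, the angle criterion applies
  recH <- rbind(rec[2, ], rec[2, ])
  recH$atom <- c("NE2", "HE2"); recH$element <- c("N", "H")
  recH$y <- c(3.1, 4.1)   # H pointing away from the acceptor
  model2 <- structure_model(rbind(recH, lig))
  pc2 <- polar_contacts(model2, dist_cutoff = 3.5, angle_min = 120)
  expect_equal(nrow(pc2), 0)   # D-H...A angle ~ 0 degrees
})
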