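# Geometric feature detection and rigid superposition.

test_that("PDB parsing captures residues, atoms and zinc", {
  toy <- paste(c(
    "ATOM      1  N   ALA A   1       0.000   0.800   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.200   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.400   0.800   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  m <- read_structure(toy)
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(unique(m$atoms$residx), 1L)
  expect_equal(nrow(m$hetero), 0L)

  with_zn <- paste(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2 ZN    ZN A 900       5.000   0.000   0.000  1.00  0.00          ZN",
    "END"), collapse = "\n")
  m2 <- read_structure(with_zn)
  expect_equal(sum(toupper(m2$hetero$resid) == "ZN"), 1L)

  expect_error(read_structure("HEADER only\nEND"), "ATOM")
})

test_that("alternate locations collapse to one atom, order-independently", {
  mk <- function(first, second) paste(c(first, second, "END"), collapse = "\n")
  lineA <- "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C"
  lineB <- "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C"
  m1 <- read_structure(mk(lineA, lineB))
  m2 <- read_structure(mk(lineB, lineA))
  expect_equal(nrow(m1$atoms), 1L)
  expect_equal(m1$atoms$x, 2)        # higher occupancy wins
  expect_equal(m1$atoms$x, m2$atoms$x)
})

test_that("zinc coordination spheres are summarised by element", {
  s3n1 <- gen_structure("zn_site", distance = 2.3,
                        ligands = c("SG", "SG", "SG", "ND1"), seed = 1)
  res <- detect_zn_site(read_structure(s3n1$pdb))
  expect_equal(res$summary, "S3N1")
  expect_equal(nrow(res$records), 4L)
  expect_equal(sort(res$records$distance), sort(s3n1$truth$distances),
               tolerance = 1e-9)

  s3o1 <- gen_structure("zn_site", distance = 2.2,
                        ligands = c("SG", "SG", "SG", "OH"), seed = 2)
  expect_equal(detect_zn_site(read_structure(s3o1$pdb))$summary, "S3O1")

  ## ligand just outside the cutoff: no ligands, empty summary
  far <- gen_structure("zn_site", distance = 3.5, seed = 3)
  resf <- detect_zn_site(read_structure(far$pdb))
  expect_equal(resf$summary, "")
  expect_equal(nrow(resf$records), 0L)

  ## no zinc at all: empty result, not an error
  none <- gen_structure("hbond", seed = 1)
  resn <- detect_zn_site(read_structure(none$pdb))
  expect_length(resn$summary, 0L)
})

test_that("hydrogen bonds respect distance, side-chain and range rules", {
  near <- gen_structure("hbond", distance = 2.9, sep = 10, seed = 1)
  hb <- detect_hbonds(read_structure(near$pdb))
  expect_equal(nrow(hb), 1L)
  expect_true(hb$long_range)
  expect_equal(hb$seq_separation, 10L)
  expect_equal(hb$distance, near$truth$distance, tolerance = 1e-9)

  ## short separation: detected but not long-range
  short <- gen_structure("hbond", distance = 2.9, sep = 2, seed = 1)
  hb2 <- detect_hbonds(read_structure(short$pdb))
  expect_equal(nrow(hb2), 1L)
  expect_false(hb2$long_range)

  ## separation exactly at the boundary (more than four residues apart)
  edge <- gen_structure("hbond", distance = 2.9, sep = 5, seed = 1)
  expect_true(detect_hbonds(read_structure(edge$pdb))$long_range)
  edge4 <- gen_structure("hbond", distance = 2.9, sep = 4, seed = 1)
  expect_false(detect_hbonds(read_structure(edge4$pdb))$long_range)

  ## beyond dmax: absent
  farhb <- gen_structure("hbond", distance = 3.6, sep = 10, seed = 1)
  expect_equal(nrow(detect_hbonds(read_structure(farhb$pdb))), 0L)
})

test_that("the Tyr-(i+4) backbone contact needs the right offset", {
  toy <- gen_structure("tyr_i4", distance = 2.9, seed = 1)
  rec <- detect_tyr_i4_hbond(read_structure(toy$pdb))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$resno_j - rec$resno_i, 4L)
  expect_equal(rec$distance, toy$truth$distance, tolerance = 1e-9)

  ## same geometry attached at i+3 must not fire
  m <- read_structure(toy$pdb)
  oh <- which(m$atoms$elety == "OH")
  n3 <- which(m$atoms$residx == m$atoms$residx[oh] + 3L & m$atoms$elety == "N")
  m$atoms[oh, c("x", "y", "z")] <-
    m$atoms[n3, c("x", "y", "z")] + c(0, 2.9, 0)
  expect_equal(nrow(detect_tyr_i4_hbond(m)), 0L)

  ## two qualifying tyrosines give two records (brute-force over all Tyr)
  m2 <- read_structure(toy$pdb)
  extra <- m2$atoms[m2$atoms$elety == "OH", ]
  donor2 <- 14L
  n2 <- which(m2$atoms$residx == donor2 + 4L & m2$atoms$elety == "N")
  extra$resno <- donor2; extra$residx <- donor2
  extra[, c("x", "y", "z")] <- m2$atoms[n2, c("x", "y", "z")] + c(0, 3.0, 0)
  m2$atoms$resid[m2$atoms$residx == donor2] <- "TYR"
  m2$atoms <- rbind(m2$atoms, extra)
  expect_equal(nrow(detect_tyr_i4_hbond(m2)), 2L)
})

test_that("cation-pi detection applies both distance and angle criteria", {
  hit <- gen_structure("cation_pi", distance = 4.2, angle = 10, seed = 1)
  rec <- detect_cation_pi(read_structure(hit$pdb))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$distance, hit$truth$distance, tolerance = 1e-6)
  expect_equal(rec$angle, hit$truth$angle, tolerance = 1e-6)

  ## edge-on arrangement rejected by the angle criterion
  edge <- gen_structure("cation_pi", distance = 4.2, angle = 80, seed = 1)
  expect_equal(nrow(detect_cation_pi(read_structure(edge$pdb))), 0L)

  ## beyond the distance cutoff
  far <- gen_structure("cation_pi", distance = 6.5, angle = 10, seed = 1)
  expect_equal(nrow(detect_cation_pi(read_structure(far$pdb))), 0L)

  ## arginine-phenylalanine pairs count too
  m <- read_structure(hit$pdb)
  m$atoms$resid[m$atoms$resid == "TYR"] <- "PHE"
  rec2 <- detect_cation_pi(m)
  expect_equal(nrow(rec2), 1L)
  expect_equal(rec2$resid_j, "PHE")

  ## missing ring atoms: pair skipped with a warning
  m3 <- read_structure(hit$pdb)
  m3$atoms <- m3$atoms[m3$atoms$elety != "CZ" | m3$atoms$resid != "TYR", ]
  expect_warning(detect_cation_pi(m3), "missing ring atoms")
})

test_that("detectors match brute-force all-pairs enumeration on toy models", {
  for (seed in 1:3) {
    for (feature in c("hbond", "tyr_i4", "zn_site", "cation_pi")) {
      toy <- gen_structure(feature, seed = seed, chain_length = 20L)
      m <- read_structure(toy$pdb)

      hb <- detect_hbonds(m)
      ohb <- oracle_hbonds(m)
      expect_equal(nrow(hb), nrow(ohb))
      if (nrow(hb))
        expect_equal(unname(sort(hb$distance)), unname(sort(ohb[, "d"])),
                     tolerance = 1e-9)

      ty <- detect_tyr_i4_hbond(m)
      oty <- oracle_tyr_i4(m)
      expect_equal(nrow(ty), nrow(oty))

      zn <- detect_zn_site(m)
      ozn <- oracle_zn(m)
      expect_equal(length(zn$summary), length(ozn))
      if (length(ozn))
        expect_equal(nrow(zn$records), sum(lengths(ozn)))

      cp <- detect_cation_pi(m)
      ocp <- oracle_cation_pi(m)
      expect_equal(nrow(cp), nrow(ocp))
      if (nrow(cp))
        expect_equal(unname(sort(cp$distance)), unname(sort(ocp[, "d"])),
                     tolerance = 1e-9)
    }
  }
})

test_that("detector outputs are invariant under rigid transforms", {
  set.seed(101)
  toys <- lapply(c("zn_site", "hbond", "tyr_i4", "cation_pi"),
                 function(f) read_structure(gen_structure(f, seed = 4)$pdb))
  for (rep in 1:25) {
    rigid <- random_rigid()
    for (m in toys) {
      mt <- transform_model(m, rigid)
      expect_equal(detect_hbonds(mt)$distance, detect_hbonds(m)$distance,
                   tolerance = 1e-6)
      expect_equal(detect_tyr_i4_hbond(mt)$distance,
                   detect_tyr_i4_hbond(m)$distance, tolerance = 1e-6)
      expect_equal(detect_zn_site(mt)$summary, detect_zn_site(m)$summary)
      cpt <- detect_cation_pi(mt); cp <- detect_cation_pi(m)
      expect_equal(cpt$distance, cp$distance, tolerance = 1e-6)
      expect_equal(cpt$angle, cp$angle, tolerance = 1e-6)
    }
  }
})

test_that("superposition recovers rigid transforms and the identity", {
  set.seed(7)
  a <- matrix(rnorm(36), ncol = 3)
  s0 <- superpose(a, a)
  expect_lt(s0$rmsd, 1e-9)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(s0$translation, rep(0, 3), tolerance = 1e-9)

  rigid <- random_rigid()
  b <- a %*% rigid$R + matrix(rigid$t, nrow(a), 3, byrow = TRUE)
  s1 <- superpose(a, b)
  expect_lt(s1$rmsd, 1e-6)
  expect_equal(det(s1$rotation), 1, tolerance = 1e-9)

  ## symmetry of the minimised RMSD
  b2 <- a + matrix(rnorm(36, sd = 0.3), ncol = 3)
  expect_equal(superpose(a, b2)$rmsd, superpose(b2, a)$rmsd, tolerance = 1e-9)

  expect_error(superpose(a[1:2, ], a[1:2, ]), "3 matched points")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("superposition RMSD matches a numeric-minimisation oracle", {
  set.seed(11)
  a <- matrix(rnorm(30), ncol = 3)
  ## single atom displaced 1 A along x
  b <- a; b[4, 1] <- b[4, 1] + 1
  s <- superpose(a, b)
  expect_lt(s$rmsd, sqrt(1 / 10) + 1e-9)   # refit can only improve
  expect_equal(s$rmsd, oracle_superpose_rmsd(a, b), tolerance = 1e-6)

  b3 <- a + matrix(rnorm(30, sd = 0.2), ncol = 3)
  expect_equal(superpose(a, b3)$rmsd, oracle_superpose_rmsd(a, b3),
               tolerance = 1e-6)
})

test_that("the combined feature wrapper stacks detector output", {
  toy <- gen_structure("cation_pi", seed = 9)
  m <- read_structure(toy$pdb)
  feats <- detect_features(m, features = c("cation_pi", "tyr_i4"))
  expect_true(all(feats$kind %in% c("cation_pi", "tyr_i4_hbond")))
  expect_equal(sum(feats$kind == "cation_pi"), 1L)
})
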