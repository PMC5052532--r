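test_that("a planted arginine salt bridge yields the full record set", {
  tc <- make_toy_complex("charged", seed = 1)
  rec <- detect_interactions(tc$structure, tc$ligand, tc$panel)
  kinds <- sort(unique(rec$kind))
  expect_setequal(kinds, c("contact", "sidechain", "polar", "hbond_donor",
                           "charged"))
  expect_true(all(rec$resname == "ARG"))
  expect_equal(min(rec$distance), 2.9, tolerance = 1e-6)
})

test_that("a ligand far from the site produces no records", {
  tc <- make_toy_complex("charged", seed = 1)
  lig <- tc$ligand
  lig$x <- lig$x + 15
  rec <- detect_interactions(tc$structure, lig, tc$panel)
  expect_equal(nrow(rec), 0)
})

test_that("every planted class is recovered exactly across seeds", {
  for (sd in c(1, 7, 23)) {
    tc <- make_toy_complex(SIFT_KINDS, seed = sd)
    rec <- detect_interactions(tc$structure, tc$ligand, tc$panel)
    got <- record_set(rec)
    exp <- record_set(tc$records)
    expect_identical(got, exp, label = paste("seed", sd))
  }
})

test_that("heavy-atom H-bond test honours distance and proxy angle", {
  d <- c(0, 0, 0)
  n <- c(-1.4, 0, 0)
  ok <- detect_hbond(d, c(2.8 * cos(30 * pi / 180), 2.8 * sin(30 * pi / 180), 0),
                     n)                    # 2.8 A, angle 150 deg
  expect_true(ok$hbond)
  expect_equal(ok$distance, 2.8, tolerance = 1e-6)
  expect_equal(ok$angle, 150, tolerance = 1e-6)
  expect_false(detect_hbond(d, c(3.6, 0, 0), n)$hbond)     # too long
  # acceptor tucked toward the antecedent: angle 60 deg fails
  bad <- detect_hbond(d, c(-1.4, 2.8 * sin(60 * pi / 180), 0), n)
  expect_false(bad$hbond)
  expect_equal(bad$angle, 60, tolerance = 1e-6)
})

test_that("aromatic detection requires planarity and centroid proximity", {
  r1 <- benzene_xyz(0)
  expect_true(detect_aromatic(r1, benzene_xyz(3.8))$aromatic)
  expect_false(detect_aromatic(r1, benzene_xyz(7.0))$aromatic)
  bent <- benzene_xyz(3.8)
  bent[1, 3] <- bent[1, 3] + 1          # one atom 1 A out of plane
  hit <- detect_aromatic(r1, bent)
  expect_false(hit$planar)
  expect_false(hit$aromatic)
  # least-squares plane-fit oracle: rms of the bent ring must exceed the
  # planarity tolerance (displacement split between the plane and atom)
  ctr <- colMeans(bent)
  sv <- svd(sweep(bent, 2, ctr))
  rms <- sqrt(mean((sweep(bent, 2, ctr) %*% sv$v[, 3])^2))
  expect_gt(rms, 0.15)
})

test_that("ring perception finds benzene and fused naphthalene cycles", {
  bz <- as_atoms(benzene_xyz())
  rings <- perceive_ligand_rings(bz)
  expect_length(rings, 1)
  expect_length(rings[[1]]$atoms, 6)
  expect_true(rings[[1]]$planar)

  # naphthalene: two fused hexagons sharing the (0, +-0.699) edge
  pts <- cbind(c(0, 0, 1.211, 1.211, 2.422, 2.422,
                 -1.211, -1.211, -2.422, -2.422),
               c(0.699, -0.699, 1.399, -1.399, 0.699, -0.699,
                 1.399, -1.399, 0.699, -0.699), 0)
  expect_equal(nrow(pts), 10)
  naph <- as_atoms(pts)
  rings <- perceive_ligand_rings(naph)
  expect_length(rings, 2)
  expect_true(all(vapply(rings, function(r) length(r$atoms) == 6,
                         logical(1))))
  expect_true(all(vapply(rings, `[[`, logical(1), "planar")))
  expect_length(intersect(rings[[1]]$atoms, rings[[2]]$atoms), 2)

  # collinear atoms carry no rings
  line <- as_atoms(cbind(c(0, 1.4, 2.8), 0, 0))
  expect_length(perceive_ligand_rings(line), 0)
})

test_that("contact dominates and contacts partition into backbone/sidechain", {
  for (sd in 1:5) {
    tc <- make_toy_complex(SIFT_KINDS, seed = sd)
    rec <- detect_interactions(tc$structure, tc$ligand, tc$panel)
    for (k in unique(paste(rec$chain, rec$seqnum))) {
      kinds <- rec$kind[paste(rec$chain, rec$seqnum) == k]
      expect_true("contact" %in% kinds)
      expect_true(any(c("backbone", "sidechain") %in% kinds))
    }
  }
})

test_that("shrinking thresholds never adds records", {
  tc <- make_toy_complex(SIFT_KINDS, seed = 9)
  wide <- default_interaction_params()
  narrow <- wide
  for (p in c("contact", "polar", "hbond_dist", "aromatic_centroid",
              "hydrophobic", "charged"))
    narrow[[p]] <- wide[[p]] - 0.8
  r_wide <- record_set(detect_interactions(tc$structure, tc$ligand,
                                           tc$panel, wide))
  r_narrow <- record_set(detect_interactions(tc$structure, tc$ligand,
                                             tc$panel, narrow))
  expect_true(all(r_narrow %in% r_wide))
})

test_that("records are invariant under rigid motion of the complex", {
  tc <- make_toy_complex(SIFT_KINDS, seed = 4)
  rec0 <- detect_interactions(tc$structure, tc$ligand, tc$panel)
  moved <- rigid_copy(tc$structure, tc$ligand, seed = 99)
  rec1 <- detect_interactions(moved$structure, moved$ligand, tc$panel)
  expect_identical(record_set(rec0), record_set(rec1))
  o0 <- rec0[order(rec0$seqnum, rec0$kind), ]
  o1 <- rec1[order(rec1$seqnum, rec1$kind), ]
  expect_equal(o0$distance, o1$distance, tolerance = 1e-6)
})

test_that("interaction records export to TSV with the complex id", {
  tc <- make_toy_complex("charged", seed = 12)
  rec <- detect_interactions(tc$structure, tc$ligand, tc$panel)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_records(rec, f, format = "tsv", complex_id = "cx1")
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(rec))
  expect_true(all(back$complex_id == "cx1"))
  expect_setequal(back$kind, rec$kind)
})

test_that("ligand atom perception types carboxylates and amines", {
  tc <- make_toy_complex(c("hbond_donor", "hbond_acceptor"), seed = 6)
  rec <- detect_interactions(tc$structure, tc$ligand, tc$panel)
  # residue 1 (SER) donates to the carboxylate; residue 2 (ASN) accepts
  # from the cationic amine - no charged bit on either (no charged group
  # on SER/ASN)
  expect_true("hbond_donor" %in% rec$kind[rec$seqnum == 1])
  expect_true("hbond_acceptor" %in% rec$kind[rec$seqnum == 2])
  expect_false("charged" %in% rec$kind)
})
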