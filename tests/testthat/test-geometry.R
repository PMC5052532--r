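test_that("minimum distance equals the brute-force all-pairs result", {
  a1 <- as_atoms(matrix(c(1, 2, 3), 1))
  expect_equal(min_distance(a1, a1)$distance, 0)
  set.seed(12)
  for (i in 1:5) {
    a <- as_atoms(matrix(rnorm(30, sd = 8), 10))
    b <- as_atoms(matrix(rnorm(21, sd = 8), 7))
    brute <- min(sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
                        outer(a$z, b$z, "-")^2))
    expect_equal(min_distance(a, b)$distance, brute)
  }
  expect_error(min_distance(a1[0, ], a1), "empty")
})

test_that("torsions follow the sign convention and rigid invariance", {
  # planar cis arrangement -> 0, anti -> 180
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  set.seed(21)
  for (i in 1:10) {
    p <- matrix(rnorm(12, sd = 4), 4, 3)
    ref <- tryCatch(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                    error = function(e) NA)
    if (is.na(ref)) next
    # independent oracle
    expect_equal(ref, bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4),
                 tolerance = 1e-6, ignore_attr = TRUE)
    # random rigid motion preserves the value
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    tr <- rnorm(3, sd = 10)
    p2 <- sweep(p %*% t(q), 2, tr, "+")
    expect_equal(dihedral(p2[1, ], p2[2, ], p2[3, ], p2[4, ]), ref,
                 tolerance = 1e-6)
    # mirror reflection flips the sign
    p3 <- p %*% diag(c(1, 1, -1))
    expect_equal(dihedral(p3[1, ], p3[2, ], p3[3, ], p3[4, ]), -ref,
                 tolerance = 1e-6)
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("chi1 is binned into rotamer states with field aliases", {
  ext <- chi1(build_residue("SER", chi1 = 180))
  expect_equal(ext$chi1, 180, tolerance = 1e-6)
  expect_equal(ext$bin, "trans")
  expect_equal(ext$label, "extended")
  folded <- chi1(build_residue("PHE", chi1 = -67))
  expect_equal(folded$chi1, -67, tolerance = 1e-6)
  expect_equal(folded$bin, "gauche_minus")
  expect_equal(folded$label, "folded_g_star")
  expect_error(chi1(build_residue("GLY")), "no chi1")
  # binning is total and exhaustive over (-180, 180]
  for (ang in seq(-175, 180, by = 20)) {
    rc <- chi1(build_residue("LEU", chi1 = ang))
    want <- if (ang >= -120 && ang < 0) "gauche_minus"
            else if (ang > 0 && ang <= 120) "gauche_plus" else "trans"
    expect_equal(rc$bin, want, label = paste("chi1 =", ang))
  }
})

test_that("the H-bond table reports planted bonds and water bridges", {
  tc <- make_toy_complex("hbond_donor", seed = 3)
  tab <- hbond_table(tc$structure, tc$ligand)
  expect_equal(nrow(tab[tab$type == "direct", ]), 1)
  expect_equal(tab$distance[1], 2.9)
  expect_equal(tab$direction[1], "residue_donates")

  # planted ligand--water 2.7 A and water--backbone O 2.8 A bridge
  ss <- make_synthetic_reference_sites()
  tab2 <- hbond_table(ss$gamma$structure, ss$gamma$ligand)
  br <- tab2[tab2$type == "water_bridge", ]
  expect_gte(nrow(br), 1)
  expect_true(any(br$distance == 2.7 & br$bridge_distance == 2.8 &
                    grepl("A:228", br$partner)))

  # apolar ligand: empty table
  cage <- build_residue("ALA")
  s <- structure(list(id = "a", atoms = cage), class = "sift_structure")
  expect_equal(nrow(hbond_table(s, as_atoms(benzene_xyz(3)))), 0)
})

test_that("clash scans use Bondi radii and match brute force", {
  cpair <- as_atoms(matrix(c(0, 0, 0), 1))                      # C
  opair <- as_atoms(matrix(c(2.2, 0, 0), 1), element = "O")     # O
  hit <- clash_scan(cpair, opair, tolerance = 0.4)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$vdw_sum, 3.22)
  expect_equal(hit$overlap, 3.22 - 2.2 - 0.4)
  far <- as_atoms(matrix(c(3.5, 0, 0), 1), element = "O")
  expect_equal(nrow(clash_scan(cpair, far, tolerance = 0.4)), 0)
  # brute-force parity on random selections
  set.seed(5)
  a <- as_atoms(matrix(rnorm(30, sd = 3), 10))
  b <- as_atoms(matrix(rnorm(30, sd = 3), 10), element = "O")
  res <- clash_scan(a, b, tolerance = 0.4)
  d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
              outer(a$z, b$z, "-")^2)
  expect_equal(nrow(res), sum(d < 1.70 + 1.52 - 0.4))
  expect_error(clash_scan(as_atoms(matrix(0, 1, 3), element = "Xx"), b),
               "Xx")
})

test_that("flood-fill volume recovers an analytic sphere", {
  sh <- make_cavity_structure(4)
  cv <- cavity_volume(sh, c(0, 0, 0), spacing = 0.4)
  expect_false(cv$open)
  expect_equal(cv$volume, 4 / 3 * pi * 4^3, tolerance = 0.10)
  expect_equal(cv$volume, cv$voxels * 0.4^3)
  # grid convergence: halving the spacing moves the estimate < 5%
  cv2 <- cavity_volume(sh, c(0, 0, 0), spacing = 0.8)
  expect_lt(abs(cv2$volume - cv$volume) / cv$volume, 0.05)
  # monotone non-increasing in probe radius
  cv3 <- cavity_volume(sh, c(0, 0, 0), spacing = 0.4, probe = 1.8)
  expect_lte(cv3$volume, cv$volume)
  # seed inside the blocked shell
  expect_error(cavity_volume(sh, c(0, 0, 7.2), spacing = 0.4),
               "seed point lies inside")
})

test_that("an open pocket is flagged and capped", {
  sh <- make_cavity_structure(4, hole_radius = 5)
  expect_warning(cv <- cavity_volume(sh, c(0, 0, 0), spacing = 0.5),
                 "open pocket")
  expect_true(cv$open)
  expect_gt(cv$volume, 0)
})

test_that("geometric measurements are rigid-motion invariant", {
  ss <- make_synthetic_reference_sites()
  a <- ss$alpha
  moved <- rigid_copy(a$structure, a$ligand, seed = 77)
  v0 <- validate_reference_geometry(a$structure, a$ligand,
                                    chi1_residue = c("A", 273),
                                    hbond_partners = c("A:464", "A:280"))
  v1 <- validate_reference_geometry(moved$structure, moved$ligand,
                                    chi1_residue = c("A", 273),
                                    hbond_partners = c("A:464", "A:280"))
  expect_equal(v0$value, v1$value, tolerance = 1e-6)
})
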