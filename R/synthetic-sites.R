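# SYNTHETIC stand-in binding sites.
#
# These miniature sites emulate the literature-reported binding-site
# geometry of a naphthalene-carboxylate PPAR pan-agonist bound to the
# PPARalpha and PPARgamma ligand-binding domains: the planted distances
# and the gate-keeper chi1 below are the reported values, but the
# coordinates are built from ideal-geometry templates, NOT taken from any
# deposited crystal structure.  They exercise the full measurement
# pipeline (parse -> H-bond table -> chi1 -> clash scan -> min distance)
# end to end; they do not validate the deposited coordinates themselves.

# align a residue so that atom `dname` sits at `point + d*u` with its
# antecedent `aname` placed anti (behind it, away from `point`)
.place_residue_at <- function(res, dname, aname, point, u, d) {
  rx <- .xyz(res)
  D <- rx[match(dname, res$name), ]
  A <- rx[match(aname, res$name), ]
  v <- (A - D); v <- v / .vnorm(v)   # bond direction A<-D mapped onto u
  u <- u / .vnorm(u)
  w <- .cross3(v, u); s <- .vnorm(w); cc <- sum(v * u)
  rot <- if (s < 1e-9) {
    if (cc > 0) diag(3) else diag(c(-1, 1, -1))
  } else {
    wx <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
    diag(3) + wx + wx %*% wx * ((1 - cc) / s^2)
  }
  rx2 <- .apply_rigid(sweep(rx, 2, D), rot)          # D at origin, v -> u
  rx2 <- sweep(rx2, 2, point + d * u, "+")
  res$x <- rx2[, 1]; res$y <- rx2[, 2]; res$z <- rx2[, 3]
  res
}

# small carboxylate ligand with an alpha carbon and two methyls
.standin_ligand <- function(serial0 = 1000L) {
  th <- 63 * pi / 180
  pos <- rbind(C1 = c(0, 0, 0),
               O1 = 1.25 * c(cos(th), sin(th), 0),
               O2 = 1.25 * c(cos(th), -sin(th), 0),
               C2 = c(-1.52, 0, 0),
               CM1 = c(-2.03, 1.25, 0.6),
               CM2 = c(-2.03, -1.25, 0.6))
  data.frame(serial = serial0 + seq_len(nrow(pos)),
             name = rownames(pos), altloc = "", resname = "LIG",
             chain = "L", seqnum = 900L, icode = "",
             x = pos[, 1], y = pos[, 2], z = pos[, 3], occupancy = 1,
             element = substr(rownames(pos), 1, 1), record = "hetero",
             stringsAsFactors = FALSE)
}

.assemble_site <- function(id, residues, ligand, waters = NULL) {
  prot <- do.call(rbind, residues)
  atoms <- rbind(prot, ligand, waters)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "sift_structure")
}

#' Synthetic stand-in binding sites with literature-style geometry
#'
#' Builds two miniature synthetic complexes around a carboxylate ligand,
#' emulating the reported binding-site geometry of a pan-agonist in the
#' PPARalpha and PPARgamma ligand-binding domains (field residue
#' numbering is used for recognisability):
#'
#' * `alpha`: gate-keeper PHE 273 planted at chi1 = -67 deg (the folded
#'   g* open-gate rotamer); carboxylate H-bonds TYR 464 (2.7 A),
#'   TYR 314 (2.7 A), HIS 440 (2.8 A), SER 280 OG (2.5 A); an
#'   ALA 454 / VAL 270 methyl-methyl contact at 3.4 A.
#' * `gamma`: carboxylate salt bridge to ARG 288 (2.7 and 2.9 A to the
#'   two guanidinium nitrogens); SER 342 placed out of H-bond range
#'   (the "lost" backbone-amide H-bond); a methyl clashing with
#'   SER 289 OG at 2.2 A; an ALA 292 methyl contact at 3.8 A; one
#'   water bridging the carboxylate (2.7 A) to a backbone carbonyl
#'   (2.8 A).
#'
#' These are synthetic constructions from ideal-geometry templates - a
#' stand-in for deposited coordinates, suitable for exercising the
#' measurement pipeline, not for validating crystal structures.
#'
#' @return List with elements `alpha` and `gamma`, each a list holding
#'   `structure`, `ligand` and `planted` (data frame of the planted
#'   measure/target/value triples).
#' @export
make_synthetic_reference_sites <- function() {
  lig <- .standin_ligand()
  O1 <- as.numeric(lig[lig$name == "O1", c("x", "y", "z")])
  O2 <- as.numeric(lig[lig$name == "O2", c("x", "y", "z")])
  CM1 <- as.numeric(lig[lig$name == "CM1", c("x", "y", "z")])
  CM2 <- as.numeric(lig[lig$name == "CM2", c("x", "y", "z")])

  ## ---- alpha-like site ----
  y464 <- .place_residue_at(build_residue("TYR", chain = "A", seqnum = 464),
                            "OH", "CZ", O1, c(1, 0.3, 0), 2.7)
  h440 <- .place_residue_at(build_residue("HIS", chain = "A", seqnum = 440),
                            "NE2", "CD2", O1, c(-0.2, 0.6, 1), 2.8)
  y314 <- .place_residue_at(build_residue("TYR", chain = "A", seqnum = 314),
                            "OH", "CZ", O2, c(1, -0.3, -0.4), 2.7)
  s280 <- .place_residue_at(build_residue("SER", chain = "A", seqnum = 280),
                            "OG", "CB", O2, c(-0.2, -0.8, 0.6), 2.5)
  f273 <- build_residue("PHE", chi1 = -67, chain = "A", seqnum = 273)
  f273[, c("x", "y", "z")] <- sweep(.xyz(f273), 2, c(0, 0, 14), "+")
  # loop 11-12 emulation: ALA methyl meets a VAL methyl at 3.4 A
  v270 <- build_residue("VAL", chain = "A", seqnum = 270)
  v270[, c("x", "y", "z")] <- sweep(.xyz(v270), 2, c(18, 0, 0), "+")
  vx <- .xyz(v270)
  cg1 <- vx[match("CG1", v270$name), ]
  uo <- cg1 - vx[match("CB", v270$name), ]
  a454 <- .place_residue_at(build_residue("ALA", chain = "A", seqnum = 454),
                            "CB", "CA", cg1, uo, 3.4)
  alpha_s <- .assemble_site("synthetic_alpha_site",
                            list(v270, f273, s280, y314, h440, a454, y464),
                            lig)
  alpha_planted <- data.frame(
    measure = c("chi1_deg", rep("hbond_dist_A", 4), "min_dist_A"),
    target = c("PHE A:273", "A:464", "A:314", "A:440", "A:280",
               "A:454~A:270"),
    value = c(-67, 2.7, 2.7, 2.8, 2.5, 3.4), stringsAsFactors = FALSE)

  ## ---- gamma-like site ----
  r288 <- build_residue("ARG", chain = "A", seqnum = 288)
  # carboxylate O1 placed in the guanidinium plane at 2.7 / 2.9 A from
  # NH1 / NH2: solve the two-circle intersection in that plane, on the
  # side away from CZ, then move the whole ligand so O1 lands there
  rx <- .xyz(r288)
  nh1 <- rx[match("NH1", r288$name), ]
  nh2 <- rx[match("NH2", r288$name), ]
  cz <- rx[match("CZ", r288$name), ]
  e1 <- (nh2 - nh1) / .vnorm(nh2 - nh1)
  zax <- .cross3(e1, cz - nh1); zax <- zax / .vnorm(zax)
  e2 <- .cross3(zax, e1)                       # in-plane, perpendicular
  if (sum(e2 * (cz - nh1)) > 0) e2 <- -e2      # point away from CZ
  dd <- .vnorm(nh2 - nh1)
  px <- (2.7^2 - 2.9^2 + dd^2) / (2 * dd)
  py <- sqrt(2.7^2 - px^2)
  o1_target <- nh1 + px * e1 + py * e2
  # rebuild the ligand analytically around o1_target so that O1 is the
  # only atom near the guanidinium: the carboxylate plane is spanned by
  # the outward direction e_out and the plane normal zax
  e_out <- (o1_target - cz); e_out <- e_out / .vnorm(e_out)
  d1 <- -e_out                               # C1 -> O1 points inward
  dc <- as.numeric(cos(117 * pi / 180) * d1 + sin(117 * pi / 180) * zax)
  d2 <- as.numeric(cos(126 * pi / 180) * d1 - sin(126 * pi / 180) * zax)
  C1g <- o1_target - 1.25 * d1
  C2g <- C1g + 1.52 * dc
  O2g_ <- C1g + 1.25 * d2
  u1 <- dc + 1.2 * e1; u1 <- u1 / .vnorm(u1)
  u2 <- dc - 1.2 * e1; u2 <- u2 / .vnorm(u2)
  CM1g_ <- C2g + 1.5 * u1
  CM2g_ <- C2g + 1.5 * u2
  lig_g <- lig
  lx <- rbind(C1g, o1_target, O2g_, C2g, CM1g_, CM2g_)
  lig_g[, c("x", "y", "z")] <- lx
  O1g <- as.numeric(lig_g[lig_g$name == "O1", c("x", "y", "z")])
  O2g <- as.numeric(lig_g[lig_g$name == "O2", c("x", "y", "z")])
  CM1g <- as.numeric(lig_g[lig_g$name == "CM1", c("x", "y", "z")])
  CM2g <- as.numeric(lig_g[lig_g$name == "CM2", c("x", "y", "z")])

  # SER 342 backbone amide out of range (the lost beta-sheet H-bond)
  s342 <- .place_residue_at(build_residue("SER", chain = "A", seqnum = 342),
                            "N", "CA", O2g_, d2 + 0.5 * e1, 5.5)
  # SER 289 hydroxyl clashing with a ligand methyl at 2.2 A
  s289 <- .place_residue_at(build_residue("SER", chain = "A", seqnum = 289),
                            "OG", "CB", CM2g_, u2, 2.2)
  # ALA 292 methyl contact with the other methyl at 3.8 A
  a292 <- .place_residue_at(build_residue("ALA", chain = "A", seqnum = 292),
                            "CB", "CA", CM1g_, u1, 3.8)
  # water bridging carboxylate O2 (2.7 A) to a backbone carbonyl (2.8 A)
  wdir <- d2 - 0.8 * e1; wdir <- wdir / .vnorm(wdir)
  wat_xyz <- O2g_ + 2.7 * wdir
  l228 <- .place_residue_at(build_residue("LEU", chain = "A", seqnum = 228),
                            "O", "C", wat_xyz, wdir, 2.8)
  wat <- data.frame(serial = 2000L, name = "O", altloc = "",
                    resname = "HOH", chain = "W", seqnum = 501L, icode = "",
                    x = wat_xyz[1], y = wat_xyz[2], z = wat_xyz[3],
                    occupancy = 1, element = "O", record = "water",
                    stringsAsFactors = FALSE)
  gamma_s <- .assemble_site("synthetic_gamma_site",
                            list(l228, r288, s289, a292, s342), lig_g, wat)
  gamma_planted <- data.frame(
    measure = c("hbond_dist_A", "clash_dist_A", "min_dist_A",
                "water_bridge_A"),
    target = c("A:288", "A:289", "A:292~ligand", "A:228"),
    value = c(2.7, 2.2, 3.8, 2.7), stringsAsFactors = FALSE)

  list(alpha = list(structure = alpha_s, ligand = lig,
                    planted = alpha_planted),
       gamma = list(structure = gamma_s, ligand = lig_g,
                    planted = gamma_planted))
}
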