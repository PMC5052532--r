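# Synthetic-fixture generators: miniature complexes with planted
# interactions of each fingerprint class at prescribed geometry,
# bit-string families with planted cluster structure, and closed
# pseudo-atom shells for cavity-volume validation.
#
# Scaffold residues are ideal-geometry amino acids built from an internal
# Z-matrix template library with rigid placement only (no minimization),
# so every planted distance and angle is analytically controlled and the
# records a correct detector must emit are known by construction.

# -- NeRF atom placement ------------------------------------------------

# position d with |d-c| = bond, angle(b,c,d) = ang (deg) and
# dihedral(a,b,c,d) = tors (deg)
.place_atom <- function(a, b, c, bond, ang, tors) {
  ar <- ang * pi / 180
  tr <- tors * pi / 180
  d2 <- c(-bond * cos(ar), bond * cos(tr) * sin(ar), bond * sin(tr) * sin(ar))
  bc <- (c - b); bc <- bc / .vnorm(bc)
  ab <- (b - a); ab <- ab / .vnorm(ab)
  n <- .cross3(ab, bc); n <- n / .vnorm(n)
  m <- .cross3(n, bc)
  c + cbind(bc, m, n) %*% d2
}

# Z-matrix side-chain templates: each row places `atom` from three
# already-placed reference atoms.  "CHI1" in the torsion column is
# replaced by the requested chi1; "CHI1+120"/"CHI1-120" likewise.
.SIDECHAIN_ZMAT <- list(
  GLY = NULL,
  ALA = list(c("CB", "C", "N", "CA", "1.53", "110.5", "-122")),
  SER = list(c("CB", "C", "N", "CA", "1.53", "110.5", "-122"),
             c("OG", "N", "CA", "CB", "1.41", "110.5", "CHI1")),
  CYS = list(c("CB", "C", "N", "CA", "1.53", "110.5", "-122"),
             c("SG", "N", "CA", "CB", "1.81", "114.0", "CHI1")),
  VAL = list(c("CB", "C", "N", "CA", "1.54", "111.5", "-122"),
             c("CG1", "N", "CA", "CB", "1.53", "110.5", "CHI1"),
             c("CG2", "N", "CA", "CB", "1.53", "110.5", "CHI1+120")),
  THR = list(c("CB", "C", "N", "CA", "1.54", "111.5", "-122"),
             c("OG1", "N", "CA", "CB", "1.41", "109.5", "CHI1"),
             c("CG2", "N", "CA", "CB", "1.53", "110.5", "CHI1+120")),
  LEU = list(c("CB", "C", "N", "CA", "1.53", "110.5", "-122"),
             c("CG", "N", "CA", "CB", "1.53", "116.0", "CHI1"),
             c("CD1", "CA", "CB", "CG", "1.53", "110.5", "180"),
             c("CD2", "CA", "CB", "CG", "1.53", "110.5", "60")),
  ILE = list(c("CB", "C", "N", "CA", "1.54", "111.5", "-122"),
             c("CG1", "N", "CA", "CB", "1.53", "110.5", "CHI1"),
             c("CG2", "N", "CA", "CB", "1.53", "110.5", "CHI1-120"),
             c("CD1", "CA", "CB", "CG1", "1.53", "113.8", "180")),
  MET = list(c("CB", "C", "N", "CA", "1.53", "110.5", "-122"),
             c("CG", "N", "CA", "CB", "1.53", "114.0", "CHI1"),
             c("SD", "CA", "CB", "CG", "1.80", "112.7", "180"),
             c("CE", "CB", "CG", "SD", "1.79", "100.9", "180")),
  ASN = list(c("CB", "C", "N", "CA", "1.53", "110.5", "-122"),
             c("CG", "N", "CA", "CB", "1.52", "112.6", "CHI1"),
             c("OD1", "CA", "CB", "CG", "1.23", "120.8", "-60"),
             c("ND2", "CA", "CB", "CG", "1.33", "116.4", "120")),
  ASP = list(c("CB", "C", "N", "CA", "1.53", "110.5", "-122"),
             c("CG", "N", "CA", "CB", "1.52", "112.6", "CHI1"),
             c("OD1", "CA", "CB", "CG", "1.25", "118.4", "-60"),
             c("OD2", "CA", "CB", "CG", "1.25", "118.4", "120")),
  GLN = list(c("CB", "C", "N", "CA", "1.53", "110.5", "-122"),
             c("CG", "N", "CA", "CB", "1.53", "114.0", "CHI1"),
             c("CD", "CA", "CB", "CG", "1.52", "112.6", "180"),
             c("OE1", "CB", "CG", "CD", "1.23", "120.8", "-60"),
             c("NE2", "CB", "CG", "CD", "1.33", "116.4", "120")),
  GLU = list(c("CB", "C", "N", "CA", "1.53", "110.5", "-122"),
             c("CG", "N", "CA", "CB", "1.53", "114.0", "CHI1"),
             c("CD", "CA", "CB", "CG", "1.52", "112.6", "180"),
             c("OE1", "CB", "CG", "CD", "1.25", "118.4", "-60"),
             c("OE2", "CB", "CG", "CD", "1.25", "118.4", "120")),
  LYS = list(c("CB", "C", "N", "CA", "1.53", "110.5", "-122"),
             c("CG", "N", "CA", "CB", "1.53", "114.0", "CHI1"),
             c("CD", "CA", "CB", "CG", "1.52", "111.3", "180"),
             c("CE", "CB", "CG", "CD", "1.52", "111.3", "180"),
             c("NZ", "CG", "CD", "CE", "1.49", "112.0", "180")),
  ARG = list(c("CB", "C", "N", "CA", "1.53", "110.5", "-122"),
             c("CG", "N", "CA", "CB", "1.53", "114.0", "CHI1"),
             c("CD", "CA", "CB", "CG", "1.52", "111.3", "180"),
             c("NE", "CB", "CG", "CD", "1.46", "112.0", "180"),
             c("CZ", "CG", "CD", "NE", "1.33", "124.2", "180"),
             c("NH1", "CD", "NE", "CZ", "1.33", "120.0", "0"),
             c("NH2", "CD", "NE", "CZ", "1.33", "120.0", "180")),
  HIS = list(c("CB", "C", "N", "CA", "1.53", "110.5", "-122"),
             c("CG", "N", "CA", "CB", "1.50", "113.8", "CHI1"),
             c("ND1", "CA", "CB", "CG", "1.38", "122.7", "90"),
             c("CD2", "CA", "CB", "CG", "1.36", "131.2", "-90"),
             c("CE1", "CB", "CG", "ND1", "1.32", "109.3", "180"),
             c("NE2", "CB", "CG", "CD2", "1.37", "107.2", "180")),
  PHE = list(c("CB", "C", "N", "CA", "1.53", "110.5", "-122"),
             c("CG", "N", "CA", "CB", "1.50", "113.8", "CHI1"),
             c("CD1", "CA", "CB", "CG", "1.39", "120.7", "90"),
             c("CD2", "CA", "CB", "CG", "1.39", "120.7", "-90"),
             c("CE1", "CB", "CG", "CD1", "1.39", "120.0", "180"),
             c("CE2", "CB", "CG", "CD2", "1.39", "120.0", "180"),
             c("CZ", "CG", "CD1", "CE1", "1.39", "120.0", "0")),
  TYR = list(c("CB", "C", "N", "CA", "1.53", "110.5", "-122"),
             c("CG", "N", "CA", "CB", "1.50", "113.8", "CHI1"),
             c("CD1", "CA", "CB", "CG", "1.39", "120.7", "90"),
             c("CD2", "CA", "CB", "CG", "1.39", "120.7", "-90"),
             c("CE1", "CB", "CG", "CD1", "1.39", "120.0", "180"),
             c("CE2", "CB", "CG", "CD2", "1.39", "120.0", "180"),
             c("CZ", "CG", "CD1", "CE1", "1.39", "120.0", "0"),
             c("OH", "CD1", "CE1", "CZ", "1.38", "120.0", "180"))
)

#' Build an ideal-geometry residue template
#'
#' Backbone N/CA/C/O plus the side chain from the internal Z-matrix
#' library, with the chi1 torsion set as requested.  Coordinates are in a
#' local frame (N at the origin).
#'
#' @param restype Three-letter residue type (template library covers the
#'   standard amino acids except PRO and TRP).
#' @param chi1 First side-chain torsion in degrees (ignored for GLY/ALA).
#' @param chain,seqnum Identifiers stamped on the atoms.
#' @return Atom data frame as in a `sift_structure` (record "polymer").
#' @export
build_residue <- function(restype, chi1 = -60, chain = "A", seqnum = 1) {
  if (!restype %in% c("GLY", names(.SIDECHAIN_ZMAT)))
    stop("no template for residue type ", restype)
  pos <- list(
    N = c(0, 0, 0),
    CA = c(1.46, 0, 0),
    C = .place_atom(c(1.46, 1, 0), c(0, 0, 0), c(1.46, 0, 0), 1.52, 111, 180)
  )
  pos$O <- .place_atom(pos$N, pos$CA, pos$C, 1.23, 120.5, -45)
  zmat <- .SIDECHAIN_ZMAT[[restype]]
  for (row in zmat) {
    tors <- switch(row[7],
                   "CHI1" = chi1,
                   "CHI1+120" = chi1 + 120,
                   "CHI1-120" = chi1 - 120,
                   as.numeric(row[7]))
    pos[[row[1]]] <- .place_atom(pos[[row[2]]], pos[[row[3]]], pos[[row[4]]],
                                 as.numeric(row[5]), as.numeric(row[6]), tors)
  }
  nm <- names(pos)
  xyz <- do.call(rbind, lapply(pos, as.numeric))
  data.frame(serial = seq_along(nm), name = nm, altloc = "",
             resname = restype, chain = chain, seqnum = seqnum, icode = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
             element = substr(nm, 1, 1), record = "polymer",
             stringsAsFactors = FALSE)
}

# -- planted interactions ----------------------------------------------

# Per-class plant templates: scaffold residue, target atom, anchor atom
# defining the approach direction, ligand motif, and the hand-derived
# expected interaction classes as a function of the planted distance
# (default thresholds).  Distances within 0.15 A of a decision boundary
# are rejected so the expected set is unambiguous.
.PLANT_TEMPLATES <- list(
  contact = list(restype = "ALA", target = "CB", anchor = "CA",
                 motif = "N", default_d = 4.0,
                 expected = function(d) if (d <= 4.5)
                   c("contact", "sidechain") else character()),
  backbone = list(restype = "GLY", target = "O", anchor = "C",
                  motif = "N", default_d = 4.0,
                  expected = function(d) if (d <= 4.5)
                    c("contact", "backbone") else character()),
  sidechain = list(restype = "LEU", target = "CD1", anchor = "CG",
                   motif = "C", default_d = 4.0,
                   expected = function(d) if (d <= 4.5)
                     c("contact", "sidechain", "hydrophobic") else character()),
  polar = list(restype = "SER", target = "OG", anchor = "CB",
               motif = "O", default_d = 3.2,
               expected = function(d) {
                 if (d <= 3.5) c("contact", "sidechain", "polar",
                                 "hbond_donor", "hbond_acceptor")
                 else if (d <= 4.5) c("contact", "sidechain")
                 else character()
               }),
  aromatic = list(restype = "PHE", target = "ring", anchor = "ring",
                  motif = "benzene", default_d = 4.2,
                  expected = function(d) {
                    if (d <= 4.4) c("contact", "sidechain", "aromatic",
                                    "hydrophobic")
                    else if (d <= 5.4) c("contact", "sidechain", "aromatic")
                    else character()
                  }),
  hydrophobic = list(restype = "VAL", target = "CG1", anchor = "CB",
                     motif = "C", default_d = 4.2,
                     expected = function(d) if (d <= 4.5)
                       c("contact", "sidechain", "hydrophobic")
                     else character()),
  hbond_donor = list(restype = "SER", target = "OG", anchor = "CB",
                     motif = "carboxylate", default_d = 2.9,
                     expected = function(d) if (d <= 3.5)
                       c("contact", "sidechain", "polar", "hbond_donor")
                     else character()),
  hbond_acceptor = list(restype = "ASN", target = "OD1", anchor = "CG",
                        motif = "N", default_d = 2.9,
                        expected = function(d) if (d <= 3.5)
                          c("contact", "sidechain", "polar", "hbond_acceptor")
                        else character()),
  charged = list(restype = "ARG", target = "NH1", anchor = "CZ",
                 motif = "carboxylate", default_d = 2.9,
                 expected = function(d) {
                   if (d <= 3.5) c("contact", "sidechain", "polar",
                                   "hbond_donor", "charged")
                   else if (d <= 4.0) c("contact", "sidechain", "charged")
                   else character()
                 })
)

# decision boundaries (default thresholds) per class template
.PLANT_BOUNDARIES <- list(
  contact = 4.5, backbone = 4.5, sidechain = 4.5, polar = c(3.5, 4.5),
  aromatic = c(4.4, 5.4), hydrophobic = 4.5, hbond_donor = 3.5,
  hbond_acceptor = 3.5, charged = c(3.5, 4.0)
)

#' Specify one planted interaction
#'
#' @param kind One of the nine fingerprint classes.
#' @param distance Planted geometry parameter in A: closest target-pair
#'   distance (ring centroid separation for `aromatic`).  Defaults to a
#'   mid-range detecting value for the class.
#' @param expect_detect When `TRUE` (default) the distance must lie
#'   inside the class's detection range; a contradictory request (e.g. an
#'   H-bond planted at 6 A) is a spec error.  When `FALSE` the site is
#'   planted beyond every threshold.
#' @return A `planted_interaction` spec.
#' @export
planted_interaction <- function(kind, distance = NULL, expect_detect = TRUE) {
  tpl <- .PLANT_TEMPLATES[[kind]]
  if (is.null(tpl)) stop("unknown interaction class: ", kind)
  if (is.null(distance))
    distance <- if (expect_detect) tpl$default_d else 9.0
  if (any(abs(distance - .PLANT_BOUNDARIES[[kind]]) < 0.15))
    stop("planted distance ", distance,
         " is within 0.15 A of a decision boundary for class ", kind)
  expected <- tpl$expected(distance)
  if (expect_detect && !kind %in% expected)
    stop("unsatisfiable spec: class ", kind, " cannot be detected at ",
         distance, " A")
  if (!expect_detect && length(expected))
    stop("spec error: expect_detect is FALSE but class ", kind,
         " geometry at ", distance, " A is still detectable")
  structure(list(kind = kind, restype = tpl$restype, distance = distance,
                 expect_detect = expect_detect, expected = expected),
            class = "planted_interaction")
}

# regular hexagon of carbons (bond 1.39) in the yz-plane, centred at 0
.benzene_local <- function() {
  th <- (0:5) * pi / 3
  cbind(0, 1.39 * cos(th), 1.39 * sin(th))
}

# ligand motif atoms in the site frame: target atom sits at the origin,
# the approach direction is +x, and the motif is planted at (d, 0, 0)
.motif_atoms <- function(motif, d) {
  switch(motif,
         N = cbind(el = "N", x = d, y = 0, z = 0),
         C = cbind(el = "C", x = d, y = 0, z = 0),
         O = cbind(el = "O", x = d, y = 0, z = 0),
         carboxylate = {
           # O1 at the plant point, C beyond it, O2 splayed at 126 deg
           o1 <- c(d, 0, 0)
           cc <- c(d + 1.25, 0, 0)
           w <- c(cos(54 * pi / 180), sin(54 * pi / 180), 0)
           o2 <- cc + 1.25 * w
           rbind(c("O", o1), c("C", cc), c("O", o2))
         },
         benzene = {
           ring <- .benzene_local()
           ring[, 1] <- d
           cbind("C", ring)
         },
         stop("unknown ligand motif ", motif))
}

#' Generate a miniature complex with planted interactions
#'
#' One ideal-geometry scaffold residue per spec is placed around a small
#' ligand so that each planted interaction is realized at its prescribed
#' distance, on sites separated by 30 A to rule out cross-talk.  Each
#' site receives a seeded random rigid rotation, which preserves every
#' planted geometry.  The records a correct detector must produce (at the
#' residue x class granularity) are returned alongside.
#'
#' @param specs List of [planted_interaction()] specs (or a character
#'   vector of class names, expanded with default geometry).
#' @param seed Integer seed for the per-site rigid orientations.
#' @return List with `structure` (a `sift_structure`), `pdb` (PDB text),
#'   `ligand` (ligand atom data frame), `panel` (scaffold panel, one
#'   residue per spec) and `records` (expected data frame with columns
#'   chain, seqnum, icode, resname, kind).
#' @export
make_toy_complex <- function(specs, seed = 1) {
  if (is.character(specs)) specs <- lapply(specs, planted_interaction)
  for (sp in specs) stopifnot(inherits(sp, "planted_interaction"))
  set.seed(seed)

  prot <- list(); lig <- list(); truth <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    tpl <- .PLANT_TEMPLATES[[sp$kind]]
    res <- build_residue(tpl$restype, chi1 = -60, chain = "A", seqnum = i)
    rx <- .xyz(res)
    if (tpl$target == "ring") {
      ring <- chem_tables()$aromatic_rings[[tpl$restype]][[1]]
      pl <- .fit_plane(rx[match(ring, res$name), , drop = FALSE])
      target <- pl$centroid
      u <- pl$normal
      # point the normal away from CA so the ligand sits over the ring face
      ca <- rx[match("CA", res$name), ]
      if (sum(u * (target - ca)) < 0) u <- -u
    } else {
      target <- rx[match(tpl$target, res$name), ]
      anchor <- rx[match(tpl$anchor, res$name), ]
      u <- (target - anchor); u <- u / .vnorm(u)
    }
    # move target to origin and align the approach direction with +x
    ex <- c(1, 0, 0)
    v <- .cross3(u, ex); s <- .vnorm(v); cc <- sum(u * ex)
    rot <- if (s < 1e-9) {
      if (cc > 0) diag(3) else diag(c(1, -1, -1))
    } else {
      vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
      diag(3) + vx + vx %*% vx * ((1 - cc) / s^2)
    }
    rx2 <- .apply_rigid(sweep(rx, 2, target), rot)
    mot <- .motif_atoms(tpl$motif, sp$distance)
    mx <- matrix(as.numeric(mot[, 2:4, drop = FALSE]), ncol = 3)

    # seeded random rigid re-orientation of the whole site, then shift
    # to the site centre
    qrot <- .random_rotation()
    ctr <- c(30 * (i - 1), 0, 0)
    rx3 <- .apply_rigid(rx2, qrot, ctr)
    mx3 <- .apply_rigid(mx, qrot, ctr)

    res$x <- rx3[, 1]; res$y <- rx3[, 2]; res$z <- rx3[, 3]
    prot[[i]] <- res
    lig[[i]] <- data.frame(el = as.character(mot[, 1]),
                           x = mx3[, 1], y = mx3[, 2], z = mx3[, 3],
                           stringsAsFactors = FALSE)
    if (length(sp$expected))
      truth[[length(truth) + 1]] <- data.frame(
        chain = "A", seqnum = i, icode = "", resname = tpl$restype,
        kind = sp$expected, stringsAsFactors = FALSE)
  }

  ligdf <- do.call(rbind, lig)
  if (is.null(ligdf)) {               # empty spec list: ligand-only file
    bz <- .benzene_local()
    ligdf <- data.frame(el = "C", x = bz[, 1], y = bz[, 2], z = bz[, 3],
                        stringsAsFactors = FALSE)
  }
  nprot <- sum(vapply(prot, nrow, integer(1)))
  lig_atoms <- if (is.null(ligdf)) NULL else data.frame(
    serial = nprot + seq_len(nrow(ligdf)),
    name = paste0(ligdf$el, seq_len(nrow(ligdf))), altloc = "",
    resname = "LIG", chain = "L", seqnum = 900L, icode = "",
    x = ligdf$x, y = ligdf$y, z = ligdf$z, occupancy = 1,
    element = ligdf$el, record = "hetero", stringsAsFactors = FALSE)
  protdf <- do.call(rbind, prot)
  if (!is.null(protdf)) protdf$serial <- seq_len(nrow(protdf))
  atoms <- rbind(protdf, lig_atoms)
  if (is.null(atoms) || nrow(atoms) == 0)
    stop("empty spec list and no ligand: nothing to emit")
  s <- structure(list(id = sprintf("toy_seed%d", seed), atoms = atoms),
                 class = "sift_structure")

  panel <- if (is.null(protdf)) NULL else {
    p <- unique(data.frame(chain = protdf$chain, seqnum = protdf$seqnum,
                           icode = protdf$icode, resname = protdf$resname,
                           stringsAsFactors = FALSE))
    p <- p[order(p$chain, p$seqnum), , drop = FALSE]
    rownames(p) <- NULL
    attr(p, "provenance") <- "toy-complex scaffold residues"
    class(p) <- c("sift_panel", "data.frame")
    p
  }
  records <- if (length(truth)) do.call(rbind, truth) else
    .empty_records()[, c("chain", "seqnum", "icode", "resname", "kind")]
  list(structure = s, pdb = write_structure(s), ligand = lig_atoms,
       panel = panel, records = records)
}

# -- planted bit strings -----------------------------------------------

#' Generate bit-string families with planted cluster structure
#'
#' Per cluster, one random prototype is drawn at the given density over
#' the 8 non-contact bits of each 9-bit block (the contact bit is then
#' derived as the OR of its block, so every generated string satisfies
#' the hierarchy invariant); members are the prototype with independent
#' bit flips at the given probability, contact re-derived.
#'
#' @param n_clusters Number of planted clusters (default 3).
#' @param members Strings per cluster (default 10).
#' @param length Bit-string length, a multiple of 9 (default 225,
#'   i.e. a 25-residue panel).
#' @param density Prototype bit density in (0, 1) (default 0.3).
#' @param flip_prob Per-bit flip probability in \[0, 0.5) (default 0.05).
#' @param seed Mandatory integer seed.
#' @return List with `fps` (list of `sift_fp` over a synthetic panel),
#'   `labels` (named integer vector of planted cluster labels) and
#'   `panel`.
#' @export
make_planted_bitstrings <- function(n_clusters = 3, members = 10,
                                    length = 225, density = 0.3,
                                    flip_prob = 0.05, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length %% 9 == 0, flip_prob >= 0, flip_prob < 0.5,
            density > 0, density < 1)
  set.seed(seed)
  blocks <- length %/% 9
  panel <- data.frame(chain = "A", seqnum = seq_len(blocks), icode = "",
                      resname = "ALA", stringsAsFactors = FALSE)
  class(panel) <- c("sift_panel", "data.frame")

  with_contact <- function(sub) {          # sub: 8 bits x blocks matrix
    full <- matrix(0L, nrow = 9, ncol = blocks)
    full[2:9, ] <- sub
    full[1, ] <- as.integer(colSums(sub) > 0)
    as.integer(full)
  }
  fps <- list(); labels <- integer()
  for (k in seq_len(n_clusters)) {
    proto <- matrix(stats::rbinom(8 * blocks, 1, density), nrow = 8)
    for (j in seq_len(members)) {
      flips <- matrix(stats::rbinom(8 * blocks, 1, flip_prob), nrow = 8)
      bits <- with_contact(xor(proto, flips) * 1L)
      id <- sprintf("c%d_m%02d", k, j)
      fps[[id]] <- structure(list(complex_id = id, panel = panel,
                                  bits = bits), class = "sift_fp")
      labels[id] <- k
    }
  }
  list(fps = unname(fps), labels = labels, panel = panel)
}

# -- cavity shell -------------------------------------------------------

# near-uniform points on a unit sphere (Fibonacci lattice)
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build a closed pseudo-atom shell enclosing a spherical cavity
#'
#' Carbon pseudo-atoms are packed on concentric spherical shells whose
#' inner probe-expanded surface sits at `radius` from the origin, densely
#' enough that a flood fill at the matching probe radius cannot leak.
#' Optionally a cylindrical hole is carved along +z to create a
#' deliberately open pocket.
#'
#' @param radius Cavity radius in A (> 0; must exceed the probe radius
#'   for the cavity to be fillable).
#' @param thickness Shell thickness in A (default 2).
#' @param probe Probe radius the shell is tuned for (default 1.4).
#' @param atom_spacing Approximate pseudo-atom spacing on each shell
#'   layer in A (default 0.8).
#' @param hole_radius Optional radius (A) of a cylindrical hole along +z.
#' @return A `sift_structure` of resname SHL pseudo-atoms.
#' @export
make_cavity_structure <- function(radius, thickness = 2, probe = 1.4,
                                  atom_spacing = 0.8, hole_radius = NULL) {
  if (radius <= 0) stop("radius must be positive")
  r0 <- radius + vdw_radius("C") + probe
  layer_r <- seq(r0, r0 + thickness, by = min(1, thickness))
  pts <- do.call(rbind, lapply(layer_r, function(rr) {
    n <- max(50L, as.integer(ceiling(4 * pi * rr^2 / atom_spacing^2)))
    .fib_sphere(n) * rr
  }))
  if (!is.null(hole_radius))
    pts <- pts[!(sqrt(pts[, 1]^2 + pts[, 2]^2) < hole_radius &
                   pts[, 3] > 0), , drop = FALSE]
  atoms <- data.frame(
    serial = seq_len(nrow(pts)), name = "C", altloc = "", resname = "SHL",
    chain = "A", seqnum = 1L, icode = "", x = pts[, 1], y = pts[, 2],
    z = pts[, 3], occupancy = 1, element = "C", record = "polymer",
    stringsAsFactors = FALSE)
  structure(list(id = sprintf("shell_r%.1f", radius), atoms = atoms),
            class = "sift_structure")
}
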