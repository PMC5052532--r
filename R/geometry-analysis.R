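# Quantitative binding-site geometry: named-pair minimum distances,
# H-bond network tables with water bridges, chi1 rotamer calling for
# gate-keeper side chains, van der Waals clash scans and grid flood-fill
# cavity volumes.

#' Minimum heavy-atom distance between two selections
#'
#' @param sel_a,sel_b Non-empty atom data frames (or n x 3 matrices).
#' @return List with `distance` (A), `atom_a`, `atom_b` (names when
#'   available, otherwise row indices).
#' @export
min_distance <- function(sel_a, sel_b) {
  nm <- function(s, i) if (is.data.frame(s) && "name" %in% names(s))
    s$name[i] else i
  xa <- if (is.data.frame(sel_a)) .xyz(sel_a) else
    matrix(as.numeric(sel_a), ncol = 3)
  xb <- if (is.data.frame(sel_b)) .xyz(sel_b) else
    matrix(as.numeric(sel_b), ncol = 3)
  if (nrow(xa) == 0 || nrow(xb) == 0) stop("empty atom selection")
  d <- .pair_dists(xa, xb)
  ix <- which(d == min(d), arr.ind = TRUE)[1, ]
  list(distance = min(d), atom_a = nm(sel_a, ix[1]), atom_b = nm(sel_b, ix[2]))
}

#' chi1 rotamer call for one residue
#'
#' chi1 is the N-CA-CB-gamma torsion (gamma atom per residue type: CG,
#' CG1, OG, OG1, SG, ...).  Bins: gauche- for chi1 in \[-120, 0), gauche+
#' for (0, 120\], trans otherwise.  Field aliases: "folded g*" = gauche-,
#' "extended" = trans - the open- vs closed-gate states of a gate-keeper
#' phenylalanine.
#'
#' @param residue Atom data frame of one residue (e.g. from
#'   [residue_atoms()]).
#' @return A `sift_rotamer`: list with `residue` (resname + key), `chi1`
#'   (degrees), `bin` and `label`.
#' @export
chi1 <- function(residue) {
  stopifnot(nrow(residue) > 0)
  rn <- residue$resname[1]
  gamma <- chem_tables()$gamma_atoms[[rn]]
  if (is.null(gamma))
    stop("no chi1 for residue type ", rn, " (no gamma atom)")
  need <- c("N", "CA", "CB", gamma)
  ix <- match(need, residue$name)
  if (anyNA(ix))
    stop("no chi1: residue ", rn, " ",
         .res_key(residue$chain[1], residue$seqnum[1], residue$icode[1]),
         " is missing atom(s) ", paste(need[is.na(ix)], collapse = ", "))
  p <- lapply(ix, function(i) as.numeric(residue[i, c("x", "y", "z")]))
  ang <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
  bin <- if (ang >= -120 && ang < 0) "gauche_minus"
         else if (ang > 0 && ang <= 120) "gauche_plus"
         else "trans"
  label <- c(gauche_minus = "folded_g_star", trans = "extended",
             gauche_plus = "other")[[bin]]
  structure(list(residue = paste(rn, .res_key(residue$chain[1],
                                              residue$seqnum[1],
                                              residue$icode[1])),
                 chi1 = ang, bin = bin, label = label),
            class = "sift_rotamer")
}

#' @export
print.sift_rotamer <- function(x, ...) {
  cat("<chi1> ", x$residue, ": ", sprintf("%.1f", x$chi1), " deg (", x$bin,
      " / ", x$label, ")\n", sep = "")
  invisible(x)
}

# donor/acceptor atom inventory of the polymer (name, antecedent) per atom
.protein_polar_atoms <- function(atoms, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  tab <- chem_tables()
  sc <- if (role == "donor") tab$sc_donors else tab$sc_acceptors
  out <- list()
  key <- .res_key(atoms$chain, atoms$seqnum, atoms$icode)
  for (k in unique(key)) {
    ra <- atoms[key == k, , drop = FALSE]
    rn <- ra$resname[1]
    ent <- sc[[rn]] %||% character()
    if (role == "donor") {
      if (rn != "PRO") ent <- c(ent, c(N = "CA"))
    } else ent <- c(ent, c(O = "C"), c(OXT = "C"))
    for (an in names(ent)) {
      i <- match(an, ra$name)
      if (is.na(i)) next
      j <- match(ent[[an]], ra$name)
      out[[length(out) + 1]] <- data.frame(
        chain = ra$chain[i], seqnum = ra$seqnum[i], icode = ra$icode[i],
        resname = rn, name = an, x = ra$x[i], y = ra$y[i], z = ra$z[i],
        ax = if (is.na(j)) NA_real_ else ra$x[j],
        ay = if (is.na(j)) NA_real_ else ra$y[j],
        az = if (is.na(j)) NA_real_ else ra$z[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Protein-ligand hydrogen-bond table with water bridges
#'
#' Lists every ligand-protein donor/acceptor pair passing the H-bond
#' thresholds, distances to 0.1 A, and water-mediated bridges: a water
#' oxygen H-bonding both a ligand polar atom and a protein polar atom
#' (distance criterion only for the water, which has no antecedent).
#'
#' @param s A `sift_structure`.
#' @param ligand Ligand atom data frame.
#' @param params Thresholds, see [default_interaction_params()].
#' @return Data frame with columns type ("direct"/"water_bridge"),
#'   ligand_atom, partner (residue label), partner_atom, distance (for
#'   bridges: ligand-water), bridge_distance (water-partner, NA for
#'   direct), direction ("ligand_donates"/"residue_donates"/"bridge").
#' @export
hbond_table <- function(s, ligand, params = default_interaction_params()) {
  pol <- s$atoms[s$atoms$record == "polymer", , drop = FALSE]
  ligp <- .perceive_ligand(ligand, params)
  lig_xyz <- .xyz(ligand)
  rows <- list()
  lab <- function(df, i) paste0(df$resname[i], " ",
                                .res_key(df$chain[i], df$seqnum[i],
                                         df$icode[i]))
  add <- function(type, la, partner, pa, d, bd = NA_real_, dir) {
    rows[[length(rows) + 1]] <<- data.frame(
      type = type, ligand_atom = la, partner = partner, partner_atom = pa,
      distance = round(d, 1), bridge_distance = round(bd, 1),
      direction = dir, stringsAsFactors = FALSE)
  }

  don <- .protein_polar_atoms(pol, "donor")
  if (!is.null(don)) {
    for (i in seq_len(nrow(don))) {
      nb <- if (is.na(don$ax[i])) NULL else c(don$ax[i], don$ay[i], don$az[i])
      for (li in which(ligp$acceptor)) {
        hb <- detect_hbond(c(don$x[i], don$y[i], don$z[i]), lig_xyz[li, ],
                           nb, params)
        if (hb$hbond)
          add("direct", ligand$name[li], lab(don, i), don$name[i],
              hb$distance, dir = "residue_donates")
      }
    }
  }
  acc <- .protein_polar_atoms(pol, "acceptor")
  if (!is.null(acc)) {
    for (i in seq_len(nrow(acc))) {
      for (li in which(ligp$donor)) {
        nbi <- ligp$antecedent[li]
        nb <- if (is.na(nbi)) NULL else lig_xyz[nbi, ]
        hb <- detect_hbond(lig_xyz[li, ], c(acc$x[i], acc$y[i], acc$z[i]),
                           nb, params)
        if (hb$hbond)
          add("direct", ligand$name[li], lab(acc, i), acc$name[i],
              hb$distance, dir = "ligand_donates")
      }
    }
  }

  # water bridges: water O within hbond_dist of a ligand polar atom and
  # of a protein donor/acceptor atom
  wat <- s$atoms[s$atoms$record == "water" & s$atoms$element == "O", ,
                 drop = FALSE]
  lig_polar <- which(ligp$donor | ligp$acceptor)
  prot_polar <- rbind(don, acc)
  if (nrow(wat) > 0 && length(lig_polar) && !is.null(prot_polar)) {
    dw_lig <- .pair_dists(.xyz(wat), lig_xyz[lig_polar, , drop = FALSE])
    dw_pro <- .pair_dists(.xyz(wat),
                          as.matrix(prot_polar[, c("x", "y", "z")]))
    for (w in seq_len(nrow(wat))) {
      lig_hits <- which(dw_lig[w, ] <= params$hbond_dist)
      pro_hits <- which(dw_pro[w, ] <= params$hbond_dist)
      for (lh in lig_hits) for (ph in pro_hits)
        add("water_bridge", ligand$name[lig_polar[lh]],
            lab(prot_polar, ph), prot_polar$name[ph],
            dw_lig[w, lh], dw_pro[w, ph], "bridge")
    }
  }
  if (!length(rows)) {
    return(data.frame(type = character(), ligand_atom = character(),
                      partner = character(), partner_atom = character(),
                      distance = numeric(), bridge_distance = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, rows)
  tab <- unique(tab)
  tab[order(tab$type, tab$partner, tab$distance), , drop = FALSE]
}

#' Steric-clash scan between two selections
#'
#' Reports every atom pair closer than the sum of Bondi van der Waals
#' radii minus `tolerance`, sorted by overlap (largest first).
#'
#' @param sel_a,sel_b Atom data frames with `element` columns.
#' @param tolerance Allowed interpenetration in A (default 0.4).
#' @return Data frame with atom names, distance, vdw_sum and overlap
#'   (`vdw_sum - distance - tolerance`, > 0 by construction).
#' @export
clash_scan <- function(sel_a, sel_b, tolerance = 0.4) {
  stopifnot(nrow(sel_a) > 0, nrow(sel_b) > 0)
  d <- .pair_dists(.xyz(sel_a), .xyz(sel_b))
  vsum <- outer(vdw_radius(sel_a$element), vdw_radius(sel_b$element), "+")
  hit <- which(d < vsum - tolerance, arr.ind = TRUE)
  out <- data.frame(
    atom_a = sel_a$name[hit[, 1]], atom_b = sel_b$name[hit[, 2]],
    distance = d[hit], vdw_sum = vsum[hit],
    overlap = vsum[hit] - d[hit] - tolerance, stringsAsFactors = FALSE)
  out[order(-out$overlap), , drop = FALSE]
}

#' Grid flood-fill cavity volume
#'
#' Builds a cubic grid over the structure's bounding box expanded by 8 A,
#' blocks every voxel within `r_vdw + probe` of a protein heavy atom, and
#' flood-fills (6-connectivity) from the seed point.  If the fill reaches
#' the bounding box the pocket is open: a warning is raised and the
#' volume of the capped region is reported.
#'
#' @param s A `sift_structure` (all non-water atoms block).
#' @param seed Numeric 3-vector inside the cavity.
#' @param spacing Grid spacing in A (default 0.4).
#' @param probe Probe radius in A (default 1.4, water-sized).
#' @param margin Bounding-box expansion in A (default 8).
#' @return A `sift_cavity`: list with `volume` (A^3), `voxels` (count),
#'   `spacing`, `probe`, `seed`, `open` (logical) and `voxel_xyz`
#'   (matrix of filled voxel centres).
#' @export
cavity_volume <- function(s, seed, spacing = 0.4, probe = 1.4, margin = 8) {
  at <- s$atoms[s$atoms$record != "water", , drop = FALSE]
  stopifnot(nrow(at) > 0, length(seed) == 3, spacing > 0, probe >= 0)
  xyz <- .xyz(at)
  rad <- vdw_radius(at$element) + probe
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]

  blocked <- array(FALSE, dim = dims)
  for (i in seq_len(nrow(at))) {
    ctr <- xyz[i, ]
    r <- rad[i]
    rng <- function(k) {
      a <- max(1L, as.integer(floor((ctr[k] - r - lo[k]) / spacing)) + 1L)
      b <- min(dims[k], as.integer(ceiling((ctr[k] + r - lo[k]) / spacing)) + 1L)
      if (a > b) integer() else a:b
    }
    ix <- rng(1); iy <- rng(2); iz <- rng(3)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- lo[1] + (ix - 1) * spacing
    gy <- lo[2] + (iy - 1) * spacing
    gz <- lo[3] + (iz - 1) * spacing
    d2 <- outer(outer((gx - ctr[1])^2, (gy - ctr[2])^2, "+"),
                (gz - ctr[3])^2, "+")
    blocked[ix, iy, iz] <- blocked[ix, iy, iz] | (d2 <= r * r)
  }

  sidx <- as.integer(round((seed - lo) / spacing)) + 1L
  if (any(sidx < 1L) || any(sidx > dims))
    stop("seed point lies outside the grid")
  if (blocked[sidx[1], sidx[2], sidx[3]])
    stop("seed point lies inside the probe-expanded protein volume")

  # BFS flood fill on linear indices, 6-connectivity
  lin <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  visited <- array(FALSE, dim = dims)
  start <- lin(sidx[1], sidx[2], sidx[3])
  visited[start] <- TRUE
  frontier <- start
  offs <- c(1L, -1L, nx, -nx, nx * ny, -(nx * ny))
  open <- FALSE
  ntot <- prod(dims)
  while (length(frontier)) {
    # decompose to guard against wrap-around at the grid faces
    f0 <- frontier - 1L
    fi <- f0 %% nx + 1L
    fj <- (f0 %/% nx) %% ny + 1L
    fk <- f0 %/% (nx * ny) + 1L
    if (any(fi == 1L | fi == nx | fj == 1L | fj == ny | fk == 1L | fk == nz))
      open <- TRUE
    nxt <- integer()
    for (o in seq_along(offs)) {
      ok <- switch(o,
                   fi < nx, fi > 1L, fj < ny, fj > 1L, fk < nz, fk > 1L)
      cand <- frontier[ok] + offs[o]
      nxt <- c(nxt, cand)
    }
    nxt <- unique(nxt[nxt >= 1L & nxt <= ntot])
    nxt <- nxt[!visited[nxt] & !blocked[nxt]]
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  if (open)
    warning("flood fill reached the bounding box: open pocket; ",
            "volume reported for the capped region")
  nvox <- sum(visited)
  fill <- which(visited)
  f0 <- fill - 1L
  vox_xyz <- cbind(lo[1] + (f0 %% nx) * spacing,
                   lo[2] + ((f0 %/% nx) %% ny) * spacing,
                   lo[3] + (f0 %/% (nx * ny)) * spacing)
  structure(list(volume = nvox * spacing^3, voxels = nvox,
                 spacing = spacing, probe = probe, seed = seed,
                 open = open, voxel_xyz = vox_xyz),
            class = "sift_cavity")
}

#' @export
print.sift_cavity <- function(x, ...) {
  cat("<cavity> ", sprintf("%.1f", x$volume), " A^3 (", x$voxels,
      " voxels at ", x$spacing, " A, probe ", x$probe, " A",
      if (x$open) ", OPEN pocket" else "", ")\n", sep = "")
  invisible(x)
}

#' Measure a named set of reference binding-site geometries
#'
#' Convenience wrapper for validating a complex against printed
#' literature values: computes the chi1 of a gate-keeper residue, a set
#' of H-bond distances (closest qualifying pair between a named residue
#' and the ligand) and minimum-distance pairs between named residues.
#'
#' @param s A `sift_structure`.
#' @param ligand Ligand atom data frame.
#' @param chi1_residue Optional `c(chain, seqnum)` of the residue whose
#'   chi1 is reported.
#' @param hbond_partners Optional character vector of residue keys
#'   (`"chain:seqnum"`) whose best ligand H-bond distance is reported.
#' @param vdw_pairs Optional list of `c(key_a, key_b)` residue-key pairs
#'   whose side-chain minimum distance is reported (use key `"ligand"`
#'   for the ligand).
#' @param params Thresholds.
#' @return Data frame with columns measure, target, value.
#' @export
validate_reference_geometry <- function(s, ligand, chi1_residue = NULL,
                                        hbond_partners = NULL,
                                        vdw_pairs = NULL,
                                        params = default_interaction_params()) {
  rows <- list()
  add <- function(measure, target, value)
    rows[[length(rows) + 1]] <<- data.frame(measure = measure,
                                            target = target, value = value,
                                            stringsAsFactors = FALSE)
  if (!is.null(chi1_residue)) {
    ra <- residue_atoms(s, chi1_residue[1], as.integer(chi1_residue[2]))
    rc <- chi1(ra)
    add("chi1_deg", rc$residue, rc$chi1)
  }
  if (!is.null(hbond_partners)) {
    hb <- hbond_table(s, ligand, params)
    for (key in hbond_partners) {
      hit <- hb[hb$type == "direct" &
                  grepl(paste0(" ", key, "$"), hb$partner), , drop = FALSE]
      add("hbond_dist_A", key,
          if (nrow(hit)) min(hit$distance) else NA_real_)
    }
  }
  if (!is.null(vdw_pairs)) {
    sel <- function(key) {
      if (key == "ligand") return(ligand)
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      ra <- residue_atoms(s, parts[1], as.integer(parts[2]))
      ra[!ra$name %in% chem_tables()$backbone, , drop = FALSE]
    }
    for (pr in vdw_pairs) {
      md <- min_distance(sel(pr[1]), sel(pr[2]))
      add("min_dist_A", paste(pr, collapse = "~"), md$distance)
    }
  }
  do.call(rbind, rows)
}
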