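# Interaction typing: detect, for every binding-site residue, which of
# the nine fingerprint classes the ligand realizes, from heavy-atom
# geometry alone.  All thresholds live in `default_interaction_params()`
# and are deliberately exposed: crystal structures carry no hydrogens, so
# H-bonds use a heavy-atom proxy angle at the donor.

#' Default geometric thresholds for interaction typing
#'
#' * `contact`: any heavy-heavy distance (4.5 A)
#' * `polar`: residue N/O/S to ligand N/O distance (3.5 A)
#' * `hbond_dist` / `hbond_angle_min`: donor-acceptor distance (3.5 A)
#'   and minimum antecedent-donor-acceptor proxy angle (90 deg)
#' * `aromatic_centroid`: ring centroid-centroid distance (5.5 A)
#' * `hydrophobic`: apolar carbon to apolar carbon distance (4.5 A)
#' * `charged`: charged-group atom to oppositely charged ligand atom
#'   distance (4.0 A)
#' * `planarity_rms`: max RMS out-of-plane deviation for a ring (0.15 A)
#' * `bond_tol`: covalent bond inference slack (0.45 A)
#' * `his_charged`: treat histidine as cationic as well as aromatic
#'
#' @return Named list of parameters.
#' @export
default_interaction_params <- function() {
  list(contact = 4.5, polar = 3.5, hbond_dist = 3.5, hbond_angle_min = 90,
       aromatic_centroid = 5.5, hydrophobic = 4.5, charged = 4.0,
       planarity_rms = 0.15, bond_tol = 0.45, his_charged = FALSE)
}

# Bond inference on an atom table: d <= r_cov(i) + r_cov(j) + tol.
# Returns integer adjacency list.
.infer_bonds <- function(atoms, tol = 0.45) {
  n <- nrow(atoms)
  adj <- vector("list", n)
  if (n < 2) return(adj)
  d <- .pair_dists(.xyz(atoms), .xyz(atoms))
  rc <- .cov_radius(atoms$element)
  lim <- outer(rc, rc, "+") + tol
  diag(d) <- Inf
  for (i in seq_len(n)) adj[[i]] <- which(d[i, ] <= lim[i, ])
  adj
}

# Ligand atom perception: polarity, donor/acceptor capability, formal
# charge (carboxylate O anionic; N with <=1 heavy neighbour cationic),
# apolar carbons and the antecedent neighbour used for proxy angles.
.perceive_ligand <- function(ligand, params = default_interaction_params()) {
  n <- nrow(ligand)
  adj <- .infer_bonds(ligand, params$bond_tol)
  el <- ligand$element
  deg <- lengths(adj)
  nbr_el <- lapply(adj, function(ix) el[ix])
  charge <- integer(n)
  donor <- logical(n)
  acceptor <- logical(n)

  # carboxylate: C bonded to two terminal O -> both O anionic acceptors
  for (i in which(el == "C")) {
    o_nb <- adj[[i]][el[adj[[i]]] == "O"]
    term_o <- o_nb[deg[o_nb] == 1]
    if (length(term_o) >= 2) charge[term_o] <- -1L
  }
  # cationic amine: N with >= 2 hydrogen-bearing free valences
  charge[el == "N" & deg <= 1] <- +1L

  for (i in seq_len(n)) {
    if (el[i] == "N") {
      donor[i] <- TRUE                      # assume protonatable N donates
      acceptor[i] <- charge[i] <= 0         # cations do not accept
    } else if (el[i] == "O") {
      if (charge[i] < 0) {                  # carboxylate O: acceptor only
        acceptor[i] <- TRUE
      } else if (deg[i] >= 2) {             # ether/ester O: acceptor only
        acceptor[i] <- TRUE
      } else {                              # hydroxyl/carbonyl: both
        donor[i] <- TRUE
        acceptor[i] <- TRUE
      }
    }
  }
  apolar_c <- el == "C" & !vapply(nbr_el, function(e) any(e %in% c("N", "O")),
                                  logical(1))
  antecedent <- vapply(adj, function(ix) if (length(ix)) ix[1] else NA_integer_,
                       integer(1))
  list(adj = adj, charge = charge, donor = donor, acceptor = acceptor,
       apolar_c = apolar_c, antecedent = antecedent)
}

#' Perceive rings in a ligand from inferred connectivity
#'
#' Bonds are inferred with a covalent-radius criterion; rings are the
#' minimal cycles of size 3-7 in the bond graph, each annotated with a
#' least-squares planarity measure.
#'
#' @param ligand Ligand atom data frame (from [extract_ligand()] or a
#'   fixture generator).
#' @param params Threshold list, see [default_interaction_params()].
#' @return List of rings; each ring is a list with `atoms` (row indices
#'   into `ligand`), `names`, `planar` (logical) and `rms` (A).
#' @export
perceive_ligand_rings <- function(ligand, params = default_interaction_params()) {
  stopifnot(nrow(ligand) >= 3)
  adj <- .infer_bonds(ligand, params$bond_tol)
  edges <- do.call(rbind, lapply(seq_along(adj), function(i) {
    j <- adj[[i]][adj[[i]] > i]
    if (length(j)) cbind(i, j) else NULL
  }))
  if (is.null(edges) || nrow(edges) == 0) return(list())
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < nrow(ligand))
    g <- igraph::add_vertices(g, nrow(ligand) - igraph::vcount(g))
  rings <- list()
  seen <- character()
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = i, to = j))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) >= 3 && length(path) <= 7) {
      key <- paste(sort(path), collapse = "-")
      if (!key %in% seen) {
        seen <- c(seen, key)
        pl <- .fit_plane(.xyz(ligand[path, , drop = FALSE]))
        rings[[length(rings) + 1]] <-
          list(atoms = path, names = ligand$name[path],
               planar = pl$rms <= params$planarity_rms, rms = pl$rms)
      }
    }
  }
  rings
}

#' Heavy-atom hydrogen-bond test
#'
#' True iff the donor-acceptor distance is at most `hbond_dist` and, when
#' the donor's heavy-atom antecedent is supplied, the
#' antecedent-donor-acceptor angle is at least `hbond_angle_min` (a proxy
#' for hydrogen placement when no hydrogens are present).
#'
#' @param donor_heavy,acceptor_heavy Numeric 3-vectors (A).
#' @param neighbor_of_donor Optional numeric 3-vector: heavy-atom
#'   antecedent of the donor.
#' @param params Threshold list, see [default_interaction_params()].
#' @return List with `hbond` (logical), `distance` (A) and `angle`
#'   (degrees, `NA` when no antecedent was supplied).
#' @export
detect_hbond <- function(donor_heavy, acceptor_heavy,
                         neighbor_of_donor = NULL,
                         params = default_interaction_params()) {
  d <- .vnorm(acceptor_heavy - donor_heavy)
  ang <- NA_real_
  ok <- d <= params$hbond_dist
  if (ok && !is.null(neighbor_of_donor)) {
    ang <- vec_angle(neighbor_of_donor, donor_heavy, acceptor_heavy)
    ok <- ang >= params$hbond_angle_min
  }
  list(hbond = ok, distance = d, angle = ang)
}

#' Aromatic (ring-ring) interaction test
#'
#' Both atom sets must contain at least 5 atoms and pass the planarity
#' check (RMS out-of-plane deviation at most `planarity_rms`); the
#' interaction holds iff the ring centroids are within
#' `aromatic_centroid`.
#'
#' @param residue_ring,ligand_ring Atom coordinate matrices (n x 3) or
#'   atom data frames with x/y/z columns.
#' @param params Threshold list.
#' @return List with `aromatic` (logical), `distance` (centroid-centroid,
#'   A) and `planar` (logical: both rings passed planarity).
#' @export
detect_aromatic <- function(residue_ring, ligand_ring,
                            params = default_interaction_params()) {
  as_mat <- function(r) if (is.data.frame(r)) .xyz(r) else
    matrix(as.numeric(r), ncol = 3)
  a <- as_mat(residue_ring); b <- as_mat(ligand_ring)
  stopifnot(nrow(a) >= 5, nrow(b) >= 5)
  pa <- .fit_plane(a); pb <- .fit_plane(b)
  planar <- pa$rms <= params$planarity_rms && pb$rms <= params$planarity_rms
  d <- .vnorm(pa$centroid - pb$centroid)
  list(aromatic = planar && d <= params$aromatic_centroid,
       distance = d, planar = planar)
}

.empty_records <- function() {
  data.frame(chain = character(), seqnum = integer(), icode = character(),
             resname = character(), kind = character(),
             ligand_atom = character(), residue_atom = character(),
             distance = numeric(), angle = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect all fingerprint interactions of a complex
#'
#' Scans every panel residue against the ligand heavy atoms and emits one
#' record per (residue, interaction class) realized, carrying the closest
#' qualifying atom pair.  A residue may carry several classes; a
#' `contact` record is emitted whenever any other class is (hierarchy
#' rule).  Residues missing the atoms a specific detector needs (e.g. an
#' incomplete aromatic ring) have that detector skipped with a warning.
#'
#' @param s A `sift_structure`.
#' @param ligand Ligand atom data frame.
#' @param panel A `sift_panel`.
#' @param params Threshold list, see [default_interaction_params()].
#' @return Data frame of interaction records (columns chain, seqnum,
#'   icode, resname, kind, ligand_atom, residue_atom, distance, angle).
#' @export
detect_interactions <- function(s, ligand, panel,
                                params = default_interaction_params()) {
  stopifnot(inherits(s, "sift_structure"), nrow(ligand) > 0)
  tab <- chem_tables()
  ligp <- .perceive_ligand(ligand, params)
  lig_xyz <- .xyz(ligand)
  lig_rings <- if (nrow(ligand) >= 3)
    Filter(function(r) r$planar, perceive_ligand_rings(ligand, params))
  else list()

  out <- list()
  add <- function(res, kind, li, ri, dist, ang = NA_real_, res_atoms = NULL) {
    out[[length(out) + 1]] <<- data.frame(
      chain = res$chain, seqnum = res$seqnum, icode = res$icode,
      resname = res$resname, kind = kind,
      ligand_atom = if (is.na(li)) "ring" else ligand$name[li],
      residue_atom = if (is.na(ri)) "ring" else res_atoms$name[ri],
      distance = dist, angle = ang, stringsAsFactors = FALSE)
  }

  for (r in seq_len(nrow(panel))) {
    res <- panel[r, , drop = FALSE]
    ra <- residue_atoms(s, res$chain, res$seqnum, res$icode)
    ra <- ra[ra$record == "polymer", , drop = FALSE]
    if (nrow(ra) == 0) {
      warning("panel residue ", .res_key(res$chain, res$seqnum, res$icode),
              " absent from structure ", s$id, "; skipped")
      next
    }
    rn <- res$resname
    D <- .pair_dists(.xyz(ra), lig_xyz)
    min_all <- which(D == min(D), arr.ind = TRUE)[1, ]
    n_before <- length(out)

    # backbone / sidechain partition of plain contacts
    bb <- ra$name %in% tab$backbone
    if (any(bb)) {
      Db <- D[bb, , drop = FALSE]
      if (min(Db) <= params$contact) {
        ix <- which(Db == min(Db), arr.ind = TRUE)[1, ]
        add(res, "backbone", ix[2], which(bb)[ix[1]], min(Db), res_atoms = ra)
      }
    }
    if (any(!bb)) {
      Ds <- D[!bb, , drop = FALSE]
      if (min(Ds) <= params$contact) {
        ix <- which(Ds == min(Ds), arr.ind = TRUE)[1, ]
        add(res, "sidechain", ix[2], which(!bb)[ix[1]], min(Ds), res_atoms = ra)
      }
    }

    # polar: residue N/O/S vs ligand N/O
    rp <- ra$element %in% c("N", "O", "S")
    lp <- ligand$element %in% c("N", "O")
    if (any(rp) && any(lp)) {
      Dp <- D[rp, lp, drop = FALSE]
      if (min(Dp) <= params$polar) {
        ix <- which(Dp == min(Dp), arr.ind = TRUE)[1, ]
        add(res, "polar", which(lp)[ix[2]], which(rp)[ix[1]], min(Dp),
            res_atoms = ra)
      }
    }

    # hydrophobic: apolar carbon pairs
    rap <- ra$name %in% (tab$apolar_carbons[[rn]] %||% character())
    if (any(rap) && any(ligp$apolar_c)) {
      Dh <- D[rap, ligp$apolar_c, drop = FALSE]
      if (min(Dh) <= params$hydrophobic) {
        ix <- which(Dh == min(Dh), arr.ind = TRUE)[1, ]
        add(res, "hydrophobic", which(ligp$apolar_c)[ix[2]],
            which(rap)[ix[1]], min(Dh), res_atoms = ra)
      }
    }

    # aromatic: residue ring templates vs perceived planar ligand rings
    templates <- tab$aromatic_rings[[rn]]
    if (!is.null(templates) && length(lig_rings)) {
      best <- NULL
      for (tpl in templates) {
        ridx <- match(tpl, ra$name)
        if (anyNA(ridx)) {
          warning("residue ", rn, " ",
                  .res_key(res$chain, res$seqnum, res$icode),
                  " lacks ring atoms ", paste(tpl[is.na(ridx)], collapse = ","),
                  "; aromatic detector skipped")
          next
        }
        for (lr in lig_rings) {
          hit <- detect_aromatic(ra[ridx, , drop = FALSE],
                                 ligand[lr$atoms, , drop = FALSE], params)
          if (hit$aromatic && (is.null(best) || hit$distance < best))
            best <- hit$distance
        }
      }
      if (!is.null(best))
        add(res, "aromatic", NA_integer_, NA_integer_, best, res_atoms = ra)
    }

    # H-bonds: residue donates (hbond_donor) / residue accepts
    donors <- tab$sc_donors[[rn]] %||% character()
    if (rn != "PRO") donors <- c(donors, c(N = "CA"))
    best_d <- NULL
    for (dn in names(donors)) {
      di <- match(dn, ra$name)
      if (is.na(di)) next
      ai <- match(donors[[dn]], ra$name)
      nb <- if (is.na(ai)) NULL else as.numeric(ra[ai, c("x", "y", "z")])
      for (li in which(ligp$acceptor)) {
        hb <- detect_hbond(as.numeric(ra[di, c("x", "y", "z")]),
                           lig_xyz[li, ], nb, params)
        if (hb$hbond && (is.null(best_d) || hb$distance < best_d$distance))
          best_d <- list(li = li, ri = di, distance = hb$distance,
                         angle = hb$angle)
      }
    }
    if (!is.null(best_d))
      add(res, "hbond_donor", best_d$li, best_d$ri, best_d$distance,
          best_d$angle, res_atoms = ra)

    acceptors <- tab$sc_acceptors[[rn]] %||% character()
    acceptors <- c(acceptors, c(O = "C"), c(OXT = "C"))
    best_a <- NULL
    for (an in names(acceptors)) {
      ai <- match(an, ra$name)
      if (is.na(ai)) next
      for (li in which(ligp$donor)) {
        nbi <- ligp$antecedent[li]
        nb <- if (is.na(nbi)) NULL else lig_xyz[nbi, ]
        hb <- detect_hbond(lig_xyz[li, ],
                           as.numeric(ra[ai, c("x", "y", "z")]), nb, params)
        if (hb$hbond && (is.null(best_a) || hb$distance < best_a$distance))
          best_a <- list(li = li, ri = ai, distance = hb$distance,
                         angle = hb$angle)
      }
    }
    if (!is.null(best_a))
      add(res, "hbond_acceptor", best_a$li, best_a$ri, best_a$distance,
          best_a$angle, res_atoms = ra)

    # charged: opposite formal signs within threshold
    cg <- tab$charged_groups[[rn]]
    if (!is.null(cg) && !(rn == "HIS" && !isTRUE(params$his_charged))) {
      rc <- which(ra$name %in% cg$atoms)
      lc <- which(ligp$charge == -cg$sign)
      if (length(rc) && length(lc)) {
        Dc <- D[rc, lc, drop = FALSE]
        if (min(Dc) <= params$charged) {
          ix <- which(Dc == min(Dc), arr.ind = TRUE)[1, ]
          add(res, "charged", lc[ix[2]], rc[ix[1]], min(Dc), res_atoms = ra)
        }
      }
    }

    # hierarchy rule: contact accompanies every other class, and stands
    # alone whenever any heavy-heavy pair is within the contact cutoff
    if (length(out) > n_before || min(D) <= params$contact)
      add(res, "contact", min_all[2], min_all[1], min(D), res_atoms = ra)
  }
  rec <- if (length(out)) do.call(rbind, out) else .empty_records()
  rec <- rec[order(rec$chain, rec$seqnum, rec$icode,
                   match(rec$kind, SIFT_KINDS)), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export interaction records
#'
#' @param records Record data frame from [detect_interactions()].
#' @param file Path.
#' @param format `"tsv"` or `"json"` (the latter requires jsonlite).
#' @param complex_id Identifier written with every row.
#' @export
write_records <- function(records, file, format = c("tsv", "json"),
                          complex_id = "complex") {
  format <- match.arg(format)
  recs <- cbind(complex_id = complex_id, records)
  if (format == "tsv") {
    write.table(recs, file, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON export")
    jsonlite::write_json(recs, file, dataframe = "rows", digits = NA)
  }
  invisible(file)
}
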