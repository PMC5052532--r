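# Structure input/output: PDB parsing (delegated to bio3d behind this
# surface), ligand extraction and binding-site panel definition.
#
# A structure is a flat atom table plus an identifier.  Author residue
# numbering is authoritative and never changed; alternate locations are
# resolved to the blank/'A' conformer; hydrogens are dropped on input
# (crystal structures generally lack them and every criterion in the
# package is defined on heavy atoms).

.res_key <- function(chain, seqnum, icode = "") {
  if (length(chain) == 0) return(character(0))
  paste0(chain, ":", seqnum, ifelse(icode == "", "", paste0(".", icode)))
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records from PDB-format text, classifies atoms as
#' polymer, hetero or water, resolves alternate locations (blank or 'A'
#' kept, others dropped with a warning) and drops hydrogens.  Author
#' chain/residue numbering and insertion codes are preserved unchanged.
#'
#' @param text Character scalar (or vector of lines) of PDB-format
#'   content, or the path of an existing file.
#' @param id Identifier stored on the returned structure.
#' @return An object of class `sift_structure`: a list with elements
#'   `id` and `atoms` (data frame with columns serial, name, altloc,
#'   resname, chain, seqnum, icode, x, y, z, occupancy, element, record).
#' @examples
#' pdb <- paste0("ATOM      1  OG  SER A 280      10.000  10.000",
#'               "  10.000  1.00  0.00           O")
#' s <- parse_structure(pdb, id = "mini")
#' nrow(s$atoms)
#' @export
parse_structure <- function(text, id = "structure") {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
    if (id == "structure") id <- sub("\\.[^.]*$", "", basename(text))
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom))
    stop("empty input: no ATOM or HETATM record found")
  # validate fixed-width records before handing to the reader
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed fixed-width ATOM/HETATM record at line ", i,
           ": shorter than 54 columns")
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(coords)))))
      stop("malformed fixed-width ATOM/HETATM record at line ", i,
           ": unreadable coordinate field")
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, verbose = FALSE,
                                          rm.alt = FALSE))
  at <- pdb$atom

  blank <- function(x) ifelse(is.na(x), "", trimws(x))
  element <- toupper(blank(at$elesy))
  noel <- element == ""
  if (any(noel)) {
    # derive from the PDB atom name: strip digits/primes, two-letter
    # symbols only for the standard halogens/metals we know radii for
    nm <- gsub("[0-9']", "", blank(at$elety)[noel])
    two <- toupper(substr(nm, 1, 2))
    element[noel] <- ifelse(two %in% c("CL", "BR"), two,
                            toupper(substr(nm, 1, 1)))
  }

  atoms <- data.frame(
    serial = at$eleno,
    rectype = blank(at$type),
    name = blank(at$elety),
    altloc = blank(at$alt),
    resname = blank(at$resid),
    chain = blank(at$chain),
    seqnum = at$resno,
    icode = blank(at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element = element,
    stringsAsFactors = FALSE
  )

  drop_alt <- !(atoms$altloc %in% c("", "A"))
  if (any(drop_alt)) {
    warning("dropped alternate-location conformer(s): ",
            paste(unique(paste0(atoms$resname[drop_alt], " ",
                                .res_key(atoms$chain[drop_alt],
                                         atoms$seqnum[drop_alt],
                                         atoms$icode[drop_alt]),
                                " altloc ", atoms$altloc[drop_alt])),
                  collapse = "; "))
    atoms <- atoms[!drop_alt, , drop = FALSE]
  }
  atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]
  if (nrow(atoms) == 0)
    stop("empty input: no heavy atoms after altloc/hydrogen filtering")

  is_water <- atoms$resname %in% .WATER_RESNAMES
  atoms$record <- ifelse(is_water, "water",
                         ifelse(atoms$rectype == "HETATM", "hetero",
                                "polymer"))
  atoms$rectype <- NULL
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "sift_structure")
}

#' @export
print.sift_structure <- function(x, ...) {
  tab <- table(x$atoms$record)
  cat("<sift_structure> ", x$id, ": ", nrow(x$atoms), " heavy atoms (",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Write a structure as PDB-format text
#'
#' @param s A `sift_structure`.
#' @param file Optional path; when `NULL` the PDB text is returned as a
#'   character scalar.
#' @return The file path (invisibly) or the PDB text.
#' @export
write_structure <- function(s, file = NULL) {
  at <- s$atoms
  tmp <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(
    pdb = NULL, file = tmp,
    xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
    type = ifelse(at$record == "polymer", "ATOM", "HETATM"),
    resno = at$seqnum,
    resid = at$resname,
    eleno = at$serial,
    elety = at$name,
    chain = ifelse(at$chain == "", " ", at$chain),
    insert = ifelse(at$icode == "", "", at$icode),
    alt = ifelse(at$altloc == "", "", at$altloc),
    o = at$occupancy, b = rep(0, nrow(at)),
    elesy = at$element, verbose = FALSE
  )
  if (is.null(file)) {
    txt <- paste(readLines(tmp, warn = FALSE), collapse = "\n")
    unlink(tmp)
    return(txt)
  }
  invisible(file)
}

# coordinate matrix of an atom table
.xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])

# unique residue table of an atom subset, in file order
.residue_table <- function(atoms) {
  key <- .res_key(atoms$chain, atoms$seqnum, atoms$icode)
  idx <- !duplicated(key)
  data.frame(chain = atoms$chain[idx], seqnum = atoms$seqnum[idx],
             icode = atoms$icode[idx], resname = atoms$resname[idx],
             key = key[idx], stringsAsFactors = FALSE)
}

#' Atoms of one residue
#'
#' @param s A `sift_structure`.
#' @param chain Chain identifier.
#' @param seqnum Author residue number.
#' @param icode Insertion code ("" for none).
#' @return Atom data frame (possibly empty).
#' @export
residue_atoms <- function(s, chain, seqnum, icode = "") {
  at <- s$atoms
  at[at$chain == chain & at$seqnum == seqnum & at$icode == icode, ,
     drop = FALSE]
}

#' Extract a ligand's heavy atoms from a structure
#'
#' Matches hetero (non-polymer, non-water) groups against a selector.
#' Waters never match.  With no selector, the structure must contain
#' exactly one non-water hetero group.
#'
#' @param s A `sift_structure`.
#' @param resname,chain,seqnum Optional selector fields; `NULL` matches
#'   anything.
#' @return Atom data frame of the matched group, with attribute
#'   `ligand_id`.
#' @export
extract_ligand <- function(s, resname = NULL, chain = NULL, seqnum = NULL) {
  het <- s$atoms[s$atoms$record == "hetero", , drop = FALSE]
  groups <- .residue_table(het)
  keep <- rep(TRUE, nrow(groups))
  if (!is.null(resname)) keep <- keep & groups$resname == resname
  if (!is.null(chain)) keep <- keep & groups$chain == chain
  if (!is.null(seqnum)) keep <- keep & groups$seqnum == seqnum
  hit <- groups[keep, , drop = FALSE]
  if (nrow(hit) == 0)
    stop("no hetero group matches the selector; available: ",
         if (nrow(groups) == 0) "(none)" else
           paste(groups$resname, groups$key, collapse = ", "))
  if (nrow(hit) > 1)
    stop("ambiguous ligand selector; matches: ",
         paste(hit$resname, hit$key, collapse = ", "),
         " - disambiguate with chain/seqnum")
  out <- het[.res_key(het$chain, het$seqnum, het$icode) == hit$key, ,
             drop = FALSE]
  attr(out, "ligand_id") <- paste(hit$resname, hit$key)
  out
}

#' Define a binding-site residue panel from one or more complexes
#'
#' The panel is the union, over all complexes, of polymer residues with
#' at least one heavy atom within `cutoff` of any ligand heavy atom,
#' ordered by (chain, seqnum, icode).  Structures that assign different
#' residue names to the same (chain, seqnum, icode) are rejected.
#'
#' @param complexes A list; each element is a list with components
#'   `structure` (a `sift_structure`) and `ligand` (atom data frame from
#'   [extract_ligand()]).
#' @param cutoff Contact cutoff in Angstrom (default 4.5).
#' @return A `sift_panel`: data frame with columns chain, seqnum, icode,
#'   resname (ordered, duplicate-free), attribute `provenance`.
#' @export
define_panel <- function(complexes, cutoff = 4.5) {
  stopifnot(length(complexes) >= 1, cutoff > 0)
  rows <- list()
  for (cx in complexes) {
    s <- cx$structure
    lig <- cx$ligand
    pol <- s$atoms[s$atoms$record == "polymer", , drop = FALSE]
    if (nrow(pol) == 0 || nrow(lig) == 0) next
    d <- .pair_dists(.xyz(pol), .xyz(lig))
    near <- apply(d, 1, min) <= cutoff
    rows[[length(rows) + 1]] <- .residue_table(pol[near, , drop = FALSE])
  }
  all <- do.call(rbind, rows)
  if (is.null(all) || nrow(all) == 0) {
    panel <- data.frame(chain = character(), seqnum = integer(),
                        icode = character(), resname = character(),
                        stringsAsFactors = FALSE)
  } else {
    # numbering-compatibility check across complexes
    for (k in unique(all$key)) {
      rn <- unique(all$resname[all$key == k])
      if (length(rn) > 1)
        stop("panel conflict: residue ", k,
             " has different names across structures: ",
             paste(rn, collapse = " vs "))
    }
    all <- all[!duplicated(all$key), , drop = FALSE]
    all <- all[order(all$chain, all$seqnum, all$icode), , drop = FALSE]
    panel <- all[, c("chain", "seqnum", "icode", "resname"), drop = FALSE]
  }
  rownames(panel) <- NULL
  attr(panel, "provenance") <- sprintf(
    "union of polymer residues with >=1 heavy atom within %.2f A of a ligand heavy atom, over %d complex(es)",
    cutoff, length(complexes))
  class(panel) <- c("sift_panel", "data.frame")
  panel
}

#' @export
print.sift_panel <- function(x, ...) {
  cat("<sift_panel> ", nrow(x), " residue(s)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Serialize / read a binding-site panel as TSV
#'
#' Columns chain, seqnum, icode, resname in panel order.
#'
#' @param panel A `sift_panel`.
#' @param file Path.
#' @return `read_panel` returns a `sift_panel`.
#' @export
write_panel <- function(panel, file) {
  write.table(as.data.frame(panel), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_panel
#' @export
read_panel <- function(file) {
  panel <- read.table(file, sep = "\t", header = TRUE,
                      colClasses = c("character", "integer", "character",
                                     "character"), na.strings = NULL)
  panel$icode[is.na(panel$icode)] <- ""
  panel$chain[is.na(panel$chain)] <- ""
  attr(panel, "provenance") <- paste("read from", file)
  class(panel) <- c("sift_panel", "data.frame")
  panel
}

.panel_keys <- function(panel) .res_key(panel$chain, panel$seqnum, panel$icode)
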