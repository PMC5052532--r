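test_that("a minimal ATOM record parses with identifiers preserved", {
  s <- parse_structure(MINIMAL_PDB, id = "mini")
  expect_s3_class(s, "sift_structure")
  expect_equal(nrow(s$atoms), 1)
  at <- s$atoms
  expect_equal(at$name, "OG")
  expect_equal(at$resname, "SER")
  expect_equal(at$chain, "A")
  expect_equal(at$seqnum, 280)
  expect_equal(at$record, "polymer")
  expect_equal(c(at$x, at$y, at$z), c(10.0, 12.5, 7.25))
})

test_that("toy-complex PDB text round-trips through write/parse", {
  tc <- make_toy_complex(SIFT_KINDS, seed = 11)
  s2 <- parse_structure(tc$pdb, id = "rt")
  a <- tc$structure$atoms
  b <- s2$atoms
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$name, b$name)
  expect_equal(a$resname, b$resname)
  expect_equal(a$seqnum, b$seqnum)
  expect_equal(a$record, b$record)
  expect_equal(round(a$x, 3), b$x)
  expect_equal(round(a$y, 3), b$y)
  expect_equal(round(a$z, 3), b$z)
})

test_that("malformed and empty inputs raise informative parse errors", {
  expect_error(parse_structure("REMARK nothing here"), "empty input")
  bad <- c(MINIMAL_PDB, "ATOM      2  CB  SER A 280      bad.xx  12.500")
  expect_error(parse_structure(bad), "line 2")
})

test_that("alternate locations beyond blank/'A' are dropped with a warning", {
  lineB <- sub("^(.{16})A", "\\1B",
               sub("OG ", "CB ", MINIMAL_PDB))  # altloc B variant
  substr(lineB, 17, 17) <- "B"
  lineA <- MINIMAL_PDB
  substr(lineA, 17, 17) <- "A"
  expect_warning(s <- parse_structure(c(lineA, lineB)), "altloc B")
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$altloc, "A")
})

test_that("extract_ligand finds the sole hetero group and never waters", {
  tc <- make_toy_complex("contact", seed = 2)
  lig <- extract_ligand(tc$structure)
  expect_equal(unique(lig$resname), "LIG")
  expect_gt(nrow(lig), 0)
  # waters never match, even by explicit resname
  wat <- as_atoms(matrix(c(50, 50, 50), 1), element = "O", resname = "HOH",
                  chain = "W", seqnum = 1L, record = "water")
  s2 <- tc$structure
  wat$serial <- max(s2$atoms$serial) + 1
  s2$atoms <- rbind(s2$atoms, wat)
  expect_error(extract_ligand(s2, resname = "HOH"), "no hetero group")
  # ambiguity: two hetero groups, no disambiguation
  lig2 <- as_atoms(matrix(c(60, 0, 0), 1), resname = "LG2", chain = "M",
                   seqnum = 901L)
  lig2$serial <- max(s2$atoms$serial) + 1
  s2$atoms <- rbind(s2$atoms, lig2)
  expect_error(extract_ligand(s2), "ambiguous")
  expect_equal(unique(extract_ligand(s2, resname = "LG2")$resname), "LG2")
})

test_that("define_panel matches a brute-force distance scan and is monotone", {
  tc <- make_toy_complex(c("contact", "polar", "hbond_donor"), seed = 5)
  s <- tc$structure
  lig <- tc$ligand
  panel <- define_panel(list(list(structure = s, ligand = lig)), cutoff = 4.5)
  # brute force over all residue-ligand atom pairs
  pol <- s$atoms[s$atoms$record == "polymer", ]
  keys <- unique(paste(pol$chain, pol$seqnum))
  brute <- vapply(keys, function(k) {
    ra <- pol[paste(pol$chain, pol$seqnum) == k, ]
    dmin <- min(sqrt(outer(ra$x, lig$x, "-")^2 + outer(ra$y, lig$y, "-")^2 +
                       outer(ra$z, lig$z, "-")^2))
    dmin <= 4.5
  }, logical(1))
  expect_equal(nrow(panel), sum(brute))
  expect_equal(nrow(panel), 3)

  expect_equal(nrow(define_panel(list(list(structure = s, ligand = lig)),
                                 cutoff = 0.1)), 0)
  # idempotent under duplicated complexes
  p2 <- define_panel(list(list(structure = s, ligand = lig),
                          list(structure = s, ligand = lig)), cutoff = 4.5)
  expect_equal(as.data.frame(panel), as.data.frame(p2), ignore_attr = TRUE)
  # monotone in cutoff
  sizes <- vapply(c(2, 3, 4.5, 6, 10), function(ct)
    nrow(define_panel(list(list(structure = s, ligand = lig)), cutoff = ct)),
    numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("panel definition rejects incompatible residue numbering", {
  tc <- make_toy_complex("contact", seed = 3)
  s2 <- tc$structure
  s2$atoms$resname[s2$atoms$record == "polymer"] <- "GLY"
  expect_error(
    define_panel(list(list(structure = tc$structure, ligand = tc$ligand),
                      list(structure = s2, ligand = tc$ligand))),
    "panel conflict")
})

test_that("panels serialize to TSV and back in order", {
  tc <- make_toy_complex(c("charged", "polar"), seed = 4)
  panel <- tc$panel
  f <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, f)
  p2 <- read_panel(f)
  expect_equal(as.data.frame(panel), as.data.frame(p2), ignore_attr = TRUE)
})
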