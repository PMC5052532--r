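# Shared helpers for the test suite: small analytic geometries and
# independent brute-force oracles.

# regular carbon hexagon (bond 1.39 A) in the xy-plane
benzene_xyz <- function(z = 0) {
  th <- (0:5) * pi / 3
  cbind(1.39 * cos(th), 1.39 * sin(th), z)
}

as_atoms <- function(xyz, element = "C", resname = "LIG", chain = "L",
                     seqnum = 900L, record = "hetero", name = NULL) {
  n <- nrow(xyz)
  data.frame(serial = seq_len(n),
             name = if (is.null(name)) paste0(element, seq_len(n)) else name,
             altloc = "", resname = resname, chain = chain, seqnum = seqnum,
             icode = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1,
             element = rep(element, length.out = n), record = record,
             stringsAsFactors = FALSE)
}

# apply a seeded random rigid motion to a sift_structure (and optionally
# a matching ligand table); used for invariance properties
rigid_copy <- function(s, ligand = NULL, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  t <- rnorm(3, sd = 20)
  rot <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(q)
    df$x <- xyz[, 1] + t[1]; df$y <- xyz[, 2] + t[2]; df$z <- xyz[, 3] + t[3]
    df
  }
  s$atoms <- rot(s$atoms)
  if (is.null(ligand)) return(s)
  list(structure = s, ligand = rot(ligand))
}

# set-arithmetic Tanimoto oracle on positions of set bits
tc_oracle <- function(a, b) {
  ia <- which(a == 1); ib <- which(b == 1)
  u <- length(union(ia, ib))
  if (u == 0) return(0)
  length(intersect(ia, ib)) / u
}

# residue x kind set of a record table, as sorted strings
record_set <- function(rec) {
  if (nrow(rec) == 0) return(character())
  sort(unique(paste(rec$chain, rec$seqnum, rec$icode, rec$kind)))
}

# minimal one-atom PDB line (serine OG), fixed-width
MINIMAL_PDB <- paste0(
  "ATOM      1  OG  SER A 280      10.000  12.500   7.250  1.00  0.00",
  "           O")
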