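# SIFt assembly and bit-string similarity.  A fingerprint is a binary
# vector of length 9 x |panel|, one fixed-order 9-bit block per panel
# residue (block order: contact, backbone, sidechain, polar, aromatic,
# hydrophobic, hbond_donor, hbond_acceptor, charged).

.panel_identical <- function(a, b) {
  identical(.panel_keys(a), .panel_keys(b)) &&
    identical(a$resname, b$resname)
}

#' Assemble a structural interaction fingerprint
#'
#' A bit is set iff at least one interaction record of that class exists
#' for that panel residue; panel residues with no records contribute
#' all-zero blocks.  Duplicate records are idempotent.
#'
#' @param records Record data frame from [detect_interactions()].
#' @param panel A `sift_panel`.
#' @param complex_id Identifier stored on the fingerprint.
#' @return A `sift_fp`: list with `complex_id`, `panel` and `bits`
#'   (integer 0/1 vector of length `9 * nrow(panel)`).
#' @export
build_sift <- function(records, panel, complex_id = "complex") {
  keys <- .panel_keys(panel)
  bits <- integer(9 * nrow(panel))
  if (nrow(records) > 0) {
    rk <- .res_key(records$chain, records$seqnum, records$icode)
    block <- match(rk, keys)
    if (anyNA(block))
      stop("panel mismatch: record(s) for residue(s) outside the panel: ",
           paste(unique(rk[is.na(block)]), collapse = ", "))
    kind <- match(records$kind, SIFT_KINDS)
    if (anyNA(kind))
      stop("unknown interaction kind: ",
           paste(unique(records$kind[is.na(kind)]), collapse = ", "))
    bits[9 * (block - 1) + kind] <- 1L
  }
  structure(list(complex_id = complex_id, panel = panel, bits = bits),
            class = "sift_fp")
}

#' @export
print.sift_fp <- function(x, ...) {
  cat("<sift_fp> ", x$complex_id, ": ", sum(x$bits), "/", length(x$bits),
      " bits set over ", nrow(x$panel), " panel residues\n", sep = "")
  invisible(x)
}

#' Tanimoto coefficient of two fingerprints
#'
#' `|a AND b| / |a OR b|`.  Both fingerprints must share the panel.  The
#' mathematically undefined all-zero vs all-zero case returns 0 with a
#' warning: an empty fingerprint means "no binding-site engagement" and
#' must not silently cluster as identical to another empty one.
#'
#' @param a,b `sift_fp` objects (or plain 0/1 vectors of equal length).
#' @return Tanimoto coefficient in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (inherits(a, "sift_fp") && inherits(b, "sift_fp")) {
    if (!.panel_identical(a$panel, b$panel))
      stop("panel mismatch: fingerprints were built on different panels")
    a <- a$bits; b <- b$bits
  }
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) {
    warning("Tanimoto of two all-zero fingerprints is undefined; returning 0")
    return(0)
  }
  sum(a & b) / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fps List of `sift_fp` objects sharing one panel.
#' @return A `sift_simmat`: symmetric matrix of Tanimoto coefficients
#'   with complex ids as dimnames.
#' @export
sift_matrix <- function(fps) {
  stopifnot(length(fps) >= 2)
  for (f in fps[-1])
    if (!.panel_identical(fps[[1]]$panel, f$panel))
      stop("panel mismatch: all fingerprints must share one panel")
  ids <- vapply(fps, function(f) f$complex_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate complex ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  B <- do.call(rbind, lapply(fps, function(f) f$bits))
  inter <- tcrossprod(B)
  ones <- rowSums(B)
  uni <- outer(ones, ones, "+") - inter
  m <- ifelse(uni == 0, 0, inter / uni)
  if (any(uni == 0))
    warning("all-zero fingerprint pair(s); their Tanimoto set to 0")
  dimnames(m) <- list(ids, ids)
  class(m) <- c("sift_simmat", class(m))
  m
}

#' Serialize fingerprints to a self-describing text file
#'
#' Header lines (prefixed `#`) carry the bit-block layout and the panel
#' (chain, seqnum, icode, resname, tab-separated); body lines are
#' `id<TAB>bitstring` with the bit string as 0/1 characters.
#'
#' @param fps List of `sift_fp`.
#' @param file Path.
#' @export
write_sifts <- function(fps, file) {
  panel <- fps[[1]]$panel
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("#layout\t", paste(SIFT_KINDS, collapse = ",")), con)
  for (i in seq_len(nrow(panel)))
    writeLines(paste("#panel", panel$chain[i], panel$seqnum[i],
                     panel$icode[i], panel$resname[i], sep = "\t"), con)
  for (f in fps)
    writeLines(paste0(f$complex_id, "\t", paste(f$bits, collapse = "")), con)
  invisible(file)
}

#' Read fingerprints written by [write_sifts()]
#'
#' @param file Path.
#' @return List of `sift_fp`.
#' @export
read_sifts <- function(file) {
  lines <- readLines(file, warn = FALSE)
  pan <- lines[startsWith(lines, "#panel")]
  parts <- strsplit(pan, "\t", fixed = TRUE)
  panel <- data.frame(
    chain = vapply(parts, `[`, "", 2),
    seqnum = as.integer(vapply(parts, `[`, "", 3)),
    icode = vapply(parts, `[`, "", 4),
    resname = vapply(parts, `[`, "", 5), stringsAsFactors = FALSE)
  class(panel) <- c("sift_panel", "data.frame")
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  lapply(strsplit(body, "\t", fixed = TRUE), function(p) {
    bits <- as.integer(strsplit(p[2], "")[[1]])
    if (length(bits) != 9 * nrow(panel))
      stop("bit string length ", length(bits), " does not match panel (",
           9 * nrow(panel), " expected)")
    structure(list(complex_id = p[1], panel = panel, bits = bits),
              class = "sift_fp")
  })
}

#' Long-format view of a fingerprint for human inspection
#'
#' @param fp A `sift_fp`.
#' @return Data frame with one row per (panel residue, class) set bit.
#' @export
sift_long <- function(fp) {
  set <- which(fp$bits == 1L)
  block <- (set - 1L) %/% 9L + 1L
  kind <- (set - 1L) %% 9L + 1L
  data.frame(chain = fp$panel$chain[block], seqnum = fp$panel$seqnum[block],
             icode = fp$panel$icode[block],
             resname = fp$panel$resname[block],
             kind = SIFT_KINDS[kind], stringsAsFactors = FALSE)
}
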