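test_that("percentile filter retains ceiling(fraction*n) best ids", {
  set.seed(4)
  scores <- data.frame(id = sprintf("c%03d", 1:100), score = rnorm(100))
  kept <- percentile_filter(scores, 0.02)
  expect_length(kept, 2)
  expect_equal(sort(kept),
               sort(scores$id[order(scores$score)][1:2]))
  expect_equal(percentile_filter(scores, 1.0),
               scores$id[order(scores$score, scores$id)])
  # ties break by id order
  tied <- data.frame(id = c("d", "b", "a", "c"), score = rep(1, 4))
  expect_equal(percentile_filter(tied, 0.5), c("a", "b"))
  expect_error(percentile_filter(data.frame(id = "a", score = NaN), 0.5),
               "NaN")
})

test_that("staged funnels compose as ceiling(f2 * ceiling(f1 * n))", {
  cfg <- funnel_config(c(htvs = 0.02, sp = 0.20))
  set.seed(11)
  for (n in c(100, 537, 1000)) {
    scores <- data.frame(id = sprintf("m%04d", seq_len(n)),
                         score = rnorm(n))
    out <- run_funnel(scores, cfg)
    n1 <- ceiling(0.02 * n)
    expect_length(out$htvs, n1)
    expect_length(out$sp, ceiling(0.20 * n1))
    expect_length(out$final, ceiling(0.20 * n1))
    expect_true(all(out$sp %in% out$htvs))
  }
  expect_error(funnel_config(c(a = 0, b = 0.5)))
  expect_error(funnel_config(c(0.1, 0.2)))
})

test_that("hits anchor to references through joint clustering", {
  pb <- make_planted_bitstrings(n_clusters = 3, members = 9, length = 225,
                                flip_prob = 0.03, seed = 19)
  # planted cluster 1 plays the reference panel; a hit identical to a
  # reference must co-cluster with it at any k < n
  refs <- pb$fps[pb$labels == 1]
  hit <- refs[[1]]
  hit$complex_id <- "hit_same"
  res <- anchor_to_references(list(hit), refs, k = 3)
  expect_true(res$anchored)
  expect_true(grepl(refs[[1]]$complex_id, res$cocluster_refs))
  # a hit orthogonal to every reference is not anchored at the planted k
  stranger <- pb$fps[pb$labels == 2][[1]]
  stranger$complex_id <- "hit_far"
  both <- anchor_to_references(list(hit, stranger),
                               c(refs, pb$fps[pb$labels == 3]), k = 3)
  expect_true(both$anchored[both$id == "hit_same"])
  expect_false(both$anchored[both$id == "hit_far"])
})

test_that("a 25-reference panel emulation anchors the planted hits", {
  pb <- make_planted_bitstrings(n_clusters = 2, members = 25, length = 225,
                                flip_prob = 0.03, seed = 29)
  refs <- pb$fps[pb$labels == 1][1:25]
  hits <- pb$fps[pb$labels == 1][1:5]     # same binding pattern as refs
  for (i in seq_along(hits)) hits[[i]]$complex_id <- paste0("hit", i)
  dec <- pb$fps[pb$labels == 2][1:5]      # different pattern
  for (i in seq_along(dec)) dec[[i]]$complex_id <- paste0("dec", i)
  res <- anchor_to_references(c(hits, dec), refs, k = 2)
  expect_true(all(res$anchored[grepl("^hit", res$id)]))
  expect_false(any(res$anchored[grepl("^dec", res$id)]))
})

test_that("buried fraction counts enclosed ligand atoms", {
  cage <- make_cavity_structure(1)
  bz <- as_atoms(benzene_xyz())
  expect_equal(buried_fraction(cage, bz), 1.0)
  far <- bz
  far$x <- far$x + 40
  expect_equal(buried_fraction(cage, far), 0.0)
  # half-buried by construction: 6 of 12 atoms within range of one CB
  res <- build_residue("ALA")
  s <- structure(list(id = "half", atoms = res), class = "sift_structure")
  cb <- as.numeric(res[res$name == "CB", c("x", "y", "z")])
  near <- sweep(benzene_xyz(), 2, cb + c(0, 0, 3), "+")
  farr <- sweep(benzene_xyz(), 2, cb + c(0, 0, 30), "+")
  lig <- as_atoms(rbind(near, farr))
  expect_equal(buried_fraction(s, lig), 0.5)
})

test_that("triage criteria evaluate anchors, co-clustering and burial", {
  crit <- triage_criteria(
    anchor_residues = list("A:342" = c("hbond_donor", "hbond_acceptor"),
                           "A:288" = c("charged", "hbond_donor",
                                       "hbond_acceptor")),
    require_reference_cocluster = FALSE)
  rec_s342 <- data.frame(chain = "A", seqnum = 342, icode = "",
                         resname = "SER", kind = "hbond_donor",
                         ligand_atom = "O1", residue_atom = "N",
                         distance = 2.9, angle = 150,
                         stringsAsFactors = FALSE)
  rep1 <- apply_criteria(list(id = "p1", records = rec_s342), criteria = crit)
  expect_true(rep1$verdict)                      # S342 alone suffices
  rep0 <- apply_criteria(list(id = "p0",
                              records = rec_s342[0, ]), criteria = crit)
  expect_false(rep0$verdict)
  expect_false(rep0$checks$anchor$pass)
  # failing only the buried-fraction proxy: anchor true, verdict false
  crit2 <- triage_criteria(anchor_residues = list("A:342" = "hbond_donor"),
                           require_reference_cocluster = FALSE,
                           min_buried_fraction = 0.8)
  rep2 <- apply_criteria(list(id = "p2", records = rec_s342, buried = 0.4),
                         criteria = crit2)
  expect_true(rep2$checks$anchor$pass)
  expect_false(rep2$checks$buried$pass)
  expect_false(rep2$verdict)
})

test_that("adding interaction records never flips a pass to a fail", {
  crit <- triage_criteria(anchor_residues = list("A:1" = "contact"),
                          require_reference_cocluster = FALSE)
  base <- data.frame(chain = "A", seqnum = 1, icode = "", resname = "ALA",
                     kind = "contact", ligand_atom = "C1",
                     residue_atom = "CB", distance = 4, angle = NA,
                     stringsAsFactors = FALSE)
  was_pass <- apply_criteria(list(id = "p", records = base),
                             criteria = crit)$verdict
  expect_true(was_pass)
  set.seed(3)
  for (i in 1:10) {
    extra <- data.frame(chain = "A", seqnum = sample(1:5, 1), icode = "",
                        resname = "ALA", kind = sample(SIFT_KINDS, 1),
                        ligand_atom = "C2", residue_atom = "CB",
                        distance = runif(1, 2, 4.5), angle = NA,
                        stringsAsFactors = FALSE)
    base <- rbind(base, extra)
    expect_true(apply_criteria(list(id = "p", records = base),
                               criteria = crit)$verdict)
  }
})

test_that("anchor residues must belong to the panel when one is given", {
  crit <- triage_criteria(anchor_residues = list("B:999" = "contact"),
                          require_reference_cocluster = FALSE)
  tc <- make_toy_complex("contact", seed = 1)
  expect_error(apply_criteria(list(id = "p", records = tc$records[0, ]),
                              criteria = crit, panel = tc$panel),
               "absent from panel")
})
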