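test_that("the peptide length boundary is exact at 30 residues", {
  cfg <- pipeline_config()
  mk_chain <- function(n) {
    fold <- generate_toy_fold(n, seed = 41)
    polymer_chain("P", fold$sequence, fold$atoms, entity_id = "9")
  }
  expect_true(is_peptide(mk_chain(29L), cfg))
  expect_false(is_peptide(mk_chain(30L), cfg))
  # across a whole census: no chain of length >= 30 ever registers
  for (n in c(8L, 15L, 29L, 30L, 31L, 60L)) {
    expect_identical(is_peptide(mk_chain(n), cfg), n < 30L)
  }
  # DNA chains are never peptides regardless of length
  dna <- polymer_chain("D", "ACGT", data.frame(
    seq_pos = 1:4, resname = c("DA", "DC", "DG", "DT"), atom = "P",
    element = "P", x = 3.4 * (0:3), y = 0, z = 0, occupancy = 1,
    altloc = ""), polymer_type = "DNA", entity_id = "9")
  expect_false(is_peptide(dna, cfg))
})

test_that("peptide interfaces use the OR rule and the 75% assignment", {
  fx <- build_peptide_complex("PQ1", seed = 42)
  doms <- ingest_annotations(fx$entry, fx$annotations)
  pis <- find_peptide_interfaces(fx$entry, doms)
  expect_length(pis, 1L)
  expect_true(all(pis[[1L]]$hmm_sites %in% 1:40))

  # C-beta clause alone (no atomic contact within 5 A) still qualifies:
  # domain and peptide helices at 14 A axis separation
  dom <- generate_toy_fold(40, seed = 43)
  pep <- generate_toy_fold(8, seed = 44, origin = c(14, 0, 24))
  e <- crystal_entry(
    "PQ2", list(polymer_chain("A", dom$sequence, dom$atoms,
                              entity_id = "1"),
                polymer_chain("P", pep$sequence, pep$atoms,
                              entity_id = "2")),
    cell = unit_cell(120, 120, 120), space_group = "P 1")
  ann <- data.frame(entry_id = "PQ2", asym_id = "A",
                    pfam_acc = "PF99999", pfam_id = "TOYD", clan = "",
                    intervals = "1-40", hmm_length = 40,
                    hmm_map = paste(sprintf("%d:%d", 1:40, 1:40),
                                    collapse = ","),
                    uniprot = "P1", species = "s")
  doms2 <- ingest_annotations(e, ann)
  ua <- make_unit(e, "A", domain = doms2[[1L]])
  up <- make_unit(e, "P")
  cs <- contact_set(ua, up)
  expect_gte(cs$n_cbeta12, 10L)
  expect_identical(cs$n_atom5, 0L)
  expect_true(is_interacting(cs, "peptide"))
  expect_false(is_interacting(cs, "chain"))
  pis2 <- find_peptide_interfaces(e, doms2)
  expect_length(pis2, 1L)

  # 75% rule: peptide snug against domain A, grazing domain B
  pep3 <- generate_toy_fold(8, seed = 45, origin = c(10, 0, 24))
  domB <- generate_toy_fold(40, seed = 46, origin = c(23.5, 0, 0))
  e3 <- crystal_entry(
    "PQ3", list(polymer_chain("A", dom$sequence, dom$atoms,
                              entity_id = "1"),
                polymer_chain("B", domB$sequence, domB$atoms,
                              entity_id = "2"),
                polymer_chain("P", pep3$sequence, pep3$atoms,
                              entity_id = "3")),
    cell = unit_cell(150, 150, 150), space_group = "P 1")
  ann3 <- rbind(ann, ann)
  ann3$entry_id <- "PQ3"
  ann3$asym_id <- c("A", "B")
  doms3 <- ingest_annotations(e3, ann3)
  pis3 <- find_peptide_interfaces(e3, doms3)
  n5 <- vapply(pis3, function(p) p$contacts$n_atom5, numeric(1L))
  chains <- vapply(pis3, `[[`, character(1L), "domain_asym")
  if (length(unique(chains)) > 1L) {
    # both sides seen: the dominant side must hold >= 75% of contacts,
    # otherwise find_peptide_interfaces would have kept only one
    expect_lt(max(tapply(n5, chains, sum)) / sum(n5), 0.75)
  } else {
    expect_identical(unique(chains), "A")
  }
})

test_that("HMM superposition recovers known transforms and matches the quaternion oracle", {
  fx <- build_peptide_complex("SP1", seed = 47)
  doms <- ingest_annotations(fx$entry, fx$annotations)
  pi1 <- find_peptide_interfaces(fx$entry, doms)[[1L]]
  ca <- pi1$dom_hmm_ca
  # identity on itself
  self <- superpose_by_hmm(ca, ca)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$R, diag(3), tolerance = 1e-9)
  # apply a known rigid transform and recover its inverse
  set.seed(48)
  ang <- stats::runif(3, 0, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0,
                 -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, 3)
  R0 <- Rz %*% Rx
  t0 <- c(5, -3, 11)
  moved <- apply_transform(ca, R0, t0)
  rownames(moved) <- rownames(ca)
  fit <- superpose_by_hmm(ca, moved)
  expect_lt(fit$rmsd, 1e-9)
  back <- apply_transform(moved, fit$R, fit$t)
  expect_lt(max(abs(back - ca)), 1e-6)
  # independent quaternion-method oracle agrees
  qfit <- oracle_quaternion_fit(moved, ca)
  expect_lt(abs(fit$rmsd - qfit$rmsd), 1e-6)
  expect_equal(fit$R, qfit$R, tolerance = 1e-6)
  # fewer than 3 shared positions is an error
  expect_error(superpose_by_hmm(ca[1:2, , drop = FALSE], ca),
               "fewer than 3")
})

test_that("peptide RMSD is zero for shifted copies and symmetric otherwise", {
  cfg <- pipeline_config()
  fx <- build_peptide_complex("PR1", seed = 49)
  doms <- ingest_annotations(fx$entry, fx$annotations)
  p1 <- find_peptide_interfaces(fx$entry, doms)[[1L]]
  self <- peptide_rmsd(p1, p1, cfg)
  expect_lt(self$rmsd, 1e-9)
  expect_identical(self$offset, 0L)

  # same binding mode, peptide extended by two leading residues
  # (geometric phase -2 puts residue 3 of the long copy where residue 1
  # of the short one sits)
  p2 <- p1
  long_pep <- generate_toy_fold(10, seed = 50, phase = -2,
                                origin = c(9.5, 0,
                                           1.5 * (40 / 2 - 8 / 2)))
  ca <- long_pep$atoms[long_pep$atoms$atom == "CA", ]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  rownames(xyz) <- as.character(ca$seq_pos)
  p2$pep_ca <- xyz
  r <- peptide_rmsd(p1, p2, cfg)
  expect_lt(r$rmsd, 1e-9)
  expect_identical(abs(r$offset), 2L)
  r_ba <- peptide_rmsd(p2, p1, cfg)
  expect_lt(abs(r$rmsd - r_ba$rmsd), 1e-6)

  # opposite binding faces are > 10 A apart
  fx2 <- build_peptide_complex("PR2", seed = 49, mode = "back")
  doms2 <- ingest_annotations(fx2$entry, fx2$annotations)
  pb <- find_peptide_interfaces(fx2$entry, doms2)[[1L]]
  expect_gt(peptide_rmsd(p1, pb, cfg)$rmsd, cfg$pep_max_rmsd)
})

test_that("binding-mode clustering obeys the N_hmm and RMSD constraints", {
  cfg <- pipeline_config()
  # 4 homologs sharing one groove -> one cluster
  pis <- list(); parent <- NULL
  for (k in 1:4) {
    fx <- build_peptide_complex(sprintf("CL%d", k), seed = 50 + k,
                                parent_sequence = parent,
                                mutation_rate = if (k == 1L) 0 else 0.2)
    if (k == 1L) parent <- fx$entry$chains$A$sequence
    doms <- ingest_annotations(fx$entry, fx$annotations)
    pis <- c(pis, find_peptide_interfaces(fx$entry, doms))
  }
  cl <- cluster_peptide_interfaces(pis, cfg)
  expect_length(cl, 1L)
  expect_length(cl[[1L]]$member_ids, 4L)
  expect_gte(length(cl[[1L]]$shared_hmm_sites), cfg$pep_min_nhmm)

  # add a second binding mode on the opposite face -> two clusters
  fxb <- build_peptide_complex("CLB", seed = 55, mode = "back",
                               parent_sequence = parent,
                               mutation_rate = 0.2)
  domsb <- ingest_annotations(fxb$entry, fxb$annotations)
  pis2 <- c(pis, find_peptide_interfaces(fxb$entry, domsb))
  cl2 <- cluster_peptide_interfaces(pis2, cfg)
  expect_length(cl2, 2L)
  expect_identical(sort(lengths(lapply(cl2, `[[`, "member_ids"))),
                   c(1L, 4L))

  # interfaces sharing only 2 HMM sites never merge even at RMSD 0
  pa <- fake_pep_iface("sa", sites = c(1, 2, 3, 4),
                       pep_ca = cbind(0:4 * 3.8, 0, 0))
  pb <- fake_pep_iface("sb", sites = c(3, 4, 30, 31),
                       pep_ca = cbind(0:4 * 3.8, 0, 0))
  expect_length(cluster_peptide_interfaces(list(pa, pb), cfg), 2L)
  # three shared sites do merge at RMSD 0
  pc <- fake_pep_iface("sc", sites = c(2, 3, 4, 40),
                       pep_ca = cbind(0:4 * 3.8, 0, 0))
  expect_length(cluster_peptide_interfaces(list(pa, pc), cfg), 1L)
  # clustering is invariant under input permutation
  cl_fwd <- cluster_peptide_interfaces(pis2, cfg)
  cl_rev <- cluster_peptide_interfaces(rev(pis2), cfg)
  expect_identical(lapply(cl_fwd, function(x) sort(x$member_ids)),
                   lapply(cl_rev, function(x) sort(x$member_ids)))
})
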