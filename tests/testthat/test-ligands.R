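mk_dom_entry <- function(id = "LD1", seed = 61, n_res = 20,
                         ligands = list()) {
  fold <- generate_toy_fold(n_res, seed = seed)
  e <- crystal_entry(
    id, list(polymer_chain("A", fold$sequence, fold$atoms,
                           entity_id = "1")),
    cell = unit_cell(100, 100, 100), space_group = "P 1",
    ligands = ligands)
  ann <- data.frame(entry_id = id, asym_id = "A", pfam_acc = "PF99999",
                    pfam_id = "TOYD", clan = "", intervals
                    = sprintf("1-%d", n_res), hmm_length = n_res,
                    hmm_map = paste(sprintf("%d:%d", seq_len(n_res),
                                            seq_len(n_res)),
                                    collapse = ","),
                    uniprot = "P1", species = "s")
  list(entry = e, dom = ingest_annotations(e, ann)[[1L]], fold = fold)
}

lig_at <- function(comp, x, y, z, id = "L1") {
  ligand_instance(comp, data.frame(atom = "C1", element = "C", x = x,
                                   y = y, z = z, occupancy = 1,
                                   altloc = ""), instance_id = id)
}

test_that("the 4.5 A ligand contact rule is inclusive and water-free", {
  base <- mk_dom_entry()
  cb <- base$fold$atoms[base$fold$atoms$atom == "CB" &
                          base$fold$atoms$seq_pos == 5L, ]
  place <- function(dist) {
    dir <- c(cb$x, cb$y, 0); dir <- dir / sqrt(sum(dir^2))
    lig_at("LIG", cb$x + dir[1L] * dist, cb$y + dir[2L] * dist, cb$z)
  }
  e44 <- mk_dom_entry(ligands = list(place(4.4)))
  p44 <- ligand_contact_profile(e44$entry, e44$dom,
                                e44$entry$ligands[[1L]])
  expect_false(is.null(p44))
  expect_true(5L %in% p44$hmm_positions)
  # exactly at the cutoff counts (axis-aligned, exactly representable)
  ch <- polymer_chain("A", "A", data.frame(
    seq_pos = 1L, resname = "ALA", atom = c("CA", "CB"), element = "C",
    x = c(-1.5, 0), y = 0, z = 0, occupancy = 1, altloc = ""),
    entity_id = "1")
  e45 <- crystal_entry("B45", list(ch), cell = unit_cell(50, 50, 50),
                       space_group = "P 1",
                       ligands = list(lig_at("LIG", 4.5, 0, 0)))
  ann45 <- data.frame(entry_id = "B45", asym_id = "A",
                      pfam_acc = "PF99999", pfam_id = "TOYD", clan = "",
                      intervals = "1-1", hmm_length = 1,
                      hmm_map = "1:1", uniprot = "P1", species = "s")
  d45 <- ingest_annotations(e45, ann45)[[1L]]
  expect_false(is.null(ligand_contact_profile(e45, d45,
                                              e45$ligands[[1L]])))
  # just beyond is rejected
  e46 <- mk_dom_entry(ligands = list(place(4.6)))
  expect_null(ligand_contact_profile(e46$entry, e46$dom,
                                     e46$entry$ligands[[1L]]))
  # water is excluded even in direct contact
  wat <- lig_at("HOH", cb$x + 1.0, cb$y, cb$z, id = "W")
  ew <- mk_dom_entry(ligands = list(wat))
  expect_true(ew$entry$ligands[[1L]]$is_water)
  expect_null(ligand_contact_profile(ew$entry, ew$dom,
                                     ew$entry$ligands[[1L]]))
})

test_that("profiles are invariant to ligand atom order", {
  lx <- build_ligand_entry("LO1", seed = 62)
  doms <- ingest_annotations(lx$entry, lx$annotations)
  lig <- lx$entry$ligands[[1L]]
  p1 <- ligand_contact_profile(lx$entry, doms[[1L]], lig)
  lig2 <- lig
  lig2$atoms <- lig$atoms[rev(seq_len(nrow(lig$atoms))), ]
  p2 <- ligand_contact_profile(lx$entry, doms[[1L]], lig2)
  expect_identical(p1$hmm_positions, p2$hmm_positions)
  expect_identical(p1$n_atomic_contacts, p2$n_atomic_contacts)
})

test_that("designed substrate and effector sites give two ligand clusters", {
  lx <- build_ligand_entry("LC1", seed = 63)
  doms <- ingest_annotations(lx$entry, lx$annotations)
  profs <- ligand_profiles(lx$entry, doms)
  expect_length(profs, 2L)  # two sites; water excluded
  cl <- cluster_ligand_sites(profs)
  expect_length(cl, 2L)
  # identical-site cofactors collapse into one cluster
  dup <- c(profs[1L], profs[1L])
  dup[[2L]]$instance_id <- "LX"
  expect_length(cluster_ligand_sites(dup), 1L)
  # disjoint sites have Jaccard 0 and never merge
  expect_equal(xtalclust:::.jaccard(as.character(profs[[1L]]$hmm_positions),
                                    as.character(profs[[2L]]$hmm_positions)),
               0)
})

test_that("nucleic acids ride the ligand machinery via assemblies", {
  nx <- build_nucleic_entry("NA1", seed = 64)
  doms <- ingest_annotations(nx$entry, nx$annotations)
  sel <- select_nucleic_interface(nx$entry, doms)
  expect_length(sel, 1L)
  expect_s3_class(sel[[1L]], "xc_ligand_profile")  # same code path
  expect_identical(sel[[1L]]$ligand_class, "DNA")
  expect_gt(length(sel[[1L]]$hmm_positions), 0L)
  expect_identical(sel[[1L]]$assembly_id, "1")

  # two assemblies: the one with more contacted positions wins
  e <- nx$entry
  far <- e$chains$D
  far$asym_id <- "E"; far$auth_id <- "E"
  far$atoms <- far$atoms[1:6, ]  # shorter strand -> fewer positions
  e2 <- crystal_entry(e$entry_id, c(e$chains, list(E = far)),
                      cell = e$cell, space_group = e$space_group,
                      sym_ops = e$sym_ops, assemblies = list(
    assembly_def("1", "author", data.frame(
      asym_id = c("A", "E"), op_index = 1L, si = 0L, sj = 0L, sk = 0L)),
    assembly_def("2", "author", data.frame(
      asym_id = c("A", "D"), op_index = 1L, si = 0L, sj = 0L, sk = 0L))))
  sel2 <- select_nucleic_interface(e2, doms)
  expect_identical(sel2[[1L]]$instance_id, "D")  # max-position rule

  # exact tie: smaller assembly id is chosen
  e3 <- crystal_entry(e$entry_id, e$chains, cell = e$cell,
                      space_group = e$space_group, sym_ops = e$sym_ops,
                      assemblies = list(
    assembly_def("2", "author", data.frame(
      asym_id = c("A", "D"), op_index = 1L, si = 0L, sj = 0L, sk = 0L)),
    assembly_def("1", "author", data.frame(
      asym_id = c("A", "D"), op_index = 1L, si = 0L, sj = 0L, sk = 0L))))
  sel3 <- select_nucleic_interface(e3, doms)
  expect_identical(sel3[[1L]]$assembly_id, "1")

  # no assemblies: asymmetric-unit fallback with a warning
  e4 <- crystal_entry(e$entry_id, e$chains, cell = e$cell,
                      space_group = e$space_group, sym_ops = e$sym_ops)
  expect_warning(sel4 <- select_nucleic_interface(e4, doms),
                 "asymmetric unit")
  expect_length(sel4, 1L)
})
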