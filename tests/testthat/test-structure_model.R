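test_that("mmCIF round trip preserves chains, cell, operators and assemblies", {
  fx <- build_synthetic_crystal("RT1", seed = 7)
  path <- withr::local_tempfile(fileext = ".cif")
  write_entry_cif(fx$entry, path)
  e2 <- read_entry(path)
  expect_s3_class(e2, "xc_entry")
  expect_identical(sort(names(e2$chains)), c("A", "B"))
  expect_identical(e2$chains$A$sequence, fx$entry$chains$A$sequence)
  expect_identical(e2$chains$B$sequence, fx$entry$chains$B$sequence)
  expect_equal(unlist(e2$cell), unlist(fx$entry$cell), tolerance = 1e-6)
  expect_identical(length(e2$sym_ops), length(fx$entry$sym_ops))
  expect_equal(length(e2$assemblies), 1L)
  expect_identical(e2$assemblies[[1L]]$provenance, "author")
  expect_equal(nrow(e2$assemblies[[1L]]$members), 2L)
  # coordinates survive at the printed precision
  expect_equal(e2$chains$A$atoms$x, fx$entry$chains$A$atoms$x,
               tolerance = 1e-4)
  # second round trip is exact
  path2 <- withr::local_tempfile(fileext = ".cif")
  write_entry_cif(e2, path2)
  expect_identical(readLines(path)[-1], readLines(path2)[-1])
})

test_that("minimal P1 mmCIF parses to one chain and the identity operator", {
  txt <- c(
    "data_MIN1", "_entry.id MIN1",
    "_cell.length_a 30.0", "_cell.length_b 30.0", "_cell.length_c 30.0",
    "_cell.angle_alpha 90.0", "_cell.angle_beta 90.0",
    "_cell.angle_gamma 90.0",
    "_symmetry.space_group_name_H-M 'P 1'",
    "loop_", "_entity_poly.entity_id", "_entity_poly.type",
    "_entity_poly.pdbx_seq_one_letter_code_can",
    "_entity_poly.pdbx_strand_id",
    "1 'polypeptide(L)' AG A",
    "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_entity_id",
    "_atom_site.label_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.auth_seq_id", "_atom_site.auth_asym_id",
    "ATOM 1 C CA . ALA A 1 1 1.0 2.0 3.0 1.00 1 A",
    "ATOM 2 C CA . GLY A 1 2 4.0 5.0 6.0 1.00 2 A")
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(txt, path)
  e <- read_entry(path)
  expect_length(e$chains, 1L)
  expect_length(e$sym_ops, 1L)
  expect_true(is_crystallographic(e))
  expect_identical(e$chains$A$sequence, "AG")
  expect_identical(e$chains$A$polymer_type, "polypeptide")
})

test_that("waters are flagged and a cell without symmetry blocks lattice work", {
  lx <- build_ligand_entry("WAT1", seed = 3)
  waters <- Filter(function(l) l$is_water, lx$entry$ligands)
  expect_length(waters, 1L)
  expect_identical(waters[[1L]]$comp_id, "HOH")
  # same entry but no space group and no operator records
  fx <- build_synthetic_crystal("NOSG", seed = 3)
  path <- withr::local_tempfile(fileext = ".cif")
  write_entry_cif(fx$entry, path)
  txt <- readLines(path)
  i0 <- grep("_space_group_symop.id", txt, fixed = TRUE) - 1L
  txt <- txt[-(i0:(i0 + 4L))]          # the whole operator loop
  txt <- txt[!grepl("space_group_name", txt)]
  writeLines(txt, path)
  e <- read_entry(path)
  expect_false(is_crystallographic(e))
  expect_error(expand_lattice(e), "non-crystallographic")
  # still usable for ligand-style workflows
  expect_length(e$chains, 2L)
})

test_that("annotation ingest validates rows and computes coverage", {
  fx <- build_synthetic_crystal("ANN1", seed = 2, n_res = 40)
  e <- fx$entry
  doms <- ingest_annotations(e, fx$annotations)
  expect_length(doms, 2L)
  expect_equal(doms[[1L]]$coverage, 1)
  expect_identical(domain_positions(doms[[1L]]), 1:40)

  split_row <- fx$annotations[1L, ]
  split_row$intervals <- "1-10;21-30"
  split_row$hmm_map <- paste(sprintf("%d:%d", c(1:10, 21:30), 1:20),
                             collapse = ",")
  split_row$hmm_length <- "20"
  d <- ingest_annotations(e, split_row)[[1L]]
  expect_equal(nrow(d$intervals), 2L)
  expect_equal(d$coverage, 1)
  expect_identical(domain_positions(d), c(1:10, 21:30))

  bad_chain <- fx$annotations[1L, ]; bad_chain$asym_id <- "Z"
  expect_error(ingest_annotations(e, bad_chain), "absent from entry")
  overlap <- split_row; overlap$intervals <- "1-10;5-30"
  expect_error(ingest_annotations(e, overlap), "overlapping")
  oor <- fx$annotations[1L, ]
  oor$hmm_map <- sub("40:40", "40:99", oor$hmm_map)
  expect_error(ingest_annotations(e, oor), "outside \\[1")
})

test_that("architectures are ordered by interval start and repeats kept", {
  fx <- build_synthetic_crystal("ARC1", seed = 4, n_res = 40)
  e <- fx$entry
  mk_row <- function(pfam, iv, map_from) {
    r <- fx$annotations[1L, ]
    r$pfam_id <- pfam
    r$intervals <- iv
    n <- diff(as.integer(strsplit(iv, "-")[[1L]])) + 1L
    r$hmm_length <- as.character(n)
    r$hmm_map <- paste(sprintf("%d:%d", map_from + seq_len(n) - 1L,
                               seq_len(n)), collapse = ",")
    r
  }
  two <- rbind(mk_row("KIN", "5-20", 5L), mk_row("SH2", "25-38", 25L))
  doms <- ingest_annotations(e, two)
  expect_identical(unname(derive_architectures(e, doms)["A"]),
                   "(KIN)_(SH2)")
  # permutation of the input list does not change the rendering
  expect_identical(unname(derive_architectures(e, rev(doms))["A"]),
                   "(KIN)_(SH2)")
  # tandem repeat preserved
  rep2 <- rbind(mk_row("ACT", "1-15", 1L), mk_row("ACT", "20-34", 20L))
  doms2 <- ingest_annotations(e, rep2)
  expect_identical(unname(derive_architectures(e, doms2)["A"]),
                   "(ACT)_(ACT)")
  # singleton and empty
  one <- ingest_annotations(e, mk_row("ACT", "1-15", 1L))
  arch <- derive_architectures(e, one)
  expect_identical(unname(arch["A"]), "(ACT)")
  expect_identical(unname(arch["B"]), "")
  expect_identical(entry_arch_key(c(A = "(X)", B = "(X)")), "(X)")
  expect_identical(entry_arch_key(c(A = "(Y)", B = "(X)")), "(X)|(Y)")
})

test_that("altloc policy keeps highest occupancy, ties alphabetical", {
  at <- data.frame(
    seq_pos = c(1L, 1L, 1L, 1L), resname = "ALA",
    atom = c("CA", "CA", "CB", "CB"), element = "C",
    x = c(0, 9, 0, 9), y = 0, z = 0,
    occupancy = c(0.4, 0.6, 0.5, 0.5), altloc = c("A", "B", "B", "A"),
    stringsAsFactors = FALSE)
  kept <- xtalclust:::.filter_altlocs(at, "seq_pos")
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$x[kept$atom == "CA"], 9)  # higher occupancy wins
  expect_equal(kept$altloc[kept$atom == "CB"], "A")  # tie: alphabetical
})

test_that("every threshold flows from the configuration object", {
  fx <- build_synthetic_crystal("CFG1", seed = 5)
  ua <- make_unit(fx$entry, "A"); ub <- make_unit(fx$entry, "B")
  cs12 <- contact_set(ua, ub, pipeline_config())
  cs8 <- contact_set(ua, ub, pipeline_config(cbeta_cutoff = 8))
  expect_lt(cs8$n_cbeta12, cs12$n_cbeta12)
  # the stricter config propagates into the interaction decision
  weak <- structure(list(pairs = data.frame(), n_cbeta12 = 10L,
                         n_atom5 = 1L), class = "xc_contacts")
  expect_true(is_interacting(weak, "chain", pipeline_config()))
  expect_false(is_interacting(weak, "chain",
                              pipeline_config(min_cbeta_pairs = 11)))
  # config files round-trip and unknown fields are rejected
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("cbeta_cutoff: 8.0", "q_cluster: 0.5"), yml)
  cfg <- read_config(yml)
  expect_equal(cfg$cbeta_cutoff, 8)
  expect_equal(cfg$q_cluster, 0.5)
  expect_equal(cfg$atom_cutoff, 5)
  writeLines("not_a_field: 1", yml)
  expect_error(read_config(yml), "unknown configuration field")
})

test_that("legacy PDB dialect reads CRYST1 and atoms via bio3d", {
  skip_if_not_installed("bio3d")
  fx <- build_synthetic_crystal("PDB1", seed = 6, n_res = 12,
                                tight_gap = 100, cell_padding = 100)
  e <- fx$entry
  path <- withr::local_tempfile(fileext = ".pdb")
  con <- file(path, "w")
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
    e$cell$a, e$cell$b, e$cell$c, 90, 90, 90, "P 1", 1), con)
  serial <- 0L
  for (ch in e$chains) {
    for (i in seq_len(nrow(ch$atoms))) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, ch$atoms$atom[i], ch$atoms$resname[i], ch$asym_id,
        ch$atoms$seq_pos[i], ch$atoms$x[i], ch$atoms$y[i],
        ch$atoms$z[i], ch$atoms$element[i]), con)
    }
  }
  writeLines("END", con)
  close(con)
  ep <- read_entry(path, dialect = "pdb")
  expect_length(ep$chains, 2L)
  expect_equal(unname(unlist(ep$cell)[1:3]),
               unname(unlist(e$cell)[1:3]), tolerance = 1e-3)
  expect_identical(ep$space_group, "P 1")
  expect_identical(ep$chains$A$sequence, e$chains$A$sequence)
  expect_equal(nrow(ep$chains$A$atoms), nrow(e$chains$A$atoms))
})
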