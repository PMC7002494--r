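test_that("contact detection matches the all-pairs brute-force oracle", {
  cfg <- pipeline_config()
  for (seed in 1:10) {
    e <- random_blob_entry(seed, n_res_a = 10, n_res_b = 10)
    ua <- make_unit(e, "A"); ub <- make_unit(e, "B")
    cs <- contact_set(ua, ub, cfg)
    orc <- oracle_contacts(ua, ub, cfg)
    got <- sort(paste(cs$pairs$seq_i, cs$pairs$seq_j))
    want <- sort(vapply(orc$pairs, paste, character(1L), collapse = " "))
    expect_identical(got, want, label = sprintf("seed %d pair list", seed))
    expect_identical(cs$n_cbeta12, orc$n_cbeta12)
    expect_identical(cs$n_atom5, orc$n_atom5)
  }
})

test_that("contact sets are symmetric and edge cases error cleanly", {
  e <- random_blob_entry(99)
  ua <- make_unit(e, "A"); ub <- make_unit(e, "B")
  ab <- contact_set(ua, ub); ba <- contact_set(ub, ua)
  expect_identical(ab$n_cbeta12, ba$n_cbeta12)
  expect_identical(ab$n_atom5, ba$n_atom5)
  expect_identical(sort(paste(ab$pairs$seq_i, ab$pairs$seq_j)),
                   sort(paste(ba$pairs$seq_j, ba$pairs$seq_i)))
  # two single-residue chains far beyond every cutoff
  mk1 <- function(id, x) {
    polymer_chain(id, "A", data.frame(
      seq_pos = 1L, resname = "ALA", atom = "CA", element = "C",
      x = x, y = 0, z = 0, occupancy = 1, altloc = ""), entity_id = id)
  }
  e2 <- crystal_entry("FAR", list(mk1("A", 0), mk1("B", 20)),
                      cell = unit_cell(100, 100, 100),
                      space_group = "P 1")
  cs <- contact_set(make_unit(e2, "A"), make_unit(e2, "B"))
  expect_equal(nrow(cs$pairs), 0L)
  # a unit without heavy atoms is rejected
  h_only <- polymer_chain("H", "A", data.frame(
    seq_pos = 1L, resname = "ALA", atom = "H", element = "H",
    x = 0, y = 0, z = 0, occupancy = 1, altloc = ""), entity_id = "H")
  e3 <- crystal_entry("HYD", list(h_only, mk1("B", 3)),
                      cell = unit_cell(50, 50, 50), space_group = "P 1")
  expect_error(make_unit(e3, "H"), "zero heavy atoms")
})

test_that("the interaction rule implements both clauses exactly", {
  mk <- function(ncb, na5) {
    structure(list(pairs = data.frame(), n_cbeta12 = ncb, n_atom5 = na5),
              class = "xc_contacts")
  }
  cases <- list(
    # n_cbeta12, n_atom5, chain/domain expectation
    list(12L, 1L, TRUE),  list(10L, 1L, TRUE),  list(9L, 5L, TRUE),
    list(11L, 0L, FALSE), list(9L, 4L, FALSE),  list(0L, 5L, TRUE),
    list(10L, 0L, FALSE), list(0L, 4L, FALSE))
  for (cs in cases) {
    expect_identical(is_interacting(mk(cs[[1L]], cs[[2L]]), "chain"),
                     cs[[3L]], label = sprintf("chain %d/%d", cs[[1L]],
                                               cs[[2L]]))
    expect_identical(is_interacting(mk(cs[[1L]], cs[[2L]]), "domain"),
                     cs[[3L]], label = sprintf("domain %d/%d", cs[[1L]],
                                               cs[[2L]]))
  }
  # peptide rule: OR between the clauses
  expect_true(is_interacting(mk(10L, 0L), "peptide"))
  expect_true(is_interacting(mk(0L, 5L), "peptide"))
  expect_false(is_interacting(mk(9L, 4L), "peptide"))
})

test_that("distance boundaries are inclusive at 12 and 5 Angstrom", {
  mk_pair <- function(dx) {
    a <- polymer_chain("A", "A", data.frame(
      seq_pos = 1L, resname = "ALA", atom = c("CA", "CB"), element = "C",
      x = c(-1.5, 0), y = 0, z = 0, occupancy = 1, altloc = ""),
      entity_id = "1")
    b <- polymer_chain("B", "A", data.frame(
      seq_pos = 1L, resname = "ALA", atom = c("CA", "CB"), element = "C",
      x = c(dx + 1.5, dx), y = 0, z = 0, occupancy = 1, altloc = ""),
      entity_id = "2")
    e <- crystal_entry("BND", list(a, b), cell = unit_cell(99, 99, 99),
                       space_group = "P 1")
    contact_set(make_unit(e, "A"), make_unit(e, "B"))
  }
  expect_identical(mk_pair(12.0)$n_cbeta12, 1L)   # CB-CB exactly 12.0
  expect_identical(mk_pair(12.001)$n_cbeta12, 0L)
  expect_identical(mk_pair(5.0)$n_atom5, 1L)      # CB-CB exactly 5.0
  expect_identical(mk_pair(5.001)$n_atom5, 0L)
})

test_that("buried surface area behaves physically and matches a dense oracle", {
  cfg <- pipeline_config()
  fx <- build_synthetic_crystal("B1", seed = 11, n_res = 16,
                                tight_gap = 100, cell_padding = 100)
  ua <- make_unit(fx$entry, "A"); ub <- make_unit(fx$entry, "B")
  b <- buried_surface_area(ua, ub, cfg)
  expect_gt(b, 0)
  # independent recomputation at 10x point density
  dense <- pipeline_config(sasa_points = 9600)
  b_dense <- buried_surface_area(ua, ub, dense)
  expect_lt(abs(b - b_dense) / b_dense, 0.02)
  # rigid pull-apart series is monotonically non-increasing
  pulls <- c(0, 2, 5, 10, 30)
  vals <- vapply(pulls, function(dx) {
    ub2 <- ub
    ub2$xyz <- sweep(ub$xyz, 2L, c(dx, 0, 0), "+")
    buried_surface_area(ua, ub2, cfg)
  }, numeric(1L))
  expect_true(all(diff(vals) <= 0.5))
  # far-separated chains bury nothing
  expect_lt(vals[length(vals)], 0.5)
})

test_that("unique-interface enumeration is deterministic and idempotent", {
  fx <- build_synthetic_crystal("U1", seed = 12)
  e <- fx$entry
  run1 <- enumerate_unique_interfaces(e, NULL, "chain",
                                      compute_bsa = FALSE,
                                      assembly_flags = FALSE)
  run2 <- enumerate_unique_interfaces(e, NULL, "chain",
                                      compute_bsa = FALSE,
                                      assembly_flags = FALSE)
  expect_identical(vapply(run1, `[[`, character(1L), "interface_id"),
                   vapply(run2, `[[`, character(1L), "interface_id"))
  expect_identical(lapply(run1, function(x) x$contacts$pairs),
                   lapply(run2, function(x) x$contacts$pairs))
  # designed interface is present exactly once
  designed <- Filter(function(x) {
    x$side_a$asym_id == "A" && x$side_b$asym_id == "B" &&
      x$side_b$op_index == 1L && all(x$side_b$shift == 0L)
  }, run1)
  expect_length(designed, 1L)
})

test_that("domain interfaces derive from chain contacts; intra-chain pairs flagged", {
  fx <- build_synthetic_crystal("D1", seed = 13)
  e <- fx$entry
  doms <- ingest_annotations(e, fx$annotations)
  ch <- enumerate_unique_interfaces(e, NULL, "chain", doms,
                                    compute_bsa = FALSE,
                                    assembly_flags = FALSE)
  dm <- enumerate_unique_interfaces(e, NULL, "domain", doms,
                                    compute_bsa = FALSE,
                                    assembly_flags = FALSE)
  expect_gt(length(dm), 0L)
  chain_pairs <- unique(unlist(lapply(ch, function(x) {
    paste(x$side_a$asym_id, x$side_b$asym_id,
          x$contacts$pairs$seq_i, x$contacts$pairs$seq_j)
  })))
  for (x in dm) {
    expect_true(all(paste(x$side_a$asym_id, x$side_b$asym_id,
                          x$contacts$pairs$seq_i,
                          x$contacts$pairs$seq_j) %in% chain_pairs))
    expect_false(x$intra_chain)
  }
  # a chain with two packed domains yields one intra-chain interface
  # and no chain-level interface
  fold <- generate_toy_fold(40, seed = 14, topology = "hairpin")
  e2 <- crystal_entry(
    "D2", list(polymer_chain("A", fold$sequence, fold$atoms,
                             entity_id = "1")),
    cell = unit_cell(120, 120, 120), space_group = "P 1")
  ann <- rbind(
    data.frame(entry_id = "D2", asym_id = "A", pfam_acc = "PF00001",
               pfam_id = "H1", clan = "", intervals = "1-20",
               hmm_length = 20,
               hmm_map = paste(sprintf("%d:%d", 1:20, 1:20),
                               collapse = ","),
               uniprot = "P1", species = "s"),
    data.frame(entry_id = "D2", asym_id = "A", pfam_acc = "PF00002",
               pfam_id = "H2", clan = "", intervals = "21-40",
               hmm_length = 20,
               hmm_map = paste(sprintf("%d:%d", 21:40, 1:20),
                               collapse = ","),
               uniprot = "P1", species = "s"))
  doms2 <- ingest_annotations(e2, ann)
  ch2 <- enumerate_unique_interfaces(e2, NULL, "chain", doms2,
                                     compute_bsa = FALSE,
                                     assembly_flags = FALSE)
  dm2 <- enumerate_unique_interfaces(e2, NULL, "domain", doms2,
                                     compute_bsa = FALSE,
                                     assembly_flags = FALSE)
  expect_length(ch2, 0L)
  expect_length(dm2, 1L)
  expect_true(dm2[[1L]]$intra_chain)
  expect_identical(dm2[[1L]]$family_key, "H1:H2")
})

test_that("assembly containment distinguishes the deposited dimer from packing", {
  fx <- build_synthetic_crystal("AS1", seed = 15)
  e <- fx$entry
  ifs <- enumerate_unique_interfaces(e, NULL, "chain",
                                     compute_bsa = FALSE,
                                     assembly_flags = FALSE)
  designed <- Filter(function(x) x$side_b$op_index == 1L &&
                       all(x$side_b$shift == 0L), ifs)[[1L]]
  packing <- Filter(function(x) !(x$side_b$op_index == 1L &&
                                    all(x$side_b$shift == 0L)), ifs)[[1L]]
  dimer <- e$assemblies[[1L]]
  expect_true(assembly_contains_interface(designed, dimer, e))
  expect_false(assembly_contains_interface(packing, dimer, e))
  monomer <- assembly_def("m", "author", data.frame(
    asym_id = "A", op_index = 1L, si = 0L, sj = 0L, sk = 0L))
  expect_false(assembly_contains_interface(designed, monomer, e))
})
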