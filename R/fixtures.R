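# Synthetic-crystal generator. Builds stylized helical folds with known
# geometry, places a designed C2 dimer in the asymmetric unit, sizes the
# unit cell so exactly one lattice-contact direction is tight, and emits
# valid mmCIF plus domain-annotation tables and a ground-truth record.
# The generator emulates the study conditions the clustering method
# targets: several crystal forms of homologous proteins sharing one
# biological dimer while each form carries its own packing contacts.

.helix_params <- list(rise = 1.5, twist = 100 * pi / 180, r_ca = 2.26,
                      r_cb = 3.79, r_n = 1.60, r_c = 1.65, r_o = 2.40)

#' Generate a toy helical fold
#'
#' Ideal-geometry alpha-helical backbone (N, CA, C, O) with C-beta
#' placed radially outward; consecutive C-alpha distances are ~3.8 A.
#' The sequence is drawn at random (19 residue types; glycine excluded
#' so every residue carries a C-beta) under the given seed, or mutated
#' from a parent sequence at `mutation_rate`.
#'
#' @param n_res number of residues (>= 8).
#' @param seed RNG seed (fold is bit-reproducible given `n_res`, `seed`
#'   and the placement arguments).
#' @param phase shifts the geometric helix index: residue `i` sits at
#'   the position of index `i + phase` (used to build extended copies
#'   of a peptide).
#' @param axis helix axis, `"z"` or `"y"`.
#' @param rot rigid rotation about the axis, radians, applied before
#'   translation.
#' @param origin translation applied last.
#' @param parent_sequence,mutation_rate mutate a parent instead of
#'   sampling a fresh sequence.
#' @param topology `"helix"` (single straight helix) or `"hairpin"`
#'   (two antiparallel helices side by side, residues split evenly);
#'   the hairpin gives the fold two structurally distinct faces.
#' @param hairpin_sep axis separation of the two hairpin helices, A.
#' @return list with `atoms` (chain atom data.frame) and `sequence`.
#' @export
generate_toy_fold <- function(n_res, seed = 1, phase = 0, axis = "z",
                              rot = 0, origin = c(0, 0, 0),
                              parent_sequence = NULL,
                              mutation_rate = 0,
                              topology = c("helix", "hairpin"),
                              hairpin_sep = 9.5) {
  topology <- match.arg(topology)
  if (n_res < 8L) stop("toy folds need at least 8 residues")
  aa <- setdiff(names(.aa1to3), "G")
  set.seed(seed)
  seq1 <- if (is.null(parent_sequence)) {
    paste(sample(aa, n_res, replace = TRUE), collapse = "")
  } else {
    s <- strsplit(parent_sequence, "")[[1L]]
    mut <- which(stats::runif(length(s)) < mutation_rate)
    for (i in mut) s[i] <- sample(setdiff(aa, s[i]), 1L)
    paste(s, collapse = "")
  }
  hp <- .helix_params
  half <- n_res %/% 2L
  rows <- list()
  for (i in seq_len(n_res)) {
    second <- topology == "hairpin" && i > half
    k <- if (second) i - half else i
    t0 <- k + phase
    x0 <- if (second) hairpin_sep else 0
    zdir <- if (second) -1 else 1
    zoff <- if (second) hp$rise * (half + 1) else 0
    put <- function(name, radius, tt, element) {
      ang <- hp$twist * tt
      rows[[length(rows) + 1L]] <<- data.frame(
        seq_pos = i, resname = .aa1to3[substr(seq1, i, i)],
        atom = name, element = element,
        x = x0 + radius * cos(ang), y = radius * sin(ang),
        z = zoff + zdir * hp$rise * tt,
        occupancy = 1, altloc = "", stringsAsFactors = FALSE)
    }
    put("N", hp$r_n, t0 - 0.33, "N")
    put("CA", hp$r_ca, t0, "C")
    put("C", hp$r_c, t0 + 0.37, "C")
    put("O", hp$r_o, t0 + 0.42, "O")
    put("CB", hp$r_cb, t0, "C")
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  Rz <- matrix(c(cos(rot), sin(rot), 0, -sin(rot), cos(rot), 0, 0, 0, 1),
               3, 3)
  xyz <- xyz %*% t(Rz)
  if (axis == "y") {
    # map local z -> y (right-handed): (x,y,z) -> (x, z, -y)
    xyz <- cbind(xyz[, 1L], xyz[, 3L], -xyz[, 2L])
  } else if (axis != "z") {
    stop("axis must be 'z' or 'y'")
  }
  xyz <- sweep(xyz, 2L, origin, "+")
  atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  list(atoms = atoms, sequence = seq1)
}

# Mirror a chain through the 2-fold axis x = d/2 (parallel to the helix
# axis): (x, y, z) -> (d - x, -y, z) for a z-axis fold. Produces the
# designed isologous dimer partner.
.c2_partner <- function(atoms, d) {
  atoms$x <- d - atoms$x
  atoms$y <- -atoms$y
  atoms
}

.fixture_chain <- function(asym_id, fold, entity_id, uniprot, species) {
  polymer_chain(asym_id, fold$sequence, fold$atoms,
                polymer_type = "polypeptide", auth_id = asym_id,
                entity_id = entity_id, uniprot = uniprot,
                species = species)
}

.fixture_annotation_row <- function(entry_id, asym_id, n_res, uniprot,
                                    species, pfam_id = "TOYD",
                                    pfam_acc = "PF99999") {
  data.frame(entry_id = entry_id, asym_id = asym_id, pfam_acc = pfam_acc,
             pfam_id = pfam_id, clan = "CLTOY",
             intervals = sprintf("1-%d", n_res), hmm_length = n_res,
             hmm_map = paste(sprintf("%d:%d", seq_len(n_res),
                                     seq_len(n_res)), collapse = ","),
             uniprot = uniprot, species = species,
             stringsAsFactors = FALSE)
}

#' Build a synthetic crystal around a designed dimer
#'
#' Places the designed C2 helical dimer in the asymmetric unit (space
#' group P1, two chains) or as one chain completed by a 2-fold screw
#' mate (space group P21), rotates the contents by `form_rot` about z,
#' and chooses the cell so that exactly one lattice direction carries a
#' tight packing contact (gap `tight_gap`) while the others are padded
#' by `cell_padding`. Errors if the designed dimer fails the
#' interaction rule.
#'
#' @param entry_id identifier.
#' @param seed RNG seed for the sequence.
#' @param n_res residues per chain.
#' @param space_group `"P 1"` or `"P 21"`.
#' @param d designed inter-axis separation, Angstrom.
#' @param form_rot rotation (radians) of the asymmetric-unit contents
#'   about z, applied before the cell is chosen.
#' @param tight_axis which cell direction carries the packing contact
#'   (`"x"`, `"y"` or `"z"`); giving each crystal form a different
#'   packing direction makes the packing interfaces form-specific.
#' @param tight_gap starting gap (A) for the packing-contact search;
#'   set >= `cell_padding` to remove packing contacts entirely.
#' @param cell_padding gap (A) across the padded directions.
#' @param parent_sequence,mutation_rate homolog construction.
#' @param uniprot,species chain metadata.
#' @param with_dimer set `FALSE` to build a monomer crystal (no
#'   designed interface) in P 1.
#' @param with_assembly write the designed dimer as the author
#'   assembly.
#' @param config configuration used to verify the designed contact.
#' @return list: `entry` (`xc_entry`), `annotations` (data.frame),
#'   `truth` (list with the designed contact record).
#' @export
build_synthetic_crystal <- function(entry_id, seed = 1, n_res = 40,
                                    space_group = "P 1", d = 9.8,
                                    form_rot = 0, tight_axis = "x",
                                    tight_gap = 4,
                                    cell_padding = 40,
                                    parent_sequence = NULL,
                                    mutation_rate = 0,
                                    uniprot = "SYNP1_TEST",
                                    species = "synthetic construct",
                                    with_dimer = TRUE,
                                    with_assembly = TRUE,
                                    config = pipeline_config()) {
  if (space_group == "P 21") {
    # helix along y (the screw axis); partner generated by the screw
    # operator, so the dimer only appears after lattice expansion
    fold <- generate_toy_fold(n_res, seed, axis = "y",
                              origin = c(d / 2, 0, 0),
                              parent_sequence = parent_sequence,
                              mutation_rate = mutation_rate)
    chains <- list(.fixture_chain("A", fold, "1", uniprot, species))
    ext_y <- diff(range(fold$atoms$y))
    # screw shift b/2 leaves roughly half the helix length in side
    # contact with the symmetry mate
    b <- ext_y + 2 * .helix_params$r_cb + 2
    ext_z <- diff(range(fold$atoms$z))
    cell <- unit_cell(2 * max(abs(fold$atoms$x)) + cell_padding, b,
                      ext_z + cell_padding)
    ops <- space_group_ops("P 21")
    asm <- if (with_assembly) {
      list(assembly_def("1", "author", data.frame(
        asym_id = "A", op_index = c(1L, 2L), si = 0L, sj = 0L, sk = 0L)))
    } else list()
    entry <- crystal_entry(entry_id, chains, cell = cell,
                           space_group = "P 1 21 1", sym_ops = ops,
                           assemblies = asm)
    # designed partner = screw image; verify the contact rule
    M <- frac_to_orth_matrix(cell)
    op <- ops[[2L]]
    pl <- structure(list(asym_id = "A", op_index = 2L,
                         shift = c(0L, 0L, 0L),
                         R = M %*% op$R %*% solve(M),
                         t = as.vector(M %*% op$t),
                         placement_id = "scrw"), class = "xc_placement")
    ua <- make_unit(entry, "A")
    ub <- make_unit(entry, "A", placement = pl)
    cs <- contact_set(ua, ub, config)
    if (!is_interacting(cs, "chain", config)) {
      stop("designed screw dimer is not contact-positive for ", entry_id)
    }
    truth <- list(entry_id = entry_id, designed_chains = c("A", "A'"),
                  designed_via = "screw", n_designed_pairs = nrow(cs$pairs))
    ann <- .fixture_annotation_row(entry_id, "A", n_res, uniprot, species)
    return(list(entry = entry, annotations = ann, truth = truth))
  }
  if (space_group != "P 1") stop("space_group must be 'P 1' or 'P 21'")
  hx <- 9.5
  fold_a <- generate_toy_fold(n_res, seed, axis = "z", rot = form_rot,
                              parent_sequence = parent_sequence,
                              mutation_rate = mutation_rate,
                              topology = "hairpin", hairpin_sep = hx)
  chains <- if (with_dimer) {
    # mirror through x = hx + d/2 + hx: the two hairpins meet via their
    # second helices at axis separation d, so the designed interface
    # lives on the helix-2 face while lattice packing uses helix 1
    atoms_b <- .rotz(.c2_partner(.rotz(fold_a$atoms, -form_rot),
                                 d + 2 * hx),
                     form_rot)
    fold_b <- list(atoms = atoms_b, sequence = fold_a$sequence)
    list(.fixture_chain("A", fold_a, "1", uniprot, species),
         .fixture_chain("B", fold_b, "1", uniprot, species))
  } else {
    list(.fixture_chain("A", fold_a, "1", uniprot, species))
  }
  all_xyz <- do.call(rbind, lapply(chains, function(ch) {
    as.matrix(ch$atoms[, c("x", "y", "z")])
  }))
  ext <- apply(all_xyz, 2L, function(v) diff(range(v)))
  ax <- match(tight_axis, c("x", "y", "z"))
  if (is.na(ax)) stop("tight_axis must be 'x', 'y' or 'z'")
  edges <- ext + cell_padding
  if (tight_gap < cell_padding) {
    # shrink the tight edge until the translated copy makes a real
    # packing contact (>= min_atom_contacts atom pairs within the
    # atomic cutoff, no clash below 3 A)
    edge <- NA_real_
    for (cand in seq(ext[ax] + tight_gap, ext[ax] - 8, by = -0.25)) {
      shift <- c(0, 0, 0); shift[ax] <- cand
      d2 <- .cross_dist2(all_xyz, sweep(all_xyz, 2L, shift, "+"))
      if (min(d2) < 3^2) break
      if (sum(d2 <= config$atom_cutoff^2) >= config$min_atom_contacts + 1) {
        edge <- cand
        break
      }
    }
    if (is.na(edge)) {
      stop("could not realize a packing contact for ", entry_id)
    }
    edges[ax] <- edge
  }
  cell <- unit_cell(edges[1L], edges[2L], edges[3L])
  asm <- if (with_assembly && with_dimer) {
    list(assembly_def("1", "author", data.frame(
      asym_id = c("A", "B"), op_index = 1L, si = 0L, sj = 0L, sk = 0L)))
  } else list()
  entry <- crystal_entry(entry_id, chains, cell = cell,
                         space_group = "P 1",
                         sym_ops = space_group_ops("P 1"),
                         assemblies = asm)
  truth <- list(entry_id = entry_id,
                designed_chains = if (with_dimer) c("A", "B") else
                  character(0),
                designed_via = if (with_dimer) "asu" else "none")
  if (with_dimer) {
    cs <- contact_set(make_unit(entry, "A"), make_unit(entry, "B"),
                      config)
    if (!is_interacting(cs, "chain", config)) {
      stop("designed dimer is not contact-positive for ", entry_id)
    }
    truth$n_designed_pairs <- nrow(cs$pairs)
    truth$designed_pairs <- paste(cs$pairs$seq_i, cs$pairs$seq_j,
                                  sep = "-")
  }
  ann <- do.call(rbind, lapply(chains, function(ch) {
    .fixture_annotation_row(entry_id, ch$asym_id, n_res, uniprot,
                            species)
  }))
  list(entry = entry, annotations = ann, truth = truth)
}

.rotz <- function(atoms, rot) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  Rz <- matrix(c(cos(rot), sin(rot), 0, -sin(rot), cos(rot), 0, 0, 0, 1),
               3, 3)
  xyz <- xyz %*% t(Rz)
  atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  atoms
}

#' Build the same crystal solved two ways: monomer and dimer ASU
#'
#' Returns two entries describing one physical crystal: the first is
#' the P21 monomer-asymmetric-unit form (the screw mate completes the
#' dimer), the second re-expresses the screw mate as an explicit second
#' chain in P1 with the identical cell. They fall into different
#' crystal forms under the four-condition rule (different space group
#' and stoichiometry) but share all lattice interfaces, so the
#' two-thirds merge rule collapses them.
#'
#' @param id_mono,id_dimer entry ids.
#' @param seed seed.
#' @param n_res residues per chain.
#' @param config configuration.
#' @return list with `mono`, `dimer` (each `entry` + `annotations`).
#' @export
build_monomer_dimer_pair <- function(id_mono = "SYNM", id_dimer = "SYND",
                                     seed = 1, n_res = 40,
                                     config = pipeline_config()) {
  fx <- build_synthetic_crystal(id_mono, seed = seed, n_res = n_res,
                                space_group = "P 21", config = config)
  e1 <- fx$entry
  M <- frac_to_orth_matrix(e1$cell)
  op <- e1$sym_ops[[2L]]
  chA <- e1$chains[["A"]]
  xyz <- .placed_xyz(as.matrix(chA$atoms[, c("x", "y", "z")]),
                     structure(list(asym_id = "A", op_index = 2L,
                                    shift = c(0L, 0L, 0L),
                                    R = M %*% op$R %*% solve(M),
                                    t = as.vector(M %*% op$t),
                                    placement_id = "scrw"),
                               class = "xc_placement"))
  atoms_b <- chA$atoms
  atoms_b$x <- xyz[, 1L]; atoms_b$y <- xyz[, 2L]; atoms_b$z <- xyz[, 3L]
  chB <- polymer_chain("B", chA$sequence, atoms_b,
                       polymer_type = "polypeptide", auth_id = "B",
                       entity_id = "1", uniprot = chA$uniprot,
                       species = chA$species)
  e2 <- crystal_entry(id_dimer, list(chA, chB), cell = e1$cell,
                      space_group = "P 1",
                      sym_ops = space_group_ops("P 1"),
                      assemblies = list(assembly_def("1", "author",
                        data.frame(asym_id = c("A", "B"), op_index = 1L,
                                   si = 0L, sj = 0L, sk = 0L))))
  ann2 <- rbind(.fixture_annotation_row(id_dimer, "A", n_res,
                                        chA$uniprot, chA$species),
                .fixture_annotation_row(id_dimer, "B", n_res,
                                        chA$uniprot, chA$species))
  list(mono = list(entry = e1, annotations = fx$annotations),
       dimer = list(entry = e2, annotations = ann2))
}

#' Build a domain-peptide complex entry
#'
#' One annotated helical domain plus a short peptide helix docked on
#' the `+x` (`mode = "front"`) or `-x` (`mode = "back"`) face, in a
#' padded P1 cell so no lattice contacts occur.
#'
#' @param entry_id identifier.
#' @param seed RNG seed.
#' @param n_res domain residues.
#' @param pep_len peptide residues (must stay below the peptide length
#'   bound to register as a peptide).
#' @param mode binding face.
#' @param gap domain-axis to peptide-axis separation, A.
#' @param parent_sequence,mutation_rate homolog construction for the
#'   domain.
#' @param uniprot,species metadata.
#' @return list: `entry`, `annotations`, `truth`.
#' @export
build_peptide_complex <- function(entry_id, seed = 1, n_res = 40,
                                  pep_len = 8,
                                  mode = c("front", "back"), gap = 9.5,
                                  parent_sequence = NULL,
                                  mutation_rate = 0,
                                  uniprot = "SYNP1_TEST",
                                  species = "synthetic construct") {
  mode <- match.arg(mode)
  dom <- generate_toy_fold(n_res, seed,
                           parent_sequence = parent_sequence,
                           mutation_rate = mutation_rate)
  x0 <- if (mode == "front") gap else -gap
  zmid <- .helix_params$rise * (n_res / 2 - pep_len / 2)
  pep <- generate_toy_fold(pep_len, seed + 1000L,
                           origin = c(x0, 0, zmid))
  chains <- list(
    .fixture_chain("A", dom, "1", uniprot, species),
    polymer_chain("P", pep$sequence, pep$atoms,
                  polymer_type = "polypeptide", auth_id = "P",
                  entity_id = "2", uniprot = NA_character_,
                  species = species))
  ext <- apply(do.call(rbind, lapply(chains, function(ch) {
    as.matrix(ch$atoms[, c("x", "y", "z")])
  })), 2L, function(v) diff(range(v)))
  cell <- unit_cell(ext[1L] + 60, ext[2L] + 60, ext[3L] + 60)
  entry <- crystal_entry(entry_id, chains, cell = cell,
                         space_group = "P 1",
                         sym_ops = space_group_ops("P 1"))
  ann <- .fixture_annotation_row(entry_id, "A", n_res, uniprot, species)
  list(entry = entry, annotations = ann,
       truth = list(entry_id = entry_id, peptide_mode = mode))
}

#' Build a domain-ligand entry
#'
#' One annotated helical domain with ligand molecules placed against
#' designed contact sites (clusters of consecutive outward C-beta
#' positions) plus one water molecule near the first site.
#'
#' @param entry_id identifier.
#' @param seed seed.
#' @param n_res domain residues.
#' @param sites list of integer vectors of residue positions; each
#'   vector gets one ligand instance centred on those C-betas.
#' @param comp_ids component codes, recycled over sites.
#' @param uniprot,species metadata.
#' @return list: `entry`, `annotations`, `truth`.
#' @export
build_ligand_entry <- function(entry_id, seed = 1, n_res = 40,
                               sites = list(5:9, 30:34),
                               comp_ids = c("LG1", "LG2"),
                               uniprot = "SYNP1_TEST",
                               species = "synthetic construct") {
  dom <- generate_toy_fold(n_res, seed)
  chains <- list(.fixture_chain("A", dom, "1", uniprot, species))
  ligands <- list()
  for (si in seq_along(sites)) {
    pos <- sites[[si]]
    cb <- dom$atoms[dom$atoms$atom == "CB" &
                      dom$atoms$seq_pos %in% pos, , drop = FALSE]
    at <- do.call(rbind, lapply(seq_len(nrow(cb)), function(i) {
      # one ligand atom 3.5 A radially outward of each site C-beta
      outward <- c(cb$x[i], cb$y[i], 0)
      outward <- outward / sqrt(sum(outward^2))
      p <- as.numeric(cb[i, c("x", "y", "z")]) + outward * 3.5
      data.frame(atom = sprintf("C%d", i), element = "C",
                 x = p[1L], y = p[2L], z = p[3L], occupancy = 1,
                 altloc = "", stringsAsFactors = FALSE)
    }))
    ligands[[si]] <- ligand_instance(
      comp_ids[(si - 1L) %% length(comp_ids) + 1L], at,
      instance_id = sprintf("L%d", si))
  }
  cb1 <- dom$atoms[dom$atoms$atom == "CB" &
                     dom$atoms$seq_pos == sites[[1L]][1L], ]
  wat <- ligand_instance("HOH", data.frame(
    atom = "O", element = "O", x = cb1$x + 3.0, y = cb1$y, z = cb1$z,
    occupancy = 1, altloc = "", stringsAsFactors = FALSE),
    instance_id = "W1")
  ligands[[length(ligands) + 1L]] <- wat
  cell <- unit_cell(100, 100, 100)
  entry <- crystal_entry(entry_id, chains, cell = cell,
                         space_group = "P 1",
                         sym_ops = space_group_ops("P 1"),
                         ligands = ligands)
  ann <- .fixture_annotation_row(entry_id, "A", n_res, uniprot, species)
  list(entry = entry, annotations = ann,
       truth = list(entry_id = entry_id, n_sites = length(sites),
                    site_residues = sites))
}

#' Build a domain-DNA entry with an assembly record
#'
#' A helical domain plus a stylized single-stranded DNA chain laid
#' along the domain face; the author assembly holds both chains, so the
#' nucleic-interface selection path (which reads assemblies) is
#' exercised.
#'
#' @param entry_id identifier.
#' @param seed seed.
#' @param n_res domain residues.
#' @param n_nt nucleotides.
#' @param gap domain-axis to strand separation, A.
#' @param uniprot,species metadata.
#' @return list: `entry`, `annotations`, `truth`.
#' @export
build_nucleic_entry <- function(entry_id, seed = 1, n_res = 40,
                                n_nt = 12, gap = 8,
                                uniprot = "SYNP1_TEST",
                                species = "synthetic construct") {
  dom <- generate_toy_fold(n_res, seed)
  set.seed(seed + 2000L)
  nt <- sample(c("DA", "DC", "DG", "DT"), n_nt, replace = TRUE)
  rows <- list()
  for (i in seq_len(n_nt)) {
    base <- c(gap, 0, 3.4 * (i - 1))
    for (k in seq_len(3L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seq_pos = i, resname = nt[i],
        atom = c("P", "C4'", "N1")[k],
        element = c("P", "C", "N")[k],
        x = base[1L] + c(1.5, 0, -1.5)[k], y = c(0.5, 0, -0.5)[k],
        z = base[3L] + c(0, 0.8, 1.6)[k],
        occupancy = 1, altloc = "", stringsAsFactors = FALSE)
    }
  }
  dna_atoms <- do.call(rbind, rows)
  chains <- list(
    .fixture_chain("A", dom, "1", uniprot, species),
    polymer_chain("D", paste(sub("^D", "", nt), collapse = ""),
                  dna_atoms, polymer_type = "DNA", auth_id = "D",
                  entity_id = "2"))
  cell <- unit_cell(120, 120, 120)
  asm <- list(assembly_def("1", "author", data.frame(
    asym_id = c("A", "D"), op_index = 1L, si = 0L, sj = 0L, sk = 0L)))
  entry <- crystal_entry(entry_id, chains, cell = cell,
                         space_group = "P 1",
                         sym_ops = space_group_ops("P 1"),
                         assemblies = asm)
  ann <- .fixture_annotation_row(entry_id, "A", n_res, uniprot, species)
  list(entry = entry, annotations = ann,
       truth = list(entry_id = entry_id, n_nt = n_nt))
}

#' Generate a multi-crystal-form benchmark set on disk
#'
#' Writes `n_forms` homolog crystals sharing the designed dimer (each
#' form rotated so its packing face differs, with cells differing well
#' beyond the crystal-form tolerance), optionally one extra monomer
#' form without the dimer, a combined domain-annotation TSV and a truth
#' JSON.
#'
#' @param dir output directory (created).
#' @param seed master seed.
#' @param n_forms number of dimer-bearing crystal forms.
#' @param n_res residues per chain.
#' @param mutation_rate per-position mutation rate between homologs.
#' @param include_no_dimer_form add one monomer-only crystal.
#' @param config configuration used to validate designed contacts.
#' @return invisible list with `entries`, `annotation_file`,
#'   `truth_file`, `paths`.
#' @export
generate_benchmark_set <- function(dir, seed = 1, n_forms = 3,
                                   n_res = 40, mutation_rate = 0.25,
                                   include_no_dimer_form = FALSE,
                                   config = pipeline_config()) {
  if (n_forms < 2L) stop("benchmark sets need at least 2 forms")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  parent <- generate_toy_fold(n_res, seed)$sequence
  entries <- list(); anns <- list(); truths <- list(); paths <- character(0)
  total <- n_forms + as.integer(include_no_dimer_form)
  for (k in seq_len(total)) {
    eid <- sprintf("SYN%d", k)
    with_dimer <- k <= n_forms
    fx <- build_synthetic_crystal(
      eid, seed = seed + k, n_res = n_res, space_group = "P 1",
      tight_axis = c("x", "y", "z")[(k - 1L) %% 3L + 1L],
      form_rot = if (with_dimer) 0 else 30 * pi / 180,
      tight_gap = 4,
      parent_sequence = if (k == 1L) NULL else parent,
      mutation_rate = if (k == 1L) 0 else mutation_rate,
      uniprot = sprintf("SYNP%d_TEST", k),
      with_dimer = with_dimer, config = config)
    if (k == 1L) parent <- fx$entry$chains[[1L]]$sequence
    path <- file.path(dir, paste0(eid, ".cif"))
    write_entry_cif(fx$entry, path)
    entries[[eid]] <- fx$entry
    anns[[eid]] <- fx$annotations
    truths[[eid]] <- fx$truth
    paths <- c(paths, path)
  }
  ann_df <- do.call(rbind, anns)
  ann_file <- file.path(dir, "annotations.tsv")
  utils::write.table(ann_df, ann_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(n_forms = n_forms,
                expected_top_cluster = list(n_crystal_forms = n_forms,
                                            n_entries = n_forms),
                no_dimer_entry = if (include_no_dimer_form) {
                  sprintf("SYN%d", total)
                } else NA,
                entries = truths)
  truth_file <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_file, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(entries = entries, annotation_file = ann_file,
                 truth_file = truth_file, paths = paths))
}
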