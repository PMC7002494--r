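# In-memory model of a crystallographic entry: polymer chains, ligand
# instances, cell/symmetry, assembly definitions, and family-annotated
# domains. Reads and writes mmCIF (cell, symmetry, entity_poly, atom_site,
# assembly generation records) plus the legacy PDB dialect.

.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)
.aa1to3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
.water_comps <- c("HOH", "DOD", "WAT", "H2O")
.dna_comps <- c("DA", "DC", "DG", "DT", "DI", "DU")
.rna_comps <- c("A", "C", "G", "U", "I")

#' Polymer chain constructor
#'
#' @param asym_id label asym id.
#' @param sequence one-letter sequence of the full polymer entity
#'   (including unmodeled residues).
#' @param atoms data.frame with columns `seq_pos`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z`, `occupancy`, `altloc`.
#' @param polymer_type one of `"polypeptide"`, `"DNA"`, `"RNA"`, `"hybrid"`.
#' @param auth_id,entity_id,uniprot,species optional metadata.
#' @return object of class `xc_chain`.
#' @export
polymer_chain <- function(asym_id, sequence, atoms,
                          polymer_type = "polypeptide",
                          auth_id = asym_id, entity_id = NA_character_,
                          uniprot = NA_character_, species = NA_character_) {
  polymer_type <- match.arg(polymer_type,
                            c("polypeptide", "DNA", "RNA", "hybrid"))
  atoms <- as.data.frame(atoms)
  need <- c("seq_pos", "resname", "atom", "element", "x", "y", "z",
            "occupancy", "altloc")
  if (!all(need %in% names(atoms))) {
    stop("chain atom table is missing columns: ",
         paste(setdiff(need, names(atoms)), collapse = ", "))
  }
  if (nrow(atoms) && any(atoms$seq_pos < 1L)) {
    stop("polymer residues must have seq_pos >= 1")
  }
  if (nrow(atoms) && max(atoms$seq_pos) > nchar(sequence)) {
    stop("chain ", asym_id, ": modeled seq_pos exceeds entity sequence length")
  }
  if (nrow(atoms) &&
      any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in chain ", asym_id)
  }
  structure(list(asym_id = asym_id, auth_id = auth_id,
                 entity_id = entity_id, sequence = sequence,
                 polymer_type = polymer_type, atoms = atoms,
                 uniprot = uniprot, species = species),
            class = "xc_chain")
}

#' Chain length (full polymer entity length, modeled or not)
#' @param chain an `xc_chain`.
#' @return integer.
#' @export
chain_length <- function(chain) nchar(chain$sequence)

#' Ligand instance constructor
#' @param comp_id chemical component code.
#' @param atoms data.frame with columns `atom`, `element`, `x`, `y`, `z`,
#'   `occupancy`, `altloc`.
#' @param instance_id unique instance label within the entry.
#' @return object of class `xc_ligand`; `is_water` is derived from
#'   `comp_id`.
#' @export
ligand_instance <- function(comp_id, atoms, instance_id = comp_id) {
  structure(list(comp_id = comp_id, instance_id = instance_id,
                 atoms = as.data.frame(atoms),
                 is_water = comp_id %in% .water_comps),
            class = "xc_ligand")
}

#' Assembly definition
#'
#' Members are symmetry-placed chain copies: each row names a chain, an
#' index into the entry's symmetry operators, and an integer cell
#' translation.
#'
#' @param assembly_id identifier.
#' @param provenance `"author"` or `"pisa"`.
#' @param members data.frame with columns `asym_id`, `op_index`, `si`,
#'   `sj`, `sk`.
#' @export
assembly_def <- function(assembly_id, provenance, members) {
  provenance <- match.arg(provenance, c("author", "pisa"))
  members <- as.data.frame(members)
  if (nrow(members) == 0L) stop("assembly members must be non-empty")
  structure(list(assembly_id = assembly_id, provenance = provenance,
                 members = members), class = "xc_assembly")
}

#' Crystal entry constructor
#'
#' @param entry_id entry identifier.
#' @param chains list of [polymer_chain()] objects.
#' @param cell an [unit_cell()] or `NULL` for non-crystallographic input.
#' @param space_group Hermann-Mauguin symbol or `NA`.
#' @param sym_ops list of fractional-space operators (`R`, `t`); the
#'   identity is required and placed first.
#' @param ligands list of [ligand_instance()] objects.
#' @param assemblies list of [assembly_def()] objects.
#' @param resolution optional resolution in Angstrom.
#' @return object of class `xc_entry`.
#' @export
crystal_entry <- function(entry_id, chains, cell = NULL,
                          space_group = NA_character_,
                          sym_ops = list(parse_symop("x,y,z")),
                          ligands = list(), assemblies = list(),
                          resolution = NA_real_) {
  if (!length(sym_ops)) stop("sym_ops must be non-empty")
  idn <- which(vapply(sym_ops, .is_identity_op, logical(1L)))
  if (!length(idn)) stop("sym_ops must include the identity operator")
  sym_ops <- c(sym_ops[idn[1L]], sym_ops[-idn[1L]])
  names(chains) <- vapply(chains, `[[`, character(1L), "asym_id")
  if (anyDuplicated(names(chains))) stop("duplicate chain asym_ids")
  for (a in assemblies) {
    bad <- setdiff(a$members$asym_id, names(chains))
    if (length(bad)) {
      stop("assembly ", a$assembly_id, " references absent chain(s): ",
           paste(bad, collapse = ", "))
    }
    if (any(a$members$op_index < 1L | a$members$op_index > length(sym_ops))) {
      stop("assembly ", a$assembly_id, " references absent operator index")
    }
  }
  structure(list(entry_id = entry_id, cell = cell,
                 space_group = space_group, sym_ops = sym_ops,
                 chains = chains, ligands = ligands,
                 assemblies = assemblies, resolution = resolution),
            class = "xc_entry")
}

#' Is an entry usable for lattice workflows?
#'
#' Requires a valid cell and resolved symmetry operators.
#' @param entry an `xc_entry`.
#' @return logical.
#' @export
is_crystallographic <- function(entry) {
  !is.null(entry$cell) && length(entry$sym_ops) >= 1L &&
    isTRUE(attr(entry, "sym_resolved", exact = TRUE) %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_crystallographic <- function(entry) {
  if (!is_crystallographic(entry)) {
    stop("non-crystallographic entry '", entry$entry_id,
         "': cell or space-group symmetry missing; ",
         "lattice workflows are unavailable")
  }
  invisible(entry)
}

#' @export
print.xc_entry <- function(x, ...) {
  cat(sprintf("<xc_entry %s> %d chain(s), %d ligand(s), %d sym op(s)%s\n",
              x$entry_id, length(x$chains), length(x$ligands),
              length(x$sym_ops),
              if (is_crystallographic(x)) {
                sprintf(", %s", x$space_group)
              } else " (non-crystallographic)"))
  invisible(x)
}

# ---- altloc policy ---------------------------------------------------------

# Keep the conformer with highest occupancy; ties resolved by the
# alphabetically first altloc code. Applied per (residue, atom name).
.filter_altlocs <- function(atoms, group_cols) {
  if (!nrow(atoms)) return(atoms)
  atoms$altloc[is.na(atoms$altloc)] <- ""
  key <- do.call(paste, c(atoms[c(group_cols, "atom")], sep = "\r"))
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  keep <- sort(ord[!duplicated(key[ord])])  # original order retained
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

# ---- mmCIF writer ----------------------------------------------------------

.cif_quote <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "."
  needs <- grepl("[ \t']", x) | x %in% c("loop_", "stop_") |
    grepl("^[_#$\\[\\]]", x)
  x[needs] <- paste0("'", gsub("'", "\"", x[needs]), "'")
  x
}

.cif_loop <- function(con, category, df) {
  cat("loop_\n", file = con)
  for (nm in names(df)) {
    cat(sprintf("_%s.%s\n", category, nm), file = con)
  }
  vals <- vapply(df, .cif_quote, character(nrow(df)))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  writeLines(apply(vals, 1L, paste, collapse = " "), con)
  cat("#\n", file = con)
}

.poly_type_cif <- c(polypeptide = "polypeptide(L)",
                    DNA = "polydeoxyribonucleotide",
                    RNA = "polyribonucleotide",
                    hybrid = "polydeoxyribonucleotide/polyribonucleotide hybrid")

#' Write a crystal entry to mmCIF
#'
#' Emits cell, symmetry (explicit operator records), polymer entities,
#' reference/source metadata, assembly generation records and atom_site
#' records. [read_entry()] on the output reproduces the model.
#'
#' @param entry an `xc_entry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_entry_cif <- function(entry, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("data_%s\n#\n_entry.id %s\n#\n", entry$entry_id,
              entry$entry_id), file = con)
  if (!is.null(entry$cell)) {
    cat(sprintf(paste0("_cell.length_a %.4f\n_cell.length_b %.4f\n",
                       "_cell.length_c %.4f\n_cell.angle_alpha %.4f\n",
                       "_cell.angle_beta %.4f\n_cell.angle_gamma %.4f\n#\n"),
                entry$cell$a, entry$cell$b, entry$cell$c,
                entry$cell$alpha, entry$cell$beta, entry$cell$gamma),
        file = con)
  }
  if (!is.na(entry$space_group)) {
    cat(sprintf("_symmetry.space_group_name_H-M '%s'\n#\n",
                entry$space_group), file = con)
  }
  if (!is.na(entry$resolution)) {
    cat(sprintf("_refine.ls_d_res_high %.3f\n#\n", entry$resolution),
        file = con)
  }
  .cif_loop(con, "space_group_symop", data.frame(
    id = seq_along(entry$sym_ops),
    operation_xyz = vapply(entry$sym_ops, symop_to_string, character(1L))
  ))
  ents <- unique(data.frame(
    entity_id = vapply(entry$chains, `[[`, character(1L), "entity_id"),
    type = .poly_type_cif[vapply(entry$chains, `[[`, character(1L),
                                 "polymer_type")],
    pdbx_seq_one_letter_code_can = vapply(entry$chains, `[[`,
                                          character(1L), "sequence"),
    stringsAsFactors = FALSE
  ))
  strand <- vapply(split(names(entry$chains),
                         vapply(entry$chains, `[[`, character(1L),
                                "entity_id"))[ents$entity_id],
                   paste, character(1L), collapse = ",")
  ents$pdbx_strand_id <- strand
  if (nrow(ents)) .cif_loop(con, "entity_poly", ents)
  unp <- data.frame(
    entity_id = ents$entity_id,
    db_name = "UNP",
    pdbx_db_accession = vapply(ents$entity_id, function(e) {
      ch <- Filter(function(c) identical(c$entity_id, e), entry$chains)
      ch[[1L]]$uniprot
    }, character(1L)),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(unp$pdbx_db_accession))) {
    .cif_loop(con, "struct_ref", unp[!is.na(unp$pdbx_db_accession), ])
  }
  src <- data.frame(
    entity_id = ents$entity_id,
    pdbx_organism_scientific = vapply(ents$entity_id, function(e) {
      ch <- Filter(function(c) identical(c$entity_id, e), entry$chains)
      ch[[1L]]$species
    }, character(1L)),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(src$pdbx_organism_scientific))) {
    .cif_loop(con, "entity_src_nat",
              src[!is.na(src$pdbx_organism_scientific), ])
  }
  if (length(entry$assemblies)) {
    adf <- data.frame(
      id = vapply(entry$assemblies, `[[`, character(1L), "assembly_id"),
      details = ifelse(vapply(entry$assemblies, `[[`, character(1L),
                              "provenance") == "pisa",
                       "software_defined_assembly (PISA)",
                       "author_defined_assembly"),
      stringsAsFactors = FALSE
    )
    .cif_loop(con, "pdbx_struct_assembly", adf)
    opers <- list(); gen <- list()
    for (a in entry$assemblies) {
      ids <- character(nrow(a$members))
      for (i in seq_len(nrow(a$members))) {
        m <- a$members[i, ]
        op <- entry$sym_ops[[m$op_index]]
        s <- symop_to_string(list(R = op$R,
                                  t = op$t + c(m$si, m$sj, m$sk)))
        hit <- match(s, vapply(opers, `[[`, character(1L), "op"))
        if (is.na(hit)) {
          opers[[length(opers) + 1L]] <- list(op = s)
          hit <- length(opers)
        }
        ids[i] <- as.character(hit)
      }
      gen[[length(gen) + 1L]] <- data.frame(
        assembly_id = a$assembly_id,
        oper_expression = vapply(split(seq_len(nrow(a$members)),
                                       a$members$asym_id),
                                 function(ii) paste(ids[ii], collapse = ","),
                                 character(1L)),
        asym_id_list = names(split(seq_len(nrow(a$members)),
                                   a$members$asym_id)),
        stringsAsFactors = FALSE
      )
    }
    .cif_loop(con, "pdbx_struct_oper_list", data.frame(
      id = seq_along(opers), type = "crystal symmetry operation",
      symmetry_operation = vapply(opers, `[[`, character(1L), "op")
    ))
    .cif_loop(con, "pdbx_struct_assembly_gen", do.call(rbind, gen))
  }
  rows <- list(); n <- 0L
  for (ch in entry$chains) {
    at <- ch$atoms
    if (!nrow(at)) next
    rows[[length(rows) + 1L]] <- data.frame(
      group_PDB = "ATOM", type_symbol = at$element,
      label_atom_id = at$atom, label_alt_id = ifelse(at$altloc == "", ".",
                                                     at$altloc),
      label_comp_id = at$resname, label_asym_id = ch$asym_id,
      label_entity_id = ch$entity_id, label_seq_id = at$seq_pos,
      Cartn_x = sprintf("%.4f", at$x), Cartn_y = sprintf("%.4f", at$y),
      Cartn_z = sprintf("%.4f", at$z),
      occupancy = sprintf("%.2f", at$occupancy),
      auth_seq_id = at$seq_pos, auth_asym_id = ch$auth_id,
      stringsAsFactors = FALSE
    )
  }
  for (lg in entry$ligands) {
    at <- lg$atoms
    rows[[length(rows) + 1L]] <- data.frame(
      group_PDB = "HETATM", type_symbol = at$element,
      label_atom_id = at$atom, label_alt_id = ".",
      label_comp_id = lg$comp_id, label_asym_id = lg$instance_id,
      label_entity_id = ".", label_seq_id = ".",
      Cartn_x = sprintf("%.4f", at$x), Cartn_y = sprintf("%.4f", at$y),
      Cartn_z = sprintf("%.4f", at$z),
      occupancy = sprintf("%.2f", at$occupancy),
      auth_seq_id = ".", auth_asym_id = lg$instance_id,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows)) {
    all_at <- do.call(rbind, rows)
    all_at <- cbind(data.frame(group_PDB = all_at$group_PDB,
                               id = seq_len(nrow(all_at))),
                    all_at[setdiff(names(all_at), "group_PDB")])
    .cif_loop(con, "atom_site", all_at)
  }
  invisible(path)
}

# ---- CIF tokenizer / parser ------------------------------------------------

.cif_tokenize <- function(lines) {
  toks <- character(0)
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (startsWith(ln, ";")) {
      val <- substring(ln, 2L)
      i <- i + 1L
      buf <- character(0)
      while (i <= n && !startsWith(lines[i], ";")) {
        buf <- c(buf, lines[i]); i <- i + 1L
      }
      toks <- c(toks, paste(c(val, buf), collapse = "\n"))
      i <- i + 1L
      next
    }
    rest <- ln
    while (nzchar(trimws(rest))) {
      m <- regexpr("^\\s*('[^']*'|\"[^\"]*\"|#.*|\\S+)", rest, perl = TRUE)
      tok <- trimws(regmatches(rest, m))
      rest <- substring(rest, m + attr(m, "match.length"))
      if (startsWith(tok, "#")) break
      if ((startsWith(tok, "'") && endsWith(tok, "'")) ||
          (startsWith(tok, "\"") && endsWith(tok, "\""))) {
        tok <- substring(tok, 2L, nchar(tok) - 1L)
      }
      toks <- c(toks, tok)
    }
    i <- i + 1L
  }
  toks
}

.cif_parse <- function(path) {
  toks <- .cif_tokenize(readLines(path, warn = FALSE))
  items <- list(); loops <- list()
  i <- 1L; n <- length(toks)
  is_kw <- function(t) grepl("^(_|loop_$|data_|stop_$)", t)
  while (i <= n) {
    t <- toks[i]
    if (startsWith(t, "data_")) {
      i <- i + 1L
    } else if (t == "loop_") {
      i <- i + 1L
      cols <- character(0)
      while (i <= n && startsWith(toks[i], "_")) {
        cols <- c(cols, toks[i]); i <- i + 1L
      }
      vals <- character(0)
      while (i <= n && !is_kw(toks[i])) {
        vals <- c(vals, toks[i]); i <- i + 1L
      }
      if (length(vals) %% length(cols) != 0L) {
        stop("malformed CIF loop at ", cols[1L], " in ", path)
      }
      m <- matrix(vals, ncol = length(cols), byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- sub("^_[^.]+\\.", "", cols)
      cat_name <- sub("\\..*$", "", sub("^_", "", cols[1L]))
      loops[[cat_name]] <- df
    } else if (startsWith(t, "_")) {
      if (i + 1L > n) stop("dangling CIF item ", t, " in ", path)
      items[[sub("^_", "", t)]] <- toks[i + 1L]
      i <- i + 2L
    } else {
      stop("unexpected CIF token '", t, "' in ", path)
    }
  }
  list(items = items, loops = loops)
}

.cif_num <- function(x) suppressWarnings(as.numeric(x))

.poly_type_from_cif <- function(x) {
  if (grepl("hybrid", x)) return("hybrid")
  if (grepl("polypeptide", x)) return("polypeptide")
  if (grepl("deoxyribo", x)) return("DNA")
  if (grepl("ribo", x)) return("RNA")
  "polypeptide"
}

# ---- read_entry ------------------------------------------------------------

#' Read a crystallographic structure file
#'
#' Parses an mmCIF (preferred) or legacy PDB file into an `xc_entry`.
#' Symmetry operators are taken from explicit operator records when
#' present, otherwise resolved from the space-group symbol via built-in
#' tables. Entries lacking a cell or resolvable symmetry are still
#' returned (usable for assembly and ligand workflows) but are flagged
#' non-crystallographic, and lattice workflows will refuse them.
#' Alternate conformers are reduced to the highest-occupancy one (ties:
#' alphabetically first altloc code).
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"mmcif"` or `"pdb"`.
#' @return an `xc_entry`.
#' @export
read_entry <- function(path, dialect = c("auto", "mmcif", "pdb")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else stop("cannot infer dialect from extension of ", path)
  }
  if (dialect == "mmcif") .read_entry_cif(path) else .read_entry_pdb(path)
}

.read_entry_cif <- function(path) {
  p <- tryCatch(.cif_parse(path), error = function(e) {
    stop("format error while parsing mmCIF ", path, ": ",
         conditionMessage(e))
  })
  entry_id <- p$items[["entry.id"]] %||%
    sub("\\.[^.]*$", "", basename(path))
  cell <- NULL
  if (!is.null(p$items[["cell.length_a"]])) {
    cell <- unit_cell(.cif_num(p$items[["cell.length_a"]]),
                      .cif_num(p$items[["cell.length_b"]]),
                      .cif_num(p$items[["cell.length_c"]]),
                      .cif_num(p$items[["cell.angle_alpha"]] %||% "90"),
                      .cif_num(p$items[["cell.angle_beta"]] %||% "90"),
                      .cif_num(p$items[["cell.angle_gamma"]] %||% "90"))
  }
  sg <- p$items[["symmetry.space_group_name_H-M"]] %||%
    p$items[["space_group.name_H-M_alt"]] %||% NA_character_
  sym_resolved <- TRUE
  ops <- NULL
  if (!is.null(p$loops$space_group_symop)) {
    ops <- lapply(p$loops$space_group_symop$operation_xyz, parse_symop)
  } else if (!is.null(p$loops$symmetry_equiv)) {
    ops <- lapply(p$loops$symmetry_equiv$pos_as_xyz, parse_symop)
  } else if (!is.na(sg)) {
    ops <- tryCatch(space_group_ops(sg), error = function(e) NULL)
    if (is.null(ops)) sym_resolved <- FALSE
  } else {
    sym_resolved <- FALSE
  }
  if (is.null(ops)) ops <- list(parse_symop("x,y,z"))
  if (is.null(cell)) sym_resolved <- FALSE

  ent_poly <- p$loops$entity_poly
  ent_type <- character(0); ent_seq <- character(0)
  if (!is.null(ent_poly)) {
    ent_type <- vapply(ent_poly$type, .poly_type_from_cif, character(1L))
    names(ent_type) <- ent_poly$entity_id
    ent_seq <- gsub("[\n ]", "", ent_poly$pdbx_seq_one_letter_code_can)
    names(ent_seq) <- ent_poly$entity_id
  }
  unp <- sp <- character(0)
  if (!is.null(p$loops$struct_ref)) {
    unp <- p$loops$struct_ref$pdbx_db_accession
    names(unp) <- p$loops$struct_ref$entity_id
  }
  if (!is.null(p$loops$entity_src_nat)) {
    sp <- p$loops$entity_src_nat$pdbx_organism_scientific
    names(sp) <- p$loops$entity_src_nat$entity_id
  }

  at <- p$loops$atom_site
  if (is.null(at)) stop("format error: no atom_site records in ", path)
  at$x <- .cif_num(at$Cartn_x); at$y <- .cif_num(at$Cartn_y)
  at$z <- .cif_num(at$Cartn_z)
  at$occupancy <- .cif_num(at$occupancy %||% rep("1", nrow(at)))
  at$occupancy[is.na(at$occupancy)] <- 1
  at$altloc <- at$label_alt_id
  at$altloc[at$altloc %in% c(".", "?")] <- ""
  is_poly <- !(at$label_seq_id %in% c(".", "?")) &
    at$label_entity_id %in% names(ent_type)

  chains <- list()
  for (asym in unique(at$label_asym_id[is_poly])) {
    sel <- at[is_poly & at$label_asym_id == asym, , drop = FALSE]
    eid <- sel$label_entity_id[1L]
    atoms <- data.frame(seq_pos = as.integer(sel$label_seq_id),
                        resname = sel$label_comp_id,
                        atom = sel$label_atom_id,
                        element = sel$type_symbol,
                        x = sel$x, y = sel$y, z = sel$z,
                        occupancy = sel$occupancy, altloc = sel$altloc,
                        stringsAsFactors = FALSE)
    atoms <- .filter_altlocs(atoms, "seq_pos")
    atoms <- atoms[order(atoms$seq_pos), , drop = FALSE]
    rownames(atoms) <- NULL
    chains[[asym]] <- polymer_chain(
      asym_id = asym, sequence = unname(ent_seq[eid]),
      atoms = atoms, polymer_type = unname(ent_type[eid]),
      auth_id = sel$auth_asym_id[1L], entity_id = eid,
      uniprot = unname(unp[eid]) %||% NA_character_,
      species = unname(sp[eid]) %||% NA_character_)
    if (is.null(chains[[asym]]$uniprot) || !length(chains[[asym]]$uniprot)) {
      chains[[asym]]$uniprot <- NA_character_
    }
  }
  ligands <- list()
  for (asym in unique(at$label_asym_id[!is_poly])) {
    sel <- at[!is_poly & at$label_asym_id == asym, , drop = FALSE]
    atoms <- data.frame(atom = sel$label_atom_id, element = sel$type_symbol,
                        x = sel$x, y = sel$y, z = sel$z,
                        occupancy = sel$occupancy, altloc = sel$altloc,
                        stringsAsFactors = FALSE)
    atoms$grp <- 1L
    atoms <- .filter_altlocs(atoms, "grp")
    atoms$grp <- NULL
    ligands[[length(ligands) + 1L]] <-
      ligand_instance(sel$label_comp_id[1L], atoms, instance_id = asym)
  }

  assemblies <- list()
  if (!is.null(p$loops$pdbx_struct_assembly_gen)) {
    opl <- p$loops$pdbx_struct_oper_list
    oper_map <- list()
    if (!is.null(opl)) {
      for (i in seq_len(nrow(opl))) {
        pop <- parse_symop(opl$symmetry_operation[i])
        hit <- NA_integer_; shift <- c(0, 0, 0)
        for (k in seq_along(ops)) {
          if (all(abs(pop$R - ops[[k]]$R) < 1e-6)) {
            dt <- pop$t - ops[[k]]$t
            if (all(abs(dt - round(dt)) < 1e-6)) {
              hit <- k; shift <- round(dt); break
            }
          }
        }
        if (is.na(hit)) {
          stop("assembly operator '", opl$symmetry_operation[i],
               "' does not resolve against the entry symmetry operators")
        }
        oper_map[[opl$id[i]]] <- list(op_index = hit, shift = shift)
      }
    }
    prov <- character(0)
    if (!is.null(p$loops$pdbx_struct_assembly)) {
      prov <- ifelse(grepl("pisa", p$loops$pdbx_struct_assembly$details,
                           ignore.case = TRUE), "pisa", "author")
      names(prov) <- p$loops$pdbx_struct_assembly$id
    }
    gen <- p$loops$pdbx_struct_assembly_gen
    for (aid in unique(gen$assembly_id)) {
      rows <- gen[gen$assembly_id == aid, , drop = FALSE]
      mem <- list()
      for (i in seq_len(nrow(rows))) {
        asyms <- strsplit(rows$asym_id_list[i], ",", fixed = TRUE)[[1L]]
        oids <- strsplit(rows$oper_expression[i], ",", fixed = TRUE)[[1L]]
        for (asym in asyms) for (oid in oids) {
          om <- oper_map[[oid]]
          if (is.null(om)) {
            stop("assembly ", aid, " references unknown operator id ", oid)
          }
          mem[[length(mem) + 1L]] <- data.frame(
            asym_id = asym, op_index = om$op_index,
            si = om$shift[1L], sj = om$shift[2L], sk = om$shift[3L])
        }
      }
      assemblies[[length(assemblies) + 1L]] <- assembly_def(
        aid, unname(prov[aid]) %||% "author", do.call(rbind, mem))
    }
  }
  res <- .cif_num(p$items[["refine.ls_d_res_high"]] %||% NA)
  out <- crystal_entry(entry_id, chains, cell = cell, space_group = sg,
                       sym_ops = ops, ligands = ligands,
                       assemblies = assemblies, resolution = res)
  attr(out, "sym_resolved") <- sym_resolved
  out
}

# Legacy PDB dialect. bio3d handles the fixed-width atom records; the
# header records it drops (CRYST1, REMARK 350) are read here.
.read_entry_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB files requires the bio3d package")
  }
  lines <- readLines(path, warn = FALSE)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  entry_id <- toupper(sub("\\.[^.]*$", "", basename(path)))

  cell <- NULL; sg <- NA_character_; sym_resolved <- TRUE
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    cr <- cr[1L]
    cell <- tryCatch(unit_cell(
      as.numeric(substr(cr, 7, 15)), as.numeric(substr(cr, 16, 24)),
      as.numeric(substr(cr, 25, 33)), as.numeric(substr(cr, 34, 40)),
      as.numeric(substr(cr, 41, 47)), as.numeric(substr(cr, 48, 54))),
      error = function(e) NULL)
    sg <- trimws(substr(cr, 56, 66))
    if (sg == "") sg <- NA_character_
  }
  ops <- if (!is.na(sg)) {
    tryCatch(space_group_ops(sg), error = function(e) NULL)
  }
  if (is.null(ops)) {
    ops <- list(parse_symop("x,y,z"))
    sym_resolved <- FALSE
  }
  if (is.null(cell)) sym_resolved <- FALSE

  a <- pdb$atom
  a$alt[is.na(a$alt)] <- ""
  std_poly <- c(names(.aa3to1), .dna_comps, .rna_comps)
  is_poly <- a$type == "ATOM" & a$resid %in% std_poly
  chains <- list()
  for (cid in unique(a$chain[is_poly])) {
    sel <- a[is_poly & a$chain == cid, , drop = FALSE]
    resnos <- sort(unique(sel$resno))
    seq_map <- stats::setNames(seq_along(resnos), resnos)
    atoms <- data.frame(seq_pos = as.integer(seq_map[as.character(sel$resno)]),
                        resname = sel$resid, atom = sel$elety,
                        element = ifelse(is.na(sel$elesy) | sel$elesy == "",
                                         substr(sel$elety, 1, 1), sel$elesy),
                        x = sel$x, y = sel$y, z = sel$z,
                        occupancy = ifelse(is.na(sel$o), 1, sel$o),
                        altloc = sel$alt, stringsAsFactors = FALSE)
    atoms <- .filter_altlocs(atoms, "seq_pos")
    atoms <- atoms[order(atoms$seq_pos), , drop = FALSE]
    rownames(atoms) <- NULL
    resnames <- sel$resid[!duplicated(sel$resno)][order(unique(sel$resno))]
    ptype <- if (all(resnames %in% .dna_comps)) "DNA"
      else if (all(resnames %in% .rna_comps)) "RNA"
      else "polypeptide"
    seq1 <- if (ptype == "polypeptide") {
      paste(ifelse(is.na(.aa3to1[resnames]), "X", .aa3to1[resnames]),
            collapse = "")
    } else paste(sub("^D", "", resnames), collapse = "")
    chains[[cid]] <- polymer_chain(cid, seq1, atoms, polymer_type = ptype,
                                   auth_id = cid, entity_id = cid)
  }
  ligands <- list()
  het <- a[!is_poly & a$type == "HETATM", , drop = FALSE]
  if (nrow(het)) {
    key <- paste(het$chain, het$resid, het$resno)
    for (k in unique(key)) {
      sel <- het[key == k, , drop = FALSE]
      atoms <- data.frame(atom = sel$elety,
                          element = ifelse(is.na(sel$elesy) | sel$elesy == "",
                                           substr(sel$elety, 1, 1),
                                           sel$elesy),
                          x = sel$x, y = sel$y, z = sel$z,
                          occupancy = ifelse(is.na(sel$o), 1, sel$o),
                          altloc = sel$alt, stringsAsFactors = FALSE)
      ligands[[length(ligands) + 1L]] <-
        ligand_instance(sel$resid[1L], atoms,
                        instance_id = gsub(" ", "_", k))
    }
  }
  assemblies <- .parse_remark350(lines, cell, ops)
  out <- crystal_entry(entry_id, chains, cell = cell, space_group = sg,
                       sym_ops = ops, ligands = ligands,
                       assemblies = assemblies)
  attr(out, "sym_resolved") <- sym_resolved
  out
}

# REMARK 350 BIOMT matrices are Cartesian; resolve each against the
# entry's fractional operators composed with integer cell shifts.
.parse_remark350 <- function(lines, cell, ops) {
  r350 <- grep("^REMARK 350", lines, value = TRUE)
  if (!length(r350) || is.null(cell)) return(list())
  M <- frac_to_orth_matrix(cell); Mi <- solve(M)
  cart_ops <- list()
  for (k in seq_along(ops)) {
    for (si in -1:1) for (sj in -1:1) for (sk in -1:1) {
      R <- M %*% ops[[k]]$R %*% Mi
      t <- as.vector(M %*% (ops[[k]]$t + c(si, sj, sk)))
      cart_ops[[length(cart_ops) + 1L]] <-
        list(op_index = k, shift = c(si, sj, sk), R = R, t = t)
    }
  }
  assemblies <- list()
  cur_id <- NULL; cur_chains <- character(0); rowsbuf <- list()
  biomt <- matrix(NA_real_, 3, 4); got <- 0L
  flush_biomt <- function() {
    if (got != 3L) return(NULL)
    for (co in cart_ops) {
      if (all(abs(biomt[, 1:3] - co$R) < 1e-4) &&
          all(abs(biomt[, 4] - co$t) < 1e-2)) {
        return(co)
      }
    }
    stop("REMARK 350 operator does not resolve against crystal symmetry")
  }
  for (ln in r350) {
    if (grepl("BIOMOLECULE:", ln)) {
      cur_id <- trimws(sub(".*BIOMOLECULE:", "", ln))
      cur_chains <- character(0)
    } else if (grepl("APPLY THE FOLLOWING TO CHAINS:", ln)) {
      cur_chains <- trimws(strsplit(
        sub(".*CHAINS:", "", ln), ",", fixed = TRUE)[[1L]])
    } else if (grepl("BIOMT[123]", ln)) {
      i <- as.integer(sub(".*BIOMT([123]).*", "\\1", ln))
      nums <- as.numeric(strsplit(trimws(
        sub(".*BIOMT[123]\\s+\\S+", "", ln)), "\\s+")[[1L]])
      biomt[i, ] <- nums
      got <- got + 1L
      if (i == 3L) {
        co <- flush_biomt()
        for (chn in cur_chains) {
          rowsbuf[[length(rowsbuf) + 1L]] <- data.frame(
            assembly_id = cur_id, asym_id = chn, op_index = co$op_index,
            si = co$shift[1L], sj = co$shift[2L], sk = co$shift[3L])
        }
        got <- 0L
      }
    }
  }
  if (!length(rowsbuf)) return(list())
  all_rows <- do.call(rbind, rowsbuf)
  lapply(unique(all_rows$assembly_id), function(aid) {
    assembly_def(aid, "author",
                 all_rows[all_rows$assembly_id == aid,
                          c("asym_id", "op_index", "si", "sj", "sk")])
  })
}

# ---- domain annotations ----------------------------------------------------

#' Ingest a domain-annotation table
#'
#' Reads the tab-delimited domain-annotation format (columns `entry_id`,
#' `asym_id`, `pfam_acc`, `pfam_id`, `clan`, `intervals` as
#' `"s1-e1;s2-e2"`, `hmm_length`, `hmm_map` as `"seqpos:hmmpos,..."`,
#' `uniprot`, `species`) and builds validated domain instances for one
#' entry. Rows referencing chains absent from the entry, overlapping
#' intervals, or HMM positions outside `[1, hmm_length]` are rejected
#' with row-level diagnostics.
#'
#' @param entry an `xc_entry`.
#' @param table path to a TSV file, or a data.frame with the schema above.
#' @return list of `xc_domain` objects.
#' @export
ingest_annotations <- function(entry, table) {
  df <- if (is.character(table)) {
    utils::read.delim(table, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = "character")
  } else {
    as.data.frame(table)
  }
  need <- c("entry_id", "asym_id", "pfam_acc", "pfam_id", "clan",
            "intervals", "hmm_length", "hmm_map", "uniprot", "species")
  if (!all(need %in% names(df))) {
    stop("annotation table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df <- df[df$entry_id == entry$entry_id, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    where <- sprintf("annotation row %d (%s/%s %s)", i, row$entry_id,
                     row$asym_id, row$pfam_id)
    chain <- entry$chains[[row$asym_id]]
    if (is.null(chain)) {
      stop(where, ": chain '", row$asym_id, "' absent from entry")
    }
    iv <- do.call(rbind, lapply(
      strsplit(row$intervals, ";", fixed = TRUE)[[1L]],
      function(s) as.integer(strsplit(s, "-", fixed = TRUE)[[1L]])))
    if (is.null(iv) || ncol(iv) != 2L || any(is.na(iv)) ||
        any(iv[, 1L] > iv[, 2L])) {
      stop(where, ": malformed intervals '", row$intervals, "'")
    }
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L])) {
      stop(where, ": overlapping intervals")
    }
    if (max(iv[, 2L]) > chain_length(chain)) {
      stop(where, ": interval end exceeds chain length ",
           chain_length(chain))
    }
    hmm_length <- as.integer(row$hmm_length)
    pairs <- strsplit(strsplit(row$hmm_map, ",", fixed = TRUE)[[1L]],
                      ":", fixed = TRUE)
    seqpos <- vapply(pairs, function(p) as.integer(p[1L]), integer(1L))
    hmmpos <- vapply(pairs, function(p) as.integer(p[2L]), integer(1L))
    if (any(is.na(seqpos)) || any(is.na(hmmpos))) {
      stop(where, ": malformed hmm_map")
    }
    in_iv <- vapply(seqpos, function(s) {
      any(s >= iv[, 1L] & s <= iv[, 2L])
    }, logical(1L))
    if (!all(in_iv)) {
      stop(where, ": hmm_map seq positions outside the domain intervals: ",
           paste(seqpos[!in_iv], collapse = ","))
    }
    if (any(hmmpos < 1L | hmmpos > hmm_length)) {
      stop(where, ": hmm positions outside [1, ", hmm_length, "]")
    }
    if (anyDuplicated(seqpos) || anyDuplicated(hmmpos)) {
      stop(where, ": hmm_map must be one-to-one")
    }
    hmm_map <- stats::setNames(hmmpos, seqpos)
    out[[length(out) + 1L]] <- structure(list(
      domain_id = sprintf("%s_%s_%s_%d", entry$entry_id, row$asym_id,
                          row$pfam_id, i),
      pfam_acc = row$pfam_acc, pfam_id = row$pfam_id,
      clan = if (row$clan %in% c("", "NA")) NA_character_ else row$clan,
      asym_id = row$asym_id, intervals = iv, hmm_map = hmm_map,
      hmm_length = hmm_length,
      coverage = length(hmm_map) / hmm_length,
      uniprot = if (row$uniprot %in% c("", "NA")) NA_character_
                else row$uniprot,
      species = if (row$species %in% c("", "NA")) NA_character_
                else row$species
    ), class = "xc_domain")
  }
  out
}

#' Residue positions covered by a domain
#' @param domain an `xc_domain`.
#' @return integer vector of seq positions.
#' @export
domain_positions <- function(domain) {
  unlist(lapply(seq_len(nrow(domain$intervals)), function(i) {
    seq.int(domain$intervals[i, 1L], domain$intervals[i, 2L])
  }), use.names = FALSE)
}

# ---- architectures ---------------------------------------------------------

#' Derive chain architectures
#'
#' Renders, per chain, the ordered list of family assignments as
#' `"(A)_(B)"`, families sorted by the start of their first interval.
#' Tandem repeats are preserved, not collapsed. Chains without domains
#' get the empty architecture `""`.
#'
#' @param entry an `xc_entry`.
#' @param domains list of `xc_domain` objects (from
#'   [ingest_annotations()]).
#' @return named character vector, one element per chain.
#' @export
derive_architectures <- function(entry, domains) {
  out <- stats::setNames(rep("", length(entry$chains)),
                         names(entry$chains))
  for (asym in names(entry$chains)) {
    ds <- Filter(function(d) d$asym_id == asym, domains)
    if (!length(ds)) next
    starts <- vapply(ds, function(d) d$intervals[1L, 1L], numeric(1L))
    fams <- vapply(ds, `[[`, character(1L), "pfam_id")[order(starts)]
    out[asym] <- paste(sprintf("(%s)", fams), collapse = "_")
  }
  out
}

#' Entry-level architecture signature
#'
#' The set of distinct chain architectures in the entry, sorted and
#' joined canonically. Copy counts are deliberately not part of the
#' signature: the asymmetric-unit stoichiometry is a separate
#' crystal-form condition, and a monomer-ASU entry must share its
#' architecture signature with the corresponding dimer-ASU entry for
#' the crystal-form merge rule to apply.
#'
#' @param archs named character vector from [derive_architectures()].
#' @return character scalar.
#' @export
entry_arch_key <- function(archs) {
  paste(sort(unique(archs)), collapse = "|")
}
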