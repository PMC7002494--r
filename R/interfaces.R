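# Residue-contact detection, the published interaction rule, enumeration
# and symmetry-deduplication of unique interfaces, buried surface areas,
# and biological-assembly containment tests.

# A "unit" is one placed side of a potential interface: a chain copy or a
# domain slice of a chain copy, with heavy atoms only and per-residue
# C-beta coordinates (C-alpha substitutes for glycine or truncated side
# chains, so the C-beta rule stays total).
make_unit <- function(entry, asym_id, placement = NULL, domain = NULL) {
  chain <- entry$chains[[asym_id]]
  if (is.null(chain)) stop("no chain '", asym_id, "' in entry")
  at <- chain$atoms
  at <- at[!(toupper(at$element) %in% c("H", "D")), , drop = FALSE]
  if (!is.null(domain)) {
    at <- at[at$seq_pos %in% domain_positions(domain), , drop = FALSE]
  }
  if (!nrow(at)) {
    stop("unit ", asym_id,
         if (!is.null(domain)) paste0("/", domain$domain_id) else "",
         " has zero heavy atoms")
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (!is.null(placement)) xyz <- .placed_xyz(xyz, placement)
  cb_rows <- integer(0)
  for (sp in unique(at$seq_pos)) {
    rows <- which(at$seq_pos == sp)
    cb <- rows[at$atom[rows] == "CB"]
    if (!length(cb)) cb <- rows[at$atom[rows] == "CA"]
    if (length(cb)) cb_rows <- c(cb_rows, cb[1L])
  }
  list(kind = if (is.null(domain)) "chain" else "domain",
       entry_id = entry$entry_id, asym_id = asym_id,
       entity_id = chain$entity_id, domain = domain,
       placement = placement, seq_pos = at$seq_pos, atom = at$atom,
       element = at$element, resname = at$resname, xyz = xyz,
       cb_seq = at$seq_pos[cb_rows],
       cb_xyz = xyz[cb_rows, , drop = FALSE])
}

#' Residue contact set between two placed units
#'
#' Lists every residue pair with any heavy-atom distance within the
#' atomic cutoff or a C-beta--C-beta distance within the C-beta cutoff,
#' together with the counts the interaction rule needs. Glycine (and any
#' residue without a modeled C-beta) uses C-alpha as the C-beta
#' surrogate.
#'
#' @param unit_a,unit_b units from `make_unit()`.
#' @param config an [pipeline_config()] object.
#' @return object of class `xc_contacts`: list with `pairs` (data.frame
#'   `seq_i`, `seq_j`, `min_dist`, `cbeta_dist`), `n_cbeta12`, `n_atom5`.
#' @export
contact_set <- function(unit_a, unit_b, config = pipeline_config()) {
  if (!nrow(unit_a$xyz) || !nrow(unit_b$xyz)) {
    stop("contact_set requires units with heavy atoms")
  }
  # residue-pair minimum heavy-atom distances
  d2 <- .cross_dist2(unit_a$xyz, unit_b$xyz)
  seq_a <- sort(unique(unit_a$seq_pos))
  mind <- matrix(Inf, length(seq_a), length(unique(unit_b$seq_pos)),
                 dimnames = list(seq_a, sort(unique(unit_b$seq_pos))))
  fb <- factor(unit_b$seq_pos, levels = colnames(mind))
  for (i in seq_along(seq_a)) {
    rows <- which(unit_a$seq_pos == seq_a[i])
    colmin <- if (length(rows) == 1L) d2[rows, ] else
      apply(d2[rows, , drop = FALSE], 2L, min)
    mind[i, ] <- tapply(colmin, fb, min)
  }
  mind <- sqrt(mind)
  # C-beta distances on the same residue-pair grid
  cbd <- matrix(NA_real_, nrow(mind), ncol(mind),
                dimnames = dimnames(mind))
  if (length(unit_a$cb_seq) && length(unit_b$cb_seq)) {
    dcb <- sqrt(.cross_dist2(unit_a$cb_xyz, unit_b$cb_xyz))
    cbd[cbind(match(as.character(unit_a$cb_seq), rownames(cbd)),
              rep(match(as.character(unit_b$cb_seq), colnames(cbd)),
                  each = length(unit_a$cb_seq)))] <- as.vector(dcb)
  }
  keep <- which(mind <= config$atom_cutoff |
                  (!is.na(cbd) & cbd <= config$cbeta_cutoff),
                arr.ind = TRUE)
  pairs <- data.frame(
    seq_i = as.integer(rownames(mind)[keep[, 1L]]),
    seq_j = as.integer(colnames(mind)[keep[, 2L]]),
    min_dist = mind[keep], cbeta_dist = cbd[keep])
  pairs <- pairs[order(pairs$seq_i, pairs$seq_j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(
    pairs = pairs,
    n_cbeta12 = sum(!is.na(pairs$cbeta_dist) &
                      pairs$cbeta_dist <= config$cbeta_cutoff),
    n_atom5 = sum(pairs$min_dist <= config$atom_cutoff)
  ), class = "xc_contacts")
}

.cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' The interaction rule
#'
#' Chain and domain level: interacting iff there are at least
#' `min_cbeta_pairs` C-beta pairs within the C-beta cutoff AND at least
#' one atomic contact within the atomic cutoff, OR at least
#' `min_atom_contacts` atomic contacts. Peptide level differs: the two
#' clauses are joined by OR (C-beta pairs alone suffice).
#'
#' @param contacts an `xc_contacts` object.
#' @param level `"chain"`, `"domain"` or `"peptide"`.
#' @param config configuration.
#' @return logical.
#' @export
is_interacting <- function(contacts, level = c("chain", "domain", "peptide"),
                           config = pipeline_config()) {
  level <- match.arg(level)
  cb <- contacts$n_cbeta12 >= config$min_cbeta_pairs
  a1 <- contacts$n_atom5 >= 1L
  a5 <- contacts$n_atom5 >= config$min_atom_contacts
  if (level == "peptide") cb || a5 else (cb && a1) || a5
}

#' Buried surface area of an interface
#'
#' Half the solvent-accessible area buried on complexation,
#' `(SASA_a + SASA_b - SASA_ab) / 2`, by deterministic Shrake-Rupley
#' sampling; clamped at zero.
#'
#' @param unit_a,unit_b placed units.
#' @param config configuration (`sasa_probe`, `sasa_points`).
#' @return area in A^2.
#' @export
buried_surface_area <- function(unit_a, unit_b,
                                config = pipeline_config()) {
  sa <- sasa(unit_a$xyz, unit_a$element, config$sasa_probe,
             config$sasa_points)
  sb <- sasa(unit_b$xyz, unit_b$element, config$sasa_probe,
             config$sasa_points)
  sab <- sasa(rbind(unit_a$xyz, unit_b$xyz),
              c(unit_a$element, unit_b$element),
              config$sasa_probe, config$sasa_points)
  max(0, (sa + sb - sab) / 2)
}

# ---- mapped contact-pair labels --------------------------------------------

# Map residue positions of one chain to common-coordinate labels.
# Domain level: the HMM match position within the family.
# Chain level: (architecture rank | family | HMM position), concatenating
# the per-domain maps in architecture order.
# Sequence-position labels ("s<pos>") are always computed as the
# identity-correspondence fallback for identical sequences.
.position_labels <- function(seq_pos, domains_chain, level,
                             domain = NULL) {
  lab <- rep(NA_character_, length(seq_pos))
  if (level == "domain" && !is.null(domain)) {
    hit <- match(as.character(seq_pos), names(domain$hmm_map))
    lab[!is.na(hit)] <- as.character(domain$hmm_map[hit[!is.na(hit)]])
  } else if (length(domains_chain)) {
    starts <- vapply(domains_chain, function(d) d$intervals[1L, 1L],
                     numeric(1L))
    ord <- order(starts)
    for (r in seq_along(ord)) {
      d <- domains_chain[[ord[r]]]
      hit <- match(as.character(seq_pos), names(d$hmm_map))
      ok <- !is.na(hit) & is.na(lab)
      lab[ok] <- sprintf("%d|%s|%d", r, d$pfam_id, d$hmm_map[hit[ok]])
    }
  }
  lab
}

.pair_strings <- function(la, lb) {
  ok <- !is.na(la) & !is.na(lb)
  sort(unique(paste(la[ok], lb[ok], sep = "~")))
}

# ---- interface construction ------------------------------------------------

.mk_interface <- function(entry, level, unit_a, unit_b, contacts,
                          domains_by_chain, config, intra_chain = FALSE) {
  dom_a <- unit_a$domain; dom_b <- unit_b$domain
  fam_a <- if (!is.null(dom_a)) dom_a$pfam_id else
    attr(unit_a, "arch") %||% ""
  fam_b <- if (!is.null(dom_b)) dom_b$pfam_id else
    attr(unit_b, "arch") %||% ""
  la <- .position_labels(contacts$pairs$seq_i,
                         domains_by_chain[[unit_a$asym_id]] %||% list(),
                         level, dom_a)
  lb <- .position_labels(contacts$pairs$seq_j,
                         domains_by_chain[[unit_b$asym_id]] %||% list(),
                         level, dom_b)
  sa <- paste0("s", contacts$pairs$seq_i)
  sb <- paste0("s", contacts$pairs$seq_j)
  side_meta <- function(unit, dom) {
    chain <- entry$chains[[unit$asym_id]]
    doms <- domains_by_chain[[unit$asym_id]] %||% list()
    n_mapped <- if (!is.null(dom)) length(dom$hmm_map) else
      sum(vapply(doms, function(d) length(d$hmm_map), integer(1L)))
    n_res <- if (!is.null(dom)) length(domain_positions(dom)) else
      chain_length(chain)
    seq1 <- if (!is.null(dom)) {
      paste(strsplit(chain$sequence, "")[[1L]][domain_positions(dom)],
            collapse = "")
    } else chain$sequence
    list(asym_id = unit$asym_id, entity_id = unit$entity_id,
         domain_id = if (!is.null(dom)) dom$domain_id else NA_character_,
         family = if (!is.null(dom)) dom$pfam_id else
           attr(unit, "arch") %||% "",
         op_index = unit$placement$op_index %||% 1L,
         shift = unit$placement$shift %||% c(0L, 0L, 0L),
         n_mapped = n_mapped, n_res = n_res, sequence = seq1,
         uniprot = if (!is.null(dom) && !is.na(dom$uniprot)) dom$uniprot
                   else chain$uniprot,
         species = if (!is.null(dom) && !is.na(dom$species)) dom$species
                   else chain$species)
  }
  structure(list(
    interface_id = NA_character_, entry_id = entry$entry_id,
    level = level,
    side_a = c(side_meta(unit_a, dom_a)),
    side_b = c(side_meta(unit_b, dom_b)),
    contacts = contacts, intra_chain = intra_chain,
    hmm_pairs = .pair_strings(la, lb),
    hmm_pairs_rev = .pair_strings(lb, la),
    seq_pairs = .pair_strings(sa, sb),
    seq_pairs_rev = .pair_strings(sb, sa),
    family_key = paste(sort(c(fam_a, fam_b)), collapse = ":"),
    bsa = NA_real_, below_bsa_min = NA,
    in_author_assembly = NA, in_pisa_assembly = NA
  ), class = "xc_interface")
}

# Canonical duplicate key: two interfaces in one crystal are
# symmetry-equivalent iff their residue-level contact sets map onto each
# other (Q = 1) under the identity sequence correspondence, sides keyed
# by entity so relabeled symmetry copies collapse.
.iface_dup_key <- function(iface) {
  fwd <- paste(iface$side_a$entity_id, iface$side_b$entity_id,
               paste(iface$seq_pairs, collapse = ";"), sep = "#")
  rev <- paste(iface$side_b$entity_id, iface$side_a$entity_id,
               paste(iface$seq_pairs_rev, collapse = ";"), sep = "#")
  if (!is.na(iface$side_a$domain_id)) {
    fwd <- paste(fwd, iface$side_a$family, iface$side_b$family)
    rev <- paste(rev, iface$side_b$family, iface$side_a$family)
  }
  min(fwd, rev)
}

.iface_sort_key <- function(iface) {
  paste(iface$side_a$asym_id, iface$side_a$op_index,
        paste(iface$side_a$shift + 1L, collapse = ""),
        iface$side_b$asym_id,
        sprintf("%03d", iface$side_b$op_index),
        paste(iface$side_b$shift + 1L, collapse = ""))
}

#' Enumerate the unique interfaces of a crystal
#'
#' Expands candidate placement pairs anchored on the identity
#' asymmetric-unit copies, applies the interaction rule, collapses
#' symmetry-equivalent duplicates to one representative (the
#' lexicographically smallest by chain id, operator index and shift), and
#' computes buried surface areas. Domain-level enumeration derives
#' domain--domain interfaces from the chain-level contact sets (by the
#' family-defined start/stop positions) and adds intra-chain domain
#' pairs, flagged `intra_chain`. Interfaces whose buried area falls below
#' the configured minimum for their level are retained in the census with
#' `below_bsa_min = TRUE`; callers drop them before clustering.
#'
#' @param entry crystallographic entry.
#' @param placements lattice from [expand_lattice()]; computed if `NULL`.
#' @param level `"chain"` or `"domain"`.
#' @param domains domain annotations (required for `level = "domain"`,
#'   used for HMM-mapped contact labels at both levels).
#' @param config configuration.
#' @param compute_bsa set `FALSE` to skip surface areas (census only).
#' @param assembly_flags set `FALSE` to skip assembly containment tests.
#' @return list of `xc_interface` objects, deterministically ordered.
#' @export
enumerate_unique_interfaces <- function(entry, placements = NULL,
                                        level = c("chain", "domain"),
                                        domains = list(),
                                        config = pipeline_config(),
                                        compute_bsa = TRUE,
                                        assembly_flags = TRUE) {
  level <- match.arg(level)
  .assert_crystallographic(entry)
  if (level == "domain" && !length(domains)) {
    stop("domain-level enumeration requires domain annotations")
  }
  if (is.null(placements)) placements <- expand_lattice(entry)
  domains_by_chain <- split(domains,
                            vapply(domains, `[[`, character(1L), "asym_id"))
  archs <- derive_architectures(entry, domains)

  prune <- max(config$prune_radius, config$cbeta_cutoff, config$atom_cutoff)
  cand <- candidate_pairs(entry, placements, prune_radius = prune)
  unit_cache <- new.env(parent = emptyenv())
  get_unit <- function(pidx) {
    key <- as.character(pidx)
    if (is.null(unit_cache[[key]])) {
      p <- placements[[pidx]]
      u <- make_unit(entry, p$asym_id, placement = p)
      attr(u, "arch") <- unname(archs[p$asym_id])
      unit_cache[[key]] <- u
    }
    unit_cache[[key]]
  }

  chain_ifaces <- list(); keys <- character(0)
  for (i in seq_len(nrow(cand))) {
    ua <- get_unit(cand$ref[i]); ub <- get_unit(cand$other[i])
    cs <- contact_set(ua, ub, config)
    if (!nrow(cs$pairs) || !is_interacting(cs, "chain", config)) next
    ifc <- .mk_interface(entry, "chain", ua, ub, cs, domains_by_chain,
                         config)
    key <- .iface_dup_key(ifc)
    hit <- match(key, keys)
    if (is.na(hit)) {
      keys <- c(keys, key)
      chain_ifaces[[length(chain_ifaces) + 1L]] <- ifc
      attr(chain_ifaces[[length(chain_ifaces)]], "units") <- list(ua, ub)
    } else if (.iface_sort_key(ifc) <
                 .iface_sort_key(chain_ifaces[[hit]])) {
      chain_ifaces[[hit]] <- ifc
      attr(chain_ifaces[[hit]], "units") <- list(ua, ub)
    }
  }
  ord <- order(vapply(chain_ifaces, .iface_sort_key, character(1L)))
  chain_ifaces <- chain_ifaces[ord]

  if (level == "chain") {
    out <- chain_ifaces
  } else {
    out <- list()
    for (ifc in chain_ifaces) {
      us <- attr(ifc, "units")
      doms_a <- domains_by_chain[[ifc$side_a$asym_id]] %||% list()
      doms_b <- domains_by_chain[[ifc$side_b$asym_id]] %||% list()
      for (da in doms_a) for (db in doms_b) {
        sub <- ifc$contacts$pairs
        sub <- sub[sub$seq_i %in% domain_positions(da) &
                     sub$seq_j %in% domain_positions(db), , drop = FALSE]
        if (!nrow(sub)) next
        cs <- structure(list(
          pairs = sub,
          n_cbeta12 = sum(!is.na(sub$cbeta_dist) &
                            sub$cbeta_dist <= config$cbeta_cutoff),
          n_atom5 = sum(sub$min_dist <= config$atom_cutoff)),
          class = "xc_contacts")
        if (!is_interacting(cs, "domain", config)) next
        ua <- make_unit(entry, ifc$side_a$asym_id, us[[1L]]$placement, da)
        ub <- make_unit(entry, ifc$side_b$asym_id, us[[2L]]$placement, db)
        difc <- .mk_interface(entry, "domain", ua, ub, cs,
                              domains_by_chain, config)
        attr(difc, "units") <- list(ua, ub)
        out[[length(out) + 1L]] <- difc
      }
    }
    # intra-chain domain pairs on the identity copies
    for (asym in names(entry$chains)) {
      ds <- domains_by_chain[[asym]] %||% list()
      if (length(ds) < 2L) next
      for (i in seq_len(length(ds) - 1L)) for (j in (i + 1L):length(ds)) {
        ua <- make_unit(entry, asym, NULL, ds[[i]])
        ub <- make_unit(entry, asym, NULL, ds[[j]])
        cs <- contact_set(ua, ub, config)
        if (!nrow(cs$pairs) || !is_interacting(cs, "domain", config)) next
        difc <- .mk_interface(entry, "domain", ua, ub, cs,
                              domains_by_chain, config,
                              intra_chain = TRUE)
        attr(difc, "units") <- list(ua, ub)
        out[[length(out) + 1L]] <- difc
      }
    }
    keyed <- vapply(out, .iface_dup_key, character(1L))
    keep <- !duplicated(keyed)
    out <- out[keep]
    out <- out[order(vapply(out, .iface_sort_key, character(1L)))]
  }

  min_bsa <- if (level == "chain") config$min_bsa_chain else
    config$min_bsa_domain
  for (i in seq_along(out)) {
    us <- attr(out[[i]], "units")
    if (compute_bsa) {
      out[[i]]$bsa <- buried_surface_area(us[[1L]], us[[2L]], config)
      out[[i]]$below_bsa_min <- out[[i]]$bsa < min_bsa
    }
    out[[i]]$interface_id <- sprintf("%s_%s%03d", entry$entry_id,
                                     substr(level, 1L, 1L), i)
    if (assembly_flags && length(entry$assemblies)) {
      auth <- Filter(function(a) a$provenance == "author",
                     entry$assemblies)
      pisa <- Filter(function(a) a$provenance == "pisa",
                     entry$assemblies)
      if (length(auth)) {
        out[[i]]$in_author_assembly <- any(vapply(auth, function(a) {
          assembly_contains_interface(out[[i]], a, entry, config)
        }, logical(1L)))
      }
      if (length(pisa)) {
        out[[i]]$in_pisa_assembly <- any(vapply(pisa, function(a) {
          assembly_contains_interface(out[[i]], a, entry, config)
        }, logical(1L)))
      }
    }
  }
  out
}

#' Does a biological assembly contain an interface?
#'
#' Instantiates the assembly from its operator expressions and tests
#' whether any chain pair in it forms an interface whose Q score against
#' the query (identity sequence correspondence, entity-matched sides) is
#' at least `q_high`.
#'
#' @param entry the entry.
#' @param interface an `xc_interface` of the same entry.
#' @param assembly an `xc_assembly`.
#' @param config configuration.
#' @return logical.
#' @export
assembly_contains_interface <- function(interface, assembly, entry,
                                        config = pipeline_config()) {
  M <- if (!is.null(entry$cell)) frac_to_orth_matrix(entry$cell) else diag(3)
  Mi <- solve(M)
  mem <- assembly$members
  units <- lapply(seq_len(nrow(mem)), function(i) {
    k <- mem$op_index[i]
    op <- entry$sym_ops[[k]]
    sh <- c(mem$si[i], mem$sj[i], mem$sk[i])
    pl <- if (k == 1L && all(sh == 0)) NULL else {
      structure(list(asym_id = mem$asym_id[i], op_index = k, shift = sh,
                     R = M %*% op$R %*% Mi,
                     t = as.vector(M %*% (op$t + sh)),
                     placement_id = "asm"), class = "xc_placement")
    }
    make_unit(entry, mem$asym_id[i], placement = pl)
  })
  if (length(units) < 2L) return(FALSE)
  q_pairs <- interface$seq_pairs
  q_pairs_rev <- interface$seq_pairs_rev
  ent_a <- interface$side_a$entity_id; ent_b <- interface$side_b$entity_id
  dom_a <- interface$side_a$domain_id; dom_b <- interface$side_b$domain_id
  pos_a <- pos_b <- NULL
  if (interface$level == "domain") {
    us <- attr(interface, "units", exact = TRUE)
    if (!is.null(us)) {
      pos_a <- unique(us[[1L]]$seq_pos); pos_b <- unique(us[[2L]]$seq_pos)
    }
  }
  for (i in seq_len(length(units) - 1L)) {
    for (j in (i + 1L):length(units)) {
      ui <- units[[i]]; uj <- units[[j]]
      pair_ents <- c(ui$entity_id, uj$entity_id)
      if (!setequal(pair_ents, c(ent_a, ent_b)) &&
          !all(pair_ents %in% c(ent_a, ent_b))) next
      cs <- tryCatch(contact_set(ui, uj, config), error = function(e) NULL)
      if (is.null(cs) || !nrow(cs$pairs)) next
      sub <- cs$pairs
      if (!is.null(pos_a)) {
        keep <- (sub$seq_i %in% pos_a & sub$seq_j %in% pos_b) |
          (sub$seq_i %in% pos_b & sub$seq_j %in% pos_a)
        sub <- sub[keep, , drop = FALSE]
        if (!nrow(sub)) next
      }
      pa <- paste0("s", sub$seq_i); pb <- paste0("s", sub$seq_j)
      cand <- .pair_strings(pa, pb); cand_rev <- .pair_strings(pb, pa)
      q <- max(.jaccard(q_pairs, cand), .jaccard(q_pairs, cand_rev),
               .jaccard(q_pairs_rev, cand))
      if (q >= config$q_high) return(TRUE)
    }
  }
  FALSE
}

.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Interface census as a data.frame
#'
#' One row per unique interface: sides, contact counts, buried area,
#' flags. Written as the interface-census TSV by the pipeline.
#'
#' @param interfaces list of `xc_interface`.
#' @return data.frame.
#' @export
interface_census <- function(interfaces) {
  if (!length(interfaces)) {
    return(data.frame(interface_id = character(0)))
  }
  do.call(rbind, lapply(interfaces, function(x) data.frame(
    interface_id = x$interface_id, entry_id = x$entry_id, level = x$level,
    side_a = x$side_a$asym_id,
    dom_a = x$side_a$domain_id %||% NA_character_,
    op_a = x$side_a$op_index, shift_a = paste(x$side_a$shift,
                                              collapse = ","),
    side_b = x$side_b$asym_id,
    dom_b = x$side_b$domain_id %||% NA_character_,
    op_b = x$side_b$op_index, shift_b = paste(x$side_b$shift,
                                              collapse = ","),
    n_cbeta12 = x$contacts$n_cbeta12, n_atom5 = x$contacts$n_atom5,
    bsa = x$bsa, intra_chain = x$intra_chain,
    below_bsa_min = x$below_bsa_min,
    in_author_assembly = x$in_author_assembly,
    in_pisa_assembly = x$in_pisa_assembly,
    family_key = x$family_key, stringsAsFactors = FALSE)))
}
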