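# Pipeline orchestration: read entries, expand lattices, enumerate and
# cluster interfaces, group crystal forms, run the peptide and ligand
# analyses, and write the on-disk cluster store (a directory of TSV
# tables plus a JSON index). Also answers protein-list interaction
# queries against a built store.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Run the full interface-clustering pipeline
#'
#' Stages: read entries, ingest annotations, expand lattices and
#' enumerate unique chain and domain interfaces, group and merge
#' crystal forms, cluster interfaces across crystal forms, detect and
#' cluster domain-peptide interfaces, profile and cluster domain-ligand
#' contacts, select nucleic-acid interfaces, and write all report
#' tables. Entries that fail to parse are quarantined (logged, skipped)
#' and the run continues. All outputs are deterministic given the
#' inputs and configuration; rerunning into the same directory
#' reproduces the tables byte for byte.
#'
#' @param entry_paths character vector of structure files, or a list of
#'   `xc_entry` objects.
#' @param annotations path to the domain-annotation TSV (or data.frame).
#' @param out_dir output directory for the cluster store; `NULL` keeps
#'   the store in memory only.
#' @param config configuration.
#' @param verbose emit per-stage progress messages.
#' @return the store: a list with entries, interfaces, crystal forms,
#'   clusters, peptide and ligand results, and all report tables.
#' @export
run_pipeline <- function(entry_paths, annotations, out_dir = NULL,
                         config = pipeline_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!length(entry_paths)) stop("at least one entry is required")

  entries <- list(); quarantined <- character(0)
  if (is.list(entry_paths) && inherits(entry_paths[[1L]], "xc_entry")) {
    for (e in entry_paths) entries[[e$entry_id]] <- e
  } else {
    for (p in entry_paths) {
      e <- tryCatch(read_entry(p), error = function(err) {
        message("quarantined ", p, ": ", conditionMessage(err))
        NULL
      })
      if (is.null(e)) quarantined <- c(quarantined, p)
      else entries[[e$entry_id]] <- e
    }
  }
  if (!length(entries)) stop("no entries could be read")
  say("stage read: %d entries (%d quarantined)", length(entries),
      length(quarantined))

  ann_df <- if (is.character(annotations)) {
    utils::read.delim(annotations, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = "character")
  } else as.data.frame(annotations)
  domains <- lapply(entries, function(e) ingest_annotations(e, ann_df))
  archs <- lapply(entries, function(e) {
    derive_architectures(e, domains[[e$entry_id]])
  })
  arch_keys <- vapply(archs, entry_arch_key, character(1L))
  say("stage annotate: %d domains",
      sum(vapply(domains, length, integer(1L))))

  chain_ifaces <- list(); domain_ifaces <- list()
  for (eid in names(entries)) {
    e <- entries[[eid]]
    if (!is_crystallographic(e)) {
      say("stage interfaces: %s is non-crystallographic, lattice skipped",
          eid)
      chain_ifaces[[eid]] <- list(); domain_ifaces[[eid]] <- list()
      next
    }
    pl <- expand_lattice(e)
    chain_ifaces[[eid]] <- enumerate_unique_interfaces(
      e, pl, "chain", domains[[eid]], config)
    domain_ifaces[[eid]] <- if (length(domains[[eid]])) {
      enumerate_unique_interfaces(e, pl, "domain", domains[[eid]],
                                  config)
    } else list()
    say("stage interfaces: %s -> %d chain, %d domain", eid,
        length(chain_ifaces[[eid]]), length(domain_ifaces[[eid]]))
  }

  forms <- group_crystal_forms(unname(entries), arch_keys, config)
  forms <- merge_equivalent_forms(forms, chain_ifaces, config)
  cf_assign <- crystal_form_assignment(forms)
  say("stage crystal forms: %d forms", length(forms))

  all_chain <- unlist(chain_ifaces, recursive = FALSE, use.names = FALSE)
  all_domain <- unlist(domain_ifaces, recursive = FALSE,
                       use.names = FALSE)
  clusters_chain <- cluster_interfaces(all_chain, cf_assign, config)
  clusters_domain <- cluster_interfaces(all_domain, cf_assign, config)
  say("stage cluster: %d chain clusters, %d domain clusters",
      length(clusters_chain), length(clusters_domain))

  pep_ifaces <- unlist(lapply(names(entries), function(eid) {
    find_peptide_interfaces(entries[[eid]], domains[[eid]], config)
  }), recursive = FALSE)
  pep_clusters <- cluster_peptide_interfaces(pep_ifaces, config)
  say("stage peptides: %d interfaces, %d clusters",
      length(pep_ifaces), length(pep_clusters))

  lig_profiles <- unlist(lapply(names(entries), function(eid) {
    ligand_profiles(entries[[eid]], domains[[eid]], config)
  }), recursive = FALSE)
  lig_clusters <- cluster_ligand_sites(lig_profiles, config)
  nuc_ifaces <- unlist(lapply(names(entries), function(eid) {
    has_nuc <- any(vapply(entries[[eid]]$chains, function(ch) {
      ch$polymer_type %in% c("DNA", "RNA")
    }, logical(1L)))
    if (!has_nuc) return(list())
    select_nucleic_interface(entries[[eid]], domains[[eid]], config)
  }), recursive = FALSE)
  say("stage ligands: %d profiles, %d site clusters, %d nucleic",
      length(lig_profiles), length(lig_clusters), length(nuc_ifaces))

  store <- list(
    entries = entries, domains = domains, arch_keys = arch_keys,
    chain_interfaces = chain_ifaces, domain_interfaces = domain_ifaces,
    crystal_forms = forms, cf_assign = cf_assign,
    clusters_chain = clusters_chain, clusters_domain = clusters_domain,
    peptide_interfaces = pep_ifaces, peptide_clusters = pep_clusters,
    ligand_profiles = lig_profiles, ligand_clusters = lig_clusters,
    nucleic_interfaces = nuc_ifaces, quarantined = quarantined,
    tables = list(
      interfaces_chain = interface_census(all_chain),
      interfaces_domain = interface_census(all_domain),
      crystal_forms = crystal_form_table(forms),
      clusters_chain = cluster_table(clusters_chain, cf_assign),
      clusters_chain_summary = cluster_summary(clusters_chain),
      clusters_domain = cluster_table(clusters_domain, cf_assign),
      clusters_domain_summary = cluster_summary(clusters_domain),
      peptide_clusters = peptide_cluster_table(pep_clusters),
      ligand_profiles = ligand_table(lig_profiles),
      nucleic_interfaces = ligand_table(nuc_ifaces)
    ))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(store$tables)) {
      .write_tsv(store$tables[[nm]], file.path(out_dir,
                                               paste0(nm, ".tsv")))
    }
    lig_cl_df <- do.call(rbind, c(list(data.frame(
      cluster_id = character(0), pfam = character(0),
      ligands = character(0), n_members = integer(0),
      consensus_positions = character(0))),
      lapply(lig_clusters, function(cl) data.frame(
        cluster_id = cl$cluster_id, pfam = cl$pfam,
        ligands = paste(cl$ligand_comp_ids, collapse = ","),
        n_members = length(cl$member_ids),
        consensus_positions = paste(cl$consensus_hmm_positions,
                                    collapse = ","),
        stringsAsFactors = FALSE))))
    .write_tsv(lig_cl_df, file.path(out_dir, "ligand_clusters.tsv"))
    idx <- list(
      n_entries = length(entries),
      entry_ids = sort(names(entries)),
      n_crystal_forms = length(forms),
      n_chain_clusters = length(clusters_chain),
      n_domain_clusters = length(clusters_domain),
      n_peptide_clusters = length(pep_clusters),
      n_ligand_clusters = length(lig_clusters),
      quarantined = quarantined)
    jsonlite::write_json(idx, file.path(out_dir, "index.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("store written to %s", out_dir)
  }
  invisible(store)
}

#' Export a cluster's member coordinates and a visualization script
#'
#' Writes each member interface as a two-chain PDB file (sides renamed
#' A and B, symmetry applied) and a plain-text command script that
#' loads and superposes the members on their common mapped positions.
#'
#' @param cluster an `xc_cluster`.
#' @param dir output directory.
#' @return invisible vector of file paths.
#' @export
export_cluster_archive <- function(cluster, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (m in cluster$members) {
    us <- attr(m, "units", exact = TRUE)
    if (is.null(us)) next
    path <- file.path(dir, paste0(m$interface_id, ".pdb"))
    con <- file(path, "w")
    serial <- 0L
    for (side in 1:2) {
      u <- us[[side]]
      for (i in seq_len(nrow(u$xyz))) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, substr(u$atom[i], 1, 4), substr(u$resname[i], 1, 3),
          c("A", "B")[side], u$seq_pos[i], u$xyz[i, 1L], u$xyz[i, 2L],
          u$xyz[i, 3L], u$element[i]), con)
      }
      writeLines("TER", con)
    }
    close(con)
    paths <- c(paths, path)
  }
  script <- file.path(dir, "superpose_members.txt")
  writeLines(c(
    sprintf("# cluster %s: %d members", cluster$cluster_id,
            length(cluster$members)),
    sprintf("load %s.pdb", vapply(cluster$members, `[[`, character(1L),
                                  "interface_id")),
    "# align all members onto the first by their common mapped positions",
    sprintf("align %s, %s",
            vapply(cluster$members, `[[`, character(1L), "interface_id"),
            cluster$members[[1L]]$interface_id)), script)
  invisible(c(paths, script))
}

#' Query structural interactions among a protein list
#'
#' Looks up, for every protein pair in scope, whether the cluster store
#' holds a domain-level cluster for any of their family pairs; an edge
#' is labeled with the largest such cluster's crystal-form and entry
#' counts. `"first_to_all"` restricts pairs to those involving the
#' first (hub) protein; `"all_to_all"` considers every pair. If no
#' structural cluster exists for a pair but one protein carries a
#' family on the professional-peptide-binding-domain list, a predicted
#' peptide:PPBD edge is emitted, labeled from the peptide-cluster
#' store.
#'
#' @param proteins data.frame with columns `name` and `families`
#'   (comma-separated family ids per protein).
#' @param store a store from [run_pipeline()].
#' @param mode `"all_to_all"` or `"first_to_all"`.
#' @param ppbd_list character vector of PPBD family ids.
#' @return data.frame of edges: `protein_a`, `protein_b`, `edge_type`,
#'   `label`, `n_crystal_forms`, `n_entries`.
#' @export
query_interaction_network <- function(proteins, store,
                                      mode = c("all_to_all",
                                               "first_to_all"),
                                      ppbd_list = character(0)) {
  mode <- match.arg(mode)
  proteins <- as.data.frame(proteins)
  fams <- strsplit(proteins$families, ",", fixed = TRUE)
  names(fams) <- proteins$name
  for (nm in proteins$name[!vapply(fams, length, integer(1L))]) {
    warning("protein ", nm, " has no family annotations; no edges")
  }
  summ <- store$tables$clusters_domain_summary
  pep <- store$peptide_clusters
  pairs <- utils::combn(seq_len(nrow(proteins)), 2L)
  if (mode == "first_to_all") {
    pairs <- pairs[, pairs[1L, ] == 1L, drop = FALSE]
  }
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- proteins$name[pairs[1L, k]]; b <- proteins$name[pairs[2L, k]]
    keys <- unique(apply(expand.grid(fams[[a]], fams[[b]]), 1L,
                         function(p) paste(sort(p), collapse = ":")))
    hit <- summ[summ$family_key %in% keys, , drop = FALSE]
    if (nrow(hit)) {
      hit <- hit[order(-hit$n_crystal_forms, -hit$n_entries), ,
                 drop = FALSE][1L, ]
      rows[[length(rows) + 1L]] <- data.frame(
        protein_a = a, protein_b = b, edge_type = "structural",
        label = hit$family_key,
        n_crystal_forms = hit$n_crystal_forms,
        n_entries = hit$n_entries, stringsAsFactors = FALSE)
    } else {
      ppbd <- intersect(c(fams[[a]], fams[[b]]), ppbd_list)
      if (length(ppbd)) {
        pc <- Filter(function(cl) cl$pfam == ppbd[1L], pep)
        n_ent <- if (length(pc)) {
          max(vapply(pc, `[[`, integer(1L), "n_entries"))
        } else NA_integer_
        rows[[length(rows) + 1L]] <- data.frame(
          protein_a = a, protein_b = b, edge_type = "predicted_peptide",
          label = paste0("peptide:", ppbd[1L]),
          n_crystal_forms = NA_integer_, n_entries = n_ent,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      edge_type = character(0), label = character(0),
                      n_crystal_forms = integer(0),
                      n_entries = integer(0)))
  }
  do.call(rbind, rows)
}
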