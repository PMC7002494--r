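# Domain-ligand contact profiles (4.5 A rule, water excluded), ligand
# binding-site clustering by shared HMM contact positions, and
# domain-nucleic-acid interface selection from biological assemblies.

.ligand_heavy <- function(lig) {
  at <- lig$atoms
  at <- at[!(toupper(at$element) %in% c("H", "D")), , drop = FALSE]
  at
}

#' Contact profile of a domain with a ligand
#'
#' A ligand interaction requires at least one atomic contact within
#' `ligand_cutoff` (4.5 A) between the domain and a non-water,
#' non-polymer component. Computed on the asymmetric unit. The profile
#' records the contacted residues mapped to HMM match positions.
#'
#' @param entry the entry.
#' @param domain an `xc_domain`.
#' @param ligand an `xc_ligand` (water returns `NULL`).
#' @param config configuration.
#' @return an `xc_ligand_profile`, or `NULL` if there is no contact.
#' @export
ligand_contact_profile <- function(entry, domain, ligand,
                                   config = pipeline_config()) {
  if (ligand$is_water) return(NULL)
  lat <- .ligand_heavy(ligand)
  if (!nrow(lat)) return(NULL)
  dom_unit <- make_unit(entry, domain$asym_id, domain = domain)
  lxyz <- as.matrix(lat[, c("x", "y", "z")])
  d2 <- .cross_dist2(dom_unit$xyz, lxyz)
  hit <- d2 <= config$ligand_cutoff^2
  if (!any(hit)) return(NULL)
  res <- sort(unique(dom_unit$seq_pos[rowSums(hit) > 0L]))
  hmm <- sort(unique(as.integer(domain$hmm_map[as.character(res)])))
  hmm <- hmm[!is.na(hmm)]
  structure(list(
    pfam = domain$pfam_id, comp_id = ligand$comp_id,
    ligand_class = "ligand", entry_id = entry$entry_id,
    domain_id = domain$domain_id, instance_id = ligand$instance_id,
    residues = res, hmm_positions = hmm,
    n_atomic_contacts = sum(hit)
  ), class = "xc_ligand_profile")
}

#' All domain-ligand profiles of an entry (asymmetric unit)
#'
#' @param entry the entry.
#' @param domains annotations.
#' @param config configuration.
#' @return list of `xc_ligand_profile`.
#' @export
ligand_profiles <- function(entry, domains,
                            config = pipeline_config()) {
  out <- list()
  for (d in domains) {
    for (lg in entry$ligands) {
      p <- ligand_contact_profile(entry, d, lg, config)
      if (!is.null(p)) out[[length(out) + 1L]] <- p
    }
  }
  out
}

#' Cluster the ligands of one family by shared binding-site positions
#'
#' Average-linkage agglomeration on the Jaccard overlap of the HMM
#' positions each ligand instance contacts; clusters merge while the
#' average overlap is at least `ligand_site_jaccard`. Separate sites
#' (e.g. a substrate site and an allosteric site) end up in separate
#' clusters.
#'
#' @param profiles list of `xc_ligand_profile` for one Pfam.
#' @param config configuration.
#' @return list of `xc_ligand_site_cluster`.
#' @export
cluster_ligand_sites <- function(profiles,
                                 config = pipeline_config()) {
  if (!length(profiles)) return(list())
  fams <- vapply(profiles, `[[`, character(1L), "pfam")
  out <- list()
  for (fam in sort(unique(fams))) {
    sub <- profiles[fams == fam]
    n <- length(sub)
    ids <- sprintf("%s_%s_%s", vapply(sub, `[[`, character(1L),
                                      "entry_id"),
                   vapply(sub, `[[`, character(1L), "instance_id"),
                   vapply(sub, `[[`, character(1L), "domain_id"))
    S <- diag(1, n)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        S[i, j] <- S[j, i] <- .jaccard(
          as.character(sub[[i]]$hmm_positions),
          as.character(sub[[j]]$hmm_positions))
      }
    }
    rownames(S) <- colnames(S) <- ids
    memberships <- average_linkage_cluster(S, config$ligand_site_jaccard)
    for (ci in seq_along(memberships)) {
      ix <- match(memberships[[ci]], ids)
      consensus <- sort(Reduce(intersect,
                               lapply(sub[ix], `[[`, "hmm_positions")))
      out[[length(out) + 1L]] <- structure(list(
        cluster_id = sprintf("lig_%s_cl%02d", fam, ci), pfam = fam,
        ligand_comp_ids = sort(unique(vapply(sub[ix], `[[`,
                                             character(1L), "comp_id"))),
        consensus_hmm_positions = consensus,
        member_ids = ids[ix], members = sub[ix]
      ), class = "xc_ligand_site_cluster")
    }
  }
  out
}

# Contact profile of a placed domain unit against a placed nucleic
# chain, using the same 4.5 A atomic-contact machinery as ligands
# (nucleic acids are treated like other ligands).
.nucleic_profile <- function(entry, domain, dom_placement, nuc_chain,
                             nuc_placement, config) {
  dom_unit <- make_unit(entry, domain$asym_id, placement = dom_placement,
                        domain = domain)
  nuc_unit <- make_unit(entry, nuc_chain$asym_id,
                        placement = nuc_placement)
  d2 <- .cross_dist2(dom_unit$xyz, nuc_unit$xyz)
  hit <- d2 <= config$ligand_cutoff^2
  if (!any(hit)) return(NULL)
  res <- sort(unique(dom_unit$seq_pos[rowSums(hit) > 0L]))
  hmm <- sort(unique(as.integer(domain$hmm_map[as.character(res)])))
  hmm <- hmm[!is.na(hmm)]
  structure(list(
    pfam = domain$pfam_id, comp_id = nuc_chain$asym_id,
    ligand_class = nuc_chain$polymer_type, entry_id = entry$entry_id,
    domain_id = domain$domain_id, instance_id = nuc_chain$asym_id,
    residues = res, hmm_positions = hmm,
    n_atomic_contacts = sum(hit)
  ), class = "xc_ligand_profile")
}

.placement_from_member <- function(entry, m) {
  k <- m$op_index
  sh <- c(m$si, m$sj, m$sk)
  if (k == 1L && all(sh == 0)) return(NULL)
  M <- frac_to_orth_matrix(entry$cell)
  op <- entry$sym_ops[[k]]
  structure(list(asym_id = m$asym_id, op_index = k, shift = sh,
                 R = M %*% op$R %*% solve(M),
                 t = as.vector(M %*% (op$t + sh)), placement_id = "asm"),
            class = "xc_placement")
}

#' Select the nucleic-acid interface of each domain instance
#'
#' Domain-DNA/RNA interfaces are evaluated within the biological
#' assemblies; for each domain instance the interface with the largest
#' number of HMM positions in contact with DNA or RNA is selected (ties
#' broken by assembly id then chain id). Entries without assemblies
#' fall back to the asymmetric unit with a warning.
#'
#' @param entry the entry.
#' @param domains annotations.
#' @param config configuration.
#' @return list of selected `xc_ligand_profile` objects (class DNA or
#'   RNA), at most one per domain instance.
#' @export
select_nucleic_interface <- function(entry, domains,
                                     config = pipeline_config()) {
  nuc <- Filter(function(ch) ch$polymer_type %in% c("DNA", "RNA"),
                entry$chains)
  if (!length(nuc) || !length(domains)) return(list())
  assemblies <- entry$assemblies
  fallback <- FALSE
  if (!length(assemblies)) {
    warning("entry ", entry$entry_id, " has no assembly records; ",
            "nucleic-acid interfaces computed from the asymmetric unit")
    fallback <- TRUE
    mem <- data.frame(asym_id = names(entry$chains), op_index = 1L,
                      si = 0L, sj = 0L, sk = 0L)
    assemblies <- list(assembly_def("ASU", "author", mem))
  }
  out <- list()
  for (d in domains) {
    best <- NULL; best_key <- NULL
    for (a in assemblies) {
      mem <- a$members
      dom_rows <- which(mem$asym_id == d$asym_id)
      nuc_rows <- which(mem$asym_id %in% names(nuc))
      for (i in dom_rows) for (j in nuc_rows) {
        pr <- .nucleic_profile(
          entry, d, .placement_from_member(entry, mem[i, ]),
          entry$chains[[mem$asym_id[j]]],
          .placement_from_member(entry, mem[j, ]), config)
        if (is.null(pr)) next
        key <- sprintf("%09d_%s_%s", 1e8 - length(pr$hmm_positions),
                       a$assembly_id, mem$asym_id[j])
        if (is.null(best) || key < best_key) {
          best <- pr; best_key <- key
          best$assembly_id <- if (fallback) NA_character_ else
            a$assembly_id
        }
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  out
}

#' Ligand/nucleic profile table
#' @param profiles list of `xc_ligand_profile`.
#' @return data.frame.
#' @export
ligand_table <- function(profiles) {
  if (!length(profiles)) {
    return(data.frame(pfam = character(0)))
  }
  do.call(rbind, lapply(profiles, function(p) data.frame(
    pfam = p$pfam, ligand = p$comp_id, class = p$ligand_class,
    entry_id = p$entry_id, domain_id = p$domain_id,
    instance_id = p$instance_id, n_contacts = p$n_atomic_contacts,
    hmm_positions = paste(p$hmm_positions, collapse = ","),
    stringsAsFactors = FALSE)))
}
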