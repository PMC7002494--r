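# Domain-peptide interfaces: detection with the peptide interaction
# rule, the 75% assignment rule, domain superposition on common HMM
# positions, minimum peptide RMSD over ungapped alignments, and
# binding-mode clustering by shared HMM contact sites.

#' Is a chain a peptide?
#'
#' A peptide is a polypeptide chain whose full polymer length (modeled
#' or not) is strictly less than `peptide_max_len` residues.
#'
#' @param chain an `xc_chain`.
#' @param config configuration.
#' @return logical.
#' @export
is_peptide <- function(chain, config = pipeline_config()) {
  chain$polymer_type == "polypeptide" &&
    chain_length(chain) < config$peptide_max_len
}

# C-alpha coordinates of a domain keyed by HMM match position.
.domain_hmm_ca <- function(entry, domain, placement = NULL) {
  chain <- entry$chains[[domain$asym_id]]
  at <- chain$atoms
  ca <- at[at$atom == "CA" &
             at$seq_pos %in% as.integer(names(domain$hmm_map)), ,
           drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  if (!is.null(placement)) xyz <- .placed_xyz(xyz, placement)
  rownames(xyz) <- as.character(
    domain$hmm_map[as.character(ca$seq_pos)])
  xyz
}

.peptide_ca <- function(chain) {
  at <- chain$atoms
  ca <- at[at$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$seq_pos), , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  rownames(xyz) <- as.character(ca$seq_pos)
  xyz
}

#' Find domain-peptide interfaces
#'
#' Scans every (annotated domain, peptide chain) pair of an entry,
#' including symmetry-placed domain copies when the entry is
#' crystallographic, and keeps pairs satisfying the peptide interaction
#' rule: at least `min_cbeta_pairs` C-beta pairs within the C-beta
#' cutoff OR at least `min_atom_contacts` atomic contacts (note the OR,
#' unlike the chain/domain rule). When one peptide contacts several
#' chains, it is assigned to the chain holding at least
#' `peptide_assign_frac` of its atomic contacts; otherwise all its
#' interfaces are kept.
#'
#' @param entry an `xc_entry`.
#' @param domains annotations from [ingest_annotations()].
#' @param config configuration.
#' @param use_lattice include symmetry-placed domain copies (default
#'   when the entry is crystallographic).
#' @return list of `xc_peptide_interface` objects.
#' @export
find_peptide_interfaces <- function(entry, domains,
                                    config = pipeline_config(),
                                    use_lattice = is_crystallographic(entry)) {
  peps <- Filter(function(ch) is_peptide(ch, config), entry$chains)
  if (!length(peps) || !length(domains)) return(list())
  pep_ids <- names(peps)
  domains <- Filter(function(d) !(d$asym_id %in% pep_ids), domains)
  if (!length(domains)) return(list())
  placements <- list(NULL)
  if (use_lattice) {
    lat <- expand_lattice(entry)
    placements <- c(placements,
                    lat[!vapply(lat, is_identity_placement, logical(1L))])
  }
  out <- list(); seen <- character(0)
  for (pid in pep_ids) {
    pep_unit <- make_unit(entry, pid)
    for (d in domains) {
      for (pl in placements) {
        if (!is.null(pl) && pl$asym_id != d$asym_id) next
        dom_unit <- make_unit(entry, d$asym_id, placement = pl,
                              domain = d)
        # cheap box prune
        if (min(.cross_dist2(dom_unit$xyz, pep_unit$xyz)) >
              config$cbeta_cutoff^2) next
        cs <- contact_set(dom_unit, pep_unit, config)
        if (!nrow(cs$pairs) || !is_interacting(cs, "peptide", config)) next
        sites <- sort(unique(as.integer(
          d$hmm_map[as.character(cs$pairs$seq_i)])))
        sites <- sites[!is.na(sites)]
        key <- paste(d$domain_id, pid,
                     paste(cs$pairs$seq_i, cs$pairs$seq_j,
                           collapse = ";"))
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- structure(list(
          id = NA_character_, entry_id = entry$entry_id,
          domain = d, domain_asym = d$asym_id, peptide_asym = pid,
          pfam_id = d$pfam_id, contacts = cs, hmm_sites = sites,
          peptide_sequence = entry$chains[[pid]]$sequence,
          dom_hmm_ca = .domain_hmm_ca(entry, d, pl),
          pep_ca = .peptide_ca(entry$chains[[pid]])
        ), class = "xc_peptide_interface")
      }
    }
  }
  # 75% assignment rule, atomic contacts counted per partner chain
  if (length(out)) {
    by_pep <- split(seq_along(out),
                    vapply(out, `[[`, character(1L), "peptide_asym"))
    keep <- logical(length(out))
    for (ix in by_pep) {
      n5 <- vapply(out[ix], function(p) p$contacts$n_atom5, numeric(1L))
      chains <- vapply(out[ix], `[[`, character(1L), "domain_asym")
      per_chain <- tapply(n5, chains, sum)
      tot <- sum(n5)
      winner <- names(per_chain)[per_chain >= config$peptide_assign_frac *
                                   tot]
      if (tot > 0 && length(winner) == 1L) {
        keep[ix] <- chains == winner
      } else {
        keep[ix] <- TRUE
      }
    }
    out <- out[keep]
  }
  for (i in seq_along(out)) {
    out[[i]]$id <- sprintf("%s_p%03d", entry$entry_id, i)
  }
  out
}

#' Superpose two domains on their common HMM positions
#'
#' Least-squares rigid superposition of C-alpha coordinates over the
#' HMM match positions the two domains share.
#'
#' @param ca_a,ca_b C-alpha coordinate matrices with HMM positions as
#'   rownames (e.g. the `dom_hmm_ca` field of a peptide interface).
#' @return list: `R`, `t` (transform moving b onto a), `rmsd`,
#'   `positions` (common HMM positions used), `residuals`.
#' @export
superpose_by_hmm <- function(ca_a, ca_b) {
  common <- intersect(rownames(ca_a), rownames(ca_b))
  if (length(common) < 3L) {
    stop("fewer than 3 common HMM positions with coordinates (",
         length(common), ")")
  }
  common <- common[order(as.integer(common))]
  fit <- kabsch(ca_b[common, , drop = FALSE],
                ca_a[common, , drop = FALSE])
  list(R = fit$R, t = fit$t, rmsd = fit$rmsd, positions = common,
       residuals = fit$residuals)
}

#' Minimum peptide RMSD between two domain-peptide interfaces
#'
#' Superposes the two domains on their common HMM positions, brings
#' interface b's peptide into interface a's frame, and scans all
#' ungapped sequence alignments (offsets) with at least
#' `min_pep_overlap` aligned residues, computing the peptide C-alpha
#' RMSD of each; the peptides themselves are not refit, so the score
#' reflects where on the domain the peptide sits. Returns the minimum
#' and the offset achieving it.
#'
#' @param pi_a,pi_b `xc_peptide_interface` objects of one family.
#' @param config configuration.
#' @return list: `rmsd` (A), `offset` (alignment shift of peptide b
#'   relative to peptide a), `n_aligned`.
#' @export
peptide_rmsd <- function(pi_a, pi_b, config = pipeline_config()) {
  sup <- superpose_by_hmm(pi_a$dom_hmm_ca, pi_b$dom_hmm_ca)
  pa <- pi_a$pep_ca
  pb <- apply_transform(pi_b$pep_ca, sup$R, sup$t)
  m <- nrow(pa); n <- nrow(pb)
  minov <- config$min_pep_overlap
  if (min(m, n) < minov) {
    stop("peptides too short for the minimum alignment overlap")
  }
  best <- Inf; best_off <- NA_integer_; best_n <- 0L
  for (off in seq.int(-(n - minov), m - minov)) {
    i_b <- seq.int(max(1L, 1L - off), min(n, m - off))
    i_a <- i_b + off
    if (length(i_b) < minov) next
    d2 <- rowSums((pa[i_a, , drop = FALSE] - pb[i_b, , drop = FALSE])^2)
    r <- sqrt(mean(d2))
    if (r < best) {
      best <- r; best_off <- off; best_n <- length(i_b)
    }
  }
  list(rmsd = best, offset = best_off, n_aligned = best_n)
}

#' Cluster domain-peptide interfaces of one family by binding mode
#'
#' Greedy agglomeration: each interface starts as its own cluster; at
#' each step the two clusters sharing the largest (average) number of
#' common interacting HMM sites are merged, as long as that shared-site
#' count is at least `pep_min_nhmm` and the (average) peptide RMSD
#' between them is at most `pep_max_rmsd`. Cross-cluster averages
#' mirror the average-linkage interface clustering. Deterministic
#' tie-breaking by member id.
#'
#' @param pis list of `xc_peptide_interface` (one Pfam family).
#' @param config configuration.
#' @return list of `xc_peptide_cluster` objects.
#' @export
cluster_peptide_interfaces <- function(pis,
                                       config = pipeline_config()) {
  if (!length(pis)) return(list())
  fams <- unique(vapply(pis, `[[`, character(1L), "pfam_id"))
  out <- list()
  for (fam in sort(fams)) {
    sub <- pis[vapply(pis, `[[`, character(1L), "pfam_id") == fam]
    n <- length(sub)
    ids <- vapply(sub, `[[`, character(1L), "id")
    Nh <- matrix(0, n, n); Rm <- matrix(Inf, n, n)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        Nh[i, j] <- Nh[j, i] <-
          length(intersect(sub[[i]]$hmm_sites, sub[[j]]$hmm_sites))
        r <- tryCatch(peptide_rmsd(sub[[i]], sub[[j]], config)$rmsd,
                      error = function(e) Inf)
        Rm[i, j] <- Rm[j, i] <- r
      }
    }
    clusters <- as.list(seq_len(n))
    repeat {
      k <- length(clusters)
      if (k < 2L) break
      best <- -Inf; bp <- NULL; bt <- NULL
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        nh <- mean(Nh[clusters[[i]], clusters[[j]]])
        rm_ <- mean(Rm[clusters[[i]], clusters[[j]]])
        if (nh < config$pep_min_nhmm || rm_ > config$pep_max_rmsd) next
        tie <- paste(sort(ids[c(clusters[[i]], clusters[[j]])]),
                     collapse = "\r")
        if (nh > best + 1e-12 ||
            (abs(nh - best) <= 1e-12 && !is.null(bt) && tie < bt)) {
          best <- nh; bp <- c(i, j); bt <- tie
        }
      }
      if (is.null(bp)) break
      clusters[[bp[1L]]] <- c(clusters[[bp[1L]]], clusters[[bp[2L]]])
      clusters[[bp[2L]]] <- NULL
    }
    clusters <- lapply(clusters, sort)
    clusters <- clusters[order(-lengths(clusters),
                               vapply(clusters, function(ix) ids[ix[1L]],
                                      character(1L)))]
    for (ci in seq_along(clusters)) {
      ix <- clusters[[ci]]
      shared <- Reduce(intersect, lapply(sub[ix], `[[`, "hmm_sites"))
      rmax <- if (length(ix) > 1L) {
        max(Rm[ix, ix][upper.tri(Rm[ix, ix])])
      } else 0
      out[[length(out) + 1L]] <- structure(list(
        cluster_id = sprintf("pep_%s_cl%02d", fam, ci), pfam = fam,
        member_ids = ids[ix], members = sub[ix],
        n_peptide_sequences = length(unique(vapply(
          sub[ix], `[[`, character(1L), "peptide_sequence"))),
        n_entries = length(unique(vapply(
          sub[ix], `[[`, character(1L), "entry_id"))),
        shared_hmm_sites = shared, max_rmsd = rmax
      ), class = "xc_peptide_cluster")
    }
  }
  out
}

#' Peptide-cluster table
#' @param pclusters list of `xc_peptide_cluster`.
#' @return data.frame, one row per member.
#' @export
peptide_cluster_table <- function(pclusters) {
  rows <- list()
  for (cl in pclusters) {
    for (m in cl$members) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = cl$cluster_id, pfam = cl$pfam,
        interface_id = m$id, entry_id = m$entry_id,
        domain_id = m$domain$domain_id, peptide_chain = m$peptide_asym,
        peptide_sequence = m$peptide_sequence,
        n_hmm_sites = length(m$hmm_sites),
        cluster_n_hmm = length(cl$shared_hmm_sites),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(cluster_id = character(0)))
  do.call(rbind, rows)
}
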