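# Interface similarity (Q score on common-position-mapped contact pairs)
# and hierarchical average-linkage clustering with the Q_avg >= 0.30
# stopping rule; cluster annotation with crystal-form / entry / protein
# counts.

#' Residue correspondence between two interfaces
#'
#' Decides how the residues of two interfaces are put into a common
#' coordinate system: via profile-HMM match positions when both sides
#' are sufficiently covered by the family model (the HMM must cover at
#' least `hmm_cov_min` of the shorter side), or by sequence position
#' when the sequences are identical. Incomparable interfaces get kind
#' `"none"`; such pairs have undefined Q and are never co-clustered.
#'
#' @param iface_a,iface_b `xc_interface` objects at the same level.
#' @param config configuration.
#' @return list with `kind` (`"hmm"`, `"identity"`, `"none"`) and
#'   `covered_fraction`.
#' @export
build_correspondence <- function(iface_a, iface_b,
                                 config = pipeline_config()) {
  if (iface_a$level != iface_b$level) {
    stop("interfaces are at different levels")
  }
  if (iface_a$family_key != iface_b$family_key) {
    stop("incompatible family keys: ", iface_a$family_key, " vs ",
         iface_b$family_key)
  }
  shorter <- min(iface_a$side_a$n_res, iface_a$side_b$n_res,
                 iface_b$side_a$n_res, iface_b$side_b$n_res)
  fracs <- c(iface_a$side_a$n_mapped, iface_a$side_b$n_mapped,
             iface_b$side_a$n_mapped, iface_b$side_b$n_mapped) /
    shorter
  covered <- min(pmin(fracs, 1))
  has_hmm <- length(iface_a$hmm_pairs) > 0L && length(iface_b$hmm_pairs) > 0L
  if (has_hmm && covered >= config$hmm_cov_min) {
    return(list(kind = "hmm", covered_fraction = covered))
  }
  seqs_a <- sort(c(iface_a$side_a$sequence, iface_a$side_b$sequence))
  seqs_b <- sort(c(iface_b$side_a$sequence, iface_b$side_b$sequence))
  if (identical(seqs_a, seqs_b)) {
    return(list(kind = "identity", covered_fraction = 1))
  }
  list(kind = "none", covered_fraction = covered)
}

#' Q similarity score between two interfaces
#'
#' With unit weights, Q is the Jaccard index of the two mapped
#' contact-pair sets: the number of common contacting residue pairs
#' divided by the number of unique pairs in the union. Q = 1 means the
#' two interfaces interact in an identical way; Q = 0 means no common
#' contacts. For pairs whose two sides carry the same family (homodimer
#' interfaces have no canonical side labels) both side orderings are
#' evaluated and the maximum taken, so Q never depends on arbitrary
#' chain labels.
#'
#' @param iface_a,iface_b interfaces with compatible family keys.
#' @param corr correspondence from [build_correspondence()]; built if
#'   `NULL`.
#' @param weights optional named numeric vector of per-pair weights
#'   (names are mapped pair labels); default unit weights.
#' @param config configuration.
#' @return Q in `[0, 1]`, or `NA` if the pair has no valid
#'   correspondence.
#' @export
q_score <- function(iface_a, iface_b, corr = NULL,
                    weights = NULL, config = pipeline_config()) {
  if (is.null(corr)) corr <- build_correspondence(iface_a, iface_b, config)
  if (corr$kind == "none") return(NA_real_)
  if (corr$kind == "hmm") {
    a_f <- iface_a$hmm_pairs; a_r <- iface_a$hmm_pairs_rev
    b_f <- iface_b$hmm_pairs; b_r <- iface_b$hmm_pairs_rev
  } else {
    a_f <- iface_a$seq_pairs; a_r <- iface_a$seq_pairs_rev
    b_f <- iface_b$seq_pairs; b_r <- iface_b$seq_pairs_rev
  }
  if (length(union(a_f, b_f)) == 0L) {
    stop("empty contact-pair union; interfaces carry no mapped contacts")
  }
  wjac <- function(x, y) {
    if (is.null(weights)) return(.jaccard(x, y))
    u <- union(x, y)
    w <- weights[u]; w[is.na(w)] <- 1
    sum(w[u %in% intersect(x, y)]) / sum(w)
  }
  same_family <- iface_a$side_a$family == iface_a$side_b$family
  if (same_family) {
    max(wjac(a_f, b_f), wjac(a_f, b_r))
  } else if (iface_a$side_a$family == iface_b$side_a$family) {
    wjac(a_f, b_f)
  } else {
    wjac(a_f, b_r)
  }
}

#' Pairwise Q matrix for a set of comparable interfaces
#'
#' @param interfaces list of interfaces sharing one family key.
#' @param config configuration.
#' @return symmetric numeric matrix (NA where no correspondence
#'   exists), unit diagonal.
#' @export
q_matrix <- function(interfaces, config = pipeline_config()) {
  n <- length(interfaces)
  Q <- diag(1, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        Q[i, j] <- Q[j, i] <- q_score(interfaces[[i]], interfaces[[j]],
                                      config = config)
      }
    }
  }
  rownames(Q) <- colnames(Q) <-
    vapply(interfaces, `[[`, character(1L), "interface_id")
  Q
}

#' Hierarchical average-linkage clustering with a similarity threshold
#'
#' Each item starts in its own cluster; at each step the two clusters
#' with the highest average pairwise similarity are merged, as long as
#' that average is at least `threshold`; the algorithm stops when no
#' pair qualifies. Undefined similarities (NA) contribute 0 to the
#' averages, so incomparable items never drive a merge. Ties are broken
#' towards the pair whose smallest member label sorts first.
#'
#' @param sim symmetric similarity matrix with item labels as dimnames.
#' @param threshold minimum average similarity for a merge.
#' @return list of character vectors (member labels), ordered by
#'   decreasing size then first member.
#' @export
average_linkage_cluster <- function(sim, threshold) {
  n <- nrow(sim)
  if (!n) return(list())
  labs <- rownames(sim) %||% as.character(seq_len(n))
  S <- as.matrix(sim)
  S[is.na(S)] <- 0
  diag(S) <- 0
  # cluster-pair contact sums are maintained incrementally so each
  # iteration is a vectorized argmax over the average matrix
  Tm <- S
  sizes <- rep(1L, n)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  repeat {
    idx <- which(active)
    if (length(idx) < 2L) break
    A <- Tm[idx, idx, drop = FALSE] / outer(sizes[idx], sizes[idx])
    diag(A) <- -Inf
    best <- max(A)
    if (best < threshold) break
    cand <- which(A >= best - 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    if (nrow(cand) > 1L) {
      keys <- apply(cand, 1L, function(rc) {
        paste(sort(labs[c(members[[idx[rc[1L]]]],
                          members[[idx[rc[2L]]]])]), collapse = "\r")
      })
      cand <- cand[order(keys), , drop = FALSE]
    }
    i <- idx[cand[1L, 1L]]; j <- idx[cand[1L, 2L]]
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    Tm[i, ] <- Tm[i, ] + Tm[j, ]
    Tm[, i] <- Tm[, i] + Tm[, j]
    active[j] <- FALSE
  }
  out <- lapply(members[active], function(ix) labs[sort(ix)])
  out[order(-lengths(out),
            vapply(out, function(x) x[1L], character(1L)))]
}

#' Cluster a set of interfaces across entries and crystal forms
#'
#' Groups interfaces by level and family key, computes pairwise Q, runs
#' the average-linkage algorithm at the `q_cluster` threshold, and
#' returns annotated clusters. Interfaces flagged below the buried-area
#' minimum are excluded before clustering.
#'
#' @param interfaces list of `xc_interface` from one or many entries.
#' @param cf_assign named character vector mapping entry_id to crystal
#'   form id (from [group_crystal_forms()]), or `NULL` to skip
#'   form counts.
#' @param config configuration.
#' @return list of `xc_cluster` objects, ordered by decreasing
#'   `n_crystal_forms` then `n_entries`.
#' @export
cluster_interfaces <- function(interfaces, cf_assign = NULL,
                               config = pipeline_config()) {
  keep <- vapply(interfaces, function(x) !isTRUE(x$below_bsa_min),
                 logical(1L))
  interfaces <- interfaces[keep]
  if (!length(interfaces)) return(list())
  grp <- vapply(interfaces, function(x) paste(x$level, x$family_key),
                character(1L))
  out <- list()
  for (g in sort(unique(grp))) {
    sub <- interfaces[grp == g]
    Q <- q_matrix(sub, config)
    memberships <- average_linkage_cluster(Q, config$q_cluster)
    ids <- vapply(sub, `[[`, character(1L), "interface_id")
    for (m in memberships) {
      members <- sub[match(m, ids)]
      cl <- structure(list(
        cluster_id = NA_character_, level = members[[1L]]$level,
        family_key = members[[1L]]$family_key,
        member_ids = m, members = members,
        q_avg_internal = if (length(m) == 1L) 1 else {
          mean(Q[m, m][upper.tri(Q[m, m])], na.rm = TRUE)
        }), class = "xc_cluster")
      out[[length(out) + 1L]] <- annotate_cluster(cl, cf_assign, config)
    }
  }
  ord <- order(-vapply(out, `[[`, numeric(1L), "n_crystal_forms"),
               -vapply(out, `[[`, numeric(1L), "n_entries"),
               vapply(out, `[[`, character(1L), "family_key"))
  out <- out[ord]
  for (i in seq_along(out)) {
    out[[i]]$cluster_id <- sprintf("%s_%s_cl%02d", out[[i]]$level,
                                   gsub("[^A-Za-z0-9]+", "-",
                                        out[[i]]$family_key), i)
  }
  out
}

#' Annotate an interface cluster
#'
#' Fills crystal-form / entry / protein counts, mean buried area,
#' minimum pairwise sequence identity across member proteins (global
#' alignment, identity = matches / alignment columns), and the fractions
#' of members present in author and PISA assemblies.
#'
#' @param cluster an `xc_cluster`.
#' @param cf_assign named entry_id -> crystal form id vector, or `NULL`.
#' @param config configuration.
#' @return the annotated cluster.
#' @export
annotate_cluster <- function(cluster, cf_assign = NULL,
                             config = pipeline_config()) {
  ms <- cluster$members
  entries <- vapply(ms, `[[`, character(1L), "entry_id")
  unps <- unlist(lapply(ms, function(x) {
    c(x$side_a$uniprot, x$side_b$uniprot)
  }))
  unps <- unique(unps[!is.na(unps)])
  seqs <- unique(unlist(lapply(ms, function(x) {
    c(x$side_a$sequence, x$side_b$sequence)
  })))
  cluster$n_entries <- length(unique(entries))
  cluster$n_crystal_forms <- if (is.null(cf_assign)) NA_integer_ else {
    if (any(!entries %in% names(cf_assign))) {
      stop("cluster member entries lack a crystal-form assignment: ",
           paste(setdiff(entries, names(cf_assign)), collapse = ", "))
    }
    length(unique(cf_assign[entries]))
  }
  cluster$n_uniprots <- length(unps)
  cluster$mean_bsa <- mean(vapply(ms, `[[`, numeric(1L), "bsa"))
  cluster$min_seq_identity <- if (length(seqs) < 2L) 1 else {
    min(utils::combn(seqs, 2L, function(p) {
      .global_identity(p[1L], p[2L])
    }))
  }
  auth <- vapply(ms, function(x) x$in_author_assembly, logical(1L))
  pisa <- vapply(ms, function(x) x$in_pisa_assembly, logical(1L))
  cluster$author_assembly_fraction <- if (all(is.na(auth))) NA_real_ else
    mean(auth, na.rm = TRUE)
  cluster$pisa_assembly_fraction <- if (all(is.na(pisa))) NA_real_ else
    mean(pisa, na.rm = TRUE)
  cluster
}

# Global (Needleman-Wunsch) alignment identity: matches divided by
# alignment columns. Linear gap penalty; ties resolved toward matches.
.global_identity <- function(s1, s2, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(s1, "")[[1L]]; b <- strsplit(s2, "")[[1L]]
  n <- length(a); m <- length(b)
  Fm <- matrix(0, n + 1L, m + 1L)
  Fm[, 1L] <- gap * (0:n); Fm[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      Fm[i + 1L, j + 1L] <- max(Fm[i, j] + sub[j],
                                Fm[i, j + 1L] + gap,
                                Fm[i + 1L, j] + gap)
    }
  }
  # traceback
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0L || j > 0L) {
    cols <- cols + 1L
    if (i > 0L && j > 0L &&
        abs(Fm[i + 1L, j + 1L] -
              (Fm[i, j] + ifelse(a[i] == b[j], match, mismatch))) < 1e-9) {
      if (a[i] == b[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L &&
               abs(Fm[i + 1L, j + 1L] - (Fm[i, j + 1L] + gap)) < 1e-9) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  matches / cols
}

#' Cluster membership table
#'
#' One row per cluster member with the annotations the evidence tables
#' report: cluster id, interface, entry, crystal form, protein, family
#' key, buried area and assembly flags.
#'
#' @param clusters list of `xc_cluster`.
#' @param cf_assign named entry -> crystal form vector, or `NULL`.
#' @return data.frame.
#' @export
cluster_table <- function(clusters, cf_assign = NULL) {
  rows <- list()
  for (cl in clusters) {
    for (m in cl$members) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = cl$cluster_id, level = cl$level,
        family_key = cl$family_key, interface_id = m$interface_id,
        entry_id = m$entry_id,
        cf_id = if (is.null(cf_assign)) NA_character_ else
          unname(cf_assign[m$entry_id]),
        uniprot_a = m$side_a$uniprot, uniprot_b = m$side_b$uniprot,
        species = m$side_a$species, bsa = m$bsa,
        intra_chain = m$intra_chain,
        in_author_assembly = m$in_author_assembly,
        in_pisa_assembly = m$in_pisa_assembly,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(cluster_id = character(0)))
  do.call(rbind, rows)
}

#' Cluster summary table
#' @param clusters list of `xc_cluster`.
#' @return data.frame, one row per cluster.
#' @export
cluster_summary <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(cluster_id = character(0)))
  }
  do.call(rbind, lapply(clusters, function(cl) data.frame(
    cluster_id = cl$cluster_id, level = cl$level,
    family_key = cl$family_key, n_members = length(cl$member_ids),
    n_crystal_forms = cl$n_crystal_forms, n_entries = cl$n_entries,
    n_uniprots = cl$n_uniprots, mean_bsa = cl$mean_bsa,
    min_seq_identity = cl$min_seq_identity,
    q_avg_internal = cl$q_avg_internal,
    author_assembly_fraction = cl$author_assembly_fraction,
    pisa_assembly_fraction = cl$pisa_assembly_fraction,
    stringsAsFactors = FALSE)))
}
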