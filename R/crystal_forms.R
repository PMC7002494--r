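# Grouping entries into crystal forms by the four equivalence rules and
# merging forms that share two thirds of highly similar interfaces.

.asu_stoichiometry <- function(entry) {
  prot <- Filter(function(ch) ch$polymer_type == "polypeptide",
                 entry$chains)
  if (!length(prot)) return("")
  counts <- table(vapply(prot, `[[`, character(1L), "entity_id"))
  paste(sort(as.integer(counts), decreasing = TRUE), collapse = ",")
}

#' Are two entries in the same crystal form?
#'
#' True iff (1) the entries have the same entry-level family
#' architecture signature, (2) the same space group, (3) the same
#' asymmetric-unit stoichiometry of protein chains, and (4) all six
#' cell parameters agree within the relative tolerance `cell_tol`
#' (evaluated per parameter as `|x1 - x2| / max(x1, x2)`).
#'
#' @param e1,e2 `xc_entry` objects.
#' @param arch1,arch2 entry architecture signatures from
#'   [entry_arch_key()].
#' @param config configuration.
#' @return logical.
#' @export
same_crystal_form <- function(e1, e2, arch1, arch2,
                              config = pipeline_config()) {
  if (!identical(arch1, arch2)) return(FALSE)
  if (!identical(e1$space_group, e2$space_group)) return(FALSE)
  if (!identical(.asu_stoichiometry(e1), .asu_stoichiometry(e2))) {
    return(FALSE)
  }
  c1 <- unlist(e1$cell); c2 <- unlist(e2$cell)
  if (is.null(c1) || is.null(c2)) return(FALSE)
  all(abs(c1 - c2) / pmax(c1, c2) <= config$cell_tol)
}

#' Group entries into crystal forms
#'
#' Crystal forms are the connected components of the pairwise
#' same-crystal-form relation (the 1 percent cell tolerance is not
#' transitive, so chained near-tolerance cells land in one form).
#' Form ids are deterministic: forms are ordered by their smallest
#' member entry id.
#'
#' @param entries list of `xc_entry`.
#' @param arch_keys named character vector of entry architecture
#'   signatures (names = entry ids).
#' @param config configuration.
#' @return list of `xc_crystal_form` objects.
#' @export
group_crystal_forms <- function(entries, arch_keys,
                                config = pipeline_config()) {
  if (!length(entries)) stop("at least one entry is required")
  ids <- vapply(entries, `[[`, character(1L), "entry_id")
  names(entries) <- ids
  n <- length(entries)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    adj[i, i] <- TRUE
    if (i < n) for (j in (i + 1L):n) {
      adj[i, j] <- adj[j, i] <- same_crystal_form(
        entries[[i]], entries[[j]], arch_keys[[ids[i]]],
        arch_keys[[ids[j]]], config)
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  forms <- lapply(unname(split(ids, comp)), function(members) {
    members <- sort(unname(members))
    rep_entry <- entries[[members[1L]]]
    structure(list(
      cf_id = NA_character_, member_entries = members,
      arch_key = arch_keys[[members[1L]]],
      space_group = rep_entry$space_group,
      representative_cell = rep_entry$cell,
      stoichiometry = .asu_stoichiometry(rep_entry),
      merged_from = character(0)), class = "xc_crystal_form")
  })
  forms <- forms[order(vapply(forms, function(f) f$member_entries[1L],
                              character(1L)))]
  for (i in seq_along(forms)) {
    forms[[i]]$cf_id <- sprintf("CF%03d", i)
  }
  forms
}

#' Merge crystal forms that share most of their interfaces
#'
#' Two forms with the same architecture signature are merged when, after
#' greedily matching their representative entries' unique interfaces by
#' best Q, at least `cf_merge_fraction` (two thirds) of the smaller
#' interface census is matched at Q >= `q_high`. This collapses e.g. a
#' monomer-asymmetric-unit form and the corresponding dimer-asymmetric-
#' unit form of the same crystal. Merging is repeated to a fixpoint.
#'
#' @param forms list from [group_crystal_forms()].
#' @param interfaces_by_entry named list: entry_id -> list of chain-level
#'   `xc_interface` for that entry.
#' @param config configuration.
#' @return list of `xc_crystal_form` (ids reassigned, `merged_from`
#'   records absorbed form ids).
#' @export
merge_equivalent_forms <- function(forms, interfaces_by_entry,
                                   config = pipeline_config()) {
  repeat {
    merged <- FALSE
    n <- length(forms)
    if (n < 2L) break
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (!identical(forms[[i]]$arch_key, forms[[j]]$arch_key)) next
        if (.forms_equivalent(forms[[i]], forms[[j]],
                              interfaces_by_entry, config)) {
          keep <- forms[[i]]
          keep$member_entries <- sort(c(forms[[i]]$member_entries,
                                        forms[[j]]$member_entries))
          keep$merged_from <- c(forms[[i]]$merged_from,
                                forms[[j]]$cf_id,
                                forms[[j]]$merged_from)
          forms[[i]] <- keep
          forms[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  forms[order(vapply(forms, function(f) f$member_entries[1L],
                     character(1L)))]
}

.forms_equivalent <- function(f1, f2, interfaces_by_entry, config) {
  i1 <- interfaces_by_entry[[f1$member_entries[1L]]]
  i2 <- interfaces_by_entry[[f2$member_entries[1L]]]
  if (is.null(i1) || is.null(i2) || !length(i1) || !length(i2)) {
    return(FALSE)
  }
  Q <- matrix(0, length(i1), length(i2))
  for (a in seq_along(i1)) {
    for (b in seq_along(i2)) {
      if (i1[[a]]$family_key != i2[[b]]$family_key) next
      q <- q_score(i1[[a]], i2[[b]], config = config)
      Q[a, b] <- if (is.na(q)) 0 else q
    }
  }
  # greedy best-Q matching
  matched <- 0L
  while (TRUE) {
    m <- which(Q == max(Q), arr.ind = TRUE)
    if (max(Q) < config$q_high) break
    m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE][1L, ]
    matched <- matched + 1L
    Q[m[1L], ] <- -1; Q[, m[2L]] <- -1
  }
  matched >= config$cf_merge_fraction * min(length(i1), length(i2))
}

#' Crystal-form assignment vector
#' @param forms list of `xc_crystal_form`.
#' @return named character vector: entry_id -> cf_id.
#' @export
crystal_form_assignment <- function(forms) {
  out <- character(0)
  for (f in forms) {
    out[f$member_entries] <- f$cf_id
  }
  out
}

#' Crystal-form table
#' @param forms list of `xc_crystal_form`.
#' @return data.frame, one row per form.
#' @export
crystal_form_table <- function(forms) {
  do.call(rbind, lapply(forms, function(f) data.frame(
    cf_id = f$cf_id, members = paste(f$member_entries, collapse = ","),
    n_entries = length(f$member_entries), space_group = f$space_group,
    cell = paste(sprintf("%.2f", unlist(f$representative_cell)),
                 collapse = ","),
    arch_key = f$arch_key, stoichiometry = f$stoichiometry,
    merged_from = paste(f$merged_from, collapse = ","),
    stringsAsFactors = FALSE)))
}
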