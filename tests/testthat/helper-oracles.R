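# Independent oracles and small fixture builders shared across tests.

# Plain double-loop contact oracle: every residue pair with any
# heavy-atom distance <= atom_cutoff or CB(-surrogate) distance <=
# cbeta_cutoff, counted independently of the package's vectorized path.
oracle_contacts <- function(unit_a, unit_b, cfg = pipeline_config()) {
  res_a <- sort(unique(unit_a$seq_pos))
  res_b <- sort(unique(unit_b$seq_pos))
  cb_of <- function(u, sp) {
    hit <- which(u$cb_seq == sp)
    if (length(hit)) u$cb_xyz[hit[1L], ] else NULL
  }
  pairs <- list(); n_cb <- 0L; n_a5 <- 0L
  for (ra in res_a) {
    for (rb in res_b) {
      ia <- which(unit_a$seq_pos == ra)
      ib <- which(unit_b$seq_pos == rb)
      dmin <- Inf
      for (i in ia) for (j in ib) {
        dmin <- min(dmin, sqrt(sum((unit_a$xyz[i, ] - unit_b$xyz[j, ])^2)))
      }
      ca <- cb_of(unit_a, ra); cb <- cb_of(unit_b, rb)
      dcb <- if (!is.null(ca) && !is.null(cb)) {
        sqrt(sum((ca - cb)^2))
      } else NA_real_
      if (dmin <= cfg$atom_cutoff || (!is.na(dcb) && dcb <= cfg$cbeta_cutoff)) {
        pairs[[length(pairs) + 1L]] <- c(ra, rb)
        if (!is.na(dcb) && dcb <= cfg$cbeta_cutoff) n_cb <- n_cb + 1L
        if (dmin <= cfg$atom_cutoff) n_a5 <- n_a5 + 1L
      }
    }
  }
  list(pairs = pairs, n_cbeta12 = n_cb, n_atom5 = n_a5)
}

# Quaternion-method rigid superposition (Horn 1987), an algorithm
# independent of the SVD/Kabsch route.
oracle_quaternion_fit <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1L]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  t <- cq - as.vector(R %*% cp)
  moved <- sweep(P %*% t(R), 2, t, "+")
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((moved - Q)^2))))
}

# Reference average-linkage partition: hclust on 1 - Q cut at the
# threshold height (undefined similarities -> 0).
oracle_average_linkage <- function(S, threshold) {
  D <- 1 - S
  D[is.na(D)] <- 1
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  stats::cutree(hc, h = 1 - threshold)
}

# A random blob "chain" for contact-oracle fuzzing: n_res residues of
# 1-4 atoms scattered in a box, with CA present in each residue.
random_blob_entry <- function(seed, n_res_a = 12, n_res_b = 12,
                              spread = 18) {
  set.seed(seed)
  mk_atoms <- function(n_res, centre) {
    rows <- list()
    for (r in seq_len(n_res)) {
      base <- centre + stats::runif(3, -spread / 2, spread / 2)
      n_at <- sample(1:4, 1)
      names_at <- c("CA", "CB", "N", "O")[seq_len(n_at)]
      for (k in seq_len(n_at)) {
        p <- base + stats::rnorm(3, 0, 1.2)
        rows[[length(rows) + 1L]] <- data.frame(
          seq_pos = r, resname = "ALA", atom = names_at[k],
          element = substr(names_at[k], 1, 1), x = p[1], y = p[2],
          z = p[3], occupancy = 1, altloc = "",
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  a <- mk_atoms(n_res_a, c(0, 0, 0))
  b <- mk_atoms(n_res_b, stats::runif(3, 2, 14))
  entry <- crystal_entry(
    sprintf("BLOB%d", seed),
    list(polymer_chain("A", strrep("A", n_res_a), a, entity_id = "1"),
         polymer_chain("B", strrep("A", n_res_b), b, entity_id = "2")),
    cell = unit_cell(80, 80, 80), space_group = "P 1",
    sym_ops = space_group_ops("P 1"))
  entry
}

# Minimal hand-constructed interface carrying given mapped contact
# pairs, for Q-score arithmetic tests.
fake_iface <- function(id, pairs, fam_a = "FAMX", fam_b = fam_a,
                       entry_id = "E1", n_res = 50, n_mapped = 50,
                       sequence_a = strrep("A", n_res),
                       sequence_b = sequence_a,
                       uniprot = "P00001", bsa = 500) {
  la <- vapply(pairs, `[[`, numeric(1L), 1L)
  lb <- vapply(pairs, `[[`, numeric(1L), 2L)
  fwd <- sort(unique(paste(la, lb, sep = "~")))
  rev <- sort(unique(paste(lb, la, sep = "~")))
  structure(list(
    interface_id = id, entry_id = entry_id, level = "domain",
    side_a = list(asym_id = "A", entity_id = "1", domain_id = "dA",
                  family = fam_a, op_index = 1L, shift = c(0L, 0L, 0L),
                  n_mapped = n_mapped, n_res = n_res,
                  sequence = sequence_a, uniprot = uniprot,
                  species = "synthetic construct"),
    side_b = list(asym_id = "B", entity_id = "1", domain_id = "dB",
                  family = fam_b, op_index = 1L, shift = c(0L, 0L, 0L),
                  n_mapped = n_mapped, n_res = n_res,
                  sequence = sequence_b, uniprot = uniprot,
                  species = "synthetic construct"),
    contacts = structure(list(pairs = data.frame(), n_cbeta12 = 12L,
                              n_atom5 = 6L), class = "xc_contacts"),
    intra_chain = FALSE,
    hmm_pairs = fwd, hmm_pairs_rev = rev,
    seq_pairs = paste0("s", fwd), seq_pairs_rev = paste0("s", rev),
    family_key = paste(sort(c(fam_a, fam_b)), collapse = ":"),
    bsa = bsa, below_bsa_min = FALSE,
    in_author_assembly = NA, in_pisa_assembly = NA
  ), class = "xc_interface")
}

# Minimal peptide interface carrying given HMM sites and peptide CA
# coordinates in a shared domain frame (identity dom_hmm_ca grid).
fake_pep_iface <- function(id, sites, pep_ca, entry_id = "E1",
                           pep_seq = strrep("A", nrow(pep_ca))) {
  grid <- as.matrix(expand.grid(x = c(0, 5, 10), y = c(0, 5, 10),
                                z = c(0, 5)))[1:12, ]
  rownames(grid) <- as.character(1:12)
  dom <- structure(list(domain_id = paste0("dom_", id),
                        pfam_id = "FAMP"), class = "xc_domain")
  structure(list(
    id = id, entry_id = entry_id, domain = dom, domain_asym = "A",
    peptide_asym = "P", pfam_id = "FAMP",
    contacts = structure(list(pairs = data.frame(), n_cbeta12 = 12L,
                              n_atom5 = 6L), class = "xc_contacts"),
    hmm_sites = sort(as.integer(sites)), peptide_sequence = pep_seq,
    dom_hmm_ca = grid, pep_ca = as.matrix(pep_ca)
  ), class = "xc_peptide_interface")
}
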