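test_that("Q score reproduces its defining boundary values and set arithmetic", {
  base <- fake_iface("i1", list(c(1, 5), c(2, 6), c(3, 7)))
  copy <- fake_iface("i2", list(c(1, 5), c(2, 6), c(3, 7)))
  expect_equal(q_score(base, copy), 1)
  expect_equal(q_score(base, base), 1)
  disjoint <- fake_iface("i3", list(c(10, 20), c(11, 21), c(12, 22)))
  expect_equal(q_score(base, disjoint), 0)
  # |{(1,5)}| / |{(1,5),(2,6),(3,7)}| with Ca={(1,5),(2,6)},
  # Cb={(1,5),(3,7)}
  a <- fake_iface("i4", list(c(1, 5), c(2, 6)))
  b <- fake_iface("i5", list(c(1, 5), c(3, 7)))
  expect_equal(q_score(a, b), 1 / 3)
  expect_true(q_score(a, b) >= 0 && q_score(a, b) <= 1)
})

test_that("Q is symmetric and invariant to homodimer side labelling", {
  set.seed(31)
  for (r in 1:20) {
    pa <- lapply(1:8, function(i) sample(1:15, 2))
    pb <- lapply(1:8, function(i) sample(1:15, 2))
    ia <- fake_iface("a", pa); ib <- fake_iface("b", pb)
    expect_equal(q_score(ia, ib), q_score(ib, ia))
  }
  # swapping the sides of one interface must not change Q for a
  # same-family pair
  fwd <- fake_iface("f", list(c(1, 9), c(2, 8), c(3, 7)))
  swp <- fake_iface("s", list(c(9, 1), c(8, 2), c(7, 3)))
  expect_equal(q_score(fwd, swp), 1)
})

test_that("correspondence rules gate which pairs are comparable", {
  # homologs with full model coverage compare via HMM positions
  a <- fake_iface("a", list(c(1, 5)), sequence_a = strrep("A", 50))
  b <- fake_iface("b", list(c(1, 5)), sequence_a = strrep("C", 50),
                  sequence_b = strrep("C", 50))
  expect_identical(build_correspondence(a, b)$kind, "hmm")
  # low coverage + different sequences: no correspondence, Q undefined
  low_a <- fake_iface("la", list(c(1, 5)), n_mapped = 30,
                      sequence_a = strrep("A", 50))
  low_b <- fake_iface("lb", list(c(1, 5)), n_mapped = 30,
                      sequence_a = strrep("C", 50),
                      sequence_b = strrep("C", 50))
  corr <- build_correspondence(low_a, low_b)
  expect_identical(corr$kind, "none")
  expect_lt(corr$covered_fraction, pipeline_config()$hmm_cov_min)
  expect_true(is.na(q_score(low_a, low_b)))
  # identical sequences fall back to the identity correspondence
  id_a <- fake_iface("ia", list(c(1, 5)), n_mapped = 30)
  id_b <- fake_iface("ib", list(c(1, 5)), n_mapped = 30)
  expect_identical(build_correspondence(id_a, id_b)$kind, "identity")
  expect_equal(q_score(id_a, id_b), 1)
  # incomparable family keys are an error
  other <- fake_iface("o", list(c(1, 5)), fam_a = "OTHER")
  expect_error(q_score(a, other), "incompatible family keys")
})

test_that("average linkage merges while Q_avg stays above threshold", {
  S <- matrix(c(1, 0.8, 0.1, 0.8, 1, 0.1, 0.1, 0.1, 1), 3, 3)
  rownames(S) <- colnames(S) <- c("i1", "i2", "i3")
  out <- average_linkage_cluster(S, 0.30)
  expect_identical(out, list(c("i1", "i2"), "i3"))
  # complete similarity: one cluster
  S1 <- matrix(1, 4, 4); rownames(S1) <- colnames(S1) <- letters[1:4]
  expect_length(average_linkage_cluster(S1, 0.30), 1L)
  # no similarity: all singletons
  S0 <- diag(1, 4); rownames(S0) <- colnames(S0) <- letters[1:4]
  expect_length(average_linkage_cluster(S0, 0.30), 4L)
  # undefined similarities never drive a merge
  Sna <- matrix(NA_real_, 2, 2); diag(Sna) <- 1
  rownames(Sna) <- colnames(Sna) <- c("x", "y")
  expect_length(average_linkage_cluster(Sna, 0.30), 2L)
})

test_that("greedy linkage agrees with the hclust reference on random matrices", {
  set.seed(32)
  for (r in 1:50) {
    n <- sample(3:50, 1L)
    S <- matrix(stats::runif(n * n), n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    rownames(S) <- colnames(S) <- sprintf("m%02d", seq_len(n))
    mine <- average_linkage_cluster(S, 0.30)
    lab <- integer(n)
    names(lab) <- rownames(S)
    for (k in seq_along(mine)) lab[mine[[k]]] <- k
    ref <- oracle_average_linkage(S, 0.30)
    tab <- table(lab, ref)
    expect_true(all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L),
                label = sprintf("partition mismatch at repeat %d", r))
  }
})

test_that("cluster annotation fills the evidence counts", {
  # 4 member interfaces over 3 crystal forms, 4 entries, 2 proteins
  mk <- function(id, entry, unp, seqs) {
    fake_iface(id, list(c(1, 5), c(2, 6), c(3, 7)), entry_id = entry,
               uniprot = unp, sequence_a = seqs, sequence_b = seqs)
  }
  members <- list(mk("c1", "E1", "P1", strrep("A", 50)),
                  mk("c2", "E2", "P1", strrep("A", 50)),
                  mk("c3", "E3", "P2", strrep("C", 50)),
                  mk("c4", "E4", "P2", strrep("C", 50)))
  cf <- c(E1 = "CF1", E2 = "CF1", E3 = "CF2", E4 = "CF3")
  cl <- structure(list(cluster_id = "t", level = "domain",
                       family_key = "FAMX:FAMX",
                       member_ids = sprintf("c%d", 1:4),
                       members = members, q_avg_internal = 1),
                  class = "xc_cluster")
  ann <- annotate_cluster(cl, cf)
  expect_identical(ann$n_crystal_forms, 3L)
  expect_identical(ann$n_entries, 4L)
  expect_identical(ann$n_uniprots, 2L)
  expect_equal(ann$mean_bsa, 500)
  expect_equal(ann$min_seq_identity, 0)
  # single-member convention
  single <- structure(list(cluster_id = "s", level = "domain",
                           family_key = "FAMX:FAMX",
                           member_ids = "c1", members = members[1L],
                           q_avg_internal = 1), class = "xc_cluster")
  ann1 <- annotate_cluster(single, cf)
  expect_identical(ann1$n_crystal_forms, 1L)
  expect_identical(ann1$n_entries, 1L)
  expect_equal(ann1$q_avg_internal, 1)
  # a member without a form assignment is an error
  expect_error(annotate_cluster(cl, cf[1:2]), "crystal-form assignment")
})

test_that("global alignment identity is exact on hand cases", {
  expect_equal(xtalclust:::.global_identity("AAAA", "AAAA"), 1)
  expect_equal(xtalclust:::.global_identity("AAAA", "CCCC"), 0)
  # one mismatch in four aligned columns
  expect_equal(xtalclust:::.global_identity("AAAA", "AACA"), 3 / 4)
})

test_that("cluster output is invariant under interface input order", {
  bm <- generate_benchmark_set(withr::local_tempdir(), seed = 33,
                               n_forms = 3)
  store <- run_pipeline(unname(bm$entries), bm$annotation_file,
                        verbose = FALSE)
  ifs <- unlist(store$chain_interfaces, recursive = FALSE,
                use.names = FALSE)
  cl1 <- cluster_interfaces(ifs, store$cf_assign)
  cl2 <- cluster_interfaces(rev(ifs), store$cf_assign)
  sets1 <- lapply(cl1, function(x) sort(x$member_ids))
  sets2 <- lapply(cl2, function(x) sort(x$member_ids))
  expect_identical(sets1, sets2)
})
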