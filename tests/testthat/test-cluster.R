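test_that("greedy OTU clustering follows count order and identity cutoff", {
  expect_identical(length(otu_cluster(character(0))$otus), 0L)

  o1 <- otu_cluster(c(a = "ACGT", b = "ACGT", c = "ACGT"), min_sites = 1)
  expect_identical(length(o1$otus), 1L)
  expect_identical(o1$otus[[1]]$count, 3L)

  set.seed(23)
  base <- random_seq(100)
  o2 <- otu_cluster(c(a = base, b = mutate_sites(base, 5)), min_sites = 10)
  expect_identical(length(o2$otus), 2L)  # identity 0.95 < 0.97

  # greedy trace: B joins A (identity 0.98); C vs representative A is 0.96
  A <- base
  B <- mutate_sites(A, 2, sites = 1:2)
  C <- mutate_sites(B, 2, sites = 3:4)
  o3 <- otu_cluster(c(A = A, B = B, C = C), counts = c(5, 3, 1),
                    min_sites = 10)
  expect_identical(length(o3$otus), 2L)
  expect_identical(o3$otus[[1]]$representative, "A")
  expect_setequal(o3$otus[[1]]$members, c("A", "B"))
  expect_identical(o3$otus[[2]]$members, "C")
  expect_identical(o3$otus[[1]]$count, 8L)
})

test_that("OTU representatives are mutually below the identity cutoff", {
  set.seed(29)
  for (rep in 1:10) {
    base <- random_seq(150)
    seqs <- stats::setNames(
      vapply(1:12, function(i) mutate_sites(base, sample(0:12, 1)),
             character(1)),
      sprintf("s%02d", 1:12))
    o <- otu_cluster(seqs, identity_cutoff = 0.97, min_sites = 10)
    reps <- vapply(o$otus, `[[`, character(1), "representative")
    if (length(reps) >= 2) {
      for (i in seq_along(reps)) for (j in seq_along(reps)) {
        if (i < j)
          expect_lt(1 - p_distance(seqs[[reps[i]]], seqs[[reps[j]]]), 0.97)
      }
    }
    # every member within (1 - cutoff) of its representative
    for (otu in o$otus) {
      for (m in otu$members)
        expect_lte(p_distance(seqs[[m]], seqs[[otu$representative]]),
                   1 - 0.97 + 1e-12)
    }
  }
})

test_that("delimit separates groups across the gap and labels ECs", {
  set.seed(31)
  x <- toy_two_groups(L = 1000, cross = 0.10)
  d <- distance_matrix(x, min_sites = 100)
  p <- delimit(d, x$meta)
  expect_identical(nrow(p$clusters), 2L)
  expect_setequal(p$clusters$label, c("X", "EC I"))
  expect_identical(unname(p$membership[c("A1", "B1")]), c("X", "EC I"))
  expect_identical(nrow(p$gap_violations), 0L)

  # single sequence -> one cluster
  x1 <- make_msa(c(solo = "ACGTACGT"))
  p1 <- delimit(distance_matrix(x1, min_sites = 1), x1$meta)
  expect_identical(nrow(p1$clusters), 1L)
})

test_that("conflicting cultured labels in one cluster raise an error", {
  seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  meta <- data.frame(id = c("a", "b"), species = c("X", "Y"),
                     source = "culture", count = 1, locality = NA)
  d <- distance_matrix(seqs, min_sites = 1)
  expect_error(delimit(d, meta), "conflict.*X / Y")
})

test_that("EC numbering is by size then smallest member id", {
  set.seed(37)
  base <- random_seq(600)
  g1 <- mutate_sites(base, 60)    # will be EC II (2 members)
  g2 <- mutate_sites(base, 120)   # will be EC I (3 members)
  seqs <- c(z1 = g1, z2 = g1, m1 = g2, m2 = g2, m3 = g2)
  x <- make_msa(seqs)
  d <- distance_matrix(x, min_sites = 100)
  p <- delimit(d, x$meta)
  expect_identical(unname(p$membership[c("m1", "z1")]), c("EC I", "EC II"))

  # equal sizes: tie broken by ascending smallest member id
  seqs2 <- c(b1 = g1, b2 = g1, a1 = g2, a2 = g2)
  x2 <- make_msa(seqs2)
  p2 <- delimit(distance_matrix(x2, min_sites = 100), x2$meta)
  expect_identical(unname(p2$membership[c("a1", "b1")]), c("EC I", "EC II"))
})

test_that("delimit clusters are invariant to input order", {
  set.seed(41)
  cfg <- sim_config(seed = 99, abundance_profile = 1)
  refs <- generate_references(cfg)
  d <- distance_matrix(refs$msa, min_sites = 100)
  p <- delimit(d, refs$msa$meta)
  perm <- sample(rownames(d))
  dp <- d[perm, perm]
  attr(dp, "min_sites") <- attr(d, "min_sites")
  pp <- delimit(dp, refs$msa$meta)
  expect_identical(membership_to_blocks(p$membership),
                   membership_to_blocks(pp$membership))
  ids <- sort(names(p$membership))
  expect_identical(p$membership[ids], pp$membership[ids])  # same labels too
})

test_that("delimit matches exhaustive single-linkage enumeration (n <= 8)", {
  set.seed(43)
  for (inst in 1:20) {
    n <- sample(3:8, 1)
    base <- random_seq(80)
    seqs <- stats::setNames(
      vapply(seq_len(n), function(i) mutate_sites(base, sample(0:12, 1)),
             character(1)),
      sprintf("q%02d", seq_len(n)))
    x <- make_msa(seqs)
    t_intra <- stats::runif(1, 0.02, 0.10)
    d <- distance_matrix(x, min_sites = 10)
    p <- delimit(d, x$meta, t_intra = t_intra, t_inter = t_intra + 0.02)
    valid <- single_linkage_oracle(unclass(d), t_intra)
    expect_identical(length(valid), 1L)  # oracle partition is unique
    expect_identical(membership_to_blocks(p$membership),
                     canon_partition(valid[[1]]))
  }
})

test_that("gap audit flags pairs inside the forbidden zone only", {
  set.seed(47)
  base <- random_seq(1000)
  # two clusters exactly 68 substitutions apart: 0.068 clears t_inter=0.067
  ok <- c(a1 = base, a2 = base, b1 = mutate_sites(base, 68))
  x <- make_msa(ok)
  p <- delimit(distance_matrix(x, min_sites = 100), x$meta)
  g <- check_gap(p, distance_matrix(x, min_sites = 100))
  expect_identical(nrow(g), 1L)
  expect_false(g$below_t_inter)
  expect_false(g$in_gap)

  # 0.05 sits inside the gap -> flagged
  bad <- c(a1 = base, b1 = mutate_sites(base, 50))
  x2 <- make_msa(bad)
  p2 <- delimit(distance_matrix(x2, min_sites = 100), x2$meta)
  g2 <- check_gap(p2, distance_matrix(x2, min_sites = 100))
  expect_true(g2$below_t_inter)
  expect_true(g2$in_gap)
  expect_identical(nrow(p2$gap_violations), 1L)

  # single cluster -> empty report
  x3 <- make_msa(c(a = base, b = base))
  p3 <- delimit(distance_matrix(x3, min_sites = 100), x3$meta)
  expect_identical(nrow(check_gap(p3, distance_matrix(x3, min_sites = 100))),
                   0L)
})
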