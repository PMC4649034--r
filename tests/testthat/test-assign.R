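# builds a reference community with one cultured species (X: two strains
# 20 sites apart on L=1000, so max_intra = 0.02) and one distant
# environmental clade (EC I)
make_ref_partition <- function(L = 1000, intra = 20, cross = 150) {
  base <- random_seq(L)
  x2 <- mutate_sites(base, intra)
  far <- mutate_sites(base, cross)
  seqs <- c(X1 = base, X2 = x2, E1 = far, E2 = far)
  meta <- data.frame(id = names(seqs), species = c("X", "X", NA, NA),
                     source = c("culture", "culture", "clone", "clone"),
                     count = 1L, locality = NA, stringsAsFactors = FALSE)
  refs <- msa(seqs, meta)
  d <- distance_matrix(refs, min_sites = 100)
  list(refs = refs, partition = delimit(d, meta))
}

test_that("queries inside the distance envelope are assigned", {
  set.seed(53)
  rp <- make_ref_partition()
  base <- rp$refs$seqs[["X1"]]

  # exact copy of a reference -> assigned at distance 0
  q0 <- make_msa(c(q0 = base))
  a0 <- assign_fragments(q0, rp$refs, rp$partition, min_sites = 80)
  expect_identical(a0$status, "assigned")
  expect_identical(a0$species, "X")
  expect_identical(a0$best_distance, 0)
  expect_identical(a0$nearest_reference, "X1")

  # query at max_intra + 0.005 from its nearest reference, slack 0.01
  q1 <- make_msa(c(q1 = mutate_sites(base, 25, sites = 101:125)))
  a1 <- assign_fragments(q1, rp$refs, rp$partition, slack = 0.01,
                         min_sites = 80)
  expect_identical(a1$status, "assigned")
  expect_identical(a1$species, "X")
})

test_that("distant and low-overlap queries are routed correctly", {
  set.seed(59)
  rp <- make_ref_partition()
  L <- 1000
  # planted fragment >= 0.08 from every species -> founder pool
  wild <- mutate_sites(random_seq(L), 0)
  qf <- make_msa(c(wild = wild))
  af <- assign_fragments(qf, rp$refs, rp$partition, min_sites = 80)
  expect_identical(af$status, "founder_pool")
  expect_true(is.na(af$species))

  # only 40 comparable sites, min_sites = 80 -> unassigned_low_overlap
  short <- paste0(substr(rp$refs$seqs[["X1"]], 1, 40), strrep("-", L - 40))
  ql <- make_msa(c(short = short))
  al <- assign_fragments(ql, rp$refs, rp$partition, min_sites = 80)
  expect_identical(al$status, "unassigned_low_overlap")
  expect_identical(al$overlap_sites, 40L)
})

test_that("envelope ties within tolerance are reported as ambiguous", {
  seqs <- c(X1 = strrep("ACGT", 50), Y1 = strrep("ACGT", 50))
  part <- structure(list(
    membership = c(X1 = "X", Y1 = "Y"),
    clusters = data.frame(label = c("X", "Y"), n_members = 1L,
                          cultured = TRUE),
    t_intra = 0.046, t_inter = 0.067,
    gap_violations = data.frame()), class = "species_partition")
  q <- make_msa(c(q = strrep("ACGT", 50)))
  a <- assign_fragments(q, seqs, part, min_sites = 80)
  expect_identical(a$status, "ambiguous")
  expect_identical(a$species, "X|Y")
})

test_that("noiseless window fragments always return to their species", {
  for (seed in c(101, 202, 303)) {
    cfg <- sim_config(seed = seed, fragment_error = 0)
    refs <- generate_references(cfg)
    d <- distance_matrix(extract_window(refs$msa, cfg$windows$core),
                         min_sites = 100)
    part <- delimit(d, refs$msa$meta)
    for (wname in names(cfg$windows)) {
      w <- cfg$windows[[wname]]
      refwin <- extract_window(refs$msa, w)
      # every strain's own window slice, re-labeled as a query
      q <- refwin$seqs
      names(q) <- paste0("q_", names(q))
      asn <- assign_fragments(make_msa(q), refwin, part, min_sites = 80)
      truth <- unname(part$membership[refs$truth$id])
      expect_identical(asn$status, rep("assigned", length(q)))
      expect_identical(asn$species, truth)
    }
  }
})

test_that("new environmental clades are founded past the gap and merged", {
  set.seed(61)
  rp <- make_ref_partition()
  base <- rp$refs$seqs[["X1"]]
  empty <- found_new_ecs(character(0), rp$refs, rp$partition)
  expect_identical(nrow(empty$new_ecs), 0L)

  # one founder at ~0.15 from everything -> next EC (EC II; EC I exists)
  lone <- make_msa(c(f1 = mutate_sites(base, 150, sites = 300:449)))
  r1 <- found_new_ecs(lone, rp$refs, rp$partition, min_sites = 80)
  expect_identical(r1$new_ecs$label, "EC II")
  expect_identical(unname(r1$membership["f1"]), "EC II")
  expect_false(r1$new_ecs$overlap_incomplete)

  # two founder OTUs mutually within t_intra merge into one EC;
  # a third founder far from both becomes its own EC
  g <- mutate_sites(base, 150, sites = 1:150)
  # 0.04 from g: below the 0.97 OTU identity (separate OTU) yet inside
  # t_intra (same new EC)
  g2 <- mutate_sites(g, 40, sites = 201:240)
  h <- mutate_sites(base, 150, sites = 500:649)  # far from g and refs
  pool <- make_msa(c(p1 = g, p2 = g, p3 = g2, p4 = h))
  r2 <- found_new_ecs(pool, rp$refs, rp$partition, min_sites = 80)
  expect_identical(nrow(r2$new_ecs), 2L)
  expect_identical(unname(r2$membership["p1"]),
                   unname(r2$membership["p3"]))
  expect_false(unname(r2$membership["p4"]) ==
                 unname(r2$membership["p1"]))
  # numbering continues after existing ECs, larger group first
  expect_setequal(r2$new_ecs$label, c("EC II", "EC III"))
  expect_identical(unname(r2$membership["p1"]), "EC II")

  # founded clades sit beyond t_inter from every pre-existing species
  for (i in seq_len(nrow(r2$new_ecs))) {
    members <- names(r2$membership)[!is.na(r2$membership) &
                                      r2$membership == r2$new_ecs$label[i]]
    for (m in members) {
      dmin <- min(vapply(names(rp$refs$seqs), function(r)
        p_distance(pool$seqs[[m]], rp$refs$seqs[[r]]), numeric(1)))
      expect_gt(dmin, rp$partition$t_inter)
    }
  }
})

test_that("the paired-site signature call is position-faithful", {
  seqs <- c(andalucina = "TTCTTTGTT", other = "TTATTTTTT",
            gapped = "TT-TTTGTT")
  calls <- call_signature(seqs, c(3, 7))
  expect_identical(calls$call, c("CG", "AT", "other"))
  expect_error(call_signature(seqs, c(3, 99)), "outside alignment")

  # permuting other columns never changes the call
  set.seed(67)
  for (i in 1:10) {
    perm <- c(1, 2, 4, 5, 6, 8, 9)[sample(7)]
    shuffled <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      ch[c(1, 2, 4, 5, 6, 8, 9)] <- ch[perm]
      paste(ch, collapse = "")
    }, character(1))
    expect_identical(call_signature(shuffled, c(3, 7))$call, calls$call)
  }
})
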