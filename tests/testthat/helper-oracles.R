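# Independent oracles and small fixture builders used across tests.

options(stygdist.quiet = TRUE)

# per-site brute-force p-distance: explicit loop, no vectorization,
# deliberately independent of the package's matrix-product path
brute_pdist <- function(a, b, min_sites = 1L) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(av) == length(bv))
  bases <- c("A", "C", "G", "T")
  n_cmp <- 0L
  n_mis <- 0L
  for (i in seq_along(av)) {
    if (av[i] %in% bases && bv[i] %in% bases) {
      n_cmp <- n_cmp + 1L
      if (av[i] != bv[i]) n_mis <- n_mis + 1L
    }
  }
  if (n_cmp < min_sites) NA_real_ else n_mis / n_cmp
}

# all set partitions of 1..n as lists of integer blocks
# (restricted-growth-string enumeration)
enum_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  recurse <- function(i, maxg) {
    if (i > n) {
      out[[length(out) + 1L]] <<- split(seq_len(n), rgs)
      return(invisible(NULL))
    }
    for (g in seq_len(maxg + 1L)) {
      rgs[i] <<- g
      recurse(i + 1L, max(maxg, g))
    }
  }
  recurse(1L, 0L)
  out
}

# exhaustive-enumeration single-linkage oracle: among all partitions,
# the valid ones have every block internally chained by distances <= t
# and no cross-block distance <= t; returns blocks of ids
single_linkage_oracle <- function(d, t) {
  n <- nrow(d)
  ids <- rownames(d)
  valid <- list()
  for (p in enum_partitions(n)) {
    ok <- TRUE
    for (blk in p) {
      # block connectivity under edges <= t, by naive closure
      reach <- logical(n)
      reach[blk[1]] <- TRUE
      repeat {
        grew <- FALSE
        for (i in blk) if (reach[i]) {
          for (j in blk) {
            if (!reach[j] && !is.na(d[i, j]) && d[i, j] <= t) {
              reach[j] <- TRUE; grew <- TRUE
            }
          }
        }
        if (!grew) break
      }
      if (!all(reach[blk])) { ok <- FALSE; break }
    }
    if (ok && length(p) > 1L) {
      for (i in seq_along(p)) for (j in seq_along(p)) {
        if (i < j) {
          cross <- d[p[[i]], p[[j]], drop = FALSE]
          if (any(!is.na(cross) & cross <= t)) ok <- FALSE
        }
      }
    }
    if (ok) valid[[length(valid) + 1L]] <- lapply(p, function(b) ids[b])
  }
  valid
}

# canonical form of a partition for set comparison
canon_partition <- function(blocks) {
  blocks <- unname(lapply(blocks, sort))
  blocks[order(vapply(blocks, `[`, character(1), 1))]
}

membership_to_blocks <- function(membership) {
  canon_partition(split(names(membership), unname(membership)))
}

random_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# mutate `k` distinct sites of a sequence string to a different base
mutate_sites <- function(seq, k, sites = NULL) {
  ch <- strsplit(seq, "")[[1]]
  if (is.null(sites)) sites <- sample(seq_along(ch), k)
  for (p in sites) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

make_msa <- function(seqs, species = NA, source = "clone", count = 1L) {
  meta <- data.frame(id = names(seqs), species = species, source = source,
                     count = count, locality = NA_character_,
                     stringsAsFactors = FALSE)
  msa(seqs, meta)
}

# two-species toy community: cluster A cultured (labeled X), cluster B
# environmental; intra distances 0, cross distance `cross` (fraction of L)
toy_two_groups <- function(L = 1000, cross = 0.10) {
  base <- random_seq(L)
  far <- mutate_sites(base, round(cross * L))
  seqs <- c(A1 = base, A2 = base, A3 = base, B1 = far, B2 = far, B3 = far)
  meta <- data.frame(id = names(seqs),
                     species = c("X", "X", "X", NA, NA, NA),
                     source = c("culture", "clone", "clone",
                                "clone", "clone", "clone"),
                     count = 1L, locality = NA_character_,
                     stringsAsFactors = FALSE)
  msa(seqs, meta)
}
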