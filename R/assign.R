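# Distance-envelope assignment of short fragments to species/ECs,
# founding of new environmental clades, and the helix-27 signature call.

ASSIGN_STATUS <- c("assigned", "ambiguous", "unassigned_low_overlap",
                   "founder_pool")

# per-species max defined intraspecific distance over the given rows;
# singleton species (and multi-member species with no defined intra
# pair) use 0 — their envelope is the slack alone
species_envelopes <- function(d, species) {
  sp <- unique(species)
  env <- stats::setNames(rep(0, length(sp)), sp)
  for (s in sp) {
    i <- which(species == s)
    if (length(i) < 2L) next
    v <- d[i, i, drop = FALSE][upper.tri(diag(length(i)))]
    v <- v[!is.na(v)]
    if (length(v)) env[s] <- max(v)
  }
  env
}

#' Assign fragments to species or environmental clades by distance envelope
#'
#' For each query the distance to species `s` is the minimum p-distance
#' from the query to any member of `s` over the window. A query is
#' `assigned` to the closest species `s*` when that distance does not
#' exceed the species' maximum intraspecific window distance plus
#' `slack`; `ambiguous` when a second species satisfies its envelope at a
#' distance within `tie_tol` of the best; `unassigned_low_overlap` when
#' no reference shares at least `min_sites` comparable sites; otherwise
#' it enters the `founder_pool` for possible new-clade founding.
#'
#' @param queries [msa] of query fragments aligned into the reference
#'   coordinate system (or pre-sliced to the window).
#' @param references [msa] of reference sequences.
#' @param partition [delimit()] result labeling the reference ids.
#' @param window Optional [anchor_window()]; when supplied both queries
#'   and references are sliced to it first.
#' @param slack Absolute distance tolerance added to each species'
#'   intraspecific envelope (default 0.01, about one substitution on a
#'   V9-sized fragment).
#' @param min_sites Minimum comparable sites (default 80 for V9-sized
#'   fragments).
#' @param tie_tol Ambiguity tolerance between competing species
#'   (default 1e-9). Ties are reported, never silently broken.
#' @return Data frame of class `assignment_table` with columns `query`,
#'   `status`, `species`, `best_distance`, `overlap_sites`,
#'   `nearest_reference`.
#' @export
assign_fragments <- function(queries, references, partition,
                             window = NULL, slack = 0.01,
                             min_sites = 80L, tie_tol = 1e-9) {
  stopifnot(inherits(partition, "species_partition"))
  if (inherits(references, "msa") && length(references$seqs) == 0L)
    stop("empty reference set")
  if (!is.null(window)) {
    references <- extract_window(references, window)
    queries <- extract_window(queries, window)
  }
  rseq <- if (inherits(references, "msa")) references$seqs else references
  qseq <- if (inherits(queries, "msa")) queries$seqs else queries
  if (length(rseq) == 0L) stop("empty reference set")
  mem <- partition$membership
  if (!all(names(rseq) %in% names(mem)))
    stop("references not covered by partition: ",
         paste(setdiff(names(rseq), names(mem)), collapse = ", "))
  rsp <- unname(mem[names(rseq)])
  Xq <- seq_char_matrix(qseq)
  Xr <- seq_char_matrix(rseq)
  if (ncol(Xq) != ncol(Xr))
    stop("queries and references have different widths; slice both to ",
         "the same window first")
  cr <- cross_pdist(Xq, Xr, min_sites = min_sites)
  # envelopes from the reference rows themselves, over the same window
  dref <- cross_pdist(Xr, Xr, min_sites = min_sites)$d
  envl <- species_envelopes(dref, rsp)
  sp <- names(envl)
  out <- data.frame(query = names(qseq),
                    status = NA_character_, species = NA_character_,
                    best_distance = NA_real_, overlap_sites = 0L,
                    nearest_reference = NA_character_,
                    stringsAsFactors = FALSE)
  for (q in seq_along(qseq)) {
    dq <- cr$d[q, ]
    out$overlap_sites[q] <- as.integer(max(cr$sites[q, ]))
    if (all(is.na(dq))) {
      out$status[q] <- "unassigned_low_overlap"
      next
    }
    dsp <- vapply(sp, function(s) {
      v <- dq[rsp == s]
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
    }, numeric(1))
    best <- which.min(dsp)               # first minimum; sp order is fixed
    dbest <- dsp[best]
    nearest_pool <- names(dq)[!is.na(dq) & rsp == sp[best] &
                                dq <= dbest + 1e-12]
    out$nearest_reference[q] <- sort(nearest_pool)[1]
    out$best_distance[q] <- dbest
    satisfies <- !is.na(dsp) & dsp <= envl + slack
    if (!satisfies[best]) {
      out$status[q] <- "founder_pool"
      next
    }
    rivals <- which(satisfies & abs(dsp - dbest) <= tie_tol)
    if (length(rivals) > 1L) {
      out$status[q] <- "ambiguous"
      out$species[q] <- paste(sp[rivals], collapse = "|")
    } else {
      out$status[q] <- "assigned"
      out$species[q] <- sp[best]
    }
  }
  class(out) <- c("assignment_table", class(out))
  out
}

#' Found new environmental clades from unassignable fragments
#'
#' Founder-pool fragments are clustered into OTUs at `identity_cutoff`.
#' Each OTU whose minimum distance to every existing species/EC exceeds
#' `t_inter` (wherever at least `min_sites` sites are comparable)
#' qualifies as new-clade material; OTUs that cannot be compared to some
#' existing clade at all are still founded but flagged
#' `overlap_incomplete`. Qualifying OTUs that are mutually within
#' `t_intra` are merged into a single new EC; new ECs are numbered after
#' the existing ones, by descending total count then ascending smallest
#' member id.
#'
#' @param founders [msa] (or named character vector) of founder-pool
#'   fragments, in the same window coordinates as `references`.
#' @param references [msa] or named character vector of reference rows.
#' @param partition Existing [delimit()] partition over the references.
#' @param identity_cutoff OTU identity cutoff (default 0.97).
#' @param t_intra,t_inter Delimitation thresholds; defaults from the
#'   partition.
#' @param min_sites Minimum comparable sites for a distance to count.
#' @param counts Read multiplicities for the founder fragments.
#' @return List with `new_ecs` (data frame label / otu_representatives /
#'   n_members / total_count / overlap_incomplete), `membership` (named
#'   vector fragment id -> EC label, NA when not founded), and `otus`
#'   (the founder `otu_set`).
#' @export
found_new_ecs <- function(founders, references, partition,
                          identity_cutoff = 0.97,
                          t_intra = partition$t_intra,
                          t_inter = partition$t_inter,
                          min_sites = 80L, counts = 1L) {
  fseq <- if (inherits(founders, "msa")) founders$seqs else founders
  rseq <- if (inherits(references, "msa")) references$seqs else references
  if (length(fseq) == 0L)
    return(list(new_ecs = data.frame(), membership = character(0),
                otus = otu_cluster(character(0))))
  if (inherits(founders, "msa")) {
    idx <- match(names(fseq), founders$meta$id)
    counts <- founders$meta$count[idx]
  }
  otus <- otu_cluster(fseq, counts = counts,
                      identity_cutoff = identity_cutoff,
                      min_sites = min_sites)
  mem <- partition$membership
  rsp <- unname(mem[names(rseq)])
  labs <- unique(rsp)
  Xr <- seq_char_matrix(rseq)
  reps <- vapply(otus$otus, `[[`, character(1), "representative")
  Xrep <- seq_char_matrix(fseq[reps])
  cr <- cross_pdist(Xrep, Xr, min_sites = min_sites)$d
  qualifies <- logical(length(reps))
  incomplete <- logical(length(reps))
  for (k in seq_along(reps)) {
    dk <- vapply(labs, function(s) {
      v <- cr[k, rsp == s]
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
    }, numeric(1))
    incomplete[k] <- anyNA(dk)
    # non-comparable clades cannot veto founding (flagged above)
    qualifies[k] <- all(dk > t_inter, na.rm = TRUE)
  }
  new_ecs <- data.frame(label = character(0),
                        otu_representatives = character(0),
                        n_members = integer(0), total_count = integer(0),
                        overlap_incomplete = logical(0),
                        stringsAsFactors = FALSE)
  membership <- stats::setNames(rep(NA_character_, length(fseq)),
                                names(fseq))
  qk <- which(qualifies)
  if (length(qk)) {
    # merge qualifying OTUs that are mutually within t_intra
    drep <- cross_pdist(seq_char_matrix(fseq[reps[qk]]),
                        seq_char_matrix(fseq[reps[qk]]),
                        min_sites = min_sites)$d
    diag(drep) <- 0
    grp <- threshold_components(drep, t_intra)
    n_existing <- sum(is_ec_label(unique(mem)))
    g_count <- vapply(unique(grp), function(g) {
      sum(vapply(otus$otus[qk[grp == g]], `[[`, integer(1), "count"))
    }, integer(1))
    g_first <- vapply(unique(grp), function(g) {
      min(unlist(lapply(otus$otus[qk[grp == g]], `[[`, "members")))
    }, character(1))
    ord <- order(-g_count, g_first, method = "radix")
    for (j in seq_along(ord)) {
      g <- unique(grp)[ord[j]]
      ks <- qk[grp == g]
      lab <- ec_label(n_existing + j)
      members <- unlist(lapply(otus$otus[ks], `[[`, "members"))
      membership[members] <- lab
      new_ecs <- rbind(new_ecs, data.frame(
        label = lab,
        otu_representatives = paste(reps[ks], collapse = ","),
        n_members = length(members),
        total_count = sum(vapply(otus$otus[ks], `[[`, integer(1), "count")),
        overlap_incomplete = any(incomplete[ks]),
        stringsAsFactors = FALSE))
    }
  }
  list(new_ecs = new_ecs, membership = membership, otus = otus)
}

#' Check the diagnostic paired-site signature (helix-27 base pair)
#'
#' The basal stem of SSU rRNA helix 27 carries a C:G pair in Andalucina
#' where other jakobids show A:T. Given the two alignment columns of the
#' pair (configuration, not computed), each row is called `CG`, `AT`, or
#' `other` (any gap, ambiguity code, or non-canonical combination).
#'
#' @param x An [msa] or named character vector of aligned rows.
#' @param col_pair Integer vector of the two alignment columns
#'   `c(col1, col2)`.
#' @return Data frame `id`, `call`, `col1`, `col2`.
#' @export
call_signature <- function(x, col_pair) {
  seqs <- if (inherits(x, "msa")) x$seqs else x
  stopifnot(length(col_pair) == 2L)
  w <- nchar(seqs[[1]])
  if (any(col_pair < 1L) || any(col_pair > w))
    stop("signature column(s) ", paste(col_pair, collapse = ","),
         " outside alignment width ", w)
  a <- toupper(substr(seqs, col_pair[1], col_pair[1]))
  b <- toupper(substr(seqs, col_pair[2], col_pair[2]))
  call <- ifelse(a == "C" & b == "G", "CG",
                 ifelse(a == "A" & b == "T", "AT", "other"))
  data.frame(id = names(seqs), call = unname(call),
             col1 = col_pair[1], col2 = col_pair[2],
             stringsAsFactors = FALSE)
}
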