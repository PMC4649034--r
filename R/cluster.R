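# OTU clustering and distance-gap species delimitation.

#' Greedy OTU clustering at an identity cutoff
#'
#' Sequences are processed by descending count (ties broken by ascending
#' id). Each sequence joins the first existing OTU whose representative
#' is within identity `1 - p_distance >= identity_cutoff`; otherwise it
#' founds a new OTU with itself as representative. This mirrors common
#' uclust-style greedy behavior and is fully deterministic.
#'
#' @param seqs Named character vector of sequences (ungapped or
#'   identically aligned).
#' @param counts Integer read multiplicities, recycled to
#'   `length(seqs)`; default 1.
#' @param identity_cutoff Identity fraction; default 0.97 (OTU_97).
#' @param min_sites Minimum comparable sites for an identity to count;
#'   pairs below it never join.
#' @return List of class `otu_set`: `otus` (list of
#'   `list(representative, members, count)`), `identity_cutoff`,
#'   `membership` (data frame id / otu / representative flag).
#' @export
otu_cluster <- function(seqs, counts = 1L, identity_cutoff = 0.97,
                        min_sites = 1L) {
  counts <- rep_len(as.integer(counts), length(seqs))
  if (length(seqs) == 0L) {
    return(structure(list(otus = list(), identity_cutoff = identity_cutoff,
                          membership = data.frame(id = character(0),
                                                  otu = integer(0),
                                                  representative = logical(0))),
                     class = "otu_set"))
  }
  ord <- order(-counts, names(seqs), method = "radix")
  ids <- names(seqs)[ord]
  sq <- seqs[ord]
  cnt <- counts[ord]
  X <- seq_char_matrix(sq)
  reps <- integer(0)            # row indices of representatives, founding order
  assign <- integer(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      d <- p_distance(X[i, ], X[reps[k], ], min_sites = min_sites)
      if (!is.na(d) && (1 - d) >= identity_cutoff) {
        assign[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
    }
  }
  otus <- lapply(seq_along(reps), function(k) {
    m <- which(assign == k)
    list(representative = ids[reps[k]], members = ids[m],
         count = sum(cnt[m]))
  })
  membership <- data.frame(id = ids, otu = assign,
                           representative = seq_along(ids) %in% reps,
                           stringsAsFactors = FALSE)
  structure(list(otus = otus, identity_cutoff = identity_cutoff,
                 membership = membership),
            class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat("otu_set:", length(x$otus), "OTUs at identity",
      x$identity_cutoff, "\n")
  invisible(x)
}

# connected components of the graph with edges d <= threshold
# (equivalent to cutting a single-linkage dendrogram at that height)
threshold_components <- function(d, threshold) {
  n <- nrow(d)
  comp <- integer(n)
  nextc <- 0L
  adj <- !is.na(d) & d <= threshold
  diag(adj) <- TRUE
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    nextc <- nextc + 1L
    queue <- i
    comp[i] <- nextc
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- nextc
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Delimit species by the distance gap
#'
#' Single-linkage clustering with linkage threshold `t_intra`: two
#' sequences fall in one species-level cluster iff they are connected by
#' a chain of pairwise distances `<= t_intra`. Clusters containing at
#' least one culture-sourced member take the (unique) species label of
#' their cultured members; clusters without cultured members become
#' environmental clades "EC I", "EC II", ... numbered by descending
#' member count, ties by ascending smallest member id. Cluster pairs
#' whose minimum inter-cluster distance falls strictly inside
#' `(t_intra, t_inter)` — i.e. inside the supposed barcoding gap — are
#' recorded as gap violations.
#'
#' @param d `p_dist` matrix over the sequences to delimit.
#' @param meta Data frame with columns `id`, `species`, `source`
#'   matching the matrix ids.
#' @param t_intra Maximum intraspecific distance (default 0.046).
#' @param t_inter Minimum interspecific distance (default 0.067).
#' @return A list of class `species_partition`: `membership` (named
#'   character vector id -> label), `clusters` (data frame label /
#'   n_members / cultured), `t_intra`, `t_inter`, `gap_violations`
#'   (data frame of offending pairs).
#' @export
delimit <- function(d, meta, t_intra = 0.046, t_inter = 0.067) {
  ids <- rownames(d)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  idx <- match(ids, meta$id)
  if (anyNA(idx))
    stop("metadata missing for ids: ",
         paste(ids[is.na(idx)], collapse = ", "))
  species <- as.character(meta$species[idx])
  source <- as.character(meta$source[idx])
  comp <- threshold_components(unclass(d), t_intra)
  labels <- character(max(comp))
  cultured <- logical(max(comp))
  for (k in seq_len(max(comp))) {
    m <- which(comp == k)
    cult <- m[source[m] == "culture"]
    cultured[k] <- length(cult) > 0L
    if (cultured[k]) {
      sp <- unique(species[cult])
      sp <- sp[!is.na(sp) & sp != ""]
      if (length(sp) == 0L)
        stop("cluster with cultured member(s) ",
             paste(ids[cult], collapse = ", "), " lacks a species label")
      if (length(sp) > 1L)
        stop("conflict: cultured members of one cluster carry labels ",
             paste(sp, collapse = " / "), " (ids: ",
             paste(ids[cult], collapse = ", "), ")")
      labels[k] <- sp
    }
  }
  if (anyDuplicated(labels[cultured]))
    stop("species label ",
         paste(unique(labels[cultured][duplicated(labels[cultured])]),
               collapse = ", "),
         " spans multiple delimited clusters")
  env <- which(!cultured)
  if (length(env)) {
    size <- tabulate(comp, max(comp))[env]
    first_id <- vapply(env, function(k) min(ids[comp == k]), character(1))
    ord <- order(-size, first_id, method = "radix")
    labels[env[ord]] <- vapply(seq_along(env), ec_label, character(1))
  }
  membership <- stats::setNames(labels[comp], ids)
  clusters <- data.frame(label = labels,
                         n_members = tabulate(comp, max(comp)),
                         cultured = cultured,
                         stringsAsFactors = FALSE)
  part <- structure(list(membership = membership, clusters = clusters,
                         t_intra = t_intra, t_inter = t_inter,
                         gap_violations = NULL),
                    class = "species_partition")
  gaps <- check_gap(part, d)
  part$gap_violations <- gaps[gaps$in_gap, , drop = FALSE]
  if (nrow(part$gap_violations))
    styg_log("WARN", nrow(part$gap_violations),
             " cluster pair(s) fall inside the distance gap (",
             t_intra, ", ", t_inter, ")")
  part
}

#' @export
print.species_partition <- function(x, ...) {
  cat("species_partition:", nrow(x$clusters), "clusters (",
      sum(x$clusters$cultured), "cultured,",
      sum(!x$clusters$cultured), "environmental );",
      "t_intra =", x$t_intra, ", t_inter =", x$t_inter, "\n")
  invisible(x)
}

#' Audit inter-cluster distances against the delimitation thresholds
#'
#' @param partition A [delimit()] result built from the same ids.
#' @param d The distance matrix used for delimitation.
#' @return Data frame with one row per cluster pair: labels, minimum
#'   inter-cluster distance, `below_t_inter` flag (distance `<
#'   t_inter`), and `in_gap` flag (strictly inside
#'   `(t_intra, t_inter)`).
#' @export
check_gap <- function(partition, d) {
  stopifnot(inherits(partition, "species_partition"))
  mem <- partition$membership
  ids <- rownames(d)
  if (!all(ids %in% names(mem)))
    stop("partition and matrix ids disagree")
  labs <- unique(partition$clusters$label)
  out <- data.frame(cluster_a = character(0), cluster_b = character(0),
                    min_inter = numeric(0), below_t_inter = logical(0),
                    in_gap = logical(0), stringsAsFactors = FALSE)
  if (length(labs) < 2L) return(out)
  pairs <- utils::combn(labs, 2L)
  for (k in seq_len(ncol(pairs))) {
    a <- ids[mem[ids] == pairs[1, k]]
    b <- ids[mem[ids] == pairs[2, k]]
    v <- d[a, b, drop = FALSE]
    v <- v[!is.na(v)]
    mind <- if (length(v)) min(v) else NA_real_
    out <- rbind(out, data.frame(
      cluster_a = pairs[1, k], cluster_b = pairs[2, k],
      min_inter = mind,
      below_t_inter = !is.na(mind) && mind < partition$t_inter,
      in_gap = !is.na(mind) && mind > partition$t_intra &&
        mind < partition$t_inter,
      stringsAsFactors = FALSE))
  }
  out
}

#' Write a partition's membership as TSV
#' @param partition A `species_partition`.
#' @param path Output path.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(id = names(partition$membership),
                   cluster = unname(partition$membership),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(partition)
}
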