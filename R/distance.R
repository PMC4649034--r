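# Uncorrected p-distances with pairwise deletion.
#
# A site enters a pairwise comparison iff BOTH rows carry an unambiguous
# base (A/C/G/T) at that column; gaps, N and IUPAC ambiguity codes are
# excluded for that pair only (pairwise deletion). Distances with fewer
# than `min_sites` comparable sites are reported as NA (undefined).

BASES <- c("A", "C", "G", "T")

#' Uncorrected p-distance between two aligned rows
#'
#' @param row_a,row_b Equal-length sequence strings (or character
#'   vectors of single residues).
#' @param min_sites Minimum number of comparable sites for the distance
#'   to be defined; below it `NA` is returned.
#' @return Mismatch fraction in `[0, 1]`, or `NA` if fewer than
#'   `min_sites` sites are comparable.
#' @examples
#' p_distance("ACGT", "ACGT")            # 0
#' p_distance("ACGT-ACGT", "ACCTAACGT")  # 1 mismatch / 8 sites = 0.125
#' @export
p_distance <- function(row_a, row_b, min_sites = 1L) {
  a <- if (length(row_a) == 1L) strsplit(toupper(row_a), "")[[1]] else toupper(row_a)
  b <- if (length(row_b) == 1L) strsplit(toupper(row_b), "")[[1]] else toupper(row_b)
  if (length(a) != length(b))
    stop("rows differ in length (", length(a), " vs ", length(b), ")")
  cmp <- a %in% BASES & b %in% BASES
  n <- sum(cmp)
  if (n < min_sites) return(NA_real_)
  sum(a[cmp] != b[cmp]) / n
}

# 0/1 indicator matrices per base for fast matrix-product distance
base_indicators <- function(X) {
  lapply(BASES, function(b) (X == b) * 1L)
}

# cross p-distance between two character matrices (rows = sequences);
# returns list(d = distances with NA below min_sites, sites = comparable
# site counts). X and Y must have equal column counts.
cross_pdist <- function(X, Y, min_sites = 1L) {
  stopifnot(ncol(X) == ncol(Y))
  ia <- base_indicators(X); ib <- base_indicators(Y)
  oka <- Reduce(`+`, ia); okb <- Reduce(`+`, ib)
  sites <- oka %*% t(okb)
  match <- Reduce(`+`, Map(function(a, b) a %*% t(b), ia, ib))
  d <- (sites - match) / sites
  d[sites < min_sites] <- NA_real_
  dimnames(d) <- list(rownames(X), rownames(Y))
  dimnames(sites) <- dimnames(d)
  list(d = d, sites = sites)
}

#' All-pairs p-distance matrix for an alignment
#'
#' @param x An [msa] or a named character vector of equal-length
#'   sequences.
#' @param min_sites Minimum comparable sites per pair; pairs below it are
#'   `NA`. Defaults to 100, suitable for full-length windows; use ~80
#'   for V9-sized fragments.
#' @return A symmetric numeric matrix of class `p_dist` with zero
#'   diagonal, `NA` marking undefined entries, and attributes
#'   `min_sites` and `sites` (comparable-site counts).
#' @export
distance_matrix <- function(x, min_sites = 100L) {
  seqs <- if (inherits(x, "msa")) x$seqs else x
  if (length(seqs) == 0L) stop("empty alignment")
  X <- seq_char_matrix(seqs)
  res <- cross_pdist(X, X, min_sites = min_sites)
  d <- res$d
  diag(d) <- 0
  if (anyNA(d))
    styg_log("WARN", sum(is.na(d[upper.tri(d)])),
             " sequence pair(s) below min_sites=", min_sites,
             " comparable sites; distances undefined")
  structure(d, class = c("p_dist", class(d)),
            min_sites = min_sites, sites = res$sites)
}

#' Intra- and inter-species distance envelopes
#'
#' Summarizes a distance matrix into the per-species maximum
#' intraspecific distance and the per-pair minimum interspecific
#' distance — the two sides of the barcoding gap.
#'
#' @param d Distance matrix from [distance_matrix()].
#' @param species Character vector of species labels, one per matrix
#'   row (names optional; matched by position to matrix ids).
#' @return A list of class `distance_summary` with `max_intra` (named
#'   numeric, singleton species omitted) and `min_inter` (data frame
#'   `species_a`, `species_b`, `min_dist`).
#' @export
summarize_distances <- function(d, species) {
  ids <- rownames(d)
  if (length(species) != nrow(d))
    stop("need one species label per matrix row")
  species <- as.character(species)
  if (all(is.na(species) | species == ""))
    stop("empty species labeling")
  if (anyNA(species) || any(species == ""))
    stop("unlabeled ids: ",
         paste(ids[is.na(species) | species == ""], collapse = ", "))
  sp <- unique(species)
  max_intra <- numeric(0)
  for (s in sp) {
    i <- which(species == s)
    if (length(i) < 2L) next
    v <- d[i, i, drop = FALSE][upper.tri(matrix(0, length(i), length(i)))]
    v <- v[!is.na(v)]
    if (length(v)) max_intra[s] <- max(v)
  }
  pairs <- if (length(sp) >= 2L) utils::combn(sp, 2L) else
    matrix(character(0), nrow = 2)
  min_inter <- data.frame(species_a = character(0),
                          species_b = character(0),
                          min_dist = numeric(0),
                          stringsAsFactors = FALSE)
  if (ncol(pairs)) {
    for (k in seq_len(ncol(pairs))) {
      a <- which(species == pairs[1, k])
      b <- which(species == pairs[2, k])
      v <- d[a, b, drop = FALSE]
      v <- v[!is.na(v)]
      if (!length(v)) next
      min_inter <- rbind(min_inter,
                         data.frame(species_a = pairs[1, k],
                                    species_b = pairs[2, k],
                                    min_dist = min(v),
                                    stringsAsFactors = FALSE))
    }
  }
  structure(list(max_intra = max_intra, min_inter = min_inter),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat("distance summary:", length(x$max_intra), "multi-member species;",
      nrow(x$min_inter), "species pairs\n")
  if (length(x$max_intra))
    cat("  max intraspecific:", format(max(x$max_intra), digits = 4), "\n")
  if (nrow(x$min_inter))
    cat("  min interspecific:", format(min(x$min_inter$min_dist),
                                       digits = 4), "\n")
  invisible(x)
}

#' Write a distance matrix as square TSV (4 decimal places)
#' @param d A `p_dist` matrix.
#' @param path Output path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- formatC(unclass(d), format = "f", digits = 4)
  m[is.na(unclass(d))] <- "NA"
  df <- data.frame(id = rownames(d), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}
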