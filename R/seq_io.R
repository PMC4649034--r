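# Accepted residue alphabet after normalization: canonical bases, gap,
# and IUPAC ambiguity codes (kept verbatim; treated as missing downstream).
DNA_OK <- c("A", "C", "G", "T", "-", "N", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V")

#' Construct a multiple sequence alignment object
#'
#' An `msa` bundles equal-length gapped sequence rows with per-row
#' metadata and a designated anchor row whose ungapped coordinates define
#' analysis windows.
#'
#' @param seqs Named character vector of equal-length, uppercase sequence
#'   strings over the DNA alphabet plus `-` and IUPAC ambiguity codes.
#' @param meta Data frame with columns `id`, `species`, `source`, `count`,
#'   `locality`; one row per sequence. Missing rows are filled with
#'   defaults (`species = NA`, `source = "clone"`, `count = 1`).
#' @param anchor_id Id of the row used as the coordinate anchor.
#' @return An object of class `msa`.
#' @seealso [read_alignment()], [anchor_to_columns()], [extract_window()]
#' @export
msa <- function(seqs, meta = NULL, anchor_id = names(seqs)[1]) {
  if (length(seqs) == 0L) stop("alignment has no sequences")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs[] <- chartr("U.", "T-", toupper(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    bad <- names(seqs)[widths != widths[1]]
    stop("ragged alignment: row(s) ", paste(bad, collapse = ", "),
         " differ in length from row ", names(seqs)[1])
  }
  if (widths[1] == 0L) stop("sequences are empty")
  ok <- vapply(strsplit(unname(seqs), "", fixed = TRUE),
               function(ch) all(ch %in% DNA_OK), logical(1))
  if (!all(ok)) {
    id <- names(seqs)[!ok][1]
    bad <- setdiff(unique(strsplit(seqs[[id]], "")[[1]]), DNA_OK)
    stop("unknown residue character(s) ", paste(bad, collapse = ""),
         " in sequence ", id)
  }
  if (!anchor_id %in% names(seqs))
    stop("anchor id '", anchor_id, "' not present in alignment")
  meta <- normalize_metadata(meta, names(seqs))
  anchor_res <- strsplit(seqs[[anchor_id]], "")[[1]]
  if (!any(anchor_res != "-"))
    stop("anchor row '", anchor_id, "' is all gaps")
  structure(list(seqs = seqs, meta = meta, anchor_id = anchor_id),
            class = "msa")
}

normalize_metadata <- function(meta, ids) {
  template <- data.frame(id = ids, species = NA_character_,
                         source = "clone", count = 1L,
                         locality = NA_character_,
                         stringsAsFactors = FALSE)
  if (is.null(meta)) return(template)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"id" %in% names(meta)) stop("metadata lacks an 'id' column")
  for (col in c("species", "source", "count", "locality"))
    if (!col %in% names(meta)) meta[[col]] <- NA
  if (anyDuplicated(meta$id))
    stop("duplicate ids in metadata: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  idx <- match(ids, meta$id)
  out <- template
  hit <- !is.na(idx)
  out$species[hit] <- as.character(meta$species[idx[hit]])
  src <- as.character(meta$source[idx[hit]])
  src[is.na(src) | src == ""] <- "clone"
  bad_src <- setdiff(src, SOURCE_LEVELS)
  if (length(bad_src))
    stop("unknown source value(s): ", paste(bad_src, collapse = ", "))
  out$source[hit] <- src
  cnt <- suppressWarnings(as.integer(meta$count[idx[hit]]))
  cnt[is.na(cnt)] <- 1L
  if (any(cnt < 0)) stop("negative counts in metadata")
  out$count[hit] <- cnt
  out$locality[hit] <- as.character(meta$locality[idx[hit]])
  out$species[!is.na(out$species) & out$species == ""] <- NA_character_
  styg_log("INFO", "metadata join: ", sum(hit), "/", length(ids),
           " alignment rows matched; ", sum(!hit), " defaulted; ",
           sum(!meta$id %in% ids), " metadata rows unused")
  out
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$seqs), "rows x", nchar(x$seqs[[1]]), "columns;",
      "anchor =", x$anchor_id, "\n")
  invisible(x)
}

#' Read a gapped FASTA alignment with optional metadata
#'
#' Sequences are uppercased and `U` is normalized to `T` on load; `.` is
#' normalized to `-`. Rows absent from the metadata table receive
#' defaults (unlabeled clone, count 1). Join statistics are logged to
#' standard error.
#'
#' @param fasta_path Path to a FASTA file of equal-length gapped rows.
#' @param metadata_path Optional path to a tab-separated table with a
#'   header row and columns `id`, `species`, `source`, `count`,
#'   `locality`. `NULL` applies defaults to every row.
#' @param anchor_id Id of the coordinate anchor row; must occur in the
#'   FASTA.
#' @return An [msa] object.
#' @export
read_alignment <- function(fasta_path, metadata_path = NULL,
                           anchor_id = NULL) {
  set <- Biostrings::readBStringSet(fasta_path)
  if (length(set) == 0L) stop("no sequences in ", fasta_path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  names(seqs) <- ids
  meta <- NULL
  if (!is.null(metadata_path)) {
    meta <- utils::read.delim(metadata_path, sep = "\t",
                              stringsAsFactors = FALSE,
                              colClasses = "character")
  } else {
    styg_log("INFO", "no metadata file; applying defaults to all rows")
  }
  if (is.null(anchor_id)) anchor_id <- ids[1]
  msa(seqs, meta, anchor_id = anchor_id)
}

#' Write an alignment (and optionally its metadata) back to disk
#'
#' @param x An [msa].
#' @param fasta_path Output FASTA path.
#' @param metadata_path Optional output TSV path for the metadata table.
#' @return `x`, invisibly.
#' @export
write_alignment <- function(x, fasta_path, metadata_path = NULL) {
  stopifnot(inherits(x, "msa"))
  set <- Biostrings::BStringSet(x$seqs)
  Biostrings::writeXStringSet(set, fasta_path, width = 80L)
  if (!is.null(metadata_path)) {
    utils::write.table(x$meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(x)
}

#' Define a window on the ungapped anchor sequence
#'
#' Coordinates are 1-based and inclusive on the ungapped anchor, matching
#' the usual convention for rRNA reference positions (e.g. the V9 region
#' spanning anchor positions 1645-1774).
#'
#' @param start,end Integer anchor positions, `1 <= start <= end`.
#' @param name Optional window name used in logs and manifests.
#' @return An object of class `anchor_window`.
#' @export
anchor_window <- function(start, end, name = sprintf("%d-%d", start, end)) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("invalid window: need 1 <= start <= end")
  structure(list(start = start, end = end, name = name),
            class = "anchor_window")
}

# ungapped anchor position -> alignment column lookup (strictly increasing)
anchor_column_map <- function(x) {
  stopifnot(inherits(x, "msa"))
  which(strsplit(x$seqs[[x$anchor_id]], "")[[1]] != "-")
}

#' Map an anchor window to alignment columns
#'
#' Returns the smallest alignment-column interval whose non-gap anchor
#' positions are exactly `window$start..window$end`.
#'
#' @param x An [msa].
#' @param window An [anchor_window()].
#' @return Integer vector `c(start_col, end_col)`, 1-based inclusive.
#' @export
anchor_to_columns <- function(x, window) {
  stopifnot(inherits(window, "anchor_window"))
  map <- anchor_column_map(x)
  if (window$end > length(map))
    stop("window ", window$name, " (", window$start, "-", window$end,
         ") exceeds ungapped anchor length ", length(map))
  c(map[window$start], map[window$end])
}

#' Restrict an alignment to the columns spanned by an anchor window
#'
#' Every row is sliced to the same column interval; metadata and the
#' anchor designation are preserved. Rows that are entirely gaps inside
#' the window are retained but flagged in the log.
#'
#' @inheritParams anchor_to_columns
#' @return An [msa] restricted to the mapped columns.
#' @export
extract_window <- function(x, window) {
  cols <- anchor_to_columns(x, window)
  seqs <- substr(x$seqs, cols[1], cols[2])
  names(seqs) <- names(x$seqs)
  allgap <- !grepl("[^-]", seqs)
  if (any(allgap))
    styg_log("WARN", "rows all-gap in window ", window$name, ": ",
             paste(names(seqs)[allgap], collapse = ", "))
  out <- x
  out$seqs <- seqs
  out
}
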