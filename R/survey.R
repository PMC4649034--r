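# Species x detection-method incidence tables and recovery statistics.

ENV_METHODS <- c("clone", "pyrotag_v4", "pyrotag_v9", "pyrotag_v6v8")

new_survey_table <- function(counts, detected = NULL,
                             column_totals = NULL, universe = NULL) {
  if (is.null(detected)) detected <- !is.na(counts) & counts > 0
  if (is.null(column_totals))
    column_totals <- colSums(counts, na.rm = TRUE)
  if (is.null(universe))
    universe <- setdiff(rownames(counts), "unresolved")
  structure(list(counts = counts, detected = detected,
                 column_totals = column_totals, universe = universe),
            class = "survey_table")
}

# deterministic row order: named species (alphabetical), then ECs by
# numeral, then "unresolved"
order_species_rows <- function(labels) {
  ec <- is_ec_label(labels)
  unres <- labels == "unresolved"
  named <- !ec & !unres
  c(sort(labels[named]), labels[ec][order(ec_number(labels[ec]))],
    labels[unres])
}

#' Tally survey records into a species x method table
#'
#' @param records Data frame with columns `species` (label, EC label, or
#'   `"unresolved"`), `source` (one of culture, clone, pyrotag_v4,
#'   pyrotag_v9, pyrotag_v6v8), and `count` (non-negative integer,
#'   default 1).
#' @return A `survey_table` with a counts matrix (rows ordered: named
#'   species alphabetically, then ECs by numeral, then unresolved), a
#'   detection matrix, per-method column totals, and the default species
#'   universe (all rows except `"unresolved"`).
#' @export
tally <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"count" %in% names(records)) records$count <- 1L
  if (nrow(records)) {
    bad <- setdiff(unique(records$source), SOURCE_LEVELS)
    if (length(bad))
      stop("unknown source value(s): ", paste(bad, collapse = ", "))
    if (any(records$count < 0)) stop("negative counts")
  }
  labels <- order_species_rows(unique(as.character(records$species)))
  counts <- matrix(0L, nrow = length(labels), ncol = length(SOURCE_LEVELS),
                   dimnames = list(labels, SOURCE_LEVELS))
  for (i in seq_len(nrow(records))) {
    counts[records$species[i], records$source[i]] <-
      counts[records$species[i], records$source[i]] +
      as.integer(records$count[i])
  }
  new_survey_table(counts)
}

#' @export
print.survey_table <- function(x, ...) {
  cat("survey_table:", nrow(x$counts), "species/clades x",
      ncol(x$counts), "methods;", sum(x$column_totals), "sequences\n")
  invisible(x)
}

#' Load the packaged literature-survey incidence fixture
#'
#' The fixture encodes the published species-by-method incidence for the
#' Stygiellidae survey: 21 cultured strains across six named species, 83
#' Sanger environmental clones, and 629 pyrotags (V4 = 1, V9 = 572,
#' V6-V8 = 56) across four clone-supported environmental clades plus the
#' V9-only clade EC V and an unresolved pool. Per-cell counts the source
#' study never printed are stored as the marker `NP` (detected, count
#' unknown) and load as `NA` with `detected = TRUE`; printed column
#' totals come from the fixture's TOTAL row. The species universe is the
#' rows with culture or clone support (the ten species-level taxa).
#'
#' @param path Fixture path; defaults to the packaged
#'   `paper_survey.tsv`.
#' @return A `survey_table`.
#' @export
read_survey_fixture <- function(path = system.file("extdata",
                                                   "paper_survey.tsv",
                                                   package = "stygdist")) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  stopifnot(identical(names(raw)[1], "species"),
            identical(names(raw)[-1], SOURCE_LEVELS))
  tot <- raw[raw$species == "TOTAL", -1, drop = FALSE]
  body <- raw[raw$species != "TOTAL", , drop = FALSE]
  cells <- as.matrix(body[, -1, drop = FALSE])
  rownames(cells) <- body$species
  detected <- cells == "NP" | (suppressWarnings(as.numeric(cells)) > 0 &
                                 !is.na(suppressWarnings(as.numeric(cells))))
  counts <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                    dimnames = dimnames(cells)))
  column_totals <- as.numeric(tot[1, ])
  names(column_totals) <- SOURCE_LEVELS
  universe <- rownames(cells)[detected[, "culture"] | detected[, "clone"]]
  new_survey_table(counts, detected = detected,
                   column_totals = column_totals, universe = universe)
}

#' Fraction of the species universe detected by a set of methods
#'
#' @param table A `survey_table`.
#' @param methods Character subset of the five detection methods.
#' @param universe Species labels forming the denominator; defaults to
#'   the table's universe (for the packaged fixture, the ten
#'   species-level taxa with culture or clone support).
#' @return Fraction in `[0, 1]` of universe species detected by at
#'   least one of the given methods.
#' @export
recovery_fraction <- function(table, methods,
                              universe = table$universe) {
  stopifnot(inherits(table, "survey_table"))
  bad <- setdiff(methods, SOURCE_LEVELS)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (length(universe) == 0L) stop("empty species universe")
  det <- table$detected[, methods, drop = FALSE]
  hit <- rownames(det) %in% universe & rowSums(det) > 0
  sum(hit) / length(universe)
}

#' Per-method relative abundances
#'
#' Each column is normalized by the sum of its defined (non-`NA`) cells,
#' so defined fractions in a column sum to 1; cells with unprinted
#' counts and columns with no defined positive mass stay `NA`.
#'
#' @param table A `survey_table`.
#' @return Numeric matrix of fractions, same shape as the counts.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "survey_table"))
  counts <- table$counts
  if (all(is.na(counts) | counts == 0))
    stop("no nonzero column in survey table")
  out <- counts * NA_real_
  for (m in colnames(counts)) {
    s <- sum(counts[, m], na.rm = TRUE)
    if (s > 0) out[, m] <- counts[, m] / s
    else styg_log("WARN", "column ", m,
                  " has no defined positive counts; fractions undefined")
  }
  out
}

#' Render a survey table as a plain-text heat map
#'
#' Cells are binned by relative abundance within each method column:
#' `.` <1%, `-` <10%, `+` <50%, `#` >=50%, blank undetected, `?`
#' detected with unprinted count.
#'
#' @param table A `survey_table`.
#' @return Character vector of lines.
#' @export
format_survey <- function(table) {
  ra <- suppressMessages(relative_abundance(table))
  sym <- matrix(" ", nrow(ra), ncol(ra), dimnames = dimnames(ra))
  sym[table$detected] <- "?"
  def <- !is.na(ra)
  sym[def & ra < 0.01] <- "."
  sym[def & ra >= 0.01 & ra < 0.10] <- "-"
  sym[def & ra >= 0.10 & ra < 0.50] <- "+"
  sym[def & ra >= 0.50] <- "#"
  sym[def & ra == 0] <- " "
  w <- max(nchar(rownames(ra)))
  header <- sprintf(paste0("%-", w, "s  %s"), "species",
                    paste(sprintf("%-12s", colnames(ra)), collapse = ""))
  rows <- vapply(seq_len(nrow(ra)), function(i) {
    sprintf(paste0("%-", w, "s  %s"), rownames(ra)[i],
            paste(sprintf("%-12s", sym[i, ]), collapse = ""))
  }, character(1))
  c(header, rows)
}

#' Write a survey table (counts plus totals) as TSV
#' @param table A `survey_table`.
#' @param path Output path.
#' @export
write_survey <- function(table, path) {
  m <- table$counts
  out <- data.frame(species = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  tot <- c(species = "TOTAL", as.list(table$column_totals))
  out <- rbind(out, as.data.frame(tot, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NP")
  invisible(table)
}
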