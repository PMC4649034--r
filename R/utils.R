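# internal helpers shared across modules

SOURCE_LEVELS <- c("culture", "clone", "pyrotag_v4", "pyrotag_v9", "pyrotag_v6v8")

# leveled logging to stderr; suppress with options(stygdist.quiet = TRUE)
styg_log <- function(level, ...) {
  if (isTRUE(getOption("stygdist.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s", level, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# roman-numeral environmental-clade labels: "EC I", "EC II", ...
ec_label <- function(i) paste("EC", as.character(utils::as.roman(i)))

is_ec_label <- function(x) grepl("^EC [IVXLCDM]+$", x)

ec_number <- function(x) {
  n <- rep(NA_integer_, length(x))
  ec <- is_ec_label(x)
  n[ec] <- as.integer(utils::as.roman(sub("^EC ", "", x[ec])))
  n
}

# split equal-length sequence strings into an n x L character matrix
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}
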