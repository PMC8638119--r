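#' @keywords internal
"_PACKAGE"

# The seven local alternative-splicing event types, in canonical order.
EVENT_TYPES <- c("SE", "MX", "A5", "A3", "RI", "AF", "AL")

#' Canonical event type levels
#'
#' Returns the seven local alternative-splicing event type labels in their
#' canonical order: skipped exon (SE), mutually exclusive exons (MX),
#' alternative 5' splice site (A5), alternative 3' splice site (A3),
#' retained intron (RI), alternative first exon (AF), alternative last
#' exon (AL).
#'
#' @return Character vector of length 7.
#' @export
event_types <- function() EVENT_TYPES

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Derive a reproducible stage seed from a master seed
#'
#' Stages of the pipeline draw their randomness from seeds derived
#' deterministically from one master seed and the stage name, so any stage
#' can be rerun in isolation with identical results.
#'
#' @param seed Integer master seed.
#' @param label Character label (e.g. a stage name).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147480009
  as.integer((abs(seed) + h) %% 2147480009)
}

# Write a data.frame as TSV atomically (tmp file + rename), with optional
# "# " comment header lines. Missing values serialize as "NA".
write_tsv <- function(df, path, comments = character()) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "wt")
  open_flag <- TRUE
  on.exit(if (open_flag) close(con), add = TRUE)
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  close(con); open_flag <- FALSE
  if (!file.rename(tmp, path)) stop2("could not write ", path)
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop2("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# Matrix (features x samples) <-> TSV with a leading id column.
write_matrix_tsv <- function(mat, path, id_col, comments = character()) {
  df <- data.frame(rownames(mat), as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path, comments)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) stop2("matrix TSV needs an id column plus >=1 sample: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}
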