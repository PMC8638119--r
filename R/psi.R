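#' Compute percent-spliced-in (PSI) from transcript TPM abundances
#'
#' For each event and sample, PSI is the summed TPM of the event's
#' inclusion transcripts divided by the summed TPM of its total transcript
#' set. Events whose total-form TPM falls below `min_total_tpm` in a sample
#' are reported as missing (`NA`) rather than as an unstable ratio; this
#' mirrors the expression floor that PSI tools apply before quantifying an
#' event.
#'
#' @param catalog An [event_catalog].
#' @param tpm Numeric matrix of transcript TPMs (transcripts x samples) with
#'   transcript ids as rownames; all values finite and >= 0.
#' @param min_total_tpm Minimum total-form TPM below which PSI is `NA`
#'   (default 1 TPM).
#' @return A `psi_matrix`: numeric matrix (events x samples) of values in
#'   `[0,1]` or `NA`, with attribute `event_type` giving each row's type.
#' @export
compute_psi <- function(catalog, tpm, min_total_tpm = 1) {
  stopifnot(is.matrix(tpm), min_total_tpm >= 0)
  if (any(!is.finite(tpm)) || any(tpm < 0))
    stop2("tpm must be finite and non-negative")
  if (anyDuplicated(rownames(tpm)))
    stop2("duplicate transcript ids in abundance matrix")
  n_ev <- nrow(catalog)
  psi <- matrix(NA_real_, n_ev, ncol(tpm),
                dimnames = list(catalog$event_id, colnames(tpm)))
  for (i in seq_len(n_ev)) {
    incl <- split_ids(catalog$inclusion_transcripts[i])
    tot <- split_ids(catalog$total_transcripts[i])
    missing_tx <- setdiff(tot, rownames(tpm))
    if (length(missing_tx) > 0L)
      stop2("event ", catalog$event_id[i], " references unknown transcript(s): ",
            paste(missing_tx, collapse = ", "))
    s_in <- colSums(tpm[incl, , drop = FALSE])
    s_tot <- colSums(tpm[tot, , drop = FALSE])
    v <- s_in / s_tot
    v[s_tot < min_total_tpm | s_tot == 0] <- NA_real_
    psi[i, ] <- v
  }
  structure(psi, event_type = stats::setNames(catalog$event_type,
                                              catalog$event_id),
            class = c("psi_matrix", class(psi)))
}

#' Filter events by missingness
#'
#' Keeps events whose fraction of missing (`NA`) PSI entries does not
#' exceed `max_missing_frac`; row order is preserved. Missing values are
#' never imputed — they propagate into downstream tests.
#'
#' @param psi A `psi_matrix` (events x samples).
#' @param max_missing_frac Maximum tolerated fraction of `NA` entries per
#'   event, in `[0,1]` (default 0.2).
#' @return The filtered `psi_matrix`.
#' @export
filter_psi <- function(psi, max_missing_frac = 0.2) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  keep <- rowMeans(is.na(psi)) <= max_missing_frac
  out <- psi[keep, , drop = FALSE]
  et <- attr(psi, "event_type")
  if (!is.null(et)) attr(out, "event_type") <- et[rownames(out)]
  class(out) <- class(psi)
  out
}

#' Read/write PSI and abundance matrices as TSV
#'
#' Rows are events (or transcripts), columns samples; missing PSI values
#' are serialized as `NA`.
#'
#' @param psi,mat Numeric matrix with rownames.
#' @param path TSV path.
#' @return The matrix (readers) or `path` invisibly (writers).
#' @export
write_psi_matrix <- function(psi, path) {
  write_matrix_tsv(psi, path, "event_id",
                   comments = "PSI (unitless, in [0,1]); NA = under-expressed event")
}

#' @rdname write_psi_matrix
#' @export
read_psi_matrix <- function(path) {
  m <- read_matrix_tsv(path)
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop2("PSI values outside [0,1] in ", path)
  structure(m, class = c("psi_matrix", class(m)))
}

#' @rdname write_psi_matrix
#' @export
write_abundance <- function(mat, path) {
  write_matrix_tsv(mat, path, "transcript_id",
                   comments = "transcript abundance (TPM)")
}

#' @rdname write_psi_matrix
#' @export
read_abundance <- function(path) {
  m <- read_matrix_tsv(path)
  if (any(!is.finite(m)) || any(m < 0))
    stop2("abundances must be finite and non-negative: ", path)
  m
}
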