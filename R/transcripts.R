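#' Transcript models
#'
#' A `transcript_models` object is a list of transcripts, each a list with
#' fields `gene_id`, `transcript_id`, `chrom`, `strand` ("+" or "-") and
#' `exons`, a two-column integer matrix (`start`, `end`) of 1-based inclusive
#' genomic intervals sorted by start. Exons within a transcript must be
#' pairwise non-overlapping and share chromosome and strand.
#'
#' @param transcripts List of transcript lists as described above.
#' @return A validated `transcript_models` object.
#' @export
transcript_models <- function(transcripts) {
  obj <- structure(transcripts, class = "transcript_models")
  validate_transcripts(obj)
  obj
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", length(x), "transcripts,",
      length(unique(vapply(x, `[[`, "", "gene_id"))), "genes\n")
  invisible(x)
}

validate_transcripts <- function(models) {
  for (tx in models) {
    id <- tx$transcript_id %||% "<unnamed>"
    ex <- tx$exons
    if (!is.matrix(ex) || ncol(ex) != 2L || nrow(ex) < 1L)
      stop2("transcript ", id, ": exons must be a start/end matrix")
    if (any(ex[, 1] > ex[, 2]))
      stop2("transcript ", id, ": exon start > end")
    if (is.unsorted(ex[, 1], strictly = FALSE))
      stop2("transcript ", id, ": exons not sorted by start")
    if (nrow(ex) > 1L && any(ex[-1L, 1] <= ex[-nrow(ex), 2]))
      stop2("transcript ", id, ": overlapping exons")
    if (!tx$strand %in% c("+", "-"))
      stop2("transcript ", id, ": strand must be '+' or '-'")
  }
  invisible(TRUE)
}

#' Read transcript models from a GTF file
#'
#' Parses exon features from a GTF annotation (1-based inclusive
#' coordinates) into one [transcript_models] entry per `transcript_id`,
#' with exons sorted by start. Lines that do not have the 9 tab-separated
#' GTF fields raise a parse error naming the line number; exon records
#' lacking `gene_id` or `transcript_id`, and transcripts whose exons
#' disagree on chromosome or strand, raise validation errors naming the
#' transcript.
#'
#' @param path Path to a GTF file.
#' @return A `transcript_models` object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  raw <- readLines(path)
  body <- !grepl("^\\s*(#|$)", raw)
  nf <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1]]
    stop2("malformed GTF line ", bad, " in ", path,
          ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf", feature.type = "exon")
  if (length(gr) == 0L) stop2("no exon features found in ", path)
  md <- S4Vectors::mcols(gr)
  tx_id <- as.character(md$transcript_id)
  gene_id <- as.character(md$gene_id)
  if (is.null(md$transcript_id) || anyNA(tx_id))
    stop2("exon feature without transcript_id in ", path)
  if (is.null(md$gene_id) || anyNA(gene_id))
    stop2("exon feature without gene_id in ", path)
  df <- data.frame(
    gene_id = gene_id, transcript_id = tx_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE)
  models <- lapply(split(df, df$transcript_id), function(d) {
    if (length(unique(d$chrom)) != 1L || length(unique(d$strand)) != 1L)
      stop2("transcript ", d$transcript_id[1],
            ": exons with inconsistent chrom/strand")
    if (any(d$strand == "*"))
      stop2("transcript ", d$transcript_id[1], ": missing strand")
    d <- d[order(d$start), , drop = FALSE]
    list(gene_id = d$gene_id[1], transcript_id = d$transcript_id[1],
         chrom = d$chrom[1], strand = d$strand[1],
         exons = cbind(start = d$start, end = d$end))
  })
  models <- models[order(names(models))]
  transcript_models(unname(models))
}

#' Write transcript models to a GTF file
#'
#' Emits one `exon` feature line per exon, carrying `gene_id` and
#' `transcript_id` attributes; the inverse of [read_gtf()].
#'
#' @param models A `transcript_models` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(tx) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$gene_id, tx$transcript_id)
    sprintf("%s\tspliceStrata\texon\t%d\t%d\t.\t%s\t.\t%s",
            tx$chrom, tx$exons[, 1], tx$exons[, 2], tx$strand, attrs)
  }))
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop2("could not write ", path)
  invisible(path)
}

# Transcription-order ("tx-space") coordinates: for "+" strand the identity,
# for "-" strand x -> -x with start/end swapped, so that 5'->3' always runs
# in increasing coordinates. Event detection operates entirely in tx-space;
# signatures are mapped back to genomic coordinates afterwards.
tx_space_exons <- function(tx) {
  ex <- tx$exons
  if (tx$strand == "+") {
    cbind(start = ex[, 1], end = ex[, 2])
  } else {
    m <- cbind(start = -ex[, 2], end = -ex[, 1])
    m[order(m[, 1]), , drop = FALSE]
  }
}

# Map a tx-space coordinate back to genomic.
genomic_coord <- function(x, strand) if (strand == "+") x else -x
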