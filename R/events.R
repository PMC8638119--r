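#' Local alternative-splicing event catalogs
#'
#' An `event_catalog` is a data.frame with one row per local
#' alternative-splicing event and columns `event_id`, `gene_id`,
#' `event_type` (one of `r paste(EVENT_TYPES, collapse = ", ")`),
#' `inclusion_transcripts` and `total_transcripts` (comma-joined transcript
#' id sets) and `defining_coords` (the splice-site coordinate signature).
#' The inclusion set is always a non-empty proper subset of the total set:
#' PSI is the inclusion-form share of the total-form abundance.
#'
#' @name event_catalog
NULL

new_event_catalog <- function(df) {
  df <- df[order(df$gene_id, match(df$event_type, EVENT_TYPES),
                 df$defining_coords), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("event_catalog", "data.frame"))
}

split_ids <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]

#' Detect local alternative-splicing events from transcript models
#'
#' Compares the isoforms of each gene pairwise and emits every supported
#' local event, classified into the seven canonical types. Detection is
#' strand-aware: exons are mapped into transcription order, so an
#' alternative 5' splice site on the minus strand (which looks like an
#' alternative 3' site in plus-strand coordinates) is labelled A5, and the
#' first/last-exon types follow transcription order likewise.
#'
#' Pattern rules ("upstream"/"downstream" in transcription order; a
#' junction is a (donor end, acceptor start) pair):
#' \describe{
#'   \item{SE}{one form uses the junction chain (d1,a1),(d2,a2), the other
#'     the skip junction (d1,a2); inclusion = exon-containing form.}
#'   \item{MX}{two non-overlapping middle exons between shared flanking
#'     junction endpoints, each exclusive to one form; inclusion = form
#'     whose middle exon is 5'-most in transcription order.}
#'   \item{A5}{shared acceptor, two donors from overlapping upstream exons;
#'     inclusion = longer-exon (proximal-intron) form.}
#'   \item{A3}{shared donor, two acceptors from overlapping downstream
#'     exons; inclusion = longer-exon form.}
#'   \item{RI}{a single exon spanning exactly two exons plus the intervening
#'     intron of another form; inclusion = intron-retaining form.}
#'   \item{AF/AL}{distinct non-overlapping first (last) exons joined to a
#'     common acceptor (from a common donor); inclusion = form whose
#'     first (last) exon is 5'-most in transcription order.}
#' }
#'
#' Events are deduplicated by coordinate signature; all transcripts
#' compatible with a form are pooled into that form's set. Output rows are
#' sorted by (gene_id, event_type, defining_coords), so repeated runs are
#' byte-identical.
#'
#' @param models A [transcript_models] object (or plain list of transcripts).
#' @return An [event_catalog] data.frame (zero rows if no events).
#' @export
detect_events <- function(models) {
  validate_transcripts(models)
  gene_ids <- vapply(models, `[[`, "", "gene_id")
  rows <- lapply(split(seq_along(models), gene_ids), function(idx) {
    detect_gene_events(models[idx])
  })
  rows <- Filter(Negate(is.null), rows[order(names(rows))])
  df <- if (length(rows) > 0L)
    do.call(rbind, c(rows, make.row.names = FALSE)) else NULL
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(event_id = character(), gene_id = character(),
                     event_type = character(),
                     inclusion_transcripts = character(),
                     total_transcripts = character(),
                     defining_coords = character(),
                     stringsAsFactors = FALSE)
  }
  new_event_catalog(df)
}

# Event detection within one gene, in transcription-order coordinate space.
detect_gene_events <- function(txs) {
  gene_id <- txs[[1]]$gene_id
  if (length(txs) < 2L) return(NULL)
  strand <- unique(vapply(txs, `[[`, "", "strand"))
  chrom <- unique(vapply(txs, `[[`, "", "chrom"))
  if (length(strand) != 1L || length(chrom) != 1L)
    stop2("gene ", gene_id, ": transcripts with inconsistent chrom/strand")
  ids <- vapply(txs, `[[`, "", "transcript_id")
  E <- lapply(txs, tx_space_exons)

  key <- function(...) paste(..., sep = "|")
  intron_map <- list()   # "d|a" -> tx indices
  intron_info <- list()  # "d|a" -> upstream/downstream exon facts
  pair_map <- list()     # "d1|a1|d2|a2" -> tx indices (consecutive introns)
  exon_map <- list()     # "s|e" -> tx indices
  ri_map <- list()       # "s|d|a|e" -> tx indices (spliced form of an RI)

  for (i in seq_along(txs)) {
    ex <- E[[i]]
    k <- nrow(ex)
    if (k < 2L) {
      kk <- key(ex[1, 1], ex[1, 2])
      exon_map[[kk]] <- c(exon_map[[kk]], i)
      next
    }
    for (j in seq_len(k)) {
      kk <- key(ex[j, 1], ex[j, 2])
      exon_map[[kk]] <- c(exon_map[[kk]], i)
    }
    d <- ex[seq_len(k - 1L), 2]
    a <- ex[seq_len(k - 1L) + 1L, 1]
    for (j in seq_len(k - 1L)) {
      kk <- key(d[j], a[j])
      intron_map[[kk]] <- c(intron_map[[kk]], i)
      info <- intron_info[[kk]] %||%
        list(d = d[j], a = a[j], up_start = Inf, up_first = TRUE,
             down_end = -Inf, down_last = TRUE)
      info$up_start <- min(info$up_start, ex[j, 1])
      info$up_first <- info$up_first && (j == 1L)
      info$down_end <- max(info$down_end, ex[j + 1L, 2])
      info$down_last <- info$down_last && (j + 1L == k)
      intron_info[[kk]] <- info
      rk <- key(ex[j, 1], d[j], a[j], ex[j + 1L, 2])
      ri_map[[rk]] <- c(ri_map[[rk]], i)
    }
    if (k >= 3L) for (j in seq_len(k - 2L)) {
      pk <- key(d[j], a[j], d[j + 1L], a[j + 1L])
      pair_map[[pk]] <- c(pair_map[[pk]], i)
    }
  }

  events <- list()
  gcoords <- function(v) {
    g <- sort(vapply(v, genomic_coord, 0, strand = strand))
    paste(g, collapse = "-")
  }
  emit <- function(type, coords, incl, excl) {
    incl <- sort(unique(ids[incl])); excl <- sort(unique(ids[excl]))
    excl <- setdiff(excl, incl)
    if (length(incl) == 0L || length(excl) == 0L) return()
    sig <- gcoords(coords)
    eid <- sprintf("%s;%s:%s:%s:%s", gene_id, type, chrom, sig, strand)
    events[[eid]] <<- data.frame(
      event_id = eid, gene_id = gene_id, event_type = type,
      inclusion_transcripts = paste(incl, collapse = ","),
      total_transcripts = paste(sort(c(incl, excl)), collapse = ","),
      defining_coords = sig, stringsAsFactors = FALSE)
  }

  # SE: inclusion junction chain vs skip junction with the same flanks.
  for (pk in names(pair_map)) {
    p <- as.numeric(strsplit(pk, "|", fixed = TRUE)[[1]])
    skip <- intron_map[[key(p[1], p[4])]]
    if (!is.null(skip))
      emit("SE", p, incl = pair_map[[pk]], excl = skip)
  }

  # MX: two junction chains sharing outer endpoints, middle exons disjoint.
  pks <- names(pair_map)
  if (length(pks) >= 2L) {
    pm <- do.call(rbind, lapply(pks, function(x)
      as.numeric(strsplit(x, "|", fixed = TRUE)[[1]])))
    for (u in seq_len(length(pks) - 1L)) for (v in (u + 1L):length(pks)) {
      p1 <- pm[u, ]; p2 <- pm[v, ]
      if (p1[1] != p2[1] || p1[4] != p2[4]) next
      if (p1[2] > p2[2]) { tmp <- p1; p1 <- p2; p2 <- tmp }
      if (p1[3] >= p2[2]) next        # middle exons must not overlap
      emit("MX", c(p1, p2[2], p2[3]),
           incl = pair_map[[key(p1[1], p1[2], p1[3], p1[4])]],
           excl = pair_map[[key(p2[1], p2[2], p2[3], p2[4])]])
    }
  }

  # RI: single exon spanning exactly an exon-intron-exon triple.
  for (rk in names(ri_map)) {
    r <- as.numeric(strsplit(rk, "|", fixed = TRUE)[[1]])
    ret <- exon_map[[key(r[1], r[4])]]
    if (!is.null(ret))
      emit("RI", r, incl = ret, excl = ri_map[[rk]])
  }

  # A5/AF (shared acceptor) and A3/AL (shared donor).
  if (length(intron_info) > 0L) {
    im <- data.frame(
      k = names(intron_info),
      d = vapply(intron_info, `[[`, 0, "d"),
      a = vapply(intron_info, `[[`, 0, "a"), stringsAsFactors = FALSE)
    for (aa in unique(im$a[duplicated(im$a)])) {
      ks <- im$k[im$a == aa]
      ds <- im$d[im$a == aa]
      o <- order(ds); ks <- ks[o]; ds <- ds[o]
      for (u in seq_len(length(ks) - 1L)) for (v in (u + 1L):length(ks)) {
        i1 <- intron_info[[ks[u]]]; i2 <- intron_info[[ks[v]]]
        overlap <- i2$up_start <= i1$d   # shorter-intron exon reaches past d1
        if (overlap) {
          emit("A5", c(i1$d, i2$d, aa),
               incl = intron_map[[ks[v]]], excl = intron_map[[ks[u]]])
        } else if (i1$up_first && i2$up_first) {
          emit("AF", c(i1$up_start, i1$d, i2$up_start, i2$d, aa),
               incl = intron_map[[ks[u]]], excl = intron_map[[ks[v]]])
        }
      }
    }
    for (dd in unique(im$d[duplicated(im$d)])) {
      ks <- im$k[im$d == dd]
      as_ <- im$a[im$d == dd]
      o <- order(as_); ks <- ks[o]; as_ <- as_[o]
      for (u in seq_len(length(ks) - 1L)) for (v in (u + 1L):length(ks)) {
        i1 <- intron_info[[ks[u]]]; i2 <- intron_info[[ks[v]]]
        overlap <- i1$down_end >= i2$a  # longer exon reaches past a2
        if (overlap) {
          emit("A3", c(dd, i1$a, i2$a),
               incl = intron_map[[ks[u]]], excl = intron_map[[ks[v]]])
        } else if (i1$down_last && i2$down_last) {
          emit("AL", c(dd, i1$a, i1$down_end, i2$a, i2$down_end),
               incl = intron_map[[ks[u]]], excl = intron_map[[ks[v]]])
        }
      }
    }
  }

  if (length(events) == 0L) return(NULL)
  do.call(rbind, c(unname(events), make.row.names = FALSE))
}

#' Write an event catalog to TSV
#'
#' Column layout follows the ioe-style "event to inclusion/total
#' transcripts" table: `event_id`, `gene_id`, `event_type`,
#' `inclusion_transcripts`, `total_transcripts` (comma-joined),
#' `defining_coords`. Round-trips through [read_event_catalog()].
#'
#' @param catalog An [event_catalog].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_event_catalog <- function(catalog, path) {
  write_tsv(as.data.frame(catalog), path,
            comments = "event catalog: inclusion/total transcript sets per local AS event")
}

#' Read an event catalog from TSV
#'
#' @param path Path written by [write_event_catalog()].
#' @return An [event_catalog].
#' @export
read_event_catalog <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  need <- c("event_id", "gene_id", "event_type", "inclusion_transcripts",
            "total_transcripts")
  if (!all(need %in% names(df)))
    stop2("event catalog ", path, " lacks columns: ",
          paste(setdiff(need, names(df)), collapse = ", "))
  bad <- setdiff(unique(df$event_type), EVENT_TYPES)
  if (length(bad) > 0L)
    stop2("unknown event_type token(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$event_id))
    stop2("duplicate event_id in ", path)
  if (is.null(df$defining_coords))
    df$defining_coords <- sub("^[^;]*;[A-Z0-9]+:[^:]+:", "",
                              sub(":[+-]$", "", df$event_id))
  new_event_catalog(df)
}
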