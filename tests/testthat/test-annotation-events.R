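test_that("read_gtf maps exon records to sorted transcript models", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    gtf)
  models <- read_gtf(gtf)
  expect_length(models, 1L)
  expect_identical(models[[1]]$exons,
                   cbind(start = c(101L, 301L), end = c(200L, 400L)))
  expect_identical(models[[1]]$gene_id, "g1")

  # out-of-order input equals sorted input
  gtf2 <- tempfile(fileext = ".gtf")
  writeLines(rev(readLines(gtf)), gtf2)
  expect_identical(unclass(read_gtf(gtf2)), unclass(models))
})

test_that("read_gtf enforces its contracts", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1\tbroken line without nine fields"), bad)
  expect_error(read_gtf(bad), "line 2")

  noid <- tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1";', noid)
  expect_error(read_gtf(noid), "transcript_id")

  mixed <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t-\t.\tgene_id "g1"; transcript_id "t1";'),
    mixed)
  expect_error(read_gtf(mixed), "t1")

  expect_error(read_gtf(tempfile()), "not found")
})

test_that("detect_events finds the canonical SE case and nothing else", {
  cat <- detect_events(se_gene())
  expect_equal(nrow(cat), 1L)
  expect_identical(cat$event_type, "SE")
  expect_identical(cat$inclusion_transcripts, "G1.t1")
  expect_identical(cat$total_transcripts, "G1.t1,G1.t2")

  # single-isoform gene: no events
  single <- transcript_models(list(
    make_tx("G2", "G2.t1", c(1, 100, 201, 300))))
  expect_equal(nrow(detect_events(single)), 0L)
})

test_that("detect_events rejects transcripts with overlapping exons", {
  bad <- list(make_tx("G1", "t1", c(101, 300, 200, 400)),
              make_tx("G1", "t2", c(101, 200, 301, 400)))
  expect_error(detect_events(bad), "overlapping")
})

test_that("an engineered annotation yields one event of each of the 7 types", {
  ann <- generate_annotation(cohort_spec(events_per_type = 1))
  cat <- detect_events(ann$models)
  expect_equal(nrow(cat), 7L)
  expect_setequal(cat$event_type, event_types())
  # ground-truth identity: detection reproduces the planted catalog exactly
  expect_identical(as.data.frame(cat), as.data.frame(ann$truth))
})

test_that("minus-strand alternative splice sites classify in transcription order", {
  # on the minus strand this donor-side pattern looks like an A3 in
  # plus-strand coordinates
  a5_minus <- transcript_models(list(
    make_tx("G1", "G1.t1", c(101, 200, 501, 600), strand = "-"),
    make_tx("G1", "G1.t2", c(101, 200, 451, 600), strand = "-")))
  expect_identical(detect_events(a5_minus)$event_type, "A5")
  # oracle: the same coordinates read as plus strand are an A3
  expect_identical(detect_events(flip_strand_models(a5_minus))$event_type,
                   "A3")
})

test_that("strand flipping swaps A5<->A3, AF<->AL and preserves SE/MX/RI", {
  ann <- generate_annotation(cohort_spec(events_per_type = 3))
  fwd <- table(detect_events(ann$models)$event_type)
  rev_ <- table(detect_events(flip_strand_models(ann$models))$event_type)
  swap <- c(SE = "SE", MX = "MX", RI = "RI",
            A5 = "A3", A3 = "A5", AF = "AL", AL = "AF")
  for (ty in event_types())
    expect_identical(unname(fwd[ty]), unname(rev_[swap[ty]]))
})

test_that("detection output is deterministic and sorted", {
  ann <- generate_annotation(cohort_spec(events_per_type = 2))
  c1 <- detect_events(ann$models)
  c2 <- detect_events(ann$models)
  expect_identical(c1, c2)
  key <- paste(c1$gene_id, match(c1$event_type, event_types()),
               c1$defining_coords)
  expect_false(is.unsorted(order(key)))
  expect_false(anyDuplicated(c1$event_id) > 0)
})

test_that("event catalogs round-trip through TSV", {
  ann <- generate_annotation(cohort_spec(events_per_type = 2))
  cat <- detect_events(ann$models)
  p <- tempfile(fileext = ".tsv")
  write_event_catalog(cat, p)
  expect_identical(as.data.frame(read_event_catalog(p)), as.data.frame(cat))

  # empty catalog: header-only body
  empty <- detect_events(transcript_models(list(
    make_tx("G1", "t1", c(1, 50)))))
  p2 <- tempfile(fileext = ".tsv")
  write_event_catalog(empty, p2)
  expect_equal(nrow(read_event_catalog(p2)), 0L)

  bad <- read_tsv_df <- utils::read.delim(p, comment.char = "#")
  bad$event_type[1] <- "XX"
  p3 <- tempfile(fileext = ".tsv")
  utils::write.table(bad, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_event_catalog(p3), "XX")
})
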