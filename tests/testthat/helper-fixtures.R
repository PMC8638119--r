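# Shared fixture builders and independent oracles for the test suite.

make_tx <- function(gene, id, exons, strand = "+", chrom = "chr1") {
  list(gene_id = gene, transcript_id = id, chrom = chrom, strand = strand,
       exons = matrix(exons, ncol = 2, byrow = TRUE,
                      dimnames = list(NULL, c("start", "end"))))
}

# A gene with an exon-skipping pattern: t1 = e1,e2,e3; t2 = e1,e3.
se_gene <- function(gene = "G1", strand = "+") {
  transcript_models(list(
    make_tx(gene, paste0(gene, ".t1"),
            c(101, 200, 301, 400, 501, 600), strand),
    make_tx(gene, paste0(gene, ".t2"), c(101, 200, 501, 600), strand)))
}

# Flip the strand label of every transcript while keeping coordinates.
# Reading the same splice sites in the opposite transcription order must
# swap A5<->A3 and AF<->AL while preserving SE/MX/RI counts.
flip_strand_models <- function(models) {
  out <- lapply(models, function(tx) {
    tx$strand <- if (tx$strand == "+") "-" else "+"
    tx
  })
  transcript_models(out)
}

# Exact two-sided permutation p-value for the Mann-Whitney U statistic
# (all label assignments enumerated; independent of rank_sum_test).
perm_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (n - n1) / 2
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  sets <- utils::combn(n, n1)
  us <- apply(sets, 2, u_of)
  mean(abs(us - mu) >= obs - 1e-12)
}

# Small, fast pipeline configuration for smoke tests.
small_pipeline_cfg <- function(outdir, seed = 5L) {
  pipeline_config(outdir = outdir, overrides = list(
    seed = seed, n_samples = 40L, n_genes = 60L, events_per_type = 2L,
    min_per_group = 3L))
}
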