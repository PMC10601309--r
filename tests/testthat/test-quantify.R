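worked_gene <- tibble::tibble(
  gene_id = "gA", chrom = "chr1", start = 1000L, end = 3000L,
  strand = "+", tss = 1000L
)

test_that("gene-body counting applies strand, pause and TRE exclusions", {
  reads <- tibble::tibble(
    chrom = "chr1",
    position = c(1050L, 1200L, 1200L, 1550L),
    strand = c("+", "+", "-", "+"),
    count = 1L
  )
  tres <- tibble::tibble(chrom = "chr1", start = 1500L, end = 1600L)
  out <- count_gene_body(reads, worked_gene, tres)
  # 1050 is inside [tss, tss+150) -> excluded; 1200 antisense -> excluded;
  # 1550 inside the TRE -> excluded; only sense 1200 remains
  expect_equal(out$sample1, 1)

  # a 900 b gene is absent from the output entirely
  short_gene <- worked_gene
  short_gene$gene_id <- "gShort"
  short_gene$end <- 1900L
  both <- dplyr::bind_rows(worked_gene, short_gene)
  out2 <- count_gene_body(reads, both, tres)
  expect_identical(out2$gene_id, "gA")

  # no reads -> zero counts for all surviving genes
  none <- reads[0, ]
  out3 <- count_gene_body(none, worked_gene, tres)
  expect_equal(out3$sample1, 0)

  # minus-strand pause window sits upstream in coordinates
  neg_gene <- tibble::tibble(gene_id = "gB", chrom = "chr1", start = 5000L,
                             end = 7000L, strand = "-", tss = 6999L)
  neg_reads <- tibble::tibble(
    chrom = "chr1", position = c(6999L, 6850L, 6849L, 5000L), strand = "-",
    count = 1L
  )
  out4 <- count_gene_body(neg_reads, neg_gene, NULL)
  expect_equal(out4$sample1, 2) # 6999 and 6850 fall in the pause window

  expect_warning(
    count_gene_body(
      tibble::tibble(chrom = "chrUn", position = 1L, strand = "+", count = 1L),
      worked_gene, NULL
    ),
    "unknown chromosome"
  )
  bad <- worked_gene
  bad$tss <- 4000L
  expect_error(count_gene_body(reads, bad, NULL), "tss outside")
})

test_that("gene-body and miRNA counting match the brute-force scanner", {
  for (seed in 1:60) {
    inst <- random_count_instance(seed)
    # instances may place all genes on one chromosome; the unknown-chromosome
    # warning is exercised separately above
    got <- suppressWarnings(
      count_gene_body(inst$reads, inst$genes, inst$tres, inst$params)
    )
    want <- oracle_count_gene_body(inst$reads, inst$genes, inst$tres,
                                   inst$params)
    expect_equal(
      as_long_counts(got),
      as_long_counts(ptseq:::matrix_to_count_table(want, "gene_id")),
      info = paste("gene instance", seed)
    )
    mir <- inst$genes[, c("chrom", "start", "end", "strand")]
    mir$mirna <- inst$genes$gene_id
    mir$end <- mir$start + 22L
    got_m <- suppressWarnings(count_mirna_locus(inst$reads, mir, inst$params))
    want_m <- oracle_count_mirna(inst$reads, mir, inst$params)
    expect_equal(
      as_long_counts(got_m),
      as_long_counts(ptseq:::matrix_to_count_table(want_m, "mirna")),
      info = paste("miRNA instance", seed)
    )
  }
})

test_that("counting is invariant to record order, splitting and inert TREs", {
  inst <- random_count_instance(101)
  base <- count_gene_body(inst$reads, inst$genes, inst$tres, inst$params)

  shuffled <- inst$reads[withr::with_seed(1, sample.int(nrow(inst$reads))), ]
  expect_equal(count_gene_body(shuffled, inst$genes, inst$tres, inst$params),
               base)

  split <- inst$reads[rep(seq_len(nrow(inst$reads)), inst$reads$count), ]
  split$count <- 1L
  expect_equal(count_gene_body(split, inst$genes, inst$tres, inst$params),
               base)

  # a TRE overlapping no gene body never changes counts
  inert <- dplyr::bind_rows(
    inst$tres,
    tibble::tibble(chrom = "chr1", start = 880000L, end = 880100L)
  )
  expect_equal(count_gene_body(inst$reads, inst$genes, inert, inst$params),
               base)
})

test_that("TPM normalization matches the closed form", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1", start = c(0L, 5000L),
    end = c(1000L, 7000L), strand = "+", tss = c(0L, 5000L)
  )
  counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(10, 10))
  tpm <- tpm_normalize(counts, genes)
  expect_equal(tpm$s1, c(2e6 / 3, 1e6 / 3), tolerance = 1e-12)
  expect_equal(sum(tpm$s1), 1e6)

  # single expressed gene takes the whole million
  one <- tpm_normalize(tibble::tibble(gene_id = "g1", s1 = 7), genes[1, ])
  expect_equal(one$s1, 1e6)

  # scale invariance
  tpm2 <- tpm_normalize(dplyr::mutate(counts, s1 = s1 * 2), genes)
  expect_equal(tpm2, tpm)

  # all-zero sample stays zero
  z <- tpm_normalize(tibble::tibble(gene_id = c("g1", "g2"), s1 = c(0, 0)),
                     genes)
  expect_equal(z$s1, c(0, 0))
})

test_that("miRNA locus counting uses the flanked window with clipping", {
  mir <- tibble::tibble(mirna = "miR-x", chrom = "chr1", start = 10000L,
                        end = 10022L, strand = "+")
  reads <- tibble::tibble(
    chrom = "chr1", position = c(5500L, 4999L, 15021L, 15022L, 10010L),
    strand = c("+", "+", "+", "+", "-"), count = 1L
  )
  out <- count_mirna_locus(reads, mir)
  # window is [5000, 15022): 5500 and 15021 counted, 4999 and 15022 not,
  # antisense 10010 not
  expect_equal(out$sample1, 2)

  # flank clipped at the chromosome start
  mir0 <- tibble::tibble(mirna = "miR-0", chrom = "chr1", start = 100L,
                         end = 122L, strand = "+")
  out0 <- count_mirna_locus(
    tibble::tibble(chrom = "chr1", position = 0L, strand = "+", count = 1L),
    mir0
  )
  expect_equal(out0$sample1, 1)

  expect_equal(count_mirna_locus(reads[0, ], mir)$sample1, 0)
})

test_that("track normalization fixes the total signal with signed strands", {
  reads <- tibble::tibble(
    chrom = "chr1", position = c(10L, 10L, 20L), strand = c("+", "+", "-"),
    count = c(2e6 - 2, 2, 2e6)
  )
  track <- normalize_track(reads)
  expect_equal(sum(abs(track$score)), 1e6)
  # every value is halved relative to raw counts (total is 4e6 here -> /4)
  expect_equal(track$score[track$strand == "-"], -2e6 / 4)
  expect_true(all(track$score[track$strand == "-"] < 0))
  expect_true(all(track$score[track$strand == "+"] > 0))

  empty <- normalize_track(reads[0, ])
  expect_equal(nrow(empty), 0)

  tmp <- withr::local_tempdir()
  paths <- write_track_bedgraph(track, file.path(tmp, "t"))
  plus <- readr::read_tsv(paths[["plus"]], col_names = FALSE,
                          show_col_types = FALSE)
  expect_equal(nrow(plus), sum(track$strand == "+"))
})
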