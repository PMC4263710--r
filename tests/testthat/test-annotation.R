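test_that("read_gtf converts 1-based inclusive GTF to 0-based half-open spans", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; gene_biotype "protein_coding";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; gene_biotype "protein_coding";',
    'chr2\tsrc\texon\t11\t20\t.\t-\t.\tgene_id "g2"; gene_biotype "lincRNA";'
  ), path)
  gs <- read_gtf(path)
  g1 <- gs[gs$gene_id == "g1", ]
  expect_equal(c(g1$start, g1$end), c(100, 400))   # span = min/max over exons
  expect_equal(nrow(g1$exons[[1]]), 2)
  expect_equal(unname(g1$exons[[1]][1, ]), c(100, 200))
  g2 <- gs[gs$gene_id == "g2", ]
  expect_equal(c(g2$start, g2$end), c(10, 20))
  expect_equal(g2$biotype, "lincRNA")
  expect_equal(g2$strand, "-")
})

test_that("read_gtf rejects malformed lines with the offending line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1";',
    "chr1\tsrc\texon\tbroken"
  ), path)
  expect_error(read_gtf(path), "line 2")

  writeLines('chr1\tsrc\texon\t101\t200\t.\t+\t.\tfoo "bar";', path)
  expect_error(read_gtf(path), "gene_id")
})

test_that("write_gtf then read_gtf reproduces the gene set exactly", {
  gs <- make_genes(
    gene_id = c("a", "b", "c", "d", "e"),
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr3"),
    start = c(100, 900, 0, 5000, 42),
    end = c(500, 1400, 250, 9000, 101),
    strand = c("+", "-", "+", "-", "+"),
    biotype = c("protein_coding", "lincRNA", "snoRNA", "unknown",
                "antisense"),
    source = rep(c("primary", "secondary"), c(3, 2)),
    exons = list(cbind(start = c(100, 300), end = c(200, 500)),
                 cbind(start = 900, end = 1400),
                 cbind(start = c(0, 100, 200), end = c(50, 150, 250)),
                 cbind(start = 5000, end = 9000),
                 cbind(start = 42, end = 101))
  )
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gs, path)
  back <- read_gtf(path)
  expect_equal(back$gene_id, gs$gene_id)
  expect_equal(back$start, gs$start)
  expect_equal(back$end, gs$end)
  expect_equal(back$strand, gs$strand)
  expect_equal(back$biotype, gs$biotype)
  expect_equal(back$source, gs$source)
  for (i in seq_len(nrow(gs))) {
    expect_equal(unname(back$exons[[i]]), unname(gs$exons[[i]]))
  }
})

test_that("merge_nonoverlapping drops overlapping secondary genes only", {
  primary <- make_genes("p1", "chr1", 150, 250)
  overlapping <- make_genes("s1", "chr1", 100, 200, source = "secondary")
  abutting <- make_genes("s2", "chr1", 250, 300, source = "secondary")
  other_chrom <- make_genes("s3", "chr2", 150, 250, source = "secondary")
  expect_equal(merge_nonoverlapping(primary, overlapping)$gene_id, "p1")
  expect_setequal(merge_nonoverlapping(primary, abutting)$gene_id,
                  c("p1", "s2"))   # half-open abutment is not overlap
  expect_setequal(merge_nonoverlapping(primary, other_chrom)$gene_id,
                  c("p1", "s3"))
})

test_that("merge_nonoverlapping matches a brute-force all-pairs scan and is idempotent", {
  set.seed(11)
  for (rep in 1:5) {
    primary <- random_genes(20)
    secondary <- random_genes(20)
    secondary$gene_id <- paste0("s_", secondary$gene_id)
    secondary$source <- "secondary"
    merged <- merge_nonoverlapping(primary, secondary)
    expected_kept <- bf_merge_kept(primary, secondary)
    expect_setequal(setdiff(merged$gene_id, primary$gene_id), expected_kept)
    expect_equal(nrow(merged), nrow(primary) + length(expected_kept))
    # re-merging the result with the kept secondary genes adds nothing
    kept <- secondary[secondary$gene_id %in% expected_kept, ]
    kept$gene_id <- paste0("again_", kept$gene_id)
    remerged <- merge_nonoverlapping(merged, kept)
    # every kept secondary gene overlaps its identical twin already present
    expect_equal(nrow(remerged), nrow(merged))
  }
})

test_that("classify_genes maps biotypes to analysis classes", {
  gs <- make_genes(paste0("g", 1:5), "chr1",
                   c(0, 1000, 2000, 3000, 4000),
                   c(500, 1500, 2500, 3500, 4500),
                   biotype = c("protein_coding", "snoRNA", "antisense",
                               "unknown", "miRNA"))
  gs <- classify_genes(gs)
  expect_equal(setNames(gs$klass, gs$gene_id),
               c(g1 = "coding", g2 = "small_rna", g3 = "lncRNA",
                 g4 = "lncRNA", g5 = "small_rna"))
})

test_that("gene_gap uses half-open arithmetic", {
  gs <- make_genes(paste0("g", 1:4), c("chr1", "chr1", "chr1", "chr2"),
                   c(100, 200, 150, 250), c(200, 300, 250, 300))
  g <- function(i) gs[gs$gene_id == paste0("g", i), ]
  expect_equal(gene_gap(g(1), g(2)), 0L)        # abutting
  expect_equal(gene_gap(g(1), g(3)), 0L)        # overlapping
  expect_equal(gene_gap(g(3), g(4)), NA_integer_)  # different chromosomes
  far <- make_genes("f", "chr1", 250, 300)
  expect_equal(gene_gap(g(1), far[1, ]), 50L)
  expect_equal(gene_gap(far[1, ], g(1)), 50L)   # symmetric
  expect_equal(gene_gap(g(2), g(2)), 0L)
})

test_that("nearest_coding_neighbor minimises gap with deterministic ties", {
  gs <- classify_genes(make_genes(
    c("q", "left", "right"), "chr1",
    c(500, 100, 700), c(600, 200, 800),
    biotype = c("lincRNA", "protein_coding", "protein_coding")))
  nb <- nearest_coding_neighbor(gs[gs$gene_id == "q", ], gs)
  expect_equal(nb$id_b, "right")
  expect_equal(nb$gap_bp, 100L)

  # equal gaps: the candidate with the smaller start wins
  tie <- classify_genes(make_genes(
    c("q", "a", "b"), "chr1",
    c(500, 100, 700), c(600, 400, 1000),
    biotype = c("lincRNA", "protein_coding", "protein_coding")))
  nb <- nearest_coding_neighbor(tie[tie$gene_id == "q", ], tie)
  expect_equal(nb$id_b, "a")

  # no coding gene on the chromosome: no pair, not an error
  lone <- classify_genes(make_genes("x", "chr9", 0, 100, biotype = "lincRNA"))
  expect_null(nearest_coding_neighbor(lone[1, ], lone))
})

test_that("nearest_coding_neighbor agrees with an exhaustive scan on random genomes", {
  set.seed(7)
  for (rep in 1:4) {
    gs <- random_genes(50)
    oracle <- bf_nearest(gs)
    for (i in seq_len(nrow(gs))) {
      got <- nearest_coding_neighbor(gs[i, ], gs)
      want <- oracle[[gs$gene_id[i]]]
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$id_b, want$id, info = gs$gene_id[i])
        expect_equal(got$gap_bp, as.integer(want$gap))
      }
    }
  }
})
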