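test_that("build_pairs yields one pair per anchor with a same-chromosome coding gene", {
  gs <- classify_genes(make_genes(
    c("p1", "p2", "p3", "n1"), c("chr1", "chr1", "chr1", "chr2"),
    c(0, 2000, 5000, 0), c(1000, 3000, 6000, 500),
    biotype = c(rep("protein_coding", 3), "lincRNA")))
  pcpc <- build_pairs(gs, "coding")
  expect_equal(nrow(pcpc), 3)             # every coding anchor paired
  expect_true(all(pcpc$pair_class == "PC-PC"))
  expect_true(all(pcpc$id_a != pcpc$id_b))
  # lncRNA alone on chr2: no pair
  expect_equal(nrow(build_pairs(gs, "lncRNA")), 0)
})

test_that("build_pairs matches the brute-force nearest scan on a random genome", {
  set.seed(61)
  gs <- random_genes(100)
  oracle <- bf_nearest(gs)
  for (anchor_klass in c("coding", "lncRNA")) {
    pairs <- build_pairs(gs, anchor_klass)
    anchors <- gs$gene_id[gs$klass == anchor_klass]
    want <- Filter(Negate(is.null), oracle[anchors])
    expect_setequal(pairs$id_a, names(want))
    for (a in pairs$id_a) {
      expect_equal(pairs$id_b[pairs$id_a == a], want[[a]]$id)
      expect_equal(pairs$gap_bp[pairs$id_a == a], as.integer(want[[a]]$gap))
    }
  }
})

test_that("filter_hi applies the distance and expression rules per pair class", {
  pairs <- data.frame(
    id_a = c("nc1", "nc2", "pc1", "pc2"),
    id_b = c("pcA", "pcB", "pcC", "pcD"),
    pair_class = c("PC-NC", "PC-NC", "PC-PC", "PC-PC"),
    gap_bp = c(5000L, 12000L, 5000L, 5000L),
    tier = "all", stringsAsFactors = FALSE)
  expressed <- c("nc2", "pc1", "pcD")
  hi <- filter_hi(pairs, expressed)
  # nc1 unexpressed lncRNA dropped; nc2 beyond 10 kb dropped;
  # pc1 expressed kept; pc2 kept because its partner pcD is expressed
  expect_setequal(hi$id_a, c("pc1", "pc2"))
  expect_true(all(hi$tier == "hi"))
  # pure subset of the input pairs
  expect_true(all(paste(hi$id_a, hi$id_b) %in% paste(pairs$id_a, pairs$id_b)))
})

test_that("pair_correlations computes profile Pearson r with NA for constants", {
  am <- rbind(a = c(1, 3, 7), b = c(1, 3, 7), flat = c(2, 2, 2))
  colnames(am) <- c("0", "5", "15")
  # d mirrors a: log2 profile reversed
  am <- rbind(am, d = rev(2^(log2(c(1, 3, 7) + 1)) - 1))
  pairs <- data.frame(id_a = c("a", "a", "a"), id_b = c("b", "d", "flat"),
                      pair_class = "PC-NC", gap_bp = 0L, tier = "all",
                      stringsAsFactors = FALSE)
  out <- pair_correlations(pairs, am)
  expect_equal(out$r[1], 1)
  expect_equal(out$r[2], bf_pearson(log2(am["a", ] + 1), log2(am["d", ] + 1)))
  expect_true(is.na(out$r[3]))
  expect_error(pair_correlations(data.frame(id_a = "zz", id_b = "a",
                                            pair_class = "PC-NC",
                                            gap_bp = 0L, tier = "all"), am),
               "zz")
})

test_that("pair correlations match the covariance formula on random profiles", {
  set.seed(62)
  am <- matrix(rlnorm(40 * 12), nrow = 40,
               dimnames = list(sprintf("g%d", 1:40),
                               c(-2, 0, 1, 3, 5, 10, 15, 20, 25, 30, 45, 60)))
  ids <- replicate(30, sample(rownames(am), 2))
  pairs <- data.frame(id_a = ids[1, ], id_b = ids[2, ], pair_class = "PC-PC",
                      gap_bp = 0L, tier = "all", stringsAsFactors = FALSE)
  out <- pair_correlations(pairs, am)
  x <- log2(am + 1)
  for (k in seq_len(nrow(out))) {
    expect_equal(out$r[k], bf_pearson(x[out$id_a[k], ], x[out$id_b[k], ]),
                 tolerance = 1e-12)
  }
})

test_that("random_pair_null is seeded, uniform over distinct coding genes", {
  set.seed(63)
  gs <- random_genes(60)
  am <- matrix(rlnorm(60 * 12), nrow = 60, dimnames = list(gs$gene_id, NULL))
  colnames(am) <- as.character(c(-2, 0, 1, 3, 5, 10, 15, 20, 25, 30, 45, 60))
  null1 <- random_pair_null(gs, am, n_pairs = 500, seed = 9)
  null2 <- random_pair_null(gs, am, n_pairs = 500, seed = 9)
  expect_identical(null1, null2)            # determinism under a fixed seed
  expect_equal(nrow(random_pair_null(gs, am, n_pairs = 0, seed = 9)), 0)
  expect_true(all(null1$id_a != null1$id_b))  # no self-pairs
  coding <- gs$gene_id[gs$klass == "coding"]
  expect_true(all(c(null1$id_a, null1$id_b) %in% coding))
  # the null leaves the caller's RNG state untouched
  set.seed(64); before <- rnorm(1)
  set.seed(64); invisible(random_pair_null(gs, am, n_pairs = 100, seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("the random null is centred near zero for independent profiles", {
  set.seed(65)
  gs <- random_genes(400, coding_frac = 1)
  am <- matrix(rlnorm(400 * 12), nrow = 400,
               dimnames = list(gs$gene_id, NULL))
  colnames(am) <- as.character(c(-2, 0, 1, 3, 5, 10, 15, 20, 25, 30, 45, 60))
  null <- random_pair_null(gs, am, n_pairs = 4000, seed = 10)
  expect_lt(abs(mean(null$r, na.rm = TRUE)), 0.05)
})

test_that("r_distribution bins correlations and breaks ties towards zero", {
  d <- r_distribution(rep(1, 10))
  expect_equal(d$peak, 0.95)
  expect_equal(sum(d$counts), 10)

  # symmetric +-r: both bins tie; resolved to the one nearer zero
  d2 <- r_distribution(c(rep(-0.55, 5), rep(0.35, 5), 0.9))
  expect_equal(d2$peak, 0.35)
  d3 <- r_distribution(c(rep(-0.35, 5), rep(0.55, 5)))
  expect_equal(d3$peak, -0.35)

  expect_equal(r_distribution(c(0.5, NA, NA))$n_undefined, 2)
  expect_error(r_distribution(c(NA_real_, NA_real_)), "no defined")
})

test_that("planted cis-coupled pairs put the modal bin at the coupling strength", {
  sim <- simulate_ontogeny(sim_config(seed = 66, n_coding = 200,
                                      n_lncrna = 120, n_cis = 80,
                                      n_decoy = 0, within_age_cv = 0.1))
  am <- age_means(sim$expr)
  planted <- sim$truth$pairs[sim$truth$pairs$kind == "concordant", ]
  pairs <- data.frame(id_a = planted$nc_id, id_b = planted$pc_id,
                      pair_class = "PC-NC", gap_bp = planted$gap_bp,
                      tier = "all", stringsAsFactors = FALSE)
  r <- pair_correlations(pairs, am)$r
  d <- r_distribution(r)
  expect_true(d$peak %in% c(0.75, 0.85))   # modal bin contains rho = 0.8
})

test_that("concordant_pairs applies significance, distance and label identity", {
  pairs <- data.frame(
    id_a = c("nc1", "nc2", "nc3", "nc4"),
    id_b = c("p1", "p2", "p3", "p4"),
    pair_class = "PC-NC",
    gap_bp = c(3000L, 3000L, 3000L, 15000L),
    tier = "hi", r = c(0.9, 0.8, 0.7, 0.9), stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c("nc1", "nc2", "nc3", "nc4"),
                   p_adj = c(0.01, 0.01, 0.5, 0.01))
  assignments <- data.frame(
    gene_id = c("nc1", "nc2", "nc3", "nc4", "p1", "p2", "p3", "p4"),
    label = c("neonatal", "neonatal", "adult", "adult",
              "neonatal", "adult", "adult", "adult"))
  out <- concordant_pairs(pairs, de, assignments)
  # nc1: all criteria met; nc2: label mismatch; nc3: not significant;
  # nc4: too far
  expect_equal(out$id_a, "nc1")
  expect_error(concordant_pairs(transform(pairs, pair_class = "PC-PC"),
                                de, assignments), "PC-NC")
})
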