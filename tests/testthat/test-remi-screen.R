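test_that("RPM normalization scales proportionally and sums tags", {
  raw <- data.frame(insertion_id = c("m1", "m2"), screen = "drug",
                    replicate = 1, round = 2, count = c(75, 25))
  sc <- normalize_counts(raw)
  expect_equal(unname(sc$counts[, 1]), c(750000, 250000))
  # two tags of one insertion are summed before scaling
  tagged <- data.frame(insertion_id = c("m1", "m1", "m2"), screen = "drug",
                       replicate = 1, round = 2, count = c(40, 60, 100),
                       tag = c("t1", "t2", "t1"))
  sc2 <- normalize_counts(tagged)
  expect_equal(unname(sc2$counts["m1", 1]), 5e5)
  # depth invariance
  raw2 <- raw; raw2$count <- raw2$count * 2
  expect_equal(normalize_counts(raw2)$counts, sc$counts)
  # duplicate rows without a tag column are rejected
  expect_error(normalize_counts(rbind(raw, raw[1, ])), "duplicate")
  # non-unique mappings are dropped before scaling
  raw3 <- raw; raw3$unique_mapping <- c(TRUE, FALSE)
  expect_equal(unname(normalize_counts(raw3)$counts["m1", 1]), 1e6)
})

test_that("abundance bins use the stated boundaries", {
  mk <- function(mean_count) {
    data.frame(insertion_id = sprintf("m%02d", seq_along(mean_count)),
               screen = "vehicle", replicate = rep(1:2,
                 each = length(mean_count)), round = 2,
               count = rep(mean_count, 2))
  }
  counts <- mk(c(99.9, 100, 500, 1000, 1000.1, 5000))
  sc <- normalize_counts(counts)
  # bypass RPM rescaling: feed the counts matrix directly at known scale
  sc$counts <- cbind(`vehicle|1|2` = c(99.9, 100, 500, 1000, 1000.1, 5000),
                     `vehicle|2|2` = c(99.9, 100, 500, 1000, 1000.1, 5000))
  rownames(sc$counts) <- sprintf("m%02d", 1:6)
  bins <- bin_mutants(sc, round = 2)
  expect_equal(as.character(bins),
               c("bin100", "bin1000", "bin1000", "bin1000", "bin10000",
                 "bin10000"))
})

test_that("log fold changes and Z-scores satisfy their identities", {
  s <- rep(0, 400)
  cfg <- screen_sim_config(seed = 2, n_mutants = 400, read_depth = 1e6,
                           selection_coefficients = s)
  sc <- normalize_counts(gen_screen_counts(cfg)$counts)
  calls <- compute_lfc_z(sc, "drug", 5)
  # count equal to the control mean gives lfc 0
  ctrl_mean <- rowMeans(sc$counts[, grepl("vehicle", colnames(sc$counts)) &
                                    grepl("5$", colnames(sc$counts))])
  drug1 <- sc$counts[, "drug|1|5"]
  close <- which(abs(drug1 - ctrl_mean) < 1e-9)
  if (length(close))
    expect_equal(calls$lfc[calls$replicate == 1][close],
                 rep(0, length(close)))
  # standardization identity per (bin, replicate)
  for (r in 1:2) for (b in unique(calls$bin)) {
    z <- calls$z[calls$replicate == r & calls$bin == b]
    z <- z[!is.na(z)]
    if (length(z) >= 3) {
      expect_lt(abs(mean(z)), 1e-9)
      expect_lt(abs(sd(z) - 1), 1e-9)
    }
  }
  # planted 8-fold enrichment at equal depth gives lfc near 3
  sc2 <- sc
  sc2$counts["mut00001", c("drug|1|5", "drug|2|5")] <-
    8 * (ctrl_mean["mut00001"] + 1) - 1
  calls2 <- compute_lfc_z(sc2, "drug", 5)
  expect_equal(calls2$lfc[calls2$insertion_id == "mut00001" &
                            calls2$replicate == 1][1],
               log2(8), tolerance = 1e-6)
})

test_that("small bins yield undefined Z-scores with a warning", {
  # counts already on the normalized scale: one lone high-abundance mutant
  m <- cbind(`drug|1|2` = c(5000, 480, 515, 505, 497),
             `drug|2|2` = c(5100, 470, 525, 500, 505),
             `vehicle|1|2` = c(4950, 500, 500, 500, 500),
             `vehicle|2|2` = c(5050, 500, 500, 500, 500))
  rownames(m) <- sprintf("m%d", 1:5)
  sc <- structure(list(
    counts = m,
    samples = data.frame(sample_id = colnames(m),
                         screen = rep(c("drug", "vehicle"), each = 2),
                         replicate = rep(1:2, 2), round = 2,
                         stringsAsFactors = FALSE)),
    class = "screen_counts")
  expect_warning(calls <- compute_lfc_z(sc, "drug", 2), "< 3 members")
  expect_true(all(is.na(calls$z[calls$insertion_id == "m1"])))
  expect_false(anyNA(calls$z[calls$insertion_id != "m1"]))
})

test_that("selection needs both replicates past the threshold", {
  mk_calls <- function(z1, z2, bin = "bin1000", round = 5) {
    data.frame(insertion_id = rep(sprintf("m%d", seq_along(z1)), 2),
               screen = "drug", round = round,
               replicate = rep(1:2, each = length(z1)), bin = bin,
               lfc = 0, z = c(z1, z2), stringsAsFactors = FALSE)
  }
  r5 <- mk_calls(c(1.6, 1.6), c(1.4, 1.7))
  r2 <- mk_calls(c(-1.2, -0.5), c(-1.5, -0.2), round = 2)
  sel <- select_mutants(r2, r5)
  expect_equal(sel$advantaged, "m2")     # (1.6, 1.7) in both reps
  expect_equal(sel$disadvantaged, "m1")  # (-1.2, -1.5) in both reps
  # bin100 mutants never count as disadvantaged
  r2b <- mk_calls(c(-1.2, -0.5), c(-1.5, -0.2), bin = "bin100", round = 2)
  expect_length(select_mutants(r2b, r5)$disadvantaged, 0)
})

test_that("a synthetic screen recovers planted selection signs", {
  n <- 2000
  s <- rep(0, n); s[1:50] <- 0.5; s[51:100] <- -0.5
  ids <- sprintf("mut%05d", 1:n)
  adv_rec <- dis_rec <- neut_fp <- numeric(0)
  for (seed in 1:5) {
    cfg <- screen_sim_config(seed = seed, n_mutants = n,
                             selection_coefficients = s)
    sc <- normalize_counts(gen_screen_counts(cfg)$counts)
    sel <- select_mutants(compute_lfc_z(sc, "drug", 2),
                          compute_lfc_z(sc, "drug", 5))
    adv_rec <- c(adv_rec, mean(ids[1:50] %in% sel$advantaged))
    dis_rec <- c(dis_rec, mean(ids[51:100] %in% sel$disadvantaged))
    neut_fp <- c(neut_fp, mean(ids[101:n] %in% c(sel$advantaged,
                                                 sel$disadvantaged)))
  }
  expect_gte(mean(adv_rec), 0.8)
  expect_gte(mean(dis_rec), 0.6)
  expect_lte(mean(neut_fp), 0.05)
})

test_that("neutral screens call few mutants in either direction", {
  n <- 800
  rates <- vapply(1:5, function(seed) {
    cfg <- screen_sim_config(seed = seed + 100, n_mutants = n,
                             read_depth = 2e6)
    sc <- normalize_counts(gen_screen_counts(cfg)$counts)
    sel <- select_mutants(compute_lfc_z(sc, "drug", 2),
                          compute_lfc_z(sc, "drug", 5))
    length(sel$advantaged) / n
  }, numeric(1))
  # both replicates must exceed z > 1.5.  The two replicate log fold
  # changes share the control-mean denominator, which correlates their
  # sampling noise at rho = (s^2/2) / (s^2/2 + s^2) = 1/3, so the expected
  # joint rate is P(z1 > 1.5, z2 > 1.5) under that correlation (numerical
  # oracle below), not the independent-replicates product.
  rho <- 1 / 3
  joint <- integrate(function(s)
    dnorm(s) * pnorm((1.5 - sqrt(rho) * s) / sqrt(1 - rho),
                     lower.tail = FALSE)^2, -Inf, Inf)$value
  expect_lte(mean(rates), 2 * joint)
  expect_gte(mean(rates), joint / 4)
})

test_that("insertion annotation applies the strand-aware 500 bp rule", {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC", "gT"),
    chrom = "chr1",
    start = c(1000, 5000, 9000, 12000),
    end = c(2000, 6000, 9500, 12100),
    strand = c("+", "-", "+", "+"),
    type = c("gene", "gene", "gene", "tRNA"), stringsAsFactors = FALSE)
  ins <- data.frame(
    insertion_id = c("i_in", "i_up300", "i_up600", "i_minus", "i_trna",
                     "i_far"),
    chrom = "chr1",
    pos = c(1500, 700, 400, 6300, 12050, 8000))
  ann <- annotate_insertions(ins, genes)
  expect_equal(ann$category[ann$insertion_id == "i_in"], "intragenic")
  expect_equal(ann$assigned_gene[ann$insertion_id == "i_in"], "gA")
  # 300 bp upstream of a + strand gene start: assigned
  expect_equal(ann$category[ann$insertion_id == "i_up300"],
               "promoter_within_500bp")
  expect_equal(ann$assigned_gene[ann$insertion_id == "i_up300"], "gA")
  # 600 bp upstream: not assigned
  expect_equal(ann$category[ann$insertion_id == "i_up600"], "intergenic")
  expect_true(is.na(ann$assigned_gene[ann$insertion_id == "i_up600"]))
  # upstream of a - strand gene means beyond its end coordinate
  expect_equal(ann$assigned_gene[ann$insertion_id == "i_minus"], "gB")
  # insertions in excluded gene classes carry the class
  expect_equal(ann$excluded_class[ann$insertion_id == "i_trna"], "tRNA")
})

test_that("gene assignment drops excluded classes and blacklisted genes", {
  ann <- data.frame(
    insertion_id = c("i1", "i2", "i3", "i4"),
    chrom = "chr1", pos = 1:4,
    category = c("intragenic", "intragenic", "intergenic",
                 "promoter_within_500bp"),
    assigned_gene = c("gA", "gP", NA, "gB"),
    excluded_class = c("none", "pseudogene", "none", "none"),
    note = NA, stringsAsFactors = FALSE)
  res <- assign_genes(c("i1", "i2", "i3", "i4"), ann, blacklist = "gB")
  expect_equal(res$genes, "gA")
  expect_equal(res$table$reason,
               c("assigned", "excluded_class:pseudogene",
                 "intergenic_no_promoter", "blacklisted_gene"))
  expect_error(assign_genes("nope", ann), "unknown mutant")
})

test_that("hypergeometric overlap matches brute-force enumeration", {
  universe <- letters[1:10]
  A <- c("a", "b", "c", "d")
  B <- c("c", "d", "e")
  res <- overlap_test(A, B, universe)
  expect_equal(res$k, 2)
  expect_equal(res$p, brute_hyper(k = 2, n = 3, N = 10, K = 4),
               tolerance = 1e-12)
  # disjoint lists in a tiny universe
  res0 <- overlap_test(c("a", "b"), c("c", "d", "e"), letters[1:8])
  expect_equal(res0$p, brute_hyper(0, 3, 8, 2), tolerance = 1e-12)
  # full-universe lists overlap with certainty
  resU <- overlap_test(universe, universe, universe)
  expect_equal(resU$p, 1)
  # closed form: both lists of 5 in a universe of 20, complete overlap
  res5 <- overlap_test(letters[1:5], letters[1:5], letters[1:20])
  expect_equal(res5$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_error(overlap_test(c("zz"), B, universe), "subsets")
})

test_that("rank-quartile statistics match the closed form", {
  z <- setNames(seq(-3, 3, length.out = 400), sprintf("m%03d", 1:400))
  top <- names(sort(z, decreasing = TRUE))[1:40]
  res <- rank_quartile_test(z, top)
  expect_equal(unname(res$counts), c(0, 0, 0, 40))
  expect_equal(res$chi_squared, 120)
  expect_lt(res$p, 1e-20)
  # uniformly spread list: p near 1
  unif <- names(z)[seq(1, 400, by = 10)]
  expect_gt(rank_quartile_test(z, unif)$p, 0.9)
  # quartile sizes differ by at most 1 for awkward N
  for (N in c(10, 13, 402)) {
    zz <- setNames(rnorm(N), sprintf("q%04d", 1:N))
    qt <- table(ceiling(4 * rank(zz, ties.method = "first") / N))
    expect_lte(diff(range(qt)), 1)
  }
  expect_error(rank_quartile_test(z, "absent"), "not scored")
})

test_that("chi-squared quartile p matches the base chisq.test oracle", {
  z <- setNames(rnorm(200), sprintf("m%03d", 1:200))
  set.seed(3)
  listed <- sample(names(z), 40)
  res <- rank_quartile_test(z, listed)
  oracle <- suppressWarnings(chisq.test(unname(res$counts),
                                        p = rep(0.25, 4)))
  expect_equal(res$chi_squared, unname(oracle$statistic))
  expect_equal(res$p, oracle$p.value)
})

test_that("GO enrichment matches brute-force enumeration on a small universe", {
  universe <- letters[1:10]
  t2g <- data.frame(term = rep(c("T1", "T2"), c(4, 3)),
                    gene = c("a", "b", "c", "d", "h", "i", "j"))
  hits <- c("a", "b", "c", "e")
  res <- go_enrichment(hits, universe, t2g, alpha = 1.1)
  p1 <- res$p[res$term == "T1"]
  expect_equal(p1, brute_hyper(k = 3, n = 4, N = 10, K = 4),
               tolerance = 1e-12)
  # a term identical to the gene list has the smallest possible p
  t2g2 <- rbind(t2g, data.frame(term = "T3", gene = hits))
  res2 <- go_enrichment(hits, universe, t2g2, alpha = 1.1)
  expect_equal(res2$term[1], "T3")
  expect_error(go_enrichment(c("zz"), universe, t2g), "subset")
})

test_that("random gene lists are enriched at roughly the nominal rate", {
  set.seed(12)
  universe <- sprintf("g%03d", 1:60)
  t2g <- data.frame(term = rep(sprintf("T%02d", 1:30), each = 10),
                    gene = unlist(lapply(1:30, function(i)
                      sample(universe, 10))))
  frac <- vapply(1:30, function(s) {
    set.seed(s + 500)
    hits <- sample(universe, 15)
    res <- go_enrichment(hits, universe, t2g, alpha = 1.1)
    mean(res$p < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.05), 0.05)
})
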