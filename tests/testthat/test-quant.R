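test_that("read counting respects the counting region", {
  models <- toy_models()
  # five reads on t1, all with CDS-internal P-sites (cds 50..200)
  r <- toy_reads("t1", c(50, 60, 70, 80, 90))
  m <- count_reads(r, models, region = "transcript")
  expect_equal(m["g1", "s1"], 5L)
  expect_equal(m["g2", "s1"], 0L)
  expect_equal(count_reads(r, models, region = "cds")["g1", "s1"], 5L)

  # P-site in the 5' UTR: counted for transcript, not for cds
  utr_read <- toy_reads("t1", 0L)  # P-site 12 < cds_start 50
  expect_equal(count_reads(utr_read, models,
                           region = "transcript")["g1", "s1"], 1L)
  expect_equal(count_reads(utr_read, models,
                           region = "cds")["g1", "s1"], 0L)

  unknown <- toy_reads("nope", 0L)
  expect_error(count_reads(unknown, models), "unknown transcript")
  lenient <- count_reads(unknown, models, strict = FALSE)
  expect_equal(sum(lenient), 0L)
  expect_equal(attr(lenient, "n_skipped"), 1L)
})

test_that("counting totals agree with simulator bookkeeping", {
  sim <- simulate_dataset(tiny_config(seed = 14, n_genes = 20,
                                      depth = 5e3))
  m <- count_reads(sim$reads, sim$models, region = "transcript")
  expect_identical(m[rownames(sim$counts_rpf), colnames(sim$counts_rpf)],
                   sim$counts_rpf)
  # the simulator places every P-site inside the CDS
  m_cds <- count_reads(sim$reads, sim$models,
                       psite_offset = sim$config$psite_offset,
                       region = "cds")
  expect_identical(m_cds[rownames(sim$counts_rpf),
                         colnames(sim$counts_rpf)],
                   sim$counts_rpf)
})

test_that("RPKM evaluates its formula exactly on hand-computed toys", {
  # count 10, length 1000 nt, library 1e6 -> 10 / (1 * 1) = 10
  lengths <- c(gA = 1000, gB = 999000 / 999)  # gB absorbs the library
  counts <- matrix(c(10L, 999990L), ncol = 1,
                   dimnames = list(c("gA", "gB"), "s"))
  rpkm <- compute_rpkm(counts, lengths = lengths)
  expect_equal(rpkm["gA", "s"], 10.0, tolerance = 1e-9)

  # zero count gives zero RPKM
  counts0 <- matrix(c(0L, 100L), ncol = 1,
                    dimnames = list(c("gA", "gB"), "s"))
  expect_equal(compute_rpkm(counts0, lengths = c(gA = 500,
                                                 gB = 500))["gA", "s"], 0)

  # counts (90, 10), lengths (300, 2000), library 100
  # gA: 90 / (0.3 * 1e-4) = 3e6 ; gB: 10 / (2 * 1e-4) = 5e4
  counts2 <- matrix(c(90L, 10L), ncol = 1,
                    dimnames = list(c("gA", "gB"), "s"))
  rpkm2 <- compute_rpkm(counts2, lengths = c(gA = 300, gB = 2000))
  expect_equal(rpkm2[, "s"], c(gA = 3.0e6, gB = 5.0e4), tolerance = 1e-9)

  expect_error(compute_rpkm(counts2 * 0L, lengths = c(gA = 1, gB = 1)),
               "zero library size")
  expect_error(compute_rpkm(counts2, lengths = c(gA = 0, gB = 10)),
               "positive")
})

test_that("RPKM is scale-consistent and re-aggregates to the library", {
  set.seed(20)
  counts <- matrix(rpois(400, 40), nrow = 100,
                   dimnames = list(sprintf("g%03d", 1:100),
                                   paste0("s", 1:4)))
  lengths <- setNames(sample(200:5000, 100), rownames(counts))
  rpkm <- compute_rpkm(counts, lengths = lengths)
  # multiplying a sample's counts by c leaves its RPKM unchanged
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 7L
  expect_equal(compute_rpkm(scaled, lengths = lengths)[, 2], rpkm[, 2],
               tolerance = 1e-12)
  # sum_i RPKM_i * length_i / 1e3 = 1e6 in every sample
  agg <- colSums(rpkm * lengths[rownames(rpkm)] / 1e3)
  expect_equal(unname(agg), rep(1e6, 4), tolerance = 1e-6)
})

test_that("the low-count filter applies '< min_reads' per assay", {
  g <- c("g39", "g40", "g41", "gRPFonly", "gMRNAonly")
  rpf <- matrix(c(39L, 40L, 41L, 100L, 39L), ncol = 1,
                dimnames = list(g, "s1"))
  mrna <- matrix(c(40L, 40L, 41L, 39L, 100L), ncol = 1,
                 dimnames = list(g, "s1"))
  f <- filter_low_count_genes(rpf, mrna, min_reads = 40L)
  expect_setequal(f$retained, c("g40", "g41"))
  expect_setequal(f$discarded$gene_id, c("g39", "gRPFonly", "gMRNAonly"))
  expect_equal(
    f$discarded$failed_assay[f$discarded$gene_id == "gRPFonly"], "MRNA")
  expect_equal(
    f$discarded$failed_assay[f$discarded$gene_id == "gMRNAonly"], "RPF")
})

test_that("the filter agrees with a brute-force scan on a 1000-gene fixture", {
  set.seed(21)
  n <- 1000
  rpf <- matrix(rpois(n * 3, 15), nrow = n,
                dimnames = list(sprintf("g%04d", 1:n), paste0("r", 1:3)))
  mrna <- matrix(rpois(n * 3, 15), nrow = n,
                 dimnames = list(sprintf("g%04d", 1:n), paste0("m", 1:3)))
  f <- filter_low_count_genes(rpf, mrna, min_reads = 40L)
  brute <- character(0)
  for (g in rownames(rpf)) {
    if (sum(rpf[g, ]) >= 40 && sum(mrna[g, ]) >= 40) {
      brute <- c(brute, g)
    }
  }
  expect_identical(f$retained, brute)
  expect_error(filter_low_count_genes(rpf[-1, ], mrna),
               "different gene universes")
})

test_that("TE is the ratio of replicate-mean RPKMs, undefined at zero mRNA", {
  cmap <- c(a1 = "A", a2 = "A", b1 = "B")
  rpf <- matrix(c(10, 10, 8, 12, 6, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("a1", "a2", "b1")))
  mrna <- matrix(c(5, 5, 4, 0, 0, 3), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("a1", "a2", "b1")))
  te <- compute_te(rpf, mrna, cmap)
  expect_equal(te$te["g1", "A"], 2.0)   # mean(10,10)/mean(5,5)
  expect_equal(te$te["g1", "B"], 2.0)   # 8/4
  expect_true(is.na(te$te["g2", "A"]))  # mRNA mean 0
  expect_equal(te$te["g2", "B"], 0.0)   # RPF 0 / mRNA 3
  expect_equal(te$undefined$gene_id, "g2")
  expect_equal(te$undefined$condition, "A")

  # equal matrices give TE 1 everywhere defined
  te1 <- compute_te(mrna, mrna, cmap)$te
  defined <- !is.na(te1)
  expect_true(all(te1[defined] == 1))

  expect_error(compute_te(rpf, mrna, c(a1 = "A", b1 = "B", zz = "C")),
               "no samples")
})

test_that("TE estimates converge to truth as dispersion vanishes", {
  cfg <- sim_config(seed = 22, n_genes = 400, depth = 1e6, dispersion = 0)
  sim <- simulate_dataset(cfg, reads = FALSE)
  lens <- setNames(sim$models$length, sim$models$gene_id)
  rpkm_rpf <- compute_rpkm(sim$counts_rpf, lengths = lens)
  rpkm_mrna <- compute_rpkm(sim$counts_mrna, lengths = lens)
  te <- compute_te(rpkm_rpf, rpkm_mrna, sim$condition_map)$te
  # true TE is defined up to a per-sample scale; compare ratio profiles
  for (cond in c("WT", "2D")) {
    est <- te[sim$truth$gene_id, cond]
    truth <- sim$truth[[paste0("te_", cond)]]
    rel <- log2(est / truth)
    rel <- rel - stats::median(rel, na.rm = TRUE)
    expect_lt(stats::median(abs(rel), na.rm = TRUE), 0.05)
  }
})
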