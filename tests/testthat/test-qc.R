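test_that("length histogram tallies exactly and flags canonical sizes", {
  r <- toy_reads("t1", c(0, 1, 2), c(28L, 28L, 30L))
  h <- footprint_length_histogram(r)
  expect_identical(h$histogram, c("28" = 2L, "30" = 1L))
  expect_equal(h$canonical_fraction, 1.0)

  short <- toy_reads("t1", c(0, 1), c(20L, 20L))
  expect_equal(footprint_length_histogram(short)$canonical_fraction, 0)
  expect_error(footprint_length_histogram(short[0, ]), "no footprints")
})

test_that("frame assignment follows P-site arithmetic", {
  models <- data.frame(transcript_id = "tx", gene_id = "g",
                       length = 100L, cds_start = 10L, cds_end = 70L)
  # 5' position 1 + offset 12 = P-site 13, (13 - 10) %% 3 = 0
  r0 <- toy_reads("tx", 1L)
  expect_equal(psite_frame_distribution(r0, models, 12L)$fractions,
               c(1, 0, 0))
  # 5' position 2 -> P-site 14 -> frame 1
  r1 <- toy_reads("tx", 2L)
  expect_equal(psite_frame_distribution(r1, models, 12L)$fractions,
               c(0, 1, 0))
  # P-site outside the CDS is excluded and reported
  routside <- toy_reads("tx", c(1L, 90L), length = 10L)
  fr <- psite_frame_distribution(routside, models, 12L)
  expect_equal(fr$n_excluded, 1L)
  expect_equal(fr$excluded_fraction, 0.5)
  expect_error(psite_frame_distribution(toy_reads("tx", 90L, 10L),
                                        models, 12L),
               "no reads")
})

test_that("vectorized frame fractions equal the one-read-at-a-time oracle", {
  models <- random_models(50)
  models <- models[models$cds_end - models$cds_start >= 60, ]
  set.seed(11)
  n <- 1e4
  i <- sample(nrow(models), n, replace = TRUE)
  pos <- floor(runif(n) * (models$length[i] - 30))
  reads <- toy_reads(models$transcript_id[i], pos, 30L)
  got <- psite_frame_distribution(reads, models, 12L)
  want <- oracle_frames(reads, models, 12L)
  expect_equal(got$fractions, want$fractions, tolerance = 1e-12)
  expect_equal(got$n_excluded, want$n_excluded)
})

test_that("metagene profile spikes where the P-sites are", {
  models <- data.frame(transcript_id = "tx", gene_id = "g",
                       length = 400L, cds_start = 60L, cds_end = 360L)
  # all P-sites exactly at the CDS start
  r <- toy_reads("tx", rep(60L - 12L, 50))
  prof <- metagene_profile(r, models, window = c(30L, 90L), 12L)
  expect_equal(prof$count[prof$position == 0], 50L)
  expect_equal(sum(prof$count), 50L)
})

test_that("uniform P-site placement gives a flat profile", {
  models <- data.frame(transcript_id = "tx", gene_id = "g",
                       length = 500L, cds_start = 100L, cds_end = 400L)
  set.seed(3)
  n <- 1e5
  width <- 60L
  rel <- sample.int(width, n, replace = TRUE) - 1L  # uniform on 0..59
  reads <- toy_reads("tx", 100L + rel - 12L)
  prof <- metagene_profile(reads, models, window = c(0L, width - 1L), 12L)
  expect_equal(sum(prof$count), n)
  p <- 1 / width
  band <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(abs(prof$count - n * p) <= band))
})

test_that("replicate correlation matches a definitional-sum Pearson", {
  set.seed(4)
  rpkm <- matrix(rlnorm(20, 2, 1), nrow = 10,
                 dimnames = list(sprintf("g%02d", 1:10), c("a", "b")))
  r2 <- replicate_correlation(rpkm)
  want <- oracle_pearson(log10(rpkm[, 1] + 0.5 * min(rpkm[, 1])),
                         log10(rpkm[, 2] + 0.5 * min(rpkm[, 2])))^2
  expect_equal(r2["a", "b"], want, tolerance = 1e-12)
  expect_equal(diag(r2), c(a = 1, b = 1))

  # identical replicates are perfectly reproducible
  same <- cbind(s1 = rpkm[, 1], s2 = rpkm[, 1])
  expect_equal(replicate_correlation(same)["s1", "s2"], 1.0)

  # independent permutations decorrelate
  set.seed(5)
  big <- matrix(rlnorm(4000, 2, 1), ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  big[, 2] <- sample(big[, 2])
  expect_lt(replicate_correlation(big)["x", "y"], 0.1)

  expect_error(replicate_correlation(rpkm[, 1, drop = FALSE]),
               "at least 2")
})

test_that("replicate correlation is invariant to gene order and column scaling", {
  set.seed(6)
  rpkm <- matrix(rlnorm(300, 1, 0.8), ncol = 3,
                 dimnames = list(sprintf("g%03d", 1:100),
                                 c("r1", "r2", "r3")))
  base <- replicate_correlation(rpkm)
  perm <- replicate_correlation(rpkm[sample(nrow(rpkm)), ])
  expect_equal(base, perm, tolerance = 1e-12)
  scaled <- rpkm
  scaled[, 2] <- scaled[, 2] * 7.5
  # a log-scale shift: the per-sample pseudocount scales with the column
  expect_equal(replicate_correlation(scaled), base, tolerance = 1e-12)
})

test_that("qc_summary sets pass flags and handles missing replicates", {
  sim <- simulate_dataset(tiny_config(seed = 12, n_genes = 40,
                                      depth = 3e4))
  lens <- setNames(sim$models$length, sim$models$gene_id)
  rpkm_rpf <- compute_rpkm(sim$counts_rpf, lengths = lens)
  rep_ <- run_qc(sim$reads, sim$models, rpkm_rpf = rpkm_rpf)
  expect_s3_class(rep_, "qc_report")
  expect_true(rep_$pass_flags$length_canonical)
  expect_true(rep_$pass_flags$periodicity)
  expect_true(is.na(rep_$pass_flags$replicate_r2_mrna))
  expect_equal(sum(rep_$length_histogram), nrow(sim$reads))
  expect_equal(sum(rep_$frame_fractions), 1, tolerance = 1e-9)

  # uniform frames fail the periodicity flag
  cfg_flat <- tiny_config(seed = 13, n_genes = 40, depth = 3e4,
                          frame_probs = c(1, 1, 1) / 3)
  sim_flat <- simulate_dataset(cfg_flat)
  rep_flat <- run_qc(sim_flat$reads, sim_flat$models)
  expect_false(rep_flat$pass_flags$periodicity)

  p <- tempfile(fileext = ".json")
  write_qc_report(rep_, p)
  parsed <- jsonlite::read_json(p)
  expect_equal(parsed$in_frame_fraction, rep_$in_frame_fraction[[1]],
               tolerance = 1e-9)
})
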