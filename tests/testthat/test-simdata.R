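test_that("config validation names the offending field", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(top_fraction = 1.2), "top_fraction")
  expect_error(sim_config(depth = -1), "depth")
  expect_error(sim_config(te_effect_fold = 1), "te_effect_fold")
  expect_error(sim_config(frame_probs = c(0.5, 0.5)), "frame_probs")
  expect_error(sim_config(utr3_length_mean = -5), "utr3_length_mean")
})

test_that("generated transcripts satisfy the CDS invariants", {
  tx <- generate_transcriptome(tiny_config(seed = 1, n_genes = 10))
  m <- tx$models
  expect_equal(nrow(m), 10L)
  expect_true(all((m$cds_end - m$cds_start) %% 3 == 0))
  expect_true(all(m$cds_start >= 0 & m$cds_end <= m$length))
  expect_identical(unname(nchar(tx$sequences[m$transcript_id])), m$length)
  cds <- substr(tx$sequences[m$transcript_id], m$cds_start + 1, m$cds_end)
  expect_true(all(startsWith(cds, "ATG")))
  last_codon <- substr(cds, nchar(cds) - 2, nchar(cds))
  expect_true(all(last_codon %in% c("TAA", "TAG", "TGA")))
})

test_that("the transcriptome generator is deterministic", {
  cfg <- tiny_config(seed = 9, n_genes = 15)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_fasta(a$sequences, f1)
  write_fasta(b$sequences, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("planted UTR motifs are recovered exactly by the scanners", {
  tx <- generate_transcriptome(
    sim_config(seed = 3, n_genes = 200, depth = 1e4,
               top_fraction = 0.3, uorf_fraction = 0.4))
  utr <- extract_five_prime_utr(tx$models, tx$sequences)
  top <- detect_top_motif(utr$utr5_seq)
  expect_identical(top$has_top, tx$features$planted_top)
  expect_identical(detect_uorfs(utr$utr5_seq), tx$features$planted_uorfs)
})

test_that("top_fraction = 1 plants a TOP motif in every gene", {
  tx <- generate_transcriptome(
    tiny_config(seed = 2, n_genes = 40, top_fraction = 1.0))
  utr <- extract_five_prime_utr(tx$models, tx$sequences)
  expect_true(all(detect_top_motif(utr$utr5_seq)$has_top))
})

test_that("planted TE effects are exact and class counts deterministic", {
  cfg <- sim_config(seed = 5, n_genes = 1000, depth = 1e4,
                    dtg_up_fraction = 0.1, dtg_down_fraction = 0.2,
                    te_effect_fold = 2.5)
  truth <- simulate_true_expression(cfg)
  expect_equal(sum(truth$class == "up"), 100L)
  expect_equal(sum(truth$class == "down"), 200L)
  ratio <- truth$te_2D / truth$te_WT
  expect_equal(ratio[truth$class == "up"],
               rep(2.5, 100), tolerance = 1e-12)
  expect_equal(ratio[truth$class == "down"],
               rep(1 / 2.5, 200), tolerance = 1e-12)
  expect_equal(ratio[truth$class == "null"],
               rep(1, 700), tolerance = 1e-12)

  cfg0 <- sim_config(seed = 5, n_genes = 50, depth = 1e4,
                     dtg_up_fraction = 0, dtg_down_fraction = 0)
  truth0 <- simulate_true_expression(cfg0)
  expect_true(all(truth0$class == "null"))
  expect_identical(truth0$te_WT, truth0$te_2D)
})

test_that("count matrices are reproducible and Poisson-concentrated at zero dispersion", {
  cfg <- sim_config(seed = 7, n_genes = 500, depth = 1e6, dispersion = 0,
                    dtg_up_fraction = 0, dtg_down_fraction = 0)
  tx <- generate_transcriptome(cfg)
  truth <- simulate_true_expression(cfg, tx$features)
  a <- simulate_count_matrices(truth, tx$models, cfg)
  b <- simulate_count_matrices(truth, tx$models, cfg)
  expect_identical(a, b)

  # Poisson concentration: count within 3 sqrt(mu) of mu for >= 99% of genes
  len <- tx$models$length[match(truth$gene_id, tx$models$gene_id)]
  w <- truth$abundance_WT * len
  mu <- cfg$depth * w / sum(w)
  obs <- a$mrna[, "WT_rep1"]
  frac_ok <- mean(abs(obs - mu) <= 3 * sqrt(mu))
  expect_gte(frac_ok, 0.99)
})

test_that("doubling depth doubles expected totals", {
  base <- sim_config(seed = 8, n_genes = 300, dispersion = 0, depth = 1e6)
  twice <- sim_config(seed = 8, n_genes = 300, dispersion = 0, depth = 2e6)
  tx <- generate_transcriptome(base)
  truth <- simulate_true_expression(base, tx$features)
  c1 <- simulate_count_matrices(truth, tx$models, base)
  c2 <- simulate_count_matrices(truth, tx$models, twice)
  ratio <- sum(c2$mrna) / sum(c1$mrna)
  expect_lt(abs(ratio - 2), 0.02 * 2)
})

test_that("aligned footprints conserve counts and respect geometry", {
  cfg <- tiny_config(seed = 4, n_genes = 25, depth = 5e3)
  tx <- generate_transcriptome(cfg)
  truth <- simulate_true_expression(cfg, tx$features)
  cm <- simulate_count_matrices(truth, tx$models, cfg)
  reads <- simulate_aligned_footprints(cm$rpf, tx$models, cfg)

  # exact bookkeeping: per-gene, per-sample read tallies equal the matrix
  gene_of <- setNames(tx$models$gene_id, tx$models$transcript_id)
  tally <- table(factor(gene_of[reads$transcript_id],
                        levels = rownames(cm$rpf)),
                 factor(reads$sample_id, levels = colnames(cm$rpf)))
  expect_equal(unclass(tally), unclass(cm$rpf), ignore_attr = TRUE)

  # geometry: lengths in the configured support, reads inside transcripts
  expect_true(all(reads$length %in% 28:32))
  idx <- match(reads$transcript_id, tx$models$transcript_id)
  expect_true(all(reads$five_prime_pos >= 0))
  expect_true(all(reads$five_prime_pos + reads$length <=
                    tx$models$length[idx]))
  # P-sites inside the CDS
  p <- reads$five_prime_pos + cfg$psite_offset
  expect_true(all(p >= tx$models$cds_start[idx] &
                    p < tx$models$cds_end[idx]))
})

test_that("pure frame-0 simulation yields a pure frame-0 distribution", {
  cfg <- tiny_config(seed = 6, n_genes = 20, depth = 5e3,
                     frame_probs = c(1, 0, 0))
  sim <- simulate_dataset(cfg)
  fr <- psite_frame_distribution(sim$reads, sim$models,
                                 cfg$psite_offset)
  expect_equal(fr$fractions, c(1, 0, 0))
})

test_that("fixture bundles round-trip and have stable checksums", {
  cfg <- tiny_config(seed = 10, n_genes = 12, depth = 2e3)
  sim <- simulate_dataset(cfg)
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- write_fixture_bundle(sim, d1)
  m2 <- write_fixture_bundle(simulate_dataset(cfg), d2)
  expect_identical(m1$md5, m2$md5)
  expect_identical(m1$md5,
                   unname(tools::md5sum(file.path(d1, m1$file))))

  models2 <- read_transcript_table(file.path(d1, "transcripts.tsv"))
  expect_equal(models2, sim$models, ignore_attr = TRUE)
  seqs2 <- read_fasta(file.path(d1, "sequences.fa"))
  expect_identical(seqs2, sim$sequences)
  counts2 <- read_count_matrix(file.path(d1, "counts_rpf.tsv"))
  expect_identical(counts2, sim$counts_rpf)
  reads2 <- read_aligned_reads(file.path(d1, "reads_rpf.tsv"), sim$models)
  expect_equal(reads2, sim$reads, ignore_attr = TRUE)
})
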