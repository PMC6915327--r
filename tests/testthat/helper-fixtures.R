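# Small shared fixtures, all built in code.

tiny_config <- function(seed = 1L, n_genes = 30L, depth = 2e4, ...) {
  sim_config(seed = seed, n_genes = n_genes, depth = depth,
             cds_codons_min = 50L, cds_codons_max = 120L, ...)
}

# A hand-sized transcript table: ids, lengths and CDS picked for easy
# mental arithmetic.
toy_models <- function() {
  data.frame(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = c("g1", "g2", "g3"),
    length = c(300L, 500L, 120L),
    cds_start = c(50L, 100L, 10L),
    cds_end = c(200L, 400L, 100L),
    stringsAsFactors = FALSE
  )
}

toy_reads <- function(transcript_id, five_prime_pos, length = 30L,
                      sample_id = "s1", assay = "RPF") {
  n <- max(lengths(list(transcript_id, five_prime_pos)))
  data.frame(
    transcript_id = rep_len(transcript_id, n),
    five_prime_pos = as.integer(rep_len(five_prime_pos, n)),
    length = as.integer(rep_len(length, n)),
    sample_id = rep_len(sample_id, n),
    assay = rep_len(assay, n),
    read_id = sprintf("r%d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

random_models <- function(n, seed = 42L) {
  set.seed(seed)
  cds_codons <- sample(10:100, n, replace = TRUE)
  utr5 <- sample(0:200, n, replace = TRUE)
  utr3 <- sample(0:300, n, replace = TRUE)
  data.frame(
    transcript_id = sprintf("t%04d", seq_len(n)),
    gene_id = sprintf("g%04d", seq_len(n)),
    length = utr5 + 3L * cds_codons + utr3,
    cds_start = utr5,
    cds_end = utr5 + 3L * cds_codons,
    stringsAsFactors = FALSE
  )
}

random_dna <- function(n, len_max = 300L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample.int(len_max, 1L),
                 replace = TRUE), collapse = "")
  }, character(1))
}

# --- Independent brute-force oracles -----------------------------------

# BH step-up computed from the definition: q_(i) = min_{j >= i}
# min(1, n * p_(j) / j), mapped back to input order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(n * ps[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Per-read frame assignment, one read at a time.
oracle_frames <- function(reads, models, offset) {
  counts <- c(0, 0, 0)
  excluded <- 0
  for (i in seq_len(nrow(reads))) {
    m <- models[models$transcript_id == reads$transcript_id[i], ]
    p <- reads$five_prime_pos[i] + offset
    if (p >= m$cds_start && p < m$cds_end) {
      f <- (p - m$cds_start) %% 3
      counts[f + 1] <- counts[f + 1] + 1
    } else {
      excluded <- excluded + 1
    }
  }
  list(fractions = counts / sum(counts), n_excluded = excluded)
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables (same margins) no more probable
# than the observed one.
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[, 1])
  n <- sum(tab[, 2])
  k <- sum(tab[1, ])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# TOP motif by whole-vector logic (no character-by-character while loop):
# pyrimidine indicator, cumulative product from position 2.
oracle_top <- function(s, min_tract = 4) {
  chars <- strsplit(s, "")[[1]]
  if (length(chars) == 0 || chars[1] != "C") {
    return(list(has_top = FALSE, tract = 0))
  }
  pyr <- chars[-1] %in% c("C", "T")
  run <- if (length(pyr) == 0) 0 else sum(cumprod(as.integer(pyr)))
  list(has_top = run >= min_tract, tract = run)
}

# uORF count by exhaustive enumeration of every (ATG, stop) position pair
# in the same frame, requiring no in-frame stop strictly between them, the
# whole ORF inside the sequence, and enough codons before the stop.
oracle_uorfs <- function(s, min_codons = 2) {
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  codon <- function(i) substr(s, i, i + 2)
  atg_pos <- Filter(function(i) codon(i) == "ATG", seq_len(max(0, n - 2)))
  stop_pos <- Filter(function(i) codon(i) %in% stops,
                     seq_len(max(0, n - 2)))
  count <- 0
  for (i in atg_pos) {
    for (j in stop_pos) {
      if (j <= i || (j - i) %% 3 != 0 || j + 2 > n) next
      between <- setdiff(seq(i + 3, j, by = 3), j)
      if (any(vapply(between, function(k) codon(k) %in% stops,
                     logical(1)))) {
        next
      }
      if ((j - i) / 3 >= min_codons) count <- count + 1
      break  # only the first in-frame stop terminates this ORF
    }
  }
  count
}

# Pearson correlation from the raw definitional sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}
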