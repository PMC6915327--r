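BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Codons used for planted uORF bodies. Chosen so that no "ATG" and no stop
# codon can arise inside a planted uORF, in any frame, including across
# codon junctions and across the junctions with the ATG start and the TAA
# stop (no codon ends in "A" while another starts with "TG", none ends in
# "AT", none starts with "TG").
UORF_BODY_CODONS <- c("GCT", "GCC", "CTG", "CCT", "TCC", "GGA", "CAA", "GAA")

random_bases <- function(n, gc) {
  if (n <= 0) return(character(0))
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

draw_lengths <- function(n, mean, sd, min) {
  pmax(as.integer(min), as.integer(round(stats::rnorm(n, mean, sd))))
}

# Replace the middle T of every ATG occurrence not listed in `keep_starts`
# (1-based positions of planted uORF starts) with C. C is not a letter of
# "ATG", so the substitution can never create a new occurrence.
destroy_unplanted_atg <- function(chars, keep_starts) {
  n <- length(chars)
  if (n < 3L) return(chars)
  i <- seq_len(n - 2L)
  hits <- i[chars[i] == "A" & chars[i + 1L] == "T" & chars[i + 2L] == "G"]
  hits <- setdiff(hits, keep_starts)
  if (length(hits)) chars[hits + 1L] <- "C"
  chars
}

build_utr5 <- function(len, is_top, n_uorfs, gc) {
  # planted segments
  prefix <- if (is_top) {
    tract <- sample(4:8, 1L)
    c("C", sample(c("C", "T"), tract, replace = TRUE))
  } else {
    sample(c("A", "G"), 1L)
  }
  uorfs <- lapply(seq_len(n_uorfs), function(k) {
    body <- sample(UORF_BODY_CODONS, sample(1:3, 1L), replace = TRUE)
    c("A", "T", "G", strsplit(paste(body, collapse = ""), "")[[1L]],
      "T", "A", "A")
  })
  planted_len <- length(prefix) + sum(lengths(uorfs))
  len <- max(len, planted_len + n_uorfs + 1L)
  spare <- len - planted_len
  # distribute background between/around planted segments
  n_gaps <- n_uorfs + 1L
  gap_len <- as.vector(stats::rmultinom(1L, spare, rep(1, n_gaps)))
  pieces <- list(prefix)
  for (k in seq_len(n_uorfs)) {
    gap <- random_bases(gap_len[k], gc)
    # a TOP tract must terminate before the background continues
    if (k == 1L && is_top && length(gap)) gap[1L] <- sample(c("A", "G"), 1L)
    pieces <- c(pieces, list(gap), list(uorfs[[k]]))
  }
  tail_gap <- random_bases(gap_len[n_gaps], gc)
  if (n_uorfs == 0L && is_top && length(tail_gap)) {
    tail_gap[1L] <- sample(c("A", "G"), 1L)
  }
  pieces <- c(pieces, list(tail_gap))
  chars <- unlist(pieces, use.names = FALSE)
  # 1-based starts of planted uORF ATGs in the assembled UTR
  starts <- integer(0)
  if (n_uorfs > 0L) {
    pos <- length(prefix)
    for (k in seq_len(n_uorfs)) {
      pos <- pos + gap_len[k]
      starts <- c(starts, pos + 1L)
      pos <- pos + length(uorfs[[k]])
    }
  }
  destroy_unplanted_atg(chars, starts)
}

build_cds <- function(n_codons) {
  all_codons <- as.vector(outer(
    as.vector(outer(BASES, BASES, paste0)), BASES, paste0))
  sense <- setdiff(all_codons, STOP_CODONS)
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Generate a synthetic transcriptome
#'
#' Builds one transcript per gene: a 5' UTR with configurable length, GC
#' content and planted TOP / uORF elements, a CDS that starts with ATG,
#' ends with a stop codon and contains no internal in-frame stop, and a 3'
#' UTR. Planted motifs are exact: a TOP-planted UTR begins with C followed
#' by >= 4 pyrimidines and then a purine; a uORF-planted UTR contains the
#' planted number of fully-contained upstream ORFs and no accidental ones
#' (every non-planted ATG in the UTR is removed during assembly), so motif
#' scanners can be validated with zero tolerance.
#'
#' @param config a [sim_config()].
#' @return list with `models` (transcript table: `transcript_id`,
#'   `gene_id`, `length`, `cds_start`, `cds_end`; coordinates 0-based
#'   half-open, stop codon included in the CDS), `sequences` (named
#'   character vector of transcript sequences) and `features` (per-gene
#'   planted-feature table: realized UTR length/GC, TOP flag, uORF count).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "transcriptome"), {
    n <- config$n_genes
    wid <- max(4L, nchar(as.character(n)))
    gene_id <- sprintf("g%0*d", wid, seq_len(n))
    transcript_id <- sprintf("tx%0*d", wid, seq_len(n))

    n_top <- round(config$top_fraction * n)
    n_uorf <- round(config$uorf_fraction * n)
    is_top <- logical(n)
    is_top[sample.int(n, n_top)] <- TRUE
    uorf_count <- integer(n)
    uorf_genes <- sample.int(n, n_uorf)
    uorf_count[uorf_genes] <- sample(1:2, n_uorf, replace = TRUE)

    utr5_len <- draw_lengths(n, config$utr5_length_mean,
                             config$utr5_length_sd, config$utr5_length_min)
    utr3_len <- draw_lengths(n, config$utr3_length_mean,
                             config$utr3_length_sd, config$utr3_length_min)
    n_codons <- sample(seq(config$cds_codons_min, config$cds_codons_max),
                       n, replace = TRUE)

    seqs <- character(n)
    real_utr5_len <- integer(n)
    gc_percent <- numeric(n)
    for (i in seq_len(n)) {
      utr5 <- build_utr5(utr5_len[i], is_top[i], uorf_count[i],
                         config$utr5_gc_target)
      real_utr5_len[i] <- length(utr5)
      gc_percent[i] <- 100 * sum(utr5 %in% c("G", "C")) / length(utr5)
      seqs[i] <- paste0(paste(utr5, collapse = ""),
                        build_cds(n_codons[i]),
                        paste(random_bases(utr3_len[i],
                                           config$utr5_gc_target),
                              collapse = ""))
    }
    names(seqs) <- transcript_id

    models <- data.frame(
      transcript_id = transcript_id,
      gene_id = gene_id,
      length = real_utr5_len + 3L * n_codons + utr3_len,
      cds_start = real_utr5_len,
      cds_end = real_utr5_len + 3L * n_codons,
      stringsAsFactors = FALSE
    )
    features <- data.frame(
      gene_id = gene_id,
      utr5_length = real_utr5_len,
      utr5_gc_percent = gc_percent,
      planted_top = is_top,
      planted_uorfs = uorf_count,
      stringsAsFactors = FALSE
    )
    list(models = models, sequences = seqs, features = features)
  })
}

#' Simulate ground-truth expression and translational efficiency
#'
#' Draws per-gene mRNA abundance (log-normal, identical across conditions:
#' the simulated contrast is purely translational) and a baseline
#' translational efficiency, then plants TE effects: a configured fraction
#' of genes has its TE in the second condition multiplied (`up`) or divided
#' (`down`) by `te_effect_fold`, exactly. Class counts follow the
#' configured fractions with deterministic rounding.
#'
#' @param config a [sim_config()].
#' @param features optional per-gene feature table from
#'   [generate_transcriptome()]; its columns are carried into the truth
#'   table.
#' @return the truth table: one row per gene with columns `gene_id`,
#'   `class` (`up` / `down` / `null`), per-condition `abundance_*` and
#'   `te_*`, plus any planted-feature columns.
#' @export
simulate_true_expression <- function(config, features = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "expression"), {
    n <- config$n_genes
    wid <- max(4L, nchar(as.character(n)))
    gene_id <- if (!is.null(features)) features$gene_id else {
      sprintf("g%0*d", wid, seq_len(n))
    }
    abundance <- stats::rlnorm(n, config$expression_logmean,
                               config$expression_logsd)
    te_base <- stats::rlnorm(n, 0, config$te_logsd)

    n_up <- round(config$dtg_up_fraction * n)
    n_down <- round(config$dtg_down_fraction * n)
    ord <- sample.int(n)
    class <- rep("null", n)
    if (n_up > 0) class[ord[seq_len(n_up)]] <- "up"
    if (n_down > 0) class[ord[n_up + seq_len(n_down)]] <- "down"

    te_b <- te_base
    te_b[class == "up"] <- te_base[class == "up"] * config$te_effect_fold
    te_b[class == "down"] <- te_base[class == "down"] / config$te_effect_fold

    truth <- data.frame(gene_id = gene_id, class = class,
                        stringsAsFactors = FALSE)
    truth[[paste0("abundance_", config$conditions[1])]] <- abundance
    truth[[paste0("abundance_", config$conditions[2])]] <- abundance
    truth[[paste0("te_", config$conditions[1])]] <- te_base
    truth[[paste0("te_", config$conditions[2])]] <- te_b
    if (!is.null(features)) {
      truth <- merge(truth, features, by = "gene_id", sort = FALSE)
      truth <- truth[match(gene_id, truth$gene_id), , drop = FALSE]
      rownames(truth) <- NULL
    }
    truth
  })
}

truth_column <- function(truth, prefix, condition) {
  col <- paste0(prefix, "_", condition)
  if (!col %in% names(truth)) {
    stop("truth table has no column '", col, "'", call. = FALSE)
  }
  truth[[col]]
}

#' Simulate footprint and total-mRNA count matrices
#'
#' Expected counts follow the standard sampling model for RNA-seq style
#' libraries: the expected mRNA count of gene *i* in a library is
#' proportional to abundance x transcript length, and the expected
#' footprint (RPF) count to abundance x TE x transcript length, scaled so
#' each library's expected total equals `depth`. Counts are drawn
#' negative-binomial with `variance = mu + dispersion * mu^2`;
#' `dispersion = 0` gives Poisson.
#'
#' @param truth truth table from [simulate_true_expression()].
#' @param models transcript table from [generate_transcriptome()].
#' @param config a [sim_config()].
#' @return list with integer matrices `rpf` and `mrna` (genes x samples,
#'   samples named `<condition>_rep<k>`) and the sample-to-condition map.
#' @export
simulate_count_matrices <- function(truth, models, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth <= 0) stop_config("depth must be > 0")
  len <- models$length[match(truth$gene_id, models$gene_id)]
  if (anyNA(len)) {
    stop("truth and transcript table cover different genes", call. = FALSE)
  }
  with_seed(derive_seed(config$seed, "counts"), {
    n <- nrow(truth)
    cmap <- condition_map(config)
    samples <- names(cmap)
    draw <- function(mu) {
      if (config$dispersion == 0) {
        stats::rpois(length(mu), mu)
      } else {
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
      }
    }
    rpf <- mrna <- matrix(0L, nrow = n, ncol = length(samples),
                          dimnames = list(truth$gene_id, samples))
    for (s in samples) {
      cond <- cmap[[s]]
      abund <- truth_column(truth, "abundance", cond)
      te <- truth_column(truth, "te", cond)
      w_m <- abund * len
      w_r <- abund * te * len
      mrna[, s] <- as.integer(draw(config$depth * w_m / sum(w_m)))
      rpf[, s] <- as.integer(draw(config$depth * w_r / sum(w_r)))
    }
    list(rpf = rpf, mrna = mrna, condition_map = cmap)
  })
}

#' Simulate transcriptome-aligned ribosome footprints
#'
#' Expands a footprint count matrix into individual aligned reads. Each
#' read's length is drawn from the configured footprint length
#' distribution, its P-site reading frame from `frame_probs`, and its
#' P-site codon uniformly among CDS positions compatible with the frame,
#' the P-site offset and the transcript bounds (reads never extend past
#' either transcript end). Genes whose CDS cannot accommodate any read are
#' skipped with a warning.
#'
#' @param counts_rpf integer matrix of footprint counts (genes x samples).
#' @param models transcript table.
#' @param config a [sim_config()].
#' @param samples columns of `counts_rpf` to expand (default all).
#' @return data.frame of aligned reads: `transcript_id`, `five_prime_pos`
#'   (0-based), `length`, `sample_id`, `assay` (`"RPF"`), `read_id`.
#' @export
simulate_aligned_footprints <- function(counts_rpf, models, config,
                                        samples = colnames(counts_rpf)) {
  stopifnot(inherits(config, "sim_config"))
  idx <- match(rownames(counts_rpf), models$gene_id)
  if (anyNA(idx)) {
    stop("count matrix contains genes absent from the transcript table",
         call. = FALSE)
  }
  tx_id <- models$transcript_id[idx]
  cs <- models$cds_start[idx]
  cl <- models$cds_end[idx] - models$cds_start[idx]
  tl <- models$length[idx]
  off <- config$psite_offset
  lens <- as.integer(names(config$footprint_length_probs))

  with_seed(derive_seed(config$seed, "reads"), {
    out <- vector("list", length(samples))
    n_dropped <- 0L
    for (k in seq_along(samples)) {
      s <- samples[k]
      cnt <- counts_rpf[, s]
      g <- rep(seq_along(cnt), cnt)
      nr <- length(g)
      if (nr == 0L) next
      len <- sample(lens, nr, replace = TRUE,
                    prob = config$footprint_length_probs)
      frame <- sample(0:2, nr, replace = TRUE, prob = config$frame_probs)
      jmin <- pmax(0, ceiling((off - cs[g] - frame) / 3))
      jmax <- pmin(floor((cl[g] - 1 - frame) / 3),
                   floor((tl[g] - len + off - cs[g] - frame) / 3))
      ok <- jmax >= jmin
      n_dropped <- n_dropped + sum(!ok)
      j <- jmin + floor(stats::runif(nr) * (jmax - jmin + 1))
      j <- pmin(j, jmax)
      five <- cs[g] + 3 * j + frame - off
      out[[k]] <- data.frame(
        transcript_id = tx_id[g][ok],
        five_prime_pos = as.integer(five[ok]),
        length = len[ok],
        sample_id = s,
        assay = "RPF",
        read_id = sprintf("%s:r%d", s, seq_len(nr)[ok]),
        stringsAsFactors = FALSE
      )
    }
    if (n_dropped > 0L) {
      warning(n_dropped,
              " read(s) skipped: CDS too short to place a footprint",
              call. = FALSE)
    }
    reads <- do.call(rbind, out)
    if (is.null(reads)) {
      reads <- data.frame(transcript_id = character(0),
                          five_prime_pos = integer(0), length = integer(0),
                          sample_id = character(0), assay = character(0),
                          read_id = character(0), stringsAsFactors = FALSE)
    }
    rownames(reads) <- NULL
    reads
  })
}

#' Downsample a count matrix to a per-sample read budget
#'
#' Multinomial thinning: columns whose total exceeds `max_per_sample` are
#' resampled to that total with probabilities proportional to the original
#' counts. Used to keep read-level QC affordable at high depth.
#'
#' @param counts integer matrix (genes x samples).
#' @param max_per_sample read budget per column.
#' @param seed seed for the thinning draw.
#' @return integer matrix of the same shape.
#' @export
downsample_counts <- function(counts, max_per_sample, seed = 1L) {
  with_seed(derive_seed(seed, "downsample"), {
    out <- counts
    for (s in seq_len(ncol(counts))) {
      tot <- sum(counts[, s])
      if (tot > max_per_sample) {
        out[, s] <- as.integer(stats::rmultinom(1L, max_per_sample,
                                                counts[, s]))
      }
    }
    out
  })
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper chaining [generate_transcriptome()],
#' [simulate_true_expression()], [simulate_count_matrices()] and
#' (optionally) [simulate_aligned_footprints()]. All randomness derives
#' from `config$seed`; identical configurations give byte-identical output.
#'
#' @param config a [sim_config()].
#' @param reads generate aligned footprint reads as well?
#' @param max_reads_per_sample cap on reads per sample for the read-level
#'   output (counts are multinomially thinned above the cap; the full
#'   count matrices are returned untouched).
#' @return list: `config`, `models`, `sequences`, `features`, `truth`,
#'   `counts_rpf`, `counts_mrna`, `condition_map`, and `reads` (or NULL).
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1, n_genes = 30, depth = 2e4))
#' dim(sim$counts_rpf)
#' @export
simulate_dataset <- function(config, reads = TRUE,
                             max_reads_per_sample = Inf) {
  tx <- generate_transcriptome(config)
  truth <- simulate_true_expression(config, tx$features)
  cm <- simulate_count_matrices(truth, tx$models, config)
  rd <- NULL
  if (reads) {
    rc <- if (is.finite(max_reads_per_sample)) {
      downsample_counts(cm$rpf, max_reads_per_sample, config$seed)
    } else {
      cm$rpf
    }
    rd <- simulate_aligned_footprints(rc, tx$models, config)
  }
  list(config = config, models = tx$models, sequences = tx$sequences,
       features = tx$features, truth = truth,
       counts_rpf = cm$rpf, counts_mrna = cm$mrna,
       condition_map = cm$condition_map, reads = rd)
}

#' Write a complete fixture bundle to disk
#'
#' Persists every component of a simulated dataset in the package's
#' plain-text formats (FASTA, TSV, YAML) together with a manifest of MD5
#' checksums, so a bundle can be verified and re-read losslessly.
#'
#' @param sim result of [simulate_dataset()].
#' @param outdir output directory (created if absent).
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
write_fixture_bundle <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create directory: ", outdir)
  hash <- object_hash(unclass(sim$config))
  files <- character(0)
  p <- function(f) file.path(outdir, f)

  write_fasta(sim$sequences, p("sequences.fa"))
  files <- c(files, "sequences.fa")
  write_transcript_table(sim$models, p("transcripts.tsv"),
                         config_hash = hash)
  files <- c(files, "transcripts.tsv")
  write_tsv_with_header(sim$truth, p("truth.tsv"), "truth table", hash)
  files <- c(files, "truth.tsv")
  write_count_matrix(sim$counts_rpf, p("counts_rpf.tsv"), assay = "RPF",
                     config_hash = hash)
  write_count_matrix(sim$counts_mrna, p("counts_mrna.tsv"), assay = "MRNA",
                     config_hash = hash)
  files <- c(files, "counts_rpf.tsv", "counts_mrna.tsv")
  if (!is.null(sim$reads)) {
    write_aligned_reads(sim$reads, p("reads_rpf.tsv"), config_hash = hash)
    files <- c(files, "reads_rpf.tsv")
  }
  cfg <- unclass(sim$config)
  cfg$footprint_length_probs <- as.list(cfg$footprint_length_probs)
  yaml::write_yaml(cfg, p("config.yaml"))
  files <- c(files, "config.yaml")

  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(manifest)
}
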