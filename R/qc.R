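#' Footprint length histogram
#'
#' Tallies ribosome footprint lengths and reports the fraction falling in
#' a canonical window (default 28-32 nt, the size range of intact
#' mammalian ribosome-protected fragments).
#'
#' @param reads aligned-read data.frame (RPF reads).
#' @param canonical length window `c(min, max)` in nt.
#' @return list with `histogram` (named integer vector, names are
#'   lengths), `canonical_fraction` and `n_reads`.
#' @examples
#' r <- data.frame(transcript_id = "t", five_prime_pos = 0L,
#'                 length = c(28L, 28L, 30L), sample_id = "s",
#'                 assay = "RPF")
#' footprint_length_histogram(r)$histogram
#' @export
footprint_length_histogram <- function(reads, canonical = c(28L, 32L)) {
  if (is.null(reads) || nrow(reads) == 0L) {
    stop("no footprints: cannot compute a length histogram",
         call. = FALSE)
  }
  tab <- table(reads$length)
  hist <- stats::setNames(as.integer(tab), names(tab))
  frac <- sum(reads$length >= canonical[1] & reads$length <= canonical[2]) /
    nrow(reads)
  list(histogram = hist, canonical_fraction = frac, n_reads = nrow(reads))
}

# P-site positions and CDS-relative frames for a read set; NA frame for
# reads whose P-site falls outside the CDS.
psite_frames <- function(reads, models, psite_offset) {
  idx <- match(reads$transcript_id, models$transcript_id)
  if (anyNA(idx)) {
    stop("reads reference transcripts absent from the annotation",
         call. = FALSE)
  }
  p <- reads$five_prime_pos + psite_offset
  cs <- models$cds_start[idx]
  ce <- models$cds_end[idx]
  inside <- p >= cs & p < ce
  frame <- ifelse(inside, (p - cs) %% 3L, NA_integer_)
  list(psite = p, frame = frame, inside = inside, cds_start = cs)
}

#' P-site reading-frame distribution
#'
#' Infers each footprint's P-site as its 5' end plus a fixed offset and
#' reports the fraction of CDS-internal P-sites in each reading frame
#' relative to the CDS start. Genuinely translating footprints concentrate
#' in frame 0; reads whose P-site falls outside the CDS are excluded from
#' the fractions but reported.
#'
#' @param reads aligned-read data.frame.
#' @param models transcript table.
#' @param psite_offset P-site offset from the 5' end (nt).
#' @return list with `fractions` (length-3 numeric, frames 0/1/2),
#'   `n_included`, `n_excluded` and `excluded_fraction`.
#' @export
psite_frame_distribution <- function(reads, models, psite_offset = 12L) {
  pf <- psite_frames(reads, models, psite_offset)
  inc <- pf$frame[!is.na(pf$frame)]
  if (length(inc) == 0L) {
    stop("no reads with a CDS-internal P-site", call. = FALSE)
  }
  fractions <- as.vector(tabulate(inc + 1L, nbins = 3L)) / length(inc)
  list(fractions = fractions,
       n_included = length(inc),
       n_excluded = sum(is.na(pf$frame)),
       excluded_fraction = mean(is.na(pf$frame)))
}

#' Metagene profile around the CDS start
#'
#' Accumulates P-site counts by position relative to the CDS start codon
#' across all genes. A 3-nt periodic sawtooth beginning at position 0 is
#' the classic signature of elongating ribosomes. Transcripts shorter than
#' the window contribute only their valid positions.
#'
#' @param reads aligned-read data.frame.
#' @param models transcript table.
#' @param window `c(upstream, downstream)` extent in nt: positions
#'   `-upstream .. downstream` relative to the CDS start are profiled.
#' @param psite_offset P-site offset from the 5' end (nt).
#' @return data.frame with `position` (relative to CDS start) and `count`.
#' @export
metagene_profile <- function(reads, models, window = c(50L, 150L),
                             psite_offset = 12L) {
  idx <- match(reads$transcript_id, models$transcript_id)
  if (anyNA(idx)) {
    stop("reads reference transcripts absent from the annotation",
         call. = FALSE)
  }
  rel <- reads$five_prime_pos + psite_offset - models$cds_start[idx]
  pos <- seq(-window[1], window[2])
  keep <- rel >= -window[1] & rel <= window[2]
  if (!any(keep)) {
    warning("no P-sites fall inside the metagene window", call. = FALSE)
  }
  count <- tabulate(rel[keep] + window[1] + 1L, nbins = length(pos))
  data.frame(position = pos, count = count)
}

# Share of metagene signal at period 3: discrete Fourier amplitude at
# frequency 1/3, normalized by total counts. Reported as a secondary
# periodicity score alongside the in-frame fraction.
periodicity_score <- function(profile) {
  counts <- profile$count[profile$position >= 0]
  if (sum(counts) == 0) return(NA_real_)
  k <- seq_along(counts) - 1L
  amp <- Mod(sum(counts * exp(-2i * pi * k / 3)))
  amp / sum(counts)
}

#' Pairwise replicate reproducibility (r-squared of log RPKM)
#'
#' Squared Pearson correlation of log10(RPKM + pseudocount) between every
#' pair of samples, restricted per pair to genes expressed (RPKM > 0) in
#' both samples. The pseudocount is per sample: half that sample's
#' smallest RPKM among the retained genes of the pair, so the statistic is
#' exactly invariant to rescaling a sample (a log-scale shift).
#' High-quality replicate libraries reproduce at r-squared above 0.9.
#'
#' @param rpkm numeric matrix of RPKM values (genes x samples).
#' @return symmetric matrix of squared correlations with unit diagonal.
#' @export
replicate_correlation <- function(rpkm) {
  if (is.null(dim(rpkm)) || ncol(rpkm) < 2L) {
    stop("replicate correlation needs at least 2 samples", call. = FALSE)
  }
  ns <- ncol(rpkm)
  r2 <- diag(1, ns)
  dimnames(r2) <- list(colnames(rpkm), colnames(rpkm))
  for (i in seq_len(ns - 1L)) {
    for (j in seq(i + 1L, ns)) {
      x <- rpkm[, i]
      y <- rpkm[, j]
      sel <- x > 0 & y > 0
      if (sum(sel) < 2L) {
        stop("fewer than 2 genes expressed in both samples ",
             colnames(rpkm)[i], " and ", colnames(rpkm)[j], call. = FALSE)
      }
      r2[i, j] <- r2[j, i] <-
        stats::cor(log10(x[sel] + 0.5 * min(x[sel])),
                   log10(y[sel] + 0.5 * min(y[sel])))^2
    }
  }
  r2
}

#' Default QC thresholds
#'
#' @param canonical footprint length window (nt).
#' @param min_canonical_fraction minimum fraction of footprints inside the
#'   canonical window.
#' @param min_in_frame minimum frame-0 fraction for the periodicity flag
#'   (a uniform 1/3 per frame fails; dominant frame 0 passes).
#' @param min_r2 minimum pairwise replicate r-squared, per assay.
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(canonical = c(28L, 32L),
                          min_canonical_fraction = 0.8,
                          min_in_frame = 0.6,
                          min_r2 = 0.9) {
  list(canonical = canonical,
       min_canonical_fraction = min_canonical_fraction,
       min_in_frame = min_in_frame,
       min_r2 = min_r2)
}

#' Aggregate footprint-library QC into a report
#'
#' Combines the length histogram, frame distribution, metagene profile and
#' per-assay replicate correlations into one report with pass flags
#' against the supplied thresholds. An r-squared flag with fewer than two
#' replicates is reported as not evaluable (NA) rather than pass/fail.
#'
#' @param length_hist result of [footprint_length_histogram()].
#' @param frames result of [psite_frame_distribution()].
#' @param metagene result of [metagene_profile()].
#' @param r2_rpf,r2_mrna replicate r-squared matrices (or NULL if a single
#'   replicate makes them not evaluable).
#' @param thresholds a [qc_thresholds()] list.
#' @param condition_map optional named character vector mapping sample ids
#'   to conditions; when given, the r-squared pass flags consider only
#'   same-condition (biological replicate) pairs, since cross-condition
#'   pairs legitimately diverge when translation differs.
#' @return object of class `qc_report`.
#' @export
qc_summary <- function(length_hist, frames, metagene,
                       r2_rpf = NULL, r2_mrna = NULL,
                       thresholds = qc_thresholds(),
                       condition_map = NULL) {
  min_offdiag <- function(m) {
    if (is.null(m) || ncol(m) < 2L) return(NA_real_)
    pair <- upper.tri(m)
    if (!is.null(condition_map)) {
      cond <- condition_map[colnames(m)]
      same <- outer(cond, cond, "==")
      pair <- pair & same
      if (!any(pair)) return(NA_real_)
    }
    min(m[pair])
  }
  r2min <- c(RPF = min_offdiag(r2_rpf), MRNA = min_offdiag(r2_mrna))
  flags <- list(
    length_canonical =
      length_hist$canonical_fraction >= thresholds$min_canonical_fraction,
    periodicity = frames$fractions[1] >= thresholds$min_in_frame,
    replicate_r2_rpf = if (is.na(r2min[["RPF"]])) NA else {
      r2min[["RPF"]] >= thresholds$min_r2
    },
    replicate_r2_mrna = if (is.na(r2min[["MRNA"]])) NA else {
      r2min[["MRNA"]] >= thresholds$min_r2
    }
  )
  structure(list(
    length_histogram = length_hist$histogram,
    canonical_fraction = length_hist$canonical_fraction,
    frame_fractions = frames$fractions,
    in_frame_fraction = frames$fractions[1],
    psite_outside_cds_fraction = frames$excluded_fraction,
    metagene = metagene,
    periodicity_score = periodicity_score(metagene),
    replicate_r2_min = r2min,
    replicate_r2_rpf = r2_rpf,
    replicate_r2_mrna = r2_mrna,
    thresholds = thresholds,
    pass_flags = flags
  ), class = "qc_report")
}

#' Run all QC metrics on a dataset
#'
#' @param reads RPF aligned-read data.frame.
#' @param models transcript table.
#' @param rpkm_rpf,rpkm_mrna RPKM matrices per assay (optional; replicate
#'   correlation is skipped when absent).
#' @param psite_offset P-site offset (nt).
#' @param window metagene window `c(upstream, downstream)`.
#' @param thresholds a [qc_thresholds()] list.
#' @param condition_map optional sample-to-condition map; see
#'   [qc_summary()].
#' @return object of class `qc_report`.
#' @export
run_qc <- function(reads, models, rpkm_rpf = NULL, rpkm_mrna = NULL,
                   psite_offset = 12L, window = c(50L, 150L),
                   thresholds = qc_thresholds(), condition_map = NULL) {
  qc_summary(
    footprint_length_histogram(reads, thresholds$canonical),
    psite_frame_distribution(reads, models, psite_offset),
    metagene_profile(reads, models, window, psite_offset),
    r2_rpf = if (!is.null(rpkm_rpf) && ncol(rpkm_rpf) >= 2L) {
      replicate_correlation(rpkm_rpf)
    },
    r2_mrna = if (!is.null(rpkm_mrna) && ncol(rpkm_mrna) >= 2L) {
      replicate_correlation(rpkm_mrna)
    },
    thresholds = thresholds,
    condition_map = condition_map
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("ribote QC report\n")
  cat(sprintf("  footprints in canonical window: %.1f%%\n",
              100 * x$canonical_fraction))
  cat(sprintf("  frame fractions (0/1/2): %.3f / %.3f / %.3f\n",
              x$frame_fractions[1], x$frame_fractions[2],
              x$frame_fractions[3]))
  cat(sprintf("  periodicity score (period-3 DFT): %.3f\n",
              x$periodicity_score))
  cat(sprintf("  min replicate r2: RPF %s, mRNA %s\n",
              format(x$replicate_r2_min[["RPF"]], digits = 3),
              format(x$replicate_r2_min[["MRNA"]], digits = 3)))
  for (f in names(x$pass_flags)) {
    v <- x$pass_flags[[f]]
    cat(sprintf("  [%s] %s\n",
                if (is.na(v)) "n/a " else if (v) "PASS" else "FAIL", f))
  }
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report a `qc_report`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_qc_report <- function(report, path) {
  out <- list(
    length_histogram = as.list(report$length_histogram),
    canonical_fraction = report$canonical_fraction,
    frame_fractions = report$frame_fractions,
    in_frame_fraction = unname(report$in_frame_fraction),
    psite_outside_cds_fraction = report$psite_outside_cds_fraction,
    periodicity_score = report$periodicity_score,
    replicate_r2_min = as.list(report$replicate_r2_min),
    thresholds = report$thresholds,
    pass_flags = report$pass_flags
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
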