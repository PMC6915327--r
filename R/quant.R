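#' Count aligned reads per gene
#'
#' Assigns each read to its transcript's gene and tallies counts per
#' sample. With `region = "transcript"` every read counts; with
#' `region = "cds"` only reads whose P-site (5' end + offset) lies inside
#' the CDS count. The gene universe is taken from the transcript table, so
#' genes without reads appear with zero counts.
#'
#' @param reads aligned-read data.frame (one assay).
#' @param models transcript table.
#' @param psite_offset P-site offset (nt), used only for `region = "cds"`.
#' @param region counting region, `"transcript"` or `"cds"`.
#' @param strict error on reads referencing unknown transcripts (default);
#'   `FALSE` skips them and reports the number skipped as an attribute.
#' @return integer matrix (genes x samples) with attribute `n_skipped`.
#' @export
count_reads <- function(reads, models, psite_offset = 12L,
                        region = c("transcript", "cds"),
                        strict = TRUE) {
  region <- match.arg(region)
  idx <- match(reads$transcript_id, models$transcript_id)
  if (anyNA(idx)) {
    if (strict) {
      bad <- reads$transcript_id[which(is.na(idx))[1L]]
      stop("read references unknown transcript '", bad, "'",
           call. = FALSE)
    }
    keep <- !is.na(idx)
    n_skipped <- sum(!keep)
    reads <- reads[keep, , drop = FALSE]
    idx <- idx[keep]
  } else {
    n_skipped <- 0L
  }
  samples <- sort(unique(reads$sample_id))
  if (region == "cds") {
    p <- reads$five_prime_pos + psite_offset
    keep <- p >= models$cds_start[idx] & p < models$cds_end[idx]
    reads <- reads[keep, , drop = FALSE]
    idx <- idx[keep]
  }
  genes <- unique(models$gene_id)
  m <- matrix(0L, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  if (nrow(reads)) {
    tab <- table(factor(models$gene_id[idx], levels = genes),
                 factor(reads$sample_id, levels = samples))
    m[] <- as.integer(tab)
  }
  attr(m, "n_skipped") <- n_skipped
  m
}

#' Convert raw counts to RPKM
#'
#' Reads Per Kilobase of transcript per Million mapped reads:
#' `RPKM_i = count_i / ((length_i / 1e3) * (library_size / 1e6))`, where
#' the library size is the per-sample sum of gene-assigned counts of the
#' supplied matrix (computed before any low-count filtering).
#'
#' @param counts integer matrix (genes x samples).
#' @param models transcript table supplying gene lengths (`length_i` =
#'   transcript length), or NULL if `lengths` is given directly.
#' @param lengths optional named numeric vector of gene lengths (nt)
#'   overriding `models`.
#' @return numeric RPKM matrix of the same shape.
#' @examples
#' m <- matrix(c(10L, 0L), 2, 1,
#'             dimnames = list(c("g1", "g2"), "s1"))
#' tx <- data.frame(transcript_id = c("t1", "t2"),
#'                  gene_id = c("g1", "g2"),
#'                  length = c(1000L, 500L), cds_start = 0L, cds_end = 300L)
#' # library size 10: RPKM = 10 / (1 * 10 / 1e6) = 1e6
#' compute_rpkm(m, tx)
#' @export
compute_rpkm <- function(counts, models = NULL, lengths = NULL) {
  if (is.null(lengths)) {
    if (is.null(models)) {
      stop("supply either a transcript table or a lengths vector",
           call. = FALSE)
    }
    lengths <- stats::setNames(models$length, models$gene_id)
  }
  len <- lengths[rownames(counts)]
  if (anyNA(len)) {
    stop("no length for gene(s): ",
         paste(utils::head(rownames(counts)[is.na(len)], 3),
               collapse = ", "), call. = FALSE)
  }
  if (any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(sweep(counts, 1, len / 1e3, "/"), 2, lib / 1e6, "/")
}

#' Discard genes with too few reads
#'
#' A gene is retained only if, in each assay separately, its raw counts
#' summed over that assay's samples reach `min_reads`; genes below the
#' threshold in either assay are discarded (default: fewer than 40 reads).
#'
#' @param counts_rpf,counts_mrna integer count matrices over the same
#'   gene universe.
#' @param min_reads retention threshold (a gene with summed counts `<
#'   min_reads` in an assay is discarded).
#' @return list with `retained` (character vector of gene ids) and
#'   `discarded` (data.frame: `gene_id`, `rpf_total`, `mrna_total`,
#'   `failed_assay`).
#' @export
filter_low_count_genes <- function(counts_rpf, counts_mrna,
                                   min_reads = 40L) {
  if (!identical(sort(rownames(counts_rpf)), sort(rownames(counts_mrna)))) {
    stop("count matrices cover different gene universes", call. = FALSE)
  }
  counts_mrna <- counts_mrna[rownames(counts_rpf), , drop = FALSE]
  rpf_total <- rowSums(counts_rpf)
  mrna_total <- rowSums(counts_mrna)
  ok_rpf <- rpf_total >= min_reads
  ok_mrna <- mrna_total >= min_reads
  keep <- ok_rpf & ok_mrna
  failed <- ifelse(!ok_rpf & !ok_mrna, "both",
                   ifelse(!ok_rpf, "RPF", "MRNA"))
  list(
    retained = rownames(counts_rpf)[keep],
    discarded = data.frame(
      gene_id = rownames(counts_rpf)[!keep],
      rpf_total = unname(rpf_total[!keep]),
      mrna_total = unname(mrna_total[!keep]),
      failed_assay = failed[!keep],
      stringsAsFactors = FALSE
    )
  )
}

#' Per-condition translational efficiency
#'
#' TE is footprint RPKM divided by total-mRNA RPKM: for each condition,
#' the RPKM of each assay is averaged over that condition's replicates and
#' the ratio of the two means is taken. TE is undefined (NA) where the
#' mRNA mean is zero; such genes are listed in the `undefined` component.
#'
#' @param rpkm_rpf,rpkm_mrna RPKM matrices over the same genes.
#' @param condition_map named character vector mapping sample ids (names)
#'   to condition labels (values); samples of both matrices must appear.
#' @return list with `te` (genes x conditions numeric matrix) and
#'   `undefined` (data.frame: `gene_id`, `condition`).
#' @export
compute_te <- function(rpkm_rpf, rpkm_mrna, condition_map) {
  if (!identical(sort(rownames(rpkm_rpf)), sort(rownames(rpkm_mrna)))) {
    stop("RPKM matrices cover different gene universes", call. = FALSE)
  }
  rpkm_mrna <- rpkm_mrna[rownames(rpkm_rpf), , drop = FALSE]
  conditions <- unique(unname(condition_map))
  cond_mean <- function(m, cond) {
    s <- intersect(colnames(m), names(condition_map)[condition_map == cond])
    if (length(s) == 0L) {
      stop("condition '", cond, "' has no samples in one assay",
           call. = FALSE)
    }
    rowMeans(m[, s, drop = FALSE])
  }
  te <- matrix(NA_real_, nrow = nrow(rpkm_rpf), ncol = length(conditions),
               dimnames = list(rownames(rpkm_rpf), conditions))
  undef <- list()
  for (cond in conditions) {
    r <- cond_mean(rpkm_rpf, cond)
    m <- cond_mean(rpkm_mrna, cond)
    v <- ifelse(m > 0, r / m, NA_real_)
    te[, cond] <- v
    if (any(m == 0)) {
      undef[[cond]] <- data.frame(
        gene_id = rownames(rpkm_rpf)[m == 0], condition = cond,
        stringsAsFactors = FALSE)
    }
  }
  undefined <- if (length(undef)) do.call(rbind, undef) else {
    data.frame(gene_id = character(0), condition = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(undefined) <- NULL
  list(te = te, undefined = undefined)
}
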