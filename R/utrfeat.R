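#' Extract 5' UTR sequences
#'
#' The 5' UTR is the transcript sequence upstream of the CDS start,
#' `sequence[0, cds_start)` in 0-based half-open coordinates. An empty UTR
#' (`cds_start = 0`) is allowed and flagged.
#'
#' @param models transcript table.
#' @param sequences named character vector of transcript sequences.
#' @return data.frame: `gene_id`, `transcript_id`, `utr5_seq`, `no_utr`
#'   flag.
#' @export
extract_five_prime_utr <- function(models, sequences) {
  seqs <- sequences[models$transcript_id]
  if (anyNA(seqs)) {
    stop("missing sequence for transcript(s): ",
         paste(utils::head(
           models$transcript_id[is.na(seqs)], 3), collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(seqs) != models$length)) {
    stop("sequence length disagrees with annotated transcript length",
         call. = FALSE)
  }
  utr <- substr(seqs, 1L, models$cds_start)
  data.frame(gene_id = models$gene_id,
             transcript_id = models$transcript_id,
             utr5_seq = unname(utr),
             no_utr = models$cds_start == 0L,
             stringsAsFactors = FALSE)
}

#' 5' UTR length and GC content
#'
#' GC percent is `100 * (G + C) / (A + C + G + T)`; N bases are excluded
#' from the denominator. All-N (or empty) sequences get NA GC and are
#' flagged.
#'
#' @param utr_sequences character vector of A/C/G/T/N sequences.
#' @return data.frame: `utr5_length`, `gc_percent`, `gc_undefined`.
#' @export
compute_length_gc <- function(utr_sequences) {
  n <- nchar(utr_sequences)
  count_of <- function(base) {
    nchar(utr_sequences) - nchar(gsub(base, "", utr_sequences, fixed = TRUE))
  }
  gc <- count_of("G") + count_of("C")
  acgt <- gc + count_of("A") + count_of("T")
  data.frame(utr5_length = n,
             gc_percent = ifelse(acgt > 0, 100 * gc / acgt, NA_real_),
             gc_undefined = acgt == 0)
}

#' Detect a 5' terminal oligopyrimidine (TOP) motif
#'
#' A TOP mRNA starts (at the cap) with a C followed by an uninterrupted
#' pyrimidine tract. The scanner reports `has_top = TRUE` when position 1
#' is `C` and the maximal run of pyrimidines (C/T) starting at position 2
#' has length at least `min_tract`; `tract_length` is that run length
#' (reported up to `max_check`), or the sub-threshold run length when the
#' motif is absent.
#'
#' @param utr_sequences character vector of 5' UTR sequences.
#' @param min_tract minimum pyrimidine-tract length after the initial C.
#' @param max_check cap on the reported tract length.
#' @return data.frame: `has_top`, `top_tract_length`.
#' @examples
#' detect_top_motif(c("CTTTTCAG", "GTTTT", "CTTAG"))
#' @export
detect_top_motif <- function(utr_sequences, min_tract = 4L,
                             max_check = 15L) {
  scan_one <- function(s) {
    if (is.na(s) || nchar(s) == 0L) return(c(FALSE, 0L))
    chars <- strsplit(s, "")[[1L]]
    if (chars[1L] != "C") return(c(FALSE, 0L))
    run <- 0L
    i <- 2L
    while (i <= length(chars) && run < max_check &&
             chars[i] %in% c("C", "T")) {
      run <- run + 1L
      i <- i + 1L
    }
    c(run >= min_tract, run)
  }
  m <- vapply(utr_sequences, scan_one, numeric(2), USE.NAMES = FALSE)
  data.frame(has_top = as.logical(m[1L, ]),
             top_tract_length = as.integer(m[2L, ]))
}

#' Count upstream open reading frames
#'
#' Counts ORFs in the 5' UTR: an ATG with an in-frame stop codon
#' (TAA/TAG/TGA) such that the whole ORF, stop included, lies within the
#' UTR, with at least `min_codons` codons before the stop (the ATG counts
#' as a codon). Each distinct ATG start counts once, so overlapping starts
#' sharing a stop each contribute.
#'
#' @param utr_sequences character vector of 5' UTR sequences.
#' @param min_codons minimum codons (including the ATG) before the stop.
#' @return integer vector of uORF counts.
#' @examples
#' detect_uorfs("AAATGGCTTAAAA")  # ATG GCT TAA -> 1
#' @export
detect_uorfs <- function(utr_sequences, min_codons = 2L) {
  count_one <- function(s) {
    if (is.na(s) || nchar(s) < 3L * (min_codons + 1L)) return(0L)
    chars <- strsplit(s, "")[[1L]]
    n <- length(chars)
    codon_at <- function(i) paste0(chars[i], chars[i + 1L], chars[i + 2L])
    count <- 0L
    for (i in seq_len(n - 2L)) {
      if (chars[i] != "A" || chars[i + 1L] != "T" || chars[i + 2L] != "G") {
        next
      }
      j <- i + 3L
      while (j + 2L <= n) {
        if (codon_at(j) %in% STOP_CODONS) {
          if ((j - i) / 3L >= min_codons) count <- count + 1L
          break
        }
        j <- j + 3L
      }
    }
    count
  }
  vapply(utr_sequences, count_one, integer(1), USE.NAMES = FALSE)
}

#' Build the per-gene 5' UTR feature table
#'
#' @param models transcript table.
#' @param sequences named character vector of transcript sequences.
#' @param groups optional named character vector (names are gene ids)
#'   assigning each gene a group label (e.g. DTG class); unnamed genes get
#'   `"background"`.
#' @param min_tract,min_codons motif-scanner parameters.
#' @return data.frame: `gene_id`, `utr5_length`, `gc_percent`, `has_top`,
#'   `top_tract_length`, `uorf_count`, `group`.
#' @export
utr_feature_table <- function(models, sequences, groups = NULL,
                              min_tract = 4L, min_codons = 2L) {
  utr <- extract_five_prime_utr(models, sequences)
  lg <- compute_length_gc(utr$utr5_seq)
  top <- detect_top_motif(utr$utr5_seq, min_tract = min_tract)
  grp <- rep("background", nrow(utr))
  if (!is.null(groups)) {
    hit <- match(utr$gene_id, names(groups))
    grp[!is.na(hit)] <- unname(groups[hit[!is.na(hit)]])
  }
  data.frame(gene_id = utr$gene_id,
             utr5_length = lg$utr5_length,
             gc_percent = lg$gc_percent,
             has_top = top$has_top,
             top_tract_length = top$top_tract_length,
             uorf_count = detect_uorfs(utr$utr5_seq,
                                       min_codons = min_codons),
             group = grp,
             stringsAsFactors = FALSE)
}

#' Compare 5' UTR features between gene groups
#'
#' Continuous features (UTR length, GC percent): one-way ANOVA across
#' groups followed by all-pairs two-sample t comparisons with Bonferroni
#' correction. Binary motif features (TOP presence, uORF presence): per
#' pair of groups, a 2x2 contingency table tested with a two-sided Fisher
#' exact test (Bonferroni-adjusted values reported alongside). Group
#' means +/- SEM are returned for every feature.
#'
#' @param records feature table from [utr_feature_table()], with a
#'   `group` column of >= 2 levels, each with >= 2 records.
#' @return list with `anova` (feature, F, p, or NA when degenerate),
#'   `pairwise` (feature, group1, group2, p_raw, p_bonferroni),
#'   `motifs` (feature, group1, group2, odds_ratio, p_fisher,
#'   p_bonferroni) and `group_summary`.
#' @export
compare_feature_groups <- function(records) {
  groups <- unique(records$group)
  if (length(groups) < 2L) {
    stop("need at least 2 groups to compare", call. = FALSE)
  }
  sizes <- table(records$group)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 records", call. = FALSE)
  }
  g <- factor(records$group, levels = groups)
  pairs <- utils::combn(as.character(groups), 2L)
  npairs <- ncol(pairs)

  continuous <- c("utr5_length", "gc_percent")
  anova_rows <- list()
  pair_rows <- list()
  for (feat in continuous) {
    x <- records[[feat]]
    ok <- is.finite(x)
    if (stats::var(x[ok]) == 0) {
      anova_rows[[feat]] <- data.frame(
        feature = feat, f = NA_real_, p = NA_real_, degenerate = TRUE)
      next
    }
    fit <- stats::aov(x[ok] ~ g[ok])
    s <- summary(fit)[[1L]]
    anova_rows[[feat]] <- data.frame(
      feature = feat, f = s[["F value"]][1L], p = s[["Pr(>F)"]][1L],
      degenerate = FALSE)
    for (k in seq_len(npairs)) {
      sel <- ok & g %in% pairs[, k]
      p_raw <- stats::t.test(x[sel] ~ droplevels(g[sel]))$p.value
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        feature = feat, group1 = pairs[1L, k], group2 = pairs[2L, k],
        p_raw = p_raw, p_bonferroni = min(1, p_raw * npairs))
    }
  }

  motif_rows <- list()
  motif_features <- list(has_top = records$has_top,
                         has_uorf = records$uorf_count > 0L)
  for (feat in names(motif_features)) {
    flag <- motif_features[[feat]]
    for (k in seq_len(npairs)) {
      sel <- g %in% pairs[, k]
      tab <- table(factor(flag[sel], levels = c(FALSE, TRUE)),
                   droplevels(g[sel]))
      ft <- stats::fisher.test(tab)
      motif_rows[[length(motif_rows) + 1L]] <- data.frame(
        feature = feat, group1 = pairs[1L, k], group2 = pairs[2L, k],
        odds_ratio = unname(ft$estimate), p_fisher = ft$p.value,
        p_bonferroni = min(1, ft$p.value * npairs))
    }
  }

  summ <- do.call(rbind, lapply(as.character(groups), function(grp) {
    r <- records[records$group == grp, ]
    data.frame(group = grp, n = nrow(r),
               utr5_length_mean = mean(r$utr5_length),
               utr5_length_sem = sem(r$utr5_length),
               gc_percent_mean = mean(r$gc_percent, na.rm = TRUE),
               gc_percent_sem = sem(r$gc_percent[is.finite(r$gc_percent)]),
               top_fraction = mean(r$has_top),
               uorf_fraction = mean(r$uorf_count > 0L))
  }))

  list(anova = do.call(rbind, anova_rows),
       pairwise = do.call(rbind, pair_rows),
       motifs = do.call(rbind, motif_rows),
       group_summary = summ)
}
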