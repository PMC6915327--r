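ASSAY_LEVELS <- c("RPF", "MRNA")

#' Read / write transcript sequences as FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()]; line-wrapped input is handled, and
#' sequences travel as a named character vector elsewhere in the package.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector of A/C/G/T/N sequences.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be named", call. = FALSE)
  }
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path, width = 70L)
  invisible(path)
}

validate_transcript_models <- function(df, path = "<in-memory>",
                                       lines = NULL) {
  loc <- function(i) {
    if (is.null(lines)) sprintf("row %d", i) else {
      sprintf("line %d", lines[i])
    }
  }
  need <- c("transcript_id", "gene_id", "length", "cds_start", "cds_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- which(duplicated(df$transcript_id))
  if (length(dup)) {
    stop(sprintf("%s %s: duplicate transcript_id '%s'", path,
                 loc(dup[1L]), df$transcript_id[dup[1L]]), call. = FALSE)
  }
  bad <- which(!(df$cds_start >= 0 & df$cds_start < df$cds_end &
                   df$cds_end <= df$length))
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf(
      "%s %s: CDS [%d, %d) invalid for transcript '%s' of length %d",
      path, loc(i), df$cds_start[i], df$cds_end[i],
      df$transcript_id[i], df$length[i]), call. = FALSE)
  }
  bad <- which((df$cds_end - df$cds_start) %% 3 != 0)
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf("%s %s: CDS length %d of '%s' is not a multiple of 3",
                 path, loc(i), df$cds_end[i] - df$cds_start[i],
                 df$transcript_id[i]), call. = FALSE)
  }
  invisible(df)
}

#' Read / write the transcript annotation table
#'
#' The canonical annotation dialect is a TSV with columns `transcript_id`,
#' `gene_id`, `length`, `cds_start`, `cds_end`; CDS coordinates are
#' transcript-space, 0-based, half-open, with the stop codon included in
#' the CDS. Leading `#` lines are comments. Reading validates every
#' invariant (CDS inside the transcript, CDS length a multiple of 3, no
#' duplicate ids) and rejects violations with the offending line number.
#'
#' @param path TSV file path.
#' @return data.frame of transcript models.
#' @export
read_transcript_table <- function(path) {
  r <- read_tsv_lines(path)
  df <- r$data
  validate_transcript_models(
    within(df, {
      length <- as.integer(parse_numeric(length, "length", path, r$lines))
      cds_start <- as.integer(parse_numeric(cds_start, "cds_start",
                                            path, r$lines))
      cds_end <- as.integer(parse_numeric(cds_end, "cds_end",
                                          path, r$lines))
    })[, c("transcript_id", "gene_id", "length", "cds_start", "cds_end")],
    path = path, lines = r$lines
  )
}

#' @rdname read_transcript_table
#' @param models transcript model data.frame.
#' @param config_hash optional provenance hash stamped into the header.
#' @export
write_transcript_table <- function(models, path, config_hash = NULL) {
  validate_transcript_models(models)
  write_tsv_with_header(
    models[, c("transcript_id", "gene_id", "length",
               "cds_start", "cds_end")],
    path, "transcript table", config_hash)
}

validate_aligned_reads <- function(df, models = NULL,
                                   path = "<in-memory>", lines = NULL) {
  loc <- function(i) {
    if (is.null(lines)) sprintf("row %d", i) else {
      sprintf("line %d", lines[i])
    }
  }
  bad <- which(!df$assay %in% ASSAY_LEVELS)
  if (length(bad)) {
    stop(sprintf("%s %s: unknown assay token '%s' (expected %s)", path,
                 loc(bad[1L]), df$assay[bad[1L]],
                 paste(ASSAY_LEVELS, collapse = "/")), call. = FALSE)
  }
  bad <- which(df$five_prime_pos < 0)
  if (length(bad)) {
    stop(sprintf("%s %s: negative five_prime_pos %d", path, loc(bad[1L]),
                 df$five_prime_pos[bad[1L]]), call. = FALSE)
  }
  bad <- which(df$length < 1)
  if (length(bad)) {
    stop(sprintf("%s %s: read length %d < 1", path, loc(bad[1L]),
                 df$length[bad[1L]]), call. = FALSE)
  }
  if (!is.null(models)) {
    idx <- match(df$transcript_id, models$transcript_id)
    bad <- which(is.na(idx))
    if (length(bad)) {
      stop(sprintf("%s %s: unknown transcript '%s'", path, loc(bad[1L]),
                   df$transcript_id[bad[1L]]), call. = FALSE)
    }
    bad <- which(df$five_prime_pos + df$length > models$length[idx])
    if (length(bad)) {
      i <- bad[1L]
      stop(sprintf(
        "%s %s: read [%d, %d) extends past the end of '%s' (length %d)",
        path, loc(i), df$five_prime_pos[i],
        df$five_prime_pos[i] + df$length[i], df$transcript_id[i],
        models$length[idx[i]]), call. = FALSE)
    }
  }
  invisible(df)
}

#' Read / write transcriptome-space aligned reads
#'
#' Aligned footprint or mRNA fragments as TSV: `transcript_id`,
#' `five_prime_pos` (0-based), `length`, `sample_id`, `assay`
#' (`RPF`/`MRNA`), `read_id`. When a transcript table is supplied the
#' reader runs in strict mode and rejects reads extending past their
#' transcript; unknown assay tokens and negative positions are always
#' rejected with the offending line.
#'
#' @param path TSV file path.
#' @param models optional transcript table enabling strict bounds checks.
#' @return data.frame of aligned reads.
#' @export
read_aligned_reads <- function(path, models = NULL) {
  r <- read_tsv_lines(path)
  df <- r$data
  need <- c("transcript_id", "five_prime_pos", "length", "sample_id",
            "assay")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$five_prime_pos <- as.integer(
    parse_numeric(df$five_prime_pos, "five_prime_pos", path, r$lines))
  df$length <- as.integer(
    parse_numeric(df$length, "length", path, r$lines))
  if (!"read_id" %in% names(df)) df$read_id <- NA_character_
  validate_aligned_reads(df, models, path = path, lines = r$lines)
}

#' @rdname read_aligned_reads
#' @param reads aligned-read data.frame.
#' @param config_hash optional provenance hash stamped into the header.
#' @export
write_aligned_reads <- function(reads, path, config_hash = NULL) {
  validate_aligned_reads(reads)
  write_tsv_with_header(
    reads[, c("transcript_id", "five_prime_pos", "length", "sample_id",
              "assay", "read_id")],
    path, "aligned reads", config_hash)
}

#' Read / write a gene x sample count matrix
#'
#' TSV with a `gene_id` key column and one integer column per sample.
#' Reading rejects negative, fractional or non-numeric cells and duplicate
#' gene ids, each with the offending line; round-trips are exact.
#'
#' @param path TSV file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  r <- read_tsv_lines(path)
  df <- r$data
  if (names(df)[1L] != "gene_id") {
    stop(path, ": first column must be 'gene_id'", call. = FALSE)
  }
  if (ncol(df) < 2L) stop(path, ": no sample columns", call. = FALSE)
  dup <- which(duplicated(df$gene_id))
  if (length(dup)) {
    stop(sprintf("%s line %d: duplicate gene_id '%s'", path,
                 r$lines[dup[1L]], df$gene_id[dup[1L]]), call. = FALSE)
  }
  m <- matrix(0L, nrow = nrow(df), ncol = ncol(df) - 1L,
              dimnames = list(df$gene_id, names(df)[-1L]))
  for (j in seq_len(ncol(df) - 1L)) {
    v <- parse_numeric(df[[j + 1L]], paste0("count in column '",
                                            names(df)[j + 1L], "'"),
                       path, r$lines)
    bad <- which(v < 0)
    if (length(bad)) {
      stop(sprintf("%s line %d: negative count %s", path,
                   r$lines[bad[1L]], format(v[bad[1L]])), call. = FALSE)
    }
    bad <- which(v != floor(v))
    if (length(bad)) {
      stop(sprintf("%s line %d: non-integer count %s", path,
                   r$lines[bad[1L]], format(v[bad[1L]])), call. = FALSE)
    }
    m[, j] <- as.integer(v)
  }
  m
}

#' @rdname read_count_matrix
#' @param counts integer matrix (genes x samples) with dimnames.
#' @param assay assay label recorded in the header comment.
#' @param config_hash optional provenance hash stamped into the header.
#' @export
write_count_matrix <- function(counts, path, assay = NULL,
                               config_hash = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must have gene rownames and sample colnames",
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  kind <- if (is.null(assay)) "count matrix" else {
    paste0("count matrix (", assay, ")")
  }
  write_tsv_with_header(df, path, kind, config_hash)
}
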