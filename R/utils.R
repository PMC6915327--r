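#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-stage substream: one master seed, fixed offsets, kept
# below .Machine$integer.max so set.seed() always accepts the value.
derive_seed <- function(seed, stage) {
  offsets <- c(
    transcriptome = 101L, expression = 202L, counts = 303L,
    reads = 404L, downsample = 505L, pipeline = 606L
  )
  if (!stage %in% names(offsets)) {
    stop("unknown RNG stage: ", stage, call. = FALSE)
  }
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(structure(
    class = c("ribote_config_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Stable hash of an R object (used to stamp output files so outputs from
# different configurations are distinguishable).
object_hash <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

# Header comment block prepended to every TSV the package writes.
ribote_header <- function(kind, config_hash = NULL) {
  lines <- c(
    sprintf("# ribote %s v1", kind),
    sprintf("# generated by ribote %s",
            as.character(utils::packageVersion("ribote")))
  )
  if (!is.null(config_hash)) {
    lines <- c(lines, sprintf("# config_hash: %s", config_hash))
  }
  lines
}

write_tsv_with_header <- function(df, path, kind, config_hash = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(ribote_header(kind, config_hash), con, sep = "\n")
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# Read a TSV written by the package (or hand-made in the same dialect):
# UTF-8, LF, leading '#' comment lines skipped. Returns the data.frame plus
# the original file line number of each data row, for parser diagnostics.
read_tsv_lines <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  body <- lines[keep]
  line_no <- which(keep)
  if (length(body) < 1L) {
    stop("no header row in ", path, call. = FALSE)
  }
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (length(body) == 1L) {
    df <- as.data.frame(matrix(character(0), nrow = 0,
                               ncol = length(header)),
                        stringsAsFactors = FALSE)
    names(df) <- header
    return(list(data = df, lines = integer(0), header = header))
  }
  cells <- strsplit(body[-1L], "\t", fixed = TRUE)
  ncol_seen <- lengths(cells)
  bad <- which(ncol_seen != length(header))
  if (length(bad)) {
    stop(sprintf("%s line %d: expected %d fields, found %d",
                 path, line_no[-1L][bad[1L]], length(header),
                 ncol_seen[bad[1L]]), call. = FALSE)
  }
  mat <- matrix(unlist(cells, use.names = FALSE),
                ncol = length(header), byrow = TRUE)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  list(data = df, lines = line_no[-1L], header = header)
}

# Strict numeric conversion: non-numeric text becomes an error, never NA.
parse_numeric <- function(x, what, path, lines) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("%s line %d: %s '%s' is not numeric",
                 path, lines[bad[1L]], what, x[bad[1L]]), call. = FALSE)
  }
  out
}

sem <- function(x) stats::sd(x) / sqrt(length(x))
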