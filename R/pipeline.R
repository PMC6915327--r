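#' Default run configuration
#'
#' The full parameter set for an end-to-end synthetic run: the simulation
#' block (see [sim_config()]) plus per-stage analysis parameters. A YAML
#' rendering ships with the package
#' (`system.file("extdata", "default_config.yaml", package = "ribote")`).
#'
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  cfg <- list(
    seed = seed,
    stages = c("simulate", "qc", "quant", "diffte", "utr"),
    simulate = unclass(sim_config(seed = seed)),
    qc = list(psite_offset = 12L, canonical_min = 28L, canonical_max = 32L,
              min_canonical_fraction = 0.8, min_in_frame = 0.6,
              min_r2 = 0.9, metagene_upstream = 50L,
              metagene_downstream = 150L, max_reads_per_sample = 1e5),
    quant = list(min_reads = 40L, region = "transcript"),
    diffte = list(lower_ratio = 0.667, upper_ratio = 1.5, alpha = 0.05,
                  standardization = "trimmed"),
    utr = list(min_tract = 4L, min_codons = 2L)
  )
  cfg$simulate$seed <- seed
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Reads a YAML run configuration (or takes an equivalent list), fills in
#' defaults for absent keys, and validates every parameter block,
#' reporting **all** violations at once rather than only the first.
#'
#' @param config path to a YAML file, or a list.
#' @return a validated `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_config("config file not found: ", config)
    }
    config <- yaml::read_yaml(config)
  }
  base <- default_run_config(seed = config$seed %||% 1L)
  for (block in c("qc", "quant", "diffte", "utr", "simulate")) {
    for (key in names(config[[block]])) {
      if (!key %in% names(base[[block]])) {
        stop_config("unknown key '", key, "' in block '", block, "'")
      }
      base[[block]][[key]] <- config[[block]][[key]]
    }
  }
  if (!is.null(config$stages)) base$stages <- config$stages
  for (key in c("annotation", "fasta", "reads", "counts_rpf",
                "counts_mrna")) {
    if (!is.null(config[[key]])) base[[key]] <- config[[key]]
  }

  errors <- character(0)
  note <- function(...) errors[[length(errors) + 1L]] <<- paste0(...)

  sim <- base$simulate
  if (!is.null(sim$footprint_length_probs)) {
    sim$footprint_length_probs <- unlist(sim$footprint_length_probs)
  }
  tryCatch(base$simulate <- do.call(sim_config, sim),
           error = function(e) note(conditionMessage(e)))

  d <- base$diffte
  if (!(is.numeric(d$alpha) && d$alpha > 0 && d$alpha < 1)) {
    note("diffte: alpha must lie in (0, 1), got ", format(d$alpha))
  }
  if (!(is.numeric(d$lower_ratio) && is.numeric(d$upper_ratio) &&
          d$lower_ratio > 0 && d$lower_ratio < 1 && d$upper_ratio > 1)) {
    note("diffte: require 0 < lower_ratio < 1 < upper_ratio")
  }
  if (!d$standardization %in% c("trimmed", "median_mad", "mean_sd")) {
    note("diffte: unknown standardization '", d$standardization, "'")
  }
  q <- base$quant
  if (!is_count(q$min_reads)) note("quant: min_reads must be an integer")
  if (!q$region %in% c("transcript", "cds")) {
    note("quant: region must be 'transcript' or 'cds'")
  }
  qc <- base$qc
  if (!is_count(qc$psite_offset)) {
    note("qc: psite_offset must be a non-negative integer")
  }
  if (!(qc$canonical_min <= qc$canonical_max)) {
    note("qc: canonical_min must not exceed canonical_max")
  }
  for (f in c("min_canonical_fraction", "min_in_frame", "min_r2")) {
    if (!is_fraction(qc[[f]])) note("qc: ", f, " must lie in [0, 1]")
  }
  u <- base$utr
  if (!is_count(u$min_tract) || u$min_tract < 1) {
    note("utr: min_tract must be a positive integer")
  }
  if (!is_count(u$min_codons) || u$min_codons < 1) {
    note("utr: min_codons must be a positive integer")
  }
  bad_stage <- setdiff(base$stages,
                       c("simulate", "qc", "quant", "diffte", "utr"))
  if (length(bad_stage)) {
    note("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  }
  for (key in c("annotation", "fasta", "reads")) {
    if (!is.null(base[[key]]) && !file.exists(base[[key]])) {
      note("referenced file for '", key, "' does not exist: ", base[[key]])
    }
  }
  if (length(errors)) {
    stop_config("invalid run config:\n  ",
                paste(errors, collapse = "\n  "))
  }
  base
}

#' Run the end-to-end pipeline
#'
#' Executes the configured stages in order — simulate, qc, quant, diffte,
#' utr — persisting every intermediate under `outdir` and writing a JSON
#' run report (package version, config hash, stage timings, QC pass
#' flags, DTG class counts). Re-running with an identical configuration
#' and seed reproduces identical result files.
#'
#' @param config a `run_config` (from [validate_config()] /
#'   [default_run_config()]) or a path to a YAML configuration.
#' @param outdir output directory.
#' @return invisibly, the run report list.
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- object_hash(unclass(config))
  report <- list(
    package_version = as.character(utils::packageVersion("ribote")),
    config_hash = hash,
    seed = config$seed,
    stages = list()
  )
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e) {
      report$stages[[name]] <<- list(status = "error",
                                     message = conditionMessage(e))
      write_run_report(report, outdir)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[name]] <<- list(
      status = "done",
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    value
  }
  stages <- config$stages
  sim <- NULL
  models <- sequences <- reads <- NULL
  counts_rpf <- counts_mrna <- NULL
  cmap <- NULL

  if ("simulate" %in% stages) {
    sim <- t_stage("simulate", {
      s <- simulate_dataset(config$simulate,
                            max_reads_per_sample =
                              config$qc$max_reads_per_sample)
      write_fixture_bundle(s, file.path(outdir, "simulate"))
      s
    })
    models <- sim$models
    sequences <- sim$sequences
    reads <- sim$reads
    counts_rpf <- sim$counts_rpf
    counts_mrna <- sim$counts_mrna
    cmap <- sim$condition_map
    conditions <- sim$config$conditions
  } else {
    models <- read_transcript_table(config$annotation)
    sequences <- if (!is.null(config$fasta)) read_fasta(config$fasta)
    reads <- if (!is.null(config$reads)) {
      read_aligned_reads(config$reads, models)
    }
    counts_rpf <- read_count_matrix(config$counts_rpf)
    counts_mrna <- read_count_matrix(config$counts_mrna)
    cmap <- stats::setNames(sub("_rep[0-9]+$", "", colnames(counts_rpf)),
                            colnames(counts_rpf))
    conditions <- unique(unname(cmap))
  }

  rpkm_rpf <- rpkm_mrna <- NULL
  te <- NULL
  retained <- NULL
  if ("quant" %in% stages) {
    qres <- t_stage("quant", {
      lengths <- stats::setNames(models$length, models$gene_id)
      rpkm_rpf <- compute_rpkm(counts_rpf, lengths = lengths)
      rpkm_mrna <- compute_rpkm(counts_mrna, lengths = lengths)
      filt <- filter_low_count_genes(counts_rpf, counts_mrna,
                                     config$quant$min_reads)
      te_all <- compute_te(rpkm_rpf[filt$retained, , drop = FALSE],
                           rpkm_mrna[filt$retained, , drop = FALSE],
                           cmap)
      qdir <- file.path(outdir, "quant")
      dir.create(qdir, showWarnings = FALSE)
      write_count_matrix(counts_rpf, file.path(qdir, "counts_rpf.tsv"),
                         assay = "RPF", config_hash = hash)
      write_count_matrix(counts_mrna, file.path(qdir, "counts_mrna.tsv"),
                         assay = "MRNA", config_hash = hash)
      write_matrix_tsv(rpkm_rpf, file.path(qdir, "rpkm_rpf.tsv"),
                       "RPKM (RPF)", hash)
      write_matrix_tsv(rpkm_mrna, file.path(qdir, "rpkm_mrna.tsv"),
                       "RPKM (MRNA)", hash)
      write_matrix_tsv(te_all$te, file.path(qdir, "te.tsv"), "TE", hash)
      write_tsv_with_header(filt$discarded,
                            file.path(qdir, "discarded.tsv"),
                            "discard log", hash)
      list(rpkm_rpf = rpkm_rpf, rpkm_mrna = rpkm_mrna,
           te = te_all$te, retained = filt$retained,
           n_discarded = nrow(filt$discarded))
    })
    rpkm_rpf <- qres$rpkm_rpf
    rpkm_mrna <- qres$rpkm_mrna
    te <- qres$te
    retained <- qres$retained
    report$n_genes_retained <- length(retained)
    report$n_genes_discarded <- qres$n_discarded
  }

  if ("qc" %in% stages) {
    qc_rep <- t_stage("qc", {
      rep_ <- run_qc(
        reads, models,
        rpkm_rpf = rpkm_rpf, rpkm_mrna = rpkm_mrna,
        psite_offset = config$qc$psite_offset,
        window = c(config$qc$metagene_upstream,
                   config$qc$metagene_downstream),
        thresholds = qc_thresholds(
          canonical = c(config$qc$canonical_min, config$qc$canonical_max),
          min_canonical_fraction = config$qc$min_canonical_fraction,
          min_in_frame = config$qc$min_in_frame,
          min_r2 = config$qc$min_r2),
        condition_map = cmap)
      dir.create(file.path(outdir, "qc"), showWarnings = FALSE)
      write_qc_report(rep_, file.path(outdir, "qc", "qc_report.json"))
      write_tsv_with_header(rep_$metagene,
                            file.path(outdir, "qc", "metagene.tsv"),
                            "metagene profile", hash)
      rep_
    })
    report$qc_pass_flags <- qc_rep$pass_flags
  }

  if ("diffte" %in% stages) {
    if (is.null(te)) {
      stop("stage 'diffte' requires stage 'quant'", call. = FALSE)
    }
    dres <- t_stage("diffte", {
      dcfg <- diffte_config(config$diffte$lower_ratio,
                            config$diffte$upper_ratio,
                            config$diffte$alpha,
                            config$diffte$standardization)
      res <- diffte_analysis(te, conditions[1], conditions[2], dcfg)
      conc <- transcription_concordance(rpkm_mrna, cmap,
                                        conditions[1], conditions[2])
      ddir <- file.path(outdir, "diffte")
      dir.create(ddir, showWarnings = FALSE)
      write_tsv_with_header(res, file.path(ddir, "diffte_results.tsv"),
                            "differential TE results", hash)
      jsonlite::write_json(
        list(class_counts = as.list(attr(res, "summary")),
             mrna_concordance_r2 = conc$r_squared),
        file.path(ddir, "summary.json"), auto_unbox = TRUE, digits = NA)
      list(res = res, conc = conc)
    })
    report$dtg_class_counts <- as.list(attr(dres$res, "summary"))
    report$mrna_concordance_r2 <- dres$conc$r_squared
  }

  if ("utr" %in% stages) {
    if (is.null(sequences)) {
      stop("stage 'utr' requires transcript sequences", call. = FALSE)
    }
    t_stage("utr", {
      groups <- NULL
      if ("diffte" %in% stages) {
        res <- read_tsv_lines(
          file.path(outdir, "diffte", "diffte_results.tsv"))$data
        lab <- c(up = paste0(conditions[1], "_repressed"),
                 down = paste0(conditions[2], "_repressed"))
        sel <- res$dtg_class %in% names(lab)
        groups <- stats::setNames(unname(lab[res$dtg_class[sel]]),
                                  res$gene_id[sel])
      }
      records <- utr_feature_table(models, sequences, groups = groups,
                                   min_tract = config$utr$min_tract,
                                   min_codons = config$utr$min_codons)
      udir <- file.path(outdir, "utr")
      dir.create(udir, showWarnings = FALSE)
      write_tsv_with_header(records, file.path(udir, "utr_features.tsv"),
                            "UTR feature table", hash)
      if (length(unique(records$group)) >= 2L &&
            all(table(records$group) >= 2L)) {
        cmp <- compare_feature_groups(records)
        write_tsv_with_header(cmp$group_summary,
                              file.path(udir, "group_summary.tsv"),
                              "UTR group summary", hash)
        write_tsv_with_header(cmp$pairwise,
                              file.path(udir, "pairwise_tests.tsv"),
                              "UTR pairwise tests", hash)
        write_tsv_with_header(cmp$motifs,
                              file.path(udir, "motif_tests.tsv"),
                              "UTR motif tests", hash)
      }
      NULL
    })
  }

  skipped <- setdiff(c("simulate", "qc", "quant", "diffte", "utr"), stages)
  if (length(skipped)) report$stages_skipped <- skipped
  write_run_report(report, outdir)
  invisible(report)
}

write_matrix_tsv <- function(m, path, kind, hash) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, kind, hash)
}

write_run_report <- function(report, outdir) {
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}
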