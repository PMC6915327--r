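#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic ribosome
#' profiling generator. The defaults describe the study design the rest of
#' the package is tested against: two conditions (`WT`, `2D`) with three
#' replicates each, paired footprint (RPF) and total-mRNA libraries,
#' log-normal transcript abundance with negative-binomial count noise,
#' footprint lengths concentrated on 28-32 nt with a mode at 29, dominant
#' frame-0 P-site periodicity, and a planted fraction of genes whose
#' translational efficiency changes 2.5-fold between conditions.
#'
#' @param seed integer master seed; every generator output is a pure
#'   function of the configuration including this seed.
#' @param n_genes number of genes (one transcript per gene).
#' @param n_replicates replicates per condition.
#' @param conditions character vector of exactly two condition labels;
#'   planted TE effects act on the second relative to the first.
#' @param utr5_length_mean,utr5_length_sd 5' UTR length distribution (nt);
#'   lengths are drawn normal, rounded, and clamped at `utr5_length_min`.
#' @param utr5_length_min minimum 5' UTR length (nt) so P-site offsets and
#'   planted motifs always fit.
#' @param utr5_gc_target target GC fraction of background UTR sequence.
#' @param top_fraction fraction of genes planted with a 5' terminal
#'   oligopyrimidine (TOP) motif: a cap-adjacent C followed by >= 4
#'   pyrimidines.
#' @param uorf_fraction fraction of genes planted with >= 1 upstream open
#'   reading frame fully contained in the 5' UTR.
#' @param cds_codons_min,cds_codons_max CDS length range in codons
#'   (including start and stop; the stop codon is part of the CDS).
#' @param utr3_length_mean,utr3_length_sd,utr3_length_min 3' UTR length
#'   distribution (nt).
#' @param expression_logmean,expression_logsd log-space (natural log)
#'   parameters of the log-normal mRNA abundance distribution.
#' @param te_logsd log-space spread of the per-gene baseline translational
#'   efficiency.
#' @param dispersion negative-binomial dispersion phi in
#'   `variance = mu + phi * mu^2`; 0 degrades to Poisson.
#' @param depth expected number of assigned reads per library.
#' @param dtg_up_fraction,dtg_down_fraction fractions of genes whose TE in
#'   the second condition is multiplied / divided by `te_effect_fold`.
#' @param te_effect_fold planted TE fold change (> 1; the default 2.5
#'   crosses the 0.667/1.5 classification thresholds).
#' @param frame_probs probabilities of P-site reading frames 0/1/2;
#'   must sum to 1.
#' @param footprint_length_probs named numeric vector: probability of each
#'   footprint length (names are lengths in nt); must sum to 1.
#' @param psite_offset P-site offset from the footprint 5' end (nt);
#'   +12 is the standard for 28-32 nt mammalian footprints.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50, depth = 1e4)
#' cfg$conditions
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_replicates = 3L,
                       conditions = c("WT", "2D"),
                       utr5_length_mean = 150,
                       utr5_length_sd = 50,
                       utr5_length_min = 25,
                       utr5_gc_target = 0.6,
                       top_fraction = 0.10,
                       uorf_fraction = 0.15,
                       cds_codons_min = 100L,
                       cds_codons_max = 500L,
                       utr3_length_mean = 300,
                       utr3_length_sd = 100,
                       utr3_length_min = 40,
                       expression_logmean = 3,
                       expression_logsd = 1,
                       te_logsd = 0.25,
                       dispersion = 0.02,
                       depth = 1e6,
                       dtg_up_fraction = 0.10,
                       dtg_down_fraction = 0.10,
                       te_effect_fold = 2.5,
                       frame_probs = c(0.85, 0.10, 0.05),
                       footprint_length_probs = c(
                         "28" = 0.15, "29" = 0.35, "30" = 0.25,
                         "31" = 0.15, "32" = 0.10
                       ),
                       psite_offset = 12L) {
  cfg <- list(
    seed = seed, n_genes = n_genes, n_replicates = n_replicates,
    conditions = conditions,
    utr5_length_mean = utr5_length_mean, utr5_length_sd = utr5_length_sd,
    utr5_length_min = utr5_length_min, utr5_gc_target = utr5_gc_target,
    top_fraction = top_fraction, uorf_fraction = uorf_fraction,
    cds_codons_min = cds_codons_min, cds_codons_max = cds_codons_max,
    utr3_length_mean = utr3_length_mean, utr3_length_sd = utr3_length_sd,
    utr3_length_min = utr3_length_min,
    expression_logmean = expression_logmean,
    expression_logsd = expression_logsd,
    te_logsd = te_logsd,
    dispersion = dispersion, depth = depth,
    dtg_up_fraction = dtg_up_fraction,
    dtg_down_fraction = dtg_down_fraction,
    te_effect_fold = te_effect_fold,
    frame_probs = frame_probs,
    footprint_length_probs = footprint_length_probs,
    psite_offset = psite_offset
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop_config("invalid simulation config: field '", field, "' ", why)
  }
  if (!is_count(cfg$seed)) fail("seed", "must be a non-negative integer")
  if (!is_count(cfg$n_genes) || cfg$n_genes < 1) {
    fail("n_genes", "must be a positive integer")
  }
  if (!is_count(cfg$n_replicates) || cfg$n_replicates < 1) {
    fail("n_replicates", "must be a positive integer")
  }
  if (length(cfg$conditions) != 2L || anyDuplicated(cfg$conditions)) {
    fail("conditions", "must be two distinct labels")
  }
  for (f in c("utr5_length_mean", "utr5_length_sd", "utr5_length_min",
              "utr3_length_mean", "utr3_length_sd", "utr3_length_min")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      fail(f, "must be non-negative")
    }
  }
  for (f in c("utr5_gc_target", "top_fraction", "uorf_fraction",
              "dtg_up_fraction", "dtg_down_fraction")) {
    if (!is_fraction(cfg[[f]])) fail(f, "must lie in [0, 1]")
  }
  if (cfg$dtg_up_fraction + cfg$dtg_down_fraction > 1) {
    fail("dtg_up_fraction", "plus dtg_down_fraction exceeds 1")
  }
  if (!is_count(cfg$cds_codons_min) || cfg$cds_codons_min < 3) {
    fail("cds_codons_min", "must be an integer >= 3")
  }
  if (!is_count(cfg$cds_codons_max) ||
      cfg$cds_codons_max < cfg$cds_codons_min) {
    fail("cds_codons_max", "must be an integer >= cds_codons_min")
  }
  for (f in c("expression_logsd", "te_logsd")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) fail(f, "must be >= 0")
  }
  if (!is.numeric(cfg$dispersion) || cfg$dispersion < 0) {
    fail("dispersion", "must be >= 0")
  }
  if (!is.numeric(cfg$depth) || cfg$depth <= 0) {
    fail("depth", "must be > 0")
  }
  if (!is.numeric(cfg$te_effect_fold) || cfg$te_effect_fold <= 1) {
    fail("te_effect_fold", "must be > 1")
  }
  fp <- cfg$frame_probs
  if (length(fp) != 3L || any(fp < 0) || abs(sum(fp) - 1) > 1e-9) {
    fail("frame_probs", "must be 3 non-negative values summing to 1")
  }
  lp <- cfg$footprint_length_probs
  if (is.null(names(lp)) || any(is.na(suppressWarnings(
        as.integer(names(lp)))))) {
    fail("footprint_length_probs", "must be named by integer lengths")
  }
  if (any(lp < 0) || abs(sum(lp) - 1) > 1e-9) {
    fail("footprint_length_probs",
         "must be non-negative and sum to 1")
  }
  if (!is_count(cfg$psite_offset)) {
    fail("psite_offset", "must be a non-negative integer")
  }
  if (cfg$psite_offset > cfg$utr5_length_min) {
    fail("psite_offset",
         "must not exceed utr5_length_min (reads must fit the transcript)")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("ribote simulation config\n")
  cat(sprintf("  %d genes, %s vs %s, %d replicates/condition\n",
              x$n_genes, x$conditions[1], x$conditions[2], x$n_replicates))
  cat(sprintf("  depth %.3g reads/library, dispersion %.3g\n",
              x$depth, x$dispersion))
  cat(sprintf("  planted DTGs: %.0f%% up, %.0f%% down at fold %.2f\n",
              100 * x$dtg_up_fraction, 100 * x$dtg_down_fraction,
              x$te_effect_fold))
  cat(sprintf("  seed %d\n", as.integer(x$seed)))
  invisible(x)
}

sample_names <- function(cfg) {
  as.vector(vapply(cfg$conditions, function(cond) {
    paste0(cond, "_rep", seq_len(cfg$n_replicates))
  }, character(cfg$n_replicates)))
}

#' Map sample names to conditions
#'
#' @param cfg a [sim_config()].
#' @return named character vector: names are sample ids, values conditions.
#' @export
condition_map <- function(cfg) {
  s <- sample_names(cfg)
  stats::setNames(rep(cfg$conditions, each = cfg$n_replicates), s)
}
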