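#' Build a run configuration
#'
#' Validates and assembles the options shared across pipeline stages.
#' All alphas must lie strictly inside (0, 1).
#'
#' @param trait_kind `"binary"` or `"quantitative"`.
#' @param alpha_power Alpha used inside the power calculators.
#' @param alpha_replication Alpha used to declare replication.
#' @param maf_min Discovery MAF filter (default 0.01).
#' @param exon_thresholds Near-exon distance cutoffs in bp.
#' @param models Model tags to fit (subset of I-IV, M1, M2).
#' @param power_threshold High-power stratum cutoff for the excess
#'   report.
#' @param sd_trait Trait SD for quantitative power.
#' @param seed Integer seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(trait_kind = "binary", alpha_power = 0.05,
                       alpha_replication = 0.05, maf_min = 0.01,
                       exon_thresholds = c(2000, 25000),
                       models = c("I", "II", "III", "IV"),
                       power_threshold = 0.6, sd_trait = 9.2,
                       seed = 1) {
  stopifnot(trait_kind %in% c("binary", "quantitative"),
            alpha_power > 0, alpha_power < 1,
            alpha_replication > 0, alpha_replication < 1,
            maf_min >= 0, maf_min < 0.5,
            all(exon_thresholds > 0),
            all(models %in% c("I", "II", "III", "IV", "M1", "M2")),
            power_threshold > 0, power_threshold < 1, sd_trait > 0)
  structure(list(trait_kind = trait_kind, alpha_power = alpha_power,
                 alpha_replication = alpha_replication,
                 maf_min = maf_min, exon_thresholds = exon_thresholds,
                 models = models, power_threshold = power_threshold,
                 sd_trait = sd_trait, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full power-replication analysis
#'
#' Orchestrates the whole chain: harmonize two summary tables, apply
#' the MAF filter, annotate exon distances, compute per-SNP power and
#' replication, fit the requested enrichment models, and produce the
#' excess-replication report. Writes tab-delimited tables, JSON fits
#' and a manifest (config and input hashes) into `out_dir`; the run is
#' deterministic given the config seed.
#'
#' @param disc,test Summary data frames (see [read_summary()]).
#' @param exons Exon interval table (see [read_exons_bed()]), or
#'   `NULL` to skip annotation (Models II/IV are then dropped).
#' @param config A [run_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List: `pairs`, `records`, `fits` (named by model tag),
#'   `excess`, `spline`, `manifest`.
#' @export
run_pipeline <- function(disc, test, exons = NULL,
                         config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_stage <- function(...) message("[powerrep] ", ...)
  pairs <- harmonize(disc, test, trait_kind = config$trait_kind)
  log_stage("harmonize: ", nrow(pairs), " shared SNPs")
  pairs <- apply_maf_filter(pairs, config$maf_min)
  log_stage("maf filter (> ", config$maf_min, "): ", nrow(pairs),
            " SNPs retained")
  if (nrow(pairs) == 0) stop("pipeline stage 'harmonize': no SNPs left")
  ann <- NULL
  models <- config$models
  if (!is.null(exons)) {
    ann <- nearest_exon_distance(pairs, exons,
                                 thresholds = config$exon_thresholds)
    log_stage("annotate: ", sum(!is.na(ann$exon_distance)),
              " SNPs within window of an exon")
  } else {
    models <- setdiff(models, c("II", "IV"))
  }
  records <- power_records(pairs, trait_kind = config$trait_kind,
                           alpha_power = config$alpha_power,
                           alpha_replication = config$alpha_replication,
                           sd_trait = config$sd_trait,
                           annotation = ann)
  log_stage("power: ", nrow(records), " records, ",
            sum(records$replicated), " replicated")
  fits <- list()
  for (m in models) {
    thr <- if (m %in% c("II", "IV")) config$exon_thresholds[1] else NULL
    fits[[m]] <- tryCatch(
      fit_model(records, m, near_exon_threshold_bp = thr),
      error = function(e) {
        log_stage("model ", m, " skipped: ", conditionMessage(e))
        NULL
      })
  }
  fits <- Filter(Negate(is.null), fits)
  excess <- excess_by_power(records, config$power_threshold)
  spl <- if (nrow(records) >= 50) spline_summary(records) else NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("powerrep")),
    config = unclass(config),
    n_disc = nrow(disc), n_test = nrow(test),
    n_pairs = nrow(pairs),
    input_hash = digest_tables(disc, test),
    timestamp = NULL  # kept out of the manifest so reruns hash alike
  )
  res <- list(pairs = pairs, records = records, fits = fits,
              excess = excess, spline = spl, manifest = manifest)
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

# order-insensitive content hash of the input tables (no external
# digest dependency: sum of a simple polynomial string hash)
digest_tables <- function(...) {
  tabs <- list(...)
  h <- 0
  for (tb in tabs) {
    s <- utils::capture.output(utils::write.csv(tb, row.names = FALSE))
    chars <- utf8ToInt(paste(s, collapse = "\n"))
    h <- (h + sum(chars * (seq_along(chars) %% 97 + 1))) %% 2^31
  }
  sprintf("%08x", h)
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$pairs, file.path(out_dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$records, file.path(out_dir, "records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in names(res$fits))
    write_fit_json(res$fits[[m]],
                   file.path(out_dir, paste0("fit_", m, ".json")))
  utils::write.table(res$excess$per_decile,
                     file.path(out_dir, "deciles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ex <- res$excess
  ex$per_decile <- NULL
  writeLines(jsonlite::toJSON(unclass(ex), auto_unbox = TRUE,
                              digits = NA),
             file.path(out_dir, "excess.json"))
  if (!is.null(res$spline))
    utils::write.table(res$spline, file.path(out_dir, "spline.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(res$manifest, auto_unbox = TRUE,
                              digits = NA, null = "null"),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' One-command synthetic end-to-end run
#'
#' Generates a synthetic study pair with [generate_study_pair()] and
#' pushes it through [run_pipeline()]; the convenience entry point for
#' demonstrations and smoke tests.
#'
#' @param preset `"synthetic-bd"` (case-control pair, 30% causal SNPs,
#'   causal effects concentrated near exons) or `"synthetic-null"`
#'   (no causal SNPs).
#' @param n_snps Number of SNPs (default 20000).
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return The [run_pipeline()] result, with the generating truth
#'   attached as `truth`.
#' @export
run_synthetic <- function(preset = c("synthetic-bd", "synthetic-null"),
                          n_snps = 20000, seed = 1, out_dir = NULL) {
  preset <- match.arg(preset)
  frac <- if (preset == "synthetic-bd") 0.3 else 0
  pair <- generate_study_pair(n_snps, frac_causal = frac,
                              exon_frac_near =
                                if (frac > 0) 0.9 else NULL,
                              seed = seed)
  cfg <- run_config(trait_kind = "binary",
                    exon_thresholds = c(2000, 10000, 25000),
                    seed = seed)
  res <- run_pipeline(pair$discovery, pair$test, exons = pair$exons,
                      config = cfg, out_dir = out_dir)
  res$truth <- pair$truth
  res
}
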