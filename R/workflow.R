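#' @title End-to-end pipeline
#'
#' @description
#' Orchestrates simulate -> connectivity -> graph features -> group
#' statistics / heritability / reliability / classification from a single
#' configuration with one master seed, expanded into per-stage child seeds
#' so stages re-run independently yet reproducibly.
#' @name workflow
NULL

#' Pipeline configuration
#'
#' @param cohort a [cohort_spec()] describing the synthetic cohort (or
#'   `NULL` if `cohort_obj` is supplied).
#' @param bands bands to analyse.
#' @param epoch_len_s PLV epoch length (default 3 s).
#' @param cost analysis cost (default 0.10).
#' @param run_gce_scan scan a representative subject for the GCE-optimal
#'   cost and record it (the fixed `cost` is still applied, mirroring the
#'   derive-once / apply-globally procedure).
#' @param n_boot bootstrap resamples for the group ANOVA.
#' @param n_reps classifier subsampling repetitions.
#' @param k cross-validation folds.
#' @param n_restarts modularity restarts.
#' @param pedigree_for_controls assign control subjects to MZ/DZ pairs (in
#'   manifest order) and estimate heritability of the graph features; needs
#'   >= 4 controls.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), bands = c("theta",
                            "alpha", "beta"), epoch_len_s = 3.0,
                            cost = 0.10, run_gce_scan = TRUE,
                            n_boot = 10000L, n_reps = 1000L, k = 10L,
                            n_restarts = 100L,
                            pedigree_for_controls = TRUE, seed = 7L) {
  stopifnot(cost > 0, cost <= 1, n_boot > 0, n_reps > 0, k > 1,
            n_restarts > 0, epoch_len_s > 0)
  stopifnot(all(bands %in% c("theta", "alpha", "beta")),
            !anyDuplicated(bands))
  structure(list(cohort = cohort, bands = bands, epoch_len_s = epoch_len_s,
                 cost = cost, run_gce_scan = run_gce_scan, n_boot = n_boot,
                 n_reps = n_reps, k = k, n_restarts = n_restarts,
                 pedigree_for_controls = pedigree_for_controls,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# controls paired off as MZ, DZ, then singletons, in manifest order
controls_pedigree <- function(manifest) {
  ids <- manifest$subject_id[manifest$group == "control"]
  n <- length(ids)
  if (n < 4) stop("pedigree stage needs at least 4 controls")
  n_pairs <- n %/% 2L
  n_mz <- ceiling(n_pairs / 2)
  zyg_fam <- c(rep("MZ", n_mz), rep("DZ", n_pairs - n_mz),
               rep("NT", n - 2L * n_pairs))
  fam_size <- ifelse(zyg_fam == "NT", 1L, 2L)
  data.frame(family_id = rep(sprintf("F%03d", seq_along(zyg_fam)), fam_size),
             individual_id = ids,
             father_id = "0", mother_id = "0",
             sex = manifest$sex[match(ids, manifest$subject_id)],
             zygosity = rep(zyg_fam, fam_size),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `manifest`, `features`
#'   (per-run and averaged), `gce` (optional scan), `group_stats`,
#'   `heritability` (optional), `reliability`, `classification` (one
#'   `classifier_report` per feature set), `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stats::setNames(child_seed(config$seed, 1:5),
                           c("simulate", "graph", "stats", "classify",
                             "pedigree"))
  spec <- config$cohort
  spec$seed <- seeds[["simulate"]]
  cohort <- generate_cohort(spec)
  if (config$k > nrow(cohort$manifest))
    stop("classify stage: k exceeds the number of subjects")

  gce <- NULL
  if (config$run_gce_scan) {
    run1 <- subject_runs(cohort, cohort$manifest$subject_id[1])[[1]]
    bc <- band_plv_matrix(run1, band = config$bands[1],
                          epoch_len_s = config$epoch_len_s)
    gce <- gce_scan(bc$matrix)
  }

  feats <- cohort_features(cohort, bands = config$bands, cost = config$cost,
                           epoch_len_s = config$epoch_len_s,
                           n_restarts = config$n_restarts,
                           seed = seeds[["graph"]])

  stats_tab <- group_stats_table(feats$averaged, n_boot = config$n_boot,
                                 seed = seeds[["stats"]])
  icc_tab <- icc_table(feats$per_run)

  herit <- NULL
  if (config$pedigree_for_controls) {
    ped <- controls_pedigree(cohort$manifest)
    fsub <- feats$averaged[feats$averaged$group == "control", ]
    herit <- h2_table(fsub, ped)
  }

  reports <- list()
  n_ctrl <- sum(cohort$manifest$group == "control")
  fsets <- config$bands
  if (length(fsets) > 1) fsets <- c(fsets, "all")
  for (fs in fsets) {
    cf <- classifier_features(feats$averaged, fs)
    reports[[fs]] <- balanced_repeated_cv(
      cf$x, cf$labels, n_reps = config$n_reps,
      n_controls_drawn = min(14L, n_ctrl), k = config$k,
      seed = seeds[["classify"]])
  }

  structure(list(manifest = cohort$manifest, features = feats, gce = gce,
                 group_stats = stats_tab, reliability = icc_tab,
                 heritability = herit, classification = reports,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("vnsnet")),
                   master_seed = config$seed, stage_seeds = as.list(seeds),
                   config = config[setdiff(names(config), "cohort")],
                   cohort_spec = unclass(config$cohort),
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "pipeline_result")
}

#' Write pipeline tables to a directory
#'
#' Each table is emitted as TSV plus a Markdown rendering; the provenance
#' record is written as JSON.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p_tsv <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, p_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p_md <- file.path(dir, paste0(name, ".md"))
    writeLines(markdown_table(df), p_md)
    paths <<- c(paths, p_tsv, p_md)
  }
  emit(result$manifest, "manifest")
  emit(result$features$averaged, "features_averaged")
  emit(result$features$per_run, "features_per_run")
  emit(result$group_stats, "group_stats")
  emit(result$reliability, "reliability")
  if (!is.null(result$heritability)) emit(result$heritability, "heritability")
  for (nm in names(result$classification)) {
    rep <- result$classification[[nm]]
    emit(as.data.frame(rep$confusion), paste0("confusion_", nm))
    emit(rep$metrics, paste0("metrics_", nm))
  }
  prov <- file.path(dir, "provenance.json")
  jsonlite::write_json(result$provenance, prov, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(c(paths, prov))
}

markdown_table <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 4,
                                                 format = "g"))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "),
                                           " |"))
  c(header, sep, body)
}
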