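#' Run the full label-noise detection pipeline
#'
#' End-to-end orchestration: read sequences and labels, transform, tune
#' the SVM, run the three-step misclassification analysis and (optionally)
#' the ensemble noise-rank filter, and write all report tables plus a run
#' manifest into an output directory. When several transforms are given,
#' per-transform candidate sets are written together with the ids frequent
#' under every transform (cross-transform agreement is treated as evidence
#' strength).
#'
#' @param fasta Path to the FASTA file.
#' @param labels Path to the `id<TAB>subtype` label TSV.
#' @param out_dir Output directory (created; all outputs live inside it).
#' @param transforms Character vector from `"aac"`, `"digram"`, `"acc"`,
#'   `"pdbt"`.
#' @param max_lag Lag for ACC/PDBT (default: 13 for ACC, 8 for PDBT).
#' @param classes Ordered class vocabulary; default order of first
#'   appearance in the label table.
#' @param config A [detector_config()].
#' @param tune_config An [svm_config()] for the grid search.
#' @param ensemble Run the ensemble noise-rank filter (default TRUE).
#' @param ensemble_cfg An [ensemble_config()]; its SVM point is replaced
#'   by the tuned one.
#' @param sanitize Sequence sanitization policy (see [read_fasta()]).
#' @return Invisibly, a named list of the per-transform `noise_report`
#'   objects plus the ensemble tables.
#' @export
run_pipeline <- function(fasta, labels, out_dir, transforms = "acc",
                         max_lag = NULL, classes = NULL,
                         config = detector_config(),
                         tune_config = svm_config(),
                         ensemble = TRUE,
                         ensemble_cfg = ensemble_config(),
                         sanitize = "drop") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_fasta(fasta, sanitize = sanitize)
  lab_tab <- read_labels(labels)
  dataset <- attach_labels(records, lab_tab, classes = classes)
  cls <- dataset_classes(dataset)

  tsv <- function(x, name) {
    write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  reports <- list()
  freq_ids <- list()
  for (tf in transforms) {
    X <- transform_dataset(dataset, tf, max_lag = max_lag)
    rep <- detect_candidates(X, dataset$label, config = config,
                             tune_config = tune_config, classes = cls)
    reports[[tf]] <- rep
    freq_ids[[tf]] <- rep$frequent$id
    suffix <- if (length(transforms) > 1) paste0("_", tf) else ""
    tsv(rep$candidates, paste0("candidates", suffix, ".tsv"))
    tsv(rep$frequent, paste0("frequent", suffix, ".tsv"))
    prof <- rep$profiles$profiles
    prof_flat <- dplyr::bind_cols(
      prof[, c("id", "true_class", "ER", "n_misclassified")],
      as_tibble(do.call(rbind, prof$assigned_counts),
                .name_repair = ~ paste0("as_", cls)),
      as_tibble(do.call(rbind, prof$votes_total),
                .name_repair = ~ paste0("votes_", cls)))
    tsv(prof_flat, paste0("profiles", suffix, ".tsv"))
    tsv(rep$profiles$iteration_metrics,
        paste0("iteration_metrics", suffix, ".tsv"))
  }
  if (length(transforms) > 1) {
    common <- Reduce(intersect, freq_ids)
    tsv(tibble(id = common), "frequent_common.tsv")
  }

  ens_out <- NULL
  if (ensemble) {
    tf1 <- transforms[1]
    X <- transform_dataset(dataset, tf1, max_lag = max_lag)
    ensemble_cfg$svm_C <- reports[[tf1]]$C_opt
    ensemble_cfg$svm_gamma <- reports[[tf1]]$gamma_opt
    flags <- run_ensemble(X, dataset$label, ensemble_cfg)
    ranked <- noise_rank(flags, ensemble_cfg$weights)
    cand <- ensemble_candidates(ranked, ensemble_cfg$min_failures,
                                length(ensemble_cfg$roster))
    ov <- overlap_report(cand$id, reports[[tf1]]$frequent$id)
    tsv(ranked, "noise_rank.tsv")
    tsv(cand, "ensemble_candidates.tsv")
    tsv(ov, "overlap.tsv")
    ens_out <- list(flags = flags, ranked = ranked, candidates = cand,
                    overlap = ov)
  }

  manifest <- list(
    package = "protnoise",
    version = as.character(utils::packageVersion("protnoise")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    inputs = list(fasta = unname(tools::md5sum(fasta)),
                  labels = unname(tools::md5sum(labels))),
    classes = cls,
    transforms = transforms,
    detector = unclass(config),
    svm = list(C_opt = map_dbl(reports, "C_opt"),
               gamma_opt = map_dbl(reports, "gamma_opt"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(reports, list(ensemble = ens_out)))
}
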