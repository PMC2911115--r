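#' Default run configuration
#'
#' A run configuration is a plain named list; [validate_config()] fills
#' defaults, normalizes key order and enforces the structural constraints
#' (nine active classifiers per factor under the default preset, constraint
#' bounds in (0, 1], positive motif windows).
#'
#' @param seed Integer run seed; per-stage child seeds are derived from it
#'   by fixed offsets.
#' @param ... Overrides of default fields (see [default_config()] output).
#' @return Canonical configuration list.
#' @export
default_config <- function(seed = 1L, ...) {
  validate_config(c(list(seed = seed), list(...)))
}

#' @rdname default_config
#' @param config Possibly partial configuration list (e.g. parsed from
#'   YAML with [read_config()]).
#' @export
validate_config <- function(config = list()) {
  defaults <- list(
    seed = 1L,
    tfs = c("mbp1", "swi4"),
    preset = "methods-text",
    pseudocount = 0.5,
    n_sets = 3L, set_size = 40L, ranks = c(10L, 20L, 30L),
    constraints = c(accuracy = 0.80, precision = 0.80, specificity = 0.90),
    mbf_motif = "ACGCGT", mbf_window = 200L,
    sbf_motif = "CRCGAA", sbf_window = 400L,
    weighted_study = "iyer",
    eps = 0.1,
    sim = list(),
    run_reports = TRUE,
    out_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  cfg <- cfg[names(defaults)]  # canonical field order regardless of input order
  if (!cfg$preset %in% c("methods-text", "file2-layout")) {
    abort("preset must be 'methods-text' or 'file2-layout'")
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) abort("seed must be set explicitly")
  if (any(cfg$constraints <= 0 | cfg$constraints > 1)) {
    abort("constraint values must lie in (0, 1]")
  }
  if (cfg$mbf_window <= 0 || cfg$sbf_window <= 0) abort("motif windows must be positive")
  for (tf in cfg$tfs) {
    n_active <- nrow(classifier_specs(tf, cfg$preset))
    if (n_active != 9L && !(tf == "swi4" && cfg$preset == "file2-layout")) {
      abort(sprintf("%s must run exactly nine classifiers, got %d", tf, n_active))
    }
  }
  cfg$sim <- do.call(sim_params, cfg$sim)
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return Canonical configuration list (see [validate_config()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("configuration file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if ("constraints" %in% names(raw)) raw$constraints <- unlist(raw$constraints)
  validate_config(raw)
}

config_hash <- function(config) {
  plain <- config
  plain$out_dir <- NULL  # where artifacts land does not change what they are
  plain$sim <- unclass(plain$sim)
  md5_of_text(paste(deparse(plain), collapse = "\n"))
}

#' Run the full synthetic evidence-integration pipeline
#'
#' Orchestrates simulate, classifier assembly, binning, LLS weight
#' training, scoring, cutoff selection and (optionally) the downstream
#' reports for both factors, as a seeded, reproducible run. Identical
#' configuration and seed yield byte-identical artifacts. Per-stage child
#' seeds derive from the run seed by fixed offsets so stages can be
#' replayed in isolation.
#'
#' @param config Configuration from [default_config()] /
#'   [validate_config()] / [read_config()].
#' @return A list of class `start_run` with elements `dataset`, `splits`,
#'   and per factor `matrix`, `binned`, `thresholds`, `weights`, `scores`,
#'   `classification`; plus `reports` (when `run_reports`), `manifest`
#'   (tibble of written artifacts with MD5 digests, empty without
#'   `out_dir`), `config`, and `warnings`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- validate_config(config)
  warnings <- character(0)
  dataset <- simulate_dataset(cfg$sim, seed = stage_seed(cfg$seed, "simulate"))
  splits <- split_truth_controls(dataset$truth, cfg$sim,
                                 seed = stage_seed(cfg$seed, "controls"))
  per_tf <- purrr::map(stats::setNames(cfg$tfs, cfg$tfs), function(tf) {
    motif <- if (tf == "mbp1") cfg$mbf_motif else cfg$sbf_motif
    window <- if (tf == "mbp1") cfg$mbf_window else cfg$sbf_window
    mat <- assemble_classifier_matrix(dataset, tf, preset = cfg$preset,
                                      motif = motif, window = window,
                                      weighted_study = cfg$weighted_study,
                                      eps = cfg$eps)
    bb <- bin_classifier_matrix(mat, cfg$n_sets, cfg$set_size, cfg$ranks,
                                seed = stage_seed(cfg$seed, paste0("bins_", tf)))
    weights <- estimate_lls_weights(bb$binned, splits$controls[[tf]],
                                    pseudocount = cfg$pseudocount)
    scores <- total_scores(bb$binned, weights)
    bench <- splits$benchmarks[[tf]]
    profile <- metric_profile(scores, bench$pos1, bench$pos2, bench$neg)
    cls <- withCallingHandlers(
      select_cutoff(profile, scores, constraints = cfg$constraints),
      warning = function(w) {
        warnings <<- c(warnings, sprintf("%s: %s", tf, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    list(matrix = mat, binned = bb$binned, thresholds = bb$thresholds,
         weights = weights, scores = scores, classification = cls)
  })
  reports <- NULL
  if (isTRUE(cfg$run_reports)) {
    mbf_targets <- per_tf$mbp1$classification$targets
    sbf_targets <- per_tf$swi4$classification$targets
    reports <- list(
      overlap = overlap_report(list(MBF = mbf_targets, SBF = sbf_targets)),
      peak_phase = purrr::map(
        list(MBF = mbf_targets, SBF = sbf_targets),
        peak_phase_distribution, cc_peaks = dataset$cc_peaks),
      motif_positions = motif_position_summary(mbf_targets, dataset$promoters,
                                               motif = "ACGCG"),
      rescore_no_motif = rescore_without(per_tf$mbp1$binned,
                                         per_tf$mbp1$weights, "motif"))
  }
  run <- structure(list(dataset = dataset, splits = splits,
                        mbp1 = per_tf$mbp1, swi4 = per_tf$swi4,
                        reports = reports,
                        manifest = tibble::tibble(stage = character(0),
                                                  path = character(0),
                                                  md5 = character(0)),
                        config = cfg, warnings = warnings),
                   class = "start_run")
  if (!is.null(cfg$out_dir)) run$manifest <- write_run_artifacts(run, cfg$out_dir)
  run
}

# Serialize the run's TSV artifacts with a provenance header and return the
# manifest of digests.
write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  prov <- c(config_hash = config_hash(cfg), seed = as.character(cfg$seed),
            preset = cfg$preset, pseudocount = as.character(cfg$pseudocount))
  entries <- list()
  emit <- function(stage, name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    entries[[length(entries) + 1]] <<- tibble::tibble(
      stage = stage, path = path, md5 = unname(tools::md5sum(path)))
  }
  emit("simulate", "expression.tsv",
       function(p) write_expression_panel(run$dataset$expression, p))
  emit("simulate", "promoters.fasta",
       function(p) write_promoters_fasta(run$dataset$promoters, p))
  for (tf in cfg$tfs) {
    emit("score", sprintf("scores_%s.tsv", tf), function(p) {
      write_ranked_scores(run[[tf]]$scores, p, provenance = prov)
    })
    emit("weights", sprintf("weights_%s.tsv", tf), function(p) {
      writeLines(sprintf("#%s=%s", names(prov), prov), p)
      readr::write_tsv(tibble::as_tibble(run[[tf]]$weights), p, na = "NA",
                       append = TRUE, col_names = TRUE)
    })
    emit("threshold", sprintf("targets_%s.tsv", tf), function(p) {
      writeLines(sprintf("#%s=%s", names(prov), prov), p)
      readr::write_tsv(tidy(run[[tf]]$classification), p, na = "NA",
                       append = TRUE, col_names = TRUE)
    })
  }
  dplyr::bind_rows(entries)
}

#' @export
print.start_run <- function(x, ...) {
  cat("Synthetic G1/S evidence-integration run\n")
  cat(sprintf("  seed %d, preset '%s', %d genes\n", x$config$seed,
              x$config$preset, nrow(x$dataset$truth)))
  for (tf in x$config$tfs) {
    cls <- x[[tf]]$classification
    cat(sprintf("  %s: cutoff %d -> %d targets (feasible: %s)\n", tf,
                cls$cutoff, length(cls$targets), ifelse(cls$feasible, "yes", "no")))
  }
  if (length(x$warnings) > 0) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
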