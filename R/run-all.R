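utils::globalVariables(c("fpr", "tpr", "lab", "accuracy", "model",
                         "wavenumber", "importance", "cancer", "control"))

#' Assemble a full run configuration
#'
#' One object drives a complete run: simulate (or load) a cohort,
#' preprocess, evaluate every model family over repeated splits, run the
#' permutation validation and render reports.
#'
#' @param cohort a [cohort_config()] to simulate, or a path to a wide CSV
#'   cohort file.
#' @param prep a [preprocess_config()].
#' @param models character vector of families (any of `"plsda"`, `"rf"`,
#'   `"svm_linear"`) or a list of [model_spec()]s.
#' @param n_repeats evaluation splits per family (default 51).
#' @param sampling `"none"` or `"smote"`.
#' @param perm_iters permutation iterations (default 1000; 0 disables the
#'   permutation stage).
#' @param perm_family family used in the permutation stage (default
#'   `"plsda"`).
#' @param base_seed integer master seed.
#' @param outdir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), prep = preprocess_config(),
                       models = c("plsda", "rf", "svm_linear"),
                       n_repeats = 51, sampling = c("none", "smote"),
                       perm_iters = 1000, perm_family = "plsda",
                       base_seed = 1L, outdir = "results") {
  sampling <- match.arg(sampling)
  if (is.character(models)) models <- lapply(models, model_spec)
  if (is.character(cohort) && !file.exists(cohort))
    stop("run_config: cohort file not found: ", cohort, call. = FALSE)
  structure(list(cohort = cohort, prep = prep, models = models,
                 n_repeats = as.integer(n_repeats), sampling = sampling,
                 perm_iters = as.integer(perm_iters),
                 perm_family = perm_family,
                 base_seed = as.integer(base_seed), outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The YAML mirrors [run_config()]; the `cohort` block mirrors
#' [cohort_config()] (or is a `path:` entry), `prep` mirrors
#' [preprocess_config()]. Absent fields take the function defaults.
#'
#' @param path YAML file path.
#' @param overrides named list overriding top-level fields (e.g.
#'   `list(base_seed = 7, outdir = "x")`).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path))
    stop("read_run_config: file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  for (nm in names(overrides)) y[[nm]] <- overrides[[nm]]
  cohort <- if (!is.null(y$cohort$path)) {
    y$cohort$path
  } else {
    args <- y$cohort
    if (!is.null(args$effect_bands))
      args$effect_bands <- do.call(rbind, lapply(args$effect_bands, function(b)
        band_spec(b$center, b$width, b$amplitude)))
    do.call(cohort_config, args[names(args) %in%
                                  names(formals(cohort_config))])
  }
  prep <- do.call(preprocess_config,
                  (y$prep %||% list())[names(y$prep %||% list()) %in%
                                         names(formals(preprocess_config))])
  run_config(cohort = cohort, prep = prep,
             models = y$models %||% c("plsda", "rf", "svm_linear"),
             n_repeats = y$n_repeats %||% 51,
             sampling = y$sampling %||% "none",
             perm_iters = y$perm_iters %||% 1000,
             perm_family = y$perm_family %||% "plsda",
             base_seed = y$base_seed %||% 1L,
             outdir = y$outdir %||% "results")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a full run
#'
#' Stages, in order: cohort (simulate or load, written to
#' `cohort.csv`), repeated evaluation per model family
#' (`metrics_<family>.csv`, pooled `roc_<family>.csv`), constrained
#' operating points (`operating_points.csv`), permutation validation
#' (`permutation.json`), Gini profile (`gini_profile.csv` when an RF ran),
#' figures, and a JSON manifest capturing configs, seeds and output MD5
#' checksums. Re-running the same configuration reproduces every numeric
#' output exactly.
#'
#' @param cfg a [run_config()] or path to its YAML file.
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly.
#' @export
run_all <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message(...)
  if (!dir.exists(cfg$outdir) &&
      !dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE))
    stop("run_all: cannot create outdir '", cfg$outdir, "'", call. = FALSE)

  say("stage 1/5: cohort")
  ds <- if (is.character(cfg$cohort)) read_wide_csv(cfg$cohort)
        else simulate_cohort(cfg$cohort)
  cohort_file <- file.path(cfg$outdir, "cohort.csv")
  write_wide_csv(ds, cohort_file)

  say("stage 2/5: repeated evaluation")
  summaries <- list()
  files <- cohort_file
  for (spec in cfg$models) {
    say("  family: ", spec$family)
    s <- run_repeats(ds, spec, cfg$prep, n_repeats = cfg$n_repeats,
                     sampling = cfg$sampling, base_seed = cfg$base_seed)
    summaries[[spec$family]] <- s
    f <- file.path(cfg$outdir, sprintf("metrics_%s.csv", spec$family))
    data.table::fwrite(s$per_repeat, f)
    files <- c(files, f)
    f <- file.path(cfg$outdir, sprintf("roc_%s.csv", spec$family))
    data.table::fwrite(data.frame(threshold = s$roc$thresholds,
                                  sensitivity = s$roc$sensitivity,
                                  specificity = s$roc$specificity), f)
    files <- c(files, f)
  }

  say("stage 3/5: operating points")
  best <- summaries[[which.max(vapply(summaries, function(s) s$roc$auc,
                                      numeric(1)))]]
  ops <- rbind(
    cbind(floor = 0.60, operating_points(best$roc, 0.60)$points),
    cbind(floor = 0.45, operating_points(best$roc, 0.45)$points))
  f <- file.path(cfg$outdir, "operating_points.csv")
  data.table::fwrite(ops, f)
  files <- c(files, f)

  perm <- NULL
  if (cfg$perm_iters > 0L) {
    say("stage 4/5: permutation validation (", cfg$perm_iters, " iters)")
    perm <- permutation_test(ds, model_spec(cfg$perm_family), cfg$prep,
                             n_iter = cfg$perm_iters,
                             sampling = cfg$sampling,
                             base_seed = cfg$base_seed,
                             allow_small = TRUE)
    f <- file.path(cfg$outdir, "permutation.json")
    jsonlite::write_json(list(observed_acc = perm$observed_acc,
                              null_acc = perm$null_acc,
                              p_value = perm$p_value,
                              p_floor = perm$p_floor,
                              n_iter = perm$n_iter, family = perm$family),
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  } else say("stage 4/5: permutation validation skipped (perm_iters = 0)")

  gini <- NULL
  if (!is.null(summaries$rf) && !is.null(summaries$rf$importance)) {
    gini <- gini_profile(summaries$rf)
    f <- file.path(cfg$outdir, "gini_profile.csv")
    data.table::fwrite(data.frame(wavenumber = gini$wavenumber,
                                  importance = gini$importance), f)
    files <- c(files, f)
  }

  say("stage 5/5: reports")
  figs <- render_reports(unname(summaries), roc = best$roc, perm = perm,
                         gini = gini, outdir = cfg$outdir)
  files <- unique(c(files, figs))

  manifest <- list(
    created = "run_all",
    base_seed = cfg$base_seed, n_repeats = cfg$n_repeats,
    sampling = cfg$sampling, perm_iters = cfg$perm_iters,
    models = vapply(cfg$models, function(m) m$family, character(1)),
    prep = unclass(cfg$prep),
    cohort = if (is.character(cfg$cohort)) cfg$cohort
             else unclass(cfg$cohort)[setdiff(names(cfg$cohort),
                                              c("bands", "effect_bands"))],
    pooled_auc = vapply(summaries, function(s) s$roc$auc, numeric(1)),
    p_value = if (!is.null(perm)) perm$p_value else NULL,
    checksums = as.list(tools::md5sum(files[file.exists(files)])))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
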