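#' @title Configuration-driven experiment pipeline
#' @description Ties the stages together into the full experiment grid
#'   (reduction methods x data-source integrations x MMSE/age flag), driven
#'   by a single YAML configuration with subcommand-style entry points:
#'   [cmd_simulate()], [cmd_run()], [cmd_permtest()], [cmd_report()]. A thin
#'   Rscript wrapper around these lives in `inst/cli/neurofuse`.
#' @name cli_pipeline
NULL

# 32-bit FNV-1a over the deparsed config, for provenance stamping.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    hi <- h %/% 2147483648; lo <- h %% 2147483648
    h <- hi * 2147483648 + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

default_run_config <- function() {
  list(
    seed = 1L,
    synth = list(n_stable = 20, n_converter = 26,
                 volume_shape = c(16L, 16L, 16L),
                 effect_size_image = 1.0, noise_sd = 0.1),
    reduction = list(method = "pca", criterion = NULL, threshold = NULL,
                     n_ica = 20),
    fusion = list(strategy = "early", use_mmse_age = FALSE,
                  weight_grid = seq(0, 1, by = 0.1)),
    svm = list(cost_grid = 2^(-5:5), kernels = "default"),
    permutation = list(n_perm = 1000),
    grid = NULL
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a run configuration from YAML
#'
#' Unspecified keys fall back to package defaults. Recognized blocks:
#' `seed`, `synth` (generator parameters), `reduction` (`method`,
#' `threshold`, `n_ica`), `fusion` (`strategy`, `use_mmse_age`,
#' `weight_grid`), `svm` (`cost_grid`, `kernels`), `permutation`
#' (`n_perm`), and optionally `grid` (lists of `reductions`, `approaches`,
#' `use_mmse_age` values for [cmd_run()]).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A named list of class `run_config`.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    known <- c(names(cfg))
    bad <- setdiff(names(user), known)
    if (length(bad))
      stop("invalid config key(s): ", paste(bad, collapse = ", "))
    cfg <- merge_config(cfg, user)
  }
  class(cfg) <- "run_config"
  cfg
}

run_config_hyperparams <- function(cfg) {
  kernels <- cfg$svm$kernels
  if (identical(kernels, "default")) kernels <- NULL
  else if (identical(kernels, "linear"))
    kernels <- list(list(kind = "linear"))
  fusion_hyperparams(cost_grid = as.numeric(cfg$svm$cost_grid),
                     kernels = kernels,
                     weight_grid = as.numeric(cfg$fusion$weight_grid))
}

run_config_synth <- function(cfg) {
  s <- cfg$synth
  if (is.null(s)) stop("config has no synth block")
  do.call(synth_config,
          c(s[intersect(names(s), names(formals(synth_config)))],
            list(seed = cfg$seed)))
}

as_pipeline_config <- function(cfg, reduction = NULL, approach = NULL,
                               use_mmse_age = NULL) {
  pipeline_config(
    reduction = reduction %||% cfg$reduction$method,
    approach = approach %||% cfg$fusion$strategy,
    use_mmse_age = use_mmse_age %||% isTRUE(cfg$fusion$use_mmse_age),
    threshold = cfg$reduction$threshold,
    n_ica = cfg$reduction$n_ica %||% 20,
    hyperparams = run_config_hyperparams(cfg),
    seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stamp <- function(cfg) {
  list(config = unclass(cfg), config_hash = config_hash(unclass(cfg)),
       seed = cfg$seed)
}

#' Simulate a cohort to disk
#'
#' @param config A `run_config` (from [load_run_config()]) with a `synth`
#'   block.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest of paths written (also saved as
#'   `manifest.json` with the verbatim config and its hash).
#' @export
cmd_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  sc <- run_config_synth(config)
  cohort <- generate_cohort(sc)
  paths <- write_cohort(cohort, out_dir)
  manifest <- c(stamp(config), list(files = paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

report_to_list <- function(rep) {
  list(reduction = if (rep$config$approach == "psych_only") "-"
         else rep$config$reduction,
       approach = rep$config$approach,
       use_mmse_age = rep$config$use_mmse_age,
       predictions = rep$predictions,
       confusion = unclass(rep$counts),
       metrics = rep$metrics[c("accuracy", "sensitivity", "specificity",
                               "lr_pos", "lr_neg")],
       auc = rep$roc$auc,
       roc = list(sens = rep$roc$sensitivities,
                  fpr = rep$roc$one_minus_specificities))
}

#' Run the evaluation grid
#'
#' Evaluates each requested (approach, reduction, MMSE/age flag)
#' combination by full leave-one-out, writing one JSON report per
#' configuration plus a combined `results.csv` (rows = approach x
#' reduction; columns = accuracy, sensitivity, specificity, LR+, LR-)
#' mirroring the classical classification-rates table layout.
#'
#' @param config A `run_config`. If `config$grid` is set, its `reductions`,
#'   `approaches` and `use_mmse_age` entries define the grid; otherwise the
#'   single configured pipeline is run.
#' @param cohort_dir Directory with an on-disk cohort ([write_cohort()]
#'   layout); `NULL` simulates from the `synth` block instead.
#' @param out_dir Output directory.
#' @return Invisibly, a data.frame of the combined results table.
#' @export
cmd_run <- function(config, cohort_dir = NULL, out_dir) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (is.null(cohort_dir)) generate_cohort(run_config_synth(config))
            else read_cohort(cohort_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- config$grid
  combos <- if (is.null(grid)) {
    list(list(reduction = config$reduction$method,
              approach = config$fusion$strategy,
              use_mmse_age = isTRUE(config$fusion$use_mmse_age)))
  } else {
    out <- list()
    for (ap in grid$approaches) {
      reds <- if (ap == "psych_only") "pca" else grid$reductions
      flags <- if (ap == "image_only") FALSE
               else as.logical(grid$use_mmse_age %||% FALSE)
      for (red in reds) for (fl in unique(flags))
        out[[length(out) + 1]] <-
          list(reduction = red, approach = ap, use_mmse_age = fl)
    }
    out
  }
  fm <- vectorize_cohort(cohort)
  rows <- list()
  for (cb in combos) {
    pc <- as_pipeline_config(config, cb$reduction, cb$approach,
                             cb$use_mmse_age)
    rep_i <- loo_cross_validate(cohort, pc, feature_matrix = fm)
    tag <- sprintf("%s_%s%s", cb$approach,
                   if (cb$approach == "psych_only") "x" else cb$reduction,
                   if (cb$use_mmse_age) "_mmse_age" else "")
    jsonlite::write_json(c(stamp(config), report_to_list(rep_i)),
                         file.path(out_dir, paste0("report_", tag, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows", factor = "string")
    f <- format_metrics(rep_i$metrics)
    rows[[length(rows) + 1]] <- data.frame(
      approach = cb$approach,
      reduction = if (cb$approach == "psych_only") "-" else cb$reduction,
      mmse_age = cb$use_mmse_age,
      accuracy = f["accuracy"], sensitivity = f["sensitivity"],
      specificity = f["specificity"], lr_pos = f["lr_pos"],
      lr_neg = f["lr_neg"], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  utils::write.csv(tab, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  invisible(tab)
}

#' Run the permutation significance test
#'
#' @param config A `run_config` whose fusion strategy uses both sources.
#' @param cohort_dir On-disk cohort directory, or `NULL` to simulate.
#' @param out_dir Output directory for `permtest.json` (includes the
#'   permuted-accuracy list and histogram counts).
#' @param n_perm,seed Override the config's permutation settings.
#' @return Invisibly, the `permutation_result`.
#' @export
cmd_permtest <- function(config, cohort_dir = NULL, out_dir,
                         n_perm = NULL, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (is.null(cohort_dir)) generate_cohort(run_config_synth(config))
            else read_cohort(cohort_dir)
  n_perm <- n_perm %||% config$permutation$n_perm %||% 1000
  seed <- seed %||% config$seed
  pc <- as_pipeline_config(config)
  res <- permutation_test(cohort, pc, n_perm = n_perm, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- graphics::hist(res$permuted_accuracies, plot = FALSE)
  jsonlite::write_json(
    c(stamp(config),
      list(observed_accuracy = res$observed_accuracy,
           p_value = res$p_value, n_perm = res$n_perm,
           permuted_accuracies = res$permuted_accuracies,
           histogram = list(breaks = h$breaks, counts = h$counts))),
    file.path(out_dir, "permtest.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}

#' Render the combined results table
#'
#' @param in_dir Directory containing a `results.csv` from [cmd_run()].
#' @param format `"csv"` (echo path) or `"md"` (markdown table to stdout).
#' @return Invisibly, the results data.frame.
#' @export
cmd_report <- function(in_dir, format = c("csv", "md")) {
  format <- match.arg(format)
  path <- file.path(in_dir, "results.csv")
  if (!file.exists(path)) stop("no results.csv in ", in_dir)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "md") {
    cat("|", paste(names(tab), collapse = " | "), "|\n")
    cat("|", paste(rep("---", ncol(tab)), collapse = " | "), "|\n")
    for (r in seq_len(nrow(tab)))
      cat("|", paste(unlist(tab[r, ]), collapse = " | "), "|\n")
  } else {
    cat(path, "\n")
  }
  invisible(tab)
}
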