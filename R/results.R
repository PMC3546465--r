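#' Write run results to disk
#'
#' Serializes a run into three files under `outdir`: `bins.csv` (RFC-4180,
#' UTF-8, header row; one row per bin x synapse with the bin statistics,
#' learning terms, gate flag and weight), `summary.json` (the per-synapse
#' stabilization/median/slope summary and per-direction averages), and
#' `manifest.json` (config snapshot, seed, package version, step counts,
#' output paths, skip counters). Numbers are written in shortest
#' round-trippable form, so [analyze_run()] on `bins.csv` reproduces
#' `summary.json` exactly.
#'
#' @param run A `dynsyn_run`.
#' @param outdir Output directory (created if missing).
#' @param window,tol Stabilization-detection settings used for the summary.
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_results <- function(run, outdir, window = 20L, tol = NULL) {
  stopifnot(inherits(run, "dynsyn_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(bins = file.path(outdir, "bins.csv"),
             summary = file.path(outdir, "summary.json"),
             manifest = file.path(outdir, "manifest.json"))
  readr::write_csv(run$bins, paths[["bins"]], na = "")
  summary <- run_summary(run$bins, window = window, tol = tol)
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  cfg <- run$config
  manifest <- list(
    package = "dynsyn",
    version = as.character(utils::packageVersion("dynsyn")),
    seed = run$seed,
    config = c(cfg[setdiff(names(cfg), c("stp", "stdp"))],
               unclass(cfg$stp), unclass(cfg$stdp)),
    start_step = 1L,
    end_step = cfg$duration_steps,
    n_bins = run$n_bins,
    input_fraction = run$input_fraction,
    skip_counts = run$skip_counts,
    outputs = as.list(basename(paths))
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(paths)
}

# The summary object serialized to summary.json, computable from bins alone.
run_summary <- function(bins, window = 20L, tol = NULL) {
  sm <- summarize_synapses(bins, window = window, tol = tol)
  per_dir <- sm |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(mean_median_weight = mean(.data$median_weight, na.rm = TRUE),
                     all_stabilized = !anyNA(.data$stab_bin),
                     .groups = "drop")
  list(synapses = sm, directions = per_dir)
}

#' Recompute the run summary from a written bins.csv
#'
#' Reads `bins.csv` from `dir` and recomputes the stabilization bins, medians
#' and slopes with the same code path as [write_results()]; serialization is
#' lossless for these inputs, so the result matches the written
#' `summary.json` exactly.
#'
#' @param dir Directory containing `bins.csv` (as written by
#'   [write_results()]), or a path to the CSV itself.
#' @param window,tol Stabilization-detection settings.
#' @return The summary list (elements `synapses` and `directions`).
#' @export
analyze_run <- function(dir, window = 20L, tol = NULL) {
  path <- if (dir.exists(dir)) file.path(dir, "bins.csv") else dir
  bins <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  run_summary(bins, window = window, tol = tol)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a run into its per-bin table
#'
#' @param x A `dynsyn_run`.
#' @param ... Unused.
#' @return The `bins` tibble: one row per bin x synapse.
#' @method tidy dynsyn_run
#' @export
tidy.dynsyn_run <- function(x, ...) {
  x$bins
}

#' One-row summary of a run
#'
#' @param x A `dynsyn_run`.
#' @param ... Unused.
#' @return A one-row tibble: input rate, seed, problem sizes, input bit
#'   fraction, number of bins, updates applied/skipped, and the mean
#'   final weight per direction.
#' @method glance dynsyn_run
#' @export
glance.dynsyn_run <- function(x, ...) {
  final <- x$bins |>
    dplyr::filter(.data$bin == max(.data$bin)) |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(w = mean(.data$weight), .groups = "drop")
  tibble::tibble(
    lambda_hz = x$config$lambda_hz,
    seed = x$seed,
    n_T = x$config$n_T, n_R = x$config$n_R, g = x$config$g,
    duration_steps = x$config$duration_steps,
    n_bins = x$n_bins,
    input_fraction = x$input_fraction,
    n_updates = sum(!is.na(x$bins$dW)),
    n_skipped = sum(!is.na(x$bins$skip)),
    mean_final_weight_BA = final$w[final$direction == "BA"],
    mean_final_weight_AB = final$w[final$direction == "AB"]
  )
}
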