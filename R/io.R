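# Plain-text serialization of simulated datasets and analysis reports.
# Missing registry values are written as empty fields; every writer has
# a deterministic row order so identical seeds give byte-identical
# files.

#' Write a simulated dataset to a directory
#'
#' Emits `cohort.csv`, `claims.csv`, `registry.csv` (missing values as
#' empty fields) and `truth.json`.
#'
#' @param sim result of [generate_cohort()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort_data <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("cohort.csv", "claims.csv", "registry.csv",
                                "truth.json"))
  utils::write.csv(sim$cohort, paths[1], row.names = FALSE, na = "")
  utils::write.csv(sim$claims, paths[2], row.names = FALSE, na = "")
  utils::write.csv(sim$registry, paths[3], row.names = FALSE, na = "")
  truth <- sim$truth
  truth$conditions <- NULL  # bulky; regenerate from config when needed
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}

#' Read a simulated dataset back from a directory
#'
#' @param dir directory written by [write_cohort_data()].
#' @return list with `cohort`, `claims`, `registry`.
#' @export
read_cohort_data <- function(dir) {
  cohort <- utils::read.csv(file.path(dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
  claims <- utils::read.csv(file.path(dir, "claims.csv"),
                            stringsAsFactors = FALSE)
  registry <- utils::read.csv(file.path(dir, "registry.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(value = "integer"))
  registry$missing <- as.logical(registry$missing)
  registry$value[registry$missing] <- NA_integer_
  list(cohort = cohort, claims = claims, registry = registry)
}

#' Write an analysis report to a directory
#'
#' For a `grid_result`: `table2_analog.csv` (crude row plus one row per
#' model x adjustment cell), `forest.csv`, `ranking_top25.csv` per
#' available source, optional `balance/` CSVs, and `run_manifest.json`
#' with the seed and package version.  For a `replication_summary`:
#' `replication_summary.csv`, `replication_per_rep.csv`, and the
#' manifest with every replicate seed.
#'
#' @param result a `grid_result` or `replication_summary`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  add <- function(p) paths[[length(paths) + 1L]] <<- p

  if (inherits(result, "grid_result")) {
    crude_row <- data.frame(
      model_id = "crude", strategy = "none", source = "none",
      adjustment = "crude", c_statistic = NA_real_,
      n_exposed = result$crude$n[["exposed"]],
      n_unexposed = result$crude$n[["unexposed"]],
      events_exposed = result$crude$events[["exposed"]],
      events_unexposed = result$crude$events[["unexposed"]],
      hr = result$crude$hr, ci_lo = result$crude$ci95[1],
      ci_hi = result$crude$ci95[2], se_log_hr = result$crude$se_log_hr,
      log_hr = result$crude$log_hr, error = NA_character_,
      stringsAsFactors = FALSE)
    tab <- rbind(crude_row, result$cells)
    p <- file.path(out_dir, "table2_analog.csv")
    utils::write.csv(tab, p, row.names = FALSE, na = "")
    add(p)
    forest <- tab[, c("model_id", "adjustment", "hr", "ci_lo", "ci_hi")]
    p <- file.path(out_dir, "forest.csv")
    utils::write.csv(forest, p, row.names = FALSE, na = "")
    add(p)
    for (src in names(result$rankings)) {
      rk <- result$rankings[[src]]
      if (is.null(rk)) next
      top <- utils::head(rk$ranking, 25L)
      top <- top[, c("dimension", "code", "level", "pc1", "pc0", "rr_cd",
                     "bias_multiplier", "abs_log_bias", "rank", "selected")]
      p <- file.path(out_dir, sprintf("ranking_top25_%s.csv", src))
      utils::write.csv(top, p, row.names = FALSE)
      add(p)
    }
    if (!is.null(result$balance)) {
      bdir <- file.path(out_dir, "balance")
      dir.create(bdir, showWarnings = FALSE)
      for (mid in names(result$balance)) {
        if (is.null(result$balance[[mid]])) next
        p <- file.path(bdir, sprintf("balance_%s.csv", mid))
        utils::write.csv(result$balance[[mid]], p, row.names = FALSE)
        add(p)
      }
    }
    manifest <- list(kind = "grid_result", seed = result$seed,
                     benchmark_hr = result$benchmark_hr,
                     package_version = as.character(utils::packageVersion("hdpsbench")))
  } else if (inherits(result, "replication_summary")) {
    p <- file.path(out_dir, "replication_summary.csv")
    utils::write.csv(result$summary, p, row.names = FALSE, na = "")
    add(p)
    p <- file.path(out_dir, "replication_per_rep.csv")
    utils::write.csv(result$per_rep, p, row.names = FALSE, na = "")
    add(p)
    manifest <- list(kind = "replication_summary", seeds = result$seeds,
                     benchmark_hr = result$benchmark_hr,
                     package_version = as.character(utils::packageVersion("hdpsbench")))
  } else {
    stop("unsupported result type", call. = FALSE)
  }
  p <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
  add(p)
  invisible(unlist(paths))
}
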