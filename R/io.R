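#' Read and write cell-record tables
#'
#' Cell records are the tabular interchange format of the package: one row
#' per segmented cell per frame, with columns `frame`, `time_h`, `cell_id`,
#' `parent_id` (empty for a root cell), `volume`, `i_ng`, `i_mkate`,
#' `bg_ng`, `bg_mkate`, `bud_ratio` (empty when the cell has no bud), and
#' optionally `population`. CSV, UTF-8, header row mandatory, missing
#' values as empty fields.
#'
#' @param path File path.
#' @return `read_cell_records()` returns a tibble; the writer returns the
#'   path invisibly.
#' @export
read_cell_records <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  need <- c("frame", "cell_id", "volume", "i_ng", "i_mkate",
            "bg_ng", "bg_mkate")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0L) {
    stop("Cell-record file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  rec
}

#' @rdname read_cell_records
#' @param records Cell-record tibble.
#' @export
write_cell_records <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Read/write a simulation configuration as structured text
#'
#' Plain `key = value` text mirroring the [sim_config()] fields, so runs
#' can be reproduced from a config file.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `read_sim_config()` returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  fp <- config$founder_pattern
  if (is.numeric(fp)) fp <- paste(as.integer(fp), collapse = "")
  lines <- c(
    paste("n_copies =", config$n_copies),
    paste("ndau =", config$ndau),
    paste("nspl =", config$nspl),
    paste("founder_pattern =", fp),
    paste("founder_fraction1 =", config$founder_fraction1),
    paste("n_generations =", config$n_generations),
    paste("generation_hours =", config$generation_hours),
    paste("n_replicates =", config$n_replicates),
    paste("seed =", config$seed)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("Malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  get <- function(key, as = as.numeric, default = NULL) {
    i <- match(key, keys)
    if (is.na(i)) {
      if (is.null(default)) stop("Config field missing: ", key)
      return(default)
    }
    as(vals[i])
  }
  sim_config(
    n_copies = get("n_copies"), ndau = get("ndau"), nspl = get("nspl"),
    founder_pattern = get("founder_pattern", as = identity,
                          default = "mixed"),
    founder_fraction1 = get("founder_fraction1", default = 0.5),
    n_generations = get("n_generations"),
    generation_hours = get("generation_hours", default = 1.5),
    n_replicates = get("n_replicates", default = 1),
    seed = get("seed", default = 1)
  )
}

#' Write a run manifest
#'
#' Records what produced a set of output files: the command label, a
#' snapshot of the configuration, the seed, package version, timestamp and
#' md5 digests of the outputs. One manifest per exported run.
#'
#' @param command Short label of the operation.
#' @param config A `sim_config` or `generator_config` (or any list).
#' @param seed Integer seed used.
#' @param outputs Character vector of output file paths.
#' @param path Manifest path (JSON).
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(command, config, seed, outputs, path) {
  manifest <- list(
    command = command,
    package = "mitoseg",
    version = as.character(utils::packageVersion("mitoseg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass_config(config),
    outputs = lapply(outputs, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

unclass_config <- function(config) {
  x <- unclass(config)
  lapply(x, function(v) if (is.list(v)) unclass_config(v) else v)
}

#' Run the simulator and export its results
#'
#' High-level entry point: simulates per the config, writes the snapshot
#' CSV (`replicate`, `generation`, `time_h`, `cell_id`, `parent_id`,
#' `allele1_count`, `n_copies`, `allele_fraction`, `strict_homoplasmic`)
#' plus a run manifest to `outdir`.
#'
#' @param config A [sim_config()] or path to a config text file.
#' @param outdir Output directory (created if missing).
#' @return Paths of the written files, invisibly.
#' @export
run_simulation <- function(config, outdir) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_population(config)
  sim_path <- file.path(outdir, "simulation.csv")
  readr::write_csv(sim, sim_path, na = "")
  man_path <- file.path(outdir, "manifest.json")
  write_run_manifest("simulate", config, config$seed, sim_path, man_path)
  invisible(c(simulation = sim_path, manifest = man_path))
}

#' Analyze a cell-record table end to end
#'
#' Runs the quantification and classification pipeline on a cell-record
#' CSV or tibble: h values per cell per frame, mixture fit and derived
#' thresholds on the final frame, per-cell classifications, and (when
#' lineage information spans more than one frame) stage-matched
#' mother-progeny correlations. All results are written as CSVs with a
#' manifest.
#'
#' @param records A cell-record tibble or path to a cell-record CSV.
#' @param outdir Output directory.
#' @param thresholds Optional fixed `(low, high)` homoplasmy thresholds;
#'   by default they are derived from the final-frame mixture fit.
#' @return Invisible named vector of output paths.
#' @export
run_analysis <- function(records, outdir, thresholds = NULL) {
  if (is.character(records)) records <- read_cell_records(records)
  if (nrow(records) == 0L) stop("Empty cell-record table.")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  htab <- add_h_values(records)
  last <- htab[htab$frame == max(htab$frame) & !is.na(htab$h), ]
  fit <- NULL
  if (is.null(thresholds)) {
    fit <- fit_gaussian_mixture(last$h)
    thresholds <- derive_thresholds(fit)
  }
  htab$class <- classify_h(htab$h, thresholds)
  h_path <- file.path(outdir, "h_values.csv")
  readr::write_csv(htab, h_path, na = "")
  thr_tab <- tibble::tibble(
    parameter = c("low", "high"), h = as.numeric(thresholds))
  if (!is.null(fit)) {
    comp_tab <- fit$components
    readr::write_csv(comp_tab, file.path(outdir, "mixture_components.csv"))
  }
  thr_path <- file.path(outdir, "thresholds.csv")
  readr::write_csv(thr_tab, thr_path)
  outputs <- c(h_path, thr_path)
  if (length(unique(htab$frame)) > 1L && "bud_ratio" %in% names(htab) &&
      any(!is.na(htab$bud_ratio))) {
    pairs <- relation_pairs(htab)
    if (nrow(pairs) > 0L) {
      pairs$population <- 1L
      pair_path <- file.path(outdir, "relation_pairs.csv")
      readr::write_csv(pairs, pair_path, na = "")
      outputs <- c(outputs, pair_path)
    }
  } else {
    message("Single-frame table: lineage stage skipped.")
  }
  man_path <- file.path(outdir, "manifest.json")
  write_run_manifest("analyze", list(thresholds = as.numeric(thresholds)),
                     NA, outputs, man_path)
  invisible(c(outputs, manifest = man_path))
}

#' Grid-fit an empirical homoplasmy curve and export the surface
#'
#' @param empirical A data frame (`time_h`, `fraction`) or path to such a
#'   CSV.
#' @param outdir Output directory.
#' @param ... Passed to [grid_search()].
#' @return The `grid_fit` object, invisibly; writes `grid_surface.csv`,
#'   `best_pair.csv` and a manifest.
#' @export
run_grid_fit <- function(empirical, outdir, ...) {
  if (is.character(empirical)) {
    empirical <- readr::read_csv(empirical, show_col_types = FALSE)
    if (!all(c("time_h", "fraction") %in% names(empirical))) {
      stop("Empirical curve CSV needs columns time_h and fraction.")
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fit <- grid_search(empirical, ...)
  grid_path <- file.path(outdir, "grid_surface.csv")
  readr::write_csv(fit$grid, grid_path)
  best_path <- file.path(outdir, "best_pair.csv")
  readr::write_csv(tibble::tibble(ndau = fit$best_ndau,
                                  nspl = fit$best_nspl,
                                  sse = min(fit$grid$sse)), best_path)
  man_path <- file.path(outdir, "manifest.json")
  write_run_manifest("fit", list(n_replicates = fit$n_replicates),
                     NA, c(grid_path, best_path), man_path)
  invisible(fit)
}
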