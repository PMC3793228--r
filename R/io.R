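read_checked_csv <- function(path, required, numeric_cols = character(0),
                             integer_cols = character(0)) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        na.strings = c("", "NA", "n.a."))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_arg("%s: missing column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), c(required, numeric_cols, integer_cols))
  for (col in c(numeric_cols, integer_cols)) {
    if (!col %in% names(df)) next
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop_arg("%s: non-numeric value '%s' in column '%s', row %d",
                 path, v[bad[1L]], col, bad[1L])
      df[[col]] <- num
    }
  }
  attr(df, "extra_columns") <- extra
  df
}

#' Read a lineage table CSV
#'
#' Schema: `lineage_id,family,hotspot,n_species,crown_age_min,crown_age_mean,
#' crown_age_max,pleistocene_count`; empty cells mean absent. Unknown extra
#' columns are kept with a warning (forward compatibility). Validates unique
#' lineage ids, `n_species >= 2`, strictly positive ages and the ordering
#' min <= mean <= max where present.
#'
#' @param path CSV path, UTF-8, header row required.
#' @return Data frame of validated lineage records.
#' @export
read_lineage_csv <- function(path) {
  df <- read_checked_csv(
    path,
    required = c("lineage_id", "hotspot", "n_species", "crown_age_mean"),
    numeric_cols = c("crown_age_min", "crown_age_mean", "crown_age_max"),
    integer_cols = c("n_species", "pleistocene_count", "pleistocene_total"))
  known <- c("lineage_id", "family", "hotspot", "n_species", "crown_age_min",
             "crown_age_mean", "crown_age_max", "pleistocene_count",
             "pleistocene_total")
  unknown <- setdiff(names(df), known)
  if (length(unknown))
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  if (anyDuplicated(df$lineage_id))
    stop_arg("%s: duplicate lineage_id: %s", path,
             paste(unique(df$lineage_id[duplicated(df$lineage_id)]),
                   collapse = ", "))
  if (any(is.na(df$n_species) | df$n_species < 2))
    stop_arg("%s: n_species must be present and >= 2 (lineage %s)", path,
             df$lineage_id[which(is.na(df$n_species) | df$n_species < 2)[1L]])
  for (col in c("crown_age_min", "crown_age_mean", "crown_age_max")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_real_, nrow(df))
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad))
      stop_arg("%s: %s must be > 0 (lineage %s)", path, col,
               df$lineage_id[bad[1L]])
  }
  ord_bad <- which((!is.na(df$crown_age_min) &
                      df$crown_age_min > df$crown_age_mean) |
                   (!is.na(df$crown_age_max) &
                      df$crown_age_max < df$crown_age_mean))
  if (length(ord_bad))
    stop_arg("%s: crown ages must satisfy min <= mean <= max (lineage %s)",
             path, df$lineage_id[ord_bad[1L]])
  df
}

#' Read a hotspot metadata CSV
#'
#' Schema: `hotspot,area_km2,species_total,species_endemic`; extra columns
#' (e.g. `*_printed` cells for [validate_hotspot_cells()]) are kept with a
#' warning. Validates positive areas, unique hotspot names, and
#' `species_endemic <= species_total` where both present.
#'
#' @param path CSV path.
#' @return Data frame of validated hotspot records.
#' @export
read_hotspot_csv <- function(path) {
  df <- read_checked_csv(
    path,
    required = c("hotspot", "area_km2", "species_total"),
    numeric_cols = c("area_km2", "mean_rate_printed",
                     "species_density_printed", "speciation_density_printed"),
    integer_cols = c("species_total", "species_endemic"))
  known <- c("hotspot", "area_km2", "species_total", "species_endemic",
             "mean_rate_printed", "species_density_printed",
             "speciation_density_printed")
  unknown <- setdiff(names(df), known)
  if (length(unknown))
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  if (anyDuplicated(df$hotspot))
    stop_arg("%s: duplicate hotspot names", path)
  if (any(is.na(df$area_km2) | df$area_km2 <= 0))
    stop_arg("%s: area_km2 must be > 0", path)
  if ("species_endemic" %in% names(df)) {
    bad <- which(!is.na(df$species_endemic) &
                   df$species_endemic > df$species_total)
    if (length(bad))
      stop_arg("%s: species_endemic exceeds species_total (%s)", path,
               df$hotspot[bad[1L]])
  }
  df
}

#' Read a bare per-lineage rate CSV
#'
#' Schema: `lineage_id,hotspot,rate` — the input of the fastest-lineage
#' resampling stage when rates come from literature rather than from
#' [rate_table()].
#'
#' @param path CSV path.
#' @return Data frame `lineage_id`, `hotspot`, `rate`.
#' @export
read_rate_csv <- function(path) {
  df <- read_checked_csv(path, required = c("lineage_id", "hotspot", "rate"),
                         numeric_cols = "rate")
  if (anyDuplicated(df$lineage_id))
    stop_arg("%s: duplicate lineage_id", path)
  if (any(!is.finite(df$rate)))
    stop_arg("%s: all rates must be finite", path)
  df[, c("lineage_id", "hotspot", "rate")]
}

write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Run the full hotspot diversification analysis
#'
#' Pipeline driver: per-lineage rates from a lineage table, per-hotspot
#' summary with bootstrap intervals and densities, printed-cell validation,
#' optional fastest-lineage resampling (when a per-lineage rate table
#' covering at least two hotspots is supplied) and optional Pleistocene
#' divergence counting (when chronogram files are supplied). All outputs are
#' plain CSV/TSV plus a JSON run log recording the seed, package version and
#' validation flags; a rerun with the same inputs and seed is byte-identical.
#'
#' @param lineages path to a lineage CSV (see [read_lineage_csv()]).
#' @param hotspots path to a hotspot metadata CSV.
#' @param rates optional path to a bare rate CSV for the resampling stage.
#' @param trees optional character vector of chronogram files.
#' @param out_dir output directory, created if needed.
#' @param epsilon,mode rate-estimator settings, see [ms_rate()].
#' @param n_boot bootstrap resamples for hotspot CIs.
#' @param resample_k,resample_n_samples,resample_n_iterations resampling
#'   settings, see [summarize_resampling()].
#' @param pleistocene_threshold age cutoff in Ma for divergence counting.
#' @param seed integer seed used for every stochastic stage (required).
#' @return Invisibly, a list with the computed tables and the paths written.
#' @export
run_full_analysis <- function(lineages, hotspots, rates = NULL, trees = NULL,
                              out_dir, epsilon = 0, mode = "crown",
                              n_boot = 1000, resample_k = 5,
                              resample_n_samples = 1000,
                              resample_n_iterations = 1000,
                              pleistocene_threshold = 2.58, seed) {
  if (missing(seed)) stop_arg("'seed' is required for stochastic stages")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  cleanup <- function() suppressWarnings(file.remove(written))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cleanup()
      stop_arg("stage '%s': %s", name, conditionMessage(e))
    })
  }
  out <- list()

  lin <- stage("rates", suppressWarnings(read_lineage_csv(lineages)))
  if (!nrow(lin)) { stop_arg("stage 'rates': empty lineage table") }
  meta <- stage("compare", suppressWarnings(read_hotspot_csv(hotspots)))
  out$rates <- stage("rates", rate_table(lin, epsilon = epsilon, mode = mode))
  p <- file.path(out_dir, "lineage_rates.csv")
  write_table_csv(out$rates, p); written <- c(written, p)

  out$summary <- stage("compare",
    assemble_summary(out$rates, meta, n_boot = n_boot, seed = seed))
  p <- file.path(out_dir, "hotspot_summary.csv")
  write_table_csv(out$summary, p); written <- c(written, p)

  out$validation <- if ("species_density_printed" %in% names(meta))
    stage("compare", validate_hotspot_cells(meta)) else NULL
  if (!is.null(out$validation)) {
    p <- file.path(out_dir, "cell_validation.csv")
    write_table_csv(out$validation, p); written <- c(written, p)
  }

  if (!is.null(rates)) {
    rt <- stage("resample", read_rate_csv(rates))
    if (length(unique(rt$hotspot)) >= 2) {
      out$resampling <- stage("resample",
        summarize_resampling(rt, k = resample_k,
                             n_samples = resample_n_samples,
                             n_iterations = resample_n_iterations,
                             seed = seed))
      p <- file.path(out_dir, "resampling_summary.csv")
      write_table_csv(out$resampling, p); written <- c(written, p)
    }
  }

  if (!is.null(trees) && length(trees)) {
    out$pleistocene <- stage("pleistocene", {
      rows <- lapply(trees, function(tf) {
        tr <- read_chronogram(tf)
        ct <- count_pleistocene_tips(tr, threshold = pleistocene_threshold)
        data.frame(tree = basename(tf), n_tips = ct$n, n_pleistocene = ct$k,
                   crown_age = crown_age(tr))
      })
      do.call(rbind, rows)
    })
    p <- file.path(out_dir, "pleistocene_counts.tsv")
    utils::write.table(out$pleistocene, p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    written <- c(written, p)
  }

  log <- list(
    package = "paramodiv",
    version = as.character(utils::packageVersion("paramodiv")),
    seed = seed, epsilon = epsilon, mode = mode, n_boot = n_boot,
    inputs = list(lineages = lineages, hotspots = hotspots,
                  rates = rates, trees = trees),
    inconsistent_cells = if (!is.null(out$validation))
      out$validation[!out$validation$consistent,
                     c("hotspot", "cell", "printed", "computed")] else NULL)
  p <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  written <- c(written, p)
  out$files <- written
  invisible(out)
}
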