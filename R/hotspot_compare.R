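#' Mean net diversification rate of a hotspot
#'
#' Arithmetic mean of the unrounded per-lineage rates of one hotspot. The
#' hotspot mean in the comparison tables is the mean of the *mean-age* rates;
#' minimum/maximum-age rates feed only the upper/lower summaries.
#'
#' @param rates numeric vector of per-lineage rates, all finite, length >= 1.
#' @return The mean rate in events per Myr.
#' @examples
#' hotspot_mean_rate(rate_table(paramo_lineages())$rate_mean_age) # 1.36
#' @export
hotspot_mean_rate <- function(rates) {
  if (!length(rates)) stop_arg("need at least one lineage rate")
  if (any(!is.finite(rates))) stop_arg("all rates must be finite")
  mean(rates)
}

#' Percentile-bootstrap confidence interval for a mean
#'
#' Resamples `length(values)` observations with replacement `n_boot` times
#' and reads the confidence interval off the empirical quantiles of the
#' resampled means (percentile bootstrap). Deterministic for a given seed.
#'
#' @param values numeric vector; a single value yields a degenerate interval
#'   with a warning.
#' @param n_boot number of bootstrap resamples (the comparison uses 1000).
#' @param conf confidence level (default 0.95, i.e. the 2.5/97.5 percentiles).
#' @param seed optional integer seed; caller's RNG state is untouched.
#' @return List with `mean`, `ci_low`, `ci_high`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 1000, conf = 0.95, seed = NULL) {
  if (!length(values) || any(!is.finite(values)))
    stop_arg("'values' must be non-empty and finite")
  if (n_boot < 1) stop_arg("'n_boot' must be >= 1")
  m <- mean(values)
  if (length(values) == 1L) {
    warning("single value: degenerate bootstrap interval", call. = FALSE)
    return(list(mean = m, ci_low = m, ci_high = m))
  }
  boots <- with_seed(seed, {
    n <- length(values)
    vapply(seq_len(n_boot),
           function(i) mean(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - conf) / 2
  qs <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  list(mean = m, ci_low = qs[1], ci_high = qs[2])
}

#' Species density of a hotspot
#'
#' @param species_total number of species in the hotspot.
#' @param area_km2 hotspot area in square kilometres, > 0.
#' @return Species per square kilometre.
#' @examples
#' species_density(3431, 35000) # 0.098
#' @export
species_density <- function(species_total, area_km2) {
  if (any(area_km2 <= 0)) stop_arg("'area_km2' must be > 0")
  if (any(species_total < 0)) stop_arg("'species_total' must be >= 0")
  species_total / area_km2
}

#' Speciation events per Myr per square kilometre
#'
#' Mean net diversification rate of a hotspot divided by its area. The
#' *unrounded* mean must be supplied: the published per-area rates derive
#' from unrounded means, not from the two-decimal cells.
#'
#' @param mean_rate mean net diversification rate, events per Myr, >= 0.
#' @param area_km2 hotspot area in square kilometres, > 0.
#' @return Speciation events per Myr per square kilometre.
#' @export
speciation_density <- function(mean_rate, area_km2) {
  if (any(area_km2 <= 0)) stop_arg("'area_km2' must be > 0")
  if (any(mean_rate < 0)) stop_arg("'mean_rate' must be >= 0")
  mean_rate / area_km2
}

#' Per-hotspot summary: mean rates, bootstrap CIs and densities
#'
#' Joins a per-lineage rate table with hotspot metadata into one summary row
#' per hotspot: lineage count, mean of the mean-age rates with its percentile
#' bootstrap interval, upper/lower summaries (means of the minimum-age and
#' maximum-age rates, the numerically larger and smaller bounds), species
#' density and speciation events per Myr per km2. Output is sorted by hotspot
#' name and invariant to input row order.
#'
#' @param rates rate table as returned by [rate_table()] (needs `hotspot`,
#'   `rate_mean_age`; `rate_min_age`/`rate_max_age` used when present).
#' @param meta hotspot metadata with `hotspot`, `area_km2`, `species_total`;
#'   every hotspot present in `rates` must have a row.
#' @param n_boot,conf,seed bootstrap settings, see [bootstrap_mean_ci()].
#' @return Data frame with one row per hotspot present in `rates`.
#' @examples
#' smry <- assemble_summary(rate_table(paramo_lineages()), hotspot_metadata(),
#'                          seed = 42)
#' smry[, c("hotspot", "mean_rate", "species_density")]
#' @export
assemble_summary <- function(rates, meta, n_boot = 1000, conf = 0.95,
                             seed = NULL) {
  if (!all(c("hotspot", "rate_mean_age") %in% names(rates)))
    stop_arg("'rates' needs columns hotspot, rate_mean_age")
  if (!all(c("hotspot", "area_km2", "species_total") %in% names(meta)))
    stop_arg("'meta' needs columns hotspot, area_km2, species_total")
  hotspots <- sort(unique(rates$hotspot))
  missing_meta <- setdiff(hotspots, meta$hotspot)
  if (length(missing_meta))
    stop_arg("no metadata for hotspot(s): %s", paste(missing_meta, collapse = ", "))
  rows <- lapply(seq_along(hotspots), function(i) {
    h <- hotspots[i]
    r <- rates[rates$hotspot == h, , drop = FALSE]
    m <- meta[match(h, meta$hotspot), , drop = FALSE]
    # sorting makes the bootstrap draw independent of input row order
    vals <- sort(r$rate_mean_age[is.finite(r$rate_mean_age)])
    ci <- suppressWarnings(
      bootstrap_mean_ci(vals, n_boot, conf,
                        seed = if (is.null(seed)) NULL else substream_seed(seed, i)))
    mean_of <- function(col)
      if (col %in% names(r) && any(is.finite(r[[col]])))
        mean(r[[col]][is.finite(r[[col]])]) else NA_real_
    data.frame(
      hotspot = h, n_lineages = nrow(r),
      mean_rate = ci$mean, ci_low = ci$ci_low, ci_high = ci$ci_high,
      mean_rate_upper = mean_of("rate_min_age"),
      mean_rate_lower = mean_of("rate_max_age"),
      species_density = species_density(m$species_total, m$area_km2),
      speciation_density = speciation_density(ci$mean, m$area_km2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate published per-area cells against recomputation
#'
#' Recomputes species density (species / area) and, where a mean rate is
#' supplied, speciation density (rate / area) from the raw columns of a
#' hotspot table carrying `*_printed` cells, and flags cells that differ from
#' the published value by more than one unit in the last published decimal
#' place (which tolerates round-versus-truncate ambiguity but catches real
#' inconsistencies, e.g. a density cell that cannot be species/area from its
#' own row).
#'
#' @param meta hotspot table such as [hotspot_metadata()]: `hotspot`,
#'   `area_km2`, `species_total` plus `species_density_printed` and
#'   optionally `mean_rate_printed`, `speciation_density_printed`.
#' @return Data frame with one row per hotspot and printed cell:
#'   `hotspot`, `cell`, `printed`, `computed`, `tolerance`, `consistent`.
#' @examples
#' v <- validate_hotspot_cells(hotspot_metadata())
#' subset(v, !consistent) # the Cerrado and Cape Floristic Region cells
#' @export
validate_hotspot_cells <- function(meta) {
  if (!"species_density_printed" %in% names(meta))
    stop_arg("'meta' carries no printed cells to validate")
  one_ulp <- function(x) {
    # one unit in the last printed decimal place, inferred from the value
    vapply(x, function(v) {
      if (is.na(v)) return(NA_real_)
      s <- format(v, scientific = FALSE, trim = TRUE, digits = 15)
      dec <- if (grepl("\\.", s)) nchar(sub(".*\\.", "", s)) else 0L
      10^(-dec)
    }, numeric(1))
  }
  rows <- list()
  add <- function(h, cell, printed, computed) {
    tol <- one_ulp(printed)
    rows[[length(rows) + 1L]] <<- data.frame(
      hotspot = h, cell = cell, printed = printed, computed = computed,
      tolerance = tol,
      consistent = !is.na(printed) & abs(computed - printed) <= tol)
  }
  for (i in seq_len(nrow(meta))) {
    h <- meta$hotspot[i]
    add(h, "species_density", meta$species_density_printed[i],
        species_density(meta$species_total[i], meta$area_km2[i]))
    if (all(c("mean_rate_printed", "speciation_density_printed") %in% names(meta))
        && !is.na(meta$mean_rate_printed[i])) {
      # the printed speciation density came from an unrounded mean; judge it
      # against the printed (2 dp) mean with the tolerance that rounding implies
      comp <- speciation_density(meta$mean_rate_printed[i], meta$area_km2[i])
      tol_from_rounding <- 0.005 / meta$area_km2[i] +
        one_ulp(meta$speciation_density_printed[i] * 1e6) * 1e-6
      rows[[length(rows) + 1L]] <- data.frame(
        hotspot = h, cell = "speciation_density",
        printed = meta$speciation_density_printed[i], computed = comp,
        tolerance = tol_from_rounding,
        consistent = !is.na(meta$speciation_density_printed[i]) &
          abs(comp - meta$speciation_density_printed[i]) <= tol_from_rounding)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
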