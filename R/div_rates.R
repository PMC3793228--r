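#' Pure-birth (Kendall--Moran) net diversification rate
#'
#' Estimates the net diversification rate of a clade from its standing
#' diversity and age under a constant-rate pure-birth model with no
#' extinction: \eqn{r = [\ln N - \ln N_0] / T}.
#'
#' With `n0 = 2` the clock starts at the crown node (two lineages already
#' present at the crown age); with `n0 = 1` it starts at the stem node. The
#' printed per-lineage rates of the packaged Paramo table reproduce under the
#' crown convention `n0 = 2`, which is therefore the default.
#'
#' @param n standing diversity (extant species count), `n >= n0`.
#' @param t clade age in Myr (crown age for `n0 = 2`, stem age for `n0 = 1`).
#' @param n0 initial diversity, 1 (stem) or 2 (crown).
#' @return Net diversification rate in speciation events per lineage per Myr.
#'   Vectorized over `n` and `t`.
#' @examples
#' pure_birth_rate(17, 0.42)        # 5.10, the Aragoa mean-age rate
#' pure_birth_rate(66, 1.47)        # 2.38, Lupinus
#' @seealso [ms_rate()] for the extinction-corrected estimator.
#' @export
pure_birth_rate <- function(n, t, n0 = 2) {
  if (!all(n0 %in% c(1, 2))) stop_arg("'n0' must be 1 (stem) or 2 (crown)")
  if (any(!is.finite(t)) || any(t <= 0)) stop_arg("clade age 't' must be > 0")
  if (any(!is.finite(n)) || any(n < n0))
    stop_arg("standing diversity 'n' must be >= n0 = %d", n0)
  (log(n) - log(n0)) / t
}

#' Magallon--Sanderson method-of-moments diversification rate
#'
#' Closed-form net diversification rate of a clade of `n` extant species and
#' age `t` under a constant-rate birth--death model with relative extinction
#' fraction \eqn{\epsilon = \mu/\lambda}, obtained by inverting the expected
#' standing diversity conditional on clade survival. At \eqn{\epsilon = 0} the
#' crown form reduces exactly to `pure_birth_rate(n, t, 2)` and the stem form
#' to `pure_birth_rate(n, t, 1)`.
#'
#' Stem: \eqn{r = \ln[n(1-\epsilon) + \epsilon] / t}. Crown:
#' \deqn{r = \frac{1}{t}\left[\ln\!\left(\tfrac{n}{2}(1-\epsilon^2) + 2\epsilon
#'   + \tfrac{1-\epsilon}{2}\sqrt{n(n\epsilon^2 - 8\epsilon + 2n\epsilon + n)}
#'   \right) - \ln 2\right].}
#'
#' @param n standing diversity; `n >= 2` for crown mode, `n >= 1` for stem.
#' @param t clade age in Myr, > 0.
#' @param epsilon relative extinction fraction in `[0, 1)`.
#' @param mode `"crown"` (age is the crown-node age) or `"stem"`.
#' @return Rate in speciation events per lineage per Myr; vectorized over
#'   `n`, `t` and `epsilon`.
#' @examples
#' ms_rate(120, 4.04)                 # 1.01, Espeletiinae at epsilon = 0
#' ms_rate(50, 10, epsilon = 0.9)     # heavy extinction correction
#' @export
ms_rate <- function(n, t, epsilon = 0, mode = c("crown", "stem")) {
  mode <- match.arg(mode)
  if (any(!is.finite(epsilon)) || any(epsilon < 0) || any(epsilon >= 1))
    stop_arg("'epsilon' must lie in [0, 1)")
  if (any(!is.finite(t)) || any(t <= 0)) stop_arg("clade age 't' must be > 0")
  n_min <- if (mode == "crown") 2 else 1
  if (any(!is.finite(n)) || any(n < n_min))
    stop_arg("'n' must be >= %d in %s mode", n_min, mode)
  if (mode == "stem") {
    log(n * (1 - epsilon) + epsilon) / t
  } else {
    disc <- n * (n * epsilon^2 - 8 * epsilon + 2 * n * epsilon + n)
    stopifnot(all(disc >= 0)) # cannot fail for n >= 2, epsilon < 1
    (log(n / 2 * (1 - epsilon^2) + 2 * epsilon +
           (1 - epsilon) / 2 * sqrt(disc)) - log(2)) / t
  }
}

#' Expected standing diversity conditional on survival
#'
#' Forward moment equation of the constant-rate birth--death process that
#' [ms_rate()] inverts: the expected number of extant species at time `t`,
#' given net rate `r` and relative extinction `epsilon`, conditional on the
#' clade surviving (stem: the single founding lineage has extant descendants;
#' crown: at least one of the two crown lineages does). Exposed so that the
#' closed-form estimator can be checked by numerical root finding.
#'
#' @param r net diversification rate per Myr.
#' @param t elapsed time, Myr.
#' @param epsilon relative extinction fraction in `[0, 1)`.
#' @param mode `"crown"` or `"stem"`.
#' @return Expected species count (not necessarily an integer).
#' @export
expected_diversity <- function(r, t, epsilon = 0, mode = c("crown", "stem")) {
  mode <- match.arg(mode)
  if (epsilon == 0) return(if (mode == "crown") 2 * exp(r * t) else exp(r * t))
  ert <- exp(r * t)
  if (mode == "stem") {
    (ert - epsilon) / (1 - epsilon)
  } else {
    # P(one lineage leaves no descendants at t)
    p_ext <- epsilon * (1 - exp(-r * t)) / (1 - epsilon * exp(-r * t))
    2 * ert / (1 - p_ext^2)
  }
}

#' Per-lineage rate table across crown-age bounds
#'
#' Applies a diversification-rate estimator to every lineage record for each
#' available crown-age bound (minimum, mean, maximum). Because the rate is
#' decreasing in age, the minimum-age column holds the numerically largest
#' rate. Records with missing minimum/maximum ages yield `NA` in the
#' corresponding column.
#'
#' @param records data frame of lineage records as returned by
#'   [read_lineage_csv()] or [paramo_lineages()]: columns `lineage_id`,
#'   `hotspot`, `n_species`, `crown_age_min`, `crown_age_mean`,
#'   `crown_age_max` (families and extra columns are carried along unused).
#' @param epsilon relative extinction fraction passed to [ms_rate()].
#' @param mode `"crown"` or `"stem"`.
#' @param n0 if non-`NULL`, use [pure_birth_rate()] with this initial
#'   diversity instead of the Magallon--Sanderson form (only meaningful with
#'   `epsilon = 0`).
#' @return Data frame with one row per lineage: `lineage_id`, `hotspot`,
#'   `n_species`, the three ages, and `rate_min_age`, `rate_mean_age`,
#'   `rate_max_age` in events per Myr.
#' @examples
#' head(rate_table(paramo_lineages()))
#' @export
rate_table <- function(records, epsilon = 0, mode = "crown", n0 = NULL) {
  required <- c("lineage_id", "hotspot", "n_species", "crown_age_mean")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop_arg("records lack column(s): %s", paste(missing_cols, collapse = ", "))
  for (col in c("crown_age_min", "crown_age_max"))
    if (!col %in% names(records)) records[[col]] <- rep(NA_real_, nrow(records))
  est <- function(n, t) {
    if (is.null(n0)) ms_rate(n, t, epsilon, mode) else pure_birth_rate(n, t, n0)
  }
  one_rate <- function(n, t, id) {
    if (is.na(t)) return(NA_real_)
    tryCatch(est(n, t),
             error = function(e) stop_arg("lineage '%s': %s", id, conditionMessage(e)))
  }
  out <- records[, intersect(c("lineage_id", "family", "hotspot", "n_species",
                               "crown_age_min", "crown_age_mean", "crown_age_max"),
                             names(records)), drop = FALSE]
  out$rate_min_age <- mapply(one_rate, records$n_species, records$crown_age_min,
                             records$lineage_id)
  out$rate_mean_age <- mapply(one_rate, records$n_species, records$crown_age_mean,
                              records$lineage_id)
  out$rate_max_age <- mapply(one_rate, records$n_species, records$crown_age_max,
                             records$lineage_id)
  rownames(out) <- NULL
  out
}
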