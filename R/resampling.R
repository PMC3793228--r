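check_rate_table <- function(table, k) {
  req <- c("lineage_id", "hotspot", "rate")
  if (!all(req %in% names(table)))
    stop_arg("rate table needs columns: %s", paste(req, collapse = ", "))
  if (any(!is.finite(table$rate))) stop_arg("all rates must be finite")
  if (anyDuplicated(table$lineage_id))
    stop_arg("duplicate lineage_id in rate table")
  counts <- table(table$hotspot)
  short <- names(counts)[counts < k]
  if (length(short))
    stop_arg("hotspot(s) with fewer than k = %d lineages: %s",
             k, paste(short, collapse = ", "))
  invisible(counts)
}

# Total order on lineages: rate descending, ties broken lexicographically by
# lineage_id (ties are measure-zero for real-valued rates but the order must
# still be reproducible). Returns the permutation of row indices.
rank_lineages <- function(table) {
  order(-table$rate, table$lineage_id, method = "radix")
}

#' One stratified resampling step
#'
#' Draws `k` lineages per hotspot without replacement, pools the draw, ranks
#' it by rate (descending; ties broken lexicographically by `lineage_id`) and
#' reports which hotspot holds the fastest lineage together with the length
#' of the leading run — how many of the top-ranked pooled lineages belong to
#' that hotspot before another hotspot first appears.
#'
#' @param table data frame `lineage_id`, `hotspot`, `rate`; every hotspot
#'   must field at least `k` lineages.
#' @param k lineages drawn per hotspot (the published procedure uses 5).
#' @return List with `fastest_hotspot` (character) and `top_run_length`
#'   (integer >= 1).
#' @export
sample_once <- function(table, k = 5) {
  check_rate_table(table, k)
  idx <- unlist(lapply(split(seq_len(nrow(table)), table$hotspot),
                       function(rows) rows[sample.int(length(rows), k)]),
                use.names = FALSE)
  pool <- table[idx, , drop = FALSE]
  ord <- rank_lineages(pool)
  hs <- pool$hotspot[ord]
  run <- which(hs != hs[1L])
  list(fastest_hotspot = hs[1L],
       top_run_length = if (length(run)) run[1L] - 1L else length(hs))
}

#' One resampling process of many stratified steps
#'
#' Repeats [sample_once()] `n_samples` times on a fixed rate table and
#' summarizes, per hotspot: the proportion of steps in which that hotspot
#' held the fastest lineage, and the maximum observed leading-run length
#' (0 for a hotspot never fastest). A secondary statistic `max_step_run`
#' gives the longest run of *consecutive steps* won by the hotspot, the
#' alternative reading of "consecutive fastest lineages".
#'
#' @inheritParams sample_once
#' @param n_samples number of stratified steps (the published procedure
#'   uses 1000).
#' @return Data frame, one row per hotspot (all hotspots in `table`, sorted):
#'   `hotspot`, `prop_fastest`, `max_run`, `max_step_run`.
#' @export
run_process <- function(table, k = 5, n_samples = 1000) {
  check_rate_table(table, k)
  hotspots <- sort(unique(table$hotspot))
  # presplit rows once; sample_once would revalidate per step
  by_h <- split(seq_len(nrow(table)), table$hotspot)
  wins <- integer(length(hotspots)); names(wins) <- hotspots
  max_run <- integer(length(hotspots)); names(max_run) <- hotspots
  winners <- character(n_samples)
  for (s in seq_len(n_samples)) {
    idx <- unlist(lapply(by_h, function(rows)
      rows[sample.int(length(rows), k)]), use.names = FALSE)
    pool <- table[idx, , drop = FALSE]
    ord <- rank_lineages(pool)
    hs <- pool$hotspot[ord]
    brk <- which(hs != hs[1L])
    run <- if (length(brk)) brk[1L] - 1L else length(hs)
    w <- hs[1L]
    winners[s] <- w
    wins[w] <- wins[w] + 1L
    if (run > max_run[w]) max_run[w] <- run
  }
  step_runs <- rle(winners)
  max_step_run <- vapply(hotspots, function(h) {
    l <- step_runs$lengths[step_runs$values == h]
    if (length(l)) max(l) else 0L
  }, integer(1))
  data.frame(hotspot = hotspots,
             prop_fastest = as.vector(wins) / n_samples,
             max_run = as.vector(max_run),
             max_step_run = as.vector(max_step_run))
}

#' Fastest-lineage resampling summary over independent iterations
#'
#' Runs `n_iterations` independent resampling processes of `n_samples`
#' stratified steps each (the published scheme is 1000 x 1000 with k = 5 on a
#' fixed rate table) and reports, per hotspot, the mean and 2.5/97.5
#' percentile interval over iterations of both summary statistics: the
#' probability of holding the fastest lineage and the maximum leading-run
#' length. Per-iteration RNG substreams are derived from `seed` by a counter
#' scheme, so results are reproducible and iteration-order independent.
#'
#' @inheritParams run_process
#' @param n_iterations number of independent repetitions of the process.
#' @param seed integer seed for reproducibility.
#' @param conf confidence level for the percentile intervals.
#' @return Data frame, one row per hotspot: `hotspot`, `prob_fastest_mean`,
#'   `prob_fastest_ci_low`, `prob_fastest_ci_high`, `max_run_mean`,
#'   `max_run_ci_low`, `max_run_ci_high`, `max_step_run_mean`.
#' @examples
#' tbl <- generate_lineage_table(
#'   data.frame(hotspot = c("A", "B"), n_lineages = 6,
#'              meanlog = log(c(1.4, 0.4)), sdlog = 0.4), seed = 7)
#' summarize_resampling(tbl, k = 5, n_samples = 50, n_iterations = 20, seed = 1)
#' @export
summarize_resampling <- function(table, k = 5, n_samples = 1000,
                                 n_iterations = 1000, seed = NULL,
                                 conf = 0.95) {
  check_rate_table(table, k)
  if (n_samples < 1 || n_iterations < 1)
    stop_arg("'n_samples' and 'n_iterations' must be >= 1")
  hotspots <- sort(unique(table$hotspot))
  props <- matrix(0, n_iterations, length(hotspots),
                  dimnames = list(NULL, hotspots))
  runs <- matrix(0, n_iterations, length(hotspots),
                 dimnames = list(NULL, hotspots))
  step_runs <- matrix(0, n_iterations, length(hotspots),
                      dimnames = list(NULL, hotspots))
  for (it in seq_len(n_iterations)) {
    res <- with_seed(if (is.null(seed)) NULL else substream_seed(seed, it),
                     run_process(table, k, n_samples))
    props[it, res$hotspot] <- res$prop_fastest
    runs[it, res$hotspot] <- res$max_run
    step_runs[it, res$hotspot] <- res$max_step_run
  }
  alpha <- (1 - conf) / 2
  qs <- function(m) apply(m, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                          names = FALSE)
  pq <- qs(props); rq <- qs(runs)
  data.frame(hotspot = hotspots,
             prob_fastest_mean = colMeans(props),
             prob_fastest_ci_low = pq[1, ], prob_fastest_ci_high = pq[2, ],
             max_run_mean = colMeans(runs),
             max_run_ci_low = rq[1, ], max_run_ci_high = rq[2, ],
             max_step_run_mean = colMeans(step_runs),
             row.names = NULL)
}

#' Exact fastest-hotspot probabilities by enumeration
#'
#' Computes, without simulation, the probability that each hotspot holds the
#' fastest lineage in a stratified draw of `k` lineages per hotspot without
#' replacement, by enumerating every k-subset of each hotspot. Because only
#' the best-ranked lineage of each hotspot's subset matters, the joint
#' product is reduced to per-hotspot distributions of the best rank, and the
#' probabilities follow exactly. Serves as the oracle against which the
#' Monte-Carlo procedure is validated on small tables.
#'
#' @inheritParams sample_once
#' @param max_combinations refuse tables whose total per-hotspot subset count
#'   exceeds this bound.
#' @return Named numeric vector of probabilities, one per hotspot, summing
#'   to 1.
#' @examples
#' tbl <- data.frame(lineage_id = c("x1", "x2", "y1", "y2"),
#'                   hotspot = c("X", "X", "Y", "Y"), rate = c(3, 1, 2, 0))
#' exact_fastest_probability(tbl, k = 1) # X: 0.75, Y: 0.25
#' @export
exact_fastest_probability <- function(table, k = 5, max_combinations = 1e6) {
  check_rate_table(table, k)
  by_h <- split(seq_len(nrow(table)), table$hotspot)
  n_comb <- sum(vapply(by_h, function(r) choose(length(r), k), numeric(1)))
  if (n_comb > max_combinations)
    stop_arg("%.3g subsets exceed the enumeration bound of %g",
             n_comb, max_combinations)
  # global total order; rank 1 = fastest overall
  glob <- integer(nrow(table))
  glob[rank_lineages(table)] <- seq_len(nrow(table))
  nr <- nrow(table)
  # P(best rank of hotspot h's k-subset = r), for each hotspot
  best_dist <- lapply(by_h, function(rows) {
    subs <- utils::combn(rows, k)
    best <- apply(matrix(glob[subs], nrow = k), 2, min)
    tabulate(best, nbins = nr) / ncol(subs)
  })
  hotspots <- names(by_h)
  # P(h fastest) = sum_r P(best_h = r) * prod_{h' != h} P(best_h' > r)
  surv <- lapply(best_dist, function(p) 1 - cumsum(p)) # P(best > r)
  probs <- vapply(seq_along(hotspots), function(i) {
    other <- rep(1, nr)
    for (j in seq_along(hotspots)) if (j != i) other <- other * surv[[j]]
    sum(best_dist[[i]] * other)
  }, numeric(1))
  names(probs) <- hotspots
  probs
}
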