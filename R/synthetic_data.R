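#' Simulate a constant-rate Yule chronogram
#'
#' Forward simulation of a pure-birth (Yule) process with speciation rate
#' `lambda` per lineage per Myr and no extinction, started from two crown
#' lineages (matching the crown-age semantics of the rate estimators) or one
#' stem lineage. Waiting times between speciation events are exponential with
#' rate `lambda` times the number of extant lineages.
#'
#' Exactly one stopping rule must be given. With `stop_time` the process runs
#' for that many Myr and the crown age equals `stop_time` exactly. With
#' `stop_tips` the process runs until the target tip count is reached and the
#' tree is then sampled after one further exponential waiting time, i.e. just
#' before the next event would occur, so all tip branches are positive.
#'
#' @param lambda speciation rate per lineage per Myr, > 0.
#' @param stop_time stop after this many Myr (crown age of the result).
#' @param stop_tips stop at this many extant tips (>= starting count).
#' @param origin `"crown"` (start with 2 lineages) or `"stem"` (start with 1).
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return An ultrametric `"phylo"` object with tips `t1, t2, ...` and
#'   attribute `event_times`, the recorded speciation times measured from the
#'   start of the process (useful as an independent check on node ages).
#' @examples
#' tr <- simulate_yule(0.5, stop_time = 5, seed = 1)
#' crown_age(tr) # 5
#' @export
simulate_yule <- function(lambda, stop_time = NULL, stop_tips = NULL,
                          origin = c("crown", "stem"), seed = NULL) {
  simulate_birth_death(lambda, mu = 0, stop_time = stop_time,
                       stop_tips = stop_tips, origin = match.arg(origin),
                       condition_on_survival = FALSE, seed = seed)
}

#' Simulate a birth-death chronogram of extant lineages
#'
#' Forward simulation of a constant-rate birth--death process (speciation
#' `lambda`, extinction `mu < lambda`), with extinct lineages pruned so the
#' returned tree is the reconstructed chronogram of extant tips. With
#' `condition_on_survival` the simulation is rejection-sampled until at least
#' two extant tips survive to the stopping time, which is the sample a crown
#' estimator sees in practice.
#'
#' @inheritParams simulate_yule
#' @param mu extinction rate per lineage per Myr, `0 <= mu < lambda`.
#' @param condition_on_survival retry (up to `max_tries`) until >= 2 extant
#'   tips remain. Without it, extinct or single-tip outcomes return `NULL`.
#' @param max_tries rejection-sampling cap.
#' @return A `"phylo"` object (or `NULL` if unconditioned and the process
#'   died), with attribute `event_times` holding the speciation times of the
#'   *surviving* reconstructed nodes, measured from process start.
#' @export
simulate_birth_death <- function(lambda, mu = 0, stop_time = NULL,
                                 stop_tips = NULL,
                                 origin = c("crown", "stem"),
                                 condition_on_survival = TRUE,
                                 seed = NULL, max_tries = 1e5) {
  origin <- match.arg(origin)
  if (!is.numeric(lambda) || lambda <= 0) stop_arg("'lambda' must be > 0")
  if (!is.numeric(mu) || mu < 0 || mu >= lambda)
    stop_arg("'mu' must satisfy 0 <= mu < lambda")
  if (is.null(stop_time) == is.null(stop_tips))
    stop_arg("give exactly one of 'stop_time' or 'stop_tips'")
  if (!is.null(stop_time) && stop_time <= 0) stop_arg("'stop_time' must be > 0")
  n_start <- if (origin == "crown") 2L else 1L
  if (!is.null(stop_tips) && (stop_tips < n_start || stop_tips < 2))
    stop_arg("'stop_tips' must be >= max(2, starting lineage count)")
  with_seed(seed, {
    for (try in seq_len(if (condition_on_survival) max_tries else 1L)) {
      sim <- bd_forward(lambda, mu, stop_time, stop_tips, n_start)
      if (!is.null(sim)) {
        built <- lineages_to_phylo(sim$lineages, sim$t_end)
        if (!is.null(built)) {
          tree <- built$tree
          # speciation times (from process start) of the nodes that survive
          # reconstruction, straight from the simulator's own bookkeeping
          attr(tree, "event_times") <- sort(built$split_times)
          attr(tree, "t_final") <- sim$t_end
          attr(tree, "config") <- list(lambda = lambda, mu = mu,
                                       stop_time = stop_time,
                                       stop_tips = stop_tips, origin = origin)
          return(tree)
        }
      }
      if (!condition_on_survival) return(NULL)
    }
    stop("no surviving tree in ", max_tries, " attempts", call. = FALSE)
  })
}

# One forward pass of the birth-death process. Lineages are rows of a record
# set: parent index, birth time, end time (split/death/present), fate.
# Returns NULL when stop_tips can never be reached (all dead).
bd_forward <- function(lambda, mu, stop_time, stop_tips, n_start) {
  parent <- rep(0L, n_start)
  t_birth <- rep(0, n_start)
  t_end <- rep(NA_real_, n_start)
  fate <- rep(NA_character_, n_start)   # "split" | "dead" | "extant"
  alive <- seq_len(n_start)
  now <- 0
  total_rate <- function() length(alive) * (lambda + mu)
  repeat {
    if (!length(alive)) {
      if (!is.null(stop_tips)) return(NULL)
      break
    }
    if (!is.null(stop_tips) && length(alive) >= stop_tips) {
      # sample just before the next event so tip branches are positive
      now <- now + stats::rexp(1, total_rate())
      break
    }
    wait <- stats::rexp(1, total_rate())
    if (!is.null(stop_time) && now + wait >= stop_time) {
      now <- stop_time
      break
    }
    now <- now + wait
    who <- alive[sample.int(length(alive), 1L)]
    if (stats::runif(1) < lambda / (lambda + mu)) {
      t_end[who] <- now; fate[who] <- "split"
      parent <- c(parent, who, who)
      t_birth <- c(t_birth, now, now)
      t_end <- c(t_end, NA_real_, NA_real_)
      fate <- c(fate, NA_character_, NA_character_)
      alive <- c(setdiff(alive, who), length(parent) - 1L, length(parent))
    } else {
      t_end[who] <- now; fate[who] <- "dead"
      alive <- setdiff(alive, who)
    }
  }
  t_end[alive] <- now
  fate[alive] <- "extant"
  list(lineages = data.frame(parent = parent, t_birth = t_birth,
                             t_end = t_end, fate = fate), t_end = now)
}

# Convert the lineage record set into a reconstructed phylo of extant tips:
# emit Newick recursively, pruning dead subtrees and collapsing the
# unifurcations pruning leaves behind. Also collects the speciation times of
# the split nodes that survive reconstruction (the crown split, for a
# crown-start process with both sides surviving, is at time 0).
# Returns NULL if < 2 extant tips.
lineages_to_phylo <- function(lin, t_now) {
  n <- nrow(lin)
  children <- split(seq_len(n), factor(lin$parent, levels = 0:n))
  tip_counter <- 0L
  split_times <- numeric(0)
  # returns list(core=<newick without pendant length>, len) or NULL if extinct
  emit <- function(i) {
    len <- lin$t_end[i] - lin$t_birth[i]
    if (lin$fate[i] == "dead") return(NULL)
    if (lin$fate[i] == "extant") {
      tip_counter <<- tip_counter + 1L
      return(list(core = paste0("t", tip_counter), len = len))
    }
    kids <- lapply(children[[i + 1L]], emit)
    kids <- kids[!vapply(kids, is.null, logical(1))]
    if (!length(kids)) return(NULL)
    if (length(kids) == 1L) # collapse the unifurcation left by pruning
      return(list(core = kids[[1]]$core, len = len + kids[[1]]$len))
    split_times <<- c(split_times, lin$t_end[i])
    inner <- paste(vapply(kids, function(k)
      sprintf("%s:%.12f", k$core, k$len), character(1)), collapse = ",")
    list(core = paste0("(", inner, ")"), len = len)
  }
  roots <- which(lin$parent == 0L)
  parts <- lapply(roots, emit)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(NULL)
  if (length(parts) == 1L) {
    if (!startsWith(parts[[1]]$core, "(")) return(NULL) # a single extant tip
    newick <- paste0(parts[[1]]$core, ";")
  } else {
    split_times <- c(split_times, 0) # the crown split itself
    newick <- paste0("(", paste(vapply(parts, function(k)
      sprintf("%s:%.12f", k$core, k$len), character(1)), collapse = ","), ");")
  }
  tree <- ape::read.tree(text = newick)
  if (is.null(tree) || ape::Ntip(tree) < 2L) return(NULL)
  list(tree = tree, split_times = split_times)
}

#' Generate a synthetic per-hotspot lineage-rate table
#'
#' Draws per-lineage net diversification rates for a set of hotspots from
#' log-normal distributions, one per hotspot, giving the fastest-lineage
#' resampling procedure a table with controllable ground truth. Rates in the
#' printed data are positive and strongly right-skewed within hotspots, which
#' the log-normal reproduces; it is a modelling convenience, not an inference.
#'
#' @param specs data frame with one row per hotspot: columns `hotspot`,
#'   `n_lineages` (>= 1), `meanlog` and `sdlog` (log-scale location and
#'   spread of the rate distribution, `sdlog >= 0`).
#' @param seed optional integer seed.
#' @return Data frame `lineage_id`, `hotspot`, `rate` with
#'   `sum(specs$n_lineages)` rows; lineage ids are `<hotspot>_L<k>`,
#'   zero-padded so lexicographic tie-breaking is well defined.
#' @examples
#' specs <- data.frame(hotspot = c("A", "B"), n_lineages = 5,
#'                     meanlog = log(c(1.4, 0.4)), sdlog = 0.5)
#' generate_lineage_table(specs, seed = 1)
#' @export
generate_lineage_table <- function(specs, seed = NULL) {
  req <- c("hotspot", "n_lineages", "meanlog", "sdlog")
  if (!all(req %in% names(specs)))
    stop_arg("specs needs columns: %s", paste(req, collapse = ", "))
  if (any(specs$n_lineages < 1)) stop_arg("'n_lineages' must be >= 1")
  if (any(specs$sdlog < 0) || anyNA(specs$sdlog)) stop_arg("'sdlog' must be >= 0")
  if (anyDuplicated(specs$hotspot)) stop_arg("duplicate hotspot in specs")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(specs)), function(i) {
      k <- specs$n_lineages[i]
      data.frame(
        lineage_id = sprintf("%s_L%03d", specs$hotspot[i], seq_len(k)),
        hotspot = specs$hotspot[i],
        rate = stats::rlnorm(k, specs$meanlog[i], specs$sdlog[i]))
    })
    do.call(rbind, rows)
  })
}

#' Packaged Paramo lineage table
#'
#' The thirteen Paramo plant lineages with their standing diversity, crown
#' ages (minimum / mean / maximum of the dated estimates, Ma) and Pleistocene
#' divergence counts, as transcribed from the source compilation. Missing
#' cells (the min/max ages of the Jamesonia+Eriosorus clade, the Valeriana
#' Pleistocene count) are `NA`.
#'
#' @return Data frame of 13 lineage records (see [read_lineage_csv()] for the
#'   column schema; `pleistocene_total` gives the species count the
#'   Pleistocene tally is out of).
#' @examples
#' paramo_lineages()[, c("lineage_id", "n_species", "crown_age_mean")]
#' @export
paramo_lineages <- function() {
  read_lineage_csv(system.file("extdata", "paramo_lineages.csv",
                               package = "paramodiv", mustWork = TRUE))
}

#' Packaged hotspot metadata table
#'
#' Area, species richness and endemism of the eight biodiversity hotspots
#' compared, with the published mean net diversification rate and per-area
#' density cells retained in `*_printed` columns so they can be validated
#' against recomputation (see [validate_hotspot_cells()]).
#'
#' @return Data frame of 8 hotspot records: `hotspot`, `area_km2`,
#'   `species_total`, `species_endemic`, `mean_rate_printed`,
#'   `species_density_printed`, `speciation_density_printed`.
#' @export
hotspot_metadata <- function() {
  suppressWarnings(
    read_hotspot_csv(system.file("extdata", "hotspot_metadata.csv",
                                 package = "paramodiv", mustWork = TRUE)))
}
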