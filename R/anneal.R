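# Simulated-annealing structure search over discrete Bayesian networks,
# with a cooling/reannealing/random-restart schedule
# and an ensemble of the top-scoring distinct structures.

#' Annealing schedule for the structure search
#'
#' Defaults follow the published search configuration: initial temperature
#' 10000, cooling factor 0.7, reannealing temperature 800, at most 2500
#' accepted or 10000 proposed networks before cooling, at least 500
#' accepted networks between reannealing events, a maximum parent count of
#' 5, and up to 10000 random restarts.  The published one-hour wall-clock
#' budget is replaced by a total proposal-count budget so runs are exactly
#' reproducible; `restarts` caps how many random restarts share that
#' budget.
#'
#' @param t0 initial temperature (> 0).
#' @param cooling cooling factor in (0, 1).
#' @param t_reanneal reannealing temperature (> 0).
#' @param max_accepted accepted networks before a cooling event.
#' @param max_proposed proposed networks before a cooling event.
#' @param min_accepted accepted networks required between reannealing
#'   events; fewer triggers a reanneal at the next cooling event.
#' @param restarts maximum number of random restarts.
#' @param max_parents in-degree bound (>= 0).
#' @param budget total number of proposals across all restarts (> 0).
#' @param ensemble_size number of top-scoring distinct DAGs to keep.
#' @param seed integer seed; the whole search is a deterministic function
#'   of data + schedule.
#' @return object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t0 = 10000, cooling = 0.7, t_reanneal = 800,
                            max_accepted = 2500L, max_proposed = 10000L,
                            min_accepted = 500L, restarts = 10000L,
                            max_parents = 5L, budget = 1e6,
                            ensemble_size = 20L, seed = 1L) {
  if (t0 <= 0 || t_reanneal <= 0) abort("temperatures must be positive")
  if (cooling <= 0 || cooling >= 1) abort("cooling factor must lie in (0, 1)")
  if (max_parents < 0L) abort("max_parents must be >= 0")
  if (budget <= 0) abort("proposal budget must be positive")
  structure(list(t0 = t0, cooling = cooling, t_reanneal = t_reanneal,
                 max_accepted = as.integer(max_accepted),
                 max_proposed = as.integer(max_proposed),
                 min_accepted = as.integer(min_accepted),
                 restarts = as.integer(restarts),
                 max_parents = as.integer(max_parents),
                 budget = as.double(budget),
                 ensemble_size = as.integer(ensemble_size),
                 seed = as.integer(seed)),
            class = "anneal_schedule")
}

#' Search DAG space by simulated annealing
#'
#' Metropolis search over single-edge moves (add, delete, reverse) that
#' preserve acyclicity and the parent bound.  A move with score change
#' `delta` is accepted with probability `min(1, exp(delta / T))`.  The
#' temperature is multiplied by the cooling factor whenever the accepted
#' or proposed count since the last cooling event reaches its cap; if
#' fewer than `min_accepted` networks were accepted since the last
#' reanneal, the temperature is reset to the reannealing temperature
#' instead.  The search restarts from a fresh random DAG (random
#' topological order, Bernoulli(0.1) edges under the parent bound) until
#' the restart cap or the proposal budget is exhausted.  The ensemble
#' collects the `ensemble_size` best-scoring *distinct* structures ever
#' visited.
#'
#' Two collection modes are available.  `"restart_best"` (default) keeps
#' each restart's best-scoring structure and returns the top distinct
#' structures across restarts: with multiple restarts this concentrates
#' the ensemble on the score optimum's Markov equivalence class, which is
#' what consensus edge frequencies need for exact skeleton recovery.
#' `"all_visited"` keeps the best distinct structures over every state
#' the chains ever occupied; its lower ranks are always dominated by the
#' single cheapest one-extra-edge family (score-tied by Markov
#' equivalence), which inflates that false pair's consensus frequency —
#' useful for diagnostics, not recommended for recovery.
#'
#' @param data discrete tibble or matrix of states (genes x samples), at
#'   least 2 nodes.
#' @param schedule an [anneal_schedule()].
#' @param ess equivalent sample size for the BDeu score.
#' @param collect ensemble collection mode, see Details.
#' @return object of class `network_ensemble`: list of `networks`
#'   (each `edges` tibble, `adjacency`, `score`), sorted by score
#'   descending, plus `nodes` and the `schedule`.
#' @export
#' @examples
#' fix <- sample_compendium(stm_fixture_bn(), 200, seed = 1)
#' ens <- anneal_search(fix$discrete,
#'                      anneal_schedule(budget = 2000, restarts = 2, seed = 1))
#' ens$networks[[1]]$score
anneal_search <- function(data, schedule = anneal_schedule(), ess = 1,
                          collect = c("restart_best", "all_visited")) {
  collect <- match.arg(collect)
  stopifnot(inherits(schedule, "anneal_schedule"))
  m <- as_gene_matrix(data, "discrete")
  nodes <- rownames(m)
  n <- length(nodes)
  if (n < 2L) abort("need at least 2 nodes to search")
  if (n > 57L) abort("the search supports at most 57 nodes")
  raw <- withr::with_seed(schedule$seed,
    .anneal_cpp(t(m), unclass(schedule), ess, collect))
  networks <- purrr::map(raw, function(nw) {
    adj <- nw$adjacency
    dimnames(adj) <- list(nodes, nodes)
    idx <- which(adj != 0L, arr.ind = TRUE)
    list(edges = tibble(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]]),
         adjacency = adj, score = nw$score)
  })
  structure(list(networks = networks, nodes = nodes, schedule = schedule),
            class = "network_ensemble")
}

#' @export
print.network_ensemble <- function(x, ...) {
  cat("Network ensemble:", length(x$networks), "distinct DAGs over",
      length(x$nodes), "nodes; best score",
      format(x$networks[[1L]]$score, digits = 8), "\n")
  invisible(x)
}

#' @export
tidy.network_ensemble <- function(x, ...) {
  purrr::imap(x$networks, function(nw, i) {
    dplyr::mutate(nw$edges, network = i, score = nw$score)
  }) |> dplyr::bind_rows()
}

#' @export
glance.network_ensemble <- function(x, ...) {
  scores <- vapply(x$networks, `[[`, numeric(1), "score")
  tibble(n_networks = length(scores), n_nodes = length(x$nodes),
         best_score = max(scores), worst_kept_score = min(scores))
}
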