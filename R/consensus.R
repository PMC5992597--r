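# Consensus network over an ensemble of top-scoring DAGs: directional
# edge frequencies, bidirectional edge significance, a retention
# threshold, and influence signs from the underlying discrete data.

#' Consensus network from a structure ensemble
#'
#' For each ordered node pair, `f(u -> v)` is the fraction of ensemble
#' DAGs containing that directed edge.  The *edge significance* of an
#' unordered pair is the sum of both directional frequencies (a DAG can
#' contain at most one direction, so significance lies in \[0, 1\]).  A
#' pair is retained iff its significance strictly exceeds `threshold`
#' (default 0.4, the published confidence cut-off).  The dominant
#' direction is the more frequent one; equal frequencies leave the edge
#' undirected.  When `data` is supplied each pair is annotated with an
#' influence sign from [influence_sign()].
#'
#' @param ensemble a [anneal_search()] result (or compatible list).
#' @param threshold retention threshold on significance (strict `>`).
#' @param data optional discrete tibble/matrix for influence signs.
#' @param sign_threshold passed to [influence_sign()].
#' @return object of class `consensus_network`: a tibble with one row per
#'   unordered pair seen in the ensemble (`from`, `to`, `freq_fwd`,
#'   `freq_rev`, `significance`, `retained`, `direction`, `sign`), plus
#'   attributes `nodes`, `threshold`, `n_networks`.
#' @export
consensus <- function(ensemble, threshold = 0.4, data = NULL,
                      sign_threshold = 0.05) {
  networks <- ensemble$networks
  if (length(networks) == 0L) abort("ensemble is empty")
  nodes <- ensemble$nodes
  counts <- Reduce(`+`, lapply(networks, function(nw) nw$adjacency != 0L))
  freq <- counts / length(networks)
  idx <- which(upper.tri(freq) & (freq + t(freq)) > 0, arr.ind = TRUE)
  tbl <- tibble(
    from = nodes[idx[, 1L]], to = nodes[idx[, 2L]],
    freq_fwd = freq[idx], freq_rev = t(freq)[idx]) |>
    dplyr::mutate(
      significance = .data$freq_fwd + .data$freq_rev,
      retained = .data$significance > threshold,
      direction = dplyr::case_when(
        freq_fwd > freq_rev ~ "forward",
        freq_rev > freq_fwd ~ "reverse",
        TRUE ~ "undirected")) |>
    dplyr::arrange(dplyr::desc(.data$significance), .data$from, .data$to)
  tbl$sign <- if (is.null(data)) {
    NA_character_
  } else {
    m <- as_gene_matrix(data, "discrete")
    purrr::map2_chr(tbl$from, tbl$to, function(u, v)
      influence_sign(m[u, ], m[v, ], threshold = sign_threshold))
  }
  structure(tbl, nodes = nodes, threshold = threshold,
            n_networks = length(networks),
            class = c("consensus_network", class(tbl)))
}

#' Influence sign of a node pair
#'
#' Sign annotation for consensus edges: the Spearman rank correlation of
#' the two state vectors, mapped to `"+"`, `"-"` or `"0"` (absolute
#' correlation below `threshold`, or either vector constant).  Symmetric
#' in its arguments and deterministic.
#'
#' @param x,y equal-length state (or expression) vectors.
#' @param threshold dead zone on |rho| mapped to `"0"` (default 0.05).
#' @return one of `"+"`, `"-"`, `"0"`.
#' @export
#' @examples
#' influence_sign(c(0, 0, 2, 2), c(2, 2, 0, 0))  # "-"
influence_sign <- function(x, y, threshold = 0.05) {
  if (length(x) != length(y)) abort("vectors must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return("0")
  rho <- cor(x, y, method = "spearman")
  if (is.na(rho) || abs(rho) < threshold) "0" else if (rho > 0) "+" else "-"
}

#' @export
tidy.consensus_network <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.consensus_network <- function(x, ...) {
  tibble(n_nodes = length(attr(x, "nodes")),
         n_pairs = nrow(x),
         n_retained = sum(x$retained),
         threshold = attr(x, "threshold"),
         n_networks = attr(x, "n_networks"))
}

#' @export
print.consensus_network <- function(x, ...) {
  cat("Consensus network over", length(attr(x, "nodes")), "nodes:",
      sum(x$retained), "pairs retained at significance >",
      attr(x, "threshold"), "from", attr(x, "n_networks"), "networks\n")
  NextMethod()
}

#' Compare a consensus network against a ground truth
#'
#' Skeleton precision and recall are computed on unordered retained pairs
#' versus the true edge set.  Direction accuracy is reported over retained
#' true pairs with a dominant direction; for edges that are reversible
#' within the Markov equivalence class of the true DAG (covered edges and
#' star-root edges have this property) orientation is not identifiable
#' from observational data, so direction accuracy is reported but not a
#' correctness criterion.
#'
#' @param truth a [ground_truth_bn()] or an edge tibble (`from`, `to`).
#' @param consensus a [consensus()] result over the same node universe.
#' @return tibble with `precision`, `recall`, `direction_accuracy`,
#'   `n_retained`, `n_true`.  By convention an empty consensus has
#'   precision 1 (with a warning when the truth is non-empty).
#' @export
recovery_eval <- function(truth, consensus) {
  true_edges <- if (inherits(truth, "ground_truth_bn")) truth$edges else as_tibble(truth)
  truth_nodes <- if (inherits(truth, "ground_truth_bn")) truth$nodes else
    unique(c(true_edges$from, true_edges$to))
  cn_nodes <- attr(consensus, "nodes")
  if (!setequal(truth_nodes, cn_nodes)) {
    abort(paste0("node universes differ: ",
                 paste(symdiff_chr(truth_nodes, cn_nodes), collapse = ", ")))
  }
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
  true_pairs <- pair_key(true_edges$from, true_edges$to)
  kept <- consensus[consensus$retained, , drop = FALSE]
  kept_pairs <- pair_key(kept$from, kept$to)
  tp <- intersect(kept_pairs, true_pairs)
  precision <- if (length(kept_pairs) == 0L) {
    if (length(true_pairs)) warn("empty consensus: precision reported as 1 by convention")
    1
  } else {
    length(tp) / length(kept_pairs)
  }
  recall <- if (length(true_pairs) == 0L) 1 else length(tp) / length(true_pairs)
  directed <- kept[pair_key(kept$from, kept$to) %in% true_pairs &
                     kept$direction != "undirected", , drop = FALSE]
  dir_acc <- if (nrow(directed) == 0L) NA_real_ else {
    oriented_from <- ifelse(directed$direction == "forward", directed$from, directed$to)
    oriented_to <- ifelse(directed$direction == "forward", directed$to, directed$from)
    mean(paste(oriented_from, oriented_to) %in% paste(true_edges$from, true_edges$to))
  }
  tibble(precision = precision, recall = recall,
         direction_accuracy = dir_acc,
         n_retained = length(kept_pairs), n_true = length(true_pairs))
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))
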