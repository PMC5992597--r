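# Hierarchical (UPGMA) and k-means clustering of expression profiles, and
# hypergeometric gene-set enrichment.

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Agglomerates gene rows by unweighted pair-group average linkage: the
#' distance between two clusters is the mean of all between-cluster pair
#' distances, so merge heights are non-decreasing (ultrametric).  Ties are
#' broken deterministically by the lexicographically smallest cluster-id
#' pair (leaves are numbered in input order, merged clusters in creation
#' order).
#'
#' @param x expression tibble (first column `gene`) or matrix with gene
#'   row names; at least 2 rows, all values finite.
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson r between
#'   row vectors).
#' @return object of class `upgma_tree` (also a valid `hclust`): merge
#'   history, merge heights, labels.
#' @export
#' @examples
#' m <- tibble::tibble(gene = c("a", "b", "c", "d"),
#'                     s1 = c(0, 1, 10, 11), s2 = 0)
#' upgma_cluster(m)$height
upgma_cluster <- function(x, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  m <- as_gene_matrix(x)
  n <- nrow(m)
  if (n < 2L) abort("need at least 2 rows to cluster")
  d <- if (metric == "euclidean") {
    as.matrix(dist(m))
  } else {
    1 - cor(t(m))
  }
  diag(d) <- Inf
  # active cluster bookkeeping: id (leaf 1..n, merges n+1..), size
  id <- seq_len(n); size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L); height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(d == min(d), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    # lexicographic tie-break on (smaller id, larger id)
    key <- order(pmin(id[idx[, 1L]], id[idx[, 2L]]),
                 pmax(id[idx[, 1L]], id[idx[, 2L]]))[1L]
    i <- idx[key, 1L]; j <- idx[key, 2L]
    height[step] <- d[i, j]
    merge[step, ] <- sort(c(hclust_code(id[i], n), hclust_code(id[j], n)))
    # UPGMA update: size-weighted average of distances
    keep <- setdiff(seq_along(id), c(i, j))
    newd <- (size[i] * d[i, keep] + size[j] * d[j, keep]) / (size[i] + size[j])
    d <- d[keep, keep, drop = FALSE]
    d <- rbind(cbind(d, newd), c(newd, Inf))
    id <- c(id[keep], n + step)
    size <- c(size[keep], size[i] + size[j])
  }
  tree <- structure(
    list(merge = merge, height = height, order = integer(n),
         labels = rownames(m), method = "average",
         dist.method = metric, call = match.call()),
    class = c("upgma_tree", "hclust"))
  tree$order <- leaf_order(merge, n)
  tree
}

# hclust merge coding: leaves negative, prior merges positive
hclust_code <- function(id, n) if (id <= n) -id else id - n

leaf_order <- function(merge, n) {
  expand <- function(k) {
    if (k < 0L) return(-k)
    c(expand(merge[k, 1L]), expand(merge[k, 2L]))
  }
  expand(nrow(merge))
}

#' @export
tidy.upgma_tree <- function(x, ...) {
  tibble(step = seq_along(x$height),
         left = x$merge[, 1L], right = x$merge[, 2L],
         height = x$height)
}

#' @export
glance.upgma_tree <- function(x, ...) {
  tibble(n_leaves = length(x$labels), n_merges = length(x$height),
         max_height = max(x$height), metric = x$dist.method)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are derived from the merge heights (each branch spans
#' the height difference between a node and its parent, with leaves at
#' height zero).
#'
#' @param tree an [upgma_cluster()] result (or any `hclust`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' k-means clustering of expression profiles
#'
#' Lloyd's algorithm from seeded random initial centroids (k distinct
#' rows).  Iterations reassign rows to the nearest centroid and recompute
#' means until assignments are stable; the within-cluster sum of squares
#' is non-increasing across iterations.  An emptied cluster is re-seeded
#' from the point farthest from its assigned centroid.
#'
#' @param x expression tibble or matrix.
#' @param k number of clusters (1 <= k <= rows).
#' @param seed integer seed; fixed seed gives identical labels.
#' @param max_iter iteration cap.
#' @return tibble `gene`, `cluster`, with attributes `wcss` (total
#'   within-cluster sum of squares) and `centers`.
#' @export
kmeans_cluster <- function(x, k, seed = 1L, max_iter = 100L) {
  m <- as_gene_matrix(x)
  if (any(!is.finite(m))) abort("values must be finite")
  n <- nrow(m)
  if (k <= 0L) abort("k must be positive")
  if (k > n) abort("k cannot exceed the number of rows")
  withr::with_seed(seed, {
    centers <- m[sample.int(n, k), , drop = FALSE]
    assign_prev <- rep(0L, n)
    for (iter in seq_len(max_iter)) {
      d2 <- outer(rowSums(m^2), rowSums(centers^2), "+") - 2 * m %*% t(centers)
      assign <- max.col(-d2, ties.method = "first")
      for (c_empty in setdiff(seq_len(k), unique(assign))) {
        far <- which.max(d2[cbind(seq_len(n), assign)])
        centers[c_empty, ] <- m[far, ]
        assign[far] <- c_empty
      }
      if (identical(assign, assign_prev)) break
      assign_prev <- assign
      for (cl in seq_len(k)) {
        centers[cl, ] <- colMeans(m[assign == cl, , drop = FALSE])
      }
    }
  })
  wcss <- sum((m - centers[assign_prev, , drop = FALSE])^2)
  out <- tibble(gene = rownames(m), cluster = assign_prev)
  attr(out, "wcss") <- wcss
  attr(out, "centers") <- centers
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each set of a collection, within a stated universe.  Collection
#' sets are intersected with the universe before testing; the query must
#' be a subset of the universe.  P-values are BH-adjusted across sets.
#'
#' @param query character vector of query genes (subset of `universe`).
#' @param universe character vector, the testing universe.
#' @param collection named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return tibble sorted by ascending p: `set`, `universe_size`,
#'   `set_size`, `query_size`, `overlap`, `p`, `p_bh`.
#' @export
#' @examples
#' hypergeom_enrich(letters[1:5], letters[1:20], list(s = letters[1:5]))
hypergeom_enrich <- function(query, universe, collection) {
  query <- unique(query); universe <- unique(universe)
  extra <- setdiff(query, universe)
  if (length(extra)) {
    abort(paste0("query genes outside the universe: ",
                 paste(head(extra, 10L), collapse = ", ")))
  }
  n_u <- length(universe); n_q <- length(query)
  rows <- purrr::imap(collection, function(members, nm) {
    set <- intersect(unique(members), universe)
    k <- length(intersect(set, query))
    # P(overlap >= k) drawing n_q genes from a universe with |set| successes
    p <- phyper(k - 1L, length(set), n_u - length(set), n_q, lower.tail = FALSE)
    tibble(set = nm, universe_size = n_u, set_size = length(set),
           query_size = n_q, overlap = k, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bh <- bh_adjust(out$p)
  dplyr::arrange(out, .data$p, .data$set)
}
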