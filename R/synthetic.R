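# Synthetic ground-truth fixtures: a discrete Bayesian network with a
# Gaussian log2 emission layer emulating a microarray compendium, and a
# replicated induction timecourse with planted log2 effects.

#' Construct a ground-truth Bayesian network
#'
#' Defines the generative process for synthetic compendium data: a DAG over
#' gene nodes, one conditional probability table (CPT) per node over the
#' three expression states \{0, 1, 2\} indexed by parent-state
#' combinations, and a Gaussian emission model mapping states to continuous
#' log2 readouts.
#'
#' CPTs are matrices with `3^(number of parents)` rows (parent-state
#' combinations in mixed-radix order, first parent varying fastest) and 3
#' columns (child states).  Emission means must be strictly increasing in
#' the state index so that discretisation can recover states in the
#' noiseless limit; the defaults `reference + c(-2, 0, 2)` log2 units are
#' chosen so the two-fold discretisation rule inverts the emission map
#' exactly.
#'
#' @param nodes character vector of node (gene) ids.
#' @param edges two-column data frame (`from`, `to`) of directed edges;
#'   may have zero rows.
#' @param cpt named list of CPT matrices, one per node.
#' @param emission_means per-state emission means on the log2 scale,
#'   length-3 numeric (shared by all nodes) or a named list of length-3
#'   vectors per node.
#' @param emission_sd emission noise standard deviation (log2 units).
#' @return object of class `ground_truth_bn`.
#' @export
ground_truth_bn <- function(nodes, edges, cpt,
                            emission_means = c(-2, 0, 2),
                            emission_sd = 0.3) {
  edges <- as_tibble(as.data.frame(edges, stringsAsFactors = FALSE))
  if (nrow(edges) && !all(c(edges$from, edges$to) %in% nodes)) {
    abort("edge endpoints must be listed in `nodes`")
  }
  if (!is.list(emission_means)) {
    emission_means <- setNames(rep(list(as.numeric(emission_means)), length(nodes)), nodes)
  }
  bn <- structure(
    list(nodes = nodes, edges = edges, cpt = cpt,
         emission_means = emission_means, emission_sd = emission_sd),
    class = "ground_truth_bn")
  validate_ground_truth_bn(bn)
}

#' Validate a ground-truth network
#'
#' Checks acyclicity (reporting a cycle if one exists), CPT row sums
#' (within 1e-12 of 1), CPT coverage of all parent-state combinations, and
#' strictly increasing emission means.
#'
#' @param bn a `ground_truth_bn`.
#' @return `bn`, invisibly, or an error.
#' @export
validate_ground_truth_bn <- function(bn) {
  adj <- edges_to_adjacency(bn$edges, bn$nodes)
  cyc <- find_cycle(adj)
  if (!is.null(cyc)) {
    abort(paste0("graph contains a cycle: ", paste(cyc, collapse = " -> ")))
  }
  for (v in bn$nodes) {
    pa <- bn$edges$from[bn$edges$to == v]
    tab <- bn$cpt[[v]]
    if (is.null(tab)) abort(paste0("missing CPT for node ", v))
    tab <- as.matrix(tab)
    if (nrow(tab) != 3L^length(pa) || ncol(tab) != 3L) {
      abort(sprintf("CPT for %s must be %d x 3 (has %d parents)",
                    v, 3L^length(pa), length(pa)))
    }
    if (any(abs(rowSums(tab) - 1) > 1e-12)) {
      abort(paste0("CPT rows for ", v, " do not sum to 1"))
    }
    if (any(tab < 0)) abort(paste0("negative CPT entry for ", v))
    mu <- bn$emission_means[[v]]
    if (length(mu) != 3L || any(diff(mu) <= 0)) {
      abort(paste0("emission means for ", v, " must be 3 strictly increasing values"))
    }
  }
  invisible(bn)
}

#' @export
print.ground_truth_bn <- function(x, ...) {
  cat("Ground-truth Bayesian network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges; emission sd", x$emission_sd, "\n")
  invisible(x)
}

# adjacency matrix (rows = from, cols = to) from an edge tibble
edges_to_adjacency <- function(edges, nodes) {
  adj <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(edges)) adj[cbind(match(edges$from, nodes), match(edges$to, nodes))] <- 1L
  adj
}

# Returns NULL if acyclic, else a vector of node names along one cycle.
find_cycle <- function(adj) {
  n <- nrow(adj)
  state <- integer(n)  # 0 unseen, 1 on stack, 2 done
  parent <- integer(n)
  cycle <- NULL
  visit <- function(v) {
    state[v] <<- 1L
    for (w in which(adj[v, ] != 0L)) {
      if (!is.null(cycle)) return()
      if (state[w] == 1L) {
        path <- v
        while (path[1L] != w) path <- c(parent[path[1L]], path)
        cycle <<- rownames(adj)[c(path, w)]
        return()
      }
      if (state[w] == 0L) { parent[w] <<- v; visit(w) }
    }
    state[v] <<- 2L
  }
  for (v in seq_len(n)) if (state[v] == 0L && is.null(cycle)) visit(v)
  cycle
}

# topological order of node indices (assumes acyclic)
topological_order <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  order <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    v <- ready[1L]; ready <- ready[-1L]
    order <- c(order, v)
    for (w in which(adj[v, ] != 0L)) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- c(ready, w)
    }
  }
  order
}

#' Six-node STM-neighbourhood fixture network
#'
#' A star DAG with STM the parent of CUC1, AIL7, CHR40, TCP3 and TCP4.
#' CUC1, AIL7 and CHR40 copy the STM state with probability `strength`
#' (activation); TCP3 and TCP4 take the opposite state with probability
#' `strength` (repression), the remaining mass spread evenly.  The root
#' STM state is uniform over \{0,1,2\}.
#'
#' @param strength diagonal CPT mass, default 0.8 (strong enough for
#'   structure recovery around n = 1000 samples, weak enough to be
#'   non-degenerate).
#' @param emission_sd emission noise sd in log2 units (default 0.3).
#' @return a [ground_truth_bn()].
#' @export
#' @examples
#' bn <- stm_fixture_bn()
#' bn$edges
stm_fixture_bn <- function(strength = 0.8, emission_sd = 0.3) {
  nodes <- c("STM", "CUC1", "AIL7", "CHR40", "TCP3", "TCP4")
  off <- (1 - strength) / 2
  copy_cpt <- matrix(off, 3, 3); diag(copy_cpt) <- strength
  invert_cpt <- copy_cpt[, 3:1]
  cpt <- list(
    STM   = matrix(1 / 3, 1, 3),
    CUC1  = copy_cpt, AIL7 = copy_cpt, CHR40 = copy_cpt,
    TCP3  = invert_cpt, TCP4 = invert_cpt)
  ground_truth_bn(
    nodes = nodes,
    edges = tibble(from = "STM", to = c("CUC1", "AIL7", "CHR40", "TCP3", "TCP4")),
    cpt = cpt, emission_sd = emission_sd)
}

#' Sample a synthetic expression compendium from a ground-truth network
#'
#' Ancestral sampling: nodes are visited in topological order and each
#' sample's state is drawn from the node's CPT row selected by its
#' parents' states.  The continuous matrix adds Gaussian noise to the
#' per-state emission means.  The same seed reproduces both matrices
#' bit-exactly.
#'
#' @param bn a [ground_truth_bn()].
#' @param n_samples number of arrays to draw (>= 1).
#' @param seed integer seed; all randomness in the call flows through it.
#' @return list with `discrete` and `expression` tibbles (genes x samples).
#' @export
#' @examples
#' fix <- sample_compendium(stm_fixture_bn(), n_samples = 4, seed = 1)
#' fix$discrete
sample_compendium <- function(bn, n_samples, seed) {
  stopifnot(n_samples >= 1)
  validate_ground_truth_bn(bn)
  nodes <- bn$nodes
  adj <- edges_to_adjacency(bn$edges, nodes)
  ord <- topological_order(adj)
  states <- matrix(NA_integer_, nrow = length(nodes), ncol = n_samples,
                   dimnames = list(nodes, paste0("s", seq_len(n_samples))))
  withr::with_seed(seed, {
    for (v in ord) {
      pa <- which(adj[, v] != 0L)
      tab <- as.matrix(bn$cpt[[nodes[v]]])
      if (length(pa) == 0L) {
        row_idx <- rep(1L, n_samples)
      } else {
        # mixed-radix parent configuration, first parent varying fastest
        row_idx <- 1L + as.integer(states[pa, , drop = FALSE] |>
          (\(m) colSums(m * 3L^(seq_along(pa) - 1L)))())
      }
      u <- runif(n_samples)
      cum <- tab[row_idx, , drop = FALSE]
      cum <- cbind(cum[, 1L], cum[, 1L] + cum[, 2L])
      states[v, ] <- (u > cum[, 1L]) + (u > cum[, 2L])
    }
    mu <- do.call(rbind, bn$emission_means[nodes])
    noiseless <- mu[cbind(rep(seq_along(nodes), n_samples), as.vector(states) + 1L)]
    expr <- matrix(noiseless, nrow = length(nodes)) +
      matrix(rnorm(length(states), sd = bn$emission_sd), nrow = length(nodes))
  })
  dimnames(expr) <- dimnames(states)
  list(discrete = gene_matrix_tbl(states),
       expression = gene_matrix_tbl(expr))
}

#' Describe a synthetic induction timecourse design
#'
#' The design emulates a replicated induction/knockdown timecourse: per
#' contrast, a control and a treated arm with the stated number of
#' replicate arrays, Gaussian noise, and planted signed log2 effects for a
#' subset of genes.
#'
#' @param n_genes number of genes.
#' @param planted tibble with columns `gene` (index or id), `contrast`,
#'   `effect` (signed log2 effect).  Use [default_timecourse_design()] for
#'   the standard four-contrast benchmark design.
#' @param contrasts contrast labels.
#' @param replicates replicates per arm (>= 2).
#' @param noise_sd noise standard deviation, log2 units.
#' @param seed integer seed.
#' @return object of class `timecourse_design`.
#' @export
timecourse_design <- function(n_genes, planted, contrasts, replicates = 3L,
                              noise_sd = 0.25, seed = 1L) {
  if (replicates < 2L) abort("at least 2 replicates per arm are required")
  planted <- as_tibble(planted)
  if (nrow(planted)) {
    stopifnot(all(c("gene", "contrast", "effect") %in% names(planted)))
    if (any(!is.finite(planted$effect))) abort("planted effects must be finite")
    if (anyDuplicated(planted[, c("gene", "contrast")])) {
      abort("planted gene indices must be unique within a contrast")
    }
    if (!all(planted$contrast %in% contrasts)) abort("planted contrast not in design")
  }
  structure(list(n_genes = as.integer(n_genes), planted = planted,
                 contrasts = contrasts, replicates = as.integer(replicates),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "timecourse_design")
}

#' Standard benchmark timecourse design
#'
#' 1000 genes; 50 planted differentially expressed genes shared across
#' four contrasts (two induction time points, two knockdown time points)
#' with |log2 effect| = 2 and alternating sign; 3 replicates per arm and
#' noise sd 0.25 log2 units.
#'
#' @param n_genes,n_planted,effect,replicates,noise_sd,seed overrides of
#'   the benchmark values.
#' @return a [timecourse_design()].
#' @export
default_timecourse_design <- function(n_genes = 1000L, n_planted = 50L,
                                      effect = 2, replicates = 3L,
                                      noise_sd = 0.25, seed = 1L) {
  contrasts <- c("STMoe_8h", "STMoe_24h", "RNAi_72h", "RNAi_9d")
  idx <- seq_len(n_planted)
  planted <- tidyr::expand_grid(gene = idx, contrast = contrasts) |>
    dplyr::mutate(effect = effect * ifelse(.data$gene %% 2L == 0L, -1, 1))
  timecourse_design(n_genes, planted, contrasts, replicates, noise_sd, seed)
}

#' Generate a synthetic timecourse from a design
#'
#' Control arms have mean 0 for every gene; treated arms have mean equal
#' to the planted effect for planted genes and 0 otherwise, plus Gaussian
#' noise of the design's sd.  Gene ids are `g1 ... gN`.
#'
#' @param design a [timecourse_design()].
#' @return list with `arms` (per contrast: list of `control` and `treated`
#'   expression tibbles) and `truth` (tibble of planted `gene`, `contrast`,
#'   `effect`; empty when nothing is planted).
#' @export
#' @examples
#' tc <- make_timecourse(default_timecourse_design(n_genes = 20, n_planted = 2))
#' names(tc$arms)
make_timecourse <- function(design) {
  stopifnot(inherits(design, "timecourse_design"))
  genes <- paste0("g", seq_len(design$n_genes))
  truth <- design$planted
  if (nrow(truth)) {
    truth <- dplyr::mutate(truth, gene = ifelse(
      is.numeric(.data$gene), genes[as.integer(.data$gene)], as.character(.data$gene)))
  } else {
    truth <- tibble(gene = character(), contrast = character(), effect = numeric())
  }
  arm <- function(label, mean_vec) {
    m <- matrix(rnorm(design$n_genes * design$replicates, sd = design$noise_sd),
                nrow = design$n_genes) + mean_vec
    dimnames(m) <- list(genes, paste0(label, "_r", seq_len(design$replicates)))
    gene_matrix_tbl(m)
  }
  arms <- withr::with_seed(design$seed, {
    lapply(setNames(design$contrasts, design$contrasts), function(ctr) {
      mu <- numeric(design$n_genes)
      pl <- truth[truth$contrast == ctr, ]
      mu[match(pl$gene, genes)] <- pl$effect
      list(control = arm(paste0(ctr, "_ctl"), 0),
           treated = arm(paste0(ctr, "_trt"), mu))
    })
  })
  list(arms = arms, truth = truth)
}

#' Write a ground-truth network to a YAML config
#'
#' Nodes, edges, CPT rows and the emission model in a plain-text,
#' human-editable layout; [read_bn_yaml()] restores the object.
#'
#' @param bn a [ground_truth_bn()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bn_yaml <- function(bn, path) {
  obj <- list(
    nodes = as.list(bn$nodes),
    edges = unname(apply(bn$edges, 1L, function(r) list(from = r[["from"]], to = r[["to"]]))),
    cpt = lapply(bn$cpt, function(tab) apply(as.matrix(tab), 1L, as.list, simplify = FALSE)),
    emission_means = lapply(bn$emission_means, as.list),
    emission_sd = bn$emission_sd)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read a ground-truth network from YAML
#' @param path file written by [write_bn_yaml()].
#' @return a [ground_truth_bn()].
#' @export
read_bn_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  edges <- if (length(obj$edges)) {
    dplyr::bind_rows(lapply(obj$edges, as_tibble))
  } else {
    tibble(from = character(), to = character())
  }
  cpt <- lapply(obj$cpt, function(rows) {
    do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  })
  ground_truth_bn(unlist(obj$nodes), edges, cpt,
                  emission_means = lapply(obj$emission_means, function(m) as.numeric(unlist(m))),
                  emission_sd = obj$emission_sd)
}
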