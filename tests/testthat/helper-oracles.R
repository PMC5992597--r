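# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the BDeu oracle uses sequential predictive
# probabilities instead of the lgamma closed form, the UPGMA oracle
# recomputes cluster distances from the raw pairwise matrix at every step,
# and the chi-squared tail uses the even-df closed-form series.

# Dirichlet-multinomial log marginal likelihood of one family by the chain
# rule: P(x_1..x_n) = prod_t P(x_t | x_1..x_{t-1}) with posterior-predictive
# updates of the Dirichlet counts.
oracle_family_loglik <- function(child_states, parent_config, q, ess) {
  a_jk <- ess / (q * 3)
  counts <- matrix(0, nrow = 3, ncol = q)
  ll <- 0
  for (t in seq_along(child_states)) {
    j <- parent_config[t]
    k <- child_states[t] + 1L
    ll <- ll + log((a_jk + counts[k, j]) / (3 * a_jk + sum(counts[, j])))
    counts[k, j] <- counts[k, j] + 1
  }
  ll
}

# Full-DAG BDeu log score from the sequential oracle.
oracle_bde <- function(adj, states, ess = 1) {
  # states: nodes x samples matrix of 0/1/2
  n <- nrow(adj)
  total <- 0
  for (v in seq_len(n)) {
    pa <- which(adj[, v] != 0L)
    cfg <- if (length(pa) == 0L) {
      rep(1L, ncol(states))
    } else {
      1L + as.integer(3L^(seq_along(pa) - 1L) %*% states[pa, , drop = FALSE])
    }
    q <- 3L^length(pa)
    total <- total + oracle_family_loglik(states[v, ], cfg, q, ess)
  }
  total
}

# chi-squared upper tail for even df = 2k: exp(-x/2) * sum_{j<k} (x/2)^j/j!
oracle_chisq_tail_even <- function(x, df) {
  k <- df / 2
  exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}

# Benjamini-Hochberg step-up by direct definition.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[ord[i]] * n / i)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# Welch two-sample t-test p-value from the textbook formulas.
oracle_welch_p <- function(x, y) {
  vx <- var(x); vy <- var(y)
  se2 <- vx / length(x) + vy / length(y)
  tt <- (mean(y) - mean(x)) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                   (vy / length(y))^2 / (length(y) - 1))
  2 * pt(abs(tt), df, lower.tail = FALSE)
}

# Brute-force UPGMA: at every step recompute every cluster-pair average
# distance from the raw matrix, merge the closest pair (lexicographic
# smallest cluster-id pair on ties).
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  ids <- seq_len(n)
  next_id <- n + 1L
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        key <- c(h, sort(c(ids[i], ids[j])))
        if (is.null(best) || h < best$h - 1e-12 ||
            (abs(h - best$h) <= 1e-12 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(h = h, i = i, j = j, key = key)
        }
      }
    }
    heights <- c(heights, best$h)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    ids[best$i] <- next_id
    next_id <- next_id + 1L
    clusters[[best$j]] <- NULL
    ids <- ids[-best$j]
  }
  heights
}

# Independent re-coding of the circuit right-hand side, written
# scalar-by-scalar from the model definition (no shared code with the
# package implementation).
oracle_rhs <- function(state, p, prif) {
  N <- length(prif)
  hp <- function(x, K) x^p$hill_n / (K^p$hill_n + x^p$hill_n)
  hm <- function(x, K) K^p$hill_n / (K^p$hill_n + x^p$hill_n)
  out <- numeric(7 * N)
  get <- function(sp, i) state[(i - 1) * 7 + sp]
  for (i in seq_len(N)) {
    mS <- get(1, i); S <- get(2, i); mC1 <- get(3, i); C1 <- get(4, i)
    Tc <- get(5, i); rC <- get(6, i); rAB <- get(7, i)
    Sl <- if (i > 1) get(2, i - 1) else S
    Sr <- if (i < N) get(2, i + 1) else S
    prom <- (p$a0 + p$a_C * hp(C1, p$K_SC1) +
               (if (p$autoregulation) p$a_S * hp(S, p$K_SS) else 0)) /
      (p$a0 + p$a_C + p$a_S)
    out[(i - 1) * 7 + 1] <- p$beta_mS * prom * hm(Tc, p$K_ST) - p$delta_mS * mS
    out[(i - 1) * 7 + 2] <- p$tau_S * mS - p$delta_S * S +
      (if (p$diffusion) p$D * (Sl + Sr - 2 * S) else 0)
    out[(i - 1) * 7 + 3] <- p$beta_mC1 * hp(S, p$K_C1S) - p$delta_mC1 * mC1 -
      p$kappa * mC1 * (rC + rAB)
    out[(i - 1) * 7 + 4] <- p$tau_C1 * mC1 - p$delta_C1 * C1
    out[(i - 1) * 7 + 5] <- p$beta_T * hp(prif[i], p$K_TP) * hm(S, p$K_TS) -
      p$delta_T * Tc
    out[(i - 1) * 7 + 6] <- p$beta_rC * hp(S, p$K_rCS) - p$delta_rC * rC
    out[(i - 1) * 7 + 7] <- p$beta_rAB * hp(Tc, p$K_rABT) - p$delta_rAB * rAB
  }
  out
}

# small helper: expression tibble from a plain matrix
expr_tbl <- function(m, genes = paste0("g", seq_len(nrow(m)))) {
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m))
}

# species order used by the model state vectors
SPECIES <- c("mS", "S", "mC1", "C1", "T", "rC", "rAB")

# minimal hand-built ensemble for consensus tests
fake_ensemble <- function(adjs, nodes) {
  structure(list(
    networks = lapply(adjs, function(a) {
      dimnames(a) <- list(nodes, nodes)
      idx <- which(a != 0L, arr.ind = TRUE)
      list(edges = tibble::tibble(from = nodes[idx[, 1]], to = nodes[idx[, 2]]),
           adjacency = a, score = 0)
    }),
    nodes = nodes), class = "network_ensemble")
}

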