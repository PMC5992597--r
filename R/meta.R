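# Differential-expression selection and Fisher inverse chi-squared
# meta-analysis with BH and Storey q-value FDR control.

#' Per-gene two-group differential-expression test
#'
#' A plain two-sided Welch t-test per gene between a control and a treated
#' arm, returning the p-value and the log2 fold-change (treated mean minus
#' control mean).  This is deliberately generic plumbing: the meta-analysis
#' consumes p-values from any upstream test.
#'
#' @param control,treated expression tibbles (first column `gene`) with at
#'   least two replicate columns each and identical gene sets.
#' @param contrast label stored in the output's `contrast` column.
#' @return p-value tibble: `gene`, `contrast`, `p`, `lfc`.
#' @export
#' @examples
#' ctl <- tibble::tibble(gene = "g1", r1 = 1.0, r2 = 1.2, r3 = 0.8)
#' trt <- tibble::tibble(gene = "g1", r1 = 3.0, r2 = 3.3, r3 = 2.7)
#' de_test(ctl, trt)
de_test <- function(control, treated, contrast = "contrast1") {
  x <- as_gene_matrix(control); y <- as_gene_matrix(treated)
  if (!identical(sort(rownames(x)), sort(rownames(y)))) {
    diffs <- c(setdiff(rownames(x), rownames(y)), setdiff(rownames(y), rownames(x)))
    abort(paste0("gene sets differ between arms: ",
                 paste(head(diffs, 10L), collapse = ", ")))
  }
  y <- y[rownames(x), , drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  if (nx < 2L || ny < 2L) abort("each arm needs at least 2 replicates")
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1L, stats::var); vy <- apply(y, 1L, stats::var)
  se2 <- vx / nx + vy / ny
  tstat <- (my - mx) / sqrt(se2)
  # Welch-Satterthwaite degrees of freedom
  df <- se2^2 / ((vx / nx)^2 / (nx - 1L) + (vy / ny)^2 / (ny - 1L))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[!is.finite(p)] <- 1  # zero-variance, zero-difference genes
  tibble(gene = rownames(x), contrast = contrast,
         p = unname(pmin(pmax(p, .Machine$double.xmin), 1)),
         lfc = unname(my - mx))
}

#' Select differentially expressed genes
#'
#' A gene is kept for a contrast iff `p < p_cut` and, when `use_fold` is
#' set, `|lfc| >= log2(fold_cut)`.  The defaults encode the conventional
#' p < 0.01 cut with a minimum two-fold change filter.  Output is ordered
#' by ascending p within contrast (deterministic).
#'
#' @param table p-value tibble (`gene`, `contrast`, `p`, optional `lfc`).
#' @param p_cut p-value cut-off (strict `<`), default 0.01.
#' @param fold_cut minimum fold change on the linear scale, default 2.
#' @param use_fold apply the fold filter (requires an `lfc` column).
#' @return tibble of kept rows, sorted by `contrast` then ascending `p`.
#' @export
select_degs <- function(table, p_cut = 0.01, fold_cut = 2, use_fold = TRUE) {
  validate_pvalue_table(table)
  if (use_fold && !"lfc" %in% names(table)) {
    abort("use_fold = TRUE requires an `lfc` column")
  }
  kept <- dplyr::filter(table, .data$p < p_cut)
  if (use_fold) kept <- dplyr::filter(kept, abs(.data$lfc) >= log2(fold_cut))
  dplyr::arrange(kept, .data$contrast, .data$p)
}

#' Combine p-values by Fisher's inverse chi-squared method
#'
#' For k independent p-values, `X2 = -2 * sum(log(p))` follows a
#' chi-squared distribution with 2k degrees of freedom under the joint
#' null; the omnibus p is the upper-tail probability.  Direction of effect
#' is deliberately ignored.  Zero p-values are an error: the statistic
#' would be infinite, and silently clamping would hide an upstream data
#' problem (clamp explicitly at the caller if that is intended).
#'
#' @param p numeric vector of p-values in (0, 1], one per contrast.
#' @return list with `statistic` (X2), `df` (2k) and `p` (omnibus).
#' @export
#' @examples
#' fisher_combine(c(0.05, 0.05))
fisher_combine <- function(p) {
  if (length(p) < 1L) abort("need at least one p-value")
  if (any(!is.finite(p)) || any(p > 1)) abort("p-values must lie in (0, 1]")
  if (any(p <= 0)) {
    abort("p-value of 0 cannot be combined; clamp at the smallest positive value explicitly if intended")
  }
  x2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(statistic = x2, df = df, p = pchisq(x2, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, name-stable wrapper over `stats::p.adjust(method = "BH")`:
#' step-up adjusted values capped at 1, preserving the input order.
#'
#' @param p p-values in (0, 1].
#' @return adjusted vector of the same length (empty in, empty out).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Storey q-values with smoother-based pi0 estimation
#'
#' The null proportion pi0 is estimated on the grid
#' lambda = 0.05, 0.10, ..., 0.95 as `mean(p > lambda) / (1 - lambda)`,
#' smoothed with a cubic smoothing spline (3 df) and evaluated at the
#' largest lambda, then clamped to (0, 1].  With fewer than 20 p-values
#' the smoother is unreliable and pi0 is fixed at 1 (q-values then equal
#' BH-adjusted p-values).  q_i = pi0 * BH_i with cumulative-minimum
#' enforcement, so q is monotone non-decreasing in p.
#'
#' @param p p-values in (0, 1].
#' @return list with `q` (same order as input) and `pi0`.
#' @export
storey_qvalue <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  n <- length(p)
  if (n >= 20L) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- predict(fit, x = max(lambda))$y
  } else {
    pi0 <- 1
  }
  pi0 <- min(max(pi0, .Machine$double.eps), 1)
  ord <- order(p, decreasing = TRUE)
  q_sorted <- cummin(pi0 * bh_adjust(p)[ord])
  q <- numeric(n)
  q[ord] <- q_sorted
  list(q = pmin(q, 1), pi0 = pi0)
}

#' Gene-level meta-analysis across contrasts
#'
#' Combines each gene's per-contrast p-values with [fisher_combine()] and
#' controls the FDR on the omnibus p-values with both BH adjustment and
#' Storey q-values.  Every gene must carry a p-value for every contrast
#' used in the combination.
#'
#' @param table long p-value tibble (`gene`, `contrast`, `p`).
#' @param contrasts contrasts to combine; defaults to all present.
#' @return a `meta_result` tibble: `gene`, `statistic`, `df`, `p_omnibus`,
#'   `p_bh`, `q`, sorted by ascending omnibus p, with the pi0 estimate as
#'   attribute `pi0`.
#' @export
#' @examples
#' tbl <- tidyr::expand_grid(gene = c("g1", "g2"), contrast = c("a", "b"))
#' tbl$p <- c(0.001, 0.002, 0.5, 0.6)
#' meta_analyse(tbl)
meta_analyse <- function(table, contrasts = unique(table$contrast)) {
  validate_pvalue_table(table)
  tbl <- dplyr::filter(table, .data$contrast %in% contrasts)
  wide <- tidyr::pivot_wider(tbl[, c("gene", "contrast", "p")],
                             names_from = "contrast", values_from = "p")
  pm <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(pm)) {
    missing <- wide$gene[!complete.cases(pm)]
    abort(paste0("genes missing a p-value for some contrast: ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  x2 <- -2 * rowSums(log(pm))
  df <- 2L * ncol(pm)
  omnibus <- pchisq(x2, df, lower.tail = FALSE)
  omnibus <- pmax(omnibus, .Machine$double.xmin)
  st <- storey_qvalue(omnibus)
  out <- tibble(gene = wide$gene, statistic = x2, df = df,
                p_omnibus = omnibus, p_bh = bh_adjust(omnibus), q = st$q) |>
    dplyr::arrange(.data$p_omnibus)
  attr(out, "pi0") <- st$pi0
  class(out) <- c("meta_result", class(out))
  out
}

#' @export
glance.meta_result <- function(x, ...) {
  tibble(n_genes = nrow(x), df = x$df[1L], pi0 = attr(x, "pi0"),
         n_q_lt_0.01 = sum(x$q < 0.01), n_q_lt_0.05 = sum(x$q < 0.05))
}

#' Relative quantification by the ddCT method
#'
#' `ddCT = (Ct_target_treated - Ct_ref_treated) -
#' (Ct_target_control - Ct_ref_control)`; fold change = `2^(-ddCT)`.
#' Also applicable to ChIP fold-enrichment against an unbound reference
#' amplicon (treated = IP, control = mock IP).
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   threshold-cycle numbers (finite, vectorised).
#' @return fold change(s).
#' @export
#' @examples
#' ddct_fold(25, 20, 26, 20)  # 2.0
ddct_fold <- function(ct_target_treated, ct_ref_treated,
                      ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts))) abort("Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
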