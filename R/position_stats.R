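# Positional comparison suite: rank-based omnibus test with mean ranks,
# Dunn's post hoc with Bonferroni adjustment, and contingency-table
# analysis with adjusted standardized residuals.

as_group_list <- function(groups) {
  if (!is.list(groups)) stop("`groups` must be a list of numeric vectors",
                             call. = FALSE)
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0)) {
    stop("every group must be non-empty", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  lapply(groups, as.numeric)
}

#' Kruskal-Wallis rank test with group mean ranks
#'
#' Nonparametric omnibus test for a location difference across k groups,
#' with the tie-corrected H statistic referred to a chi-square
#' distribution on k - 1 degrees of freedom. Group mean ranks are
#' reported alongside, matching the conventional presentation. The
#' degenerate all-values-identical case is returned as H = 0, p = 1.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return Object of class `kw_test`: list with `H`, `df`, `p`,
#'   `mean_ranks` (named) and `n`.
#' @export
#' @examples
#' kw_rank_test(list(a = 1:3, b = 4:6)) # H = 27/7
kw_rank_test <- function(groups) {
  groups <- as_group_list(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  mean_ranks <- c(tapply(rank(x), g, mean))
  if (length(unique(x)) == 1L) {
    out <- list(H = 0, df = length(groups) - 1L, p = 1,
                mean_ranks = mean_ranks, n = length(x))
  } else {
    kt <- stats::kruskal.test(x, g)
    out <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p = kt$p.value, mean_ranks = mean_ranks, n = length(x))
  }
  structure(out, class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat("Kruskal-Wallis rank test: H(", x$df, ") = ",
      format(x$H, digits = 6), ", p = ", format_p(x$p), ", n = ", x$n, "\n",
      sep = "")
  cat("mean ranks:\n")
  print(round(x$mean_ranks, 2))
  invisible(x)
}

format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

#' Dunn's post hoc pairwise comparisons
#'
#' Rank-based pairwise z tests following a Kruskal-Wallis omnibus:
#' for each of the k(k-1)/2 pairs, the difference in mean ranks divided
#' by its tie-corrected standard error
#' `sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j))`.
#' Two-sided p-values are Bonferroni-adjusted over all pairs.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Significance level for the flags (default 0.05).
#' @return Tibble with one row per pair: `pair`, `z`, `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
dunn_posthoc <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  N <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  tie_sizes <- base::table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_base * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- if (se > 0) (mean_ranks[[i]] - mean_ranks[[j]]) / se else 0
    tibble::tibble(pair = paste(i, j, sep = "-"), z = z)
  })
  out <- dplyr::bind_rows(rows)
  out$p_raw <- 2 * stats::pnorm(-abs(out$z))
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out$significant <- out$p_adjusted < alpha
  out
}

#' Contingency-table analysis with adjusted standardized residuals
#'
#' Pearson chi-square test of independence on an r x c count table,
#' with the per-cell adjusted standardized residual
#' `z = (O - E) / sqrt(E (1 - row_total/N) (1 - col_total/N))`
#' and two-sided cell significance under a Bonferroni correction over
#' all r x c cells. Rows or columns with a zero marginal are dropped
#' with a warning; a table degenerate to one row or column has zero
#' residuals by construction.
#'
#' @param tab Matrix (or table) of non-negative counts.
#' @param alpha Significance level for cell flags (default 0.05).
#' @return Object of class `contingency_test`: list with `chi2`, `df`,
#'   `p`, `expected`, `residuals` (adjusted standardized), `p_cells`,
#'   `significant` (logical matrix), `alpha`.
#' @export
#' @examples
#' contingency_residuals(matrix(c(20, 10, 10, 20), 2))
contingency_residuals <- function(tab, alpha = 0.05) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(tab) == 0) stop("table total must be positive", call. = FALSE)
  zero_r <- rowSums(tab) == 0
  zero_c <- colSums(tab) == 0
  if (any(zero_r) || any(zero_c)) {
    warning("dropping ", sum(zero_r), " zero-marginal row(s) and ",
            sum(zero_c), " zero-marginal column(s)", call. = FALSE)
    tab <- tab[!zero_r, !zero_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    # with a single row or column the expected counts equal the observed
    z <- tab * 0
    return(structure(list(chi2 = 0, df = 0L, p = 1, expected = tab,
                          residuals = z, p_cells = z + 1,
                          significant = z > 0, alpha = alpha),
                     class = "contingency_test"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  z <- ct$stdres
  p_cells <- 2 * stats::pnorm(-abs(z))
  m <- length(tab)
  structure(list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, expected = ct$expected, residuals = z,
                 p_cells = p_cells,
                 significant = pmin(1, p_cells * m) < alpha, alpha = alpha),
            class = "contingency_test")
}

#' @export
print.contingency_test <- function(x, ...) {
  cat("Contingency analysis: chi2(", x$df, ") = ", format(x$chi2, digits = 6),
      ", p = ", format_p(x$p), "\n", sep = "")
  cat("adjusted standardized residuals:\n")
  print(round(x$residuals, 2))
  invisible(x)
}
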