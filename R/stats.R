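#' Spearman rank correlation with exact small-sample p-values
#'
#' Computes Spearman's rho as the Pearson correlation of midranks (average
#' ranks on ties), written out at the formula level, with a two-sided
#' p-value from the t approximation for n >= 10 and from exact enumeration
#' of all n! rank permutations for n < 10.
#'
#' @param x,y Numeric vectors of equal length n >= 3, finite.
#' @return A list of class `picocycle_spearman` with `rho`, `p_value`, `n`
#'   and `method` ("t approximation" or "exact permutation").
#' @export
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) abort("Spearman correlation needs n >= 3.")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("Inputs must be finite.")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    abort("Spearman rho is undefined for a constant vector.",
          class = "picocycle_constant_input")
  }
  rho <- rank_pearson(rx, ry)
  if (n >= 10) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  } else {
    perms <- permutations_of(n)
    # rho for every permutation of y's ranks against x's ranks
    rhos <- apply(perms, 1, function(idx) rank_pearson(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  }
  structure(
    list(rho = unname(rho), p_value = max(p, .Machine$double.xmin),
         n = n, method = method),
    class = "picocycle_spearman"
  )
}

rank_pearson <- function(rx, ry) {
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# all permutations of 1..n as an (n!) x n integer matrix
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    idx <- seq(row, row + nrow(sub) - 1)
    out[idx, 1] <- k
    out[idx, -1] <- matrix(rest[sub], nrow(sub), n - 1)
    row <- row + nrow(sub)
  }
  out
}

tie_correction_sum <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank-sum test with tie correction
#'
#' Formula-level H statistic with the standard tie correction
#' H' = H / (1 - sum(t^3 - t) / (N^3 - N)) and a chi-square reference
#' distribution on k - 1 degrees of freedom. When every value is identical
#' the statistic is 0 with p = 1 by convention.
#'
#' @param values Numeric measurements.
#' @param groups Group labels of the same length; >= 2 groups, each
#'   nonempty.
#' @return A list of class `picocycle_kw` with `statistic`, `p_value`, `df`,
#'   `n`.
#' @export
kruskal_wallis_test <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) abort("Need at least 2 groups.")
  if (any(table(groups) == 0)) abort("Every group needs at least one value.")
  N <- length(values)
  if (N < 3) abort("Need total n >= 3.")
  r <- rank(values)
  k <- nlevels(groups)
  mean_ranks <- tapply(r, groups, mean)
  n_i <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(n_i * (mean_ranks - (N + 1) / 2)^2)
  C <- 1 - tie_correction_sum(r) / (N^3 - N)
  if (C <= 0) {
    # all values identical
    return(structure(
      list(statistic = 0, p_value = 1, df = k - 1, n = N),
      class = "picocycle_kw"
    ))
  }
  H <- H / C
  structure(
    list(
      statistic = unname(H),
      p_value = pchisq(H, df = k - 1, lower.tail = FALSE),
      df = k - 1, n = N
    ),
    class = "picocycle_kw"
  )
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics on the joint midranks,
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) *
#' (1/n_i + 1/n_j)), with two-sided normal p-values and a multiplicity
#' adjustment (Holm by default). The sign of z follows the order of the
#' group factor levels (first minus second).
#'
#' @inheritParams kruskal_wallis_test
#' @param adjust One of "holm", "bonferroni", "none".
#' @return A tibble of class `picocycle_dunn` with `group1`, `group2`, `z`,
#'   `p_raw`, `p_adjusted`.
#' @export
dunn_test <- function(values, groups, adjust = c("holm", "bonferroni",
                                                 "none")) {
  adjust <- match.arg(adjust)
  stopifnot(length(values) == length(groups))
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) abort("Need at least 2 groups.")
  N <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  n_i <- tabulate(groups)
  names(n_i) <- levels(groups)
  var_term <- N * (N + 1) / 12 - tie_correction_sum(r) / (12 * (N - 1))
  pairs <- combn(levels(groups), 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt(var_term * (1 / n_i[p[1]] + 1 / n_i[p[2]]))
    if (se == 0) return(0)
    (mean_ranks[p[1]] - mean_ranks[p[2]]) / se
  })
  p_raw <- 2 * pnorm(-abs(z))
  out <- tibble(
    group1 = pairs[1, ],
    group2 = pairs[2, ],
    z = unname(z),
    p_raw = unname(p_raw),
    p_adjusted = unname(p.adjust(p_raw, method = adjust))
  )
  class(out) <- c("picocycle_dunn", class(out))
  out
}

#' Hellinger transformation of a count matrix
#'
#' Square root of per-sample (row) relative abundances. Euclidean distance
#' between transformed rows equals the Hellinger distance between the
#' composition vectors, which is the standard preparation for ANOSIM and
#' ordination on abundance data.
#'
#' @param x Nonnegative matrix or data frame, samples in rows; every row
#'   sum must be positive.
#' @return A numeric matrix of the same shape.
#' @export
#' @examples
#' hellinger_transform(rbind(c(1, 1), c(4, 0)))
hellinger_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) abort("Counts must be nonnegative.")
  rs <- rowSums(x)
  if (any(rs == 0)) {
    abort("Every sample (row) must have a positive total.",
          class = "picocycle_zero_rowsum")
  }
  sqrt(sweep(x, 1, rs, "/"))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test comparing between-group and within-group
#' pairwise distances: R = (rbar_B - rbar_W) / (M / 2), with M = n(n-1)/2
#' distances ranked with midranks, so R lies in [-1, 1] and is invariant
#' under any strictly increasing transform of the distances. The p-value is
#' (1 + #(permuted R >= observed)) / (1 + n_perm) over seeded random label
#' permutations.
#'
#' @param d A symmetric distance matrix, a `dist` object, or a data/count
#'   matrix (samples in rows) from which Euclidean distances are taken.
#' @param labels Group labels, one per sample; >= 2 groups of >= 2 members.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Integer seed for the permutations (default 1).
#' @return A list of class `picocycle_anosim` with `statistic` (R),
#'   `p_value`, `n`, `n_perm`, `perm_stats`.
#' @export
anosim_test <- function(d, labels, n_perm = 9999, seed = 1) {
  if (inherits(d, "dist")) {
    dm <- as.matrix(d)
  } else {
    dm <- as.matrix(d)
    if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-12)) {
      dm <- as.matrix(stats::dist(dm))
    }
  }
  n <- nrow(dm)
  labels <- as.character(labels)
  stopifnot(length(labels) == n, n_perm >= 1)
  sizes <- table(labels)
  if (length(sizes) < 2) abort("ANOSIM needs at least 2 groups.")
  if (any(sizes < 2)) {
    abort("Every group needs at least 2 members.",
          class = "picocycle_anosim_group_size")
  }
  lt <- lower.tri(dm)
  i_idx <- row(dm)[lt]
  j_idx <- col(dm)[lt]
  r <- rank(dm[lt])
  M <- length(r)

  stat_for <- function(lab) {
    within <- lab[i_idx] == lab[j_idx]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  observed <- stat_for(labels)

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, globalenv()),
      add = TRUE
    )
    set.seed(seed)
    code
  }
  perm_stats <- withr_seed({
    # one n x n_perm matrix of permuted labels, evaluated column-wise
    lab_mat <- replicate(n_perm, sample(labels))
    wmat <- lab_mat[i_idx, , drop = FALSE] == lab_mat[j_idx, , drop = FALSE]
    n_within <- colSums(wmat)
    sum_within <- colSums(r * wmat)
    rW <- sum_within / n_within
    rB <- (sum(r) - sum_within) / (M - n_within)
    (rB - rW) / (M / 2)
  })
  p <- (1 + sum(perm_stats >= observed - 1e-12)) / (1 + n_perm)
  structure(
    list(statistic = unname(observed), p_value = p, n = n,
         n_perm = n_perm, perm_stats = perm_stats),
    class = "picocycle_anosim"
  )
}

# ---- broom-style methods ----------------------------------------------------

#' @export
tidy.picocycle_spearman <- function(x, ...) {
  tibble(estimate = x$rho, p.value = x$p_value, n = x$n, method = x$method)
}

#' @export
glance.picocycle_spearman <- function(x, ...) tidy(x)

#' @export
tidy.picocycle_kw <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, df = x$df, n = x$n)
}

#' @export
glance.picocycle_kw <- function(x, ...) tidy(x)

#' @export
tidy.picocycle_dunn <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
tidy.picocycle_anosim <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, n = x$n,
         n_perm = x$n_perm)
}

#' @export
glance.picocycle_anosim <- function(x, ...) tidy(x)

#' @export
print.picocycle_spearman <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (n = %d, p = %.4g, %s)\n",
              x$rho, x$n, x$p_value, x$method))
  invisible(x)
}

#' @export
print.picocycle_kw <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4f (df = %d, n = %d, p = %.4g)\n",
              x$statistic, x$df, x$n, x$p_value))
  invisible(x)
}

#' @export
print.picocycle_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4f (n = %d, %d permutations, p = %.4g)\n",
              x$statistic, x$n, x$n_perm, x$p_value))
  invisible(x)
}
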