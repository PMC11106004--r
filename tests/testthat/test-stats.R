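test_that("spearman matches the rank-then-Pearson oracle, ties included", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1))$rho, -1)
  set.seed(5)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    x <- sample(1:6, n, replace = TRUE)   # heavy ties
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    oracle <- cor(rank(x), rank(y))
    expect_equal(spearman_rho(x, y)$rho, oracle, tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5),
               class = "picocycle_constant_input")
})

test_that("spearman p-values match cor.test in both regimes", {
  # exact enumeration below n = 10
  a <- spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  b <- cor.test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5), method = "spearman")
  expect_equal(a$p_value, b$p.value, tolerance = 1e-12)
  expect_equal(a$method, "exact permutation")
  # t approximation at n >= 10
  set.seed(6)
  x <- rnorm(15); y <- x + rnorm(15)
  a2 <- spearman_rho(x, y)
  b2 <- cor.test(x, y, method = "spearman")
  expect_equal(a2$rho, unname(b2$estimate), tolerance = 1e-12)
})

test_that("Kruskal-Wallis matches base R with ties and handles degeneracy", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    g <- rep(letters[1:k], times = sample(3:8, k, replace = TRUE))
    v <- sample(1:10, length(g), replace = TRUE)
    a <- kruskal_wallis_test(v, g)
    b <- kruskal.test(v, factor(g))
    expect_equal(a$statistic, unname(b$statistic), tolerance = 1e-10)
    expect_equal(a$p_value, b$p.value, tolerance = 1e-10)
  }
  # two identical groups: H = 0
  expect_equal(kruskal_wallis_test(c(1, 2, 3, 1, 2, 3),
                                   rep(c("a", "b"), each = 3))$statistic,
               0, tolerance = 1e-12)
  # all values equal: H = 0, p = 1 by convention
  deg <- kruskal_wallis_test(rep(5, 6), rep(c("a", "b"), 3))
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)
  expect_error(kruskal_wallis_test(1:3, c("a", "a", "a")))
})

test_that("Kruskal-Wallis H equals the exhaustive rank-statistic oracle", {
  # groups {1,2} and {3,4}: enumerate all 6 assignments of ranks
  v <- c(1, 2, 3, 4)
  H_obs <- kruskal_wallis_test(v, c("a", "a", "b", "b"))$statistic
  ranks <- rank(v)
  combos <- combn(4, 2)
  H_all <- apply(combos, 2, function(idx) {
    N <- 4
    Ra <- mean(ranks[idx]); Rb <- mean(ranks[-idx])
    12 / (N * (N + 1)) * (2 * (Ra - 2.5)^2 + 2 * (Rb - 2.5)^2)
  })
  # the observed assignment is columns {1,2} vs {3,4}
  expect_equal(H_obs, H_all[combos[1, ] == 1 & combos[2, ] == 2][1],
               tolerance = 1e-12)
  # and the observed H is the maximum over assignments (complete separation)
  expect_equal(H_obs, max(H_all), tolerance = 1e-12)
})

test_that("Dunn z matches the direct formula on an untied 3-group toy", {
  res <- dunn_test(1:9, rep(c("A", "B", "C"), each = 3), adjust = "none")
  # mean ranks 2, 5, 8; sigma2 = N(N+1)/12 = 7.5; se = sqrt(7.5 * 2/3)
  expect_equal(res$z, c(-3, -6, -3) / sqrt(7.5 * 2 / 3), tolerance = 1e-12)
  expect_equal(res$p_raw, res$p_adjusted)
  # equal mean ranks give z = 0
  res0 <- dunn_test(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(res0$z, 0)
  # Holm adjustment never decreases a p-value
  resh <- dunn_test(1:9, rep(c("A", "B", "C"), each = 3), adjust = "holm")
  expect_true(all(resh$p_adjusted >= resh$p_raw - 1e-15))
})

test_that("Hellinger transform is sqrt of row proportions", {
  h <- hellinger_transform(rbind(c(1, 1), c(4, 0)))
  expect_equal(h, rbind(sqrt(c(0.5, 0.5)), c(1, 0)))
  # Euclidean distance between rows equals the definitional Hellinger
  # distance between composition vectors
  set.seed(8)
  x <- matrix(rpois(30, 5) + 1, nrow = 3)
  h2 <- hellinger_transform(x)
  p <- x / rowSums(x)
  d_def <- sqrt(sum((sqrt(p[1, ]) - sqrt(p[2, ]))^2))
  expect_equal(unname(as.matrix(dist(h2))[1, 2]), d_def, tolerance = 1e-12)
  expect_error(hellinger_transform(rbind(c(0, 0), c(1, 2))),
               class = "picocycle_zero_rowsum")
})

test_that("ANOSIM statistic behaves and matches vegan", {
  skip_if_not_installed("vegan")
  # all pairwise distances equal: R = 0
  d0 <- matrix(1, 6, 6); diag(d0) <- 0
  expect_equal(anosim_test(d0, rep(c("a", "b"), each = 3),
                           n_perm = 99)$statistic, 0)
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(rnorm(48), 12)
    lab <- rep(c("a", "b"), each = 6)
    a <- anosim_test(dist(m), lab, n_perm = 99, seed = i)
    b <- vegan::anosim(dist(m), lab, permutations = 9)
    expect_equal(a$statistic, unname(b$statistic), tolerance = 1e-12)
    expect_true(a$statistic >= -1 && a$statistic <= 1)
  }
  expect_error(anosim_test(dist(matrix(rnorm(12), 4)), c("a", "a", "a", "b"),
                           n_perm = 9),
               class = "picocycle_anosim_group_size")
})

test_that("ANOSIM permutation p agrees with exhaustive enumeration at n = 6", {
  set.seed(10)
  m <- matrix(rnorm(18), 6)
  dm <- as.matrix(dist(m))
  lab <- rep(c("a", "b"), each = 3)
  # exhaustive: all 10 distinct two-group labelings of 6 samples
  lt <- lower.tri(dm); r <- rank(dm[lt]); M <- sum(lt)
  ii <- row(dm)[lt]; jj <- col(dm)[lt]
  combos <- combn(6, 3)
  stats <- apply(combos, 2, function(idx) {
    l <- ifelse(seq_len(6) %in% idx, "a", "b")
    w <- l[ii] == l[jj]
    (mean(r[!w]) - mean(r[w])) / (M / 2)
  })
  obs <- anosim_test(dm, lab, n_perm = 9999, seed = 2)
  p_exact <- mean(stats >= obs$statistic - 1e-12)
  expect_lt(abs(obs$p_value - p_exact), 0.03)  # Monte-Carlo error margin
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(12)
  x <- rlnorm(20); y <- x * exp(rnorm(20, 0, 0.4))
  f <- function(v) log(v + 1)
  expect_equal(spearman_rho(x, y)$rho, spearman_rho(f(x), f(y))$rho,
               tolerance = 1e-12)
  g <- rep(c("a", "b"), each = 10)
  expect_equal(kruskal_wallis_test(x, g)$statistic,
               kruskal_wallis_test(f(x), g)$statistic, tolerance = 1e-12)
  expect_equal(dunn_test(x, g)$z, dunn_test(f(x), g)$z, tolerance = 1e-12)
  m <- matrix(rlnorm(60), 12)
  d <- as.matrix(dist(m))
  lab <- rep(c("a", "b"), each = 6)
  expect_equal(anosim_test(d, lab, n_perm = 49, seed = 1)$statistic,
               anosim_test(sqrt(d), lab, n_perm = 49, seed = 1)$statistic,
               tolerance = 1e-12)
})
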