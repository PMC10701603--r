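test_that("gene z-scores follow the (x - mean)/sd definition with n-1 sd", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  expect_equal(unname(zscore_by_gene(m)["g1", ]), c(-1, 0, 1))

  m2 <- rbind(m, g2 = c(5, 5, 5))
  expect_warning(z2 <- zscore_by_gene(m2), "zero-variance")
  expect_equal(unname(z2["g2", ]), c(0, 0, 0))

  z <- zscore_by_gene(toy_matrix(30, 12))
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  sds <- apply(z, 1, sd)
  expect_true(all(abs(sds - 1) < 1e-9 | sds == 0))
})

test_that("activity score is the mean z over present signature genes", {
  m <- toy_matrix(12, 6)
  # single-gene signature equals that gene's z-scores
  sc1 <- activity_score(m, "G001")
  expect_equal(as.numeric(sc1), unname(zscore_by_gene(m)["G001", ]))

  # a sample sitting exactly at the gene-wise means has z = 0 for every gene,
  # so the full-signature score of that sample is 0
  base <- unclass(toy_matrix(10, 5, seed = 4))
  center <- rowMeans(base)
  withmean <- cbind(base, center = center)  # appending the mean keeps row means at `center`
  expect_equal(unname(rowMeans(withmean)), unname(center), tolerance = 1e-12)
  sc <- activity_score(expression_matrix(withmean), rownames(withmean))
  expect_equal(unname(sc["center"]), 0, tolerance = 1e-12)

  # 4 genes x 3 samples hand-computed oracle
  toy <- matrix(c(1, 2, 3,
                  2, 2, 2,
                  0, 1, 5,
                  4, 3, 2), 4, 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  zhand <- t(apply(toy, 1, function(r) if (sd(r) == 0) r * 0 else (r - mean(r)) / sd(r)))
  sc_toy <- suppressWarnings(activity_score(expression_matrix(toy), paste0("g", 1:4)))
  expect_equal(as.numeric(sc_toy), unname(colMeans(zhand)), tolerance = 1e-9)

  # invariance to gene order and to absent genes
  m <- toy_matrix(15, 8)
  a <- activity_score(m, c("G002", "G005", "G009"))
  b <- activity_score(m, c("G009", "G002", "G005"))
  expect_equal(as.numeric(a), as.numeric(b))
  d <- suppressWarnings(activity_score(m, c("G002", "G005", "G009",
                                            "ghost1", "ghost2", "ghost3", "ghost4")))
  expect_equal(as.numeric(a), as.numeric(d))
  expect_equal(attr(d, "n_genes_missing"), 4L)
  expect_error(activity_score(m, c("nope1", "nope2")), "no signature gene")
})

test_that("empirical p and null quantiles follow the stated formulas", {
  expect_equal(empirical_p(5, rep(0, 999)), 1 / 1000)
  expect_equal(empirical_p(0, c(1, 2, 3)), 1)
  expect_equal(empirical_p(2.5, c(1, 2, 3, 4)), (1 + 2) / 5)

  m <- toy_matrix(30, 10)
  nd <- random_set_null(m, 5, 50, function(s) 1, seed = 3, observed = 1)
  expect_equal(nd$quantile, 0.5)  # degenerate null, midpoint convention
  expect_equal(nd$summary$sd, 0)

  nd2 <- random_set_null(m, 5, 999, function(s) mean(s), seed = 4, observed = 100)
  expect_equal(nd2$empirical_p, 1 / 1000)
  expect_true(nd2$empirical_p > 0 && nd2$empirical_p <= 1)
})

test_that("true signatures beat size-matched random sets on coupled cohorts", {
  cfg <- tiny_cfg(activity_coupling = 0.8, cohort_n = 200L)
  sig <- sprintf("G%05d", 1:25)
  co <- simulate_cohort(cfg, sig)
  anchor <- as.numeric(co$matrix[cfg$anchor_gene, ])
  obs <- cor(as.numeric(activity_score(co$matrix, sig)), anchor)
  nd <- random_set_null(co$matrix, length(sig), 200,
                        function(s) cor(as.numeric(s), anchor),
                        seed = 5, observed = obs)
  expect_gt(obs, quantile(nd$values, 0.95))
  expect_lt(nd$empirical_p, 0.05)
})

test_that("score recovery tracks the planted coupling", {
  cfg <- tiny_cfg(activity_coupling = 0.8, cohort_n = 500L)
  sig <- sprintf("G%05d", 1:30)
  co <- simulate_cohort(cfg, sig)
  r <- cor(as.numeric(activity_score(co$matrix, sig)), co$activity)
  expect_gte(r, cfg$activity_coupling - 0.1)
})

test_that("polynomial R^2 equals the brute-force 1 - SSE/SST", {
  set.seed(6)
  # degree-6 interpolation of 7 points is exact
  x <- 1:7; y <- rnorm(7)
  expect_equal(poly_fit_r2(x, y, 6)$r2, 1, tolerance = 1e-9)

  # response orthogonal to the polynomial basis: SSE = SST, R^2 = 0
  x2 <- seq(-1, 1, length.out = 25)
  y0 <- rnorm(25)
  y_perp <- resid(lm(y0 ~ poly(x2, 6)))
  expect_equal(poly_fit_r2(x2, y_perp, 6)$r2, 0, tolerance = 1e-9)

  # 20-point cubic + noise against direct residual arithmetic
  x3 <- seq(0, 3, length.out = 20)
  y3 <- 2 + x3 - 0.5 * x3^3 + rnorm(20, 0, 0.2)
  pf <- poly_fit_r2(x3, y3, 6)
  sse <- sum((y3 - pf$fitted)^2)
  sst <- sum((y3 - mean(y3))^2)
  expect_equal(pf$r2, 1 - sse / sst, tolerance = 1e-9)
  expect_true(pf$r2 >= 0 && pf$r2 <= 1)

  expect_error(poly_fit_r2(1:6, rnorm(6), 6), "more points")
  expect_error(poly_fit_r2(1:10, rep(2, 10), 3), "zero variance")
})

test_that("recovery-curve cell scores match hand enumeration and bounds", {
  # 10 genes, 3-gene set, cutoff 5
  expr <- c(g01 = 10, g02 = 9, g03 = 8, g04 = 7, g05 = 6,
            g06 = 5, g07 = 4, g08 = 3, g09 = 2, g10 = 1)
  m <- expression_matrix(matrix(expr, ncol = 1, dimnames = list(names(expr), "c1")),
                         scale = "counts")
  # set at ranks 1, 3, 5: hits cumsum = 1,1,2,2,3 -> area 9; max = 1+2+3+3+3 = 12
  sc <- aucell_score(m, c("g01", "g03", "g05"), top_fraction = 0.5)
  expect_equal(as.numeric(sc), 9 / 12)
  # all set genes in the top |S| ranks -> 1
  expect_equal(as.numeric(aucell_score(m, c("g01", "g02", "g03"), 0.5)), 1)
  # all set genes below the cutoff -> 0
  expect_equal(as.numeric(aucell_score(m, c("g08", "g09", "g10"), 0.5)), 0)

  # invariance under a monotone transform of a cell's values
  set.seed(9)
  cells <- matrix(rpois(200 * 20, 5) + matrix(runif(200 * 20), 200), 200, 20,
                  dimnames = list(sprintf("g%03d", 1:200), sprintf("c%02d", 1:20)))
  em <- expression_matrix(cells, scale = "counts")
  sig <- sprintf("g%03d", 1:15)
  a <- aucell_score(em, sig, seed = 10)
  b <- aucell_score(expression_matrix(log1p(cells), scale = "log_counts"),
                    sig, seed = 10)
  expect_equal(as.numeric(a), as.numeric(b))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("rank-sum comparisons match exact enumeration", {
  expect_equal(compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$p, 1)
  cmp <- compare_groups(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(cmp$p, 0.1)  # 2/20 orderings as extreme, two-sided
  set.seed(12)
  big <- compare_groups(c(rnorm(200), rnorm(200, 1.5)),
                        rep(c("a", "b"), each = 200))
  expect_lt(big$p, 1e-6)
})
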