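ref_matrix_with_anchor <- function(n_extra = 6L, n_samples = 30L, seed = 2L) {
  set.seed(seed)
  anchor <- rnorm(n_samples)
  rows <- list(
    NR3C1 = anchor,
    pos1 = anchor + rnorm(n_samples, 0, 0.3),
    pos2 = 2 * anchor + rnorm(n_samples, 0, 0.5),
    neg1 = -anchor + rnorm(n_samples, 0, 0.3)
  )
  for (i in seq_len(n_extra)) rows[[paste0("noise", i)]] <- rnorm(n_samples)
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  expression_matrix(m)
}

test_that("model QC discards outlier models by the median + 3 MAD rule", {
  sets <- list(a = paste0("g", 1:200), b = paste0("g", 1:210),
               c = paste0("g", 1:190), d = paste0("g", 1:205),
               e = paste0("g", 1:3000))
  counts <- lengths(sets)
  cutoff_oracle <- median(counts) + 3 * mad(counts)
  q <- qc_filter_models(sets)
  expect_equal(q$report$discarded, unname(counts > cutoff_oracle))
  expect_equal(names(q$retained), c("a", "b", "c", "d"))

  same <- list(a = paste0("g", 1:50), b = paste0("g", 1:50), c = paste0("g", 1:50))
  expect_false(any(qc_filter_models(same)$report$discarded))
  expect_error(qc_filter_models(same[1:2]), ">= 3")
})

test_that("occurrence filter counts models per gene", {
  sets <- list(A = c("g1", "g2"), B = c("g1", "g3"), C = c("g1", "g2"))
  expect_equal(occurrence_filter(sets, 3)$retained, "g1")
  expect_setequal(occurrence_filter(sets, 2)$retained, c("g1", "g2"))
  expect_setequal(occurrence_filter(sets, 1)$retained, c("g1", "g2", "g3"))
})

test_that("elbow curve is non-increasing with the knee at max chord distance", {
  # occurrence counts engineered so sizes decay geometrically
  genes <- unlist(lapply(1:6, function(k) rep(paste0("k", k, "_", seq_len(2^(6 - k))), 1)))
  occ_target <- rep(1:6, times = 2^(5:0))
  sets <- lapply(1:6, function(m) {
    unlist(lapply(seq_along(occ_target), function(i) {
      if (occ_target[i] >= m) paste0("gene", i)
    }))
  })
  ec <- elbow_curve(sets)
  expect_true(all(diff(ec$curve$size) <= 0))
  expect_equal(ec$curve$size[1], length(occ_target))  # k=1 equals union size
  # independent distance-to-chord computation
  x <- ec$curve$k; y <- ec$curve$size
  x1 <- x[1]; y1 <- y[1]; x2 <- x[length(x)]; y2 <- y[length(y)]
  d <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  expect_equal(ec$knee, x[which.max(d)])
  expect_true(ec$knee > 1 && ec$knee < 6)

  const <- list(a = c("g1", "g2"), b = c("g1", "g2"))
  expect_true(is.na(elbow_curve(const)$knee))
})

test_that("anchor filter keeps positive correlations with strict R > 0", {
  ref <- ref_matrix_with_anchor()
  sig <- anchor_correlation_filter(c("pos1", "pos2", "neg1"), ref, "NR3C1")
  expect_setequal(sig$genes, c("pos1", "pos2"))
  expect_true(all(sig$anchor_r > 0))

  # gene identical to the anchor: R = 1
  m <- unclass(ref)
  m <- rbind(m, same = m["NR3C1", ])
  ref2 <- expression_matrix(m)
  sig2 <- anchor_correlation_filter("same", ref2, "NR3C1")
  expect_equal(unname(sig2$anchor_r["same"]), 1)

  # exactly orthogonal constructed vector: R = 0, dropped (strict >)
  orth <- matrix(c(1, 2, 3, 4, 1, -1, -1, 1, 5, 5, 1, 2), 3, 4, byrow = TRUE,
                 dimnames = list(c("NR3C1", "orthog", "other"), paste0("s", 1:4)))
  expect_equal(cor(orth["NR3C1", ], orth["orthog", ]), 0)
  sig3 <- anchor_correlation_filter(c("orthog", "other"), expression_matrix(orth), "NR3C1")
  expect_false("orthog" %in% sig3$genes)

  # absent and zero-variance genes dropped with warnings; flat anchor errors
  expect_warning(anchor_correlation_filter(c("pos1", "ghost"), ref, "NR3C1"),
                 "absent")
  flat <- expression_matrix(matrix(c(1, 1, 1, 1, 2, 3), 2, 3, byrow = TRUE,
                                   dimnames = list(c("NR3C1", "g"), paste0("s", 1:3))))
  expect_error(anchor_correlation_filter("g", flat, "NR3C1"), "zero variance")
})

test_that("occurrence and anchor filters commute and shrink the gene set", {
  ref <- ref_matrix_with_anchor(n_extra = 10)
  sets <- list(A = c("pos1", "pos2", "neg1", "noise1"),
               B = c("pos1", "neg1", "noise2"),
               C = c("pos1", "pos2", "neg1"))
  occ_then_anchor <- anchor_correlation_filter(
    occurrence_filter(sets, 2)$retained, ref, "NR3C1")$genes
  pre <- anchor_correlation_filter(unique(unlist(sets)), ref, "NR3C1")$genes
  occ <- occurrence_filter(sets, 2)
  anchor_then_occ <- intersect(pre, occ$retained)
  expect_setequal(occ_then_anchor, anchor_then_occ)

  # shrinking in min_models and under the anchor filter
  for (k in 1:3) {
    ret_k <- occurrence_filter(sets, k)$retained
    expect_lte(length(anchor_correlation_filter(ret_k, ref, "NR3C1")$genes),
               length(ret_k))
    if (k > 1) expect_lte(length(ret_k), length(occurrence_filter(sets, k - 1)$retained))
  }
})

test_that("signature overlap reports intersections and Jaccard", {
  ov <- signature_overlap(c("A", "B", "C"),
                          list(same = c("A", "B", "C"), disj = c("X", "Y"),
                               half = c("B", "C", "D")))
  expect_equal(ov$jaccard[ov$set == "same"], 1)
  expect_equal(ov$intersection[ov$set == "disj"], 0)
  expect_equal(ov$jaccard[ov$set == "disj"], 0)
  expect_equal(ov$intersection[ov$set == "half"], 2)
  expect_equal(ov$jaccard[ov$set == "half"], 0.5)
})

test_that("build_signature recovers planted responsive genes on a small panel", {
  cfg <- tiny_cfg(n_models = 8L, responder_penetrance = 0.8)
  pan <- simulate_model_panel(cfg)
  sets <- lapply(pan$models, function(m) {
    significant_up(moderated_t_contrast(m$matrix, m$arms))
  })
  truth <- pan$truth$gene[pan$truth$responsive]
  co <- simulate_cohort(cfg, truth, seed = 99L)
  sig <- build_signature(sets, co$matrix, cfg$anchor_gene)
  sens <- length(intersect(sig$genes, truth)) / length(truth)
  prec <- length(intersect(sig$genes, truth)) / length(sig$genes)
  expect_gte(sens, 0.8)
  expect_gte(prec, 0.9)
  expect_true(all(sig$occurrence[sig$genes] >= 3))
})
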