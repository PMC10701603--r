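# Shared fixtures, built in code. Small scales keep the default run fast;
# the heavier study-condition checks live in test-acceptance.R.

tiny_cfg <- function(...) {
  defaults <- list(n_models = 6L, n_genes = 400L, n_responsive = 30L,
                   cohort_n = 120L, n_cells = 60L, seed = 17L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# small log-intensity matrix with named genes/samples
toy_matrix <- function(n_genes = 20L, n_samples = 10L, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 7, 1),
              n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  expression_matrix(m, scale = "log_intensity")
}

# independent log-rank oracle: aggregated hypergeometric sums per event time
oracle_logrank <- function(times, events, groups) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  stopifnot(length(lev) == 2L)
  ts <- sort(unique(times[events == 1]))
  o1 <- e1 <- v1 <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == lev[1L])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == lev[1L])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v1 <- v1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (o1 - e1)^2 / v1
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# adjusted Rand index (for planted-partition recovery checks)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# brute-force ssGSEA running sum for one sample and one set
oracle_ssgsea <- function(expr, set_genes, weight = 0.25) {
  genes <- names(expr)
  r <- rank(expr, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  in_set <- genes %in% set_genes
  num <- 0; p_in <- 0; p_out <- 0; total <- 0
  wsum <- sum(r[in_set]^weight)
  n_out <- sum(!in_set)
  for (i in ord) {
    if (in_set[i]) p_in <- p_in + r[i]^weight / wsum else p_out <- p_out + 1 / n_out
    total <- total + (p_in - p_out)
  }
  unname(total)
}
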