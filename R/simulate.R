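# Synthetic-data generators with planted ground truth. Every generator is a
# pure function of (cfg, seed): the global RNG state is saved and restored.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulation configuration
#'
#' Holds all knobs for the synthetic perturbation panel, tumor cohort,
#' single-cell and peak generators. Defaults describe the study conditions:
#' 20 treated/vehicle models profiled on a log-intensity scale, 10,000 genes
#' of which 200 respond to the hormone with mean log2 fold change 2.0 and
#' per-model penetrance 0.6, a 500-sample cohort whose latent activity is
#' coupled to signature genes and the anchor gene at 0.8, and a survival
#' effect of hazard ratio 2.5 between low and high activity.
#'
#' @param n_models number of perturbation models.
#' @param n_genes size of the gene universe.
#' @param n_responsive number of truly hormone-responsive genes.
#' @param effect_logfc mean planted log2 fold change in treated arms.
#' @param responder_penetrance probability a responsive gene is induced in a
#'   given model.
#' @param n_samples_per_arm samples per treatment arm per model (>= 2).
#' @param cohort_n cohort size (>= 20).
#' @param anchor_gene id of the anchor gene coupled to the latent activity.
#' @param activity_coupling correlation strength in [0,1] between the latent
#'   activity and signature/anchor gene expression.
#' @param hazard_ratio survival hazard ratio of low- versus high-activity
#'   samples (> 0).
#' @param n_cells cells per group in the single-cell generator.
#' @param censor_rate target censoring fraction for cohort survival.
#' @param seed default integer seed for all generators.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_models = 20L, n_genes = 10000L, n_responsive = 200L,
                       effect_logfc = 2.0, responder_penetrance = 0.6,
                       n_samples_per_arm = 4L, cohort_n = 500L,
                       anchor_gene = "NR3C1", activity_coupling = 0.8,
                       hazard_ratio = 2.5, n_cells = 200L,
                       censor_rate = 0.3, seed = 17L) {
  cfg <- list(n_models = as.integer(n_models), n_genes = as.integer(n_genes),
              n_responsive = as.integer(n_responsive), effect_logfc = effect_logfc,
              responder_penetrance = responder_penetrance,
              n_samples_per_arm = as.integer(n_samples_per_arm),
              cohort_n = as.integer(cohort_n), anchor_gene = anchor_gene,
              activity_coupling = activity_coupling, hazard_ratio = hazard_ratio,
              n_cells = as.integer(n_cells), censor_rate = censor_rate,
              seed = as.integer(seed))
  if (cfg$n_responsive >= cfg$n_genes) stop("n_responsive must be < n_genes")
  if (cfg$responder_penetrance <= 0 || cfg$responder_penetrance > 1) {
    stop("responder_penetrance must be in (0, 1]")
  }
  if (cfg$hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (cfg$activity_coupling < 0 || cfg$activity_coupling > 1) {
    stop("activity_coupling must be in [0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_ids <- function(n) sprintf("G%05d", seq_len(n))

#' Simulate a panel of treated/vehicle perturbation models
#'
#' Per model: per-gene baseline log intensity ~ Normal(7, 1.5^2); the treated
#' arm adds `effect_logfc` (jittered by Normal(0, 0.1^2)) to each responsive
#' gene with probability `responder_penetrance`; within-arm noise is
#' Normal(0, 0.3^2). A counts mode draws negative-binomial counts
#' (dispersion 0.1) around the same log2 means.
#'
#' @param cfg a [sim_config()].
#' @param mode `"log_intensity"` (default) or `"counts"`.
#' @param seed integer seed (default `cfg$seed`).
#' @return list with `models` (per model: `matrix`, an `ExpressionMatrix`,
#'   and `arms`, a character vector `"vehicle"`/`"treated"`) and `truth`
#'   (data frame: gene, responsive flag, and one induced flag per model).
#' @export
simulate_model_panel <- function(cfg, mode = c("log_intensity", "counts"),
                                 seed = cfg$seed) {
  mode <- match.arg(mode)
  if (cfg$n_samples_per_arm < 2L) stop("need >= 2 samples per arm for differential testing")
  with_seed(seed, {
    genes <- sim_gene_ids(cfg$n_genes)
    responsive <- sort(sample.int(cfg$n_genes, cfg$n_responsive))
    resp_flag <- seq_len(cfg$n_genes) %in% responsive
    n <- cfg$n_samples_per_arm
    arms <- rep(c("vehicle", "treated"), each = n)
    induced <- matrix(FALSE, cfg$n_genes, cfg$n_models)
    models <- vector("list", cfg$n_models)
    for (m in seq_len(cfg$n_models)) {
      base <- stats::rnorm(cfg$n_genes, 7, 1.5)
      ind <- resp_flag & (stats::runif(cfg$n_genes) <= cfg$responder_penetrance)
      if (cfg$effect_logfc == 0) ind <- rep(FALSE, cfg$n_genes)
      induced[, m] <- ind
      shift <- ifelse(ind, cfg$effect_logfc + stats::rnorm(cfg$n_genes, 0, 0.1), 0)
      mu <- outer(base, rep(1, 2 * n))
      mu[, arms == "treated"] <- mu[, arms == "treated"] + shift
      if (mode == "log_intensity") {
        vals <- mu + matrix(stats::rnorm(length(mu), 0, 0.3), nrow(mu))
        sc <- "log_intensity"
      } else {
        vals <- matrix(stats::rnbinom(length(mu), mu = 2^mu, size = 1 / 0.1), nrow(mu))
        sc <- "counts"
      }
      dimnames(vals) <- list(genes, paste0("M", m, "_", arms, "_", rep(seq_len(n), 2)))
      models[[m]] <- list(matrix = expression_matrix(vals, scale = sc), arms = arms)
    }
    names(models) <- paste0("model_", seq_len(cfg$n_models))
    truth <- data.frame(gene = genes, responsive = resp_flag,
                        stringsAsFactors = FALSE)
    for (m in seq_len(cfg$n_models)) truth[[paste0("induced_model_", m)]] <- induced[, m]
    list(models = models, truth = truth)
  })
}

#' Simulate a tumor cohort with a latent activity variable
#'
#' Latent activity `a_i ~ Normal(0,1)`. Signature genes and the anchor gene
#' follow `coupling * a_i + sqrt(1 - coupling^2) * noise` (per-gene
#' standardized); background genes are independent standard normals. Subtype
#' is LumA when activity is above the cohort median, LumB otherwise, with a
#' 15% label flip. Survival times are exponential with log hazard
#' `-log(hazard_ratio) * a_i` (high activity protective) under uniform
#' censoring at the configured rate; the mitotic category is the inverted
#' activity tertile.
#'
#' @param cfg a [sim_config()].
#' @param signature_genes character vector of signature gene ids (made rows
#'   of the cohort matrix).
#' @param seed integer seed (default `cfg$seed`).
#' @return list with `matrix` (`ExpressionMatrix`), `cohort` (`CohortTable`),
#'   and `activity` (named latent activity vector).
#' @export
simulate_cohort <- function(cfg, signature_genes, seed = cfg$seed) {
  if (cfg$cohort_n < 20L) stop("cohort_n must be >= 20")
  with_seed(seed, {
    n <- cfg$cohort_n
    genes <- union(sim_gene_ids(cfg$n_genes), c(signature_genes, cfg$anchor_gene))
    samples <- sprintf("S%04d", seq_len(n))
    a <- stats::rnorm(n)
    names(a) <- samples
    rho <- cfg$activity_coupling
    vals <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
                   dimnames = list(genes, samples))
    coupled <- union(signature_genes, cfg$anchor_gene)
    for (g in coupled) {
      vals[g, ] <- rho * a + sqrt(1 - rho^2) * stats::rnorm(n)
    }
    subtype <- ifelse(a > stats::median(a), "LumA", "LumB")
    flip <- stats::runif(n) < 0.15
    subtype[flip] <- ifelse(subtype[flip] == "LumA", "LumB", "LumA")
    haz <- exp(-log(cfg$hazard_ratio) * a)
    t_event <- stats::rexp(n, rate = haz)
    cens_max <- stats::quantile(t_event, 1 - cfg$censor_rate) * 2
    t_cens <- stats::runif(n, 0, cens_max)
    time <- pmin(t_event, t_cens) * 12  # months
    event <- as.integer(t_event <= t_cens)
    tert <- cut(a, stats::quantile(a, c(0, 1 / 3, 2 / 3, 1)), include.lowest = TRUE,
                labels = c("high", "intermediate", "low"))
    cohort <- cohort_table(samples, subtype, time, event,
                           mitotic_category = as.character(tert),
                           subtype_levels = c("LumA", "LumB"))
    list(matrix = expression_matrix(vals, scale = "log_intensity"),
         cohort = cohort, activity = a)
  })
}

#' Simulate single-cell count matrices with per-group activity shifts
#'
#' Negative-binomial counts (dispersion 0.1) with log-normal library-size
#' factors; the expected counts of signature genes are scaled by
#' `exp(group_activity)` in each group.
#'
#' @param cfg a [sim_config()]; `cfg$n_cells` cells are drawn per group.
#' @param groups named numeric vector of per-group activity shifts, e.g.
#'   `c(LumA = 1.5, LumB = 0)`.
#' @param signature_genes gene ids whose means respond to the group activity.
#' @param n_genes gene universe size for the cell matrix (default 2000 keeps
#'   single-cell runs light).
#' @param seed integer seed (default `cfg$seed`).
#' @return list with `matrix` (counts `ExpressionMatrix`) and `cells`
#'   (data frame: cell_id, group).
#' @export
simulate_single_cells <- function(cfg, groups, signature_genes,
                                  n_genes = 2000L, seed = cfg$seed) {
  if (is.null(names(groups)) || any(names(groups) == "")) stop("groups must be named")
  if (cfg$n_cells < 10L) warning("groups with < 10 cells give unstable comparisons")
  with_seed(seed, {
    genes <- union(sim_gene_ids(n_genes), signature_genes)
    base_mu <- exp(stats::rnorm(length(genes), log(2), 1))
    names(base_mu) <- genes
    total <- cfg$n_cells * length(groups)
    cell_id <- sprintf("C%05d", seq_len(total))
    group <- rep(names(groups), each = cfg$n_cells)
    libf <- exp(stats::rnorm(total, 0, 0.3))
    mu <- outer(base_mu, libf)
    sig <- intersect(signature_genes, genes)
    for (g in names(groups)) {
      idx <- group == g
      mu[sig, idx] <- mu[sig, idx] * exp(groups[[g]])
    }
    vals <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / 0.1),
                   nrow(mu), dimnames = list(genes, cell_id))
    list(matrix = expression_matrix(vals, scale = "counts"),
         cells = data.frame(cell_id = cell_id, group = group,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a gene annotation over a synthetic genome
#'
#' Places one TSS per gene on a small number of chromosomes with ~250 kb
#' spacing plus jitter, so proximity windows of neighbouring genes do not
#' overlap.
#'
#' @param gene_ids character vector of gene ids.
#' @param n_chrom number of synthetic chromosomes.
#' @param spacing base spacing between consecutive TSSs (bp).
#' @param seed integer seed.
#' @return a `GeneAnnotation`.
#' @export
simulate_gene_annotation <- function(gene_ids, n_chrom = 4L, spacing = 250000L,
                                     seed = 17L) {
  with_seed(seed, {
    n <- length(gene_ids)
    chrom <- paste0("chr", rep_len(seq_len(n_chrom), n))
    pos_in_chrom <- unlist(lapply(split(seq_len(n), chrom), seq_along), use.names = FALSE)
    ord <- order(chrom)
    idx <- seq_len(n)[ord]
    tss <- integer(n)
    tss[idx] <- 150000L + (pos_in_chrom - 1L) * spacing +
      sample.int(50000L, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gene_annotation(gene_ids, chrom, tss, strand)
  })
}

#' Simulate ChIP peaks enriched near signature-gene TSSs
#'
#' Peaks fall uniformly over the synthetic genome except inside the
#' +/- 100 kb windows around signature-gene TSSs, where the density is
#' multiplied by a factor that decays linearly with the 10 kb distance bin:
#' `enrichment_fold` in the first bin down to ~1 in the last.
#'
#' @param annotation a `GeneAnnotation` covering the genome.
#' @param signature gene ids whose TSS neighbourhoods are enriched.
#' @param enrichment_fold density multiplier at the TSS-proximal bin
#'   (1 = uniform).
#' @param n_peaks number of peaks to draw.
#' @param seed integer seed.
#' @param peak_width width of each peak interval (bp).
#' @return a `PeakSet`.
#' @export
simulate_peaks <- function(annotation, signature, enrichment_fold = 1,
                           n_peaks = 10000L, seed = 17L, peak_width = 200L) {
  if (n_peaks == 0L) return(peak_set())
  with_seed(seed, {
    chrom_len <- tapply(annotation$tss, annotation$chrom, max) + 200000L
    sig <- annotation[annotation$gene_id %in% signature, , drop = FALSE]
    # piecewise-constant density: background weight 1, window bins weighted
    segs <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                       w = numeric(0))
    bins <- 10L
    binw <- 10000L
    mult <- 1 + (enrichment_fold - 1) * (bins - seq_len(bins) + 1) / bins
    win <- list()
    if (nrow(sig) > 0L && enrichment_fold != 1) {
      for (i in seq_len(nrow(sig))) {
        tss <- sig$tss[i]
        for (b in seq_len(bins)) {
          for (side in c(-1, 1)) {
            s <- tss + side * ifelse(side < 0, b * binw, (b - 1) * binw)
            e <- s + binw
            s <- max(0, s); e <- min(e, chrom_len[[sig$chrom[i]]])
            if (e > s) win[[length(win) + 1L]] <-
                data.frame(chrom = sig$chrom[i], start = s, end = e, w = mult[b])
          }
        }
      }
    }
    win <- if (length(win)) do.call(rbind, win) else segs
    # background = whole chromosomes; windows add (w - 1) extra weight on top,
    # which yields exactly the uniform law when enrichment_fold = 1
    bg <- data.frame(chrom = names(chrom_len), start = 0, end = as.numeric(chrom_len),
                     w = 1)
    ex <- if (nrow(win)) transform(win, w = w - 1) else win
    segs <- rbind(bg, ex[ex$w > 0, , drop = FALSE])
    wt <- segs$w * (segs$end - segs$start)
    pick <- sample.int(nrow(segs), n_peaks, replace = TRUE, prob = wt)
    pos <- segs$start[pick] + stats::runif(n_peaks) * (segs$end[pick] - segs$start[pick])
    start <- pmax(0, round(pos - peak_width / 2))
    peak_set(segs$chrom[pick], start, start + peak_width)
  })
}
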