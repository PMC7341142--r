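#' Squared dosage correlation between two SNPs
#'
#' r^2 over pairwise-complete individuals; sign-invariant, so allele coding
#' does not matter.
#'
#' @param a,b Dosage vectors.
#' @return r^2 in `[0, 1]`, or `NA` when fewer than two complete pairs or
#'   zero variance (undefined, distinct from 0).
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `window_snps` target SNPs, any pair with r^2 above
#' `r2_max` loses one member (the one with the lower non-missing count, then
#' the later position); the window then slides by `step` SNPs. No surviving
#' pair within a window exceeds the threshold.
#'
#' @param gm [genotype_matrix()] providing dosages (sites sorted).
#' @param targets Site ids eligible for pruning (e.g. non-outlier SNPs).
#' @param r2_max r^2 threshold (default 0.2).
#' @param window_snps,step Window size and slide step in SNPs (defaults 50
#'   and 5).
#' @return Character vector of surviving target site ids.
#' @export
prune_ld <- function(gm, targets, r2_max = 0.2, window_snps = 50, step = 5) {
  idx_all <- which(gm$sites$id %in% targets)
  alive <- rep(TRUE, length(idx_all))
  names(alive) <- gm$sites$id[idx_all]
  nonmiss <- colSums(!is.na(gm$dosage[, idx_all, drop = FALSE]))
  prune_window <- function(win) {
    dropped <- FALSE
    for (ai in seq_len(length(win) - 1)) {
      for (bi in seq(ai + 1, length(win))) {
        a <- win[ai]; b <- win[bi]
        if (!alive[a] || !alive[b]) next
        r2 <- ld_r2(gm$dosage[, idx_all[a]], gm$dosage[, idx_all[b]])
        if (!is.na(r2) && r2 > r2_max) {
          ## drop the SNP with fewer calls; tie -> the later position
          drop <- if (nonmiss[a] < nonmiss[b]) a
                  else if (nonmiss[b] < nonmiss[a]) b
                  else b
          alive[drop] <<- FALSE
          dropped <- TRUE
        }
      }
    }
    dropped
  }
  for (ch in unique(gm$sites$chrom[idx_all])) {
    on_ch <- which(gm$sites$chrom[idx_all] == ch)
    ## slide over the currently surviving SNPs until a clean pass, so no
    ## surviving pair within a window of survivors can exceed the threshold
    repeat {
      surv <- on_ch[alive[on_ch]]
      if (length(surv) < 2) break
      any_drop <- FALSE
      for (st in seq(1, length(surv), by = step)) {
        win <- surv[st:min(st + window_snps - 1, length(surv))]
        win <- win[alive[win]]
        if (length(win) >= 2 && prune_window(win)) any_drop <- TRUE
        if (st + window_snps - 1 >= length(surv)) break
      }
      if (!any_drop) break
    }
  }
  names(alive)[alive]
}

#' Frequency-matched control sample
#'
#' Draws, per frequency bin, as many control SNPs (without replacement) from
#' the pool as there are outliers in the bin; when a bin's pool is smaller
#' than required, all of it is taken and the deficit recorded.
#'
#' @param outlier_freq Named numeric vector: frequency per outlier SNP
#'   (names are site ids). The caller chooses which frequency to match on.
#' @param pool_freq Named numeric vector: frequency per candidate control
#'   SNP (typically LD-pruned non-outliers).
#' @param n_bins Number of equal-width bins on `[0, 1]` (default 10).
#' @param seed Integer seed for the draw.
#' @return List with `controls` (site ids), `deficit` (total shortfall) and
#'   `per_bin` (data frame `bin n_outliers n_pool n_sampled`).
#' @export
frequency_match_sample <- function(outlier_freq, pool_freq, n_bins = 10,
                                   seed = 1) {
  set.seed(seed)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  cut_bin <- function(f) pmin(findInterval(f, breaks, rightmost.closed = TRUE),
                              n_bins)
  ob <- cut_bin(outlier_freq)
  pb <- cut_bin(pool_freq)
  controls <- character(0)
  per_bin <- data.frame(bin = seq_len(n_bins), n_outliers = 0L, n_pool = 0L,
                        n_sampled = 0L)
  for (b in seq_len(n_bins)) {
    want <- sum(ob == b)
    pool_b <- names(pool_freq)[pb == b]
    per_bin$n_outliers[b] <- want
    per_bin$n_pool[b] <- length(pool_b)
    if (want == 0) next
    take <- min(want, length(pool_b))
    if (take < want)
      warning("frequency bin ", b, ": pool deficit of ", want - take, " SNP(s)")
    if (take > 0)
      controls <- c(controls, sample(pool_b, take))
    per_bin$n_sampled[b] <- take
  }
  list(controls = controls, deficit = sum(per_bin$n_outliers - per_bin$n_sampled),
       per_bin = per_bin)
}

#' Bootstrap comparison of heterozygote frequencies
#'
#' Resamples both groups with replacement `n_boot` times and compares the
#' group means; the two-sided p-value is twice the fraction of resampled
#' mean differences on the opposite side of 0 from the observed difference,
#' capped at 1.
#'
#' @param het_outliers,het_controls Per-SNP heterozygote frequencies.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return List with `mean_outliers`, `mean_controls`, `diff` and `p_value`.
#' @export
heterozygosity_enrichment <- function(het_outliers, het_controls,
                                      n_boot = 1000, seed = 1) {
  if (length(het_outliers) < 2 || length(het_controls) < 2)
    stop("both groups need at least two SNPs")
  set.seed(seed)
  obs <- mean(het_outliers) - mean(het_controls)
  boot <- replicate(n_boot, {
    mean(sample(het_outliers, replace = TRUE)) -
      mean(sample(het_controls, replace = TRUE))
  })
  opposite <- if (obs >= 0) mean(boot <= 0) else mean(boot >= 0)
  list(mean_outliers = mean(het_outliers), mean_controls = mean(het_controls),
       diff = obs, p_value = min(1, 2 * opposite))
}

#' Local recombination rates from a genetic map
#'
#' Computes the cM span of non-overlapping physical tiles (default 1 Mbp),
#' labels each SNP with its tile's rate and partitions SNPs into
#' recombination quantiles.
#'
#' @param map A [read_genetic_map()] data frame.
#' @param sites Site data frame (`chrom`, `pos`, `id`).
#' @param window_mbp Tile width in Mbp (default 1).
#' @param n_quantiles Number of rate quantile groups (default 5, quintiles).
#' @return List with `windows` (`chrom start end rate`), `snp_rate` (named
#'   vector) and `snp_quantile` (named integer vector in 1..n_quantiles).
#' @export
recombination_rates <- function(map, sites, window_mbp = 1, n_quantiles = 5) {
  w <- window_mbp * 1e6
  idx <- floor(sites$pos / w)
  key <- paste(sites$chrom, idx, sep = "@")
  uk <- unique(key)
  first <- match(uk, key)
  start <- idx[first] * w
  cm0 <- interpolate_cm(map, sites$chrom[first], start)
  cm1 <- interpolate_cm(map, sites$chrom[first], start + w)
  rate <- (cm1 - cm0) / window_mbp
  windows <- data.frame(chrom = sites$chrom[first], start = start,
                        end = start + w, rate = rate)
  snp_rate <- rate[match(key, uk)]
  names(snp_rate) <- sites$id
  if (length(unique(snp_rate)) == 1) {
    q <- rep(1L, length(snp_rate))
  } else {
    edges <- unique(stats::quantile(snp_rate, probs = seq(0, 1,
                                                          length.out = n_quantiles + 1)))
    q <- pmin(findInterval(snp_rate, edges, rightmost.closed = TRUE),
              length(edges) - 1)
  }
  names(q) <- sites$id
  list(windows = windows, snp_rate = snp_rate, snp_quantile = q)
}

#' Stratified control sample over frequency and recombination strata
#'
#' Samples controls without replacement per (ancestral-frequency bin x
#' recombination quantile) cell to match the outlier count in that cell;
#' deficits are recorded.
#'
#' @param outlier_freq,pool_freq Named ancestral-frequency vectors (names
#'   are site ids) for outliers and candidate controls.
#' @param snp_quantile Named recombination-quantile labels covering both
#'   sets (from [recombination_rates()]).
#' @param bin_width Ancestral-frequency bin width (default 0.1).
#' @param seed Integer seed.
#' @return List with `controls`, `deficit` and `per_cell` data frame.
#' @export
stratified_control_sample <- function(outlier_freq, pool_freq, snp_quantile,
                                      bin_width = 0.1, seed = 1) {
  set.seed(seed)
  n_bins <- ceiling(1 / bin_width)
  bin_of <- function(f) pmin(floor(f / bin_width) + 1L, n_bins)
  o_cell <- paste(bin_of(outlier_freq), snp_quantile[names(outlier_freq)])
  p_cell <- paste(bin_of(pool_freq), snp_quantile[names(pool_freq)])
  cells <- unique(o_cell)
  controls <- character(0)
  per_cell <- data.frame(cell = cells, n_outliers = NA_integer_,
                         n_pool = NA_integer_, n_sampled = NA_integer_)
  for (ci in seq_along(cells)) {
    want <- sum(o_cell == cells[ci])
    pool_c <- names(pool_freq)[p_cell == cells[ci]]
    take <- min(want, length(pool_c))
    if (take < want)
      warning("stratification cell ", cells[ci], ": deficit of ",
              want - take, " SNP(s)")
    if (take > 0) controls <- c(controls, sample(pool_c, take))
    per_cell[ci, 2:4] <- c(want, length(pool_c), take)
  }
  list(controls = controls,
       deficit = sum(per_cell$n_outliers - per_cell$n_sampled),
       per_cell = per_cell)
}

#' GERP-weighted genetic load around a focal SNP
#'
#' Sums conservation-score-weighted genotypes over genotyped SNPs with
#' positive GERP score inside the 1 cM window centred on the focal SNP.
#' Under the additive model a genotype contributes dosage/2 of the score;
#' under the recessive model it contributes the full score only when
#' homozygous for the alternative allele. Missing genotypes contribute 0.
#'
#' @param focal_id Focal site id.
#' @param gm [genotype_matrix()] of the population scored.
#' @param gerp Data frame `chrom pos score` (positive scores mark
#'   evolutionary constraint).
#' @param map A [read_genetic_map()] data frame.
#' @param model `"additive"` or `"recessive"`.
#' @param window_cm Window width in cM (default 1, i.e. +/- 0.5).
#' @return List with `per_individual` (named numeric), `mean_load`,
#'   `n_sites` (contributing SNPs) and `empty` flag.
#' @export
gerp_window_load <- function(focal_id, gm, gerp, map,
                             model = c("additive", "recessive"),
                             window_cm = 1) {
  model <- match.arg(model)
  f <- match(focal_id, gm$sites$id)
  if (is.na(f)) stop("focal SNP not in genotype matrix: ", focal_id)
  cm_all <- interpolate_cm(map, gm$sites$chrom, gm$sites$pos)
  centre <- cm_all[f]
  in_win <- gm$sites$chrom == gm$sites$chrom[f] &
    cm_all >= centre - window_cm / 2 & cm_all <= centre + window_cm / 2
  key <- paste(gm$sites$chrom, gm$sites$pos)
  gkey <- paste(gerp$chrom, gerp$pos)
  score <- gerp$score[match(key, gkey)]
  use <- in_win & !is.na(score) & score > 0
  if (!any(use))
    return(list(per_individual = stats::setNames(numeric(length(gm$samples)),
                                                 gm$samples),
                mean_load = 0, n_sites = 0L, empty = TRUE))
  dos <- gm$dosage[, use, drop = FALSE]
  g <- if (model == "additive") dos / 2 else (dos == 2L) * 1
  g[is.na(g)] <- 0
  load <- as.vector(g %*% score[use])
  names(load) <- gm$samples
  list(per_individual = load, mean_load = mean(load),
       n_sites = sum(use), empty = FALSE)
}

#' Compare genetic load between outlier and control windows
#'
#' Welch two-sided t-test on per-window mean loads.
#'
#' @param outlier_loads,control_loads Numeric vectors of window loads.
#' @return List with `mean_outliers`, `mean_controls` and `p_value` (`NA`
#'   when both groups are degenerate).
#' @export
compare_load <- function(outlier_loads, control_loads) {
  if (length(outlier_loads) < 2 || length(control_loads) < 2)
    stop("both groups need at least two values")
  p <- if (stats::var(outlier_loads) == 0 && stats::var(control_loads) == 0) {
    NA_real_
  } else {
    stats::t.test(outlier_loads, control_loads)$p.value
  }
  list(mean_outliers = mean(outlier_loads),
       mean_controls = mean(control_loads), p_value = p)
}
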