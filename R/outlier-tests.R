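#' Configuration for the allele-frequency outlier tests
#'
#' Both tests model three binomial sampling events: landrace (LR)
#' genotyping from the ancestral accession, survival of a pool of `n_H` DH
#' lines, and genotyping of a DH subsample.
#'
#' @param n_H Surviving DH pool size (default 100).
#' @param grid Candidate ancestral frequencies for the maximum-likelihood
#'   search (default 100 evenly spaced values from 0.01 to 0.99).
#' @param prior_alpha,prior_beta Beta prior parameters on the unknown
#'   ancestral frequency in the joint-probability test (default 1/2, 1/2,
#'   the Jeffreys prior).
#' @param mass Probability mass of the central confidence interval
#'   (default 0.95).
#' @param outlier_fraction Fraction of sites flagged by the joint test
#'   (default 0.05, the top 5 percent of -log10(P)).
#' @param ml_mode `"joint"` maximizes the likelihood surface over (grid
#'   frequency, pool count) jointly; `"marginal"` sums the surface over pool
#'   counts first.
#' @param interval_type `"central"` (equal-tail) or `"hpd"`
#'   (highest-density) construction of the DH-count interval.
#' @return List of class `model_config`.
#' @export
model_config <- function(n_H = 100,
                         grid = seq(0.01, 0.99, length.out = 100),
                         prior_alpha = 0.5, prior_beta = 0.5,
                         mass = 0.95, outlier_fraction = 0.05,
                         ml_mode = c("joint", "marginal"),
                         interval_type = c("central", "hpd")) {
  stopifnot(n_H >= 1, all(diff(grid) > 0), all(grid > 0), all(grid < 1),
            prior_alpha > 0, prior_beta > 0,
            mass > 0, mass < 1, outlier_fraction > 0, outlier_fraction < 1)
  structure(list(n_H = as.integer(n_H), grid = grid,
                 prior_alpha = prior_alpha, prior_beta = prior_beta,
                 mass = mass, outlier_fraction = outlier_fraction,
                 ml_mode = match.arg(ml_mode),
                 interval_type = match.arg(interval_type)),
            class = "model_config")
}

## log of the three-binomial surface, grid rows x pool counts 0..n_H columns
log_surface <- function(l, n_L, d, n_D, config, log_PH = NULL) {
  grid <- config$grid
  i <- 0:config$n_H
  if (is.null(log_PH))
    log_PH <- outer(grid, i, function(j, k) stats::dbinom(k, config$n_H, j,
                                                          log = TRUE))
  log_PL <- stats::dbinom(l, n_L, grid, log = TRUE)
  log_PD <- stats::dbinom(d, n_D, i / config$n_H, log = TRUE)
  log_PH + log_PL + rep(log_PD, each = length(grid))
}

#' Likelihood surface for the ancestral frequency of one site
#'
#' Entry (j, i) is the product of three binomial masses: the genotyped DH
#' allele count `d` out of `n_D` at pool frequency i/n_H, the pool count `i`
#' out of `n_H` at ancestral frequency grid\[j\], and the LR allele count
#' `l` out of `n_L` at grid\[j\]. Computed in log space and exponentiated
#' (the `0^0 = 1` boundary cases are handled by the binomial mass itself).
#'
#' @param l,n_L LR alternative-allele count and chromosome count.
#' @param d,n_D DH alternative-allele count and chromosome count.
#' @param config A [model_config()].
#' @return Numeric matrix (grid frequencies x pool counts 0..n_H) with the
#'   grid as row names.
#' @export
likelihood_surface <- function(l, n_L, d, n_D, config = model_config()) {
  stopifnot(n_L >= 1, n_D >= 1, l >= 0, l <= n_L, d >= 0, d <= n_D)
  surf <- exp(log_surface(l, n_L, d, n_D, config))
  dimnames(surf) <- list(format(config$grid), 0:config$n_H)
  surf
}

## argmax over the surface with the declared tie-breaks; works on log scale
surface_argmax <- function(log_surf, config, rel_tol = 1e-12) {
  if (all(!is.finite(log_surf)))
    stop("likelihood surface underflowed to zero everywhere")
  m <- max(log_surf)
  if (config$ml_mode == "marginal") {
    row_m <- apply(log_surf, 1, max)
    rows <- log(rowSums(exp(log_surf - m))) # relative marginal likelihood
    best <- max(rows)
    j <- which(rows >= best - rel_tol)[1]   # tie -> smaller grid frequency
  } else {
    hit <- which(log_surf >= m - rel_tol, arr.ind = TRUE)
    j <- min(hit[, 1])                      # tie -> smaller grid frequency
  }
  config$grid[j]
}

#' Maximum-likelihood ancestral frequency from a likelihood surface
#'
#' The grid frequency whose surface entry (or marginal over pool counts,
#' under `ml_mode = "marginal"`) is largest; likelihood ties are broken to
#' the smaller frequency.
#'
#' @param surface Matrix from [likelihood_surface()].
#' @param config The [model_config()] that produced it.
#' @return The estimated ancestral frequency (a grid value).
#' @export
ml_ancestral_frequency <- function(surface, config = model_config()) {
  if (all(surface == 0))
    stop("likelihood surface underflowed to zero everywhere")
  surface_argmax(log(surface), config)
}

#' Distribution of the genotyped DH allele count at a given ancestral frequency
#'
#' Mixture of binomials: P(s) = sum_i Binom(s; n_D, i/n_H) Binom(i; n_H, p),
#' the distribution of the DH-sample allele count after pool survival and
#' genotyping under neutrality.
#'
#' @param p_anc Ancestral frequency in (0, 1).
#' @param n_D Genotyped DH chromosome count.
#' @param config A [model_config()].
#' @return Numeric probability vector over s in 0..n_D (sums to 1).
#' @export
dh_count_distribution <- function(p_anc, n_D, config = model_config()) {
  stopifnot(p_anc > 0, p_anc < 1, n_D >= 1)
  i <- 0:config$n_H
  M <- outer(0:n_D, i / config$n_H, function(s, q) stats::dbinom(s, n_D, q))
  as.vector(M %*% stats::dbinom(i, config$n_H, p_anc))
}

#' Central (equal-tail) interval of a discrete probability vector
#'
#' `s_lo` is the largest count with cumulative mass below it under
#' (1 - mass)/2; `s_hi` is the smallest count with tail mass above it under
#' (1 - mass)/2. The contained mass is therefore at least `mass`.
#'
#' @param p Probability vector over counts `0..length(p)-1`.
#' @param mass Target interval mass (default 0.95).
#' @param type `"central"` or `"hpd"` (highest-density: counts accumulated
#'   in decreasing probability order until `mass` is reached; the interval
#'   is their range).
#' @return Integer vector `c(s_lo, s_hi)`.
#' @export
central_interval <- function(p, mass = 0.95, type = c("central", "hpd")) {
  type <- match.arg(type)
  stopifnot(abs(sum(p) - 1) < 1e-6)
  n <- length(p) - 1L
  if (type == "hpd") {
    ord <- order(p, decreasing = TRUE)
    k <- which(cumsum(p[ord]) >= mass - 1e-12)[1]
    sel <- ord[seq_len(k)] - 1L
    return(c(min(sel), max(sel)))
  }
  tail <- (1 - mass) / 2
  below <- c(0, cumsum(p))[seq_len(n + 1)]   # P(S < s) for s = 0..n
  above <- rev(c(0, cumsum(rev(p))))[-1]     # P(S > s) for s = 0..n
  s_lo <- max(which(below < tail - 1e-15)) - 1L
  s_hi <- min(which(above < tail - 1e-15)) - 1L
  c(s_lo, s_hi)
}

#' aSFS outlier classification of sites
#'
#' For each site: estimate the ancestral frequency by grid maximum
#' likelihood over the three-stage sampling surface, build the neutral
#' distribution of the genotyped DH allele count at that estimate, take its
#' central interval, and classify the observed DH count as `below`, `above`
#' or `inside` the interval. Sites outside the interval are aSFS outliers.
#'
#' @param counts Data frame from [site_counts()] (columns `site_id l n_L d
#'   n_D`); per-site chromosome counts may vary with missingness.
#' @param config A [model_config()].
#' @param p_anc Optional vector of ancestral frequencies to use instead of
#'   the ML estimate (e.g. simulation truth, for calibration studies).
#' @return Data frame `site_id l n_L d n_D p_anc_hat s_lo s_hi class`.
#' @export
asfs_classify <- function(counts, config = model_config(), p_anc = NULL) {
  ns <- nrow(counts)
  grid <- config$grid
  i <- 0:config$n_H
  log_PH <- outer(grid, i, function(j, k) stats::dbinom(k, config$n_H, j,
                                                        log = TRUE))
  M_cache <- new.env(parent = emptyenv())
  get_M <- function(n_D) {
    key <- as.character(n_D)
    if (is.null(M_cache[[key]]))
      M_cache[[key]] <- outer(0:n_D, i / config$n_H,
                              function(s, q) stats::dbinom(s, n_D, q))
    M_cache[[key]]
  }
  p_hat <- numeric(ns); s_lo <- integer(ns); s_hi <- integer(ns)
  for (k in seq_len(ns)) {
    l <- counts$l[k]; n_L <- counts$n_L[k]
    d <- counts$d[k]; n_D <- counts$n_D[k]
    if (n_L < 1 || n_D < 1) { p_hat[k] <- NA; s_lo[k] <- s_hi[k] <- NA; next }
    p_hat[k] <- if (is.null(p_anc)) {
      surface_argmax(log_surface(l, n_L, d, n_D, config, log_PH), config)
    } else p_anc[k]
    P <- as.vector(get_M(n_D) %*% stats::dbinom(i, config$n_H, p_hat[k]))
    ci <- central_interval(P, config$mass, config$interval_type)
    s_lo[k] <- ci[1]; s_hi[k] <- ci[2]
  }
  cls <- ifelse(is.na(s_lo), NA_character_,
                ifelse(counts$d < s_lo, "below",
                       ifelse(counts$d > s_hi, "above", "inside")))
  data.frame(site_id = counts$site_id, l = counts$l, n_L = counts$n_L,
             d = counts$d, n_D = counts$n_D, p_anc_hat = p_hat,
             s_lo = s_lo, s_hi = s_hi, class = cls, row.names = NULL)
}

## log(sum(exp(x))) guarding against all -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Joint probability of the observed LR and DH allele counts under neutrality
#'
#' The probability of observing LR count `l` and DH count `d` under the
#' three-stage neutral sampling model, integrating the unknown ancestral
#' frequency over a Beta(alpha, beta) prior (default the Jeffreys prior
#' Beta(1/2, 1/2)):
#' \deqn{P = \binom{n_L}{l}\binom{n_D}{d}\sum_{i=0}^{n_H}\binom{n_H}{i}
#'   \frac{B(k+\alpha, n-k+\beta)}{B(\alpha, \beta)}
#'   (i/n_H)^d (1-i/n_H)^{n_D-d}}
#' with k = i + l and n = n_L + n_H. Computed in log space with log-gamma;
#' `0^0 = 1` at the pool-count boundaries. Low P marks sites whose joint
#' counts are unlikely under drift alone.
#'
#' @param l,n_L,d,n_D Site counts (vectorized over sites).
#' @param config A [model_config()].
#' @return Data frame `P neg_log10_P` with one row per site.
#' @export
joint_probability <- function(l, n_L, d, n_D, config = model_config()) {
  stopifnot(length(n_L) %in% c(1, length(l)), all(l >= 0), all(d >= 0))
  ns <- max(length(l), length(d))
  l <- rep_len(l, ns); n_L <- rep_len(n_L, ns)
  d <- rep_len(d, ns); n_D <- rep_len(n_D, ns)
  nH <- config$n_H
  a <- config$prior_alpha; b <- config$prior_beta
  i <- 0:nH
  q <- i / nH
  lchoose_i <- lchoose(nH, i)
  ## k log(x) with the 0 * log(0) = 0 convention
  xlog <- function(k, x) {
    out <- k * log(x)
    out[k == 0] <- 0
    out
  }
  logP <- vapply(seq_len(ns), function(s) {
    k <- i + l[s]
    n <- n_L[s] + nH
    terms <- lchoose_i + lbeta(k + a, n - k + b) - lbeta(a, b) +
      xlog(d[s], q) + xlog(n_D[s] - d[s], 1 - q)
    lchoose(n_L[s], l[s]) + lchoose(n_D[s], d[s]) + logsumexp(terms)
  }, numeric(1))
  data.frame(P = exp(logP), neg_log10_P = -logP / log(10))
}

#' Flag joint-probability outliers within an accession
#'
#' The threshold is the empirical nearest-rank (1 - fraction) quantile of
#' -log10(P) within the accession; a site is flagged iff strictly above it,
#' so ties never inflate the flagged fraction beyond `fraction`.
#'
#' @param neg_log10_P Vector of -log10 joint probabilities.
#' @param fraction Target outlier fraction (default 0.05).
#' @return Logical vector of flags, with the threshold as attribute
#'   `threshold`.
#' @export
flag_joint_outliers <- function(neg_log10_P, fraction = 0.05) {
  n <- length(neg_log10_P)
  if (n < 20) stop("at least 20 sites are required to flag outliers")
  sorted <- sort(neg_log10_P)
  thr <- sorted[ceiling((1 - fraction) * n)]
  structure(neg_log10_P > thr, threshold = thr)
}

#' Outlier sharing across accessions
#'
#' @param sets Named list of character vectors (outlier site ids per
#'   accession).
#' @return Data frame `sharing_level count`: how many sites are outliers in
#'   exactly 1, 2, ... accessions; counts sum to the size of the union.
#' @export
outlier_overlap <- function(sets) {
  A <- length(sets)
  all_ids <- unique(unlist(sets))
  level <- rowSums(vapply(sets, function(s) all_ids %in% s,
                          logical(length(all_ids))))
  data.frame(sharing_level = seq_len(A),
             count = vapply(seq_len(A), function(k) sum(level == k),
                            integer(1)))
}

#' Fate of outlier alleles in the DH population
#'
#' For outlier sites segregating in the LR (0 < l < n_L): `lost` if the
#' alternative allele is absent from the DH sample, `fixed` if it is the
#' only allele, else `segregating`. Non-outliers and sites not segregating
#' in LR get `NA`.
#'
#' @param counts Data frame from [site_counts()].
#' @param is_outlier Logical vector aligned to `counts`.
#' @return Character vector of fates.
#' @export
outlier_fate <- function(counts, is_outlier) {
  fate <- rep(NA_character_, nrow(counts))
  seg_lr <- counts$l > 0 & counts$l < counts$n_L
  idx <- is_outlier & seg_lr
  fate[idx & counts$d == 0] <- "lost"
  fate[idx & counts$d == counts$n_D] <- "fixed"
  fate[idx & counts$d > 0 & counts$d < counts$n_D] <- "segregating"
  fate
}
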