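# LD pruning, matched sampling, heterozygosity enrichment, GERP load

test_that("r2 is the squared dosage correlation, sign-invariant", {
  a <- c(0, 1, 2, 1, 0, 2)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, 2 - a), 1)
  expect_true(is.na(ld_r2(a, rep(1, 6))))
  set.seed(11)
  for (r in 1:10) {
    x <- sample(0:2, 20, TRUE); y <- sample(0:2, 20, TRUE)
    if (var(x) == 0 || var(y) == 0) next
    oracle <- (cov(x, y) / sqrt(var(x) * var(y)))^2
    expect_equal(ld_r2(x, y), oracle, tolerance = 1e-12)
  }
  # pairwise-complete behaviour
  x <- c(0, 1, 2, NA); y <- c(0, 1, 2, 2)
  expect_equal(ld_r2(x, y), 1)
})

test_that("LD pruning leaves no surviving pair above the threshold", {
  set.seed(23)
  base <- matrix(sample(0:2, 20 * 30, TRUE), 20, 30)
  # plant a duplicate pair: SNPs 5 and 6 identical
  base[, 6] <- base[, 5]
  gm <- make_gm(base)
  kept <- prune_ld(gm, gm$sites$id, window_snps = 10, step = 3)
  expect_false(all(c("s005", "s006") %in% kept))
  expect_true(any(c("s005", "s006") %in% kept))
  # post-condition audit: exhaustive pair check inside windows
  idx <- match(kept, gm$sites$id)
  for (st in seq(1, length(idx), by = 3)) {
    win <- idx[st:min(st + 9, length(idx))]
    if (length(win) < 2) next
    prs <- combn(win, 2)
    r2s <- apply(prs, 2, function(p) ld_r2(gm$dosage[, p[1]],
                                           gm$dosage[, p[2]]))
    expect_true(all(is.na(r2s) | r2s <= 0.2 + 1e-12))
  }
  # independent SNPs with low r2 survive untouched
  set.seed(24)
  ind <- matrix(rbinom(500 * 10, 2, 0.5), 500, 10)
  gmi <- make_gm(ind)
  prs <- combn(10, 2)
  if (all(apply(prs, 2, function(p) ld_r2(ind[, p[1]], ind[, p[2]])) <= 0.2))
    expect_equal(prune_ld(gmi, gmi$sites$id), gmi$sites$id)
})

test_that("frequency matching draws per-bin equal counts and logs deficits", {
  out_f <- setNames(c(0.42, 0.45, 0.48), paste0("o", 1:3))
  pool_f <- setNames(c(0.41, 0.44, 0.46, 0.49, 0.91), paste0("p", 1:5))
  fm <- frequency_match_sample(out_f, pool_f, seed = 2)
  expect_equal(length(fm$controls), 3)
  expect_true(all(fm$controls %in% paste0("p", 1:4)))  # same bin [0.4, 0.5)
  expect_equal(fm$deficit, 0)
  # deficit: only one pool SNP in the outlier bin
  expect_warning(fm2 <- frequency_match_sample(out_f,
                                               setNames(0.43, "p1"), seed = 2),
                 "deficit")
  expect_equal(fm2$deficit, 2)
  # determinism under a fixed seed
  expect_identical(frequency_match_sample(out_f, pool_f, seed = 5)$controls,
                   frequency_match_sample(out_f, pool_f, seed = 5)$controls)
})

test_that("bootstrap het comparison is near-null for identical groups and reproducible", {
  set.seed(31)
  g <- runif(60, 0.2, 0.6)
  he <- heterozygosity_enrichment(g, g, seed = 3)
  expect_gt(he$p_value, 0.5)
  expect_equal(he$diff, 0)
  r1 <- heterozygosity_enrichment(g, g + 0.1, seed = 7)
  r2 <- heterozygosity_enrichment(g, g + 0.1, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_lt(r1$p_value, 0.05)
  expect_error(heterozygosity_enrichment(1, g), "two")
})

test_that("recombination rates recover map slopes and split SNPs evenly", {
  sites <- data.frame(chrom = "1",
                      pos = as.integer(seq(1e4, 4e6 - 1e4, by = 1e4)),
                      ref = "A", alt = "T",
                      id = sprintf("s%03d", 1:399))
  lin <- data.frame(chrom = "1", pos = c(0L, 4000000L), cM = c(0, 4))
  class(lin) <- c("genetic_map", "data.frame")
  rr <- recombination_rates(lin, sites)
  expect_equal(unname(rr$windows$rate), rep(1, 4))
  expect_true(all(rr$snp_quantile == 1))
  # piecewise map: two distinct rates, and quantiles partition near-evenly
  pw <- data.frame(chrom = "1", pos = c(0L, 2000000L, 4000000L),
                   cM = c(0, 1, 5))
  class(pw) <- c("genetic_map", "data.frame")
  rr2 <- recombination_rates(pw, sites, n_quantiles = 2)
  expect_equal(sort(unique(rr2$windows$rate)), c(0.5, 2))
  tb <- table(rr2$snp_quantile)
  expect_lt(max(tb) - min(tb), 0.2 * length(sites$id))
})

test_that("stratified controls match outliers cell by cell when pools suffice", {
  q <- setNames(rep(1:2, each = 50), sprintf("x%03d", 1:100))
  freq <- setNames(rep(c(0.15, 0.55), 50), sprintf("x%03d", 1:100))
  out_ids <- sprintf("x%03d", 1:10)
  pool_ids <- sprintf("x%03d", 11:100)
  sc <- stratified_control_sample(freq[out_ids], freq[pool_ids], q, seed = 9)
  expect_equal(sc$deficit, 0)
  expect_equal(length(sc$controls), 10)
  bin <- function(f) floor(f / 0.1) + 1
  marg_out <- table(bin(freq[out_ids]), q[out_ids])
  marg_ctl <- table(bin(freq[sc$controls]), q[sc$controls])
  expect_equal(as.vector(marg_ctl), as.vector(marg_out))
  expect_identical(
    stratified_control_sample(freq[out_ids], freq[pool_ids], q, seed = 4)$controls,
    stratified_control_sample(freq[out_ids], freq[pool_ids], q, seed = 4)$controls)
})

test_that("GERP window load weights genotypes per model", {
  lin <- data.frame(chrom = "1", pos = c(0L, 10000000L), cM = c(0, 10))
  class(lin) <- c("genetic_map", "data.frame")
  # one individual hom-alt, one het, one hom-ref at a single scored site
  gm <- make_gm(rbind(c(2L, 2L), c(1L, 2L), c(0L, 2L)))
  gerp <- data.frame(chrom = "1", pos = c(1000L, 2000L), score = c(2, -1))
  add <- gerp_window_load("s001", gm, gerp, lin, "additive")
  rec <- gerp_window_load("s001", gm, gerp, lin, "recessive")
  # only the positive-score site contributes
  expect_equal(add$n_sites, 1L)
  expect_equal(unname(add$per_individual), c(2, 1, 0))
  expect_equal(unname(rec$per_individual), c(2, 0, 0))
  # hand-summed oracle over several sites, additive >= recessive
  set.seed(41)
  d5 <- matrix(sample(c(0:2, NA), 4 * 5, TRUE), 4, 5)
  gm5 <- make_gm(d5)
  g5 <- data.frame(chrom = "1", pos = gm5$sites$pos,
                   score = c(1.5, -0.5, 0.7, 2.2, 0.1))
  a5 <- gerp_window_load("s003", gm5, g5, lin, "additive")
  r5 <- gerp_window_load("s003", gm5, g5, lin, "recessive")
  pos <- g5$score > 0
  oracle <- sapply(1:4, function(i) {
    g <- d5[i, pos] / 2; g[is.na(g)] <- 0
    sum(g5$score[pos] * g)
  })
  expect_equal(unname(a5$per_individual), oracle)
  expect_true(all(a5$per_individual >= r5$per_individual - 1e-12))
  # no positive-score site in window -> zero load, flagged
  far <- data.frame(chrom = "1", pos = 1000L, score = -3)
  z <- gerp_window_load("s001", gm, far, lin, "additive")
  expect_true(z$empty)
  expect_equal(z$mean_load, 0)
})

test_that("load comparison detects a built-in group shift", {
  set.seed(51)
  a <- rnorm(100, 5); b <- a + 2
  cmp <- compare_load(b, a)
  expect_lt(cmp$p_value, 1e-6)
  expect_gt(cmp$mean_outliers, cmp$mean_controls)
  same <- compare_load(a, a)
  expect_equal(same$p_value, 1)
  expect_true(is.na(compare_load(c(1, 1), c(1, 1))$p_value))
})
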