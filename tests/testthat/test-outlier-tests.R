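# The aSFS and joint-probability outlier machinery

test_that("the likelihood surface equals naive products of binomial masses", {
  cfg <- model_config(n_H = 20)
  set.seed(15)
  for (r in 1:10) {
    n_L <- sample(4:40, 1); n_D <- sample(4:40, 1)
    l <- sample(0:n_L, 1); d <- sample(0:n_D, 1)
    surf <- likelihood_surface(l, n_L, d, n_D, cfg)
    # naive scalar oracle, no log space
    naive <- outer(seq_along(cfg$grid), 0:20, Vectorize(function(jj, i) {
      choose(n_D, d) * (i / 20)^d * (1 - i / 20)^(n_D - d) *
        choose(20, i) * cfg$grid[jj]^i * (1 - cfg$grid[jj])^(20 - i) *
        choose(n_L, l) * cfg$grid[jj]^l * (1 - cfg$grid[jj])^(n_L - l)
    }))
    expect_equal(unname(surf), naive, tolerance = 1e-12)
  }
})

test_that("grid ML matches an exhaustive argmax oracle and honors tie-breaks", {
  cfg <- model_config(n_H = 30)
  # monotone boundary cases
  s0 <- likelihood_surface(0, 20, 0, 30, cfg)
  expect_equal(ml_ancestral_frequency(s0, cfg), 0.01)
  s1 <- likelihood_surface(20, 20, 30, 30, cfg)
  expect_equal(ml_ancestral_frequency(s1, cfg), 0.99)
  # symmetric counts: 0.5 is off-grid, tie broken to the lower neighbour
  cfg100 <- model_config(n_H = 100)
  ss <- likelihood_surface(23, 46, 58, 116, cfg100)
  expect_equal(ml_ancestral_frequency(ss, cfg100), cfg100$grid[50])
  expect_lt(cfg100$grid[50], 0.5)
  # exhaustive argmax over the grid on random sites
  set.seed(25)
  for (r in 1:50) {
    n_L <- sample(4:60, 1); n_D <- sample(4:60, 1)
    l <- sample(0:n_L, 1); d <- sample(0:n_D, 1)
    surf <- likelihood_surface(l, n_L, d, n_D, cfg)
    oracle <- cfg$grid[which.max(apply(surf, 1, max))]
    expect_equal(ml_ancestral_frequency(surf, cfg), oracle)
  }
})

test_that("the DH count distribution is a normalized binomial mixture", {
  # hand enumeration: n_H = 1, n_D = 2, p = 0.5 -> mass 1/2 at 0 and at 2
  expect_equal(dh_count_distribution(0.5, 2, model_config(n_H = 1)),
               c(0.5, 0, 0.5))
  # normalization across random configurations
  set.seed(35)
  for (r in 1:50) {
    cfg <- model_config(n_H = sample(1:200, 1))
    P <- dh_count_distribution(runif(1, 0.01, 0.99), sample(1:100, 1), cfg)
    expect_lt(abs(sum(P) - 1), 1e-9)
  }
  # large-pool limit: mixture approaches Binomial(n_D, p)
  P <- dh_count_distribution(0.3, 10, model_config(n_H = 1e4))
  expect_equal(P, dbinom(0:10, 10, 0.3), tolerance = 1e-3)
})

test_that("central intervals carry at least the target mass", {
  expect_equal(central_interval(c(0, 0, 0, 1, 0)), c(3, 3))
  expect_equal(central_interval(rep(0.05, 20)), c(0, 19))
  set.seed(45)
  for (r in 1:50) {
    P <- dh_count_distribution(runif(1, 0.05, 0.95), sample(5:80, 1),
                               model_config(n_H = 50))
    ci <- central_interval(P)
    expect_gte(sum(P[(ci[1]:ci[2]) + 1]), 0.95)
    hpd <- central_interval(P, type = "hpd")
    expect_gte(sum(P[(hpd[1]:hpd[2]) + 1]), 0.95 - 1e-12)
  }
})

test_that("aSFS classification flags extreme losses and covers neutral sites", {
  cfg <- model_config()
  # extreme loss: common in LR, absent in DH
  ext <- asfs_classify(data.frame(site_id = "x", l = 23, n_L = 46,
                                  d = 0, n_D = 116), cfg)
  expect_equal(ext$class, "below")
  mirror <- asfs_classify(data.frame(site_id = "x", l = 23, n_L = 46,
                                     d = 116, n_D = 116), cfg)
  expect_equal(mirror$class, "above")
  # neutral simulation, intervals at the TRUE ancestral frequency:
  # coverage at least the interval mass
  sim <- simulate_accession(sim_config(n_sites = 4000, seed = 55))
  cnt <- site_counts(sim$lr, sim$dh)
  res <- asfs_classify(cnt, cfg, p_anc = sim$truth$p_anc)
  expect_gte(mean(res$class == "inside"), 0.95)
})

test_that("ancestral frequency recovery improves with sample size", {
  cfg <- model_config()
  mae <- sapply(c(20, 200), function(n) {
    sim <- simulate_accession(sim_config(n_sites = 500,
                                         n_lr_individuals = n / 2,
                                         n_dh_lines = n / 2, seed = 65))
    cnt <- site_counts(sim$lr, sim$dh)
    est <- asfs_classify(cnt, cfg)$p_anc_hat
    mean(abs(est - sim$truth$p_anc))
  })
  expect_lt(mae[2], mae[1])
})

test_that("joint probabilities match hand-derived values and integrate to one", {
  cfg1 <- model_config(n_H = 1)
  jp <- joint_probability(c(0, 0), 1, c(0, 1), 1, cfg1)
  # hand evaluation of the two-term sum with B(1/2,5/2)/B(1/2,1/2) = 3/8
  # and B(3/2,3/2)/B(1/2,1/2) = 1/8
  expect_equal(jp$P, c(0.375, 0.125), tolerance = 1e-12)
  # numeric-integration oracle: integrate the three-binomial product
  # against the Beta(1/2, 1/2) prior
  oracle <- function(l, n_L, d, n_D, n_H) {
    integrand <- function(x) {
      dbeta(x, 0.5, 0.5) *
        vapply(x, function(p) {
          sum(vapply(0:n_H, function(i) {
            dbinom(i, n_H, p) * dbinom(d, n_D, i / n_H)
          }, numeric(1))) * dbinom(l, n_L, p)
        }, numeric(1))
    }
    integrate(integrand, 0, 1, rel.tol = 1e-10)$value
  }
  expect_equal(joint_probability(0, 1, 0, 1, cfg1)$P, oracle(0, 1, 0, 1, 1),
               tolerance = 1e-8)
  cfg5 <- model_config(n_H = 5)
  expect_equal(joint_probability(2, 4, 5, 6, cfg5)$P, oracle(2, 4, 5, 6, 5),
               tolerance = 1e-8)
  # exhaustive total mass over all 35 (l, d) cells
  g <- expand.grid(l = 0:4, d = 0:6)
  expect_equal(sum(joint_probability(g$l, 4, g$d, 6, cfg5)$P), 1,
               tolerance = 1e-8)
  # label symmetry under the symmetric prior
  Pm <- matrix(joint_probability(g$l, 4, g$d, 6, cfg5)$P, 5, 7)
  expect_equal(Pm, Pm[5:1, 7:1])
})

test_that("log-space joint probability agrees with a naive implementation", {
  naive_jp <- function(l, n_L, d, n_D, n_H) {
    k <- (0:n_H) + l; n <- n_L + n_H
    choose(n_L, l) * choose(n_D, d) *
      sum(choose(n_H, 0:n_H) * beta(k + 0.5, n - k + 0.5) / beta(0.5, 0.5) *
            ((0:n_H) / n_H)^d * (1 - (0:n_H) / n_H)^(n_D - d))  # 0^0 = 1 in R
  }
  cfg <- model_config(n_H = 40)
  set.seed(75)
  for (r in 1:20) {
    n_L <- sample(4:40, 1); n_D <- sample(4:40, 1)
    l <- sample(0:n_L, 1); d <- sample(0:n_D, 1)
    expect_equal(joint_probability(l, n_L, d, n_D, cfg)$P,
                 naive_jp(l, n_L, d, n_D, 40), tolerance = 1e-10)
  }
})

test_that("top-5% flagging never exceeds its fraction and respects ties", {
  x <- 1:100
  f <- flag_joint_outliers(x)
  expect_equal(sum(f), 5)
  expect_true(all(which(f) > 95))
  expect_equal(sum(flag_joint_outliers(rep(3.5, 100))), 0)
  set.seed(85)
  y <- rexp(10000)
  expect_lte(mean(flag_joint_outliers(y)), 0.05)
  expect_error(flag_joint_outliers(1:10), "20")
})

test_that("outlier overlap partitions the union by sharing level", {
  disj <- list(a = c("s1", "s2"), b = c("s3"), c = c("s4", "s5"))
  od <- outlier_overlap(disj)
  expect_equal(od$count, c(5L, 0L, 0L))
  ident <- list(a = c("s1", "s2"), b = c("s1", "s2"), c = c("s1", "s2"),
                d = c("s1", "s2"), e = c("s1", "s2"))
  expect_equal(outlier_overlap(ident)$count, c(0L, 0L, 0L, 0L, 2L))
  set.seed(95)
  sets <- lapply(1:4, function(i) sample(sprintf("s%02d", 1:30), 12))
  names(sets) <- letters[1:4]
  ov <- outlier_overlap(sets)
  union_ids <- unique(unlist(sets))
  oracle <- table(factor(sapply(union_ids, function(id)
    sum(sapply(sets, function(s) id %in% s))), levels = 1:4))
  expect_equal(ov$count, as.integer(oracle))
  expect_equal(sum(ov$count), length(union_ids))
})

test_that("outlier fates classify loss, fixation and segregation", {
  cnt <- data.frame(site_id = c("a", "b", "c", "d", "e"),
                    l = c(5, 5, 5, 0, 5), n_L = 40,
                    d = c(0, 60, 3, 10, 30), n_D = 60)
  fate <- outlier_fate(cnt, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(fate, c("lost", "fixed", "segregating", NA, NA))
})

test_that("selection is detected above the neutral false-positive rate", {
  cfg <- model_config()
  simc <- sim_config(n_sites = 4000, sfs_par = c(0.3, 0.3), s = 0.5,
                     selected_fraction = 0.5, seed = 105)
  sim <- simulate_accession(simc)
  cnt <- site_counts(sim$lr, sim$dh)
  sel <- sim$truth$s > 0
  asfs <- asfs_classify(cnt, cfg)
  a_flag <- asfs$class != "inside"
  jp <- joint_probability(cnt$l, cnt$n_L, cnt$d, cnt$n_D, cfg)
  j_flag <- as.logical(flag_joint_outliers(jp$neg_log10_P))
  for (flag in list(a_flag, j_flag)) {
    pt <- prop.test(c(sum(flag[sel]), sum(flag[!sel])),
                    c(sum(sel), sum(!sel)), alternative = "greater")
    expect_lt(pt$p.value, 0.01)
  }
})
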