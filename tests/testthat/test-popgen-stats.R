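test_that("Hudson per-site components match direct evaluation", {
  # frozen worked example: p1 = 0.2, p2 = 0.8, n1 = n2 = 50
  comp <- hudson_fst_site(0.2, 0.8, 50, 50)
  expect_equal(comp$num, 0.36 - 2 * (0.16 / 49), tolerance = 1e-15)
  expect_equal(comp$num, 0.3534693877551020, tolerance = 1e-12)
  expect_equal(comp$den, 0.68)
  expect_equal(comp$num / comp$den, 0.5198079231692677, tolerance = 1e-12)
  # equal frequencies: F_ST -> 0 for large n
  c2 <- hudson_fst_site(0.4, 0.4, 1e6, 1e6)
  expect_lt(abs(c2$num / c2$den), 1e-5)
  # fixed difference: numerator = denominator = 1
  c3 <- hudson_fst_site(1, 0, 50, 50)
  expect_equal(c3$num, 1)
  expect_equal(c3$den, 1)
  expect_error(hudson_fst_site(0.5, 0.5, 1, 50), "exceed")
  expect_error(hudson_fst_site(1.2, 0.5, 50, 50), "frequencies")
})

test_that("combining F_ST is a ratio of averages, not an average of ratios", {
  set.seed(10)
  p1 <- runif(200); p2 <- runif(200)
  comp <- hudson_fst_site(p1, p2, 40, 60)
  expect_equal(combine_fst(comp$num, comp$den),
               sum(comp$num) / sum(comp$den))
  # duplicating the site set leaves the combined value unchanged
  expect_equal(combine_fst(rep(comp$num, 2), rep(comp$den, 2)),
               combine_fst(comp$num, comp$den))
  # single site reduces to the site ratio
  expect_equal(combine_fst(comp$num[1], comp$den[1]), comp$num[1] / comp$den[1])
  # unequal denominators: combined differs from the mean of ratios
  num <- c(0.2 * 0.5, 0.8 * 2); den <- c(0.5, 2)
  expect_equal(combine_fst(num, den), (0.1 + 1.6) / 2.5)
  expect_true(abs(combine_fst(num, den) - 0.5) > 0.1)
  expect_warning(v <- combine_fst(0, 0), "monomorphic")
  expect_true(is.na(v))
})

test_that("identical population snapshots give F_ST of exactly 0", {
  comp <- hudson_fst_site(c(0.1, 0.5), c(0.1, 0.5), c(30, 30), c(30, 30))
  # with equal sample sizes and equal frequencies the numerator reduces to
  # minus twice the sampling correction; combined over matched sites the
  # expectation is 0 -- for the exact-equality case use n -> Inf
  compInf <- hudson_fst_site(c(0.1, 0.5), c(0.1, 0.5), c(1e9, 1e9), c(1e9, 1e9))
  expect_equal(combine_fst(compInf$num, compInf$den), 0, tolerance = 1e-7)
  expect_lt(combine_fst(comp$num, comp$den), 0) # finite-sample correction
})

test_that("simulation F_ST matches an independent per-site oracle", {
  sim <- quick_sim(51, N = 40, L = 1e5, neutral = FALSE, mu = 1e-6,
                   track_neutral = TRUE, snapshot_prepulse = TRUE)
  res <- fst_between(sim, "snapshot")
  vc <- introgsim:::variant_counts(sim, "snapshot")
  n1 <- attr(vc, "n_hap_recipient"); n2 <- attr(vc, "n_hap_donor")
  p1 <- vc$count_recipient / n1; p2 <- vc$count_donor / n2
  keep <- !((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_equal(res$fst, sum(num[keep]) / sum(den[keep]), tolerance = 1e-12)
  expect_true(res$fst <= 1)
  # markers are excluded from differentiation
  sim_m <- quick_sim(51, N = 40, L = 1e5, neutral = FALSE, mu = 1e-6,
                     track_neutral = TRUE, snapshot_prepulse = TRUE,
                     marker_spacing = 500)
  res_m <- fst_between(sim_m, "snapshot")
  expect_false(any(res_m$per_site$id %in% sim_m$marker_ids))
})

test_that("site F_ST component identity holds on random frequencies", {
  set.seed(4)
  p1 <- runif(1e4); p2 <- runif(1e4)
  n1 <- sample(10:100, 1e4, replace = TRUE); n2 <- sample(10:100, 1e4, replace = TRUE)
  comp <- hudson_fst_site(p1, p2, n1, n2)
  brute_num <- mapply(function(a, b, x, y)
    (a - b)^2 - a * (1 - a) / (x - 1) - b * (1 - b) / (y - 1), p1, p2, n1, n2)
  brute_den <- mapply(function(a, b) a * (1 - b) + b * (1 - a), p1, p2)
  expect_equal(comp$num, brute_num, tolerance = 1e-12)
  expect_equal(comp$den, brute_den, tolerance = 1e-12)
})

test_that("the SFS bins sites by derived count with tail pooling", {
  expect_identical(sum(sfs(integer(0))), 0L)
  s <- sfs(3L, fold_threshold = 25)
  expect_identical(unname(s[3]), 1L)
  expect_identical(sum(s), 1L)
  # random toy genotype matrix against a counting oracle
  set.seed(6)
  k <- 40
  geno <- matrix(rbinom(k * 200, 1, 0.2), nrow = k)
  counts <- colSums(geno)
  counts <- counts[counts > 0 & counts < k]
  s <- sfs(counts, fold_threshold = 10)
  oracle <- c(vapply(1:9, function(i) sum(counts == i), integer(1)),
              sum(counts >= 10))
  expect_identical(unname(s), oracle)
  expect_identical(sum(s), length(counts))
  expect_identical(names(s)[10], ">=10")
})

test_that("private and shared variants partition the segregating set", {
  sim <- quick_sim(53, N = 40, L = 1e5, neutral = FALSE, mu = 1e-6,
                   track_neutral = TRUE, snapshot_prepulse = TRUE)
  ps <- private_shared(sim, "snapshot")
  expect_identical(unname(ps[["private_donor"]] + ps[["private_recipient"]] +
                          ps[["shared"]]), unname(ps[["total"]]))
  # set-operation oracle
  vc <- introgsim:::variant_counts(sim, "snapshot")
  expect_identical(unname(ps[["private_donor"]]),
                   sum(vc$count_recipient == 0))
  expect_identical(unname(ps[["shared"]]),
                   sum(vc$count_recipient > 0 & vc$count_donor > 0))
})

test_that("tie-randomized Spearman matches midrank on average", {
  x <- 1:20
  expect_equal(spearman_random_ties(x, x)$rho, 1)
  expect_equal(spearman_random_ties(x, -x)$rho, -1)
  expect_equal(spearman_random_ties(x, x)$p_value, 0)
  # tied data: mean rho over randomization seeds approximates midrank rho
  set.seed(12)
  xt <- rep(1:5, each = 8)
  yt <- xt + rnorm(40, sd = 2)
  rhos <- replicate(400, spearman_random_ties(xt, yt)$rho)
  midrank <- cor(xt, yt, method = "spearman")
  expect_lt(abs(mean(rhos) - midrank), 0.02)
  expect_warning(res <- spearman_random_ties(rep(1, 5), c(1, 2, 3, 4, 5) * 0),
                 "constant")
  expect_true(is.na(res$rho))
})

test_that("load summaries expose the fitness ratio and count means", {
  sim <- quick_sim(57, N = 40, L = 1e5, neutral = FALSE, mu = 5e-7,
                   dominance = dominance_model("recessive"),
                   track_neutral = FALSE)
  ls_ <- load_summary(sim)
  expect_identical(nrow(ls_$by_pop), 2L)
  wr <- ls_$by_pop$mean_w[ls_$by_pop$pop == "recipient"]
  wd <- ls_$by_pop$mean_w[ls_$by_pop$pop == "donor"]
  expect_equal(ls_$w_ratio, wr / wd)
  expect_true(all(ls_$by_pop$mean_w > 0 & ls_$by_pop$mean_w <= 1))
  # pre-split there is one population and no ratio
  ls0 <- load_summary(sim, gen = 0)
  expect_true(is.na(ls0$w_ratio))
  expect_error(load_summary(sim, gen = 123456), "not recorded")
})

test_that("globally fixed variants cannot influence relative fitness", {
  # adding a variant homozygous in every individual multiplies every w by
  # the same factor, leaving the ratio of population means unchanged
  add <- dominance_model("additive")
  w_pop <- function(genos) vapply(genos, function(g)
    individual_fitness(g$s, g$h, g$copies, add), numeric(1))
  popA <- list(list(s = -0.1, h = 0.5, copies = 1),
               list(s = -0.2, h = 0.5, copies = 2))
  popB <- list(list(s = -0.05, h = 0.5, copies = 1),
               list(s = numeric(0), h = numeric(0), copies = integer(0)))
  r0 <- mean(w_pop(popA)) / mean(w_pop(popB))
  with_fixed <- function(pop) lapply(pop, function(g)
    list(s = c(g$s, -0.3), h = c(g$h, 0.5), copies = c(g$copies, 2)))
  r1 <- mean(w_pop(with_fixed(popA))) / mean(w_pop(with_fixed(popB)))
  expect_equal(r1, r0, tolerance = 1e-12)
})
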