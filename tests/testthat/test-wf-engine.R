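test_that("rescaling transforms parameters the standard way", {
  st <- generate_random_structure(50000, seed = 1)
  cfg <- sim_config(st, demography = model_preset(0, N_A = 10000))
  expect_identical(rescale(cfg), cfg) # c = 1 is the identity

  cfg5 <- sim_config(st, demography = model_preset(0, N_A = 10000),
                     scaling = scaling_config(5),
                     dominance = dominance_human_hs())
  sc <- rescale(cfg5)
  expect_identical(sc$demography$N_A, 2000)
  expect_identical(sc$demography$burn_in, 20000)
  expect_equal(sc$dfe$mean_s, dfe_human()$mean_s * 5)
  expect_equal(sc$mu, 1.5e-8 * 5)
  expect_equal(sc$structure$length, cfg5$structure$length) # L unchanged
  # recombination transform; approximately r*c for small r
  expect_equal(sc$structure$recomb_map$rate, 0.5 * (1 - (1 - 2e-8)^5))
  expect_equal(sc$structure$recomb_map$rate, 5e-8, tolerance = 1e-6)
  expect_equal(rescale_rate(0.01, 5), 0.0480396016, tolerance = 1e-10)
  # h(s) still evaluated on the unscaled coefficient
  expect_equal(sc$dominance$hs_slope, 7071.07 / 5)
  expect_error(rescale(sc), "already")

  tiny <- sim_config(st, demography = model_preset(0, N_A = 7),
                     scaling = scaling_config(5))
  expect_error(rescale(tiny), "below 2")
})

test_that("model presets build the documented size schedules", {
  for (m in 0:4) {
    dm <- model_preset(m, N_A = 1000)
    sch <- introgsim:::build_schedule(dm)
    expect_identical(sch$split_gen, 10000L)
    expect_identical(sch$pulse_gen, 12000L)
    expect_identical(sch$T_end, 13000L)
    expect_true(all(sch$sizes[1:10000, 2] == 0)) # no donor before the split
    expect_true(all(sch$sizes[, 1] >= 1))
  }
  s0 <- introgsim:::build_schedule(model_preset(0, N_A = 1000))$sizes
  expect_true(all(s0[, 1] == 1000)) # constant sizes every generation
  s4 <- introgsim:::build_schedule(model_preset(4, N_A = 1000))$sizes
  expect_identical(s4[10001 + 1500, 1], 100L)  # reduced after the split
  expect_identical(s4[12001, 1], 1000L)        # restored at the pulse
  expect_identical(s4[12001, 2], 1000L)        # donor stays at N_A
  s2 <- introgsim:::build_schedule(model_preset(2, N_A = 1000))$sizes
  expect_identical(s2[12001, 2], 100L)
  s1 <- introgsim:::build_schedule(model_preset(1, N_A = 1000))$sizes
  expect_identical(s1[10001 + 1950, 1], 100L)
  expect_identical(s1[10001 + 1800, 1], 1000L)
})

test_that("reference recombination keeps mutations and ancestry consistent", {
  h1 <- haplotype(1000, c(100L, 450L, 800L), rep("neutral", 3),
                  rep(0, 3), rep(0.5, 3),
                  tibble::tibble(start = 0L, end = 1000L, origin = "donor"))
  h2 <- haplotype(1000, c(120L, 500L), rep("neutral", 2), rep(0, 2),
                  rep(0.5, 2),
                  tibble::tibble(start = 0L, end = 1000L, origin = "recipient"))
  # no breakpoints: exact copy of the starting haplotype
  g <- recombine_gamete(h1, h2, integer(0), start_hap = 1)
  expect_identical(g$positions, h1$positions)
  expect_identical(g$segments$origin, "donor")
  # one breakpoint at 400: take h1 over [0,400), h2 over [400,1000)
  g <- recombine_gamete(h1, h2, 400L, start_hap = 1)
  expect_identical(g$positions, c(100L, 500L))
  expect_identical(g$segments$origin, c("donor", "recipient"))
  expect_identical(g$segments$end, c(400L, 1000L))
  # mutations always lie inside segments inherited from their haplotype
  set.seed(5)
  for (i in 1:20) {
    bp <- sort(sample(1:999, sample(0:4, 1)))
    g <- recombine_gamete(h1, h2, bp, start_hap = sample(1:2, 1))
    for (j in seq_along(g$positions)) {
      seg <- g$segments[g$segments$start <= g$positions[j] &
                        g$segments$end > g$positions[j], ]
      from_h1 <- g$positions[j] %in% h1$positions
      expect_identical(seg$origin, if (from_h1) "donor" else "recipient")
    }
  }
})

test_that("crossover counts follow the map length in Morgans", {
  set.seed(8)
  st <- generate_random_structure(5e5, recomb_rate = 1e-6) # 0.5 Morgans
  ks <- lengths(draw_crossovers(st, 4000))
  expect_lt(abs(mean(ks) - 0.5), 3 * sd(ks) / sqrt(4000))
  st0 <- generate_random_structure(5e5, seed = 1, recomb_rate = 0)
  expect_identical(lengths(draw_crossovers(st0, 10)), rep(0L, 10))
})

test_that("reference gamete mutation matches its sampling model", {
  st <- toy_structure()
  h <- haplotype(1000)
  expect_identical(mutate_gamete(h, st, mu = 0), h)
  set.seed(3)
  counts <- integer(400); ns <- 0L; syn <- 0L
  for (i in seq_len(400)) {
    g <- mutate_gamete(h, st, mu = 2e-3) # mean 2 per gamete
    counts[i] <- length(g$positions)
    ns <- ns + sum(g$classes == "nonsynonymous")
    syn <- syn + sum(g$classes == "synonymous")
  }
  expect_lt(abs(mean(counts) - 2), 3 * sd(counts) / sqrt(400))
  # exonic class odds 2.31 : 1
  expect_lt(abs(ns / syn - 2.31), 3 * 2.31 * sqrt(1 / ns + 1 / syn))
  # nonsynonymous mutations carry negative s, others zero
  g <- mutate_gamete(h, st, mu = 5e-3)
  expect_true(all(g$s[g$classes == "nonsynonymous"] < 0))
  expect_true(all(g$s[g$classes != "nonsynonymous"] == 0))
})

test_that("engine mutation targeting reproduces the exonic class odds", {
  # a neutral run keeps class assignment unbiased by selection
  sim <- quick_sim(21, N = 40, L = 2e5, neutral = TRUE, mu = 3e-5,
                   track_neutral = TRUE)
  tab <- table(sim$mutations$class)
  ns <- tab[["nonsynonymous"]]; syn <- tab[["synonymous"]]
  expect_gt(ns + syn, 500)
  expect_lt(abs(ns / syn - 2.31), 3 * 2.31 * sqrt(1 / ns + 1 / syn))
})

test_that("runs are reproducible from the seed", {
  a <- quick_sim(17, N = 40, L = 5e4, marker_spacing = 500)
  b <- quick_sim(17, N = 40, L = 5e4, marker_spacing = 500)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$final$segments, b$final$segments)
  expect_identical(a$final$haplotypes, b$final$haplotypes)
})

test_that("full selfing makes every offspring a single-parent product", {
  # with selfing probability 1 from the start, heterozygosity collapses:
  # homozygous deleterious sites approach the per-haplotype count
  set.seed(30)
  st <- generate_random_structure(2e5, recomb_rate = 1e-8)
  run_selfing <- function(p) {
    cfg <- sim_config(st, dominance = dominance_model("recessive"),
                      demography = model_preset(0, N_A = 50),
                      mating = mating_config(selfing_recipient = p,
                                             selfing_donor = p,
                                             selfing_ancestral = p),
                      mu = 5e-7, track_neutral = FALSE)
    run_simulation(cfg, seed = 31, keep_state = FALSE)
  }
  ts1 <- run_selfing(1)$timeseries
  ts0 <- run_selfing(0)$timeseries
  last1 <- ts1[ts1$gen == max(ts1$gen) & ts1$pop == "recipient", ]
  last0 <- ts0[ts0$gen == max(ts0$gen) & ts0$pop == "recipient", ]
  # fraction of carried deleterious sites that are homozygous
  f1 <- last1$hom_per_ind / last1$del_per_hap
  f0 <- last0$hom_per_ind / last0$del_per_hap
  expect_gt(f1, 0.9)
  expect_lt(f0, 0.6)
})

test_that("no globally fixed non-marker mutation survives pruning", {
  sim <- quick_sim(23, N = 30, L = 1e5, neutral = FALSE, mu = 1e-6,
                   track_neutral = TRUE, marker_spacing = 1000)
  st <- sim$final
  n_hap <- nrow(st$hap_info)
  counts <- table(unlist(st$haplotypes))
  full <- as.integer(names(counts)[counts == n_hap])
  cls <- sim$mutations$class[match(full, sim$mutations$id)]
  expect_true(all(cls == "marker"))
  # substitutions were logged with their fixation generation
  expect_true(all(sim$substitutions$gen_fixed >= 1))
})

test_that("recorded mean fitness matches a direct per-individual recomputation", {
  sim <- quick_sim(29, N = 30, L = 1e5, neutral = FALSE, mu = 5e-7,
                   dominance = dominance_human_hs(), track_neutral = FALSE)
  st <- sim$final
  mt <- sim$mutations
  sel_ids <- mt$id[mt$s < 0]
  w <- numeric(0)
  for (p in c("recipient", "donor")) {
    info <- st$hap_info[st$hap_info$pop == p, ]
    wp <- vapply(split(info$hap_id, info$ind), function(hid) {
      a <- intersect(st$haplotypes[[hid[1]]], sel_ids)
      b <- intersect(st$haplotypes[[hid[2]]], sel_ids)
      ids <- union(a, b)
      copies <- (ids %in% a) + (ids %in% b)
      idx <- match(ids, mt$id)
      individual_fitness(mt$s[idx], mt$h[idx], copies, dominance_human_hs())
    }, numeric(1))
    ts <- sim$timeseries
    rec <- ts[ts$gen == sim$final_gen & ts$pop == p, ]
    expect_equal(mean(wp), rec$mean_w, tolerance = 1e-4)
  }
})

test_that("X mode produces hemizygous males at a 1:1 sex ratio", {
  sim <- quick_sim(31, N = 40, L = 5e4, x_mode = TRUE)
  info <- sim$final$hap_info
  info_r <- info[info$pop == "recipient", ]
  per_ind <- table(info_r$ind)
  sexes <- info_r$sex[!duplicated(info_r$ind)]
  expect_identical(sum(sexes == "male"), sum(sexes == "female"))
  expect_true(all(per_ind[sexes == "male"] == 1))
  expect_true(all(per_ind[sexes == "female"] == 2))
})

test_that("equilibrium and zero-post-admixture schedules run", {
  st <- generate_random_structure(5e4, seed = 4)
  cfg <- sim_config(st, demography = equilibrium_model(30, 100), neutral = TRUE)
  sim <- run_simulation(cfg, seed = 1)
  expect_identical(sim$final_gen, 100L)
  expect_true(all(sim$timeseries$pop == "recipient"))
  expect_true(all(sim$timeseries$p_I == 0))

  cfg2 <- sim_config(st, demography = demographic_model(30, burn_in = 50,
                                                        t_s = 20,
                                                        post_admixture = 0),
                     neutral = TRUE)
  sim2 <- run_simulation(cfg2, seed = 2)
  expect_identical(sim2$final_gen, 70L)
  expect_identical(sim2$pulse_gen, 70L)
})
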