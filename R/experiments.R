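# Experiment drivers: replicate grids over demographic models,
# recombination rates and dominance modes; the split-time sweep; the
# partial-selfing grid; and the X-versus-autosome comparison.
#
# Study conditions follow the admixture-pulse design: burn-in 10 N_A,
# split-to-pulse time 2 N_A (unless swept), pulse fraction 5%, and N_A
# generations post-admixture. The default desk-scale profile runs the
# N_A = 10,000 model rescaled by c = 20 (so 500 diploids) on 500 kb of
# randomly generated genic structure; each replicate draws its own
# structure, as in the randomly-generated-structure design.

run_seed_for <- function(base, idx) {
  s <- as.numeric(base) + 7919 * idx
  as.integer(s %% 2147483647)
}

dominance_for <- function(dominance) {
  if (inherits(dominance, "dominance_model")) return(dominance)
  switch(dominance,
         additive = dominance_model("additive"),
         recessive = dominance_model("recessive"),
         hs = dominance_human_hs(),
         stop("unknown dominance mode: ", dominance))
}

# one replicate: fresh random structure + full run
run_one <- function(run_seed, model, dominance, r,
                    N_A = 10000, c = 20, L = 5e5,
                    t_s = 2 * N_A, post = N_A,
                    dfe = dfe_human(), mu = 1.5e-8,
                    neutral = FALSE, track_neutral = FALSE,
                    marker_spacing = 0, x_mode = FALSE,
                    selfing_recipient = 0, selfing_donor = 0,
                    record_every = NULL, snapshot_prepulse = FALSE,
                    structure_seed = NULL, keep_state = FALSE) {
  set.seed(run_seed)
  struct <- generate_random_structure(L, seed = structure_seed,
                                      recomb_rate = r)
  cfg <- sim_config(
    structure = struct, dfe = dfe, dominance = dominance_for(dominance),
    demography = model_preset(model, N_A = N_A, t_s = t_s,
                              post_admixture = post),
    mating = mating_config(selfing_recipient = selfing_recipient,
                           selfing_donor = selfing_donor,
                           mode = if (x_mode) "x_chromosome" else "autosome"),
    scaling = scaling_config(c), mu = mu,
    marker_spacing = marker_spacing, track_neutral = track_neutral,
    neutral = neutral)
  run_simulation(cfg, seed = NULL, record_every = record_every,
                 snapshot_prepulse = snapshot_prepulse, keep_state = keep_state)
}

# per-generation w_R/w_D and p_I for one run, as a tidy tibble
run_trajectory <- function(sim) {
  ts <- sim$timeseries
  gens <- sort(unique(ts$gen))
  wr <- ts$mean_w[match(paste(gens, "recipient"), paste(ts$gen, ts$pop))]
  wd <- ts$mean_w[match(paste(gens, "donor"), paste(ts$gen, ts$pop))]
  pi_ <- ts$p_I[match(paste(gens, "recipient"), paste(ts$gen, ts$pop))]
  tibble(gen = gens, w_ratio = wr / wd, p_I = pi_)
}

final_p_i <- function(sim) {
  ts <- sim$timeseries
  ts$p_I[ts$gen == sim$final_gen & ts$pop == "recipient"]
}

w_ratio_at <- function(sim, gen) {
  ts <- sim$timeseries[sim$timeseries$gen == gen, ]
  ts$mean_w[ts$pop == "recipient"] / ts$mean_w[ts$pop == "donor"]
}

#' Run a replicate grid over models, recombination rates and dominance
#'
#' Every cell of the grid is run `n_reps` times with deterministically
#' derived seeds and a fresh random genome structure per replicate. Returns
#' per-replicate endpoints and aggregated trajectories (mean and 25th-75th
#' quantile bands of w_R/w_D and p_I through time).
#'
#' @param models Demographic model ids (subset of 0-4).
#' @param rates Unscaled per-bp recombination rates (standard grid:
#'   `10^-6 .. 10^-9`).
#' @param dominance Dominance modes (`"additive"`, `"recessive"`, `"hs"`).
#' @param n_reps Replicates per cell.
#' @param seed Root seed; replicate seeds are derived from it.
#' @param N_A,c,L Ancestral size, scaling constant, chromosome length of
#'   the profile (defaults: the desk-scale profile `N_A` 10,000, `c` 20,
#'   500 kb).
#' @param neutral Force all selection coefficients to zero.
#' @param ... Passed to the single-replicate runner (e.g. `mu`, `dfe`,
#'   `marker_spacing`, `record_every`).
#' @return A list with `replicates` and `trajectories` tibbles.
#' @export
run_grid <- function(models = 0, rates = 1e-8, dominance = "additive",
                     n_reps = 3, seed = 1, N_A = 10000, c = 20, L = 5e5,
                     neutral = FALSE, ...) {
  cells <- expand.grid(model = models, r = rates, dominance = dominance,
                       stringsAsFactors = FALSE)
  reps <- list(); trajs <- list(); idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (j in seq_len(n_reps)) {
      idx <- idx + 1L
      s <- run_seed_for(seed, idx)
      sim <- run_one(s, cells$model[ci], cells$dominance[ci], cells$r[ci],
                     N_A = N_A, c = c, L = L, neutral = neutral, ...)
      reps[[idx]] <- tibble(model = cells$model[ci], r = cells$r[ci],
                            dominance = cells$dominance[ci], rep = j,
                            seed = s,
                            p_I_final = final_p_i(sim),
                            p_I_pulse = sim$timeseries$p_I[
                              sim$timeseries$gen == sim$pulse_gen &
                              sim$timeseries$pop == "recipient"],
                            w_ratio_prepulse = w_ratio_at(sim, sim$pulse_gen - 1L),
                            w_ratio_final = w_ratio_at(sim, sim$final_gen))
      tr <- run_trajectory(sim)
      tr$model <- cells$model[ci]; tr$r <- cells$r[ci]
      tr$dominance <- cells$dominance[ci]; tr$rep <- j
      trajs[[idx]] <- tr
    }
  }
  replicates <- do.call(rbind, reps)
  traj <- do.call(rbind, trajs)
  agg <- do.call(rbind, lapply(
    split(traj, list(traj$model, traj$r, traj$dominance, traj$gen),
          drop = TRUE),
    function(d) tibble(model = d$model[1], r = d$r[1],
                       dominance = d$dominance[1], gen = d$gen[1],
                       p_I_mean = mean(d$p_I), p_I_q25 = quantile(d$p_I, .25),
                       p_I_q75 = quantile(d$p_I, .75),
                       w_ratio_mean = mean(d$w_ratio, na.rm = TRUE),
                       w_ratio_q25 = quantile(d$w_ratio, .25, na.rm = TRUE),
                       w_ratio_q75 = quantile(d$w_ratio, .75, na.rm = TRUE))))
  agg <- agg[order(agg$model, agg$r, agg$dominance, agg$gen), ]
  list(replicates = replicates, trajectories = agg)
}

#' Split-time sweep
#'
#' Varies the time `t_s` between the population split and the admixture
#' pulse for Models 0 and 4, recording F_ST immediately before the pulse,
#' the private/shared variant partition at that time, and the long-term
#' p_I. Low recombination (r = 1e-9 unscaled) and recessive fitness by
#' default, matching the heterosis design.
#'
#' @param ts_values Unscaled split-to-pulse times.
#' @param models Model ids (0 and/or 4).
#' @param n_reps Replicates per (model, t_s) cell.
#' @param seed Root seed.
#' @param N_A,c,L Profile parameters.
#' @param r Unscaled recombination rate.
#' @param dominance Dominance mode.
#' @param ... Passed to the single-replicate runner.
#' @return A tibble with one row per replicate.
#' @export
run_split_sweep <- function(ts_values, models = c(0, 4), n_reps = 3,
                            seed = 1, N_A = 10000, c = 20, L = 5e5,
                            r = 1e-9, dominance = "recessive", ...) {
  out <- list(); idx <- 0L
  for (m in models) for (tsv in ts_values) for (j in seq_len(n_reps)) {
    idx <- idx + 1L
    s <- run_seed_for(seed, idx)
    sim <- run_one(s, m, dominance, r, N_A = N_A, c = c, L = L, t_s = tsv,
                   track_neutral = TRUE, snapshot_prepulse = TRUE, ...)
    fst <- fst_between(sim, "snapshot")
    ps <- private_shared(sim, "snapshot")
    out[[idx]] <- tibble(model = m, t_s = tsv, rep = j, seed = s,
                         fst_pulse = fst$fst,
                         p_I_final = final_p_i(sim),
                         private_donor = ps[["private_donor"]],
                         private_recipient = ps[["private_recipient"]],
                         shared = ps[["shared"]])
  }
  do.call(rbind, out)
}

#' Partial-selfing grid
#'
#' Seven admixture scenarios between an outcrossing and a partially selfing
#' population under Model 0 demography: both outcrossing; the outcrosser as
#' donor with recipient selfing probabilities `levels`; and the partial
#' selfer as donor with the same probabilities. Defaults use the
#' Arabidopsis selection parameters (gamma DFE shape 0.185,
#' E[s] = -0.00048655, the h(s) dominance relationship, mu = 7e-9).
#'
#' @param levels Selfing probabilities for the partially selfing population.
#' @param n_reps Replicates per scenario.
#' @param seed Root seed.
#' @param N_A,c,L,r Profile parameters.
#' @param dfe,dominance,mu Selection parameters.
#' @param ... Passed to the single-replicate runner.
#' @return A list with `replicates` and `summary` (mean and SE of final
#'   p_I per scenario).
#' @export
run_selfing_grid <- function(levels = c(0.25, 0.5, 0.75), n_reps = 3,
                             seed = 1, N_A = 10000, c = 20, L = 5e5,
                             r = 1e-8, dfe = dfe_arabidopsis(),
                             dominance = dominance_arabidopsis_hs(),
                             mu = 7e-9, ...) {
  cells <- rbind(data.frame(selfing_donor = 0, selfing_recipient = 0),
                 data.frame(selfing_donor = 0, selfing_recipient = levels),
                 data.frame(selfing_donor = levels, selfing_recipient = 0))
  out <- list(); idx <- 0L
  for (ci in seq_len(nrow(cells))) for (j in seq_len(n_reps)) {
    idx <- idx + 1L
    s <- run_seed_for(seed, idx)
    sim <- run_one(s, 0, dominance, r, N_A = N_A, c = c, L = L,
                   dfe = dfe, mu = mu,
                   selfing_donor = cells$selfing_donor[ci],
                   selfing_recipient = cells$selfing_recipient[ci], ...)
    out[[idx]] <- tibble(selfing_donor = cells$selfing_donor[ci],
                         selfing_recipient = cells$selfing_recipient[ci],
                         rep = j, seed = s, p_I_final = final_p_i(sim))
  }
  replicates <- do.call(rbind, out)
  summ <- do.call(rbind, lapply(
    split(replicates,
          list(replicates$selfing_donor, replicates$selfing_recipient),
          drop = TRUE),
    function(d) tibble(selfing_donor = d$selfing_donor[1],
                       selfing_recipient = d$selfing_recipient[1],
                       p_I_mean = mean(d$p_I_final),
                       p_I_se = sd(d$p_I_final) / sqrt(nrow(d)))))
  list(replicates = replicates,
       summary = summ[order(summ$selfing_donor, summ$selfing_recipient), ])
}

#' X chromosome versus autosome comparison
#'
#' For each (model, dominance, replicate) the same random genome structure
#' is simulated twice: once with autosomal inheritance and once in
#' X-chromosome mode (hemizygous males, no male recombination,
#' dosage-compensated fitness). Reports the mean final p_I per chromosome
#' type and the autosome-over-X fold difference.
#'
#' @param models Model ids.
#' @param dominance Dominance modes.
#' @param n_reps Replicates per cell.
#' @param seed Root seed.
#' @param N_A,c,L,r Profile parameters.
#' @param ... Passed to the single-replicate runner.
#' @return A list with `replicates` and `summary` (per model, dominance and
#'   chromosome: mean p_I, SE, and the A/X ratio of means).
#' @export
run_x_vs_autosome <- function(models = c(0, 2, 4),
                              dominance = c("additive", "recessive"),
                              n_reps = 3, seed = 1, N_A = 10000, c = 20,
                              L = 5e5, r = 1e-8, ...) {
  cells <- expand.grid(model = models, dominance = dominance,
                       stringsAsFactors = FALSE)
  out <- list(); idx <- 0L
  for (ci in seq_len(nrow(cells))) for (j in seq_len(n_reps)) {
    idx <- idx + 1L
    ss <- run_seed_for(seed, 100000L + idx)  # shared structure seed
    for (chrom in c("autosome", "x")) {
      s <- run_seed_for(seed, idx + ifelse(chrom == "x", 50000L, 0L))
      sim <- run_one(s, cells$model[ci], cells$dominance[ci], r,
                     N_A = N_A, c = c, L = L, x_mode = (chrom == "x"),
                     structure_seed = ss, ...)
      out[[length(out) + 1]] <- tibble(model = cells$model[ci],
                                       dominance = cells$dominance[ci],
                                       chromosome = chrom, rep = j, seed = s,
                                       p_I_final = final_p_i(sim))
    }
  }
  replicates <- do.call(rbind, out)
  summ <- do.call(rbind, lapply(
    split(replicates, list(replicates$model, replicates$dominance),
          drop = TRUE),
    function(d) {
      a <- d$p_I_final[d$chromosome == "autosome"]
      x <- d$p_I_final[d$chromosome == "x"]
      tibble(model = d$model[1], dominance = d$dominance[1],
             p_I_autosome = mean(a), se_autosome = sd(a) / sqrt(length(a)),
             p_I_x = mean(x), se_x = sd(x) / sqrt(length(x)),
             a_over_x = mean(a) / mean(x))
    }))
  list(replicates = replicates, summary = summ)
}
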