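# Simulation configuration and the forward Wright-Fisher driver.
#
# The generation clock: generation 0 is the mutation-free founding
# population. `split_gen = burn_in` is the first generation at which the two
# subpopulations exist (their ancestry labels are assigned then),
# `pulse_gen = burn_in + t_s` is the single admixed offspring generation, and
# the run ends at `pulse_gen + post_admixture`. All durations are in
# (possibly rescaled) generations.

#' Demographic model: one split, one admixture pulse
#'
#' An ancestral population of `N_A` diploids evolves for `burn_in`
#' generations, splits into a recipient and a donor subpopulation, and after
#' `t_s` generations a single one-generation pulse moves a fraction
#' `pulse_fraction` of the recipient's parentage to the donor. The run
#' continues `post_admixture` generations beyond the pulse. Subpopulation
#' sizes follow piecewise-constant schedules given as (offset, size) rows,
#' where `offset` is generations after the split at which `size` takes
#' effect.
#'
#' @param N_A Ancestral diploid population size.
#' @param burn_in Burn-in duration (default 10 N_A generations).
#' @param t_s Generations between the split and the admixture pulse
#'   (default 2 N_A).
#' @param post_admixture Generations simulated after the pulse (default N_A).
#' @param pulse_fraction Admixture fraction f in (0, 1) (default 0.05).
#' @param recipient_schedule,donor_schedule Data frames with columns
#'   `offset`, `size`; default constant `N_A`.
#' @return A `demographic_model` object.
#' @export
demographic_model <- function(N_A, burn_in = 10 * N_A, t_s = 2 * N_A,
                              post_admixture = N_A, pulse_fraction = 0.05,
                              recipient_schedule = NULL,
                              donor_schedule = NULL) {
  if (N_A < 2) stop("`N_A` must be >= 2")
  if (pulse_fraction <= 0 || pulse_fraction >= 1)
    stop("`pulse_fraction` must be in (0, 1)")
  if (is.null(recipient_schedule))
    recipient_schedule <- tibble(offset = 0, size = N_A)
  if (is.null(donor_schedule))
    donor_schedule <- tibble(offset = 0, size = N_A)
  for (sch in list(recipient_schedule, donor_schedule)) {
    if (any(sch$size < 1)) stop("population sizes must be >= 1")
    if (sch$offset[1] != 0 || is.unsorted(sch$offset, strictly = TRUE))
      stop("schedule offsets must start at 0 and increase strictly")
  }
  structure(list(N_A = N_A, burn_in = burn_in, t_s = t_s,
                 post_admixture = post_admixture,
                 pulse_fraction = pulse_fraction,
                 recipient_schedule = as_tibble(recipient_schedule),
                 donor_schedule = as_tibble(donor_schedule),
                 admixture = TRUE),
            class = "demographic_model")
}

#' Single equilibrium population (no split, no admixture)
#'
#' A constant-size population evolved for `generations` generations from a
#' mutation-free founding state, used for mutation-selection-drift
#' equilibrium checks such as site-frequency-spectrum comparisons.
#'
#' @param N_A Diploid population size.
#' @param generations Run length (default 10 N_A).
#' @return A `demographic_model` with no admixture event.
#' @export
equilibrium_model <- function(N_A, generations = 10 * N_A) {
  dm <- demographic_model(N_A, burn_in = generations, t_s = 1,
                          post_admixture = 0)
  dm$admixture <- FALSE
  dm
}

#' Demographic model presets 0-4
#'
#' Five admixture scenarios sharing the split / pulse schedule of
#' [demographic_model()] and differing in subpopulation sizes. The reduced
#' size is `N_A / 10` (the schedule details of the bottleneck models are
#' reconstructions exposed here so they stay editable):
#'
#' * Model 0 - both subpopulations stay at `N_A`.
#' * Model 1 - recipient bottleneck to `N_A/10` for the last `0.1 N_A`
#'   generations before the pulse, recovering at the pulse.
#' * Model 2 - donor at `N_A/10` from the split onward (donor carries the
#'   higher load; introgressed ancestry is deleterious).
#' * Model 3 - recipient at `N_A/10` from the split onward.
#' * Model 4 - recipient at `N_A/10` from the split, restored to `N_A` at
#'   the pulse (donor fitter, recipient expands at admixture).
#'
#' @param model Integer 0-4.
#' @param N_A Ancestral diploid size.
#' @param reduced_size Size of the reduced subpopulation (default `N_A/10`).
#' @param t_s Split-to-admixture time (default `2 N_A`).
#' @param ... Passed on to [demographic_model()].
#' @return A `demographic_model`.
#' @export
model_preset <- function(model, N_A = 10000, reduced_size = round(N_A / 10),
                         t_s = 2 * N_A, ...) {
  stopifnot(model %in% 0:4)
  rs <- ds <- NULL
  if (model == 1) {
    bt <- round(0.1 * N_A)
    rs <- tibble(offset = c(0, t_s - bt, t_s), size = c(N_A, reduced_size, N_A))
  } else if (model == 2) {
    ds <- tibble(offset = 0, size = reduced_size)
  } else if (model == 3) {
    rs <- tibble(offset = 0, size = reduced_size)
  } else if (model == 4) {
    rs <- tibble(offset = c(0, t_s), size = c(reduced_size, N_A))
  }
  demographic_model(N_A, t_s = t_s, recipient_schedule = rs,
                    donor_schedule = ds, ...)
}

#' Mating configuration
#'
#' @param selfing_recipient,selfing_donor,selfing_ancestral Probability that
#'   an offspring of the respective population is produced by
#'   self-fertilization (one parent supplies both gametes).
#' @param mode `"autosome"` or `"x_chromosome"`. In X mode males are
#'   hemizygous, sons receive a recombined maternal X, daughters a recombined
#'   maternal X plus the paternal X copied without recombination, and sexes
#'   alternate so the ratio is 1:1. Selfing is not available in X mode.
#' @return A `mating_config` object.
#' @export
mating_config <- function(selfing_recipient = 0, selfing_donor = 0,
                          selfing_ancestral = 0,
                          mode = c("autosome", "x_chromosome")) {
  mode <- match.arg(mode)
  sp <- c(selfing_ancestral, selfing_recipient, selfing_donor)
  if (any(sp < 0 | sp > 1)) stop("selfing probabilities must be in [0, 1]")
  if (mode == "x_chromosome" && any(sp > 0))
    stop("selfing is not supported in X-chromosome mode")
  structure(list(selfing_recipient = selfing_recipient,
                 selfing_donor = selfing_donor,
                 selfing_ancestral = selfing_ancestral, mode = mode),
            class = "mating_config")
}

#' Scaling configuration
#'
#' @param c Scaling constant >= 1 (1 = unscaled). See [rescale()].
#' @export
scaling_config <- function(c = 1) {
  if (c < 1) stop("scaling constant must be >= 1")
  structure(list(c = c, applied = FALSE), class = "scaling_config")
}

#' Assemble a simulation configuration
#'
#' @param structure A [genome_structure()].
#' @param dfe A [dfe_params()] (ignored when `neutral = TRUE`).
#' @param dominance A [dominance_model()].
#' @param demography A [demographic_model()] or [model_preset()].
#' @param mating A [mating_config()].
#' @param scaling A [scaling_config()].
#' @param mu Per-bp per-generation mutation rate (unscaled).
#' @param ns_syn_ratio Nonsynonymous : synonymous targeting ratio within
#'   exons (default 2.31).
#' @param marker_spacing Spacing in bp of neutral ancestry marker mutations
#'   placed on every donor haplotype one generation before the pulse; 0
#'   disables markers. Markers never enter fitness, the SFS, or F_ST.
#' @param track_neutral Keep synonymous and non-exonic neutral mutations in
#'   the simulation state. They never affect dynamics; disabling them makes
#'   large runs substantially faster while leaving ancestry and fitness
#'   untouched.
#' @param prune_every Cadence (generations) at which mutations fixed across
#'   all extant haplotypes are removed from the state and logged as
#'   substitutions. Relative fitnesses are invariant to this cadence.
#' @param fitness_scheme `"multiplicative"` (within-locus multiplicative,
#'   the default) or `"textbook"` (het `1 - h|s|`, hom `1 - |s|`), kept for
#'   site-frequency-spectrum equivalence checks.
#' @param neutral Force all selection coefficients to 0 (drift-only run).
#' @return A `sim_config` object.
#' @export
sim_config <- function(structure, dfe = dfe_human(),
                       dominance = dominance_model("additive"),
                       demography = model_preset(0),
                       mating = mating_config(),
                       scaling = scaling_config(1),
                       mu = 1.5e-8, ns_syn_ratio = 2.31,
                       marker_spacing = 0, track_neutral = TRUE,
                       prune_every = 100,
                       fitness_scheme = c("multiplicative", "textbook"),
                       neutral = FALSE) {
  stopifnot(inherits(structure, "genome_structure"),
            inherits(dominance, "dominance_model"),
            inherits(demography, "demographic_model"),
            inherits(mating, "mating_config"),
            inherits(scaling, "scaling_config"))
  if (!neutral) stopifnot(inherits(dfe, "dfe_params"))
  if (mu < 0) stop("`mu` must be >= 0")
  if (ns_syn_ratio <= 0) stop("`ns_syn_ratio` must be > 0")
  structure(list(structure = structure, dfe = dfe, dominance = dominance,
                 demography = demography, mating = mating, scaling = scaling,
                 mu = mu, ns_syn_ratio = ns_syn_ratio,
                 marker_spacing = marker_spacing,
                 track_neutral = track_neutral, prune_every = prune_every,
                 fitness_scheme = match.arg(fitness_scheme),
                 neutral = neutral),
            class = "sim_config")
}

#' Rescale a recombination rate
#'
#' The per-bp crossover probability transforms as
#' `0.5 * (1 - (1 - 2 r)^c)`, which is approximately r*c for small r.
#'
#' @param r Per-bp crossover probability.
#' @param c Scaling constant.
#' @export
rescale_rate <- function(r, c) 0.5 * (1 - (1 - 2 * r)^c)

#' Rescale a simulation configuration
#'
#' Applies the standard forward-simulation rescaling with constant `c`:
#' population sizes become `round(N / c)`, times `round(t / c)`, selection
#' coefficients `s * c`, the mutation rate `mu * c`, and each map rate
#' `0.5 (1 - (1 - 2 r)^c)`. Sequence length is unchanged. The h(s)
#' relationship keeps operating on the unscaled coefficient, so its slope is
#' divided by `c`.
#'
#' @param config A [sim_config()].
#' @return A `sim_config` with `scaling$applied = TRUE`; `c = 1` returns the
#'   configuration unchanged.
#' @export
rescale <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cc <- config$scaling$c
  if (config$scaling$applied) stop("configuration is already rescaled")
  if (cc == 1) return(config)
  out <- config
  dm <- config$demography
  scale_n <- function(n) {
    n2 <- round(n / cc)
    if (any(n2 < 2)) stop("rescaled population size below 2; reduce c")
    n2
  }
  dm$N_A <- scale_n(dm$N_A)
  dm$burn_in <- round(dm$burn_in / cc)
  dm$t_s <- max(1, round(dm$t_s / cc))
  dm$post_admixture <- round(dm$post_admixture / cc)
  dm$recipient_schedule$offset <- round(dm$recipient_schedule$offset / cc)
  dm$recipient_schedule$size <- scale_n(dm$recipient_schedule$size)
  dm$donor_schedule$offset <- round(dm$donor_schedule$offset / cc)
  dm$donor_schedule$size <- scale_n(dm$donor_schedule$size)
  out$demography <- dm
  if (!out$neutral) out$dfe$mean_s <- out$dfe$mean_s * cc
  out$mu <- out$mu * cc
  out$structure$recomb_map$rate <- rescale_rate(out$structure$recomb_map$rate, cc)
  if (out$dominance$mode == "hs") out$dominance$hs_slope <- out$dominance$hs_slope / cc
  out$scaling$applied <- TRUE
  out
}

# piecewise-constant schedule lookup: size at `offset` generations post-split
schedule_size <- function(schedule, offset) {
  idx <- findInterval(offset, schedule$offset)
  schedule$size[pmax(idx, 1)]
}

# build the (T+1) x 2 per-generation size matrix plus the event generations
build_schedule <- function(dm) {
  if (!isTRUE(dm$admixture)) { # equilibrium run: split/pulse never happen
    T_end <- as.integer(dm$burn_in)
    return(list(sizes = cbind(rep(as.integer(dm$N_A), T_end + 1),
                              rep(0L, T_end + 1)),
                split_gen = T_end + 5L, pulse_gen = T_end + 7L,
                T_end = T_end))
  }
  split_gen <- as.integer(dm$burn_in)
  pulse_gen <- split_gen + as.integer(dm$t_s)
  T_end <- pulse_gen + as.integer(dm$post_admixture)
  t <- 0:T_end
  rec <- ifelse(t < split_gen, dm$N_A,
                schedule_size(dm$recipient_schedule, t - split_gen))
  don <- ifelse(t < split_gen, 0,
                schedule_size(dm$donor_schedule, t - split_gen))
  list(sizes = cbind(as.integer(rec), as.integer(don)),
       split_gen = split_gen, pulse_gen = pulse_gen, T_end = T_end)
}

#' Run a forward simulation
#'
#' Executes burn-in, split, divergence, the admixture pulse and the
#' post-admixture phase of `config`, recording population summaries at
#' regular intervals (always including the generations just before and after
#' the pulse and the final generation). If `config$scaling$c > 1` the
#' configuration is rescaled first; all returned quantities are on the
#' scaled clock.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @param record_every Recording interval in scaled generations (default:
#'   about 50 records across the run).
#' @param snapshot_prepulse Keep a full haplotype-level snapshot of the
#'   generation immediately before the pulse (after marker placement), for
#'   F_ST / load / private-shared analyses at the admixture time.
#' @param keep_state Export the final-generation haplotype state (mutation
#'   lists and ancestry segments). Disable when only the recorded time
#'   series is needed; this makes replicate sweeps markedly cheaper.
#' @return A `wf_sim` object: `timeseries` (per recorded generation and
#'   population: mean fitness over segregating selected sites, the
#'   introgression-derived ancestry fraction `p_I`, mean derived deleterious
#'   sites per haplotype and homozygous ones per individual), `mutations`
#'   (id, position, s, h, class, origin), `haplotypes` / `hap_info` /
#'   `segments` for the final generation, the optional `snapshot`,
#'   `substitutions`, and bookkeeping fields (`L`, `split_gen`, `pulse_gen`,
#'   `final_gen`, the scaled `config`).
#' @export
run_simulation <- function(config, seed = NULL, record_every = NULL,
                           snapshot_prepulse = FALSE, keep_state = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  sc <- if (config$scaling$c > 1 && !config$scaling$applied) rescale(config) else config
  dm <- sc$demography
  sch <- build_schedule(dm)
  if (is.null(record_every))
    record_every <- max(1L, as.integer(round(sch$T_end / 50)))
  record_gens <- unique(sort(c(seq(0L, sch$T_end, by = record_every),
                               sch$split_gen, sch$pulse_gen - 1L,
                               sch$pulse_gen, sch$T_end)))
  ex <- exon_intervals(sc$structure)
  x_mode <- sc$mating$mode == "x_chromosome"
  if (x_mode && any(sch$sizes[sch$sizes[, 1] > 0, 1] < 2))
    stop("X mode needs at least 2 diploids per population")
  par <- list(
    L = sc$structure$length,
    exon_start = as.integer(ex$start), exon_end = as.integer(ex$end),
    map_end = as.integer(sc$structure$recomb_map$end),
    map_rate = as.numeric(sc$structure$recomb_map$rate),
    mu = sc$mu,
    ns_frac = sc$ns_syn_ratio / (1 + sc$ns_syn_ratio),
    dfe_shape = if (sc$neutral) 1 else sc$dfe$shape,
    dfe_scale = if (sc$neutral) 0 else abs(sc$dfe$mean_s) / sc$dfe$shape,
    dominance_mode = match(sc$dominance$mode, c("additive", "recessive", "hs")) - 1L,
    hs_h0 = sc$dominance$hs_intercept, hs_k = sc$dominance$hs_slope,
    fitness_scheme = match(sc$fitness_scheme, c("multiplicative", "textbook")) - 1L,
    neutral_sim = sc$neutral,
    x_mode = x_mode,
    track_neutral = sc$track_neutral,
    marker_spacing = as.integer(sc$marker_spacing),
    prune_every = as.integer(sc$prune_every),
    sizes = sch$sizes,
    split_gen = sch$split_gen, pulse_gen = sch$pulse_gen,
    pulse_frac = dm$pulse_fraction,
    selfing = c(sc$mating$selfing_ancestral, sc$mating$selfing_recipient,
                sc$mating$selfing_donor),
    record_gens = as.integer(record_gens),
    snapshot_prepulse = snapshot_prepulse,
    export_final = keep_state)
  raw <- run_wf_cpp(par)

  classes <- c("neutral", "nonsynonymous", "synonymous", "marker")
  ts <- as_tibble(raw$timeseries)
  ts$pop <- c("recipient", "donor")[ts$pop + 1L]
  mt <- as_tibble(raw$mutations)
  mt$class <- classes[mt$cls + 1L]
  mt$cls <- NULL
  mt$origin_pop <- c("recipient", "donor")[mt$origin_pop + 1L]

  out <- list(timeseries = ts, mutations = mt,
              final = if (!is.null(raw$final)) state_tables(raw$final),
              snapshot = if (!is.null(raw$snapshot)) state_tables(raw$snapshot),
              substitutions = as_tibble(raw$substitutions),
              marker_ids = raw$marker_ids,
              L = sc$structure$length,
              split_gen = sch$split_gen, pulse_gen = sch$pulse_gen,
              final_gen = raw$final_gen,
              config = sc, seed = seed)
  class(out) <- "wf_sim"
  out
}

# convert an engine state export into hap_info / haplotypes / segments
state_tables <- function(st) {
  nh <- length(st$pop)
  hap_info <- tibble(hap_id = seq_len(nh),
                     pop = c("recipient", "donor")[st$pop + 1L],
                     ind = st$ind, which = st$which,
                     sex = c("female", "male")[st$sex + 1L])
  ends <- st$seg_end
  hap_of_seg <- rep(seq_len(nh), st$seg_count)
  first_of_hap <- c(TRUE, hap_of_seg[-1] != hap_of_seg[-length(hap_of_seg)])
  starts <- c(0L, ends[-length(ends)])
  starts[first_of_hap] <- 0L
  segments <- tibble(hap_id = hap_of_seg, start = starts, end = ends,
                     origin = c("recipient", "donor")[st$seg_org + 1L])
  list(hap_info = hap_info, haplotypes = st$hap_muts, segments = segments)
}

#' @export
print.wf_sim <- function(x, ...) {
  cat("<wf_sim> L =", x$L, "bp; split at", x$split_gen,
      "; pulse at", x$pulse_gen, "; final generation", x$final_gen, "\n")
  fin <- x$timeseries[x$timeseries$gen == x$final_gen, ]
  for (i in seq_len(nrow(fin)))
    cat(sprintf("  %-9s n = %d  mean_w = %.4f  p_I = %s\n", fin$pop[i],
                fin$n[i], fin$mean_w[i],
                ifelse(is.na(fin$p_I[i]), "-", sprintf("%.4f", fin$p_I[i]))))
  invisible(x)
}
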