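# Shared fixtures: tiny structures and quick simulation configurations used
# across the unit tests. Everything is generated in code; no stored data.

# a deterministic two-exon toy chromosome of 1000 bp
toy_structure <- function(rate = 1e-8) {
  genome_structure(
    1000,
    tibble::tibble(kind = c("intergenic", "exon", "intron", "exon", "intergenic"),
                   start = c(0L, 200L, 300L, 400L, 600L),
                   end = c(200L, 300L, 400L, 600L, 1000L)),
    uniform_recomb_map(1000, rate))
}

# small admixture run: N diploids, 100 kb, schedule scaled to desk size
quick_sim <- function(seed, N = 60, L = 1e5, model = 0, neutral = TRUE,
                      dominance = dominance_model("additive"),
                      r = 1e-8, mu = 1.5e-8, marker_spacing = 0,
                      track_neutral = TRUE, x_mode = FALSE, ...) {
  set.seed(seed)
  st <- generate_random_structure(L, recomb_rate = r)
  cfg <- sim_config(
    st, dfe = dfe_human(), dominance = dominance,
    demography = model_preset(model, N_A = N),
    mating = mating_config(mode = if (x_mode) "x_chromosome" else "autosome"),
    mu = mu, marker_spacing = marker_spacing,
    track_neutral = track_neutral, neutral = neutral)
  run_simulation(cfg, seed = NULL, ...)
}

# hand-built wf_sim-like object with explicit recipient ancestry segments,
# for exact-oracle tests of the ancestry summaries
synthetic_segments_sim <- function(L, donor_tracts, n_hap) {
  # donor_tracts: list of tibbles (start, end) per haplotype
  seg <- list()
  for (h in seq_len(n_hap)) {
    d <- donor_tracts[[h]]
    bounds <- sort(unique(c(0L, d$start, d$end, L)))
    s <- head(bounds, -1); e <- bounds[-1]
    org <- ifelse(vapply(s, function(x) any(d$start <= x & d$end > x), logical(1)),
                  "donor", "recipient")
    seg[[h]] <- tibble::tibble(hap_id = h, start = s, end = e, origin = org)
  }
  st <- list(hap_info = tibble::tibble(hap_id = seq_len(n_hap), pop = "recipient",
                                       ind = seq_len(n_hap), which = 1L,
                                       sex = "female"),
             haplotypes = rep(list(integer(0)), n_hap),
             segments = do.call(rbind, seg))
  structure(list(final = st, snapshot = NULL, L = L,
                 mutations = tibble::tibble(id = integer(0), pos = integer(0)),
                 marker_ids = integer(0)),
            class = "wf_sim")
}

# brute-force per-bp desert oracle
desert_oracle <- function(sim) {
  st <- sim$final
  L <- sim$L
  covered <- logical(L)
  d <- st$segments[st$segments$origin == "donor", ]
  for (i in seq_len(nrow(d))) covered[(d$start[i] + 1):d$end[i]] <- TRUE
  runs <- rle(!covered)
  ends <- cumsum(runs$lengths)
  starts <- c(0L, head(ends, -1))
  keep <- runs$values
  tibble::tibble(start = starts[keep], end = ends[keep],
                 length = (ends - starts)[keep])
}
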