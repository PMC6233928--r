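# Population-genetic summaries: load, Hudson/Bhatia F_ST, site frequency
# spectra, private/shared partitions, and tie-randomized Spearman
# correlations for window-level landscape statistics.

# per-population derived-allele counts for every mutation carried by at
# least one haplotype in the given state
variant_counts <- function(sim, state = c("final", "snapshot"),
                           include_markers = FALSE) {
  st <- sim_state(sim, state)
  nbins <- max(sim$mutations$id) + 1L
  count_pop <- function(p) {
    hids <- st$hap_info$hap_id[st$hap_info$pop == p]
    ids <- unlist(st$haplotypes[hids], use.names = FALSE)
    list(counts = tabulate(ids + 1L, nbins = nbins), n_hap = length(hids))
  }
  rec <- count_pop("recipient")
  don <- count_pop("donor")
  present <- which(rec$counts > 0 | don$counts > 0) - 1L
  out <- tibble(id = present,
                count_recipient = rec$counts[present + 1L],
                count_donor = don$counts[present + 1L])
  out$class <- sim$mutations$class[match(out$id, sim$mutations$id)]
  out$pos <- sim$mutations$pos[match(out$id, sim$mutations$id)]
  out$s <- sim$mutations$s[match(out$id, sim$mutations$id)]
  if (!include_markers) out <- out[out$class != "marker", ]
  attr(out, "n_hap_recipient") <- rec$n_hap
  attr(out, "n_hap_donor") <- don$n_hap
  out
}

#' Population load summary
#'
#' Mean fitness per population over segregating selected sites (globally
#' fixed variants are pruned by the engine and excluded), the recipient /
#' donor fitness ratio w_R / w_D, mean derived deleterious sites per
#' haplotype, and mean homozygous derived deleterious sites per individual,
#' read from the recorded time series.
#'
#' @param sim A `wf_sim` object.
#' @param gen Generation to summarise (default: the final generation; the
#'   generation just before the pulse is always recorded too).
#' @return A list with `by_pop` (tibble) and `w_ratio` (w_R / w_D, `NA`
#'   while only one population exists).
#' @export
load_summary <- function(sim, gen = NULL) {
  if (is.null(gen)) gen <- sim$final_gen
  rows <- sim$timeseries[sim$timeseries$gen == gen, ]
  if (nrow(rows) == 0)
    stop("generation ", gen, " was not recorded; recorded: ",
         paste(utils::head(unique(sim$timeseries$gen), 20), collapse = ", "), " ...")
  wr <- rows$mean_w[rows$pop == "recipient"]
  wd <- rows$mean_w[rows$pop == "donor"]
  list(by_pop = rows[, c("pop", "n", "mean_w", "del_per_hap", "hom_per_ind")],
       w_ratio = if (length(wd) == 1) wr / wd else NA_real_)
}

#' Hudson per-site F_ST components
#'
#' Numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`; vectorized over sites.
#'
#' @param p1,p2 Sample allele frequencies in the two populations.
#' @param n1,n2 Haploid sample sizes (> 1).
#' @return A list with `num` and `den` per site.
#' @export
hudson_fst_site <- function(p1, p2, n1, n2) {
  if (any(n1 <= 1) || any(n2 <= 1)) stop("sample sizes must exceed 1")
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) stop("frequencies must be in [0, 1]")
  list(num = (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1),
       den = p1 * (1 - p2) + p2 * (1 - p1))
}

#' Combine per-site F_ST across sites
#'
#' Ratio of averages: `sum(num) / sum(den)`. Negative per-site numerators
#' are retained, as is standard for this combination. Sites monomorphic in
#' both samples contribute zero to both sums and should be excluded by the
#' caller; if every site is monomorphic the result is flagged `NA`.
#'
#' @param num,den Per-site components from [hudson_fst_site()].
#' @return Combined F_ST (scalar), `NA` if the denominator sum is zero.
#' @export
combine_fst <- function(num, den) {
  sd_ <- sum(den)
  if (sd_ == 0) {
    warning("all sites monomorphic; combined F_ST undefined")
    return(NA_real_)
  }
  sum(num) / sd_
}

#' F_ST between the two subpopulations of a simulation
#'
#' Hudson per-site components combined across sites (ratio of averages) over
#' all segregating non-marker variants of the requested classes, excluding
#' sites monomorphic in both samples. Use `state = "snapshot"` (with
#' `snapshot_prepulse = TRUE` in [run_simulation()]) for differentiation at
#' the admixture time.
#'
#' @param sim A `wf_sim` object.
#' @param state `"snapshot"` or `"final"`.
#' @param classes Functional classes to include (default: everything except
#'   markers).
#' @return A list with `fst`, the per-site tibble, and the sample sizes.
#' @export
fst_between <- function(sim, state = c("snapshot", "final"),
                        classes = c("nonsynonymous", "synonymous", "neutral")) {
  state <- match.arg(state)
  vc <- variant_counts(sim, state)
  vc <- vc[vc$class %in% classes, ]
  n1 <- attr(vc, "n_hap_recipient"); n2 <- attr(vc, "n_hap_donor")
  if (is.null(n2) || n2 == 0) stop("both populations must exist in the chosen state")
  p1 <- vc$count_recipient / n1
  p2 <- vc$count_donor / n2
  poly <- !((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
  comp <- hudson_fst_site(p1[poly], p2[poly], n1, n2)
  list(fst = combine_fst(comp$num, comp$den),
       per_site = tibble(id = vc$id[poly], p_recipient = p1[poly],
                         p_donor = p2[poly], num = comp$num, den = comp$den),
       n_hap = c(recipient = n1, donor = n2))
}

#' Site frequency spectrum with tail pooling
#'
#' Counts of segregating sites by derived-allele sample count; all sites at
#' count >= `fold_threshold` are pooled into the final bin.
#'
#' @param counts Derived-allele counts per site (integer, in `1..k-1`).
#' @param fold_threshold Pooling threshold (default 25).
#' @return Named integer vector: bins `1 .. fold_threshold-1` plus
#'   `">=threshold"`.
#' @export
sfs <- function(counts, fold_threshold = 25) {
  stopifnot(fold_threshold >= 2)
  counts <- counts[counts > 0]
  pooled <- pmin(counts, fold_threshold)
  out <- tabulate(pooled, nbins = fold_threshold)
  names(out) <- c(as.character(seq_len(fold_threshold - 1)),
                  paste0(">=", fold_threshold))
  out
}

#' Site frequency spectrum from a simulation
#'
#' Derived-allele counts in a without-replacement sample of haplotypes from
#' one population (ancestral-state polarity is exact in simulation: the
#' ancestral allele is absence of the mutation). Markers are excluded.
#'
#' @param sim A `wf_sim` object.
#' @param pop `"recipient"` or `"donor"`.
#' @param sample_size Number of haplotypes to sample (default: all).
#' @param classes Functional classes to include.
#' @param state `"final"` or `"snapshot"`.
#' @param fold_threshold Pooling threshold for [sfs()].
#' @return Named integer vector of SFS bins.
#' @export
sfs_from_sim <- function(sim, pop = "recipient", sample_size = NULL,
                         classes = "nonsynonymous",
                         state = c("final", "snapshot"),
                         fold_threshold = 25) {
  st <- sim_state(sim, state)
  hids <- st$hap_info$hap_id[st$hap_info$pop == pop]
  if (!is.null(sample_size)) {
    if (sample_size > length(hids)) stop("sample_size exceeds available haplotypes")
    hids <- sample(hids, sample_size)
  }
  ids <- unlist(st$haplotypes[hids], use.names = FALSE)
  cls <- sim$mutations$class[match(ids, sim$mutations$id)]
  ids <- ids[cls %in% classes]
  cnt <- table(ids)
  cnt <- cnt[cnt < length(hids)]  # drop sample-fixed sites
  sfs(as.integer(cnt), fold_threshold)
}

#' Private and shared variant counts
#'
#' Partition of segregating non-marker variants into private-to-donor,
#' private-to-recipient, and shared; the three counts always sum to the
#' total number of segregating variants.
#'
#' @param sim A `wf_sim` object.
#' @param state `"snapshot"` or `"final"`.
#' @return Named integer vector
#'   `(private_donor, private_recipient, shared, total)`.
#' @export
private_shared <- function(sim, state = c("snapshot", "final")) {
  vc <- variant_counts(sim, state)
  pd <- sum(vc$count_recipient == 0)
  pr <- sum(vc$count_donor == 0)
  sh <- sum(vc$count_recipient > 0 & vc$count_donor > 0)
  c(private_donor = pd, private_recipient = pr, shared = sh,
    total = nrow(vc))
}

#' Spearman correlation with randomized tie ranks
#'
#' Ranks are assigned with ties broken by a random permutation (under the
#' caller's RNG), then the Pearson correlation of the ranks is computed with
#' a two-sided p-value from the large-sample t approximation for
#' H1: rho != 0.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return A list with `rho` and `p_value`.
#' @export
spearman_random_ties <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need equal-length vectors with n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector; correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  rx <- rank(x, ties.method = "random")
  ry <- rank(y, ties.method = "random")
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) return(list(rho = rho, p_value = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * pt(-abs(tt), df = n - 2))
}
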