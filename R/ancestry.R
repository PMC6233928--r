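# Quantifying introgression-derived ancestry: exact segment tracking and
# neutral marker mutations, plus introgression deserts.

sim_state <- function(sim, state = c("final", "snapshot")) {
  state <- match.arg(state)
  st <- sim[[state]]
  if (is.null(st))
    stop("no ", state, " state stored in this simulation (rerun with ",
         if (state == "snapshot") "snapshot_prepulse" else "keep_state",
         " = TRUE)")
  st
}

recipient_hap_ids <- function(st) st$hap_info$hap_id[st$hap_info$pop == "recipient"]

#' Introgression-derived ancestry from exact segments
#'
#' Computes the fraction of recipient-population ancestry tracing to the
#' donor population from the recorded ancestry segments; this is exact, not
#' an estimate. Per-window values are donor-labelled bp divided by window bp
#' times the number of sampled haplotypes, so the base-pair-weighted mean of
#' the window values equals the global value.
#'
#' @param sim A `wf_sim` object from [run_simulation()].
#' @param windows Optional window tibble from [make_windows()]; if `NULL`
#'   only the global value is returned.
#' @param state `"final"` or `"snapshot"`.
#' @return A list with `p_I_global`, `by_window` (tibble or `NULL`), and
#'   `method = "segment"`.
#' @export
p_i_from_segments <- function(sim, windows = NULL,
                              state = c("final", "snapshot")) {
  st <- sim_state(sim, state)
  rh <- recipient_hap_ids(st)
  seg <- st$segments[st$segments$hap_id %in% rh &
                     st$segments$origin == "donor", ]
  n_hap <- length(rh)
  global <- sum(as.numeric(seg$end - seg$start)) / (as.numeric(sim$L) * n_hap)
  by_window <- NULL
  if (!is.null(windows)) {
    p <- vapply(seq_len(nrow(windows)), function(i) {
      ov <- pmin(seg$end, windows$end[i]) - pmax(seg$start, windows$start[i])
      sum(as.numeric(pmax(ov, 0))) /
        (as.numeric(windows$end[i] - windows$start[i]) * n_hap)
    }, numeric(1))
    by_window <- tibble(start = windows$start, end = windows$end, p_I = p)
  }
  list(p_I_global = global, by_window = by_window, method = "segment")
}

#' Introgression-derived ancestry from marker mutations
#'
#' Estimates p_I from the allele frequencies of the neutral marker mutations
#' placed on every donor haplotype one generation before the pulse
#' (`marker_spacing` in [sim_config()]). The global estimate is the mean
#' marker frequency over all markers; per-window estimates average the
#' markers inside each window, and windows containing no marker are reported
#' as `NA`.
#'
#' @inheritParams p_i_from_segments
#' @return A list with `p_I_global`, `by_window`, and `method = "marker"`.
#' @export
p_i_from_markers <- function(sim, windows = NULL,
                             state = c("final", "snapshot")) {
  if (length(sim$marker_ids) == 0)
    stop("no markers were placed (set marker_spacing in sim_config)")
  st <- sim_state(sim, state)
  rh <- recipient_hap_ids(st)
  n_hap <- length(rh)
  ids <- unlist(st$haplotypes[rh], use.names = FALSE)
  counts <- table(factor(ids[ids %in% sim$marker_ids],
                         levels = sim$marker_ids))
  freq <- as.numeric(counts) / n_hap
  pos <- sim$mutations$pos[match(sim$marker_ids, sim$mutations$id)]
  by_window <- NULL
  if (!is.null(windows)) {
    p <- vapply(seq_len(nrow(windows)), function(i) {
      inw <- pos >= windows$start[i] & pos < windows$end[i]
      if (!any(inw)) return(NA_real_)
      mean(freq[inw])
    }, numeric(1))
    by_window <- tibble(start = windows$start, end = windows$end, p_I = p)
  }
  list(p_I_global = mean(freq), by_window = by_window, method = "marker")
}

#' Introgression deserts
#'
#' Maximal intervals of the chromosome in which no sampled recipient
#' haplotype carries any donor ancestry. With `per_haplotype = TRUE` the
#' desert set is computed separately for every haplotype instead of
#' population-wide.
#'
#' @inheritParams p_i_from_segments
#' @param per_haplotype Compute deserts per haplotype rather than across the
#'   whole sample.
#' @return A tibble of disjoint maximal intervals (`start`, `end`, `length`,
#'   and `hap_id` when per-haplotype).
#' @export
desert_lengths <- function(sim, state = c("final", "snapshot"),
                           per_haplotype = FALSE) {
  st <- sim_state(sim, state)
  rh <- recipient_hap_ids(st)
  donor <- st$segments[st$segments$hap_id %in% rh &
                       st$segments$origin == "donor", ]
  complement <- function(d) {
    if (nrow(d) == 0)
      return(tibble(start = 0L, end = sim$L, length = sim$L))
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    gaps <- IRanges::gaps(ir, start = 1L, end = sim$L)
    tibble(start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps),
           length = IRanges::width(gaps))
  }
  if (!per_haplotype) return(complement(donor))
  out <- lapply(rh, function(h) {
    d <- complement(donor[donor$hap_id == h, ])
    d$hap_id <- h
    d
  })
  do.call(rbind, out)
}
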