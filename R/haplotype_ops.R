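# Reference (pure-R) implementations of the per-gamete operations that the
# compiled engine performs internally. They operate on a light `haplotype`
# object and exist so the sampling scheme can be inspected and checked
# against independent oracles at small scale.

#' Light haplotype object
#'
#' @param L Chromosome length in bp.
#' @param positions Sorted mutation positions carried by the haplotype.
#' @param classes Functional class per mutation (`"neutral"`,
#'   `"nonsynonymous"`, `"synonymous"`, `"marker"`).
#' @param s,h Selection and dominance coefficients per mutation.
#' @param segments Ancestry tibble (start, end, origin) tiling `[0, L)`.
#' @return A `haplotype` object.
#' @export
haplotype <- function(L, positions = integer(0), classes = character(0),
                      s = numeric(0), h = numeric(0), segments = NULL) {
  if (is.null(segments))
    segments <- tibble(start = 0L, end = as.integer(L), origin = "recipient")
  stopifnot(!is.unsorted(positions), all(positions >= 0 & positions < L))
  structure(list(L = as.integer(L), positions = as.integer(positions),
                 classes = classes, s = s, h = h,
                 segments = as_tibble(segments)),
            class = "haplotype")
}

#' Draw crossover breakpoints from a recombination map
#'
#' The crossover count is Poisson with mean equal to the total map length in
#' Morgans; breakpoint positions fall proportionally to the local rate.
#'
#' @param structure A [genome_structure()].
#' @param n Number of gametes to draw breakpoints for.
#' @return A list of `n` sorted integer vectors of breakpoint positions.
#' @export
draw_crossovers <- function(structure, n = 1) {
  map <- structure$recomb_map
  starts <- c(0L, head(map$end, -1))
  seg_m <- map$rate * (map$end - starts)
  tot <- sum(seg_m)
  lapply(seq_len(n), function(i) {
    if (tot <= 0) return(integer(0))
    k <- stats::rpois(1, tot)
    if (k == 0) return(integer(0))
    u <- runif(k, 0, tot)
    cum <- cumsum(seg_m)
    idx <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
    idx <- pmin(idx, length(seg_m))
    pos <- starts[idx] + floor((u - c(0, cum)[idx]) / map$rate[idx])
    sort(unique(as.integer(pmin(pmax(pos, 0), structure$length - 1))))
  })
}

#' Recombine two haplotypes into a gamete
#'
#' Deterministic given the breakpoints: the gamete copies `hap1` (or `hap2`
#' if `start_hap = 2`) up to the first breakpoint, then alternates. Mutations
#' and ancestry segments are inherited consistently from the same parental
#' haplotype over each interval.
#'
#' @param hap1,hap2 [haplotype()] objects on the same chromosome.
#' @param breakpoints Sorted breakpoint positions in (0, L).
#' @param start_hap Which haplotype the gamete starts on (1 or 2).
#' @return A [haplotype()].
#' @export
recombine_gamete <- function(hap1, hap2, breakpoints = integer(0),
                             start_hap = 1) {
  stopifnot(hap1$L == hap2$L)
  L <- hap1$L
  bounds <- c(0L, as.integer(breakpoints), L)
  haps <- list(hap1, hap2)
  cur <- start_hap
  keep_idx <- list(integer(0), integer(0))
  seg <- list()
  for (j in seq_len(length(bounds) - 1)) {
    from <- bounds[j]; to <- bounds[j + 1]
    hh <- haps[[cur]]
    keep_idx[[cur]] <- c(keep_idx[[cur]],
                         which(hh$positions >= from & hh$positions < to))
    ov <- hh$segments[hh$segments$end > from & hh$segments$start < to, ]
    if (nrow(ov) > 0) {
      ov$start <- pmax(ov$start, from); ov$end <- pmin(ov$end, to)
      seg[[length(seg) + 1]] <- ov
    }
    cur <- 3L - cur
  }
  seg <- do.call(rbind, seg)
  # merge adjacent segments with equal origin
  if (nrow(seg) > 1) {
    same <- c(FALSE, seg$origin[-1] == seg$origin[-nrow(seg)])
    grp <- cumsum(!same)
    seg <- tibble(start = tapply(seg$start, grp, min),
                  end = tapply(seg$end, grp, max),
                  origin = tapply(seg$origin, grp, function(x) x[1]))
    seg$start <- as.integer(seg$start); seg$end <- as.integer(seg$end)
    seg$origin <- as.character(seg$origin)
  }
  i1 <- keep_idx[[1]]; i2 <- keep_idx[[2]]
  pos <- c(hap1$positions[i1], hap2$positions[i2])
  ord <- order(pos)
  haplotype(L, pos[ord],
            c(hap1$classes[i1], hap2$classes[i2])[ord],
            c(hap1$s[i1], hap2$s[i2])[ord],
            c(hap1$h[i1], hap2$h[i2])[ord],
            seg)
}

#' Add new mutations to a gamete
#'
#' The number of new mutations is Poisson with mean `mu * L`; positions are
#' uniform. Mutations landing in exons are nonsynonymous with probability
#' `ns_syn_ratio / (1 + ns_syn_ratio)` (default 2.31 : 1 odds) and
#' synonymous otherwise; mutations outside exons are neutral. Nonsynonymous
#' mutations draw s from the DFE and h from the dominance model; positions
#' colliding with sites already on the gamete are redrawn (infinite-sites
#' within the haplotype).
#'
#' @param hap A [haplotype()].
#' @param structure A [genome_structure()] (provides exon intervals).
#' @param mu Per-bp per-gamete mutation rate.
#' @param dfe A [dfe_params()].
#' @param dominance A [dominance_model()].
#' @param ns_syn_ratio Nonsynonymous : synonymous targeting odds in exons.
#' @return The mutated [haplotype()].
#' @export
mutate_gamete <- function(hap, structure, mu, dfe = dfe_human(),
                          dominance = dominance_model("additive"),
                          ns_syn_ratio = 2.31) {
  n <- stats::rpois(1, mu * hap$L)
  if (n == 0) return(hap)
  ex <- exon_intervals(structure)
  ns_frac <- ns_syn_ratio / (1 + ns_syn_ratio)
  taken <- hap$positions
  pos <- integer(n); cls <- character(n); s <- numeric(n); h <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      p <- as.integer(floor(runif(1, 0, hap$L)))
      if (!(p %in% taken)) break
    }
    taken <- c(taken, p)
    exonic <- nrow(ex) > 0 &&
      any(p >= ex$start & p < ex$end)
    if (exonic && runif(1) < ns_frac) {
      cls[i] <- "nonsynonymous"
      s[i] <- sample_selection_coefficients(1, dfe)
      h[i] <- assign_dominance(s[i], dominance)
    } else {
      cls[i] <- if (exonic) "synonymous" else "neutral"
      s[i] <- 0; h[i] <- 0.5
    }
    pos[i] <- p
  }
  allpos <- c(hap$positions, pos)
  ord <- order(allpos)
  haplotype(hap$L, allpos[ord],
            c(hap$classes, cls)[ord], c(hap$s, s)[ord], c(hap$h, h)[ord],
            hap$segments)
}
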