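# Chromosome structure: genic elements plus a piecewise-constant
# recombination map. Coordinates are 0-based, half-open throughout.

#' Construct a genome structure
#'
#' A `genome_structure` bundles a chromosome length, an ordered set of
#' genomic elements (exon / intron / intergenic) that tile `[0, L)` without
#' gaps or overlaps, and a piecewise-constant recombination map covering the
#' same interval.
#'
#' @param length Chromosome length in base pairs.
#' @param elements A data frame with columns `kind` (one of `"exon"`,
#'   `"intron"`, `"intergenic"`), `start`, `end` (0-based, half-open).
#' @param recomb_map A data frame with columns `end` (ascending interval
#'   ends, the last equal to `length`) and `rate` (per-bp per-generation
#'   crossover probability), as returned by [uniform_recomb_map()] or
#'   [read_recomb_map()].
#' @return An object of class `genome_structure`.
#' @export
genome_structure <- function(length, elements, recomb_map) {
  length <- as.integer(length)
  stopifnot(length > 0)
  elements <- as_tibble(elements)
  if (!all(c("kind", "start", "end") %in% names(elements)))
    stop("`elements` needs columns kind, start, end")
  if (!all(elements$kind %in% c("exon", "intron", "intergenic")))
    stop("element kind must be exon, intron or intergenic")
  elements$start <- as.integer(elements$start)
  elements$end <- as.integer(elements$end)
  if (nrow(elements) == 0 || elements$start[1] != 0L ||
      elements$end[nrow(elements)] != length ||
      any(elements$end <= elements$start) ||
      (nrow(elements) > 1 &&
       any(elements$start[-1] != elements$end[-nrow(elements)])))
    stop("elements must tile [0, length) without gaps or overlaps")
  recomb_map <- as_tibble(recomb_map)
  if (!all(c("end", "rate") %in% names(recomb_map)))
    stop("`recomb_map` needs columns end, rate")
  if (any(recomb_map$rate < 0)) stop("recombination rates must be >= 0")
  if (is.unsorted(recomb_map$end, strictly = TRUE) ||
      recomb_map$end[nrow(recomb_map)] != length)
    stop("recombination map must have strictly increasing ends covering [0, length)")
  out <- list(length = length, elements = elements, recomb_map = recomb_map)
  class(out) <- "genome_structure"
  out
}

#' @export
print.genome_structure <- function(x, ...) {
  ex <- exon_intervals(x)
  cat("<genome_structure> L =", x$length, "bp;",
      nrow(x$elements), "elements;",
      sprintf("exonic fraction %.3f;", sum(ex$end - ex$start) / x$length),
      "mean r =", format(mean_map_rate(x), digits = 4), "per bp\n")
  invisible(x)
}

#' Uniform recombination map
#'
#' @param length Chromosome length in bp.
#' @param rate Per-bp per-generation crossover probability.
#' @return A map data frame usable in [genome_structure()].
#' @export
uniform_recomb_map <- function(length, rate) {
  stopifnot(length > 0, rate >= 0)
  tibble(end = as.integer(length), rate = rate)
}

#' Generate a random chromosome structure
#'
#' Lays out alternating intergenic regions and genes until the requested
#' length is reached; a gene is an exon followed, with probability
#' `exon_continue_prob` per step, by an (intron, exon) pair, so the first and
#' last element of every gene is an exon. Exon lengths are drawn from
#' Lognormal(meanlog = log 50, sdlog = log 2), intron lengths from
#' Lognormal(meanlog = log 100, sdlog = log 1.5), intergenic lengths from
#' Uniform(100, 5000). The final element is truncated at `length` and keeps
#' its kind. The median exon length is therefore exp(meanlog) = 50 bp and the
#' mean intergenic length (100 + 5000)/2 = 2550 bp under the defaults.
#'
#' @param length Chromosome length in bp.
#' @param seed Optional integer; when given, the structure is reproducible
#'   and the caller's RNG state is left untouched.
#' @param exon_meanlog,exon_sdlog Lognormal parameters for exon lengths.
#' @param intron_meanlog,intron_sdlog Lognormal parameters for intron lengths.
#' @param intergenic_min,intergenic_max Uniform bounds for intergenic lengths.
#' @param exon_continue_prob Probability of appending another (intron, exon)
#'   pair to the growing gene.
#' @param recomb_rate Per-bp crossover probability for the uniform map
#'   attached to the structure.
#' @return A [genome_structure()].
#' @export
generate_random_structure <- function(length, seed = NULL,
                                      exon_meanlog = log(50),
                                      exon_sdlog = log(2),
                                      intron_meanlog = log(100),
                                      intron_sdlog = log(1.5),
                                      intergenic_min = 100,
                                      intergenic_max = 5000,
                                      exon_continue_prob = 0.8,
                                      recomb_rate = 1e-8) {
  length <- as.integer(length)
  if (length <= 0) stop("`length` must be positive")
  if (exon_sdlog < 0 || intron_sdlog < 0)
    stop("lognormal sdlog parameters must be >= 0")
  if (intergenic_min <= 0 || intergenic_max < intergenic_min)
    stop("invalid intergenic length bounds")
  if (exon_continue_prob < 0 || exon_continue_prob >= 1)
    stop("`exon_continue_prob` must be in [0, 1)")

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }

  kinds <- character(0)
  lens <- integer(0)
  total <- 0L
  while (total < length) {
    block_k <- "intergenic"
    block_l <- as.integer(round(runif(1, intergenic_min, intergenic_max)))
    block_k <- c(block_k, "exon")
    block_l <- c(block_l, max(1L, as.integer(round(rlnorm(1, exon_meanlog, exon_sdlog)))))
    while (runif(1) < exon_continue_prob) {
      block_k <- c(block_k, "intron", "exon")
      block_l <- c(block_l,
                   max(1L, as.integer(round(rlnorm(1, intron_meanlog, intron_sdlog)))),
                   max(1L, as.integer(round(rlnorm(1, exon_meanlog, exon_sdlog)))))
    }
    kinds <- c(kinds, block_k)
    lens <- c(lens, block_l)
    total <- total + sum(block_l)
  }
  ends <- cumsum(as.numeric(lens))
  keep <- which(ends - lens < length)  # elements starting before L
  kinds <- kinds[keep]
  lens <- lens[keep]
  ends <- pmin(ends[keep], length)
  starts <- c(0, head(ends, -1))
  genome_structure(length,
                   tibble(kind = kinds, start = as.integer(starts),
                          end = as.integer(ends)),
                   uniform_recomb_map(length, recomb_rate))
}

#' Load exon annotations from a BED file
#'
#' Reads 0-based half-open exon intervals for a single chromosome.
#' Overlapping or bookended exon records are merged, and everything outside
#' exons is labelled intergenic: for loaded annotations the intron/intergenic
#' distinction collapses to a single neutral non-exonic class, which is all
#' the mutation model distinguishes.
#'
#' @param path Path to a BED file (at least chrom, start, end columns).
#' @param chrom_length Chromosome length in bp.
#' @param recomb_map Optional recombination map; defaults to a uniform
#'   1e-8 per-bp map.
#' @return A [genome_structure()].
#' @export
read_annotation <- function(path, chrom_length, recomb_map = NULL) {
  chrom_length <- as.integer(chrom_length)
  raw <- tryCatch(readLines(path), error = function(e) stop("cannot read ", path))
  keep <- !grepl("^(#|track|browser)", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- seq_along(raw)[keep]
  if (is.null(recomb_map)) recomb_map <- uniform_recomb_map(chrom_length, 1e-8)
  if (length(lines) == 0) {
    return(genome_structure(chrom_length,
                            tibble(kind = "intergenic", start = 0L,
                                   end = chrom_length),
                            recomb_map))
  }
  fields <- strsplit(lines, "[ \t]+")
  starts <- ends <- integer(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3)
      stop("malformed BED record at line ", lineno[i], ": fewer than 3 fields")
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      stop("malformed BED record at line ", lineno[i], ": bad interval")
    if (e > chrom_length)
      stop("BED record at line ", lineno[i], " extends past the chromosome end")
    starts[i] <- s; ends[i] <- e
  }
  merged <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  ms <- IRanges::start(merged) - 1L
  me <- IRanges::end(merged)
  kinds <- character(0); es <- integer(0); ee <- integer(0)
  pos <- 0L
  for (i in seq_along(ms)) {
    if (ms[i] > pos) {
      kinds <- c(kinds, "intergenic"); es <- c(es, pos); ee <- c(ee, ms[i])
    }
    kinds <- c(kinds, "exon"); es <- c(es, ms[i]); ee <- c(ee, me[i])
    pos <- me[i]
  }
  if (pos < chrom_length) {
    kinds <- c(kinds, "intergenic"); es <- c(es, pos); ee <- c(ee, chrom_length)
  }
  genome_structure(chrom_length,
                   tibble(kind = kinds, start = es, end = ee), recomb_map)
}

#' Read a piecewise-constant recombination map
#'
#' The file is whitespace-delimited text with two columns: the 0-based start
#' position of an interval and the per-bp crossover rate that applies from
#' that position to the next one (the last interval extends to `length`).
#' A single `(0, r)` row therefore yields a uniform map.
#'
#' @param path Path to the map file.
#' @param length Chromosome length in bp.
#' @return A map data frame with columns `end` and `rate`.
#' @export
read_recomb_map <- function(path, length) {
  length <- as.integer(length)
  tab <- read.table(path, header = FALSE, col.names = c("pos", "rate"))
  if (nrow(tab) == 0) stop("empty recombination map file")
  if (any(tab$rate < 0)) stop("negative recombination rate in map file")
  if (is.unsorted(tab$pos, strictly = TRUE))
    stop("map positions must be strictly increasing")
  if (tab$pos[1] != 0) stop("the first map position must be 0")
  if (tab$pos[nrow(tab)] >= length)
    stop("map positions must be smaller than the chromosome length")
  tibble(end = as.integer(c(tab$pos[-1], length)), rate = tab$rate)
}

#' Write / read a genome structure as TSV
#'
#' The element table is written as (kind, start, end); the map as
#' (pos, rate) in the [read_recomb_map()] dialect.
#'
#' @param structure A [genome_structure()].
#' @param elements_path,map_path Output file paths.
#' @export
write_structure <- function(structure, elements_path, map_path) {
  write.table(structure$elements, elements_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  map <- structure$recomb_map
  write.table(data.frame(pos = c(0L, head(map$end, -1)), rate = map$rate),
              map_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(structure)
}

#' @rdname write_structure
#' @param length Chromosome length in bp (read side).
#' @export
read_structure <- function(elements_path, map_path, length) {
  el <- read.table(elements_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  genome_structure(length, el, read_recomb_map(map_path, length))
}

# ---- internal helpers -----------------------------------------------------

exon_intervals <- function(structure) {
  el <- structure$elements
  el[el$kind == "exon", c("start", "end")]
}

# cumulative exonic bp strictly below position x (vectorized)
exonic_bp_upto <- function(x, ex) {
  if (nrow(ex) == 0) return(rep(0, length(x)))
  cum <- cumsum(ex$end - ex$start)
  idx <- findInterval(x, ex$start)
  out <- numeric(length(x))
  pos <- idx > 0
  full <- ifelse(idx > 1, cum[pmax(idx - 1, 1)], 0)
  part <- pmin(pmax(x - ex$start[pmax(idx, 1)], 0), (ex$end - ex$start)[pmax(idx, 1)])
  out[pos] <- full[pos] + part[pos]
  out
}

# cumulative Morgans below position x (vectorized)
morgans_upto <- function(x, map) {
  starts <- c(0L, head(map$end, -1))
  cum <- cumsum(map$rate * (map$end - starts))
  idx <- findInterval(x, starts)  # >= 1 for x >= 0
  full <- ifelse(idx > 1, cum[pmax(idx - 1, 1)], 0)
  full + map$rate[idx] * (x - starts[idx])
}

mean_map_rate <- function(structure) {
  morgans_upto(structure$length, structure$recomb_map) / structure$length
}

#' Partition a chromosome into analysis windows
#'
#' Non-overlapping windows of `size` bp tiling the chromosome (the terminal
#' window may be shorter). Exon density is exonic bp / window bp; the mean
#' recombination rate is the base-pair-weighted mean of the map over the
#' window.
#'
#' @param structure A [genome_structure()].
#' @param size Window size in bp (default 100 kb).
#' @return A tibble with columns `start`, `end`, `exon_density`, `mean_r`.
#' @export
make_windows <- function(structure, size = 100000) {
  stopifnot(size > 0)
  L <- structure$length
  starts <- seq(0L, L - 1L, by = as.integer(size))
  ends <- pmin(starts + as.integer(size), L)
  ex <- exon_intervals(structure)
  exbp <- exonic_bp_upto(ends, ex) - exonic_bp_upto(starts, ex)
  m <- morgans_upto(ends, structure$recomb_map) -
    morgans_upto(starts, structure$recomb_map)
  tibble(start = starts, end = ends,
         exon_density = exbp / (ends - starts),
         mean_r = m / (ends - starts))
}
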