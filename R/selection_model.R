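# Distribution of fitness effects, dominance models, and the
# multiplicative-within-locus fitness scheme.
#
# Sign convention: selection coefficients are stored signed (s <= 0, 0 for
# neutral classes). Fitness formulas consume |s|; the h(s) dominance
# relationship consumes signed s.

#' Gamma distribution of fitness effects
#'
#' New nonsynonymous mutations receive selection coefficients s = -G with
#' G ~ Gamma(shape, scale = |mean_s| / shape), so E[s] = `mean_s`.
#'
#' @param shape Gamma shape parameter (> 0).
#' @param mean_s Expected selection coefficient (< 0).
#' @return A `dfe_params` object.
#' @export
dfe_params <- function(shape, mean_s) {
  if (!is.numeric(shape) || shape <= 0) stop("`shape` must be > 0")
  if (!is.numeric(mean_s) || mean_s >= 0) stop("`mean_s` must be < 0")
  structure(list(shape = shape, mean_s = mean_s), class = "dfe_params")
}

#' @describeIn dfe_params Human preset: shape 0.186, E[s] = -0.01314833.
#' @export
dfe_human <- function() dfe_params(0.186, -0.01314833)

#' @describeIn dfe_params Arabidopsis preset: shape 0.185, E[s] = -0.00048655.
#' @export
dfe_arabidopsis <- function() dfe_params(0.185, -0.00048655)

#' Sample selection coefficients from a DFE
#'
#' @param n Number of draws.
#' @param dfe A [dfe_params()] object.
#' @return Numeric vector of strictly negative selection coefficients.
#' @export
sample_selection_coefficients <- function(n, dfe) {
  stopifnot(inherits(dfe, "dfe_params"))
  -rgamma(n, shape = dfe$shape, scale = abs(dfe$mean_s) / dfe$shape)
}

#' Dominance model
#'
#' Three modes: `"additive"` (h = 0.5 for every mutation), `"recessive"`
#' (h = 0), and `"hs"`, the hyperbolic relationship
#' `h(s) = hs_intercept / (1 - hs_slope * s)` for s <= 0, which anchors
#' h(0) at the intercept and decreases monotonically in |s|.
#'
#' The human relationship h(s) = 0.5 / (1 - 7071.07 s) is this form directly.
#' The Arabidopsis relationship h(s) = 1 / ((1/0.987) - 39547 s) is the same
#' hyperbola with intercept 0.987 and slope 0.987 * 39547.
#'
#' @param mode One of `"additive"`, `"recessive"`, `"hs"`.
#' @param hs_intercept h at s = 0 (only used for `"hs"`).
#' @param hs_slope Coefficient multiplying s in the denominator.
#' @return A `dominance_model` object.
#' @export
dominance_model <- function(mode = c("additive", "recessive", "hs"),
                            hs_intercept = 0.5, hs_slope = 7071.07) {
  mode <- match.arg(mode)
  if (mode == "hs") {
    if (hs_intercept <= 0 || hs_intercept > 1) stop("`hs_intercept` must be in (0, 1]")
    if (hs_slope <= 0) stop("`hs_slope` must be > 0")
  }
  structure(list(mode = mode,
                 hs_intercept = if (mode == "hs") hs_intercept else
                   switch(mode, additive = 0.5, recessive = 0),
                 hs_slope = if (mode == "hs") hs_slope else 0),
            class = "dominance_model")
}

#' @describeIn dominance_model Human h(s) preset: 0.5 / (1 - 7071.07 s).
#' @export
dominance_human_hs <- function() dominance_model("hs", 0.5, 7071.07)

#' @describeIn dominance_model Arabidopsis h(s) preset:
#'   1 / ((1/0.987) - 39547 s), i.e. intercept 0.987, slope 0.987 * 39547.
#' @export
dominance_arabidopsis_hs <- function() dominance_model("hs", 0.987, 0.987 * 39547)

#' Assign dominance coefficients
#'
#' @param s Selection coefficients (<= 0).
#' @param model A [dominance_model()].
#' @return Dominance coefficients in `[0, 1]`, vectorized over `s`.
#' @export
assign_dominance <- function(s, model) {
  stopifnot(inherits(model, "dominance_model"))
  if (any(s > 0)) stop("positive selection coefficients are out of scope (s must be <= 0)")
  switch(model$mode,
         additive = rep(0.5, length(s)),
         recessive = rep(0, length(s)),
         hs = model$hs_intercept / (1 - model$hs_slope * s))
}

#' Per-locus multiplicative fitness factor
#'
#' Under the within-locus multiplicative scheme, a heterozygote contributes
#' `1 - h|s|` and a homozygote `(1 - 0.5|s|)^2` (recessive homozygotes:
#' `1 - |s|`). This makes additive (h = 0.5) fitness depend only on the
#' number of deleterious allele copies, eliminating the `0.25 s^2`
#' heterozygote excess of the naive stacked-additive scheme, which computes
#' homozygotes as `1 - |s|` (available as `scheme = "textbook"`). Factors are
#' clipped at 0; |s| > 1 yields factor 0 with a warning.
#'
#' @param s Selection coefficients (<= 0, signed).
#' @param h Dominance coefficients.
#' @param copies Number of derived allele copies (0, 1 or 2), recycled
#'   against `s`.
#' @param model A [dominance_model()] (only its mode matters here).
#' @param scheme `"multiplicative"` (default) or `"textbook"`.
#' @return Multiplicative fitness factors, one per locus.
#' @export
locus_fitness_factor <- function(s, h, copies,
                                 model = dominance_model("additive"),
                                 scheme = c("multiplicative", "textbook")) {
  scheme <- match.arg(scheme)
  stopifnot(all(copies %in% 0:2))
  sa <- abs(s)
  if (any(sa > 1))
    warning("|s| > 1 at ", sum(sa > 1), " locus/loci; fitness factor clipped to 0")
  n <- max(length(s), length(copies))
  s <- rep_len(s, n); h <- rep_len(h, n); sa <- rep_len(sa, n)
  copies <- rep_len(copies, n)
  hom <- if (model$mode == "recessive" || scheme == "textbook") 1 - sa
         else (1 - 0.5 * sa)^2
  f <- ifelse(copies == 0, 1, ifelse(copies == 1, 1 - h * sa, hom))
  pmax(f, 0)
}

#' Individual fitness across loci
#'
#' Fitness is the product of per-locus factors over segregating selected
#' mutations (globally fixed variants are assumed pruned). Under the
#' additive mode the result depends only on the total number of deleterious
#' allele copies, regardless of how they are distributed over zygosity
#' configurations.
#'
#' @inheritParams locus_fitness_factor
#' @return A single fitness value in `[0, 1]`.
#' @export
individual_fitness <- function(s, h, copies,
                               model = dominance_model("additive"),
                               scheme = c("multiplicative", "textbook")) {
  if (length(s) == 0) return(1)
  prod(locus_fitness_factor(s, h, copies, model, scheme))
}

#' X-linked fitness factors with dosage compensation
#'
#' Females use the autosomal factors. Hemizygous males carrying the derived
#' allele receive the female homozygote factor, so male carriers and female
#' homozygotes have equal fitness; in the additive model heterozygous
#' females are intermediate.
#'
#' @inheritParams locus_fitness_factor
#' @param sex `"female"` or `"male"`.
#' @return Per-locus fitness factors.
#' @export
x_fitness_factor <- function(s, h, copies, sex = c("female", "male"),
                             model = dominance_model("additive")) {
  sex <- match.arg(sex)
  if (sex == "female") return(locus_fitness_factor(s, h, copies, model))
  if (any(copies > 1)) stop("hemizygous males cannot carry 2 copies at an X locus")
  # a carrier male gets the female homozygote factor
  locus_fitness_factor(s, h, ifelse(copies == 1, 2, 0), model)
}

#' @describeIn x_fitness_factor Product over loci for one individual.
#' @export
x_fitness <- function(s, h, copies, sex = c("female", "male"),
                      model = dominance_model("additive")) {
  if (length(s) == 0) return(1)
  prod(x_fitness_factor(s, h, copies, sex, model))
}
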