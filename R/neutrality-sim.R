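# Coalescent null distributions for SFS-based neutrality tests and
# empirical, Bonferroni-adjusted p-values.

#' @useDynLib PopGenFlux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Demographic models for the coalescent simulator
#'
#' Constructors for the three supported population-size histories, all in
#' coalescent units (time in 2N0 generations, sizes relative to the
#' present-day size).
#'
#' * `equilibriumModel()`: constant size.
#' * `growthModel(alpha)`: exponential growth at rate `alpha` (the size at
#'   time `t` backwards is `exp(-alpha * t)`), i.e. the population has been
#'   growing toward the present.
#' * `bottleneckModel(tBottleneck, bottleneckSize, tRecovery,
#'   ancestralSize)`: three-epoch history — present size 1 until
#'   `tBottleneck`, then `bottleneckSize` until `tRecovery`, then
#'   `ancestralSize`.
#'
#' The growth and bottleneck parameter values are study inputs (typically
#' cited from demographic inference literature), not package defaults.
#'
#' @param alpha exponential growth rate (>= 0)
#' @param tBottleneck,tRecovery epoch change times, `0 < tBottleneck <
#'   tRecovery`
#' @param bottleneckSize,ancestralSize relative sizes (> 0)
#' @return a [DemographicModel-class]
#' @export
equilibriumModel <- function() {
  new("DemographicModel", kind = "equilibrium",
      epochs = data.frame(start = 0, size = 1, growth = 0),
      params = numeric())
}

#' @rdname equilibriumModel
#' @export
growthModel <- function(alpha) {
  stopifnot(alpha >= 0)
  new("DemographicModel", kind = "exponential_growth",
      epochs = data.frame(start = 0, size = 1, growth = alpha),
      params = c(alpha = alpha))
}

#' @rdname equilibriumModel
#' @export
bottleneckModel <- function(tBottleneck, bottleneckSize, tRecovery,
                            ancestralSize) {
  stopifnot(tBottleneck > 0, tRecovery > tBottleneck,
            bottleneckSize > 0, ancestralSize > 0)
  new("DemographicModel", kind = "three_epoch_bottleneck",
      epochs = data.frame(start = c(0, tBottleneck, tRecovery),
                          size = c(1, bottleneckSize, ancestralSize),
                          growth = c(0, 0, 0)),
      params = c(tBottleneck = tBottleneck, bottleneckSize = bottleneckSize,
                 tRecovery = tRecovery, ancestralSize = ancestralSize))
}

# rebuild a model of the same kind from a (partially) new parameter vector
updateModel <- function(model, params) {
  p <- model@params
  p[names(params)] <- params
  switch(model@kind,
         equilibrium = equilibriumModel(),
         exponential_growth = growthModel(p[["alpha"]]),
         three_epoch_bottleneck = bottleneckModel(
           p[["tBottleneck"]], p[["bottleneckSize"]],
           p[["tRecovery"]], p[["ancestralSize"]]),
         stop("unknown model kind"))
}

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel:", object@kind, "\n")
  print(object@epochs, row.names = FALSE)
})

#' Build a simulation configuration
#'
#' @param n sample size
#' @param L locus length in sites
#' @param thetaPerSite population mutation rate per site
#' @param R population recombination parameter for the region
#' @param model a [DemographicModel-class]
#' @param replicates default replicate count for null distributions
#' @return a [SimulationConfig-class]
#' @export
simulationConfig <- function(n, L, thetaPerSite, R = 0,
                             model = equilibriumModel(),
                             replicates = 10000L) {
  new("SimulationConfig", n = as.integer(n), L = as.integer(L),
      thetaPerSite = thetaPerSite, R = R, model = model,
      replicates = as.integer(replicates))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: n =", object@n, ", L =", object@L,
      ", theta/site =", object@thetaPerSite, ", R =", object@R,
      ", model =", object@model@kind,
      ", replicates =", object@replicates, "\n")
})

#' Population recombination parameter with X-linkage scaling
#'
#' `R = 3 Ne r L` for X-linked loci (three X chromosomes per breeding
#' pair), `R = 4 Ne r L` for autosomes.
#'
#' @param Ne effective population size
#' @param rPerBp recombination rate per base pair per generation
#' @param L region length in base pairs
#' @param xLinked X-linked scaling (default `TRUE`)
#' @return numeric R
#' @examples
#' effectiveR(1e6, 3.34e-8, 1500)        # X-linked: 150.3
#' @export
effectiveR <- function(Ne, rPerBp, L, xLinked = TRUE) {
  stopifnot(Ne > 0, rPerBp >= 0, L > 0)
  (if (xLinked) 3 else 4) * Ne * rPerBp * L
}

#' Simulate one coalescent replicate
#'
#' Draws one ancestral-recombination-graph realization for the configured
#' sample: lineages coalesce at rate `k(k-1)/2` (time-rescaled by the
#' demographic model), recombination splits ancestral material at rate
#' proportional to `R`, and infinite-sites mutations are placed on the
#' marginal genealogies at rate `theta_locus / 2` per unit time. Mutations
#' are returned as a 0/1 haplotype matrix (0 = ancestral) so derived-allele
#' counts are column sums.
#'
#' @param cfg a [SimulationConfig-class]
#' @param thetaPerSite optionally override the configured theta (used for
#'   prior draws)
#' @param model optionally override the configured demographic model
#' @return list with `positions` (in `[0,1)`), `genotypes` (n x S 0/1
#'   matrix), `derivedCounts`, `S`
#' @export
simulateReplicate <- function(cfg, thetaPerSite = NULL, model = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  th <- if (is.null(thetaPerSite)) cfg@thetaPerSite else thetaPerSite
  mod <- if (is.null(model)) cfg@model else model
  res <- sim_arg(cfg@n, th * cfg@L, cfg@R,
                 mod@epochs$start, mod@epochs$size, mod@epochs$growth)
  g <- res$genotypes
  list(positions = res$positions, genotypes = g,
       derivedCounts = if (ncol(g)) colSums(g) else integer(),
       S = ncol(g))
}

#' Summary statistics of a simulated replicate
#'
#' Computes S, total pi, Tajima's D and (unnormalized) Fay and Wu's H from
#' the 0/1 haplotype matrix of [simulateReplicate()]. `thetaPi` from the
#' spectrum equals pairwise pi exactly.
#'
#' @param sim output of [simulateReplicate()]
#' @param n sample size
#' @return named numeric vector `S`, `pi`, `D`, `H`
#' @export
simStats <- function(sim, n) {
  i <- sim$derivedCounts
  piTotal <- sum(2 * i * (n - i)) / (n * (n - 1))
  D <- if (sim$S > 0) tajimasD(sim$S, piTotal, n) else NA_real_
  H <- fayWuH(i, n)$H
  c(S = sim$S, pi = piTotal, D = as.numeric(D), H = H)
}

#' Simulate a null distribution of a statistic
#'
#' Per replicate: draws any parameters listed in `priors` from independent
#' uniform distributions, simulates under the (possibly updated) model, and
#' evaluates `statisticFn`. Replicates where the statistic is undefined
#' (e.g. Tajima's D at S = 0) are recorded and excluded from the returned
#' values (skip-and-record policy), or re-drawn when
#' `undefined = "resample"`.
#'
#' @param cfg a [SimulationConfig-class]
#' @param statisticFn function(sim, n) returning one numeric value
#' @param priors named list of `c(lo, hi)` uniform bounds; recognized
#'   names: `theta_per_site` plus the demographic parameter names of the
#'   model kind (`alpha`, `tBottleneck`, `bottleneckSize`, `tRecovery`,
#'   `ancestralSize`)
#' @param replicates overrides `cfg@replicates`
#' @param undefined `"skip"` (default) or `"resample"`
#' @return object of class `nullDistribution`: list with sorted `values`,
#'   `nUndefined`, `draws` (data.frame of parameter draws), `replicates`
#' @export
nullDistribution <- function(cfg, statisticFn, priors = NULL,
                             replicates = NULL,
                             undefined = c("skip", "resample")) {
  undefined <- match.arg(undefined)
  reps <- if (is.null(replicates)) cfg@replicates else as.integer(replicates)
  drawOne <- function() {
    if (is.null(priors)) return(list(theta = NULL, model = NULL, par = NULL))
    par <- vapply(priors, function(b) runif(1, b[1], b[2]), numeric(1))
    theta <- if ("theta_per_site" %in% names(par))
      par[["theta_per_site"]] else NULL
    dem <- par[setdiff(names(par), "theta_per_site")]
    model <- if (length(dem)) updateModel(cfg@model, dem) else NULL
    list(theta = theta, model = model, par = par)
  }
  values <- numeric(0)
  draws <- list()
  nUndefined <- 0L
  i <- 0L
  guard <- 0L
  while (i < reps) {
    guard <- guard + 1L
    if (guard > 50L * reps) stop("all replicates yield undefined statistics")
    d <- drawOne()
    sim <- simulateReplicate(cfg, d$theta, d$model)
    v <- statisticFn(sim, cfg@n)
    if (is.na(v)) {
      nUndefined <- nUndefined + 1L
      if (undefined == "skip") i <- i + 1L
      next
    }
    values <- c(values, v)
    if (!is.null(d$par)) draws[[length(draws) + 1L]] <- d$par
    i <- i + 1L
  }
  if (!length(values)) stop("all replicates yield undefined statistics")
  structure(list(values = sort(values), nUndefined = nUndefined,
                 draws = if (length(draws)) as.data.frame(do.call(rbind,
                                                                  draws))
                         else NULL,
                 replicates = reps),
            class = "nullDistribution")
}

#' @export
print.nullDistribution <- function(x, ...) {
  cat("nullDistribution:", length(x$values), "defined values (",
      x$nUndefined, "undefined )\n")
  print(summary(x$values))
  invisible(x)
}

#' Empirical p-value of an observed statistic
#'
#' Proportion of null values equal to or more extreme than the observed
#' value: `<=` for the lower tail (negative statistics), `>=` for the
#' upper tail. A zero count is reported as `"< 1/N"`.
#'
#' @param observed observed statistic
#' @param nullValues numeric vector (a `nullDistribution` is also accepted)
#' @param tail `"lower"` or `"upper"`
#' @return list with `p` (count/N; 0 when no null value is as extreme),
#'   `count`, `n`, `display` (the report rendering, e.g. `"< 0.0002"`)
#' @export
empiricalPValue <- function(observed, nullValues,
                            tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (inherits(nullValues, "nullDistribution"))
    nullValues <- nullValues$values
  if (!length(nullValues)) stop("empty null distribution")
  cnt <- if (tail == "lower") sum(nullValues <= observed)
         else sum(nullValues >= observed)
  N <- length(nullValues)
  list(p = cnt / N, count = cnt, n = N,
       display = if (cnt == 0L) paste0("< ", format(1 / N))
                 else format(cnt / N))
}

#' Bonferroni-adjusted decisions for a family of tests
#'
#' Per-test cutoff `familyAlpha / k`; a test rejects only when its p-value
#' is strictly below the cutoff (a p-value exactly at the cutoff does not
#' reject).
#'
#' @param pValues numeric vector
#' @param familyAlpha family-wise level (default 0.025, i.e. a two-sided
#'   0.05 split over the two tails)
#' @param k number of tests in the family (default `length(pValues)`)
#' @return data.frame with `p`, `cutoff`, `reject`
#' @export
bonferroni <- function(pValues, familyAlpha = 0.025, k = length(pValues)) {
  stopifnot(k >= 1)
  cutoff <- familyAlpha / k
  data.frame(p = pValues, cutoff = cutoff, reject = pValues < cutoff)
}
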