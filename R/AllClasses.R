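#' @import methods
NULL

#' Tweedie (compound Poisson-Gamma) parameter set
#'
#' Holds the three parameters of the power-variance-function Tweedie family
#' restricted to the compound Poisson-Gamma range \eqn{1 < \rho < 2}: the mean
#' \eqn{\mu} (counts), the dispersion \eqn{\Phi > 0}, and the power index
#' \eqn{\rho}. The implied variance is \eqn{\Phi \mu^{\rho}}; for every
#' parameter set used by the simulator this exceeds the mean, i.e. the model
#' is overdispersed.
#'
#' @slot mu positive mean expression level (counts).
#' @slot phi positive dispersion parameter.
#' @slot rho power index, strictly inside (1, 2).
#'
#' @export
setClass("TweedieParams",
  representation(mu = "numeric", phi = "numeric", rho = "numeric"))

setValidity("TweedieParams", function(object) {
  msg <- character()
  if (length(object@mu) != 1L || !is.finite(object@mu) || object@mu <= 0)
    msg <- c(msg, "'mu' must be a single positive finite number")
  if (length(object@phi) != 1L || !is.finite(object@phi) || object@phi <= 0)
    msg <- c(msg, "'phi' must be a single positive finite number")
  if (length(object@rho) != 1L || !is.finite(object@rho) ||
      object@rho <= 1 || object@rho >= 2)
    msg <- c(msg, "'rho' must lie strictly inside (1, 2)")
  if (length(msg)) msg else TRUE
})

#' @param mu positive mean expression level.
#' @param phi positive dispersion.
#' @param rho power index in (1, 2).
#' @rdname TweedieParams-class
#' @return `TweedieParams()` returns a validated `TweedieParams` object.
#' @examples
#' p <- TweedieParams(mu = 20, phi = 2, rho = 1.2)
#' tweedieVariance(p)
#' @export
TweedieParams <- function(mu, phi, rho = 1.2) {
  new("TweedieParams", mu = as.numeric(mu), phi = as.numeric(phi),
      rho = as.numeric(rho))
}

setMethod("show", "TweedieParams", function(object) {
  cat(sprintf("TweedieParams: mu=%g, phi=%g, rho=%g (variance %.4g)\n",
              object@mu, object@phi, object@rho,
              object@phi * object@mu^object@rho))
})

#' Per-class simulation scheme for one gene class
#'
#' Pairs the Tweedie parameters used for the experimental and control groups
#' of one gene class (`"null"`, `"up"` or `"down"`). Null genes must use
#' identical parameters in both groups.
#'
#' @slot label class label, one of `"null"`, `"up"`, `"down"`.
#' @slot experimental `TweedieParams` for experimental-group samples.
#' @slot control `TweedieParams` for control-group samples.
#'
#' @export
setClass("GeneClassSpec",
  representation(label = "character", experimental = "TweedieParams",
                 control = "TweedieParams"))

setValidity("GeneClassSpec", function(object) {
  msg <- character()
  if (!(object@label %in% c("null", "up", "down")))
    msg <- c(msg, "label must be one of 'null', 'up', 'down'")
  if (object@label == "null") {
    same <- isTRUE(all.equal(object@experimental@mu, object@control@mu)) &&
      isTRUE(all.equal(object@experimental@phi, object@control@phi)) &&
      isTRUE(all.equal(object@experimental@rho, object@control@rho))
    if (!same)
      msg <- c(msg, "null genes must use identical parameters in both groups")
  }
  if (length(msg)) msg else TRUE
})

#' @param label gene class label.
#' @param experimental,control `TweedieParams` for each group.
#' @rdname GeneClassSpec-class
#' @return `GeneClassSpec()` returns a validated `GeneClassSpec`.
#' @export
GeneClassSpec <- function(label, experimental, control) {
  new("GeneClassSpec", label = label, experimental = experimental,
      control = control)
}

#' Simulation configuration
#'
#' Full parameterization of one simulated two-group experiment: the number of
#' null / up-regulated / down-regulated genes, the number of biological
#' replicates per group, the number of repetitions used by the benchmark, the
#' seed, the per-class Tweedie schemes, and whether draws are rounded to
#' integer counts.
#'
#' Defaults mirror the study design this package re-creates: 9000 null genes,
#' 500 up- and 500 down-regulated genes, K replicates per group with K drawn
#' from \{2,...,5\}, and 30 repetitions per condition.
#'
#' @slot nNull,nUp,nDown gene counts per class.
#' @slot kReplicates samples per group (>= 2).
#' @slot nRepetitions repetitions per condition (used by [runBenchmark()]).
#' @slot seed integer seed.
#' @slot classSpecs named list of three [GeneClassSpec-class] objects
#'   (`null`, `up`, `down`).
#' @slot roundToInteger round draws to nearest nonnegative integer counts.
#'
#' @export
setClass("SimulationConfig",
  representation(nNull = "integer", nUp = "integer", nDown = "integer",
                 kReplicates = "integer", nRepetitions = "integer",
                 seed = "integer", classSpecs = "list",
                 roundToInteger = "logical"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nNull < 0L || object@nUp < 0L || object@nDown < 0L)
    msg <- c(msg, "gene counts must be nonnegative")
  if (object@nNull + object@nUp + object@nDown < 1L)
    msg <- c(msg, "at least one gene is required")
  if (object@kReplicates < 2L)
    msg <- c(msg, "kReplicates must be >= 2 (each group needs >= 2 samples)")
  if (object@nRepetitions < 1L)
    msg <- c(msg, "nRepetitions must be >= 1")
  if (!identical(sort(names(object@classSpecs)), c("down", "null", "up")))
    msg <- c(msg, "classSpecs must be a named list with 'null', 'up', 'down'")
  if (length(msg)) msg else TRUE
})

#' Default per-class Tweedie schemes
#'
#' The study design: null genes use (rho=1.2, mu=20, phi=2) in both groups;
#' up-regulated genes keep the experimental group at (20, 2) and raise the
#' control group to (mu=40, phi=2.2); down-regulated genes lower the control
#' group to (mu=10, phi=1.8). The shifted parameters sit in the *control*
#' group, matching the generating scheme this package re-creates; class labels
#' record the scheme name, not a sign convention.
#'
#' @return named list of three [GeneClassSpec-class] objects.
#' @export
defaultClassSpecs <- function() {
  base <- TweedieParams(mu = 20, phi = 2, rho = 1.2)
  list(
    null = GeneClassSpec("null", base, base),
    up   = GeneClassSpec("up",   base, TweedieParams(40, 2.2, 1.2)),
    down = GeneClassSpec("down", base, TweedieParams(10, 1.8, 1.2)))
}

#' @param nNull,nUp,nDown gene counts per class.
#' @param kReplicates biological replicates per group.
#' @param nRepetitions repetitions per condition.
#' @param seed integer seed.
#' @param classSpecs named list of `GeneClassSpec` objects; see
#'   [defaultClassSpecs()].
#' @param roundToInteger logical; round Tweedie draws to integer counts.
#' @rdname SimulationConfig-class
#' @return `SimulationConfig()` returns a validated `SimulationConfig`.
#' @examples
#' cfg <- SimulationConfig(kReplicates = 2, seed = 1)
#' cfg
#' @export
SimulationConfig <- function(nNull = 9000, nUp = 500, nDown = 500,
                             kReplicates = 2, nRepetitions = 30,
                             seed = 1, classSpecs = defaultClassSpecs(),
                             roundToInteger = TRUE) {
  new("SimulationConfig", nNull = as.integer(nNull), nUp = as.integer(nUp),
      nDown = as.integer(nDown), kReplicates = as.integer(kReplicates),
      nRepetitions = as.integer(nRepetitions), seed = as.integer(seed),
      classSpecs = classSpecs, roundToInteger = isTRUE(roundToInteger))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d null + %d up + %d down genes, K=%d per group\n",
    object@nNull, object@nUp, object@nDown, object@kReplicates))
  cat(sprintf("  repetitions=%d, seed=%d, roundToInteger=%s\n",
              object@nRepetitions, object@seed, object@roundToInteger))
})

#' Result of one differential-expression statistic
#'
#' Per-gene evidence from one DEA method: a nonnegative ranking score (larger
#' means stronger evidence of differential expression), an optional two-sided
#' p-value (absent for the entropy-based DEF statistic), the binary call under
#' the recorded decision rule, and the rule itself.
#'
#' @slot method method name.
#' @slot geneIds gene identifiers.
#' @slot score per-gene evidence score (NA when a gene was skipped).
#' @slot pValue per-gene p-value in \[0,1\] or all-NA when the method yields
#'   none.
#' @slot called logical DE call per gene.
#' @slot decisionRule list describing the rule: `list(type="alpha",alpha=...)`
#'   or `list(type="topP", P=...)`, or `list(type="none")` before calling.
#'
#' @export
setClass("DEAResult",
  representation(method = "character", geneIds = "character",
                 score = "numeric", pValue = "numeric", called = "logical",
                 decisionRule = "list"))

setValidity("DEAResult", function(object) {
  n <- length(object@geneIds)
  msg <- character()
  if (length(object@score) != n || length(object@pValue) != n ||
      length(object@called) != n)
    msg <- c(msg, "score, pValue and called must match geneIds in length")
  p <- object@pValue[!is.na(object@pValue)]
  if (length(p) && (any(p < 0) || any(p > 1)))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

.DEAResult <- function(method, geneIds, score, pValue = NULL, called = NULL,
                       decisionRule = list(type = "none")) {
  n <- length(geneIds)
  if (is.null(pValue)) pValue <- rep(NA_real_, n)
  if (is.null(called)) called <- rep(FALSE, n)
  new("DEAResult", method = method, geneIds = as.character(geneIds),
      score = as.numeric(score), pValue = as.numeric(pValue),
      called = as.logical(called), decisionRule = decisionRule)
}

setMethod("show", "DEAResult", function(object) {
  cat(sprintf("DEAResult '%s': %d genes, %d called",
              object@method, length(object@geneIds), sum(object@called)))
  rule <- object@decisionRule
  if (identical(rule$type, "alpha"))
    cat(sprintf(" (p < %g)", rule$alpha))
  else if (identical(rule$type, "topP"))
    cat(sprintf(" (top %d by score)", rule$P))
  cat("\n")
})

#' Coerce a DEAResult to a data.frame
#'
#' @param x a [DEAResult-class].
#' @param ... ignored.
#' @return data.frame with columns `gene_id`, `score`, `p_value`, `called`.
#' @export
setMethod("as.data.frame", "DEAResult", function(x, ...) {
  data.frame(gene_id = x@geneIds, score = x@score, p_value = x@pValue,
             called = x@called, stringsAsFactors = FALSE)
})

#' Empirical-Bayes moderated variance model
#'
#' Hyperparameters and per-gene variances of the hierarchical variance model
#' behind the moderated t-statistic: the prior degrees of freedom `d0` and
#' prior variance `s0Sq`, the per-gene residual degrees of freedom and
#' residual variances, and the shrunken (posterior) variances
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d_j s_j^2) / (d_0 + d_j)}.
#'
#' @slot d0 prior degrees of freedom (possibly large when variances are
#'   homogeneous; never infinite).
#' @slot s0Sq prior variance.
#' @slot dj per-gene residual degrees of freedom.
#' @slot sjSq per-gene residual variance.
#' @slot sTildeSq per-gene shrunken variance.
#'
#' @export
setClass("ModeratedVarianceModel",
  representation(d0 = "numeric", s0Sq = "numeric", dj = "numeric",
                 sjSq = "numeric", sTildeSq = "numeric"))

setMethod("show", "ModeratedVarianceModel", function(object) {
  cat(sprintf("ModeratedVarianceModel: d0=%.4g, s0^2=%.4g, %d genes\n",
              object@d0, object@s0Sq, length(object@sjSq)))
})

#' Entropy-weight-method composite scores
#'
#' Metric weights and 0-100 composite scores produced by [ewmComposite()].
#'
#' @slot directions named character vector, `"benefit"` or `"cost"` per
#'   metric.
#' @slot weights named nonnegative weights summing to 1.
#' @slot composite named per-method composite scores on a 0-100 scale.
#' @slot normalized the min-max normalized decision matrix used internally.
#'
#' @export
setClass("EWMResult",
  representation(directions = "character", weights = "numeric",
                 composite = "numeric", normalized = "matrix"))

setValidity("EWMResult", function(object) {
  msg <- character()
  if (abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must sum to 1")
  if (any(object@weights < 0))
    msg <- c(msg, "weights must be nonnegative")
  if (any(object@composite < -1e-9 | object@composite > 100 + 1e-9))
    msg <- c(msg, "composite scores must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EWMResult", function(object) {
  cat("EWMResult\n  weights:\n")
  print(round(object@weights, 4))
  cat("  composite (0-100):\n")
  print(round(sort(object@composite, decreasing = TRUE), 2))
})

#' Benchmark configuration
#'
#' Describes a full benchmark run: the simulation settings, the methods to
#' compare, the grid of replicate numbers K, the number of repetitions per K,
#' the decision rules, and the master seed from which every repetition's seed
#' is derived.
#'
#' @slot simulation a [SimulationConfig-class] (its `kReplicates` and `seed`
#'   are overridden per grid cell).
#' @slot methods character vector of method names; see [deaMethods()].
#' @slot kGrid integer vector of replicates-per-group values.
#' @slot nRepetitions repetitions per K.
#' @slot alpha significance level for p-value methods.
#' @slot topP number of top-scoring genes called for score-only methods
#'   (the DEF statistic).
#' @slot masterSeed integer master seed.
#'
#' @export
setClass("BenchmarkConfig",
  representation(simulation = "SimulationConfig", methods = "character",
                 kGrid = "integer", nRepetitions = "integer",
                 alpha = "numeric", topP = "integer", masterSeed = "integer"))

setValidity("BenchmarkConfig", function(object) {
  msg <- character()
  bad <- setdiff(object@methods, deaMethods())
  if (length(bad))
    msg <- c(msg, paste0("unknown methods: ", paste(bad, collapse = ", ")))
  if (!length(object@kGrid) || any(object@kGrid < 2L))
    msg <- c(msg, "kGrid must be nonempty with every K >= 2")
  if (object@nRepetitions < 1L)
    msg <- c(msg, "nRepetitions must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (object@topP < 1L)
    msg <- c(msg, "topP must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param simulation a [SimulationConfig-class].
#' @param methods method names; defaults to all of [deaMethods()].
#' @param kGrid integer vector of replicate numbers.
#' @param nRepetitions repetitions per K.
#' @param alpha significance level for p-value methods.
#' @param topP top-P rule size for score-only methods.
#' @param masterSeed master seed.
#' @rdname BenchmarkConfig-class
#' @return `BenchmarkConfig()` returns a validated `BenchmarkConfig`.
#' @export
BenchmarkConfig <- function(simulation = SimulationConfig(),
                            methods = deaMethods(), kGrid = 2:5,
                            nRepetitions = 30, alpha = 0.05, topP = 1000,
                            masterSeed = 1) {
  new("BenchmarkConfig", simulation = simulation, methods = methods,
      kGrid = as.integer(kGrid), nRepetitions = as.integer(nRepetitions),
      alpha = as.numeric(alpha), topP = as.integer(topP),
      masterSeed = as.integer(masterSeed))
}

setMethod("show", "BenchmarkConfig", function(object) {
  cat(sprintf("BenchmarkConfig: %d methods, K in {%s}, %d repetitions\n",
              length(object@methods),
              paste(object@kGrid, collapse = ","), object@nRepetitions))
})

#' Aggregated benchmark report
#'
#' Output of [runBenchmark()]: the per-repetition metric table, the per
#' (method, K) aggregate (mean, sd and contributing repetition count per
#' metric), the per-K entropy-weight composite scores, and provenance.
#'
#' @slot perRepetition data.frame, one row per (method, K, repetition).
#' @slot summary data.frame, one row per (method, K) with `<metric>_mean`,
#'   `<metric>_sd`, `<metric>_n` columns.
#' @slot ewm named list of [EWMResult-class] objects, one per K.
#' @slot config the [BenchmarkConfig-class] used.
#'
#' @export
setClass("BenchmarkReport",
  representation(perRepetition = "data.frame", summary = "data.frame",
                 ewm = "list", config = "BenchmarkConfig"))

setMethod("show", "BenchmarkReport", function(object) {
  cat(sprintf("BenchmarkReport: %d methods x K in {%s} x %d repetitions\n",
              length(object@config@methods),
              paste(object@config@kGrid, collapse = ","),
              object@config@nRepetitions))
  cat("  use benchmarkSummary(), benchmarkMetrics(), benchmarkScores()\n")
})

#' Accessors for benchmark reports
#'
#' @param object a [BenchmarkReport-class].
#' @return `benchmarkMetrics()` the per-repetition metric table;
#'   `benchmarkSummary()` the per (method, K) aggregate table;
#'   `benchmarkScores()` the named list of per-K [EWMResult-class] objects.
#' @export
benchmarkMetrics <- function(object) object@perRepetition

#' @rdname benchmarkMetrics
#' @export
benchmarkSummary <- function(object) object@summary

#' @rdname benchmarkMetrics
#' @export
benchmarkScores <- function(object) object@ewm
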