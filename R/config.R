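#' Run configuration
#'
#' Bundles every tunable of a full analysis run: the factorization rank and
#' regularization weight, iteration budget, co-expression threshold, the
#' ordered association-view names, and the grids used by rank selection and
#' the Fmax threshold sweep. Defaults follow the method's standard
#' operating point (k = 52, alpha = 1, 100 iterations, rank grid 40..64 in
#' steps of 4, alpha sweep 0.1..1.9 in steps of 0.2).
#'
#' @param k factorization rank (positive integer).
#' @param alpha nonnegative regularization weight shared across views.
#' @param iterations maximum number of update iterations (default 100).
#' @param seed integer RNG seed recorded with every randomized operation.
#' @param coexprThreshold Pearson threshold in [0, 1] for co-expression
#'   edges and the expression view.
#' @param viewList ordered, unique names of the association views.
#' @param thresholdGrid strictly increasing score thresholds in [0, 1] for
#'   the Fmax sweep.
#' @param kGrid ordered candidate ranks for instability-based selection.
#' @param alphaGrid regularization weights for the sensitivity sweep.
#' @param tau number of random restarts per rank in the instability curve.
#' @param theta propagation mixing parameter in (0, 1) for the
#'   label-propagation baselines.
#' @param logExpression whether expression matrices are log2(x+1)
#'   transformed before correlation.
#' @param useAbsoluteCorrelation whether co-expression edges use |r|
#'   instead of dropping negative correlations.
#' @param updateVariant "standard" Lee-Seung multiplicative steps or the
#'   damped "sqrt" variant (elementwise square root of the update ratio).
#' @return A validated list of class "RunConfig".
#' @examples
#' cfg <- runConfig(k = 6, alpha = 1)
#' cfg$iterations
#' @export
runConfig <- function(k = 52L, alpha = 1, iterations = 100L, seed = 1L,
                      coexprThreshold = 0.5,
                      viewList = c("coexpression", "disease"),
                      thresholdGrid = seq(0, 1, by = 0.01),
                      kGrid = seq(40L, 64L, by = 4L),
                      alphaGrid = seq(0.1, 1.9, by = 0.2),
                      tau = 10L, theta = 0.5,
                      logExpression = FALSE,
                      useAbsoluteCorrelation = FALSE,
                      updateVariant = c("standard", "sqrt")) {
  updateVariant <- match.arg(updateVariant)
  k <- as.integer(k); iterations <- as.integer(iterations)
  tau <- as.integer(tau); kGrid <- as.integer(kGrid)
  if (k < 1L) stop("k must be a positive integer")
  if (alpha < 0) stop("alpha must be nonnegative")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (coexprThreshold < 0 || coexprThreshold > 1)
    stop("coexprThreshold must lie in [0, 1]")
  if (anyDuplicated(viewList)) stop("view names must be unique")
  if (any(thresholdGrid < 0) || any(thresholdGrid > 1) ||
      any(diff(thresholdGrid) <= 0))
    stop("thresholdGrid must be strictly increasing within [0, 1]")
  if (any(kGrid < 1L)) stop("kGrid entries must be positive")
  if (tau < 2L) stop("tau must be >= 2")
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  structure(list(
    k = k, alpha = alpha, iterations = iterations, seed = as.integer(seed),
    coexprThreshold = coexprThreshold, viewList = viewList,
    thresholdGrid = thresholdGrid, kGrid = kGrid, alphaGrid = alphaGrid,
    tau = tau, theta = theta, logExpression = isTRUE(logExpression),
    useAbsoluteCorrelation = isTRUE(useAbsoluteCorrelation),
    updateVariant = updateVariant), class = "RunConfig")
}

#' Read a run configuration from a flat YAML file
#'
#' The file holds flat key-value pairs named as the [runConfig()] arguments;
#' keys absent from the file keep their defaults, and `...` overrides take
#' precedence over the file (the command-line convention).
#'
#' @param path YAML file path, or NULL for defaults only.
#' @param ... named overrides applied on top of the file values.
#' @return A "RunConfig" list.
#' @export
readRunConfig <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("config file must be a YAML mapping")
    unknown <- setdiff(names(vals), names(formals(runConfig)))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(runConfig, vals)
}

#' Write a run configuration to YAML
#'
#' @param config a "RunConfig" list.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
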