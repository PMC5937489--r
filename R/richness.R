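# Abundance-based richness estimation from insertion-event multiplicities.
# The abundance vector is the per-site event count (how many independent
# transformants integrated at each site); rarefaction asks how many distinct
# sites would have been seen at a smaller sampling depth, and the estimators
# project how many usable sites the sampled genome carries in total.

#' Abundance vector of insertion events per site
#'
#' @param x integer vector of per-site event counts (all >= 1).
#' @return an `abundance_vector`: `x`, `N` (total events), `S_obs` (observed
#'   sites), `F1` (singletons), `F2` (doubletons).
#' @export
abundance_vector <- function(x) {
  x <- as.integer(x)
  if (length(x) == 0L) stop("empty abundance vector")
  if (any(x < 1L)) stop("event counts must be >= 1")
  structure(list(x = x, N = sum(x), S_obs = length(x),
                 F1 = sum(x == 1L), F2 = sum(x == 2L)),
            class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat(sprintf("%d events over %d sites (%d singletons, %d doubletons)\n",
              x$N, x$S_obs, x$F1, x$F2))
  invisible(x)
}

#' Hypergeometric rarefaction curve
#'
#' Expected number of distinct sites among a uniform random subsample of
#' `n` of the `N` observed events:
#' E(S_n) = sum_i (1 - choose(N - x_i, n) / choose(N, n)),
#' computed in log space. The curve is exact (no resampling), monotone
#' non-decreasing and concave, with E(S_1) = 1 and E(S_N) = S_obs.
#'
#' @param abund an [abundance_vector()] (or a bare count vector).
#' @param n_grid subsample sizes (default `1:N`).
#' @return a data.frame of class `rarefaction_curve`: `n`, `richness`; the
#'   observed richness is attached as attribute `S_obs`.
#' @export
rarefaction_curve <- function(abund, n_grid = NULL) {
  if (!inherits(abund, "abundance_vector")) abund <- abundance_vector(abund)
  N <- abund$N
  n_grid <- as.integer(n_grid %||% seq_len(N))
  if (any(n_grid < 1L) || any(n_grid > N))
    stop("interpolation sizes must lie in [1, N]; extrapolation is not supported")
  richness <- vapply(n_grid, function(n) {
    # log-space: choose(N - x_i, n) / choose(N, n); term is 1 when n > N - x_i
    lt <- lchoose(N - abund$x, n) - lchoose(N, n)
    sum(1 - exp(lt))
  }, numeric(1))
  out <- data.frame(n = n_grid, richness = richness)
  attr(out, "S_obs") <- abund$S_obs
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Chao1 richness estimator
#'
#' Classic: S_obs + F1^2 / (2 F2); bias-corrected:
#' S_obs + F1 (F1 - 1) / (2 (F2 + 1)). When F2 = 0 the classic form is
#' undefined and the bias-corrected form is used with a warning.
#'
#' @param abund an [abundance_vector()] (or a bare count vector).
#' @param bias_corrected use the bias-corrected form (default FALSE).
#' @return the richness estimate (numeric scalar, always >= S_obs).
#' @export
chao1 <- function(abund, bias_corrected = FALSE) {
  if (!inherits(abund, "abundance_vector")) abund <- abundance_vector(abund)
  if (!bias_corrected && abund$F2 == 0L) {
    warning("no doubletons: falling back to the bias-corrected Chao1")
    bias_corrected <- TRUE
  }
  if (bias_corrected) {
    abund$S_obs + abund$F1 * (abund$F1 - 1) / (2 * (abund$F2 + 1))
  } else {
    abund$S_obs + abund$F1^2 / (2 * abund$F2)
  }
}

#' Fit a saturating asymptote to a rarefaction curve
#'
#' Least-squares fit of a saturating accumulation model to the interpolated
#' rarefaction curve, giving a curve-based projection of the total number of
#' usable sites. Two model families are available:
#'
#' * `"exponential"` (default): S(n) = S_max (1 - (1 - 1/S_max)^n), the
#'   exact expected accumulation when n events are drawn with replacement
#'   from a finite pool of S_max equally usable sites; its asymptote is an
#'   approximately unbiased estimate of the pool size under that sampling
#'   model.
#' * `"michaelis"`: S(n) = S_max n / (B + n), the generic saturating
#'   hyperbola. Its tail is heavier than finite-pool sampling produces, so
#'   fitted asymptotes from shallow surveys run systematically high; it is
#'   kept for curves that genuinely follow a hyperbolic law.
#'
#' Fits are deterministic (analytic start values, bounded Levenberg-
#' Marquardt, fixed tolerances) and bounded below by the observed richness.
#' A flat curve (already saturated) returns S_max = S_obs directly.
#'
#' @param curve a [rarefaction_curve()] with at least 4 points.
#' @param model accumulation model (see above).
#' @return list: `S_max`, `B` (`NA` for the one-parameter exponential
#'   model), `residual_norm`, `converged`, `method`.
#' @export
fit_asymptote <- function(curve, model = c("exponential", "michaelis")) {
  stopifnot(inherits(curve, "rarefaction_curve"))
  model <- match.arg(model)
  d <- data.frame(n = curve$n, S = curve$richness)
  if (nrow(d) < 4L) stop("need at least 4 interpolation points")
  S_obs <- attr(curve, "S_obs") %||% max(d$S)
  if (diff(range(d$S)) < 1e-8) {
    return(list(S_max = max(d$S), B = NA_real_, residual_norm = 0,
                converged = TRUE, method = "saturated"))
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
  if (model == "exponential") {
    fit <- try(minpack.lm::nlsLM(
      S ~ Smax * (1 - (1 - 1 / Smax)^n), data = d,
      start = list(Smax = 2 * max(d$S)),
      lower = c(Smax = max(max(d$S), 1 + 1e-9)), control = ctl
    ), silent = TRUE)
  } else {
    lin <- stats::lm(I(1 / S) ~ I(1 / n), data = d[d$S > 0, , drop = FALSE])
    S0 <- unname(1 / stats::coef(lin)[1])
    B0 <- unname(stats::coef(lin)[2] * S0)
    if (!is.finite(S0) || S0 <= max(d$S)) S0 <- max(d$S) * 1.5
    if (!is.finite(B0) || B0 <= 0) B0 <- max(d$n) / 4
    fit <- try(minpack.lm::nlsLM(
      S ~ Smax * n / (B + n), data = d,
      start = list(Smax = S0, B = B0),
      lower = c(Smax = max(d$S), B = 1e-9), control = ctl
    ), silent = TRUE)
  }
  if (inherits(fit, "try-error"))
    stop("asymptote fit failed to converge: ", attr(fit, "condition")$message)
  co <- stats::coef(fit)
  S_max <- unname(co["Smax"])
  if (S_max < S_obs - 1e-6)
    stop("fit converged below the observed richness; not reporting S_max")
  list(S_max = S_max,
       B = if (model == "michaelis") unname(co["B"]) else NA_real_,
       residual_norm = sqrt(sum(stats::residuals(fit)^2)),
       converged = TRUE, method = paste0("nlsLM/", model))
}

#' Richness summary for a site table
#'
#' Convenience wrapper computing the abundance summary, Chao1 (both forms)
#' and the asymptote projection from per-site event counts.
#'
#' @param counts integer vector of per-site event counts.
#' @return list with `abundance`, `curve`, `chao1_classic`,
#'   `chao1_bias_corrected`, `asymptote`.
#' @export
richness_summary <- function(counts) {
  ab <- abundance_vector(counts)
  curve <- rarefaction_curve(ab)
  cl <- if (ab$F2 > 0L) chao1(ab) else NA_real_
  list(abundance = ab, curve = curve,
       chao1_classic = cl,
       chao1_bias_corrected = chao1(ab, bias_corrected = TRUE),
       asymptote = if (ab$N >= 4L) fit_asymptote(curve) else NULL)
}
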