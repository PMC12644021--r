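# Two-component gamma-Poisson empirical-Bayes shrinker (MGPS).
#
# Model: the observed drug-event count n is Poisson(lambda * E) with E the
# expected count under independence; the relative reporting rate lambda has
# the two-component gamma mixture prior
#   lambda ~ w * Gamma(alpha1, beta1) + (1 - w) * Gamma(alpha2, beta2)
# (shape/rate). The posterior is again a two-component gamma mixture with
# components Gamma(alpha_j + n, beta_j + E) and weight Qn on component 1.
# EBGM is the posterior geometric mean exp(E[log lambda | n]).

#' Gamma-mixture prior of the empirical-Bayes shrinker
#'
#' @param alpha1,beta1 shape and rate of the first gamma component.
#' @param alpha2,beta2 shape and rate of the second component.
#' @param w mixture weight of the first component, in (0, 1).
#' @return object of class `mgps_prior`.
#' @export
mgps_prior <- function(alpha1, beta1, alpha2, beta2, w) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0, w > 0, w < 1)
  structure(list(alpha1 = alpha1, beta1 = beta1,
                 alpha2 = alpha2, beta2 = beta2, w = w),
            class = "mgps_prior")
}

#' The literature default MGPS prior
#'
#' The widely used starting hyperparameters
#' `(alpha1, beta1, alpha2, beta2, w) = (0.2, 0.1, 2, 4, 1/3)`, also the
#' fallback when maximum-likelihood fitting fails or the pair universe is
#' too sparse.
#'
#' @return an [mgps_prior()].
#' @export
default_mgps_prior <- function() mgps_prior(0.2, 0.1, 2, 4, 1 / 3)

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(
    "<mgps_prior a1=%.4g b1=%.4g a2=%.4g b2=%.4g w=%.4g%s>\n",
    x$alpha1, x$beta1, x$alpha2, x$beta2, x$w,
    if (isTRUE(attr(x, "fitted"))) " (fitted)" else ""))
  invisible(x)
}

# log gamma-Poisson (negative binomial) marginal: P(n | alpha, beta, E)
lnb_marginal <- function(n, alpha, beta, E) {
  lgamma(alpha + n) - lgamma(alpha) - lgamma(n + 1) +
    alpha * (log(beta) - log(beta + E)) +
    n * (log(E) - log(beta + E))
}

#' Posterior quantities of the gamma-Poisson shrinker
#'
#' For observed count `n` and expected count `E` under the prior, computes
#' the posterior weight `Qn` of the first mixture component from the
#' negative-binomial marginals (in log space), the posterior geometric mean
#' `EBGM = exp(E[log lambda | n])` in closed form via the digamma function,
#' and optionally the 5th posterior percentile `EB05` by root-finding on
#' the posterior mixture CDF.
#'
#' @param n observed counts (vectorized, non-negative).
#' @param E expected counts (vectorized, strictly positive).
#' @param prior an [mgps_prior()].
#' @param eb05 also compute the 5th posterior percentile.
#' @return data.table with columns `n`, `E`, `qn`, `ebgm` (and `eb05`).
#' @export
#' @examples
#' mgps_posterior(10, 2, default_mgps_prior())
mgps_posterior <- function(n, E, prior = default_mgps_prior(), eb05 = FALSE) {
  stopifnot(inherits(prior, "mgps_prior"))
  if (any(E <= 0)) undefined_metric("EBGM undefined for E <= 0")
  if (any(n < 0)) stop("n must be non-negative")
  k <- max(length(n), length(E))
  n <- rep_len(n, k); E <- rep_len(E, k)

  l1 <- log(prior$w) + lnb_marginal(n, prior$alpha1, prior$beta1, E)
  l2 <- log1p(-prior$w) + lnb_marginal(n, prior$alpha2, prior$beta2, E)
  m <- pmax(l1, l2)
  qn <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))

  elog <- qn * (digamma(prior$alpha1 + n) - log(prior$beta1 + E)) +
    (1 - qn) * (digamma(prior$alpha2 + n) - log(prior$beta2 + E))
  out <- data.table::data.table(n = n, E = E, qn = qn, ebgm = exp(elog))
  if (eb05) {
    out[, eb05 := mapply(posterior_quantile, n, E, qn,
                         MoreArgs = list(prior = prior, p = 0.05))]
  }
  out[]
}

# quantile of the posterior gamma mixture by root finding on its CDF
posterior_quantile <- function(n, E, qn, prior, p = 0.05) {
  a1 <- prior$alpha1 + n; b1 <- prior$beta1 + E
  a2 <- prior$alpha2 + n; b2 <- prior$beta2 + E
  cdf <- function(x) {
    qn * pgamma(x, a1, rate = b1) + (1 - qn) * pgamma(x, a2, rate = b2) - p
  }
  lo <- min(qgamma(p / 2, a1, rate = b1), qgamma(p / 2, a2, rate = b2))
  hi <- max(qgamma(1 - (1 - p) / 2, a1, rate = b1),
            qgamma(1 - (1 - p) / 2, a2, rate = b2))
  lo <- max(lo * 0.5, .Machine$double.xmin)
  hi <- hi * 2 + 1e-8
  uniroot(cdf, c(lo, hi), tol = 1e-10)$root
}

mixture_negloglik <- function(theta, n, E) {
  a1 <- exp(theta[1]); b1 <- exp(theta[2])
  a2 <- exp(theta[3]); b2 <- exp(theta[4])
  w <- plogis(theta[5])
  l1 <- log(w) + lnb_marginal(n, a1, b1, E)
  l2 <- log1p(-w) + lnb_marginal(n, a2, b2, E)
  m <- pmax(l1, l2)
  ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
  if (!is.finite(ll)) return(1e12)
  -ll
}

#' Fit the MGPS prior by maximum marginal likelihood
#'
#' Maximizes the summed log negative-binomial mixture marginal over all
#' `(n, E)` drug–event pairs, optimizing on an unconstrained scale (log for
#' shapes/rates, logit for the weight) with several deterministic starting
#' points. The fitted components are reordered so that the first component
#' has the smaller prior mean (`alpha/beta`), resolving label switching.
#' Falls back to [default_mgps_prior()] with a warning on sparse input
#' (fewer than `min_pairs` pairs with `E > 0`, or all counts zero) or
#' optimizer failure.
#'
#' @param n,E vectors of observed and expected counts over the pair universe.
#' @param min_pairs minimum usable pair count before falling back.
#' @param starts list of numeric(5) starting values on the natural scale
#'   `(alpha1, beta1, alpha2, beta2, w)`; defaults to the literature default
#'   prior plus two dispersed variants.
#' @return an [mgps_prior()] with attributes `fitted` (logical), `loglik`
#'   and `convergence` (the [stats::optim()] code, 0 meaning success).
#' @export
fit_mgps_prior <- function(n, E, min_pairs = 100, starts = NULL) {
  ok <- is.finite(n) & is.finite(E) & E > 0 & n >= 0
  n <- n[ok]; E <- E[ok]
  fallback <- function(reason) {
    warning("fit_mgps_prior: ", reason, "; using the default prior",
            call. = FALSE)
    p <- default_mgps_prior()
    attr(p, "fitted") <- FALSE
    p
  }
  if (length(n) < min_pairs) return(fallback("too few usable pairs"))
  if (all(n == 0)) return(fallback("all counts are zero"))

  if (is.null(starts)) {
    starts <- list(c(0.2, 0.1, 2, 4, 1 / 3),
                   c(1, 1, 1, 1, 0.5),
                   c(0.5, 0.05, 5, 5, 0.2))
  }
  best <- NULL
  for (s in starts) {
    theta0 <- c(log(s[1:4]), qlogis(s[5]))
    fit <- tryCatch(
      optim(theta0, mixture_negloglik, n = n, E = E, method = "BFGS",
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(fallback("optimizer failed"))

  a1 <- exp(best$par[1]); b1 <- exp(best$par[2])
  a2 <- exp(best$par[3]); b2 <- exp(best$par[4])
  w <- plogis(best$par[5])
  if (a1 / b1 > a2 / b2) {  # order components by prior mean
    tmp <- c(a1, b1); a1 <- a2; b1 <- b2; a2 <- tmp[1]; b2 <- tmp[2]
    w <- 1 - w
  }
  w <- min(max(w, 1e-8), 1 - 1e-8)
  p <- mgps_prior(a1, b1, a2, b2, w)
  attr(p, "fitted") <- TRUE
  attr(p, "loglik") <- -best$value
  attr(p, "convergence") <- best$convergence
  p
}

#' Drug–event pair counts for prior fitting
#'
#' Builds the `(n, E)` pair universe over a set of joined reports: for each
#' (drug name, PT) pair, `n` is the number of reports mentioning both, and
#' `E = (drug reports) * (event reports) / N` the expectation under
#' independence. Report-level counting: a pair counts once per report.
#'
#' @param reports joined reports ([bind_reports()] output), deduplicated or
#'   not at the caller's discretion.
#' @return data.table with columns `drug`, `event`, `n`, `E`.
#' @export
pair_counts <- function(reports) {
  dt <- data.table::as.data.table(reports)
  N <- nrow(dt)
  if (N == 0L) {
    return(data.table::data.table(drug = character(0), event = character(0),
                                  n = integer(0), E = numeric(0)))
  }
  rid <- seq_len(N)
  long_d <- data.table::data.table(
    rid = rep(rid, lengths(dt$drug_names)),
    drug = toupper(unlist(dt$drug_names)))
  long_d <- unique(long_d[!is.na(drug)])
  long_e <- data.table::data.table(
    rid = rep(rid, lengths(dt$pts)),
    event = normalize_pt(unlist(dt$pts)))
  long_e <- unique(long_e[!is.na(event)])

  n_drug <- long_d[, .(n_drug = .N), by = drug]
  n_event <- long_e[, .(n_event = .N), by = event]
  pairs <- merge(long_d, long_e, by = "rid", allow.cartesian = TRUE)
  pairs <- pairs[, .(n = .N), by = .(drug, event)]
  pairs <- merge(pairs, n_drug, by = "drug")
  pairs <- merge(pairs, n_event, by = "event")
  pairs[, E := n_drug * n_event / N]
  pairs[, c("n_drug", "n_event") := NULL]
  data.table::setcolorder(pairs, c("drug", "event", "n", "E"))
  pairs[]
}
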