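#' Empirical degree distribution of a supply network
#'
#' Tabulates the probability `p_k` that a randomly chosen node has (in- or
#' out-) degree `k`. In the stored buyer-to-supplier orientation the
#' in-degree counts a node's customers and the out-degree its suppliers.
#' Self-loops contribute 1 to both degrees of their node. Probabilities are
#' normalised over all nodes, including those of degree zero.
#'
#' @param net a `supply_network`.
#' @param direction `"in"` or `"out"`.
#' @return a `degree_distribution`: list with `direction`, `support`
#'   (strictly increasing observed degrees), `probabilities`, `counts`,
#'   `n_nodes` and the per-node `degrees`.
#' @export
degree_distribution <- function(net, direction = c("in", "out")) {
  direction <- match.arg(direction)
  if (n_nodes(net) == 0) stop("empty network has no degree distribution",
                              call. = FALSE)
  deg <- node_degrees(net, loops = TRUE)[[direction]]
  tab <- table(deg)
  structure(
    list(direction = direction,
         support = as.numeric(names(tab)),
         probabilities = as.numeric(tab) / length(deg),
         counts = as.numeric(tab),
         n_nodes = length(deg),
         degrees = deg),
    class = "degree_distribution"
  )
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("<degree_distribution> %s-degree, %d nodes, support %s..%s\n",
              x$direction, x$n_nodes, min(x$support), max(x$support)))
  invisible(x)
}

model_fun <- function(model) {
  switch(model,
    power_law = function(k, par) par[["a"]] * k^(-par[["b"]]),
    exponential = function(k, par) par[["a"]] * exp(-par[["b"]] * k),
    log_normal = function(k, par) {
      1 / (k * par[["sigma"]] * sqrt(2 * pi)) *
        exp(-(log(k) - par[["mu"]])^2 / (2 * par[["sigma"]]^2))
    },
    stop("unknown model: ", model, call. = FALSE)
  )
}

# support actually used by a model fit: k = 0 is excluded for the power law
# and the log-normal, whose densities are undefined there
model_support <- function(model, support) {
  if (model == "exponential") support else support[support >= 1]
}

fit_start <- function(model, k, p) {
  if (model == "power_law") {
    cf <- coef(lm(log(p) ~ log(k), subset = p > 0))
    list(a = unname(exp(cf[1])), b = unname(-cf[2]))
  } else if (model == "exponential") {
    cf <- coef(lm(log(p) ~ k, subset = p > 0))
    list(a = unname(exp(cf[1])), b = unname(-cf[2]))
  } else {
    lk <- log(k)
    mu <- sum(p * lk) / sum(p)
    sg <- sqrt(sum(p * (lk - mu)^2) / sum(p))
    list(mu = mu, sigma = max(sg, 0.2))
  }
}

#' Fit a probability model to a degree distribution
#'
#' Nonlinear least squares (Levenberg-Marquardt) of one of the three model
#' functions against the empirical `(k, p_k)` pairs:
#' * power law `p(k) = a k^-b`,
#' * exponential `p(k) = a exp(-b k)`,
#' * log-normal `p(k) = 1 / (k sigma sqrt(2 pi)) exp(-(ln k - mu)^2 /
#'   (2 sigma^2))`.
#'
#' The power law and the log-normal are fitted over `k >= 1` only (both are
#' undefined at `k = 0`); the exponential is fitted over the full support.
#' Starting values come from log-log (power law), log-linear (exponential)
#' or log-moment (log-normal) regressions; on failure the fit is retried
#' with up to 5 perturbed starts.
#'
#' @param dist a [degree_distribution()].
#' @param model `"power_law"`, `"exponential"` or `"log_normal"`.
#' @param ... passed on to [chi_square_gof()] for the goodness-of-fit
#'   summary stored in the result.
#' @return a `degree_model_fit`: list with `model`, `params` (named vector:
#'   `a`, `b` or `mu`, `sigma`), `chi2`, `dof`, `p_value`, `fit_support`,
#'   and the distribution fitted.
#' @export
fit_model <- function(dist, model = c("power_law", "exponential",
                                      "log_normal"), ...) {
  stopifnot(inherits(dist, "degree_distribution"))
  model <- match.arg(model)
  ks <- model_support(model, dist$support)
  p <- dist$probabilities[match(ks, dist$support)]
  if (length(ks) < 2) {
    stop("fewer support points (", length(ks),
         ") than model parameters (2)", call. = FALSE)
  }
  f <- model_fun(model)
  start <- fit_start(model, ks, p)
  fit <- NULL
  last_err <- NULL
  for (attempt in 0:5) {
    st <- if (attempt == 0) start else
      lapply(start, function(v) v * exp(rnorm(1, 0, 0.3)))
    fit <- if (model == "log_normal") {
      st$sigma <- abs(st$sigma) + 1e-3
      tryCatch(
        minpack.lm::nlsLM(
          p ~ f(ks, list(mu = mu, sigma = sigma)),
          start = st[c("mu", "sigma")],
          lower = c(mu = -Inf, sigma = 1e-6),
          control = minpack.lm::nls.lm.control(maxiter = 500)
        ),
        error = function(e) e
      )
    } else {
      tryCatch(
        minpack.lm::nlsLM(
          p ~ f(ks, list(a = a, b = b)),
          start = st[c("a", "b")],
          control = minpack.lm::nls.lm.control(maxiter = 500)
        ),
        error = function(e) e
      )
    }
    if (!inherits(fit, "error")) break
    last_err <- fit
  }
  if (inherits(fit, "error")) {
    stop("model fit failed to converge after perturbed restarts (",
         conditionMessage(last_err), ")", call. = FALSE)
  }
  params <- coef(fit)
  if (model == "log_normal") params["sigma"] <- abs(params[["sigma"]])
  out <- structure(
    list(model = model, params = params, chi2 = NA_real_, dof = NA_integer_,
         p_value = NA_real_, fit_support = ks, distribution = dist),
    class = "degree_model_fit"
  )
  gof <- chi_square_gof(dist, out, ...)
  out$chi2 <- gof$chi2
  out$dof <- gof$dof
  out$p_value <- gof$p_value
  out
}

#' @export
print.degree_model_fit <- function(x, ...) {
  cat(sprintf("<degree_model_fit> %s on %s-degree: %s; chi2 = %.4g (dof %d, p = %.4g)\n",
              x$model, x$distribution$direction,
              paste(names(x$params), signif(x$params, 4), sep = "=",
                    collapse = ", "),
              x$chi2, x$dof, x$p_value))
  invisible(x)
}

#' Pearson chi-squared statistic
#'
#' `sum((observed - expected)^2 / expected)` over matching bins.
#'
#' @param observed,expected numeric vectors of equal length; all expected
#'   values must be positive.
#' @return the statistic.
#' @export
chisq_statistic <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  if (any(expected <= 0)) {
    stop("expected value <= 0 in a used bin; exclude zero-expectation bins",
         call. = FALSE)
  }
  sum((observed - expected)^2 / expected)
}

#' Chi-squared goodness of fit of a degree-model fit
#'
#' Compares observed and model-predicted bin contents over the fitted
#' support. By default the comparison is on counts: the expected content of
#' bin `k` is `n * p_hat(k)` with the model probabilities renormalised over
#' the used bins so that expected and observed totals agree (the behaviour
#' of standard chi-squared routines). Degrees of freedom default to
#' `bins - 1`; the textbook `bins - 1 - n_params` correction is available
#' via `dof_correction`.
#'
#' @param dist a [degree_distribution()].
#' @param fit a [fit_model()] result on that distribution.
#' @param include_zero_bin whether the `k = 0` bin enters the comparison.
#'   Defaults to `TRUE` for the exponential model and is forced `FALSE`
#'   (with an error if requested) for the power law and log-normal, which
#'   are undefined at zero.
#' @param use_counts compare counts (default) or probabilities.
#' @param dof_correction subtract the number of fitted parameters from the
#'   degrees of freedom.
#' @return list with `chi2`, `dof`, `p_value` (upper tail) and `bins`.
#' @export
chi_square_gof <- function(dist, fit, include_zero_bin = NULL,
                           use_counts = TRUE, dof_correction = FALSE) {
  stopifnot(inherits(dist, "degree_distribution"),
            inherits(fit, "degree_model_fit"))
  model <- fit$model
  if (model %in% c("power_law", "log_normal")) {
    if (isTRUE(include_zero_bin)) {
      stop("the ", model, " density is undefined at k = 0; ",
           "the zero bin must be excluded", call. = FALSE)
    }
    bins <- dist$support[dist$support >= 1]
  } else {
    if (is.null(include_zero_bin)) include_zero_bin <- TRUE
    bins <- if (include_zero_bin) dist$support else
      dist$support[dist$support >= 1]
  }
  obs_p <- dist$probabilities[match(bins, dist$support)]
  pred <- model_fun(model)(pmax(bins, ifelse(model == "exponential", 0, 1)),
                           as.list(fit$params))
  if (any(!is.finite(pred)) || any(pred < 0) || all(pred == 0)) {
    stop("expected value <= 0 in a used bin; exclude zero-expectation bins",
         call. = FALSE)
  }
  obs <- if (use_counts) obs_p * dist$n_nodes else obs_p
  expd <- pred / sum(pred) * sum(obs)
  # a strictly positive model can underflow at extreme degrees; floor the
  # expectation so the (huge) misfit stays finite
  expd <- pmax(expd, sum(obs) * 1e-12)
  chi2 <- chisq_statistic(obs, expd)
  dof <- length(bins) - 1L - if (dof_correction) length(fit$params) else 0L
  if (dof < 1) stop("non-positive degrees of freedom", call. = FALSE)
  list(chi2 = chi2, dof = dof,
       p_value = pchisq(chi2, dof, lower.tail = FALSE), bins = bins)
}

#' Select the best-fitting degree model
#'
#' Among fits of the same degree distribution, returns the one with the
#' smallest chi-squared statistic. Exact ties are broken by the smaller
#' number of parameters, then lexically by model name; the tie-break is
#' recorded on the result as attribute `tie_break`.
#'
#' @param fits list of [fit_model()] results on one distribution.
#' @return the winning `degree_model_fit`.
#' @export
select_best_model <- function(fits) {
  stopifnot(length(fits) >= 1)
  if (length(fits) == 1) return(fits[[1]])
  fp <- function(f) list(f$distribution$direction, f$distribution$support,
                         f$distribution$counts)
  ref <- fp(fits[[1]])
  same <- vapply(fits, function(f) isTRUE(all.equal(fp(f), ref)), logical(1))
  if (!all(same)) {
    stop("fits compare different degree distributions", call. = FALSE)
  }
  chi <- vapply(fits, function(f) f$chi2, numeric(1))
  npar <- vapply(fits, function(f) length(f$params), numeric(1))
  nm <- vapply(fits, function(f) f$model, character(1))
  ord <- order(chi, npar, nm)
  best <- fits[[ord[1]]]
  tied <- which(chi == chi[ord[1]])
  if (length(tied) > 1) {
    attr(best, "tie_break") <- sprintf(
      "tie on chi2 among {%s}; resolved by parameter count then model name",
      paste(nm[tied], collapse = ", "))
  }
  best
}
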