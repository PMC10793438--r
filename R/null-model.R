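# Gamma GLM null model for confluency/initial count ratios.
#
# For a tested variant v against a reference variant at the same position,
# the observed confluency ratio r_cf is modelled as
#
#   r_cf ~ Gamma(shape = alpha, scale = mu_v / alpha),
#   mu_v = exp(intercept) * r_init^a * p_init^b,
#
# a gamma GLM with log link and covariates log r_init and log p_init (no
# intercept by default: the null mean formula has none).  alpha is shared
# across variants.  Calibrated on all-neutral barcode control experiments,
# the model yields a one-sided upper-tail p-value for any observed r_cf:
# small p means the variant expanded more than neutral dynamics explain,
# i.e. a fitness advantage (functionally deleterious protein).

#' Build calibration/test triplets from a count table
#'
#' A triplet (r_cf, r_init, p_init) summarizes one tested variant against a
#' reference variant within one library and replicate: the tested/reference
#' count ratio at confluency and at Day 9, plus the tested variant's Day-9
#' proportion among all variants at the position.
#'
#' With `reference = "all"` (control calibration) every variant within each
#' experiment serves in turn as the reference and each remaining variant
#' contributes one triplet against it: k barcodes yield k(k-1) triplets per
#' experiment, so the 3-experiment, 20-barcode control design yields 1,140.
#' With `reference = "synonymous"` (assay testing) the synonymous variant
#' (`alt_aa == ref_aa`) anchors each library and every missense variant
#' contributes one triplet.
#'
#' @param counts Count-table tibble (see [simulate_assay()] for the schema).
#' @param reference `"all"` or `"synonymous"`.
#' @param pseudocount Added to every count before ratios and proportions
#'   (default 0.5).  Set to 0 to forbid zeros: any zero count then errors.
#' @return Tibble: `library_id`, `replicate_id`, `residue_index`, `ref_aa`,
#'   `alt_aa`, `variant`, `reference`, `r_cf`, `r_init`, `p_init`.
#' @export
build_triplets <- function(counts, reference = c("all", "synonymous"),
                           pseudocount = 0.5) {
  reference <- arg_match(reference)
  check_columns(counts, c("library_id", "replicate_id", "alt_aa",
                          "count_day9", "count_confluent"))
  check_scalar_number(pseudocount, "pseudocount", lower = 0)
  if (pseudocount == 0 &&
      any(counts$count_day9 == 0 | counts$count_confluent == 0)) {
    abort("zero counts present and `pseudocount = 0`; cannot form ratios.")
  }
  if (!"residue_index" %in% names(counts)) counts$residue_index <- NA_integer_
  if (!"ref_aa" %in% names(counts)) counts$ref_aa <- NA_character_
  counts |>
    group_by(.data$library_id, .data$replicate_id) |>
    group_modify_triplets(reference, pseudocount) |>
    ungroup()
}

group_modify_triplets <- function(grouped, reference, pseudocount) {
  dplyr::group_modify(grouped, function(g, key) {
    if (nrow(g) < 2L) {
      abort("each library/replicate needs at least 2 variants.")
    }
    c9 <- g$count_day9 + pseudocount
    ccf <- g$count_confluent + pseudocount
    p_init <- c9 / sum(c9)
    if (reference == "all") {
      idx <- expand_grid(v = seq_len(nrow(g)), r = seq_len(nrow(g)))
      idx <- idx[idx$v != idx$r, ]
    } else {
      r <- which(g$alt_aa == g$ref_aa)
      if (length(r) != 1L) {
        abort("missing (or duplicated) synonymous anchor in a library.")
      }
      idx <- tibble(v = setdiff(seq_len(nrow(g)), r), r = r)
    }
    tibble(
      residue_index = g$residue_index[idx$v],
      ref_aa = g$ref_aa[idx$v],
      alt_aa = g$alt_aa[idx$v],
      variant = variant_label(g$ref_aa[idx$v], g$residue_index[idx$v],
                              g$alt_aa[idx$v]),
      reference = variant_label(g$ref_aa[idx$r], g$residue_index[idx$r],
                                g$alt_aa[idx$r]),
      r_cf = ccf[idx$v] / ccf[idx$r],
      r_init = c9[idx$v] / c9[idx$r],
      p_init = p_init[idx$v]
    )
  })
}

#' Fit the gamma GLM null model
#'
#' Estimates the exponents `a` (on `r_init`) and `b` (on `p_init`) by
#' iteratively reweighted least squares for a gamma GLM with log link (for
#' the log link the IRLS working weights are constant, so each iteration is a
#' least-squares solve on the adjusted response), then estimates the shared
#' shape `alpha` by maximizing the gamma log-likelihood given the fitted
#' means (one-dimensional digamma root-find), with a method-of-moments
#' estimate from Pearson residuals available as an alternative.
#'
#' @param triplets Tibble from [build_triplets()] with columns `r_cf`,
#'   `r_init`, `p_init`.
#' @param intercept Include a log-scale intercept?  Default `FALSE`, matching
#'   the null mean formula `mu = r_init^a * p_init^b`.
#' @param shape_method `"mle"` (default) or `"moments"`.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   relative deviance change.
#' @return A `gamma_null` object: shape, exponents, optional intercept, log
#'   likelihood, n, convergence diagnostics.
#' @export
fit_null <- function(triplets, intercept = FALSE,
                     shape_method = c("mle", "moments"),
                     max_iter = 100L, tol = 1e-10) {
  shape_method <- arg_match(shape_method)
  check_columns(triplets, c("r_cf", "r_init", "p_init"))
  y <- triplets$r_cf
  if (any(!is.finite(y) | y <= 0)) abort("`r_cf` must be positive and finite.")
  if (nrow(triplets) < 10L) abort("need at least 10 triplets to calibrate.")
  X <- cbind(log_r_init = log(triplets$r_init),
             log_p_init = log(triplets$p_init))
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  if (qr(X)$rank < ncol(X)) abort("collinear covariates; cannot fit.")

  beta <- qr.solve(X, log(y))  # log-scale least squares start
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    beta <- qr.solve(X, z)
    mu <- exp(drop(X %*% beta))
    dev <- -2 * sum(log(y / mu) - (y - mu) / mu)
    if (is.finite(dev_old) && abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged) {
    warn(sprintf("IRLS did not converge in %d iterations.", max_iter))
  }
  mu <- exp(drop(X %*% beta))
  shape <- switch(shape_method,
                  mle = gamma_shape_mle(y, mu),
                  moments = gamma_shape_moments(y, mu, p = ncol(X)))
  ll <- sum(dgamma(y, shape = shape, scale = mu / shape, log = TRUE))
  structure(
    list(
      shape = shape,
      exp_rinit = unname(beta["log_r_init"]),
      exp_pinit = unname(beta["log_p_init"]),
      intercept = if (intercept) unname(beta["(Intercept)"]) else 0,
      has_intercept = intercept,
      loglik = ll,
      n = length(y),
      iterations = iter,
      converged = converged,
      shape_method = shape_method
    ),
    class = "gamma_null"
  )
}

# MLE of the gamma shape given fitted means: with d_i = y_i / mu_i the score
# equation is log(a) - digamma(a) + 1 + mean(log d) - mean(d) = 0, which is
# monotone decreasing in a.
gamma_shape_mle <- function(y, mu) {
  d <- y / mu
  k <- 1 + mean(log(d)) - mean(d)
  if (k >= 0) abort("degenerate ratios; gamma shape MLE undefined.")
  f <- function(a) log(a) - digamma(a) + k
  uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-12)$root
}

# Method-of-moments fallback: reciprocal of the Pearson dispersion.
gamma_shape_moments <- function(y, mu, p) {
  disp <- sum(((y - mu) / mu)^2) / (length(y) - p)
  1 / disp
}

#' @export
print.gamma_null <- function(x, ...) {
  cat("<gamma_null>  r_cf ~ Gamma(shape, mean = ",
      if (x$has_intercept) "exp(c) * " else "",
      "r_init^a * p_init^b)\n", sep = "")
  cat(sprintf("  shape = %.4g (%s), a = %.4g, b = %.4g%s\n",
              x$shape, x$shape_method, x$exp_rinit, x$exp_pinit,
              if (x$has_intercept) sprintf(", c = %.4g", x$intercept) else ""))
  cat(sprintf("  n = %d triplets, logLik = %.2f, %s in %d IRLS iterations\n",
              x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
tidy.gamma_null <- function(x, ...) {
  terms <- c("shape", "log(r_init)", "log(p_init)")
  est <- c(x$shape, x$exp_rinit, x$exp_pinit)
  if (x$has_intercept) {
    terms <- c(terms, "(Intercept)")
    est <- c(est, x$intercept)
  }
  tibble(term = terms, estimate = est)
}

#' @export
glance.gamma_null <- function(x, ...) {
  tibble(shape = x$shape, exp_rinit = x$exp_rinit, exp_pinit = x$exp_pinit,
         intercept = x$intercept, logLik = x$loglik, nobs = x$n,
         converged = x$converged, shape_method = x$shape_method)
}

#' Predicted null mean for triplets
#'
#' @param model A `gamma_null` model.
#' @param triplets Tibble with `r_init`, `p_init`.
#' @return Numeric vector of predicted means.
#' @export
predict_null_mean <- function(model, triplets) {
  check_columns(triplets, c("r_init", "p_init"))
  exp(model$intercept +
        model$exp_rinit * log(triplets$r_init) +
        model$exp_pinit * log(triplets$p_init))
}

#' Gamma upper-tail probability
#'
#' Upper tail of a gamma distribution parameterized by shape and mean
#' (scale = mean / shape); the elementary p-value of the null model.
#'
#' @param x Observed value(s).
#' @param shape Gamma shape.
#' @param mean Gamma mean.
#' @param log.p Return log probability?
#' @return `P(X >= x)` (or its log).
#' @export
#' @examples
#' gamma_upper_tail(2, shape = 2, mean = 2)  # Erlang tail e^-2 * (1 + 2)
gamma_upper_tail <- function(x, shape, mean, log.p = FALSE) {
  if (any(shape <= 0) || any(mean <= 0)) abort("invalid model parameters.")
  pgamma(x, shape = shape, scale = mean / shape, lower.tail = FALSE,
         log.p = log.p)
}

#' One-sided p-values for observed confluency ratios
#'
#' Adds the null-model upper-tail probability of each triplet's `r_cf`:
#' the probability, under neutral dynamics, of a confluency ratio at least as
#' large as observed.  Log p-values are carried alongside so that extreme
#' significance survives floating-point underflow.
#'
#' @param triplets Triplet tibble.
#' @param model A fitted `gamma_null`.
#' @return `triplets` with `mu` (null mean), `p_value` and `log_p` columns.
#' @export
variant_pvalue <- function(triplets, model) {
  if (!inherits(model, "gamma_null")) abort("`model` must be a gamma_null.")
  check_columns(triplets, c("r_cf", "r_init", "p_init"))
  mu <- predict_null_mean(model, triplets)
  lp <- gamma_upper_tail(triplets$r_cf, model$shape, mu, log.p = TRUE)
  triplets |>
    mutate(mu = mu, log_p = lp, p_value = pmin(exp(lp), 1))
}

#' Simulate triplets directly from the null model
#'
#' Draws covariates (log-normal `r_init`, log-normal `p_init` centered near a
#' 1/20 library share) and responses from the gamma law, for calibration and
#' parameter-recovery checks.
#'
#' @param n Number of triplets.
#' @param shape,a,b Generating parameters (defaults 5, 1, 0.5).
#' @param seed Integer seed.
#' @param sdlog Spread of the log covariates (default 0.5).
#' @param constant_mean If `TRUE`, responses ignore the covariates and share
#'   mean 1 (zero-effect data).
#' @return Triplet tibble with the generating `mu_true` attached.
#' @export
simulate_null_triplets <- function(n, shape = 5, a = 1, b = 0.5, seed = 1L,
                                   sdlog = 0.5, constant_mean = FALSE) {
  withr::local_seed(seed)
  r_init <- exp(rnorm(n, 0, sdlog))
  p_init <- exp(pmin(rnorm(n, log(0.05), sdlog), -0.2))
  mu <- if (constant_mean) rep(1, n) else r_init^a * p_init^b
  tibble(
    library_id = "model", replicate_id = 1L,
    residue_index = NA_integer_, ref_aa = NA_character_,
    alt_aa = sprintf("V%04d", seq_len(n)),
    variant = sprintf("V%04d", seq_len(n)),
    reference = "model",
    r_cf = rgamma(n, shape = shape, scale = mu / shape),
    r_init = r_init, p_init = p_init, mu_true = mu
  )
}

#' Serialize and restore a fitted null model
#'
#' The model is stored as a small JSON document (shape, exponents, intercept,
#' diagnostics), human-readable and stable across sessions.
#'
#' @param model A `gamma_null`.
#' @param path File path.
#' @return `write_null_model()` returns `path` invisibly; `read_null_model()`
#'   the restored `gamma_null`.
#' @export
write_null_model <- function(model, path) {
  if (!inherits(model, "gamma_null")) abort("`model` must be a gamma_null.")
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_null_model
#' @export
read_null_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj[c("shape", "exp_rinit", "exp_pinit", "intercept",
                  "has_intercept", "loglik", "n", "iterations", "converged",
                  "shape_method")],
            class = "gamma_null")
}

#' Gamma log-likelihood of triplets under given parameters
#'
#' Utility for likelihood comparisons (e.g. fitted vs generating parameters).
#'
#' @param triplets Triplet tibble.
#' @param shape,a,b,intercept Model parameters.
#' @return Scalar log-likelihood.
#' @export
loglik_gamma_null <- function(triplets, shape, a, b, intercept = 0) {
  mu <- exp(intercept + a * log(triplets$r_init) + b * log(triplets$p_init))
  sum(dgamma(triplets$r_cf, shape = shape, scale = mu / shape, log = TRUE))
}
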