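#' Fit a correlated multistate model by maximum likelihood
#'
#' Maximises the frailty-integrated log-likelihood over the working-scale
#' parameter vector (log intensities, log frailty variance, the power-link
#' exponent and covariate coefficients on the natural scale) with BFGS, then
#' computes a central finite-difference Hessian of the negative log-likelihood
#' at the optimum for Wald standard errors.
#'
#' Default starting values are crude occurrence/exposure rates (transition
#' counts divided by person-time at risk in the origin state, floored at
#' 0.01 per year), `theta = 0.5`, `alpha = 1` and zero covariate effects.
#'
#' @param data Panel data (see [cmsm_loglik()] for the required layout).
#' @param spec A [cmsm_spec()].
#' @param init Optional start values: a [cmsm_model()], a previous
#'   [cmsm_fit()], or a named working-scale vector.
#' @param quad A [quad_control()]; the default inside the optimiser is the
#'   deterministic fixed Gauss--Legendre rule.
#' @param control Passed to [stats::optim()] (`maxit`, `reltol`, ...).
#' @param tie_theta For the `"separate"` link only: constrain the two frailty
#'   variances to be equal (one shared parameter), e.g. for likelihood-ratio
#'   testing of equal variances.
#' @param se Compute the numeric Hessian and Wald covariance at the optimum
#'   (set `FALSE` to skip when only the maximised likelihood is needed).
#' @return An object of class `cmsm_fit` with the fitted [cmsm_model()],
#'   working-scale estimates and covariance, log-likelihood, AIC and
#'   convergence diagnostics. Use [tidy()] / [glance()] /
#'   [cmsm_confint()] to extract results.
#' @seealso [cmsm_lrtest()], [cmsm_aic()], [cmsm_ebayes()]
#' @export
cmsm_fit <- function(data, spec, init = NULL,
                     quad = quad_control("fixed"),
                     control = list(), tie_theta = FALSE, se = TRUE) {
  stopifnot(inherits(spec, "cmsm_spec"))
  if (tie_theta && spec$link != "separate")
    abort("`tie_theta` only applies to the separate-frailty link.")
  ints <- panel_intervals(data, spec)
  if (ints$n < 2) abort("need at least 2 subjects to fit.")

  info <- par_info(spec, tie_theta)
  par0 <- init_par(init, ints, spec, info, tie_theta)

  nll <- function(par) {
    if (any(abs(par) > 40)) return(1e10)  # rates beyond exp(40)/yr: reject
    ll <- tryCatch({
      m <- model_from_par(spec, par, info, tie_theta)
      sum(integrated_ll_by_subject(ints, m, quad))
    }, error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)
  opt <- optim(par0, nll, method = "BFGS", control = ctrl)

  grad <- num_gradient(nll, opt$par)
  if (se) {
    H <- num_hessian(nll, opt$par, rel_step = 1e-4)
    vcov <- tryCatch({
      V <- solve(H)
      (V + t(V)) / 2
    }, error = function(e) {
      warn("singular Hessian: standard errors unavailable.")
      matrix(NA_real_, length(par0), length(par0))
    })
  } else {
    H <- vcov <- matrix(NA_real_, length(par0), length(par0))
  }
  dimnames(H) <- dimnames(vcov) <- list(info$name, info$name)

  loglik <- -opt$value
  k <- length(par0)
  structure(
    list(
      model = model_from_par(spec, opt$par, info, tie_theta),
      spec = spec,
      par = setNames(opt$par, info$name),
      par_info = info,
      tie_theta = tie_theta,
      vcov = vcov,
      hessian = H,
      loglik = loglik,
      k = k,
      aic = cmsm_aic(loglik, k),
      converged = opt$convergence == 0L,
      gradient_norm = sqrt(sum(grad^2)),
      counts = opt$counts,
      n_subjects = ints$n,
      quad = quad
    ),
    class = "cmsm_fit"
  )
}

# ---- working-scale parameter vector -----------------------------------------

# table describing each free parameter: name, role, process, transition,
# covariate, and the working-scale transform ("log" or "identity")
par_info <- function(spec, tie_theta = FALSE) {
  name <- character(); role <- character(); proc <- character()
  lab <- character(); cov <- character(); transform <- character()
  add <- function(n, r, p = NA, l = NA, cv = NA, tr) {
    name <<- c(name, n); role <<- c(role, r); proc <<- c(proc, p)
    lab <<- c(lab, l); cov <<- c(cov, cv); transform <<- c(transform, tr)
  }
  for (p in spec$processes)
    for (l in spec$labels)
      add(paste0(p, ":", l), "intensity", p, l, tr = "log")
  for (p in spec$processes)
    for (cv in spec$covariates[[p]])
      for (l in spec$labels)
        add(paste0(p, ":", l, ":", cv), "beta", p, l, cv, tr = "identity")
  if (spec$link %in% c("simple", "inverse", "power_inverse")) {
    add("theta", "theta", tr = "log")
  } else if (spec$link == "separate") {
    if (tie_theta) add("theta", "theta", tr = "log")
    else for (p in spec$processes)
      add(paste0("theta(", p, ")"), "theta", p, tr = "log")
  }
  if (spec$link == "power_inverse") add("alpha", "alpha", tr = "identity")
  tibble(name = name, role = role, process = proc, label = lab,
         covariate = cov, transform = transform)
}

model_from_par <- function(spec, par, info, tie_theta = FALSE) {
  nat <- ifelse(info$transform == "log", exp(par), par)
  intens <- lapply(spec$processes, function(p) {
    nat[info$role == "intensity" & info$process == p]
  })
  names(intens) <- spec$processes
  beta <- NULL
  if (any(info$role == "beta")) {
    beta <- list()
    for (p in spec$processes) {
      covs <- spec$covariates[[p]]
      if (!length(covs)) next
      b <- matrix(NA_real_, nrow(spec$transitions), length(covs),
                  dimnames = list(spec$labels, covs))
      for (cv in covs)
        b[, cv] <- nat[info$role == "beta" & info$process == p & info$covariate == cv]
      beta[[p]] <- b
    }
  }
  theta <- nat[info$role == "theta"]
  if (spec$link == "separate" && tie_theta) theta <- rep(theta, 2)
  alpha <- if (spec$link == "power_inverse") nat[info$role == "alpha"] else NULL
  cmsm_model(spec, intens,
             theta = if (length(theta)) unname(theta) else NULL,
             alpha = unname(alpha), beta = beta)
}

par_from_model <- function(model, info, tie_theta = FALSE) {
  spec <- model$spec
  nat <- numeric(nrow(info))
  for (i in seq_len(nrow(info))) {
    nat[i] <- switch(info$role[i],
      intensity = model$intensities[[info$process[i]]][[info$label[i]]],
      beta = model$beta[[info$process[i]]][info$label[i], info$covariate[i]],
      theta = if (is.na(info$process[i])) model$theta[1] else
        model$theta[match(info$process[i], spec$processes)],
      alpha = model$alpha
    )
  }
  work <- ifelse(info$transform == "log", log(pmax(nat, 1e-8)), nat)
  setNames(work, info$name)
}

init_par <- function(init, ints, spec, info, tie_theta) {
  if (is.null(init)) {
    crude <- crude_rates(ints, spec)
    nat <- numeric(nrow(info))
    for (i in seq_len(nrow(info))) {
      nat[i] <- switch(info$role[i],
        intensity = crude[[info$process[i]]][[info$label[i]]],
        beta = 0, theta = 0.5, alpha = 1)
    }
    return(setNames(ifelse(info$transform == "log", log(nat), nat), info$name))
  }
  if (inherits(init, "cmsm_fit")) return(init_par(init$model, ints, spec, info, tie_theta))
  if (inherits(init, "cmsm_model")) return(par_from_model(init, info, tie_theta))
  if (is.numeric(init)) {
    if (length(init) != nrow(info)) abort("`init` has the wrong length.")
    return(setNames(as.numeric(init), info$name))
  }
  abort("`init` must be NULL, a cmsm_model, a cmsm_fit or a numeric vector.")
}

# occurrence/exposure starting rates: transitions r->s divided by observed
# person-time with origin state r, floored at 0.01 / year
crude_rates <- function(ints, spec) {
  out <- list()
  for (p in spec$processes) {
    pp <- ints$proc[[p]]
    rates <- setNames(numeric(nrow(spec$transitions)), spec$labels)
    for (k in seq_len(nrow(spec$transitions))) {
      r <- spec$transitions[k, 1]; s <- spec$transitions[k, 2]
      n_rs <- sum(pp$from == r & pp$to == s)
      time_r <- sum(pp$dt[pp$from == r])
      rates[k] <- if (time_r > 0) n_rs / time_r else 0
    }
    out[[p]] <- pmax(rates, 0.01)
  }
  out
}

# ---- numeric derivatives ----------------------------------------------------

num_gradient <- function(f, x, rel_step = 1e-6) {
  h <- rel_step * pmax(abs(x), 1)
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h[i]
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, numeric(1))
}

# central finite-difference Hessian with relative step (working scale)
num_hessian <- function(f, x, rel_step = 1e-4) {
  k <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) for (j in seq(i + 1, k)) {
      ej <- numeric(k); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

# ---- summaries --------------------------------------------------------------

#' Akaike information criterion
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of free parameters.
#' @return `2 * k - 2 * loglik`.
#' @examples
#' cmsm_aic(-2448.96, 8)  # 4913.92
#' @export
cmsm_aic <- function(loglik, k) {
  stopifnot(k >= 0)
  2 * k - 2 * loglik
}

#' Likelihood-ratio test between nested fits
#'
#' @param nested,full Two [cmsm_fit()] objects on the same data, the first
#'   nested within the second.
#' @return A tibble with `statistic` (`2 * (loglik_full - loglik_nested)`),
#'   `df` and `p.value` from the upper chi-squared tail.
#' @export
cmsm_lrtest <- function(nested, full) {
  stopifnot(inherits(nested, "cmsm_fit"), inherits(full, "cmsm_fit"))
  df <- full$k - nested$k
  if (df <= 0) abort("`full` must have more free parameters than `nested`.")
  stat <- 2 * (full$loglik - nested$loglik)
  if (stat < -1e-6)
    abort("negative likelihood-ratio statistic: one of the fits did not converge.")
  stat <- max(stat, 0)
  tibble(statistic = stat, df = df, p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Wald confidence intervals on the natural scale
#'
#' Intervals for intensities and frailty variances are computed on the log
#' (working) scale and exponentiated, hence asymmetric about the estimate;
#' intervals for the power exponent and covariate effects are symmetric.
#'
#' @param fit A [cmsm_fit()].
#' @param level Confidence level.
#' @return A tibble with `term`, `estimate`, `conf.low`, `conf.high`.
#' @export
cmsm_confint <- function(fit, level = 0.95) {
  td <- tidy(fit, conf.int = TRUE, conf.level = level)
  td[, c("term", "estimate", "conf.low", "conf.high")]
}

#' @export
logLik.cmsm_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' Tidy a fitted correlated multistate model
#'
#' @param x A [cmsm_fit()].
#' @param conf.int Include Wald confidence limits (see [cmsm_confint()] for
#'   the construction).
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, natural-scale
#'   `estimate`, `std.error` (on the working scale: log scale for intensities
#'   and frailty variances), and optionally `conf.low` / `conf.high`.
#' @export
tidy.cmsm_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  info <- x$par_info
  se <- sqrt(pmax(diag(x$vcov), 0))
  est <- ifelse(info$transform == "log", exp(x$par), x$par)
  out <- tibble(term = info$name, estimate = unname(est), std.error = unname(se))
  if (conf.int) {
    if (anyNA(se)) abort("confidence intervals unavailable: singular Hessian.")
    z <- qnorm(1 - (1 - conf.level) / 2)
    lo <- x$par - z * se; hi <- x$par + z * se
    out$conf.low <- unname(ifelse(info$transform == "log", exp(lo), lo))
    out$conf.high <- unname(ifelse(info$transform == "log", exp(hi), hi))
  }
  out
}

#' Glance at a fitted correlated multistate model
#'
#' @param x A [cmsm_fit()].
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `AIC`, `df` (free parameters),
#'   `nobs` (subjects), `converged`, `gradient_norm`.
#' @export
glance.cmsm_fit <- function(x, ...) {
  tibble(logLik = x$loglik, AIC = x$aic, df = x$k, nobs = x$n_subjects,
         converged = x$converged, gradient_norm = x$gradient_norm)
}

#' @export
print.cmsm_fit <- function(x, ...) {
  cat("Correlated multistate model fit (link:", x$spec$link, ")\n")
  cat(sprintf("  subjects: %d   log-likelihood: %.4f   AIC: %.4f   k: %d\n",
              x$n_subjects, x$loglik, x$aic, x$k))
  cat(sprintf("  converged: %s (|grad| = %.2g)\n", x$converged, x$gradient_norm))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Serialise a fit report to JSON
#'
#' Writes estimates, confidence intervals, log-likelihood, AIC and convergence
#' metadata to a JSON file.
#'
#' @param fit A [cmsm_fit()].
#' @param path Output file.
#' @param level Confidence level for the intervals.
#' @return `path`, invisibly.
#' @export
cmsm_fit_write <- function(fit, path, level = 0.95) {
  td <- tryCatch(tidy(fit, conf.int = TRUE, conf.level = level),
                 error = function(e) tidy(fit))
  report <- list(
    link = fit$spec$link,
    estimates = td,
    loglik = fit$loglik,
    aic = fit$aic,
    k = fit$k,
    n_subjects = fit$n_subjects,
    converged = fit$converged,
    gradient_norm = fit$gradient_norm,
    quadrature = unclass(fit$quad)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
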