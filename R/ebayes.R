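#' Empirical Bayes frailty estimates
#'
#' Computes each subject's posterior-mean frailty given their observed
#' trajectory and the model parameters,
#' `uhat_i = E(U_i | data_i) = Int u f(u) L_i(u) du / Int f(u) L_i(u) du`,
#' with both integrals evaluated by the same quadrature engine as the
#' likelihood and a shared per-subject scaling constant so the ratio is
#' underflow-safe. A subject with no informative intervals gets exactly the
#' prior mean, 1.
#'
#' @param data Panel data (see [cmsm_loglik()]).
#' @param object A [cmsm_fit()] or [cmsm_model()] with a frailty link
#'   (not `"none"`).
#' @param quad A [quad_control()].
#' @return A tibble of class `cmsm_eb` with column `id` and one `uhat` column
#'   (`uhat_<process>` per process for the `"separate"` link).
#' @seealso [cmsm_eb_summary()], [autoplot.cmsm_eb()]
#' @export
cmsm_ebayes <- function(data, object, quad = quad_control()) {
  model <- if (inherits(object, "cmsm_fit")) object$model else object
  stopifnot(inherits(model, "cmsm_model"))
  spec <- model$spec
  if (spec$link == "none")
    abort("empirical Bayes estimates require a frailty link (link != \"none\").")
  ints <- if (inherits(data, "cmsm_intervals")) data else panel_intervals(data, spec)

  out <- tibble(id = ints$ids)
  if (spec$link == "separate") {
    for (j in 1:2) {
      p <- spec$processes[j]
      out[[paste0("uhat_", p)]] <-
        eb_one(ints, model, quad, procs = p, theta = model$theta[j])
    }
  } else {
    out$uhat <- eb_one(ints, model, quad, procs = spec$processes,
                       theta = model$theta[1])
  }
  class(out) <- c("cmsm_eb", class(out))
  out
}

eb_one <- function(ints, model, quad, procs, theta) {
  sh <- 1 / theta
  if (quad$method == "fixed") {
    nd <- frailty_nodes(theta, quad$n_nodes)
    ll <- cond_ll_matrix(ints, model, nd$u, procs)
    lu <- log(nd$u)
    return(vapply(seq_len(ints$n), function(i) {
      num <- logsumexp(nd$lw + ll[i, ] + lu)
      den <- logsumexp(nd$lw + ll[i, ])
      exp(num - den)
    }, numeric(1)))
  }
  grid_u <- unique(sort(c(qgamma(seq(0.02, 0.98, length.out = 13), sh, sh), 1)))
  llg <- cond_ll_matrix(ints, model, grid_u, procs)
  r <- frailty_range(theta)
  vlo <- exp(-r[["hi"]]); vhi <- exp(-r[["lo"]])
  vapply(seq_len(ints$n), function(i) {
    ci <- max(llg[i, ])  # shared scaling for numerator and denominator
    sub <- subset_ints(ints, i)
    ig <- function(v, moment) {
      uu <- -log(v)
      lli <- cond_ll_matrix(sub, model, uu, procs)[1, ]
      uu^moment * exp(lli - ci) * dgamma(uu, sh, sh) / v
    }
    den <- integrate(function(v) ig(v, 0), vlo, vhi, rel.tol = quad$rel_tol,
                     abs.tol = quad$abs_tol, subdivisions = 500L)$value
    if (den <= 0) abort(sprintf("posterior normaliser underflowed for subject %s.",
                                ints$ids[i]))
    num <- integrate(function(v) ig(v, 1), vlo, vhi, rel.tol = quad$rel_tol,
                     abs.tol = quad$abs_tol, subdivisions = 500L)$value
    num / den
  }, numeric(1))
}

#' Cohort summary of empirical Bayes estimates
#'
#' @param eb A [cmsm_ebayes()] table.
#' @return A tibble with one row per frailty column: mean, median, standard
#'   deviation, minimum and maximum of the subject-level estimates.
#' @export
cmsm_eb_summary <- function(eb) {
  cols <- setdiff(names(eb), "id")
  purrr::map_dfr(cols, function(cl) {
    v <- eb[[cl]]
    tibble(estimate = cl, mean = mean(v), median = median(v),
           sd = sd(v), min = min(v), max = max(v))
  })
}
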