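#' Log-likelihood of a panel of subjects
#'
#' Computes the log-likelihood of long-format panel data under a parameterised
#' correlated multistate model. Each subject contributes the product over
#' visits and processes of interval transition probabilities (matrix
#' exponentials of the subject-specific generators); with a frailty link the
#' subject's contribution is integrated over the gamma frailty distribution
#' numerically, after the substitution `v = exp(-u)`.
#'
#' Visits at which a process's state is missing are bridged for that process:
#' its interval chain runs between consecutive *observed* states, leaving the
#' other process untouched. Subjects with fewer than two observed states on a
#' process contribute nothing for that process; a subject with a single visit
#' contributes 0 overall.
#'
#' @param data Panel data: a data frame with columns `id`, `time` (years,
#'   strictly increasing within subject) and one observed-state column per
#'   process named as in the model's spec (integers `1..K`, `NA` = missing),
#'   plus any covariate columns.
#' @param model A [cmsm_model()].
#' @param u If supplied, the conditional log-likelihood at this fixed frailty
#'   value (length 2 for the `"separate"` link, one per process; a scalar is
#'   recycled). If `NULL` (default) the frailty is integrated out.
#' @param quad A [quad_control()].
#' @param by_subject If `TRUE`, return a tibble of per-subject contributions
#'   instead of their sum.
#' @return The total log-likelihood (a number), or a tibble with columns
#'   `id`, `loglik` when `by_subject = TRUE`.
#' @examples
#' spec <- cmsm_spec(processes = c("eGFR", "PU"), link = "inverse")
#' mod <- cmsm_model(spec,
#'   intensities = list(eGFR = c(0.053, 0.496, 0.073, 0.453),
#'                      PU   = c(0.468, 0.653, 0.127, 2.111)),
#'   theta = 0.549)
#' panel <- tibble::tibble(id = "001", time = c(0, 1.14, 2.17, 3.05),
#'                         eGFR = c(1, 1, 2, 2), PU = c(2, 2, 2, 3))
#' cmsm_loglik(panel, mod)
#' @export
cmsm_loglik <- function(data, model, u = NULL, quad = quad_control(),
                        by_subject = FALSE) {
  stopifnot(inherits(model, "cmsm_model"))
  ints <- if (inherits(data, "cmsm_intervals")) data else
    panel_intervals(data, model$spec)
  ll <- if (is.null(u)) {
    integrated_ll_by_subject(ints, model, quad)
  } else {
    conditional_ll_by_subject(ints, model, u)
  }
  if (by_subject) tibble(id = ints$ids, loglik = ll) else sum(ll)
}

conditional_ll_by_subject <- function(ints, model, u) {
  spec <- model$spec
  if (any(!is.finite(u)) || any(u <= 0)) abort("`u` must be positive.")
  if (spec$link == "separate") {
    if (length(u) == 1L) u <- rep(u, 2)
    cond_ll_matrix(ints, model, u[1], procs = spec$processes[1])[, 1] +
      cond_ll_matrix(ints, model, u[2], procs = spec$processes[2])[, 1]
  } else {
    if (length(u) != 1L) abort("`u` must be a scalar for this link.")
    cond_ll_matrix(ints, model, u)[, 1]
  }
}

integrated_ll_by_subject <- function(ints, model, quad) {
  spec <- model$spec
  switch(spec$link,
    none = cond_ll_matrix(ints, model, 1)[, 1],
    separate = {
      integrate_frailty(ints, model, quad, procs = spec$processes[1],
                        theta = model$theta[1]) +
        integrate_frailty(ints, model, quad, procs = spec$processes[2],
                          theta = model$theta[2])
    },
    integrate_frailty(ints, model, quad, procs = spec$processes,
                      theta = model$theta[1])
  )
}

# log of  integral L_i(u) f(u; theta) du  for each subject, over chosen processes
integrate_frailty <- function(ints, model, quad, procs, theta) {
  if (!is.finite(theta) || theta <= 0) abort("`theta` must be positive.")
  if (quad$method == "fixed") {
    nd <- frailty_nodes(theta, quad$n_nodes)
    ll <- cond_ll_matrix(ints, model, nd$u, procs)
    return(apply(ll, 1, function(r) logsumexp(nd$lw + r)))
  }
  # adaptive: per-subject scaled integrand on the v = exp(-u) scale
  sh <- 1 / theta
  grid_u <- unique(sort(c(qgamma(seq(0.02, 0.98, length.out = 13), sh, sh), 1)))
  llg <- cond_ll_matrix(ints, model, grid_u, procs)
  r <- frailty_range(theta)
  vlo <- exp(-r[["hi"]]); vhi <- exp(-r[["lo"]])
  vapply(seq_len(ints$n), function(i) {
    ci <- max(llg[i, ])  # per-subject scaling constant (underflow control)
    sub <- subset_ints(ints, i)
    f <- function(v) {
      uu <- -log(v)
      lli <- cond_ll_matrix(sub, model, uu, procs)[1, ]
      exp(lli - ci) * dgamma(uu, sh, sh) / v
    }
    val <- tryCatch(
      integrate(f, vlo, vhi, rel.tol = quad$rel_tol, abs.tol = quad$abs_tol,
                subdivisions = 500L)$value,
      error = function(e) abort(sprintf(
        "frailty quadrature failed for subject %s: %s",
        ints$ids[i], conditionMessage(e))))
    if (val <= 0) abort(sprintf("frailty integral underflowed for subject %s.",
                                ints$ids[i]))
    ci + log(val)
  }, numeric(1))
}

# ---- panel preprocessing ----------------------------------------------------

# Decompose a validated panel into per-process observation intervals:
# for each process, vectors (subj, dt, from, to) over consecutive observed
# states, plus the covariate values at each interval's left endpoint.
panel_intervals <- function(data, spec) {
  data <- validate_panel(data, spec)
  ids <- unique(data$id)
  si <- match(data$id, ids)
  single <- !(ids %in% data$id[duplicated(data$id)])
  if (any(single))
    warn(sprintf("%d subject(s) have a single visit and contribute 0 to the likelihood.",
                 sum(single)))
  proc <- list()
  for (p in spec$processes) {
    st <- data[[p]]
    obs <- which(!is.na(st))
    s <- si[obs]; tt <- data$time[obs]; ss <- as.integer(st[obs])
    m <- length(obs)
    pair <- if (m >= 2) which(s[-1] == s[-m]) else integer(0)
    covs <- spec$covariates[[p]]
    X <- NULL
    if (length(covs)) {
      X <- as.matrix(data[obs[pair], covs, drop = FALSE])
      if (anyNA(X)) abort(sprintf("missing covariate values (%s) at interval starts.",
                                  paste(covs, collapse = ", ")))
    }
    proc[[p]] <- list(
      subj = s[pair],
      dt = tt[pair + 1] - tt[pair],
      from = ss[pair],
      to = ss[pair + 1],
      X = X
    )
  }
  structure(list(ids = ids, n = length(ids), proc = proc), class = "cmsm_intervals")
}

subset_ints <- function(ints, i) {
  proc <- lapply(ints$proc, function(pp) {
    keep <- pp$subj == i
    list(subj = rep(1L, sum(keep)), dt = pp$dt[keep], from = pp$from[keep],
         to = pp$to[keep], X = if (is.null(pp$X)) NULL else pp$X[keep, , drop = FALSE])
  })
  structure(list(ids = ints$ids[i], n = 1L, proc = proc), class = "cmsm_intervals")
}

# n_subjects x length(u_vec) matrix of conditional log-likelihoods.
# Interval probabilities are floored at 1e-300 before logging so that a
# stray zero cannot poison the frailty integral. The frailty multiplier is
# folded in as u^e per transition (e = 0 none, 1 simple, +/-1 inverse,
# +/-alpha power-inverse on the second process).
cond_ll_matrix <- function(ints, model, u_vec, procs = NULL) {
  spec <- model$spec
  procs <- procs %||% spec$processes
  K <- spec$n_states
  n_trans <- nrow(spec$transitions)
  M <- matrix(0, ints$n, length(u_vec))
  for (p in procs) {
    pp <- ints$proc[[p]]
    if (length(pp$dt) == 0) next
    j <- match(p, spec$processes)
    base <- model$intensities[[p]]
    expo <- switch(spec$link,
      none = rep(0, n_trans),
      simple = rep(1, n_trans),
      power_inverse = ifelse(spec$deterioration, 1, -1) *
        (if (j == 2L) model$alpha else 1),
      ifelse(spec$deterioration, 1, -1)  # inverse, separate
    )
    groups <- if (is.null(pp$X)) {
      list(list(rows = seq_along(pp$dt), x = NULL))
    } else {
      key <- apply(pp$X, 1, paste, collapse = "\r")
      lapply(split(seq_along(key), key), function(rows)
        list(rows = rows, x = pp$X[rows[1], ]))
    }
    for (g in groups) {
      rates0 <- base
      if (!is.null(g$x))
        rates0 <- rates0 * exp(as.numeric(model$beta[[p]] %*% g$x[spec$covariates[[p]]]))
      dts <- pp$dt[g$rows]
      ud <- unique(dts)
      idx <- cbind(pp$from[g$rows], pp$to[g$rows], match(dts, ud))
      LP <- matrix(0, length(g$rows), length(u_vec))
      for (k in seq_along(u_vec)) {
        Q <- make_generator(K, spec$transitions, rates0 * u_vec[k]^expo)
        P <- tpm_multi(Q, ud)
        prob <- P[idx]
        prob[prob < 1e-300] <- 1e-300
        LP[, k] <- log(prob)
      }
      tl <- rowsum(LP, pp$subj[g$rows])
      rows <- as.integer(rownames(tl))
      M[rows, ] <- M[rows, , drop = FALSE] + tl
    }
  }
  if (any(!is.finite(M)))
    abort("non-finite conditional log-likelihood (degenerate parameters).")
  M
}
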