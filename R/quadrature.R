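#' Quadrature options for the frailty integral
#'
#' Controls how the gamma frailty is integrated out of the likelihood (and out
#' of empirical Bayes and frailty-averaged occupancy computations). Integration
#' is performed after the substitution `v = exp(-u)`, which maps the frailty's
#' support onto `(0, 1]`; the integration range is further restricted to the
#' gamma distribution's `[1e-12, 1 - 1e-12]` quantile range so that the rule
#' keeps seeing the prior mass even when `theta` is tiny and the prior is
#' nearly a point mass at 1.
#'
#' @param method `"adaptive"` for adaptive quadrature (`stats::integrate`),
#'   the default for one-off evaluations; `"fixed"` for a deterministic
#'   Gauss--Legendre rule, the default inside [cmsm_fit()].
#' @param rel_tol,abs_tol Tolerances for the adaptive method.
#' @param n_nodes Node count for the fixed Gauss--Legendre rule.
#' @return A list of class `cmsm_quad`.
#' @export
quad_control <- function(method = c("adaptive", "fixed"),
                         rel_tol = 1e-7, abs_tol = 1e-9, n_nodes = 96L) {
  method <- match.arg(method)
  stopifnot(rel_tol > 0, abs_tol > 0, n_nodes >= 2)
  structure(list(method = method, rel_tol = rel_tol, abs_tol = abs_tol,
                 n_nodes = as.integer(n_nodes)),
            class = "cmsm_quad")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# quantile range of a gamma(1/theta, 1/theta) frailty holding all but 2e-12 mass
frailty_range <- function(theta, p_tail = 1e-12) {
  sh <- 1 / theta
  c(lo = qgamma(p_tail, sh, sh), hi = qgamma(1 - p_tail, sh, sh))
}

# Gauss-Legendre rule on [a, b]; the reference rule on [-1, 1] is cached per
# node count (its construction costs an eigendecomposition)
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n, a, b) {
  key <- as.character(n)
  base <- .gl_cache[[key]]
  if (is.null(base)) {
    base <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- base
  }
  list(x = (a + b) / 2 + (b - a) / 2 * base$x, w = base$w * (b - a) / 2)
}

# Gauss-Legendre rule on v = exp(-u) in (0, 1]: nodes u_k and log-weights lw_k
# such that  integral h(u) f(u; theta) du  ~  sum exp(lw_k) h(u_k)
frailty_nodes <- function(theta, n_nodes = 96L) {
  sh <- 1 / theta
  r <- frailty_range(theta)
  gl <- gauss_legendre(n_nodes, exp(-r[["hi"]]), exp(-r[["lo"]]))
  u <- -log(gl$x)
  lw <- log(gl$w) + dgamma(u, sh, sh, log = TRUE) + u  # + u is the 1/v Jacobian
  list(u = u, lw = lw)
}
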