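#' Attach parameter values to a model specification
#'
#' Bundles a [cmsm_spec()] with concrete parameter values: baseline transition
#' intensities per process (per year), the frailty variance `theta`, the
#' power-link exponent `alpha`, and covariate coefficients. The result is the
#' object that the likelihood, occupancy and simulation functions consume; a
#' fitted model ([cmsm_fit()]) contains one evaluated at the maximum-likelihood
#' estimates.
#'
#' @param spec A [cmsm_spec()].
#' @param intensities Named list, one element per process, each a numeric
#'   vector of nonnegative baseline intensities. Vectors may be named by
#'   transition label (`"1->2"`, ...) or given in the spec's transition order.
#' @param theta Frailty variance parameter(s): a single positive number for
#'   shared-frailty links, a length-2 vector for `"separate"`, `NULL` for
#'   `"none"`. The frailty is gamma with shape `1/theta` and rate `1/theta`
#'   (mean 1, variance `theta`).
#' @param alpha Exponent of the `"power_inverse"` link (any real; 1 recovers
#'   the `"inverse"` link exactly).
#' @param beta Optional named list per process of coefficient matrices
#'   (rows = transitions, columns = that process's covariates); covariate
#'   values act as `exp(beta %*% x)` on the intensities.
#' @return An object of class `cmsm_model`.
#' @examples
#' spec <- cmsm_spec(processes = c("eGFR", "PU"), link = "inverse")
#' mod <- cmsm_model(spec,
#'   intensities = list(eGFR = c(0.053, 0.496, 0.073, 0.453),
#'                      PU   = c(0.468, 0.653, 0.127, 2.111)),
#'   theta = 0.549)
#' @export
cmsm_model <- function(spec, intensities, theta = NULL, alpha = NULL, beta = NULL) {
  stopifnot(inherits(spec, "cmsm_spec"))
  n_trans <- nrow(spec$transitions)
  procs <- spec$processes
  if (!is.list(intensities) || !setequal(names(intensities), procs))
    abort("`intensities` must be a named list with one element per process.")
  intensities <- lapply(procs, function(p) {
    v <- intensities[[p]]
    if (!is.null(names(v))) {
      miss <- setdiff(spec$labels, names(v))
      if (length(miss)) abort(paste0("missing intensities for ", p, ": ",
                                     paste(miss, collapse = ", ")))
      v <- v[spec$labels]
    }
    if (length(v) != n_trans)
      abort(sprintf("`intensities$%s` must have %d entries.", p, n_trans))
    if (any(!is.finite(v)) || any(v < 0))
      abort("baseline intensities must be finite and nonnegative.")
    setNames(as.numeric(v), spec$labels)
  })
  names(intensities) <- procs

  nth <- n_frailties(spec)
  if (nth == 0L) {
    if (!is.null(theta)) abort("`theta` is not used when link = \"none\".")
  } else {
    if (is.null(theta) || length(theta) != nth || any(theta <= 0))
      abort(sprintf("`theta` must be %d positive value(s) for link \"%s\".",
                    nth, spec$link))
    theta <- as.numeric(theta)
  }
  if (spec$link == "power_inverse") {
    if (is.null(alpha)) alpha <- 1
    stopifnot(is.finite(alpha))
  } else if (!is.null(alpha)) {
    abort("`alpha` is only used by the power_inverse link.")
  }

  if (!is.null(beta)) {
    for (p in names(beta)) {
      covs <- spec$covariates[[p]]
      b <- as.matrix(beta[[p]])
      if (is.null(covs) || ncol(b) != length(covs) || nrow(b) != n_trans)
        abort(sprintf("`beta$%s` must be a %d x %d matrix matching the covariate design.",
                      p, n_trans, length(covs)))
      dimnames(b) <- list(spec$labels, covs)
      beta[[p]] <- b
    }
  }

  structure(
    list(spec = spec, intensities = intensities, theta = theta,
         alpha = if (spec$link == "power_inverse") as.numeric(alpha) else NULL,
         beta = beta),
    class = "cmsm_model"
  )
}

#' @export
print.cmsm_model <- function(x, ...) {
  cat("Correlated multistate model (link:", x$spec$link, ")\n")
  for (p in x$spec$processes) {
    cat("  ", p, ": ",
        paste(sprintf("%s %.4g", x$spec$labels, x$intensities[[p]]), collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$theta))
    cat("  theta:", paste(signif(x$theta, 4), collapse = ", "), "\n")
  if (!is.null(x$alpha)) cat("  alpha:", signif(x$alpha, 4), "\n")
  invisible(x)
}

#' Write / read a parameterised model as YAML
#'
#' Round-trips a [cmsm_model()] (specification plus parameter values) through
#' a YAML file, the format the command-line interface reads.
#'
#' @param model A [cmsm_model()].
#' @param path File path.
#' @return `cmsm_model_write()` returns `path` invisibly; `cmsm_model_read()`
#'   returns a [cmsm_model()].
#' @export
cmsm_model_write <- function(model, path) {
  stopifnot(inherits(model, "cmsm_model"))
  x <- spec_to_list(model$spec)
  x$intensities <- lapply(model$intensities, as.list)
  x$theta <- model$theta
  x$alpha <- model$alpha
  if (!is.null(model$beta))
    x$beta <- lapply(model$beta, function(b) as.list(as.data.frame(b)))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname cmsm_model_write
#' @export
cmsm_model_read <- function(path) {
  x <- yaml::read_yaml(path)
  spec <- spec_from_list(x)
  beta <- NULL
  if (!is.null(x$beta))
    beta <- lapply(x$beta, function(b) do.call(cbind, lapply(b, unlist)))
  cmsm_model(spec,
             intensities = lapply(x$intensities, unlist),
             theta = unlist(x$theta), alpha = x$alpha, beta = beta)
}
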