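#' Specify a correlated multistate model
#'
#' A model specification bundles everything that defines the structure of a
#' correlated multistate model: the shared state space, the set of allowed
#' instantaneous transitions with their direction labels (worsening vs.
#' improving), the frailty link variant that couples the processes, and the
#' covariate design. It carries no parameter values; see [cmsm_model()] for
#' attaching intensities and variance components.
#'
#' The frailty link decides how a subject's positive random effect `u` enters
#' the transition intensities:
#' \describe{
#'   \item{`"none"`}{no random effect; the two processes are independent
#'     time-homogeneous Markov chains.}
#'   \item{`"simple"`}{`u` multiplies every intensity of both processes:
#'     fast movers move fast in both directions.}
#'   \item{`"inverse"`}{`u` multiplies worsening intensities and `1/u`
#'     improving intensities, for both processes: subjects who deteriorate
#'     quickly also recover slowly.}
#'   \item{`"power_inverse"`}{as `"inverse"` for the first process; the second
#'     process uses `u^alpha` / `u^-alpha`, letting the shared effect act with
#'     a different log-scale variability on the second process.}
#'   \item{`"separate"`}{each process has its own independent frailty, each
#'     acting as in `"inverse"`; the joint likelihood factorises.}
#' }
#'
#' @param n_states Number of states per process (`K >= 2`). States are labelled
#'   `1..K`, 1 being least severe.
#' @param processes Character vector of process names (length 2 by default);
#'   panel data must carry one observed-state column per process with exactly
#'   these names.
#' @param transitions Allowed instantaneous transitions, as a character vector
#'   of `"r->s"` labels or a two-column matrix of `(from, to)` pairs. Defaults
#'   to the reversible birth--death structure (moves between adjacent states
#'   only).
#' @param deterioration Subset of `transitions` flagged as worsening moves,
#'   same format. Defaults to transitions into a higher-numbered state
#'   (`r -> r+1`). The classification is explicit so that non-birth--death
#'   structures remain expressible.
#' @param link Frailty link variant; see Details.
#' @param covariates Optional named list (one element per process) of character
#'   vectors naming covariate columns whose values act log-linearly on that
#'   process's transition intensities, with one coefficient per transition.
#' @return An object of class `cmsm_spec`.
#' @examples
#' spec <- cmsm_spec(processes = c("eGFR", "PU"), link = "inverse")
#' spec
#' n_free_params(spec)
#' @seealso [cmsm_model()], [cmsm_fit()], [re_multiplier()]
#' @export
cmsm_spec <- function(n_states = 3,
                      processes = c("p1", "p2"),
                      transitions = NULL,
                      deterioration = NULL,
                      link = c("none", "simple", "inverse", "power_inverse", "separate"),
                      covariates = NULL) {
  link <- match.arg(link)
  K <- as.integer(n_states)
  if (K < 2) abort("`n_states` must be at least 2.")
  processes <- as.character(processes)
  if (anyDuplicated(processes)) abort("`processes` must be distinct names.")
  if (link == "power_inverse" && length(processes) != 2)
    abort("the power-inverse link is defined for exactly two processes.")

  if (is.null(transitions)) {
    from <- c(seq_len(K - 1), 2:K)
    to <- c(2:K, seq_len(K - 1))
    trans <- cbind(from = from, to = to)
    # order as 1->2, 2->1, 2->3, 3->2, ...
    trans <- trans[order(pmin(from, to), -to), , drop = FALSE]
  } else {
    trans <- parse_transitions(transitions)
  }
  storage.mode(trans) <- "integer"
  if (any(trans < 1L) || any(trans > K))
    abort("transition states must lie in 1..K.")
  if (any(trans[, 1] == trans[, 2]))
    abort("self-transitions are not allowed.")
  labs <- trans_label(trans[, 1], trans[, 2])
  if (anyDuplicated(labs)) abort("duplicated transitions in `transitions`.")

  if (is.null(deterioration)) {
    det <- trans[, 2] == trans[, 1] + 1L
  } else {
    dlabs <- trans_label_of(deterioration)
    if (!all(dlabs %in% labs))
      abort("`deterioration` must be a subset of the allowed transitions.")
    det <- labs %in% dlabs
  }

  if (!is.null(covariates)) {
    if (!is.list(covariates) || is.null(names(covariates)))
      abort("`covariates` must be a named list, one element per process.")
    extra <- setdiff(names(covariates), processes)
    if (length(extra))
      abort(paste0("unknown process in `covariates`: ", paste(extra, collapse = ", ")))
    covariates <- lapply(covariates, as.character)
  }

  structure(
    list(
      n_states = K,
      processes = processes,
      transitions = trans,
      labels = labs,
      deterioration = det,
      link = link,
      covariates = covariates
    ),
    class = "cmsm_spec"
  )
}

trans_label <- function(from, to) paste0(from, "->", to)

parse_transitions <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(x)
    if (ncol(m) != 2) abort("transition matrix must have two columns (from, to).")
    m <- cbind(from = as.integer(m[, 1]), to = as.integer(m[, 2]))
    return(m)
  }
  parts <- strsplit(as.character(x), "->", fixed = TRUE)
  if (any(lengths(parts) != 2)) abort("transitions must look like \"1->2\".")
  cbind(
    from = as.integer(vapply(parts, `[`, "", 1)),
    to = as.integer(vapply(parts, `[`, "", 2))
  )
}

trans_label_of <- function(x) {
  m <- parse_transitions(x)
  trans_label(m[, 1], m[, 2])
}

#' @export
print.cmsm_spec <- function(x, ...) {
  cat("Correlated multistate model specification\n")
  cat("  states per process :", x$n_states, "\n")
  cat("  processes          :", paste(x$processes, collapse = ", "), "\n")
  dirs <- ifelse(x$deterioration, "worsening", "improving")
  cat("  transitions        :", paste(sprintf("%s (%s)", x$labels, dirs), collapse = ", "), "\n")
  cat("  frailty link       :", x$link, "\n")
  if (!is.null(x$covariates)) {
    for (p in names(x$covariates)) {
      if (length(x$covariates[[p]]))
        cat("  covariates on", p, ":", paste(x$covariates[[p]], collapse = ", "), "\n")
    }
  }
  cat("  free parameters    :", n_free_params(x), "\n")
  invisible(x)
}

process_index <- function(spec, process) {
  if (is.character(process)) {
    j <- match(process, spec$processes)
    if (is.na(j)) abort(paste0("unknown process: ", process))
    return(j)
  }
  j <- as.integer(process)
  if (j < 1L || j > length(spec$processes)) abort("process index out of range.")
  j
}

#' Frailty multiplier on a transition intensity
#'
#' Evaluates the link function `g` that scales a baseline transition intensity
#' for a subject with frailty `u`, under the spec's link variant. Worsening
#' and improving transitions may be scaled differently (see [cmsm_spec()]).
#' Every variant satisfies `g(1) = 1`, so a subject with frailty 1 is the
#' "typical" subject with the baseline intensities.
#'
#' @param spec A [cmsm_spec()].
#' @param process Process name or index.
#' @param from,to Transition (must be an allowed transition of `spec`).
#' @param u Positive frailty value(s); vectorised.
#' @param alpha Exponent used only by the `"power_inverse"` variant (applied
#'   to the second process).
#' @return Numeric vector of multipliers, same length as `u`, all positive.
#' @examples
#' spec <- cmsm_spec(link = "inverse")
#' re_multiplier(spec, 1, 1, 2, u = 2)   # worsening: 2
#' re_multiplier(spec, 1, 2, 1, u = 2)   # improving: 0.5
#' @export
re_multiplier <- function(spec, process, from, to, u, alpha = 1) {
  stopifnot(inherits(spec, "cmsm_spec"))
  if (any(!is.finite(u)) || any(u <= 0)) abort("`u` must be positive.")
  j <- process_index(spec, process)
  k <- match(trans_label(as.integer(from), as.integer(to)), spec$labels)
  if (is.na(k)) abort(sprintf("transition %d->%d is not allowed.", from, to))
  worsening <- spec$deterioration[k]
  switch(spec$link,
    none = rep(1, length(u)),
    simple = u,
    inverse = ,
    separate = if (worsening) u else 1 / u,
    power_inverse = {
      a <- if (j == 2L) alpha else 1
      if (worsening) u^a else u^(-a)
    }
  )
}

#' Number of free parameters of a specification
#'
#' Counts the parameters estimated when a model with this specification is fit:
#' one baseline intensity per allowed transition per process, one coefficient
#' per covariate per transition of its process, the frailty variance
#' parameter(s) (none for `"none"`, one otherwise, two for `"separate"`), and
#' the exponent for `"power_inverse"`.
#'
#' @param spec A [cmsm_spec()].
#' @return Integer parameter count (the `k` of the AIC).
#' @examples
#' n_free_params(cmsm_spec(link = "none"))     # 8
#' n_free_params(cmsm_spec(link = "inverse"))  # 9
#' @export
n_free_params <- function(spec) {
  stopifnot(inherits(spec, "cmsm_spec"))
  n_trans <- nrow(spec$transitions)
  n_proc <- length(spec$processes)
  k <- n_trans * n_proc
  if (!is.null(spec$covariates)) {
    for (p in names(spec$covariates))
      k <- k + n_trans * length(spec$covariates[[p]])
  }
  k <- k + switch(spec$link,
    none = 0L, simple = 1L, inverse = 1L, power_inverse = 2L, separate = 2L
  )
  as.integer(k)
}

n_frailties <- function(spec) {
  switch(spec$link, none = 0L, separate = 2L, 1L)
}

#' Write / read a model specification as YAML
#'
#' Serialises the structural part of a model (state space, transitions and
#' direction flags, link variant, covariate design) to a YAML file, and reads
#' it back.
#'
#' @param spec A [cmsm_spec()].
#' @param path File path.
#' @return `cmsm_spec_write()` returns `path` invisibly; `cmsm_spec_read()`
#'   returns a [cmsm_spec()].
#' @export
cmsm_spec_write <- function(spec, path) {
  stopifnot(inherits(spec, "cmsm_spec"))
  yaml::write_yaml(spec_to_list(spec), path)
  invisible(path)
}

spec_to_list <- function(spec) {
  list(
    n_states = spec$n_states,
    processes = as.list(spec$processes),
    transitions = as.list(spec$labels),
    deterioration = as.list(spec$labels[spec$deterioration]),
    link = spec$link,
    covariates = spec$covariates
  )
}

spec_from_list <- function(x) {
  cmsm_spec(
    n_states = x$n_states,
    processes = unlist(x$processes),
    transitions = unlist(x$transitions),
    deterioration = unlist(x$deterioration),
    link = x$link,
    covariates = x$covariates
  )
}

#' @rdname cmsm_spec_write
#' @export
cmsm_spec_read <- function(path) {
  spec_from_list(yaml::read_yaml(path))
}
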