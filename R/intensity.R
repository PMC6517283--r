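#' Subject-specific generator matrix
#'
#' Builds the K x K transition-intensity (generator) matrix of one process for
#' a subject with frailty `u`, optionally at fixed covariate values. Each
#' allowed off-diagonal entry is
#' `g(u) * baseline * exp(beta' x)`, with `g` the spec's frailty link
#' ([re_multiplier()]); diagonal entries make rows sum to zero; disallowed
#' transitions are exactly zero.
#'
#' @param model A [cmsm_model()].
#' @param process Process name or index.
#' @param u Positive frailty value (scalar). For the `"separate"` link this is
#'   the frailty of the chosen process.
#' @param covariates Named numeric vector of covariate values for this
#'   process's design (required when the model has covariates on the process).
#' @return A K x K numeric matrix with zero row sums.
#' @examples
#' spec <- cmsm_spec(processes = c("eGFR", "PU"), link = "inverse")
#' mod <- cmsm_model(spec,
#'   intensities = list(eGFR = c(0.053, 0.496, 0.073, 0.453),
#'                      PU   = c(0.468, 0.653, 0.127, 2.111)),
#'   theta = 0.549)
#' build_generator(mod, "eGFR", u = 2)
#' @export
build_generator <- function(model, process, u = 1, covariates = NULL) {
  stopifnot(inherits(model, "cmsm_model"))
  spec <- model$spec
  if (length(u) != 1 || !is.finite(u) || u <= 0) abort("`u` must be a positive scalar.")
  j <- process_index(spec, process)
  p <- spec$processes[j]
  rates <- model$intensities[[p]]

  g <- vapply(seq_len(nrow(spec$transitions)), function(k) {
    re_multiplier(spec, j, spec$transitions[k, 1], spec$transitions[k, 2], u,
                  alpha = model$alpha %||% 1)
  }, numeric(1))
  rates <- rates * g

  covs <- spec$covariates[[p]]
  if (length(covs)) {
    if (is.null(covariates))
      abort(sprintf("process %s has covariates (%s); supply fixed `covariates` values.",
                    p, paste(covs, collapse = ", ")))
    x <- covariates[covs]
    if (anyNA(x)) abort("covariate values missing for the process design.")
    rates <- rates * exp(as.numeric(model$beta[[p]] %*% x))
  }

  make_generator(spec$n_states, spec$transitions, rates)
}

make_generator <- function(K, transitions, rates) {
  Q <- matrix(0, K, K)
  Q[transitions] <- rates
  diag(Q) <- -rowSums(Q)
  Q
}

validate_generator <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q) || any(!is.finite(Q)))
    abort("`Q` must be a finite square matrix.")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) abort("off-diagonal generator entries must be nonnegative.")
  if (max(abs(rowSums(Q))) > 1e-8) abort("generator rows must sum to zero.")
  invisible(Q)
}

#' Interval transition-probability matrix
#'
#' Computes `P(dt) = expm(Q * dt)`, the matrix of state-to-state transition
#' probabilities over an interval of length `dt` for a time-homogeneous Markov
#' chain with generator `Q`. Uses an eigendecomposition fast path when the
#' generator is diagonalisable with a well-conditioned eigenbasis, and falls
#' back to Pade scaling-and-squaring (`Matrix::expm`) otherwise.
#'
#' @param Q Generator matrix (nonnegative off-diagonals, zero row sums).
#' @param dt Nonnegative interval length(s) in years; vectorised.
#' @return For scalar `dt`, a K x K stochastic matrix; for vector `dt`, a
#'   K x K x length(dt) array.
#' @examples
#' Q <- matrix(c(-0.3, 0.3, 0.7, -0.7), 2, 2, byrow = TRUE)
#' transition_matrix(Q, 1)[1, 1]  # 0.7 + 0.3 * exp(-1)
#' @export
transition_matrix <- function(Q, dt) {
  validate_generator(Q)
  if (any(dt < 0) || any(!is.finite(dt))) abort("`dt` must be finite and nonnegative.")
  P <- tpm_multi(Q, dt)
  if (length(dt) == 1L) P[, , 1] else P
}

# matrix exponentials of Q*dt for a vector of dt, as a K x K x n array
tpm_multi <- function(Q, dts) {
  K <- nrow(Q)
  n <- length(dts)
  ev <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(ev)) {
    Vi <- tryCatch(solve(ev$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      # sanity: does the decomposition reconstruct Q?
      recon <- ev$vectors %*% (ev$values * Vi)
      scale <- max(1, max(abs(Q)))
      if (max(Mod(recon - Q)) < 1e-9 * scale) {
        # P(dt) = sum_k exp(val_k * dt) * v_k w_k', vectorised over dt
        M <- matrix(0i, K, K * K)
        for (k in seq_len(K))
          M[k, ] <- as.vector(ev$vectors[, k] %o% Vi[k, ])
        E <- exp(outer(dts, ev$values))        # n x K
        P <- Re(E %*% M)                       # n x K^2, column-major slices
        P[P < 0] <- 0; P[P > 1] <- 1
        rs <- P %*% slice_rowsum_mat(K)            # row sums of each slice
        if (isTRUE(max(abs(rs - 1)) < 1e-8))
          return(array(t(P), dim = c(K, K, n)))
      }
    }
  }
  # robust fallback: Pade scaling-and-squaring per interval
  if (any(!is.finite(Q))) abort("non-finite generator entries.")
  arr <- array(0, dim = c(K, K, n))
  for (i in seq_len(n)) {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * dts[i], sparse = FALSE)))
    arr[, , i] <- pmin(pmax(P, 0), 1)
  }
  if (any(!is.finite(arr))) abort("matrix exponential produced non-finite entries.")
  arr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# K^2 x K indicator mapping flattened (column-major) K x K slices to row sums
.rs_cache <- new.env(parent = emptyenv())
slice_rowsum_mat <- function(K) {
  key <- as.character(K)
  m <- .rs_cache[[key]]
  if (is.null(m)) {
    m <- kronecker(rep(1, K), diag(K))
    .rs_cache[[key]] <- m
  }
  m
}
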