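# Pseudo-inverse (linear least-squares) unmixing of mixed pulses.
#
# Model: y = A x + N with N zero-mean white Gaussian, so the
# maximum-likelihood per-crystal amplitudes are x-hat = (A'A)^-1 A' y.
# The K x K normal equations are solved through a Cholesky factorization
# rather than an explicit inverse; assemble_matrix() guarantees A'A is
# well-conditioned.

pinv_factor <- function(a) chol(crossprod(a))

pinv_apply <- function(r, a, y) {
  backsolve(r, backsolve(r, crossprod(a, y), transpose = TRUE))
}

#' Unmix one waveform by pseudo-inverse
#'
#' Solves the least-squares problem `min ||y - A x||^2` for the per-crystal
#' component amplitudes of one mixed record. Under the additive white
#' Gaussian noise model this is the maximum-likelihood estimate. The
#' solution is unconstrained: small negative estimates are legitimate
#' noise-driven outcomes and are not clipped by default.
#'
#' @param a A [assemble_matrix()] template matrix.
#' @param y A [pulse_waveform()] on the same grid, or a numeric vector of
#'   matching length.
#' @param baseline_subtract Subtract the mean of the leading
#'   `baseline_samples` samples from `y` before solving (the same treatment
#'   the templates received); default `TRUE`.
#' @param baseline_samples Number of leading baseline samples (default 80).
#' @param nonnegative If `TRUE`, solve the nonnegative least-squares problem
#'   instead (exact active-set enumeration, practical for small K).
#' @return An object of class `"energy_estimate"`: named numeric vector of
#'   K amplitudes in template-peak units, with attributes `method = "pinv"`
#'   and `label_type = "amplitude"`.
#' @seealso [convert_estimate()], [batch_estimate()]
#' @export
pinv_solve <- function(a, y, baseline_subtract = TRUE,
                       baseline_samples = 80L, nonnegative = FALSE) {
  stopifnot(inherits(a, "template_matrix"))
  if (inherits(y, "pulse_waveform")) {
    if (!same_grid(y$grid, a$grid)) stop("waveform grid does not match templates")
    y <- y$samples
  }
  if (length(y) != nrow(a$profiles)) stop("length(y) must match templates")
  if (baseline_subtract) y <- y - mean(y[seq_len(baseline_samples)])
  x <- if (nonnegative) nnls_enum(a$profiles, y)
  else drop(pinv_apply(pinv_factor(a$profiles), a$profiles, y))
  names(x) <- a$crystal_names
  structure(x, method = "pinv", label_type = "amplitude",
            class = "energy_estimate")
}

# Exact NNLS by active-set enumeration: for each subset S of free
# coordinates solve the restricted LS, keep feasible solutions, return the
# one with smallest residual. Exponential in K but K is the number of
# crystals (2 in practice).
nnls_enum <- function(a, y) {
  k <- ncol(a)
  best <- NULL; best_rss <- Inf
  for (bits in 0:(2^k - 1)) {
    free <- which(bitwAnd(bits, 2^(seq_len(k) - 1L)) > 0)
    x <- numeric(k)
    if (length(free) > 0) {
      af <- a[, free, drop = FALSE]
      xf <- drop(pinv_apply(pinv_factor(af), af, y))
      if (any(xf < 0)) next
      x[free] <- xf
    }
    rss <- sum((y - a %*% x)^2)
    if (rss < best_rss) { best_rss <- rss; best <- x }
  }
  best
}

#' Convert an estimate between label types
#'
#' The solve always returns component amplitudes in template-peak units
#' (templates are peak-normalized, so these are direct amplitude-label
#' estimates). Integral-label estimates are obtained by multiplying each
#' component by the time integral of its template column; the solve itself
#' is identical for both label types.
#'
#' @param x An `"energy_estimate"` (or an `n x K` matrix of estimates).
#' @param a The [assemble_matrix()] used for the solve.
#' @param label_type `"amplitude"` or `"integral"`.
#' @return The estimate(s) in the requested label units.
#' @export
convert_estimate <- function(x, a, label_type = c("amplitude", "integral")) {
  label_type <- match.arg(label_type)
  stopifnot(inherits(a, "template_matrix"))
  if (label_type == "amplitude") {
    attr(x, "label_type") <- "amplitude"
    return(x)
  }
  ints <- colSums(a$profiles) * a$grid$sample_period
  out <- if (is.matrix(x)) sweep(x, 2L, ints, `*`) else {
    y <- unclass(x) * ints
    names(y) <- names(x)
    y
  }
  attr(out, "method") <- attr(x, "method")
  attr(out, "label_type") <- "integral"
  attr(out, "class") <- oldClass(x)
  out
}

#' Unmix every event of a dataset
#'
#' Applies the pseudo-inverse solve to all waveforms of a dataset with one
#' factorization of `A'A` reused across events; equivalent to (and tested
#' against) the per-event loop.
#'
#' @param a A [assemble_matrix()] template matrix.
#' @param dataset A `mixed_event_dataset` (or bare `n x n_samples` matrix).
#' @param label_type `"integral"` or `"amplitude"`: units of the returned
#'   estimates (see [convert_estimate()]).
#' @param baseline_subtract,baseline_samples As in [pinv_solve()].
#' @return `n_events x K` matrix of estimates with attributes
#'   `method = "pinv"` and `label_type`.
#' @export
batch_estimate <- function(a, dataset,
                           label_type = c("integral", "amplitude"),
                           baseline_subtract = TRUE, baseline_samples = 80L) {
  label_type <- match.arg(label_type)
  stopifnot(inherits(a, "template_matrix"))
  w <- if (is.matrix(dataset)) dataset else {
    stopifnot(inherits(dataset, "mixed_event_dataset"))
    if (!same_grid(dataset$grid, a$grid)) {
      stop("dataset grid does not match templates")
    }
    dataset$waveforms
  }
  if (nrow(w) < 1L) stop("dataset is empty")
  if (baseline_subtract) {
    w <- w - rowMeans(w[, seq_len(baseline_samples), drop = FALSE])
  }
  r <- pinv_factor(a$profiles)
  xh <- t(pinv_apply(r, a$profiles, t(w)))   # n x K
  colnames(xh) <- a$crystal_names
  xh <- structure(xh, method = "pinv", label_type = "amplitude")
  convert_estimate(xh, a, label_type)
}
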