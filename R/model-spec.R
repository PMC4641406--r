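#' Specify a model of continuous trait evolution
#'
#' Families:
#' \describe{
#'   \item{`BM1`}{Brownian motion, one rate `sigma2` and root state `x0`.}
#'   \item{`BMS`}{Multi-rate Brownian motion: one `sigma2` per regime.}
#'   \item{`ACDC`}{Brownian motion whose rate changes exponentially through
#'     time, `sigma2(t) = sigma2 * exp(r * t)` with `t` the height from the
#'     root; `r < 0` is the decelerating early-burst (DC) case, `r > 0` the
#'     accelerating (AC) case.}
#'   \item{`OU1`}{Single-regime Ornstein-Uhlenbeck with rate `sigma2`,
#'     selection strength `alpha`, optimum `theta`.}
#'   \item{`OUM`, `OUMV`, `OUMA`, `OUMVA`}{Two-or-more-regime OU in which,
#'     respectively, the optima; optima and rates; optima and selection
#'     strengths; or all three vary among regimes.}
#' }
#'
#' For OU families the root state is fixed at the optimum of the root regime
#' (a non-stationary start); for BM-type families `x0` is an explicit
#' parameter. Per-regime parameters are named by regime label.
#'
#' @param family Model family, see Details.
#' @param sigma2 Diffusion rate(s), strictly positive; named by regime where
#'   the family calls for per-regime rates.
#' @param alpha Selection strength(s), strictly positive (OU families).
#' @param theta Optimum (OU families), per regime where applicable.
#' @param r Exponential rate-change exponent (`ACDC` only).
#' @param x0 Root state (BM-type families only).
#' @param regimes Regime labels, required for multi-regime families when the
#'   parameter vectors are unnamed.
#' @return A `model_spec` object.
#' @export
#' @examples
#' model_spec("BM1", sigma2 = 1, x0 = 0)
#' model_spec("OUMVA",
#'   sigma2 = c(a = 0.5, b = 2), alpha = c(a = 2, b = 0.5),
#'   theta = c(a = -1, b = 1)
#' )
model_spec <- function(family = c("BM1", "BMS", "ACDC", "OU1", "OUM", "OUMV",
                                  "OUMA", "OUMVA"),
                       sigma2, alpha = NULL, theta = NULL, r = NULL,
                       x0 = NULL, regimes = NULL) {
  family <- match.arg(family)
  multi <- .family_multi(family)
  if (is.null(regimes)) {
    regimes <- names(sigma2) %||% names(theta) %||% names(alpha)
  }
  fix_len <- function(p, per_regime, what) {
    if (is.null(p)) abort(sprintf("family %s requires `%s`", family, what))
    if (per_regime) {
      if (length(p) == 1 && length(regimes) > 1) p <- setNames(rep(p, length(regimes)), regimes)
      if (is.null(names(p))) names(p) <- regimes
      if (is.null(names(p)) || anyNA(names(p))) {
        abort(sprintf("`%s` must be named by regime for family %s", what, family))
      }
    } else {
      if (length(p) != 1) abort(sprintf("`%s` must be scalar for family %s", what, family))
    }
    p
  }
  if (!all(is.finite(sigma2)) || any(sigma2 <= 0)) abort("`sigma2` must be finite and > 0")
  sigma2 <- fix_len(sigma2, multi$sigma2, "sigma2")
  if (family %in% .ou_families()) {
    if (!all(is.finite(alpha)) || any(alpha <= 0)) abort("`alpha` must be finite and > 0")
    alpha <- fix_len(alpha, multi$alpha, "alpha")
    theta <- fix_len(theta, multi$theta, "theta")
    if (!all(is.finite(theta))) abort("`theta` must be finite")
    x0 <- NULL
  } else {
    x0 <- x0 %||% 0
    if (!is.finite(x0)) abort("`x0` must be finite")
    alpha <- NULL
    theta <- NULL
  }
  if (family == "ACDC") {
    r <- r %||% 0
    if (!is.finite(r)) abort("`r` must be finite")
  } else {
    r <- NULL
  }
  structure(
    list(
      family = family, sigma2 = sigma2, alpha = alpha, theta = theta,
      r = r, x0 = x0, regimes = regimes
    ),
    class = "model_spec"
  )
}

.ou_families <- function() c("OU1", "OUM", "OUMV", "OUMA", "OUMVA")

# which parameters vary per regime
.family_multi <- function(family) {
  switch(family,
    BM1 = list(sigma2 = FALSE, alpha = FALSE, theta = FALSE),
    BMS = list(sigma2 = TRUE, alpha = FALSE, theta = FALSE),
    ACDC = list(sigma2 = FALSE, alpha = FALSE, theta = FALSE),
    OU1 = list(sigma2 = FALSE, alpha = FALSE, theta = FALSE),
    OUM = list(sigma2 = FALSE, alpha = FALSE, theta = TRUE),
    OUMV = list(sigma2 = TRUE, alpha = FALSE, theta = TRUE),
    OUMA = list(sigma2 = FALSE, alpha = TRUE, theta = TRUE),
    OUMVA = list(sigma2 = TRUE, alpha = TRUE, theta = TRUE)
  )
}

# number of free parameters (AICc k) for a family with m regimes
.family_k <- function(family, m, se_mode = "none") {
  k <- switch(family,
    BM1 = 2, # sigma2, x0
    BMS = m + 1,
    ACDC = 3, # sigma2, r, x0
    OU1 = 3, # sigma2, alpha, theta (root tied to theta)
    OUM = m + 2,
    OUMV = 2 * m + 1,
    OUMA = 2 * m + 1,
    OUMVA = 3 * m
  )
  if (se_mode == "estimate") k <- k + 1
  k
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec: %s>\n", x$family))
  fmt <- function(v) paste(sprintf("%s=%.6g", names(v) %||% "", v), collapse = ", ")
  cat("  sigma2:", fmt(x$sigma2), "\n")
  if (!is.null(x$alpha)) cat("  alpha: ", fmt(x$alpha), "\n")
  if (!is.null(x$theta)) cat("  theta: ", fmt(x$theta), "\n")
  if (!is.null(x$r)) cat("  r:     ", format(x$r, digits = 6), "\n")
  if (!is.null(x$x0)) cat("  x0:    ", format(x$x0, digits = 6), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
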