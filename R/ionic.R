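# Aliev-Panfilov phenomenological ionic model (dimensionless form).

#' Aliev-Panfilov parameters
#'
#' @param K,a,b,eps0,c1,c2 dimensionless constants; `a` is the excitation
#'   threshold and the factor `eps0 + c1 w / (c2 + u)` tunes the restitution
#'   properties of the recovery variable.
#' @return object of class `ionic_params`
#' @export
ionic_params <- function(K = 8, a = 0.01, b = 0.15, eps0 = 0.002,
                         c1 = 0.2, c2 = 0.3) {
  p <- list(K = K, a = a, b = b, eps0 = eps0, c1 = c1, c2 = c2)
  stopifnot(all(vapply(p, is.finite, logical(1))), K > 0)
  class(p) <- "ionic_params"
  p
}

#' Ionic current I_ion(u, w) = K u (u - a)(u - 1) + u w
#'
#' @param u,w potential and gating vectors (same length)
#' @param p `ionic_params`
#' @return current vector (elementwise, no clipping)
#' @export
ionic_current <- function(u, w, p) {
  if (length(u) != length(w)) stop("shape mismatch: length(u) != length(w)")
  p$K * u * (u - p$a) * (u - 1) + u * w
}

#' Gating dynamics g(u, w) = (eps0 + c1 w / (c2 + u)) * (-w - K u (u - b - 1))
#'
#' The recovery variable evolves as dw/dt + g(u, w) = 0, i.e. dw/dt = -g(u, w);
#' all solver updates use this sign convention.
#'
#' @inheritParams ionic_current
#' @param guard smallest allowed |c2 + u| before aborting (division guard)
#' @return rate vector g(u, w)
#' @export
gating_rhs <- function(u, w, p, guard = 1e-8) {
  if (length(u) != length(w)) stop("shape mismatch: length(u) != length(w)")
  den <- p$c2 + u
  if (any(abs(den) < guard))
    stop("gating_rhs: c2 + u too close to zero (|c2+u| < guard)")
  (p$eps0 + p$c1 * w / den) * (-w - p$K * u * (u - p$b - 1))
}
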