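# Internal scalar root finding for strictly monotone residual functions.
#
# Both nonlinear solves in the model (interface charge neutrality in psi0,
# channel electrostatics in phi_ch) have strictly monotone residuals, so a
# sign-changing bracket contains exactly one root and bisection is globally
# convergent. Brackets start at [-2, 2] V and expand geometrically; failure
# to find a sign change before the physical limit signals inconsistent
# parameters.

.expand_bracket <- function(f, lo = -2, hi = 2, limit = 5, what = "root") {
  flo <- f(lo); fhi <- f(hi)
  while (sign(flo) == sign(fhi) && sign(flo) != 0) {
    if (lo <= -limit && hi >= limit) {
      abort(sprintf(
        "no %s in the physical range [%g, %g] V (residuals %.3g and %.3g have equal sign); check parameter consistency",
        what, -limit, limit, flo, fhi))
    }
    w <- hi - lo
    lo <- max(lo - w, -limit)
    hi <- min(hi + w, limit)
    flo <- f(lo); fhi <- f(hi)
  }
  list(lo = lo, hi = hi, flo = flo, fhi = fhi)
}

# bisection to machine precision on x, then report the best |f| seen
.bisect <- function(f, lo, hi, flo, fhi, tol_f = 1e-12, max_iter = 200L) {
  if (flo == 0) return(list(root = lo, f = 0, iterations = 0L))
  if (fhi == 0) return(list(root = hi, f = 0, iterations = 0L))
  best_x <- lo; best_f <- flo
  if (abs(fhi) < abs(flo)) { best_x <- hi; best_f <- fhi }
  iter <- 0L
  while (iter < max_iter) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break # interval at machine resolution
    fm <- f(mid)
    iter <- iter + 1L
    if (abs(fm) < abs(best_f)) { best_x <- mid; best_f <- fm }
    if (fm == 0) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
  }
  list(root = best_x, f = best_f, iterations = iter)
}

# safeguarded Newton with numerical derivative; falls back to bisection
# steps whenever the Newton step leaves the bracket
.newton_safeguarded <- function(f, lo, hi, flo, fhi, tol_f = 1e-12,
                                max_iter = 100L) {
  x <- (lo + hi) / 2
  fx <- f(x)
  iter <- 1L
  best_x <- x; best_f <- fx
  while (iter < max_iter && abs(fx) > 0) {
    h <- max(abs(x), 1) * 1e-7
    dfdx <- (f(x + h) - f(x - h)) / (2 * h)
    x_new <- if (is.finite(dfdx) && dfdx != 0) x - fx / dfdx else NA_real_
    if (!is.finite(x_new) || x_new <= lo || x_new >= hi) {
      x_new <- (lo + hi) / 2 # safeguard: bisect
    }
    if (x_new == x) break
    fx_new <- f(x_new)
    iter <- iter + 1L
    if (sign(fx_new) == sign(flo)) { lo <- x_new; flo <- fx_new } else { hi <- x_new; fhi <- fx_new }
    x <- x_new; fx <- fx_new
    if (abs(fx) < abs(best_f)) { best_x <- x; best_f <- fx }
    if (abs(best_f) <= tol_f && (hi - lo) < 1e-12) break
  }
  # polish with bisection so the two methods share the same terminal accuracy
  out <- .bisect(f, lo, hi, flo, fhi, tol_f = tol_f)
  if (abs(out$f) < abs(best_f)) { best_x <- out$root; best_f <- out$f }
  list(root = best_x, f = best_f, iterations = iter + out$iterations)
}

.solve_monotone <- function(f, lo = -2, hi = 2, limit = 5, tol_f = 1e-12,
                            method = c("bisection", "newton"),
                            what = "root") {
  method <- match.arg(method)
  br <- .expand_bracket(f, lo, hi, limit = limit, what = what)
  if (method == "bisection") {
    .bisect(f, br$lo, br$hi, br$flo, br$fhi, tol_f = tol_f)
  } else {
    .newton_safeguarded(f, br$lo, br$hi, br$flo, br$fhi, tol_f = tol_f)
  }
}
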