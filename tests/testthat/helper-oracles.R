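## Numerical characteristic-function inversion (Imhof-type) for the
## upper tail of a weighted sum of independent 1-df chi-squares:
## independent oracle for the Monte-Carlo theoretical fit test.
imhofTail <- function(q, w) {
  integrand <- function(u) {
    theta <- 0.5 * rowSums(sapply(w, function(wj) atan(wj * u))) - 0.5 * q * u
    rho <- exp(0.25 * rowSums(sapply(w, function(wj) log1p(wj^2 * u^2))))
    sin(theta) / (u * rho)
  }
  ## the integrand decays polynomially and oscillates; a finite cutoff
  ## with many subdivisions is accurate to well below MC resolution
  0.5 + integrate(function(u) integrand(cbind(u)), lower = 1e-8,
                  upper = 400, subdivisions = 5000L,
                  rel.tol = 1e-8)$value / pi
}
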