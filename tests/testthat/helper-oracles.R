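# Independent reference implementations used as oracles. These deliberately
# share no code with the package: scalar arithmetic, adaptive Gauss-Kronrod
# quadrature (stats::integrate) and plain Riemann sums, against the
# package's vectorised composite-trapezoid machinery.

# scalar Mermin dielectric function, straight transcription
oracle_eps_mermin <- function(k, omega, rs, gamma) {
  kf <- (9 * pi / 4)^(1 / 3) / rs
  lind <- function(w) {            # complex Lindhard at complex frequency w
    z <- k / (2 * kf)
    u <- w / (k * kf)
    g <- function(x) (1 - x^2) * (log(x + 1) - log(x - 1))
    1 + (1 / (pi * kf)) / z^2 * (0.5 + (g(z - u) + g(z + u)) / (8 * z))
  }
  z <- k / (2 * kf)
  eps0 <- 1 + (1 / (pi * kf)) / z^2 *
    (0.5 + (1 - z^2) / (4 * z) * log(abs((1 + z) / (1 - z))))
  epsL <- lind(complex(real = omega, imaginary = gamma))
  igw <- complex(imaginary = gamma) / omega
  1 + (1 + igw) * (epsL - 1) / (1 + igw * (epsL - 1) / (eps0 - 1))
}

# brute-force dense adaptive quadrature of the linear-response stopping
# integral; the inner frequency integral is split around the plasmon line
# (located by uniroot on Re eps) so the adaptive rule resolves it
oracle_stopping <- function(v, rs, gamma = 0.02) {
  kf <- (9 * pi / 4)^(1 / 3) / rs
  wp <- sqrt(3) * rs^(-1.5)
  inner <- function(k) {
    kv <- k * v
    f <- function(om) om * Im(-1 / oracle_eps_mermin(k, om, rs, gamma))
    wbg <- sqrt(wp^2 + 0.6 * k^2 * kf^2 + k^4 / 4)
    wc <- NA_real_
    lo <- 0.5 * wbg; hi <- 1.5 * wbg
    relo <- Re(oracle_eps_mermin(k, lo, rs, gamma))
    rehi <- Re(oracle_eps_mermin(k, hi, rs, gamma))
    if (is.finite(relo) && is.finite(rehi) && relo * rehi < 0) {
      wc <- stats::uniroot(function(w) Re(oracle_eps_mermin(k, w, rs, gamma)),
                           c(lo, hi), tol = 1e-12)$root
    }
    brks <- c(kv * 1e-9, kv)
    if (is.finite(wc)) {
      brks <- c(brks, wc + gamma * c(-50, -5, 0, 5, 50))
    }
    brks <- sort(unique(pmin(pmax(brks, kv * 1e-9), kv)))
    tot <- 0
    for (i in seq_len(length(brks) - 1)) {
      if (brks[i + 1] <= brks[i] * (1 + 1e-13)) next
      tot <- tot + stats::integrate(function(x) vapply(x, f, numeric(1)),
                                    brks[i], brks[i + 1],
                                    rel.tol = 1e-8, abs.tol = 1e-14,
                                    subdivisions = 500L,
                                    stop.on.error = FALSE)$value
    }
    tot
  }
  F_lnk <- function(lk) vapply(lk, function(l) inner(exp(l)), numeric(1))
  res <- stats::integrate(F_lnk, log(1e-3 / rs), log(max(50 / rs, 3 * v)),
                          rel.tol = 1e-7, abs.tol = 1e-14,
                          subdivisions = 800L, stop.on.error = FALSE)
  2 / (pi * v^2) * res$value
}

# dense-grid quadrature of the logarithmic ELF moment for a Drude model,
# evaluated directly from the analytic form at n points
oracle_drude_I_eV <- function(A, omega0_ha, gamma_ha, n = 1e6,
                              lo_eV = 0.01, hi_eV = 1e5) {
  ha <- 27.211386
  w <- exp(seq(log(lo_eV / ha), log(hi_eV / ha), length.out = n))
  elf <- numeric(n)
  for (i in seq_along(A)) {
    elf <- elf + A[i] * gamma_ha[i] * w /
      ((w^2 - omega0_ha[i]^2)^2 + (gamma_ha[i] * w)^2)
  }
  f <- w * elf
  dw <- diff(w)
  num <- sum(0.5 * (f[-1] * log(w[-1]) + f[-n] * log(w[-n])) * dw)
  den <- sum(0.5 * (f[-1] + f[-n]) * dw)
  exp(num / den) * ha
}

# fixed-step Riemann midpoint integration of dT / (rho S(T))
oracle_csda_range <- function(T0, I_eV, material, T_min = 1, n = 1e5) {
  Tm <- seq(T_min, T0, length.out = n + 1)
  mid <- 0.5 * (Tm[-1] + Tm[-(n + 1)])
  h <- (T0 - T_min) / n
  sum(h / (material$density * bethe_mass_stopping(mid, I_eV, material)))
}

# shared slow-to-build fixtures, cached for the test session
test_cache <- new.env(parent = emptyenv())

cached_default_kernel <- function() {
  if (is.null(test_cache$kern)) test_cache$kern <- default_kernel()
  test_cache$kern
}
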