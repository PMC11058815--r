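# Free-electron-gas stopping kernels S(v, r_s).
#
# The built-in analytic kernel is linear response with the Mermin dielectric
# function (the number-conserving relaxation-time extension of Lindhard).
# Linear response loses accuracy around the stopping maximum — that is a
# documented limitation, not hidden; non-perturbative kernels enter as
# tabulated files through load_kernel_table().

# internal: Fermi momentum (= Fermi velocity in au) for Wigner-Seitz radius rs
fermi_momentum <- function(rs) (9 * pi / 4)^(1 / 3) / rs

# internal: complex Lindhard dielectric at complex frequency w (Hartree).
# k and w may be equal-shaped arrays. Principal-branch logs taken separately
# give the correct retarded continuation for Im(w) > 0.
lindhard_eps_complex <- function(k, w, kf) {
  z <- k / (2 * kf)
  u <- w / (k * kf)            # v_F = k_F in au
  xm <- z - u
  xp <- z + u
  G <- function(x) (1 - x * x) * (log(x + 1) - log(x - 1))
  f <- 0.5 + (G(xm) + G(xp)) / (8 * z)
  chi2 <- 1 / (pi * kf)
  1 + chi2 / (z * z) * f
}

# internal: static (omega = 0) Lindhard dielectric, real k vector
lindhard_eps_static <- function(k, kf) {
  z <- k / (2 * kf)
  lg <- ifelse(abs(z - 1) < 1e-12, 0, (1 - z^2) / (4 * z) * log(abs((1 + z) / (1 - z))))
  1 + (1 / (pi * kf)) / z^2 * (0.5 + lg)
}

# internal: Mermin dielectric on equal-shaped arrays k, omega (real, Hartree);
# eps0 is the static Lindhard dielectric at the same k (recycled by R).
mermin_eps <- function(k, omega, kf, gamma, eps0 = NULL) {
  if (is.null(eps0)) eps0 <- lindhard_eps_static(k, kf)
  epsL <- lindhard_eps_complex(k, complex(real = omega, imaginary = gamma), kf)
  ig_w <- complex(imaginary = gamma) / omega
  num <- (1 + ig_w) * (epsL - 1)
  den <- 1 + ig_w * (epsL - 1) / (eps0 - 1)
  1 + num / den
}

# internal: energy-loss function Im[-1/eps_M]
mermin_im_inv_eps <- function(k, omega, kf, gamma, eps0 = NULL) {
  e <- mermin_eps(k, omega, kf, gamma, eps0)
  Im(-1 / e)
}

#' Linear-response (Mermin/Lindhard) stopping power of a free electron gas
#'
#' Stopping power of a unit point charge (bare proton) moving at velocity
#' \code{v} through a homogeneous electron gas of Wigner-Seitz radius
#' \code{r_s}:
#' \deqn{S(v) = \frac{2}{\pi v^2}\int_0^\infty \frac{dk}{k}
#'       \int_0^{kv} \omega\,\mathrm{Im}\!\left[\frac{-1}{\epsilon(k,\omega)}
#'       \right] d\omega,}
#' with \eqn{\epsilon} the Mermin dielectric function at damping
#' \code{damping}. The undamped RPA plasmon is a delta line; the Mermin form
#' broadens it while conserving the f-sum, which keeps the double quadrature
#' robust. The outer k integral runs on a logarithmic grid over
#' \code{[1e-3/r_s, max(50/r_s, 3v)]} (the upper limit always covers the
#' close-collision region \eqn{k \le 2v}); the inner frequency integral uses
#' a composite trapezoid grid: uniform points over \code{[0, kv]} plus
#' Cauchy-spaced points concentrated on the plasmon line, whose position is
#' located by bisection on \eqn{\mathrm{Re}\,\epsilon = 0}.
#'
#' @param v projectile velocity in atomic units (> 0).
#' @param r_s Wigner-Seitz radius in bohr, within [0.3, 10].
#' @param damping Mermin damping gamma in Hartree (> 0). Default 0.02.
#' @param nk outer (momentum) grid size.
#' @param nw inner (frequency) grid size.
#' @return Stopping power in Hartree/bohr (scalar).
#' @examples
#' \donttest{
#' lindhard_stopping(2, 2)        # near the stopping maximum
#' bethe_asymptote(10, plasmon_frequency(2))
#' }
#' @export
lindhard_stopping <- function(v, r_s, damping = 0.02, nk = 400L, nw = 300L) {
  if (!is.finite(v) || v <= 0) stop("velocity must be positive")
  if (!is.finite(r_s) || r_s < 0.3 * (1 - 1e-9) || r_s > 10 * (1 + 1e-9)) {
    stop("r_s outside kernel validity [0.3, 10]: ", r_s)
  }
  if (!is.finite(damping) || damping <= 0) stop("damping must be positive")
  kf <- fermi_momentum(r_s)
  wp <- plasmon_frequency(r_s)

  k <- exp(seq(log(1e-3 / r_s), log(max(50 / r_s, 3 * v)), length.out = nk))
  kv <- k * v
  eps0 <- lindhard_eps_static(k, kf)

  # plasmon line position: Bohm-Gross estimate refined by bisection on
  # Re eps_M = 0 where a sign change exists
  w_bg <- sqrt(wp^2 + 0.6 * k^2 * kf^2 + k^4 / 4)
  lo <- 0.7 * w_bg
  hi <- 1.3 * w_bg
  f_re <- function(w) Re(mermin_eps(k, w, kf, damping, eps0))
  flo <- f_re(lo)
  fhi <- f_re(hi)
  has_root <- is.finite(flo) & is.finite(fhi) & (flo * fhi < 0)
  for (it in 1:45) {
    mid <- 0.5 * (lo + hi)
    fm <- f_re(mid)
    left <- (flo * fm < 0)
    hi <- ifelse(has_root & left, mid, hi)
    fhi <- ifelse(has_root & left, fm, fhi)
    lo <- ifelse(has_root & !left, mid, lo)
    flo <- ifelse(has_root & !left, fm, flo)
  }
  w_c <- ifelse(has_root, 0.5 * (lo + hi), w_bg)

  n1 <- max(8L, as.integer(round(0.4 * nw)))
  n2 <- nw - n1
  # uniform backbone over the full window
  U <- outer(kv, seq(1 / n1, 1, length.out = n1))
  # Cauchy-spaced cluster around the plasmon line (only meaningful when the
  # line sits inside the window); elsewhere fall back to offset uniform points
  s <- max(damping / 2, 1e-4)
  inside <- w_c < kv
  th_lo <- atan((pmax(kv * 1e-6, 1e-8) - w_c) / s)
  th_hi <- atan((kv - w_c) / s)
  tt <- seq(0, 1, length.out = n2)
  TH <- matrix(th_lo, nk, n2) + outer(th_hi - th_lo, tt)
  CL <- matrix(w_c, nk, n2) + s * tan(TH)
  FB <- outer(kv, seq(0.5 / n2, 1 - 0.5 / n2, length.out = n2))
  CL[!inside, ] <- FB[!inside, ]
  CL <- pmin(pmax(CL, matrix(kv * 1e-8, nk, n2)), matrix(kv, nk, n2))

  W <- cbind(U, CL)
  W <- t(apply(W, 1, sort))
  K <- matrix(k, nk, nw)
  E0 <- matrix(eps0, nk, nw)
  F <- W * mermin_im_inv_eps(K, W, kf, damping, E0)
  dW <- W[, -1, drop = FALSE] - W[, -nw, drop = FALSE]
  inner <- rowSums(0.5 * (F[, -1, drop = FALSE] + F[, -nw, drop = FALSE]) * dW)
  outer_int <- pracma::trapz(log(k), inner)
  2 / (pi * v^2) * outer_int
}

#' High-velocity Bethe asymptote of FEG stopping
#'
#' \eqn{S(v) = (\omega_p^2/v^2)\ln(2v^2/\omega_p)} — the leading high-velocity
#' behaviour of stopping in an electron gas of plasmon frequency
#' \eqn{\omega_p}.
#'
#' @param v velocity in atomic units.
#' @param omega_p plasmon frequency in Hartree.
#' @return Stopping power in Hartree/bohr. Vectorised.
#' @export
bethe_asymptote <- function(v, omega_p) {
  arg <- 2 * v^2 / omega_p
  if (any(arg <= 1)) stop("outside Bethe validity: 2 v^2 / omega_p must exceed 1")
  omega_p^2 / v^2 * log(arg)
}

#' Analytic Mermin/Lindhard FEG kernel object
#'
#' Wraps \code{\link{lindhard_stopping}} in the pluggable kernel contract
#' used by \code{\link{penn_average}}: a list with an \code{evaluate(v, rs)}
#' function (vectorised over \code{rs}), validity ranges and a label.
#' Evaluation cost is one double quadrature per \code{(v, rs)} pair; for
#' curve-level work sample it once into a table with
#' \code{\link{sample_kernel_table}}.
#'
#' @param damping Mermin damping in Hartree.
#' @param nk,nw quadrature grid sizes (see \code{\link{lindhard_stopping}}).
#' @return An object of class \code{feg_kernel}.
#' @export
feg_kernel_analytic <- function(damping = 0.02, nk = 400L, nw = 300L) {
  kern <- list(
    kind = "analytic",
    rs_range = c(0.3, 10),
    v_range = c(1e-4, 100),
    damping = damping,
    label = sprintf("Mermin linear response (gamma = %.3g Ha)", damping)
  )
  kern$evaluate <- function(v, rs) {
    vapply(rs, function(r) lindhard_stopping(v, r, damping = damping,
                                             nk = nk, nw = nw), numeric(1))
  }
  structure(kern, class = "feg_kernel")
}

#' @export
print.feg_kernel <- function(x, ...) {
  cat(sprintf("FEG stopping kernel [%s]: %s\n  validity: r_s in [%.3g, %.3g] bohr, v in [%.3g, %.3g] au\n",
              x$kind, x$label, x$rs_range[1], x$rs_range[2],
              x$v_range[1], x$v_range[2]))
  invisible(x)
}

#' Sample a kernel onto an (r_s, v) grid
#'
#' @param kernel a \code{feg_kernel}.
#' @param rs_grid,v_grid strictly increasing grids (bohr, au).
#' @return An object of class \code{kernel_table}: \code{rs}, \code{v} and
#'   the matrix \code{S} (rows = r_s, cols = v) in Hartree/bohr.
#' @export
sample_kernel_table <- function(kernel, rs_grid, v_grid) {
  stopifnot(inherits(kernel, "feg_kernel"))
  if (any(diff(rs_grid) <= 0) || any(diff(v_grid) <= 0)) {
    stop("grids must be strictly increasing")
  }
  S <- matrix(NA_real_, length(rs_grid), length(v_grid))
  for (j in seq_along(v_grid)) {
    S[, j] <- kernel$evaluate(v_grid[j], rs_grid)
  }
  structure(list(rs = rs_grid, v = v_grid, S = S,
                 provenance = kernel$label),
            class = "kernel_table")
}

#' Write a kernel table to TSV
#'
#' Long format with header \code{rs_au v_au S_au}, one row per grid cell.
#'
#' @param tab a \code{kernel_table}.
#' @param path output path.
#' @export
write_kernel_table <- function(tab, path) {
  stopifnot(inherits(tab, "kernel_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# FEG stopping kernel table: %s", tab$provenance), con)
  writeLines("rs_au\tv_au\tS_au", con)
  for (i in seq_along(tab$rs)) {
    writeLines(sprintf("%.12g\t%.12g\t%.12g", tab$rs[i], tab$v, tab$S[i, ]), con)
  }
  invisible(path)
}

#' Load a tabulated FEG stopping kernel
#'
#' Reads a long-format TSV with header \code{rs_au v_au S_au} holding
#' stopping power on a complete (r_s, v) grid — the storage contract for
#' kernels produced externally (e.g. jellium real-time simulations, where
#' the stored quantity is the energy loss per traversal divided by the
#' cluster diameter). Returns a kernel that interpolates bilinearly in
#' (log r_s, log v), is exact at grid nodes, clamps out-of-range r_s to the
#' nearest edge with a warning, and switches to the Bethe asymptote at
#' \eqn{\omega_p(r_s)} for velocities above the grid top. Below the grid
#' bottom velocity the friction regime \eqn{S \propto v} is extrapolated.
#'
#' @param path TSV path.
#' @return An object of class \code{feg_kernel} (kind \code{"tabulated"}).
#' @export
load_kernel_table <- function(path) {
  if (!file.exists(path)) stop("kernel table not found: ", path)
  d <- utils::read.table(path, header = TRUE, comment.char = "#")
  if (!all(c("rs_au", "v_au", "S_au") %in% names(d))) {
    stop("kernel table must have header 'rs_au v_au S_au': ", path)
  }
  if (any(!is.finite(d$S_au)) || any(d$S_au < 0)) {
    stop("kernel table contains negative or non-finite stopping values")
  }
  rs <- sort(unique(d$rs_au))
  v <- sort(unique(d$v_au))
  if (length(rs) < 2 || length(v) < 2) {
    stop("kernel table needs at least 2 distinct r_s and v values")
  }
  if (nrow(d) != length(rs) * length(v)) {
    stop(sprintf("incomplete or duplicated grid: %d rows, expected %d",
                 nrow(d), length(rs) * length(v)))
  }
  key <- paste(d$rs_au, d$v_au)
  if (anyDuplicated(key)) stop("duplicate (rs, v) rows in kernel table")
  S <- matrix(NA_real_, length(rs), length(v))
  S[cbind(match(d$rs_au, rs), match(d$v_au, v))] <- d$S_au
  tabulated_kernel(structure(list(rs = rs, v = v, S = S,
                                  provenance = paste("loaded from", path)),
                             class = "kernel_table"))
}

#' Turn a kernel table into an interpolating kernel
#'
#' @param tab a \code{kernel_table} (see \code{\link{sample_kernel_table}}).
#' @return A \code{feg_kernel} of kind \code{"tabulated"} with the
#'   interpolation/extrapolation policy of \code{\link{load_kernel_table}}.
#' @export
tabulated_kernel <- function(tab) {
  stopifnot(inherits(tab, "kernel_table"))
  lrs <- log(tab$rs)
  lv <- log(tab$v)
  # interpolate log S: stopping is positive and power-law-like in both
  # variables, so the log-log-log chord error is far smaller than for S
  # itself (node values are reproduced exactly either way)
  lS <- log(pmax(tab$S, 1e-300))
  rs_rng <- range(tab$rs)
  v_rng <- range(tab$v)
  kern <- list(
    kind = "tabulated",
    rs_range = rs_rng,
    v_range = c(v_rng[1] * 1e-3, Inf),   # friction + Bethe extensions
    grid_v_range = v_rng,
    table = tab,
    label = paste0("tabulated kernel (", length(tab$rs), " x ",
                   length(tab$v), " grid; ", tab$provenance, ")")
  )
  interp_inside <- function(v, rs) {
    xq <- pmin(pmax(log(v), lv[1]), lv[length(lv)])
    yq <- pmin(pmax(log(rs), lrs[1]), lrs[length(lrs)])
    i <- pmin(pmax(findInterval(yq, lrs), 1L), length(lrs) - 1L)
    j <- pmin(pmax(findInterval(xq, lv), 1L), length(lv) - 1L)
    ty <- (yq - lrs[i]) / (lrs[i + 1] - lrs[i])
    tx <- (xq - lv[j]) / (lv[j + 1] - lv[j])
    exp((1 - ty) * ((1 - tx) * lS[cbind(i, j)] + tx * lS[cbind(i, j + 1)]) +
          ty * ((1 - tx) * lS[cbind(i + 1, j)] + tx * lS[cbind(i + 1, j + 1)]))
  }
  kern$evaluate <- function(v, rs) {
    if (length(v) == 1) v <- rep(v, length(rs))
    if (length(rs) == 1) rs <- rep(rs, length(v))
    n_clamped <- sum(rs < rs_rng[1] | rs > rs_rng[2])
    if (n_clamped > 0) {
      warning(sprintf("%d r_s value(s) outside table range [%.3g, %.3g]; clamped to nearest edge",
                      n_clamped, rs_rng[1], rs_rng[2]), call. = FALSE)
    }
    rs_c <- pmin(pmax(rs, rs_rng[1]), rs_rng[2])
    out <- numeric(length(v))
    hi <- v > v_rng[2]
    lo <- v < v_rng[1]
    mid <- !hi & !lo
    if (any(mid)) out[mid] <- interp_inside(v[mid], rs_c[mid])
    if (any(hi)) out[hi] <- bethe_asymptote(v[hi], plasmon_frequency(rs_c[hi]))
    if (any(lo)) {
      out[lo] <- interp_inside(rep(v_rng[1], sum(lo)), rs_c[lo]) *
        v[lo] / v_rng[1]
    }
    out
  }
  structure(kern, class = "feg_kernel")
}

# package-level cache for the default kernel table
.pennstop_cache <- new.env(parent = emptyenv())

#' Default tabulated FEG kernel
#'
#' The package's workhorse kernel for curve-level computation: the analytic
#' Mermin kernel sampled once per session onto a 15 x 26 logarithmic
#' (r_s, v) grid spanning r_s 0.3-10 bohr and v 0.05-25 au, then
#' interpolated bilinearly in log-log. Sampling takes some seconds and is
#' cached for the session.
#'
#' @param damping Mermin damping in Hartree (cache key).
#' @return A \code{feg_kernel} of kind \code{"tabulated"}.
#' @export
default_kernel <- function(damping = 0.02) {
  key <- sprintf("default_%.6g", damping)
  if (!is.null(.pennstop_cache[[key]])) return(.pennstop_cache[[key]])
  rs_grid <- exp(seq(log(0.3), log(10), length.out = 15))
  v_grid <- exp(seq(log(0.05), log(25), length.out = 26))
  tab <- sample_kernel_table(feg_kernel_analytic(damping = damping),
                             rs_grid, v_grid)
  kern <- tabulated_kernel(tab)
  kern$label <- paste0(kern$label, " [default]")
  .pennstop_cache[[key]] <- kern
  kern
}
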