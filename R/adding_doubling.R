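# Forward adding-doubling radiative transfer for a homogeneous slab, and the
# inverse search (IAD) recovering (mu_a, mu_s') from total reflectance and
# transmittance.
#
# Discrete-ordinates formulation: angular flux is represented on a
# Gauss-Radau quadrature over direction cosines mu in (0, 1] with a fixed
# node at mu = 1, so a collimated normal-incidence beam lives exactly on a
# quadrature node and Beer-Lambert attenuation of the unscattered beam is
# exact.  Reflection/transmission operators are flux-to-flux matrices; a thin
# starting layer (single-scattering accurate) is doubled up to the full
# optical thickness, then Fresnel boundary interfaces are added by solving
# the internal multiple-reflection balance.

#' Unpolarized Fresnel reflectance
#'
#' Average of s- and p-polarized Fresnel reflectances for a planar interface.
#' Returns 1 beyond the critical angle.
#'
#' @param n_incident,n_transmitted Refractive indices (>= 1).
#' @param cos_incidence Cosine of the incidence angle, in `[0, 1]`; vectorized.
#' @return Reflectance fraction(s) in `[0, 1]`.
#' @export
fresnel_unpolarized <- function(n_incident, n_transmitted, cos_incidence) {
  if (any(n_incident < 1) || any(n_transmitted < 1))
    stop("refractive indices must be >= 1")
  if (any(cos_incidence < 0 | cos_incidence > 1))
    stop("cos_incidence must be in [0, 1]")
  ci <- cos_incidence
  s2i <- 1 - ci^2
  s2t <- (n_incident / n_transmitted)^2 * s2i
  r <- numeric(length(ci))
  tir <- s2t >= 1
  r[tir] <- 1
  ok <- !tir
  if (any(ok)) {
    ct <- sqrt(1 - s2t[ok])
    cio <- ci[ok]
    ni <- rep_len(n_incident, length(ci))[ok]
    nt <- rep_len(n_transmitted, length(ci))[ok]
    rs <- ((ni * cio - nt * ct) / (ni * cio + nt * ct))^2
    rp <- ((nt * cio - ni * ct) / (nt * cio + ni * ct))^2
    r[ok] <- 0.5 * (rs + rp)
  }
  # matched media: exactly zero (avoid 0/0 at grazing incidence)
  r[abs(rep_len(n_incident, length(ci)) - rep_len(n_transmitted, length(ci))) <
      .Machine$double.eps] <- 0
  pmin(pmax(r, 0), 1)
}

.radau_cache <- new.env(parent = emptyenv())

# Gauss-Radau quadrature on [0, 1] with a fixed node at mu = 1 (weights sum
# to 1).  Built from the Legendre Jacobi matrix with the last diagonal entry
# modified so that x = -1 is an eigenvalue (Golub 1973), then mapped by
# mu = (1 - x) / 2.  Cached per order.
radau_mu <- function(order) {
  key <- as.character(order)
  if (!is.null(.radau_cache[[key]])) return(.radau_cache[[key]])
  .radau_cache[[key]] <- radau_mu_compute(order)
  .radau_cache[[key]]
}

# Plain Gauss-Legendre nodes/weights on [0, 1] (weights sum to 1).
gauss01 <- function(n) {
  k <- seq_len(n - 1)
  off <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, n)
  for (j in k) J[j, j + 1] <- J[j + 1, j] <- off[j]
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(mu = (e$values[ord] + 1) / 2, w = (2 * e$vectors[1, ord]^2) / 2)
}

# Quadrature over internal direction cosines for a slab of index n_slab in
# n_outside.  With an index mismatch the internal Fresnel reflectance jumps
# at the critical cosine, so the quadrature is split there: Gauss nodes on
# [0, mu_c] (the totally internally reflected cone) and Radau nodes with a
# fixed endpoint at mu = 1 on [mu_c, 1], half the order each.
slab_quadrature <- function(order, n_slab, n_outside) {
  if (n_slab <= n_outside) return(radau_mu(order))
  mu_c <- sqrt(1 - (n_outside / n_slab)^2)
  key <- sprintf("%d_%.12g", order, mu_c)
  if (!is.null(.radau_cache[[key]])) return(.radau_cache[[key]])
  lo <- gauss01(order %/% 2)
  hi <- radau_mu(order - order %/% 2)
  out <- list(mu = c(lo$mu * mu_c, mu_c + hi$mu * (1 - mu_c)),
              w = c(lo$w * mu_c, hi$w * (1 - mu_c)))
  .radau_cache[[key]] <- out
  out
}

radau_mu_compute <- function(order) {
  n <- as.integer(order)
  if (n < 2) stop("quadrature order must be >= 2")
  k <- seq_len(n - 1)
  beta <- k^2 / (4 * k^2 - 1)          # monic Legendre recurrence
  # monic p_{n-1}(a), p_{n-2}(a) at a = -1
  a <- -1
  pm2 <- 1; pm1 <- a                    # p_0, p_1
  if (n >= 3) for (j in 2:(n - 1)) {
    p <- a * pm1 - beta[j - 1] * pm2
    pm2 <- pm1; pm1 <- p
  }
  alpha_star <- a - beta[n - 1] * pm2 / pm1
  J <- diag(c(rep(0, n - 1), alpha_star))
  off <- sqrt(beta)
  for (j in k) J[j, j + 1] <- J[j + 1, j] <- off[j]
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2             # total measure 2 on [-1, 1]
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  x[1] <- -1                            # snap the fixed node exactly
  mu <- (1 - x) / 2
  ord2 <- order(mu)
  list(mu = mu[ord2], w = (w / 2)[ord2])
}

# Azimuthally averaged Henyey-Greenstein redistribution matrices on the
# quadrature nodes: hpp for same-hemisphere, hpm for opposite-hemisphere
# transfer.  Columns renormalized so scattering conserves energy exactly
# under the quadrature.
hg_redistribution <- function(mu, w, g) {
  M <- length(mu)
  if (g == 0) return(list(hpp = matrix(1, M, M), hpm = matrix(1, M, M)))
  L <- min(256L, max(8L, ceiling(log(1e-12) / log(g))))
  # Legendre P_l(mu) for l = 0..L
  P <- matrix(0, M, L + 1)
  P[, 1] <- 1; P[, 2] <- mu
  if (L >= 2) for (l in 2:L)
    P[, l + 1] <- ((2 * l - 1) * mu * P[, l] - (l - 1) * P[, l - 1]) / l
  coef <- (2 * (0:L) + 1) * g^(0:L)
  sgn <- (-1)^(0:L)
  hpp <- P %*% (coef * t(P))
  hpm <- P %*% (coef * sgn * t(P))
  hpp <- pmax(hpp, 0); hpm <- pmax(hpm, 0)
  norm <- colSums(w * (hpp + hpm)) / 2
  list(hpp = sweep(hpp, 2, norm, "/"), hpm = sweep(hpm, 2, norm, "/"))
}

# One doubling step: operators of a layer stacked on an identical layer.
ad_double <- function(R, T) {
  M <- solve(diag(nrow(R)) - R %*% R)
  list(R = R + T %*% M %*% R %*% T, T = T %*% M %*% T)
}

# General adding of two (top-bottom symmetric) layers, light incident on L1.
ad_add <- function(L1, L2) {
  M <- solve(diag(nrow(L1$R)) - L1$R %*% L2$R)
  list(R = L1$R + L1$T %*% L2$R %*% M %*% L1$T,
       T = L2$T %*% M %*% L1$T)
}

# Bare-slab flux operators (no boundaries) by thin-layer init + doubling.
ad_slab_operators <- function(mu_a, mu_s, d, g, quad) {
  mu <- quad$mu; w <- quad$w; M <- length(mu)
  mu_t <- mu_a + mu_s
  tau <- mu_t * d
  if (!is.finite(tau)) stop("optical thickness not finite")
  if (tau < 1e-12) return(list(R = matrix(0, M, M), T = diag(M)))
  a <- mu_s / mu_t
  k <- max(10L, ceiling(log2(tau / 1e-4)))
  tau0 <- tau / 2^k
  att <- exp(-tau0 / mu)
  H <- hg_redistribution(mu, w, g)
  # strict single-scattering source term (a*tau0/(2*mu_j)): keeps the
  # reciprocity relation exact through doubling; error O(tau0^2)
  sc <- a * tau0 / (2 * mu)
  T0 <- diag(att) + (w * H$hpp) %*% diag(sc, M)
  R0 <- (w * H$hpm) %*% diag(sc, M)
  R <- R0; T <- T0
  for (i in seq_len(k)) {
    st <- ad_double(R, T)
    R <- st$R; T <- st$T
  }
  list(R = R, T = T)
}

#' Total reflectance and transmittance of a homogeneous slab
#'
#' Adding-doubling solution for collimated normal incidence on a slab of
#' thickness `d` with refractive index `n_slab` bounded by `n_outside` above
#' and below.  Henyey-Greenstein single scattering with anisotropy `g`.
#'
#' @param mu_a,mu_s Absorption and scattering coefficients, mm^-1.  With the
#'   default `g = 0` the similarity relation applies and `mu_s` is the
#'   reduced scattering coefficient.
#' @param d Slab thickness, mm.
#' @param g Anisotropy factor in `[0, 1)`.
#' @param n_slab,n_outside Refractive indices.
#' @param quadrature_order Number of Radau nodes (even, >= 4).
#' @return List with `R_t` and `T_t`, total (specular + diffuse) fractions;
#'   `0 <= R_t, T_t` and `R_t + T_t <= 1`.
#' @export
slab_rt <- function(mu_a, mu_s, d, g = 0, n_slab = 1.34, n_outside = 1.0,
                    quadrature_order = 16) {
  if (quadrature_order < 4 || quadrature_order %% 2 != 0)
    stop("quadrature_order must be even and >= 4")
  if (mu_a < 0 || mu_s < 0 || d <= 0) stop("need mu_a, mu_s >= 0 and d > 0")
  quad <- slab_quadrature(quadrature_order, n_slab, n_outside)
  ops <- ad_slab_operators(mu_a, mu_s, d, g, quad)
  ad_add_boundaries(ops$R, ops$T, quad, n_slab, n_outside)
}

# Add Fresnel boundary interfaces to bare-slab operators and evaluate the
# totals for an external collimated normal-incidence unit beam.
ad_add_boundaries <- function(R, T, quad, n_slab, n_outside) {
  mu <- quad$mu; M <- length(mu)
  r_spec <- fresnel_unpolarized(n_outside, n_slab, 1)
  rho <- fresnel_unpolarized(n_slab, n_outside, mu)
  s <- numeric(M)
  i1 <- which.max(mu)                  # the mu = 1 Radau node
  s[i1] <- 1 - r_spec
  if (all(R == 0) && identical(T, diag(M))) {
    # transparent slab: per-node incoherent etalon (modes beyond the
    # critical angle are trapped but carry no source and tally nothing)
    d_b <- ifelse(rho < 1, s / (1 - rho^2), 0)
    u_t <- rho * d_b
  } else if (all(rho == 0)) {
    u_t <- as.vector(R %*% s)
    d_b <- as.vector(T %*% s)
  } else {
    RP <- R %*% diag(rho, M); TP <- T %*% diag(rho, M)
    A <- rbind(cbind(diag(M) - RP, -TP), cbind(-TP, diag(M) - RP))
    b <- c(as.vector(R %*% s), as.vector(T %*% s))
    sol <- solve(A, b)
    u_t <- sol[1:M]; d_b <- sol[(M + 1):(2 * M)]
  }
  list(R_t = r_spec + sum((1 - rho) * u_t),
       T_t = sum((1 - rho) * d_b))
}

#' Recover optical properties from a total reflectance/transmittance pair
#'
#' Inverse adding-doubling: finds `(mu_a, mu_s')` minimizing the sum of
#' squared relative residuals of [slab_rt()] against the measured pair, via
#' a coarse log-spaced grid search over `[1e-4, 10]^2` mm^-1 followed by
#' Nelder-Mead refinement in log space.
#'
#' @param R_t,T_t Measured total reflectance and transmittance fractions.
#' @param d Slab thickness, mm.
#' @param n_slab,n_outside Refractive indices.
#' @param g_assumed Anisotropy assumed during inversion (default 0, i.e. the
#'   recovered scattering coefficient is the reduced one).
#' @param start Optional `c(mu_a, mu_s')` warm start; skips the grid when its
#'   refined residual is acceptable.
#' @param quadrature_order Passed to [slab_rt()].
#' @param grid_n Grid points per axis for the coarse search.
#' @return List with `mu_a`, `mu_s_prime`, `residual` (objective at the
#'   optimum) and `converged`.  Non-convergence is flagged, never silent.
#' @export
invert_rt <- function(R_t, T_t, d, n_slab = 1.34, n_outside = 1.0,
                      g_assumed = 0, start = NULL, quadrature_order = 16,
                      grid_n = 10) {
  if (!is.finite(R_t) || !is.finite(T_t) || R_t < 0 || T_t < 0)
    stop("measurements must be finite and non-negative")
  if (R_t + T_t > 1) stop("unphysical measurement: R_t + T_t > 1")
  eps <- 1e-6
  obj <- function(p) {
    mua <- 10^p[1]; mus <- 10^p[2]
    if (mua > 20 || mus > 20) return(1e6)
    rt <- slab_rt(mua, mus, d, g_assumed, n_slab, n_outside, quadrature_order)
    ((rt$R_t - R_t) / max(R_t, eps))^2 + ((rt$T_t - T_t) / max(T_t, eps))^2
  }
  refine <- function(p0) {
    stats::optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-12))
  }
  best <- NULL
  if (!is.null(start)) {
    fit <- refine(log10(pmax(start, 1e-5)))
    if (fit$value < 1e-8) best <- fit
  }
  if (is.null(best)) {
    gr <- seq(log10(1e-4), log10(10), length.out = grid_n)
    vals <- outer(gr, gr, Vectorize(function(a, s) obj(c(a, s))))
    ix <- arrayInd(which.min(vals), dim(vals))
    fit <- refine(c(gr[ix[1]], gr[ix[2]]))
    best <- fit
  }
  list(mu_a = 10^best$par[1], mu_s_prime = 10^best$par[2],
       residual = best$value,
       converged = best$convergence == 0 && best$value < 1e-4)
}

#' Extract an optical-property spectrum from measurement records
#'
#' Applies [invert_rt()] independently per wavelength, warm-starting each
#' wavelength at the previous solution.  Unphysical or non-convergent
#' wavelengths are masked (`NA`) without affecting their neighbours.
#'
#' @param records Data frame with columns `wavelength_nm`, `R_t`, `T_t`.
#' @param d Slab thickness, mm.
#' @param n_slab,n_outside,g_assumed,quadrature_order Passed to [invert_rt()].
#' @return An [optical_spectrum()] (masked entries `NA`) with attributes
#'   `n_masked` and `residuals`.
#' @export
extract_op_spectrum <- function(records, d, n_slab = 1.34, n_outside = 1.0,
                                g_assumed = 0, quadrature_order = 16) {
  stopifnot(all(c("wavelength_nm", "R_t", "T_t") %in% names(records)))
  records <- records[order(records$wavelength_nm), , drop = FALSE]
  n <- nrow(records)
  mua <- musp <- resid <- rep(NA_real_, n)
  prev <- NULL
  for (i in seq_len(n)) {
    fit <- tryCatch(
      invert_rt(records$R_t[i], records$T_t[i], d, n_slab, n_outside,
                g_assumed, start = prev, quadrature_order = quadrature_order),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      mua[i] <- fit$mu_a; musp[i] <- fit$mu_s_prime; resid[i] <- fit$residual
      prev <- c(fit$mu_a, fit$mu_s_prime)
    }
  }
  out <- optical_spectrum(records$wavelength_nm, mua, musp, g = g_assumed,
                          allow_na = TRUE)
  attr(out, "n_masked") <- sum(is.na(mua))
  attr(out, "residuals") <- resid
  out
}
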