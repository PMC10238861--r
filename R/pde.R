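#' Cortical flow velocity profile
#'
#' The experimentally fitted anterior-directed flow profile on the 1D
#' membrane (x measured from the anterior pole, domain 0..60 um):
#' `v(x) = ((60 - x)/74) exp(-(60 - x)^2/391) - (x/1000) exp(-x^2/100)`,
#' in um/s. The profile peaks near the posterior (~0.115 um/s at x ~ 46 um)
#' and vanishes at both poles.
#'
#' @param x position(s) from the anterior pole, um.
#' @param L domain length, um (the profile constants are calibrated for 60).
#' @return velocity, um/s (positive = anterior-directed transport).
#' @export
flow_velocity <- function(x, L = 60) {
  ((L - x) / 74) * exp(-(L - x)^2 / 391) - (x / 1000) * exp(-x^2 / 100)
}

#' PDE model parameters
#'
#' Parameters of the 1D advection-diffusion-membrane-exchange model
#' `dA/dt = D d2A/dx2 + d(vA)/dx + k_on A_cyt - k_off A`, with the uniform
#' cytoplasmic pool closed by `A_cyt = rho_A - psi * mean(A)`. Flow is
#' active for `t_flow` seconds and then switched off for `t_post` seconds.
#'
#' @param D membrane diffusivity, um^2/s.
#' @param k_off membrane dissociation rate, 1/s.
#' @param k_on membrane binding rate, 1/s; defaults to `k_off` (the model's
#'   reference condition).
#' @param rho_A total protein amount, um^-3.
#' @param psi surface-to-volume ratio, um^-1.
#' @param L membrane length, um.
#' @param n_grid finite-volume cells.
#' @param t_flow flow-phase duration, s.
#' @param t_post post-flow duration, s.
#' @param dt_out output sampling interval, s.
#' @param velocity velocity profile function of x (um/s); default
#'   [flow_velocity()].
#' @param rtol,atol integration tolerances.
#' @param method a [deSolve::ode()] method; `"lsoda"` (adaptive,
#'   stiffness-switching, default) or `"ode45"` (adaptive Runge-Kutta) are
#'   both supported and agree at the reference parameters.
#' @param scheme advective face interpolation: `"central"` (second order,
#'   default) or `"upwind"` (first order, used as fallback if central
#'   produces negative concentrations).
#' @return object of class `pde_params`.
#' @export
pde_params <- function(D = 0.1, k_off = 0.005, k_on = k_off, rho_A = 1.56,
                       psi = 0.174, L = 60, n_grid = 400L, t_flow = 500,
                       t_post = 1500, dt_out = 2, velocity = flow_velocity,
                       rtol = 1e-8, atol = 1e-10, method = "lsoda",
                       scheme = c("central", "upwind")) {
  check_scalar(D, "D", min = 0)
  check_scalar(k_off, "k_off", min = 0)
  check_scalar(k_on, "k_on", min = 0)
  check_scalar(rho_A, "rho_A", min = 0, strict = TRUE)
  check_scalar(psi, "psi", min = 0, strict = TRUE)
  check_scalar(L, "L", min = 0, strict = TRUE)
  check_scalar(t_flow, "t_flow", min = 0, strict = TRUE)
  check_scalar(t_post, "t_post", min = 0)
  stop_if(as.integer(n_grid) < 10L, "n_grid must be >= 10")
  structure(list(D = D, k_off = k_off, k_on = k_on, rho_A = rho_A, psi = psi,
                 L = L, n_grid = as.integer(n_grid), t_flow = t_flow,
                 t_post = t_post, dt_out = dt_out, velocity = velocity,
                 rtol = rtol, atol = atol, method = method,
                 scheme = match.arg(scheme)),
            class = "pde_params")
}

## Conservative finite-volume right-hand side. States are cell averages on a
## uniform grid; diffusive and advective fluxes vanish at both boundaries
## (zero-flux; the flow profile itself is ~0 at the poles). The advection
## term enters as +d(vA)/dx, so positive v transports mass towards x = 0
## (the anterior pole).
pde_rhs_factory <- function(p) {
  n <- p$n_grid
  dx <- p$L / n
  vf <- p$velocity(seq_len(n - 1L) * dx)  # interior faces
  function(t, A, parms) {
    von <- if (t <= p$t_flow) 1 else 0
    Acyt <- p$rho_A - p$psi * mean(A)
    dif <- p$D * diff(A) / dx                  # -flux at interior faces
    Aface <- if (p$scheme == "central") (A[-1L] + A[-n]) / 2
             else ifelse(vf >= 0, A[-1L], A[-n])  # upwind: v>0 moves mass to lower x
    G <- von * vf * Aface
    adv <- (c(G, 0) - c(0, G)) / dx            # + d(vA)/dx with zero-flux ends
    diffu <- (c(dif, 0) - c(0, dif)) / dx
    list(diffu + adv + p$k_on * Acyt - p$k_off * A)
  }
}

#' Solve the advection-diffusion-exchange model
#'
#' Method-of-lines integration of the single-species model from the uniform
#' equilibrium `A(x, 0) = rho_A / (1 + psi)` (exact when `k_on = k_off`;
#' otherwise the general fixed point `k_on rho_A / (k_off + k_on psi)`).
#' Flow is active on `[0, t_flow]` and zero afterwards.
#'
#' @param params a [pde_params()].
#' @return object of class `pde_solution`: `times`, `x` (cell centres, um),
#'   `A` (time x space membrane concentration), `A_cyt(t)`, `params`.
#' @export
solve_pde <- function(params) {
  stopifnot(inherits(params, "pde_params"))
  p <- params
  A0 <- rep(p$k_on * p$rho_A / (p$k_off + p$k_on * p$psi), p$n_grid)
  if (p$k_off == 0 && p$k_on == 0) A0 <- rep(p$rho_A / (1 + p$psi), p$n_grid)
  sol <- integrate_phases(p, A0)
  if (min(sol$A) < -1e-6 * max(abs(sol$A)) && p$scheme == "central") {
    ## central interpolation can undershoot on sharp fronts; retry upwind
    p$scheme <- "upwind"
    sol <- integrate_phases(p, A0)
  }
  stop_if(min(sol$A) < -1e-6 * max(abs(sol$A)),
          sprintf("negative concentrations beyond tolerance (min %.3g)", min(sol$A)))
  sol$A[sol$A < 0] <- 0
  structure(list(times = sol$times, x = sol$x, A = sol$A,
                 A_cyt = p$rho_A - p$psi * rowMeans(sol$A), params = p),
            class = "pde_solution")
}

## Integrate flow phase then post-flow phase (the RHS switches v off at
## t_flow; splitting at the discontinuity keeps the adaptive stepper honest).
integrate_phases <- function(p, A0) {
  rhs <- pde_rhs_factory(p)
  t1 <- seq(0, p$t_flow, by = p$dt_out)
  if (t1[length(t1)] < p$t_flow) t1 <- c(t1, p$t_flow)
  out1 <- deSolve::ode(A0, t1, rhs, NULL, method = p$method,
                       rtol = p$rtol, atol = p$atol)
  check_ode(out1)
  if (p$t_post > 0) {
    t2 <- seq(p$t_flow, p$t_flow + p$t_post, by = p$dt_out)
    if (t2[length(t2)] < p$t_flow + p$t_post) t2 <- c(t2, p$t_flow + p$t_post)
    out2 <- deSolve::ode(out1[nrow(out1), -1L], t2, rhs, NULL,
                         method = p$method, rtol = p$rtol, atol = p$atol)
    check_ode(out2)
    times <- c(out1[, 1L], out2[-1L, 1L])
    A <- rbind(out1[, -1L, drop = FALSE], out2[-1L, -1L, drop = FALSE])
  } else {
    times <- out1[, 1L]
    A <- out1[, -1L, drop = FALSE]
  }
  dx <- p$L / p$n_grid
  list(times = times, x = (seq_len(p$n_grid) - 0.5) * dx, A = unname(A))
}

check_ode <- function(out) {
  stop_if(any(!is.finite(out)), "PDE integration failed to converge")
  invisible(out)
}

#' @export
print.pde_solution <- function(x, ...) {
  p <- x$params
  cat(sprintf("PDE solution: D = %g um^2/s, k_on = %g, k_off = %g /s, flow %g s + %g s post\n",
              p$D, p$k_on, p$k_off, p$t_flow, p$t_post))
  m <- compute_metrics(x)
  cat(sprintf("  peak ASI %.3f, peak depletion %.3f (end of flow)\n",
              m$peak_ASI, m$peak_depletion))
  invisible(x)
}

#' @export
plot.pde_solution <- function(x, times = NULL, ...) {
  p <- x$params
  if (is.null(times)) times <- c(p$t_flow, min(p$t_flow + 300, max(x$times)))
  idx <- vapply(times, function(t) which.min(abs(x$times - t)), integer(1))
  cols <- grDevices::hcl.colors(length(idx), "viridis")
  graphics::matplot(x$x, t(x$A[idx, , drop = FALSE]), type = "l", lty = 1,
                    col = cols, xlab = "x from anterior pole (um)",
                    ylab = "membrane concentration", ...)
  graphics::legend("topright", legend = sprintf("t = %g s", x$times[idx]),
                   col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Segregation metrics of a PDE solution
#'
#' Pole concentrations are means over the anterior- and posterior-most 30%
#' of the membrane. The asymmetry index uses the convention with maximum 0.5
#' at complete posterior clearance, `ASI = (A - P) / (2 (A + P))`; posterior
#' depletion uses the convention with maximum 1, `1 - P / <I>`
#' (`convention = "methods"` switches to the raw `(A - P)/(A + P)` and
#' `P/<I>` forms). Decay half-times are the first times after flow cessation
#' at which each metric falls to half its end-of-flow value (first
#' crossing), with an exponential-decay fit reported as a cross-check.
#'
#' @param sol a [solve_pde()] result.
#' @param convention `"results"` (default) or `"methods"`.
#' @return object of class `segregation_metrics`: time series `ASI(t)`,
#'   `depletion(t)`, pole means, `peak_ASI`, `peak_depletion` (at the end of
#'   flow), `ASI_300`, `depletion_300` (300 s post-flow), `t_half_ASI`,
#'   `t_half_depletion` (s after flow cessation; `Inf` when the metric never
#'   reaches half within the simulated window), and exponential-fit
#'   cross-check half-times.
#' @export
compute_metrics <- function(sol, convention = c("results", "methods")) {
  stopifnot(inherits(sol, "pde_solution"))
  convention <- match.arg(convention)
  p <- sol$params
  ia <- sol$x <= 0.3 * p$L
  ip <- sol$x >= 0.7 * p$L
  Am <- rowMeans(sol$A[, ia, drop = FALSE])
  Pm <- rowMeans(sol$A[, ip, drop = FALSE])
  I <- rowMeans(sol$A)
  asi <- (Am - Pm) / (Am + Pm)
  dep <- Pm / I
  if (convention == "results") {
    asi <- asi / 2
    dep <- 1 - dep
  }
  i_end <- which.min(abs(sol$times - p$t_flow))
  post <- sol$times >= p$t_flow
  t_post <- sol$times[post] - p$t_flow
  half_time <- function(m) {
    m_end <- m[i_end]
    mp <- m[post]
    k <- which(mp <= m_end / 2)
    if (!length(k)) return(Inf)
    ## linear interpolation between the bracketing samples
    k <- k[1]
    if (k == 1L) return(0)
    t0 <- t_post[k - 1L]; t1 <- t_post[k]
    m0 <- mp[k - 1L]; m1 <- mp[k]
    t0 + (m0 - m_end / 2) / (m0 - m1) * (t1 - t0)
  }
  exp_half <- function(m) {
    mp <- m[post]
    if (length(t_post) < 5L || mp[1] <= 0) return(NA_real_)
    ok <- mp > 1e-12 * mp[1]
    if (sum(ok) < 5L) return(NA_real_)
    fit <- tryCatch(stats::lm(log(mp[ok]) ~ t_post[ok]), error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    rate <- -stats::coef(fit)[2]
    if (rate <= 0) Inf else log(2) / rate
  }
  structure(list(times = sol$times, ASI = asi, depletion = dep,
                 A_pole = Am, P_pole = Pm, mean_A = I,
                 peak_ASI = asi[i_end], peak_depletion = dep[i_end],
                 max_ASI = max(asi), max_depletion = max(dep),
                 ASI_300 = asi_at(sol$times, asi, p$t_flow + 300),
                 depletion_300 = asi_at(sol$times, dep, p$t_flow + 300),
                 t_half_ASI = half_time(asi),
                 t_half_depletion = half_time(dep),
                 t_half_ASI_expfit = exp_half(asi),
                 t_half_depletion_expfit = exp_half(dep),
                 convention = convention),
            class = "segregation_metrics")
}

asi_at <- function(times, m, t) {
  if (t > max(times)) return(NA_real_)
  m[which.min(abs(times - t))]
}

#' @export
print.segregation_metrics <- function(x, ...) {
  cat(sprintf("Segregation metrics (%s convention):\n", x$convention))
  cat(sprintf("  end of flow: ASI = %.3f, posterior depletion = %.3f\n",
              x$peak_ASI, x$peak_depletion))
  cat(sprintf("  +300 s:      ASI = %.3f, posterior depletion = %.3f\n",
              x$ASI_300, x$depletion_300))
  cat(sprintf("  decay t1/2:  ASI %.4g s, depletion %.4g s\n",
              x$t_half_ASI, x$t_half_depletion))
  invisible(x)
}

#' Phase-diagram sweep over diffusivity and off-rate
#'
#' Runs [solve_pde()] + [compute_metrics()] over a (D, k_off) grid with
#' `k_on = k_off`, collecting the four phase-diagram surfaces: peak ASI,
#' peak posterior depletion, and the decay half-time of each. Individual
#' cell failures are recorded and the sweep continues.
#'
#' @param D_values,k_off_values grids (log-spaced recommended).
#' @param params template [pde_params()] supplying everything else.
#' @return data frame of class `pde_sweep` with columns `D`, `k_off`,
#'   `peak_ASI`, `peak_depletion`, `t_half_ASI`, `t_half_depletion`, `error`.
#' @export
sweep_pde <- function(D_values, k_off_values, params = pde_params()) {
  grid <- expand.grid(D = D_values, k_off = k_off_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$D <- grid$D[i]; p$k_off <- grid$k_off[i]; p$k_on <- grid$k_off[i]
    m <- tryCatch(compute_metrics(solve_pde(p)), error = function(e) e)
    if (inherits(m, "error"))
      data.frame(D = p$D, k_off = p$k_off, peak_ASI = NA, peak_depletion = NA,
                 t_half_ASI = NA, t_half_depletion = NA,
                 error = conditionMessage(m))
    else
      data.frame(D = p$D, k_off = p$k_off, peak_ASI = m$peak_ASI,
                 peak_depletion = m$peak_depletion, t_half_ASI = m$t_half_ASI,
                 t_half_depletion = m$t_half_depletion, error = NA_character_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pde_sweep", "data.frame")
  out
}

#' Two-state (fast/slow exchanging) model
#'
#' Extension with two membrane species sharing one cytoplasmic pool:
#' binding flux `k_on A_cyt` is split `fraction_fast : 1 - fraction_fast`
#' between a fast-exchanging state (rate `k_off_fast`) and a slow one
#' (`k_off_slow`). Total binding is kept at the single-species reference
#' `k_on` of the base parameters.
#'
#' @param params base [pde_params()] (its `k_off` is superseded by the two
#'   state-specific rates; `k_on` sets the total binding rate).
#' @param k_off_fast,k_off_slow dissociation rates, 1/s
#'   (`k_off_fast >= k_off_slow > 0`).
#' @param fraction_fast fraction of binding events entering the fast state.
#' @return object of class `pde_solution_two_state`: `times`, `x`, `A_fast`,
#'   `A_slow`, `A` (total), `A_cyt`, `fast_fraction(t)` (membrane share of
#'   fast molecules), and `params`.
#' @export
solve_two_state <- function(params = pde_params(), k_off_fast = 1,
                            k_off_slow = 0.001, fraction_fast = 0.5) {
  stopifnot(inherits(params, "pde_params"))
  stop_if(k_off_slow <= 0 || k_off_fast < k_off_slow,
          "need k_off_fast >= k_off_slow > 0")
  stop_if(fraction_fast < 0 || fraction_fast > 1,
          "fraction_fast must be in [0, 1]")
  p <- params
  n <- p$n_grid
  dx <- p$L / n
  vf <- p$velocity(seq_len(n - 1L) * dx)
  f <- fraction_fast
  rhs <- function(t, y, parms) {
    Af <- y[seq_len(n)]; As <- y[n + seq_len(n)]
    von <- if (t <= p$t_flow) 1 else 0
    Acyt <- p$rho_A - p$psi * (mean(Af) + mean(As))
    one <- function(A, koff, frac) {
      dif <- p$D * diff(A) / dx
      Aface <- if (p$scheme == "central") (A[-1L] + A[-n]) / 2
               else ifelse(vf >= 0, A[-1L], A[-n])
      G <- von * vf * Aface
      (c(dif, 0) - c(0, dif)) / dx + (c(G, 0) - c(0, G)) / dx +
        frac * p$k_on * Acyt - koff * A
    }
    list(c(one(Af, k_off_fast, f), one(As, k_off_slow, 1 - f)))
  }
  ## uniform equilibrium initial condition shared-pool fixed point:
  ## Af* = f k_on Acyt / k_off_fast, As* = (1-f) k_on Acyt / k_off_slow,
  ## Acyt* = rho_A / (1 + psi k_on (f/k_off_fast + (1-f)/k_off_slow))
  w <- p$k_on * (f / k_off_fast + (1 - f) / k_off_slow)
  Acyt0 <- p$rho_A / (1 + p$psi * w)
  y0 <- c(rep(f * p$k_on * Acyt0 / k_off_fast, n),
          rep((1 - f) * p$k_on * Acyt0 / k_off_slow, n))
  t1 <- seq(0, p$t_flow, by = p$dt_out)
  out1 <- deSolve::ode(y0, t1, rhs, NULL, method = p$method,
                       rtol = p$rtol, atol = p$atol)
  check_ode(out1)
  times <- out1[, 1L]; Y <- out1[, -1L, drop = FALSE]
  if (p$t_post > 0) {
    t2 <- seq(p$t_flow, p$t_flow + p$t_post, by = p$dt_out)
    out2 <- deSolve::ode(Y[nrow(Y), ], t2, rhs, NULL, method = p$method,
                         rtol = p$rtol, atol = p$atol)
    check_ode(out2)
    times <- c(times, out2[-1L, 1L])
    Y <- rbind(Y, out2[-1L, -1L, drop = FALSE])
  }
  Af <- unname(Y[, seq_len(n), drop = FALSE])
  As <- unname(Y[, n + seq_len(n), drop = FALSE])
  A <- Af + As
  structure(list(times = times, x = (seq_len(n) - 0.5) * dx,
                 A_fast = Af, A_slow = As, A = A,
                 A_cyt = p$rho_A - p$psi * (rowMeans(Af) + rowMeans(As)),
                 fast_fraction = rowMeans(Af) / rowMeans(A),
                 k_off_fast = k_off_fast, k_off_slow = k_off_slow,
                 fraction_fast = f, params = p),
            class = c("pde_solution_two_state", "pde_solution"))
}
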