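#' Fit membrane cross-section profiles
#'
#' Quantifies a computationally straightened membrane image (rows = position
#' along the membrane, columns = perpendicular cross-section). After a
#' rolling average along the membrane axis, each cross-section is fit by
#' nonlinear least squares to the sum of a Gaussian (membrane pool) and a
#' scaled error-function step (cytoplasmic pool) sharing the same centre `c`
#' and width `w`:
#' `I(d) = a exp(-(d - c)^2 / (2 w^2)) + b (1 - erf((d - c)/(sqrt(2) w)))/2 + o`
#' with the cytoplasm on the low-`d` side. The membrane concentration at
#' each position is the Gaussian amplitude `a`; the cytoplasm concentration
#' is the plateau `b`. Non-convergent positions are flagged and interpolated
#' from their neighbours.
#'
#' @param img numeric matrix, positions x cross-section (cytoplasm towards
#'   column 1, exterior towards the last column).
#' @param pixel_size um per px (metadata only).
#' @param rolling_width rolling-average window along the membrane axis, px.
#' @return data frame of class `membrane_profile_fit` with one row per
#'   position: `position`, `amplitude`, `center`, `width`, `cytoplasm`,
#'   `offset`, `residual_sd`, `converged`. The fitted functional form is
#'   recorded in attribute `model`.
#' @export
fit_membrane_profile <- function(img, pixel_size = 0.255, rolling_width = 20L) {
  stop_if(!is.matrix(img) || any(!is.finite(img)), "img must be a finite matrix")
  n_pos <- nrow(img); n_d <- ncol(img)
  stop_if(n_d < 8L, "cross-section too narrow to fit")
  if (rolling_width > 1L) {
    k <- min(rolling_width, n_pos)
    img <- apply(img, 2, function(col)
      stats::filter(col, rep(1 / k, k), sides = 2))
    ## fill the filter's NA margins with the nearest averaged value
    img <- apply(img, 2, function(col) {
      ok <- which(!is.na(col))
      col[seq_len(min(ok) - 1L)] <- col[min(ok)]
      col[seq(max(ok) + 1L, length.out = length(col) - max(ok))] <- col[max(ok)]
      col
    })
  }
  d <- seq_len(n_d)
  fit_one <- function(yv) {
    ## starting values: centre at the peak, plateau from the first columns
    b0 <- max(mean(yv[seq_len(max(2L, n_d %/% 8L))]), 1e-6)
    o0 <- min(yv)
    c0 <- which.max(yv)
    a0 <- max(yv[c0] - b0 / 2 - o0, 1e-6)
    fit <- tryCatch(minpack.lm::nlsLM(
      yv ~ a * exp(-(d - cc)^2 / (2 * w^2)) +
        b * (1 - erf_((d - cc) / (sqrt(2) * w))) / 2 + o,
      start = list(a = a0, cc = c0, w = 2, b = b0, o = o0),
      lower = c(a = 0, cc = 1, w = 0.3, b = 0, o = -Inf),
      upper = c(a = Inf, cc = n_d, w = n_d, b = Inf, o = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(rep(NA_real_, 6))
    cf <- stats::coef(fit)
    c(cf["a"], cf["cc"], cf["w"], cf["b"], cf["o"],
      stats::sd(stats::resid(fit)))
  }
  res <- t(apply(img, 1, fit_one))
  out <- data.frame(position = seq_len(n_pos), amplitude = res[, 1],
                    center = res[, 2], width = res[, 3], cytoplasm = res[, 4],
                    offset = res[, 5], residual_sd = res[, 6],
                    converged = !is.na(res[, 1]))
  ## interpolate non-convergent positions from neighbours
  for (col in c("amplitude", "center", "width", "cytoplasm", "offset")) {
    bad <- !out$converged
    if (any(bad) && any(!bad))
      out[[col]][bad] <- stats::approx(out$position[!bad], out[[col]][!bad],
                                       xout = out$position[bad], rule = 2)$y
  }
  attr(out, "model") <-
    "a*exp(-(d-c)^2/(2w^2)) + b*(1-erf((d-c)/(sqrt(2)w)))/2 + o; shared c,w; cytoplasm at low d"
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("membrane_profile_fit", "data.frame")
  out
}

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Segregation metrics from a membrane concentration series
#'
#' Computes pole averages over the anterior- and posterior-most 30% of the
#' perimeter positions, the asymmetry index and posterior depletion (same
#' conventions as [compute_metrics()]), and membrane-to-cytoplasm ratios at
#' both poles.
#'
#' @param membrane numeric vector of membrane concentrations ordered from
#'   the anterior pole (position 1) to the posterior pole (last position).
#' @param cytoplasm scalar or per-position cytoplasm concentration.
#' @param convention `"results"` (ASI max 0.5, depletion max 1) or
#'   `"methods"`.
#' @return list of class `profile_metrics`: `A_pole`, `P_pole`, `ASI`,
#'   `depletion`, `mc_anterior`, `mc_posterior`.
#' @export
segregation_from_profile <- function(membrane, cytoplasm = NA_real_,
                                     convention = c("results", "methods")) {
  convention <- match.arg(convention)
  n <- length(membrane)
  stop_if(n < 10L, "need at least 10 positions")
  stop_if(any(!is.finite(membrane)), "membrane series must be finite")
  ia <- seq_len(ceiling(0.3 * n))
  ip <- seq(n - ceiling(0.3 * n) + 1L, n)
  A <- mean(membrane[ia]); P <- mean(membrane[ip]); I <- mean(membrane)
  asi <- (A - P) / (A + P)
  dep <- P / I
  if (convention == "results") { asi <- asi / 2; dep <- 1 - dep }
  cyt <- if (length(cytoplasm) == 1L) rep(cytoplasm, 2)
         else c(mean(cytoplasm[ia]), mean(cytoplasm[ip]))
  structure(list(A_pole = A, P_pole = P, ASI = asi, depletion = dep,
                 mc_anterior = A / cyt[1], mc_posterior = P / cyt[2],
                 convention = convention),
            class = "profile_metrics")
}

#' @export
print.profile_metrics <- function(x, ...) {
  cat(sprintf("Profile metrics (%s): ASI = %.3f, depletion = %.3f, M:C ant/post = %.3g/%.3g\n",
              x$convention, x$ASI, x$depletion, x$mc_anterior, x$mc_posterior))
  invisible(x)
}

#' Fit a FRAP recovery curve
#'
#' Normalizes the bleached-region intensity against an unbleached control
#' region (correcting acquisition photobleaching) and then to the pre-bleach
#' baseline, and fits the one-component association model
#' `I(t) = plateau * (1 - exp(-t / tau))` to the post-bleach samples. The
#' characteristic turnover time `tau` estimates `1 / k_off`.
#'
#' @param time time points, s (bleach at `t = 0`; `time < 0` = pre-bleach).
#' @param bleached intensity in the bleached region.
#' @param control intensity in the unbleached control region (optional).
#' @param normalized set `TRUE` when `bleached` is already fully normalized
#'   (skips both normalization steps).
#' @return object of class `frap_fit`: `tau` (s), `k_off` (1/s), `plateau`,
#'   `tau_ci` (95%), `curve` (normalized data + fit), `normalization`.
#' @export
fit_frap <- function(time, bleached, control = NULL, normalized = FALSE) {
  stop_if(length(time) != length(bleached), "time/bleached length mismatch")
  y <- bleached
  norm <- "none"
  if (!normalized) {
    if (!is.null(control)) {
      stop_if(length(control) != length(bleached), "control length mismatch")
      y <- y / control
      norm <- "bleached/control"
    }
    pre <- time < 0
    stop_if(!any(pre), "no pre-bleach samples to normalize against")
    y <- y / mean(y[pre])
    norm <- paste(norm, "then /pre-bleach mean")
  }
  post <- time >= 0
  stop_if(sum(post) < 5L, "need >= 5 post-bleach samples")
  tp <- time[post]; yp <- y[post]
  stop_if(max(yp) <= 0.02, "no recovery detectable: tau unbounded")
  if (stats::sd(yp) < 1e-3 && mean(yp) > 0.9)
    stop("curve is flat near 1: nothing was bleached (degenerate fit)")
  i63 <- which(yp >= 0.63 * max(yp))[1]
  tau0 <- if (is.na(i63) || tp[i63] <= 0) diff(range(tp)) / 5 else tp[i63]
  st <- list(P = max(yp), tau = tau0)
  fit <- minpack.lm::nlsLM(yp ~ P * (1 - exp(-tp / tau)), start = st,
                           lower = c(P = 0, tau = 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))["tau"], error = function(e) NA_real_)
  ci <- cf["tau"] + c(-1, 1) * stats::qt(0.975, df = sum(post) - 2) * se
  structure(list(tau = unname(cf["tau"]), k_off = unname(1 / cf["tau"]),
                 plateau = unname(cf["P"]),
                 tau_se = unname(se), tau_ci = unname(ci),
                 curve = data.frame(time = time, normalized = y),
                 normalization = norm, fit = fit),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("FRAP fit: tau = %.4g s (95%% CI %.4g..%.4g), k_off = %.4g /s, plateau = %.3g\n",
              x$tau, x$tau_ci[1], x$tau_ci[2], x$k_off, x$plateau))
  invisible(x)
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$curve$time, x$curve$normalized, pch = 16, cex = 0.6,
                 xlab = "time after bleach (s)", ylab = "normalized intensity", ...)
  tp <- seq(0, max(x$curve$time), length.out = 200)
  graphics::lines(tp, x$plateau * (1 - exp(-tp / x$tau)), col = 2, lwd = 2)
  invisible(x)
}

## ---- synthetic generators for this module's fixtures -----------------------

#' Synthetic straightened-membrane image
#'
#' Builds a straightened membrane matrix from a membrane concentration
#' series and a cytoplasm level using the same Gaussian + error-function
#' cross-section model the fitter assumes, plus Gaussian noise. Used for
#' round-trip validation (including re-quantifying PDE solutions as images).
#'
#' @param membrane membrane concentration per position (vector).
#' @param cytoplasm cytoplasm plateau (scalar or vector).
#' @param n_d cross-section width, px.
#' @param center,width membrane centre and width, px.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return numeric matrix positions x cross-section.
#' @export
synth_membrane_image <- function(membrane, cytoplasm, n_d = 50L, center = 25,
                                 width = 2, noise_sd = 0, seed = 1L) {
  set.seed(derive_seed(seed, "membrane-image"))
  n <- length(membrane)
  cyt <- rep(cytoplasm, length.out = n)
  d <- seq_len(n_d)
  img <- vapply(seq_len(n), function(i)
    membrane[i] * exp(-(d - center)^2 / (2 * width^2)) +
      cyt[i] * (1 - erf_((d - center) / (sqrt(2) * width))) / 2,
    numeric(n_d))
  img <- t(img)
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                                        nrow(img), ncol(img))
  img
}

#' Synthetic FRAP recovery curve
#'
#' @param tau turnover time, s.
#' @param t_max,dt sampling window/interval, s.
#' @param n_pre pre-bleach samples.
#' @param plateau recovery plateau.
#' @param noise_sd Gaussian noise SD on the normalized curve.
#' @param seed RNG seed.
#' @return data frame `time`, `bleached` (already normalized scale).
#' @export
synth_frap_curve <- function(tau, t_max = 600, dt = 5, n_pre = 3L,
                             plateau = 1, noise_sd = 0, seed = 1L) {
  set.seed(derive_seed(seed, paste0("frap", tau)))
  t_post <- seq(0, t_max, by = dt)
  t_pre <- -rev(seq_len(n_pre)) * dt
  y <- c(rep(1, n_pre), plateau * (1 - exp(-t_post / tau)))
  time <- c(t_pre, t_post)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  data.frame(time = time, bleached = y)
}
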