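## Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

check_scalar <- function(x, name, min = -Inf, strict = FALSE, finite = TRUE) {
  stop_if(!is.numeric(x) || length(x) != 1L, sprintf("'%s' must be a numeric scalar", name))
  stop_if(finite && !is.finite(x), sprintf("'%s' must be finite", name))
  if (strict) stop_if(x <= min, sprintf("'%s' must be > %g", name, min))
  else stop_if(x < min, sprintf("'%s' must be >= %g", name, min))
  invisible(x)
}

## Deterministic per-stage seed derivation from one global seed. Keeps every
## derived seed a valid 32-bit integer and decorrelates stages so that adding
## draws in one stage does not shift another stage's stream.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483563) + 1L
}

## 2D convolution (same-size output, zero-padded borders) via FFT.
conv2_fft <- function(img, kernel) {
  ni <- dim(img); nk <- dim(kernel)
  n1 <- ni[1] + nk[1] - 1L; n2 <- ni[2] + nk[2] - 1L
  pi_ <- matrix(0, n1, n2); pk <- matrix(0, n1, n2)
  pi_[seq_len(ni[1]), seq_len(ni[2])] <- img
  pk[seq_len(nk[1]), seq_len(nk[2])] <- kernel
  full <- Re(fft(fft(pi_) * fft(pk), inverse = TRUE)) / (n1 * n2)
  r0 <- (nk[1] - 1L) %/% 2L; c0 <- (nk[2] - 1L) %/% 2L
  full[r0 + seq_len(ni[1]), c0 + seq_len(ni[2])]
}

gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  outer(k, k)
}

boxcar_kernel <- function(size) {
  size <- as.integer(size)
  matrix(1 / (size * size), size, size)
}

## Grey-scale dilation (moving maximum) over a (2r+1)x(2r+1) square window,
## computed by shifting and pmax; fast enough for the image sizes used here.
max_filter <- function(img, r) {
  out <- img
  nr <- nrow(img); nc <- ncol(img)
  for (dy in -r:r) {
    rows <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    for (dx in -r:r) {
      if (dx == 0L && dy == 0L) next
      cols <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
      out <- pmax(out, img[rows, cols, drop = FALSE])
    }
  }
  out
}

## Catmull-Rom cubic interpolation weights for fractional offset t in [0,1).
catmull_rom_w <- function(t) {
  c(-0.5 * t^3 + t^2 - 0.5 * t,
    1.5 * t^3 - 2.5 * t^2 + 1,
    -1.5 * t^3 + 2 * t^2 + 0.5 * t,
    0.5 * t^3 - 0.5 * t^2)
}

## Bicubic (Catmull-Rom) interpolation of matrix z (rows ~ y grid, cols ~ x
## grid, both uniform) at arbitrary points; clamps to the grid hull so edge
## queries degrade to nearest-cell behaviour.
interp_bicubic <- function(xg, yg, z, x, y) {
  nx <- length(xg); ny <- length(yg)
  dxg <- xg[2] - xg[1]; dyg <- yg[2] - yg[1]
  fx <- (x - xg[1]) / dxg; fy <- (y - yg[1]) / dyg
  fx <- pmin(pmax(fx, 0), nx - 1); fy <- pmin(pmax(fy, 0), ny - 1)
  i <- pmin(floor(fx), nx - 2); j <- pmin(floor(fy), ny - 2)
  tx <- fx - i; ty <- fy - j
  out <- numeric(length(x))
  for (k in seq_along(x)) {
    ii <- pmin(pmax(i[k] + (-1:2) + 1L, 1L), nx)   # 1-based column indices
    jj <- pmin(pmax(j[k] + (-1:2) + 1L, 1L), ny)
    wx <- catmull_rom_w(tx[k]); wy <- catmull_rom_w(ty[k])
    out[k] <- as.numeric(t(wy) %*% z[jj, ii] %*% wx)
  }
  out
}

## Bilinear interpolation (used for texture warping where overshoot-free
## sampling matters more than smoothness).
interp_bilinear <- function(z, x, y) {
  ## x, y in 1-based pixel coordinates (x = column, y = row)
  nr <- nrow(z); nc <- ncol(z)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  tx <- x - x0; ty <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  z[i00] * (1 - tx) * (1 - ty) + z[i01] * tx * (1 - ty) +
    z[i10] * (1 - tx) * ty + z[i11] * tx * ty
}

## Minimal-total-squared-displacement bipartite assignment on a candidate
## edge list. Connected components of the candidate graph are solved exactly
## by enumeration when small, greedily (sorted by cost) otherwise. Ties are
## broken towards lower row index (deterministic runs).
assign_min_cost <- function(rows, cols, costs, exact_limit = 8L) {
  if (length(rows) == 0L) return(integer(0))
  edges <- data.frame(r = rows, c = cols, w = costs)
  ## union-find over rows/cols to split components
  ids <- c(paste0("r", unique(edges$r)), paste0("c", unique(edges$c)))
  parent <- stats::setNames(ids, ids)
  find <- function(a) { while (parent[[a]] != a) a <- parent[[a]]; a }
  for (k in seq_len(nrow(edges))) {
    a <- find(paste0("r", edges$r[k])); b <- find(paste0("c", edges$c[k]))
    if (a != b) parent[[a]] <- b
  }
  comp <- vapply(paste0("r", edges$r), find, character(1))
  sel <- logical(nrow(edges))
  for (cmp in unique(comp)) {
    idx <- which(comp == cmp)
    sub <- edges[idx, , drop = FALSE]
    rs <- unique(sub$r); cs <- unique(sub$c)
    if (length(rs) <= exact_limit && length(cs) <= exact_limit && nrow(sub) <= 20L) {
      sel[idx[assign_exact(sub, rs, cs)]] <- TRUE
    } else {
      ord <- order(sub$w, sub$r, sub$c)
      used_r <- character(0); used_c <- character(0)
      for (k in ord) {
        if (!(sub$r[k] %in% used_r) && !(sub$c[k] %in% used_c)) {
          sel[idx[k]] <- TRUE
          used_r <- c(used_r, sub$r[k]); used_c <- c(used_c, sub$c[k])
        }
      }
    }
  }
  which(sel)
}

## Exact search over matchings of a small component: maximise matched pairs,
## then minimise total cost. Returns indices into `sub`.
assign_exact <- function(sub, rs, cs) {
  best <- list(n = -1L, w = Inf, pick = integer(0))
  n_edge <- nrow(sub)
  recurse <- function(k, used_c, pick, w) {
    ## bound: remaining edges
    if (best$n > length(pick) + (n_edge - k + 1L)) return()
    if (k > n_edge) {
      n <- length(pick)
      if (n > best$n || (n == best$n && w < best$w)) best <<- list(n = n, w = w, pick = pick)
      return()
    }
    ## rows are grouped: decide edges in order; a row may appear in several edges
    r <- sub$r[k]
    if (!any(sub$r[pick] == r) && !(sub$c[k] %in% used_c)) {
      recurse(k + 1L, c(used_c, sub$c[k]), c(pick, k), w + sub$w[k])
    }
    recurse(k + 1L, used_c, pick, w)
  }
  ## order edges by row then cost for stable tie-breaking
  ord <- order(sub$r, sub$w, sub$c)
  sub2 <- sub[ord, , drop = FALSE]
  n_edge <- nrow(sub2)
  sub <- sub2
  recurse(1L, character(0), integer(0), 0)
  ord[best$pick]
}
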