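#' @importFrom rlang %||% abort warn .data
#' @importFrom stats median mad quantile rnorm runif rpois rchisq sd var
#' @importFrom stats pnorm pt phyper p.adjust setNames complete.cases
#' @importFrom stats aov kruskal.test shapiro.test ks.test t.test density
#' @importFrom stats na.omit pchisq
#' @importFrom utils head tail
NULL

# single entry point for all randomness: run `code` under a locally-set seed,
# leaving the caller's RNG state untouched; seed = NULL uses the current stream
with_seed_or_stream <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), force(code))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || (finite && !is.finite(x)) ||
      (!finite && is.na(x))) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1) {
  assert_number(x, name, lower = lower)
  if (x != round(x)) abort(sprintf("`%s` must be an integer count", name))
  invisible(as.integer(x))
}

# von Mises sampler (Best & Fisher rejection method); kappa = 0 is uniform,
# kappa = Inf is a point mass at mu
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(runif(n, -pi, pi) + mu)
  if (!is.finite(kappa)) return(rep(mu, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.5 * (n - length(out))))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    out <- c(out, (sign(u3 - 0.5) * acos(f))[ok])
  }
  out[seq_len(n)] + mu
}

# elementwise median across a list of equal-length numeric vectors using an
# odd-even transposition sorting network (all ops vectorised)
stack_median <- function(vecs) {
  k <- length(vecs)
  for (pass in seq_len(k)) {
    start <- if (pass %% 2 == 1) 1L else 2L
    j <- start
    while (j < k) {
      lo <- pmin(vecs[[j]], vecs[[j + 1]])
      vecs[[j + 1]] <- pmax(vecs[[j]], vecs[[j + 1]])
      vecs[[j]] <- lo
      j <- j + 2L
    }
  }
  if (k %% 2 == 1) vecs[[(k + 1) / 2]] else (vecs[[k / 2]] + vecs[[k / 2 + 1]]) / 2
}

# offsets (di, dj) of a disk of given pixel radius, centre included
disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[g$di^2 + g$dj^2 <= radius^2, , drop = FALSE]
}

# shift a matrix by (di, dj) with replicate padding at the borders
shift_replicate <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - di, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dj, 1L), nc)
  m[ri, ci, drop = FALSE]
}
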