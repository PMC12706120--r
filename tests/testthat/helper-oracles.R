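# Independent oracles used across the suite.

# exhaustive minimum-cost assignment between point sets a and b within a
# gate: maximises match count, then minimises summed squared distance, by
# enumerating all injective assignments (feasible for <= 6 points/side).
brute_force_assignment <- function(a, b, gate) {
  n1 <- nrow(a); n2 <- nrow(b)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  ok <- d2 <= gate^2
  best <- list(n = -1L, cost = Inf, match = rep(NA_integer_, n2))
  recurse <- function(j, used, match, n, cost) {
    if (j > n2) {
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost, match = match)
      }
      return(invisible())
    }
    recurse(j + 1L, used, match, n, cost)      # leave b[j] unmatched
    for (i in seq_len(n1)) {
      if (!used[i] && ok[i, j]) {
        used[i] <- TRUE; match[j] <- i
        recurse(j + 1L, used, match, n + 1L, cost + d2[i, j])
        used[i] <- FALSE; match[j] <- NA_integer_
      }
    }
  }
  recurse(1L, rep(FALSE, n1), rep(NA_integer_, n2), 0L, 0)
  best
}

# greedy-free point-in-mask lookup for ROI assignment
brute_force_roi_lookup <- function(x_um, y_um, mask, pixel_size) {
  vapply(seq_along(x_um), function(i) {
    r <- floor(y_um[i] / pixel_size) + 1
    c <- floor(x_um[i] / pixel_size) + 1
    as.integer(mask[r, c])
  }, integer(1))
}

# numeric two-filter oracle for preprocessing: plain-R disk median then
# grayscale opening, written independently (nested loops, no shared helpers)
oracle_preprocess <- function(frame, median_radius, ball_radius) {
  nr <- nrow(frame); nc <- ncol(frame)
  pad_get <- function(m, i, j) m[min(max(i, 1), nr), min(max(j, 1), nc)]
  neighborhood <- function(m, i, j, radius) {
    vals <- c()
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (di^2 + dj^2 <= radius^2) vals <- c(vals, pad_get(m, i + di, j + dj))
    }
    vals
  }
  med <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    med[i, j] <- median(neighborhood(frame, i, j, median_radius))
  }
  ero <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    ero[i, j] <- min(neighborhood(med, i, j, ball_radius))
  }
  dil <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    dil[i, j] <- max(neighborhood(ero, i, j, ball_radius))
  }
  pmax(med - dil, 0)
}

# render a small noiseless test field directly (independent of render_video)
# with point-sampled (not pixel-integrated) Gaussians: used only where the
# difference does not matter (centroid checks at high sampling)
centroid_of <- function(frame) {
  tot <- sum(frame)
  rows <- sum(row(frame) * frame) / tot
  cols <- sum(col(frame) * frame) / tot
  c(row = rows, col = cols)
}

# Kruskal-Wallis H via the direct rank formula (no ties assumed)
kw_h_oracle <- function(groups_list) {
  x <- unlist(groups_list)
  n <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups_list), lengths(groups_list))
  rsum <- tapply(r, idx, sum)
  ns <- lengths(groups_list)
  12 / (n * (n + 1)) * sum(rsum^2 / ns) - 3 * (n + 1)
}
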