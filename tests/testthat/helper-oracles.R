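# Independent oracles and shared fixtures for the test suite.

# Closed-form total SASA of two possibly-overlapping spheres (spherical-cap
# formula), independent of the package's point-sampling path.
two_sphere_oracle <- function(r1, r2, d, probe) {
  R1 <- r1 + probe
  R2 <- r2 + probe
  a1 <- 4 * pi * R1^2
  a2 <- 4 * pi * R2^2
  if (d < R1 + R2) {
    x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
    h1 <- R1 - x1
    h2 <- R2 - (d - x1)
    a1 <- a1 - 2 * pi * R1 * max(h1, 0)
    a2 <- a2 - 2 * pi * R2 * max(h2, 0)
  }
  a1 + a2
}

# Brute-force per-point recount of context-attributed buried area: plain
# double loops, no reuse of the package's occlusion helpers.
attribution_oracle <- function(pep, ctx, sel, probe, n_points) {
  pts <- ribotunnel:::unit_sphere_points(n_points)
  hydro <- polar <- 0
  for (i in sel) {
    R <- pep$radius[i] + probe
    P <- sweep(pts * R, 2, c(pep$x[i], pep$y[i], pep$z[i]), "+")
    for (k in seq_len(nrow(P))) {
      p <- P[k, ]
      blocked_pep <- FALSE
      for (j in seq_len(nrow(pep))) {
        if (j == i) next
        if (sum((p - c(pep$x[j], pep$y[j], pep$z[j]))^2) <
            (pep$radius[j] + probe)^2) { blocked_pep <- TRUE; break }
      }
      if (blocked_pep) next
      best_depth <- -Inf
      best_class <- NA
      for (j in seq_len(nrow(ctx))) {
        dj <- sqrt(sum((p - c(ctx$x[j], ctx$y[j], ctx$z[j]))^2))
        depth <- (ctx$radius[j] + probe) - dj
        if (depth > 0 && depth > best_depth) {
          best_depth <- depth
          best_class <- ctx$hydrophobic[j]
        }
      }
      if (!is.na(best_class)) {
        patch <- 4 * pi * R^2 / n_points
        if (best_class) hydro <- hydro + patch else polar <- polar + patch
      }
    }
  }
  list(hydrophobic = hydro, polar = polar)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_sphere_set <- function(ss, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(ss[, c("x", "y", "z")]) %*% t(R)
  ss$x <- xyz[, 1] + t[1]
  ss$y <- xyz[, 2] + t[2]
  ss$z <- xyz[, 3] + t[3]
  ss
}

poly_peptide <- function(code, n, ...) {
  peptide_sequence(strrep(code, n), id = paste0("poly", code), ...)
}
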