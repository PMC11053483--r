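# Independent brute-force oracle for the spatial step geometry, written
# directly from the definitions (projection of footstep midpoints onto the
# local three-point trajectory) before the package implementation, and kept
# separate from it.

oracle_project_point <- function(p, a, d) {
  # orthogonal projection of p onto the line through a with direction d
  t <- sum((p - a) * d) / sum(d * d)
  a + t * d
}

oracle_segment_line <- function(p1, p2, p3) {
  # y = k x + b with k from the endpoints and b through the first midpoint
  # (axis-swapped when near-vertical); return point + direction
  if (abs(p1[1] - p3[1]) < 1e-9) {
    k <- (p1[1] - p3[1]) / (p1[2] - p3[2])
    b <- (p1[1] + p2[1]) / 2 - k * (p1[2] + p2[2]) / 2
    list(a = c(b, 0), d = c(k, 1))
  } else {
    k <- (p1[2] - p3[2]) / (p1[1] - p3[1])
    b <- (p1[2] + p2[2]) / 2 - k * (p1[1] + p2[1]) / 2
    list(a = c(0, b), d = c(1, k))
  }
}

oracle_spatial_params <- function(P) {
  P <- as.matrix(P)
  n <- nrow(P)
  l <- w <- theta <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    ln <- oracle_segment_line(P[i - 1, ], P[i, ], P[i + 1, ])
    proj_i <- oracle_project_point(P[i, ], ln$a, ln$d)
    w[i] <- sqrt(sum((P[i, ] - proj_i)^2))
    m1 <- (P[i - 1, ] + P[i, ]) / 2
    m2 <- (P[i, ] + P[i + 1, ]) / 2
    q1 <- oracle_project_point(m1, ln$a, ln$d)
    q2 <- oracle_project_point(m2, ln$a, ln$d)
    l[i] <- sqrt(sum((q2 - q1)^2))
    theta[i] <- atan2(w[i], l[i]) * 180 / pi
  }
  s <- c(l[-1] + l[-n], NA_real_)
  s[is.na(l)] <- NA_real_
  data.frame(step_length = l, step_width = w, step_angle = theta,
             stride_length = s)
}
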