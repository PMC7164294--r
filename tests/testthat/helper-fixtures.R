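# Shared fixtures, all built in code.

# flat unit square in z = 0, two triangles, counter-clockwise from +z
flat_square <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  corr_surface(v, rbind(c(1, 2, 3), c(1, 3, 4)), "square")
}

# icosphere: subdivided icosahedron projected onto the unit sphere
icosphere <- function(subdivisions = 2, template_id = "icosphere") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (k in seq_len(subdivisions)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  corr_surface(v, f, template_id)
}

# deterministic rotation from axis (unnormalised) and angle in degrees
rotation_about <- function(axis, angle_deg) {
  ax <- axis / sqrt(sum(axis^2))
  ang <- angle_deg * pi / 180
  k <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)
}

# small template pair, memoised per session (used across test files)
local({
  cache <- new.env(parent = emptyenv())
  test_template <<- function(n_vertices = 800L) {
    key <- as.character(n_vertices)
    if (is.null(cache[[key]])) {
      cache[[key]] <- make_template(sim_config(n_vertices = n_vertices))
    }
    cache[[key]]
  }
})

# configuration for a noise-free, fixed-pose generator
quiet_config <- function(...) {
  sim_config(noise_sd = 0, pose_jitter_deg = 0, pose_jitter_mm = 0,
             teeth_displacement = 0, ...)
}

expect_valid_rotation <- function(r) {
  expect_lt(max(abs(crossprod(r) - diag(3))), 1e-9)
  expect_lt(abs(det(r) - 1), 1e-9)
}
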