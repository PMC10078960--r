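# Independent numeric oracles used across the test files.

# area and second moments of an elliptical annulus by 1-D quadrature over
# strip widths (independent of the closed forms in the package)
annulus_quadrature <- function(W, H, t) {
  a <- W / 2; b <- H / 2; ai <- a - t; bi <- b - t
  strip <- function(x, semi_x, semi_y) {
    ifelse(abs(x) < semi_x, 2 * semi_y * sqrt(pmax(0, 1 - x^2 / semi_x^2)), 0)
  }
  int <- function(f, lim) {
    integrate(f, -lim, lim, rel.tol = 1e-10, subdivisions = 2000L)$value
  }
  area <- int(function(x) strip(x, a, b) - strip(x, ai, bi), a)
  I_height_axis <- int(function(x) x^2 * (strip(x, a, b) - strip(x, ai, bi)), a)
  I_width_axis <- int(function(y) y^2 * (strip(y, b, a) - strip(y, bi, ai)), b)
  list(area = area, I_height_axis = I_height_axis,
       I_width_axis = I_width_axis)
}

# largest principal angle (radians) between the column space of A (p x k)
# and the row space of B (k x p); both assumed orthonormal
max_principal_angle <- function(A, B) {
  sv <- svd(t(A) %*% t(B))$d
  max(acos(pmin(1, sv)))
}

polyline_length <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

# small synthetic ribcage population built from two known orthogonal modes
# on a fixed score grid (no randomness)
make_rank2_population <- function(rib_points = 8) {
  template <- thoraxvar:::template_ribcage_vector(rib_points)
  p <- length(template)
  basis <- qr.Q(qr(cbind(sin(seq_len(p)), cos(seq_len(p) / 3))))
  scores <- expand.grid(s1 = c(-20, -10, 0, 10, 20), s2 = c(-6, 0, 6))
  subjects <- lapply(seq_len(nrow(scores)), function(i) {
    vec <- template + basis[, 1] * scores$s1[i] + basis[, 2] * scores$s2[i]
    thoraxvar:::unflatten_ribcage(vec, rib_points)
  })
  list(subjects = subjects, basis = basis, scores = scores,
       template = template)
}
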