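# internal helpers shared across modules

`%||%` <- rlang::`%||%`

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    rlang::abort(sprintf("`%s` must be a single positive number", name))
  invisible(x)
}

assert_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    rlang::abort(sprintf("`%s` must be a numeric matrix", name))
  invisible(x)
}

is_integerish_values <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) < tol)
}

# bilinear interpolation of matrix `m` at real-valued (row, col) positions
# (1-based, pixel-centred); positions are clamped to the matrix extent
interp_bilinear <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# shoelace area of a closed polygon given as an n x 2 (row, col) matrix
polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# resample a closed polyline to n vertices at uniform arc length
resample_closed <- function(v, n) {
  vc <- rbind(v, v[1, , drop = FALSE])
  seg <- sqrt(diff(vc[, 1])^2 + diff(vc[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) rlang::abort("degenerate contour: zero perimeter")
  at <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  cbind(
    stats::approx(s, vc[, 1], xout = at, rule = 2)$y,
    stats::approx(s, vc[, 2], xout = at, rule = 2)$y
  )
}

# standard error of the mean, NA-safe
se_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
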