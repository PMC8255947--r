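## Shared fixtures: everything is built in code at test time.

fix_bg <- function() opticalBackground(0.01, 1)
fix_geom <- function(bg = fix_bg()) slabGeometry(40, bg)
fix_axis <- function(n_t = 164, dt = 25) timeAxis(dt, n_t)

## short axis + scheme for cheap kernel tests
fix_short <- function() {
  ax <- fix_axis(96)
  list(axis = ax, scheme = windowScheme(ax, 10))
}

## binary disk mask matrix (x along rows), center in pixel coords
diskMatrix <- function(nr, nc, ci, cj, r) {
  outer(seq_len(nr), seq_len(nc), function(i, j) (i - ci)^2 + (j - cj)^2 < r^2) * 1
}

## smoothed-threshold random blob masks for property tests
randomBlobMask <- function(n = 48, frac = 0.8) {
  k <- exp(-(-12:12)^2 / (2 * 3^2)); k <- k / sum(k)
  m <- matrix(rnorm(n * n), n, n)
  sm <- t(apply(apply(m, 2, function(col) stats::filter(c(rev(col[1:12]), col, rev(col[(n-11):n])), k, sides = 2)[13:(n+12)]), 1,
                function(row) stats::filter(c(rev(row[1:12]), row, rev(row[(n-11):n])), k, sides = 2)[13:(n+12)]))
  msk <- sm > stats::quantile(sm, frac)
  planarMask(msk, 1)
}

## synthetic default-phantom B-mode image + truth, fixed seed
fix_us <- function(seed = 11) {
  set.seed(seed)
  spec <- phantomSpec()
  c(synthUSImage(spec), list(spec = spec))
}

## seed ring just inside the true border, pixel coords
ringSeeds <- function(spec, image, n = 8, inset = 1) {
  cc <- spec@incl_center; r <- spec@incl_diameter / 2 - inset
  ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind((cc[1] + r * cos(ang) - image@origin[1]) / image@pitch + 1,
        (cc[3] + r * sin(ang) - image@origin[2]) / image@pitch + 1)
}
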