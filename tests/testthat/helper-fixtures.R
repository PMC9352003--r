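# Programmatic fixtures shared across the test files. Everything is built
# in code; no binary data ships with the package.

# flat-colour frame with optional painted shapes (height x width x 3)
blank_image <- function(h, w, level = 235) {
  array(level, dim = c(h, w, 3))
}

# paint every pixel where `where` (h x w logical) is TRUE with colour `col`
paint <- function(image, where, col) {
  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[where] <- col[ch]
    image[, , ch] <- plane
  }
  image
}

# logical disc / ellipse masks on the pixel grid (x = column, y = row)
disc_where <- function(h, w, cx, cy, r) {
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

ellipse_where <- function(h, w, cx, cy, a, b) {
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
}

apple_red <- c(200, 40, 40)
defect_dark <- c(50, 30, 15)

# brute-force raw moment by explicit double loop (oracle)
moment_loops <- function(mask, p, q) {
  acc <- 0
  for (y in seq_len(nrow(mask))) {
    for (x in seq_len(ncol(mask))) {
      acc <- acc + x^p * y^q * mask[y, x]
    }
  }
  acc
}

# small spectra_set with a linear Brix signal, for chemometrics tests
toy_spectra <- function(n = 24, w = 80, seed = 1, noise = 0.001) {
  set.seed(seed)
  wl <- seq(500, 900, length.out = w)
  brix <- runif(n, 9, 14)
  base <- 0.6 - 0.1 * ((wl - 700) / 200)^2
  band <- exp(-0.5 * ((wl - 760) / 10)^2)
  R <- matrix(base, n, w, byrow = TRUE) -
    outer(brix * 0.01, band) +
    matrix(rnorm(n * w, sd = noise), n, w)
  spectra_set(wl, R, brix = brix)
}
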