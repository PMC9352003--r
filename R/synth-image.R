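#' Specification of a synthetic apple image
#'
#' Parameters for [render_apple()]: a red-hued filled ellipse (the fruit)
#' on a light background, with optional dark defect blobs and a small
#' specular highlight, emulating a top-view photograph of an apple in a
#' light box.
#'
#' @param diameter_px Horizontal fruit diameter in pixels (`>= 20`).
#' @param aspect Horizontal/vertical extent ratio (`> 0`); the vertical
#'   diameter is `diameter_px / aspect`.
#' @param defect_fraction Target fraction of fruit area covered by dark
#'   defect blobs, in `[0, 0.2]`.
#' @param n_defect_blobs Number of blobs the defect area is split into.
#' @param highlight Draw a small white specular highlight on the fruit?
#' @param background_level 8-bit grey level of the light background.
#' @param frame Height/width of the (square) image in pixels.
#' @param center Optional `c(x, y)` fruit centre; defaults to the frame
#'   centre. Useful for translation-invariance checks.
#' @param noise_sd Pixel noise standard deviation (8-bit units).
#' @param seed Integer seed; identical specs render byte-identical
#'   images.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(diameter_px = 140, aspect = 1, defect_fraction = 0,
                       n_defect_blobs = 3, highlight = TRUE,
                       background_level = 235, frame = 256, center = NULL,
                       noise_sd = 2, seed = 1) {
  if (diameter_px < 20) abort("`diameter_px` must be >= 20.", class = "fujigrade_invalid_parameter")
  if (aspect <= 0) abort("`aspect` must be positive.", class = "fujigrade_invalid_parameter")
  if (defect_fraction < 0 || defect_fraction > 0.2) {
    abort("`defect_fraction` must lie in [0, 0.2].", class = "fujigrade_invalid_parameter")
  }
  structure(
    list(diameter_px = diameter_px, aspect = aspect,
         defect_fraction = defect_fraction, n_defect_blobs = n_defect_blobs,
         highlight = highlight, background_level = background_level,
         frame = frame, center = center, noise_sd = noise_sd, seed = seed),
    class = "image_spec"
  )
}

#' Render a synthetic apple image with known ground truth
#'
#' Draws the fruit ellipse, defect blobs (discs placed fully inside the
#' fruit; overlap allowed, area counted on the rendered raster) and an
#' optional specular highlight, then adds mild pixel noise. The returned
#' ground truth is computed from the rendered raster itself: `t` is the
#' drawn defect-pixel count over the fruit-pixel count, `lambda` the
#' horizontal/vertical extent ratio of the fruit mask, and `wp` its
#' larger extent — so truth and measurement share the same geometry but
#' not the same code path.
#'
#' @param spec An [image_spec()].
#' @param config A [vision_config()] used only to label the ground-truth
#'   measurements.
#' @return A list with `image` (height x width x 3 array in `[0, 255]`),
#'   `truth` (one-row tibble like [measure_apple()] output), and the
#'   drawn `fruit_mask` and `defect_mask`.
#' @examples
#' ap <- render_apple(image_spec(diameter_px = 100, seed = 7))
#' ap$truth
#' @export
render_apple <- function(spec, config = vision_config()) {
  stopifnot(inherits(spec, "image_spec"))
  h <- spec$frame; w <- spec$frame
  a <- spec$diameter_px / 2                 # horizontal semi-axis
  b <- spec$diameter_px / (2 * spec$aspect) # vertical semi-axis
  ctr <- if (is.null(spec$center)) c((w + 1) / 2, (h + 1) / 2) else spec$center
  if (ctr[1] - a < 2 || ctr[1] + a > w - 1 || ctr[2] - b < 2 || ctr[2] + b > h - 1) {
    abort("Fruit does not fit inside the frame.", class = "fujigrade_render_error")
  }
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  fruit <- matrix(as.integer(((xs - ctr[1]) / a)^2 + ((ys - ctr[2]) / b)^2 <= 1), h, w)

  with_local_seed(spec$seed, {
    img <- array(0, dim = c(h, w, 3))
    bg <- spec$background_level
    fruit_col <- c(200, 40, 40)
    defect_col <- c(50, 30, 15)
    for (ch in 1:3) img[, , ch] <- ifelse(fruit == 1, fruit_col[ch], bg)

    defect <- matrix(0L, h, w)
    if (spec$defect_fraction > 0) {
      target <- spec$defect_fraction * sum(fruit)
      r_blob <- max(2.5, sqrt(target / (spec$n_defect_blobs * pi)))
      for (k in seq_len(spec$n_defect_blobs)) {
        # uniform point in the ellipse shrunk so the blob stays inside
        sa <- max(a - r_blob - 2, 1); sb <- max(b - r_blob - 2, 1)
        repeat {
          u <- runif(1, -1, 1); v <- runif(1, -1, 1)
          if (u^2 + v^2 <= 1) break
        }
        cx <- ctr[1] + u * sa; cy <- ctr[2] + v * sb
        blob <- (xs - cx)^2 + (ys - cy)^2 <= r_blob^2
        defect[blob & fruit == 1] <- 1L
      }
      for (ch in 1:3) {
        plane <- img[, , ch]; plane[defect == 1] <- defect_col[ch]
        img[, , ch] <- plane
      }
    }

    if (spec$highlight) {
      hx <- ctr[1] - a / 3; hy <- ctr[2] - b / 3
      hl <- (xs - hx)^2 + (ys - hy)^2 <= 5^2 & fruit == 1 & defect == 0
      for (ch in 1:3) {
        plane <- img[, , ch]; plane[hl] <- 250
        img[, , ch] <- plane
      }
    }

    if (spec$noise_sd > 0) {
      img <- img + array(rnorm(length(img), sd = spec$noise_sd), dim = dim(img))
    }
    img <- pmin(pmax(round(img), 0), 255)

    cols <- which(colSums(fruit) > 0); rows <- which(rowSums(fruit) > 0)
    dx <- max(cols) - min(cols); dy <- max(rows) - min(rows)
    t_true <- sum(defect) / sum(fruit)
    lambda_true <- dx / dy
    # same geometric definition as the measurement (2 * max centroid-to-
    # boundary distance), evaluated on the drawn mask itself
    cen <- contour_centroid(fruit)
    inner <- fruit[2:(h - 1), 2:(w - 1)] &
      fruit[1:(h - 2), 2:(w - 1)] & fruit[3:h, 2:(w - 1)] &
      fruit[2:(h - 1), 1:(w - 2)] & fruit[2:(h - 1), 3:w]
    boundary <- fruit == 1
    boundary[2:(h - 1), 2:(w - 1)] <- fruit[2:(h - 1), 2:(w - 1)] == 1 & !inner
    bidx <- which(boundary, arr.ind = TRUE)
    wp_true <- 2 * sqrt(max((bidx[, 2] - cen[1])^2 + (bidx[, 1] - cen[2])^2))
    truth <- tibble(
      t = t_true, lambda = lambda_true, wp = wp_true,
      defect_label = classify_defect(t_true, config),
      shape_label = classify_shape(lambda_true, config),
      size_label = classify_size(wp_true, config)
    )
    list(image = img, truth = truth, fruit_mask = fruit, defect_mask = defect)
  })
}

#' Simulate pixel/millimetre calibration pairs
#'
#' Draws image diameters `Wp` uniformly over a pixel range and generates
#' caliper diameters `Wr = slope * Wp + intercept + noise`, emulating the
#' data behind the size calibration regression.
#'
#' @param n Number of pairs (`>= 2`).
#' @param slope,intercept Generating line (defaults: the reference
#'   calibration, 0.4052 mm/px and 13.5015 mm).
#' @param noise_sd Gaussian noise SD on `Wr`, mm.
#' @param wp_range Pixel range `Wp` is drawn from.
#' @param seed Integer seed.
#' @return A tibble with columns `wp` (px) and `wr` (mm).
#' @export
make_calibration_pairs <- function(n, slope = 0.4052, intercept = 13.5015,
                                   noise_sd = 2, wp_range = c(110, 190),
                                   seed = 1) {
  if (n < 2) abort("`n` must be >= 2.", class = "fujigrade_invalid_parameter")
  with_local_seed(seed, {
    wp <- runif(n, wp_range[1], wp_range[2])
    tibble(wp = wp, wr = slope * wp + intercept + rnorm(n, sd = noise_sd))
  })
}

#' Benchmark the appearance classifiers on rendered fixtures
#'
#' Renders a batch of synthetic apples with randomized diameter, aspect
#' ratio and defect coverage, measures each through the full vision
#' pipeline, and compares the measured labels with the generator's
#' ground truth. The batch composition mirrors a physical grading trial:
#' half the fruit defect-free and half with clearly visible defects,
#' half nearly round and half nearly oval, and diameters drawn evenly
#' across the four size classes (including values near the class
#' boundaries).
#'
#' @param n Number of fruit to render (default 200).
#' @param seed Integer seed for the batch composition.
#' @param config A [vision_config()].
#' @return A tibble with one row per fruit: the ground-truth and
#'   measured values of `t`, `lambda`, `wp` and the three labels
#'   (`truth_*` / `meas_*` columns).
#' @examples
#' bench <- appearance_benchmark(n = 10, seed = 1)
#' mean(bench$truth_size_label == bench$meas_size_label)
#' @export
appearance_benchmark <- function(n = 200, seed = 1, config = vision_config()) {
  params <- with_local_seed(seed, {
    size_class <- sample(rep(1:4, length.out = n))
    lo <- c(164, 139, 127, 100)[size_class]
    hi <- c(185, 164, 139, 127)[size_class]
    tibble(
      diameter = runif(n, lo, hi),
      aspect = ifelse(runif(n) < 0.5,
                      runif(n, 0.985, 1.045),                  # nearly round
                      ifelse(runif(n) < 0.5,                   # nearly oval
                             runif(n, 0.90, 0.975),
                             runif(n, 1.055, 1.15))),
      defect = ifelse(runif(n) < 0.5, 0, runif(n, 0.004, 0.05)),
      blobs = sample(1:4, n, replace = TRUE),
      seed = seed + seq_len(n)
    )
  })
  purrr::pmap_dfr(params, function(diameter, aspect, defect, blobs, seed) {
    ap <- render_apple(image_spec(diameter_px = diameter, aspect = aspect,
                                  defect_fraction = defect,
                                  n_defect_blobs = blobs, seed = seed),
                       config)
    truth <- ap$truth
    names(truth) <- paste0("truth_", names(truth))
    meas <- measure_apple(ap$image, config)
    names(meas) <- paste0("meas_", names(meas))
    dplyr::bind_cols(truth, meas)
  })
}
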