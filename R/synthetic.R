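# Seeded synthetic CT phantoms emulating the class-conditional intensity and
# texture structure of kidney CT slices: hyperdense small foci (stones),
# homogeneous hypodense round regions with a sharp rim (cysts), and
# irregular heterogeneous regions (tumors) inside an anti-aliased kidney
# ellipse over a darker background. Intensities live on [0, 1]. The phantoms
# are a test surface for the windowing/texture pipeline, not a clinical
# simulator.

#' Phantom generation parameters
#'
#' Intensity bands are chosen so the class contrasts the pipeline is built
#' to exploit hold by construction: the stone level exceeds the parenchyma
#' band maximum, the cyst level sits below its minimum, and the tumor's
#' correlated internal noise exceeds the cyst's (near-zero) internal
#' variation.
#'
#' @param size Image side length in pixels.
#' @param background Background intensity band `c(lo, hi)`.
#' @param parenchyma Kidney parenchyma intensity band.
#' @param kidney_axes Relative semi-axis ranges of the kidney ellipse
#'   (fractions of `size`).
#' @param cyst_radius,stone_radius,tumor_radius Lesion radius ranges as
#'   fractions of `size` (stones in pixels at `size = 64`, scaled).
#' @param cyst_level,stone_level Lesion intensity bands.
#' @param tumor_perturb Radial boundary perturbation amplitude (fraction of
#'   the radius).
#' @param tumor_noise_amp,tumor_noise_scale Amplitude and Gaussian smoothing
#'   scale (pixels) of the tumor's correlated internal noise.
#' @param base_noise Acquisition noise s.d. added to every phantom.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(size = 64,
                           background = c(0.10, 0.18),
                           parenchyma = c(0.35, 0.60),
                           kidney_axes = list(a = c(0.28, 0.38), b = c(0.20, 0.28)),
                           cyst_radius = c(0.08, 0.16),
                           cyst_level = c(0.08, 0.20),
                           stone_radius = c(0.06, 0.10),
                           stone_level = c(0.88, 0.98),
                           tumor_radius = c(0.10, 0.18),
                           tumor_perturb = 0.25,
                           tumor_noise_amp = 0.10,
                           tumor_noise_scale = 2,
                           base_noise = 0.01) {
  if (stone_level[1] <= parenchyma[2]) {
    stop_input("stone level must exceed the parenchyma band maximum")
  }
  if (cyst_level[2] >= parenchyma[1]) {
    stop_input("cyst level must lie below the parenchyma band minimum")
  }
  vals <- c(background, parenchyma, cyst_level, stone_level)
  if (any(vals < 0 | vals > 1)) stop_input("all intensity bands must lie in [0, 1]")
  if (max(cyst_radius, stone_radius, tumor_radius) >= min(kidney_axes$b)) {
    stop_input("lesion radius range exceeds the smallest kidney semi-axis")
  }
  structure(as.list(environment()), class = "phantom_params")
}

# Smoothstep edge profile for anti-aliasing: 1 inside, 0 outside, smooth
# over `width` pixels around r = 1 (normalized radius).
smooth_inside <- function(r, width) {
  t <- clamp01((1 - r) / width + 0.5)
  t * t * (3 - 2 * t)
}

gaussian_kernel_1d <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a matrix (replicate borders) used for the
# tumor's spatially correlated noise.
gaussian_blur <- function(x, sigma) {
  k <- gaussian_kernel_1d(sigma)
  n <- length(k)
  xc <- as_chwn(x)
  w <- array(matrix(k, n, 1) %*% matrix(k, 1, n), c(n, n, 1, 1))
  from_chwn(conv2d_fwd_cpp(xc, w, numeric(0), 1L, (n - 1L) %/% 2L, 1L, 1L))
}

#' Generate one synthetic phantom
#'
#' Deterministic under `(label, params, seed)`. Builds background + kidney
#' ellipse, adds the class-specific lesion, then adds the base acquisition
#' noise and clips to `[0, 1]`.
#'
#' @param label One of `"normal"`, `"cyst"`, `"stone"`, `"tumor"`.
#' @param params A [phantom_params()].
#' @param seed Integer seed.
#' @return An object of class `phantom_sample`: list with `image` (size x
#'   size matrix in `[0,1]`), `label`, and `meta` (lesion geometry, seed,
#'   noise sigma).
#' @export
generate_phantom <- function(label = c("normal", "cyst", "stone", "tumor"),
                             params = phantom_params(), seed = 1) {
  label <- match.arg(label)
  stopifnot(inherits(params, "phantom_params"))
  s <- params$size
  with_seed(seed, {
    bg <- runif(1, params$background[1], params$background[2])
    img <- matrix(bg, s, s)
    # gentle illumination gradient across the field of view
    grad_dir <- runif(1, 0, 2 * pi)
    gx <- matrix(rep(seq(-0.5, 0.5, length.out = s), each = s), s, s)
    gy <- matrix(rep(seq(-0.5, 0.5, length.out = s), times = s), s, s)
    img <- img + 0.02 * (cos(grad_dir) * gx + sin(grad_dir) * gy)

    cx <- s / 2 + runif(1, -0.06, 0.06) * s
    cy <- s / 2 + runif(1, -0.06, 0.06) * s
    a <- runif(1, params$kidney_axes$a[1], params$kidney_axes$a[2]) * s
    b <- runif(1, params$kidney_axes$b[1], params$kidney_axes$b[2]) * s
    phi <- runif(1, -pi / 6, pi / 6)
    par_level <- runif(1, params$parenchyma[1], params$parenchyma[2])

    xs <- matrix(rep(seq_len(s), each = s), s, s) - cx # column coordinate
    ys <- matrix(rep(seq_len(s), times = s), s, s) - cy # row coordinate
    xr <- xs * cos(phi) + ys * sin(phi)
    yr <- -xs * sin(phi) + ys * cos(phi)
    r_ell <- sqrt((xr / a)^2 + (yr / b)^2)
    mask <- smooth_inside(r_ell, width = 1.5 / min(a, b))
    img <- img * (1 - mask) + par_level * mask

    meta <- list(label = label, seed = seed, kidney = c(cx = cx, cy = cy,
                 a = a, b = b, phi = phi), lesion = NULL, sigma = params$base_noise)
    if (label != "normal") {
      radius_range <- switch(label, cyst = params$cyst_radius,
                             stone = params$stone_radius,
                             tumor = params$tumor_radius)
      r_les <- runif(1, radius_range[1], radius_range[2]) * s
      if (r_les >= min(a, b)) stop_input("lesion larger than kidney")
      # place the lesion centre well inside the ellipse
      theta <- runif(1, 0, 2 * pi)
      rho <- runif(1, 0, 0.5)
      lx <- cx + rho * (a - r_les) * cos(theta) * cos(phi) -
        rho * (b - r_les) * sin(theta) * sin(phi)
      ly <- cy + rho * (a - r_les) * cos(theta) * sin(phi) +
        rho * (b - r_les) * sin(theta) * cos(phi)
      dx <- matrix(rep(seq_len(s), each = s), s, s) - lx
      dy <- matrix(rep(seq_len(s), times = s), s, s) - ly
      rr <- sqrt(dx^2 + dy^2)
      if (label == "cyst") {
        lvl <- runif(1, params$cyst_level[1], params$cyst_level[2])
        lmask <- smooth_inside(rr / r_les, width = 0.8 / r_les) # sharp rim
        img <- img * (1 - lmask) + lvl * lmask
      } else if (label == "stone") {
        lvl <- runif(1, params$stone_level[1], params$stone_level[2])
        lmask <- smooth_inside(rr / r_les, width = 1.2 / r_les)
        img <- img * (1 - lmask) + lvl * lmask
      } else { # tumor: irregular boundary + correlated internal noise
        ang <- atan2(dy, dx)
        pert <- 0
        for (k in 2:5) {
          pert <- pert + runif(1, -1, 1) * cos(k * ang + runif(1, 0, 2 * pi))
        }
        r_theta <- r_les * (1 + params$tumor_perturb * pert / 4)
        lvl <- par_level + runif(1, -0.12, 0.12)
        lmask <- smooth_inside(rr / pmax(r_theta, 1), width = 1.5 / r_les)
        tex <- gaussian_blur(matrix(rnorm(s * s), s, s), params$tumor_noise_scale)
        tex <- tex / max(sd(tex), 1e-8) * params$tumor_noise_amp
        img <- img * (1 - lmask) + (lvl + tex) * lmask
      }
      meta$lesion <- list(x = lx, y = ly, radius = r_les, level = lvl)
    }
    img <- clamp01(img)
    img <- clamp01(img + matrix(rnorm(s * s, sd = params$base_noise), s, s))
    structure(list(image = img, label = label, meta = meta),
              class = "phantom_sample")
  })
}

#' Add Gaussian acquisition noise
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation `sigma` on
#' the `[0,1]` intensity scale, then clips to `[0,1]`. `sigma = 0` returns
#' the input unchanged; deterministic under `seed`.
#'
#' @param image Numeric matrix or array in `[0,1]`.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Noisy image, same shape.
#' @export
add_noise <- function(image, sigma, seed = 1) {
  if (sigma < 0) stop_input("sigma must be nonnegative")
  if (sigma == 0) return(image)
  noise <- with_seed(seed, array(rnorm(length(image), sd = sigma),
                                 dim(image) %||% length(image)))
  clamp01(image + noise)
}

#' Augmentation specification
#'
#' Label-preserving geometric and photometric jitter: rotation (degrees),
#' isotropic scaling, horizontal/vertical flips, translation (fraction of
#' the side), additive brightness, multiplicative contrast about the mean,
#' and gamma correction. Each transform fires independently with
#' probability `prob`.
#'
#' @param rotate Max absolute rotation in degrees (<= 15).
#' @param scale Scale range.
#' @param translate Max absolute translation as a fraction of the side.
#' @param flip_h,flip_v Allow horizontal / vertical flips.
#' @param brightness Max absolute additive brightness shift.
#' @param contrast Contrast factor range.
#' @param gamma Gamma range.
#' @param prob Per-transform application probability.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(rotate = 15, scale = c(0.9, 1.1), translate = 0.05,
                         flip_h = TRUE, flip_v = TRUE,
                         brightness = 0.05, contrast = c(0.9, 1.1),
                         gamma = c(0.85, 1.2), prob = 0.5) {
  if (rotate < 0 || rotate > 15) stop_input("rotation must lie in [0, 15] degrees")
  if (scale[1] < 0.9 - 1e-9 || scale[2] > 1.1 + 1e-9) {
    stop_input("scale range must lie within [0.9, 1.1]")
  }
  if (translate < 0 || translate > 0.2) stop_input("translate must lie in [0, 0.2]")
  if (prob < 0 || prob > 1) stop_input("prob must lie in [0, 1]")
  structure(as.list(environment()), class = "augment_spec")
}

# Affine resample of a matrix: output pixel (r, c) is sampled at the source
# location given by the inverse transform (rotation about the centre, then
# scaling, then translation), bilinear interpolation, replicate borders.
affine_resample <- function(image, angle = 0, scale = 1, tx = 0, ty = 0) {
  s1 <- nrow(image); s2 <- ncol(image)
  cr <- (s1 + 1) / 2; cc <- (s2 + 1) / 2
  rows <- matrix(rep(seq_len(s1), times = s2), s1, s2) - cr
  cols <- matrix(rep(seq_len(s2), each = s1), s1, s2) - cc
  th <- -angle * pi / 180 # inverse rotation
  src_r <- (cos(th) * rows - sin(th) * cols) / scale + cr - ty * s1
  src_c <- (sin(th) * rows + cos(th) * cols) / scale + cc - tx * s2
  r0 <- floor(src_r); c0 <- floor(src_c)
  tr <- src_r - r0; tc <- src_c - c0
  cl <- function(v, n) pmin(pmax(v, 1), n)
  idx <- function(r, c) image[cbind(as.vector(cl(r, s1)), as.vector(cl(c, s2)))]
  out <- (1 - tr) * (1 - tc) * idx(r0, c0) + (1 - tr) * tc * idx(r0, c0 + 1) +
    tr * (1 - tc) * idx(r0 + 1, c0) + tr * tc * idx(r0 + 1, c0 + 1)
  matrix(out, s1, s2)
}

#' Apply seeded augmentation
#'
#' @param image H x W matrix in `[0,1]`.
#' @param spec An [augment_spec()]; with all probabilities zero this is the
#'   identity.
#' @param seed Integer seed.
#' @return Augmented image, clipped to `[0,1]`.
#' @export
augment <- function(image, spec = augment_spec(), seed = 1) {
  stopifnot(inherits(spec, "augment_spec"))
  with_seed(seed, {
    img <- image
    angle <- if (runif(1) < spec$prob) runif(1, -spec$rotate, spec$rotate) else 0
    scl <- if (runif(1) < spec$prob) runif(1, spec$scale[1], spec$scale[2]) else 1
    tx <- if (runif(1) < spec$prob) runif(1, -spec$translate, spec$translate) else 0
    ty <- if (runif(1) < spec$prob) runif(1, -spec$translate, spec$translate) else 0
    if (angle != 0 || scl != 1 || tx != 0 || ty != 0) {
      img <- affine_resample(img, angle, scl, tx, ty)
    }
    if (spec$flip_h && runif(1) < spec$prob) img <- img[, rev(seq_len(ncol(img)))]
    if (spec$flip_v && runif(1) < spec$prob) img <- img[rev(seq_len(nrow(img))), ]
    if (runif(1) < spec$prob) img <- img + runif(1, -spec$brightness, spec$brightness)
    if (runif(1) < spec$prob) {
      f <- runif(1, spec$contrast[1], spec$contrast[2])
      img <- (img - mean(img)) * f + mean(img)
    }
    if (runif(1) < spec$prob) {
      g <- runif(1, spec$gamma[1], spec$gamma[2])
      img <- clamp01(img)^g
    }
    clamp01(img)
  })
}

# Largest-remainder apportionment of n into parts proportional to p.
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Generate a labelled phantom dataset
#'
#' Stratified class counts match `proportions` within rounding
#' (largest-remainder apportionment); each class is split 7:1.5:1.5 into
#' train/val/test. Optionally writes the class-per-directory PNG layout
#' (`dir/<split>/<class>/*.png`) plus a `metadata.csv`.
#'
#' @param n Total number of samples.
#' @param proportions Class proportions (named or in class order), summing
#'   to 1. Defaults: binary 0.5/0.5; four-class the empirical kidney CT
#'   class mix 0.408/0.298/0.111/0.183 (normal/cyst/stone/tumor).
#' @param params A [phantom_params()].
#' @param seed Global seed.
#' @param task `"binary"` (normal vs stone) or `"fourclass"`.
#' @param dir Output directory for the PNG layout, or `NULL` (in-memory
#'   only).
#' @param split Split fractions.
#' @return List with `images` (size x size x n array), `labels` (factor),
#'   `split` (factor train/val/test), and `metadata` (tibble).
#' @export
generate_dataset <- function(n, proportions = NULL, params = phantom_params(),
                             seed = 1, task = c("binary", "fourclass"),
                             dir = NULL,
                             split = c(train = 0.7, val = 0.15, test = 0.15)) {
  task <- match.arg(task)
  classes <- if (task == "binary") c("normal", "stone") else
    c("normal", "cyst", "stone", "tumor")
  if (is.null(proportions)) {
    proportions <- if (task == "binary") c(0.5, 0.5) else
      c(0.408, 0.298, 0.111, 0.183)
  }
  if (length(proportions) != length(classes)) {
    stop_input("proportions must have one entry per class (%d)", length(classes))
  }
  if (abs(sum(proportions) - 1) > 1e-6) stop_input("proportions must sum to 1")
  if (n < length(classes)) stop_input("n is smaller than the number of classes")
  counts <- apportion(n, proportions)

  s <- params$size
  images <- array(0, c(s, s, n))
  labels <- character(n)
  split_f <- character(n)
  meta_rows <- vector("list", n)
  i <- 0L
  for (ci in seq_along(classes)) {
    nsplit <- apportion(counts[ci], split)
    split_lab <- rep(names(split), nsplit)
    for (j in seq_len(counts[ci])) {
      i <- i + 1L
      sm <- generate_phantom(classes[ci], params,
                             derive_seed(seed, "data", ci * 1000000L + j))
      images[, , i] <- sm$image
      labels[i] <- classes[ci]
      split_f[i] <- split_lab[j]
      les <- sm$meta$lesion
      meta_rows[[i]] <- tibble::tibble(
        id = i, label = classes[ci], split = split_lab[j],
        seed = sm$meta$seed, sigma = sm$meta$sigma,
        lesion_x = les$x %||% NA_real_, lesion_y = les$y %||% NA_real_,
        lesion_radius = les$radius %||% NA_real_,
        lesion_level = les$level %||% NA_real_)
    }
  }
  metadata <- do.call(rbind, meta_rows)
  out <- list(images = images,
              labels = factor(labels, levels = classes),
              split = factor(split_f, levels = names(split)),
              metadata = metadata, classes = classes, params = params,
              seed = seed, task = task)
  if (!is.null(dir)) {
    paths <- character(n)
    for (i in seq_len(n)) {
      d <- file.path(dir, split_f[i], labels[i])
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      paths[i] <- file.path(d, sprintf("phantom_%05d.png", i))
      png::writePNG(images[, , i], paths[i])
    }
    out$metadata$path <- paths
    write.csv(out$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  }
  out
}

#' Read a class-per-directory PNG dataset
#'
#' Loads `dir/<split>/<class>/*.png` (as written by [generate_dataset()])
#' into the in-memory dataset shape. Images are converted to single-channel
#' `[0,1]` matrices.
#'
#' @param dir Dataset root directory.
#' @return List with `images`, `labels`, `split`, `classes`.
#' @export
read_image_dataset <- function(dir) {
  files <- list.files(dir, pattern = "\\.png$", recursive = TRUE,
                      full.names = TRUE)
  if (length(files) == 0) stop_input("no PNG files found under %s", dir)
  rel <- strsplit(substring(files, nchar(dir) + 2), "/")
  splits <- vapply(rel, `[`, "", 1)
  labels <- vapply(rel, `[`, "", 2)
  img1 <- png::readPNG(files[1])
  if (length(dim(img1)) == 3) img1 <- img1[, , 1]
  images <- array(0, c(dim(img1), length(files)))
  for (i in seq_along(files)) {
    im <- png::readPNG(files[i])
    if (length(dim(im)) == 3) im <- im[, , 1]
    images[, , i] <- im
  }
  list(images = images, labels = factor(labels),
       split = factor(splits, levels = c("train", "val", "test")),
       classes = levels(factor(labels)))
}
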