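# Synthetic prosthesis-phantom radiographs.
#
# Stands in for the private clinical dataset: each sample is a grayscale
# image containing a stylised stem + head + cup implant silhouette over a
# femur, plus one deterministic lesion primitive per positive label, with
# per-sample geometric jitter and additive Gaussian noise. Labels are drawn
# from an exact 7-bit joint distribution: independent Bernoulli marginals
# re-weighted by pairwise odds multipliers (2^7 = 128 states, normalised in
# closed form), so the sampler is exactly the distribution it claims.

#' Phantom dataset specification
#'
#' The defaults mirror the clinical study conditions: 443 samples with
#' marginal label frequencies equal to the reported per-complication counts
#' (269, 158, 30, 28, 187, 25, 34 of 443) and independent labels (unit
#' co-occurrence multipliers), at 64-pixel resolution.
#'
#' @param n_samples Sample count.
#' @param image_size Image side in pixels.
#' @param marginals Length-7 vector of base label probabilities in `[0, 1]`.
#' @param cooccurrence Symmetric 7x7 matrix of positive pairwise odds
#'   multipliers (diagonal ignored); entry `(i, j) = m` multiplies the joint
#'   odds of labels i and j both being positive by `m`.
#' @param noise_sigma Additive pixel-noise standard deviation.
#' @param lesion_strength Intensity amplitude of lesion primitives.
#' @param seed Integer seed controlling labels and all per-sample jitter.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_samples = 443, image_size = 64,
                         marginals = c(269, 158, 30, 28, 187, 25, 34) / 443,
                         cooccurrence = NULL, noise_sigma = 0.05,
                         lesion_strength = 0.4, seed = 1) {
  if (length(marginals) != 7 || any(marginals < 0) || any(marginals > 1)) {
    stop_thanet("marginals must be 7 probabilities in [0, 1]")
  }
  if (is.null(cooccurrence)) cooccurrence <- matrix(1, 7, 7)
  if (!all(dim(cooccurrence) == c(7, 7)) || any(cooccurrence <= 0)) {
    stop_thanet("cooccurrence must be a positive 7x7 matrix")
  }
  if (!isTRUE(all.equal(cooccurrence, t(cooccurrence)))) {
    stop_thanet("cooccurrence matrix must be symmetric")
  }
  if (image_size < 32) stop_thanet("image_size must be at least 32")
  structure(list(n_samples = n_samples, image_size = image_size,
                 marginals = marginals, cooccurrence = cooccurrence,
                 noise_sigma = noise_sigma,
                 lesion_strength = lesion_strength, seed = seed),
            class = "phantom_spec")
}

#' Exact joint label distribution of a phantom specification
#'
#' Enumerates all 128 label states and returns their normalised
#' probabilities under the marginal/odds-multiplier model; this closed form
#' is what [sample_labels()] draws from.
#'
#' @param spec A [phantom_spec()].
#' @return List with `states` (128 x 7 binary matrix) and `prob`
#'   (length-128 probabilities summing to 1).
#' @export
label_joint <- function(spec) {
  states <- as.matrix(expand.grid(rep(list(0:1), 7)))
  colnames(states) <- complication_labels()
  p <- spec$marginals
  logw <- numeric(nrow(states))
  for (k in 1:7) {
    logw <- logw + ifelse(states[, k] == 1, log(p[k]), log1p(-p[k]))
  }
  for (i in 1:6) {
    for (j in (i + 1):7) {
      m <- spec$cooccurrence[i, j]
      if (m != 1) logw <- logw + log(m) * states[, i] * states[, j]
    }
  }
  w <- exp(logw - max(logw[is.finite(logw)]))
  w[!is.finite(w)] <- 0
  list(states = states, prob = w / sum(w))
}

#' Sample label vectors for a phantom dataset
#'
#' Seed-deterministic draw of `spec$n_samples` label vectors from the exact
#' joint of [label_joint()]. With unit co-occurrence the labels are
#' independent Bernoulli with the configured marginals; a multiplier above 1
#' inflates the joint probability of its label pair.
#'
#' @param spec A [phantom_spec()].
#' @return `n_samples x 7` binary matrix with label-name columns.
#' @export
sample_labels <- function(spec) {
  joint <- label_joint(spec)
  idx <- with_seed(spec$seed,
                   sample.int(nrow(joint$states), spec$n_samples,
                              replace = TRUE, prob = joint$prob))
  joint$states[idx, , drop = FALSE]
}

## ---- rendering ------------------------------------------------------------

# Fixed unit-square geometry of the phantom. Lesion regions are disjoint by
# construction so a region-mean statistic identifies each label.
phantom_geom <- list(
  stem_top = 0.40, stem_bot = 0.95, stem_hw0 = 0.085, stem_taper = 0.05,
  head_c = c(0.44, 0.28), head_r = 0.075,
  cup_c = c(0.43, 0.27), cup_r = 0.115, cup_t = 0.022,
  stripe_l = 0.36, stripe_r = 0.64, stripe_hw = 0.015, stripe_top = 0.35,
  neck_from = c(0.50, 0.42)
)

stem_halfwidth <- function(y) {
  g <- phantom_geom
  pmax(0.02, g$stem_hw0 - g$stem_taper * (y - g$stem_top) /
         (g$stem_bot - g$stem_top))
}

# Coordinate grids: X[i,j], Y[i,j] are the unit coordinates of pixel (i,j),
# with Y increasing downwards (row index) and X rightwards (column index).
unit_grid <- function(s) {
  v <- (seq_len(s) - 0.5) / s
  list(X = matrix(v, s, s, byrow = TRUE), Y = matrix(v, s, s))
}

disc_mask <- function(gr, c, r) (gr$X - c[1])^2 + (gr$Y - c[2])^2 <= r^2

in_stem <- function(gr, hw_scale = 1) {
  g <- phantom_geom
  hw <- stem_halfwidth(gr$Y) * hw_scale
  abs(gr$X - 0.5) <= hw & gr$Y >= g$stem_top & gr$Y <= g$stem_bot
}

segment_mask <- function(gr, a, b, halfwidth) {
  d <- b - a
  len2 <- sum(d^2)
  t <- pmin(pmax(((gr$X - a[1]) * d[1] + (gr$Y - a[2]) * d[2]) / len2, 0), 1)
  px <- a[1] + t * d[1]; py <- a[2] + t * d[2]
  (gr$X - px)^2 + (gr$Y - py)^2 <= halfwidth^2
}

# Deterministic implant-and-femur template (no lesions, no noise).
#' Phantom base template
#' @param spec A [phantom_spec()].
#' @return `image_size x image_size` intensity matrix in `[0, 1]`.
#' @export
phantom_template <- function(spec) {
  g <- phantom_geom
  gr <- unit_grid(spec$image_size)
  img <- matrix(0.08, spec$image_size, spec$image_size)
  # femur: medullary canal and cortical stripes
  canal <- gr$X > g$stripe_l & gr$X < g$stripe_r & gr$Y > g$stripe_top
  img[canal] <- 0.25
  for (sx in c(g$stripe_l, g$stripe_r)) {
    stripe <- abs(gr$X - sx) <= g$stripe_hw & gr$Y > g$stripe_top
    img[stripe] <- 0.55
  }
  # acetabular cup arc (upper half annulus)
  rr <- sqrt((gr$X - g$cup_c[1])^2 + (gr$Y - g$cup_c[2])^2)
  cup <- abs(rr - g$cup_r) <= g$cup_t & gr$Y < g$cup_c[2] + 0.02
  img[cup] <- 0.80
  # implant: stem wedge, neck, head
  img[in_stem(gr)] <- 0.95
  img[segment_mask(gr, g$neck_from, g$head_c, 0.02)] <- 0.95
  img[disc_mask(gr, g$head_c, g$head_r)] <- 0.95
  img
}

#' Nominal lesion regions
#'
#' Logical masks (one per label) of the image regions where each lesion
#' primitive expresses itself; the regions are mutually disjoint, so the
#' mean intensity inside a region is a sufficient statistic for its label on
#' noise-free renders.
#'
#' @param spec A [phantom_spec()].
#' @return Named list of 7 logical matrices.
#' @export
phantom_regions <- function(spec) {
  gr <- unit_grid(spec$image_size)
  g <- phantom_geom
  list(
    loosening = in_stem(gr, 1.28) & !in_stem(gr, 1.02) &
      gr$Y > 0.50 & gr$Y < 0.90,
    osteolysis = disc_mask(gr, c(0.61, 0.46), 0.045),
    fracture = abs(gr$X - g$stripe_r) <= 0.045 & gr$Y > 0.60 & gr$Y < 0.84,
    dislocation = disc_mask(gr, g$head_c, 0.030),
    wear = disc_mask(gr, c(g$head_c[1], g$head_c[2] + 0.060), 0.018),
    infection = gr$X > 0.26 & gr$X < 0.335 & gr$Y > 0.50 & gr$Y < 0.88,
    other = abs(gr$X - 0.12) <= 0.05 & abs(gr$Y - 0.12) <= 0.05
  )
}

#' Render one phantom radiograph
#'
#' Deterministic for fixed `(labels, spec, sample_seed)`. The base template
#' always contains the implant silhouette; each positive label adds its
#' primitive: loosening a radiolucent band along the stem border, osteolysis
#' a lytic blob beside the proximal stem, fracture a thin dark line crossing
#' the lateral cortex, dislocation a head drawn outside the cup, wear an
#' eccentric (superiorly shifted) head, infection mottled periosteal
#' speckles along the medial cortex, and "other" a small bright marker.
#' Geometry is jittered per sample within documented ranges.
#'
#' @param labels Length-7 binary vector.
#' @param spec A [phantom_spec()].
#' @param sample_seed Integer seed for this sample's jitter and noise.
#' @return A `phantom_sample`: list with `image` (matrix in `[0, 1]`),
#'   `labels`, `provenance` (per-lesion render parameters).
#' @export
render_phantom <- function(labels, spec, sample_seed = 1) {
  stopifnot(length(labels) == 7, all(labels %in% c(0, 1)))
  g <- phantom_geom
  ls <- spec$lesion_strength
  with_seed(sample_seed, {
    s <- spec$image_size
    gr <- unit_grid(s)
    img <- phantom_template(spec)
    prov <- list()

    head_c <- g$head_c
    if (labels[4] == 1) {                     # dislocation: head leaves cup
      ang <- stats::runif(1, 20, 60) * pi / 180
      d <- stats::runif(1, 0.10, 0.13)
      head_c <- head_c + c(sin(ang), -cos(ang)) * d
      prov$dislocation <- list(angle = ang, displacement = d)
    }
    if (labels[5] == 1) {                     # wear: eccentric head in cup
      d <- stats::runif(1, 0.024, 0.032)
      head_c <- head_c + c(0, -d)
      prov$wear <- list(shift = d)
    }
    if (labels[4] == 1 || labels[5] == 1) {
      # redraw head (and neck) at displaced position
      img[disc_mask(gr, g$head_c, g$head_r + 0.004)] <- 0.25
      rr <- sqrt((gr$X - g$cup_c[1])^2 + (gr$Y - g$cup_c[2])^2)
      cup <- abs(rr - g$cup_r) <= g$cup_t & gr$Y < g$cup_c[2] + 0.02
      img[cup] <- 0.80
      img[segment_mask(gr, g$neck_from, head_c, 0.02)] <- 0.95
      img[disc_mask(gr, head_c, g$head_r)] <- 0.95
    }
    if (labels[1] == 1) {                     # loosening: periprosthetic line
      w <- stats::runif(1, 1.24, 1.34)
      band <- in_stem(gr, w) & !in_stem(gr, 1.02) & gr$Y > 0.50 & gr$Y < 0.90
      img[band] <- pmax(img[band] - ls * stats::runif(1, 0.85, 1), 0)
      prov$loosening <- list(width_scale = w)
    }
    if (labels[2] == 1) {                     # osteolysis: lytic blob
      c0 <- c(0.61, 0.46) + stats::runif(2, -0.010, 0.010)
      sig <- stats::runif(1, 0.020, 0.028)
      bl <- exp(-((gr$X - c0[1])^2 + (gr$Y - c0[2])^2) / (2 * sig^2))
      img <- pmax(img - 1.1 * ls * bl, 0)
      prov$osteolysis <- list(center = c0, sigma = sig)
    }
    if (labels[3] == 1) {                     # fracture: cortical break
      yf <- stats::runif(1, 0.64, 0.80)
      th <- stats::runif(1, -0.45, 0.45)
      dist <- abs((gr$Y - yf) - th * (gr$X - g$stripe_r))
      line <- dist <= 0.008 & abs(gr$X - g$stripe_r) <= 0.04
      img[line] <- 0.10
      prov$fracture <- list(y = yf, slope = th)
    }
    if (labels[6] == 1) {                     # infection: periosteal mottling
      # mottled, predominantly sclerotic (bright) reaction on the dark
      # medial soft-tissue background, with scattered lytic dots
      nd <- 26
      cx <- stats::runif(nd, 0.27, 0.325)
      cy <- stats::runif(nd, 0.51, 0.87)
      cr <- stats::runif(nd, 0.008, 0.016)
      bright <- stats::runif(nd) < 0.8
      for (k in seq_len(nd)) {
        m <- disc_mask(gr, c(cx[k], cy[k]), cr[k])
        img[m] <- pmin(pmax(img[m] + ifelse(bright[k], 1, -0.5) * ls, 0), 1)
      }
      prov$infection <- list(n_dots = nd)
    }
    if (labels[7] == 1) {                     # other: corner marker
      c0 <- c(0.12, 0.12) + stats::runif(2, -0.008, 0.008)
      cross <- (abs(gr$X - c0[1]) <= 0.030 & abs(gr$Y - c0[2]) <= 0.008) |
               (abs(gr$X - c0[1]) <= 0.008 & abs(gr$Y - c0[2]) <= 0.030)
      img[cross] <- 0.90
      prov$other <- list(center = c0)
    }
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(s * s, sd = spec$noise_sigma), s, s)
    }
    structure(list(image = pmin(pmax(img, 0), 1),
                   labels = as.integer(labels), provenance = prov),
              class = "phantom_sample")
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_samples` PNG images plus a CSV manifest in the dialect of
#' [load_manifest()]; regeneration with the same specification reproduces
#' the identical label matrix and images.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
generate_dataset <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_thanet("cannot create directory: ", out_dir)
  labels <- sample_labels(spec)
  files <- sprintf("phantom_%04d.png", seq_len(spec$n_samples))
  for (i in seq_len(spec$n_samples)) {
    sm <- render_phantom(labels[i, ], spec, derive_seed(spec$seed, i))
    png::writePNG(sm$image, file.path(out_dir, files[i]))
  }
  records <- data.frame(image = files, labels, check.names = FALSE)
  manifest <- file.path(out_dir, "manifest.csv")
  write_manifest(records, manifest)
  invisible(manifest)
}

#' Generate a phantom dataset in memory
#'
#' Same sampling and rendering as [generate_dataset()] without touching the
#' filesystem; convenient for training experiments.
#'
#' @param spec A [phantom_spec()].
#' @return List with `x` (`size x size x 3 x N` image tensor, grayscale
#'   replicated to three channels) and `y` (`N x 7` label matrix).
#' @export
phantom_tensors <- function(spec) {
  labels <- sample_labels(spec)
  s <- spec$image_size
  x <- array(0, c(s, s, 3, spec$n_samples))
  for (i in seq_len(spec$n_samples)) {
    sm <- render_phantom(labels[i, ], spec, derive_seed(spec$seed, i))
    x[, , , i] <- sm$image
  }
  list(x = x, y = labels)
}
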