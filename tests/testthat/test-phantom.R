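# Phantom generator: exact label joint, rendering fidelity, disk round trip.

test_that("label sampler hits configured marginals under independence", {
  spec <- phantom_spec(n_samples = 2000, seed = 42)
  y <- sample_labels(spec)
  p <- spec$marginals
  se <- sqrt(p * (1 - p) / 2000)
  emp <- colMeans(y)
  expect_true(all(abs(emp - p) <= 3 * se + 1e-12))
  # exact joint marginals equal the configured ones in closed form
  joint <- label_joint(spec)
  expect_equal(as.vector(crossprod(joint$states, joint$prob)), p,
               tolerance = 1e-12)
})

test_that("degenerate marginals give degenerate labels", {
  y <- sample_labels(phantom_spec(n_samples = 50, marginals = rep(0, 7)))
  expect_true(all(y == 0))
  y1 <- sample_labels(phantom_spec(n_samples = 50,
                                   marginals = c(1, rep(0, 6))))
  expect_true(all(y1[, 1] == 1) && all(y1[, -1] == 0))
})

test_that("co-occurrence multipliers lift joint probabilities monotonically", {
  ors <- vapply(c(1, 2, 4), function(m) {
    co <- matrix(1, 7, 7); co[1, 2] <- co[2, 1] <- m
    joint <- label_joint(phantom_spec(cooccurrence = co))
    s <- joint$states; pr <- joint$prob
    p11 <- sum(pr[s[, 1] == 1 & s[, 2] == 1])
    p00 <- sum(pr[s[, 1] == 0 & s[, 2] == 0])
    p10 <- sum(pr[s[, 1] == 1 & s[, 2] == 0])
    p01 <- sum(pr[s[, 1] == 0 & s[, 2] == 1])
    (p11 * p00) / (p10 * p01)
  }, numeric(1))
  expect_true(all(diff(ors) > 0))
  # empirical lift on a Monte-Carlo draw
  co <- matrix(1, 7, 7); co[1, 2] <- co[2, 1] <- 4
  y <- sample_labels(phantom_spec(n_samples = 5000, cooccurrence = co,
                                  seed = 9))
  lift <- mean(y[, 1] * y[, 2]) / (mean(y[, 1]) * mean(y[, 2]))
  expect_gt(lift, 1)
})

test_that("rendering is deterministic and anchored to the template", {
  spec <- phantom_spec(image_size = 64, noise_sigma = 0.05)
  lab <- c(1, 0, 1, 0, 1, 0, 1)
  s1 <- render_phantom(lab, spec, sample_seed = 123)
  s2 <- render_phantom(lab, spec, sample_seed = 123)
  expect_identical(s1$image, s2$image)
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  # zero noise + all-zero labels reproduce the deterministic template
  spec0 <- phantom_spec(image_size = 64, noise_sigma = 0)
  s0 <- render_phantom(rep(0, 7), spec0, sample_seed = 5)
  expect_identical(s0$image, phantom_template(spec0))
  expect_length(s0$provenance, 0)
  # provenance records exactly the drawn lesions
  expect_setequal(names(s1$provenance),
                  c("loosening", "fracture", "wear", "other"))
})

test_that("each lesion leaves a separable signature in its region", {
  spec <- phantom_spec(image_size = 64, noise_sigma = 0)
  regions <- phantom_regions(spec)
  labs <- complication_labels()
  for (k in seq_along(labs)) {
    pos <- vapply(1:10, function(i) {
      l <- rep(0, 7); l[k] <- 1
      mean(render_phantom(l, spec, sample_seed = 1000 * k + i)$image[regions[[k]]])
    }, numeric(1))
    neg <- vapply(1:10, function(i) {
      mean(render_phantom(rep(0, 7), spec,
                          sample_seed = 5000 + i)$image[regions[[k]]])
    }, numeric(1))
    # region-mean statistic separates positives from negatives perfectly
    expect_true(max(pos) < min(neg) || min(pos) > max(neg),
                label = paste("separation for", labs[k]))
  }
})

test_that("loosening darkens the stem border band beyond noise", {
  spec <- phantom_spec(image_size = 64, noise_sigma = 0.02)
  band <- phantom_regions(spec)$loosening
  d <- vapply(1:8, function(i) {
    on <- render_phantom(c(1, rep(0, 6)), spec, sample_seed = i)$image
    off <- render_phantom(rep(0, 7), spec, sample_seed = i)$image
    mean(off[band]) - mean(on[band])
  }, numeric(1))
  # band darkening far beyond the pixel noise level on the band mean
  expect_true(all(d > 5 * 0.02))
})

test_that("generate_dataset writes a loadable, reproducible dataset", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(n_samples = 30, image_size = 48, seed = 77)
  manifest <- generate_dataset(spec, dir)
  expect_equal(length(list.files(dir, pattern = "\\.png$")), 30)
  rec <- load_manifest(manifest, image_root = dir)
  expect_equal(nrow(rec), 30)
  expect_equal(label_matrix(rec), sample_labels(spec), ignore_attr = TRUE)
  # regeneration reproduces the identical label matrix and first image
  dir2 <- withr::local_tempdir()
  generate_dataset(spec, dir2)
  expect_identical(png::readPNG(file.path(dir, "phantom_0001.png")),
                   png::readPNG(file.path(dir2, "phantom_0001.png")))
})
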