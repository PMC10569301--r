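# Dataset schema and split machinery.
#
# A dataset is a CSV manifest with one header row — an `image` column plus
# the seven complication columns in canonical order — and one row per
# radiograph; images are PNG (or JPEG/TIFF when EBImage is installed),
# pre-cropped to the periprosthetic region.

#' Canonical complication label set
#'
#' The fixed, ordered seven-label panel annotated on each radiograph. The
#' order defines the label index `k` used by the MC-CSRA coefficients and
#' the manifest column order.
#'
#' @return Character vector of length 7.
#' @export
complication_labels <- function() {
  c("loosening", "osteolysis", "fracture", "dislocation", "wear",
    "infection", "other")
}

#' Load a dataset manifest
#'
#' Reads a CSV manifest (comma-separated, UTF-8, header required: `image`
#' plus the seven label columns in [complication_labels()] order) and
#' validates every label as 0/1. Malformed rows, out-of-range labels and
#' unknown or misordered columns raise errors naming the offence; missing
#' image files are reported as a warning when `image_root` is given.
#'
#' @param csv_path Manifest path.
#' @param image_root Optional directory that image paths are relative to;
#'   when given, file existence is checked and a `path` column added.
#' @return Data frame with columns `image` and the seven labels (integer
#'   0/1), one row per record.
#' @export
load_manifest <- function(csv_path, image_root = NULL) {
  if (!file.exists(csv_path)) stop_thanet("manifest not found: ", csv_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  want <- c("image", complication_labels())
  if (!identical(names(df), want)) {
    extra <- setdiff(names(df), want)
    if (length(extra)) {
      stop_thanet("unknown column(s) in manifest: ",
                  paste(extra, collapse = ", "))
    }
    stop_thanet("manifest columns must be exactly: ",
                paste(want, collapse = ", "))
  }
  for (lab in complication_labels()) {
    v <- df[[lab]]
    bad <- which(!v %in% c("0", "1"))
    if (length(bad)) {
      stop_thanet("label '", lab, "' has value '", v[bad[1]],
                  "' outside {0,1} at data row ", bad[1])
    }
    df[[lab]] <- as.integer(v)
  }
  if (any(df$image == "" | is.na(df$image))) {
    stop_thanet("empty image reference at data row ",
                which(df$image == "" | is.na(df$image))[1])
  }
  if (!is.null(image_root)) {
    df$path <- file.path(image_root, df$image)
    missing <- !file.exists(df$path)
    if (any(missing)) {
      warning(sum(missing), " image file(s) missing, e.g. ",
              df$path[which(missing)[1]], call. = FALSE)
    }
  }
  df
}

#' Write a dataset manifest
#' @param records Data frame with `image` and the seven label columns.
#' @param csv_path Output path.
#' @return `csv_path`, invisibly.
#' @export
write_manifest <- function(records, csv_path) {
  want <- c("image", complication_labels())
  utils::write.csv(records[, want], csv_path, row.names = FALSE,
                   quote = FALSE)
  invisible(csv_path)
}

#' Extract the label matrix from manifest records
#' @param records Manifest data frame.
#' @return `N x 7` integer matrix with label-name columns.
#' @export
label_matrix <- function(records) {
  as.matrix(records[, complication_labels()])
}

#' Build a cross-validation fold plan
#'
#' Shuffles record indices with a seeded generator and deals them
#' round-robin, so fold sizes differ by at most one and every record sits in
#' exactly one fold. Deterministic for fixed `(n_records, n_folds, seed)`.
#'
#' @param n_records Record count (or a records data frame).
#' @param n_folds Fold count (default 5).
#' @param seed Integer seed.
#' @return A `fold_plan`: list with `assignments` (fold index per record),
#'   `n_folds`, `seed`.
#' @export
make_folds <- function(n_records, n_folds = 5, seed = 1) {
  if (is.data.frame(n_records)) n_records <- nrow(n_records)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2) stop_thanet("n_folds must be at least 2")
  if (n_folds > n_records) {
    stop_thanet("n_folds (", n_folds, ") exceeds record count (", n_records, ")")
  }
  perm <- with_seed(seed, sample.int(n_records))
  assignments <- integer(n_records)
  assignments[perm] <- ((seq_len(n_records) - 1L) %% n_folds) + 1L
  structure(list(assignments = assignments, n_folds = n_folds, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("fold plan:", length(x$assignments), "records,", x$n_folds,
      "folds (sizes", paste(tabulate(x$assignments, x$n_folds),
                            collapse = "/"), ") seed", x$seed, "\n")
  invisible(x)
}

#' Fold sizes of a plan
#' @param plan A `fold_plan`.
#' @return Integer vector of per-fold record counts.
#' @export
fold_sizes <- function(plan) tabulate(plan$assignments, plan$n_folds)

#' Serialise / restore a fold plan as JSON
#' @param plan A `fold_plan`.
#' @param path JSON path.
#' @return `path` invisibly / the restored `fold_plan`.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(assignments = as.integer(p$assignments),
                 n_folds = as.integer(p$n_folds), seed = as.integer(p$seed)),
            class = "fold_plan")
}

#' Train/validation/test split in 6:2:2 proportions
#'
#' Shuffles indices with a seeded generator and cuts 60/20/20 (train and
#' validation rounded down, remainder to test). Exhaustive, disjoint and
#' seed-deterministic.
#'
#' @param n_records Record count (or a records data frame).
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_622 <- function(n_records, seed = 1) {
  if (is.data.frame(n_records)) n_records <- nrow(n_records)
  if (n_records < 5) stop_thanet("need at least 5 records for a 6:2:2 split")
  perm <- with_seed(seed, sample.int(n_records))
  n_tr <- floor(0.6 * n_records)
  n_va <- floor(0.2 * n_records)
  list(train = sort(perm[seq_len(n_tr)]),
       val = sort(perm[n_tr + seq_len(n_va)]),
       test = sort(perm[(n_tr + n_va + 1L):n_records]))
}

## ---- image preprocessing --------------------------------------------------

#' Preprocessing specification
#'
#' @param target_size Output side in pixels (224 matches the full-scale
#'   model; the printed backbone MAC budget is only consistent with
#'   224-pixel input, which calibrates this default).
#' @param mean,sd Per-channel normalisation constants; the defaults are the
#'   standard ImageNet statistics used with ImageNet-style backbones.
#' @param color_mode `"grayscale3"` replicates a grayscale radiograph to
#'   three identical channels; `"rgb"` keeps colour channels.
#' @return A `preprocess_spec` list.
#' @export
preprocess_spec <- function(target_size = 224,
                            mean = c(0.485, 0.456, 0.406),
                            sd = c(0.229, 0.224, 0.225),
                            color_mode = c("grayscale3", "rgb")) {
  color_mode <- match.arg(color_mode)
  stopifnot(target_size >= 8, length(mean) == 3, length(sd) == 3, all(sd > 0))
  structure(list(target_size = target_size, mean = mean, sd = sd,
                 color_mode = color_mode), class = "preprocess_spec")
}

read_image_array <- function(path) {
  if (!file.exists(path)) stop_thanet("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (requireNamespace("EBImage", quietly = TRUE)) {
    d <- EBImage::imageData(EBImage::readImage(path))   # x-major layout
    if (length(dim(d)) == 2) t(d) else aperm(d, c(2, 1, 3))
  } else {
    stop_thanet("cannot read image (only PNG supported without EBImage): ",
                path)
  }
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]  # alpha
  img
}

# Bilinear resize of a 2-D matrix (align-corners = FALSE convention).
resize_bilinear <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  src_r <- pmin(pmax((seq_len(h) - 0.5) * H / h - 0.5, 0), H - 1)
  src_c <- pmin(pmax((seq_len(w) - 0.5) * W / w - 0.5, 0), W - 1)
  r0 <- pmin(floor(src_r), H - 1); r1 <- pmin(r0 + 1, H - 1)
  c0 <- pmin(floor(src_c), W - 1); c1 <- pmin(c0 + 1, W - 1)
  dr <- src_r - r0; dc <- src_c - c0
  a <- m[r0 + 1, c0 + 1, drop = FALSE] * outer(1 - dr, 1 - dc)
  b <- m[r1 + 1, c0 + 1, drop = FALSE] * outer(dr, 1 - dc)
  d <- m[r0 + 1, c1 + 1, drop = FALSE] * outer(1 - dr, dc)
  e <- m[r1 + 1, c1 + 1, drop = FALSE] * outer(dr, dc)
  a + b + d + e
}

#' Preprocess one radiograph
#'
#' Decodes (when given a path), converts to three channels, resizes to the
#' target size by bilinear interpolation and normalises each channel by the
#' configured mean and standard deviation.
#'
#' @param image Image path, 2-D grayscale matrix, or `H x W x 3` array with
#'   values in `[0, 1]`.
#' @param spec A [preprocess_spec()].
#' @return Normalised `target x target x 3` array.
#' @export
preprocess <- function(image, spec = preprocess_spec()) {
  if (is.character(image)) image <- read_image_array(image)
  if (is.matrix(image)) {
    image <- array(rep(image, 3), c(dim(image), 3))
  } else if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop_thanet("image must be grayscale or 3-channel")
  }
  if (spec$color_mode == "grayscale3" && !all(image[, , 1] == image[, , 2])) {
    g <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
    image <- array(rep(g, 3), c(dim(g), 3))
  }
  ts <- spec$target_size
  out <- array(0, c(ts, ts, 3))
  for (ch in 1:3) {
    r <- if (all(dim(image)[1:2] == c(ts, ts))) image[, , ch]
         else resize_bilinear(image[, , ch], ts, ts)
    out[, , ch] <- (r - spec$mean[ch]) / spec$sd[ch]
  }
  if (!all(is.finite(out))) stop_thanet("non-finite pixels after preprocessing")
  out
}

#' Load a batch of manifest images as a tensor
#' @param records Manifest data frame with a `path` column (or `image`
#'   resolvable against `image_root`).
#' @param spec A [preprocess_spec()].
#' @param image_root Optional image directory.
#' @return `target x target x 3 x N` array.
#' @export
load_image_batch <- function(records, spec = preprocess_spec(),
                             image_root = NULL) {
  paths <- if (!is.null(records$path)) records$path
           else if (!is.null(image_root)) file.path(image_root, records$image)
           else records$image
  ts <- spec$target_size
  out <- array(0, c(ts, ts, 3, length(paths)))
  for (i in seq_along(paths)) out[, , , i] <- preprocess(paths[i], spec)
  out
}
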