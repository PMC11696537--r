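# In-memory dataset container and PNG/CSV manifest I/O.
#
# An image_dataset holds grayscale images in [0,1] as H x W matrices, a
# 3-column class-weight matrix on the probability simplex (the soft label),
# optional binary lesion masks (NULL for mask-less samples), and per-sample
# provenance (source) and split tags. On disk it is a manifest CSV
# (path,mask_path,split,w_normal,w_benign,w_malignant,source[,parents])
# next to 8-bit grayscale PNGs.

#' Construct an image dataset
#'
#' @param images list of H x W numeric matrices with values in `[0,1]`.
#' @param labels n x 3 numeric matrix of class weights (rows on the simplex),
#'   columns ordered normal, benign, malignant.
#' @param masks optional list of binary H x W matrices (or `NULL` entries for
#'   samples without a mask, e.g. the normal class).
#' @param source character vector of provenance tags (one of
#'   original, sda, pixel_mixup, manifold_flag, dreamon, dreamoff).
#' @param split character vector of split tags (`"train"`, `"test"`,
#'   `"val"`, or `NA` before splitting).
#' @param parents optional character vector recording parent sample ids for
#'   mixed samples.
#' @return an object of class `image_dataset`.
#' @export
image_dataset <- function(images, labels, masks = NULL, source = "original",
                          split = NA_character_, parents = NA_character_) {
  n <- length(images)
  labels <- matrix(as.numeric(labels), nrow = n, ncol = 3,
                   dimnames = list(NULL, WEIGHT_COLS))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (!is.matrix(img)) stop("images must be matrices")
    if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
      stop("pixel values must lie in [0,1]")
    if (!is_simplex(labels[i, ])) stop("label row ", i, " not on the simplex")
  }
  if (is.null(masks)) masks <- vector("list", n)
  stopifnot(length(masks) == n)
  for (m in masks)
    if (!is.null(m) && !all(m %in% c(0, 1)))
      stop("mask values must be 0/1")
  structure(list(
    images = images,
    labels = labels,
    masks = masks,
    source = rep_len(as.character(source), n),
    split = rep_len(as.character(split), n),
    parents = rep_len(as.character(parents), n)
  ), class = "image_dataset")
}

#' @export
length.image_dataset <- function(x) length(x$images)

#' @export
`[.image_dataset` <- function(x, i) {
  i <- seq_len(length(x))[i]
  structure(list(
    images = x$images[i],
    labels = x$labels[i, , drop = FALSE],
    masks = x$masks[i],
    source = x$source[i],
    split = x$split[i],
    parents = x$parents[i]
  ), class = "image_dataset")
}

#' Concatenate image datasets
#' @param ... image_dataset objects.
#' @return a single combined `image_dataset`.
#' @export
dataset_bind <- function(...) {
  parts <- list(...)
  structure(list(
    images = do.call(c, lapply(parts, `[[`, "images")),
    labels = do.call(rbind, lapply(parts, `[[`, "labels")),
    masks = do.call(c, lapply(parts, `[[`, "masks")),
    source = do.call(c, lapply(parts, `[[`, "source")),
    split = do.call(c, lapply(parts, `[[`, "split")),
    parents = do.call(c, lapply(parts, `[[`, "parents"))
  ), class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  n <- length(x)
  sz <- if (n) paste(dim(x$images[[1]]), collapse = "x") else "-"
  cat(sprintf("<image_dataset> %d samples, %s px\n", n, sz))
  dom <- dominant_class(x$labels)
  cat("  classes:", paste(sprintf("%s=%d", CLASSES, tabulate(dom, 3)),
                          collapse = " "), "\n")
  cat("  sources:", paste(names(table(x$source)), table(x$source),
                          sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Dominant (argmax) class index per label row, first maximum wins
#' @param labels n x 3 weight matrix.
#' @return integer vector in 1..3.
#' @export
dominant_class <- function(labels) {
  apply(matrix(labels, ncol = 3), 1, which.max)
}

#' @export
as.data.frame.image_dataset <- function(x, ...) {
  data.frame(split = x$split,
             w_normal = x$labels[, 1], w_benign = x$labels[, 2],
             w_malignant = x$labels[, 3],
             source = x$source, parents = x$parents,
             stringsAsFactors = FALSE)
}

#' Write a dataset to disk as PNGs plus a manifest CSV
#'
#' Images are written as 8-bit grayscale PNGs under `dir/images/`, masks
#' (values 0/255) under `dir/masks/`, and a manifest CSV with columns
#' `path,mask_path,split,w_normal,w_benign,w_malignant,source,parents` at
#' `dir/manifest.csv`. With `format = "rds"` the float arrays are stored
#' losslessly via R serialization instead of 8-bit PNG.
#'
#' @param ds an `image_dataset`.
#' @param dir output directory (created if missing).
#' @param format `"png"` (8-bit, portable) or `"rds"` (lossless floats).
#' @return the manifest data frame, invisibly.
#' @export
write_dataset <- function(ds, dir, format = c("png", "rds")) {
  format <- match.arg(format)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  n <- length(ds)
  ext <- format
  path <- file.path("images", sprintf("img_%05d.%s", seq_len(n), ext))
  mask_path <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (format == "png") {
      png::writePNG(ds$images[[i]], file.path(dir, path[i]))
    } else {
      saveRDS(ds$images[[i]], file.path(dir, path[i]))
    }
    if (!is.null(ds$masks[[i]])) {
      mask_path[i] <- file.path("masks", sprintf("mask_%05d.%s", i, ext))
      if (format == "png") {
        png::writePNG(ds$masks[[i]], file.path(dir, mask_path[i]))
      } else {
        saveRDS(ds$masks[[i]], file.path(dir, mask_path[i]))
      }
    }
  }
  man <- cbind(data.frame(path = path, mask_path = mask_path,
                          stringsAsFactors = FALSE),
               as.data.frame(ds))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `manifest.csv`.
#' @return an `image_dataset`.
#' @export
read_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  read_one <- function(p) {
    if (grepl("\\.rds$", p)) readRDS(file.path(dir, p))
    else {
      img <- png::readPNG(file.path(dir, p))
      if (length(dim(img)) == 3) img <- img[, , 1]
      img
    }
  }
  images <- lapply(man$path, read_one)
  masks <- lapply(seq_len(nrow(man)), function(i) {
    if (is.na(man$mask_path[i])) NULL else round(read_one(man$mask_path[i]))
  })
  image_dataset(images, as.matrix(man[, WEIGHT_COLS]), masks,
                source = man$source, split = man$split,
                parents = if ("parents" %in% names(man)) man$parents
                          else NA_character_)
}
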