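#' Dataset and probability-map file I/O
#'
#' Rasters are row-major, 0-based conceptually; in memory they are R
#' matrices indexed `[row, col]`, 1-based, and masks hold class indices
#' with 0 = background. On disk, images are 8-bit grayscale PNG (intensity
#' clamped to `[0, 1]`), masks are single-channel 8-bit PNG whose pixel
#' value IS the class index, and a bundle is tied together by a
#' `manifest.csv` with columns `image_path`, `mask_path` (empty for
#' unlabeled items) and `split` in `{labeled, unlabeled, test}`.
#'
#' @name coda-io
NULL

write_gray_png <- function(mat, path) {
  png::writePNG(pmin(pmax(mat, 0), 1), path)
}

write_mask_png <- function(mask, path) {
  if (max(mask) > 255L) stop("mask class index exceeds 8-bit range",
                             call. = FALSE)
  png::writePNG(mask / 255, path)
}

read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x
}

read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Write a dataset bundle to disk
#'
#' @param bundle a `dataset_bundle` from [generate_bundle()].
#' @param dir output directory; must be empty or absent unless
#'   `force = TRUE`.
#' @param force overwrite an existing non-empty directory.
#' @return the manifest path, invisibly.
#' @export
write_bundle <- function(bundle, dir, force = FALSE) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  if (dir.exists(dir) && length(dir(dir)) > 0L && !force)
    stop("output directory ", dir,
         " exists and is not empty (use force = TRUE to overwrite)",
         call. = FALSE)
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  rows <- list()
  idx <- 0L
  for (split in c("labeled", "unlabeled", "test")) {
    part <- bundle[[split]]
    for (i in seq_along(part$images)) {
      idx <- idx + 1L
      img_rel <- sprintf("images/%s_%03d.png", split, i)
      write_gray_png(part$images[[i]], file.path(dir, img_rel))
      mask_rel <- ""
      if (split != "unlabeled") {
        mask_rel <- sprintf("masks/%s_%03d.png", split, i)
        write_mask_png(part$masks[[i]], file.path(dir, mask_rel))
      }
      rows[[idx]] <- data.frame(image_path = img_rel,
                                mask_path = mask_rel, split = split,
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load a dataset bundle from a manifest
#'
#' @param manifest path to a `manifest.csv` (paths inside are resolved
#'   relative to its directory).
#' @return a list with `labeled`, `unlabeled`, `test` parts (`images`,
#'   `masks`).
#' @export
load_bundle <- function(manifest) {
  if (!file.exists(manifest))
    stop("manifest not readable: ", manifest, call. = FALSE)
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("image_path", "mask_path", "split")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  base <- dirname(manifest)
  out <- list()
  for (split in c("labeled", "unlabeled", "test")) {
    sub <- df[df$split == split, , drop = FALSE]
    images <- lapply(sub$image_path,
                     function(p) read_gray_png(file.path(base, p)))
    masks <- lapply(sub$mask_path, function(p)
      if (is.na(p) || p == "") NULL
      else read_mask_png(file.path(base, p)))
    out[[split]] <- list(images = images, masks = masks)
  }
  out
}

#' Serialize / deserialize a probability map as JSON
#'
#' @param probs a `prob_map`.
#' @param path file path.
#' @return `write_prob_map` returns `path` invisibly; `read_prob_map`
#'   returns a `prob_map`.
#' @export
write_prob_map <- function(probs, path) {
  check_prob_map(probs)
  jsonlite::write_json(list(values = probs$values, aligned = probs$aligned),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prob_map
#' @export
read_prob_map <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- doc$values
  if (is.list(v)) v <- do.call(rbind, v)
  prob_map(matrix(as.numeric(v), nrow = NROW(v)),
           aligned = isTRUE(doc$aligned))
}

#' Read / write a flat key-value run-configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are
#' rejected so that typos cannot silently fall back to defaults.
#'
#' @param path file path.
#' @return `read_run_config` returns a named list of character values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad))
    stop("malformed config line(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  stats::setNames(lapply(kv, function(m) trimws(m[3])),
                  vapply(kv, function(m) m[2], ""))
}

#' @rdname read_run_config
#' @param values named list of scalar values to persist.
#' @export
write_run_config <- function(values, path) {
  lines <- vapply(names(values), function(k) {
    v <- values[[k]]
    if (is.null(v)) v <- ""
    paste0(k, " = ", format(v, scientific = FALSE))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
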