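# File interchange: PNG stimuli, TSV similarity matrices and descriptor
# tables with JSON sidecars, TSV rating tables, NIfTI volumes and masks.

#' Write stimulus images as PNG files
#'
#' @param stimuli a `stimulus_set`.
#' @param dir output directory (created if missing).
#' @return invisibly, the file paths written (`scene_001.png`, ...).
#' @export
write_stimulus_pngs <- function(stimuli, dir) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("scene_%03d.png", seq_along(stimuli$images)))
  for (i in seq_along(stimuli$images)) {
    png::writePNG(stimuli$images[[i]], paths[i])
  }
  invisible(paths)
}

#' Read a PNG or JPEG-decoded array as an image
#'
#' @param path PNG file path.
#' @return numeric array in \[0, 1\] (matrix for grayscale, h x w x 3 for
#'   color; an alpha channel, if present, is dropped).
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  img
}

#' Write a similarity matrix as TSV with metadata header
#'
#' Metadata (`method`, `transform`, `n`, pair ordering) is stored as
#' `#key=value` comment lines above a tab-separated matrix.
#'
#' @param m a [similarity_matrix()].
#' @param path output file.
#' @export
write_similarity_tsv <- function(m, path) {
  stopifnot(inherits(m, "similarity_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#method=%s", attr(m, "method")),
               sprintf("#transform=%s", attr(m, "transform")),
               sprintf("#n=%d", nrow(m)),
               "#pair_order=row-major strict upper triangle, 1-based"), con)
  utils::write.table(unclass(m), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
}

#' Read a similarity matrix written by [write_similarity_tsv()]
#' @param path TSV file path.
#' @return a [similarity_matrix()].
#' @export
read_similarity_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  kv <- stats::setNames(vapply(meta, `[`, "", 2L),
                        vapply(meta, `[`, "", 1L))
  m <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)],
                                   sep = "\t"))
  dimnames(m) <- NULL
  similarity_matrix(m, method = kv[["method"]], transform = kv[["transform"]])
}

#' Write a descriptor matrix as TSV with a JSON configuration sidecar
#'
#' @param features scenes x dims matrix.
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @param config named list recording the extraction configuration (method,
#'   k, seed, stride, ...).
#' @export
write_descriptor_tsv <- function(features, path, config = list()) {
  utils::write.table(as.matrix(features), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(config, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

#' Read a descriptor matrix and its JSON sidecar
#' @param path TSV path written by [write_descriptor_tsv()].
#' @return matrix with attribute `config`.
#' @export
read_descriptor_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attr(m, "config") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  m
}

#' Write a rating table as TSV
#' @param ratings a [rating_table()].
#' @param path output file.
#' @export
write_rating_tsv <- function(ratings, path) {
  stopifnot(inherits(ratings, "rating_table"))
  utils::write.table(as.data.frame(ratings), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Read a rating table from TSV
#' @param path file written by [write_rating_tsv()].
#' @return a [rating_table()].
#' @export
read_rating_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  rating_table(df)
}

#' Read NIfTI volumes into a plain array
#'
#' @param path NIfTI file (3-D single volume or 4-D volume series).
#' @return numeric array.
#' @export
read_nifti_volumes <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim(arr))
}

#' Write an array as NIfTI
#'
#' @param volumes 3-D or 4-D numeric array.
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_nifti_volumes <- function(volumes, path) {
  RNifti::writeNifti(RNifti::asNifti(volumes), path)
  invisible(path)
}

#' Write the volume index sidecar for a trial series
#'
#' @param index data frame with columns `scene`, `repetition`, `timepoint`.
#' @param path output TSV.
#' @export
write_volume_index_tsv <- function(index, path) {
  utils::write.table(index, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' Read a volume index sidecar
#' @param path TSV with columns `scene`, `repetition`, `timepoint`.
#' @return data frame.
#' @export
read_volume_index_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE)
}
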