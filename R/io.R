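# Dataset IO in the DRIVE-style triplet layout:
#   <dir>/images/<id>.png   RGB fundus image
#   <dir>/labels/<id>.png   binary vessel label
#   <dir>/fov/<id>.png      binary FOV mask

#' Write samples as a DRIVE-style PNG triplet layout
#'
#' @param samples list of [FundusSample-class] objects.
#' @param dir output directory; `images/`, `labels/`, `fov/` are created.
#' @return `dir`, invisibly.
#' @export
writeFundusDataset <- function(samples, dir) {
  for (sub in c("images", "labels", "fov"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    id <- sampleId(s)
    png::writePNG(sampleImage(s) / 255,
                  file.path(dir, "images", paste0(id, ".png")))
    png::writePNG(vesselLabel(s),
                  file.path(dir, "labels", paste0(id, ".png")))
    png::writePNG(fovMask(s),
                  file.path(dir, "fov", paste0(id, ".png")))
  }
  invisible(dir)
}

#' Read a DRIVE-style dataset directory
#'
#' Ids are matched by file name across `images/`, `labels/` and `fov/`.
#' Labels and FOV masks are binarized at 0.5 (some datasets store them
#' with antialiased edges).
#'
#' @param dir dataset directory as written by [writeFundusDataset()].
#' @return list of [FundusSample-class] objects.
#' @export
readFundusDataset <- function(dir) {
  files <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$"))
  if (length(files) == 0) stop("no PNG images found under ", dir)
  lapply(files, function(f) {
    id <- sub("\\.png$", "", f)
    img <- png::readPNG(file.path(dir, "images", f))
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img <- round(img[, , 1:3, drop = FALSE] * 255)
    readMask <- function(sub) {
      m <- png::readPNG(file.path(dir, sub, f))
      if (length(dim(m)) == 3) m <- m[, , 1]
      (m >= 0.5) * 1
    }
    lab <- readMask("labels"); fov <- readMask("fov")
    fundusSample(img, lab * fov, fov, id)
  })
}
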