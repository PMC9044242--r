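#' FundusSample: one fundus image with its label and field of view
#'
#' Container for a single dataset item in the DRIVE/STARE/CHASE layout: an
#' RGB fundus image, a pixel-level binary vessel label, and a binary
#' field-of-view (FOV) mask delimiting the circular retinal area. All
#' segmentation metrics in this package are restricted to FOV pixels.
#'
#' @slot image numeric array `H x W x 3`, intensities in `[0, 255]`.
#' @slot label numeric matrix `H x W` with values in `{0, 1}` (1 = vessel).
#' @slot fov numeric matrix `H x W` with values in `{0, 1}` (1 = inside FOV).
#' @slot sampleId character scalar identifier.
#'
#' @details Validity requires matching spatial dimensions, binary label and
#'   FOV, and no vessel pixel outside the FOV.
#'
#' @examples
#' cfg <- synthConfig(height = 96, width = 96, seed = 1)
#' s <- renderFundus(generateVesselTree(cfg), cfg)
#' s
#' dim(sampleImage(s))
#' @export
setClass("FundusSample",
  representation(
    image = "array",
    label = "matrix",
    fov = "matrix",
    sampleId = "character"
  )
)

setValidity("FundusSample", function(object) {
  msg <- character()
  di <- dim(object@image)
  if (length(di) != 3 || di[3] != 3)
    msg <- c(msg, "image must be an H x W x 3 array")
  if (!all(dim(object@label) == di[1:2]))
    msg <- c(msg, "label dimensions must match image")
  if (!all(dim(object@fov) == di[1:2]))
    msg <- c(msg, "fov dimensions must match image")
  if (!isBinaryMask(object@label))
    msg <- c(msg, "label must be binary {0,1}")
  if (!isBinaryMask(object@fov))
    msg <- c(msg, "fov must be binary {0,1}")
  if (isBinaryMask(object@label) && isBinaryMask(object@fov) &&
      any(object@label == 1 & object@fov == 0))
    msg <- c(msg, "vessel pixels must lie inside the FOV")
  if (length(object@sampleId) != 1)
    msg <- c(msg, "sampleId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a FundusSample
#'
#' @param image numeric `H x W x 3` array, intensities in `[0, 255]`.
#' @param label binary `H x W` matrix (1 = vessel).
#' @param fov binary `H x W` matrix (1 = inside field of view).
#' @param sampleId character identifier.
#' @return A validated [FundusSample-class] object.
#' @export
fundusSample <- function(image, label, fov, sampleId = "sample") {
  new("FundusSample",
      image = image, label = label, fov = fov,
      sampleId = as.character(sampleId))
}

#' @describeIn FundusSample-class the RGB image array
#' @param x,object a `FundusSample`
#' @export
sampleImage <- function(x) x@image

#' @describeIn FundusSample-class the binary vessel label matrix
#' @export
vesselLabel <- function(x) x@label

#' @describeIn FundusSample-class the binary field-of-view matrix
#' @export
fovMask <- function(x) x@fov

#' @describeIn FundusSample-class the sample identifier
#' @export
sampleId <- function(x) x@sampleId

setMethod("show", "FundusSample", function(object) {
  d <- dim(object@image)
  cat("FundusSample \"", object@sampleId, "\": ", d[1], " x ", d[2],
      " px, vessel fraction (FOV) ",
      sprintf("%.3f", sum(object@label) / max(1, sum(object@fov))),
      "\n", sep = "")
})

#' ConfusionCounts: pooled FOV-restricted confusion matrix
#'
#' True/false positive/negative pixel counts pooled over one or more test
#' images, restricted to field-of-view pixels. Feeds all threshold-level
#' metrics (F1, Se, Sp, Acc, G-mean, MCC).
#'
#' @slot tp,tn,fp,fn non-negative numeric counts.
#' @examples
#' confusionFromCounts(tp = 10, tn = 80, fp = 5, fn = 5)
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", tn = "numeric",
                 fp = "numeric", fn = "numeric")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (length(v) != 4 || any(!is.finite(v)) || any(v < 0))
    "tp, tn, fp, fn must be single non-negative finite numbers"
  else TRUE
})

#' Construct ConfusionCounts directly from the four counts
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return A [ConfusionCounts-class] object.
#' @export
confusionFromCounts <- function(tp, tn, fp, fn) {
  new("ConfusionCounts", tp = as.numeric(tp), tn = as.numeric(tn),
      fp = as.numeric(fp), fn = as.numeric(fn))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts (FOV-pooled): TP=", object@tp, " TN=", object@tn,
      " FP=", object@fp, " FN=", object@fn, "\n", sep = "")
})

#' MetricsReport: the full segmentation metric suite
#'
#' Holds accuracy, sensitivity (recall on vessels), specificity, F1, G-mean
#' (geometric mean of Se and Sp), Matthews correlation coefficient, AUC and
#' the gray-level binarization threshold in `[0, 255]`. Slots not yet
#' computed (e.g. `auc` before ROC analysis) are `NA`.
#'
#' @slot acc,se,sp,f1,gmean,mcc,auc numeric scalars.
#' @slot threshold integer gray-level threshold, or `NA`.
#' @export
setClass("MetricsReport",
  representation(acc = "numeric", se = "numeric", sp = "numeric",
                 f1 = "numeric", gmean = "numeric", mcc = "numeric",
                 auc = "numeric", threshold = "numeric")
)

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  v <- c(Acc = object@acc, Se = object@se, Sp = object@sp, F1 = object@f1,
         G = object@gmean, MCC = object@mcc, AUC = object@auc)
  for (n in names(v))
    cat(sprintf("  %-4s %s\n", n,
                ifelse(is.na(v[[n]]), "NA", sprintf("%.4f", v[[n]]))))
  if (!is.na(object@threshold))
    cat("  threshold", object@threshold, "\n")
})

#' Convert a MetricsReport to a named list
#' @param report a [MetricsReport-class]
#' @return named list of the metric values.
#' @export
metricsAsList <- function(report) {
  list(acc = report@acc, se = report@se, sp = report@sp, f1 = report@f1,
       gmean = report@gmean, mcc = report@mcc, auc = report@auc,
       threshold = report@threshold)
}
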