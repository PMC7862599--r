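#' @import methods
#' @importFrom stats median quantile mad rnorm runif rpois rbeta qbeta rmultinom
#'   optim cor pt lm coef sd dist setNames aggregate pnorm
#' @importFrom utils combn head
NULL

#' Multichannel microscopy field
#'
#' An \code{ImageField} holds the co-registered 2-D intensity channels of one
#' microscope field together with its physical pixel size. Channels are plain
#' numeric matrices in photon-count-like units; all channels share one shape.
#' Physical coordinates follow the 0-based pixel-center convention:
#' a pixel at matrix position \code{[r, c]} sits at
#' \code{x = (c - 1) * pixelSize}, \code{y = (r - 1) * pixelSize} micrometres.
#'
#' @slot channels named list of numeric matrices, one per channel.
#' @slot pixelSize pixel edge length in micrometres per pixel.
#' @slot fieldId character identifier of the field.
#'
#' @export
setClass("ImageField",
  representation(channels = "list", pixelSize = "numeric", fieldId = "character"),
  prototype(channels = list(), pixelSize = 0.1, fieldId = "field")
)

setValidity("ImageField", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("channels must have unique non-empty names")
  if (!all(vapply(ch, function(m) is.matrix(m) && is.numeric(m), logical(1))))
    return("every channel must be a numeric matrix")
  dims <- vapply(ch, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all channels must share the same dimensions")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number (um/pixel)")
  TRUE
})

#' Construct an ImageField
#'
#' @param channels named list of numeric matrices.
#' @param pixelSize pixel size in micrometres per pixel.
#' @param fieldId field identifier.
#' @return an \linkS4class{ImageField}.
#' @examples
#' f <- ImageField(list(DAPI = matrix(0, 8, 8)), pixelSize = 0.1)
#' channelNames(f)
#' @export
ImageField <- function(channels, pixelSize = 0.1, fieldId = "field") {
  new("ImageField", channels = channels, pixelSize = as.numeric(pixelSize),
      fieldId = as.character(fieldId))
}

#' @describeIn ImageField names of the channels.
#' @param x an \code{ImageField}.
#' @export
channelNames <- function(x) names(x@channels)

#' @describeIn ImageField extract one channel as a numeric matrix.
#' @param name channel name.
#' @export
getChannel <- function(x, name) {
  if (!name %in% names(x@channels))
    stop("channel '", name, "' not present; available: ",
         paste(names(x@channels), collapse = ", "))
  x@channels[[name]]
}

#' @describeIn ImageField pixel size in micrometres per pixel.
#' @export
pixelSize <- function(x) x@pixelSize

setMethod("show", "ImageField", function(object) {
  d <- dim(object@channels[[1]])
  cat("ImageField '", object@fieldId, "': ", d[1], " x ", d[2],
      " px (", round(d[1] * object@pixelSize, 1), " x ",
      round(d[2] * object@pixelSize, 1), " um), ",
      length(object@channels), " channel(s): ",
      paste(names(object@channels), collapse = ", "), "\n", sep = "")
})

setMethod("dim", "ImageField", function(x) dim(x@channels[[1]]))

#' ROC analysis result
#'
#' Holds the area under the ROC curve with its DeLong confidence interval and
#' the Youden-optimal operating point for a binary lesion contrast scored by
#' the abnormal 53BP1 fraction (or any monotone score).
#'
#' @slot auc area under the ROC curve, in [0, 1].
#' @slot ciLo,ciHi DeLong 95\% confidence limits, clipped to [0, 1].
#' @slot cutoff Youden-optimal threshold (predict positive when score >= cutoff).
#' @slot sensitivity,specificity percent, at the cutoff.
#' @slot youden Youden's J = sensitivity/100 + specificity/100 - 1.
#' @export
setClass("RocResult",
  representation(auc = "numeric", ciLo = "numeric", ciHi = "numeric",
                 cutoff = "numeric", sensitivity = "numeric",
                 specificity = "numeric", youden = "numeric"))

setValidity("RocResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  if (object@ciLo > object@auc + 1e-12 || object@ciHi < object@auc - 1e-12)
    return("confidence interval must bracket the AUC")
  j <- object@sensitivity / 100 + object@specificity / 100 - 1
  if (abs(j - object@youden) > 1e-8)
    return("youden must equal sensitivity/100 + specificity/100 - 1")
  TRUE
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf(
    "ROC: AUC %.3f (95%% CI %.3f-%.3f); Youden cutoff %.1f%% -> sens %.1f%%, spec %.1f%% (J = %.2f)\n",
    object@auc, object@ciLo, object@ciHi, object@cutoff,
    object@sensitivity, object@specificity, object@youden))
})

#' @describeIn RocResult area under the curve.
#' @param x a \code{RocResult}.
#' @export
auc <- function(x) x@auc

#' @describeIn RocResult Youden-optimal cutoff.
#' @export
cutoff <- function(x) x@cutoff

# pattern classes, in canonical order; the last three are "abnormal"
PATTERN_CLASSES <- c("stable", "lowDDR", "highDDR", "largeFocus", "diffuse")
ABNORMAL_CLASSES <- c("highDDR", "largeFocus", "diffuse")

#' Pattern class levels
#'
#' The five per-nucleus 53BP1 expression patterns, in canonical order.
#' \code{highDDR}, \code{largeFocus} and \code{diffuse} count as abnormal.
#' @return character vector of length 5.
#' @export
patternClasses <- function() PATTERN_CLASSES

#' Is a pattern class abnormal?
#' @param class character vector of pattern class names.
#' @return logical vector.
#' @export
isAbnormal <- function(class) class %in% ABNORMAL_CLASSES
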