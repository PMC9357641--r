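#' @describeIn MPMStack-class compact display
#' @param object an \code{MPMStack}.
#' @export
setMethod("show", "MPMStack", function(object) {
  g <- object@geometry
  cat(sprintf(
    "MPMStack %s (patient %s, group %s, %s tissue)\n", object@imageId,
    object@patientId, object@group, object@tissueLabel))
  cat(sprintf("  %d x %d px (%.2f um/px), %d channel(s), %d plane(s)\n",
              g@widthPx, g@heightPx, g@pixelSizeUm, g@nChannels, g@nPlanes))
  invisible(NULL)
})

#' @describeIn TileSet-class compact display
#' @param object a \code{TileSet}.
#' @export
setMethod("show", "TileSet", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("TileSet: %d tile(s) of %d x %d x %d\n", d[4], d[1], d[2], d[3]))
  extra <- intersect(c("is_blank", "truth_label", "score", "split"),
                     names(object@info))
  if (length(extra))
    cat("  manifest columns:", paste(names(object@info), collapse = ", "),
        "\n")
  invisible(NULL)
})

#' @describeIn ConfusionMatrix-class compact display
#' @param object a \code{ConfusionMatrix}.
#' @export
setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (tiles)\n")
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2,
              dimnames = list(predicted = c("positive", "negative"),
                              actual = c("positive", "negative")))
  print(m)
  mm <- matrixMetrics(object)
  cat(sprintf("accuracy %.3f  precision %.3f  recall %.3f  F %.3f\n",
              mm["accuracy"], mm["precision"], mm["recall"],
              mm["f_measure"]))
  invisible(NULL)
})

#' @describeIn TileClassifierModel-class compact display
#' @param object a \code{TileClassifierModel}.
#' @export
setMethod("show", "TileClassifierModel", function(object) {
  cat(sprintf("TileClassifierModel (%s, input %d px)\n",
              object@architecture, object@inputSide))
  if (nrow(object@history))
    cat(sprintf("  trained %d epoch(s); best validation accuracy %.4f\n",
                max(object@history$epoch), object@validationScore))
  else cat("  untrained (random initialization)\n")
  invisible(NULL)
})
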