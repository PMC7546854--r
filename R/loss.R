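#' Block-wise normalized cross-correlation loss
#'
#' Minus the sum over regions of the cosine similarity between paired deep
#' feature vectors:
#' \deqn{L = -\sum_{i=1}^{N} \frac{\langle f_{w,i}, f_{a,i}\rangle}
#'   {\sqrt{\langle f_{w,i}, f_{w,i}\rangle \langle f_{a,i}, f_{a,i}\rangle}}}
#' The loss lies in [-N, N], reaching -N exactly when every paired block is
#' positively proportional, and is invariant to positive rescaling of either
#' side's features.
#'
#' @param warpedFeats,fixedFeats paired \code{\linkS4class{FeatureBlocks}}
#'   with matching region count and feature dimension
#' @param dropDegenerate if TRUE, blocks whose feature vector has zero norm
#'   on either side (a constant region that collapsed under the feature
#'   maps) are dropped from the sum and the effective N is attached as an
#'   attribute; if FALSE (default) such blocks raise an error
#' @return scalar loss with attribute \code{effectiveN}
#' @export
blockNCCLoss <- function(warpedFeats, fixedFeats, dropDegenerate = FALSE) {
  w <- if (is(warpedFeats, "FeatureBlocks")) warpedFeats@blocks else as.matrix(warpedFeats)
  a <- if (is(fixedFeats, "FeatureBlocks")) fixedFeats@blocks else as.matrix(fixedFeats)
  if (!all(dim(w) == dim(a)))
    stop("paired feature blocks must share region count and dimension")
  nw <- sqrt(colSums(w^2))
  na <- sqrt(colSums(a^2))
  bad <- nw < 1e-12 | na < 1e-12
  if (any(bad)) {
    if (!dropDegenerate)
      stop("degenerate feature block: ", sum(bad), " of ", ncol(w),
           " regions have zero-norm features (constant region); ",
           "set dropDegenerate = TRUE to drop them")
    w <- w[, !bad, drop = FALSE]; a <- a[, !bad, drop = FALSE]
    nw <- nw[!bad]; na <- na[!bad]
    if (ncol(w) == 0L) stop("all feature blocks are degenerate")
  }
  loss <- -sum(colSums(w * a) / (nw * na))
  attr(loss, "effectiveN") <- length(nw)
  loss
}
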