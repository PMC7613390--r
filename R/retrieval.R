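#' Multiband green-LAI retrieval
#'
#' Per-sensor GPR retrieval models mapping surface reflectance spectra to
#' green LAI with predictive uncertainty. Two band dialects are supported:
#' a 10-band Sentinel-2-like set and a 6-band Landsat-8-like set; a 10-band
#' training table can be resampled to the 6 shared bands so one campaign
#' dataset serves both sensors.
#'
#' @name lai-retrieval
NULL

#' Train a green-LAI retrieval model
#'
#' @param pairs list with \code{reflectance} (n x D matrix) and \code{lai},
#'   as produced by \code{\link{spectraLaiPairs}}
#' @param dialect band dialect the model is trained for
#' @param seed seed passed to \code{\link{fitGPR}}
#' @return a \code{GPRModel} with attributes \code{dialect} and
#'   \code{band_names}
#' @export
trainLaiModel <- function(pairs, dialect = pairs$dialect, seed = 1) {
  bs <- bandSet(dialect)
  D <- ncol(pairs$reflectance)
  if (D != length(bs$names))
    stop("reflectance width ", D, " does not match dialect '", dialect,
         "' (", length(bs$names), " bands)")
  m <- fitGPR(pairs$reflectance, pairs$lai, seed = seed)
  attr(m, "dialect") <- dialect
  attr(m, "band_names") <- bs$names
  m
}

#' Resample a 10-band training table to the 6-band dialect
#'
#' Selects the six columns whose center wavelengths match the 6-band sensor
#' (bands 2, 3, 4, 8A, 11, 12 of the 10-band set).
#'
#' @param pairs a 10-band pairs list
#' @return a 6-band pairs list suitable for \code{\link{trainLaiModel}}
#' @export
resamplePairsToL8 <- function(pairs) {
  if (pairs$dialect != "S2-10band") stop("pairs are not in the 10-band dialect")
  R <- pairs$reflectance[, .S2_TO_L8, drop = FALSE]
  colnames(R) <- .BAND_SETS[["L8-6band"]]$names
  list(reflectance = R, lai = pairs$lai, dialect = "L8-6band")
}

#' Per-band relevance of a fitted retrieval model
#'
#' The inverse lengthscale 1/sigma_b of the ARD kernel: the shorter the
#' lengthscale of a band, the more the prediction responds to it.
#'
#' @param model a fitted \code{GPRModel} (any D >= 1)
#' @return named non-negative numeric vector of relevances
#' @export
bandRelevance <- function(model) {
  r <- 1 / model$theta$lengthscales
  nm <- attr(model, "band_names")
  if (!is.null(nm)) names(r) <- nm
  r
}

#' Retrieve LAI from reflectance data
#'
#' Applies a trained retrieval model row-wise to a reflectance table or
#' pixel-wise to a (rows, cols, bands) array. NA spectra propagate to NA
#' outputs; negative predicted LAI is clipped to 0 and the clip count is
#' recorded.
#'
#' @param model a model from \code{\link{trainLaiModel}}
#' @param x n x D reflectance matrix, or a 3-d array (rows, cols, D)
#' @return list of class \code{RetrievalResult}: \code{lai} and \code{lai_sd}
#'   shaped like the input's spatial part, plus \code{n_clipped}
#' @export
retrieveLai <- function(model, x) {
  D <- ncol(model$X)
  isArray <- is.array(x) && length(dim(x)) == 3
  if (isArray) {
    dd <- dim(x)
    if (dd[3] != D) stop("stack has ", dd[3], " bands; model dialect '",
                         attr(model, "dialect"), "' expects ", D)
    X <- matrix(x, nrow = dd[1] * dd[2], ncol = dd[3])
  } else {
    X <- as.matrix(x)
    if (ncol(X) != D) stop("input has ", ncol(X), " bands; model dialect '",
                           attr(model, "dialect"), "' expects ", D)
  }
  ok <- stats::complete.cases(X)
  lai <- rep(NA_real_, nrow(X)); sdv <- rep(NA_real_, nrow(X))
  if (any(ok)) {
    pr <- gprPredict(model, X[ok, , drop = FALSE])
    lai[ok] <- pr$mean
    sdv[ok] <- sqrt(pr$variance)
  }
  nClipped <- sum(lai < 0, na.rm = TRUE)
  lai[!is.na(lai) & lai < 0] <- 0
  if (isArray) {
    lai <- matrix(lai, dd[1], dd[2]); sdv <- matrix(sdv, dd[1], dd[2])
  }
  structure(list(lai = lai, lai_sd = sdv, n_clipped = nClipped,
                 dialect = attr(model, "dialect")),
            class = "RetrievalResult")
}
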