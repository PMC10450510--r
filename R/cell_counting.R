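#' Cell-counting pipeline configuration
#'
#' Parameters of the automated stained-cell-body counter. The pipeline
#' names fixed operations (denoise, adaptive threshold, blur, opening,
#' dilation, outline extraction, +/- 2 SD size filter); every numeric knob
#' lives here.
#'
#' @param resize linear resize factor applied before processing.
#' @param denoiseSigma Gaussian denoise SD (px, after resize).
#' @param threshBlock adaptive-threshold box half-width (px); the local mean
#'   window is (2*threshBlock+1) squared.
#' @param threshOffset adaptive-threshold offset: a pixel is foreground when
#'   darker than its local mean by more than this; must exceed the
#'   background texture amplitude while staying well below the stain
#'   contrast.
#' @param blurSigma post-threshold Gaussian blur SD (px).
#' @param morphSize opening/dilation structuring-element size (px, odd).
#' @param morphIter dilation iterations.
#' @param sizeSd size filter half-width: keep contours with area within
#'   mean +/- sizeSd SD of the per-image contour-area distribution.
#' @param thickness_um section thickness for the volume conversion (um).
#' @return list of class \code{CountingConfig}.
#' @export
countingConfig <- function(resize = 0.5, denoiseSigma = 1.5,
                           threshBlock = 25, threshOffset = 0.15,
                           blurSigma = 1, morphSize = 3, morphIter = 1,
                           sizeSd = 2, thickness_um = 60) {
    stopifnot(resize > 0, morphSize %% 2 == 1, thickness_um > 0)
    cfg <- as.list(environment())
    class(cfg) <- "CountingConfig"
    cfg
}

#' Select the highest-contrast channel of an RGB image
#'
#' Returns the channel with maximal intensity standard deviation; ties go to
#' the first channel in R, G, B order. Single-channel input is returned
#' unchanged.
#'
#' @param img numeric array h x w x 3 (or h x w matrix).
#' @return h x w matrix.
#' @export
selectChannel <- function(img) {
    if (is.matrix(img) || length(dim(img)) == 2) return(as.matrix(img))
    stopifnot(length(dim(img)) == 3)
    sds <- apply(img, 3, stats::sd)
    img[, , which.max(sds)]
}

#' Count stained cell bodies in a grayscale micrograph
#'
#' Pipeline: Gaussian denoise, adaptive (local-mean) threshold of dark
#' objects, Gaussian blur, morphological opening then dilation, connected
#' component outlines, and a size filter keeping contours whose area lies
#' within mean +/- 2 SD of the per-image contour-area distribution.
#' Deterministic for fixed config.
#'
#' @param gray numeric matrix in [0, 1]; cells are dark on a bright
#'   background.
#' @param cfg a \code{\link{countingConfig}}.
#' @return list: n_cells, contours (list of x/y outline matrices in
#'   processed-image px), areas (kept contour areas, px^2), labels (the
#'   filtered label matrix).
#' @export
countCells <- function(gray, cfg = countingConfig()) {
    stopifnot(is.matrix(gray), all(dim(gray) > 0))
    img <- EBImage::Image(t(gray))        # EBImage is x,y ordered
    if (cfg$resize != 1)
        img <- EBImage::resize(img, w = max(1, round(dim(img)[1] * cfg$resize)))
    if (cfg$denoiseSigma > 0)
        img <- EBImage::gblur(img, sigma = cfg$denoiseSigma)
    ## dark cells -> bright foreground, then local-mean adaptive threshold
    inv <- 1 - img
    if (diff(range(inv)) > 0)
        inv <- EBImage::normalize(inv, ft = c(0, 1))
    bw <- EBImage::thresh(inv, w = cfg$threshBlock, h = cfg$threshBlock,
                          offset = cfg$threshOffset)
    if (cfg$blurSigma > 0)
        bw <- EBImage::gblur(bw, sigma = cfg$blurSigma) > 0.5
    kern <- EBImage::makeBrush(cfg$morphSize, shape = "box")
    bw <- EBImage::opening(bw, kern)
    for (i in seq_len(cfg$morphIter)) bw <- EBImage::dilate(bw, kern)
    lab <- EBImage::bwlabel(bw)
    nObj <- max(lab)
    if (nObj == 0)
        return(list(n_cells = 0L, contours = list(), areas = numeric(),
                    labels = lab))
    areas <- as.numeric(table(factor(as.integer(lab)[as.integer(lab) > 0],
                                     levels = seq_len(nObj))))
    keep <- if (length(areas) > 1) {
        m <- mean(areas); s <- stats::sd(areas)
        which(areas >= m - cfg$sizeSd * s & areas <= m + cfg$sizeSd * s)
    } else seq_along(areas)
    drop <- setdiff(seq_len(nObj), keep)
    if (length(drop)) lab <- EBImage::rmObjects(lab, drop, reenumerate = TRUE)
    contours <- EBImage::ocontour(lab)
    list(n_cells = length(keep), contours = contours,
         areas = areas[keep], labels = lab)
}

#' Volumetric cell density
#'
#' Count over tissue area times section thickness, scaled to a reporting
#' volume. Supplying the area in physical units makes the density invariant
#' to image resizing.
#'
#' @param n cell count.
#' @param tissue_area_um2 net tissue area of the field (um^2).
#' @param thickness_um section thickness (um).
#' @param per_um3 reporting volume (default 1e6 um^3).
#' @return cells per \code{per_um3} um^3.
#' @export
cellDensity <- function(n, tissue_area_um2, thickness_um = 60,
                        per_um3 = 1e6) {
    assertNum(tissue_area_um2, "tissue_area_um2", lower = 1e-12)
    assertNum(thickness_um, "thickness_um", lower = 1e-12)
    n / (tissue_area_um2 * thickness_um) * per_um3
}
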