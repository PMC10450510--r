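#' Render a synthetic stained-cell micrograph with known centroids
#'
#' Places \code{n} dark elliptical blobs (immunostained cell bodies) on a
#' bright, low-frequency textured background with additive pixel noise.
#' Blob radii are drawn from a Normal truncated at +/- 2 SD; a minimum
#' centroid separation is enforced by rejection sampling so ground-truth
#' objects stay resolvable.
#'
#' @param n number of cells.
#' @param cfg a \code{\link{simConfig}} (fields \code{imageSize},
#'   \code{cellRadius_px}, \code{cellRadiusSd_px}, \code{minSeparation_px},
#'   \code{bgLevel}, \code{cellLevel}, \code{textureSd},
#'   \code{textureScale_px}, \code{imageNoiseSd}).
#' @param seed RNG seed; defaults to \code{cfg$seed + 3}.
#' @return list with \code{image} (numeric matrix in [0, 1], rows = y) and
#'   \code{centroids} (data.frame x, y, radius in px).
#' @export
renderCellsImage <- function(n, cfg = simConfig(), seed = cfg$seed + 3L) {
    w <- cfg$imageSize[1]; h <- cfg$imageSize[2]
    stopifnot(w > 0, h > 0, n >= 0)
    sep <- cfg$minSeparation_px
    pad <- cfg$cellRadius_px * 2 + 2
    ## capacity guard: a grid at the separation distance bounds what can fit
    if (n > floor((w - 2 * pad) / sep + 1) * floor((h - 2 * pad) / sep + 1))
        stop("too many cells for the image area at the configured separation")
    withSeed(seed, {
        ## low-frequency texture: blurred white noise on top of the bright bg
        tex <- matrix(stats::rnorm(w * h), h, w)
        if (cfg$textureSd > 0) {
            k <- makeGaussianKernel(cfg$textureScale_px)
            tex <- as.matrix(EBImage::filter2(tex, k))
            tex <- tex / stats::sd(tex) * cfg$textureSd
        } else tex <- 0 * tex
        img <- cfg$bgLevel + tex

        cx <- numeric(0); cy <- numeric(0); rad <- numeric(0)
        tries <- 0L
        while (length(cx) < n) {
            x <- stats::runif(1, pad, w - pad)
            y <- stats::runif(1, pad, h - pad)
            if (!length(cx) || all((cx - x)^2 + (cy - y)^2 >= sep^2)) {
                r <- cfg$cellRadius_px +
                    pmax(-2, pmin(2, stats::rnorm(1))) * cfg$cellRadiusSd_px
                cx <- c(cx, x); cy <- c(cy, y); rad <- c(rad, max(2, r))
            }
            tries <- tries + 1L
            if (tries > 200L * max(1L, n))
                stop("could not place all cells at the configured separation")
        }
        ## dark ellipses, slightly anisotropic, random orientation
        xs <- matrix(rep(seq_len(w), each = h), h, w)
        ys <- matrix(rep(seq_len(h), times = w), h, w)
        for (i in seq_len(length(cx))) {
            th <- stats::runif(1, 0, pi)
            a <- rad[i] * stats::runif(1, 0.85, 1.15)
            b <- rad[i] * stats::runif(1, 0.7, 1)
            dx <- xs - cx[i]; dy <- ys - cy[i]
            u <- dx * cos(th) + dy * sin(th)
            v <- -dx * sin(th) + dy * cos(th)
            inside <- (u / a)^2 + (v / b)^2 <= 1
            img[inside] <- cfg$cellLevel
        }
        if (cfg$imageNoiseSd > 0)
            img <- img + matrix(stats::rnorm(w * h, 0, cfg$imageNoiseSd), h, w)
        img[img < 0] <- 0
        img[img > 1] <- 1
        list(image = img,
             centroids = data.frame(x = cx, y = cy, radius = rad))
    })
}

makeGaussianKernel <- function(sigma) {
    s <- max(1, sigma)
    r <- ceiling(3 * s)
    x <- seq(-r, r)
    k <- outer(x, x, function(i, j) exp(-(i^2 + j^2) / (2 * s^2)))
    k / sum(k)
}
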