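# Shared numeric helpers. Voxel i (1-based) along an axis with spacing w has
# its centre at (i - 0.5) * w; all physical quantities are in micrometres.

#' Voxel volume of a stack or label volume
#' @param x a `ZStack` or `LabelVolume`
#' @return voxel volume in cubic micrometres
#' @export
voxel_volume <- function(x) prod(x$voxel_size)

# run RNG-dependent code under a fixed seed without disturbing the caller's
# RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Global Otsu threshold of an intensity array
#'
#' Maximises between-class variance on a 256-bin histogram of the full 3D
#' array (not per plane), the standard automatic foreground/background split
#' for well-separated stain and background modes.
#'
#' @param x numeric array or vector of intensities
#' @param n_bins number of histogram bins
#' @return threshold value; voxels strictly above it are foreground
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  b <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(x, b, rightmost.closed = TRUE),
                           nbins = n_bins))
  mids <- (b[-1] + b[-length(b)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[n_bins]
  mt <- m[n_bins]
  w0 <- w[-n_bins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[-n_bins] / w0
  mu1 <- (mt - m[-n_bins]) / w1
  bc <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  k <- which.max(bc)
  (mids[k] + mids[k + 1]) / 2
}

# mode of a binned intensity histogram: midpoint of the fullest bin
histogram_mode <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  b <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, b, rightmost.closed = TRUE), nbins = n_bins)
  k <- which.max(h)
  (b[k] + b[k + 1]) / 2
}

# lognormal with unit mean and given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# physical coordinates (um) of voxel array indices (matrix with cols z,y,x)
voxel_centers_um <- function(idx, voxel_size) {
  sweep(idx - 0.5, 2, voxel_size, `*`)
}

# centroids (um) per label from a label array; returns matrix with rownames =
# label ids and columns z,y,x
label_centroids_um <- function(labels, voxel_size) {
  dm <- dim(labels)
  nz <- which(labels > 0)
  if (length(nz) == 0)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("z", "y", "x"))))
  lab <- labels[nz]
  z <- ((nz - 1) %% dm[1]) + 1
  r <- (nz - 1) %/% dm[1]
  y <- (r %% dm[2]) + 1
  x <- (r %/% dm[2]) + 1
  cz <- rowsum(z - 0.5, lab)
  cy <- rowsum(y - 0.5, lab)
  cx <- rowsum(x - 0.5, lab)
  cnt <- rowsum(rep(1, length(lab)), lab)
  out <- cbind(cz / cnt * voxel_size[1],
               cy / cnt * voxel_size[2],
               cx / cnt * voxel_size[3])
  dimnames(out) <- list(rownames(cnt), c("z", "y", "x"))
  out
}

# label ids touching any face of the array
labels_touching_border <- function(labels) {
  dm <- dim(labels)
  ids <- c(labels[1, , ], labels[dm[1], , ],
           labels[, 1, ], labels[, dm[2], ],
           labels[, , 1], labels[, , dm[3]])
  sort(unique(ids[ids > 0]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(name, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(class = c(name, "cardiomorph_error", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}
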