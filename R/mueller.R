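#' Construct a Mueller-matrix image
#'
#' A `mueller_image` stores one 4x4 real Mueller matrix per pixel in
#' column-major vectorized form (a 16 x (H*W) matrix), along with the image
#' dimensions, pixel size, acquisition geometry and a validity mask.
#'
#' @param vec 16 x N numeric matrix; column j is `c(M_j)` for pixel j
#'   (pixels in column-major image order).
#' @param dim Integer vector `c(H, W)`.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param geometry `"transmission"` or `"reflection"`.
#' @param valid_mask Logical H x W matrix; defaults to pixels with positive
#'   unpolarized transmittance `m[1,1]`.
#' @return An object of class `mueller_image`.
#' @export
mueller_image <- function(vec, dim, pixel_size_um = 17,
                          geometry = c("transmission", "reflection"),
                          valid_mask = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(is.matrix(vec), nrow(vec) == 16L, ncol(vec) == prod(dim))
  if (is.null(valid_mask)) valid_mask <- matrix(vec[1L, ] > 0, dim[1], dim[2])
  structure(
    list(vec = vec, dim = as.integer(dim), pixel_size_um = pixel_size_um,
         geometry = geometry, valid_mask = valid_mask),
    class = "mueller_image"
  )
}

#' @export
print.mueller_image <- function(x, ...) {
  cat("Mueller-matrix image:", x$dim[1], "x", x$dim[2], "pixels,",
      x$pixel_size_um, "um/px,", x$geometry, "geometry\n")
  cat("  valid pixels:", sum(x$valid_mask), "/", prod(x$dim), "\n")
  invisible(x)
}

#' Extract the Mueller matrix at one pixel
#'
#' @param img A [mueller_image()].
#' @param i,j Row and column pixel indices.
#' @return 4x4 numeric matrix.
#' @export
mueller_at <- function(img, i, j) {
  matrix(img$vec[, (j - 1L) * img$dim[1] + i], 4L, 4L)
}

#' Build a Mueller image of pure isotropic depolarizers
#'
#' Each pixel with depolarization `delta` becomes `diag(1, 1-delta, 1-delta,
#' 1-delta)`; `NA` pixels are marked invalid.
#'
#' @param delta H x W matrix of per-pixel depolarization in `[0, 1]` (`NA`
#'   for background/invalid pixels).
#' @inheritParams mueller_image
#' @return A [mueller_image()].
#' @export
mueller_from_delta <- function(delta, pixel_size_um = 17,
                               geometry = "transmission") {
  d <- dim(delta)
  n <- prod(d)
  vec <- matrix(0, 16L, n)
  a <- as.numeric(1 - delta)
  a[is.na(a)] <- 0
  vec[1L, ] <- ifelse(is.na(as.numeric(delta)), 0, 1)
  vec[6L, ] <- vec[11L, ] <- vec[16L, ] <- a * vec[1L, ]
  mueller_image(vec, d, pixel_size_um, geometry,
                valid_mask = matrix(!is.na(delta), d[1], d[2]))
}

#' Simulate a polarization-resolved image stack
#'
#' Forward model: frame k at each pixel is `(1/2) t(a_k) %*% M %*% g_k` for
#' the instrument's k-th generator/analyzer pair, optionally degraded with
#' multiplicative Gaussian noise (standard deviation `noise_sd` relative to
#' the noiseless frame value). Negative intensities after noise are clamped
#' to zero and counted.
#'
#' @param truth A [mueller_image()] of ground-truth Mueller matrices.
#' @param instrument An [build_instrument()] model.
#' @param noise `"none"` or `"gaussian"`.
#' @param noise_sd Relative noise standard deviation (e.g. `0.01` for 1%).
#' @param seed Integer seed fixing the noise realization.
#' @return An object of class `polarization_stack` with elements `frames`
#'   (K x N matrix), `dim`, `instrument`, `pixel_size_um`, `geometry`, and
#'   `n_clamped`.
#' @export
simulate_stack <- function(truth, instrument, noise = c("none", "gaussian"),
                           noise_sd = 0.01, seed = 1L) {
  noise <- match.arg(noise)
  frames <- instrument$W %*% truth$vec
  n_clamped <- 0L
  if (noise == "gaussian") {
    set.seed(seed)
    frames <- frames * (1 + matrix(stats::rnorm(length(frames), sd = noise_sd),
                                   nrow(frames), ncol(frames)))
    neg <- frames < 0
    n_clamped <- sum(neg)
    if (n_clamped > 0L) {
      frames[neg] <- 0
      warning(n_clamped, " negative intensities clamped to zero",
              call. = FALSE)
    }
  }
  structure(
    list(frames = frames, dim = truth$dim, instrument = instrument,
         pixel_size_um = truth$pixel_size_um, geometry = truth$geometry,
         n_clamped = n_clamped),
    class = "polarization_stack"
  )
}

#' @export
print.polarization_stack <- function(x, ...) {
  cat("Polarization stack:", nrow(x$frames), "frames of",
      x$dim[1], "x", x$dim[2], "pixels (", x$geometry, ")\n")
  invisible(x)
}

#' Reconstruct per-pixel Mueller matrices from a polarization stack
#'
#' Solves, for every pixel, the linear system `W %*% vec(M) = I` in least
#' squares through the Moore-Penrose pseudo-inverse of the instrument's
#' measurement matrix. Pixels whose frames are all zero are flagged invalid.
#'
#' @param stack A [simulate_stack()] result (or an equivalently shaped stack
#'   read from disk).
#' @return A [mueller_image()].
#' @export
reconstruct_mueller <- function(stack) {
  inst <- stack$instrument
  if (nrow(stack$frames) != inst$n_frames)
    stop("stack has ", nrow(stack$frames), " frames but instrument expects ",
         inst$n_frames, call. = FALSE)
  vec <- inst$W_pinv %*% stack$frames
  nonzero <- colSums(abs(stack$frames)) > 0
  valid <- matrix(nonzero & vec[1L, ] > 0, stack$dim[1], stack$dim[2])
  mueller_image(vec, stack$dim, stack$pixel_size_um, stack$geometry,
                valid_mask = valid)
}

#' Lu-Chipman polar decomposition of a Mueller matrix
#'
#' Factorizes a (normalized) Mueller matrix as
#' `M = M_delta %*% M_R %*% M_D`: a depolarizer, a retarder and a
#' diattenuator. The diattenuation vector is read from the first row of M;
#' after dividing out the diattenuator, the depolarizer block is the signed
#' symmetric square root of `m' %*% t(m')` (sign from `det(m')`), and the
#' retarder is what remains.
#'
#' @param M 4x4 numeric Mueller matrix with `M[1,1] > 0`. It is normalized
#'   by `M[1,1]` internally.
#' @param tol Numerical tolerance for singular diattenuators and depolarizer
#'   blocks.
#' @return An object of class `polar_decomposition`: a list with
#'   `diattenuation` (D in `[0,1]`), `depolarization` (net depolarization
#'   `1 - |tr(m_delta)|/3` in `[0,1]`), `retardance` (radians in `[0, pi]`),
#'   component matrices `M_D`, `M_delta`, `M_R`, and `singular_diattenuator`
#'   (TRUE when D is within `tol` of 1 and a pseudo-inverse was used).
#' @examples
#' dec <- lu_chipman(diag(c(1, 0.65, 0.65, 0.65)))
#' dec$depolarization  # 0.35
#' @export
lu_chipman <- function(M, tol = 1e-9) {
  stopifnot(is.matrix(M), all(dim(M) == c(4L, 4L)))
  if (M[1L, 1L] <= 0)
    stop("M[1,1] must be positive", call. = FALSE)
  M <- M / M[1L, 1L]

  d <- M[1L, 2:4]
  D <- sqrt(sum(d^2))
  singular <- FALSE
  if (D < tol) {
    M_D <- diag(4)
    Mp <- M
  } else {
    dh <- d / D
    sq <- sqrt(max(1 - D^2, 0))
    m_D <- sq * diag(3) + (1 - sq) * tcrossprod(dh)
    M_D <- rbind(c(1, d), cbind(d, m_D))
    if (D >= 1 - tol) {
      singular <- TRUE
      Mp <- M %*% .pinv(M_D)
    } else {
      Mp <- M %*% solve(M_D)
    }
  }

  mp <- Mp[2:4, 2:4]
  ev <- eigen(tcrossprod(mp), symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  s <- if (det(mp) < 0) -1 else 1
  m_delta <- s * (ev$vectors %*% (sqrt(lam) * t(ev$vectors)))
  delta <- 1 - abs(sum(diag(m_delta))) / 3
  P_delta <- Mp[2:4, 1L]
  M_delta <- rbind(c(1, 0, 0, 0), cbind(P_delta, m_delta))

  if (abs(det(m_delta)) < tol^2) {
    m_R <- .pinv(m_delta) %*% mp
  } else {
    m_R <- solve(m_delta, mp)
  }
  M_R <- rbind(c(1, 0, 0, 0), cbind(rep(0, 3), m_R))
  cosR <- (1 + sum(diag(m_R))) / 2 - 1
  retardance <- acos(min(1, max(-1, cosR)))

  structure(
    list(diattenuation = D,
         depolarization = min(1, max(0, delta)),
         retardance = retardance,
         M_D = M_D, M_delta = M_delta, M_R = M_R,
         singular_diattenuator = singular),
    class = "polar_decomposition"
  )
}

#' @export
print.polar_decomposition <- function(x, ...) {
  cat(sprintf(
    "Lu-Chipman decomposition: D = %.4f, depolarization = %.4f, R = %.4f rad\n",
    x$diattenuation, x$depolarization, x$retardance))
  if (x$singular_diattenuator)
    cat("  (singular diattenuator: pseudo-inverse fallback used)\n")
  invisible(x)
}

# Depolarization only, trimmed per-pixel core (same algebra as lu_chipman).
.delta_one <- function(v, tol = 1e-9) {
  M <- matrix(v, 4L, 4L)
  if (M[1L, 1L] <= 0) return(NA_real_)
  M <- M / M[1L, 1L]
  d <- M[1L, 2:4]
  D2 <- sum(d^2)
  if (D2 < tol^2) {
    mp <- M[2:4, 2:4]
  } else {
    D <- sqrt(D2)
    dh <- d / D
    sq <- sqrt(max(1 - D2, 0))
    m_D <- sq * diag(3) + (1 - sq) * tcrossprod(dh)
    M_D <- rbind(c(1, d), cbind(d, m_D))
    Mi <- if (D >= 1 - tol) .pinv(M_D) else solve(M_D)
    mp <- (M %*% Mi)[2:4, 2:4]
  }
  lam <- pmax(eigen(tcrossprod(mp), symmetric = TRUE,
                    only.values = TRUE)$values, 0)
  min(1, max(0, 1 - sum(sqrt(lam)) / 3))
}

#' Per-pixel depolarization or surviving-polarization map
#'
#' Applies the Lu-Chipman decomposition to every valid pixel of a Mueller
#' image. With `metric = "surviving_polarization"` the complement
#' `1 - depolarization` is returned, the display convention used for
#' reflection-geometry imaging of thick tissue.
#'
#' @param img A [mueller_image()].
#' @param metric `"depolarization"` or `"surviving_polarization"`.
#' @return An object of class `depolarization_map`: list with `values`
#'   (H x W matrix in `[0,1]`, `NA` at invalid pixels), `metric`, `geometry`
#'   and `pixel_size_um`.
#' @export
depolarization_map <- function(img,
                               metric = c("depolarization",
                                          "surviving_polarization")) {
  metric <- match.arg(metric)
  n <- prod(img$dim)
  vals <- rep(NA_real_, n)
  idx <- which(as.logical(img$valid_mask))
  if (length(idx))
    vals[idx] <- vapply(idx, function(j) .delta_one(img$vec[, j]), numeric(1))
  if (metric == "surviving_polarization") vals <- 1 - vals
  structure(
    list(values = matrix(vals, img$dim[1], img$dim[2]), metric = metric,
         geometry = img$geometry, pixel_size_um = img$pixel_size_um),
    class = "depolarization_map"
  )
}

#' Convert a depolarization map to the complementary metric
#'
#' @param map A [depolarization_map()].
#' @return The same map with `values` replaced by `1 - values` and `metric`
#'   switched.
#' @export
convert_metric <- function(map) {
  map$values <- 1 - map$values
  map$metric <- if (map$metric == "depolarization")
    "surviving_polarization" else "depolarization"
  map
}

#' @export
print.depolarization_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("%s map: %d x %d px, %g um/px; mean %.3f (n = %d valid)\n",
              x$metric, nrow(x$values), ncol(x$values), x$pixel_size_um,
              mean(v), length(v)))
  invisible(x)
}
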