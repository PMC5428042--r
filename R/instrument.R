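#' Canonical Stokes vectors for polarization states
#'
#' Returns the intensity-normalized (s0 = 1) Stokes vector of a named, fully
#' polarized state: horizontal (`"H"`), vertical (`"V"`), +45 degrees
#' (`"P45"`), -45 degrees (`"M45"`), right circular (`"R"`) and left circular
#' (`"L"`).
#'
#' @param state Character name of the polarization state.
#' @return Numeric length-4 Stokes vector `(s0, s1, s2, s3)`.
#' @examples
#' stokes_state("H")  # c(1, 1, 0, 0)
#' @export
stokes_state <- function(state) {
  tab <- list(
    H   = c(1,  1,  0,  0),
    V   = c(1, -1,  0,  0),
    P45 = c(1,  0,  1,  0),
    M45 = c(1,  0, -1,  0),
    R   = c(1,  0,  0,  1),
    L   = c(1,  0,  0, -1)
  )
  if (!state %in% names(tab))
    stop("unknown polarization state: ", state, call. = FALSE)
  tab[[state]]
}

#' Degree of polarization of a Stokes vector
#'
#' @param s Numeric length-4 Stokes vector.
#' @return `sqrt(s1^2 + s2^2 + s3^2) / s0`, in `[0, 1]` for physical states.
#' @export
stokes_dop <- function(s) {
  stopifnot(length(s) == 4L, s[1] > 0)
  sqrt(sum(s[2:4]^2)) / s[1]
}

#' Build a polarimetric instrument model
#'
#' Constructs the measurement matrix for a dual-rotating polarization state
#' generator (PSG) / analyzer (PSA) scheme. The default scheme pairs six
#' generator states (H, V, +45, -45, R, L) with four analyzer states
#' (H, V, +45, R), giving 24 polarization-resolved frames per acquisition.
#' A detected frame value for generator Stokes vector g and analyzer Stokes
#' vector a applied to a sample Mueller matrix M is `(1/2) * t(a) %*% M %*% g`
#' (the 1/2 is the ideal-polarizer detection factor), so each row of the
#' K x 16 measurement matrix W is `kronecker(g, a) / 2` acting on the
#' column-major vectorization of M.
#'
#' @param psg_states Character vector of generator state names (see
#'   [stokes_state()]).
#' @param psa_states Character vector of analyzer state names.
#' @param pairs Optional two-column integer matrix of (psg index, psa index)
#'   pairs; defaults to the full cross product.
#' @return An object of class `instrument_model` with elements `psg`, `psa`
#'   (Stokes vectors by column), `pairs`, `W` (K x 16 measurement matrix),
#'   `condition_number`, and `n_frames`.
#' @details The measurement matrix must have rank 16 for the per-pixel Mueller
#'   matrix to be recoverable; a rank-deficient scheme is rejected with an
#'   error naming the dimension of the unobservable subspace.
#' @examples
#' inst <- build_instrument()
#' inst$n_frames           # 24
#' qr(inst$W)$rank         # 16
#' @export
build_instrument <- function(psg_states = c("H", "V", "P45", "M45", "R", "L"),
                             psa_states = c("H", "V", "P45", "R"),
                             pairs = NULL) {
  psg <- vapply(psg_states, stokes_state, numeric(4))
  psa <- vapply(psa_states, stokes_state, numeric(4))
  if (is.null(pairs)) {
    pairs <- as.matrix(expand.grid(psg = seq_len(ncol(psg)),
                                   psa = seq_len(ncol(psa))))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L)
    stop("'pairs' must be a two-column (psg, psa) index matrix", call. = FALSE)
  K <- nrow(pairs)
  if (K < 16L)
    stop("scheme has ", K, " measurements; at least 16 are required",
         call. = FALSE)
  W <- matrix(0, K, 16L)
  for (k in seq_len(K)) {
    g <- psg[, pairs[k, 1L]]
    a <- psa[, pairs[k, 2L]]
    # I_k = (1/2) a' M g = (1/2) (g  (x)  a)' vec(M), vec() column-major
    W[k, ] <- kronecker(g, a) / 2
  }
  sv <- svd(W, nu = 0, nv = 0)$d
  rank <- sum(sv > max(sv) * 1e-10)
  if (rank < 16L)
    stop("measurement scheme is rank deficient (rank ", rank,
         " < 16): ", 16L - rank,
         " Mueller degrees of freedom are unobservable", call. = FALSE)
  structure(
    list(psg = psg, psa = psa, pairs = pairs, W = W,
         W_pinv = .pinv(W),
         condition_number = sv[1] / sv[length(sv)],
         n_frames = K),
    class = "instrument_model"
  )
}

#' @export
print.instrument_model <- function(x, ...) {
  cat("Polarimetric instrument model\n")
  cat("  generator states:", ncol(x$psg),
      " analyzer states:", ncol(x$psa), "\n")
  cat("  frames per acquisition:", x$n_frames, "\n")
  cat("  measurement matrix condition number:",
      format(x$condition_number, digits = 4), "\n")
  invisible(x)
}

# Moore-Penrose pseudo-inverse via SVD; tolerance relative to largest
# singular value.
.pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > max(s$d) * tol
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
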