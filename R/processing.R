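#' Extract the transient triplet differential signal
#'
#' Subtracts the pump-only and probe-only measurements from the pump+probe
#' measurement, element-wise. Works identically on image frames and on raw
#' A-line trace stacks (no realignment: the traces share one acquisition
#' clock). Negative pixels — pure noise where no triplet absorber is present
#' — are retained.
#'
#' @param triple A `measurement_triple` (frame or A-line mode), or any list
#'   with `pump_frame`, `probe_frame`, `pumpprobe_frame` of identical shape.
#' @return An object of class `ttd_result` with `ttd_map`, `scheme`, `mode`.
#' @export
extract_ttd <- function(triple) {
  f <- triple[c("pump_frame", "probe_frame", "pumpprobe_frame")]
  if (any(vapply(f, is.null, logical(1))))
    stop("triple must contain pump_frame, probe_frame and pumpprobe_frame")
  d <- lapply(f, dim)
  if (!identical(d[[1]], d[[2]]) || !identical(d[[1]], d[[3]]))
    stop("the three frames must have identical shape")
  structure(list(ttd_map = f$pumpprobe_frame - f$pump_frame - f$probe_frame,
                 scheme = triple$scheme,
                 mode = if (is.null(triple$mode)) "frame" else triple$mode),
            class = "ttd_result")
}

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves `min ||A x - b||` subject to `x >= 0` by the classical active-set
#' algorithm. Used per pixel by [spectral_unmix()].
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric vector of length m.
#' @param tol Dual-feasibility tolerance; default scales with the problem.
#' @return List with `x` (solution), `residual` (Euclidean norm of `Ax - b`).
#' @export
nnls_solve <- function(A, b, tol = NULL) {
  A <- as.matrix(A); b <- as.numeric(b)
  if (nrow(A) != length(b)) stop("dimensions of A and b disagree")
  n <- ncol(A)
  if (is.null(tol)) tol <- 1e-10 * max(1, sum(abs(A)))
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      P <- which(passive)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[P] > 0)) { x <- z; break }
      # step toward z until the first passive variable hits zero
      neg <- P[z[P] <= 0]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P[x[P] <= tol]] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, residual = sqrt(sum((A %*% x - b)^2)))
}

#' Constrained spectral unmixing of multi-wavelength frames
#'
#' Per pixel, solves the linear system relating the photoacoustic signals at
#' the unmixing wavelengths (570, 606, 660 nm by default) to the
#' concentrations of Hb, HbO2 and the dye via their specific absorptions,
#' subject to nonnegativity of the estimated concentrations. The lumped gain
#' constant is never separated out, so concentrations are relative
#' (gain-scaled) quantities.
#'
#' @param frames Named list of signal matrices, one per wavelength; names are
#'   wavelengths in nm (e.g. `"570"`). Exactly the unmixing wavelengths must
#'   be present.
#' @param wavelengths Unmixing wavelengths, nm; default `c(570, 606, 660)`.
#' @param species The three modelled chromophores; default Hb, HbO2, dye.
#' @param A Optional absorption matrix overriding [absorption_matrix()].
#' @return An object of class `unmix_result` with `hb_map`, `hbo2_map`,
#'   `mbnp_map`, `residual_map`, `wavelengths_used`.
#' @export
spectral_unmix <- function(frames, wavelengths = c(570, 606, 660),
                           species = c("Hb", "HbO2", "MBNP_ground"),
                           A = NULL) {
  have <- suppressWarnings(as.numeric(names(frames)))
  if (any(is.na(have)))
    stop("frames must be named by wavelength in nm")
  missing <- setdiff(wavelengths, have)
  if (length(missing) > 0)
    stop("missing frames at wavelength(s): ", paste(missing, collapse = ", "))
  frames <- frames[as.character(wavelengths)]
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("all frames must share the same shape")
  if (is.null(A)) A <- absorption_matrix(wavelengths, species)
  if (abs(det(A)) < 1e-12 * prod(sqrt(colSums(A^2)))) {
    cors <- stats::cor(A)
    diag(cors) <- 0
    pair <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    stop("absorption matrix is singular; spectra of ",
         colnames(A)[pair[1]], " and ", colnames(A)[pair[2]],
         " are collinear at the chosen wavelengths")
  }
  Y <- do.call(rbind, lapply(frames, as.vector))  # wavelengths x pixels
  npx <- ncol(Y)
  X <- matrix(0, 3, npx)
  res <- numeric(npx)
  # fast path: accept the unconstrained solve wherever it is nonnegative
  X0 <- solve(A, Y)
  ok <- colSums(X0 < 0) == 0
  X[, ok] <- X0[, ok]
  for (i in which(!ok)) {
    s <- nnls_solve(A, Y[, i])
    X[, i] <- s$x
    res[i] <- s$residual
  }
  shape_map <- function(v) matrix(v, d[1], d[2])
  structure(list(hb_map = shape_map(X[1, ]), hbo2_map = shape_map(X[2, ]),
                 mbnp_map = shape_map(X[3, ]), residual_map = shape_map(res),
                 wavelengths_used = wavelengths),
            class = "unmix_result")
}

#' Single-wavelength differential enhancement
#'
#' Element-wise difference between a frame acquired with the contrast agent
#' present and a baseline frame with zero agent concentration, both at the
#' agent's ground-state absorption peak. Negative values (noise) are kept.
#'
#' @param frame,baseline_frame Signal matrices of identical shape.
#' @return Difference map.
#' @export
single_wavelength_diff <- function(frame, baseline_frame) {
  if (!identical(dim(frame), dim(baseline_frame)))
    stop("frame and baseline_frame must have identical shape")
  frame - baseline_frame
}

#' Normalize a signal map or series to its maximum
#'
#' Display normalization used when comparing methods: the maximum of the
#' input maps to exactly 1. Zero input is returned unchanged.
#'
#' @param x Numeric vector, matrix or list of matrices.
#' @return Same shape as `x`, scaled so the global maximum is 1.
#' @export
normalize_to_max <- function(x) {
  vals <- if (is.list(x)) unlist(x) else x
  m <- max(vals)
  if (m == 0) return(x)
  if (is.list(x)) lapply(x, function(e) e / m) else x / m
}
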