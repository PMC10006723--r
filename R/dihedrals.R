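#' Wrap angles into (-180, 180]
#'
#' Maps any finite angle in degrees to its congruent value modulo 360 in the
#' half-open interval (-180, 180]; -180 maps to +180. Vectorised.
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Wrapped angles, same length.
#' @examples
#' wrap_angle(c(190, -180, 45, 360))
#' @export
wrap_angle <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    stop("angles must be finite numbers")
  }
  w <- theta - 360 * floor(theta / 360)   # [0, 360)
  w[w > 180] <- w[w > 180] - 360          # (-180, 180]
  w[w == -180] <- 180
  w
}

#' Construct a dihedral trajectory object
#'
#' @param angles Numeric frames x angles matrix (degrees); wrapped on input.
#' @param labels Angle names (e.g. \code{phi_1, psi_1, ...}); defaults to
#'   column names or generated phi/psi pairs.
#' @param stride_steps MD steps between recorded frames (metadata).
#' @return Object of class \code{"dihedral_trajectory"}.
#' @export
dihedral_trajectory <- function(angles, labels = colnames(angles),
                                stride_steps = 1000L) {
  angles <- as.matrix(angles)
  if (nrow(angles) < 1L) stop("trajectory must contain at least one frame")
  if (any(!is.finite(angles))) stop("non-finite dihedral values")
  if (ncol(angles) %% 2L != 0L) {
    stop("angle columns must come in phi/psi pairs (even column count)")
  }
  if (is.null(labels)) {
    k <- ncol(angles) / 2L
    labels <- as.vector(rbind(paste0("phi_", seq_len(k)),
                              paste0("psi_", seq_len(k))))
  }
  if (length(labels) != ncol(angles)) stop("labels do not match columns")
  angles <- apply(angles, 2L, wrap_angle)
  if (!is.matrix(angles)) angles <- matrix(angles, nrow = 1L)
  dimnames(angles) <- list(NULL, labels)
  structure(list(angles = angles, labels = labels,
                 stride_steps = as.integer(stride_steps)),
            class = "dihedral_trajectory")
}

#' @export
print.dihedral_trajectory <- function(x, ...) {
  cat(sprintf("Dihedral trajectory: %d frames x %d angles (stride %d steps)\n",
              nrow(x$angles), ncol(x$angles), x$stride_steps))
  invisible(x)
}

#' Read a per-frame backbone dihedral table
#'
#' Canonical format: delimiter-separated numeric columns with a one-line
#' header of angle labels; an optional leading \code{frame} index column is
#' dropped. Angles are in degrees and are wrapped to (-180, 180] on input.
#'
#' @param path File path.
#' @param sep Field separator; \code{""} (default) splits on any whitespace,
#'   use \code{","} for CSV.
#' @param stride_steps Stride metadata for the returned trajectory.
#' @return A \code{"dihedral_trajectory"}.
#' @export
read_dihedral_table <- function(path, sep = "", stride_steps = 1000L) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot read dihedral table ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0L) stop("dihedral table has zero frames: ", path)
  if (tolower(names(df)[1L]) %in% c("frame", "index", "t")) df <- df[-1L]
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad) > 0L) {
    col <- bad[1L]
    row <- which(is.na(suppressWarnings(as.numeric(as.character(df[[col]])))))
    stop(sprintf("non-numeric value in column '%s' (data row %s)",
                 names(df)[col], if (length(row)) row[1L] else "?"))
  }
  dihedral_trajectory(as.matrix(df), labels = names(df),
                      stride_steps = stride_steps)
}

#' Sin/cos feature embedding of dihedral angles
#'
#' The circular embedding underlying dPCA: each angle theta contributes the
#' pair (cos theta, sin theta), removing the artificial discontinuity at the
#' periodic boundary. Columns are ordered, for each angle in label order,
#' cos then sin.
#'
#' @param traj A \code{"dihedral_trajectory"}.
#' @return Numeric frames x (2 * n_angles) matrix with columns
#'   \code{cos_<label>}, \code{sin_<label>}.
#' @export
encode_sincos <- function(traj) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  rad <- traj$angles * pi / 180
  n <- ncol(rad)
  out <- matrix(0, nrow = nrow(rad), ncol = 2L * n)
  out[, 2L * seq_len(n) - 1L] <- cos(rad)
  out[, 2L * seq_len(n)]      <- sin(rad)
  colnames(out) <- as.vector(rbind(paste0("cos_", traj$labels),
                                   paste0("sin_", traj$labels)))
  out
}

#' Frames recorded by a production run
#'
#' Frame accounting for a fixed-timestep MD run that records every
#' \code{stride_steps} integration steps: a 1 microsecond run at a 2 fs
#' timestep recorded every 1000 steps yields 500,000 frames.
#'
#' @param length_us Simulated time in microseconds.
#' @param timestep_fs Integration timestep in femtoseconds.
#' @param stride_steps Steps between recorded frames.
#' @return Integer frame count.
#' @examples
#' n_recorded_frames(1, 2, 1000)  # 500000
#' @export
n_recorded_frames <- function(length_us = 1, timestep_fs = 2,
                              stride_steps = 1000) {
  stopifnot(length_us > 0, timestep_fs > 0, stride_steps > 0)
  steps <- length_us * 1e9 / timestep_fs
  as.integer(round(steps / stride_steps))
}
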