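#' Construct a multi-echo magnitude image stack
#'
#' @param data Numeric array whose last dimension indexes echoes (e.g.
#'   \code{x,y,echo} or \code{x,y,z,echo}); all magnitudes non-negative.
#' @param te_ms Echo times, ms, strictly increasing, length matching the
#'   last dimension (at least 2 echoes).
#' @param voxel_size_um Isotropic voxel size, um (metadata).
#' @return Object of class \code{multi_echo_stack}.
#' @export
multi_echo_stack <- function(data, te_ms, voxel_size_um = 100) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (nd < 2) stop("data must be an array with echoes in the last dimension")
  if (length(te_ms) < 2) stop("at least 2 echoes are required")
  if (is.unsorted(te_ms, strictly = TRUE))
    stop("echo times must be strictly increasing")
  if (dim(data)[nd] != length(te_ms))
    stop("last dimension of data must match the number of echo times")
  if (any(data < 0)) stop("magnitude images must be non-negative")
  structure(list(data = data, te_ms = te_ms, voxel_size_um = voxel_size_um),
            class = "multi_echo_stack")
}

#' Voxelwise mono-exponential R2* fit
#'
#' Fits \code{y = A exp(-TE * R2*)} in every voxel.  The default
#' \code{"loglinear"} method is a weighted (by squared signal) linear
#' regression of \code{log y} on TE, which is exact on noiseless data and
#' stable with only a few echoes; \code{"nonlinear"} refines the
#' log-linear start by Levenberg-Marquardt least squares on the original
#' scale.  Voxels with any non-positive signal are flagged invalid rather
#' than raising; negative fitted rates (possible under noise) are retained
#' and flagged.
#'
#' @param stack A [multi_echo_stack()].
#' @param method \code{"loglinear"} or \code{"nonlinear"}.
#' @return Object of class \code{r2star_map} with per-voxel arrays
#'   \code{r2star} (ms^-1), \code{A}, \code{rss} (residual sum of squares
#'   on the fitted scale), logical \code{valid} and \code{negative_rate}.
#' @export
#' @examples
#' te <- c(12.5, 23.3, 33.9, 44.6)
#' sig <- array(rep(1000 * exp(-0.033 * te), each = 4), c(2, 2, 4))
#' fit <- fit_r2star(multi_echo_stack(sig, te))
#' range(fit$r2star)
fit_r2star <- function(stack, method = c("loglinear", "nonlinear")) {
  stopifnot(inherits(stack, "multi_echo_stack"))
  method <- match.arg(method)
  d <- dim(stack$data)
  nd <- length(d)
  sdim <- d[-nd]
  ne <- d[nd]
  te <- stack$te_ms
  Y <- matrix(stack$data, prod(sdim), ne)
  valid <- rowSums(Y > 0) == ne
  r2 <- A <- rss <- rep(NA_real_, nrow(Y))
  if (any(valid)) {
    L <- log(Y[valid, , drop = FALSE])
    W <- Y[valid, , drop = FALSE]^2
    sw <- rowSums(W)
    te_m <- matrix(te, nrow(L), ne, byrow = TRUE)
    mte <- rowSums(W * te_m) / sw
    mL <- rowSums(W * L) / sw
    cte <- te_m - mte
    slope <- rowSums(W * cte * L) / rowSums(W * cte^2)
    intercept <- mL - slope * mte
    r2[valid] <- -slope
    A[valid] <- exp(intercept)
    fitted <- exp(intercept + slope * te_m)
    rss[valid] <- rowSums((Y[valid, , drop = FALSE] - fitted)^2)
  }
  if (method == "nonlinear" && any(valid)) {
    for (v in which(valid)) {
      y <- Y[v, ]
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ A0 * exp(-te * r0),
                          start = list(A0 = A[v], r0 = r2[v]),
                          control = minpack.lm::nls.lm.control(
                            maxiter = 100, ftol = 1e-14, ptol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- stats::coef(fit)
        A[v] <- cf[["A0"]]; r2[v] <- cf[["r0"]]
        rss[v] <- sum(stats::residuals(fit)^2)
      }
    }
  }
  shape <- function(x) array(x, sdim)
  structure(list(r2star = shape(r2), A = shape(A), rss = shape(rss),
                 valid = shape(valid),
                 negative_rate = shape(!is.na(r2) & r2 < 0),
                 te_ms = te, method = method),
            class = "r2star_map")
}

#' Summarize an ROI by its median R2*
#'
#' The median over valid ROI voxels is the per-sample summary statistic
#' (more stable than the mean against ROI placement and outlying voxels).
#'
#' @param map An \code{r2star_map} from [fit_r2star()].
#' @param roi Logical (or 0/1) array of the same spatial shape.
#' @return List with \code{median_r2star} (ms^-1), \code{n_voxels} used,
#'   and the \code{roi}.
#' @export
roi_median <- function(map, roi) {
  stopifnot(inherits(map, "r2star_map"))
  roi <- array(as.logical(roi), dim(map$r2star))
  use <- roi & map$valid
  if (!any(use)) stop("ROI does not overlap any valid voxel")
  list(median_r2star = stats::median(map$r2star[use]),
       n_voxels = sum(use), roi = roi)
}

#' Rectangular ROI helper
#'
#' Draws an axis-aligned rectangular (or box) ROI mask, mainly for tests
#' and simulations; real ROIs are user-supplied masks.
#'
#' @param dim Spatial dimensions of the target map.
#' @param lower,upper Inclusive corner indices (vectors matching
#'   \code{length(dim)}).
#' @return Logical array mask.
#' @export
rect_roi <- function(dim, lower, upper) {
  m <- array(FALSE, dim)
  idx <- lapply(seq_along(dim), function(k) lower[k]:upper[k])
  do.call("[<-", c(list(m), idx, list(value = TRUE)))
}

## NIfTI I/O -----------------------------------------------------------------

#' Read / write a multi-echo stack as NIfTI plus a JSON sidecar
#'
#' The image volume (echoes as the last dimension) is stored as NIfTI and
#' the echo times in a JSON sidecar next to it (same path with extension
#' \code{.json}).
#'
#' @param stack A [multi_echo_stack()].
#' @param path NIfTI file path (e.g. \code{stack.nii}).
#' @return \code{write_echo_stack} returns \code{path} invisibly;
#'   \code{read_echo_stack} returns a [multi_echo_stack()].
#' @export
write_echo_stack <- function(stack, path) {
  stopifnot(inherits(stack, "multi_echo_stack"))
  RNifti::writeNifti(RNifti::asNifti(stack$data), path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(te_ms = stack$te_ms,
                            voxel_size_um = stack$voxel_size_um),
                       side, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_echo_stack
#' @export
read_echo_stack <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  multi_echo_stack(array(as.numeric(img), dim(img)), side$te_ms,
                   voxel_size_um = side$voxel_size_um)
}
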