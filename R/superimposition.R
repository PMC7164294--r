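# Weighted rigid alignment. Rotation + translation only: a similarity
# (scaled) Procrustes would absorb growth into the scale factor, and growth
# in millimetres is exactly the quantity under study.

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation is not orthonormal within 1e-9", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation determinant is not +1 (reflection or scaling)",
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or a surface
#'
#' @param transform a `rigid_transform`.
#' @param x N x 3 point matrix or a `corr_surface`.
#' @return transformed points / surface (`R x + t` rowwise).
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "corr_surface")) {
    out <- x
    out$vertices <- apply_transform(transform, x$vertices)
    return(out)
  }
  r <- transform$rotation
  tr <- transform$translation
  # elementwise (not BLAS) so results are independent of matrix blocking
  cbind(x[, 1] * r[1, 1] + x[, 2] * r[1, 2] + x[, 3] * r[1, 3] + tr[1],
        x[, 1] * r[2, 1] + x[, 2] * r[2, 2] + x[, 3] * r[2, 3] + tr[2],
        x[, 1] * r[3, 1] + x[, 2] * r[3, 2] + x[, 3] * r[3, 3] + tr[3])
}

#' Compose two rigid transforms
#' @param a,b `rigid_transform`s; the result applies `b` first, then `a`.
#' @return composed `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, as.numeric(-rt %*% transform$translation))
}

#' Geodesic angle between two rotations, in degrees
#' @param r1,r2 3 x 3 rotation matrices.
#' @return angle of the relative rotation, degrees.
#' @export
rotation_angle_deg <- function(r1, r2 = diag(3)) {
  tr <- sum(diag(crossprod(r2, r1)))
  acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
}

#' Weighted rigid Kabsch alignment
#'
#' Closed-form rotation + translation minimising the weighted sum of squared
#' distances `sum_i w_i ||R m_i + t - f_i||^2` via SVD of the weighted
#' cross-covariance, with a determinant-sign correction so that the solution
#' is always a proper rotation (never a reflection), and no scaling factor.
#'
#' @param moving,fixed N x 3 point matrices (mm).
#' @param weights length-N nonnegative weights.
#' @return a `rigid_transform` mapping `moving` onto `fixed`.
#' @export
weighted_kabsch <- function(moving, fixed,
                            weights = rep(1, nrow(moving))) {
  stopifnot(nrow(moving) == nrow(fixed), length(weights) == nrow(moving))
  if (!all(is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and nonnegative", call. = FALSE)
  }
  if (sum(weights > 0) < 3L) {
    stop("degenerate alignment: fewer than 3 points with positive weight",
         call. = FALSE)
  }
  w <- weights / sum(weights)
  mc <- colSums(moving * w)
  fc <- colSums(fixed * w)
  m0 <- sweep(moving, 2L, mc)
  f0 <- sweep(fixed, 2L, fc)
  # 3x3 weighted cross-covariance via sequential column sums: zero-weight
  # rows then contribute exact zeros, so they can never perturb the solve
  wm0 <- m0 * w
  h <- matrix(0, 3, 3)
  for (k in 1:3) h[, k] <- colSums(wm0 * f0[, k])
  s <- svd(h)
  if (s$d[2] <= 1e-12 * max(s$d[1], 1e-300)) {
    stop("degenerate alignment: weighted points are (near-)collinear",
         call. = FALSE)
  }
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(r, fc - as.numeric(r %*% mc))
}

#' Robust alignment configuration
#'
#' Controls the iteratively reweighted Procrustes: a Gaussian weight kernel in
#' residual distance whose scale is re-estimated each iteration from the
#' median absolute residual (1.4826 x median, floored at `scale_floor`), so
#' regions where the two shapes genuinely differ are progressively
#' down-weighted and alignment is driven by the mutually similar regions.
#'
#' @param max_iterations maximum reweighting iterations (pairwise).
#' @param convergence_tol convergence threshold on the change in weighted RMS
#'   residual (mm).
#' @param scale_floor minimal robust scale sigma (mm), preventing weight
#'   collapse on near-identical shapes.
#' @param kappa kernel width multiplier: weights are
#'   `exp(-r^2 / (2 (kappa sigma)^2))`.
#' @param outer_max_iterations maximum outer iterations of the generalized
#'   (group-wise) alignment.
#' @return object of class `robust_config`.
#' @export
robust_config <- function(max_iterations = 100L, convergence_tol = 1e-6,
                          scale_floor = 1e-6, kappa = 1.0,
                          outer_max_iterations = 20L) {
  stopifnot(max_iterations >= 1, convergence_tol > 0, scale_floor > 0,
            kappa > 0, outer_max_iterations >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 scale_floor = scale_floor, kappa = kappa,
                 outer_max_iterations = as.integer(outer_max_iterations)),
            class = "robust_config")
}

#' Robust iteratively reweighted pairwise Procrustes superimposition
#'
#' Alternates a weighted Kabsch solve with a weight update
#' `w_i = base_i * exp(-r_i^2 / (2 (kappa sigma)^2))`, where `r_i` is the
#' current point residual and `sigma = max(1.4826 * median(r_i), scale_floor)`
#' over vertices with positive base weight, until the weighted RMS residual
#' stabilises. Vertices with base weight zero (teeth) never influence the
#' transform.
#'
#' @param moving,fixed `corr_surface`s on one template; `moving` is aligned
#'   onto `fixed`.
#' @param base_weights length-N base weights in \[0, 1\] (teeth = 0).
#' @param config a `robust_config`.
#' @return object of class `alignment_result`: list with `transform`
#'   (`rigid_transform`), `aligned_moving` (`corr_surface` in the fixed
#'   frame), `final_weights`, `residuals` (mm), `weighted_rms` (mm),
#'   `iterations`, `converged`.
#' @export
robust_procrustes_pair <- function(moving, fixed,
                                   base_weights = rep(1, n_vertices(moving)),
                                   config = robust_config()) {
  check_same_template(moving, fixed)
  n <- n_vertices(moving)
  stopifnot(length(base_weights) == n, all(base_weights >= 0),
            all(base_weights <= 1))
  mv <- moving$vertices
  fv <- fixed$vertices
  core <- base_weights > 0
  w <- base_weights
  prev_rms <- Inf
  converged <- FALSE
  iter <- 0L
  transform <- NULL
  repeat {
    iter <- iter + 1L
    transform <- weighted_kabsch(mv, fv, w)
    aligned <- apply_transform(transform, mv)
    resid <- sqrt(rowSums((aligned - fv)^2))
    sigma <- max(1.4826 * stats::median(resid[core]), config$scale_floor)
    w <- base_weights * exp(-resid^2 / (2 * (config$kappa * sigma)^2))
    rms <- sqrt(sum(w * resid^2) / sum(w))
    if (is.finite(prev_rms) && abs(prev_rms - rms) < config$convergence_tol) {
      converged <- TRUE
      prev_rms <- rms
      break
    }
    prev_rms <- rms
    if (iter >= config$max_iterations) break
  }
  aligned_surface <- moving
  aligned_surface$vertices <- apply_transform(transform, mv)
  resid <- sqrt(rowSums((aligned_surface$vertices - fv)^2))
  structure(
    list(transform = transform, aligned_moving = aligned_surface,
         final_weights = w, residuals = resid, weighted_rms = prev_rms,
         iterations = iter, converged = converged),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> weighted RMS %.4g mm after %d iteration(s)%s\n",
    x$weighted_rms, x$iterations,
    if (x$converged) ", converged" else " (not converged)"))
  invisible(x)
}

#' Generalized (group-wise) robust Procrustes superimposition
#'
#' Iteratively aligns every surface onto an evolving consensus with
#' [robust_procrustes_pair()] and re-estimates the consensus as the per-vertex
#' mean of the aligned surfaces. The first surface seeds the consensus (and
#' hence the orientation gauge); the consensus centroid is translated to the
#' origin for identifiability. Stops when the consensus moves by less than
#' `config$convergence_tol` RMS or after `config$outer_max_iterations`.
#'
#' @param surfaces non-empty list of `corr_surface`s on one template.
#' @param base_weights length-N base weights (teeth = 0).
#' @param config a `robust_config`.
#' @return list with `aligned` (list of aligned `corr_surface`s), `consensus`
#'   (`corr_surface` centred at the origin), `alignments` (last round's
#'   `alignment_result`s), `objective_trace` (base-weighted mean squared
#'   distance to consensus per outer iteration), `outer_iterations`,
#'   `converged`.
#' @export
generalized_robust_procrustes <- function(surfaces,
                                          base_weights = NULL,
                                          config = robust_config()) {
  if (length(surfaces) == 0L) {
    stop("need at least one surface", call. = FALSE)
  }
  if (length(surfaces) == 1L) {
    cons <- .center_surface(surfaces[[1]])
    return(list(aligned = list(cons), consensus = cons, alignments = list(),
                objective_trace = 0, outer_iterations = 0L,
                converged = TRUE))
  }
  for (i in seq_along(surfaces)[-1]) {
    check_same_template(surfaces[[1]], surfaces[[i]])
  }
  n <- n_vertices(surfaces[[1]])
  if (is.null(base_weights)) base_weights <- rep(1, n)
  consensus <- .center_surface(surfaces[[1]])
  converged <- FALSE
  trace <- numeric(0)
  aligned <- surfaces
  alignments <- NULL
  for (outer in seq_len(config$outer_max_iterations)) {
    alignments <- lapply(surfaces, robust_procrustes_pair, fixed = consensus,
                         base_weights = base_weights, config = config)
    aligned <- lapply(alignments, `[[`, "aligned_moving")
    acc <- Reduce(`+`, lapply(aligned, `[[`, "vertices")) / length(aligned)
    new_consensus <- consensus
    new_consensus$vertices <- sweep(acc, 2L, colMeans(acc))
    obj <- mean(vapply(aligned, function(s) {
      sum(base_weights * rowSums((s$vertices - new_consensus$vertices)^2)) /
        sum(base_weights)
    }, numeric(1)))
    trace <- c(trace, obj)
    shift <- sqrt(mean((new_consensus$vertices - consensus$vertices)^2))
    consensus <- new_consensus
    if (shift < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  list(aligned = aligned, consensus = consensus, alignments = alignments,
       objective_trace = trace, outer_iterations = length(trace),
       converged = converged)
}

.center_surface <- function(surface) {
  surface$vertices <- sweep(surface$vertices, 2L, colMeans(surface$vertices))
  surface
}

#' Export an alignment result as JSON plus per-vertex CSV
#'
#' @param result an `alignment_result`.
#' @param json_path path for the transform summary (rotation row-major,
#'   translation, iterations, convergence flag).
#' @param csv_path optional path for per-vertex final weights and residuals.
#' @return invisibly `json_path`.
#' @export
write_alignment_result <- function(result, json_path, csv_path = NULL) {
  jsonlite::write_json(
    list(rotation = as.numeric(t(result$transform$rotation)),
         translation = result$transform$translation,
         weighted_rms_mm = result$weighted_rms,
         iterations = result$iterations,
         converged = result$converged),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    utils::write.csv(
      data.frame(vertex_index = seq_along(result$final_weights) - 1L,
                 weight = result$final_weights,
                 residual_mm = result$residuals),
      csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
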