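#' Construct a corresponded surface
#'
#' A corresponded surface is a triangulated mesh whose vertex order *is* the
#' anatomical correspondence: vertex `i` denotes the same anatomical location
#' on every surface that shares a `template_id`. All coordinates are in
#' millimetres.
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm).
#' @param faces integer T x 3 matrix of 1-based vertex indices, one triangle
#'   per row, counter-clockwise winding as seen from outside the surface.
#' @param template_id character identifier of the shared template topology.
#' @return An object of class `corr_surface`: a list with elements
#'   `vertices`, `faces`, `template_id`.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' s <- corr_surface(v, rbind(c(1, 2, 3)), "tri")
#' n_vertices(s)
#' @export
corr_surface <- function(vertices, faces, template_id = "template") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) {
    stop("`vertices` must be an N x 3 matrix", call. = FALSE)
  }
  if (ncol(faces) != 3L) {
    stop("`faces` must be a T x 3 matrix of triangles", call. = FALSE)
  }
  if (!all(is.finite(vertices))) {
    stop("all vertex coordinates must be finite", call. = FALSE)
  }
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n)) {
    stop("face indices must lie in [1, ", n, "]", call. = FALSE)
  }
  structure(
    list(vertices = vertices, faces = faces,
         template_id = as.character(template_id)),
    class = "corr_surface"
  )
}

#' @export
print.corr_surface <- function(x, ...) {
  cat(sprintf("<corr_surface> %d vertices, %d faces, template '%s'\n",
              nrow(x$vertices), nrow(x$faces), x$template_id))
  invisible(x)
}

#' Number of vertices of a corresponded surface
#' @param surface a `corr_surface`.
#' @return integer vertex count.
#' @export
n_vertices <- function(surface) nrow(surface$vertices)

#' Check that two surfaces live on the same template
#'
#' Verifies identical template id, vertex count and face array; used by every
#' operation that pairs surfaces vertexwise.
#'
#' @param a,b `corr_surface` objects.
#' @return invisibly `TRUE`; otherwise a correspondence error is thrown.
#' @export
check_same_template <- function(a, b) {
  if (!inherits(a, "corr_surface") || !inherits(b, "corr_surface")) {
    stop("both arguments must be corr_surface objects", call. = FALSE)
  }
  if (!identical(a$template_id, b$template_id)) {
    stop(sprintf("correspondence error: template ids differ ('%s' vs '%s')",
                 a$template_id, b$template_id), call. = FALSE)
  }
  if (nrow(a$vertices) != nrow(b$vertices)) {
    stop(sprintf(paste0("correspondence error: vertex counts differ ",
                        "(%d vs %d) on template '%s'"),
                 nrow(a$vertices), nrow(b$vertices), a$template_id),
         call. = FALSE)
  }
  if (!identical(a$faces, b$faces)) {
    stop("correspondence error: face arrays differ on a shared template",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Verify consistent winding
#'
#' A closed, consistently wound triangle mesh traverses every interior edge
#' exactly once in each direction. Boundary edges (traversed once) are allowed
#' unless `closed = TRUE`.
#'
#' @param surface a `corr_surface`.
#' @param closed require that the mesh be closed (no boundary edges).
#' @return invisibly `TRUE`, or an error describing the defect.
#' @export
check_winding <- function(surface, closed = FALSE) {
  f <- surface$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key)) {
    stop("inconsistent winding: a directed edge is traversed twice",
         call. = FALSE)
  }
  rkey <- paste(he[, 2], he[, 1])
  unmatched <- !(key %in% rkey)
  if (closed && any(unmatched)) {
    stop(sprintf("mesh is not closed: %d boundary edges", sum(unmatched)),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Area-weighted per-vertex unit normals
#'
#' The normal at a vertex is the normalised sum of the (area-weighted) normals
#' of its incident faces; since the cross product of two triangle edges has
#' magnitude twice the triangle area, summing raw cross products weights by
#' area automatically. Normals point outward for counter-clockwise winding.
#'
#' @param surface a `corr_surface`.
#' @return N x 3 matrix of unit normals.
#' @export
compute_vertex_normals <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  n <- nrow(v)
  incident <- tabulate(f, nbins = n)
  if (any(incident == 0L)) {
    bad <- which(incident == 0L)
    stop(sprintf("isolated vertices with no incident face: %s",
                 paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  acc <- rowsum(rbind(fn, fn, fn), group = as.vector(f), reorder = TRUE)
  out <- matrix(0, n, 3)
  out[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(out^2))
  if (any(len < .Machine$double.eps)) {
    stop("degenerate normal (zero-area neighbourhood) at vertex ",
         which(len < .Machine$double.eps)[1], call. = FALSE)
  }
  out / len
}

#' Signed per-vertex displacement between two corresponded surfaces
#'
#' Computes the displacement vectors `to - from` at each corresponded vertex
#' and their projections onto the unit normals of the *from* surface. Positive
#' scalars mean outward movement (bone apposition), negative inward. Both
#' surfaces must already be in a common frame: superimposition is the caller's
#' responsibility.
#'
#' @param from_surface,to_surface `corr_surface` objects on one template.
#' @return An object of class `displacement_field`: list with `scalars`
#'   (length-N signed mm), `vectors` (N x 3 mm), and `frame_surface_id`
#'   (the template id of the surface whose normals define the sign).
#' @export
signed_displacement <- function(from_surface, to_surface) {
  check_same_template(from_surface, to_surface)
  vec <- to_surface$vertices - from_surface$vertices
  nrm <- compute_vertex_normals(from_surface)
  structure(
    list(scalars = rowSums(vec * nrm), vectors = vec,
         frame_surface_id = from_surface$template_id),
    class = "displacement_field"
  )
}

#' Region mask with alignment base weights
#'
#' Per-vertex anatomical labels and the base alignment weights they induce:
#' teeth vertices get weight zero so that dental movement never influences
#' skeletal superimposition; every other region gets weight one.
#'
#' @param labels length-N character vector with values among
#'   `"teeth"`, `"condyle_left"`, `"condyle_right"`, `"chin"`, `"body"`.
#' @param n_template expected template vertex count (optional check).
#' @return object of class `region_mask`: list with `labels` (factor) and
#'   `base_weights` (numeric in \[0, 1\], 0 exactly at teeth).
#' @export
region_mask <- function(labels, n_template = NULL) {
  valid <- c("teeth", "condyle_left", "condyle_right", "chin", "body")
  labels <- as.character(labels)
  if (!all(labels %in% valid)) {
    stop("unknown region label(s): ",
         paste(unique(setdiff(labels, valid)), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(n_template) && length(labels) != n_template) {
    stop(sprintf("mask length %d does not match template N = %d",
                 length(labels), n_template), call. = FALSE)
  }
  structure(
    list(labels = factor(labels, levels = valid),
         base_weights = as.numeric(labels != "teeth")),
    class = "region_mask"
  )
}

#' Indices of the vertices carrying a region label
#' @param mask a `region_mask`.
#' @param region region name.
#' @return integer vertex indices.
#' @export
region_vertices <- function(mask, region) {
  which(as.character(mask$labels) == region)
}

#' Patient series of corresponded surfaces at ordered timepoints
#'
#' @param patient_id identifier.
#' @param sex `"male"` or `"female"`.
#' @param timepoints named list, names among `"T1"`, `"T2"`, `"T3"`, each
#'   element a list with `age` (years) and `surface` (`corr_surface`).
#' @return object of class `patient_series`.
#' @export
patient_series <- function(patient_id, sex, timepoints) {
  sex <- match.arg(sex, c("male", "female"))
  labs <- names(timepoints)
  if (is.null(labs) || !all(labs %in% c("T1", "T2", "T3"))) {
    stop("timepoints must be named among T1, T2, T3", call. = FALSE)
  }
  if (length(timepoints) < 2L) {
    stop("a patient series needs at least two timepoints", call. = FALSE)
  }
  ages <- vapply(timepoints, function(tp) tp$age, numeric(1))
  ord <- order(match(labs, c("T1", "T2", "T3")))
  timepoints <- timepoints[ord]
  ages <- ages[ord]
  if (any(diff(ages) <= 0)) {
    stop("ages must be strictly increasing across timepoints", call. = FALSE)
  }
  for (i in seq_along(timepoints)[-1]) {
    check_same_template(timepoints[[1]]$surface, timepoints[[i]]$surface)
  }
  structure(
    list(patient_id = as.character(patient_id), sex = sex,
         timepoints = timepoints),
    class = "patient_series"
  )
}

#' Single normative (untreated) observation
#'
#' One cross-sectional subject of the normative growth cohort.
#'
#' @param subject_id identifier.
#' @param sex `"male"` or `"female"`.
#' @param age age in years.
#' @param surface a `corr_surface`.
#' @return object of class `normative_observation`.
#' @export
normative_observation <- function(subject_id, sex, age, surface) {
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(is.finite(age), inherits(surface, "corr_surface"))
  structure(
    list(subject_id = as.character(subject_id), sex = sex,
         age = as.numeric(age), surface = surface),
    class = "normative_observation"
  )
}
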