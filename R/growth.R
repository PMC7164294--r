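# Sex-specific Nadaraya-Watson kernel regression of vertex coordinates on
# age, fitted on a normative cohort brought into one common consensus frame.
# Both sexes are pooled for superimposition (one frame, so patients of either
# sex are compared without cross-sex alignment bias) but regressed separately.

#' Fit the normative kernel-regression growth model
#'
#' Superimposes all normative observations (both sexes pooled, teeth
#' zero-weighted) with [generalized_robust_procrustes()] and stores the
#' aligned surfaces together with their ages, sexes and the kernel bandwidth.
#'
#' @param observations list of `normative_observation`s on one template; at
#'   least two per sex that will be queried.
#' @param base_weights length-N base alignment weights (teeth = 0).
#' @param h Gaussian kernel bandwidth in years.
#' @param config a `robust_config` used for superimposition.
#' @param age_range optional `c(min, max)` years; defaults to the observed
#'   age range. Queries outside it are errors, not extrapolations.
#' @return object of class `growth_model`: list with `coords` (N x 3 x n
#'   array of aligned coordinates), `ages`, `sexes`, `h`, `age_range`,
#'   `template_id`, `faces`, `consensus`, `config`, `base_weights`.
#' @export
fit_growth_model <- function(observations, base_weights = NULL, h = 1.0,
                             config = robust_config(), age_range = NULL) {
  if (length(observations) == 0L) {
    stop("empty normative cohort", call. = FALSE)
  }
  stopifnot(h > 0)
  surfaces <- lapply(observations, `[[`, "surface")
  ages <- vapply(observations, `[[`, numeric(1), "age")
  sexes <- vapply(observations, `[[`, character(1), "sex")
  gpa <- generalized_robust_procrustes(surfaces, base_weights, config)
  n <- n_vertices(surfaces[[1]])
  coords <- array(0, dim = c(n, 3L, length(surfaces)))
  for (i in seq_along(gpa$aligned)) coords[, , i] <- gpa$aligned[[i]]$vertices
  if (is.null(age_range)) age_range <- range(ages)
  if (any(ages < age_range[1] | ages > age_range[2])) {
    stop("observation age outside the declared age range", call. = FALSE)
  }
  structure(
    list(coords = coords, ages = ages, sexes = sexes, h = h,
         age_range = age_range,
         template_id = surfaces[[1]]$template_id,
         faces = surfaces[[1]]$faces,
         consensus = gpa$consensus,
         config = config,
         base_weights = if (is.null(base_weights)) rep(1, n) else base_weights),
    class = "growth_model"
  )
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf(
    "<growth_model> %d observations (%d male, %d female), ages %.1f-%.1f yr, h = %.2f yr\n",
    length(x$ages), sum(x$sexes == "male"), sum(x$sexes == "female"),
    x$age_range[1], x$age_range[2], x$h))
  invisible(x)
}

#' Kernel weights of a growth-model query
#'
#' Gaussian Nadaraya-Watson weights over the observations of one sex,
#' normalised to sum to one (a convex combination).
#'
#' @param model a `growth_model`.
#' @param age query age in years (within the model's age range).
#' @param sex `"male"` or `"female"`.
#' @return numeric vector over all observations: zero for the other sex,
#'   normalised Gaussian kernel weights for the queried sex.
#' @export
kernel_weights <- function(model, age, sex) {
  sex <- match.arg(sex, c("male", "female"))
  if (!any(model$sexes == sex)) {
    stop("no ", sex, " observations in the growth model", call. = FALSE)
  }
  if (age < model$age_range[1] || age > model$age_range[2]) {
    stop(sprintf(
      "query age %.2f outside the model age range [%.2f, %.2f]; no extrapolation",
      age, model$age_range[1], model$age_range[2]), call. = FALSE)
  }
  k <- numeric(length(model$ages))
  sel <- model$sexes == sex
  k[sel] <- exp(-((age - model$ages[sel]) / model$h)^2 / 2)
  tot <- sum(k)
  if (tot < 1e-12) {
    stop(sprintf(
      "no effective neighbours at age %.2f (kernel mass %.3g); increase the bandwidth h",
      age, tot), call. = FALSE)
  }
  k / tot
}

#' Synthesize the expected normative surface at an age and sex
#'
#' Nadaraya-Watson estimate per coordinate:
#' `v_hat(age) = sum_i K((age - a_i)/h) v_i / sum_i K((age - a_i)/h)` over the
#' aligned observations of the given sex, Gaussian kernel. The result lives in
#' the consensus frame of the fitted model.
#'
#' @param model a `growth_model`.
#' @param age query age in years.
#' @param sex `"male"` or `"female"`.
#' @return a `corr_surface` in the consensus frame.
#' @export
expected_surface <- function(model, age, sex) {
  k <- kernel_weights(model, age, sex)
  dims <- dim(model$coords)
  flat <- matrix(model$coords, nrow = dims[1] * dims[2], ncol = dims[3])
  est <- matrix(as.numeric(flat %*% k), nrow = dims[1], ncol = 3L)
  corr_surface(est, model$faces, model$template_id)
}

#' Expected normative change over an age interval
#'
#' Synthesizes expected surfaces at `age_from` and `age_to`, superimposes the
#' later onto the earlier with the same robust settings used for patient
#' processing, and returns the signed displacement along the earlier
#' surface's normals. Passing expected surfaces through the identical
#' geometry operators as observed patient pairs is what makes the later
#' subtraction meaningful.
#'
#' @param model a `growth_model`.
#' @param age_from,age_to ages in years (both within the model range).
#' @param sex `"male"` or `"female"`.
#' @param base_weights base alignment weights; defaults to the model's.
#' @param config `robust_config`; defaults to the model's.
#' @return object of class `expected_change`: list with `field`
#'   (`displacement_field`), `age_from`, `age_to`, `sex`.
#' @export
expected_change <- function(model, age_from, age_to, sex,
                            base_weights = model$base_weights,
                            config = model$config) {
  s_from <- expected_surface(model, age_from, sex)
  s_to <- expected_surface(model, age_to, sex)
  ali <- robust_procrustes_pair(s_to, s_from, base_weights, config)
  structure(
    list(field = signed_displacement(s_from, ali$aligned_moving),
         age_from = age_from, age_to = age_to, sex = sex),
    class = "expected_change"
  )
}

#' Serialize / load a growth model as a plain-file directory
#'
#' Writes aligned surfaces as PLY, a metadata CSV (`subject_id,sex,age`) and a
#' JSON header (bandwidth, age range, template id, robust configuration).
#'
#' @param model a `growth_model`.
#' @param dir directory to create.
#' @return invisibly `dir`.
#' @export
write_growth_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nobs <- length(model$ages)
  for (i in seq_len(nobs)) {
    write_surface(
      corr_surface(model$coords[, , i], model$faces, model$template_id),
      file.path(dir, sprintf("aligned_%04d.ply", i)))
  }
  utils::write.csv(
    data.frame(subject_id = sprintf("aligned_%04d", seq_len(nobs)),
               sex = model$sexes, age = model$ages),
    file.path(dir, "metadata.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(h = model$h, age_range = model$age_range,
         template_id = model$template_id,
         base_weights = model$base_weights,
         config = unclass(model$config)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_growth_model
#' @export
read_growth_model <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "model.json"),
                             simplifyVector = TRUE)
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  surfaces <- lapply(meta$subject_id, function(id) {
    read_surface(file.path(dir, paste0(id, ".ply")), hdr$template_id)
  })
  n <- n_vertices(surfaces[[1]])
  coords <- array(0, dim = c(n, 3L, length(surfaces)))
  for (i in seq_along(surfaces)) coords[, , i] <- surfaces[[i]]$vertices
  cfg <- do.call(robust_config, as.list(hdr$config))
  structure(
    list(coords = coords, ages = meta$age, sexes = meta$sex, h = hdr$h,
         age_range = hdr$age_range, template_id = hdr$template_id,
         faces = surfaces[[1]]$faces,
         consensus = NULL, config = cfg, base_weights = hdr$base_weights),
    class = "growth_model"
  )
}
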