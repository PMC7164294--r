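# Per-patient observed change, growth subtraction, group means and region
# summaries. The subtraction operates on normal-projected scalars (not on
# 3-vectors): observed and expected changes live in different frames, and the
# quantity reported and tested is the change along the surface normals.

#' Observed morphological change of a patient over an interval
#'
#' Aligns the later surface onto the earlier with robust Procrustes (teeth
#' zero-weighted) and returns the signed displacement along the earlier
#' surface's normals. Any residual difference after rigid alignment is the
#' morphological change over the interval.
#'
#' @param patient a `patient_series`.
#' @param t_from,t_to timepoint labels (`"T1"`, `"T2"`, `"T3"`).
#' @param base_weights length-N base alignment weights.
#' @param config a `robust_config`.
#' @return a `displacement_field`, with the alignment attached as attribute
#'   `"alignment"`.
#' @export
observed_change <- function(patient, t_from, t_to, base_weights,
                            config = robust_config()) {
  for (tp in c(t_from, t_to)) {
    if (!tp %in% names(patient$timepoints)) {
      stop("patient ", patient$patient_id, " has no timepoint ", tp,
           call. = FALSE)
    }
  }
  from <- patient$timepoints[[t_from]]$surface
  to <- patient$timepoints[[t_to]]$surface
  ali <- robust_procrustes_pair(to, from, base_weights, config)
  field <- signed_displacement(from, ali$aligned_moving)
  attr(field, "alignment") <- ali
  field
}

#' Treatment-effect map: observed change minus expected growth
#'
#' The orthopedic effect attributable to treatment is the observed per-vertex
#' change minus the normative growth expected for a subject of the same sex
#' over the same exact age interval, both measured along surface normals.
#'
#' @param patient a `patient_series` whose sex is present in the model and
#'   whose ages at both timepoints lie within the model age range.
#' @param model a `growth_model`.
#' @param t_from,t_to timepoint labels.
#' @param base_weights base alignment weights.
#' @param config a `robust_config`.
#' @return object of class `effect_map`: list with `effect_scalars`
#'   (length-N mm), `interval` (c(from, to)), `patient_id`, `template_id`,
#'   and `components` (the observed and expected `displacement_field`s).
#' @export
treatment_effect <- function(patient, model, t_from, t_to, base_weights,
                             config = robust_config()) {
  obs <- observed_change(patient, t_from, t_to, base_weights, config)
  a_from <- patient$timepoints[[t_from]]$age
  a_to <- patient$timepoints[[t_to]]$age
  exp_ch <- expected_change(model, a_from, a_to, patient$sex,
                            base_weights, config)
  structure(
    list(effect_scalars = obs$scalars - exp_ch$field$scalars,
         interval = c(t_from, t_to),
         patient_id = patient$patient_id,
         template_id = patient$timepoints[[t_from]]$surface$template_id,
         components = list(observed = obs, expected = exp_ch$field)),
    class = "effect_map"
  )
}

#' Vertexwise group-mean effect map
#'
#' @param effects non-empty list of `effect_map`s for one interval and
#'   template.
#' @return an `effect_map` with `patient_id = "group_mean"`.
#' @export
group_mean_effect <- function(effects) {
  if (length(effects) == 0L) stop("empty effect list", call. = FALSE)
  iv <- effects[[1]]$interval
  tid <- effects[[1]]$template_id
  for (e in effects) {
    if (!identical(e$interval, iv)) {
      stop("mixed intervals in group mean", call. = FALSE)
    }
    if (!identical(e$template_id, tid)) {
      stop("mixed templates in group mean", call. = FALSE)
    }
  }
  mean_scalars <- Reduce(`+`, lapply(effects, `[[`, "effect_scalars")) /
    length(effects)
  structure(
    list(effect_scalars = mean_scalars, interval = iv,
         patient_id = "group_mean", template_id = tid, components = NULL),
    class = "effect_map"
  )
}

#' Per-region summary statistics of an effect map
#'
#' Mean, standard deviation, minimum and maximum of the effect scalars per
#' anatomical region. The teeth region is excluded from skeletal regions but
#' reported as a separate `teeth` row (dento-alveolar change).
#'
#' @param effect an `effect_map` (or a `displacement_field`).
#' @param mask a `region_mask` on the same template.
#' @return data.frame with columns `region`, `n_vertices`, `mean`, `sd`,
#'   `min`, `max` (mm).
#' @export
summarize_regions <- function(effect, mask) {
  scalars <- if (inherits(effect, "effect_map")) effect$effect_scalars
             else effect$scalars
  if (length(scalars) != length(mask$labels)) {
    stop("correspondence error: mask length does not match effect field",
         call. = FALSE)
  }
  regions <- c("condyle_left", "condyle_right", "chin", "body", "teeth")
  rows <- lapply(regions, function(r) {
    idx <- region_vertices(mask, r)
    x <- scalars[idx]
    data.frame(region = r, n_vertices = length(idx),
               mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x))
  })
  do.call(rbind, rows)
}

#' Export an effect map as a coloured PLY
#'
#' Writes the effect scalars as the `quality` property with a diverging
#' red/white/blue colormap (red outward, white zero, blue inward).
#'
#' @param effect an `effect_map`.
#' @param surface the template `corr_surface` to carry the field.
#' @param path output PLY path.
#' @param limit colormap saturation (mm).
#' @return invisibly `path`.
#' @export
write_effect_map <- function(effect, surface, path, limit = 2.0) {
  write_surface(surface, path, scalars = effect$effect_scalars,
                colors = colormap_diverging(effect$effect_scalars, limit))
}
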