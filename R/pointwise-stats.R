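# Pointwise exceedance counting and one-tailed exact binomial testing against
# a symmetric null. Under the null, a patient is equally likely to grow
# faster or slower than the normative prediction at any vertex (p0 = 0.5);
# with a clinical margin delta > 0 the true null exceedance probability is
# at most 0.5, so keeping p0 = 0.5 is conservative.

#' Per-vertex exceedance counts over a patient group
#'
#' Counts, at every vertex, the patients whose effect scalar strictly exceeds
#' the cutoff `delta`. With `delta = 0` this is the primary
#' "more-than-predicted" sign counting; positive cutoffs restrict attention
#' to clinically important magnitudes.
#'
#' @param effects non-empty list of `effect_map`s for one interval/template.
#' @param delta cutoff in mm (>= 0); exceedance is strict (`> delta`).
#' @return list with `successes` (length-N integer) and `n` (group size).
#' @export
exceedance_counts <- function(effects, delta = 0) {
  if (length(effects) == 0L) stop("empty effect list", call. = FALSE)
  stopifnot(delta >= 0)
  tid <- effects[[1]]$template_id
  nvert <- length(effects[[1]]$effect_scalars)
  succ <- integer(nvert)
  for (e in effects) {
    if (!identical(e$template_id, tid) ||
        length(e$effect_scalars) != nvert) {
      stop("mixed templates in exceedance counting", call. = FALSE)
    }
    succ <- succ + (e$effect_scalars > delta)
  }
  list(successes = succ, n = length(effects))
}

#' One-tailed exact binomial p-values
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`, computed by
#' direct summation of the probability mass function in log space. Vectorised
#' over `successes`.
#'
#' @param successes integer vector of per-vertex success counts in
#'   \[0, n\].
#' @param n group size.
#' @param p0 null success probability (default 0.5, the symmetric null).
#' @return numeric vector of p-values in (0, 1\].
#' @export
binomial_pointwise_test <- function(successes, n, p0 = 0.5) {
  stopifnot(length(n) == 1L, n >= 1, p0 > 0, p0 < 1)
  if (any(successes < 0 | successes > n) || any(successes != round(successes))) {
    stop("successes must be integers in [0, n]", call. = FALSE)
  }
  j <- 0:n
  logpmf <- lchoose(n, j) + j * log(p0) + (n - j) * log1p(-p0)
  pmf <- exp(logpmf)
  # upper-tail sums, accumulated from the top for accuracy at small p
  tail_p <- rev(cumsum(rev(pmf)))
  pmin(tail_p[successes + 1L], 1)
}

#' Bicolour significance classification
#'
#' Yellow (significant) iff `p < alpha` strictly; p-values at or above alpha
#' are green (not significant).
#'
#' @param p_values numeric vector of p-values.
#' @param alpha significance level (default 0.05).
#' @return list with `significant` (logical) and `color` (character,
#'   `"yellow"`/`"green"`).
#' @export
significance_map <- function(p_values, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  sig <- p_values < alpha
  list(significant = sig, color = ifelse(sig, "yellow", "green"))
}

#' Per-vertex exceedance proportions
#'
#' @param successes integer vector of success counts.
#' @param n group size (> 0).
#' @return numeric vector `successes / n` in \[0, 1\].
#' @export
proportion_map <- function(successes, n) {
  stopifnot(n > 0)
  successes / n
}

#' Run the pointwise exceedance test over a patient group
#'
#' Convenience wrapper chaining [exceedance_counts()],
#' [binomial_pointwise_test()], [significance_map()] and [proportion_map()].
#'
#' @param effects list of `effect_map`s for one interval.
#' @param delta cutoff in mm.
#' @param p0 null success probability.
#' @param alpha significance level.
#' @param adjust optional multiple-testing adjustment across vertices; the
#'   default `"none"` matches pointwise mapping, `"BH"` applies
#'   Benjamini-Hochberg as a clearly labelled extension.
#' @return object of class `pointwise_test_result`: list with `threshold`,
#'   `null_p0`, `n`, `successes`, `p_values`, `significant`, `proportion`,
#'   `alpha`, `adjust`.
#' @export
pointwise_test <- function(effects, delta = 0, p0 = 0.5, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  cnt <- exceedance_counts(effects, delta)
  p <- binomial_pointwise_test(cnt$successes, cnt$n, p0)
  p_used <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
  sig <- significance_map(p_used, alpha)
  structure(
    list(threshold = delta, null_p0 = p0, n = cnt$n,
         successes = cnt$successes, p_values = p,
         significant = sig$significant,
         proportion = proportion_map(cnt$successes, cnt$n),
         alpha = alpha, adjust = adjust),
    class = "pointwise_test_result"
  )
}

#' @export
print.pointwise_test_result <- function(x, ...) {
  cat(sprintf(
    "<pointwise_test_result> n = %d, delta = %.2f mm, p0 = %.2f: %d/%d vertices significant at alpha = %.2f\n",
    x$n, x$threshold, x$null_p0, sum(x$significant), length(x$significant),
    x$alpha))
  invisible(x)
}

#' Per-region aggregate statistics of a pointwise test
#'
#' @param result a `pointwise_test_result`.
#' @param mask a `region_mask` on the same template.
#' @return data.frame with, per region: minimum/median/maximum p-value, mean
#'   exceedance proportion, and fraction of region vertices significant.
#' @export
summarize_test_regions <- function(result, mask) {
  regions <- c("condyle_left", "condyle_right", "chin", "body", "teeth")
  rows <- lapply(regions, function(r) {
    idx <- region_vertices(mask, r)
    data.frame(region = r, n_vertices = length(idx),
               p_min = min(result$p_values[idx]),
               p_median = stats::median(result$p_values[idx]),
               p_max = max(result$p_values[idx]),
               mean_proportion = mean(result$proportion[idx]),
               frac_significant = mean(result$significant[idx]))
  })
  do.call(rbind, rows)
}

#' Export a pointwise test as a bicolour PLY map
#'
#' Vertex colours yellow/green by significance; the exceedance proportion is
#' written as the `quality` scalar.
#'
#' @param result a `pointwise_test_result`.
#' @param surface template `corr_surface`.
#' @param path output PLY path.
#' @return invisibly `path`.
#' @export
write_significance_map <- function(result, surface, path) {
  write_surface(surface, path, scalars = result$proportion,
                colors = colormap_significance(result$significant))
}
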