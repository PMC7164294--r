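# Seeded synthetic study generator. Produces a parametric mandible proxy (a
# U-shaped tube with condylar knobs, a chin prominence and a superior teeth
# ridge), normative cross-sectional growth cohorts, and treated patient
# series with known ground-truth injected effect fields. Every output is a
# pure function of (seed, config).

#' Simulation configuration
#'
#' Defaults encode the study design being emulated: a normative cohort of
#' 654 subjects (268 male / 386 female) aged 8.5-19.5 years, and 20 treated
#' patients (6 male / 14 female, T1 age ~ N(12.76, 0.89) years) observed at
#' three timepoints with a functional-appliance phase of 0.8 years (T1-T2)
#' and a fixed-appliance phase of 1.85 years (T2-T3). Treatment injects an
#' outward effect of 1.8 mm at the condyles and 0.5 mm at the chin over
#' T1-T2 that persists, with per-patient magnitude heterogeneity
#' (`response_scale_range`) so that essentially all patients exceed a 0.5 mm
#' condylar cutoff but only about half exceed 1.5 mm.
#'
#' @param seed integer RNG seed; identical seed + config gives bit-identical
#'   outputs.
#' @param n_vertices template resolution (default 2000; 17415 reproduces the
#'   dense-template scale).
#' @param age_range normative age span in years.
#' @param growth_rates named list per region (`condyle`, `chin`, `body`,
#'   `teeth`) of `list(base, spurt_gain)`: base growth rate in mm/year and
#'   the relative amplitude of the pubertal spurt.
#' @param spurt_center named ages (years) of peak pubertal growth per sex.
#' @param spurt_width Gaussian width (years) of the spurt.
#' @param treatment_effect named magnitudes (mm) injected over T1-T2 at
#'   `condyle` and `chin` (region interiors; feathered at boundaries).
#' @param responder_fraction probability that a patient responds at all;
#'   non-responders receive a zero injected field.
#' @param response_scale_range range of the per-responder uniform magnitude
#'   multiplier (heterogeneous expression of the effect).
#' @param noise_sd per-vertex isotropic observation noise sd (mm).
#' @param pose_jitter_deg,pose_jitter_mm maximal random rigid pose: rotation
#'   angle (degrees) and translation per axis (mm).
#' @param teeth_displacement maximal arbitrary dental movement per timepoint
#'   (mm), applied inside the teeth region only.
#' @param n_normative,normative_male_fraction normative cohort size and male
#'   fraction. The emulated cohort prints 268 males and 386 females, which
#'   sum to 654; the defaults reproduce those sex counts exactly.
#' @param n_patients,patient_male_fraction treated cohort size and male
#'   fraction (6/20).
#' @param patient_age_mean,patient_age_sd T1 age distribution (years).
#' @param interval_t1t2,interval_t2t3 interval lengths in years.
#' @param feather_hops graph-distance width (edges) of the smooth feathering
#'   ramp at region boundaries; vertices deeper inside a region carry the
#'   full regional rate/effect exactly.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_vertices = 2000L,
                       age_range = c(8.5, 19.5),
                       growth_rates = list(
                         condyle = list(base = 0.25, spurt_gain = 1.5),
                         chin = list(base = 0.10, spurt_gain = 1.0),
                         body = list(base = 0.08, spurt_gain = 0.8),
                         teeth = list(base = 0.08, spurt_gain = 0.8)),
                       spurt_center = c(male = 14, female = 12),
                       spurt_width = 1.25,
                       treatment_effect = c(condyle = 1.8, chin = 0.5),
                       responder_fraction = 1.0,
                       response_scale_range = c(0.4, 1.2),
                       noise_sd = 0.1,
                       pose_jitter_deg = 10,
                       pose_jitter_mm = 5,
                       teeth_displacement = 1.0,
                       n_normative = 654L,
                       normative_male_fraction = 268 / 654,
                       n_patients = 20L,
                       patient_male_fraction = 6 / 20,
                       patient_age_mean = 12.76,
                       patient_age_sd = 0.89,
                       interval_t1t2 = 0.8,
                       interval_t2t3 = 1.85,
                       feather_hops = 3L) {
  stopifnot(n_vertices >= 500, age_range[1] < age_range[2],
            responder_fraction >= 0, responder_fraction <= 1,
            noise_sd >= 0, pose_jitter_deg >= 0, pose_jitter_mm >= 0,
            teeth_displacement >= 0, all(treatment_effect >= 0),
            feather_hops >= 1)
  structure(as.list(environment()), class = "sim_config")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Centerline of the U: left condyle (s=0) down the left ramus, around the
# corpus through the chin (s=0.5), up to the right condyle (s=1).
.mandible_centerline <- function(s, r_corpus = 30, h_ramus = 25) {
  len <- 2 * h_ramus + pi * r_corpus
  u <- s * len
  p <- matrix(0, length(s), 3)
  t <- matrix(0, length(s), 3)
  left <- u < h_ramus
  p[left, ] <- cbind(-r_corpus, 0, h_ramus - u[left])
  t[left, ] <- matrix(c(0, 0, -1), sum(left), 3, byrow = TRUE)
  mid <- !left & u < h_ramus + pi * r_corpus
  psi <- -pi / 2 + (u[mid] - h_ramus) / r_corpus
  p[mid, ] <- cbind(r_corpus * sin(psi), r_corpus * cos(psi), 0)
  t[mid, ] <- cbind(cos(psi), -sin(psi), 0)
  right <- !left & !mid
  p[right, ] <- cbind(r_corpus, 0, u[right] - h_ramus - pi * r_corpus)
  t[right, ] <- matrix(c(0, 0, 1), sum(right), 3, byrow = TRUE)
  list(points = p, tangents = t, length = len)
}

.normalize_rows <- function(m) m / sqrt(rowSums(m^2))

#' Generate the synthetic mandible template and its region mask
#'
#' Deterministic parametric mandible proxy: a swept tube along a U-shaped
#' centerline (two vertical rami joined by a semicircular corpus), with
#' swollen condylar knobs at the two posterior-superior ends, an anterior
#' chin prominence, and a raised "teeth" ridge strip along the superior
#' corpus. Regions (`condyle_left`, `condyle_right`, `chin`, `teeth`,
#' `body`) are labelled by construction; the mesh is closed, consistently
#' wound with outward normals, and contains exactly `config$n_vertices`
#' vertices (a few deterministic edge splits in the inferior corpus absorb
#' the remainder of the grid factorisation).
#'
#' @param config a `sim_config`.
#' @return list with `surface` (a `corr_surface`), `mask` (a `region_mask`
#'   with an extra `feather` matrix of per-vertex region weights used by the
#'   generators).
#' @export
make_template <- function(config = sim_config()) {
  n <- as.integer(config$n_vertices)
  n_th <- max(10L, as.integer(round(sqrt((n - 2L) / 5))))
  n_s <- (n - 2L) %/% n_th
  n_extra <- (n - 2L) - n_s * n_th
  if (n_s < 20L) stop("resolution too low to contain all regions",
                      call. = FALSE)

  s <- (seq_len(n_s) - 0.5) / n_s
  cl <- .mandible_centerline(s)
  # parallel-transported tube frame (no seam at the ramus/corpus corners)
  n1 <- matrix(0, n_s, 3)
  n2 <- matrix(0, n_s, 3)
  n1[1, ] <- c(-1, 0, 0)                     # outward at the left condyle
  n1[1, ] <- n1[1, ] - sum(n1[1, ] * cl$tangents[1, ]) * cl$tangents[1, ]
  n1[1, ] <- n1[1, ] / sqrt(sum(n1[1, ]^2))
  for (i in 2:n_s) {
    v <- n1[i - 1, ] - sum(n1[i - 1, ] * cl$tangents[i, ]) * cl$tangents[i, ]
    n1[i, ] <- v / sqrt(sum(v^2))
  }
  for (i in 1:n_s) {
    tg <- cl$tangents[i, ]
    n2[i, ] <- c(tg[2] * n1[i, 3] - tg[3] * n1[i, 2],
                 tg[3] * n1[i, 1] - tg[1] * n1[i, 3],
                 tg[1] * n1[i, 2] - tg[2] * n1[i, 1])
  }

  theta <- 2 * pi * (seq_len(n_th) - 1L) / n_th
  r0 <- 6
  # s-dependent radius: condylar knobs at the ends, slight chin swelling
  r_s <- r0 + 2.5 * (exp(-(s / 0.05)^2) + exp(-((1 - s) / 0.05)^2))

  si <- rep(seq_len(n_s), each = n_th)
  ti <- rep(seq_len(n_th), times = n_s)
  dirs <- cos(theta[ti]) * n1[si, ] + sin(theta[ti]) * n2[si, ]
  verts <- cl$points[si, ] + r_s[si] * dirs

  # directed features from world-space direction of the tube radius
  d_up <- dirs[, 3]
  d_ant <- dirs[, 2]
  sv <- s[si]
  chin_geom <- pmax(0, d_ant) * exp(-((sv - 0.5) / 0.06)^2)
  verts <- verts + 2.0 * chin_geom * dirs
  teeth_geom <- pmax(0, (d_up - 0.5) / 0.5) *
    as.numeric(sv > 0.28 & sv < 0.72)
  verts <- verts + 1.5 * teeth_geom * dirs

  # cap apices beyond the condylar ends
  apex0 <- cl$points[1, ] - cl$tangents[1, ] * (r_s[1] * 0.8)
  apex1 <- cl$points[n_s, ] + cl$tangents[n_s, ] * (r_s[n_s] * 0.8)
  verts <- rbind(verts, apex0, apex1)
  ia0 <- n_s * n_th + 1L
  ia1 <- n_s * n_th + 2L

  vid <- function(i, j) (i - 1L) * n_th + ((j - 1L) %% n_th) + 1L
  i_grid <- rep(seq_len(n_s - 1L), each = n_th)
  j_grid <- rep(seq_len(n_th), times = n_s - 1L)
  f1 <- cbind(vid(i_grid, j_grid), vid(i_grid, j_grid + 1L),
              vid(i_grid + 1L, j_grid + 1L))
  f2 <- cbind(vid(i_grid, j_grid), vid(i_grid + 1L, j_grid + 1L),
              vid(i_grid + 1L, j_grid))
  jj <- seq_len(n_th)
  cap0 <- cbind(ia0, vid(1L, jj + 1L), vid(1L, jj))
  cap1 <- cbind(ia1, vid(n_s, jj), vid(n_s, jj + 1L))
  faces <- rbind(f1, f2, cap0, cap1)

  # orient all faces outward (winding is globally consistent by construction;
  # fix the single global sign against the tube-radial direction)
  probe <- vid(n_s %/% 2L, 1L)
  # use a face incident to the probe vertex on the corpus
  frow <- which(rowSums(faces == probe) > 0)[1]
  tri <- faces[frow, ]
  a <- verts[tri[2], ] - verts[tri[1], ]
  b <- verts[tri[3], ] - verts[tri[1], ]
  fn <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  outward <- dirs[probe, ]
  if (sum(fn * outward) < 0) faces <- faces[, c(1L, 3L, 2L)]

  # per-vertex construction attributes carried through edge splits
  s_attr <- c(sv, 0, 1)
  dup_attr <- c(d_up, 0, 0)
  dant_attr <- c(d_ant, 0, 0)
  teeth_attr <- c(teeth_geom, 0, 0)
  chin_attr <- c(chin_geom, 0, 0)

  # absorb the vertex-count remainder with deterministic edge splits on
  # inferior corpus edges (plain body region, far from all labelled regions)
  if (n_extra > 0L) {
    cand_rows <- seq.int(from = max(2L, n_s %/% 2L - 6L),
                         to = min(n_s - 1L, n_s %/% 2L + 6L), by = 2L)
    cand <- NULL
    for (i0 in cand_rows) {
      for (j0 in seq_len(n_th - 1L)) {
        va <- vid(i0, j0); vb <- vid(i0, j0 + 1L)
        if (dup_attr[va] < -0.3 && dup_attr[vb] < -0.3) {
          cand <- rbind(cand, c(va, vb))
        }
      }
      if (!is.null(cand) && nrow(cand) >= n_extra) break
    }
    if (is.null(cand) || nrow(cand) < n_extra) {
      stop("resolution too low to absorb the vertex-count remainder",
           call. = FALSE)
    }
    for (k in seq_len(n_extra)) {
      va <- cand[k, 1]; vb <- cand[k, 2]
      hit_ab <- which((faces[, 1] == va & faces[, 2] == vb) |
                      (faces[, 2] == va & faces[, 3] == vb) |
                      (faces[, 3] == va & faces[, 1] == vb))
      hit_ba <- which((faces[, 1] == vb & faces[, 2] == va) |
                      (faces[, 2] == vb & faces[, 3] == va) |
                      (faces[, 3] == vb & faces[, 1] == va))
      stopifnot(length(hit_ab) == 1L, length(hit_ba) == 1L)
      vm <- nrow(verts) + 1L
      verts <- rbind(verts, (verts[va, ] + verts[vb, ]) / 2)
      s_attr <- c(s_attr, (s_attr[va] + s_attr[vb]) / 2)
      dup_attr <- c(dup_attr, (dup_attr[va] + dup_attr[vb]) / 2)
      dant_attr <- c(dant_attr, (dant_attr[va] + dant_attr[vb]) / 2)
      teeth_attr <- c(teeth_attr, 0)
      chin_attr <- c(chin_attr, 0)
      split_one <- function(tri, a, b, m) {
        ia <- which(tri == a); ib <- which(tri == b)
        other <- tri[-c(ia, ib)]
        rbind(replace(tri, ib, m), replace(tri, ia, m))
      }
      newf <- rbind(split_one(faces[hit_ab, ], va, vb, vm),
                    split_one(faces[hit_ba, ], vb, va, vm))
      faces <- rbind(faces[-c(hit_ab, hit_ba), ], newf)
    }
  }

  surf <- corr_surface(verts, faces,
                       template_id = sprintf("synthetic-mandible-%d", n))

  labels <- rep("body", nrow(verts))
  labels[s_attr <= 0.055] <- "condyle_left"
  labels[s_attr >= 0.945] <- "condyle_right"
  labels[teeth_attr > 0.12 & labels == "body"] <- "teeth"
  labels[chin_attr > 0.3 & labels == "body"] <- "chin"
  mask <- region_mask(labels, nrow(verts))
  mask$feather <- .feather_weights(surf, labels,
                                   c("condyle_left", "condyle_right",
                                     "chin", "teeth"),
                                   config$feather_hops)
  list(surface = surf, mask = mask)
}

# Per-vertex region weights: exactly 1 at every vertex carrying the region
# label, decaying linearly with graph distance outside it and reaching 0
# after `hops` edges. Labelled vertices therefore carry regional
# rates/effects exactly, while the fields stay smooth across boundaries.
.feather_weights <- function(surface, labels, regions, hops) {
  f <- surface$faces
  n <- nrow(surface$vertices)
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  adj <- split(edges[, 2], edges[, 1])
  out <- matrix(0, n, length(regions), dimnames = list(NULL, regions))
  for (r in regions) {
    inside <- labels == r
    if (!any(inside)) next
    depth <- rep(Inf, n)                       # BFS hops to the region
    depth[inside] <- 0
    frontier <- which(inside)
    d <- 0L
    while (length(frontier) > 0L && d < hops) {
      d <- d + 1L
      nb <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
      nb <- nb[is.infinite(depth[nb])]
      depth[nb] <- d
      frontier <- nb
    }
    out[, r] <- pmax(0, 1 - depth / (hops + 1))
  }
  out
}

# Cumulative normative growth (mm) of one region over [a1, a2]:
# rate(a) = base * (1 + gain * exp(-((a - mu)/w)^2 / 2)), integrated in
# closed form via pnorm.
.region_growth <- function(rate, a1, a2, mu, w) {
  rate$base * ((a2 - a1) +
    rate$spurt_gain * w * sqrt(2 * pi) *
      (stats::pnorm((a2 - mu) / w) - stats::pnorm((a1 - mu) / w)))
}

# Per-vertex cumulative growth scalars (mm) over [a1, a2] for one sex.
.growth_field <- function(mask, sex, a1, a2, config) {
  mu <- config$spurt_center[[sex]]
  w <- config$spurt_width
  g <- vapply(c("condyle", "chin", "body", "teeth"), function(r) {
    .region_growth(config$growth_rates[[r]], a1, a2, mu, w)
  }, numeric(1))
  fe <- mask$feather
  special <- fe[, "condyle_left"] * g[["condyle"]] +
    fe[, "condyle_right"] * g[["condyle"]] +
    fe[, "chin"] * g[["chin"]] +
    fe[, "teeth"] * g[["teeth"]]
  resid <- pmax(0, 1 - rowSums(fe))
  special + resid * g[["body"]]
}

#' Noiseless normative growth of the template over an age interval
#'
#' Displaces template vertices outward along the template's vertex normals by
#' the integral of the age-, sex- and region-dependent growth rate over
#' `[age_from, age_to]`. Rates are smooth in age (Gaussian pubertal spurt
#' with sex-specific timing) and in space (feathered region profiles);
#' growth is additive across adjacent intervals by construction. No noise is
#' added here.
#'
#' @param template the template `corr_surface` from [make_template()].
#' @param mask the matching `region_mask` (with feather weights).
#' @param sex `"male"` or `"female"`.
#' @param age_from,age_to interval in years.
#' @param config a `sim_config`.
#' @return a `corr_surface`.
#' @export
simulate_growth <- function(template, mask, sex, age_from, age_to,
                            config = sim_config()) {
  sex <- match.arg(sex, c("male", "female"))
  g <- .growth_field(mask, sex, age_from, age_to, config)
  nrm <- compute_vertex_normals(template)
  out <- template
  out$vertices <- template$vertices + g * nrm
  out
}

.random_rigid_pose <- function(config) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, config$pose_jitter_deg) * pi / 180
  k <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  r <- diag(3) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)
  tr <- stats::runif(3, -config$pose_jitter_mm, config$pose_jitter_mm)
  rigid_transform(r, tr)
}

# Arbitrary smooth dental movement: one random direction applied across the
# teeth region, scaled by the teeth feather weights.
.random_teeth_displacement <- function(mask, config) {
  if (config$teeth_displacement <= 0) {
    return(matrix(0, length(mask$labels), 3))
  }
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  mag <- stats::runif(1, 0.3, 1) * config$teeth_displacement
  mask$feather[, "teeth"] %o% (mag * dir)
}

.observe <- function(surface, mask, config) {
  n <- n_vertices(surface)
  out <- surface
  out$vertices <- surface$vertices +
    .random_teeth_displacement(mask, config) +
    matrix(stats::rnorm(3 * n, sd = config$noise_sd), n, 3)
  apply_transform(.random_rigid_pose(config), out)
}

#' Simulate a cross-sectional normative cohort
#'
#' Ages are uniform over the configured age range; sexes follow the
#' configured male fraction (deterministic counts). Each observation is the
#' noiseless growth surface at its age plus per-vertex Gaussian noise, a
#' random rigid pose, and a random dental displacement.
#'
#' @param n_subjects cohort size (>= 2).
#' @param config a `sim_config`.
#' @param template,mask optionally a precomputed template pair (otherwise
#'   generated from `config`).
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return list of `normative_observation`s.
#' @export
simulate_normative_cohort <- function(n_subjects, config = sim_config(),
                                      template = NULL, mask = NULL,
                                      seed = config$seed + 1L) {
  stopifnot(n_subjects >= 2)
  if (is.null(template)) {
    tm <- make_template(config)
    template <- tm$surface
    mask <- tm$mask
  }
  n_male <- round(n_subjects * config$normative_male_fraction)
  sexes <- rep(c("male", "female"), c(n_male, n_subjects - n_male))
  .with_seed(seed, {
    ages <- stats::runif(n_subjects, config$age_range[1], config$age_range[2])
    lapply(seq_len(n_subjects), function(i) {
      base <- simulate_growth(template, mask, sexes[i],
                              config$age_range[1], ages[i], config)
      normative_observation(sprintf("norm_%04d", i), sexes[i], ages[i],
                            .observe(base, mask, config))
    })
  })
}

#' Simulate one treated patient series with ground truth
#'
#' T1 is the normative growth surface at `age_t1`; T2 continues normative
#' growth and adds the injected treatment-effect field (responders only,
#' outward along template normals at the condyles and chin, feathered at
#' region boundaries, scaled by a per-patient uniform magnitude draw); T3
#' continues growth with the T2 effect persisting but nothing further
#' injected. Observation noise, random pose and dental movement are applied
#' independently per timepoint.
#'
#' @param config a `sim_config`.
#' @param sex `"male"` or `"female"`.
#' @param age_t1 T1 age in years.
#' @param durations lengths of T1-T2 and T2-T3 in years.
#' @param patient_id identifier.
#' @param template,mask optional precomputed template pair.
#' @param seed RNG seed; defaults to `config$seed + 2`.
#' @return list with `series` (a `patient_series`) and `truth` (list with
#'   `effect_scalars` — the injected per-vertex field in mm —, `responder`,
#'   `response_scale`, and `growth_scalars` per interval).
#' @export
simulate_treated_patient <- function(config = sim_config(),
                                     sex = "female",
                                     age_t1 = config$patient_age_mean,
                                     durations = c(config$interval_t1t2,
                                                   config$interval_t2t3),
                                     patient_id = "patient",
                                     template = NULL, mask = NULL,
                                     seed = config$seed + 2L) {
  sex <- match.arg(sex, c("male", "female"))
  if (is.null(template)) {
    tm <- make_template(config)
    template <- tm$surface
    mask <- tm$mask
  }
  a1 <- age_t1
  a2 <- a1 + durations[1]
  a3 <- a2 + durations[2]
  stopifnot(a1 >= config$age_range[1], a3 <= config$age_range[2])
  fe <- mask$feather
  base_effect <- (fe[, "condyle_left"] + fe[, "condyle_right"]) *
    config$treatment_effect[["condyle"]] +
    fe[, "chin"] * config$treatment_effect[["chin"]]
  nrm <- compute_vertex_normals(template)
  .with_seed(seed, {
    responder <- stats::runif(1) < config$responder_fraction
    scale <- if (responder) {
      stats::runif(1, config$response_scale_range[1],
                   config$response_scale_range[2])
    } else 0
    effect <- scale * base_effect
    shape1 <- simulate_growth(template, mask, sex, config$age_range[1], a1,
                              config)
    shape2 <- simulate_growth(template, mask, sex, config$age_range[1], a2,
                              config)
    shape3 <- simulate_growth(template, mask, sex, config$age_range[1], a3,
                              config)
    shape2$vertices <- shape2$vertices + effect * nrm
    shape3$vertices <- shape3$vertices + effect * nrm
    series <- patient_series(patient_id, sex, list(
      T1 = list(age = a1, surface = .observe(shape1, mask, config)),
      T2 = list(age = a2, surface = .observe(shape2, mask, config)),
      T3 = list(age = a3, surface = .observe(shape3, mask, config))))
    truth <- list(
      effect_scalars = effect,
      responder = responder,
      response_scale = scale,
      growth_scalars = list(
        t1_t2 = .growth_field(mask, sex, a1, a2, config),
        t2_t3 = .growth_field(mask, sex, a2, a3, config),
        t1_t3 = .growth_field(mask, sex, a1, a3, config)))
    list(series = series, truth = truth)
  })
}

#' Simulate the full study
#'
#' One call reproducing the emulated study design at configurable scale: a
#' normative cross-sectional cohort plus a treated cohort with three
#' timepoints each and stored ground truths.
#'
#' @param config a `sim_config`.
#' @param n_normative normative cohort size (defaults to
#'   `config$n_normative`).
#' @return object of class `sim_study`: list with `template`, `mask`,
#'   `normative`, `patients` (list of `patient_series`), `truths`, `config`.
#' @export
simulate_study <- function(config = sim_config(),
                           n_normative = config$n_normative) {
  tm <- make_template(config)
  normative <- simulate_normative_cohort(n_normative, config,
                                         tm$surface, tm$mask,
                                         seed = config$seed + 1L)
  n_pat <- config$n_patients
  n_male <- round(n_pat * config$patient_male_fraction)
  sexes <- rep(c("male", "female"), c(n_male, n_pat - n_male))
  ages <- .with_seed(config$seed + 7L, {
    a <- stats::rnorm(n_pat, config$patient_age_mean, config$patient_age_sd)
    lo <- config$age_range[1]
    hi <- config$age_range[2] - config$interval_t1t2 - config$interval_t2t3
    pmin(pmax(a, lo), hi)
  })
  sims <- lapply(seq_len(n_pat), function(i) {
    simulate_treated_patient(config, sexes[i], ages[i],
                             patient_id = sprintf("patient_%02d", i),
                             template = tm$surface, mask = tm$mask,
                             seed = config$seed + 100L + i)
  })
  structure(
    list(template = tm$surface, mask = tm$mask, normative = normative,
         patients = lapply(sims, `[[`, "series"),
         truths = lapply(sims, `[[`, "truth"),
         config = config),
    class = "sim_study"
  )
}

#' Write a simulated study to the standard on-disk layout
#'
#' Surfaces as PLY, the region mask as CSV, normative and patient metadata
#' as CSV, ground truths as JSON.
#'
#' @param study a `sim_study`.
#' @param dir output directory (created).
#' @return invisibly `dir`.
#' @export
write_study <- function(study, dir) {
  parent <- dirname(normalizePath(dir, mustWork = FALSE))
  if (!dir.exists(parent)) {
    stop("I/O error: parent directory does not exist: ", parent,
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE)
  dir.create(file.path(dir, "normative"), showWarnings = FALSE)
  dir.create(file.path(dir, "patients"), showWarnings = FALSE)
  write_surface(study$template, file.path(dir, "template.ply"))
  write_region_mask(study$mask, file.path(dir, "region_mask.csv"))
  norm_meta <- do.call(rbind, lapply(study$normative, function(o) {
    data.frame(subject_id = o$subject_id, sex = o$sex, age = o$age)
  }))
  utils::write.csv(norm_meta, file.path(dir, "normative", "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  for (o in study$normative) {
    write_surface(o$surface,
                  file.path(dir, "normative", paste0(o$subject_id, ".ply")))
  }
  pat_meta <- do.call(rbind, lapply(study$patients, function(p) {
    do.call(rbind, lapply(names(p$timepoints), function(tp) {
      data.frame(patient_id = p$patient_id, sex = p$sex, timepoint = tp,
                 age = p$timepoints[[tp]]$age)
    }))
  }))
  utils::write.csv(pat_meta, file.path(dir, "patients", "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  for (p in study$patients) {
    for (tp in names(p$timepoints)) {
      write_surface(p$timepoints[[tp]]$surface,
                    file.path(dir, "patients",
                              sprintf("%s_%s.ply", p$patient_id, tp)))
    }
  }
  truths <- lapply(seq_along(study$truths), function(i) {
    tr <- study$truths[[i]]
    list(patient_id = study$patients[[i]]$patient_id,
         responder = tr$responder, response_scale = tr$response_scale,
         effect_scalars = tr$effect_scalars)
  })
  jsonlite::write_json(truths, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir study directory.
#' @return a `sim_study`-like list (without ground truths unless present).
#' @export
read_study <- function(dir) {
  template <- read_surface(file.path(dir, "template.ply"))
  mask <- read_region_mask(file.path(dir, "region_mask.csv"),
                           n_vertices(template))
  nm <- utils::read.csv(file.path(dir, "normative", "metadata.csv"),
                        stringsAsFactors = FALSE)
  normative <- lapply(seq_len(nrow(nm)), function(i) {
    normative_observation(
      nm$subject_id[i], nm$sex[i], nm$age[i],
      read_surface(file.path(dir, "normative",
                             paste0(nm$subject_id[i], ".ply")),
                   template$template_id, template))
  })
  pm <- utils::read.csv(file.path(dir, "patients", "metadata.csv"),
                        stringsAsFactors = FALSE)
  patients <- lapply(split(pm, pm$patient_id), function(rows) {
    tps <- lapply(seq_len(nrow(rows)), function(k) {
      list(age = rows$age[k],
           surface = read_surface(
             file.path(dir, "patients",
                       sprintf("%s_%s.ply", rows$patient_id[k],
                               rows$timepoint[k])),
             template$template_id, template))
    })
    names(tps) <- rows$timepoint
    patient_series(rows$patient_id[1], rows$sex[1], tps)
  })
  patients <- patients[order(names(patients))]
  gt_path <- file.path(dir, "ground_truth.json")
  truths <- if (file.exists(gt_path)) {
    jsonlite::read_json(gt_path, simplifyVector = TRUE)
  }
  list(template = template, mask = mask, normative = normative,
       patients = unname(patients), truths = truths)
}
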