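# Observed change, growth subtraction, group means, region summaries.

# small shared fixture: template + normative model, computed once
local({
  cache <- new.env(parent = emptyenv())
  effect_fixture <<- function() {
    if (is.null(cache$fx)) {
      tm <- test_template()
      cfg <- sim_config(n_vertices = 800L, n_normative = 200L)
      cohort <- simulate_normative_cohort(200, cfg, tm$surface, tm$mask,
                                          seed = 101)
      model <- fit_growth_model(cohort, tm$mask$base_weights, h = 1)
      cache$fx <- list(tm = tm, cfg = cfg, model = model)
    }
    cache$fx
  }
})

test_that("a pure pose change yields zero observed change", {
  tm <- test_template()
  s <- tm$surface
  tr <- rigid_transform(rotation_about(c(1, 2, -1), 18), c(3, -6, 1))
  p <- patient_series("p", "female",
                      list(T1 = list(age = 12, surface = s),
                           T2 = list(age = 12.8,
                                     surface = apply_transform(tr, s))))
  oc <- observed_change(p, "T1", "T2", tm$mask$base_weights)
  expect_lt(max(abs(oc$scalars)), 1e-6)
  expect_error(observed_change(p, "T1", "T3"), "no timepoint T3")
})

test_that("uniform inflation is recovered despite arbitrary zero-weight movement", {
  s <- icosphere(3)
  s$vertices <- 20 * s$vertices              # realistic mm scale
  n <- n_vertices(s)
  nrm <- compute_vertex_normals(s)
  bw <- rep(1, n)
  # an equatorial band, the analogue of a dental arch along the jaw
  patch <- order(abs(s$vertices[, 3]))[seq_len(round(0.1 * n))]
  bw[patch] <- 0
  t2 <- s
  t2$vertices <- s$vertices + 0.5 * nrm
  set.seed(13)
  t2$vertices[patch, ] <- t2$vertices[patch, ] +
    matrix(rnorm(3 * length(patch), sd = 2), length(patch), 3)
  p <- patient_series("p", "male",
                      list(T1 = list(age = 12, surface = s),
                           T2 = list(age = 13, surface = t2)))
  oc <- observed_change(p, "T1", "T2", bw)
  kept <- setdiff(seq_len(n), patch)
  expect_lt(max(abs(oc$scalars[kept] - 0.5)), 0.05)
})

test_that("observed change is antisymmetric at the region level", {
  fx <- effect_fixture()
  pat <- simulate_treated_patient(fx$cfg, "female", 12,
                                  template = fx$tm$surface,
                                  mask = fx$tm$mask, seed = 301)
  fwd <- observed_change(pat$series, "T1", "T2", fx$tm$mask$base_weights)
  rev_series <- patient_series("p", "female", list(
    T1 = list(age = 12, surface = pat$series$timepoints$T2$surface),
    T2 = list(age = 12.8, surface = pat$series$timepoints$T1$surface)))
  bwd <- observed_change(rev_series, "T1", "T2", fx$tm$mask$base_weights)
  for (r in c("condyle_left", "condyle_right", "chin", "body")) {
    idx <- region_vertices(fx$tm$mask, r)
    expect_lt(abs(mean(fwd$scalars[idx]) + mean(bwd$scalars[idx])), 0.02)
  }
})

test_that("null patients have near-zero condylar effect", {
  fx <- effect_fixture()
  cfg0 <- sim_config(n_vertices = 800L, responder_fraction = 0)
  cond <- c(region_vertices(fx$tm$mask, "condyle_left"),
            region_vertices(fx$tm$mask, "condyle_right"))
  ages <- c(11, 13.5, 16)
  for (k in 1:3) {
    pat <- simulate_treated_patient(cfg0, "female", ages[k],
                                    template = fx$tm$surface,
                                    mask = fx$tm$mask, seed = 400 + k)
    expect_true(all(pat$truth$effect_scalars == 0))
    em <- treatment_effect(pat$series, fx$model, "T1", "T2",
                           fx$tm$mask$base_weights)
    expect_lt(abs(mean(em$effect_scalars[cond])), 0.1)
  }
})

test_that("an injected 1.8 mm condylar effect is recovered within 0.3 mm", {
  fx <- effect_fixture()
  cfg1 <- sim_config(n_vertices = 800L, responder_fraction = 1,
                     response_scale_range = c(1, 1))
  pat <- simulate_treated_patient(cfg1, "male", 12.5,
                                  template = fx$tm$surface,
                                  mask = fx$tm$mask, seed = 501)
  em <- treatment_effect(pat$series, fx$model, "T1", "T2",
                         fx$tm$mask$base_weights)
  cond <- c(region_vertices(fx$tm$mask, "condyle_left"),
            region_vertices(fx$tm$mask, "condyle_right"))
  expect_lt(abs(mean(em$effect_scalars[cond]) - 1.8), 0.3)
  expect_identical(
    em$effect_scalars,
    em$components$observed$scalars - em$components$expected$scalars)
})

test_that("a degenerate zero-length interval gives an exactly zero field", {
  tm <- test_template()
  s <- tm$surface
  p <- patient_series("p", "female",
                      list(T1 = list(age = 12, surface = s),
                           T2 = list(age = 13, surface = s)))
  oc <- observed_change(p, "T1", "T1", tm$mask$base_weights)
  expect_lt(max(abs(oc$scalars)), 1e-9)
})

test_that("effect maps are invariant to the stored pose of the inputs", {
  fx <- effect_fixture()
  pat <- simulate_treated_patient(fx$cfg, "female", 12.2,
                                  template = fx$tm$surface,
                                  mask = fx$tm$mask, seed = 601)
  e1 <- treatment_effect(pat$series, fx$model, "T1", "T2",
                         fx$tm$mask$base_weights)
  tr <- rigid_transform(rotation_about(c(1, 0, 2), 33), c(10, -5, 8))
  posed <- pat$series
  posed$timepoints$T2$surface <-
    apply_transform(tr, posed$timepoints$T2$surface)
  e2 <- treatment_effect(posed, fx$model, "T1", "T2",
                         fx$tm$mask$base_weights)
  expect_lt(max(abs(e1$effect_scalars - e2$effect_scalars)), 1e-6)
})

make_fake_effect <- function(scalars, interval = c("T1", "T2"),
                             id = "p", template_id = "t") {
  structure(list(effect_scalars = scalars, interval = interval,
                 patient_id = id, template_id = template_id,
                 components = NULL),
            class = "effect_map")
}

test_that("group mean is the vertexwise arithmetic mean", {
  e <- make_fake_effect(c(1, -2, 3))
  expect_equal(group_mean_effect(list(e))$effect_scalars, c(1, -2, 3))
  neg <- make_fake_effect(-c(1, -2, 3))
  expect_equal(group_mean_effect(list(e, neg))$effect_scalars, c(0, 0, 0))
  set.seed(71)
  maps <- lapply(1:20, function(i) {
    base <- if (i <= 10) 2.0 else 0.0
    make_fake_effect(base + rnorm(50, sd = 0.2))
  })
  gm <- group_mean_effect(maps)
  expect_identical(gm$patient_id, "group_mean")
  expect_lt(abs(mean(gm$effect_scalars) - 1.0), 0.2)
  # commutes with vertexwise affine rescaling
  aff <- lapply(maps, function(m) {
    make_fake_effect(2 * m$effect_scalars + 1)
  })
  expect_equal(group_mean_effect(aff)$effect_scalars,
               2 * gm$effect_scalars + 1, tolerance = 1e-12)
  expect_error(group_mean_effect(list()), "empty")
  mixed <- make_fake_effect(1:50, interval = c("T2", "T3"))
  expect_error(group_mean_effect(list(maps[[1]], mixed)), "mixed intervals")
})

test_that("region summaries aggregate exactly the labelled vertices", {
  tm <- test_template()
  n <- n_vertices(tm$surface)
  const <- make_fake_effect(rep(1.25, n), template_id = tm$surface$template_id)
  rs <- summarize_regions(const, tm$mask)
  expect_true(all(rs$mean == 1.25))
  expect_true(all(rs$sd == 0))
  expect_equal(sum(rs$n_vertices), n)

  ind <- numeric(n)
  cond <- c(region_vertices(tm$mask, "condyle_left"),
            region_vertices(tm$mask, "condyle_right"))
  ind[cond] <- 2.0
  rs <- summarize_regions(make_fake_effect(ind), tm$mask)
  expect_equal(rs$mean[rs$region == "condyle_left"], 2.0)
  expect_equal(rs$mean[rs$region == "condyle_right"], 2.0)
  expect_equal(rs$mean[rs$region == "body"], 0.0)
})

test_that("a simulated responder group recovers the configured region effects", {
  fx <- effect_fixture()
  cfg1 <- sim_config(n_vertices = 800L, responder_fraction = 1,
                     response_scale_range = c(1, 1))
  maps <- lapply(1:6, function(i) {
    pat <- simulate_treated_patient(cfg1, "female", 12,
                                    template = fx$tm$surface,
                                    mask = fx$tm$mask, seed = 700 + i)
    treatment_effect(pat$series, fx$model, "T1", "T2",
                     fx$tm$mask$base_weights)
  })
  rs <- summarize_regions(group_mean_effect(maps), fx$tm$mask)
  expect_lt(abs(rs$mean[rs$region == "condyle_left"] - 1.8), 0.2)
  expect_lt(abs(rs$mean[rs$region == "condyle_right"] - 1.8), 0.2)
  expect_lt(abs(rs$mean[rs$region == "chin"] - 0.5), 0.2)
})
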