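# Synthetic study generator: template construction, growth fields,
# cohorts, treated patients, determinism, ground-truth bookkeeping.

test_that("the template is a closed orientable mesh with all regions present", {
  tm <- test_template()
  s <- tm$surface
  expect_identical(n_vertices(s), 800L)
  check_winding(s, closed = TRUE)
  # outward orientation: positive signed volume via the divergence theorem
  v <- s$vertices
  f <- s$faces
  vol <- sum(vapply(seq_len(nrow(f)), function(i) {
    det(rbind(v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]))
  }, numeric(1))) / 6
  expect_gt(vol, 0)
  counts <- table(tm$mask$labels)
  expect_true(all(counts > 0))
  expect_identical(counts[["condyle_left"]], counts[["condyle_right"]])
})

test_that("template generation is deterministic and hits the requested count", {
  a <- make_template(sim_config(n_vertices = 700L))
  b <- make_template(sim_config(n_vertices = 700L))
  expect_identical(a$surface$vertices, b$surface$vertices)
  expect_identical(a$surface$faces, b$surface$faces)
  expect_identical(n_vertices(a$surface), 700L)
  expect_error(sim_config(n_vertices = 100L))
})

test_that("the dense-template scale of 17415 vertices is reproducible", {
  tm <- make_template(sim_config(n_vertices = 17415L))
  expect_identical(n_vertices(tm$surface), 17415L)
  check_winding(tm$surface, closed = TRUE)
})

test_that("growth displaces labelled regions exactly and is additive", {
  tm <- test_template()
  cfg <- quiet_config(
    n_vertices = 800L,
    growth_rates = list(condyle = list(base = 0.2, spurt_gain = 0),
                        chin = list(base = 0, spurt_gain = 0),
                        body = list(base = 0, spurt_gain = 0),
                        teeth = list(base = 0, spurt_gain = 0)))
  s <- tm$surface
  same <- simulate_growth(s, tm$mask, "female", 12, 12, cfg)
  expect_identical(same$vertices, s$vertices)

  g <- simulate_growth(s, tm$mask, "female", 10, 12, cfg)
  d <- signed_displacement(s, g)
  cond <- c(region_vertices(tm$mask, "condyle_left"),
            region_vertices(tm$mask, "condyle_right"))
  expect_lt(max(abs(d$scalars[cond] - 0.4)), 1e-9)

  # additivity across subintervals (default age-dependent rates)
  cfg2 <- quiet_config(n_vertices = 800L)
  g13 <- simulate_growth(s, tm$mask, "male", 9, 15, cfg2)
  g12 <- simulate_growth(s, tm$mask, "male", 9, 12, cfg2)
  step <- g12
  mid <- simulate_growth(s, tm$mask, "male", 12, 15, cfg2)
  step$vertices <- g12$vertices + (mid$vertices - s$vertices)
  expect_lt(max(abs(step$vertices - g13$vertices)), 1e-6)
})

test_that("normative cohorts honour noise settings, seeds and sex splits", {
  tm <- test_template()
  cfg0 <- quiet_config(n_vertices = 800L)
  cohort <- simulate_normative_cohort(5, cfg0, tm$surface, tm$mask,
                                      seed = 42)
  for (o in cohort) {
    clean <- simulate_growth(tm$surface, tm$mask, o$sex,
                             cfg0$age_range[1], o$age, cfg0)
    expect_lt(max(abs(o$surface$vertices - clean$vertices)), 1e-9)
  }
  cfg <- sim_config(n_vertices = 800L)
  c1 <- simulate_normative_cohort(6, cfg, tm$surface, tm$mask, seed = 7)
  c2 <- simulate_normative_cohort(6, cfg, tm$surface, tm$mask, seed = 7)
  expect_identical(lapply(c1, `[[`, "surface"),
                   lapply(c2, `[[`, "surface"))

  small <- make_template(sim_config(n_vertices = 500L))
  big <- simulate_normative_cohort(654, sim_config(n_vertices = 500L),
                                   small$surface, small$mask, seed = 3)
  sexes <- vapply(big, `[[`, character(1), "sex")
  expect_identical(sum(sexes == "male"), 268L)
  expect_identical(sum(sexes == "female"), 386L)
})

test_that("treated patients carry exact ground truth", {
  tm <- test_template()
  cfg0 <- sim_config(n_vertices = 800L, responder_fraction = 0)
  pat <- simulate_treated_patient(cfg0, "female", 12,
                                  template = tm$surface, mask = tm$mask,
                                  seed = 11)
  expect_true(all(pat$truth$effect_scalars == 0))
  expect_false(pat$truth$responder)

  cfg1 <- sim_config(n_vertices = 800L, responder_fraction = 1,
                     response_scale_range = c(1, 1))
  pat <- simulate_treated_patient(cfg1, "male", 12.5,
                                  template = tm$surface, mask = tm$mask,
                                  seed = 12)
  cond <- region_vertices(tm$mask, "condyle_left")
  expect_true(all(pat$truth$effect_scalars[cond] == 1.8))
  chin <- region_vertices(tm$mask, "chin")
  expect_true(all(pat$truth$effect_scalars[chin] == 0.5))
})

test_that("ground-truth bookkeeping closes on noiseless constructions", {
  tm <- test_template()
  cfg <- quiet_config(n_vertices = 800L, responder_fraction = 1,
                      response_scale_range = c(1, 1))
  pat <- simulate_treated_patient(cfg, "female", 12,
                                  template = tm$surface, mask = tm$mask,
                                  seed = 21)
  t1 <- pat$series$timepoints$T1$surface
  t2 <- pat$series$timepoints$T2$surface
  growth_only <- simulate_growth(
    tm$surface, tm$mask, "female",
    pat$series$timepoints$T1$age, pat$series$timepoints$T2$age, cfg)
  nrm <- compute_vertex_normals(tm$surface)
  injected <- (t2$vertices - t1$vertices) -
    (growth_only$vertices - tm$surface$vertices)
  expect_lt(max(abs(rowSums(injected * nrm) - pat$truth$effect_scalars)),
            1e-9)
})

test_that("responder assignment is a reproducible seeded Bernoulli draw", {
  tm <- test_template()
  cfg <- sim_config(n_vertices = 800L, responder_fraction = 0.5)
  draw <- function() {
    vapply(1:20, function(i) {
      simulate_treated_patient(cfg, "female", 12, template = tm$surface,
                               mask = tm$mask, seed = 1000 + i)$truth$responder
    }, logical(1))
  }
  r1 <- draw()
  r2 <- draw()
  expect_identical(r1, r2)
  expect_gte(sum(r1), 5L)
  expect_lte(sum(r1), 15L)
})

test_that("a full simulated study matches the configured design", {
  cfg <- sim_config(n_vertices = 600L, n_normative = 12L)
  study <- simulate_study(cfg)
  expect_length(study$patients, 20L)
  expect_length(study$normative, 12L)
  for (p in study$patients) {
    expect_identical(names(p$timepoints), c("T1", "T2", "T3"))
  }
  sexes <- vapply(study$patients, `[[`, character(1), "sex")
  expect_identical(sum(sexes == "male"), 6L)
  expect_identical(sum(sexes == "female"), 14L)
  ages <- vapply(study$patients, function(p) p$timepoints$T1$age, numeric(1))
  expect_true(all(ages >= cfg$age_range[1]))
  expect_true(all(ages + cfg$interval_t1t2 + cfg$interval_t2t3 <=
                    cfg$age_range[2]))
})

test_that("study directories are written deterministically", {
  cfg <- sim_config(n_vertices = 600L, n_normative = 4L, n_patients = 2L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg), file.path(d1, "study"))
  write_study(simulate_study(cfg), file.path(d2, "study"))
  f1 <- list.files(file.path(d1, "study"), recursive = TRUE)
  f2 <- list.files(file.path(d2, "study"), recursive = TRUE)
  expect_identical(f1, f2)
  sum1 <- tools::md5sum(file.path(d1, "study", f1))
  sum2 <- tools::md5sum(file.path(d2, "study", f2))
  expect_identical(unname(sum1), unname(sum2))
  expect_error(write_study(simulate_study(cfg),
                           file.path(d1, "missing", "deep", "study")),
               "parent directory")
})

test_that("study directories round trip through read_study", {
  cfg <- sim_config(n_vertices = 600L, n_normative = 3L, n_patients = 2L)
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(study, file.path(dir, "study"))
  back <- read_study(file.path(dir, "study"))
  expect_identical(length(back$normative), length(study$normative))
  expect_identical(length(back$patients), length(study$patients))
  expect_lt(max(abs(back$template$vertices - study$template$vertices)), 1e-6)
  expect_identical(as.character(back$mask$labels),
                   as.character(study$mask$labels))
  o1 <- study$normative[[1]]$surface$vertices
  o2 <- back$normative[[1]]$surface$vertices
  expect_lt(max(abs(o1 - o2)), 1e-6)
})
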