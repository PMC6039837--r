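small_profile <- function(within, global, nch = 6, nmod = 2, len = 12,
                          fs = 120, freqs = 4:8) {
  coupling_profile(nch, nmod, within = within, global = global,
                   fs_hz = fs, run_length_s = len, osc_freqs = freqs)
}

test_that("full module coupling gives PLV 1 within a module", {
  prof <- small_profile(within = 1, global = 0)
  run <- generate_run(prof, seed = 2)
  bc <- band_plv_matrix(run, "theta")
  same_mod <- outer(prof$module, prof$module, "==")
  diag(same_mod) <- FALSE
  expect_true(all(abs(bc$matrix[same_mod] - 1) < 1e-6))
  # across modules phases are independent: clearly below locking
  expect_true(all(bc$matrix[!same_mod & upper.tri(same_mod)] < 0.995))
})

test_that("run generation is deterministic and rejects bad parameters", {
  prof <- small_profile(0.4, 0.2)
  r1 <- generate_run(prof, run_index = 2, seed = 77)
  r2 <- generate_run(prof, run_index = 2, seed = 77)
  expect_identical(r1$data, r2$data)
  r3 <- generate_run(prof, run_index = 2, seed = 78)
  expect_false(identical(r1$data, r3$data))

  bad <- prof; bad$run_length_s <- 0
  expect_error(generate_run(bad), "positive")
  expect_error(coupling_profile(6, 2, within = 1.2, global = 0))
  expect_error(coupling_profile(6, 2, within = 0.2, global = 0, fs_hz = 50))
})

test_that("marginal variance is constant across channels", {
  prof <- small_profile(0.5, 0.3, nch = 8, len = 30)
  run <- generate_run(prof, seed = 5)
  v <- apply(run$data, 1, var)
  expect_lt(diff(range(v)) / mean(v), 0.25)
})

test_that("increasing within-coupling increases within-module PLV", {
  mean_within <- function(w, seed) {
    prof <- small_profile(w, 0, nch = 8, len = 24)
    run <- generate_run(prof, seed = seed)
    bc <- band_plv_matrix(run, "theta")
    same <- outer(prof$module, prof$module, "==") & upper.tri(bc$matrix)
    mean(bc$matrix[same])
  }
  for (seed in c(3, 14, 25)) {
    vals <- vapply(c(0.1, 0.45, 0.8), mean_within, numeric(1), seed = seed)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("cohort manifest has the documented structure", {
  spec <- cohort_spec(n_per_group = c(non_responder = 9L, responder = 14L,
                                      control = 14L),
                      n_channels = 6L, run_length_s = 6,
                      control_run_length_s = 6, fs_hz = 120,
                      osc_freqs = 4:8, seed = 3L)
  coh <- generate_cohort(spec)
  man <- coh$manifest
  expect_equal(nrow(man), 37)
  expect_equal(unname(table(man$group)[c("non_responder", "responder",
                                         "control")]),
               c(9L, 14L, 14L), ignore_attr = TRUE)
  # about half of each patient group sedated, controls never
  expect_equal(sum(man$sedation[man$group == "responder"]), 7)
  expect_equal(sum(man$sedation[man$group == "non_responder"]),
               round(0.5 * 9))
  expect_true(all(man$sedation[man$group == "control"] == 0))
  expect_true(all(man$sex %in% c("M", "F")))
  expect_true(all(man$age > 0))

  # degenerate single-subject cohort works
  tiny <- generate_cohort(cohort_spec(
    n_per_group = c(non_responder = 0L, responder = 0L, control = 1L),
    n_channels = 4L, run_length_s = 4, control_run_length_s = 4,
    fs_hz = 120, osc_freqs = 4:8))
  expect_equal(nrow(tiny$manifest), 1)
  expect_equal(tiny$manifest$group, "control")
})

test_that("cohorts are reproducible and runs regenerate identically", {
  spec <- cohort_spec(n_per_group = c(non_responder = 1L, responder = 1L,
                                      control = 1L),
                      n_channels = 4L, run_length_s = 4,
                      control_run_length_s = 4, fs_hz = 120,
                      osc_freqs = 4:8, n_runs = 2L, seed = 9L)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  r1 <- subject_runs(c1, "R01")
  r2 <- subject_runs(c2, "R01")
  expect_identical(r1[[2]]$data, r2[[2]]$data)
  expect_false(identical(r1[[1]]$data, r1[[2]]$data))
  expect_error(subject_runs(c1, "nope"), "unknown subject")
})

test_that("cohort files round-trip through disk", {
  spec <- cohort_spec(n_per_group = c(non_responder = 0L, responder = 1L,
                                      control = 1L),
                      n_channels = 4L, run_length_s = 4,
                      control_run_length_s = 4, fs_hz = 120,
                      osc_freqs = 4:8, n_runs = 1L, seed = 5L)
  coh <- generate_cohort(spec)
  dir <- file.path(tempdir(), "cohort-rt")
  man <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  path1 <- strsplit(man$run_paths[1], ";")[[1]][1]
  back <- read_run(path1)
  orig <- subject_runs(coh, man$subject_id[1])[[1]]
  expect_equal(back$data, orig$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$fs_hz, 120)
  unlink(dir, recursive = TRUE)
})

test_that("twin traits: MZ genetic sharing is exact and h2 = 0 decorrelates", {
  sim1 <- generate_twin_traits(pedigree_spec(25, 0, 0, h2_true = 1,
                                             covariate_betas = c(sex = 0,
                                                                 age = 0),
                                             seed = 6))
  tr <- sim1$data$trait
  # h2 = 1: MZ co-twins are identical (no environmental term)
  expect_equal(tr[seq(1, 50, 2)], tr[seq(2, 50, 2)], tolerance = 1e-12)

  sim0 <- generate_twin_traits(pedigree_spec(40, 0, 0, h2_true = 0,
                                             covariate_betas = c(sex = 0,
                                                                 age = 0),
                                             seed = 7))
  t0 <- sim0$data$trait
  r0 <- cor(t0[seq(1, 80, 2)], t0[seq(2, 80, 2)])
  expect_lt(abs(r0), 3 / sqrt(40))

  expect_error(pedigree_spec(h2_true = 1.4), "h2")
})

test_that("MZ correlation exceeds DZ correlation for heritable traits", {
  wins <- sapply(1:50, function(s) {
    sim <- generate_twin_traits(pedigree_spec(15, 15, 0, h2_true = 0.7,
                                              covariate_betas = c(sex = 0,
                                                                  age = 0),
                                              seed = 200 + s))
    tr <- sim$data$trait
    zyg <- sim$pedigree$zygosity
    mz <- tr[zyg == "MZ"]; dz <- tr[zyg == "DZ"]
    cor(mz[c(TRUE, FALSE)], mz[c(FALSE, TRUE)]) >
      cor(dz[c(TRUE, FALSE)], dz[c(FALSE, TRUE)])
  })
  expect_gt(mean(wins), 0.7)
  expect_lt(binom.test(sum(wins), 50, 0.5)$p.value, 0.01)
})

test_that("default profiles separate the groups by theta-band topology", {
  # with default group profiles and n = 14 per group, run-averaged theta
  # modularity medians must order controls > responders > non-responders in
  # at least 95% of 20 seeded replicates; transitivity shows the reverse
  # pattern in the replicate-pooled medians
  med <- function(v, g, grp) stats::median(v[g == grp])
  q_ok <- logical(20)
  t_med <- matrix(NA_real_, 20, 3,
                  dimnames = list(NULL, c("control", "responder",
                                          "non_responder")))
  for (s in 1:20) {
    spec <- cohort_spec(
      n_per_group = c(non_responder = 14L, responder = 14L, control = 14L),
      n_channels = 16L, run_length_s = 36, control_run_length_s = 36,
      fs_hz = 127.15, osc_freqs = 4:8, seed = s)
    coh <- generate_cohort(spec)
    f <- cohort_features(coh, bands = "theta", n_restarts = 10L, seed = s)
    a <- f$averaged
    qc <- med(a$modularity, a$group, "control")
    qr <- med(a$modularity, a$group, "responder")
    qn <- med(a$modularity, a$group, "non_responder")
    q_ok[s] <- qc > qr && qr > qn
    for (g in colnames(t_med))
      t_med[s, g] <- med(a$transitivity, a$group, g)
  }
  expect_gte(mean(q_ok), 0.95)
  t_pool <- apply(t_med, 2, median)
  expect_lt(t_pool[["control"]], t_pool[["responder"]])
  expect_lt(t_pool[["responder"]], t_pool[["non_responder"]])
})

test_that("pedigree table is FAM-like with twins sharing age", {
  sim <- generate_twin_traits(pedigree_spec(2, 2, 3, seed = 8))
  ped <- sim$pedigree
  expect_equal(names(ped), c("family_id", "individual_id", "father_id",
                             "mother_id", "sex", "zygosity"))
  expect_equal(nrow(ped), 11)
  expect_setequal(unique(ped$zygosity), c("MZ", "DZ", "NT"))
  ages <- sim$data$age
  expect_equal(ages[1], ages[2])  # first MZ pair shares age
})
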