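fake_composites <- function(z_count, z_elong, agent = "X", serum = "low",
                            doses = dose_series(100)) {
  rbind(
    data.frame(agent = agent, dose = doses, serum = serum,
               measurement = "count", n = 4L, z_hat = z_count),
    data.frame(agent = agent, dose = doses, serum = serum,
               measurement = "elongation", n = 4L, z_hat = z_elong))
}

test_that("matrix assembly is complete, ordered, and order-invariant", {
  d <- demo_design(serum = c("low", "high"))
  pl <- generate_plate(d, seed = 2)
  sm <- simulate_well_summaries(pl, seed = 3)
  sc <- score_screen(sm, pl$plate_map)
  m <- build_matrix(sc)
  expect_equal(dim(m$values), c(14L, 4L))      # 2 agents x 7 doses; 2 x 2
  expect_false(any(is.na(m$values)))
  expect_true(all(diff(order(m$rows$agent, m$rows$dose)) == 1))
  m2 <- build_matrix(sc[sample(nrow(sc)), ])
  expect_identical(m, m2)
  # a missing condition stays NA, not zero
  m3 <- build_matrix(sc[-5, ])
  expect_equal(sum(is.na(m3$values)), 1L)
  expect_error(build_matrix(rbind(sc, sc[1, ])), "duplicate")
  expect_error(build_matrix(sc[0, ]), "no composite")
})

test_that("hit calls implement the dual-phenotype decision rule", {
  z0 <- rep(0, 7)
  up <- c(0, 0, 0, 0, 0, 8, 9); dn <- -up
  expect_equal(call_hits(build_matrix(fake_composites(z0, z0)))$call, "none")
  expect_equal(call_hits(build_matrix(fake_composites(up, z0)))$call,
               "proliferation_only")
  expect_equal(call_hits(build_matrix(fake_composites(z0, up)))$call,
               "differentiation_only")
  expect_equal(call_hits(build_matrix(fake_composites(up, up)))$call,
               "dual_phenotype")
  expect_equal(call_hits(build_matrix(fake_composites(dn, up)))$call,
               "anti_proliferative_differentiation")
  # direction switch: decreasing elongation as differentiation signature
  expect_equal(call_hits(build_matrix(fake_composites(up, dn)),
                         elong_direction = "decrease")$call,
               "dual_phenotype")
  expect_equal(call_hits(build_matrix(fake_composites(up, dn)))$call,
               "proliferation_only")
  # min_doses: a single passing dose is not enough by default
  one <- c(0, 0, 0, 0, 0, 0, 9)
  expect_equal(call_hits(build_matrix(fake_composites(one, one)))$call,
               "none")
  expect_equal(call_hits(build_matrix(fake_composites(one, one)),
                         min_doses = 1)$call, "dual_phenotype")
  # dual requires the conjunction within one serum condition
  two_serum <- rbind(fake_composites(up, z0, serum = "low"),
                     fake_composites(z0, up, serum = "high"))
  expect_false(call_hits(build_matrix(two_serum))$call == "dual_phenotype")
})

test_that("hit class never demotes as the effect size grows", {
  rank <- c(none = 0, proliferation_only = 1, differentiation_only = 1,
            anti_proliferative_differentiation = 2, dual_phenotype = 2)
  last <- -1
  for (amp in c(0, 1, 2.5, 5, 10, 20)) {
    z <- amp * c(0, 0, 0, 0.2, 0.5, 0.9, 1)
    call <- call_hits(build_matrix(fake_composites(z, z)))$call
    expect_gte(rank[[call]], last)
    last <- rank[[call]]
  }
  expect_equal(last, 2)
})

test_that("reports round-trip and record the seed in the manifest", {
  d <- demo_design()
  pl <- generate_plate(d, seed = 4)
  sm <- simulate_well_summaries(pl, seed = 5)
  m <- build_matrix(score_screen(sm, pl$plate_map))
  h <- call_hits(m)
  out1 <- file.path(tempdir(), "rep1"); out2 <- file.path(tempdir(), "rep2")
  write_report(m, h, out1, seed = 4L)
  write_report(m, h, out2, seed = 4L)
  long <- utils::read.csv(file.path(out1, "composite_z_long.csv"))
  got <- long[order(long$agent, long$dose, long$serum, long$measurement), ]
  df <- phenoscreen:::screen_matrix_df(m)
  want <- df[order(df$agent, df$dose, df$serum, df$measurement), ]
  expect_equal(got$z_hat, want$z_hat)
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(man$seed, 4L)
  expect_identical(readLines(file.path(out1, "composite_z_matrix.csv")),
                   readLines(file.path(out2, "composite_z_matrix.csv")))
  expect_identical(readLines(file.path(out1, "hit_table.csv")),
                   readLines(file.path(out2, "hit_table.csv")))
  expect_true(file.exists(file.path(out1, "heatmap_count.png")))
})

test_that("strong dual agents are called dual_phenotype almost always", {
  eff <- list(EDN3 = effect_model(ec50 = 10, hill = 1.5, emax_count = 0.6,
                                  emax_elong = 0.15))
  d <- demo_design(agents = "EDN3", n_ctrl = 24L, effects = eff,
                   baseline_count = 100)
  calls <- vapply(1:100, function(i) {
    pl <- generate_plate(d, seed = 3000 + i)
    sm <- simulate_well_summaries(pl, seed = 4000 + i)
    call_hits(build_matrix(score_screen(sm, pl$plate_map)))$call
  }, "")
  expect_gte(mean(calls == "dual_phenotype"), 0.95)
})
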