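# PC 34:2 transition used throughout: factors from the package's chem layer,
# cross-checked against printed values in test-acceptance.R.
pc342_lib <- function() {
  lib_row("PC_34:2", 758.6, 184.07, "C42H81O8NP", "C5H15O4NP", "ConstantProduct")
}

test_that("find_interference_edges discovers the M1/M2 ladder", {
  run <- mrm_run("r1", list(const_channel(758.6, 184.07),
                            const_channel(759.6, 184.07),
                            const_channel(760.6, 184.07)))
  lib <- pc342_lib()
  ann <- annotate_dataset(run, lib)
  g <- find_interference_edges(run, ann, lib)
  sid <- channel_id(758.6, 184.07, "Positive", 33)
  expect_setequal(g$edges$source_id, sid)
  e1 <- g$edges[g$edges$affected_id == channel_id(759.6, 184.07, "Positive", 33), ]
  e2 <- g$edges[g$edges$affected_id == channel_id(760.6, 184.07, "Positive", 33), ]
  expect_equal(unname(c(e1$i, e1$j)), c(1L, 0L))
  expect_equal(e1$factor, 0.41, tolerance = 0.02)
  expect_equal(unname(c(e2$i, e2$j)), c(2L, 0L))
  expect_equal(e2$factor, 0.090, tolerance = 0.02)
  # processing order ascends in Q1
  expect_equal(g$order, c(channel_id(759.6, 184.07, "Positive", 33),
                          channel_id(760.6, 184.07, "Positive", 33)))
})

test_that("collision-energy mismatch suppresses edges", {
  run <- mrm_run("r1", list(const_channel(758.6, 184.07, ce = 33),
                            const_channel(759.6, 184.07, ce = 35)))
  lib <- pc342_lib()
  g <- find_interference_edges(run, annotate_dataset(run, lib), lib)
  expect_equal(nrow(g$edges), 0)
  # within +/- 1.0 V the edge appears
  run2 <- mrm_run("r1", list(const_channel(758.6, 184.07, ce = 33),
                             const_channel(759.6, 184.07, ce = 34)))
  g2 <- find_interference_edges(run2, annotate_dataset(run2, lib), lib)
  expect_equal(nrow(g2$edges), 1)
})

test_that("single-channel runs and ineligible annotations give empty graphs", {
  run <- mrm_run("r1", list(const_channel(758.6, 184.07)))
  lib <- pc342_lib()
  g <- find_interference_edges(run, annotate_dataset(run, lib), lib)
  expect_equal(nrow(g$edges), 0)
  # formula-less rows can never source edges
  run2 <- mrm_run("r1", list(const_channel(758.6, 184.07),
                             const_channel(759.6, 184.07)))
  bare <- lib_row("PC_34:2_noformula", 758.6, 184.07)
  g2 <- find_interference_edges(run2, annotate_dataset(run2, bare), bare)
  expect_equal(nrow(g2$edges), 0)
})

test_that("resample_onto interpolates linearly and zeroes outside the span", {
  t <- c(0, 1); y <- c(0, 10)
  expect_equal(resample_onto(t, y, 0.5), 5)
  expect_equal(resample_onto(t, y, t), y)
  expect_equal(resample_onto(c(0, 10), c(100, 100), c(-1, 5, 11)), c(0, 100, 0))
  expect_error(resample_onto(1, 5, 1), ">= 2 points")
})

test_that("subtraction on constant traces matches hand computation", {
  run <- mrm_run("r1", list(const_channel(758.6, 184.07, value = 100),
                            const_channel(759.6, 184.07, value = 50)))
  lib <- pc342_lib()
  g <- find_interference_edges(run, annotate_dataset(run, lib), lib)
  f <- g$edges$factor[1]
  out <- apply_deisotoping(run, g)
  corrected <- out$run$channels[[channel_id(759.6, 184.07, "Positive", 33)]]
  expect_equal(corrected$intensities, rep(50 - f * 100, 21))
  # source channel untouched (no incoming edges)
  expect_equal(out$run$channels[[channel_id(758.6, 184.07, "Positive", 33)]],
               run$channels[[1]])
})

test_that("three-channel cascade uses already-corrected sources", {
  # hand-constructed graph: a -> b (0.4), a -> c (0.1), b -> c (0.4) on
  # constant traces 100 / 60 / 30; expected corrected values 100 / 20 / 12
  a <- const_channel(700.0, 184.07, value = 100)
  b <- const_channel(701.0, 184.07, value = 60)
  c_ <- const_channel(702.0, 184.07, value = 30)
  run <- mrm_run("r1", list(a, b, c_))
  edges <- data.frame(
    source_id = c(a$id, a$id, b$id), affected_id = c(b$id, c_$id, c_$id),
    compound = c("A", "A", "B"), i = c(1L, 2L, 1L), j = 0L,
    factor = c(0.4, 0.1, 0.4), stringsAsFactors = FALSE)
  graph <- structure(list(edges = edges, order = c(b$id, c_$id)),
                     class = "interference_graph")
  out <- apply_deisotoping(run, graph)
  expect_equal(out$run$channels[[a$id]]$intensities, rep(100, 21))
  expect_equal(out$run$channels[[b$id]]$intensities, rep(60 - 0.4 * 100, 21))
  expect_equal(out$run$channels[[c_$id]]$intensities,
               rep(30 - 0.1 * 100 - 0.4 * 20, 21))
})

test_that("redundant source channels subtract once via the pointwise max", {
  # same transition acquired twice (CE differs inside the id grain but ids
  # must differ: use two q3 values inside mass_tol of the prediction)
  s1 <- const_channel(758.6, 184.07, value = 100)
  s2 <- const_channel(758.6, 184.12, value = 90)
  aff <- const_channel(759.6, 184.07, value = 50)
  run <- mrm_run("r1", list(s1, s2, aff))
  lib <- pc342_lib()
  ann <- annotate_dataset(run, lib)
  g <- find_interference_edges(run, ann, lib)
  sub <- g$edges[g$edges$affected_id == aff$id, ]
  expect_equal(nrow(sub), 2)  # both source channels predict the same spot
  f <- sub$factor[1]
  out <- apply_deisotoping(run, g)
  # max(f*100, f*90) subtracted once, not the sum
  expect_equal(out$run$channels[[aff$id]]$intensities, rep(50 - f * 100, 21))
})

test_that("multi-annotated source channels use the max-factor annotation", {
  s <- const_channel(758.6, 184.07, value = 100)
  aff <- const_channel(759.6, 184.07, value = 50)
  run <- mrm_run("r1", list(s, aff))
  # two eligible compounds on the same source channel with different factors
  # (a different assumed fragmentation gives a different neutral fragment)
  lib <- rbind(pc342_lib(),
               lib_row("alt_cmpd", 758.6, 184.07, "C42H81O8NP",
                       "C10H20O2", "ConstantProduct"))
  ann <- annotate_dataset(run, lib)
  g <- find_interference_edges(run, ann, lib)
  both <- g$edges[g$edges$affected_id == aff$id, ]
  expect_equal(nrow(both), 2)
  f_max <- max(both$factor)
  out <- apply_deisotoping(run, g)
  expect_equal(out$run$channels[[aff$id]]$intensities, rep(50 - f_max * 100, 21))
  expect_setequal(out$report$compound,
                  both$compound[which.max(both$factor)])
})

test_that("clamp_negative floors residuals at zero", {
  s <- const_channel(758.6, 184.07, value = 1000)
  aff <- const_channel(759.6, 184.07, value = 50)
  run <- mrm_run("r1", list(s, aff))
  lib <- pc342_lib()
  g <- find_interference_edges(run, annotate_dataset(run, lib), lib)
  neg <- apply_deisotoping(run, g)$run$channels[[aff$id]]$intensities
  expect_true(all(neg < 0))
  cfg <- deiso_config(clamp_negative = TRUE)
  clamped <- apply_deisotoping(run, g, cfg)$run$channels[[aff$id]]$intensities
  expect_true(all(clamped == 0))
})

test_that("graphs referencing unknown channels are rejected", {
  run <- mrm_run("r1", list(const_channel(758.6, 184.07)))
  edges <- data.frame(source_id = "nope", affected_id = run$channels[[1]]$id,
                      compound = "x", i = 1L, j = 0L, factor = 0.1)
  graph <- structure(list(edges = edges, order = run$channels[[1]]$id),
                     class = "interference_graph")
  expect_error(apply_deisotoping(run, graph), "absent from run")
})

# ---- property suites (criterion-level versions live in test-acceptance.R) ---

random_interference_run <- function() {
  n <- sample(3:6, 1)
  # annotated source at 758.6 plus channels on its isotopologue ladder
  q1 <- 758.6 + c(0, sort(sample(1:12, n - 1)))
  channels <- lapply(q1, function(q) {
    t <- seq(0, 5, by = 0.25)
    mrm_channel(q, 184.07, "Positive", 33, t,
                abs(rnorm(length(t), 50, 30)))
  })
  mrm_run("r", channels)
}

test_that("pointwise dominance and identity hold on random instances", {
  set.seed(101)
  lib <- pc342_lib()
  for (rep in 1:50) {
    run <- random_interference_run()
    ann <- annotate_dataset(run, lib)
    g <- find_interference_edges(run, ann, lib)
    out <- apply_deisotoping(run, g)
    for (id in names(run$channels)) {
      expect_true(all(out$run$channels[[id]]$intensities <=
                        run$channels[[id]]$intensities + 1e-12))
    }
    # identity: empty graph leaves the run untouched
    empty <- structure(list(edges = g$edges[0, ], order = character(0)),
                       class = "interference_graph")
    expect_identical(apply_deisotoping(run, empty)$run, run)
  }
})

test_that("correction is linear in the input intensities (clamp off)", {
  set.seed(202)
  lib <- pc342_lib()
  run <- mrm_run("r1", list(gaussian_channel(758.6, apex = 4),
                            gaussian_channel(759.6, apex = 6, height = 400),
                            gaussian_channel(760.6, apex = 5, height = 200)))
  ann <- annotate_dataset(run, lib)
  g <- find_interference_edges(run, ann, lib)
  base <- apply_deisotoping(run, g)$run
  for (c_scale in c(0.5, 3, 17)) {
    scaled <- run
    scaled$channels <- lapply(scaled$channels, function(ch) {
      ch$intensities <- ch$intensities * c_scale; ch
    })
    out <- apply_deisotoping(scaled, g)$run
    for (id in names(run$channels)) {
      expect_equal(out$channels[[id]]$intensities,
                   base$channels[[id]]$intensities * c_scale,
                   tolerance = 1e-12)
    }
  }
})

test_that("ascending-Q1 cascade equals fixed-point iteration of the system", {
  set.seed(303)
  # second eligible compound on the 759.6 channel creates a genuine chain
  lib <- rbind(pc342_lib(),
               lib_row("SM_38:1;O2", 759.6, 184.07, "C43H88N2O6P",
                       "C5H15O4NP", "ConstantProduct"))
  run <- mrm_run("r1", list(gaussian_channel(758.6, apex = 4),
                            gaussian_channel(759.6, apex = 4.5, height = 500),
                            gaussian_channel(760.6, apex = 5, height = 250)))
  ann <- annotate_dataset(run, lib)
  g <- find_interference_edges(run, ann, lib)
  cascade <- apply_deisotoping(run, g)$run
  # oracle: iterate x_T = raw_T - sum_S f * x_S until convergence
  raw <- lapply(run$channels, `[[`, "intensities")
  x <- raw
  for (iter in 1:20) {
    x_new <- raw
    for (e in seq_len(nrow(g$edges))) {
      tid <- g$edges$affected_id[e]
      x_new[[tid]] <- x_new[[tid]] - g$edges$factor[e] * x[[g$edges$source_id[e]]]
    }
    x <- x_new
  }
  for (id in names(raw)) {
    expect_equal(cascade$channels[[id]]$intensities, x[[id]], tolerance = 1e-9)
  }
})
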