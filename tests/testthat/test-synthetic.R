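test_that("the default design reproduces the study layout", {
  des <- her_design_default()
  expect_s3_class(des, "her_design")
  expect_setequal(unique(des$cell_line), her_cell_lines()$name)
  egf_doses <- sort(unique(des$egf_ng_ml[des$egf_ng_ml > 0 &
                                           des$hrg_ng_ml == 0]))
  hrg_doses <- sort(unique(des$hrg_ng_ml[des$hrg_ng_ml > 0 &
                                           des$egf_ng_ml == 0]))
  expect_equal(range(egf_doses), c(0.6, 30))
  expect_equal(range(hrg_doses), c(4, 120))
  # dose-response sampling times are exactly 0/10/30/60 min
  dr <- des[des$measurement == "pR1t" & des$time_min <= 60 &
              des$egf_ng_ml == 0.6, ]
  expect_setequal(unique(dr$time_min), c(0, 10, 30, 60))
  # the combined-ligand condition is present
  expect_true(any(des$egf_ng_ml == 12 & des$hrg_ng_ml == 40))
  # 2-h time courses cover all three measurement families
  tc <- des[des$egf_ng_ml == 12 & des$hrg_ng_ml == 40, ]
  expect_setequal(unique(tc$measurement),
                  c("pR1t", "pR2t", "pR3t", "pR1i", "pR2i", "pR3i",
                    "mR1t", "mR2t", "mR3t"))
  expect_equal(max(tc$time_min), 120)
  # blocking conditions at 10 and 30 min
  blk <- des[des$block > 0, ]
  expect_setequal(unique(blk$time_min), c(10, 30))
  expect_equal(unique(blk$block), 0.95)
  expect_true(all(des$replicates >= 2))
})

test_that("cv = 0 reproduces noiseless model output exactly", {
  des <- her_design_small("parental")
  dat <- her_synthesize(des, truth_params, cv = 0, seed = 3)
  pred <- her_predict_design(des, truth_params)
  expect_equal(dat$value, rep(pred, times = des$replicates))
  expect_equal(nrow(dat), sum(des$replicates))
})

test_that("generation is deterministic given the seed", {
  des <- her_design_small("parental")
  d1 <- her_synthesize(des, truth_params, cv = 0.1, seed = 42)
  d2 <- her_synthesize(des, truth_params, cv = 0.1, seed = 42)
  expect_identical(d1, d2)
  d3 <- her_synthesize(des, truth_params, cv = 0.1, seed = 43)
  expect_false(identical(d1$value, d3$value))
})

test_that("replicate means converge to the noiseless value", {
  # law of large numbers on one condition with 10,000 replicates
  des <- data.frame(cell_line = "parental", egf_ng_ml = 12, hrg_ng_ml = 0,
                    block = 0, time_min = 30, measurement = "pR1t",
                    replicates = 10000L)
  class(des) <- c("her_design", "data.frame")
  cv <- 0.1
  dat <- her_synthesize(des, truth_params, cv = cv, seed = 9)
  mu <- her_predict_design(des, truth_params)
  expect_equal(mean(dat$value) / mu, 1, tolerance = 3 * cv / sqrt(10000))
})

test_that("scaling all pf scales all phospho records linearly", {
  des <- her_design_small("parental")
  des <- des[grepl("^p", des$measurement), ]
  pf_names <- grep("^pf", her_free_names(), value = TRUE)
  p2 <- her_set_free(truth_params,
                     setNames(her_free_values(truth_params)[pf_names] * 3,
                              pf_names))
  d1 <- her_synthesize(des, truth_params, cv = 0, seed = 1)
  d2 <- her_synthesize(des, p2, cv = 0, seed = 1)
  expect_equal(d2$value, 3 * d1$value, tolerance = 1e-8)
})

test_that("datasets round-trip losslessly through CSV", {
  des <- her_design_small("parental")
  dat <- her_synthesize(des, truth_params, cv = 0.1, seed = 5)
  f <- tempfile(fileext = ".csv")
  her_write_dataset(dat, f)
  back <- her_read_dataset(f)
  expect_equal(nrow(back), nrow(dat))
  for (col in names(back)) {
    if (is.numeric(back[[col]]))
      expect_equal(back[[col]], unname(dat[[col]]), tolerance = 1e-12)
    else expect_equal(back[[col]], dat[[col]])
  }
  unlink(f)
})
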