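test_that("identical data in both groups gives a null exposure effect", {
  ex <- climb_experiment(n_tubes = 4, effect = 1, seed = 51)
  one <- ex$tab[ex$tab$tube <= 4, ]
  dup <- one
  dup$tube <- dup$tube + 4
  tab <- rbind(one, dup)
  cd <- climber_data(tab, ex$design, group_size = 10)
  r <- test_exposure_ratio(cd, "rm_anova")
  expect_lt(abs(r$estimate), 1e-12)
  expect_gt(r$terms$p_value, 0.99)
  hm <- subsample_frames(join_design(frame_mean_heights(tab), ex$design),
                         every = 30)
  r2 <- suppressWarnings(test_exposure_height(hm))
  expect_lt(abs(r2$estimate), 1e-6)
})

test_that("the binomial GLMM returns the exposure term and flags", {
  ex <- climb_experiment(n_tubes = 5, effect = 1, seed = 52)
  gd <- ratio_glmm_data(ex$tab, ex$design, subsample_every = 50)
  r <- suppressWarnings(test_exposure_ratio(gd, "binomial_glmm"))
  expect_equal(r$terms$term, "Exposure")
  expect_true(r$terms$p_value >= 0 && r$terms$p_value <= 1)
  expect_true(is.finite(r$estimate) && is.finite(r$se))
  expect_type(r$singular, "logical")
})

test_that("a strong speed reduction is detected by ANOVA and LME", {
  ex <- climb_experiment(n_tubes = 15, effect = 0.6, seed = 53)
  cd <- climber_data(ex$tab, ex$design, group_size = 10)
  expect_lt(test_exposure_ratio(cd, "rm_anova")$terms$p_value, 0.01)
  hm <- subsample_frames(join_design(frame_mean_heights(ex$tab),
                                     ex$design), every = 15)
  r <- suppressWarnings(test_exposure_height(hm))
  expect_lt(r$terms$p_value, 0.01)
  # sham climbs higher than exposed: sham - exposed > 0
  expect_gt(r$estimate, 0)
})

test_that("the LME coefficient recovers the injected height difference", {
  ex <- climb_experiment(n_tubes = 15, effect = 0.7, seed = 54)
  hm <- join_design(frame_mean_heights(ex$tab), ex$design)
  r <- suppressWarnings(test_exposure_height(subsample_frames(hm, 15)))
  # injected difference: group means of the simulated tube-average heights
  truth <- tapply(hm$Ycm, hm$Exposure, mean)
  injected <- unname(truth["sham"] - truth["exposed"])
  expect_lt(abs(r$estimate - injected), 2 * r$se)
})

test_that("condition enters the LME as a crossed fixed effect", {
  ex1 <- climb_experiment(n_tubes = 4, effect = 1, seed = 55)
  ex2 <- climb_experiment(n_tubes = 4, effect = 1, seed = 56)
  ex2$tab$tube <- ex2$tab$tube + 8
  ex2$design$tube <- ex2$design$tube + 8
  ex2$design$id <- paste0("c2_", ex2$design$id)
  ex1$design$condition <- "90uT"; ex2$design$condition <- "300uT"
  tab <- rbind(ex1$tab, ex2$tab)
  design <- rbind(ex1$design, ex2$design)
  hm <- subsample_frames(join_design(frame_mean_heights(tab), design),
                         every = 30)
  r <- suppressWarnings(test_exposure_height(hm))
  expect_setequal(r$terms$term,
                  c("Exposure", "condition", "Exposure:condition"))
  expect_true(all(r$terms$p_value >= 0 & r$terms$p_value <= 1))
})

test_that("degenerate designs raise informative errors", {
  ex <- climb_experiment(n_tubes = 3, effect = 1, seed = 57)
  hm <- join_design(frame_mean_heights(ex$tab), ex$design)
  hm$Exposure <- "sham"
  expect_error(test_exposure_height(hm), "two Exposure levels")
  cd <- climber_data(ex$tab, ex$design)
  cd$Exposure <- "sham"
  expect_error(test_exposure_ratio(cd, "rm_anova"), "two Exposure levels")
  bad <- ex$design
  bad$tube[2] <- bad$tube[1]
  expect_error(join_design(ex$tab, bad), "several ids")
})
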