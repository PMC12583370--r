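test_that("corrected_mean does background subtraction with clipping", {
  ch <- matrix(50, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(corrected_mean(ch, mask, 10), 40)
  expect_equal(corrected_mean(ch, mask, 60), 0)
  expect_error(corrected_mean(ch, matrix(FALSE, 10, 10), 10), "empty mask")
})

test_that("compartment masks are disjoint for disjoint markers and contained in the cell", {
  net <- generate_network(6, 1, 3, seed = 15)
  f <- render_field(net, spec = render_spec(seed = 4))
  cfg <- mn_config()
  masks <- compartment_masks(f, cfg)
  expect_false(any(masks$mito & masks$er))
  expect_true(all(masks$cell[masks$mito]))
  expect_true(all(masks$cell[masks$er]))
  # estimated mito mask overlaps the generating tube well
  jac <- sum(masks$mito & f$truth$mito_mask) /
    sum(masks$mito | f$truth$mito_mask)
  expect_gte(jac, 0.8)
})

test_that("blank marker channels give empty flagged masks", {
  blank <- fluorescence_field(matrix(5, 64, 64), matrix(0, 64, 64),
                              matrix(0, 64, 64), pixel_size = 0.1)
  masks <- compartment_masks(blank, mn_config(threshold_method = "otsu"))
  expect_false(any(masks$mito))
  expect_true("empty_mito_mask" %in% masks$flags)
  mc <- measure_calcium(blank, mn_config(threshold_method = "otsu"))
  expect_true(is.na(mc$ca_mito))
  expect_match(mc$qc_flag, "empty_mito_mask")
})

test_that("homogeneous calcium gives equal compartment means; localized signal ranks them", {
  net <- generate_network(6, 1, 3, seed = 16)
  f <- render_field(net, spec = render_spec(noise_sd = 0, seed = 5))
  # truly uniform calcium: every mask sees the same intensity
  f$calcium <- matrix(50, nrow(f$calcium), ncol(f$calcium))
  f$controls$calcium <- matrix(10, nrow(f$calcium), ncol(f$calcium))
  mc <- measure_calcium(f, mn_config())
  expect_equal(mc$ca_mito, mc$ca_er)
  expect_equal(mc$ca_mito, mc$ca_whole_cell)
  expect_equal(mc$ca_mito, 40)

  f2 <- render_field(net, calcium = calcium_levels(20, 120, 20),
                     spec = render_spec(noise_sd = 0, seed = 5))
  mc2 <- measure_calcium(f2, mn_config())
  expect_gt(mc2$ca_mito, mc2$ca_er)
})

test_that("linearity and background invariance of corrected means", {
  net <- generate_network(5, 0, 5, seed = 17)
  f <- render_field(net, spec = render_spec(noise_sd = 2, seed = 6))
  bg <- estimate_background(f$calcium, f$controls$calcium)
  m <- f$truth$mito_mask
  base <- corrected_mean(f$calcium, m, bg)
  # scaling the channel by k scales the corrected mean by k (bg scaled too)
  expect_equal(corrected_mean(f$calcium * 3, m, bg * 3), 3 * base)
  # adding c to channel and control leaves the corrected mean unchanged
  bg2 <- estimate_background(f$calcium + 7, f$controls$calcium + 7)
  expect_equal(corrected_mean(f$calcium + 7, m, bg2), base)
})

test_that("noisy compartment means recover truth within the CLT bound", {
  # quick version of the acceptance check: 20 fields, noise_sd = 5
  net <- generate_network(8, 2, 2, seed = 18)
  ok <- 0L; total <- 0L
  for (i in 1:20) {
    f <- render_field(net, calcium = calcium_levels(40, 100, 60),
                      spec = render_spec(noise_sd = 5, background_level = 10,
                                         seed = 600 + i))
    bg <- estimate_background(f$calcium, f$controls$calcium)
    for (cmp in list(c("mito_mask", "mito"), c("er_mask", "er"),
                     c("cell_mask", "whole_cell"))) {
      mask <- f$truth[[cmp[1]]]
      est <- corrected_mean(f$calcium, mask, bg)
      truth <- f$truth$expected_means[[cmp[2]]]
      bound <- 3 * 5 / sqrt(sum(mask))
      total <- total + 1L
      if (abs(est - truth) <= bound) ok <- ok + 1L
    }
  }
  expect_gte(ok / total, 0.9)
})
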