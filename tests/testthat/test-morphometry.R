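test_that("build_graph classifies the canonical Y and a straight rod", {
  yk <- y_skeleton(10)
  g <- build_graph(yk)
  expect_equal(g$branch_count, 3L)
  expect_equal(g$junction_count, 1L)
  expect_equal(g$rod_count, 0L)
  expect_equal(g$component_count, 1L)
  # three 10-px arms + the shared center, counted once per branch
  expect_equal(sort(g$branch_lengths_px), c(11, 11, 11))
  expect_equal(branching(g), 1 / 3)
  expect_equal(fragmentation(g), 0)

  rod <- matrix(FALSE, 20, 20); rod[5, 3:17] <- TRUE
  gr <- build_graph(rod)
  expect_equal(gr$branch_count, 1L)
  expect_equal(gr$junction_count, 0L)
  expect_equal(gr$rod_count, 1L)
  expect_equal(gr$branch_lengths_px, 15)
  expect_equal(fragmentation(gr), 1)
})

test_that("metrics flag the empty graph instead of crashing", {
  g <- build_graph(matrix(FALSE, 5, 5))
  expect_equal(g$branch_count, 0L)
  expect_true("empty_skeleton" %in% g$qc_flags)
  expect_warning(expect_true(is.na(fragmentation(g))), "undefined")
  expect_warning(expect_true(is.na(branching(g))), "undefined")
  expect_warning(expect_true(is.na(mean_branch_length(g))), "undefined")
})

test_that("isolated pixels and loops are handled as 1-px rods / closed branches", {
  sk <- matrix(FALSE, 20, 20)
  sk[3, 3] <- TRUE                       # isolated pixel
  th <- seq(0, 2 * pi, length.out = 200) # ring (closed loop, no junction)
  sk[cbind(12 + round(5 * sin(th)), 12 + round(5 * cos(th)))] <- TRUE
  sk <- skeletonize(sk)
  g <- build_graph(sk)
  expect_equal(g$branch_count, 2L)
  expect_equal(g$junction_count, 0L)
  expect_equal(g$rod_count, 2L)
  expect_true(1 %in% g$branch_lengths_px)
})

test_that("junction merging absorbs short bridges between junction clusters", {
  # two degree-3 junctions joined by a 2-px bridge; the four outer arms
  # leave diagonally so no incidental junction clusters form
  sk <- matrix(FALSE, 40, 40)
  A <- c(20, 15); B <- c(20, 18)
  sk[A[1], A[2]] <- TRUE; sk[B[1], B[2]] <- TRUE
  sk[20, 16:17] <- TRUE                       # bridge
  for (t in 1:6) {
    sk[A[1] - t, A[2] - t] <- TRUE            # NW arm at A
    sk[A[1] + t, A[2] - t] <- TRUE            # SW arm at A
    sk[B[1] - t, B[2] + t] <- TRUE            # NE arm at B
    sk[B[1] + t, B[2] + t] <- TRUE            # SE arm at B
  }
  g0 <- build_graph(sk)
  expect_equal(g0$junction_count, 2L)
  expect_equal(g0$branch_count, 5L)
  g1 <- build_graph(sk, junction_merge_px = 3)
  expect_equal(g1$junction_count, 1L)
  expect_equal(g1$branch_count, 4L)
  expect_equal(g1$rod_count, 0L)
})

test_that("scale property: pixel_size scales length only", {
  net <- generate_network(8, 2, 3, seed = 21)
  g <- build_graph(net$skeleton)
  expect_equal(mean_branch_length(g, 0.2), 2 * mean_branch_length(g, 0.1))
  expect_equal(fragmentation(g), net$true_rod_count / net$true_branch_count)
  expect_equal(branching(g),
               net$true_junction_count / net$true_branch_count)
})

test_that("adding a rod strictly increases fragmentation when below 1", {
  set.seed(40)
  for (i in 1:5) {
    # junction-bearing networks: fragmentation < 1, so one more rod
    # strictly raises (R+1)/(B+1) above R/B
    top <- random_topology(max_b = 15, max_j = 4)
    while (top$J == 0) top <- random_topology(max_b = 15, max_j = 4)
    net <- generate_network(top$B, top$J, top$R, seed = 100 + i)
    g1 <- build_graph(net$skeleton)
    sk2 <- net$skeleton
    sk2[2, 2:12] <- TRUE   # extra rod in the clear margin corner
    g2 <- build_graph(sk2)
    expect_equal(g2$rod_count, g1$rod_count + 1L)
    expect_gt(fragmentation(g2), fragmentation(g1))
  }
})

test_that("measure_field recovers noiseless rendered truth and flags blanks", {
  net <- generate_network(10, 2, 4, seed = 33)
  f <- render_field(net, spec = render_spec(noise_sd = 0,
                                            background_level = 0, seed = 2))
  met <- measure_field(f, mn_config(threshold_method = "otsu"))
  expect_equal(met$branch_count, 10L)
  expect_equal(met$junction_count, 2L)
  expect_equal(met$rod_count, 4L)
  expect_equal(met$fragmentation, 0.4)
  expect_equal(met$qc_flag, "")

  blank <- fluorescence_field(matrix(0, 64, 64), matrix(0, 64, 64),
                              matrix(0, 64, 64), pixel_size = 0.1)
  mb <- measure_field(blank, mn_config(threshold_method = "otsu"))
  expect_true(is.na(mb$fragmentation))
  expect_match(mb$qc_flag, "empty_mask|no_branches")
})
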