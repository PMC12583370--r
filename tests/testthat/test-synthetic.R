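test_that("generate_network honours requested topology in the basic cases", {
  # junction-free: disjoint rods only
  net <- generate_network(5, 0, 5, image_shape = c(256, 256), seed = 1)
  expect_equal(net$true_rod_count, 5L)
  expect_equal(net$true_branch_count, 5L)
  g <- build_graph(net$skeleton)
  expect_equal(g$branch_count, 5L)
  expect_equal(g$junction_count, 0L)
  expect_equal(g$component_count, 5L)

  # minimal junction case: one Y
  nety <- generate_network(3, 1, 0, seed = 2)
  gy <- build_graph(nety$skeleton)
  expect_equal(gy$branch_count, 3L)
  expect_equal(gy$junction_count, 1L)
  expect_equal(gy$component_count, 1L)

  # the mixed reference case
  netm <- generate_network(12, 4, 3, seed = 7)
  gm <- build_graph(netm$skeleton)
  expect_equal(c(gm$branch_count, gm$junction_count, gm$rod_count),
               c(12L, 4L, 3L))
})

test_that("infeasible topologies are rejected up front", {
  expect_error(generate_network(5, 0, 3, seed = 1), "infeasible")
  expect_error(generate_network(4, 2, 2, seed = 1), "infeasible")   # m < 2J+1
  expect_error(generate_network(20, 2, 2, seed = 1), "infeasible")  # m > 4J
  expect_error(generate_network(40, 12, 0, image_shape = c(48, 48),
                                seed = 1), "too small")
})

test_that("generated skeletons are fixed points of skeletonize", {
  set.seed(77)
  for (i in 1:5) {
    top <- random_topology(max_b = 20, max_j = 6)
    net <- generate_network(top$B, top$J, top$R, seed = 300 + i)
    expect_identical(unname(skeletonize(net$skeleton)),
                     unname(net$skeleton))
  }
})

test_that("round-trip exactness holds across many random topologies", {
  set.seed(123)
  for (i in 1:30) {
    top <- random_topology()
    net <- generate_network(top$B, top$J, top$R, seed = 4000 + i)
    g <- build_graph(net$skeleton)
    expect_equal(g$branch_count, top$B)
    expect_equal(g$junction_count, top$J)
    expect_equal(g$rod_count, top$R)
    expect_equal(sort(g$branch_lengths_px),
                 sort(net$true_branch_lengths))
  }
})

test_that("identical seeds reproduce identical networks and renders", {
  n1 <- generate_network(9, 2, 3, seed = 5)
  n2 <- generate_network(9, 2, 3, seed = 5)
  expect_identical(n1$skeleton, n2$skeleton)
  f1 <- render_field(n1, spec = render_spec(seed = 9))
  f2 <- render_field(n1, spec = render_spec(seed = 9))
  expect_identical(f1$calcium, f2$calcium)
  expect_identical(f1$mito, f2$mito)
  expect_identical(f1$er, f2$er)
})

test_that("rendered calcium has the requested compartment expectations", {
  net <- generate_network(8, 2, 2, seed = 11)
  ca <- calcium_levels(whole_cell = 40, mito = 100, er = 60)
  f <- render_field(net, calcium = ca,
                    spec = render_spec(noise_sd = 0, background_level = 0,
                                       seed = 3))
  expect_equal(mean(f$calcium[f$truth$mito_mask]), 100)
  expect_equal(mean(f$calcium[f$truth$er_mask]), 60)
  expect_error(render_field(net, calcium = calcium_levels(whole_cell = 5),
                            spec = render_spec(background_level = 10)))
})

test_that("effect_spec validates and generate_experiment produces a balanced layout", {
  expect_error(effect_spec(n_replicates = 1))
  expect_error(effect_spec(fields_per_replicate = 0))

  spec <- effect_spec(n_replicates = 2, fields_per_replicate = 1, seed = 9)
  ex <- generate_experiment(spec)
  expect_equal(nrow(ex$fields), 3 * 2 * 2 * 1)
  tab <- table(ex$fields$katp_level, ex$fields$rotenone)
  expect_true(all(tab == 2))
  # stats layer runs with positive residual df on the minimal design
  agg <- aggregate_replicates(ex$fields)
  at <- two_way_anova(agg$fragmentation, agg$katp_level, agg$rotenone)
  expect_gt(at$df[4], 0)
  expect_true(all(at$p_value[1:3] >= 0 & at$p_value[1:3] <= 1))
})

test_that("experiment generation is seed-deterministic and records truth", {
  s <- effect_spec(n_replicates = 2, fields_per_replicate = 2, seed = 42)
  e1 <- generate_experiment(s)
  e2 <- generate_experiment(s)
  expect_identical(e1$fields, e2$fields)
  expect_identical(e1$mtt, e2$mtt)
  expect_equal(nrow(e1$truth), 6 * length(s$variables))
  # null spec: all condition means equal the baselines
  expect_true(all(tapply(e1$truth$true_mean, e1$truth$variable,
                         function(x) length(unique(x))) == 1))
})

test_that("reported_effects sets the documented shift directions", {
  spec <- reported_effects(effect_spec(), magnitude = 2)
  sh <- spec$shifts
  expect_gt(sh$fragmentation$b[["rotenone"]], 0)
  expect_lt(sh$branching$b[["rotenone"]], 0)
  expect_lt(sh$ca_mito$b[["rotenone"]], 0)
  expect_lt(sh$ca_er$b[["rotenone"]], 0)
  expect_lt(sh$ca_whole_cell$b[["rotenone"]], 0)
  expect_true(all(sh$mean_branch_length_um$a > 0))
  expect_equal(sh$fragmentation$b[["rotenone"]],
               2 * spec$variables$fragmentation$between_sd)
})
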