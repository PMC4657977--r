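test_that("batches are reproducible from the master seed", {
  f <- odour_field_gaussian(c(0, 0), 10)
  prot <- protocol(f, arena_rectangle(100, 65), 8, 60,
                   start = start_square(c(0, 0), 12), seed = 77)
  b1 <- run_batch(prot, larva_params())
  b2 <- run_batch(prot, larva_params())
  expect_identical(b1$final, b2$final)
  for (i in seq_along(b1$trajectories))
    expect_identical(as.data.frame(b1$trajectories[[i]]),
                     as.data.frame(b2$trajectories[[i]]))
  b3 <- run_batch(protocol(f, arena_rectangle(100, 65), 8, 60,
                           start = start_square(c(0, 0), 12), seed = 78),
                  larva_params())
  expect_false(identical(b1$final$mid_x_mm, b3$final$mid_x_mm))
})

test_that("wall truncation stops at the first head contact", {
  f <- odour_field_uniform()
  arena <- arena_circle(30)
  prot <- protocol(f, arena, 6, 600, start = start_square(c(0, 0), 4),
                   truncation = trunc_wall(), seed = 5)
  b <- run_batch(prot, larva_params())
  for (tr in b$trajectories) {
    expect_identical(attr(tr, "cause"), "wall")
    h <- cbind(tr$head_x_mm, tr$head_y_mm)
    contacts <- wall_contact(arena, h)$contact
    expect_true(contacts[length(contacts)])       # final row touches
    expect_false(any(contacts[-length(contacts)])) # none before
  }
})

test_that("radius truncation stops once the centroid reaches the target", {
  f <- odour_field_gaussian(c(20, 0), 10)
  prot <- protocol(f, arena_rectangle(100, 65), 5, 600,
                   start = start_square(c(-20, 0), 4),
                   orientation = orient_toward(c(20, 0), 10),
                   truncation = trunc_radius(c(20, 0), 5),
                   discard = "non_arrivals", seed = 2)
  b <- run_batch(prot, larva_params())
  for (tr in b$trajectories) {
    d <- sqrt((tr$mid_x_mm - 20)^2 + tr$mid_y_mm^2)
    expect_lte(d[length(d)], 5)
    expect_true(all(d[-length(d)] > 5))
  }
})

test_that("an impossible discard rule raises an explicit error", {
  f <- odour_field_uniform()
  # target ring is unreachable within the duration
  prot <- protocol(f, arena_rectangle(100, 65), 2, 1,
                   start = start_square(c(-40, 0), 4),
                   truncation = trunc_radius(c(45, 0), 1),
                   discard = "non_arrivals", seed = 3)
  expect_error(suppressWarnings(run_batch(prot, larva_params())),
               "no larvae survived")
})

test_that("start poses respect the protocol's start and orientation rules", {
  f <- odour_field_uniform()
  prot <- protocol(f, arena_rectangle(100, 65), 40, 2,
                   start = start_square(c(10, 5), 12),
                   orientation = orient_toward(c(40, 5), 30), seed = 4)
  b <- run_batch(prot, larva_params(), record = "final")
  expect_true(all(abs(b$final$start_x - 10) <= 6))
  expect_true(all(abs(b$final$start_y - 5) <= 6))
  ang <- atan2(5 - b$final$start_y, 40 - b$final$start_x) * 180 / pi
  expect_true(all(abs(wrap_angle(b$final$start_orientation - ang)) <= 30))
})

test_that("trajectories round-trip through CSV with metadata", {
  tr <- uniform_larva(duration = 10, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  tr2 <- read_trajectory_csv(path)
  expect_equal(as.data.frame(tr2), as.data.frame(tr), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(attr(tr2, "cause"), attr(tr, "cause"))
  expect_identical(attr(tr2, "dt"), attr(tr, "dt"))
  unlink(c(path, paste0(path, ".json")))
})

test_that("record = 'final' matches the last row of a full recording", {
  p <- larva_params()
  f <- odour_field_gaussian(c(0, 0), 10)
  full <- simulate_larva(p, f, duration = 60, seed = 14, larva_index = 2)
  fin <- simulate_larva(p, f, duration = 60, seed = 14, larva_index = 2,
                        record = "final")
  expect_equal(nrow(fin), 2)
  expect_equal(as.numeric(fin[2, ]), as.numeric(full[nrow(full), ]))
})

test_that("YAML experiment configs drive a full run", {
  cfg_path <- tempfile(fileext = ".yaml")
  writeLines(
    "name: mini
larva:
  v_forward: 1.0
mechanisms:
  scaling: 1.0
landscape:
  kind: gaussian
  peak: [0, 0]
  sigma: 10
arena:
  kind: rectangle
  width: 100
  height: 65
protocol:
  n_larvae: 3
  duration: 30
  start: {kind: square, centre: [0, 0], side: 12}
seed: 5
", cfg_path)
  res <- run_experiment(cfg_path)
  expect_equal(res$name, "mini")
  expect_equal(nrow(res$batch$final), 3)
  expect_length(res$straightness, 3)
  # schema violations are caught with actionable messages
  writeLines("protocol: {duration: 10}", cfg_path)
  expect_error(run_experiment(cfg_path), "n_larvae")
  writeLines("nonsense: 1\nprotocol: {n_larvae: 1, duration: 1}", cfg_path)
  expect_error(run_experiment(cfg_path), "unknown config section")
  unlink(cfg_path)
})

test_that("experiment bundles echo the resolved configuration", {
  outdir <- tempfile()
  res <- run_experiment("pi_scan", seed = 2, n = 20, duration = 20,
                        scalings = c(1), out = outdir)
  expect_true(file.exists(file.path(outdir, "config.yaml")))
  expect_true(file.exists(file.path(outdir, "results.json")))
  cfg <- yaml::read_yaml(file.path(outdir, "config.yaml"))
  expect_equal(cfg$n, 20)
  expect_equal(cfg$seed, 2)
  unlink(outdir, recursive = TRUE)
})

test_that("fixture files are deterministic under a seed", {
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  spec <- list(duration = 60, n_turns = 3, n_casts = 4)
  generate_fixture("trajectory", spec, p1, seed = 9)
  generate_fixture("trajectory", spec, p2, seed = 9)
  expect_identical(readLines(p1), readLines(p2))
  p3 <- tempfile(fileext = ".tsv")
  generate_fixture("landscape",
                   list(field = odour_field_gaussian(c(0, 0), 5),
                        extent = c(-5, 5, -5, 5), cell = 1), p3)
  g <- read_odour_grid(p3)
  expect_equal(concentration(g, c(0, 0)), 1)
  unlink(c(p1, p2, p3, paste0(c(p1, p2), ".json")))
})
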