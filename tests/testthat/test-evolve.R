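test_that("genome encode/decode round-trips exactly", {
  set.seed(3)
  for (i in 1:20) {
    g <- runif(7)
    expect_equal(genome_encode(genome_decode(g)), g,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(genome_decode(runif(6)), "genome")
  expect_error(genome_decode(c(runif(6), 1.2)), "genome")
  # bounds map onto the parameter box
  lo <- genome_decode(rep(0, 7)); hi <- genome_decode(rep(1, 7))
  expect_equal(c(lo$w11, lo$tau1, lo$g_s), c(-16, 0.1, -50),
               ignore_attr = TRUE)
  expect_equal(c(hi$w11, hi$tau1, hi$g_s), c(16, 10, 50),
               ignore_attr = TRUE)
})

test_that("battery construction is deterministic and spec-shaped", {
  b1 <- fitness_battery(seed = 4)
  b2 <- fitness_battery(seed = 4)
  expect_identical(b1, b2)
  expect_equal(sort(unique(b1$width)), c(1, 3))
  expect_true(all(b1$height >= 0.5 & b1$height <= 1))
  expect_true(all(abs(b1$offset) %in% c(6, 8, 10)))
})

test_that("a stationary agent scores the closed-form fitness of its battery", {
  battery <- fitness_battery(seed = 2, n_narrow = 3, n_wide = 3)
  # stationary: narrow trials score 0; wide trials score
  # min(1, d_start / (L/2 - d_start))
  wide <- battery$kind == "wide"
  expected <- mean(c(rep(0, sum(!wide)),
                     pmin(1, abs(battery$offset[wide]) /
                            (20 - abs(battery$offset[wide])))))
  expect_equal(fitness(genome_encode(inert_agent()), battery), expected,
               tolerance = 1e-12)
})

test_that("fitness is order-free over trials", {
  set.seed(8)
  g <- runif(7)
  battery <- fitness_battery(seed = 5, n_narrow = 3, n_wide = 3)
  perm <- battery[sample(nrow(battery)), ]
  expect_equal(fitness(g, battery), fitness(g, perm))
})

test_that("mirroring the motor genes and start offsets leaves fitness unchanged", {
  set.seed(21)
  battery <- fitness_battery(seed = 6, n_narrow = 2, n_wide = 2)
  mirrored_battery <- battery
  mirrored_battery$offset <- -mirrored_battery$offset
  for (i in 1:20) {
    g <- runif(7)
    g_mirror <- g
    g_mirror[c(2, 4)] <- 1 - g[c(2, 4)]   # negate w21 and theta2
    f1 <- fitness(g, battery)
    f2 <- fitness(g_mirror, mirrored_battery)
    expect_equal(f1, f2, tolerance = 1e-9)
  }
})

test_that("the GA is reproducible and its best-so-far trace non-decreasing", {
  cfg <- evolve_config(pop = 10, generations = 4,
                       battery_args = list(n_narrow = 2, n_wide = 2))
  r1 <- evolve_agents(cfg, seed = 42)
  r2 <- evolve_agents(cfg, seed = 42)
  expect_identical(r1$best_genome, r2$best_genome)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history$best) >= 0))
  expect_true(all(r1$best_genome >= 0 & r1$best_genome <= 1))
  r3 <- evolve_agents(cfg, seed = 43)
  expect_false(identical(r1$best_genome, r3$best_genome))
})

test_that("the shipped reference agent loads reproducibly and solves its task", {
  a1 <- reference_agent()
  a2 <- reference_agent()
  expect_identical(a1, a2)
  expect_s3_class(a1, "smc_agent")
  # held-out battery (different seed from the freeze battery)
  held_out <- fitness_battery(seed = 977)
  expect_gte(fitness(a1, held_out), 0.85)
})

test_that("genome files round-trip with provenance fields", {
  g <- runif(7)
  f <- tempfile(fileext = ".json")
  write_genome(g, f, seed = 12L, fitness = 0.9)
  x <- read_genome(f)
  expect_equal(x$genome, g)
  expect_equal(x$seed, 12L)
  jsonlite::write_json(list(genes = g), f, auto_unbox = TRUE)
  expect_error(read_genome(f), "genome")
})
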