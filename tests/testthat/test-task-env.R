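test_that("log-quadratic maps implement the stated rules and worked values", {
  sub1 <- reward_map("Sub1")
  add1 <- reward_map("Add1")

  # peak of Sub1 at equal slices: log-odds = w0 = 4
  expect_equal(reward_probability(sub1, stimulus(3, 3)), 1 / (1 + exp(-4)),
               tolerance = 1e-12)
  # peak of Add1 on the full-pie diagonal
  expect_equal(reward_probability(add1, stimulus(2, 4)), 1 / (1 + exp(-4)),
               tolerance = 1e-12)

  grid <- stimulus_grid()
  p_sub <- reward_probability(sub1, grid)
  p_add <- reward_probability(add1, grid)
  expect_true(all(p_sub > 0 & p_sub < 1))
  expect_true(all(p_add > 0 & p_add < 1))

  # dependence only through the subspace feature, checked by enumeration
  expect_equal(tapply(p_sub, abs(grid[, "u1"] - grid[, "u2"]), function(x)
    diff(range(x))) |> unname() |> max(), 0, tolerance = 1e-14)
  expect_equal(tapply(p_add, abs(grid[, "u1"] + grid[, "u2"] - 6), function(x)
    diff(range(x))) |> unname() |> max(), 0, tolerance = 1e-14)

  # symmetry of the quadratic form
  for (a in 1:5) for (b in 1:5) {
    expect_equal(reward_probability(sub1, stimulus(a, b)),
                 reward_probability(sub1, stimulus(b, a)))
  }
})

test_that("best-possible accuracies hit the calibrated ceilings", {
  expect_equal(round(best_possible_accuracy(reward_map("Sub1"))), 95)
  expect_equal(round(best_possible_accuracy(reward_map("Add1"))), 95)
  # sign flip of the off-diagonal entry is an exact symmetry of the grid
  expect_identical(best_possible_accuracy(reward_map("Sub1")),
                   best_possible_accuracy(reward_map("Add1")))
  # log-linear maps are calibrated to 93% exactly
  expect_equal(best_possible_accuracy(reward_map("Sub2")), 93,
               tolerance = 1e-6)
  expect_equal(best_possible_accuracy(reward_map("Add2")), 93,
               tolerance = 1e-6)
})

test_that("log-linear maps lean the right way at the rule boundary", {
  sub2 <- reward_map("Sub2")
  add2 <- reward_map("Add2")
  # equal slices / sum exactly six fall just below the strict rules
  expect_lt(reward_probability(sub2, stimulus(3, 3)), 0.5)
  expect_gt(reward_probability(sub2, stimulus(4, 3)), 0.5)
  expect_lt(reward_probability(add2, stimulus(3, 3)), 0.5)
  expect_gt(reward_probability(add2, stimulus(4, 3)), 0.5)
})

test_that("invalid stimuli and map ids are rejected", {
  expect_error(reward_map("Mul1"))
  expect_error(stimulus(0, 3))
  expect_error(reward_probability(reward_map("Sub1"), c(0.5, 3)))
  expect_error(make_condition(5))
  expect_error(generate_trials(reward_map("Sub1"), 3L, 10))
  expect_error(generate_trials(reward_map("Sub1"), 1L, 0))
})

test_that("condition table pairs maps with the right subspace relation", {
  c1 <- make_condition(1)
  expect_equal(c1$task1_map$map_id, "Add1")
  expect_equal(c1$task2_map$map_id, "Add2")
  expect_equal(c1$relation, "same")
  c2 <- make_condition(2)
  expect_equal(c(c2$task1_map$map_id, c2$task2_map$map_id), c("Sub1", "Sub2"))
  expect_equal(c2$relation, "same")
  c4 <- make_condition(4)
  expect_equal(c(c4$task1_map$map_id, c4$task2_map$map_id), c("Sub1", "Add2"))
  expect_equal(c4$relation, "different")
  for (row in 1:4) {
    cc <- make_condition(row)
    expect_equal(cc$relation,
                 if (cc$task1_map$subspace == cc$task2_map$subspace)
                   "same" else "different")
  }
})

test_that("trial generation is uniform, reproducible, and reward-consistent", {
  m <- reward_map("Sub1")
  set.seed(7)
  blk <- generate_trials(m, 1L, 5000)
  # empirical stimulus frequencies close to uniform over 25 cells
  counts <- table(factor(paste(blk$records$u1, blk$records$u2),
                         levels = paste(stimulus_grid()[, 1],
                                        stimulus_grid()[, 2])))
  chisq <- sum((counts - 200)^2 / 200)
  expect_lt(chisq, 60)  # df = 24, far tail

  # argmax policy approaches the 95% ceiling
  set.seed(8)
  blk2 <- generate_trials(m, 1L, 10000, policy = "argmax")
  expect_equal(mean(blk2$reward), 0.95, tolerance = 0.01)

  # per-configuration reward rate tracks the map probability: the realised
  # outcome underlying (decision, reward) has rate p(y = 1 | u)
  y_rate <- tapply(blk$y, paste(blk$records$u1, blk$records$u2), mean)
  p <- reward_probability(m, stimulus_grid())
  names(p) <- paste(stimulus_grid()[, 1], stimulus_grid()[, 2])
  expect_lt(max(abs(y_rate - p[names(y_rate)])), 0.06)

  # reproducibility
  set.seed(99); a <- generate_trials(m, 1L, 50)
  set.seed(99); b <- generate_trials(m, 1L, 50)
  expect_identical(a$records, b$records)

  # continuous sampling stays inside the cue space
  set.seed(5)
  cb <- generate_trials(m, 1L, 200, stimuli = "continuous")
  expect_true(all(cb$U[, 1] >= 1 & cb$U[, 1] <= 5))
  expect_false(all(cb$U[, 1] == round(cb$U[, 1])))
})

test_that("trial logs round-trip through CSV", {
  blk <- small_block(30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(blk, path)
  header <- readLines(path, n = 1)
  expect_equal(header, "trial,block,task,u1,u2,decision,reward")
  back <- read_trials(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$records$reward, blk$records$reward)
  expect_equal(back[[1]]$U, blk$U)
})

test_that("map config echo includes calibrated parameters", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_maps_config(path)
  txt <- readLines(path)
  expect_true(any(grepl("^Sub2\\.beta = ", txt)))
  expect_true(any(grepl("^Sub1\\.w0 = 4", txt)))
  beta <- as.numeric(sub(".* = ", "", txt[grepl("^Sub2\\.beta", txt)]))
  expect_gt(beta, 0)
})
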