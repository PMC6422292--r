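toy_problem <- function(R, M, S) {
  R <- as.matrix(R)
  if (is.null(rownames(R))) rownames(R) <- paste0("J", seq_len(nrow(R)))
  if (is.null(colnames(R))) colnames(R) <- paste0("m", seq_len(ncol(R)))
  structure(list(joints = rownames(R), gravity_moments = M, moment_arms = R,
                 strengths = stats::setNames(S, colnames(R))),
            class = "recruitment_problem")
}

test_that("assembled problems match the free-body module joint by joint", {
  cs <- default_constants()
  pos <- build_posture(spinopelvic_params("RT3", 40, 50, "med"), cs)
  chain <- build_chain(pos, cs)
  ms <- build_muscle_set(pos, cs)
  pr <- assemble_problem(chain, ms, pos)
  expect_equal(dim(pr$moment_arms), c(6, nrow(ms$fascicles)))
  for (j in joint_labels()) {
    expect_equal(unname(pr$gravity_moments[j]),
                 superincumbent_load(chain, j)$moment)
  }
  # zero gravity zeroes every demand
  cs0 <- cs; cs0$gravity <- 0
  chain0 <- build_chain(pos, cs0)
  pr0 <- assemble_problem(chain0, ms, pos)
  expect_equal(unname(pr0$gravity_moments), rep(0, 6))
})

test_that("assembly flags unbalanceable joints", {
  cs <- default_constants()
  pos <- build_posture(spinopelvic_params("RT4", 50, 60, "back"), cs)
  chain <- build_chain(pos, cs)
  ms <- build_muscle_set(pos, cs)
  # strip every flexor: back postures need flexion moments somewhere
  ms$fascicles <- ms$fascicles[!ms$fascicles$group %in%
                                 c("rectus_abdominis", "psoas"), ]
  expect_error(assemble_problem(chain, ms, pos), "no flexor crosses")
})

test_that("single-extensor equilibrium and symmetric splitting are exact", {
  s1 <- solve_recruitment(toy_problem(matrix(0.05, 1, 1), 20, 1000))
  expect_equal(unname(s1$muscle_forces), 400)          # f = M / r
  expect_lt(s1$equilibrium_residual, 1e-9)
  s2 <- solve_recruitment(toy_problem(matrix(0.05, 1, 2), 20, c(1000, 1000)))
  expect_equal(unname(s2$muscle_forces), c(200, 200), tolerance = 1e-9)
})

test_that("the cubic criterion splits synergists by strength^1.5", {
  pr <- toy_problem(matrix(0.05, 1, 2), 20, c(1000, 500))
  sol <- solve_recruitment(pr, p = 3)
  ratio <- sol$muscle_forces[[1]] / sol$muscle_forces[[2]]
  expect_equal(ratio, 2^1.5, tolerance = 1e-6)
  # and agrees with the brute-force oracle within 0.1 %
  ora <- oracle_recruitment(pr$moment_arms, 20, c(1000, 500))
  expect_equal(sol$objective_value, ora$objective, tolerance = 1e-3)
})

test_that("antagonists stay silent when gravity already extends the joint", {
  # one joint, extensor + flexor, net extension gravity moment
  pr <- toy_problem(matrix(c(0.05, -0.08), 1, 2), -4, c(1000, 1000))
  sol <- solve_recruitment(pr)
  expect_equal(unname(sol$muscle_forces[1]), 0, tolerance = 1e-6)
  expect_equal(unname(sol$muscle_forces[2]), 50, tolerance = 1e-6)
  # KKT: the silent extensor's reduced gradient must not favour activation
  expect_lte(sum(pr$moment_arms[, 1] * sol$multipliers), 1e-9)
})

test_that("the solver matches exhaustive search on random small programs", {
  set.seed(42)
  for (k in 1:12) {
    nj <- sample(1:2, 1)
    nm <- nj + sample(1:2, 1)          # 2-4 muscles, redundant
    R <- matrix(runif(nj * nm, -0.1, 0.1), nj, nm)
    S <- runif(nm, 300, 2000)
    f_true <- runif(nm, 0, 0.4) * S    # feasibility by construction
    M <- drop(R %*% f_true)
    pr <- toy_problem(R, M, S)
    sol <- solve_recruitment(pr)
    expect_lt(sol$equilibrium_residual, 1e-6)
    ora <- oracle_recruitment(R, M, S)
    expect_equal(sol$objective_value, ora$objective, tolerance = 1e-3)
  }
})

test_that("over-strength activations warn instead of failing", {
  pr <- toy_problem(matrix(0.05, 1, 1), 20, 100)     # needs 400 N from 100 N
  expect_warning(sol <- solve_recruitment(pr), "activation exceeds 1")
  expect_equal(unname(sol$muscle_forces), 400)
})

test_that("reaction forces satisfy conservation and level additivity", {
  cs <- default_constants()
  grid <- sample_grid(cs)
  for (i in seq_len(nrow(grid))) {
    pos <- build_posture(grid[i, ], cs)
    chain <- build_chain(pos, cs)
    ms <- build_muscle_set(pos, cs)
    sol <- solve_recruitment(assemble_problem(chain, ms, pos))
    for (level in c("L4L5", "L5S1")) {
      reaction <- intersegmental_force(chain, ms, sol, level, pos)
      grav <- superincumbent_load(chain, level)$force
      pull <- c(0, 0)
      for (r in seq_len(nrow(ms$fascicles))) {
        if (!level %in% strsplit(ms$fascicles$spanned[r], ",")[[1]]) next
        u <- line_of_action(ms$fascicles[r, ])$unit
        pull <- pull - sol$muscle_forces[[ms$fascicles$name[r]]] * u
      }
      # reaction (on the inferior element) minus all loads on the upper body
      expect_lt(max(abs(reaction - grav - pull)), 1e-6)
      # standing gives a caudally transmitted (downward) resultant
      expect_lt(unname(reaction["y"]), 0)
    }
  }
  expect_error(intersegmental_force(NULL, NULL, NULL, "hip", NULL),
               "unknown joint")
})

test_that("the end-to-end pipeline is deterministic and gravity-scaled", {
  cs <- default_constants()
  p <- spinopelvic_params("RT1", 25, 40, "med")
  r1 <- simulate_configuration(p, cs)
  r2 <- simulate_configuration(p, cs)
  expect_identical(r1, r2)
  expect_gt(r1$fl4l5c, 0)             # standing is compressive at L4L5
  expect_gt(r1$fl5s1c, 0)
  cs0 <- cs; cs0$gravity <- 0
  r0 <- simulate_configuration(p, cs0)
  cols <- c("fl4l5_x", "fl4l5_y", "fl5s1_x", "fl5s1_y", "fl4l5c", "fl4l5s",
            "fl5s1c", "fl5s1s", "f_mf", "f_es", "f_ra")
  expect_equal(unname(unlist(r0[cols])), rep(0, length(cols)),
               tolerance = 1e-9)
})
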