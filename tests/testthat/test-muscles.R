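fas_row <- function(ox, oy, ix, iy, spanned = "L5S1", strength = 100,
                    name = "toy", group = "toy") {
  data.frame(name = name, group = group, ox = ox, oy = oy, ix = ix, iy = iy,
             strength = strength, spanned = paste(spanned, collapse = ","),
             stringsAsFactors = FALSE)
}

toy_posture <- function(joints) {
  structure(list(joints = joints), class = "posture_config")
}

origin_joints <- matrix(0, 6, 2, dimnames = list(joint_labels(), c("x", "y")))

test_that("lines of action are unit vectors along the fascicle", {
  f <- fas_row(0, 0, 0, 0.1)
  expect_equal(line_of_action(f)$unit, c(0, 1))
  f45 <- fas_row(0, 0, 0.1, 0.1)
  expect_equal(line_of_action(f45)$unit, c(sqrt(2) / 2, sqrt(2) / 2))
  expect_error(line_of_action(fas_row(0.2, 0.3, 0.2, 0.3)), "degenerate")
})

test_that("moment arms carry the extension-positive sign convention", {
  pos <- toy_posture(origin_joints)
  # line through the joint centre: zero lever
  expect_equal(moment_arm(fas_row(0, -0.2, 0, 0.2), "L5S1", pos), 0)
  # vertical line posterior of the joint: extensor side, positive
  expect_equal(moment_arm(fas_row(-0.05, -0.2, -0.05, 0.2), "L5S1", pos), 0.05)
  # vertical line anterior of the joint: flexor side, negative
  expect_equal(moment_arm(fas_row(0.08, -0.2, 0.08, 0.2), "L5S1", pos), -0.08)
  # joints not spanned contribute nothing rather than erroring
  expect_equal(moment_arm(fas_row(-0.05, -0.2, -0.05, 0.2), "L3L4", pos), 0)
})

test_that("moment arms are translation invariant and rotation equivariant", {
  pos <- toy_posture(origin_joints)
  f <- fas_row(-0.04, -0.1, -0.06, 0.25)
  r0 <- moment_arm(f, "L5S1", pos)
  # rigid translation of fascicle and joints together
  f_t <- fas_row(-0.04 + 0.3, -0.1 - 0.2, -0.06 + 0.3, 0.25 - 0.2)
  pos_t <- toy_posture(sweep(origin_joints, 2, c(-0.3, 0.2), "-"))
  expect_equal(moment_arm(f_t, "L5S1", pos_t), r0, tolerance = 1e-12)
  # rigid rotation preserves the perpendicular distance and its sign
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  o <- R %*% c(-0.04, -0.1); i <- R %*% c(-0.06, 0.25)
  expect_equal(moment_arm(fas_row(o[1], o[2], i[1], i[2]), "L5S1", pos), r0,
               tolerance = 1e-12)
})

test_that("the default set gives both moment signs at every lumbar joint", {
  cs <- default_constants()
  grid <- sample_grid(cs)
  for (i in seq_len(nrow(grid))) {
    pos <- build_posture(grid[i, ], cs)
    ms <- build_muscle_set(pos, cs)
    for (j in joint_labels()) {
      arms <- spinoload:::fascicle_arms(ms, j, pos)
      expect_true(any(arms > 0), label = paste("extensor at", j))
      expect_true(any(arms < 0), label = paste("flexor at", j))
    }
  }
  # the long extensor pulls on the extensor side of mid-lumbar joints
  pos <- build_posture(spinopelvic_params("RT2", 30, 40, "med"), cs)
  ms <- build_muscle_set(pos, cs)
  es <- ms$fascicles[ms$fascicles$name == "ES", ]
  expect_gt(moment_arm(es, "L3L4", pos), 0)
})

test_that("losing all flexors is a configuration error", {
  cs <- default_constants()
  pos <- build_posture(spinopelvic_params("RT1", 30, 40, "med"), cs)
  ms <- build_muscle_set(pos, cs)
  ms$fascicles <- ms$fascicles[!ms$fascicles$group %in%
                                 c("rectus_abdominis", "psoas"), ]
  expect_error(spinoload:::check_coverage(ms, pos), "without both")
})

test_that("muscle geometry exports to JSON", {
  cs <- default_constants()
  pos <- build_posture(spinopelvic_params("RT3", 40, 50, "front"), cs)
  ms <- build_muscle_set(pos, cs)
  tmp <- tempfile(fileext = ".json")
  export_muscle_geometry_json(ms, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(nrow(back), nrow(ms$fascicles))
  expect_equal(back$strength[back$name == "ES"],
               cs$muscles$erector_spinae$strength)
})
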