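test_that("lumbar orientations reproduce the per-type reference rotations", {
  expect_equal(unname(lumbar_orientations("RT1")), c(-17, -22, -27, -19, -8))
  expect_equal(unname(lumbar_orientations("RT2")), c(-12, -13, -8, -1, 9))
  expect_error(lumbar_orientations("RT5"), "unknown Roussouly type")
})

test_that("sacral rotation is the offset from the default inclination", {
  expect_equal(sacrum_rotation(40, 30), 10)   # 10 deg anterior for SS 40
  expect_equal(sacrum_rotation(30, 30), 0)
  expect_equal(sacrum_rotation(25, 30), -5)   # posterior rotation
  expect_error(sacrum_rotation(60), "design union")
  expect_equal(sacrum_rotation(60, strict = FALSE), 30)
})

test_that("hip shift reproduces the requested pelvic incidence exactly", {
  # unshifted geometry (hip plumb under the midpoint) measures PI = SS
  expect_equal(hip_offset_for_pi(40, 40, 0.09), 0)
  # closure against an independent trigonometric re-measurement
  for (ss in c(25, 40, 55)) for (pi_t in ss + c(-5, 0, 15, 30)) {
    x <- hip_offset_for_pi(pi_t, ss, 0.09)
    measured <- atan2(x, 0.09) * 180 / pi + ss
    expect_equal(measured, pi_t, tolerance = 1e-9)
  }
  # strictly monotone in the target for fixed slope
  xs <- vapply(30:70, hip_offset_for_pi, numeric(1), ss = 40, hip_drop = 0.09)
  expect_true(all(diff(xs) > 0))
  expect_error(hip_offset_for_pi(135, 40, 0.09), "unreachable")
  expect_error(hip_offset_for_pi(50, 40, 0), "positive")
})

test_that("the L5-S1 anterior-axis difference matches the worked values", {
  expect_equal(anterior_axis_angle_difference("RT1", 35), 43)
  expect_equal(anterior_axis_angle_difference("RT2", 35), 26)
  # type whose L5 orientation equals the slope has parallel axes
  cs <- default_constants()
  cs$design$rt$RT3$vertebral_rotation["L5"] <- 35
  expect_equal(anterior_axis_angle_difference("RT3", 35, cs), 0)
  expect_error(anterior_axis_angle_difference("RT1", 50), "design range")
})

test_that("the L5-S1 wedge angle spans -43 to -13 over the design grid", {
  expect_equal(l5s1_wedge_angle("RT1", 35), -43)
  expect_equal(l5s1_wedge_angle("RT3", 35), -13)
  expect_equal(l5s1_wedge_angle("RT2", 25), -16)  # 9 - 25
  cs <- default_constants()
  wedges <- unlist(lapply(rt_labels(), function(rt) {
    e <- spinoload:::rt_entry(rt, cs)
    vapply(e$ss[1]:e$ss[2], l5s1_wedge_angle, numeric(1), rt = rt)
  }))
  expect_identical(range(wedges), c(-43, -13))
  # wedge and axis difference are negatives of each other on extension inputs
  for (rt in rt_labels()) {
    e <- spinoload:::rt_entry(rt, cs)
    for (ss in e$ss)
      expect_equal(anterior_axis_angle_difference(rt, ss),
                   -l5s1_wedge_angle(rt, ss))
  }
})

test_that("thoracic rotation solves the SVA target with closure", {
  cs <- default_constants()
  # identity: asking for the SVA of the unrotated chain returns 0
  orient <- lumbar_orientations("RT2", cs)
  joints <- spinoload:::lumbar_joint_positions(orient, cs$geometry$lumbar_length)
  t12l1 <- joints["T12L1", ]
  corner_x <- -cs$geometry$endplate_width / 2 * cos(30 * pi / 180)
  sva0 <- 100 * (t12l1[1] - corner_x)   # C7 sits straight above T12L1 at 0 deg
  expect_equal(thoracic_rotation_for_sva(sva0, t12l1, corner_x, 0.42), 0,
               tolerance = 1e-7)
  # monotone: larger target, larger (more flexed) rotation
  phis <- vapply(seq(-6, 9, by = 1), thoracic_rotation_for_sva, numeric(1),
                 t12l1 = t12l1, corner_x = corner_x, thorax_length = 0.42)
  expect_true(all(diff(phis) > 0))
  expect_error(
    thoracic_rotation_for_sva(80, t12l1, corner_x, 0.42),
    "achievable"
  )
})

test_that("built postures close on all three imposed alignment parameters", {
  cs <- default_constants()
  grid <- sample_grid(cs)
  for (i in seq_len(nrow(grid))) {
    pos <- build_posture(grid[i, ], cs)
    expect_equal(measure_ss(pos), grid$ss[i], tolerance = 1e-9)
    expect_equal(measure_pi(pos), grid$pi[i], tolerance = 1e-9)
    expect_equal(oracle_sva(pos), pos$params$sva, tolerance = 1e-6)
    expect_equal(oracle_pi(pos), grid$pi[i], tolerance = 1e-9)
    expect_true(all(is.finite(pos$joints)))
    expect_true(all(is.finite(pos$com_positions)))
    # head stays at its default orientation (neck counter-rotation)
    expect_equal(unname(pos$segment_orientations["head"]), 0)
  }
})

test_that("vertebral world orientations depend only on the lumbar type", {
  a <- build_posture(spinopelvic_params("RT3", 35, 40, "back"))
  b <- build_posture(spinopelvic_params("RT3", 45, 60, "front"))
  lv <- c("L1", "L2", "L3", "L4", "L5")
  expect_identical(a$segment_orientations[lv], b$segment_orientations[lv])
  expect_identical(a$joints, b$joints)
})

test_that("lumbar lordosis follows the T12-to-S1 rule", {
  expect_equal(compute_ll(0, 40), 40)
  expect_equal(compute_ll(17, 17), 0)
  expect_equal(compute_ll(-10, 30) - compute_ll(-10, 25), 5)  # linear in SS
  pos <- build_posture(spinopelvic_params("RT1", 30, 40, "med"))
  expect_equal(pos$ll_deg, compute_ll(pos$t12_inclination, 30))
})

test_that("postures export to JSON and read back", {
  pos <- build_posture(spinopelvic_params("RT1", 25, 40, "med"))
  tmp <- tempfile(fileext = ".json")
  export_posture_json(pos, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$ll_deg, pos$ll_deg)
  expect_equal(back$joints$x[back$joints$name == "T12L1"],
               unname(pos$joints["T12L1", "x"]))
})
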