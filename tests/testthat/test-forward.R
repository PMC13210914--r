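test_that("default array has the 13 sensorimotor labels plus 3 orthogonal references", {
  expect_setequal(fix_array$names[!fix_array$is_reference],
                  c("FC1", "C1", "CP1", "FC3", "C3", "CP3", "FC5",
                    "C5", "CP5", "FC7", "C7", "CP7", "C9"))
  expect_equal(sum(fix_array$is_reference), 3)
  # unit orientations
  expect_equal(sqrt(rowSums(fix_array$orientations^2)),
               rep(1, 16), tolerance = 1e-12)
  # scalp sensors are radial
  scalp <- which(!fix_array$is_reference)
  for (i in scalp) {
    u <- fix_array$positions[i, ] - fix_head$center
    u <- u / sqrt(sum(u^2))
    expect_lt(max(abs(u - fix_array$orientations[i, ])), 1e-9)
  }
  # reference axes mutually orthogonal, 35-40 cm out
  refs <- which(fix_array$is_reference)
  O <- fix_array$orientations[refs, ]
  expect_lt(max(abs((O %*% t(O))[upper.tri(diag(3))])), 1e-6)
  d <- sqrt(rowSums(fix_array$positions[refs, ]^2)) -
    fix_head$scalp_radius
  expect_true(all(d >= 0.35 & d <= 0.40))
})

test_that("radial sources are externally silent in the sphere model", {
  set.seed(11)
  for (k in 1:10) {
    p <- stats::rnorm(3); p <- p / sqrt(sum(p^2)) * stats::runif(1, 0.01, 0.08)
    q <- p * 2^-27   # exactly radial moment (power-of-two scaling)
    fp <- stats::rnorm(3); fp <- fp / sqrt(sum(fp^2)) * 0.12
    expect_lt(max(abs(sarvas_field(p, q, fp, fix_head))), 1e-30)
  }
  # dipole at the center: any moment is radial; field defined and zero
  expect_equal(sarvas_field(c(0, 0, 0), c(0, 0, 1e-8), c(0, 0, 0.12),
                            fix_head), c(0, 0, 0))
})

test_that("external radial field matches the primary-current Biot-Savart oracle", {
  set.seed(12)
  for (k in 1:20) {
    p <- stats::rnorm(3); p <- p / sqrt(sum(p^2)) * 0.06
    q <- stats::rnorm(3) * 1e-8
    fp <- stats::rnorm(3); fp <- fp / sqrt(sum(fp^2)) *
      stats::runif(1, 0.095, 0.3)
    rhat <- fp / sqrt(sum(fp^2))
    b_sphere <- sum(sarvas_field(p, q, fp, fix_head) * rhat)
    b_free <- sum(biot_savart_dipole(p, q, fp) * rhat)
    expect_lt(abs(b_sphere - b_free),
              1e-9 * max(abs(b_free), 1e-25))
  }
})

test_that("the forward field is linear in the dipole moment", {
  p <- c(0.02, 0.03, 0.04)
  q <- c(3e-9, -2e-9, 1e-9)
  fp <- c(0, 0.05, 0.11)
  b1 <- sarvas_field(p, q, fp, fix_head)
  expect_identical(sarvas_field(p, 2 * q, fp, fix_head), 2 * b1)
  q2 <- c(-1e-9, 4e-9, 2e-9)
  expect_equal(sarvas_field(p, q + q2, fp, fix_head),
               b1 + sarvas_field(p, q2, fp, fix_head),
               tolerance = 1e-12)
})

test_that("field points inside the sphere and exterior dipoles are rejected", {
  expect_error(sarvas_field(c(0, 0, 0.05), c(1e-9, 0, 0),
                            c(0, 0, 0.05), fix_head), "outside")
  expect_error(sarvas_field(c(0, 0, 0.095), c(1e-9, 0, 0),
                            c(0, 0, 0.2), fix_head), "inside")
})

test_that("lead field entries equal direct Sarvas projections", {
  L <- fix_lead$matrix
  scalp <- which(!fix_array$is_reference)
  set.seed(13)
  for (k in 1:5) {
    i <- sample(length(scalp), 1)
    j <- sample(nrow(fix_grid$vertices), 1)
    B <- sarvas_field(fix_grid$vertices[j, ],
                      fix_grid$orientations[j, ],
                      fix_array$positions[scalp[i], ], fix_head)
    expect_equal(L[i, j],
                 sum(fix_array$orientations[scalp[i], ] * B))
  }
  # a radially oriented probe source would contribute nothing
  j <- 5
  q_rad <- fix_grid$vertices[j, ] * 2^-7   # exactly radial
  col <- vapply(scalp, function(i)
    sum(fix_array$orientations[i, ] *
          sarvas_field(fix_grid$vertices[j, ], q_rad,
                       fix_array$positions[i, ], fix_head)), 0)
  expect_lt(sqrt(sum(col^2)), 1e-30)
})

test_that("sensitivity decays monotonically with source depth", {
  v <- central_vertex(fix_grid, "postcentral gyrus")
  u <- fix_grid$vertices[v, ] / sqrt(sum(fix_grid$vertices[v, ]^2))
  ori <- fix_grid$orientations[v, ]
  scalp <- which(!fix_array$is_reference)
  norms <- vapply(seq(0.07, 0.03, by = -0.01), function(r) {
    col <- vapply(scalp, function(i)
      sum(fix_array$orientations[i, ] *
            sarvas_field(r * u, ori, fix_array$positions[i, ],
                         fix_head)), 0)
    sqrt(sum(col^2))
  }, 0)
  expect_true(all(diff(norms) < 0))
})

test_that("sensitivity map reproduces the anterior-posterior ROI gradient", {
  sm <- sensitivity_map(fix_lead)
  expect_true(all(sm$values >= 0))
  roi <- sm$roi
  best <- roi$roi[which.max(roi$mean)]
  expect_true(best %in% c("precentral gyrus", "postcentral gyrus"))
  expect_lt(roi$mean[roi$roi == "superior parietal lobule"],
            roi$mean[roi$roi == "postcentral gyrus"])
  # single-channel lead: values are absolute entries
  l1 <- fix_lead
  l1$matrix <- fix_lead$matrix[1, , drop = FALSE]
  expect_equal(sensitivity_map(l1)$values, abs(fix_lead$matrix[1, ]))
})

test_that("across-subject sensitivity maps report a between-subject SD", {
  sm <- sensitivity_map(list(fix_lead, fix_lead))
  expect_equal(sm$roi$sd, rep(0, 6))
})

test_that("geometry TSV serialization round-trips", {
  f1 <- tempfile(fileext = ".tsv")
  write_geometry_tsv(fix_array, f1)
  a2 <- read_geometry_tsv(f1)
  expect_equal(a2$names, fix_array$names)
  expect_equal(a2$positions, fix_array$positions, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(a2$is_reference, fix_array$is_reference)
  f2 <- tempfile(fileext = ".tsv")
  write_geometry_tsv(fix_grid, f2)
  g2 <- read_geometry_tsv(f2, head = fix_head)
  expect_equal(g2$roi_labels, fix_grid$roi_labels)
  expect_equal(g2$vertices, fix_grid$vertices, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("invalid geometries are rejected", {
  expect_error(sphere_head(source_radius = 0.1), "source_radius")
  expect_error(sensor_array(c("a", "a"), matrix(0, 2, 3),
                            matrix(c(1, 0, 0, 1, 0, 0), 2, byrow = TRUE),
                            c(FALSE, FALSE)), "unique")
  # off-shell vertex
  expect_error(source_grid(matrix(c(0, 0, 0.05), 1), matrix(c(0, 1, 0), 1),
                           "central sulcus", fix_head), "shell")
  # radial orientation
  expect_error(source_grid(matrix(c(0, 0, 0.07), 1), matrix(c(0, 0, 1), 1),
                           "central sulcus", fix_head), "tangential")
})
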