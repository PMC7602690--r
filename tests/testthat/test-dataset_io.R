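# Landmark tables, fluctuations, moments, constraint detection, angles.

test_that("CSV reading honours the dialect and round-trips", {
  p <- write_tiny_csv(S = 2L, n = 8L)
  ds <- read_landmark_table(p)
  expect_s3_class(ds, "landmark_dataset")
  expect_equal(nrow(ds$coords), 2L)
  expect_equal(ds$n_landmarks, 8L)

  p2 <- tempfile(fileext = ".csv")
  write_landmark_table(ds, p2)
  ds2 <- read_landmark_table(p2)
  expect_equal(ds2$coords, ds$coords, tolerance = 1e-11)
  expect_identical(ds2$gender, ds$gender)

  # adapter config maps a foreign layout onto the native dialect
  df <- utils::read.csv(p)
  names(df)[names(df) == "gender"] <- "sex"
  df$sex <- ifelse(df$sex == "F", "female", "male")
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(df, p3, row.names = FALSE, quote = FALSE)
  ds3 <- read_landmark_table(p3, format_config = list(
    column_map = c(gender = "sex"),
    gender_map = c(female = "F", male = "M")))
  expect_identical(ds3$gender, ds$gender)
})

test_that("malformed tables raise specific errors", {
  p <- write_tiny_csv(S = 3L, n = 8L)
  df <- utils::read.csv(p)

  d1 <- df[, setdiff(names(df), "gender")]
  p1 <- tempfile(fileext = ".csv")
  utils::write.csv(d1, p1, row.names = FALSE, quote = FALSE)
  expect_error(read_landmark_table(p1), "gender")

  d2 <- df
  d2$x1[2] <- "oops"
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(d2, p2, row.names = FALSE, quote = FALSE)
  expect_error(read_landmark_table(p2), "row 2")

  d3 <- df
  d3$gender[1] <- "X"
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(d3, p3, row.names = FALSE, quote = FALSE)
  expect_error(read_landmark_table(p3), "gender code")

  expect_error(read_landmark_table(tempfile()), "not found")
})

test_that("fluctuations are centred and standardisation flags zero variance", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)           # records (1,2), (3,4)
  fl <- compute_fluctuations(list(deltas = x, n_landmarks = 1L))
  expect_equal(fl$mean, c(2, 3))
  expect_equal(fl$deltas, matrix(c(-1, 1, -1, 1), 2, 2), ignore_attr = TRUE)

  set.seed(4)
  y <- matrix(rnorm(50 * 4), 50, 4)
  y[, 3] <- 7                                 # constant column
  fs <- compute_fluctuations(list(deltas = y, n_landmarks = 2L),
                             standardize = TRUE)
  expect_lt(max(abs(colMeans(fs$deltas))), 1e-12)
  expect_true(fs$zero_variance[3])
  expect_equal(unname(colMeans(fs$deltas[, -3]^2)), rep(1, 3))

  cst <- matrix(5, 4, 4)
  fc <- compute_fluctuations(list(deltas = cst, n_landmarks = 2L))
  expect_true(all(fc$deltas == 0))
})

test_that("moment statistics match hand-enumerated values", {
  x <- matrix(c(1, -1, 2, -2), 2, 2)          # records (1,2), (-1,-2)
  m <- moment_statistics(x, max_order = 2L)
  expect_equal(m$cov, matrix(c(1, 2, 2, 4), 2, 2), ignore_attr = TRUE)

  set.seed(9)
  v <- rnorm(3)
  m3 <- moment_statistics(rbind(v, -v), max_order = 3L)
  expect_equal(m3$mean, rep(0, 3), ignore_attr = TRUE)
  expect_true(all(abs(m3$third$value) < 1e-14))
  arr <- third_moment_array(m3)
  expect_equal(arr, aperm(arr, c(2, 1, 3)))   # permutation symmetry

  mrep <- moment_statistics(rbind(v, v) - rep(v, each = 2), max_order = 2L)
  expect_true(all(abs(mrep$cov) < 1e-14))
})

test_that("moments of a known Gaussian are recovered at S = 10,000", {
  set.seed(11)
  cv <- matrix(c(2, 0.6, 0.6, 1), 2, 2)
  x <- MASS::mvrnorm(10000, c(1, -1), cv)
  fl <- compute_fluctuations(list(deltas = x, n_landmarks = 1L))
  m <- moment_statistics(fl, 2L)
  expect_equal(fl$mean, c(1, -1), tolerance = 5 * sqrt(2 / 10000) * 3)
  se_cov <- 5 * sqrt(2 * max(cv)^2 / 10000)
  expect_lt(max(abs(m$cov - cv)), se_cov)
})

test_that("constraint detection finds exact null modes and a valid reduction", {
  expect_equal(ncol(find_constraints(diag(3))$null_vectors), 0L)
  expect_equal(find_constraints(diag(3))$projector, diag(3))

  b1 <- find_constraints(matrix(c(1, 1, 1, 1), 2, 2))
  expect_equal(ncol(b1$null_vectors), 1L)
  expect_equal(abs(b1$null_vectors[, 1]), rep(1 / sqrt(2), 2))
  expect_equal(sum(b1$null_vectors[, 1]), 0)   # direction (1, -1)

  expect_error(find_constraints(matrix(0, 2, 2)), "degenerate")

  ds <- make_two_class_study(synthetic_study_spec(seed = 5))
  fl <- compute_fluctuations(ds)
  mom <- moment_statistics(fl, 2L)
  b <- find_constraints(mom)
  expect_equal(ncol(b$null_vectors), 6L)
  expect_equal(b$rank, 10L)
  # projector: symmetric idempotent of the right rank, annihilates nulls
  expect_equal(b$projector, t(b$projector))
  expect_equal(b$projector %*% b$projector, b$projector, tolerance = 1e-12)
  expect_lt(max(abs(b$projector %*% b$null_vectors)), 1e-10)

  red <- reduce_and_standardize(fl, b)
  expect_equal(ncol(red$deltas), 10L)
  expect_equal(unname(colMeans(red$deltas^2)), rep(1, 10), tolerance = 1e-9)
  # idempotent in rank: reduced data has no null modes left
  b2 <- find_constraints(moment_statistics(red, 2L))
  expect_equal(ncol(b2$null_vectors), 0L)
  # the recorded linear map reproduces full-frame vectors on the support
  tmap <- reduction_map(red)
  rec <- red$deltas %*% t(tmap)
  expect_lt(max(abs(rec - fl$deltas %*% b$projector)), 1e-8)
})

test_that("angle histograms use the full circle and handle zero fluctuations", {
  # columns are (x1, x2, y1, y2); landmark 1 fluctuations are cols 1 and 3
  dz <- rbind(c(1, 0, 1, 0),     # lm1: (1, 1)  -> pi/4
              c(-1, 0, 0, 0),    # lm1: (-1, 0) -> pi
              c(0, 1, 0, 1))     # lm1: (0, 0)  -> excluded
  fl <- list(deltas = dz, n_landmarks = 2L)
  h1 <- angle_histogram(fl, 1L, n_bins = 8L)
  expect_equal(h1$n_excluded, 1L)              # record 3 has zero at lm 1
  expect_equal(h1$n_used, 2L)
  # angles pi/4 (record 1: dx=1, dy=1) and pi (record 2: dx=-1, dy=0)
  w <- 2 * pi / 8
  expect_equal(sum(h1$density) * w, 1, tolerance = 1e-9)
  # pi/4 lands in bin (0, pi/4] (mid pi/8); pi in (3pi/4, pi] (mid 7pi/8)
  expect_equal(h1$mids[h1$density > 0], c(pi / 8, 7 * pi / 8))
  expect_error(angle_histogram(list(deltas = matrix(0, 3, 4),
                                    n_landmarks = 2L), 1L), "zero")
})

test_that("isotropic fluctuations give a flat angle histogram", {
  set.seed(21)
  n <- 1e5
  d <- cbind(rnorm(n), rnorm(n))
  h <- angle_histogram(list(deltas = d, n_landmarks = 1L), 1L, n_bins = 24L)
  p0 <- 1 / 24
  se <- sqrt(p0 * (1 - p0) / n)
  width <- 2 * pi / 24
  expect_lt(max(abs(h$density * width - p0)), 4 * se)
})

test_that("angle histograms are rotation equivariant", {
  set.seed(22)
  n <- 5e4
  d <- cbind(rnorm(n, sd = 2), rnorm(n))
  nb <- 24L
  psi <- 2 * pi * 3 / nb                       # rotate by 3 whole bins
  rot <- cbind(c(cos(psi), sin(psi)), c(-sin(psi), cos(psi)))
  dr <- t(rot %*% t(d))
  h0 <- angle_histogram(list(deltas = d, n_landmarks = 1L), 1L, n_bins = nb)
  h1 <- angle_histogram(list(deltas = dr, n_landmarks = 1L), 1L, n_bins = nb)
  shifted <- h0$density[((seq_len(nb) - 1L - 3L) %% nb) + 1L]
  expect_equal(h1$density, shifted, tolerance = 1e-12)
})
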