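# SPD-manifold calculus: matrix functions, AIRM distance, tangent maps,
# Karcher mean, and the TSV round trip.

test_that("matrix functions follow diagonal closed forms and refuse to clip", {
  expect_equal(spd_matfun(diag(2), "log"), matrix(0, 2, 2))
  expect_equal(spd_matfun(diag(c(4, 9)), "sqrt"), diag(c(2, 3)))
  expect_equal(spd_matfun(diag(c(1, exp(2))), "log"), diag(c(0, 2)))
  expect_equal(spd_matfun(diag(c(1, 2)), "exp"), diag(exp(c(1, 2))))
  # rotated case against scalar functions of eigenvalues
  S <- rand_spd(5, seed = 2)[[1]]
  eg <- eigen(S, symmetric = TRUE)
  expect_equal(spd_matfun(S, "inv_sqrt"),
               eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors),
               tolerance = 1e-12)
  expect_error(spd_matfun(matrix(c(1, 1, 1, 1), 2), "log"), "eigenvalue")
  expect_error(spd_matfun(matrix(c(1, 2, 3, 4), 2), "log"), "symmetric")
})

test_that("regularization shifts the spectrum and surfaces singularity", {
  expect_equal(regularize(diag(2), 1), diag(2, 2))
  S <- rand_spd(4, seed = 3)[[1]]
  expect_equal(regularize(S, 0), S)
  # rank-1 PSD: smallest eigenvalue becomes exactly lambda
  R1 <- matrix(1, 2, 2)
  ev <- eigen(regularize(R1, 0.001), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), 0.001, tolerance = 1e-12)
  expect_error(regularize(R1, 0), "singular")
  expect_error(regularize(matrix(1:4, 2), 0.1), "symmetric")
  expect_error(regularize(diag(2), -1), "nonnegative")
})

test_that("geodesic distance matches the eigenvalue-formula oracle and the AIRM axioms", {
  A <- rand_spd(4, seed = 4)[[1]]
  expect_equal(geodesic_distance(A, A), 0, tolerance = 1e-10)
  expect_equal(geodesic_distance(diag(2), diag(c(exp(1), exp(1)))), sqrt(2))
  expect_equal(geodesic_distance(diag(2), diag(c(4, 9))),
               sqrt(log(4)^2 + log(9)^2))
  # independent oracle: sqrt(sum(log(eigen(solve(A) %*% B))^2))
  set.seed(10)
  for (i in 1:25) {
    p <- sample(2:10, 1)
    AB <- generate_spd(p, 2, seed = 1000 + i)
    d <- geodesic_distance(AB[[1]], AB[[2]])
    lam <- Re(eigen(solve(AB[[1]]) %*% AB[[2]], only.values = TRUE)$values)
    expect_equal(d, sqrt(sum(log(lam)^2)), tolerance = 1e-10)
    expect_equal(geodesic_distance(AB[[2]], AB[[1]]), d, tolerance = 1e-8)
    # affine invariance under random congruence
    M <- matrix(rnorm(p * p), p, p)
    while (abs(det(M)) < 1e-3) M <- matrix(rnorm(p * p), p, p)
    dM <- geodesic_distance(symmetrize_for_test(M %*% AB[[1]] %*% t(M)),
                            symmetrize_for_test(M %*% AB[[2]] %*% t(M)))
    expect_equal(dM, d, tolerance = 1e-8 * d)
  }
  expect_error(geodesic_distance(diag(2), diag(3)), "mismatch")
})

test_that("tangent projection and retraction invert each other and hit closed forms", {
  C <- rand_spd(5, seed = 5)[[1]]
  expect_lt(frob(tangent_project(C, C)), 1e-8)
  S <- rand_spd(5, seed = 6)[[1]]
  expect_equal(unclass(tangent_project(S, diag(5)))[, ], spd_matfun(S, "log"),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(unclass(tangent_project(diag(c(4, 9)), diag(2)))[, ],
               diag(c(log(4), log(9))), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(tangent_retract(matrix(0, 3, 3), C_ref = rand_spd(3, seed = 7)[[1]]),
               rand_spd(3, seed = 7)[[1]], tolerance = 1e-12)
  expect_equal(tangent_retract(diag(c(1, 2)), diag(2)), diag(exp(c(1, 2))))
  for (i in 1:100) {
    p <- 2 + (i %% 7)
    M <- generate_spd(p, 2, seed = 2000 + i)
    Th <- tangent_project(M[[1]], M[[2]])
    back <- tangent_retract(Th, M[[2]])
    expect_lt(frob(back - M[[1]]) / frob(M[[1]]), 1e-8)
  }
})

test_that("tangent matrices carry a reference identifier", {
  M <- rand_spd(4, 2, seed = 8)
  t1 <- tangent_project(M[[1]], M[[2]])
  t2 <- tangent_project(M[[1]], M[[2]], reference_id = "refA")
  expect_type(attr(t1, "reference_id"), "character")
  expect_identical(attr(t2, "reference_id"), "refA")
})

test_that("Karcher mean satisfies its identities and the two-matrix closed form", {
  A <- rand_spd(4, seed = 9)[[1]]
  expect_equal(riemann_mean(list(A)), A, ignore_attr = TRUE)
  expect_equal(riemann_mean(list(A, A)), A, ignore_attr = TRUE, tolerance = 1e-9)
  # commuting case: entrywise geometric mean of eigenvalues
  expect_equal(riemann_mean(list(diag(c(1, 4)), diag(c(4, 1)))), diag(2, 2),
               ignore_attr = TRUE, tolerance = 1e-9)
  # closed-form geodesic midpoint A^(1/2) (A^(-1/2) B A^(-1/2))^(1/2) A^(1/2)
  for (i in 1:10) {
    M <- generate_spd(5, 2, seed = 3000 + i)
    Ah <- spd_matfun(M[[1]], "sqrt"); Aw <- spd_matfun(M[[1]], "inv_sqrt")
    mid <- Ah %*% spd_matfun(symmetrize_for_test(Aw %*% M[[2]] %*% Aw), "sqrt") %*% Ah
    km <- riemann_mean(M)
    expect_lt(frob(km - mid) / frob(mid), 1e-8)
    expect_lt(attr(km, "grad_norm"), 1e-8)
  }
  # mean of several matrices satisfies the first-order condition
  S <- generate_spd(6, 8, seed = 31)
  mu <- riemann_mean(S)
  W <- spd_matfun(mu, "inv_sqrt")
  grad <- Reduce(`+`, lapply(S, function(x) {
    spd_matfun(symmetrize_for_test(W %*% x %*% W), "log")
  })) / length(S)
  expect_lt(frob(grad), 1e-8)
  expect_error(riemann_mean(list()), "nonempty")
  expect_error(riemann_mean(S, max_iter = 1), "converge")
})

test_that("tangent Euclidean distance matches geodesic distance near the reference", {
  C <- rand_spd(6, seed = 12, cap = 10)[[1]]
  set.seed(99)
  for (i in 1:20) {
    V1 <- matrix(rnorm(36), 6); V1 <- (V1 + t(V1)) / 2; V1 <- V1 / frob(V1)
    V2 <- matrix(rnorm(36), 6); V2 <- (V2 + t(V2)) / 2; V2 <- V2 / frob(V2)
    S1 <- tangent_retract(0.005 * V1, C)
    S2 <- tangent_retract(0.005 * V2, C)
    t1 <- tangent_project(S1, C); t2 <- tangent_project(S2, C)
    euc <- frob(t1 - t2)
    geo <- geodesic_distance(S1, S2)
    expect_lt(abs(euc - geo) / geo, 0.01)
  }
})

test_that("scalar (1x1) matrices are supported throughout", {
  a <- matrix(4, 1, 1); b <- matrix(9, 1, 1)
  expect_equal(geodesic_distance(a, b), abs(log(9 / 4)))
  expect_equal(riemann_mean(list(a, b)), matrix(6, 1, 1),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(unclass(tangent_project(b, a))[, ], matrix(log(9 / 4)),
               ignore_attr = TRUE)
})

test_that("matrix TSV round trip is bit stable at 17 significant digits", {
  set.seed(5)
  M <- matrix(rnorm(20) * 10^sample(-8:8, 20, TRUE), 4, 5)
  colnames(M) <- paste0("r", 1:5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(M, path)
  M2 <- read_matrix_tsv(path)
  expect_identical(unname(M), unname(M2))
  expect_identical(colnames(M2), colnames(M))
  # headerless round trip
  write_matrix_tsv(unname(M), path)
  expect_identical(read_matrix_tsv(path), unname(M))
})
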