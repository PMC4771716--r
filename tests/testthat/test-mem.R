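test_that("path graph on 3 sites yields 2 orthonormal centred eigenvectors", {
  g <- gabriel_graph(data.frame(x = c(0, 1, 2), y = c(0, 0, 0)))
  b <- mem_basis(g)
  V <- b$vectors
  expect_equal(ncol(V), 2)
  expect_equal(crossprod(V), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lt(max(abs(colSums(V))), 1e-10)   # orthogonal to the constant
})

test_that("MEM count is n - 1 on connected general-position graphs", {
  for (case in list(c(20, 21), c(35, 22), c(50, 23))) {
    b <- random_mem(case[1], case[2])
    expect_equal(ncol(b$vectors), case[1] - 1)
    expect_equal(length(b$values), case[1] - 1)
  }
})

test_that("basis is orthonormal and reconstructs the doubly centred matrix", {
  b <- random_mem(30, 31)
  V <- b$vectors
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-10)
  W <- b$graph$W
  n <- b$n
  H <- diag(n) - 1 / n
  omega <- H %*% W %*% H
  recon <- V %*% diag(b$values) %*% t(V)
  expect_lt(max(abs(recon - omega)), 1e-8)
})

test_that("Moran's I of a 3-site path with x = (1,2,3) is zero", {
  g <- gabriel_graph(data.frame(x = c(0, 1, 2), y = c(0, 0, 0)))
  # cross-products (x1-x2bar)(x2-x2bar) + (x2-x2bar)(x3-x2bar) vanish
  expect_equal(morans_i(c(1, 2, 3), g), 0, tolerance = 1e-12)
})

test_that("Moran's I satisfies the eigenvalue identity for every MEM", {
  for (seed in c(41, 42, 43)) {
    b <- random_mem(25, seed)
    direct <- vapply(seq_len(ncol(b$vectors)),
                     function(k) morans_i(b$vectors[, k], b$graph),
                     numeric(1))
    expect_lt(max(abs(direct - b$n * b$values / b$sum_w)), 1e-8)
  }
})

test_that("constant input is rejected by Moran's I", {
  g <- gabriel_graph(random_sites(10, 5))
  expect_error(morans_i(rep(2, 10), g), "constant")
})

test_that("eigenvalue order is descending and Moran sign matches eigenvalue sign", {
  b <- random_mem(40, 51)
  expect_true(all(diff(b$values) <= 1e-12))
  expect_equal(sign(b$morans_i), sign(b$values))
})

test_that("sign convention puts the largest-magnitude entry positive", {
  b <- random_mem(20, 61)
  for (j in seq_len(ncol(b$vectors))) {
    col <- b$vectors[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("sign split partitions the basis and labels agree with Moran's I", {
  b <- random_mem(30, 71)
  parts <- mem_split(b)
  expect_equal(ncol(parts$broad_medium) + ncol(parts$fine), b$n - 1)
  expect_equal(sort(c(colnames(parts$broad_medium), colnames(parts$fine))),
               sort(colnames(b$vectors)))
  direct <- vapply(colnames(parts$broad_medium),
                   function(nm) morans_i(b$vectors[, nm], b$graph), numeric(1))
  expect_true(all(direct > 0))
  direct_f <- vapply(colnames(parts$fine),
                     function(nm) morans_i(b$vectors[, nm], b$graph), numeric(1))
  expect_true(all(direct_f < 0))
})

test_that("path-graph MEMs run from positive to negative Moran's I", {
  g <- gabriel_graph(data.frame(x = 0:5, y = rep(0, 6)))
  b <- mem_basis(g)
  expect_gt(morans_i(b$vectors[, 1], g), 0)
  expect_lt(morans_i(b$vectors[, ncol(b$vectors)], g), 0)
})

test_that("MEM export round-trips vectors and sidecar metadata", {
  b <- random_mem(12, 81)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mem_csv(b, path)
  got <- utils::read.csv(path)
  expect_equal(as.matrix(got[, -1]), b$vectors, tolerance = 1e-12,
               ignore_attr = TRUE)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(side$eigenvalues, b$values, tolerance = 1e-12)
  expect_equal(side$n, b$n)
})
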