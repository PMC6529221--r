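test_that("directional overlap and combined scores match hand arithmetic", {
  dims <- c(8, 8, 4)
  arr_a <- array(FALSE, dims); arr_a[1:10] <- TRUE
  arr_b <- array(FALSE, dims); arr_b[1:40] <- TRUE
  a <- mk_mask(arr_a); b <- mk_mask(arr_b)
  expect_equal(directional_overlap(a, b), 100)
  expect_equal(directional_overlap(b, a), 25)
  s <- overlap_score(a, b)
  expect_equal(s$p1, 100)
  expect_equal(s$p2, 25)
  expect_equal(s$mean_score, 62.5)
  expect_equal(s$max_score, 100)
  expect_equal(s$min_score, 25)

  expect_equal(overlap_score(a, a)$mean_score, 100)
  expect_equal(overlap_score(a, a)$min_score, 100)
  arr_c <- array(FALSE, dims); arr_c[50:60] <- TRUE
  expect_equal(overlap_score(a, mk_mask(arr_c))$mean_score, 0)
  # mean rule is symmetric in the arguments
  s_rev <- overlap_score(b, a)
  expect_equal(s_rev$mean_score, s$mean_score)
  expect_error(directional_overlap(mk_mask(array(FALSE, dims)), b), "empty")
})

test_that("pairwise matrices equal brute-force voxel counting", {
  set.seed(51)
  dims <- c(10, 10, 5)
  fam <- lapply(1:3, function(i) {
    mk_mask(array(runif(prod(dims)) > 0.6, dims),
            cell_type = sprintf("ct%d", i))
  })
  m <- pairwise_matrix(fam, fam, combine = "mean")
  expect_equal(dim(m$values), c(3L, 3L))
  expect_equal(unname(diag(m$values)), rep(100, 3))
  expect_equal(m$values, t(m$values))
  for (i in 1:3) {
    for (j in 1:3) {
      expect_equal(m$values[i, j], oracle_overlap_scores(fam[[i]], fam[[j]])$mean)
    }
  }
  for (comb in c("max", "min")) {
    mm <- pairwise_matrix(fam, fam, combine = comb)
    for (i in 1:3) for (j in 1:3) {
      expect_equal(mm$values[i, j],
                   oracle_overlap_scores(fam[[i]], fam[[j]])[[comb]])
    }
  }

  disj1 <- mk_mask(array(c(rep(TRUE, 20), rep(FALSE, prod(dims) - 20)), dims))
  disj2 <- mk_mask(array(c(rep(FALSE, prod(dims) - 20), rep(TRUE, 20)), dims))
  z <- pairwise_matrix(list(x = disj1), list(y = disj2))
  expect_equal(unname(z$values[1, 1]), 0)

  expect_error(pairwise_matrix(list(bad = mk_mask(array(FALSE, dims))), fam),
               "empty mask.*bad")
})

test_that("interaction classification uses a strict 15% rule and row fractions", {
  vals <- matrix(15, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m <- structure(list(values = vals, combine = "mean",
                      row_labels = letters[1:4], col_labels = letters[1:4]),
                 class = "lh_overlap_matrix")
  cls <- classify_interactions(m, threshold = 15)
  expect_false(any(cls$significant))
  expect_equal(cls$frac_rows_with_any, 0)
  expect_equal(cls$frac_rows_with_none, 1)

  vals2 <- matrix(0, 10, 4, dimnames = list(paste0("r", 1:10), letters[1:4]))
  vals2[1, 2] <- 30; vals2[4, 1] <- 16; vals2[7, 3] <- 99
  m2 <- structure(list(values = vals2, combine = "mean",
                       row_labels = paste0("r", 1:10),
                       col_labels = letters[1:4]),
                  class = "lh_overlap_matrix")
  cls2 <- classify_interactions(m2)
  expect_equal(cls2$frac_rows_with_any, 0.3)
  expect_equal(cls2$frac_rows_with_none, 0.7)
  expect_equal(sum(cls2$frac_rows_with_any, cls2$frac_rows_with_none), 1)
  g <- glance(cls2)
  expect_equal(g$frac_rows_with_any, 0.3)

  # self-overlap never counts for a square matrix
  vals3 <- diag(4) * 100
  dimnames(vals3) <- list(letters[1:4], letters[1:4])
  m3 <- structure(list(values = vals3, combine = "mean",
                       row_labels = letters[1:4], col_labels = letters[1:4]),
                  class = "lh_overlap_matrix")
  expect_equal(classify_interactions(m3)$frac_rows_with_any, 0)
})

test_that("clustering matches naive complete-linkage agglomeration", {
  # two well-separated blocks
  set.seed(52)
  vals <- rbind(matrix(rnorm(12, 0, 0.5), 3),
                matrix(rnorm(12, 50, 0.5), 3))
  rownames(vals) <- paste0("r", 1:6); colnames(vals) <- paste0("c", 1:4)
  m <- structure(list(values = vals, combine = "mean",
                      row_labels = rownames(vals),
                      col_labels = colnames(vals)),
                 class = "lh_overlap_matrix")
  cl <- cluster_matrix(m)
  memb_impl <- stats::cutree(cl$row_tree, k = 2)
  memb_oracle <- oracle_complete_linkage_k(vals, 2)
  # same partition up to label swap
  expect_equal(length(unique(paste(memb_impl, memb_oracle))), 2)

  # identical rows merge first at height zero
  vals2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  colnames(vals2) <- paste0("c", 1:3)
  m2 <- structure(list(values = vals2, combine = "mean",
                       row_labels = rownames(vals2),
                       col_labels = colnames(vals2)),
                  class = "lh_overlap_matrix")
  tr <- cluster_matrix(m2)$row_tree
  expect_equal(tr$height[1], 0)
  expect_setequal(abs(tr$merge[1, ]), c(1, 2))

  # permutation of rows: same tree topology (equal cophenetic distances)
  perm <- c(4, 1, 6, 3, 2, 5)
  mp <- structure(list(values = vals[perm, ], combine = "mean",
                       row_labels = rownames(vals)[perm],
                       col_labels = colnames(vals)),
                  class = "lh_overlap_matrix")
  cp <- cluster_matrix(mp)
  coph1 <- as.matrix(stats::cophenetic(cl$row_tree))
  coph2 <- as.matrix(stats::cophenetic(cp$row_tree))
  expect_equal(coph1[rownames(vals), rownames(vals)],
               coph2[rownames(vals), rownames(vals)])

  expect_error(cluster_matrix(structure(
    list(values = vals[1, , drop = FALSE], combine = "mean",
         row_labels = "r1", col_labels = colnames(vals)),
    class = "lh_overlap_matrix")), "at least 2")
})

test_that("axon-dendrite relation reproduces closed-form least squares", {
  mk_om <- function(vals, rows, cols) {
    dimnames(vals) <- list(rows, cols)
    structure(list(values = vals, combine = "mean", row_labels = rows,
                   col_labels = cols), class = "lh_overlap_matrix")
  }
  # distinct row/col sets: every cell enters the fit
  x_vals <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  y_vals <- matrix(c(2.1, 3.9, 6.2, 8.1, 9.7, 12.3), 2, 3)
  dm <- mk_om(x_vals, c("r1", "r2"), c("c1", "c2", "c3"))
  am <- mk_om(y_vals, c("r1", "r2"), c("c1", "c2", "c3"))
  rel <- axon_dendrite_relation(am, dm)
  x <- as.numeric(x_vals); y <- as.numeric(y_vals)
  slope_cf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept_cf <- mean(y) - slope_cf * mean(x)
  r2_cf <- slope_cf^2 * sum((x - mean(x))^2) / sum((y - mean(y))^2)
  expect_equal(rel$slope, slope_cf)
  expect_equal(rel$intercept, intercept_cf)
  expect_equal(rel$r_squared, r2_cf)
  expect_equal(glance(rel)$n_pairs, 6)

  # identical matrices give r^2 = 1
  expect_equal(axon_dendrite_relation(am, am)$r_squared, 1)

  # independent random matrices: r^2 near zero
  set.seed(53)
  big1 <- mk_om(matrix(runif(900, 0, 100), 30), paste0("r", 1:30),
                paste0("c", 1:30))
  big2 <- mk_om(matrix(runif(900, 0, 100), 30), paste0("r", 1:30),
                paste0("c", 1:30))
  expect_lt(axon_dendrite_relation(big1, big2)$r_squared, 0.05)

  # constant predictor degenerates with a warning
  const <- mk_om(matrix(5, 2, 3), c("r1", "r2"), c("c1", "c2", "c3"))
  expect_warning(relc <- axon_dendrite_relation(am, const), "constant")
  expect_equal(relc$r_squared, 0)
})

test_that("score invariants hold across random mask pairs", {
  set.seed(54)
  dims <- c(12, 12, 6)
  for (i in 1:15) {
    a <- mk_mask(array(runif(prod(dims)) > runif(1, 0.3, 0.7), dims))
    b <- mk_mask(array(runif(prod(dims)) > runif(1, 0.3, 0.7), dims))
    if (sum(a$data) == 0 || sum(b$data) == 0) next
    s <- overlap_score(a, b)
    expect_true(all(c(s$p1, s$p2) >= 0 & c(s$p1, s$p2) <= 100))
    expect_true(s$min_score <= s$mean_score & s$mean_score <= s$max_score)
    expect_equal(s$mean_score, (s$p1 + s$p2) / 2)
    # growing the intersection (holding sizes fixed) never lowers any score
    outside_a <- which(b$data & !a$data)
    inside_spare <- which(a$data & !b$data)
    if (length(outside_a) >= 1 && length(inside_spare) >= 1) {
      a2 <- a
      a2$data[outside_a[1]] <- TRUE
      a2$data[inside_spare[1]] <- FALSE
      s2 <- overlap_score(a2, b)
      expect_gte(s2$mean_score, s$mean_score)
      expect_gte(s2$max_score, s$max_score)
      expect_gte(s2$min_score, s$min_score)
    }
  }
})

test_that("screen coverage arithmetic reproduces the ~38% core coverage", {
  expect_equal(round(coverage_percentage(63, 165)), 38)
  expect_equal(coverage_percentage(63, 165), 100 * 63 / 165)
  expect_error(coverage_percentage(10, 0), "n_total")
})
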