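test_that("PCA centres scores, orders components and reconstructs exactly", {
  set.seed(1)
  x <- matrix(rnorm(60), 12, 5)
  m <- fit_pca(x, n_components = 5L)
  expect_equal(unname(colMeans(m$scores)), rep(0, 5), tolerance = 1e-12)
  expect_true(all(diff(m$explained_variance_fraction) <= 1e-12))
  expect_equal(sum(m$explained_all), 1)
  # orthonormal loadings
  expect_equal(crossprod(m$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full-rank reconstruction of the centred matrix
  xc <- scale(x, scale = FALSE)
  expect_equal(m$scores %*% t(m$loadings), xc, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("rank-1 data put all variance on PC1", {
  v <- c(1, 2, 3, 4, 5)
  x <- outer(seq(-2, 2, length.out = 9), v)
  m <- fit_pca(x, n_components = 2L)
  expect_equal(m$explained_variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("fit_pca agrees with the covariance-eigendecomposition oracle", {
  set.seed(99)
  for (rep in 1:50) {
    x <- matrix(rnorm(50), 10, 5)
    m <- fit_pca(x, n_components = 5L)
    o <- oracle_pca(x)
    expect_equal(m$explained_all, o$fractions, tolerance = 1e-8)
    # scores equal up to per-column sign
    expect_equal(abs(m$scores), abs(o$scores), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("infeasible component counts are rejected", {
  x <- matrix(rnorm(20), 4, 5)
  expect_error(fit_pca(x, n_components = 4L), class = "validation_error")
  x[1, 1] <- NA
  expect_error(fit_pca(x, 2L), class = "validation_error")
})

test_that("venetian-blinds PRESS is near zero for rank-1 data and finite", {
  v <- c(2, 1, 0.5, 3, 1)
  x <- outer(seq(1, 4, length.out = 20), v)
  press <- venetian_blinds_press(x, max_components = 3L, n_splits = 5L)
  expect_lt(press[1], 1e-16)
  expect_true(all(is.finite(press)) && all(press >= 0))
})

test_that("PRESS identifies a 2-factor structure in noisy data", {
  set.seed(5)
  n <- 40
  scores <- matrix(rnorm(n * 2, sd = c(3, 2)), n, 2, byrow = TRUE)
  load2 <- matrix(rnorm(10), 2, 5)
  x <- scores %*% load2 + matrix(rnorm(n * 5, sd = 0.05), n, 5)
  press <- venetian_blinds_press(x, max_components = 4L, n_splits = 10L)
  expect_true(which.min(press) %in% c(2L, 3L))
  expect_error(venetian_blinds_press(x[1:8, ], max_components = 8L),
               class = "validation_error")
})

test_that("score distances are Euclidean and metric", {
  scores <- rbind(a = c(0, 0), b = c(3, 4), c = c(6, 8))
  m <- structure(list(mean_vector = c(0, 0), loadings = diag(2),
                      scores = scores,
                      explained_variance_fraction = c(0.7, 0.3),
                      explained_all = c(0.7, 0.3), n_components = 2L),
                 class = "pca_model")
  d <- score_distances(m, 2L)
  dm <- attr(d, "matrix")
  expect_equal(dm["a", "b"], 5)
  expect_equal(dm["a", "c"], 10)
  expect_equal(dm, t(dm))
  # triangle inequality on random data
  set.seed(3)
  r <- fit_pca(matrix(rnorm(40), 8, 5), 3L)
  rd <- attr(score_distances(r, 3L), "matrix")
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(rd[i, j], rd[i, k] + rd[k, j] + 1e-12)
  # identical rows are at distance zero
  dup <- fit_pca(rbind(matrix(rnorm(35), 7, 5))[c(1, 1, 2:7), ], 2L)
  expect_equal(attr(score_distances(dup, 2L), "matrix")[1, 2], 0)
})

test_that("greedy pair selection honours subject and disjointness rules", {
  # contrived 20-recording, 10-subject geometry
  set.seed(11)
  x <- matrix(rnorm(100), 20, 5)
  rownames(x) <- sprintf("r%02d", 1:20)
  subjects <- setNames(rep(sprintf("s%d", 1:10), each = 2), rownames(x))
  d <- score_distances(fit_pca(x, 4L), 2L)
  sel <- select_pairs(d, subjects, n_each = 5L)
  ids <- c(sel$similar$id1, sel$similar$id2,
           sel$dissimilar$id1, sel$dissimilar$id2)
  expect_length(unique(ids), 20L)
  expect_true(all(subjects[sel$similar$id1] != subjects[sel$similar$id2]))
  expect_true(all(subjects[sel$dissimilar$id1] != subjects[sel$dissimilar$id2]))
  expect_true(!is.unsorted(sel$similar$distance))
  expect_true(!is.unsorted(rev(sel$dissimilar$distance)))
  # invariance to input row order (distinct distances)
  shuffled <- d[sample(nrow(d)), ]
  sel2 <- select_pairs(shuffled, subjects, n_each = 5L)
  expect_equal(sel$similar, sel2$similar)
  expect_equal(sel$dissimilar, sel2$dissimilar)
})

test_that("same-subject recordings are never paired, even at distance zero", {
  d <- data.frame(id1 = c("a1", "a1", "a2", "b1", "a1", "a2"),
                  id2 = c("a2", "b1", "c1", "c1", "c1", "b1"),
                  distance = c(0, 1, 2, 3, 4, 5))
  subjects <- c(a1 = "a", a2 = "a", b1 = "b", c1 = "c")
  sel <- select_pairs(d, subjects, n_each = 1L)
  # a1-a2 sit at distance 0 but share a subject: the similar pair skips them
  expect_equal(sort(c(sel$similar$id1, sel$similar$id2)), c("a1", "b1"))
  expect_equal(sort(c(sel$dissimilar$id1, sel$dissimilar$id2)), c("a2", "c1"))
  expect_error(select_pairs(d, subjects, n_each = 2L),
               class = "selection_error")
})

test_that("hand-run greedy rule on 4 recordings from 2 subjects", {
  d <- data.frame(id1 = c("a1", "a1", "a2", "a2"),
                  id2 = c("b1", "b2", "b1", "b2"),
                  distance = c(1, 2, 3, 4))
  subjects <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  sel <- select_pairs(d, subjects, n_each = 1L)
  expect_equal(sel$similar$distance, 1)           # a1-b1
  expect_equal(sel$dissimilar$distance, 4)        # a2-b2, the unused pair
})

test_that("pair ranking compares two distance tables by rank correlation", {
  set.seed(21)
  x <- matrix(rnorm(100), 20, 5)
  rownames(x) <- sprintf("r%02d", 1:20)
  subjects <- setNames(rep(sprintf("s%d", 1:10), each = 2), rownames(x))
  d <- score_distances(fit_pca(x, 4L), 2L)
  sel <- select_pairs(d, subjects, 5L)
  same <- rank_pairs(sel, d, d)
  expect_equal(same$spearman, 1)
  expect_equal(same$ranking$rank_a, same$ranking$rank_b)
  # reversing the distances reverses the ranking
  rev_d <- d
  rev_d$distance <- max(d$distance) - d$distance
  expect_equal(rank_pairs(sel, d, rev_d)$spearman, -1)
  # independent random tables almost surely give |rho| < 1
  rand_d <- d
  set.seed(22)
  rand_d$distance <- runif(nrow(d))
  expect_lt(abs(rank_pairs(sel, d, rand_d)$spearman), 1)
  # missing pair is an error
  key <- paste(pmin(d$id1, d$id2), pmax(d$id1, d$id2))
  want <- paste(pmin(sel$similar$id1[1], sel$similar$id2[1]),
                pmax(sel$similar$id1[1], sel$similar$id2[1]))
  expect_error(rank_pairs(sel, d, d[key != want, ]),
               class = "validation_error")
})
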