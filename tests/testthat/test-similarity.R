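# small helper: build a panel data.frame from a coefficient matrix
panel_from_matrix <- function(m, groups = "indica", prefix = "CV") {
  df <- data.frame(name = sprintf("%s%02d", prefix, seq_len(nrow(m))),
                   group = rep_len(groups, nrow(m)), m,
                   stringsAsFactors = FALSE)
  cultivar_panel(df)
}

random_panel_matrix <- function(n) {
  sp <- default_parameter_space(ga_coefficients())
  m <- t(replicate(n, space_runif_test(sp)))
  colnames(m) <- sp$names
  m
}

test_that("joint min-max scaling hits {0,1} and zeroes constant columns", {
  m <- random_panel_matrix(2)
  p <- panel_from_matrix(m)
  s <- scale_panel(p)
  for (j in colnames(s)) expect_setequal(s[, j], c(0, 1))

  m3 <- random_panel_matrix(3)
  m3[, "G1"] <- 55  # constant column
  s3 <- scale_panel(panel_from_matrix(m3))
  expect_true(all(s3[, "G1"] == 0))
  expect_true(all(s3 >= 0 & s3 <= 1))
})

test_that("scaling is invariant to positive per-column rescaling of the inputs", {
  set.seed(71)
  for (i in 1:20) {
    m <- random_panel_matrix(5)
    f <- runif(ncol(m), 0.1, 10)
    m2 <- sweep(m, 2, f, "*")
    colnames(m2) <- colnames(m)
    s1 <- scale_panel(panel_from_matrix(m))
    s2 <- scale_panel(panel_from_matrix(m2))
    expect_equal(unname(s1), unname(s2), tolerance = 1e-10)
    # hence Euclidean nearest-neighbour order is preserved
    d1 <- as.matrix(dist(s1)); d2 <- as.matrix(dist(s2))
    expect_equal(apply(d1 + diag(Inf, nrow(d1)), 1, which.min),
                 apply(d2 + diag(Inf, nrow(d2)), 1, which.min))
  }
})

test_that("pairwise distances follow the standard formulas", {
  m <- rbind(id = c(0, 0), a = c(0, 0), b = c(3, 4))
  attr(m, "n_ideotypes") <- 1L
  d <- pairwise_distances(m)
  expect_equal(unname(d["id", "a", ]), c(0, 0, 1))  # zero vector: cosine 1
  expect_equal(unname(d["id", "b", "euclidean"]), 5)
  expect_equal(unname(d["id", "b", "manhattan"]), 7)

  m2 <- rbind(id = c(1, 2), par = c(2, 4), other = c(2, 1))
  attr(m2, "n_ideotypes") <- 1L
  d2 <- pairwise_distances(m2)
  expect_equal(unname(d2["id", "par", "cosine"]), 0, tolerance = 1e-12)
  expect_gt(d2["id", "par", "euclidean"], 0)
})

test_that("the similarity index hits its endpoints and the worked example", {
  # one ideotype, two cultivars, single metric with d_bar = (2, 8)
  d <- array(c(2, 8), dim = c(1, 2, 1),
             dimnames = list("id", c("a", "b"), "euclidean"))
  si <- similarity_index(d)
  expect_equal(unname(si$similarity["id", ]), c(0.75, 0))

  # zero-distance pair -> similarity 1
  d0 <- array(c(0, 5), dim = c(1, 2, 1),
              dimnames = list("id", c("a", "b"), "euclidean"))
  expect_equal(unname(similarity_index(d0)$similarity["id", "a"]), 1)

  # all pairs identical -> all similarities defined as 1
  dz <- array(0, dim = c(1, 2, 1),
              dimnames = list("id", c("a", "b"), "euclidean"))
  expect_true(all(similarity_index(dz)$similarity == 1))
})

test_that("top-k frequencies agree with brute-force enumeration", {
  set.seed(81)
  metrics <- c("euclidean", "manhattan", "cosine")
  for (rep in 1:10) {
    m <- random_panel_matrix(8)
    panel <- panel_from_matrix(m[3:8, , drop = FALSE])
    ideo <- data.frame(name = c("ID1", "ID2"), group = "ideotype",
                       m[1:2, , drop = FALSE])
    scaled <- scale_panel(panel, ideo)
    d <- pairwise_distances(scaled, metrics)
    k <- sample(1:4, 1)
    got <- topk_frequency(d, k)
    for (v in c("ID1", "ID2")) {
      counts <- integer(6); names(counts) <- panel$name
      for (mt in metrics) {
        ord <- order(d[v, , mt], dimnames(d)[[2]])
        top <- dimnames(d)[[2]][ord][seq_len(k)]
        counts[top] <- counts[top] + 1L
      }
      counts <- counts[counts > 0]
      got_v <- got$per_ideotype[[v]]
      expect_equal(sum(got_v$frequency), 3 * k)
      for (cv in names(counts))
        expect_equal(got_v$frequency[got_v$cultivar == cv],
                     unname(counts[cv]))
      # ordering: frequency descending, ties by lower averaged distance
      expect_true(all(diff(got_v$frequency) <= 0))
    }
  }
  # k = cultivar count with one metric: every cultivar appears once
  m <- random_panel_matrix(5)
  panel <- panel_from_matrix(m[2:5, , drop = FALSE])
  ideo <- data.frame(name = "ID1", group = "ideotype", m[1, , drop = FALSE])
  d1 <- pairwise_distances(scale_panel(panel, ideo), "euclidean")
  fr <- topk_frequency(d1, k = 4)
  expect_true(all(fr$per_ideotype$ID1$frequency == 1))
})

test_that("an exact ideotype copy in the panel is a perfect self-match", {
  set.seed(91)
  m <- random_panel_matrix(7)
  ideo <- data.frame(name = "ID1", group = "ideotype", m[1, , drop = FALSE])
  panel <- panel_from_matrix(m)  # CV01 is the exact copy
  rep <- similarity_report(panel, ideo)
  expect_equal(unname(rep$similarity["ID1", "CV01"]), 1)
  top <- rep$frequency$per_ideotype$ID1
  expect_identical(top$cultivar[1], "CV01")
  expect_equal(top$frequency[1], 3)  # nearest under all three metrics
  # PCA validation agrees on the nearest cultivar
  expect_identical(rep$pca$nearest$ID1[1], "CV01")
})

test_that("metric-wise dominance implies a higher similarity", {
  set.seed(101)
  for (rep in 1:20) {
    m <- random_panel_matrix(7)
    panel <- panel_from_matrix(m[2:7, , drop = FALSE])
    ideo <- data.frame(name = "ID1", group = "ideotype", m[1, , drop = FALSE])
    d <- pairwise_distances(scale_panel(panel, ideo))
    si <- similarity_index(d)$similarity
    cvs <- dimnames(d)[[2]]
    for (a in cvs) for (b in cvs) {
      if (a != b && all(d["ID1", a, ] < d["ID1", b, ]))
        expect_gt(si["ID1", a], si["ID1", b])
    }
  }
})

test_that("panel row order does not change similarities", {
  set.seed(111)
  m <- random_panel_matrix(9)
  panel <- panel_from_matrix(m[2:9, , drop = FALSE])
  ideo <- data.frame(name = "ID1", group = "ideotype", m[1, , drop = FALSE])
  r1 <- similarity_report(panel, ideo)
  perm <- sample(nrow(panel))
  r2 <- similarity_report(cultivar_panel(panel[perm, ]), ideo)
  expect_equal(r1$similarity[, colnames(r1$similarity)],
               r2$similarity[, colnames(r1$similarity)])
  expect_equal(r1$frequency$global, r2$frequency$global)
})

test_that("PCA validation decomposes variance correctly", {
  set.seed(121)
  # collinear columns: PC1 carries everything
  v <- rnorm(6)
  m <- sapply(1:8, function(j) j * v)
  colnames(m) <- ga_coefficients()
  p <- pca_validate(panel_from_matrix(m))
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-10)

  # variance fractions sum to 1; all-component distances equal z-scored ones
  for (rep in 1:5) {
    m <- random_panel_matrix(10)
    p <- pca_validate(panel_from_matrix(m))
    expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-10)
    z <- scale(m)
    dz <- as.matrix(dist(z))
    ds <- as.matrix(dist(p$scores))
    expect_equal(unname(ds), unname(dz), tolerance = 1e-8)
  }
})

test_that("panels validate and round-trip as CSV", {
  m <- random_panel_matrix(4)
  p <- panel_from_matrix(m, groups = c("indica", "japonica", "hybrid"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, path)
  back <- read_panel(path)
  expect_equal(as.data.frame(back), as.data.frame(p), tolerance = 1e-10)
  expect_error(cultivar_panel(p[, -2]), "missing column")
  dup <- p; dup$name[2] <- dup$name[1]
  expect_error(cultivar_panel(dup), "duplicate")
})
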