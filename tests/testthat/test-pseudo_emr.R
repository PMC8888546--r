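test_that("exact 1-D 2-means matches hand-worked examples", {
  res <- dichotomize_kmeans(c(1, 2, 10, 11))
  expect_equal(res$labels, c(0L, 0L, 1L, 1L))
  expect_equal(res$cut_point, 6)

  expect_equal(dichotomize_kmeans(c(0, 10))$labels, c(0L, 1L))

  expect_error(dichotomize_kmeans(c(5, 5, 5)), "ZeroVariance")
  expect_error(dichotomize_kmeans(c(1, NA, NA)), "ZeroVariance")
})

test_that("2-means handles missing values and labels the high cluster present", {
  res <- dichotomize_kmeans(c(100, NA, 1, 2, 99))
  expect_equal(res$labels, c(1L, NA, 0L, 0L, 1L))
})

test_that("2-means agrees with the naive split-point oracle on random vectors", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(3:50, 1)
    v <- round(rnorm(n, sd = sample(c(0.5, 1, 10), 1)), 2)
    if (length(unique(v)) < 2) next
    got <- dichotomize_kmeans(v)
    want <- oracle_kmeans_1d(v)
    wcss_of <- function(lab) {
      sum(tapply(v, lab, function(g) sum((g - mean(g))^2)))
    }
    expect_equal(wcss_of(got$labels), want$wcss, tolerance = 1e-10)
  }
})

test_that("fixed clinical thresholds override data-driven cuts", {
  expect_equal(apply_threshold_override(c(10, 20, 30),
                                        list(cut = 18, direction = "above")),
               c(0L, 1L, 1L))
  expect_equal(apply_threshold_override(c(10, 20),
                                        list(cut = 18, direction = "below")),
               c(1L, 0L))
  expect_equal(apply_threshold_override(c(1, 2, NA),
                                        list(cut = 18, direction = "above")),
               c(0L, 0L, NA))
  expect_error(apply_threshold_override(1:3, list(cut = 18)), "direction")
})

test_that("sparsity filter removes features present in at most one subject", {
  df <- data.frame(a = c(1, 0, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 0, 0),
                   d = c(1, 1, 1, 1))
  ft <- feature_table(df, paste0("s", 1:4),
                      kinds = c(a = "binary", b = "binary", c = "binary",
                                d = "binary"))
  ft$binarized <- TRUE
  out <- filter_sparse_features(ft)
  expect_setequal(names(out$data), c("b", "d"))
  expect_setequal(attr(out, "exclusion_log")$feature, c("a", "c"))
})

test_that("documents carry hyphenated terms and honour the name map", {
  df <- data.frame(`floppy infant` = c(1, 0), allergies = c(1, 1),
                   check.names = FALSE)
  ft <- feature_table(df, c("s1", "s2"),
                      kinds = c(`floppy infant` = "binary",
                                allergies = "binary"))
  ft$binarized <- TRUE
  corp <- build_documents(ft, name_map = c(`floppy infant` = "infant-floppy"))
  expect_setequal(corp$documents[[1]], c("infant-floppy", "allergies"))
  expect_equal(corp$documents[[2]], "allergies")

  corp2 <- build_documents(ft)
  expect_true("floppy-infant" %in% corp2$documents[[1]])
})

test_that("subjects with no present features are dropped with a warning", {
  df <- data.frame(a = c(1, 0, NA), b = c(0, 0, NA))
  ft <- feature_table(df, c("s1", "s2", "s3"),
                      kinds = c(a = "binary", b = "binary"))
  ft$binarized <- TRUE
  expect_warning(corp <- build_documents(ft), "no present features")
  expect_equal(corp$doc_subject_map, "s1")
  expect_equal(corp$documents, list("a"))
})

test_that("colliding term labels raise an error", {
  df <- data.frame(`Night Waking` = 1:0, `night waking` = 0:1,
                   check.names = FALSE)
  ft <- feature_table(df, c("s1", "s2"),
                      kinds = setNames(rep("binary", 2), names(df)))
  ft$binarized <- TRUE
  expect_error(build_documents(ft), "TermCollision")
})

test_that("binarization expands categoricals and logs degenerate features", {
  df <- data.frame(diag = c("adhd", "none", "tic", "adhd"),
                   iq = c(70, 100, 105, 130),
                   flat = c(3, 3, 3, 3),
                   delay_months = c(30, 2, 40, 1))
  ft <- feature_table(df, paste0("s", 1:4),
                      kinds = c(diag = "categorical", iq = "continuous",
                                flat = "continuous",
                                delay_months = "continuous"),
                      overrides = list(delay_months =
                                         list(cut = 24, direction = "above")))
  bt <- binarize_features(ft)
  expect_setequal(names(bt$data),
                  c("diag.adhd", "diag.none", "diag.tic", "iq", "delay_months"))
  expect_equal(bt$data$delay_months, c(1L, 0L, 1L, 0L))
  expect_equal(attr(bt, "exclusion_log")$feature, "flat")
  expect_true(all(unlist(bt$data) %in% c(0L, 1L)))
})

test_that("a document is exactly the set of the subject's present features", {
  set.seed(7)
  n <- 30
  p <- 12
  df <- as.data.frame(matrix(rbinom(n * p, 1, 0.4), n, p))
  names(df) <- paste0("feat ", seq_len(p))
  ft <- feature_table(df, paste0("s", 1:n),
                      kinds = setNames(rep("binary", p), names(df)))
  corp <- make_pseudo_emr(ft)
  bt <- attr(corp, "feature_table")
  for (i in seq_along(corp$documents)) {
    sid <- corp$doc_subject_map[i]
    row <- bt$data[match(sid, bt$subject_ids), ]
    present <- gsub("\\s+", "-", tolower(names(row)[row == 1L]))
    expect_setequal(corp$documents[[i]], present)
    expect_equal(anyDuplicated(corp$documents[[i]]), 0L)
  }
})

test_that("pipeline is invariant to subject row order", {
  set.seed(8)
  n <- 25
  df <- as.data.frame(matrix(rbinom(n * 8, 1, 0.5), n, 8))
  names(df) <- paste0("f", 1:8)
  ids <- paste0("s", 1:n)
  ft <- feature_table(df, ids, kinds = setNames(rep("binary", 8), names(df)))
  perm <- sample(n)
  ft2 <- feature_table(df[perm, ], ids[perm],
                       kinds = setNames(rep("binary", 8), names(df)))
  c1 <- make_pseudo_emr(ft)
  c2 <- make_pseudo_emr(ft2)
  expect_equal(c1$vocabulary, c2$vocabulary)
  d1 <- setNames(c1$documents, c1$doc_subject_map)
  d2 <- setNames(c2$documents, c2$doc_subject_map)
  expect_setequal(names(d1), names(d2))
  for (nm in names(d1)) expect_setequal(d1[[nm]], d2[[nm]])
})
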