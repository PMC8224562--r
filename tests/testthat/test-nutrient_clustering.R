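## small profile matrix with two well-separated blobs
two_blob_profiles <- function(n = 40, seed = 21) {
  set.seed(seed)
  half <- n / 2
  base <- matrix(rnorm(n * 7, sd = 0.3), n,
                 dimnames = list(sprintf("r%02d", 1:n),
                                 recipemine:::.nutrient_cols))
  base[1:half, "sodium_mg"] <- base[1:half, "sodium_mg"] + 20
  base[(half + 1):n, "fiber_g"] <- base[(half + 1):n, "fiber_g"] + 20
  abs(base)
}

test_that("kmeans degenerate cases: k = 1 and k = n", {
  prof <- two_blob_profiles(20)
  km1 <- kmeans_cluster(prof, k = 1, seed = 1, restarts = 2)
  ## standardized space: centroid at the origin, inertia = p * (n - 1)
  expect_equal(unname(km1$centroids[1, ]), rep(0, 7), tolerance = 1e-10)
  expect_equal(km1$inertia, 7 * (20 - 1), tolerance = 1e-8)
  kmn <- kmeans_cluster(prof, k = 20, seed = 1, restarts = 2)
  expect_equal(kmn$inertia, 0, tolerance = 1e-10)
  expect_equal(sort(unique(kmn$assignments)), 1:20)
  expect_error(kmeans_cluster(prof, k = 21), class = "recipemine_k_error")
})

test_that("kmeans recovers two planted blobs and matches the stats::kmeans optimum", {
  prof <- two_blob_profiles(40)
  km <- kmeans_cluster(prof, k = 2, seed = 4, restarts = 5)
  truth <- rep(1:2, each = 20)
  expect_equal(adjusted_rand_index(km$assignments, truth), 1.0)
  ## independent oracle: same standardization, Lloyd from many random starts
  x <- scale(prof)
  ref <- stats::kmeans(x, centers = 2, nstart = 20, algorithm = "Lloyd",
                       iter.max = 100)
  expect_equal(km$inertia, ref$tot.withinss, tolerance = 1e-8)
  ## centroids equal member means in standardized space
  for (j in 1:2) {
    members <- names(km$assignments)[km$assignments == j]
    xs <- scale(prof, center = km$scaling$center, scale = km$scaling$sd)
    expect_equal(unname(km$centroids[j, ]), unname(colMeans(xs[members, ])),
                 tolerance = 1e-10)
  }
})

test_that("kmeans is deterministic under seed and assigns every recipe once", {
  prof <- two_blob_profiles(30)
  k1 <- kmeans_cluster(prof, k = 3, seed = 9, restarts = 4)
  k2 <- kmeans_cluster(prof, k = 3, seed = 9, restarts = 4)
  expect_identical(k1$assignments, k2$assignments)
  expect_identical(k1$inertia, k2$inertia)
  expect_equal(length(k1$assignments), nrow(prof))
  expect_equal(sum(k1$sizes), nrow(prof))
})

test_that("representative_ingredients: idf ordering and hand-computed toy", {
  ## 2 clusters; "marker" only in cluster 1, "ubiquitous" in both
  corpus <- mk_corpus(
    mk_clean_recipe("a1", "X", c("marker", "ubiquitous")),
    mk_clean_recipe("a2", "X", c("marker", "ubiquitous")),
    mk_clean_recipe("b1", "X", c("other", "ubiquitous")),
    mk_clean_recipe("b2", "X", c("other", "ubiquitous")))
  model <- structure(list(k = 2,
                          assignments = c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L)),
                     class = "cluster_model")
  reps <- representative_ingredients(model, corpus, top_n = 3)
  r1 <- reps[reps$cluster == 1, ]
  ## hand tf-idf: marker tf=2, idf=ln(3/2)+1; ubiquitous tf=2, idf=ln(3/3)+1
  expect_equal(r1$ingredient[1], "marker")
  expect_equal(r1$score[r1$ingredient == "marker"], 2 * (log(3 / 2) + 1))
  expect_equal(r1$score[r1$ingredient == "ubiquitous"], 2)
  ## exclusive beats equally frequent shared ingredient in both clusters
  r2 <- reps[reps$cluster == 2, ]
  expect_equal(r2$ingredient[1], "other")
  expect_error(representative_ingredients(model, mk_corpus(
    mk_clean_recipe("zz", "X", "salt"))), class = "recipemine_id_mismatch")
})

test_that("characterize_clusters thresholds centroid z-scores", {
  cents <- rbind(rep(0, 7),
                 c(0, 0, 0, 0, 0, 0, 2.5),
                 c(1.2, 0, 0, 0, 1.8, 0, 0))
  colnames(cents) <- recipemine:::.nutrient_cols
  model <- structure(list(k = 3, centroids = cents), class = "cluster_model")
  labs <- characterize_clusters(model, z_threshold = 1.0)
  expect_equal(labs[["1"]], "balanced")
  expect_equal(labs[["2"]], "high_sodium")
  expect_setequal(labs[["3"]], c("high_fiber", "high_carbohydrate"))
  ## monotonicity: raising the threshold never adds a label
  labs_hi <- characterize_clusters(model, z_threshold = 2.0)
  for (j in names(labs))
    expect_true(all(setdiff(labs_hi[[j]], "balanced") %in% labs[[j]]))
})

test_that("merge_into_groups: label-set auto-merge and explicit merge map", {
  labs <- list(`1` = "high_sodium", `2` = "high_sodium", `3` = "high_fiber")
  ga <- merge_into_groups(labs)
  expect_equal(unname(ga$group_of), c("G1", "G1", "G2"))
  expect_setequal(ga$groups[["G1"]], c("1", "2"))
  expect_match(ga$annotations$annotation[ga$annotations$group == "G1"],
               "hypertension")
  ## all balanced -> one group
  ga2 <- merge_into_groups(list(`1` = "balanced", `2` = "balanced"))
  expect_length(ga2$groups, 1)
  ## explicit merge map applied verbatim; unknown cluster rejected
  mm <- data.frame(cluster = c(1, 2, 3), group = c("A", "A", "D"))
  ga3 <- merge_into_groups(labs, merge_map = mm)
  expect_equal(unname(ga3$group_of[c("1", "2", "3")]), c("A", "A", "D"))
  expect_error(merge_into_groups(labs, data.frame(cluster = 9, group = "A")),
               class = "recipemine_merge_error")
  ## merged clusters without a shared label draw a warning, not an error
  expect_warning(
    merge_into_groups(list(`1` = "high_fat", `2` = "high_sugar"),
                      data.frame(cluster = 1:2, group = "A")),
    class = "recipemine_merge_warning")
})

test_that("adjusted_rand_index matches hand-enumerated values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjusted_rand_index(rep(1, 5), rep(2, 5)), 1) # both trivial
})

test_that("nearest_recipes lists members closest to each centroid", {
  prof <- two_blob_profiles(20)
  km <- kmeans_cluster(prof, k = 2, seed = 2, restarts = 3)
  nr <- nearest_recipes(km, prof, m = 3)
  expect_equal(nrow(nr), 6)
  for (j in 1:2) {
    sub <- nr[nr$cluster == j, ]
    expect_true(all(diff(sub$distance) >= 0))
    expect_true(all(km$assignments[sub$id] == j))
  }
})
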