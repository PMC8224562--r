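## k-means clustering of recipes in nutrient space, representative
## ingredients per cluster (cluster-as-document tf-idf), nutrient
## characterization by centroid z-scores, and merging characterized
## clusters into groups.
##
## Features are the seven nutrients z-scored per column (raw units would
## let sodium in mg dominate Euclidean distance); energy is excluded from
## the features because it is an exact linear combination of three of
## them. Initialization is k-means++ from the given seed, with
## farthest-point reseeding of empty clusters and the best of `restarts`
## runs by inertia.

kmeans_features <- function(profiles) {
  feats <- intersect(.nutrient_cols, colnames(profiles))
  if (length(feats) == 0) feats <- setdiff(colnames(profiles), "energy_kcal")
  profiles[, feats, drop = FALSE]
}

## squared Euclidean distances points (n x p) -> centers (k x p)
dist2 <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- pmax(dist2(x, centers[1, , drop = FALSE])[, 1], 0)
  for (j in seq_len(k - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = prob), ]
    d2 <- pmin(d2, pmax(dist2(x, centers[j + 1, , drop = FALSE])[, 1], 0))
  }
  centers
}

lloyd <- function(x, centers, max_iter = 100) {
  k <- nrow(centers)
  assign_old <- rep(0L, nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- dist2(x, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    for (j in which(tabulate(assign_new, k) == 0)) {
      ## empty cluster: reseed from the point farthest from its own center
      far <- which.max(d2[cbind(seq_len(nrow(x)), assign_new)])
      centers[j, ] <- x[far, ]
      assign_new[far] <- j
    }
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[assign_new == j, , drop = FALSE])
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
  }
  d2 <- dist2(x, centers)
  assign_new <- max.col(-d2, ties.method = "first")
  inertia <- sum(pmax(d2[cbind(seq_len(nrow(x)), assign_new)], 0))
  list(assignments = assign_new, centers = centers, inertia = inertia)
}

#' Cluster recipes in standardized nutrient space
#'
#' @param profiles matrix from [corpus_nutrients()]; only the seven
#'   nutrient columns are used as features.
#' @param k number of clusters (default 20).
#' @param seed seed for k-means++ initialization.
#' @param restarts independent runs; the best by inertia is kept
#'   (default 10).
#' @param max_iter Lloyd iteration cap per run.
#' @return a `cluster_model`: list with `k`, `assignments` (named integer,
#'   recipe id -> cluster 1..k), `centroids` (k x nutrients, standardized
#'   space), `inertia`, `sizes`, `seed` and `scaling` (per-nutrient center
#'   and sd).
#' @export
kmeans_cluster <- function(profiles, k = 20, seed = 42, restarts = 10,
                           max_iter = 100) {
  x_raw <- kmeans_features(profiles)
  n <- nrow(x_raw)
  if (k > n) stop_rm("k = %d exceeds number of recipes (%d)", k, n,
                     class = "recipemine_k_error")
  ctr <- colMeans(x_raw)
  scl <- apply(x_raw, 2, stats::sd)
  scl[scl == 0] <- 1
  x <- scale(x_raw, center = ctr, scale = scl)
  attr(x, "scaled:center") <- NULL; attr(x, "scaled:scale") <- NULL
  best <- NULL
  set.seed(derive_seed(seed, 4))
  for (r in seq_len(restarts)) {
    fit <- lloyd(x, kmeanspp_init(x, k), max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  colnames(best$centers) <- colnames(x)
  structure(list(k = k,
                 assignments = setNames(best$assignments,
                                        rownames(profiles) %||% as.character(seq_len(n))),
                 centroids = best$centers, inertia = best$inertia,
                 sizes = tabulate(best$assignments, k), seed = seed,
                 scaling = list(center = ctr, sd = scl)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster model> k = %d, n = %d, inertia = %.2f\n",
              x$k, length(x$assignments), x$inertia))
  invisible(x)
}

#' @export
as.data.frame.cluster_model <- function(x, ...) {
  data.frame(id = names(x$assignments), cluster = unname(x$assignments),
             stringsAsFactors = FALSE)
}

#' Representative ingredients of each cluster
#'
#' Each cluster is treated as one pooled document made of its recipes'
#' ingredient sets: tf is the ingredient's recipe count within the
#' cluster, idf = ln((1+k)/(1+df)) + 1 over the k cluster-documents, and
#' ingredients are ranked by tf*idf (ties: higher tf, then key).
#'
#' @param model a [kmeans_cluster()] fit.
#' @param corpus the `recipe_corpus` the model was fitted on (ids must
#'   match).
#' @param top_n ingredients listed per cluster (default 10).
#' @return data frame `cluster`, `rank`, `ingredient`, `tf`, `score`.
#' @export
representative_ingredients <- function(model, corpus, top_n = 10) {
  sets <- recipe_ingredient_sets(corpus)
  cl <- model$assignments[names(sets)]
  if (any(is.na(cl)))
    stop_rm("corpus ids do not match the fitted model",
            class = "recipemine_id_mismatch")
  k <- model$k
  ings <- sort(unique(unlist(sets)))
  tf <- matrix(0L, length(ings), k, dimnames = list(ings, NULL))
  for (i in seq_along(sets))
    tf[sets[[i]], cl[i]] <- tf[sets[[i]], cl[i]] + 1L
  df_term <- rowSums(tf > 0)
  idf <- log((1 + k) / (1 + df_term)) + 1
  score <- tf * idf
  out <- lapply(seq_len(k), function(j) {
    nz <- which(tf[, j] > 0)
    if (!length(nz)) return(NULL) # empty cluster
    ord <- nz[order(-score[nz, j], -tf[nz, j], ings[nz])]
    n <- min(top_n, length(ord))
    data.frame(cluster = j, rank = seq_len(n), ingredient = ings[ord][seq_len(n)],
               tf = tf[ord, j][seq_len(n)], score = score[ord, j][seq_len(n)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.nutrient_label_map <- c(
  carbohydrate_g = "high_carbohydrate", protein_g = "high_protein",
  fat_g = "high_fat", saturated_fat_g = "high_saturated_fat",
  fiber_g = "high_fiber", sugar_g = "high_sugar", sodium_mg = "high_sodium")

#' Characterize clusters by centroid z-scores
#'
#' A cluster gets the label `high_<nutrient>` for every nutrient whose
#' centroid exceeds `z_threshold` standard deviations above the corpus
#' mean; a cluster exceeding none is `balanced`.
#'
#' @param model a [kmeans_cluster()] fit (centroids are already in
#'   standardized space).
#' @param z_threshold z-score threshold (default 1.0).
#' @return named list: cluster id -> character vector of labels.
#' @export
characterize_clusters <- function(model, z_threshold = 1.0) {
  cents <- model$centroids
  labs <- lapply(seq_len(model$k), function(j) {
    hi <- colnames(cents)[cents[j, ] > z_threshold]
    hi <- unname(.nutrient_label_map[hi])
    if (length(hi)) sort(hi) else "balanced"
  })
  names(labs) <- as.character(seq_len(model$k))
  labs
}

#' Built-in annotation table for characterization labels
#'
#' Static text mapping each nutrient-characterization label to its dietary
#' interpretation and literature citation keys. Shipped as package data;
#' no risk inference is computed.
#'
#' @return data frame `label`, `annotation`, `citation_keys`.
#' @export
group_annotations <- function() {
  path <- system.file("extdata", "group_annotations.csv",
                      package = "recipemine", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Merge characterized clusters into groups
#'
#' With an explicit `merge_map` (the manual-curation path) the map is
#' validated and applied verbatim; otherwise clusters with identical label
#' sets are merged automatically. Each group is annotated with the static
#' dietary-interpretation text of its labels.
#'
#' @param labels output of [characterize_clusters()].
#' @param merge_map optional data frame with columns `cluster`, `group`.
#' @param annotations annotation table (default [group_annotations()]).
#' @return a `group_assignment`: list with `labels`, `group_of` (named
#'   character, cluster -> group id), `groups` (list group -> clusters)
#'   and `annotations` (data frame `group`, `labels`, `annotation`).
#' @export
merge_into_groups <- function(labels, merge_map = NULL,
                              annotations = group_annotations()) {
  clusters <- names(labels)
  if (!is.null(merge_map)) {
    unknown <- setdiff(as.character(merge_map$cluster), clusters)
    if (length(unknown))
      stop_rm("merge map references unknown cluster(s): %s",
              paste(unknown, collapse = ", "), class = "recipemine_merge_error")
    group_of <- setNames(as.character(merge_map$group),
                         as.character(merge_map$cluster))
    group_of <- group_of[clusters]
    group_of[is.na(group_of)] <- paste0("ungrouped_", clusters[is.na(group_of)])
    names(group_of) <- clusters
    shared <- vapply(split(clusters, group_of), function(cl)
      length(cl) == 1 || length(Reduce(intersect, labels[cl])) > 0, logical(1))
    if (any(!shared))
      warn_rm("group(s) without a shared characterization label: %s",
              paste(names(shared)[!shared], collapse = ", "),
              class = "recipemine_merge_warning")
  } else {
    key <- vapply(labels, function(l) paste(sort(l), collapse = "+"), character(1))
    uk <- unique(key) # order of first appearance = lowest member cluster
    group_of <- setNames(paste0("G", match(key, uk)), clusters)
  }
  groups <- split(clusters, group_of)
  ann <- do.call(rbind, lapply(names(groups), function(g) {
    labs <- sort(unique(unlist(labels[groups[[g]]])))
    txt <- annotations$annotation[match(labs, annotations$label)]
    data.frame(group = g, labels = paste(labs, collapse = "; "),
               annotation = paste(stats::na.omit(txt), collapse = " | "),
               stringsAsFactors = FALSE)
  }))
  structure(list(labels = labels, group_of = group_of, groups = groups,
                 annotations = ann),
            class = "group_assignment")
}

#' Recipes nearest each cluster centroid
#'
#' @param model a [kmeans_cluster()] fit.
#' @param profiles the profile matrix the model was fitted on.
#' @param m recipes per cluster (default 5).
#' @return data frame `cluster`, `rank`, `id`, `distance` (standardized
#'   space).
#' @export
nearest_recipes <- function(model, profiles, m = 5) {
  x <- scale(kmeans_features(profiles), center = model$scaling$center,
             scale = model$scaling$sd)
  d2 <- dist2(x, model$centroids)
  out <- lapply(seq_len(model$k), function(j) {
    members <- which(model$assignments[rownames(profiles)] == j)
    if (!length(members)) return(NULL)
    ord <- members[order(d2[members, j])]
    n <- min(m, length(ord))
    data.frame(cluster = j, rank = seq_len(n), id = rownames(profiles)[ord][seq_len(n)],
               distance = sqrt(pmax(d2[ord[seq_len(n)], j], 0)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
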