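# Multi-model inference over archives: sampling, distance matrices,
# embedding, common/distinguishing interaction sets, knockout disruption.

#' Sample archive records without replacement
#'
#' @param archive a `search_archive` data.frame
#' @param k sample size
#' @return sampled archive (rows in original relative order)
#' @export
sample_archive <- function(archive, k) {
  if (k > nrow(archive))
    stop("cannot sample ", k, " of ", nrow(archive), " records")
  idx <- sort(sample.int(nrow(archive), k))
  out <- archive[idx, ]
  rownames(out) <- NULL
  out
}

edge_sets_of <- function(models) {
  if (inherits(models, "search_archive") || is.data.frame(models))
    return(models$edges)
  lapply(models, function(m) {
    if (inherits(m, "boolean_model")) names(interactions_of(m))
    else as.character(m)
  })
}

#' Pairwise Jaccard distance matrix
#'
#' Entries `1 - jaccard(i, j)` over interaction sets; zero diagonal;
#' symmetric. Prespecified edges, shared by construction across archive
#' models, are excluded by the edge-set representation.
#'
#' @param models archive data.frame, list of [boolean_model()], or list of
#'   edge-id character vectors
#' @return square symmetric matrix in `[0, 1]`
#' @export
jaccard_distance_matrix <- function(models) {
  sets <- edge_sets_of(models)
  if (length(sets) < 2L) stop("need at least two models")
  n <- length(sets)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- 1 - jaccard_sets(sets[[i]], sets[[j]])
  d
}

#' Two-dimensional embedding of a model distance matrix
#'
#' Classical multidimensional scaling of the precomputed Jaccard distance
#' matrix; deterministic. Axis signs are fixed so the first model has
#' non-negative coordinates.
#'
#' @param d distance matrix from [jaccard_distance_matrix()]
#' @return n x 2 coordinate matrix
#' @export
embed_2d <- function(d) {
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  k <- min(2L, nrow(d) - 1L)
  xy <- cmdscale(stats::as.dist(d), k = k)
  while (ncol(xy) < 2L) xy <- cbind(xy, 0)
  for (j in 1:2) if (xy[1L, j] < 0) xy[, j] <- -xy[, j]
  colnames(xy) <- c("dim1", "dim2")
  xy
}

#' Group archive records into clusters
#'
#' Default labels are search-run provenance (`search_id`); alternatively a
#' distance-threshold hierarchical clustering of the Jaccard distances.
#'
#' @param archive a `search_archive` data.frame
#' @param by `"provenance"` or `"distance"`
#' @param h cut height for `by = "distance"`
#' @return object of class `cluster_view`: named list of archives
#' @export
cluster_archive <- function(archive, by = c("provenance", "distance"), h = 0.5) {
  by <- match.arg(by)
  labels <- if (by == "provenance") as.character(archive$search_id)
  else {
    d <- jaccard_distance_matrix(archive)
    as.character(stats::cutree(stats::hclust(stats::as.dist(d), "average"), h = h))
  }
  groups <- split(seq_len(nrow(archive)), labels)
  out <- lapply(groups, function(ix) {
    a <- archive[ix, ]
    rownames(a) <- NULL
    a
  })
  structure(out, class = "cluster_view", label_source = by)
}

#' @export
print.cluster_view <- function(x, ...) {
  cat(sprintf("Cluster view (%s labels): %d cluster(s) of sizes %s\n",
              attr(x, "label_source"), length(x),
              paste(vapply(x, nrow, 0L), collapse = ", ")))
  invisible(x)
}

#' Interactions common to a model cluster
#'
#' Interactions present in at least `threshold` of the cluster's models.
#' Prespecified edges (shared by construction) are reported separately.
#'
#' @param models archive rows / models of one cluster
#' @param threshold frequency threshold in `(0, 1]`
#' @param prespecified optional character vector of prespecified edge ids
#' @return list with `common` (named frequency vector, edges at or above the
#'   threshold), `frequencies` (all edges) and `prespecified`
#' @export
common_interactions <- function(models, threshold = 0.9, prespecified = character(0)) {
  stopifnot(threshold > 0, threshold <= 1)
  sets <- edge_sets_of(models)
  n <- length(sets)
  tab <- table(unlist(lapply(sets, unique)))
  freq <- setNames(as.numeric(tab) / n, names(tab))
  freq <- freq[setdiff(names(freq), prespecified)]
  freq <- sort(freq, decreasing = TRUE)
  eps <- 1e-12
  list(common = freq[freq >= threshold - eps],
       frequencies = freq,
       prespecified = prespecified)
}

#' Per-cluster intersection with a reference interaction set
#'
#' For each model, the size of the intersection of its interactions with the
#' reference model's interactions; aggregated as mean / median / max, with
#' the cluster size.
#'
#' @param models archive rows / models of one cluster
#' @param reference_edges reference interaction ids (character) or a
#'   [boolean_model()]
#' @param exclude_prespecified drop these edge ids from the reference before
#'   intersecting (the prior-knowledge edges every model contains)
#' @return one-row data.frame: `mean`, `median`, `max`, `cluster_size`
#' @export
intersection_stats <- function(models, reference_edges,
                               exclude_prespecified = character(0)) {
  if (inherits(reference_edges, "boolean_model"))
    reference_edges <- names(interactions_of(reference_edges,
                                             include_prespecified = TRUE))
  ref <- setdiff(reference_edges, exclude_prespecified)
  sets <- edge_sets_of(models)
  sizes <- vapply(sets, function(s) length(intersect(unique(s), ref)), 0L)
  data.frame(mean = mean(sizes), median = median(sizes),
             max = if (length(sizes)) max(sizes) else 0L,
             cluster_size = length(sizes))
}

itemset_support <- function(mat, items) {
  # mat: models x item logical matrix
  if (length(items) == 1L) return(mean(mat[, items]))
  mean(rowSums(mat[, items, drop = FALSE]) == length(items))
}

#' Mine distinguishing interaction sets
#'
#' Levelwise frequent-itemset search over each cluster's interaction sets:
#' itemsets of up to `max_size` interactions with in-cluster support at
#' least `in_freq` and support at most `out_freq` in every other cluster.
#' In-cluster support is anti-monotone, so candidates grow only from
#' frequent subsets. Among nested qualifying sets with identical support
#' signature only the minimal ones are reported. Output order is
#' deterministic (size, then lexicographic).
#'
#' @param clusters a [cluster_archive()] view (or named list of archives /
#'   edge-set lists)
#' @param max_size largest itemset size
#' @param in_freq minimum in-cluster frequency
#' @param out_freq maximum frequency in any other cluster
#' @return named list (per cluster) of data.frames with `set` (list column
#'   of edge ids), `size`, `in_freq`, `max_out_freq`
#' @export
distinguishing_sets <- function(clusters, max_size = 5L, in_freq = 0.9,
                                out_freq = 0.1) {
  stopifnot(in_freq > out_freq)
  sets_by_cluster <- lapply(clusters, edge_sets_of)
  nm <- names(sets_by_cluster) %||% as.character(seq_along(sets_by_cluster))
  out <- setNames(vector("list", length(sets_by_cluster)), nm)
  eps <- 1e-12
  for (ci in seq_along(sets_by_cluster)) {
    target <- sets_by_cluster[[ci]]
    items <- sort(unique(unlist(target)))
    if (!length(items)) { out[[ci]] <- empty_dsets(); next }
    tmat <- vapply(items, function(it)
      vapply(target, function(s) it %in% s, TRUE), logical(length(target)))
    tmat <- matrix(tmat, nrow = length(target),
                   dimnames = list(NULL, items))
    omats <- lapply(sets_by_cluster[-ci], function(cl)
      matrix(vapply(items, function(it)
        vapply(cl, function(s) it %in% s, TRUE), logical(length(cl))),
        nrow = length(cl), dimnames = list(NULL, items)))
    frequent_items <- items[colMeans(tmat) >= in_freq - eps]
    if (!length(frequent_items)) { out[[ci]] <- empty_dsets(); next }
    results <- list()
    frontier <- lapply(frequent_items, identity) # frequent itemsets, size k
    k <- 1L
    while (length(frontier) && k <= max_size) {
      qualifying <- list()
      for (s in frontier) {
        insup <- itemset_support(tmat, s)
        outsup <- if (length(omats))
          max(vapply(omats, itemset_support, 0, items = s)) else 0
        if (outsup <= out_freq + eps)
          qualifying[[length(qualifying) + 1L]] <-
            list(set = s, in_freq = insup, max_out_freq = outsup)
      }
      results <- c(results, qualifying)
      if (k < max_size) {
        cand <- list()
        seen <- character(0)
        for (s in frontier) {
          for (it in frequent_items) {
            if (it %in% s) next
            ns <- sort(c(s, it))
            kk <- paste(ns, collapse = "\r")
            if (kk %in% seen) next
            seen <- c(seen, kk)
            if (itemset_support(tmat, ns) >= in_freq - eps)
              cand[[length(cand) + 1L]] <- ns
          }
        }
        frontier <- cand
      } else frontier <- list()
      k <- k + 1L
    }
    out[[ci]] <- minimal_dsets(results)
  }
  out
}

empty_dsets <- function() {
  df <- data.frame(size = integer(0), in_freq = numeric(0),
                   max_out_freq = numeric(0))
  df$set <- list()
  df
}

minimal_dsets <- function(results) {
  if (!length(results)) return(empty_dsets())
  sizes <- vapply(results, function(r) length(r$set), 0L)
  ord <- order(sizes, vapply(results, function(r) paste(r$set, collapse = ";"), ""))
  results <- results[ord]
  sizes <- sizes[ord]
  keep <- rep(TRUE, length(results))
  eps <- 1e-9
  for (i in seq_along(results)) {
    if (!keep[i]) next
    for (j in seq_along(results)) {
      if (i == j || sizes[j] >= sizes[i]) next
      same_sig <- abs(results[[i]]$in_freq - results[[j]]$in_freq) < eps &&
        abs(results[[i]]$max_out_freq - results[[j]]$max_out_freq) < eps
      if (same_sig && all(results[[j]]$set %in% results[[i]]$set)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  results <- results[keep]
  df <- data.frame(size = vapply(results, function(r) length(r$set), 0L),
                   in_freq = vapply(results, function(r) r$in_freq, 0),
                   max_out_freq = vapply(results, function(r) r$max_out_freq, 0))
  df$set <- lapply(results, function(r) r$set)
  df
}

#' Rank interaction sets by knockout disruption
#'
#' For each set, knocks its interactions out of a sample of the cluster's
#' models and measures the mean reduction in condition similarity. Models
#' lacking any of the set's edges are skipped and counted. Sets are returned
#' sorted by mean reduction (the top row is the maximally disruptive set).
#'
#' @param sets list of interaction-id character vectors (e.g. the `set`
#'   column of [distinguishing_sets()])
#' @param models list of [boolean_model()] objects of the cluster
#' @param conditions list of [condition()] objects
#' @param n_sample number of models sampled per set
#' @return data.frame: `set` (list column), `mean_reduction`, `se_reduction`,
#'   `n_models`, `n_skipped`
#' @export
disruption_rank <- function(sets, models, conditions, n_sample = 100L) {
  pick <- if (length(models) > n_sample)
    models[sort(sample.int(length(models), n_sample))] else models
  base_scores <- vapply(pick, multi_condition_score, 0, conditions = conditions)
  model_edges <- lapply(pick, function(m) names(interactions_of(m)))
  rows <- lapply(sets, function(s) {
    s <- as.character(s)
    usable <- vapply(model_edges, function(e) all(s %in% e), TRUE)
    if (length(s) == 0L) usable <- rep(TRUE, length(pick)) # empty set: no-op
    red <- vapply(which(usable), function(i) {
      if (!length(s)) return(0)
      km <- knockout_interactions(pick[[i]], as.list(s))
      base_scores[i] - multi_condition_score(km, conditions)
    }, 0)
    data.frame(mean_reduction = if (length(red)) mean(red) else 0,
               se_reduction = if (length(red) > 1L) sd(red) / sqrt(length(red)) else 0,
               n_models = length(red), n_skipped = sum(!usable))
  })
  df <- do.call(rbind, rows)
  df$set <- lapply(sets, as.character)
  ord <- order(-df$mean_reduction,
               vapply(df$set, function(s) paste(s, collapse = ";"), ""))
  df <- df[ord, ]
  rownames(df) <- NULL
  df
}
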