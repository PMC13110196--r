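#' Pairwise distances between subject time series
#'
#' Euclidean distances between the subjects' series vectors of one group,
#' after per-visit median imputation of missing entries (as for
#' [lof_scores()]). This is the substrate of the similarity plot used to
#' spot subjects with few near neighbours.
#'
#' @param group a `ts_group` with at least two subjects.
#' @return Symmetric, zero-diagonal distance matrix with subject ids as
#'   dimnames.
#' @export
subject_distances <- function(group) {
  if (length(group$subject_ids) < 2L) {
    rlang::abort("need at least 2 subjects", class = "sitespotter_data_error")
  }
  m <- impute_visit_median(group$values)
  as.matrix(stats::dist(m))
}

#' Similarity-plot coordinates
#'
#' Classical metric multidimensional scaling of a subject distance matrix
#' to two dimensions (double-centring eigendecomposition). The embedding
#' is deterministic up to reflection; each axis's sign is fixed so that
#' the coordinate of largest magnitude is positive. Points generated in
#' the plane are recovered exactly; in general the embedding preserves
#' the ordering of the large distances, which is what visual outlier
#' screening relies on.
#'
#' @param distances symmetric distance matrix (>= 3 subjects).
#' @return Subjects x 2 coordinate matrix.
#' @export
similarity_coordinates <- function(distances) {
  n <- nrow(distances)
  if (is.null(n) || n < 3L) {
    rlang::abort("need at least 3 subjects for a similarity plot",
                 class = "sitespotter_data_error")
  }
  xy <- stats::cmdscale(stats::as.dist(distances), k = 2L)
  if (ncol(xy) < 2L) {
    xy <- cbind(xy, matrix(0, n, 2L - ncol(xy)))
  }
  for (j in 1:2) {
    i_max <- which.max(abs(xy[, j]))
    if (xy[i_max, j] < 0) xy[, j] <- -xy[, j]
  }
  dimnames(xy) <- list(rownames(distances), c("dim1", "dim2"))
  xy
}

#' Subject-level outlier report for one group
#'
#' Combines the two subject-screening views: similarity-plot coordinates
#' with a per-subject isolation statistic (mean distance to the `k`
#' nearest neighbours; isolated subjects have few near neighbours), and,
#' when a feature matrix is supplied, per-feature extremity ranks
#' (rank 1 = most extreme, two-sided).
#'
#' @param group a `ts_group` with at least 3 subjects.
#' @param features optional `feature_matrix` for the same group.
#' @param k number of nearest neighbours for the isolation statistic.
#' @return List with `group_id`, `coordinates`, `isolation` and (when
#'   `features` is given) `feature_ranks`, a tibble of per-feature ranks.
#' @export
subject_outlier_report <- function(group, features = NULL, k = 5L) {
  d <- subject_distances(group)
  n <- nrow(d)
  k <- min(k, n - 1L)
  iso <- vapply(seq_len(n), function(i) {
    mean(sort(d[i, -i], partial = k)[seq_len(k)])
  }, numeric(1))
  names(iso) <- rownames(d)
  rep <- list(
    group_id = group$group_id,
    coordinates = similarity_coordinates(d),
    isolation = iso
  )
  if (!is.null(features)) {
    ranks <- tibble::tibble(subject_id = features$subject_id)
    for (f in intersect(feature_names(), names(features))) {
      ranks[[f]] <- extremity_rank(features[[f]], features$subject_id)
    }
    rep$feature_ranks <- ranks
  }
  structure(rep, class = "subject_outlier_report")
}

# two-sided extremity |v - median| / MAD, rank 1 = most extreme; MAD = 0
# falls back to |v - median|; ties and NAs broken/ordered by subject id
extremity_stat <- function(v) {
  med <- stats::median(v, na.rm = TRUE)
  mad <- stats::mad(v, na.rm = TRUE)
  if (!is.finite(mad) || mad == 0) {
    rlang::warn("MAD is zero; falling back to absolute deviation")
    abs(v - med)
  } else {
    abs(v - med) / mad
  }
}

extremity_rank <- function(v, subject_id) {
  ext <- suppressWarnings(extremity_stat(v))
  ext[is.na(ext)] <- -Inf # undefined features rank last
  ord <- order(-ext, subject_id)
  rk <- integer(length(v))
  rk[ord] <- seq_along(v)
  rk
}

#' Rank subjects by feature extremity
#'
#' Orders subjects by the two-sided extremity `|value - median| / MAD` of
#' one feature, most extreme first, and returns the top `top_n`. The
#' robust centre/scale means a single gross outlier cannot mask itself by
#' inflating the spread. When the MAD is zero the plain absolute
#' deviation is used (with a warning); exact ties are broken by subject
#' id, so the ordering is deterministic.
#'
#' @param features a `feature_matrix`.
#' @param feature feature column name.
#' @param top_n number of subjects to return.
#' @return Character vector of subject ids, most extreme first.
#' @export
rank_extreme_subjects <- function(features, feature, top_n = 10L) {
  if (!feature %in% names(features)) {
    rlang::abort(sprintf("feature '%s' not present", feature),
                 class = "sitespotter_config_error")
  }
  v <- features[[feature]]
  defined <- !is.na(v)
  if (!any(defined)) {
    rlang::abort(sprintf("feature '%s' is undefined for every subject", feature),
                 class = "sitespotter_data_error")
  }
  ext <- extremity_stat(v[defined])
  ids <- features$subject_id[defined]
  ids[order(-ext, ids)][seq_len(min(top_n, length(ids)))]
}
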