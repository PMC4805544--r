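#' Principal components of the population response
#'
#' Extracts the major modes of variation of a neuron-by-time auROC matrix.
#' Columns (time bins) are mean-centered but not variance-scaled, since
#' auROC values already share the `[0, 1]` scale. Component signs are fixed
#' so that each component's largest-magnitude loading is positive, making
#' the decomposition deterministic.
#'
#' @param mat An `auroc_matrix` or a plain numeric matrix (neurons x bins).
#' @param n_components Number of components to keep.
#' @return A list of class `response_pca` with `scores` (neurons x
#'   n_components), `loadings` (bins x n_components), `explained` (variance
#'   shares of the kept components) and `center`.
#' @export
response_pca <- function(mat, n_components = 3) {
  x <- if (inherits(mat, "auroc_matrix")) mat$values else as.matrix(mat)
  if (n_components > min(dim(x))) {
    stop("response_pca: n_components exceeds matrix rank bound min(",
         nrow(x), ", ", ncol(x), ")")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  load <- p$rotation[, k, drop = FALSE]
  scores <- p$x[, k, drop = FALSE]
  # sign convention: largest |loading| of each component is positive
  for (j in k) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  tot <- sum(p$sdev^2)
  out <- list(scores = scores, loadings = load,
              explained = if (tot > 0) p$sdev[k]^2 / tot else rep(0, length(k)),
              center = p$center)
  class(out) <- "response_pca"
  out
}

#' Complete-linkage clustering of neurons in component space
#'
#' Agglomerative hierarchical clustering on Euclidean distances between
#' neurons' component scores, using complete linkage, with the tree cut at
#' the unique height yielding exactly `k` clusters. Merge ties are resolved
#' by the standard lowest-index rule, so the result is deterministic given
#' the input order.
#'
#' @param scores A `response_pca` or a numeric matrix (neurons x features).
#' @param k Number of clusters to extract.
#' @return Integer vector of cluster indices (1..k), in input order.
#' @export
cluster_neurons <- function(scores, k = 3) {
  x <- if (inherits(scores, "response_pca")) scores$scores else
    as.matrix(scores)
  if (nrow(x) < k) {
    stop("cluster_neurons: fewer neurons (", nrow(x), ") than clusters (",
         k, ")")
  }
  if (nrow(x) == k) return(seq_len(k))
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "complete")
  unname(stats::cutree(hc, k = k))
}

#' Label the three response archetypes
#'
#' Given exactly three clusters and the auROC matrix they were derived
#' from, computes each cluster's mean auROC trace and assigns:
#' `sustained_inhibited` to the cluster with the lowest mean over the full
#' window (the suppression-dominated trace); of the remaining two, `phasic`
#' to the cluster with the larger transient index (onset-window mean minus
#' late-window mean) and `sustained_excited` to the other. Ties on a
#' deciding statistic raise an error rather than being broken arbitrarily.
#'
#' @param clusters Integer cluster indices from [cluster_neurons()].
#' @param mat The `auroc_matrix` used for clustering.
#' @param config An [analysis_config()]; its `onset_window` and
#'   `sustained_window` define the transient index.
#' @return A data.frame of class `class_labels` with columns `neuron_id`,
#'   `cluster`, `archetype`.
#' @export
label_archetypes <- function(clusters, mat, config = analysis_config()) {
  stopifnot(inherits(mat, "auroc_matrix"))
  ids <- sort(unique(clusters))
  if (length(ids) != 3) {
    stop("label_archetypes: expected exactly 3 clusters, got ", length(ids))
  }
  traces <- t(vapply(ids, function(cl) {
    colMeans(mat$values[clusters == cl, , drop = FALSE])
  }, numeric(ncol(mat$values))))
  overall <- rowMeans(traces)
  if (anyDuplicated(signif(overall, 12))) {
    stop("label_archetypes: ambiguous assignment - clusters tie on mean auROC")
  }
  inhib <- which.min(overall)
  rest <- setdiff(seq_along(ids), inhib)
  onset <- mat$bin_centers >= mat$window[1] &
    mat$bin_centers < mat$window[1] + config$onset_window
  late <- mat$bin_centers >= config$sustained_window[1] &
    mat$bin_centers < config$sustained_window[2]
  if (!any(onset) || !any(late)) {
    stop("label_archetypes: matrix window does not cover onset and late bins")
  }
  transient <- rowMeans(traces[, onset, drop = FALSE]) -
    rowMeans(traces[, late, drop = FALSE])
  if (abs(diff(transient[rest])) < 1e-12) {
    stop("label_archetypes: ambiguous assignment - clusters tie on transient index")
  }
  phasic <- rest[which.max(transient[rest])]
  arch <- character(3)
  arch[inhib] <- "sustained_inhibited"
  arch[phasic] <- "phasic"
  arch[setdiff(rest, phasic)] <- "sustained_excited"
  out <- data.frame(neuron_id = mat$neuron_ids,
                    cluster = match(clusters, ids),
                    archetype = arch[match(clusters, ids)],
                    stringsAsFactors = FALSE)
  class(out) <- c("class_labels", "data.frame")
  out
}

#' Waveform criteria for putative dopamine neurons
#'
#' @param min_negative_half_width Minimum negative half-width in
#'   microseconds (standard criterion 450).
#' @param deflection_ratio_threshold Threshold on the ratio of the (signed)
#'   maximal positive to the (signed) minimal negative voltage deflection.
#'   With the negative deflection stored as a negative number, a ratio
#'   above 0 requires a genuinely negative numerator, so the operative
#'   reading - a genuinely positive maximal deflection - is applied: the
#'   criterion passes when `max_positive_deflection >
#'   deflection_ratio_threshold * |min_negative_deflection|`.
#' @return An object of class `waveform_criteria`.
#' @export
waveform_criteria <- function(min_negative_half_width = 450,
                              deflection_ratio_threshold = 0) {
  stopifnot(min_negative_half_width > 0)
  out <- list(min_negative_half_width = min_negative_half_width,
              deflection_ratio_threshold = deflection_ratio_threshold)
  class(out) <- "waveform_criteria"
  out
}

#' Classify waveforms as wide (putative dopaminergic) or not
#'
#' A neuron passes when its negative half-width exceeds the width criterion
#' and its maximal positive deflection exceeds the ratio threshold times the
#' magnitude of its minimal negative deflection (so with the default
#' threshold of 0, a genuinely positive deflection is required).
#'
#' @param features Data.frame with columns `neuron_id`,
#'   `negative_half_width` (us), `max_positive_deflection`,
#'   `min_negative_deflection` (signed, negative).
#' @param criteria A [waveform_criteria()].
#' @return Logical vector `wide_waveform`, one element per row of
#'   `features`.
#' @export
classify_waveform <- function(features, criteria = waveform_criteria()) {
  req <- c("negative_half_width", "max_positive_deflection",
           "min_negative_deflection")
  miss <- setdiff(req, names(features))
  if (length(miss)) {
    stop("classify_waveform: missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(features$min_negative_deflection == 0)) {
    stop("classify_waveform: zero negative deflection - ratio undefined")
  }
  if (any(features$min_negative_deflection > 0)) {
    stop("classify_waveform: min_negative_deflection must be stored signed (negative)")
  }
  wide <- features$negative_half_width > criteria$min_negative_half_width
  ratio_ok <- features$max_positive_deflection >
    criteria$deflection_ratio_threshold * abs(features$min_negative_deflection)
  wide & ratio_ok
}

#' Full response-type classification
#'
#' Convenience wrapper: auROC matrix -> 3 principal components -> 3-cluster
#' complete-linkage clustering -> archetype labels, plus the waveform flag
#' when features are supplied.
#'
#' @param mat An `auroc_matrix`.
#' @param config An [analysis_config()].
#' @param waveforms Optional waveform feature table (see
#'   [classify_waveform()]).
#' @param n_components,k Components kept and clusters extracted.
#' @return A `class_labels` data.frame with columns `neuron_id`, `cluster`,
#'   `archetype` and (if waveforms were given) `wide_waveform`.
#' @export
classify_neurons <- function(mat, config = analysis_config(),
                             waveforms = NULL, n_components = 3, k = 3) {
  pca <- response_pca(mat, n_components)
  cl <- cluster_neurons(pca, k)
  labels <- label_archetypes(cl, mat, config)
  if (!is.null(waveforms)) {
    m <- match(labels$neuron_id, waveforms$neuron_id)
    labels$wide_waveform <- classify_waveform(waveforms[m, , drop = FALSE])
  }
  labels
}
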