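#' Cultivar panel
#'
#' A panel of genotypes for similarity analysis: one row per entry with a
#' unique `name`, a `group` label (`indica`, `japonica`, `hybrid` or
#' `ideotype`) and the eight coefficients `P1, P5, P2R, PHINT, P2O, G1, G2,
#' G3`.
#'
#' @param df data.frame with columns `name`, `group` and the eight
#'   coefficients.
#' @return data.frame of class `cultivar_panel`.
#' @export
cultivar_panel <- function(df) {
  need <- c("name", "group", ga_coefficients())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cultivar_panel: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$name)) stop("cultivar_panel: duplicate names")
  if (anyNA(df[need])) stop("cultivar_panel: missing values")
  df <- as.data.frame(df)[need]
  class(df) <- c("cultivar_panel", "data.frame")
  df
}

#' @rdname cultivar_panel
#' @param path CSV path with header `name,group,P1,P5,P2R,PHINT,P2O,G1,G2,G3`.
#' @export
read_panel <- function(path) {
  cultivar_panel(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname cultivar_panel
#' @param panel a `cultivar_panel`.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' Joint min-max scaling of cultivars and ideotypes
#'
#' Coefficient scales span four orders of magnitude (thermal times of hundreds
#' of GDD against grain weights of hundredths of a gram), so raw distances
#' would be dominated by a single coefficient. Each coefficient is min-max
#' scaled to `[0, 1]` over the *combined* cultivar + ideotype set; a constant
#' coefficient maps to 0.
#'
#' @param panel a [cultivar_panel()] of field cultivars.
#' @param ideotypes a [cultivar_panel()] (or coefficient data.frame) of
#'   ideotypes; may be `NULL`.
#' @return numeric matrix (rows named by entry; ideotype rows first) with an
#'   attribute `n_ideotypes`.
#' @export
scale_panel <- function(panel, ideotypes = NULL) {
  cols <- ga_coefficients()
  m_cult <- as.matrix(panel[cols])
  rownames(m_cult) <- panel$name
  m <- m_cult
  n_id <- 0L
  if (!is.null(ideotypes)) {
    m_id <- as.matrix(as.data.frame(ideotypes)[cols])
    rownames(m_id) <- as.data.frame(ideotypes)$name
    m <- rbind(m_id, m_cult)
    n_id <- nrow(m_id)
  }
  if (nrow(m) < 2) stop("scale_panel: need at least 2 entries")
  rng <- apply(m, 2, range)
  span <- rng[2, ] - rng[1, ]
  scaled <- sweep(m, 2, rng[1, ])
  scaled <- sweep(scaled, 2, ifelse(span > 0, span, 1), "/")
  scaled[, span == 0] <- 0
  attr(scaled, "n_ideotypes") <- n_id
  scaled
}

# distance between one vector and the rows of a matrix, per metric
.dist_to <- function(v, m, metric) {
  switch(metric,
    euclidean = sqrt(colSums((t(m) - v)^2)),
    manhattan = colSums(abs(t(m) - v)),
    cosine = {
      nv <- sqrt(sum(v^2))
      nm <- sqrt(rowSums(m^2))
      d <- numeric(nrow(m))
      zero <- nv == 0 | nm == 0
      # an all-zero vector has no direction: define its cosine distance as 1
      d[zero] <- 1
      if (any(!zero))
        d[!zero] <- 1 - as.vector(m[!zero, , drop = FALSE] %*% v) /
          (nv * nm[!zero])
      pmax(0, d)
    },
    stop("unknown metric: ", metric))
}

#' Ideotype-to-cultivar distance tensor
#'
#' Distances from every ideotype to every cultivar under each metric.
#'
#' @param scaled matrix from [scale_panel()] (ideotype rows first), or a plain
#'   matrix with `n_ideotypes` supplied.
#' @param metrics any of `"euclidean"`, `"manhattan"`, `"cosine"`.
#' @param n_ideotypes number of leading rows that are ideotypes (defaults to
#'   the `scale_panel` attribute).
#' @return numeric array `[ideotype, cultivar, metric]` with dimnames.
#' @export
pairwise_distances <- function(scaled,
                               metrics = c("euclidean", "manhattan", "cosine"),
                               n_ideotypes = attr(scaled, "n_ideotypes")) {
  if (is.null(n_ideotypes) || n_ideotypes < 1)
    stop("pairwise_distances: no ideotype rows identified")
  if (any(!is.finite(scaled))) stop("pairwise_distances: non-finite input")
  idx_v <- seq_len(n_ideotypes)
  m_cult <- scaled[-idx_v, , drop = FALSE]
  d <- array(NA_real_,
             dim = c(n_ideotypes, nrow(m_cult), length(metrics)),
             dimnames = list(rownames(scaled)[idx_v], rownames(m_cult),
                             metrics))
  for (v in idx_v)
    for (mt in metrics)
      d[v, , mt] <- .dist_to(scaled[v, ], m_cult, mt)
  d
}

#' Similarity index from a distance tensor
#'
#' Each metric is first normalized by its own maximum (so Manhattan's larger
#' magnitudes do not dominate), the metrics are averaged into `d_bar`, and
#' similarity is `1 - d_bar / max(d_bar)`: 1 for a zero-distance pair, 0 for
#' the most distant pair. If every pair is identical (`max(d_bar) = 0`) all
#' similarities are defined as 1.
#'
#' @param dist_tensor array from [pairwise_distances()].
#' @return list: `similarity` and `d_bar` matrices (ideotype x cultivar).
#' @export
similarity_index <- function(dist_tensor) {
  metrics <- dimnames(dist_tensor)[[3]]
  norm <- dist_tensor
  for (mt in metrics) {
    mx <- max(dist_tensor[, , mt])
    if (mx > 0) norm[, , mt] <- dist_tensor[, , mt] / mx
  }
  d_bar <- apply(norm, c(1, 2), mean)
  mx <- max(d_bar)
  sim <- if (mx > 0) 1 - d_bar / mx else array(1, dim(d_bar), dimnames(d_bar))
  list(similarity = sim, d_bar = d_bar)
}

#' Top-k frequency consensus
#'
#' For each ideotype, the `k` nearest cultivars under every metric are pooled
#' and counted: a cultivar nearest under all metrics gets frequency equal to
#' the number of metrics. Ties in the ranking are broken by lower averaged
#' distance, then by name. A global ranking aggregates counts over ideotypes.
#'
#' @param dist_tensor array from [pairwise_distances()].
#' @param k top-k per metric (default 4; must not exceed the cultivar count).
#' @return list: `per_ideotype` (list of data.frames `cultivar`, `frequency`,
#'   `d_bar`) and `global` (data.frame `cultivar`, `frequency`).
#' @export
topk_frequency <- function(dist_tensor, k = 4) {
  metrics <- dimnames(dist_tensor)[[3]]
  cultivars <- dimnames(dist_tensor)[[2]]
  if (k > length(cultivars)) stop("topk_frequency: k exceeds cultivar count")
  d_bar <- similarity_index(dist_tensor)$d_bar
  per <- lapply(dimnames(dist_tensor)[[1]], function(v) {
    picks <- unlist(lapply(metrics, function(mt) {
      d <- dist_tensor[v, , mt]
      cultivars[order(d, cultivars)][seq_len(k)]
    }))
    counts <- table(picks)
    df <- data.frame(cultivar = names(counts),
                     frequency = as.integer(counts),
                     d_bar = d_bar[v, names(counts)],
                     stringsAsFactors = FALSE, row.names = NULL)
    df[order(-df$frequency, df$d_bar, df$cultivar), , drop = FALSE]
  })
  names(per) <- dimnames(dist_tensor)[[1]]
  all_counts <- table(unlist(lapply(per, function(df)
    rep(df$cultivar, df$frequency))))
  global <- data.frame(cultivar = names(all_counts),
                       frequency = as.integer(all_counts),
                       stringsAsFactors = FALSE, row.names = NULL)
  global <- global[order(-global$frequency, global$cultivar), , drop = FALSE]
  list(per_ideotype = per, global = global)
}

#' PCA validation of the similarity ranking
#'
#' Z-scores the combined coefficient matrix, eigendecomposes its covariance,
#' and reports variance fractions plus the nearest cultivars per ideotype by
#' Euclidean distance in the space of the leading principal components — an
#' independent check on the metric-consensus ranking. Constant columns are
#' dropped before standardization; rank deficiency is handled by truncating
#' to positive eigenvalues.
#'
#' @param panel a [cultivar_panel()].
#' @param ideotypes ideotype entries (as in [scale_panel()]).
#' @param n_pc components used for the distance check (default 3).
#' @return list: `scores` (entries x PCs), `variance_fraction`,
#'   `n_ideotypes`, `nearest` (list per ideotype of cultivars ordered by
#'   PC-space distance).
#' @export
pca_validate <- function(panel, ideotypes = NULL, n_pc = 3) {
  cols <- ga_coefficients()
  m_cult <- as.matrix(panel[cols]); rownames(m_cult) <- panel$name
  m <- m_cult; n_id <- 0L
  if (!is.null(ideotypes)) {
    m_id <- as.matrix(as.data.frame(ideotypes)[cols])
    rownames(m_id) <- as.data.frame(ideotypes)$name
    m <- rbind(m_id, m_cult); n_id <- nrow(m_id)
  }
  if (nrow(m) < 3) stop("pca_validate: need at least 3 entries")
  keep <- apply(m, 2, stats::sd) > 0
  z <- scale(m[, keep, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  pos <- pc$sdev^2 > 1e-12 * max(pc$sdev^2)
  scores <- pc$x[, pos, drop = FALSE]
  varfrac <- pc$sdev[pos]^2 / sum(pc$sdev^2)
  nearest <- NULL
  if (n_id > 0) {
    use <- seq_len(min(n_pc, ncol(scores)))
    s_id <- scores[seq_len(n_id), use, drop = FALSE]
    s_cu <- scores[-seq_len(n_id), use, drop = FALSE]
    nearest <- lapply(seq_len(n_id), function(v) {
      d <- sqrt(colSums((t(s_cu) - s_id[v, ])^2))
      names(sort(d))
    })
    names(nearest) <- rownames(s_id)
  }
  list(scores = scores, variance_fraction = varfrac, n_ideotypes = n_id,
       nearest = nearest)
}

#' Full similarity report
#'
#' Scales, computes the distance tensor, the similarity matrix, the top-k
#' frequency consensus and the PCA validation in one call.
#'
#' @param panel field-cultivar [cultivar_panel()].
#' @param ideotypes ideotype entries.
#' @param metrics distance metrics (see [pairwise_distances()]).
#' @param k top-k per metric.
#' @return list of class `similarity_report` with elements `distances`,
#'   `similarity`, `d_bar`, `frequency`, `pca`.
#' @export
similarity_report <- function(panel, ideotypes,
                              metrics = c("euclidean", "manhattan", "cosine"),
                              k = 4) {
  scaled <- scale_panel(panel, ideotypes)
  d <- pairwise_distances(scaled, metrics)
  si <- similarity_index(d)
  structure(list(distances = d, similarity = si$similarity,
                 d_bar = si$d_bar,
                 frequency = topk_frequency(d, k),
                 pca = pca_validate(panel, ideotypes)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("Similarity report:", nrow(x$similarity), "ideotype(s) x",
      ncol(x$similarity), "cultivars\n")
  cat("Global frequency ranking (top 5):\n")
  print(utils::head(x$frequency$global, 5))
  cat(sprintf("PCA: top-3 variance fraction %.3f\n",
              sum(x$pca$variance_fraction[1:min(3, length(x$pca$variance_fraction))])))
  invisible(x)
}
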