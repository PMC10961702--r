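# Chemical-structure clustering: Tanimoto distance on binary fingerprints,
# Ward hierarchical clustering with a fixed-height cut, 1-nearest-neighbour
# assignment of new chemicals to existing clusters, cluster activity
# labeling, and the Henry's-law volatility filter.

#' Tanimoto distance between two binary fingerprints
#'
#' `D = 1 - |a AND b| / |a OR b|`. Identical fingerprints have distance 0 and
#' disjoint non-empty fingerprints distance 1. Two all-zero fingerprints are
#' treated as identical (distance 0); the distance between an empty and a
#' non-empty fingerprint is 1.
#'
#' @param a,b 0/1 (or logical) vectors of equal length.
#' @return Distance between 0 and 1.
#' @export
#' @examples
#' tanimoto_distance(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1 - 1/3
tanimoto_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprints must have equal bit length (got ",
         length(a), " and ", length(b), ")")
  }
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0L) return(0)
  1 - sum(a & b) / u
}

#' Pairwise Tanimoto distance matrix
#'
#' @param fingerprints Chemicals x bits 0/1 matrix with chemical ids as
#'   rownames.
#' @return A `dist` object of pairwise Tanimoto distances.
#' @export
tanimoto_matrix <- function(fingerprints) {
  x <- as.matrix(fingerprints)
  if (!all(x %in% c(0, 1))) stop("fingerprints must be binary 0/1")
  storage.mode(x) <- "double"
  inter <- tcrossprod(x)
  r <- rowSums(x)
  un <- outer(r, r, "+") - inter
  d <- 1 - inter / un
  d[un == 0] <- 0
  diag(d) <- 0
  stats::as.dist(d)
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under Ward's minimum-variance criterion. The
#' default is the squared-distance (`"ward.D2"`) update applied directly to
#' the Tanimoto distances; the classic form (`"ward.D"`) is available.
#' Applying Ward linkage to a non-Euclidean distance such as Tanimoto is a
#' standard approximation in cheminformatics rather than an exact
#' minimum-variance procedure.
#'
#' @param distances A `dist` object or a square symmetric non-negative
#'   matrix with zero diagonal.
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return An `hclust` tree; merge heights are non-decreasing.
#' @export
ward_cluster <- function(distances, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  if (is.matrix(distances)) {
    if (nrow(distances) != ncol(distances)) {
      stop("distance matrix must be square")
    }
    if (any(distances < 0)) stop("distances must be non-negative")
    if (any(abs(distances - t(distances)) > 1e-12)) {
      stop("distance matrix must be symmetric")
    }
    if (any(diag(distances) != 0)) {
      stop("distance matrix must have a zero diagonal")
    }
    distances <- stats::as.dist(distances)
  }
  if (!inherits(distances, "dist")) {
    stop("distances must be a dist object or a square matrix")
  }
  if (any(distances < 0)) stop("distances must be non-negative")
  stats::hclust(distances, method = method)
}

#' Cut a cluster tree at a fixed height
#'
#' Clusters are the connected components joined by merges strictly below the
#' cut height; the cluster count is non-increasing in the height. The
#' workflow default cut height is 1.
#'
#' @param tree An `hclust` tree from [ward_cluster()].
#' @param height Non-negative cut height (default 1).
#' @return Named integer vector of cluster labels.
#' @export
cut_tree <- function(tree, height = 1) {
  if (!inherits(tree, "hclust")) stop("tree must be an hclust object")
  if (!is.numeric(height) || length(height) != 1L || height < 0) {
    stop("height must be a single non-negative number")
  }
  stats::cutree(tree, h = height)
}

# cross Tanimoto distances: queries x references
tanimoto_cross <- function(query, reference) {
  q <- as.matrix(query); r <- as.matrix(reference)
  if (ncol(q) != ncol(r)) {
    stop("query and reference fingerprints must have equal bit length")
  }
  storage.mode(q) <- "double"; storage.mode(r) <- "double"
  inter <- tcrossprod(q, r)
  un <- outer(rowSums(q), rowSums(r), "+") - inter
  d <- 1 - inter / un
  d[un == 0] <- 0
  d
}

#' Assign chemicals to existing clusters by k-nearest neighbours
#'
#' Assigns each query fingerprint the cluster of its nearest reference
#' chemical under Tanimoto distance (k = 1 by default, as used when mapping
#' the AR model set onto the chemical-universe clusters). Ties are broken
#' deterministically: the lowest cluster id wins, then the lexicographically
#' smallest reference chemical id.
#'
#' @param query A fingerprint vector or queries x bits matrix (rownames =
#'   chemical ids).
#' @param reference References x bits 0/1 matrix with rownames.
#' @param labels Cluster labels for the reference chemicals (named by
#'   chemical id, or aligned to the reference rows).
#' @param k Number of neighbours (majority vote for k > 1, ties to the
#'   lowest cluster id).
#' @return Named integer/character vector of cluster assignments.
#' @export
assign_knn <- function(query, reference, labels, k = 1L) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  reference <- as.matrix(reference)
  if (nrow(reference) == 0L) stop("reference fingerprint set is empty")
  if (!is.null(names(labels)) && !is.null(rownames(reference))) {
    labels <- labels[rownames(reference)]
  }
  if (length(labels) != nrow(reference)) {
    stop("labels must cover every reference chemical")
  }
  k <- as.integer(k)
  if (k < 1L || k > nrow(reference)) stop("k must be in 1..n_reference")
  d <- tanimoto_cross(query, reference)
  ref_ids <- rownames(reference)
  if (is.null(ref_ids)) ref_ids <- as.character(seq_len(nrow(reference)))
  out <- vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, ]
    if (k == 1L) {
      # ties: lowest cluster id wins (then lexicographic chemical id, which
      # cannot change the winning label)
      nearest <- which(di == min(di))
      min(labels[nearest])
    } else {
      o <- order(di, labels, ref_ids)[seq_len(k)]
      votes <- table(labels[o])
      winners <- names(votes)[votes == max(votes)]
      min(winners)
    }
  }, labels[1L][[1L]])
  names(out) <- rownames(query)
  out
}

#' Label clusters by the activity of their chemicals
#'
#' A cluster is `both-effect` if it contains at least one agonist-positive
#' and at least one antagonist-positive chemical (possibly the same
#' chemical), `agonist-active`/`antagonist-active` if only one mode is
#' present, and `no-effect` otherwise. Chemicals without a call are treated
#' as inactive and reported.
#'
#' @param labels Named vector mapping chemical_id to cluster id.
#' @param agonist_calls,antagonist_calls Named 0/1 call vectors.
#' @return Data frame with one row per cluster: `cluster_id`, `label`, and
#'   per-category chemical counts (`n_agonist`, `n_antagonist`, `n_both`,
#'   `n_inactive`, `n_chemicals`). Chemicals missing a call are listed in
#'   the `missing_calls` attribute.
#' @export
label_clusters <- function(labels, agonist_calls, antagonist_calls) {
  if (is.null(names(labels))) stop("labels must be named by chemical_id")
  chems <- names(labels)
  get_call <- function(calls) {
    out <- calls[chems]
    out[is.na(out)] <- 0L
    out
  }
  missing <- union(setdiff(chems, names(agonist_calls)),
                   setdiff(chems, names(antagonist_calls)))
  if (length(missing) > 0L) {
    message(length(missing),
            " chemical(s) without activity calls treated as inactive")
  }
  ag <- as.integer(get_call(agonist_calls))
  ant <- as.integer(get_call(antagonist_calls))
  category <- ifelse(ag == 1L & ant == 1L, "both",
                     ifelse(ag == 1L, "agonist",
                            ifelse(ant == 1L, "antagonist", "inactive")))
  cl <- as.character(labels)
  uc <- sort(unique(cl))
  count <- function(cat) {
    as.integer(table(factor(cl[category == cat], levels = uc)))
  }
  n_ag <- count("agonist"); n_ant <- count("antagonist")
  n_both <- count("both"); n_in <- count("inactive")
  has_ag <- n_ag + n_both > 0L
  has_ant <- n_ant + n_both > 0L
  label <- ifelse(has_ag & has_ant, "both-effect",
                  ifelse(has_ag, "agonist-active",
                         ifelse(has_ant, "antagonist-active", "no-effect")))
  out <- data.frame(
    cluster_id = uc, label = label,
    n_agonist = n_ag, n_antagonist = n_ant, n_both = n_both,
    n_inactive = n_in,
    n_chemicals = n_ag + n_ant + n_both + n_in,
    stringsAsFactors = FALSE
  )
  attr(out, "missing_calls") <- missing
  out
}

#' Henry's-law volatility category
#'
#' Categorizes chemicals as `high`, `moderate`, `slight` or `none` by
#' comparing the Henry's law constant (atm m^3/mol) against strictly
#' decreasing thresholds. The defaults (high above 1e-3, moderate above
#' 1e-5, slight above 1e-7) are configurable placeholders for the regulatory
#' aqueous-volatilization cutoffs.
#'
#' @param henry Numeric vector of Henry's law constants; `NA` stays `NA`.
#' @param thresholds Named vector `c(high=, moderate=, slight=)`, strictly
#'   decreasing.
#' @return Character vector of categories.
#' @export
volatility_category <- function(henry,
                                thresholds = c(high = 1e-3,
                                               moderate = 1e-5,
                                               slight = 1e-7)) {
  if (!all(c("high", "moderate", "slight") %in% names(thresholds))) {
    stop("thresholds must be named high, moderate, slight")
  }
  th <- thresholds[c("high", "moderate", "slight")]
  if (any(diff(th) >= 0)) {
    stop("volatility thresholds must be strictly decreasing")
  }
  ifelse(is.na(henry), NA_character_,
         ifelse(henry > th["high"], "high",
                ifelse(henry > th["moderate"], "moderate",
                       ifelse(henry > th["slight"], "slight", "none"))))
}

#' Volatility filter
#'
#' Removes chemicals categorized `high` or `moderate` (too volatile for
#' reliable in vitro screening); `slight`/`none` chemicals are retained.
#' Chemicals with a missing Henry's law constant are retained and flagged
#' rather than silently dropped.
#'
#' @param records Data frame with columns `chemical_id` and
#'   `henrys_law_constant`.
#' @param thresholds See [volatility_category()].
#' @return List with `retained` (chemical ids), `removed` (data frame with
#'   categories), and `flagged` (ids lacking a Henry's law constant).
#' @export
volatility_filter <- function(records,
                              thresholds = c(high = 1e-3,
                                             moderate = 1e-5,
                                             slight = 1e-7)) {
  required <- c("chemical_id", "henrys_law_constant")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop("records missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  cat <- volatility_category(records$henrys_law_constant, thresholds)
  volatile <- !is.na(cat) & cat %in% c("high", "moderate")
  flagged <- records$chemical_id[is.na(cat)]
  if (length(flagged) > 0L) {
    message(length(flagged),
            " chemical(s) lack a Henry's law constant; retained and flagged")
  }
  list(
    retained = records$chemical_id[!volatile],
    removed = data.frame(chemical_id = records$chemical_id[volatile],
                         category = cat[volatile],
                         stringsAsFactors = FALSE),
    flagged = flagged,
    category = stats::setNames(cat, records$chemical_id)
  )
}
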