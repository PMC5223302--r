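#' Build a set of office-cluster specifications
#'
#' Creates the cluster-level frame for a triplet-matched trial: each cluster
#' is an office work unit with at least 50 eligible employees and an
#' arbitrary-unit contagion-risk score used only through its rank.
#'
#' @param n_clusters Number of clusters; must be a positive multiple of 3
#'   (the canonical trial has 21).
#' @param n_corporations Number of corporations the clusters are nested in.
#' @param n_eligible Integer vector (recycled) of eligible employees per
#'   cluster; all values must be >= 50.
#' @param score_dist Function of `n` returning `n` risk scores
#'   (default: uniform on (0, 100)). Only ranks matter downstream.
#' @param seed Optional integer seed for the score draw.
#' @return A data frame with columns `cluster_id`, `corporation_id`,
#'   `n_eligible`, `risk_score`.
#' @examples
#' cl <- make_clusters(21, seed = 1)
#' design <- randomize_arms(assign_triplets(cl), seed = 2)
#' table(design$arm)
#' @export
make_clusters <- function(n_clusters = 21L, n_corporations = 6L,
                          n_eligible = 60L,
                          score_dist = function(n) stats::runif(n, 0, 100),
                          seed = NULL) {
  if (n_clusters < 3L || n_clusters %% 3L != 0L)
    stop("n_clusters must be a positive multiple of 3", call. = FALSE)
  if (any(n_eligible < 50L))
    stop("every cluster must have at least 50 eligible employees", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    cluster_id = sprintf("C%02d", seq_len(n_clusters)),
    corporation_id = sprintf("corp%d", rep_len(seq_len(n_corporations), n_clusters)),
    n_eligible = rep_len(as.integer(n_eligible), n_clusters),
    risk_score = score_dist(n_clusters),
    stringsAsFactors = FALSE
  )
}

validate_clusters <- function(clusters) {
  req <- c("cluster_id", "risk_score")
  if (!is.data.frame(clusters) || !all(req %in% names(clusters)))
    stop("clusters must be a data frame with columns cluster_id and risk_score",
         call. = FALSE)
  if (anyDuplicated(clusters$cluster_id))
    stop("cluster ids must be distinct", call. = FALSE)
  if (any(!is.finite(clusters$risk_score)))
    stop("risk scores must be finite", call. = FALSE)
  if ("n_eligible" %in% names(clusters) && any(clusters$n_eligible < 50))
    stop("every cluster must have at least 50 eligible employees", call. = FALSE)
  invisible(clusters)
}

#' Partition clusters into score-ranked triplets
#'
#' Clusters are ranked by descending contagion-risk score and split into
#' triplets of contiguous ranks: ranks 1-3 form triplet 1, ranks 4-6
#' triplet 2, and so on. Tied scores are broken deterministically by
#' lexicographic cluster id so that a given cluster set always yields the
#' same design.
#'
#' @param clusters Data frame as returned by [make_clusters()]. The number
#'   of rows must be a positive multiple of 3 (21 in the canonical design,
#'   giving 7 triplets).
#' @return A `trial_design` data frame: the clusters sorted by descending
#'   score with added columns `rank`, `triplet` and `arm` (`NA` until
#'   [randomize_arms()] is called).
#' @seealso [randomize_arms()]
#' @export
assign_triplets <- function(clusters) {
  validate_clusters(clusters)
  n <- nrow(clusters)
  if (n < 3L || n %% 3L != 0L)
    stop("number of clusters must be a positive multiple of 3, got ", n,
         call. = FALSE)
  ord <- order(-clusters$risk_score, clusters$cluster_id)
  design <- clusters[ord, , drop = FALSE]
  design$rank <- seq_len(n)
  design$triplet <- (design$rank - 1L) %/% 3L + 1L
  design$arm <- rep(NA_character_, n)
  rownames(design) <- NULL
  class(design) <- c("trial_design", "data.frame")
  design
}

#' Arm labels used throughout the package
#' @return Character vector `c("control", "soap_water", "alcohol_rub")`.
#' @export
trial_arms <- function() c("control", "soap_water", "alcohol_rub")

#' Randomize one member of each triplet into each trial arm
#'
#' Within every triplet the three arms (control, soap-and-water wash,
#' alcohol-based hand rub) are assigned by a uniformly random permutation,
#' so each arm ends up with exactly one cluster per triplet.
#'
#' @param design A `trial_design` from [assign_triplets()].
#' @param seed Integer seed governing the permutations.
#' @return The design with the `arm` column filled in.
#' @export
randomize_arms <- function(design, seed) {
  if (!inherits(design, "trial_design") || is.null(design$triplet))
    stop("design must come from assign_triplets()", call. = FALSE)
  if (!missing(seed)) set.seed(seed)
  arms <- trial_arms()
  for (tr in unique(design$triplet)) {
    idx <- which(design$triplet == tr)
    stopifnot(length(idx) == 3L)
    design$arm[idx] <- sample(arms)
  }
  design
}

#' @export
print.trial_design <- function(x, ...) {
  n_tr <- length(unique(x$triplet))
  cat("Triplet-matched cluster-randomized trial design\n")
  cat(sprintf("  %d clusters in %d score-ranked triplets\n", nrow(x), n_tr))
  if (all(is.na(x$arm))) {
    cat("  arms not yet randomized\n")
  } else {
    tab <- table(x$arm)
    cat("  clusters per arm:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a trial design as CSV
#'
#' @param design A `trial_design`.
#' @param path File path.
#' @return `write_design` returns `path` invisibly; `read_design` returns a
#'   `trial_design`.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(d) <- c("trial_design", "data.frame")
  d
}
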