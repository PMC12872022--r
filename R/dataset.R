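#' Mine negative training examples from decoy proteomes
#'
#' Screens every proteome protein against each calibrated profile and
#' keeps, as all-zero-label negatives, those that pass the standard hit
#' filters against at least one profile.  This mirrors building a negative
#' set from distant homologs in organisms unlikely to degrade plastics.
#'
#' @param profiles list of calibrated `profile_hmm` objects.
#' @param proteomes non-empty protein sequence-record `data.frame`.
#' @param evalue_max,bitscore_min,bias_fraction filter thresholds
#'   (see [filter_hits()]).
#' @return a sequence-record `data.frame` of mined negatives with a
#'   `provenance` column set to `"negative_mined"`.
#' @export
mine_negatives <- function(profiles, proteomes, evalue_max = 1e-5,
                           bitscore_min = 20, bias_fraction = 0.10) {
  if (is.null(proteomes) || nrow(proteomes) == 0L) {
    stop("empty proteome set")
  }
  db_size <- nrow(proteomes)
  hits <- list()
  for (prof in profiles) {
    if (is.null(prof$calibration)) {
      stop("profile for ", prof$polymer, " is not calibrated")
    }
    for (i in seq_len(nrow(proteomes))) {
      hits[[length(hits) + 1L]] <-
        score_protein(prof, proteomes$seq[i], proteomes$id[i], db_size)
    }
  }
  hits <- do.call(rbind, hits)
  kept <- filter_hits(hits, evalue_max, bitscore_min, bias_fraction)
  neg <- proteomes[proteomes$id %in% unique(kept$protein_id), , drop = FALSE]
  if (nrow(neg)) neg$provenance <- "negative_mined"
  neg
}

#' Cluster-aware train/test split
#'
#' Clusters sequences at `identity` with [greedy_cluster()], shuffles the
#' clusters with `seed` and assigns the first
#' `ceiling(test_fraction * n_clusters)` whole clusters to the test set,
#' the rest to training.  Whole-cluster assignment prevents near-duplicate
#' leakage between the two sides.
#'
#' @param records protein sequence-record `data.frame` (>= 5 clusters).
#' @param identity clustering identity threshold (default 0.95).
#' @param test_fraction fraction of clusters assigned to test (default 0.2).
#' @param seed RNG seed for the cluster shuffle.
#' @return a list of class `split_result`: `train_ids`, `test_ids`,
#'   `seed`, `test_cluster_fraction`, `realized_test_fraction` and the
#'   cluster table.
#' @export
cluster_split <- function(records, identity = 0.95, test_fraction = 0.2,
                          seed = 42L) {
  cl <- greedy_cluster(records, threshold = identity)
  reps <- unique(cl$representative_id)
  n_clusters <- length(reps)
  if (n_clusters < 5L) stop("need at least 5 clusters to split")
  n_test <- ceiling(test_fraction * n_clusters)
  if (n_test < 1L || n_test >= n_clusters) {
    stop("test_fraction leaves an empty train or test set")
  }
  set.seed(seed)
  shuffled <- sample(reps)
  test_reps <- shuffled[seq_len(n_test)]
  test_ids <- cl$member_id[cl$representative_id %in% test_reps]
  train_ids <- setdiff(cl$member_id, test_ids)
  structure(list(train_ids = train_ids, test_ids = test_ids, seed = seed,
                 test_cluster_fraction = test_fraction,
                 realized_test_fraction = length(test_ids) / nrow(records),
                 clusters = cl),
            class = "split_result")
}

#' One-hot polymer label matrix
#'
#' @param annotations named list: protein id -> character vector of
#'   degraded polymers (empty vector or `character(0)` = negative).
#'   Multi-label entries are allowed.
#' @param polymers ordered character vector of polymer columns.
#' @return an n x k 0/1 matrix with ids as row names.
#' @export
one_hot_labels <- function(annotations, polymers) {
  unknown <- setdiff(unique(unlist(annotations)), polymers)
  if (length(unknown)) {
    stop("unknown polymer label(s): ", paste(unknown, collapse = ", "))
  }
  vals <- vapply(annotations, function(a) {
    as.integer(polymers %in% a)
  }, integer(length(polymers)))
  m <- if (length(polymers) == 1L) matrix(vals, ncol = 1L) else t(vals)
  colnames(m) <- polymers
  rownames(m) <- names(annotations)
  m
}
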