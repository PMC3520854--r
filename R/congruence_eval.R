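#' Classify a query set against multiple training sets
#'
#' Trains one model per set, bootstrap-classifies every query against
#' every model and applies the confidence threshold, producing the
#' complete query-by-set classification table underlying all congruence
#' analytics. Per-set random seeds are derived deterministically from
#' the master seed and the set name, so runs are reproducible and
#' insensitive to the order in which sets are given.
#'
#' @param queries Named character vector of query sequences.
#' @param training_sets Named list of `"training_set"` objects (names
#'   default to each set's own `name`).
#' @param cutoff_pct Confidence threshold applied to every cell
#'   (default 60).
#' @param seed Master integer seed.
#' @param trials Bootstrap trials per classification (default 100).
#' @param word_size Word length for the models (default 8).
#' @return An object of class `"classification_table"`: list with
#'   `queries`, `sets`, `cutoff`, `labels` and `confidence`
#'   (query x set x rank arrays) and `winning_genus` (query x set).
#' @export
classify_all <- function(queries, training_sets, cutoff_pct = 60, seed,
                         trials = 100L, word_size = 8L) {
  stopifnot(length(queries) >= 1L, length(training_sets) >= 1L)
  if (is.null(names(training_sets)))
    names(training_sets) <- vapply(training_sets, `[[`, character(1L), "name")
  qids <- names(queries)
  sets <- names(training_sets)
  nq <- length(queries)
  ns <- length(sets)
  labels <- array(NA_character_, c(nq, ns, 6L),
                  dimnames = list(qids, sets, TAX_RANKS))
  confidence <- array(NA_real_, c(nq, ns, 6L),
                      dimnames = list(qids, sets, TAX_RANKS))
  winning <- matrix(NA_character_, nq, ns, dimnames = list(qids, sets))
  for (s in seq_len(ns)) {
    model <- nbc_train(training_sets[[s]], word_size)
    set_seed <- .derive_seed(seed, sets[[s]])
    for (q in seq_len(nq)) {
      cl <- bootstrap_classify(model, queries[[q]], trials = trials,
                               seed = .derive_seed(set_seed, qids[[q]]),
                               query_id = qids[[q]])
      cl <- apply_threshold(cl, cutoff_pct)
      labels[q, s, ] <- cl$labels
      confidence[q, s, ] <- cl$confidence
      winning[q, s] <- cl$winning_genus
    }
  }
  structure(list(queries = qids, sets = sets, cutoff = cutoff_pct,
                 labels = labels, confidence = confidence,
                 winning_genus = winning),
            class = "classification_table")
}

# Deterministic 31-bit seed from a base seed and a string tag.
.derive_seed <- function(seed, tag) {
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(as.character(tag)))
    h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

#' @export
print.classification_table <- function(x, ...) {
  cat("classification table: ", length(x$queries), " queries x ",
      length(x$sets), " training sets (cutoff ", x$cutoff, "%)\n", sep = "")
  invisible(x)
}

.rank_index <- function(rank) {
  if (is.character(rank)) {
    r <- match(rank, TAX_RANKS)
    if (is.na(r)) stop("unknown rank: ", rank)
    r
  } else {
    r <- as.integer(rank)
    if (is.na(r) || r < 1L || r > 6L) stop("rank must be in 1..6")
    r
  }
}

#' Rank-wise congruence of classifications across training sets
#'
#' For each query at the given rank: *congruent* means every set reports
#' the same label and that label is not `"unclassified"`;
#' *mutually different* means all pairwise labels differ
#' (`"unclassified"` counting as a label of its own); *partial* is
#' everything else. The three categories partition the query set.
#'
#' @param table A `"classification_table"` with at least 2 sets.
#' @param rank Rank name or index (1 = Domain ... 6 = Genus).
#' @return Named integer vector `c(n_congruent, n_mutually_different,
#'   n_partial)`.
#' @export
rank_congruence <- function(table, rank) {
  stopifnot(inherits(table, "classification_table"))
  if (length(table$sets) < 2L)
    stop("congruence needs at least 2 training sets")
  r <- .rank_index(rank)
  labs <- table$labels[, , r, drop = FALSE]
  ns <- length(table$sets)
  n_con <- 0L; n_diff <- 0L
  for (q in seq_along(table$queries)) {
    l <- labs[q, , 1L]
    u <- unique(l)
    if (length(u) == 1L && u != "unclassified") n_con <- n_con + 1L
    else if (length(u) == ns) n_diff <- n_diff + 1L
  }
  c(n_congruent = n_con, n_mutually_different = n_diff,
    n_partial = length(table$queries) - n_con - n_diff)
}

#' Pairwise agreement counts between training sets at a rank
#'
#' @inheritParams rank_congruence
#' @return Symmetric integer matrix (set x set); entry (i, j) is the
#'   number of queries with identical non-`"unclassified"` labels at the
#'   rank; the diagonal is the number of queries.
#' @export
pairwise_agreement <- function(table, rank) {
  stopifnot(inherits(table, "classification_table"))
  if (length(table$sets) < 2L)
    stop("agreement needs at least 2 training sets")
  r <- .rank_index(rank)
  ns <- length(table$sets)
  out <- matrix(length(table$queries), ns, ns,
                dimnames = list(table$sets, table$sets))
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    li <- table$labels[, i, r]
    lj <- table$labels[, j, r]
    agree <- sum(li == lj & li != "unclassified")
    out[i, j] <- agree
    out[j, i] <- agree
  }
  out
}

#' Unclassified counts per training set
#'
#' A query is unclassified overall for a set when even its Domain rank
#' is `"unclassified"` after thresholding. Per-rank counts are also
#' reported, since in practice most threshold failures occur at the
#' deeper ranks.
#'
#' @param table A `"classification_table"`.
#' @return List with `overall` (named integer vector per set) and
#'   `by_rank` (rank x set integer matrix).
#' @export
unclassified_counts <- function(table) {
  stopifnot(inherits(table, "classification_table"))
  by_rank <- apply(table$labels == "unclassified", c(3L, 2L), sum)
  dimnames(by_rank) <- list(TAX_RANKS, table$sets)
  list(overall = by_rank["Domain", ], by_rank = by_rank)
}

#' Mean family-rank bootstrap confidence per assigned family
#'
#' For each training set, queries are grouped by the family label that
#' set assigned them (queries unclassified at Family are excluded) and
#' the family-rank bootstrap confidences are averaged — the per-set
#' family summary behind heat-map style comparisons.
#'
#' @param table A `"classification_table"`.
#' @return Data frame with columns `set`, `family`, `mean_confidence`,
#'   `n_queries`.
#' @export
mean_bootstrap_by_family <- function(table) {
  stopifnot(inherits(table, "classification_table"))
  rows <- list()
  for (s in seq_along(table$sets)) {
    fam <- table$labels[, s, "Family"]
    conf <- table$confidence[, s, "Family"]
    keep <- fam != "unclassified"
    if (!any(keep)) next
    agg <- tapply(conf[keep], fam[keep], mean)
    cnt <- tapply(conf[keep], fam[keep], length)
    rows[[s]] <- data.frame(set = table$sets[[s]], family = names(agg),
                            mean_confidence = as.numeric(agg),
                            n_queries = as.integer(cnt),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(), family = character(),
                      mean_confidence = numeric(), n_queries = integer())
  rownames(out) <- NULL
  out
}

#' Exact dereplication of reads
#'
#' Collapses byte-identical reads (after uppercase/gap-strip
#' normalization) into unique sequences with abundances. The
#' representative id of each unique sequence is the first-seen read id.
#'
#' @param reads Named character vector of reads.
#' @return List with `sequences` (named character vector of unique
#'   sequences, first-seen order), `abundance` (named integer vector)
#'   and `members` (named list mapping representative id to member read
#'   ids).
#' @export
dereplicate_exact <- function(reads) {
  norm <- toupper(gsub("[-.]", "", reads))
  first <- !duplicated(norm)
  rep_of <- names(reads)[first][match(norm, norm[first])]
  members <- split(names(reads), factor(rep_of, levels = names(reads)[first]))
  list(sequences = stats::setNames(norm[first], names(reads)[first]),
       abundance = stats::setNames(as.integer(lengths(members)),
                                   names(reads)[first]),
       members = members)
}

#' Cluster unique sequences into OTUs
#'
#' Operational taxonomic units at an identity threshold (default 97%),
#' using the same greedy centroid engine as [dereplicate()] so the two
#' stages cannot diverge in behavior.
#'
#' @param unique_seqs Named character vector of unique sequences.
#' @param threshold Identity threshold in (0, 1] (default 0.97).
#' @return As [greedy_cluster()].
#' @export
otu_cluster <- function(unique_seqs, threshold = 0.97) {
  greedy_cluster(unique_seqs, threshold)
}

#' Per-family unique-sequence and OTU tallies
#'
#' Groups queries by the family label assigned by one training set and
#' counts, per family, the unique sequences and the distinct OTUs they
#' fall into.
#'
#' @param partition An OTU partition from [otu_cluster()] over the query
#'   sequences.
#' @param table A `"classification_table"` covering the same query ids.
#' @param set Name of the training set whose family labels to use.
#' @return Data frame with columns `family`, `n_unique`, `n_otus`.
#' @export
otu_by_family <- function(partition, table, set) {
  stopifnot(inherits(table, "classification_table"))
  s <- match(set, table$sets)
  if (is.na(s)) stop("unknown training set: ", set)
  ids <- names(partition$membership)
  q <- match(ids, table$queries)
  if (anyNA(q)) stop("partition contains ids absent from the table")
  fam <- table$labels[q, s, "Family"]
  n_unique <- tapply(ids, fam, length)
  n_otus <- tapply(partition$membership, fam,
                   function(m) length(unique(m)))
  out <- data.frame(family = names(n_unique),
                    n_unique = as.integer(n_unique),
                    n_otus = as.integer(n_otus),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$family), , drop = FALSE]
}

#' Full congruence report across training sets
#'
#' Bundles the rank-wise congruence partition, pairwise agreement,
#' unclassified counts and per-family mean bootstrap for one
#' classification table.
#'
#' @param table A `"classification_table"` with at least 2 sets.
#' @return An object of class `"congruence_report"`: list with
#'   `n_queries`, `per_rank` (data frame), `pairwise` (list of matrices
#'   by rank), `unclassified`, `family_bootstrap`.
#' @export
congruence_report <- function(table) {
  per_rank <- do.call(rbind, lapply(seq_len(6L), function(r) {
    cc <- rank_congruence(table, r)
    data.frame(rank = TAX_RANKS[[r]], n_congruent = cc[["n_congruent"]],
               n_mutually_different = cc[["n_mutually_different"]],
               n_partial = cc[["n_partial"]], stringsAsFactors = FALSE)
  }))
  structure(list(n_queries = length(table$queries),
                 per_rank = per_rank,
                 pairwise = stats::setNames(
                   lapply(seq_len(6L), function(r) pairwise_agreement(table, r)),
                   TAX_RANKS),
                 unclassified = unclassified_counts(table),
                 family_bootstrap = mean_bootstrap_by_family(table)),
            class = "congruence_report")
}

#' @export
print.congruence_report <- function(x, ...) {
  cat("congruence report over", x$n_queries, "queries\n")
  print(x$per_rank, row.names = FALSE)
  invisible(x)
}

#' Write congruence report tables as TSV files
#'
#' Emits `congruence.tsv` (rank-wise partition), `agreement.tsv`
#' (long-format pairwise counts), `unclassified.tsv` (per-rank per-set
#' counts) and `family_bootstrap.tsv` (long-format heat-map table:
#' family x set x mean bootstrap x count) into a directory.
#'
#' @param report A `"congruence_report"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_congruence_tsvs <- function(report, dir) {
  stopifnot(inherits(report, "congruence_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "congruence.tsv")
  utils::write.table(report$per_rank, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  agree <- do.call(rbind, lapply(names(report$pairwise), function(r) {
    m <- report$pairwise[[r]]
    idx <- which(upper.tri(m), arr.ind = TRUE)
    data.frame(rank = r, set1 = rownames(m)[idx[, 1L]],
               set2 = colnames(m)[idx[, 2L]], n_agree = m[idx],
               stringsAsFactors = FALSE)
  }))
  p <- file.path(dir, "agreement.tsv")
  utils::write.table(agree, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  un <- report$unclassified$by_rank
  un_df <- data.frame(rank = rep(rownames(un), ncol(un)),
                      set = rep(colnames(un), each = nrow(un)),
                      n_unclassified = as.integer(un),
                      stringsAsFactors = FALSE)
  p <- file.path(dir, "unclassified.tsv")
  utils::write.table(un_df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "family_bootstrap.tsv")
  utils::write.table(report$family_bootstrap, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
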