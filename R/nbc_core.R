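#' Extract overlapping words (k-mers) from a DNA sequence
#'
#' Enumerates every overlapping substring of length `word_size` composed
#' only of `A`, `C`, `G`, `T`; windows overlapping an ambiguity code are
#' skipped. Order is preserved and duplicates retained (use
#' `distinct = TRUE` for the distinct-word view used by the classifier).
#'
#' @param sequence DNA string.
#' @param word_size Word length in bases (>= 1).
#' @param distinct If `TRUE`, return each word once in order of first
#'   occurrence.
#' @return Character vector of words; empty when the sequence is shorter
#'   than `word_size`.
#' @examples
#' extract_words("ACGTNACGT", 4)
#' @export
extract_words <- function(sequence, word_size, distinct = FALSE) {
  stopifnot(length(sequence) == 1L, word_size >= 1L)
  sequence <- toupper(sequence)
  starts <- .valid_window_starts(sequence, as.integer(word_size))
  if (length(starts) == 0L) return(character())
  words <- substring(sequence, starts, starts + word_size - 1L)
  if (distinct) unique(words) else words
}

# Base-4 codes per position (A=0, C=1, G=2, T=3; NA otherwise).
.base_codes <- c(A = 0L, C = 1L, G = 2L, T = 3L)

.seq_codes <- function(sequence) {
  unname(.base_codes[strsplit(sequence, "", fixed = TRUE)[[1L]]])
}

# Start positions of windows containing no ambiguity code.
.valid_window_starts <- function(sequence, word_size) {
  v <- .seq_codes(sequence)
  n <- length(v)
  if (n < word_size) return(integer(0L))
  m <- n - word_size + 1L
  bad <- logical(m)
  for (j in seq_len(word_size))
    bad <- bad | is.na(v[j:(j + m - 1L)])
  which(!bad)
}

# Words as 1-based integer codes in 1..4^word_size, order preserved,
# duplicates retained. The dense code space keeps model training and
# scoring vectorized.
.word_codes <- function(sequence, word_size) {
  sequence <- toupper(sequence)
  v <- .seq_codes(sequence)
  n <- length(v)
  if (n < word_size) return(integer(0L))
  m <- n - word_size + 1L
  idx <- numeric(m)
  bad <- logical(m)
  for (j in seq_len(word_size)) {
    cj <- v[j:(j + m - 1L)]
    bad <- bad | is.na(cj)
    cj[is.na(cj)] <- 0L
    idx <- idx * 4 + cj
  }
  as.integer(idx[!bad]) + 1L
}

#' Train a naive Bayesian classifier model
#'
#' Builds the word-presence model from a training set. With `N` training
#' sequences of which `n(w)` contain word `w` at least once, the word
#' prior is `(n(w) + 0.5) / (N + 1)`; for a genus with `M` sequences of
#' which `m(w)` contain `w`, the conditional probability is
#' `(m(w) + prior(w)) / (M + 1)`. The pseudo-counts keep every
#' conditional probability strictly positive, so no genus score is ever
#' `-Inf`.
#'
#' @param refs A `"training_set"`.
#' @param word_size Word length in bases (1..10; default 8, the published
#'   classifier's choice).
#' @return An object of class `"nbc_model"` with elements `word_size`,
#'   `genera` (sorted), `lineage`/`lineage_incertae` (genus x rank),
#'   `counts` (4^word_size x genus word document counts), `M` (sequences
#'   per genus), `n_word` (word document counts over the whole set),
#'   `prior`, and `n_train`.
#' @export
nbc_train <- function(refs, word_size = 8L) {
  stopifnot(inherits(refs, "training_set"))
  word_size <- as.integer(word_size)
  if (word_size < 1L || word_size > 10L)
    stop("word_size must be in 1..10")
  if (length(refs$id) == 0L)
    stop("empty training set")
  genera <- sort(unique(refs$labels[, "Genus"]))
  gidx <- match(refs$labels[, "Genus"], genera)
  grow <- match(genera, refs$labels[, "Genus"])
  lineage <- refs$labels[grow, , drop = FALSE]
  rownames(lineage) <- genera
  lineage_incertae <- refs$incertae[grow, , drop = FALSE]
  rownames(lineage_incertae) <- genera
  K <- 4L^word_size
  G <- length(genera)
  n_word <- integer(K)
  counts <- matrix(0L, K, G)
  for (i in seq_along(refs$id)) {
    u <- unique(.word_codes(refs$sequence[[i]], word_size))
    if (length(u) == 0L)
      stop("training sequence yields no words: ", refs$id[[i]])
    n_word[u] <- n_word[u] + 1L
    counts[u, gidx[[i]]] <- counts[u, gidx[[i]]] + 1L
  }
  N <- length(refs$id)
  structure(list(word_size = word_size, genera = genera,
                 lineage = lineage, lineage_incertae = lineage_incertae,
                 counts = counts, M = tabulate(gidx, G), n_word = n_word,
                 prior = (n_word + 0.5) / (N + 1), n_train = N),
            class = "nbc_model")
}

#' @export
print.nbc_model <- function(x, ...) {
  cat("naive Bayesian classifier model: ", length(x$genera), " genera, ",
      x$n_train, " training sequences, word size ", x$word_size, "\n",
      sep = "")
  invisible(x)
}

# Per-word log conditional probabilities for one read: a V x G matrix
# over the read's distinct words (V of them) and the model's genera.
.read_logprob <- function(model, read) {
  idx <- unique(.word_codes(read, model$word_size))
  if (length(idx) == 0L)
    stop("no classifiable words")
  lp <- log(model$counts[idx, , drop = FALSE] + model$prior[idx])
  lp <- sweep(lp, 2L, log(model$M + 1), `-`)
  dimnames(lp) <- list(NULL, model$genera)
  lp
}

#' Classify a read by maximum joint probability
#'
#' Scores each genus as the sum over the read's *distinct* words of the
#' log conditional word probability, and returns the maximizing genus.
#' Exact score ties are broken by the lexicographically smallest genus
#' identifier.
#'
#' @param model An `"nbc_model"`.
#' @param read DNA string yielding at least one valid word.
#' @return List with `genus` (winning genus), `scores` (named log-joint
#'   score per genus) and `lineage` (the winner's `"tax_path"`).
#' @export
nbc_classify <- function(model, read) {
  stopifnot(inherits(model, "nbc_model"))
  lp <- .read_logprob(model, read)
  scores <- colSums(lp)
  win <- which.max(scores)  # genera sorted, so first max = lexicographic
  list(genus = model$genera[[win]],
       scores = scores,
       lineage = tax_path(model$lineage[win, ],
                          model$lineage_incertae[win, ]))
}

#' Bootstrap confidence classification
#'
#' Runs `trials` bootstrap trials; each samples `max(1, floor(V/8))` of
#' the read's `V` distinct words uniformly with replacement, classifies
#' on that subset and records the winning genus. The reported genus is
#' the one winning the most trials (ties to the lexicographically
#' smallest), and the confidence at each rank is 100 times the fraction
#' of trials whose winner's lineage passes through the reported taxon at
#' that rank — hence confidence is always non-decreasing from Genus up
#' to Domain.
#'
#' @param model An `"nbc_model"`.
#' @param read DNA string yielding at least one valid word.
#' @param trials Number of bootstrap trials (default 100).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param query_id Optional id recorded in the result.
#' @return An object of class `"nbc_classification"`: list with
#'   `query_id`, `winning_genus`, `labels` (6 rank labels), `incertae`,
#'   `confidence` (6 values in \[0, 100\]), `threshold_applied`
#'   (`NULL` until [apply_threshold()]).
#' @export
bootstrap_classify <- function(model, read, trials = 100L, seed,
                               query_id = "query") {
  stopifnot(inherits(model, "nbc_model"))
  trials <- as.integer(trials)
  if (is.na(trials) || trials < 1L)
    stop("trials must be a positive integer")
  lp <- .read_logprob(model, read)
  V <- nrow(lp)
  s <- max(1L, V %/% 8L)
  G <- ncol(lp)
  samp <- withr::with_seed(seed,
    matrix(sample.int(V, s * trials, replace = TRUE), nrow = s))
  winners <- integer(trials)
  for (t in seq_len(trials)) {
    sc <- colSums(lp[samp[, t], , drop = FALSE])
    winners[[t]] <- which.max(sc)
  }
  wins <- tabulate(winners, G)
  best <- which.max(wins)  # ties -> lexicographically smallest genus
  win_lineage <- model$lineage[best, ]
  conf <- vapply(seq_len(6L), function(r) {
    100 * sum(model$lineage[winners, r] == win_lineage[[r]]) / trials
  }, numeric(1L))
  structure(list(query_id = query_id,
                 winning_genus = model$genera[[best]],
                 labels = stats::setNames(win_lineage, TAX_RANKS),
                 incertae = stats::setNames(model$lineage_incertae[best, ],
                                            TAX_RANKS),
                 confidence = stats::setNames(conf, TAX_RANKS),
                 threshold_applied = NULL),
            class = "nbc_classification")
}

#' @export
print.nbc_classification <- function(x, ...) {
  cat("query ", x$query_id, " -> ", x$winning_genus, "\n", sep = "")
  for (r in seq_len(6L))
    cat(sprintf("  %-7s %-30s %6.1f\n", TAX_RANKS[[r]], x$labels[[r]],
                x$confidence[[r]]))
  if (!is.null(x$threshold_applied))
    cat("  (", x$threshold_applied, "% confidence threshold applied)\n",
        sep = "")
  invisible(x)
}

#' Apply a bootstrap confidence threshold
#'
#' Scanning from Domain to Genus, the first rank whose confidence falls
#' below `cutoff_pct` and every deeper rank are relabelled
#' `"unclassified"` (truncation is prefix-monotone). A query whose
#' Domain rank falls below the cutoff is unclassified overall.
#'
#' @param x An `"nbc_classification"`.
#' @param cutoff_pct Confidence threshold in \[0, 100\] (default 60, the
#'   conventional reporting threshold). Confidence exactly equal to the
#'   cutoff passes.
#' @return The classification with sub-threshold ranks relabelled and
#'   `threshold_applied` set.
#' @export
apply_threshold <- function(x, cutoff_pct = 60) {
  stopifnot(inherits(x, "nbc_classification"))
  if (!is.numeric(cutoff_pct) || length(cutoff_pct) != 1L ||
      is.na(cutoff_pct) || cutoff_pct < 0 || cutoff_pct > 100)
    stop("cutoff_pct must be a number in [0, 100]")
  fail <- which(x$confidence < cutoff_pct)
  if (length(fail)) {
    drop <- fail[[1L]]:6L
    x$labels[drop] <- "unclassified"
    x$incertae[drop] <- FALSE
  }
  x$threshold_applied <- cutoff_pct
  x
}
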