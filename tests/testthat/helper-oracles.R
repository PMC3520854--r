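# Independent oracles used to check the implementation. These are
# deliberately naive (string words, explicit loops, textbook DP) and
# share no code with the package internals.

# All overlapping substrings of length w containing only ACGT.
oracle_words <- function(sequence, w) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < w) return(character())
  subs <- substring(sequence, 1:(n - w + 1), w:n)
  subs[grepl("^[ACGT]+$", subs)]
}

# Per-word log conditional probabilities for a read, computed directly
# from the pseudo-count formulas: prior(w) = (n(w)+0.5)/(N+1),
# P(w|G) = (m(w)+prior(w))/(M+1). Returns V x G matrix over the read's
# distinct words and the sorted genera.
oracle_read_logprob <- function(ref_seqs, ref_genus, read, w) {
  N <- length(ref_seqs)
  seq_words <- lapply(ref_seqs, function(s) unique(oracle_words(s, w)))
  read_w <- unique(oracle_words(read, w))
  genera <- sort(unique(ref_genus))
  L <- matrix(NA_real_, length(read_w), length(genera),
              dimnames = list(read_w, genera))
  for (wd in read_w) {
    nw <- sum(vapply(seq_words, function(x) wd %in% x, logical(1)))
    prior <- (nw + 0.5) / (N + 1)
    for (g in genera) {
      members <- seq_words[ref_genus == g]
      m <- sum(vapply(members, function(x) wd %in% x, logical(1)))
      L[wd, g] <- log((m + prior) / (length(members) + 1))
    }
  }
  L
}

# Brute-force genus scores: sum of per-word logs over distinct words.
oracle_classify <- function(ref_seqs, ref_genus, read, w) {
  L <- oracle_read_logprob(ref_seqs, ref_genus, read, w)
  scores <- colSums(L)
  list(scores = scores, genus = names(scores)[which.max(scores)])
}

# Monte-Carlo bootstrap re-simulation: `trials` subsets of
# s = max(1, floor(V/8)) words with replacement, argmax per subset
# (ties to the first of the sorted genera), confidence per rank relative
# to the most-winning genus's lineage. `lineages` is a genus x 6 matrix.
oracle_bootstrap <- function(ref_seqs, ref_genus, read, w, lineages,
                             trials, seed) {
  L <- oracle_read_logprob(ref_seqs, ref_genus, read, w)
  V <- nrow(L)
  s <- max(1L, V %/% 8L)
  set.seed(seed)
  picks <- matrix(sample.int(V, s * trials, replace = TRUE), nrow = s)
  winners <- apply(picks, 2L, function(rows)
    which.max(colSums(L[rows, , drop = FALSE])))
  wins <- tabulate(winners, ncol(L))
  best <- which.max(wins)
  conf <- vapply(1:6, function(r)
    100 * mean(lineages[winners, r] == lineages[best, r]), numeric(1))
  list(genus = colnames(L)[best], confidence = conf)
}

# Textbook Needleman-Wunsch (match +1, mismatch -1, gap -2) with
# traceback; identity = matches / columns after trimming terminal gaps.
oracle_nw_identity <- function(a, b) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- (0:n) * -2
  S[1, ] <- (0:m) * -2
  for (i in 1:n) for (j in 1:m)
    S[i + 1, j + 1] <- max(S[i, j] + if (A[i] == B[j]) 1 else -1,
                           S[i, j + 1] - 2, S[i + 1, j] - 2)
  i <- n; j <- m; pa <- character(); pb <- character()
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (A[i] == B[j]) 1 else -1)) {
      pa <- c(A[i], pa); pb <- c(B[j], pb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
      pa <- c(A[i], pa); pb <- c("-", pb); i <- i - 1
    } else {
      pa <- c("-", pa); pb <- c(B[j], pb); j <- j - 1
    }
  }
  gap <- pa == "-" | pb == "-"
  inner <- which(!gap)
  if (!length(inner)) return(0)
  span <- inner[1]:inner[length(inner)]
  sum(pa[span] == pb[span]) / length(span)
}

# All-pairs + connected-components partition oracle for well-separated
# planted clusters (any consistent identity metric recovers them).
oracle_components <- function(seqs, threshold) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- oracle_nw_identity(seqs[[i]], seqs[[j]]) >= threshold
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n))
      if (adj[i, j] && comp[j] != comp[i]) {
        new <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- new
        changed <- TRUE
      }
    if (!changed) break
  }
  split(names(seqs), comp)
}

# --- random instance / fixture generators (seeded by the caller) ------

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Substitute a fraction of positions (uniform over the 3 alternatives).
mutate_dna <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit)
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# A small random training set with hierarchical labels; genera g1..gk,
# each genus in family f<ceil(k/2)>, all in one phylum.
random_instance <- function(max_genera = 6, max_refs = 5,
                            len_range = c(40, 80)) {
  k <- sample(2:max_genera, 1)
  ids <- character(); seqs <- character(); rows <- list()
  for (g in seq_len(k)) {
    base <- random_dna(sample(len_range[1]:len_range[2], 1))
    for (r in seq_len(sample(1:max_refs, 1))) {
      id <- sprintf("g%d_s%d", g, r)
      ids <- c(ids, id)
      seqs <- c(seqs, mutate_dna(base, 0.05))
      rows[[id]] <- c("Bacteria", "P1", "P1_C",
                      sprintf("f%d_O", ceiling(g / 2)),
                      sprintf("f%d", ceiling(g / 2)), sprintf("g%d", g))
    }
  }
  list(set = training_set("rand", stats::setNames(seqs, ids),
                          taxonomy_map(ids, do.call(rbind, rows))),
       genus = vapply(rows, `[[`, "", 6L)[match(ids, names(rows))],
       seqs = stats::setNames(seqs, ids))
}

# Planted clusters: k centers at ~`between` divergence from a common
# root, members at ~`within` divergence from their center.
planted_clusters <- function(k, per, len, within, between) {
  root <- random_dna(len)
  seqs <- character(); truth <- integer()
  for (c in seq_len(k)) {
    center <- mutate_dna(root, between)
    for (m in seq_len(per)) {
      seqs <- c(seqs, mutate_dna(center, within))
      truth <- c(truth, c)
    }
  }
  names(seqs) <- sprintf("c%d_m%d", truth, stats::ave(truth, truth,
                                                      FUN = seq_along))
  list(seqs = seqs, truth = truth)
}

# A tiny manually assembled classification table for congruence tests.
manual_table <- function(labels_by_set, conf = NULL) {
  # labels_by_set: list(set -> query x 6 matrix of labels)
  sets <- names(labels_by_set)
  nq <- nrow(labels_by_set[[1]])
  qids <- sprintf("q%d", seq_len(nq))
  labs <- array(NA_character_, c(nq, length(sets), 6),
                dimnames = list(qids, sets, taxnbc::TAX_RANKS))
  cf <- array(100, c(nq, length(sets), 6),
              dimnames = list(qids, sets, taxnbc::TAX_RANKS))
  for (s in seq_along(sets)) {
    labs[, s, ] <- labels_by_set[[s]]
    if (!is.null(conf)) cf[, s, ] <- conf[[s]]
  }
  structure(list(queries = qids, sets = sets, cutoff = 60,
                 labels = labs, confidence = cf,
                 winning_genus = labs[, , 6, drop = TRUE]),
            class = "classification_table")
}
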