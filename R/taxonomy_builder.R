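#' Filter sequences by ungapped length
#'
#' Keeps near-full-length candidates: sequences whose ungapped length is
#' at least `min_len` bases. Order is preserved; kept/discarded counts
#' are reported via `message()`.
#'
#' @param seqs Named character vector of sequences.
#' @param min_len Minimum ungapped length in bases, inclusive
#'   (default 1250).
#' @return The kept subset of `seqs`.
#' @export
length_filter <- function(seqs, min_len = 1250L) {
  stopifnot(min_len >= 1L)
  ungapped <- nchar(gsub("[-.]", "", seqs))
  keep <- ungapped >= min_len
  message("length filter (>= ", min_len, " bp): kept ", sum(keep),
          ", discarded ", sum(!keep))
  seqs[keep]
}

#' Global-alignment percent identity between two DNA sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1,
#' gap -2; identity is the fraction of matching columns among alignment
#' columns remaining after trimming terminal gap columns. Symmetric in
#' its arguments.
#'
#' @param a,b Non-empty DNA strings.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  .alignment_identities(a, b)
}

# Identities of many patterns against one subject in a single vectorized
# alignment call. Returns a numeric vector along `patterns`.
.alignment_identities <- function(patterns, subject) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = 2)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  vapply(seq_along(pat), function(i)
    .column_identity(pat[[i]], sub[[i]]), numeric(1L))
}

# Identity over aligned strings after trimming terminal gap columns.
.column_identity <- function(p, s) {
  pc <- strsplit(p, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  gap <- pc == "-" | sc == "-"
  inner <- which(!gap)
  if (length(inner) == 0L) return(0)
  span <- inner[[1L]]:inner[[length(inner)]]
  sum(pc[span] == sc[span]) / length(span)
}

#' Greedy centroid clustering at an identity threshold
#'
#' Shared clustering engine for 99% dereplication of full-length
#' candidates and 97% OTU generation. Sequences are processed
#' longest-first (ties broken by lexicographic id); each joins the first
#' existing representative with pairwise identity at or above the
#' threshold, otherwise it founds a new cluster. Representatives are
#' returned in founding order.
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Identity threshold in (0, 1].
#' @return List with `representatives` (named character vector of
#'   representative sequences, founding order) and `membership` (named
#'   character vector mapping every input id to its representative id).
#' @export
greedy_cluster <- function(seqs, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  ids <- names(seqs)
  if (length(seqs) == 0L)
    return(list(representatives = stats::setNames(character(), character()),
                membership = stats::setNames(character(), character())))
  ord <- order(-nchar(seqs), ids)
  rep_ids <- character()
  rep_seqs <- character()
  membership <- stats::setNames(character(length(seqs)), ids)
  for (i in ord) {
    assigned <- NA_character_
    if (length(rep_ids)) {
      idents <- .alignment_identities(rep_seqs, seqs[[i]])
      hit <- which(idents >= threshold)
      if (length(hit))
        assigned <- rep_ids[[hit[[1L]]]]  # first representative wins
    }
    if (is.na(assigned)) {
      rep_ids <- c(rep_ids, ids[[i]])
      rep_seqs <- c(rep_seqs, seqs[[i]])
      assigned <- ids[[i]]
    }
    membership[[ids[[i]]]] <- assigned
  }
  list(representatives = stats::setNames(rep_seqs, rep_ids),
       membership = membership)
}

#' Dereplicate near-identical sequences
#'
#' Collapses a candidate set at an identity threshold (default 99%)
#' using [greedy_cluster()].
#'
#' @inheritParams greedy_cluster
#' @param threshold Identity threshold in (0, 1] (default 0.99).
#' @return As [greedy_cluster()].
#' @export
dereplicate <- function(seqs, threshold = 0.99) {
  greedy_cluster(seqs, threshold)
}

#' Best cultured hit for a novel sequence
#'
#' Returns the cultured reference maximizing global-alignment identity
#' to the novel sequence (ties broken by lexicographically smallest id);
#' an in-repository replacement for a nearest-cultured-representative
#' database query.
#'
#' @param novel DNA string.
#' @param cultured A non-empty `"training_set"` of cultured references.
#' @return List with `hit_id` and `identity`.
#' @export
best_cultured_hit <- function(novel, cultured) {
  stopifnot(inherits(cultured, "training_set"))
  if (length(cultured$id) == 0L)
    stop("empty cultured reference set")
  idents <- .alignment_identities(cultured$sequence, novel)
  best <- max(idents)
  cand <- cultured$id[idents == best]
  list(hit_id = sort(cand)[[1L]], identity = best)
}

#' Assign a taxonomy to a novel sequence from its best cultured hit
#'
#' The genus/class placement rule for novel environmental sequences:
#' if the best cultured hit is more than 95% identical, the novel
#' sequence adopts the hit's full lineage down to genus
#' (`basis = "genus_by_identity"`). Otherwise the sequence is placed in
#' the class supplied by the user's phylogenetic framework and the
#' ranks below Class are marked *incertae sedis*
#' (`basis = "class_incertae_sedis"`): Domain and Phylum are taken from
#' the hit, Class is `clade_class`, and Order/Family/Genus are filled
#' with the clade name when one is supplied (e.g. an environment-specific
#' group name at Family) or with placeholders repeating the deepest
#' named label. A previously published genus name can be preserved at
#' Genus via `genus_name` while the clade name occupies Family.
#'
#' @param novel_id Id of the novel sequence.
#' @param hit The best cultured hit, as a `"tax_path"` lineage.
#' @param identity Identity fraction of the hit in \[0, 1\].
#' @param clade_class Class label from the phylogenetic framework;
#'   required when `identity <= 0.95`.
#' @param clade_name Optional clade label placed at Family.
#' @param genus_name Optional published genus name retained at Genus.
#' @param hit_id Optional id of the hit (recorded in the result).
#' @return An object of class `"clade_assignment"`: list with
#'   `novel_id`, `hit_id`, `identity`, `basis` and `assigned`
#'   (a `"tax_path"`).
#' @export
assign_taxonomy <- function(novel_id, hit, identity, clade_class = NULL,
                            clade_name = NULL, genus_name = NULL,
                            hit_id = NA_character_) {
  stopifnot(inherits(hit, "tax_path"), identity >= 0, identity <= 1)
  if (identity > 0.95) {
    assigned <- hit
    basis <- "genus_by_identity"
  } else {
    if (is.null(clade_class) || !nzchar(clade_class))
      stop("unplaced sequence: ", novel_id,
           " has no cultured hit above 95% identity and no clade class")
    labels <- c(hit$labels[["Domain"]], hit$labels[["Phylum"]], clade_class,
                rep(NA_character_, 3L))
    flags <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
    fam <- if (!is.null(clade_name) && nzchar(clade_name)) clade_name
           else clade_class
    labels[[4L]] <- fam
    labels[[5L]] <- fam
    labels[[6L]] <- if (!is.null(genus_name) && nzchar(genus_name)) genus_name
                    else fam
    assigned <- tax_path(labels, flags)
    basis <- "class_incertae_sedis"
  }
  structure(list(novel_id = novel_id, hit_id = hit_id,
                 identity = identity, basis = basis, assigned = assigned),
            class = "clade_assignment")
}

#' Build an environment-specific custom reference database
#'
#' Pipeline for turning candidate full-length sequences into a custom
#' training set: length filter, dereplication of the survivors at an
#' identity threshold, best-cultured-hit search for every representative,
#' and taxonomy assignment by the genus-by-identity / class-incertae-sedis
#' rule. Clade placements for representatives lacking a >95% hit come
#' from `clade_map`, a data frame with columns `id`, `clade_class` and
#' optionally `clade_name` and `genus_name` keyed by candidate id.
#'
#' @param candidates Named character vector of candidate sequences.
#' @param cultured A `"training_set"` of cultured references with full
#'   taxonomies.
#' @param clade_map Data frame supplying clade placements (may be empty
#'   when every representative has a >95% hit).
#' @param min_len Length-filter threshold in bases (default 1250).
#' @param derep_threshold Dereplication identity threshold
#'   (default 0.99).
#' @param name Name for the resulting training set.
#' @return List with `set` (the custom `"training_set"`) and
#'   `provenance` (data frame: representative id, cluster size, hit id,
#'   identity, basis).
#' @export
build_custom_db <- function(candidates, cultured, clade_map = NULL,
                            min_len = 1250L, derep_threshold = 0.99,
                            name = "custom") {
  kept <- length_filter(candidates, min_len)
  clusters <- dereplicate(kept, derep_threshold)
  reps <- clusters$representatives
  if (length(reps) == 0L)
    stop("empty training set: no candidates survive filtering")
  if (is.null(clade_map))
    clade_map <- data.frame(id = character(), clade_class = character())
  assignments <- lapply(names(reps), function(id) {
    hit <- best_cultured_hit(reps[[id]], cultured)
    row <- match(hit$hit_id, cultured$id)
    hit_path <- tax_path(cultured$labels[row, ], cultured$incertae[row, ])
    m <- match(id, clade_map$id)
    getcol <- function(col) {
      if (!is.na(m) && col %in% names(clade_map)) clade_map[[col]][[m]]
      else NULL
    }
    assign_taxonomy(id, hit_path, hit$identity,
                    clade_class = getcol("clade_class"),
                    clade_name = getcol("clade_name"),
                    genus_name = getcol("genus_name"),
                    hit_id = hit$hit_id)
  })
  labels <- do.call(rbind, lapply(assignments, function(a) a$assigned$labels))
  incertae <- do.call(rbind, lapply(assignments,
                                    function(a) a$assigned$incertae))
  tax <- taxonomy_map(names(reps), labels, incertae)
  set <- training_set(name, reps, tax)
  provenance <- data.frame(
    id = names(reps),
    cluster_size = as.integer(table(clusters$membership)[names(reps)]),
    hit_id = vapply(assignments, function(a) a$hit_id, character(1L)),
    identity = vapply(assignments, function(a) a$identity, numeric(1L)),
    basis = vapply(assignments, function(a) a$basis, character(1L)),
    stringsAsFactors = FALSE)
  list(set = set, provenance = provenance)
}
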