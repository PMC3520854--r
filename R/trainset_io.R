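#' Read a FASTA file of DNA sequences
#'
#' Parses a FASTA file into ids and normalized sequences. The id of a
#' record is the header token up to the first whitespace. Sequences are
#' uppercased and alignment gap characters (`-`, `.`) are stripped.
#'
#' @param path Path to an existing FASTA file.
#' @return A named character vector of sequences; names are record ids,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub("[-.]", "", as.character(set)))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence record(s) in ", path, ": ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, path))` recovers
#' `x` whenever `x` is already normalized (uppercase, no gap characters).
#'
#' @param seqs Named character vector of sequences (names are ids).
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (length(seqs) && (is.null(names(seqs)) || any(!nzchar(names(seqs)))))
    stop("all sequences must be named")
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a mothur-dialect taxonomy file
#'
#' Each line is `id<TAB>Rank1;Rank2;...;` with an optional trailing
#' semicolon. Lineages are normalized to exactly six ranks (Domain,
#' Phylum, Class, Order, Family, Genus): shorter lineages are padded
#' downward with incertae-sedis placeholders repeating the deepest named
#' label; more than six (unprefixed) ranks is an error. Labels carrying
#' the `_incertae_sedis` suffix are stripped to the bare label with the
#' corresponding flag set.
#'
#' @param path Path to an existing taxonomy file.
#' @return An object of class `"taxonomy_map"`: list with `id` (character),
#'   `labels` (n x 6 character matrix) and `incertae` (n x 6 logical
#'   matrix); rows in file order.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path))
    stop("taxonomy file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  ids <- character(n)
  labels <- matrix(character(), 0L, 6L)
  incertae <- matrix(logical(), 0L, 6L)
  if (n) {
    has_tab <- grepl("\t", lines, fixed = TRUE)
    if (any(!has_tab))
      stop("taxonomy line ", which(!has_tab)[1L], " has no tab separator")
    ids <- sub("\t.*$", "", lines)
    lineages <- sub("^[^\t]*\t", "", lines)
    parsed <- lapply(seq_len(n), function(i)
      .parse_lineage(lineages[[i]], paste0(" (line ", i, ", id ", ids[[i]], ")")))
    labels <- do.call(rbind, lapply(parsed, `[[`, "labels"))
    incertae <- do.call(rbind, lapply(parsed, `[[`, "incertae"))
  }
  if (anyDuplicated(ids))
    stop("duplicate id(s) in taxonomy file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  taxonomy_map(ids, labels, incertae)
}

#' Construct a taxonomy map
#'
#' @param id Character vector of sequence ids.
#' @param labels n x 6 character matrix of bare rank labels.
#' @param incertae n x 6 logical matrix of incertae-sedis flags
#'   (default all `FALSE`).
#' @return An object of class `"taxonomy_map"`.
#' @export
taxonomy_map <- function(id, labels,
                         incertae = matrix(FALSE, length(id), 6L)) {
  id <- as.character(id)
  labels <- matrix(as.character(labels), nrow = length(id), ncol = 6L,
                   dimnames = list(NULL, TAX_RANKS))
  incertae <- matrix(as.logical(incertae), nrow = length(id), ncol = 6L,
                     dimnames = list(NULL, TAX_RANKS))
  if (length(id)) {
    bad <- !nzchar(labels) | is.na(labels)
    if (any(bad))
      stop("empty rank label(s) for id(s): ",
           paste(unique(id[rowSums(bad) > 0L]), collapse = ", "))
    if (any(grepl("[;\t]", labels)))
      stop("rank labels may not contain ';' or tab")
  }
  structure(list(id = id, labels = labels, incertae = incertae),
            class = "taxonomy_map")
}

#' @export
print.taxonomy_map <- function(x, ...) {
  cat("taxonomy map:", length(x$id), "lineages\n")
  invisible(x)
}

#' Write a taxonomy map to a mothur-dialect taxonomy file
#'
#' Incertae-sedis flags are serialized by appending `_incertae_sedis`
#' to the flagged label; [read_taxonomy()] recovers them.
#'
#' @param tax A `"taxonomy_map"` (see [taxonomy_map()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "taxonomy_map"))
  lines <- vapply(seq_along(tax$id), function(i)
    paste0(tax$id[[i]], "\t",
           .serialize_lineage(tax$labels[i, ], tax$incertae[i, ])),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a training set
#'
#' A training set pairs reference sequences with their six-rank
#' taxonomies — the two files from which a naive Bayesian classifier
#' model is built. Invariants enforced: unique non-whitespace ids,
#' non-empty sequences, a taxonomy for every sequence, and
#' parent-uniqueness (within one set, a label at a given rank has exactly
#' one parent label at the rank above).
#'
#' @param name Name of the set (used in reports and seed derivation).
#' @param seqs Named character vector of reference sequences.
#' @param tax A `"taxonomy_map"` covering every sequence id.
#' @return An object of class `"training_set"`: list with `name`, `id`,
#'   `sequence`, `labels` (n x 6), `incertae` (n x 6).
#' @export
training_set <- function(name, seqs, tax) {
  if (length(seqs) == 0L)
    return(structure(list(name = as.character(name), id = character(),
                          sequence = character(),
                          labels = matrix(character(), 0L, 6L,
                                          dimnames = list(NULL, TAX_RANKS)),
                          incertae = matrix(logical(), 0L, 6L,
                                            dimnames = list(NULL, TAX_RANKS))),
                     class = "training_set"))
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)) || any(grepl("\\s", ids)))
    stop("sequence ids must be non-empty and contain no whitespace")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  stopifnot(inherits(tax, "taxonomy_map"))
  hit <- match(ids, tax$id)
  if (anyNA(hit))
    stop("sequence(s) without taxonomy: ",
         paste(ids[is.na(hit)], collapse = ", "))
  labels <- tax$labels[hit, , drop = FALSE]
  incertae <- tax$incertae[hit, , drop = FALSE]
  .check_parent_uniqueness(labels)
  structure(list(name = as.character(name), id = ids,
                 sequence = unname(as.character(seqs)),
                 labels = labels, incertae = incertae),
            class = "training_set")
}

# Each (rank, label) must have exactly one parent label at the rank above;
# a genus label must map to exactly one full lineage.
.check_parent_uniqueness <- function(labels) {
  for (r in 2L:6L) {
    pairs <- unique(data.frame(label = labels[, r], parent = labels[, r - 1L],
                               stringsAsFactors = FALSE))
    dup <- pairs$label[duplicated(pairs$label)]
    if (length(dup))
      stop("taxon label(s) with multiple parents at rank ", TAX_RANKS[r],
           ": ", paste(unique(dup), collapse = ", "))
  }
  lin <- unique(apply(labels, 1L, paste, collapse = ";"))
  gen <- sub("^.*;", "", lin)
  if (anyDuplicated(gen))
    stop("genus label(s) with multiple lineages: ",
         paste(unique(gen[duplicated(gen)]), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.training_set <- function(x, ...) {
  cat("training set '", x$name, "': ", length(x$id), " reference sequences, ",
      length(unique(x$labels[, "Genus"])), " genera\n", sep = "")
  invisible(x)
}

#' @export
length.training_set <- function(x) length(x$id)

#' Read a training set from FASTA + taxonomy files
#'
#' @param name Name for the set.
#' @param fasta_path Path to the reference FASTA file.
#' @param tax_path Path to the companion taxonomy file.
#' @return A `"training_set"`.
#' @export
read_training_set <- function(name, fasta_path, tax_path) {
  training_set(name, read_fasta(fasta_path), read_taxonomy(tax_path))
}

#' Write a training set to FASTA + taxonomy files
#'
#' @param set A `"training_set"`.
#' @param fasta_path,tax_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_training_set <- function(set, fasta_path, tax_path) {
  stopifnot(inherits(set, "training_set"))
  write_fasta(stats::setNames(set$sequence, set$id), fasta_path)
  write_taxonomy(taxonomy_map(set$id, set$labels, set$incertae), tax_path)
  invisible(list(fasta = fasta_path, taxonomy = tax_path))
}

#' Augment a base training set with a custom database
#'
#' Returns the union of the two sets' references (base references first,
#' custom references after), e.g. extending a general-purpose reference
#' database with environment-specific sequences. Ids must be disjoint:
#' a collision is an error, never a silent override.
#'
#' @param base,custom `"training_set"` objects.
#' @param name Name for the combined set (default `"<base>+<custom>"`).
#' @return A `"training_set"` of size `length(base) + length(custom)`.
#' @export
augment <- function(base, custom, name = paste0(base$name, "+", custom$name)) {
  stopifnot(inherits(base, "training_set"), inherits(custom, "training_set"))
  clash <- intersect(base$id, custom$id)
  if (length(clash))
    stop("id collision(s) between base and custom sets: ",
         paste(clash, collapse = ", "))
  ids <- c(base$id, custom$id)
  seqs <- stats::setNames(c(base$sequence, custom$sequence), ids)
  tax <- taxonomy_map(ids,
                      rbind(base$labels, custom$labels),
                      rbind(base$incertae, custom$incertae))
  training_set(name, seqs, tax)
}
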