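#' Write a classifier model to a flat TSV serialization
#'
#' Versioned plain-text model format, so training is reproducible and
#' the model inspectable. Sections are introduced by `[header]`,
#' `[genera]` (genus, sequence count, serialized lineage),
#' `[word_doc_counts]` (word, number of training sequences containing
#' it) and `[genus_word_counts]` (word, genus, count); words are written
#' as DNA strings.
#'
#' @param model An `"nbc_model"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nbc_model <- function(model, path) {
  stopifnot(inherits(model, "nbc_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#taxnbc-model\t1",
               "[header]",
               paste0("word_size\t", model$word_size),
               paste0("n_train\t", model$n_train),
               "[genera]"), con)
  for (g in seq_along(model$genera))
    writeLines(paste0(model$genera[[g]], "\t", model$M[[g]], "\t",
                      .serialize_lineage(model$lineage[g, ],
                                         model$lineage_incertae[g, ])), con)
  present <- which(model$n_word > 0L)
  words <- .decode_words(present, model$word_size)
  writeLines("[word_doc_counts]", con)
  writeLines(paste0(words, "\t", model$n_word[present]), con)
  writeLines("[genus_word_counts]", con)
  for (g in seq_along(model$genera)) {
    nz <- which(model$counts[, g] > 0L)
    if (length(nz))
      writeLines(paste0(.decode_words(nz, model$word_size), "\t",
                        model$genera[[g]], "\t", model$counts[nz, g]), con)
  }
  invisible(path)
}

# Integer word codes (1-based) back to DNA strings.
.decode_words <- function(codes, word_size) {
  v <- codes - 1L
  out <- matrix("", length(codes), word_size)
  for (j in word_size:1L) {
    out[, j] <- c("A", "C", "G", "T")[(v %% 4L) + 1L]
    v <- v %/% 4L
  }
  apply(out, 1L, paste, collapse = "")
}

#' Read a classifier model from its flat serialization
#'
#' @param path Path written by [write_nbc_model()].
#' @return An `"nbc_model"`.
#' @export
read_nbc_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[[1L]], "#taxnbc-model"))
    stop("not a taxnbc model file: ", path)
  sec <- cumsum(lines %in% c("[header]", "[genera]", "[word_doc_counts]",
                             "[genus_word_counts]"))
  body <- split(lines, sec)
  get_section <- function(k) {
    x <- body[[as.character(k)]]
    x[-1L]
  }
  hdr <- strsplit(get_section(1L), "\t", fixed = TRUE)
  hv <- stats::setNames(vapply(hdr, `[[`, "", 2L),
                        vapply(hdr, `[[`, "", 1L))
  word_size <- as.integer(hv[["word_size"]])
  n_train <- as.integer(hv[["n_train"]])
  gen <- strsplit(get_section(2L), "\t", fixed = TRUE)
  genera <- vapply(gen, `[[`, "", 1L)
  M <- as.integer(vapply(gen, `[[`, "", 2L))
  parsed <- lapply(vapply(gen, `[[`, "", 3L), .parse_lineage)
  lineage <- do.call(rbind, lapply(parsed, `[[`, "labels"))
  dimnames(lineage) <- list(genera, TAX_RANKS)
  lineage_incertae <- do.call(rbind, lapply(parsed, `[[`, "incertae"))
  dimnames(lineage_incertae) <- list(genera, TAX_RANKS)
  K <- 4L^word_size
  n_word <- integer(K)
  wdc <- strsplit(get_section(3L), "\t", fixed = TRUE)
  if (length(wdc)) {
    codes <- vapply(vapply(wdc, `[[`, "", 1L), .word_codes, integer(1L),
                    word_size = word_size)
    n_word[codes] <- as.integer(vapply(wdc, `[[`, "", 2L))
  }
  counts <- matrix(0L, K, length(genera))
  gwc <- strsplit(get_section(4L), "\t", fixed = TRUE)
  if (length(gwc)) {
    codes <- vapply(vapply(gwc, `[[`, "", 1L), .word_codes, integer(1L),
                    word_size = word_size)
    gi <- match(vapply(gwc, `[[`, "", 2L), genera)
    counts[cbind(codes, gi)] <- as.integer(vapply(gwc, `[[`, "", 3L))
  }
  structure(list(word_size = word_size, genera = genera,
                 lineage = lineage, lineage_incertae = lineage_incertae,
                 counts = counts, M = M, n_word = n_word,
                 prior = (n_word + 0.5) / (n_train + 1), n_train = n_train),
            class = "nbc_model")
}
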