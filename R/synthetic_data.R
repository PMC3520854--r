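#' Simulation scenario configuration
#'
#' Parameters of the seeded simulator: a six-rank bacterial taxonomy
#' (Domain fixed to "Bacteria"), per-genus reference sequence families
#' generated by substitution-only divergence down the hierarchy, and
#' short directional reads excised from a hypervariable-region-like
#' subwindow with per-base substitution errors.
#'
#' The default divergences (within genus 2%, between genera 8%, between
#' families 15%, between phyla 25% substituted sites per branch) give a
#' strict identity ordering within genus > within family > within phylum,
#' the separability real rRNA taxonomies show at these ranks. The default
#' read window (positions 20-340 of a 1300 bp reference, truncated to
#' 250 bp) emulates sequencing a 5'-end hypervariable stretch of the
#' gene.
#'
#' @param seed Integer seed; all generated output is deterministic given
#'   the configuration.
#' @param n_phyla,families_per_phylum,genera_per_family Taxonomy shape
#'   (defaults 4, 2, 2: 16 genera in 8 families).
#' @param refs_per_genus Reference sequences per genus (default 5).
#' @param ref_length Reference length in bp (default 1300).
#' @param divergence Named numeric vector of per-branch substitution
#'   fractions: `within_genus`, `between_genera`, `between_families`,
#'   `between_phyla`; must be strictly increasing.
#' @param read_window Integer pair: first and last reference position of
#'   the amplified window (default `c(20, 340)`).
#' @param read_length Read length in bp (default 250); reads are the
#'   first `read_length` bases of the window.
#' @param read_error_rate Per-base substitution error rate in
#'   \[0, 0.25\] (default 0.005).
#' @param n_reads Number of reads to simulate (default 500).
#' @param holdout_genera Genus labels absent from base training sets but
#'   present in the custom set (used by [make_holdout_scenario()]).
#' @param holdout_read_fraction Fraction of reads drawn from holdout
#'   genera in the holdout scenario (default 0.5).
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(seed = 1L,
                            n_phyla = 4L,
                            families_per_phylum = 2L,
                            genera_per_family = 2L,
                            refs_per_genus = 5L,
                            ref_length = 1300L,
                            divergence = c(within_genus = 0.02,
                                           between_genera = 0.08,
                                           between_families = 0.15,
                                           between_phyla = 0.25),
                            read_window = c(20L, 340L),
                            read_length = 250L,
                            read_error_rate = 0.005,
                            n_reads = 500L,
                            holdout_genera = character(),
                            holdout_read_fraction = 0.5) {
  need <- c("within_genus", "between_genera", "between_families",
            "between_phyla")
  if (!all(need %in% names(divergence)))
    stop("divergence must name: ", paste(need, collapse = ", "))
  divergence <- divergence[need]
  if (any(diff(divergence) <= 0))
    stop("divergences must increase strictly with rank distance")
  if (read_error_rate < 0 || read_error_rate > 0.25)
    stop("read_error_rate must be in [0, 0.25]")
  if (length(read_window) != 2L || read_window[[1L]] < 1L ||
      read_window[[2L]] > ref_length || read_window[[1L]] >= read_window[[2L]])
    stop("read_window must fit inside the reference length")
  stopifnot(n_phyla >= 1L, families_per_phylum >= 1L,
            genera_per_family >= 1L, refs_per_genus >= 1L, n_reads >= 0L,
            holdout_read_fraction >= 0, holdout_read_fraction <= 1)
  structure(list(seed = as.integer(seed), n_phyla = as.integer(n_phyla),
                 families_per_phylum = as.integer(families_per_phylum),
                 genera_per_family = as.integer(genera_per_family),
                 refs_per_genus = as.integer(refs_per_genus),
                 ref_length = as.integer(ref_length),
                 divergence = divergence,
                 read_window = as.integer(read_window),
                 read_length = as.integer(read_length),
                 read_error_rate = read_error_rate,
                 n_reads = as.integer(n_reads),
                 holdout_genera = as.character(holdout_genera),
                 holdout_read_fraction = holdout_read_fraction),
            class = "scenario_config")
}

#' Generate the scenario's six-rank taxonomy
#'
#' Deterministic systematic labelling: Domain "Bacteria"; phyla
#' `P1..`, one class per phylum (`P1_C`), families `P1_F1..`, one order
#' per family (`P1_F1_O`), genera `P1_F1_G1..`.
#'
#' @param config A `"scenario_config"`.
#' @return A `"taxonomy_map"` with one row per genus; ids are genus
#'   labels.
#' @export
generate_taxonomy <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  rows <- list()
  for (p in seq_len(config$n_phyla))
    for (f in seq_len(config$families_per_phylum))
      for (g in seq_len(config$genera_per_family)) {
        phy <- paste0("P", p)
        fam <- paste0(phy, "_F", f)
        rows[[length(rows) + 1L]] <-
          c(Domain = "Bacteria", Phylum = phy, Class = paste0(phy, "_C"),
            Order = paste0(fam, "_O"), Family = fam,
            Genus = paste0(fam, "_G", g))
      }
  labels <- do.call(rbind, rows)
  taxonomy_map(labels[, "Genus"], labels)
}

# Substitute each position independently with probability `rate`; the
# replacement base is uniform over the three alternatives.
.mutate <- function(bases, rate) {
  hit <- which(stats::runif(length(bases)) < rate)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    bases[hit] <- c("A", "C", "G", "T")[
      ((match(bases[hit], c("A", "C", "G", "T")) - 1L + shift) %% 4L) + 1L]
  }
  bases
}

#' Generate reference sequences down the taxonomy
#'
#' A single root sequence is drawn uniformly over ACGT, then mutated
#' down the hierarchy: one ancestor per phylum (at the between-phyla
#' fraction), per family (between-families), per genus (between-genera),
#' and finally each reference mutates its genus ancestor at the
#' within-genus fraction. Substitution-only, so reference coordinates
#' stay alignable and window excision stays well defined.
#'
#' @param config A `"scenario_config"`.
#' @return A `"training_set"` named `"reference"` with
#'   `refs_per_genus` sequences per genus, ids `<genus>_r<j>`; its
#'   taxonomy is the true lineage of every reference.
#' @export
generate_references <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  tax <- generate_taxonomy(config)
  div <- config$divergence
  withr::with_seed(config$seed, {
    root <- sample(c("A", "C", "G", "T"), config$ref_length, replace = TRUE)
    ids <- character(); seqs <- character(); rows <- integer()
    for (p in seq_len(config$n_phyla)) {
      anc_p <- .mutate(root, div[["between_phyla"]])
      for (f in seq_len(config$families_per_phylum)) {
        anc_f <- .mutate(anc_p, div[["between_families"]])
        for (g in seq_len(config$genera_per_family)) {
          anc_g <- .mutate(anc_f, div[["between_genera"]])
          genus <- paste0("P", p, "_F", f, "_G", g)
          row <- match(genus, tax$id)
          for (j in seq_len(config$refs_per_genus)) {
            ids <- c(ids, paste0(genus, "_r", j))
            seqs <- c(seqs, paste(.mutate(anc_g, div[["within_genus"]]),
                                  collapse = ""))
            rows <- c(rows, row)
          }
        }
      }
    }
  })
  training_set("reference", stats::setNames(seqs, ids),
               taxonomy_map(ids, tax$labels[rows, , drop = FALSE]))
}

#' Simulate directional amplicon-like reads from references
#'
#' Each read picks a source genus (uniform, or weighted toward holdout
#' genera via `genus_weights`), a reference uniformly within the genus,
#' excises the configured window, truncates it to the read length and
#' applies independent per-base substitution errors. Reads are
#' forward-oriented.
#'
#' @param config A `"scenario_config"`.
#' @param refs A `"training_set"` of source references.
#' @param genus_weights Optional named numeric vector of sampling
#'   weights per genus (default uniform).
#' @return List with `reads` (named character vector, ids
#'   `read<k>`) and `truth` (data frame: `read_id`, `source_ref`, one
#'   column per rank).
#' @export
generate_reads <- function(config, refs, genus_weights = NULL) {
  stopifnot(inherits(config, "scenario_config"), inherits(refs, "training_set"))
  if (length(refs$id) == 0L) stop("no reference sequences to read from")
  genera <- sort(unique(refs$labels[, "Genus"]))
  if (is.null(genus_weights)) {
    genus_weights <- stats::setNames(rep(1, length(genera)), genera)
  } else {
    if (!all(names(genus_weights) %in% genera))
      stop("genus_weights names unknown genera")
    genus_weights <- genus_weights[genera]
    genus_weights[is.na(genus_weights)] <- 0
    names(genus_weights) <- genera
  }
  w0 <- config$read_window[[1L]]
  w1 <- min(config$read_window[[2L]], w0 + config$read_length - 1L)
  if (w1 > min(nchar(refs$sequence)))
    stop("read window exceeds reference bounds")
  by_genus <- split(seq_along(refs$id), refs$labels[, "Genus"])
  n <- config$n_reads
  withr::with_seed(.derive_seed(config$seed, "reads"), {
    gpick <- sample(genera, n, replace = TRUE, prob = genus_weights)
    src <- vapply(gpick, function(g) {
      idx <- by_genus[[g]]
      idx[[sample.int(length(idx), 1L)]]
    }, integer(1L))
    reads <- vapply(src, function(i) {
      bases <- strsplit(substr(refs$sequence[[i]], w0, w1), "")[[1L]]
      paste(.mutate(bases, config$read_error_rate), collapse = "")
    }, character(1L))
  })
  ids <- sprintf("read%05d", seq_len(n))
  truth <- data.frame(read_id = ids, source_ref = refs$id[src],
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(refs$labels[src, , drop = FALSE],
                                      stringsAsFactors = FALSE))
  rownames(truth) <- NULL
  list(reads = stats::setNames(unname(reads), ids), truth = truth)
}

#' Build a novel-clade holdout scenario
#'
#' Emulates the evaluation design in which query reads derive partly
#' from lineages absent from general-purpose base training sets but
#' present in an environment-specific custom set. From the full
#' reference pool, the holdout genera's references form the custom set
#' (with correct taxonomy); three base sets are built from the remaining
#' references by jackknifing genus coverage — each base set drops all
#' references of a distinct random third of the non-holdout genera,
#' emulating the breadth differences between independently curated
#' databases — and by applying a per-set label dialect, a recorded,
#' invertible renaming of Phylum..Family labels emulating their
#' taxonomic-framework disagreement. Reads are drawn with the
#' configured enrichment for holdout genera.
#'
#' @param config A `"scenario_config"` with non-empty `holdout_genera`.
#' @param base_names Names of the three base sets.
#' @return List with `base_sets` (named list of three `"training_set"`
#'   objects), `custom` (a `"training_set"`), `reads`, `truth`,
#'   `dialect_map` (data frame: set, rank, original, dialect),
#'   `dropped_genera` (named list: genera absent from each base set) and
#'   `config`.
#' @export
make_holdout_scenario <- function(config,
                                  base_names = c("baseA", "baseB", "baseC")) {
  stopifnot(inherits(config, "scenario_config"))
  if (length(config$holdout_genera) == 0L)
    stop("holdout_genera must be non-empty")
  refs <- generate_references(config)
  genera <- unique(refs$labels[, "Genus"])
  unknown <- setdiff(config$holdout_genera, genera)
  if (length(unknown))
    stop("unknown holdout genus(es): ", paste(unknown, collapse = ", "))
  hold <- refs$labels[, "Genus"] %in% config$holdout_genera
  custom <- training_set("custom",
                         stats::setNames(refs$sequence[hold], refs$id[hold]),
                         taxonomy_map(refs$id[hold],
                                      refs$labels[hold, , drop = FALSE]))
  nonhold <- setdiff(genera, config$holdout_genera)
  dropped <- withr::with_seed(.derive_seed(config$seed, "jackknife"),
    split(sample(nonhold), rep_len(seq_len(3L), length(nonhold))))
  dialect_rows <- list()
  base_sets <- stats::setNames(vector("list", 3L), base_names)
  for (b in seq_len(3L)) {
    idx <- which(!hold & !(refs$labels[, "Genus"] %in% dropped[[b]]))
    labels <- refs$labels[idx, , drop = FALSE]
    for (r in 2L:5L) {  # Phylum..Family; Domain and Genus keep their names
      orig <- unique(labels[, r])
      dial <- paste0(orig, "@", base_names[[b]])
      labels[, r] <- dial[match(labels[, r], orig)]
      dialect_rows[[length(dialect_rows) + 1L]] <-
        data.frame(set = base_names[[b]], rank = TAX_RANKS[[r]],
                   original = orig, dialect = dial, stringsAsFactors = FALSE)
    }
    base_sets[[b]] <- training_set(
      base_names[[b]],
      stats::setNames(refs$sequence[idx], refs$id[idx]),
      taxonomy_map(refs$id[idx], labels))
  }
  f <- config$holdout_read_fraction
  weights <- stats::setNames(rep(0, length(genera)), genera)
  is_hold <- genera %in% config$holdout_genera
  weights[is_hold] <- f / sum(is_hold)
  weights[!is_hold] <- (1 - f) / sum(!is_hold)
  rd <- generate_reads(config, refs, genus_weights = weights)
  names(dropped) <- base_names
  list(base_sets = base_sets, custom = custom,
       reads = rd$reads, truth = rd$truth,
       dialect_map = do.call(rbind, dialect_rows),
       dropped_genera = dropped, config = config)
}

#' Invert a label dialect
#'
#' Maps dialected labels back to their original names using the dialect
#' map recorded by [make_holdout_scenario()].
#'
#' @param labels Character vector of (possibly dialected) labels.
#' @param dialect_map The scenario's dialect map.
#' @return Character vector of original labels.
#' @export
undialect <- function(labels, dialect_map) {
  m <- match(labels, dialect_map$dialect)
  out <- labels
  out[!is.na(m)] <- dialect_map$original[m[!is.na(m)]]
  out
}

#' Write a full scenario to a directory
#'
#' Emits the three base sets and the custom set (FASTA + taxonomy),
#' the reads FASTA, the truth TSV, the dialect map TSV and a flat
#' key-value echo of the configuration.
#'
#' @param scenario Output of [make_holdout_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(scenario$base_sets))
    write_training_set(scenario$base_sets[[nm]],
                       file.path(dir, paste0(nm, ".fasta")),
                       file.path(dir, paste0(nm, ".tax")))
  write_training_set(scenario$custom, file.path(dir, "custom.fasta"),
                     file.path(dir, "custom.tax"))
  write_fasta(scenario$reads, file.path(dir, "reads.fasta"))
  utils::write.table(scenario$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scenario$dialect_map, file.path(dir, "dialect_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- scenario$config
  flat <- vapply(names(cfg), function(k)
    paste0(k, "\t", paste(cfg[[k]], collapse = ",")), character(1L))
  writeLines(flat, file.path(dir, "config.tsv"))
  invisible(dir)
}
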