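#' Taxonomic ranks used throughout the package
#'
#' The six ranks predominantly used for prokaryotic rRNA classification,
#' from most to least inclusive.
#'
#' @format Character vector of length 6.
#' @export
TAX_RANKS <- c("Domain", "Phylum", "Class", "Order", "Family", "Genus")

# Label suffix used to serialize incertae-sedis flags into taxonomy files.
.INCERTAE_SUFFIX <- "_incertae_sedis"

#' Construct a six-rank taxonomy path
#'
#' A taxonomy path is an ordered lineage of exactly six rank labels
#' (Domain, Phylum, Class, Order, Family, Genus), each optionally flagged
#' *incertae sedis* — i.e. deliberately unsettled below a confidently
#' assigned rank.
#'
#' @param labels Character vector of exactly 6 non-empty rank labels.
#'   Labels may not contain semicolons or tabs (reserved by the taxonomy
#'   file format).
#' @param incertae Logical vector of length 6 flagging each rank as
#'   incertae sedis. Defaults to all `FALSE`.
#' @return An object of class `"tax_path"`: a list with elements `labels`
#'   and `incertae`.
#' @examples
#' tax_path(c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
#'            "Orbales", "Orbaceae", "Orbus"))
#' @export
tax_path <- function(labels, incertae = rep(FALSE, 6L)) {
  labels <- as.character(labels)
  incertae <- as.logical(incertae)
  if (length(labels) != 6L)
    stop("a taxonomy path must have exactly 6 rank labels, got ",
         length(labels))
  if (any(is.na(labels)) || any(!nzchar(labels)))
    stop("taxonomy path labels must be non-empty")
  if (any(grepl("[;\t]", labels)))
    stop("taxonomy path labels may not contain ';' or tab")
  if (length(incertae) != 6L || any(is.na(incertae)))
    stop("'incertae' must be 6 non-missing logical flags")
  structure(list(labels = stats::setNames(labels, TAX_RANKS),
                 incertae = stats::setNames(incertae, TAX_RANKS)),
            class = "tax_path")
}

#' @export
print.tax_path <- function(x, ...) {
  shown <- ifelse(x$incertae, paste0(x$labels, " [incertae sedis]"),
                  x$labels)
  cat(paste(shown, collapse = "; "), "\n")
  invisible(x)
}

#' @export
format.tax_path <- function(x, ...) .serialize_lineage(x$labels, x$incertae)

# lineage <-> text ------------------------------------------------------

# Serialize labels + flags to "A;B;...;F;" with the incertae suffix
# appended to flagged labels.
.serialize_lineage <- function(labels, incertae) {
  out <- ifelse(incertae & !endsWith(labels, .INCERTAE_SUFFIX),
                paste0(labels, .INCERTAE_SUFFIX), labels)
  paste0(paste(out, collapse = ";"), ";")
}

# Parse one semicolon-delimited lineage string into bare labels + flags,
# padding lineages shorter than 6 ranks with placeholders derived from
# the deepest named rank. Returns list(labels, incertae).
.parse_lineage <- function(text, context = "") {
  text <- sub(";+$", "", text)
  parts <- if (nzchar(text)) strsplit(text, ";", fixed = TRUE)[[1L]] else character()
  parts <- trimws(parts)
  if (any(!nzchar(parts)))
    stop("empty rank label in lineage", context)
  # Greengenes/SILVA-style rank prefixes: keep only the six canonical ranks.
  if (length(parts) && all(grepl("^[a-zA-Z]__", parts))) {
    keys <- tolower(substr(parts, 1L, 1L))
    keep <- keys %in% c("d", "k", "p", "c", "o", "f", "g")
    parts <- sub("^[a-zA-Z]__", "", parts[keep])
    parts <- parts[nzchar(parts)]
  }
  if (length(parts) > 6L)
    stop("lineage has ", length(parts), " ranks (max 6)", context)
  if (length(parts) == 0L)
    stop("empty lineage", context)
  flags <- endsWith(parts, .INCERTAE_SUFFIX)
  labels <- ifelse(flags, substr(parts, 1L, nchar(parts) - nchar(.INCERTAE_SUFFIX)),
                   parts)
  if (any(!nzchar(labels)))
    stop("bare incertae-sedis label in lineage", context)
  if (length(labels) < 6L) {
    deepest <- labels[length(labels)]
    pad <- 6L - length(labels)
    labels <- c(labels, rep(deepest, pad))
    flags <- c(flags, rep(TRUE, pad))
  }
  list(labels = labels, incertae = flags)
}
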