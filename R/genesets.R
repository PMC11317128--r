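#' Gene-set collections
#'
#' A collection is stored as a long data.frame with columns `set`, `gene`
#' and `weight`, carrying a collection `name` attribute. Weights default to 1
#' for plain membership; signed weights (e.g. +1 activation / -1 repression in
#' transcription-factor regulons) are preserved and used directly as the
#' regressor in the enrichment model.
#'
#' @param sets data.frame with columns `set`, `gene` and optionally `weight`.
#' @param name Collection name (used as the `resource` label downstream).
#' @return Object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, name = "collection") {
  if (!all(c("set", "gene") %in% names(sets)))
    stop_validation("gene sets need 'set' and 'gene' columns")
  if (is.null(sets$weight)) sets$weight <- 1
  if (!all(is.finite(sets$weight))) stop_validation("gene-set weights must be finite")
  dup <- duplicated(sets[, c("set", "gene")])
  if (any(dup)) {
    warning(sprintf("%d duplicate (set, gene) pairs collapsed to first occurrence",
                    sum(dup)))
    sets <- sets[!dup, , drop = FALSE]
  }
  out <- data.frame(set = as.character(sets$set), gene = as.character(sets$gene),
                    weight = as.numeric(sets$weight), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, name = name, class = c("geneset_collection", "data.frame"))
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection '%s': %d sets, %d set-gene pairs\n",
              attr(x, "name"), length(unique(x$set)), nrow(x)))
  invisible(x)
}

#' Read gene sets from GMT or weighted three-column TSV
#'
#' GMT lines are `set <tab> description <tab> gene1 <tab> gene2 ...`; every
#' member receives weight 1. The weighted format has columns
#' `set <tab> gene <tab> weight` (header optional, detected) and allows
#' negative weights for repressive interactions.
#'
#' @param path Input file.
#' @param format `"gmt"` or `"weighted-tsv"`; guessed from the extension when
#'   missing.
#' @param name Collection name; defaults to the file name without extension.
#' @return A [geneset_collection()].
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "weighted-tsv"),
                           name = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "weighted-tsv"
  name <- name %||% sub("\\.[^.]+$", "", basename(path))
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(seq_along(lines), function(i) {
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
      if (length(f) < 3L)
        stop_format("malformed GMT line %d in %s (need >= 3 fields)", i, path)
      data.frame(set = f[[1L]], gene = f[-(1:2)], weight = 1,
                 stringsAsFactors = FALSE)
    })
    sets <- do.call(rbind, recs)
  } else {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) != 3L)
      stop_format("weighted gene-set TSV %s must have 3 columns", path)
    # tolerate a header row
    if (!is.numeric(tab[[3L]]) && suppressWarnings(is.na(as.numeric(tab[1L, 3L])))) {
      tab <- tab[-1L, , drop = FALSE]
    }
    w <- suppressWarnings(as.numeric(tab[[3L]]))
    if (anyNA(w)) {
      bad <- which(is.na(w))[1L]
      stop_format("non-numeric weight at line %d of %s", bad, path)
    }
    sets <- data.frame(set = tab[[1L]], gene = tab[[2L]], weight = w,
                       stringsAsFactors = FALSE)
  }
  geneset_collection(sets, name = name)
}

#' Write gene sets to GMT or weighted TSV
#'
#' @param coll A [geneset_collection()].
#' @param path Output file.
#' @param format `"gmt"` (weights not representable, all treated as
#'   membership) or `"weighted-tsv"`.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(coll, path, format = c("weighted-tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "gmt") {
    by_set <- split(coll$gene, coll$set)
    lines <- vapply(names(by_set), function(s)
      paste(c(s, "na", by_set[[s]]), collapse = "\t"), character(1L))
    writeLines(lines, path)
  } else {
    utils::write.table(coll[, c("set", "gene", "weight")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
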