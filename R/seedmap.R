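#' Read a PheCode mapping table
#'
#' Delimited text with columns \code{icd}, \code{phecode}, \code{label} and
#' \code{excl_phecodes} (comma-separated PheCode ranges such as
#' \code{"250-250.99"}, possibly empty), compatible with the published
#' PheCode v1.2 layout. ICD codes are normalized on read.
#'
#' @param path path to the mapping file (tab or comma delimited, gzip ok).
#' @param sep separator; \code{NULL} auto-detects.
#' @return data frame with columns \code{icd}, \code{phecode}, \code{label},
#'   \code{excl_phecodes}.
#' @export
read_phecode_map <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- .guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("icd", "phecode")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mapping file lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(df$label)) df$label <- df$phecode
  if (is.null(df$excl_phecodes)) df$excl_phecodes <- ""
  df$icd <- normalize_code(df$icd)
  df
}

# parse "250-250.99,290-290.9" into a 2-column numeric range matrix
.parse_excl_ranges <- function(s) {
  if (is.na(s) || !nzchar(s)) return(matrix(numeric(), 0, 2))
  parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
  out <- t(vapply(parts, function(p) {
    ab <- strsplit(trimws(p), "-", fixed = TRUE)[[1L]]
    a <- suppressWarnings(as.numeric(ab[1L]))
    b <- if (length(ab) > 1L) suppressWarnings(as.numeric(ab[2L])) else a
    c(a, b)
  }, numeric(2)))
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Build the PheCode seed map for a corpus
#'
#' Joins a PheCode mapping onto the corpus's guided-modality vocabulary and
#' keeps the PheCodes with at least \code{min_seed_size} seed codes present.
#' Each surviving PheCode becomes one guided topic; topics are ordered by
#' PheCode identifier so the topic index is reproducible.
#'
#' @param map data frame as returned by \code{\link{read_phecode_map}}, or a
#'   path to such a file.
#' @param corpus a \code{\link{sage_corpus}} (filtered vocabulary).
#' @param min_seed_size minimum number of in-vocabulary seed codes per topic
#'   (default 1).
#' @return object of class \code{"sage_seedmap"} with \code{topics} (PheCode
#'   ids), \code{labels}, \code{seed_sets} (list of guided-vocab index
#'   vectors), \code{exclusions} (list of numeric range matrices),
#'   \code{icd_to_phecode} (data frame) and \code{n_unmatched}, the count of
#'   mapping rows whose ICD code is absent from the vocabulary.
#' @export
build_seed_map <- function(map, corpus, min_seed_size = 1) {
  if (is.character(map)) map <- read_phecode_map(map)
  map$icd <- normalize_code(map$icd)
  vocab <- corpus$vocab[[corpus$guided]]
  present <- map$icd %in% vocab
  n_unmatched <- sum(!present)
  m <- map[present, , drop = FALSE]
  m <- m[!duplicated(m[c("icd", "phecode")]), , drop = FALSE]
  sizes <- table(m$phecode)
  keep <- names(sizes)[sizes >= min_seed_size]
  if (length(keep) == 0L) {
    stop("no PheCode retains >= ", min_seed_size, " seed codes in the vocabulary")
  }
  topics <- sort(keep)
  seed_sets <- lapply(topics, function(k) sort(match(m$icd[m$phecode == k], vocab)))
  labels <- vapply(topics, function(k) m$label[m$phecode == k][1L], character(1))
  excl <- lapply(topics, function(k) {
    s <- m$excl_phecodes[m$phecode == k]
    .parse_excl_ranges(s[nzchar(s)][1L] %||% "")
  })
  structure(list(
    topics = topics, labels = unname(labels),
    seed_sets = stats::setNames(seed_sets, topics),
    exclusions = stats::setNames(excl, topics),
    icd_to_phecode = m[c("icd", "phecode")],
    guided_vocab = vocab, n_unmatched = n_unmatched
  ), class = "sage_seedmap")
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L) return(b)
  if (length(a) == 1L && is.na(a)) return(b)
  a
}

#' @export
print.sage_seedmap <- function(x, ...) {
  sz <- lengths(x$seed_sets)
  cat("PheCode seed map:", length(x$topics), "topics over",
      length(x$guided_vocab), "guided codes\n")
  cat(sprintf("  seed-set sizes: min %d, median %.0f, max %d; %d unmatched map rows\n",
              min(sz), stats::median(sz), max(sz), x$n_unmatched))
  invisible(x)
}

#' Patient-by-PheCode seed count matrix
#'
#' Entry (d, k) is the total guided-modality count of patient d over topic
#' k's seed codes — the raw material for the mixture-model topic priors.
#'
#' @param corpus a \code{sage_corpus}.
#' @param seeds a \code{sage_seedmap}.
#' @return dense numeric matrix, patients x PheCodes.
#' @export
phecode_count_matrix <- function(corpus, seeds) {
  g <- corpus$counts[[corpus$guided]]
  K <- length(seeds$topics)
  ind <- Matrix::sparseMatrix(
    i = unlist(seeds$seed_sets, use.names = FALSE),
    j = rep.int(seq_len(K), lengths(seeds$seed_sets)),
    x = 1, dims = c(ncol(g), K))
  out <- as.matrix(g %*% ind)
  dimnames(out) <- list(corpus$patients, seeds$topics)
  out
}

#' Does a PheCode fall in a topic's control-exclusion ranges?
#'
#' @param phecode character or numeric PheCode identifier(s).
#' @param ranges 2-column numeric matrix of inclusive ranges, as stored in a
#'   seed map's \code{exclusions}.
#' @return logical vector.
#' @export
phecode_in_exclusion <- function(phecode, ranges) {
  p <- suppressWarnings(as.numeric(phecode))
  vapply(p, function(v) {
    if (is.na(v) || nrow(ranges) == 0L) return(FALSE)
    any(v >= ranges[, 1L] & v <= ranges[, 2L])
  }, logical(1))
}
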