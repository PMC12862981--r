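#' Normalize an EHR code string
#'
#' Codes are uppercased and dots are removed so that dialect variants such as
#' \code{"E11.3"} and \code{"E113"} collapse to one vocabulary entry and join
#' reliably against PheCode maps. Applied uniformly across modalities
#' (medication/ATC codes contain no dots, so the rule is a no-op there).
#'
#' @param x character vector of raw codes.
#' @return character vector of normalized codes.
#' @export
normalize_code <- function(x) {
  gsub(".", "", toupper(trimws(as.character(x))), fixed = TRUE)
}

#' Construct a multi-modal EHR corpus
#'
#' A corpus holds one sparse patient-by-code count matrix per modality, with a
#' shared, ordered patient axis. Exactly one modality is flagged as the
#' guided modality (the one whose codes are anchored to PheCode seed sets,
#' typically ICD diagnoses).
#'
#' @param counts named list of sparse (or dense) non-negative integer
#'   matrices, one per modality, each \code{D x V_m} with patient row names
#'   and code column names.
#' @param guided name of the guided modality (must be in
#'   \code{names(counts)}).
#' @return an object of class \code{"sage_corpus"} with elements
#'   \code{patients}, \code{modalities}, \code{guided}, \code{counts}
#'   (list of \code{dgCMatrix}), \code{vocab} (list of character vectors) and
#'   \code{doc_length} (total tokens per patient across modalities).
#' @export
sage_corpus <- function(counts, guided) {
  stopifnot(is.list(counts), length(counts) >= 1L, !is.null(names(counts)))
  if (!guided %in% names(counts)) {
    stop("guided modality '", guided, "' not among modalities: ",
         paste(names(counts), collapse = ", "))
  }
  patients <- rownames(counts[[1L]])
  if (is.null(patients)) stop("count matrices must carry patient row names")
  counts <- lapply(counts, function(m) {
    m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"), "dMatrix")
    if (any(m@x < 0)) stop("negative counts are not allowed")
    if (any(m@x != round(m@x))) stop("counts must be integers")
    if (!identical(rownames(m), patients)) stop("patient axes differ across modalities")
    if (anyDuplicated(colnames(m))) stop("duplicate vocabulary entries within a modality")
    m
  })
  doc_length <- Reduce(`+`, lapply(counts, Matrix::rowSums))
  structure(list(
    patients   = patients,
    modalities = names(counts),
    guided     = guided,
    counts     = counts,
    vocab      = lapply(counts, colnames),
    doc_length = as.numeric(doc_length),
    empty      = doc_length == 0
  ), class = "sage_corpus")
}

#' @export
print.sage_corpus <- function(x, ...) {
  cat("Multi-modal EHR corpus:", length(x$patients), "patients,",
      length(x$modalities), "modalities\n")
  for (m in x$modalities) {
    tag <- if (m == x$guided) " (guided)" else ""
    cat(sprintf("  %s%s: %d codes, %.0f tokens\n", m, tag,
                length(x$vocab[[m]]), sum(x$counts[[m]])))
  }
  cat(sprintf("  tokens per patient: median %.0f, %d empty patients\n",
              stats::median(x$doc_length), sum(x$empty)))
  invisible(x)
}

# guess the field separator from the header line
.guess_sep <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  hdr <- readLines(con, n = 1L)
  if (length(hdr) == 0L) return("\t")
  if (grepl("\t", hdr)) "\t" else ","
}

#' Read a long-format multi-modal EHR corpus
#'
#' Expects delimited text (tab or comma, gzip transparently supported) with
#' one row per (patient, modality, code, count); the count column is optional
#' and defaults to 1. Duplicate (patient, modality, code) rows are summed
#' after code normalization, and patient and vocabulary orderings are
#' lexicographic, so two loads of the same file yield identical indices.
#'
#' @param path path to the delimited file.
#' @param modalities character vector of expected modality names; rows with
#'   any other modality are rejected (with offending row numbers).
#' @param guided name of the guided modality.
#' @param schema named list mapping roles \code{patient}, \code{modality},
#'   \code{code}, \code{count} to column names in the file.
#' @param sep field separator; \code{NULL} (default) auto-detects tab vs
#'   comma from the header.
#' @return a \code{\link{sage_corpus}}.
#' @export
read_sage_corpus <- function(path, modalities, guided,
                             schema = list(patient = "patient_id",
                                           modality = "modality",
                                           code = "code",
                                           count = "count"),
                             sep = NULL) {
  if (is.null(sep)) sep <- .guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (nrow(df) == 0L) stop("empty corpus file: ", path)
  need <- c(schema$patient, schema$modality, schema$code)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cnt <- if (!is.null(schema$count) && schema$count %in% names(df)) {
    as.numeric(df[[schema$count]])
  } else rep(1, nrow(df))
  if (anyNA(cnt)) stop("non-numeric counts at rows: ",
                       paste(utils::head(which(is.na(cnt)), 5), collapse = ", "))
  if (any(cnt < 0)) stop("negative counts at rows: ",
                         paste(utils::head(which(cnt < 0), 5), collapse = ", "))
  mod <- df[[schema$modality]]
  bad <- which(!mod %in% modalities)
  if (length(bad)) stop("unknown modality '", mod[bad[1L]], "' at rows: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  pat <- df[[schema$patient]]
  code <- normalize_code(df[[schema$code]])
  patients <- sort(unique(pat))
  mats <- lapply(modalities, function(m) {
    keep <- mod == m
    vocab <- sort(unique(code[keep]))
    if (length(vocab) == 0L) {
      return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                  dims = c(length(patients), 0L),
                                  dimnames = list(patients, character())))
    }
    Matrix::sparseMatrix(
      i = match(pat[keep], patients), j = match(code[keep], vocab),
      x = cnt[keep], dims = c(length(patients), length(vocab)),
      dimnames = list(patients, vocab))  # duplicate triplets are summed
  })
  names(mats) <- modalities
  sage_corpus(mats, guided = guided)
}

#' Write a corpus in long format
#'
#' Inverse of \code{\link{read_sage_corpus}}: one row per
#' (patient, modality, code, count), tab-delimited, count > 0 rows only.
#'
#' @param corpus a \code{sage_corpus}.
#' @param path output path (\code{.gz} suffix writes gzip).
#' @export
write_sage_corpus <- function(corpus, path) {
  rows <- lapply(corpus$modalities, function(m) {
    tm <- methods::as(corpus$counts[[m]], "TsparseMatrix")
    if (length(tm@x) == 0L) return(NULL)
    data.frame(patient_id = corpus$patients[tm@i + 1L], modality = m,
               code = corpus$vocab[[m]][tm@j + 1L], count = tm@x,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$patient_id, df$modality, df$code), , drop = FALSE]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a corpus as a MatrixMarket bundle
#'
#' Writes one MTX sparse matrix per modality plus plain-text vocabulary and
#' patient index files, and a small manifest naming the guided modality.
#'
#' @param corpus a \code{sage_corpus}.
#' @param dir output directory (created if absent).
#' @export
write_corpus_bundle <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(corpus$patients, file.path(dir, "patients.txt"))
  for (m in corpus$modalities) {
    Matrix::writeMM(corpus$counts[[m]], file.path(dir, paste0("counts_", m, ".mtx")))
    writeLines(corpus$vocab[[m]], file.path(dir, paste0("vocab_", m, ".txt")))
  }
  writeLines(c(paste0("modalities: ", paste(corpus$modalities, collapse = ",")),
               paste0("guided: ", corpus$guided)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a corpus written by \code{\link{write_corpus_bundle}}
#' @param dir bundle directory.
#' @return a \code{sage_corpus}.
#' @export
read_corpus_bundle <- function(dir) {
  man <- readLines(file.path(dir, "manifest.txt"))
  modalities <- strsplit(sub("^modalities: ", "", man[1L]), ",")[[1L]]
  guided <- sub("^guided: ", "", man[2L])
  patients <- readLines(file.path(dir, "patients.txt"))
  mats <- lapply(modalities, function(m) {
    mat <- methods::as(Matrix::readMM(file.path(dir, paste0("counts_", m, ".mtx"))),
                       "CsparseMatrix")
    dimnames(mat) <- list(patients,
                          readLines(file.path(dir, paste0("vocab_", m, ".txt"))))
    mat
  })
  names(mats) <- modalities
  sage_corpus(mats, guided = guided)
}

#' Drop rare codes from a corpus
#'
#' Codes whose corpus-wide total count falls below \code{min_occurrences} are
#' removed from the vocabulary. Patients left with zero tokens are retained
#' (flagged in \code{$empty}) so downstream score matrices keep a fixed
#' patient axis; such patients receive prior-only inferences.
#'
#' @param corpus a \code{sage_corpus}.
#' @param min_occurrences non-negative integer threshold; codes with total
#'   count \code{< min_occurrences} are dropped (default 10).
#' @return the filtered \code{sage_corpus}.
#' @export
filter_vocabulary <- function(corpus, min_occurrences = 10) {
  stopifnot(min_occurrences >= 0)
  mats <- lapply(corpus$counts, function(m) {
    m[, Matrix::colSums(m) >= min_occurrences, drop = FALSE]
  })
  sage_corpus(mats, guided = corpus$guided)
}

#' Split dated diagnosis events into prevalent and incident indicators
#'
#' An event maps to PheCodes through the seed map's ICD-to-PheCode relation.
#' A (patient, PheCode) pair is \emph{prevalent} when any mapped event falls
#' strictly before the patient's baseline date, and \emph{incident} when no
#' such prior record exists and at least one mapped event falls on or after
#' baseline (half-open convention: the baseline day itself counts as
#' incident). Prevalent and incident are therefore mutually exclusive.
#'
#' @param events data frame with columns \code{patient_id}, \code{code}
#'   (raw ICD, normalized internally) and \code{date} (parseable as
#'   \code{Date}).
#' @param baseline data frame with columns \code{patient_id} and
#'   \code{baseline_date}, or a named \code{Date}/character vector.
#' @param seeds a \code{\link{build_seed_map}} result supplying the
#'   ICD-to-PheCode relation and topic order.
#' @param patients optional character vector fixing the patient axis
#'   (defaults to patients present in \code{baseline}).
#' @return list with logical patient-by-PheCode matrices \code{prevalent} and
#'   \code{incident}, plus \code{n_dropped}: events for patients lacking a
#'   baseline date (those patients are excluded with a warning).
#' @export
split_events <- function(events, baseline, seeds, patients = NULL) {
  if (is.data.frame(baseline)) {
    bl <- as.Date(baseline$baseline_date)
    names(bl) <- as.character(baseline$patient_id)
  } else {
    bl <- as.Date(baseline)
    names(bl) <- names(baseline)
  }
  if (is.null(patients)) patients <- sort(names(bl))
  ev <- data.frame(patient = as.character(events$patient_id),
                   code = normalize_code(events$code),
                   date = as.Date(events$date), stringsAsFactors = FALSE)
  no_bl <- !(ev$patient %in% names(bl))
  n_dropped <- sum(no_bl)
  if (n_dropped > 0L) {
    warning(n_dropped, " events dropped: patients without a baseline date")
    ev <- ev[!no_bl, , drop = FALSE]
  }
  K <- length(seeds$topics)
  prevalent <- matrix(FALSE, length(patients), K,
                      dimnames = list(patients, seeds$topics))
  incident <- prevalent
  map <- seeds$icd_to_phecode
  hit <- merge(ev, map, by.x = "code", by.y = "icd")
  hit <- hit[hit$patient %in% patients & hit$phecode %in% seeds$topics, , drop = FALSE]
  if (nrow(hit)) {
    before <- hit$date < bl[hit$patient]
    idx <- cbind(match(hit$patient, patients), match(hit$phecode, seeds$topics))
    prevalent[idx[before, , drop = FALSE]] <- TRUE
    incident[idx[!before, , drop = FALSE]] <- TRUE
    incident[prevalent] <- FALSE  # prior record voids incidence
  }
  list(prevalent = prevalent, incident = incident, n_dropped = n_dropped)
}
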