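# ICD-10 organ-system chapters: letter + numeric range, inclusive.
.icd10_chapters <- data.frame(
  letter = c("A", "B", "C", "D", "D", "E", "F", "G", "H", "H", "I", "J",
             "K", "L", "M", "N", "O", "P", "Q", "R", "S", "T", "V", "W",
             "X", "Y", "Z", "U"),
  lo = c(0, 0, 0, 0, 50, 0, 0, 0, 0, 60, 0, 0,
         0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
         0, 0, 0, 0),
  hi = c(99, 99, 97, 48, 89, 90, 99, 99, 59, 95, 99, 99,
         93, 99, 99, 99, 99, 96, 99, 99, 99, 98, 99, 99,
         99, 98, 99, 99),
  chapter = c("I", "I", "II", "II", "III", "IV", "V", "VI", "VII", "VIII",
              "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII",
              "XVIII", "XIX", "XIX", "XX", "XX", "XX", "XX", "XXI", "XXII"),
  stringsAsFactors = FALSE)

#' ICD-10 organ-system chapter of a code
#'
#' Maps normalized ICD-10 codes to their chapter (Roman numeral) from the
#' first letter and the two-digit numeric block, e.g. \code{"E11"} ->
#' chapter IV (endocrine), \code{"C91"} -> chapter II (neoplasms). Codes
#' that do not parse return \code{NA}.
#'
#' @param codes character vector of ICD-10 codes (dots optional).
#' @return character vector of chapter labels.
#' @export
icd10_chapter <- function(codes) {
  codes <- normalize_code(codes)
  letter <- substr(codes, 1, 1)
  num <- suppressWarnings(as.numeric(substr(codes, 2, 3)))
  out <- rep(NA_character_, length(codes))
  ok <- which(letter %in% .icd10_chapters$letter & !is.na(num))
  for (i in ok) {
    hit <- .icd10_chapters$letter == letter[i] &
      num[i] >= .icd10_chapters$lo & num[i] <= .icd10_chapters$hi
    if (any(hit)) out[i] <- .icd10_chapters$chapter[which(hit)[1L]]
  }
  out
}

#' Topic purity over top-ranked codes
#'
#' For each topic, takes the \code{n_top} highest-probability codes
#' (deterministic tie-break by vocabulary order) and computes the share
#' belonging to the modal chapter; codes without a chapter label are
#' excluded from the denominator (and counted). Purity of 1 means every top
#' code comes from one organ system.
#'
#' @param phi topics x codes probability matrix (column names = codes).
#' @param chapter_of function mapping codes to chapter labels
#'   (default \code{\link{icd10_chapter}}), or a named character vector.
#' @param n_top number of top codes per topic (default 5).
#' @param thresholds purity thresholds to summarize over.
#' @return list of class \code{"sage_purity"}: \code{per_topic} data frame
#'   (topic, dominant chapter, purity, n_labelled, top codes), \code{mean}
#'   purity and \code{frac_at_least} per threshold.
#' @export
topic_purity <- function(phi, chapter_of = icd10_chapter, n_top = 5L,
                         thresholds = c(0.6, 0.9)) {
  if (n_top < 1) stop("n_top must be >= 1")
  vocab <- colnames(phi)
  chap <- if (is.function(chapter_of)) chapter_of(vocab) else
    unname(chapter_of[vocab])
  per <- lapply(seq_len(nrow(phi)), function(k) {
    ord <- order(-phi[k, ], seq_along(vocab))[seq_len(min(n_top, length(vocab)))]
    ch <- chap[ord]
    lab <- ch[!is.na(ch)]
    if (length(lab) == 0L) {
      return(data.frame(topic = rownames(phi)[k] %||% as.character(k),
                        dominant = NA_character_, purity = NA_real_,
                        n_labelled = 0L,
                        top_codes = paste(vocab[ord], collapse = ",")))
    }
    tab <- sort(table(lab), decreasing = TRUE)
    data.frame(topic = rownames(phi)[k] %||% as.character(k),
               dominant = names(tab)[1L],
               purity = as.numeric(tab[1L]) / length(lab),
               n_labelled = length(lab),
               top_codes = paste(vocab[ord], collapse = ","))
  })
  per <- do.call(rbind, per)
  p <- per$purity[!is.na(per$purity)]
  structure(list(per_topic = per, mean = mean(p),
                 frac_at_least = stats::setNames(
                   vapply(thresholds, function(t) mean(p >= t), numeric(1)),
                   paste0(">=", thresholds)),
                 n_top = n_top),
            class = "sage_purity")
}

#' @export
print.sage_purity <- function(x, ...) {
  cat(sprintf("Topic purity (top-%d codes): mean %.3f over %d topics\n",
              x$n_top, x$mean, nrow(x$per_topic)))
  for (nm in names(x$frac_at_least)) {
    cat(sprintf("  fraction with purity %s: %.2f\n", nm, x$frac_at_least[nm]))
  }
  invisible(x)
}

# Pearson correlation matrix with zero-variance rows mapped to 0 correlation
.cor_safe <- function(mat_rows) {
  sds <- apply(mat_rows, 1, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  out <- matrix(0, nrow(mat_rows), nrow(mat_rows),
                dimnames = list(rownames(mat_rows), rownames(mat_rows)))
  if (any(!zero)) {
    out[!zero, !zero] <- stats::cor(t(mat_rows[!zero, , drop = FALSE]))
  }
  diag(out) <- 1
  attr(out, "zero_variance") <- rownames(mat_rows)[zero]
  out
}

#' Phenotype similarity: correlation between topic-feature distributions
#'
#' Pearson correlation across topics of their feature distributions (rows of
#' phi). Related topics share clinical code patterns. Zero-variance rows are
#' flagged and assigned correlation 0 off-diagonal.
#'
#' @param phi topics x codes matrix.
#' @param n_top neighbors reported per topic.
#' @return symmetric K x K correlation matrix with unit diagonal; attributes
#'   \code{"zero_variance"} and \code{"neighbors"} (top-\code{n_top} most
#'   similar topics per topic).
#' @export
topic_similarity <- function(phi, n_top = 5L) {
  stopifnot(nrow(phi) >= 2)
  out <- .cor_safe(phi)
  attr(out, "neighbors") <- .top_neighbors(out, n_top)
  out
}

#' Phenotype comorbidity: correlation between patient topic loadings
#'
#' Pearson correlation across topics of patients' mixture weights (columns
#' of theta). Topics loading on the same patients co-occur as comorbidities.
#'
#' @param theta patients x topics matrix.
#' @param n_top neighbors reported per topic.
#' @return symmetric K x K correlation matrix as in
#'   \code{\link{topic_similarity}}.
#' @export
topic_comorbidity <- function(theta, n_top = 5L) {
  stopifnot(ncol(theta) >= 2)
  out <- .cor_safe(t(theta))
  attr(out, "neighbors") <- .top_neighbors(out, n_top)
  out
}

.top_neighbors <- function(cm, n_top) {
  lapply(stats::setNames(seq_len(nrow(cm)), rownames(cm)), function(k) {
    v <- cm[k, ]
    v[k] <- -Inf
    ord <- order(-v, seq_along(v))[seq_len(min(n_top, length(v) - 1L))]
    stats::setNames(cm[k, ord], colnames(cm)[ord])
  })
}

#' Precision at K for incident-diagnosis ranking
#'
#' Patients are ranked by a risk score for one target PheCode; precision at
#' K is the share of incident cases among the top-K eligible patients. The
#' eligible pool removes prevalent cases of the target (they cannot become
#' incident) and removes non-cases carrying any control-exclusion PheCode.
#' Ties in risk break deterministically by patient index. The random
#' baseline reported alongside is the incident prevalence in the eligible
#' pool.
#'
#' @param risk numeric risk vector (e.g. a column of theta or of calibrated
#'   scores).
#' @param incident logical/0-1 vector: incident case for the target.
#' @param prevalent logical/0-1 vector: prevalent case for the target.
#' @param excluded logical vector: carries a control-exclusion PheCode
#'   (defaults to none); exclusion removes non-cases only.
#' @param k_values K sweep (default 10..100 by 10).
#' @return data frame with columns \code{k}, \code{n_cases_top},
#'   \code{precision}, \code{baseline}; attribute \code{"pool_size"}.
#' @export
precision_at_k <- function(risk, incident, prevalent,
                           excluded = NULL, k_values = seq(10L, 100L, 10L)) {
  n <- length(risk)
  incident <- as.logical(incident)
  prevalent <- as.logical(prevalent)
  if (is.null(excluded)) excluded <- rep(FALSE, n)
  eligible <- !prevalent & (incident | !as.logical(excluded))
  r <- risk[eligible]
  inc <- incident[eligible]
  ord <- order(-r, seq_along(r))
  pool <- length(r)
  if (length(k_values) == 0L || max(k_values) > pool) {
    warning("eligible pool (", pool, ") smaller than max K; truncating")
    k_values <- k_values[k_values <= pool]
  }
  if (length(k_values) == 0L) {
    out <- data.frame(k = integer(), n_cases_top = numeric(),
                      precision = numeric(), baseline = numeric())
    attr(out, "pool_size") <- pool
    return(out)
  }
  cum <- cumsum(inc[ord])
  out <- data.frame(k = k_values,
                    n_cases_top = cum[k_values],
                    precision = cum[k_values] / k_values,
                    baseline = mean(inc))
  attr(out, "pool_size") <- pool
  out
}

#' Exclusion mask for a target PheCode
#'
#' Marks patients whose prevalent records include any PheCode inside the
#' target topic's control-exclusion ranges (other than the target itself),
#' for use as \code{excluded} in \code{\link{precision_at_k}}.
#'
#' @param prevalent patients x PheCodes logical matrix (from
#'   \code{\link{split_events}}).
#' @param seeds a \code{sage_seedmap}.
#' @param target target PheCode identifier.
#' @return logical vector over patients.
#' @export
exclusion_mask <- function(prevalent, seeds, target) {
  ranges <- seeds$exclusions[[as.character(target)]]
  if (is.null(ranges) || nrow(ranges) == 0L) {
    return(rep(FALSE, nrow(prevalent)))
  }
  in_range <- phecode_in_exclusion(colnames(prevalent), ranges) &
    colnames(prevalent) != as.character(target)
  if (!any(in_range)) return(rep(FALSE, nrow(prevalent)))
  rowSums(prevalent[, in_range, drop = FALSE]) > 0
}
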