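# Shared in-code fixtures: tiny corpora, seed maps and metrics.

# Build a corpus from long triplets without touching the file readers.
mk_corpus <- function(patient, modality, code, count, guided = "ICD") {
  df <- data.frame(patient = patient, modality = modality,
                   code = sagehr::normalize_code(code), count = count,
                   stringsAsFactors = FALSE)
  patients <- sort(unique(df$patient))
  mods <- unique(df$modality)
  mats <- lapply(mods, function(m) {
    sub <- df[df$modality == m, , drop = FALSE]
    vocab <- sort(unique(sub$code))
    Matrix::sparseMatrix(i = match(sub$patient, patients),
                         j = match(sub$code, vocab), x = sub$count,
                         dims = c(length(patients), length(vocab)),
                         dimnames = list(patients, vocab))
  })
  names(mats) <- mods
  sage_corpus(mats, guided = guided)
}

tiny_map <- function() {
  data.frame(icd = c("E110", "E113", "C911"),
             phecode = c("250.2", "250.2", "204.1"),
             label = c("T2D", "T2D", "Leukemia"),
             excl_phecodes = c("250-250.99", "250-250.99", "204-204.99"),
             stringsAsFactors = FALSE)
}

tiny_guided_corpus <- function() {
  mk_corpus(
    patient = c("p1", "p1", "p1", "p2", "p2", "p3"),
    modality = c("ICD", "ICD", "MED", "ICD", "MED", "ICD"),
    code = c("E110", "E113", "A10BA02", "C911", "A10BB09", "E119"),
    count = c(2, 3, 1, 4, 2, 1))
}

# Rank-based AUROC (probability a case outranks a control).
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (sum(r[as.logical(label)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Mixture (pi-weighted) guided topic-word matrix from a fit and from truth.
mixture_phi <- function(fit) {
  tp <- expected_topics(fit$state)
  fit$state$pi * tp$phi_s + (1 - fit$state$pi) * tp$phi_r[[fit$state$guided]]
}

true_mixture_phi <- function(sim) {
  sim$truth$pi * sim$truth$phi_s + (1 - sim$truth$pi) * sim$truth$phi_r[[1L]]
}

# Topic matching by maximal seed-set overlap between estimated and true
# seed sets (identity when the same map was used; kept explicit so tests
# do not silently assume anchoring).
match_by_seed_overlap <- function(fit_seeds, true_seed_sets) {
  vapply(seq_along(fit_seeds$seed_sets), function(k) {
    ov <- vapply(true_seed_sets, function(s)
      length(intersect(fit_seeds$seed_sets[[k]], s)), numeric(1))
    which.max(ov)
  }, integer(1))
}
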