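#' @export
print.sage <- function(x, ...) {
  st <- x$state
  cat("Seed-and-guided multi-modal topic model\n")
  cat(sprintf("  %d patients, %d topics, modalities: %s (guided: %s)\n",
              length(x$patients), st$K,
              paste(st$modalities, collapse = ", "), st$guided))
  cat(sprintf("  beta = %s, mu = %.3g, epochs run = %d\n",
              paste(signif(st$beta, 3), collapse = "/"), st$mu, st$epoch))
  cat(sprintf("  seed rates pi: min %.3f, median %.3f, max %.3f\n",
              min(st$pi), stats::median(st$pi), max(st$pi)))
  if (any(is.finite(x$history$val_nll))) {
    cat(sprintf("  final validation NLL/token: %.5f\n",
                utils::tail(x$history$val_nll[is.finite(x$history$val_nll)], 1)))
  }
  invisible(x)
}

#' @export
summary.sage <- function(object, n_top = 5L, ...) {
  tp <- expected_topics(object$state)
  g <- object$state$guided
  top <- lapply(seq_len(object$state$K), function(k) {
    W <- object$state$pi[k] * tp$phi_s[k, ] +
      (1 - object$state$pi[k]) * tp$phi_r[[g]][k, ]
    names(sort(W, decreasing = TRUE))[seq_len(min(n_top, length(W)))]
  })
  out <- list(model = object,
              topics = data.frame(
                phecode = object$seeds$topics,
                label = object$seeds$labels,
                pi = unname(object$state$pi),
                seed_size = unname(lengths(object$seeds$seed_sets)),
                mean_theta = colMeans(object$theta),
                top_codes = vapply(top, paste, character(1), collapse = ","),
                row.names = NULL),
              history = object$history)
  class(out) <- "summary.sage"
  out
}

#' @export
print.summary.sage <- function(x, ...) {
  print(x$model)
  cat("\nTop guided-modality codes per topic:\n")
  print(utils::head(x$topics, 10), right = FALSE)
  if (nrow(x$topics) > 10) cat("  ... and", nrow(x$topics) - 10, "more topics\n")
  invisible(x)
}

#' Extract topic-word distributions
#'
#' \code{coef} on a fitted model returns the expected topic distributions:
#' regular topics per modality, seed topics, and seed rates.
#'
#' @param object a fitted \code{sage} model.
#' @param ... unused.
#' @return the \code{\link{expected_topics}} list.
#' @export
coef.sage <- function(object, ...) expected_topics(object$state)

#' Predict from a fitted guided topic model
#'
#' \code{type = "topics"} folds in the patients of \code{newdata} under
#' frozen global statistics and returns their posterior topic mixtures
#' (\code{\link{infer_theta}}); \code{type = "icd"} additionally maps
#' mixtures through the per-topic marginal word distribution to expected
#' guided-code probabilities (\code{\link{expected_icd_matrix}}).
#'
#' @param object fitted \code{sage}.
#' @param newdata a \code{sage_corpus}; defaults to the training corpus's
#'   stored theta when omitted.
#' @param prior prior matrix (or \code{sage_prior}) for the new patients.
#' @param type \code{"topics"} or \code{"icd"}.
#' @param n_inner fold-in sweeps.
#' @param ... unused.
#' @return a patients-by-topics or patients-by-codes matrix.
#' @export
predict.sage <- function(object, newdata = NULL, prior = NULL,
                         type = c("topics", "icd"), n_inner = 20L, ...) {
  type <- match.arg(type)
  theta <- if (is.null(newdata)) {
    object$theta
  } else {
    if (is.null(prior)) stop("prior required for new patients")
    infer_theta(object$state, newdata, prior, n_inner = n_inner)
  }
  if (type == "topics") return(theta)
  expected_icd_matrix(theta, object$state)
}

#' Serialize a fitted model as a plain-text checkpoint
#'
#' Writes the global statistics (MTX matrices), seed rates, hyperparameters
#' and vocabularies so a fit can be reloaded without any binary artifacts.
#'
#' @param object fitted \code{sage} (or bare \code{sage_state}).
#' @param dir output directory.
#' @export
write_sage_model <- function(object, dir) {
  st <- if (inherits(object, "sage")) object$state else object
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in st$modalities) {
    Matrix::writeMM(Matrix::Matrix(st$n[[m]], sparse = TRUE),
                    file.path(dir, paste0("n_", m, ".mtx")))
    writeLines(st$vocab[[m]], file.path(dir, paste0("vocab_", m, ".txt")))
  }
  Matrix::writeMM(Matrix::Matrix(st$s, sparse = TRUE), file.path(dir, "s.mtx"))
  Matrix::writeMM(Matrix::Matrix(st$smask * 1, sparse = TRUE),
                  file.path(dir, "seed_mask.mtx"))
  writeLines(colnames(st$smask), file.path(dir, "topics.txt"))
  meta <- c(sprintf("version: 1"),
            sprintf("modalities: %s", paste(st$modalities, collapse = ",")),
            sprintf("guided: %s", st$guided),
            sprintf("beta: %s", paste(sprintf("%.17g", st$beta), collapse = ",")),
            sprintf("mu: %.17g", st$mu),
            sprintf("pi_a: %.17g", st$pi_a), sprintf("pi_b: %.17g", st$pi_b),
            sprintf("epoch: %d", st$epoch), sprintf("rng_seed: %d", st$rng_seed),
            sprintf("pi: %s", paste(sprintf("%.17g", st$pi), collapse = ",")))
  writeLines(meta, file.path(dir, "model_meta.txt"))
  invisible(dir)
}

#' Reload a checkpoint written by \code{\link{write_sage_model}}
#' @param dir checkpoint directory.
#' @return a \code{sage_state}.
#' @export
read_sage_model <- function(dir) {
  meta <- readLines(file.path(dir, "model_meta.txt"))
  gv <- function(key) sub(paste0("^", key, ": "), "",
                          grep(paste0("^", key, ": "), meta, value = TRUE))
  modalities <- strsplit(gv("modalities"), ",")[[1L]]
  topics <- readLines(file.path(dir, "topics.txt"))
  vocab <- lapply(modalities, function(m)
    readLines(file.path(dir, paste0("vocab_", m, ".txt"))))
  names(vocab) <- modalities
  n <- lapply(modalities, function(m) {
    x <- as.matrix(Matrix::readMM(file.path(dir, paste0("n_", m, ".mtx"))))
    dimnames(x) <- list(vocab[[m]], topics)
    x
  })
  names(n) <- modalities
  guided <- gv("guided")
  s <- as.matrix(Matrix::readMM(file.path(dir, "s.mtx")))
  smask <- as.matrix(Matrix::readMM(file.path(dir, "seed_mask.mtx"))) > 0
  dimnames(s) <- dimnames(smask) <- list(vocab[[guided]], topics)
  structure(list(
    n = n, n_col = lapply(n, colSums), s = s, s_col = colSums(s),
    pi = stats::setNames(as.numeric(strsplit(gv("pi"), ",")[[1L]]), topics),
    smask = smask, Vk = colSums(smask),
    beta = stats::setNames(as.numeric(strsplit(gv("beta"), ",")[[1L]]), modalities),
    mu = as.numeric(gv("mu")), pi_a = as.numeric(gv("pi_a")),
    pi_b = as.numeric(gv("pi_b")), K = length(topics), guided = guided,
    modalities = modalities, vocab = vocab,
    epoch = as.integer(gv("epoch")), rng_seed = as.integer(gv("rng_seed"))
  ), class = "sage_state")
}
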