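#' Expected patient-by-code probability matrix
#'
#' Multiplies the patient topic mixtures by the model's marginal word
#' distribution per topic. For the guided modality the marginal mixes the
#' seed and regular distributions with the seed rate:
#' \code{phi[k, j] = pi_k phi_s[k, j] + (1 - pi_k) phi_r[k, j]}
#' (the \code{"regular"} choice uses \code{phi_r} alone). Rows sum to 1 over
#' the guided vocabulary.
#'
#' @param theta patients x topics mixture matrix.
#' @param state a \code{sage_state} or fitted \code{sage}.
#' @param mixture \code{"pi_weighted"} (default) or \code{"regular"}.
#' @return patients x guided-codes matrix of probabilities.
#' @export
expected_icd_matrix <- function(theta, state,
                                mixture = c("pi_weighted", "regular")) {
  mixture <- match.arg(mixture)
  if (inherits(state, "sage")) state <- state$state
  stopifnot(ncol(theta) == state$K)
  tp <- expected_topics(state)
  W <- if (mixture == "pi_weighted") {
    state$pi * tp$phi_s + (1 - state$pi) * tp$phi_r[[state$guided]]
  } else {
    tp$phi_r[[state$guided]]
  }
  out <- theta %*% W
  dimnames(out) <- list(rownames(theta), state$vocab[[state$guided]])
  out
}

# Intercept-only 1-D Newton at a fixed slope.
.refit_intercept <- function(y, off, b0) {
  for (j in 1:50) {
    p0 <- stats::plogis(b0 + off)
    step <- sum(y - p0) / sum(pmax(p0 * (1 - p0), 1e-10))
    b0 <- b0 + step
    if (abs(step) < 1e-10) break
  }
  b0
}

# One-feature logistic regression by iteratively reweighted least squares,
# with step-halving on the log-likelihood. In one dimension the data are
# linearly separable exactly when the case and control feature ranges do not
# overlap; the MLE slope then diverges, so it is clamped at +/- cap (with the
# intercept refit at the clamped slope) and flagged unconverged.
.irls_logistic <- function(y, x, max_iter = 200L, tol = 1e-12, cap = 30) {
  separable <- max(x[y == 0]) < min(x[y == 1]) ||
    max(x[y == 1]) < min(x[y == 0])
  if (separable) {
    sl <- cap * sign(mean(x[y == 1]) - mean(x[y == 0]))
    b0 <- .refit_intercept(y, x * sl, stats::qlogis(mean(y)))
    return(list(intercept = b0, slope = sl, converged = FALSE))
  }
  b <- c(stats::qlogis(mean(y)), 0)
  X <- cbind(1, x)
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(pmin(eta, 700))))
  }
  ll_old <- ll(b)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    wt <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / wt
    XtW <- t(X * wt)
    bn <- tryCatch(drop(solve(XtW %*% X, XtW %*% z)), error = function(e) b)
    # step-halving keeps extreme but non-separable fits stable
    step <- bn - b
    ll_new <- ll(bn)
    h <- 0L
    while (ll_new < ll_old && h < 30L) {
      step <- step / 2
      bn <- b + step
      ll_new <- ll(bn)
      h <- h + 1L
    }
    if (sum(abs(bn - b)) < tol * (1 + sum(abs(b)))) {
      b <- bn
      converged <- TRUE
      break
    }
    b <- bn
    ll_old <- ll_new
  }
  list(intercept = unname(b[1L]), slope = unname(b[2L]),
       converged = converged)
}

#' Calibrate one code's inferred probabilities against its observed status
#'
#' Fits a one-feature logistic regression of the observed binary code
#' indicator on the model-inferred probability, by IRLS on the cross-entropy
#' loss, and returns the rescaled probabilities
#' \code{yhat = plogis(slope * ytilde + intercept)}. The rescaling lifts the
#' inferred probabilities (tiny, because they come from a Dirichlet over
#' 1000+ phenotypes) onto the observed prevalence scale while preserving
#' patient ranking whenever the slope is positive. Constant responses are
#' flagged and passed through uncalibrated; separable fits are capped at
#' \code{|slope| <= 30} and flagged unconverged.
#'
#' @param y binary response vector (observed code presence).
#' @param y_tilde inferred probability vector.
#' @param cap slope magnitude cap.
#' @return list with \code{slope}, \code{intercept}, \code{converged},
#'   \code{cases} and the calibrated \code{yhat}.
#' @export
calibrate_code <- function(y, y_tilde, cap = 30) {
  stopifnot(length(y) == length(y_tilde), all(y %in% c(0, 1)),
            all(is.finite(y_tilde)))
  cases <- sum(y)
  if (cases == 0L || cases == length(y)) {
    return(list(slope = NA_real_, intercept = NA_real_, converged = FALSE,
                cases = cases, yhat = y_tilde))
  }
  f <- .irls_logistic(y, y_tilde, cap = cap)
  list(slope = f$slope, intercept = f$intercept, converged = f$converged,
       cases = cases,
       yhat = stats::plogis(f$slope * y_tilde + f$intercept))
}

#' Calibrate every guided code
#'
#' Applies \code{\link{calibrate_code}} column-wise: response = observed
#' presence of the code in the corpus, feature = the model's expected
#' probability from \code{\link{expected_icd_matrix}}.
#'
#' @param y_obs binary patients x codes matrix (observed code presence), or
#'   a \code{sage_corpus} whose guided counts are binarized internally.
#' @param y_tilde patients x codes inferred probability matrix.
#' @param cap slope cap.
#' @return list with \code{yhat} (calibrated matrix) and \code{model}
#'   (per-code data frame of slope, intercept, converged, cases).
#' @export
calibrate_icd <- function(y_obs, y_tilde, cap = 30) {
  if (inherits(y_obs, "sage_corpus")) {
    y_obs <- as.matrix(y_obs$counts[[y_obs$guided]] > 0) * 1
  }
  y_obs <- as.matrix(y_obs)
  stopifnot(identical(dim(y_obs), dim(y_tilde)))
  yhat <- y_tilde
  mods <- vector("list", ncol(y_obs))
  for (j in seq_len(ncol(y_obs))) {
    f <- calibrate_code(y_obs[, j], y_tilde[, j], cap = cap)
    yhat[, j] <- f$yhat
    mods[[j]] <- data.frame(code = colnames(y_obs)[j] %||% as.character(j),
                            slope = f$slope, intercept = f$intercept,
                            converged = f$converged, cases = f$cases)
  }
  list(yhat = yhat, model = do.call(rbind, mods))
}

#' Aggregate calibrated code probabilities onto PheCodes
#'
#' PheCode semantics are "any constituent diagnosis", so the default
#' noisy-OR rule combines a PheCode's mapped codes as
#' \code{1 - prod(1 - yhat_j)}; \code{"max"} takes the largest constituent
#' probability instead. The expected sample size per PheCode is the column
#' sum of the resulting score matrix.
#'
#' @param y_hat calibrated patients x guided-codes matrix.
#' @param seeds a \code{sage_seedmap}; PheCodes with no mapped in-vocabulary
#'   code are dropped (recorded in \code{dropped_topics}).
#' @param rule \code{"noisy_or"} or \code{"max"}.
#' @return object of class \code{"sage_scores"}: \code{scores} (patients x
#'   PheCodes, in [0, 1]), \code{expected_n} (column sums), \code{rule},
#'   \code{dropped_topics}.
#' @export
aggregate_to_phecodes <- function(y_hat, seeds, rule = c("noisy_or", "max")) {
  rule <- match.arg(rule)
  sets <- seeds$seed_sets
  nonempty <- lengths(sets) > 0
  dropped <- seeds$topics[!nonempty]
  sets <- sets[nonempty]
  scores <- matrix(0, nrow(y_hat), length(sets),
                   dimnames = list(rownames(y_hat), names(sets)))
  for (k in seq_along(sets)) {
    block <- y_hat[, sets[[k]], drop = FALSE]
    scores[, k] <- if (rule == "noisy_or") {
      1 - apply(1 - block, 1, prod)
    } else {
      apply(block, 1, max)
    }
  }
  structure(list(scores = scores, expected_n = colSums(scores),
                 rule = rule, dropped_topics = dropped),
            class = "sage_scores")
}

#' @export
print.sage_scores <- function(x, ...) {
  cat(sprintf("Phenotype scores (%s): %d patients x %d PheCodes\n",
              x$rule, nrow(x$scores), ncol(x$scores)))
  cat(sprintf("  expected sample sizes: min %.1f, median %.1f, max %.1f\n",
              min(x$expected_n), stats::median(x$expected_n),
              max(x$expected_n)))
  if (length(x$dropped_topics)) {
    cat("  dropped (no mapped codes):",
        paste(x$dropped_topics, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Calibrated phenotype scores from a fitted model
#'
#' Convenience wrapper chaining \code{\link{expected_icd_matrix}},
#' \code{\link{calibrate_icd}} against the training corpus's observed codes,
#' and \code{\link{aggregate_to_phecodes}}.
#'
#' @param object fitted \code{sage}.
#' @param corpus the corpus supplying observed code presence (training
#'   corpus by default usage).
#' @param theta mixture matrix (defaults to the fit's theta).
#' @param rule aggregation rule.
#' @param mixture topic-word mixture choice for the expected matrix.
#' @return a \code{sage_scores} with the calibration table attached as
#'   \code{$calibration}.
#' @export
phenotype_scores <- function(object, corpus, theta = object$theta,
                             rule = c("noisy_or", "max"),
                             mixture = c("pi_weighted", "regular")) {
  yt <- expected_icd_matrix(theta, object$state, mixture = match.arg(mixture))
  cal <- calibrate_icd(corpus, yt)
  out <- aggregate_to_phecodes(cal$yhat, object$seeds, rule = match.arg(rule))
  out$calibration <- cal$model
  out
}

#' Export phenotype scores as PLINK-format quantitative traits
#'
#' Writes a whitespace-delimited phenotype file (header \code{FID IID}
#' followed by one column per PheCode passing the expected-sample-size
#' threshold; missing patients coded \code{-9}) plus a column manifest
#' listing included and excluded PheCodes with their expected sample sizes.
#'
#' @param scores a \code{sage_scores}.
#' @param ids data frame with columns \code{FID}, \code{IID} and
#'   \code{patient_id} linking family/individual identifiers to the score
#'   rows; defaults to using patient ids for both.
#' @param path output file path (manifest written to \code{path.manifest}).
#' @param min_expected_n minimum expected sample size for a PheCode column.
#' @param transform \code{"probability"} (default) or \code{"logit"}.
#' @return invisibly, the manifest data frame.
#' @export
export_quantitative_traits <- function(scores, ids = NULL, path,
                                       min_expected_n = 0,
                                       transform = c("probability", "logit")) {
  transform <- match.arg(transform)
  pts <- rownames(scores$scores)
  if (is.null(ids)) {
    ids <- data.frame(FID = pts, IID = pts, patient_id = pts,
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(ids$IID)) stop("duplicate IIDs in id table")
  keep <- scores$expected_n >= min_expected_n
  manifest <- data.frame(phecode = colnames(scores$scores),
                         expected_n = unname(scores$expected_n),
                         included = unname(keep))
  sc <- scores$scores[, keep, drop = FALSE]
  if (transform == "logit") {
    sc <- stats::qlogis(pmin(pmax(sc, 1e-12), 1 - 1e-12))
  }
  ridx <- match(ids$patient_id, pts)
  vals <- matrix(-9, nrow(ids), ncol(sc))
  seen <- !is.na(ridx)
  vals[seen, ] <- sc[ridx[seen], , drop = FALSE]
  cols <- paste0("PHE_", gsub("[^0-9A-Za-z_.]", "_", colnames(sc)))
  df <- data.frame(FID = ids$FID, IID = ids$IID, check.names = FALSE)
  for (j in seq_len(ncol(vals))) df[[cols[j]]] <- sprintf("%.6f", vals[, j])
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  utils::write.table(manifest, paste0(path, ".manifest"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
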