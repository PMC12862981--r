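# Two-component 1-D Gaussian mixture by EM with deterministic
# percentile initialization. Returns responsibilities of the
# larger-mean ("active") component, or NULL on degeneracy.
.gmm2_em <- function(x, max_iter = 500L, tol = 1e-8, var_floor = 1e-6) {
  n <- length(x)
  if (n < 2L || length(unique(x)) < 2L) return(NULL)
  mu <- stats::quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
  if (mu[1L] == mu[2L]) mu <- range(x)
  v <- rep(max(stats::var(x), var_floor), 2L)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- cbind(w[1L] * stats::dnorm(x, mu[1L], sqrt(v[1L])),
                  w[2L] * stats::dnorm(x, mu[2L], sqrt(v[2L])))
    tot <- rowSums(dens)
    if (any(!is.finite(tot)) || any(tot <= 0)) return(NULL)
    r <- dens / tot
    nk <- colSums(r)
    if (any(nk < 1e-10)) return(NULL)  # component collapse
    w <- nk / n
    mu <- colSums(r * x) / nk
    v <- pmax(colSums(r * (outer(x, mu, "-")^2)) / nk, var_floor)
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  active <- which.max(mu)
  list(resp_active = r[, active], means = mu, vars = v, weights = w,
       active = active, iters = it, loglik = ll)
}

#' Fit per-phenotype mixture-model topic priors
#'
#' For each phenotype topic, a two-component Gaussian mixture is fit by EM to
#' the (by default log1p-transformed) per-patient seed counts from
#' \code{\link{phecode_count_matrix}}. The component with the larger mean is
#' interpreted as the "phenotype-active" regime, and the patient-specific
#' Dirichlet prior weight is an affine map of the active-component posterior
#' responsibility:
#' \deqn{\alpha_{dk} = \mathrm{floor} + \mathrm{scale} \cdot P(\mathrm{active} \mid x_{dk}).}
#' Degenerate columns (constant counts, or EM collapse) fall back to the
#' floor value and are flagged. The fit is fully deterministic: EM is
#' initialized from the 10th/90th percentiles, with a variance floor of
#' 1e-6, at most 500 iterations and a 1e-8 log-likelihood tolerance.
#'
#' @param pc_counts patients-by-PheCodes count matrix.
#' @param alpha_scale multiplier on the responsibility (default 1).
#' @param alpha_floor additive floor keeping the Dirichlet proper
#'   (default 0.01).
#' @param transform \code{"log1p"} (default; stabilizes EM on heavy-tailed
#'   counts) or \code{"raw"}.
#' @return object of class \code{"sage_prior"}: \code{alpha} (patients x
#'   topics, all entries positive), \code{fit} (per-topic mixture parameters
#'   and a \code{degenerate} flag), plus the call parameters.
#' @export
fit_gmm_prior <- function(pc_counts, alpha_scale = 1, alpha_floor = 0.01,
                          transform = c("log1p", "raw")) {
  transform <- match.arg(transform)
  pc_counts <- as.matrix(pc_counts)
  if (any(!is.finite(pc_counts))) stop("non-finite PheCode counts")
  if (nrow(pc_counts) < 2L) stop("need at least 2 patients to fit mixtures")
  x_all <- if (transform == "log1p") log1p(pc_counts) else pc_counts
  K <- ncol(pc_counts)
  alpha <- matrix(alpha_floor, nrow(pc_counts), K, dimnames = dimnames(pc_counts))
  fit <- vector("list", K)
  for (k in seq_len(K)) {
    g <- .gmm2_em(x_all[, k])
    if (is.null(g)) {
      fit[[k]] <- list(degenerate = TRUE)
    } else {
      alpha[, k] <- alpha_floor + alpha_scale * g$resp_active
      fit[[k]] <- list(degenerate = FALSE, means = g$means, vars = g$vars,
                       weights = g$weights, active = g$active,
                       iters = g$iters, loglik = g$loglik)
    }
  }
  names(fit) <- colnames(pc_counts)
  structure(list(alpha = alpha, fit = fit, alpha_scale = alpha_scale,
                 alpha_floor = alpha_floor, transform = transform),
            class = "sage_prior")
}

#' @export
print.sage_prior <- function(x, ...) {
  ndeg <- sum(vapply(x$fit, `[[`, logical(1), "degenerate"))
  cat(sprintf("Topic prior: %d patients x %d topics (%s counts), %d degenerate topics\n",
              nrow(x$alpha), ncol(x$alpha), x$transform, ndeg))
  cat(sprintf("  alpha in [%.4g, %.4g] (floor %.3g, scale %.3g)\n",
              min(x$alpha), max(x$alpha), x$alpha_floor, x$alpha_scale))
  invisible(x)
}

#' Serialize a topic prior as MTX plus a metadata sidecar
#' @param prior a \code{sage_prior}.
#' @param dir output directory.
#' @export
write_prior <- function(prior, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(prior$alpha, sparse = TRUE),
                  file.path(dir, "alpha.mtx"))
  writeLines(rownames(prior$alpha), file.path(dir, "patients.txt"))
  writeLines(colnames(prior$alpha), file.path(dir, "topics.txt"))
  meta <- do.call(rbind, lapply(names(prior$fit), function(k) {
    f <- prior$fit[[k]]
    if (f$degenerate) {
      data.frame(topic = k, degenerate = TRUE, mean1 = NA, mean2 = NA,
                 var1 = NA, var2 = NA, w1 = NA, w2 = NA)
    } else {
      data.frame(topic = k, degenerate = FALSE, mean1 = f$means[1L],
                 mean2 = f$means[2L], var1 = f$vars[1L], var2 = f$vars[2L],
                 w1 = f$weights[1L], w2 = f$weights[2L])
    }
  }))
  num <- vapply(meta, is.numeric, logical(1))
  meta[num] <- lapply(meta[num], function(x) {
    ifelse(is.na(x), "NA", sprintf("%.17g", x))
  })
  utils::write.table(meta, file.path(dir, "fit_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
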