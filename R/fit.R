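# ---- internal: flattened corpus representation -------------------------
# The engine works on (doc, modality, code, count) triplets; identical codes
# within a document share one responsibility vector, weighted by count.
.flatten_corpus <- function(corpus) {
  M <- length(corpus$modalities)
  parts <- lapply(seq_len(M), function(mi) {
    tm <- methods::as(corpus$counts[[mi]], "TsparseMatrix")
    list(doc = tm@i + 1L, w = tm@j + 1L, c = tm@x,
         mod = rep.int(mi, length(tm@x)))
  })
  fl <- list(doc = unlist(lapply(parts, `[[`, "doc")),
             w   = unlist(lapply(parts, `[[`, "w")),
             c   = unlist(lapply(parts, `[[`, "c")),
             mod = unlist(lapply(parts, `[[`, "mod")),
             D = length(corpus$patients),
             V = vapply(corpus$counts, ncol, integer(1)),
             M = M, guided = match(corpus$guided, corpus$modalities))
  fl$doc_rows <- split(seq_along(fl$doc),
                       factor(fl$doc, levels = seq_len(fl$D)))
  fl
}

# ---- state ------------------------------------------------------------
#' Initialize global model statistics
#'
#' Builds the global sufficient-statistic container the collapsed variational
#' engine updates: per-modality expected regular-topic counts \code{n}
#' (jittered uniformly in (0, \code{jitter}) to break ties), expected seed
#' counts \code{s} pre-assigned with weight 1 on every (seed code, topic)
#' pair — the informative initialization that anchors each topic to its
#' PheCode — and seed rates \code{pi} at \code{pi_init}.
#'
#' @param corpus a \code{\link{sage_corpus}}.
#' @param seeds a \code{\link{build_seed_map}} result.
#' @param beta regular-topic Dirichlet smoothing (scalar or one value per
#'   modality).
#' @param mu seed-topic Dirichlet smoothing.
#' @param pi_init initial seed-topic rate.
#' @param pi_a,pi_b Beta pseudo-counts smoothing the seed-rate estimate.
#' @param jitter upper bound of the uniform jitter on \code{n}.
#' @param seed integer RNG seed for the jitter.
#' @return a list of class \code{"sage_state"}.
#' @export
sage_init_state <- function(corpus, seeds, beta = 0.1, mu = 0.1,
                            pi_init = 0.7, pi_a = 1, pi_b = 1,
                            jitter = 0.01, seed = 1L) {
  stopifnot(all(beta > 0), mu > 0, pi_a > 0, pi_b > 0,
            pi_init > 0, pi_init < 1)
  M <- length(corpus$modalities)
  K <- length(seeds$topics)
  beta <- rep_len(beta, M)
  names(beta) <- corpus$modalities
  Vg <- length(corpus$vocab[[corpus$guided]])
  smask <- matrix(FALSE, Vg, K, dimnames = list(corpus$vocab[[corpus$guided]],
                                                seeds$topics))
  for (k in seq_len(K)) smask[seeds$seed_sets[[k]], k] <- TRUE
  set.seed(seed)
  n <- lapply(corpus$modalities, function(m) {
    V <- length(corpus$vocab[[m]])
    matrix(stats::runif(V * K, 0, jitter), V, K,
           dimnames = list(corpus$vocab[[m]], seeds$topics))
  })
  names(n) <- corpus$modalities
  s <- smask * 1.0
  structure(list(
    n = n, n_col = lapply(n, colSums), s = s, s_col = colSums(s),
    pi = stats::setNames(rep(pi_init, K), seeds$topics),
    smask = smask, Vk = colSums(smask),
    beta = beta, mu = mu, pi_a = pi_a, pi_b = pi_b,
    K = K, guided = corpus$guided, modalities = corpus$modalities,
    vocab = corpus$vocab, epoch = 0L, rng_seed = seed
  ), class = "sage_state")
}

# Per-row (token-group) likelihood factors under frozen global statistics.
# Returns Lsum (T x K, the x-marginalized word likelihood scaled by the
# seed-rate mixture) and xp (T x K posterior seed-indicator probability;
# zero for unguided rows). xp does not depend on the document counts, so it
# is fixed across CVB0 sweeps of a batch.
.row_likelihoods <- function(fl, rows, state) {
  K <- state$K
  Lsum <- matrix(0, length(rows), K)
  xp <- matrix(0, length(rows), K)
  mod <- fl$mod[rows]
  for (mi in seq_len(fl$M)) {
    sel <- which(mod == mi)
    if (!length(sel)) next
    wsel <- fl$w[rows[sel]]
    nm <- state$n[[mi]]
    denom <- state$n_col[[mi]] + state$beta[mi] * fl$V[mi]
    Pn <- (nm[wsel, , drop = FALSE] + state$beta[mi]) /
      rep(denom, each = length(sel))
    if (mi == fl$guided) {
      sden <- state$s_col + state$mu * state$Vk
      sden[state$Vk == 0] <- 1  # empty seed set: numerator is masked to 0
      Ps <- ((state$s[wsel, , drop = FALSE] + state$mu) *
               state$smask[wsel, , drop = FALSE]) / rep(sden, each = length(sel))
      L1 <- Ps * rep(state$pi, each = length(sel))
      L0 <- Pn * rep(1 - state$pi, each = length(sel))
      tot <- L1 + L0
      Lsum[sel, ] <- tot
      xp[sel, ] <- ifelse(tot > 0, L1 / pmax(tot, 1e-300), 0)
    } else {
      Lsum[sel, ] <- Pn
    }
  }
  list(Lsum = Lsum, xp = xp)
}

# CVB0 sweeps for a batch of documents under frozen global statistics.
# Token responsibilities are updated jointly (all token groups per sweep)
# from m_dk^{-tok} = m_dk - gamma (zeroth-order single-token exclusion).
.cvb0_batch <- function(fl, docs, state, alpha, n_inner,
                        return_gamma = FALSE) {
  K <- state$K
  rows <- unlist(fl$doc_rows[docs], use.names = FALSE)
  B <- length(docs)
  alpha_loc <- alpha[docs, , drop = FALSE]
  if (length(rows) == 0L) {  # all-empty batch: prior-only
    theta <- alpha_loc / rowSums(alpha_loc)
    return(list(docs = docs, m = matrix(0, B, K), theta = theta,
                hat_n = lapply(fl$V, function(v) matrix(0, v, K)),
                hat_s = matrix(0, fl$V[fl$guided], K),
                t_col = numeric(K)))
  }
  did <- match(fl$doc[rows], docs)
  cc <- fl$c[rows]
  lik <- .row_likelihoods(fl, rows, state)
  arow <- alpha_loc[did, , drop = FALSE]
  gamma <- arow / rowSums(arow)
  m <- matrix(0, B, K)
  for (it in seq_len(n_inner)) {
    rs <- rowsum(cc * gamma, did)
    m[] <- 0
    m[as.integer(rownames(rs)), ] <- rs
    A <- m[did, , drop = FALSE] - gamma + arow
    R <- pmax(A * lik$Lsum, 1e-300)
    rtot <- rowSums(R)
    if (any(rtot <= 0) || any(!is.finite(rtot))) {
      stop("degenerate responsibility row; check that alpha, beta, mu > 0")
    }
    gamma <- R / rtot
  }
  rs <- rowsum(cc * gamma, did)
  m[] <- 0
  m[as.integer(rownames(rs)), ] <- rs
  theta <- (m + alpha_loc) / (rowSums(m) + rowSums(alpha_loc))
  # batch sufficient statistics
  hat_n <- vector("list", fl$M)
  hat_s <- matrix(0, fl$V[fl$guided], K)
  t_col <- numeric(K)
  mod <- fl$mod[rows]
  for (mi in seq_len(fl$M)) {
    acc <- matrix(0, fl$V[mi], K)
    sel <- which(mod == mi)
    if (length(sel)) {
      wgt <- cc[sel] * gamma[sel, , drop = FALSE]
      if (mi == fl$guided) {
        t_col <- colSums(wgt)
        ws <- wgt * lik$xp[sel, , drop = FALSE]
        rs <- rowsum(ws, fl$w[rows[sel]])
        hat_s[as.integer(rownames(rs)), ] <- rs
        wgt <- wgt - ws
      }
      rs <- rowsum(wgt, fl$w[rows[sel]])
      acc[as.integer(rownames(rs)), ] <- rs
    }
    hat_n[[mi]] <- acc
  }
  out <- list(docs = docs, m = m, theta = theta, hat_n = hat_n,
              hat_s = hat_s, t_col = t_col)
  if (return_gamma) {
    out$gamma <- gamma
    out$x_prob <- lik$xp
    out$rows <- rows
  }
  out
}

#' Variational update of a single patient document
#'
#' Runs \code{n_inner} CVB0 sweeps for one document under frozen global
#' statistics and returns the token-level responsibilities. For a
#' guided-modality code the joint responsibility over (topic, seed
#' indicator) factorizes into \code{gamma} (topic responsibility) and
#' \code{x_prob} (posterior probability the token came from the seed
#' distribution). Token groups of identical codes share one responsibility
#' vector, weighted by their count.
#'
#' @param corpus a \code{sage_corpus}.
#' @param d patient index or identifier.
#' @param state a \code{\link{sage_init_state}} result (or \code{fit$state}).
#' @param alpha either the full patient-by-topic prior matrix or the single
#'   prior row for this patient.
#' @param n_inner number of CVB0 sweeps (default 5).
#' @return list with per-modality \code{gamma} matrices (unique codes x
#'   topics, rownames = codes), \code{x_prob} for the guided modality,
#'   \code{m} (expected per-topic token mass) and \code{theta} (posterior
#'   mean topic mixture; sums to 1).
#' @export
update_document <- function(corpus, d, state, alpha, n_inner = 5) {
  stopifnot(n_inner >= 1)
  if (is.character(d)) d <- match(d, corpus$patients)
  fl <- .flatten_corpus(corpus)
  if (is.null(dim(alpha))) {  # a single prior row for this patient
    amat <- matrix(1e-12, length(corpus$patients), state$K)
    amat[d, ] <- alpha
  } else {
    amat <- as.matrix(alpha)
  }
  res <- .cvb0_batch(fl, d, state, amat, n_inner, return_gamma = TRUE)
  gamma_by_mod <- list()
  xp_g <- NULL
  if (!is.null(res$rows)) {
    mod <- fl$mod[res$rows]
    for (mi in seq_len(fl$M)) {
      sel <- which(mod == mi)
      g <- res$gamma[sel, , drop = FALSE]
      rownames(g) <- corpus$vocab[[mi]][fl$w[res$rows[sel]]]
      colnames(g) <- colnames(state$smask)
      gamma_by_mod[[corpus$modalities[mi]]] <- g
      if (mi == fl$guided) {
        xp_g <- res$x_prob[sel, , drop = FALSE]
        dimnames(xp_g) <- dimnames(g)
      }
    }
  }
  list(gamma = gamma_by_mod, x_prob = xp_g,
       m = drop(res$m), theta = drop(res$theta))
}

#' Expected topic-word distributions from a fitted state
#'
#' Regular topics: \code{phi_r[[m]][k,w] = (n_wk + beta)/(n_.k + beta V_m)}.
#' Seed topics (guided modality only):
#' \code{phi_s[k,w] = (s_wk + mu)/(s_.k + mu V_k)} on topic k's seed set and
#' exactly zero elsewhere, so each row sums to 1 over its support. Topics
#' with an empty seed set get an all-zero \code{phi_s} row and are listed in
#' \code{empty_seed_topics}.
#'
#' @param state a \code{sage_state} (or a fitted \code{sage} object's
#'   \code{$state}).
#' @return list with \code{phi_r} (per-modality K x V matrices),
#'   \code{phi_s} (K x V_guided), \code{pi}, \code{empty_seed_topics}.
#' @export
expected_topics <- function(state) {
  if (inherits(state, "sage")) state <- state$state
  phi_r <- lapply(seq_along(state$n), function(mi) {
    V <- nrow(state$n[[mi]])
    t(state$n[[mi]] + state$beta[mi]) /
      (state$n_col[[mi]] + state$beta[mi] * V)
  })
  names(phi_r) <- state$modalities
  sden <- state$s_col + state$mu * state$Vk
  empty <- state$Vk == 0
  sden[empty] <- 1
  phi_s <- t((state$s + state$mu) * state$smask) / sden
  phi_s[empty, ] <- 0
  list(phi_r = phi_r, phi_s = phi_s, pi = state$pi,
       empty_seed_topics = names(state$Vk)[empty])
}

#' Training control parameters
#'
#' @param batch_size documents per stochastic mini-batch (default 1000);
#'   values \code{>= D} give full-batch training with unit step size.
#' @param max_epochs maximum passes over the corpus.
#' @param n_inner CVB0 sweeps per document per epoch.
#' @param tau0,kappa step-size schedule \code{rho_t = (tau0 + t)^(-kappa)}
#'   over mini-batch updates; \code{kappa} must lie in (0.5, 1] for
#'   stochastic convergence.
#' @param pi_init,pi_a,pi_b seed-rate initialization and Beta smoothing.
#' @param jitter initialization jitter on regular-topic counts.
#' @param seed RNG seed governing jitter and batch shuffling.
#' @param tol relative change in validation per-token NLL declaring
#'   convergence (checked only when a validation corpus is supplied).
#' @param completion_fraction token fraction folded in when scoring the
#'   validation set.
#' @param verbose print per-epoch progress.
#' @return list of class \code{"sage_control"}.
#' @export
sage_control <- function(batch_size = 1000L, max_epochs = 50L, n_inner = 5L,
                         tau0 = 1, kappa = 0.7, pi_init = 0.7,
                         pi_a = 1, pi_b = 1, jitter = 0.01, seed = 1L,
                         tol = 1e-4, completion_fraction = 0.5,
                         verbose = FALSE) {
  stopifnot(batch_size >= 1, max_epochs >= 1, n_inner >= 1,
            kappa > 0.5, kappa <= 1, tau0 > 0)
  structure(as.list(environment()), class = "sage_control")
}

#' Fit a seed-and-guided multi-modal topic model
#'
#' The main fitting function. Patients are documents; each modality
#' contributes a bag of codes. Guided-modality codes are generated from a
#' per-topic mixture of a seed distribution (support restricted to the
#' topic's PheCode seed set, mixed in with probability \code{pi_k}) and a
#' full-vocabulary regular distribution; unguided modalities use regular
#' distributions only. Patient topic mixtures carry the document-specific
#' Dirichlet prior \code{alpha} from \code{\link{fit_gmm_prior}}, which is
#' held fixed throughout training. Inference is zeroth-order collapsed
#' variational Bayes over token assignments, with global expected counts
#' updated by stochastic mini-batch (SVI) steps; when \code{batch_size}
#' covers the whole corpus the step size is 1 and training reduces to
#' full-batch variational EM.
#'
#' @param corpus a \code{\link{sage_corpus}} (vocabulary already filtered).
#' @param seeds a \code{\link{build_seed_map}} result.
#' @param prior a \code{\link{fit_gmm_prior}} result (or a bare alpha
#'   matrix) aligned with \code{corpus$patients}.
#' @param beta regular-topic smoothing (scalar or per modality).
#' @param mu seed-topic smoothing.
#' @param control a \code{\link{sage_control}} list.
#' @param validation optional held-out \code{sage_corpus} used to track
#'   per-token negative log-likelihood and declare convergence.
#' @param prior_validation prior for the validation patients (required with
#'   \code{validation}).
#' @return object of class \code{"sage"} with elements \code{state} (global
#'   statistics and hyperparameters), \code{theta} (patients x topics
#'   posterior mixtures from a final frozen-global fold-in), \code{alpha},
#'   \code{seeds}, \code{history} (per-epoch log), \code{control},
#'   \code{call}.
#' @seealso \code{\link{predict.sage}}, \code{\link{expected_topics}},
#'   \code{\link{heldout_nll}}, \code{\link{phenotype_scores}}
#' @export
sage <- function(corpus, seeds, prior, beta = 0.1, mu = 0.1,
                 control = sage_control(), validation = NULL,
                 prior_validation = NULL) {
  cl <- match.call()
  alpha <- if (inherits(prior, "sage_prior")) prior$alpha else as.matrix(prior)
  stopifnot(nrow(alpha) == length(corpus$patients),
            ncol(alpha) == length(seeds$topics), all(alpha > 0))
  if (!is.null(validation) && is.null(prior_validation)) {
    stop("prior_validation required when a validation corpus is given")
  }
  D <- length(corpus$patients)
  batch_size <- min(control$batch_size, D)
  if (control$batch_size > D && control$verbose) {
    message("batch_size clamped to D = ", D)
  }
  full_batch <- batch_size >= D
  state <- sage_init_state(corpus, seeds, beta = beta, mu = mu,
                           pi_init = control$pi_init, pi_a = control$pi_a,
                           pi_b = control$pi_b, jitter = control$jitter,
                           seed = control$seed)
  fl <- .flatten_corpus(corpus)
  t_step <- 0L
  hist <- data.frame(epoch = integer(), rho = numeric(), val_nll = numeric())
  val_prev <- Inf
  for (epoch in seq_len(control$max_epochs)) {
    order_d <- if (full_batch) seq_len(D) else sample.int(D)
    starts <- seq(1L, D, by = batch_size)
    rho_last <- NA_real_
    for (b in starts) {
      docs <- order_d[b:min(b + batch_size - 1L, D)]
      t_step <- t_step + 1L
      rho <- if (full_batch) 1 else (control$tau0 + t_step)^(-control$kappa)
      rho_last <- rho
      res <- .cvb0_batch(fl, docs, state, alpha, control$n_inner)
      scale <- D / length(docs)
      for (mi in seq_len(fl$M)) {
        state$n[[mi]] <- (1 - rho) * state$n[[mi]] + rho * scale * res$hat_n[[mi]]
      }
      state$s <- (1 - rho) * state$s + rho * scale * res$hat_s
      state$n_col <- lapply(state$n, colSums)
      state$s_col <- colSums(state$s)
      # seed-rate update: Beta posterior mean over seed vs regular guided mass
      gcol <- state$n_col[[fl$guided]]
      state$pi <- (state$s_col + state$pi_a) /
        (state$s_col + gcol + state$pi_a + state$pi_b)
    }
    state$epoch <- epoch
    val_nll <- NA_real_
    if (!is.null(validation)) {
      val_nll <- heldout_nll(state, validation, prior_validation,
                             completion_fraction = control$completion_fraction,
                             n_inner = control$n_inner,
                             seed = control$seed + 1000L)
      if (control$verbose) {
        message(sprintf("epoch %d: val NLL/token %.5f", epoch, val_nll))
      }
    } else if (control$verbose) {
      message("epoch ", epoch)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, rho = rho_last,
                                   val_nll = val_nll))
    if (!is.null(validation) && is.finite(val_prev) &&
        abs(val_prev - val_nll) / abs(val_prev) < control$tol) {
      val_prev <- val_nll
      break
    }
    val_prev <- val_nll
  }
  # final frozen-global fold-in for training-set theta
  theta <- infer_theta(state, corpus, alpha, n_inner = max(control$n_inner, 10L))
  structure(list(state = state, theta = theta, alpha = alpha, seeds = seeds,
                 patients = corpus$patients, history = hist,
                 control = control, beta = state$beta, mu = state$mu,
                 call = cl),
            class = "sage")
}

#' Fold in patients under frozen global statistics
#'
#' Infers posterior topic mixtures for (possibly unseen) patients without
#' touching the global expected counts. Codes absent from the trained
#' vocabulary are dropped (their count is reported via the
#' \code{"n_dropped_codes"} attribute); patients with no usable tokens get
#' the normalized prior row.
#'
#' @param state a \code{sage_state} or fitted \code{sage} object.
#' @param corpus corpus of patients to fold in.
#' @param alpha prior matrix (or \code{sage_prior}) for those patients.
#' @param n_inner CVB0 sweeps (default 20).
#' @return patients x topics matrix; rows sum to 1.
#' @export
infer_theta <- function(state, corpus, alpha, n_inner = 20L) {
  if (inherits(state, "sage")) state <- state$state
  if (inherits(alpha, "sage_prior")) alpha <- alpha$alpha
  alpha <- as.matrix(alpha)
  # project corpus onto the trained vocabulary
  dropped <- 0
  mats <- lapply(state$modalities, function(m) {
    cm <- corpus$counts[[m]]
    if (is.null(cm)) stop("corpus lacks modality '", m, "'")
    keep <- colnames(cm) %in% state$vocab[[m]]
    dropped <<- dropped + sum(cm[, !keep, drop = FALSE])
    out <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(nrow(cm), length(state$vocab[[m]])),
                                dimnames = list(rownames(cm), state$vocab[[m]]))
    cmk <- cm[, keep, drop = FALSE]
    out[, colnames(cmk)] <- cmk
    out
  })
  names(mats) <- state$modalities
  proj <- sage_corpus(mats, guided = state$guided)
  fl <- .flatten_corpus(proj)
  D <- length(proj$patients)
  theta <- matrix(0, D, state$K,
                  dimnames = list(proj$patients, colnames(state$smask)))
  blocks <- split(seq_len(D), ceiling(seq_len(D) / 2000))
  for (docs in blocks) {
    res <- .cvb0_batch(fl, docs, state, alpha, n_inner)
    theta[docs, ] <- res$theta
  }
  attr(theta, "n_dropped_codes") <- dropped
  theta
}

#' Held-out per-token negative log-likelihood by document completion
#'
#' For each held-out patient a binomial split assigns each token to a
#' fold-in half (used to infer theta under frozen globals) or a scoring
#' half. Scored guided tokens use the model's marginal word distribution
#' \code{pi_k phi_s + (1 - pi_k) phi_r}; unguided tokens use \code{phi_r}.
#' Returns total negative log-likelihood divided by the number of scored
#' tokens.
#'
#' @param state a \code{sage_state} or fitted \code{sage}.
#' @param corpus held-out corpus (disjoint patients from training).
#' @param alpha prior for the held-out patients.
#' @param completion_fraction expected fraction of tokens folded in.
#' @param n_inner CVB0 sweeps for the fold-in.
#' @param seed RNG seed for the token split.
#' @return per-token NLL (scalar).
#' @export
heldout_nll <- function(state, corpus, alpha, completion_fraction = 0.5,
                        n_inner = 10L, seed = 1L) {
  if (inherits(state, "sage")) state <- state$state
  if (inherits(alpha, "sage_prior")) alpha <- alpha$alpha
  alpha <- as.matrix(alpha)
  if (length(corpus$patients) == 0L) stop("empty held-out set")
  set.seed(seed)
  fold <- list()
  score <- list()
  for (m in corpus$modalities) {
    cm <- methods::as(corpus$counts[[m]], "TsparseMatrix")
    cf <- stats::rbinom(length(cm@x), cm@x, completion_fraction)
    mk <- function(x) Matrix::sparseMatrix(i = cm@i + 1L, j = cm@j + 1L, x = x,
                                           dims = dim(cm), dimnames = dimnames(cm))
    fold[[m]] <- mk(cf)
    score[[m]] <- mk(cm@x - cf)
  }
  if (sum(vapply(score, sum, numeric(1))) == 0) {
    stop("token split left nothing to score; lower completion_fraction")
  }
  theta <- infer_theta(state, sage_corpus(fold, guided = corpus$guided),
                       alpha, n_inner = n_inner)
  tp <- expected_topics(state)
  nll <- 0
  ntok <- 0
  for (mi in seq_along(corpus$modalities)) {
    m <- corpus$modalities[mi]
    sm <- methods::as(score[[m]], "TsparseMatrix")
    keep <- colnames(sm) %in% state$vocab[[m]]
    widx <- match(colnames(sm)[sm@j + 1L], state$vocab[[m]])
    ok <- !is.na(widx) & sm@x > 0
    if (!any(ok)) next
    W <- if (m == state$guided) {
      state$pi * tp$phi_s + (1 - state$pi) * tp$phi_r[[m]]
    } else tp$phi_r[[m]]
    p <- rowSums(theta[sm@i[ok] + 1L, , drop = FALSE] *
                   t(W)[widx[ok], , drop = FALSE])
    nll <- nll - sum(sm@x[ok] * log(pmax(p, 1e-300)))
    ntok <- ntok + sum(sm@x[ok])
  }
  nll / ntok
}

#' Grid search for topic smoothing hyperparameters
#'
#' Trains a short-budget model per (beta, mu) grid point and returns the
#' pair minimizing validation held-out NLL; exact ties break toward larger
#' smoothing.
#'
#' @param corpus,seeds,prior training inputs as for \code{\link{sage}}.
#' @param validation,prior_validation held-out inputs.
#' @param beta_grid,mu_grid candidate values.
#' @param control a \code{sage_control}; keep \code{max_epochs} small.
#' @return list with \code{beta}, \code{mu} and the full \code{table} of
#'   grid NLLs.
#' @export
tune_hyperparams <- function(corpus, seeds, prior, validation,
                             prior_validation,
                             beta_grid = c(0.01, 0.1, 1),
                             mu_grid = c(0.01, 0.1, 1),
                             control = sage_control(max_epochs = 5L)) {
  stopifnot(length(beta_grid) >= 1, length(mu_grid) >= 1)
  grid <- expand.grid(beta = beta_grid, mu = mu_grid)
  grid$nll <- NA_real_
  for (i in seq_len(nrow(grid))) {
    fit <- sage(corpus, seeds, prior, beta = grid$beta[i], mu = grid$mu[i],
                control = control)
    grid$nll[i] <- heldout_nll(fit, validation, prior_validation,
                               n_inner = control$n_inner,
                               seed = control$seed + 1000L)
  }
  best <- grid[order(grid$nll, -(grid$beta + grid$mu)), ][1L, ]
  list(beta = best$beta, mu = best$mu, table = grid)
}
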