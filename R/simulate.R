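#' Simulator configuration
#'
#' Desk-scale defaults emulating the model's own generative process: 2000
#' patients, 5 PheCode-anchored topics over 3 modalities (guided plus two
#' unguided), 4 seed codes per topic, seed rates drawn uniformly in
#' [0.6, 0.9], and negative-binomial document lengths (mean 60, dispersion
#' 5) mimicking heavy-tailed EHR record sizes.
#'
#' @param D patients.
#' @param K phenotype topics.
#' @param V integer vector of vocabulary sizes, one per modality; the first
#'   modality is guided.
#' @param seed_size seed codes per topic.
#' @param modalities modality names (first = guided).
#' @param mod_prop expected token share per modality.
#' @param phi_conc Dirichlet concentration of regular topic-word
#'   distributions (small = sparse, well-separated topics).
#' @param seed_conc Dirichlet concentration of seed distributions over each
#'   seed set.
#' @param pi_range range of true seed-topic rates.
#' @param doc_mean,doc_disp negative-binomial document-length parameters
#'   (mean and size).
#' @param active_frac probability a patient is "active" for a topic.
#' @param alpha_base,alpha_active Dirichlet prior weight for inactive /
#'   added weight for active topics when drawing true theta.
#' @param disjoint_seeds keep seed sets disjoint across topics.
#' @param prev_rate,hazard,theta_ref event-model parameters: prevalent
#'   probability is \code{prev_rate * min(1, theta/theta_ref)} and, for the
#'   undiagnosed, incident probability is
#'   \code{hazard * min(1, theta/theta_ref)}.
#' @param keep_tokens retain the token-level table (doc, modality, topic,
#'   seed indicator, code) in the truth bundle.
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(D = 2000L, K = 5L, V = c(100L, 60L, 60L),
                       seed_size = 4L,
                       modalities = c("ICD", "MED", "PROC")[seq_along(V)],
                       mod_prop = c(0.5, 0.25, 0.25)[seq_along(V)],
                       phi_conc = 0.1, seed_conc = 1,
                       pi_range = c(0.6, 0.9),
                       doc_mean = 60, doc_disp = 5,
                       active_frac = 0.15, alpha_base = 0.1,
                       alpha_active = 5,
                       disjoint_seeds = TRUE,
                       prev_rate = 0.6, hazard = 0.5, theta_ref = 0.5,
                       keep_tokens = FALSE, seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, stopifnot(
    D >= 1, K >= 1, all(V >= 1), seed_size >= 1,
    length(modalities) == length(V), length(mod_prop) == length(V),
    all(mod_prop > 0), phi_conc > 0, seed_conc > 0,
    pi_range[1] > 0, pi_range[2] < 1, pi_range[1] <= pi_range[2],
    doc_mean > 0, doc_disp > 0, active_frac >= 0, active_frac <= 1,
    alpha_base > 0, alpha_active >= 0,
    prev_rate >= 0, prev_rate <= 1, hazard >= 0, theta_ref > 0))
  if (cfg$disjoint_seeds && cfg$K * cfg$seed_size > cfg$V[1L]) {
    stop("guided vocabulary too small for disjoint seed sets")
  }
  cfg$mod_prop <- cfg$mod_prop / sum(cfg$mod_prop)
  structure(cfg, class = "sim_config")
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  x / rowSums(x)
}

# Synthetic ICD-10-like guided vocabulary: each topic's seed codes share one
# chapter letter, so topic purity has a planted signal; background codes
# draw letters at random.
.make_guided_vocab <- function(K, seed_size, V) {
  chapters <- rep(c("E", "C", "I", "F", "G", "J", "K", "N", "A", "M"),
                  length.out = K)
  seed_codes <- lapply(seq_len(K), function(k) {
    paste0(chapters[k],
           sprintf("%02d", 10 + ((k - 1) * seed_size + seq_len(seed_size) - 1) %% 80),
           (k - 1) %% 10)
  })
  pool <- as.vector(outer(LETTERS[1:20], sprintf("%02d", 10:99), paste0))
  pool <- setdiff(paste0(pool, "9"), unlist(seed_codes))
  n_bg <- V - K * seed_size
  if (n_bg < 0) stop("guided vocabulary too small")
  bg <- sample(pool, n_bg)
  list(seed_codes = seed_codes, vocab = sort(c(unlist(seed_codes), bg)))
}

#' Simulate a multi-modal EHR corpus with known ground truth
#'
#' Samples from the model's generative process: true topic mixtures
#' \code{theta_d ~ Dir(alpha_d)} with boosted weight on each patient's
#' active topics; per token a topic \code{z ~ Cat(theta_d)} and a modality;
#' guided tokens flip a seed indicator \code{x ~ Bern(pi_z)} and draw the
#' code from the seed distribution (support = the topic's seed set) or the
#' regular distribution, while unguided tokens always use the modality's
#' regular distribution. Also emits a PheCode map whose topic identifiers
#' are \code{"1.0", "2.0", ...} and whose seed codes share an ICD-10
#' chapter letter per topic.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param dir optional directory; when given, the corpus (long format), the
#'   map, and MTX truth matrices are written there.
#' @return list with \code{corpus} (a \code{sage_corpus}), \code{map}
#'   (PheCode map data frame), \code{seeds} (a \code{sage_seedmap} built on
#'   the corpus), and \code{truth} (theta, phi_r per modality, phi_s, pi,
#'   seed sets, active-topic labels, and optionally the token table).
#' @export
simulate_corpus <- function(cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed)
  M <- length(cfg$V)
  gv <- .make_guided_vocab(cfg$K, cfg$seed_size, cfg$V[1L])
  vocabs <- c(list(gv$vocab),
              lapply(seq_len(M - 1L) + 1L, function(mi) {
                sort(paste0(cfg$modalities[mi], sprintf("%04d", seq_len(cfg$V[mi]))))
              }))
  names(vocabs) <- cfg$modalities
  seed_idx <- lapply(gv$seed_codes, function(s) match(sort(s), gv$vocab))
  # true parameters
  phi_r <- lapply(seq_len(M), function(mi) {
    .rdirichlet(cfg$K, rep(cfg$phi_conc, cfg$V[mi]))
  })
  names(phi_r) <- cfg$modalities
  phi_s <- matrix(0, cfg$K, cfg$V[1L])
  for (k in seq_len(cfg$K)) {
    phi_s[k, seed_idx[[k]]] <- drop(.rdirichlet(1, rep(cfg$seed_conc, cfg$seed_size)))
  }
  pi_true <- stats::runif(cfg$K, cfg$pi_range[1], cfg$pi_range[2])
  active <- matrix(stats::runif(cfg$D * cfg$K) < cfg$active_frac, cfg$D, cfg$K)
  alpha_true <- cfg$alpha_base + cfg$alpha_active * active
  theta <- t(apply(alpha_true, 1, function(a) {
    g <- stats::rgamma(cfg$K, shape = a)
    g / sum(g)
  }))
  N_d <- pmax(1L, stats::rnbinom(cfg$D, size = cfg$doc_disp, mu = cfg$doc_mean))
  # token-level sampling
  doc <- rep.int(seq_len(cfg$D), N_d)
  Ttot <- length(doc)
  z <- integer(Ttot)
  pos <- c(0L, cumsum(N_d))
  for (d in seq_len(cfg$D)) {
    z[(pos[d] + 1L):pos[d + 1L]] <- sample.int(cfg$K, N_d[d], replace = TRUE,
                                               prob = theta[d, ])
  }
  mod <- sample.int(M, Ttot, replace = TRUE, prob = cfg$mod_prop)
  x <- integer(Ttot)
  gsel <- mod == 1L
  x[gsel] <- stats::rbinom(sum(gsel), 1L, pi_true[z[gsel]])
  w <- integer(Ttot)
  for (mi in seq_len(M)) {
    for (k in seq_len(cfg$K)) {
      if (mi == 1L) {
        selS <- which(mod == mi & z == k & x == 1L)
        if (length(selS)) {
          w[selS] <- seed_idx[[k]][sample.int(cfg$seed_size, length(selS),
                                              replace = TRUE,
                                              prob = phi_s[k, seed_idx[[k]]])]
        }
        selR <- which(mod == mi & z == k & x == 0L)
      } else {
        selR <- which(mod == mi & z == k)
      }
      if (length(selR)) {
        w[selR] <- sample.int(cfg$V[mi], length(selR), replace = TRUE,
                              prob = phi_r[[mi]][k, ])
      }
    }
  }
  patients <- sprintf("P%05d", seq_len(cfg$D))
  mats <- lapply(seq_len(M), function(mi) {
    sel <- mod == mi
    Matrix::sparseMatrix(i = doc[sel], j = w[sel], x = 1,
                         dims = c(cfg$D, cfg$V[mi]),
                         dimnames = list(patients, vocabs[[mi]]))
  })
  names(mats) <- cfg$modalities
  corpus <- sage_corpus(mats, guided = cfg$modalities[1L])
  map <- data.frame(
    icd = unlist(gv$seed_codes),
    phecode = rep(sprintf("%.1f", seq_len(cfg$K)), each = cfg$seed_size),
    label = rep(sprintf("Simulated phenotype %d", seq_len(cfg$K)),
                each = cfg$seed_size),
    excl_phecodes = rep(sprintf("%.2f-%.2f", seq_len(cfg$K) - 0.5,
                                seq_len(cfg$K) + 0.5), each = cfg$seed_size),
    stringsAsFactors = FALSE)
  seeds <- build_seed_map(map, corpus, min_seed_size = 1)
  dimnames(theta) <- list(patients, seeds$topics)
  colnames(phi_s) <- gv$vocab
  for (mi in seq_len(M)) colnames(phi_r[[mi]]) <- vocabs[[mi]]
  truth <- list(theta = theta, phi_r = phi_r, phi_s = phi_s,
                pi = stats::setNames(pi_true, seeds$topics),
                seed_sets = stats::setNames(seed_idx, seeds$topics),
                active = active, N_d = N_d)
  if (cfg$keep_tokens) {
    truth$tokens <- data.frame(doc = doc, modality = cfg$modalities[mod],
                               topic = z, seed = x,
                               code = vapply(seq_len(Ttot), function(i)
                                 vocabs[[mod[i]]][w[i]], character(1)))
  }
  out <- list(corpus = corpus, map = map, seeds = seeds, truth = truth,
              cfg = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_sage_corpus(corpus, file.path(dir, "corpus.tsv"))
    utils::write.table(map, file.path(dir, "phecode_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    Matrix::writeMM(Matrix::Matrix(theta, sparse = TRUE),
                    file.path(dir, "true_theta.mtx"))
    writeLines(patients, file.path(dir, "patients.txt"))
    out$files <- c(corpus = file.path(dir, "corpus.tsv"),
                   map = file.path(dir, "phecode_map.tsv"))
  }
  out
}

#' Simulate prevalent and incident diagnosis events
#'
#' Every patient shares one baseline date. For each target topic, a
#' prevalent diagnosis occurs before baseline with probability increasing
#' in the patient's true topic weight; undiagnosed patients then become
#' incident after baseline with probability \code{hazard * min(1,
#' theta/theta_ref)}. When \code{hazard > 0}, each target is guaranteed at
#' least one incident case (the highest-theta undiagnosed patient is
#' promoted if sampling yielded none). Event codes are drawn from the
#' topic's seed set.
#'
#' @param sim a \code{\link{simulate_corpus}} result.
#' @param targets PheCode identifiers to generate events for (default all).
#' @param baseline_date shared baseline date.
#' @return list with \code{events} (patient_id, code, date), \code{baseline}
#'   (patient_id, baseline_date), and the true \code{prevalent} /
#'   \code{incident} indicator matrices.
#' @export
simulate_events <- function(sim, targets = sim$seeds$topics,
                            baseline_date = as.Date("2010-01-01")) {
  cfg <- sim$cfg
  set.seed(cfg$seed + 7L)
  theta <- sim$truth$theta
  patients <- rownames(theta)
  K <- length(sim$seeds$topics)
  prevalent <- matrix(FALSE, nrow(theta), K,
                      dimnames = list(patients, sim$seeds$topics))
  incident <- prevalent
  ev <- list()
  for (k in match(as.character(targets), sim$seeds$topics)) {
    p <- pmin(1, theta[, k] / cfg$theta_ref)
    prev <- stats::runif(nrow(theta)) < cfg$prev_rate * p
    undiag <- !prev
    inc <- undiag & (stats::runif(nrow(theta)) < cfg$hazard * p)
    if (cfg$hazard > 0 && !any(inc)) {
      cand <- which(undiag)[which.max(theta[undiag, k])]
      inc[cand] <- TRUE
    }
    prevalent[, k] <- prev
    incident[, k] <- inc
    codes <- sim$seeds$guided_vocab[sim$seeds$seed_sets[[k]]]
    mk <- function(idx, offs) {
      if (!any(idx)) return(NULL)
      data.frame(patient_id = patients[idx],
                 code = sample(codes, sum(idx), replace = TRUE),
                 date = baseline_date + offs, stringsAsFactors = FALSE)
    }
    ev[[length(ev) + 1L]] <- mk(prev, -sample(30:365, sum(prev), replace = TRUE))
    ev[[length(ev) + 1L]] <- mk(inc, sample(30:365, sum(inc), replace = TRUE))
  }
  events <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  list(events = events,
       baseline = data.frame(patient_id = patients,
                             baseline_date = baseline_date,
                             stringsAsFactors = FALSE),
       prevalent = prevalent, incident = incident)
}
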