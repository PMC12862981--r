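#' Read and validate a run configuration
#'
#' YAML configuration with blocks \code{paths} (corpus, phecode_map, outdir,
#' optionally events/baseline), \code{corpus} (modalities, guided, schema,
#' min_occurrences), \code{prior} (transform, alpha_scale, alpha_floor,
#' min_seed_size), \code{train} (beta, mu, batch_size, max_epochs, n_inner,
#' kappa, tau0, tol), \code{score} (rule, mixture, min_expected_n),
#' \code{evaluate} (n_top, k_values), and a top-level \code{seed}. Missing
#' optional fields take the package defaults; structural problems are
#' reported with the offending field name.
#'
#' @param path YAML file path.
#' @return validated config list of class \code{"sage_config"}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list (already parsed).
#' @export
validate_run_config <- function(cfg) {
  fail <- function(field) stop("config error: missing or invalid field '",
                               field, "'", call. = FALSE)
  if (is.null(cfg$paths$corpus)) fail("paths.corpus")
  if (is.null(cfg$paths$phecode_map)) fail("paths.phecode_map")
  if (is.null(cfg$paths$outdir)) fail("paths.outdir")
  if (is.null(cfg$corpus$modalities)) fail("corpus.modalities")
  if (is.null(cfg$corpus$guided)) fail("corpus.guided")
  if (!cfg$corpus$guided %in% cfg$corpus$modalities) fail("corpus.guided")
  defaults <- list(
    seed = 1L,
    corpus = list(min_occurrences = 10L,
                  schema = list(patient = "patient_id", modality = "modality",
                                code = "code", count = "count")),
    prior = list(transform = "log1p", alpha_scale = 1, alpha_floor = 0.01,
                 min_seed_size = 1L),
    train = list(beta = 0.1, mu = 0.1, batch_size = 1000L, max_epochs = 20L,
                 n_inner = 5L, kappa = 0.7, tau0 = 1, tol = 1e-4),
    score = list(rule = "noisy_or", mixture = "pi_weighted",
                 min_expected_n = 0),
    evaluate = list(n_top = 5L, k_values = seq(10L, 100L, 10L)))
  for (blk in names(defaults)) {
    if (blk == "seed") {
      cfg$seed <- cfg$seed %||% defaults$seed
    } else {
      for (f in names(defaults[[blk]])) {
        cfg[[blk]][[f]] <- cfg[[blk]][[f]] %||% defaults[[blk]][[f]]
      }
    }
  }
  structure(cfg, class = "sage_config")
}

# derive a stage-specific seed from the run seed (stage-name hashed) so
# stages are individually reproducible without sharing RNG streams
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435L + h) %% .Machine$integer.max)
}

.log_line <- function(con, level, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  level, msg)
  writeLines(line, con)
  invisible(line)
}

#' Run the full phenotyping pipeline from a configuration
#'
#' Stages execute in dependency order: load and filter the corpus, build
#' the seed map, fit the mixture-model topic priors, train the guided topic
#' model, compute calibrated phenotype scores, evaluate topic purity (and,
#' when event data are configured, precision at K), and export PLINK-format
#' quantitative traits. All artifacts, a resolved-config snapshot, and a
#' line-delimited log are written under \code{paths.outdir}. Outputs are
#' deterministic given the config and its seed.
#'
#' @param config a \code{\link{read_run_config}} result, a config list, or
#'   a YAML path.
#' @return invisibly, a list with the fitted model, scores, evaluation
#'   tables and artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "sage_config")) config <- validate_run_config(config)
  outdir <- config$paths$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(outdir, "pipeline.log"), "wt")
  on.exit(close(logcon))
  yaml::write_yaml(unclass(config), file.path(outdir, "resolved_config.yaml"))
  tic <- function() Sys.time()
  stage <- function(name, expr) {
    t0 <- tic()
    res <- expr
    .log_line(logcon, "INFO", sprintf("%s done in %.1fs", name,
                                      as.numeric(difftime(tic(), t0, "secs"))))
    res
  }
  corpus <- stage("prepare", {
    co <- read_sage_corpus(config$paths$corpus,
                           modalities = config$corpus$modalities,
                           guided = config$corpus$guided,
                           schema = config$corpus$schema)
    .log_line(logcon, "INFO", sprintf("loaded %d patients", length(co$patients)))
    filter_vocabulary(co, config$corpus$min_occurrences)
  })
  seeds <- stage("seed-map", {
    build_seed_map(config$paths$phecode_map, corpus,
                   min_seed_size = config$prior$min_seed_size)
  })
  prior <- stage("init-prior", {
    fit_gmm_prior(phecode_count_matrix(corpus, seeds),
                  alpha_scale = config$prior$alpha_scale,
                  alpha_floor = config$prior$alpha_floor,
                  transform = config$prior$transform)
  })
  fit <- stage("train", {
    ctrl <- sage_control(batch_size = config$train$batch_size,
                         max_epochs = config$train$max_epochs,
                         n_inner = config$train$n_inner,
                         kappa = config$train$kappa, tau0 = config$train$tau0,
                         tol = config$train$tol,
                         seed = .stage_seed(config$seed, "train"))
    sage(corpus, seeds, prior, beta = config$train$beta,
         mu = config$train$mu, control = ctrl)
  })
  write_sage_model(fit, file.path(outdir, "model"))
  utils::write.table(
    data.frame(patient_id = rownames(fit$theta),
               format(as.data.frame(fit$theta), digits = 17)),
    file.path(outdir, "theta.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  scores <- stage("score", {
    phenotype_scores(fit, corpus, rule = config$score$rule,
                     mixture = config$score$mixture)
  })
  export_quantitative_traits(scores, path = file.path(outdir, "traits.pheno"),
                             min_expected_n = config$score$min_expected_n)
  evals <- stage("evaluate", {
    tp <- expected_topics(fit$state)
    g <- fit$state$guided
    phi_mix <- fit$state$pi * tp$phi_s + (1 - fit$state$pi) * tp$phi_r[[g]]
    rownames(phi_mix) <- fit$seeds$topics
    pur <- topic_purity(phi_mix, n_top = config$evaluate$n_top)
    utils::write.table(pur$per_topic, file.path(outdir, "topic_purity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ev <- list(purity = pur)
    if (!is.null(config$paths$events) && !is.null(config$paths$baseline)) {
      events <- utils::read.table(config$paths$events, header = TRUE,
                                  sep = "\t", colClasses = "character")
      baseline <- utils::read.table(config$paths$baseline, header = TRUE,
                                    sep = "\t", colClasses = "character")
      sp <- split_events(events, baseline, seeds, patients = corpus$patients)
      prec <- do.call(rbind, lapply(seq_along(seeds$topics), function(k) {
        pk <- precision_at_k(fit$theta[, k], sp$incident[, k],
                             sp$prevalent[, k],
                             excluded = exclusion_mask(sp$prevalent, seeds,
                                                       seeds$topics[k]),
                             k_values = config$evaluate$k_values)
        cbind(phecode = seeds$topics[k], pk)
      }))
      utils::write.table(prec, file.path(outdir, "precision_at_k.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ev$precision <- prec
    }
    ev
  })
  .log_line(logcon, "INFO", "pipeline complete")
  invisible(list(corpus = corpus, seeds = seeds, prior = prior, fit = fit,
                 scores = scores, evaluation = evals, outdir = outdir))
}
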