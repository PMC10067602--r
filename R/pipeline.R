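pipeline_defaults <- function() {
  list(
    seed = NULL, out_dir = NULL,
    stages = c("simulate", "encode", "train", "score", "evaluate",
               "cluster", "classify", "characterize", "rrg"),
    expression_file = NULL, clinical_file = NULL, maf_file = NULL,
    gmt_file = NULL,
    use_published_model = FALSE,
    # simulation
    n_samples = 300L, n_genes = 150L, n_signature_genes = 66L,
    n_subtypes = 3L, subtype_shift = 1.5, planted_pairs = NULL,
    censoring_target = 0.4, batch_distortion = "none",
    simulate_mutation_rate = 100,
    # model building
    low = 0.2, high = 0.8, alpha = 0.05, n_folds = 10L, keep_alpha = 0.05,
    # evaluation
    horizons = c(1, 3, 5), year_days = 365.25,
    # subtyping
    k_range = 2:6, reps = 1000L, subsample = 0.8, mlp_grid = FALSE,
    mlp_max_iter = 100L, classifier_folds = 10L,
    # characterization / rrg
    exome_mb = 38, rrg_adj_p = 0.01
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("configuration must set a seed")
  bad_stage <- setdiff(cfg$stages, defaults$stages)
  if (length(bad_stage) > 0L) stop("unknown stage(s): ",
                                   paste(bad_stage, collapse = ", "))
  if (!("simulate" %in% cfg$stages) &&
      (is.null(cfg$expression_file) || is.null(cfg$clinical_file))) {
    stop("without the simulate stage, expression_file and clinical_file are required")
  }
  cfg
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write_tsv(df, path)
}

#' Run the end-to-end gene-pair prognostic pipeline
#'
#' Orchestrates the analysis stages in dependency order — simulate (or
#' load) a cohort, encode pair features, fit the risk model (or use the
#' bundled published one), score samples, evaluate survival separation
#' and time-dependent AUC, discover and classify subtypes, characterise
#' risk groups (enrichment scores and mutation burden), and select
#' risk-related genes. Each stage writes its artifact plus a JSON
#' manifest recording parameters, the stage seed and input/output file
#' checksums (no timestamps), so a rerun with the same configuration
#' reproduces identical artifacts byte for byte. A single global seed
#' drives all stages; per-stage seeds are derived deterministically from
#' it and the stage name.
#'
#' @param config A named list of configuration values or the path to a
#'   YAML file holding one. Unknown keys are a validation error before
#'   any stage runs. Required: `seed` and `out_dir`; stages default to
#'   the full sequence. See the package vignette for the key reference.
#' @return An object of class `pairprog_run`: list of per-stage results,
#'   including the model funnel counts, evaluation report and the paths
#'   of all written artifacts.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$out_dir)) stop("configuration must set out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg, files = character(0))
  manifests <- list()
  emit <- function(stage, params, inputs, outputs) {
    sums <- function(paths) {
      s <- tools::md5sum(paths)
      names(s) <- basename(paths)   # path-independent manifests
      as.list(s)
    }
    man <- list(stage = stage, params = params,
                seed = derive_seed(cfg$seed, stage),
                inputs = sums(inputs), outputs = sums(outputs))
    path <- file.path(cfg$out_dir, sprintf("manifest-%s.json", stage))
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
    manifests[[stage]] <<- man
    report$files <<- c(report$files, outputs, path)
  }
  on_stage <- function(s) s %in% cfg$stages

  # --- simulate / load ------------------------------------------------
  if (on_stage("simulate")) {
    sc <- sim_config(n_samples = cfg$n_samples, n_genes = cfg$n_genes,
                     n_signature_genes = cfg$n_signature_genes,
                     n_subtypes = cfg$n_subtypes,
                     subtype_shift = cfg$subtype_shift,
                     planted_pairs = cfg$planted_pairs,
                     censoring_target = cfg$censoring_target,
                     batch_distortion = cfg$batch_distortion,
                     seed = derive_seed(cfg$seed, "simulate"))
    cohort <- simulate_cohort(sc)
    expr <- cohort$expression
    clinical <- cohort$survival
    signature <- cohort$signature_genes
    mut <- simulate_mutations(clinical$sample,
                              lambda = cfg$simulate_mutation_rate,
                              genes = rownames(expr),
                              seed = derive_seed(cfg$seed, "mutations"))
    f_expr <- write_matrix_tsv(expr, file.path(cfg$out_dir, "expression.tsv"))
    f_clin <- write_tsv(clinical, file.path(cfg$out_dir, "clinical.tsv"))
    f_mut <- write_tsv(data.frame(Hugo_Symbol = mut$gene,
                                  Tumor_Sample_Barcode = mut$sample,
                                  Variant_Classification = mut$variant_classification),
                       file.path(cfg$out_dir, "mutations.tsv"))
    f_truth <- write_tsv(data.frame(sample = names(cohort$true_subtype),
                                    subtype = cohort$true_subtype),
                         file.path(cfg$out_dir, "true_subtypes.tsv"))
    emit("simulate",
         cfg[c("n_samples", "n_genes", "n_signature_genes", "n_subtypes",
               "subtype_shift", "censoring_target", "batch_distortion")],
         character(0), c(f_expr, f_clin, f_mut, f_truth))
    report$simulate <- list(realized_censoring = cohort$realized_censoring)
  } else {
    expr <- read_expression(cfg$expression_file)
    clinical <- read_clinical(cfg$clinical_file)
    keep <- intersect(colnames(expr), clinical$sample)
    expr <- expr[, keep, drop = FALSE]
    clinical <- clinical[match(keep, clinical$sample), , drop = FALSE]
    signature <- rownames(expr)
    mut <- if (!is.null(cfg$maf_file)) read_maf_lite(cfg$maf_file) else NULL
    cohort <- NULL
  }

  # --- encode ---------------------------------------------------------
  pfm <- NULL
  if (on_stage("encode") || on_stage("train") || on_stage("score")) {
    pairs <- enumerate_pairs(signature)
    pfm_all <- encode_pairs(expr, pairs)
    pfm <- filter_informative(pfm_all, low = cfg$low, high = cfg$high)
    f_pairs <- write_matrix_tsv(pfm$indicators,
                                file.path(cfg$out_dir, "pair_features.tsv"),
                                id_col = "pair")
    emit("encode", cfg[c("low", "high")], character(0), f_pairs)
    report$encode <- list(enumerated = nrow(pairs),
                          informative = nrow(pfm$pairs),
                          deleted = attr(pfm, "n_deleted"))
  }

  # --- train / published model ---------------------------------------
  model <- NULL
  if (on_stage("train")) {
    if (isTRUE(cfg$use_published_model)) {
      model <- published_mkpc()
    } else {
      model <- mkpc(pfm, clinical, alpha = cfg$alpha, n_folds = cfg$n_folds,
                    keep_alpha = cfg$keep_alpha, low = cfg$low, high = cfg$high,
                    seed = derive_seed(cfg$seed, "train"))
    }
    f_model <- write_model(model, file.path(cfg$out_dir, "model.json"))
    emit("train", cfg[c("alpha", "n_folds", "keep_alpha", "use_published_model")],
         character(0), f_model)
    report$train <- list(funnel = model$funnel, n_terms = nrow(model$terms),
                         cutoff = model$cutoff)
  }

  # --- score ----------------------------------------------------------
  scores <- NULL
  if (on_stage("score") && !is.null(model)) {
    scores <- score_mkpc(model, expr)
    f_scores <- write_tsv(scores, file.path(cfg$out_dir, "scores.tsv"))
    emit("score", list(cutoff = model$cutoff), character(0), f_scores)
    report$score <- list(n_high = sum(scores$risk_group == "high"),
                         n_low = sum(scores$risk_group == "low"))
  }

  # --- evaluate -------------------------------------------------------
  if (on_stage("evaluate") && !is.null(scores)) {
    surv <- clinical[match(scores$sample, clinical$sample), , drop = FALSE]
    ev <- list()
    if (length(unique(scores$risk_group)) == 2L) {
      lr <- logrank_test(surv, scores$risk_group)
      ev$logrank <- lr[c("chi_square", "df", "p_value")]
      ev$km <- lapply(split(seq_len(nrow(surv)), scores$risk_group),
                      function(i) as.data.frame(km_estimate(surv[i, ])))
    } else {
      ev$logrank <- list(note = "not evaluable: single risk group")
    }
    ok_h <- cfg$horizons * cfg$year_days < max(surv$time)
    if (any(ok_h)) {
      ev$auc <- as.data.frame(td_auc(scores$mkpc_score, surv,
                                     horizons = cfg$horizons[ok_h],
                                     year_days = cfg$year_days))
    }
    f_eval <- file.path(cfg$out_dir, "evaluation.json")
    jsonlite::write_json(ev, f_eval, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    emit("evaluate", cfg[c("horizons", "year_days")], character(0), f_eval)
    report$evaluate <- ev
  }

  # --- cluster --------------------------------------------------------
  labels <- NULL
  if (on_stage("cluster")) {
    cr <- consensus_cluster(expr, genes = signature, k_range = cfg$k_range,
                            reps = cfg$reps, subsample = cfg$subsample,
                            seed = derive_seed(cfg$seed, "cluster"))
    labels <- cr$labels_chosen
    f_lab <- write_tsv(data.frame(sample = names(labels), subtype = labels),
                       file.path(cfg$out_dir, "subtypes.tsv"))
    emit("cluster", cfg[c("k_range", "reps", "subsample")], character(0), f_lab)
    report$cluster <- list(chosen_k = cr$chosen_k, pac = cr$pac,
                           cdf_area = cr$cdf_area,
                           sizes = as.integer(table(labels)))
  }

  # --- classify -------------------------------------------------------
  if (on_stage("classify") && !is.null(labels)) {
    med <- medoid_classifier_train(expr, labels, genes = signature)
    mlp <- if (isTRUE(cfg$mlp_grid)) {
      mlp_grid_search(expr, labels, genes = signature,
                      folds = cfg$classifier_folds,
                      seed = derive_seed(cfg$seed, "classify"),
                      max_iter = cfg$mlp_max_iter)
    } else {
      mlp_fit(expr, labels, genes = signature,
              seed = derive_seed(cfg$seed, "classify"),
              max_iter = cfg$mlp_max_iter)
    }
    cmp <- compare_classifiers(med, mlp, expr, clinical)
    f_pred <- write_tsv(data.frame(sample = colnames(expr),
                                   medoid = cmp$classifier_a$labels,
                                   mlp = cmp$classifier_b$labels),
                        file.path(cfg$out_dir, "classified.tsv"))
    emit("classify", cfg[c("mlp_grid", "mlp_max_iter", "classifier_folds")],
         character(0), f_pred)
    report$classify <- list(p_medoid = cmp$classifier_a$p_value,
                            p_mlp = cmp$classifier_b$p_value,
                            winner = c("medoid", "mlp")[cmp$winner],
                            mlp_cv_accuracy = mlp$cv_accuracy)
  }

  # --- characterize ---------------------------------------------------
  if (on_stage("characterize") && !is.null(scores)) {
    ch <- list()
    if (!is.null(cfg$gmt_file)) {
      sets <- read_gmt(cfg$gmt_file)
      ss <- ssgsea_score(expr, sets)
      f_ss <- write_matrix_tsv(ss, file.path(cfg$out_dir, "ssgsea.tsv"),
                               id_col = "gene_set")
      report$files <- c(report$files, f_ss)
      ch$ssgsea_sets <- nrow(ss)
    }
    if (!is.null(mut)) {
      tmb <- compute_tmb(mut, exome_size_mb = cfg$exome_mb,
                         sample_roster = scores$sample)
      f_tmb <- write_tsv(tmb, file.path(cfg$out_dir, "tmb.tsv"))
      if (length(unique(scores$risk_group)) == 2L) {
        ch$tmb_wilcoxon <- group_compare(tmb$tmb, scores$risk_group)
      }
      emit("characterize", cfg["exome_mb"], character(0), f_tmb)
    }
    report$characterize <- ch
  }

  # --- rrg ------------------------------------------------------------
  if (on_stage("rrg") && !is.null(scores) &&
      length(unique(scores$risk_group)) == 2L) {
    de <- differential_expression(log1p(expr), scores$risk_group,
                                  adj_p_threshold = cfg$rrg_adj_p)
    degs <- de$gene[de$deg]
    if (length(degs) >= 2L) {
      rrg <- select_rrg(expr[degs, , drop = FALSE], scores$linear_sum,
                        seed = derive_seed(cfg$seed, "rrg"))
      report$rrg <- list(n_deg = length(degs),
                         lasso = rrg$lasso_selected, rf = rrg$rf_selected,
                         final = rrg$final)
    } else {
      report$rrg <- list(n_deg = length(degs),
                         note = "fewer than two differential genes")
    }
    f_rrg <- file.path(cfg$out_dir, "rrg.json")
    jsonlite::write_json(report$rrg, f_rrg, auto_unbox = TRUE, pretty = TRUE)
    emit("rrg", cfg["rrg_adj_p"], character(0), f_rrg)
  }

  report$manifests <- manifests
  class(report) <- "pairprog_run"
  report
}

#' @export
print.pairprog_run <- function(x, ...) {
  cat("Pipeline run\n")
  if (!is.null(x$train)) {
    cat("  funnel:", paste(x$train$funnel, collapse = " -> "), "\n")
  }
  if (!is.null(x$evaluate$logrank$p_value)) {
    cat(sprintf("  risk-group log-rank p: %.3g\n", x$evaluate$logrank$p_value))
  }
  if (!is.null(x$cluster)) {
    cat(sprintf("  consensus k: %d (sizes %s)\n", x$cluster$chosen_k,
                paste(x$cluster$sizes, collapse = "/")))
  }
  cat(sprintf("  %d artifact file(s) in %s\n", length(unique(x$files)),
              x$config$out_dir))
  invisible(x)
}
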