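#' Default pipeline configuration
#'
#' Every run of [run_pipeline()] starts from these settings, merged with
#' user overrides; the resolved copy is written next to the outputs so
#' runs are auditable and repeatable.
#'
#' @param mode `"simulate"` (synthetic cohort from the bundled summary
#'   tables), `"feature-table"` (read a cohort TSV) or `"signals"`
#'   (extract features from per-subject signal sessions).
#' @param output_dir Output directory.
#' @param seed Integer seed used by every stochastic stage.
#' @return Nested configuration list.
#' @export
default_config <- function(mode = "simulate", output_dir = "flexiphys_out",
                           seed = 1L) {
  list(
    mode = mode,
    output_dir = output_dir,
    seed = as.integer(seed),
    log_level = "info",
    simulate = list(source = "physio",   # physio | neuropsych | both | rule
                    n_per_group = NULL),
    feature_table = list(path = NULL),
    signals = list(manifests = NULL),
    stats = list(adjust = "none"),
    classify = list(methods = c("kNN", "SVM", "RandomForest", "NaiveBayes"),
                    top_k = 10L, final_k = 2L),
    tree = list(max_depth = 3L, min_leaf = 2L)
  )
}

.log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) {
    message("[flexiphys] ", ...)
  }
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]])) {
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

# stage wrapper: failures abort naming the stage
.stage <- function(name, cfg, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' simulate / load -> (extract) -> group statistics -> ranking ->
#' leave-one-out classifier comparison on all features, the top-k
#' ranked features and the final reduced set -> decision tree -> report.
#' Outputs (cohort TSV, comparison TSV, ranking TSV, results JSON, rule
#' text, Markdown report, resolved config) land in `output_dir`;
#' identical `(config, seed)` give identical result files.
#'
#' @param config A configuration list (merged over [default_config()])
#'   or the path of a YAML file holding one.
#' @return Invisibly, a list with the cohort, comparisons, ranking,
#'   `cv_results` (per feature set, per method), tree and file paths.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_config(), config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- .stage("input", cfg, switch(
    cfg$mode,
    "simulate" = {
      if (identical(cfg$simulate$source, "rule")) {
        generate_rule_cohort(seed = cfg$seed)
      } else {
        specs <- cohort_specs_from_summary(
          reference_summary_tables(cfg$simulate$source),
          n = cfg$simulate$n_per_group)
        generate_cohort(specs, seed = cfg$seed)
      }
    },
    "feature-table" = {
      if (is.null(cfg$feature_table$path)) stop("feature_table$path not set")
      read_cohort_tsv(cfg$feature_table$path)
    },
    "signals" = {
      if (is.null(cfg$signals$manifests)) stop("signals$manifests not set")
      extract_cohort_features(cfg$signals$manifests)
    },
    stop("unknown mode `", cfg$mode, "`")
  ))
  .log(cfg, "cohort: ", nrow(cohort), " subjects, ",
       ncol(cohort) - 3L, " features")

  cohort <- .stage("group_stats", cfg, {
    if (!"group" %in% names(cohort)) {
      if (!"CFI" %in% names(cohort)) {
        stop("no `group` labels and no `CFI` column to split on")
      }
      cohort$group <- median_split(cohort$CFI)
    }
    cohort
  })
  comparisons <- .stage("group_stats", cfg,
                        t_test_table(cohort, adjust = cfg$stats$adjust))

  ranking <- .stage("ranking", cfg, rank_features(cohort))

  feature_sets <- .stage("classification", cfg, {
    sets <- list(all = ranking$feature)
    if (cfg$classify$top_k < nrow(ranking)) {
      sets[[paste0("top", cfg$classify$top_k)]] <-
        ranking$feature[seq_len(cfg$classify$top_k)]
    }
    if (cfg$classify$final_k < cfg$classify$top_k) {
      sets[[paste0("top", cfg$classify$final_k)]] <-
        ranking$feature[seq_len(cfg$classify$final_k)]
    }
    sets
  })
  cv_results <- .stage("classification", cfg, {
    lapply(feature_sets, function(fs) {
      compare_classifiers(cohort, cfg$classify$methods, seed = cfg$seed,
                          features = fs)
    })
  })

  tree <- .stage("tree", cfg,
                 fit_decision_tree(cohort, max_depth = cfg$tree$max_depth,
                                   min_leaf = cfg$tree$min_leaf))

  paths <- .stage("report", cfg,
                  .write_report(cfg, cohort, comparisons, ranking,
                                cv_results, tree))
  invisible(list(config = cfg, cohort = cohort, comparisons = comparisons,
                 ranking = ranking, cv_results = cv_results, tree = tree,
                 paths = paths))
}

#' Extract a cohort feature table from per-subject signal sessions
#'
#' @param manifests Character vector of `session.json` paths (one per
#'   subject), as written by [write_session()].
#' @return Cohort `data.frame` of extracted cardiac and peripheral
#'   features (no `group` column; attach one or split on `CFI`).
#' @export
extract_cohort_features <- function(manifests) {
  rows <- lapply(manifests, function(m) {
    ses <- read_session(m)
    s <- ses$signals
    feats <- c(
      if (!is.null(s$BVP)) cardiac_features(s$BVP),
      peripheral_features(rsp = s$RSP, emg1 = s$EMG1, emg2 = s$EMG2,
                          sc = s$SC)
    )
    cbind(data.frame(subject_id = ses$subject_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(feats), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.cv_to_list <- function(cvs) {
  lapply(cvs, function(r) {
    list(auc = r$auc, ca = r$ca, f1 = r$f1, precision = r$precision,
         recall = r$recall,
         confusion_matrix = unclass(r$confusion_matrix))
  })
}

.tree_to_list <- function(node) {
  if (node$type == "leaf") {
    list(leaf = TRUE, class = node$class, n = node$n,
         proportions = as.list(node$proportions))
  } else {
    list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
         n = node$n, left = .tree_to_list(node$left),
         right = .tree_to_list(node$right))
  }
}

.write_report <- function(cfg, cohort, comparisons, ranking, cv_results,
                          tree) {
  out <- cfg$output_dir
  p <- list(
    config = file.path(out, "resolved_config.yaml"),
    cohort = file.path(out, "cohort.tsv"),
    comparisons = file.path(out, "group_comparisons.tsv"),
    ranking = file.path(out, "ranking.tsv"),
    results = file.path(out, "results.json"),
    rules = file.path(out, "tree_rules.txt"),
    report = file.path(out, "report.md")
  )
  yaml::write_yaml(cfg, p$config)
  write_cohort_tsv(cohort, p$cohort)
  utils::write.table(comparisons, p$comparisons, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ranking, p$ranking, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  results <- list(
    seed = cfg$seed,
    n_subjects = nrow(cohort),
    cv = lapply(cv_results, .cv_to_list),
    tree = .tree_to_list(tree$root)
  )
  jsonlite::write_json(results, p$results, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(tree_rules(tree), p$rules)

  sig <- comparisons[comparisons$p_two_tailed < 0.05, "feature_name"]
  md <- c(
    "# flexiphys run report", "",
    sprintf("- mode: %s, seed: %d", cfg$mode, cfg$seed),
    sprintf("- subjects: %d (%s)", nrow(cohort),
            paste(sprintf("%s: %d", names(table(cohort$group)),
                          as.integer(table(cohort$group))), collapse = ", ")),
    "", "## Group comparisons",
    sprintf("- features tested: %d; significant at 0.05: %s",
            nrow(comparisons),
            if (length(sig)) paste(sig, collapse = ", ") else "none"),
    "", "## Feature ranking (top 10)",
    sprintf("%2d. %s (gain %.3f)", seq_len(min(10, nrow(ranking))),
            ranking$feature[seq_len(min(10, nrow(ranking)))],
            ranking$score[seq_len(min(10, nrow(ranking)))]),
    "", "## Leave-one-out cross-validation")
  for (set in names(cv_results)) {
    md <- c(md, sprintf("### feature set: %s", set),
            "| method | AUC | CA | F1 | precision | recall |",
            "|---|---|---|---|---|---|")
    for (m in names(cv_results[[set]])) {
      r <- cv_results[[set]][[m]]
      md <- c(md, sprintf("| %s | %.3f | %.3f | %.3f | %.3f | %.3f |",
                          m, r$auc, r$ca, r$f1, r$precision, r$recall))
    }
    md <- c(md, "")
  }
  md <- c(md, "## Decision rules", "```", tree_rules(tree), "```")
  writeLines(md, p$report)
  p
}
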