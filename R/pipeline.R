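stop_validation <- function(msg, subclass) {
  stop(structure(class = c(subclass, "dietddm_validation_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

# Atomic CSV write: temp file in the target directory, then rename.
write_csv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  path
}

#' Read and validate a trial table
#'
#' Reads a trial CSV and checks the schema: rating codes in
#' \{-2, -1, 1, 2\} (a zero code raises `dietddm_error_rating_code`),
#' non-zero signed response times, and, when a `choice` column is present,
#' agreement between its labels and the sign of `rt_signed`
#' (`dietddm_error_choice_sign` otherwise).  Unknown columns raise
#' `dietddm_error_unknown_column`.
#'
#' @param path CSV path with a header row.
#' @return Validated data.frame of trials.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trial_table(df)
}

#' @rdname read_trial_table
#' @param trials an in-memory trial table to validate.
#' @export
validate_trial_table <- function(trials) {
  known <- c("participant_id", "trial_index", "taste", "health", "sv",
             "calorie_density", "choice", "rt_signed", "group")
  extra <- setdiff(names(trials), known)
  if (length(extra))
    stop_validation(paste("unknown column(s):", paste(extra, collapse = ", ")),
                    "dietddm_error_unknown_column")
  required <- c("participant_id", "taste", "health", "rt_signed")
  miss <- setdiff(required, names(trials))
  if (length(miss))
    stop_validation(paste("missing column(s):", paste(miss, collapse = ", ")),
                    "dietddm_error_missing_column")
  for (col in intersect(c("taste", "health", "sv"), names(trials))) {
    if (!all(trials[[col]] %in% c(-2, -1, 1, 2)))
      stop_validation(sprintf(
        "column '%s' contains rating codes outside {-2, -1, 1, 2}", col),
        "dietddm_error_rating_code")
  }
  if (any(trials$rt_signed == 0))
    stop_validation("rt_signed contains zero response times",
                    "dietddm_error_zero_rt")
  if ("choice" %in% names(trials)) {
    ok <- (trials$choice == "yes" & trials$rt_signed > 0) |
      (trials$choice == "no" & trials$rt_signed < 0)
    if (!all(ok))
      stop_validation(
        "choice labels disagree with the sign of rt_signed (yes must be positive)",
        "dietddm_error_choice_sign")
  }
  trials
}

#' Write a named list of tables to CSV
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm)
    write_csv_atomic(tables[[nm]], file.path(dir, paste0(nm, ".csv"))),
    character(1))
  invisible(paths)
}

#' Pearson correlation (report-stage utility)
#'
#' @param x,y numeric vectors.
#' @return list with `r`, `t`, `df`, two-tailed `p`.
#' @export
pearson_correlation <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value)
}

#' Pipeline run configuration
#'
#' @param stages subset of `simulate`, `fit`, `compare`, `groupdiff`,
#'   `mediate`, `valuation`, `report` in any order; executed in dependency
#'   order.
#' @param truth a [ground_truth_config()] for the simulate stage.
#' @param sampler list of sampler settings (`n_chains`, `n_iter`,
#'   `burn_in`, `thin`, `seeds`).
#' @param variants model variants fitted in the compare stage.
#' @param n_boot,mediation_seed bootstrap settings for the mediate stage.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "fit", "compare", "groupdiff",
                                  "mediate", "valuation", "report"),
                       truth = ground_truth_config(),
                       sampler = list(n_chains = 3, n_iter = 2400,
                                      burn_in = 1200, thin = 3,
                                      seeds = NULL),
                       variants = c("two_weight", "taste_only",
                                    "health_only"),
                       n_boot = 10000, mediation_seed = 42L,
                       out_dir = tempfile("dietddm_run_")) {
  known <- c("simulate", "fit", "compare", "groupdiff", "mediate",
             "valuation", "report")
  stopifnot(all(stages %in% known))
  structure(list(stages = stages, truth = truth, sampler = sampler,
                 variants = variants, n_boot = n_boot,
                 mediation_seed = as.integer(mediation_seed),
                 out_dir = out_dir),
            class = "run_config")
}

chains_to_long <- function(chains, group, variant) {
  kept <- dim(chains$draws)[1]
  pars <- chains$parameters
  do.call(rbind, lapply(seq_len(chains$n_chains), function(k) {
    data.frame(model = variant, group = group, chain = k,
               iteration = rep(seq_len(kept), length(pars)),
               parameter = rep(pars, each = kept),
               value = as.vector(chains$draws[, k, pars]),
               stringsAsFactors = FALSE)
  }))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order on a synthetic study:
#' simulate the cohort; fit the requested model variants per suggestion
#' group; compare variants by DIC; compute posterior-probability group
#' contrasts; run the bootstrap mediation; fit per-subject valuation
#' regressions with second-level t-tests; and write a report with the
#' correlation utilities.  Every output CSV/JSON is listed in a manifest
#' with MD5 content hashes, and the log records seeds, retained draw
#' counts and psrf summaries.
#'
#' @param config a [run_config()].
#' @return The manifest (data.frame of files and hashes), invisibly; all
#'   outputs are written under `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("seed: %d", config$truth$seed))
  written <- character(0)

  study <- generate_study(config$truth)
  if ("simulate" %in% config$stages)
    written <- c(written, write_synthetic_dataset(study, config$out_dir))

  need_fit <- any(c("fit", "compare", "groupdiff") %in% config$stages)
  fits <- NULL
  if (need_fit) {
    sm <- config$sampler
    groups <- levels(study$participants$group)
    fits <- list()
    dic_rows <- list()
    for (g in groups) {
      ids <- study$participants$participant_id[study$participants$group == g]
      tr <- study$trials[study$trials$participant_id %in% ids, ]
      for (v in config$variants) {
        if (v != "two_weight" && !"compare" %in% config$stages) next
        model <- build_ddm_model(tr, variant = v)
        seeds <- if (is.null(sm$seeds)) NULL
                 else sm$seeds + 100L * match(g, groups) +
                      10L * match(v, config$variants)
        ch <- sample_posterior(model, n_chains = sm$n_chains,
                               n_iter = sm$n_iter, burn_in = sm$burn_in,
                               thin = sm$thin, seeds = seeds)
        if (v == "two_weight") {
          fits[[g]] <- ch
          pt <- psrf_table(ch)
          log_lines <- c(log_lines, sprintf(
            "fit %s/%s: %d retained draws x %d chains, max psrf = %.4f",
            g, v, dim(ch$draws)[1], ch$n_chains, max(pt$psrf)))
        }
        dic_rows[[paste(g, v)]] <- data.frame(
          group = g, variant = v,
          dic = dic(concat_chains(ch, "deviance")),
          stringsAsFactors = FALSE)
      }
      long <- chains_to_long(fits[[g]], g, "two_weight")
      written <- c(written, write_csv_atomic(
        long, file.path(config$out_dir, sprintf("posterior_%s.csv", g))))
    }
    if ("compare" %in% config$stages) {
      dic_tab <- do.call(rbind, dic_rows)
      ranked <- do.call(rbind, lapply(split(dic_tab, dic_tab$group),
        function(d) {
          cm <- compare_models(stats::setNames(d$dic, d$variant))
          cm$group <- d$group[1]
          cm
        }))
      rownames(ranked) <- NULL
      written <- c(written, write_csv_atomic(
        ranked, file.path(config$out_dir, "dic_comparison.csv")))
    }
    if ("groupdiff" %in% config$stages) {
      contrasts <- group_contrast_table(fits)
      written <- c(written, write_csv_atomic(
        contrasts, file.path(config$out_dir, "group_contrasts.csv")))
    }
  }

  if ("mediate" %in% config$stages) {
    res <- bootstrap_mediation(study$mediation, n_boot = config$n_boot,
                               seed = config$mediation_seed,
                               roi = study$mediation$roi[1])
    gate <- bonferroni_gate(res$p[["ab"]])
    med_tab <- data.frame(roi = res$roi, path = names(res$estimates),
                          estimate = unname(res$estimates),
                          se = unname(res$se), p = unname(res$p),
                          stringsAsFactors = FALSE)
    med_tab$bonferroni_threshold <- gate$threshold
    med_tab$significant <- med_tab$p < gate$threshold
    written <- c(written, write_csv_atomic(
      med_tab, file.path(config$out_dir, "mediation_results.csv")))
  }

  if ("valuation" %in% config$stages) {
    betas <- do.call(rbind, lapply(
      split(study$trials, study$trials$participant_id), valuation_glm))
    betas$group <- study$participants$group[
      match(betas$participant_id, study$participants$participant_id)]
    ttests <- second_level_ttests(split(betas, betas$group))
    written <- c(written,
                 write_csv_atomic(betas, file.path(config$out_dir,
                                                   "valuation_betas.csv")),
                 write_csv_atomic(ttests, file.path(config$out_dir,
                                                    "valuation_ttests.csv")))
  }

  if ("report" %in% config$stages) {
    # per-participant calorie-density/value correlations by calorie level
    rows <- lapply(split(study$trials, study$trials$participant_id),
      function(tr) {
        lab <- calorie_median_split(tr$calorie_density)
        data.frame(
          participant_id = tr$participant_id[1],
          r_low = suppressWarnings(
            stats::cor(tr$calorie_density[lab == "low"],
                       tr$sv[lab == "low"])),
          r_high = suppressWarnings(
            stats::cor(tr$calorie_density[lab == "high"],
                       tr$sv[lab == "high"])))
      })
    written <- c(written, write_csv_atomic(
      do.call(rbind, rows),
      file.path(config$out_dir, "calorie_correlations.csv")))
  }

  log_path <- file.path(config$out_dir, "run.log")
  writeLines(log_lines, log_path)
  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   file.path(config$out_dir, "manifest.json"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
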