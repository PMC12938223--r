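#' Classification accuracy
#'
#' @param predictions predicted integer labels.
#' @param truth true integer labels, same length.
#' @return fraction of exact matches in `[0, 1]`.
#' @export
evaluateAccuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth) || length(truth) < 1L)
    stop("predictions and truth must have equal positive length",
         call. = FALSE)
  mean(as.integer(predictions) == as.integer(truth))
}

#' Paired Wilcoxon signed-rank test on per-subject scores
#'
#' Two-sided signed-rank test on paired differences, the convention used to
#' compare strategies on per-subject mean accuracies. Zero differences are
#' dropped before ranking; if none remain the p-value is 1 by convention.
#' For `n <= 25` untied differences the exact null distribution is used
#' (e.g. nine subjects, all differences of one sign: p = 2/2^9 ~ 0.0039).
#'
#' @param scoresA,scoresB numeric vectors of paired per-subject scores.
#' @return two-sided p-value.
#' @export
wilcoxonPaired <- function(scoresA, scoresB) {
  if (length(scoresA) != length(scoresB))
    stop("paired scores must have equal length", call. = FALSE)
  d <- scoresA - scoresB
  d <- d[d != 0]
  if (!length(d)) return(1)
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)$p.value)
}

#' Default benchmark arms
#'
#' The strategy/budget grid of the reference synthetic benchmark: the five
#' main strategies fine-tuned on the full training half (8 trials per class
#' under the default population), plus the few-shot sweep of CE-only and
#' regularized transfer at reduced budgets 0.25 and 0.5 (budget 1 rows
#' double as the few-shot full-budget arm).
#'
#' @return `data.frame` with columns `strategy` and `budget`.
#' @export
defaultBenchmarkArms <- function() {
  rbind(
    data.frame(strategy = c("original", "tl", "tl_msfs", "rand_pos",
                            "msfs_nogate"),
               budget = 1),
    data.frame(strategy = rep(c("tl", "tl_msfs"), times = 2),
               budget = rep(c(0.25, 0.5), each = 2)))
}

#' Reference benchmark configuration
#'
#' The package's fixed desk-scale study conditions: the default
#' [SynthSpec()] population (4 subjects, 2 classes, 16 trials per class),
#' the default [TransferPlan()] (60 pretraining epochs, 200 fine-tuning
#' epochs, batch 8, Adam at lr 0.001 / weight decay 0.009), the default
#' gate (omega 1, threshold 0.2), and the arms of
#' [defaultBenchmarkArms()].
#'
#' @param seeds run seeds (each seed redraws the population and the
#'   training randomness).
#' @return a config list for [runExperiment()].
#' @export
benchmarkConfig <- function(seeds = 1:10) {
  list(spec = SynthSpec(), plan = TransferPlan(), gate = GateConfig(),
       arms = defaultBenchmarkArms(), seeds = as.integer(seeds))
}

#' Run a multi-strategy transfer experiment
#'
#' Executes the leave-one-subject-out protocol for every `(strategy,
#' budget)` arm over all run seeds: per seed a fresh synthetic population is
#' drawn, each subject in turn is the target (half-split into train/test),
#' the source pool is pretrained once per target and every arm fine-tunes
#' from that shared initialization on the (budget-subsampled) target
#' training split. Identical configs produce identical results tables.
#'
#' @param config list with elements `spec` ([SynthSpec-class]), `plan`
#'   ([TransferPlan-class]), `gate` ([GateConfig-class]), `arms`
#'   (`data.frame(strategy, budget)`), `seeds` (integer vector), and
#'   optionally `outDir`.
#' @return list with `results` (rows: subject, strategy, seed, budget,
#'   split, accuracy), `summary` (mean accuracy per strategy x budget),
#'   `pvalues` (paired Wilcoxon vs the CE-only transfer arm at the same
#'   budget, on per-subject means), and `manifest`.
#' @export
runExperiment <- function(config) {
  spec0 <- config$spec; plan <- config$plan; gate <- config$gate
  arms <- config$arms; seeds <- config$seeds
  stopifnot(is(spec0, "SynthSpec"), is(plan, "TransferPlan"),
            is(gate, "GateConfig"), is.data.frame(arms), length(seeds) >= 1L)
  valid <- c("original", "tl", "tl_msfs", "rand_pos", "msfs_nogate")
  bad <- setdiff(arms$strategy, valid)
  if (length(bad))
    stop("invalid strategy: ", paste(bad, collapse = ", "),
         "; valid: ", paste(valid, collapse = ", "), call. = FALSE)
  rows <- list()
  for (seed in seeds) {
    spec <- spec0
    spec@seed <- deriveSeed(seed, 23, spec0@seed)
    subjects <- generateSyntheticSubjects(spec)
    splits <- lapply(seq_along(subjects), function(i)
      splitDataset(subjects[[i]], deriveSeed(seed, 3, i)))
    for (i in seq_along(subjects)) {
      pool <- poolDatasets(lapply(splits[-i], `[[`, "train"))
      template <- freshModel(listTemplate(subjects[[i]], plan),
                             deriveSeed(seed, 5, i))
      pre <- pretrain(template, pool, plan, seed = deriveSeed(seed, 7, i))
      train <- splits[[i]]$train
      for (a in seq_len(nrow(arms))) {
        b <- arms$budget[a]
        keep <- stratifiedSubsample(trialLabels(train), b,
                                    deriveSeed(seed, 9, i, round(b * 1000)))
        acc <- runArm(arms$strategy[a], pre, template, train[keep],
                      splits[[i]]$test, plan, gate,
                      seed = deriveSeed(seed, 13, i))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subjectId(subjects[[i]]), strategy = arms$strategy[a],
          seed = seed, budget = b, split = "test", accuracy = acc,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(accuracy ~ strategy + budget, data = results,
                              FUN = mean)
  names(summary)[names(summary) == "accuracy"] <- "meanAccuracy"
  pvalues <- experimentPvalues(results)
  manifest <- list(configHash = configHash(list(
                     spec = spec0, plan = plan, gate = gate, arms = arms,
                     seeds = seeds)),
                   seeds = seeds,
                   nSubjects = spec0@nSubjects,
                   package = as.character(utils::packageVersion("msfs")),
                   rVersion = R.version.string)
  out <- list(results = results, summary = summary, pvalues = pvalues,
              manifest = manifest)
  if (!is.null(config$outDir)) writeExperiment(out, config$outDir)
  out
}

# Per-subject means over seeds, then paired Wilcoxon of every arm against
# the CE-only transfer arm at the same budget.
experimentPvalues <- function(results) {
  out <- list()
  for (b in unique(results$budget)) {
    sub <- results[results$budget == b, ]
    if (!"tl" %in% sub$strategy) next
    base <- stats::aggregate(accuracy ~ subject, sub[sub$strategy == "tl", ],
                             mean)
    for (st in setdiff(unique(sub$strategy), "tl")) {
      cmp <- stats::aggregate(accuracy ~ subject,
                              sub[sub$strategy == st, ], mean)
      m <- merge(base, cmp, by = "subject", suffixes = c(".tl", ".cmp"))
      out[[length(out) + 1L]] <- data.frame(
        strategy = st, baseline = "tl", budget = b,
        p = wilcoxonPaired(m$accuracy.cmp, m$accuracy.tl))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(strategy = character(), baseline = character(),
               budget = numeric(), p = numeric())
}

writeExperiment <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(out$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(out$pvalues, file.path(dir, "pvalues.csv"),
                   row.names = FALSE)
  writeLines(c(paste0("configHash: ", out$manifest$configHash),
               paste0("seeds: ", paste(out$manifest$seeds, collapse = " ")),
               paste0("package: ", out$manifest$package),
               paste0("r: ", out$manifest$rVersion)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
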