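#' @name mdr
#' @title Multifactor dimensionality reduction (MDR)
#'
#' @description
#' From-scratch MDR for small SNP panels. A k-locus combination collapses
#' the 3^k multi-locus genotype cells into a one-dimensional high/low-risk
#' attribute: a cell is high risk when its case:control ratio reaches the
#' ratio of cases to controls among the individuals entering the table
#' (the canonical unbalanced-design threshold, not 1.0). Models are scored
#' by balanced accuracy under stratified 10-fold cross-validation;
#' cross-validation consistency (CVC) counts the folds in which a
#' combination is the best of its size on training balanced accuracy; the
#' best overall model maximizes testing balanced accuracy (ties: higher
#' CVC, then fewer loci). Significance comes from a label-permutation test
#' that re-runs the full search on each permutation, so the null
#' distribution reflects model selection.
NULL

# integer cell index (1..3^k) per sample; NA when any combo genotype missing
combo_cells <- function(panel, combo) {
  jj <- vapply(combo, function(s) match_snp(panel, s), 0L)
  g <- panel$genotypes[, jj, drop = FALSE]
  cells <- rep(1L, nrow(g))
  mult <- 1L
  for (k in seq_along(jj)) {
    cells <- cells + g[, k] * mult
    mult <- mult * 3L
  }
  cells
}

cell_tuples <- function(k) {
  as.matrix(do.call(expand.grid, rep(list(0:2), k)))
}

#' Case/control counts per multi-locus genotype cell
#'
#' Tabulates complete-data individuals (no missing genotype at any combo
#' SNP) into the 3^k genotype cells of a SNP combination. The risk
#' threshold carried with the table is the case:control ratio of the
#' individuals entering it.
#'
#' @param panel a [genotype_panel].
#' @param combo character vector of distinct SNP ids.
#' @return A list of class `cell_table`: `combo`, `tuples` (3^k x k dosage
#'   matrix), `cases`, `controls` (counts per cell), `threshold`,
#'   `n_case`, `n_control`.
#' @export
cell_counts <- function(panel, combo) {
  if (!length(combo) || anyDuplicated(combo))
    stop("combo must be a non-empty set of distinct SNPs")
  cells <- combo_cells(panel, combo)
  ok <- !is.na(cells)
  if (!any(ok))
    stop("empty-table error: every individual is missing a combo genotype")
  is_case <- panel$phenotype == "case"
  nbins <- 3L^length(combo)
  ca <- tabulate(cells[ok & is_case], nbins)
  co <- tabulate(cells[ok & !is_case], nbins)
  if (sum(co) == 0)
    stop("empty-table error: no controls enter the table")
  structure(list(combo = combo, tuples = cell_tuples(length(combo)),
                 cases = ca, controls = co,
                 threshold = sum(ca) / sum(co),
                 n_case = sum(ca), n_control = sum(co)),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> ", paste(x$combo, collapse = " x "), ", threshold ",
      round(x$threshold, 3), "\n", sep = "")
  seen <- x$cases + x$controls > 0
  df <- data.frame(cell = apply(x$tuples[seen, , drop = FALSE], 1, paste,
                                collapse = "/"),
                   cases = x$cases[seen], controls = x$controls[seen])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Label genotype cells high or low risk
#'
#' A cell is high risk when `cases/controls >= threshold` (a cell with
#' cases but zero controls is high; ties go to high, deterministically).
#' Cells unobserved in the table follow the empty-cell policy: `"low"`
#' (default) or `"exclude"` (such individuals are dropped from scoring at
#' prediction time).
#'
#' @param table a [cell_counts()] result.
#' @param unseen empty-cell policy, `"low"` or `"exclude"`.
#' @return A list of class `mdr_risk_model`: `combo`, `high` (logical per
#'   cell), `seen`, `unseen`, `threshold`, plus the training counts used
#'   for ranking scores.
#' @export
classify_cells <- function(table, unseen = c("low", "exclude")) {
  unseen <- match.arg(unseen)
  ca <- table$cases; co <- table$controls
  high <- ifelse(co > 0, ca / co >= table$threshold, ca > 0)
  structure(list(combo = table$combo, high = high, seen = ca + co > 0,
                 unseen = unseen, threshold = table$threshold,
                 cases = ca, controls = co),
            class = "mdr_risk_model")
}

#' @export
print.mdr_risk_model <- function(x, ...) {
  cat("<mdr_risk_model> ", paste(x$combo, collapse = " x "), ": ",
      sum(x$high & x$seen), " high / ", sum(!x$high & x$seen),
      " low risk cells (threshold ", round(x$threshold, 3),
      ", unseen -> ", x$unseen, ")\n", sep = "")
  invisible(x)
}

#' Predict case/control from an MDR risk model
#'
#' @param object an `mdr_risk_model`.
#' @param panel a [genotype_panel].
#' @param ... unused.
#' @return Character vector of `"case"`/`"control"` predictions, `NA` for
#'   individuals with a missing combo genotype (or, under the `"exclude"`
#'   policy, an unseen cell).
#' @export
predict.mdr_risk_model <- function(object, panel, ...) {
  cells <- combo_cells(panel, object$combo)
  pred <- rep(NA_character_, length(cells))
  ok <- !is.na(cells)
  if (object$unseen == "exclude") ok <- ok & object$seen[cells]
  pred[ok] <- ifelse(object$high[cells[ok]], "case", "control")
  pred
}

#' Balanced accuracy of a risk model on a panel subset
#'
#' (sensitivity + specificity) / 2, predicting case for high-risk cells and
#' control for low-risk cells. Undefined (NA, with a warning) when the
#' subset lacks one of the classes among scored individuals.
#'
#' @param model an `mdr_risk_model`.
#' @param panel a [genotype_panel] (typically a held-out subset).
#' @return Balanced accuracy in `[0, 1]`, or `NA`.
#' @export
balanced_accuracy <- function(model, panel) {
  pred <- predict(model, panel)
  ok <- !is.na(pred)
  is_case <- panel$phenotype == "case"
  n_ca <- sum(ok & is_case); n_co <- sum(ok & !is_case)
  if (n_ca == 0L || n_co == 0L) {
    warning("balanced accuracy undefined: one class absent among scored individuals")
    return(NA_real_)
  }
  sens <- sum(pred == "case" & is_case, na.rm = TRUE) / n_ca
  spec <- sum(pred == "control" & !is_case, na.rm = TRUE) / n_co
  (sens + spec) / 2
}

# seed-fixed stratified fold assignment, shared across combos
stratified_folds <- function(is_case, n_folds, seed) {
  with_seed(seed, {
    f <- integer(length(is_case))
    for (cls in c(TRUE, FALSE)) {
      idx <- which(is_case == cls)
      f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    f
  })
}

# core CV engine: per-fold training/testing BA for one combo's cell vector.
# Training counts are derived by subtracting the fold's counts from the
# totals, so each fold costs two small tabulations.
eval_combo_cv <- function(cells, nbins, is_case, fold_id, n_folds,
                          threshold_ratio = NULL, unseen_low = TRUE) {
  ok <- !is.na(cells)
  ca_all <- tabulate(cells[ok & is_case], nbins)
  co_all <- tabulate(cells[ok & !is_case], nbins)
  train_ba <- test_ba <- rep(NA_real_, n_folds)
  for (f in seq_len(n_folds)) {
    te <- ok & fold_id == f
    ca_te <- tabulate(cells[te & is_case], nbins)
    co_te <- tabulate(cells[te & !is_case], nbins)
    ca_tr <- ca_all - ca_te
    co_tr <- co_all - co_te
    n_ca <- sum(ca_tr); n_co <- sum(co_tr)
    if (n_ca == 0 || n_co == 0) next
    thr <- if (is.null(threshold_ratio)) n_ca / n_co else threshold_ratio
    high <- ifelse(co_tr > 0, ca_tr / co_tr >= thr, ca_tr > 0)
    if (!unseen_low) {
      seen <- ca_tr + co_tr > 0
      ca_te <- ca_te * seen; co_te <- co_te * seen
    }
    train_ba[f] <- (sum(ca_tr[high]) / n_ca + sum(co_tr[!high]) / n_co) / 2
    nte_ca <- sum(ca_te); nte_co <- sum(co_te)
    if (nte_ca > 0 && nte_co > 0)
      test_ba[f] <- (sum(ca_te[high]) / nte_ca +
                     sum(co_te[!high]) / nte_co) / 2
  }
  list(train_ba = train_ba, test_ba = test_ba)
}

#' Stratified cross-validation of one SNP combination
#'
#' Folds are stratified by case/control status and fixed by `seed`, so every
#' combination evaluated with the same seed shares the same folds (paired
#' comparisons stay valid). In each fold the cell labels are fitted on the
#' nine training parts and evaluated on the held-out part; a fold whose
#' training or test part lacks a class is skipped with a warning.
#'
#' @param panel a [genotype_panel].
#' @param combo character vector of SNP ids.
#' @param folds number of folds (default 10).
#' @param seed integer seed fixing the fold assignment.
#' @param unseen empty-cell policy for testing-fold cells absent from
#'   training (`"low"` or `"exclude"`).
#' @return A list of class `mdr_cv`: `combo`, per-fold data frame `folds`
#'   (`fold`, `training_ba`, `testing_ba`), and the fold-averaged
#'   `training_ba` / `testing_ba`.
#' @export
cross_validate <- function(panel, combo, folds = 10L, seed = 1L,
                           unseen = c("low", "exclude")) {
  unseen <- match.arg(unseen)
  is_case <- panel$phenotype == "case"
  if (sum(is_case) < folds || sum(!is_case) < folds)
    stop("need at least ", folds, " cases and controls for ", folds, "-fold CV")
  fold_id <- stratified_folds(is_case, folds, seed)
  cells <- combo_cells(panel, combo)
  r <- eval_combo_cv(cells, 3L^length(combo), is_case, fold_id, folds,
                     unseen_low = unseen == "low")
  if (anyNA(r$train_ba) || anyNA(r$test_ba))
    warning("fold(s) with an empty class were skipped")
  structure(list(combo = combo,
                 folds = data.frame(fold = seq_len(folds),
                                    training_ba = r$train_ba,
                                    testing_ba = r$test_ba),
                 training_ba = mean(r$train_ba, na.rm = TRUE),
                 testing_ba = mean(r$test_ba, na.rm = TRUE)),
            class = "mdr_cv")
}

#' Exhaustive MDR model search
#'
#' Enumerates every k-locus combination for each k in `k_range`, evaluates
#' each by stratified cross-validation (shared folds), and reports per size
#' the combination with the highest mean testing balanced accuracy,
#' together with its cross-validation consistency — the number of folds in
#' which it was the fold's best-of-size on training balanced accuracy. The
#' overall best model maximizes testing BA (ties: higher CVC, then fewer
#' loci). With `n_perm > 0` a permutation p-value is attached to the best
#' model by re-running the whole search on permuted labels (see
#' [permutation_pvalue()]).
#'
#' @param panel a [genotype_panel].
#' @param k_range integer vector of model sizes to search.
#' @param folds number of CV folds.
#' @param seed integer seed (folds + permutations).
#' @param n_perm permutations for the best model's p-value (0 = none).
#' @param snps SNP ids to search over (default: all panel SNPs).
#' @param unseen empty-cell policy.
#' @return A list of class `mdr_search`: `summary` (one row per k: `k`,
#'   `combo`, `training_ba`, `testing_ba`, `cvc`), `best` (list `combo`,
#'   `k`, `training_ba`, `testing_ba`, `cvc`, `perm_p`), `models` (per-k
#'   full tables), `folds`, `seed`.
#' @export
mdr_search <- function(panel, k_range = 1:2, folds = 10L, seed = 1L,
                       n_perm = 0L, snps = panel$snps$snp_id,
                       unseen = c("low", "exclude")) {
  unseen <- match.arg(unseen)
  if (max(k_range) > length(snps))
    stop("k_range exceeds the number of SNPs")
  is_case <- panel$phenotype == "case"
  if (sum(is_case) < folds || sum(!is_case) < folds)
    stop("need at least ", folds, " cases and controls for ", folds, "-fold CV")
  fold_id <- stratified_folds(is_case, folds, seed)
  prep <- mdr_prepare(panel, k_range, snps)
  res <- mdr_eval_all(prep, is_case, fold_id, folds, unseen == "low")

  per_k <- lapply(seq_along(prep$combos_by_k), function(ki) {
    combos <- prep$combos_by_k[[ki]]
    tr <- res$train_ba[[ki]]; te <- res$test_ba[[ki]]
    cvc <- integer(ncol(combos))
    for (f in seq_len(folds)) {
      row <- tr[f, ]
      if (all(is.na(row))) next
      b <- which.max(row)
      cvc[b] <- cvc[b] + 1L
    }
    data.frame(k = nrow(combos),
               combo = apply(combos, 2L, paste, collapse = ","),
               training_ba = colMeans(tr, na.rm = TRUE),
               testing_ba = colMeans(te, na.rm = TRUE),
               cvc = cvc, stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, lapply(per_k, function(tab) {
    best <- order(-tab$testing_ba, -tab$cvc)[1L]
    tab[best, , drop = FALSE]
  }))
  rownames(summary) <- NULL
  ord <- order(-summary$testing_ba, -summary$cvc, summary$k)
  best_row <- summary[ord[1L], ]
  best <- list(combo = strsplit(best_row$combo, ",")[[1L]], k = best_row$k,
               training_ba = best_row$training_ba,
               testing_ba = best_row$testing_ba,
               cvc = best_row$cvc, perm_p = NA_real_)
  if (n_perm > 0L)
    best$perm_p <- permutation_pvalue(panel, combo = NULL, n_perm = n_perm,
                                      seed = seed, k_range = k_range,
                                      folds = folds, snps = snps,
                                      unseen = unseen,
                                      statistic = "search_best",
                                      observed = best$testing_ba)
  structure(list(summary = summary, best = best, models = per_k,
                 folds = folds, seed = seed),
            class = "mdr_search")
}

#' @export
print.mdr_search <- function(x, ...) {
  cat("<mdr_search> best model: ", paste(x$best$combo, collapse = " x "),
      sprintf(" (testing BA %.4f, CVC %d/%d%s)\n", x$best$testing_ba,
              x$best$cvc, x$folds,
              if (!is.na(x$best$perm_p))
                sprintf(", perm p = %.4g", x$best$perm_p) else ""), sep = "")
  print(transform(x$summary, training_ba = round(training_ba, 4),
                  testing_ba = round(testing_ba, 4)), row.names = FALSE)
  invisible(x)
}

mdr_prepare <- function(panel, k_range, snps) {
  combos_by_k <- lapply(k_range, function(k) utils::combn(snps, k))
  cells_by_k <- lapply(combos_by_k, function(combos)
    lapply(seq_len(ncol(combos)), function(j)
      combo_cells(panel, combos[, j])))
  list(combos_by_k = combos_by_k, cells_by_k = cells_by_k, k_range = k_range)
}

mdr_eval_all <- function(prep, is_case, fold_id, folds, unseen_low) {
  train_ba <- list(); test_ba <- list()
  for (ki in seq_along(prep$combos_by_k)) {
    k <- nrow(prep$combos_by_k[[ki]])
    nbins <- 3L^k
    cl <- prep$cells_by_k[[ki]]
    tr <- te <- matrix(NA_real_, folds, length(cl))  # folds x combos
    for (j in seq_along(cl)) {
      r <- eval_combo_cv(cl[[j]], nbins, is_case, fold_id, folds,
                         unseen_low = unseen_low)
      tr[, j] <- r$train_ba
      te[, j] <- r$test_ba
    }
    train_ba[[ki]] <- tr
    test_ba[[ki]] <- te
  }
  list(train_ba = train_ba, test_ba = test_ba)
}

#' Permutation p-value for an MDR model
#'
#' Case/control labels are permuted `n_perm` times (fold structure held
#' fixed) and the cross-validated testing balanced accuracy recomputed per
#' permutation; `p = (r + 1) / (n_perm + 1)` where `r` counts permutations
#' reaching the observed statistic. Two statistics are available:
#' * `"search_best"` (default) — the maximum mean testing BA over the whole
#'   combo search is recomputed on each permutation, so the null accounts
#'   for model selection. This is the p-value [mdr_search()] attaches.
#' * `"combo"` — the mean testing BA of one fixed combination.
#'
#' @param panel a [genotype_panel].
#' @param combo SNP ids (required for `statistic = "combo"`).
#' @param n_perm number of permutations (>= 99 recommended).
#' @param seed integer seed (folds + permutations).
#' @param k_range,snps search space for `statistic = "search_best"`.
#' @param folds number of CV folds.
#' @param unseen empty-cell policy.
#' @param statistic `"search_best"` or `"combo"`.
#' @param observed optional pre-computed observed statistic (internal use).
#' @return Permutation p-value, never below `1 / (n_perm + 1)`.
#' @export
permutation_pvalue <- function(panel, combo = NULL, n_perm = 1000L, seed = 1L,
                               k_range = 1:2, folds = 10L,
                               snps = panel$snps$snp_id,
                               unseen = c("low", "exclude"),
                               statistic = c("search_best", "combo"),
                               observed = NULL) {
  statistic <- match.arg(statistic)
  unseen <- match.arg(unseen)
  if (n_perm < 99L) stop("use at least 99 permutations")
  is_case <- panel$phenotype == "case"
  fold_id <- stratified_folds(is_case, folds, seed)
  unseen_low <- unseen == "low"

  if (statistic == "combo") {
    if (is.null(combo)) stop("statistic = 'combo' requires a combo")
    cells <- combo_cells(panel, combo)
    nbins <- 3L^length(combo)
    stat_fun <- function(y) {
      r <- eval_combo_cv(cells, nbins, y, fold_id, folds,
                         unseen_low = unseen_low)
      mean(r$test_ba, na.rm = TRUE)
    }
  } else {
    prep <- mdr_prepare(panel, k_range, snps)
    stat_fun <- function(y) {
      res <- mdr_eval_all(prep, y, fold_id, folds, unseen_low)
      max(vapply(res$test_ba, function(te)
        max(colMeans(te, na.rm = TRUE), na.rm = TRUE), 0))
    }
  }
  if (is.null(observed)) observed <- stat_fun(is_case)
  r <- with_seed(seed + 1L, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      y <- sample(is_case)
      if (stat_fun(y) >= observed - 1e-12) hits <- hits + 1L
    }
    hits
  })
  (r + 1) / (n_perm + 1)
}

#' Whole-data classification metrics for an MDR risk model
#'
#' Confusion-matrix metrics from whole-panel predictions (high-risk cell ->
#' case): accuracy, precision, sensitivity, specificity, F1
#' (`2 * precision * sensitivity / (precision + sensitivity)`), the
#' Matthews correlation coefficient, and a precision-recall AUC computed as
#' average precision (step interpolation) over individuals ranked by their
#' cell's fitted case proportion. With no predicted positives the
#' precision-based metrics are returned as `NA`.
#'
#' @param model an `mdr_risk_model` (from [classify_cells()]).
#' @param panel a [genotype_panel].
#' @return A list of class `class_metrics`: `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1`, `mcc`, `pr_auc`, `n`.
#' @export
class_metrics <- function(model, panel) {
  pred <- predict(model, panel)
  ok <- !is.na(pred)
  is_case <- panel$phenotype == "case"
  if (!any(ok & is_case) || !any(ok & !is_case))
    stop("both classes must be present among scored individuals")
  tp <- sum(ok & pred == "case" & is_case)
  fp <- sum(ok & pred == "case" & !is_case)
  fn <- sum(ok & pred == "control" & is_case)
  tn <- sum(ok & pred == "control" & !is_case)
  n <- tp + fp + fn + tn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  f1 <- if (!is.na(precision) && precision + sens > 0)
    2 * precision * sens / (precision + sens) else NA_real_
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_

  # PR-AUC: rank by the cell's fitted case proportion, average precision
  cells <- combo_cells(panel, model$combo)
  score <- rep(NA_real_, length(cells))
  okc <- !is.na(cells)
  tot <- model$cases + model$controls
  score[okc] <- ifelse(tot[cells[okc]] > 0,
                       model$cases[cells[okc]] / pmax(tot[cells[okc]], 1), 0)
  use <- ok & !is.na(score)
  pr_auc <- average_precision(score[use], is_case[use])

  structure(list(accuracy = (tp + tn) / n, precision = precision,
                 sensitivity = sens, specificity = spec, f1 = f1, mcc = mcc,
                 pr_auc = pr_auc, n = n),
            class = "class_metrics")
}

# step-interpolated average precision over distinct score thresholds;
# ties are handled as blocks, avoiding optimistic within-tie ordering
average_precision <- function(score, is_pos) {
  n_pos <- sum(is_pos)
  if (n_pos == 0L) return(NA_real_)
  thr <- sort(unique(score), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(is_pos[score == t]), 0))
  np <- cumsum(vapply(thr, function(t) sum(score == t), 0))
  prec <- tp / np
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * prec)
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.3f | precision %.3f | sensitivity %.3f | ",
                     "specificity %.3f\nF1 %.3f | MCC %.3f | PR-AUC %.3f ",
                     "(n = %d)\n"),
              x$accuracy, x$precision, x$sensitivity, x$specificity,
              x$f1, x$mcc, x$pr_auc, x$n))
  invisible(x)
}

plugin_entropy <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

mutual_info <- function(x, y) {
  plugin_entropy(x) + plugin_entropy(y) -
    plugin_entropy(paste(x, y, sep = "\r"))
}

#' Entropy-based interaction analysis
#'
#' Information-gain decomposition of the class variable over SNP genotypes
#' (plug-in entropies, log base 2, reported as percent of the class entropy
#' H(C)): the main effect of SNP A is `I(A;C) / H(C)`, and the pairwise
#' interaction of A and B is `[I(A,B;C) - I(A;C) - I(B;C)] / H(C)` —
#' positive for synergy, negative for redundancy. Each quantity uses the
#' individuals with complete data for the SNPs involved. SNPs constant in
#' the complete-data subset carry zero information and are excluded from
#' clustering with a note. The interaction dendrogram applies
#' average-linkage hierarchical clustering to the dissimilarity
#' `1 - |interaction| / max |interaction|`.
#'
#' @param panel a [genotype_panel].
#' @param snps SNP ids (>= 2; default all panel SNPs).
#' @return A list of class `entropy_report`: `main_ig` (named %, per SNP),
#'   `pair_ig` (data frame `snp_a`, `snp_b`, `ig_pct`), `hclust`, `newick`,
#'   `notes`.
#' @export
entropy_analysis <- function(panel, snps = panel$snps$snp_id) {
  if (length(snps) < 2L) stop("need at least 2 SNPs")
  is_case <- panel$phenotype == "case"
  g <- panel$genotypes[, vapply(snps, function(s) match_snp(panel, s), 0L),
                       drop = FALSE]
  notes <- character(0)

  main_ig <- vapply(seq_along(snps), function(j) {
    ok <- !is.na(g[, j])
    hc <- plugin_entropy(is_case[ok])
    if (hc == 0) return(0)
    mutual_info(g[ok, j], is_case[ok]) / hc * 100
  }, 0)
  names(main_ig) <- snps
  constant <- vapply(seq_along(snps), function(j) {
    x <- g[!is.na(g[, j]), j]
    length(unique(x)) < 2L
  }, TRUE)
  if (any(constant)) {
    main_ig[constant] <- 0
    notes <- c(notes, paste0("constant SNP(s) excluded from clustering: ",
                             paste(snps[constant], collapse = ", ")))
  }

  pairs <- utils::combn(seq_along(snps), 2L)
  pair_ig <- data.frame(snp_a = snps[pairs[1L, ]], snp_b = snps[pairs[2L, ]],
                        ig_pct = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    ok <- !is.na(g[, a]) & !is.na(g[, b])
    hc <- plugin_entropy(is_case[ok])
    if (hc == 0) next
    joint <- paste(g[ok, a], g[ok, b], sep = "\r")
    ii <- mutual_info(joint, is_case[ok]) -
      mutual_info(g[ok, a], is_case[ok]) - mutual_info(g[ok, b], is_case[ok])
    pair_ig$ig_pct[k] <- ii / hc * 100
  }

  keep <- which(!constant)
  hc_obj <- NULL; newick <- NA_character_
  if (length(keep) >= 2L) {
    dm <- matrix(0, length(keep), length(keep),
                 dimnames = list(snps[keep], snps[keep]))
    mx <- max(abs(pair_ig$ig_pct[pair_ig$snp_a %in% snps[keep] &
                                   pair_ig$snp_b %in% snps[keep]]), na.rm = TRUE)
    if (is.finite(mx) && mx > 0) {
      for (k in seq_len(ncol(pairs))) {
        a <- pairs[1L, k]; b <- pairs[2L, k]
        if (constant[a] || constant[b] || is.na(pair_ig$ig_pct[k])) next
        dis <- 1 - abs(pair_ig$ig_pct[k]) / mx
        dm[snps[a], snps[b]] <- dm[snps[b], snps[a]] <- dis
      }
      hc_obj <- stats::hclust(stats::as.dist(dm), method = "average")
      newick <- ape::write.tree(ape::as.phylo(hc_obj))
    } else notes <- c(notes, "all pairwise interactions zero; no dendrogram")
  }
  structure(list(main_ig = main_ig, pair_ig = pair_ig, hclust = hc_obj,
                 newick = newick, notes = notes),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat("<entropy_report> main-effect information gain (% of H(C)):\n")
  print(round(x$main_ig, 2))
  top <- x$pair_ig[order(-abs(x$pair_ig$ig_pct)), ][1:min(3, nrow(x$pair_ig)), ]
  cat("strongest pairwise interactions (% of H(C); + synergy, - redundancy):\n")
  print(transform(top, ig_pct = round(ig_pct, 2)), row.names = FALSE)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
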