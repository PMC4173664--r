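#' Subset label maps from the stimulus catalog
#'
#' Turns the printed subset membership columns of the catalog into long
#' label maps. Labels are taken from the table as printed, not recomputed
#' from the arousal ranges; stimuli without a label are excluded from that
#' subset.
#'
#' @param catalog a [stimulus_catalog()].
#' @return tibble: `subset` (alpha/beta/gamma), `stimulus_id`, `class`.
#' @export
assign_subsets <- function(catalog = stimulus_catalog()) {
  catalog |>
    dplyr::select(stimulus_id = "id", alpha = "subset_alpha",
                  beta = "subset_beta", gamma = "subset_gamma") |>
    tidyr::pivot_longer(cols = c("alpha", "beta", "gamma"),
                        names_to = "subset", values_to = "class") |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::arrange(.data$subset, .data$stimulus_id)
}

#' Assemble the per-trial feature matrix for the picture-viewing study
#'
#' For every subject of a simulated (or imported) study-1 dataset: grab
#' gestures are detected from the flexion channels and turned into an
#' artifact mask; the skin-conductance trace is low-pass filtered and
#' decomposed; phasic features are computed from the 5 s post-onset response
#' windows (rows whose window is more than `mask_tol` masked get NA
#' phasic features); the ECG is processed to an RR series and the HRV
#' battery is computed on the 20 s stimulus windows. One row per subject and
#' stimulus presentation.
#'
#' @param dataset a `study1_dataset` from [simulate_study1()].
#' @param sc_window_len phasic response-window length in seconds.
#' @param mask_tol maximum masked fraction tolerated inside a response
#'   window before the phasic features are dropped.
#' @param min_latency earliest admissible SCR onset after stimulus onset.
#' @return tibble: `subject`, `stimulus_id`, `arousal`, phasic features,
#'   HRV features.
#' @export
segment_and_assemble <- function(dataset, sc_window_len = 5, mask_tol = 0.5,
                                 min_latency = 0) {
  stopifnot(inherits(dataset, "study1_dataset"))
  stim_dur <- dataset$protocol$stimulus_duration
  purrr::map_dfr(dataset$subjects, function(su) {
    onsets <- su$events |> dplyr::filter(.data$type == "stimulus_onset")
    grabs <- detect_grabs(su$flexion)
    mask <- build_artifact_mask(grabs, su$edr)
    dec <- deconvolve_edr(lowpass_zero_phase(su$edr))
    sc <- purrr::map_dfr(seq_len(nrow(onsets)), function(i) {
      t0 <- onsets$time[i]
      if (masked_fraction(mask, t0, t0 + sc_window_len) > mask_tol) {
        tibble::tibble(nSCR = NA_integer_, Lat = NA_real_, AmpSum = NA_real_,
                       Mean_SCR = NA_real_, Var_SCR = NA_real_,
                       AUC_SCR = NA_real_, Max_SCR = NA_real_)
      } else {
        phasic_features(dec, t0, window_len = sc_window_len,
                        min_latency = min_latency, mask = mask)
      }
    })
    peaks <- detect_qrs_pan_tompkins(su$ecg)
    rr <- rr_from_peaks(peaks)
    hrv <- hrv_window_features(
      rr, tibble::tibble(start = onsets$time, end = onsets$time + stim_dur)
    ) |> dplyr::select(-"window_start", -"window_end")
    dplyr::bind_cols(
      tibble::tibble(subject = su$subject, stimulus_id = onsets$stimulus_id,
                     arousal = onsets$arousal),
      sc, hrv
    )
  })
}

#' Univariate class-difference screening of a feature matrix
#'
#' For each feature: a Lilliefors-corrected Kolmogorov-Smirnov screen routes
#' the comparison to the parametric path (independent-samples t-test for two
#' classes, one-way ANOVA for three) when every class looks normal, and to
#' the nonparametric path (Mann-Whitney, or Kruskal-Wallis with
#' Bonferroni-corrected pairwise Mann-Whitney follow-ups) otherwise.
#' Constant features are skipped with a reason.
#'
#' @param matrix feature tibble including a `class` column; every other
#'   numeric column is screened.
#' @param alpha significance level.
#' @return tibble: `feature`, `test`, `statistic`, `p_value`, `significant`,
#'   `skipped`, `reason`, plus per-class location summaries nested in
#'   `class_summary`.
#' @export
univariate_stats <- function(matrix, alpha = 0.05) {
  if (!"class" %in% names(matrix)) abort("`matrix` needs a `class` column.")
  cls <- factor(matrix$class)
  if (nlevels(cls) < 2) abort("Need at least 2 classes.")
  feats <- names(matrix)[vapply(matrix, is.numeric, logical(1))]
  feats <- setdiff(feats, c("subject", "stimulus_id", "arousal"))
  purrr::map_dfr(feats, function(f) {
    x <- matrix[[f]]
    ok <- is.finite(x)
    xs <- x[ok]
    cs <- droplevels(cls[ok])
    summ <- tibble::tibble(
      class = levels(cs),
      mean = vapply(levels(cs), function(l) mean(xs[cs == l]), numeric(1)),
      median = vapply(levels(cs), function(l) median(xs[cs == l]), numeric(1))
    )
    base <- tibble::tibble(feature = f, class_summary = list(summ))
    if (length(unique(xs)) < 2 || nlevels(cs) < 2 || any(table(cs) < 3)) {
      return(dplyr::bind_cols(base, tibble::tibble(
        test = NA_character_, statistic = NA_real_, p_value = NA_real_,
        significant = FALSE, skipped = TRUE,
        reason = "constant feature or too few observations per class"
      )))
    }
    normal <- all(vapply(levels(cs), function(l) {
      v <- xs[cs == l]
      if (length(unique(v)) < 4 || length(v) < 5) return(FALSE)
      nortest::lillie.test(v)$p.value > alpha
    }, logical(1)))
    two <- nlevels(cs) == 2
    if (normal && two) {
      tt <- t.test(xs ~ cs)
      res <- tibble::tibble(test = "t", statistic = unname(tt$statistic),
                            p_value = tt$p.value)
    } else if (normal) {
      av <- stats::oneway.test(xs ~ cs, var.equal = TRUE)
      res <- tibble::tibble(test = "anova", statistic = unname(av$statistic),
                            p_value = av$p.value)
    } else if (two) {
      mw <- suppressWarnings(wilcox.test(xs ~ cs))
      res <- tibble::tibble(test = "mann_whitney",
                            statistic = unname(mw$statistic), p_value = mw$p.value)
    } else {
      kw <- kruskal.test(xs, cs)
      res <- tibble::tibble(test = "kruskal_wallis",
                            statistic = unname(kw$statistic), p_value = kw$p.value)
    }
    dplyr::bind_cols(base, res) |>
      dplyr::mutate(significant = is.finite(.data$p_value) & .data$p_value < alpha,
                    skipped = FALSE, reason = NA_character_)
  })
}

#' Bonferroni-corrected pairwise Mann-Whitney follow-ups
#'
#' @param x numeric vector; `class` grouping factor.
#' @param alpha significance level applied after correction.
#' @return tibble with one row per class pair.
#' @export
pairwise_mw <- function(x, class, alpha = 0.05) {
  cls <- factor(class)
  prs <- utils::combn(levels(cls), 2, simplify = FALSE)
  res <- purrr::map_dfr(prs, function(p) {
    w <- suppressWarnings(wilcox.test(x[cls == p[1]], x[cls == p[2]]))
    tibble::tibble(class1 = p[1], class2 = p[2], p_value = w$p.value)
  })
  res$p_adjusted <- pmin(1, res$p_value * nrow(res))
  res$significant <- res$p_adjusted < alpha
  res
}

#' Reduce standardized features by PCA
#'
#' Columns are z-scored (zero-variance columns dropped) and projected onto
#' the smallest number of principal components whose cumulative explained
#' variance reaches `variance_fraction`. The fitted center/scale/rotation
#' are kept so held-out rows can be projected without leakage.
#'
#' @param x numeric matrix or data frame of features (rows = observations).
#' @param variance_fraction target cumulative explained variance.
#' @return object of class `pca_reduction`: `scores`, `rotation`, `center`,
#'   `scale`, `k`, `explained`.
#' @export
pca_reduce <- function(x, variance_fraction = 0.90) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (nrow(x) < 2) abort("Need at least 2 rows.")
  keep <- apply(x, 2, function(v) stats::var(v) > 0 & all(is.finite(v)))
  if (!any(keep)) abort("All features have zero variance.")
  x <- x[, keep, drop = FALSE]
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(expl) >= variance_fraction - 1e-12)[1]
  structure(
    list(scores = pc$x[, seq_len(k), drop = FALSE],
         rotation = pc$rotation[, seq_len(k), drop = FALSE],
         center = pc$center, scale = pc$scale, k = k,
         explained = cumsum(expl)[k], kept_cols = colnames(x)),
    class = "pca_reduction"
  )
}

#' Project new rows with a fitted PCA reduction
#'
#' @param object a `pca_reduction`.
#' @param newdata matrix/data frame with the training columns.
#' @param ... unused.
#' @export
predict.pca_reduction <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)
  if (is.null(colnames(nd))) colnames(nd) <- paste0("V", seq_len(ncol(nd)))
  nd <- nd[, object$kept_cols, drop = FALSE]
  scale(nd, center = object$center, scale = object$scale) %*% object$rotation
}

#' Repeated 80/20 validation of a PCA + linear-discriminant classifier
#'
#' Monte-Carlo cross-validation: in each of `n_iter` iterations the rows are
#' split into a stratified random 80% training / 20% test partition;
#' missing entries are imputed by the training-column median,
#' standardization and PCA (90% variance) are fitted on the training rows
#' only, a pooled-covariance linear discriminant with uniform priors is
#' trained, and the test confusion matrix is normalized per true class to
#' percent. The report is the element-wise mean and SD of the confusion
#' matrices over iterations.
#'
#' @param matrix feature tibble/matrix (numeric columns only are used).
#' @param labels class label per row.
#' @param n_iter number of random splits.
#' @param train_frac training fraction.
#' @param variance_fraction PCA explained-variance target.
#' @param seed integer seed; fixed seed reproduces the splits exactly.
#' @return object of class `ldc_validation`: `mean` and `sd` confusion
#'   matrices (percent; true classes as columns), `accuracies`
#'   (per-iteration overall accuracy, percent), `k_retained`, `classes`,
#'   `n_iter`.
#' @export
ldc_cross_validate <- function(matrix, labels, n_iter = 40, train_frac = 0.80,
                               variance_fraction = 0.90, seed = NULL) {
  X <- if (is.matrix(matrix)) {
    matrix
  } else {
    as.matrix(dplyr::select(tibble::as_tibble(matrix), dplyr::where(is.numeric)))
  }
  storage.mode(X) <- "double"
  lab <- factor(labels)
  if (nlevels(lab) < 2) abort("Need at least 2 classes.")
  if (any(table(lab) < 2)) abort("Every class needs at least 2 members.")
  drop_rows <- rowSums(is.finite(X)) == 0
  X <- X[!drop_rows, , drop = FALSE]
  lab <- droplevels(lab[!drop_rows])
  ncl <- nlevels(lab)
  conf_list <- vector("list", n_iter)
  accs <- numeric(n_iter)
  ks <- integer(n_iter)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      repeat {
        tr_idx <- unlist(lapply(levels(lab), function(l) {
          idx <- which(lab == l)
          n_tr <- max(1L, min(length(idx) - 1L, round(train_frac * length(idx))))
          sample(idx, n_tr)
        }))
        te_idx <- setdiff(seq_along(lab), tr_idx)
        if (nlevels(droplevels(lab[tr_idx])) == ncl && length(te_idx) > 0) break
      }
      Xtr <- X[tr_idx, , drop = FALSE]
      Xte <- X[te_idx, , drop = FALSE]
      med <- apply(Xtr, 2, function(v) median(v[is.finite(v)]))
      med[!is.finite(med)] <- 0
      for (j in seq_len(ncol(Xtr))) {
        Xtr[!is.finite(Xtr[, j]), j] <- med[j]
        Xte[!is.finite(Xte[, j]), j] <- med[j]
      }
      red <- pca_reduce(Xtr, variance_fraction)
      ks[it] <- red$k
      Str <- red$scores
      Ste <- predict(red, Xte)
      fit <- MASS::lda(Str, grouping = droplevels(lab[tr_idx]),
                       prior = rep(1 / ncl, ncl))
      pred <- predict(fit, Ste)$class
      cm <- table(predicted = factor(pred, levels = levels(lab)),
                  truth = factor(lab[te_idx], levels = levels(lab)))
      col_n <- colSums(cm)
      cmp <- sweep(cm, 2, pmax(col_n, 1), "/") * 100
      cmp[, col_n == 0] <- NA
      conf_list[[it]] <- cmp
      accs[it] <- 100 * sum(diag(cm)) / sum(cm)
    }
  })
  arr <- simplify2array(conf_list)
  structure(
    list(
      mean = apply(arr, c(1, 2), mean, na.rm = TRUE),
      sd = apply(arr, c(1, 2), sd, na.rm = TRUE),
      accuracies = accs,
      k_retained = ks,
      classes = levels(lab),
      n_iter = n_iter
    ),
    class = "ldc_validation"
  )
}

#' @export
print.ldc_validation <- function(x, ...) {
  cat("Linear-discriminant validation over", x$n_iter, "random 80/20 splits\n")
  cat("Mean confusion matrix (%, true classes as columns):\n")
  print(round(x$mean, 2))
  cat("SD:\n")
  print(round(x$sd, 2))
  cat(sprintf("Mean accuracy: %.1f%% (SD %.1f), PCs retained (median): %d\n",
              mean(x$accuracies), sd(x$accuracies), as.integer(median(x$k_retained))))
  invisible(x)
}

#' Run the complete picture-viewing analysis
#'
#' Feature assembly, subset labelling, univariate screening and classifier
#' validation for one subset, end to end.
#'
#' @param dataset a `study1_dataset`.
#' @param subset `"alpha"`, `"beta"` or `"gamma"`.
#' @param n_iter validation iterations.
#' @param seed integer seed for the validation splits.
#' @param features optional pre-assembled feature matrix (skips assembly).
#' @return list: `features` (labelled matrix), `stats`, `validation`.
#' @export
run_study1_analysis <- function(dataset, subset = "alpha", n_iter = 40,
                                seed = NULL, features = NULL) {
  fm <- features %||% segment_and_assemble(dataset)
  maps <- assign_subsets(dataset$protocol$catalog)
  lab <- maps[maps$subset == subset, ]
  m <- dplyr::inner_join(fm, lab, by = c(stimulus_id = "stimulus_id"))
  num <- m |> dplyr::select(dplyr::where(is.numeric),
                            -dplyr::any_of(c("subject", "stimulus_id", "arousal")))
  stats_rep <- univariate_stats(dplyr::bind_cols(num, class = m$class))
  val <- ldc_cross_validate(num, m$class, n_iter = n_iter, seed = seed)
  list(features = m, stats = stats_rep, validation = val)
}
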