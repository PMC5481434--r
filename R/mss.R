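#' Candidate thresholds for one marker
#'
#' Midpoints between consecutive sorted unique observed values: every
#' distinct dichotomization of the observed data is realized by exactly one
#' candidate, which is what scanning "all threshold combinations" means
#' relative to a finite sample. For large samples the grid is capped by
#' taking evenly spaced candidates along the sorted midpoints.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param max_candidates cap on the number of candidates (default 50).
#' @return strictly increasing numeric vector of thresholds.
#' @export
candidate_thresholds <- function(values, max_candidates = 50L) {
  u <- sort(unique(values))
  if (length(u) < 2) stop("need at least 2 distinct values")
  mids <- (u[-1] + u[-length(u)]) / 2
  if (length(mids) > max_candidates) {
    keep <- unique(round(seq(1, length(mids), length.out = max_candidates)))
    mids <- mids[keep]
  }
  mids
}

#' Binarize marker values at per-marker thresholds
#'
#' @param values numeric matrix/data.frame (patients x markers) or vector.
#' @param thresholds one threshold per marker.
#' @return integer matrix of 0/1 states; 1 means strictly above threshold.
#'   With midpoint candidates no observed value can equal a threshold.
#' @export
binarize <- function(values, thresholds) {
  x <- as.matrix(values)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  stopifnot(ncol(x) == length(thresholds))
  s <- t(t(x) > thresholds) * 1L
  dimnames(s) <- dimnames(x)
  s
}

.state_index <- function(states) {
  # marker j contributes bit 2^(j-1); matches the C++ scan
  as.integer(as.matrix(states) %*% 2^(seq_len(ncol(states)) - 1))
}

.as_case01 <- function(labels, case_label) {
  if (is.logical(labels)) return(as.integer(labels))
  as.integer(as.character(labels) == case_label)
}

#' Construct a panel rule
#'
#' @param markers character vector of 1-3 marker names.
#' @param thresholds one threshold per marker.
#' @param case_states integer vector of state indices (0-based, marker 1 is
#'   the least significant bit) classified as case; all other states are
#'   control.
#' @return object of class `panel_rule`.
#' @export
panel_rule <- function(markers, thresholds, case_states) {
  stopifnot(length(markers) >= 1, length(markers) <= 3,
            length(thresholds) == length(markers),
            all(case_states >= 0), all(case_states < 2^length(markers)))
  structure(list(markers = markers, thresholds = thresholds,
                 case_states = sort(unique(as.integer(case_states)))),
            class = "panel_rule")
}

#' Fit the majority state rule
#'
#' Each observed binary marker state is labeled by its majority class;
#' ties and unobserved states are control. Per-state majority labeling is
#' the training-accuracy-optimal assignment, so a fitted rule is at least
#' as accurate on its training data as any single-threshold rule over the
#' same markers.
#'
#' @param states binary matrix (patients x markers, from [binarize()]).
#' @param labels case/control labels.
#' @param case_label value of `labels` identifying cases.
#' @param markers,thresholds carried into the returned rule (thresholds may
#'   be omitted when only state-level classification is needed).
#' @return a [panel_rule()] with an additional `state_table` data.frame
#'   (state index, per-marker bits, case and control counts, class).
#' @export
fit_state_rule <- function(states, labels, case_label = "case",
                           markers = colnames(states), thresholds = NULL) {
  states <- as.matrix(states)
  stopifnot(nrow(states) >= 1, ncol(states) >= 1, ncol(states) <= 3)
  y <- .as_case01(labels, case_label)
  stopifnot(length(y) == nrow(states))
  m <- ncol(states)
  if (is.null(markers)) markers <- paste0("m", seq_len(m))
  idx <- .state_index(states)
  n_case <- tabulate(idx[y == 1] + 1L, nbins = 2^m)
  n_ctrl <- tabulate(idx[y == 0] + 1L, nbins = 2^m)
  cls <- ifelse(n_case > n_ctrl, "case", "control")
  st <- data.frame(state = 0:(2^m - 1))
  for (j in seq_len(m))
    st[[markers[j]]] <- bitwAnd(st$state %/% 2^(j - 1), 1L)
  st$n_case <- n_case; st$n_control <- n_ctrl; st$class <- cls
  rule <- panel_rule(markers,
                     if (is.null(thresholds)) rep(NA_real_, m) else thresholds,
                     which(cls == "case") - 1L)
  rule$state_table <- st
  rule
}

#' Compact wildcard (1/0/X) form of a rule's case states
#'
#' Merges case states differing in a single marker bit into rows with `X`
#' ("either above or below"); purely a display compression, classification
#' always uses the full state set.
#'
#' @param rule a `panel_rule`.
#' @return data.frame with one column per marker (values `"0"`, `"1"`,
#'   `"X"`) and a `class` column; a single all-`X` control row when the
#'   rule has no case states.
#' @export
compact_state_table <- function(rule) {
  m <- length(rule$markers)
  if (length(rule$case_states) == 0) {
    out <- as.data.frame(as.list(setNames(rep("X", m), rule$markers)),
                         stringsAsFactors = FALSE)
    out$class <- "control"
    return(out)
  }
  # implicants as character vectors over "0","1","X"
  imps <- lapply(rule$case_states, function(s)
    as.character(bitwAnd(s %/% 2^(seq_len(m) - 1), 1L)))
  covered_states <- function(imp) {
    free <- which(imp == "X")
    base <- sum(as.integer(replace(imp, free, "0")) * 2^(seq_len(m) - 1))
    if (!length(free)) return(base)
    offs <- 0
    for (f in free) offs <- c(offs, offs + 2^(f - 1))
    base + offs
  }
  repeat {
    merged <- FALSE
    out <- list()
    used <- rep(FALSE, length(imps))
    for (i in seq_along(imps)) for (j in seq_along(imps)) {
      if (i >= j) next
      di <- which(imps[[i]] != imps[[j]])
      if (length(di) == 1 && imps[[i]][di] != "X" && imps[[j]][di] != "X") {
        cand <- replace(imps[[i]], di, "X")
        out[[length(out) + 1]] <- cand
        used[c(i, j)] <- TRUE
        merged <- TRUE
      }
    }
    imps <- unique(c(imps[!used], out))
    if (!merged) break
  }
  # drop implicants fully covered by another
  keep <- rep(TRUE, length(imps))
  for (i in seq_along(imps)) for (j in seq_along(imps)) {
    if (i == j || !keep[i]) next
    if (all(covered_states(imps[[i]]) %in% covered_states(imps[[j]])) &&
        !identical(imps[[i]], imps[[j]])) keep[i] <- FALSE
  }
  imps <- imps[keep]
  out <- as.data.frame(do.call(rbind, imps), stringsAsFactors = FALSE)
  names(out) <- rule$markers
  out$class <- "case"
  out
}

#' Classify patients with a panel rule
#'
#' @param rule a `panel_rule` with thresholds.
#' @param values data.frame/matrix containing the rule's marker columns.
#' @return factor `case`/`control`.
#' @export
classify <- function(rule, values) {
  values <- as.data.frame(values)
  missing <- setdiff(rule$markers, names(values))
  if (length(missing))
    stop("missing marker value(s): ", paste(missing, collapse = ", "))
  if (any(is.na(rule$thresholds))) stop("rule has no thresholds")
  st <- binarize(values[rule$markers], rule$thresholds)
  idx <- .state_index(st)
  factor(ifelse(idx %in% rule$case_states, "case", "control"),
         levels = c("case", "control"))
}

#' Confusion counts and derived fractions of a panel
#'
#' Either supply confusion counts directly, or a rule plus labeled data.
#'
#' @param tp,fn,fp,tn confusion counts.
#' @return object of class `panel_performance`: the four counts plus
#'   `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)` and
#'   `accuracy = (TP+TN)/total`.
#' @export
panel_performance <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0, tp + fn + fp + tn > 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 accuracy = (tp + tn) / (tp + fn + fp + tn)),
            class = "panel_performance")
}

#' @export
print.panel_performance <- function(x, ...) {
  cat(sprintf(
    "TP %d  FN %d  FP %d  TN %d | sens %.1f%%  spec %.1f%%  acc %.1f%%\n",
    x$tp, x$fn, x$fp, x$tn, 100 * x$sensitivity, 100 * x$specificity,
    100 * x$accuracy))
  invisible(x)
}

#' @rdname panel_performance
#' @param rule a `panel_rule`.
#' @param values labeled marker data.
#' @param labels case/control labels for `values`.
#' @param case_label value identifying cases.
#' @export
evaluate_panel <- function(rule, values, labels, case_label = "case") {
  stopifnot(length(labels) == nrow(as.data.frame(values)),
            nrow(as.data.frame(values)) >= 1)
  y <- .as_case01(labels, case_label)
  pred <- classify(rule, values) == "case"
  panel_performance(tp = sum(pred & y == 1), fn = sum(!pred & y == 1),
                    fp = sum(pred & y == 0), tn = sum(!pred & y == 0))
}

.mss_prepare <- function(values, labels, case_label, max_markers,
                         max_candidates) {
  X <- as.matrix(as.data.frame(values))
  storage.mode(X) <- "double"
  y <- .as_case01(labels, case_label)
  stopifnot(length(y) == nrow(X), ncol(X) >= 1)
  grids <- lapply(seq_len(ncol(X)), function(j)
    candidate_thresholds(X[, j], max_candidates))
  p <- ncol(X)
  mm <- min(max_markers, p)
  subsets <- do.call(rbind, lapply(seq_len(mm), function(m) {
    cb <- t(combn(p, m))
    cbind(cb, matrix(0L, nrow(cb), 3 - m))
  }))
  storage.mode(subsets) <- "integer"
  list(X = X, y = y, grids = grids, subsets = subsets)
}

#' Exhaustive Marker State Space panel search
#'
#' Scans every marker subset of size 1 to `max_markers` and every
#' combination of candidate thresholds (one per subset member); for each,
#' fits the majority state rule on the data and keeps it when training
#' sensitivity and specificity both reach their minima.
#'
#' @param values numeric data (patients x markers) with named columns.
#' @param labels case/control labels.
#' @param min_sens,min_spec training minima (defaults 0.80 / 0.80).
#' @param max_markers panel size limit (default 3).
#' @param max_candidates threshold-grid cap per marker (default 50).
#' @param case_label value of `labels` identifying cases.
#' @return data.frame of class `panel_search` with one row per qualifying
#'   panel: marker names, thresholds, case-state mask, confusion counts,
#'   sensitivity, specificity, accuracy; ordered by accuracy (desc), then
#'   marker names and thresholds. Attribute `n_panels` holds the count.
#'   Use [panel_rule_from_row()] to materialize a row as a `panel_rule`.
#' @export
search_panels <- function(values, labels, min_sens = 0.80, min_spec = 0.80,
                          max_markers = 3L, max_candidates = 50L,
                          case_label = "case") {
  prep <- .mss_prepare(values, labels, case_label, max_markers,
                       max_candidates)
  if (sum(prep$y) < 2 || sum(prep$y == 0) < 2)
    stop("need at least 2 patients per class")
  sc <- mss_scan_cpp(prep$X, prep$y, prep$grids, prep$subsets,
                     min_sens, min_spec, NULL, NULL, TRUE)
  nm <- colnames(prep$X)
  sub <- prep$subsets[sc$subset, , drop = FALSE]
  mk <- matrix(NA_character_, nrow(sub), 3)
  for (j in 1:3) mk[sub[, j] > 0, j] <- nm[sub[sub[, j] > 0, j]]
  out <- data.frame(
    marker1 = mk[, 1], marker2 = mk[, 2], marker3 = mk[, 3],
    t1 = sc$t1, t2 = sc$t2, t3 = sc$t3, case_mask = sc$case_mask,
    tp = sc$tp, fn = sc$fn, fp = sc$fp, tn = sc$tn,
    stringsAsFactors = FALSE)
  out$sensitivity <- with(out, ifelse(tp + fn > 0, tp / (tp + fn), NA))
  out$specificity <- with(out, ifelse(tn + fp > 0, tn / (tn + fp), NA))
  out$accuracy <- with(out, (tp + tn) / (tp + fn + fp + tn))
  o <- order(-out$accuracy, out$marker1, out$marker2, out$marker3,
             out$t1, out$t2, out$t3)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_panels") <- sc$n_panels
  class(out) <- c("panel_search", "data.frame")
  out
}

#' Materialize one row of a [search_panels()] result as a rule
#'
#' @param panels a `panel_search` data.frame.
#' @param i row index (default 1, the top panel).
#' @return a [panel_rule()].
#' @export
panel_rule_from_row <- function(panels, i = 1L) {
  row <- panels[i, ]
  mks <- stats::na.omit(c(row$marker1, row$marker2, row$marker3))
  thr <- c(row$t1, row$t2, row$t3)[seq_along(mks)]
  cs <- which(bitwAnd(row$case_mask %/% 2^(0:(2^length(mks) - 1)), 1L) == 1L) - 1L
  panel_rule(as.character(mks), thr, cs)
}

.mss_cv_core <- function(X, y, grids_fun, k, rounds, min_sens, min_spec,
                         max_markers, max_candidates, seed,
                         randomize_labels = FALSE) {
  n <- nrow(X)
  if (k > n) stop("k greater than the number of samples")
  set.seed(seed)
  acc <- matrix(NA_real_, rounds, k,
                dimnames = list(paste0("round", seq_len(rounds)),
                                paste0("split", seq_len(k))))
  npan <- matrix(0, rounds, k)
  p <- ncol(X)
  mm <- min(max_markers, p)
  subsets <- do.call(rbind, lapply(seq_len(mm), function(m) {
    cb <- t(combn(p, m))
    cbind(cb, matrix(0L, nrow(cb), 3 - m))
  }))
  storage.mode(subsets) <- "integer"
  for (r in seq_len(rounds)) {
    yr <- if (randomize_labels) rbinom(n, 1, 0.5) else y
    fold <- sample(rep(seq_len(k), length.out = n))
    for (s in seq_len(k)) {
      tr <- fold != s
      grids <- lapply(seq_len(p), function(j) {
        v <- X[tr, j]
        if (length(unique(v)) < 2) return(numeric(0))
        candidate_thresholds(v, max_candidates)
      })
      if (any(vapply(grids, length, 0L) == 0)) next
      sc <- mss_scan_cpp(X[tr, , drop = FALSE], yr[tr], grids, subsets,
                         min_sens, min_spec,
                         X[!tr, , drop = FALSE], yr[!tr], FALSE)
      npan[r, s] <- sc$n_panels
      if (sc$n_panels > 0) acc[r, s] <- 100 * sc$mean_test_accuracy
    }
  }
  cv_report(acc, n_panels = npan, seed = seed)
}

#' Build a cross-validation report from a split-accuracy matrix
#'
#' Splits where no panel met the training minima are `NA` ("no accuracies
#' are given") and stay absent: round medians are computed over present
#' splits only, and the overall value is the mean of the available round
#' medians.
#'
#' @param accuracy numeric matrix, rounds x splits, percent correct
#'   (`NA` = no qualifying panel for that split).
#' @param n_panels optional matrix of qualifying-panel counts.
#' @param seed optional seed recorded for reproducibility.
#' @return object of class `cv_report`: `accuracy`, `round_medians`,
#'   `overall` (mean of round medians), `n_panels`, `seed`.
#' @export
cv_report <- function(accuracy, n_panels = NULL, seed = NULL) {
  accuracy <- as.matrix(accuracy)
  rm_ <- apply(accuracy, 1, function(v)
    if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE))
  overall <- if (all(is.na(rm_))) NA_real_ else mean(rm_, na.rm = TRUE)
  structure(list(accuracy = accuracy, round_medians = rm_,
                 overall = overall, n_panels = n_panels, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 0, ...) {
  disp <- x$accuracy
  txt <- ifelse(is.na(disp), "—",
                paste0(formatC(disp, format = "f", digits = digits), "%"))
  med <- ifelse(is.na(x$round_medians), "—",
                paste0(formatC(x$round_medians, format = "f",
                               digits = digits), "%"))
  tab <- cbind(txt, Median = med)
  print(tab, quote = FALSE)
  cat(sprintf("Average of round medians: %s\n",
              if (is.na(x$overall)) "—"
              else paste0(formatC(x$overall, format = "f",
                                  digits = digits), "%")))
  invisible(x)
}

#' 10-fold cross-validation of the MSS search
#'
#' For each of `rounds` independent random partitions into `k` groups, each
#' group is set aside in turn, the panel search runs on the remainder
#' (threshold grids recomputed on the training samples only), every
#' qualifying panel is applied to the set-aside group, and the split's
#' value is the mean percent-correct over those panels -- absent when no
#' panel meets the training minima.
#'
#' @inheritParams search_panels
#' @param k number of folds (default 10).
#' @param rounds independent repetitions (default 5).
#' @param seed integer seed; the full report is reproducible from it.
#' @return a [cv_report()].
#' @export
cross_validate <- function(values, labels, k = 10L, rounds = 5L,
                           min_sens = 0.80, min_spec = 0.80,
                           max_markers = 3L, max_candidates = 50L,
                           seed = 1L, case_label = "case") {
  X <- as.matrix(as.data.frame(values))
  storage.mode(X) <- "double"
  y <- .as_case01(labels, case_label)
  .mss_cv_core(X, y, NULL, k, rounds, min_sens, min_spec, max_markers,
               max_candidates, seed, randomize_labels = FALSE)
}

#' Random-label null of the cross-validated search
#'
#' Replaces the class labels by an independent fair-coin assignment per
#' sample (class sizes as drawn, not fixed) once per round, then runs the
#' identical cross-validation machinery. On data where the true labels are
#' predictable, nearly all null splits should yield no qualifying panels.
#'
#' @inheritParams cross_validate
#' @export
random_label_null <- function(values, labels = NULL, k = 10L, rounds = 5L,
                              min_sens = 0.80, min_spec = 0.80,
                              max_markers = 3L, max_candidates = 50L,
                              seed = 1L, case_label = "case") {
  X <- as.matrix(as.data.frame(values))
  storage.mode(X) <- "double"
  y <- rep(0L, nrow(X))  # replaced per round
  .mss_cv_core(X, y, NULL, k, rounds, min_sens, min_spec, max_markers,
               max_candidates, seed, randomize_labels = TRUE)
}
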